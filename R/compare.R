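# Peak-set comparison across conditions, metagene profiling over a
# standardised transcript model (10 bins 5'UTR, 50 CDS, 40 3'UTR), region
# proportions, and a fixed-motif (GGACU) enrichment check.

#' Compare two peak sets called on the same annotation
#'
#' Two peaks are "common" when they lie on the same gene and share at least
#' 1 nt. A gene is a common m6A gene when it carries at least one common
#' peak; genes whose peaks never overlap the other condition's are unique to
#' their condition.
#'
#' @param peaks_a,peaks_b Peak tibbles (`gene_id`, `start`, `end`, ...), e.g.
#'   per-condition slices of `tidy(call_peaks(...))`.
#' @param models Optional transcript table used to verify both sets come
#'   from the same annotation.
#' @return A list of class `peak_comparison`: `common_pairs` (tibble of
#'   overlapping A/B peak pairs), `unique_a`, `unique_b` (peak tibbles),
#'   and character vectors `common_genes`, `unique_genes_a`, `unique_genes_b`.
#' @export
compare_peak_sets <- function(peaks_a, peaks_b, models = NULL) {
  if (!is.null(models) && anyDuplicated(models$gene_id)) {
    abort("annotation mismatch: more than one model per gene",
          class = "meripscan_input_error")
  }
  a <- peaks_a |> mutate(.id_a = dplyr::row_number())
  b <- peaks_b |> mutate(.id_b = dplyr::row_number())
  pairs <- inner_join(
    select(a, ".id_a", "gene_id", start_a = "start", end_a = "end"),
    select(b, ".id_b", "gene_id", start_b = "start", end_b = "end"),
    by = "gene_id", relationship = "many-to-many") |>
    filter(.data$start_a < .data$end_b, .data$start_b < .data$end_a)
  unique_a <- a |> filter(!.data$.id_a %in% pairs$.id_a) |> select(-".id_a")
  unique_b <- b |> filter(!.data$.id_b %in% pairs$.id_b) |> select(-".id_b")
  common_genes <- sort(unique(pairs$gene_id))
  out <- list(
    common_pairs = select(pairs, -".id_a", -".id_b"),
    unique_a = unique_a,
    unique_b = unique_b,
    common_genes = common_genes,
    unique_genes_a = sort(setdiff(unique(peaks_a$gene_id), common_genes)),
    unique_genes_b = sort(setdiff(unique(peaks_b$gene_id), common_genes))
  )
  class(out) <- "peak_comparison"
  out
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat("<peak_comparison>\n")
  cat(sprintf("  common peak pairs: %d\n", nrow(x$common_pairs)))
  cat(sprintf("  unique peaks: %d (A), %d (B)\n", nrow(x$unique_a), nrow(x$unique_b)))
  cat(sprintf("  genes: %d common, %d unique to A, %d unique to B\n",
              length(x$common_genes), length(x$unique_genes_a),
              length(x$unique_genes_b)))
  invisible(x)
}

#' @describeIn compare_peak_sets Gene-level classification as a tibble.
#' @param x A `peak_comparison`.
#' @param ... Unused.
#' @export
tidy.peak_comparison <- function(x, ...) {
  dplyr::bind_rows(
    tibble(gene_id = x$common_genes, class = "common"),
    tibble(gene_id = x$unique_genes_a, class = "unique_a"),
    tibble(gene_id = x$unique_genes_b, class = "unique_b")
  )
}

#' Metagene bin of a peak summit
#'
#' Places each summit on a standardised mRNA axis: 10 bins for the 5'UTR,
#' 50 for the CDS, 40 for the 3'UTR (0..99, 5' to 3'). The fractional
#' position of the summit within its region picks the bin, clamped to the
#' region's last bin.
#'
#' @param summit Transcript summit positions.
#' @param cds_start,cds_end,length The transcript's CDS offsets and length.
#' @return Integer bin indices 0..99; `NA` where a region is empty
#'   (non-coding or UTR-less models).
#' @export
metagene_bin <- function(summit, cds_start, cds_end, length) {
  utr5_len <- cds_start
  cds_len <- cds_end - cds_start
  utr3_len <- length - cds_end
  usable <- utr5_len > 0 & cds_len > 0 & utr3_len > 0 &
    summit >= 0 & summit < length
  bin <- ifelse(summit < cds_start,
                pmin(9, floor(summit / utr5_len * 10)),
                ifelse(summit < cds_end,
                       10 + pmin(49, floor((summit - cds_start) / cds_len * 50)),
                       60 + pmin(39, floor((summit - cds_end) / utr3_len * 40))))
  as.integer(ifelse(usable, bin, NA))
}

peaks_with_bins <- function(peaks, models) {
  peaks |>
    inner_join(select(models, "gene_id", "cds_start", "cds_end", "length"),
               by = "gene_id") |>
    mutate(bin = metagene_bin(.data$summit, .data$cds_start, .data$cds_end,
                              .data$length),
           region = dplyr::case_when(
             is.na(.data$bin) ~ NA_character_,
             .data$bin < 10 ~ "utr5",
             .data$bin < 60 ~ "cds",
             TRUE ~ "utr3"))
}

#' Metagene profile of a peak set
#'
#' Percentage of peak summits falling in each of 100 bins of a standardised
#' transcript (5'UTR 10 bins, CDS 50, 3'UTR 40). Peaks on transcripts with
#' an empty region (e.g. non-coding) are skipped and counted.
#'
#' @param peaks Peak tibble with `gene_id` and `summit`.
#' @param models Transcript table.
#' @return A tibble of class `metagene_profile` with `bin` (0..99),
#'   `region`, and `percent`; attributes `n_peaks` (used) and `n_skipped`.
#' @export
metagene_profile <- function(peaks, models) {
  pb <- peaks_with_bins(peaks, models)
  used <- filter(pb, !is.na(.data$bin))
  if (nrow(used) == 0L) {
    abort("no usable peaks for the metagene profile", class = "meripscan_input_error")
  }
  grid <- tibble(bin = 0:99) |>
    mutate(region = dplyr::case_when(.data$bin < 10 ~ "utr5",
                                     .data$bin < 60 ~ "cds",
                                     TRUE ~ "utr3"))
  prof <- used |>
    count(.data$bin) |>
    dplyr::right_join(grid, by = "bin") |>
    mutate(percent = 100 * dplyr::coalesce(.data$n, 0L) / nrow(used)) |>
    arrange(.data$bin) |>
    select("bin", "region", "percent")
  structure(prof, class = c("metagene_profile", class(prof)),
            n_peaks = nrow(used), n_skipped = nrow(pb) - nrow(used))
}

#' Peak proportions per mRNA region
#'
#' Fraction of peak summits in the 5'UTR, CDS and 3'UTR.
#'
#' @inheritParams metagene_profile
#' @return Tibble `region`, `n`, `fraction` (fractions sum to 1).
#' @export
region_proportions <- function(peaks, models) {
  pb <- peaks_with_bins(peaks, models) |> filter(!is.na(.data$region))
  if (nrow(pb) == 0L) {
    abort("no usable peaks for region proportions", class = "meripscan_input_error")
  }
  tibble(region = c("utr5", "cds", "utr3")) |>
    left_join(count(pb, .data$region), by = "region") |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           fraction = .data$n / sum(.data$n))
}

#' GGACU motif enrichment under peaks
#'
#' Counts fixed-motif occurrences (U and T treated alike) whose start lies
#' under a peak versus in the peak-free remainder of the same transcripts,
#' and compares the two per-nt occurrence rates with a one-sided Fisher
#' exact test.
#'
#' @param peaks Peak tibble (`gene_id`, `start`, `end`).
#' @param sequences Transcript sequences: a named character vector, a
#'   `Biostrings::DNAStringSet`/`RNAStringSet`, or a path to a FASTA file.
#' @param motif Motif string (default `"GGACU"`).
#' @return One-row tibble with occurrence counts, covered lengths, per-nt
#'   rates, `fold` enrichment and `p_value`.
#' @export
motif_enrichment <- function(peaks, sequences, motif = "GGACU") {
  seqs <- as_sequence_vector(sequences)
  motif <- gsub("U", "T", toupper(motif))
  genes <- unique(peaks$gene_id)
  missing <- setdiff(genes, names(seqs))
  if (length(missing)) {
    warn(paste0("no sequence for gene(s), skipped: ",
                paste(missing, collapse = ", ")))
    genes <- setdiff(genes, missing)
  }
  if (length(genes) == 0L) {
    abort("no transcript sequences available for any peak gene",
          class = "meripscan_input_error")
  }
  peak_hits <- bg_hits <- 0L
  peak_len <- bg_len <- 0L
  for (g in genes) {
    s <- gsub("U", "T", toupper(seqs[[g]]))
    L <- nchar(s)
    occ <- as.integer(gregexpr(motif, s, fixed = TRUE)[[1]])
    occ <- occ[occ > 0] - 1L  # 0-based motif start positions
    pk <- peaks |> filter(.data$gene_id == g) |>
      mutate(start = pmax(0, .data$start), end = pmin(L, .data$end))
    in_peak <- rep(FALSE, L)
    for (i in seq_len(nrow(pk))) {
      if (pk$end[i] > pk$start[i]) {
        in_peak[(pk$start[i] + 1):pk$end[i]] <- TRUE
      }
    }
    hit_in <- if (length(occ)) sum(in_peak[occ + 1L]) else 0L
    peak_hits <- peak_hits + hit_in
    bg_hits <- bg_hits + length(occ) - hit_in
    peak_len <- peak_len + sum(in_peak)
    bg_len <- bg_len + L - sum(in_peak)
  }
  peak_rate <- if (peak_len > 0) peak_hits / peak_len else 0
  bg_rate <- if (bg_len > 0) bg_hits / bg_len else 0
  fold <- if (peak_hits + bg_hits == 0) {
    0
  } else if (bg_rate == 0) {
    Inf
  } else {
    peak_rate / bg_rate
  }
  p <- fisher_window_test(peak_hits, bg_hits,
                          peak_len - peak_hits, bg_len - bg_hits)
  tibble(motif = motif, peak_hits = peak_hits, bg_hits = bg_hits,
         peak_len = peak_len, bg_len = bg_len,
         peak_rate = peak_rate, bg_rate = bg_rate,
         fold = fold, p_value = p)
}

as_sequence_vector <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("reading FASTA requires the Biostrings package")
    }
    ss <- Biostrings::readDNAStringSet(sequences)
    return(setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
  }
  if (inherits(sequences, "XStringSet")) {
    return(setNames(as.character(sequences),
                    sub("\\s.*$", "", names(sequences))))
  }
  if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      abort("sequences must be named by gene_id", class = "meripscan_input_error")
    }
    return(sequences)
  }
  abort("unsupported sequence container", class = "meripscan_input_error")
}
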