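# Window-level testing and peak assembly.
#
# The 2x2 Fisher table contrasts a window against the rest of its gene:
#   [ window IP      , window input       ]
#   [ gene IP - win  , gene input - win   ]
# tested one-sided toward IP enrichment (the enrichment-score filter already
# fixes the direction of interest). Raw integer counts enter the test;
# median normalisation feeds the enrichment score and reporting only.

#' One-sided Fisher exact p for IP enrichment in a window
#'
#' Exact hypergeometric tail probability P(X >= ip_in) for the 2x2 table
#' `[ip_in, input_in; ip_rest, input_rest]`, vectorised. An all-zero table
#' gives p = 1.
#'
#' @param ip_in,input_in Window IP and input fragment counts.
#' @param ip_rest,input_rest Rest-of-gene IP and input counts.
#' @return Numeric vector of p-values.
#' @examples
#' fisher_window_test(10, 0, 0, 10)  # 1 / choose(20, 10)
#' @export
fisher_window_test <- function(ip_in, input_in, ip_rest, input_rest) {
  if (any(c(ip_in, input_in, ip_rest, input_rest) < 0)) {
    abort("Fisher table entries must be non-negative", class = "meripscan_input_error")
  }
  total <- ip_in + input_in + ip_rest + input_rest
  phyper(ip_in - 1, ip_in + ip_rest, total - (ip_in + ip_rest),
         ip_in + input_in, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment over one joint family (all tested windows of a
#' dataset).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "meripscan_input_error")
  }
  p.adjust(p, method = "BH")
}

#' Median-normalised enrichment score
#'
#' `ES = (a * d) / (b * c)` with `a`, `c` the window's IP and input counts
#' and `b`, `d` the gene's median window counts: the IP:input count ratio
#' after per-gene median normalisation. When the window input count `c` is
#' zero, a pseudocount of 1/2 is added to both `a` and `c` to keep the score
#' finite.
#'
#' @param a Window IP count. @param b Gene IP median.
#' @param c Window input count. @param d Gene input median.
#' @return Numeric vector of enrichment scores.
#' @examples
#' enrichment_score(40, 10, 8, 10)  # 5
#' @export
enrichment_score <- function(a, b, c, d) {
  if (any(b <= 0) || any(d <= 0)) {
    abort("enrichment score undefined for zero-median genes (skip them upstream)",
          class = "meripscan_coverage_error")
  }
  zero <- c == 0
  ((a + 0.5 * zero) * d) / (b * (c + 0.5 * zero))
}

#' Flag positive windows
#'
#' A window is positive when its FDR-adjusted q is strictly below `q_max`
#' and `log2(ES)` is at least `min_log2_es` (both thresholds at the printed
#' defaults FDR < 0.01, log2 ES >= 1).
#'
#' @param stats Tibble with `q_value` and `es` columns.
#' @param q_max,min_log2_es Thresholds.
#' @return The tibble with a logical `positive` column.
#' @export
call_positive_windows <- function(stats, q_max = 0.01, min_log2_es = 1) {
  stats |>
    mutate(positive = .data$q_value < q_max & log2(.data$es) >= min_log2_es)
}

#' Merge overlapping positive windows into peaks
#'
#' Maximal chains of overlapping positive windows become one peak. The
#' summit is the midpoint of the constituent window with the highest ES;
#' `min_q` is the smallest constituent q. Peak-level `es` is recomputed by
#' the caller over the merged interval.
#'
#' @param positive Window-stat tibble restricted to positive windows, with
#'   `gene_id`, `start`, `end`, `es`, `q_value`.
#' @return Tibble of peaks: `gene_id`, `start`, `end`, `n_windows`,
#'   `summit`, `min_q`, `max_window_es`.
#' @export
merge_windows <- function(positive) {
  if (nrow(positive) == 0L) {
    return(tibble(gene_id = character(), start = numeric(), end = numeric(),
                  n_windows = integer(), summit = numeric(), min_q = numeric(),
                  max_window_es = numeric()))
  }
  positive |>
    arrange(.data$gene_id, .data$start) |>
    group_by(.data$gene_id) |>
    mutate(run_end = cummax(.data$end),
           new_run = .data$start >= dplyr::lag(.data$run_end, default = -Inf),
           run = cumsum(.data$new_run)) |>
    group_by(.data$gene_id, .data$run) |>
    summarise(n_windows = dplyr::n(),
              summit = {
                i <- which.max(.data$es)
                (.data$start[i] + .data$end[i]) / 2
              },
              min_q = min(.data$q_value),
              max_window_es = max(.data$es),
              # start/end last: they shadow the window columns once computed
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("gene_id", "start", "end", "n_windows", "summit", "min_q",
           "max_window_es")
}

#' Call m6A peaks from IP/input reads
#'
#' The full per-condition pipeline: extend reads to fragment length, project
#' onto each gene's longest isoform, count 100-nt windows sliding by 10 nt,
#' drop windows below 1/20 of the gene's top window in both libraries, test
#' retained windows with a one-sided Fisher exact test against the rest of
#' the gene, adjust with Benjamini-Hochberg across all tested windows,
#' flag windows with `q < fdr` and `log2(ES) >= min_log2_es`, and merge
#' overlapping positive windows into peaks. Genes with zero median or zero
#' top coverage in either library are skipped and logged.
#'
#' @param reads Tibble of aligned reads (`chrom`, `start`, `end`, `strand`,
#'   `sample` in IP/input, optional `condition`), e.g. from
#'   [read_reads_bed()] or [simulate_merip()].
#' @param models Transcript annotation; reduced to longest isoforms internally.
#' @param window,step Sliding-window geometry (nt).
#' @param fragment_length Fragment size reads are extended to (nt).
#' @param min_frac Low-coverage window exclusion fraction.
#' @param fdr FDR threshold (strict).
#' @param min_log2_es log2 enrichment-score threshold (inclusive).
#' @return An object of class `merip_call`: a list with tibbles `peaks`
#'   (per-condition peaks with recomputed peak ES), `windows` (all window
#'   statistics), and `skipped` (genes without testable coverage).
#' @export
call_peaks <- function(reads, models, window = 100, step = 10,
                       fragment_length = 150, min_frac = 1 / 20,
                       fdr = 0.01, min_log2_es = 1) {
  if (!"sample" %in% names(reads)) {
    abort("reads need a `sample` column with IP/input labels",
          class = "meripscan_input_error")
  }
  if (!"condition" %in% names(reads)) reads$condition <- "all"
  present <- reads |> distinct(.data$condition, .data$sample)
  for (cond in unique(reads$condition)) {
    have <- present$sample[present$condition == cond]
    lack <- setdiff(c("IP", "input"), have)
    if (length(lack)) {
      abort(sprintf("condition '%s' is missing its %s library", cond,
                    paste(lack, collapse = " and ")),
            class = "meripscan_input_error")
    }
  }
  models <- select_longest_isoform(models)
  extended <- extend_reads(reads, fragment_length)
  tx <- map_to_transcript(extended, models)

  conds <- sort(unique(reads$condition))
  res <- purrr::map(conds, function(cond) {
    iv <- filter(tx, .data$condition == cond)
    wins <- count_windows(iv, models, window, step)
    skipped <- wins |>
      distinct(.data$gene_id, .data$ip_median, .data$input_median,
               .data$ip_top, .data$input_top) |>
      filter(.data$ip_median == 0 | .data$input_median == 0 |
               .data$ip_top == 0 | .data$input_top == 0) |>
      mutate(condition = cond, reason = "insufficient coverage") |>
      select("condition", "gene_id", "reason")
    usable <- wins |>
      anti_join(skipped, by = "gene_id") |>
      filter_low_windows(min_frac) |>
      normalize_counts()
    gene_tot <- usable |>
      group_by(.data$gene_id) |>
      summarise(ip_total = sum(.data$ip_count),
                input_total = sum(.data$input_count), .groups = "drop")
    tested <- usable |>
      filter(.data$retained) |>
      left_join(gene_tot, by = "gene_id") |>
      mutate(p_value = fisher_window_test(.data$ip_count, .data$input_count,
                                          .data$ip_total - .data$ip_count,
                                          .data$input_total - .data$input_count),
             es = enrichment_score(.data$ip_count, .data$ip_median,
                                   .data$input_count, .data$input_median)) |>
      mutate(q_value = bh_fdr(.data$p_value)) |>
      call_positive_windows(q_max = fdr, min_log2_es = min_log2_es)
    peaks <- tested |>
      filter(.data$positive) |>
      merge_windows()
    if (nrow(peaks) > 0) {
      med <- usable |>
        distinct(.data$gene_id, .data$ip_median, .data$input_median)
      pk <- peaks |> mutate(.pid = dplyr::row_number())
      in_peak <- iv |>
        select("gene_id", iv_start = "start", iv_end = "end", "sample") |>
        inner_join(select(pk, ".pid", "gene_id", pk_start = "start",
                          pk_end = "end"),
                   by = "gene_id", relationship = "many-to-many") |>
        filter(.data$iv_start < .data$pk_end, .data$iv_end > .data$pk_start) |>
        count(.data$.pid, .data$sample) |>
        tidyr::pivot_wider(names_from = "sample", values_from = "n",
                           values_fill = 0L)
      for (col in c("IP", "input")) {
        if (!col %in% names(in_peak)) in_peak[[col]] <- 0L
      }
      peaks <- pk |>
        left_join(in_peak, by = ".pid") |>
        left_join(med, by = "gene_id") |>
        mutate(ip_count = dplyr::coalesce(.data$IP, 0L),
               input_count = dplyr::coalesce(.data$input, 0L),
               peak_es = enrichment_score(.data$ip_count, .data$ip_median,
                                          .data$input_count, .data$input_median)) |>
        select("gene_id", "start", "end", "n_windows", "summit",
               "peak_es", "max_window_es", "min_q")
    } else {
      peaks$peak_es <- numeric(0)
      peaks <- select(peaks, "gene_id", "start", "end", "n_windows",
                      "summit", "peak_es", "max_window_es", "min_q")
    }
    list(windows = mutate(tested, condition = cond, .before = 1),
         peaks = mutate(peaks, condition = cond, .before = 1),
         skipped = skipped)
  })

  empty_peaks <- tibble(condition = character(), gene_id = character(),
                        start = numeric(), end = numeric(),
                        n_windows = integer(), summit = numeric(),
                        peak_es = numeric(), max_window_es = numeric(),
                        min_q = numeric())
  empty_windows <- tibble(condition = character(), gene_id = character(),
                          start = numeric(), end = numeric(),
                          ip_count = integer(), input_count = integer(),
                          p_value = numeric(), q_value = numeric(),
                          es = numeric(), positive = logical())
  out <- list(
    peaks = dplyr::bind_rows(c(list(empty_peaks), purrr::map(res, "peaks"))) |>
      arrange(.data$condition, .data$gene_id, .data$start),
    windows = dplyr::bind_rows(c(list(empty_windows),
                                 purrr::map(res, "windows"))),
    skipped = dplyr::bind_rows(c(list(tibble(condition = character(),
                                             gene_id = character(),
                                             reason = character())),
                                 purrr::map(res, "skipped"))),
    params = list(window = window, step = step,
                  fragment_length = fragment_length, min_frac = min_frac,
                  fdr = fdr, min_log2_es = min_log2_es)
  )
  class(out) <- "merip_call"
  out
}

#' @export
print.merip_call <- function(x, ...) {
  cat("<merip_call>\n")
  cat("  windows tested:", nrow(x$windows), "\n")
  tab <- x$peaks |> count(.data$condition)
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  peaks [%s]: %d\n", tab$condition[i], tab$n[i]))
  }
  if (nrow(x$skipped)) {
    cat("  genes skipped (insufficient coverage):", nrow(x$skipped), "\n")
  }
  invisible(x)
}

#' @describeIn call_peaks Tidy peak table (one row per peak).
#' @param x A `merip_call` object.
#' @param ... Unused.
#' @export
tidy.merip_call <- function(x, ...) x$peaks

#' @describeIn call_peaks One-row-per-condition summary of the peak calling.
#' @export
glance.merip_call <- function(x, ...) {
  x$windows |>
    group_by(.data$condition) |>
    summarise(n_windows_tested = dplyr::n(),
              n_positive = sum(.data$positive), .groups = "drop") |>
    left_join(x$peaks |> count(.data$condition, name = "n_peaks"),
              by = "condition") |>
    left_join(x$skipped |> count(.data$condition, name = "n_genes_skipped"),
              by = "condition") |>
    mutate(n_peaks = dplyr::coalesce(.data$n_peaks, 0L),
           n_genes_skipped = dplyr::coalesce(.data$n_genes_skipped, 0L))
}
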