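# Transcript annotation: loading, longest-isoform selection, and the
# genome <-> transcript coordinate maps everything downstream lives in.
#
# Conventions: all coordinates are 0-based, half-open. A transcript model is
# one row of a tibble with an `exons` list-column (tibble of genomic
# start/end, non-overlapping, sorted by start). Transcript coordinate 0 is
# the 5' end of the mRNA: the lowest genomic coordinate on "+", the highest
# on "-". `cds_start`/`cds_end` are transcript-coordinate offsets; equal
# offsets mean non-coding.

#' Read transcript annotation (BED12 or GTF) into a transcript table
#'
#' Parses a transcript annotation into one row per transcript with exon
#' structure and strand-aware CDS offsets in transcript coordinates.
#'
#' @param path Path to a BED12 or GTF file.
#' @param format `"auto"` (by extension), `"bed12"` or `"gtf"`.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `length`, `cds_start`, `cds_end` and list-column `exons`
#'   (tibbles of genomic `start`, `end`).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t400\tgeneA\t0\t+\t150\t350\t0\t1\t300,\t0,", bed)
#' read_annotation(bed)
#' @export
read_annotation <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path), class = "meripscan_input_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed12"
  }
  switch(format, bed12 = read_bed12(path), gtf = read_gtf(path))
}

read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("annotation file contains no records", class = "meripscan_input_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::map2(fields, seq_along(fields), parse_bed12_line)
  models <- dplyr::bind_rows(rows)
  validate_transcripts(models)
  models
}

parse_bed12_line <- function(f, line_no) {
  if (length(f) < 12L) {
    abort(sprintf("BED12 parse error at line %d: %d fields (12 required)",
                  line_no, length(f)),
          class = "meripscan_parse_error")
  }
  num <- suppressWarnings(as.numeric(f[c(2, 3, 7, 8, 10)]))
  if (anyNA(num)) {
    abort(sprintf("BED12 parse error at line %d: non-numeric coordinate field", line_no),
          class = "meripscan_parse_error")
  }
  chrom_start <- num[1]; chrom_end <- num[2]
  thick_start <- num[3]; thick_end <- num[4]
  block_count <- num[5]
  strand <- f[6]
  if (!strand %in% c("+", "-")) {
    abort(sprintf("BED12 parse error at line %d: strand must be + or -", line_no),
          class = "meripscan_parse_error")
  }
  sizes  <- suppressWarnings(as.numeric(strsplit(f[11], ",", fixed = TRUE)[[1]]))
  starts <- suppressWarnings(as.numeric(strsplit(f[12], ",", fixed = TRUE)[[1]]))
  if (block_count < 1L) {
    abort(sprintf("BED12 parse error at line %d: transcript has no exon blocks", line_no),
          class = "meripscan_parse_error")
  }
  if (anyNA(sizes) || anyNA(starts) ||
      length(sizes) != block_count || length(starts) != block_count) {
    abort(sprintf("BED12 parse error at line %d: block sizes/starts do not match blockCount",
                  line_no),
          class = "meripscan_parse_error")
  }
  exons <- tibble(start = chrom_start + starts, end = chrom_start + starts + sizes)
  if (any(exons$end <= exons$start) || is.unsorted(exons$start, strictly = TRUE) ||
      any(head(exons$end, -1) > tail(exons$start, -1))) {
    abort(sprintf("BED12 parse error at line %d: exon blocks overlap or are unsorted", line_no),
          class = "meripscan_parse_error")
  }
  name <- f[4]
  # name may carry "gene|transcript"; otherwise gene == transcript
  parts <- strsplit(name, "|", fixed = TRUE)[[1]]
  gene_id <- parts[1]
  transcript_id <- if (length(parts) > 1L) parts[2] else parts[1]
  build_transcript_row(gene_id, transcript_id, f[1], strand, exons,
                       thick_start, thick_end)
}

read_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GTF requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  needed <- c("type", "gene_id", "transcript_id")
  if (!all(needed %in% names(df))) {
    abort("GTF lacks gene_id/transcript_id attributes", class = "meripscan_parse_error")
  }
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) {
    abort("GTF contains no exon records", class = "meripscan_parse_error")
  }
  cds <- df[df$type == "CDS", , drop = FALSE]
  cds_rng <- if (nrow(cds)) {
    cds |>
      group_by(.data$transcript_id) |>
      summarise(thick_start = min(.data$start) - 1, thick_end = max(.data$end),
                .groups = "drop")
  } else {
    tibble(transcript_id = character(), thick_start = numeric(), thick_end = numeric())
  }
  ex |>
    as_tibble() |>
    mutate(start = .data$start - 1) |>  # GRanges 1-based closed -> 0-based half-open
    group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::group_map(function(d, key) {
      exons <- d |> arrange(start) |> select("start", "end")
      thick <- cds_rng[cds_rng$transcript_id == key$transcript_id, ]
      ts <- if (nrow(thick)) thick$thick_start else exons$start[1]
      te <- if (nrow(thick)) thick$thick_end else exons$start[1]
      build_transcript_row(key$gene_id, key$transcript_id,
                           as.character(d$seqnames[1]), as.character(d$strand[1]),
                           exons, ts, te)
    }) |>
    dplyr::bind_rows() |>
    validate_transcripts()
}

build_transcript_row <- function(gene_id, transcript_id, chrom, strand, exons,
                                 thick_start, thick_end) {
  len <- sum(exons$end - exons$start)
  # exonic nt strictly before genomic position g
  exonic_before <- function(g) sum(pmax(0, pmin(exons$end, g) - exons$start))
  if (thick_end > thick_start) {
    if (strand == "+") {
      cds_start <- exonic_before(thick_start)
      cds_end   <- exonic_before(thick_end)
    } else {
      cds_start <- len - exonic_before(thick_end)
      cds_end   <- len - exonic_before(thick_start)
    }
  } else {
    cds_start <- cds_end <- 0
  }
  tibble(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, length = len,
         cds_start = cds_start, cds_end = cds_end,
         exons = list(exons))
}

validate_transcripts <- function(models) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "strand", "length",
                  "cds_start", "cds_end", "exons") %in% names(models)))
  bad <- models$cds_start > models$cds_end | models$cds_end > models$length
  if (any(bad)) {
    abort(paste0("inconsistent CDS offsets for transcript(s): ",
                 paste(models$transcript_id[bad], collapse = ", ")),
          class = "meripscan_parse_error")
  }
  models
}

#' Write a transcript table as BED12
#'
#' Inverse of [read_annotation()] for the BED12 dialect; the name field is
#' `gene|transcript`. Tab-separated, no header.
#'
#' @param models Transcript table.
#' @param path Output file.
#' @export
write_annotation_bed12 <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    ex <- m$exons[[1]]
    chrom_start <- min(ex$start)
    if (m$cds_end > m$cds_start) {
      # genomic extent of the CDS: map its first and last transcript base
      g1 <- transcript_to_genome(m, m$cds_start)
      g2 <- transcript_to_genome(m, m$cds_end - 1)
      thick <- c(min(g1, g2), max(g1, g2) + 1)
    } else {
      thick <- c(chrom_start, chrom_start)
    }
    paste(m$chrom, chrom_start, max(ex$end),
          paste0(m$gene_id, "|", m$transcript_id), 0, m$strand,
          thick[1], thick[2], 0, nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - chrom_start, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Keep each gene's longest isoform
#'
#' When a gene has several isoforms the longest one is retained; length ties
#' break deterministically by lexicographically smallest `transcript_id`.
#'
#' @param models Transcript table from [read_annotation()].
#' @return A tibble with exactly one row per `gene_id`.
#' @export
select_longest_isoform <- function(models) {
  models |>
    arrange(.data$gene_id, dplyr::desc(.data$length), .data$transcript_id) |>
    distinct(.data$gene_id, .keep_all = TRUE)
}

#' Read aligned reads from a BED6 file
#'
#' The BED name field may carry the library as `sample:condition`
#' (e.g. `IP:control`); otherwise supply `sample`/`condition`.
#'
#' @param path BED6 file of aligned reads.
#' @param sample,condition Library labels used when the name field does not
#'   encode them.
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `sample`, `condition`.
#' @export
read_reads_bed <- function(path, sample = NULL, condition = NULL) {
  if (!file.exists(path)) {
    abort(paste0("reads file not found: ", path), class = "meripscan_input_error")
  }
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 6L) {
    abort(sprintf("BED6 reads file %s has %d columns (6 required)", path, ncol(df)),
          class = "meripscan_parse_error")
  }
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  bad <- which(!df$strand %in% c("+", "-") | df$end <= df$start | df$start < 0)
  if (length(bad)) {
    abort(sprintf("BED6 parse error at line %d of %s", bad[1], path),
          class = "meripscan_parse_error")
  }
  out <- as_tibble(df[, 1:6])
  if (is.null(sample) || is.null(condition)) {
    parts <- stringr::str_split_fixed(out$name, ":", 2)
    if (any(parts[, 2] == "")) {
      abort("read names do not encode sample:condition; pass sample= and condition=",
            class = "meripscan_input_error")
    }
    out$sample <- parts[, 1]
    out$condition <- parts[, 2]
  } else {
    out$sample <- sample
    out$condition <- condition
  }
  select(out, "chrom", "start", "end", "strand", "sample", "condition")
}

#' Extend aligned reads to fragment length
#'
#' Each read keeps its strand-aware 5' end and grows to `fragment_length`
#' (sequenced reads are the 5'-most part of the immunoprecipitated fragment).
#' Extension happens in genomic space, before exon projection.
#'
#' @param reads Tibble with `chrom`, `start`, `end`, `strand` (plus any other
#'   columns, preserved).
#' @param fragment_length Target fragment size in nt (default 150).
#' @return The input tibble with `start`/`end` adjusted.
#' @examples
#' r <- tibble::tibble(chrom = "chr1", start = 1100, end = 1180, strand = "+")
#' extend_reads(r)  # start 1100, end 1250
#' @export
extend_reads <- function(reads, fragment_length = 150) {
  lens <- reads$end - reads$start
  if (any(fragment_length < lens)) {
    abort(sprintf("fragment_length (%d) is shorter than a read (%d nt)",
                  fragment_length, max(lens)),
          class = "meripscan_config_error")
  }
  reads |>
    mutate(start = ifelse(.data$strand == "+", .data$start,
                          pmax(0, .data$end - fragment_length)),
           end = ifelse(.data$strand == "+", .data$start + fragment_length,
                        .data$end))
}

# Long exon table with per-exon transcript offsets; one row per exon.
# tx_off is the transcript coordinate of the exon's 5'-most base.
exon_offsets <- function(models) {
  purrr::pmap(list(models$gene_id, models$chrom, models$strand, models$exons,
                   models$length),
              function(g, ch, st, ex, len) {
    sizes <- ex$end - ex$start
    if (st == "+") {
      off <- cumsum(c(0, head(sizes, -1)))
    } else {
      off <- len - cumsum(sizes)  # offset of the exon's highest genomic base
    }
    tibble(gene_id = g, chrom = ch, strand = st,
           ex_start = ex$start, ex_end = ex$end, tx_off = off)
  }) |>
    dplyr::bind_rows()
}

#' Project extended reads onto transcript coordinates
#'
#' Intersects each (extended) read's genomic extent with a transcript's exons
#' and maps the exonic overlap to one transcript-coordinate interval,
#' strand-aware. Reads with no exonic overlap (intronic, wrong chromosome)
#' are dropped. Junction-spanning reads keep only their exonic overlap, so
#' the mapped interval length never exceeds the read's genomic length.
#'
#' @param reads Extended reads (see [extend_reads()]).
#' @param models Transcript table, one isoform per gene.
#' @return Tibble `gene_id`, `start`, `end` (transcript coordinates) plus the
#'   reads' `sample` and `condition` columns when present.
#' @export
map_to_transcript <- function(reads, models) {
  ex <- exon_offsets(models)
  keep <- intersect(c("sample", "condition"), names(reads))
  r <- reads |>
    mutate(.read_id = dplyr::row_number()) |>
    select(dplyr::all_of(c("chrom", "start", "end", ".read_id", keep)))
  hits <- inner_join(r, ex, by = "chrom", relationship = "many-to-many") |>
    filter(.data$start < .data$ex_end, .data$end > .data$ex_start) |>
    mutate(ov_start = pmax(.data$start, .data$ex_start),
           ov_end = pmin(.data$end, .data$ex_end),
           tx_start = ifelse(.data$strand == "+",
                             .data$tx_off + .data$ov_start - .data$ex_start,
                             .data$tx_off + .data$ex_end - .data$ov_end),
           tx_end = ifelse(.data$strand == "+",
                           .data$tx_off + .data$ov_end - .data$ex_start,
                           .data$tx_off + .data$ex_end - .data$ov_start))
  if (nrow(hits) == 0L) {
    return(tibble(gene_id = character(), start = numeric(), end = numeric()) |>
             dplyr::bind_cols(r[0, keep, drop = FALSE]))
  }
  # one interval per read x gene; reads hitting a single exon (the vast
  # majority) skip the grouped reduction entirely
  key <- paste(hits$.read_id, hits$gene_id, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  single <- hits[!dup, , drop = FALSE]
  out <- dplyr::bind_cols(
    tibble(gene_id = single$gene_id, start = single$tx_start,
           end = single$tx_end),
    single[, keep, drop = FALSE])
  if (any(dup)) {
    m <- hits[dup, , drop = FALSE]
    o <- order(m$.read_id, m$gene_id)
    m <- m[o, , drop = FALSE]
    g <- cumsum(!duplicated(paste(m$.read_id, m$gene_id, sep = "\r")))
    frst <- !duplicated(g)
    merged <- dplyr::bind_cols(
      tibble(gene_id = m$gene_id[frst],
             start = as.numeric(tapply(m$tx_start, g, min)),
             end = as.numeric(tapply(m$tx_end, g, max))),
      m[frst, keep, drop = FALSE])
    out <- dplyr::bind_rows(out, merged)
  }
  arrange(out, .data$gene_id, .data$start)
}

#' Map transcript positions to genomic positions
#'
#' Inverse of the read projection for single positions: transcript
#' coordinate `pos` (0-based) on `model` (one transcript row) becomes the
#' genomic coordinate of that base.
#'
#' @param model One-row transcript table.
#' @param pos Vector of transcript positions in `[0, length)`.
#' @return Numeric vector of genomic base positions.
#' @export
transcript_to_genome <- function(model, pos) {
  stopifnot(nrow(model) == 1L)
  if (any(pos < 0 | pos >= model$length)) {
    abort("transcript position out of bounds", class = "meripscan_input_error")
  }
  ex <- model$exons[[1]]
  sizes <- ex$end - ex$start
  if (model$strand == "+") {
    cum <- cumsum(c(0, head(sizes, -1)))
    i <- findInterval(pos, c(cum, sum(sizes)), rightmost.closed = FALSE)
    ex$start[i] + (pos - cum[i])
  } else {
    # walk exons in 5'->3' transcript order (reverse genomic order)
    ord <- rev(seq_len(nrow(ex)))
    cum <- cumsum(c(0, head(sizes[ord], -1)))
    i <- findInterval(pos, c(cum, sum(sizes)))
    j <- ord[i]
    ex$end[j] - 1 - (pos - cum[i])
  }
}

#' Map genomic positions to transcript positions
#'
#' @param model One-row transcript table.
#' @param gpos Vector of genomic base positions; must fall in an exon.
#' @return Numeric vector of transcript positions.
#' @export
genome_to_transcript_pos <- function(model, gpos) {
  stopifnot(nrow(model) == 1L)
  ex <- model$exons[[1]]
  sizes <- ex$end - ex$start
  hit <- vapply(gpos, function(g) {
    i <- which(g >= ex$start & g < ex$end)
    if (length(i) != 1L) NA_integer_ else i
  }, integer(1))
  if (anyNA(hit)) {
    abort("genomic position not exonic", class = "meripscan_input_error")
  }
  if (model$strand == "+") {
    cum <- cumsum(c(0, head(sizes, -1)))
    cum[hit] + (gpos - ex$start[hit])
  } else {
    ord <- rev(seq_len(nrow(ex)))
    cum_tx <- numeric(nrow(ex))
    cum_tx[ord] <- cumsum(c(0, head(sizes[ord], -1)))
    cum_tx[hit] + (ex$end[hit] - 1 - gpos)
  }
}
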