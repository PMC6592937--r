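# Sliding-window fragment counting on transcript coordinates.
#
# Window grid: starts 0, 10, 20, ... with width 100 by default;
# floor((L - window)/step) + 1 windows for transcripts of length L >= window,
# a single full-length window otherwise. Medians and per-sample top counts
# are computed over ALL windows of a gene, before any exclusion.

#' Number of sliding windows on a transcript
#' @param length Transcript length (nt).
#' @param window,step Window width and step (nt).
#' @return Integer vector of window counts.
#' @export
n_windows <- function(length, window = 100, step = 10) {
  ifelse(length >= window, (length - window) %/% step + 1L, 1L)
}

window_grid <- function(models, window = 100, step = 10) {
  nw <- n_windows(models$length, window, step)
  tibble(gene_id = rep(models$gene_id, nw),
         length = rep(models$length, nw),
         win = sequence(nw) - 1L) |>
    mutate(start = .data$win * step,
           end = pmin(.data$start + window, .data$length))
}

#' Count IP and input fragments in sliding windows
#'
#' A fragment contributes 1 to every window its transcript interval overlaps
#' by at least 1 nt. Gene-level medians (the `b` and `d` of the enrichment
#' score) and per-sample top counts are taken over all windows of the gene.
#'
#' @param intervals Transcript intervals from [map_to_transcript()], with a
#'   `sample` column holding `"IP"` / `"input"`.
#' @param models Transcript table (one isoform per gene).
#' @param window,step Window width and step in nt (defaults 100 and 10).
#' @return Tibble with one row per gene x window: `gene_id`, `start`, `end`,
#'   `ip_count`, `input_count`, and gene-level `ip_median`, `input_median`,
#'   `ip_top`, `input_top`.
#' @export
count_windows <- function(intervals, models, window = 100, step = 10) {
  if (nrow(models) == 0L) {
    abort("empty annotation", class = "meripscan_input_error")
  }
  stopifnot(window > 0, step > 0)
  grid <- window_grid(models, window, step)

  iv <- intervals |>
    inner_join(select(models, "gene_id", "length"), by = "gene_id")
  counts <- if (nrow(iv) > 0) {
    # overlapping window indices k: k*step > start - window and k*step < end
    k_lo <- pmax(0, (iv$start - window) %/% step + 1)
    k_hi <- pmin(n_windows(iv$length, window, step) - 1,
                 ceiling(iv$end / step) - 1)
    # short transcripts (< window) have the single window 0 covering all
    k_lo <- ifelse(iv$length < window, 0, k_lo)
    k_hi <- ifelse(iv$length < window, 0, k_hi)
    nk <- as.integer(pmax(0, k_hi - k_lo + 1))
    tibble(gene_id = rep(iv$gene_id, nk),
           sample = rep(iv$sample, nk),
           win = sequence(nk, from = as.integer(k_lo))) |>
      count(.data$gene_id, .data$sample, .data$win, name = "n") |>
      tidyr::pivot_wider(names_from = "sample", values_from = "n",
                         values_fill = 0L)
  } else {
    tibble(gene_id = character(), win = integer())
  }
  for (col in c("IP", "input")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  grid |>
    left_join(counts, by = c("gene_id", "win")) |>
    mutate(ip_count = dplyr::coalesce(.data$IP, 0L),
           input_count = dplyr::coalesce(.data$input, 0L)) |>
    select("gene_id", "start", "end", "ip_count", "input_count") |>
    group_by(.data$gene_id) |>
    mutate(ip_median = median(.data$ip_count),
           input_median = median(.data$input_count),
           ip_top = max(.data$ip_count),
           input_top = max(.data$input_count)) |>
    ungroup()
}

#' Flag low-coverage windows for exclusion
#'
#' A window is excluded only when its count is below `fraction` of the
#' gene's top window in BOTH the IP and the input library; this guards
#' against annotation inaccuracies at transcript edges. Medians are left
#' untouched.
#'
#' @param windows Window table from [count_windows()].
#' @param fraction Exclusion threshold relative to the top window (default 1/20).
#' @return The window table with a logical `retained` column.
#' @export
filter_low_windows <- function(windows, fraction = 1 / 20) {
  windows |>
    mutate(retained = !(.data$ip_count < fraction * .data$ip_top &
                          .data$input_count < fraction * .data$input_top))
}

#' Median-normalise window counts
#'
#' Divides each window count by the gene's median window count per sample.
#' Genes whose IP or input median is zero cannot be normalised and are the
#' caller's responsibility to skip.
#'
#' @param windows Window table from [count_windows()].
#' @return The table with `ip_norm` and `input_norm` columns.
#' @export
normalize_counts <- function(windows) {
  if (any(windows$ip_median == 0 | windows$input_median == 0)) {
    abort("zero median coverage: gene(s) must be skipped before normalisation",
          class = "meripscan_coverage_error")
  }
  windows |>
    mutate(ip_norm = .data$ip_count / .data$ip_median,
           input_norm = .data$input_count / .data$input_median)
}
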