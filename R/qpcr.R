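# qPCR quantification (delta-delta-Cq expression, gene-specific m6A-IP
# enrichment), actinomycin-D mRNA decay half-lives, and the caliper
# tumor-volume utility.
#
# Cq tables are long tibbles with one row per technical replicate:
#   sample, gene, (role,) replicate, cq
# Replicates are averaged before any delta is formed; amplification
# efficiency is fixed at 2 (no standard-curve correction).

mean_cq <- function(data, sample, gene, role = NULL) {
  rows <- data$sample == sample & data$gene == gene
  if (!is.null(role)) rows <- rows & data$role == role
  if (!any(rows)) {
    abort(sprintf("no Cq values for sample '%s', gene '%s'%s", sample, gene,
                  if (is.null(role)) "" else paste0(", role '", role, "'")),
          class = "meripscan_input_error")
  }
  mean(data$cq[rows])
}

#' Relative expression by the delta-delta-Cq method
#'
#' Fold change of a target gene relative to a reference gene and a control
#' sample: `fold = 2^-ddCq` with `dCq = Cq(target) - Cq(reference)` per
#' sample and `ddCq = dCq(sample) - dCq(control)`. Technical replicates are
#' averaged first.
#'
#' @param data Long Cq tibble with columns `sample`, `gene`, `cq`.
#' @param target Target gene id.
#' @param reference Reference (housekeeping) gene id, e.g. HPRT1.
#' @param control_sample Sample whose expression defines fold = 1.
#' @return Tibble with one row per sample: `delta_cq`, `delta_delta_cq`,
#'   `fold_change`.
#' @export
relative_expression <- function(data, target, reference, control_sample) {
  if (!reference %in% data$gene) {
    abort(sprintf("reference gene '%s' absent from the Cq table", reference),
          class = "meripscan_input_error")
  }
  samples <- unique(data$sample)
  if (!control_sample %in% samples) {
    abort(sprintf("control sample '%s' absent from the Cq table", control_sample),
          class = "meripscan_input_error")
  }
  dcq <- vapply(samples, function(s) {
    mean_cq(data, s, target) - mean_cq(data, s, reference)
  }, numeric(1))
  ddcq <- dcq - dcq[[control_sample]]
  tibble(sample = samples, gene = target,
         delta_cq = unname(dcq), delta_delta_cq = unname(ddcq),
         fold_change = 2^-unname(ddcq))
}

#' Gene-specific m6A enrichment from IP/input qPCR
#'
#' Percent-of-input style enrichment: `2^(Cq(input) - Cq(IP)) /
#' input_fraction`, where `input_fraction` is the share of material saved
#' as input (default 0.05). Optionally rescaled so a control sample equals 1.
#'
#' @param data Long Cq tibble with columns `sample`, `gene`, `role`
#'   (`"IP"`/`"input"`), `cq`.
#' @param input_fraction Fraction of material kept as input, in (0, 1].
#' @param control_sample Optional sample whose enrichment defines 1.
#' @return Tibble per sample x gene with `m6a_level` and, when a control is
#'   given, `relative_m6a`.
#' @export
m6a_enrichment <- function(data, input_fraction = 0.05, control_sample = NULL) {
  if (!is.numeric(input_fraction) || input_fraction <= 0 || input_fraction > 1) {
    abort("input_fraction must lie in (0, 1]", class = "meripscan_config_error")
  }
  combos <- distinct(data, .data$sample, .data$gene)
  out <- combos |>
    mutate(m6a_level = purrr::map2_dbl(.data$sample, .data$gene, function(s, g) {
      2^(mean_cq(data, s, g, "input") - mean_cq(data, s, g, "IP")) / input_fraction
    }))
  if (!is.null(control_sample)) {
    ctrl <- out |>
      filter(.data$sample == control_sample) |>
      select("gene", ctrl_level = "m6a_level")
    out <- out |>
      left_join(ctrl, by = "gene") |>
      mutate(relative_m6a = .data$m6a_level / .data$ctrl_level) |>
      select(-"ctrl_level")
  }
  out
}

#' Fit an exponential decay to an actinomycin-D time course
#'
#' Least-squares line through `ln(relative abundance)` versus time with the
#' intercept fixed at 0 (abundance is normalised to 1 at t = 0 by
#' construction). `k = -slope`, half-life `= ln(2)/k`. Non-decaying series
#' (`k <= 0`) are reported as stable with infinite half-life.
#'
#' @param data Tibble with time and abundance columns.
#' @param time,value Column names (defaults `hours`, `value`).
#' @return Object of class `decay_fit` with elements `k` (1/h),
#'   `half_life` (h), `r_squared`, `stable`, `n` and the normalised data.
#' @examples
#' fit_decay(tibble::tibble(hours = c(0, 3, 6), value = c(1, 0.5, 0.25)))
#' @export
fit_decay <- function(data, time = "hours", value = "value") {
  t <- data[[time]]
  v <- data[[value]]
  if (length(t) < 3L || !any(t == 0)) {
    abort("decay fit needs >= 3 timepoints including t = 0",
          class = "meripscan_input_error")
  }
  if (any(v <= 0)) {
    abort("nonpositive abundance: log-linear decay fit undefined",
          class = "meripscan_input_error")
  }
  ord <- order(t)
  t <- t[ord]; v <- v[ord]
  if (anyDuplicated(t)) {
    abort("timepoints must be strictly increasing", class = "meripscan_input_error")
  }
  v <- v / v[t == 0]
  y <- log(v)
  slope <- sum(t * y) / sum(t^2)
  k <- -slope
  ss_res <- sum((y - slope * t)^2)
  ss_tot <- sum(y^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(list(k = k,
                 half_life = if (k > 0) log(2) / k else Inf,
                 stable = k <= 0,
                 r_squared = r2, n = length(t),
                 data = tibble(hours = t, rel_abundance = v)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit>\n")
  if (x$stable) {
    cat("  stable transcript (k <= 0), half-life = Inf\n")
  } else {
    cat(sprintf("  k = %.4f /h, half-life = %.2f h, R^2 = %.3f\n",
                x$k, x$half_life, x$r_squared))
  }
  invisible(x)
}

#' @describeIn fit_decay Parameter estimates as a tibble.
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("k", "half_life"),
         estimate = c(x$k, x$half_life),
         unit = c("1/h", "h"))
}

#' @describeIn fit_decay One-row model summary.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(k = x$k, half_life = x$half_life, stable = x$stable,
         r_squared = x$r_squared, n = x$n)
}

#' Decay half-lives for many series at once
#'
#' Maps [fit_decay()] over every gene x condition group of a long decay
#' table.
#'
#' @param data Tibble with `gene`, `condition`, `hours`, `value`.
#' @param time,value Column names of the time and abundance columns.
#' @return Tibble with one row per gene x condition and the [glance()]
#'   columns of each fit.
#' @export
decay_half_lives <- function(data, time = "hours", value = "value") {
  data |>
    group_by(.data$gene, .data$condition) |>
    dplyr::group_modify(~ glance(fit_decay(.x, time = time, value = value))) |>
    ungroup()
}

#' Xenograft tumor volume from caliper diameters
#'
#' `volume (mm^3) = d^2 * D / 2` with `d` the shortest and `D` the longest
#' diameter.
#'
#' @param d,D Shortest and longest tumor diameters (mm); vectorised.
#' @return Volumes in mm^3.
#' @examples
#' tumor_volume(5, 10)  # 125
#' @export
tumor_volume <- function(d, D) {
  if (any(d <= 0)) {
    abort("shortest diameter must be positive", class = "meripscan_input_error")
  }
  if (any(d > D)) {
    abort("shortest diameter exceeds longest (d > D)", class = "meripscan_input_error")
  }
  d^2 * D / 2
}
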