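# ggplot2 views of the result types.

region_fills <- c(utr5 = "#8da0cb", cds = "#66c2a5", utr3 = "#fc8d62")

#' Plot a metagene profile
#'
#' Bar chart of peak-summit percentages over the 100-bin standardised
#' transcript, with the 5'UTR / CDS / 3'UTR segments shaded.
#'
#' @param object A `metagene_profile` from [metagene_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$percent,
                                   fill = .data$region)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = c(9.5, 59.5), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_fill_manual(values = region_fills,
                               breaks = c("utr5", "cds", "utr3"),
                               labels = c("5'UTR", "CDS", "3'UTR")) +
    ggplot2::labs(x = "standardised transcript position (bin)",
                  y = "% of peaks", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.metagene_profile
#' @param profile A `metagene_profile`.
#' @export
plot_metagene <- function(profile, ...) autoplot(profile, ...)

#' Plot region proportions for one or more conditions
#'
#' @param ... Named region-proportion tibbles from [region_proportions()],
#'   e.g. `plot_region_proportions(control = rp_ctrl, knockdown = rp_kd)`.
#' @return A ggplot object.
#' @export
plot_region_proportions <- function(...) {
  tabs <- list(...)
  if (is.null(names(tabs)) || any(names(tabs) == "")) {
    names(tabs) <- paste0("set", seq_along(tabs))
  }
  df <- purrr::imap(tabs, ~ mutate(.x, condition = .y)) |>
    dplyr::bind_rows() |>
    mutate(region = factor(.data$region, levels = c("utr5", "cds", "utr3")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$fraction,
                                   fill = .data$region)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = region_fills,
                               labels = c("5'UTR", "CDS", "3'UTR")) +
    ggplot2::labs(x = NULL, y = "fraction of peaks", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an mRNA decay fit
#'
#' Points are the normalised abundances; the line is the fitted
#' exponential.
#'
#' @param object A `decay_fit` from [fit_decay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble(hours = seq(0, max(df$hours), length.out = 100)) |>
    mutate(rel_abundance = exp(-object$k * .data$hours))
  lab <- if (object$stable) "stable" else sprintf("t1/2 = %.2f h", object$half_life)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$rel_abundance)) +
    ggplot2::geom_line(data = grid, colour = "#3366aa") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::annotate("text", x = max(df$hours), y = max(df$rel_abundance),
                      hjust = 1, vjust = 1, label = lab) +
    ggplot2::labs(x = "hours after actinomycin D",
                  y = "relative abundance (log scale)") +
    ggplot2::theme_minimal()
}
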