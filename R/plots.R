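# ggplot2 figures for each result type: PETH heatmap + mean trace,
# modulation-proportion bars, correlation CDFs per class, and significant-
# pair proportion matrices.

#' @importFrom ggplot2 ggplot aes geom_tile geom_line geom_ribbon geom_col
#'   geom_vline facet_grid facet_wrap labs theme_minimal scale_fill_gradient2
#'   scale_fill_viridis_c stat_ecdf autoplot annotate theme element_blank
#' @export
ggplot2::autoplot

#' Plot a peri-event time histogram
#'
#' Event-by-lag heatmap with the across-event mean (+/- SEM) below, the
#' standard way event-aligned single-unit responses are displayed.
#'
#' @param object a [compute_peth()] result
#' @param title panel title
#' @param ... ignored
#' @return a patchwork of two ggplots
#' @export
autoplot.peth <- function(object, title = "event-aligned activity", ...) {
  mat <- object$matrix
  df <- tidyr::expand_grid(event = seq_len(nrow(mat)),
                           i = seq_len(ncol(mat))) %>%
    mutate(lag = object$lag[.data$i], value = as.vector(t(mat)))
  p1 <- ggplot(df, aes(x = .data$lag, y = .data$event, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = "z") +
    geom_vline(xintercept = 0, linetype = 2, colour = "white") +
    labs(title = title, x = NULL, y = "event") +
    theme_minimal()
  md <- tidy.peth(object)
  p2 <- ggplot(md, aes(x = .data$lag, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem), alpha = 0.3) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "time from event (s)", y = "mean") +
    theme_minimal()
  patchwork::wrap_plots(p1, p2, ncol = 1, heights = c(2, 1))
}

#' Bar chart of modulation-label proportions per context
#'
#' @param summary output of [population_summary()]
#' @return a ggplot
#' @export
plot_modulation_proportions <- function(summary) {
  check_cols(summary, c("context", "label", "prop"))
  ggplot(summary, aes(x = .data$context, y = .data$prop, fill = .data$label)) +
    geom_col(position = "stack") +
    labs(x = NULL, y = "proportion of units", fill = "modulation") +
    theme_minimal()
}

#' Cumulative distributions of pair correlations per class cell
#'
#' One ECDF per ACC label, faceted by cerebellar label and epoch mode —
#' the standard display for comparing same-sign vs opposite-sign class
#' pairs, with the off-bout epoch as the companion panel.
#'
#' @param pairs a `pair_corr` tibble with labels, or the `distributions`
#'   element of [class_summary()]
#' @return a ggplot
#' @export
plot_corr_cdf <- function(pairs) {
  df <- if (inherits(pairs, "pair_class_summary")) pairs$distributions else pairs
  check_cols(df, c("cb_label", "acc_label", "mode", "r"))
  df <- filter(df, !is.na(.data$r))
  if (nrow(df) == 0) {
    return(ggplot() +
             annotate("text", x = 0, y = 0.5, label = "no pairs") +
             theme_minimal() + labs(x = "r", y = "cumulative fraction"))
  }
  ggplot(df, aes(x = .data$r, colour = .data$acc_label,
                 linetype = .data$mode)) +
    stat_ecdf() +
    facet_wrap(~ .data$cb_label) +
    labs(x = "Pearson r", y = "cumulative fraction",
         colour = "ACC label", linetype = "epoch") +
    theme_minimal()
}

#' Matrix of significantly correlated pair percentages
#'
#' @param summary a [class_summary()] result
#' @param direction `"positive"` or `"negative"`
#' @return a ggplot
#' @export
plot_sig_matrix <- function(summary, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  mats <- if (inherits(summary, "pair_class_summary")) summary$matrices else summary
  check_cols(mats, c("cb_label", "acc_label", "mode"))
  col <- if (direction == "positive") "pct_sig_pos" else "pct_sig_neg"
  ggplot(mats, aes(x = .data$acc_label, y = .data$cb_label,
                   fill = .data[[col]])) +
    geom_tile() +
    facet_wrap(~ .data$mode) +
    scale_fill_gradient2(low = "white", high = "firebrick",
                         name = paste0("% sig ", direction),
                         na.value = "grey80") +
    labs(x = "ACC label", y = "cerebellar label") +
    theme_minimal()
}

#' @export
autoplot.pair_class_summary <- function(object, ...) {
  plot_corr_cdf(object)
}
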