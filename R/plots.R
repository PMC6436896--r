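#' Plot the contact-score map
#'
#' Upper triangle of the APC-corrected scores; optionally overlays a truth
#' contact map on the lower triangle.
#'
#' @param object A `contact_scores` tibble from [score_contacts()].
#' @param truth Optional truth table (see [ppv_curve()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_scores <- function(object, truth = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$j, y = .data$i,
                                            fill = .data$apc_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "APC score") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "site j", y = "site i") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    tt <- contact_truth_table(truth)
    tt <- dplyr::filter(tt, .data$is_contact)
    p <- p + ggplot2::geom_tile(
      data = tibble::tibble(i = pmax(tt$i, tt$j), j = pmin(tt$i, tt$j)),
      ggplot2::aes(x = .data$j, y = .data$i), fill = "grey30",
      inherit.aes = FALSE)
  }
  p
}

#' Plot a positive-predictive-value curve
#'
#' @param ppv Tibble from [ppv_curve()].
#' @return A ggplot object.
#' @export
plot_ppv <- function(ppv) {
  ggplot2::ggplot(ppv, ggplot2::aes(x = .data$rank, y = .data$ppv)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "rank", y = "PPV") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param object An `rbm_fit`.
#' @param ... Unused.
#' @return A ggplot object (metrics vs update, free scales).
#' @export
autoplot.rbm_fit <- function(object, ...) {
  hist <- object$history
  long <- tidyr::pivot_longer(hist, -"update", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$update, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot hidden-unit input distributions with activity curves
#'
#' @param dist Result of [input_distributions()].
#' @param units Units to show (default: all present).
#' @return A ggplot object: weighted input histograms (bars) with the
#'   conditional mean-activity curve overlaid (line, free scale).
#' @export
plot_input_distributions <- function(dist, units = NULL) {
  h <- dist$histogram; a <- dist$activity
  if (!is.null(units)) {
    h <- dplyr::filter(h, .data$unit %in% units)
    a <- dplyr::filter(a, .data$unit %in% units)
  }
  scale_per_unit <- dplyr::summarise(
    dplyr::group_by(h, .data$unit), top = max(.data$weight), .groups = "drop")
  a <- dplyr::left_join(a, scale_per_unit, by = "unit")
  rng <- max(abs(a$mean_activity)) + 1e-9
  a$scaled <- a$mean_activity / rng * a$top
  ggplot2::ggplot(h) +
    ggplot2::geom_col(ggplot2::aes(x = .data$mid, y = .data$weight),
                      width = h$upper - h$lower, fill = "steelblue") +
    ggplot2::geom_line(data = a,
                       ggplot2::aes(x = .data$input, y = .data$scaled),
                       color = "black") +
    ggplot2::facet_wrap(~unit, scales = "free") +
    ggplot2::labs(x = "input I", y = "weighted count") +
    ggplot2::theme_minimal()
}

#' Sequence-logo style plot of one hidden unit's weights
#'
#' Letters above zero favor, and letters below zero disfavor, the unit's
#' activation; letter size is the absolute weight.
#'
#' @param params An [rbm].
#' @param unit Hidden-unit index.
#' @param min_weight Hide entries with `|w|` below this value.
#' @return A ggplot object.
#' @export
plot_weight_logo <- function(params, unit, min_weight = 0.05) {
  df <- tidy.rbm(params, units = unit)
  df <- dplyr::filter(df, abs(.data$weight) >= min_weight)
  pos <- dplyr::mutate(
    dplyr::arrange(dplyr::group_by(df[df$weight > 0, ], .data$site),
                   .data$weight),
    y = cumsum(.data$weight) - .data$weight / 2)
  neg <- dplyr::mutate(
    dplyr::arrange(dplyr::group_by(df[df$weight < 0, ], .data$site),
                   dplyr::desc(.data$weight)),
    y = cumsum(.data$weight) - .data$weight / 2)
  both <- dplyr::bind_rows(pos, neg)
  ggplot2::ggplot(both, ggplot2::aes(x = .data$site, y = .data$y,
                                     label = .data$symbol,
                                     size = abs(.data$weight),
                                     color = .data$weight > 0)) +
    ggplot2::geom_text(fontface = "bold", show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "navy")) +
    ggplot2::labs(x = "site", y = "weight",
                  title = paste("hidden unit", unit)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
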