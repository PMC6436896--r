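#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an RBM into a long weight table
#'
#' One row per (hidden unit, site, symbol) weight entry; convenient for
#' dplyr/ggplot2 pipelines over the learned motifs.
#'
#' @param x An [rbm] or `rbm_fit`.
#' @param units Optional subset of hidden units.
#' @param ... Unused.
#' @return Tibble with columns `unit`, `site`, `symbol`, `weight`.
#' @export
tidy.rbm <- function(x, units = seq_len(x$M), ...) {
  rows <- lapply(units, function(mu) {
    tibble::tibble(unit = mu,
                   site = rep(seq_len(x$N), times = x$q),
                   symbol = rep(x$alphabet, each = x$N),
                   weight = as.vector(x$w[, , mu]))
  })
  dplyr::bind_rows(rows)
}

#' One-row model summary
#'
#' @param x An [rbm] or `rbm_fit`.
#' @param ... Unused.
#' @return Tibble with `N`, `q`, `M`, `variant`, `n_parameters`,
#'   `mean_weight_norm`, `max_weight_norm` and, for fitted models,
#'   `n_updates`.
#' @export
glance.rbm <- function(x, ...) {
  out <- tibble::tibble(N = x$N, q = x$q, M = x$M, variant = x$pot$variant,
                        n_parameters = length(x$g) + length(x$w) +
                          sum(lengths(x$pot[setdiff(names(x$pot),
                                                    c("variant", "M"))])),
                        mean_weight_norm = mean(weight_norms(x)),
                        max_weight_norm = max(weight_norms(x)))
  if (!is.null(x$config)) out$n_updates <- x$config$n_updates
  out
}

#' Per-unit summary of a fitted RBM
#'
#' @param x An `rbm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per hidden unit: `unit`, `weight_norm`,
#'   `participation_ratio`, and the unit's potential parameters.
#' @export
tidy.rbm_fit <- function(x, ...) {
  rep_ <- export_unit_reports(x)
  out <- dplyr::arrange(rep_$summary, .data$unit)[
    , c("unit", "weight_norm", "participation_ratio")]
  for (nm in setdiff(names(x$pot), c("variant", "M"))) out[[nm]] <- x$pot[[nm]]
  out
}
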