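#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior parameter summaries of a fitted block model
#'
#' @param x an `sbm_fit`.
#' @param ... unused.
#' @return a tibble with one row per scalar parameter: `parameter`, `mean`,
#'   `sd`, `rhat`, `ess`.
#' @export
tidy.sbm_fit <- function(x, ...) {
  x$diagnostics
}

#' One-row fit overview
#'
#' @param x an `sbm_fit`.
#' @param ... unused.
#' @return a tibble with `model`, `k`, `n_devices`, `n_divs`, `n_nodes`,
#'   `n_chains`, `n_draws`, `mean_loglik`, `max_rhat`.
#' @export
glance.sbm_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, k = x$k,
    n_devices = length(x$devices),
    n_divs = length(x$divs), n_nodes = x$n,
    n_chains = length(unique(x$chain)), n_draws = length(x$chain),
    mean_loglik = mean(x$draws$loglik),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE)
  )
}

#' Plot posterior connection-probability curves
#'
#' Lower-triangle grid of `eta_ij(t)` posterior means with central credible
#' bands, one panel per community pair, mirroring the usual presentation of
#' temporal block-model output.
#'
#' @param object an `sbm_fit` (temporal model).
#' @param ... passed to [posterior_eta()].
#' @return a ggplot object.
#' @export
autoplot.sbm_fit <- function(object, ...) {
  curves <- posterior_eta(object, ...)
  plot_eta_curves(curves)
}

#' @rdname autoplot.sbm_fit
#' @export
autoplot.fit_summary <- function(object, ...) {
  autoplot.sbm_fit(object$fit, ...)
}

#' @param curves a tibble from [posterior_eta()] or [predict_eta()].
#' @rdname autoplot.sbm_fit
#' @export
plot_eta_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$div, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_grid(i ~ j, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "DIV", y = expression(eta(t))) +
    ggplot2::theme_minimal()
}

#' Plot average degree against correlation threshold
#'
#' @param sweep a tibble from [threshold_sweep()].
#' @return a ggplot object.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$threshold, y = .data$avg_degree)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cross-correlation threshold", y = "average degree") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
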