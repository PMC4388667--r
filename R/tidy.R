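#' Tidiers and plots for scan and null objects
#'
#' @param x object.
#' @param ... unused.
#' @name wfgp-tidiers
NULL

#' @rdname wfgp-tidiers
#' @method tidy er_scan
#' @export
tidy.er_scan <- function(x, ...) as_tibble(x)

#' @rdname wfgp-tidiers
#' @method glance er_scan
#' @export
glance.er_scan <- function(x, ...) {
  top <- which.min(x$rank)
  tibble(n_sites = nrow(x), max_lambda = max(x$lambda),
         top_site = x$site[top], top_pos = x$pos[top],
         s_hat_top = x$s_hat[top])
}

#' @rdname wfgp-tidiers
#' @method tidy er_null
#' @export
tidy.er_null <- function(x, ...) {
  tibble(sim = seq_along(x$lambda_max), lambda_max = x$lambda_max)
}

#' @rdname wfgp-tidiers
#' @method glance er_null
#' @export
glance.er_null <- function(x, ...) {
  tibble(n_sims = x$n_sims,
         q95 = quantile(x$lambda_max, 0.95, names = FALSE),
         q99 = quantile(x$lambda_max, 0.99, names = FALSE))
}

#' @rdname wfgp-tidiers
#' @param object object to plot.
#' @method autoplot er_scan
#' @export
autoplot.er_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$lambda)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "position (bp)",
                  y = expression(Lambda ~ "(likelihood ratio)")) +
    ggplot2::theme_minimal()
}

#' @rdname wfgp-tidiers
#' @method autoplot er_null
#' @export
autoplot.er_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$lambda_max)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = expression("max"[sites] ~ Lambda),
                  y = "neutral simulations") +
    ggplot2::theme_minimal()
}

#' @rdname wfgp-tidiers
#' @method autoplot er_experiment
#' @export
autoplot.er_experiment <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gen, y = .data$freq,
                                  group = interaction(.data$site, .data$rep))) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::facet_wrap(~rep, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "generation", y = "derived-allele frequency") +
    ggplot2::theme_minimal()
}
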