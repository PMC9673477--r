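#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style tidiers
#'
#' `tidy()` returns per-term (or per-fold) tibbles, `glance()` one-row
#' model-level summaries, for the fitted and evaluated objects of the
#' package.
#'
#' @param x a fitted or evaluated object.
#' @param ... unused.
#' @name gs-tidiers
NULL

#' @rdname gs-tidiers
#' @export
tidy.gs_rrblup <- function(x, ...) {
  tibble::tibble(term = names(x$w) %||% paste0("M", seq_along(x$w)),
                 estimate = unname(x$w))
}

#' @rdname gs-tidiers
#' @export
glance.gs_rrblup <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, sigma2_g = x$sigma2_g,
                 sigma2_e = x$sigma2_e, reml_loglik = x$reml_loglik,
                 n_markers = length(x$w))
}

#' @rdname gs-tidiers
#' @export
tidy.gs_bayes <- function(x, ...) {
  tibble::tibble(
    term = x$marker_ids %||% paste0("M", seq_along(x$posterior_mean_w)),
    estimate = as.numeric(x$posterior_mean_w),
    inclusion_prob = as.numeric(x$posterior_inclusion))
}

#' @rdname gs-tidiers
#' @export
glance.gs_bayes <- function(x, ...) {
  tibble::tibble(variant = x$variant, pi = x$posterior_mean_pi,
                 sigma2_e = x$posterior_mean_se2,
                 mu = x$posterior_mean_mu, n_kept = x$n_kept)
}

#' @rdname gs-tidiers
#' @export
tidy.gs_penalized <- function(x, ...) {
  tibble::tibble(term = names(x$w) %||% paste0("M", seq_along(x$w)),
                 estimate = unname(x$w))
}

#' @rdname gs-tidiers
#' @export
glance.gs_penalized <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, l1_ratio = x$l1_ratio,
                 n_nonzero = sum(x$w != 0), objective = x$objective)
}

#' @rdname gs-tidiers
#' @export
tidy.gs_evaluation <- function(x, ...) x$results

#' @rdname gs-tidiers
#' @export
glance.gs_evaluation <- function(x, ...) x$summary

#' @rdname gs-tidiers
#' @export
tidy.gs_importance_report <- function(x, ...) x$detail

#' @rdname gs-tidiers
#' @export
glance.gs_importance_report <- function(x, ...) x$summary

#' @rdname gs-tidiers
#' @export
tidy.gs_phenotype <- function(x, ...) {
  tibble::tibble(sample_id = names(x$y), y = unname(x$y),
                 u = x$truth$u, epsilon = x$truth$epsilon)
}

#' @rdname gs-tidiers
#' @export
glance.gs_phenotype <- function(x, ...) {
  rf <- x$realized_fractions
  tibble::tibble(config = x$config$name, n = length(x$y),
                 heritability = x$config$heritability,
                 background_fraction = rf[["background"]],
                 noise_fraction = rf[["noise"]],
                 causal_fraction = sum(rf) - rf[["background"]] - rf[["noise"]],
                 sigma2 = x$truth$sigma2, seed = x$seed)
}

#' Plot methods
#'
#' `autoplot()` for evaluations draws the models-by-phenotypes explained
#' variance heatmap; for simulated phenotypes the phenotype distribution;
#' for importance reports the effect-size versus importance scatter (log
#' scales for display, causal markers highlighted).
#'
#' @param object the object to plot.
#' @param ... passed on.
#' @name gs-autoplot
NULL

#' @rdname gs-autoplot
#' @export
autoplot.gs_evaluation <- function(object, ...) {
  results_heatmap(object)$plot
}

#' @rdname gs-autoplot
#' @export
autoplot.gs_phenotype <- function(object, bins = 30, ...) {
  tibble::tibble(y = object$y) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$y)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(title = sprintf("Simulated phenotype %s (seed %d)",
                                  object$config$name, object$seed),
                  x = "phenotype", y = "count") +
    ggplot2::theme_minimal()
}

#' @rdname gs-autoplot
#' @param correlation result of [effect_importance_correlation()].
#' @export
plot_effect_importance <- function(correlation, ...) {
  ggplot2::ggplot(correlation$pairs,
                  ggplot2::aes(x = .data$avg_importance, y = .data$effect,
                               colour = .data$is_causal,
                               size = .data$is_causal)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 1.5, `TRUE` = 3)) +
    ggplot2::labs(x = "fold-averaged importance", y = "|effect size|",
                  subtitle = sprintf("Pearson r = %.3f", correlation$pearson_r)) +
    ggplot2::guides(size = "none") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
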