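# ggplot2 visualizations for the main result types.

#' Volcano plot of differential-expression results
#'
#' @param object A `newrna_de` tibble from [de_compound()].
#' @param alpha Significance cutoff drawn on the plot (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.newrna_de <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_diff,
                                       y = -log10(.data$p_value),
                                       colour = .data$q_value < alpha)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = sprintf("q < %g", alpha)) +
    ggplot2::labs(x = "log2 difference (treated - control)",
                  y = "-log10 p", title = unique(object$compound_id)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of promoter-factor enrichment
#'
#' @param object A `newrna_enrichment` tibble from [factor_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.newrna_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = log2(.data$fold_change),
                                       y = -log10(.data$p_value),
                                       colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "significant") +
    ggplot2::labs(x = "log2 fold change (up vs down)", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Posterior density of the new-RNA fraction for one gene
#'
#' Plots the normalized grid posterior attached to a [posterior_grid()]
#' result, with the posterior mean and credible bounds marked.
#'
#' @param estimate One-row tibble from [posterior_grid()].
#' @return A ggplot object.
#' @export
plot_pi_posterior <- function(estimate) {
  post <- attr(estimate, "posterior")
  if (is.null(post)) stop("estimate carries no posterior attribute", call. = FALSE)
  ggplot2::ggplot(post, ggplot2::aes(x = .data$pi, y = .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = estimate$pi_mean, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(estimate$ci_low, estimate$ci_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "new-RNA fraction", y = "posterior weight") +
    ggplot2::theme_minimal()
}

#' Observed labeled counts against the fitted telegraph distribution
#'
#' @param object A `telegraph_fit` from [fit_kinetics()].
#' @param counts The labeled counts the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.telegraph_fit <- function(object, counts, ...) {
  p <- labeled_count_distribution(object$k_on, object$k_off, object$k_syn,
                                  object$k_deg, object$t,
                                  max_count = max(counts))
  obs <- tibble(count = as.integer(names(table(counts))),
                freq = as.numeric(table(counts)) / length(counts))
  fit <- tibble(count = seq_along(p) - 1L, prob = p)
  fit <- fit[fit$count <= max(counts) + 5, ]
  ggplot2::ggplot() +
    ggplot2::geom_col(data = obs, ggplot2::aes(x = .data$count, y = .data$freq),
                      fill = "grey75") +
    ggplot2::geom_line(data = fit, ggplot2::aes(x = .data$count, y = .data$prob),
                       colour = "firebrick") +
    ggplot2::labs(x = "labeled molecules per cell", y = "probability") +
    ggplot2::theme_minimal()
}
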