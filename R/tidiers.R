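#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fold-change estimate
#'
#' @param x A [ratio_estimate()].
#' @param ... Unused.
#' @return A one-row tibble with `comparison`, `fraction`, `variant`,
#'   `ratio`, `ci_low`, `ci_high`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
tidy.ratio_estimate <- function(x, ...) {
  tidy_ratio_row(x)
}

#' Tidy a mixture fit
#'
#' @param x A `mixture_fit` from [fit_lognormal_normal_mixture()].
#' @param ... Unused.
#' @return A tibble with one row per component (`lognormal`, `normal`):
#'   `component`, `weight`, `location`, `scale`.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(
    component = c("lognormal", "normal"),
    weight = c(x$weight_lognormal, 1 - x$weight_lognormal),
    location = c(x$mu_log, x$mu_norm),
    scale = c(x$sigma_log, x$sigma_norm)
  )
}

#' One-row model summary of a mixture fit
#'
#' @inheritParams tidy.mixture_fit
#' @return A one-row tibble: `weight_lognormal`, `loglik`, `n_iter`,
#'   `converged`, `degenerate`.
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(
    weight_lognormal = x$weight_lognormal,
    loglik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged,
    degenerate = x$degenerate
  )
}

#' Plot an aggregate particle series
#'
#' Time course of the aerosol and droplet fractions, optionally with event
#' annotations marked.
#'
#' @param object An [aggregate_size_fractions()] series.
#' @param annotations Optional annotation tibble (`time_s`, `label`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aggregate_series <- function(object, annotations = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("aerosol", "droplet"),
                              names_to = "fraction", values_to = "counts")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s / 60,
                                          y = .data$counts)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~fraction, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = "Counts per interval")
  if (!is.null(annotations) && nrow(annotations) > 0) {
    p <- p + ggplot2::geom_vline(
      data = annotations,
      ggplot2::aes(xintercept = .data$time_s / 60, colour = .data$label),
      linetype = "dashed"
    ) + ggplot2::labs(colour = "event")
  }
  p
}

#' Forest-style plot of fold-change comparisons
#'
#' Point estimates with 95% CIs on a log scale, one row per comparison,
#' faceted by size fraction.
#'
#' @param results `study_results` from [run_study()] or a tidy comparison
#'   tibble.
#' @return A ggplot object.
#' @export
plot_comparisons <- function(results) {
  tab <- if (inherits(results, "study_results")) results$comparisons else
    as_tibble(results)
  tab <- mutate(tab, label = ifelse(is.na(.data$variant),
                                    .data$comparison,
                                    paste(.data$comparison, .data$variant)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$ratio, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~fraction, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Fold change (log scale)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
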