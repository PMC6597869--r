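#' Plot a K scan
#'
#' BIC and AIC against the number of clusters, with the selected range
#' shaded.
#'
#' @param object A [kscan()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kscan
#' @export
autoplot.kscan <- function(object, ...) {
  d <- tidyr::pivot_longer(object$scan, c("bic", "aic"),
                           names_to = "criterion", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$k, .data$value,
                                  colour = .data$criterion)) +
    ggplot2::annotate("rect", xmin = object$k_lo, xmax = object$k_hi,
                      ymin = -Inf, ymax = Inf, alpha = 0.1) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters K", y = "information criterion",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Posterior probability against missing data
#'
#' The diagnostic scatter separating incursives whose posterior support
#' is limited by missing data (a declining band among well-assigned
#' individuals) from low-posterior, low-missingness incursives that
#' suggest unsampled source populations.
#'
#' @param report An assignment report tibble (needs `missingness`,
#'   `posterior_top`, `confidence`).
#' @return A ggplot.
#' @export
plot_missingness_posterior <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(.data$missingness, .data$posterior_top,
                               shape = .data$confidence,
                               colour = .data$confidence)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::lims(y = c(0, 1)) +
    ggplot2::labs(x = "proportion of missing data",
                  y = "posterior probability of membership",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Discriminant scatter of references and incursives
#'
#' Two-dimensional discriminant view: linear discriminant axes are fit
#' on the reference individuals' PC scores (the visualization step of
#' DAPC; assignment itself is by cluster membership) and incursives are
#' projected onto them.
#'
#' @param result An `incursion_result`.
#' @param n_pcs PCs fed to the discriminant analysis (default 20).
#' @return A ggplot.
#' @export
plot_dapc_scatter <- function(result, n_pcs = 20) {
  ref <- result$panel$reference
  pcs <- fit_pca(result$gm, ref$id,
                 n_components = min(n_pcs, length(ref$id) - 1))
  ld <- MASS::lda(pcs$scores, grouping = factor(ref$label))
  ref_ld <- pcs$scores %*% ld$scaling
  d_ref <- tibble::tibble(ld1 = ref_ld[, 1],
                          ld2 = if (ncol(ref_ld) > 1) ref_ld[, 2] else 0,
                          label = ref$label, role = "reference")
  d <- d_ref
  if (length(result$panel$incursives)) {
    inc_sc <- project_pca(pcs, result$gm, result$panel$incursives)
    inc_ld <- inc_sc %*% ld$scaling
    d <- dplyr::bind_rows(d_ref, tibble::tibble(
      ld1 = inc_ld[, 1],
      ld2 = if (ncol(inc_ld) > 1) inc_ld[, 2] else 0,
      label = "incursive", role = "incursive"))
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$ld1, .data$ld2,
                                  colour = .data$label,
                                  shape = .data$role)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "discriminant axis 1", y = "discriminant axis 2",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
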