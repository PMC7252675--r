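#' Tidy a haplotype scan
#'
#' @param x A `hap_scan` object.
#' @param ... Unused.
#' @return The association tibble (one row per haplotype test).
#' @method tidy hap_scan
#' @export
tidy.hap_scan <- function(x, ...) x$assoc

#' One-row summary of a haplotype scan
#'
#' @param x A `hap_scan` object.
#' @param ... Unused.
#' @return A tibble with `model`, `n_windows`, `n_tests`,
#'   `bonferroni_alpha`, `lambda`, `n_samples`, `conditioned`, `top_p`.
#' @method glance hap_scan
#' @export
glance.hap_scan <- function(x, ...) {
  tibble(model = x$model, n_windows = x$n_windows, n_tests = x$n_tests,
         bonferroni_alpha = x$bonferroni_alpha, lambda = x$lambda,
         n_samples = x$n_samples, conditioned = x$conditioned,
         top_p = if (x$n_tests > 0) min(x$assoc$p) else NA_real_)
}

#' Tidy a REML fit
#'
#' @param x A `reml_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per variance component.
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble(component = c("additive", "permanent_environment", "residual"),
         estimate = c(x$sigma_g2, x$sigma_pe2, x$sigma_e2))
}

#' One-row summary of a REML fit
#'
#' @param x A `reml_fit` object.
#' @param ... Unused.
#' @return A tibble with the ratios, likelihood and convergence info.
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble(h2 = x$h2, repeatability = x$repeatability, loglik = x$loglik,
         n_iter = x$n_iter, converged = x$converged,
         n_records = x$n_records %||% NA_integer_)
}

#' Manhattan plot of a haplotype scan
#'
#' Plots `-log10(P)` of every haplotype test against genomic position
#' (midpoint of its window), with the Bonferroni threshold drawn as a
#' horizontal line and significant haplotypes highlighted. An empty scan
#' yields empty axes without error.
#'
#' @param object A `hap_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hap_scan
#' @export
autoplot.hap_scan <- function(object, ...) {
  a <- object$assoc
  thr <- object$bonferroni_alpha
  if (nrow(a) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(x = "position", y = expression(-log[10](P))) +
             ggplot2::theme_minimal())
  }
  a <- dplyr::mutate(a, mid_bp = (.data$start_bp + .data$end_bp) / 2,
                     neglogp = -log10(.data$p),
                     significant = .data$p < thr)
  ggplot2::ggplot(a, ggplot2::aes(x = .data$mid_bp / 1e6, y = .data$neglogp)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(thr), colour = "red",
                        linetype = "dashed") +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](P)),
                  title = sprintf("%s model: %d tests, lambda = %.2f",
                                  object$model, object$n_tests, object$lambda)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.hap_scan
#' @param scan A `hap_scan` object.
#' @param path Optional file to save the figure to (via
#'   [ggplot2::ggsave()]).
#' @export
make_manhattan <- function(scan, path = NULL) {
  p <- autoplot(scan)
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 9, height = 3.5, dpi = 150)
  p
}
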