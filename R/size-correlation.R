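#' Regress mitogenome length on a component length
#'
#' Ordinary least squares of total genome length on one component length
#' across genomes. R-squared is the squared Pearson correlation; the
#' p-value comes from the slope t-statistic, t = r sqrt((n-2)/(1-r^2)),
#' against Student-t with n-2 degrees of freedom (identical to the OLS
#' slope test for simple regression).
#'
#' @param data data frame with one row per genome
#' @param component bare column name of the component length
#' @param total bare column name of the genome length (default `total`)
#' @return object of class `size_fit` wrapping the `lm` fit; `tidy()`,
#'   `glance()` and `autoplot()` methods are provided
#' @export
fit_size_component <- function(data, component, total = total) {
  comp <- rlang::enquo(component)
  tot <- rlang::enquo(total)
  x <- rlang::eval_tidy(comp, data)
  y <- rlang::eval_tidy(tot, data)
  stopifnot(length(x) >= 3, !anyNA(x), !anyNA(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    fit <- NULL
    r2 <- NaN; p <- NaN; slope <- NaN; intercept <- NaN
  } else {
    fit <- stats::lm(y ~ x)
    r <- stats::cor(x, y)
    r2 <- r^2
    tstat <- r * sqrt((length(x) - 2) / (1 - r2))
    p <- 2 * stats::pt(abs(tstat), df = length(x) - 2, lower.tail = FALSE)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  structure(
    list(component = rlang::as_label(comp), n = length(x),
         slope = slope, intercept = intercept, r_squared = r2,
         p_value = p, fit = fit,
         data = tibble::tibble(component_length = x, genome_length = y)),
    class = "size_fit")
}

#' @export
print.size_fit <- function(x, ...) {
  cat(sprintf("<size_fit> genome length ~ %s: n = %d, R^2 = %.3f, p = %.3g\n",
              x$component, x$n, x$r_squared, x$p_value))
  invisible(x)
}

#' @method tidy size_fit
#' @export
tidy.size_fit <- function(x, ...) {
  tibble::tibble(component = x$component,
                 term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance size_fit
#' @export
glance.size_fit <- function(x, ...) {
  tibble::tibble(component = x$component, n = x$n, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 p_value = x$p_value)
}

#' Size regressions for every component of a cohort decomposition
#'
#' @param decomp tibble of [decompose_genome()] rows (one per genome),
#'   optionally with the `heg` overlay column
#' @param components columns to regress against `total`
#' @return tibble with one row per component: `component`, `n`, `slope`,
#'   `intercept`, `r_squared`, `p_value`
#' @export
size_correlations <- function(decomp,
                              components = c(.COMPONENTS, "heg")) {
  components <- intersect(components, names(decomp))
  purrr::map_dfr(components, function(cmp) {
    f <- fit_size_component(decomp, !!rlang::sym(cmp))
    out <- glance.size_fit(f)
    out$component <- cmp
    out
  })
}

#' @method autoplot size_fit
#' @export
autoplot.size_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$component_length,
                               y = .data$genome_length)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = paste(object$component, "length (nt)"),
      y = "mitogenome length (nt)",
      title = sprintf("R² = %.3f, p = %.2g",
                      object$r_squared, object$p_value)) +
    ggplot2::theme_minimal()
}
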