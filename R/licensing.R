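#' Fit the licensing-fraction vs abundance relation
#'
#' Ordinary least squares of the measured licensed fraction (fraction of
#' cells with an Mcm double hexamer loaded at the site, in [0, 1]) on ChEC
#' abundance.  The fitted line converts relative ChEC abundance into an
#' absolute licensing estimate.
#'
#' @param measurements data.frame with columns `abundance` and `fraction`
#'   (at least two rows with distinct abundances).
#' @return An object of class `licensing_model` with elements `slope`,
#'   `intercept`, `r_squared`, `fit` (the `lm`), `measurements`.
#' @export
fit_licensing_model <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("abundance", "fraction") %in% colnames(measurements)))
  m <- measurements
  if (nrow(m) < 2L) stop("need at least two measurements")
  if (length(unique(m$abundance)) < 2L)
    stop("all abundances identical: singular fit")
  if (any(m$fraction < 0 | m$fraction > 1))
    stop("licensed fractions must lie in [0, 1]")
  fit <- stats::lm(fraction ~ abundance, data = m)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 fit = fit,
                 measurements = m),
            class = "licensing_model")
}

#' @export
print.licensing_model <- function(x, ...) {
  cat(sprintf(paste0("<licensing_model> fraction = %.4g + %.4g * abundance",
                     " (r^2 = %.3f, n = %d)\n"),
              x$intercept, x$slope, x$r_squared, nrow(x$measurements)))
  invisible(x)
}

#' Predict licensed fractions from a fitted model
#'
#' Predictions are clamped to [0, 1]; the logical attribute `"clamped"`
#' flags where clamping occurred.
#'
#' @param object A `licensing_model`.
#' @param abundance Numeric vector of abundances.
#' @param ... Unused.
#' @return Numeric vector of fractions in [0, 1].
#' @export
predict.licensing_model <- function(object, abundance, ...) {
  raw <- object$intercept + object$slope * abundance
  out <- pmin(1, pmax(0, raw))
  attr(out, "clamped") <- raw != out
  out
}

#' Licensed-cell percentage of a cohort
#'
#' Propagates the top-cohort licensing fraction to another cohort via its
#' relative abundance: `100 * cohort1_fraction * relative_abundance`,
#' reported to one decimal.  E.g. a cohort at 1.5% of cohort-1 abundance
#' with cohort 1 licensed in 69% of cells is licensed in
#' `100 * 0.69 * 0.015 = 1.0%` of cells.
#'
#' @param cohort1_fraction Licensing fraction of the top cohort, in [0, 1].
#' @param relative_abundance Cohort abundance relative to cohort 1 (>= 0;
#'   cohort-1 median = 1).
#' @return Percentage, rounded to one decimal.
#' @export
licensed_percent <- function(cohort1_fraction, relative_abundance) {
  if (!all(is.finite(cohort1_fraction)) ||
      !all(is.finite(relative_abundance)))
    stop("inputs must be finite")
  if (any(cohort1_fraction < 0) || any(relative_abundance < 0))
    stop("inputs must be non-negative")
  if (any(cohort1_fraction > 1))
    stop("'cohort1_fraction' is a fraction in [0, 1]")
  round(100 * cohort1_fraction * relative_abundance, 1L)
}
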