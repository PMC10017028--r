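# Length normalization and linear temperature-trend fitting with 90%
# confidence intervals for chain-level N_w and N_pp.

#' Length-normalize a per-temperature series
#'
#' Divides chain-level means by the peptide residue count (lipidation site
#' plus ELP), so constructs of different length are comparable; pass the
#' pentad count instead for a per-repeat normalization.
#'
#' @param values per-temperature means
#' @param n_residues positive residue (or repeat) count
#' @return normalized values
#' @export
normalize_series <- function(values, n_residues) {
  if (length(n_residues) != 1 || n_residues <= 0)
    stop("n_residues must be a single positive count")
  values / n_residues
}

#' Ordinary least squares temperature trend with 90% confidence interval
#'
#' Fits `y ~ x` by OLS (optionally weighted by `1 / (y_sd^2 / n_frames)`,
#' the inverse squared standard errors of the per-temperature means) and
#' reports the slope with its two-sided 90% t-interval on n - 2 degrees of
#' freedom.
#'
#' @param x temperatures, K (at least 3 distinct values).
#' @param y per-temperature means (typically length-normalized).
#' @param y_sd optional per-temperature standard deviations.
#' @param n_frames optional frames per temperature; with `y_sd` enables
#'   the weighted fit.
#' @return object of class `TrendFit`: `slope`, `intercept`,
#'   `slope_ci90`, `r_squared`, `n_points`, and the underlying `lm` fit
#' @export
fit_linear_trend <- function(x, y, y_sd = NULL, n_frames = NULL) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct temperatures for a trend fit")
  dat <- data.frame(x = x, y = y)
  if (!is.null(y_sd) && !is.null(n_frames)) {
    se2 <- y_sd^2 / n_frames
    if (any(se2 <= 0)) stop("weighted fit needs positive y_sd")
    fit <- lm(y ~ x, data = dat, weights = 1 / se2)
  } else {
    fit <- lm(y ~ x, data = dat)
  }
  ci <- suppressWarnings(confint(fit, "x", level = 0.90))
  structure(list(slope = unname(coef(fit)["x"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 slope_ci90 = unname(c(ci[1], ci[2])),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_points = length(x),
                 lm = fit),
            class = "TrendFit")
}

#' @export
print.TrendFit <- function(x, ...) {
  cat(sprintf("TrendFit: slope %.6g [90%% CI %.6g, %.6g], intercept %.6g, R^2 %.4f, n = %d\n",
              x$slope, x$slope_ci90[1], x$slope_ci90[2], x$intercept,
              x$r_squared, x$n_points))
  invisible(x)
}

#' Pointwise 90% confidence band of a fitted trend line
#'
#' @param fit [fit_linear_trend()] result
#' @param x_new temperatures at which to evaluate the band
#' @return data.frame with `x`, `fit`, `lwr`, `upr`
#' @export
trend_band <- function(fit, x_new) {
  stopifnot(inherits(fit, "TrendFit"))
  p <- predict(fit$lm, newdata = data.frame(x = x_new),
               interval = "confidence", level = 0.90)
  data.frame(x = x_new, fit = p[, "fit"], lwr = p[, "lwr"],
             upr = p[, "upr"])
}
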