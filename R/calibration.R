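## Calibration regressions relating experimental percent backbone exchange
## to model predictors, with the summary statistics used to rank models
## (slope, intercept and their standard errors, R^2, residual sum of
## squares, average percent error).

#' Ordinary least-squares line fit with calibration statistics
#'
#' @param x Predictor values (length >= 3, nonzero variance).
#' @param y Response values.
#' @param model_id Optional label.
#' @return Object of class \code{regression_fit}: list with \code{m},
#'   \code{b}, \code{se_m}, \code{se_b}, \code{r_squared}, \code{ss_res},
#'   \code{n}, \code{model_id}, and the underlying \code{lm} fit.
#' @examples
#' fit_line(1:5, 2 * (1:5) + 1)
#' @export
fit_line <- function(x, y, model_id = NA_character_) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("at least 3 points are required")
  if (stats::var(x) == 0) stop("predictor has zero variance")
  fit <- stats::lm(y ~ x, data = data.frame(x, y))
  ## collinear calibrations are legitimate inputs here; silence summary.lm's
  ## "essentially perfect fit" advisory
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(list(m = unname(co["x", "Estimate"]),
                 b = unname(co["(Intercept)", "Estimate"]),
                 se_m = unname(co["x", "Std. Error"]),
                 se_b = unname(co["(Intercept)", "Std. Error"]),
                 r_squared = sm$r.squared,
                 ss_res = sum(stats::residuals(fit)^2),
                 n = length(x), model_id = model_id, fit = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit%s: m = %.4g (%.2g), b = %.4g (%.2g), R^2 = %.3f, SS_res = %.4g, n = %d\n",
              if (is.na(x$model_id)) "" else paste0(" [", x$model_id, "]"),
              x$m, x$se_m, x$b, x$se_b, x$r_squared, x$ss_res, x$n))
  invisible(x)
}

#' Average percent error of a calibration line
#'
#' Per point, the relative deviation of the fitted line from the observed
#' response: \eqn{100 |m x_i + b - y_i| / |y_i|}; reported as mean with
#' standard error of the mean.  Points with \code{y = 0} are excluded with
#' a warning.  Set \code{inverse = TRUE} to measure against the prediction
#' instead of the observation.
#'
#' @param fit A \code{\link{fit_line}} result.
#' @param x,y The data to evaluate on.
#' @param inverse Use the predicted value as the denominator.
#' @return List with \code{mean}, \code{sem}, \code{per_point}, \code{n}.
#' @export
percent_error <- function(fit, x, y, inverse = FALSE) {
  stopifnot(inherits(fit, "regression_fit"), length(x) == length(y))
  pred <- fit$m * x + fit$b
  denom <- if (inverse) pred else y
  keep <- denom != 0
  if (!all(keep))
    warning(sum(!keep), " point(s) with zero denominator excluded")
  err <- 100 * abs(pred[keep] - y[keep]) / abs(denom[keep])
  list(mean = mean(err),
       sem = if (length(err) > 1) stats::sd(err) / sqrt(length(err)) else 0,
       per_point = err, n = length(err))
}

#' Compare calibration models against experimental exchange
#'
#' Fits one calibration line per predictor model (experimental percent BB
#' exchange regressed on each model's theoretical values) and tabulates the
#' regression statistics, ranked by R^2.
#'
#' @param experimental Named numeric vector of experimental percent BB
#'   exchange per peptide.
#' @param predictors Named list of numeric vectors (same peptides) of
#'   per-model predictor values; models with missing peptides are skipped
#'   with a warning.
#' @return data.frame (one row per model): \code{model}, \code{m},
#'   \code{se_m}, \code{b}, \code{se_b}, \code{r_squared}, \code{ss_res},
#'   \code{pct_error}, \code{pct_error_sem}; attribute \code{fits} holds the
#'   \code{regression_fit} objects.
#' @export
compare_models <- function(experimental, predictors) {
  stopifnot(is.list(predictors), length(predictors) >= 1)
  peps <- names(experimental)
  fits <- list()
  rows <- list()
  for (mod in names(predictors)) {
    pv <- predictors[[mod]]
    if (!is.null(peps) && !is.null(names(pv))) {
      if (!all(peps %in% names(pv))) {
        warning("model '", mod, "' is missing peptides; skipped")
        next
      }
      pv <- pv[peps]
    } else if (length(pv) != length(experimental)) {
      warning("model '", mod, "' has mismatched length; skipped")
      next
    }
    fit <- fit_line(pv, unname(experimental), model_id = mod)
    pe <- percent_error(fit, pv, unname(experimental))
    fits[[mod]] <- fit
    rows[[mod]] <- data.frame(model = mod, m = fit$m, se_m = fit$se_m,
                              b = fit$b, se_b = fit$se_b,
                              r_squared = fit$r_squared, ss_res = fit$ss_res,
                              pct_error = pe$mean, pct_error_sem = pe$sem,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no model could be fitted")
  out <- do.call(rbind, rows)
  out <- out[order(-out$r_squared), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
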