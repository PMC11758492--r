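## Deuterium uptake from isotopic envelopes: centroids, before/after shifts,
## internal-standard scaling and charge-state pooling.

#' Construct a peak list
#'
#' @param mz m/z values (thomson), strictly increasing.
#' @param intensity Nonnegative intensities, at least one positive.
#' @param charge Positive integer charge state.
#' @param label Optional \code{"before"}/\code{"after"} tag.
#' @param replicate_id Optional replicate identifier.
#' @return Object of class \code{peak_list}.
#' @export
peak_list <- function(mz, intensity, charge = 1L, label = NA_character_,
                      replicate_id = NA_character_) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1)
  if (is.unsorted(mz, strictly = TRUE)) stop("m/z values must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be nonnegative")
  if (!any(intensity > 0)) stop("at least one intensity must be positive")
  if (!(charge >= 1 && charge == round(charge))) stop("charge must be a positive integer")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 charge = as.integer(charge), label = label,
                 replicate_id = replicate_id),
            class = "peak_list")
}

#' Read a peak list from CSV/TSV
#'
#' Expects a header with columns \code{mz} and \code{intensity}; the
#' delimiter (comma or tab) is inferred from the header line.
#'
#' @param path File path.
#' @inheritParams peak_list
#' @return \code{\link{peak_list}}.
#' @export
read_peak_list <- function(path, charge = 1L, label = NA_character_,
                           replicate_id = NA_character_) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("mz", "intensity") %in% names(tab)))
    stop("peak list file must have columns 'mz' and 'intensity'")
  tab <- tab[order(tab$mz), ]
  peak_list(tab$mz, tab$intensity, charge = charge, label = label,
            replicate_id = replicate_id)
}

#' Intensity-weighted centroid of an isotopic envelope
#'
#' The centroid m/z is the intensity-weighted mean of the peak positions;
#' the neutral centroid mass removes the charging protons:
#' \eqn{M = z \cdot \bar{m/z} - z \cdot m_p}.
#'
#' @param peaks A \code{\link{peak_list}}.
#' @return Numeric neutral centroid mass (Da) with attributes \code{mz}
#'   (centroid m/z) and \code{uncertainty} (weighted standard error of the
#'   centroid over the isotopic peaks, Da, neutral-mass scale).
#' @export
centroid <- function(peaks) {
  stopifnot(inherits(peaks, "peak_list"))
  w <- peaks$intensity / sum(peaks$intensity)
  m <- sum(w * peaks$mz)
  n <- sum(peaks$intensity > 0)
  se_mz <- if (n > 1) sqrt(sum(w * (peaks$mz - m)^2) / n) else 0
  z <- peaks$charge
  structure(z * m - z * PROTON_MASS, mz = m, uncertainty = z * se_mz)
}

#' Deuterium uptake from before/after envelopes
#'
#' Uptake is the difference of neutral centroid masses after and before D2O
#' exposure; expressed against the number of exchangeable sites it becomes a
#' percent incorporation using the D-H mass difference (1.00628 Da per
#' exchanged hydrogen).
#'
#' @param before,after \code{\link{peak_list}}s at the same charge state.
#' @param n_sites Total exchangeable hydrogens of the ion.
#' @param back_exchange_tol Negative shifts beyond this magnitude (Da) are
#'   flagged as back-exchange; they are reported, not rejected.
#' @param clamp_negative If \code{TRUE}, negative shifts are clamped to 0.
#' @return Object of class \code{deuterium_uptake}: list with \code{shift}
#'   (Da), \code{uncertainty} (Da), \code{percent_of_sites},
#'   \code{charge}, \code{back_exchange} flag.
#' @examples
#' b <- peak_list(c(147.1, 148.1), c(1, 0.3))
#' a <- peak_list(c(150.1, 151.1, 152.1), c(0.5, 1, 0.6))
#' uptake(b, a, n_sites = 6)
#' @export
uptake <- function(before, after, n_sites, back_exchange_tol = 0.05,
                   clamp_negative = FALSE) {
  stopifnot(inherits(before, "peak_list"), inherits(after, "peak_list"))
  if (before$charge != after$charge)
    stop("before/after peak lists must share a charge state")
  stopifnot(n_sites >= 1)
  mb <- centroid(before)
  ma <- centroid(after)
  shift <- as.numeric(ma) - as.numeric(mb)
  back <- shift < -back_exchange_tol
  if (back)
    warning("negative mass shift (", signif(shift, 4),
            " Da): flagged as back-exchange")
  if (clamp_negative && shift < 0) shift <- 0
  unc <- sqrt(attr(mb, "uncertainty")^2 + attr(ma, "uncertainty")^2)
  structure(list(shift = shift, uncertainty = unc,
                 percent_of_sites = 100 * shift / (DELTA_MD * n_sites),
                 n_sites = n_sites, charge = before$charge,
                 replicate_id = after$replicate_id, back_exchange = back),
            class = "deuterium_uptake")
}

#' @export
print.deuterium_uptake <- function(x, ...) {
  cat(sprintf("deuterium_uptake: %.4f Da (+/- %.4f) = %.2f%% of %d sites [z=%d]%s\n",
              x$shift, x$uncertainty, x$percent_of_sites, x$n_sites, x$charge,
              if (isTRUE(x$back_exchange)) " [back-exchange]" else ""))
  invisible(x)
}

#' Scale analyte uptake to a fixed internal-standard exchange level
#'
#' Analyte uptake is regressed (ordinary least squares) on the co-sprayed
#' internal standard's percent exchange across exposures, and the best-fit
#' line is evaluated at a fixed reference level (75 percent by convention),
#' normalising away run-to-run differences in D2O exposure.  The prediction
#' uncertainty is propagated from the slope/intercept covariance.
#'
#' @param standard_pct Internal-standard percent exchange per exposure.
#' @param analyte_uptake Analyte deuterium uptake (Da) per exposure.
#' @param level Reference exchange level (percent) at which to evaluate.
#' @return List with \code{value} (Da at \code{level}), \code{se},
#'   \code{slope}, \code{intercept}, \code{fit} (the \code{lm} object).
#' @examples
#' scale_to_standard(c(40, 60, 80), c(8, 12, 16), level = 75)
#' @export
scale_to_standard <- function(standard_pct, analyte_uptake, level = 75) {
  stopifnot(length(standard_pct) == length(analyte_uptake))
  if (length(standard_pct) < 2)
    stop("at least 2 exposures are required")
  if (stats::var(standard_pct) == 0)
    stop("standard percent values are all equal: slope is unidentifiable")
  fit <- stats::lm(analyte_uptake ~ standard_pct,
                   data = data.frame(standard_pct, analyte_uptake))
  pr <- stats::predict(fit, newdata = data.frame(standard_pct = level),
                       se.fit = TRUE)
  list(value = unname(pr$fit), se = unname(pr$se.fit),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), level = level, fit = fit)
}

#' Pool deuterium uptake across charge states
#'
#' Weighted mean of per-charge-state uptake values with propagated
#' uncertainty \eqn{\sqrt{\sum (w_i u_i)^2} / \sum w_i} (weights treated as
#' fixed).  Default weights are the total ion intensities of the charge
#' states; inverse-variance weighting is available.
#'
#' @param shift Per-charge-state uptake values (Da).
#' @param uncertainty Per-value uncertainties (Da).
#' @param weights Optional explicit weights (e.g. total ion intensities).
#' @param scheme \code{"intensity"} (use \code{weights}, equal if absent) or
#'   \code{"inverse_variance"}.
#' @return List with \code{value}, \code{uncertainty}, \code{weights}.
#' @export
combine_charge_states <- function(shift, uncertainty = NULL, weights = NULL,
                                  scheme = c("intensity", "inverse_variance")) {
  scheme <- match.arg(scheme)
  n <- length(shift)
  if (n < 1) stop("no values to combine")
  if (is.null(uncertainty)) uncertainty <- rep(0, n)
  stopifnot(length(uncertainty) == n)
  w <- switch(scheme,
    intensity = if (is.null(weights)) rep(1, n) else weights,
    inverse_variance = {
      if (any(uncertainty <= 0))
        stop("inverse-variance weighting needs positive uncertainties")
      1 / uncertainty^2
    })
  stopifnot(length(w) == n, all(w > 0))
  w <- w / sum(w)
  list(value = sum(w * shift),
       uncertainty = sqrt(sum((w * uncertainty)^2)),
       weights = w, scheme = scheme)
}
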