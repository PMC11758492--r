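## Side-chain exchange decomposition: solve per-site-class propensities from
## amino-acid-standard data by nonnegative least squares, then subtract the
## side-chain contribution from total uptake to obtain percent backbone
## exchange.

#' Fit side-chain exchange propensities from standards
#'
#' Solves \eqn{\min_{p \ge 0} \| W^{1/2}(C p - d) \|^2} where rows of
#' \code{counts} give the per-class exchangeable-hydrogen counts of each
#' standard and \code{observed} their measured uptake (Da, i.e. deuteriums
#' incorporated) at the common reference condition.  The active-set
#' nonnegative solution is cross-checked against the analytical ordinary
#' least-squares solution of the normal equations: the two coincide whenever
#' the unconstrained optimum is already elementwise nonnegative.
#'
#' @param counts Numeric matrix (standards x site classes) with column names
#'   naming the classes.  Classes with identical behaviour (e.g. the S/T/Y
#'   hydroxyls) should be pooled into one column before fitting.
#' @param observed Observed uptake per standard (Da).
#' @param uncertainty Optional per-observation standard deviations; used for
#'   weighting only when \code{weighted = TRUE}.
#' @param weighted If \code{TRUE}, rows are weighted by inverse variance.
#' @param clip If \code{TRUE} (default) propensities above 1 are clipped to 1
#'   with a flag: a propensity is a fraction of a class's hydrogens
#'   exchanged, so values above 1 indicate model misfit, not physics.
#' @return Object of class \code{propensity_table}: data.frame with columns
#'   \code{class}, \code{propensity}, \code{se} (OLS-based, \code{NA} for
#'   boundary-active classes), \code{clipped}; attribute \code{ols} carries
#'   the unconstrained cross-check solution and \code{residual_norm} the
#'   residual sum of squares at the solution.
#' @export
fit_propensities <- function(counts, observed, uncertainty = NULL,
                             weighted = FALSE, clip = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have class column names")
  stopifnot(nrow(counts) == length(observed))
  if (qr(counts)$rank < ncol(counts)) {
    ## name columns involved in the deficiency: those whose removal restores
    ## full rank of the remainder
    dep <- colnames(counts)[apply(
      diag(ncol(counts)), 2,
      function(e) qr(counts[, !as.logical(e), drop = FALSE])$rank ==
        qr(counts)$rank)]
    stop("design is rank deficient; unresolvable classes: ",
         paste(dep, collapse = ", "))
  }
  C <- counts
  d <- as.numeric(observed)
  if (weighted) {
    if (is.null(uncertainty) || any(uncertainty <= 0))
      stop("weighted fit needs positive uncertainties")
    sw <- 1 / uncertainty
    C <- C * sw
    d <- d * sw
  }
  nn <- pracma::lsqnonneg(C, d)
  p <- nn$x
  names(p) <- colnames(counts)

  ## analytical OLS cross-check via the normal equations
  ols <- drop(solve(crossprod(C), crossprod(C, d)))
  names(ols) <- colnames(counts)
  s2 <- sum((d - C %*% ols)^2) / max(1, nrow(C) - ncol(C))
  se <- sqrt(diag(solve(crossprod(C))) * s2)
  se[p == 0 & ols < 0] <- NA_real_  # boundary-active: OLS se not meaningful

  clipped <- rep(FALSE, length(p))
  if (clip && any(p > 1)) {
    clipped <- p > 1
    warning("propensity above 1 for class(es) ",
            paste(names(p)[clipped], collapse = ", "), "; clipped to 1")
    p[clipped] <- 1
  }
  out <- data.frame(class = names(p), propensity = unname(p),
                    se = unname(se), clipped = clipped,
                    stringsAsFactors = FALSE)
  attr(out, "ols") <- ols
  attr(out, "residual_norm") <- sum((d - C %*% p)^2)
  class(out) <- c("propensity_table", "data.frame")
  out
}

#' Side-chain deuterium contribution of a peptide
#'
#' Dot product of the peptide's per-class exchangeable-hydrogen counts with
#' the fitted class propensities, in exchanged-hydrogen (Da-equivalent)
#' units.  Every class present in the inventory must be covered by the
#' table; \code{pooling} maps inventory classes onto (possibly pooled) table
#' classes.
#'
#' @param inventory A \code{\link{enumerate_sites}} result.
#' @param table A \code{propensity_table} (or named numeric vector of
#'   propensities).
#' @param pooling Named character vector mapping inventory class ->
#'   table class; defaults pool the S/T/Y hydroxyls into \code{"hydroxyl"}
#'   (identity for everything else).
#' @return Numeric side-chain contribution with attribute \code{se} when the
#'   table carries uncertainties.
#' @export
side_contribution <- function(inventory, table, pooling = NULL) {
  stopifnot(inherits(inventory, "site_inventory"))
  if (inherits(table, "propensity_table")) {
    p <- stats::setNames(table$propensity, table$class)
    pse <- stats::setNames(table$se, table$class)
  } else {
    p <- table
    pse <- stats::setNames(rep(NA_real_, length(p)), names(p))
  }
  cnt <- inventory$side_chain_counts
  cnt <- cnt[cnt > 0]
  cls <- names(cnt)
  if (!is.null(pooling)) {
    hit <- cls %in% names(pooling)
    cls[hit] <- pooling[cls[hit]]
  }
  miss <- setdiff(unique(cls), names(p))
  if (length(miss))
    stop("no propensity for class(es): ", paste(miss, collapse = ", "))
  contrib <- sum(cnt * p[cls])
  se <- if (all(is.na(pse[cls]))) NA_real_ else
    sqrt(sum((cnt * ifelse(is.na(pse[cls]), 0, pse[cls]))^2))
  structure(contrib, se = se)
}

#' Percent backbone exchange
#'
#' \eqn{\%BB = 100 (D_{tot} - D_{side}) / n_{bb}}: total uptake minus the
#' side-chain contribution, expressed as a percentage of backbone amide
#' hydrogens.  Negative results (side-chain model over-subtraction) are
#' flagged, not rejected.
#'
#' @param total Total deuterium uptake (Da).
#' @param n_bb Number of backbone amide hydrogens (> 0).
#' @param side Side-chain contribution (Da).
#' @param u_total,u_side Uncertainties (Da); side defaults to exact.
#' @return Object of class \code{backbone_exchange}: list with
#'   \code{percent_bb}, \code{uncertainty} (percent), inputs, and a
#'   \code{negative} flag.
#' @examples
#' percent_backbone(total = 24.0, n_bb = 20, side = 17.79, u_total = 0.5)
#' @export
percent_backbone <- function(total, n_bb, side, u_total = 0, u_side = 0) {
  stopifnot(n_bb > 0)
  pct <- 100 * (total - side) / n_bb
  unc <- 100 * sqrt(u_total^2 + u_side^2) / n_bb
  if (pct < 0) warning("negative backbone exchange (", signif(pct, 3), "%)")
  structure(list(total_uptake = total, side_contribution = side,
                 backbone_sites = n_bb, percent_bb = pct, uncertainty = unc,
                 negative = pct < 0),
            class = "backbone_exchange")
}

#' @export
print.backbone_exchange <- function(x, ...) {
  cat(sprintf("backbone_exchange: %.2f%% (+/- %.2f) [total %.2f - side %.2f over %d amides]\n",
              x$percent_bb, x$uncertainty, x$total_uptake,
              x$side_contribution, x$backbone_sites))
  invisible(x)
}
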