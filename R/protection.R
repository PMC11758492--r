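## Protection factors from state traces and theoretical backbone exchange.
##
## PF_i = f_closed,i / f_open,i: the population ratio of exchange-incompetent
## to exchange-competent states of an amide.  The digital rule counts a
## residue as exchanged when ln(PF) < 0 (open-dominated); the combined
## kinetic model converts PF and the intrinsic rate into an exchange
## probability 1 - exp(-k_int t / PF) over a reaction time t.

#' Protection factors from a state trace
#'
#' @param trace A \code{\link{classify_states}} result.
#' @param clamp If \code{TRUE} (default) f_open is clamped to
#'   [1/n, 1 - 1/n] so PF stays finite; clamped residues are flagged
#'   (saturated statistics, PF only bounded by the frame count).
#' @return Object of class \code{pf_profile}: data.frame with columns
#'   \code{resno}, \code{aa}, \code{f_open}, \code{pf}, \code{ln_pf},
#'   \code{k_eq} (= 1/PF), \code{clamped}; attributes \code{model},
#'   \code{n}.
#' @examples
#' tr <- state_trace_from_matrix(matrix(c(TRUE, FALSE), 1, 10))
#' protection_factors(tr)  # f_open = 0.5 -> PF = 1, ln PF = 0
#' @export
protection_factors <- function(trace, clamp = TRUE) {
  stopifnot(inherits(trace, "state_trace"))
  f_o <- trace$summary$f_open
  n <- trace$n
  clamped <- rep(FALSE, length(f_o))
  if (clamp) {
    lo <- 1 / n
    clamped <- f_o < lo | f_o > 1 - lo
    f_o <- pmin(pmax(f_o, lo), 1 - lo)
  } else if (any(f_o %in% c(0, 1))) {
    stop("f_open of 0 or 1 encountered with clamp = FALSE")
  }
  pf <- (1 - f_o) / f_o
  out <- data.frame(resno = trace$summary$resno, aa = trace$summary$aa,
                    f_open = f_o, pf = pf, ln_pf = log(pf), k_eq = 1 / pf,
                    clamped = clamped)
  attr(out, "model") <- trace$model
  attr(out, "n") <- n
  class(out) <- c("pf_profile", "data.frame")
  out
}

#' Aggregate protection-factor profiles across replicates
#'
#' Replicate trajectories are classified independently; aggregation averages
#' the per-residue open fractions across replicates (default) and rebuilds
#' PF from the mean, or averages per-replicate ln(PF) directly
#' (\code{method = "ln_pf"}).  The standard error of the mean of ln(PF)
#' across replicates is attached either way.
#'
#' @param profiles List of \code{pf_profile}s over identical residue sets
#'   and the same state model.
#' @param method \code{"f_open"} (average populations, then PF) or
#'   \code{"ln_pf"} (average per-replicate ln PF).
#' @return A \code{pf_profile} with additional columns \code{ln_pf_sem} and
#'   \code{f_open_sem}; attribute \code{n_replicates}.
#' @export
aggregate_replicates <- function(profiles, method = c("f_open", "ln_pf")) {
  method <- match.arg(method)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "pf_profile")))
  models <- vapply(profiles, function(p) attr(p, "model"), character(1))
  if (length(unique(models)) != 1) stop("mismatched state models")
  res0 <- profiles[[1]]$resno
  if (!all(vapply(profiles, function(p) identical(p$resno, res0), TRUE)))
    stop("mismatched residue sets")
  k <- length(profiles)
  fo <- sapply(profiles, function(p) p$f_open)
  lp <- sapply(profiles, function(p) p$ln_pf)
  if (is.null(dim(fo))) { fo <- matrix(fo, nrow = 1); lp <- matrix(lp, nrow = 1) }
  sem <- function(m) if (k > 1) apply(m, 1, stats::sd) / sqrt(k) else
    rep(0, nrow(m))
  f_mean <- rowMeans(fo)
  ln_pf <- if (method == "f_open") log((1 - f_mean) / f_mean) else
    rowMeans(lp)
  pf <- exp(ln_pf)
  out <- data.frame(resno = res0, aa = profiles[[1]]$aa,
                    f_open = f_mean, pf = pf, ln_pf = ln_pf, k_eq = 1 / pf,
                    clamped = Reduce(`|`, lapply(profiles, function(p) p$clamped)),
                    f_open_sem = sem(fo), ln_pf_sem = sem(lp))
  attr(out, "model") <- models[1]
  attr(out, "n") <- attr(profiles[[1]], "n")
  attr(out, "n_replicates") <- k
  class(out) <- c("pf_profile", "data.frame")
  out
}

theoretical_exchange <- function(contrib, profile, model, t = NA_real_) {
  out <- list(resno = profile$resno, contribution = contrib,
              percent_bb_theory = 100 * mean(contrib),
              n_backbone = length(contrib), model = model, t = t)
  class(out) <- "theoretical_exchange"
  out
}

#' @export
print.theoretical_exchange <- function(x, ...) {
  cat(sprintf("theoretical_exchange (%s): %.2f%% BB over %d amides\n",
              x$model, x$percent_bb_theory, x$n_backbone))
  invisible(x)
}

#' Digital (sign-of-ln-PF) theoretical exchange
#'
#' A residue contributes 1 exchange event when ln(PF) < 0 (open states
#' dominate) and 0 otherwise; ln(PF) exactly 0 counts as not exchanged.
#'
#' @param profile A \code{\link{protection_factors}} result.
#' @return \code{theoretical_exchange} with binary contributions and
#'   \code{percent_bb_theory}.
#' @export
digital_exchange <- function(profile) {
  stopifnot(inherits(profile, "pf_profile"))
  theoretical_exchange(as.numeric(profile$ln_pf < 0), profile,
                       model = paste0("digital_", attr(profile, "model")))
}

#' Combined kinetic-model theoretical exchange
#'
#' Per-residue exchange probability over reaction time \code{t}:
#' \eqn{HDX_i = 1 - \exp(-k_{int,i}\, t / PF_i)}, the EX2-like observed rate
#' \eqn{k_{obs} = k_{int}/PF} integrated over \code{t}.  The reaction time
#' is arbitrary for calibration purposes (rescaling t is equivalent to
#' rescaling all k_int).
#'
#' @param profile A \code{\link{protection_factors}} result.
#' @param kint A \code{\link{kint_profile}} covering the same residues.
#' @param t Reaction time, seconds (default 1).
#' @return \code{theoretical_exchange} with contributions in [0, 1].
#' @export
cmb_exchange <- function(profile, kint, t = 1.0) {
  stopifnot(inherits(profile, "pf_profile"), t > 0)
  i <- match(profile$resno, kint$residue)
  if (anyNA(i))
    stop("k_int missing for residue(s): ",
         paste(profile$resno[is.na(i)], collapse = ", "))
  contrib <- 1 - exp(-kint$k_int[i] * t / profile$pf)
  theoretical_exchange(contrib, profile,
                       model = paste0("cmb_", attr(profile, "model")), t = t)
}
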