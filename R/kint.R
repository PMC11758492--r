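## Intrinsic backbone-amide exchange rates (k_int).
##
## Poly-DL-alanine reference rates with per-residue neighbour corrections
## and Arrhenius temperature scaling; the model the HDX field uses to
## predict unprotected-amide exchange from primary sequence alone.

## Reference log10 rates at 293 K in D2O (acid: /M/min, base: /M/min,
## water: /min) and activation energies (kcal/mol).
KINT_REF <- list(
  logkA = 2.04, logkB = 10.36, logkW = -1.5,
  EaA = 14.0, EaB = 17.0, EaW = 19.0,
  Tref = 293.0, pKD = 15.05, R = 0.0019872  # kcal/mol/K
)

#' Load the packaged intrinsic-rate factor table
#'
#' @param path Optional path to an alternative factor table (TSV with columns
#'   \code{res}, \code{acid_lambda}, \code{acid_rho}, \code{base_lambda},
#'   \code{base_rho}); defaults to the packaged reference set.
#' @return data.frame of log10 rate factors, one row per residue plus
#'   \code{NT}/\code{CT} terminal rows.
#' @export
kint_factor_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kint_factors.tsv", package = "hdxcalib",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  rownames(tab) <- tab$res
  tab
}

arrhenius <- function(temperature, Ea) {
  exp(-Ea / KINT_REF$R * (1 / temperature - 1 / KINT_REF$Tref))
}

#' Per-residue intrinsic exchange rates
#'
#' Computes the intrinsic (unprotected) backbone-amide exchange rate for each
#' residue of a peptide as the sum of acid-, base- and water-catalysed terms.
#' Each term is a poly-DL-alanine reference rate multiplied by log-additive
#' corrections from the residue's own side chain (lambda) and the preceding
#' residue's side chain (rho), with terminal-group corrections for the
#' residue-2 amide (free ammonium N-terminus) and the final amide (free
#' carboxylate C-terminus), and Arrhenius temperature scaling per catalysis
#' channel.  Proline (no amide hydrogen) and residue 1 (alpha-amine, not an
#' amide) carry no rate.
#'
#' @param pep An \code{\link{peptide}} object.
#' @param pH Measured pH of the exchange medium (pH meter reading).
#' @param temperature Kelvin.
#' @param pD_offset Correction added to the pH reading to obtain pD in D2O
#'   (glass-electrode isotope artefact); default 0.4.
#' @param factors Factor table from \code{\link{kint_factor_table}}.
#' @return Object of class \code{kint_profile}: data.frame with columns
#'   \code{residue} (1-based index), \code{aa}, \code{k_acid}, \code{k_base},
#'   \code{k_water}, \code{k_int} (all 1/s), with attributes \code{pH},
#'   \code{temperature}.
#' @examples
#' kint_profile(peptide("AAAAA"), pH = 7, temperature = 300)
#' @export
kint_profile <- function(pep, pH = 7.0, temperature = 300.0,
                         pD_offset = 0.4, factors = kint_factor_table()) {
  stopifnot(inherits(pep, "hdx_peptide"))
  if (!(pH > 0 && pH < 14)) stop("pH must lie in (0, 14)")
  if (!(temperature > 0)) stop("temperature must be positive (kelvin)")
  res <- pep$residues
  n <- length(res)
  if (n < 2)
    stop("k_int profile needs at least 2 residues (residue 1 has no amide)")
  miss <- setdiff(res, rownames(factors))
  if (length(miss))
    stop("missing factor-table entry for residue(s): ",
         paste(miss, collapse = ", "))

  pD <- pH + pD_offset
  conc_D <- 10^(-pD)
  conc_OD <- 10^(pD - KINT_REF$pKD)
  kA <- 10^KINT_REF$logkA * arrhenius(temperature, KINT_REF$EaA) / 60
  kB <- 10^KINT_REF$logkB * arrhenius(temperature, KINT_REF$EaB) / 60
  kW <- 10^KINT_REF$logkW * arrhenius(temperature, KINT_REF$EaW) / 60

  idx <- setdiff(which(res != "P"), 1L)
  out <- lapply(idx, function(i) {
    la_a <- factors[res[i], "acid_lambda"]
    la_b <- factors[res[i], "base_lambda"]
    rh_a <- factors[res[i - 1L], "acid_rho"]
    rh_b <- factors[res[i - 1L], "base_rho"]
    if (i == 2L && pep$n_term == "free") {
      rh_a <- rh_a + factors["NT", "acid_rho"]
      rh_b <- rh_b + factors["NT", "base_rho"]
    }
    if (i == n && pep$c_term == "acid") {
      la_a <- la_a + factors["CT", "acid_lambda"]
      la_b <- la_b + factors["CT", "base_lambda"]
    }
    if (anyNA(c(la_a, la_b, rh_a, rh_b)))
      stop("factor table has no usable entry for pair ",
           res[i - 1L], "-", res[i], " at residue ", i)
    k_acid <- kA * conc_D * 10^(la_a + rh_a)
    k_base <- kB * conc_OD * 10^(la_b + rh_b)
    k_water <- kW * 10^(la_b + rh_b)
    c(k_acid = k_acid, k_base = k_base, k_water = k_water,
      k_int = k_acid + k_base + k_water)
  })
  prof <- cbind(data.frame(residue = idx, aa = res[idx],
                           stringsAsFactors = FALSE),
                as.data.frame(do.call(rbind, out)))
  rownames(prof) <- NULL
  attr(prof, "pH") <- pH
  attr(prof, "temperature") <- temperature
  attr(prof, "pD_offset") <- pD_offset
  class(prof) <- c("kint_profile", "data.frame")
  prof
}
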