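## Peptide definition and exchangeable-site enumeration.

## Labile side-chain hydrogens per residue, neutral forms.  Arginine's
## guanidino group carries 4 H in the neutral form; lysine's amine 2.
SIDE_CHAIN_H <- list(
  K = c(amine = 2L),
  R = c(guanidino = 4L),
  S = c(hydroxyl = 1L), T = c(hydroxyl = 1L), Y = c(hydroxyl = 1L),
  D = c(carboxyl = 1L), E = c(carboxyl = 1L),
  N = c(amide_sidechain = 2L), Q = c(amide_sidechain = 2L),
  H = c(imidazole = 1L),
  W = c(indole = 1L),
  C = c(thiol = 1L)
)

SITE_CLASSES <- c("amine", "guanidino", "hydroxyl", "carboxyl",
                  "amide_sidechain", "imidazole", "indole", "thiol",
                  "n_terminal_amine", "c_terminal_acid", "c_terminal_amide")

#' Define a peptide with terminal modifications
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param n_term N-terminal state: \code{"free"} (alpha-amine, 2 labile H) or
#'   \code{"acetyl"} (capped; the residue-1 amide hydrogen is then counted
#'   with the backbone, except for proline which has none).
#' @param c_term C-terminal state: \code{"acid"} (free carboxylic acid,
#'   1 labile H) or \code{"amide"} (C-terminal amide, 2 labile H).
#' @param charge Number of chargng protons for MS-ion site counting; each
#'   proton on a heteroatom is itself exchangeable, so \code{charge} is added
#'   to the total site count (used for free-amino-acid internal standards).
#'   Neutral-form counting (\code{charge = 0}) is the default and matches
#'   side-chain/backbone site bookkeeping for peptides.
#' @return An object of class \code{hdx_peptide}.
#' @examples
#' peptide("RPPGFSPFR")
#' peptide("PAAAAKAAAAKAAAAKAAAAK", n_term = "acetyl")
#' @export
peptide <- function(sequence, n_term = c("free", "acetyl"),
                    c_term = c("acid", "amide"), charge = 0L) {
  n_term <- match.arg(n_term)
  c_term <- match.arg(c_term)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!res %in% names(AA1TO3))
  if (length(bad))
    stop("unknown residue letter '", res[bad[1]], "' at position ", bad[1])
  if (!is.numeric(charge) || charge < 0 || charge != round(charge))
    stop("charge must be a nonnegative integer")
  structure(list(sequence = paste(res, collapse = ""), residues = res,
                 n_term = n_term, c_term = c_term, charge = as.integer(charge)),
            class = "hdx_peptide")
}

#' @export
print.hdx_peptide <- function(x, ...) {
  nt <- if (x$n_term == "acetyl") "Ac-" else ""
  ct <- if (x$c_term == "amide") "-NH2" else ""
  cat("hdx_peptide: ", nt, x$sequence, ct,
      "  (", length(x$residues), " residues",
      if (x$charge > 0) paste0(", +", x$charge) else "", ")\n", sep = "")
  invisible(x)
}

#' Enumerate exchangeable hydrogen sites
#'
#' Counts labile hydrogens on a peptide by site class: backbone amides
#' (residues 2..n excluding proline, plus the residue-1 amide when the
#' N-terminus is acetylated and residue 1 is not proline), side-chain
#' heteroatom hydrogens in their neutral forms, and terminal groups.
#' Charging protons (\code{charge} in \code{\link{peptide}}) are added to the
#' total only, mirroring site counting for protonated MS ions.
#'
#' @param pep An \code{\link{peptide}} object.
#' @return An object of class \code{site_inventory} with elements
#'   \code{backbone_count}, \code{side_chain_counts} (named integer vector
#'   over site classes, terminal classes included), and \code{total}.
#' @examples
#' enumerate_sites(peptide("PAAAAKAAAAKAAAAKAAAAK", n_term = "acetyl"))
#' enumerate_sites(peptide("K", charge = 1))  # free lysine [M+H]+: 6 sites
#' @export
enumerate_sites <- function(pep) {
  stopifnot(inherits(pep, "hdx_peptide"))
  res <- pep$residues
  n <- length(res)

  side <- integer(length(SITE_CLASSES))
  names(side) <- SITE_CLASSES
  for (r in res) {
    h <- SIDE_CHAIN_H[[r]]
    if (!is.null(h)) side[names(h)] <- side[names(h)] + h
  }

  ## Backbone amides: residue 1's alpha-amino group is not an amide unless
  ## acetylated; prolines never contribute.
  backbone <- sum(res[-1] != "P")
  if (pep$n_term == "free") {
    side["n_terminal_amine"] <- 2L
  } else if (res[1] != "P") {
    backbone <- backbone + 1L
  }
  if (pep$c_term == "acid") {
    side["c_terminal_acid"] <- 1L
  } else {
    side["c_terminal_amide"] <- 2L
  }

  structure(list(backbone_count = as.integer(backbone),
                 side_chain_counts = side,
                 side_total = as.integer(sum(side)),
                 charge = pep$charge,
                 total = as.integer(backbone + sum(side) + pep$charge)),
            class = "site_inventory")
}

#' @export
print.site_inventory <- function(x, ...) {
  nz <- x$side_chain_counts[x$side_chain_counts > 0]
  cat("site_inventory: backbone =", x$backbone_count,
      " side/terminal =", x$side_total,
      " total =", x$total, "\n")
  if (length(nz))
    cat("  ", paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate a site inventory
#'
#' @param x A \code{site_inventory}.
#' @param ... Unused.
#' @return data.frame with columns \code{class}, \code{count}.
#' @export
as.data.frame.site_inventory <- function(x, ...) {
  data.frame(class = c("backbone", names(x$side_chain_counts)),
             count = c(x$backbone_count, unname(x$side_chain_counts)),
             stringsAsFactors = FALSE)
}
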