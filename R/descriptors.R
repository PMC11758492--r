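## Structural-flexibility descriptors of peptide ensembles: gyration-tensor
## shape (Rg, asphericity), backbone RMSD densities, residue contact
## frequencies and a dihedral-window helicity measure.

#' Per-frame radius of gyration and asphericity
#'
#' For each frame the (mass-weighted) gyration tensor is diagonalised;
#' \eqn{R_g = \sqrt{\lambda_1+\lambda_2+\lambda_3}} and the asphericity
#' \eqn{\delta = 1 - 3(\lambda_1\lambda_2 + \lambda_2\lambda_3 +
#' \lambda_3\lambda_1)/(\lambda_1+\lambda_2+\lambda_3)^2}, which is 0 for a
#' spherically symmetric distribution and 1 in the rod (collinear) limit.
#'
#' @param traj An \code{\link{read_trajectory}} object.
#' @param atoms Atom row indices (default: all protein atoms).
#' @param mass_weighted Weight atoms by element mass (default) or uniformly.
#' @return data.frame: \code{frame}, \code{rg}, \code{delta};
#'   \code{delta} is \code{NA} for degenerate (single-point) geometry.
#' @export
shape_series <- function(traj, atoms = NULL, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "hdx_trajectory"))
  if (is.null(atoms)) atoms <- traj$protein
  w <- if (mass_weighted) {
    el <- traj$atoms$element[atoms]
    miss <- setdiff(unique(el), names(ATOMIC_MASS))
    if (length(miss)) stop("no mass for element(s): ", paste(miss, collapse = ", "))
    unname(ATOMIC_MASS[el])
  } else rep(1, length(atoms))
  w <- w / sum(w)
  out <- t(vapply(seq_len(traj$n_frames), function(f) {
    co <- frame_coords(traj, f, atoms)
    mu <- colSums(co * w)
    cc <- sweep(co, 2, mu)
    S <- crossprod(cc * w, cc)
    lam <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    tr <- sum(lam)
    delta <- if (tr <= 0) NA_real_ else
      1 - 3 * (lam[1] * lam[2] + lam[2] * lam[3] + lam[3] * lam[1]) / tr^2
    c(rg = sqrt(max(tr, 0)), delta = delta)
  }, numeric(2)))
  data.frame(frame = seq_len(traj$n_frames), rg = out[, "rg"],
             delta = out[, "delta"])
}

backbone_atom_idx <- function(traj, names = c("N", "CA", "C")) {
  traj$protein[traj$atoms$elety[traj$protein] %in% names]
}

#' Backbone RMSD to a reference frame
#'
#' Root-mean-square deviation of the backbone (N, CA, C) atoms to a
#' reference frame, after optimal rigid-body superposition when
#' \code{fit = TRUE} (Kabsch, via bio3d).
#'
#' @param traj An \code{\link{read_trajectory}} object.
#' @param reference_frame Frame index used as reference (default 1).
#' @param fit Superpose before measuring (default \code{TRUE}).
#' @return Numeric vector of per-frame RMSD (Angstrom).
#' @export
backbone_rmsd <- function(traj, reference_frame = 1, fit = TRUE) {
  stopifnot(inherits(traj, "hdx_trajectory"))
  bb <- backbone_atom_idx(traj)
  if (length(bb) < 3) stop("fewer than 3 backbone atoms resolved")
  xyz_inds <- as.vector(rbind(3 * bb - 2, 3 * bb - 1, 3 * bb))
  ref <- traj$xyz[reference_frame, ]
  as.numeric(bio3d::rmsd(a = ref, b = traj$xyz,
                         a.inds = xyz_inds, b.inds = xyz_inds, fit = fit))
}

#' Residue contact frequency map
#'
#' Fraction of frames in which the minimum heavy-atom distance between two
#' residues is at or below \code{cutoff}, for residue pairs separated by at
#' least \code{min_sep} in sequence.  Diagonal and near-diagonal entries
#' are 0 by construction.
#'
#' @param traj An \code{\link{read_trajectory}} object.
#' @param cutoff Contact distance (Angstrom), default 4.5.
#' @param min_sep Minimum |i - j| sequence separation, default 2.
#' @return Symmetric residue x residue matrix of contact frequencies in
#'   [0, 1], dimnames = residue numbers.
#' @export
contact_map <- function(traj, cutoff = 4.5, min_sep = 2) {
  stopifnot(inherits(traj, "hdx_trajectory"))
  resnos <- as.integer(names(traj$sequence))
  heavy <- traj$protein[traj$atoms$element[traj$protein] != "H"]
  byres <- split(heavy, factor(traj$atoms$resno[heavy], levels = resnos))
  nres <- length(resnos)
  cm <- matrix(0, nres, nres, dimnames = list(resnos, resnos))
  pairs <- which(outer(seq_len(nres), seq_len(nres),
                       function(i, j) j - i >= min_sep), arr.ind = TRUE)
  for (f in seq_len(traj$n_frames)) {
    co <- frame_coords(traj, f)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      a <- co[byres[[i]], , drop = FALSE]
      b <- co[byres[[j]], , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      if (min(d2) <= cutoff^2) cm[i, j] <- cm[i, j] + 1
    }
  }
  cm <- cm / traj$n_frames
  cm + t(cm)
}

phi_psi <- function(traj, frame) {
  resnos <- as.integer(names(traj$sequence))
  co <- frame_coords(traj, frame)
  idx <- function(r, name) {
    rows <- traj$protein[traj$atoms$resno[traj$protein] == r &
                           traj$atoms$elety[traj$protein] == name]
    if (length(rows) == 1) rows else NA_integer_
  }
  out <- data.frame(resno = resnos, phi = NA_real_, psi = NA_real_)
  for (k in seq_along(resnos)) {
    r <- resnos[k]
    N <- idx(r, "N"); CA <- idx(r, "CA"); C <- idx(r, "C")
    if (k > 1) {
      Cp <- idx(resnos[k - 1], "C")
      if (!anyNA(c(Cp, N, CA, C)))
        out$phi[k] <- dihedral_deg(co[Cp, ], co[N, ], co[CA, ], co[C, ])
    }
    if (k < length(resnos)) {
      Nn <- idx(resnos[k + 1], "N")
      if (!anyNA(c(N, CA, C, Nn)))
        out$psi[k] <- dihedral_deg(co[N, ], co[CA, ], co[C, ], co[Nn, ])
    }
  }
  out
}

#' Dihedral-window helicity
#'
#' Fraction of frames in which an interior residue's backbone dihedrals fall
#' in the alpha-helical region: \eqn{\phi \in -57 \pm w}, \eqn{\psi \in
#' -47 \pm w} (window \code{w} default 30 degrees).  This is a documented
#' dihedral approximation to pattern-based secondary-structure assignment,
#' not a reimplementation of it.  Terminal residues (no phi or no psi) are
#' reported as \code{NA}.
#'
#' @param traj An \code{\link{read_trajectory}} object.
#' @param window Half-width of the dihedral acceptance window (degrees).
#' @return data.frame: \code{resno}, \code{aa}, \code{helix_fraction}.
#' @export
helicity <- function(traj, window = 30) {
  stopifnot(inherits(traj, "hdx_trajectory"))
  resnos <- as.integer(names(traj$sequence))
  counts <- rep(0, length(resnos))
  defined <- rep(FALSE, length(resnos))
  for (f in seq_len(traj$n_frames)) {
    pp <- phi_psi(traj, f)
    ok <- !is.na(pp$phi) & !is.na(pp$psi)
    defined <- defined | ok
    hel <- ok & abs(pp$phi - (-57)) <= window & abs(pp$psi - (-47)) <= window
    counts <- counts + hel
  }
  frac <- counts / traj$n_frames
  frac[!defined] <- NA_real_
  data.frame(resno = resnos, aa = unname(traj$sequence),
             helix_fraction = frac)
}
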