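## Hydrogen-bond geometry operators for backbone amide hydrogens.
## Convention: the donor is the amide N-H; an acceptor oxygen/nitrogen is in
## hydrogen-bond geometry when dist(H, acceptor) <= cutoff and the
## N-H...acceptor angle at H is within `angle_tol` of linear (>= 180 -
## angle_tol degrees).  An N...acceptor distance convention is selectable.

hbond_geometry <- function(h, n, acc, dist_cutoff, angle_min, dist_mode) {
  if (!nrow(acc)) return(logical(0))
  ref <- if (dist_mode == "h_o") h else n
  d2 <- rowSums(sweep(acc, 2, ref)^2)
  ok <- d2 <= dist_cutoff^2
  if (any(ok)) {
    u <- vunit(n - h)
    va <- sweep(acc[ok, , drop = FALSE], 2, h)
    cosang <- (va %*% u) / sqrt(rowSums(va^2))
    ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
    ok[ok] <- ang >= angle_min
  }
  ok
}

#' Count water molecules hydrogen-bonded to an amide hydrogen
#'
#' @param traj An \code{\link{read_trajectory}} object.
#' @param frame Frame index.
#' @param residue Residue number (must have a resolved amide hydrogen).
#' @param dist_cutoff Distance cutoff, Angstrom (default 3.3).
#' @param angle_min Minimum N-H...O angle, degrees (default 150, i.e. within
#'   30 degrees of linear).
#' @param dist_mode Distance measured from the amide H (\code{"h_o"},
#'   default) or from the amide N (\code{"n_o"}) to the water oxygen.
#' @return Integer count of water oxygens in hydrogen-bond geometry.
#' @export
water_hbond_count <- function(traj, frame, residue, dist_cutoff = 3.3,
                              angle_min = 150, dist_mode = c("h_o", "n_o")) {
  dist_mode <- match.arg(dist_mode)
  i <- match(residue, traj$amide$resno)
  if (is.na(i)) stop("residue ", residue, " has no resolved amide hydrogen")
  co <- frame_coords(traj, frame)
  h <- co[traj$amide$h[i], ]
  n <- co[traj$amide$n[i], ]
  wat <- co[traj$water_o, , drop = FALSE]
  sum(hbond_geometry(h, n, wat, dist_cutoff, angle_min, dist_mode))
}

#' Test for an intramolecular hydrogen bond from an amide hydrogen
#'
#' Acceptors are all protein nitrogen/oxygen heavy atoms except the
#' residue's own backbone N, under the same distance/angle geometry as
#' \code{\link{water_hbond_count}}.
#'
#' @inheritParams water_hbond_count
#' @return \code{TRUE} if any protein acceptor is in hydrogen-bond geometry.
#' @export
intra_hbond_exists <- function(traj, frame, residue, dist_cutoff = 3.3,
                               angle_min = 150, dist_mode = c("h_o", "n_o")) {
  dist_mode <- match.arg(dist_mode)
  i <- match(residue, traj$amide$resno)
  if (is.na(i)) stop("residue ", residue, " has no resolved amide hydrogen")
  co <- frame_coords(traj, frame)
  h <- co[traj$amide$h[i], ]
  n <- co[traj$amide$n[i], ]
  acc_idx <- setdiff(traj$acceptors, traj$amide$n[i])
  acc <- co[acc_idx, , drop = FALSE]
  any(hbond_geometry(h, n, acc, dist_cutoff, angle_min, dist_mode))
}
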