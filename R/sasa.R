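## Shrake-Rupley solvent-accessible surface area, per atom.  Test points on
## a deterministic golden-spiral sphere of radius r_atom + r_probe; a point
## is accessible if outside every neighbour's probe-expanded sphere.

sasa_points <- function(coords, radii, targets, probe = 1.4, n_points = 960) {
  pts <- sphere_points(n_points)
  vapply(targets, function(t) {
    rt <- radii[t] + probe
    d2 <- rowSums(sweep(coords, 2, coords[t, ])^2)
    reach <- (radii + probe + rt)^2
    nb <- which(d2 < reach & d2 > 0)
    nb <- nb[nb != t]
    sp <- sweep(pts * rt, 2, coords[t, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      rj2 <- (radii[j] + probe)^2
      acc <- acc & (rowSums(sweep(sp, 2, coords[j, ])^2) > rj2)
      if (!any(acc)) break
    }
    4 * pi * rt^2 * mean(acc)
  }, numeric(1))
}

atom_radii <- function(elements, radii = VDW_RADII) {
  miss <- setdiff(unique(elements), names(radii))
  if (length(miss))
    stop("no van der Waals radius for element(s): ",
         paste(miss, collapse = ", "))
  unname(radii[elements])
}

#' SASA of backbone amide hydrogens
#'
#' Per-atom Shrake-Rupley solvent-accessible surface area of each resolved
#' backbone amide hydrogen in one frame.  By default the occluding set is
#' all non-water atoms (solvent is what the probe represents, so waters do
#' not occlude); Bondi radii including hydrogens; probe 1.4 Angstrom.
#'
#' @param traj An \code{\link{read_trajectory}} object.
#' @param frame Frame index.
#' @param probe Probe radius (Angstrom).
#' @param n_points Sphere test points per atom.
#' @param occluders \code{"nonwater"} (default), \code{"protein"}, or
#'   \code{"all"}.
#' @param radii Named per-element radii (Angstrom).
#' @return Named numeric vector (residue number -> SASA in Angstrom^2).
#' @export
sasa_amide_h <- function(traj, frame, probe = 1.4, n_points = 960,
                         occluders = c("nonwater", "protein", "all"),
                         radii = VDW_RADII) {
  stopifnot(inherits(traj, "hdx_trajectory"))
  occluders <- match.arg(occluders)
  keep <- switch(occluders, nonwater = traj$nonwater,
                 protein = traj$protein, all = seq_len(nrow(traj$atoms)))
  keep <- union(keep, traj$amide$h)
  coords <- frame_coords(traj, frame, keep)
  r <- atom_radii(traj$atoms$element[keep], radii)
  tgt <- match(traj$amide$h, keep)
  out <- sasa_points(coords, r, tgt, probe = probe, n_points = n_points)
  names(out) <- traj$amide$resno
  out
}
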