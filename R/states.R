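## Per-frame open/closed classification of backbone amides.
##
## Two models:
##   inter: open  <=> SASA(NH) >= threshold AND >= `min_waters` waters in
##          hydrogen-bond geometry with the amide hydrogen.
##   intra: closed <=> SASA(NH) < threshold OR any intramolecular
##          hydrogen bond donated by the amide hydrogen; open otherwise.
## The inter open condition is strictly stronger than the intra one under
## shared geometry parameters, so the intra open set contains the inter
## open set frame-by-frame.

#' Classify open/closed amide states across a trajectory
#'
#' @param traj An \code{\link{read_trajectory}} object.
#' @param model \code{"inter"} (solvent-exposure + water coordination) or
#'   \code{"intra"} (burial or intramolecular hydrogen bonding closes).
#' @param sasa_threshold Open requires SASA >= this (Angstrom^2);
#'   default 8.3.
#' @param min_waters Water count required for the inter model (default 2).
#' @param dist_cutoff,angle_min,dist_mode Hydrogen-bond geometry, see
#'   \code{\link{water_hbond_count}}.
#' @param probe,n_points,occluders SASA parameters, see
#'   \code{\link{sasa_amide_h}}.
#' @param n_max Maximum number of frames analysed; longer trajectories are
#'   subsampled by an even stride (default 25000).
#' @return Object of class \code{state_trace}: list with \code{model},
#'   \code{open} (residues x frames logical matrix), \code{frames} (indices
#'   used), \code{n} (frames analysed) and \code{summary} (data.frame:
#'   resno, aa, f_open, f_closed, tau_open, tau_closed — mean dwell lengths
#'   in frames, \code{NA} when a state is never visited).
#' @export
classify_states <- function(traj, model = c("inter", "intra"),
                            sasa_threshold = 8.3, min_waters = 2,
                            dist_cutoff = 3.3, angle_min = 150,
                            dist_mode = c("h_o", "n_o"),
                            probe = 1.4, n_points = 960,
                            occluders = "nonwater", n_max = 25000) {
  stopifnot(inherits(traj, "hdx_trajectory"))
  model <- match.arg(model)
  dist_mode <- match.arg(dist_mode)
  frames <- seq_len(traj$n_frames)
  if (traj$n_frames > n_max)
    frames <- unique(round(seq(1, traj$n_frames, length.out = n_max)))
  nres <- nrow(traj$amide)
  open <- matrix(NA, nres, length(frames),
                 dimnames = list(traj$amide$resno, NULL))
  for (k in seq_along(frames)) {
    f <- frames[k]
    sasa <- sasa_amide_h(traj, f, probe = probe, n_points = n_points,
                         occluders = occluders)
    exposed <- sasa >= sasa_threshold
    for (i in seq_len(nres)) {
      r <- traj$amide$resno[i]
      if (model == "inter") {
        open[i, k] <- exposed[i] &&
          water_hbond_count(traj, f, r, dist_cutoff, angle_min,
                            dist_mode) >= min_waters
      } else {
        open[i, k] <- exposed[i] &&
          !intra_hbond_exists(traj, f, r, dist_cutoff, angle_min, dist_mode)
      }
    }
  }
  summary <- state_summary(open, traj$amide)
  structure(list(model = model, open = open, frames = frames,
                 n = length(frames), summary = summary,
                 params = list(sasa_threshold = sasa_threshold,
                               min_waters = min_waters,
                               dist_cutoff = dist_cutoff,
                               angle_min = angle_min, dist_mode = dist_mode,
                               probe = probe, n_points = n_points,
                               occluders = occluders)),
            class = "state_trace")
}

state_summary <- function(open, amide) {
  f_open <- rowMeans(open)
  dwell <- t(apply(open, 1, function(row) {
    r <- rle(row)
    c(tau_open = if (any(r$values)) mean(r$lengths[r$values]) else NA_real_,
      tau_closed = if (any(!r$values)) mean(r$lengths[!r$values]) else NA_real_)
  }))
  data.frame(resno = amide$resno, aa = amide$aa,
             f_open = f_open, f_closed = 1 - f_open,
             tau_open = dwell[, "tau_open"],
             tau_closed = dwell[, "tau_closed"],
             row.names = NULL)
}

#' Build a state trace from an explicit open/closed matrix
#'
#' Wraps a residues x frames logical matrix (TRUE = open) as a
#' \code{state_trace}, computing the population and dwell-time summaries.
#' Used for ground-truth manifests and for feeding known state patterns to
#' the protection-factor machinery.
#'
#' @param open Logical matrix, residues x frames.
#' @param model Model tag to attach.
#' @param resno,aa Residue numbers and one-letter codes.
#' @return A \code{state_trace}.
#' @examples
#' state_trace_from_matrix(matrix(c(TRUE, FALSE), 2, 10), model = "inter")
#' @export
state_trace_from_matrix <- function(open, model = "inter",
                                    resno = seq_len(nrow(open)),
                                    aa = rep("A", nrow(open))) {
  open <- as.matrix(open)
  rownames(open) <- resno
  structure(list(model = model, open = open, frames = seq_len(ncol(open)),
                 n = ncol(open),
                 summary = state_summary(open, data.frame(resno = resno,
                                                          aa = aa)),
                 params = list()),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat("state_trace (M_", x$model, "): ", nrow(x$open), " residues x ",
      x$n, " frames\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}
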