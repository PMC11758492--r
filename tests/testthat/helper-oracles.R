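# Independent brute-force oracles and small fixture builders.  Oracles are
# written as plain loops over explicit geometry so they share no code path
# with the vectorised implementations they check.

# Monte-Carlo SASA of one atom: random points on its probe-expanded sphere,
# accessibility tested against every other atom by explicit looping.
oracle_sasa_mc <- function(coords, radii, target, probe = 1.4,
                           n_mc = 20000, seed = 42) {
  set.seed(seed)
  rt <- radii[target] + probe
  z <- stats::runif(n_mc, -1, 1)
  th <- stats::runif(n_mc, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  pts <- cbind(r * cos(th), r * sin(th), z) * rt
  pts <- sweep(pts, 2, coords[target, ], "+")
  acc <- rep(TRUE, n_mc)
  for (j in seq_len(nrow(coords))) {
    if (j == target) next
    rj <- radii[j] + probe
    dx <- pts[, 1] - coords[j, 1]
    dy <- pts[, 2] - coords[j, 2]
    dz <- pts[, 3] - coords[j, 3]
    acc <- acc & (dx^2 + dy^2 + dz^2 > rj^2)
  }
  4 * pi * rt^2 * mean(acc)
}

# All-pairs hydrogen-bond count: explicit per-acceptor loop with acos.
oracle_hbond_count <- function(h, n, acceptors, dist_cutoff = 3.3,
                               angle_min = 150) {
  cnt <- 0L
  for (k in seq_len(nrow(acceptors))) {
    a <- acceptors[k, ]
    d <- sqrt(sum((a - h)^2))
    if (d > dist_cutoff) next
    v1 <- (n - h) / sqrt(sum((n - h)^2))
    v2 <- (a - h) / d
    ang <- acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
    if (ang >= angle_min) cnt <- cnt + 1L
  }
  cnt
}

# Gyration tensor by explicit double loop; returns Rg and asphericity.
oracle_shape <- function(coords, w) {
  w <- w / sum(w)
  mu <- c(sum(coords[, 1] * w), sum(coords[, 2] * w), sum(coords[, 3] * w))
  S <- matrix(0, 3, 3)
  for (i in seq_len(nrow(coords))) {
    d <- coords[i, ] - mu
    S <- S + w[i] * outer(d, d)
  }
  lam <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
  tr <- sum(lam)
  c(rg = sqrt(tr),
    delta = 1 - 3 * (lam[1] * lam[2] + lam[2] * lam[3] +
                       lam[3] * lam[1]) / tr^2)
}

# Wrap a hand-built atom table + frame list as an hdx_trajectory.
custom_traj <- function(atoms, frames) {
  xyz <- do.call(rbind, lapply(frames, function(co) as.vector(t(co))))
  hdxcalib:::build_trajectory(atoms, xyz)
}

atom_row <- function(elety, resid, resno, chain = "A") {
  data.frame(elety = elety, resid = resid, resno = resno, chain = chain,
             element = hdxcalib:::elety2element(elety),
             stringsAsFactors = FALSE)
}

# A single solvated amide probe: N-H pointing +z, two waters and a carbon
# whose positions the caller supplies.  Residue 1 is a dummy so that
# residue 2 carries the amide.
amide_probe_traj <- function(water_o = NULL, extra_c = NULL) {
  atoms <- rbind(
    atom_row("N", "ALA", 1), atom_row("CA", "ALA", 1),
    atom_row("C", "ALA", 1), atom_row("O", "ALA", 1),
    atom_row("N", "ALA", 2), atom_row("H", "ALA", 2),
    atom_row("CA", "ALA", 2), atom_row("C", "ALA", 2),
    atom_row("O", "ALA", 2))
  co <- rbind(c(-6, 0, 0), c(-5, 0.8, 0), c(-4, 0, 0), c(-4, -1.2, 0),
              c(0, 0, 0), c(0, 0, 1.01),
              c(1.2, -0.8, -0.3), c(2.2, 0.1, -0.5), c(2.4, 1.2, -0.9))
  if (!is.null(water_o)) {
    for (i in seq_len(nrow(water_o))) {
      atoms <- rbind(atoms, atom_row("OH2", "TIP3", 2 + i, "W"),
                     atom_row("H1", "TIP3", 2 + i, "W"),
                     atom_row("H2", "TIP3", 2 + i, "W"))
      co <- rbind(co, water_o[i, ], water_o[i, ] + c(0.96, 0, 0),
                  water_o[i, ] + c(-0.24, 0.93, 0))
    }
  }
  if (!is.null(extra_c)) {
    for (i in seq_len(nrow(extra_c))) {
      atoms <- rbind(atoms, atom_row(paste0("C", i), "CAG", 100 + i, "X"))
      co <- rbind(co, extra_c[i, ])
    }
  }
  custom_traj(atoms, list(co))
}

# Random "frame": an amide probe with waters thrown uniformly in a box
# around the hydrogen.
random_probe_traj <- function(n_waters, seed) {
  set.seed(seed)
  wat <- cbind(stats::runif(n_waters, -4, 4), stats::runif(n_waters, -4, 4),
               stats::runif(n_waters, -3, 5))
  amide_probe_traj(water_o = wat)
}

table1_bb_data <- function() {
  list(x = c(20, 16, 5, 12, 20), y = c(1.5, 6.1, 17.6, 10.8, 31.0),
       peptides = c("PA", "Nt17", "BK", "KDD", "PS"))
}
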