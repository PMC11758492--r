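tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))

point_cloud_traj <- function(frames) {
  atoms <- do.call(rbind, lapply(seq_len(nrow(frames[[1]])), function(i)
    atom_row("CA", "ALA", 1)))
  custom_traj(atoms, frames)
}

test_that("asphericity spans its sphere-to-rod limits", {
  # regular tetrahedron: isotropic gyration tensor -> delta = 0
  s <- shape_series(point_cloud_traj(list(tetra)), mass_weighted = FALSE)
  expect_equal(s$delta, 0, tolerance = 1e-12)
  expect_equal(s$rg, sqrt(3), tolerance = 1e-12)
  # collinear points -> delta = 1
  line <- cbind(seq(0, 9), 0, 0)
  s2 <- shape_series(point_cloud_traj(list(line)), mass_weighted = FALSE)
  expect_equal(s2$delta, 1, tolerance = 1e-12)
})

test_that("gyration shape matches a loop-assembled tensor on random clouds", {
  set.seed(15)
  for (i in 1:12) {
    co <- matrix(rnorm(3 * 15, sd = 3), ncol = 3)
    s <- shape_series(point_cloud_traj(list(co)), mass_weighted = FALSE)
    want <- oracle_shape(co, rep(1, 15))
    expect_equal(s$rg, unname(want["rg"]), tolerance = 1e-10)
    expect_equal(s$delta, unname(want["delta"]), tolerance = 1e-10)
    # rigid-body invariance
    rot <- hdxcalib:::random_rotation()
    s2 <- shape_series(point_cloud_traj(
      list(sweep(co %*% t(rot), 2, c(5, -2, 1), "+"))),
      mass_weighted = FALSE)
    expect_equal(s2$rg, s$rg, tolerance = 1e-10)
    expect_equal(s2$delta, s$delta, tolerance = 1e-10)
  }
})

test_that("mass weighting changes the gyration radius as expected", {
  toy <- make_toy_trajectory("AKA", n_frames = 1, f_open = 1,
                             family = "extended", dir = tempdir(),
                             name = "rgw")
  traj <- read_trajectory(toy$pdb)
  rg_m <- shape_series(traj)$rg
  rg_g <- shape_series(traj, mass_weighted = FALSE)$rg
  expect_false(isTRUE(all.equal(rg_m, rg_g)))
})

test_that("backbone RMSD removes rigid-body motion only when fitted", {
  toy <- make_toy_trajectory("AAAAA", n_frames = 1, f_open = 1,
                             family = "helix", dir = tempdir(), name = "rms")
  traj <- read_trajectory(toy$pdb)
  co <- hdxcalib:::frame_coords(traj, 1)
  rot <- { set.seed(2); hdxcalib:::random_rotation() }
  frames <- list(co, sweep(co %*% t(rot), 2, c(3, 4, 5), "+"),
                 sweep(co, 2, c(1, 0, 0), "+"))
  tr3 <- custom_traj(traj$atoms, frames)
  fit <- backbone_rmsd(tr3, reference_frame = 1, fit = TRUE)
  expect_equal(fit[1], 0, tolerance = 1e-8)
  expect_equal(fit[2], 0, tolerance = 1e-6)   # superposition removes rigid motion
  nofit <- backbone_rmsd(tr3, reference_frame = 1, fit = FALSE)
  expect_equal(nofit[3], 1, tolerance = 1e-6) # uniform 1 A shift
})

test_that("contact maps separate extended chains from helices", {
  te <- make_toy_trajectory("AAAAAAAAAA", n_frames = 1, f_open = 0,
                            family = "extended", dir = tempdir(),
                            name = "cme")
  cm_e <- contact_map(read_trajectory(te$pdb))
  long <- abs(row(cm_e) - col(cm_e)) >= 3
  expect_true(all(cm_e[long] == 0))
  expect_true(all(cm_e >= 0 & cm_e <= 1))
  expect_true(isSymmetric(cm_e))
  expect_true(all(diag(cm_e) == 0))
  th <- make_toy_trajectory("AAAAAAAAAA", n_frames = 1, f_open = 0,
                            family = "helix", dir = tempdir(), name = "cmh")
  cm_h <- contact_map(read_trajectory(th$pdb))
  i <- 1:6
  expect_true(all(cm_h[cbind(i, i + 4)] == 1))
})

test_that("helicity windows classify ideal conformers and mixtures", {
  th <- make_toy_trajectory("AAAAAAA", n_frames = 1, f_open = 0,
                            family = "helix", dir = tempdir(), name = "heh")
  trh <- read_trajectory(th$pdb)
  h <- helicity(trh)
  expect_true(all(h$helix_fraction[2:6] == 1))
  expect_true(is.na(h$helix_fraction[1]) && is.na(h$helix_fraction[7]))
  te <- make_toy_trajectory("AAAAAAA", n_frames = 1, f_open = 0,
                            family = "extended", dir = tempdir(),
                            name = "hee")
  tre <- read_trajectory(te$pdb)
  expect_true(all(helicity(tre)$helix_fraction[2:6] == 0))
  # a 3-frame mixture: 1 helix + 2 extended frames -> fraction 1/3
  mix <- custom_traj(trh$atoms,
                     list(hdxcalib:::frame_coords(trh, 1),
                          hdxcalib:::frame_coords(tre, 1),
                          hdxcalib:::frame_coords(tre, 1)))
  expect_equal(helicity(mix)$helix_fraction[2:6], rep(1 / 3, 5))
})
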