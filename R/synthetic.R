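## Synthetic fixtures with construction-known ground truth: toy hydrated
## trajectories with controllable per-residue open fractions, binomially
## deuterated isotopic envelopes, and amino-acid-standard exchange series.
## No physics is simulated; waters and burial cages are placed analytically
## inside or outside the hydrogen-bond acceptance cone.

## ---- ideal-geometry chain builder -------------------------------------

BOND <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
             n_h = 1.01)
ANGLE <- list(n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7,
              ca_c_o = 120.8)

## Build one backbone conformation (N, H, CA, C, O per residue; no H on
## residue 1 or prolines) from per-residue phi/psi.  Returns list(atoms=
## data.frame(elety, resid, resno, chain, element), coords = N x 3).
build_chain <- function(sequence, phi, psi) {
  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  stopifnot(length(phi) == n, length(psi) == n)
  pos <- list(); lab <- list()
  add <- function(name, resno, xyz) {
    pos[[length(pos) + 1L]] <<- xyz
    lab[[length(lab) + 1L]] <<- c(name, resno)
  }
  N <- c(0, 0, 0)
  CA <- c(BOND$n_ca, 0, 0)
  th <- (180 - ANGLE$n_ca_c) * pi / 180
  C <- CA + BOND$ca_c * c(cos(th), sin(th), 0)
  Nprev <- N; CAprev <- CA; Cprev <- C
  add("N", 1, N); add("CA", 1, CA); add("C", 1, C)
  for (i in 2:max(n, 2)) {
    if (i > n) break
    Ni <- place_atom(Nprev, CAprev, Cprev, BOND$c_n, ANGLE$ca_c_n,
                     psi[i - 1])
    ## carbonyl O of residue i-1, in-plane opposite the new N
    Oi1 <- place_atom(Nprev, CAprev, Cprev, BOND$c_o, ANGLE$ca_c_o,
                      psi[i - 1] - 180)
    add("O", i - 1, Oi1)
    CAi <- place_atom(CAprev, Cprev, Ni, BOND$n_ca, ANGLE$c_n_ca, 180)
    Ci <- place_atom(Cprev, Ni, CAi, BOND$ca_c, ANGLE$n_ca_c, phi[i])
    if (res[i] != "P") {
      Hd <- vunit(vunit(Ni - Cprev) + vunit(Ni - CAi))
      add("H", i, Ni + BOND$n_h * Hd)
    }
    add("N", i, Ni); add("CA", i, CAi); add("C", i, Ci)
    Nprev <- Ni; CAprev <- CAi; Cprev <- Ci
  }
  ## terminal carbonyl O
  On <- place_atom(Nprev, CAprev, Cprev, BOND$c_o, ANGLE$ca_c_o,
                   psi[n] - 180)
  add("O", n, On)
  lab <- do.call(rbind, lab)
  atoms <- data.frame(elety = lab[, 1],
                      resid = unname(AA1TO3[res[as.integer(lab[, 2])]]),
                      resno = as.integer(lab[, 2]), chain = "A",
                      stringsAsFactors = FALSE)
  atoms$element <- elety2element(atoms$elety)
  ord <- order(atoms$resno, match(atoms$elety, c("N", "H", "CA", "C", "O")))
  list(atoms = atoms[ord, ], coords = do.call(rbind, pos)[ord, ])
}

family_dihedrals <- function(family, n) {
  switch(family,
         helix = list(phi = rep(-57, n), psi = rep(-47, n)),
         extended = list(phi = rep(-139, n), psi = rep(135, n)),
         coil = list(phi = stats::runif(n, -160, -50),
                     psi = stats::runif(n, -70, 160)))
}

## Rigid, well-separated amide units: one peptide-like unit per residue on a
## 9 Angstrom pitch, amide H pointing +z with nothing above it.  An
## idealized probe geometry: every amide H has high, frame-constant solvent
## exposure, so open/closed is governed purely by water/cage placement.
dilute_chain <- function(sequence, pitch = 9) {
  res <- strsplit(toupper(sequence), "")[[1]]
  unit <- rbind(N = c(0, 0, 0), H = c(0, 0, BOND$n_h),
                CA = c(1.23, -0.75, -0.30), C = c(2.20, 0.20, -0.50),
                O = c(2.40, 1.30, -0.90))
  rows <- list(); coords <- list()
  for (i in seq_along(res)) {
    names_i <- rownames(unit)
    if (i == 1 || res[i] == "P") names_i <- setdiff(names_i, "H")
    for (nm in names_i) {
      rows[[length(rows) + 1L]] <- c(nm, i)
      coords[[length(coords) + 1L]] <- unit[nm, ] + c((i - 1) * pitch, 0, 0)
    }
  }
  lab <- do.call(rbind, rows)
  atoms <- data.frame(elety = lab[, 1],
                      resid = unname(AA1TO3[res[as.integer(lab[, 2])]]),
                      resno = as.integer(lab[, 2]), chain = "A",
                      stringsAsFactors = FALSE)
  atoms$element <- elety2element(atoms$elety)
  list(atoms = atoms, coords = do.call(rbind, coords))
}

## Evenly spread k open frames over n (Bresenham schedule).
spread_schedule <- function(k, n) {
  j <- seq_len(n)
  floor(j * k / n) > floor((j - 1) * k / n)
}

## ---- multi-model PDB writer -------------------------------------------

write_multimodel_pdb <- function(atoms, xyz, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nfr <- nrow(xyz)
  for (f in seq_len(nfr)) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      ## cols: serial 7-11, name 14-16, resName 18-21, chain 22, resSeq 23-26
      "ATOM  %5d  %-3s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(atoms)), atoms$elety, atoms$resid, atoms$chain,
      atoms$resno, co[, 1], co[, 2], co[, 3], atoms$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- toy trajectory generator -----------------------------------------

#' Generate a toy hydrated trajectory with known open/closed states
#'
#' Builds a peptide-like topology plus per-amide waters (and, in
#' \code{"bury"} mode, carbon burial cages), then toggles them frame by
#' frame so that each amide satisfies the solvent-exposure + water
#' coordination open criterion in exactly the prescribed fraction of
#' frames.  The \code{"dilute"} family (rigid, well-separated amide units)
#' is the default for state control because every amide hydrogen then has
#' high, frame-constant solvent exposure and residues cannot shadow each
#' other; \code{"helix"}, \code{"extended"} and \code{"coil"} build ideal
#' or dihedral-sampled chain geometries for hydrogen-bond and descriptor
#' fixtures (state toggling still places waters, but chain self-occlusion
#' is then physics, not bookkeeping).
#'
#' In \code{"dehydrate"} closed frames only the waters leave (closed under
#' the water-coordination model, still open under the intramolecular
#' model); in \code{"bury"} closed frames a carbon cage also encloses the
#' amide hydrogen (closed under both models).
#'
#' @param sequence One-letter sequence.
#' @param n_frames Number of frames.
#' @param f_open Target open fraction: scalar or one value per amide
#'   residue (residues 2..n excluding prolines).
#' @param family \code{"dilute"}, \code{"helix"}, \code{"extended"} or
#'   \code{"coil"}.
#' @param closed_mode \code{"dehydrate"} or \code{"bury"} (bury requires
#'   the dilute family).
#' @param pattern Open-frame schedule: \code{"spread"} (even Bresenham
#'   spread), \code{"block"} (open frames first) or \code{"alternate"}.
#' @param seed Seed fixing all randomness (coil dihedrals).
#' @param dir Output directory.
#' @param name Basename for the emitted files.
#' @return List with \code{pdb} (multi-model PDB path), \code{states_tsv}
#'   (ground-truth per-frame states), and \code{manifest}: list with
#'   \code{open} (amide x frame logical matrix), \code{resno},
#'   \code{f_open_target}, \code{f_open_realized}, \code{family},
#'   \code{closed_mode}, \code{seed}.
#' @examples
#' \donttest{
#' toy <- make_toy_trajectory("AAAA", n_frames = 10, f_open = 0.5)
#' traj <- read_trajectory(toy$pdb)
#' }
#' @export
make_toy_trajectory <- function(sequence, n_frames, f_open = 0.5,
                                family = c("dilute", "helix", "extended",
                                           "coil"),
                                closed_mode = c("dehydrate", "bury"),
                                pattern = c("spread", "block", "alternate"),
                                seed = 1, dir = tempdir(), name = "toy") {
  family <- match.arg(family)
  closed_mode <- match.arg(closed_mode)
  pattern <- match.arg(pattern)
  stopifnot(n_frames >= 1)
  res <- strsplit(toupper(sequence), "")[[1]]
  if (any(!res %in% names(AA1TO3))) stop("invalid sequence")
  amide_res <- setdiff(which(res != "P"), 1L)
  n_am <- length(amide_res)
  if (length(f_open) == 1) f_open <- rep(f_open, n_am)
  if (length(f_open) != n_am)
    stop("f_open must be scalar or one value per amide residue (", n_am, ")")
  if (any(f_open < 0 | f_open > 1)) stop("f_open must lie in [0, 1]")
  k_open <- round(f_open * n_frames)
  if (closed_mode == "bury" && family != "dilute")
    stop("burial cages require the dilute family")

  set.seed(seed)
  ## base chain (static except for coil, which is resampled per frame)
  base <- if (family == "dilute") dilute_chain(sequence) else {
    dh <- family_dihedrals(family, length(res))
    build_chain(sequence, dh$phi, dh$psi)
  }
  atoms <- base$atoms

  ## per-amide decorations: 2 waters (+ optional 6-carbon cage)
  wat_rows <- list(); cage_rows <- list()
  next_resno <- length(res)
  for (i in seq_len(n_am)) {
    next_resno <- next_resno + 1L
    for (nm in c("OH2", "H1", "H2"))
      wat_rows[[length(wat_rows) + 1L]] <-
        data.frame(elety = nm, resid = "TIP3", resno = next_resno,
                   chain = "W", element = substr(nm, 1, 1),
                   stringsAsFactors = FALSE)
    next_resno <- next_resno + 1L
    for (nm in c("OH2", "H1", "H2"))
      wat_rows[[length(wat_rows) + 1L]] <-
        data.frame(elety = nm, resid = "TIP3", resno = next_resno,
                   chain = "W", element = substr(nm, 1, 1),
                   stringsAsFactors = FALSE)
    if (closed_mode == "bury") {
      next_resno <- next_resno + 1L
      for (j in 1:6)
        cage_rows[[length(cage_rows) + 1L]] <-
          data.frame(elety = paste0("C", j), resid = "CAG",
                     resno = next_resno, chain = "X", element = "C",
                     stringsAsFactors = FALSE)
    }
  }
  atoms <- rbind(atoms, do.call(rbind, wat_rows))
  if (length(cage_rows)) atoms <- rbind(atoms, do.call(rbind, cage_rows))
  n_atoms <- nrow(atoms)

  ## open-frame schedules
  open <- matrix(FALSE, n_am, n_frames)
  for (i in seq_len(n_am)) {
    open[i, ] <- switch(pattern,
      spread = spread_schedule(k_open[i], n_frames),
      block = seq_len(n_frames) <= k_open[i],
      alternate = {
        ## odd frames first, so k <= n/2 yields a strict open/closed
        ## alternation; excess opens spill into even frames
        fr <- seq_len(n_frames)
        pref <- c(fr[fr %% 2 == 1], fr[fr %% 2 == 0])
        out <- rep(FALSE, n_frames)
        out[pref[seq_len(k_open[i])]] <- TRUE
        out
      })
  }
  rownames(open) <- amide_res

  ## indices of protein N/H per amide in the atom table
  h_idx <- vapply(amide_res, function(r)
    which(atoms$resno == r & atoms$elety == "H" & atoms$chain == "A"),
    integer(1))
  n_idx <- vapply(amide_res, function(r)
    which(atoms$resno == r & atoms$elety == "N" & atoms$chain == "A"),
    integer(1))
  wat_o <- which(atoms$resid == "TIP3" & atoms$elety == "OH2")
  cage_idx <- which(atoms$resid == "CAG")

  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1)) * 2.5
  wat_h <- rbind(c(0.96, 0, 0), c(-0.24, 0.93, 0))

  xyz <- matrix(NA_real_, n_frames, 3 * n_atoms)
  for (f in seq_len(n_frames)) {
    if (family == "coil" && f > 1) {
      dh <- family_dihedrals("coil", length(res))
      base <- build_chain(sequence, dh$phi, dh$psi)
    }
    co <- matrix(NA_real_, n_atoms, 3)
    co[seq_len(nrow(base$coords)), ] <- base$coords
    for (i in seq_len(n_am)) {
      H <- co[h_idx[i], ]
      N <- co[n_idx[i], ]
      u <- vunit(H - N)
      ## a stable perpendicular to u
      p <- vunit(if (abs(u[1]) < 0.9) c(1, 0, 0) - u * u[1] else
                   c(0, 1, 0) - u * u[2])
      far <- c(0, 60 + 6 * i, 25)
      o1 <- H + 2.9 * u
      o2 <- H + 3.0 * (cos(20 * pi / 180) * u + sin(20 * pi / 180) * p)
      if (!open[i, f]) { o1 <- o1 + far; o2 <- o2 + far }
      w1 <- wat_o[2 * i - 1]; w2 <- wat_o[2 * i]
      co[w1, ] <- o1; co[w1 + 1, ] <- o1 + wat_h[1, ]; co[w1 + 2, ] <- o1 + wat_h[2, ]
      co[w2, ] <- o2; co[w2 + 1, ] <- o2 + wat_h[1, ]; co[w2 + 2, ] <- o2 + wat_h[2, ]
      if (closed_mode == "bury") {
        cg <- cage_idx[(6 * (i - 1) + 1):(6 * i)]
        center <- if (open[i, f]) H + c(0, -60 - 6 * i, -25) else H
        co[cg, ] <- sweep(octa, 2, center, "+")
      }
    }
    xyz[f, ] <- as.vector(t(co))
  }

  pdb_path <- file.path(dir, paste0(name, ".pdb"))
  write_multimodel_pdb(atoms, xyz, pdb_path)
  states_path <- file.path(dir, paste0(name, "_states.tsv"))
  st <- data.frame(resno = rep(amide_res, n_frames),
                   frame = rep(seq_len(n_frames), each = n_am),
                   open = as.integer(open[cbind(
                     rep(seq_len(n_am), n_frames),
                     rep(seq_len(n_frames), each = n_am))]))
  utils::write.table(st, states_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  list(pdb = pdb_path, states_tsv = states_path,
       manifest = list(open = open, resno = amide_res,
                       f_open_target = f_open,
                       f_open_realized = k_open / n_frames,
                       n_frames = n_frames, family = family,
                       closed_mode = closed_mode, pattern = pattern,
                       seed = seed))
}

## ---- isotopic envelope generator --------------------------------------

#' Generate before/after isotopic envelopes with known incorporation
#'
#' The after envelope is the exact convolution of the base (undeuterated)
#' envelope with a Binomial(n_sites, p) number of deuteriums, each adding
#' the D-H mass difference; its centroid shift is exactly
#' \code{n_sites * p * 1.00628} Da in neutral mass.  Optional seeded
#' multiplicative Gaussian intensity noise.
#'
#' @param n_sites Number of exchangeable sites.
#' @param p Per-site incorporation probability in [0, 1].
#' @param charge Charge state.
#' @param base_mz,base_intensity Base envelope (defaults: a small
#'   three-isotope pattern at m/z 147.113).
#' @param noise Relative intensity noise standard deviation.
#' @param seed Seed for the noise.
#' @return List with \code{before}, \code{after} (\code{\link{peak_list}}s)
#'   and \code{expected_shift} (Da, neutral mass).
#' @export
make_envelope <- function(n_sites, p, charge = 1, base_mz = NULL,
                          base_intensity = NULL, noise = 0, seed = 1) {
  stopifnot(p >= 0, p <= 1, n_sites >= 1)
  if (is.null(base_mz))
    base_mz <- 147.113 + (0:2) * 1.00336 / charge
  if (is.null(base_intensity)) base_intensity <- c(1, 0.12, 0.01)
  stopifnot(length(base_mz) == length(base_intensity))
  set.seed(seed)
  noisy <- function(int) {
    if (noise > 0) pmax(int * (1 + stats::rnorm(length(int), 0, noise)), 0)
    else int
  }
  before <- peak_list(base_mz, noisy(base_intensity), charge = charge,
                      label = "before")
  k <- 0:n_sites
  wk <- stats::dbinom(k, n_sites, p)
  mz <- as.vector(outer(base_mz, k * DELTA_MD / charge, "+"))
  int <- as.vector(outer(base_intensity, wk))
  keep <- int > 0
  ord <- order(mz[keep])
  after <- peak_list(mz[keep][ord], noisy(int[keep][ord]), charge = charge,
                     label = "after")
  list(before = before, after = after,
       expected_shift = n_sites * p * DELTA_MD)
}

## ---- amino-acid-standard generator ------------------------------------

#' Site-class design matrix for free-amino-acid standards
#'
#' Builds the standards design matrix from single free amino acids: each
#' row is one standard, columns are its side-chain class counts with the
#' two terminal classes pooled into one \code{"terminal"} column (a free
#' amino acid always carries both termini, so they are inseparable by
#' design and are fitted as one pooled class).
#'
#' @param residues One-letter codes of the amino-acid standards.
#' @return Count matrix (standards x classes) with rownames = residues.
#' @export
standard_design <- function(residues = c("K", "R", "S", "A")) {
  rows <- lapply(residues, function(r) {
    inv <- enumerate_sites(peptide(r))
    cnt <- inv$side_chain_counts
    term <- cnt["n_terminal_amine"] + cnt["c_terminal_acid"] +
      cnt["c_terminal_amide"]
    cnt <- cnt[!names(cnt) %in% c("n_terminal_amine", "c_terminal_acid",
                                  "c_terminal_amide")]
    c(cnt, terminal = unname(term))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- residues
  m[, colSums(m) > 0, drop = FALSE]
}

#' Generate an amino-acid-standard dataset from known propensities
#'
#' Observations are \code{designs \%*\% propensities} plus seeded additive
#' Gaussian noise; the ground truth is returned alongside.
#'
#' @param propensities Named numeric vector (class -> propensity in [0,1])
#'   covering the design's columns.
#' @param designs Count matrix (standards x classes), e.g. from
#'   \code{\link{standard_design}}.
#' @param noise Additive noise standard deviation (Da).
#' @param seed Seed.
#' @return List with \code{counts}, \code{observed}, \code{uncertainty}
#'   (the noise level, replicated), and \code{truth}.
#' @export
make_standards <- function(propensities, designs, noise = 0, seed = 1) {
  designs <- as.matrix(designs)
  miss <- setdiff(colnames(designs), names(propensities))
  if (length(miss))
    stop("propensities missing for class(es): ", paste(miss, collapse = ", "))
  p <- propensities[colnames(designs)]
  stopifnot(all(p >= 0 & p <= 1))
  set.seed(seed)
  obs <- drop(designs %*% p) + stats::rnorm(nrow(designs), 0, noise)
  list(counts = designs, observed = obs,
       uncertainty = rep(max(noise, .Machine$double.eps), nrow(designs)),
       truth = p)
}
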