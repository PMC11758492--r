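## MD trajectory container: topology + frames with resolved backbone amide
## hydrogens and water oxygens.  File reading is delegated to bio3d
## (PDB topology, DCD or multi-model PDB coordinates).

WATER_RESNAMES <- c("TIP3", "TIP3P", "HOH", "WAT", "SOL")
AMIDE_H_NAMES <- c("H", "HN", "HN1")
WATER_O_NAMES <- c("OH2", "OW", "O")

elety2element <- function(elety) {
  e <- sub("^[0-9]+", "", toupper(elety))
  first2 <- substr(e, 1, 2)
  out <- ifelse(first2 %in% c("CL", "BR", "NA", "MG", "ZN", "FE"),
                first2, substr(e, 1, 1))
  out
}

#' Read an MD trajectory
#'
#' Reads a PDB topology (optionally multi-model, supplying the frames) and,
#' if given, a separate DCD coordinate file.  Backbone amide hydrogens are
#' resolved by atom name for every protein residue after the first,
#' excluding prolines; water oxygens by residue/atom name.
#'
#' @param topology Path to a PDB file.
#' @param coords Optional path to a DCD file; when \code{NULL} the models of
#'   the topology PDB are the frames.
#' @param water_names Residue names treated as water.
#' @param amide_h_names Atom-name aliases for the backbone amide hydrogen.
#' @return Object of class \code{hdx_trajectory}: list with \code{atoms}
#'   (data.frame: elety, resid, resno, element), \code{xyz}
#'   (frames x 3N matrix, bio3d layout), \code{n_frames}, \code{amide}
#'   (data.frame: resno, aa, h, n with atom row indices), index vectors
#'   \code{protein}, \code{water_o}, \code{acceptors} (protein N/O heavy
#'   atoms), and \code{sequence}.
#' @export
read_trajectory <- function(topology, coords = NULL,
                            water_names = WATER_RESNAMES,
                            amide_h_names = AMIDE_H_NAMES) {
  pdb <- bio3d::read.pdb(topology, multi = TRUE)
  atoms <- pdb$atom[, c("elety", "resid", "resno", "chain")]
  atoms$element <- elety2element(atoms$elety)
  xyz <- pdb$xyz
  if (!is.null(coords)) {
    if (!grepl("\\.dcd$", coords, ignore.case = TRUE))
      stop("unsupported coordinate format (PDB models or DCD expected): ",
           coords)
    xyz <- bio3d::read.dcd(coords, verbose = FALSE)
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) == 1) xyz <- t(xyz)
  if (ncol(xyz) != 3 * nrow(atoms))
    stop("atom-count mismatch: topology has ", nrow(atoms),
         " atoms but coordinates have ", ncol(xyz) / 3)
  build_trajectory(atoms, xyz, water_names, amide_h_names,
                   source = c(topology = topology, coords = coords))
}

## Assemble and validate the trajectory object from an atom table and a
## frames x 3N coordinate matrix.
build_trajectory <- function(atoms, xyz, water_names = WATER_RESNAMES,
                             amide_h_names = AMIDE_H_NAMES, source = NULL) {
  is_water <- atoms$resid %in% water_names
  is_protein <- atoms$resid %in% names(AA3) & !is_water
  water_o <- which(is_water & atoms$elety %in% WATER_O_NAMES)

  prot <- which(is_protein)
  if (!length(prot)) stop("no protein residues found")
  resnos <- sort(unique(atoms$resno[prot]))
  seq1 <- vapply(resnos, function(r) {
    unname(AA3[atoms$resid[prot][match(r, atoms$resno[prot])]])
  }, character(1))
  names(seq1) <- resnos

  need <- resnos[-1][seq1[-1] != "P"]
  amide <- lapply(need, function(r) {
    rows <- prot[atoms$resno[prot] == r]
    h <- rows[atoms$elety[rows] %in% amide_h_names]
    n <- rows[atoms$elety[rows] == "N"]
    list(resno = r, h = h, n = n)
  })
  nh <- vapply(amide, function(a) length(a$h), integer(1))
  if (any(nh != 1L))
    stop("amide hydrogen not uniquely resolvable for residue(s): ",
         paste(need[nh != 1L], collapse = ", "))
  if (any(vapply(amide, function(a) length(a$n), integer(1)) != 1L))
    stop("backbone N not resolvable for all amide residues")
  amide <- data.frame(resno = need, aa = unname(seq1[as.character(need)]),
                      h = vapply(amide, function(a) a$h[1], integer(1)),
                      n = vapply(amide, function(a) a$n[1], integer(1)))

  acceptors <- prot[atoms$element[prot] %in% c("N", "O")]
  structure(list(atoms = atoms, xyz = xyz, n_frames = nrow(xyz),
                 amide = amide, protein = prot,
                 nonwater = which(!is_water), water_o = water_o,
                 acceptors = acceptors, sequence = seq1, source = source),
            class = "hdx_trajectory")
}

#' @export
print.hdx_trajectory <- function(x, ...) {
  cat("hdx_trajectory:", length(x$sequence), "protein residues (",
      paste(x$sequence, collapse = ""), "),", nrow(x$atoms), "atoms,",
      x$n_frames, "frames,", length(x$water_o), "waters\n")
  invisible(x)
}

## N x 3 coordinates of one frame (optionally a subset of atoms).
frame_coords <- function(traj, frame, atoms = NULL) {
  row <- traj$xyz[frame, ]
  m <- matrix(row, ncol = 3, byrow = TRUE)
  if (is.null(atoms)) m else m[atoms, , drop = FALSE]
}
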