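#' Construct a solvent trajectory
#'
#' Frames of water and cosolvent heavy-atom coordinates around a rigid
#' solute. Molecule counts per species are constant across frames and every
#' frame shares the same atom ordering. Hydrogens are assumed already
#' removed (the loaders drop them); all occupancy and distance computations
#' use heavy atoms only.
#'
#' @param coords list of n_atoms x 3 numeric matrices (Angstrom), one per
#'   frame, identical dimensions and atom order.
#' @param mol_species character vector, one entry per molecule, each
#'   `"water"` or `"cosolvent"`.
#' @param mol_id integer vector, one entry per atom, giving the molecule
#'   (1-based, consecutive) each atom belongs to. Defaults to one atom per
#'   molecule.
#' @param box `NULL` (open boundaries) or an n_frames x 3 matrix of
#'   orthorhombic box lengths (Angstrom); distances then use the
#'   minimum-image convention.
#' @param dt frame spacing in ns (metadata, `NA` if unknown).
#' @return object of class `solvent_trajectory` with components `coords`,
#'   `mol_species`, `mol_id`, `box`, `dt`, `n_w`, `n_x`.
#' @export
solvent_trajectory <- function(coords, mol_species, mol_id = NULL, box = NULL,
                               dt = NA_real_) {
  if (!is.list(coords) || length(coords) == 0L)
    stop("coords must be a non-empty list of frames")
  n_atoms <- nrow(coords[[1L]])
  for (i in seq_along(coords)) {
    f <- coords[[i]]
    if (!is.matrix(f) || ncol(f) != 3L)
      stop("frame ", i, " is not an n x 3 coordinate matrix")
    if (nrow(f) != n_atoms)
      stop("frame ", i, " has ", nrow(f), " atoms; expected ", n_atoms)
    if (any(!is.finite(f))) stop("non-finite coordinates in frame ", i)
  }
  if (is.null(mol_id)) mol_id <- seq_len(n_atoms)
  mol_id <- as.integer(mol_id)
  if (length(mol_id) != n_atoms) stop("mol_id must have one entry per atom")
  n_mol <- max(mol_id)
  if (!setequal(unique(mol_id), seq_len(n_mol)))
    stop("mol_id must be consecutive 1..n_mol")
  if (length(mol_species) != n_mol)
    stop("mol_species must have one entry per molecule")
  if (!all(mol_species %in% c("water", "cosolvent")))
    stop("mol_species entries must be 'water' or 'cosolvent'")
  if (!is.null(box)) {
    box <- as.matrix(box)
    if (nrow(box) == 1L) box <- box[rep(1L, length(coords)), , drop = FALSE]
    if (nrow(box) != length(coords) || ncol(box) != 3L)
      stop("box must be an n_frames x 3 matrix of box lengths")
    if (any(!is.finite(box)) || any(box <= 0))
      stop("box lengths must be finite and positive")
  }
  structure(list(coords = coords, mol_species = mol_species,
                 mol_id = mol_id, box = box, dt = dt,
                 n_w = sum(mol_species == "water"),
                 n_x = sum(mol_species == "cosolvent")),
            class = "solvent_trajectory")
}

#' @export
print.solvent_trajectory <- function(x, ...) {
  cat(sprintf("<solvent_trajectory> %d frames, N_w = %d, N_x = %d (%d atoms/frame)%s\n",
              length(x$coords), x$n_w, x$n_x, nrow(x$coords[[1L]]),
              if (is.null(x$box)) ", open boundaries" else ", periodic"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x a [solvent_trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(x) length(x$coords)

#' Read solvent frames from a multi-model PDB file
#'
#' Loads a multi-frame solvent trajectory from a multi-model (MODEL/ENDMDL)
#' PDB file. Residue names are classified through the species map; protein
#' records (standard amino acids) are skipped, hydrogens are dropped, and
#' any other unclassifiable residue name is an error. Orthorhombic box
#' lengths are taken from a CRYST1 record when present.
#'
#' @param file path to a (multi-model) PDB file.
#' @param map [species_map()].
#' @param dt frame spacing in ns (metadata).
#' @return a [solvent_trajectory()].
#' @export
read_solvent_frames <- function(file, map = species_map(), dt = NA_real_) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  sp <- classify_resid(at$resid, map)
  protein <- toupper(at$resid) %in% AMINO_ACIDS |
    (toupper(at$resid) == "GLY" & at$type == "ATOM")
  if (any(is.na(sp) & !protein)) {
    bad <- unique(toupper(at$resid[is.na(sp) & !protein]))
    stop("solvent residue name(s) not in species map: ",
         paste(bad, collapse = ", "))
  }
  keep <- !is.na(sp) & !protein
  elem <- toupper(trimws(at$elesy))
  guess <- is.na(elem) | elem == ""
  if (any(guess)) elem[guess] <- guess_element(at$elety[guess])
  keep <- keep & elem != "H"
  if (!any(keep)) stop("no solvent heavy atoms in ", file)
  at <- at[keep, , drop = FALSE]
  sp <- sp[keep]
  # molecules: runs of constant (chain, resno, resid)
  key <- paste(at$chain, at$resno, at$resid, sep = "\r")
  new_mol <- c(TRUE, key[-1L] != key[-length(key)])
  mol_id <- cumsum(new_mol)
  mol_species <- sp[new_mol]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  idx <- bio3d::atom2xyz(which(keep))
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, idx], ncol = 3L, byrow = TRUE))
  box <- read_cryst1(file)
  if (!is.null(box)) box <- matrix(box, nrow = 1L)
  solvent_trajectory(frames, mol_species = mol_species, mol_id = mol_id,
                     box = box, dt = dt)
}

# box lengths from the first CRYST1 record, or NULL
read_cryst1 <- function(file) {
  con <- file(file, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) return(NULL)
    if (startsWith(ln, "CRYST1")) {
      abc <- c(as.numeric(substr(ln, 7, 15)), as.numeric(substr(ln, 16, 24)),
               as.numeric(substr(ln, 25, 33)))
      if (any(is.na(abc))) return(NULL)
      return(abc)
    }
    if (startsWith(ln, "ATOM") || startsWith(ln, "HETATM")) return(NULL)
  }
}

#' Write solvent frames as a multi-model PDB file
#'
#' Fixture-friendly inverse of [read_solvent_frames()]: one MODEL per frame,
#' water molecules as `HOH`, cosolvent as `GOL`, heavy atoms only, with a
#' CRYST1 record when the trajectory is periodic.
#'
#' @param traj a [solvent_trajectory()].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_solvent_frames <- function(traj, file) {
  stopifnot(inherits(traj, "solvent_trajectory"))
  resid <- ifelse(traj$mol_species == "water", "HOH", "GOL")[traj$mol_id]
  elety <- ifelse(traj$mol_species == "water", "O", "C1")[traj$mol_id]
  # per-molecule atom counter for multi-atom cosolvents
  within <- stats::ave(traj$mol_id, traj$mol_id, FUN = seq_along)
  multi <- traj$mol_id %in% traj$mol_id[duplicated(traj$mol_id)]
  elety[multi] <- paste0(substr(elety[multi], 1, 1), within[multi])
  lines <- character(0)
  if (!is.null(traj$box))
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     traj$box[1, 1], traj$box[1, 2], traj$box[1, 3])
  n_at <- length(traj$mol_id)
  for (f in seq_along(traj$coords)) {
    xyz <- traj$coords[[f]]
    lines <- c(lines, sprintf("MODEL     %4d", f),
               sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_len(n_at) %% 100000L, elety, resid, traj$mol_id %% 10000L,
                       xyz[, 1], xyz[, 2], xyz[, 3],
                       ifelse(traj$mol_species[traj$mol_id] == "water", "O", "C")),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}
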