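#' Construct a solute structure
#'
#' A `solute` is the rigid protein (or pseudo-atom toy) around which solvent
#' is counted: atom coordinates, element symbols, van der Waals radii and
#' residue identity. Atoms are stored sorted by (chain, residue number) so
#' that residue order -- used for tie-breaking in shell assignment -- is the
#' natural (chain, number) order.
#'
#' @param atoms data.frame with columns `x`, `y`, `z` (Angstrom), `elety`
#'   (atom name), `elem` (element symbol), `chain`, `resno`, `resid`
#'   (residue name); optional `radius` (Angstrom, otherwise looked up from
#'   `radii` by element).
#' @param radii named radii table as from [vdw_radii()].
#' @param label free-text system name.
#' @return object of class `solute` with components `atoms` (data.frame,
#'   incl. `radius` and `res_index`), `residues` (one row per residue:
#'   `chain`, `resno`, `resid`, `first`, `last`) and `label`.
#' @export
solute <- function(atoms, radii = vdw_radii(), label = "solute") {
  need <- c("x", "y", "z", "elety", "elem", "chain", "resno", "resid")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty solute: no atoms")
  atoms$elem <- toupper(trimws(atoms$elem))
  if (is.null(atoms$radius)) {
    unknown <- !(atoms$elem %in% names(radii))
    if (any(unknown)) {
      i <- which(unknown)[1L]
      stop(sprintf("unknown element '%s' for atom %s (%s %s%s): not in radii table",
                   atoms$elem[i], atoms$elety[i], atoms$resid[i],
                   atoms$chain[i], atoms$resno[i]))
    }
    atoms$radius <- unname(radii[atoms$elem])
  }
  if (any(!is.finite(atoms$radius)) || any(atoms$radius <= 0))
    stop("van der Waals radii must be finite and strictly positive")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("solute coordinates must be finite")
  # stable sort by (chain, resno): fixes residue order for tie-breaks
  ord <- order(atoms$chain, atoms$resno)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  res_index <- match(key, unique(key))
  atoms$res_index <- res_index
  first <- which(!duplicated(res_index))
  last <- c(first[-1L] - 1L, nrow(atoms))
  residues <- data.frame(
    chain = atoms$chain[first], resno = atoms$resno[first],
    resid = atoms$resid[first], first = first, last = last,
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, residues = residues, label = label),
            class = "solute")
}

#' @export
print.solute <- function(x, ...) {
  cat(sprintf("<solute> %s: %d atoms, %d residues, %d chain(s)\n",
              x$label, nrow(x$atoms), nrow(x$residues),
              length(unique(x$residues$chain))))
  invisible(x)
}

#' Read a solute structure from a PDB file
#'
#' Loads protein atoms from a PDB file; solvent records (residue names in the
#' species map) are skipped here and belong to the trajectory loader. Every
#' element must be present in the radii table.
#'
#' @param file path to a PDB file.
#' @param radii named radii table, see [vdw_radii()].
#' @param map [species_map()] used to recognise and skip solvent records.
#' @param label system name (defaults to the file name).
#' @param keep_hydrogens keep solute hydrogens? Default `TRUE`; solute
#'   hydrogens carry radii and contribute to the van der Waals surface.
#' @return a [solute()].
#' @export
read_solute <- function(file, radii = vdw_radii(), map = species_map(),
                        label = basename(file), keep_hydrogens = TRUE) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  at <- pdb$atom
  sp <- classify_resid(at$resid, map)
  # ATOM-typed GLY is glycine, not the glycerol alias
  solvent <- !is.na(sp) & !(toupper(at$resid) == "GLY" & at$type == "ATOM")
  at <- at[!solvent, , drop = FALSE]
  if (nrow(at) == 0L) stop("no solute atoms in ", file)
  elem <- toupper(trimws(at$elesy))
  guess <- is.na(elem) | elem == ""
  if (any(guess)) elem[guess] <- guess_element(at$elety[guess])
  if (!keep_hydrogens) {
    keep <- elem != "H"
    at <- at[keep, , drop = FALSE]; elem <- elem[keep]
  }
  solute(
    data.frame(x = at$x, y = at$y, z = at$z, elety = trimws(at$elety),
               elem = elem, chain = ifelse(is.na(at$chain), "A", at$chain),
               resno = at$resno, resid = trimws(at$resid),
               stringsAsFactors = FALSE),
    radii = radii, label = label
  )
}

# element symbol from a PDB atom name: strip digits, try 2-letter then
# 1-letter symbol
guess_element <- function(elety) {
  vapply(elety, function(e) {
    e <- toupper(gsub("[0-9' ]", "", trimws(e)))
    if (nchar(e) == 0L) return(NA_character_)
    two <- substr(e, 1L, 2L)
    if (two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE", "MN", "CU"))
      return(two)
    substr(e, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Residue keys
#'
#' Canonical "chain:resno" keys for the residues of a solute, used to address
#' per-residue results.
#' @param x a [solute()] or a data.frame with `chain` and `resno` columns.
#' @return character vector of keys.
#' @export
residue_keys <- function(x) {
  df <- if (inherits(x, "solute")) x$residues else x
  paste(df$chain, df$resno, sep = ":")
}

#' Write a residue-colored PDB
#'
#' Writes the structure with a per-residue numeric annotation in the
#' temperature-factor (B) column (fixed width, 2 decimals), the standard
#' channel for residue-level coloring in molecular viewers (e.g. red/blue
#' maps of per-residue Delta-Gamma). Atoms of unmapped residues carry 0.
#'
#' @param x a [solute()].
#' @param values data.frame with columns `chain`, `resno`, `value`, or a
#'   named numeric vector keyed by "chain:resno".
#' @param file output PDB path.
#' @return invisibly, the per-atom annotation vector.
#' @export
write_residue_coloring <- function(x, values, file) {
  stopifnot(inherits(x, "solute"))
  if (is.numeric(values) && !is.null(names(values))) {
    values <- data.frame(
      chain = sub(":.*$", "", names(values)),
      resno = as.integer(sub("^.*:", "", names(values))),
      value = unname(values), stringsAsFactors = FALSE)
  }
  keys <- residue_keys(x)
  vkeys <- paste(values$chain, values$resno, sep = ":")
  missing <- setdiff(vkeys, keys)
  if (length(missing))
    stop("residue(s) not in structure: ", paste(missing, collapse = ", "))
  per_res <- stats::setNames(rep(0, nrow(x$residues)), keys)
  per_res[vkeys] <- values$value
  b <- per_res[x$atoms$res_index]
  at <- x$atoms
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(at)),
    resno = at$resno, resid = at$resid, eleno = seq_len(nrow(at)),
    elety = at$elety, chain = at$chain,
    o = rep(1, nrow(at)), b = round(unname(b), 2), elesy = at$elem
  )
  invisible(unname(b))
}
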