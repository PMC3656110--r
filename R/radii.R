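#' Default van der Waals radii
#'
#' Bondi-type van der Waals radii (Angstrom) used to define the protein
#' surface for solvation-shell counting. The table is pinned for
#' reproducibility and can be overridden entry-wise; Gamma at a fixed 5 A
#' cutoff is only weakly sensitive to the radii source.
#'
#' @param override optional named numeric vector of radii (element symbol ->
#'   Angstrom) merged over the defaults.
#' @return named numeric vector, element symbol (upper case) -> radius in
#'   Angstrom.
#' @examples
#' vdw_radii()[["C"]]
#' vdw_radii(c(C = 1.8))[["C"]]
#' @export
vdw_radii <- function(override = NULL) {
  r <- c(
    H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, F = 1.47, "CL" = 1.75, "BR" = 1.85, I = 1.98,
    "SE" = 1.90, B = 1.92, "FE" = 1.80, "ZN" = 1.39, "MG" = 1.73,
    "CA" = 2.31, "NA" = 2.27, K = 2.75, "MN" = 1.73, "CU" = 1.40,
    # generic pseudo-atom used by the synthetic configuration generator
    X = 1.90
  )
  if (!is.null(override)) {
    stopifnot(is.numeric(override), !is.null(names(override)))
    r[toupper(names(override))] <- unname(override)
  }
  if (any(r <= 0)) stop("van der Waals radii must be strictly positive")
  r
}

#' Solvent species map
#'
#' Classifies solvent residue names into water and cosolvent species. The
#' two name sets must be disjoint.
#'
#' @param water character vector of water residue names.
#' @param cosolvent character vector of cosolvent residue names (defaults
#'   cover common glycerol names).
#' @return object of class `species_map`.
#' @examples
#' sm <- species_map()
#' sm$water
#' @export
species_map <- function(water = c("HOH", "TIP3", "TIP", "WAT", "SOL", "SPC", "H2O"),
                        cosolvent = c("GOL", "GLYC", "GLY")) {
  water <- toupper(water); cosolvent <- toupper(cosolvent)
  if (length(intersect(water, cosolvent)) > 0)
    stop("water and cosolvent residue-name sets must be disjoint: ",
         paste(intersect(water, cosolvent), collapse = ", "))
  structure(list(water = water, cosolvent = cosolvent), class = "species_map")
}

# classify residue names -> "water"/"cosolvent"/NA
classify_resid <- function(resid, map) {
  resid <- toupper(resid)
  out <- rep(NA_character_, length(resid))
  out[resid %in% map$water] <- "water"
  out[resid %in% map$cosolvent] <- "cosolvent"
  out
}

# standard amino-acid residue names (used to route protein records away from
# the solvent loader)
AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "MSE", "CYX", "HID", "HIE", "HIP"
)
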