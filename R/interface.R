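# Interface decomposition of a protein-protein complex.
#
# inte(D): all residues of the complex with at least one atom within an
# atom-center distance D of the partner protein; non-inte(D) is the rest.
# Regional Gamma values are sums of member-residue series, so
# Gamma^inte + Gamma^non-inte = Gamma holds frame-wise by construction.

#' Partition a complex into interface and non-interface residues
#'
#' A residue of side A belongs to the interface region inte(D) when at least
#' one of its atoms lies within an atom-center distance `D` of any atom of
#' side B (and symmetrically); interface residues of both sides are pooled.
#' Membership uses atom-center distances, distinct from the vdW-surface
#' distances of the solvation-shell counting.
#'
#' @param sol a [solute()] holding the complex.
#' @param chains_A character vector of chain ids forming side A; the
#'   remaining chains form side B.
#' @param D interface distance in Angstrom (>= 0).
#' @return object of class `region_partition`: `D`, `inte` and `noninte`
#'   residue data.frames (chain, resno, resid), `side` per residue, and the
#'   full residue table.
#' @export
interface_residues <- function(sol, chains_A, D) {
  stopifnot(inherits(sol, "solute"))
  if (D < 0) stop("D must be >= 0")
  ch <- sol$residues$chain
  in_A <- ch %in% chains_A
  if (!any(in_A) || all(in_A))
    stop("chain split leaves a side empty (chains_A = ",
         paste(chains_A, collapse = ","), ")")
  atoms_A <- sol$atoms$chain %in% chains_A
  xa <- as.matrix(sol$atoms[atoms_A, c("x", "y", "z")])
  xb <- as.matrix(sol$atoms[!atoms_A, c("x", "y", "z")])
  # min distance from each A atom to side B (chunked all-pairs)
  mind_A <- min_cross_distance(xa, xb)
  mind_B <- min_cross_distance(xb, xa)
  mind <- numeric(nrow(sol$atoms))
  mind[atoms_A] <- mind_A; mind[!atoms_A] <- mind_B
  res_min <- tapply(mind, sol$atoms$res_index, min)
  inte <- as.numeric(res_min) <= D
  res <- sol$residues[, c("chain", "resno", "resid")]
  res$side <- ifelse(in_A, "A", "B")
  res$min_cross_dist <- as.numeric(res_min)
  structure(list(D = D, inte = res[inte, , drop = FALSE],
                 noninte = res[!inte, , drop = FALSE],
                 residues = res, chains_A = chains_A),
            class = "region_partition")
}

# min over rows of y of distance from each row of x
min_cross_distance <- function(x, y, chunk = 2048L) {
  n <- nrow(x)
  out <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    d2 <- matrix(0, nrow(y), hi - lo + 1L)
    for (c in 1:3) {
      dx <- outer(y[, c], x[lo:hi, c], "-")
      d2 <- d2 + dx * dx
    }
    out[lo:hi] <- sqrt(apply(d2, 2, min))
  }
  out
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> D = %.1f A: %d interface, %d non-interface residues\n",
              x$D, nrow(x$inte), nrow(x$noninte)))
  invisible(x)
}

#' Regional preferential interaction coefficients
#'
#' Sums per-residue Gamma series over the members of the interface and
#' non-interface regions. By construction the two regional series add up to
#' the global series in every frame.
#'
#' @param gres a [gamma_per_residue()] result for the complex.
#' @param partition a [interface_residues()] partition of the same complex.
#' @return list with `inte` and `noninte` `gamma_estimate`s (scope
#'   `"region"`), and `D`.
#' @export
regional_gamma <- function(gres, partition) {
  stopifnot(inherits(gres, "gamma_residue_set"),
            inherits(partition, "region_partition"))
  keys <- colnames(gres$series)
  region_series <- function(members) {
    if (nrow(members) == 0L)
      return(rep(0, nrow(gres$series)))
    mk <- residue_keys(members)
    missing <- setdiff(mk, keys)
    if (length(missing))
      stop("residue(s) missing from Gamma map: ", paste(missing, collapse = ", "))
    rowSums(gres$series[, mk, drop = FALSE])
  }
  list(inte = gamma_estimate(region_series(partition$inte), gres$cutoff,
                             scope = "region"),
       noninte = gamma_estimate(region_series(partition$noninte), gres$cutoff,
                                scope = "region"),
       D = partition$D)
}

#' Difference of preferential interaction coefficients upon association
#'
#' Delta-Gamma = Gamma(complex) - Gamma(free A) - Gamma(free B), with the
#' standard error combined in quadrature (the three trajectories are
#' independent). Positive Delta-Gamma means cosolvent favours the associated
#' state (K_A increases with cosolvent activity).
#'
#' @param complex,freeA,freeB `gamma_estimate`s, or `list(value, se)` pairs.
#' @param scope scope tag (`"global"`, `"inte"`, `"non-inte"`, `"residue"`).
#' @return object of class `delta_gamma`: `value`, `se`, `components`,
#'   `scope`.
#' @examples
#' delta_gamma(list(value = -20.6, se = 1.5),
#'             list(value = -11.1, se = 0.4),
#'             list(value = -5.2, se = 0.8))
#' @export
delta_gamma <- function(complex, freeA, freeB, scope = "global") {
  g <- lapply(list(complex = complex, freeA = freeA, freeB = freeB),
              function(x) {
    if (is.null(x$value) || is.null(x$se))
      stop("each component needs a value and an se")
    list(value = x$value, se = x$se)
  })
  structure(list(
    value = g$complex$value - g$freeA$value - g$freeB$value,
    se = sqrt(g$complex$se^2 + g$freeA$se^2 + g$freeB$se^2),
    components = g, scope = scope), class = "delta_gamma")
}

#' @export
print.delta_gamma <- function(x, ...) {
  cat(sprintf("Delta-Gamma (%s): %.2f +/- %.2f\n", x$scope, x$value, x$se))
  invisible(x)
}

# match residues of `from` (chain, resno, resid) to rows of `to`; an
# override data.frame (chain, resno, to_chain, to_resno) rewrites keys first.
match_residues <- function(from, to, override = NULL) {
  fk <- paste(from$chain, from$resno, from$resid)
  if (!is.null(override)) {
    ok <- paste(override$chain, override$resno)
    idx <- match(paste(from$chain, from$resno), ok)
    hit <- !is.na(idx)
    fk[hit] <- paste(override$to_chain[idx[hit]], override$to_resno[idx[hit]],
                     from$resid[hit])
  }
  match(fk, paste(to$chain, to$resno, to$resid))
}

#' Determine the interface distance D*
#'
#' Scans a grid of interface distances D and returns the smallest D at
#' which the non-interface solvation change
#' Delta-Gamma^non-inte(D) = Gamma^non-inte(complex) - Gamma^non-inte(freeA)
#' - Gamma^non-inte(freeB) does not significantly differ from zero
#' (|Delta| <= k * quadrature SE). Free-state regions are obtained by
#' mapping complex residues onto the free structures by (chain, residue
#' number, residue name) equality, optionally via an override table.
#'
#' @param sol_complex [solute()] of the complex.
#' @param chains_A chain ids of side A within the complex.
#' @param gres_complex,gres_freeA,gres_freeB [gamma_per_residue()] results
#'   for complex and free states (same cutoff and species settings).
#' @param D_grid ascending numeric grid of D values (Angstrom), default 3:12.
#' @param k significance multiplier, default 1.
#' @param mapping optional override data.frame (chain, resno, to_chain,
#'   to_resno) for renumbered free structures.
#' @return list with `D_star`, `partition` at D*, `scan` data.frame
#'   (D, gamma_noninte_complex, gamma_noninte_freeA, gamma_noninte_freeB,
#'   delta_noninte, se, pass).
#' @export
determine_interface_distance <- function(sol_complex, chains_A, gres_complex,
                                         gres_freeA, gres_freeB,
                                         D_grid = 3:12, k = 1,
                                         mapping = NULL) {
  if (is.unsorted(D_grid, strictly = TRUE)) stop("D grid must be ascending")
  free_series <- function(gres_free, members) {
    if (nrow(members) == 0L) return(rep(0, nrow(gres_free$series)))
    idx <- match_residues(members, gres_free$residues, override = mapping)
    if (any(is.na(idx))) {
      bad <- residue_keys(members)[is.na(idx)]
      stop("complex residue(s) without free-state counterpart: ",
           paste(bad, collapse = ", "))
    }
    rowSums(gres_free$series[, idx, drop = FALSE])
  }
  scan <- data.frame(D = D_grid, gamma_noninte_complex = NA_real_,
                     gamma_noninte_freeA = NA_real_,
                     gamma_noninte_freeB = NA_real_,
                     delta_noninte = NA_real_, se = NA_real_, pass = FALSE)
  partitions <- vector("list", length(D_grid))
  for (i in seq_along(D_grid)) {
    part <- interface_residues(sol_complex, chains_A, D_grid[i])
    partitions[[i]] <- part
    reg <- regional_gamma(gres_complex, part)
    ni <- part$noninte
    gA <- gamma_estimate(free_series(gres_freeA,
                                     ni[ni$chain %in% chains_A, , drop = FALSE]),
                         gres_freeA$cutoff, scope = "region")
    gB <- gamma_estimate(free_series(gres_freeB,
                                     ni[!(ni$chain %in% chains_A), , drop = FALSE]),
                         gres_freeB$cutoff, scope = "region")
    dg <- delta_gamma(reg$noninte, gA, gB, scope = "non-inte")
    scan$gamma_noninte_complex[i] <- reg$noninte$value
    scan$gamma_noninte_freeA[i] <- gA$value
    scan$gamma_noninte_freeB[i] <- gB$value
    scan$delta_noninte[i] <- dg$value
    scan$se[i] <- dg$se
    scan$pass[i] <- abs(dg$value) <= k * dg$se
  }
  if (!any(scan$pass)) {
    cond <- structure(class = c("prefint_no_dstar", "error", "condition"),
                      list(message = paste0(
                        "no D on the grid satisfies |Delta-Gamma^non-inte| <= ",
                        k, "*SE"), call = sys.call(-1), scan = scan))
    stop(cond)
  }
  i_star <- which(scan$pass)[1L]
  list(D_star = D_grid[i_star], partition = partitions[[i_star]], scan = scan,
       k = k)
}

#' Residue-level solvation changes upon association
#'
#' Delta-Gamma_res = Gamma_res(complex) - Gamma_res(free counterpart), with
#' quadrature SEs and a significance flag |Delta| > k * SE. The result can be
#' written onto the structure with [write_residue_coloring()] (positive
#' values red, negative blue, in the usual viewer convention).
#'
#' @param gres_complex [gamma_per_residue()] of the complex.
#' @param gres_freeA,gres_freeB [gamma_per_residue()] of the free sides.
#' @param chains_A chain ids of side A in the complex.
#' @param k significance multiplier, default 2.
#' @param mapping optional override table, see
#'   [determine_interface_distance()].
#' @return data.frame: chain, resno, resid, gamma_complex, gamma_free,
#'   delta, se, significant.
#' @export
residue_delta_map <- function(gres_complex, gres_freeA, gres_freeB, chains_A,
                              k = 2, mapping = NULL) {
  res <- gres_complex$residues
  out <- data.frame(chain = res$chain, resno = res$resno, resid = res$resid,
                    gamma_complex = res$gamma, gamma_free = NA_real_,
                    delta = NA_real_, se = NA_real_, significant = NA,
                    stringsAsFactors = FALSE)
  in_A <- res$chain %in% chains_A
  for (side in c(TRUE, FALSE)) {
    gfree <- if (side) gres_freeA else gres_freeB
    rows <- which(in_A == side)
    if (!length(rows)) next
    idx <- match_residues(res[rows, , drop = FALSE], gfree$residues,
                          override = mapping)
    if (any(is.na(idx))) {
      bad <- residue_keys(res[rows, , drop = FALSE])[is.na(idx)]
      stop("unmapped complex residue(s): ", paste(bad, collapse = ", "))
    }
    out$gamma_free[rows] <- gfree$residues$gamma[idx]
    out$delta[rows] <- out$gamma_complex[rows] - out$gamma_free[rows]
    out$se[rows] <- sqrt(res$se[rows]^2 + gfree$residues$se[idx]^2)
  }
  out$significant <- abs(out$delta) > k * out$se
  out
}
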