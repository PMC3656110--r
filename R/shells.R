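# Solvation-shell classification and preferential interaction coefficients.
#
# The two-domain counting model: a solvent molecule is "local" when its
# surface distance -- min over (its heavy atoms x all solute atoms) of
# (atom-atom distance minus the solute atom's vdW radius) -- is at most the
# cutoff (default 5 A). Per frame,
#   Gamma(t) = n_x^II(t) - n_w^II(t) * (N_x - n_x^II(t)) / (N_w - n_w^II(t))
# with n^II the local counts and N the totals per species.

# distance from each point to the solute vdW surface, plus the solute atom
# attaining the minimum. box: NULL or length-3 orthorhombic lengths
# (minimum-image). Returns list(dist, atom).
surface_distance_points <- function(sol, pts, box = NULL, chunk = 4096L) {
  sx <- as.matrix(sol$atoms[, c("x", "y", "z")])
  r <- sol$atoms$radius
  m <- nrow(sx); n <- nrow(pts)
  dist <- numeric(n); atom <- integer(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    k <- hi - lo + 1L
    d2 <- matrix(0, m, k)
    for (c in 1:3) {
      dx <- outer(sx[, c], pts[lo:hi, c], "-")
      if (!is.null(box)) dx <- dx - box[c] * round(dx / box[c])
      d2 <- d2 + dx * dx
    }
    ds <- sqrt(d2) - r                   # recycles r down columns
    # argmin per point; ties -> first solute atom = lowest (chain, resno)
    amin <- max.col(-t(ds), ties.method = "first")
    atom[lo:hi] <- amin
    dist[lo:hi] <- ds[cbind(amin, seq_len(k))]
  }
  list(dist = dist, atom = atom)
}

#' Classify a solvent frame into local and bulk domains
#'
#' Computes, for every solvent molecule of one frame, its distance to the
#' solute van der Waals surface (minimum over the molecule's heavy atoms and
#' all solute atoms of atom-atom distance minus the solute atom's radius),
#' flags it local when that distance is at most `cutoff`, and assigns each
#' local molecule to the residue attaining the minimum (exact ties go to the
#' lowest (chain, residue-number) residue).
#'
#' @param sol a [solute()].
#' @param frame n_atoms x 3 coordinate matrix (one trajectory frame), or a
#'   [solvent_trajectory()] together with `frame_index`.
#' @param cutoff shell cutoff in Angstrom (> 0), default 5.
#' @param box `NULL` or length-3 orthorhombic box lengths.
#' @param mol_id molecule index per atom (default: one atom per molecule).
#' @param frame_index frame to classify when `frame` is a trajectory.
#' @return data.frame with one row per molecule: `mol`, `dist` (surface
#'   distance, Angstrom), `local` (logical), `res_index` (assigned residue,
#'   `NA` for bulk molecules), and the residue's `chain`/`resno`.
#' @export
classify_frame <- function(sol, frame, cutoff = 5, box = NULL, mol_id = NULL,
                           frame_index = 1L) {
  stopifnot(inherits(sol, "solute"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (inherits(frame, "solvent_trajectory")) {
    traj <- frame
    frame <- traj$coords[[frame_index]]
    if (is.null(mol_id)) mol_id <- traj$mol_id
    if (is.null(box) && !is.null(traj$box)) box <- traj$box[frame_index, ]
  }
  if (is.null(frame) || nrow(frame) == 0L) stop("empty solvent frame")
  if (is.null(mol_id)) mol_id <- seq_len(nrow(frame))
  sd <- surface_distance_points(sol, frame, box = box)
  n_mol <- max(mol_id)
  # per-molecule minimum over member heavy atoms (first atom wins exact ties)
  ord <- order(mol_id, sd$dist, seq_along(mol_id))
  firsts <- ord[!duplicated(mol_id[ord])]
  dist <- sd$dist[firsts][order(mol_id[firsts])]
  atom <- sd$atom[firsts][order(mol_id[firsts])]
  res_index <- sol$atoms$res_index[atom]
  local <- dist <= cutoff
  res_index[!local] <- NA_integer_
  data.frame(mol = seq_len(n_mol), dist = dist, local = local,
             res_index = res_index,
             chain = sol$residues$chain[res_index],
             resno = sol$residues$resno[res_index],
             stringsAsFactors = FALSE)
}

# per-frame, per-residue local counts for a whole trajectory.
# Returns list(nw: F x R matrix, nx: F x R matrix). A bounding-box prefilter
# (open boundaries only) skips atoms that cannot be within the cutoff; the
# result is identical to the all-pairs count.
count_residue_occupancy <- function(sol, traj, cutoff) {
  stopifnot(inherits(sol, "solute"), inherits(traj, "solvent_trajectory"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  R <- nrow(sol$residues)
  nf <- n_frames(traj)
  nw <- matrix(0L, nf, R); nx <- matrix(0L, nf, R)
  is_w <- traj$mol_species == "water"
  sx <- as.matrix(sol$atoms[, c("x", "y", "z")])
  rmax <- max(sol$atoms$radius)
  lo_b <- apply(sx, 2, min) - (cutoff + rmax)
  hi_b <- apply(sx, 2, max) + (cutoff + rmax)
  for (f in seq_len(nf)) {
    pts <- traj$coords[[f]]
    if (nrow(pts) == 0L) stop("empty solvent frame ", f)
    box <- if (!is.null(traj$box)) traj$box[f, ] else NULL
    if (is.null(box)) {
      cand <- pts[, 1] >= lo_b[1] & pts[, 1] <= hi_b[1] &
              pts[, 2] >= lo_b[2] & pts[, 2] <= hi_b[2] &
              pts[, 3] >= lo_b[3] & pts[, 3] <= hi_b[3]
    } else cand <- rep(TRUE, nrow(pts))
    if (any(cand)) {
      sd <- surface_distance_points(sol, pts[cand, , drop = FALSE], box = box)
      mid <- traj$mol_id[cand]
      ord <- order(mid, sd$dist, seq_along(mid))
      firsts <- ord[!duplicated(mid[ord])]
      dist <- sd$dist[firsts]; atom <- sd$atom[firsts]
      mols <- mid[firsts]
      loc <- dist <= cutoff
      if (any(loc)) {
        res <- sol$atoms$res_index[atom[loc]]
        w <- is_w[mols[loc]]
        if (any(w)) nw[f, ] <- tabulate(res[w], nbins = R)
        if (any(!w)) nx[f, ] <- tabulate(res[!w], nbins = R)
      }
    }
  }
  list(nw = nw, nx = nx)
}

#' Block-averaging standard error
#'
#' Standard error of the mean of a (possibly autocorrelated) series by block
#' averaging: the series is divided into 2^k blocks (k = 2, 3, ...; at least
#' 4 blocks), SE(k) = sd(block means)/sqrt(number of blocks), and the plateau
#' value is taken as the maximum SE over the two largest block lengths with
#' at least 4 blocks. The result is floored at half the naive i.i.d. standard
#' error sd/sqrt(n).
#'
#' @param series numeric vector, length >= 8.
#' @return standard error (>= 0).
#' @examples
#' block_error(rep(1, 100))  # 0
#' @export
block_error <- function(series) {
  n <- length(series)
  if (n < 8L) stop("series too short for block error: need >= 8, got ", n)
  v <- stats::var(series)
  if (v == 0) return(0)
  naive <- sqrt(v / n)
  ks <- 2:floor(log2(n))
  se_k <- vapply(ks, function(k) {
    nb <- 2L^k
    L <- n %/% nb
    bm <- colMeans(matrix(series[seq_len(nb * L)], nrow = L))
    stats::sd(bm) / sqrt(nb)
  }, numeric(1))
  plateau <- max(se_k[seq_len(min(2L, length(se_k)))])
  max(plateau, naive / 2)
}

# gamma_estimate constructor
gamma_estimate <- function(series, cutoff, scope = "global",
                           value = mean(series)) {
  se <- if (length(series) >= 8L) block_error(series)
        else stats::sd(series) / sqrt(length(series))
  if (is.na(se)) se <- 0
  structure(list(value = value, se = se, series = series,
                 n_frames = length(series), cutoff = cutoff, scope = scope),
            class = "gamma_estimate")
}

#' @export
print.gamma_estimate <- function(x, ...) {
  cat(sprintf("Gamma (%s, cutoff %.1f A): %.3f +/- %.3f  [%d frames]\n",
              x$scope, x$cutoff, x$value, x$se, x$n_frames))
  invisible(x)
}

# per-frame Gamma series from total local counts
gamma_series_from_counts <- function(nw_tot, nx_tot, N_w, N_x) {
  bulk_w <- N_w - nw_tot
  if (any(bulk_w < 1)) {
    f <- which(bulk_w < 1)[1L]
    stop("no bulk water left in frame ", f,
         " (all ", N_w, " waters local); Gamma is undefined")
  }
  nx_tot - nw_tot * (N_x - nx_tot) / bulk_w
}

#' Global preferential interaction coefficient
#'
#' Counts water and cosolvent molecules in the local solvation domain
#' (surface distance <= `cutoff`) per frame and forms the two-domain
#' estimate Gamma(t) = n_x - n_w (N_x - n_x)/(N_w - n_w). The default
#' estimator averages the per-frame (instantaneous) Gamma series; a
#' ratio-of-means variant inserts trajectory-mean counts into the same
#' formula. The standard error comes from [block_error()].
#'
#' @param sol a [solute()].
#' @param traj a [solvent_trajectory()].
#' @param cutoff shell cutoff in Angstrom, default 5.
#' @param estimator `"instantaneous"` (default; mean of the per-frame
#'   series) or `"ratio_of_means"`.
#' @return a `gamma_estimate` (value, se, per-frame series, frames, cutoff).
#' @export
gamma_global <- function(sol, traj, cutoff = 5,
                         estimator = c("instantaneous", "ratio_of_means")) {
  estimator <- match.arg(estimator)
  cnt <- count_residue_occupancy(sol, traj, cutoff)
  nw_tot <- rowSums(cnt$nw); nx_tot <- rowSums(cnt$nx)
  series <- gamma_series_from_counts(nw_tot, nx_tot, traj$n_w, traj$n_x)
  value <- if (estimator == "instantaneous") mean(series) else {
    mw <- mean(nw_tot); mx <- mean(nx_tot)
    mx - mw * (traj$n_x - mx) / (traj$n_w - mw)
  }
  gamma_estimate(series, cutoff, scope = "global", value = value)
}

#' Residue-resolved preferential interaction coefficients
#'
#' Partitions each frame's local solvent molecules over the residues they
#' are assigned to (nearest vdW surface) and forms, per residue,
#' Gamma_res(t) = n_x,res(t) - n_w,res(t) (N_x - n_x)/(N_w - n_w) with the
#' frame's global bulk ratio. Because the assignment is a partition, the
#' residue series sum to the global Gamma series frame by frame.
#'
#' @inheritParams gamma_global
#' @return object of class `gamma_residue_set`: `residues` data.frame
#'   (chain, resno, resid, gamma, se), per-residue series matrix `series`
#'   (frames x residues), the `global` `gamma_estimate`, `cutoff`.
#' @export
gamma_per_residue <- function(sol, traj, cutoff = 5) {
  cnt <- count_residue_occupancy(sol, traj, cutoff)
  nw_tot <- rowSums(cnt$nw); nx_tot <- rowSums(cnt$nx)
  bulk_w <- traj$n_w - nw_tot
  if (any(bulk_w < 1)) {
    f <- which(bulk_w < 1)[1L]
    stop("no bulk water left in frame ", f)
  }
  ratio <- (traj$n_x - nx_tot) / bulk_w
  G <- cnt$nx - cnt$nw * ratio          # frames x residues
  colnames(G) <- residue_keys(sol)
  res <- sol$residues[, c("chain", "resno", "resid")]
  res$gamma <- colMeans(G)
  res$se <- apply(G, 2, function(s)
    if (length(s) >= 8L) block_error(s) else stats::sd(s) / sqrt(length(s)))
  global <- gamma_estimate(rowSums(G), cutoff, scope = "global")
  structure(list(residues = res, series = G, global = global,
                 cutoff = cutoff, n_frames = n_frames(traj)),
            class = "gamma_residue_set")
}

#' @export
print.gamma_residue_set <- function(x, ...) {
  cat(sprintf("<gamma_residue_set> %d residues, %d frames, cutoff %.1f A; global Gamma = %.3f +/- %.3f\n",
              nrow(x$residues), x$n_frames, x$cutoff,
              x$global$value, x$global$se))
  invisible(x)
}

#' @export
as.data.frame.gamma_residue_set <- function(x, ...) {
  data.frame(scope = "residue", chain = x$residues$chain,
             residue_number = x$residues$resno,
             residue_name = x$residues$resid,
             gamma = x$residues$gamma, se = x$residues$se,
             n_frames = x$n_frames, cutoff_A = x$cutoff,
             stringsAsFactors = FALSE)
}

#' Write Gamma estimates as TSV
#'
#' @param x a `gamma_residue_set` or `gamma_estimate`.
#' @param file output path.
#' @param scope scope label for a bare `gamma_estimate`.
#' @return invisibly, the data.frame written.
#' @export
write_gamma_tsv <- function(x, file, scope = NULL) {
  df <- if (inherits(x, "gamma_residue_set")) {
    rbind(data.frame(scope = "global", chain = NA, residue_number = NA,
                     residue_name = NA, gamma = x$global$value,
                     se = x$global$se, n_frames = x$n_frames,
                     cutoff_A = x$cutoff, stringsAsFactors = FALSE),
          as.data.frame(x))
  } else {
    data.frame(scope = if (is.null(scope)) x$scope else scope,
               chain = NA, residue_number = NA, residue_name = NA,
               gamma = x$value, se = x$se, n_frames = x$n_frames,
               cutoff_A = x$cutoff, stringsAsFactors = FALSE)
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
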