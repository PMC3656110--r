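# Volumetric solvent occupancy maps: per-species 3D grids, preferential-
# solvation classification, hydration-site detection, OpenDX export.

#' Accumulate per-species solvent occupancy on a 3D grid
#'
#' Deposits every in-bounds solvent heavy atom of every frame into its
#' containing voxel (half-open intervals `[lo, hi)`), separately for water
#' and cosolvent. The grid covers the solute bounding box plus `padding` on
#' every side. Bulk reference number densities are estimated from voxels
#' whose centers lie farther than `bulk_dist` from the solute van der Waals
#' surface, i.e. outside the perturbed local domain.
#'
#' @param sol a [solute()].
#' @param traj a [solvent_trajectory()].
#' @param spacing voxel edge length in Angstrom (> 0), default 0.5.
#' @param padding grid margin around the solute bounding box in Angstrom,
#'   default 10.
#' @param bulk_dist surface distance (Angstrom) beyond which voxels count as
#'   bulk, default 8.
#' @return object of class `concentration_grid`: `origin`, `spacing`,
#'   `dims`, `counts` (list of water/cosolvent integer arrays), `bulk_mask`
#'   (logical array), `bulk_density` (molecules/A^3 per species),
#'   `n_frames`, `bulk_dist`.
#' @export
accumulate_grid <- function(sol, traj, spacing = 0.5, padding = 10,
                            bulk_dist = 8) {
  stopifnot(inherits(sol, "solute"), inherits(traj, "solvent_trajectory"))
  if (spacing <= 0) stop("spacing must be > 0")
  sx <- as.matrix(sol$atoms[, c("x", "y", "z")])
  origin <- unname(apply(sx, 2, min)) - padding
  span <- unname(apply(sx, 2, max)) + padding - origin
  dims <- pmax(1L, as.integer(ceiling(span / spacing)))
  counts <- list(water = array(0L, dims), cosolvent = array(0L, dims))
  atom_species <- traj$mol_species[traj$mol_id]
  for (f in seq_len(n_frames(traj))) {
    pts <- traj$coords[[f]]
    ijk <- floor(sweep(pts, 2, origin, "-") / spacing)
    ok <- ijk[, 1] >= 0 & ijk[, 1] < dims[1] &
          ijk[, 2] >= 0 & ijk[, 2] < dims[2] &
          ijk[, 3] >= 0 & ijk[, 3] < dims[3]
    if (!any(ok)) next
    lin <- 1L + ijk[ok, 1] + dims[1] * (ijk[ok, 2] + dims[2] * ijk[ok, 3])
    sp <- atom_species[ok]
    for (s in c("water", "cosolvent")) {
      if (any(sp == s)) {
        tab <- tabulate(lin[sp == s], nbins = prod(dims))
        counts[[s]] <- counts[[s]] + array(tab, dims)
      }
    }
  }
  centers <- voxel_centers(origin, spacing, dims)
  sd <- surface_distance_points(sol, centers)
  bulk_mask <- array(sd$dist > bulk_dist, dims)
  if (!any(bulk_mask))
    stop("empty bulk region (no voxel farther than ", bulk_dist,
         " A from the solute surface); increase padding")
  vol <- spacing^3
  nb <- sum(bulk_mask)
  bulk_density <- vapply(counts, function(a)
    sum(a[bulk_mask]) / (n_frames(traj) * nb * vol), numeric(1))
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 counts = counts, bulk_mask = bulk_mask,
                 bulk_density = bulk_density, n_frames = n_frames(traj),
                 bulk_dist = bulk_dist),
            class = "concentration_grid")
}

# matrix of voxel-center coordinates, x fastest (R column-major order)
voxel_centers <- function(origin, spacing, dims) {
  gx <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing
  gy <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing
  gz <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing
  cbind(rep(gx, times = dims[2] * dims[3]),
        rep(rep(gy, each = dims[1]), times = dims[3]),
        rep(gz, each = dims[1] * dims[2]))
}

#' @export
print.concentration_grid <- function(x, ...) {
  cat(sprintf("<concentration_grid> %d x %d x %d voxels @ %.2f A, %d frames; bulk rho_w = %.4g, rho_x = %.4g /A^3\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$n_frames,
              x$bulk_density[["water"]], x$bulk_density[["cosolvent"]]))
  invisible(x)
}

#' Classify voxels by preferential solvation
#'
#' A voxel is cosolvent-preferred when its occupancy ratio exceeds the bulk
#' composition by more than the fold threshold, (c_x/c_w) > f (rho_x/rho_w),
#' and both species exceed the minimum occupancy; water-preferred is the
#' symmetric condition with factor 1/f. Voxels with total occupancy below
#' the minimum are undersampled.
#'
#' @param grid a [accumulate_grid()] result.
#' @param fold fold threshold f (> 1), default 2.
#' @param min_occupancy minimum counts, default 20.
#' @return integer array over the grid with codes: -1 water-preferred,
#'   0 neutral, 1 cosolvent-preferred, 2 undersampled.
#' @export
classify_preferential <- function(grid, fold = 2, min_occupancy = 20) {
  stopifnot(inherits(grid, "concentration_grid"))
  if (fold <= 1) stop("fold threshold must be > 1")
  if (any(grid$bulk_density <= 0))
    stop("zero bulk density for ",
         paste(names(grid$bulk_density)[grid$bulk_density <= 0],
               collapse = ", "),
         ": the bulk composition ratio is undefined")
  cw <- grid$counts$water; cx <- grid$counts$cosolvent
  rw <- grid$bulk_density[["water"]]; rx <- grid$bulk_density[["cosolvent"]]
  cls <- array(0L, grid$dims)
  under <- (cw + cx) < min_occupancy
  enough <- cw > min_occupancy & cx > min_occupancy
  # cx/cw > f rx/rw  <=>  cx rw > f rx cw  (multiplicative, division-safe)
  pref_x <- enough & (cx * rw > fold * rx * cw)
  pref_w <- enough & (cx * rw < (rx / fold) * cw)
  cls[pref_x] <- 1L
  cls[pref_w] <- -1L
  cls[under] <- 2L
  cls
}

#' Detect high-occupancy hydration sites
#'
#' Finds localized water positions comparable to crystallographic waters:
#' greedy non-overlapping local maxima of the water occupancy grid (26-voxel
#' neighborhood; centers at least two site radii apart), whose occupancy --
#' the fraction of frames with at least one water heavy atom within
#' `site_radius` of the center -- reaches `occupancy_min`. Sites are ranked
#' by occupancy (ties by center coordinates).
#'
#' @param grid a [accumulate_grid()] result.
#' @param traj the [solvent_trajectory()] the grid was accumulated from
#'   (needed for frame-wise occupancy).
#' @param site_radius site radius in Angstrom (>= spacing), default 1.
#' @param occupancy_min minimum occupancy fraction, default 0.5.
#' @return data.frame: x, y, z (site center, Angstrom), occupancy, rank.
#' @export
find_hydration_sites <- function(grid, traj, site_radius = 1,
                                 occupancy_min = 0.5) {
  stopifnot(inherits(grid, "concentration_grid"))
  if (site_radius < grid$spacing)
    stop("site_radius must be at least the grid spacing")
  a <- grid$counts$water
  d <- grid$dims
  # local maxima over the 26-neighborhood (>= all neighbors, > 0)
  is_max <- a > 0L
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    if (ox == 0 && oy == 0 && oz == 0) next
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    vx <- xs + ox; vy <- ys + oy; vz <- zs + oz
    okx <- vx >= 1 & vx <= d[1]; oky <- vy >= 1 & vy <= d[2]
    okz <- vz >= 1 & vz <= d[3]
    sub <- array(FALSE, d)
    sub[xs[okx], ys[oky], zs[okz]] <-
      a[xs[okx], ys[oky], zs[okz]] >= a[vx[okx], vy[oky], vz[okz]]
    # border voxels have no neighbor at this offset: condition satisfied
    full <- array(TRUE, d)
    full[xs[okx], ys[oky], zs[okz]] <- sub[xs[okx], ys[oky], zs[okz]]
    is_max <- is_max & full
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      occupancy = numeric(0), rank = integer(0)))
  cnt <- a[cand]
  ord <- order(-cnt, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  centers <- sweep((cand - 0.5) * grid$spacing, 2, grid$origin, "+")
  keep <- logical(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- centers[keep, , drop = FALSE]
    d2 <- colSums((t(prev) - centers[i, ])^2)
    keep[i] <- all(d2 >= (2 * site_radius)^2)
  }
  centers <- centers[keep, , drop = FALSE]
  # frame-wise occupancy within site_radius
  is_w_atom <- traj$mol_species[traj$mol_id] == "water"
  hits <- matrix(0L, nrow(centers), n_frames(traj))
  r2 <- site_radius^2
  for (f in seq_len(n_frames(traj))) {
    pts <- traj$coords[[f]][is_w_atom, , drop = FALSE]
    for (s in seq_len(nrow(centers))) {
      d2 <- (pts[, 1] - centers[s, 1])^2 + (pts[, 2] - centers[s, 2])^2 +
            (pts[, 3] - centers[s, 3])^2
      hits[s, f] <- any(d2 <= r2)
    }
  }
  occ <- rowMeans(hits)
  sel <- occ >= occupancy_min
  centers <- centers[sel, , drop = FALSE]; occ <- occ[sel]
  ord <- order(-occ, centers[, 1], centers[, 2], centers[, 3])
  data.frame(x = centers[ord, 1], y = centers[ord, 2], z = centers[ord, 3],
             occupancy = occ[ord], rank = seq_along(ord))
}

#' Write a scalar field as an OpenDX file
#'
#' Writes a grid quantity in the standard OpenDX scalar-field layout
#' (gridpositions/gridconnections/array objects; data ordered with the z
#' index varying fastest, as molecular viewers expect).
#'
#' @param grid a [accumulate_grid()] result.
#' @param what `"water"`, `"cosolvent"`, a numeric/integer array of the
#'   grid's dimensions (e.g. a [classify_preferential()] classification), or
#'   `"density"`/`"density_cosolvent"` for counts converted to molecules/A^3.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_volumetric <- function(grid, what, file) {
  stopifnot(inherits(grid, "concentration_grid"))
  vol <- grid$spacing^3
  a <- if (is.character(what)) {
    switch(what,
           water = grid$counts$water,
           cosolvent = grid$counts$cosolvent,
           density = grid$counts$water / (grid$n_frames * vol),
           density_cosolvent = grid$counts$cosolvent / (grid$n_frames * vol),
           stop("unknown field '", what, "'"))
  } else what
  if (!all(dim(a) == grid$dims)) stop("field dimensions do not match grid")
  if (any(!is.finite(a))) stop("grid values must be finite")
  d <- grid$dims
  vals <- as.vector(aperm(a, c(3, 2, 1)))   # z fastest, x slowest
  n <- length(vals)
  pad <- c(vals, rep(NA_real_, (3 - n %% 3) %% 3))
  rows <- matrix(pad, ncol = 3, byrow = TRUE)
  data_lines <- apply(rows, 1, function(v)
    paste(format(v[!is.na(v)], trim = TRUE, digits = 10), collapse = " "))
  hdr <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1] + grid$spacing / 2, grid$origin[2] + grid$spacing / 2,
            grid$origin[3] + grid$spacing / 2),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  )
  ftr <- c('attribute "dep" string "positions"',
           'object "density" class field',
           'component "positions" value 1',
           'component "connections" value 2',
           'component "data" value 3')
  writeLines(c(hdr, data_lines, ftr), file)
  invisible(file)
}

#' Read an OpenDX scalar field
#'
#' Minimal reader for the layout written by [write_volumetric()] (and by
#' common molecular-simulation tools): regular grid positions, rank-0 data
#' with the z index fastest.
#'
#' @param file path to a .dx file.
#' @return list: `origin` (first voxel center), `spacing` (per-axis deltas),
#'   `dims`, `values` (array indexed x, y, z).
#' @export
read_volumetric <- function(file) {
  lines <- readLines(file)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1L]
  if (is.na(gp)) stop("not an OpenDX gridpositions file: ", file)
  d <- as.integer(strsplit(sub(".*counts +", "", gp), " +")[[1L]])
  org <- as.numeric(strsplit(sub("^ *origin +", "",
                                 grep("^ *origin", lines, value = TRUE)[1L]),
                             " +")[[1L]])
  deltas <- vapply(grep("^ *delta", lines, value = TRUE)[1:3], function(l)
    as.numeric(strsplit(sub("^ *delta +", "", l), " +")[[1L]]), numeric(3))
  spacing <- c(deltas[1, 1], deltas[2, 2], deltas[3, 3])
  i0 <- grep("data follows", lines)[1L]
  iend <- grep("^ *attribute", lines)
  iend <- if (length(iend)) min(iend[iend > i0]) - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1L):iend]), " +")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(d)) stop("expected ", prod(d), " values, got ",
                                    length(vals))
  arr <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  list(origin = org, spacing = spacing, dims = d, values = arr)
}

#' Write hydration sites as TSV
#'
#' @param sites data.frame from [find_hydration_sites()].
#' @param file output path.
#' @return invisibly, `sites`.
#' @export
write_sites_tsv <- function(sites, file) {
  utils::write.table(sites, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sites)
}
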