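# Synthetic solvent configurations with known ground truth.
#
# Solvent molecules are placed by rejection sampling: uniform proposals in
# the box, rejected inside the solute hard core, accepted in each region
# with probability proportional to that region's enrichment factor
# (normalized so the largest factor maps to 1). Regions, in precedence
# order: the dewetted contact cylinder (two-blob complexes), the solvation
# shell (surface distance <= shell width), and bulk (factor 1). Exact
# molecule counts per species per frame; a fixed seed regenerates the
# trajectory bit for bit.

#' Build a spherical pseudo-atom solute
#'
#' A toy solute: pseudo-atoms (element X, vdW radius 1.9 A) on a Fibonacci
#' sphere plus one center atom, each atom its own residue.
#'
#' @param n_atoms number of surface atoms, default 12.
#' @param radius sphere radius in Angstrom (0 gives a single atom).
#' @param center center coordinates.
#' @param chain chain id.
#' @param resno_start first residue number.
#' @param label system name.
#' @return a [solute()].
#' @export
sphere_solute <- function(n_atoms = 12, radius = 4, center = c(0, 0, 0),
                          chain = "A", resno_start = 1L, label = "sphere") {
  pts <- matrix(rep(center, each = 1L), ncol = 3)
  if (radius > 0 && n_atoms > 0) {
    i <- seq_len(n_atoms) - 0.5
    phi <- acos(1 - 2 * i / n_atoms)
    theta <- pi * (1 + sqrt(5)) * i
    pts <- rbind(pts, cbind(center[1] + radius * sin(phi) * cos(theta),
                            center[2] + radius * sin(phi) * sin(theta),
                            center[3] + radius * cos(phi)))
  }
  n <- nrow(pts)
  solute(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    elety = "X", elem = "X", chain = chain,
                    resno = resno_start - 1L + seq_len(n),
                    resid = "SYN", stringsAsFactors = FALSE),
         label = label)
}

#' Build a two-blob complex solute
#'
#' Two spherical pseudo-atom blobs (chains A and B) facing each other along
#' the x axis, their centers `separation` apart and the contact midpoint at
#' the origin. The model "protein-protein complex" of the generator.
#'
#' @param separation center-center distance along x in Angstrom.
#' @param blob_radius radius of each blob.
#' @param n_atoms surface atoms per blob.
#' @param label system name.
#' @return a [solute()] with chains A and B.
#' @export
two_blob_solute <- function(separation = 12, blob_radius = 4, n_atoms = 12,
                            label = "two-blob complex") {
  a <- sphere_solute(n_atoms, blob_radius, center = c(-separation / 2, 0, 0),
                     chain = "A")
  b <- sphere_solute(n_atoms, blob_radius, center = c(separation / 2, 0, 0),
                     chain = "B")
  solute(rbind(a$atoms[, c("x", "y", "z", "elety", "elem", "chain", "resno",
                           "resid", "radius")],
               b$atoms[, c("x", "y", "z", "elety", "elem", "chain", "resno",
                           "resid", "radius")]),
         label = label)
}

#' Specify a synthetic solvation scenario
#'
#' Defines the study conditions for one generated system: solute geometry,
#' box, solvent composition, per-region enrichment factors, an optional
#' dewetted contact cylinder, the frame model, and the mandatory seed.
#'
#' @param sol a [solute()] (e.g. [sphere_solute()] or [two_blob_solute()]).
#' @param box length-3 orthorhombic box lengths in Angstrom (centered at the
#'   origin).
#' @param N_w,N_x water and cosolvent molecule counts per frame.
#' @param n_frames number of frames.
#' @param shell_width solvation-shell width in Angstrom, default 5.
#' @param shell_factor_x,shell_factor_w enrichment factors (>= 0) for
#'   cosolvent/water in the shell; 1 = no perturbation, 0 = total exclusion.
#' @param contact `NULL`, or a dewetted contact region for two-blob
#'   complexes: `list(radius, half_length, factor_w, factor_x)` -- a
#'   cylinder around the x axis (|x| <= half_length, sqrt(y^2+z^2) <=
#'   radius) with its own per-species factors.
#' @param patch `NULL`, or a peripheral binding patch:
#'   `list(center, radius, factor_w, factor_x)` -- a sphere with its own
#'   factors, taking precedence over the shell.
#' @param frame_model `"iid"` (default) or `"ar1"`.
#' @param rho AR(1) molecule-retention probability per frame (frame
#'   autocorrelation), used when `frame_model = "ar1"`.
#' @param seed integer random seed (mandatory).
#' @return object of class `scenario_spec`.
#' @export
scenario <- function(sol, box = c(40, 40, 40), N_w = 400, N_x = 40,
                     n_frames = 100, shell_width = 5, shell_factor_x = 1,
                     shell_factor_w = 1, contact = NULL, patch = NULL,
                     frame_model = c("iid", "ar1"), rho = 0.9, seed) {
  if (missing(seed)) stop("a random seed is mandatory")
  frame_model <- match.arg(frame_model)
  stopifnot(inherits(sol, "solute"), length(box) == 3, all(box > 0),
            N_w >= 1, N_x >= 0, n_frames >= 1, shell_width > 0,
            shell_factor_x >= 0, shell_factor_w >= 0)
  if (!is.null(contact))
    stopifnot(contact$radius > 0, contact$half_length > 0,
              contact$factor_w >= 0, contact$factor_x >= 0)
  if (!is.null(patch))
    stopifnot(length(patch$center) == 3, patch$radius > 0,
              patch$factor_w >= 0, patch$factor_x >= 0)
  structure(list(sol = sol, box = box, N_w = N_w, N_x = N_x,
                 n_frames = n_frames, shell_width = shell_width,
                 shell_factor_x = shell_factor_x,
                 shell_factor_w = shell_factor_w,
                 contact = contact, patch = patch,
                 frame_model = frame_model, rho = rho,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# per-point per-species acceptance factor; surface_dist precomputed or NULL.
# Returns matrix n x 2 (water, cosolvent); hard-core points get factor 0.
region_factors <- function(spec, pts, surface_dist = NULL) {
  if (is.null(surface_dist))
    surface_dist <- surface_distance_points(spec$sol, pts)$dist
  n <- nrow(pts)
  fw <- rep(1, n); fx <- rep(1, n)
  shell <- surface_dist <= spec$shell_width
  fw[shell] <- spec$shell_factor_w
  fx[shell] <- spec$shell_factor_x
  if (!is.null(spec$patch)) {
    d2 <- (pts[, 1] - spec$patch$center[1])^2 +
          (pts[, 2] - spec$patch$center[2])^2 +
          (pts[, 3] - spec$patch$center[3])^2
    inp <- d2 <= spec$patch$radius^2
    fw[inp] <- spec$patch$factor_w
    fx[inp] <- spec$patch$factor_x
  }
  if (!is.null(spec$contact)) {
    inc <- abs(pts[, 1]) <= spec$contact$half_length &
           (pts[, 2]^2 + pts[, 3]^2) <= spec$contact$radius^2
    fw[inc] <- spec$contact$factor_w
    fx[inc] <- spec$contact$factor_x
  }
  core <- surface_dist < 0
  fw[core] <- 0; fx[core] <- 0
  cbind(water = fw, cosolvent = fx)
}

# sample n accepted positions for one species
sample_positions <- function(spec, n, species, max_tries = 2000L) {
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  fmax <- max(1, if (species == "water")
    c(spec$shell_factor_w, spec$contact$factor_w, spec$patch$factor_w) else
    c(spec$shell_factor_x, spec$contact$factor_x, spec$patch$factor_x))
  out <- matrix(NA_real_, n, 3L)
  got <- 0L
  for (try in seq_len(max_tries)) {
    m <- max(64L, 4L * (n - got))
    prop <- cbind(stats::runif(m, -spec$box[1] / 2, spec$box[1] / 2),
                  stats::runif(m, -spec$box[2] / 2, spec$box[2] / 2),
                  stats::runif(m, -spec$box[3] / 2, spec$box[3] / 2))
    f <- region_factors(spec, prop)[, species]
    acc <- stats::runif(m) < f / fmax
    k <- min(sum(acc), n - got)
    if (k > 0L) {
      out[got + seq_len(k), ] <- prop[acc, , drop = FALSE][seq_len(k), ]
      got <- got + k
    }
    if (got == n) return(out)
  }
  stop("infeasible solvent density: acceptance region too small for ",
       species)
}

#' Generate a synthetic solvent system
#'
#' Realizes a [scenario()]: a solute, a solvent trajectory with exact
#' per-species molecule counts each frame, and a ground-truth record of the
#' region geometry, factors and seed. Identical spec and seed give
#' bit-identical output. With `frame_model = "ar1"`, each molecule keeps its
#' position from the previous frame with probability `rho` and is resampled
#' otherwise, giving frame-autocorrelated occupancies with marginal
#' distributions unchanged.
#'
#' @param spec a [scenario()].
#' @return list: `sol` ([solute()]), `traj` ([solvent_trajectory()]),
#'   `truth` (spec plus derived geometry).
#' @export
generate_system <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  n_mol <- spec$N_w + spec$N_x
  species <- rep(c("water", "cosolvent"), c(spec$N_w, spec$N_x))
  frames <- vector("list", spec$n_frames)
  prev <- NULL
  for (f in seq_len(spec$n_frames)) {
    if (spec$frame_model == "iid" || is.null(prev)) {
      cur <- rbind(sample_positions(spec, spec$N_w, "water"),
                   sample_positions(spec, spec$N_x, "cosolvent"))
    } else {
      keep <- stats::runif(n_mol) < spec$rho
      cur <- prev
      rw <- which(!keep & species == "water")
      rx <- which(!keep & species == "cosolvent")
      if (length(rw)) cur[rw, ] <- sample_positions(spec, length(rw), "water")
      if (length(rx)) cur[rx, ] <- sample_positions(spec, length(rx), "cosolvent")
    }
    frames[[f]] <- cur
    prev <- cur
  }
  traj <- solvent_trajectory(frames, mol_species = species,
                             box = matrix(spec$box, nrow = 1L))
  list(sol = spec$sol, traj = traj,
       truth = list(spec = spec, seed = spec$seed,
                    shell_width = spec$shell_width,
                    contact = spec$contact, patch = spec$patch))
}

#' Free-state counterparts of a two-blob complex scenario
#'
#' Splits a two-blob complex scenario into its two free blobs: each blob is
#' re-solvated alone, with the same box, composition and shell factors but
#' without the contact region (and without the patch unless it belongs to
#' that blob), mirroring the free/associated comparison with known truth.
#'
#' @param spec a [scenario()] whose solute is a [two_blob_solute()].
#' @param seed_A,seed_B seeds for the two free systems (default: spec seed
#'   + 1, + 2).
#' @return list of two [scenario()]s, `A` and `B`, each with the blob
#'   recentered at the origin.
#' @export
split_free_states <- function(spec, seed_A = spec$seed + 1L,
                              seed_B = spec$seed + 2L) {
  stopifnot(inherits(spec, "scenario_spec"))
  one <- function(chain, seed) {
    at <- spec$sol$atoms
    at <- at[at$chain == chain, , drop = FALSE]
    shift <- c(mean(range(at$x)), mean(range(at$y)), mean(range(at$z)))
    at$x <- at$x - shift[1]; at$y <- at$y - shift[2]; at$z <- at$z - shift[3]
    sol <- solute(at[, c("x", "y", "z", "elety", "elem", "chain", "resno",
                         "resid", "radius")],
                  label = paste0("free blob ", chain))
    patch <- spec$patch
    if (!is.null(patch)) {
      # keep the patch only if it sits on this blob (nearest chain wins)
      dp <- surface_distance_points(spec$sol,
                                    matrix(patch$center, 1L, 3L))
      patch_chain <- spec$sol$atoms$chain[dp$atom]
      patch <- if (patch_chain == chain) {
        p <- patch; p$center <- p$center - shift; p
      } else NULL
    }
    scenario(sol, box = spec$box, N_w = spec$N_w, N_x = spec$N_x,
             n_frames = spec$n_frames, shell_width = spec$shell_width,
             shell_factor_x = spec$shell_factor_x,
             shell_factor_w = spec$shell_factor_w,
             contact = NULL, patch = patch,
             frame_model = spec$frame_model, rho = spec$rho, seed = seed)
  }
  list(A = one("A", seed_A), B = one("B", seed_B))
}

#' Canonical dewetted-contact complex scenario
#'
#' The reference study conditions for the two-blob association experiment: a
#' 26-residue two-blob complex (blob radius 4 A, centers 12 A apart) in a
#' 56 x 44 x 44 A box at liquid-water-like density (3400 waters, 370
#' cosolvent molecules, about a 6 molal mole ratio), with two-fold cosolvent
#' shell enrichment and a dewetted contact cylinder (radius 5 A, half-length
#' 3 A) from which cosolvent is totally excluded and water reduced to 30%.
#' Association-induced solvation changes are thereby confined to residues
#' near the contact, emulating a dewetted protein-protein interface.
#'
#' @param seed random seed.
#' @param n_frames frames per system, default 400.
#' @return a [scenario()].
#' @export
dewetted_contact_scenario <- function(seed, n_frames = 400) {
  scenario(two_blob_solute(separation = 12, blob_radius = 4, n_atoms = 12),
           box = c(56, 44, 44), N_w = 3400, N_x = 370,
           n_frames = n_frames, shell_factor_x = 2,
           contact = list(radius = 5, half_length = 3,
                          factor_w = 0.3, factor_x = 0),
           seed = seed)
}

#' Brute-force Gamma series (test oracle)
#'
#' Computes the per-frame Gamma series by all-pairs distance evaluation
#' with no spatial indexing or prefiltering -- a deliberately naive oracle
#' for validating [gamma_global()] on small instances (at most 500 solvent
#' molecules and 200 frames).
#'
#' @param sol a [solute()].
#' @param traj a [solvent_trajectory()].
#' @param cutoff shell cutoff in Angstrom.
#' @return numeric per-frame Gamma series.
#' @export
brute_force_gamma <- function(sol, traj, cutoff = 5) {
  n_mol <- length(traj$mol_species)
  if (n_mol > 500L || n_frames(traj) > 200L)
    stop("instance too large for the brute-force oracle (<= 500 molecules, <= 200 frames)")
  sx <- as.matrix(sol$atoms[, c("x", "y", "z")])
  r <- sol$atoms$radius
  is_w <- traj$mol_species == "water"
  series <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    pts <- traj$coords[[f]]
    box <- if (!is.null(traj$box)) traj$box[f, ] else NULL
    mol_dist <- rep(Inf, n_mol)
    for (i in seq_len(nrow(pts))) {           # every solvent atom ...
      best <- Inf
      for (a in seq_len(nrow(sx))) {          # ... against every solute atom
        d <- pts[i, ] - sx[a, ]
        if (!is.null(box)) d <- d - box * round(d / box)
        dd <- sqrt(sum(d * d)) - r[a]
        if (dd < best) best <- dd
      }
      m <- traj$mol_id[i]
      if (best < mol_dist[m]) mol_dist[m] <- best
    }
    loc <- mol_dist <= cutoff
    n_w <- sum(loc & is_w); n_x <- sum(loc & !is_w)
    series[f] <- n_x - n_w * (traj$n_x - n_x) / (traj$n_w - n_w)
  }
  series
}

#' Expected Gamma of a scenario by deterministic quadrature
#'
#' Independent analytic oracle: integrates the generator's acceptance
#' density on a fine grid over the box to obtain each species' probability
#' of landing in the local domain (and in each residue's territory), then
#' forms the expected counts and the first-order expectation of Gamma.
#' Depends only on the scenario geometry, never on sampled frames.
#'
#' @param spec a [scenario()].
#' @param cutoff shell cutoff for the local domain, default 5.
#' @param spacing quadrature grid spacing in Angstrom, default 0.5.
#' @return list: `gamma` (expected global Gamma), `p_local` (per species),
#'   `E_n` (expected local counts per species), `residues` (data.frame with
#'   per-residue expected counts and expected Gamma contributions).
#' @export
expected_gamma <- function(spec, cutoff = 5, spacing = 0.5) {
  stopifnot(inherits(spec, "scenario_spec"))
  gx <- seq(-spec$box[1] / 2 + spacing / 2, spec$box[1] / 2, by = spacing)
  gy <- seq(-spec$box[2] / 2 + spacing / 2, spec$box[2] / 2, by = spacing)
  gz <- seq(-spec$box[3] / 2 + spacing / 2, spec$box[3] / 2, by = spacing)
  R <- nrow(spec$sol$residues)
  tot <- c(water = 0, cosolvent = 0)
  loc <- c(water = 0, cosolvent = 0)
  res_w <- numeric(R); res_x <- numeric(R)
  # sweep z-slabs to bound memory
  for (z in gz) {
    pts <- cbind(rep(gx, times = length(gy)),
                 rep(gy, each = length(gx)), z)
    sd <- surface_distance_points(spec$sol, pts)
    f <- region_factors(spec, pts, surface_dist = sd$dist)
    tot <- tot + colSums(f)
    inloc <- sd$dist >= 0 & sd$dist <= cutoff
    loc <- loc + colSums(f[inloc, , drop = FALSE])
    if (any(inloc)) {
      res <- spec$sol$atoms$res_index[sd$atom[inloc]]
      res_w <- res_w + as.numeric(tapply(f[inloc, "water"], factor(res, levels = seq_len(R)), sum, default = 0))
      res_x <- res_x + as.numeric(tapply(f[inloc, "cosolvent"], factor(res, levels = seq_len(R)), sum, default = 0))
    }
  }
  res_w[is.na(res_w)] <- 0; res_x[is.na(res_x)] <- 0
  p_local <- loc / tot
  E_n <- c(water = spec$N_w * p_local[["water"]],
           cosolvent = spec$N_x * p_local[["cosolvent"]])
  ratio <- (spec$N_x - E_n[["cosolvent"]]) / (spec$N_w - E_n[["water"]])
  resdf <- spec$sol$residues[, c("chain", "resno", "resid")]
  resdf$E_nw <- spec$N_w * res_w / tot[["water"]]
  resdf$E_nx <- spec$N_x * res_x / tot[["cosolvent"]]
  resdf$gamma <- resdf$E_nx - resdf$E_nw * ratio
  list(gamma = E_n[["cosolvent"]] - E_n[["water"]] * ratio,
       p_local = p_local, E_n = E_n, residues = resdf)
}
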