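test_that("a single atom deposits into exactly one voxel and counts conserve", {
  sol <- one_atom_solute(1.9)
  traj <- water_traj(list(matrix(c(3.26, -1.1, 0.7), 1, 3)))
  grid <- accumulate_grid(sol, traj, spacing = 0.5, padding = 12)
  expect_equal(sum(grid$counts$water), 1L)
  expect_equal(sum(grid$counts$water == 1L), 1L)
  idx <- which(grid$counts$water == 1L, arr.ind = TRUE)
  lo <- grid$origin + (idx - 1) * grid$spacing
  expect_true(all(c(3.26, -1.1, 0.7) >= lo) &&
              all(c(3.26, -1.1, 0.7) < lo + grid$spacing))
})

test_that("atoms outside the grid bounds are dropped without error", {
  sol <- one_atom_solute(1.9)
  traj <- water_traj(list(matrix(c(500, 500, 500), 1, 3)))
  grid <- accumulate_grid(sol, traj, spacing = 0.5, padding = 12)
  expect_equal(sum(grid$counts$water), 0L)
})

test_that("too small a padding leaves no bulk region", {
  sol <- one_atom_solute(1.9)
  traj <- water_traj(list(matrix(c(1, 1, 1), 1, 3)))
  expect_error(accumulate_grid(sol, traj, spacing = 1, padding = 3,
                               bulk_dist = 8), "padding")
})

test_that("uniform solvent occupancies follow Poisson statistics in the bulk", {
  spec <- scenario(sphere_solute(8, 3), box = c(30, 30, 30), N_w = 400,
                   N_x = 0, n_frames = 600, seed = 55)
  sys <- generate_system(spec)
  grid <- accumulate_grid(sys$sol, sys$traj, spacing = 1.5, padding = 8,
                          bulk_dist = 8)
  lam <- grid$bulk_density[["water"]] * grid$spacing^3 * grid$n_frames
  counts <- grid$counts$water[grid$bulk_mask]
  # mean count within 3 Poisson SE of lambda for >= 99% of bulk voxels
  z <- abs(counts - lam) / sqrt(lam)
  expect_gte(mean(z <= 3), 0.99)
  # conservation: all deposits are accounted for
  n_dep <- sum(vapply(sys$traj$coords, function(f) {
    ijk <- floor(sweep(f, 2, grid$origin, "-") / grid$spacing)
    sum(ijk[, 1] >= 0 & ijk[, 1] < grid$dims[1] &
        ijk[, 2] >= 0 & ijk[, 2] < grid$dims[2] &
        ijk[, 3] >= 0 & ijk[, 3] < grid$dims[3])
  }, numeric(1)))
  expect_equal(sum(grid$counts$water), n_dep)
})

test_that("voxel classification compares occupancy ratios to the bulk ratio", {
  sol <- one_atom_solute(1.9)
  grid <- structure(list(origin = c(0, 0, 0), spacing = 1, dims = c(2L, 2L, 2L),
                         counts = list(water = array(50L, c(2, 2, 2)),
                                       cosolvent = array(5L, c(2, 2, 2))),
                         bulk_mask = array(TRUE, c(2, 2, 2)),
                         bulk_density = c(water = 0.05, cosolvent = 0.005),
                         n_frames = 1000L, bulk_dist = 8),
                    class = "concentration_grid")
  # every voxel exactly at the bulk ratio -> neutral
  expect_true(all(classify_preferential(grid, fold = 2,
                                        min_occupancy = 10) == 0L))
  # zero total occupancy -> undersampled
  grid$counts$water[1, 1, 1] <- 0L; grid$counts$cosolvent[1, 1, 1] <- 0L
  # strong cosolvent excess -> cosolvent-preferred
  grid$counts$cosolvent[2, 2, 2] <- 60L
  # strong water excess -> water-preferred
  grid$counts$cosolvent[1, 2, 1] <- 60L; grid$counts$water[1, 2, 1] <- 6000L
  cls <- classify_preferential(grid, fold = 2, min_occupancy = 10)
  expect_equal(cls[1, 1, 1], 2L)
  expect_equal(cls[2, 2, 2], 1L)
  expect_equal(cls[1, 2, 1], -1L)
  expect_equal(cls[2, 1, 1], 0L)
})

test_that("classification depends only on ratios relative to bulk", {
  spec <- scenario(sphere_solute(12, 4), box = c(36, 36, 36), N_w = 400,
                   N_x = 80, n_frames = 800, shell_factor_x = 4, seed = 21)
  sys <- generate_system(spec)
  grid <- accumulate_grid(sys$sol, sys$traj, spacing = 2, padding = 9)
  cls <- classify_preferential(grid, fold = 2, min_occupancy = 20)
  # doubling both species leaves the classification unchanged
  grid2 <- grid
  grid2$counts$water <- grid$counts$water * 2L
  grid2$counts$cosolvent <- grid$counts$cosolvent * 2L
  grid2$bulk_density <- grid$bulk_density * 2
  cls2 <- classify_preferential(grid2, fold = 2, min_occupancy = 20)
  # voxels above the doubled min-occupancy threshold behave identically
  enough <- grid$counts$water > 20 & grid$counts$cosolvent > 20
  expect_equal(cls[enough], cls2[enough])
  # shell voxels are predominantly cosolvent-preferred at fold 2 when the
  # generator enriched by 4; bulk voxels predominantly neutral
  centers <- prefint:::voxel_centers(grid$origin, grid$spacing, grid$dims)
  sd <- prefint:::surface_distance_points(sys$sol, centers)
  shell <- array(sd$dist >= 0 & sd$dist <= 4, grid$dims)
  sampled <- cls != 2L
  expect_gt(mean(cls[shell & sampled] == 1L), 0.5)
  expect_gt(mean(cls[grid$bulk_mask & sampled] == 0L), 0.9)
})

test_that("a tethered water is recovered as a full-occupancy hydration site", {
  sol <- one_atom_solute(1.9)
  pos <- c(4.1, 0.3, -0.2)
  frames <- replicate(40, {
    m <- matrix(runif(60, -12, 12), 20, 3)
    m[1, ] <- pos
    m
  }, simplify = FALSE)
  traj <- water_traj(frames)
  grid <- accumulate_grid(sol, traj, spacing = 0.5, padding = 14)
  sites <- find_hydration_sites(grid, traj, site_radius = 1,
                                occupancy_min = 0.8)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$occupancy, 1.0)
  expect_lt(sqrt(sum((as.numeric(sites[1, c("x", "y", "z")]) - pos)^2)),
            sqrt(3) * grid$spacing)
})

test_that("two tethered waters 6 A apart give two ranked sites", {
  sol <- one_atom_solute(1.9)
  p1 <- c(4, 0, 0); p2 <- c(4, 6, 0)
  frames <- lapply(1:50, function(f) {
    m <- matrix(runif(90, -12, 12), 30, 3)
    m[1, ] <- p1
    if (f <= 45) m[2, ] <- p2   # second site occupied 90% of frames
    m
  })
  traj <- water_traj(frames)
  grid <- accumulate_grid(sol, traj, spacing = 0.5, padding = 14)
  sites <- find_hydration_sites(grid, traj, site_radius = 1,
                                occupancy_min = 0.5)
  expect_gte(nrow(sites), 2L)
  top2 <- sites[1:2, ]
  d1 <- min(sqrt(colSums((t(as.matrix(top2[, 1:3])) - p1)^2)))
  d2 <- min(sqrt(colSums((t(as.matrix(top2[, 1:3])) - p2)^2)))
  expect_lt(d1, sqrt(3) * grid$spacing)
  expect_lt(d2, sqrt(3) * grid$spacing)
  expect_gte(top2$occupancy[1], top2$occupancy[2])
})

test_that("uniform solvent yields no high-occupancy site", {
  spec <- scenario(sphere_solute(8, 3), box = c(30, 30, 30), N_w = 200,
                   N_x = 0, n_frames = 200, seed = 66)
  sys <- generate_system(spec)
  grid <- accumulate_grid(sys$sol, sys$traj, spacing = 1, padding = 8)
  sites <- find_hydration_sites(grid, sys$traj, site_radius = 1,
                                occupancy_min = 0.5)
  # expected per-frame sphere occupancy rho * (4/3) pi r^3 ~ 0.03 << 0.5
  expect_equal(nrow(sites), 0L)
})

test_that("site detection is translation-equivariant", {
  sol <- one_atom_solute(1.9)
  pos <- c(4, 0, 0)
  frames <- replicate(30, {
    m <- matrix(runif(45, -12, 12), 15, 3)
    m[1, ] <- pos
    m
  }, simplify = FALSE)
  shift <- c(7.25, -3.5, 1.75)
  traj <- water_traj(frames)
  traj_s <- water_traj(lapply(frames, function(f) sweep(f, 2, shift, "+")))
  at2 <- sol$atoms
  at2$x <- at2$x + shift[1]; at2$y <- at2$y + shift[2]; at2$z <- at2$z + shift[3]
  sol_s <- solute(at2[, c("x", "y", "z", "elety", "elem", "chain", "resno",
                          "resid", "radius")])
  s1 <- find_hydration_sites(accumulate_grid(sol, traj, 0.5, 14), traj,
                             1, 0.8)
  s2 <- find_hydration_sites(accumulate_grid(sol_s, traj_s, 0.5, 14), traj_s,
                             1, 0.8)
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(as.matrix(s2[, 1:3]), sweep(as.matrix(s1[, 1:3]), 2, shift, "+"),
               tolerance = 1e-9)
})

test_that("OpenDX output round-trips values, origin and spacing", {
  sol <- one_atom_solute(1.9)
  traj <- water_traj(list(matrix(c(3.1, 0, 0, -2.2, 1, 4), 2, 3, byrow = TRUE)))
  grid <- accumulate_grid(sol, traj, spacing = 2, padding = 10)
  f <- tempfile(fileext = ".dx")
  write_volumetric(grid, "water", f)
  back <- read_volumetric(f)
  expect_equal(back$dims, grid$dims)
  expect_equal(back$values, grid$counts$water, ignore_attr = TRUE)
  expect_equal(back$origin, grid$origin + grid$spacing / 2, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$spacing, rep(2, 3), tolerance = 1e-9, ignore_attr = TRUE)
  # classification codes round-trip as integers
  cls <- array(rep(c(-1L, 0L, 1L, 2L), length.out = prod(grid$dims)),
               grid$dims)
  write_volumetric(grid, cls, f)
  expect_equal(read_volumetric(f)$values, cls, ignore_attr = TRUE)
  # an all-zero field is a valid file
  write_volumetric(grid, array(0, grid$dims), f)
  expect_true(all(read_volumetric(f)$values == 0))
})
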