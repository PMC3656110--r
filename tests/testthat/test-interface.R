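# two 3-residue chains with exactly one contact pair at 4.2 A; next nearest
# atom-atom cross distance is 6.8 A
contact_fixture <- function() {
  solute(data.frame(
    x = c(0, 0, 0, 4.2, 6.8, 8),
    y = c(0, 4, 8, 0, 4, 8),
    z = 0,
    elety = "X", elem = "X",
    chain = rep(c("A", "B"), each = 3),
    resno = rep(1:3, 2),
    resid = "SYN", radius = 1.9))
}

simple_complex <- function() {
  # chain A residues at x = 0, -5, -10; chain B at x = 4.2, 11, 18 (y = 0)
  solute(data.frame(
    x = c(0, -5, -10, 4.2, 11, 18), y = 0, z = 0,
    elety = "X", elem = "X",
    chain = rep(c("A", "B"), each = 3),
    resno = rep(1:3, 2), resid = "SYN", radius = 1.9))
}

test_that("interface membership follows atom-center distances", {
  sol <- simple_complex()
  # D = 0: no two atoms coincide -> empty interface
  p0 <- interface_residues(sol, "A", 0)
  expect_equal(nrow(p0$inte), 0L)
  expect_equal(nrow(p0$noninte), 6L)
  # D beyond the complex diameter: everything interfacial
  pall <- interface_residues(sol, "A", 100)
  expect_equal(nrow(pall$inte), 6L)
  expect_equal(nrow(pall$noninte), 0L)
  # brute-force derived: only A:1 (x=0) and B:1 (x=4.2) are within 5 A
  p5 <- interface_residues(sol, "A", 5)
  expect_setequal(residue_keys(p5$inte), c("A:1", "B:1"))
  # monotone: inte(D) grows with D
  for (D in c(0, 3, 7, 12, 20)) {
    pa <- interface_residues(sol, "A", D)
    pb <- interface_residues(sol, "A", D + 2)
    expect_true(all(residue_keys(pa$inte) %in% residue_keys(pb$inte)))
  }
  expect_error(interface_residues(sol, c("A", "B"), 5), "empty")
})

test_that("one contact pair at 4.2 A is the exact D = 5 interface", {
  sol <- contact_fixture()
  # independent brute force over all cross-chain atom pairs
  a <- sol$atoms[sol$atoms$chain == "A", ]
  b <- sol$atoms[sol$atoms$chain == "B", ]
  dmat <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
    sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2))
  expect_equal(sort(unique(round(apply(dmat, 1, min), 1)))[1], 4.2)
  pairs <- which(dmat <= 5, arr.ind = TRUE)
  truth <- unique(c(paste0("A:", a$resno[pairs[, 1]]),
                    paste0("B:", b$resno[pairs[, 2]])))
  p <- interface_residues(sol, "A", 5)
  expect_setequal(residue_keys(p$inte), truth)
})

test_that("regional coefficients partition the global one exactly", {
  sys <- generate_system(scenario(two_blob_solute(), box = c(44, 40, 40),
                                  N_w = 300, N_x = 30, n_frames = 30,
                                  seed = 12))
  gr <- gamma_per_residue(sys$sol, sys$traj)
  for (D in c(0, 5, 9, 100)) {
    part <- interface_residues(sys$sol, "A", D)
    reg <- regional_gamma(gr, part)
    expect_equal(reg$inte$series + reg$noninte$series, gr$global$series,
                 tolerance = 1e-12)
  }
  # degenerate partition: everything interfacial -> inte equals global
  reg_all <- regional_gamma(gr, interface_residues(sys$sol, "A", 100))
  expect_equal(reg_all$inte$series, gr$global$series, tolerance = 1e-12)
  expect_equal(reg_all$noninte$series, rep(0, n_frames(sys$traj)))
})

test_that("delta_gamma combines values and standard errors in quadrature", {
  dg <- delta_gamma(list(value = -20.6, se = 1.5), list(value = -11.1, se = 0.4),
                    list(value = -5.2, se = 0.8))
  expect_equal(dg$value, -4.3, tolerance = 1e-12)
  expect_equal(dg$se, sqrt(1.5^2 + 0.4^2 + 0.8^2))
  expect_equal(round(dg$se, 1), 1.7)
  dgi <- delta_gamma(list(value = -6.7, se = 0.5), list(value = -1.9, se = 0.2),
                     list(value = -1.8, se = 0.2), scope = "inte")
  expect_equal(dgi$value, -3.0, tolerance = 1e-12)
  expect_equal(round(dgi$se, 1), 0.6)
  dg0 <- delta_gamma(list(value = 0, se = 0), list(value = 0, se = 0),
                     list(value = 0, se = 0))
  expect_equal(dg0$value, 0)
  expect_equal(dg0$se, 0)
})

test_that("null complex and free states give D* at the smallest grid value", {
  spec <- scenario(two_blob_solute(), box = c(44, 40, 40), N_w = 600,
                   N_x = 60, n_frames = 150, seed = 31)
  free <- split_free_states(spec)
  cpx <- generate_system(spec)
  fa <- generate_system(free$A); fb <- generate_system(free$B)
  g_cpx <- gamma_per_residue(cpx$sol, cpx$traj)
  g_fa <- gamma_per_residue(fa$sol, fa$traj)
  g_fb <- gamma_per_residue(fb$sol, fb$traj)
  dst <- determine_interface_distance(cpx$sol, "A", g_cpx, g_fa, g_fb,
                                      D_grid = 3:12, k = 1)
  expect_equal(dst$D_star, 3)
  expect_equal(nrow(dst$scan), 10L)
})

test_that("a perturbation confined near the contact bounds D*", {
  # cosolvent binding pocket between the blobs, radius 4 around the contact
  # midpoint: every perturbed residue has atoms within ~6 A of the partner
  spec <- scenario(two_blob_solute(), box = c(48, 40, 40), N_w = 1200,
                   N_x = 130, n_frames = 250,
                   patch = list(center = c(0, 0, 0), radius = 4,
                                factor_w = 1, factor_x = 8), seed = 57)
  free <- split_free_states(spec)
  cpx <- generate_system(spec)
  fa <- generate_system(free$A); fb <- generate_system(free$B)
  g_cpx <- gamma_per_residue(cpx$sol, cpx$traj)
  g_fa <- gamma_per_residue(fa$sol, fa$traj)
  g_fb <- gamma_per_residue(fb$sol, fb$traj)
  dst <- determine_interface_distance(cpx$sol, "A", g_cpx, g_fa, g_fb,
                                      D_grid = 3:12, k = 1)
  expect_lte(dst$D_star, 7)
  # the scan reports every grid point with SEs
  expect_true(all(is.finite(dst$scan$delta_noninte)))
  expect_true(all(dst$scan$se >= 0))
})

test_that("the D* scan error carries the full scan report", {
  spec <- scenario(two_blob_solute(), box = c(44, 40, 40), N_w = 300,
                   N_x = 30, n_frames = 30, seed = 3)
  free <- split_free_states(spec)
  cpx <- generate_system(spec)
  fa <- generate_system(free$A); fb <- generate_system(free$B)
  g_cpx <- gamma_per_residue(cpx$sol, cpx$traj)
  g_fa <- gamma_per_residue(fa$sol, fa$traj)
  g_fb <- gamma_per_residue(fb$sol, fb$traj)
  # k = 0 with a D grid stopping short of the full complex: nothing passes
  err <- tryCatch(
    determine_interface_distance(cpx$sol, "A", g_cpx, g_fa, g_fb,
                                 D_grid = 3:5, k = 0),
    prefint_no_dstar = function(e) e)
  expect_s3_class(err, "prefint_no_dstar")
  expect_equal(nrow(err$scan), 3L)
})

test_that("residue delta maps localize a one-residue enrichment patch", {
  sol <- two_blob_solute()
  # patch on a specific blob-B residue, far from the contact
  target_atom <- which.max(sol$atoms$x)   # outermost B atom
  center <- as.numeric(sol$atoms[target_atom, c("x", "y", "z")])
  target_key <- residue_keys(sol$residues[sol$atoms$res_index[target_atom], ])
  spec <- scenario(sol, box = c(48, 40, 40), N_w = 1200, N_x = 130,
                   n_frames = 250,
                   patch = list(center = center, radius = 3.5,
                                factor_w = 1, factor_x = 10), seed = 91)
  free <- split_free_states(spec)
  # free states regenerate without the complex-only patch
  free$A$patch <- NULL; free$B$patch <- NULL
  cpx <- generate_system(spec)
  fa <- generate_system(free$A); fb <- generate_system(free$B)
  g_cpx <- gamma_per_residue(cpx$sol, cpx$traj)
  g_fa <- gamma_per_residue(fa$sol, fa$traj)
  g_fb <- gamma_per_residue(fb$sol, fb$traj)
  dmap <- residue_delta_map(g_cpx, g_fa, g_fb, "A", k = 2)
  row <- dmap[paste(dmap$chain, dmap$resno, sep = ":") == target_key, ]
  expect_true(row$significant)
  expect_gt(row$delta, 0)
  # chain-A residues are untouched by a patch on the far side of B
  far <- dmap[dmap$chain == "A", ]
  expect_true(all(abs(far$delta) <= 4 * far$se))
})

test_that("residue significance is calibrated near its nominal level under the null", {
  hits <- 0L; total <- 0L
  for (seed in c(211, 223, 227)) {
    spec <- scenario(two_blob_solute(), box = c(44, 40, 40), N_w = 600,
                     N_x = 60, n_frames = 64, seed = seed)
    free <- split_free_states(spec)
    cpx <- generate_system(spec)
    fa <- generate_system(free$A); fb <- generate_system(free$B)
    dmap <- residue_delta_map(gamma_per_residue(cpx$sol, cpx$traj),
                              gamma_per_residue(fa$sol, fa$traj),
                              gamma_per_residue(fb$sol, fb$traj), "A", k = 2)
    hits <- hits + sum(dmap$significant)
    total <- total + nrow(dmap)
  }
  # two-sided ~2 SE flags: per-residue false-positive rate stays near the
  # nominal ~5% (binomial slack for 78 draws)
  expect_lt(hits / total, 0.15)
})
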