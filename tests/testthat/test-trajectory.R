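toy_chain <- function(seed = 1, n = 10) {
  toy <- make_toy_complex(n_residues = n, contact_patch = integer(0),
                          seed = seed)
  select_structure(toy$structure, "A")
}

test_that("Kabsch superposition nulls rigid motion and matches the
           grid-search oracle", {
  chain <- toy_chain()
  c0 <- pepforge:::structure_coords(chain)
  fit0 <- kabsch_superpose(c0, c0)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)

  th <- 37 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(c0 %*% t(R), 2, c(5, -3, 2), "+")
  fit <- kabsch_superpose(c0, moved)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)

  ## 4-point toy with one displaced point: oracle grid search over
  ## rotations agrees within 1e-3
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  mob <- ref
  mob[4, ] <- mob[4, ] + c(0.6, -0.8, 0)
  mob <- sweep(mob %*% t(R), 2, c(1, 2, 3), "+")
  fit2 <- kabsch_superpose(ref, mob)
  expect_equal(fit2$rmsd, rmsd_grid_oracle(ref, mob), tolerance = 1e-3)
  expect_error(kabsch_superpose(ref, mob[1:3, ]), "shape")
})

test_that("RMSD is symmetric and invariant to rigid pre-transforms", {
  chain <- toy_chain(3)
  c0 <- pepforge:::structure_coords(chain)
  set.seed(4)
  c1 <- c0 + matrix(rnorm(length(c0), sd = 0.4), ncol = 3)
  expect_equal(kabsch_superpose(c0, c1)$rmsd, kabsch_superpose(c1, c0)$rmsd,
               tolerance = 1e-8)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  pre <- sweep(c1 %*% t(R), 2, c(-4, 9, 2), "+")
  expect_equal(kabsch_superpose(c0, pre)$rmsd, kabsch_superpose(c0, c1)$rmsd,
               tolerance = 1e-8)
})

test_that("RMSD series: zeros for static input, analytic mean for harmonic
           fluctuation", {
  chain <- toy_chain()
  static <- make_trajectory(chain, n_frames = 20, amplitudes = 0, seed = 1)
  rs <- rmsd_series(static$trajectory)
  expect_equal(rs$rmsd, rep(0, 20), tolerance = 1e-10)

  sigma <- 0.5
  tr <- make_trajectory(chain, n_frames = 400, amplitudes = sigma, seed = 2)
  rs2 <- rmsd_series(tr$trajectory, selection = NULL, ref_frame = 1)
  expect_equal(rs2$rmsd[1], 0, tolerance = 1e-10)
  ## frame-vs-frame displacement has per-coordinate variance 2 sigma^2 (both
  ## frames fluctuate); superposition removes ~6 of the 3N degrees of
  ## freedom. Expected RMSD ~ sqrt(2 sigma^2 (3N - 6) / N) in Angstrom.
  n_at <- dim(tr$trajectory$coords)[2]
  n_eff_modes <- 3 * 10 - 6  # displacements are per-residue (10 residues)
  expected_nm <- sqrt(2 * sigma^2 * n_eff_modes / (3 * 10)) / 10
  expect_equal(mean(rs2$rmsd[-1]), expected_nm, tolerance = 0.10)
  expect_error(rmsd_series(tr$trajectory, ref_frame = 999), "range")
})

test_that("RMSF recovers per-residue amplitude structure", {
  chain <- toy_chain(5, n = 12)
  static <- make_trajectory(chain, n_frames = 5, amplitudes = 0, seed = 1)
  expect_equal(rmsf(static$trajectory)$rmsf, rep(0, 12), tolerance = 1e-10)

  amps <- rep(0.3, 12)
  amps[4] <- 0.9  # 3x the rest
  tr <- make_trajectory(chain, n_frames = 500, amplitudes = amps, seed = 9)
  rf <- rmsf(tr$trajectory)
  expect_equal(which.max(rf$rmsf), 4)
  ## 3:1 amplitude ratio reproduced within 15%
  expect_equal(rf$rmsf[4] / mean(rf$rmsf[-4]), 3, tolerance = 0.15)

  single <- tr$trajectory
  single$coords <- single$coords[1, , , drop = FALSE]
  single$times <- single$times[1]
  expect_error(rmsf(single), "2 frames")
})

test_that("RMSF rank order is exact for amplitude ratios >= 1.5", {
  chain <- toy_chain(6, n = 8)
  amps <- c(0.2, 0.3, 0.45, 0.7, 1.05, 1.6, 2.4, 3.6)
  tr <- make_trajectory(chain, n_frames = 500, amplitudes = amps, seed = 13)
  rf <- rmsf(tr$trajectory)
  expect_equal(order(rf$rmsf), order(amps))
})

test_that("radius of gyration matches analytic and brute-force values", {
  expect_equal(radius_of_gyration(matrix(c(0, 0, 0), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 0.1)
  set.seed(77)
  cloud <- matrix(rnorm(150, sd = 4), ncol = 3)
  masses <- runif(50, 1, 16)
  com <- colSums(cloud * masses) / sum(masses)
  direct <- sqrt(sum(masses * rowSums(sweep(cloud, 2, com)^2)) /
                   sum(masses)) / 10
  expect_equal(radius_of_gyration(cloud, masses), direct)
  expect_error(radius_of_gyration(cloud, rep(0, 50)), "mass")
  chain <- toy_chain()
  tr <- make_trajectory(chain, n_frames = 5, amplitudes = 0, seed = 1)
  rg <- rg_series(tr$trajectory)
  expect_equal(length(unique(round(rg$rg, 10))), 1)
})

test_that("SASA series tracks per-frame geometry", {
  one <- atoms_structure(0, 0, 0, radius = 1.7)
  tr <- trajectory(one, array(0, dim = c(3, 1, 3)))
  ss <- sasa_series(tr, sasa_params(n_test_points = 960))
  expect_equal(ss$sasa, rep(4 * pi * 3.1^2 / 100, 3), tolerance = 0.01)

  ## breathing dimer: oscillating distance anti-correlates with overlap
  dists <- c(2, 3, 4, 3, 2, 3, 4, 3)
  dimer <- atoms_structure(c(0, 2), c(0, 0), c(0, 0), radius = 1.7)
  coords <- lapply(dists, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  tr2 <- trajectory(dimer, coords)
  ss2 <- sasa_series(tr2, sasa_params(n_test_points = 960))
  direct <- vapply(dists, function(d)
    sum(two_sphere_analytic(d, 1.7, 1.7, 1.4)) / 100, 1.0)
  expect_equal(ss2$sasa, direct, tolerance = 0.01)
  expect_gt(cor(ss2$sasa, dists), 0.99)
})

test_that("hydrogen-bond series counts per frame", {
  base <- data.frame(model = 1L, serial = 1:2, name = c("N", "O"),
                     altloc = "", resname = "ALA", chain = c("A", "B"),
                     resseq = 1L, icode = "", x = c(0, 2.9), y = 0, z = 0,
                     occupancy = 1, bfactor = 0, element = c("N", "O"),
                     hetero = FALSE, radius = 1.5)
  s <- pepforge:::new_structure(base)
  dists <- c(2.9, 2.9, 6.0, 6.0, 2.9)
  coords <- lapply(dists, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  tr <- trajectory(s, coords)
  hb <- hbond_series(tr, "A", "B")
  expect_equal(hb$n_hbonds, as.integer(dists <= 3.5))
})

test_that("PCA satisfies the trace identity and isolates 1D motion", {
  chain <- toy_chain(2, n = 6)
  static <- make_trajectory(chain, n_frames = 4, amplitudes = 0, seed = 1)
  p0 <- traj_pca(static$trajectory)
  expect_equal(sum(p0$eigenvalues), 0, tolerance = 1e-12)

  ## internal motion confined to one axis: antisymmetric x-stretch (a pure
  ## translation would be removed by the superposition)
  c0 <- pepforge:::structure_coords(chain)
  half <- seq_len(nrow(c0)) <= nrow(c0) / 2
  shifts <- seq(-2, 2, length.out = 9)
  coords <- lapply(shifts, function(s) {
    cc <- c0
    cc[half, 1] <- cc[half, 1] + s
    cc[!half, 1] <- cc[!half, 1] - s
    cc
  })
  tr <- trajectory(chain, coords)
  p1 <- traj_pca(tr)
  expect_gt(p1$eigenvalues[1] / sum(p1$eigenvalues), 0.99)

  tr2 <- make_trajectory(chain, n_frames = 60, amplitudes = 0.4, seed = 3)
  p2 <- traj_pca(tr2$trajectory)
  aligned <- pepforge:::superpose_to_mean(
    tr2$trajectory, seq_len(dim(tr2$trajectory$coords)[2]))$aligned
  X <- matrix(aligned, nrow = 60)
  total_var <- sum(apply(X, 2, var))
  expect_equal(sum(p2$eigenvalues), total_var, tolerance = 1e-8)
})

test_that("3-state hopping yields separable PCA clusters", {
  chain <- toy_chain(4, n = 8)
  tr <- make_trajectory(chain, n_frames = 150, mode = "hopping",
                        n_states = 3, state_sd = 3, seed = 21)
  p <- traj_pca(tr$trajectory)
  expect_gt(mean_silhouette(p$projections, tr$state_labels), 0.5)
})

test_that("free-energy landscapes are Boltzmann inversions with zero
           minimum", {
  ## all points in one bin
  one <- free_energy_landscape(cbind(rep(1, 50), rep(2, 50)), bins = 8)
  expect_equal(min(one$free_energy), 0)
  expect_equal(sort(unique(as.vector(one$free_energy))),
               c(0, one$cap))
  ## uniform occupancy: every occupied bin at 0
  gr <- expand.grid(x = 1:6, y = 1:6)
  unif <- free_energy_landscape(cbind(gr$x, gr$y), bins = 6)
  expect_true(all(abs(unif$free_energy) < 1e-12))
  ## isotropic Gaussian: radial profile is quadratic, F = kT r^2 / (2 s^2)
  set.seed(10)
  pts <- matrix(rnorm(2 * 40000, sd = 1), ncol = 2)
  fel <- free_energy_landscape(pts, temperature = 300, bins = 41)
  cx <- (fel$pc1_edges[-1] + fel$pc1_edges[-42]) / 2
  cy <- (fel$pc2_edges[-1] + fel$pc2_edges[-42]) / 2
  r2grid <- outer(cx^2, cy^2, "+")
  occ <- fel$free_energy < fel$cap & r2grid < 4
  kt <- 0.0019872041 * 300
  fit <- lm(as.vector(fel$free_energy[occ]) ~ as.vector(r2grid[occ]))
  expect_equal(unname(coef(fit)[2]), kt / 2, tolerance = 0.1)
  ## FEL minimum sits in the modal bin
  counts_mode <- which(fel$free_energy == 0, arr.ind = TRUE)
  expect_true(nrow(counts_mode) >= 1)
})

test_that("trajectory PDB round trip preserves frames", {
  chain <- toy_chain(8, n = 4)
  tr <- make_trajectory(chain, n_frames = 3, amplitudes = 0.4, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr$trajectory, path)
  back <- read_trajectory_pdb(path)
  expect_equal(dim(back$coords), dim(tr$trajectory$coords))
  expect_equal(back$coords[2, , ], tr$trajectory$coords[2, , ],
               tolerance = 1e-3)
})
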