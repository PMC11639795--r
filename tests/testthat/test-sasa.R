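ANALYTIC_SPHERE <- 4 * pi * 3.1^2  # r = 1.7, probe = 1.4

test_that("isolated sphere reproduces the analytic area for both algorithms", {
  s <- atoms_structure(0, 0, 0, radius = 1.7)
  sr <- sasa_shrake_rupley(s, sasa_params(n_test_points = 960))
  lr <- sasa_lee_richards(s, sasa_params(slice_width = 0.1))
  expect_equal(sr$total, ANALYTIC_SPHERE, tolerance = 0.01)
  expect_equal(lr$total, ANALYTIC_SPHERE, tolerance = 0.01)
})

test_that("a small atom inside a larger one has zero area", {
  s <- atoms_structure(c(0, 0), c(0, 0), c(0, 0), radius = c(1.0, 3.0))
  for (alg in c("shrake", "lee")) {
    res <- compute_sasa(s, sasa_params(), alg)
    expect_equal(res$per_atom$area[1], 0)
    expect_gt(res$per_atom$area[2], 0)
  }
})

test_that("dimer areas match the analytic two-sphere result and the
           random-point oracle", {
  d <- 2.0
  s <- atoms_structure(c(0, d), c(0, 0), c(0, 0), radius = 1.7)
  analytic <- two_sphere_analytic(d, 1.7, 1.7, 1.4)
  coords <- cbind(c(0, d), 0, 0)
  oracle <- sasa_point_oracle(coords, c(1.7, 1.7), 1.4, n_points = 1e5)
  expect_equal(oracle, analytic, tolerance = 0.01)  # oracle sanity
  for (alg in c("shrake", "lee")) {
    res <- compute_sasa(s, sasa_params(n_test_points = 960,
                                       slice_width = 0.1), alg)
    expect_equal(res$per_atom$area, analytic, tolerance = 0.02)
    expect_equal(res$per_atom$area, oracle, tolerance = 0.02)
  }
})

test_that("quadrature error decays with resolution on the occluded dimer", {
  s <- atoms_structure(c(0, 2), c(0, 0), c(0, 0), radius = 1.7)
  truth <- sum(two_sphere_analytic(2, 1.7, 1.7, 1.4))
  err_sr <- vapply(c(100, 960, 4000), function(np)
    abs(sasa_shrake_rupley(s, sasa_params(n_test_points = np))$total - truth),
    1.0)
  expect_true(all(diff(err_sr) < 0))
  expect_lt(err_sr[3] / truth, 0.005)
  err_lr <- vapply(c(0.5, 0.25, 0.05), function(sw)
    abs(sasa_lee_richards(s, sasa_params(slice_width = sw))$total - truth),
    1.0)
  expect_lt(err_lr[3], err_lr[1])
})

test_that("linear triatomic chain matches the random-point oracle within 2%", {
  x <- c(0, 2.2, 4.4)
  s <- atoms_structure(x, c(0, 0, 0), c(0, 0, 0), radius = c(1.7, 1.5, 1.8))
  oracle <- sasa_point_oracle(cbind(x, 0, 0), c(1.7, 1.5, 1.8), 1.4,
                              n_points = 5e4)
  for (alg in c("shrake", "lee")) {
    res <- compute_sasa(s, sasa_params(n_test_points = 960,
                                       slice_width = 0.1), alg)
    expect_equal(res$per_atom$area, oracle, tolerance = 0.02)
  }
})

test_that("the two algorithms agree within 2% on fixture structures", {
  toy <- make_toy_complex(seed = 5)
  p <- sasa_params()
  sr <- sasa_shrake_rupley(toy$structure, p)
  lr <- sasa_lee_richards(toy$structure, p)
  expect_equal(sr$total, lr$total, tolerance = 0.02)
  ## per-residue agreement too
  expect_equal(sr$per_residue$area, lr$per_residue$area, tolerance = 0.05)
})

test_that("SASA is invariant under rigid-body motion", {
  toy <- make_toy_complex(seed = 2)
  s <- toy$structure
  ## general rotation mixing all three axes, plus a translation
  th <- 0.7; ph <- 0.5
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(ph), 0, sin(ph), 0, 1, 0, -sin(ph), 0, cos(ph)), 3, 3)
  move <- function(s) {
    xyz <- cbind(s$atoms$x, s$atoms$y, s$atoms$z) %*% (Rz %*% Ry)
    s$atoms$x <- xyz[, 1] + 11.3
    s$atoms$y <- xyz[, 2] - 7.9
    s$atoms$z <- xyz[, 3] + 3.4
    s
  }
  ## translation alone is exact at any resolution (the lattice rides on
  ## the atom centres)
  shifted <- s
  shifted$atoms$x <- s$atoms$x + 31
  shifted$atoms$z <- s$atoms$z - 17
  expect_equal(sasa_shrake_rupley(shifted, sasa_params())$total,
               sasa_shrake_rupley(s, sasa_params())$total,
               tolerance = 1e-10)
  ## rotation invariance holds to 0.1% in the quadrature-converged regime
  p_sr <- sasa_params(n_test_points = 4000)
  expect_equal(sasa_shrake_rupley(move(s), p_sr)$total,
               sasa_shrake_rupley(s, p_sr)$total, tolerance = 0.001)
  p_lr <- sasa_params(slice_width = 0.05)
  expect_equal(sasa_lee_richards(move(s), p_lr)$total,
               sasa_lee_richards(s, p_lr)$total, tolerance = 0.001)
})

test_that("per-residue aggregation sums to the total", {
  toy <- make_toy_complex(seed = 3)
  res <- sasa_shrake_rupley(toy$structure, sasa_params())
  expect_equal(sum(res$per_residue$area), res$total, tolerance = 1e-9)
  one <- atoms_structure(0, 0, 0, radius = 1.7)
  r1 <- sasa_shrake_rupley(one, sasa_params())
  expect_equal(r1$per_residue$area, r1$total)
  ## determinism: identical runs give identical numbers
  res2 <- sasa_shrake_rupley(toy$structure, sasa_params())
  expect_identical(res$per_atom$area, res2$per_atom$area)
})

test_that("delta-SASA detects burial and vanishes for a distant ligand", {
  toy <- make_toy_complex(seed = 1)
  rep <- delta_sasa(toy$structure, "A", "B", toy$interface)
  expect_gt(rep$delta_sasa, 0)
  expect_equal(rep$delta_sasa,
               rep$unbound_site_sasa - rep$bound_site_sasa,
               tolerance = 1e-9)
  ## burial cannot be negative beyond quadrature noise
  expect_true(all(rep$per_residue$delta > -0.5))

  far <- toy$structure
  bmask <- far$atoms$chain == "B"
  far$atoms$x[bmask] <- far$atoms$x[bmask] + 100
  rep_far <- delta_sasa(far, "A", "B", toy$interface)
  expect_equal(rep_far$delta_sasa, 0, tolerance = 1e-6)

  expect_error(delta_sasa(toy$structure, "A", "A", toy$interface),
               "overlap")
  expect_warning(rep0 <- delta_sasa(toy$structure, "A", "B",
                                    residue_keys(character(0), integer(0))),
                 "empty")
  expect_equal(rep0$delta_sasa, 0)
})

test_that("delta-SASA on a constructed patch matches the point oracle", {
  toy <- make_toy_complex(n_residues = 8, contact_patch = 4:5, seed = 6)
  site <- toy$interface
  p <- sasa_params(n_test_points = 960)
  rep <- delta_sasa(toy$structure, "A", "B", site, p)
  ## oracle: dense random-point areas for site atoms, bound and unbound
  a <- toy$structure$atoms
  site_atoms <- which(a$chain == "A" & a$resseq %in% site$resseq)
  rec <- which(a$chain == "A")
  all_xyz <- cbind(a$x, a$y, a$z)
  ub <- sasa_point_oracle(all_xyz[rec, ], a$radius[rec], 1.4, 2e4)
  bd <- sasa_point_oracle(all_xyz, a$radius, 1.4, 2e4)
  oracle_delta <- sum(ub[match(site_atoms, rec)]) - sum(bd[site_atoms])
  expect_equal(rep$delta_sasa, oracle_delta, tolerance = 0.02)
})

test_that("interface detection recovers exactly the constructed patch", {
  toy <- make_toy_complex(n_residues = 12, contact_patch = 5:7, seed = 1)
  res <- structure_residues(select_structure(toy$structure, "A"))
  rep <- delta_sasa(toy$structure, "A", "B", res[, c("chain", "resseq", "icode")])
  ifc <- detect_interface(rep, 1.0)
  expect_equal(format_residue_keys(ifc), c("A:5", "A:6", "A:7"))
  ## all-zero report -> empty list
  far <- toy$structure
  bmask <- far$atoms$chain == "B"
  far$atoms$y[bmask] <- far$atoms$y[bmask] + 100
  rep0 <- delta_sasa(far, "A", "B", res[, c("chain", "resseq", "icode")])
  expect_equal(nrow(detect_interface(rep0, 1.0)), 0)
})

test_that("hydrogen bonds follow distance geometry and match the pair-scan
           oracle", {
  ## constructed N...O pair at 2.9 A
  mk <- function(d) {
    a <- rbind(
      data.frame(model = 1L, serial = 1L, name = "N", altloc = "",
                 resname = "ALA", chain = "A", resseq = 1L, icode = "",
                 x = 0, y = 0, z = 0, occupancy = 1, bfactor = 0,
                 element = "N", hetero = FALSE, radius = 1.55),
      data.frame(model = 1L, serial = 2L, name = "O", altloc = "",
                 resname = "ALA", chain = "B", resseq = 1L, icode = "",
                 x = d, y = 0, z = 0, occupancy = 1, bfactor = 0,
                 element = "O", hetero = FALSE, radius = 1.52))
    pepforge:::new_structure(a)
  }
  expect_equal(nrow(detect_hbonds(mk(2.9), "A", "B")), 1)
  expect_equal(nrow(detect_hbonds(mk(5.0), "A", "B")), 0)

  ## synthetic backbone ladder: N(i) of chain B placed 2.9 A above O(i) of
  ## chain A for 4 residues; counts must equal the exhaustive pair scan
  toy <- make_toy_complex(n_residues = 6, contact_patch = 2:5,
                          inter_chain_gap = 3.2, seed = 8)
  found <- detect_hbonds(toy$structure, "B", "A")
  expect_equal(nrow(found), hbond_pair_oracle(toy$structure, "B", "A"))
  ## sorted by donor key
  if (nrow(found) > 1) {
    rank <- pepforge:::residue_key_rank(found$donor_resseq, found$donor_icode)
    expect_true(all(diff(rank) >= 0))
  }
})

test_that("explicit hydrogens enable the angle criterion", {
  base <- data.frame(model = 1L, serial = 1:3,
                     name = c("N", "H", "O"), altloc = "",
                     resname = "ALA", chain = c("A", "A", "B"),
                     resseq = c(1L, 1L, 1L), icode = "",
                     x = c(0, 1.0, 2.9), y = 0, z = 0,
                     occupancy = 1, bfactor = 0,
                     element = c("N", "H", "O"), hetero = FALSE,
                     radius = 1.5)
  s_lin <- pepforge:::new_structure(base)
  hits <- detect_hbonds(s_lin, "A", "B")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$angle, 180, tolerance = 1e-6)
  ## bend the hydrogen so the D-H...A angle drops below 120 degrees
  bent <- base
  bent$x[2] <- 0
  bent$y[2] <- 1.0
  s_bent <- pepforge:::new_structure(bent)
  expect_equal(nrow(detect_hbonds(s_bent, "A", "B")), 0)
})
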