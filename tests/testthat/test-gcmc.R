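test_that("Lennard-Jones pair energy has its node, minimum and cutoff where it should", {
  ff <- fixture_ff()
  s <- 3.431  # sigma of the C-C pair
  expect_equal(lj_pair_energy("C", "C", s, ff), 0, tolerance = 1e-12)
  expect_equal(lj_pair_energy("C", "C", 2^(1 / 6) * s, ff), -52.84,
               tolerance = 1e-9)
  expect_equal(lj_pair_energy("C", "C", ff$cutoff + 0.001, ff), 0)
  expect_identical(lj_pair_energy("C", "C", 0, ff), Inf)
  # Lorentz-Berthelot mixing: node of the C-O pair at (sC + sO)/2
  so <- (3.431 + 3.118) / 2
  expect_equal(lj_pair_energy("C", "O", so, ff), 0, tolerance = 1e-12)
  # shifted tail is zero at the cutoff and continuous
  ffs <- forcefield(tail = "shifted")
  expect_equal(lj_pair_energy("C", "C", ffs$cutoff - 1e-9, ffs), 0,
               tolerance = 1e-6)
})

test_that("incremental energies match a brute-force recomputation", {
  ff <- fixture_ff()
  g <- fixture_guests()
  # pair of unit guests at the LJ minimum: total energy -epsilon
  sys <- mofscreen:::build_sim_system(empty_box(30), g$unit, ff, 25.6)
  sys$supercell <- NULL
  rmin <- 2^(1 / 6) * 3.73
  e <- mofscreen:::total_energy_cpp(sys, list(matrix(c(5, 5, 5), 1),
                                              matrix(c(5 + rmin, 5, 5), 1)))
  expect_equal(e, -120, tolerance = 1e-9)
  # minimum image: same pair across the boundary
  e2 <- mofscreen:::total_energy_cpp(sys, list(matrix(c(1, 5, 5), 1),
                                               matrix(c(30 - rmin + 1, 5, 5), 1)))
  expect_equal(e2, -120, tolerance = 1e-9)
  # long-run drift of the incremental energy vs full recomputation
  s <- make_cubic_framework(10)
  r <- run_gcmc(s, g$sn38_like, ff,
                gcmc_config(T = 250, fugacity = 5e5, cycles = 800,
                            equilibration = 200, seed = 2),
                drift_check_every = 1000)
  expect_lt(r$max_drift, 1e-6)
  expect_gt(r$mean_N, 0)
})

test_that("empty-box uptake reproduces the ideal gas: mean and Poisson variance", {
  ff <- fixture_ff()
  gu <- fixture_guests()$unit
  box <- empty_box(30)
  r <- run_gcmc(box, gu, ff, gcmc_config(T = 300, fugacity = 1e5,
                                         cycles = 6000, equilibration = 1000,
                                         seed = 5))
  expect_equal(r$betafV, 0.6519, tolerance = 1e-3)
  expect_lt(abs(r$mean_N - r$betafV), 3 * max(r$se_N, 0.01))
  v <- var(r$N_trace)
  expect_lt(abs(v - r$mean_N) / r$mean_N, 0.15)  # Var(N) = <N> for Poisson
})

test_that("uptake is monotone in fugacity", {
  ff <- fixture_ff()
  gu <- fixture_guests()$unit
  s <- make_cubic_framework(10)
  ns <- vapply(c(2e4, 1e5, 5e5), function(f) {
    run_gcmc(s, gu, ff, gcmc_config(T = 300, fugacity = f, cycles = 2500,
                                    equilibration = 500, seed = 7))$mean_N
  }, numeric(1))
  expect_true(all(diff(ns) > 0))
})

test_that("Widom insertion: exact in an empty box, suppressed in a crowded one", {
  ff <- fixture_ff()
  gu <- fixture_guests()$unit
  w <- widom_henry(empty_box(30), gu, ff, T = 300, insertions = 1e4, seed = 1)
  expect_equal(w$mean_boltzmann, 1, tolerance = 1e-12)
  expect_equal(w$henry, w$beta, tolerance = 1e-12)
  wd <- widom_henry(make_dense_block(a = 10), gu, ff, T = 300,
                    insertions = 1e4, seed = 2)
  expect_lt(wd$henry, wd$beta)  # overlap-dominated framework
})

test_that("low-fugacity GCMC uptake agrees with the Widom Henry coefficient", {
  ff <- fixture_ff()
  gu <- fixture_guests()$unit
  s <- make_cubic_framework(10)
  w <- widom_henry(s, gu, ff, T = 300, insertions = 5e4, seed = 5)
  sup <- build_supercell(s, 25.6)
  V <- sup$cell$volume
  f <- 0.04 / (w$henry * V)  # target mean_N ~ 0.04 (< 0.05, Henry regime)
  r <- run_gcmc(s, gu, ff, gcmc_config(T = 300, fugacity = f, cycles = 20000,
                                       equilibration = 3000, seed = 6))
  combined_se <- sqrt(r$se_N^2 + (w$se * f * V)^2) + 1e-4
  expect_lt(abs(r$mean_N - w$henry * f * V), 3 * combined_se)
})

test_that("lattice-gas GCMC matches the closed-form isotherm over the activity sweep", {
  lg <- make_lattice_gas(M = 100, eps_site = 40)
  for (z in c(0.05, 0.3, 1.14, 3, 10)) {  # x = z e^{-eps/T} spans the isotherm
    r <- run_lattice_gcmc(lg$M, lg$eps_site, z = z, T = 300, steps = 3e5,
                          seed = round(100 * z))
    exact <- lg$isotherm(z, 300)
    expect_equal(r$mean_N, exact, tolerance = 0.035)
    expect_equal(r$exact_N, exact, tolerance = 1e-12)
  }
  # single-site chain: stationary occupancy obeys detailed balance
  r1 <- run_lattice_gcmc(1, eps_site = 0, z = 2, steps = 3e5, seed = 9)
  expect_equal(r1$mean_N, 2 / 3, tolerance = 0.02)
})

test_that("trajectories are bit-identical for a fixed seed and differ across seeds", {
  ff <- fixture_ff()
  gu <- fixture_guests()$unit
  s <- make_cubic_framework(10)
  cfg <- gcmc_config(T = 300, fugacity = 2e5, cycles = 800, equilibration = 200,
                     seed = 42)
  r1 <- run_gcmc(s, gu, ff, cfg)
  r2 <- run_gcmc(s, gu, ff, cfg)
  expect_identical(r1$N_trace, r2$N_trace)
  expect_identical(r1$mean_N, r2$mean_N)
  cfg2 <- cfg; cfg2$seed <- 43L
  r3 <- run_gcmc(s, gu, ff, cfg2)
  expect_false(identical(r1$N_trace, r3$N_trace))
})

test_that("frameworks too tight for the guest come back flagged inaccessible", {
  ff <- fixture_ff()
  r <- run_gcmc(make_dense_block(a = 10), fixture_guests()$gemcitabine_like,
                ff, gcmc_config(cycles = 400, equilibration = 100, seed = 3))
  expect_equal(r$mean_N, 0)
  expect_true(r$inaccessible)
  expect_equal(r$loading_mg_per_g, 0)
})

test_that("loading conversions implement the mass-balance identities", {
  expect_equal(loading_conversions(10, 263.2, 2632)$mg_per_g, 1000)
  expect_equal(loading_conversions(10, 263.2, 2632)$wt_percent, 50)
  expect_equal(loading_conversions(0, 263.2, 2632)$wt_percent, 0)
  c3 <- loading_conversions(1, 263.2, 2632)
  expect_equal(c3$mg_per_g, 100)
  expect_equal(c3$wt_percent, 100 * 100 / 1100)
  expect_error(loading_conversions(1, 263.2, 0), "framework_mass")
})

test_that("configuration contracts are enforced", {
  expect_error(gcmc_config(move_probs = c(0.3, 0.2, 0.4, 0.1)), "equal")
  expect_error(gcmc_config(move_probs = c(0.2, 0.2, 0.2, 0.2)), "sum to 1")
  expect_error(gcmc_config(cycles = 100, equilibration = 100))
  tri <- periodic_structure(unit_cell(10, 10, 10, 80, 90, 90),
                            data.frame(element = "C", fx = 0, fy = 0, fz = 0))
  expect_error(run_gcmc(tri, fixture_guests()$unit, fixture_ff()),
               "orthogonal")
})
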