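test_that("cubic corner framework honours its closed-form pore metrics", {
  s <- make_cubic_framework(a = 10, element = "C")
  expect_equal(nrow(s$sites), 1)
  r <- unname(vdw_radius("C"))
  g <- compute_distance_grid(s, spacing = 0.2)
  expect_lt(abs(largest_cavity_diameter(g) - (sqrt(3) * 10 - 2 * r)), 0.01)
  expect_lt(abs(pore_limiting_diameter(g) - (sqrt(2) * 10 - 2 * r)), 0.01)
  # tight cell still generated, with a warning
  expect_warning(make_cubic_framework(a = 3), "non-porous")
  # generated CIF reparses to the same single-site cubic cell
  s2 <- parse_cif(write_cif(s))
  expect_equal(nrow(s2$sites), 1)
  expect_equal(s2$cell$a, 10, tolerance = 1e-6)
})

test_that("dilation series strictly increases void fraction, factor 1 is the base", {
  ser <- make_dilation_series(a = 10, factors = c(1, 1.2, 1.5, 2))
  vf <- vapply(ser, function(s) {
    accessible_pore_volume(s, probe_radius = 0, samples = 4000, seed = 1,
                           accessible = FALSE)$void_fraction
  }, numeric(1))
  expect_true(all(diff(vf) > 0))
  base <- make_cubic_framework(a = 10)
  expect_equal(ser[[1]]$sites, base$sites)
  expect_equal(ser[[1]]$cell$a, base$cell$a)
  # LCD(f a) = f sqrt(3) a - 2 r when radii stay fixed
  g <- compute_distance_grid(ser[[4]], spacing = 0.25)
  expect_lt(abs(largest_cavity_diameter(g) -
                (sqrt(3) * 20 - 2 * unname(vdw_radius("C")))), 0.02)
})

test_that("guest models carry the drug formula masses and ordered minimal diameters", {
  g <- make_guest_models()
  expect_equal(g$gemcitabine_like$molar_mass, formula_mass("C9H11F2N3O4"),
               tolerance = 1e-3)  # gemcitabine
  expect_equal(g$sn38_like$molar_mass, formula_mass("C22H20N2O5"),
               tolerance = 1e-3)  # SN-38
  expect_equal(g$paclitaxel_like$molar_mass, formula_mass("C47H51NO14"),
               tolerance = 1e-3)  # paclitaxel
  expect_lt(g$gemcitabine_like$minimal_diameter, g$sn38_like$minimal_diameter)
  expect_lt(g$sn38_like$minimal_diameter, g$paclitaxel_like$minimal_diameter)
  # site clouds are centered on the centroid
  expect_equal(colMeans(as.matrix(g$paclitaxel_like$sites[, c("x", "y", "z")])),
               c(x = 0, y = 0, z = 0), tolerance = 1e-9)
})

test_that("lattice-gas closed form has the right limits", {
  lg <- make_lattice_gas(M = 100, eps_site = 40)
  x1 <- exp(-40 / 300)
  expect_equal(lg$isotherm(1 / x1, 300), 50)               # x = 1 -> M/2
  z <- 1e-4
  expect_equal(lg$isotherm(z, 300), 100 * z * x1, tolerance = 1e-3)  # Henry
  expect_equal(lg$isotherm(1e9, 300), 100, tolerance = 1e-6)         # saturation
})

test_that("toxicity generator is a pure function of its seed and matches its priors", {
  d1 <- make_toxicity_dataset(n = 400, seed = 7)
  d2 <- make_toxicity_dataset(n = 400, seed = 7)
  expect_identical(d1$ld50, d2$ld50)
  expect_identical(d1$combo, d2$combo)
  expect_identical(d1$label, d2$label)
  d3 <- make_toxicity_dataset(n = 400, seed = 8)
  expect_false(identical(d1$ld50, d3$ld50))
  # class proportions near the priors at n = 2000
  big <- make_toxicity_dataset(n = 2000, seed = 7)
  prop <- prop.table(table(big$drawn_class))[c("fatal", "toxic", "safe")]
  expect_true(all(abs(prop - c(0.25, 0.35, 0.40)) < 0.03))
  # labels are consistent with the category scheme by construction
  expect_identical(big$label, ld50_to_custom_category(big$ld50))
  # the planted rule achieves the advertised Bayes accuracy
  expect_gte(big$bayes$accuracy_realized, 0.90)
  expect_error(make_toxicity_dataset(priors = c(fatal = 0.5, toxic = 0.5, safe = 0.5)),
               "sum to 1")
})

test_that("screening library regenerates identically with a manifest that matches", {
  l1 <- make_screening_library(seed = 1)
  l2 <- make_screening_library(seed = 1)
  expect_identical(lapply(l1$structures, write_cif),
                   lapply(l2$structures, write_cif))
  expect_equal(nrow(l1$manifest), 6)
  expect_identical(sort(unique(l1$manifest$expected_stage)),
                   c("biocompat", "loading", "porosity"))
  expect_identical(l1$manifest$name,
                   vapply(l1$structures, function(s) s$name, character(1)))
})

test_that("the synthetic channel stand-in reproduces its designed diameters", {
  s <- make_channel_framework(diameters = c(24, 10), atom_spacing = 2.0)
  g <- compute_distance_grid(s, spacing = 0.3)
  # wall atoms sit on a discrete grid, so the realized free diameter can
  # exceed the request by a fraction of the atom spacing
  expect_lt(abs(largest_cavity_diameter(g) - 24), 1.5)
  p <- pore_size_distribution(g)
  expect_gte(nrow(p), 2)
  expect_lt(abs(p$diameter[1] - 24), 1.5)
  expect_lt(abs(p$diameter[2] - 10), 1.5)
})
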