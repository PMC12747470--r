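test_that("distance grid matches closed-form values at known points", {
  s <- make_cubic_framework(a = 10)
  g <- compute_distance_grid(s, spacing = 0.5, radii = c(C = 1.5))
  # body center (on-grid for even dims): 10 sqrt(3)/2 - 1.5
  arr <- array(g$values, g$dims)
  mid <- g$dims / 2 + 1
  expect_equal(arr[mid[1], mid[2], mid[3]], 10 * sqrt(3) / 2 - 1.5,
               tolerance = 1e-9)
  # at the atom: -r
  expect_equal(arr[1, 1, 1], -1.5, tolerance = 1e-12)
  # refinement changes the maximum by less than a grid diagonal
  g2 <- compute_distance_grid(s, spacing = 0.25, radii = c(C = 1.5))
  expect_lt(abs(max(g2$values) - max(g$values)), sqrt(3) * 0.5)
  expect_error(compute_distance_grid(empty_box(10)), "empty")
})

test_that("corner-lattice LCD and PLD match their closed forms", {
  r <- unname(vdw_radius("C"))
  for (a in c(8, 10, 13)) {
    s <- make_cubic_framework(a = a)
    g <- compute_distance_grid(s, spacing = 0.2)
    # LCD is polished by continuous refinement: near-exact
    expect_lt(abs(largest_cavity_diameter(g) - (sqrt(3) * a - 2 * r)), 0.02)
    # PLD resolution is the grid; off-lattice bottlenecks cost up to a
    # grid diagonal
    expect_lt(abs(pore_limiting_diameter(g) - (sqrt(2) * a - 2 * r)), 0.45)
    expect_lte(pore_limiting_diameter(g), largest_cavity_diameter(g))
  }
})

test_that("PLD <= LCD and both scale with uniform dilation and shrink with fatter atoms", {
  s1 <- make_cubic_framework(a = 10)
  s2 <- make_cubic_framework(a = 20)
  g1 <- compute_distance_grid(s1, spacing = 0.2)
  g2 <- compute_distance_grid(s2, spacing = 0.2)
  r <- unname(vdw_radius("C"))
  # LCD(2a) = 2 sqrt(3) a - 2r (radii do not scale)
  expect_lt(abs(largest_cavity_diameter(g2) -
                (2 * (largest_cavity_diameter(g1) + 2 * r) - 2 * r)), 0.05)
  # growing the vdW radius shrinks both descriptors
  gfat <- compute_distance_grid(s1, spacing = 0.2, radii = c(C = 2.4))
  expect_lt(largest_cavity_diameter(gfat), largest_cavity_diameter(g1))
  expect_lt(pore_limiting_diameter(gfat), pore_limiting_diameter(g1))
})

test_that("dense structures have zero LCD/PLD and empty PSD", {
  d <- make_dense_block(a = 8)
  g <- compute_distance_grid(d, spacing = 0.3)
  expect_equal(largest_cavity_diameter(g), 0)
  expect_equal(pore_limiting_diameter(g), 0)
  expect_equal(nrow(pore_size_distribution(g)), 0)
})

test_that("pore-size distribution resolves one peak per channel system", {
  one <- make_channel_framework(diameters = 12, atom_spacing = 1.8, wall = 5)
  g1 <- compute_distance_grid(one, spacing = 0.3)
  p1 <- pore_size_distribution(g1)
  expect_gte(nrow(p1), 1)
  expect_equal(p1$diameter[1], 12, tolerance = 1.0 / 12)
  two <- make_channel_framework(diameters = c(20, 9), atom_spacing = 1.8)
  g2 <- compute_distance_grid(two, spacing = 0.3)
  p2 <- pore_size_distribution(g2)
  expect_gte(nrow(p2), 2)
  expect_equal(p2$diameter[1], 20, tolerance = 1.2)
  expect_equal(p2$diameter[2], 9, tolerance = 1.2)
})

test_that("Monte-Carlo pore volume matches analytic sphere subtraction", {
  box <- empty_box(12)
  av0 <- accessible_pore_volume(box, probe_radius = 1, samples = 2000, seed = 1,
                                accessible = FALSE)
  expect_equal(av0$void_fraction, 1)
  s <- make_cubic_framework(a = 10)
  av <- accessible_pore_volume(s, probe_radius = 0, samples = 40000, seed = 2,
                               accessible = FALSE, radii = c(C = 1.5))
  analytic <- 1 - (4 * pi / 3) * 1.5^3 / 1000
  expect_lt(abs(av$void_fraction - analytic), 3 * av$se + 1e-6)
  # independent fine-grid oracle
  g <- compute_distance_grid(s, spacing = 0.15, radii = c(C = 1.5))
  grid_vf <- mean(g$values >= 0)
  expect_lt(abs(av$void_fraction - grid_vf), 0.01)
})

test_that("isolated cavities are excluded in accessible mode only", {
  # dense block with a buried spherical pocket
  a <- 12
  n <- 8
  gpts <- (seq_len(n) - 1) / n
  pts <- expand.grid(fx = gpts, fy = gpts, fz = gpts)
  ctr <- c(0.5, 0.5, 0.5)
  d2 <- ((pts$fx - ctr[1]) * a)^2 + ((pts$fy - ctr[2]) * a)^2 +
    ((pts$fz - ctr[3]) * a)^2
  pocket <- periodic_structure(unit_cell(a, a, a),
                               data.frame(element = "C",
                                          pts[d2 > 4.5^2, , drop = FALSE]),
                               name = "pocket")
  on <- accessible_pore_volume(pocket, probe_radius = 0.5, samples = 8000,
                               seed = 3, accessible = TRUE, grid_spacing = 0.25)
  off <- accessible_pore_volume(pocket, probe_radius = 0.5, samples = 8000,
                                seed = 3, accessible = FALSE)
  expect_equal(on$void_fraction, 0)
  expect_gt(off$void_fraction, 0.01)
})

test_that("porosity filter is inclusive at the boundary", {
  s <- make_cubic_framework(a = 10)
  pd <- pore_descriptors(s, spacing = 0.3, probe_radius = 0, samples = 4000)
  expect_true(porosity_filter(pd, 6))
  expect_false(porosity_filter(pd, 50))
  expect_true(porosity_filter(pd, pd$pld))  # exact equality passes
})
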