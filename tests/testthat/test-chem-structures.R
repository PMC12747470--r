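test_that("unit-cell volume matches the triclinic closed form", {
  expect_equal(unit_cell(10, 10, 10)$volume, 1000)
  a <- 7.1; b <- 9.3; cc <- 11.7; al <- 72; be <- 101; ga <- 88
  cell <- unit_cell(a, b, cc, al, be, ga)
  ca <- cos(al * pi / 180); cb <- cos(be * pi / 180); cg <- cos(ga * pi / 180)
  analytic <- a * b * cc * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  expect_equal(cell$volume, analytic, tolerance = 1e-9)
  expect_equal(cell$volume, det(cell$lattice), tolerance = 1e-12)
  expect_error(unit_cell(-1, 2, 3), "positive")
  expect_error(unit_cell(1, 2, 3, alpha = 181), "angles")
})

test_that("minimum-image distance wraps, is symmetric and bounded by the raw distance", {
  cell <- unit_cell(10, 10, 10)
  expect_equal(min_image_distance(cell, c(0.1, 0, 0), c(0.9, 0, 0)), 2)
  expect_equal(min_image_distance(cell, c(0.3, 0.7, 0.2), c(0.3, 0.7, 0.2)), 0)
  tri <- unit_cell(8, 9, 10, 80, 95, 104)
  set.seed(42)
  shifts <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  for (i in 1:25) {
    p <- runif(3); q <- runif(3)
    d <- min_image_distance(tri, p, q)
    # brute force over 5x5x5 images
    dc <- (matrix(q - p, 125, 3, byrow = TRUE) + shifts) %*% tri$lattice
    brute <- sqrt(min(rowSums(dc^2)))
    expect_equal(d, brute, tolerance = 1e-12)
    expect_equal(min_image_distance(tri, q, p), d, tolerance = 1e-12)
    raw <- sqrt(sum(((q - p) %*% tri$lattice)^2))
    expect_lte(d, raw + 1e-12)
  }
})

test_that("supercell replication reaches the requested width", {
  s <- make_cubic_framework(a = 10)
  expect_equal(nrow(build_supercell(s, 24)$sites), 27)   # ceil(24/10) = 3
  expect_equal(nrow(build_supercell(s, 20)$sites), 8)    # ceil(20/10) = 2
  expect_identical(build_supercell(s, 9)$sites, s$sites) # already wide enough
  sup <- build_supercell(s, 24)
  expect_equal(mass_per_cell(sup), 27 * mass_per_cell(s))
  expect_true(all(cell_perpendicular_widths(sup$cell) >= 24))
})

test_that("CIF parsing expands symmetry and deduplicates images", {
  s1 <- parse_cif(write_cif(make_cubic_framework(a = 10)))
  expect_equal(nrow(s1$sites), 1)  # identity expansion
  s4 <- parse_cif(cif_with_symops())
  expect_equal(nrow(s4$sites), 4)  # 4 distinct images
  # brute-force dedup oracle: all pairwise min-image distances > 0.1
  fr <- as.matrix(s4$sites[, c("fx", "fy", "fz")])
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gt(min_image_distance(s4$cell, fr[i, ], fr[j, ]), 0.1)
  }
  # an operator producing a coincident image is merged
  doc <- sub("'x, -y, -z'", "'x+1, y, z'", cif_with_symops(), fixed = TRUE)
  expect_equal(nrow(parse_cif(doc)$sites), 3)
})

test_that("CIF write -> parse round-trips structures", {
  set.seed(1)
  s <- periodic_structure(
    unit_cell(12.3, 11.1, 9.7),
    data.frame(element = c("Zr", "O", "C", "H"), fx = runif(4), fy = runif(4),
               fz = runif(4)),
    name = "roundtrip"
  )
  s2 <- parse_cif(write_cif(s))
  expect_equal(nrow(s2$sites), nrow(s$sites))
  expect_equal(as.matrix(s2$sites[, c("fx", "fy", "fz")]),
               as.matrix(s$sites[, c("fx", "fy", "fz")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(s2$sites$element, s$sites$element)
  # documents differing by one coordinate differ in exactly that field
  s3 <- s; s3$sites$fx[2] <- s$sites$fx[2] + 1e-3
  d <- setdiff(strsplit(write_cif(s3), "\n")[[1]], strsplit(write_cif(s), "\n")[[1]])
  expect_length(d, 1)
})

test_that("CIF error paths: missing cell, empty sites, disorder, bad element", {
  expect_error(parse_cif("data_x\nloop_\n_atom_site_fract_x\n0.1\n"),
               "cell-parameter")
  expect_error(parse_cif("data_x\n_cell_length_a 10\n_cell_length_b 10\n_cell_length_c 10\n"),
               "empty-structure")
  doc <- sub("C1 C 0.15 0.20 0.25",
             "C1 C 0.15 0.20 0.25 0.5",
             sub("_atom_site_fract_z", "_atom_site_fract_z\n_atom_site_occupancy",
                 cif_with_symops()))
  expect_error(parse_cif(doc), "occupancy")
  expect_error(parse_cif(sub("C1 C", "C1 Qq", cif_with_symops())), "unrecognized")
})

test_that("type-symbol oxidation suffixes are stripped", {
  doc <- sub("C1 C ", "Zr1 Zr4+ ", cif_with_symops())
  expect_identical(unique(parse_cif(doc)$sites$element), "Zr")
})

test_that("bond perception uses covalent radii and periodic images", {
  two_c <- function(d) small_molecule(
    data.frame(element = c("C", "C"), x = c(0, d), y = 0, z = 0))
  expect_equal(nrow(perceive_bonds(two_c(1.50))), 1)  # 1.50 <= 1.52 + 0.45
  expect_equal(nrow(perceive_bonds(two_c(5.0))), 0)
  # across the cell boundary: frac 0.98 and 0.02 in a 10 A cell are 0.4 A apart
  s <- periodic_structure(unit_cell(10, 10, 10),
                          data.frame(element = c("C", "C"),
                                     fx = c(0.98, 0.02), fy = 0, fz = 0))
  b <- perceive_bonds(s)
  expect_equal(nrow(b), 1)
  expect_equal(b$dist, 0.4, tolerance = 1e-9)
  expect_equal(min_image_distance(s$cell, c(0.98, 0, 0), c(0.02, 0, 0)), 0.4)
  # agreement with an all-pairs brute-force check on a random fixture
  set.seed(3)
  fx <- periodic_structure(unit_cell(8, 8, 8),
                           data.frame(element = sample(c("C", "O", "H"), 12, TRUE),
                                      fx = runif(12), fy = runif(12), fz = runif(12)))
  got <- perceive_bonds(fx)
  rc <- covalent_radius(fx$sites$element)
  expected <- 0L
  for (i in 1:11) for (j in (i + 1):12) {
    d <- min_image_distance(fx$cell,
                            unlist(fx$sites[i, c("fx", "fy", "fz")]),
                            unlist(fx$sites[j, c("fx", "fy", "fz")]))
    if (d <= rc[i] + rc[j] + 0.45) expected <- expected + 1L
  }
  expect_equal(nrow(got), expected)
})

test_that("formula masses come out at tabulated values", {
  expect_equal(formula_mass("C9H11F2N3O4"), 263.2, tolerance = 1e-3)
  expect_equal(formula_mass("H2O"), 18.015, tolerance = 1e-3)
  expect_error(formula_mass("C9X11"), "unrecognized")
})
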