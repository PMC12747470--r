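test_that("building blocks of a toy MOF: metals counted, linkers unwrapped and capped", {
  s <- mofscreen:::make_toy_mof("Zr", a = 25)
  bb <- split_building_blocks(s)
  expect_identical(names(bb$metals), "Zr")
  expect_identical(unname(bb$metals), 2L)
  expect_equal(length(bb$linkers), 1)
  expect_equal(nrow(bb$unique_linkers), 1)
  lk <- bb$linkers[[1]]
  # atom conservation before capping
  expect_equal(sum(bb$metals) + attr(lk, "n_atoms_uncapped"), nrow(s$sites))
  # protonation capping restores the carboxylic acids
  expect_equal(mol_formula(lk), "C8H6O4")  # terephthalic acid
  f <- featurize_linker(lk)$values
  expect_equal(unname(f["carboxylic_acid"]), 2)
  expect_false(attr(lk, "polymeric"))
})

test_that("a structure with two identical disconnected linkers deduplicates to one", {
  lnk <- build_linker("benzene")
  a <- 30
  place <- function(offset) {
    data.frame(element = lnk$atoms$element,
               fx = (lnk$atoms$x + offset[1]) / a,
               fy = (lnk$atoms$y + offset[2]) / a,
               fz = (lnk$atoms$z + offset[3]) / a)
  }
  s <- periodic_structure(unit_cell(a, a, a),
                          rbind(data.frame(element = "Zn", fx = 0, fy = 0, fz = 0),
                                place(c(8, 8, 8)), place(c(20, 20, 20))),
                          name = "two_linkers")
  bb <- split_building_blocks(s)
  expect_identical(unname(bb$metals["Zn"]), 1L)
  expect_equal(length(bb$linkers), 2)
  expect_equal(nrow(bb$unique_linkers), 1)
  expect_equal(bb$unique_linkers$multiplicity, 2L)
})

test_that("an all-metal lattice yields metals and zero linkers", {
  s <- make_dense_block(a = 6, element = "Fe")
  bb <- split_building_blocks(s)
  expect_identical(names(bb$metals), "Fe")
  expect_equal(length(bb$linkers), 0)
  expect_equal(nrow(bb$unique_linkers), 0)
})

test_that("deconstruction is invariant to a uniform translation", {
  s <- mofscreen:::make_toy_mof("Zr", a = 25)
  t <- s
  shift <- wrap_frac(as.matrix(t$sites[, c("fx", "fy", "fz")]) + 0.5)
  t$sites$fx <- shift[, 1]; t$sites$fy <- shift[, 2]; t$sites$fz <- shift[, 3]
  b1 <- split_building_blocks(s)
  b2 <- split_building_blocks(t)
  expect_identical(b1$metals, b2$metals)
  expect_identical(b1$unique_linkers$signature, b2$unique_linkers$signature)
  expect_identical(b1$unique_linkers$multiplicity, b2$unique_linkers$multiplicity)
})

test_that("linkers crossing the cell boundary unwrap with periodic bond lengths preserved", {
  # benzene placed so the ring straddles a cell face
  lnk <- build_linker("benzene")
  a <- 12
  s <- periodic_structure(
    unit_cell(a, a, a),
    data.frame(element = lnk$atoms$element,
               fx = (lnk$atoms$x + 0.1) / a,  # ring center near fx = 0
               fy = (lnk$atoms$y + 6) / a, fz = (lnk$atoms$z + 6) / a),
    name = "straddle"
  )
  bb <- split_building_blocks(s)
  expect_equal(length(bb$linkers), 1)
  m <- bb$linkers[[1]]
  expect_equal(n_atoms(m), 12)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  fr <- as.matrix(s$sites[, c("fx", "fy", "fz")])
  for (r in seq_len(nrow(m$bonds))) {
    dcart <- sqrt(sum((xyz[m$bonds$i[r], ] - xyz[m$bonds$j[r], ])^2))
    dper <- min_image_distance(s$cell, fr[m$bonds$i[r], ], fr[m$bonds$j[r], ])
    expect_equal(dcart, dper, tolerance = 1e-6)
  }
})

test_that("an infinite rod component is flagged polymeric", {
  # a continuous carbon chain along x wraps the cell
  a <- 10
  n <- 8
  s <- periodic_structure(unit_cell(a, a, a),
                          data.frame(element = "C", fx = (0:(n - 1)) / n,
                                     fy = 0.5, fz = 0.5),
                          name = "rod")
  expect_warning(bb <- split_building_blocks(s), "polymeric")
  expect_true(attr(bb$linkers[[1]], "polymeric"))
})

test_that("canonical signatures are ordering-invariant and discriminate isomers", {
  m <- build_linker("benzene", c("carboxyl", "hydroxyl"))
  sig <- canonical_signature(m)
  set.seed(5)
  for (k in 1:60) {
    perm <- sample(n_atoms(m))
    expect_identical(canonical_signature(permute_molecule(m, perm)), sig)
  }
  expect_false(canonical_signature(build_linker("benzene")) ==
               canonical_signature(build_linker("pyridine")))
  expect_false(canonical_signature(build_linker("benzene", "hydroxyl")) ==
               canonical_signature(build_linker("benzene", "amine")))
  # disconnected input is rejected
  disc <- small_molecule(data.frame(element = c("C", "C"), x = c(0, 9), y = 0, z = 0))
  expect_error(canonical_signature(disc), "connected")
})
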