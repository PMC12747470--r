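test_that("GHS bins honor the inclusive-upper-bound convention and are monotone", {
  expect_identical(as.character(ld50_to_ghs_category(3)), "Cat1")
  expect_identical(as.character(ld50_to_ghs_category(5)), "Cat1")
  expect_identical(as.character(ld50_to_ghs_category(300)), "Cat3")
  expect_identical(as.character(ld50_to_ghs_category(2000)), "Cat4")
  expect_identical(as.character(ld50_to_ghs_category(8300)), "NotClassified")
  x <- sort(c(10^seq(-1, 4.5, length.out = 60), 5, 50, 300, 2000, 5000))
  codes <- as.integer(ld50_to_ghs_category(x))
  expect_true(all(diff(codes) >= 0))  # raising LD50 never lowers the category
  expect_error(ld50_to_ghs_category(0), "positive")
})

test_that("three-class scheme: 8300 is safe, boundaries go to the more toxic class", {
  expect_identical(as.character(ld50_to_custom_category(8300)), "safe")
  expect_identical(as.character(ld50_to_custom_category(10)), "fatal")
  expect_identical(as.character(ld50_to_custom_category(50)), "fatal")    # t_fatal inclusive
  expect_identical(as.character(ld50_to_custom_category(2000)), "toxic")  # t_safe inclusive
  x <- 10^seq(0, 4.5, length.out = 80)
  codes <- as.integer(ld50_to_custom_category(x))
  expect_true(all(diff(codes) >= 0))
  expect_error(ld50_to_custom_category(-5), "positive")
})

test_that("Gasteiger charges: symmetry, neutrality and electronegativity ordering", {
  h2 <- assign_partial_charges(small_molecule(
    data.frame(element = c("H", "H"), x = c(0, 0.74), y = 0, z = 0),
    data.frame(i = 1, j = 2)))
  expect_equal(h2$atoms$charge, c(0, 0))
  ch4 <- small_molecule(
    data.frame(element = c("C", "H", "H", "H", "H"),
               x = c(0, 1.09, -1.09, 0, 0), y = c(0, 0, 0, 1.09, -1.09),
               z = 0),
    data.frame(i = 1, j = 2:5))
  ch4 <- assign_partial_charges(ch4)
  expect_equal(sum(ch4$atoms$charge), 0, tolerance = 1e-9)
  expect_equal(diff(range(ch4$atoms$charge[2:5])), 0, tolerance = 1e-12)
  expect_gt(ch4$atoms$charge[2], 0)  # H positive relative to C
  hf <- assign_partial_charges(small_molecule(
    data.frame(element = c("H", "F"), x = c(0, 0.92), y = 0, z = 0),
    data.frame(i = 1, j = 2)))
  expect_gt(hf$atoms$charge[1], 0)
  expect_lt(hf$atoms$charge[2], 0)
  # charged species: total equals the net formal charge
  oh <- assign_partial_charges(small_molecule(
    data.frame(element = c("O", "H"), x = c(0, 0.96), y = 0, z = 0),
    data.frame(i = 1, j = 2), net_charge = -1L))
  expect_equal(sum(oh$atoms$charge), -1, tolerance = 1e-6)
})

test_that("featurization counts substructures and is ordering-invariant", {
  benz <- featurize_linker(build_linker("benzene"))$values
  expect_equal(unname(benz["benzene_ring"]), 1)
  expect_equal(unname(benz["nitro"]), 0)
  expect_equal(unname(benz["charge_mean"]), 0, tolerance = 1e-9)
  nb <- featurize_linker(build_linker("benzene", "nitro"))$values
  expect_equal(unname(nb["nitro"]), 1)
  expect_equal(unname(nb["ring_nitro"]), 1)
  m <- build_linker("pyridine", c("amine", "chloro"))
  v <- featurize_linker(m)$values
  set.seed(8)
  v2 <- featurize_linker(permute_molecule(m, sample(n_atoms(m))))$values
  expect_equal(v2, v, tolerance = 1e-12)
  # methane: no fragments beyond CH patterns, geometry ~ 2 projected C-H bonds
  ch4 <- small_molecule(
    data.frame(element = c("C", "H", "H", "H", "H"),
               x = c(0, 1.09, -1.09, 0, 0), y = c(0, 0, 0, 1.09, -1.09), z = 0),
    data.frame(i = 1, j = 2:5))
  g <- featurize_linker(ch4)$values
  expect_equal(unname(g["max_distance"]), 2 * 1.09, tolerance = 1e-9)
  expect_equal(unname(g["benzene_ring"]), 0)
  expect_equal(unname(g["cycle_rank"]), 0)
  # feature vector has the documented fixed length (>= 40 fragment patterns)
  expect_gte(length(mofscreen:::pattern_names()), 40)
  expect_identical(names(v), mofscreen:::feature_names())
})

test_that("classifier learns a deterministic single-fragment rule almost perfectly", {
  set.seed(21)
  mols <- list()
  lab <- character()
  for (i in 1:240) {
    kind <- sample(c("fatal", "toxic", "safe"), 1)
    d <- switch(kind, fatal = "nitro", toxic = "amine", safe = "hydroxyl")
    extra <- sample(c("methyl", "chloro", ""), 1)
    mols[[i]] <- build_linker(sample(c("benzene", "pyridine"), 1),
                              c(d, if (nzchar(extra)) extra))
    lab <- c(lab, kind)
  }
  ds <- list(molecules = mols,
             label = factor(lab, levels = c("fatal", "toxic", "safe")))
  mod <- train_toxicity_classifier(ds, seed = 2, num_trees = 200)
  expect_gte(mod$report$accuracy, 0.95)
})

test_that("permuted labels collapse accuracy to the majority-class rate", {
  ds <- fixture_dataset()
  set.seed(33)
  shuffled <- list(molecules = ds$molecules, label = sample(ds$label))
  mod <- train_toxicity_classifier(shuffled, seed = 3, num_trees = 200)
  maj <- max(prop.table(table(shuffled$label)))
  expect_lt(abs(mod$report$accuracy - maj), 0.05)
})

test_that("held-out accuracy tracks the planted Bayes accuracy", {
  ds <- fixture_dataset()
  mod <- fixture_model()
  B <- ds$bayes$accuracy_realized
  expect_gte(mod$report$accuracy, B - 0.07)
  expect_lte(mod$report$accuracy, B + 0.02)  # finite-sample allowance
})

test_that("prediction contract: probabilities sum to one, planted toxicophore is fatal", {
  mod <- fixture_model()
  pr <- predict_toxicity(mod, build_linker("benzene", "nitro"))
  expect_equal(sum(pr$probabilities), 1, tolerance = 1e-9)
  expect_identical(as.character(pr$category), "fatal")
  expect_gt(pr$probabilities[1, "fatal"], 0.5)
  # an overfit model memorizes its training records
  ds <- fixture_dataset()
  over <- train_toxicity_classifier(ds, split = 0.95, seed = 4, num_trees = 400)
  idx <- c(2, 11, 53)
  for (i in idx) {
    pr_i <- predict_toxicity(over, ds$molecules[[i]])
    # only check records whose label matches the planted expectation (noise
    # flips near bin edges are genuine)
    if (ds$bayes$prediction[i] == ds$label[i]) {
      expect_identical(as.character(pr_i$category), as.character(ds$label[i]))
    }
  }
})

test_that("models serialize and reload with identical predictions", {
  mod <- fixture_model()
  path <- tempfile(fileext = ".rds")
  save_toxicity_model(mod, path)
  mod2 <- load_toxicity_model(path)
  probe <- build_linker("pyridine", "amine")
  expect_identical(predict_toxicity(mod, probe)$probabilities,
                   predict_toxicity(mod2, probe)$probabilities)
})

test_that("MOF biocompatibility verdict is conjunctive, whitelisting is explicit", {
  mod <- fixture_model()
  tab <- load_metal_table()
  expect_identical(tab["Zr", "verdict"], "biocompatible")
  expect_identical(tab["Cd", "verdict"], "not_biocompatible")
  expect_identical(tab["Ni", "verdict"], "not_biocompatible")

  zr <- split_building_blocks(mofscreen:::make_toy_mof("Zr", a = 25))
  out <- assess_mof_biocompatibility(zr, mod, tab)
  expect_identical(out$verdict, "highly biocompatible")

  cd <- split_building_blocks(mofscreen:::make_toy_mof("Cd", a = 25))
  out_cd <- assess_mof_biocompatibility(cd, mod, tab)
  expect_identical(out_cd$verdict, "rejected")
  expect_match(paste(out_cd$failures, collapse = " "), "Cd")

  zn <- split_building_blocks(mofscreen:::make_toy_mof("Zn", a = 25))
  expect_identical(assess_mof_biocompatibility(zn, mod, tab)$verdict, "rejected")
  wl <- assess_mof_biocompatibility(zn, mod, tab, whitelist = "Zn")
  expect_identical(wl$verdict, "highly biocompatible")
  expect_true(wl$whitelisted)

  # unknown metal errors instead of silently passing
  missing_tab <- tab[tab$element != "Zr", ]
  expect_error(assess_mof_biocompatibility(zr, mod, missing_tab), "absent")
})

test_that("verdict is monotone: degrading one linker never rescues a rejection", {
  mod <- fixture_model()
  cd <- split_building_blocks(mofscreen:::make_toy_mof("Cd", a = 25))
  base <- assess_mof_biocompatibility(cd, mod)
  expect_identical(base$verdict, "rejected")
  # swap the safe linker for a predicted-fatal one; still rejected
  worse <- cd
  bad <- build_linker("benzene", "nitro")
  attr(bad, "n_atoms_uncapped") <- n_atoms(bad)
  attr(bad, "polymeric") <- FALSE
  attr(bad, "likely_solvent") <- FALSE
  worse$linkers[[1]] <- bad
  out <- assess_mof_biocompatibility(worse, mod)
  expect_identical(out$verdict, "rejected")
  expect_gte(length(out$failures), length(base$failures))
})
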