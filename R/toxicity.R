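# LD50 category schemes, the three-class linker toxicity classifier, and
# the per-MOF biocompatibility verdict.

.toxicity_levels <- c("fatal", "toxic", "safe")

#' GHS acute-oral-toxicity category from LD50
#'
#' UN Globally Harmonized System bins (oral route, upper bounds inclusive):
#' (0,5] Cat1, (5,50] Cat2, (50,300] Cat3, (300,2000] Cat4, (2000,5000]
#' Cat5, above 5000 NotClassified.
#'
#' @param ld50 Oral-rat LD50 in mg/kg; must be positive. Vectorized.
#' @return Factor with levels Cat1..Cat5, NotClassified.
#' @examples
#' ld50_to_ghs_category(c(3, 300, 8300))
#' @export
ld50_to_ghs_category <- function(ld50) {
  if (any(!is.finite(ld50)) || any(ld50 <= 0)) {
    stop("LD50 must be positive", call. = FALSE)
  }
  lev <- c("Cat1", "Cat2", "Cat3", "Cat4", "Cat5", "NotClassified")
  idx <- findInterval(ld50, c(5, 50, 300, 2000, 5000), left.open = FALSE) + 1L
  # findInterval with these breakpoints puts ld50 == 5 into Cat2; shift
  # boundary values down to honor the inclusive-upper-bound convention
  on_edge <- ld50 %in% c(5, 50, 300, 2000, 5000)
  idx[on_edge] <- idx[on_edge] - 1L
  factor(lev[idx], levels = lev)
}

#' Three-class toxicity category from LD50
#'
#' The screening scheme groups the GHS bins into three classes:
#' `fatal` (LD50 <= `t_fatal`), `toxic` (`t_fatal` < LD50 <= `t_safe`),
#' `safe` (LD50 > `t_safe`). Defaults `t_fatal` = 50 and `t_safe` = 2000
#' mg/kg group GHS Cat 1-2 / 3-4 / 5-and-above; boundaries are inclusive
#' on the more toxic side.
#'
#' @param ld50 Oral-rat LD50 in mg/kg, positive. Vectorized.
#' @param t_fatal,t_safe Class thresholds in mg/kg, `t_fatal < t_safe`.
#' @return Factor with ordered levels fatal < toxic < safe.
#' @examples
#' ld50_to_custom_category(c(10, 500, 8300))  # fatal, toxic, safe
#' @export
ld50_to_custom_category <- function(ld50, t_fatal = 50, t_safe = 2000) {
  if (any(!is.finite(ld50)) || any(ld50 <= 0)) {
    stop("LD50 must be positive", call. = FALSE)
  }
  stopifnot(t_fatal < t_safe)
  out <- ifelse(ld50 <= t_fatal, "fatal", ifelse(ld50 <= t_safe, "toxic", "safe"))
  factor(out, levels = .toxicity_levels, ordered = TRUE)
}

#' Load the packaged (or a user) metal-toxicity table
#'
#' @param path CSV with columns `element`, `verdict`
#'   (`biocompatible`/`not_biocompatible`), `note` and optionally
#'   `ld50_salt_mg_per_kg`; defaults to the curated table shipped with the
#'   package.
#' @return Data frame keyed by element.
#' @export
load_metal_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "metal_toxicity.csv", package = "mofscreen")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "verdict") %in% names(tab)))
  if (anyDuplicated(tab$element)) stop("duplicate element in metal table", call. = FALSE)
  rownames(tab) <- tab$element
  tab
}

#' Train the three-class linker toxicity classifier
#'
#' Featurizes the molecules (see [featurize_linker()]), makes a stratified
#' train/validation split, and fits a random-forest probability ensemble.
#' The held-out report carries accuracy, per-class precision/recall and the
#' confusion matrix.
#'
#' @param dataset A `toxicity_dataset` (see [make_toxicity_dataset()]) or a
#'   list with `molecules` (list of [small_molecule()]) and `ld50`
#'   (mg/kg) or `label` (factor fatal/toxic/safe).
#' @param split Fraction of records used for training (default 0.8).
#' @param seed RNG seed controlling the split and the forest.
#' @param num_trees Trees in the ensemble.
#' @param t_fatal,t_safe Category thresholds applied when only LD50 is given.
#' @return An object of class `toxicity_model`: the fitted forest, feature
#'   version, training metadata, and the held-out `report`.
#' @export
train_toxicity_classifier <- function(dataset, split = 0.8, seed = 1L,
                                      num_trees = 500L,
                                      t_fatal = 50, t_safe = 2000) {
  mols <- dataset$molecules
  if (length(mols) < 50L) stop("need at least 50 records", call. = FALSE)
  label <- dataset$label
  if (is.null(label)) label <- ld50_to_custom_category(dataset$ld50, t_fatal, t_safe)
  label <- factor(as.character(label), levels = .toxicity_levels)
  if (nlevels(droplevels(label)) < 3L) {
    stop("degenerate labels: need all three classes present", call. = FALSE)
  }
  X <- featurize_matrix(mols)
  set.seed(seed)
  idx_train <- unlist(lapply(split(seq_along(label), label), function(ix) {
    sample(ix, size = floor(split * length(ix)))
  }), use.names = FALSE)
  idx_val <- setdiff(seq_along(label), idx_train)
  df_train <- data.frame(X[idx_train, , drop = FALSE], .label = label[idx_train])
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df_train,
    num.trees = num_trees, probability = TRUE, seed = seed,
    num.threads = 1L, respect.unordered.factors = "order"
  )
  model <- structure(
    list(forest = fit, feature_version = .pattern_version,
         levels = .toxicity_levels,
         meta = list(seed = seed, split = split, n = length(label),
                     t_fatal = t_fatal, t_safe = t_safe,
                     num_trees = num_trees)),
    class = "toxicity_model"
  )
  # held-out report
  probs <- predict(fit, data = data.frame(X[idx_val, , drop = FALSE]))$predictions
  pred <- classify_probs(probs, .toxicity_levels)
  truth <- label[idx_val]
  cm <- table(truth = truth, predicted = pred)
  acc <- mean(as.character(pred) == as.character(truth))
  per_class <- do.call(rbind, lapply(.toxicity_levels, function(k) {
    tp <- cm[k, k]
    data.frame(class = k,
               precision = tp / max(sum(cm[, k]), 1),
               recall = tp / max(sum(cm[k, ]), 1))
  }))
  model$report <- list(accuracy = acc, confusion = cm, per_class = per_class,
                       n_validation = length(idx_val))
  model
}

#' @export
print.toxicity_model <- function(x, ...) {
  cat(sprintf("toxicity_model (%s): %d trees, trained on %d records\n",
              x$feature_version, x$meta$num_trees, x$meta$n))
  cat(sprintf("  held-out accuracy: %.3f (n = %d)\n",
              x$report$accuracy, x$report$n_validation))
  invisible(x)
}

# argmax with ties broken toward the more toxic class (levels are ordered
# fatal < toxic < safe, so the first max index is the conservative pick)
classify_probs <- function(probs, levels) {
  probs <- probs[, levels, drop = FALSE]
  idx <- apply(probs, 1, function(p) which(p >= max(p) - 1e-12)[1])
  factor(levels[idx], levels = levels, ordered = TRUE)
}

#' Predict the toxicity category of a molecule
#'
#' @param model A [train_toxicity_classifier()] model.
#' @param mol A [small_molecule()], a `linker_features` object, or a
#'   feature matrix.
#' @return List with `category` (ordered factor, ties broken toward the
#'   more toxic class) and `probabilities` (row-stochastic matrix).
#' @export
predict_toxicity <- function(model, mol) {
  stopifnot(inherits(model, "toxicity_model"))
  X <- if (inherits(mol, "small_molecule")) {
    rbind(featurize_linker(mol)$values)
  } else if (inherits(mol, "linker_features")) {
    if (!identical(mol$version, model$feature_version)) {
      stop("feature-version mismatch: model ", model$feature_version,
           " vs features ", mol$version, call. = FALSE)
    }
    rbind(mol$values)
  } else as.matrix(mol)
  colnames(X) <- feature_names()
  probs <- predict(model$forest, data = data.frame(X))$predictions
  probs <- probs[, model$levels, drop = FALSE]
  list(category = classify_probs(probs, model$levels), probabilities = probs)
}

#' Save / load a trained toxicity model
#'
#' Serialization is bit-faithful: a reloaded model gives identical
#' predictions.
#'
#' @param model A `toxicity_model`.
#' @param path File path.
#' @return `load_toxicity_model` returns the model.
#' @export
save_toxicity_model <- function(model, path) {
  stopifnot(inherits(model, "toxicity_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_toxicity_model
#' @export
load_toxicity_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "toxicity_model"))
  m
}

#' Assess the biocompatibility of a MOF from its building blocks
#'
#' A framework is "highly biocompatible" iff every metal element is
#' `biocompatible` in the metal table AND every unique, classifiable linker
#' is predicted `safe`. Metals on the `whitelist` are admitted with a
#' `whitelisted` flag even when the table marks them otherwise (the route
#' by which well-tolerated Fe- and Zn-based carriers re-enter screening on
#' in-vivo evidence). Polymeric linkers cannot be classified and are
#' reported but do not veto. A metal missing from the table is an error,
#' never a silent pass.
#'
#' @param blocks A [split_building_blocks()] result.
#' @param model A trained `toxicity_model`.
#' @param metal_table From [load_metal_table()].
#' @param whitelist Character vector of metal symbols to admit regardless of
#'   table verdict.
#' @return List with `verdict` (`"highly biocompatible"` / `"rejected"`),
#'   `whitelisted` (logical), `metal_report`, `linker_report`, and
#'   `failures` (character description of every failing block).
#' @export
assess_mof_biocompatibility <- function(blocks, model,
                                        metal_table = load_metal_table(),
                                        whitelist = character()) {
  stopifnot(inherits(blocks, "building_blocks"))
  failures <- character()
  whitelisted <- FALSE

  metal_report <- NULL
  if (length(blocks$metals)) {
    els <- names(blocks$metals)
    unknown <- setdiff(els, metal_table$element)
    if (length(unknown)) {
      stop("metal(s) absent from toxicity table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    verdicts <- metal_table[els, "verdict"]
    wl <- els %in% whitelist
    ok <- verdicts == "biocompatible" | wl
    whitelisted <- any(wl & verdicts != "biocompatible")
    metal_report <- data.frame(element = els, count = as.integer(blocks$metals),
                               verdict = verdicts, whitelisted = wl,
                               pass = ok, stringsAsFactors = FALSE)
    failures <- c(failures,
                  sprintf("metal %s is %s", els[!ok], verdicts[!ok]))
  }

  linker_report <- NULL
  if (nrow(blocks$unique_linkers)) {
    rows <- lapply(seq_len(nrow(blocks$unique_linkers)), function(r) {
      mol <- blocks$linkers[[blocks$unique_linkers$index[r]]]
      if (isTRUE(attr(mol, "polymeric"))) {
        return(data.frame(linker = mol$name, formula = mol_formula(mol),
                          category = NA_character_, p_safe = NA_real_,
                          polymeric = TRUE, likely_solvent = FALSE,
                          multiplicity = blocks$unique_linkers$multiplicity[r],
                          pass = NA, stringsAsFactors = FALSE))
      }
      pr <- predict_toxicity(model, mol)
      data.frame(linker = mol$name, formula = mol_formula(mol),
                 category = as.character(pr$category),
                 p_safe = pr$probabilities[1, "safe"],
                 polymeric = FALSE,
                 likely_solvent = isTRUE(attr(mol, "likely_solvent")),
                 multiplicity = blocks$unique_linkers$multiplicity[r],
                 pass = pr$category == "safe", stringsAsFactors = FALSE)
    })
    linker_report <- do.call(rbind, rows)
    bad <- which(!is.na(linker_report$pass) & !linker_report$pass)
    failures <- c(failures,
                  sprintf("linker %s predicted %s",
                          linker_report$formula[bad], linker_report$category[bad]))
  }

  verdict <- if (length(failures)) "rejected" else "highly biocompatible"
  list(verdict = verdict, whitelisted = whitelisted,
       metal_report = metal_report, linker_report = linker_report,
       failures = failures)
}
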