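# Synthetic acute-oral-toxicity datasets with planted structure-activity
# rules. Molecules are assembled from a small fragment grammar (benzene /
# pyridine scaffolds with common decorations); each fragment carries a
# multiplicative LD50 effect, so expected log10-LD50 is an exact function
# of composition. Labels derive from the realized (noisy) LD50 through the
# three-class scheme, which makes the Bayes-optimal rule computable in
# closed form and its accuracy reportable alongside the data.

.scaffold_mu <- c(benzene = 3.5, pyridine = 3.1)       # log10 mg/kg
.decoration_mu <- c(nitro = -2.3, amine = -0.7, chloro = -0.3, fluoro = -0.2,
                    hydroxyl = 0.4, carboxyl = 0.3, methyl = 0.1)

#' Build a linker molecule from the fragment grammar
#'
#' Deterministic constructor used by the synthetic toxicity generator and
#' handy for worked examples (e.g. `build_linker("benzene",
#' c("carboxyl", "carboxyl", "carboxyl"))` is a trimesic-acid-like linker).
#'
#' @param scaffold `"benzene"` or `"pyridine"`.
#' @param decorations Character vector (possibly empty, max 5) drawn from
#'   `names(mofscreen:::.decoration_mu)`; placed at ring positions 2, 4, 6,
#'   3, 5 in that order.
#' @return A [small_molecule()] with 3D coordinates and Kekule bond orders.
#' @export
build_linker <- function(scaffold = c("benzene", "pyridine"),
                         decorations = character()) {
  scaffold <- match.arg(scaffold)
  stopifnot(length(decorations) <= 5,
            all(decorations %in% names(.decoration_mu)))
  rr <- 1.39
  ang <- (0:5) * pi / 3
  atoms <- data.frame(element = rep("C", 6),
                      x = rr * cos(ang), y = rr * sin(ang), z = 0,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1))
  if (scaffold == "pyridine") atoms$element[1] <- "N"
  # ring positions available for decoration/H (position 1 stays bare N for
  # pyridine)
  slots <- c(2L, 4L, 6L, 3L, 5L)
  used <- slots[seq_along(decorations)]
  add_atom <- function(el, pos) {
    atoms <<- rbind(atoms, data.frame(element = el, x = pos[1], y = pos[2],
                                      z = pos[3], stringsAsFactors = FALSE))
    nrow(atoms)
  }
  add_bond <- function(i, j, o = 1) {
    bonds <<- rbind(bonds, data.frame(i = i, j = j, order = o))
  }
  for (d in seq_along(decorations)) {
    p <- used[d]
    u <- c(cos(ang[p]), sin(ang[p]), 0)  # outward radial unit vector
    v <- c(-sin(ang[p]), cos(ang[p]), 0) # in-plane tangent
    base <- c(atoms$x[p], atoms$y[p], atoms$z[p])
    dec <- decorations[d]
    if (dec == "methyl") {
      c1 <- add_atom("C", base + 1.50 * u)
      add_bond(p, c1)
      for (s in 0:2) {
        dir <- 0.36 * u + 0.85 * (cos(2 * pi * s / 3) * v +
                                  sin(2 * pi * s / 3) * c(0, 0, 1))
        add_bond(c1, add_atom("H", base + 1.50 * u + 1.09 * dir / sqrt(sum(dir^2))))
      }
    } else if (dec == "hydroxyl") {
      o1 <- add_atom("O", base + 1.36 * u)
      add_bond(p, o1)
      add_bond(o1, add_atom("H", base + 1.36 * u + 0.96 * (0.5 * u + 0.87 * v)))
    } else if (dec == "amine") {
      n1 <- add_atom("N", base + 1.40 * u)
      add_bond(p, n1)
      add_bond(n1, add_atom("H", base + 1.40 * u + 1.01 * (0.5 * u + 0.87 * v)))
      add_bond(n1, add_atom("H", base + 1.40 * u + 1.01 * (0.5 * u - 0.87 * v)))
    } else if (dec == "nitro") {
      n1 <- add_atom("N", base + 1.47 * u)
      add_bond(p, n1)
      add_bond(n1, add_atom("O", base + 1.47 * u + 1.22 * (0.5 * u + 0.87 * v)), 2)
      add_bond(n1, add_atom("O", base + 1.47 * u + 1.22 * (0.5 * u - 0.87 * v)), 1)
    } else if (dec == "carboxyl") {
      c1 <- add_atom("C", base + 1.48 * u)
      add_bond(p, c1)
      add_bond(c1, add_atom("O", base + 1.48 * u + 1.21 * (0.5 * u + 0.87 * v)), 2)
      o2 <- add_atom("O", base + 1.48 * u + 1.34 * (0.5 * u - 0.87 * v))
      add_bond(c1, o2)
      add_bond(o2, add_atom("H", base + 1.48 * u + 1.34 * (0.5 * u - 0.87 * v) +
                              0.96 * u))
    } else if (dec == "chloro") {
      add_bond(p, add_atom("Cl", base + 1.74 * u))
    } else if (dec == "fluoro") {
      add_bond(p, add_atom("F", base + 1.35 * u))
    }
  }
  # hydrogens on remaining ring carbons
  for (p in setdiff(if (scaffold == "pyridine") 2:6 else 1:6, used)) {
    u <- c(cos(ang[p]), sin(ang[p]), 0)
    add_bond(p, add_atom("H", c(atoms$x[p], atoms$y[p], 0) + 1.08 * u))
  }
  small_molecule(atoms, bonds, net_charge = 0L,
                 name = paste0(scaffold,
                               if (length(decorations)) paste0("_", paste(decorations, collapse = "-"))
                               else ""))
}

# expected log10 LD50 of a grammar molecule
planted_mu <- function(scaffold, decorations) {
  unname(.scaffold_mu[scaffold] + sum(.decoration_mu[decorations]))
}

# class-conditional assembly menus: each row is one combo with a sampling
# weight; expected log10 LD50 sits well inside the class bin
.class_menu <- list(
  fatal = list(
    list(w = 0.15, s = "benzene", d = "nitro"),
    list(w = 0.20, s = "benzene", d = c("nitro", "amine")),
    list(w = 0.15, s = "benzene", d = c("nitro", "chloro")),
    list(w = 0.15, s = "pyridine", d = "nitro"),
    list(w = 0.20, s = "pyridine", d = c("nitro", "amine")),
    list(w = 0.15, s = "pyridine", d = c("nitro", "chloro"))
  ),
  toxic = list(
    list(w = 0.30, s = "benzene", d = "amine"),
    list(w = 0.20, s = "pyridine", d = "amine"),
    list(w = 0.15, s = "benzene", d = c("amine", "chloro")),
    list(w = 0.20, s = "pyridine", d = "chloro"),
    list(w = 0.15, s = "pyridine", d = c("chloro", "chloro"))
  ),
  safe = list(
    list(w = 0.30, s = "benzene", d = "hydroxyl"),
    list(w = 0.20, s = "benzene", d = c("hydroxyl", "carboxyl")),
    list(w = 0.20, s = "benzene", d = c("hydroxyl", "methyl")),
    list(w = 0.15, s = "benzene", d = c("hydroxyl", "hydroxyl")),
    list(w = 0.15, s = "benzene", d = c("carboxyl", "carboxyl"))
  )
)

#' Generate a synthetic toxicity dataset with planted rules
#'
#' Draws a target class from `priors`, assembles a molecule from the
#' class-conditional grammar menu, computes its planted expected log10-LD50
#' from the fragment effects, adds Gaussian noise of width `sigma` (log10
#' units), and labels the record from the realized LD50 through
#' [ld50_to_custom_category()]. Because expected LD50 is an exact function
#' of composition, the Bayes-optimal rule and its accuracy on the realized
#' sample are returned with the data.
#'
#' @param n Number of records.
#' @param priors Named class probabilities (fatal, toxic, safe), summing
#'   to 1.
#' @param sigma Log10-LD50 noise standard deviation (default 0.35).
#' @param seed RNG seed; the dataset is a pure function of the arguments.
#' @param t_fatal,t_safe Label thresholds in mg/kg.
#' @return Object of class `toxicity_dataset`: `molecules`, `ld50`
#'   (mg/kg), `label`, `mu` (planted log10 means), `bayes` (list with
#'   `prediction`, `accuracy_realized`, `accuracy_expected`), `provenance`.
#' @export
make_toxicity_dataset <- function(n = 2000L,
                                  priors = c(fatal = 0.25, toxic = 0.35, safe = 0.40),
                                  sigma = 0.35, seed = 7L,
                                  t_fatal = 50, t_safe = 2000) {
  stopifnot(n >= 1, sigma > 0)
  if (abs(sum(priors) - 1) > 1e-9) stop("priors must sum to 1", call. = FALSE)
  if (!all(.toxicity_levels %in% names(priors))) {
    stop("priors must be named fatal/toxic/safe", call. = FALSE)
  }
  set.seed(seed)
  cls <- sample(.toxicity_levels, n, replace = TRUE,
                prob = priors[.toxicity_levels])
  molecules <- vector("list", n)
  mu <- numeric(n)
  combo_key <- character(n)
  for (i in seq_len(n)) {
    menu <- .class_menu[[cls[i]]]
    wts <- vapply(menu, `[[`, numeric(1), "w")
    pick <- menu[[sample.int(length(menu), 1, prob = wts)]]
    molecules[[i]] <- build_linker(pick$s, pick$d)
    mu[i] <- planted_mu(pick$s, pick$d)
    combo_key[i] <- paste(pick$s, paste(pick$d, collapse = "+"))
  }
  ld50 <- 10^(mu + stats::rnorm(n, 0, sigma))
  label <- ld50_to_custom_category(ld50, t_fatal, t_safe)
  # Bayes-optimal rule: argmax of class probability given the planted mean
  b1 <- log10(t_fatal); b2 <- log10(t_safe)
  p_fatal <- stats::pnorm((b1 - mu) / sigma)
  p_toxic <- stats::pnorm((b2 - mu) / sigma) - p_fatal
  p_safe <- 1 - p_fatal - p_toxic
  P <- cbind(fatal = p_fatal, toxic = p_toxic, safe = p_safe)
  bayes_pred <- factor(.toxicity_levels[max.col(P, ties.method = "first")],
                       levels = .toxicity_levels, ordered = TRUE)
  structure(
    list(molecules = molecules, ld50 = ld50, label = label, mu = mu,
         combo = combo_key, drawn_class = cls,
         bayes = list(prediction = bayes_pred,
                      accuracy_realized = mean(bayes_pred == label),
                      accuracy_expected = mean(apply(P, 1, max))),
         provenance = list(kind = "synthetic", n = n, priors = priors,
                           sigma = sigma, seed = seed,
                           t_fatal = t_fatal, t_safe = t_safe)),
    class = "toxicity_dataset"
  )
}

#' @export
print.toxicity_dataset <- function(x, ...) {
  cat(sprintf("toxicity_dataset (%s): %d records, Bayes accuracy %.3f (realized)\n",
              x$provenance$kind, length(x$ld50), x$bayes$accuracy_realized))
  print(table(x$label))
  invisible(x)
}
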