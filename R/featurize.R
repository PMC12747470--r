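# Linker featurization: substructure-pattern counts, partial-charge
# statistics, and size/shape descriptors. Deterministic and invariant to
# atom ordering; this is the feature contract of the toxicity classifier.

#' Featurize an organic linker
#'
#' Computes the fixed-length feature vector used by the toxicity
#' classifier: counts of the packaged substructure patterns (see
#' `pattern_names()`), partial-charge statistics (min/max/mean/sd, from
#' Gasteiger-Marsili charges assigned on the fly), and geometry statistics
#' (heavy-atom count, longest intramolecular distance, radius of gyration,
#' graph cycle rank). If the molecule carries no 3D coordinates (all atoms
#' at the origin), a deterministic distance-geometry fallback embeds the
#' bond graph by classical multidimensional scaling of graph distances
#' scaled to 1.5 Angstrom per bond.
#'
#' @param mol A connected [small_molecule()].
#' @return An object of class `linker_features`: `values` (named numeric
#'   vector, fixed length per featurizer version), `version`.
#' @export
featurize_linker <- function(mol) {
  stopifnot(inherits(mol, "small_molecule"))
  if (!is_connected_mol(mol)) {
    stop("featurize_linker requires a connected molecule", call. = FALSE)
  }
  mol <- assign_partial_charges(mol)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  if (nrow(xyz) > 1 && all(abs(xyz) < 1e-12)) {
    xyz <- embed_by_graph_distance(mol)
  }
  frag <- count_all_patterns(mol)
  q <- mol$atoms$charge
  heavy <- sum(mol$atoms$element != "H")
  if (nrow(xyz) > 1) {
    dmax <- max(stats::dist(xyz))
    ctr <- colMeans(xyz)
    rg <- sqrt(mean(rowSums((xyz - matrix(ctr, nrow(xyz), 3, byrow = TRUE))^2)))
  } else {
    dmax <- 0; rg <- 0
  }
  cyc <- nrow(mol$bonds) - n_atoms(mol) + 1L  # cycle rank (connected graph)
  vals <- c(frag,
            charge_min = min(q), charge_max = max(q),
            # the mean is net charge / n exactly (PEOE conserves charge);
            # computing it that way avoids 1e-17 floating noise that a tree
            # ensemble would otherwise split on
            charge_mean = mol$net_charge / length(q),
            charge_sd = if (length(q) > 1) stats::sd(q) else 0,
            heavy_atoms = heavy, max_distance = dmax,
            radius_gyration = rg, cycle_rank = as.numeric(cyc))
  vals[abs(vals) < 1e-12] <- 0
  structure(list(values = vals, version = .pattern_version),
            class = "linker_features")
}

#' @export
print.linker_features <- function(x, ...) {
  nz <- x$values[x$values != 0]
  cat(sprintf("linker_features (%s): %d features, %d non-zero\n",
              x$version, length(x$values), length(nz)))
  print(utils::head(sort(nz, decreasing = TRUE), 12))
  invisible(x)
}

feature_names <- function() {
  c(pattern_names(), "charge_min", "charge_max", "charge_mean", "charge_sd",
    "heavy_atoms", "max_distance", "radius_gyration", "cycle_rank")
}

embed_by_graph_distance <- function(mol) {
  g <- mol_igraph(mol)
  d <- igraph::distances(g) * 1.5
  xy <- stats::cmdscale(d, k = min(3, n_atoms(mol) - 1))
  out <- matrix(0, n_atoms(mol), 3)
  out[, seq_len(ncol(xy))] <- xy
  out
}

# Featurize a list of molecules into a feature matrix, caching by canonical
# signature (synthetic datasets contain many repeated molecules).
featurize_matrix <- function(mols) {
  cache <- new.env(parent = emptyenv())
  rows <- lapply(mols, function(m) {
    key <- tryCatch(canonical_signature(m), error = function(e) NA_character_)
    if (!is.na(key) && !is.null(cache[[key]])) return(cache[[key]])
    v <- featurize_linker(m)$values
    if (!is.na(key)) cache[[key]] <- v
    v
  })
  X <- do.call(rbind, rows)
  colnames(X) <- feature_names()
  X
}
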