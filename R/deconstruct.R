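# Deconstruction of a MOF into building blocks: metal centers and organic
# linkers. Metals are removed, the remaining periodic bond graph is split
# into connected components, each component is unwrapped across periodic
# boundaries into a finite Cartesian fragment, and dangling metal-binding
# atoms are capped (by default protonated, so carboxylates are read back as
# carboxylic acids - the form toxicity data are reported for).

#' Split a MOF into metal centers and organic linkers
#'
#' @param structure A [periodic_structure()].
#' @param cap Capping scheme for atoms that were bonded to a removed metal:
#'   `"protonate"` (default) adds an H to O/N donor atoms, `"none"` leaves
#'   the open valence.
#' @param tolerance Bond-perception tolerance in Angstrom (see
#'   [perceive_bonds()]).
#' @param solvent_max_atoms Components with at most this many atoms
#'   (before capping) are flagged `likely_solvent` (default 6).
#' @return An object of class `building_blocks`: `metals` (named integer
#'   vector of element counts), `linkers` (list of [small_molecule()], one
#'   per organic component, each with attributes `n_atoms_uncapped`,
#'   `polymeric`, `likely_solvent`), and `unique_linkers` (data frame with
#'   `signature`, `multiplicity`, `index` of a representative in `linkers`).
#'   Polymeric (infinite, rod-like) components are kept but flagged and are
#'   excluded from classification downstream.
#' @examples
#' lib <- make_screening_library(seed = 1)
#' split_building_blocks(lib$structures[[1]])
#' @export
split_building_blocks <- function(structure, cap = c("protonate", "none"),
                                  tolerance = 0.45, solvent_max_atoms = 6L) {
  cap <- match.arg(cap)
  stopifnot(inherits(structure, "periodic_structure"))
  s <- structure$sites
  n <- nrow(s)
  metal <- if (n) is_metal(s$element) else logical()
  metals <- table(s$element[metal])
  metals <- stats::setNames(as.integer(metals), names(metals))

  org_idx <- which(!metal)
  if (!length(org_idx)) {
    return(structure(list(metals = metals, linkers = list(),
                          unique_linkers = empty_unique_linkers()),
                     class = "building_blocks"))
  }

  bonds <- perceive_bonds(structure, tolerance = tolerance)
  # organic-organic bonds define the components; organic-metal bonds mark
  # donor atoms for capping
  is_org <- !metal
  oo <- bonds[is_org[bonds$i] & is_org[bonds$j], , drop = FALSE]
  om <- bonds[xor(is_org[bonds$i], is_org[bonds$j]), , drop = FALSE]
  donor <- integer(0)       # organic atom index
  donor_metal <- integer(0) # its metal partner (for cap direction)
  if (nrow(om)) {
    o_side <- ifelse(is_org[om$i], om$i, om$j)
    m_side <- ifelse(is_org[om$i], om$j, om$i)
    donor <- o_side; donor_metal <- m_side
  }

  # union-find over organic atoms
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(oo)) for (r in seq_len(nrow(oo))) {
    a <- find(oo$i[r]); b <- find(oo$j[r])
    if (a != b) parent[a] <- b
  }
  comp_root <- vapply(org_idx, find, integer(1))
  comp_id <- match(comp_root, unique(comp_root))

  L <- structure$cell$lattice
  fr <- as.matrix(s[, c("fx", "fy", "fz")])
  linkers <- list()
  for (cid in sort(unique(comp_id))) {
    members <- org_idx[comp_id == cid]
    sub <- unwrap_component(members, oo, fr, L)
    atoms <- data.frame(element = s$element[members],
                        x = sub$xyz[, 1], y = sub$xyz[, 2], z = sub$xyz[, 3],
                        stringsAsFactors = FALSE)
    bl <- sub$bonds  # local indices
    n_uncapped <- nrow(atoms)
    # cap former metal-binding donors
    if (cap == "protonate" && length(donor)) {
      here <- which(donor %in% members & s$element[donor] %in% c("O", "N"))
      for (h in here) {
        d_local <- match(donor[h], members)
        m_global <- donor_metal[h]
        # H along the (minimum-image) direction from donor to the removed metal
        dfr <- fr[m_global, ] - fr[donor[h], ]
        dfr <- dfr - round(dfr)
        dir <- as.vector(dfr %*% L)
        nrm <- sqrt(sum(dir^2))
        if (nrm < 1e-8) dir <- c(1, 0, 0) else dir <- dir / nrm
        blen <- if (s$element[donor[h]] == "O") 0.96 else 1.01
        hpos <- sub$xyz[d_local, ] + blen * dir
        atoms <- rbind(atoms, data.frame(element = "H", x = hpos[1],
                                         y = hpos[2], z = hpos[3]))
        bl <- rbind(bl, data.frame(i = d_local, j = nrow(atoms), order = 1))
      }
    }
    mol <- small_molecule(atoms, bl, net_charge = 0L,
                          name = sprintf("%s_linker%d", structure$name, cid))
    mol <- assign_bond_orders_by_length(mol)
    attr(mol, "n_atoms_uncapped") <- n_uncapped
    attr(mol, "polymeric") <- sub$polymeric
    attr(mol, "likely_solvent") <- n_uncapped <= solvent_max_atoms
    if (sub$polymeric) {
      warning(sprintf("component %d of '%s' is polymeric (wraps the cell); excluded from classification",
                      cid, structure$name), call. = FALSE)
    }
    linkers[[length(linkers) + 1L]] <- mol
  }

  sigs <- vapply(linkers, function(m) {
    if (isTRUE(attr(m, "polymeric"))) paste0("polymeric:", mol_formula(m))
    else canonical_signature(m)
  }, character(1))
  uni <- data.frame(signature = unique(sigs), stringsAsFactors = FALSE)
  uni$multiplicity <- vapply(uni$signature, function(sg) sum(sigs == sg), integer(1))
  uni$index <- vapply(uni$signature, function(sg) which(sigs == sg)[1], integer(1))
  rownames(uni) <- NULL

  structure(list(metals = metals, linkers = linkers, unique_linkers = uni),
            class = "building_blocks")
}

empty_unique_linkers <- function() {
  data.frame(signature = character(), multiplicity = integer(),
             index = integer(), stringsAsFactors = FALSE)
}

#' @export
print.building_blocks <- function(x, ...) {
  cat("building_blocks:\n  metals: ",
      if (length(x$metals)) paste(sprintf("%s x%d", names(x$metals), x$metals),
                                  collapse = ", ") else "(none)", "\n", sep = "")
  cat(sprintf("  linkers: %d instance(s), %d unique\n",
              length(x$linkers), nrow(x$unique_linkers)))
  invisible(x)
}

# Unwrap one connected component across periodic boundaries by BFS over its
# bonds, accumulating integer image shifts. Returns Cartesian coordinates of
# a connected finite fragment, its bonds re-indexed locally, and whether the
# component is polymeric (reaches one of its own atoms at two different
# image shifts, i.e. wraps around the cell).
unwrap_component <- function(members, oo_bonds, fr, L) {
  m <- length(members)
  local <- match(seq_len(nrow(fr)), members)  # global -> local or NA
  bl <- oo_bonds[oo_bonds$i %in% members & oo_bonds$j %in% members, , drop = FALSE]
  adj <- vector("list", m)
  if (nrow(bl)) for (r in seq_len(nrow(bl))) {
    li <- local[bl$i[r]]; lj <- local[bl$j[r]]
    sh <- c(bl$sx[r], bl$sy[r], bl$sz[r])
    adj[[li]] <- c(adj[[li]], list(list(to = lj, shift = sh)))
    adj[[lj]] <- c(adj[[lj]], list(list(to = li, shift = -sh)))
  }
  ufrac <- matrix(NA_real_, m, 3)
  ufrac[1, ] <- fr[members[1], ]
  polymeric <- FALSE
  queue <- 1L
  visited <- c(TRUE, rep(FALSE, m - 1L))
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (e in adj[[u]]) {
      v <- e$to
      # fr[v] + shift - fr[u] is the bond displacement in fractional
      # coordinates under the stored image; adding it to the unwrapped
      # position of u extends the fragment consistently.
      cand <- ufrac[u, ] + (fr[members[v], ] + e$shift) - fr[members[u], ]
      if (!visited[v]) {
        ufrac[v, ] <- cand
        visited[v] <- TRUE
        queue <- c(queue, v)
      } else if (max(abs(ufrac[v, ] - cand)) > 1e-6) {
        polymeric <- TRUE
      }
    }
  }
  xyz <- ufrac %*% L
  bonds_local <- if (nrow(bl)) {
    data.frame(i = local[bl$i], j = local[bl$j], order = 1)
  } else data.frame(i = integer(), j = integer(), order = numeric())
  list(xyz = xyz, bonds = bonds_local, polymeric = polymeric)
}

# Assign bond orders from interatomic distances (fragments coming from
# crystal structures carry no order information). Pair-specific thresholds:
# C-C <= 1.45 A (covers aromatic and olefinic), C-O/C-N/N-O <= 1.32 A,
# triple bonds C-C <= 1.23, C-N <= 1.20. Everything else stays single.
assign_bond_orders_by_length <- function(mol) {
  if (!nrow(mol$bonds)) return(mol)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  el <- mol$atoms$element
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    pair <- paste(sort(c(el[i], el[j])), collapse = "-")
    o <- 1
    if (pair == "C-C") { if (d <= 1.23) o <- 3 else if (d <= 1.45) o <- 2 }
    else if (pair == "C-N") { if (d <= 1.20) o <- 3 else if (d <= 1.32) o <- 2 }
    else if (pair %in% c("C-O", "N-O")) { if (d <= 1.32) o <- 2 }
    mol$bonds$order[r] <- o
  }
  mol
}
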