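# Small (non-periodic) molecules: explicit atoms with Cartesian coordinates,
# a bond list with orders, and a net formal charge. This is the
# representation of an organic linker after deconstruction.

#' Construct a small molecule
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` (Angstrom)
#'   and optionally `charge` (partial charge in e, default 0).
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices) and
#'   optionally `order` (default 1). May have zero rows.
#' @param net_charge Integer net charge in e.
#' @param name Identifier.
#' @param notation Optional line-notation string carried as metadata.
#' @return An object of class `small_molecule`.
#' @export
small_molecule <- function(atoms, bonds = NULL, net_charge = 0L,
                           name = "molecule", notation = NULL) {
  stopifnot(is.data.frame(atoms))
  required <- c("element", "x", "y", "z")
  if (length(setdiff(required, names(atoms)))) {
    stop("atoms needs columns element, x, y, z", call. = FALSE)
  }
  check_elements(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- rep(0, nrow(atoms))
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  if (is.null(bonds$order)) bonds$order <- rep(1, nrow(bonds))
  if (nrow(bonds)) {
    if (any(bonds$i == bonds$j)) stop("self-loop bond", call. = FALSE)
    if (any(bonds$i < 1 | bonds$j < 1 | bonds$i > nrow(atoms) | bonds$j > nrow(atoms))) {
      stop("bond index out of range", call. = FALSE)
    }
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  structure(
    list(atoms = atoms[, c("element", "x", "y", "z", "charge")],
         bonds = bonds[, c("i", "j", "order")],
         net_charge = as.integer(net_charge),
         name = name, notation = notation),
    class = "small_molecule"
  )
}

#' @export
print.small_molecule <- function(x, ...) {
  els <- table(x$atoms$element)
  cat(sprintf("small_molecule '%s': %s, %d bond(s), net charge %+d e\n",
              x$name, paste(sprintf("%s%d", names(els), els), collapse = ""),
              nrow(x$bonds), x$net_charge))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

mol_formula <- function(mol) {
  els <- table(mol$atoms$element)
  paste(sprintf("%s%d", names(els), els), collapse = "")
}

#' Molar mass of a molecule
#' @param mol A [small_molecule()].
#' @return g/mol.
#' @export
molecular_mass <- function(mol) sum(atomic_mass(mol$atoms$element))

#' Perceive bonds from interatomic distances
#'
#' Two atoms are bonded iff their distance does not exceed the sum of their
#' covalent radii plus `tolerance`. For a [periodic_structure()] the
#' minimum-image distance is used, so bonds across cell boundaries are
#' found; the returned table then carries the integer image shift
#' (`sx`, `sy`, `sz`) of atom `j` relative to atom `i` realizing the bond.
#'
#' @param x A [small_molecule()] or [periodic_structure()].
#' @param tolerance Distance slack in Angstrom (default 0.45).
#' @return Data frame with columns `i`, `j`, `dist` (and image shifts for
#'   periodic input). Bond `order` is set to 1; order perception is not
#'   attempted.
#' @export
perceive_bonds <- function(x, tolerance = 0.45) UseMethod("perceive_bonds")

#' @export
perceive_bonds.small_molecule <- function(x, tolerance = 0.45) {
  xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
  rc <- covalent_radius(x$atoms$element)
  n <- nrow(xyz)
  out <- list()
  if (n >= 2) {
    d <- as.matrix(stats::dist(xyz))
    cut <- outer(rc, rc, "+") + tolerance
    hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) {
      out <- data.frame(i = hit[, 1], j = hit[, 2], order = 1,
                        dist = d[hit])
    }
  }
  if (!length(out)) out <- data.frame(i = integer(), j = integer(),
                                      order = numeric(), dist = numeric())
  out
}

#' @export
perceive_bonds.periodic_structure <- function(x, tolerance = 0.45) {
  s <- x$sites
  n <- nrow(s)
  res <- data.frame(i = integer(), j = integer(), order = numeric(),
                    dist = numeric(), sx = integer(), sy = integer(),
                    sz = integer())
  if (n < 2) return(res)
  rc <- covalent_radius(s$element)
  fr <- as.matrix(s[, c("fx", "fy", "fz")])
  L <- x$cell$lattice
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  rows <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    d0 <- fr[js, , drop = FALSE] -
      matrix(fr[i, ], nrow = length(js), ncol = 3, byrow = TRUE)
    best <- rep(Inf, length(js)); bestk <- rep(1L, length(js))
    for (k in seq_len(nrow(shifts))) {
      dc <- (d0 + matrix(shifts[k, ], nrow = length(js), ncol = 3, byrow = TRUE)) %*% L
      dk <- sqrt(rowSums(dc^2))
      upd <- dk < best
      best[upd] <- dk[upd]; bestk[upd] <- k
    }
    cut <- rc[i] + rc[js] + tolerance
    sel <- which(best <= cut)
    if (length(sel)) {
      rows[[i]] <- data.frame(i = i, j = js[sel], order = 1, dist = best[sel],
                              sx = shifts[bestk[sel], 1],
                              sy = shifts[bestk[sel], 2],
                              sz = shifts[bestk[sel], 3])
    }
  }
  got <- Filter(Negate(is.null), rows)
  if (length(got)) res <- do.call(rbind, got)
  rownames(res) <- NULL
  res
}
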