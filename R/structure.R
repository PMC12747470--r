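# Periodic crystal structures: a unit cell plus atom sites in fractional
# coordinates. The substrate of all geometry and GCMC operations.

#' Construct a periodic structure
#'
#' A crystal structure given by a [unit_cell()] and a table of atom sites in
#' fractional coordinates. Fractional coordinates are always wrapped into
#' `[0, 1)`; element symbols must be present in the packaged element table.
#'
#' @param cell A [unit_cell()].
#' @param sites A data frame with columns `element`, `fx`, `fy`, `fz` and
#'   optionally `charge` (partial charge, e; default 0) and `label`.
#'   May have zero rows (an empty box, used by simulation oracles).
#' @param name Identifier used in reports and CIF data-block names.
#' @return An object of class `periodic_structure` with elements `cell`,
#'   `sites` (wrapped, with `charge` and `label` filled in) and `name`.
#' @seealso [parse_cif()], [write_cif()], [mass_per_cell()]
#' @export
periodic_structure <- function(cell, sites, name = "structure") {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(sites))
  required <- c("element", "fx", "fy", "fz")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) {
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(sites)) {
    check_elements(sites$element)
    w <- wrap_frac(as.matrix(sites[, c("fx", "fy", "fz")]))
    sites$fx <- w[, 1]; sites$fy <- w[, 2]; sites$fz <- w[, 3]
  }
  if (is.null(sites$charge)) sites$charge <- rep(0, nrow(sites))
  if (is.null(sites$label)) {
    sites$label <- if (nrow(sites)) paste0(sites$element, seq_len(nrow(sites))) else character()
  }
  rownames(sites) <- NULL
  structure(
    list(cell = cell,
         sites = sites[, c("element", "fx", "fy", "fz", "charge", "label")],
         name = name),
    class = "periodic_structure"
  )
}

#' @export
print.periodic_structure <- function(x, ...) {
  cat(sprintf("periodic_structure '%s': %d site(s), V = %.2f A^3, M = %.2f g/mol per cell\n",
              x$name, nrow(x$sites), x$cell$volume, mass_per_cell(x)))
  els <- table(x$sites$element)
  if (length(els)) {
    cat("  composition:", paste(sprintf("%s%d", names(els), els), collapse = " "), "\n")
  }
  invisible(x)
}

#' Framework mass per unit cell
#'
#' @param structure A [periodic_structure()].
#' @return Sum of atomic masses over sites, in g/mol.
#' @export
mass_per_cell <- function(structure) {
  stopifnot(inherits(structure, "periodic_structure"))
  if (!nrow(structure$sites)) return(0)
  sum(atomic_mass(structure$sites$element))
}

n_sites <- function(structure) nrow(structure$sites)

# Cartesian coordinates of all sites (n x 3, Angstrom).
site_cart <- function(structure) {
  if (!nrow(structure$sites)) return(matrix(numeric(), 0, 3))
  frac_to_cart(structure$cell,
               as.matrix(structure$sites[, c("fx", "fy", "fz")]))
}

#' Expand a structure to a supercell of minimum perpendicular width
#'
#' Replicates the cell along each lattice vector by the smallest integer
#' that makes every perpendicular cell width at least `min_width`. Needed
#' so the minimum-image convention is valid at a given interaction cutoff
#' (width >= 2 x cutoff).
#'
#' @param structure A [periodic_structure()].
#' @param min_width Minimum perpendicular width in Angstrom (> 0).
#' @return A new `periodic_structure`; site count and [mass_per_cell()]
#'   scale by the replication product.
#' @examples
#' s <- make_cubic_framework(a = 10)
#' n_rep <- nrow(build_supercell(s, 24)$sites)  # 27 sites: 3 x 3 x 3
#' @export
build_supercell <- function(structure, min_width) {
  stopifnot(inherits(structure, "periodic_structure"), min_width > 0)
  widths <- cell_perpendicular_widths(structure$cell)
  reps <- pmax(1L, as.integer(ceiling(min_width / widths - 1e-9)))
  if (all(reps == 1L)) return(structure)
  cell0 <- structure$cell
  L <- cell0$lattice * reps  # row i scaled by reps[i]
  new_cell <- unit_cell(cell0$a * reps[1], cell0$b * reps[2], cell0$c * reps[3],
                        cell0$alpha, cell0$beta, cell0$gamma)
  s <- structure$sites
  shifts <- expand.grid(i = seq_len(reps[1]) - 1L,
                        j = seq_len(reps[2]) - 1L,
                        k = seq_len(reps[3]) - 1L)
  out <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(r) {
    t <- s
    t$fx <- (s$fx + shifts$i[r]) / reps[1]
    t$fy <- (s$fy + shifts$j[r]) / reps[2]
    t$fz <- (s$fz + shifts$k[r]) / reps[3]
    t
  }))
  periodic_structure(new_cell, out,
                     name = sprintf("%s_%dx%dx%d", structure$name,
                                    reps[1], reps[2], reps[3]))
}
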