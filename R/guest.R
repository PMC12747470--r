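# Rigid guest models: interaction sites in a body frame centered at the
# centroid, a molar mass, and a derived minimal projection diameter used by
# the porosity filter.

#' Construct a rigid guest model
#'
#' @param name Guest identifier.
#' @param sites Data frame with columns `type` (force-field type label),
#'   `x`, `y`, `z` (body-frame coordinates, Angstrom) and optionally
#'   `charge` (e). Coordinates are re-centered at the centroid.
#' @param molar_mass Molar mass in g/mol (> 0).
#' @param ff A [forcefield()] used to derive the minimal diameter (sigma of
#'   the sites provides the vdW padding).
#' @return Object of class `rigid_guest` with `minimal_diameter`:
#'   the guest's smallest projection width, approximated as the middle
#'   eigen-extent of the site cloud plus the largest site sigma.
#' @export
rigid_guest <- function(name, sites, molar_mass, ff = forcefield()) {
  stopifnot(is.data.frame(sites), nrow(sites) >= 1, molar_mass > 0)
  if (is.null(sites$charge)) sites$charge <- rep(0, nrow(sites))
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  sites$x <- xyz[, 1]; sites$y <- xyz[, 2]; sites$z <- xyz[, 3]
  idx <- ff_index(ff, sites$type)
  sig <- ff$table$sigma_A[idx]
  if (nrow(sites) > 1) {
    ev <- eigen(stats::cov(xyz) * (nrow(xyz) - 1) / nrow(xyz),
                symmetric = TRUE)$values
    ev[ev < 0] <- 0
    extents <- 2 * sqrt(ev) * sqrt(3)  # eigen-extent of a uniform cloud
    middle <- sort(extents)[2]
  } else middle <- 0
  structure(list(name = name,
                 sites = sites[, c("type", "x", "y", "z", "charge")],
                 molar_mass = molar_mass,
                 minimal_diameter = middle + max(sig)),
            class = "rigid_guest")
}

#' @export
print.rigid_guest <- function(x, ...) {
  cat(sprintf("rigid_guest '%s': %d site(s), M = %.1f g/mol, minimal diameter %.2f A\n",
              x$name, nrow(x$sites), x$molar_mass, x$minimal_diameter))
  invisible(x)
}
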