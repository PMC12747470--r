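# Lennard-Jones force field: per-type epsilon (K) and sigma (Angstrom)
# with Lorentz-Berthelot mixing. The packaged table carries generic
# UFF-style parameters for framework elements and coarse guest-site types;
# absolute isotherms are not the goal - screening ranks are.

#' Load a Lennard-Jones parameter table and build a force field
#'
#' @param path CSV with columns `type`, `epsilon_K`, `sigma_A`; defaults to
#'   the packaged table.
#' @param cutoff Spherical cutoff r_c in Angstrom (default 12.8).
#' @param tail One of `"truncated"` (plain cutoff) or `"shifted"`
#'   (potential shifted to zero at the cutoff).
#' @param electrostatics `"off"` (default) or `"dsf"` (damped shifted
#'   force with damping `alpha`).
#' @param alpha DSF damping parameter in 1/Angstrom.
#' @return Object of class `forcefield`.
#' @export
forcefield <- function(path = NULL, cutoff = 12.8,
                       tail = c("truncated", "shifted"),
                       electrostatics = c("off", "dsf"), alpha = 0.2) {
  tail <- match.arg(tail)
  electrostatics <- match.arg(electrostatics)
  if (is.null(path)) {
    path <- system.file("extdata", "lj_params.csv", package = "mofscreen")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("type", "epsilon_K", "sigma_A") %in% names(tab)))
  if (any(tab$epsilon_K < 0) || any(tab$sigma_A <= 0)) {
    stop("force field requires epsilon >= 0 and sigma > 0", call. = FALSE)
  }
  if (cutoff <= max(tab$sigma_A)) {
    stop("cutoff must exceed the largest sigma", call. = FALSE)
  }
  rownames(tab) <- tab$type
  structure(list(table = tab, cutoff = cutoff, tail = tail,
                 electrostatics = electrostatics, alpha = alpha),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("forcefield: %d types, cutoff %.1f A, %s tail, electrostatics %s\n",
              nrow(x$table), x$cutoff, x$tail, x$electrostatics))
  invisible(x)
}

ff_index <- function(ff, types) {
  idx <- match(types, ff$table$type)
  if (anyNA(idx)) {
    stop("force field has no parameters for type(s): ",
         paste(unique(types[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Lennard-Jones pair energy
#'
#' 12-6 potential `4 eps [(sigma/r)^12 - (sigma/r)^6]` in Kelvin with
#' Lorentz-Berthelot mixing between the two types, truncated (optionally
#' shifted) at the cutoff. `r = 0` is treated as infinite repulsion
#' (overlap rejection), not an error.
#'
#' @param type_i,type_j Type labels present in the force-field table.
#' @param r Distance in Angstrom (vectorized).
#' @param ff A [forcefield()].
#' @return Energy in K.
#' @examples
#' ff <- forcefield()
#' lj_pair_energy("C", "C", 3.431, ff)            # 0 at r = sigma
#' lj_pair_energy("C", "C", 2^(1/6) * 3.431, ff)  # -epsilon at the minimum
#' @export
lj_pair_energy <- function(type_i, type_j, r, ff) {
  stopifnot(inherits(ff, "forcefield"), all(r >= 0))
  i <- ff_index(ff, type_i); j <- ff_index(ff, type_j)
  s <- (ff$table$sigma_A[i] + ff$table$sigma_A[j]) / 2
  e <- sqrt(ff$table$epsilon_K[i] * ff$table$epsilon_K[j])
  u <- ifelse(r == 0, Inf, {
    sr6 <- (s / pmax(r, 1e-300))^6
    4 * e * sr6 * (sr6 - 1)
  })
  if (ff$tail == "shifted") {
    src6 <- (s / ff$cutoff)^6
    u <- u - 4 * e * src6 * (src6 - 1)
  }
  u[r >= ff$cutoff] <- 0
  u
}
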