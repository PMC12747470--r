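# Pore-geometry descriptors on a periodic distance grid: largest cavity
# diameter (LCD), pore-limiting diameter (PLD) via percolation analysis,
# pore-size distribution, and Monte-Carlo accessible pore volume. These are
# the quantities that eliminate non-porous candidates and explain loading
# trends.

#' Periodic distance grid of a structure
#'
#' Samples the periodic distance transform on a regular fractional grid:
#' each grid value is the distance to the nearest framework-atom van der
#' Waals surface (negative inside an atom), exact to within half a grid
#' diagonal.
#'
#' @param structure A [periodic_structure()].
#' @param spacing Target grid spacing in Angstrom (default 0.2 for reported
#'   descriptors; 0.5 is adequate for coarse library screening).
#' @param radii Optional named vector overriding the packaged van der Waals
#'   radii per element.
#' @return Object of class `distance_grid`: `values` (numeric array in
#'   x-fastest order), `dims`, `spacing` (actual per-axis spacings), `cell`.
#' @export
compute_distance_grid <- function(structure, spacing = 0.2, radii = NULL) {
  stopifnot(inherits(structure, "periodic_structure"), spacing > 0)
  if (!nrow(structure$sites)) stop("empty structure", call. = FALSE)
  cell <- structure$cell
  dims <- pmax(2L, as.integer(ceiling(c(cell$a, cell$b, cell$c) / spacing)))
  r <- site_radii(structure, radii)
  vals <- dist_grid_cpp(cell$lattice,
                        as.matrix(structure$sites[, c("fx", "fy", "fz")]),
                        r, dims, is_orthogonal_cell(cell))
  structure(list(values = vals, dims = dims,
                 spacing = c(cell$a, cell$b, cell$c) / dims,
                 cell = cell, radii_max = max(r),
                 sites_frac = as.matrix(structure$sites[, c("fx", "fy", "fz")]),
                 radii = r),
            class = "distance_grid")
}

site_radii <- function(structure, radii = NULL) {
  el <- structure$sites$element
  r <- vdw_radius(el)
  if (!is.null(radii)) {
    hit <- el %in% names(radii)
    r[hit] <- radii[el[hit]]
  }
  unname(r)
}

#' @export
print.distance_grid <- function(x, ...) {
  cat(sprintf("distance_grid: %d x %d x %d points, spacing %.3f/%.3f/%.3f A, max clearance %.3f A\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3], max(x$values)))
  invisible(x)
}

#' Largest cavity diameter (LCD)
#'
#' Diameter of the largest sphere fitting anywhere in the void space:
#' twice the maximum of the distance grid. Zero for structures with no
#' void.
#'
#' @param grid A [compute_distance_grid()] result.
#' @param refine Polish the best grid point by local continuous
#'   maximization of the clearance (default TRUE), removing the half-grid
#'   discretization error.
#' @return LCD in Angstrom.
#' @examples
#' g <- compute_distance_grid(make_cubic_framework(a = 10), spacing = 0.25)
#' largest_cavity_diameter(g)  # sqrt(3)*10 - 2*r_vdw
#' @export
largest_cavity_diameter <- function(grid, refine = TRUE) {
  stopifnot(inherits(grid, "distance_grid"))
  best <- max(grid$values)
  if (refine && best > 0 && nrow(grid$sites_frac)) {
    idx <- which.max(grid$values) - 1L
    i <- idx %% grid$dims[1]
    j <- (idx %/% grid$dims[1]) %% grid$dims[2]
    k <- idx %/% (grid$dims[1] * grid$dims[2])
    start <- c(i, j, k) / grid$dims
    ortho <- is_orthogonal_cell(grid$cell)
    obj <- function(p) {
      -clearance_cpp(grid$cell$lattice, grid$sites_frac, grid$radii,
                     wrap_frac(p), ortho)
    }
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
    best <- max(best, -opt$value)
  }
  max(0, 2 * best)
}

#' Pore-limiting diameter (PLD)
#'
#' The largest probe diameter d for which the void region
#' `{clearance >= d/2}` contains a component percolating to its own
#' periodic image along at least one lattice direction. Computed by
#' incremental union-find percolation over grid levels; resolution is the
#' grid spacing.
#'
#' @param grid A [compute_distance_grid()] result.
#' @return PLD in Angstrom (0 when nothing percolates).
#' @export
pore_limiting_diameter <- function(grid) {
  stopifnot(inherits(grid, "distance_grid"))
  t <- percolation_threshold_cpp(grid$values, grid$dims)
  if (!is.finite(t)) {
    if (t > 0) return(Inf)  # empty-framework grid percolates everywhere
    return(0)
  }
  max(0, 2 * t)
}

#' Pore-size distribution peaks
#'
#' Histogram of largest-covering-sphere diameters over void grid points
#' (the diameter of the largest sphere that contains each point while
#' fitting in the void), with peaks reported as local maxima above a weight
#' threshold, sorted by decreasing diameter. Two distinct channel systems
#' appear as two peaks.
#'
#' @param grid A [compute_distance_grid()] result (orthogonal cells).
#' @param min_weight Minimum fraction of void points under a peak.
#' @param bin_width Histogram bin width in Angstrom (default: max grid
#'   spacing).
#' @return Data frame `diameter` (Angstrom), `weight` (fraction of void
#'   points), largest first; zero rows when there is no void.
#' @export
pore_size_distribution <- function(grid, min_weight = 0.02, bin_width = NULL) {
  stopifnot(inherits(grid, "distance_grid"))
  if (!is_orthogonal_cell(grid$cell)) {
    stop("pore_size_distribution supports orthogonal cells", call. = FALSE)
  }
  cover <- covering_radius_cpp(grid$values, grid$dims,
                               grid$spacing[1], grid$spacing[2], grid$spacing[3])
  cover <- cover[is.finite(cover) & cover > 0]
  if (!length(cover)) {
    return(data.frame(diameter = numeric(), weight = numeric()))
  }
  if (is.null(bin_width)) bin_width <- max(grid$spacing)
  d <- 2 * cover
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE)
  w <- h$counts / length(d)
  mids <- h$mids
  # local maxima over the histogram (plateaus collapse to their last bin)
  n <- length(w)
  cand <- which(w >= min_weight & w >= c(-Inf, w[-n]) & w >= c(w[-1], -Inf))
  peaks <- cand[c(diff(cand) > 1, TRUE)]
  out <- data.frame(diameter = mids[peaks], weight = w[peaks])
  out <- out[order(-out$diameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Guest-accessible pore volume by Monte-Carlo probe insertion
#'
#' Inserts a hard-sphere probe at uniformly random points; the fraction
#' with clearance at least the probe radius is the void fraction, and the
#' volume follows as void fraction x cell volume / cell mass (cm^3/g).
#' With `accessible = TRUE` (default) only points inside a void component
#' that percolates at the probe radius are counted - isolated pockets a
#' guest cannot reach are excluded.
#'
#' @param structure A [periodic_structure()].
#' @param probe_radius Probe radius in Angstrom (>= 0).
#' @param samples Number of Monte-Carlo points.
#' @param seed RNG seed.
#' @param accessible Restrict to the percolating component (needs a grid;
#'   see `grid_spacing`).
#' @param grid_spacing Spacing of the component-labelling grid used in
#'   accessible mode.
#' @param radii Optional vdW-radius overrides.
#' @return List with `volume_cm3_per_g` (NA for a massless empty box),
#'   `void_fraction`, `se` (binomial standard error of the void fraction),
#'   `samples`, `probe_radius`.
#' @export
accessible_pore_volume <- function(structure, probe_radius = 0,
                                   samples = 20000L, seed = 1L,
                                   accessible = TRUE, grid_spacing = 0.3,
                                   radii = NULL) {
  stopifnot(inherits(structure, "periodic_structure"), probe_radius >= 0)
  cell <- structure$cell
  set.seed(seed)
  pts <- matrix(stats::runif(3 * samples), ncol = 3)
  if (!nrow(structure$sites)) {
    clear <- rep(Inf, samples)
  } else {
    clear <- clearance_cpp(cell$lattice,
                           as.matrix(structure$sites[, c("fx", "fy", "fz")]),
                           site_radii(structure, radii), pts,
                           is_orthogonal_cell(cell))
  }
  ok <- clear >= probe_radius
  if (accessible && nrow(structure$sites)) {
    grid <- compute_distance_grid(structure, spacing = grid_spacing, radii = radii)
    lab <- label_components_cpp(grid$values, grid$dims, probe_radius)
    perc_labels <- which(lab$percolating)
    if (!length(perc_labels)) {
      ok[] <- FALSE
    } else {
      idx <- floor(pts * matrix(grid$dims, samples, 3, byrow = TRUE))
      idx[idx == matrix(grid$dims, samples, 3, byrow = TRUE)] <- 0
      lin <- idx[, 3] * grid$dims[1] * grid$dims[2] + idx[, 2] * grid$dims[1] +
        idx[, 1] + 1
      ok <- ok & (lab$labels[lin] %in% perc_labels)
    }
  }
  vf <- mean(ok)
  se <- sqrt(vf * (1 - vf) / samples)
  mass <- mass_per_cell(structure)
  vol <- if (mass > 0) {
    vf * cell$volume / mass * 0.6022141  # A^3/(g/mol) -> cm^3/g (x N_A, unit juggling)
  } else NA_real_
  list(volume_cm3_per_g = vol, void_fraction = vf, se = se,
       samples = samples, probe_radius = probe_radius)
}

#' All pore descriptors of a framework
#'
#' Convenience wrapper computing LCD, PLD, PSD peaks, accessible volume and
#' the porosity verdict in one pass.
#'
#' @param structure A [periodic_structure()].
#' @param spacing Grid spacing (Angstrom).
#' @param probe_radius Probe radius for the volume and verdict (Angstrom).
#' @param samples,seed Monte-Carlo settings for the volume.
#' @param radii Optional vdW overrides.
#' @return Object of class `pore_descriptors` with fields `pld`, `lcd`,
#'   `psd_peaks`, `accessible_volume` (cm^3/g), `void_fraction`, `porous`.
#' @export
pore_descriptors <- function(structure, spacing = 0.2, probe_radius = 0,
                             samples = 20000L, seed = 1L, radii = NULL) {
  grid <- compute_distance_grid(structure, spacing = spacing, radii = radii)
  lcd <- largest_cavity_diameter(grid)
  pld <- pore_limiting_diameter(grid)
  psd <- if (is_orthogonal_cell(structure$cell)) {
    pore_size_distribution(grid)
  } else data.frame(diameter = numeric(), weight = numeric())
  av <- accessible_pore_volume(structure, probe_radius = probe_radius,
                               samples = samples, seed = seed,
                               grid_spacing = max(spacing, 0.25), radii = radii)
  structure(list(pld = pld, lcd = lcd, psd_peaks = psd,
                 accessible_volume = av$volume_cm3_per_g,
                 void_fraction = av$void_fraction,
                 porous = pld >= 2 * probe_radius && av$void_fraction > 0,
                 spacing = spacing, probe_radius = probe_radius),
            class = "pore_descriptors")
}

#' @export
print.pore_descriptors <- function(x, ...) {
  cat(sprintf("pore_descriptors: PLD %.2f A, LCD %.2f A, void fraction %.3f, V_acc %s cm^3/g, %s\n",
              x$pld, x$lcd, x$void_fraction,
              ifelse(is.na(x$accessible_volume), "NA",
                     sprintf("%.3f", x$accessible_volume)),
              if (x$porous) "porous" else "non-porous"))
  if (nrow(x$psd_peaks)) {
    cat("  PSD peaks (A):", paste(sprintf("%.2f (w=%.2f)", x$psd_peaks$diameter,
                                          x$psd_peaks$weight), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Porosity filter for a guest of given minimal diameter
#'
#' A framework passes iff its PLD is at least the guest's minimal projection
#' diameter (inclusive) and it has accessible volume.
#'
#' @param descriptors A [pore_descriptors()] result.
#' @param guest_min_diameter Guest minimal diameter in Angstrom.
#' @return Logical.
#' @export
porosity_filter <- function(descriptors, guest_min_diameter) {
  stopifnot(inherits(descriptors, "pore_descriptors"))
  isTRUE(descriptors$pld >= guest_min_diameter) &&
    isTRUE(!is.na(descriptors$void_fraction) && descriptors$void_fraction > 0)
}
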