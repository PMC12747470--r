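# Toy periodic frameworks with closed-form pore metrics, the synthetic
# screening library with a ground-truth manifest, and a synthetic
# PCN-222-like two-channel framework. These stand in for licensed
# structure-database entries; none mimics a real topology.

#' Cubic corner-atom framework
#'
#' One atom per cell corner. Closed forms with vdW radius r:
#' LCD = sqrt(3) a - 2 r (body center), PLD = sqrt(2) a - 2 r (face
#' center bottleneck).
#'
#' @param a Lattice constant in Angstrom.
#' @param element Atom type at the corner.
#' @param name Structure name.
#' @return A [periodic_structure()] with one site. A framework with
#'   `a <= 2 r` is non-porous by construction (generated with a warning).
#' @export
make_cubic_framework <- function(a, element = "C", name = NULL) {
  stopifnot(a > 0)
  r <- vdw_radius(element)
  if (a <= 2 * r) {
    warning("a <= 2 r_vdw: framework is non-porous by construction", call. = FALSE)
  }
  if (is.null(name)) name <- sprintf("cubic_%s_a%.3g", element, a)
  periodic_structure(unit_cell(a, a, a),
                     data.frame(element = element, fx = 0, fy = 0, fz = 0),
                     name = name)
}

#' Empty simulation box
#'
#' A zero-site orthorhombic cell, the ideal-gas oracle geometry for GCMC.
#'
#' @param a,b,c Box lengths in Angstrom.
#' @return A [periodic_structure()] with no sites.
#' @export
empty_box <- function(a, b = a, c = a) {
  periodic_structure(unit_cell(a, b, c),
                     data.frame(element = character(), fx = numeric(),
                                fy = numeric(), fz = numeric()),
                     name = sprintf("empty_box_%g", a))
}

#' Uniform dilation series of a cubic framework
#'
#' Scaled copies of a corner-atom framework: same topology, strictly
#' increasing void fraction and accessible pore volume with the factor
#' (atom radii do not scale, so LCD(f a) = sqrt(3) f a - 2 r).
#'
#' @param a Base lattice constant (Angstrom).
#' @param factors Dilation factors (>= 1).
#' @param element Corner atom type.
#' @return List of [periodic_structure()].
#' @export
make_dilation_series <- function(a = 10, factors = c(1, 1.2, 1.5, 2),
                                 element = "C") {
  stopifnot(all(factors >= 1))
  lapply(factors, function(f) {
    make_cubic_framework(a * f, element,
                         name = sprintf("dilate_%s_f%.3g", element, f))
  })
}

#' Dense (non-porous) block
#'
#' Atoms on a simple grid whose spacing is below the atom diameter, so the
#' van der Waals spheres overlap everywhere: PLD = 0 by construction.
#'
#' @param a Cell edge (Angstrom).
#' @param element Atom type.
#' @param spacing Target grid spacing; the default 0.95 x 2r/sqrt(3) keeps
#'   even the body-center gap of the atom grid inside the vdW spheres.
#' @return A [periodic_structure()].
#' @export
make_dense_block <- function(a = 10, element = "C", spacing = NULL) {
  r <- unname(vdw_radius(element))
  if (is.null(spacing)) spacing <- 0.95 * 2 * r / sqrt(3)
  n <- max(2L, ceiling(a / spacing))
  g <- (seq_len(n) - 1) / n
  pts <- expand.grid(fx = g, fy = g, fz = g)
  periodic_structure(unit_cell(a, a, a),
                     data.frame(element = element, pts),
                     name = sprintf("dense_%s_a%.3g", element, a))
}

#' Synthetic two-channel framework with prescribed free diameters
#'
#' Carbon walls on a regular grid, pierced by straight 1D channels along z
#' with the requested *free* diameters (wall-atom keep-out radius =
#' channel radius + vdW radius, so the clearance diameter on the axis is
#' exactly the request, up to grid resolution). With the default two
#' channels of 36 and 17 Angstrom this is a synthetic stand-in for the
#' PCN-222 channel system (hexagonal mesochannels ~3.6 nm, triangular
#' microchannels ~1.7 nm): same diagnostic geometry, no real topology.
#'
#' @param diameters Free channel diameters in Angstrom, largest first.
#' @param element Wall atom type.
#' @param wall Minimum wall thickness between channel keep-outs (Angstrom).
#' @param atom_spacing Wall-atom grid spacing (Angstrom); must be below the
#'   vdW diameter so walls are tight.
#' @param c_height Cell height along the channel axis.
#' @return A [periodic_structure()] whose LCD is the largest diameter and
#'   whose pore-size distribution shows one peak per channel.
#' @export
make_channel_framework <- function(diameters = c(36, 17), element = "C",
                                   wall = 6, atom_spacing = 2.0,
                                   c_height = 4) {
  stopifnot(length(diameters) >= 1, all(diameters > 0))
  diameters <- sort(diameters, decreasing = TRUE)
  r <- vdw_radius(element)
  keep <- diameters / 2 + r  # no atom center within this radius of an axis
  # channels side by side along x, centered in y
  Lx <- sum(2 * keep) + wall * (length(diameters) + 1)
  Ly <- 2 * max(keep) + wall
  centers_x <- cumsum(c(0, utils::head(2 * keep, -1))) + wall * seq_along(keep) + keep
  nx <- ceiling(Lx / atom_spacing); ny <- ceiling(Ly / atom_spacing)
  nz <- max(2L, ceiling(c_height / atom_spacing))
  gx <- (seq_len(nx) - 0.5) / nx * Lx
  gy <- (seq_len(ny) - 0.5) / ny * Ly
  gz <- (seq_len(nz) - 0.5) / nz
  pts <- expand.grid(x = gx, y = gy)
  inside <- rep(FALSE, nrow(pts))
  for (ch in seq_along(keep)) {
    dx <- pts$x - centers_x[ch]
    dx <- dx - Lx * round(dx / Lx)
    dy <- pts$y - Ly / 2
    dy <- dy - Ly * round(dy / Ly)
    inside <- inside | (dx^2 + dy^2 < keep[ch]^2)
  }
  wall_pts <- pts[!inside, , drop = FALSE]
  sites <- do.call(rbind, lapply(gz, function(z) {
    data.frame(element = element, fx = wall_pts$x / Lx, fy = wall_pts$y / Ly,
               fz = z)
  }))
  periodic_structure(unit_cell(Lx, Ly, c_height), sites,
                     name = sprintf("synthetic_channels_%s",
                                    paste(round(diameters, 1), collapse = "_")))
}

#' Synthetic PCN-222-like channel framework
#'
#' [make_channel_framework()] with free diameters 36 and 17 Angstrom - the
#' published channel diameters of PCN-222 (3.6 nm hexagonal mesochannels,
#' 1.7 nm triangular microchannels). A synthetic geometry stand-in for the
#' licensed crystal structure, used to validate LCD / pore-size-distribution
#' recovery; it reproduces the channel metrics, not the crystal chemistry.
#'
#' @param atom_spacing Wall-atom grid spacing in Angstrom.
#' @return A [periodic_structure()].
#' @export
make_pcn222_like <- function(atom_spacing = 2.0) {
  s <- make_channel_framework(diameters = c(36, 17), atom_spacing = atom_spacing)
  s$name <- "synthetic_pcn222_like"
  s
}

# A toy MOF cell: one metal atom coordinated to a terephthalate-style
# linker (benzene + 2 carboxyls, acidic H replaced by the metal contact).
# When dense = TRUE the remaining space is filled with extra metal atoms so
# the framework is non-porous while the building blocks stay unchanged.
make_toy_mof <- function(metal = "Zr", a = 25, dense = FALSE, name = NULL) {
  lnk <- build_linker("benzene", c("carboxyl", "carboxyl"))
  at <- lnk$atoms; bd <- lnk$bonds
  # the two acidic hydrogens: H bonded to an O that is bonded to a C with
  # two O neighbors
  acidic_h <- integer()
  metal_pos <- list()
  for (r in seq_len(nrow(bd))) {
    i <- bd$i[r]; j <- bd$j[r]
    if (at$element[i] == "O" && at$element[j] == "H") { o <- i; h <- j }
    else if (at$element[j] == "O" && at$element[i] == "H") { o <- j; h <- i }
    else next
    opos <- unlist(at[o, c("x", "y", "z")])
    hpos <- unlist(at[h, c("x", "y", "z")])
    dir <- (hpos - opos) / sqrt(sum((hpos - opos)^2))
    acidic_h <- c(acidic_h, h)
    metal_pos[[length(metal_pos) + 1L]] <- opos + 2.2 * dir
  }
  keep <- setdiff(seq_len(nrow(at)), acidic_h)
  remap <- match(seq_len(nrow(at)), keep)
  at <- at[keep, , drop = FALSE]
  bd <- bd[bd$i %in% keep & bd$j %in% keep, , drop = FALSE]
  bd$i <- remap[bd$i]; bd$j <- remap[bd$j]
  cell <- unit_cell(a, a, a)
  ctr <- a / 2
  org <- data.frame(element = at$element,
                    fx = (at$x + ctr) / a, fy = (at$y + ctr) / a,
                    fz = (at$z + ctr) / a)
  met <- do.call(rbind, lapply(metal_pos, function(p) {
    data.frame(element = metal, fx = (p[1] + ctr) / a, fy = (p[2] + ctr) / a,
               fz = (p[3] + ctr) / a)
  }))
  sites <- rbind(met, org)
  if (dense) {
    # fill with metal atoms outside a 3.5 A keep-out around existing atoms
    rm <- vdw_radius(metal)
    spacing <- 1.8 * rm * 0.85
    n <- ceiling(a / spacing)
    g <- (seq_len(n) - 1) / n
    grid <- as.matrix(expand.grid(fx = g, fy = g, fz = g))
    exist <- as.matrix(sites[, c("fx", "fy", "fz")])
    keep_pt <- rep(TRUE, nrow(grid))
    for (k in seq_len(nrow(exist))) {
      d <- grid - matrix(exist[k, ], nrow(grid), 3, byrow = TRUE)
      d <- d - round(d)
      keep_pt <- keep_pt & (rowSums((d * a)^2) > 3.5^2)
    }
    fill <- data.frame(element = metal, fx = grid[keep_pt, 1],
                       fy = grid[keep_pt, 2], fz = grid[keep_pt, 3])
    sites <- rbind(sites, fill)
  }
  if (is.null(name)) {
    name <- sprintf("toy_mof_%s_a%.3g%s", metal, a, if (dense) "_dense" else "")
  }
  periodic_structure(cell, sites, name = name)
}

#' Synthetic six-structure screening library with ground truth
#'
#' The default end-to-end fixture: two frameworks with toxic metal nodes
#' (Cd, Ni - must fail biocompatibility), two dense frameworks with
#' biocompatible Zr nodes and safe linkers (must fail the porosity gate),
#' and two porous Zr frameworks with safe linkers (must reach the loading
#' stage). Every structure embeds the same terephthalate-style linker, so
#' outcomes are decided by the stage under test. The manifest records the
#' expected terminal stage per structure.
#'
#' @param seed RNG seed (the library itself is deterministic; the seed is
#'   recorded for provenance and reserved for randomized variants).
#' @return List with `structures` (list of [periodic_structure()]) and
#'   `manifest` (data frame: `name`, `expected_stage` one of
#'   `biocompat` / `porosity` / `loading`).
#' @export
make_screening_library <- function(seed = 1L) {
  structures <- list(
    make_toy_mof("Cd", a = 25, name = "lib_cd_porous"),
    make_toy_mof("Ni", a = 25, name = "lib_ni_porous"),
    make_toy_mof("Zr", a = 14, dense = TRUE, name = "lib_zr_dense1"),
    make_toy_mof("Zr", a = 16, dense = TRUE, name = "lib_zr_dense2"),
    make_toy_mof("Zr", a = 25, name = "lib_zr_porous1"),
    make_toy_mof("Zr", a = 28, name = "lib_zr_porous2")
  )
  manifest <- data.frame(
    name = vapply(structures, function(s) s$name, character(1)),
    expected_stage = c("biocompat", "biocompat", "porosity", "porosity",
                       "loading", "loading"),
    stringsAsFactors = FALSE
  )
  list(structures = structures, manifest = manifest, seed = seed)
}

#' Lattice-gas system specification (exact-isotherm oracle)
#'
#' @param M Number of independent adsorption sites.
#' @param eps_site Site adsorption energy in K.
#' @return List with the closed-form isotherm
#'   `isotherm(z, T) = M x/(1+x)`, `x = z exp(-eps_site/T)`; simulate it
#'   with [run_lattice_gcmc()].
#' @export
make_lattice_gas <- function(M = 100L, eps_site = 0) {
  stopifnot(M >= 1)
  list(M = as.integer(M), eps_site = eps_site,
       isotherm = function(z, T = 300) {
         x <- z * exp(-eps_site / T)
         M * x / (1 + x)
       })
}
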