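# Grand canonical Monte Carlo estimation of drug loading: rigid guests in a
# rigid framework at fixed temperature and fugacity. The compiled core
# (src/gcmc.cpp) does the sampling; this file handles supercell
# construction, configuration, block averaging and unit conversions.

.kB_Pa_A3 <- 1.380649e7  # Boltzmann constant in Pa A^3 / K

#' GCMC configuration
#'
#' @param T Temperature in K.
#' @param fugacity Guest fugacity in Pa (equals pressure for an ideal
#'   reservoir).
#' @param move_probs Probabilities of (insert, delete, translate, rotate)
#'   moves; insert and delete must be equal (detailed balance) and the four
#'   must sum to 1.
#' @param cycles Total Monte-Carlo cycles (one cycle = max(20, N) moves).
#' @param equilibration Cycles discarded before averaging (< `cycles`).
#' @param max_translation Initial maximum translation displacement
#'   (Angstrom); auto-tuned toward ~40% acceptance during equilibration and
#'   frozen for production.
#' @param seed RNG seed; fixes the trajectory bit-for-bit.
#' @param min_box_width Minimum perpendicular supercell width in Angstrom
#'   (default 2 x 12.8, validating minimum image at the default cutoff).
#' @param n_blocks Block count for the standard error of mean N.
#' @return List of class `gcmc_config`.
#' @export
gcmc_config <- function(T = 298, fugacity = 1e5,
                        move_probs = c(insert = 0.25, delete = 0.25,
                                       translate = 0.4, rotate = 0.1),
                        cycles = 4000L, equilibration = 1000L,
                        max_translation = 1.0, seed = 1L,
                        min_box_width = 25.6, n_blocks = 10L) {
  stopifnot(T > 0, fugacity >= 0, length(move_probs) == 4,
            cycles > equilibration, n_blocks >= 2)
  if (abs(sum(move_probs) - 1) > 1e-9) {
    stop("move probabilities must sum to 1", call. = FALSE)
  }
  if (abs(move_probs[1] - move_probs[2]) > 1e-9) {
    stop("insert and delete probabilities must be equal", call. = FALSE)
  }
  structure(list(T = T, fugacity = fugacity, move_probs = unname(move_probs),
                 cycles = as.integer(cycles),
                 equilibration = as.integer(equilibration),
                 max_translation = max_translation, seed = as.integer(seed),
                 min_box_width = min_box_width,
                 n_blocks = as.integer(n_blocks)),
            class = "gcmc_config")
}

# Build the list consumed by the C++ core: orthorhombic supercell, typed
# framework atoms, guest template, LJ table rows in use.
build_sim_system <- function(structure, guest, ff, min_box_width) {
  stopifnot(inherits(structure, "periodic_structure"),
            inherits(guest, "rigid_guest"), inherits(ff, "forcefield"))
  if (!is_orthogonal_cell(structure$cell)) {
    stop("GCMC requires an orthogonal (all angles 90) cell; re-cast the structure first",
         call. = FALSE)
  }
  sup <- build_supercell(structure, min_box_width)
  frame_types_lab <- sup$sites$element
  all_types <- unique(c(frame_types_lab, guest$sites$type))
  idx <- ff_index(ff, all_types)
  eps <- ff$table$epsilon_K[idx]
  sig <- ff$table$sigma_A[idx]
  list(box = c(sup$cell$a, sup$cell$b, sup$cell$c),
       frame_xyz = site_cart(sup),
       frame_type = match(frame_types_lab, all_types) - 1L,
       frame_charge = sup$sites$charge,
       guest_xyz = as.matrix(guest$sites[, c("x", "y", "z")]),
       guest_type = match(guest$sites$type, all_types) - 1L,
       guest_charge = guest$sites$charge,
       eps = eps, sig = sig,
       cutoff = ff$cutoff, shifted = identical(ff$tail, "shifted"),
       use_elec = identical(ff$electrostatics, "dsf"), alpha = ff$alpha,
       supercell = sup)
}

#' Run a GCMC simulation of guest uptake
#'
#' Expands the framework to a supercell satisfying the minimum-image
#' convention at the force-field cutoff, runs insertion / deletion /
#' translation / rotation moves with the standard fugacity-form acceptance
#' rules, discards equilibration, and block-averages the production guest
#' count. If no insertion ever succeeds the result is a zero-loading record
#' flagged `inaccessible`.
#'
#' @param structure A [periodic_structure()] with an orthogonal cell (may
#'   be an empty box).
#' @param guest A [rigid_guest()].
#' @param ff A [forcefield()].
#' @param config A [gcmc_config()].
#' @param access_mask Optional accessibility mask from
#'   [accessibility_mask()]: insertions outside the percolating void
#'   component are pre-rejected.
#' @param drift_check_every Recompute the total energy every this many
#'   steps and track the worst relative deviation of the incremental
#'   energy (0 = off).
#' @return Object of class `gcmc_result`: `mean_N` (per simulation box),
#'   `se_N` (block-averaged), `loading_mg_per_g`, `loading_wt_percent`,
#'   `acceptance` (per move), `energy` (mean/final, K), `inaccessible`,
#'   `n_blocks`, `config`, `supercell_info`.
#' @examples
#' \donttest{
#' box <- empty_box(30)
#' g <- make_guest_models()$unit
#' r <- run_gcmc(box, g, forcefield(), gcmc_config(T = 300, fugacity = 1e5,
#'                                                 cycles = 2000, equilibration = 500))
#' r$mean_N  # ~ beta f V = 0.652
#' }
#' @export
run_gcmc <- function(structure, guest, ff = forcefield(),
                     config = gcmc_config(), access_mask = NULL,
                     drift_check_every = 0L) {
  sys <- build_sim_system(structure, guest, ff, config$min_box_width)
  conf <- list(T = config$T, fugacity = config$fugacity,
               move_probs = config$move_probs, cycles = config$cycles,
               equilibration = config$equilibration,
               max_translation = config$max_translation, tune = TRUE,
               access_mask = if (is.null(access_mask)) integer() else access_mask$mask,
               access_dims = if (is.null(access_mask)) integer(3) else access_mask$dims,
               drift_check_every = as.integer(drift_check_every))
  set.seed(config$seed)
  raw <- run_gcmc_cpp(sys[setdiff(names(sys), "supercell")], conf)

  Ntr <- raw$N_trace
  nb <- config$n_blocks
  blocks <- split(Ntr, cut(seq_along(Ntr), nb, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  mean_N <- mean(Ntr)
  se_N <- stats::sd(bm) / sqrt(nb)
  sup <- sys$supercell
  M_box <- mass_per_cell(sup)
  conv <- if (M_box > 0) {
    loading_conversions(mean_N, guest$molar_mass, M_box)
  } else list(mg_per_g = NA_real_, wt_percent = NA_real_)
  acc <- raw$acc / pmax(raw$att, 1)
  names(acc) <- c("insert", "delete", "translate", "rotate")
  inaccessible <- !raw$ever_inserted && mean_N == 0
  structure(list(mean_N = mean_N, se_N = se_N, N_trace = Ntr,
                 loading_mg_per_g = conv$mg_per_g,
                 loading_wt_percent = conv$wt_percent,
                 acceptance = acc,
                 energy = list(mean_K = mean(raw$U_trace),
                               final_K = utils::tail(raw$U_trace, 1)),
                 inaccessible = inaccessible,
                 max_drift = raw$max_drift,
                 betafV = raw$bfV,
                 n_blocks = nb,
                 supercell_info = list(n_sites = nrow(sup$sites),
                                       box = c(sup$cell$a, sup$cell$b, sup$cell$c),
                                       mass_g_per_mol = M_box),
                 config = config),
            class = "gcmc_result")
}

#' @export
print.gcmc_result <- function(x, ...) {
  cat(sprintf("gcmc_result: <N> = %.4f +/- %.4f per box", x$mean_N, x$se_N))
  if (!is.na(x$loading_mg_per_g)) {
    cat(sprintf("  (%.1f mg/g, %.1f wt.%%)", x$loading_mg_per_g, x$loading_wt_percent))
  }
  cat("\n")
  if (x$inaccessible) cat("  flag: inaccessible (no insertion ever accepted)\n")
  cat("  acceptance:", paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Accessibility mask for GCMC insertions
#'
#' Labels the void grid at the guest's radius and marks the percolating
#' component(s); insertions proposed outside are rejected up front, so
#' isolated pockets the guest could never diffuse into do not contribute
#' to loading.
#'
#' @param structure A [periodic_structure()] (the *unit* cell; the mask is
#'   built on the supercell used by [run_gcmc()], pass the same
#'   `min_box_width`).
#' @param probe_radius Probe radius in Angstrom.
#' @param min_box_width As in [gcmc_config()].
#' @param spacing Grid spacing of the mask.
#' @return List with `mask` (integer grid vector, 1 = allowed) and `dims`,
#'   or NULL when nothing percolates (callers should treat the framework
#'   as inaccessible).
#' @export
accessibility_mask <- function(structure, probe_radius, min_box_width = 25.6,
                               spacing = 0.4) {
  sup <- build_supercell(structure, min_box_width)
  if (!nrow(sup$sites)) return(NULL)
  grid <- compute_distance_grid(sup, spacing = spacing)
  lab <- label_components_cpp(grid$values, grid$dims, probe_radius)
  perc <- which(lab$percolating)
  if (!length(perc)) return(NULL)
  list(mask = as.integer(lab$labels %in% perc), dims = grid$dims)
}

#' Henry coefficient by Widom test-particle insertion
#'
#' `K_H = beta <exp(-beta dU)>` averaged over uniform random insertion
#' positions and orientations, in molecules / (A^3 Pa). In an empty box
#' `K_H = beta = 1/(kB T)` exactly.
#'
#' @param structure,guest,ff As in [run_gcmc()].
#' @param T Temperature (K).
#' @param insertions Number of trial insertions (>= 1e4).
#' @param seed RNG seed.
#' @param min_box_width Supercell width, as in [gcmc_config()].
#' @return List with `henry` (molecules A^-3 Pa^-1), `se`,
#'   `mean_boltzmann`, `beta` (the empty-box reference value of `henry`).
#' @export
widom_henry <- function(structure, guest, ff = forcefield(), T = 298,
                        insertions = 2e4, seed = 1L, min_box_width = 25.6) {
  stopifnot(insertions >= 1e4)
  sys <- build_sim_system(structure, guest, ff, min_box_width)
  set.seed(seed)
  w <- widom_cpp(sys[setdiff(names(sys), "supercell")], T, as.integer(insertions))
  beta <- 1 / (.kB_Pa_A3 * T)
  list(henry = beta * w$mean_boltzmann, se = beta * w$se_boltzmann,
       mean_boltzmann = w$mean_boltzmann, se_boltzmann = w$se_boltzmann,
       beta = beta)
}

#' Lattice-gas GCMC (exact-isotherm oracle mode)
#'
#' Grand canonical sampling of M independent adsorption sites with site
#' energy `eps_site` at activity `z`; the closed-form isotherm is
#' `<N> = M x / (1 + x)` with `x = z exp(-eps_site/T)`.
#'
#' @param M Number of sites.
#' @param eps_site Site energy in K.
#' @param z Dimensionless activity.
#' @param T Temperature in K.
#' @param steps Total single-site moves.
#' @param equilibration Moves discarded.
#' @param seed RNG seed.
#' @return List with `mean_N`, `var_N`, `exact_N` (closed form), `trace`.
#' @export
run_lattice_gcmc <- function(M, eps_site = 0, z = 1, T = 300,
                             steps = 2e5, equilibration = 2e4, seed = 1L) {
  stopifnot(M >= 1)
  set.seed(seed)
  r <- lattice_gcmc_cpp(as.integer(M), eps_site, z, T,
                        as.integer(steps), as.integer(equilibration))
  list(mean_N = r$mean_N, var_N = r$var_N,
       exact_N = M * r$theta_exact, trace = r$trace)
}

#' Convert a mean guest count to mg/g and wt.% loading
#'
#' `mg/g = 1000 N M_guest / M_box`; `wt.% = 100 m_drug / (m_drug +
#' m_framework)`, so a loading of 1 g drug per g framework (1000 mg/g) is
#' exactly 50 wt.%.
#'
#' @param mean_N Average guest count per simulation box.
#' @param guest_molar_mass g/mol.
#' @param framework_mass_per_box g/mol for the same box.
#' @return List with `mg_per_g` and `wt_percent`.
#' @examples
#' loading_conversions(10, 263.2, 2632)  # 1000 mg/g, 50 wt.%
#' @export
loading_conversions <- function(mean_N, guest_molar_mass, framework_mass_per_box) {
  stopifnot(framework_mass_per_box > 0, guest_molar_mass > 0, mean_N >= 0)
  mg <- 1000 * mean_N * guest_molar_mass / framework_mass_per_box
  list(mg_per_g = mg, wt_percent = 100 * mg / (1000 + mg))
}
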