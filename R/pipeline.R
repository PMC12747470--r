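# The hierarchical screening cascade: biocompatibility -> porosity -> GCMC
# loading -> threshold. Every input structure ends in exactly one terminal
# state with a recorded reason; survivor counts are monotone along the
# cascade.

#' Screening configuration
#'
#' @param threshold_mg_per_g Loading threshold; the default 1000 mg/g
#'   (1 g drug per g framework) is the 50 wt.% bar.
#' @param T,fugacity,cycles,equilibration,seed GCMC settings (see
#'   [gcmc_config()]).
#' @param spacing Distance-grid spacing for pore descriptors (Angstrom).
#' @param volume_samples Monte-Carlo samples for accessible volume.
#' @param whitelist Metal symbols admitted at the biocompatibility stage
#'   despite an adverse table verdict (e.g. `c("Fe", "Zn")`).
#' @param require_all_drugs A framework passes overall only if it passes
#'   the threshold for every drug (default TRUE; set FALSE for an
#'   any-drug reading).
#' @param min_box_width Minimum GCMC supercell width (Angstrom).
#' @param use_accessibility_mask Pre-reject GCMC insertions outside the
#'   percolating void component.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(threshold_mg_per_g = 1000, T = 298, fugacity = 1e5,
                          cycles = 2000L, equilibration = 500L, seed = 1L,
                          spacing = 0.35, volume_samples = 10000L,
                          whitelist = character(), require_all_drugs = TRUE,
                          min_box_width = 25.6,
                          use_accessibility_mask = TRUE) {
  stopifnot(threshold_mg_per_g > 0)
  structure(list(threshold_mg_per_g = threshold_mg_per_g, T = T,
                 fugacity = fugacity, cycles = as.integer(cycles),
                 equilibration = as.integer(equilibration),
                 seed = as.integer(seed), spacing = spacing,
                 volume_samples = as.integer(volume_samples),
                 whitelist = whitelist,
                 require_all_drugs = require_all_drugs,
                 min_box_width = min_box_width,
                 use_accessibility_mask = use_accessibility_mask),
            class = "screen_config")
}

#' Apply the loading threshold
#'
#' @param loadings_mg_per_g Numeric vector of loadings.
#' @param threshold_mg_per_g Threshold (inclusive).
#' @return Logical vector.
#' @examples
#' apply_loading_threshold(c(1200, 1000, 800))  # TRUE TRUE FALSE
#' @export
apply_loading_threshold <- function(loadings_mg_per_g, threshold_mg_per_g = 1000) {
  stopifnot(threshold_mg_per_g > 0)
  !is.na(loadings_mg_per_g) & loadings_mg_per_g >= threshold_mg_per_g
}

#' Screen a structure library through the hierarchical cascade
#'
#' Each structure is deconstructed and assessed for biocompatibility; the
#' survivors are tested against the porosity gate for each drug (PLD vs
#' that drug's minimal diameter); surviving (structure, drug) pairs get a
#' GCMC loading estimate; finally the loading threshold is applied per
#' drug and overall. Failures are recorded with reasons, never dropped,
#' and per-structure work is order-independent.
#'
#' @param structures List of [periodic_structure()] (entries may also be
#'   CIF file paths, read on the fly; a failing read becomes an error
#'   record, not an exception).
#' @param drugs Named list of [rigid_guest()] models.
#' @param model A trained `toxicity_model`.
#' @param config A [screen_config()].
#' @param ff A [forcefield()].
#' @param metal_table From [load_metal_table()].
#' @return Object of class `screening_report`: `records` (one per
#'   structure), `survivors` (per-stage counts), `scatter` (data frame:
#'   structure x drug with accessible pore volume, PLD, LCD and loading -
#'   the loading-vs-pore-volume table), `config`.
#' @export
screen_library <- function(structures, drugs, model, config = screen_config(),
                           ff = forcefield(), metal_table = load_metal_table()) {
  if (!length(structures)) stop("empty structure library", call. = FALSE)
  if (!length(drugs)) stop("no drugs configured", call. = FALSE)
  if (is.null(names(drugs))) {
    names(drugs) <- vapply(drugs, function(d) d$name, character(1))
  }
  records <- lapply(structures, function(s) {
    screen_one(s, drugs, model, config, ff, metal_table)
  })
  names(records) <- vapply(records, function(r) r$name, character(1))
  stages <- vapply(records, function(r) r$stage_reached, character(1))
  survivors <- c(
    input = length(records),
    biocompat = sum(stages %in% c("porosity", "loading", "passed")),
    porosity = sum(stages %in% c("loading", "passed")),
    threshold = sum(stages == "passed")
  )
  scatter <- do.call(rbind, lapply(records, function(r) {
    if (is.null(r$gcmc)) return(NULL)
    do.call(rbind, lapply(names(r$gcmc), function(d) {
      g <- r$gcmc[[d]]
      data.frame(structure = r$name, drug = d,
                 pore_volume_cm3_per_g = r$pores$accessible_volume,
                 pld = r$pores$pld, lcd = r$pores$lcd,
                 loading_mg_per_g = g$loading_mg_per_g,
                 loading_wt_percent = g$loading_wt_percent,
                 mean_N = g$mean_N, se_N = g$se_N,
                 passes_threshold = isTRUE(r$passes_threshold[[d]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(scatter) <- NULL
  structure(list(records = records, survivors = survivors,
                 scatter = scatter, config = config),
            class = "screening_report")
}

screen_one <- function(s, drugs, model, config, ff, metal_table) {
  if (is.character(s)) {
    s <- tryCatch(suppressWarnings(read_cif(s)), error = function(e) e)
    if (inherits(s, "error")) {
      return(list(name = "unreadable", stage_reached = "error",
                  reason = conditionMessage(s)))
    }
  }
  rec <- list(name = s$name, stage_reached = "biocompat", reason = NULL,
              seed = config$seed)
  bio <- tryCatch({
    blocks <- split_building_blocks(s)
    assess_mof_biocompatibility(blocks, model, metal_table,
                                whitelist = config$whitelist)
  }, error = function(e) e)
  if (inherits(bio, "error")) {
    rec$stage_reached <- "error"
    rec$reason <- conditionMessage(bio)
    return(rec)
  }
  rec$biocompatibility <- bio
  if (bio$verdict != "highly biocompatible") {
    rec$reason <- paste("biocompatibility:",
                        paste(bio$failures, collapse = "; "))
    return(rec)
  }
  # porosity stage (probe radius 0 for the volume; the gate is per drug)
  pores <- pore_descriptors(s, spacing = config$spacing, probe_radius = 0,
                            samples = config$volume_samples,
                            seed = config$seed)
  rec$pores <- pores
  gate <- vapply(drugs, function(d) {
    porosity_filter(pores, d$minimal_diameter)
  }, logical(1))
  rec$porosity_pass <- gate
  if (!any(gate)) {
    rec$stage_reached <- "porosity"
    rec$reason <- sprintf("porosity: PLD %.2f A below every drug's minimal diameter",
                          pores$pld)
    return(rec)
  }
  if (config$require_all_drugs && !all(gate)) {
    rec$stage_reached <- "porosity"
    rec$reason <- sprintf("porosity: PLD %.2f A excludes drug(s) %s",
                          pores$pld,
                          paste(names(drugs)[!gate], collapse = ", "))
    return(rec)
  }
  # loading stage
  rec$stage_reached <- "loading"
  gcfg <- gcmc_config(T = config$T, fugacity = config$fugacity,
                      cycles = config$cycles,
                      equilibration = config$equilibration,
                      seed = config$seed,
                      min_box_width = config$min_box_width)
  rec$gcmc <- lapply(drugs[gate], function(d) {
    mask <- if (config$use_accessibility_mask) {
      accessibility_mask(s, probe_radius = d$minimal_diameter / 2,
                         min_box_width = config$min_box_width)
    } else NULL
    run_gcmc(s, d, ff, gcfg, access_mask = mask)
  })
  rec$passes_threshold <- lapply(rec$gcmc, function(g) {
    apply_loading_threshold(g$loading_mg_per_g, config$threshold_mg_per_g)
  })
  pass_vec <- unlist(rec$passes_threshold)
  overall <- if (config$require_all_drugs) {
    all(gate) && all(pass_vec)
  } else any(pass_vec)
  if (overall) {
    rec$stage_reached <- "passed"
  } else {
    rec$reason <- sprintf("threshold: loading below %.0f mg/g for drug(s) %s",
                          config$threshold_mg_per_g,
                          paste(names(pass_vec)[!pass_vec], collapse = ", "))
  }
  rec
}

#' @export
print.screening_report <- function(x, ...) {
  cat("screening_report:\n  survivors:",
      paste(sprintf("%s %d", names(x$survivors), x$survivors),
            collapse = " -> "), "\n")
  for (r in x$records) {
    cat(sprintf("  %-18s %-10s %s\n", r$name, r$stage_reached,
                r$reason %||% ""))
  }
  invisible(x)
}

#' Loading-vs-pore-volume regression
#'
#' Least-squares fit of loading (mg/g) against accessible pore volume
#' (cm^3/g), restricted to records above the PLD knee (PLD at least the
#' guest's minimal diameter) - the regime where uptake scales with volume.
#'
#' @param report A [screen_library()] report (or its `scatter` table).
#' @param drug Drug name to fit (default: first in the table).
#' @param guest_min_diameter PLD knee in Angstrom; defaults to 0 (all
#'   records in the scatter already passed the gate).
#' @return List with `slope`, `intercept`, `r_squared`, `n`, `knee`,
#'   `excluded` (row count below the knee), or `insufficient_data = TRUE`
#'   when fewer than 3 points remain.
#' @export
loading_volume_regression <- function(report, drug = NULL,
                                      guest_min_diameter = 0) {
  tab <- if (inherits(report, "screening_report")) report$scatter else report
  if (is.null(tab) || !nrow(tab)) {
    return(list(insufficient_data = TRUE, n = 0))
  }
  if (is.null(drug)) drug <- tab$drug[1]
  tab <- tab[tab$drug == drug, , drop = FALSE]
  keep <- tab$pld >= guest_min_diameter
  fittab <- tab[keep, , drop = FALSE]
  if (nrow(fittab) < 3) {
    return(list(insufficient_data = TRUE, n = nrow(fittab),
                knee = guest_min_diameter, excluded = sum(!keep)))
  }
  fit <- stats::lm(loading_mg_per_g ~ pore_volume_cm3_per_g, data = fittab)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # degenerate flat fits warn
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = nrow(fittab), knee = guest_min_diameter, excluded = sum(!keep),
       insufficient_data = FALSE)
}

#' Export a screening report
#'
#' Writes `report.csv` (one row per structure x drug, including
#' pre-loading failures with their reasons), `report.json` (full audit)
#' and `scatter.csv` (the loading-vs-pore-volume table) with deterministic
#' field order; re-export of the same report is byte-identical.
#'
#' @param report A [screen_library()] report.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "screening_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(report$records, function(r) {
    data.frame(structure = r$name, stage_reached = r$stage_reached,
               reason = r$reason %||% "", stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$structure), , drop = FALSE]
  p1 <- file.path(dir, "report.csv")
  utils::write.csv(rows, p1, row.names = FALSE)
  p2 <- file.path(dir, "scatter.csv")
  sc <- report$scatter
  if (!is.null(sc) && nrow(sc)) sc <- sc[order(sc$structure, sc$drug), , drop = FALSE]
  utils::write.csv(sc, p2, row.names = FALSE)
  p3 <- file.path(dir, "report.json")
  audit <- list(
    survivors = as.list(report$survivors),
    config = unclass(report$config),
    records = lapply(report$records, function(r) {
      list(name = r$name, stage_reached = r$stage_reached,
           reason = r$reason %||% "",
           loadings = if (!is.null(r$gcmc)) {
             lapply(r$gcmc, function(g) {
               list(mean_N = g$mean_N, se_N = g$se_N,
                    mg_per_g = g$loading_mg_per_g,
                    wt_percent = g$loading_wt_percent,
                    inaccessible = g$inaccessible)
             })
           } else NULL)
    }))
  jsonlite::write_json(audit, p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3))
}
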