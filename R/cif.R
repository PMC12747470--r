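# Minimal crystallographic CIF reader/writer covering the subset emitted by
# structure databases: cell parameters, symmetry operators in xyz notation
# (both `_symmetry_equiv_pos_as_xyz` and `_space_group_symop_operation_xyz`
# dialects), and the atom-site loop. If no symmetry loop is present the
# structure is taken as P1.

#' Parse a CIF document into a periodic structure
#'
#' Reads cell parameters and the atom-site loop from a CIF document, applies
#' any listed symmetry operators, merges duplicate symmetry images (closer
#' than `merge_tol` under minimum image), wraps fractional coordinates into
#' `[0, 1)` and strips oxidation-state suffixes from type symbols
#' (`"Zr4+"` is read as `"Zr"`).
#'
#' Sites with occupancy below 1 are rejected: partially occupied (disordered)
#' frameworks are outside the screening scope.
#'
#' @param text CIF document as a single string or character vector of lines.
#' @param merge_tol Distance below which symmetry images are considered the
#'   same site (Angstrom, default 0.1).
#' @return A [periodic_structure()].
#' @examples
#' doc <- write_cif(make_cubic_framework(a = 10))
#' parse_cif(doc)
#' @export
parse_cif <- function(text, merge_tol = 0.1) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)

  name <- sub("^data_", "", grep("^data_", lines, value = TRUE)[1])
  if (is.na(name) || !nzchar(name)) name <- "structure"

  get_num <- function(tag) {
    ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    val <- trimws(sub(paste0("^", tag), "", ln[1]))
    as.numeric(sub("\\(.*\\)", "", val))  # strip esd parentheses
  }
  a <- get_num("_cell_length_a"); b <- get_num("_cell_length_b")
  cc <- get_num("_cell_length_c")
  al <- get_num("_cell_angle_alpha"); be <- get_num("_cell_angle_beta")
  ga <- get_num("_cell_angle_gamma")
  if (anyNA(c(a, b, cc))) {
    stop("CIF format error: missing cell-parameter block", call. = FALSE)
  }
  if (is.na(al)) al <- 90; if (is.na(be)) be <- 90; if (is.na(ga)) ga <- 90
  cell <- unit_cell(a, b, cc, al, be, ga)

  loops <- cif_loops(lines)

  # symmetry operators (either dialect); default P1
  symops <- "x, y, z"
  for (lp in loops) {
    hit <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
                lp$tags)
    if (length(hit)) {
      symops <- vapply(lp$rows, function(r) gsub("['\"]", "", r[[hit[1]]]),
                       character(1))
      break
    }
  }

  site_loop <- NULL
  for (lp in loops) {
    if (any(grepl("^_atom_site_fract_x$", lp$tags))) { site_loop <- lp; break }
  }
  if (is.null(site_loop) || !length(site_loop$rows)) {
    stop("CIF empty-structure error: no atom sites listed", call. = FALSE)
  }
  col <- function(tag) match(tag, site_loop$tags)
  i_lab <- col("_atom_site_label"); i_typ <- col("_atom_site_type_symbol")
  i_x <- col("_atom_site_fract_x"); i_y <- col("_atom_site_fract_y")
  i_z <- col("_atom_site_fract_z"); i_occ <- col("_atom_site_occupancy")
  i_chg <- col("_atom_site_charge")
  num <- function(s) as.numeric(sub("\\(.*\\)", "", s))

  rows <- site_loop$rows
  raw <- data.frame(
    label = vapply(rows, function(r) if (!is.na(i_lab)) r[[i_lab]] else NA_character_, character(1)),
    type = vapply(rows, function(r) {
      if (!is.na(i_typ)) r[[i_typ]] else if (!is.na(i_lab)) r[[i_lab]] else NA_character_
    }, character(1)),
    fx = vapply(rows, function(r) num(r[[i_x]]), numeric(1)),
    fy = vapply(rows, function(r) num(r[[i_y]]), numeric(1)),
    fz = vapply(rows, function(r) num(r[[i_z]]), numeric(1)),
    occ = vapply(rows, function(r) if (!is.na(i_occ)) num(r[[i_occ]]) else 1, numeric(1)),
    charge = vapply(rows, function(r) if (!is.na(i_chg)) num(r[[i_chg]]) else 0, numeric(1)),
    stringsAsFactors = FALSE
  )
  raw$occ[is.na(raw$occ)] <- 1
  if (any(raw$occ < 1 - 1e-6)) {
    stop("CIF disorder error: site(s) with occupancy < 1 (",
         paste(unique(raw$label[raw$occ < 1 - 1e-6]), collapse = ", "),
         "); only ordered structures are screened", call. = FALSE)
  }
  element <- normalize_element(sub("^([A-Za-z]{1,2}).*$", "\\1", raw$type))
  check_elements(element)

  ops <- lapply(symops, parse_symop)
  expanded <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    p <- c(raw$fx[i], raw$fy[i], raw$fz[i])
    imgs <- unique(do.call(rbind, lapply(ops, function(op) {
      wrap_frac(as.vector(op$R %*% p + op$t))
    })))
    data.frame(element = element[i], fx = imgs[, 1], fy = imgs[, 2],
               fz = imgs[, 3], charge = raw$charge[i],
               label = if (is.na(raw$label[i])) element[i] else raw$label[i],
               stringsAsFactors = FALSE)
  }))

  # merge duplicate images across operators/sites (brute-force: desk scale)
  keep <- rep(TRUE, nrow(expanded))
  fr <- as.matrix(expanded[, c("fx", "fy", "fz")])
  for (i in seq_len(nrow(expanded))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(expanded)) > i)
    for (k in j) {
      if (min_image_distance(cell, fr[i, ], fr[k, ]) < merge_tol) keep[k] <- FALSE
    }
  }
  periodic_structure(cell, expanded[keep, , drop = FALSE], name = name)
}

# Parse one xyz symmetry operator ("-y+1/2, x-y, z") into rotation R and
# translation t acting on fractional coordinates.
parse_symop <- function(op) {
  comps <- trimws(strsplit(tolower(op), ",", fixed = TRUE)[[1]])
  if (length(comps) != 3L) stop("malformed symmetry operator: ", op, call. = FALSE)
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (i in 1:3) {
    s <- gsub(" ", "", comps[i])
    if (!grepl("^[xyz0-9+./-]+$", s)) {
      stop("malformed symmetry operator component: ", comps[i], call. = FALSE)
    }
    # split into signed terms
    terms <- regmatches(s, gregexpr("[+-]?[^+-]+", s))[[1]]
    for (tm in terms) {
      sign <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (body %in% c("x", "y", "z")) {
        R[i, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        f <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        t[i] <- t[i] + sign * f[1] / f[2]
      } else {
        t[i] <- t[i] + sign * as.numeric(body)
      }
    }
  }
  list(R = R, t = t)
}

#' Write a periodic structure as a P1 CIF document
#'
#' Emits an explicit P1 description (every site listed, identity symmetry)
#' with fixed column order and 6 decimal places on fractional coordinates,
#' so that `parse_cif(write_cif(s))` round-trips losslessly to that
#' precision.
#'
#' @param structure A [periodic_structure()].
#' @param path Optional file path; when given the document is also written
#'   to disk (UTF-8).
#' @return The CIF document as a single string, invisibly when `path` is
#'   given.
#' @export
write_cif <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "periodic_structure"))
  cell <- structure$cell
  nm <- gsub("[^A-Za-z0-9_-]", "_", structure$name)
  if (!nzchar(nm)) nm <- "structure"
  s <- structure$sites
  hdr <- c(
    paste0("data_", nm),
    "_symmetry_space_group_name_H-M   'P 1'",
    sprintf("_cell_length_a    %.6f", cell$a),
    sprintf("_cell_length_b    %.6f", cell$b),
    sprintf("_cell_length_c    %.6f", cell$c),
    sprintf("_cell_angle_alpha %.6f", cell$alpha),
    sprintf("_cell_angle_beta  %.6f", cell$beta),
    sprintf("_cell_angle_gamma %.6f", cell$gamma),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "  'x, y, z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_charge"
  )
  body <- if (nrow(s)) {
    sprintf("%-8s %-4s %.6f %.6f %.6f 1.0 %.6f",
            gsub("\\s", "_", s$label), s$element, s$fx, s$fy, s$fz, s$charge)
  } else character()
  doc <- paste(c(hdr, body, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' @rdname parse_cif
#' @param path Path to a CIF file on disk.
#' @export
read_cif <- function(path, merge_tol = 0.1) {
  parse_cif(readLines(path, warn = FALSE, encoding = "UTF-8"), merge_tol)
}

# Split CIF lines into loop_ blocks: list(tags = character, rows = list of
# character vectors). Quoted values with spaces are supported.
cif_loops <- function(lines) {
  loops <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (identical(lines[i], "loop_")) {
      i <- i + 1L
      tags <- character()
      while (i <= n && startsWith(lines[i], "_")) {
        tags <- c(tags, strsplit(lines[i], "\\s+")[[1]][1])
        i <- i + 1L
      }
      rows <- list()
      while (i <= n && nzchar(lines[i]) && !startsWith(lines[i], "_") &&
             !identical(lines[i], "loop_") && !startsWith(lines[i], "data_")) {
        vals <- cif_tokens(lines[i])
        # values may wrap over lines until the row is complete
        while (length(vals) < length(tags) && i + 1L <= n &&
               nzchar(lines[i + 1L]) && !startsWith(lines[i + 1L], "_") &&
               !identical(lines[i + 1L], "loop_")) {
          i <- i + 1L
          vals <- c(vals, cif_tokens(lines[i]))
        }
        if (length(vals)) rows[[length(rows) + 1L]] <- as.list(vals)
        i <- i + 1L
      }
      loops[[length(loops) + 1L]] <- list(tags = tags, rows = rows)
    } else {
      i <- i + 1L
    }
  }
  loops
}

cif_tokens <- function(line) {
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}
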