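# Element reference data used across the package: atomic masses, covalent
# radii (Cordero-type), van der Waals radii (Bondi-type with common
# extensions), metal/non-metal classification, and Gasteiger-Marsili PEOE
# electronegativity coefficients.

.element_data <- local({
  # symbol, atomic mass (g/mol), covalent radius (A), vdW radius (A), metal?
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
symbol mass    rcov  rvdw  metal
H      1.008   0.31  1.20  FALSE
He     4.003   0.28  1.40  FALSE
Li     6.941   1.28  1.82  TRUE
Be     9.012   0.96  1.53  TRUE
B      10.811  0.84  1.92  FALSE
C      12.011  0.76  1.70  FALSE
N      14.007  0.71  1.55  FALSE
O      15.999  0.66  1.52  FALSE
F      18.998  0.57  1.47  FALSE
Ne     20.180  0.58  1.54  FALSE
Na     22.990  1.66  2.27  TRUE
Mg     24.305  1.41  1.73  TRUE
Al     26.982  1.21  1.84  TRUE
Si     28.086  1.11  2.10  FALSE
P      30.974  1.07  1.80  FALSE
S      32.065  1.05  1.80  FALSE
Cl     35.453  1.02  1.75  FALSE
Ar     39.948  1.06  1.88  FALSE
K      39.098  2.03  2.75  TRUE
Ca     40.078  1.76  2.31  TRUE
Sc     44.956  1.70  2.11  TRUE
Ti     47.867  1.60  2.14  TRUE
V      50.942  1.53  2.12  TRUE
Cr     51.996  1.39  2.06  TRUE
Mn     54.938  1.39  2.05  TRUE
Fe     55.845  1.32  2.04  TRUE
Co     58.933  1.26  2.00  TRUE
Ni     58.693  1.24  1.97  TRUE
Cu     63.546  1.32  1.96  TRUE
Zn     65.380  1.22  2.01  TRUE
Ga     69.723  1.22  1.87  TRUE
Ge     72.640  1.20  2.11  FALSE
As     74.922  1.19  1.85  FALSE
Se     78.960  1.20  1.90  FALSE
Br     79.904  1.20  1.85  FALSE
Kr     83.798  1.16  2.02  FALSE
Rb     85.468  2.20  3.03  TRUE
Sr     87.620  1.95  2.49  TRUE
Y      88.906  1.90  2.32  TRUE
Zr     91.224  1.75  2.23  TRUE
Nb     92.906  1.64  2.18  TRUE
Mo     95.960  1.54  2.17  TRUE
Tc     98.000  1.47  2.16  TRUE
Ru     101.070 1.46  2.13  TRUE
Rh     102.906 1.42  2.10  TRUE
Pd     106.420 1.39  2.10  TRUE
Ag     107.868 1.45  2.11  TRUE
Cd     112.411 1.44  2.18  TRUE
In     114.818 1.42  1.93  TRUE
Sn     118.710 1.39  2.17  TRUE
Sb     121.760 1.39  2.06  FALSE
Te     127.600 1.38  2.06  FALSE
I      126.904 1.39  1.98  FALSE
Xe     131.293 1.40  2.16  FALSE
Cs     132.905 2.44  3.43  TRUE
Ba     137.327 2.15  2.68  TRUE
La     138.905 2.07  2.43  TRUE
Ce     140.116 2.04  2.42  TRUE
Pr     140.908 2.03  2.40  TRUE
Nd     144.242 2.01  2.39  TRUE
Sm     150.360 1.98  2.36  TRUE
Eu     151.964 1.98  2.35  TRUE
Gd     157.250 1.96  2.34  TRUE
Tb     158.925 1.94  2.33  TRUE
Dy     162.500 1.92  2.31  TRUE
Ho     164.930 1.92  2.30  TRUE
Er     167.259 1.89  2.29  TRUE
Tm     168.934 1.90  2.27  TRUE
Yb     173.054 1.87  2.26  TRUE
Lu     174.967 1.87  2.24  TRUE
Hf     178.490 1.75  2.23  TRUE
Ta     180.948 1.70  2.22  TRUE
W      183.840 1.62  2.18  TRUE
Re     186.207 1.51  2.16  TRUE
Os     190.230 1.44  2.16  TRUE
Ir     192.217 1.41  2.13  TRUE
Pt     195.084 1.36  2.13  TRUE
Au     196.967 1.36  2.14  TRUE
Hg     200.590 1.32  2.23  TRUE
Tl     204.383 1.45  1.96  TRUE
Pb     207.200 1.46  2.02  TRUE
Bi     208.980 1.48  2.07  TRUE
Th     232.038 2.06  2.45  TRUE
U      238.029 1.96  2.41  TRUE
")
  rownames(tab) <- tab$symbol
  tab
})

# Gasteiger-Marsili electronegativity polynomials chi(q) = a + b q + c q^2,
# keyed by element and (for C, N, O) hybridization: sp3/sp2/sp.
.peoe_params <- local({
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
key    a      b      c
H      7.17   6.24  -0.56
C.sp3  7.98   9.18   1.88
C.sp2  8.79   9.32   1.51
C.sp   10.39  9.45   0.73
N.sp3  11.54  10.82  1.36
N.sp2  12.87  11.15  0.85
N.sp   15.68  11.70 -0.27
O.sp3  14.18  12.92  1.39
O.sp2  17.07  13.79  0.47
F      14.66  13.85  2.31
Cl     11.00  9.69   1.35
Br     10.08  8.47   1.16
I      9.90   7.96   0.96
S      10.14  9.13   1.38
P      8.90   8.24   0.96
B      5.98   6.82   1.61
Si     7.30   6.57   0.66
")
  rownames(tab) <- tab$key
  tab
})

check_elements <- function(elements, what = "element") {
  bad <- setdiff(unique(elements), rownames(.element_data))
  if (length(bad)) {
    stop(sprintf("unrecognized %s symbol(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(elements)
}

#' Atomic masses, radii and metal classification
#'
#' Accessors for the packaged element table: atomic masses (g/mol),
#' covalent radii and van der Waals radii (Angstrom), and a metal /
#' non-metal classification covering alkali, alkaline-earth, transition and
#' post-transition metals, lanthanides and actinides.
#'
#' @param elements Character vector of element symbols (e.g. `"Zr"`).
#' @return Numeric vector (masses, radii) or logical vector (`is_metal`),
#'   one entry per input symbol.
#' @examples
#' atomic_mass(c("C", "H", "O"))
#' is_metal(c("Zr", "C"))
#' @export
atomic_mass <- function(elements) {
  check_elements(elements)
  stats::setNames(.element_data[elements, "mass"], elements)
}

#' @rdname atomic_mass
#' @export
covalent_radius <- function(elements) {
  check_elements(elements)
  stats::setNames(.element_data[elements, "rcov"], elements)
}

#' @rdname atomic_mass
#' @export
vdw_radius <- function(elements) {
  check_elements(elements)
  stats::setNames(.element_data[elements, "rvdw"], elements)
}

#' @rdname atomic_mass
#' @export
is_metal <- function(elements) {
  check_elements(elements)
  stats::setNames(.element_data[elements, "metal"], elements)
}

#' Molar mass of a molecular formula
#'
#' Sums tabulated atomic masses over a Hill-style formula string such as
#' `"C9H11F2N3O4"` (gemcitabine).
#'
#' @param formula Character scalar, element symbols each followed by an
#'   optional count.
#' @return Molar mass in g/mol.
#' @examples
#' formula_mass("C9H11F2N3O4")  # 263.2
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || paste(parts, collapse = "") != formula) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(sub("^[A-Z][a-z]?", "", parts))
  n[is.na(n)] <- 1L
  sum(atomic_mass(el) * n)
}

# Strip oxidation-state / charge suffixes from CIF type symbols: "Zr4+" -> "Zr",
# "O2-" -> "O", "Fe3+" -> "Fe"; also normalizes case.
normalize_element <- function(symbols) {
  s <- sub("[0-9]*[+-]*$", "", symbols)
  s <- paste0(toupper(substring(s, 1, 1)), tolower(substring(s, 2)))
  s
}
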