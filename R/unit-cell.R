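# Triclinic unit cells, fractional <-> Cartesian conversion, and the
# periodic minimum-image metric.

#' Construct a unit cell
#'
#' A triclinic unit cell described by lengths `a`, `b`, `c` (Angstrom) and
#' angles `alpha`, `beta`, `gamma` (degrees). The derived 3x3 lattice matrix
#' has the lattice vectors as rows (standard crystallographic convention:
#' `a` along x, `b` in the xy plane), so Cartesian coordinates are
#' `frac %*% lattice`.
#'
#' @param a,b,c Cell lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with elements `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, `lattice` (3x3 matrix, rows are lattice
#'   vectors in Angstrom) and `volume` (Angstrom^3).
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' cell$volume  # 1000
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("cell lengths must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  # standard triclinic lattice construction
  v1 <- c(a, 0, 0)
  v2 <- c(b * cg, b * sg, 0)
  cz2 <- 1 - cb^2 - ((ca - cb * cg) / sg)^2
  if (cz2 <= 0) stop("degenerate cell: angles admit no positive volume", call. = FALSE)
  v3 <- c(c * cb, c * (ca - cb * cg) / sg, c * sqrt(cz2))
  lattice <- rbind(a = v1, b = v2, c = v3)
  colnames(lattice) <- c("x", "y", "z")
  vol <- det(lattice)
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         lattice = lattice, volume = vol),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit_cell: a=%.4f b=%.4f c=%.4f A, alpha=%.2f beta=%.2f gamma=%.2f deg, V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

is_orthogonal_cell <- function(cell, tol = 1e-9) {
  all(abs(c(cell$alpha, cell$beta, cell$gamma) - 90) < tol)
}

#' Convert between fractional and Cartesian coordinates
#'
#' @param cell A [unit_cell()].
#' @param frac,cart Numeric matrix (n x 3) or length-3 vector of coordinates.
#' @return An n x 3 matrix of converted coordinates.
#' @export
frac_to_cart <- function(cell, frac) {
  frac <- rbind_coords(frac)
  frac %*% cell$lattice
}

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(cell, cart) {
  cart <- rbind_coords(cart)
  cart %*% solve(cell$lattice)
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  stopifnot(ncol(x) == 3)
  x
}

#' Wrap fractional coordinates into [0, 1)
#'
#' @param frac Numeric matrix (n x 3) or length-3 vector.
#' @return Coordinates with each component reduced modulo 1.
#' @export
wrap_frac <- function(frac) {
  frac <- rbind_coords(frac)
  w <- frac - floor(frac)
  w[w >= 1] <- 0  # guards 1 - eps rounding
  w
}

#' Minimum-image distance between two fractional points
#'
#' Distance under periodic boundary conditions, minimized over the 27
#' nearest periodic images. This is exact whenever the cell's perpendicular
#' widths are at least twice the distance of interest; for extremely skewed
#' cells and large distances more distant images could in principle win, a
#' regime no routine in this package operates in (supercells are always
#' expanded first, see [build_supercell()]).
#'
#' @param cell A [unit_cell()].
#' @param frac_p,frac_q Fractional coordinates (length-3), wrapped to [0,1).
#' @return Distance in Angstrom.
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' min_image_distance(cell, c(0.1, 0, 0), c(0.9, 0, 0))  # 2
#' @export
min_image_distance <- function(cell, frac_p, frac_q) {
  d <- wrap_frac(frac_q) - wrap_frac(frac_p)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dc <- (matrix(d, nrow = 27, ncol = 3, byrow = TRUE) + shifts) %*% cell$lattice
  sqrt(min(rowSums(dc^2)))
}

# Perpendicular widths of the cell along each lattice direction:
# width_i = V / area(face spanned by the other two vectors).
cell_perpendicular_widths <- function(cell) {
  L <- cell$lattice
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  areas <- c(sqrt(sum(cross(L[2, ], L[3, ])^2)),
             sqrt(sum(cross(L[3, ], L[1, ])^2)),
             sqrt(sum(cross(L[1, ], L[2, ])^2)))
  cell$volume / areas
}
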