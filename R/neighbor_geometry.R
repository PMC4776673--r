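#' Build a cell list for fast neighbor queries
#'
#' Atoms are hashed into a cubic grid whose cell side is
#' `2 * (max(radii) + probe_radius)`, so that any pair of atoms whose
#' solvent-extended spheres intersect is found in the same or an adjacent
#' cell.  This makes contact detection linear in the number of atoms.
#'
#' @param coordinates numeric n x 3 matrix of atom centers (Angstrom).
#' @param radii numeric vector of n atomic radii (Angstrom), all >= 0.
#' @param probe_radius probe sphere radius (Angstrom), >= 0.
#' @return An object of class `"cell_list"`: a list with elements
#'   `cell_side`, `origin`, `grid_shape` and `cell_membership` (a list of
#'   integer vectors of 1-based atom indices, one per cell, in column-major
#'   grid order).
#' @seealso [neighbors()]
#' @export
#' @examples
#' cl <- build_cell_list(matrix(rnorm(30), 10, 3), rep(2, 10), 1.4)
#' cl$grid_shape
build_cell_list <- function(coordinates, radii, probe_radius = 1.4) {
  coordinates <- as_coord_matrix(coordinates)
  n <- nrow(coordinates)
  if (n < 1L) stop("cell list requires at least one atom", call. = FALSE)
  radii <- as.numeric(radii)
  if (length(radii) != n) stop("length(radii) must equal nrow(coordinates)", call. = FALSE)
  if (any(!is.finite(coordinates))) stop("coordinates must be finite", call. = FALSE)
  if (any(radii < 0)) stop("radii must be non-negative", call. = FALSE)
  if (probe_radius < 0) stop("probe_radius must be non-negative", call. = FALSE)
  cl <- cpp_cell_list(coordinates, radii, probe_radius)
  structure(cl, class = "cell_list")
}

#' Neighbors of one atom via a cell list
#'
#' Returns the indices `j != atom_index` whose solvent-extended spheres
#' intersect that of the query atom: `||x_i - x_j|| < r_i + r_j + 2 * probe`.
#' The inequality is strict, so exactly tangent spheres are not neighbors
#' (a tangent sphere occludes a set of measure zero).
#'
#' @inheritParams build_cell_list
#' @param cell_list a `"cell_list"` built from the same coordinates.
#' @param atom_index 1-based index of the query atom.
#' @return Sorted integer vector of neighbor indices (possibly empty).
#' @export
neighbors <- function(cell_list, coordinates, radii, probe_radius, atom_index) {
  coordinates <- as_coord_matrix(coordinates)
  n <- nrow(coordinates)
  if (length(atom_index) != 1L || is.na(atom_index) ||
      atom_index < 1L || atom_index > n)
    stop("atom_index out of range", call. = FALSE)
  i <- as.integer(atom_index)
  side <- cell_list$cell_side
  org <- cell_list$origin
  shp <- cell_list$grid_shape
  ci <- pmin(pmax(floor((coordinates[i, ] - org) / side), 0), shp - 1L)
  cand <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    cc <- ci + c(dx, dy, dz)
    if (any(cc < 0) || any(cc >= shp)) next
    idx <- cc[1] + shp[1] * (cc[2] + shp[2] * cc[3]) + 1
    cand <- c(cand, cell_list$cell_membership[[idx]])
  }
  cand <- cand[cand != i]
  if (!length(cand)) return(integer(0))
  d <- sqrt(colSums((t(coordinates[cand, , drop = FALSE]) - coordinates[i, ])^2))
  cut <- radii[i] + radii[cand] + 2 * probe_radius
  sort(cand[d < cut])
}

#' Near-uniform points on the unit sphere via the Fibonacci spiral
#'
#' Point k of n (k = 0, ..., n-1) is placed at height
#' `z_k = 1 - (2k + 1)/n` and azimuth `k * pi * (3 - sqrt(5))` (the golden
#' angle).  The lattice approximates an even distribution for any n and is
#' deterministic, which makes Shrake & Rupley results reproducible.
#'
#' @param n number of points, >= 1.
#' @return An object of class `"sphere_points"`: a list with `points`
#'   (n x 3 matrix of unit vectors) and `count`.
#' @export
#' @examples
#' sp <- fibonacci_sphere(100)
#' range(sqrt(rowSums(sp$points^2)))  # all 1
fibonacci_sphere <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  k <- seq_len(n) - 1
  z <- 1 - (2 * k + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  structure(list(points = cbind(r * cos(phi), r * sin(phi), z), count = n),
            class = "sphere_points")
}

# coerce coordinate input (matrix, data.frame, or flat xyz vector) to n x 3
as_coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) %% 3 != 0)
      stop("flat coordinate vector length must be a multiple of 3", call. = FALSE)
    x <- matrix(x, ncol = 3, byrow = TRUE)
  }
  if (ncol(x) != 3) stop("coordinates must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  unname(x)
}
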