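#' Seeded random sphere packing
#'
#' Uniform centers in a cubic box and uniform radii in a range, fully
#' determined by the seed (the global RNG state is saved and restored).
#' Used as synthetic input for convergence and property checks.
#'
#' @param n number of spheres, >= 1.
#' @param box_side box edge length, Angstrom.
#' @param radius_range length-2 numeric, min and max radius.
#' @param seed integer seed.
#' @return An object of class `"packing"`: list with `coordinates`
#'   (n x 3), `radii`, `seed`.
#' @export
#' @examples
#' p <- random_packing(50, 20, c(1.5, 2), seed = 1)
#' identical(p$coordinates, random_packing(50, 20, c(1.5, 2), seed = 1)$coordinates)
random_packing <- function(n, box_side, radius_range = c(1.5, 2.0), seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (box_side <= 0) stop("box_side must be positive", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  coords <- matrix(runif(3 * n, 0, box_side), ncol = 3)
  radii <- runif(n, radius_range[1], radius_range[2])
  structure(list(coordinates = coords, radii = radii, seed = as.integer(seed)),
            class = "packing")
}

#' Exact SASA of two spheres
#'
#' Closed-form solvent accessible areas of a pair of spheres with probe:
#' with extended radii `R_k = r_k + probe` and center distance `d`,
#' disjoint spheres (`d >= R1 + R2`) are fully exposed (`4*pi*R^2` each);
#' if one extended sphere contains the other, the inner area is 0; for
#' partial overlap each sphere loses a spherical cap of height
#' `h_k = R_k - (d^2 + R_k^2 - R_other^2) / (2d)`, leaving
#' `2*pi*R_k*(2*R_k - h_k)`.
#'
#' @param c1,c2 length-3 centers, Angstrom.
#' @param r1,r2 sphere radii, Angstrom (> 0).
#' @param probe probe radius, Angstrom (>= 0).
#' @return Numeric length-2 vector `(area1, area2)`, Angstrom^2.
#' @export
#' @examples
#' two_sphere_analytic(c(1, 1, 1), 2, c(2, 2, 2), 3, 1.4)
two_sphere_analytic <- function(c1, r1, c2, r2, probe = 1.4) {
  if (r1 <= 0 || r2 <= 0) stop("radii must be positive", call. = FALSE)
  R1 <- r1 + probe
  R2 <- r2 + probe
  d <- sqrt(sum((as.numeric(c1) - as.numeric(c2))^2))
  full <- 4 * pi * c(R1, R2)^2
  if (d >= R1 + R2) return(full)
  if (d + R1 <= R2) return(c(0, full[2]))
  if (d + R2 <= R1) return(c(full[1], 0))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(2 * pi * R1 * (2 * R1 - h1), 2 * pi * R2 * (2 * R2 - h2))
}

#' Render a packing as toy PDB text
#'
#' Each sphere becomes a fixed-column ATOM record with generic identity
#' (residue `DUM`, atom `C`, element C, chain A), one residue per atom.
#' Useful for exercising the parser and the end-to-end pipeline without
#' real structure files.
#'
#' @param packing a `"packing"` from [random_packing()], or an n x 3
#'   coordinate matrix.
#' @param chain_id chain identifier for the generated records.
#' @return Character vector of PDB lines.
#' @export
toy_pdb <- function(packing, chain_id = "A") {
  xyz <- if (inherits(packing, "packing")) packing$coordinates
         else as_coord_matrix(packing)
  n <- nrow(xyz)
  sprintf("ATOM  %5d  C   DUM %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          seq_len(n), chain_id, seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3])
}

#' Poly-alanine toy PDB text
#'
#' An extended poly-alanine chain (N, CA, C, O, CB per residue) with
#' plausible geometry, every atom classifiable by the ProtOr set without
#' element fallback.
#'
#' @param n_res number of alanine residues, >= 1.
#' @param chain_id chain identifier.
#' @return Character vector of PDB lines.
#' @export
#' @examples
#' s <- read_pdb(poly_ala_pdb(5))
#' nrow(s$atoms)  # 25
poly_ala_pdb <- function(n_res, chain_id = "A") {
  if (n_res < 1) stop("n_res must be >= 1", call. = FALSE)
  # idealized local offsets of one alanine, residues spaced 3.8 A along x
  template <- list(
    c("N", "N", 0.00, 0.00, 0.00),
    c("CA", "C", 1.46, 0.00, 0.00),
    c("C", "C", 2.00, 1.42, 0.00),
    c("O", "O", 1.25, 2.39, 0.00),
    c("CB", "C", 2.20, -0.76, 1.20))
  lines <- character(0)
  serial <- 0L
  for (res in seq_len(n_res)) {
    shift <- (res - 1) * 3.8
    flip <- if (res %% 2 == 0) -1 else 1        # alternate side chains
    for (a in template) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %s ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, format_atom_name(a[1]), chain_id, res,
        as.numeric(a[3]) + shift, as.numeric(a[4]) * flip,
        as.numeric(a[5]) * flip, a[2]))
    }
  }
  lines
}
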