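# independent oracles and fixture builders used across the suite

# O(n^2) all-pairs neighbor scan (oracle for the cell-list implementation)
brute_force_neighbors <- function(coords, radii, probe, i) {
  d <- sqrt(colSums((t(coords) - coords[i, ])^2))
  cut <- radii[i] + radii + 2 * probe
  out <- which(d < cut)
  sort(out[out != i])
}

# Monte-Carlo surface-point integration of the two-sphere SASA
mc_two_sphere <- function(c1, r1, c2, r2, probe, n_pts = 20000, seed = 42) {
  set.seed(seed)
  R1 <- r1 + probe
  R2 <- r2 + probe
  u <- matrix(rnorm(3 * n_pts), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  p1 <- sweep(u * R1, 2, as.numeric(c1), "+")
  f1 <- mean(sqrt(colSums((t(p1) - as.numeric(c2))^2)) > R2)
  p2 <- sweep(u * R2, 2, as.numeric(c2), "+")
  f2 <- mean(sqrt(colSums((t(p2) - as.numeric(c1))^2)) > R1)
  list(area = c(4 * pi * R1^2 * f1, 4 * pi * R2^2 * f2),
       # binomial standard error propagated to the area scale
       se = c(4 * pi * R1^2 * sqrt(f1 * (1 - f1) / n_pts),
              4 * pi * R2^2 * sqrt(f2 * (1 - f2) / n_pts)))
}

# a small two-chain structure: two poly-alanine strands, optionally close
# enough to bury surface at the interface
two_chain_structure <- function(n_res = 4, separation = 5) {
  a <- poly_ala_pdb(n_res, chain_id = "A")
  b <- poly_ala_pdb(n_res, chain_id = "B")
  # shift chain B along y by rewriting its y column
  sb <- read_pdb(b)
  sb$atoms$y <- sb$atoms$y + separation
  b2 <- sprintf(
    "ATOM  %5d %s ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    sb$atoms$serial + 1000L, sasar:::format_atom_name(sb$atoms$name), "B",
    sb$atoms$residue_number, sb$atoms$x, sb$atoms$y, sb$atoms$z,
    sb$atoms$element)
  assign_radii(read_pdb(c(a, b2)))
}

# rigid rotation about z by angle theta
rotate_z <- function(coords, theta) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  coords %*% t(R)
}
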