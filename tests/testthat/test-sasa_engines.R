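test_that("an isolated sphere is exact for both engines at any resolution", {
  exact <- 4 * pi * 3.4^2
  for (ns in c(1, 7, 20, 100))
    expect_equal(sasa_lee_richards(c(0, 0, 0), 2, 1.4, ns), exact)
  for (np in c(1, 10, 100))
    expect_equal(sasa_shrake_rupley(c(0, 0, 0), 2, 1.4, np), exact)
})

test_that("the two-sphere case converges to the spherical-cap closed form", {
  xyz <- c(1, 1, 1, 2, 2, 2)
  exact <- two_sphere_analytic(c(1, 1, 1), 2, c(2, 2, 2), 3, 1.4)
  lr <- sasa_lee_richards(xyz, c(2, 3), 1.4, 1000)
  expect_true(all(abs(lr - exact) / exact < 0.001))
  sr <- sasa_shrake_rupley(xyz, c(2, 3), 1.4, 5000)
  expect_true(all(abs(sr - exact) / exact < 0.005))
})

test_that("a sphere inside another has exactly zero area", {
  for (alg in c("lee_richards", "shrake_rupley")) {
    r <- calc_sasa_coords(c(0, 0, 0, 0, 0, 0), c(1, 3),
                          sasa_params(alg, n_slices = 17, n_points = 64))
    expect_identical(r$per_atom_area[1], 0)
    expect_equal(r$per_atom_area[2], 4 * pi * 4.4^2)
  }
})

test_that("coincident equal spheres resolve by the deterministic tie-break", {
  for (alg in c("lee_richards", "shrake_rupley")) {
    r <- calc_sasa_coords(c(5, 5, 5, 5, 5, 5), c(2, 2), sasa_params(alg))
    expect_equal(r$per_atom_area[1], 4 * pi * 3.4^2)  # lower index wins
    expect_identical(r$per_atom_area[2], 0)
  }
})

test_that("per-atom areas respect the sphere-area bounds on random packings", {
  for (seed in 1:5) {
    p <- random_packing(80, 18, c(1.2, 2.2), seed = seed)
    for (alg in c("lee_richards", "shrake_rupley")) {
      r <- calc_sasa_coords(p$coordinates, p$radii, sasa_params(alg))
      expect_true(all(r$per_atom_area >= 0))
      expect_true(all(r$per_atom_area <= 4 * pi * (p$radii + 1.4)^2 + 1e-9))
      expect_equal(r$total, sum(r$per_atom_area))
    }
  }
})

test_that("appending an atom never increases any existing atom's area", {
  p <- random_packing(40, 12, c(1.5, 2), seed = 23)
  extra <- matrix(c(6, 6, 6), 1, 3)
  for (alg in c("lee_richards", "shrake_rupley")) {
    par <- sasa_params(alg)
    before <- calc_sasa_coords(p$coordinates, p$radii, par)$per_atom_area
    after <- calc_sasa_coords(rbind(p$coordinates, extra), c(p$radii, 1.8),
                              par)$per_atom_area
    expect_true(all(after[1:40] <= before + 1e-12))
  }
})

test_that("areas are bitwise invariant under translation and worker count", {
  p <- random_packing(60, 15, c(1.5, 2), seed = 5)
  # dyadic coordinates and shifts make the translated positions exactly
  # representable, so any area change would reveal translation-dependent
  # state (e.g. grid-origin effects) rather than rounding
  p$coordinates <- round(p$coordinates * 1024) / 1024
  shift <- c(13.75, -201.5, 55.125)
  for (alg in c("lee_richards", "shrake_rupley")) {
    par1 <- sasa_params(alg, n_workers = 1)
    par4 <- sasa_params(alg, n_workers = 4)
    base <- calc_sasa_coords(p$coordinates, p$radii, par1)$per_atom_area
    moved <- calc_sasa_coords(sweep(p$coordinates, 2, shift, "+"), p$radii,
                              par1)$per_atom_area
    expect_identical(moved, base)
    expect_identical(calc_sasa_coords(p$coordinates, p$radii, par4)$per_atom_area,
                     base)
  }
})

test_that("rotation changes areas by less than 1% at comparable resolutions", {
  p <- random_packing(60, 15, c(1.5, 2), seed = 9)
  # default L&R (20 slices) and S&R at its equivalent-accuracy resolution
  # (about 1000 points); coarser point counts have a larger discretization
  # wobble by design
  pars <- list(sasa_params("lee_richards"),
               sasa_params("shrake_rupley", n_points = 1000))
  for (par in pars) {
    base <- calc_sasa_coords(p$coordinates, p$radii, par)$total
    rot <- calc_sasa_coords(rotate_z(p$coordinates, 0.83), p$radii, par)$total
    expect_lt(abs(rot - base) / base, 0.01)
  }
})

test_that("high-resolution runs of the two engines agree per atom", {
  p <- random_packing(100, 16, c(1.5, 2), seed = 31)
  lr <- sum(sasa_lee_richards(p$coordinates, p$radii, 1.4, 1000))
  sr <- sum(sasa_shrake_rupley(p$coordinates, p$radii, 1.4, 5000))
  expect_lt(error_per_atom(sr, lr, 100), 0.05)
})

test_that("a single atom's area increases strictly with probe radius", {
  probes <- c(0, 0.7, 1.4, 2.0)
  areas <- vapply(probes, function(p)
    sum(sasa_lee_richards(c(0, 0, 0), 1.8, p, 20)), numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("structure dispatch checks radii and preserves atom order", {
  s <- read_pdb(poly_ala_pdb(4))
  expect_error(calc_sasa(s), "unassigned")
  s <- assign_radii(s)
  r <- calc_sasa(s)
  expect_equal(length(r$per_atom_area), nrow(s$atoms))
  direct <- calc_sasa_coords(cbind(s$atoms$x, s$atoms$y, s$atoms$z),
                             s$atoms$radius)
  expect_identical(r$per_atom_area, direct$per_atom_area)
  expect_s3_class(r$parameters_used, "sasa_params")
})

test_that("error_per_atom computes |A - A_ref| / N", {
  expect_equal(error_per_atom(100, 100, 10), 0)
  expect_equal(error_per_atom(110, 100, 10), 1.0)
  expect_equal(error_per_atom(90, 100, 10), 1.0)
  expect_error(error_per_atom(1, 1, 0))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(sasa_params(probe_radius = -1))
  expect_error(sasa_params(n_slices = 0))
  expect_error(sasa_params(n_points = 0))
  expect_error(sasa_params(n_workers = 0))
  p <- sasa_params()
  expect_equal(p$algorithm, "lee_richards")
  expect_equal(p$probe_radius, 1.4)
  expect_equal(p$n_slices, 20L)
  expect_equal(p$n_workers, 2L)
})
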