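# Rasterization, the Helmholtz grid solver and the near-to-far transform.

test_that("rasterization: homogeneous map, disc area, center-point limit", {
  sc <- scene(list(), n_med = 1.35, extent = c(-2e-6, 2e-6, -2e-6, 2e-6))
  map <- rasterize_scene(sc, 0.1e-6, boundary_width = 1e-6)
  expect_true(all(map$n2 == 1.35^2))
  # disc area from permittivity averaging
  a <- 1e-6
  scd <- make_single_cylinder(a, 1.42, 1.35)
  mapd <- rasterize_scene(scd, 0.1e-6, subsampling = 10, boundary_width = 1e-6)
  area <- sum(mapd$n2 - 1.35^2) * mapd$dx^2 / (1.42^2 - 1.35^2)
  expect_equal(area, pi * a^2, tolerance = 10 / 10^2)
  # subsampling = 1 equals center-point rasterization
  map1 <- rasterize_scene(scd, 0.1e-6, subsampling = 1, boundary_width = 1e-6)
  xs <- map1$origin[1] + (seq_len(nrow(map1$n2)) - 1) * map1$dx
  ys <- map1$origin[2] + (seq_len(ncol(map1$n2)) - 1) * map1$dx
  inside <- outer(xs^2, ys^2, "+") <= a^2
  expect_equal(map1$n2, ifelse(inside, 1.42^2, 1.35^2))
})

test_that("homogeneous map returns the incident field", {
  sc <- scene(list(), n_med = 1.35, extent = c(-3e-6, 3e-6, -3e-6, 3e-6))
  map <- rasterize_scene(sc, 0.1e-6, boundary_width = 3e-6)
  kmed <- 2 * pi * 1.35 / 1.3e-6
  inc <- plane_wave_grid(map, kmed, 0.2)
  sol <- helmholtz_solve(map, inc, 2 * pi / 1.3e-6)
  expect_lt(sqrt(sum(Mod(sol$scattered)^2) / sum(Mod(inc)^2)), 1e-5)
  expect_equal(sol$total, inc)
})

test_that("line source radiates an isotropic far field of known amplitude", {
  k <- 2 * pi * 1.35 / 1.3e-6
  ctr <- circle_contour(3e-6, 400,
                        function(tt) rep((1i / 4) * hank(0, k * 3e-6), length(tt)),
                        function(tt) rep(-(1i / 4) * k * hank(1, k * 3e-6),
                                         length(tt)))
  A <- near_to_far(ctr, k, seq(0, 2 * pi, length.out = 33)[-33])
  expect_lt(stats::sd(Mod(A)) / mean(Mod(A)), 1e-6)
  expect_equal(mean(A), (1i / 4) * exp(-1i * pi / 4), tolerance = 1e-6)
})

test_that("analytic near field on a contour reproduces the series far field", {
  kmed <- 2 * pi * 1.35 / 1.3e-6
  co <- cylinder_series_coefficients(1.42 / 1.35, kmed * 1e-6, "perpendicular")
  nf <- function(R) {
    s <- series_near_field(co, kmed, R, seq(0, 2 * pi, length.out = 721)[-721])
    circle_contour(R, 720, function(tt) s$val, function(tt) s$dval)
  }
  phis <- seq(0, 2 * pi, length.out = 181)[-181]
  Fs <- cylinder_scattering_amplitude(co, phis)
  A1 <- near_to_far(nf(3e-6), kmed, phis)
  expect_lt(sqrt(sum(Mod(A1 - Fs)^2) / sum(Mod(Fs)^2)), 1e-4)
  # contour-radius independence (2x radius)
  A2 <- near_to_far(nf(6e-6), kmed, phis)
  expect_lt(max(Mod(A1 - A2)) / max(Mod(A1)), 1e-6)
})

test_that("grid solver matches the series on a weak off-center cylinder", {
  lam0 <- 1.3e-6; k0 <- 2 * pi / lam0; kmed <- k0 * 1.35
  a <- 0.8e-6
  ctr_off <- c(0.9e-6, -0.7e-6)
  scn <- scene(list(list(type = "disc", center = ctr_off, radius = a,
                         index = 1.40)),
               n_med = 1.35, extent = c(-4e-6, 4e-6, -4e-6, 4e-6))
  map <- rasterize_scene(scn, lam0 / 16, boundary_width = 8e-6)
  inc <- plane_wave_grid(map, kmed, 0)
  sol <- helmholtz_solve(map, inc, k0)
  expect_lte(sol$residual, solver_config()$tolerance)
  gc <- grid_contour(map, sol$scattered, 3.4e-6)
  phis <- seq(0, 2 * pi, length.out = 241)[-241]
  Ag <- near_to_far(gc, kmed, phis)
  co <- cylinder_series_coefficients(1.40 / 1.35, kmed * a, "perpendicular")
  # series amplitude translated to the offset center
  Fs <- cylinder_scattering_amplitude(co, phis) *
    exp(1i * kmed * ((1 - cos(phis)) * ctr_off[1] - sin(phis) * ctr_off[2]))
  expect_lt(sqrt(sum(Mod(Ag - Fs)^2) / sum(Mod(Fs)^2)), 0.02)
})

test_that("gmres scheme solves the same problem within tolerance", {
  lam0 <- 1.3e-6; k0 <- 2 * pi / lam0; kmed <- k0 * 1.35
  scn <- make_single_cylinder(0.6e-6, 1.42, 1.35)
  map <- rasterize_scene(scn, lam0 / 13, boundary_width = 6e-6)
  inc <- plane_wave_grid(map, kmed, 0)
  s1 <- helmholtz_solve(map, inc, k0,
                        solver_config(scheme = "convergent_born"))
  s2 <- helmholtz_solve(map, inc, k0, solver_config(scheme = "gmres_fdfd"))
  expect_lte(s2$residual, 1e-5)
  expect_lt(max(Mod(s1$scattered - s2$scattered)) /
              max(Mod(s1$scattered)), 1e-3)
})

test_that("non-convergence is reported with the residual", {
  lam0 <- 1.3e-6; k0 <- 2 * pi / lam0
  scn <- make_single_cylinder(0.6e-6, 1.42, 1.35)
  map <- rasterize_scene(scn, lam0 / 13, boundary_width = 6e-6)
  inc <- plane_wave_grid(map, k0 * 1.35, 0)
  expect_error(helmholtz_solve(map, inc, k0,
                               solver_config(max_iterations = 3,
                                             fallback = FALSE)),
               "residual")
})

test_that("plane-wave reciprocity holds on an asymmetric two-cylinder map", {
  # reciprocity is exact in the continuum; on the grid it holds to the
  # discretization error (rasterized boundaries, contour quadrature), which
  # must shrink under refinement
  lam0 <- 1.3e-6; k0 <- 2 * pi / lam0; kmed <- k0 * 1.35
  scn <- scene(list(list(type = "disc", center = c(-0.9e-6, 0.8e-6),
                         radius = 0.5e-6, index = 1.42),
                    list(type = "disc", center = c(1.1e-6, -0.4e-6),
                         radius = 0.7e-6, index = 1.40)),
               n_med = 1.35, extent = c(-3.4e-6, 3.4e-6, -3.4e-6, 3.4e-6))
  th_in <- 0.25; th_out <- 2.1
  recip_err <- function(res) {
    map <- rasterize_scene(scn, lam0 / res, boundary_width = 7e-6)
    amp <- function(ti, to) {
      sol <- helmholtz_solve(map, plane_wave_grid(map, kmed, ti), k0)
      near_to_far(grid_contour(map, sol$scattered, 2.9e-6), kmed, to)
    }
    a12 <- amp(th_in, th_out)
    a21 <- amp(th_out + pi, th_in + pi)
    Mod(a12 - a21) / Mod(a12)
  }
  e16 <- recip_err(16)
  e32 <- recip_err(32)
  expect_lt(e16, 0.05)
  expect_lt(e32, e16 / 2)
})

test_that("optical theorem holds for the grid solution", {
  lam0 <- 1.3e-6; k0 <- 2 * pi / lam0; kmed <- k0 * 1.35
  a <- 1e-6
  scn <- make_single_cylinder(a, 1.42, 1.35)
  scn$extent <- c(-4e-6, 4e-6, -4e-6, 4e-6)
  map <- rasterize_scene(scn, lam0 / 24, boundary_width = 8e-6)
  inc <- plane_wave_grid(map, kmed, 0)
  sol <- helmholtz_solve(map, inc, k0)
  gc <- grid_contour(map, sol$scattered, 3.4e-6)
  n <- 720
  phis <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  A <- near_to_far(gc, kmed, phis)
  csca <- 2 / (pi * kmed) * sum(Mod(A)^2) * 2 * pi / n
  # forward amplitude via the optical theorem (lossless medium)
  cext <- -4 / kmed * Re(exp(1i * pi / 4) * A[1])
  expect_equal(cext, csca, tolerance = 0.01)
})
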