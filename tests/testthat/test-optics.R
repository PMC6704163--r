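# Source, lens train and reference arm.

test_that("fiber mode field has the stated values and energy", {
  mode <- fiber_mode(w0 = 4.6e-6, E0 = 2)
  expect_equal(fiber_mode_field(0, mode), 2)
  expect_equal(fiber_mode_field(mode$w0, mode), 2 / exp(1))
  # energy by adaptive quadrature against the closed form E0^2 w0 sqrt(pi/2)
  en <- integrate(function(y) Mod(fiber_mode_field(y, mode))^2,
                  -8 * mode$w0, 8 * mode$w0, rel.tol = 1e-10)$value
  expect_equal(en, mode$E0^2 * mode$w0 * sqrt(pi / 2), tolerance = 1e-8)
})

test_that("field on the first lens matches the angular-spectrum quadrature", {
  sys <- default_system(); mode <- default_mode()
  k <- 2 * pi / 1.3e-6
  # on-axis closed form
  expect_equal(field_on_first_lens(0, k, mode, sys),
               mode$E0 * mode$w0 / sqrt(2i * sys$f1 / k + mode$w0^2) *
                 exp(1i * k * sys$f1))
  # even in y
  ys <- c(0.5e-3, 1.5e-3, 3e-3)
  expect_equal(Mod(field_on_first_lens(ys, k, mode, sys)),
               Mod(field_on_first_lens(-ys, k, mode, sys)))
  # paraxial angular-spectrum integral as independent oracle (dense trapezoid;
  # the integrand is a chirped Gaussian in ky)
  oracle <- function(y) {
    lim <- 8 / mode$w0   # integrand support (Gaussian in ky)
    ky <- seq(-lim, lim, length.out = 80001)
    v <- exp(-ky^2 * mode$w0^2 / 4 + 1i * ky * y +
               1i * (k - ky^2 / (2 * k)) * sys$f1)
    h <- ky[2] - ky[1]
    (sum(v) - (v[1] + v[length(v)]) / 2) * h *
      mode$E0 * mode$w0 / (sqrt(2 * pi) * sqrt(2))
  }
  for (y in c(0, 1e-3, 3.5e-3)) {
    expect_lt(Mod(field_on_first_lens(y, k, mode, sys) - oracle(y)) /
                Mod(oracle(y)), 1e-3)
  }
})

test_that("midplane field matches the Fresnel quadrature and its width readoff", {
  sys <- default_system(); mode <- default_mode()
  k <- 2 * pi / 1.3e-6
  w <- 2 * sys$f1 / (k * mode$w0)
  expect_equal(Mod(midplane_field(w, k, mode, sys)) /
                 Mod(midplane_field(0, k, mode, sys)), exp(-1),
               tolerance = 1e-12)
  ph <- Arg(midplane_field(0, k, mode, sys))
  expect_equal(exp(1i * ph), exp(1i * (Arg(1 - 1i) + 2 * k * sys$f1)),
               tolerance = 1e-10)
  # Fresnel integral of (field on lens) x (lens transmission) as oracle
  lam <- 2 * pi / k
  oracle <- function(y) {
    g <- function(xi, part) {
      u <- field_on_first_lens(xi, k, mode, sys) *
        exp(-1i * k * xi^2 / (2 * sys$f1)) *
        exp(1i * k * sys$f1 * (1 + 0.5 * ((y - xi) / sys$f1)^2))
      if (part == "re") Re(u) else Im(u)
    }
    lim <- 6e-3
    (integrate(g, -lim, lim, part = "re", rel.tol = 1e-11,
               subdivisions = 2000L)$value +
       1i * integrate(g, -lim, lim, part = "im", rel.tol = 1e-11,
                      subdivisions = 2000L)$value) *
      exp(-1i * pi / 4) / sqrt(lam * sys$f1)
  }
  for (y in c(0, 1e-3, 2.5e-3)) {
    expect_lt(Mod(midplane_field(y, k, mode, sys) - oracle(y)) /
                Mod(oracle(y)), 1e-3)
  }
})

test_that("aperture half-angle follows the sine condition", {
  sys <- optical_system(h = 3.5e-3, f2 = 36e-3)
  expect_equal(aperture_half_angle(sys), asin(3.5 / 36), tolerance = 1e-12)
  expect_equal(asin(3.5 / 36), 0.09737, tolerance = 1e-4)
  # the tangent convention would differ by < 0.5 %
  expect_lt(abs(atan(3.5 / 36) - asin(3.5 / 36)) / asin(3.5 / 36), 0.005)
  expect_error(optical_system(h = 40e-3, f2 = 36e-3), "geometry")
  expect_equal(aperture_half_angle(optical_system(h = 1e-9)), 1e-9 / 36e-3,
               tolerance = 1e-6)
})

test_that("Debye-Wolf focus: symmetry, channel separation, refined quadrature", {
  sys <- default_system(); mode <- default_mode()
  k <- 2 * pi / 1.3e-6
  g <- gauss_nodes_test <- pracma::gaussLegendre(201, -sys$alpha_max, sys$alpha_max)
  fld <- midplane_field(sys$f2 * sin(g$x), k, mode, sys)
  ys <- seq(1e-6, 8e-6, length.out = 5)
  Ep <- debye_wolf_focus(g$x, g$w, fld, k, 0, ys, "perpendicular", sys)
  Em <- debye_wolf_focus(g$x, g$w, fld, k, 0, -ys, "perpendicular", sys)
  expect_equal(Mod(Ep[, "Ez"]), Mod(Em[, "Ez"]), tolerance = 1e-10)
  # perpendicular input produces no in-plane components, and vice versa
  expect_true(all(Ep[, c("Ex", "Ey")] == 0))
  Epar <- debye_wolf_focus(g$x, g$w, fld, k, 0, ys, "parallel", sys)
  expect_true(all(Epar[, "Ez"] == 0))
  expect_gt(max(Mod(Epar[, "Ey"])), 0)
  # off-focus point against a 10x-refined quadrature
  g2 <- pracma::gaussLegendre(2010, -sys$alpha_max, sys$alpha_max)
  fld2 <- midplane_field(sys$f2 * sin(g2$x), k, mode, sys)
  a1 <- debye_wolf_focus(g$x, g$w, fld, k, 10e-6, 3e-6, "perpendicular", sys)
  a2 <- debye_wolf_focus(g2$x, g2$w, fld2, k, 10e-6, 3e-6, "perpendicular", sys)
  expect_lt(Mod(a1[, "Ez"] - a2[, "Ez"]) / Mod(a2[, "Ez"]), 1e-6)
  expect_error(debye_wolf_focus(numeric(0), numeric(0), complex(0), k, 0, 0,
                                "perpendicular", sys), "empty")
})

test_that("focal spot narrows monotonically with aperture", {
  mode <- default_mode()
  k <- 2 * pi / 1.3e-6
  fwhm <- vapply(c(2e-3, 3.5e-3, 5e-3), function(h) {
    sys <- optical_system(h = h)
    g <- pracma::gaussLegendre(201, -sys$alpha_max, sys$alpha_max)
    fld <- midplane_field(sys$f2 * sin(g$x), k, mode, sys)
    ys <- seq(0, 25e-6, length.out = 600)
    I <- Mod(debye_wolf_focus(g$x, g$w, fld, k, 0, ys, "perpendicular",
                              sys)[, "Ez"])^2
    2 * ys[which(I < max(I) / 2)[1]]
  }, numeric(1))
  expect_true(all(diff(fwhm) < 0))
})

test_that("reference far field: cylindrical decay and far-field limit", {
  sys <- default_system(); mode <- default_mode()
  k <- 2 * pi / 1.3e-6
  r1 <- reference_arm_far_field(0.02, 1e-3, k, "perpendicular", sys, mode)
  r4 <- reference_arm_far_field(0.02, 4e-3, k, "perpendicular", sys, mode)
  expect_equal(unname(Mod(r1[, "Ez"]) / Mod(r4[, "Ez"])), 2, tolerance = 1e-12)
  expect_error(reference_arm_far_field(0, -1, k, "perpendicular", sys, mode),
               "positive")
  # sqrt(cos) factor at alpha = 0 is 1: amplitude equals the on-axis density
  r0 <- reference_arm_far_field(0, 1e-3, k, "perpendicular", sys, mode)
  dens <- beam_angular_amplitude(0, k, mode, sys)
  expect_equal(unname(Mod(r0[, "Ez"])),
               Mod(dens * pi * sqrt(2 / (pi * k * 1e-3))), tolerance = 1e-12)
  # brute-force Debye-Wolf propagation converges to the closed form as kl grows
  alpha <- 0.03
  errs <- vapply(c(0.5e-3, 5e-3, 50e-3), function(l) {
    g <- pracma::gaussLegendre(4001, -sys$alpha_max, sys$alpha_max)
    fld <- midplane_field(sys$f2 * sin(g$x), k, mode, sys)
    num <- debye_wolf_focus(g$x, g$w, fld, k, l * cos(alpha), l * sin(alpha),
                            "perpendicular", sys)[, "Ez"]
    cls <- reference_arm_far_field(alpha, l, k, "perpendicular", sys,
                                   mode)[, "Ez"]
    abs(Mod(num) - Mod(cls)) / Mod(cls)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))   # error decreases with distance
  expect_lt(errs[3], 0.01)           # < 1 % amplitude error at k l ~ 2e5
})

test_that("polarisation channels never mix through the chain", {
  sys <- default_system(); mode <- default_mode()
  sp <- tiny_spectrum(4)
  scn <- make_single_cylinder(2e-6, 1.42, 1.35, center = c(0, 1e-6))
  for (pol in c("perpendicular", "parallel")) {
    k <- sp$k[1]
    g <- pracma::gaussLegendre(101, -sys$alpha_max, sys$alpha_max)
    fld <- midplane_field(sys$f2 * sin(g$x), k, mode, sys)
    E <- debye_wolf_focus(g$x, g$w, fld, k, c(0, 2e-6), c(1e-6, -3e-6), pol, sys)
    if (pol == "perpendicular") {
      expect_identical(max(Mod(E[, c("Ex", "Ey")])), 0)
    } else {
      expect_identical(max(Mod(E[, "Ez"])), 0)
    }
  }
})
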