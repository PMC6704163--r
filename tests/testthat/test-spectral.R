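# Spectrum construction, coupling, reconstruction, and image metrics.

test_that("spectrum: temporal width, peak, cut-off and range", {
  sp <- build_spectrum(1.3e-6, 170e-9, 1e-3, 160)
  expect_equal(sp$b, 2 * sqrt(log(2)) * (1.3e-6)^2 / (pi * c0 * 170e-9),
               tolerance = 1e-12)
  expect_equal(max(sp$S), sp$b / sqrt(2), tolerance = 1e-12)
  expect_equal(sp$S[1], sp$epsilon * max(sp$S), tolerance = 1e-12)
  expect_equal(sp$S[160], sp$epsilon * max(sp$S), tolerance = 1e-12)
  expect_equal(diff(range(sp$omega)), 4 / sp$b * sqrt(log(1 / sp$epsilon)),
               tolerance = 1e-12)
})

test_that("maximum visible depth agrees with the coarse estimate and is monotone", {
  sp <- build_spectrum()
  d19 <- max_visible_depth(160, sp$b, 1e-3, 1.35)
  # coarse estimate pi/(2 dk) from the wavenumber spacing
  dom <- diff(range(sp$omega)) / (160 - 1)
  d17 <- pi / (2 * dom * 1.35 / c0)
  expect_lt(abs(d19 - d17) / d17, 0.02)
  ds <- vapply(c(40, 80, 160, 320), function(N)
    max_visible_depth(N, sp$b, 1e-3, 1.35), numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("fiber coupling overlap integral", {
  mode <- fiber_mode()
  y <- seq(-5 * mode$w0, 5 * mode$w0, length.out = 4001)
  # Gaussian x Gaussian has the closed form w0 sqrt(pi/2)
  got <- coupling_amplitude(y, exp(-y^2 / mode$w0^2), mode)
  expect_equal(Re(got), mode$w0 * sqrt(pi / 2), tolerance = 1e-8)
  # odd field couples to zero
  expect_lt(Mod(coupling_amplitude(y, y * exp(-y^2 / mode$w0^2),
                                   mode)) / mode$w0^2, 1e-10)
  # smooth field vs 10x-refined quadrature
  f <- function(y) exp(-0.3 * (y / mode$w0)^2 + 2i * y / mode$w0)
  y2 <- seq(-5 * mode$w0, 5 * mode$w0, length.out = 40001)
  expect_equal(coupling_amplitude(y, f(y), mode),
               coupling_amplitude(y2, f(y2), mode), tolerance = 1e-8)
  expect_warning(coupling_amplitude(seq(-mode$w0, mode$w0, length.out = 11),
                                    rep(1, 11), mode), "sampling")
})

test_that("reconstruction: shift theorem, zero delay, Parseval", {
  sp <- build_spectrum(N = 160)
  nmed <- 1.35
  aref <- exp(-((sp$omega - mean(sp$omega)) * sp$b / 4)^2) + 0.2
  for (x0 in c(12e-6, 37e-6)) {
    tau <- 2 * nmed * x0 / c0
    cpl <- spectral_coupling(aref * exp(1i * sp$omega * tau), aref, sp$k)
    a <- reconstruct_ascan(cpl, sp, nmed)
    pk <- a$depth[which.max(a$intensity)]
    expect_lt(abs(pk - x0), diff(a$depth)[1] + 1e-12)   # within one bin
  }
  # zero delay: single peak at depth 0, nothing else above -60 dB outside the
  # coherence envelope of the main peak
  cpl0 <- spectral_coupling(aref, aref, sp$k)
  a0 <- reconstruct_ascan(cpl0, sp, nmed)
  expect_equal(a0$depth[which.max(a0$intensity)], 0)
  away <- abs(a0$depth) > 10e-6
  expect_lt(max(a0$intensity[away]) / max(a0$intensity), 1e-3)
  # Parseval with the 1/sqrt(N) scaling
  z <- sp$S^2 * cpl0$alpha_sca * Conj(cpl0$alpha_ref)
  expect_equal(sum(Mod(z)^2), sum(Mod(a0$complex_signal)^2), tolerance = 1e-12)
  expect_error(reconstruct_ascan(spectral_coupling(aref[-1], aref[-1],
                                                   sp$k[-1]), sp, nmed),
               "match")
})

test_that("a delay beyond t_max aliases to the DFT-predicted depth", {
  sp <- build_spectrum(N = 160)
  nmed <- 1.35
  ctmax <- max_visible_depth(160, sp$b, sp$epsilon, nmed)
  period <- depth_period(sp, nmed)
  aref <- rep(1 + 0i, 160)
  x0 <- ctmax + 13e-6                       # beyond the unambiguous range
  x_alias <- x0 - period                    # exact bin arithmetic prediction
  cpl <- spectral_coupling(aref * exp(1i * sp$omega * 2 * nmed * x0 / c0),
                           aref, sp$k)
  a <- reconstruct_ascan(cpl, sp, nmed)
  pk <- a$depth[which.max(a$intensity)]
  expect_lt(abs(pk - x_alias), diff(a$depth)[1] + 1e-12)
})

test_that("integrated error: identities and the double-loop oracle", {
  set.seed(42)
  A <- matrix(runif(30), 5, 6)
  expect_equal(integrated_error(A, A), 0)
  expect_equal(integrated_error(A, 2 * A), 1)
  B <- matrix(runif(30), 5, 6)
  num <- 0; den <- 0
  for (i in 1:5) for (j in 1:6) {
    num <- num + (A[i, j] - B[i, j])^2
    den <- den + A[i, j]^2
  }
  expect_equal(integrated_error(A, B), sqrt(num) / sqrt(den), tolerance = 1e-15)
  expect_error(integrated_error(matrix(numeric(0), 0, 0), A), "empty")
  # resampling path: a constant image survives bilinear resampling exactly
  C <- matrix(1, 9, 9)
  expect_equal(integrated_error(matrix(1, 5, 5), C), 0)
})

test_that("echo-train tracing follows the measured spacing", {
  # synthetic A-scan: echoes at -4, 6, 16 um with decreasing strength
  d <- seq(-50e-6, 50e-6, length.out = 401)
  I <- exp(-((d + 4e-6) / 1e-6)^2) + 0.8 * exp(-((d - 6e-6) / 1e-6)^2) +
    1e-3 * exp(-((d - 16e-6) / 1e-6)^2)
  a <- structure(list(depth = d, intensity = I), class = "ascan")
  tr <- axial_echo_train(a, orders = 1)
  expect_equal(tr$depth, c(-4e-6, 6e-6, 16e-6), tolerance = 1e-2)
})
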