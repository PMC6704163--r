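# shared fixtures and small analytic helpers for the tests

c0 <- 299792458

default_system <- function(...) optical_system(...)
default_mode <- function() fiber_mode()

# Hankel functions of the first kind and their derivative (scalar order)
hank <- function(n, x) besselJ(x, n) + 1i * besselY(x, n)
hank_d <- function(n, x) if (n == 0) -hank(1, x) else hank(n - 1, x) - n / x * hank(n, x)

# scattered near field of a cylinder (perpendicular pol, plane wave from +x
# direction) from the series coefficients, plus its radial derivative
series_near_field <- function(coef, k, r, phi) {
  nmax <- length(coef) - 1L
  val <- rep(0 + 0i, length(phi)); dval <- val
  for (n in 0:nmax) {
    cn <- if (n == 0) 1 else 2
    val <- val + cn * (1i)^n * coef[n + 1] * hank(n, k * r) * cos(n * phi)
    dval <- dval + cn * (1i)^n * coef[n + 1] * k * hank_d(n, k * r) * cos(n * phi)
  }
  list(val = val, dval = dval)
}

# circle contour carrying an analytic field
circle_contour <- function(R, n, val_fun, dval_fun) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  field_contour(cbind(R * cos(tt), R * sin(tt)),
                cbind(cos(tt), sin(tt)),
                rep(2 * pi * R / n, n),
                val_fun(tt), dval_fun(tt))
}

# small spectra keep the slow chain tests fast
tiny_spectrum <- function(N = 16, epsilon = 1e-3)
  build_spectrum(1.3e-6, 170e-9, epsilon, N)
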