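# Source, lens train and reference arm: Gaussian fiber mode, Fresnel
# propagation through the afocal 4f telescope, cylindrical-lens Debye-Wolf
# focusing, and the closed-form reference-arm far field.

#' Describe the interferometer lens train
#'
#' The sample and reference arms are identical afocal telescopes: a collimating
#' lens of focal length `f1` and a focusing lens of focal length `f2`, with an
#' aperture stop of radius `h` between them. Under the sine condition the stop
#' limits the focusing half-angle in sample space to `alpha_max = asin(h/f2)`.
#'
#' @param f1 focal length of the collimating lenses L1/L3 (m)
#' @param f2 focal length of the focusing lenses L2/L4 (m)
#' @param h aperture radius (m); must satisfy `0 < h < f2`
#' @param n_med background refractive index of the sample medium
#' @param n_debye refractive index used inside the angular limits of the
#'   Debye-Wolf integral when rendering the focused beam. The default of 1
#'   avoids strong side lobes in the displayed beam; pass `n_med` for the
#'   physically consistent choice required when injecting the beam into the
#'   grid solver.
#' @return an object of class `optical_system`
#' @examples
#' sys <- optical_system()
#' sys$alpha_max   # about 0.0974 rad for the default telescope
#' @export
optical_system <- function(f1 = 25e-3, f2 = 36e-3, h = 3.5e-3,
                           n_med = 1.35, n_debye = 1) {
  stopifnot(f1 > 0, f2 > 0, h > 0, n_med >= 1, n_debye > 0)
  if (h >= f2) stop("invalid geometry: aperture radius h must be smaller than f2")
  structure(list(f1 = f1, f2 = f2, h = h,
                 alpha_max = asin(h / f2),
                 n_med = n_med, n_debye = n_debye),
            class = "optical_system")
}

#' @export
print.optical_system <- function(x, ...) {
  cat(sprintf(
    "2D OCT lens train: f1 = %.3g mm, f2 = %.3g mm, h = %.3g mm\n",
    x$f1 * 1e3, x$f2 * 1e3, x$h * 1e3))
  cat(sprintf("  aperture half-angle %.4f rad (NA %.4f), n_med = %.3f\n",
              x$alpha_max, sin(x$alpha_max) * x$n_med, x$n_med))
  invisible(x)
}

#' Aperture half-angle of the focusing lens
#'
#' Maps the aperture radius to the focusing half-angle via the sine condition
#' (`h = f2 sin(alpha)`), as appropriate for aplanatic lenses. The tangent
#' convention `atan(h/f2)` would differ by less than 0.5% at this numerical
#' aperture; it is documented here but not used.
#'
#' @param sys an [optical_system()]
#' @return half-angle in radians
#' @export
aperture_half_angle <- function(sys) {
  stopifnot(inherits(sys, "optical_system"))
  asin(sys$h / sys$f2)
}

#' Describe the single-mode fiber
#'
#' @param w0 half of the fiber mode-field diameter (m)
#' @param E0 peak field amplitude (arbitrary units)
#' @return an object of class `fiber_mode`
#' @export
fiber_mode <- function(w0 = 4.6e-6, E0 = 1) {
  stopifnot(w0 > 0, is.finite(E0), E0 != 0)
  structure(list(w0 = w0, E0 = E0), class = "fiber_mode")
}

#' Validate a polarisation label
#'
#' The two-dimensional geometry decouples the out-of-plane field (E along the
#' cylinder axis, "perpendicular" to the scattering plane) from the in-plane
#' field ("parallel"); the two channels never mix.
#' @noRd
check_pol <- function(pol) match.arg(pol, c("perpendicular", "parallel"))

#' Gaussian mode field at the fiber end face
#'
#' @param y lateral coordinate (m), vectorized
#' @param mode a [fiber_mode()]
#' @return field amplitude `E0 * exp(-y^2/w0^2)`
#' @export
fiber_mode_field <- function(y, mode) {
  mode$E0 * exp(-y^2 / mode$w0^2)
}

#' Field incident on the collimating lens
#'
#' Closed-form paraxial propagation of the Gaussian fiber mode over the focal
#' distance `f1`, i.e. the stationary-phase/paraxial evaluation of the angular
#' spectrum integral. Intended for the well-collimated regime `k*w0 >> 1`.
#'
#' @param y lateral coordinate on the lens (m), vectorized
#' @param k vacuum wavenumber (rad/m)
#' @param mode a [fiber_mode()]
#' @param sys an [optical_system()]
#' @return complex field amplitude
#' @export
field_on_first_lens <- function(y, k, mode, sys) {
  w0 <- mode$w0
  f1 <- sys$f1
  cw <- 2i * f1 / k + w0^2                 # complex Gaussian width parameter
  mode$E0 * w0 / sqrt(cw) * exp(1i * k * f1 - k * y^2 / (2i * f1 + k * w0^2))
}

#' Collimated field in the plane of the aperture stop
#'
#' Closed form of the Fresnel integral that carries the field from the
#' collimating lens to the common focal plane between the lenses (the lens
#' thickness is neglected). The result is a Gaussian of 1/e half-width
#' `2*f1/(k*w0)` with an overall phase `2*k*f1` plus the (1-1i) Fresnel factor.
#'
#' @inheritParams field_on_first_lens
#' @return complex field amplitude
#' @export
midplane_field <- function(y, k, mode, sys) {
  w0 <- mode$w0
  f1 <- sys$f1
  lam <- 2 * pi / k
  (1 - 1i) * w0 * mode$E0 * sqrt(pi) / sqrt(2 * f1 * lam) *
    exp(2i * k * f1 - (y * k * w0 / (2 * f1))^2)
}

#' Angular amplitude density of the focused beam
#'
#' The integrand density of the cylindrical Debye-Wolf integral: the midplane
#' field mapped onto the converging angular spectrum through the sine
#' condition (`y = f2 sin(theta)`), apodized by `sqrt(cos(theta))` and carrying
#' the `sqrt(f2/lambda) * exp(-i pi/4 + i k f2)` prefactor. The focused field
#' is the integral of `angular_amplitude * exp(i k_d (y sin + x cos))` over
#' theta; the same density weights the incident plane waves in the analytic
#' cylinder-scattering path.
#'
#' @param theta focusing angles (rad), `|theta| <= alpha_max`
#' @param k vacuum wavenumber (rad/m)
#' @param mode a [fiber_mode()]
#' @param sys an [optical_system()]
#' @return complex amplitude density per radian
#' @export
beam_angular_amplitude <- function(theta, k, mode, sys) {
  lam <- 2 * pi / k
  sqrt(sys$f2 / lam) * exp(-1i * pi / 4 + 1i * k * sys$f2) *
    sqrt(cos(theta)) * midplane_field(sys$f2 * sin(theta), k, mode, sys)
}

#' Focus a field with the cylindrical-lens Debye-Wolf integral
#'
#' Numerically integrates the one-dimensional Debye-Wolf integral over the
#' converging angular spectrum, for lenses fulfilling the sine condition. The
#' supplied `field` values are the midplane field sampled at `f2 sin(theta)`;
#' the apodization `sqrt(cos theta)` and all prefactors are applied here. For
#' perpendicular polarisation only the out-of-plane component `Ez` is
#' non-zero; for parallel polarisation the lens rotation produces `Ex` and
#' `Ey`. The plane-wave phases inside the integral use `k * n_debye`.
#'
#' @param theta angular quadrature nodes (rad)
#' @param weights quadrature weights matching `theta`
#' @param field complex midplane field at `f2 sin(theta)`
#' @param k vacuum wavenumber (rad/m)
#' @param x,y sample-space evaluation points (m), equal length (recycled)
#' @param pol `"perpendicular"` or `"parallel"`
#' @param sys an [optical_system()]
#' @return complex matrix with columns `Ex`, `Ey`, `Ez`, one row per point
#' @export
debye_wolf_focus <- function(theta, weights, field, k, x, y, pol, sys) {
  pol <- check_pol(pol)
  if (length(theta) == 0L) stop("empty angular grid")
  if (!all(is.finite(Re(field)) & is.finite(Im(field))))
    stop("non-finite input field")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  kd <- k * sys$n_debye
  lam <- 2 * pi / k
  pref <- sqrt(sys$f2 / lam) * exp(-1i * pi / 4 + 1i * k * sys$f2)
  apod <- sqrt(cos(theta)) * weights * field
  # plane-wave synthesis: phase matrix (points x angles)
  ph <- exp(1i * kd * (outer(y, sin(theta)) + outer(x, cos(theta))))
  out <- matrix(0 + 0i, n, 3, dimnames = list(NULL, c("Ex", "Ey", "Ez")))
  if (pol == "perpendicular") {
    out[, "Ez"] <- pref * as.vector(ph %*% apod)
  } else {
    out[, "Ex"] <- pref * as.vector(ph %*% (-sin(theta) * apod))
    out[, "Ey"] <- pref * as.vector(ph %*% (cos(theta) * apod))
  }
  out
}

#' Analytic reference-arm far field
#'
#' Closed form of the field returned by an ideal mirror placed at the focus of
#' the reference-arm telescope: per observation angle one outgoing cylindrical
#' wave whose amplitude is the converging angular density at the same angle,
#' multiplied by `pi * sqrt(2/(pi k l)) * exp(i k l - i pi/4)` (Jacobi-Anger
#' reduction of the Debye-Wolf integral in the far-field limit) and by the
#' mirror reflection coefficient.
#'
#' @param alpha observation angles (rad), `|alpha| <= alpha_max`
#' @param l radial distance from the focus/mirror (m), `l > 0`; far-field
#'   validity requires `k*l >> 1`
#' @param k vacuum wavenumber (rad/m)
#' @param pol `"perpendicular"` or `"parallel"`
#' @param sys an [optical_system()]
#' @param mode a [fiber_mode()] (sets the illuminating midplane field)
#' @param mirror_r complex mirror reflection coefficient (default ideal mirror)
#' @return complex matrix with columns `Ex`, `Ey`, `Ez`
#' @export
reference_arm_far_field <- function(alpha, l, k, pol, sys, mode, mirror_r = 1) {
  pol <- check_pol(pol)
  if (any(l <= 0)) stop("radial distance l must be positive")
  lam <- 2 * pi / k
  e3 <- midplane_field(sys$f2 * sin(alpha), k, mode, sys)
  amp <- sqrt(sys$f2 / lam) * exp(-1i * pi / 4 + 1i * k * sys$f2) *
    sqrt(cos(alpha)) * pi * sqrt(2 / (pi * k * l)) *
    exp(1i * k * l - 1i * pi / 4) * mirror_r
  out <- matrix(0 + 0i, length(alpha), 3,
                dimnames = list(NULL, c("Ex", "Ey", "Ez")))
  if (pol == "perpendicular") {
    out[, "Ez"] <- amp * e3
  } else {
    out[, "Ex"] <- amp * (-sin(alpha) * e3)
    out[, "Ey"] <- amp * (cos(alpha) * e3)
  }
  out
}

#' Reference-arm far-field amplitude in the collection normalization
#'
#' Scalar channel amplitude of the mirror return, defined so that the physical
#' field is `amplitude * sqrt(2/(pi k l)) * exp(i k l)`: the quantity consumed
#' by the detection chain ([couple_far_field()]). For the parallel channel this
#' is the transverse (in-plane) amplitude.
#' @noRd
reference_far_amplitude <- function(alpha, k, mode, sys, mirror_r = 1) {
  pi * exp(-1i * pi / 4) * beam_angular_amplitude(alpha, k, mode, sys) * mirror_r
}
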