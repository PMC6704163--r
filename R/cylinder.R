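# Exact scattering by infinite circular cylinders at normal incidence:
# series coefficients, scattering amplitude, cross-section, and the analytic
# far-field path of the simulator (focused beam in, collection circle out).

# J'_n and Y'_n via the standard recurrence; n is an integer vector, x scalar.
bessel_j_tab <- function(nmax, x) vapply(0:(nmax + 1L), function(n) besselJ(x, n), numeric(1))
bessel_y_tab <- function(nmax, x) vapply(0:(nmax + 1L), function(n) besselY(x, n), numeric(1))

# tables of f_n and f'_n for n = 0..nmax from a table of f_0..f_{nmax+1}
deriv_from_tab <- function(tab, x) {
  nmax <- length(tab) - 2L
  n <- 0:nmax
  f <- tab[n + 1L]
  # f'_n = f_{n-1} - (n/x) f_n; for n = 0, f'_0 = -f_1
  fp <- c(-tab[2L], tab[n[-1L]] - (n[-1L] / x) * tab[n[-1L] + 1L])
  list(f = f, fp = fp)
}

#' Default truncation order for the cylinder series
#'
#' Wiscombe-style rule: `x + 4 x^(1/3) + 2`, rounded up.
#' @param size_param size parameter `k_med * a`
#' @return integer truncation order
#' @export
cylinder_order_max <- function(size_param) {
  as.integer(ceiling(size_param + 4 * size_param^(1 / 3) + 2))
}

#' Scattering coefficients of an infinite cylinder at normal incidence
#'
#' Series coefficients of the outgoing Hankel-function expansion of the field
#' scattered by a homogeneous circular cylinder, for a plane wave at normal
#' incidence. `"perpendicular"` polarisation (E along the cylinder axis) is the
#' transverse-magnetic case; `"parallel"` (E in the scattering plane) is the
#' transverse-electric case solved through the axial magnetic field. The total
#' exterior field is `sum_n i^n (J_n(k rho) + b_n H1_n(k rho)) e^(i n phi)`.
#'
#' @param m_rel relative refractive index `n_cyl / n_med`
#' @param size_param size parameter `k_med * a` (dimensionless, > 0)
#' @param pol `"perpendicular"` or `"parallel"`
#' @param order_max series truncation order; default [cylinder_order_max()]
#' @return complex vector `b_0 .. b_order_max`
#' @export
cylinder_series_coefficients <- function(m_rel, size_param, pol,
                                         order_max = cylinder_order_max(size_param)) {
  pol <- check_pol(pol)
  stopifnot(size_param > 0, m_rel > 0, order_max >= 0)
  if (m_rel == 1) return(rep(0 + 0i, order_max + 1L))
  x <- size_param; m <- m_rel
  jx  <- deriv_from_tab(bessel_j_tab(order_max, x), x)
  yx  <- deriv_from_tab(bessel_y_tab(order_max, x), x)
  jmx <- deriv_from_tab(bessel_j_tab(order_max, m * x), m * x)
  hx  <- jx$f + 1i * yx$f
  hxp <- jx$fp + 1i * yx$fp
  if (!all(is.finite(jmx$f)) || !all(is.finite(hx)))
    stop("non-finite Bessel evaluation; size parameter out of range")
  if (pol == "perpendicular") {
    num <- m * jmx$fp * jx$f - jx$fp * jmx$f
    den <- hxp * jmx$f - m * jmx$fp * hx
  } else {
    num <- jmx$fp * jx$f - m * jx$fp * jmx$f
    den <- m * hxp * jmx$f - jmx$fp * hx
  }
  num / den
}

#' Far-field scattering amplitude of the cylinder series
#'
#' Evaluates `F(delta) = exp(-i pi/4) * (b_0 + 2 sum_n b_n cos(n delta))`, the
#' amplitude such that the scattered field at distance l and scattering angle
#' delta (measured from the incident direction) tends to
#' `F * sqrt(2/(pi k l)) * exp(i k l)`.
#'
#' @param coef complex coefficients from [cylinder_series_coefficients()]
#' @param delta scattering angles (rad); any numeric shape
#' @return complex amplitudes with the shape of `delta`
#' @export
cylinder_scattering_amplitude <- function(coef, delta) {
  nmax <- length(coef) - 1L
  cd <- cos(delta)
  acc <- array(coef[1L] + 0i, dim = dim(cd) %||% length(cd))
  if (nmax >= 1L) {
    cprev <- array(1, dim = dim(cd) %||% length(cd))  # cos(0 * delta)
    ccur <- cd                                        # cos(1 * delta)
    acc <- acc + 2 * coef[2L] * ccur
    n <- 2L
    while (n <= nmax) {
      cnext <- 2 * cd * ccur - cprev                  # Chebyshev recurrence
      acc <- acc + 2 * coef[n + 1L] * cnext
      cprev <- ccur; ccur <- cnext
      n <- n + 1L
    }
  }
  exp(-1i * pi / 4) * acc
}

#' Scattering cross-section (per unit length) of an infinite cylinder
#'
#' `C_sca = (4/k_med) * (|b_0|^2 + 2 sum |b_n|^2)`, in meters (2D geometry).
#'
#' @param coef coefficients from [cylinder_series_coefficients()]
#' @param k_med wavenumber in the surrounding medium (rad/m)
#' @return scattering cross-section per unit length (m)
#' @export
cylinder_csca <- function(coef, k_med) {
  4 / k_med * (Mod(coef[1L])^2 + 2 * sum(Mod(coef[-1L])^2))
}

#' Far-field container
#'
#' Complex angular amplitudes on the collection circle, normalized so that the
#' physical scattered field at large `k*l` is
#' `amplitude(angle) * sqrt(2/(pi k l)) * exp(i k l)`. Collection angle `alpha`
#' labels the outgoing direction `(-cos(alpha), sin(alpha))` (back toward the
#' collecting lens, which sits on the negative optical axis).
#'
#' @param angles strictly increasing observation angles (rad)
#' @param amplitudes complex amplitudes, same length
#' @param k vacuum wavenumber (rad/m)
#' @param polarisation `"perpendicular"` or `"parallel"`
#' @return an object of class `far_field`
#' @export
far_field <- function(angles, amplitudes, k, polarisation) {
  stopifnot(length(angles) == length(amplitudes),
            all(diff(angles) > 0),
            all(is.finite(Re(amplitudes)) & is.finite(Im(amplitudes))))
  structure(list(angles = angles, amplitudes = amplitudes, k = k,
                 polarisation = check_pol(polarisation)),
            class = "far_field")
}

#' Angular spectrum of the focused probe beam
#'
#' Bundles the Gauss-Legendre angular quadrature with the Debye-Wolf amplitude
#' density; this is the "beam" consumed by the analytic scattering path.
#'
#' @param k vacuum wavenumber (rad/m)
#' @param mode a [fiber_mode()]
#' @param sys an [optical_system()]
#' @param n_theta number of angular quadrature nodes
#' @return list with `theta`, `weights`, `amplitude`
#' @export
beam_spectrum <- function(k, mode, sys, n_theta = 201) {
  g <- gauss_nodes(n_theta, -sys$alpha_max, sys$alpha_max)
  list(theta = g$nodes, weights = g$weights,
       amplitude = beam_angular_amplitude(g$nodes, k, mode, sys))
}

#' Far field scattered by one cylinder under focused illumination
#'
#' Superposes the exact series response over the incident plane-wave spectrum
#' of the focused beam: every incident angle contributes the textbook cylinder
#' scattering amplitude, weighted by the Debye-Wolf angular density and
#' phase-shifted for the cylinder-center offset on both the incident and the
#' scattered leg (phases at the in-medium wavenumber `k * n_med`).
#'
#' @param beam angular spectrum from [beam_spectrum()]
#' @param cyl list with `center` (length-2, m), `radius` (m), `index`
#' @param k vacuum wavenumber (rad/m)
#' @param pol `"perpendicular"` or `"parallel"`
#' @param n_med background refractive index
#' @param angles collection angles (rad); default: the beam's own nodes
#' @return a [far_field()]
#' @export
cylinder_far_field <- function(beam, cyl, k, pol, n_med,
                               angles = beam$theta) {
  pol <- check_pol(pol)
  kmed <- k * n_med
  xs <- kmed * cyl$radius
  m <- cyl$index / n_med
  if (m == 1) return(far_field(angles, rep(0 + 0i, length(angles)), k, pol))
  coef <- cylinder_series_coefficients(m, xs, pol)
  delta <- outer(pi - angles, beam$theta, "-")
  fmat <- cylinder_scattering_amplitude(coef, delta)
  amp <- .cyl_translate_matvec(fmat, beam, angles, kmed, cyl$center)
  far_field(angles, amp, k, pol)
}

# amplitude vector for one cylinder: u(alpha) * (F %*% (q(theta) * w * eps))
# where u, q carry the center-offset phases on the scattered/incident legs.
.cyl_translate_matvec <- function(fmat, beam, angles, kmed, center) {
  qin <- exp(1i * kmed * (center[1] * cos(beam$theta) +
                          center[2] * sin(beam$theta)))
  uout <- exp(1i * kmed * (center[1] * cos(angles) -
                           center[2] * sin(angles)))
  uout * as.vector(fmat %*% (qin * beam$weights * beam$amplitude))
}

# Analytic far field of a whole scene of discs (single-scattering
# superposition of exact per-cylinder responses; inter-cylinder multiple
# scattering is not included on this path -- use the grid solver for that).
# beam_shift shifts the illumination laterally by y_s (scanning).
scene_far_field_analytic <- function(scene, beam, k, pol, n_med, angles,
                                     y_shift = 0) {
  discs <- Filter(function(p) p$type == "disc", scene$primitives)
  if (length(discs) == 0L)
    return(far_field(angles, rep(0 + 0i, length(angles)), k, pol))
  kmed <- k * n_med
  # scanning the beam by +y_shift is equivalent to shifting centers by -y_shift
  keyf <- vapply(discs, function(p) paste(p$radius, p$index), character(1))
  amp <- rep(0 + 0i, length(angles))
  for (key in unique(keyf)) {
    grp <- discs[keyf == key]
    m <- grp[[1]]$index / n_med
    if (m == 1) next
    coef <- cylinder_series_coefficients(m, kmed * grp[[1]]$radius, pol)
    delta <- outer(pi - angles, beam$theta, "-")
    fmat <- cylinder_scattering_amplitude(coef, delta)
    for (p in grp) {
      ctr <- c(p$center[1], p$center[2] - y_shift)
      amp <- amp + .cyl_translate_matvec(fmat, beam, angles, kmed, ctr)
    }
  }
  far_field(angles, amp, k, pol)
}
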