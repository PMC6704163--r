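# Spectral sampling, fiber-coupled detection, and Fourier-domain
# reconstruction of A-scans and B-scans.

#' Sampled Gaussian source spectrum
#'
#' Builds the angular-frequency grid for a Gaussian source of central vacuum
#' wavelength `lambda0` and FWHM bandwidth `delta_lambda`. The grid spans the
#' symmetric interval where the spectral amplitude
#' `S = b/sqrt(2) exp(-(b/2 (omega - omega0))^2)` has decayed to
#' `epsilon * max(S)` (the spectrometer sensitivity cut-off), sampled at `N`
#' uniformly spaced frequencies. The temporal width is
#' `b = 2 sqrt(ln 2) lambda0^2 / (pi c delta_lambda)`.
#'
#' @param lambda0 central vacuum wavelength (m)
#' @param delta_lambda FWHM bandwidth (m)
#' @param epsilon spectral cut-off, 0 < epsilon < 1
#' @param N number of sampled wavenumbers (even, for the DFT convention used
#'   in reconstruction)
#' @return object of class `source_spectrum` with fields `lambda0`,
#'   `delta_lambda`, `b`, `epsilon`, `N`, `omega`, `S`, `k` (vacuum
#'   wavenumbers `omega/c`)
#' @examples
#' sp <- build_spectrum(1.3e-6, 170e-9, 1e-3, 160)
#' sp$b          # about 1.8e-14 s
#' @export
build_spectrum <- function(lambda0 = 1.3e-6, delta_lambda = 170e-9,
                           epsilon = 1e-3, N = 160L) {
  stopifnot(lambda0 > 0, delta_lambda > 0, epsilon > 0, epsilon < 1, N >= 2)
  b <- 2 * sqrt(log(2)) * lambda0^2 / (pi * .c0 * delta_lambda)
  omega0 <- 2 * pi * .c0 / lambda0
  half <- 2 * sqrt(log(1 / epsilon)) / b
  omega <- seq(omega0 - half, omega0 + half, length.out = N)
  structure(list(lambda0 = lambda0, delta_lambda = delta_lambda, b = b,
                 epsilon = epsilon, N = as.integer(N), omega = omega,
                 S = b / sqrt(2) * exp(-(b / 2 * (omega - omega0))^2),
                 k = omega / .c0),
            class = "source_spectrum")
}

#' @export
print.source_spectrum <- function(x, ...) {
  cat(sprintf("source spectrum: lambda0 = %.0f nm, FWHM = %.0f nm, b = %.3g s\n",
              x$lambda0 * 1e9, x$delta_lambda * 1e9, x$b))
  cat(sprintf("  %d wavenumbers, cut-off epsilon = %g\n", x$N, x$epsilon))
  invisible(x)
}

#' Maximum visible depth of the reconstruction
#'
#' Deepest unambiguous depth (counted from the focus) before signals alias
#' back through the periodicity of the inverse discrete Fourier transform,
#' with the index convention `-N/2 .. N/2 - 1`:
#' `c t_max` with
#' `t_max = (1/(2 n_med)) (N/2 + 1/N - 3/2) pi b / (2 sqrt(ln(1/epsilon)))`.
#'
#' @param N number of sampled wavenumbers (even)
#' @param b temporal width of the source (s)
#' @param epsilon spectral cut-off
#' @param n_med refractive index of the medium
#' @return maximum visible depth (m)
#' @examples
#' max_visible_depth(160, build_spectrum()$b, 1e-3, 1.35) * 1e6  # about 92 um
#' @export
max_visible_depth <- function(N, b, epsilon, n_med) {
  stopifnot(N >= 4, N %% 2 == 0)
  tmax <- 1 / (2 * n_med) * (N / 2 + 1 / N - 3 / 2) * pi * b /
    (2 * sqrt(log(1 / epsilon)))
  .c0 * tmax
}

#' Depth period of the reconstruction
#'
#' Full unambiguous period of the depth axis set by the frequency spacing:
#' signals at `x` and `x + depth_period` are indistinguishable.
#'
#' @param spectrum a [build_spectrum()]
#' @param n_med refractive index of the medium
#' @return depth period (m)
#' @export
depth_period <- function(spectrum, n_med) {
  dom <- spectrum$omega[2] - spectrum$omega[1]
  2 * pi / dom * .c0 / (2 * n_med)
}

#' Fiber-coupling overlap integral
#'
#' Amount of light coupled into the Gaussian detection fiber mode:
#' `integral field(y) exp(-y^2/w0^2) dy` by quadrature. The contribution of
#' the field component parallel to the optical axis is neglected.
#'
#' @param y sample points (m); should cover at least 4 w0 on each side
#' @param field complex field values at `y`
#' @param mode a [fiber_mode()]
#' @param weights quadrature weights; trapezoid weights from `y` when omitted
#' @return complex coupling amplitude
#' @export
coupling_amplitude <- function(y, field, mode, weights = NULL) {
  stopifnot(length(y) == length(field))
  if (max(y) < 4 * mode$w0 || min(y) > -4 * mode$w0)
    warning("field sampling narrower than 4*w0 on each side; coupling may be inaccurate")
  if (is.null(weights)) {
    n <- length(y)
    weights <- c(diff(y)[1] / 2,
                 (y[3:n] - y[1:(n - 2)]) / 2,
                 diff(y)[n - 1] / 2)
  }
  sum(weights * field * exp(-y^2 / mode$w0^2))
}

#' Precomputed nodes for the detection back-propagation
#'
#' Quadrature geometry of the collection chain: lens-plane nodes over the
#' aperture, the matching collection angles on the far-field circle, the
#' focusing angles of the collimating lens, and the fiber-plane nodes for the
#' overlap integral. Depends only on the lens train and fiber, not on k.
#'
#' @param sys an [optical_system()]
#' @param mode a [fiber_mode()]
#' @param n_xi lens-plane nodes (resolves the aperture chirp)
#' @param n_theta1 angular nodes of the collimating-lens Debye-Wolf integral
#' @param n_yf fiber-plane nodes
#' @return list used by [couple_far_field()]
#' @export
detection_quadrature <- function(sys, mode, n_xi = 2048, n_theta1 = 201,
                                 n_yf = 161) {
  gxi <- gauss_nodes(n_xi, -sys$h, sys$h)
  alpha1 <- asin(sys$h / sys$f1)
  gth <- gauss_nodes(n_theta1, -alpha1, alpha1)
  gyf <- gauss_nodes(n_yf, -4 * mode$w0, 4 * mode$w0)
  list(xi = gxi$nodes, wxi = gxi$weights,
       alo = atan(gxi$nodes / sys$f2),       # collection angles on the circle
       th1 = gth$nodes, wth1 = gth$weights,
       ym = sys$f1 * sin(gth$nodes),         # midplane points needed by L1
       yf = gyf$nodes, wyf = gyf$weights)
}

#' Couple collected far fields back into the detection fiber
#'
#' Backward pass of the interferometer for one wavenumber: the outgoing
#' cylindrical far field is sampled on the collecting lens, propagated to the
#' midplane with the Fresnel integral (paraxial lens transmission), focused
#' onto the fiber end face with the Debye-Wolf integral of the collimating
#' lens, and overlapped with the fiber mode. Both interferometer arms must be
#' passed through this same operator so that common phases cancel in the
#' cross-correlation. For the parallel channel the in-plane rotation
#' contributes a `cos(theta)` on the fiber-plane `Ey` component; the axial
#' component is neglected.
#'
#' @param B_list list of complex far-field amplitude vectors, each sampled at
#'   the collection angles `quad$alo` (normalization of [far_field()])
#' @param k vacuum wavenumber (rad/m)
#' @param sys an [optical_system()]
#' @param mode a [fiber_mode()]
#' @param pol `"perpendicular"` or `"parallel"`
#' @param quad nodes from [detection_quadrature()]
#' @return complex coupling amplitudes, one per element of `B_list`
#' @export
couple_far_field <- function(B_list, k, sys, mode, pol, quad) {
  pol <- check_pol(pol)
  if (!is.list(B_list)) B_list <- list(B_list)
  lam <- 2 * pi / k
  r <- sqrt(sys$f2^2 + quad$xi^2)
  prop <- sqrt(2 / (pi * k * r)) * exp(1i * k * r) *
    exp(-1i * k * quad$xi^2 / (2 * sys$f2))          # lens transmission
  fres <- exp(-1i * pi / 4) / sqrt(lam * sys$f2) *
    exp(1i * k * sys$f2 *
          (1 + (outer(quad$ym, quad$xi, "-"))^2 / (2 * sys$f2^2)))
  gpol <- if (pol == "perpendicular") 1 else cos(quad$th1)
  dw_w <- quad$wth1 * sqrt(cos(quad$th1)) * gpol
  dw <- sqrt(sys$f1 / lam) * exp(-1i * pi / 4 + 1i * k * sys$f1) *
    exp(1i * k * outer(quad$yf, sin(quad$th1)))
  fib <- quad$wyf * exp(-quad$yf^2 / mode$w0^2)
  vapply(B_list, function(B) {
    M <- fres %*% (quad$wxi * B * prop)
    sum(fib * (dw %*% (dw_w * M)))
  }, complex(1))
}

#' Spectral coupling amplitudes of the two arms
#'
#' @param alpha_sca complex sample-arm coupling amplitudes per wavenumber
#' @param alpha_ref complex reference-arm coupling amplitudes per wavenumber
#' @param k vacuum wavenumber grid (rad/m)
#' @return object of class `spectral_coupling`
#' @export
spectral_coupling <- function(alpha_sca, alpha_ref, k) {
  stopifnot(length(alpha_sca) == length(alpha_ref),
            length(alpha_sca) == length(k),
            all(is.finite(Mod(alpha_sca))), all(is.finite(Mod(alpha_ref))))
  structure(list(alpha_sca = alpha_sca, alpha_ref = alpha_ref, k = k),
            class = "spectral_coupling")
}

#' Reconstruct an A-scan from spectral coupling amplitudes
#'
#' Forms the cross-correlation spectrum `alpha_sca * Conj(alpha_ref)` (which
#' suppresses the DC and autocorrelation terms), weights it by the spectral
#' power `|S|^2` (or amplitude `S`), and applies the inverse discrete Fourier
#' transform with indices `-N/2 .. N/2 - 1`. Times map to depth through
#' `x = t c / (2 n_med)`. The transform is scaled by `1/sqrt(N)` so that the
#' energy of the weighted spectral product equals the energy of the complex
#' A-scan (Parseval).
#'
#' @param coupling a [spectral_coupling()]
#' @param spectrum the [build_spectrum()] used to sample the couplings
#' @param n_med refractive index of the medium
#' @param weighting `"power"` (default) or `"amplitude"` spectral weighting
#' @return object of class `ascan` with `depth` (m, ascending, length N, the
#'   maximum equal to [max_visible_depth()]), `time` (s), `intensity`
#'   (magnitudes) and `complex_signal`
#' @export
reconstruct_ascan <- function(coupling, spectrum, n_med,
                              weighting = c("power", "amplitude")) {
  weighting <- match.arg(weighting)
  N <- spectrum$N
  if (length(coupling$alpha_sca) != N)
    stop("coupling length does not match the spectrum")
  if (N %% 2 != 0) stop("N must be even for the -N/2 .. N/2-1 DFT convention")
  w <- if (weighting == "power") spectrum$S^2 else spectrum$S
  z <- w * coupling$alpha_sca * Conj(coupling$alpha_ref)
  raw <- fft(z) / sqrt(N)                       # sum_m z_m e^{-2 pi i m n / N}
  j <- 0:(N - 1)
  nsig <- ifelse(j <= N / 2 - 1, j, j - N)
  dom <- spectrum$omega[2] - spectrum$omega[1]
  t <- 2 * pi * nsig / (N * dom)
  sig <- raw * exp(-1i * spectrum$omega[1] * t)  # phase of the omega_min origin
  ord <- order(t)
  structure(list(depth = t[ord] * .c0 / (2 * n_med), time = t[ord],
                 intensity = Mod(sig[ord]), complex_signal = sig[ord],
                 n_med = n_med, weighting = weighting),
            class = "ascan")
}

#' @export
print.ascan <- function(x, ...) {
  pk <- which.max(x$intensity)
  cat(sprintf("A-scan: %d depths in [%.2f, %.2f] um; strongest signal at %.2f um\n",
              length(x$depth), min(x$depth) * 1e6, max(x$depth) * 1e6,
              x$depth[pk] * 1e6))
  invisible(x)
}

#' Locate echo peaks in an A-scan
#'
#' Local maxima of the magnitude, sorted by decreasing strength.
#'
#' @param ascan an [reconstruct_ascan()] result
#' @param n_peaks maximum number of peaks
#' @param min_rel discard peaks weaker than `min_rel` times the strongest
#' @return data frame with `depth` (m) and `intensity`
#' @export
find_echoes <- function(ascan, n_peaks = 10L, min_rel = 1e-6) {
  I <- ascan$intensity
  n <- length(I)
  loc <- which(I[2:(n - 1)] > I[1:(n - 2)] & I[2:(n - 1)] >= I[3:n]) + 1L
  loc <- loc[I[loc] >= min_rel * max(I)]
  loc <- loc[order(-I[loc])]
  loc <- loc[seq_len(min(n_peaks, length(loc)))]
  data.frame(depth = ascan$depth[loc], intensity = I[loc])
}

#' Trace the specular echo train of an axial A-scan
#'
#' Identifies the front- and back-surface echoes (the two strongest local
#' maxima) and extends the train to higher orders by arithmetic extrapolation
#' of the measured echo spacing: every additional pair of internal traversals
#' adds the same optical distance, so the echo of order `j` is expected near
#' `p_back + j * (p_back - p_front)`. Each member is located as the local
#' maximum nearest the extrapolated position (within an eighth of the spacing,
#' since the extrapolation is accurate to about a depth bin while unrelated
#' wave features sit several bins away); the measurement uses only the A-scan
#' itself.
#'
#' @param ascan an `ascan`
#' @param orders how many echoes beyond the back surface to locate
#' @return data frame with `order` (0 = front, 1 = back, ...), `depth` (m) and
#'   `intensity`; extrapolated members without a local maximum in the window
#'   are dropped
#' @export
axial_echo_train <- function(ascan, orders = 1L) {
  I <- ascan$intensity; d <- ascan$depth
  n <- length(I)
  loc <- which(I[2:(n - 1)] > I[1:(n - 2)] & I[2:(n - 1)] >= I[3:n]) + 1L
  main <- loc[order(-I[loc])][1:2]
  front <- min(d[main]); back <- max(d[main])
  spacing <- back - front
  out <- data.frame(order = c(0L, 1L), depth = c(front, back),
                    intensity = I[match(c(front, back), d)])
  for (j in seq_len(orders)) {
    pred <- back + j * spacing
    cand <- loc[abs(d[loc] - pred) <= spacing / 8]
    if (!length(cand)) next
    best <- cand[which.min(abs(d[cand] - pred))]
    out <- rbind(out, data.frame(order = j + 1L, depth = d[best],
                                 intensity = I[best]))
  }
  out
}

#' Integrated image error
#'
#' Relative L2 distance between two images,
#' `sqrt(sum |I_a - I_b|^2) / sqrt(sum |I_a|^2)`, with `I_b` resampled to the
#' shape of `I_a` by bilinear interpolation when the shapes differ.
#'
#' @param I_a,I_b numeric matrices (or objects with an `intensity` matrix)
#' @return dimensionless error
#' @export
integrated_error <- function(I_a, I_b) {
  if (!is.matrix(I_a)) I_a <- as.matrix(I_a$intensity %||% I_a)
  if (!is.matrix(I_b)) I_b <- as.matrix(I_b$intensity %||% I_b)
  if (length(I_a) == 0 || length(I_b) == 0) stop("empty image")
  if (!all(dim(I_a) == dim(I_b)))
    I_b <- bilinear_resample(I_b, nrow(I_a), ncol(I_a))
  sqrt(sum((I_a - I_b)^2)) / sqrt(sum(I_a^2))
}

#' Bilinear resampling of a matrix
#'
#' @param m numeric matrix
#' @param nr,nc target dimensions
#' @return resampled matrix
#' @export
bilinear_resample <- function(m, nr, nc) {
  src_r <- if (nrow(m) > 1) seq(1, nrow(m), length.out = nr) else rep(1, nr)
  src_c <- if (ncol(m) > 1) seq(1, ncol(m), length.out = nc) else rep(1, nc)
  r0 <- pmax(pmin(floor(src_r), nrow(m) - 1L), 1L)
  c0 <- pmax(pmin(floor(src_c), ncol(m) - 1L), 1L)
  fr <- src_r - r0; fc <- src_c - c0
  r1 <- pmin(r0 + 1L, nrow(m)); c1 <- pmin(c0 + 1L, ncol(m))
  (1 - fr) %o% (1 - fc) * m[r0, c0, drop = FALSE] +
    fr %o% (1 - fc) * m[r1, c0, drop = FALSE] +
    (1 - fr) %o% fc * m[r0, c1, drop = FALSE] +
    fr %o% fc * m[r1, c1, drop = FALSE]
}
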