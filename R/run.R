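# Full simulation drivers: A-scan and B-scan orchestration over wavenumbers
# and scan positions, for the analytic cylinder path and the grid solver.

#' Simulate a B-scan tomogram
#'
#' For every sampled wavenumber and every lateral scan position: synthesize
#' the focused probe beam, compute the scattered far field on the collection
#' circle (exact cylinder series superposition for `solver = "analytic"`, or
#' rasterization plus the Helmholtz grid solver and the near-to-far transform
#' for `solver = "grid"`), propagate it back through the lens train into the
#' detection fiber, and pair it with the analytic reference-arm coupling. The
#' per-position interferograms are reconstructed into A-scans and stacked.
#'
#' Scanning shifts the illumination laterally relative to the scene (sample
#' and instrument scanning are equivalent); the detection fiber is assumed to
#' stay on the lens axis.
#'
#' The stored `intensity` matrix is the cross-correlation magnitude divided by
#' `normalization`, the reference-arm intensity in the reconstruction scaling,
#' so that a sample arm identical to the reference arm (a mirror at the focus)
#' gives a normalized intensity of exactly 1 at depth 0. Doubling the source
#' amplitude leaves the normalized tomogram unchanged.
#'
#' @param scn a [scene()]
#' @param sys an [optical_system()]
#' @param spectrum a [build_spectrum()]
#' @param mode a [fiber_mode()]
#' @param pol `"perpendicular"` or `"parallel"`
#' @param y_positions lateral scan positions (m)
#' @param solver `"analytic"` (exact series; disc primitives only, neglecting
#'   inter-cylinder multiple scattering) or `"grid"` (Helmholtz solver on the
#'   rasterized map; perpendicular polarisation)
#' @param cfg [solver_config()] for the grid solver
#' @param n_theta angular quadrature nodes of the illumination spectrum
#' @param n_collect collection angles at which the scattered far field is
#'   evaluated before spline interpolation onto the (finer) lens-plane
#'   quadrature; the far field is smooth on this angular scale
#' @param quad detection nodes, default [detection_quadrature()]
#' @param dx grid spacing for `solver = "grid"`; default resolves the
#'   shortest sampled wavelength with 13 cells
#' @param subsampling,boundary_width rasterization parameters (grid solver)
#' @param mirror_r reference mirror reflection coefficient
#' @param progress print one line per wavenumber (grid solver can be slow)
#' @return object of class `tomogram`: `depth` (m), `y_positions` (m),
#'   `intensity` (depth x position, normalized), `complex_signal`,
#'   `normalization`, plus the run parameters
#' @export
run_bscan <- function(scn, sys, spectrum, mode = fiber_mode(),
                      pol = "perpendicular", y_positions = 0,
                      solver = c("analytic", "grid"),
                      cfg = solver_config(), n_theta = 201, n_collect = 257,
                      quad = detection_quadrature(sys, mode),
                      dx = NULL, subsampling = 10L, boundary_width = 10e-6,
                      mirror_r = 1, progress = FALSE) {
  solver <- match.arg(solver)
  pol <- check_pol(pol)
  stopifnot(inherits(scn, "scene"), inherits(spectrum, "source_spectrum"))
  N <- spectrum$N
  npos <- length(y_positions)
  if (solver == "analytic") {
    bad <- vapply(scn$primitives, function(p) p$type != "disc", logical(1))
    if (any(bad))
      stop("the analytic path supports disc primitives only; use solver = \"grid\"")
  } else {
    if (pol != "perpendicular")
      stop("the grid solver handles the perpendicular (out-of-plane) channel; ",
           "use the analytic path for parallel polarisation on cylinder scenes")
    if (is.null(dx)) dx <- 2 * pi / max(spectrum$k) / 13
    map <- rasterize_scene(scn, dx, subsampling, boundary_width)
    # sampling contour: just inside the non-absorbing interior
    half <- max(abs(scn$extent)) - 3 * dx
  }
  alpha_sca <- matrix(0 + 0i, N, npos)
  alpha_ref <- rep(0 + 0i, N)
  acoll <- gauss_nodes(n_collect, min(quad$alo), max(quad$alo))$nodes
  for (i in seq_len(N)) {
    k <- spectrum$k[i]
    Bref <- reference_far_amplitude(quad$alo, k, mode, sys, mirror_r)
    if (solver == "analytic") {
      beam <- beam_spectrum(k, mode, sys, n_theta)
      Bs <- lapply(y_positions, function(ys) {
        bc <- scene_far_field_analytic(scn, beam, k, pol, sys$n_med, acoll,
                                       y_shift = ys)$amplitudes
        interp_complex(acoll, bc, quad$alo)
      })
    } else {
      kmed <- k * sys$n_med
      Bs <- lapply(y_positions, function(ys) {
        inc <- beam_on_grid(map, k, mode, sys, y_shift = ys,
                            n_theta = n_theta)
        sol <- helmholtz_solve(map, inc, k, cfg)
        ctr <- grid_contour(map, sol$scattered, half)
        # collection circle direction (-cos a, sin a) is phi = pi - a
        bc <- near_to_far(ctr, kmed, pi - acoll)
        interp_complex(acoll, bc, quad$alo)
      })
    }
    cpl <- couple_far_field(c(list(Bref), Bs), k, sys, mode, pol, quad)
    alpha_ref[i] <- cpl[1]
    alpha_sca[i, ] <- cpl[-1]
    if (progress)
      message(sprintf("k %d/%d done", i, N))
  }
  w <- spectrum$S^2
  normalization <- sum(w * Mod(alpha_ref)^2) / sqrt(N)
  asc <- lapply(seq_len(npos), function(j)
    reconstruct_ascan(spectral_coupling(alpha_sca[, j], alpha_ref, spectrum$k),
                      spectrum, sys$n_med))
  intensity <- vapply(asc, function(a) a$intensity, numeric(N)) / normalization
  csig <- vapply(asc, function(a) a$complex_signal, complex(N))
  structure(list(depth = asc[[1]]$depth, y_positions = y_positions,
                 intensity = matrix(intensity, N, npos),
                 complex_signal = matrix(csig, N, npos),
                 normalization = normalization,
                 alpha_ref = alpha_ref, alpha_sca = alpha_sca,
                 polarisation = pol, solver = solver, n_med = sys$n_med,
                 spectrum = spectrum, system = sys),
            class = "tomogram")
}

#' Simulate a single A-scan
#'
#' One-position convenience wrapper around [run_bscan()]; see there for
#' details.
#'
#' @inheritParams run_bscan
#' @param y_position lateral position of the beam axis (m)
#' @param ... passed to [run_bscan()]
#' @return an `ascan` (normalized intensity), with the `tomogram` attached as
#'   attribute `tomogram`
#' @export
run_ascan <- function(scn, sys, spectrum, mode = fiber_mode(),
                      pol = "perpendicular", y_position = 0, ...) {
  tg <- run_bscan(scn, sys, spectrum, mode, pol, y_positions = y_position, ...)
  a <- structure(list(depth = tg$depth,
                      time = tg$depth * 2 * tg$n_med / .c0,
                      intensity = tg$intensity[, 1],
                      complex_signal = tg$complex_signal[, 1],
                      n_med = tg$n_med, weighting = "power"),
                 class = "ascan")
  attr(a, "tomogram") <- tg
  a
}

#' @export
print.tomogram <- function(x, ...) {
  cat(sprintf("tomogram: %d depths x %d positions (%s, %s solver)\n",
              nrow(x$intensity), ncol(x$intensity), x$polarisation, x$solver))
  cat(sprintf("  depth range [%.1f, %.1f] um, normalization %.3g\n",
              min(x$depth) * 1e6, max(x$depth) * 1e6, x$normalization))
  invisible(x)
}
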