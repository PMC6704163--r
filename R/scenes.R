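# Sample geometries: single cylinders, symmetric/jittered cylinder clusters,
# ziggurat profiles, randomized dentin-tubule slabs, and the mean-free-path
# diagnostic.

#' Scene container
#'
#' A scene is a background refractive index plus a list of geometric
#' primitives: discs (`center`, `radius`, `index`) and axis-aligned rectangles
#' (`xmin`, `xmax`, `ymin`, `ymax`, `index`). Coordinates are in meters; `x` is
#' the optical axis (positive into the sample, origin at the beam focus) and
#' `y` is lateral.
#'
#' @param primitives list of primitive lists (each with a `type` of `"disc"`
#'   or `"rect"`)
#' @param n_med background refractive index
#' @param extent bounding box `c(xmin, xmax, ymin, ymax)` (m); computed from
#'   the primitives (with a margin) when omitted
#' @return an object of class `scene`
#' @export
scene <- function(primitives = list(), n_med = 1.35, extent = NULL) {
  stopifnot(n_med >= 1)
  for (p in primitives) {
    stopifnot(p$type %in% c("disc", "rect"), p$index >= 1)
    if (p$type == "disc") stopifnot(p$radius > 0)
  }
  if (is.null(extent)) extent <- scene_extent(primitives)
  structure(list(primitives = primitives, n_med = n_med, extent = extent),
            class = "scene")
}

scene_extent <- function(primitives, margin = 2e-6) {
  if (length(primitives) == 0L) return(c(-margin, margin, -margin, margin))
  xs <- ys <- NULL
  for (p in primitives) {
    if (p$type == "disc") {
      xs <- c(xs, p$center[1] - p$radius, p$center[1] + p$radius)
      ys <- c(ys, p$center[2] - p$radius, p$center[2] + p$radius)
    } else {
      xs <- c(xs, p$xmin, p$xmax); ys <- c(ys, p$ymin, p$ymax)
    }
  }
  c(min(xs) - margin, max(xs) + margin, min(ys) - margin, max(ys) + margin)
}

#' @export
print.scene <- function(x, ...) {
  nd <- sum(vapply(x$primitives, function(p) p$type == "disc", logical(1)))
  nr <- length(x$primitives) - nd
  e <- x$extent * 1e6
  cat(sprintf("scene: %d disc(s), %d rectangle(s), n_med = %.3f\n", nd, nr, x$n_med))
  cat(sprintf("  extent x [%.2f, %.2f] um, y [%.2f, %.2f] um\n",
              e[1], e[2], e[3], e[4]))
  invisible(x)
}

#' Single-cylinder scene
#'
#' One infinite circular cylinder of radius `a` and index `n_cyl` in a
#' background of index `n_med`. The attribute `echo_separation` carries the
#' predicted optical distance between the front- and back-surface echoes in
#' the reconstructed tomogram, `d = 2 a n_cyl / n_med` (the factor `n_cyl /
#' n_med` is the depth distortion caused by mapping time to depth with the
#' background index).
#'
#' @param a cylinder radius (m)
#' @param n_cyl cylinder refractive index
#' @param n_med background refractive index
#' @param center cylinder center `c(x, y)` (m), default at the beam focus
#' @return a [scene()] with attribute `echo_separation` (m)
#' @export
make_single_cylinder <- function(a, n_cyl, n_med, center = c(0, 0)) {
  stopifnot(a > 0)
  sc <- scene(list(list(type = "disc", center = center, radius = a,
                        index = n_cyl)), n_med = n_med)
  attr(sc, "echo_separation") <- echo_separation(a, n_cyl, n_med)
  sc
}

#' Predicted front-back echo separation of a cylinder
#'
#' @inheritParams make_single_cylinder
#' @return optical separation `2 a n_cyl / n_med` (m)
#' @export
echo_separation <- function(a, n_cyl, n_med) 2 * a * n_cyl / n_med

#' Phantom specification for randomized cylinder scenes
#'
#' @param n_cyl_count number of cylinders
#' @param region list describing the fill region: either
#'   `list(type = "disc", center, radius)` or
#'   `list(type = "rect", xmin, xmax, ymin, ymax)` (m)
#' @param radius cylinder radius (m)
#' @param index cylinder refractive index
#' @param seed integer seed; identical spec + seed give bit-identical scenes
#' @param allow_overlap may cylinders overlap (default `TRUE`, matching the
#'   unconstrained placements used for the reference phantoms)
#' @param jitter optional per-axis maximum displacement `c(jx, jy)` (m) applied
#'   to lattice sites; `NULL` keeps the symmetric lattice
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(n_cyl_count, region, radius, index, seed = 1L,
                         allow_overlap = TRUE, jitter = NULL) {
  stopifnot(n_cyl_count >= 0, radius > 0, index >= 1)
  structure(list(n_cyl_count = as.integer(n_cyl_count), region = region,
                 radius = radius, index = index, seed = as.integer(seed),
                 allow_overlap = isTRUE(allow_overlap), jitter = jitter),
            class = "phantom_spec")
}

# hexagonal lattice sites inside a disc region, mirror-symmetric about y = 0
# (and x = 0); sites are selected nearest-center first, keeping +/-y partners
# together so the selected configuration stays exactly mirror-symmetric.
hex_sites_in_disc <- function(count, center, region_radius, pitch) {
  dy <- pitch * sqrt(3) / 2
  jmax <- ceiling(region_radius / dy) + 1L
  imax <- ceiling(region_radius / pitch) + 1L
  pts <- NULL
  for (j in -jmax:jmax) {
    xoff <- if (j %% 2 == 0) (-imax:imax) * pitch else ((-imax:imax) + 0.5) * pitch
    pts <- rbind(pts, cbind(xoff, j * dy))
  }
  r2 <- pts[, 1]^2 + pts[, 2]^2
  keep <- r2 <= region_radius^2
  pts <- pts[keep, , drop = FALSE]; r2 <- r2[keep]
  # group +/-y partners: same radius, same x, same |y|
  key <- paste(signif(r2, 10), signif(pts[, 1], 10), signif(abs(pts[, 2]), 10))
  ord <- order(r2, abs(pts[, 2]), pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]; key <- key[ord]
  sel <- logical(nrow(pts))
  n_sel <- 0L
  i <- 1L
  while (i <= nrow(pts) && n_sel < count) {
    idx <- which(key == key[i] & !sel)
    if (n_sel + length(idx) <= count) {
      sel[idx] <- TRUE
      n_sel <- n_sel + length(idx)
    }
    i <- i + 1L
  }
  if (n_sel < count)
    stop("could not place the requested count symmetrically; enlarge the region")
  sweep(pts[sel, , drop = FALSE], 2, center, "+")
}

min_pair_distance <- function(pts) {
  if (nrow(pts) < 2) return(Inf)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  min(d)
}

#' Cluster of identical cylinders in a region
#'
#' Builds the multi-cylinder phantom: a mirror-symmetric hexagonal-lattice fill
#' of the region (the published symmetric arrangement is not tabulated, so a
#' lattice with the same count and radius stands in for it), optionally
#' perturbed by independent uniform per-axis jitter bounded by
#' `spec$jitter`. Deterministic for a fixed seed. The returned scene carries a
#' `displacement` attribute with the achieved min/max/mean overall shift.
#'
#' @param spec a [phantom_spec()]; `region` must be a disc for the lattice fill
#' @param n_med background refractive index
#' @param pitch lattice pitch (m); default `2.2 * radius` (touching is
#'   excluded but the fill stays dense enough for the reference counts)
#' @return a [scene()]
#' @export
make_cylinder_cluster <- function(spec, n_med = 1.35,
                                  pitch = 2.2 * spec$radius) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_cyl_count == 0L) return(scene(list(), n_med = n_med))
  if (!identical(spec$region$type, "disc"))
    stop("lattice cluster fill requires a disc region")
  base <- hex_sites_in_disc(spec$n_cyl_count, spec$region$center,
                            spec$region$radius, pitch)
  pts <- base
  if (!is.null(spec$jitter)) {
    jx <- spec$jitter[1]; jy <- spec$jitter[if (length(spec$jitter) > 1) 2 else 1]
    pts <- with_seed(spec$seed, {
      n <- nrow(base)
      for (try in 1:100) {
        cand <- base + cbind(stats::runif(n, -jx, jx), stats::runif(n, -jy, jy))
        if (spec$allow_overlap || min_pair_distance(cand) >= 2 * spec$radius)
          break
        cand <- NULL
      }
      if (is.null(cand)) stop("placement failed: jitter always produced overlap")
      cand
    })
  }
  prims <- lapply(seq_len(nrow(pts)), function(i)
    list(type = "disc", center = pts[i, ], radius = spec$radius,
         index = spec$index))
  sc <- scene(prims, n_med = n_med)
  shift <- sqrt(rowSums((pts - base)^2))
  attr(sc, "displacement") <- c(min = min(shift), max = max(shift),
                                mean = mean(shift))
  sc
}

#' Ziggurat (stepped-plateau) scene
#'
#' Stacked axis-aligned slabs of strictly decreasing width, mirror-symmetric
#' about `y = 0`, with all plateau surfaces normal to the optical axis. The
#' first (widest) element is the base, placed deepest; the last (narrowest)
#' plateau faces the incident beam at depth `x0`.
#'
#' @param plateau_widths strictly decreasing slab widths (m), base first
#' @param step_height height of each step along the optical axis (m)
#' @param index refractive index of the structure
#' @param n_med background refractive index
#' @param x0 depth of the top plateau surface (m)
#' @return a [scene()]
#' @export
make_ziggurat <- function(plateau_widths, step_height, index, n_med,
                          x0 = 0) {
  stopifnot(length(plateau_widths) >= 1, step_height > 0)
  if (any(diff(plateau_widths) >= 0))
    stop("plateau widths must be strictly decreasing (base first)")
  K <- length(plateau_widths)
  prims <- lapply(seq_len(K), function(i) {
    # element i sits at depth slot K - i (narrowest, i = K, at the top)
    s <- K - i
    list(type = "rect",
         xmin = x0 + s * step_height, xmax = x0 + (s + 1) * step_height,
         ymin = -plateau_widths[i] / 2, ymax = plateau_widths[i] / 2,
         index = index)
  })
  scene(prims, n_med = n_med)
}

#' Dentin slab with water-filled tubules
#'
#' A slab of dentin containing randomly placed water-filled tubules modeled as
#' discs. The background index equals the dentin index everywhere so that the
#' air-dentin surface reflection is suppressed and only the tubules scatter.
#' Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()]; `region` must be a rectangle (the slab)
#' @param n_dentin dentin refractive index (background), default 1.52
#' @param n_tubule tubule refractive index, default 1.33 (water)
#' @return a [scene()] with `n_med = n_dentin`
#' @export
make_dentin_slab <- function(spec, n_dentin = 1.52, n_tubule = 1.33) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_cyl_count == 0L)
    return(scene(list(), n_med = n_dentin,
                 extent = c(spec$region$xmin, spec$region$xmax,
                            spec$region$ymin, spec$region$ymax)))
  if (!identical(spec$region$type, "rect"))
    stop("dentin slab requires a rectangular region")
  r <- spec$region; a <- spec$radius
  pts <- with_seed(spec$seed, {
    acc <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(acc) < spec$n_cyl_count) {
      if (tries > 200L * spec$n_cyl_count)
        stop("placement failed: region too dense for non-overlapping tubules")
      cand <- c(stats::runif(1, r$xmin + a, r$xmax - a),
                stats::runif(1, r$ymin + a, r$ymax - a))
      ok <- spec$allow_overlap || nrow(acc) == 0L ||
        min(sqrt((acc[, 1] - cand[1])^2 + (acc[, 2] - cand[2])^2)) >= 2 * a
      if (ok) acc <- rbind(acc, cand)
      tries <- tries + 1L
    }
    acc
  })
  prims <- lapply(seq_len(nrow(pts)), function(i)
    list(type = "disc", center = pts[i, ], radius = a, index = n_tubule))
  scene(prims, n_med = n_dentin,
        extent = c(r$xmin, r$xmax, r$ymin, r$ymax))
}

#' Mean free path of a cylinder suspension
#'
#' `L = pi a^2 / (C_sca f)` with the area-concentration factor
#' `f = count pi a^2 / (Lx Ly)`; `C_sca` is the exact scattering cross-section
#' of one infinite cylinder at the in-medium wavelength `lambda0 / n_med`.
#'
#' @param a cylinder radius (m)
#' @param n_cyl cylinder refractive index
#' @param n_med surrounding (slab) refractive index
#' @param lambda0 vacuum wavelength (m)
#' @param count number of cylinders in the slab
#' @param Lx,Ly slab dimensions (m)
#' @param pol `"perpendicular"` or `"parallel"`
#' @return mean free path (m)
#' @examples
#' # dense dentin-tubule slab: about 7.0 um
#' mean_free_path(1e-6, 1.33, 1.52, 1.3e-6, 122, 40.4e-6, 69.3e-6,
#'                "perpendicular") * 1e6
#' @export
mean_free_path <- function(a, n_cyl, n_med, lambda0, count, Lx, Ly, pol) {
  stopifnot(a > 0, lambda0 > 0, count > 0, Lx > 0, Ly > 0)
  kmed <- 2 * pi * n_med / lambda0
  coef <- cylinder_series_coefficients(n_cyl / n_med, kmed * a, pol)
  csca <- cylinder_csca(coef, kmed)
  if (csca <= 0) stop("zero scattering cross-section: no index contrast")
  f <- count * pi * a^2 / (Lx * Ly)
  pi * a^2 / (csca * f)
}
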