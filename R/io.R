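# Configuration-driven runs and file I/O: scenes and tomograms as JSON/CSV,
# index maps as TIFF + JSON sidecar, interferograms as CSV, run summaries.

#' Serialize a scene to JSON
#'
#' @param scn a [scene()]
#' @param path output file
#' @export
write_scene <- function(scn, path) {
  jsonlite::write_json(
    list(n_med = scn$n_med, extent = scn$extent, primitives = scn$primitives),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene from JSON
#'
#' @param path file written by [write_scene()]
#' @return a [scene()]
#' @export
read_scene <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  prims <- lapply(x$primitives, function(p) {
    p$center <- as.numeric(p$center)
    p
  })
  scene(prims, n_med = x$n_med, extent = as.numeric(x$extent))
}

#' Export a far field as CSV
#'
#' Columns: angle (rad), Re, Im.
#' @param ff a [far_field()]
#' @param path output file
#' @export
write_far_field <- function(ff, path) {
  write.csv(data.frame(angle = ff$angles, Re = Re(ff$amplitudes),
                       Im = Im(ff$amplitudes)), path, row.names = FALSE)
  invisible(path)
}

#' Export an index map as TIFF with a JSON sidecar
#'
#' Writes `n2` as a single-precision grayscale TIFF (values scaled into
#' \[0, 1\] with the scaling recorded in the sidecar) plus `<path>.json` with
#' `dx`, `origin`, `boundary_width`, `subsampling`, `n_med`.
#'
#' @param map an [index_map()]
#' @param path output TIFF file
#' @export
write_index_map <- function(map, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write index maps")
  lo <- min(map$n2); hi <- max(map$n2)
  scl <- if (hi > lo) (map$n2 - lo) / (hi - lo) else map$n2 * 0
  tiff::writeTIFF(scl, path, bits.per.sample = 32L)
  jsonlite::write_json(list(dx = map$dx, origin = map$origin,
                            boundary_width = map$boundary_width,
                            subsampling = map$subsampling, n_med = map$n_med,
                            n2_min = lo, n2_max = hi, dim = dim(map$n2)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an index map written by [write_index_map()]
#'
#' @param path TIFF file with JSON sidecar
#' @return an [index_map()]
#' @export
read_index_map <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read index maps")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scl <- tiff::readTIFF(path)
  n2 <- scl * (meta$n2_max - meta$n2_min) + meta$n2_min
  index_map(matrix(n2, meta$dim[1], meta$dim[2]), meta$dx,
            as.numeric(meta$origin), meta$boundary_width, meta$subsampling,
            n_med = meta$n_med)
}

#' Write tomogram artifacts
#'
#' Writes, depending on `formats`: `tomogram.csv` (long form: depth, y,
#' value), `tomogram.json` (axes metadata plus the normalized intensity as a
#' portable float array), `tomogram.png` / `tomogram.tiff` (16-bit grayscale,
#' linear or decadic-log scale), and `interferogram.csv`
#' (omega, Re/Im alpha_sca, Re/Im alpha_ref, per scan position).
#'
#' @param tg a [run_bscan()] result
#' @param dir output directory (created if needed)
#' @param formats subset of `c("csv", "json", "png", "tiff")`
#' @param scale `"linear"` or `"log"` (decadic log of normalized values, used
#'   for the image formats)
#' @param floor_db dynamic-range floor for the log display
#' @return the directory, invisibly
#' @export
write_tomogram <- function(tg, dir, formats = c("csv", "json"),
                           scale = c("linear", "log"), floor_db = -80) {
  scale <- match.arg(scale)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if ("csv" %in% formats) {
    long <- data.frame(
      depth = rep(tg$depth, times = length(tg$y_positions)),
      y = rep(tg$y_positions, each = length(tg$depth)),
      value = as.vector(tg$intensity))
    write.csv(long, file.path(dir, "tomogram.csv"), row.names = FALSE)
  }
  if ("json" %in% formats) {
    jsonlite::write_json(
      list(depth = tg$depth, y_positions = tg$y_positions,
           normalization = tg$normalization, polarisation = tg$polarisation,
           solver = tg$solver, n_med = tg$n_med, scale = "linear",
           intensity = tg$intensity),
      file.path(dir, "tomogram.json"), auto_unbox = TRUE, digits = NA)
  }
  img <- NULL
  if (any(c("png", "tiff") %in% formats)) {
    v <- tg$intensity
    if (scale == "log") {
      v <- 10 * log10(pmax(v / max(v), 10^(floor_db / 10)))
      v <- (v - floor_db) / (-floor_db)
    } else v <- v / max(v)
    img <- pmin(pmax(v, 0), 1)        # rows = depth, columns = lateral
  }
  if ("png" %in% formats) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required for PNG export")
    png::writePNG(img, file.path(dir, "tomogram.png"), dpi = NULL)
  }
  if ("tiff" %in% formats) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF export")
    tiff::writeTIFF(img, file.path(dir, "tomogram.tiff"), bits.per.sample = 16L)
  }
  intf <- data.frame(
    omega = rep(tg$spectrum$omega, times = length(tg$y_positions)),
    y = rep(tg$y_positions, each = length(tg$spectrum$omega)),
    Re_alpha_sca = as.vector(Re(tg$alpha_sca)),
    Im_alpha_sca = as.vector(Im(tg$alpha_sca)),
    Re_alpha_ref = rep(Re(tg$alpha_ref), times = length(tg$y_positions)),
    Im_alpha_ref = rep(Im(tg$alpha_ref), times = length(tg$y_positions)))
  write.csv(intf, file.path(dir, "interferogram.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read the JSON tomogram artifact
#'
#' @param path `tomogram.json` written by [write_tomogram()]
#' @return list with the stored axes and intensity matrix
#' @export
read_tomogram <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$intensity <- matrix(unlist(x$intensity), length(x$depth),
                        length(x$y_positions))
  x
}

# build a scene from the config scene block
.scene_from_config <- function(sc) {
  type <- sc$type %||% stop("config error at scene.type: missing")
  switch(type,
    json = read_scene(sc$file),
    single_cylinder = make_single_cylinder(sc$radius, sc$n_cyl, sc$n_med,
                                           center = as.numeric(sc$center %||% c(0, 0))),
    cluster = make_cylinder_cluster(
      phantom_spec(sc$count, list(type = "disc",
                                  center = as.numeric(sc$region_center %||% c(0, 0)),
                                  radius = sc$region_radius),
                   sc$radius, sc$n_cyl, seed = sc$seed %||% 1L,
                   allow_overlap = sc$allow_overlap %||% TRUE,
                   jitter = if (!is.null(sc$jitter)) as.numeric(sc$jitter)),
      n_med = sc$n_med),
    ziggurat = make_ziggurat(as.numeric(sc$plateau_widths), sc$step_height,
                             sc$index, sc$n_med, x0 = sc$x0 %||% 0),
    dentin = make_dentin_slab(
      phantom_spec(sc$count, list(type = "rect", xmin = sc$xmin, xmax = sc$xmax,
                                  ymin = sc$ymin, ymax = sc$ymax),
                   sc$radius %||% 1e-6, sc$n_tubule %||% 1.33,
                   seed = sc$seed %||% 1L,
                   allow_overlap = sc$allow_overlap %||% TRUE),
      n_dentin = sc$n_dentin %||% 1.52, n_tubule = sc$n_tubule %||% 1.33),
    stop("config error at scene.type: unknown type '", type, "'"))
}

#' Run a full simulation from a YAML configuration file
#'
#' The configuration has `instrument`, `scene`, `solver`, `scan` and `output`
#' blocks (all units SI); see the bundled example under
#' `system.file("examples", package = "octsim2d")`. Writes the tomogram
#' artifacts, the interferograms, the resolved configuration (including the
#' seed) and a run log into the output directory. Identical configuration and
#' seed give bit-identical outputs.
#'
#' @param path YAML configuration file
#' @return the [run_bscan()] tomogram, invisibly
#' @export
run_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- function(block, field, default = NULL) {
    v <- cfg[[block]][[field]]
    if (is.null(v)) {
      if (is.null(default))
        stop(sprintf("config error at %s.%s: missing required field",
                     block, field))
      v <- default
    }
    v
  }
  N <- as.integer(need("instrument", "n_wavenumbers", 160L))
  if (N %% 2 != 0)
    stop("config error at instrument.n_wavenumbers: N must be even ",
         "(the reconstruction uses the -N/2 .. N/2-1 DFT index convention)")
  sysm <- optical_system(
    f1 = need("instrument", "f1", 25e-3), f2 = need("instrument", "f2", 36e-3),
    h = need("instrument", "h", 3.5e-3),
    n_med = need("instrument", "n_med", 1.35),
    n_debye = need("instrument", "n_debye", 1))
  mode <- fiber_mode(w0 = need("instrument", "w0", 4.6e-6),
                     E0 = need("instrument", "E0", 1))
  spectrum <- build_spectrum(
    lambda0 = need("instrument", "lambda0", 1.3e-6),
    delta_lambda = need("instrument", "delta_lambda", 170e-9),
    epsilon = need("instrument", "epsilon", 1e-3), N = N)
  scn <- .scene_from_config(cfg$scene %||%
                              stop("config error at scene: missing block"))
  scan <- cfg$scan %||% list()
  ys <- if (!is.null(scan$y_positions)) as.numeric(scan$y_positions)
        else seq(scan$y_from %||% 0, scan$y_to %||% 0,
                 length.out = scan$n_positions %||% 1)
  pol <- check_pol(scan$polarisation %||% "perpendicular")
  sol <- cfg$solver %||% list()
  solver <- sol$path %||% "analytic"
  scfg <- solver_config(tolerance = sol$tolerance %||% 1e-5,
                        max_iterations = sol$max_iterations %||% 2000,
                        scheme = sol$scheme %||% "convergent_born")
  out <- cfg$output %||% list()
  dir <- out$dir %||% stop("config error at output.dir: missing")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  tg <- run_bscan(scn, sysm, spectrum, mode, pol, y_positions = ys,
                  solver = solver, cfg = scfg,
                  dx = sol$dx %||% NULL,
                  subsampling = sol$subsampling %||% 10L,
                  boundary_width = sol$boundary_width %||% 10e-6)
  write_tomogram(tg, dir,
                 formats = unlist(out$formats %||% c("csv", "json")),
                 scale = out$scale %||% "linear")
  write_scene(scn, file.path(dir, "scene.json"))
  yaml::write_yaml(cfg, file.path(dir, "config_resolved.yaml"))
  log <- c(sprintf("octsim2d %s", as.character(packageVersion("octsim2d"))),
           sprintf("R %s", R.version.string),
           sprintf("config: %s", normalizePath(path)),
           sprintf("config sha: %s", .file_hash(path)),
           sprintf("seed: %s", cfg$scene$seed %||% "none"),
           sprintf("solver: %s (%s)", solver, scfg$scheme),
           sprintf("positions: %d, wavenumbers: %d", length(ys), N),
           sprintf("normalization: %.17g", tg$normalization),
           sprintf("elapsed: %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  writeLines(log, file.path(dir, "run.log"))
  invisible(tg)
}

# small dependency-free content hash (DJB2 over the file bytes, hex)
.file_hash <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Summarize a tomogram
#'
#' Reports, per A-scan, the strongest echo depths, plus the global maximum,
#' the stored normalization constant, and the maximum visible depth of the
#' run's sampling parameters.
#'
#' @param tg a `tomogram` from [run_bscan()], or the path of a
#'   `tomogram.json` artifact
#' @param threshold report peaks stronger than `threshold` times the global
#'   maximum
#' @return list with `peaks` (data frame: y, depth, intensity), `global_max`,
#'   `normalization`, `max_visible_depth`
#' @export
summarize <- function(tg, threshold = 1e-3) {
  if (is.character(tg)) {
    meta <- read_tomogram(tg)
    depth <- meta$depth; ys <- meta$y_positions; I <- meta$intensity
    norm <- meta$normalization; mvd <- NA_real_
  } else {
    depth <- tg$depth; ys <- tg$y_positions; I <- tg$intensity
    norm <- tg$normalization
    mvd <- max_visible_depth(tg$spectrum$N, tg$spectrum$b,
                             tg$spectrum$epsilon, tg$n_med)
  }
  gmax <- max(I)
  rows <- list()
  for (j in seq_along(ys)) {
    v <- I[, j]; n <- length(v)
    loc <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
    loc <- loc[v[loc] >= threshold * gmax]
    if (length(loc))
      rows[[j]] <- data.frame(y = ys[j], depth = depth[loc],
                              intensity = v[loc])
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(y = numeric(0), depth = numeric(0), intensity = numeric(0))
  structure(list(peaks = peaks[order(peaks$y, -peaks$intensity), ],
                 global_max = gmax, normalization = norm,
                 max_visible_depth = mvd),
            class = "tomogram_summary")
}

#' @export
print.tomogram_summary <- function(x, ...) {
  cat(sprintf("global max %.4g (normalization %.4g); max visible depth %s\n",
              x$global_max, x$normalization,
              if (is.na(x$max_visible_depth)) "unknown"
              else sprintf("%.1f um", x$max_visible_depth * 1e6)))
  if (nrow(x$peaks)) {
    cat(sprintf("%d peak(s):\n", nrow(x$peaks)))
    print(within(x$peaks, {depth <- depth * 1e6; y <- y * 1e6}),
          row.names = FALSE)
    cat("(depth, y in um)\n")
  } else cat("no peaks above threshold\n")
  invisible(x)
}
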