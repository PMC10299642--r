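#' Generate a ground-truth kinocilium centreline
#'
#' Builds a smooth 3D space curve emulating a single kinocilium of the
#' lateral crista: a straight proximal-distal axis (along x) with an
#' optional sinusoidal lateral bow in y, rescaled so that the polyline arc
#' length equals `length_um` exactly. Curvature of kinocilia ranges from
#' essentially straight (wild type) to visibly bent (microtubule
#' inner-protein overexpression), which `curvature_amp` parameterizes.
#'
#' @param length_um Target arc length in micrometres (> 0). Lateral-crista
#'   kinocilia of larval zebrafish run roughly 25--40 um.
#' @param curvature_amp Peak lateral displacement of the sinusoidal bow, um.
#'   0 gives a straight segment.
#' @param n_points Number of control points (>= 2).
#' @param rng_seed Optional integer; when given, the phase of the sinusoidal
#'   bow is randomized reproducibly, otherwise the phase is 0.
#' @param pattern Along-filament intensity pattern label, one of
#'   `"uniform"`, `"proximal"`, `"distal"`, `"bulbed"` (see
#'   [profile_model()]).
#' @param amplitude Peak emitter intensity in gray units (16-bit scale).
#' @param pattern_params Named list of overrides for the pattern shape
#'   constants of [profile_model()].
#' @param cycles Number of full sine periods of the bow along the filament.
#' @param z_rise_um Total linear rise in z from base to tip, um (0 keeps the
#'   curve in a single optical plane).
#' @param origin Length-3 numeric `(x, y, z)` physical offset of the base, um.
#' @param id Optional curve identifier used in error messages and outputs.
#'
#' @return A `ground_truth_curve`: list with `points` (n x 3 matrix, columns
#'   `x`, `y`, `z` in um), `arc_length` (polyline sum, equal to `length_um`
#'   within 1e-3 um), `pattern`, `amplitude`, `pattern_params`, `id`.
#' @export
generate_curve <- function(length_um, curvature_amp = 0, n_points = 200L,
                           rng_seed = NULL, pattern = "uniform",
                           amplitude = 3000, pattern_params = list(),
                           cycles = 1, z_rise_um = 0,
                           origin = c(0, 0, 0), id = "kc") {
  if (!is.numeric(length_um) || length_um <= 0) {
    stop("`length_um` must be positive", call. = FALSE)
  }
  if (n_points < 2L) stop("`n_points` must be at least 2", call. = FALSE)
  if (curvature_amp < 0) stop("`curvature_amp` must be >= 0", call. = FALSE)
  phase <- if (is.null(rng_seed)) 0 else {
    withr::with_seed(as.integer(rng_seed), stats::runif(1, 0, 2 * pi))
  }
  tt <- seq(0, 1, length.out = n_points)
  yy <- if (curvature_amp > 0) curvature_amp * sin(2 * pi * cycles * tt + phase) -
    curvature_amp * sin(phase) else rep(0, n_points)
  zz <- z_rise_um * tt

  polylen <- function(ax) {
    dx <- diff(ax * tt); dy <- diff(yy); dz <- diff(zz)
    sum(sqrt(dx^2 + dy^2 + dz^2))
  }
  # solve for the axial extent giving the requested polyline arc length
  base_len <- polylen(0)
  if (base_len >= length_um) {
    stop("lateral/axial displacement alone exceeds `length_um`; ",
         "reduce `curvature_amp` or `z_rise_um`", call. = FALSE)
  }
  ax <- if (base_len == 0 && curvature_amp == 0) length_um else {
    stats::uniroot(function(a) polylen(a) - length_um,
                   lower = 0, upper = length_um, tol = 1e-12)$root
  }
  pts <- cbind(x = ax * tt + origin[1], y = yy + origin[2], z = zz + origin[3])
  structure(
    list(points = pts,
         arc_length = polylen(ax),
         pattern = match.arg(pattern, c("uniform", "proximal", "distal", "bulbed")),
         amplitude = amplitude,
         pattern_params = pattern_params,
         id = as.character(id)),
    class = "ground_truth_curve"
  )
}

# default shape constants for the along-filament patterns; s is the
# normalized arc position (0 = base, 1 = distal tip)
.pattern_defaults <- list(
  uniform  = list(),
  proximal = list(s0 = 0.45, k = 0.07, floor = 0.05),
  distal   = list(s0 = 0.60, k = 0.08, floor = 0.15),
  bulbed   = list(s0 = 0.60, k = 0.08, floor = 0.15,
                  bump_amp = 0.45, bump_sigma = 1.5 / 32)
)

#' Relative intensity of an along-filament localization pattern
#'
#' Closed-form idealizations of the qualitative localization classes seen
#' for kinocilial proteins: `"uniform"` (tubulin-like, constant along the
#' axoneme), `"proximal"` (middle-proximal restriction: a plateau followed
#' by a logistic fall-off), `"distal"` (tip enrichment with middle-proximal
#' depletion: a logistic rise), and `"bulbed"` (distal enrichment plus a
#' Gaussian accumulation at the tip, as in strong overexpression
#' phenotypes).
#'
#' @param pattern Pattern label.
#' @param s Normalized arc position(s) in `[0, 1]`; 0 is the base, 1 the tip.
#' @param params Named list overriding the pattern shape constants:
#'   `s0` (logistic midpoint), `k` (logistic width), `floor` (baseline
#'   fraction), and for `"bulbed"` also `bump_amp` and `bump_sigma`
#'   (tip-bump height and width in normalized units; the default width
#'   corresponds to 1.5 um on a 32 um filament).
#'
#' @return Relative intensity values in `[0, 1]`, same length as `s`.
#' @export
profile_model <- function(pattern, s, params = list()) {
  pattern <- match.arg(pattern, names(.pattern_defaults))
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("`s` must lie in [0, 1]", call. = FALSE)
  }
  p <- utils::modifyList(.pattern_defaults[[pattern]], params)
  switch(pattern,
    uniform  = rep(1, length(s)),
    proximal = p$floor + (1 - p$floor) * stats::plogis((p$s0 - s) / p$k),
    distal   = p$floor + (1 - p$floor) * stats::plogis((s - p$s0) / p$k),
    bulbed   = pmin(1, 0.75 * (p$floor + (1 - p$floor) *
                                 stats::plogis((s - p$s0) / p$k)) +
                       p$bump_amp * exp(-(1 - s)^2 / (2 * p$bump_sigma^2)))
  )
}

#' Bundle curves and imaging parameters into a scene manifest
#'
#' The manifest is the ground-truth record of a synthetic scene: which
#' filaments it contains, the point-spread-function widths, background,
#' noise model and the seed that makes rendering reproducible.
#'
#' @param curves List of [generate_curve()] objects.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF standard deviations, um
#'   (lateral / axial). Must be >= 0.
#' @param background Constant background level, gray units.
#' @param noise_sd Additive Gaussian read-noise standard deviation, gray
#'   units; 0 disables.
#' @param poisson Logical; add Poisson shot noise (each voxel replaced by a
#'   Poisson draw with its noiseless mean)?
#' @param seed Integer seed consumed at render time.
#' @return A `scene_manifest` object.
#' @export
scene_manifest <- function(curves, psf_sigma_xy = 0.15, psf_sigma_z = 0.35,
                           background = 100, noise_sd = 0, poisson = FALSE,
                           seed = 1L) {
  if (inherits(curves, "ground_truth_curve")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, TRUE, "ground_truth_curve")),
            psf_sigma_xy >= 0, psf_sigma_z >= 0, noise_sd >= 0,
            background >= 0)
  structure(
    list(curves = curves, psf_sigma_xy = psf_sigma_xy,
         psf_sigma_z = psf_sigma_z, background = background,
         noise_sd = noise_sd, poisson = isTRUE(poisson),
         seed = as.integer(seed)),
    class = "scene_manifest"
  )
}

#' Voxel seeds for a curve's base and tip
#'
#' Rounds the physical base and tip coordinates of a ground-truth curve to
#' the nearest voxel, the only place where spacing anisotropy enters the
#' geometry of rendering and tracing.
#'
#' @param curve A [generate_curve()] object.
#' @param spacing_xy,spacing_z Voxel spacing, um.
#' @return List with integer `(z, y, x)` vectors `base` and `tip` (1-based).
#' @export
curve_seeds <- function(curve, spacing_xy = 0.064, spacing_z = 0.65) {
  tovox <- function(p) c(z = round(unname(p["z"]) / spacing_z) + 1,
                         y = round(unname(p["y"]) / spacing_xy) + 1,
                         x = round(unname(p["x"]) / spacing_xy) + 1)
  n <- nrow(curve$points)
  list(base = vapply(tovox(curve$points[1, ]), as.integer, 1L),
       tip  = vapply(tovox(curve$points[n, ]), as.integer, 1L))
}

# resample a curve's polyline at fixed arc-length steps; returns a matrix
# with columns x, y, z, s (s = arc position from the base)
.resample_curve <- function(points, ds) {
  seg <- sqrt(rowSums(diff(points)^2))
  cs <- c(0, cumsum(seg))
  total <- cs[length(cs)]
  s <- seq(0, total, by = ds)
  if (s[length(s)] < total) s <- c(s, total)
  cbind(x = stats::approx(cs, points[, "x"], xout = s)$y,
        y = stats::approx(cs, points[, "y"], xout = s)$y,
        z = stats::approx(cs, points[, "z"], xout = s)$y,
        s = s)
}

#' Render a synthetic confocal stack from a scene manifest
#'
#' Forward imaging model: each filament is a line emitter whose local
#' brightness is `amplitude * profile_model(pattern, s)`; the line is
#' densely resampled and each sample deposits an anisotropic 3D Gaussian
#' (the PSF) into the voxel grid, normalized so that the on-axis intensity
#' of a long filament equals its amplitude. Background, optional Poisson
#' shot noise and additive Gaussian read noise follow; values are clipped
#' to the 16-bit range (kept as floating point; [write_stack()] rounds to
#' integers). Rendering is deterministic given the manifest seed.
#'
#' @param manifest A [scene_manifest()].
#' @param shape Integer `(nz, ny, nx)` grid dimensions.
#' @param spacing_xy,spacing_z Voxel spacing, um.
#' @param name Stack label.
#' @return A [voxel_grid()].
#' @export
render_stack <- function(manifest, shape, spacing_xy = 0.064,
                         spacing_z = 0.65, name = "synthetic") {
  stopifnot(inherits(manifest, "scene_manifest"), length(shape) == 3L)
  shape <- as.integer(shape)
  ext <- c(z = (shape[1] - 1) * spacing_z,
           y = (shape[2] - 1) * spacing_xy,
           x = (shape[3] - 1) * spacing_xy)
  arr <- array(0, dim = shape)
  sxy <- manifest$psf_sigma_xy; sz <- manifest$psf_sigma_z
  rx <- max(1L, ceiling(3 * sxy / spacing_xy))
  rz <- max(1L, ceiling(3 * sz / spacing_z))
  ds <- spacing_xy  # dense line resampling step
  kern1d <- function(d, sigma, spacing) {
    if (sigma > 0) exp(-d^2 / (2 * sigma^2)) else as.numeric(abs(d) <= spacing / 2)
  }
  norm <- max(sqrt(2 * pi) * sxy, ds)

  for (ci in seq_along(manifest$curves)) {
    cv <- manifest$curves[[ci]]
    pts <- cv$points
    if (any(pts[, "x"] < 0 | pts[, "x"] > ext["x"] |
            pts[, "y"] < 0 | pts[, "y"] > ext["y"] |
            pts[, "z"] < 0 | pts[, "z"] > ext["z"])) {
      stop(sprintf("curve %d ('%s') extends outside the grid", ci, cv$id),
           call. = FALSE)
    }
    sm <- .resample_curve(pts, ds)
    w <- cv$amplitude *
      profile_model(cv$pattern, sm[, "s"] / max(sm[, "s"]), cv$pattern_params) *
      ds / norm
    for (i in seq_len(nrow(sm))) {
      izc <- round(sm[i, "z"] / spacing_z) + 1
      iyc <- round(sm[i, "y"] / spacing_xy) + 1
      ixc <- round(sm[i, "x"] / spacing_xy) + 1
      iz <- max(1L, izc - rz):min(shape[1], izc + rz)
      iy <- max(1L, iyc - rx):min(shape[2], iyc + rx)
      ix <- max(1L, ixc - rx):min(shape[3], ixc + rx)
      kz <- kern1d((iz - 1) * spacing_z - sm[i, "z"], sz, spacing_z)
      ky <- kern1d((iy - 1) * spacing_xy - sm[i, "y"], sxy, spacing_xy)
      kx <- kern1d((ix - 1) * spacing_xy - sm[i, "x"], sxy, spacing_xy)
      arr[iz, iy, ix] <- arr[iz, iy, ix] + w[i] * outer(kz, ky %o% kx)
    }
  }
  arr <- arr + manifest$background
  if (manifest$poisson || manifest$noise_sd > 0) {
    arr <- withr::with_seed(manifest$seed, {
      a <- arr
      if (manifest$poisson) {
        a <- array(stats::rpois(length(a), lambda = pmax(a, 0)), dim = dim(a))
      }
      if (manifest$noise_sd > 0) {
        a <- a + stats::rnorm(length(a), 0, manifest$noise_sd)
      }
      a
    })
  }
  arr <- pmin(pmax(arr, 0), 65535)
  voxel_grid(arr, spacing_xy, spacing_z, name)
}

#' Write / read a scene manifest as JSON
#'
#' The JSON round trip is lossless: a manifest written and re-read renders
#' a bit-identical stack under the same seed.
#'
#' @param manifest A [scene_manifest()].
#' @param path JSON file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the reconstructed `scene_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "scene_manifest"))
  out <- unclass(manifest)
  out$curves <- lapply(manifest$curves, function(cv) {
    u <- unclass(cv)
    u$points <- apply(cv$points, 2, identity, simplify = FALSE)
    u
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  curves <- lapply(raw$curves, function(cv) {
    pts <- cbind(x = unlist(cv$points$x), y = unlist(cv$points$y),
                 z = unlist(cv$points$z))
    structure(
      list(points = pts, arc_length = as.numeric(cv$arc_length),
           pattern = cv$pattern, amplitude = as.numeric(cv$amplitude),
           pattern_params = lapply(cv$pattern_params, unlist), id = cv$id),
      class = "ground_truth_curve")
  })
  scene_manifest(curves, raw$psf_sigma_xy, raw$psf_sigma_z, raw$background,
                 raw$noise_sd, raw$poisson, raw$seed)
}

#' Simulate a grouped kinocilium length study
#'
#' Hierarchical noise model for per-larva length variation: each larva draws
#' a normal offset around its group's true mean (`sd_between`), and each of
#' its kinocilia adds independent within-larva scatter (`sd_within`);
#' lengths are truncated at zero by redrawing (which never triggers at
#' realistic means near 26--37 um). Each group needs at least five
#' kinocilia per larva so that the per-larva average of the five tallest is
#' defined.
#'
#' @param group_specs Named list; each element a list with `true_mean` (um),
#'   `sd_between`, `sd_within` (um, >= 0), `n_larvae` (>= 1) and
#'   `kinocilia_per_larva` (>= 5).
#' @param rng_seed Integer seed.
#' @return A data.frame with columns `group`, `larva`, `kinocilium`,
#'   `length_um`, `measurable` (all `TRUE` here; tracing may clear it).
#' @export
simulate_length_study <- function(group_specs, rng_seed = 1L) {
  stopifnot(is.list(group_specs), length(names(group_specs)) == length(group_specs))
  for (g in names(group_specs)) {
    sp <- group_specs[[g]]
    if (sp$kinocilia_per_larva < 5) {
      stop(sprintf(paste0("group '%s': `kinocilia_per_larva` must be >= 5 so the ",
                          "per-larva average of the five tallest kinocilia is defined"), g),
           call. = FALSE)
    }
    if (sp$n_larvae < 1) stop("`n_larvae` must be >= 1", call. = FALSE)
    if (sp$sd_between < 0 || sp$sd_within < 0) {
      stop("standard deviations must be >= 0", call. = FALSE)
    }
  }
  withr::with_seed(as.integer(rng_seed), {
    rows <- lapply(names(group_specs), function(g) {
      sp <- group_specs[[g]]
      larva_off <- stats::rnorm(sp$n_larvae, 0, sp$sd_between)
      do.call(rbind, lapply(seq_len(sp$n_larvae), function(l) {
        mu <- sp$true_mean + larva_off[l]
        len <- stats::rnorm(sp$kinocilia_per_larva, mu, sp$sd_within)
        while (any(len <= 0)) {
          bad <- len <= 0
          len[bad] <- stats::rnorm(sum(bad), mu, sp$sd_within)
        }
        data.frame(group = g, larva = sprintf("%s_L%02d", g, l),
                   kinocilium = seq_len(sp$kinocilia_per_larva),
                   length_um = len, measurable = TRUE,
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
}

#' Write / read a length dataset as TSV
#'
#' Plain TSV with header `group, larva, kinocilium, length_um, measurable`.
#'
#' @param dataset Data.frame as returned by [simulate_length_study()].
#' @param path TSV file path.
#' @return `write_length_table` returns `path` invisibly; `read_length_table`
#'   the data.frame.
#' @export
write_length_table <- function(dataset, path) {
  utils::write.table(dataset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_length_table
#' @export
read_length_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$measurable <- as.logical(df$measurable)
  df
}
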