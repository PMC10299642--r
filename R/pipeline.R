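#' Trace a kinocilium and sample its intensity profile in one step
#'
#' Convenience wrapper chaining the tracing and profiling stages: trace the
#' filament between the given seeds, decimate and flatten the path to a 2D
#' polyline, and sample the fixed-step intensity profile on the maximum
#' Z-projection.
#'
#' @param stack A [voxel_grid()].
#' @param base_seed,tip_seed Integer `(z, y, x)` voxel seeds (1-based).
#' @param width_px Perpendicular averaging width in pixels (default 2).
#' @param step_um Sampling step, um (default 0.064).
#' @param every Path decimation factor for [path_to_polyline()].
#' @param kinocilium_id Identifier carried through.
#' @return An `intensity_profile` with an added `path` attribute holding
#'   the `traced_path`.
#' @export
profile_from_trace <- function(stack, base_seed, tip_seed, width_px = 2L,
                               step_um = 0.064, every = 4L,
                               kinocilium_id = "kc") {
  pth <- trace_filament(stack, base_seed, tip_seed)
  poly <- path_to_polyline(pth, every = every)
  prof <- sample_profile(max_project(stack), poly, width_px = width_px,
                         step_um = step_um, spacing_xy = stack$spacing_xy,
                         kinocilium_id = kinocilium_id)
  attr(prof, "path") <- pth
  prof
}

#' End-to-end pattern recovery on synthetic kinocilia
#'
#' The package's self-validation experiment: render single-kinocilium
#' confocal scenes with known along-filament localization patterns, run the
#' full measurement pipeline (trace, project, profile, filter, register,
#' classify), and compare the recovered regionalization class against the
#' ground truth. Filament lengths, bow amplitudes and bow phases vary
#' randomly within realistic lateral-crista ranges; all randomness flows
#' from `rng_seed`.
#'
#' @param n_kinocilia Number of simulated kinocilia (split evenly across
#'   `patterns`).
#' @param rng_seed Integer seed.
#' @param noise_sd Additive Gaussian noise of the scenes, gray units.
#' @param patterns Localization patterns to cycle through.
#' @param length_range Filament arc-length range, um (kept above the 32 um
#'   measurability threshold).
#' @param curvature_range Sinusoidal bow amplitude range, um.
#' @param amplitude Peak filament intensity, gray units.
#' @param background Scene background, gray units.
#' @param tau Classifier dead-band half-width.
#' @return Data.frame with one row per kinocilium: `kinocilium_id`,
#'   `truth`, `class`, `centroid`, `length_um` (measured profile length).
#' @export
pattern_recovery_experiment <- function(n_kinocilia = 40L, rng_seed = 1L,
                                        noise_sd = 20,
                                        patterns = c("distal", "uniform",
                                                     "proximal"),
                                        length_range = c(33, 38),
                                        curvature_range = c(0.4, 1.2),
                                        amplitude = 3000, background = 100,
                                        tau = 0.05) {
  truth <- rep(patterns, length.out = n_kinocilia)
  par <- withr::with_seed(as.integer(rng_seed), data.frame(
    length_um = stats::runif(n_kinocilia, length_range[1], length_range[2]),
    curvature = stats::runif(n_kinocilia, curvature_range[1], curvature_range[2]),
    phase_seed = sample.int(.Machine$integer.max - 1L, n_kinocilia),
    noise_seed = sample.int(.Machine$integer.max - 1L, n_kinocilia)))
  sxy <- 0.064; sz <- 0.65
  margin <- 1.0
  profs <- vector("list", n_kinocilia)
  for (i in seq_len(n_kinocilia)) {
    amp <- par$curvature[i]
    cv <- generate_curve(par$length_um[i], curvature_amp = amp,
                         rng_seed = par$phase_seed[i], pattern = truth[i],
                         amplitude = amplitude,
                         origin = c(margin, 2 * amp + margin, 2 * sz),
                         id = sprintf("kc%02d_%s", i, truth[i]))
    nx <- ceiling((max(cv$points[, "x"]) + margin) / sxy) + 1L
    ny <- ceiling((4 * amp + 2 * margin) / sxy) + 1L
    man <- scene_manifest(cv, background = background, noise_sd = noise_sd,
                          seed = par$noise_seed[i])
    st <- render_stack(man, c(5L, ny, nx), sxy, sz)
    sds <- curve_seeds(cv, sxy, sz)
    profs[[i]] <- profile_from_trace(st, sds$base, sds$tip,
                                     kinocilium_id = cv$id)
  }
  kept <- filter_measurable(profs, min_len_um = 32)
  ens <- register_distal(kept)
  cls <- classify_registered(ens, background = background, tau = tau)
  ids <- vapply(profs, `[[`, "", "kinocilium_id")
  out <- data.frame(kinocilium_id = ids, truth = truth,
                    length_um = vapply(profs, `[[`, 0, "length_um"),
                    stringsAsFactors = FALSE)
  out <- merge(out, cls, by = "kinocilium_id", all.x = TRUE, sort = FALSE)
  out[match(ids, out$kinocilium_id), ]
}

#' Classify every kinocilium of a registered ensemble
#'
#' Applies [regionalization_index()] to each row after subtracting the
#' stated background level (negative residuals clamp to zero), so that the
#' centroid reflects filament signal rather than the constant camera
#' offset.
#'
#' @param ensemble A [register_distal()] result.
#' @param background Background gray level to subtract (default 0).
#' @param tau Dead-band half-width of the classifier (default 0.05).
#' @return Data.frame with `kinocilium_id`, `centroid`, `class`.
#' @export
classify_registered <- function(ensemble, background = 0, tau = 0.05) {
  stopifnot(inherits(ensemble, "registered_ensemble"))
  m <- ensemble$matrix
  rows <- lapply(seq_len(nrow(m)), function(i) {
    ri <- regionalization_index(pmax(m[i, ] - background, 0), tau = tau)
    data.frame(kinocilium_id = rownames(m)[i], centroid = ri$centroid,
               class = ri$class, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
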