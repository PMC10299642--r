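#' Maximum Z-projection of a stack
#'
#' Collapses a confocal Z-stack to a 2D image by taking, at each `(y, x)`
#' pixel, the maximum intensity over all optical sections -- the standard
#' presentation for encoding pixel intensity along thin fluorescent
#' structures.
#'
#' @param stack A [voxel_grid()].
#' @return Numeric matrix (rows = y, columns = x).
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "voxel_grid"))
  d <- dim(stack$data)
  if (d[1] < 1L) stop("empty stack", call. = FALSE)
  out <- stack$data[1, , , drop = TRUE]
  if (d[1] > 1L) {
    for (z in 2:d[1]) out <- pmax(out, stack$data[z, , , drop = TRUE])
  }
  out
}

#' Sample an intensity profile along a polyline at fixed arc-length steps
#'
#' Emulates a segmented-line plot profile on a projection image: gray
#' values are read by bilinear interpolation every `step_um` along the
#' polyline's arc length, and a line width of `width_px` averages that many
#' perpendicular samples spaced one pixel apart, centred on the line (width
#' 2 reads at offsets of plus and minus half a pixel).
#'
#' @param image Numeric matrix (rows = y, columns = x), e.g. from
#'   [max_project()].
#' @param polyline Matrix with columns `x`, `y` in micrometres.
#' @param width_px Number of perpendicular samples averaged per position
#'   (default 2).
#' @param step_um Sampling step along the arc, um (default 0.064, one
#'   lateral pixel).
#' @param spacing_xy Lateral pixel pitch of `image`, um.
#' @param kinocilium_id Identifier carried into the result.
#' @return An `intensity_profile`: list with `kinocilium_id`, `positions`
#'   (um from the base, `0, step, 2*step, ...`), `values` (mean gray) and
#'   `length_um` (the last position).
#' @export
sample_profile <- function(image, polyline, width_px = 2L, step_um = 0.064,
                           spacing_xy = 0.064, kinocilium_id = "kc") {
  stopifnot(is.matrix(image), is.matrix(polyline), ncol(polyline) >= 2)
  if (step_um <= 0) stop("`step_um` must be positive", call. = FALSE)
  xs <- polyline[, "x"]; ys <- polyline[, "y"]
  ext_x <- (ncol(image) - 1) * spacing_xy
  ext_y <- (nrow(image) - 1) * spacing_xy
  margin <- (width_px / 2) * spacing_xy
  bad <- which(xs < -1e-9 | xs > ext_x + 1e-9 |
                 ys < -1e-9 | ys > ext_y + 1e-9)
  if (length(bad)) {
    stop(sprintf("polyline vertex %d (x=%.3f, y=%.3f um) lies outside the image",
                 bad[1], xs[bad[1]], ys[bad[1]]), call. = FALSE)
  }

  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  keep <- seg > 0
  if (!any(keep)) stop("polyline has zero length", call. = FALSE)
  # collapse zero-length segments
  xs <- c(xs[1], xs[-1][keep]); ys <- c(ys[1], ys[-1][keep])
  seg <- seg[keep]
  cs <- c(0, cumsum(seg))
  total <- cs[length(cs)]
  # small epsilon so an exact multiple of the step is not lost to rounding
  pos <- seq(0, by = step_um, length.out = floor(total / step_um + 1e-7) + 1)

  # point and unit tangent at each arc position
  i <- findInterval(pos, cs, rightmost.closed = TRUE)
  i[i >= length(cs)] <- length(cs) - 1
  fr <- (pos - cs[i]) / seg[i]
  px <- xs[i] + fr * (xs[i + 1] - xs[i])
  py <- ys[i] + fr * (ys[i + 1] - ys[i])
  tx <- (xs[i + 1] - xs[i]) / seg[i]
  ty <- (ys[i + 1] - ys[i]) / seg[i]
  # perpendicular offsets: width_px samples spaced one pixel, centred
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * spacing_xy
  gx <- (seq_len(ncol(image)) - 1) * spacing_xy
  gy <- (seq_len(nrow(image)) - 1) * spacing_xy
  sx <- rep(px, times = width_px) + rep(offs, each = length(pos)) * rep(-ty, width_px)
  sy <- rep(py, times = width_px) + rep(offs, each = length(pos)) * rep(tx, width_px)
  sx <- pmin(pmax(sx, 0), ext_x)
  sy <- pmin(pmax(sy, 0), ext_y)
  vals <- pracma::interp2(gx, gy, image, sx, sy, method = "linear")
  values <- rowMeans(matrix(vals, nrow = length(pos), ncol = width_px))

  structure(list(kinocilium_id = as.character(kinocilium_id),
                 positions = pos, values = values,
                 length_um = pos[length(pos)]),
            class = "intensity_profile")
}

#' Keep only profiles long enough to measure unambiguously
#'
#' Profiles must span at least `min_len_um` (default 32 um) so that a full
#' tip-registered window exists; the boundary is inclusive and input order
#' is preserved.
#'
#' @param profiles List of `intensity_profile` objects.
#' @param min_len_um Minimum profile length, um.
#' @return Filtered list.
#' @export
filter_measurable <- function(profiles, min_len_um = 32) {
  keep <- vapply(profiles, function(p) p$length_um >= min_len_um, TRUE)
  profiles[keep]
}

#' Register profiles at the distal tip over a fixed window
#'
#' Kinocilia differ in length, so profiles are aligned at their distal-most
#' measurement: each profile contributes exactly its last
#' `window_um / step_um + 1` samples (501 for a 32 um window at 0.064 um
#' steps), and any proximal overhang of longer kinocilia is discarded.
#' Column 1 of the matrix is the proximal end of the window (position 0
#' um), the last column the tip (position `window_um`).
#'
#' @param profiles List of `intensity_profile` objects, all with
#'   `length_um >= window_um` (see [filter_measurable()]).
#' @param window_um Window length, um (default 32).
#' @param step_um Sampling step, um (default 0.064).
#' @return A `registered_ensemble`: list with `matrix` (K x 501, row names
#'   = kinocilium ids), `positions` (0..window_um), `window_um`, `step_um`.
#' @export
register_distal <- function(profiles, window_um = 32, step_um = 0.064) {
  ncols <- as.integer(round(window_um / step_um)) + 1L
  rows <- lapply(profiles, function(p) {
    n <- length(p$values)
    if (n < ncols) {
      stop(sprintf("profile '%s' (%.2f um) is shorter than the %g um window; filter first",
                   p$kinocilium_id, p$length_um, window_um), call. = FALSE)
    }
    p$values[(n - ncols + 1L):n]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(profiles, `[[`, "", "kinocilium_id")
  structure(list(matrix = m,
                 positions = seq(0, by = step_um, length.out = ncols),
                 window_um = window_um, step_um = step_um),
            class = "registered_ensemble")
}

#' Locally weighted (Loess) smooth evaluated at the input positions
#'
#' Degree-1 local regression with tricube weights, fit exactly (no
#' interpolation surface) so that collinear input is reproduced to
#' numerical precision.
#'
#' @param x,y Numeric vectors.
#' @param span Loess span fraction. When the neighbourhood would hold fewer
#'   than four points the smoother degenerates to its global limit, an
#'   ordinary least-squares line.
#' @return Fitted values at `x`.
#' @export
fit_loess <- function(x, y, span = 0.75) {
  if (length(x) * span < 4) {
    return(as.numeric(stats::fitted(stats::lm(y ~ x))))
  }
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
}

#' Average a registered ensemble and rescale for presentation
#'
#' Position-wise mean gray values over all registered kinocilia are
#' min-max normalized to a 0--100 scale (so the display is comparable
#' across transgenes with different overall fluorescence levels), shown as
#' `log2(1 + rescaled)` (the +1 offset handles the exact zero at the
#' minimum), and smoothed with a Loess curve.
#'
#' @param ensemble A [register_distal()] result.
#' @param loess_span Loess span fraction (default 0.75).
#' @return An `averaged_profile`: list with `positions`, `mean_gray`,
#'   `rescaled`, `log2_values`, `loess`, `span`.
#' @export
average_rescale_log <- function(ensemble, loess_span = 0.75) {
  stopifnot(inherits(ensemble, "registered_ensemble"))
  mg <- colMeans(ensemble$matrix)
  rng <- range(mg)
  if (rng[2] - rng[1] <= 0) {
    stop("averaged profile is perfectly flat; min-max rescaling is undefined",
         call. = FALSE)
  }
  rescaled <- 100 * (mg - rng[1]) / (rng[2] - rng[1])
  lg <- log2(1 + rescaled)
  structure(list(positions = ensemble$positions, mean_gray = mg,
                 rescaled = rescaled, log2_values = lg,
                 loess = fit_loess(ensemble$positions, lg, loess_span),
                 span = loess_span),
            class = "averaged_profile")
}

#' @export
plot.averaged_profile <- function(x, ...) {
  graphics::plot(x$positions, x$log2_values, pch = 16, cex = 0.3,
                 col = "grey55", xlab = "position along kinocilium (um)",
                 ylab = "log2(1 + rescaled intensity)", ...)
  graphics::lines(x$positions, x$loess, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Intensity centroid along the filament and regionalization class
#'
#' Summarizes an along-filament weight vector (e.g. a registered intensity
#' row) by its normalized centroid `s` in `[0, 1]` and classifies the
#' pattern: `"proximal"` if `s < 0.5 - tau`, `"distal"` if
#' `s > 0.5 + tau`, otherwise `"uniform"`.
#'
#' @param profile_values Non-negative weights at equally spaced positions
#'   from base-of-window (first) to tip (last); at least one must be
#'   positive.
#' @param tau Dead-band half-width around 0.5 (default 0.05).
#' @return List with `centroid` and `class`.
#' @export
regionalization_index <- function(profile_values, tau = 0.05) {
  w <- as.numeric(profile_values)
  if (any(w < 0) || all(w == 0) || any(!is.finite(w))) {
    stop("weights must be non-negative, finite, with at least one positive value",
         call. = FALSE)
  }
  s <- if (length(w) == 1L) 0.5 else (seq_along(w) - 1) / (length(w) - 1)
  cen <- sum(s * w) / sum(w)
  cls <- if (cen < 0.5 - tau) "proximal" else if (cen > 0.5 + tau) "distal" else "uniform"
  list(centroid = cen, class = cls)
}

#' Export profiles as tidy TSV
#'
#' One row per (kinocilium, position): columns `kinocilium_id`,
#' `position_um`, `value`.
#'
#' @param profiles List of `intensity_profile` objects.
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_profiles_tidy <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(kinocilium_id = p$kinocilium_id, position_um = p$positions,
               value = p$values, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an averaged profile as TSV
#'
#' Columns `position_um, mean_gray, rescaled, log2_value, loess`.
#'
#' @param avg An `averaged_profile`.
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_averaged_profile <- function(avg, path) {
  df <- data.frame(position_um = avg$positions, mean_gray = avg$mean_gray,
                   rescaled = avg$rescaled, log2_value = avg$log2_values,
                   loess = avg$loess)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
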