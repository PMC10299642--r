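#' Trace a kinocilium from base to tip through a Z-stack
#'
#' Seeded, automated tracing: given user- or manifest-supplied base and tip
#' voxels, the tracer finds the minimum-cost path on the 26-connected voxel
#' graph. The cost of stepping between two neighbouring voxels is the mean
#' of their darkness penalties `(I_max - I + 1)` multiplied by the physical
#' step length, so the optimal path follows the bright filament ridge while
#' accounting for the anisotropic voxel spacing. `NA` voxels are treated as
#' masked and are never entered.
#'
#' @param stack A [voxel_grid()].
#' @param base_seed,tip_seed Integer `(z, y, x)` voxel triples (1-based).
#' @return A `traced_path`: list with `voxels` (n x 3 integer matrix,
#'   columns `z`, `y`, `x`), `physical` (matching micrometre coordinates),
#'   `cost` (accumulated path cost), `spacing_xy`, `spacing_z`. The first
#'   row is the base, the last the tip. Identical seeds give a single-point
#'   path with a warning.
#' @export
trace_filament <- function(stack, base_seed, tip_seed) {
  stopifnot(inherits(stack, "voxel_grid"),
            length(base_seed) == 3L, length(tip_seed) == 3L)
  d <- dim(stack$data)
  chk <- function(s, what) {
    if (any(s < 1L) || any(s > d)) {
      stop(sprintf("%s seed (%s) lies outside the %d x %d x %d grid",
                   what, paste(s, collapse = ","), d[1], d[2], d[3]),
           call. = FALSE)
    }
  }
  base_seed <- as.integer(round(base_seed)); tip_seed <- as.integer(round(tip_seed))
  chk(base_seed, "base"); chk(tip_seed, "tip")
  lin <- function(s) (s[1] - 1L) + d[1] * ((s[2] - 1L) + d[2] * (s[3] - 1L))
  if (all(base_seed == tip_seed)) {
    warning("base and tip seeds are identical; returning a single-point path")
    vox <- matrix(base_seed, nrow = 1, dimnames = list(NULL, c("z", "y", "x")))
    return(.traced_path(vox, 0, stack))
  }
  res <- dijkstra_trace(as.numeric(stack$data), d, lin(base_seed),
                        lin(tip_seed), stack$spacing_xy, stack$spacing_z)
  idx <- res$path
  vox <- cbind(z = idx %% d[1] + 1L,
               y = (idx %/% d[1]) %% d[2] + 1L,
               x = idx %/% (d[1] * d[2]) + 1L)
  .traced_path(vox, res$cost, stack)
}

.traced_path <- function(vox, cost, stack) {
  phys <- cbind(z = (vox[, "z"] - 1) * stack$spacing_z,
                y = (vox[, "y"] - 1) * stack$spacing_xy,
                x = (vox[, "x"] - 1) * stack$spacing_xy)
  structure(list(voxels = vox, physical = phys, cost = cost,
                 spacing_xy = stack$spacing_xy, spacing_z = stack$spacing_z),
            class = "traced_path")
}

#' @export
print.traced_path <- function(x, ...) {
  cat(sprintf("<traced_path> %d voxels, chord %.2f um, arc %.2f um\n",
              nrow(x$voxels), euclidean_length(x), path_length(x)))
  invisible(x)
}

#' Cost of a voxel path under the tracing cost model
#'
#' Recomputes the accumulated edge cost of an arbitrary voxel path on a
#' stack (mean darkness penalty of each step's endpoints times physical
#' step length). Used to verify cost-optimality of traced paths.
#'
#' @param stack A [voxel_grid()].
#' @param voxels n x 3 integer matrix of `(z, y, x)` voxels.
#' @return Total path cost (0 for single-point paths).
#' @export
path_cost <- function(stack, voxels) {
  if (nrow(voxels) < 2L) return(0)
  imax <- max(stack$data, na.rm = TRUE)
  pen <- imax - stack$data[voxels] + 1
  stp <- diff(voxels)
  len <- sqrt((stp[, 2]^2 + stp[, 3]^2) * stack$spacing_xy^2 +
                stp[, 1]^2 * stack$spacing_z^2)
  sum(0.5 * (pen[-length(pen)] + pen[-1]) * len)
}

#' Base-to-tip chord length of a traced path
#'
#' The straight-line (Euclidean) distance between the first and last
#' physical points, `sqrt((dx*sxy)^2 + (dy*sxy)^2 + (dz*sz)^2)` -- the
#' conventional kinocilial length readout.
#'
#' @param path A `traced_path` from [trace_filament()].
#' @param spacing_xy,spacing_z Optional overrides of the spacing stored in
#'   the path (um, > 0).
#' @return Length in micrometres.
#' @export
euclidean_length <- function(path, spacing_xy = NULL, spacing_z = NULL) {
  sp <- .path_spacing(path, spacing_xy, spacing_z)
  v <- path$voxels
  n <- nrow(v)
  dv <- v[n, ] - v[1, ]
  sqrt((dv["y"]^2 + dv["x"]^2) * sp$xy^2 + dv["z"]^2 * sp$z^2)[[1]]
}

#' Polyline arc length of a traced path
#'
#' Sum of the physical lengths of all consecutive voxel steps. Always at
#' least the chord length, with equality for collinear paths.
#'
#' @inheritParams euclidean_length
#' @return Length in micrometres.
#' @export
path_length <- function(path, spacing_xy = NULL, spacing_z = NULL) {
  sp <- .path_spacing(path, spacing_xy, spacing_z)
  v <- path$voxels
  if (nrow(v) < 2L) return(0)
  stp <- diff(v)
  sum(sqrt((stp[, "y"]^2 + stp[, "x"]^2) * sp$xy^2 + stp[, "z"]^2 * sp$z^2))
}

.path_spacing <- function(path, spacing_xy, spacing_z) {
  xy <- if (is.null(spacing_xy)) path$spacing_xy else spacing_xy
  z <- if (is.null(spacing_z)) path$spacing_z else spacing_z
  if (!is.numeric(xy) || xy <= 0 || !is.numeric(z) || z <= 0) {
    stop("voxel spacings must be positive", call. = FALSE)
  }
  list(xy = xy, z = z)
}

#' Chord and arc length of a traced path, side by side
#'
#' @inheritParams euclidean_length
#' @param metric Which metric feeds downstream statistics: `"chord"`
#'   (default, base-to-tip Euclidean distance) or `"arc"` (polyline sum).
#' @return List with `euclidean_um`, `path_um`, `method` and `length_um`
#'   (the selected metric's value).
#' @export
length_result <- function(path, spacing_xy = NULL, spacing_z = NULL,
                          metric = c("chord", "arc")) {
  metric <- match.arg(metric)
  eu <- euclidean_length(path, spacing_xy, spacing_z)
  ar <- path_length(path, spacing_xy, spacing_z)
  list(euclidean_um = eu, path_um = ar, method = metric,
       length_um = if (metric == "chord") eu else ar)
}

#' Decimate a traced path to suppress voxel-level jaggedness
#'
#' 26-connected voxel paths zig-zag at the pixel scale, which inflates the
#' polyline arc length relative to the smooth filament. Keeping every
#' `every`-th voxel (plus both endpoints) yields a polyline that follows
#' the filament at a coarser step and measures arc length with far less
#' discretization bias.
#'
#' @param path A `traced_path`.
#' @param every Keep every `every`-th voxel (default 4).
#' @return A `traced_path` with the decimated voxel set.
#' @export
simplify_path <- function(path, every = 4L) {
  n <- nrow(path$voxels)
  keep <- unique(c(seq(1L, n, by = as.integer(every)), n))
  out <- path
  out$voxels <- path$voxels[keep, , drop = FALSE]
  out$physical <- path$physical[keep, , drop = FALSE]
  out
}

#' Flatten a traced path to a 2D polyline for profile sampling
#'
#' Projects the (decimated) path onto the image plane, matching profile
#' measurement on maximum Z-projections.
#'
#' @param path A `traced_path`.
#' @param every Decimation passed to [simplify_path()].
#' @return Matrix with columns `x`, `y` (um).
#' @export
path_to_polyline <- function(path, every = 4L) {
  sp <- simplify_path(path, every)
  cbind(x = sp$physical[, "x"], y = sp$physical[, "y"])
}

#' Flag whether a path was unambiguously traceable
#'
#' A traced kinocilium counts as measurable when the dimmest voxel along
#' its path still clears the background by two noise standard deviations;
#' below that the trace may have wandered off the filament.
#'
#' @param path A `traced_path`.
#' @param stack The [voxel_grid()] it was traced on.
#' @param background Background level, gray units.
#' @param noise_sd Noise standard deviation estimate, gray units.
#' @return Logical.
#' @export
is_measurable <- function(path, stack, background, noise_sd) {
  min(stack$data[path$voxels]) >= background + 2 * noise_sd
}

#' Per-larva average of the five tallest kinocilia
#'
#' The biological replicate for length statistics is the larva, summarized
#' by the mean of its five longest measurable kinocilia. Larvae with fewer
#' than five measurable records are dropped with a warning rather than
#' averaged over fewer.
#'
#' @param dataset Data.frame with columns `group`, `larva`, `length_um` and
#'   optionally `measurable` (missing column means all measurable).
#' @return Data.frame with one row per retained larva: `group`, `larva`,
#'   `mean_top5_um`.
#' @export
per_larva_top5 <- function(dataset) {
  stopifnot(all(c("group", "larva", "length_um") %in% names(dataset)))
  if (!"measurable" %in% names(dataset)) dataset$measurable <- TRUE
  dataset <- dataset[dataset$measurable, , drop = FALSE]
  # every larva must belong to exactly one group
  gmap <- unique(dataset[, c("group", "larva")])
  if (anyDuplicated(gmap$larva)) {
    stop("a larva appears in more than one group", call. = FALSE)
  }
  parts <- split(dataset$length_um, dataset$larva)
  short <- names(parts)[vapply(parts, length, 1L) < 5L]
  if (length(short)) {
    warning(sprintf("dropping %d larva(e) with fewer than 5 measurable kinocilia: %s",
                    length(short), paste(short, collapse = ", ")))
    parts <- parts[!names(parts) %in% short]
  }
  top5 <- vapply(parts, function(v) mean(sort(v, decreasing = TRUE)[1:5]), 0)
  out <- data.frame(larva = names(top5), mean_top5_um = unname(top5),
                    stringsAsFactors = FALSE)
  out$group <- gmap$group[match(out$larva, gmap$larva)]
  out[order(out$group, out$larva), c("group", "larva", "mean_top5_um")]
}

#' Read a seed table for batch tracing
#'
#' TSV with header `stack_id, kinocilium_id, base_z, base_y, base_x,
#' tip_z, tip_y, tip_x` (1-based voxel indices).
#'
#' @param path TSV file path.
#' @return Data.frame.
#' @export
read_seed_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
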