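# Shared builders for synthetic single-filament scenes and small oracles.

# Render one kinocilium-like filament in a grid sized to fit it, with a
# margin so the PSF never clips at the borders.
build_scene <- function(length_um = 33, curvature_amp = 1,
                        pattern = "uniform", noise_sd = 0, seed = 1L,
                        amplitude = 3000, spacing_xy = 0.064,
                        spacing_z = 0.65, rng_seed = NULL, nz = 5L,
                        id = pattern) {
  margin <- 1.0
  origin <- c(margin, 2 * curvature_amp + margin, 2 * spacing_z)
  cv <- generate_curve(length_um, curvature_amp, n_points = 200L,
                       rng_seed = rng_seed, pattern = pattern,
                       amplitude = amplitude, origin = origin, id = id)
  nx <- ceiling((max(cv$points[, "x"]) + margin) / spacing_xy) + 1L
  ny <- ceiling((4 * curvature_amp + 2 * margin) / spacing_xy) + 1L
  man <- scene_manifest(cv, background = 100, noise_sd = noise_sd,
                        seed = seed)
  st <- render_stack(man, c(nz, ny, nx), spacing_xy, spacing_z)
  list(stack = st, manifest = man, curve = cv,
       seeds = curve_seeds(cv, spacing_xy, spacing_z))
}

# Independent single-source shortest-path solver (O(V^2) scan) over the
# 26-connected voxel graph with the same edge-cost definition, for
# cross-checking the tracer on tiny grids.
reference_min_cost <- function(arr, sxy, sz, from, to) {
  d <- dim(arr)
  imax <- max(arr)
  coords <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                                  x = seq_len(d[3])))
  nv <- nrow(coords)
  idx_of <- function(s) which(coords[, 1] == s[1] & coords[, 2] == s[2] &
                                coords[, 3] == s[3])
  dist <- rep(Inf, nv); done <- rep(FALSE, nv)
  dist[idx_of(from)] <- 0
  goal <- idx_of(to)
  pen <- imax - arr[coords] + 1
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || done[goal]) break
    done[u] <- TRUE
    dz <- coords[, 1] - coords[u, 1]
    dy <- coords[, 2] - coords[u, 2]
    dx <- coords[, 3] - coords[u, 3]
    nb <- which(abs(dz) <= 1 & abs(dy) <= 1 & abs(dx) <= 1 & !done &
                  (dz != 0 | dy != 0 | dx != 0))
    if (length(nb)) {
      step <- sqrt((dy[nb]^2 + dx[nb]^2) * sxy^2 + dz[nb]^2 * sz^2)
      cand <- dist[u] + 0.5 * (pen[u] + pen[nb]) * step
      upd <- cand < dist[nb]
      dist[nb[upd]] <- cand[upd]
    }
  }
  dist[goal]
}
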