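test_that("generated curves hit the requested arc length exactly", {
  straight <- generate_curve(32, curvature_amp = 0, n_points = 50)
  chord <- sqrt(sum((straight$points[50, ] - straight$points[1, ])^2))
  expect_equal(straight$arc_length, 32, tolerance = 1e-12)
  expect_equal(chord, 32, tolerance = 1e-12)

  two <- generate_curve(5, n_points = 2)
  expect_identical(nrow(two$points), 2L)
  expect_equal(two$arc_length, 5)

  curved <- generate_curve(32, curvature_amp = 3, n_points = 400, rng_seed = 11)
  chord_c <- sqrt(sum((curved$points[400, ] - curved$points[1, ])^2))
  expect_lt(chord_c, 32)
  expect_equal(curved$arc_length, 32, tolerance = 1e-3)
  # independent arc-length check: dense numerical integration of the same
  # sinusoidal displacement (axial extent and phase read off the points)
  ax <- curved$points[400, "x"] - curved$points[1, "x"]
  tt <- seq(0, 1, length.out = 400)
  yfun <- stats::splinefun(tt, curved$points[, "y"])
  td <- seq(0, 1, length.out = 2e5)
  dense <- sum(sqrt(diff(ax * td)^2 + diff(yfun(td))^2))
  expect_equal(dense, 32, tolerance = 5e-3)

  expect_error(generate_curve(-1), "positive")
  expect_error(generate_curve(10, n_points = 1), "at least 2")
})

test_that("intensity pattern models obey their defining shapes", {
  s <- seq(0, 1, length.out = 101)
  expect_equal(profile_model("uniform", c(0, 0.37, 1)), c(1, 1, 1))
  # uniform integrates to exactly 1; all patterns have positive finite mean
  for (pat in c("uniform", "proximal", "distal", "bulbed")) {
    m <- mean(profile_model(pat, s))
    expect_true(is.finite(m) && m > 0)
  }
  expect_equal(mean(profile_model("uniform", s)), 1)

  expect_gt(profile_model("distal", 1), profile_model("distal", 0.5))
  # proximal is monotone non-increasing (finite-difference sign check)
  prox <- profile_model("proximal", s)
  expect_true(all(diff(prox) <= 1e-12))
  # bulbed exceeds its distal base near the tip
  expect_gt(profile_model("bulbed", 1), profile_model("distal", 1) * 0.75)

  expect_error(profile_model("distal", 1.2), "\\[0, 1\\]")
  expect_error(profile_model("distal", -0.1), "\\[0, 1\\]")
})

test_that("rendering is deterministic, background-exact and PSF-centred", {
  # background-only scene
  empty <- scene_manifest(list(), background = 100, noise_sd = 0, seed = 1)
  st0 <- render_stack(empty, c(3, 10, 12))
  expect_true(all(st0$data == 100))

  # straight filament along x at fixed (y, z): the per-column argmax of the
  # max projection must sit within 1 px of the true row
  cv <- generate_curve(6, curvature_amp = 0, origin = c(0.5, 2.0, 1.3),
                       amplitude = 2000)
  man <- scene_manifest(cv, noise_sd = 0, seed = 3)
  st <- render_stack(man, c(5, 64, 120))
  mip <- max_project(st)
  true_row <- round(2.0 / 0.064) + 1
  cols <- (round(0.7 / 0.064)):(round(6.3 / 0.064))
  hits <- vapply(cols, function(j) which.max(mip[, j]), 1L)
  expect_true(all(abs(hits - true_row) <= 1))

  # nearest voxel to any curve point is at least background
  sds <- curve_seeds(cv)
  expect_gte(st$data[sds$base[1], sds$base[2], sds$base[3]], 100)

  # determinism under a seed, including noise
  man_n <- scene_manifest(cv, noise_sd = 25, poisson = TRUE, seed = 42)
  a <- render_stack(man_n, c(5, 64, 120))
  b <- render_stack(man_n, c(5, 64, 120))
  expect_identical(a$data, b$data)

  # curve outside the grid names the offender
  far <- generate_curve(6, origin = c(0.5, 10, 1.3), id = "escapee")
  expect_error(render_stack(scene_manifest(far, seed = 1), c(5, 64, 120)),
               "escapee")
})

test_that("rendered signal is linear in curve amplitude below clipping", {
  mk <- function(amp) {
    cv <- generate_curve(5, curvature_amp = 0.5, origin = c(0.5, 1.5, 1.3),
                        amplitude = amp)
    render_stack(scene_manifest(cv, background = 100, noise_sd = 0, seed = 1),
                 c(5, 60, 100))$data - 100
  }
  one <- mk(800); two <- mk(1600)
  expect_true(max(abs(two - 2 * one)) <= 1e-6)
})

test_that("scene manifests round-trip through JSON to identical stacks", {
  cv <- generate_curve(6, curvature_amp = 1, rng_seed = 5,
                       origin = c(0.5, 2.5, 1.3), pattern = "bulbed")
  man <- scene_manifest(cv, noise_sd = 15, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(man, path)
  man2 <- read_manifest(path)
  s1 <- render_stack(man, c(5, 90, 120))
  s2 <- render_stack(man2, c(5, 90, 120))
  expect_identical(s1$data, s2$data)
})

test_that("stacks survive the 16-bit TIFF round trip", {
  cv <- generate_curve(4, origin = c(0.5, 1, 0.65))
  st <- render_stack(scene_manifest(cv, noise_sd = 10, seed = 2), c(3, 40, 80))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  st2 <- read_stack(path)
  expect_equal(st2$data, round(st$data))  # TIFF stores rounded 16-bit values
  expect_equal(st2$spacing_z, st$spacing_z)
})

test_that("length study simulation honours its design and noise model", {
  # degenerate: no noise at all reproduces the true mean exactly
  quiet <- simulate_length_study(list(
    g = list(true_mean = 35.4, sd_between = 0, sd_within = 0,
             n_larvae = 3, kinocilia_per_larva = 6)), rng_seed = 1)
  expect_true(all(quiet$length_um == 35.4))
  expect_identical(nrow(quiet), 18L)

  # grand mean lands within 3 standard errors of the truth (CLT bound)
  big <- simulate_length_study(list(
    g = list(true_mean = 30, sd_between = 1, sd_within = 2,
             n_larvae = 200, kinocilia_per_larva = 8)), rng_seed = 7)
  se <- sqrt(1^2 / 200 + 2^2 / nrow(big))
  expect_lt(abs(mean(big$length_um) - 30), 3 * se)

  # groups partition exactly by label and are reproducible under seed
  two <- simulate_length_study(list(
    ctrl = list(true_mean = 35, sd_between = 1, sd_within = 1,
                n_larvae = 4, kinocilia_per_larva = 5),
    severe = list(true_mean = 26, sd_between = 1, sd_within = 1,
                  n_larvae = 3, kinocilia_per_larva = 5)), rng_seed = 3)
  expect_identical(sort(unique(two$group)), c("ctrl", "severe"))
  expect_identical(nrow(two), 4L * 5L + 3L * 5L)
  expect_true(all(table(unique(two[, c("group", "larva")])$larva) == 1))
  again <- simulate_length_study(list(
    ctrl = list(true_mean = 35, sd_between = 1, sd_within = 1,
                n_larvae = 4, kinocilia_per_larva = 5),
    severe = list(true_mean = 26, sd_between = 1, sd_within = 1,
                  n_larvae = 3, kinocilia_per_larva = 5)), rng_seed = 3)
  expect_identical(two, again)

  expect_error(simulate_length_study(list(
    g = list(true_mean = 30, sd_between = 0, sd_within = 0,
             n_larvae = 2, kinocilia_per_larva = 4)), 1),
    "five tallest")
})

test_that("length tables round-trip through TSV", {
  df <- simulate_length_study(list(
    g = list(true_mean = 33, sd_between = 0.5, sd_within = 1.5,
             n_larvae = 2, kinocilia_per_larva = 5)), rng_seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_length_table(df, path)
  back <- read_length_table(path)
  expect_equal(back$length_um, df$length_um, tolerance = 1e-12)
  expect_identical(back$group, df$group)
  expect_identical(back$measurable, df$measurable)
})
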