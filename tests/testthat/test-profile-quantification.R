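test_that("maximum projection takes the per-pixel max over slices", {
  one <- voxel_grid(array(runif(30, 0, 100), dim = c(1, 5, 6)), 0.1, 0.5)
  expect_equal(max_project(one), one$data[1, , ])

  set.seed(5)
  st <- voxel_grid(array(runif(90, 0, 1000), dim = c(3, 5, 6)), 0.1, 0.5)
  mip <- max_project(st)
  # brute-force per-pixel loop oracle
  for (y in 1:5) for (x in 1:6) {
    expect_identical(mip[y, x], max(st$data[, y, x]))
  }
  expect_gte(min(mip), min(st$data))
  expect_identical(max(mip), max(st$data))
})

test_that("profile sampling is exact on constant and ramp images", {
  sxy <- 0.064
  const <- matrix(500, nrow = 30, ncol = 200)
  line <- cbind(x = c(0.5, 11), y = c(1, 1))
  pc <- sample_profile(const, line, spacing_xy = sxy)
  expect_true(all(pc$values == 500))

  # ramp I(x) = column index - 1, sampled along a horizontal line: the
  # profile is linear with slope 1/spacing_xy gray per um (analytic
  # bilinear interpolation of a plane is exact)
  ramp <- matrix(rep(0:199, each = 30), nrow = 30)
  pr <- sample_profile(ramp, line, spacing_xy = sxy)
  slopes <- diff(pr$values) / diff(pr$positions)
  expect_equal(slopes, rep(1 / sxy, length(slopes)), tolerance = 1e-6)
  expect_equal(pr$values[1], 0.5 / sxy, tolerance = 1e-6)

  # a polyline of exactly 32 um at 0.064 um steps has 501 samples
  img <- matrix(100, nrow = 40, ncol = 520)
  p32 <- sample_profile(img, cbind(x = c(0, 32), y = c(1.2, 1.2)),
                        spacing_xy = sxy)
  expect_identical(length(p32$values), 501L)
  expect_equal(p32$length_um, 32, tolerance = 1e-9)

  expect_error(sample_profile(const, cbind(x = c(0.5, 50), y = c(1, 1)),
                              spacing_xy = sxy), "vertex")
})

test_that("measurability filtering keeps lengths >= 32 um inclusively", {
  mk <- function(len) structure(list(kinocilium_id = as.character(len),
                                     positions = c(0, len), values = c(1, 1),
                                     length_um = len),
                                class = "intensity_profile")
  out <- filter_measurable(list(mk(31.9), mk(32), mk(40)))
  expect_identical(vapply(out, `[[`, "", "kinocilium_id"), c("32", "40"))
  expect_identical(filter_measurable(list()), list())

  set.seed(8)
  lens <- runif(100, 20, 45)
  got <- filter_measurable(lapply(lens, mk), min_len_um = 32)
  want <- lapply(lens, mk)[lens >= 32]
  expect_identical(vapply(got, `[[`, "", "kinocilium_id"),
                   vapply(want, `[[`, "", "kinocilium_id"))
})

test_that("distal registration keeps exactly the last 501 samples", {
  mkprof <- function(n, id = "p") {
    structure(list(kinocilium_id = id,
                   positions = (seq_len(n) - 1) * 0.064,
                   values = seq_len(n) * 1.0,
                   length_um = (n - 1) * 0.064),
              class = "intensity_profile")
  }
  # exactly 32 um: the row is the profile verbatim
  ex <- register_distal(list(mkprof(501)))
  expect_identical(ncol(ex$matrix), 501L)
  expect_equal(ex$matrix[1, ], as.numeric(1:501))

  # 40 um profile (626 samples): row = samples 126..626 (last 501)
  long <- register_distal(list(mkprof(626)))
  expect_equal(long$matrix[1, ], as.numeric(126:626))

  # window arithmetic holds for any admissible profile length
  for (n in c(501, 555, 626, 700)) {
    expect_identical(ncol(register_distal(list(mkprof(n)))$matrix), 501L)
  }

  # ensemble column means equal a per-column loop over rows
  ens <- register_distal(list(mkprof(501, "a"), mkprof(560, "b"),
                              mkprof(626, "c")))
  avg <- average_rescale_log(ens)
  loop <- vapply(1:501, function(j) mean(ens$matrix[, j]), 0)
  expect_equal(unname(avg$mean_gray), loop)

  expect_error(register_distal(list(mkprof(400))), "shorter")
})

test_that("min-max rescaling and log2 presentation follow the definitions", {
  ens <- structure(list(matrix = matrix(c(10, 20, 30), nrow = 1),
                        positions = c(0, 0.064, 0.128),
                        window_um = 0.128, step_um = 0.064),
                   class = "registered_ensemble")
  avg <- average_rescale_log(ens)
  expect_equal(unname(avg$rescaled), c(0, 50, 100))
  expect_equal(unname(avg$log2_values), c(0, log2(51), log2(101)))
  expect_equal(unname(avg$mean_gray), c(10, 20, 30))  # single row verbatim

  flat <- structure(list(matrix = matrix(7, nrow = 2, ncol = 4),
                         positions = (0:3) * 0.064, window_um = 0.192,
                         step_um = 0.064),
                    class = "registered_ensemble")
  expect_error(average_rescale_log(flat), "flat")
})

test_that("the Loess smoother reproduces collinear data exactly", {
  x <- seq(0, 32, length.out = 501)
  y <- 3 + 0.21 * x
  fit <- fit_loess(x, y, span = 0.75)
  interior <- x > 1 & x < 31
  expect_lt(max(abs(fit[interior] - y[interior])), 1e-6)
})

test_that("the regionalization centroid matches closed-form cases", {
  expect_equal(regionalization_index(rep(4, 101))$centroid, 0.5)
  expect_identical(regionalization_index(rep(4, 101))$class, "uniform")

  point <- c(rep(0, 100), 5)
  expect_equal(regionalization_index(point)$centroid, 1.0)
  expect_identical(regionalization_index(point)$class, "distal")

  # linear ramp w(s) = s: centroid = (int s^2)/(int s) = 2/3; the Riemann
  # sum at 501 points agrees with the closed form
  s <- seq(0, 1, length.out = 501)
  ri <- regionalization_index(s)
  riemann <- sum(s * s) / sum(s)
  expect_equal(ri$centroid, riemann)
  expect_equal(ri$centroid, 2 / 3, tolerance = 2e-3)  # discrete grid is O(1/n) off
  expect_identical(ri$class, "distal")

  expect_error(regionalization_index(rep(0, 10)), "positive")
  expect_error(regionalization_index(c(1, -2, 3)), "non-negative")
})

test_that("profile statistics are invariant to global intensity scaling", {
  sc <- build_scene(length_um = 33, curvature_amp = 0.5, pattern = "distal",
                    noise_sd = 0, rng_seed = 2)
  prof <- function(st) {
    profile_from_trace(st, curve_seeds(sc$curve)$base,
                       curve_seeds(sc$curve)$tip, kinocilium_id = "kc")
  }
  p1 <- prof(sc$stack)
  scaled <- voxel_grid(sc$stack$data * 3, sc$stack$spacing_xy,
                       sc$stack$spacing_z)
  p3 <- prof(scaled)
  e1 <- register_distal(filter_measurable(list(p1)))
  e3 <- register_distal(filter_measurable(list(p3)))
  a1 <- average_rescale_log(e1); a3 <- average_rescale_log(e3)
  expect_equal(a3$rescaled, a1$rescaled, tolerance = 1e-9)
  expect_equal(a3$log2_values, a1$log2_values, tolerance = 1e-9)
  r1 <- regionalization_index(e1$matrix[1, ])
  r3 <- regionalization_index(e3$matrix[1, ])
  expect_equal(r3$centroid, r1$centroid, tolerance = 1e-9)
  expect_identical(r3$class, r1$class)
})

test_that("profile and averaged-profile TSV exports are readable", {
  mkprof <- function(id) structure(
    list(kinocilium_id = id, positions = (0:3) * 0.064,
         values = c(5, 6, 7, 8), length_um = 0.192),
    class = "intensity_profile")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profiles_tidy(list(mkprof("a"), mkprof("b")), path)
  tidy <- read.table(path, sep = "\t", header = TRUE)
  expect_identical(nrow(tidy), 8L)
  expect_identical(unique(tidy$kinocilium_id), c("a", "b"))
})
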