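# Synthetic generator: wave integration, rendering, population sampling.

test_that("zero-amplitude beats are straight segments along +x", {
  p <- beat_params(total_length = 80, beat_frequency = 4, duration = 0.5,
                   fps = 16, envelope_kind = "custom",
                   amplitude_envelope = function(s) rep(0, length(s)))
  ser <- simulate_beat(p)
  expect_equal(max(abs(ser$y)), 0)
  expect_equal(ser$x[1, ], ser$s, tolerance = 1e-10)
  expect_true(all(apply(ser$x, 1, function(r) all(diff(r) > 0))))
})

test_that("generated beats conserve arc length within 0.1%", {
  for (kind in c("flexible", "stiff-midpiece")) {
    p <- beat_params(beat_frequency = 3, envelope_kind = kind,
                     envelope_scale = 1.2, duration = 2 / 3, fps = 36)
    ser <- simulate_beat(p)
    expect_lt(max(abs(arc_lengths(ser) / p$total_length - 1)), 1e-3)
  }
})

test_that("resampled points are uniformly spaced along the curve", {
  p <- make_quick_beat(envelope_scale = 1.1)
  ser <- simulate_beat(p)
  dx <- ser$x[, -1] - ser$x[, -ncol(ser$x)]
  dy <- ser$y[, -1] - ser$y[, -ncol(ser$y)]
  chord <- sqrt(dx^2 + dy^2)
  expect_lt(max(abs(chord - ser$ds)), 1e-3)
})

test_that("transverse excursion matches a dense-quadrature oracle", {
  # A(s) ramping 0 -> 1 rad over 60 um, f = 5 Hz; excursion at s = 28.7 um
  env <- function(s) pmin(pmax(s / 60, 0), 1)
  p <- beat_params(total_length = 110, beat_frequency = 5, wavelength = 110,
                   envelope_kind = "custom", amplitude_envelope = env,
                   duration = 0.4, fps = 60)
  ser <- simulate_beat(p)
  # oracle: direct quadrature of the same psi field on a much finer grid
  s_fine <- seq(0, 110, length.out = 80001)
  h <- diff(s_fine[1:2])
  sm <- (s_fine[-1] + s_fine[-length(s_fine)]) / 2
  tt <- (seq_len(24) - 1) / 60
  y_oracle_at <- function(s0) {
    keep <- sm <= s0
    vapply(tt, function(t1) {
      psi <- env(sm[keep]) * sin(2 * pi * (5 * t1 - sm[keep] / 110))
      sum(sin(psi)) * h
    }, 0)
  }
  j <- which.min(abs(ser$s - 28.7))
  expect_equal(ser$y[, j], y_oracle_at(ser$s[j]), tolerance = 1e-3)
})

test_that("rendering recovers a straight rod and obeys the seed contract", {
  rod <- make_static_rod(60, n_frames = 2)
  sc0 <- render_frames(rod, noise = "none")
  # argmax ridge positions within 0.5 px of the true line (y = 0)
  img <- sc0$images[[1]]
  cols <- which(apply(img, 2, max) > sc0$background + 20)
  ridge_rows <- apply(img[, cols], 2, which.max)
  y_um <- sc0$origin[2] + (ridge_rows - 1) * sc0$pixel_size
  expect_lt(max(abs(y_um)), 0.5 * sc0$pixel_size + 1e-9)
  # seed contract: same seed identical, different seeds differ only in noise
  s1 <- render_frames(rod, snr = 10, seed = 1)
  s1b <- render_frames(rod, snr = 10, seed = 1)
  s2 <- render_frames(rod, snr = 10, seed = 2)
  expect_identical(s1$images, s1b$images)
  expect_false(identical(s1$images, s2$images))
  expect_identical(render_frames(rod, noise = "none")$images, sc0$images)
})

test_that("rendered intensity centroid matches the centerline centroid", {
  p <- make_quick_beat(envelope_scale = 0.6)
  ser <- simulate_beat(p)
  sc <- render_frames(ser, pixel_size = 0.33, psf_sigma = 0.6, noise = "none")
  for (f in c(1, 7)) {
    img <- sc$images[[f]] - sc$background
    tot <- sum(img)
    cx <- sum(t(img) * (sc$origin[1] + (seq_len(ncol(img)) - 1) * 0.33)) / tot
    cy <- sum(img * (sc$origin[2] + (seq_len(nrow(img)) - 1) * 0.33)) / tot
    # oracle: centroid of the true centerline (uniform arc-length weight)
    expect_lt(abs(cx - mean(ser$x[f, ])), 0.33)
    expect_lt(abs(cy - mean(ser$y[f, ])), 0.33)
  }
})

test_that("a flagellum leaving an explicit canvas names the offending frame", {
  rod <- make_static_rod(60, n_frames = 1)
  expect_error(render_frames(rod, dim = c(40, 40), origin = c(0, -5)),
               "frame 1", class = "flagkin_geometry_error")
})

test_that("single-category populations land in the printed amplitude bins", {
  spec_hf <- population_spec(c(1, 0, 0, 0), n_cells = 12, seed = 3)
  cells <- sample_population(spec_hf)
  amps <- vapply(cells, function(cl)
    flagkin:::ground_truth_mid_amplitude(cl$params), 0)
  expect_true(all(amps >= 27 * 0.97 & amps <= 39 * 1.03))
  expect_true(all(vapply(cells, function(cl)
    as.character(cl$label), "") == "highly_flexible"))

  spec_hs <- population_spec(c(0, 0, 0, 1), n_cells = 12, seed = 4)
  cells <- sample_population(spec_hs)
  amps <- vapply(cells, function(cl)
    flagkin:::ground_truth_mid_amplitude(cl$params), 0)
  expect_true(all(amps >= 0.6 * 0.97 & amps <= 6 * 1.03))
})

test_that("multinomial category counts match the binomial oracle", {
  set.seed(42)
  n <- 10000
  cats <- flagkin:::allocate_categories(rep(0.25, 4), n, "multinomial")
  counts <- table(factor(cats, levels = flagkin:::FLEX_LEVELS))
  sd_bin <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) <= 3 * sd_bin))
  # stratified allocation is exact
  strat <- flagkin:::allocate_categories(c(0.17, 0.6, 0.19, 0.04), 100,
                                         "stratified")
  expect_equal(as.numeric(table(factor(strat, levels = flagkin:::FLEX_LEVELS))),
               c(17, 60, 19, 4))
})

test_that("population sampling is reproducible for a fixed seed", {
  spec <- population_spec(c(0, 0.5, 0.25, 0.25), n_cells = 4, seed = 9)
  c1 <- sample_population(spec)
  c2 <- sample_population(spec)
  expect_identical(vapply(c1, function(cl) cl$params$envelope_scale, 0),
                   vapply(c2, function(cl) cl$params$envelope_scale, 0))
})

test_that("invalid beat parameters are rejected", {
  expect_flagkin_error(beat_params(total_length = -1),
                       "flagkin_invalid_parameter")
  expect_flagkin_error(beat_params(fps = 0), "flagkin_invalid_parameter")
  expect_flagkin_error(beat_params(duration = 0.1, beat_frequency = 5),
                       "flagkin_invalid_parameter")
  expect_flagkin_error(
    beat_params(envelope_kind = "custom",
                amplitude_envelope = function(s) -s),
    "flagkin_invalid_parameter")
  expect_flagkin_error(
    flagkin:::solve_envelope_scale(55, "flexible", 5, 0.4, 60),
    "flagkin_solver_error")
})

test_that("TIFF and CSV round trips preserve the data", {
  rod <- make_static_rod(30, n_frames = 2, ds = 1)
  sc <- render_frames(rod, snr = 10, seed = 5)
  tf <- tempfile(fileext = ".tif")
  write_scene_tiff(sc, tf)
  back <- read_stack_tiff(tf)
  expect_equal(back, sc$images)
  cf <- tempfile(fileext = ".csv")
  write_centerline_csv(rod, cf)
  rod2 <- read_centerline_csv(cf, ds = rod$ds, fps = rod$fps)
  expect_equal(rod2$x, rod$x, ignore_attr = TRUE)
  expect_equal(rod2$y, rod$y, ignore_attr = TRUE)
  unlink(c(tf, cf))
})
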