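test_that("terminal steps: noiseless single and double steps", {
  # single molecule bleaching at the end of a bright track
  expect_equal(terminal_step_heights(c(rep(224, 6), 56, 56, 0, 0)), 56)
  # two equal terminal steps
  expect_equal(terminal_step_heights(c(rep(448, 6), 112, 112, 56, 56, 0, 0)),
               c(56, 56))
  # no trailing segment below the threshold: empty, not an error
  expect_length(terminal_step_heights(rep(100, 10)), 0)
  expect_error(terminal_step_heights(5), "at least 2")
})

test_that("terminal steps on noisy simulated traces sit near the truth", {
  tr <- simulate_bleach_traces(60, brightness = 56, bleach_prob = 0.05,
                               noise_sd = 9, initial_molecules = 4, seed = 12)
  heights <- unlist(lapply(split(tr$intensity, tr$trace_id),
                           terminal_step_heights))
  heights <- heights[heights > 0]
  expect_gt(length(heights), 40)
  # oracle: the ground-truth plateau step is 56 with plateau-mean noise of
  # at most 9/sqrt(2) per plateau; the median of many steps must sit within
  # 3 standard errors of 56
  med_se <- 1.25 * (9 / sqrt(2)) / sqrt(length(heights))
  expect_lt(abs(median(heights) - 56), 3 * med_se + 2)
})

test_that("characteristic brightness: degenerate, Gaussian and bimodal", {
  cal <- characteristic_brightness(rep(56, 25))
  expect_equal(cal$brightness, 56)
  expect_equal(cal$uncertainty, 0)

  set.seed(10)
  h <- rnorm(500, 56, 9)
  cal2 <- characteristic_brightness(h)
  # oracle: mode of the same sample's Silverman-bandwidth KDE
  d <- density(h, bw = "nrd0")
  expect_equal(cal2$brightness, d$x[which.max(d$y)], tolerance = 1e-9)
  expect_true(cal2$brightness >= 53 && cal2$brightness <= 59)

  h3 <- c(rep(56, 400), rep(112, 100))
  cal3 <- characteristic_brightness(h3 + rnorm(500, 0, 1e-6))
  expect_equal(cal3$brightness, 56, tolerance = 1)

  expect_error(characteristic_brightness(rep(56, 5)), "at least 20")
})

test_that("initial intensity: constant, hand-computed OLS and precondition", {
  expect_equal(initial_intensity(rep(7.5, 10), 0.01), 7.5)
  # hand OLS: samples 10, 8, 6, 4 at frame centres 0.5..3.5 -> intercept 11
  expect_equal(initial_intensity(c(10, 8, 6, 4), 1), 11)
  expect_error(initial_intensity(c(1, 2, 3), 1), "at least 4")
})

test_that("initial intensity is exact on affine traces", {
  set.seed(33)
  for (rep in 1:50) {
    a <- runif(1, -50, 300); b <- runif(1, -40, 40); dt <- runif(1, 0.001, 1)
    y <- a + b * ((0:9 + 0.5) * dt)
    expect_equal(initial_intensity(y, dt), a, tolerance = 1e-8)
  }
})

test_that("stoichiometry division and exclusion of non-physical samples", {
  cal <- characteristic_brightness(rep(56, 20))
  expect_equal(stoichiometry(56, cal), 1.0)
  expect_equal(stoichiometry(280, cal), 5.0)
  expect_true(is.na(stoichiometry(-3, cal)))
  expect_error(stoichiometry(56, 0), "> 0")
})

test_that("calibration recovery across brightness values", {
  # the trace-level generator at brightness B must calibrate back to B
  # within the reported +/- 9-scale uncertainty band (scaled with B)
  for (B in c(28, 56, 112)) {
    tr <- simulate_bleach_traces(250, brightness = B, bleach_prob = 0.05,
                                 noise_sd = 9 * B / 56,
                                 initial_molecules = 1:5, seed = 100 + B)
    heights <- unlist(lapply(split(tr$intensity, tr$trace_id),
                             terminal_step_heights))
    cal <- characteristic_brightness(heights[heights > 0])
    expect_lt(abs(cal$brightness - B), 9 * B / 56)
  }
})

test_that("stoichiometry steps of up to 12 molecules resolve without ambiguity", {
  # paper-matched trace noise: the single-molecule brightness is 56 +/- 9
  # photoelectrons, so trace samples carry SD-9 noise
  for (n in c(1, 6, 12)) {
    tr <- simulate_bleach_traces(60, brightness = 56, bleach_prob = 0.03,
                                 noise_sd = 9,
                                 initial_molecules = n, seed = 300 + n)
    est <- sapply(split(tr, tr$trace_id), function(t1)
      initial_intensity(t1$intensity, 0.01) / 56)
    expect_lt(median(abs(est - n)), 0.5)
  }
})

test_that("count_tracks pools steps, filters short and late tracks", {
  mk_track <- function(id, frames, intensity, acq = 1L)
    data.frame(track_id = id, frame = frames, row = 10, col = 10,
               summed_intensity = intensity, background_mean = 0,
               background_sd = 1, roi_label = 1L, extended = FALSE,
               acquisition_id = acq)
  t1 <- mk_track(0L, 0:19, c(rep(280, 8), rep(224, 2), rep(168, 2),
                             rep(112, 2), rep(56, 3), rep(0, 3)))
  t2 <- mk_track(1L, 0:2, rep(100, 3))          # too short: excluded
  t3 <- mk_track(2L, 10:29, c(rep(112, 10), rep(56, 5), rep(0, 5)))  # late
  tracks <- rbind(t1, t2, t3)
  res <- count_tracks(tracks, 0.01, calibration = 56,
                      step_args = list(min_plateau = 2L))
  expect_equal(res$samples$track_id, 0L)
  expect_equal(res$samples$stoichiometry, 5, tolerance = 1e-9)
  expect_gt(length(res$step_heights), 0)
})
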