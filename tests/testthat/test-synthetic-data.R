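test_that("config invariants are enforced", {
  expect_error(slimfield_config(multiple_weights = c("1" = 0.5, "2" = 0.4)),
               "sum to 1")
  expect_error(slimfield_config(maturation_prob = 1.2), "probability")
  expect_error(slimfield_config(brightness = -1), "> 0")
  expect_error(slimfield_config(bleach_prob = NaN), "probability")
  expect_error(pam_config(Fo = 1, Fm = 0.5), "exceed")
  expect_error(pam_config(pulse_times = c(-1, 5)), ">= 0")
  expect_error(ecs_config(tau = 0), "> 0")
  expect_error(ecs_config(sample_interval = 0.01), "0.005")
})

test_that("empty stack: no sources, no noise gives all zeros", {
  cfg <- slimfield_config(n_complexes = 0, background_rate = 0,
                          read_noise_sd = 0, frame_count = 5,
                          image_shape = c(16, 16),
                          roi = list(type = "disc", radius = 6), seed = 1)
  sim <- simulate_image_stack(cfg)
  expect_true(all(sim$stack$pixels == 0))
  expect_equal(nrow(sim$truth$complexes), 0L)
})

test_that("single immobile pentamer deposits ~280 photoelectrons in the disc", {
  cfg <- slimfield_config(n_complexes = 1, multiple_weights = c("1" = 1),
                          maturation_prob = 1, brightness = 56,
                          bleach_prob = 0, diffusion_coeff = 0,
                          background_rate = 0, read_noise_sd = 0,
                          frame_count = 3, seed = 11)
  sim <- simulate_image_stack(cfg)
  pos <- sim$truth$trajectories[sim$truth$trajectories$frame == 0, ]
  m <- measure_spot(sim$stack$pixels[, , 1], c(pos$row, pos$col))
  # oracle: mass of a 2-D Gaussian inside radius 5 is 1 - exp(-r^2/(2 s^2))
  frac <- 1 - exp(-25 / (2 * 1.5^2))
  expect_gt(frac, 0.98)
  # Poisson quantization of a noiseless expectation: compare against the
  # truncated-PSF expectation within 2% plus counting noise (3 sd ~ 50)
  expect_lt(abs(m$summed_intensity - 280 * frac), 0.02 * 280 + 3 * sqrt(280))
})

test_that("bleach frames are geometric with mean 1/p", {
  cfg <- slimfield_config(n_complexes = 50, multiple_weights = c("2" = 1),
                          bleach_prob = 0.05, frame_count = 400,
                          image_shape = c(96, 96),
                          roi = list(type = "disc", radius = 40),
                          min_separation = 2, seed = 5)
  sim <- simulate_image_stack(cfg)
  lit <- sim$truth$molecules$frames_lit
  expect_gt(length(lit), 400)
  sem <- sqrt((1 - 0.05) / 0.05^2 / length(lit))
  expect_lt(abs(mean(lit) - 1 / 0.05), 3 * sem + 0.5)
})

test_that("stacks are deterministic under a fixed seed", {
  cfg <- small_slimfield_config(seed = 77)
  s1 <- simulate_image_stack(cfg)
  s2 <- simulate_image_stack(cfg)
  expect_identical(s1$stack$pixels, s2$stack$pixels)
  expect_identical(s1$truth$molecules, s2$truth$molecules)
})

test_that("noiseless photon budget matches live fluorophores x brightness", {
  cfg <- slimfield_config(n_complexes = 4, multiple_weights = c("1" = 1),
                          maturation_prob = 1, bleach_prob = 0.05,
                          background_rate = 0, read_noise_sd = 0,
                          frame_count = 30, min_separation = 12, seed = 9)
  sim <- simulate_image_stack(cfg)
  for (f in c(1L, 10L, 30L)) {
    live <- sum(sim$truth$live_counts[, f])
    tot <- sum(sim$stack$pixels[, , f])
    expected <- 56 * live
    # Poisson noise on the frame total: 4 sd; PSF truncation < 1%
    expect_lt(abs(tot - expected), 0.01 * expected + 4 * sqrt(max(expected, 1)) + 1)
  }
})

test_that("live counts never increase when blinking is off", {
  cfg <- small_slimfield_config(bleach_prob = 0.05, seed = 21)
  sim <- simulate_image_stack(cfg)
  for (i in seq_len(nrow(sim$truth$live_counts)))
    expect_true(all(diff(sim$truth$live_counts[i, ]) <= 0))
})

test_that("bleach traces: noiseless single-molecule and 5-molecule starts", {
  tr1 <- simulate_bleach_traces(1, brightness = 56, bleach_prob = 0.5,
                                noise_sd = 0, initial_molecules = 1, seed = 2)
  x <- tr1$intensity
  expect_equal(x[1], 56 * tr1$true_molecules[1])
  expect_true(all(x %in% c(0, 56)))
  expect_true(all(diff(tr1$true_molecules) <= 0))
  tr5 <- simulate_bleach_traces(1, noise_sd = 0, initial_molecules = 5,
                                bleach_prob = 0.05, seed = 3)
  expect_equal(tr5$intensity[1], 280)
  expect_error(simulate_bleach_traces(1, noise_sd = -1), "noise_sd")
  expect_error(simulate_bleach_traces(1, initial_molecules = 0), ">= 1")
})

test_that("noisy bleach-trace plateau means match brightness x m(t)", {
  tr <- simulate_bleach_traces(40, brightness = 56, bleach_prob = 0.03,
                               noise_sd = 9, initial_molecules = 3, seed = 8)
  # oracle: average the samples of each ground-truth plateau; the mean must
  # sit within 3 standard errors of brightness * m
  for (id in 0:4) {
    t1 <- tr[tr$trace_id == id, ]
    for (m in unique(t1$true_molecules)) {
      sel <- t1$true_molecules == m
      if (sum(sel) < 4) next
      se <- 9 / sqrt(sum(sel))
      expect_lt(abs(mean(t1$intensity[sel]) - 56 * m), 3 * se)
    }
  }
})

test_that("PAM pulses follow Fm / (1 + NPQ) exactly without noise", {
  # unquenched: every pulse maximum equals Fm
  cfg0 <- pam_config(npq_schedule = function(t) 0 * t, noise_sd = 0)
  tr0 <- simulate_pam_trace(cfg0)
  res0 <- analyze_pam(tr0)
  expect_equal(res0$fm_prime, rep(1.0, length(cfg0$pulse_times)),
               tolerance = 1e-12)
  # NPQ = 1 everywhere implies Fm' = Fm / 2
  cfg1 <- pam_config(npq_schedule = function(t) rep(1, length(t)),
                     noise_sd = 0)
  tr1 <- simulate_pam_trace(cfg1)
  expect_equal(analyze_pam(tr1)$fm_prime,
               rep(0.5, length(cfg1$pulse_times)), tolerance = 1e-12)
  expect_error(pam_config(pulse_times = -5), ">= 0")
})

test_that("ECS decay hits amplitude/e at one time constant", {
  cfg <- ecs_config(pmf_amplitude = 0.8, tau = 0.05, noise_sd = 0,
                    light_off_time = 0.3, sample_interval = 0.001)
  tr <- simulate_ecs_trace(cfg)
  s <- ecs_signal(tr)
  i <- which.min(abs(tr$time - (0.3 + 0.05)))
  expect_equal(s[i], 0.8 / exp(1), tolerance = 1e-2)
})

test_that("NPQ round trip: simulated PAM traces recover the schedule", {
  sched <- data.frame(time = c(0, 10, 40, 70), npq = c(0, 1.2, 0.8, 0.2))
  cfg <- pam_config(npq_schedule = sched, noise_sd = 0.002, seed = 4)
  tr <- simulate_pam_trace(cfg)
  res <- analyze_pam(tr)
  programmed <- sapply(cfg$pulse_times, function(t)
    sched$npq[max(which(sched$time <= t))])
  expect_equal(res$npq_series, programmed, tolerance = 0.05)
})
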