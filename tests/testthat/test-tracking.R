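test_that("no spots on an all-zero frame; empty mask is empty, not an error", {
  img <- matrix(0, 32, 32)
  expect_equal(nrow(detect_spots(img)), 0L)
  expect_equal(nrow(detect_spots(img + 5, mask = matrix(0L, 32, 32))), 0L)
})

test_that("a noiseless Gaussian spot is found within 0.3 px of its centre", {
  img <- gaussian_spot_image(41, 41, 20, 20, amp = 50, sigma = 1.5)
  # oracle: the analytic image's argmax and centre of mass are both (20, 20)
  expect_equal(which(img == max(img), arr.ind = TRUE)[1, ],
               c(row = 21, col = 21))
  spots <- detect_spots(img)
  expect_equal(nrow(spots), 1L)
  expect_lt(abs(spots$row - 20), 0.3)
  expect_lt(abs(spots$col - 20), 0.3)
})

test_that("two well-separated spots are both found, no more", {
  img <- gaussian_spot_image(41, 41, 14, 14) +
    gaussian_spot_image(41, 41, 26, 26)
  # oracle: brute-force 8-neighbour local-maxima scan of the analytic image
  brute <- 0L
  for (r in 2:40) for (c in 2:40) {
    nb <- img[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (img[r, c] == max(nb) && sum(nb == max(nb)) == 1L)
      brute <- brute + 1L
  }
  expect_equal(brute, 2L)
  expect_equal(nrow(detect_spots(img)), 2L)
})

test_that("measure_spot: flat field cancels; delta source is returned whole", {
  for (b in c(0, 7, 123)) {
    m <- measure_spot(matrix(b, 31, 31), c(15, 15))
    expect_equal(m$summed_intensity, 0)
    expect_equal(m$background_mean, b)
  }
  img <- matrix(0, 31, 31); img[16, 16] <- 100
  expect_equal(measure_spot(img, c(15, 15))$summed_intensity, 100)
})

test_that("measure_spot recovers a constructed spot total on background", {
  img <- integrated_spot_image(41, 41, 20, 20, total = 500, offset = 10)
  m <- measure_spot(img, c(20, 20))
  # oracle: direct construction; disc holds >= 99.6% of the flux
  expect_lt(abs(m$summed_intensity - 500), 0.01 * 500)
  expect_equal(m$background_mean, 10, tolerance = 0.02)
})

test_that("measure_spot equals a brute-force double loop on random images", {
  set.seed(42)
  params <- tracking_params()
  for (rep in seq_len(100)) {
    nr <- sample(20:30, 1); nc <- sample(20:30, 1)
    img <- matrix(rpois(nr * nc, 20), nr, nc)
    cen <- c(runif(1, 8, nr - 9), runif(1, 8, nc - 9))
    m <- measure_spot(img, cen, params)
    disc_sum <- 0; disc_n <- 0L; ann <- c()
    for (r in 0:(nr - 1)) for (c in 0:(nc - 1)) {
      d <- sqrt((r - cen[1])^2 + (c - cen[2])^2)
      if (d <= 5) { disc_sum <- disc_sum + img[r + 1, c + 1]; disc_n <- disc_n + 1L }
      else if (d > 5 && d <= 8) ann <- c(ann, img[r + 1, c + 1])
    }
    expect_equal(m$summed_intensity, disc_sum - disc_n * mean(ann),
                 tolerance = 1e-12)
    expect_equal(m$background_mean, mean(ann), tolerance = 1e-12)
    expect_equal(m$background_sd, sd(ann), tolerance = 1e-12)
  }
})

test_that("candidate filter keeps the boundary and discards strictly below", {
  spots <- data.frame(summed_intensity = c(39, 40, 41),
                      background_sd = c(100, 100, 100))
  kept <- filter_candidates(spots, tracking_params())
  expect_equal(kept$summed_intensity, c(40, 41))
  # degenerate noiseless threshold: everything non-negative survives
  s0 <- data.frame(summed_intensity = c(0, 5), background_sd = c(0, 0))
  expect_equal(nrow(filter_candidates(s0, tracking_params())), 2L)
})

test_that("candidate filter is monotone in the threshold factor", {
  set.seed(1)
  spots <- data.frame(summed_intensity = rnorm(200, 30, 30),
                      background_sd = runif(200, 0, 100))
  kept <- sapply(seq(0, 2, by = 0.1), function(k)
    nrow(filter_candidates(spots, tracking_params(candidate_factor = k))))
  expect_true(all(diff(kept) <= 0))
})

test_that("linking: immobile spots give one track each, never merged", {
  mk <- function(frame, row, col)
    data.frame(frame = frame, row = row, col = col)
  one <- do.call(rbind, lapply(0:9, function(f) mk(f, 10, 10)))
  linked <- link_tracks(one, tracking_params(min_track_length = 4))
  expect_equal(length(unique(linked$track_id)), 1L)
  expect_equal(nrow(linked), 10L)
  two <- do.call(rbind, lapply(0:9, function(f)
    rbind(mk(f, 10, 10), mk(f, 30, 30))))
  linked2 <- link_tracks(two, tracking_params(max_link_displacement = 5,
                                              min_track_length = 4))
  expect_equal(length(unique(linked2$track_id)), 2L)
  expect_true(all(table(linked2$track_id) == 10L))
})

test_that("linking follows a moving spot within the gate", {
  # 1 px/frame stepper; exhaustive assignment on a single particle is the
  # chain of nearest neighbours, i.e. one track
  spots <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, row = 10 + f, col = 10)))
  linked <- link_tracks(spots, tracking_params(max_link_displacement = 5,
                                               min_track_length = 4))
  expect_equal(length(unique(linked$track_id)), 1L)
  # beyond the gate the chain breaks into short fragments that are dropped
  far <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, row = 10 + 6 * f, col = 10)))
  linked2 <- link_tracks(far, tracking_params(max_link_displacement = 5,
                                              min_track_length = 4))
  expect_equal(nrow(linked2), 0L)
})

test_that("noiseless well-separated simulation: track count and intensities", {
  cfg <- slimfield_config(n_complexes = 3, multiple_weights = c("1" = 1),
                          maturation_prob = 1, bleach_prob = 0,
                          diffusion_coeff = 0.02, background_rate = 0,
                          read_noise_sd = 0, frame_count = 25,
                          min_separation = 16, seed = 31)
  sim <- simulate_image_stack(cfg)
  tracks <- track_stack(sim$stack, sim$mask,
                        tracking_params(threshold_sd = 2))
  expect_equal(length(unique(tracks$track_id)), 3L)
  live <- tracks[!tracks$extended, ]
  expect_lt(max(abs(live$summed_intensity - 280)), 0.02 * 280 + 3 * sqrt(280))
})
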