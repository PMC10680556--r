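# Shared fixtures: tiny configs and analytic images used across test files.

# analytic sampled Gaussian spot (peak amplitude `amp`) on a constant offset
gaussian_spot_image <- function(nr, nc, row, col, amp = 50, sigma = 1.5,
                                offset = 0) {
  rows <- matrix(0:(nr - 1), nr, nc)
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  offset + amp * exp(-((rows - row)^2 + (cols - col)^2) / (2 * sigma^2))
}

# integrated-PSF spot with known total flux (the camera model's expectation)
integrated_spot_image <- function(nr, nc, row, col, total = 500,
                                  sigma = 1.5, offset = 0) {
  fy <- pnorm((0:(nr - 1) + 0.5 - row) / sigma) -
    pnorm((0:(nr - 1) - 0.5 - row) / sigma)
  fx <- pnorm((0:(nc - 1) + 0.5 - col) / sigma) -
    pnorm((0:(nc - 1) - 0.5 - col) / sigma)
  offset + total * outer(fy, fx)
}

small_slimfield_config <- function(...) {
  slimfield_config(n_complexes = 3, frame_count = 40,
                   image_shape = c(40, 40),
                   roi = list(type = "disc", radius = 13, center = NULL),
                   min_separation = 9, ...)
}

# stated-world pipeline study used by the acceptance tests; scale is the
# number of acquisitions (the full criterion run uses 25)
run_pentamer_study <- function(seed, n_acq, frame_count = 300,
                               bootstrap = 0) {
  all_tracks <- NULL
  for (a in seq_len(n_acq)) {
    cfg <- slimfield_config(frame_count = frame_count,
                            seed = derive_seed(seed, a))
    sim <- simulate_image_stack(cfg)
    tr <- track_stack(sim$stack, sim$mask)
    if (nrow(tr)) {
      tr$acquisition_id <- a
      all_tracks <- rbind(all_tracks, tr)
    }
  }
  counted <- count_tracks(all_tracks, frame_interval = 0.01)
  per <- estimate_periodicity(counted$samples, bootstrap = bootstrap,
                              seed = derive_seed(seed, 999L))
  n_tracks <- length(unique(paste(all_tracks$acquisition_id,
                                  all_tracks$track_id)))
  list(tracks = all_tracks, counted = counted, periodicity = per,
       n_tracks = n_tracks)
}
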