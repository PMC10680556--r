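# Synthetic-data generators.  These produce the stated world every
# downstream stage is tested against: diffusing ROI-confined complexes whose
# tagged-subunit counts are multiples of a base unit, a calibrated
# photoelectron camera model, and PAM / ECS photophysiology traces with
# known programmed parameters.

roi_mask_from_spec <- function(roi, image_shape) {
  nr <- image_shape[1L]; nc <- image_shape[2L]
  if (is.null(roi) || identical(roi$type, "all"))
    return(matrix(1L, nr, nc))
  if (!identical(roi$type, "disc"))
    stop_config("unsupported roi type: ", roi$type)
  ctr <- roi$center
  if (is.null(ctr)) ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  rows <- matrix(0:(nr - 1), nr, nc)
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  d2 <- (rows - ctr[1L])^2 + (cols - ctr[2L])^2
  m <- matrix(0L, nr, nc)
  m[d2 <= roi$radius^2] <- 1L
  m
}

# Expected photoelectrons per pixel for point emitters with an integrated
# 2-D Gaussian PSF.  positions: matrix [n, 2] of 0-based (row, col);
# amplitudes: expected total photoelectrons per emitter.
render_psf <- function(positions, amplitudes, sigma, nr, nc) {
  if (!nrow(positions)) return(matrix(0, nr, nc))
  render_psf_cpp(positions, as.numeric(amplitudes), sigma,
                 as.integer(nr), as.integer(nc))
}

place_complexes <- function(n, roi, image_shape, min_separation) {
  nr <- image_shape[1L]; nc <- image_shape[2L]
  ctr <- roi$center
  if (is.null(ctr)) ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  rad <- max(roi$radius - 2, 1)
  pos <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    for (try in seq_len(200L)) {
      u <- stats::runif(1); th <- stats::runif(1, 0, 2 * pi)
      p <- ctr + sqrt(u) * rad * c(cos(th), sin(th))
      if (i == 1L || all(sqrt(rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                                       matrix(p, i - 1L, 2L, byrow = TRUE))^2)) >=
                         min_separation)) break
    }
    pos[i, ] <- p
  }
  pos
}

reflect_in_disc <- function(pos, ctr, rad) {
  repeat {
    d <- sqrt(sum((pos - ctr)^2))
    if (d <= rad || d == 0) return(pos)
    new_d <- max(2 * rad - d, 0)  # radial fold at the boundary
    pos <- ctr + (pos - ctr) * (new_d / d)
    if (new_d == 0) return(pos)
  }
}

#' Simulate a Slimfield image stack with ground truth
#'
#' Each fluorescent, unbleached, non-dark molecule deposits an integrated
#' Gaussian PSF of expected total `brightness` photoelectrons per frame at
#' its complex's position.  Pixel values are Poisson-distributed about
#' (signal + background) plus Gaussian read noise, clipped at zero and
#' quantized to unsigned 16-bit integers (gain = 1: the camera is assumed
#' photoelectron-calibrated).  Molecules photobleach irreversibly and blink
#' reversibly per frame; complexes perform 2-D Brownian motion reflected at
#' the ROI boundary.  Identical configs and seeds give identical output.
#'
#' @param config a [slimfield_config()].
#' @return list with `stack` ([image_stack()]), `mask` (ROI label matrix)
#'   and `truth`, a list of `complexes` (id, multiple, true_subunits,
#'   true_fluorophores), `molecules` (complex_id, molecule_id, frames_lit =
#'   number of frames emitted before the irreversible bleach), and
#'   `trajectories` (complex_id, frame, row, col, n_live).
#' @export
simulate_image_stack <- function(config) {
  stopifnot(inherits(config, "slimfield_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nr <- config$image_shape[1L]; nc <- config$image_shape[2L]
  nf <- config$frame_count
  mask <- roi_mask_from_spec(config$roi, config$image_shape)
  n <- config$n_complexes

  multiples <- as.integer(names(config$multiple_weights))
  k <- if (n) multiples[sample.int(length(multiples), n, replace = TRUE,
                                   prob = config$multiple_weights)]
       else integer(0)
  subunits <- k * config$unit_size
  fluor <- if (n) stats::rbinom(n, subunits, config$maturation_prob) else integer(0)
  complexes <- data.frame(complex_id = seq_len(n) - 1L, multiple = k,
                          true_subunits = subunits, true_fluorophores = fluor)

  mol_complex <- rep(complexes$complex_id, fluor)
  n_mol <- length(mol_complex)
  # per-frame photophysics: lit[m] while not bleached and not dark
  bleached <- rep(FALSE, n_mol)
  dark <- rep(FALSE, n_mol)
  frames_lit <- integer(n_mol)

  ctr <- config$roi$center
  if (is.null(ctr)) ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  rad <- if (identical(config$roi$type, "disc")) config$roi$radius
         else max(nr, nc)
  pos <- place_complexes(n, config$roi, config$image_shape,
                         config$min_separation)
  step_sd <- sqrt(2 * config$diffusion_coeff)

  pixels <- array(0L, dim = c(nr, nc, nf))
  traj_row <- traj_col <- matrix(NA_real_, max(n, 1L), nf)
  live_mat <- matrix(0L, nrow = max(n, 1L), ncol = nf)
  for (f in seq_len(nf)) {
    emitting <- !bleached & !dark
    live <- if (n) tabulate(mol_complex[emitting] + 1L, nbins = n) else integer(0)
    if (n) live_mat[, f] <- live
    signal <- render_psf(pos, config$brightness * live, config$psf_sigma,
                         nr, nc)
    expected <- signal + config$background_rate
    img <- stats::rpois(nr * nc, expected)
    if (config$read_noise_sd > 0)
      img <- img + stats::rnorm(nr * nc, 0, config$read_noise_sd)
    img <- pmin(pmax(round(img), 0), 65535)
    pixels[, , f] <- as.integer(img)
    if (n) {
      traj_row[, f] <- pos[, 1L]
      traj_col[, f] <- pos[, 2L]
    }
    # photophysics transitions applied after the frame is emitted
    frames_lit <- frames_lit + as.integer(emitting)
    if (n_mol) {
      newly_bleached <- emitting &
        stats::runif(n_mol) < config$bleach_prob
      bleached <- bleached | newly_bleached
      if (config$blink_off_prob > 0 || config$blink_on_prob > 0) {
        go_dark <- !bleached & !dark & stats::runif(n_mol) < config$blink_off_prob
        wake <- dark & stats::runif(n_mol) < config$blink_on_prob
        dark <- (dark | go_dark) & !wake
      }
    }
    # Brownian step, reflected at the ROI boundary
    if (n && step_sd > 0) {
      pos <- pos + matrix(stats::rnorm(2L * n, 0, step_sd), n, 2L)
      for (i in seq_len(n)) pos[i, ] <- reflect_in_disc(pos[i, ], ctr, rad)
    }
  }
  molecules <- data.frame(complex_id = mol_complex,
                          molecule_id = seq_len(n_mol) - 1L,
                          frames_lit = frames_lit)
  trajectories <- if (n)
    data.frame(complex_id = rep(complexes$complex_id, nf),
               frame = rep(seq_len(nf) - 1L, each = n),
               row = as.vector(traj_row), col = as.vector(traj_col),
               n_live = as.vector(live_mat))
  else
    data.frame(complex_id = integer(0), frame = integer(0),
               row = numeric(0), col = numeric(0), n_live = integer(0))
  list(stack = image_stack(pixels, pixel_size = config$pixel_size,
                           frame_interval = config$frame_interval,
                           exposure = config$exposure),
       mask = mask,
       truth = list(complexes = complexes, molecules = molecules,
                    trajectories = trajectories, live_counts = live_mat))
}

#' Simulate photobleaching intensity traces
#'
#' Direct trace-level generator bypassing the imaging model, for unit tests
#' and calibration of the counting stage.  Each trace is
#' `I(t) = brightness * m(t) + N(0, noise_sd)` where `m(t)` is a
#' non-increasing integer path from the trace's initial molecule count to 0;
#' each molecule independently survives a per-frame bleaching coin with
#' probability `1 - bleach_prob` (so the number of frames a molecule emits
#' is geometric with mean `1 / bleach_prob`).
#'
#' @param n_traces number of traces.
#' @param brightness photoelectrons per frame per molecule.
#' @param bleach_prob per-molecule per-frame bleaching probability.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param initial_molecules integer >= 1: either a scalar, a pool sampled
#'   uniformly per trace (length > 1), or one value per trace
#'   (length `n_traces`).
#' @param seed integer RNG seed or `NULL`.
#' @param tail_frames zero-signal frames appended after the last bleach.
#' @return `data.frame(trace_id, frame, intensity, true_molecules)`; frames
#'   are 0-based.
#' @export
simulate_bleach_traces <- function(n_traces, brightness = 56,
                                   bleach_prob = 0.05, noise_sd = 9,
                                   initial_molecules = 1L, seed = NULL,
                                   tail_frames = 10L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(initial_molecules < 1)) stop("initial_molecules must be >= 1")
  check_prob(bleach_prob, "bleach_prob")
  if (!is.null(seed)) set.seed(seed)
  m0 <- if (length(initial_molecules) == n_traces) as.integer(initial_molecules)
        else if (length(initial_molecules) == 1L)
          rep(as.integer(initial_molecules), n_traces)
        else sample(as.integer(initial_molecules), n_traces, replace = TRUE)
  out <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    lit <- stats::rgeom(m0[i], bleach_prob) + 1L  # frames emitted per molecule
    nf <- max(lit) + tail_frames
    nf <- max(nf, 4L)
    m <- vapply(0:(nf - 1L), function(f) sum(lit > f), integer(1L))
    intensity <- brightness * m
    if (noise_sd > 0) intensity <- intensity + stats::rnorm(nf, 0, noise_sd)
    out[[i]] <- data.frame(trace_id = i - 1L, frame = 0:(nf - 1L),
                           intensity = intensity, true_molecules = m)
  }
  do.call(rbind, out)
}

npq_at <- function(schedule, t) {
  if (is.function(schedule)) return(pmax(0, schedule(t)))
  f <- stats::approx(schedule$time, schedule$npq, xout = t,
                     method = "constant", rule = 2)$y
  pmax(0, f)
}

#' Simulate a PAM chlorophyll-fluorescence trace
#'
#' Saturating-pulse maxima at `pulse_times` equal `Fm / (1 + NPQ(t))` (the
#' definition NPQ = (Fm - Fm') / Fm' inverted); in darkness NPQ(t) is taken
#' from the schedule as programmed.  Between pulses the stationary
#' fluorescence is `Fo` in darkness and `Fo + 0.3 * (Fm'(t) - Fo)` in
#' actinic light.
#'
#' @param config a [pam_config()].
#' @return object of class `pam_trace`: list with `time`, `fluorescence`,
#'   `pulse_times`, `pulse_width`, `light_on`, `light_off`, `Fm`, `Fo`,
#'   and the programmed `npq_schedule`.
#' @export
simulate_pam_trace <- function(config) {
  stopifnot(inherits(config, "pam_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  t <- seq(0, config$duration, by = config$sample_interval)
  npq <- npq_at(config$npq_schedule, t)
  fmp <- config$Fm / (1 + npq)
  in_light <- t >= config$light_on & t < config$light_off
  f <- ifelse(in_light, config$Fo + 0.3 * (fmp - config$Fo), config$Fo)
  in_pulse <- rep(FALSE, length(t))
  for (tp in config$pulse_times)
    in_pulse <- in_pulse | (t >= tp & t < tp + config$pulse_width)
  f[in_pulse] <- fmp[in_pulse]
  if (config$noise_sd > 0) f <- f + stats::rnorm(length(t), 0, config$noise_sd)
  structure(list(time = t, fluorescence = f,
                 pulse_times = config$pulse_times,
                 pulse_width = config$pulse_width,
                 light_on = config$light_on, light_off = config$light_off,
                 Fm = config$Fm, Fo = config$Fo,
                 npq_schedule = config$npq_schedule),
            class = "pam_trace")
}

#' Simulate a dual-wavelength electrochromic-shift trace
#'
#' The normalized signal equals `pmf_amplitude` while the light is on, then
#' `offset + pmf_amplitude * exp(-(t - light_off_time) / tau)`.  The raw
#' 520 nm channel is the normalized signal scaled by `ecs_st`; the 545 nm
#' reference channel carries only noise.
#'
#' @param config an [ecs_config()].
#' @return object of class `ecs_trace`: list with `time`, `a520`, `a545`,
#'   `ecs_st`, `light_off_time`.
#' @export
simulate_ecs_trace <- function(config) {
  stopifnot(inherits(config, "ecs_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  t <- seq(0, config$duration, by = config$sample_interval)
  dark <- t >= config$light_off_time
  norm_sig <- ifelse(dark,
                     config$offset + config$pmf_amplitude *
                       exp(-(t - config$light_off_time) / config$tau),
                     config$pmf_amplitude)
  a520 <- norm_sig * config$ecs_st
  a545 <- rep(0, length(t))
  if (config$noise_sd > 0) {
    a520 <- a520 + stats::rnorm(length(t), 0, config$noise_sd)
    a545 <- a545 + stats::rnorm(length(t), 0, config$noise_sd)
  }
  structure(list(time = t, a520 = a520, a545 = a545,
                 ecs_st = config$ecs_st,
                 light_off_time = config$light_off_time),
            class = "ecs_trace")
}
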