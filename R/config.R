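#' @keywords internal
stop_config <- function(...) {
  stop(structure(class = c("slimcount_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_config(name, " must be a single probability in [0, 1]")
  x
}

check_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop_config(name, if (strict) " must be a single finite value > 0"
                else " must be a single finite value >= 0")
  x
}

#' Simulation configuration for Slimfield image stacks
#'
#' Describes the stated world of a Slimfield acquisition: diffusing,
#' ROI-confined complexes whose tagged-subunit counts are multiples of a base
#' assembly unit, imaged with an integrated Gaussian point-spread function on
#' a photoelectron-calibrated camera with Poisson shot noise and Gaussian
#' read noise.
#'
#' Defaults mirror the acquisition conditions the analysis assumes:
#' 53 nm/pixel, 10 ms exposure, single-molecule brightness of 56
#' photoelectrons per frame per molecule.  The nominal frame rate quoted for
#' the instrument (180 frames/s) is inconsistent with a 10 ms exposure; the
#' default frame interval equals the exposure (10 ms, back-to-back frames)
#' and both are configurable.
#'
#' @param unit_size integer, molecules per base assembly (pentamer = 5).
#' @param multiple_weights named probability vector over the assembly
#'   multiple k; a complex carries `k * unit_size` tag sites.  Names are the
#'   integer multiples.
#' @param maturation_prob probability that a tag site carries a fluorescent
#'   (matured) fluorophore.  Default 1: with partial maturation the expected
#'   fluorophore count per complex is `maturation_prob * k * unit_size`, so
#'   the recoverable periodicity is the thinned unit, not `unit_size`.
#' @param brightness photoelectrons per frame per fluorescent molecule.
#' @param bleach_prob per-molecule, per-frame irreversible photobleaching
#'   probability.
#' @param blink_off_prob,blink_on_prob per-frame reversible dark-state
#'   switching probabilities (default 0: no blinking in the stated world).
#' @param n_complexes number of complexes in the ROI.
#' @param diffusion_coeff Brownian diffusion coefficient, px^2/frame.
#' @param psf_sigma Gaussian PSF standard deviation in pixels (default 1.5,
#'   about 0.21 * lambda / NA at 585 nm, NA 1.49, 53 nm/px).
#' @param frame_count number of frames.
#' @param frame_interval,exposure seconds.  Frame `i` spans
#'   `[i * frame_interval, i * frame_interval + exposure)` and its intensity
#'   is attributed to the frame-centre time `(i + 0.5) * frame_interval`.
#' @param pixel_size nm per pixel.
#' @param image_shape integer `(rows, cols)`.
#' @param roi list describing the ROI mask: `list(type = "disc",
#'   radius = r, center = c(row, col))` (centre `NULL` = image centre).
#' @param background_rate expected background photoelectrons/pixel/frame.
#' @param read_noise_sd Gaussian read noise SD in photoelectrons.
#' @param min_separation minimum initial distance between complexes, px.
#' @param seed integer RNG seed, or `NULL`.
#' @return object of class `slimfield_config`.
#' @export
slimfield_config <- function(unit_size = 5,
                             multiple_weights = c("1" = 0.5, "2" = 0.3, "3" = 0.2),
                             maturation_prob = 1,
                             brightness = 56,
                             bleach_prob = 0.03,
                             blink_off_prob = 0,
                             blink_on_prob = 0,
                             n_complexes = 9,
                             diffusion_coeff = 0.05,
                             psf_sigma = 1.5,
                             frame_count = 300,
                             frame_interval = 0.010,
                             exposure = 0.010,
                             pixel_size = 53,
                             image_shape = c(64, 64),
                             roi = list(type = "disc", radius = 22, center = NULL),
                             background_rate = 5,
                             read_noise_sd = 2,
                             min_separation = 10,
                             seed = NULL) {
  if (!is.numeric(unit_size) || length(unit_size) != 1L || unit_size < 1 ||
      unit_size != round(unit_size))
    stop_config("unit_size must be an integer >= 1")
  if (!is.numeric(multiple_weights) || is.null(names(multiple_weights)) ||
      any(multiple_weights < 0) || any(!is.finite(multiple_weights)))
    stop_config("multiple_weights must be a named non-negative numeric vector")
  if (abs(sum(multiple_weights) - 1) > 1e-8)
    stop_config("multiple_weights must sum to 1")
  k <- suppressWarnings(as.integer(names(multiple_weights)))
  if (any(is.na(k)) || any(k < 1))
    stop_config("multiple_weights names must be positive integer multiples")
  check_prob(maturation_prob, "maturation_prob")
  check_prob(bleach_prob, "bleach_prob")
  check_prob(blink_off_prob, "blink_off_prob")
  check_prob(blink_on_prob, "blink_on_prob")
  check_pos(brightness, "brightness")
  check_pos(psf_sigma, "psf_sigma")
  check_pos(frame_interval, "frame_interval")
  check_pos(exposure, "exposure")
  check_pos(pixel_size, "pixel_size")
  check_pos(diffusion_coeff, "diffusion_coeff", strict = FALSE)
  check_pos(background_rate, "background_rate", strict = FALSE)
  check_pos(read_noise_sd, "read_noise_sd", strict = FALSE)
  if (!is.numeric(n_complexes) || n_complexes < 0 ||
      n_complexes != round(n_complexes))
    stop_config("n_complexes must be a non-negative integer")
  if (!is.numeric(frame_count) || frame_count < 1)
    stop_config("frame_count must be >= 1")
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop_config("image_shape must be (rows, cols), each >= 8")
  structure(list(
    unit_size = as.integer(unit_size), multiple_weights = multiple_weights,
    maturation_prob = maturation_prob, brightness = brightness,
    bleach_prob = bleach_prob, blink_off_prob = blink_off_prob,
    blink_on_prob = blink_on_prob, n_complexes = as.integer(n_complexes),
    diffusion_coeff = diffusion_coeff, psf_sigma = psf_sigma,
    frame_count = as.integer(frame_count), frame_interval = frame_interval,
    exposure = exposure, pixel_size = pixel_size,
    image_shape = as.integer(image_shape), roi = roi,
    background_rate = background_rate, read_noise_sd = read_noise_sd,
    min_separation = min_separation, seed = seed),
    class = "slimfield_config")
}

#' Simulation configuration for PAM fluorescence traces
#'
#' @param Fo,Fm dark-adapted minimum and maximum fluorescence yield
#'   (relative units), `Fm > Fo > 0`.
#' @param npq_schedule target NPQ(t): a `data.frame(time, npq)` interpreted
#'   as a right-continuous step function, or a function of time.  NPQ must
#'   be >= 0.
#' @param pulse_times saturating-pulse onset times, s (all >= 0).
#' @param light_on,light_off actinic illumination window, s.
#' @param pulse_width saturating pulse duration, s.
#' @param sample_interval s.
#' @param duration record length, s (default covers the last pulse).
#' @param noise_sd Gaussian noise SD on the fluorescence signal.
#' @param seed integer RNG seed or `NULL`.
#' @return object of class `pam_config`.
#' @export
pam_config <- function(Fo = 0.2, Fm = 1.0,
                       npq_schedule = data.frame(time = c(0, 10, 70),
                                                 npq = c(0, 1.0, 0.3)),
                       pulse_times = c(5, seq(15, 65, by = 10),
                                       seq(75, 125, by = 10)),
                       light_on = 10, light_off = 70,
                       pulse_width = 0.3, sample_interval = 0.1,
                       duration = NULL, noise_sd = 0, seed = NULL) {
  check_pos(Fm, "Fm"); check_pos(Fo, "Fo")
  if (Fm <= Fo) stop_config("Fm must exceed Fo")
  if (any(pulse_times < 0)) stop_config("pulse times must be >= 0")
  pulse_times <- sort(pulse_times)
  if (is.data.frame(npq_schedule)) {
    if (!all(c("time", "npq") %in% names(npq_schedule)) ||
        any(npq_schedule$npq < 0))
      stop_config("npq_schedule must have columns time, npq with npq >= 0")
  } else if (!is.function(npq_schedule)) {
    stop_config("npq_schedule must be a data.frame or a function")
  }
  check_pos(pulse_width, "pulse_width"); check_pos(sample_interval, "sample_interval")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  if (is.null(duration)) duration <- max(pulse_times) + 5
  structure(list(Fo = Fo, Fm = Fm, npq_schedule = npq_schedule,
                 pulse_times = pulse_times, light_on = light_on,
                 light_off = light_off, pulse_width = pulse_width,
                 sample_interval = sample_interval, duration = duration,
                 noise_sd = noise_sd, seed = seed),
            class = "pam_config")
}

#' Simulation configuration for electrochromic-shift (ECS) traces
#'
#' The simulated normalized ECS signal sits at `pmf_amplitude` while the
#' actinic light is on and decays as
#' `offset + pmf_amplitude * exp(-(t - light_off_time) / tau)` afterwards.
#' The raw 520 nm channel is the normalized signal scaled by `ecs_st`; the
#' 545 nm reference channel carries noise only.
#'
#' @param pmf_amplitude steady-state light signal in ECS_ST-normalized units.
#' @param tau decay time constant, s.
#' @param ecs_st normalization amplitude in raw signal units.
#' @param light_off_time s from record start.
#' @param duration total record length, s.
#' @param sample_interval s; must be <= 0.005 so that at least 20 samples
#'   fall inside the 100 ms decay-fit window.
#' @param offset post-decay plateau in normalized units.
#' @param noise_sd per-channel Gaussian noise SD in raw signal units.
#' @param seed integer RNG seed or `NULL`.
#' @return object of class `ecs_config`.
#' @export
ecs_config <- function(pmf_amplitude = 0.8, tau = 0.05, ecs_st = 1,
                       light_off_time = 0.3, duration = 1.0,
                       sample_interval = 0.002, offset = 0,
                       noise_sd = 0, seed = NULL) {
  check_pos(tau, "tau"); check_pos(ecs_st, "ecs_st")
  check_pos(sample_interval, "sample_interval")
  if (sample_interval > 0.005)
    stop_config("sample_interval must be <= 0.005 s (>= 20 samples in the 100 ms fit window)")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  if (light_off_time <= 0 || light_off_time >= duration)
    stop_config("light_off_time must fall inside the record")
  structure(list(pmf_amplitude = pmf_amplitude, tau = tau, ecs_st = ecs_st,
                 light_off_time = light_off_time, duration = duration,
                 sample_interval = sample_interval, offset = offset,
                 noise_sd = noise_sd, seed = seed),
            class = "ecs_config")
}

config_constructors <- list(slimfield = slimfield_config,
                            pam = pam_config, ecs = ecs_config)

#' Load and validate a configuration from JSON
#'
#' Unknown keys are an error naming the offending key; known keys are passed
#' through the corresponding constructor, which enforces all invariants.
#'
#' @param path JSON file.
#' @param type one of `"slimfield"`, `"pam"`, `"ecs"`.
#' @return a validated config object.
#' @export
load_config <- function(path, type = c("slimfield", "pam", "ecs")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ctor <- config_constructors[[type]]
  known <- names(formals(ctor))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_config("unknown config key(s) for ", type, " config: ",
                paste(bad, collapse = ", "))
  if (type == "slimfield" && !is.null(raw$multiple_weights))
    raw$multiple_weights <- unlist(raw$multiple_weights)
  if (type == "slimfield" && !is.null(raw$roi)) raw$roi <- as.list(raw$roi)
  if (type == "pam" && !is.null(raw$npq_schedule))
    raw$npq_schedule <- as.data.frame(raw$npq_schedule)
  do.call(ctor, raw)
}

#' Save a configuration as JSON
#' @param config a config object.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$multiple_weights))
    x$multiple_weights <- as.list(x$multiple_weights)  # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
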