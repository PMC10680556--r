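# Molecular counting: calibrate the characteristic single-molecule
# brightness from terminal photobleaching steps, and convert each track's
# backward-extrapolated initial intensity into a stoichiometry.

#' Edge-preserving Chung-Kennedy filter
#'
#' Each output sample is a variance-weighted blend of the means of a
#' trailing window ending at the sample and a leading window starting at
#' it; at a step edge the flatter window dominates, so plateaus are averaged
#' without smearing the transition.
#'
#' @param x numeric trace.
#' @param window window length W (samples).
#' @param p weighting exponent (weights are `1 / (var + eps)^p`).
#' @return filtered trace, same length.
#' @export
ck_filter <- function(x, window = 8L, p = 1) {
  n <- length(x)
  if (n < 2L) return(x)
  eps <- max(1e-12, 1e-9 * stats::var(x))
  ck_filter_cpp(as.numeric(x), as.integer(window), p, eps)
}

find_plateaus <- function(filtered, threshold) {
  jumps <- which(abs(diff(filtered)) > threshold)
  # successive jump indices belong to one transition; keep run starts
  if (length(jumps) > 1L)
    jumps <- jumps[c(TRUE, diff(jumps) > 1L)]
  starts <- c(1L, jumps + 1L)
  ends <- c(jumps, length(filtered))
  data.frame(start = starts, end = ends)
}

# Merge adjacent plateaus whose mean difference is statistically
# insignificant against the per-frame noise (two-sample z at merge_z),
# removing spurious change points that would otherwise contribute
# near-zero step heights.
merge_plateaus <- function(plate, x, sigma, merge_z) {
  if (sigma <= 0 || nrow(plate) < 2L) return(plate)
  repeat {
    if (nrow(plate) < 2L) break
    len <- plate$end - plate$start + 1L
    mu <- vapply(seq_len(nrow(plate)), function(i)
      mean(x[plate$start[i]:plate$end[i]]), numeric(1))
    z <- abs(diff(mu)) / (sigma * sqrt(1 / len[-length(len)] + 1 / len[-1L]))
    i <- which.min(z)
    if (z[i] >= merge_z) break
    plate$end[i] <- plate$end[i + 1L]
    plate <- plate[-(i + 1L), , drop = FALSE]
  }
  rownames(plate) <- NULL
  plate
}

#' Extract terminal photobleaching step heights from an intensity trace
#'
#' After sufficient photobleaching only step-like blinking remains at the
#' end of a track.  The trailing low-intensity segment (below
#' `tail_fraction` of the backward-extrapolated initial intensity) is
#' filtered with an edge-preserving Chung-Kennedy filter; change points in
#' the filtered trace delimit plateaus, and the returned heights are the
#' absolute differences of successive plateau means (raw-trace means) for
#' plateaus of at least `min_plateau` frames.
#'
#' The step that carries the trace *into* the trailing segment is itself a
#' terminal step, so the plateau immediately preceding the first
#' sub-threshold plateau is retained as the reference level.
#'
#' @param intensity_trace numeric vector (>= 2 samples).
#' @param tail_fraction fraction of the extrapolated initial intensity below
#'   which a plateau belongs to the trailing segment.
#' @param ck_window,ck_p Chung-Kennedy filter parameters.
#' @param min_plateau minimum plateau length in frames.
#' @param threshold_sds change-point threshold in units of the robust SD of
#'   the filtered trace's first differences.
#' @param merge_z adjacent plateaus whose mean difference is below this
#'   two-sample z score (against the per-frame noise) are re-merged,
#'   suppressing spurious change points.
#' @return numeric vector of step heights (possibly empty).
#' @export
terminal_step_heights <- function(intensity_trace, tail_fraction = 0.25,
                                  ck_window = 8L, ck_p = 1,
                                  min_plateau = 2L, threshold_sds = 4,
                                  merge_z = 3) {
  x <- as.numeric(intensity_trace)
  if (length(x) < 2L) stop("trace must have at least 2 samples")
  i0 <- if (length(x) >= 4L) initial_intensity(x, 1) else max(x)
  if (!is.finite(i0) || i0 <= 0) i0 <- max(x)
  if (stats::mad(diff(x)) == 0 && length(unique(x)) <= length(x) / 2) {
    # effectively noiseless: plateaus are literal runs of equal values
    f <- x
    thr <- 1e-8 * max(abs(x), 1)
  } else {
    f <- ck_filter(x, window = ck_window, p = ck_p)
    thr <- max(threshold_sds * stats::mad(diff(f)),
               1e-8 * max(abs(f), 1))
  }
  plate <- find_plateaus(f, thr)
  plate <- merge_plateaus(plate, x, stats::mad(diff(x)) / sqrt(2), merge_z)
  plate$len <- plate$end - plate$start + 1L
  plate$mean <- vapply(seq_len(nrow(plate)), function(i)
    mean(x[plate$start[i]:plate$end[i]]), numeric(1))
  in_tail <- plate$mean < tail_fraction * i0
  if (!any(in_tail)) return(numeric(0))
  first <- which(in_tail)[1L]
  plate <- plate[max(1L, first - 1L):nrow(plate), , drop = FALSE]
  plate <- plate[plate$len >= min_plateau, , drop = FALSE]
  if (nrow(plate) < 2L) return(numeric(0))
  abs(diff(plate$mean))
}

#' Calibrate the characteristic single-molecule brightness
#'
#' The brightness is the mode of a Gaussian-kernel density (Silverman
#' bandwidth) over the pooled terminal step heights; the uncertainty is the
#' half-width of the density's full width at half maximum.
#'
#' @param step_heights numeric vector of step observations.
#' @param min_steps calibration floor; fewer observations is an error
#'   instructing more data.
#' @return object of class `brightness_calibration`: list with `brightness`,
#'   `uncertainty`, `n_steps`, `step_heights`.
#' @export
characteristic_brightness <- function(step_heights, min_steps = 20L) {
  h <- step_heights[is.finite(step_heights) & step_heights > 0]
  if (length(h) < min_steps)
    stop("calibration requires at least ", min_steps,
         " step observations (got ", length(h),
         "); acquire more photobleaching data")
  if (stats::sd(h) == 0) {
    return(structure(list(brightness = h[1L], uncertainty = 0,
                          n_steps = length(h), step_heights = h),
                     class = "brightness_calibration"))
  }
  d <- stats::density(h, bw = "nrd0")
  mode_i <- which.max(d$y)
  half <- d$y[mode_i] / 2
  above <- d$y >= half
  lo <- d$x[which(above)[1L]]
  hi <- d$x[rev(which(above))[1L]]
  structure(list(brightness = d$x[mode_i], uncertainty = (hi - lo) / 2,
                 n_steps = length(h), step_heights = h),
            class = "brightness_calibration")
}

#' @export
print.brightness_calibration <- function(x, ...) {
  cat(sprintf("<brightness_calibration> %.1f +/- %.1f photoelectrons/frame/molecule (n = %d steps)\n",
              x$brightness, x$uncertainty, x$n_steps))
  invisible(x)
}

#' Backward-extrapolated initial intensity of a track
#'
#' Ordinary least squares through the first four summed-intensity samples at
#' frame-centre times `(i + 0.5) * frame_interval`, `i = 0..3`, evaluated at
#' `t = 0` (illumination onset).  Exact on any affine trace; a constant
#' trace returns the constant.
#'
#' @param intensity_trace numeric vector, length >= 4 (shorter traces are a
#'   precondition error and should be excluded upstream).
#' @param frame_interval s.
#' @return photoelectrons at `t = 0`.
#' @export
initial_intensity <- function(intensity_trace, frame_interval) {
  if (length(intensity_trace) < 4L)
    stop("initial_intensity requires at least 4 samples")
  y <- as.numeric(intensity_trace[1:4])
  t <- (0:3 + 0.5) * frame_interval
  tbar <- mean(t); ybar <- mean(y)
  slope <- sum((t - tbar) * (y - ybar)) / sum((t - tbar)^2)
  ybar - slope * tbar
}

#' Convert an initial intensity to a stoichiometry
#'
#' The fractional quotient initial intensity / single-molecule brightness;
#' not rounded (the periodicity kernel density performs the effective
#' discretization).  Non-positive intensities yield `NA` and should be
#' excluded.
#'
#' @param initial_intensity photoelectrons.
#' @param calibration a `brightness_calibration` or a bare brightness value.
#' @return molecules (fractional), or `NA` for non-physical samples.
#' @export
stoichiometry <- function(initial_intensity, calibration) {
  b <- if (inherits(calibration, "brightness_calibration"))
    calibration$brightness else as.numeric(calibration)
  if (!is.finite(b) || b <= 0) stop("calibration brightness must be > 0")
  s <- initial_intensity / b
  s[!is.finite(s) | s <= 0] <- NA_real_
  s
}

#' Count molecules for every track in a track table
#'
#' Orders each track by frame, extrapolates its initial intensity, pools
#' terminal step heights across tracks for self-calibration when no
#' calibration is supplied, and divides.  Tracks shorter than 4 frames are
#' excluded with a logged reason; samples with non-positive stoichiometry
#' are dropped.
#'
#' The backward extrapolation targets `t = 0`, illumination onset, so it is
#' only photobleaching-independent for tracks present from the start of the
#' acquisition: tracks first detected after `max_start_frame` are excluded
#' from the stoichiometry samples (they are fragments of partially bleached
#' complexes) but still contribute terminal steps to the calibration.
#'
#' @param tracks track table (see [track_stack()]), optionally with an
#'   `acquisition_id` column.
#' @param frame_interval s.
#' @param calibration optional `brightness_calibration` or brightness value;
#'   `NULL` self-calibrates from the tracks' terminal steps.
#' @param min_steps calibration floor passed to
#'   [characteristic_brightness()].
#' @param max_start_frame latest first-detection frame (0-based) for a
#'   track to yield a stoichiometry sample; `Inf` keeps all tracks.
#' @param step_args arguments passed to [terminal_step_heights()]; the
#'   defaults are tuned for camera-noise track traces (longer minimum
#'   plateau than the generic trace-level default).
#' @param verbose log exclusions.
#' @return list with `samples` (`data.frame(track_id, acquisition_id,
#'   initial_intensity, stoichiometry)`), `calibration`, and `step_heights`.
#' @export
count_tracks <- function(tracks, frame_interval, calibration = NULL,
                         min_steps = 20L, max_start_frame = 2,
                         step_args = list(ck_window = 8L, min_plateau = 4L,
                                          threshold_sds = 3, merge_z = 2.5),
                         verbose = FALSE) {
  if (!"acquisition_id" %in% names(tracks))
    tracks$acquisition_id <- 0L
  key <- interaction(tracks$acquisition_id, tracks$track_id, drop = TRUE)
  traces <- split(tracks, key)
  steps <- list(); rows <- list()
  for (tr in traces) {
    tr <- tr[order(tr$frame), ]
    x <- tr$summed_intensity
    if (length(x) < 4L) {
      if (verbose)
        message("track ", tr$track_id[1L], " (acq ", tr$acquisition_id[1L],
                ") excluded: only ", length(x), " frames (< 4)")
      next
    }
    steps[[length(steps) + 1L]] <-
      do.call(terminal_step_heights, c(list(x), step_args))
    if (tr$frame[1L] > max_start_frame) {
      if (verbose)
        message("track ", tr$track_id[1L], " (acq ", tr$acquisition_id[1L],
                ") excluded from stoichiometry: starts at frame ",
                tr$frame[1L])
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = tr$track_id[1L], acquisition_id = tr$acquisition_id[1L],
      initial_intensity = initial_intensity(x, frame_interval))
  }
  samples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), acquisition_id = integer(0),
               initial_intensity = numeric(0))
  all_steps <- unlist(steps)
  if (is.null(calibration))
    calibration <- characteristic_brightness(all_steps, min_steps = min_steps)
  if (!inherits(calibration, "brightness_calibration"))
    calibration <- structure(list(brightness = as.numeric(calibration),
                                  uncertainty = NA_real_,
                                  n_steps = length(all_steps),
                                  step_heights = all_steps),
                             class = "brightness_calibration")
  samples$stoichiometry <- stoichiometry(samples$initial_intensity,
                                         calibration)
  excluded <- is.na(samples$stoichiometry)
  if (verbose && any(excluded))
    message(sum(excluded), " track(s) excluded: non-positive stoichiometry")
  samples <- samples[!excluded, , drop = FALSE]
  rownames(samples) <- NULL
  list(samples = samples, calibration = calibration,
       step_heights = all_steps)
}
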