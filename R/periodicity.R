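# Peak-interval periodicity: turn a population of per-track stoichiometry
# samples into the modal repeat unit of the stoichiometry distribution.

#' Fixed-bandwidth Gaussian kernel density of stoichiometry samples
#'
#' Unlike [stats::density()], the bandwidth is fixed in molecule units
#' (default 0.7 molecules, reflecting the measurement's background standard
#' deviation) rather than data-driven, so peak positions are comparable
#' across acquisitions.  The grid runs from 0 to `max(samples) + 4 *
#' kernel_width` at a step of at most `grid_step`; the density is
#' renormalized to integrate to 1 over the grid.
#'
#' @param samples numeric vector of stoichiometries (>= 1 sample).
#' @param kernel_width Gaussian kernel SD in molecules.
#' @param weights optional positive kernel weights, recycled to the samples.
#' @param grid_step maximum grid spacing, molecules.
#' @return object of class `stoich_kde`: list with `grid`, `density`,
#'   `kernel_width`, `n`.
#' @export
stoichiometry_kde <- function(samples, kernel_width = 0.7, weights = NULL,
                              grid_step = 0.01) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("stoichiometry_kde requires at least 1 sample")
  if (kernel_width <= 0) stop("kernel_width must be > 0")
  if (is.null(weights)) weights <- rep(1, length(samples))
  weights <- rep_len(weights, length(samples))
  if (any(weights <= 0)) stop("weights must be strictly positive")
  hi <- max(samples) + 4 * kernel_width
  grid <- seq(0, hi, length.out = max(2L, ceiling(hi / grid_step) + 1L))
  dens <- mixture_density(grid, samples, kernel_width, weights)
  # renormalize: kernel mass below 0 is truncated by the grid
  area <- trapezoid(grid, dens)
  structure(list(grid = grid, density = dens / area,
                 kernel_width = kernel_width, n = length(samples)),
            class = "stoich_kde")
}

# density of a weighted Gaussian mixture, normalized to unit weight
mixture_density <- function(x, centers, width, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(centers))
  w <- weights / sum(weights)
  out <- numeric(length(x))
  for (i in seq_along(centers))
    out <- out + w[i] * stats::dnorm(x, centers[i], width)
  out
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2

#' Locate peaks of a stoichiometry density
#'
#' Local maxima of the density with topographic prominence at least
#' `min_prominence_fraction` times the global maximum; positions are
#' refined by quadratic interpolation through the three grid points at each
#' maximum.  A flat or monotone density has no interior peaks.
#'
#' @param distribution a `stoich_kde`.
#' @param min_prominence_fraction prominence floor relative to the global
#'   density maximum.
#' @return `data.frame(position, height)` sorted by position (possibly
#'   empty).
#' @export
find_density_peaks <- function(distribution, min_prominence_fraction = 0.05) {
  stopifnot(inherits(distribution, "stoich_kde"))
  x <- distribution$grid; y <- distribution$density
  n <- length(y)
  empty <- data.frame(position = numeric(0), height = numeric(0))
  if (n < 3L) return(empty)
  i <- 2:(n - 1L)
  is_max <- y[i] > y[i - 1L] & y[i] >= y[i + 1L]
  idx <- i[is_max]
  # collapse flat-topped runs to their first sample
  if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) > 1L)]
  if (!length(idx)) return(empty)
  prom <- vapply(idx, function(p) {
    left <- y[1:p]; right <- y[p:n]
    higher_l <- which(left > y[p])
    base_l <- min(left[if (length(higher_l)) (max(higher_l) + 1L):p else 1:p])
    higher_r <- which(right > y[p])
    base_r <- min(right[if (length(higher_r)) 1:(min(higher_r) - 1L) else 1:length(right)])
    y[p] - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= min_prominence_fraction * max(y)
  idx <- idx[keep]
  if (!length(idx)) return(empty)
  pos <- vapply(idx, function(p) {
    y0 <- y[p - 1L]; y1 <- y[p]; y2 <- y[p + 1L]
    denom <- y0 - 2 * y1 + y2
    delta <- if (abs(denom) < .Machine$double.eps) 0 else
      0.5 * (y0 - y2) / denom
    x[p] + delta * (x[2L] - x[1L])
  }, numeric(1))
  out <- data.frame(position = pos, height = y[idx])
  out[order(out$position), , drop = FALSE]
}

#' Aggregate peak intervals across acquisitions
#'
#' For each acquisition, every pairwise difference between its sorted peak
#' positions is an interval (all pairs, not adjacent-only, unless
#' `adjacent_only`); intervals are weighted by inverse square-root distance
#' (`size^-0.5`), discounting the larger shot noise of broader intervals,
#' and pooled across the population.
#'
#' @param peaks_by_acquisition list of numeric peak-position vectors, one
#'   per acquisition.
#' @param mean_stoichiometry mean stoichiometry over all samples feeding the
#'   peaks (used downstream for the interval-density bandwidth).
#' @param adjacent_only use only adjacent peak differences.
#' @return object of class `interval_set`: list with `intervals`
#'   (`data.frame(size, weight, acquisition)`), `mean_stoichiometry`,
#'   `n_intervals`.  No acquisition with >= 2 peaks gives an empty set.
#' @export
peak_intervals <- function(peaks_by_acquisition, mean_stoichiometry = NA_real_,
                           adjacent_only = FALSE) {
  rows <- list()
  for (a in seq_along(peaks_by_acquisition)) {
    p <- sort(peaks_by_acquisition[[a]])
    if (length(p) < 2L) next
    sizes <- if (adjacent_only) diff(p) else {
      cmb <- utils::combn(p, 2L)
      cmb[2L, ] - cmb[1L, ]
    }
    sizes <- sizes[sizes > 0]
    if (!length(sizes)) next
    rows[[length(rows) + 1L]] <- data.frame(size = sizes,
                                            weight = sizes^(-0.5),
                                            acquisition = a)
  }
  intervals <- if (length(rows)) do.call(rbind, rows) else
    data.frame(size = numeric(0), weight = numeric(0),
               acquisition = integer(0))
  structure(list(intervals = intervals,
                 mean_stoichiometry = mean_stoichiometry,
                 n_intervals = nrow(intervals)),
            class = "interval_set")
}

interval_density_mode <- function(sizes, weights, width, grid_step = 0.01) {
  hi <- max(sizes) + 4 * width
  grid <- seq(0, hi, length.out = max(2L, ceiling(hi / grid_step) + 1L))
  dens <- mixture_density(grid, sizes, width, weights)
  pk <- find_density_peaks(structure(list(grid = grid, density = dens,
                                          kernel_width = width,
                                          n = length(sizes)),
                                     class = "stoich_kde"),
                           min_prominence_fraction = 0)
  if (!nrow(pk)) return(grid[which.max(dens)])
  pk$position[which.max(pk$height)]
}

#' Modal peak interval (periodicity) with bootstrap confidence interval
#'
#' A weighted Gaussian-kernel density over the interval sizes, with
#' bandwidth `0.7 * sqrt(mean_stoichiometry / n_intervals)` molecules
#' (discounting the larger shot noise of intervals between peaks of higher
#' stoichiometry), whose mode is the periodicity.  The 95% CI comes from
#' `bootstrap` resamples of whole acquisitions with replacement, recomputing
#' the mode (and bandwidth) each time and taking the 2.5/97.5 percentiles.
#'
#' @param interval_set an `interval_set` with `n_intervals >= 1`.
#' @param base_width base kernel width, molecules.
#' @param bootstrap number of bootstrap resamples (0 disables the CI).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `periodicity_result`: list with `periodicity`,
#'   `ci95`, `interval_kernel_width`, `n_intervals`, `degenerate_ci`,
#'   `status`.
#' @export
interval_mode <- function(interval_set, base_width = 0.7, bootstrap = 1000L,
                          seed = NULL) {
  stopifnot(inherits(interval_set, "interval_set"))
  iv <- interval_set$intervals
  if (!nrow(iv))
    return(structure(list(periodicity = NA_real_,
                          ci95 = c(NA_real_, NA_real_),
                          interval_kernel_width = NA_real_,
                          n_intervals = 0L, degenerate_ci = TRUE,
                          status = "insufficient peaks"),
                     class = "periodicity_result"))
  ms <- interval_set$mean_stoichiometry
  if (!is.finite(ms) || ms <= 0) ms <- mean(iv$size)
  width <- base_width * sqrt(ms / nrow(iv))
  mode_hat <- interval_density_mode(iv$size, iv$weight, width)
  acqs <- unique(iv$acquisition)
  ci <- c(mode_hat, mode_hat)
  degenerate <- length(acqs) < 2L || length(unique(iv$size)) == 1L
  if (bootstrap > 0L && !degenerate) {
    if (!is.null(seed)) set.seed(seed)
    modes <- numeric(bootstrap)
    by_acq <- split(iv, iv$acquisition)
    for (b in seq_len(bootstrap)) {
      pick <- sample(length(by_acq), length(by_acq), replace = TRUE)
      bs <- do.call(rbind, by_acq[pick])
      wb <- base_width * sqrt(ms / nrow(bs))
      modes[b] <- interval_density_mode(bs$size, bs$weight, wb,
                                        grid_step = 0.02)
    }
    ci <- unname(stats::quantile(modes, c(0.025, 0.975)))
  }
  structure(list(periodicity = mode_hat, ci95 = ci,
                 interval_kernel_width = width, n_intervals = nrow(iv),
                 degenerate_ci = degenerate, status = "ok"),
            class = "periodicity_result")
}

#' @export
print.periodicity_result <- function(x, ...) {
  if (!is.finite(x$periodicity)) {
    cat("<periodicity_result> undefined:", x$status, "\n")
  } else {
    cat(sprintf("<periodicity_result> %.2f molecules (95%% CI %.2f-%.2f, %d intervals)%s\n",
                x$periodicity, x$ci95[1L], x$ci95[2L], x$n_intervals,
                if (x$degenerate_ci) " [degenerate CI]" else ""))
  }
  invisible(x)
}

#' Estimate the assembly periodicity from stoichiometry samples
#'
#' Runs the full periodicity stage: a fixed-bandwidth kernel density and
#' peak finding per acquisition, pairwise peak-interval aggregation weighted
#' by inverse square-root distance, and the weighted interval-density mode
#' with a bootstrap 95% CI.  The population-level stoichiometry distribution
#' is also returned for reporting.
#'
#' @param samples `data.frame` with `stoichiometry` and `acquisition_id`
#'   columns (a bare numeric vector is treated as one acquisition).
#' @param kernel_width stoichiometry kernel width, molecules.
#' @param min_prominence_fraction peak prominence floor.
#' @param adjacent_only see [peak_intervals()].
#' @param bootstrap,seed see [interval_mode()].
#' @return list with `periodicity` (a `periodicity_result`), `intervals`,
#'   `population_kde`, `population_peaks`, `peaks_by_acquisition`,
#'   `n_tracks`.
#' @export
estimate_periodicity <- function(samples, kernel_width = 0.7,
                                 min_prominence_fraction = 0.05,
                                 adjacent_only = FALSE, bootstrap = 1000L,
                                 seed = NULL) {
  if (is.numeric(samples))
    samples <- data.frame(stoichiometry = samples, acquisition_id = 0L)
  stopifnot(all(c("stoichiometry", "acquisition_id") %in% names(samples)))
  samples <- samples[is.finite(samples$stoichiometry), , drop = FALSE]
  if (!nrow(samples)) {
    res <- interval_mode(peak_intervals(list()), bootstrap = 0L)
    return(list(periodicity = res, intervals = peak_intervals(list()),
                population_kde = NULL, population_peaks = NULL,
                peaks_by_acquisition = list(), n_tracks = 0L))
  }
  by_acq <- split(samples$stoichiometry, samples$acquisition_id)
  peaks <- lapply(by_acq, function(s)
    find_density_peaks(stoichiometry_kde(s, kernel_width),
                       min_prominence_fraction)$position)
  ivs <- peak_intervals(peaks, mean_stoichiometry = mean(samples$stoichiometry),
                        adjacent_only = adjacent_only)
  pop_kde <- stoichiometry_kde(samples$stoichiometry, kernel_width)
  list(periodicity = interval_mode(ivs, base_width = kernel_width,
                                   bootstrap = bootstrap, seed = seed),
       intervals = ivs, population_kde = pop_kde,
       population_peaks = find_density_peaks(pop_kde,
                                             min_prominence_fraction),
       peaks_by_acquisition = peaks, n_tracks = nrow(samples))
}
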