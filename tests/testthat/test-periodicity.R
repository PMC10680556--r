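test_that("stoichiometry KDE: single kernel, normalization, errors", {
  d <- stoichiometry_kde(5)
  expect_equal(d$grid[which.max(d$density)], 5, tolerance = 0.011)
  # densities integrate to one on their grid
  area <- sum(diff(d$grid) * (d$density[-1] + d$density[-length(d$density)])) / 2
  expect_equal(area, 1, tolerance = 1e-6)
  expect_error(stoichiometry_kde(numeric(0)), "at least 1")
  expect_error(stoichiometry_kde(5, kernel_width = 0), "> 0")
})

test_that("KDE matches the analytic two-Gaussian mixture", {
  d <- stoichiometry_kde(c(5, 10), kernel_width = 0.7)
  # oracle: analytic mixture maxima located by optimize()
  mix <- function(x) 0.5 * dnorm(x, 5, 0.7) + 0.5 * dnorm(x, 10, 0.7)
  m1 <- optimize(mix, c(3, 7), maximum = TRUE)$maximum
  m2 <- optimize(mix, c(8, 12), maximum = TRUE)$maximum
  pk <- find_density_peaks(d)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$position, c(m1, m2), tolerance = 0.02)
  # weighted 3:1 mixture keeps the global mode at 5
  d2 <- stoichiometry_kde(c(5, 5, 5, 10), kernel_width = 0.7)
  pk2 <- find_density_peaks(d2)
  expect_equal(pk2$position[which.max(pk2$height)], 5, tolerance = 0.02)
})

test_that("KDE equals brute-force mixture evaluation at random points", {
  set.seed(77)
  samples <- runif(40, 1, 14)
  d <- stoichiometry_kde(samples, kernel_width = 0.7)
  # renormalization constant: trapezoid area of the raw mixture
  raw <- sapply(d$grid, function(x) mean(dnorm(x, samples, 0.7)))
  area <- sum(diff(d$grid) * (raw[-1] + raw[-length(raw)])) / 2
  idx <- sample(length(d$grid), 1000, replace = TRUE)
  brute <- sapply(d$grid[idx], function(x) mean(dnorm(x, samples, 0.7))) / area
  expect_lt(max(abs(d$density[idx] - brute)), 1e-9)
})

test_that("peak finding: prominence filter and monotone segments", {
  d <- stoichiometry_kde(c(rep(5, 50), 10), kernel_width = 0.7)
  pk_all <- find_density_peaks(d, min_prominence_fraction = 0)
  pk_strict <- find_density_peaks(d, min_prominence_fraction = 0.5)
  expect_equal(nrow(pk_all), 2L)
  expect_equal(nrow(pk_strict), 1L)
  # strictly monotone density: no interior peak
  mono <- structure(list(grid = seq(0, 1, 0.01),
                         density = seq(0, 1, 0.01), kernel_width = 1, n = 1),
                    class = "stoich_kde")
  expect_equal(nrow(find_density_peaks(mono)), 0L)
})

test_that("peak intervals: pairwise enumeration and weights", {
  iv <- peak_intervals(list(c(5, 10, 15)), mean_stoichiometry = 10)
  expect_equal(sort(iv$intervals$size), c(5, 5, 10))
  expect_equal(iv$intervals$weight, iv$intervals$size^(-0.5))
  expect_equal(iv$n_intervals, 3L)
  # single peak: no intervals; two acquisitions aggregate
  expect_equal(peak_intervals(list(5))$n_intervals, 0L)
  iv2 <- peak_intervals(list(c(5, 10), c(5, 10)))
  expect_equal(iv2$intervals$size, c(5, 5))
  expect_equal(iv2$intervals$acquisition, c(1L, 2L))
  # adjacent-only drops the compound interval
  iv3 <- peak_intervals(list(c(5, 10, 15)), adjacent_only = TRUE)
  expect_equal(sort(iv3$intervals$size), c(5, 5))
})

test_that("interval mode: weighted-mixture oracle and degenerate cases", {
  iv <- peak_intervals(list(c(5, 10, 15)), mean_stoichiometry = 10)
  res <- interval_mode(iv, bootstrap = 0)
  # oracle: direct evaluation of the 3-kernel weighted mixture on a fine grid
  w2 <- 0.7 * sqrt(10 / 3)
  grid <- seq(0, 15, by = 0.001)
  sizes <- iv$intervals$size; wts <- iv$intervals$weight / sum(iv$intervals$weight)
  dens <- sapply(grid, function(x) sum(wts * dnorm(x, sizes, w2)))
  expect_equal(res$interval_kernel_width, w2)
  expect_equal(res$periodicity, grid[which.max(dens)], tolerance = 0.01)

  # all intervals identical: CI collapses onto the mode
  ivd <- peak_intervals(list(c(0, 5), c(3, 8)), mean_stoichiometry = 5)
  resd <- interval_mode(ivd, bootstrap = 100, seed = 1)
  expect_equal(resd$periodicity, 5, tolerance = 0.02)
  expect_equal(resd$ci95, c(resd$periodicity, resd$periodicity))
  expect_true(resd$degenerate_ci)

  # single interval: degenerate flagged result
  res1 <- interval_mode(peak_intervals(list(c(2, 7)), mean_stoichiometry = 5))
  expect_equal(res1$periodicity, 5, tolerance = 0.02)
  expect_true(res1$degenerate_ci)

  # no intervals: explicit insufficient-peaks status
  res0 <- interval_mode(peak_intervals(list(5)))
  expect_equal(res0$status, "insufficient peaks")
  expect_true(is.na(res0$periodicity))
})

test_that("periodicity is invariant under uniform weight rescaling", {
  iv <- peak_intervals(list(c(5, 10, 15), c(5.2, 9.8)),
                       mean_stoichiometry = 9)
  res1 <- interval_mode(iv, bootstrap = 0)
  iv$intervals$weight <- iv$intervals$weight * 37.5
  res2 <- interval_mode(iv, bootstrap = 0)
  expect_equal(res1$periodicity, res2$periodicity)
})

test_that("bootstrap CI brackets the mode and is seed-reproducible", {
  set.seed(19)
  peaks <- lapply(1:12, function(a) c(5, 10, 15) + rnorm(3, 0, 0.3))
  iv <- peak_intervals(peaks, mean_stoichiometry = 10)
  r1 <- interval_mode(iv, bootstrap = 200, seed = 4)
  r2 <- interval_mode(iv, bootstrap = 200, seed = 4)
  expect_equal(r1$ci95, r2$ci95)
  expect_true(r1$ci95[1] <= r1$periodicity + 1e-9)
  expect_true(r1$ci95[2] >= r1$periodicity - 1e-9)
})

test_that("estimate_periodicity recovers the unit on clean grouped samples", {
  set.seed(5)
  samples <- do.call(rbind, lapply(1:15, function(a) {
    k <- sample(1:3, 8, TRUE, c(.5, .3, .2))
    data.frame(stoichiometry = 5 * k + rnorm(8, 0, 0.7), acquisition_id = a)
  }))
  res <- estimate_periodicity(samples, bootstrap = 0)
  expect_equal(res$periodicity$periodicity, 5, tolerance = 0.5)
  top <- res$population_peaks
  expect_equal(top$position[which.max(top$height)], 5, tolerance = 0.5)
})
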