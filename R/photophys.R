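# Photophysiology formula set: PAM-derived quenching metrics, ECS-derived
# proton-motive-force metrics, chlorophyll and specific growth rate.

#' Quenching and quantum-yield formulas
#'
#' `npq(Fm, Fm_prime) = (Fm - Fm') / Fm'`;
#' `yii(Fm_prime, F) = (Fm' - F) / Fm'`;
#' `fv_fm(Fm, Fo) = (Fm - Fo) / Fm`.
#' All are scale invariant: multiplying every fluorescence value by c > 0
#' leaves them unchanged.  Non-positive denominators are an error.
#'
#' @param Fm dark-adapted maximal fluorescence yield.
#' @param Fm_prime maximal fluorescence yield in actinic light.
#' @param F stationary fluorescence.
#' @param Fo dark-adapted minimal fluorescence yield.
#' @return the metric value(s).
#' @export
npq <- function(Fm, Fm_prime) {
  if (any(Fm_prime <= 0)) stop("Fm' must be > 0")
  (Fm - Fm_prime) / Fm_prime
}

#' @rdname npq
#' @export
yii <- function(Fm_prime, F) {
  if (any(Fm_prime <= 0)) stop("Fm' must be > 0")
  (Fm_prime - F) / Fm_prime
}

#' @rdname npq
#' @export
fv_fm <- function(Fm, Fo) {
  if (any(Fm <= 0)) stop("Fm must be > 0")
  (Fm - Fo) / Fm
}

#' Fast-relaxing (energy-dependent) NPQ component
#'
#' qE estimate: NPQ at the light-to-dark transition (the last pulse in
#' light) minus the minimum NPQ over the dark-relaxation pulses.
#'
#' @param npq_series NPQ values, one per saturating pulse.
#' @param pulse_times pulse times, s.
#' @param light_off time of the light-to-dark transition, s.
#' @return the fast-relaxing NPQ.
#' @export
fast_relaxing_npq <- function(npq_series, pulse_times, light_off) {
  stopifnot(length(npq_series) == length(pulse_times))
  in_light <- pulse_times <= light_off
  dark <- pulse_times > light_off
  if (!any(dark)) stop("no saturating pulses after light off")
  if (!any(in_light)) stop("no saturating pulses before light off")
  npq_end <- npq_series[which(in_light)[sum(in_light)]]
  npq_end - min(npq_series[dark])
}

#' Analyze a PAM fluorescence trace
#'
#' For each saturating pulse the maximal yield Fm' is the maximum
#' fluorescence within the pulse window and the stationary F is the mean
#' over the second preceding the pulse; NPQ and Y(II) follow from the
#' printed formulas, Fv/Fm from the dark-adapted Fm and Fo, and qE from
#' [fast_relaxing_npq()].
#'
#' @param trace a `pam_trace` (see [simulate_pam_trace()]) or a list with
#'   `time`, `fluorescence`, `pulse_times`, `pulse_width`, `light_off`,
#'   `Fm`, `Fo`.
#' @param pre_window s of stationary fluorescence averaged before each
#'   pulse.
#' @return list with `pulse_times`, `fm_prime`, `f_stationary`,
#'   `npq_series`, `yii_series`, `fv_fm`, `qe_fast`.
#' @export
analyze_pam <- function(trace, pre_window = 1.0) {
  t <- trace$time; f <- trace$fluorescence
  pw <- if (!is.null(trace$pulse_width)) trace$pulse_width else 0.3
  fm_prime <- f_stat <- numeric(length(trace$pulse_times))
  for (i in seq_along(trace$pulse_times)) {
    tp <- trace$pulse_times[i]
    in_pulse <- t >= tp & t < tp + pw
    if (!any(in_pulse)) stop("no samples inside pulse at t = ", tp)
    fm_prime[i] <- max(f[in_pulse])
    pre <- t >= tp - pre_window & t < tp
    f_stat[i] <- if (any(pre)) mean(f[pre]) else NA_real_
  }
  npq_series <- npq(trace$Fm, fm_prime)
  yii_series <- yii(fm_prime, f_stat)
  qe <- tryCatch(fast_relaxing_npq(npq_series, trace$pulse_times,
                                   trace$light_off),
                 error = function(e) NA_real_)
  list(pulse_times = trace$pulse_times, fm_prime = fm_prime,
       f_stationary = f_stat, npq_series = npq_series,
       yii_series = yii_series,
       fv_fm = fv_fm(trace$Fm, trace$Fo), qe_fast = qe)
}

#' ECS signal and proton-motive-force size
#'
#' The ECS signal is the difference between the absorbance changes at 520
#' and 545 nm, normalized by the ECS_ST amplitude when available.  PMF size
#' is the mean signal over the final `light_window` of illumination minus
#' the minimum over the `dark_window` after light-off.
#'
#' @param trace an `ecs_trace` (see [simulate_ecs_trace()]) or a list with
#'   `time`, `a520`, `a545`, `light_off_time` and optionally `ecs_st`.
#' @param normalize divide by `ecs_st` when present.
#' @return numeric signal series.
#' @export
ecs_signal <- function(trace, normalize = TRUE) {
  s <- trace$a520 - trace$a545
  if (normalize && !is.null(trace$ecs_st)) {
    if (trace$ecs_st <= 0) stop("ecs_st must be > 0 for normalization")
    s <- s / trace$ecs_st
  }
  s
}

#' @rdname ecs_signal
#' @param light_window s of light signal averaged before light-off.
#' @param dark_window s searched for the post-illumination minimum.
#' @param smooth_samples boxcar width (samples) applied before taking the
#'   post-illumination minimum, so instrument noise does not bias the
#'   minimum downward; 1 disables.
#' @export
pmf <- function(trace, light_window = 0.1, dark_window = 0.3,
                normalize = TRUE, smooth_samples = 5L) {
  t <- trace$time; off <- trace$light_off_time
  if (off <= min(t) || off > max(t))
    stop("light_off_time outside the record")
  s <- ecs_signal(trace, normalize)
  if (smooth_samples > 1L) {
    sm <- stats::filter(s, rep(1 / smooth_samples, smooth_samples),
                        sides = 2)
    s_min <- ifelse(is.na(sm), s, as.numeric(sm))
  } else s_min <- s
  light <- t >= off - light_window & t < off
  dark <- t > off & t <= off + dark_window
  if (!any(light) || !any(dark))
    stop("insufficient samples around light-off for the PMF windows")
  mean(s[light]) - min(s_min[dark])
}

#' Proton conductivity from the ECS decay
#'
#' Least-squares single-exponential fit (amplitude, offset, tau) to the ECS
#' signal over the first `fit_window` (100 ms) after light-off;
#' `g_h = 1 / tau`.  The fit is flagged invalid when it does not converge,
#' when tau falls outside the window scale, or when the fitted amplitude is
#' not resolvable above the residual noise (no decay).
#'
#' @inheritParams ecs_signal
#' @param fit_window s after light-off used for the fit.
#' @return list with `g_h` (s^-1), `tau`, `amplitude`, `offset`, `valid`.
#' @export
g_h <- function(trace, fit_window = 0.1, normalize = TRUE) {
  t <- trace$time; off <- trace$light_off_time
  s <- ecs_signal(trace, normalize)
  sel <- t >= off & t <= off + fit_window
  if (sum(sel) < 10L)
    stop("need >= 10 samples within ", fit_window, " s of light-off")
  tt <- t[sel] - off; y <- s[sel]
  a0 <- y[1L] - min(y); c0 <- min(y)
  obj <- function(par) {
    a <- par[1L]; cc <- par[2L]; tau <- exp(par[3L])
    sum((y - (cc + a * exp(-tt / tau)))^2)
  }
  fit <- stats::optim(c(max(a0, 1e-6), c0, log(fit_window / 3)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  a <- fit$par[1L]; cc <- fit$par[2L]; tau <- exp(fit$par[3L])
  resid_sd <- sqrt(fit$value / length(y))
  valid <- fit$convergence == 0 && a > 0 && tau > 0 &&
    tau < 100 * fit_window && a > max(2 * resid_sd, 1e-9 * max(abs(y), 1))
  list(g_h = if (valid) 1 / tau else NA_real_, tau = tau, amplitude = a,
       offset = cc, valid = valid)
}

#' Proton flux
#'
#' `v_h = PMF x g_h`, identically.
#' @param pmf PMF size.
#' @param g_h proton conductivity, s^-1.
#' @return PMF * g_h.
#' @export
v_h <- function(pmf, g_h) pmf * g_h

#' Analyze an ECS trace
#'
#' Computes PMF size, proton conductivity and proton flux from a
#' dual-wavelength ECS record, plus the simple steady-state-dark-point
#' decomposition of the PMF into its electric (delta-psi) and osmotic
#' (delta-pH) fractions: the delta-psi fraction is (light steady state -
#' dark steady state) / PMF and the delta-pH fraction its complement.  The
#' partitioning is reduced fidelity: it assumes the dark steady state has
#' fully relaxed within the record.
#'
#' @inheritParams pmf
#' @param steady_window s at the end of the record averaged as the dark
#'   steady state.
#' @return list with `pmf`, `g_h`, `tau`, `v_h`, `valid`, `dpsi_fraction`,
#'   `dph_fraction`.
#' @export
analyze_ecs <- function(trace, light_window = 0.1, dark_window = 0.3,
                        steady_window = 0.1, normalize = TRUE) {
  p <- pmf(trace, light_window, dark_window, normalize)
  fit <- g_h(trace, normalize = normalize)
  t <- trace$time; s <- ecs_signal(trace, normalize)
  off <- trace$light_off_time
  light_steady <- mean(s[t >= off - light_window & t < off])
  dark_steady <- mean(s[t >= max(t) - steady_window])
  dpsi <- if (p != 0) (light_steady - dark_steady) / p else NA_real_
  list(pmf = p, g_h = fit$g_h, tau = fit$tau,
       v_h = v_h(p, fit$g_h), valid = fit$valid,
       dpsi_fraction = dpsi, dph_fraction = 1 - dpsi)
}

#' Total chlorophyll from methanol-extract absorbances
#'
#' `22.12 * Abs652 + 2.71 * Abs665` micrograms per mL.
#' @param a652,a665 absorbances at 652 and 665 nm (>= 0).
#' @return micrograms chlorophyll per mL.
#' @export
total_chlorophyll <- function(a652, a665) {
  if (any(a652 < 0) || any(a665 < 0)) stop("absorbances must be >= 0")
  22.12 * a652 + 2.71 * a665
}

#' Specific growth rate
#'
#' `mu = ln(N2 / N1) / t` per hour.
#' @param n1,n2 cell densities at the start and end of the interval (> 0).
#' @param t interval length, h (> 0).
#' @return growth rate, h^-1.
#' @export
specific_growth_rate <- function(n1, n2, t) {
  if (any(n1 <= 0) || any(n2 <= 0) || any(t <= 0))
    stop("n1, n2 and t must all be > 0")
  log(n2 / n1) / t
}
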