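#' Construct a current-clamp sweep
#'
#' One voltage sweep with a square current step, as digitized by the
#' acquisition system (50 kHz by default).
#'
#' @param vm_mv per-sample membrane potential (mV).
#' @param sample_rate_hz sampling rate. Default 50000.
#' @param injected_current_pa step amplitude (pA).
#' @param step_onset,step_offset 1-based sample indices of the step.
#' @return object of class \code{voltage_sweep}.
#' @export
voltage_sweep <- function(vm_mv, sample_rate_hz = 50000,
                          injected_current_pa = 0,
                          step_onset = NA_integer_,
                          step_offset = NA_integer_) {
  if (!all(is.finite(vm_mv))) fail("vm_mv must be finite")
  if (sample_rate_hz <= 0) fail("sample_rate_hz must be positive")
  structure(list(vm_mv = vm_mv, sample_rate_hz = sample_rate_hz,
                 injected_current_pa = injected_current_pa,
                 step_onset = step_onset, step_offset = step_offset),
            class = "voltage_sweep")
}

## dV/dt in mV/ms by central differences (one-sided at the edges);
## boxcar_n > 1 applies a moving-average pre-filter to the voltage first
dvdt_mv_ms <- function(vm, rate_hz, boxcar_n = 1L) {
  if (boxcar_n > 1L) {
    k <- rep(1 / boxcar_n, boxcar_n)
    pad <- boxcar_n                          # edge-replicate so the ends
    ext <- c(rep(vm[1], pad), vm, rep(vm[length(vm)], pad))  # stay smooth
    sm <- stats::filter(ext, k, sides = 2)
    vm <- as.numeric(sm[(pad + 1):(pad + length(vm))])
  }
  n <- length(vm)
  d <- numeric(n)
  d[2:(n - 1)] <- (vm[3:n] - vm[1:(n - 2)]) / 2
  d[1] <- vm[2] - vm[1]
  d[n] <- vm[n] - vm[n - 1]
  d * rate_hz / 1000
}

#' Action-potential threshold
#'
#' The membrane potential at the first sample where dV/dt (central
#' differences, mV/ms) exceeds the slope criterion, per AP. APs are
#' segmented by requiring the derivative to fall back below the criterion
#' between detections. Both the first-AP threshold and the mean over APs
#' are reported.
#'
#' @param sweep a \code{voltage_sweep}.
#' @param dvdt_crit slope criterion in mV/ms. Default 10.
#' @param boxcar_n optional moving-average pre-filter width in samples
#'   applied before differentiation (1 = off, the default).
#' @return list(threshold_mv (first AP), per_ap_mv, mean_mv, n_ap).
#' @export
ap_threshold <- function(sweep, dvdt_crit = 10, boxcar_n = 1L) {
  stopifnot(inherits(sweep, "voltage_sweep"))
  d <- dvdt_mv_ms(sweep$vm_mv, sweep$sample_rate_hz, boxcar_n)
  above <- d > dvdt_crit
  if (!any(above)) fail("no AP detected")
  edges <- which(diff(c(FALSE, above)) == 1L)
  thr <- sweep$vm_mv[edges]
  list(threshold_mv = thr[1L], per_ap_mv = thr, mean_mv = mean(thr),
       n_ap = length(thr))
}

#' Resting membrane potential
#'
#' Mean Vm over the zero-current baseline window of a sweep (the samples
#' before the step, or the whole sweep when no step is present).
#'
#' @param sweep a \code{voltage_sweep} with zero injected current during
#'   the baseline.
#' @return mV.
#' @export
resting_vm <- function(sweep) {
  stopifnot(inherits(sweep, "voltage_sweep"))
  idx <- if (is.na(sweep$step_onset)) seq_along(sweep$vm_mv)
  else seq_len(sweep$step_onset - 1L)
  if (length(idx) == 0L) fail("no baseline: window fully inside the step")
  mean(sweep$vm_mv[idx])
}

#' Input resistance from subthreshold current steps
#'
#' Per sweep, the steady-state voltage deflection (mean over the last part
#' of the step minus the pre-step baseline) divided by the injected
#' current, converted to megaohms; sweeps containing APs (by the dV/dt
#' criterion) are excluded, and the result is the mean over the remaining
#' sweeps.
#'
#' @param sweeps list of \code{voltage_sweep} with nonzero current steps.
#' @param steady_frac final fraction of the step used as steady state.
#'   Default 0.2.
#' @param baseline_ms pre-step baseline length. Default 100.
#' @param dvdt_crit AP-detection slope criterion (mV/ms). Default 10.
#' @param boxcar_n moving-average pre-filter width for the AP check
#'   (1 = off, the default; useful on noisy sweeps).
#' @return list(r_mohm, per_sweep_mohm, n_used).
#' @export
input_resistance <- function(sweeps, steady_frac = 0.2, baseline_ms = 100,
                             dvdt_crit = 10, boxcar_n = 1L) {
  vals <- vapply(sweeps, function(s) {
    stopifnot(inherits(s, "voltage_sweep"))
    if (s$injected_current_pa == 0) return(NA_real_)
    d <- dvdt_mv_ms(s$vm_mv, s$sample_rate_hz, boxcar_n)
    if (any(d > dvdt_crit)) return(NA_real_)       # spiking sweep: excluded
    on <- s$step_onset; off <- s$step_offset
    nb <- min(on - 1L, round(baseline_ms / 1000 * s$sample_rate_hz))
    if (nb < 1L) return(NA_real_)
    base <- mean(s$vm_mv[(on - nb):(on - 1L)])
    len <- off - on + 1L
    ss <- mean(s$vm_mv[(off - ceiling(steady_frac * len) + 1L):off])
    # mV / pA = GOhm; report MOhm
    (ss - base) / s$injected_current_pa * 1000
  }, 0)
  if (all(is.na(vals))) fail("no subthreshold sweep available")
  list(r_mohm = mean(vals, na.rm = TRUE), per_sweep_mohm = vals,
       n_used = sum(!is.na(vals)))
}

#' Simulate current-clamp sweeps from a passive RC cell
#'
#' Synthetic sweeps for validating the property extractors: an RC membrane
#' (exponential charging toward I*R) with optional Gaussian noise, and
#' optionally a spiking sweep whose depolarization slope steps from a
#' subthreshold to a suprathreshold rate exactly at a generative AP
#' threshold.
#'
#' @param resting_mv resting potential. Default -67.
#' @param r_mohm input resistance. Default 130.
#' @param tau_ms membrane time constant. Default 15.
#' @param currents_pa vector of step amplitudes. Default c(-100, -50, 50).
#' @param step_ms step duration. Default 500.
#' @param pre_ms,post_ms padding around the step. Defaults 200 and 100.
#' @param sample_rate_hz sampling rate. Default 50000.
#' @param noise_sd_mv Gaussian voltage noise SD. The noise is band-limited
#'   (8-sample moving average) the way an acquisition Bessel filter would
#'   shape it, so sample-to-sample derivatives stay physiological.
#'   Default 0.
#' @param ap_threshold_mv when non-NA, append a sweep with a slope ramp
#'   crossing the dV/dt criterion exactly at this voltage.
#' @param seed integer seed.
#' @return list of \code{voltage_sweep}.
#' @export
simulate_rc_sweeps <- function(resting_mv = -67, r_mohm = 130, tau_ms = 15,
                               currents_pa = c(-100, -50, 50),
                               step_ms = 500, pre_ms = 200, post_ms = 100,
                               sample_rate_hz = 50000, noise_sd_mv = 0,
                               ap_threshold_mv = NA_real_, seed = NULL) {
  with_seed_(seed, {
    dt_ms <- 1000 / sample_rate_hz
    n_pre <- round(pre_ms / dt_ms); n_step <- round(step_ms / dt_ms)
    n_post <- round(post_ms / dt_ms)
    sweeps <- lapply(currents_pa, function(I) {
      t_step <- (seq_len(n_step) - 1L) * dt_ms
      dv <- I * r_mohm / 1000                     # pA * MOhm = mV at t=inf
      v <- c(rep(resting_mv, n_pre),
             resting_mv + dv * (1 - exp(-t_step / tau_ms)),
             resting_mv + dv * exp(-(seq_len(n_post) - 1L) * dt_ms /
                                     tau_ms))
      if (noise_sd_mv > 0) {
        raw <- stats::rnorm(length(v) + 7L, 0, noise_sd_mv * sqrt(8))
        v <- v + stats::filter(raw, rep(1 / 8, 8), sides = 1)[-(1:7)]
      }
      voltage_sweep(v, sample_rate_hz, I, n_pre + 1L, n_pre + n_step)
    })
    if (!is.na(ap_threshold_mv)) {
      # 5 mV/ms subthreshold ramp up to threshold, then 20 mV/ms
      ramp1 <- seq(resting_mv, ap_threshold_mv, by = 5 * dt_ms)
      ramp2 <- seq(ap_threshold_mv + 20 * dt_ms,
                   ap_threshold_mv + 40, by = 20 * dt_ms)
      v <- c(rep(resting_mv, n_pre), ramp1, ramp2,
             rep(resting_mv, n_post))
      sweeps <- c(sweeps,
                  list(voltage_sweep(v, sample_rate_hz, 200, n_pre + 1L,
                                     n_pre + length(ramp1) +
                                       length(ramp2))))
    }
    sweeps
  })
}
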