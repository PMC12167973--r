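#' Global noise SD of a fluorescence trace
#'
#' The SD of the Fc samples lying between 0.5 and 1.5 times the trace
#' median. Restricting to this band around the median excludes transient
#' peaks so the estimate reflects the noise floor. Population (1/n) SD is
#' used; 0 is returned when fewer than two samples fall in the band (a
#' degenerate band, e.g. median 0, gives 0).
#'
#' @param fc numeric neuropil-subtracted fluorescence trace.
#' @return non-negative scalar (a.u.).
#' @export
global_noise_sd <- function(fc) {
  if (length(fc) == 0L || all(is.na(fc))) fail("fc is empty or all NA")
  med <- stats::median(fc, na.rm = TRUE)
  band <- sort(c(0.5 * med, 1.5 * med))
  sub <- fc[!is.na(fc) & fc >= band[1] & fc <= band[2]]
  if (length(sub) < 2L) return(0)
  pop_sd(sub)
}

#' Locate the fluorescence peak following a deconvolved spike
#'
#' The local maximum of Fc in the window from the spike frame to nine
#' frames after it (clipped at the trace end; first index wins ties).
#' Fc_max is the mean of the three Fc samples centred on the maximum,
#' clipped at the trace edges.
#'
#' @param fc fluorescence trace.
#' @param spike_frame 1-based frame index of the deconvolved spike.
#' @return list(peak_frame, fc_max).
#' @export
event_peak <- function(fc, spike_frame) {
  T_ <- length(fc)
  stopifnot(spike_frame >= 1L, spike_frame <= T_)
  win <- spike_frame:min(T_, spike_frame + 9L)
  m <- win[which.max(fc[win])]
  nb <- max(1L, m - 1L):min(T_, m + 1L)
  list(peak_frame = m, fc_max = mean(fc[nb]))
}

#' Local linear baseline preceding a spike
#'
#' Least-squares line fitted to the 11 Fc samples from 30 to 20 frames
#' before the spike; the baseline is the fitted value at the -20 frame
#' position and the local noise SD is the RMSE of the fit. Spikes earlier
#' than frame 31 have no local baseline window and are flagged; validity
#' for such events falls back to the global SD alone.
#'
#' @param fc fluorescence trace.
#' @param spike_frame 1-based spike frame.
#' @return list(fc_base, local_sd, has_baseline).
#' @export
local_baseline <- function(fc, spike_frame) {
  if (spike_frame < 31L)
    return(list(fc_base = NA_real_, local_sd = NA_real_,
                has_baseline = FALSE))
  idx <- (spike_frame - 30L):(spike_frame - 20L)
  x <- seq_along(idx)           # 1..11; position 11 is frame spike-20
  y <- fc[idx]
  xm <- mean(x); ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  inter <- ym - slope * xm
  fit <- inter + slope * x
  list(fc_base = fit[11L],
       local_sd = sqrt(mean((y - fit)^2)),
       has_baseline = TRUE)
}

#' Noise-filter a deconvolved spike train
#'
#' For every frame carrying deconvolved activity an event record is built
#' from the fluorescence trace: the post-spike peak (Fc_max), the local
#' linear baseline (Fc_base) and the local noise SD. The event amplitude
#' is Fc_max - Fc_base, and the event is valid only if the amplitude
#' strictly exceeds the noise SD; by default it must exceed both the local
#' and the global SD (the conservative reading), optionally either one
#' (\code{rule = "either"}). Invalid events are zeroed in the returned
#' train, which is the train all downstream analysis uses.
#'
#' @param fc fluorescence trace.
#' @param spks non-negative deconvolved activity, same length as fc.
#' @param rule "both" (amplitude > max(local, global), default) or
#'   "either" (> min of the two).
#' @return an object of class \code{filtered_train}: list with
#'   \code{spks_filtered}, \code{events} (data.frame: spike_frame,
#'   peak_frame, fc_max, fc_base, local_sd, amplitude, valid,
#'   has_baseline), \code{global_sd}.
#' @export
filter_train <- function(fc, spks, rule = c("both", "either")) {
  rule <- match.arg(rule)
  if (length(fc) != length(spks)) fail("fc and spks lengths differ")
  if (any(spks < 0, na.rm = TRUE)) fail("spks must be non-negative")
  T_ <- length(fc)
  gsd <- global_noise_sd(fc)
  frames <- which(spks > 0)
  n <- length(frames)
  if (n == 0L) {
    ev <- data.frame(spike_frame = integer(), peak_frame = integer(),
                     fc_max = numeric(), fc_base = numeric(),
                     local_sd = numeric(), amplitude = numeric(),
                     valid = logical(), has_baseline = logical())
    return(structure(list(spks_filtered = numeric(T_), events = ev,
                          global_sd = gsd), class = "filtered_train"))
  }
  # peak search, all events at once: argmax of fc over [f, f+9] clipped
  win <- outer(frames, 0:9, `+`)
  win[win > T_] <- T_
  vals <- matrix(fc[win], nrow = n)
  m <- win[cbind(seq_len(n), max.col(vals, ties.method = "first"))]
  # fc_max: mean of up to three samples around m via cumulative sums
  cs <- c(0, cumsum(fc))
  lo <- pmax.int(1L, m - 1L); hi <- pmin.int(T_, m + 1L)
  fc_max <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  # local linear baseline on the 11 samples [f-30, f-20] in closed form;
  # x = 1..11, so Sx = 66, Sxx = 506, centered Sxx = 110
  has_bl <- frames >= 31L
  fc_base <- local_sd <- rep(NA_real_, n)
  if (any(has_bl)) {
    wts <- 11:1                       # filter() convolution: newest first
    sxy_all <- stats::filter(fc, wts, method = "convolution", sides = 1)
    cs2 <- c(0, cumsum(fc^2))
    t20 <- frames[has_bl] - 20L       # window end position
    sy <- cs[t20 + 1L] - cs[t20 - 10L]
    syy <- cs2[t20 + 1L] - cs2[t20 - 10L]
    sxy <- as.numeric(sxy_all[t20])
    slope <- (sxy - 66 * sy / 11) / 110
    inter <- sy / 11 - slope * 6      # x-bar = 6
    fc_base[has_bl] <- inter + slope * 11
    sse <- pmax(0, (syy - sy^2 / 11) - slope^2 * 110)
    local_sd[has_bl] <- sqrt(sse / 11)
  }
  med <- stats::median(fc)
  amp <- ifelse(has_bl, fc_max - fc_base, fc_max - med)
  thr <- ifelse(has_bl,
                if (rule == "both") pmax(local_sd, gsd)
                else pmin(local_sd, gsd),
                gsd)
  valid <- is.finite(amp) & amp > thr
  out <- numeric(T_)
  out[frames[valid]] <- spks[frames[valid]]
  ev <- data.frame(spike_frame = frames, peak_frame = m, fc_max = fc_max,
                   fc_base = fc_base, local_sd = local_sd,
                   amplitude = amp, valid = valid,
                   has_baseline = has_bl)
  structure(list(spks_filtered = out, events = ev, global_sd = gsd),
            class = "filtered_train")
}

#' Per-cell activity metrics from a filtered train
#'
#' Mean activity is the mean of the noise-filtered deconvolved train over
#' all frames; event frequency counts valid events per second; mean
#' amplitude averages the fluorescence amplitudes of valid events (NA when
#' there are none).
#'
#' @param train a \code{filtered_train}.
#' @param duration_s trace duration in seconds.
#' @return list(mean_activity, event_freq_hz, mean_amplitude).
#' @export
activity_metrics <- function(train, duration_s) {
  stopifnot(inherits(train, "filtered_train"), duration_s > 0)
  valid <- train$events[train$events$valid, , drop = FALSE]
  list(mean_activity = mean(train$spks_filtered),
       event_freq_hz = nrow(valid) / duration_s,
       mean_amplitude = if (nrow(valid)) mean(valid$amplitude) else NA_real_)
}
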