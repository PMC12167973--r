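# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use different primitives (lm(), approx-style
# scalar loops) than the package code they check.

# --- naive event-filter oracle -------------------------------------------
# Scalar reimplementation of the validity rule: for every spks>0 frame,
# find the Fc max in the next 9 frames, average three samples around it,
# fit lm() on the -30..-20 window, compare amplitude to the noise SDs.
oracle_filter <- function(fc, spks, rule = "both") {
  med <- median(fc)
  band <- sort(c(0.5 * med, 1.5 * med))
  sub <- fc[fc >= band[1] & fc <= band[2]]
  gsd <- if (length(sub) < 2) 0 else sqrt(mean((sub - mean(sub))^2))
  frames <- which(spks > 0)
  valid <- logical(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    win <- f:min(length(fc), f + 9)
    m <- win[which.max(fc[win])]
    nb <- max(1, m - 1):min(length(fc), m + 1)
    fc_max <- mean(fc[nb])
    if (f >= 31) {
      d <- data.frame(x = 1:11, y = fc[(f - 30):(f - 20)])
      fit <- lm(y ~ x, data = d)
      fc_base <- predict(fit, data.frame(x = 11))
      lsd <- sqrt(mean(residuals(fit)^2))
      amp <- fc_max - fc_base
      thr <- if (rule == "both") max(lsd, gsd) else min(lsd, gsd)
    } else {
      amp <- fc_max - med
      thr <- gsd
    }
    valid[k] <- amp > thr
  }
  list(frames = frames, valid = valid)
}

# --- naive peak-base oracle ----------------------------------------------
# Prominence by explicit flank scans; crossings by scanning every segment
# between the base and the peak for the first sign change, interpolated.
oracle_peak_base <- function(y, p, rel_height = 0.93) {
  n <- length(y)
  left <- if (p > 1) rev(seq_len(p - 1)) else integer()
  stop_l <- 0
  for (i in left) if (y[i] > y[p]) { stop_l <- i; break }
  lseg <- (stop_l + 1):p
  lmin_idx <- lseg[which.min(y[lseg])]
  right <- if (p < n) (p + 1):n else integer()
  stop_r <- n + 1
  for (i in right) if (y[i] > y[p]) { stop_r <- i; break }
  rseg <- p:(stop_r - 1)
  rmin_idx <- rseg[which.min(y[rseg])]
  prom <- y[p] - max(y[lmin_idx], y[rmin_idx])
  wh <- y[p] - rel_height * prom
  li <- lmin_idx
  for (i in p:lmin_idx) if (y[i] <= wh) { li <- i; break }
  left_ip <- if (y[li] < wh && li < p)
    li + (wh - y[li]) / (y[li + 1] - y[li]) else li
  ri <- rmin_idx
  for (i in p:rmin_idx) if (y[i] <= wh) { ri <- i; break }
  right_ip <- if (y[ri] < wh && ri > p)
    ri - (wh - y[ri]) / (y[ri - 1] - y[ri]) else ri
  list(left_ip = left_ip, right_ip = right_ip, prominence = prom,
       start_bin = max(1L, as.integer(floor(left_ip))),
       end_bin = min(n, as.integer(ceiling(right_ip))))
}

# --- shared null-calibration run -----------------------------------------
# Both shuffle tests are calibrated on the same 500 spatially untuned
# active cells; the expensive filtering pass is shared and memoised so the
# two calibration tests reuse one computation.
.null_calib <- new.env(parent = emptyenv())
get_null_calibration <- function() {
  if (!is.null(.null_calib$res)) return(.null_calib$res)
  beh <- gen_behavior(behavior_config(), seed = 201)
  bn <- spatial_binning(80, 800)
  gpass <- lpass <- 0L
  for (batch in 1:5) {
    cells <- lapply(1:100, function(i)
      ground_truth_cell(i, "active_nonplace", baseline_rate_hz = 0.5))
    ses <- gen_session(beh, cells, noise_config(render_images = FALSE),
                       seed = 210 + batch)
    for (i in 1:100) {
      ft <- filter_train(ses$fc[i, ], ses$spks[i, ])
      g <- global_si_test(ft$spks_filtered, beh, bn, n_shuffle = 500,
                          seed = batch * 1000 + i)
      if (isTRUE(g$pass)) gpass <- gpass + 1L
      # forced candidate region in mid-track for the untuned null
      l <- local_si_test(ft$spks_filtered, beh, bn, 35, 45,
                         n_shuffle = 500, seed = batch * 2000 + i)
      if (isTRUE(l$pass)) lpass <- lpass + 1L
    }
  }
  .null_calib$res <- list(n = 500L, gpass = gpass, lpass = lpass)
  .null_calib$res
}

# --- fixture builders -----------------------------------------------------
# short, fast behavior trace shared by unit tests
quick_behavior <- function(n_laps = 10, seed = 1, ...) {
  gen_behavior(behavior_config(n_laps = n_laps, ...), seed = seed)
}

# place cells with enforced field separation (the well-separated regime:
# >= ~120 cm apart, narrow fields, low out-of-field rate)
separated_place_cell <- function(id, k, track_length = 800,
                                 peak_rate = 2) {
  seg <- track_length / k
  centers <- (seq_len(k) - 0.5) * seg + runif(k, -0.1, 0.1) * seg
  centers <- pmin(pmax(centers, 45), track_length - 45)
  ground_truth_cell(id, "place", centers,
                    runif(k, 15, 18), rep(peak_rate, k),
                    baseline_rate_hz = 0.1)
}
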