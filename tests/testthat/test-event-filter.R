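test_that("global noise SD follows the median-band definition", {
  expect_equal(global_noise_sd(c(1, 1, 1, 1)), 0)
  # median 2, band [1, 3] keeps all three: population SD sqrt(2/3)
  expect_equal(global_noise_sd(c(1, 2, 3)), sqrt(2 / 3))
  # median 0 collapses the band to [0, 0]; only exact zeros remain
  expect_equal(global_noise_sd(c(-5, -1, 0, 0, 1, 5)), 0)
  expect_error(global_noise_sd(numeric()), "empty")
})

test_that("the fluorescence peak search window and averaging are exact", {
  fc <- rep(2, 40)
  pk <- event_peak(fc, 10)
  expect_equal(pk$peak_frame, 10)        # plateau: first index wins
  expect_equal(pk$fc_max, 2)
  fc <- numeric(40); fc[14:16] <- c(4, 6, 4)
  pk <- event_peak(fc, 11)               # window frames 11..20
  expect_equal(pk$peak_frame, 15)
  expect_equal(pk$fc_max, 14 / 3)
  # spike at the last frame: one-frame window, clipped neighbors
  fc <- c(numeric(39), 7)
  pk <- event_peak(fc, 40)
  expect_equal(pk$peak_frame, 40)
  expect_equal(pk$fc_max, mean(c(0, 7)))
})

test_that("the local linear baseline is exact on noiseless inputs", {
  fc <- 2 * (1:100)
  bl <- local_baseline(fc, 60)
  expect_equal(bl$fc_base, 2 * 40)       # fitted value at frame 60 - 20
  expect_equal(bl$local_sd, 0)
  bl <- local_baseline(rep(5, 100), 60)
  expect_equal(bl$fc_base, 5)
  expect_equal(bl$local_sd, 0)
  expect_false(local_baseline(fc, 30)$has_baseline)
  expect_true(local_baseline(fc, 31)$has_baseline)
})

test_that("local noise SD tracks the generating noise level", {
  set.seed(31)
  sds <- replicate(400, {
    fc <- rnorm(80, 100, 3)
    local_baseline(fc, 65)$local_sd
  })
  expect_lt(abs(mean(sds) - 3) / 3, 0.15)
})

test_that("events at the noise threshold are rejected (strict >)", {
  # constant trace: amplitude 0 equals both SDs (0); must be rejected
  fc <- rep(10, 100)
  spks <- numeric(100); spks[50] <- 1
  ft <- filter_train(fc, spks)
  expect_false(ft$events$valid)
  expect_true(all(ft$spks_filtered == 0))
  # any positive amplitude over a zero noise floor passes
  fc[52] <- 10.5
  ft <- filter_train(fc, spks)
  expect_true(ft$events$valid)
  expect_equal(ft$spks_filtered[50], 1)
})

test_that("large fluorescence-backed events pass, trace-free ones fail", {
  set.seed(32)
  T_ <- 4000
  fc <- 100 + rnorm(T_, 0, 1)
  kern <- 50 * exp(-(0:80) / 21)
  true_f <- seq(200, 3800, by = 180)
  for (f in true_f) fc[f:(f + 80)] <- fc[f:(f + 80)] + kern
  false_f <- true_f + 90                  # far from any transient
  spks <- numeric(T_)
  spks[true_f] <- 50
  spks[false_f] <- 0.1
  ft <- filter_train(fc, spks)
  ev <- ft$events
  expect_true(all(ev$valid[ev$spike_frame %in% true_f]))
  expect_false(any(ev$valid[ev$spike_frame %in% false_f]))
})

test_that("empty and invalid spike trains are handled", {
  ft <- filter_train(rep(1, 50), numeric(50))
  expect_equal(nrow(ft$events), 0)
  expect_true(all(ft$spks_filtered == 0))
  expect_error(filter_train(rep(1, 50), c(-1, numeric(49))),
               "non-negative")
  expect_error(filter_train(rep(1, 50), numeric(49)), "lengths")
})

test_that("filtering is idempotent", {
  beh <- quick_behavior(n_laps = 4, seed = 33)
  ses <- gen_session(beh, sample_cells(4, p_silent = 0, seed = 34),
                     noise_config(render_images = FALSE), seed = 35)
  for (i in 1:4) {
    ft1 <- filter_train(ses$fc[i, ], ses$spks[i, ])
    ft2 <- filter_train(ses$fc[i, ], ft1$spks_filtered)
    expect_identical(ft2$spks_filtered, ft1$spks_filtered)
    expect_true(all(ft2$events$valid))
  }
})

test_that("raising the noise threshold never adds valid events", {
  beh <- quick_behavior(n_laps = 4, seed = 36)
  ses <- gen_session(beh, sample_cells(3, p_silent = 0, seed = 37),
                     noise_config(render_images = FALSE), seed = 38)
  for (i in 1:3) {
    ft <- filter_train(ses$fc[i, ], ses$spks[i, ])
    ev <- ft$events
    thr <- pmax(ifelse(ev$has_baseline, ev$local_sd, 0), ft$global_sd)
    prev <- sum(ev$valid)
    for (scale in c(1, 1.5, 2, 4)) {
      n <- sum(ev$amplitude > thr * scale)
      expect_lte(n, prev)
      prev <- n
    }
  }
})

test_that("the either-rule is at least as permissive as the both-rule", {
  beh <- quick_behavior(n_laps = 4, seed = 39)
  ses <- gen_session(beh, sample_cells(3, p_silent = 0, seed = 40),
                     noise_config(render_images = FALSE), seed = 41)
  for (i in 1:3) {
    both <- filter_train(ses$fc[i, ], ses$spks[i, ], rule = "both")
    either <- filter_train(ses$fc[i, ], ses$spks[i, ], rule = "either")
    expect_true(all(both$events$valid <= either$events$valid))
  }
})

test_that("activity metrics are plain arithmetic over the filtered train", {
  ft <- structure(list(
    spks_filtered = c(0, 1, 0, 2),
    events = data.frame(spike_frame = c(2, 4), peak_frame = c(2, 4),
                        fc_max = c(5, 6), fc_base = c(1, 1),
                        local_sd = c(0.1, 0.1), amplitude = c(4, 5),
                        valid = c(TRUE, TRUE),
                        has_baseline = c(TRUE, TRUE)),
    global_sd = 0.2), class = "filtered_train")
  m <- activity_metrics(ft, duration_s = 4)
  expect_equal(m$mean_activity, 0.75)
  expect_equal(m$event_freq_hz, 0.5)
  expect_equal(m$mean_amplitude, 4.5)
  ft$events <- ft$events[0, ]
  ft$spks_filtered <- numeric(4)
  m <- activity_metrics(ft, 60)
  expect_equal(m$mean_activity, 0)
  expect_equal(m$event_freq_hz, 0)
  expect_true(is.na(m$mean_amplitude))
})
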