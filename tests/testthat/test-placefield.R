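# deterministic behavior where each lap visits every bin once at a fixed
# speed: convenient for exact tuning-curve arithmetic
grid_behavior <- function(n_laps, n_bins = 80, track = 800, speed = 35) {
  pos <- rep((seq_len(n_bins) - 0.5) * track / n_bins, n_laps)
  out <- data.frame(time_s = seq_along(pos) / 30, position_cm = pos,
                    speed_cm_s = speed, lap = rep(seq_len(n_laps),
                                                  each = n_bins),
                    lick = FALSE)
  attr(out, "frame_rate_hz") <- 30
  attr(out, "track_length_cm") <- track
  class(out) <- c("behavior_trace", "data.frame")
  out
}

mk_curve <- function(lambda, occupancy = NULL, counts = NULL) {
  n <- length(lambda)
  if (is.null(counts)) counts <- rep(100L, n)
  if (is.null(occupancy)) occupancy <- counts / sum(counts)
  structure(list(lambda = lambda, occupancy = occupancy, counts = counts,
                 lap_subset = "all", binning = spatial_binning(n, n * 10)),
            class = "tuning_curve")
}

test_that("slow (lap, bin) cells are excluded, with a strict cutoff", {
  beh <- grid_behavior(3)
  bn <- spatial_binning(80, 800)
  expect_true(all(valid_sample_mask(beh, bn)))
  beh$speed_cm_s[beh$lap == 2 & beh$position_cm > 60 &
                   beh$position_cm < 70] <- 0   # lap 2 stalls in bin 7
  vm <- valid_sample_mask(beh, bn)
  bad <- beh$lap == 2 & findInterval(beh$position_cm,
                                     bn$bin_edges_cm) == 7
  expect_true(all(!vm[bad]))
  expect_true(all(vm[!bad]))
  beh$speed_cm_s[bad] <- 4                      # exactly at cutoff: kept
  expect_true(all(valid_sample_mask(beh, bn)))
})

test_that("tuning curves are occupancy-normalized bin means", {
  beh <- grid_behavior(4)
  bn <- spatial_binning(80, 800)
  tc0 <- tuning_curve(numeric(nrow(beh)), beh, bn)
  expect_true(all(tc0$lambda == 0))
  tc1 <- tuning_curve(rep(1, nrow(beh)), beh, bn)
  expect_true(all(tc1$lambda == 1))
  expect_equal(sum(tc1$occupancy), 1)
  expect_error(tuning_curve(rep(1, nrow(beh)), beh, bn,
                            valid = rep(FALSE, nrow(beh))), "no valid")
})

test_that("the tuning peak lands in the true field's bin", {
  beh <- quick_behavior(n_laps = 40, seed = 50)
  cell <- ground_truth_cell(1, "place", 400, 20, 2, 0.1)
  ses <- gen_session(beh, list(cell),
                     noise_config(render_images = FALSE), seed = 51)
  ft <- filter_train(ses$fc[1, ], ses$spks[1, ])
  tc <- tuning_curve(ft$spks_filtered, beh, spatial_binning(80, 800))
  expect_true(abs(which.max(tc$lambda) - 40.5) <= 1.5)
})

test_that("the odd-even gate computes Pearson r with clear failures", {
  a <- mk_curve(c(1, 2, 3, 4))
  expect_equal(odd_even_gate(a, a)$r, 1)
  expect_true(odd_even_gate(a, a)$pass)
  g <- odd_even_gate(mk_curve(c(1, 0, 1, 0)), mk_curve(c(0, 1, 0, 1)))
  expect_equal(g$r, -1)
  expect_false(g$pass)
  g <- odd_even_gate(mk_curve(rep(2, 4)), a)
  expect_false(g$pass)
  expect_equal(g$reason, "degenerate")
})

test_that("spatial information matches closed forms", {
  expect_equal(spatial_information(mk_curve(rep(3, 8))), 0)
  # one active bin among 4 with equal occupancy: log2(4) bits/event
  expect_equal(spatial_information(mk_curve(c(5, 0, 0, 0))), 2,
               tolerance = 1e-12)
  # p = (.5, .5), lambda = (2, 0): SI = 1
  expect_equal(spatial_information(mk_curve(c(2, 0))), 1,
               tolerance = 1e-12)
  # invariant to rescaling all rates
  y <- c(0.2, 3, 1, 0, 5, 2, 0.7, 0)
  expect_equal(spatial_information(mk_curve(y)),
               spatial_information(mk_curve(7.3 * y)), tolerance = 1e-12)
  expect_true(is.na(spatial_information(mk_curve(rep(0, 5)))))
})

test_that("a shift-invariant train cannot pass the global SI test", {
  beh <- grid_behavior(6)
  g <- global_si_test(rep(1, nrow(beh)), beh, spatial_binning(80, 800),
                      n_shuffle = 120, seed = 52)
  expect_equal(g$si, 0)
  expect_false(g$pass)
  expect_error(global_si_test(rep(1, nrow(beh)), beh,
                              spatial_binning(80, 800), n_shuffle = 50),
               "at least 100")
})

test_that("global SI test is deterministic under a fixed seed", {
  beh <- quick_behavior(n_laps = 8, seed = 53)
  ses <- gen_session(beh, list(ground_truth_cell(1, "place", 300, 20, 2,
                                                 0.2)),
                     noise_config(render_images = FALSE), seed = 54)
  ft <- filter_train(ses$fc[1, ], ses$spks[1, ])
  bn <- spatial_binning(80, 800)
  g1 <- global_si_test(ft$spks_filtered, beh, bn, 200, seed = 55)
  g2 <- global_si_test(ft$spks_filtered, beh, bn, 200, seed = 55)
  expect_identical(g1, g2)
})

test_that("peak detection applies an inclusive height threshold", {
  expect_equal(find_peaks_curve(c(0, 7, 0)), 2)
  expect_length(find_peaks_curve(c(0, 5, 0)), 0)
  expect_equal(find_peaks_curve(c(0, 6, 0)), 2)       # height 6 included
  expect_equal(find_peaks_curve(c(0, 8, 8, 8, 0)), 2) # plateau: leftmost
  expect_length(find_peaks_curve(c(9, 0, 0)), 0)      # edges excluded
})

test_that("shallow-valley neighbors are pruned toward the larger peak", {
  y <- c(0, 10, 6, 7, 0)          # valley 6 > 5 = half of 10: drop the 7
  expect_equal(prune_adjacent(y, c(2, 4)), 2)
  y <- c(0, 10, 4, 7, 0)          # valley 4 <= 5: both stay
  expect_equal(prune_adjacent(y, c(2, 4)), c(2, 4))
  expect_equal(prune_adjacent(c(0, 9, 0), 2), 2)
  y <- c(0, 8, 7, 8, 0)           # equal heights: the right peak goes
  expect_equal(prune_adjacent(y, c(2, 4)), 2)
})

test_that("the triangular curve yields the hand-worked base", {
  # bins 1..3 here correspond to 0-based bins 0..2: base (0, 2)
  b <- peak_base(c(0, 10, 0), 2, rel_height = 0.93)
  expect_equal(b$prominence, 10)
  expect_equal(b$eval_height, 0.7)
  expect_equal(b$left_ip, 1.07, tolerance = 1e-12)
  expect_equal(b$right_ip, 2.93, tolerance = 1e-12)
  expect_equal(b$start_bin, 1L)
  expect_equal(b$end_bin, 3L)
})

test_that("peak bases are symmetric and scale-invariant", {
  y <- c(0, 1, 3, 8, 10, 8, 3, 1, 0)
  b <- peak_base(y, 5)
  expect_equal(b$left_ip - 1, 9 - b$right_ip, tolerance = 1e-9)
  b2 <- peak_base(y * 13.7, 5)
  expect_equal(b$start_bin, b2$start_bin)
  expect_equal(b$end_bin, b2$end_bin)
  expect_equal(b$left_ip, b2$left_ip, tolerance = 1e-9)
})

test_that("peak bases always contain their peak", {
  set.seed(56)
  for (k in 1:50) {
    y <- abs(cumsum(rnorm(60)))
    for (p in find_peaks_curve(y, height = 0)) {
      b <- peak_base(y, p)
      expect_true(b$start_bin <= p && p <= b$end_bin)
    }
  }
})

test_that("overlapping and adjacent bases merge; merging is idempotent", {
  y <- c(rep(1, 10))
  f <- data.frame(peak_bin = c(4, 6), start_bin = c(3, 5),
                  end_bin = c(5, 8))
  m <- merge_bases(f, y)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start_bin, m$end_bin), c(3, 8))
  f <- data.frame(peak_bin = c(4, 7), start_bin = c(3, 6),
                  end_bin = c(5, 8))
  m <- merge_bases(f, y)                        # adjacent: end+1 == start
  expect_equal(c(m$start_bin, m$end_bin), c(3, 8))
  f <- data.frame(peak_bin = c(4, 8), start_bin = c(3, 7),
                  end_bin = c(5, 9))
  m <- merge_bases(f, y)
  expect_equal(nrow(m), 2)
  expect_identical(merge_bases(m, y), m)
  # merged peak is the argmax within the union
  y2 <- c(0, 0, 1, 2, 9, 3, 1, 0, 0, 0)
  f <- data.frame(peak_bin = c(4, 6), start_bin = c(3, 5),
                  end_bin = c(5, 7))
  expect_equal(merge_bases(f, y2)$peak_bin, 5)
})

test_that("a constant train in the candidate region fails the local test", {
  beh <- grid_behavior(8)
  l <- local_si_test(rep(1, nrow(beh)), beh, spatial_binning(80, 800),
                     35, 45, n_shuffle = 120, seed = 57)
  expect_false(l$pass)
})

test_that("lap coverage applies the inclusive 30 percent rule", {
  beh <- grid_behavior(50)
  bn <- spatial_binning(80, 800)
  put_events <- function(n_laps_hit) {
    spks <- numeric(nrow(beh))
    hit <- beh$lap <= n_laps_hit &
      beh$position_cm > 400 & beh$position_cm < 410
    spks[hit] <- 1
    spks
  }
  cv <- lap_coverage(put_events(15), beh, bn, 41, 41)
  expect_equal(cv$frac, 0.30)
  expect_true(cv$pass)
  cv <- lap_coverage(put_events(14), beh, bn, 41, 41)
  expect_equal(cv$frac, 0.28)
  expect_false(cv$pass)
  cv <- lap_coverage(put_events(50), beh, bn, 41, 41)
  expect_equal(cv$frac, 1)
})

test_that("the classification cascade composes its gates", {
  beh <- quick_behavior(n_laps = 30, seed = 58)
  bn <- spatial_binning(80, 800)
  cfg <- pipeline_config(n_shuffle_global = 200, n_shuffle_local = 200)
  cl <- classify_cell(numeric(nrow(beh)), beh, bn, cfg, seed = 59)
  expect_equal(cl$label, "silent")
  # a weak field passes the SI tests but never reaches peak height 6
  cells <- list(ground_truth_cell(1, "place", 400, 20, 0.7, 0.05))
  ses <- gen_session(beh, cells,
                     noise_config(event_amp = 80, render_images = FALSE),
                     seed = 60)
  ft <- filter_train(ses$fc[1, ], ses$spks[1, ])
  tc <- tuning_curve(ft$spks_filtered, beh, bn)
  expect_lt(max(tc$lambda, na.rm = TRUE), 6)
  cl <- classify_cell(ft$spks_filtered, beh, bn, cfg, seed = 61)
  expect_equal(cl$label, "putative_place")
  expect_equal(nrow(cl$fields), 0)
})
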