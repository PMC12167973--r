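test_that("an all-silent population produces no activity and flat fc", {
  beh <- quick_behavior(n_laps = 2, seed = 4)
  cells <- lapply(1:3, function(i) ground_truth_cell(i, "silent"))
  ses <- gen_session(beh, cells,
                     noise_config(fc_noise_sd = 0, render_images = FALSE),
                     seed = 5)
  expect_true(all(ses$spks == 0))
  expect_true(all(ses$fc == 100))
  expect_null(ses$suite2p_masks)  # images not rendered
})

test_that("place-cell events concentrate in the true field", {
  beh <- quick_behavior(n_laps = 40, seed = 6)
  cell <- ground_truth_cell(1, "place", 425, 20, 2, 0)
  ses <- gen_session(beh, list(cell),
                     noise_config(render_images = FALSE), seed = 7)
  ev_pos <- beh$position_cm[ses$spks_true[1, ] > 0]
  h <- hist(ev_pos, breaks = seq(0, 800, by = 50), plot = FALSE)
  expect_equal(which.max(h$counts), 9)   # the bin containing 425 cm
  expect_true(all(abs(ev_pos - 425) < 200))
})

test_that("session generation is bit-reproducible under a fixed seed", {
  beh <- quick_behavior(n_laps = 2, seed = 8)
  cells <- sample_cells(5, seed = 1)
  s1 <- gen_session(beh, cells, noise_config(frame_dim = c(96L, 96L)),
                    seed = 9)
  s2 <- gen_session(beh, cells, noise_config(frame_dim = c(96L, 96L)),
                    seed = 9)
  expect_identical(s1, s2)
})

test_that("constant-rate event counts are Poisson (mean/variance ratio)", {
  beh <- quick_behavior(n_laps = 40, seed = 10, pause_p = 0)
  cell <- ground_truth_cell(1, "active_nonplace", baseline_rate_hz = 2)
  ses <- gen_session(beh, list(cell),
                     noise_config(false_event_rate_hz = 0,
                                  render_images = FALSE), seed = 11)
  ev <- ses$spks_true[1, ] > 0
  # 1,000 disjoint windows of a constant-rate train are iid Poisson counts
  nwin <- 1000L
  wlen <- floor(length(ev) / nwin)
  counts <- colSums(matrix(ev[seq_len(nwin * wlen)], nrow = wlen))
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.1)
})

test_that("activity-based masks exist only for cells with true events", {
  beh <- quick_behavior(n_laps = 3, seed = 12)
  cells <- sample_cells(20, p_silent = 0.5, seed = 13)
  ses <- gen_session(beh, cells, noise_config(frame_dim = c(256L, 256L)),
                     seed = 14)
  active <- rownames(ses$spks_true)[rowSums(ses$spks_true > 0) > 0]
  expect_setequal(names(ses$suite2p_masks), active)
  expect_length(ses$cellpose_masks, 20)
})

test_that("sampled populations hit the requested silent fraction", {
  cells <- sample_cells(2000, p_silent = 0.5, seed = 15)
  frac <- mean(vapply(cells, `[[`, "", "class") == "silent")
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("a frozen Markov chain keeps the day-1 silent set", {
  cfg <- cohort_config(n_cells_per_fov = 200, unsilencing_rate = 0,
                       silencing_rate = 0, seed = 16)
  ds <- simulate_day_states(200, cfg, seed = 17)
  for (d in 2:6)
    expect_identical(ds$states[, d], ds$states[, 1])
})

test_that("the persistent subpopulation never unsilences", {
  cfg <- cohort_config(n_cells_per_fov = 400, unsilencing_rate = 1,
                       persistent_silent_frac = 0.1, seed = 18)
  ds <- simulate_day_states(400, cfg, seed = 19)
  s1 <- ds$states[, 1] == "silent"
  always <- rowSums(ds$states == "silent") == 6
  expect_gte(sum(always), 0.1 * sum(s1) - 1)
  expect_true(all(ds$states[ds$persistent, ] == "silent"))
})

test_that("a noise-free movie frame is proportional to the source mask", {
  beh <- quick_behavior(n_laps = 2, seed = 20)
  cell <- ground_truth_cell(1, "active_nonplace", baseline_rate_hz = 1)
  ses <- gen_session(beh, list(cell),
                     noise_config(frame_dim = c(64L, 64L), fc_noise_sd = 0,
                                  false_event_rate_hz = 0), seed = 21)
  mov <- render_movie(ses, "1", pixel_noise_sd = 0, seed = 22)
  f <- which(ses$spks_true[1, ] > 0)[1]
  frame <- mov$frames[, , f]
  m <- ses$cellpose_masks[["1"]]
  inmask <- frame[cbind(m[, 1] - mov$box[1] + 1, m[, 2] - mov$box[3] + 1)]
  expect_true(all(inmask > 0))
  expect_true(all(abs(inmask - inmask[1]) < 1e-9))  # uniform over the mask
  expect_equal(sum(abs(frame)), sum(abs(inmask)))  # zero off-mask
  expect_error(render_movie(ses, character()), "at least one")
})

test_that("a zero-activity session renders to pure pixel noise", {
  beh <- quick_behavior(n_laps = 2, seed = 23)
  ses <- gen_session(beh, list(ground_truth_cell(1, "silent")),
                     noise_config(frame_dim = c(64L, 64L), fc_noise_sd = 0),
                     seed = 24)
  mov <- render_movie(ses, "1", pixel_noise_sd = 0.5, seed = 25)
  expect_lt(abs(mean(mov$frames)), 0.01)
  expect_lt(abs(sd(mov$frames) - 0.5), 0.02)
})
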