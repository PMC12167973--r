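sq_mask <- function(r0, c0, h, w)
  as.matrix(expand.grid(row = r0:(r0 + h - 1), col = c0:(c0 + w - 1)))

test_that("ROI matching applies the 75 percent overlap rule", {
  dim_ <- c(64L, 64L)
  a <- list(A = sq_mask(10, 10, 10, 10))          # 100 px
  # identical mask: overlap fraction 1 -> matched
  m <- match_roi_sets(a, list(S = sq_mask(10, 10, 10, 10)), dim_)
  expect_equal(m$pairs$activity_id, "S")
  expect_equal(m$pairs$overlap_frac, 1)
  # 70 of 100 px shared -> below threshold -> silent candidate
  m <- match_roi_sets(a, list(S = sq_mask(10, 10, 7, 10)), dim_)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$unmatched, "A")
  # two candidates at 0.8 and 0.9: the larger overlap wins
  m <- match_roi_sets(a, list(S1 = sq_mask(12, 10, 8, 10),
                              S2 = sq_mask(11, 10, 9, 10)), dim_)
  expect_equal(m$pairs$activity_id, "S2")
  expect_equal(m$pairs$overlap_frac, 0.9)
  expect_error(match_roi_sets(list(A = a$A, A = a$A), a["A"], dim_),
               "duplicate")
})

test_that("ROI matching is invariant to input order", {
  dim_ <- c(64L, 64L)
  a <- list(A = sq_mask(5, 5, 8, 8), B = sq_mask(30, 30, 8, 8),
            C = sq_mask(50, 50, 6, 6))
  s <- list(X = sq_mask(5, 5, 8, 8), Y = sq_mask(30, 31, 8, 8))
  m1 <- match_roi_sets(a, s, dim_)
  m2 <- match_roi_sets(rev(a), rev(s), dim_)
  o1 <- m1$pairs[order(m1$pairs$anatomy_id), ]
  o2 <- m2$pairs[order(m2$pairs$anatomy_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_setequal(m1$unmatched, m2$unmatched)
})

test_that("cells without an activity ROI are classified silent", {
  beh <- quick_behavior(n_laps = 3, seed = 70)
  cells <- list(ground_truth_cell(1, "silent"),
                ground_truth_cell(2, "active_nonplace",
                                  baseline_rate_hz = 1))
  ses <- gen_session(beh, cells, noise_config(frame_dim = c(96L, 96L)),
                     seed = 71)
  st <- classify_silent(ses)
  expect_equal(unname(st["1"]), "silent")
  expect_equal(unname(st["2"]), "active")
})

test_that("rigid registration recovers exact integer shifts", {
  set.seed(72)
  a <- matrix(rnorm(64 * 64), 64, 64)
  roll <- function(m, dy, dx)
    m[(seq_len(nrow(m)) - 1 - dy) %% nrow(m) + 1,
      (seq_len(ncol(m)) - 1 - dx) %% ncol(m) + 1]
  expect_equal(register_days(a, a), c(dy = 0L, dx = 0L))
  expect_equal(register_days(a, roll(a, 3, -2)), c(dy = 3L, dx = -2L))
  expect_error(register_days(matrix(1, 8, 8), matrix(1, 8, 8)), "flat")
})

test_that("registration tolerates 10 percent noise", {
  set.seed(73)
  a <- matrix(rnorm(64 * 64), 64, 64)
  roll <- function(m, dy, dx)
    m[(seq_len(nrow(m)) - 1 - dy) %% nrow(m) + 1,
      (seq_len(ncol(m)) - 1 - dx) %% ncol(m) + 1]
  hits <- 0L
  for (k in 1:100) {
    dy <- sample(-10:10, 1); dx <- sample(-10:10, 1)
    b <- roll(a, dy, dx) + matrix(rnorm(64 * 64, 0, 0.1), 64, 64)
    if (identical(register_days(a, b), c(dy = as.integer(dy),
                                         dx = as.integer(dx))))
      hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("identical daily ROI sets yield one full track per cell", {
  dim_ <- c(64L, 64L)
  day <- list(A = sq_mask(5, 5, 8, 8), B = sq_mask(30, 30, 8, 8))
  tracks <- link_tracks(rep(list(day), 6), matrix(0L, 6, 2), dim_)
  expect_equal(length(unique(tracks$track_id)), 2)
  expect_equal(nrow(tracks), 12)
  # every track keeps its identity
  for (t in unique(tracks$track_id))
    expect_length(unique(tracks$roi_id[tracks$track_id == t]), 1)
})

test_that("a cell missing on one day drops out of the track set", {
  dim_ <- c(64L, 64L)
  day <- list(A = sq_mask(5, 5, 8, 8), B = sq_mask(30, 30, 8, 8))
  days <- rep(list(day), 6)
  days[[3]] <- day["B"]
  tracks <- link_tracks(days, matrix(0L, 6, 2), dim_)
  expect_equal(unique(tracks$roi_id), "B")
  expect_equal(nrow(tracks), 6)
})

test_that("linking compensates known rigid shifts", {
  dim_ <- c(96L, 96L)
  base <- list(A = sq_mask(10, 10, 8, 8), B = sq_mask(40, 20, 8, 8),
               C = sq_mask(70, 60, 8, 8))
  shifts <- rbind(c(0L, 0L), c(5L, -3L), c(-2L, 6L))
  days <- lapply(1:3, function(d)
    lapply(base, function(m)
      cbind(m[, 1] + shifts[d, 1], m[, 2] + shifts[d, 2])))
  tracks <- link_tracks(days, shifts, dim_)
  expect_equal(length(unique(tracks$track_id)), 3)
  for (t in unique(tracks$track_id))
    expect_length(unique(tracks$roi_id[tracks$track_id == t]), 1)
})

test_that("persistently silent counts are cumulative and non-increasing", {
  st <- rbind(rep("silent", 4),
              c("silent", "active", "silent", "silent"),
              c("active", "silent", "silent", "silent"))
  ps <- persistent_silence(st)
  expect_equal(ps$counts, c(2L, 1L, 1L, 1L))
  expect_equal(ps$normalized, c(1, 0.5, 0.5, 0.5))
  set.seed(74)
  for (k in 1:20) {
    st <- matrix(sample(c("silent", "active"), 60, replace = TRUE), 10, 6)
    expect_true(all(diff(persistent_silence(st)$counts) <= 0))
  }
})

test_that("footprints correlate with their mask and resist rescaling", {
  # hand-built movie: 20x20 patch, event frames 31..35 show the mask
  roi <- sq_mask(6, 6, 5, 5)
  frames <- array(0, dim = c(20, 20, 60))
  maskimg <- matrix(0, 20, 20); maskimg[roi] <- 1
  for (t in 31:35) frames[, , t] <- maskimg * 10
  mov <- list(frames = frames, box = c(1L, 20L, 1L, 20L))
  fp <- footprint_validate(mov, roi)
  expect_equal(nrow(fp), 1)
  expect_gt(fp$r, 0.99)
  expect_true(fp$accepted)
  # affine intensity rescaling leaves the correlation unchanged
  mov2 <- list(frames = frames * 3.7 + 11, box = mov$box)
  fp2 <- footprint_validate(mov2, roi, trace = apply(frames, 3, mean))
  expect_equal(fp2$r, fp$r, tolerance = 1e-9)
  # anti-correlated footprint (complement of the mask) is rejected
  framesC <- array(0, dim = c(20, 20, 60))
  for (t in 31:35) framesC[, , t] <- (1 - maskimg) * 10
  movC <- list(frames = framesC, box = mov$box)
  fpC <- footprint_validate(movC, roi, trace = apply(frames, 3, mean))
  expect_lt(fpC$r, 0)
  expect_false(fpC$accepted)
})

test_that("overlapping ROIs with disjoint events are attributed correctly", {
  beh <- quick_behavior(n_laps = 3, seed = 75)
  T_ <- nrow(beh)
  fc <- matrix(100, 2, T_)
  kern <- 60 * exp(-(0:60) / 21)
  ev1 <- c(300, 900, 1500); ev2 <- c(600, 1200, 1800)
  for (f in ev1) fc[1, f:(f + 60)] <- fc[1, f:(f + 60)] + kern
  for (f in ev2) fc[2, f:(f + 60)] <- fc[2, f:(f + 60)] + kern
  rownames(fc) <- c("1", "2")
  masks <- list(`1` = sq_mask(10, 10, 8, 8), `2` = sq_mask(14, 14, 8, 8))
  ses <- structure(list(behavior = beh, fc = fc, spks = fc * 0,
                        cellpose_masks = masks, suite2p_masks = masks,
                        mean_image = matrix(0, 40, 40),
                        truth = NULL, noise_cfg = noise_config(
                          frame_dim = c(40L, 40L))),
                   class = "session_data")
  mov <- render_movie(ses, c("1", "2"), pixel_noise_sd = 0.2, seed = 76)
  fp1 <- footprint_validate(mov, masks[["1"]],
                            trace = fc[1, ] - median(fc[1, ]))
  fp2 <- footprint_validate(mov, masks[["2"]],
                            trace = fc[2, ] - median(fc[2, ]))
  expect_gte(nrow(fp1), 3)
  expect_true(all(fp1$r > 0.5))
  expect_true(all(fp2$r > 0.5))
  # cross-attribution: cell 1's events against cell 2's mask must fail
  fpx <- footprint_validate(mov, masks[["2"]],
                            trace = fc[1, ] - median(fc[1, ]))
  expect_true(all(fpx$r < 0.5))
})
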