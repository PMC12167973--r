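#!/usr/bin/env Rscript
# Population statistics over the tracked cohort: per-day state fractions,
# and a bootstrap effect-size CI comparing the mean activity (over active
# sessions) of high-persistence cells (active on >= 4 of 6 days) against
# low-persistence cells (active 1-3 days). The simulated Markov chain is
# homogeneous -- persistence is independent of activity level -- so the
# expected difference is zero and the CI should straddle 0; the point of
# the script is the statistical machinery, not an effect. Requires
# analysis/01_simulate_cohort.R and analysis/03_track_days.R.
#   Rscript analysis/05_population_stats.R

library(ca1drift)

root <- file.path("results", "cohort")
tracks <- read.csv(file.path("results", "tracks.csv"))
n_days <- max(tracks$day)
states <- matrix(tracks$state[order(tracks$track_id, tracks$day)],
                 ncol = n_days, byrow = TRUE)

# mean activity per track per day, from the noise-filtered trains
day1 <- read_session_dir(file.path(root, "day1"))
fps <- attr(day1$behavior, "frame_rate_hz")
mean_act <- matrix(NA_real_, nrow(states), n_days)
for (d in seq_len(n_days)) {
  ses <- read_session_dir(file.path(root, sprintf("day%d", d)))
  dur <- nrow(ses$behavior) / fps
  ids <- tracks$roi_id[tracks$day == d][order(tracks$track_id[
    tracks$day == d])]
  for (t in seq_len(nrow(states))) {
    i <- match(ids[t], rownames(ses$spks))
    ft <- filter_train(ses$fc[i, ], ses$spks[i, ])
    mean_act[t, d] <- activity_metrics(ft, dur)$mean_activity
  }
}

n_active_days <- rowSums(states == "active")
act_mean <- vapply(seq_len(nrow(states)), function(t)
  mean(mean_act[t, states[t, ] == "active"]), 0)  # active sessions only
grp_a <- act_mean[n_active_days >= 4]
grp_b <- act_mean[n_active_days >= 1 & n_active_days <= 3]

ci <- bootstrap_diff_ci(grp_a, grp_b, statistic = "mean",
                        n_resamples = 5000, seed = 505)
gt <- group_tests(list(high_persistence = grp_a,
                       low_persistence = grp_b))

message(sprintf(
  "mean activity, high-persistence (n=%d) vs low-persistence (n=%d):",
  length(grp_a), length(grp_b)))
message(sprintf("  difference %.3f, 95%% bootstrap CI [%.3f, %.3f]",
                ci$observed, ci$ci_low, ci$ci_high))
message(sprintf("  KS p = %.3g, Mann-Whitney p = %.3g",
                gt$ks$p, gt$mwu$p))

out <- list(n_high_persistence = length(grp_a),
            n_low_persistence = length(grp_b),
            mean_activity_diff = ci$observed,
            ci_low = ci$ci_low, ci_high = ci$ci_high,
            ks_p = gt$ks$p, mwu_p = gt$mwu$p,
            silent_frac_per_day = colMeans(states == "silent"))
jsonlite::write_json(out, file.path("results", "population_stats.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/population_stats.json")
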