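#!/usr/bin/env Rscript
# Simulate a six-day imaging cohort with known ground truth and export it
# as plain-text session directories under results/cohort/day<k>/.
#
# One animal, 60 cells, 30 laps per day in the 8-m virtual corridor at
# 30 Hz. About half the cells are silent on day 1; silent/active states
# evolve day-to-day by the Markov unsilencing/silencing model and place
# fields drift. Run from the repository root:
#   Rscript analysis/01_simulate_cohort.R

library(ca1drift)

seed <- 20260922L
out <- file.path("results", "cohort")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cc <- cohort_config(n_animals = 1L, n_cells_per_fov = 60L, n_days = 6L,
                    p_silent = 0.5, unsilencing_rate = 0.54,
                    silencing_rate = 0.54, persistent_silent_frac = 0.1,
                    drift_sd_cm = 20, max_shift_px = 6L, seed = seed)
co <- gen_cohort(cc, behavior_config(n_laps = 30),
                 noise_config(frame_dim = c(256L, 256L)))
an <- co$animals[[1]]

for (d in seq_along(an$days))
  write_session_dir(an$days[[d]], file.path(out, sprintf("day%d", d)))

truth <- data.frame(cell_id = seq_len(cc$n_cells_per_fov),
                    base_class = vapply(an$cells, `[[`, "", "class"),
                    persistent = an$persistent)
write.csv(truth, file.path(out, "truth_cells.csv"), row.names = FALSE)
write.csv(data.frame(day = seq_len(cc$n_days),
                     dy = an$shifts[, 1], dx = an$shifts[, 2]),
          file.path(out, "truth_shifts.csv"), row.names = FALSE)
write.csv(as.data.frame(an$states), file.path(out, "truth_states.csv"),
          row.names = FALSE)

message(sprintf("wrote %d days of %d cells to %s", cc$n_days,
                cc$n_cells_per_fov, out))
message(sprintf("day-1 silent fraction (truth): %.2f",
                mean(an$states[, 1] == "silent")))
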