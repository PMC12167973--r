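#' Multi-day cohort configuration
#'
#' Parameters of the multi-day population model: on day 1 roughly half the
#' cells are silent; thereafter each cell's silent/active state evolves as a
#' two-state Markov chain (silent-to-active with the unsilencing rate,
#' active-to-silent with the silencing rate), except for a designated
#' persistently silent subpopulation that never unsilences. Place-field
#' centers jitter from day to day (representational drift) and the field of
#' view is repositioned by a small rigid integer shift each day.
#'
#' @param n_animals number of animals (independent fields of view).
#' @param n_cells_per_fov cells per field of view. Default 100.
#' @param n_days imaging days. Default 6.
#' @param p_silent probability a cell is silent on day 1. Default 0.5.
#' @param unsilencing_rate per-day silent-to-active probability. Default
#'   0.54, the mean rate measured over consecutive session pairs.
#' @param silencing_rate per-day active-to-silent probability. Default
#'   0.54, which keeps the silent fraction stationary at \code{p_silent}.
#' @param drift_sd_cm SD of the day-to-day field-center random walk.
#'   Default 20.
#' @param persistent_silent_frac fraction of day-1 silent cells that never
#'   unsilence regardless of the chain. Default 0.
#' @param p_place probability an active cell is a place cell. Default 0.5.
#' @param max_shift_px bound on the per-day rigid FOV shift. Default 8.
#' @param seed integer seed.
#' @return an object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_animals = 1L, n_cells_per_fov = 100L,
                          n_days = 6L, p_silent = 0.5,
                          unsilencing_rate = 0.54, silencing_rate = 0.54,
                          drift_sd_cm = 20, persistent_silent_frac = 0,
                          p_place = 0.5, max_shift_px = 8L, seed = NULL) {
  for (p in c(p_silent, unsilencing_rate, silencing_rate,
              persistent_silent_frac, p_place))
    if (p < 0 || p > 1) fail("probabilities must lie in [0, 1]")
  if (n_days < 1) fail("n_days must be at least 1")
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate per-day silent/active states
#'
#' Day 1 states are Bernoulli(p_silent); later days follow the Markov
#' chain, with the persistent subpopulation (a random fraction of the day-1
#' silent cells) pinned to silent.
#'
#' @param n_cells number of cells.
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer seed.
#' @return list with \code{states} (n_cells x n_days character matrix of
#'   "silent"/"active") and \code{persistent} (logical vector).
#' @export
simulate_day_states <- function(n_cells, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed_(seed, {
    st <- matrix("", n_cells, config$n_days)
    st[, 1] <- ifelse(stats::runif(n_cells) < config$p_silent,
                      "silent", "active")
    s1 <- which(st[, 1] == "silent")
    n_pers <- round(config$persistent_silent_frac * length(s1))
    persistent <- rep(FALSE, n_cells)
    if (n_pers > 0L)
      persistent[sample(s1, n_pers)] <- TRUE
    if (config$n_days > 1L) {
      for (d in 2:config$n_days) {
        u <- stats::runif(n_cells)
        prev <- st[, d - 1]
        st[, d] <- ifelse(prev == "silent",
                          ifelse(!persistent & u < config$unsilencing_rate,
                                 "active", "silent"),
                          ifelse(u < config$silencing_rate,
                                 "silent", "active"))
      }
    }
    list(states = st, persistent = persistent)
  })
}

## drifted copy of a cell for one day, or a silent stand-in
day_cell <- function(cell, state, drift, track_length) {
  if (state == "silent") return(ground_truth_cell(cell$cell_id, "silent"))
  if (cell$class != "place" || cell$n_fields == 0L) {
    out <- cell
    if (out$class == "silent")  # silent base identity active today: untuned
      out <- ground_truth_cell(cell$cell_id, "active_nonplace",
                               baseline_rate_hz = 0.3)
    return(out)
  }
  out <- cell
  out$field_centers_cm <- pmin(pmax(cell$field_centers_cm + drift, 10),
                               track_length - 10)
  out
}

#' Generate a multi-day cohort
#'
#' Draws day states from the Markov model, drifts place-field centers by a
#' Gaussian random walk, repositions the field of view by a rigid integer
#' shift each day, and (optionally) renders each day into a full
#' \code{session_data} via \code{\link{gen_session}}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param behavior_cfg a \code{\link{behavior_config}} reused each day.
#' @param noise_cfg a \code{\link{noise_config}}.
#' @param render_sessions logical; when FALSE only ground truth (states,
#'   per-day cell parameters, shifts) is produced, which is cheap enough
#'   for very large cohorts. Default TRUE.
#' @return object of class \code{cohort_data}: list of \code{animals}, each
#'   with \code{states}, \code{persistent}, \code{shifts} (n_days x 2,
#'   day-1 row zero), \code{cells} (base identities), \code{days} (per-day
#'   \code{session_data}, or per-day truth cell lists when not rendered),
#'   plus the \code{config}.
#' @export
gen_cohort <- function(config = cohort_config(),
                       behavior_cfg = behavior_config(),
                       noise_cfg = noise_config(),
                       render_sessions = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- if (is.null(config$seed)) 1L else config$seed
  animals <- vector("list", config$n_animals)
  for (a in seq_len(config$n_animals)) {
    aseed <- derive_seed(seed, paste0("animal", a))
    cells <- sample_cells(config$n_cells_per_fov,
                          behavior_cfg$track_length_cm,
                          p_silent = config$p_silent,
                          p_place = config$p_place,
                          seed = derive_seed(aseed, "cells"))
    ds <- simulate_day_states(config$n_cells_per_fov, config,
                              seed = derive_seed(aseed, "states"))
    shifts <- matrix(0L, config$n_days, 2)
    drift <- matrix(0, config$n_cells_per_fov, 1)
    days <- vector("list", config$n_days)
    centers <- NULL
    dr <- with_seed_(derive_seed(aseed, "drift"), {
      # cumulative field-center random walk, one offset per cell per day
      apply(matrix(stats::rnorm(config$n_cells_per_fov * config$n_days, 0,
                                config$drift_sd_cm),
                   config$n_cells_per_fov), 1, cumsum)
    })  # n_days x n_cells; day 1 included (small initial jitter)
    dr[1, ] <- 0
    shifts[-1, ] <- with_seed_(derive_seed(aseed, "shifts"),
                               matrix(sample(seq(-config$max_shift_px,
                                                 config$max_shift_px),
                                             2 * (config$n_days - 1),
                                             replace = TRUE),
                                      ncol = 2))
    if (render_sessions && isTRUE(noise_cfg$render_images)) {
      centers <- with_seed_(derive_seed(aseed, "centers"),
                            sample_centers(config$n_cells_per_fov,
                                           noise_cfg$frame_dim,
                                           noise_cfg$roi_radius_px,
                                           margin = noise_cfg$roi_radius_px +
                                             config$max_shift_px + 1))
    }
    for (d in seq_len(config$n_days)) {
      dcells <- lapply(seq_along(cells), function(i)
        day_cell(cells[[i]], ds$states[i, d], dr[d, i],
                 behavior_cfg$track_length_cm))
      if (render_sessions) {
        beh <- gen_behavior(behavior_cfg,
                            seed = derive_seed(aseed, paste0("beh", d)))
        days[[d]] <- gen_session(beh, dcells, noise_cfg,
                                 seed = derive_seed(aseed, paste0("ses", d)),
                                 centers = if (is.null(centers)) NULL else
                                   sweep(centers, 2, -shifts[d, ]))
      } else {
        days[[d]] <- dcells
      }
    }
    animals[[a]] <- list(states = ds$states, persistent = ds$persistent,
                         shifts = shifts, cells = cells, days = days)
  }
  structure(list(animals = animals, config = config,
                 rendered = render_sessions), class = "cohort_data")
}
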