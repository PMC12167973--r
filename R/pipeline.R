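#' Pipeline configuration
#'
#' Collects every stage's tunable parameters with the analysis defaults:
#' 4 cm/s speed cutoff, 0.25 odd-even correlation gate, 1,500 shuffles with
#' 99th/95th percentile criteria for the global/local SI tests, peak height
#' 6 (deconvolved-activity units), relative prominence height 0.93, 30
#' percent lap coverage, 75 percent ROI-overlap matching, 0.5 footprint
#' correlation (Gaussian sigma 2 frames, median + 2 SD event detection),
#' and 5,000 bootstrap resamples. The object round-trips losslessly through
#' JSON via \code{\link{write_config}} / \code{\link{read_config}}.
#'
#' @param speed_cutoff_cm_s spatial-analysis speed cutoff.
#' @param odd_even_r_min reliability gate threshold.
#' @param n_shuffle_global,global_probs global SI test shuffles/percentile.
#' @param peak_height tuning-curve peak height threshold.
#' @param rel_height relative prominence descent for base delineation.
#' @param extend_frac local-SI region extension per side (base widths).
#' @param n_shuffle_local,local_probs local SI test shuffles/percentile.
#' @param coverage_min_frac minimum lap-coverage fraction.
#' @param n_bins spatial bins.
#' @param overlap_min ROI-matching overlap fraction.
#' @param footprint_r_min,footprint_sigma,footprint_thr_sd footprint
#'   validation parameters.
#' @param bootstrap_n bootstrap resamples.
#' @param filter_rule event-filter noise rule ("both"/"either").
#' @param seed master seed fanned out to stages via
#'   \code{\link{derive_seed}}.
#' @return object of class \code{pipeline_config} (a named list).
#' @export
pipeline_config <- function(speed_cutoff_cm_s = 4, odd_even_r_min = 0.25,
                            n_shuffle_global = 1500L, global_probs = 0.99,
                            peak_height = 6, rel_height = 0.93,
                            extend_frac = 0.5, n_shuffle_local = 1500L,
                            local_probs = 0.95, coverage_min_frac = 0.30,
                            n_bins = 80L, overlap_min = 0.75,
                            footprint_r_min = 0.5, footprint_sigma = 2,
                            footprint_thr_sd = 2, bootstrap_n = 5000L,
                            filter_rule = "both", seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a \code{pipeline_config}.
#' @param path file path.
#' @return \code{read_config} returns the restored \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the per-session pipeline
#'
#' Noise-filters every cell's deconvolved train against its fluorescence
#' trace, classifies each cell (silent / active non-place / putative place
#' / place), computes activity metrics, and, when ROI masks are present,
#' adds the anatomy-vs-activity ROI silent call.
#'
#' @param session a \code{session_data}.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{classification} (one row per cell) and
#'   \code{fields} (one row per candidate field), both data.frames, plus
#'   \code{binning}.
#' @export
run_session <- function(session, config = pipeline_config()) {
  stopifnot(inherits(session, "session_data"),
            inherits(config, "pipeline_config"))
  beh <- session$behavior
  binning <- spatial_binning(config$n_bins, attr(beh, "track_length_cm"))
  fps <- attr(beh, "frame_rate_hz")
  dur <- nrow(beh) / fps
  ids <- rownames(session$spks)
  roi_state <- if (!is.null(session$cellpose_masks))
    classify_silent(session)
  else NULL
  cls_rows <- vector("list", length(ids))
  fld_rows <- vector("list", length(ids))
  bin_w <- binning$track_length_cm / binning$n_bins
  for (i in seq_along(ids)) {
    ft <- filter_train(session$fc[i, ], session$spks[i, ],
                       rule = config$filter_rule)
    met <- activity_metrics(ft, dur)
    cl <- classify_cell(ft$spks_filtered, beh, binning, config,
                        seed = derive_seed(config$seed,
                                           paste0("cell", ids[i])))
    nf <- sum(cl$fields$significant)
    cls_rows[[i]] <- data.frame(
      cell_id = ids[i], label = cl$label, odd_even_r = cl$odd_even_r,
      global_si = cl$global_si, global_si_p = cl$global_si_p,
      n_fields = nf, n_candidate_fields = nrow(cl$fields),
      mean_activity = met$mean_activity,
      event_freq_hz = met$event_freq_hz,
      mean_amplitude = met$mean_amplitude,
      roi_state = if (is.null(roi_state)) NA_character_
      else unname(roi_state[ids[i]]))
    if (nrow(cl$fields))
      fld_rows[[i]] <- cbind(cell_id = ids[i], cl$fields,
                             start_cm = (cl$fields$start_bin - 1L) * bin_w,
                             end_cm = cl$fields$end_bin * bin_w)
  }
  list(classification = do.call(rbind, cls_rows),
       fields = do.call(rbind, fld_rows),
       binning = binning)
}

#' Run the multi-day cohort pipeline
#'
#' Registers consecutive mean images (rigid integer translation), links
#' anatomy ROIs into day-complete cell tracks, assigns per-day
#' silent/active states from the ROI matching, and summarizes the cohort:
#' per-day state fractions, persistently silent counts, the mean
#' unsilencing rate over consecutive day pairs, and the theoretical
#' memoryless decay it predicts.
#'
#' @param cohort a rendered \code{cohort_data} (one animal per entry).
#' @param config a \code{\link{pipeline_config}}.
#' @param classify logical; also run the per-session classification
#'   cascade for every day (slower). Default FALSE.
#' @return object of class \code{cohort_summary}.
#' @export
run_cohort <- function(cohort, config = pipeline_config(),
                       classify = FALSE) {
  stopifnot(inherits(cohort, "cohort_data"), isTRUE(cohort$rendered))
  per_animal <- lapply(seq_along(cohort$animals), function(a) {
    an <- cohort$animals[[a]]
    days <- an$days
    n_days <- length(days)
    for (d in seq_len(n_days))
      if (is.null(days[[d]]$mean_image))
        fail("day ", d, " is missing a mean image")
    shifts <- matrix(0L, n_days, 2)
    for (d in seq_len(n_days - 1L) + 1L)
      shifts[d, ] <- register_days(days[[1]]$mean_image,
                                   days[[d]]$mean_image)
    tracks <- link_tracks(lapply(days, `[[`, "cellpose_masks"), shifts,
                          days[[1]]$noise_cfg$frame_dim,
                          config$overlap_min)
    if (nrow(tracks) == 0L) fail("no day-complete tracks")
    n_tr <- max(tracks$track_id)
    states <- matrix("", n_tr, n_days)
    for (d in seq_len(n_days)) {
      st <- classify_silent(days[[d]])
      rid <- tracks$roi_id[tracks$day == d]
      states[, d] <- unname(st[rid])
    }
    cls <- if (classify)
      lapply(days, run_session, config = config)
    else NULL
    list(shifts = shifts, tracks = tracks, states = states,
         sessions = cls)
  })
  states_all <- do.call(rbind, lapply(per_animal, `[[`, "states"))
  n_days <- ncol(states_all)
  ur <- unsilencing_rate(states_all)
  ps <- persistent_silence(states_all)
  fr <- lapply(seq_len(n_days), function(d)
    session_fractions(states_all, d))
  structure(list(per_animal = per_animal,
                 n_tracks = nrow(states_all),
                 silent_frac = vapply(fr, `[[`, 0, "silent_frac"),
                 active_frac = vapply(fr, `[[`, 0, "active_frac"),
                 persistently_silent = ps,
                 u = ur$u, u_pooled = ur$pooled,
                 theoretical_curve = theoretical_decay(ur$u, n_days)),
            class = "cohort_summary")
}
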