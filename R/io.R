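#' Write a session to a directory of plain-text files
#'
#' One directory per day: \code{behavior.csv} (time_s, position_cm,
#' speed_cm_s, lap, lick), \code{fc.csv} and \code{spks.csv} (one row per
#' cell, first column cell_id), \code{masks_cellpose.csv} /
#' \code{masks_suite2p.csv} (roi_id, row, col), \code{mean_image.csv},
#' \code{truth.json}, \code{meta.json}.
#'
#' @param session a \code{session_data}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_session_dir <- function(session, dir) {
  stopifnot(inherits(session, "session_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  beh <- session$behavior
  utils::write.csv(as.data.frame(beh), file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  wmat <- function(m, f)
    utils::write.csv(data.frame(cell_id = rownames(m), m,
                                check.names = FALSE),
                     file.path(dir, f), row.names = FALSE)
  wmat(session$fc, "fc.csv")
  wmat(session$spks, "spks.csv")
  wmask <- function(masks, f) {
    if (is.null(masks)) return(invisible())
    df <- do.call(rbind, lapply(names(masks), function(id)
      data.frame(roi_id = id, row = masks[[id]][, 1],
                 col = masks[[id]][, 2])))
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  }
  wmask(session$cellpose_masks, "masks_cellpose.csv")
  wmask(session$suite2p_masks, "masks_suite2p.csv")
  if (!is.null(session$mean_image))
    utils::write.table(session$mean_image,
                       file.path(dir, "mean_image.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(lapply(session$truth, unclass),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(
    list(frame_rate_hz = attr(beh, "frame_rate_hz"),
         track_length_cm = attr(beh, "track_length_cm"),
         frame_dim = session$noise_cfg$frame_dim),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session directory written by \code{\link{write_session_dir}}
#'
#' @param dir directory path.
#' @return a \code{session_data} (without \code{spks_true}).
#' @export
read_session_dir <- function(dir) {
  need <- file.path(dir, c("behavior.csv", "fc.csv", "spks.csv",
                           "meta.json"))
  for (f in need) if (!file.exists(f)) fail("missing input file: ", f)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  beh <- utils::read.csv(file.path(dir, "behavior.csv"))
  attr(beh, "frame_rate_hz") <- meta$frame_rate_hz
  attr(beh, "track_length_cm") <- meta$track_length_cm
  class(beh) <- c("behavior_trace", "data.frame")
  rmat <- function(f) {
    df <- utils::read.csv(file.path(dir, f), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    dimnames(m)[[2]] <- NULL
    m
  }
  rmask <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    df <- utils::read.csv(p)
    lapply(split(df, as.character(df$roi_id)), function(g)
      cbind(g$row, g$col))
  }
  mi <- if (file.exists(file.path(dir, "mean_image.csv")))
    as.matrix(utils::read.table(file.path(dir, "mean_image.csv"),
                                sep = ","))
  else NULL
  if (!is.null(mi)) dimnames(mi) <- NULL
  truth <- if (file.exists(file.path(dir, "truth.json")))
    lapply(jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE, simplifyDataFrame =
                                 FALSE),
           function(x) {
             x$field_centers_cm <- as.numeric(unlist(x$field_centers_cm))
             x$field_widths_cm <- as.numeric(unlist(x$field_widths_cm))
             x$field_peak_rate_hz <-
               as.numeric(unlist(x$field_peak_rate_hz))
             structure(x, class = "gt_cell")
           })
  else NULL
  ncfg <- noise_config(frame_dim = if (!is.null(meta$frame_dim))
    as.integer(meta$frame_dim) else c(512L, 505L))
  structure(list(behavior = beh, fc = rmat("fc.csv"),
                 spks = rmat("spks.csv"), spks_true = NULL,
                 cellpose_masks = rmask("masks_cellpose.csv"),
                 suite2p_masks = rmask("masks_suite2p.csv"),
                 mean_image = mi, truth = truth, noise_cfg = ncfg),
            class = "session_data")
}

#' Export per-cell event tables
#'
#' Writes one CSV per cell (spike_frame, peak_frame, fc_max, fc_base,
#' local_sd, amplitude, valid) as produced by \code{\link{filter_train}}.
#'
#' @param trains named list of \code{filtered_train}.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_event_tables <- function(trains, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(trains), function(id) {
    p <- file.path(dir, paste0("events_", id, ".csv"))
    utils::write.csv(trains[[id]]$events, p, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}
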