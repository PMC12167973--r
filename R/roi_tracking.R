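## pairwise pixel-overlap counts between two named lists of pixel matrices;
## returns data.frame(a, b, n_overlap) for pairs sharing at least one pixel
overlap_counts <- function(masks_a, masks_b, dim) {
  if (length(masks_a) == 0L || length(masks_b) == 0L)
    return(data.frame(a = character(), b = character(),
                      n_overlap = integer()))
  lin <- function(m) (m[, 2] - 1L) * dim[1] + m[, 1]
  da <- data.frame(px = unlist(lapply(masks_a, lin)),
                   a = rep(names(masks_a),
                           vapply(masks_a, nrow, 0L)))
  db <- data.frame(px = unlist(lapply(masks_b, lin)),
                   b = rep(names(masks_b),
                           vapply(masks_b, nrow, 0L)))
  mm <- merge(da, db, by = "px")
  if (nrow(mm) == 0L)
    return(data.frame(a = character(), b = character(),
                      n_overlap = integer()))
  agg <- stats::aggregate(list(n_overlap = rep(1L, nrow(mm))),
                          by = list(a = mm$a, b = mm$b), FUN = sum)
  agg
}

#' Match anatomy-based to activity-based ROI sets
#'
#' An anatomy ROI and an activity ROI are considered the same cell if their
#' pixel overlap exceeds 75 percent of the anatomy mask size (strictly).
#' Each anatomy ROI pairs with at most one activity ROI: the largest
#' overlap wins, ties broken by the lower activity roi id. Anatomy ROIs
#' with no accepted partner are returned as silent-cell candidates.
#'
#' @param anatomy,activity named lists of pixel matrices (n x 2, row/col)
#'   on the same grid; names are roi ids and must be unique.
#' @param dim grid dimensions c(rows, cols).
#' @param overlap_min overlap fraction threshold. Default 0.75.
#' @return list with \code{pairs} (data.frame: anatomy_id, activity_id,
#'   overlap_frac) and \code{unmatched} (character anatomy ids).
#' @export
match_roi_sets <- function(anatomy, activity, dim, overlap_min = 0.75) {
  if (anyDuplicated(names(anatomy)) || anyDuplicated(names(activity)))
    fail("duplicate roi ids")
  ov <- overlap_counts(anatomy, activity, dim)
  sizes <- vapply(anatomy, nrow, 0L)
  pairs <- data.frame(anatomy_id = character(), activity_id = character(),
                      overlap_frac = numeric())
  for (aid in names(anatomy)) {
    cand <- ov[ov$a == aid, , drop = FALSE]
    if (nrow(cand) == 0L) next
    frac <- cand$n_overlap / sizes[[aid]]
    ord <- order(-frac, cand$b)          # largest overlap, then lower id
    best <- ord[1L]
    if (frac[best] > overlap_min)
      pairs <- rbind(pairs, data.frame(anatomy_id = aid,
                                       activity_id = cand$b[best],
                                       overlap_frac = frac[best]))
  }
  list(pairs = pairs,
       unmatched = setdiff(names(anatomy), pairs$anatomy_id))
}

#' Classify cells of a session as silent or active
#'
#' Anatomy ROIs with no matched activity ROI are silent: an
#' activity-correlation segmenter cannot find cells that never fire. The
#' stricter composite rule additionally marks matched cells silent when
#' their noise-filtered train carries no valid event.
#'
#' @param session a \code{session_data}.
#' @param rule "unmatched" (default) or "strict".
#' @param valid_event_counts named per-cell counts of valid events (needed
#'   for \code{rule = "strict"}).
#' @return named character vector ("silent"/"active") over anatomy ROIs,
#'   plus attribute \code{match} with the ROI matching.
#' @export
classify_silent <- function(session, rule = c("unmatched", "strict"),
                            valid_event_counts = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(session, "session_data"))
  mt <- match_roi_sets(session$cellpose_masks, session$suite2p_masks,
                       session$noise_cfg$frame_dim)
  state <- stats::setNames(rep("active", length(session$cellpose_masks)),
                           names(session$cellpose_masks))
  state[mt$unmatched] <- "silent"
  if (rule == "strict") {
    if (is.null(valid_event_counts))
      fail("strict rule needs valid_event_counts")
    zero <- names(valid_event_counts)[valid_event_counts == 0]
    state[intersect(names(state), zero)] <- "silent"
  }
  attr(state, "match") <- mt
  state
}

#' Rigid translation between two mean images
#'
#' Integer-pixel translation maximizing the circular cross-correlation of
#' the mean-subtracted images (FFT-based). Returns (dy, dx) such that image
#' b matches image a shifted down by dy and right by dx.
#'
#' @param img_a,img_b numeric matrices of identical dimensions.
#' @return integer vector c(dy, dx).
#' @export
register_days <- function(img_a, img_b) {
  stopifnot(all(dim(img_a) == dim(img_b)))
  if (stats::sd(img_a) == 0 || stats::sd(img_b) == 0)
    fail("registration undefined for a flat image")
  a <- img_a - mean(img_a); b <- img_b - mean(img_b)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  idx <- which.max(cc)
  dy <- (idx - 1L) %% nrow(a)
  dx <- (idx - 1L) %/% nrow(a)
  if (dy > nrow(a) / 2) dy <- dy - nrow(a)
  if (dx > ncol(a) / 2) dx <- dx - ncol(a)
  c(dy = as.integer(dy), dx = as.integer(dx))
}

#' Link anatomy ROIs across days into cell tracks
#'
#' Consecutive-day anatomy ROI sets are compared after compensating the
#' rigid day shifts; two ROIs link when their overlap exceeds the same
#' threshold used within-day (fraction of the earlier day's mask,
#' strictly), greedily by descending overlap so links are one-to-one.
#' Only chains present on every day become tracks.
#'
#' @param daily_masks list (one per day) of named lists of pixel matrices.
#' @param shifts n_days x 2 integer matrix of rigid shifts relative to day
#'   1 (day-1 row zero).
#' @param dim grid dimensions.
#' @param overlap_min threshold. Default 0.75.
#' @return data.frame (track_id, day, roi_id), complete tracks only.
#' @export
link_tracks <- function(daily_masks, shifts, dim, overlap_min = 0.75) {
  n_days <- length(daily_masks)
  stopifnot(n_days >= 1L, nrow(shifts) == n_days)
  # chains start as day-1 ROIs
  chains <- lapply(names(daily_masks[[1L]]), function(id) id)
  for (d in seq_len(n_days - 1L)) {
    rel <- shifts[d + 1L, ] - shifts[d, ]
    nxt <- lapply(daily_masks[[d + 1L]], function(m)
      cbind(m[, 1] - rel[1], m[, 2] - rel[2]))
    ov <- overlap_counts(daily_masks[[d]], nxt, dim)
    sizes <- vapply(daily_masks[[d]], nrow, 0L)
    if (nrow(ov)) {
      ov$frac <- ov$n_overlap / sizes[ov$a]
      ov <- ov[ov$frac > overlap_min, , drop = FALSE]
      ov <- ov[order(-ov$frac, ov$a, ov$b), , drop = FALSE]
    }
    link <- character(0)
    used_b <- character(0)
    for (k in seq_len(nrow(ov))) {
      if (!(ov$a[k] %in% names(link)) && !(ov$b[k] %in% used_b)) {
        link[ov$a[k]] <- ov$b[k]
        used_b <- c(used_b, ov$b[k])
      }
    }
    chains <- lapply(chains, function(ch) {
      if (length(ch) < d) return(ch)           # already broken
      nx <- link[ch[d]]
      if (is.na(nx)) ch else c(ch, unname(nx))
    })
  }
  keep <- vapply(chains, length, 0L) == n_days
  chains <- chains[keep]
  if (length(chains) == 0L)
    return(data.frame(track_id = integer(), day = integer(),
                      roi_id = character()))
  data.frame(track_id = rep(seq_along(chains), each = n_days),
             day = rep(seq_len(n_days), length(chains)),
             roi_id = unlist(chains))
}

#' Persistently silent cell counts
#'
#' For k = 1..n_days, the number of tracks silent on all of days 1..k;
#' non-increasing in k by construction. Also returned normalized to the
#' day-1 count.
#'
#' @param states character matrix (tracks x days) of "silent"/"active".
#' @return list(counts, normalized).
#' @export
persistent_silence <- function(states) {
  stopifnot(is.matrix(states))
  n_days <- ncol(states)
  sil <- states == "silent"
  run <- rep(TRUE, nrow(states))
  counts <- integer(n_days)
  for (k in seq_len(n_days)) {
    run <- run & sil[, k]
    counts[k] <- sum(run)
  }
  list(counts = counts,
       normalized = if (counts[1L] > 0) counts / counts[1L]
       else rep(NA_real_, n_days))
}

#' Validate calcium events by spatial footprint
#'
#' Attributes putative events to their source ROI. The ROI's raw
#' fluorescence is smoothed (Gaussian, sigma 2 frames); putative events are
#' maximal runs where the smoothed trace exceeds its median plus 2
#' population SDs. For each event the footprint is the mean movie frame
#' over the run minus the mean over an equal-length pre-event baseline,
#' restricted to the ROI's bounding box dilated by 5 px; the event is
#' accepted when the Pearson correlation between the footprint and the
#' binary mask over that box exceeds 0.5. Events with no room for a
#' baseline are skipped with a warning. The correlation is invariant to
#' affine rescaling of movie intensities.
#'
#' @param movie list(frames, box) as from \code{\link{render_movie}}.
#' @param roi pixel matrix (full-grid coordinates).
#' @param trace raw per-frame ROI fluorescence; computed as the mean of the
#'   ROI's movie pixels when NULL.
#' @param sigma Gaussian smoothing SD in frames. Default 2.
#' @param thr_sd SD multiplier for event detection. Default 2.
#' @param dilate_px bounding-box dilation. Default 5.
#' @param r_min acceptance threshold on the correlation. Default 0.5.
#' @return data.frame (event_start, event_end, r, accepted).
#' @export
footprint_validate <- function(movie, roi, trace = NULL, sigma = 2,
                               thr_sd = 2, dilate_px = 5L, r_min = 0.5) {
  frames <- movie$frames; box <- movie$box
  h <- dim(frames)[1]; w <- dim(frames)[2]; T_ <- dim(frames)[3]
  rloc <- cbind(roi[, 1] - box[1] + 1L, roi[, 2] - box[3] + 1L)
  if (any(rloc[, 1] < 1L | rloc[, 1] > h | rloc[, 2] < 1L | rloc[, 2] > w))
    fail("movie patch does not cover the ROI")
  if (is.null(trace)) {
    lin <- rloc[, 1] + (rloc[, 2] - 1L) * h
    trace <- vapply(seq_len(T_), function(t)
      mean(frames[lin + (t - 1L) * h * w]), 0)
  }
  sm <- gaussian_smooth(trace, sigma)
  thr <- stats::median(sm) + thr_sd * pop_sd(sm)
  above <- sm > thr
  if (!any(above))
    return(data.frame(event_start = integer(), event_end = integer(),
                      r = numeric(), accepted = logical()))
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L); ends <- which(d == -1L) - 1L
  bb <- c(max(1L, min(rloc[, 1]) - dilate_px),
          min(h, max(rloc[, 1]) + dilate_px),
          max(1L, min(rloc[, 2]) - dilate_px),
          min(w, max(rloc[, 2]) + dilate_px))
  maskimg <- matrix(0, bb[2] - bb[1] + 1L, bb[4] - bb[3] + 1L)
  maskimg[cbind(rloc[, 1] - bb[1] + 1L, rloc[, 2] - bb[3] + 1L)] <- 1
  out <- lapply(seq_along(starts), function(k) {
    s <- starts[k]; e <- ends[k]; len <- e - s + 1L
    if (s - len < 1L) {
      warning("event at movie start skipped: no pre-event baseline")
      return(NULL)
    }
    evm <- apply(frames[bb[1]:bb[2], bb[3]:bb[4], s:e, drop = FALSE],
                 c(1, 2), mean)
    bsm <- apply(frames[bb[1]:bb[2], bb[3]:bb[4], (s - len):(s - 1L),
                        drop = FALSE], c(1, 2), mean)
    fp <- evm - bsm
    r <- suppressWarnings(stats::cor(as.vector(fp), as.vector(maskimg)))
    data.frame(event_start = s, event_end = e, r = r,
               accepted = is.finite(r) && r > r_min)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(event_start = integer(), event_end = integer(),
                      r = numeric(), accepted = logical())
  out
}
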