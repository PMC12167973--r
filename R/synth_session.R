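#' Imaging-noise and forward-model configuration
#'
#' Parameters of the forward model that turns ground-truth event rates into
#' the data structures an upstream segmentation/deconvolution tool would
#' emit: a deconvolved activity train (\code{spks}) and a neuropil-subtracted
#' fluorescence trace (\code{fc}) per cell, plus ROI masks and a mean image.
#'
#' Deconvolved-activity units are arbitrary upstream-tool units; the default
#' event amplitude is scaled so the tuning-curve peak of a simulated place
#' cell clears the peak-detection height threshold (default 6) with margin.
#'
#' @param fluor_tau_s exponential decay time of the fluorescence kernel
#'   (s). Default 0.7, a GCaMP6s-like indicator.
#' @param event_amp mean deconvolved amplitude per event (a.u.). Default 150.
#' @param event_amp_sdlog lognormal sdlog of event amplitudes. Default 0.25.
#' @param fc_event_amp fluorescence jump per unit spks (a.u.). Default 1.
#' @param fc_noise_sd Gaussian noise SD added to fc (a.u.). Default 2.
#' @param fc_baseline fc offset (a.u.). Default 100.
#' @param false_event_rate_hz rate of spurious small-amplitude entries
#'   injected into spks with no fluorescence counterpart, exercising the
#'   event noise filter. Default 0.2.
#' @param false_event_amp amplitude of the spurious entries (a.u.).
#'   Default 1.
#' @param frame_dim imaging grid (rows, cols). Default c(512, 505).
#' @param roi_radius_px ROI disc radius in pixels. Default 6.
#' @param render_images logical; generate masks and the mean image (skip
#'   for trace-only simulations). Default TRUE.
#' @return an object of class \code{noise_config}.
#' @export
noise_config <- function(fluor_tau_s = 0.7, event_amp = 150,
                         event_amp_sdlog = 0.25, fc_event_amp = 1,
                         fc_noise_sd = 2, fc_baseline = 100,
                         false_event_rate_hz = 0.2, false_event_amp = 1,
                         frame_dim = c(512L, 505L), roi_radius_px = 6,
                         render_images = TRUE) {
  stopifnot(fluor_tau_s > 0, event_amp > 0, fc_noise_sd >= 0,
            length(frame_dim) == 2L)
  structure(as.list(environment()), class = "noise_config")
}

## circular ROI pixel set around an integer center, clipped to the grid
disc_mask <- function(center_rc, radius, dim) {
  r0 <- max(1L, floor(center_rc[1] - radius))
  r1 <- min(dim[1], ceiling(center_rc[1] + radius))
  c0 <- max(1L, floor(center_rc[2] - radius))
  c1 <- min(dim[2], ceiling(center_rc[2] + radius))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  keep <- (g$row - center_rc[1])^2 + (g$col - center_rc[2])^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

## spread n ROI centers over the grid with a minimum separation
sample_centers <- function(n, dim, radius, min_sep = 3 * radius,
                           margin = radius + 1) {
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L; tries <- 0L
  while (placed < n && tries < 200L * n) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, margin, dim[1] - margin),
              stats::runif(1, margin, dim[2] - margin))
    if (placed == 0L ||
        min((centers[seq_len(placed), 1] - cand[1])^2 +
              (centers[seq_len(placed), 2] - cand[2])^2) >= min_sep^2) {
      placed <- placed + 1L
      centers[placed, ] <- round(cand)
    }
  }
  if (placed < n) fail("could not place ", n, " non-overlapping ROIs")
  centers
}

#' Simulate one imaging session
#'
#' Events are drawn per frame from an inhomogeneous Poisson process with
#' rate = baseline + sum of Gaussian fields evaluated at the animal's
#' position. The deconvolved train carries the event amplitudes at the event
#' frames (plus configurable small-amplitude false events that have no
#' fluorescence counterpart); fc is the true event train convolved with an
#' exponential indicator kernel plus Gaussian noise. Silent cells emit no
#' true events. Anatomy-based masks exist for every cell; activity-based
#' masks only for cells with at least one true event, mirroring an
#' activity-correlation segmenter that cannot find silent cells.
#'
#' @param behavior a \code{behavior_trace}.
#' @param cells list of \code{gt_cell}.
#' @param noise_cfg a \code{\link{noise_config}}.
#' @param seed integer seed.
#' @param centers optional n x 2 matrix of ROI centers (row, col); sampled
#'   on the grid when NULL. Supplying them lets multi-day simulations keep
#'   cell positions consistent across days up to a rigid shift.
#' @return an object of class \code{session_data}: list with
#'   \code{behavior}, matrices \code{fc} and \code{spks} (cells x frames),
#'   \code{spks_true}, \code{cellpose_masks}, \code{suite2p_masks} (named
#'   lists of pixel matrices), \code{mean_image}, \code{truth},
#'   \code{noise_cfg}.
#' @export
gen_session <- function(behavior, cells, noise_cfg = noise_config(),
                        seed = NULL, centers = NULL) {
  stopifnot(inherits(behavior, "behavior_trace"),
            inherits(noise_cfg, "noise_config"))
  with_seed_(seed, {
    T_ <- nrow(behavior)
    fps <- attr(behavior, "frame_rate_hz")
    n <- length(cells)
    spks <- spks_true <- fc <- matrix(0, n, T_)
    # shared exponential kernel, truncated at 5 tau; the convolution runs
    # over an FFT grid padded to a 2-3-5-smooth length, which keeps the
    # transform fast for arbitrary trace lengths
    klen <- max(2L, ceiling(5 * noise_cfg$fluor_tau_s * fps))
    kern <- exp(-(0:(klen - 1L)) / (noise_cfg$fluor_tau_s * fps))
    L <- stats::nextn(T_ + klen - 1L, c(2, 3, 5))
    kfft <- stats::fft(c(kern, numeric(L - klen)))
    for (i in seq_len(n)) {
      cl <- cells[[i]]
      if (cl$class != "silent") {
        rate <- cell_rate(cl, behavior$position_cm)
        counts <- stats::rpois(T_, rate / fps)
        ev <- which(counts > 0L)
        if (length(ev)) {
          amps <- stats::rlnorm(length(ev),
                                log(noise_cfg$event_amp) -
                                  noise_cfg$event_amp_sdlog^2 / 2,
                                noise_cfg$event_amp_sdlog) * counts[ev]
          spks_true[i, ev] <- amps
        }
      }
      # false events: deconvolution noise with no fluorescence transient.
      # Only cells the activity-based segmenter would find (i.e. cells with
      # true events) carry a deconvolved train at all, so silent cells stay
      # identically zero.
      if (cl$class != "silent" && any(spks_true[i, ] > 0)) {
        nf <- stats::rpois(1L, noise_cfg$false_event_rate_hz * T_ / fps)
        if (nf > 0L) {
          ff <- sample.int(T_, min(nf, T_))
          ff <- ff[spks_true[i, ff] == 0]
          spks[i, ff] <- noise_cfg$false_event_amp
        }
      }
      spks[i, ] <- spks[i, ] + spks_true[i, ]
      tr <- spks_true[i, ]
      sig <- if (any(tr > 0))
        Re(stats::fft(stats::fft(c(tr, numeric(L - T_))) * kfft,
                      inverse = TRUE))[seq_len(T_)] / L
      else numeric(T_)
      fc[i, ] <- noise_cfg$fc_baseline + noise_cfg$fc_event_amp * sig +
        stats::rnorm(T_, 0, noise_cfg$fc_noise_sd)
    }
    rownames(spks) <- rownames(spks_true) <- rownames(fc) <-
      vapply(cells, function(c) as.character(c$cell_id), "")

    cellpose <- suite2p <- NULL; mean_image <- NULL
    if (isTRUE(noise_cfg$render_images)) {
      dim_ <- noise_cfg$frame_dim
      if (is.null(centers))
        centers <- sample_centers(n, dim_, noise_cfg$roi_radius_px)
      stopifnot(nrow(centers) == n)
      cellpose <- lapply(seq_len(n), function(i)
        disc_mask(centers[i, ], noise_cfg$roi_radius_px, dim_))
      names(cellpose) <- rownames(fc)
      active <- which(rowSums(spks_true > 0) > 0)
      suite2p <- lapply(active, function(i) {
        # activity mask: same soma, 1 px offset, a few boundary px dropped
        m <- disc_mask(centers[i, ] + sample(c(-1L, 0L, 1L), 2L, TRUE),
                       noise_cfg$roi_radius_px, dim_)
        m[sample.int(nrow(m), max(1L, round(0.9 * nrow(m)))), , drop = FALSE]
      })
      names(suite2p) <- rownames(fc)[active]
      mean_image <- matrix(stats::rnorm(prod(dim_), 10, 1), dim_[1], dim_[2])
      bright <- 10 + rowMeans(spks_true) / 2
      for (i in seq_len(n)) {
        m <- cellpose[[i]]
        mean_image[m] <- mean_image[m] + bright[i]
      }
    }
    structure(list(behavior = behavior, fc = fc, spks = spks,
                   spks_true = spks_true, cellpose_masks = cellpose,
                   suite2p_masks = suite2p, mean_image = mean_image,
                   truth = cells, noise_cfg = noise_cfg),
              class = "session_data")
  })
}

#' Render a movie patch from a session
#'
#' Each frame is the sum over the selected ROIs of the ROI's mask times its
#' instantaneous baseline-subtracted fluorescence, plus pixel noise.
#' Overlapping ROIs add. Used to exercise spatial-footprint validation.
#'
#' @param session a \code{session_data} with masks rendered.
#' @param roi_ids character ids of ROIs to render (anatomy masks used).
#' @param pad pixels of padding around the ROIs' joint bounding box.
#' @param pixel_noise_sd Gaussian pixel noise SD. Default 0.5.
#' @param seed integer seed.
#' @return list with \code{frames} (rows x cols x T array), \code{box}
#'   (r0, r1, c0, c1 in full-grid coordinates).
#' @export
render_movie <- function(session, roi_ids, pad = 10L, pixel_noise_sd = 0.5,
                         seed = NULL) {
  stopifnot(inherits(session, "session_data"))
  if (length(roi_ids) == 0L) fail("roi_ids must name at least one ROI")
  masks <- session$cellpose_masks[as.character(roi_ids)]
  if (any(vapply(masks, is.null, TRUE))) fail("unknown ROI id")
  with_seed_(seed, {
    px <- do.call(rbind, masks)
    box <- c(max(1L, min(px[, 1]) - pad),
             min(nrow(session$mean_image), max(px[, 1]) + pad),
             max(1L, min(px[, 2]) - pad),
             min(ncol(session$mean_image), max(px[, 2]) + pad))
    h <- box[2] - box[1] + 1L; w <- box[4] - box[3] + 1L
    T_ <- ncol(session$fc)
    frames <- array(stats::rnorm(h * w * T_, 0, pixel_noise_sd),
                    dim = c(h, w, T_))
    for (id in as.character(roi_ids)) {
      m <- masks[[id]]
      tr <- session$fc[id, ] - stats::median(session$fc[id, ])
      lin <- (m[, 1] - box[1] + 1L) + (m[, 2] - box[3]) * h
      for (t in seq_len(T_)) {
        if (tr[t] != 0)
          frames[lin + (t - 1L) * h * w] <- frames[lin + (t - 1L) * h * w] +
            tr[t]
      }
    }
    list(frames = frames, box = box)
  })
}
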