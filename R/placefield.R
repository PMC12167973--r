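#' Spatial binning of the corridor
#'
#' Half-open bins [left, right) covering [0, track_length). The bin count
#' is a free analysis parameter; the default 80 gives 10 cm bins on the
#' 800 cm corridor.
#'
#' @param n_bins number of bins. Default 80.
#' @param track_length_cm corridor length. Default 800.
#' @return object of class \code{spatial_binning} with \code{n_bins},
#'   \code{track_length_cm}, \code{bin_edges_cm}.
#' @export
spatial_binning <- function(n_bins = 80L, track_length_cm = 800) {
  stopifnot(n_bins >= 2L, track_length_cm > 0)
  structure(list(n_bins = as.integer(n_bins),
                 track_length_cm = track_length_cm,
                 bin_edges_cm = seq(0, track_length_cm,
                                    length.out = n_bins + 1L)),
            class = "spatial_binning")
}

## 1-based bin index of each position; positions at/after track end clip
## into the last bin
bin_index <- function(position_cm, binning) {
  b <- findInterval(position_cm, binning$bin_edges_cm,
                    rightmost.closed = FALSE)
  pmin.int(pmax.int(b, 1L), binning$n_bins)
}

#' Frames valid for spatial analysis
#'
#' Computes the mean running speed in every (lap, bin) cell and invalidates
#' all frames of cells whose mean speed is below the cutoff (strictly; a
#' cell at exactly the cutoff is kept). Applied before every tuning-curve
#' computation so stationary periods do not contaminate spatial tuning.
#'
#' @param behavior a \code{behavior_trace}.
#' @param binning a \code{spatial_binning}.
#' @param speed_cutoff_cm_s cutoff. Default 4.
#' @return logical per-frame vector.
#' @export
valid_sample_mask <- function(behavior, binning, speed_cutoff_cm_s = 4) {
  b <- bin_index(behavior$position_cm, binning)
  cell <- behavior$lap * (binning$n_bins + 1L) + b
  mu <- tapply(behavior$speed_cm_s, cell, mean)
  slow <- as.numeric(names(mu)[mu < speed_cutoff_cm_s])
  !(cell %in% slow)
}

#' Occupancy-normalized tuning curve
#'
#' Mean deconvolved activity per spatial bin over the valid frames of the
#' selected laps, together with the occupancy distribution (fraction of
#' valid frames per bin). Bins never visited under the selection are NA in
#' the activity vector and carry zero occupancy.
#'
#' @param spks per-frame deconvolved activity (noise-filtered).
#' @param behavior a \code{behavior_trace}.
#' @param binning a \code{spatial_binning}.
#' @param lap_subset "all", "odd" or "even" (lap 1 is odd).
#' @param valid per-frame logical from \code{\link{valid_sample_mask}};
#'   computed with defaults when NULL.
#' @return object of class \code{tuning_curve}: list with \code{lambda}
#'   (per-bin mean activity), \code{occupancy}, \code{counts} (valid frames
#'   per bin), \code{lap_subset}, \code{binning}.
#' @export
tuning_curve <- function(spks, behavior, binning,
                         lap_subset = c("all", "odd", "even"),
                         valid = NULL) {
  lap_subset <- match.arg(lap_subset)
  stopifnot(length(spks) == nrow(behavior))
  if (is.null(valid)) valid <- valid_sample_mask(behavior, binning)
  keep <- valid & switch(lap_subset,
                         all = TRUE,
                         odd = behavior$lap %% 2L == 1L,
                         even = behavior$lap %% 2L == 0L)
  if (!any(keep)) fail("no valid frames under this lap selection")
  b <- bin_index(behavior$position_cm[keep], binning)
  counts <- tabulate(b, binning$n_bins)
  sums <- numeric(binning$n_bins)
  agg <- rowsum(spks[keep], b)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  lambda <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  structure(list(lambda = lambda, occupancy = counts / sum(counts),
                 counts = counts, lap_subset = lap_subset,
                 binning = binning),
            class = "tuning_curve")
}

#' Odd-even lap reliability gate
#'
#' Pearson correlation between the odd-lap and even-lap tuning curves over
#' bins visited in both; cells below the threshold are excluded from place
#' cell analysis. A zero-variance curve makes r undefined and fails the
#' gate with reason "degenerate".
#'
#' @param curve_odd,curve_even \code{tuning_curve}s on identical binning.
#' @param r_min threshold. Default 0.25 (gate passes at r >= r_min).
#' @return list(r, pass, reason).
#' @export
odd_even_gate <- function(curve_odd, curve_even, r_min = 0.25) {
  stopifnot(curve_odd$binning$n_bins == curve_even$binning$n_bins)
  ok <- !is.na(curve_odd$lambda) & !is.na(curve_even$lambda)
  x <- curve_odd$lambda[ok]; y <- curve_even$lambda[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, pass = FALSE, reason = "degenerate"))
  r <- stats::cor(x, y)
  list(r = r, pass = r >= r_min, reason = if (r >= r_min) "" else "low_r")
}

## SI in bits/event from per-bin activity sums and frame counts
si_from_sums <- function(sums, counts) {
  tot <- sum(counts)
  if (tot == 0L) return(NA_real_)
  p <- counts / tot
  lam <- ifelse(counts > 0L, sums / pmax(counts, 1L), 0)
  lbar <- sum(p * lam)
  if (lbar <= 0) return(NA_real_)
  nz <- lam > 0
  sum(p[nz] * (lam[nz] / lbar) * log2(lam[nz] / lbar))
}

#' Spatial information of a tuning curve
#'
#' The bits-per-event information measure
#' \eqn{SI = \sum_i p_i (\lambda_i/\bar\lambda) \log_2(\lambda_i/\bar\lambda)}
#' with \eqn{\bar\lambda = \sum_i p_i \lambda_i}; zero-activity bins
#' contribute 0. Undefined (NA) for a silent cell.
#'
#' @param curve a \code{tuning_curve}.
#' @return SI in bits/event, or NA.
#' @export
spatial_information <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  si_from_sums(ifelse(is.na(curve$lambda), 0,
                      curve$lambda) * curve$counts, curve$counts)
}

#' Global spatial-information shuffle test
#'
#' The observed SI is compared against a null built by circularly rotating
#' the full deconvolved train in time by a uniform random shift in
#' {1, ..., T-1} (identity excluded), recomputing the tuning curve against
#' the unshifted behavior each time. The cell passes if its SI strictly
#' exceeds the 99th percentile (linear interpolation) of the shuffled SIs.
#'
#' @param spks noise-filtered deconvolved train.
#' @param behavior a \code{behavior_trace}.
#' @param binning a \code{spatial_binning}.
#' @param n_shuffle number of rotations. Default 1500; at least 100.
#' @param probs percentile for the pass criterion. Default 0.99.
#' @param seed integer seed.
#' @param valid optional precomputed valid-frame mask.
#' @return list(si, p, pass, crit, shuffled).
#' @export
global_si_test <- function(spks, behavior, binning, n_shuffle = 1500L,
                           probs = 0.99, seed = NULL, valid = NULL) {
  if (n_shuffle < 100L) fail("n_shuffle must be at least 100")
  stopifnot(length(spks) == nrow(behavior))
  if (is.null(valid)) valid <- valid_sample_mask(behavior, binning)
  T_ <- length(spks)
  bof <- integer(T_)                    # bin of frame; 0 = invalid
  bof[valid] <- bin_index(behavior$position_cm[valid], binning)
  counts <- tabulate(bof[bof > 0L], binning$n_bins)
  nz <- which(spks > 0)
  vz <- spks[nz]
  sums_at <- function(frames) {
    b <- bof[frames]
    keep <- b > 0L
    sums <- numeric(binning$n_bins)
    if (any(keep)) {
      agg <- rowsum(vz[keep], b[keep])
      sums[as.integer(rownames(agg))] <- agg[, 1]
    }
    sums
  }
  si_obs <- si_from_sums(sums_at(nz), counts)
  if (is.na(si_obs))
    return(list(si = NA_real_, p = NA_real_, pass = FALSE,
                crit = NA_real_, shuffled = numeric()))
  sh <- with_seed_(seed, sample.int(T_ - 1L, n_shuffle, replace = TRUE))
  si_null <- vapply(sh, function(s)
    si_from_sums(sums_at((nz - 1L + s) %% T_ + 1L), counts), 0)
  si_null[is.na(si_null)] <- 0
  crit <- pctl(si_null, probs)
  list(si = si_obs,
       p = (1 + sum(si_null >= si_obs)) / (1 + n_shuffle),
       pass = si_obs > crit, crit = crit, shuffled = si_null)
}

#' Peaks of a tuning curve
#'
#' Interior strict local maxima at or above the height threshold; a plateau
#' counts once at its leftmost sample. NA bins are treated as 0.
#'
#' @param lambda per-bin activity values.
#' @param height inclusive height threshold. Default 6.
#' @return integer vector of peak bins (1-based), possibly empty.
#' @export
find_peaks_curve <- function(lambda, height = 6) {
  y <- ifelse(is.na(lambda), 0, lambda)
  n <- length(y)
  peaks <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i                               # plateau scan
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i] && y[i] >= height)
        peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

#' Discard minor peaks separated by shallow valleys
#'
#' For each adjacent peak pair, if the minimum of the curve between them
#' exceeds half of the larger peak's height the smaller peak is discarded
#' (on equal heights the right peak is dropped). Re-evaluated left to right
#' until stable.
#'
#' @param lambda per-bin activity values.
#' @param peaks sorted peak bins from \code{\link{find_peaks_curve}}.
#' @return pruned peak bins.
#' @export
prune_adjacent <- function(lambda, peaks) {
  y <- ifelse(is.na(lambda), 0, lambda)
  repeat {
    if (length(peaks) < 2L) return(peaks)
    dropped <- FALSE
    for (k in seq_len(length(peaks) - 1L)) {
      a <- peaks[k]; b <- peaks[k + 1L]
      valley <- min(y[(a + 1L):(b - 1L)])
      if (valley > 0.5 * max(y[a], y[b])) {
        drop <- if (y[a] < y[b]) k else k + 1L   # tie: right peak goes
        peaks <- peaks[-drop]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) return(peaks)
  }
}

## prominence of a peak: height above the higher of the two flanking
## valleys, each valley searched out to the nearest strictly higher sample
## or the curve end; returns the bounding base indices too
peak_prominence <- function(y, p) {
  n <- length(y)
  i <- p; lmin <- y[p]; lbase <- p
  while (i > 1L && y[i - 1L] <= y[p]) {
    i <- i - 1L
    if (y[i] < lmin) { lmin <- y[i]; lbase <- i }
  }
  if (i == 1L && y[1L] < lmin) { lmin <- y[1L]; lbase <- 1L }
  i <- p; rmin <- y[p]; rbase <- p
  while (i < n && y[i + 1L] <= y[p]) {
    i <- i + 1L
    if (y[i] < rmin) { rmin <- y[i]; rbase <- i }
  }
  if (i == n && y[n] < rmin) { rmin <- y[n]; rbase <- n }
  list(prominence = y[p] - max(lmin, rmin),
       left_base = lbase, right_base = rbase)
}

#' Delineate a peak's base by relative prominence height
#'
#' The evaluation height is peak height minus \code{rel_height} times the
#' peak's prominence. Crossing positions left and right of the peak are
#' found by linear interpolation along the curve (bounded by the peak's
#' prominence bases); the base start/end bins are the nearest integer bins
#' covering the whole base (floor of the left crossing, ceiling of the
#' right).
#'
#' @param lambda per-bin activity values.
#' @param peak_bin a peak surviving \code{\link{prune_adjacent}}.
#' @param rel_height fraction of prominence to descend. Default 0.93.
#' @return list(start_bin, end_bin, left_ip, right_ip, eval_height,
#'   prominence).
#' @export
peak_base <- function(lambda, peak_bin, rel_height = 0.93) {
  y <- ifelse(is.na(lambda), 0, lambda)
  n <- length(y)
  pr <- peak_prominence(y, peak_bin)
  wh <- y[peak_bin] - rel_height * pr$prominence
  i <- peak_bin
  while (i > pr$left_base && y[i] > wh) i <- i - 1L
  left_ip <- if (y[i] < wh) i + (wh - y[i]) / (y[i + 1L] - y[i]) else i
  i <- peak_bin
  while (i < pr$right_base && y[i] > wh) i <- i + 1L
  right_ip <- if (y[i] < wh) i - (wh - y[i]) / (y[i - 1L] - y[i]) else i
  list(start_bin = max(1L, as.integer(floor(left_ip))),
       end_bin = min(n, as.integer(ceiling(right_ip))),
       left_ip = left_ip, right_ip = right_ip,
       eval_height = wh, prominence = pr$prominence)
}

#' Merge overlapping or adjacent peak bases
#'
#' Bases whose bin intervals overlap or touch (end + 1 = next start) are
#' unified into a single field whose peak bin is the bin of maximal
#' activity within the union.
#'
#' @param fields data.frame with columns start_bin, end_bin, peak_bin.
#' @param lambda per-bin activity values.
#' @return merged data.frame, sorted by start_bin.
#' @export
merge_bases <- function(fields, lambda) {
  if (nrow(fields) <= 1L) return(fields)
  y <- ifelse(is.na(lambda), 0, lambda)
  fields <- fields[order(fields$start_bin), , drop = FALSE]
  out <- fields[1L, , drop = FALSE]
  for (k in 2:nrow(fields)) {
    last <- nrow(out)
    if (fields$start_bin[k] <= out$end_bin[last] + 1L) {
      out$end_bin[last] <- max(out$end_bin[last], fields$end_bin[k])
      span <- out$start_bin[last]:out$end_bin[last]
      out$peak_bin[last] <- span[which.max(y[span])]
    } else out <- rbind(out, fields[k, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Local spatial-information shuffle test for one candidate field
#'
#' The candidate region is the field base extended on both sides by half
#' the base width (in bins, rounded outward, clipped to the track). The
#' observed local SI uses only valid frames whose position falls in the
#' region; the null is built by circularly rotating, independently within
#' each lap, that lap's region samples by a uniform random shift (laps with
#' fewer than two region frames stay unshuffled). The field passes if the
#' observed SI strictly exceeds the 95th percentile of the null.
#'
#' @param spks noise-filtered deconvolved train.
#' @param behavior a \code{behavior_trace}.
#' @param binning a \code{spatial_binning}.
#' @param start_bin,end_bin field base (inclusive).
#' @param extend_frac extension on each side as a fraction of base width.
#'   Default 0.5.
#' @param n_shuffle shuffles. Default 1500; at least 100.
#' @param probs percentile criterion. Default 0.95.
#' @param seed integer seed.
#' @param valid optional precomputed valid-frame mask.
#' @return list(si, p, pass, crit, region = c(start, end)).
#' @export
local_si_test <- function(spks, behavior, binning, start_bin, end_bin,
                          extend_frac = 0.5, n_shuffle = 1500L,
                          probs = 0.95, seed = NULL, valid = NULL) {
  if (n_shuffle < 100L) fail("n_shuffle must be at least 100")
  if (is.null(valid)) valid <- valid_sample_mask(behavior, binning)
  w <- end_bin - start_bin + 1L
  ext <- as.integer(ceiling(extend_frac * w))
  r0 <- max(1L, start_bin - ext); r1 <- min(binning$n_bins, end_bin + ext)
  bof <- integer(length(spks))
  bof[valid] <- bin_index(behavior$position_cm[valid], binning)
  in_region <- bof >= r0 & bof <= r1
  rframes <- which(in_region)
  if (length(rframes) == 0L)
    return(list(si = NA_real_, p = NA_real_, pass = FALSE,
                crit = NA_real_, region = c(r0, r1)))
  rlap <- behavior$lap[rframes]
  rbin <- bof[rframes] - r0 + 1L
  nb <- r1 - r0 + 1L
  counts <- tabulate(rbin, nb)
  # per-lap layout: offset of each region frame within its lap's sequence
  ord <- order(rlap, rframes)
  rlap <- rlap[ord]; rbin <- rbin[ord]
  lap_len <- as.integer(table(rlap))
  lap_ids <- as.integer(names(table(rlap)))
  lap_start <- cumsum(c(0L, lap_len[-length(lap_len)]))  # 0-based offsets
  lap_of <- rep(seq_along(lap_ids), lap_len)
  off <- sequence(lap_len) - 1L                          # 0-based in lap
  vals <- spks[rframes][ord]
  nzi <- which(vals > 0)
  sums_obs <- numeric(nb)
  if (length(nzi)) {
    agg <- rowsum(vals[nzi], rbin[nzi])
    sums_obs[as.integer(rownames(agg))] <- agg[, 1]
  }
  si_obs <- si_from_sums(sums_obs, counts)
  if (is.na(si_obs))
    return(list(si = NA_real_, p = NA_real_, pass = FALSE,
                crit = NA_real_, region = c(r0, r1)))
  nlap <- length(lap_ids)
  shifts <- with_seed_(seed, {
    Lrep <- rep(lap_len, n_shuffle)
    s <- ifelse(Lrep < 2L,
                0L, as.integer(floor(stats::runif(length(Lrep)) *
                                       (Lrep - 1L))) + 1L)
    matrix(s, nrow = nlap)
  })
  nz_lap <- lap_of[nzi]; nz_off <- off[nzi]; nz_val <- vals[nzi]
  nz_len <- lap_len[nz_lap]; nz_ls <- lap_start[nz_lap]
  si_null <- vapply(seq_len(n_shuffle), function(k) {
    new_off <- (nz_off + shifts[nz_lap, k]) %% nz_len
    b <- rbin[nz_ls + new_off + 1L]
    sums <- numeric(nb)
    agg <- rowsum(nz_val, b)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    si_from_sums(sums, counts)
  }, 0)
  si_null[is.na(si_null)] <- 0
  crit <- pctl(si_null, probs)
  list(si = si_obs,
       p = (1 + sum(si_null >= si_obs)) / (1 + n_shuffle),
       pass = si_obs > crit, crit = crit, region = c(r0, r1))
}

#' Lap coverage of a field
#'
#' Fraction of laps carrying at least one valid event inside the field's
#' base bins; a field must be expressed in at least 30 percent of laps
#' (inclusive) to count as a place field.
#'
#' @param spks noise-filtered deconvolved train.
#' @param behavior a \code{behavior_trace}.
#' @param binning a \code{spatial_binning}.
#' @param start_bin,end_bin field base.
#' @param min_frac threshold. Default 0.30.
#' @param valid optional precomputed valid-frame mask.
#' @return list(frac, pass).
#' @export
lap_coverage <- function(spks, behavior, binning, start_bin, end_bin,
                         min_frac = 0.30, valid = NULL) {
  if (is.null(valid)) valid <- valid_sample_mask(behavior, binning)
  b <- bin_index(behavior$position_cm, binning)
  hit <- valid & spks > 0 & b >= start_bin & b <= end_bin
  n_laps <- max(behavior$lap)
  frac <- length(unique(behavior$lap[hit])) / n_laps
  list(frac = frac, pass = frac >= min_frac)
}

#' Classify one cell for one session
#'
#' Runs the full per-session decision cascade on a noise-filtered train:
#' cells with no valid events are silent; cells failing the odd-even
#' reliability gate or the global SI shuffle test are active non-place;
#' cells passing the global test are putative place cells; a putative place
#' cell with at least one delineated field passing both the local SI test
#' and the lap-coverage requirement is a place cell.
#'
#' @param spks_filtered noise-filtered deconvolved train.
#' @param behavior a \code{behavior_trace}.
#' @param binning a \code{spatial_binning}.
#' @param params list of stage parameters; see \code{\link{pipeline_config}}
#'   (entries: speed_cutoff_cm_s, odd_even_r_min, n_shuffle_global,
#'   global_probs, peak_height, rel_height, extend_frac, n_shuffle_local,
#'   local_probs, coverage_min_frac).
#' @param seed integer seed for the shuffle tests.
#' @return object of class \code{cell_classification}: list with
#'   \code{label}, \code{odd_even_r}, \code{global_si}, \code{global_si_p},
#'   \code{fields} (data.frame, one row per merged candidate field).
#' @export
classify_cell <- function(spks_filtered, behavior, binning,
                          params = pipeline_config(), seed = NULL) {
  pm <- params
  valid <- valid_sample_mask(behavior, binning, pm$speed_cutoff_cm_s)
  empty_fields <- data.frame(peak_bin = integer(), start_bin = integer(),
                             end_bin = integer(), local_si = numeric(),
                             local_si_p = numeric(), pass_local = logical(),
                             coverage = numeric(), pass_coverage = logical(),
                             significant = logical())
  res <- list(label = "silent", odd_even_r = NA_real_,
              global_si = NA_real_, global_si_p = NA_real_,
              fields = empty_fields)
  class(res) <- "cell_classification"
  if (sum(spks_filtered[valid]) == 0) return(res)

  gate <- odd_even_gate(
    tuning_curve(spks_filtered, behavior, binning, "odd", valid),
    tuning_curve(spks_filtered, behavior, binning, "even", valid),
    pm$odd_even_r_min)
  res$odd_even_r <- gate$r
  res$label <- "active_nonplace"
  if (!gate$pass) return(res)

  gl <- global_si_test(spks_filtered, behavior, binning,
                       n_shuffle = pm$n_shuffle_global,
                       probs = pm$global_probs,
                       seed = if (is.null(seed)) NULL else
                         derive_seed(seed, "global"),
                       valid = valid)
  res$global_si <- gl$si; res$global_si_p <- gl$p
  if (!isTRUE(gl$pass)) return(res)
  res$label <- "putative_place"

  curve <- tuning_curve(spks_filtered, behavior, binning, "all", valid)
  peaks <- prune_adjacent(curve$lambda,
                          find_peaks_curve(curve$lambda, pm$peak_height))
  if (length(peaks) == 0L) return(res)
  bases <- do.call(rbind, lapply(peaks, function(p) {
    b <- peak_base(curve$lambda, p, pm$rel_height)
    data.frame(peak_bin = p, start_bin = b$start_bin, end_bin = b$end_bin)
  }))
  bases <- merge_bases(bases, curve$lambda)
  fields <- do.call(rbind, lapply(seq_len(nrow(bases)), function(k) {
    f <- bases[k, ]
    lt <- local_si_test(spks_filtered, behavior, binning,
                        f$start_bin, f$end_bin,
                        extend_frac = pm$extend_frac,
                        n_shuffle = pm$n_shuffle_local,
                        probs = pm$local_probs,
                        seed = if (is.null(seed)) NULL else
                          derive_seed(seed, paste0("local", k)),
                        valid = valid)
    cv <- if (isTRUE(lt$pass))
      lap_coverage(spks_filtered, behavior, binning, f$start_bin,
                   f$end_bin, pm$coverage_min_frac, valid)
    else list(frac = NA_real_, pass = FALSE)
    data.frame(peak_bin = f$peak_bin, start_bin = f$start_bin,
               end_bin = f$end_bin, local_si = lt$si, local_si_p = lt$p,
               pass_local = isTRUE(lt$pass), coverage = cv$frac,
               pass_coverage = isTRUE(cv$pass),
               significant = isTRUE(lt$pass) && isTRUE(cv$pass))
  }))
  res$fields <- fields
  if (any(fields$significant)) res$label <- "place"
  res
}
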