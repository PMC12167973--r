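#' Construct a ground-truth cell
#'
#' The generative description of one simulated CA1 pyramidal cell: its
#' activity class, Gaussian place-field parameters and baseline event rate.
#' Silent cells emit no true events.
#'
#' @param cell_id integer id.
#' @param class one of "silent", "active_nonplace", "place".
#' @param field_centers_cm,field_widths_cm,field_peak_rate_hz numeric
#'   vectors, one entry per field (1-6 fields for place cells; width is the
#'   Gaussian SD in cm).
#' @param baseline_rate_hz out-of-field event rate. Default 0.
#' @return an object of class \code{gt_cell}.
#' @export
ground_truth_cell <- function(cell_id, class = c("silent", "active_nonplace",
                                                 "place"),
                              field_centers_cm = numeric(),
                              field_widths_cm = numeric(),
                              field_peak_rate_hz = numeric(),
                              baseline_rate_hz = 0) {
  class <- match.arg(class)
  n_fields <- length(field_centers_cm)
  if (class == "place" && (n_fields < 1L || n_fields > 6L))
    fail("place cells carry between 1 and 6 fields")
  if (class != "place" && n_fields > 0L)
    fail("only place cells carry fields")
  if (class == "silent" && baseline_rate_hz != 0)
    fail("silent cells must have zero baseline rate")
  stopifnot(length(field_widths_cm) == n_fields,
            length(field_peak_rate_hz) == n_fields)
  structure(list(cell_id = as.integer(cell_id), class = class,
                 n_fields = n_fields, field_centers_cm = field_centers_cm,
                 field_widths_cm = field_widths_cm,
                 field_peak_rate_hz = field_peak_rate_hz,
                 baseline_rate_hz = baseline_rate_hz),
            class = "gt_cell")
}

#' Sample a population of ground-truth cells
#'
#' Draws the per-session mixture the imaging study reports: about half the
#' cells silent, the rest split between spatially untuned and place cells
#' carrying 1-6 Gaussian fields.
#'
#' @param n number of cells.
#' @param track_length_cm corridor length.
#' @param p_silent probability a cell is silent. Default 0.5.
#' @param p_place probability an active cell is a place cell. Default 0.5.
#' @param field_count_probs probabilities of 1..6 fields for a place cell.
#'   Default heavily favors single fields.
#' @param width_range_cm range of Gaussian field SDs. Default c(15, 30).
#' @param peak_rate_hz place-field peak event rate. Default 2.
#' @param baseline_rate_hz active-cell out-of-field rate. Default 0.3.
#' @param seed integer seed.
#' @return list of \code{gt_cell}.
#' @export
sample_cells <- function(n, track_length_cm = 800, p_silent = 0.5,
                         p_place = 0.5,
                         field_count_probs = c(0.55, 0.2, 0.1, 0.07, 0.05,
                                               0.03),
                         width_range_cm = c(15, 30), peak_rate_hz = 2,
                         baseline_rate_hz = 0.3, seed = NULL) {
  with_seed_(seed, {
    lapply(seq_len(n), function(i) {
      if (stats::runif(1) < p_silent)
        return(ground_truth_cell(i, "silent"))
      if (stats::runif(1) >= p_place)
        return(ground_truth_cell(i, "active_nonplace",
                                 baseline_rate_hz = baseline_rate_hz))
      k <- sample.int(6L, 1L, prob = field_count_probs)
      # spread centers so multi-field cells have separable fields
      centers <- sort(stats::runif(k, 0.05, 0.95)) * track_length_cm
      ground_truth_cell(i, "place",
                        field_centers_cm = centers,
                        field_widths_cm = stats::runif(k, width_range_cm[1],
                                                       width_range_cm[2]),
                        field_peak_rate_hz = rep(peak_rate_hz, k),
                        baseline_rate_hz = baseline_rate_hz)
    })
  })
}

#' Instantaneous event rate of a cell along the track
#'
#' Baseline plus a sum of Gaussian bumps evaluated at the given positions.
#'
#' @param cell a \code{gt_cell}.
#' @param position_cm numeric positions.
#' @return event rate in Hz, same length as \code{position_cm}.
#' @export
cell_rate <- function(cell, position_cm) {
  stopifnot(inherits(cell, "gt_cell"))
  r <- rep(cell$baseline_rate_hz, length(position_cm))
  for (j in seq_len(cell$n_fields)) {
    r <- r + cell$field_peak_rate_hz[j] *
      exp(-(position_cm - cell$field_centers_cm[j])^2 /
            (2 * cell$field_widths_cm[j]^2))
  }
  r
}
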