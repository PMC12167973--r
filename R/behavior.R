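#' Virtual-corridor behavior configuration
#'
#' Parameters of the simulated navigation task: a head-fixed animal runs
#' laps on a linear virtual corridor at a roughly constant speed, slows in
#' an approach window before the reward zone (RZ) where lick propensity
#' rises, and is teleported back to the corridor start on lap completion.
#'
#' @param track_length_cm corridor length (cm). Default 800 (an ~8 m track).
#' @param n_laps number of laps to simulate. Default 50.
#' @param frame_rate_hz imaging/behavior sampling rate. Default 30.
#' @param mean_speed_cm_s mean running speed outside the RZ approach.
#'   Default 35 (well-trained animals run ~30-40 cm/s).
#' @param speed_sd_cm_s stationary SD of the within-lap speed fluctuation
#'   (an Ornstein-Uhlenbeck process, so fluctuations are correlated over
#'   \code{speed_tau_s}). Default 5.
#' @param speed_tau_s correlation time of the speed fluctuation (s).
#'   Default 0.5.
#' @param lap_speed_sdlog lognormal sdlog of the per-lap mean-speed
#'   multiplier (lap-to-lap running-speed variability). Default 0.15.
#' @param pause_p probability of a reward stop on a lap. Default 0.7.
#' @param pause_mean_s mean duration of the reward stop at RZ entry
#'   (exponential; speed near zero while paused). Default 1.5.
#' @param rz_start_cm,rz_end_cm reward-zone interval. Defaults 720 and 800.
#' @param approach_window_cm distance before \code{rz_start_cm} over which
#'   the animal slows and starts licking. Default 100.
#' @param slowdown_factor multiplier applied to the mean speed inside the
#'   approach window and RZ. Default 0.5.
#' @param lick_p_base,lick_p_rz per-frame lick probability outside/inside
#'   the approach+RZ window. Defaults 0.005 and 0.25.
#' @param teleport logical; jump back to position 0 at lap end. Default TRUE.
#' @return an object of class \code{behavior_config}.
#' @export
behavior_config <- function(track_length_cm = 800, n_laps = 50,
                            frame_rate_hz = 30, mean_speed_cm_s = 35,
                            speed_sd_cm_s = 5, speed_tau_s = 0.5,
                            lap_speed_sdlog = 0.15, pause_p = 0.7,
                            pause_mean_s = 1.5,
                            rz_start_cm = 720, rz_end_cm = 800,
                            approach_window_cm = 100, slowdown_factor = 0.5,
                            lick_p_base = 0.005, lick_p_rz = 0.25,
                            teleport = TRUE) {
  if (track_length_cm <= 0) fail("track_length_cm must be positive")
  if (n_laps < 1) fail("n_laps must be at least 1")
  if (frame_rate_hz <= 0) fail("frame_rate_hz must be positive")
  if (mean_speed_cm_s <= 0) fail("mean_speed_cm_s must be positive")
  if (!(rz_start_cm > 0 && rz_start_cm < rz_end_cm &&
        rz_end_cm <= track_length_cm))
    fail("reward zone must satisfy 0 < rz_start_cm < rz_end_cm <= track length")
  structure(as.list(environment()), class = "behavior_config")
}

#' Simulate a virtual-corridor behavior trace
#'
#' Integrates a noisy running-speed process at the imaging frame rate until
#' \code{n_laps} laps are complete. Each lap draws a mean-speed multiplier
#' (lap-to-lap variability); within a lap speed fluctuates as a correlated
#' Ornstein-Uhlenbeck process. Speed is multiplied by
#' \code{slowdown_factor} inside the RZ approach window, where the per-frame
#' lick probability is elevated; on most laps the animal stops at RZ entry
#' to consume the reward (near-zero speed for an exponential duration),
#' which both decorrelates lap timing and produces the slow-running periods
#' the spatial analysis must discard. Completing a lap teleports the animal
#' to position 0. Deterministic under a fixed seed.
#'
#' @param config a \code{\link{behavior_config}}.
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @return a \code{data.frame} of class \code{behavior_trace} with per-frame
#'   columns \code{time_s}, \code{position_cm}, \code{speed_cm_s},
#'   \code{lap} (1-based, non-decreasing) and \code{lick} (logical), and
#'   attributes \code{frame_rate_hz}, \code{track_length_cm},
#'   \code{n_teleports} and \code{config}.
#' @export
gen_behavior <- function(config = behavior_config(), seed = NULL) {
  stopifnot(inherits(config, "behavior_config"))
  with_seed_(seed, {
    cfg <- config
    dt <- 1 / cfg$frame_rate_hz
    # frames needed per lap at the slow-zone-adjusted mean speed, + head room
    est <- ceiling(cfg$n_laps * cfg$track_length_cm /
                     (cfg$mean_speed_cm_s * cfg$slowdown_factor) / dt) + 1000L
    pos <- speed <- time <- numeric(est)
    lap <- integer(est)
    lick <- logical(est)
    p <- 0; l <- 1L; i <- 0L; teleports <- 0L
    phi <- exp(-dt / cfg$speed_tau_s)          # OU autoregression
    ou_sd <- cfg$speed_sd_cm_s * sqrt(1 - phi^2)
    ou <- stats::rnorm(1L, 0, cfg$speed_sd_cm_s)
    new_lap <- function() {
      list(mult = stats::rlnorm(1L, -cfg$lap_speed_sdlog^2 / 2,
                                cfg$lap_speed_sdlog),
           pause = if (stats::runif(1L) < cfg$pause_p)
             stats::rexp(1L, 1 / max(cfg$pause_mean_s, 1e-9)) else 0)
    }
    lp <- new_lap()
    pause_left <- 0
    paused_this_lap <- FALSE
    while (l <= cfg$n_laps) {
      i <- i + 1L
      if (i > est) {  # grow buffers (rare)
        pos <- c(pos, numeric(est)); speed <- c(speed, numeric(est))
        time <- c(time, numeric(est)); lap <- c(lap, integer(est))
        lick <- c(lick, logical(est)); est <- 2L * est
      }
      slow <- p >= (cfg$rz_start_cm - cfg$approach_window_cm)
      if (!paused_this_lap && p >= cfg$rz_start_cm && lp$pause > 0) {
        pause_left <- lp$pause
        paused_this_lap <- TRUE
      }
      ou <- phi * ou + stats::rnorm(1L, 0, ou_sd)
      v <- if (pause_left > 0) {
        pause_left <- pause_left - dt
        abs(stats::rnorm(1L, 0, 0.5))          # consuming reward: ~0 cm/s
      } else {
        mu <- cfg$mean_speed_cm_s * lp$mult *
          if (slow) cfg$slowdown_factor else 1
        max(0, mu + ou)
      }
      pos[i] <- p; speed[i] <- v; time[i] <- (i - 1L) * dt; lap[i] <- l
      lick[i] <- stats::runif(1L) <
        if (slow) cfg$lick_p_rz else cfg$lick_p_base
      p <- p + v * dt
      if (p >= cfg$track_length_cm) {
        teleports <- teleports + 1L
        l <- l + 1L
        p <- if (cfg$teleport) 0 else p - cfg$track_length_cm
        lp <- new_lap()
        pause_left <- 0
        paused_this_lap <- FALSE
      }
    }
    out <- data.frame(time_s = time[seq_len(i)], position_cm = pos[seq_len(i)],
                      speed_cm_s = speed[seq_len(i)], lap = lap[seq_len(i)],
                      lick = lick[seq_len(i)])
    attr(out, "frame_rate_hz") <- cfg$frame_rate_hz
    attr(out, "track_length_cm") <- cfg$track_length_cm
    attr(out, "n_teleports") <- teleports
    attr(out, "config") <- cfg
    class(out) <- c("behavior_trace", "data.frame")
    out
  })
}
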