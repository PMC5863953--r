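#' Multi-sine target waveform coefficients
#'
#' The pursuit target is a sum of four sines in wrist angle. Amplitudes are in
#' degrees, frequencies in rad/s, so the slowest component has a period of
#' about 52 s and the fastest about 9.8 s over a 40 s trial.
#'
#' @return A data.frame with columns `amplitude` (degrees) and
#'   `frequency` (rad/s), one row per sine component.
#' @export
target_components <- function() {
  data.frame(
    amplitude = c(-7.8, 1.6, 9.4, -10.6),
    frequency = c(0.12, 0.28, 0.37, 0.64)
  )
}

#' Generate the deterministic multi-sine target trajectory
#'
#' Evaluates the four-component multi-sine target (and its analytic
#' derivative) on a regular time grid. The trajectory is deterministic given
#' its arguments; display noise is *not* part of the trajectory — it is
#' realized separately through the spot cloud (see [render_cloud()]), and the
#' true target returned here is the one tracking error is scored against.
#'
#' @param duration Trial length in seconds (default 40).
#' @param dt Time step in seconds (default 0.005).
#' @param phase_offset Time offset in seconds added to the evaluation time,
#'   implementing the randomized "initial time" of each trial; must lie in
#'   \[0, 30\].
#' @param seed Optional integer; when supplied and `phase_offset` is `NULL`,
#'   the offset is drawn uniformly from \[0, 30\] under this seed.
#' @return An object of class `target_trajectory`: a list with `times`,
#'   `position` (degrees), `velocity` (deg/s), `phase_offset`, `dt`.
#' @export
generate_target <- function(duration = 40, dt = 0.005, phase_offset = NULL,
                            seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be a positive number of seconds", call. = FALSE)
  }
  if (!is.numeric(dt) || dt <= 0) {
    stop("`dt` must be a positive number of seconds", call. = FALSE)
  }
  if (is.null(phase_offset)) {
    if (is.null(seed)) {
      phase_offset <- 0
    } else {
      set.seed(seed)
      phase_offset <- stats::runif(1, 0, 30)
    }
  }
  if (phase_offset < 0 || phase_offset > 30) {
    stop("`phase_offset` must lie in [0, 30] seconds", call. = FALSE)
  }
  times <- seq(0, duration, by = dt)
  comp <- target_components()
  tau <- times + phase_offset
  position <- rep(0, length(tau))
  velocity <- rep(0, length(tau))
  for (k in seq_len(nrow(comp))) {
    a <- comp$amplitude[k]
    w <- comp$frequency[k]
    position <- position + a * sin(w * tau)
    velocity <- velocity + a * w * cos(w * tau)
  }
  structure(
    list(times = times, position = position, velocity = velocity,
         phase_offset = phase_offset, dt = dt, duration = duration),
    class = "target_trajectory"
  )
}

#' @exportS3Method base::print
print.target_trajectory <- function(x, ...) {
  cat("<target_trajectory> ", length(x$times), " samples over ",
      x$duration, " s (dt = ", x$dt, " s), phase offset ",
      round(x$phase_offset, 3), " s\n", sep = "")
  cat("  position range [", round(min(x$position), 2), ", ",
      round(max(x$position), 2), "] deg\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.target_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, target_deg = x$position,
             target_vel_deg_s = x$velocity)
}

#' Render the noisy spot-cloud display of a target trajectory
#'
#' The target is shown to a subject as a cloud of spots drawn i.i.d. from a
#' normal distribution centred on the true target position; the cloud is
#' refreshed every 0.4 s and the spread is a per-subject constant (their
#' visual noise level).
#'
#' @param traj A [generate_target()] trajectory.
#' @param spread Standard deviation of the spots about the target, degrees.
#' @param spot_count Spots per refresh frame (default 10).
#' @param refresh_interval Seconds between display refreshes (default 0.4).
#' @param seed Integer seed for the spot draws.
#' @return An object of class `visual_cloud`: list with `frame_times`,
#'   `spots` (frames x spot_count matrix, degrees), `spread`, `spot_count`,
#'   `refresh_interval`.
#' @export
render_cloud <- function(traj, spread, spot_count = 10, refresh_interval = 0.4,
                         seed = NULL) {
  stopifnot(inherits(traj, "target_trajectory"))
  if (!is.numeric(spread) || spread <= 0) {
    stop("`spread` must be a positive standard deviation in degrees",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  frame_times <- seq(0, traj$duration - 1e-9, by = refresh_interval)
  idx <- pmin(length(traj$times), floor(frame_times / traj$dt) + 1L)
  centres <- traj$position[idx]
  spots <- matrix(stats::rnorm(length(centres) * spot_count,
                               mean = rep(centres, spot_count), sd = spread),
                  nrow = length(centres), ncol = spot_count)
  structure(
    list(frame_times = frame_times, spots = spots, spread = spread,
         spot_count = spot_count, refresh_interval = refresh_interval),
    class = "visual_cloud"
  )
}

#' @exportS3Method base::print
print.visual_cloud <- function(x, ...) {
  cat("<visual_cloud> ", nrow(x$spots), " frames x ", x$spot_count,
      " spots, spread ", x$spread, " deg, refresh ", x$refresh_interval,
      " s\n", sep = "")
  invisible(x)
}

#' Coupling stiffness levels of the experiment
#'
#' @return Named numeric vector of spring constants in Nm/rad:
#'   hard 17.2, medium 1.7, soft 0.3.
#' @export
stiffness_levels <- function() {
  c(hard = 17.2, medium = 1.7, soft = 0.3)
}

#' Build the 45-trial block schedule
#'
#' Three blocks of 15 trials; every dyad starts with the medium stiffness
#' block and the order of the hard and soft blocks is randomized (or forced
#' via `order`). Each trial is independently connected or solo with
#' probability 1/2 (a "binary die").
#'
#' @param order `"random"`, `"medium-hard-soft"` or `"medium-soft-hard"`.
#' @param seed Integer seed (used for the block-order permutation and the
#'   connected-trial coin flips).
#' @param n_per_block Trials per block (default 15).
#' @param trial_duration Seconds per trial (default 40).
#' @return Object of class `trial_schedule`: a data.frame with columns
#'   `trial`, `block`, `level` (hard/medium/soft), `stiffness` (Nm/rad),
#'   `connected` (logical), plus attributes `order` (1 = medium,hard,soft;
#'   0 = medium,soft,hard) and `trial_duration`.
#' @export
build_schedule <- function(order = c("random", "medium-hard-soft",
                                     "medium-soft-hard"),
                           seed = NULL, n_per_block = 15,
                           trial_duration = 40) {
  order <- match.arg(order)
  if (!is.null(seed)) set.seed(seed)
  if (order == "random") {
    order <- sample(c("medium-hard-soft", "medium-soft-hard"), 1)
  }
  lev <- strsplit(order, "-")[[1]]
  levels_per_block <- lev
  ks <- stiffness_levels()
  n_trials <- 3L * n_per_block
  sched <- data.frame(
    trial = seq_len(n_trials),
    block = rep(1:3, each = n_per_block),
    level = rep(levels_per_block, each = n_per_block),
    stiffness = rep(unname(ks[levels_per_block]), each = n_per_block),
    connected = stats::runif(n_trials) < 0.5,
    stringsAsFactors = FALSE
  )
  structure(sched,
            class = c("trial_schedule", "data.frame"),
            order = if (identical(levels_per_block[2], "hard")) 1L else 0L,
            trial_duration = trial_duration)
}

#' Export a trajectory to CSV
#'
#' Columns `time_s`, `target_deg`, `target_vel_deg_s`.
#' @param traj A `target_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Export a trial schedule to JSON
#'
#' @param schedule A `trial_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  obj <- list(
    order = attr(schedule, "order"),
    trial_duration = attr(schedule, "trial_duration"),
    trials = as.data.frame(schedule)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
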