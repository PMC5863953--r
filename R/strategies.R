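DEG <- pi / 180

# per-call noise draws for one agent: standard normals for the visual,
# force-sensing and haptic-channel observations
draw_agent_noise <- function(n, seed) {
  set.seed(seed)
  matrix(stats::rnorm(3L * n), n, 3,
         dimnames = list(NULL, c("vis", "frc", "hap")))
}

new_trial_result <- function(traj, theta_rad, u, force = NULL, extra = list(),
                             diverged = FALSE) {
  target_rad <- traj$position * DEG
  n <- length(theta_rad)
  err_deg <- tracking_error(theta_rad[seq_len(n)] / DEG,
                            traj$position[seq_len(n)])
  structure(c(list(
    times = traj$times[seq_len(n)],
    theta_deg = theta_rad / DEG,
    target_deg = traj$position[seq_len(n)],
    u = u,
    force = force,
    rms_error_deg = if (diverged) NA_real_ else err_deg,
    effort_nm = if (diverged) NA_real_ else simulated_effort(u),
    diverged = diverged
  ), extra), class = "trial_result")
}

#' @exportS3Method base::print
print.trial_result <- function(x, ...) {
  cat("<trial_result> ", length(x$times), " samples; RMS error ",
      signif(x$rms_error_deg, 4), " deg; effort ", signif(x$effort_nm, 4),
      " Nm", if (isTRUE(x$diverged)) " [DIVERGED]", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trial_result <- function(x, ...) {
  d <- data.frame(time_s = x$times, theta_deg = x$theta_deg,
                  target_deg = x$target_deg, u_nm = x$u)
  if (!is.null(x$force)) d$force_nm <- x$force
  d
}

#' Simulate a solo visual tracking trial
#'
#' One LQG agent tracks the multi-sine target through its noisy visual
#' observation; no coupling force acts (`F == 0`). The agent runs an
#' iterative Kalman filter over its internal random-walk-velocity target
#' model and applies the infinite-horizon LQR gain to the estimated
#' tracking-error state.
#'
#' @param agent An [agent_spec()].
#' @param traj A [generate_target()] trajectory (degrees).
#' @param seed Integer seed for the observation noise.
#' @return A `trial_result`: time series (`theta_deg`, `target_deg`, `u`) and
#'   scalar summaries `rms_error_deg`, `effort_nm`.
#' @export
run_solo <- function(agent, traj, seed = 1) {
  stopifnot(inherits(agent, "agent_spec"), inherits(traj, "target_trajectory"))
  n <- length(traj$times)
  noise <- draw_agent_noise(n, seed)
  res <- sim_solo_cpp(traj$position * DEG, traj$velocity * DEG, traj$dt,
                      agent$inertia, agent$Lp, agent$Lv, agent$sigma_v2,
                      agent$sigma_mu2, noise[, "vis"],
                      as.integer(round(0.4 / traj$dt)))
  new_trial_result(traj, res$theta, res$u, diverged = res$diverged,
                   extra = list(t_est_deg = res$t_est / DEG))
}

#' Simulate a haptic-only tracking trial
#'
#' The target is invisible; the wrist is coupled to it by a spring whose
#' force is both applied to the plant and sensed (with additive force noise)
#' as the only observation of the target. Tracking error decreases with
#' stiffness: a harder spring transmits the target's motion more faithfully
#' per unit of force-sensing noise.
#'
#' @param agent An [agent_spec()].
#' @param coupling A [coupling_spec()] with `stiffness > 0`.
#' @param traj Target trajectory.
#' @param seed Integer seed.
#' @param obs_interval Seconds between independent force percepts (default
#'   0.4: haptic perception, like the visual display, contributes one
#'   independent sample per refresh interval).
#' @return A `trial_result` (with `force` series).
#' @export
run_haptic_tracking <- function(agent, coupling, traj, seed = 1,
                                obs_interval = 0.4) {
  stopifnot(inherits(agent, "agent_spec"), inherits(coupling, "coupling_spec"))
  if (coupling$stiffness <= 0) {
    stop("haptic tracking needs `stiffness > 0`: a zero-stiffness coupling ",
         "carries no information about the target", call. = FALSE)
  }
  n <- length(traj$times)
  noise <- draw_agent_noise(n, seed)
  res <- sim_haptic_cpp(traj$position * DEG, traj$velocity * DEG, traj$dt,
                        agent$inertia, agent$Lp, agent$Lv,
                        coupling$stiffness, coupling$damping,
                        agent$sigma_f^2, agent$sigma_mu2, noise[, "frc"],
                        as.integer(round(obs_interval / traj$dt)))
  new_trial_result(traj, res$theta, res$u, force = res$force,
                   diverged = res$diverged,
                   extra = list(t_est_deg = res$t_est / DEG))
}

#' Stiffness-dependent haptic channel noise model
#'
#' In neuromechanical goal sharing the haptic estimate of the partner's goal
#' carries the partner's visual noise plus an extra variance `sigma_s2(K)`
#' due to the compliance of the coupling; `sigma_s2` is non-increasing in K
#' and zero in the rigid limit.
#'
#' @param sigma_s2 Named numeric vector of extra variances (deg^2), one per
#'   stiffness level, e.g. `c(hard = 0, medium = 1.2, soft = 4.5)`.
#' @return Object of class `haptic_noise_model`.
#' @export
haptic_noise_model <- function(sigma_s2) {
  if (any(sigma_s2 < 0)) stop("`sigma_s2` must be >= 0", call. = FALSE)
  structure(list(sigma_s2 = sigma_s2), class = "haptic_noise_model")
}

#' Calibrate the haptic channel noise from haptic-only tracking
#'
#' Runs (or takes, from a haptic-tracking data table) the haptic-only
#' tracking condition at each stiffness level and converts the tracking
#' errors into the additive channel variance `sigma_s2(K)`: the mean squared
#' tracking error at K minus the floor at the hardest K, clamped at zero.
#'
#' @param agent Agent used for the simulated calibration; its `sigma_f`
#'   (default 0.1 Nm here) is the human force-discrimination noise of the
#'   calibration experiment, distinct from the high-fidelity haptic pathway
#'   the interaction strategies assume.
#' @param stiffness Named vector of stiffness levels (Nm/rad).
#' @param n_trials Trials per stiffness level (default 5, as in the
#'   calibration experiment design).
#' @param n_subjects Simulated subjects (default 8).
#' @param seed Integer seed.
#' @param errors Optional data.frame with columns `stiffness` (Nm/rad) and
#'   `error_deg`; when supplied (e.g. from [read_s2()]) it overrides the
#'   simulation.
#' @param duration,dt Trial length and step for the simulated calibration.
#' @return A [haptic_noise_model()] with attributes `errors` (the per-trial
#'   table) and `mean_error_deg` (per-level mean RMS error).
#' @export
calibrate_haptic_noise <- function(agent = agent_spec(sigma_f = 0.1),
                                   stiffness = stiffness_levels(),
                                   n_trials = 5, n_subjects = 8, seed = 1,
                                   errors = NULL, duration = 40, dt = 0.005) {
  if (is.null(errors)) {
    rows <- list()
    k <- 0L
    for (s in seq_len(n_subjects)) {
      for (lev in names(stiffness)) {
        cp <- coupling_spec(stiffness[[lev]], inertia = agent$inertia)
        for (tr in seq_len(n_trials)) {
          k <- k + 1L
          traj <- generate_target(duration, dt,
                                  seed = seed * 100003L + k)
          res <- run_haptic_tracking(agent, cp, traj,
                                     seed = seed * 200003L + k)
          rows[[k]] <- data.frame(subject = s, level = lev,
                                  stiffness = stiffness[[lev]], trial = tr,
                                  error_deg = res$rms_error_deg)
        }
      }
    }
    errors <- do.call(rbind, rows)
  } else {
    stopifnot(all(c("stiffness", "error_deg") %in% names(errors)))
    lv <- names(stiffness)[match(round(errors$stiffness, 1),
                                 round(unname(stiffness), 1))]
    errors$level <- lv
  }
  mse <- tapply(errors$error_deg^2, errors$level, mean)
  mean_err <- tapply(errors$error_deg, errors$level, mean)
  hardest <- names(stiffness)[which.max(stiffness)]
  sigma_s2 <- pmax(mse - mse[[hardest]], 0)
  sigma_s2 <- sigma_s2[names(stiffness)]
  model <- haptic_noise_model(sigma_s2)
  attr(model, "errors") <- errors
  attr(model, "mean_error_deg") <- mean_err[names(stiffness)]
  model
}

#' @exportS3Method base::print
print.haptic_noise_model <- function(x, ...) {
  cat("<haptic_noise_model> sigma_s2 (deg^2):\n")
  print(signif(x$sigma_s2, 4))
  invisible(x)
}

#' Follow-the-leader observation switch
#'
#' Returns which reference the agent tracks: the target when one's own wrist
#' is at least as close to the (estimated) target as the partner's wrist
#' (ties inclusive), otherwise the partner's wrist.
#'
#' @param own_theta Own wrist angle.
#' @param target_est Estimated target position.
#' @param partner_theta Partner wrist angle (estimate from the spring force).
#' @return List with `reference` (`"target"` or `"partner"`) and
#'   `observation` (own angle minus the tracked reference).
#' @export
observe_follow_leader <- function(own_theta, target_est, partner_theta) {
  if (abs(own_theta - target_est) <= abs(partner_theta - target_est)) {
    list(reference = "target", observation = own_theta - target_est)
  } else {
    list(reference = "partner", observation = own_theta - partner_theta)
  }
}

#' Precision-weighted fusion of goal observations
#'
#' Combines independent noisy observations of the same quantity with weights
#' inverse to their variances (the optimal static cue combination); the fused
#' variance never exceeds the smallest channel variance. An infinite-variance
#' channel is ignored.
#'
#' @param values Channel observations.
#' @param variances Channel variances (> 0, may be `Inf`).
#' @return List with `estimate` and `variance`.
#' @export
integrate_goals <- function(values, variances) {
  stopifnot(length(values) == length(variances), all(variances > 0))
  w <- 1 / variances
  keep <- is.finite(w) & w > 0
  if (!any(keep)) stop("all channels uninformative", call. = FALSE)
  list(estimate = sum(values[keep] * w[keep]) / sum(w[keep]),
       variance = 1 / sum(w[keep]))
}

#' Tuning constants of the partner-representation filter
#'
#' Process-noise and prior settings of the extended Kalman filter that
#' identifies the partner and infers their goal during coupled trials.
#' `q_acc` absorbs the partner's unmodeled control jitter (rad^2/s^2 per
#' step on the wrist-velocity state); `q_gain_rel` is the relative
#' random-walk rate of the gain states; `gain_prior_rel` the relative prior
#' SD about the self-as-prior gain initialization; `sub_var` the clamp
#' variance of the own-target substitution during identification;
#' `q_tvel_mult` multiplies the internal-model velocity diffusion for the
#' partner-target state (the partner's goal estimate jitters much faster
#' than the physical target).
#'
#' @param q_acc,q_gain_rel,gain_prior_rel,sub_var,q_tvel_mult Numeric
#'   tuning constants.
#' @return Named list.
#' @export
dyad_ekf_control <- function(q_acc = 1e-4, q_gain_rel = 1e-5,
                             gain_prior_rel = 0.5, sub_var = 1e-6,
                             q_tvel_mult = 1) {
  list(q_acc = q_acc, q_gain_rel = q_gain_rel,
       gain_prior_rel = gain_prior_rel, sub_var = sub_var,
       q_tvel_mult = q_tvel_mult)
}

strategy_code <- function(strategy) {
  switch(strategy, follow_leader = 0L, goal_integration = 1L,
         neuromechanical = 1L,
         stop("unknown strategy: ", strategy, call. = FALSE))
}

#' Simulate a connected dyad trial
#'
#' Two agents track the same target while their wrists are joined by the
#' elastic coupling; each receives only the observations its strategy
#' defines. For `goal_integration` and `neuromechanical` each agent runs an
#' extended Kalman filter over a representation of the partner (wrist state,
#' feedback gains, partner target), identified from the interaction force;
#' after a burn-in during which one's own target substitutes for the
#' partner's, the inferred partner target is fused with the visual channel,
#' weighted by `sigma_v_partner^2 + sigma_s2(K)`. `neuromechanical` differs
#' from `goal_integration` only through a nonzero `sigma_s2`.
#'
#' @param a1,a2 [agent_spec()]s for the two partners.
#' @param coupling A [coupling_spec()]; `stiffness = 0` decouples the pair
#'   (each agent falls back to solo vision).
#' @param traj Target trajectory.
#' @param strategy `"follow_leader"`, `"goal_integration"` or
#'   `"neuromechanical"`.
#' @param seed Integer seed; per-agent noise seeds derive from it unless
#'   `agent_seeds` is given.
#' @param agent_seeds Optional length-2 integer vector of per-agent noise
#'   seeds (exposing these makes label-swap symmetry exact).
#' @param sigma_s2_deg2 Extra haptic channel variance (deg^2) at this
#'   stiffness; 0 for pure goal integration.
#' @param burn_in Seconds of identification burn-in with own-target
#'   substitution (default 5).
#' @param force_compensation Fraction of the measured coupling torque
#'   cancelled feedforward by the controller (default 1: the spring is a
#'   known disturbance the LQG agent compensates; the compensation torque
#'   counts toward effort). 0 reproduces the raw uncompensated control law.
#' @param ekf_control List of EKF tuning constants (`q_acc`, `q_gain_rel`,
#'   `gain_prior_rel`, `sub_var`).
#' @return List of two `trial_result`s (one per agent), each with the fused
#'   target estimate, the inferred partner target and the identified gain
#'   trajectories attached.
#' @export
run_dyad <- function(a1, a2, coupling, traj,
                     strategy = c("neuromechanical", "goal_integration",
                                  "follow_leader"),
                     seed = 1, agent_seeds = NULL, sigma_s2_deg2 = 0,
                     burn_in = 5, force_compensation = 1,
                     ekf_control = dyad_ekf_control()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(a1, "agent_spec"), inherits(a2, "agent_spec"),
            inherits(coupling, "coupling_spec"),
            inherits(traj, "target_trajectory"))
  n <- length(traj$times)
  if (is.null(agent_seeds)) {
    agent_seeds <- c(seed * 2L + 1L, seed * 2L + 2L)
  }
  no1 <- draw_agent_noise(n, agent_seeds[1])
  no2 <- draw_agent_noise(n, agent_seeds[2])
  agl <- function(ag, partner) {
    list(inertia = ag$inertia, Lp = ag$Lp, Lv = ag$Lv,
         sigma_v2 = ag$sigma_v2, sigma_mu2 = ag$sigma_mu2,
         sigma_f2 = ag$sigma_f^2,
         # haptic channel carries the partner's visual noise plus the
         # coupling-softness term (rad^2 internally); it is fused once per
         # display refresh, the rate at which its error decorrelates
         hap_var = partner$sigma_v2 + sigma_s2_deg2 * DEG^2,
         hap_noise_var = sigma_s2_deg2 * DEG^2,
         gain_init_p = ag$Lp / ag$inertia,
         gain_init_v = ag$Lv / ag$inertia)
  }
  res <- sim_dyad_cpp(traj$position * DEG, traj$velocity * DEG, traj$dt,
                      strategy_code(strategy), coupling$stiffness,
                      coupling$damping, as.integer(round(burn_in / traj$dt)),
                      agl(a1, a2), agl(a2, a1),
                      cbind(no1[, "vis"], no2[, "vis"]),
                      cbind(no1[, "frc"], no2[, "frc"]),
                      cbind(no1[, "hap"], no2[, "hap"]),
                      ekf_control$q_acc, ekf_control$q_gain_rel,
                      ekf_control$gain_prior_rel, ekf_control$sub_var,
                      if (is.null(ekf_control$q_tvel_mult)) 1
                      else ekf_control$q_tvel_mult,
                      as.integer(round(0.4 / traj$dt)), force_compensation,
                      as.integer(round(0.4 / traj$dt)))
  out <- lapply(1:2, function(a) {
    new_trial_result(
      traj, res$theta[, a], res$u[, a],
      force = if (a == 1) res$force1 else -res$force1,
      diverged = res$diverged,
      extra = list(t_fused_deg = res$t_fused[, a] / DEG,
                   t_tilde_deg = res$t_tilde[, a] / DEG,
                   gains = cbind(p = res$gains_p[, a], v = res$gains_v[, a]),
                   strategy = strategy)
    )
  })
  names(out) <- c("agent1", "agent2")
  out
}

#' Identify the partner's feedback policy from the interaction force
#'
#' Runs the extended Kalman filter over the internal partner representation
#' (wrist state, feedback gains, partner target) on recorded histories of
#' the interaction force and one's own proprioception, with one's own target
#' substituted for the partner's throughout (identification phase). The
#' gains enter the dynamics multiplicatively, so the filter is linearized
#' about the current estimate at every step.
#'
#' @param force Interaction force history, Nm (force on one's own wrist).
#' @param own_theta n x 2 matrix (or list of two vectors) of own wrist angle
#'   and velocity, rad / rad s^-1.
#' @param own_target n x 2 matrix of the substituted target (own estimate or
#'   the true target), rad / rad s^-1.
#' @param coupling A [coupling_spec()] with nonzero stiffness.
#' @param dt Time step, s.
#' @param sigma_f Force sensing noise SD, Nm.
#' @param gain_init Length-2 initial guess for the acceleration feedback
#'   gains (self-as-prior default: own LQR gains over inertia).
#' @param partner_spring_accel Optional known acceleration input acting on
#'   the partner (e.g. the spring reaction), rad/s^2; default none.
#' @param control EKF tuning constants as in [run_dyad()], plus `q_tvel`.
#' @param window,tol Convergence check: the gains are declared converged
#'   when their standard deviation over the final `window` seconds is below
#'   `tol` times their magnitude.
#' @return Object of class `partner_model`: `gains` (final `[L_p, L_v]`),
#'   `gain_history`, `wrist`, `target`, `converged`, `cov_gain`.
#' @export
identify_partner_policy <- function(force, own_theta, own_target, coupling,
                                    dt = 0.005, sigma_f = 0.01,
                                    gain_init = NULL,
                                    partner_spring_accel = NULL,
                                    control = list(q_acc = 1e-6,
                                                   q_gain_rel = 1e-5,
                                                   gain_prior_rel = 0.5,
                                                   sub_var = 1e-6,
                                                   q_tvel = 2e-2),
                                    window = 5, tol = 0.1) {
  stopifnot(inherits(coupling, "coupling_spec"))
  if (coupling$stiffness <= 0) {
    stop("partner policy is unidentifiable at zero coupling stiffness: ",
         "the force channel carries no information", call. = FALSE)
  }
  own_theta <- as.matrix(own_theta)
  own_target <- as.matrix(own_target)
  n <- length(force)
  if (is.null(gain_init)) {
    ag <- agent_spec()
    gain_init <- c(ag$Lp / ag$inertia, ag$Lv / ag$inertia)
  }
  if (is.null(partner_spring_accel)) partner_spring_accel <- rep(0, n)
  res <- ekf_partner_cpp(force, own_theta[, 1], own_theta[, 2],
                         own_target[, 1], own_target[, 2],
                         partner_spring_accel, dt,
                         coupling$stiffness, coupling$damping, sigma_f^2,
                         n, gain_init[1], gain_init[2],
                         control$q_acc, control$q_gain_rel,
                         control$gain_prior_rel, control$sub_var,
                         control$q_tvel)
  w <- max(2L, min(n, as.integer(round(window / dt))))
  tail_idx <- (n - w + 1L):n
  g <- res$gains[n, ]
  sdev <- apply(res$gains[tail_idx, , drop = FALSE], 2, stats::sd)
  converged <- all(sdev <= tol * pmax(abs(g), 1e-8))
  structure(list(gains = g, gain_history = res$gains, wrist = res$wrist,
                 target = res$target, cov_gain = res$cov_gain,
                 converged = converged, coupling = coupling, dt = dt,
                 sigma_f = sigma_f, control = control),
            class = "partner_model")
}

#' @exportS3Method base::print
print.partner_model <- function(x, ...) {
  cat("<partner_model> gains [", paste(signif(x$gains, 4), collapse = ", "),
      "], ", if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' Infer the partner's target from proprioception and haptics only
#'
#' With the partner's feedback gains identified, reruns the partner filter
#' with the target states free (no substitution): the only observations are
#' one's own wrist state and the interaction force, yet the partner's goal
#' trajectory can be reconstructed.
#'
#' @param pm A converged [identify_partner_policy()] result.
#' @param force,own_theta As in [identify_partner_policy()].
#' @param partner_spring_accel Optional known partner acceleration input.
#' @return n x 2 matrix of the inferred partner target (position, velocity).
#' @export
infer_partner_target <- function(pm, force, own_theta,
                                 partner_spring_accel = NULL) {
  stopifnot(inherits(pm, "partner_model"))
  if (!pm$converged) {
    stop("partner gains are not identified; run identify_partner_policy() ",
         "until convergence before inferring the target", call. = FALSE)
  }
  own_theta <- as.matrix(own_theta)
  n <- length(force)
  if (is.null(partner_spring_accel)) partner_spring_accel <- rep(0, n)
  ctl <- pm$control
  res <- ekf_partner_cpp(force, own_theta[, 1], own_theta[, 2],
                         rep(0, n), rep(0, n), partner_spring_accel,
                         pm$dt, pm$coupling$stiffness, pm$coupling$damping,
                         pm$sigma_f^2, 0L, pm$gains[1], pm$gains[2],
                         ctl$q_acc, ctl$q_gain_rel / 10,
                         0.1, ctl$sub_var, ctl$q_tvel)
  res$target
}
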