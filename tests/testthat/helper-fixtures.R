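# short-trial fixtures shared across test files: 10 s trials keep the suite
# fast while leaving every mechanism (burn-in, refresh cycles, filters)
# exercised

short_traj <- function(seed = NULL, phase_offset = if (is.null(seed)) 0,
                       duration = 10) {
  generate_target(duration = duration, dt = 0.005,
                  phase_offset = phase_offset, seed = seed)
}

default_agent <- function(sigma_v_deg = 3, ...) {
  agent_spec(sigma_v_deg = sigma_v_deg, ...)
}

# independent evaluation of the four-term multi-sine, kept deliberately
# separate from the package implementation
eval_multisine <- function(tau) {
  -7.8 * sin(0.12 * tau) + 1.6 * sin(0.28 * tau) +
    9.4 * sin(0.37 * tau) - 10.6 * sin(0.64 * tau)
}

# simulate a partner that follows the internal partner-representation
# dynamics exactly: acceleration feedback toward a target state
sim_policy_partner <- function(traj, gains, dt = 0.005) {
  n <- length(traj$times)
  tp <- traj$position * pi / 180
  tv <- traj$velocity * pi / 180
  th <- numeric(n)
  thd <- numeric(n)
  x <- 0
  xd <- 0
  for (i in seq_len(n)) {
    th[i] <- x
    thd[i] <- xd
    acc <- -gains[1] * (x - tp[i]) - gains[2] * (xd - tv[i])
    x <- x + xd * dt
    xd <- xd + acc * dt
  }
  cbind(th, thd)
}

# recover planted partner gains from the force channel at stiffness K;
# the harness force noise (0.05 Nm) is large enough that the per-sample
# information differs measurably across the three stiffness levels
recover_gains <- function(K, seed, gains = c(4, 0.8), sigma_f = 0.05) {
  traj <- generate_target(seed = seed)
  pw <- sim_policy_partner(traj, gains)
  n <- nrow(pw)
  cp <- coupling_spec(K)
  set.seed(seed + 1000L)
  force <- K * pw[, 1] + cp$damping * pw[, 2] +
    stats::rnorm(n, 0, sigma_f)
  identify_partner_policy(force, cbind(rep(0, n), rep(0, n)),
                          cbind(traj$position * pi / 180,
                                traj$velocity * pi / 180),
                          cp, sigma_f = sigma_f, gain_init = gains / 2)
}
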