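test_that("solo trials are deterministic given a seed", {
  ag <- default_agent()
  tr <- short_traj()
  r1 <- run_solo(ag, tr, seed = 5)
  r2 <- run_solo(ag, tr, seed = 5)
  expect_identical(r1$theta_deg, r2$theta_deg)
  expect_identical(r1$rms_error_deg, r2$rms_error_deg)
  r3 <- run_solo(ag, tr, seed = 6)
  expect_false(identical(r1$theta_deg, r3$theta_deg))
})

test_that("zero-stiffness dyad reduces to two independent solo trials", {
  a1 <- default_agent(2)
  a2 <- default_agent(5)
  tr <- short_traj()
  cp <- coupling_spec(0, damping = 0)
  for (strat in c("follow_leader", "goal_integration", "neuromechanical")) {
    d <- run_dyad(a1, a2, cp, tr, strategy = strat, agent_seeds = c(11, 12))
    s1 <- run_solo(a1, tr, seed = 11)
    s2 <- run_solo(a2, tr, seed = 12)
    expect_equal(d$agent1$rms_error_deg, s1$rms_error_deg, tolerance = 1e-12)
    expect_equal(d$agent2$rms_error_deg, s2$rms_error_deg, tolerance = 1e-12)
  }
})

test_that("swapping agent labels swaps outputs exactly", {
  a1 <- default_agent(2)
  a2 <- default_agent(5)
  tr <- short_traj()
  cp <- coupling_spec(1.7)
  d12 <- run_dyad(a1, a2, cp, tr, strategy = "goal_integration",
                  agent_seeds = c(21, 22))
  d21 <- run_dyad(a2, a1, cp, tr, strategy = "goal_integration",
                  agent_seeds = c(22, 21))
  expect_identical(d12$agent1$theta_deg, d21$agent2$theta_deg)
  expect_identical(d12$agent2$u, d21$agent1$u)
  expect_identical(d12$agent1$force, -d21$agent1$force)
})

test_that("neuromechanical with zero channel noise is goal integration", {
  a1 <- default_agent(2)
  a2 <- default_agent(5)
  tr <- short_traj()
  cp <- coupling_spec(17.2)
  gi <- run_dyad(a1, a2, cp, tr, strategy = "goal_integration",
                 agent_seeds = c(3, 4))
  nm <- run_dyad(a1, a2, cp, tr, strategy = "neuromechanical",
                 agent_seeds = c(3, 4), sigma_s2_deg2 = 0)
  expect_identical(gi$agent1$theta_deg, nm$agent1$theta_deg)
  expect_identical(gi$agent2$u, nm$agent2$u)
})

test_that("coupling forces are antisymmetric at every step", {
  d <- run_dyad(default_agent(2), default_agent(5), coupling_spec(17.2),
                short_traj(), strategy = "neuromechanical",
                agent_seeds = c(7, 8))
  expect_equal(d$agent1$force, -d$agent2$force)
})

test_that("follow-the-leader switch picks the nearer wrist, ties to target", {
  # tie: inclusive branch tracks the target
  expect_equal(observe_follow_leader(1, 0, -1)$reference, "target")
  # partner exactly on target, self off: observation is theta - partner
  o <- observe_follow_leader(0.5, 0, 0)
  expect_equal(o$reference, "partner")
  expect_equal(o$observation, 0.5)
  # scripted scenario against a hand-built branch table
  own <- c(0.0, 0.2, 0.4, -0.3, 0.1)
  tgt <- c(0.0, 0.0, 0.1, 0.0, 0.0)
  par <- c(0.5, 0.1, 0.2, -0.1, -0.4)
  expected <- c("target", "partner", "partner", "partner", "target")
  got <- vapply(1:5, function(i) {
    observe_follow_leader(own[i], tgt[i], par[i])$reference
  }, character(1))
  expect_equal(got, expected)
})

test_that("goal fusion weights channels inversely to variance", {
  # equal variances: midpoint
  f <- integrate_goals(c(2, 4), c(1, 1))
  expect_equal(f$estimate, 3)
  # fused variance never exceeds the best channel
  f2 <- integrate_goals(c(2, 4, 1), c(0.5, 2, 3))
  expect_lte(f2$variance, 0.5)
  # infinite-variance channel drops out
  f3 <- integrate_goals(c(2, 100), c(1, Inf))
  expect_equal(f3$estimate, 2)
  expect_error(integrate_goals(c(1), c(Inf)), "uninformative")
})

test_that("partner policy identification recovers planted gains", {
  pm <- recover_gains(17.2, seed = 2)
  expect_true(pm$converged)
  expect_lt(abs(pm$gains[1] - 4) / 4, 0.15)
  expect_lt(abs(pm$gains[2] - 0.8) / 0.8, 0.15)
  # no excitation: a partner clamped at the (constant) target position gives
  # no gain information — covariance does not contract
  n <- 2001
  cp <- coupling_spec(17.2)
  force <- rep(0, n)
  pm0 <- identify_partner_policy(force, cbind(rep(0, n), rep(0, n)),
                                 cbind(rep(0, n), rep(0, n)), cp,
                                 gain_init = c(2, 0.4))
  expect_gt(pm0$cov_gain[n], 0.5 * pm0$cov_gain[1])
  # zero stiffness is unidentifiable by construction
  expect_error(identify_partner_policy(force, cbind(rep(0, n), rep(0, n)),
                                       cbind(rep(0, n), rep(0, n)),
                                       coupling_spec(0, damping = 0)),
               "unidentifiable")
})

test_that("partner target inference needs identified gains and tracks a static goal", {
  n <- 4001
  dt <- 0.005
  K <- 17.2
  cp <- coupling_spec(K)
  gains <- c(4, 0.8)
  goal <- 0.3
  # partner settles on a constant target
  th <- numeric(n); thd <- numeric(n); x <- 0; xd <- 0
  for (i in 1:n) {
    th[i] <- x; thd[i] <- xd
    acc <- -gains[1] * (x - goal) - gains[2] * xd
    x <- x + xd * dt; xd <- xd + acc * dt
  }
  set.seed(9)
  force <- K * th + cp$damping * thd + stats::rnorm(n, 0, 0.01)
  own <- cbind(rep(0, n), rep(0, n))
  pm <- identify_partner_policy(force, own, cbind(rep(goal, n), rep(0, n)),
                                cp, gain_init = c(2, 0.4))
  tt <- infer_partner_target(pm, force, own)
  expect_equal(stats::median(tt[(n - 400):n, 1]), goal, tolerance = 0.05)

  pm$converged <- FALSE
  expect_error(infer_partner_target(pm, force, own), "identified")
})

test_that("haptic-only tracking error is ordered by stiffness", {
  ag <- agent_spec(sigma_f = 0.1)
  med <- vapply(c(hard = 17.2, medium = 1.7, soft = 0.3), function(K) {
    cp <- coupling_spec(K)
    stats::median(vapply(1:5, function(s) {
      run_haptic_tracking(ag, cp, short_traj(seed = s),
                          seed = 50 + s)$rms_error_deg
    }, numeric(1)))
  }, numeric(1))
  expect_lt(med[["hard"]], med[["medium"]])
  expect_lt(med[["medium"]], med[["soft"]])
  expect_error(run_haptic_tracking(ag, coupling_spec(0, damping = 0),
                                   short_traj()), "stiffness")
})

test_that("haptic noise calibration is non-negative and soft-dominated", {
  nm <- calibrate_haptic_noise(n_trials = 2, n_subjects = 3, seed = 4,
                               duration = 20)
  expect_true(all(nm$sigma_s2 >= 0))
  expect_equal(nm$sigma_s2[["hard"]], 0)
  expect_gt(nm$sigma_s2[["soft"]], nm$sigma_s2[["medium"]])
  # empirical errors override the simulation
  fake <- data.frame(stiffness = rep(c(17.2, 1.7, 0.3), each = 4),
                     error_deg = rep(c(1, 2, 5), each = 4))
  nm2 <- calibrate_haptic_noise(errors = fake)
  expect_equal(nm2$sigma_s2[["soft"]], 24)
  expect_equal(nm2$sigma_s2[["medium"]], 3)
})
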