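# independent finite-horizon dynamic-programming recursion, written apart
# from the package's fixed-point solver
backward_lqr <- function(A, B, Q, R, n = 20000, tol = 1e-10) {
  P <- Q
  L_old <- NULL
  for (i in seq_len(n)) {
    L <- solve(R + t(B) %*% P %*% B, t(B) %*% P %*% A)
    P <- Q + t(A) %*% P %*% A - t(A) %*% P %*% B %*% L
    if (!is.null(L_old) && max(abs(L - L_old)) < tol * max(abs(L))) break
    L_old <- L
  }
  L
}

# closed-form infinite-horizon quadratic cost of a fixed stable gain via the
# discrete Lyapunov equation, solved by vectorization
closed_loop_cost <- function(L, A, B, Q, R, x0) {
  Acl <- A - B %*% L
  Qbar <- Q + t(L) %*% R %*% L
  n <- nrow(A)
  S <- matrix(solve(diag(n^2) - kronecker(t(Acl), t(Acl)), as.vector(Qbar)),
              n, n)
  as.numeric(t(x0) %*% S %*% x0)
}

test_that("LQR gain matches an independent value-iteration oracle", {
  ctrl <- solve_lqr()
  L_vi <- backward_lqr(ctrl$A, ctrl$B, ctrl$q * ctrl$Q, ctrl$R)
  expect_equal(as.vector(ctrl$L), as.vector(L_vi), tolerance = 1e-8)

  # closed loop strictly stable at defaults
  expect_lt(max(Mod(ctrl$closed_loop_eigenvalues)), 1)
})

test_that("LQR gain is optimal against perturbed gains and scale invariant", {
  ctrl <- solve_lqr()
  x0 <- c(0.2, -0.1)
  j_opt <- closed_loop_cost(ctrl$L, ctrl$A, ctrl$B, ctrl$q * ctrl$Q, ctrl$R,
                            x0)
  set.seed(1)
  for (i in 1:10) {
    Lp <- ctrl$L + matrix(stats::rnorm(2, 0, 0.05 * max(abs(ctrl$L))), 1, 2)
    jp <- tryCatch(closed_loop_cost(Lp, ctrl$A, ctrl$B, ctrl$q * ctrl$Q,
                                    ctrl$R, x0), error = function(e) Inf)
    expect_gte(jp, j_opt - 1e-10)
  }

  # scaling q and R together leaves the gain unchanged
  c1 <- solve_lqr(q = 1, R = 100)
  c2 <- solve_lqr(q = 5, R = 500)
  expect_equal(c1$L, c2$L, tolerance = 1e-9)

  expect_error(solve_lqr(q = -1), "q")
  expect_error(solve_lqr(R = 0), "positive definite")
  expect_error(solve_lqr(Q = diag(c(-1, 1))), "semi-definite")
})

test_that("position gain grows with the state-cost multiplier", {
  qs <- 10^seq(-1, 1, length.out = 5)
  lps <- vapply(qs, function(q) solve_lqr(q = q)$L[1, 1], numeric(1))
  expect_true(all(diff(lps) > 0))
})

test_that("kalman_step matches batch weighted least squares on a scalar", {
  # static scalar state observed 50 times with heteroscedastic noise: the
  # sequential filter must equal the closed-form weighted mean
  set.seed(3)
  truth <- 1.4
  vars <- stats::runif(50, 0.5, 3)
  z <- truth + stats::rnorm(50, 0, sqrt(vars))
  est <- 0
  P <- matrix(1e8, 1, 1)
  for (i in seq_along(z)) {
    st <- kalman_step(est, P, z[i], H = 1, R_obs = vars[i])
    est <- st$estimate
    P <- st$covariance
  }
  w <- 1 / vars
  batch <- sum(w * z) / (sum(w) + 1e-8)
  expect_equal(est, batch, tolerance = 1e-10)
  expect_equal(as.numeric(P), 1 / (sum(w) + 1e-8), tolerance = 1e-10)
})

test_that("kalman_step limits: uninformative and perfect channels", {
  est <- c(1, 0)
  P <- diag(c(0.5, 0.5))
  H <- matrix(c(1, 0), 1, 2)
  # infinite-noise channel leaves the estimate at its prediction
  st <- kalman_step(est, P, z = 99, H = H, R_obs = 1e18)
  expect_equal(st$estimate, est, tolerance = 1e-6)
  # zero-noise channel pins the observed coordinate
  st2 <- kalman_step(est, P, z = 2.5, H = H, R_obs = 1e-14)
  expect_equal(st2$estimate[1], 2.5, tolerance = 1e-6)
  # non-finite observation is skipped and counted
  st3 <- kalman_step(est, P, z = NaN, H = H, R_obs = 1)
  expect_equal(st3$estimate, est)
  expect_equal(st3$skipped_channels, 1)
})

test_that("delay compensation equals the matrix power of the transition", {
  A <- matrix(c(1, 0, 0.005, 1), 2, 2)
  x <- c(0.3, -0.2)
  expect_equal(compensate_delay(x, 0, A), x)
  expect_equal(compensate_delay(x, 2 * 0.005, A),
               c(0.3 - 0.2 * 0.01, -0.2))
  k <- 7
  Ak <- diag(2)
  for (i in seq_len(k)) Ak <- Ak %*% A
  expect_equal(compensate_delay(x, k * 0.005, A), as.numeric(Ak %*% x))
  expect_error(compensate_delay(x, -0.005, A), "delay")
  expect_error(compensate_delay(x, 0.0033, A), "multiple")
})

test_that("solo tracking error grows with visual noise", {
  errs <- vapply(c(1, 3, 8, 16), function(sv) {
    ag <- agent_spec(sigma_v_deg = sv)
    stats::median(vapply(1:6, function(s) {
      run_solo(ag, generate_target(seed = s), seed = 100 + s)$rms_error_deg
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  # calibration: the default skill range spans roughly the 1-6 degree band
  expect_gt(errs[1], 0.8)
  expect_lt(errs[3], 9)
})
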