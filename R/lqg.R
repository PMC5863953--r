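#' Solve a discrete algebraic Riccati equation by fixed-point iteration
#'
#' Iterates `P <- Q + A'PA - A'PB (R + B'PB)^-1 B'PA` to convergence.
#'
#' @param A,B State and input matrices.
#' @param Q,R State and control cost matrices.
#' @param tol Convergence tolerance on the max absolute element change.
#' @param max_iter Iteration cap.
#' @return The stabilizing solution `P`.
#' @keywords internal
solve_dare <- function(A, B, Q, R, tol = 1e-12, max_iter = 100000L) {
  P <- Q
  for (i in seq_len(max_iter)) {
    BtP <- crossprod(B, P)
    G <- solve(R + BtP %*% B, BtP %*% A)
    Pn <- Q + crossprod(A, P %*% A) - crossprod(A, t(BtP) %*% G)
    if (max(abs(Pn - P)) < tol * max(1, max(abs(Pn)))) {
      return(Pn)
    }
    P <- Pn
  }
  stop("Riccati iteration did not converge; check that (A, B) is ",
       "stabilizable and Q is positive semi-definite", call. = FALSE)
}

#' Infinite-horizon discrete LQR gain
#'
#' Solves for the feedback gain `L = [L_p, L_v]` minimizing the quadratic
#' cost `sum x' (q Q) x + u' R u` for the tracking-error state
#' `x = [theta - t, vel - t_vel]`. Certainty equivalence: the same gain is
#' applied to the estimated state during closed-loop simulation.
#'
#' @param A State transition matrix (default the double integrator at `dt`).
#' @param B Input matrix (default `[0, dt/I]`).
#' @param q Positive scalar multiplier on the state cost.
#' @param Q Base state cost (default `diag(1, 0.1)`).
#' @param R Control cost (scalar > 0, default 100: with the default plant
#'   this yields a closed-loop natural frequency near 1 Hz, the bandwidth of
#'   human wrist pursuit).
#' @param dt,inertia Used to build the default `A`, `B`.
#' @return Object of class `controller_params`: list with `L` (1x2 gain),
#'   `P` (Riccati solution), the matrices, and the closed-loop eigenvalues.
#' @export
solve_lqr <- function(A = NULL, B = NULL, q = 1, Q = diag(c(1, 0.1)),
                      R = 100, dt = 0.005, inertia = 0.0025) {
  if (is.null(A)) A <- matrix(c(1, 0, dt, 1), 2, 2)
  if (is.null(B)) B <- plant_b_matrix(dt, inertia)
  if (q <= 0) stop("`q` must be > 0", call. = FALSE)
  R <- as.matrix(R)
  if (any(eigen(R, only.values = TRUE)$values <= 0)) {
    stop("control cost `R` must be positive definite", call. = FALSE)
  }
  ev <- eigen(as.matrix(Q), only.values = TRUE)$values
  if (any(ev < -1e-12)) {
    stop("state cost `Q` must be positive semi-definite", call. = FALSE)
  }
  P <- solve_dare(A, B, q * as.matrix(Q), R)
  L <- solve(R + crossprod(B, P %*% B), crossprod(B, P %*% A))
  cl <- eigen(A - B %*% L, only.values = TRUE)$values
  if (max(Mod(cl)) >= 1) {
    stop("closed loop is not stable; (A, B) may not be stabilizable",
         call. = FALSE)
  }
  structure(list(L = L, P = P, A = A, B = B, q = q, Q = Q, R = R,
                 closed_loop_eigenvalues = cl),
            class = "controller_params")
}

#' @exportS3Method base::print
print.controller_params <- function(x, ...) {
  cat("<controller_params> L = [", paste(signif(x$L, 5), collapse = ", "),
      "], q = ", x$q, ", spectral radius ",
      signif(max(Mod(x$closed_loop_eigenvalues)), 4), "\n", sep = "")
  invisible(x)
}

#' One predict/update step of a Kalman filter
#'
#' Standard linear predict/update. Channels with non-finite observations
#' (e.g. dropped display frames) are skipped and counted, leaving the
#' estimate at its prediction.
#'
#' @param estimate Prior state mean (length-n).
#' @param covariance Prior state covariance (n x n, PSD).
#' @param z Observation vector (length-m); entries may be `NA`/`NaN`.
#' @param H m x n observation matrix.
#' @param R_obs Observation noise covariance (m x m or length-m variances).
#' @param A State transition (defaults to identity: update-only step).
#' @param W Process noise covariance (defaults to zero).
#' @param u Optional known additive input to the state prediction.
#' @return List with `estimate`, `covariance`, `innovation`,
#'   `skipped_channels`.
#' @export
kalman_step <- function(estimate, covariance, z, H, R_obs,
                        A = diag(length(estimate)),
                        W = matrix(0, length(estimate), length(estimate)),
                        u = rep(0, length(estimate))) {
  H <- matrix(H, ncol = length(estimate))
  if (is.vector(R_obs) && length(R_obs) == nrow(H)) R_obs <- diag(R_obs, nrow(H))
  # predict
  x <- as.numeric(A %*% estimate) + u
  P <- A %*% covariance %*% t(A) + W
  ok <- is.finite(z)
  innovation <- rep(NA_real_, length(z))
  if (any(ok)) {
    Hk <- H[ok, , drop = FALSE]
    Rk <- R_obs[ok, ok, drop = FALSE]
    y <- z[ok] - as.numeric(Hk %*% x)
    S <- Hk %*% P %*% t(Hk) + Rk
    K <- P %*% t(Hk) %*% solve(S)
    x <- x + as.numeric(K %*% y)
    IKH <- diag(length(x)) - K %*% Hk
    # Joseph form keeps the covariance symmetric PSD
    P <- IKH %*% P %*% t(IKH) + K %*% Rk %*% t(K)
    innovation[ok] <- y
  }
  list(estimate = x, covariance = (P + t(P)) / 2, innovation = innovation,
       skipped_channels = sum(!ok))
}

#' Compensate a sensory delay by forward propagation
#'
#' Propagates a state estimate forward `delay/dt` steps through the
#' noise-free state equation (i.e. applies `A^k`), the standard way a
#' delayed sensory measurement is referred to "now" before control.
#'
#' @param estimate State estimate at the delayed time.
#' @param delay Delay in seconds (>= 0, integer multiple of `dt`).
#' @param A One-step transition matrix.
#' @param dt Time step, s.
#' @return The propagated estimate.
#' @export
compensate_delay <- function(estimate, delay, A, dt = 0.005) {
  if (delay < 0) stop("`delay` must be >= 0", call. = FALSE)
  k <- delay / dt
  if (abs(k - round(k)) > 1e-9) {
    stop("`delay` must be an integer multiple of `dt`", call. = FALSE)
  }
  k <- as.integer(round(k))
  x <- as.numeric(estimate)
  for (i in seq_len(k)) x <- as.numeric(A %*% x)
  x
}

#' Specification of one simulated subject
#'
#' Bundles the plant, the controller cost weights, the internal target model
#' and the subject's sensory noise. `sigma_v_deg` is the per-subject visual
#' noise (the spread of the spot cloud) and is the "skill" knob: solo
#' tracking error grows monotonically with it.
#'
#' @param sigma_v_deg Visual noise standard deviation, degrees.
#' @param sigma_mu2 Internal-model velocity diffusion, rad^2/s^3.
#' @param q State-cost multiplier (> 0).
#' @param Q Base state cost matrix.
#' @param R Control cost.
#' @param inertia Wrist inertia, kg m^2.
#' @param dt Simulation step, s.
#' @param delay Compensated sensory delay, s (default 0).
#' @param sigma_f Haptic force sensing noise standard deviation, Nm
#'   (default 0.01: the interaction strategies treat the haptic pathway as
#'   high fidelity; the human-scale value 0.1 is used when emulating the
#'   haptic-tracking perception experiment).
#' @return Object of class `agent_spec` with the precomputed LQR gain.
#' @export
agent_spec <- function(sigma_v_deg = 6, sigma_mu2 = 2e-2, q = 1,
                       Q = diag(c(1, 0.1)), R = 100,
                       inertia = 0.0025, dt = 0.005, delay = 0,
                       sigma_f = 0.01) {
  if (sigma_v_deg <= 0) stop("`sigma_v_deg` must be > 0", call. = FALSE)
  ctrl <- solve_lqr(q = q, Q = Q, R = R, dt = dt, inertia = inertia)
  structure(list(
    sigma_v_deg = sigma_v_deg,
    sigma_v2 = (sigma_v_deg * pi / 180)^2,
    sigma_mu2 = sigma_mu2,
    q = q, Q = Q, R = R,
    inertia = inertia, dt = dt, delay = delay,
    sigma_f = sigma_f,
    controller = ctrl,
    Lp = ctrl$L[1, 1], Lv = ctrl$L[1, 2]
  ), class = "agent_spec")
}

#' @exportS3Method base::print
print.agent_spec <- function(x, ...) {
  cat("<agent_spec> sigma_v = ", x$sigma_v_deg, " deg, sigma_mu2 = ",
      x$sigma_mu2, ", q = ", x$q, ", L = [", signif(x$Lp, 4), ", ",
      signif(x$Lv, 4), "]\n", sep = "")
  invisible(x)
}
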