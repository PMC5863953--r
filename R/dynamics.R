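#' Convert stiffness between Nm/deg and Nm/rad
#'
#' Trial data files report the connection stiffness in Nm/deg; all internal
#' computation uses SI Nm/rad. 0.3 Nm/deg corresponds to 17.2 Nm/rad.
#'
#' @param k Stiffness value(s).
#' @return Converted stiffness.
#' @export
nm_per_deg_to_nm_per_rad <- function(k) k * 180 / pi

#' @rdname nm_per_deg_to_nm_per_rad
#' @export
nm_per_rad_to_nm_per_deg <- function(k) k * pi / 180

#' Wrist plant specification
#'
#' A point inertia about the wrist flexion/extension axis driven by the motor
#' torque plus the coupling torque: `I theta'' = u + F`. Discretized with the
#' explicit first-order scheme the model is defined in: the plant IS the
#' discrete system, not an approximation of a continuous one.
#'
#' @param inertia Moment of inertia in kg m^2 (default 0.0025, hand plus
#'   handle about the wrist axis).
#' @param theta Initial angle, rad.
#' @param theta_dot Initial angular velocity, rad/s.
#' @return Object of class `wrist_plant`.
#' @export
wrist_plant <- function(inertia = 0.0025, theta = 0, theta_dot = 0) {
  if (!is.numeric(inertia) || inertia <= 0) {
    stop("`inertia` must be positive", call. = FALSE)
  }
  structure(list(inertia = inertia, state = c(theta, theta_dot)),
            class = "wrist_plant")
}

#' Elastic coupling specification
#'
#' The virtual elastic band joining the two wrists (or a wrist and the target
#' in haptic-only tracking): a spring of stiffness `K` with viscous damping
#' `D`. `K = D = 0` is the solo condition, with identically zero force.
#'
#' @param stiffness Spring constant K, Nm/rad (>= 0).
#' @param damping Damping D, Nm s/rad; `NULL` (default) uses
#'   `0.5 * sqrt(K * inertia)`, a fixed fraction of critical damping that
#'   also stands in for intrinsic wrist viscosity and keeps the stiff
#'   coupled mode stable under the explicit integration scheme.
#' @param inertia Inertia used for the default damping rule.
#' @return Object of class `coupling_spec` with elements `stiffness`,
#'   `damping`.
#' @export
coupling_spec <- function(stiffness, damping = NULL, inertia = 0.0025) {
  if (stiffness < 0) stop("`stiffness` must be >= 0", call. = FALSE)
  if (is.null(damping)) damping <- 0.5 * sqrt(stiffness * inertia)
  if (damping < 0) stop("`damping` must be >= 0", call. = FALSE)
  structure(list(stiffness = stiffness, damping = damping),
            class = "coupling_spec")
}

#' Elastic coupling torque on one's own wrist
#'
#' `F = K (theta_partner - theta) + D (vel_partner - vel)`. The torque on the
#' partner is the exact negative, so the spring injects zero net impulse into
#' the pair.
#'
#' @param own Numeric length-2 state `c(angle, velocity)` of one's own wrist
#'   (rad, rad/s).
#' @param partner Partner's wrist state, same layout.
#' @param coupling A [coupling_spec()].
#' @return Torque in Nm.
#' @export
coupling_force <- function(own, partner, coupling) {
  stopifnot(length(own) == 2, length(partner) == 2,
            inherits(coupling, "coupling_spec"))
  if (!all(is.finite(own)) || !all(is.finite(partner))) {
    stop("wrist states must be finite", call. = FALSE)
  }
  coupling$stiffness * (partner[1] - own[1]) +
    coupling$damping * (partner[2] - own[2])
}

#' Advance the wrist plant one step
#'
#' Explicit first-order update: `angle += vel * dt`,
#' `vel += (u + F) * dt / I`.
#'
#' @param plant A [wrist_plant()].
#' @param u Motor torque, Nm.
#' @param force Coupling torque, Nm (0 when solo).
#' @param dt Time step, s.
#' @return The plant with its state advanced.
#' @export
step_plant <- function(plant, u, force = 0, dt = 0.005) {
  stopifnot(inherits(plant, "wrist_plant"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (!is.finite(u) || !is.finite(force)) {
    stop("non-finite torque in plant step", call. = FALSE)
  }
  s <- plant$state
  plant$state <- c(s[1] + s[2] * dt,
                   s[2] + (u + force) * dt / plant$inertia)
  plant
}

#' Internal target process model
#'
#' The agent's generative model of the target: position integrates velocity
#' and velocity performs a Gaussian random walk. This is the model the Kalman
#' filter assumes, deliberately distinct from the true deterministic
#' multi-sine target; `sigma_mu2` scales the assumed velocity diffusion.
#'
#' @param dt Time step, s.
#' @param sigma_mu2 Velocity diffusion intensity, rad^2/s^3: the velocity
#'   increment over one step has variance `sigma_mu2 * dt`.
#' @return Object of class `target_process_model` with transition matrix `A`,
#'   process covariance `W`, and the parameters.
#' @export
target_process_model <- function(dt = 0.005, sigma_mu2 = 2e-2) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (sigma_mu2 < 0) stop("`sigma_mu2` must be >= 0", call. = FALSE)
  structure(list(
    A = matrix(c(1, 0, dt, 1), 2, 2),
    W = diag(c(0, sigma_mu2 * dt)),
    dt = dt, sigma_mu2 = sigma_mu2
  ), class = "target_process_model")
}

#' Advance a target state under the internal process model
#'
#' @param model A [target_process_model()].
#' @param state Length-2 `c(position, velocity)`.
#' @param noise Optional standard-normal draw for the velocity increment;
#'   drawn from the session RNG when `NULL`.
#' @return The next state.
#' @export
step_target_model <- function(model, state, noise = NULL) {
  stopifnot(inherits(model, "target_process_model"), length(state) == 2)
  if (is.null(noise)) noise <- stats::rnorm(1)
  nxt <- as.numeric(model$A %*% state)
  nxt[2] <- nxt[2] + sqrt(model$sigma_mu2 * model$dt) * noise
  nxt
}

#' Plant input matrix
#' @param dt Time step, s.
#' @param inertia Wrist inertia, kg m^2.
#' @return 2x1 matrix `[0, dt/I]`.
#' @keywords internal
plant_b_matrix <- function(dt, inertia) matrix(c(0, dt / inertia), 2, 1)
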