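// Closed-loop trial simulation kernels.
//
// All stochastic inputs are pre-drawn standard normal vectors supplied from R,
// so every simulation is reproducible under set.seed() and label-swap
// symmetric (each agent owns its noise columns). States are SI (rad, rad/s);
// unit conversion happens at the R boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2-state Kalman filter over the agent's internal target model
// x = [position, velocity], A = [[1, dt], [0, 1]], W = diag(0, sigma_mu2*dt)
struct Kf2 {
  arma::vec2 x;
  arma::mat22 P;

  void init(double p0, double v0, double pvar, double vvar) {
    x = {p0, v0};
    P.zeros();
    P(0, 0) = pvar;
    P(1, 1) = vvar;
  }

  // scalar observation z = h0*x0 + h1*x1 + noise(var r)
  void update(double z, double h0, double h1, double r) {
    double y = z - (h0 * x(0) + h1 * x(1));
    double s = h0 * (P(0, 0) * h0 + P(0, 1) * h1) +
               h1 * (P(1, 0) * h0 + P(1, 1) * h1) + r;
    double k0 = (P(0, 0) * h0 + P(0, 1) * h1) / s;
    double k1 = (P(1, 0) * h0 + P(1, 1) * h1) / s;
    x(0) += k0 * y;
    x(1) += k1 * y;
    // (I - K H) P, symmetrized
    double p00 = P(0, 0), p01 = P(0, 1), p10 = P(1, 0), p11 = P(1, 1);
    P(0, 0) = (1 - k0 * h0) * p00 - k0 * h1 * p10;
    P(0, 1) = (1 - k0 * h0) * p01 - k0 * h1 * p11;
    P(1, 0) = -k1 * h0 * p00 + (1 - k1 * h1) * p10;
    P(1, 1) = -k1 * h0 * p01 + (1 - k1 * h1) * p11;
    double off = 0.5 * (P(0, 1) + P(1, 0));
    P(0, 1) = off;
    P(1, 0) = off;
  }

  void predict(double dt, double sigma_mu2) {
    x(0) += dt * x(1);
    // P <- A P A' + W
    double p00 = P(0, 0), p01 = P(0, 1), p11 = P(1, 1);
    P(0, 0) = p00 + dt * (p01 + p01) + dt * dt * p11;
    P(0, 1) = p01 + dt * p11;
    P(1, 0) = P(0, 1);
    P(1, 1) = p11 + sigma_mu2 * dt;
  }
};

// Extended Kalman filter over the internal representation of the partner:
// state [p_th, p_thd, Lp, Lv, pt, ptd]
//  p_th, p_thd : partner wrist angle / velocity
//  Lp, Lv      : partner feedback (acceleration) gains, random-walk constants
//  pt, ptd     : partner's target (the quantity goal sharing wants)
// Dynamics: partner accelerates toward its target with gains [Lp, Lv] plus a
// known input (the spring reaction the partner feels, when supplied).
struct EkfPartner {
  arma::vec::fixed<6> x;
  arma::mat::fixed<6, 6> P;
  double q_acc, q_gp, q_gv, q_tvel;
  double lp_hi, lv_hi;  // gain sanity bounds (projection onto [0, hi])

  void init(double th0, double thd0, double lp0, double lv0,
            double t0, double td0, double gain_prior_rel) {
    x = {th0, thd0, lp0, lv0, t0, td0};
    P.zeros();
    P(0, 0) = 0.01;
    P(1, 1) = 0.05;
    P(2, 2) = std::pow(gain_prior_rel * std::max(std::abs(lp0), 1.0), 2);
    P(3, 3) = std::pow(gain_prior_rel * std::max(std::abs(lv0), 1.0), 2);
    P(4, 4) = 0.1;
    P(5, 5) = 0.05;
    lp_hi = 10.0 * std::max(std::abs(lp0), 1.0);
    lv_hi = 10.0 * std::max(std::abs(lv0), 1.0);
  }

  // keep the gain states in a physically sensible band; without this the
  // multiplicative nonlinearity can run away numerically on long trials
  void clamp() {
    x(2) = std::min(std::max(x(2), 0.0), lp_hi);
    x(3) = std::min(std::max(x(3), 0.0), lv_hi);
  }

  void predict(double dt, double a_known) {
    double pth = x(0), pthd = x(1), lp = x(2), lv = x(3), pt = x(4),
           ptd = x(5);
    double ep = pth - pt, ev = pthd - ptd;
    arma::mat::fixed<6, 6> F;
    F.eye();
    F(0, 1) = dt;
    F(1, 0) = -lp * dt;
    F(1, 1) = 1.0 - lv * dt;
    F(1, 2) = -ep * dt;
    F(1, 3) = -ev * dt;
    F(1, 4) = lp * dt;
    F(1, 5) = lv * dt;
    F(4, 5) = dt;
    x(0) = pth + pthd * dt;
    x(1) = pthd + (-lp * ep - lv * ev + a_known) * dt;
    x(4) = pt + ptd * dt;
    P = F * P * F.t();
    P(1, 1) += q_acc;
    P(2, 2) += q_gp;
    P(3, 3) += q_gv;
    P(5, 5) += q_tvel * dt;
    P = 0.5 * (P + P.t());
    clamp();
  }

  // observation: spring force F = K (p_th - th_own) + D (p_thd - thd_own)
  void update_force(double f_obs, double th_own, double thd_own, double K,
                    double D, double r) {
    arma::vec::fixed<6> H;
    H.zeros();
    H(0) = K;
    H(1) = D;
    double pred = K * (x(0) - th_own) + D * (x(1) - thd_own);
    scalar_update(f_obs - pred, H, r);
  }

  // clamp the partner-target states to a substituted target (identification
  // phase: one's own target stands in for the partner's)
  void update_target_sub(double tpos, double tvel, double r) {
    arma::vec::fixed<6> H;
    H.zeros();
    H(4) = 1.0;
    scalar_update(tpos - x(4), H, r);
    H(4) = 0.0;
    H(5) = 1.0;
    scalar_update(tvel - x(5), H, r);
  }

  void scalar_update(double innov, const arma::vec::fixed<6>& H, double r) {
    arma::vec::fixed<6> PH = P * H;
    double s = arma::dot(H, PH) + r;
    arma::vec::fixed<6> K = PH / s;
    x += K * innov;
    // Joseph form: numerically keeps P positive semi-definite under the
    // strong force updates at hard coupling
    arma::mat::fixed<6, 6> IKH;
    IKH.eye();
    IKH -= K * H.t();
    P = IKH * P * IKH.t() + (K * K.t()) * r;
    P = 0.5 * (P + P.t());
    clamp();
  }

  // last-resort guard: a non-finite state would otherwise poison the whole
  // trial; reset the covariance and re-anchor the estimate
  void heal(double lp0, double lv0, double gain_prior_rel) {
    if (x.is_finite() && P.is_finite()) return;
    double th = std::isfinite(x(0)) ? x(0) : 0.0;
    double pt = std::isfinite(x(4)) ? x(4) : th;
    init(th, 0.0, lp0, lv0, pt, 0.0, gain_prior_rel);
  }
};

static inline bool bad(double v) { return !std::isfinite(v) || std::abs(v) > 1e3; }

// [[Rcpp::export]]
List sim_solo_cpp(const arma::vec& tpos, const arma::vec& tvel, double dt,
                  double inertia, double Lp, double Lv, double sigma_v2,
                  double sigma_mu2, const arma::vec& e_vis, int vis_every) {
  int n = tpos.n_elem;
  arma::vec theta(n), theta_dot(n), u(n), t_est(n);
  double th = 0.0, thd = 0.0;
  double sd_v = std::sqrt(sigma_v2);
  Kf2 kf;
  kf.init(0.0, 0.0, 0.3, 0.05);
  bool diverged = false;
  for (int i = 0; i < n; ++i) {
    // the target is displayed as a refreshed spot cloud: one independent
    // visual sample per refresh interval, held between refreshes
    if (vis_every <= 1 || i % vis_every == 0) {
      kf.update(tpos(i) + sd_v * e_vis(i), 1.0, 0.0, sigma_v2);
    }
    double ui = -(Lp * (th - kf.x(0)) + Lv * (thd - kf.x(1)));
    theta(i) = th;
    theta_dot(i) = thd;
    u(i) = ui;
    t_est(i) = kf.x(0);
    th += thd * dt;
    thd += ui * dt / inertia;
    kf.predict(dt, sigma_mu2);
    if (bad(th) || bad(thd)) { diverged = true; break; }
  }
  return List::create(_["theta"] = theta, _["theta_dot"] = theta_dot,
                      _["u"] = u, _["t_est"] = t_est,
                      _["diverged"] = diverged);
}

// Haptic-only tracking: the target is invisible; the wrist is coupled to it
// by a spring (K, D) whose force is both felt (observation, with sensor
// noise) and applied to the plant.
// [[Rcpp::export]]
List sim_haptic_cpp(const arma::vec& tpos, const arma::vec& tvel, double dt,
                    double inertia, double Lp, double Lv, double K, double D,
                    double sigma_f2, double sigma_mu2,
                    const arma::vec& e_frc, int frc_every) {
  int n = tpos.n_elem;
  arma::vec theta(n), theta_dot(n), u(n), t_est(n), force(n);
  double th = 0.0, thd = 0.0;
  double sd_f = std::sqrt(sigma_f2);
  Kf2 kf;
  kf.init(0.0, 0.0, 0.3, 0.05);
  bool diverged = false;
  for (int i = 0; i < n; ++i) {
    double F = K * (tpos(i) - th) + D * (tvel(i) - thd);
    // observation z = K (t - th) + D (td - thd) + noise; in target-state
    // coordinates H = [K, D] with known offset -(K th + D thd)
    if (frc_every <= 1 || i % frc_every == 0) {
      double z = F + sd_f * e_frc(i);
      double pred = K * (kf.x(0) - th) + D * (kf.x(1) - thd);
      kf.update(z - pred + (K * kf.x(0) + D * kf.x(1)), K, D, sigma_f2);
    }
    double ui = -(Lp * (th - kf.x(0)) + Lv * (thd - kf.x(1)));
    theta(i) = th;
    theta_dot(i) = thd;
    u(i) = ui;
    t_est(i) = kf.x(0);
    force(i) = F;
    th += thd * dt;
    thd += (ui + F) * dt / inertia;
    kf.predict(dt, sigma_mu2);
    if (bad(th) || bad(thd)) { diverged = true; break; }
  }
  return List::create(_["theta"] = theta, _["theta_dot"] = theta_dot,
                      _["u"] = u, _["t_est"] = t_est, _["force"] = force,
                      _["diverged"] = diverged);
}

// Coupled dyad simulation.
// strategy: 0 follow-the-leader, 1 goal integration / neuromechanical goal
// sharing (the two differ only in hap_var / hap_noise_var, which carry the
// stiffness-dependent channel noise sigma_s^2 for the neuromechanical model).
// [[Rcpp::export]]
List sim_dyad_cpp(const arma::vec& tpos, const arma::vec& tvel, double dt,
                  int strategy, double K, double D, int burn_steps,
                  const List& agent1, const List& agent2,
                  const arma::mat& e_vis, const arma::mat& e_frc,
                  const arma::mat& e_hap, double q_acc, double q_gain_rel,
                  double gain_prior_rel, double sub_var, double q_tvel_mult,
                  int hap_every, double f_comp, int vis_every) {
  int n = tpos.n_elem;
  List agents[2] = {agent1, agent2};
  double inertia[2], Lp[2], Lv[2], sigma_v2[2], sigma_mu2[2], sigma_f2[2],
      hap_var[2], hap_noise_sd[2], lp0[2], lv0[2];
  for (int a = 0; a < 2; ++a) {
    List ag = agents[a];
    inertia[a] = as<double>(ag["inertia"]);
    Lp[a] = as<double>(ag["Lp"]);
    Lv[a] = as<double>(ag["Lv"]);
    sigma_v2[a] = as<double>(ag["sigma_v2"]);
    sigma_mu2[a] = as<double>(ag["sigma_mu2"]);
    sigma_f2[a] = as<double>(ag["sigma_f2"]);
    hap_var[a] = as<double>(ag["hap_var"]);
    hap_noise_sd[a] = std::sqrt(as<double>(ag["hap_noise_var"]));
    lp0[a] = as<double>(ag["gain_init_p"]);
    lv0[a] = as<double>(ag["gain_init_v"]);
  }
  double th[2] = {0.0, 0.0}, thd[2] = {0.0, 0.0};
  Kf2 own[2];
  EkfPartner ekf[2];
  double pth_prev[2] = {0.0, 0.0}, pthd_est[2] = {0.0, 0.0};
  double alpha = std::exp(-dt / 0.05);  // partner-velocity smoothing, 50 ms
  for (int a = 0; a < 2; ++a) {
    own[a].init(0.0, 0.0, 0.3, 0.05);
    ekf[a].q_acc = q_acc;
    ekf[a].q_gp = std::pow(q_gain_rel * std::max(std::abs(lp0[a]), 1.0), 2);
    ekf[a].q_gv = std::pow(q_gain_rel * std::max(std::abs(lv0[a]), 1.0), 2);
    // the partner-target state tracks the partner's (jittery) goal
    // estimate, which diffuses much faster than the target model proper
    ekf[a].q_tvel = sigma_mu2[a] * q_tvel_mult;
    ekf[a].init(0.0, 0.0, lp0[a], lv0[a], 0.0, 0.0, gain_prior_rel);
  }
  arma::mat theta(n, 2), u(n, 2), t_fused(n, 2), t_tilde(n, 2);
  arma::mat gains_p(n, 2), gains_v(n, 2);
  arma::vec force1(n);
  bool diverged = false;
  bool use_ekf = (strategy >= 1) && (K > 0.0);
  for (int i = 0; i < n && !diverged; ++i) {
    double F[2];
    F[0] = K * (th[1] - th[0]) + D * (thd[1] - thd[0]);
    F[1] = -F[0];
    double ui[2];
    for (int a = 0; a < 2; ++a) {
      bool vis_frame = (vis_every <= 1 || i % vis_every == 0);
      bool follow_partner = false;
      double pth = 0.0;
      if (strategy == 0 && K > 0.0) {
        // follow the leader: the observation itself switches (partner's
        // wrist replaces the target), so while following the partner no
        // visual information about the target is received
        pth = th[a] + F[a] / K;
        if (i > 0) {
          pthd_est[a] = alpha * pthd_est[a] +
                        (1.0 - alpha) * (pth - pth_prev[a]) / dt;
        }
        pth_prev[a] = pth;
        double e_self = std::abs(th[a] - own[a].x(0));
        double e_part = std::abs(pth - own[a].x(0));
        follow_partner = e_self > e_part;
      }
      if (vis_frame && !follow_partner) {
        own[a].update(tpos(i) + std::sqrt(sigma_v2[a]) * e_vis(i, a), 1.0,
                      0.0, sigma_v2[a]);
      }
      if (use_ekf) {
        double f_obs = F[a] + std::sqrt(sigma_f2[a]) * e_frc(i, a);
        ekf[a].update_force(f_obs, th[a], thd[a], K, D, sigma_f2[a]);
        if (i < burn_steps) {
          ekf[a].update_target_sub(own[a].x(0), own[a].x(1), sub_var);
        } else {
          // the partner-goal channel carries one independent sample's worth
          // of information per refresh interval; it is fused smoothly by
          // spreading that information over every step (variance and
          // injected noise scaled by the window), which avoids estimate
          // jumps the controller would chase. Channel variance: partner's
          // visual noise + coupling-softness term + the filter's own
          // uncertainty about the partner's goal.
          double m = std::max(hap_every, 1);
          double zh = ekf[a].x(4) +
                      std::sqrt(m) * hap_noise_sd[a] * e_hap(i, a);
          own[a].update(zh, 1.0, 0.0,
                        m * (hap_var[a] + ekf[a].P(4, 4)));
        }
      }
      double ref_p = own[a].x(0), ref_v = own[a].x(1);
      if (follow_partner) {
        ref_p = pth;
        ref_v = pthd_est[a];
      }
      // feedforward compensation of the measured coupling force: a known
      // disturbance input the LQG controller cancels (f_comp = 1) or
      // ignores (f_comp = 0); the compensation torque is part of the effort
      ui[a] = -(Lp[a] * (th[a] - ref_p) + Lv[a] * (thd[a] - ref_v)) -
              f_comp * F[a];
      theta(i, a) = th[a];
      u(i, a) = ui[a];
      t_fused(i, a) = own[a].x(0);
      t_tilde(i, a) = ekf[a].x(4);
      gains_p(i, a) = ekf[a].x(2);
      gains_v(i, a) = ekf[a].x(3);
    }
    force1(i) = F[0];
    for (int a = 0; a < 2; ++a) {
      th[a] += thd[a] * dt;
      thd[a] += (ui[a] + F[a]) * dt / inertia[a];
      own[a].predict(dt, sigma_mu2[a]);
      if (use_ekf) {
        // the partner feels the spring reaction -F[a]; whatever they do not
        // cancel (1 - f_comp) is a known input to the internal partner model
        ekf[a].predict(dt, -(1.0 - f_comp) * F[a] / inertia[a == 0 ? 1 : 0]);
        ekf[a].heal(lp0[a], lv0[a], gain_prior_rel);
      }
      if (bad(th[a]) || bad(thd[a])) diverged = true;
    }
  }
  return List::create(_["theta"] = theta, _["u"] = u, _["force1"] = force1,
                      _["t_fused"] = t_fused, _["t_tilde"] = t_tilde,
                      _["gains_p"] = gains_p, _["gains_v"] = gains_v,
                      _["diverged"] = diverged);
}

// Offline EKF over recorded histories: identification of the partner's
// feedback gains and inference of their target from proprioception + the
// interaction force only.
// sub_until: steps during which the substituted target (t_sub) clamps the
// partner-target states (identification); afterwards the target states are
// free (inference).
// [[Rcpp::export]]
List ekf_partner_cpp(const arma::vec& force, const arma::vec& th_own,
                     const arma::vec& thd_own, const arma::vec& t_sub_pos,
                     const arma::vec& t_sub_vel, const arma::vec& a_known,
                     double dt, double K, double D, double sigma_f2,
                     int sub_until, double lp0, double lv0, double q_acc,
                     double q_gain_rel, double gain_prior_rel, double sub_var,
                     double q_tvel) {
  int n = force.n_elem;
  EkfPartner ekf;
  ekf.q_acc = q_acc;
  ekf.q_gp = std::pow(q_gain_rel * std::max(std::abs(lp0), 1.0), 2);
  ekf.q_gv = std::pow(q_gain_rel * std::max(std::abs(lv0), 1.0), 2);
  ekf.q_tvel = q_tvel;
  double pth0 = (K > 0.0) ? th_own(0) + force(0) / K : th_own(0);
  ekf.init(pth0, 0.0, lp0, lv0, t_sub_pos(0), t_sub_vel(0), gain_prior_rel);
  arma::mat gains(n, 2), wrist(n, 2), target(n, 2);
  arma::vec cov_gain(n);
  for (int i = 0; i < n; ++i) {
    ekf.update_force(force(i), th_own(i), thd_own(i), K, D, sigma_f2);
    if (i < sub_until) {
      ekf.update_target_sub(t_sub_pos(i), t_sub_vel(i), sub_var);
    }
    gains(i, 0) = ekf.x(2);
    gains(i, 1) = ekf.x(3);
    wrist(i, 0) = ekf.x(0);
    wrist(i, 1) = ekf.x(1);
    target(i, 0) = ekf.x(4);
    target(i, 1) = ekf.x(5);
    cov_gain(i) = ekf.P(2, 2) + ekf.P(3, 3);
    ekf.predict(dt, a_known(i));
    ekf.heal(lp0, lv0, gain_prior_rel);
  }
  return List::create(_["gains"] = gains, _["wrist"] = wrist,
                      _["target"] = target, _["cov_gain"] = cov_gain);
}
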