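// Closed-loop simulation core for the 2-DOF inverted-pendulum body.
//
// Generalized coordinates: r (leg extension, prismatic) and theta (ankle
// angle from vertical, +forward). COM: x = r sin(theta), y = r cos(theta).
// Equations of motion (point mass m, generalized forces F_r along the leg
// and tau at the ankle, external horizontal force Fx at the COM):
//   r''     = r th'^2 - g cos(th) + (F_r + Fx sin(th)) / m
//   theta'' = g sin(th)/r - 2 r' th'/r + (tau + Fx r cos(th)) / (m r^2)
// The backward perturbation is Fx = -K * max(y', 0) * m.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Body {
  double m, g, K;
};

static inline double ydot_of(double r, double th, double rd, double thd) {
  return rd * std::cos(th) - r * thd * std::sin(th);
}

static inline double pert_fx(double yd, const Body& b) {
  // signed horizontal force; backward (-x) when the COM rises
  return yd > 0.0 ? -b.K * yd * b.m : 0.0;
}

static inline void gen_accel(double r, double th, double rd, double thd,
                             double Fr, double tau, double Fx, const Body& b,
                             double& rdd, double& thdd) {
  rdd = r * thd * thd - b.g * std::cos(th) + (Fr + Fx * std::sin(th)) / b.m;
  thdd = (b.g * std::sin(th)) / r - 2.0 * rd * thd / r +
         (tau + Fx * r * std::cos(th)) / (b.m * r * r);
}

static inline void cart_accel(double r, double th, double rd, double thd,
                              double rdd, double thdd, double& ax, double& ay) {
  const double s = std::sin(th), c = std::cos(th);
  ax = rdd * s + 2.0 * rd * thd * c + r * thdd * c - r * thd * thd * s;
  ay = rdd * c - 2.0 * rd * thd * s - r * thdd * s - r * thd * thd * c;
}

// exact inverse dynamics of the unperturbed body: commands realizing the
// desired Cartesian COM acceleration at the given state
static inline void inv_dyn(double r, double th, double rd, double thd,
                           double ax, double ay, const Body& b,
                           double& Fr, double& tau) {
  const double s = std::sin(th), c = std::cos(th);
  const double h1 = 2.0 * rd * thd * c - r * thd * thd * s;
  const double h2 = -2.0 * rd * thd * s - r * thd * thd * c;
  const double u = ax - h1, v = ay - h2;
  const double rdd = s * u + c * v;
  const double thdd = (c * u - s * v) / r;
  Fr = b.m * (rdd - r * thd * thd + b.g * c);
  tau = b.m * r * r * thdd + 2.0 * b.m * r * rd * thd - b.m * b.g * r * s;
}

static inline void deriv(const double st[4], double Fr, double tau,
                         bool pert, const Body& b, double out[4]) {
  double yd = ydot_of(st[0], st[1], st[2], st[3]);
  double Fx = pert ? pert_fx(yd, b) : 0.0;
  double rdd, thdd;
  gen_accel(st[0], st[1], st[2], st[3], Fr, tau, Fx, b, rdd, thdd);
  out[0] = st[2];
  out[1] = st[3];
  out[2] = rdd;
  out[3] = thdd;
}

static inline void rk4_step(double st[4], double Fr, double tau, bool pert,
                            const Body& b, double dt) {
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  deriv(st, Fr, tau, pert, b, k1);
  for (int j = 0; j < 4; ++j) tmp[j] = st[j] + 0.5 * dt * k1[j];
  deriv(tmp, Fr, tau, pert, b, k2);
  for (int j = 0; j < 4; ++j) tmp[j] = st[j] + 0.5 * dt * k2[j];
  deriv(tmp, Fr, tau, pert, b, k3);
  for (int j = 0; j < 4; ++j) tmp[j] = st[j] + dt * k3[j];
  deriv(tmp, Fr, tau, pert, b, k4);
  for (int j = 0; j < 4; ++j)
    st[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
}

static inline bool state_ok(const double st[4]) {
  for (int j = 0; j < 4; ++j)
    if (!std::isfinite(st[j])) return false;
  return st[0] > 0.2 && st[0] < 1.8 && std::fabs(st[1]) < 1.2;
}

// [[Rcpp::export(name = ".sim_trial_cpp")]]
List sim_trial_cpp(NumericMatrix ref, NumericVector state0, NumericMatrix W,
                   double err_trace, List par) {
  const Body b{as<double>(par["mass"]), as<double>(par["gravity"]),
               as<double>(par["K"])};
  const bool pert = b.K > 0.0;
  const double dt = as<double>(par["dt"]);
  const double f_max = as<double>(par["f_max"]);
  const double tau_max = as<double>(par["tau_max"]);
  const double kpx = as<double>(par["kp_x"]), kpy = as<double>(par["kp_y"]);
  const double kdx = as<double>(par["kd_x"]), kdy = as<double>(par["kd_y"]);
  const double cap = as<double>(par["mult_cap"]);
  const double cscale = as<double>(par["mult_scale"]);
  const double eta = as<double>(par["eta"]);
  const double lambda = as<double>(par["lambda"]);
  const bool learn = as<bool>(par["learn"]);

  const int n = ref.nrow();
  NumericMatrix traj(n, 8);   // t x y xd yd xdd ydd zmp
  NumericMatrix cmds(n, 2);   // F_r tau (net)
  NumericVector mult(n);
  NumericMatrix Wout(clone(W));
  double trace2 = err_trace * err_trace;

  double st[4] = {state0[0], state0[1], state0[2], state0[3]};
  int n_valid = n;
  bool diverged = false;

  for (int i = 0; i < n; ++i) {
    const double r = st[0], th = st[1], rd = st[2], thd = st[3];
    const double s = std::sin(th), c = std::cos(th);
    const double x = r * s, y = r * c;
    const double xd = rd * s + r * thd * c;
    const double yd = rd * c - r * thd * s;

    // feature basis of the additive internal-model term; the last two carry
    // the shapes of the pull's generalized forces
    double phi[8] = {1.0, r, th, rd, thd, yd, yd * s, yd * r * c};
    double dFr = 0.0, dTau = 0.0;
    for (int j = 0; j < 8; ++j) {
      dFr += Wout(0, j) * phi[j];
      dTau += Wout(1, j) * phi[j];
    }

    // feed-forward: exact unperturbed inverse dynamics + learned additive term
    double Fr0, tau0;
    inv_dyn(r, th, rd, thd, ref(i, 4), ref(i, 5), b, Fr0, tau0);

    // feedback: scaled PD on COM error, mapped through J^T
    const double g_mult = std::min(cap, cscale * std::sqrt(trace2));
    const double fx = g_mult * (kpx * (ref(i, 0) - x) + kdx * (ref(i, 2) - xd));
    const double fy = g_mult * (kpy * (ref(i, 1) - y) + kdy * (ref(i, 3) - yd));
    const double Qr_fb = s * fx + c * fy;
    const double Qth_fb = r * c * fx - r * s * fy;

    double Fr = Fr0 + dFr + Qr_fb;
    double tau = tau0 + dTau + Qth_fb;
    if (Fr > f_max) Fr = f_max;
    if (Fr < -f_max) Fr = -f_max;
    if (tau > tau_max) tau = tau_max;
    if (tau < -tau_max) tau = -tau_max;

    // true accelerations under the net command (ideal acceleration sensing)
    const double Fx = pert ? pert_fx(yd, b) : 0.0;
    double rdd, thdd, ax, ay;
    gen_accel(r, th, rd, thd, Fr, tau, Fx, b, rdd, thdd);
    cart_accel(r, th, rd, thd, rdd, thdd, ax, ay);

    // ground-reaction ZMP; the pull acts at the COM so its reaction enters
    double denom = ay + b.g;
    if (denom < 1e-3) denom = 1e-3;
    const double zmp = x - y * (ax - Fx / b.m) / denom;

    traj(i, 0) = i * dt;
    traj(i, 1) = x;
    traj(i, 2) = y;
    traj(i, 3) = xd;
    traj(i, 4) = yd;
    traj(i, 5) = ax;
    traj(i, 6) = ay;
    traj(i, 7) = zmp;
    cmds(i, 0) = Fr;
    cmds(i, 1) = tau;
    mult[i] = g_mult;

    if (learn) {
      // model-predicted acceleration for the applied command
      double rddh, thddh, axh, ayh;
      gen_accel(r, th, rd, thd, Fr - dFr, tau - dTau, 0.0, b, rddh, thddh);
      cart_accel(r, th, rd, thd, rddh, thddh, axh, ayh);
      const double eax = ax - axh, eay = ay - ayh;
      trace2 = lambda * trace2 + (1.0 - lambda) * (eax * eax + eay * eay);

      // command-space error: what the model would have prescribed for the
      // observed acceleration versus what was actually applied
      double Frn, taun;
      inv_dyn(r, th, rd, thd, ax, ay, b, Frn, taun);
      const double euF = Fr - (Frn + dFr);
      const double euT = tau - (taun + dTau);
      double p2 = 0.0;
      for (int j = 0; j < 8; ++j) p2 += phi[j] * phi[j];
      const double gain = eta / (1.0 + p2);
      for (int j = 0; j < 8; ++j) {
        Wout(0, j) += gain * euF * phi[j];
        Wout(1, j) += gain * euT * phi[j];
      }
    }

    rk4_step(st, Fr, tau, pert, b, dt);
    if (!state_ok(st)) {
      n_valid = i + 1;
      diverged = true;
      break;
    }
  }

  if (n_valid < n) {
    traj = traj(Range(0, n_valid - 1), _);
    cmds = cmds(Range(0, n_valid - 1), _);
    mult = mult[Range(0, n_valid - 1)];
  }

  return List::create(_["traj"] = traj, _["cmds"] = cmds, _["mult"] = mult,
                      _["W"] = Wout, _["err_trace"] = std::sqrt(trace2),
                      _["n_valid"] = n_valid, _["truncated"] = diverged,
                      _["final_state"] = NumericVector::create(st[0], st[1],
                                                               st[2], st[3]));
}

// [[Rcpp::export(name = ".sim_openloop_cpp")]]
List sim_openloop_cpp(NumericMatrix cmds, NumericVector state0, List par) {
  const Body b{as<double>(par["mass"]), as<double>(par["gravity"]),
               as<double>(par["K"])};
  const bool pert = b.K > 0.0;
  const double dt = as<double>(par["dt"]);
  const int n = cmds.nrow();
  NumericMatrix traj(n, 8);
  double st[4] = {state0[0], state0[1], state0[2], state0[3]};
  int n_valid = n;
  bool diverged = false;

  for (int i = 0; i < n; ++i) {
    const double r = st[0], th = st[1], rd = st[2], thd = st[3];
    const double s = std::sin(th), c = std::cos(th);
    const double x = r * s, y = r * c;
    const double xd = rd * s + r * thd * c;
    const double yd = rd * c - r * thd * s;
    const double Fx = pert ? pert_fx(yd, b) : 0.0;
    double rdd, thdd, ax, ay;
    gen_accel(r, th, rd, thd, cmds(i, 0), cmds(i, 1), Fx, b, rdd, thdd);
    cart_accel(r, th, rd, thd, rdd, thdd, ax, ay);
    double denom = ay + b.g;
    if (denom < 1e-3) denom = 1e-3;
    traj(i, 0) = i * dt;
    traj(i, 1) = x;
    traj(i, 2) = y;
    traj(i, 3) = xd;
    traj(i, 4) = yd;
    traj(i, 5) = ax;
    traj(i, 6) = ay;
    traj(i, 7) = x - y * (ax - Fx / b.m) / denom;
    rk4_step(st, cmds(i, 0), cmds(i, 1), pert, b, dt);
    if (!state_ok(st)) {
      n_valid = i + 1;
      diverged = true;
      break;
    }
  }
  if (n_valid < n) traj = traj(Range(0, n_valid - 1), _);
  return List::create(_["traj"] = traj, _["n_valid"] = n_valid,
                      _["truncated"] = diverged,
                      _["final_state"] = NumericVector::create(st[0], st[1],
                                                               st[2], st[3]));
}
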