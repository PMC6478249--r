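#include <Rcpp.h>
using namespace Rcpp;

// Core trial stepper for the coin game.
//
// Horizontal coin dynamics per step of length dt:
//   x' = x_def + (x - x_def) * exp(-lambda * dt) + eps + pressed * dir * N(mu_k, sigma_k)
// with eps ~ N(0, sigma_walk * sqrt(dt)), the result clamped to [0, 1].
// A walk draw is consumed every step (even when sigma_walk == 0) so that the
// R-level step_coin() reference consumes the RNG stream identically.
//
// policy_kind: 0 = absent (never press), 1 = ideal bang-bang controller
// (press at the policy rate whenever the coin is outside the desired window
// on the default-target side), 2 = free-running stochastic responder
// (press with probability rate * dt at each step once t >= latency).

// [[Rcpp::export]]
List sim_trials_cpp(IntegerVector policy_kind,
                    NumericVector press_rate,
                    NumericVector latency,
                    IntegerVector press_dir,
                    NumericVector x_start,
                    NumericVector x_default,
                    NumericVector x_desired,
                    double dt,
                    double response_duration,
                    double lambda,
                    double sigma_walk,
                    double press_mu,
                    double press_sigma,
                    double window_halfwidth,
                    bool store_trajectory = false) {
  int n_trials = policy_kind.size();
  int n_steps = (int)std::round(response_duration / dt);
  double decay = std::exp(-lambda * dt);
  double walk_sd = sigma_walk * std::sqrt(dt);

  List press_times(n_trials);
  NumericVector final_x(n_trials);
  List traj(store_trajectory ? n_trials : 0);

  for (int i = 0; i < n_trials; ++i) {
    double x = x_start[i];
    double xd = x_default[i];
    double xg = x_desired[i];
    int dir = press_dir[i];
    int kind = policy_kind[i];
    double rate = press_rate[i];
    double lat = latency[i];
    double min_gap = (rate > 0) ? 1.0 / rate : R_PosInf;
    double p_press = rate * dt;
    double last_press = -1e12;

    std::vector<double> times;
    NumericVector tr(store_trajectory ? (n_steps + 1) : 0);
    if (store_trajectory) tr[0] = x;

    for (int s = 0; s < n_steps; ++s) {
      double t = s * dt;
      bool press = false;
      if (kind == 1) {
        bool outside = (dir != 0) && (dir * (xg - x) > window_halfwidth);
        press = outside && (t - last_press >= min_gap - 1e-12);
      } else if (kind == 2) {
        if (t >= lat && p_press > 0.0) press = (unif_rand() < p_press);
      }
      double eps = norm_rand() * walk_sd;
      double xn = xd + (x - xd) * decay + eps;
      if (press) {
        double delta = press_mu + press_sigma * norm_rand();
        xn += dir * delta;
        times.push_back(t);
        last_press = t;
      }
      x = std::min(1.0, std::max(0.0, xn));
      if (store_trajectory) tr[s + 1] = x;
    }
    press_times[i] = wrap(times);
    final_x[i] = x;
    if (store_trajectory) traj[i] = tr;
  }
  return List::create(_["press_times"] = press_times,
                      _["final_x"] = final_x,
                      _["trajectory"] = traj);
}
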