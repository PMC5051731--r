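#include <Rcpp.h>
using namespace Rcpp;

// Sigmoid drift-field weight. `r` is measured from the field's origin
// (chromatin edge for the attractive field, cell boundary for the repulsive
// one). r_half = +Inf gives the degenerate all-drift field (weight 1).
static inline double field_weight_c(double r, double r_half, double s) {
  return 1.0 / (1.0 + std::exp((r - r_half) / s));
}

// Random walk in a drift field, one particle at a time so that a fixed R
// seed yields bit-identical output. Exactly one uniform deviate is consumed
// per step (the Brownian angle), keeping the RNG stream layout simple.
//
// Coordinates are cell-centred Cartesian (um). A particle is captured when
// its radial distance drops to <= r_chr; the crossing sample is recorded and
// the track ends. The cortex reflects (radial mirror). With open_domain the
// walk is free (no cortex, no capture) -- used for timestep validation.
// [[Rcpp::export]]
List rwd_simulate_cpp(int n_p, double total_time, double dt,
                      double r_cell, double r_chr,
                      double d_eff, double v_eff,
                      bool a_on, double a_rhalf, double a_s,
                      bool r_on, double r_rhalf, double r_s,
                      double record_interval, bool open_domain,
                      NumericVector x_start, NumericVector y_start) {
  const int n_steps = (int)std::lround(total_time / dt);
  const int rec_every = std::max(1, (int)std::lround(record_interval / dt));
  const double v_brown = (d_eff > 0.0) ? std::sqrt(4.0 * d_eff / dt) : 0.0;
  const bool custom_start = x_start.size() > 0;

  std::vector<int> out_id;
  std::vector<double> out_t, out_x, out_y;
  NumericVector t_c(n_p, NA_REAL), d_n(n_p), xs0(n_p), ys0(n_p);
  // rough preallocation: recorded samples per particle
  out_id.reserve((size_t)n_p * (n_steps / rec_every + 2));
  out_t.reserve(out_id.capacity());
  out_x.reserve(out_id.capacity());
  out_y.reserve(out_id.capacity());

  for (int p = 0; p < n_p; ++p) {
    double x, y;
    if (custom_start) {
      x = x_start[p]; y = y_start[p];
    } else {
      // uniform by area over the cytoplasmic annulus
      double u = R::runif(0.0, 1.0);
      double rr = std::sqrt(r_chr * r_chr + u * (r_cell * r_cell - r_chr * r_chr));
      double th = R::runif(0.0, 2.0 * M_PI);
      x = rr * std::cos(th); y = rr * std::sin(th);
    }
    xs0[p] = x; ys0[p] = y;
    d_n[p] = std::max(0.0, std::hypot(x, y) - r_chr);

    out_id.push_back(p + 1); out_t.push_back(0.0);
    out_x.push_back(x); out_y.push_back(y);

    for (int step = 1; step <= n_steps; ++step) {
      double r = std::hypot(x, y);
      double phi_a = a_on ? field_weight_c(std::max(0.0, r - r_chr), a_rhalf, a_s) : 0.0;
      double phi_r = r_on ? field_weight_c(std::max(0.0, r_cell - r), r_rhalf, r_s) : 0.0;

      double speed = phi_a * v_eff +
        (1.0 - phi_a) * (phi_r * v_eff + (1.0 - phi_r) * v_brown);

      double theta_df = R::runif(0.0, 2.0 * M_PI);
      double cx, cy;
      if (r > 0.0) {
        double cdr = -x / r, sdr = -y / r;  // unit vector toward the centre
        // cortical mixture first (phi_r against Brownian), then phi_a
        double icx = phi_r * cdr + (1.0 - phi_r) * std::cos(theta_df);
        double icy = phi_r * sdr + (1.0 - phi_r) * std::sin(theta_df);
        double n = std::hypot(icx, icy);
        if (n > 0.0) { icx /= n; icy /= n; }
        cx = phi_a * cdr + (1.0 - phi_a) * icx;
        cy = phi_a * sdr + (1.0 - phi_a) * icy;
        double m = std::hypot(cx, cy);
        if (m > 0.0) { cx /= m; cy /= m; } else { cx = std::cos(theta_df); cy = std::sin(theta_df); }
      } else {
        cx = std::cos(theta_df); cy = std::sin(theta_df);
      }

      x += speed * dt * cx;
      y += speed * dt * cy;

      double t_now = step * dt;
      if (!open_domain) {
        double rn = std::hypot(x, y);
        if (rn > r_cell) {  // radial mirror reflection
          double rref = 2.0 * r_cell - rn;
          if (rref < 0.0) rref = 0.0;
          x *= rref / rn; y *= rref / rn;
          rn = rref;
        }
        if (rn <= r_chr) {  // captured: record crossing sample, end track
          out_id.push_back(p + 1); out_t.push_back(t_now);
          out_x.push_back(x); out_y.push_back(y);
          t_c[p] = t_now;
          break;
        }
      }
      if (step % rec_every == 0) {
        out_id.push_back(p + 1); out_t.push_back(t_now);
        out_x.push_back(x); out_y.push_back(y);
      }
    }
  }

  return List::create(
    _["track_id"] = wrap(out_id), _["t_s"] = wrap(out_t),
    _["x_um"] = wrap(out_x), _["y_um"] = wrap(out_y),
    _["t_c"] = t_c, _["d_n"] = d_n, _["x0"] = xs0, _["y0"] = ys0);
}
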