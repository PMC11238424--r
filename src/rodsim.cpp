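#include <Rcpp.h>
using namespace Rcpp;

// Closest points between two 2D segments p1 +/- e1 and p2 +/- e2
// (centers p, half-extent vectors e). Returns squared distance and the
// axis parameters s, t in [-1, 1] of the closest points.
static double segseg_closest(double p1x, double p1y, double e1x, double e1y,
                             double p2x, double p2y, double e2x, double e2y,
                             double& s, double& t) {
  // parameterize P(s) = p1 + s*e1, Q(t) = p2 + t*e2, s,t in [-1,1]
  double rx = p1x - p2x, ry = p1y - p2y;
  double a = e1x * e1x + e1y * e1y;
  double e = e2x * e2x + e2y * e2y;
  double b = e1x * e2x + e1y * e2y;
  double c = e1x * rx + e1y * ry;
  double f = e2x * rx + e2y * ry;
  double denom = a * e - b * b;
  if (a < 1e-14 && e < 1e-14) { s = t = 0.0; }
  else if (a < 1e-14) { s = 0.0; t = std::max(-1.0, std::min(1.0, -f / e)); }
  else if (e < 1e-14) { t = 0.0; s = std::max(-1.0, std::min(1.0, -c / a)); }
  else {
    if (denom > 1e-14 * a * e)
      s = std::max(-1.0, std::min(1.0, (b * f - c * e) / denom));
    else
      s = 0.0; // near-parallel: pick midpoint, then clamp t
    t = (b * s - f) / e;
    if (t > 1.0) { t = 1.0; s = std::max(-1.0, std::min(1.0, (b - c) / a)); }
    else if (t < -1.0) { t = -1.0; s = std::max(-1.0, std::min(1.0, (-b - c) / a)); }
  }
  double dx = rx + s * e1x - t * e2x;
  double dy = ry + s * e1y - t * e2y;
  return dx * dx + dy * dy;
}

static inline void wrap_nematic(double& th, double& v) {
  // keep angle in [-pi/2, pi/2); flipping the representative flips the
  // polarity carried by the signed speed
  while (th >= M_PI_2) { th -= M_PI; v = -v; }
  while (th < -M_PI_2) { th += M_PI; v = -v; }
}

// Overdamped self-propelled growing rods in a circular well.
// Emits one state per frame interval, starting at t = 0.
// [[Rcpp::export]]
List simulate_rods_cpp(NumericVector x0, NumericVector y0, NumericVector th0,
                       NumericVector len0, NumericVector sp0,
                       IntegerVector id0, IntegerVector parent0,
                       double width, double well_radius,
                       double mobility, double k_rep, double k_wall,
                       double noise_trans, double noise_rot,
                       double growth_rate, double division_length,
                       double v0, double speed_sd, double division_kick,
                       double dt, double frame_interval, int n_frames,
                       bool wall_reversal) {
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> th(th0.begin(), th0.end());
  std::vector<double> len(len0.begin(), len0.end());
  std::vector<double> sp(sp0.begin(), sp0.end());
  std::vector<int> id(id0.begin(), id0.end());
  std::vector<int> parent(parent0.begin(), parent0.end());
  int next_id = 0;
  for (size_t i = 0; i < id.size(); ++i) next_id = std::max(next_id, id[i]);
  ++next_id;

  int steps_per_frame = std::max(1, (int)std::lround(frame_interval / dt));
  double sq2Dt = std::sqrt(2.0 * noise_trans * dt);
  double sq2Dr = std::sqrt(2.0 * noise_rot * dt);
  List frames(n_frames);

  for (int fr = 0; fr < n_frames; ++fr) {
    int n = (int)x.size();
    // emit current state
    {
      NumericVector ox(n), oy(n), oth(n), olen(n), osp(n);
      IntegerVector oid(n), opar(n);
      for (int i = 0; i < n; ++i) {
        if (!R_finite(x[i]) || !R_finite(y[i]) || !R_finite(th[i]))
          stop("non-finite rod state at frame %d: reduce the time step (dt = %g s)", fr, dt);
        ox[i] = x[i]; oy[i] = y[i]; oth[i] = th[i];
        olen[i] = len[i]; osp[i] = sp[i]; oid[i] = id[i]; opar[i] = parent[i];
      }
      frames[fr] = List::create(_["x"] = ox, _["y"] = oy, _["angle"] = oth,
                                _["length"] = olen, _["speed"] = osp,
                                _["id"] = oid, _["parent"] = opar,
                                _["time"] = fr * frame_interval);
    }
    if (fr == n_frames - 1) break;

    for (int step = 0; step < steps_per_frame; ++step) {
      int m = (int)x.size();
      std::vector<double> fx(m, 0.0), fy(m, 0.0), tq(m, 0.0);
      // pairwise soft spherocylinder repulsion + torque from lever arm
      if (k_rep > 0.0) {
        for (int i = 0; i < m; ++i) {
          double ai = std::max((len[i] - width) / 2.0, 0.0);
          double e1x = ai * std::cos(th[i]), e1y = ai * std::sin(th[i]);
          for (int j = i + 1; j < m; ++j) {
            double cd = std::hypot(x[i] - x[j], y[i] - y[j]);
            if (cd > (len[i] + len[j]) / 2.0 + width) continue;
            double aj = std::max((len[j] - width) / 2.0, 0.0);
            double e2x = aj * std::cos(th[j]), e2y = aj * std::sin(th[j]);
            double s, t;
            double d2 = segseg_closest(x[i], y[i], e1x, e1y,
                                       x[j], y[j], e2x, e2y, s, t);
            double d = std::sqrt(d2);
            double overlap = width - d;
            if (overlap <= 0.0) continue;
            double nxv, nyv;
            if (d > 1e-9) {
              nxv = (x[i] + s * e1x - x[j] - t * e2x) / d;
              nyv = (y[i] + s * e1y - y[j] - t * e2y) / d;
            } else { // coincident contact points: random push
              double ang = unif_rand() * 2.0 * M_PI;
              nxv = std::cos(ang); nyv = std::sin(ang);
            }
            double fmag = k_rep * overlap;
            double Fx = fmag * nxv, Fy = fmag * nyv;
            fx[i] += Fx; fy[i] += Fy;
            fx[j] -= Fx; fy[j] -= Fy;
            // torques about rod centers (z components of lever x force)
            tq[i] += (s * e1x) * Fy - (s * e1y) * Fx;
            tq[j] -= (t * e2x) * Fy - (t * e2y) * Fx;
          }
        }
      }
      // wall confinement on centers; optionally reverse the run of a rod
      // pushing outward at the wall (keeps confined phantom rods mixed)
      double R_in = well_radius - width / 2.0;
      for (int i = 0; i < m; ++i) {
        double r = std::hypot(x[i], y[i]);
        if (r > R_in && r > 1e-12) {
          double fmag = k_wall * (r - R_in);
          fx[i] -= fmag * x[i] / r;
          fy[i] -= fmag * y[i] / r;
          if (wall_reversal &&
              sp[i] * (std::cos(th[i]) * x[i] + std::sin(th[i]) * y[i]) > 0.0)
            sp[i] = -sp[i];
        }
      }
      // integrate (Euler-Maruyama)
      for (int i = 0; i < m; ++i) {
        double mob_r = 12.0 * mobility / (len[i] * len[i]);
        x[i] += (sp[i] * std::cos(th[i]) + mobility * fx[i]) * dt;
        y[i] += (sp[i] * std::sin(th[i]) + mobility * fy[i]) * dt;
        th[i] += mob_r * tq[i] * dt;
        if (noise_trans > 0.0) { x[i] += sq2Dt * norm_rand(); y[i] += sq2Dt * norm_rand(); }
        if (noise_rot > 0.0) th[i] += sq2Dr * norm_rand();
        wrap_nematic(th[i], sp[i]);
        // hard cap: centers never leave the well
        double r = std::hypot(x[i], y[i]);
        if (r > well_radius) { x[i] *= well_radius / r; y[i] *= well_radius / r; }
        if (growth_rate > 0.0) len[i] *= std::exp(growth_rate * dt);
      }
      // divisions (after growth): symmetric midpoint split
      if (growth_rate > 0.0 && division_length > 0.0) {
        int m0 = (int)x.size();
        for (int i = 0; i < m0; ++i) {
          if (len[i] < division_length) continue;
          double L = len[i], cx = std::cos(th[i]), cy = std::sin(th[i]);
          double off = L / 4.0;
          int mother = id[i];
          // daughter 1 replaces the mother in place
          double th1 = th[i] + division_kick * norm_rand();
          double th2 = th[i] + division_kick * norm_rand();
          double v1 = (unif_rand() < 0.5 ? -1.0 : 1.0) * v0 * std::exp(speed_sd * norm_rand());
          double v2 = (unif_rand() < 0.5 ? -1.0 : 1.0) * v0 * std::exp(speed_sd * norm_rand());
          double x1 = x[i] + off * cx, y1 = y[i] + off * cy;
          double x2 = x[i] - off * cx, y2 = y[i] - off * cy;
          x[i] = x1; y[i] = y1; th[i] = th1; sp[i] = v1;
          len[i] = L / 2.0; id[i] = next_id++; parent[i] = mother;
          wrap_nematic(th[i], sp[i]);
          x.push_back(x2); y.push_back(y2); th.push_back(th2);
          len.push_back(L / 2.0); sp.push_back(v2);
          id.push_back(next_id++); parent.push_back(mother);
          wrap_nematic(th.back(), sp.back());
        }
      }
    }
  }
  return frames;
}
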