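#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Objective and analytic gradient of the coarse-grained multi-state
// Cartesian minimizer.  Coordinates are a flat vector laid out as an R array
// dim c(3, L, N): component d of bead i in state s sits at d + 3*i + 3*L*s.
//
// Terms:
//  - distance restraints on the r^-6 average over states of the bead-bead
//    distance (upper violated above the bound, lower/steric below);
//  - harmonic chain connectivity |x_{i+1}-x_i| -> bond_len per state;
//  - steric repulsion below steric_min between non-neighbour beads per state;
//  - flat-bottom bundling between corresponding beads of state pairs
//    (zero inside half-width, harmonic outside), weight per state pair.

static inline double dist3(const double* a, const double* b, double* u) {
  u[0] = a[0] - b[0]; u[1] = a[1] - b[1]; u[2] = a[2] - b[2];
  double d = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  if (d < 1e-9) d = 1e-9;
  return d;
}

// [[Rcpp::export(name = ".ms_objective_cpp")]]
List ms_objective_cpp(NumericVector coords, int L, int N,
                      IntegerVector r_i, IntegerVector r_j,
                      NumericVector r_bound, IntegerVector r_type,
                      NumericVector r_weight,
                      double bond_len, double w_chain,
                      double steric_min, double w_steric,
                      NumericMatrix bundle_w, double bundle_halfwidth,
                      NumericVector state_w) {
  const int nR = r_i.size();
  const double* x = coords.begin();
  NumericVector grad(coords.size());
  double* g = grad.begin();
  double energy = 0.0, e_restraint = 0.0;
  double u[3];
  std::vector<double> ds(N), inv1(N), inv6(N), ux(N), uy(N), uz(N);

  // distance restraints with r^-6 state averaging
  for (int r = 0; r < nR; ++r) {
    const int bi = r_i[r], bj = r_j[r];
    double m6 = 0.0;
    for (int s = 0; s < N; ++s) {
      const double* pi = x + 3 * (bi + L * s);
      const double* pj = x + 3 * (bj + L * s);
      double d = dist3(pi, pj, u);
      ds[s] = d;
      ux[s] = u[0]; uy[s] = u[1]; uz[s] = u[2];
      double inv = 1.0 / d, i2 = inv * inv, i6 = i2 * i2 * i2;
      inv1[s] = inv; inv6[s] = i6;
      m6 += state_w[s] * i6;
    }
    double dstar = std::pow(m6, -1.0 / 6.0);
    double excess = (r_type[r] == 0) ? (dstar - r_bound[r])
                                     : (r_bound[r] - dstar);
    if (excess <= 0.0) continue;
    double w = r_weight[r];
    energy += w * excess * excess;
    e_restraint += w * excess * excess;
    double dE_ddstar = (r_type[r] == 0 ? 2.0 : -2.0) * w * excess;
    double d3 = dstar * dstar * dstar;
    double d7 = d3 * d3 * dstar;
    for (int s = 0; s < N; ++s) {
      // d dstar / d d_s = w_s * (dstar/d_s)^7
      double f = dE_ddstar * d7 * inv6[s] * inv1[s] * state_w[s];
      double* gi = g + 3 * (bi + L * s);
      double* gj = g + 3 * (bj + L * s);
      double inv = inv1[s];
      double cx = f * ux[s] * inv, cy = f * uy[s] * inv,
             cz = f * uz[s] * inv;
      gi[0] += cx; gj[0] -= cx;
      gi[1] += cy; gj[1] -= cy;
      gi[2] += cz; gj[2] -= cz;
    }
  }

  // chain connectivity
  for (int s = 0; s < N; ++s) {
    for (int i = 0; i + 1 < L; ++i) {
      const double* pi = x + 3 * (i + L * s);
      const double* pj = x + 3 * (i + 1 + L * s);
      double d = dist3(pi, pj, u);
      double diff = d - bond_len;
      energy += w_chain * diff * diff;
      double f = 2.0 * w_chain * diff;
      double* gi = g + 3 * (i + L * s);
      double* gj = g + 3 * (i + 1 + L * s);
      for (int k = 0; k < 3; ++k) {
        double c = f * u[k] / d;
        gi[k] += c; gj[k] -= c;
      }
    }
  }

  // steric repulsion between non-neighbours
  if (w_steric > 0.0) {
    for (int s = 0; s < N; ++s) {
      for (int i = 0; i < L; ++i) {
        for (int j = i + 2; j < L; ++j) {
          const double* pi = x + 3 * (i + L * s);
          const double* pj = x + 3 * (j + L * s);
          double d = dist3(pi, pj, u);
          if (d >= steric_min) continue;
          double diff = d - steric_min;
          energy += w_steric * diff * diff;
          double f = 2.0 * w_steric * diff;
          double* gi = g + 3 * (i + L * s);
          double* gj = g + 3 * (j + L * s);
          for (int k = 0; k < 3; ++k) {
            double c = f * u[k] / d;
            gi[k] += c; gj[k] -= c;
          }
        }
      }
    }
  }

  // flat-bottom bundling between corresponding beads of state pairs
  for (int s = 0; s < N; ++s) {
    for (int t = s + 1; t < N; ++t) {
      double w = bundle_w(s, t);
      if (w <= 0.0) continue;
      for (int i = 0; i < L; ++i) {
        const double* ps = x + 3 * (i + L * s);
        const double* pt = x + 3 * (i + L * t);
        double d = dist3(ps, pt, u);
        if (d <= bundle_halfwidth) continue;
        double diff = d - bundle_halfwidth;
        energy += w * diff * diff;
        double f = 2.0 * w * diff;
        double* gs = g + 3 * (i + L * s);
        double* gt = g + 3 * (i + L * t);
        for (int k = 0; k < 3; ++k) {
          double c = f * u[k] / d;
          gs[k] += c; gt[k] -= c;
        }
      }
    }
  }

  return List::create(_["energy"] = energy, _["gradient"] = grad,
                      _["restraint_energy"] = e_restraint);
}
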