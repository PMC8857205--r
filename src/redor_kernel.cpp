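// Two-spin REDOR propagation kernel.
//
// The observed proton coherence evolves under the heteronuclear dipolar
// coupling to the fluorine spin; the fluorine experiences its CSA and the
// rotor-synchronized pi-pulse train.  Because the full Hamiltonian is block
// diagonal in the observed-spin Iz basis, the normalized REDOR signal is
//
//   S/S0 = < Re Tr[ U+(T) U-(T)^dagger ] / 2 >_powder
//
// where U+/U- are 2x2 fluorine-space propagators under
//   H(+/-)(t) = w_CSA(t) Sz (+/-) w_D(t) Sz + w_RF(t) Sx,
// piecewise constant in time.  The pulse train (two pi pulses per rotor
// period, centred at tau_r/4 and 3 tau_r/4) makes H periodic with the rotor
// period, so propagators are built over one period and raised to the number
// of rotor cycles in each mixing time.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef std::complex<double> cplx;

struct Mat2 {
  cplx a, b, c, d;  // [[a, b], [c, d]]
};

static inline Mat2 mat_mult(const Mat2 &X, const Mat2 &Y) {
  Mat2 Z;
  Z.a = X.a * Y.a + X.b * Y.c;
  Z.b = X.a * Y.b + X.b * Y.d;
  Z.c = X.c * Y.a + X.d * Y.c;
  Z.d = X.c * Y.b + X.d * Y.d;
  return Z;
}

// U = exp(-i (wz Sz + wx Sx) dt), spin-1/2 operators S = sigma/2
static inline Mat2 step_prop(double wz, double wx, double dt) {
  double om = std::sqrt(wz * wz + wx * wx);
  double phi = 0.5 * om * dt;
  double cs = std::cos(phi), sn = std::sin(phi);
  double nz = (om > 0.0) ? wz / om : 0.0;
  double nx = (om > 0.0) ? wx / om : 0.0;
  Mat2 U;
  U.a = cplx(cs, -sn * nz);
  U.b = cplx(0.0, -sn * nx);
  U.c = cplx(0.0, -sn * nx);
  U.d = cplx(cs, sn * nz);
  return U;
}

// left-multiply by z rotation exp(-i theta Sz)
static inline void apply_z(Mat2 &U, double theta) {
  cplx em(std::cos(0.5 * theta), -std::sin(0.5 * theta));
  cplx ep = std::conj(em);
  U.a *= em; U.b *= em;
  U.c *= ep; U.d *= ep;
}

// left-multiply by x rotation exp(-i theta Sx)
static inline void apply_x(Mat2 &U, double theta) {
  double cs = std::cos(0.5 * theta), sn = std::sin(0.5 * theta);
  cplx mi(0.0, -1.0);
  Mat2 R;
  R.a = cplx(cs, 0.0); R.b = mi * sn;
  R.c = mi * sn;       R.d = cplx(cs, 0.0);
  Mat2 V = mat_mult(R, U);
  U = V;
}

static inline double re_tr_ab_dag(const Mat2 &A, const Mat2 &B) {
  // Re Tr[A B^dagger] = Re sum_ij A_ij conj(B_ij)
  return (A.a * std::conj(B.a) + A.b * std::conj(B.b) +
          A.c * std::conj(B.c) + A.d * std::conj(B.d)).real();
}

struct Step {
  double t_mid;   // time at step midpoint (s)
  double dt;      // step duration (s); 0 for an instantaneous (ideal) pulse
  bool rf_on;     // RF field present during this step
};

// Build the step plan for one rotor period with pulses centred at
// tau_r/4 and 3 tau_r/4.  Segment boundaries fall exactly on pulse edges so
// the nominal pulse length is honoured independent of the step grid.
static std::vector<Step> build_steps(double tau_r, double tp, int n_steps) {
  std::vector<Step> plan;
  double dt0 = tau_r / n_steps;
  double c1 = 0.25 * tau_r, c2 = 0.75 * tau_r;
  std::vector<double> bounds;
  std::vector<bool> on;
  if (tp > 0.0) {
    bounds = {0.0, c1 - tp / 2, c1 + tp / 2, c2 - tp / 2, c2 + tp / 2, tau_r};
    on = {false, true, false, true, false};
  } else {
    bounds = {0.0, c1, c2, tau_r};
    on = {false, false, false};
  }
  for (size_t s = 0; s + 1 < bounds.size(); ++s) {
    double len = bounds[s + 1] - bounds[s];
    int m = std::max(1, (int)std::ceil(len / dt0));
    double dt = len / m;
    for (int k = 0; k < m; ++k) {
      Step st;
      st.t_mid = bounds[s] + (k + 0.5) * dt;
      st.dt = dt;
      st.rf_on = on[s];
      plan.push_back(st);
    }
    if (tp == 0.0 && (s == 0 || s == 1) && bounds[s + 1] < tau_r) {
      Step st; st.t_mid = bounds[s + 1]; st.dt = 0.0; st.rf_on = true;
      plan.push_back(st);
    }
  }
  return plan;
}

// [[Rcpp::export]]
NumericMatrix redor_kernel_cpp(NumericVector d_hz,
                               NumericVector csa_rad,   // traceless PAS values (rad/s): xx, yy, zz
                               NumericMatrix orient,    // n x 2: alpha, beta (rad)
                               int n_gamma,
                               NumericVector flips_rad,
                               NumericVector flip_w,
                               double mas_hz,
                               double pulse_length,
                               IntegerVector n_periods,
                               int n_steps) {
  const double tau_r = 1.0 / mas_hz;
  const double w_r = 2.0 * M_PI * mas_hz;
  const double theta_m = std::acos(1.0 / std::sqrt(3.0));
  const double st_m = std::sin(theta_m), ct_m = std::cos(theta_m);

  const int n_or = orient.nrow();
  const int n_d = d_hz.size();
  const int n_t = n_periods.size();
  const int n_f = flips_rad.size();

  std::vector<Step> plan = build_steps(tau_r, pulse_length, n_steps);
  const int n_pl = plan.size();

  int max_n = 0;
  for (int j = 0; j < n_t; ++j) max_n = std::max(max_n, n_periods[j]);

  NumericMatrix out(n_d, n_t);
  std::fill(out.begin(), out.end(), 0.0);

  // scratch arrays over the step plan
  std::vector<double> pz2(n_pl), wcsa(n_pl), wd(n_pl);

  const double dxx = csa_rad[0], dyy = csa_rad[1], dzz = csa_rad[2];

  for (int io = 0; io < n_or; ++io) {
    double al = orient(io, 0), be = orient(io, 1);
    double ca = std::cos(al), sa = std::sin(al);
    double cb = std::cos(be), sb = std::sin(be);
    // PAS axes after Ry(beta) Rz(alpha), expressed in the rotor frame
    // e_x -> u1, e_y -> u2, e_z -> u3
    double u1x = cb * ca, u1y = sa, u1z = -sb * ca;
    double u2x = -cb * sa, u2y = ca, u2z = sb * sa;
    double u3x = sb, u3y = 0.0, u3z = cb;

    for (int ig = 0; ig < n_gamma; ++ig) {
      double gam = 2.0 * M_PI * ig / n_gamma;
      // projections of each axis on B0 at every step midpoint
      for (int s = 0; s < n_pl; ++s) {
        double phi = gam + w_r * plan[s].t_mid;
        double cp = std::cos(phi), sp = std::sin(phi);
        double p1 = st_m * (u1x * cp - u1y * sp) + ct_m * u1z;
        double p2 = st_m * (u2x * cp - u2y * sp) + ct_m * u2z;
        double p3 = st_m * (u3x * cp - u3y * sp) + ct_m * u3z;
        pz2[s] = p3 * p3;
        wcsa[s] = dxx * p1 * p1 + dyy * p2 * p2 + dzz * p3 * p3;
      }

      for (int id = 0; id < n_d; ++id) {
        double b_rad = 2.0 * M_PI * d_hz[id];
        for (int s = 0; s < n_pl; ++s)
          wd[s] = b_rad * 0.5 * (3.0 * pz2[s] - 1.0);

        for (int f = 0; f < n_f; ++f) {
          double flip = flips_rad[f];
          double w1 = (pulse_length > 0.0) ? flip / pulse_length : 0.0;

          Mat2 A = {1.0, 0.0, 0.0, 1.0};
          Mat2 B = {1.0, 0.0, 0.0, 1.0};
          double thp = 0.0, thm = 0.0;  // accumulated free-evolution phases

          for (int s = 0; s < n_pl; ++s) {
            double wzp = wcsa[s] + wd[s];
            double wzm = wcsa[s] - wd[s];
            if (!plan[s].rf_on) {
              thp += wzp * plan[s].dt;
              thm += wzm * plan[s].dt;
            } else {
              if (thp != 0.0 || thm != 0.0) {
                apply_z(A, thp); apply_z(B, thm);
                thp = 0.0; thm = 0.0;
              }
              if (plan[s].dt == 0.0) {
                apply_x(A, flip); apply_x(B, flip);
              } else {
                Mat2 Up = step_prop(wzp, w1, plan[s].dt);
                Mat2 Um = step_prop(wzm, w1, plan[s].dt);
                A = mat_mult(Up, A);
                B = mat_mult(Um, B);
              }
            }
          }
          if (thp != 0.0 || thm != 0.0) {
            apply_z(A, thp); apply_z(B, thm);
          }

          // raise the one-period propagators to each mixing time
          double wgt = flip_w[f] / (double)(n_or * n_gamma);
          Mat2 PA = {1.0, 0.0, 0.0, 1.0};
          Mat2 PB = {1.0, 0.0, 0.0, 1.0};
          int k = 0;
          for (int j = 0; j < n_t; ++j) {
            int target = n_periods[j];
            while (k < target) {
              PA = mat_mult(A, PA);
              PB = mat_mult(B, PB);
              ++k;
            }
            out(id, j) += wgt * 0.5 * re_tr_ab_dag(PA, PB);
          }
        }
      }
    }
  }
  return out;
}
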