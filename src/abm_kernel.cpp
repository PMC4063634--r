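#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear interpolation on a uniform lookup grid over [xmin, xmax].
static inline double lut(const double* g, int ng, double xmin, double inv_dx,
                         double x) {
  double t = (x - xmin) * inv_dx;
  if (t <= 0.0) return g[0];
  if (t >= ng - 1) return g[ng - 1];
  int i = (int)t;
  double f = t - i;
  return g[i] * (1.0 - f) + g[i + 1] * f;
}

// a^H: repeated squaring when H is a small whole number, std::pow otherwise
static inline double pow_h(double a, double H, int Hi) {
  if (Hi > 0) {
    double r = 1.0, b = a;
    int e = Hi;
    while (e) {
      if (e & 1) r *= b;
      b *= b;
      e >>= 1;
    }
    return r;
  }
  return std::pow(a, H);
}

// Run-and-tumble stepper with per-cell adaptation dynamics.
//
// The internal state is the deviation free energy g = f - F0(x), where
// f is the total receptor free energy and F0(x) = log(1/a0(x) - 1) the
// locally adapted value, so a = 1/(1+exp(F0(x)+g)) and g = 0 is the adapted
// state. Methylation kinetics relax g at the adaptation rate
// (dg = -(a0-a)/(tau_m a0(1-a0)) dt, the free-energy image of a linear-in-
// activity methylation rate), and transport through the gradient drives it
// by the perceived signal change dg = v*dir*(AoA(x)*(F0+g-G) + Gp(x)) dt
// with AoA = (dalpha/dT) T'(x)/alpha and Gp the spatial derivative of the
// ligand/pH free energy. The adapted level's own spatial variation
// re-references the baseline adiabatically (it is not a perceived
// stimulus). For chemical and pH signals (F0, alpha constant) this is an
// exact change of variables from methylation dynamics.
//
// Motor: tumble events at rate B(a)/tau_t with the new direction drawn
// uniformly from {-1,+1}; rotational diffusion reverses the direction at
// rate D_r. Boundaries are reflecting. Time-averaged occupancy and
// per-direction activity/methylation/tumble statistics are accumulated
// after burn-in.
// [[Rcpp::export]]
List sim_kernel(NumericVector x, IntegerVector dir, NumericVector g,
                int nsteps, int burn_steps, double dt,
                double xmin, double xmax,
                NumericVector F0g, NumericVector Gg, NumericVector Gpg,
                NumericVector AoAg, NumericVector a0g, NumericVector km2g,
                NumericVector Ag, NumericVector vg, NumericVector KHg,
                double m0, double H, double tau_t, double Dr,
                int nbins) {
  const int n = x.size();
  const int ng = F0g.size();
  const double inv_dx = (ng - 1) / (xmax - xmin);
  const double bw = (xmax - xmin) / nbins;
  const double* F0 = F0g.begin();
  const double* G = Gg.begin();
  const double* Gp = Gpg.begin();
  const double* AoA = AoAg.begin();
  const double* a0 = a0g.begin();
  const double* km2 = km2g.begin();
  const double* A = Ag.begin();
  const double* vv = vg.begin();
  const double* KH = KHg.begin();
  const int Hi = (H == std::floor(H) && H >= 1 && H <= 64) ? (int)H : 0;
  const double p_rot = Dr * dt;

  NumericVector occ(nbins);
  NumericMatrix occ_q(4, nbins);      // sampling window split into quarters
  NumericMatrix occ_dir(2, nbins);    // row 0: dir=-1, row 1: dir=+1
  NumericMatrix a_sum(2, nbins);
  NumericMatrix m_sum(2, nbins);
  NumericMatrix tumbles(2, nbins);

  const int sample_steps = nsteps - burn_steps;
  for (int s = 0; s < nsteps; ++s) {
    const bool sampling = s >= burn_steps;
    int quarter = 0;
    if (sampling && sample_steps > 0) {
      quarter = (int)(4.0 * (s - burn_steps) / sample_steps);
      if (quarter > 3) quarter = 3;
    }
    for (int i = 0; i < n; ++i) {
      double xi = x[i];
      double f0 = lut(F0, ng, xmin, inv_dx, xi);
      double u1 = f0 + g[i] - lut(G, ng, xmin, inv_dx, xi); // N*alpha*(m0-m)
      double a = 1.0 / (1.0 + std::exp(f0 + g[i]));
      double aH = pow_h(a, H, Hi);
      double zm = aH / ((aH + lut(KH, ng, xmin, inv_dx, xi)) * tau_t);

      int b = 0;
      int d = dir[i] > 0 ? 1 : 0;
      if (sampling) {
        b = (int)((xi - xmin) / bw);
        if (b < 0) b = 0;
        if (b >= nbins) b = nbins - 1;
        occ[b] += 1.0;
        occ_q(quarter, b) += 1.0;
        occ_dir(d, b) += 1.0;
        a_sum(d, b) += a;
        m_sum(d, b) += m0 - u1 / lut(A, ng, xmin, inv_dx, xi);
      }

      // motor tumble and rotational reversal, mutually exclusive within a
      // step (their coincidence has probability O(dt^2))
      double p_tum = zm * dt;
      double u = unif_rand();
      if (u < p_tum) {
        if (sampling) tumbles(d, b) += 1.0;
        dir[i] = (u < 0.5 * p_tum) ? -1 : 1;
      } else if (u < p_tum + p_rot) {
        dir[i] = -dir[i];
      }

      double v = lut(vv, ng, xmin, inv_dx, xi);
      // adaptation relaxes g toward 0; transport drives it by the
      // perceived signal gradient
      g[i] += dt * (lut(km2, ng, xmin, inv_dx, xi) *
                      (a - lut(a0, ng, xmin, inv_dx, xi)) +
                    dir[i] * v *
                      (lut(AoA, ng, xmin, inv_dx, xi) * u1 +
                       lut(Gp, ng, xmin, inv_dx, xi)));

      xi += dir[i] * v * dt;
      while (xi < xmin || xi > xmax) {       // reflecting boundaries
        if (xi < xmin) { xi = 2.0 * xmin - xi; dir[i] = -dir[i]; }
        if (xi > xmax) { xi = 2.0 * xmax - xi; dir[i] = -dir[i]; }
      }
      x[i] = xi;
    }
  }

  return List::create(_["occ"] = occ, _["occ_q"] = occ_q,
                      _["occ_dir"] = occ_dir, _["a_sum"] = a_sum,
                      _["m_sum"] = m_sum, _["tumbles"] = tumbles,
                      _["x"] = x, _["dir"] = dir, _["g"] = g,
                      _["sample_steps"] = sample_steps);
}
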