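// Compiled core for scenario fitting: panel prediction and the relative
// squared-error objective, evaluated thousands of times per optimizer
// restart.
//
// Parameter vector layout (mirrored by theta_layout() on the R side):
//   [0..2]  eps12, eps13, eps23        (kT)
//   [3]     log(lambda)                (EMSA -> in vivo Kh scale)
//   then a block for Pv, then a block for Ps:
//     kinetic block (15):       A[8] (activity scale), rho[7] (configs
//                               "001".."111" by bit value, rho("000") = 1)
//     thermodynamic block (12): log R[8] (RNAP occupancy ratio),
//                               log vmax, eta[3] (kT)
//
// Configuration ids use bits s1 s2 s3 for boxes 0A1..0A3, id = 4*s1+2*s2+s3.
// All transcendental terms are hoisted out of the strain/timepoint loops.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const int S1[8] = {0, 0, 0, 0, 1, 1, 1, 1};
const int S2[8] = {0, 0, 1, 1, 0, 0, 1, 1};
const int S3[8] = {0, 1, 0, 1, 0, 1, 0, 1};

struct PromBlock {
  bool thermo;
  double A[8];    // kinetic activity scale, or thermodynamic R(t)
  double rho[8];  // rho[0] = 1
  double vmax;
  double F[8];    // exp(-eta . s) per configuration (thermo), else 1
};

int parse_block(const NumericVector& th, int off, bool thermo, int T,
                PromBlock& b) {
  b.thermo = thermo;
  for (int c = 0; c < 8; ++c) {
    b.rho[c] = 1.0;
    b.F[c] = 1.0;
  }
  if (!thermo) {
    for (int t = 0; t < T; ++t) b.A[t] = th[off + t];
    for (int c = 1; c < 8; ++c) b.rho[c] = th[off + T + c - 1];
    b.vmax = 0.0;
    return off + T + 7;
  }
  for (int t = 0; t < T; ++t) b.A[t] = std::exp(th[off + t]);
  b.vmax = std::exp(th[off + T]);
  double e1 = th[off + T + 1], e2 = th[off + T + 2], e3 = th[off + T + 3];
  for (int c = 0; c < 8; ++c)
    b.F[c] = std::exp(-(e1 * S1[c] + e2 * S2[c] + e3 * S3[c]));
  return off + T + 4;
}

NumericMatrix predict_impl(NumericVector theta, List spec) {
  NumericVector conc = spec["conc"];
  NumericVector kh = spec["kh"];
  double n0a = as<double>(spec["n0a"]);
  int ctrl_v = as<int>(spec["ctrl_v"]);  // 0 kinetic, 1 thermodynamic
  int ctrl_s = as<int>(spec["ctrl_s"]);
  IntegerVector cohort = spec["cohort"];  // 0 PvPs, 1 Pv, 2 Ps
  IntegerMatrix present = spec["present"];
  NumericVector lower = spec["lower"];
  NumericVector upper = spec["upper"];

  int T = conc.size();
  int L = cohort.size();
  if (T > 8) stop("at most 8 timepoints supported");

  // Guard finite-difference probes just outside the box constraints.
  NumericVector th = clone(theta);
  for (int i = 0; i < th.size(); ++i) {
    if (th[i] < lower[i]) th[i] = lower[i];
    if (th[i] > upper[i]) th[i] = upper[i];
  }

  double lambda = std::exp(th[3]);
  PromBlock bv, bs;
  int off = 4;
  off = parse_block(th, off, ctrl_v == 1, T, bv);
  off = parse_block(th, off, ctrl_s == 1, T, bs);
  if (off != th.size()) stop("theta length does not match the layout");

  // Per-box saturation ratios (c_t / (lambda kh_i))^n0a ...
  double x[3][8];
  for (int i = 0; i < 3; ++i)
    for (int t = 0; t < T; ++t)
      x[i][t] = std::pow(conc[t] / (lambda * kh[i]), n0a);
  // ... and pair-energy factors exp(-eps . s s) per configuration.
  double epsw[8];
  {
    double e12 = th[0], e13 = th[1], e23 = th[2];
    for (int c = 0; c < 8; ++c)
      epsw[c] = std::exp(-(e12 * S1[c] * S2[c] + e13 * S1[c] * S3[c] +
                           e23 * S2[c] * S3[c]));
  }

  NumericMatrix pred(L, T);
  for (int l = 0; l < L; ++l) {
    int coh = cohort[l];
    bool use_v = (coh == 0 || coh == 1);
    bool use_s = (coh == 0 || coh == 2);
    bool tv = use_v && bv.thermo, ts = use_s && bs.thermo;
    int p1 = present(l, 0), p2 = present(l, 1), p3 = present(l, 2);
    for (int t = 0; t < T; ++t) {
      double Z = 0.0, kin = 0.0, occ_v = 0.0, occ_s = 0.0;
      for (int s = 0; s < 8; ++s) {
        if ((S1[s] && !p1) || (S2[s] && !p2) || (S3[s] && !p3)) continue;
        double W = epsw[s];
        if (S1[s]) W *= x[0][t];
        if (S2[s]) W *= x[1][t];
        if (S3[s]) W *= x[2][t];
        double gv = 0.0, gs = 0.0, fv = 1.0, fs = 1.0;
        if (tv) {
          gv = bv.A[t] * bv.F[s];
          fv = 1.0 + gv;
        }
        if (ts) {
          gs = bs.A[t] * bs.F[s];
          fs = 1.0 + gs;
        }
        double wfull = W * fv * fs;
        Z += wfull;
        if (use_v && !bv.thermo) kin += wfull * bv.A[t] * bv.rho[s];
        if (use_s && !bs.thermo) kin += wfull * bs.A[t] * bs.rho[s];
        if (tv) occ_v += W * gv * fs;
        if (ts) occ_s += W * fv * gs;
      }
      double v = kin / Z;
      if (tv) v += bv.vmax * occ_v / Z;
      if (ts) v += bs.vmax * occ_s / Z;
      pred(l, t) = v;
    }
  }
  return pred;
}

}  // namespace

// [[Rcpp::export(name = "panel_predict_cpp")]]
NumericMatrix panel_predict_cpp(NumericVector theta, List spec) {
  return predict_impl(theta, spec);
}

// [[Rcpp::export(name = "panel_objective_cpp")]]
double panel_objective_cpp(NumericVector theta, List spec) {
  NumericMatrix X = spec["X"];
  IntegerVector cohort = spec["cohort"];
  NumericMatrix pred = predict_impl(theta, spec);
  int T = X.ncol();
  double terms[3] = {0.0, 0.0, 0.0};
  int counts[3] = {0, 0, 0};
  for (int l = 0; l < pred.nrow(); ++l) {
    int coh = cohort[l];
    for (int t = 0; t < T; ++t) {
      double r = (pred(l, t) - X(l, t)) / X(l, t);
      terms[coh] += r * r;
      ++counts[coh];
    }
  }
  double E = 0.0;
  for (int i = 0; i < 3; ++i)
    if (counts[i] > 0) E += terms[i] / counts[i];
  return E;
}
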