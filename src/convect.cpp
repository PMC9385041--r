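#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Invert blood oxygen content C = alpha_b * P + chb_h * P^n/(p50^n + P^n)
// by bracketed Newton iteration (content is strictly increasing in P).
static double po2_from_content(double c, double alpha, double chbh,
                               double n, double p50) {
  if (c <= 0.0) return 0.0;
  double p50n = std::pow(p50, n);
  double lo = 0.0, hi = 200.0;
  for (int i = 0; i < 64; i++) {
    double pn = std::pow(hi, n);
    if (alpha * hi + chbh * pn / (p50n + pn) >= c) break;
    hi *= 2.0;
  }
  double p = std::min(c / (alpha + chbh / p50), hi);
  for (int i = 0; i < 100; i++) {
    double pn = std::pow(p, n);
    double s = pn / (p50n + pn);
    double f = alpha * p + chbh * s - c;
    if (f > 0.0) hi = p; else lo = p;
    double ds = (p > 0.0) ? n * std::pow(p, n - 1.0) * p50n /
                              ((p50n + pn) * (p50n + pn))
                          : 0.0;
    double step = f / (alpha + chbh * ds);
    double pn1 = p - step;
    if (pn1 <= lo || pn1 >= hi) pn1 = 0.5 * (lo + hi);
    if (std::fabs(pn1 - p) < 1e-12) { p = pn1; break; }
    p = pn1;
  }
  return p;
}

// smooth non-negativity clamp for blood content (keeps the vessel system C1
// so Newton converges); eps is a small fraction of the arterial content
static inline double soft_pos(double x, double eps) {
  return 0.5 * (x + std::sqrt(x * x + eps * eps));
}
static inline double soft_pos_d(double x, double eps) {
  return 0.5 * (1.0 + x / std::sqrt(x * x + eps * eps));
}

// March blood oxygen content along the flow-directed vessel network.
// Segments must be topologically ordered (descending upstream pressure);
// elements within a segment are listed in flow order via the CSR arrays.
// All indices 0-based. Returns the mean PO2 of each element (NA where the
// element does not lie on an active segment).
// [[Rcpp::export]]
List convect_po2(IntegerVector seg_ptr, IntegerVector elem_idx,
                 IntegerVector seg_up, IntegerVector seg_down,
                 NumericVector seg_q, NumericVector q_elem,
                 int n_nodes, int inlet, double c_art,
                 double alpha_b, double chb_h, double hill_n, double p50,
                 int n_elem_total) {
  int ns = seg_up.size();
  double eps = 1e-3 * c_art;
  NumericVector pb(n_elem_total, NA_REAL);
  NumericVector node_content(n_nodes, NA_REAL);
  std::vector<double> in_q(n_nodes, 0.0), in_o2(n_nodes, 0.0);
  node_content[inlet] = c_art;
  for (int s = 0; s < ns; s++) {
    int u = seg_up[s];
    double C;
    if (u == inlet) C = c_art;
    else if (in_q[u] > 0.0) C = in_o2[u] / in_q[u];
    else C = 0.0;
    if (u != inlet) node_content[u] = C;
    double Q = seg_q[s];
    for (int k = seg_ptr[s]; k < seg_ptr[s + 1]; k++) {
      int e = elem_idx[k];
      double cend = soft_pos(C - q_elem[e] / Q, eps);
      double cm = 0.5 * (C + cend);
      pb[e] = po2_from_content(cm, alpha_b, chb_h, hill_n, p50);
      C = cend;
    }
    in_q[seg_down[s]] += Q;
    in_o2[seg_down[s]] += Q * C;
  }
  return List::create(_["pb"] = pb, _["node_content"] = node_content);
}

// Blood PO2 of every active element at the current source strengths plus the
// exact Jacobian -dPb_i/dq_j (n_act x n_act) of the convection map,
// accounting for the clamping of depleted blood content (where the content
// clamps at zero the corresponding derivatives vanish). `act_pos` maps
// global element index -> 0-based active position (-1 if inactive).
// Sensitivities are propagated through flow-weighted mixing at nodes.
// [[Rcpp::export]]
List convect_jacobian(IntegerVector seg_ptr, IntegerVector elem_idx,
                      IntegerVector seg_up, IntegerVector seg_down,
                      NumericVector seg_q, IntegerVector act_pos,
                      NumericVector q_elem,
                      int n_nodes, int inlet, double c_art,
                      double alpha_b, double chb_h, double hill_n,
                      double p50, int n_act) {
  int ns = seg_up.size();
  double p50n = std::pow(p50, hill_n);
  NumericVector pb(n_act);
  NumericMatrix J(n_act, n_act);   // -dPb_i/dq_j, >= 0
  std::vector<std::vector<double> > node_acc(n_nodes);
  std::vector<double> in_q(n_nodes, 0.0), in_o2(n_nodes, 0.0);
  std::vector<double> run(n_act);
  for (int s = 0; s < ns; s++) {
    int u = seg_up[s];
    double C;
    if (u == inlet) {
      C = c_art;
      std::fill(run.begin(), run.end(), 0.0);
    } else if (in_q[u] > 0.0) {
      C = in_o2[u] / in_q[u];
      double iq = in_q[u];
      if (node_acc[u].empty()) std::fill(run.begin(), run.end(), 0.0);
      else for (int j = 0; j < n_act; j++) run[j] = node_acc[u][j] / iq;
    } else {
      C = 0.0;
      std::fill(run.begin(), run.end(), 0.0);
    }
    double Q = seg_q[s];
    double eps = 1e-3 * c_art;
    for (int k = seg_ptr[s]; k < seg_ptr[s + 1]; k++) {
      int e = elem_idx[k];
      int p = act_pos[e];
      double qe = (p >= 0) ? q_elem[e] : 0.0;
      double craw = C - qe / Q;
      double w = soft_pos_d(craw, eps);   // d cend / d craw
      double cend = soft_pos(craw, eps);
      double cm = 0.5 * (C + cend);
      if (p >= 0) {
        double P = po2_from_content(cm, alpha_b, chb_h, hill_n, p50);
        pb[p] = P;
        double pn = std::pow(P, hill_n);
        double ds = (P > 0.0) ? hill_n * std::pow(P, hill_n - 1.0) * p50n /
                                  ((p50n + pn) * (p50n + pn))
                              : 0.0;
        double dPdC = 1.0 / (alpha_b + chb_h * ds);
        // -dcm/dq_j = 0.5 (1 + w) run_j (upstream) + 0.5 w / Q (own)
        for (int j = 0; j < n_act; j++)
          J(p, j) = dPdC * 0.5 * (1.0 + w) * run[j];
        J(p, p) += dPdC * 0.5 * w / Q;
        // propagate the end-content sensitivity: -dcend/dq_j
        for (int j = 0; j < n_act; j++) run[j] *= w;
        run[p] += w / Q;
      }
      C = cend;
    }
    int v = seg_down[s];
    if (node_acc[v].empty()) node_acc[v].assign(n_act, 0.0);
    for (int j = 0; j < n_act; j++) node_acc[v][j] += Q * run[j];
    in_q[v] += Q;
    in_o2[v] += Q * C;
  }
  return List::create(_["pb"] = pb, _["J"] = J);
}
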