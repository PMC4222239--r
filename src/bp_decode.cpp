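#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sum-product (belief propagation) decoding of a binary LDPC code on the
// Tanner graph of H, with hard-decision channel input. Channel LLRs are
// +/- llr_mag according to the received bit. Flooding schedule; terminates
// early as soon as the hard decision satisfies all parity checks.
//
// edge_row / edge_col are 0-based endpoints of each edge of the Tanner
// graph (one entry per 1 in H).
//
// [[Rcpp::export(name = ".bp_decode_cpp")]]
List bp_decode_cpp(IntegerVector hard_bits, IntegerVector edge_row,
                   IntegerVector edge_col, int m, int n,
                   double llr_mag, int max_iter) {
  const int E = edge_row.size();
  // adjacency: edges grouped by check and by variable
  std::vector<int> chk_deg(m, 0), var_deg(n, 0);
  for (int e = 0; e < E; ++e) {
    chk_deg[edge_row[e]]++;
    var_deg[edge_col[e]]++;
  }
  std::vector<int> chk_ptr(m + 1, 0), var_ptr(n + 1, 0);
  for (int i = 0; i < m; ++i) chk_ptr[i + 1] = chk_ptr[i] + chk_deg[i];
  for (int j = 0; j < n; ++j) var_ptr[j + 1] = var_ptr[j] + var_deg[j];
  std::vector<int> chk_edges(E), var_edges(E);
  {
    std::vector<int> cpos(chk_ptr.begin(), chk_ptr.end() - 1);
    std::vector<int> vpos(var_ptr.begin(), var_ptr.end() - 1);
    for (int e = 0; e < E; ++e) {
      chk_edges[cpos[edge_row[e]]++] = e;
      var_edges[vpos[edge_col[e]]++] = e;
    }
  }

  std::vector<double> L(n);
  for (int j = 0; j < n; ++j) L[j] = (hard_bits[j] == 0) ? llr_mag : -llr_mag;

  std::vector<double> Q(E), R(E, 0.0), post(n);
  for (int e = 0; e < E; ++e) Q[e] = L[edge_col[e]];

  IntegerVector out(n);
  auto syndrome_ok = [&](const IntegerVector &bits) {
    for (int i = 0; i < m; ++i) {
      int s = 0;
      for (int t = chk_ptr[i]; t < chk_ptr[i + 1]; ++t)
        s ^= bits[edge_col[chk_edges[t]]];
      if (s) return false;
    }
    return true;
  };

  for (int j = 0; j < n; ++j) out[j] = hard_bits[j];
  if (syndrome_ok(out)) {
    return List::create(_["bits"] = out, _["converged"] = true,
                        _["iterations"] = 0);
  }

  const double CLAMP = 0.9999999999999;
  bool converged = false;
  int iter = 0;
  std::vector<double> th(E);
  while (iter < max_iter) {
    ++iter;
    // check-node update: R[e] = 2 atanh( prod_{e' != e} tanh(Q[e']/2) )
    for (int e = 0; e < E; ++e) {
      double t = std::tanh(Q[e] / 2.0);
      if (t > CLAMP) t = CLAMP;
      if (t < -CLAMP) t = -CLAMP;
      th[e] = t;
    }
    for (int i = 0; i < m; ++i) {
      int lo = chk_ptr[i], hi = chk_ptr[i + 1];
      double prod = 1.0;
      bool zero = false;
      for (int t = lo; t < hi; ++t) {
        double v = th[chk_edges[t]];
        if (v == 0.0) { zero = true; }
        prod *= v;
      }
      for (int t = lo; t < hi; ++t) {
        int e = chk_edges[t];
        double excl;
        if (!zero) {
          excl = prod / th[e];
        } else {
          excl = 1.0;
          for (int t2 = lo; t2 < hi; ++t2)
            if (t2 != t) excl *= th[chk_edges[t2]];
        }
        if (excl > CLAMP) excl = CLAMP;
        if (excl < -CLAMP) excl = -CLAMP;
        R[e] = 2.0 * std::atanh(excl);
      }
    }
    // variable-node update and posterior
    for (int j = 0; j < n; ++j) {
      double sum = L[j];
      for (int t = var_ptr[j]; t < var_ptr[j + 1]; ++t) sum += R[var_edges[t]];
      post[j] = sum;
      for (int t = var_ptr[j]; t < var_ptr[j + 1]; ++t) {
        int e = var_edges[t];
        Q[e] = sum - R[e];
      }
      out[j] = (post[j] < 0.0) ? 1 : 0;
    }
    if (syndrome_ok(out)) { converged = true; break; }
  }

  return List::create(_["bits"] = out, _["converged"] = converged,
                      _["iterations"] = iter);
}
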