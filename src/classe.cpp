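// Numerical core of the compound-state ClaSSE model.
//
// Integrates the coupled extinction/likelihood system along branches with an
// adaptive Cash-Karp Runge-Kutta scheme, runs the postorder pruning pass over
// a whole tree, and evaluates the extinction probabilities E_i(t) on an age
// grid for stochastic mapping.  D is log-rescaled per branch to avoid
// underflow on deep trees.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int S;
  const double* Q;      // column-major S x S, Q(i,j) = rate i -> j
  std::vector<double> qtot;
  const int* cp; const int* cl; const int* cr; const double* crate;
  int nc;
  const double* mu;
  std::vector<double> lamtot;
};

Model make_model(const NumericMatrix& Q, const IntegerVector& cp,
                 const IntegerVector& cl, const IntegerVector& cr,
                 const NumericVector& crate, const NumericVector& mu) {
  Model M;
  M.S = Q.nrow();
  M.Q = Q.begin();
  M.qtot.assign(M.S, 0.0);
  for (int j = 0; j < M.S; ++j)
    for (int i = 0; i < M.S; ++i)
      M.qtot[i] += Q(i, j);
  M.cp = cp.begin(); M.cl = cl.begin(); M.cr = cr.begin();
  M.crate = crate.begin();
  M.nc = cp.size();
  M.mu = mu.begin();
  M.lamtot.assign(M.S, 0.0);
  for (int c = 0; c < M.nc; ++c) M.lamtot[M.cp[c] - 1] += M.crate[c];
  return M;
}

// dE_i = mu_i - T_i E_i + sum_j Q_ij E_j + sum_{(j,k)} r E_j E_k
// dD_i =      - T_i D_i + sum_j Q_ij D_j + sum_{(j,k)} r (D_j E_k + D_k E_j)
// with T_i = Lambda_i + Qtot_i + mu_i; rows of `clad` are unordered pairs.
void deriv(const Model& M, const double* y, double* dy) {
  const int S = M.S;
  const double* E = y; const double* D = y + S;
  double* dE = dy; double* dD = dy + S;
  for (int i = 0; i < S; ++i) {
    double tot = M.lamtot[i] + M.qtot[i] + M.mu[i];
    dE[i] = M.mu[i] - tot * E[i];
    dD[i] = -tot * D[i];
  }
  for (int j = 0; j < S; ++j) {
    const double* qc = M.Q + (std::size_t)j * S;  // column j: Q(i, j)
    const double Ej = E[j], Dj = D[j];
    if (Ej != 0.0 || Dj != 0.0)
      for (int i = 0; i < S; ++i) {
        dE[i] += qc[i] * Ej;
        dD[i] += qc[i] * Dj;
      }
  }
  for (int c = 0; c < M.nc; ++c) {
    const int i = M.cp[c] - 1, j = M.cl[c] - 1, k = M.cr[c] - 1;
    const double r = M.crate[c];
    dE[i] += r * E[j] * E[k];
    dD[i] += r * (D[j] * E[k] + D[k] * E[j]);
  }
}

// Cash-Karp RK4(5) coefficients
const double b21 = 0.2;
const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
const double b41 = 0.3, b42 = -0.9, b43 = 1.2;
const double b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0, b63 = 575.0 / 13824.0,
             b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0;
const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
             c6 = 512.0 / 1771.0;
const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
             dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
             dc6 = c6 - 0.25;

struct Stepper {
  const Model* M;
  int n;
  std::vector<double> k1, k2, k3, k4, k5, k6, ytmp, yerr;
  explicit Stepper(const Model& model)
      : M(&model), n(2 * model.S),
        k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), ytmp(n), yerr(n) {}

  // one Cash-Karp step of size h from y into yout; returns max scaled error
  double step(const std::vector<double>& y, double h, std::vector<double>& yout,
              double rtol, double atol) {
    deriv(*M, y.data(), k1.data());
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * b21 * k1[i];
    deriv(*M, ytmp.data(), k2.data());
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    deriv(*M, ytmp.data(), k3.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    deriv(*M, ytmp.data(), k4.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
    deriv(*M, ytmp.data(), k5.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                            b64 * k4[i] + b65 * k5[i]);
    deriv(*M, ytmp.data(), k6.data());
    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      yout[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      const double err = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] +
                              dc5 * k5[i] + dc6 * k6[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(yout[i]));
      errmax = std::max(errmax, std::fabs(err) / sc);
    }
    return errmax;
  }
};

// integrate the joint system over [0, len]; D is rescaled, log factor
// accumulated into *logscale.  Returns false on non-finite state.
bool integrate(const Model& M, std::vector<double>& y, double len,
               double rtol, double atol, double* logscale) {
  if (len <= 0.0) return true;
  Stepper st(M);
  const int S = M.S;
  std::vector<double> ynew(2 * S);
  double t = 0.0;
  double h = len * 0.1;
  int iter = 0;
  while (t < len) {
    if (++iter > 1000000) return false;
    if (t + h > len) h = len - t;
    double errmax = st.step(y, h, ynew, rtol, atol);
    if (!std::isfinite(errmax)) { h *= 0.1; if (h < 1e-14 * len) return false; continue; }
    if (errmax > 1.0) {
      double hnew = 0.9 * h * std::pow(errmax, -0.25);
      h = std::max(hnew, 0.1 * h);
      if (h < 1e-14 * len) return false;
      continue;
    }
    t += h;
    y.swap(ynew);
    // keep E within [0,1] against roundoff
    for (int i = 0; i < S; ++i) {
      if (y[i] < 0.0) y[i] = 0.0;
      if (y[i] > 1.0) y[i] = 1.0;
    }
    double dmax = 0.0;
    for (int i = 0; i < S; ++i) dmax = std::max(dmax, std::fabs(y[S + i]));
    if (dmax > 0.0 && (dmax < 1e-30 || dmax > 1e30)) {
      for (int i = 0; i < S; ++i) y[S + i] /= dmax;
      *logscale += std::log(dmax);
    }
    h = (errmax > 1e-8) ? 0.9 * h * std::pow(errmax, -0.2) : 5.0 * h;
  }
  return true;
}

}  // namespace

// [[Rcpp::export]]
List cpp_branch_integrate(NumericVector y0, double len, NumericMatrix Q,
                          IntegerVector cp, IntegerVector cl, IntegerVector cr,
                          NumericVector crate, NumericVector mu,
                          double rtol, double atol) {
  Model M = make_model(Q, cp, cl, cr, crate, mu);
  if (y0.size() != 2 * M.S) stop("y0 must have length 2*S");
  std::vector<double> y(y0.begin(), y0.end());
  double logscale = 0.0;
  if (!integrate(M, y, len, rtol, atol, &logscale))
    stop("branch integration failed (non-finite state)");
  return List::create(_["y"] = NumericVector(y.begin(), y.end()),
                      _["logscale"] = logscale);
}

// Postorder pruning over a binary tree.  `edge` uses ape numbering (tips
// 1..ntip, root ntip+1) and must be in postorder; tipD holds per-tip initial
// D columns; e0 the shared tip extinction initial condition.
// [[Rcpp::export]]
List cpp_tree_prune(IntegerMatrix edge, NumericVector edge_length, int n_tip,
                    NumericMatrix tipD, NumericVector e0, NumericMatrix Q,
                    IntegerVector cp, IntegerVector cl, IntegerVector cr,
                    NumericVector crate, NumericVector mu,
                    double rtol, double atol) {
  Model M = make_model(Q, cp, cl, cr, crate, mu);
  const int S = M.S;
  const int n_edge = edge.nrow();
  const int n_node = n_edge + 1;
  NumericMatrix nodeE(S, n_node), nodeD(S, n_node);
  NumericVector nodeLog(n_node);
  std::vector<int> n_children(n_node, 0);
  NumericMatrix topE(S, n_edge), topD(S, n_edge);
  NumericVector topLog(n_edge);
  std::vector<std::vector<int>> child_edges(n_node);

  for (int t = 0; t < n_tip; ++t) {
    for (int i = 0; i < S; ++i) {
      nodeE(i, t) = e0[i];
      nodeD(i, t) = tipD(i, t);
    }
  }
  for (int e = 0; e < n_edge; ++e) {
    const int child = edge(e, 1) - 1;
    const int parent = edge(e, 0) - 1;
    std::vector<double> y(2 * S);
    for (int i = 0; i < S; ++i) { y[i] = nodeE(i, child); y[S + i] = nodeD(i, child); }
    double logscale = nodeLog[child];
    if (!integrate(M, y, edge_length[e], rtol, atol, &logscale))
      stop("branch integration failed (non-finite state) on edge %d", e + 1);
    for (int i = 0; i < S; ++i) { topE(i, e) = y[i]; topD(i, e) = y[S + i]; }
    topLog[e] = logscale;
    child_edges[parent].push_back(e);
    if (++n_children[parent] == 2) {
      const int eL = child_edges[parent][0], eR = child_edges[parent][1];
      std::vector<double> D(S, 0.0);
      for (int c = 0; c < M.nc; ++c) {
        const int i = M.cp[c] - 1, j = M.cl[c] - 1, k = M.cr[c] - 1;
        const double r = M.crate[c];
        if (j == k)
          D[i] += r * topD(j, eL) * topD(j, eR);
        else
          D[i] += r * (topD(j, eL) * topD(k, eR) + topD(k, eL) * topD(j, eR));
      }
      double dmax = 0.0;
      for (int i = 0; i < S; ++i) dmax = std::max(dmax, std::fabs(D[i]));
      double lg = topLog[eL] + topLog[eR];
      if (dmax > 0.0) {
        for (int i = 0; i < S; ++i) D[i] /= dmax;
        lg += std::log(dmax);
      }
      for (int i = 0; i < S; ++i) {
        nodeD(i, parent) = D[i];
        nodeE(i, parent) = topE(i, eL);  // equal to eR's for ultrametric input
      }
      nodeLog[parent] = lg;
    } else if (n_children[parent] > 2) {
      stop("tree must be strictly binary");
    }
  }
  return List::create(_["nodeE"] = nodeE, _["nodeD"] = nodeD,
                      _["nodeLog"] = nodeLog, _["topE"] = topE,
                      _["topD"] = topD, _["topLog"] = topLog);
}

// E_i(t) on an increasing age grid starting at 0 (tips).
// [[Rcpp::export]]
NumericMatrix cpp_E_grid(NumericVector ages, NumericVector e0, NumericMatrix Q,
                         IntegerVector cp, IntegerVector cl, IntegerVector cr,
                         NumericVector crate, NumericVector mu,
                         double rtol, double atol) {
  Model M = make_model(Q, cp, cl, cr, crate, mu);
  const int S = M.S;
  const int n = ages.size();
  NumericMatrix out(S, n);
  std::vector<double> y(2 * S, 0.0);
  for (int i = 0; i < S; ++i) y[i] = e0[i];
  double t = 0.0, logscale = 0.0;
  for (int g = 0; g < n; ++g) {
    if (ages[g] < t) stop("ages must be nondecreasing");
    if (!integrate(M, y, ages[g] - t, rtol, atol, &logscale))
      stop("E integration failed");
    t = ages[g];
    for (int i = 0; i < S; ++i) out(i, g) = y[i];
  }
  return out;
}
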