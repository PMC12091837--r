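// Alignment and superposition kernels.
//
// Needleman-Wunsch global alignment with affine gaps (Gotoh), under the
// convention that a gap of length L scores open + (L - 1) * extend.
// Sequences arrive as 0-based integer codes into the substitution matrix.
// Tie-break order in the traceback is fixed (diagonal, then gap in b,
// then gap in a) so results are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG_INF = -1e30;

struct NWResult {
  double score;
  std::vector<int> pi;  // matched positions in a (0-based)
  std::vector<int> pj;  // matched positions in b
};

static NWResult nw_align(const std::vector<int>& a, const std::vector<int>& b,
                         const NumericMatrix& sub, double open, double extend,
                         bool traceback) {
  const int m = a.size(), n = b.size();
  arma::mat M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  // X: gap in b (consumes a); Y: gap in a (consumes b)
  M.fill(NEG_INF); X.fill(NEG_INF); Y.fill(NEG_INF);
  M(0, 0) = 0.0;
  for (int i = 1; i <= m; ++i) X(i, 0) = open + (i - 1) * extend;
  for (int j = 1; j <= n; ++j) Y(0, j) = open + (j - 1) * extend;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      double dm = std::max(M(i - 1, j - 1),
                           std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = dm + s;
      X(i, j) = std::max(M(i - 1, j) + open,
                         std::max(X(i - 1, j) + extend,
                                  Y(i - 1, j) + open));
      Y(i, j) = std::max(M(i, j - 1) + open,
                         std::max(Y(i, j - 1) + extend,
                                  X(i, j - 1) + open));
    }
  }

  NWResult out;
  out.score = std::max(M(m, n), std::max(X(m, n), Y(m, n)));
  if (!traceback) return out;

  // walk back; state 0 = M, 1 = X, 2 = Y
  int i = m, j = n;
  int state = (M(m, n) >= X(m, n) && M(m, n) >= Y(m, n)) ? 0
            : (X(m, n) >= Y(m, n)) ? 1 : 2;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double target = M(i, j) - sub(a[i - 1], b[j - 1]);
      out.pi.push_back(i - 1);
      out.pj.push_back(j - 1);
      if (std::abs(M(i - 1, j - 1) - target) < eps) state = 0;
      else if (std::abs(X(i - 1, j - 1) - target) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      double target = X(i, j);
      if (std::abs(M(i - 1, j) + open - target) < eps) state = 0;
      else if (std::abs(X(i - 1, j) + extend - target) < eps) state = 1;
      else state = 2;
      --i;
      if (i == 0 && j > 0 && state != 2) state = 2;
    } else {
      double target = Y(i, j);
      if (std::abs(M(i, j - 1) + open - target) < eps) state = 0;
      else if (std::abs(Y(i, j - 1) + extend - target) < eps) state = 2;
      else state = 1;
      --j;
      if (j == 0 && i > 0 && state != 1) state = 1;
    }
  }
  std::reverse(out.pi.begin(), out.pi.end());
  std::reverse(out.pj.begin(), out.pj.end());
  return out;
}

// [[Rcpp::export(name = ".cpp_nw_score")]]
double cpp_nw_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double open, double extend) {
  std::vector<int> av = as<std::vector<int>>(a);
  std::vector<int> bv = as<std::vector<int>>(b);
  return nw_align(av, bv, sub, open, extend, false).score;
}

// [[Rcpp::export(name = ".cpp_nw_pairs")]]
IntegerMatrix cpp_nw_pairs(IntegerVector a, IntegerVector b,
                           NumericMatrix sub, double open, double extend) {
  std::vector<int> av = as<std::vector<int>>(a);
  std::vector<int> bv = as<std::vector<int>>(b);
  NWResult r = nw_align(av, bv, sub, open, extend, true);
  IntegerMatrix out(r.pi.size(), 2);
  for (size_t k = 0; k < r.pi.size(); ++k) {
    out(k, 0) = r.pi[k] + 1;  // 1-based for R
    out(k, 1) = r.pj[k] + 1;
  }
  colnames(out) = CharacterVector::create("i", "j");
  return out;
}

// All pairwise alignment scores (including the diagonal self-scores).
// [[Rcpp::export(name = ".cpp_pairwise_scores")]]
NumericMatrix cpp_pairwise_scores(List seqs, NumericMatrix sub, double open,
                                  double extend) {
  int n = seqs.size();
  std::vector<std::vector<int>> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = as<std::vector<int>>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = nw_align(sv[i], sv[j], sub, open, extend, false).score;
      out(i, j) = s;
      out(j, i) = s;
    }
  }
  return out;
}

// Kabsch RMSD of paired points (rows of p / q), proper rotation only.
static double kabsch_rmsd(const arma::mat& p, const arma::mat& q,
                          arma::mat& R, arma::rowvec& pc, arma::rowvec& qc) {
  pc = arma::mean(p, 0);
  qc = arma::mean(q, 0);
  arma::mat P = p.each_row() - pc;
  arma::mat Q = q.each_row() - qc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, P.t() * Q);
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  R = V * D * U.t();
  arma::mat res = P * R.t() - Q;
  return std::sqrt(arma::accu(res % res) / p.n_rows);
}

static double rmsd_refined(const arma::mat& pall, const arma::mat& qall,
                           std::vector<int>& ip, std::vector<int>& jp,
                           int cycles, double cutoff) {
  arma::mat R;
  arma::rowvec pc, qc;
  arma::uvec ui(ip.size()), uj(jp.size());
  for (size_t k = 0; k < ip.size(); ++k) { ui[k] = ip[k]; uj[k] = jp[k]; }
  double rmsd = kabsch_rmsd(pall.rows(ui), qall.rows(uj), R, pc, qc);
  for (int c = 0; c < cycles; ++c) {
    arma::mat p = pall.rows(ui), q = qall.rows(uj);
    arma::mat moved = (p.each_row() - pc) * R.t();
    moved.each_row() += qc;
    arma::vec dev = arma::sqrt(arma::sum(arma::square(moved - q), 1));
    arma::uvec keep = arma::find(dev <= cutoff);
    if (keep.n_elem == ui.n_elem || keep.n_elem < 3) break;
    ui = ui(keep);
    uj = uj(keep);
    rmsd = kabsch_rmsd(pall.rows(ui), qall.rows(uj), R, pc, qc);
  }
  return rmsd;
}

// [[Rcpp::export(name = ".cpp_rmsd_refine")]]
double cpp_rmsd_refine(NumericMatrix p, NumericMatrix q, IntegerMatrix pairs,
                       int cycles, double cutoff) {
  arma::mat pa = as<arma::mat>(p), qa = as<arma::mat>(q);
  std::vector<int> ip(pairs.nrow()), jp(pairs.nrow());
  for (int k = 0; k < pairs.nrow(); ++k) {
    ip[k] = pairs(k, 0) - 1;
    jp[k] = pairs(k, 1) - 1;
  }
  return rmsd_refined(pa, qa, ip, jp, cycles, cutoff);
}

// Best ungapped-offset pairing (degenerate fallback when the optimal
// alignment is completely gapped); overlap >= 3.
static bool ungapped_pairs(const std::vector<int>& a,
                           const std::vector<int>& b,
                           const NumericMatrix& sub,
                           std::vector<int>& ip, std::vector<int>& jp) {
  int m = a.size(), n = b.size();
  double best = NEG_INF;
  int best_shift = 0;
  bool found = false;
  for (int shift = -(n - 3); shift <= m - 3; ++shift) {
    int lo = std::max(0, shift), hi = std::min(m, n + shift);
    if (hi - lo < 3) continue;
    double sc = 0.0;
    for (int i = lo; i < hi; ++i) sc += sub(a[i], b[i - shift]);
    if (sc > best) { best = sc; best_shift = shift; found = true; }
  }
  if (!found) return false;
  int lo = std::max(0, best_shift), hi = std::min(m, n + best_shift);
  ip.clear(); jp.clear();
  for (int i = lo; i < hi; ++i) { ip.push_back(i); jp.push_back(i - best_shift); }
  return true;
}

// Full pairwise C-alpha RMSD matrix: align, pair, superpose, refine.
// [[Rcpp::export(name = ".cpp_rmsd_matrix")]]
NumericMatrix cpp_rmsd_matrix(List seqs, List coords, NumericMatrix sub,
                              double open, double extend, int cycles,
                              double cutoff) {
  int n = seqs.size();
  std::vector<std::vector<int>> sv(n);
  std::vector<arma::mat> cv(n);
  for (int i = 0; i < n; ++i) {
    sv[i] = as<std::vector<int>>(seqs[i]);
    cv[i] = as<arma::mat>(coords[i]);
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      NWResult r = nw_align(sv[i], sv[j], sub, open, extend, true);
      std::vector<int> ip = r.pi, jp = r.pj;
      if ((int)ip.size() < 3) {
        if (!ungapped_pairs(sv[i], sv[j], sub, ip, jp)) {
          stop("fewer than 3 paired C-alpha atoms between two structures");
        }
      }
      double v = rmsd_refined(cv[i], cv[j], ip, jp, cycles, cutoff);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
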