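// Superposition-based structural metrics.
//
// Kabsch least-squares superposition (proper rotations only), the
// seed-extension GDT search over cutoffs {1,2,4,8} A, and the analogous
// TM-score search with the length-dependent d0. All searches operate on
// CA coordinate matrices (L x 3).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Optimal proper rotation R and translation t minimising ||A R' + t - B||.
// Returns rmsd; R, t written through references. A, B are n x 3.
static double kabsch_core(const arma::mat& A, const arma::mat& B,
                          arma::mat& R, arma::rowvec& t) {
  arma::rowvec ca = arma::mean(A, 0);
  arma::rowvec cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca;
  arma::mat Bc = B.each_row() - cb;
  arma::mat H = Ac.t() * Bc;        // 3 x 3
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (d < 0.0) ? -1.0 : 1.0;
  R = V * D * U.t();                // x_new = R * x
  t = cb - ca * R.t();
  arma::mat Afit = Ac * R.t();
  double ss = arma::accu(arma::square(Afit - Bc));
  return std::sqrt(ss / A.n_rows);
}

// [[Rcpp::export(name = ".kabsch_cpp")]]
List kabsch_cpp(const arma::mat& A, const arma::mat& B) {
  arma::mat R;
  arma::rowvec t;
  double rmsd = kabsch_core(A, B, R, t);
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["rmsd"] = rmsd);
}

// Squared distances of all rows of A (transformed) to rows of B.
static arma::vec fit_distances(const arma::mat& A, const arma::mat& B,
                               const arma::uvec& subset) {
  arma::mat R;
  arma::rowvec t;
  kabsch_core(A.rows(subset), B.rows(subset), R, t);
  arma::mat Afit = A * R.t();
  Afit.each_row() += t;
  return arma::sqrt(arma::sum(arma::square(Afit - B), 1));
}

// Seed-extension search: best fraction of residues within `cutoff` after
// superposition, maximised over seed fragments of lengths {3,5,7} at every
// start position, each refined by iterative superpose-and-include. For
// chains of up to 10 residues every residue subset of size >= 3 is used as
// a seed, which makes the search exhaustive (equal to enumeration) there.
// [[Rcpp::export(name = ".gdt_fractions_cpp")]]
NumericVector gdt_fractions_cpp(const arma::mat& A, const arma::mat& B,
                                NumericVector cutoffs) {
  const arma::uword L = A.n_rows;
  const int seed_lens[3] = {3, 5, 7};
  std::vector<arma::uvec> seeds;
  if (L <= 10) {
    for (unsigned mask = 0; mask < (1u << L); ++mask) {
      if (__builtin_popcount(mask) < 3) continue;
      std::vector<arma::uword> idx;
      for (arma::uword k = 0; k < L; ++k)
        if (mask & (1u << k)) idx.push_back(k);
      seeds.push_back(arma::uvec(idx));
    }
  } else {
    for (int si = 0; si < 3; ++si) {
      arma::uword sl = (arma::uword)seed_lens[si];
      if (sl > L) continue;
      for (arma::uword s = 0; s + sl <= L; ++s)
        seeds.push_back(arma::regspace<arma::uvec>(s, s + sl - 1));
    }
  }
  NumericVector out(cutoffs.size());
  for (int ci = 0; ci < cutoffs.size(); ++ci) {
    double cut = cutoffs[ci];
    double best = 0.0;
    for (const arma::uvec& seed : seeds) {
      arma::uvec subset = seed;
      for (int iter = 0; iter < 20; ++iter) {
        if (subset.n_elem < 3) break;
        arma::vec d = fit_distances(A, B, subset);
        arma::uvec inc = arma::find(d <= cut + 1e-9);
        double frac = (double)inc.n_elem / (double)L;
        if (frac > best) best = frac;
        if (inc.n_elem == subset.n_elem &&
            arma::all(inc == subset)) break;
        subset = inc;
      }
    }
    out[ci] = best;
  }
  return out;
}

// TM-score search. d0 supplied by the caller (length-dependent formula).
// Seeds: fragments of lengths {3, 5, 7, L/2, L}; inclusion cutoff for the
// iteration is max(d0, 1.5) A, relaxed when the subset collapses.
// [[Rcpp::export(name = ".tm_score_cpp")]]
double tm_score_cpp(const arma::mat& A, const arma::mat& B, double d0) {
  const arma::uword L = A.n_rows;
  std::vector<arma::uword> lens = {3, 5, 7, L / 2, L};
  double best = 0.0;
  double d0sq = d0 * d0;
  for (arma::uword sl : lens) {
    if (sl < 3 || sl > L) continue;
    arma::uword step = (sl >= L) ? L : std::max((arma::uword)1, sl / 2);
    for (arma::uword s = 0; s + sl <= L; s += step) {
      arma::uvec subset = arma::regspace<arma::uvec>(s, s + sl - 1);
      double cut = std::max(d0, 1.5);
      for (int iter = 0; iter < 20; ++iter) {
        if (subset.n_elem < 3) { cut *= 1.5; break; }
        arma::vec d = fit_distances(A, B, subset);
        double tm = arma::accu(1.0 / (1.0 + arma::square(d) / d0sq)) / L;
        if (tm > best) best = tm;
        arma::uvec inc = arma::find(d <= cut);
        if (inc.n_elem < 3) { cut *= 1.5; continue; }
        if (inc.n_elem == subset.n_elem && arma::all(inc == subset)) break;
        subset = inc;
      }
      if (sl >= L) break;
    }
  }
  return best;
}

// All-pairs GDT-TS on a list of L x 3 coordinate matrices (symmetric).
// [[Rcpp::export(name = ".gdt_matrix_cpp")]]
NumericMatrix gdt_matrix_cpp(List coords) {
  int n = coords.size();
  NumericMatrix M(n, n);
  NumericVector cuts = NumericVector::create(1.0, 2.0, 4.0, 8.0);
  std::vector<arma::mat> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as<arma::mat>(coords[i]);
  for (int i = 0; i < n; ++i) {
    M(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      NumericVector fr = gdt_fractions_cpp(xs[i], xs[j], cuts);
      double g = (fr[0] + fr[1] + fr[2] + fr[3]) / 4.0;
      M(i, j) = g;
      M(j, i) = g;
    }
  }
  return M;
}

// All-pairs TM-score matrix.
// [[Rcpp::export(name = ".tm_matrix_cpp")]]
NumericMatrix tm_matrix_cpp(List coords, double d0) {
  int n = coords.size();
  NumericMatrix M(n, n);
  std::vector<arma::mat> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as<arma::mat>(coords[i]);
  for (int i = 0; i < n; ++i) {
    M(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double s = tm_score_cpp(xs[i], xs[j], d0);
      M(i, j) = s;
      M(j, i) = s;
    }
  }
  return M;
}
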