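// Metropolis simulated annealing of a coarse-grained CA trace against a
// restraint energy: weighted bounded-potential distance restraints
// (CB-level restraints evaluated on pseudo-CB atoms rebuilt from the CA
// geometry), chain-bond terms (3.8 +/- 0.1 A), pseudo-torsion restraints
// over the CA trace, and a soft-sphere clash term. Single-residue Cartesian
// proposals with incremental energy evaluation; the best-energy snapshot is
// returned. Uses R's RNG, so results are reproducible under set.seed().

#include <RcppArmadillo.h>
#include <set>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double BOND_LEN = 3.8;
static const double BOND_TOL = 0.1;
static const double BOND_SD = 0.1;
static const double CLASH_D = 3.5;
static const double CLASH_SD = 0.5;

static inline double bounded_pot(double d, double lb, double ub, double sd) {
  if (d < lb) {
    double z = (d - lb) / sd;
    return z * z;
  }
  if (d <= ub) return 0.0;
  double knee = ub + 0.5 * sd;
  if (d <= knee) {
    double z = (d - ub) / sd;
    return z * z;
  }
  return (d - knee) / sd + 0.25;
}

static inline double dist3(const arma::mat& X, int i, int j) {
  double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
         dz = X(i, 2) - X(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Pseudo-CB for residue i from the local CA frame; terminal or degenerate
// residues fall back to the CA position.
static arma::rowvec pseudo_cb(const arma::mat& ca, int i) {
  int L = ca.n_rows;
  if (i <= 0 || i >= L - 1) return ca.row(i);
  arma::rowvec u1 = ca.row(i) - ca.row(i - 1);
  arma::rowvec u2 = ca.row(i) - ca.row(i + 1);
  double n1 = arma::norm(u1), n2 = arma::norm(u2);
  if (n1 < 1e-8 || n2 < 1e-8) return ca.row(i);
  u1 /= n1;
  u2 /= n2;
  arma::rowvec v = u1 + u2;
  arma::rowvec nrm = arma::cross(u1, u2);
  double nv = arma::norm(v), nn = arma::norm(nrm);
  if (nv < 1e-8 || nn < 1e-8) return ca.row(i);
  arma::rowvec dir = 0.83 * (v / nv) + 0.55 * (nrm / nn);
  dir /= arma::norm(dir);
  return ca.row(i) + 1.53 * dir;
}

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

// Dihedral over CA(i-1), CA(i), CA(i+1), CA(i+2), radians.
static double ca_torsion(const arma::mat& ca, int i) {
  arma::rowvec b1 = ca.row(i) - ca.row(i - 1);
  arma::rowvec b2 = ca.row(i + 1) - ca.row(i);
  arma::rowvec b3 = ca.row(i + 2) - ca.row(i + 1);
  arma::rowvec c1 = arma::cross(b1, b2);
  arma::rowvec c2 = arma::cross(b2, b3);
  double x = arma::dot(c1, c2);
  double y = arma::dot(arma::cross(c1, c2), b2 / (arma::norm(b2) + 1e-12));
  return std::atan2(y, x);
}

struct AnnealState {
  arma::mat ca;
  arma::mat cb;
  int L;
  // restraints
  arma::ivec ri, rj;
  arma::ivec cbi, cbj;
  arma::vec lb, ub, sd, w;
  // torsion entries (dihedral anchored at residue idx: CA idx-1 .. idx+2)
  arma::ivec tor_idx;
  arma::vec tor_target, tor_tol, tor_w;
  // incidence
  std::vector<std::vector<int>> res2restr;
  std::vector<std::vector<int>> res2tor;
  double bond_w, clash_w, tor_scale;

  arma::rowvec atom(int r, int use_cb) const {
    return use_cb ? cb.row(r) : ca.row(r);
  }

  double restraint_energy(int k) const {
    double d = arma::norm(atom(ri[k], cbi[k]) - atom(rj[k], cbj[k]));
    return w[k] * bounded_pot(d, lb[k], ub[k], sd[k]);
  }

  double torsion_energy(int k) const {
    int i = tor_idx[k];
    double diff = wrap_pi(ca_torsion(ca, i) - tor_target[k]);
    double excess = std::fabs(diff) - tor_tol[k];
    if (excess <= 0.0) return 0.0;
    double z = excess / tor_tol[k];
    return tor_scale * tor_w[k] * z * z;
  }

  double bond_energy(int i) const {  // bond between i and i+1
    double d = dist3(ca, i, i + 1);
    return bond_w * bounded_pot(d, BOND_LEN - BOND_TOL, BOND_LEN + BOND_TOL,
                                BOND_SD);
  }

  double clash_energy_res(int k) const {
    double e = 0.0;
    for (int j = 0; j < L; ++j) {
      if (std::abs(j - k) < 2) continue;
      double d = dist3(ca, k, j);
      if (d < CLASH_D) {
        double z = (CLASH_D - d) / CLASH_SD;
        e += clash_w * z * z;
      }
    }
    return e;
  }

  // Terms touched by a move of residue k.
  double local_energy(int k) const {
    double e = 0.0;
    for (int r : res2restr[k]) e += restraint_energy(r);
    for (int t : res2tor[k]) e += torsion_energy(t);
    if (k > 0) e += bond_energy(k - 1);
    if (k < L - 1) e += bond_energy(k);
    e += clash_energy_res(k);
    return e;
  }

  double full_energy() const {
    double e = 0.0;
    for (arma::uword k = 0; k < ri.n_elem; ++k) e += restraint_energy(k);
    for (arma::uword t = 0; t < tor_idx.n_elem; ++t) e += torsion_energy(t);
    for (int i = 0; i < L - 1; ++i) e += bond_energy(i);
    for (int i = 0; i < L; ++i)
      for (int j = i + 2; j < L; ++j) {
        double d = dist3(ca, i, j);
        if (d < CLASH_D) {
          double z = (CLASH_D - d) / CLASH_SD;
          e += clash_w * z * z;
        }
      }
    return e;
  }

  void refresh_cb(int k) {
    for (int i = std::max(0, k - 1); i <= std::min(L - 1, k + 1); ++i)
      cb.row(i) = pseudo_cb(ca, i);
  }
};

// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(const arma::mat& ca0, IntegerVector ri, IntegerVector rj,
                IntegerVector cbi, IntegerVector cbj, NumericVector lb,
                NumericVector ub, NumericVector sd, NumericVector w,
                IntegerVector tor_idx, NumericVector tor_target_deg,
                NumericVector tor_tol_deg, NumericVector tor_w, int n_steps,
                double T_start, double T_end, double step_size,
                double bond_weight, double clash_weight,
                double torsion_weight) {
  AnnealState st;
  st.ca = ca0;
  st.L = ca0.n_rows;
  int L = st.L;
  int nr = ri.size();
  st.ri = arma::ivec(nr);
  st.rj = arma::ivec(nr);
  st.cbi = arma::ivec(nr);
  st.cbj = arma::ivec(nr);
  st.lb = as<arma::vec>(lb);
  st.ub = as<arma::vec>(ub);
  st.sd = as<arma::vec>(sd);
  st.w = as<arma::vec>(w);
  for (int k = 0; k < nr; ++k) {
    st.ri[k] = ri[k] - 1;
    st.rj[k] = rj[k] - 1;
    st.cbi[k] = cbi[k];
    st.cbj[k] = cbj[k];
  }
  int nt = tor_idx.size();
  st.tor_idx = arma::ivec(nt);
  st.tor_target = arma::vec(nt);
  st.tor_tol = arma::vec(nt);
  st.tor_w = as<arma::vec>(tor_w);
  for (int k = 0; k < nt; ++k) {
    st.tor_idx[k] = tor_idx[k] - 1;  // anchored residue, 0-based
    st.tor_target[k] = tor_target_deg[k] * M_PI / 180.0;
    st.tor_tol[k] = std::max(1e-3, tor_tol_deg[k] * M_PI / 180.0);
  }
  st.bond_w = bond_weight;
  st.clash_w = clash_weight;
  st.tor_scale = torsion_weight;

  // incidence lists
  st.res2restr.assign(L, {});
  st.res2tor.assign(L, {});
  for (int k = 0; k < nr; ++k) {
    std::set<int> deps;
    for (int e = 0; e < 2; ++e) {
      int r = e == 0 ? st.ri[k] : st.rj[k];
      int usecb = e == 0 ? st.cbi[k] : st.cbj[k];
      deps.insert(r);
      if (usecb) {
        if (r > 0) deps.insert(r - 1);
        if (r < L - 1) deps.insert(r + 1);
      }
    }
    for (int d : deps) st.res2restr[d].push_back(k);
  }
  for (int k = 0; k < nt; ++k) {
    int i = st.tor_idx[k];
    for (int d = i - 1; d <= i + 2; ++d)
      if (d >= 0 && d < L) st.res2tor[d].push_back(k);
  }

  st.cb = arma::mat(L, 3);
  for (int i = 0; i < L; ++i) st.cb.row(i) = pseudo_cb(st.ca, i);

  RNGScope scope;
  bool greedy = (T_start <= T_end * (1.0 + 1e-12));
  double E = st.full_energy();
  double E0 = E;
  double bestE = E;
  arma::mat best = st.ca;
  long accepted = 0;
  double cool = (n_steps > 1)
                    ? std::pow(T_end / T_start, 1.0 / (double)(n_steps - 1))
                    : 1.0;
  double T = T_start;
  for (int stp = 0; stp < n_steps; ++stp) {
    double sigma = step_size * std::sqrt(std::max(T / T_start, 0.01));
    bool accept;
    double dE;
    if (L >= 6 && unif_rand() < 0.02) {
      // hinge move: rotate one chain end about a random axis through a
      // pivot residue; full-energy evaluation (rare, so affordable)
      int h = 1 + (int)std::floor(unif_rand() * (L - 2));
      bool downstream = unif_rand() < 0.5;
      arma::rowvec axis(3);
      for (int c = 0; c < 3; ++c) axis(c) = norm_rand();
      axis /= (arma::norm(axis) + 1e-12);
      double ang = 0.35 * std::sqrt(std::max(T / T_start, 0.01)) *
                   norm_rand();
      double ca_ = std::cos(ang), sa_ = std::sin(ang);
      arma::mat K = {{0, -axis(2), axis(1)},
                     {axis(2), 0, -axis(0)},
                     {-axis(1), axis(0), 0}};
      arma::mat Rm = arma::eye(3, 3) + sa_ * K + (1.0 - ca_) * K * K;
      arma::mat old_ca = st.ca;
      arma::mat old_cb = st.cb;
      double e_before = st.full_energy();
      arma::rowvec pivot = st.ca.row(h);
      int from = downstream ? h + 1 : 0;
      int to = downstream ? L - 1 : h - 1;
      for (int r = from; r <= to; ++r)
        st.ca.row(r) = (st.ca.row(r) - pivot) * Rm.t() + pivot;
      for (int r = 0; r < L; ++r) st.cb.row(r) = pseudo_cb(st.ca, r);
      double e_after = st.full_energy();
      dE = e_after - e_before;
      if (greedy)
        accept = (dE <= 0.0);
      else
        accept = (dE <= 0.0) || (unif_rand() < std::exp(-dE / T));
      if (accept) {
        E = e_after;
        ++accepted;
        if (E < bestE - 1e-12) {
          bestE = E;
          best = st.ca;
        }
      } else {
        st.ca = old_ca;
        st.cb = old_cb;
        E = e_before;
      }
      if (!greedy) T *= cool;
      continue;
    }
    int k = (int)std::floor(unif_rand() * L);
    if (k >= L) k = L - 1;
    arma::rowvec old = st.ca.row(k);
    arma::mat oldcb = st.cb.rows(std::max(0, k - 1), std::min(L - 1, k + 1));
    double e_before = st.local_energy(k);
    st.ca(k, 0) += sigma * norm_rand();
    st.ca(k, 1) += sigma * norm_rand();
    st.ca(k, 2) += sigma * norm_rand();
    st.refresh_cb(k);
    double e_after = st.local_energy(k);
    dE = e_after - e_before;
    if (greedy)
      accept = (dE <= 0.0);
    else
      accept = (dE <= 0.0) || (unif_rand() < std::exp(-dE / T));
    if (accept) {
      E += dE;
      ++accepted;
      if (E < bestE - 1e-12) {
        bestE = E;
        best = st.ca;
      }
    } else {
      st.ca.row(k) = old;
      st.cb.rows(std::max(0, k - 1), std::min(L - 1, k + 1)) = oldcb;
    }
    if ((stp + 1) % 50000 == 0) {  // guard against incremental drift
      E = st.full_energy();
      if (E < bestE - 1e-12) {
        bestE = E;
        best = st.ca;
      }
    }
    if (!greedy) T *= cool;
  }
  // re-evaluate the snapshot exactly
  arma::mat cur = st.ca;
  st.ca = best;
  for (int i = 0; i < L; ++i) st.cb.row(i) = pseudo_cb(st.ca, i);
  double bestE_exact = st.full_energy();
  return List::create(_["coords"] = best, _["energy"] = bestE_exact,
                      _["energy_initial"] = E0,
                      _["acceptance"] = (double)accepted / (double)n_steps);
}

// [[Rcpp::export(name = ".pseudo_cb_cpp")]]
arma::mat pseudo_cb_all(const arma::mat& ca) {
  arma::mat cb(ca.n_rows, 3);
  for (arma::uword i = 0; i < ca.n_rows; ++i)
    cb.row(i) = pseudo_cb(ca, (int)i);
  return cb;
}
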