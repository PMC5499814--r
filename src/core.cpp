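// Computational core: GY94-type codon rate matrices with eigendecomposition,
// Felsenstein pruning for the 4-class branch-site mixture, profile-profile
// protein alignment, and Gillespie simulation of codon evolution with
// frame-preserving indels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Eig {
  arma::mat V;   // D^{-1/2} U
  arma::mat W;   // U^T D^{1/2}
  arma::vec lam;
};

// unscaled GY94 rate matrix: q_ij = pi_j * kappa^[transition] * omega^[nonsyn]
// for single-nucleotide changes; type codes: 0 none, 1 syn tv, 2 syn ts,
// 3 nonsyn tv, 4 nonsyn ts
arma::mat gy94_Q(const arma::imat& type, const arma::vec& pi, double kappa,
                 double omega) {
  const int n = 61;
  arma::mat Q(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double rs = 0.0;
    for (int j = 0; j < n; ++j) {
      int t = type(i, j);
      if (t == 0) continue;
      double r = pi[j];
      if (t == 2 || t == 4) r *= kappa;
      if (t >= 3) r *= omega;
      Q(i, j) = r;
      rs += r;
    }
    Q(i, i) = -rs;
  }
  return Q;
}

Eig eig_reversible(const arma::imat& type, const arma::vec& pi, double kappa,
                   double omega) {
  arma::mat Q = gy94_Q(type, pi, kappa, omega);
  arma::vec s = arma::sqrt(pi);
  arma::mat B = Q;
  for (int i = 0; i < 61; ++i)
    for (int j = 0; j < 61; ++j)
      B(i, j) *= s[i] / s[j];
  B = 0.5 * (B + B.t());
  Eig e;
  arma::mat U;
  arma::eig_sym(e.lam, U, B);
  e.V = U;
  e.V.each_col() /= s;
  e.W = U.t();
  e.W.each_row() %= s.t();
  return e;
}

arma::mat pmat(const Eig& e, double t) {
  arma::mat M = e.V;
  arma::rowvec ex = arma::exp(e.lam.t() * t);
  M.each_row() %= ex;
  arma::mat P = M * e.W;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// conditional likelihoods at the root of one subtree, given background
// eigensystem; prog describes a postorder edge list (children before
// parents).  A tip-only side (n_nodes == 0) returns the tip indicator.
arma::mat subtree_cond(const List& prog, const IntegerMatrix& tips,
                       const Eig& eig, double u, int npat) {
  const int n_nodes = as<int>(prog["n_nodes"]);
  if (n_nodes == 0) {
    int tip = as<int>(prog["tip"]) - 1;
    arma::mat C(61, npat, arma::fill::zeros);
    for (int p = 0; p < npat; ++p) {
      int s = tips(tip, p);
      if (s > 0) C(s - 1, p) = 1.0;
      else C.col(p).ones();
    }
    return C;
  }
  IntegerVector child_node = prog["edge_child_node"];
  IntegerVector parent_node = prog["edge_parent_node"];
  IntegerVector child_tip = prog["edge_child_tip"];
  NumericVector len = prog["edge_len"];
  std::vector<arma::mat> cond(n_nodes);
  std::vector<bool> init(n_nodes, false);
  const int ne = child_node.size();
  for (int k = 0; k < ne; ++k) {
    arma::mat P = pmat(eig, u * len[k]);
    arma::mat contrib;
    if (child_tip[k] > 0) {
      int tip = child_tip[k] - 1;
      contrib.set_size(61, npat);
      for (int p = 0; p < npat; ++p) {
        int s = tips(tip, p);
        if (s > 0) contrib.col(p) = P.col(s - 1);
        else contrib.col(p).ones();
      }
    } else {
      contrib = P * cond[child_node[k] - 1];
    }
    int par = parent_node[k] - 1;
    if (!init[par]) { cond[par] = contrib; init[par] = true; }
    else cond[par] %= contrib;
  }
  return cond[n_nodes - 1];
}

arma::rowvec combine_root(const arma::mat& A, const arma::mat& B,
                          const arma::mat& Pfg, const arma::vec& pi) {
  arma::mat PB = Pfg * B;
  arma::mat M = A % PB;
  M.each_col() %= pi;
  return arma::sum(M, 0);
}

} // namespace

// Per-site-pattern likelihoods of the four branch-site classes.
// Classes: 0 (bg omega0 / fg omega0), 1 (bg 1 / fg 1),
//          2a (bg omega0 / fg omega2), 2b (bg 1 / fg omega2).
// Pass omega2 = 1 for the null model; only_m0 computes class 0 only
// (single-ratio M0 model with omega = omega0).
// [[Rcpp::export]]
NumericMatrix cpp_class_site_lik(IntegerMatrix type_, NumericVector pi_,
                                 double kappa, double omega0, double omega2,
                                 double u, double t_fg, List progA, List progB,
                                 IntegerMatrix tips, bool only_m0) {
  arma::imat type(61, 61);
  for (int i = 0; i < 61; ++i)
    for (int j = 0; j < 61; ++j) type(i, j) = type_(i, j);
  arma::vec pi = as<arma::vec>(pi_);
  const int npat = tips.ncol();

  Eig e0 = eig_reversible(type, pi, kappa, omega0);
  arma::mat A0 = subtree_cond(progA, tips, e0, u, npat);
  arma::mat B0 = subtree_cond(progB, tips, e0, u, npat);
  NumericMatrix out(4, npat);
  arma::mat Pfg0 = pmat(e0, u * t_fg);
  arma::rowvec c0 = combine_root(A0, B0, Pfg0, pi);
  for (int p = 0; p < npat; ++p) out(0, p) = c0[p];
  if (only_m0) return out;

  Eig e1 = eig_reversible(type, pi, kappa, 1.0);
  arma::mat A1 = subtree_cond(progA, tips, e1, u, npat);
  arma::mat B1 = subtree_cond(progB, tips, e1, u, npat);
  arma::mat Pfg1 = pmat(e1, u * t_fg);
  arma::rowvec c1 = combine_root(A1, B1, Pfg1, pi);

  Eig e2 = eig_reversible(type, pi, kappa, omega2);
  arma::mat Pfg2 = pmat(e2, u * t_fg);
  arma::rowvec c2a = combine_root(A0, B0, Pfg2, pi);
  arma::rowvec c2b = combine_root(A1, B1, Pfg2, pi);
  for (int p = 0; p < npat; ++p) {
    out(1, p) = c1[p];
    out(2, p) = c2a[p];
    out(3, p) = c2b[p];
  }
  return out;
}

// Transition probability matrix exp(Q t) for a scaled or unscaled GY94
// model, via symmetric eigendecomposition.
// [[Rcpp::export]]
NumericMatrix cpp_pmat(IntegerMatrix type_, NumericVector pi_, double kappa,
                       double omega, double t, double scale) {
  arma::imat type(61, 61);
  for (int i = 0; i < 61; ++i)
    for (int j = 0; j < 61; ++j) type(i, j) = type_(i, j);
  arma::vec pi = as<arma::vec>(pi_);
  Eig e = eig_reversible(type, pi, kappa, omega);
  arma::mat P = pmat(e, t * scale);
  return wrap(P);
}

// Affine-gap (Gotoh) global alignment of two alignment profiles.
// profA, profB: (n_res x L) residue frequency columns (gap mass excluded,
// columns need not sum to 1); sub: n_res x n_res substitution scores.
// Returns path codes: 0 = columns from both, 1 = column from A vs gap,
// 2 = column from B vs gap.
// [[Rcpp::export]]
IntegerVector cpp_profile_align(NumericMatrix profA, NumericMatrix profB,
                                NumericMatrix sub, double gap_open,
                                double gap_ext) {
  const int la = profA.ncol(), lb = profB.ncol(), nr = sub.nrow();
  arma::mat A = as<arma::mat>(profA), B = as<arma::mat>(profB),
            S = as<arma::mat>(sub);
  arma::mat score = A.t() * S * B; // la x lb column-pair scores
  const double NEG = -1e30;
  arma::mat M(la + 1, lb + 1), X(la + 1, lb + 1), Y(la + 1, lb + 1);
  arma::imat tM(la + 1, lb + 1), tX(la + 1, lb + 1), tY(la + 1, lb + 1);
  M.fill(NEG); X.fill(NEG); Y.fill(NEG);
  M(0, 0) = 0.0;
  for (int i = 1; i <= la; ++i) {
    X(i, 0) = -gap_open - gap_ext * (i - 1);
    tX(i, 0) = i == 1 ? 0 : 1;
  }
  for (int j = 1; j <= lb; ++j) {
    Y(0, j) = -gap_open - gap_ext * (j - 1);
    tY(0, j) = j == 1 ? 0 : 2;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double m = M(i - 1, j - 1), x = X(i - 1, j - 1), y = Y(i - 1, j - 1);
      double best = m; int tb = 0;
      if (x > best) { best = x; tb = 1; }
      if (y > best) { best = y; tb = 2; }
      M(i, j) = best + score(i - 1, j - 1);
      tM(i, j) = tb;
      double xo = M(i - 1, j) - gap_open, xe = X(i - 1, j) - gap_ext;
      if (xo >= xe) { X(i, j) = xo; tX(i, j) = 0; }
      else { X(i, j) = xe; tX(i, j) = 1; }
      double yo = M(i, j - 1) - gap_open, ye = Y(i, j - 1) - gap_ext;
      if (yo >= ye) { Y(i, j) = yo; tY(i, j) = 0; }
      else { Y(i, j) = ye; tY(i, j) = 2; }
    }
  }
  int i = la, j = lb, state;
  double best = M(la, lb); state = 0;
  if (X(la, lb) > best) { best = X(la, lb); state = 1; }
  if (Y(la, lb) > best) { best = Y(la, lb); state = 2; }
  std::vector<int> path;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      path.push_back(0);
      state = tM(i, j);
      --i; --j;
    } else if (state == 1) {
      path.push_back(1);
      state = tX(i, j);
      --i;
    } else {
      path.push_back(2);
      state = tY(i, j);
      --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}

// Gillespie evolution of one codon sequence along one branch.
// seq: codon states 1..61; omega_site: per-site omega on this branch;
// base_class/selected/pos: per-site annotations carried through indels;
// t: branch duration on the normalized time scale (rate_scale multiplies
// all substitution rates so that the branch's scheme-average rate is 1);
// insertions draw a baseline class from (atom_omegas, atom_probs) and are
// flagged selected with probability fg_fraction; the foreground omega
// applies to selected sites only when fg_active is true (the tested
// branch).  subst_indel_ratio is the event-rate ratio; prob_ins the
// insertion share of indel events; q_geo the geometric length parameter.
// [[Rcpp::export]]
List cpp_evolve_branch(IntegerVector seq_, NumericVector omega_site_,
                       IntegerVector base_class_, LogicalVector selected_,
                       NumericVector pos_, double t, double rate_scale,
                       IntegerMatrix type_, NumericVector pi_, double kappa,
                       NumericVector atom_omegas, NumericVector atom_probs,
                       double fg_fraction, double fg_omega, bool fg_active,
                       double subst_indel_ratio, double prob_ins,
                       double q_geo) {
  const int n61 = 61;
  std::vector<int> seq(seq_.begin(), seq_.end());
  std::vector<double> omg(omega_site_.begin(), omega_site_.end());
  std::vector<int> bcl(base_class_.begin(), base_class_.end());
  std::vector<int> sel(selected_.begin(), selected_.end());
  std::vector<double> pos(pos_.begin(), pos_.end());
  arma::vec pi = as<arma::vec>(pi_);
  arma::imat type(n61, n61);
  for (int i = 0; i < n61; ++i)
    for (int j = 0; j < n61; ++j) type(i, j) = type_(i, j);

  // per-codon synonymous and nonsynonymous exit-rate components
  arma::vec syn_exit(n61, arma::fill::zeros), ns_exit(n61, arma::fill::zeros);
  for (int i = 0; i < n61; ++i)
    for (int j = 0; j < n61; ++j) {
      int tc = type(i, j);
      if (tc == 0) continue;
      double r = pi[j] * ((tc == 2 || tc == 4) ? kappa : 1.0);
      if (tc >= 3) ns_exit[i] += r; else syn_exit[i] += r;
    }

  int n_sub = 0, n_ins = 0, n_del = 0;
  double clock = 0.0;
  const int n_atoms = atom_omegas.size();

  auto draw_atom = [&]() {
    double uu = R::runif(0.0, 1.0), c = 0.0;
    for (int k = 0; k < n_atoms; ++k) {
      c += atom_probs[k];
      if (uu <= c) return k;
    }
    return n_atoms - 1;
  };
  auto geom_len = [&]() {
    // P(L = k) = (1 - q) q^(k-1), k >= 1
    return 1 + (int)R::rgeom(1.0 - q_geo);
  };

  while (true) {
    const int L = (int)seq.size();
    double r_sub = 0.0;
    std::vector<double> site_rate(L);
    for (int s = 0; s < L; ++s) {
      double r = (syn_exit[seq[s] - 1] + omg[s] * ns_exit[seq[s] - 1]) *
                 rate_scale;
      site_rate[s] = r;
      r_sub += r;
    }
    double r_ind = r_sub / subst_indel_ratio;
    double r_tot = r_sub + r_ind;
    if (r_tot <= 0.0) break;
    clock += R::rexp(1.0 / r_tot);
    if (clock >= t) break;
    if (R::runif(0.0, 1.0) < r_sub / r_tot) {
      // substitution: pick site by rate, then target codon by row rates
      double uu = R::runif(0.0, 1.0) * r_sub, c = 0.0;
      int s = L - 1;
      for (int k = 0; k < L; ++k) {
        c += site_rate[k];
        if (uu <= c) { s = k; break; }
      }
      int from = seq[s] - 1;
      double row[61], rowsum = 0.0;
      for (int j = 0; j < n61; ++j) {
        int tc = type(from, j);
        double r = 0.0;
        if (tc != 0) {
          r = pi[j] * ((tc == 2 || tc == 4) ? kappa : 1.0);
          if (tc >= 3) r *= omg[s];
        }
        row[j] = r;
        rowsum += r;
      }
      double u2 = R::runif(0.0, 1.0) * rowsum, c2 = 0.0;
      for (int j = 0; j < n61; ++j) {
        c2 += row[j];
        if (u2 <= c2) { seq[s] = j + 1; break; }
      }
      ++n_sub;
    } else if (R::runif(0.0, 1.0) < prob_ins) {
      // insertion after position j0 (0..L)
      int j0 = (int)std::floor(R::runif(0.0, 1.0) * (L + 1));
      if (j0 > L) j0 = L;
      int len = geom_len();
      double lo = (j0 == 0) ? pos.front() - 1.0 : pos[j0 - 1];
      double hi = (j0 == L) ? pos.back() + 1.0 : pos[j0];
      std::vector<int> nseq(len);
      std::vector<double> nomg(len), npos(len);
      std::vector<int> nbcl(len), nsel(len);
      for (int k = 0; k < len; ++k) {
        double uu = R::runif(0.0, 1.0), c = 0.0;
        int cod = n61 - 1;
        for (int j = 0; j < n61; ++j) {
          c += pi[j];
          if (uu <= c) { cod = j; break; }
        }
        nseq[k] = cod + 1;
        int a = draw_atom();
        bool fsel = fg_fraction > 0.0 && R::runif(0.0, 1.0) < fg_fraction;
        nbcl[k] = a + 1;
        nsel[k] = fsel ? 1 : 0;
        nomg[k] = (fsel && fg_active) ? fg_omega : atom_omegas[a];
        npos[k] = lo + (hi - lo) * (k + 1.0) / (len + 1.0);
      }
      seq.insert(seq.begin() + j0, nseq.begin(), nseq.end());
      omg.insert(omg.begin() + j0, nomg.begin(), nomg.end());
      bcl.insert(bcl.begin() + j0, nbcl.begin(), nbcl.end());
      sel.insert(sel.begin() + j0, nsel.begin(), nsel.end());
      pos.insert(pos.begin() + j0, npos.begin(), npos.end());
      ++n_ins;
    } else {
      if (L > 1) {
        int start = (int)std::floor(R::runif(0.0, 1.0) * L);
        if (start >= L) start = L - 1;
        int len = geom_len();
        if (len > L - start) len = L - start;
        if (len >= L) len = L - 1; // never delete the whole sequence
        if (len > 0) {
          seq.erase(seq.begin() + start, seq.begin() + start + len);
          omg.erase(omg.begin() + start, omg.begin() + start + len);
          bcl.erase(bcl.begin() + start, bcl.begin() + start + len);
          sel.erase(sel.begin() + start, sel.begin() + start + len);
          pos.erase(pos.begin() + start, pos.begin() + start + len);
          ++n_del;
        }
      }
    }
  }
  return List::create(_["seq"] = wrap(seq), _["base_class"] = wrap(bcl),
                      _["selected"] = wrap(sel), _["pos"] = wrap(pos),
                      _["n_sub"] = n_sub, _["n_ins"] = n_ins,
                      _["n_del"] = n_del);
}
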