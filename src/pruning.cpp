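// Felsenstein pruning for a GY94-style codon model with branch categories.
// The 61x61 generator is built per category from (kappa, omega_cat, pi),
// scaled to one expected substitution per codon per unit branch length, and
// exponentiated through the symmetric eigendecomposition that reversibility
// affords. Per-pattern scaling guards against underflow on large trees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat build_Q(double kappa, double omega, const vec& pi,
                   const imat& pair_type) {
  const uword n = pi.n_elem;
  mat Q(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < n; ++j) {
      if (i == j) continue;
      double mult;
      switch (pair_type(i, j)) {
        case 1: mult = 1.0; break;            // synonymous transversion
        case 2: mult = kappa; break;          // synonymous transition
        case 3: mult = omega; break;          // nonsynonymous transversion
        case 4: mult = omega * kappa; break;  // nonsynonymous transition
        default: continue;                    // multi-nucleotide change
      }
      Q(i, j) = mult * pi(j);
    }
  }
  vec rs = sum(Q, 1);
  Q.diag() = -rs;
  double mean_rate = dot(pi, rs);
  if (mean_rate > 0) Q /= mean_rate;
  return Q;
}

struct EigQ {
  mat U;      // D^{-1/2} V
  mat Uinv;   // V' D^{1/2}
  vec lambda;
};

static EigQ eig_decompose(const mat& Q, const vec& pi) {
  vec sq = sqrt(pi);
  mat S = diagmat(sq) * Q * diagmat(1.0 / sq);
  S = 0.5 * (S + S.t());  // enforce symmetry against round-off
  vec eval;
  mat evec;
  eig_sym(eval, evec, S);
  EigQ e;
  e.U = diagmat(1.0 / sq) * evec;
  e.Uinv = evec.t() * diagmat(sq);
  e.lambda = eval;
  return e;
}

static mat pmat(const EigQ& e, double t) {
  mat P = e.U * diagmat(exp(e.lambda * t)) * e.Uinv;
  P.elem(find(P < 0)).zeros();  // clip tiny negative round-off
  return P;
}

// [[Rcpp::export]]
arma::mat codon_pmat_cpp(double kappa, double omega, const arma::vec& pi,
                         const arma::imat& pair_type, double t) {
  mat Q = build_Q(kappa, omega, pi, pair_type);
  return pmat(eig_decompose(Q, pi), t);
}

// [[Rcpp::export]]
arma::mat codon_Q_cpp(double kappa, double omega, const arma::vec& pi,
                      const arma::imat& pair_type) {
  return build_Q(kappa, omega, pi, pair_type);
}

// tip_states: ntip x npat, 1-based codon index, 0 = missing/ambiguous.
// edges: nedge x 2 (parent, child), ape node numbering (tips 1..ntip,
// root = ntip+1), ordered so children appear before their parent edge
// (supply a valid postorder). edge_cat: 1-based category per edge.
// [[Rcpp::export]]
double codon_loglik_cpp(const arma::imat& tip_states,
                        const arma::vec& weights,
                        const arma::imat& edges,
                        const arma::vec& edge_len,
                        const arma::ivec& edge_cat,
                        double kappa,
                        const arma::vec& omegas,
                        const arma::vec& pi,
                        const arma::imat& pair_type) {
  const uword nstate = pi.n_elem;
  const uword ntip = tip_states.n_rows;
  const uword npat = tip_states.n_cols;
  const uword nedge = edges.n_rows;
  const uword nnode = ntip + nedge + 1;  // upper bound on node ids

  std::vector<EigQ> eigs(omegas.n_elem);
  for (uword c = 0; c < omegas.n_elem; ++c) {
    mat Q = build_Q(kappa, omegas(c), pi, pair_type);
    eigs[c] = eig_decompose(Q, pi);
  }

  // partial likelihoods per node, lazily allocated
  std::vector<mat> part(nnode + 1);
  std::vector<bool> has(nnode + 1, false);
  rowvec logscale(npat, fill::zeros);

  for (uword e = 0; e < nedge; ++e) {
    uword parent = edges(e, 0);
    uword child = edges(e, 1);
    mat P = pmat(eigs[edge_cat(e) - 1], edge_len(e));

    mat Lc;
    if (child <= ntip) {
      Lc.zeros(nstate, npat);
      for (uword p = 0; p < npat; ++p) {
        int s = tip_states(child - 1, p);
        if (s > 0) Lc(s - 1, p) = 1.0;
        else Lc.col(p).ones();
      }
    } else {
      Lc = part[child];
      part[child].reset();
    }

    mat up = P * Lc;
    if (!has[parent]) {
      part[parent] = up;
      has[parent] = true;
    } else {
      part[parent] %= up;
      // rescale to dodge underflow
      rowvec m = max(part[parent], 0);
      for (uword p = 0; p < npat; ++p) {
        if (m(p) > 0 && m(p) < 1e-100) {
          part[parent].col(p) /= m(p);
          logscale(p) += std::log(m(p));
        }
      }
    }
  }

  uword root = edges(nedge - 1, 0);
  rowvec site_lik = pi.t() * part[root];
  double ll = 0.0;
  for (uword p = 0; p < npat; ++p) {
    if (site_lik(p) <= 0) return -std::numeric_limits<double>::infinity();
    ll += weights(p) * (std::log(site_lik(p)) + logscale(p));
  }
  return ll;
}

// Log-likelihood with its full analytic gradient: edge lengths via the
// two-pass (postorder partials / preorder outside-vector) algorithm, kappa
// and the per-category omegas via the eigendecomposition form of the
// Frechet derivative of exp(tQ). The generator normalisation (mean rate 1)
// is differentiated through.

struct QDeriv {
  mat Q;      // normalised generator
  mat dQdk;   // d(normalised Q)/d kappa
  mat dQdw;   // d(normalised Q)/d omega
};

static QDeriv build_Q_derivs(double kappa, double omega, const vec& pi,
                             const imat& pair_type) {
  const uword n = pi.n_elem;
  mat Q(n, n, fill::zeros), dk(n, n, fill::zeros), dw(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < n; ++j) {
      if (i == j) continue;
      switch (pair_type(i, j)) {
        case 1: Q(i, j) = pi(j); break;
        case 2: Q(i, j) = kappa * pi(j); dk(i, j) = pi(j); break;
        case 3: Q(i, j) = omega * pi(j); dw(i, j) = pi(j); break;
        case 4: Q(i, j) = omega * kappa * pi(j);
                dk(i, j) = omega * pi(j); dw(i, j) = kappa * pi(j); break;
        default: break;
      }
    }
  }
  Q.diag() = -sum(Q, 1);
  dk.diag() = -sum(dk, 1);
  dw.diag() = -sum(dw, 1);
  double r = -dot(pi, Q.diag());
  double drk = -dot(pi, dk.diag());
  double drw = -dot(pi, dw.diag());
  QDeriv out;
  out.Q = Q / r;
  out.dQdk = dk / r - Q * (drk / (r * r));
  out.dQdw = dw / r - Q * (drw / (r * r));
  return out;
}

// divided-difference kernel for d exp(tQ) in the eigenbasis
static mat frechet_gamma(const vec& lambda, double t) {
  const uword n = lambda.n_elem;
  vec el = exp(lambda * t);
  mat G(n, n);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < n; ++j) {
      double d = lambda(i) - lambda(j);
      G(i, j) = (std::abs(d) > 1e-10) ? (el(i) - el(j)) / d
                                      : t * std::exp(0.5 * t * (lambda(i) + lambda(j)));
    }
  }
  return G;
}

// [[Rcpp::export]]
Rcpp::List codon_loglik_grad_cpp(const arma::imat& tip_states,
                                 const arma::vec& weights,
                                 const arma::imat& edges,
                                 const arma::vec& edge_len,
                                 const arma::ivec& edge_cat,
                                 double kappa,
                                 const arma::vec& omegas,
                                 const arma::vec& pi,
                                 const arma::imat& pair_type) {
  const uword nstate = pi.n_elem;
  const uword ntip = tip_states.n_rows;
  const uword npat = tip_states.n_cols;
  const uword nedge = edges.n_rows;
  const uword ncat = omegas.n_elem;
  const uword nnode = ntip + nedge + 1;

  std::vector<QDeriv> qd(ncat);
  std::vector<EigQ> eigs(ncat);
  std::vector<mat> Ak(ncat), Aw(ncat);  // Uinv * dQ * U, t-independent
  for (uword c = 0; c < ncat; ++c) {
    qd[c] = build_Q_derivs(kappa, omegas(c), pi, pair_type);
    eigs[c] = eig_decompose(qd[c].Q, pi);
    Ak[c] = eigs[c].Uinv * qd[c].dQdk * eigs[c].U;
    Aw[c] = eigs[c].Uinv * qd[c].dQdw * eigs[c].U;
  }

  std::vector<mat> D(nnode + 1);
  std::vector<mat> M(nedge);
  std::vector<mat> P(nedge);
  std::vector<bool> has(nnode + 1, false);
  std::vector<rowvec> logscale(nnode + 1);

  for (uword e = 0; e < nedge; ++e) {
    uword parent = edges(e, 0);
    uword child = edges(e, 1);
    P[e] = pmat(eigs[edge_cat(e) - 1], edge_len(e));
    if (child <= ntip) {
      mat Lc(nstate, npat, fill::zeros);
      for (uword p = 0; p < npat; ++p) {
        int s = tip_states(child - 1, p);
        if (s > 0) Lc(s - 1, p) = 1.0;
        else Lc.col(p).ones();
      }
      D[child] = Lc;
      logscale[child] = rowvec(npat, fill::zeros);
    }
    M[e] = P[e] * D[child];
    if (!has[parent]) {
      D[parent] = M[e];
      logscale[parent] = logscale[child];
      has[parent] = true;
    } else {
      D[parent] %= M[e];
      logscale[parent] += logscale[child];
      rowvec m = max(D[parent], 0);
      for (uword p = 0; p < npat; ++p) {
        if (m(p) > 0 && m(p) < 1e-100) {
          D[parent].col(p) /= m(p);
          logscale[parent](p) += std::log(m(p));
        }
      }
    }
  }

  uword root = edges(nedge - 1, 0);
  rowvec site_lik = pi.t() * D[root];
  double ll = 0.0;
  for (uword p = 0; p < npat; ++p) {
    if (site_lik(p) <= 0)
      return Rcpp::List::create(
        Rcpp::Named("loglik") = -std::numeric_limits<double>::infinity(),
        Rcpp::Named("grad_edge") = Rcpp::NumericVector(nedge),
        Rcpp::Named("grad_kappa") = 0.0,
        Rcpp::Named("grad_omegas") = Rcpp::NumericVector(ncat));
    ll += weights(p) * (std::log(site_lik(p)) + logscale[root](p));
  }

  std::vector<mat> W(nnode + 1);
  W[root] = repmat(pi, 1, npat);
  vec grad_edge(nedge, fill::zeros);
  double grad_kappa = 0.0;
  vec grad_omegas(ncat, fill::zeros);

  for (uword ei = nedge; ei-- > 0;) {  // reverse postorder = preorder
    uword parent = edges(ei, 0);
    uword child = edges(ei, 1);
    uword c = edge_cat(ei) - 1;
    mat X = W[parent];
    for (uword e2 = 0; e2 < nedge; ++e2) {
      if (edges(e2, 0) == edges(ei, 0) && e2 != ei) X %= M[e2];
    }
    const mat& PD = M[ei];
    rowvec den = sum(X % PD, 0);

    mat QPD = qd[c].Q * PD;
    mat G = frechet_gamma(eigs[c].lambda, edge_len(ei));
    mat dPk = eigs[c].U * (G % Ak[c]) * eigs[c].Uinv;
    mat dPw = eigs[c].U * (G % Aw[c]) * eigs[c].Uinv;
    rowvec num_t = sum(X % QPD, 0);
    rowvec num_k = sum(X % (dPk * D[child]), 0);
    rowvec num_w = sum(X % (dPw * D[child]), 0);
    for (uword p = 0; p < npat; ++p) {
      if (den(p) > 0) {
        double w_over = weights(p) / den(p);
        grad_edge(ei) += w_over * num_t(p);
        grad_kappa += w_over * num_k(p);
        grad_omegas(c) += w_over * num_w(p);
      }
    }
    if (child > ntip) {
      W[child] = P[ei].t() * X;
      rowvec m = max(W[child], 0);
      for (uword p = 0; p < npat; ++p)
        if (m(p) > 0 && (m(p) < 1e-100 || m(p) > 1e100)) W[child].col(p) /= m(p);
    }
  }

  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("grad_edge") = Rcpp::wrap(grad_edge),
                            Rcpp::Named("grad_kappa") = grad_kappa,
                            Rcpp::Named("grad_omegas") = Rcpp::wrap(grad_omegas));
}
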