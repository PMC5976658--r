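// Block-coordinate descent for the space-by-time factorisation
//   minimise  sum_l || M^l - Wt A^l Ws ||_F^2   s.t. all factors >= 0
// Blocks are updated cyclically (Wt -> {A^l} -> Ws). Each block is solved
// by exact coordinate-wise non-negative updates (HALS for the synergy
// matrices, entrywise coordinate descent for the per-trial coefficient
// matrices), so the objective is non-increasing at every step.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static double objective(const cube& Mdat, const mat& Wt, const mat& Ws,
                        const cube& A) {
  double f = 0.0;
  for (uword l = 0; l < Mdat.n_slices; ++l) {
    mat R = Mdat.slice(l) - Wt * A.slice(l) * Ws;
    f += accu(R % R);
  }
  return f;
}

// [[Rcpp::export]]
Rcpp::List sbt_fit_cpp(const arma::cube& Mdat, arma::mat Wt, arma::mat Ws,
                       arma::cube A, int max_iter, double tol, int sweeps) {
  const uword T = Mdat.n_rows, M = Mdat.n_cols, L = Mdat.n_slices;
  const uword K = Wt.n_cols, N = Ws.n_rows;
  const double eps = 1e-12;
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  double prev = objective(Mdat, Wt, Ws, A);
  trace.push_back(prev);
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // ---- Wt update (HALS over columns) ----
    {
      mat P(T, K, fill::zeros), Q(K, K, fill::zeros);
      for (uword l = 0; l < L; ++l) {
        mat B = A.slice(l) * Ws;        // K x M
        P += Mdat.slice(l) * B.t();
        Q += B * B.t();
      }
      for (int s = 0; s < sweeps; ++s) {
        for (uword k = 0; k < K; ++k) {
          double d = Q(k, k);
          if (d < eps) continue;
          vec w = Wt.col(k) + (P.col(k) - Wt * Q.col(k)) / d;
          w.transform([](double v) { return v > 0.0 ? v : 0.0; });
          Wt.col(k) = w;
        }
      }
    }
    // ---- A update (coordinate descent per trial) ----
    {
      mat Gt = Wt.t() * Wt;             // K x K
      mat Gs = Ws * Ws.t();             // N x N
      for (uword l = 0; l < L; ++l) {
        mat F = Wt.t() * Mdat.slice(l) * Ws.t();   // K x N
        mat& Al = A.slice(l);
        mat R = Gt * Al * Gs;                       // gradient + F
        for (int s = 0; s < sweeps; ++s) {
          for (uword i = 0; i < K; ++i) {
            for (uword j = 0; j < N; ++j) {
              double d = Gt(i, i) * Gs(j, j);
              if (d < eps) continue;
              double anew = Al(i, j) - (R(i, j) - F(i, j)) / d;
              if (anew < 0.0) anew = 0.0;
              double delta = anew - Al(i, j);
              if (delta != 0.0) {
                Al(i, j) = anew;
                R += delta * (Gt.col(i) * Gs.row(j));
              }
            }
          }
        }
      }
    }
    // ---- Ws update (HALS over rows) ----
    {
      mat P(N, M, fill::zeros), Q(N, N, fill::zeros);
      for (uword l = 0; l < L; ++l) {
        mat C = Wt * A.slice(l);        // T x N
        P += C.t() * Mdat.slice(l);
        Q += C.t() * C;
      }
      for (int s = 0; s < sweeps; ++s) {
        for (uword j = 0; j < N; ++j) {
          double d = Q(j, j);
          if (d < eps) continue;
          rowvec w = Ws.row(j) + (P.row(j) - Q.row(j) * Ws) / d;
          w.transform([](double v) { return v > 0.0 ? v : 0.0; });
          Ws.row(j) = w;
        }
      }
    }

    double cur = objective(Mdat, Wt, Ws, A);
    trace.push_back(cur);
    if (prev - cur <= tol * std::max(prev, 1e-300)) {
      converged = true;
      prev = cur;
      break;
    }
    prev = cur;
  }

  return Rcpp::List::create(
    Rcpp::Named("Wt") = Wt, Rcpp::Named("Ws") = Ws, Rcpp::Named("A") = A,
    Rcpp::Named("objective") = prev,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged);
}
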