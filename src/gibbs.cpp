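// Single-site Gibbs sampler for Gaussian mixed models with class fixed
// effects, IID / pedigree-structured / order-1 random-regression random
// terms, and heterogeneous residual-variance classes.  Location parameters
// are sampled equation-by-equation from their full conditionals while a
// residual vector e = y - W theta is maintained; variances from scaled
// inverse chi-square, the 2x2 regression covariance from an inverse
// Wishart.  Uses R's RNG, so set.seed() on the R side fixes the chain.
#include <Rcpp.h>
using namespace Rcpp;

struct SparseCSC {
  IntegerVector p, i;
  NumericVector x;
  int ncol;
  SparseCSC() : ncol(0) {}
  explicit SparseCSC(S4 m) {
    p = m.slot("p");
    i = m.slot("i");
    x = m.slot("x");
    IntegerVector dim = m.slot("Dim");
    ncol = dim[1];
  }
};

struct Block {
  int kind;        // 0 fixed, 1 iid, 2 pedigree, 3 random regression
  int start;       // 0-based first coefficient
  int q;           // number of levels
  int nb;          // bases (1 unless rr)
  bool has_K;      // pedigree-type precision (A-inverse) present
  SparseCSC K;     // q x q precision structure (A-inverse), if has_K
  double prior_df, prior_scale;       // iid/pedigree variance prior
  double prior_df_G;                  // rr inverse-Wishart df
  std::vector<double> prior_V;        // rr inverse-Wishart scale (nb*nb)
  double sigma2;                      // current variance (kind 1,2)
  std::vector<double> G;              // current G0 (nb*nb, kind 3)
  std::vector<double> Ginv;           // its inverse
};

static void inv2(const std::vector<double>& A, std::vector<double>& Ai) {
  double det = A[0] * A[3] - A[1] * A[2];
  Ai[0] = A[3] / det; Ai[1] = -A[1] / det;
  Ai[2] = -A[2] / det; Ai[3] = A[0] / det;
}

// draw from inverse-Wishart(df, scale S) for 2x2 via Bartlett on Wishart(df, S^-1)
static void riwish2(double df, const std::vector<double>& S, std::vector<double>& out) {
  std::vector<double> Sinv(4);
  inv2(S, Sinv);
  // chol of Sinv (lower): L L' = Sinv
  double l11 = std::sqrt(Sinv[0]);
  double l21 = Sinv[1] / l11;
  double l22 = std::sqrt(Sinv[3] - l21 * l21);
  // Bartlett: A lower, diag sqrt(chisq), offdiag N(0,1)
  double a11 = std::sqrt(R::rchisq(df));
  double a21 = R::rnorm(0.0, 1.0);
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  // LA
  double m11 = l11 * a11;
  double m21 = l21 * a11 + l22 * a21;
  double m22 = l22 * a22;
  // W = (LA)(LA)'
  std::vector<double> W(4);
  W[0] = m11 * m11; W[1] = m11 * m21; W[2] = W[1]; W[3] = m21 * m21 + m22 * m22;
  inv2(W, out);
}

// scaled inverse chi-square draw: (SS + df*scale) / chisq(n + df)
static double rsinvchisq(double SS, double n, double df, double scale) {
  double dof = n + df;
  if (dof < 1.0) dof = 1.0;
  return (SS + df * scale) / R::rchisq(dof);
}

// quadratic/bilinear forms with sparse K: u' K v
static double quad_K(const SparseCSC& K, const double* u, const double* v) {
  double s = 0.0;
  for (int col = 0; col < K.ncol; ++col) {
    double vc = v[col];
    if (vc == 0.0) continue;
    for (int idx = K.p[col]; idx < K.p[col + 1]; ++idx) {
      s += u[K.i[idx]] * K.x[idx] * vc;
    }
  }
  return s;
}

// [[Rcpp::export(name = ".gibbs_mme_cpp")]]
List gibbs_mme_cpp(S4 W_, NumericVector y, IntegerVector rclass, int nclass,
                   List blocks_, List control) {
  SparseCSC W(W_);
  const int n = y.size();
  const int pdim = W.ncol;

  const int n_iter = as<int>(control["n_iter"]);
  const int burn_in = as<int>(control["burn_in"]);
  const int thin = as<int>(control["thin"]);
  const bool update_var = as<bool>(control["update_variances"]);
  const double rdf = as<double>(control["resid_prior_df"]);
  const double rscale = as<double>(control["resid_prior_scale"]);
  NumericVector sigma2e = clone(as<NumericVector>(control["resid_start"]));
  IntegerVector keep_idx = control["keep_idx"]; // 0-based coefficient chains

  std::vector<Block> blocks;
  for (int b = 0; b < blocks_.size(); ++b) {
    List bl = blocks_[b];
    Block B;
    B.kind = as<int>(bl["kind"]);
    B.start = as<int>(bl["start"]);
    B.q = as<int>(bl["q"]);
    B.nb = as<int>(bl["nb"]);
    B.has_K = bl.containsElementNamed("K") && !Rf_isNull(bl["K"]);
    if (B.has_K) B.K = SparseCSC(as<S4>(bl["K"]));
    if (B.kind == 1 || B.kind == 2) {
      B.prior_df = as<double>(bl["prior_df"]);
      B.prior_scale = as<double>(bl["prior_scale"]);
      B.sigma2 = as<double>(bl["sigma2"]);
    }
    if (B.kind == 3) {
      B.prior_df_G = as<double>(bl["prior_df"]);
      B.prior_V = as<std::vector<double> >(bl["prior_V"]);
      B.G = as<std::vector<double> >(bl["G0"]);
      B.Ginv.resize(4);
      inv2(B.G, B.Ginv);
    }
    blocks.push_back(B);
  }

  std::vector<double> theta(pdim, 0.0);
  std::vector<double> e(y.begin(), y.end());
  std::vector<int> nclassrec(nclass, 0);
  for (int r = 0; r < n; ++r) nclassrec[rclass[r]]++;

  // variance-chain layout: per block (iid/ped: 1; rr: 3 [g11,g12,g22]) + residual classes
  int nvar = 0;
  for (size_t b = 0; b < blocks.size(); ++b) {
    if (blocks[b].kind == 1 || blocks[b].kind == 2) nvar += 1;
    if (blocks[b].kind == 3) nvar += 3;
  }
  nvar += nclass;
  int n_ret = (n_iter - burn_in) / thin;
  NumericMatrix var_chain(n_ret, nvar);
  NumericMatrix coef_chain(n_ret, keep_idx.size());
  std::vector<double> mean_theta(pdim, 0.0), m2_theta(pdim, 0.0);
  int ret = 0;

  RNGScope scope;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // ---- location parameters: random-regression pairs jointly (2x2 block
    // full conditional; single-site updates mix very poorly when a level's
    // covariate values barely vary), everything else single site
    for (size_t b = 0; b < blocks.size(); ++b) {
      Block& B = blocks[b];
      if (B.kind == 3) {
        for (int v = 0; v < B.q; ++v) {
          int j0 = B.start + v;
          int j1 = B.start + B.q + v;
          double th0 = theta[j0], th1 = theta[j1];
          // data cross-products over the level's records (both columns share
          // the indicator's sparsity pattern and row ordering)
          double C00 = 0.0, C01 = 0.0, C11 = 0.0, r0 = 0.0, r1 = 0.0;
          int len = W.p[j0 + 1] - W.p[j0];
          for (int k2 = 0; k2 < len; ++k2) {
            int idx0 = W.p[j0] + k2;
            int idx1 = W.p[j1] + k2;
            int r = W.i[idx0];
            double w0 = W.x[idx0];
            double w1 = W.x[idx1];
            double ri = 1.0 / sigma2e[rclass[r]];
            double ecorr = e[r] + w0 * th0 + w1 * th1;
            C00 += w0 * w0 * ri; C01 += w0 * w1 * ri; C11 += w1 * w1 * ri;
            r0 += w0 * ecorr * ri; r1 += w1 * ecorr * ri;
          }
          // prior: Ginv (x) K; own-level diagonal block plus cross-level sums
          double kvv = 1.0, s0 = 0.0, s1 = 0.0;
          if (B.has_K) {
            kvv = 0.0;
            for (int idx = B.K.p[v]; idx < B.K.p[v + 1]; ++idx) {
              int w2 = B.K.i[idx];
              if (w2 == v) { kvv = B.K.x[idx]; continue; }
              s0 += B.K.x[idx] * theta[B.start + w2];
              s1 += B.K.x[idx] * theta[B.start + B.q + w2];
            }
          }
          double P00 = B.Ginv[0] * kvv, P01 = B.Ginv[2] * kvv,
                 P11 = B.Ginv[3] * kvv;
          double off0 = B.Ginv[0] * s0 + B.Ginv[2] * s1;
          double off1 = B.Ginv[1] * s0 + B.Ginv[3] * s1;
          double L00 = C00 + P00, L01 = C01 + P01, L11 = C11 + P11;
          double rhs0 = r0 - off0, rhs1 = r1 - off1;
          // solve and sample from N(Lambda^-1 rhs, Lambda^-1) via Cholesky
          double c11 = std::sqrt(L00);
          double c21 = L01 / c11;
          double c22 = std::sqrt(L11 - c21 * c21);
          // mean: forward then back substitution
          double t0 = rhs0 / c11;
          double t1 = (rhs1 - c21 * t0) / c22;
          double z1 = R::rnorm(0.0, 1.0), z0 = R::rnorm(0.0, 1.0);
          double n1 = (t1 + z1) / c22;
          double n0 = (t0 + z0 - c21 * n1) / c11;
          double d0 = n0 - th0, d1 = n1 - th1;
          for (int k2 = 0; k2 < len; ++k2) {
            int idx0 = W.p[j0] + k2;
            int idx1 = W.p[j1] + k2;
            e[W.i[idx0]] -= W.x[idx0] * d0 + W.x[idx1] * d1;
          }
          theta[j0] = n0; theta[j1] = n1;
        }
        continue;
      }
      for (int v = 0; v < B.q * B.nb; ++v) {
        int j = B.start + v;
        // data part
        double cdat = 0.0, rdat = 0.0;
        double th_j = theta[j];
        for (int idx = W.p[j]; idx < W.p[j + 1]; ++idx) {
          int r = W.i[idx];
          double w = W.x[idx];
          double ri = 1.0 / sigma2e[rclass[r]];
          cdat += w * w * ri;
          rdat += w * (e[r] + w * th_j) * ri;
        }
        // prior part
        double pdiag = 0.0, poff = 0.0;
        if (B.kind == 1) {
          pdiag = 1.0 / B.sigma2;
        } else if (B.kind == 2) {
          double inv_s2 = 1.0 / B.sigma2;
          int lev = v;
          for (int idx = B.K.p[lev]; idx < B.K.p[lev + 1]; ++idx) {
            int w2 = B.K.i[idx];
            double kv = B.K.x[idx] * inv_s2;
            if (w2 == lev) pdiag += kv;
            else poff += kv * theta[B.start + w2];
          }
        } else if (B.kind == 3) {
          int base = v / B.q;     // coefficient-major layout
          int lev = v % B.q;
          for (int b2 = 0; b2 < B.nb; ++b2) {
            double g = B.Ginv[base + 2 * b2]; // Ginv[base, b2] col-major 2x2
            if (g == 0.0) continue;
            if (B.has_K) {
              for (int idx = B.K.p[lev]; idx < B.K.p[lev + 1]; ++idx) {
                int w2 = B.K.i[idx];
                double kv = B.K.x[idx] * g;
                int jj = B.start + b2 * B.q + w2;
                if (jj == j) pdiag += kv;
                else poff += kv * theta[jj];
              }
            } else {
              int jj = B.start + b2 * B.q + lev;
              if (jj == j) pdiag += g;
              else poff += g * theta[jj];
            }
          }
        }
        double lhs = cdat + pdiag;
        if (lhs <= 0.0) continue; // coefficient with no data and flat prior
        double mu = (rdat - poff) / lhs;
        double newval = mu + R::rnorm(0.0, 1.0) / std::sqrt(lhs);
        double delta = newval - th_j;
        if (delta != 0.0) {
          for (int idx = W.p[j]; idx < W.p[j + 1]; ++idx) {
            e[W.i[idx]] -= W.x[idx] * delta;
          }
          theta[j] = newval;
        }
      }
    }

    // ---- variances
    if (update_var) {
      for (size_t b = 0; b < blocks.size(); ++b) {
        Block& B = blocks[b];
        const double* th = &theta[B.start];
        if (B.kind == 1) {
          double SS = 0.0;
          for (int v = 0; v < B.q; ++v) SS += th[v] * th[v];
          B.sigma2 = rsinvchisq(SS, B.q, B.prior_df, B.prior_scale);
        } else if (B.kind == 2) {
          double SS = quad_K(B.K, th, th);
          B.sigma2 = rsinvchisq(SS, B.q, B.prior_df, B.prior_scale);
        } else if (B.kind == 3) {
          std::vector<double> S(4);
          const double* u0 = th;
          const double* u1 = th + B.q;
          if (B.has_K) {
            S[0] = quad_K(B.K, u0, u0);
            S[1] = quad_K(B.K, u0, u1);
            S[3] = quad_K(B.K, u1, u1);
          } else {
            S[0] = S[1] = S[3] = 0.0;
            for (int v = 0; v < B.q; ++v) {
              S[0] += u0[v] * u0[v];
              S[1] += u0[v] * u1[v];
              S[3] += u1[v] * u1[v];
            }
          }
          S[2] = S[1];
          for (int k = 0; k < 4; ++k) S[k] += B.prior_V[k];
          riwish2(B.q + B.prior_df_G, S, B.G);
          inv2(B.G, B.Ginv);
        }
      }
      // ---- ancillarity rescaling for random-regression slopes: a joint
      // Metropolis move u1 -> s*u1, G0 -> diag(1,s) G0 diag(1,s) that keeps
      // the standardized effects fixed.  Breaks the funnel-shaped coupling
      // between the slope solutions and their variance, which traps the
      // plain conjugate scheme near zero when per-level slope information
      // is weak.  The group-move Jacobian (s^(q+3)) cancels against the
      // conditional-normal prior (s^-q) and most of the inverse-Wishart
      // term (s^-(df+3)), leaving likelihood ratio * s^-df * the (tiny)
      // Wishart-scale exponential term.
      for (size_t b = 0; b < blocks.size(); ++b) {
        Block& B = blocks[b];
        if (B.kind != 3) continue;
        double s = std::exp(R::rnorm(0.0, 0.3));
        double dll = 0.0;
        for (int v = 0; v < B.q; ++v) {
          int j1 = B.start + B.q + v;
          double th1 = theta[j1];
          if (th1 == 0.0) continue;
          for (int idx = W.p[j1]; idx < W.p[j1 + 1]; ++idx) {
            int r = W.i[idx];
            double T = W.x[idx] * th1;
            double enew = e[r] - (s - 1.0) * T;
            dll += -0.5 * (enew * enew - e[r] * e[r]) / sigma2e[rclass[r]];
          }
        }
        // prior df correction s^(3 - df_G) and the inverse-Wishart scale term
        std::vector<double> Gp(4);
        Gp[0] = B.G[0]; Gp[1] = s * B.G[1]; Gp[2] = s * B.G[2];
        Gp[3] = s * s * B.G[3];
        std::vector<double> Gpi(4);
        inv2(Gp, Gpi);
        double tr_new = B.prior_V[0] * Gpi[0] + B.prior_V[1] * Gpi[2] +
                        B.prior_V[2] * Gpi[1] + B.prior_V[3] * Gpi[3];
        double tr_old = B.prior_V[0] * B.Ginv[0] + B.prior_V[1] * B.Ginv[2] +
                        B.prior_V[2] * B.Ginv[1] + B.prior_V[3] * B.Ginv[3];
        double logacc = dll - B.prior_df_G * std::log(s) -
                        0.5 * (tr_new - tr_old);
        if (std::log(R::runif(0.0, 1.0)) < logacc) {
          for (int v = 0; v < B.q; ++v) {
            int j1 = B.start + B.q + v;
            double th1 = theta[j1];
            if (th1 != 0.0) {
              for (int idx = W.p[j1]; idx < W.p[j1 + 1]; ++idx) {
                e[W.i[idx]] -= (s - 1.0) * W.x[idx] * th1;
              }
              theta[j1] = s * th1;
            }
          }
          B.G = Gp;
          inv2(B.G, B.Ginv);
        }
      }
      // residual classes
      std::vector<double> SSc(nclass, 0.0);
      for (int r = 0; r < n; ++r) SSc[rclass[r]] += e[r] * e[r];
      for (int c = 0; c < nclass; ++c) {
        sigma2e[c] = rsinvchisq(SSc[c], nclassrec[c], rdf, rscale);
      }
    }

    // ---- periodic residual refresh against round-off drift
    if (iter % 500 == 0) {
      std::vector<double> Wt(n, 0.0);
      for (int j = 0; j < pdim; ++j) {
        double th_j = theta[j];
        if (th_j == 0.0) continue;
        for (int idx = W.p[j]; idx < W.p[j + 1]; ++idx) {
          Wt[W.i[idx]] += W.x[idx] * th_j;
        }
      }
      for (int r = 0; r < n; ++r) e[r] = y[r] - Wt[r];
    }

    // ---- retain
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      int col = 0;
      for (size_t b = 0; b < blocks.size(); ++b) {
        Block& B = blocks[b];
        if (B.kind == 1 || B.kind == 2) var_chain(ret, col++) = B.sigma2;
        if (B.kind == 3) {
          var_chain(ret, col++) = B.G[0];
          var_chain(ret, col++) = B.G[1];
          var_chain(ret, col++) = B.G[3];
        }
      }
      for (int c = 0; c < nclass; ++c) var_chain(ret, col++) = sigma2e[c];
      for (int k = 0; k < keep_idx.size(); ++k) {
        coef_chain(ret, k) = theta[keep_idx[k]];
      }
      ret++;
      double w1 = 1.0 / ret;
      for (int j = 0; j < pdim; ++j) {
        double d = theta[j] - mean_theta[j];
        mean_theta[j] += d * w1;
        m2_theta[j] += d * (theta[j] - mean_theta[j]);
      }
    }
    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector pm(pdim), psd(pdim);
  for (int j = 0; j < pdim; ++j) {
    pm[j] = mean_theta[j];
    psd[j] = ret > 1 ? std::sqrt(m2_theta[j] / (ret - 1)) : NA_REAL;
  }
  return List::create(_["var_chain"] = var_chain,
                      _["coef_chain"] = coef_chain,
                      _["coef_mean"] = pm,
                      _["coef_sd"] = psd,
                      _["n_retained"] = ret);
}
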