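// Core numerics for sparse NMF: Kendall tau-a, the Hoyer sparseness
// projection, and the alternating update loop (multiplicative when a factor
// is unconstrained, projected gradient with adaptive step size otherwise).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Kendall tau-a: (concordant - discordant) / (n(n-1)/2); ties count as
// neither concordant nor discordant.
// [[Rcpp::export]]
double cpp_kendall_tau_a(const arma::vec& x, const arma::vec& y) {
  const arma::uword n = x.n_elem;
  long long conc = 0, disc = 0;
  for (arma::uword i = 0; i + 1 < n; ++i) {
    const double xi = x[i], yi = y[i];
    for (arma::uword j = i + 1; j < n; ++j) {
      const double dx = xi - x[j];
      const double dy = yi - y[j];
      if (dx == 0.0 || dy == 0.0) continue;
      if ((dx > 0.0) == (dy > 0.0)) ++conc; else ++disc;
    }
  }
  const double total = 0.5 * static_cast<double>(n) * static_cast<double>(n - 1);
  return (static_cast<double>(conc) - static_cast<double>(disc)) / total;
}

// Hoyer's projection: closest non-negative vector to x with prescribed L1
// and L2 norms. Iteratively projects onto the sum hyperplane, solves for the
// intersection with the L2 sphere, and clamps negative coordinates to zero.
// [[Rcpp::export]]
arma::vec cpp_hoyer_project(const arma::vec& x, double l1, double l2) {
  const arma::uword n = x.n_elem;
  arma::vec s = x + (l1 - arma::accu(x)) / static_cast<double>(n);
  std::vector<bool> zeroed(n, false);
  arma::uword n_zero = 0;

  const arma::uword max_rounds = 10 * n + 100;
  for (arma::uword round = 0; round < max_rounds; ++round) {
    const double mval = l1 / static_cast<double>(n - n_zero);
    arma::vec m(n);
    for (arma::uword i = 0; i < n; ++i) m[i] = zeroed[i] ? 0.0 : mval;

    const arma::vec w = s - m;
    const double a = arma::dot(w, w);
    const double b = 2.0 * arma::dot(m, w);
    const double c = arma::dot(m, m) - l2 * l2;
    double t = 0.0;
    if (a > 1e-300) {
      double disc = b * b - 4.0 * a * c;
      if (disc < 0.0) disc = 0.0;
      t = (-b + std::sqrt(disc)) / (2.0 * a);
    }
    s = m + t * w;

    bool any_neg = false;
    for (arma::uword i = 0; i < n; ++i) {
      if (!zeroed[i] && s[i] < 0.0) {
        s[i] = 0.0;
        zeroed[i] = true;
        ++n_zero;
        any_neg = true;
      }
    }
    if (!any_neg) return s;
    if (n_zero >= n) break;
    // restore the L1 constraint on the surviving coordinates
    double rest = 0.0;
    for (arma::uword i = 0; i < n; ++i) if (!zeroed[i]) rest += s[i];
    const double adj = (l1 - rest) / static_cast<double>(n - n_zero);
    for (arma::uword i = 0; i < n; ++i) if (!zeroed[i]) s[i] += adj;
  }
  Rcpp::stop("Hoyer projection failed to converge");
  return s; // unreachable
}

static inline double frob_loss(const arma::mat& V, const arma::mat& W,
                               const arma::mat& H) {
  return 0.5 * arma::accu(arma::square(V - W * H));
}

// target L1 for a vector of given L2 so that Hoyer sparseness equals s
static inline double target_l1(double l2, double s, double n) {
  const double rn = std::sqrt(n);
  return l2 * (rn - s * (rn - 1.0));
}

// Project each column of M (sparseness on W) or each row (sparseness on H)
// to the target sparseness, preserving each vector's L2 norm.
static void project_cols(arma::mat& M, double s) {
  const double n = static_cast<double>(M.n_rows);
  for (arma::uword j = 0; j < M.n_cols; ++j) {
    arma::vec col = M.col(j);
    double l2 = arma::norm(col, 2);
    if (l2 < 1e-12) { // dead column: restart from a tiny uniform vector
      col.fill(1e-8);
      l2 = arma::norm(col, 2);
    }
    M.col(j) = cpp_hoyer_project(col, target_l1(l2, s, n), l2);
  }
}

static void project_rows(arma::mat& M, double s) {
  const double n = static_cast<double>(M.n_cols);
  for (arma::uword i = 0; i < M.n_rows; ++i) {
    arma::vec row = M.row(i).t();
    double l2 = arma::norm(row, 2);
    if (l2 < 1e-12) {
      row.fill(1e-8);
      l2 = arma::norm(row, 2);
    }
    M.row(i) = cpp_hoyer_project(row, target_l1(l2, s, n), l2).t();
  }
}

// Alternating sparse-NMF updates. s_w constrains columns of W, s_h rows of
// H; a zero value leaves that factor under multiplicative updates.
// [[Rcpp::export]]
List cpp_nmf_fit(const arma::mat& V, arma::mat W, arma::mat H,
                 double s_w, double s_h, int max_iter, double tol) {
  const double eps = 1e-12;
  double mu_w = 1.0, mu_h = 1.0;
  double loss = frob_loss(V, W, H);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  trace.push_back(loss);
  bool converged = false, diverged = false;
  int n_increase = 0;
  int iter = 0;

  if (s_w > 0.0) project_cols(W, s_w);
  if (s_h > 0.0) project_rows(H, s_h);
  loss = frob_loss(V, W, H);

  for (iter = 1; iter <= max_iter; ++iter) {
    // ---- update W ----
    if (s_w > 0.0) {
      const arma::mat grad = (W * H - V) * H.t();
      for (int ls = 0; ls < 40; ++ls) {
        arma::mat Wn = W - mu_w * grad;
        project_cols(Wn, s_w);
        const double new_loss = frob_loss(V, Wn, H);
        if (new_loss <= loss) {
          W = Wn;
          loss = new_loss;
          mu_w *= 1.2;
          break;
        }
        mu_w /= 2.0;
      }
    } else {
      const arma::mat num = V * H.t();
      const arma::mat den = W * (H * H.t());
      W %= num / (den + eps);
      loss = frob_loss(V, W, H);
    }

    // ---- update H ----
    if (s_h > 0.0) {
      const arma::mat grad = W.t() * (W * H - V);
      for (int ls = 0; ls < 40; ++ls) {
        arma::mat Hn = H - mu_h * grad;
        project_rows(Hn, s_h);
        const double new_loss = frob_loss(V, W, Hn);
        if (new_loss <= loss) {
          H = Hn;
          loss = new_loss;
          mu_h *= 1.2;
          break;
        }
        mu_h /= 2.0;
      }
    } else {
      const arma::mat num = W.t() * V;
      const arma::mat den = (W.t() * W) * H;
      H %= num / (den + eps);
      loss = frob_loss(V, W, H);
    }

    const double prev = trace.back();
    trace.push_back(loss);

    if (loss > prev * (1.0 + 1e-10)) {
      if (++n_increase >= 10) { diverged = true; break; }
    } else {
      n_increase = 0;
    }
    const double denom = std::max(prev, 1e-300);
    if (std::fabs(prev - loss) / denom < tol) { converged = true; break; }
  }

  return List::create(_["W"] = W, _["H"] = H,
                      _["loss_trace"] = trace,
                      _["converged"] = converged,
                      _["diverged"] = diverged,
                      _["iterations"] = std::min(iter, max_iter));
}
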