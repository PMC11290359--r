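#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact (dense) t-SNE primitives. Kept deliberately simple: all in-scope
// problem sizes are a few thousand cells, where O(n^2) is faster in practice
// than tree/interpolation approximations and is bit-reproducible.

// Squared Euclidean distance matrix.
static NumericMatrix sq_dist(const NumericMatrix& X) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = X(i, k) - X(j, k);
        s += d * d;
      }
      D(i, j) = s;
      D(j, i) = s;
    }
  }
  return D;
}

// Symmetric affinity matrix P (sums to 1) from a data matrix, with the
// per-point bandwidth set by binary search so the conditional distribution
// has the requested perplexity.
// [[Rcpp::export(name = ".tsne_affinities")]]
NumericMatrix tsne_affinities(NumericMatrix X, double perplexity,
                              int max_iter = 50, double tol = 1e-5) {
  int n = X.nrow();
  NumericMatrix D = sq_dist(X);
  NumericMatrix P(n, n);
  double logU = std::log(perplexity);

  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = R_NegInf, betamax = R_PosInf;
    std::vector<double> row(n);
    for (int it = 0; it < max_iter; ++it) {
      double sumP = 0.0;
      for (int j = 0; j < n; ++j) {
        row[j] = (j == i) ? 0.0 : std::exp(-beta * D(i, j));
        sumP += row[j];
      }
      if (sumP < 1e-300) sumP = 1e-300;
      double sumDP = 0.0;
      for (int j = 0; j < n; ++j) if (j != i) sumDP += D(i, j) * row[j];
      // Shannon entropy of the conditional distribution
      double H = std::log(sumP) + beta * sumDP / sumP;
      double diff = H - logU;
      if (std::fabs(diff) < tol) break;
      if (diff > 0) {
        betamin = beta;
        beta = std::isfinite(betamax) ? (beta + betamax) / 2.0 : beta * 2.0;
      } else {
        betamax = beta;
        beta = std::isfinite(betamin) ? (beta + betamin) / 2.0 : beta / 2.0;
      }
      for (int j = 0; j < n; ++j) row[j] = (j == i) ? 0.0 : std::exp(-beta * D(i, j));
    }
    double sumP = 0.0;
    for (int j = 0; j < n; ++j) sumP += row[j];
    if (sumP < 1e-300) sumP = 1e-300;
    for (int j = 0; j < n; ++j) P(i, j) = row[j] / sumP;
  }

  // symmetrize and normalize to a joint distribution
  double tot = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = P(i, j) + P(j, i);
      P(i, j) = v;
      P(j, i) = v;
      tot += 2.0 * v;
    }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      P(i, j) /= tot;
      if (P(i, j) < 1e-12) P(i, j) = 1e-12;
    }
  return P;
}

// Gradient of the (possibly exaggerated) KL objective at Y.
// grad_i = 4 * sum_j (p_ij - q_ij) w_ij (y_i - y_j), w_ij = 1/(1+|y_i-y_j|^2).
// [[Rcpp::export(name = ".tsne_gradient")]]
NumericMatrix tsne_gradient(NumericMatrix Y, NumericMatrix P,
                            double exaggeration = 1.0) {
  int n = Y.nrow();
  std::vector<double> yx(n), yy(n);
  for (int i = 0; i < n; ++i) { yx[i] = Y(i, 0); yy[i] = Y(i, 1); }
  // pass 1: normalization constant of the t kernel
  double Z = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = yx[i] - yx[j], dy = yy[i] - yy[j];
      Z += 2.0 / (1.0 + dx * dx + dy * dy);
    }
  double invZ = 1.0 / Z;
  // pass 2: symmetric accumulation (P is symmetric, so each unordered pair
  // contributes equal and opposite forces)
  NumericMatrix G(n, 2);
  const double* p = P.begin();
  for (int i = 0; i < n; ++i) {
    double gx = 0.0, gy = 0.0;
    const double* pi = p + (R_xlen_t)i * n;
    for (int j = i + 1; j < n; ++j) {
      double dx = yx[i] - yx[j], dy = yy[i] - yy[j];
      double w = 1.0 / (1.0 + dx * dx + dy * dy);
      double mult = (exaggeration * pi[j] - w * invZ) * w;
      gx += mult * dx;
      gy += mult * dy;
      G(j, 0) -= 4.0 * mult * dx;
      G(j, 1) -= 4.0 * mult * dy;
    }
    G(i, 0) += 4.0 * gx;
    G(i, 1) += 4.0 * gy;
  }
  return G;
}

// KL(P || Q) at the current layout, for monitoring convergence.
// [[Rcpp::export(name = ".tsne_kl")]]
double tsne_kl(NumericMatrix Y, NumericMatrix P) {
  int n = Y.nrow();
  double Z = 0.0;
  NumericMatrix W(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = Y(i, 0) - Y(j, 0), dy = Y(i, 1) - Y(j, 1);
      double w = 1.0 / (1.0 + dx * dx + dy * dy);
      W(i, j) = w;
      Z += 2.0 * w;
    }
  double kl = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double p = P(i, j) + P(j, i);
      if (p <= 0) continue;
      double q = 2.0 * W(i, j) / Z;
      if (q < 1e-300) q = 1e-300;
      kl += p * std::log(p / q);
    }
  return kl;
}
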