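// Fast kernels for coherency-matrix entropy imaging.
//
// The per-pixel operation is: average vec(J) vec(J)^H over a truncated
// rectangular kernel, optionally subtract an additive-noise term sigma2*I,
// clip negative eigenvalues, and return the base-4 von Neumann entropy of
// the trace-normalised eigenvalue spectrum.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double EIG_CLIP = 0.0;
static const double TRACE_TOL = 1e-300;

// entropy of a clipped, trace-normalised eigenvalue set, base-4 logarithm
static double entropy_from_eigs(arma::vec lam) {
  lam.transform([](double v) { return v > EIG_CLIP ? v : 0.0; });
  const double s = arma::accu(lam);
  if (!(s > TRACE_TOL) || !std::isfinite(s)) return NA_REAL;
  double e = 0.0;
  for (arma::uword i = 0; i < lam.n_elem; ++i) {
    const double p = lam(i) / s;
    if (p > 0.0) e -= p * std::log(p);
  }
  return e / std::log(4.0);
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_entropy_batch(const arma::cx_cube& C) {
  const arma::uword n = C.n_slices;
  NumericVector out(n);
  arma::vec lam;
  for (arma::uword k = 0; k < n; ++k) {
    arma::cx_mat Ck = 0.5 * (C.slice(k) + C.slice(k).t());  // enforce Hermitian
    arma::eig_sym(lam, Ck);
    out[k] = entropy_from_eigs(lam);
  }
  return out;
}

// Entropy map over one B-scan.  `t_arr` holds the vectorised Jones matrix
// (column-stacking order J11, J21, J12, J22) as a complex array of dim
// (nz, nx, 4).  Kernel is kz x kx, centred, truncated at the borders
// (mean over available pixels only; no padding).  sigma2 is the additive
// complex-noise power per Jones element, subtracted from the coherency
// diagonal before eigen-decomposition.
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_entropy_map(const ComplexVector& t_arr,
                              int nz, int nx,
                              int kz, int kx,
                              double sigma2) {
  typedef std::complex<double> cplx;
  const cplx* T = reinterpret_cast<const cplx*>(t_arr.begin());
  const int hz = kz / 2, hx = kx / 2;

  // summed-area tables of the 10 upper-triangle products t_a * conj(t_b)
  const int pairs_a[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
  const int pairs_b[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};
  const int nzs = nz + 1, nxs = nx + 1;
  std::vector<std::vector<cplx> > sat(10);
  for (int q = 0; q < 10; ++q) {
    sat[q].assign(static_cast<size_t>(nzs) * nxs, cplx(0.0, 0.0));
    const cplx* A = T + static_cast<size_t>(pairs_a[q]) * nz * nx;
    const cplx* B = T + static_cast<size_t>(pairs_b[q]) * nz * nx;
    std::vector<cplx>& S = sat[q];
    for (int j = 0; j < nx; ++j) {
      for (int i = 0; i < nz; ++i) {
        const cplx p = A[i + static_cast<size_t>(j) * nz] *
                       std::conj(B[i + static_cast<size_t>(j) * nz]);
        S[(i + 1) + static_cast<size_t>(j + 1) * nzs] =
            p + S[i + static_cast<size_t>(j + 1) * nzs] +
            S[(i + 1) + static_cast<size_t>(j) * nzs] -
            S[i + static_cast<size_t>(j) * nzs];
      }
    }
  }

  NumericMatrix out(nz, nx);
  arma::cx_mat C(4, 4);
  arma::vec lam;
  for (int j = 0; j < nx; ++j) {
    const int c0 = std::max(0, j - hx), c1 = std::min(nx - 1, j + hx);
    for (int i = 0; i < nz; ++i) {
      const int r0 = std::max(0, i - hz), r1 = std::min(nz - 1, i + hz);
      const double cnt = static_cast<double>(r1 - r0 + 1) * (c1 - c0 + 1);
      for (int q = 0; q < 10; ++q) {
        const std::vector<cplx>& S = sat[q];
        const cplx sum = S[(r1 + 1) + static_cast<size_t>(c1 + 1) * nzs] -
                         S[r0 + static_cast<size_t>(c1 + 1) * nzs] -
                         S[(r1 + 1) + static_cast<size_t>(c0) * nzs] +
                         S[r0 + static_cast<size_t>(c0) * nzs];
        cplx m = sum / cnt;
        const int a = pairs_a[q], b = pairs_b[q];
        if (a == b) {
          C(a, b) = cplx(m.real() - sigma2, 0.0);
        } else {
          C(a, b) = m;
          C(b, a) = std::conj(m);
        }
      }
      arma::eig_sym(lam, C);
      out(i, j) = entropy_from_eigs(lam);
    }
  }
  return out;
}

// Exact two-sided permutation p-value for the Spearman correlation of two
// rank vectors (ties allowed; permutes ry over all n! arrangements).
// Intended for n <= 10.
//' @noRd
// [[Rcpp::export]]
double cpp_spearman_perm_pvalue(const arma::vec& rx, const arma::vec& ry) {
  const int n = rx.n_elem;
  if (n > 10) stop("exact permutation p-value limited to n <= 10");
  const double mx = arma::mean(rx), my = arma::mean(ry);
  const double sx = std::sqrt(arma::accu(arma::square(rx - mx)));
  const double sy = std::sqrt(arma::accu(arma::square(ry - my)));
  if (sx == 0.0 || sy == 0.0) stop("constant ranks");
  arma::vec cx = rx - mx, cy = ry - my;
  const double obs = std::fabs(arma::dot(cx, cy) / (sx * sy));

  // Heap's algorithm over permutations of cy
  std::vector<double> y(cy.begin(), cy.end());
  std::vector<int> c(n, 0);
  long long total = 1, hits = 0;
  const double eps = 1e-12;
  double stat = std::fabs(arma::dot(cx, arma::vec(y)) / (sx * sy));
  if (stat >= obs - eps) ++hits;
  int i = 0;
  long long count = 1;
  while (i < n) {
    if (c[i] < i) {
      if (i % 2 == 0) std::swap(y[0], y[i]);
      else std::swap(y[c[i]], y[i]);
      double dot = 0.0;
      for (int k = 0; k < n; ++k) dot += cx[k] * y[k];
      stat = std::fabs(dot / (sx * sy));
      if (stat >= obs - eps) ++hits;
      ++count;
      ++c[i];
      i = 0;
    } else {
      c[i] = 0;
      ++i;
    }
  }
  total = count;
  return static_cast<double>(hits) / static_cast<double>(total);
}
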