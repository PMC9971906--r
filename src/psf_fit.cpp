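#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Integrated symmetric 2D Gaussian + constant background, fitted to a small
// window by Levenberg-Marquardt. Model per pixel (x, y integer centers):
//   mu = b + A * gx(x) * gy(y),  gx = Phi((dx+.5)/s) - Phi((dx-.5)/s)
// Parameters theta = (x0, y0, A, b, s). Thousands of fits per movie make
// this the one hot spot worth compiled code.

static inline double phi(double z) { return 0.5 * erfc(-z * M_SQRT1_2); }
static inline double dnorm_(double z) {
  return exp(-0.5 * z * z) / 2.5066282746310002;
}

// [[Rcpp::export(name = ".psf_fit_cpp")]]
List psf_fit_cpp(NumericMatrix img, double x_lo, double y_lo,
                 NumericVector start, int max_iter = 100,
                 double tol = 1e-12) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  const double x_hi = x_lo + nc - 1, y_hi = y_lo + nr - 1;
  double x0 = start[0], y0 = start[1], A = start[2], b = start[3],
         s = start[4];
  const double s_lo = 0.3, s_hi = 0.5 * std::max(nr, nc);

  std::vector<double> gx(nc), gy(nr), dgx(nc), dgy(nr), dsx(nc), dsy(nr);
  double lambda = 1e-3, rss = 0.0;
  bool converged = false;

  auto model = [&](double x0_, double y0_, double A_, double b_, double s_,
                   bool want_grad) -> double {
    for (int j = 0; j < nc; ++j) {
      double dx = (x_lo + j) - x0_;
      double ap = (dx + 0.5) / s_, am = (dx - 0.5) / s_;
      gx[j] = phi(ap) - phi(am);
      if (want_grad) {
        dgx[j] = -(dnorm_(ap) - dnorm_(am)) / s_;          // d gx / d x0
        dsx[j] = -(ap * dnorm_(ap) - am * dnorm_(am)) / s_; // d gx / d s
      }
    }
    for (int i = 0; i < nr; ++i) {
      double dy = (y_lo + i) - y0_;
      double ap = (dy + 0.5) / s_, am = (dy - 0.5) / s_;
      gy[i] = phi(ap) - phi(am);
      if (want_grad) {
        dgy[i] = -(dnorm_(ap) - dnorm_(am)) / s_;
        dsy[i] = -(ap * dnorm_(ap) - am * dnorm_(am)) / s_;
      }
    }
    double ss = 0.0;
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j) {
        double r = img(i, j) - (b_ + A_ * gx[j] * gy[i]);
        ss += r * r;
      }
    return ss;
  };

  rss = model(x0, y0, A, b, s, false);

  for (int it = 0; it < max_iter; ++it) {
    model(x0, y0, A, b, s, true); // refresh gx/gy and gradients at theta
    // accumulate J^T J and J^T r (5 parameters)
    double JTJ[5][5] = {{0}}, JTr[5] = {0};
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) {
        double g = gx[j] * gy[i];
        double r = img(i, j) - (b + A * g);
        double Jrow[5];
        Jrow[0] = A * dgx[j] * gy[i];   // d mu / d x0
        Jrow[1] = A * gx[j] * dgy[i];   // d mu / d y0
        Jrow[2] = g;                    // d mu / d A
        Jrow[3] = 1.0;                  // d mu / d b
        Jrow[4] = A * (dsx[j] * gy[i] + gx[j] * dsy[i]); // d mu / d s
        for (int a = 0; a < 5; ++a) {
          JTr[a] += Jrow[a] * r;
          for (int c = a; c < 5; ++c) JTJ[a][c] += Jrow[a] * Jrow[c];
        }
      }
    }
    for (int a = 0; a < 5; ++a)
      for (int c = 0; c < a; ++c) JTJ[a][c] = JTJ[c][a];

    bool stepped = false;
    for (int tries = 0; tries < 12 && !stepped; ++tries) {
      double M[5][5], v[5];
      for (int a = 0; a < 5; ++a) {
        v[a] = JTr[a];
        for (int c = 0; c < 5; ++c) M[a][c] = JTJ[a][c];
        M[a][a] *= (1.0 + lambda);
        M[a][a] += 1e-12;
      }
      // Gaussian elimination with partial pivoting
      int piv[5] = {0, 1, 2, 3, 4};
      bool singular = false;
      for (int a = 0; a < 5 && !singular; ++a) {
        int p = a;
        for (int r2 = a + 1; r2 < 5; ++r2)
          if (std::fabs(M[r2][a]) > std::fabs(M[p][a])) p = r2;
        if (std::fabs(M[p][a]) < 1e-14) { singular = true; break; }
        if (p != a) {
          for (int c = 0; c < 5; ++c) std::swap(M[a][c], M[p][c]);
          std::swap(v[a], v[p]);
          std::swap(piv[a], piv[p]);
        }
        for (int r2 = a + 1; r2 < 5; ++r2) {
          double f = M[r2][a] / M[a][a];
          for (int c = a; c < 5; ++c) M[r2][c] -= f * M[a][c];
          v[r2] -= f * v[a];
        }
      }
      if (singular) { lambda *= 10; continue; }
      double d[5];
      for (int a = 4; a >= 0; --a) {
        double acc = v[a];
        for (int c = a + 1; c < 5; ++c) acc -= M[a][c] * d[c];
        d[a] = acc / M[a][a];
      }
      double nx0 = std::min(std::max(x0 + d[0], x_lo), x_hi);
      double ny0 = std::min(std::max(y0 + d[1], y_lo), y_hi);
      double nA = std::max(A + d[2], 0.0);
      double nb = b + d[3];
      double ns = std::min(std::max(s + d[4], s_lo), s_hi);
      double nrss = model(nx0, ny0, nA, nb, ns, false);
      if (nrss < rss) {
        double rel = (rss - nrss) / std::max(rss, 1e-300);
        x0 = nx0; y0 = ny0; A = nA; b = nb; s = ns; rss = nrss;
        lambda = std::max(lambda * 0.3, 1e-12);
        stepped = true;
        if (rel < tol) { converged = true; }
      } else {
        lambda *= 10;
      }
    }
    if (!stepped) { converged = true; break; } // stuck in a (local) minimum
    if (converged) break;
  }

  return List::create(
    _["x0"] = x0, _["y0"] = y0, _["amplitude"] = A, _["background"] = b,
    _["sigma"] = s, _["rss"] = rss, _["converged"] = converged,
    _["n"] = n);
}
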