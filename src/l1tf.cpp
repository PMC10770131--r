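// Primal-dual interior-point solver for l1 trend filtering:
//   minimize 0.5 * ||x - z||^2 + lambda * sum |z_{t-1} - 2 z_t + z_{t+1}|
// solved through its dual box-constrained QP
//   minimize 0.5 * ||D' nu||^2 - (D x)' nu   s.t.  |nu_i| <= lambda,
// with z = x - D' nu. Newton systems are pentadiagonal and solved by a
// banded LDL' factorisation in O(n) per iteration.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// y = D v (second difference), v length n, y length n-2
static void Dmul(const std::vector<double>& v, std::vector<double>& y) {
  const int m = (int)v.size() - 2;
  for (int i = 0; i < m; ++i) y[i] = v[i] - 2.0 * v[i + 1] + v[i + 2];
}

// y = D' w, w length m = n-2, y length n
static void Dtmul(const std::vector<double>& w, std::vector<double>& y) {
  const int n = (int)w.size() + 2;
  for (int i = 0; i < n; ++i) y[i] = 0.0;
  for (int i = 0; i < (int)w.size(); ++i) {
    y[i] += w[i];
    y[i + 1] -= 2.0 * w[i];
    y[i + 2] += w[i];
  }
}

// Banded LDL' factorisation of a pentadiagonal SPD matrix given by its
// diagonal d0 and sub-diagonals d1, d2 (overwritten with L and D entries),
// followed by a solve. Bands: A(i,i)=d0[i], A(i+1,i)=d1[i], A(i+2,i)=d2[i].
static void band_ldl(std::vector<double>& d0, std::vector<double>& d1,
                     std::vector<double>& d2) {
  const int m = (int)d0.size();
  for (int i = 0; i < m; ++i) {
    double di = d0[i];
    if (i >= 1) di -= d1[i - 1] * d1[i - 1] * d0[i - 1];
    if (i >= 2) di -= d2[i - 2] * d2[i - 2] * d0[i - 2];
    d0[i] = di;
    if (i + 1 < m) {
      double l1 = d1[i];
      if (i >= 1) l1 -= d1[i - 1] * d2[i - 1] * d0[i - 1];
      d1[i] = l1 / di;
    }
    if (i + 2 < m) d2[i] = d2[i] / di;
  }
}

static void band_solve(const std::vector<double>& d0,
                       const std::vector<double>& d1,
                       const std::vector<double>& d2,
                       std::vector<double>& b) {
  const int m = (int)d0.size();
  for (int i = 0; i < m; ++i) {             // L y = b
    if (i >= 1) b[i] -= d1[i - 1] * b[i - 1];
    if (i >= 2) b[i] -= d2[i - 2] * b[i - 2];
  }
  for (int i = 0; i < m; ++i) b[i] /= d0[i]; // D y
  for (int i = m - 1; i >= 0; --i) {         // L' z = y
    if (i + 1 < m) b[i] -= d1[i] * b[i + 1];
    if (i + 2 < m) b[i] -= d2[i] * b[i + 2];
  }
}

static void l1tf_one(const double* xp, int n, double lambda, double reltol,
                     int maxiter, double* out) {
  const int m = n - 2;
  const double ALPHA = 0.01, BETA = 0.5, MU = 2.0;
  const int MAXLSITER = 30;

  std::vector<double> x(xp, xp + n), Dx(m), z(m, 0.0), mu1(m, 1.0),
      mu2(m, 1.0), f1(m, -lambda), f2(m, -lambda);
  {
    std::vector<double> tmp(m);
    Dmul(x, tmp);
    Dx = tmp;
  }

  // constant bands of DDT (pentadiagonal 1 -4 6 -4 1), factorised once for
  // the primal-objective bound
  std::vector<double> c0(m, 6.0), c1(m > 1 ? m - 1 : 0, -4.0),
      c2(m > 2 ? m - 2 : 0, 1.0);
  std::vector<double> f0 = c0, fa = c1, fb = c2;
  band_ldl(f0, fa, fb);

  // Above lambda_max = ||(DD')^{-1} D x||_inf the box constraint is slack and
  // the optimum is the projection of x onto the null space of D, i.e. the
  // least-squares line. One iterative-refinement step on the nu solve guards
  // the boundary test against the O(n^4) conditioning of DD'.
  {
    std::vector<double> nu_ls = Dx, res(m), corr(m), Dtnu(n);
    band_solve(f0, fa, fb, nu_ls);
    Dtmul(nu_ls, Dtnu);
    Dmul(Dtnu, res);
    for (int i = 0; i < m; ++i) res[i] = Dx[i] - res[i];
    corr = res;
    band_solve(f0, fa, fb, corr);
    double nmax = 0.0;
    for (int i = 0; i < m; ++i)
      nmax = std::max(nmax, std::fabs(nu_ls[i] + corr[i]));
    if (nmax <= lambda) {
      // fit x ~ a + b*(i - ibar) directly for numerical exactness
      double ibar = 0.5 * (n - 1), sx = 0.0, sxt = 0.0, stt = 0.0;
      for (int i = 0; i < n; ++i) {
        double ti = i - ibar;
        sx += x[i];
        sxt += x[i] * ti;
        stt += ti * ti;
      }
      double a = sx / n, b = sxt / stt;
      for (int i = 0; i < n; ++i) out[i] = a + b * (i - ibar);
      return;
    }
  }

  std::vector<double> DTz(n), DDTz(m), w(m), r(m), dz(m), dmu1(m), dmu2(m),
      d0(m), d1(m > 1 ? m - 1 : 0), d2(m > 2 ? m - 2 : 0),
      nz(m), nmu1(m), nmu2(m), nf1(m), nf2(m), nDTz(n), nDDTz(m), tmpm(m);

  double t = 1e-10, step = INFINITY;
  for (int iter = 0; iter < maxiter; ++iter) {
    Dtmul(z, DTz);
    Dmul(DTz, DDTz);
    double DTz2 = 0.0, Dxz = 0.0;
    for (int i = 0; i < n; ++i) DTz2 += DTz[i] * DTz[i];
    for (int i = 0; i < m; ++i) Dxz += Dx[i] * z[i];

    double summu = 0.0;
    for (int i = 0; i < m; ++i) {
      w[i] = Dx[i] - (mu1[i] - mu2[i]);
      summu += mu1[i] + mu2[i];
    }
    tmpm = w;
    band_solve(f0, fa, fb, tmpm); // DDT^{-1} w
    double quad = 0.0, l1term = 0.0;
    for (int i = 0; i < m; ++i) {
      quad += w[i] * tmpm[i];
      l1term += std::fabs(Dx[i] - DDTz[i]);
    }
    double pobj1 = 0.5 * quad + lambda * summu;
    double pobj2 = 0.5 * DTz2 + lambda * l1term;
    double pobj = pobj1 < pobj2 ? pobj1 : pobj2;
    double dobj = -0.5 * DTz2 + Dxz;
    double gap = pobj - dobj;
    if (gap <= reltol * std::max(1.0, std::fabs(pobj))) break;

    if (step >= 0.2) {
      double tcand = 2.0 * m * MU / gap;
      t = std::max(tcand, 1.2 * t);
    }

    // Newton system: (DDT - diag(mu1/f1 + mu2/f2)) dz = -DDTz + w + resid
    for (int i = 0; i < m; ++i) {
      d0[i] = 6.0 - (mu1[i] / f1[i] + mu2[i] / f2[i]);
      r[i] = -DDTz[i] + Dx[i] + (1.0 / t) / f1[i] - (1.0 / t) / f2[i];
    }
    for (int i = 0; i + 1 < m; ++i) d1[i] = -4.0;
    for (int i = 0; i + 2 < m; ++i) d2[i] = 1.0;
    band_ldl(d0, d1, d2);
    dz = r;
    band_solve(d0, d1, d2, dz);

    double res0 = 0.0;
    for (int i = 0; i < m; ++i) {
      dmu1[i] = -(mu1[i] + ((1.0 / t) + dz[i] * mu1[i]) / f1[i]);
      dmu2[i] = -(mu2[i] + ((1.0 / t) - dz[i] * mu2[i]) / f2[i]);
      double rd = DDTz[i] - w[i];
      double rc1 = -mu1[i] * f1[i] - 1.0 / t;
      double rc2 = -mu2[i] * f2[i] - 1.0 / t;
      res0 += rd * rd + rc1 * rc1 + rc2 * rc2;
    }
    res0 = std::sqrt(res0);

    // largest feasible step keeping mu > 0, then backtracking on residual
    double s = 1.0;
    for (int i = 0; i < m; ++i) {
      if (dmu1[i] < 0) s = std::min(s, -0.99 * mu1[i] / dmu1[i]);
      if (dmu2[i] < 0) s = std::min(s, -0.99 * mu2[i] / dmu2[i]);
    }
    int ls;
    for (ls = 0; ls < MAXLSITER; ++ls) {
      bool feasible = true;
      for (int i = 0; i < m; ++i) {
        nz[i] = z[i] + s * dz[i];
        nmu1[i] = mu1[i] + s * dmu1[i];
        nmu2[i] = mu2[i] + s * dmu2[i];
        nf1[i] = nz[i] - lambda;
        nf2[i] = -nz[i] - lambda;
        if (nf1[i] >= 0 || nf2[i] >= 0) feasible = false;
      }
      if (feasible) {
        Dtmul(nz, nDTz);
        Dmul(nDTz, nDDTz);
        double res = 0.0;
        for (int i = 0; i < m; ++i) {
          double rd = nDDTz[i] - Dx[i] + (nmu1[i] - nmu2[i]);
          double rc1 = -nmu1[i] * nf1[i] - 1.0 / t;
          double rc2 = -nmu2[i] * nf2[i] - 1.0 / t;
          res += rd * rd + rc1 * rc1 + rc2 * rc2;
        }
        res = std::sqrt(res);
        if (res <= (1.0 - ALPHA * s) * res0) break;
      }
      s *= BETA;
    }
    step = s;
    z = nz; mu1 = nmu1; mu2 = nmu2; f1 = nf1; f2 = nf2;
  }

  Dtmul(z, DTz);
  for (int i = 0; i < n; ++i) out[i] = x[i] - DTz[i];
}

// [[Rcpp::export(name = ".l1tf_cpp")]]
NumericMatrix l1tf_cpp(NumericMatrix x, double lambda, double reltol = 1e-10,
                       int maxiter = 60) {
  const int n = x.nrow(), mcols = x.ncol();
  NumericMatrix out(n, mcols);
  for (int j = 0; j < mcols; ++j)
    l1tf_one(&x(0, j), n, lambda, reltol, maxiter, &out(0, j));
  return out;
}
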