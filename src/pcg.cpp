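// Preconditioned conjugate gradient solver for the 7-point finite-difference
// discretization of div(sigma grad V) = -source with Dirichlet conditions on
// the box boundary (ghost cells at half a spacing outside the grid).
// Matrix-free stencil; incomplete-Cholesky IC(0) preconditioner, which keeps
// iteration counts bounded under the large conductivity contrasts of the
// implanted-cochlea maps (insulating carrier vs. metal contacts).
//
// Units: face conductances in mS, right-hand side in uA, solution in mV.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// y = A x with A_ii = diag[i], off-diagonals -g along each axis
static void stencil_matvec(const std::vector<double>& x,
                           std::vector<double>& y,
                           const double* diag,
                           const double* gx,
                           const double* gy,
                           const double* gz,
                           int nx, int ny, int nz) {
  const int nxy = nx * ny;
  const int n = nxy * nz;
  for (int i = 0; i < n; ++i) y[i] = diag[i] * x[i];
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const int base = k * nxy + j * nx;
      for (int i = 0; i < nx - 1; ++i) {
        const int id = base + i;
        const double g = gx[id];
        y[id]     -= g * x[id + 1];
        y[id + 1] -= g * x[id];
      }
    }
  }
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      const int base = k * nxy + j * nx;
      for (int i = 0; i < nx; ++i) {
        const int id = base + i;
        const double g = gy[id];
        y[id]      -= g * x[id + nx];
        y[id + nx] -= g * x[id];
      }
    }
  }
  for (int k = 0; k < nz - 1; ++k) {
    const int base = k * nxy;
    for (int id = base; id < base + nxy; ++id) {
      const double g = gz[id];
      y[id]       -= g * x[id + nxy];
      y[id + nxy] -= g * x[id];
    }
  }
}

// Modified-IC(0) pivots d for M = (D + L) D^-1 (D + L)^T with L the strictly
// lower stencil part of A; dropped fill is lumped onto the diagonal
// (Gustafsson relaxation omega), which roughly halves CG iteration counts
// on these high-contrast Poisson problems relative to plain IC(0).
static void ic0_pivots(std::vector<double>& d,
                       const double* diag,
                       const double* gx, const double* gy, const double* gz,
                       int nx, int ny, int nz) {
  const int nxy = nx * ny;
  const double om = 0.95;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const int base = k * nxy + j * nx;
      for (int i = 0; i < nx; ++i) {
        const int id = base + i;
        double t = diag[id];
        if (i > 0) {
          const double g = gx[id - 1];
          t -= g * (g + om * (gy[id - 1] + gz[id - 1])) / d[id - 1];
        }
        if (j > 0) {
          const double g = gy[id - nx];
          t -= g * (g + om * (gx[id - nx] + gz[id - nx])) / d[id - nx];
        }
        if (k > 0) {
          const double g = gz[id - nxy];
          t -= g * (g + om * (gx[id - nxy] + gy[id - nxy])) / d[id - nxy];
        }
        d[id] = (t > 1e-300) ? t : diag[id]; // breakdown guard
      }
    }
  }
}

// z = M^-1 r
static void ic0_apply(const std::vector<double>& r, std::vector<double>& z,
                      std::vector<double>& work,
                      const std::vector<double>& d,
                      const double* gx, const double* gy, const double* gz,
                      int nx, int ny, int nz) {
  const int nxy = nx * ny;
  const int n = nxy * nz;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const int base = k * nxy + j * nx;
      for (int i = 0; i < nx; ++i) {
        const int id = base + i;
        double t = r[id];
        if (i > 0) t += gx[id - 1] * work[id - 1];
        if (j > 0) t += gy[id - nx] * work[id - nx];
        if (k > 0) t += gz[id - nxy] * work[id - nxy];
        work[id] = t / d[id];
      }
    }
  }
  for (int k = nz - 1; k >= 0; --k) {
    for (int j = ny - 1; j >= 0; --j) {
      const int base = k * nxy + j * nx;
      for (int i = nx - 1; i >= 0; --i) {
        const int id = base + i;
        double t = 0.0;
        if (i < nx - 1) t += gx[id] * z[id + 1];
        if (j < ny - 1) t += gy[id] * z[id + nx];
        if (k < nz - 1) t += gz[id] * z[id + nxy];
        z[id] = work[id] + t / d[id];
      }
    }
  }
}

// [[Rcpp::export]]
List pcg_solve(NumericVector diag, NumericVector gx, NumericVector gy,
               NumericVector gz, NumericVector b, IntegerVector dims,
               double tol, int maxit, NumericVector x0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double* dg = diag.begin();
  const double* px = gx.begin();
  const double* py = gy.begin();
  const double* pz = gz.begin();
  std::vector<double> x(n, 0.0), r(n), z(n), p(n), Ap(n), d(n), work(n);
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    return List::create(_["v"] = NumericVector(n), _["iterations"] = 0,
                        _["residual"] = 0.0);
  }
  ic0_pivots(d, dg, px, py, pz, nx, ny, nz);
  if (x0.size() == n) {
    for (int i = 0; i < n; ++i) x[i] = x0[i];
    stencil_matvec(x, Ap, dg, px, py, pz, nx, ny, nz);
    for (int i = 0; i < n; ++i) r[i] = b[i] - Ap[i];
  } else {
    for (int i = 0; i < n; ++i) r[i] = b[i];
  }
  ic0_apply(r, z, work, d, px, py, pz, nx, ny, nz);
  double rz = 0.0;
  for (int i = 0; i < n; ++i) { p[i] = z[i]; rz += r[i] * z[i]; }
  double resid = 1.0;
  int it = 0;
  std::vector<double> res_hist;
  for (it = 1; it <= maxit; ++it) {
    stencil_matvec(p, Ap, dg, px, py, pz, nx, ny, nz);
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    const double alpha = rz / pAp;
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rnorm += r[i] * r[i];
    }
    resid = std::sqrt(rnorm) / bnorm;
    res_hist.push_back(resid);
    if (resid <= tol) break;
    ic0_apply(r, z, work, d, px, py, pz, nx, ny, nz);
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) rz_new += r[i] * z[i];
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }
  NumericVector v(n);
  for (int i = 0; i < n; ++i) v[i] = x[i];
  return List::create(_["v"] = v,
                      _["iterations"] = std::min(it, maxit),
                      _["residual"] = resid,
                      _["residual_history"] = wrap(res_hist));
}
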