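#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Five-point Laplacian with mirror (ghost = edge value) closure. The mirror
// closure makes the stencil an exact discrete divergence of face fluxes with
// zero flux through the domain boundary, so sum(lap(f)) == 0 to rounding.
static inline double lap_at(const double* f, int i, int j, int nx, int ny,
                            double inv_dx2) {
    const int k = i + nx * j;
    const double c = f[k];
    const double up = (i > 0)      ? f[k - 1]  : c;
    const double dn = (i < nx - 1) ? f[k + 1]  : c;
    const double lf = (j > 0)      ? f[k - nx] : c;
    const double rt = (j < ny - 1) ? f[k + nx] : c;
    return (up + dn + lf + rt - 4.0 * c) * inv_dx2;
}

static void lap5(const double* f, double* out, int nx, int ny, double inv_dx2) {
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
            out[i + nx * j] = lap_at(f, i, j, nx, ny, inv_dx2);
}

// [[Rcpp::export]]
NumericMatrix cpp_laplacian5(NumericMatrix f, double dx) {
    int nx = f.nrow(), ny = f.ncol();
    NumericMatrix out(nx, ny);
    lap5(f.begin(), out.begin(), nx, ny, 1.0 / (dx * dx));
    return out;
}

// One evaluation of dphi/dt per the governing dynamics:
//  additive grouping:  M*lap(-phi + phi^3 - eps^2 lap phi)
//                      + 2 phi eps C0 B - eps^2 lap B
//  conserved grouping: environment terms moved inside the outer M*lap(.)
// with B = eps * C0 * (phi^2 - 1). Three sweeps: B (pointwise), mu (fused
// with lap phi), combine (fused with lap mu, lap B); interior sites take a
// branch-free fast path.
static void rhs_eval(const double* phi, const double* C0, double* out,
                     double* B, double* mu, int nx, int ny, double M,
                     double eps, double inv_dx2, bool conserved) {
    const int n = nx * ny;
    const double eps2 = eps * eps;
    for (int k = 0; k < n; ++k)
        B[k] = eps * C0[k] * (phi[k] * phi[k] - 1.0);

    if (conserved) {
        std::vector<double> lapB(n);
        lap5(B, lapB.data(), nx, ny, inv_dx2);
        for (int j = 0; j < ny; ++j) {
            const bool jedge = (j == 0 || j == ny - 1);
            int k = nx * j;
            for (int i = 0; i < nx; ++i, ++k) {
                const double p = phi[k];
                const double lp = (jedge || i == 0 || i == nx - 1)
                    ? lap_at(phi, i, j, nx, ny, inv_dx2)
                    : (phi[k - 1] + phi[k + 1] + phi[k - nx] + phi[k + nx]
                       - 4.0 * p) * inv_dx2;
                mu[k] = -p + p * p * p - eps2 * lp
                        + 2.0 * p * eps * C0[k] * B[k] - eps2 * lapB[k];
            }
        }
        lap5(mu, out, nx, ny, inv_dx2);
        for (int k = 0; k < n; ++k) out[k] *= M;
        return;
    }

    for (int j = 0; j < ny; ++j) {
        const bool jedge = (j == 0 || j == ny - 1);
        int k = nx * j;
        for (int i = 0; i < nx; ++i, ++k) {
            const double p = phi[k];
            const double lp = (jedge || i == 0 || i == nx - 1)
                ? lap_at(phi, i, j, nx, ny, inv_dx2)
                : (phi[k - 1] + phi[k + 1] + phi[k - nx] + phi[k + nx]
                   - 4.0 * p) * inv_dx2;
            mu[k] = -p + p * p * p - eps2 * lp;
        }
    }
    for (int j = 0; j < ny; ++j) {
        const bool jedge = (j == 0 || j == ny - 1);
        int k = nx * j;
        for (int i = 0; i < nx; ++i, ++k) {
            double lmu, lB;
            if (jedge || i == 0 || i == nx - 1) {
                lmu = lap_at(mu, i, j, nx, ny, inv_dx2);
                lB = lap_at(B, i, j, nx, ny, inv_dx2);
            } else {
                lmu = (mu[k - 1] + mu[k + 1] + mu[k - nx] + mu[k + nx]
                       - 4.0 * mu[k]) * inv_dx2;
                lB = (B[k - 1] + B[k + 1] + B[k - nx] + B[k + nx]
                      - 4.0 * B[k]) * inv_dx2;
            }
            out[k] = M * lmu + 2.0 * phi[k] * eps * C0[k] * B[k] - eps2 * lB;
        }
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_rhs(NumericMatrix phi, NumericMatrix C0, double M,
                      double eps, double dx, bool conserved) {
    int nx = phi.nrow(), ny = phi.ncol();
    const int n = nx * ny;
    NumericMatrix out(nx, ny);
    std::vector<double> B(n), mu(n);
    rhs_eval(phi.begin(), C0.begin(), out.begin(), B.data(), mu.data(),
             nx, ny, M, eps, 1.0 / (dx * dx), conserved);
    return out;
}

// Explicit Euler stepping with Dirichlet pinning re-imposed after every step.
// res_idx is 0-based into the column-major field. Aborts (ok = FALSE) on
// non-finite values or overshoot beyond 1 + delta, checked every check_every
// steps and at the end.
// [[Rcpp::export]]
List cpp_run_steps(NumericMatrix phi_in, NumericMatrix C0, double M,
                   double eps, double dt, double dx, int nsteps,
                   IntegerVector res_idx, NumericVector res_val,
                   bool conserved, double delta, int check_every) {
    int nx = phi_in.nrow(), ny = phi_in.ncol();
    const int n = nx * ny;
    NumericMatrix phi = clone(phi_in);
    double* p = phi.begin();
    std::vector<double> B(n), mu(n), r(n);
    const double inv_dx2 = 1.0 / (dx * dx);
    const int nres = res_idx.size();
    if (check_every < 1) check_every = 1;

    for (int s = 0; s < nsteps; ++s) {
        rhs_eval(p, C0.begin(), r.data(), B.data(), mu.data(), nx, ny, M, eps,
                 inv_dx2, conserved);
        for (int k = 0; k < n; ++k) p[k] += dt * r[k];
        for (int q = 0; q < nres; ++q) p[res_idx[q]] = res_val[q];
        if ((s + 1) % check_every == 0 || s == nsteps - 1) {
            double mx = 0.0;
            bool bad = false;
            for (int k = 0; k < n; ++k) {
                const double a = std::fabs(p[k]);
                if (!std::isfinite(p[k])) { bad = true; break; }
                if (a > mx) mx = a;
            }
            if (bad || mx > 1.0 + delta) {
                return List::create(_["phi"] = phi, _["steps_done"] = s + 1,
                                    _["ok"] = false, _["max_abs_phi"] = mx);
            }
        }
    }
    double mx = 0.0;
    for (int k = 0; k < n; ++k)
        if (std::fabs(p[k]) > mx) mx = std::fabs(p[k]);
    return List::create(_["phi"] = phi, _["steps_done"] = nsteps,
                        _["ok"] = true, _["max_abs_phi"] = mx);
}
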