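#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope).
static void dt1d(const double* f, double* d, int n, double* z, int* v) {
    int k = 0;
    v[0] = 0;
    z[0] = -std::numeric_limits<double>::infinity();
    z[1] = std::numeric_limits<double>::infinity();
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                (2.0 * q - 2.0 * v[k]);
            if (s <= z[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        const double dq = q - v[k];
        d[q] = dq * dq + f[v[k]];
    }
}

// Exact Euclidean distance transform: squared distance from each site to the
// nearest FALSE site of `pore` (pixel-centre metric).
static std::vector<double> edt2(const LogicalMatrix& pore) {
    const int nx = pore.nrow(), ny = pore.ncol();
    const double INF = 1e18;
    std::vector<double> g(nx * ny);
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
            g[i + nx * j] = pore(i, j) ? INF : 0.0;
    int nmax = std::max(nx, ny);
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);
    // transform along columns (x direction)
    for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) f[i] = g[i + nx * j];
        dt1d(f.data(), d.data(), nx, z.data(), v.data());
        for (int i = 0; i < nx; ++i) g[i + nx * j] = d[i];
    }
    // then along rows (y direction)
    for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) f[j] = g[i + nx * j];
        dt1d(f.data(), d.data(), ny, z.data(), v.data());
        for (int j = 0; j < ny; ++j) g[i + nx * j] = d[j];
    }
    return g;
}

// [[Rcpp::export]]
NumericMatrix cpp_distance_transform(LogicalMatrix pore) {
    const int nx = pore.nrow(), ny = pore.ncol();
    std::vector<double> g = edt2(pore);
    NumericMatrix out(nx, ny);
    for (int k = 0; k < nx * ny; ++k) out[k] = std::sqrt(g[k]);
    return out;
}

// Local thickness: for each pore site, the diameter (2r) of the largest
// disc that lies in the pore space (centre at some pore site with EDT radius
// r) and covers the site. Matrix sites get 0.
// [[Rcpp::export]]
NumericMatrix cpp_local_thickness(LogicalMatrix pore) {
    const int nx = pore.nrow(), ny = pore.ncol();
    std::vector<double> g = edt2(pore);
    NumericMatrix thick(nx, ny);
    for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
            const int k = i + nx * j;
            if (!pore(i, j)) continue;
            const double r = std::sqrt(g[k]);
            const double diam = 2.0 * r;
            const int ri = (int)std::floor(r);
            for (int dj = -ri; dj <= ri; ++dj) {
                const int jj = j + dj;
                if (jj < 0 || jj >= ny) continue;
                const double rem = r * r - (double)dj * dj;
                if (rem < 0) continue;
                const int di_max = (int)std::floor(std::sqrt(rem));
                for (int di = -di_max; di <= di_max; ++di) {
                    const int ii = i + di;
                    if (ii < 0 || ii >= nx) continue;
                    double& t = thick(ii, jj);
                    if (diam > t) t = diam;
                }
            }
        }
    }
    return thick;
}
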