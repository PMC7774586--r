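#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope distance transform along one
// line of samples with spacing h. f holds squared distances on input,
// d receives updated squared distances.
static void dt1d(const double* f, double* d, int n, double h,
                 std::vector<int>& v, std::vector<double>& z) {
    int k = 0;
    v[0] = 0;
    z[0] = -std::numeric_limits<double>::infinity();
    z[1] = std::numeric_limits<double>::infinity();
    for (int q = 1; q < n; ++q) {
        double xq = q * h;
        double s;
        while (true) {
            double xv = v[k] * h;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
            if (s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * h;
        while (z[k + 1] < xq) ++k;
        double xv = v[k] * h;
        d[q] = (xq - xv) * (xq - xv) + f[v[k]];
    }
}

//' @title Exact Euclidean distance transform on a 3D grid (internal)
//' @description For every voxel, the Euclidean distance in millimetres to the
//'   nearest `TRUE` voxel centre of `feature`, honouring anisotropic spacing.
//' @param feature logical vector of length prod(dim) in column-major order
//' @param dim integer grid dimensions (length 3)
//' @param spacing voxel size per axis in mm (length 3)
//' @return numeric vector of distances (mm); Inf where no feature exists
//' @noRd
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector feature, IntegerVector dim,
                        NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (feature.size() != n)
        stop("feature length does not match dim");
    // large finite sentinel instead of infinity: lines mixing reachable and
    // unreachable samples stay well-defined in the lower-envelope update
    const double INF = 1e15;
    std::vector<double> g(n);
    for (R_xlen_t i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax);
    std::vector<int> v(nmax);
    std::vector<double> z(nmax + 1);

    // pass along x (fastest-varying index)
    for (int kz = 0; kz < nz; ++kz)
        for (int ky = 0; ky < ny; ++ky) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
            for (int i = 0; i < nx; ++i) f[i] = g[base + i];
            dt1d(f.data(), d.data(), nx, spacing[0], v, z);
            for (int i = 0; i < nx; ++i) g[base + i] = d[i];
        }
    // pass along y
    for (int kz = 0; kz < nz; ++kz)
        for (int kx = 0; kx < nx; ++kx) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
            for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)j * nx];
            dt1d(f.data(), d.data(), ny, spacing[1], v, z);
            for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)j * nx] = d[j];
        }
    // pass along z
    for (int ky = 0; ky < ny; ++ky)
        for (int kx = 0; kx < nx; ++kx) {
            R_xlen_t base = (R_xlen_t)ky * nx + kx;
            for (int k = 0; k < nz; ++k) f[k] = g[base + (R_xlen_t)k * nx * ny];
            dt1d(f.data(), d.data(), nz, spacing[2], v, z);
            for (int k = 0; k < nz; ++k) g[base + (R_xlen_t)k * nx * ny] = d[k];
        }

    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = (g[i] >= 1e14) ? R_PosInf : std::sqrt(g[i]);
    return out;
}
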