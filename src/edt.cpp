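#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D lower-envelope passes with per-axis metric weight (mm^2).

static const double BIG = 1e30;

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w2) {
    int k = 0;
    v[0] = 0;
    z[0] = -BIG;
    z[1] = BIG;
    for (int q = 1; q < n; q++) {
        double s = 0.0;
        while (true) {
            int p = v[k];
            s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
                (2.0 * w2 * (q - p));
            if (s <= z[k] && k > 0) {
                k--;
            } else {
                break;
            }
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = BIG;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        while (z[k + 1] < q) k++;
        int p = v[k];
        d[q] = w2 * (double)(q - p) * (q - p) + f[p];
    }
}

// Squared distance (mm^2) from every voxel centre to the nearest
// foreground voxel centre. Foreground voxels get 0.
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t N = (R_xlen_t)nx * ny * nz;
    std::vector<double> D(N);
    for (R_xlen_t i = 0; i < N; i++) D[i] = mask[i] ? 0.0 : BIG;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // x lines
    double w2 = spacing[0] * spacing[0];
    for (int zz = 0; zz < nz; zz++)
        for (int yy = 0; yy < ny; yy++) {
            R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            for (int xx = 0; xx < nx; xx++) f[xx] = D[base + xx];
            dt1d(f, d, v, z, nx, w2);
            for (int xx = 0; xx < nx; xx++) D[base + xx] = d[xx];
        }
    // y lines
    w2 = spacing[1] * spacing[1];
    for (int zz = 0; zz < nz; zz++)
        for (int xx = 0; xx < nx; xx++) {
            R_xlen_t base = xx + (R_xlen_t)nx * ny * zz;
            for (int yy = 0; yy < ny; yy++) f[yy] = D[base + (R_xlen_t)nx * yy];
            dt1d(f, d, v, z, ny, w2);
            for (int yy = 0; yy < ny; yy++) D[base + (R_xlen_t)nx * yy] = d[yy];
        }
    // z lines
    w2 = spacing[2] * spacing[2];
    for (int yy = 0; yy < ny; yy++)
        for (int xx = 0; xx < nx; xx++) {
            R_xlen_t base = xx + (R_xlen_t)nx * yy;
            R_xlen_t stride = (R_xlen_t)nx * ny;
            for (int zz = 0; zz < nz; zz++) f[zz] = D[base + stride * zz];
            dt1d(f, d, v, z, nz, w2);
            for (int zz = 0; zz < nz; zz++) D[base + stride * zz] = d[zz];
        }

    NumericVector out(N);
    for (R_xlen_t i = 0; i < N; i++)
        out[i] = (D[i] >= BIG * 0.5) ? R_PosInf : D[i];
    out.attr("dim") = dim;
    return out;
}
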