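#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Synchronous (Jacobi) neighbor-average filling of zero-motion voxels.
// Fill voxels are replaced by the mean of their currently nonzero
// 6-neighbors; seeds (nonzero, non-fill voxels) never change. Stops when
// the mean per-voxel update magnitude drops below tol (mm).
// [[Rcpp::export]]
List smoothfill_cpp(NumericVector f, LogicalVector fill, IntegerVector dim,
                    double tol, int maxIter) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t N = (R_xlen_t)nx * ny * nz;
    std::vector<double> A(f.begin(), f.end());   // 3 components, stride N
    std::vector<double> B(A);
    std::vector<R_xlen_t> fidx;
    for (R_xlen_t i = 0; i < N; i++)
        if (fill[i]) fidx.push_back(i);
    const R_xlen_t nFill = (R_xlen_t)fidx.size();
    int iter = 0;
    double res = 0.0;
    if (nFill > 0) {
        const R_xlen_t off[6] = {-1, +1, -(R_xlen_t)nx, +(R_xlen_t)nx,
                                 -(R_xlen_t)nx * ny, +(R_xlen_t)nx * ny};
        res = R_PosInf;
        while (iter < maxIter) {
            iter++;
            double sumDelta = 0.0;
            bool any = false;
            for (R_xlen_t k = 0; k < nFill; k++) {
                R_xlen_t i = fidx[k];
                int x = (int)(i % nx);
                int y = (int)((i / nx) % ny);
                int z = (int)(i / ((R_xlen_t)nx * ny));
                double s0 = 0, s1 = 0, s2 = 0;
                int cnt = 0;
                for (int d = 0; d < 6; d++) {
                    if ((d == 0 && x == 0) || (d == 1 && x == nx - 1) ||
                        (d == 2 && y == 0) || (d == 3 && y == ny - 1) ||
                        (d == 4 && z == 0) || (d == 5 && z == nz - 1))
                        continue;
                    R_xlen_t j = i + off[d];
                    double v0 = A[j], v1 = A[j + N], v2 = A[j + 2 * N];
                    if (v0 != 0.0 || v1 != 0.0 || v2 != 0.0) {
                        s0 += v0; s1 += v1; s2 += v2;
                        cnt++;
                    }
                }
                if (cnt > 0) {
                    double n0 = s0 / cnt, n1 = s1 / cnt, n2 = s2 / cnt;
                    double d0 = n0 - A[i], d1 = n1 - A[i + N],
                           d2 = n2 - A[i + 2 * N];
                    sumDelta += std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
                    B[i] = n0; B[i + N] = n1; B[i + 2 * N] = n2;
                    any = true;
                }
            }
            res = sumDelta / (double)nFill;
            if (!any) { res = 0.0; break; }
            for (R_xlen_t k = 0; k < nFill; k++) {
                R_xlen_t i = fidx[k];
                A[i] = B[i]; A[i + N] = B[i + N]; A[i + 2 * N] = B[i + 2 * N];
            }
            if (res < tol) break;
        }
    }
    NumericVector out(A.begin(), A.end());
    out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
    return List::create(_["field"] = out, _["iterations"] = iter,
                        _["residual"] = res);
}
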