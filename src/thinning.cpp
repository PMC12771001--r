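#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Topology-preserving 3D curve thinning: iteratively deletes simple,
// non-endpoint border voxels in six directional subpasses until stable.
// Simpleness follows the local characterization of Malandain & Bertrand:
//   (A) exactly one 26-connected foreground component in the punctured
//       3x3x3 neighborhood, and
//   (B) exactly one 6-connected background component in the 18-neighborhood
//       that is 6-adjacent to the center voxel.
// Deletions are sequential with re-checks, so connectivity is never broken.

static inline int nbIndex(int dx, int dy, int dz) {
    return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static bool condA(const bool nb[27]) {
    // 26-connected fg components among the 26 neighbors
    bool seen[27] = {false};
    int ncomp = 0;
    int stack[27];
    for (int i = 0; i < 27; i++) {
        if (i == 13 || !nb[i] || seen[i]) continue;
        ncomp++;
        if (ncomp > 1) return false;
        int top = 0;
        stack[top++] = i;
        seen[i] = true;
        while (top > 0) {
            int cur = stack[--top];
            int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
            for (int dz = -1; dz <= 1; dz++)
                for (int dy = -1; dy <= 1; dy++)
                    for (int dx = -1; dx <= 1; dx++) {
                        int x = cx + dx, y = cy + dy, z = cz + dz;
                        if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2)
                            continue;
                        int j = x + 3 * y + 9 * z;
                        if (j == 13 || j == cur || !nb[j] || seen[j]) continue;
                        seen[j] = true;
                        stack[top++] = j;
                    }
        }
    }
    return ncomp == 1;
}

static bool condB(const bool nb[27]) {
    // 6-connected bg components within the 18-neighborhood that touch the
    // center through a face
    static const int faceIdx[6] = {
        nbIndex(-1, 0, 0), nbIndex(1, 0, 0), nbIndex(0, -1, 0),
        nbIndex(0, 1, 0),  nbIndex(0, 0, -1), nbIndex(0, 0, 1)};
    bool in18[27];
    for (int i = 0; i < 27; i++) {
        int cx = i % 3 - 1, cy = (i / 3) % 3 - 1, cz = i / 9 - 1;
        int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
        in18[i] = (m == 1 || m == 2);
    }
    bool seen[27] = {false};
    int ncomp = 0;
    int stack[27];
    for (int f = 0; f < 6; f++) {
        int i = faceIdx[f];
        if (nb[i] || seen[i]) continue;  // must be background, unvisited
        ncomp++;
        if (ncomp > 1) return false;
        int top = 0;
        stack[top++] = i;
        seen[i] = true;
        while (top > 0) {
            int cur = stack[--top];
            int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
            const int d6[6][3] = {{-1, 0, 0}, {1, 0, 0},  {0, -1, 0},
                                  {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
            for (int k = 0; k < 6; k++) {
                int x = cx + d6[k][0], y = cy + d6[k][1], z = cz + d6[k][2];
                if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2)
                    continue;
                int j = x + 3 * y + 9 * z;
                if (j == 13 || !in18[j] || nb[j] || seen[j]) continue;
                seen[j] = true;
                stack[top++] = j;
            }
        }
    }
    return ncomp == 1;
}

struct Grid {
    const std::vector<char> &img;
    int nx, ny, nz;
    bool at(int x, int y, int z) const {
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
            return false;
        return img[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] != 0;
    }
};

static void neighborhood(const Grid &g, int x, int y, int z, bool nb[27]) {
    for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++)
                nb[nbIndex(dx, dy, dz)] = g.at(x + dx, y + dy, z + dz);
}

static int countNb26(const bool nb[27]) {
    int n = 0;
    for (int i = 0; i < 27; i++)
        if (i != 13 && nb[i]) n++;
    return n;
}

// Anchor voxels (optional) are never deleted: they pin the skeleton to
// user-chosen landmark positions (e.g. manually selected centerline
// endpoints), preventing the tail retreat thinning otherwise shows on
// tapering tips.
// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dim,
                         Nullable<LogicalVector> anchor = R_NilValue) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t N = (R_xlen_t)nx * ny * nz;
    std::vector<char> img(N);
    for (R_xlen_t i = 0; i < N; i++) img[i] = mask[i] ? 1 : 0;
    std::vector<char> anch(N, 0);
    if (anchor.isNotNull()) {
        LogicalVector a(anchor);
        for (R_xlen_t i = 0; i < N; i++) anch[i] = a[i] ? 1 : 0;
    }
    Grid g{img, nx, ny, nz};

    const int dirs[6][3] = {{0, 0, 1},  {0, 0, -1}, {0, 1, 0},
                            {0, -1, 0}, {1, 0, 0},  {-1, 0, 0}};
    bool nb[27];
    std::vector<R_xlen_t> cand;
    bool changed = true;
    while (changed) {
        changed = false;
        for (int d = 0; d < 6; d++) {
            cand.clear();
            for (int z = 0; z < nz; z++)
                for (int y = 0; y < ny; y++)
                    for (int x = 0; x < nx; x++) {
                        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
                        if (!img[i] || anch[i]) continue;
                        if (g.at(x + dirs[d][0], y + dirs[d][1],
                                 z + dirs[d][2]))
                            continue;  // not a border voxel for this pass
                        neighborhood(g, x, y, z, nb);
                        if (countNb26(nb) <= 1) continue;  // endpoint
                        if (condA(nb) && condB(nb)) cand.push_back(i);
                    }
            for (R_xlen_t ci = 0; ci < (R_xlen_t)cand.size(); ci++) {
                R_xlen_t i = cand[ci];
                int x = (int)(i % nx);
                int y = (int)((i / nx) % ny);
                int z = (int)(i / ((R_xlen_t)nx * ny));
                neighborhood(g, x, y, z, nb);
                if (countNb26(nb) <= 1) continue;
                if (!(condA(nb) && condB(nb))) continue;
                img[i] = 0;
                changed = true;
            }
        }
    }

    LogicalVector out(N);
    for (R_xlen_t i = 0; i < N; i++) out[i] = img[i] != 0;
    out.attr("dim") = dim;
    return out;
}
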