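#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Quantized ROIs arrive as integer arrays in x-fastest order; level 0 marks
// voxels outside the mask, levels 1..ng index the gray-level bins.

static const int DIR13[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int lin(int x, int y, int z, int nx, int ny) {
    return x + nx * (y + ny * z);
}

static inline bool inb(int x, int y, int z, int nx, int ny, int nz) {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// Symmetric gray-level co-occurrence counts merged over the 13 unique 3D
// directions (each counted in both orientations).
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, int nx, int ny, int nz,
                       int ng, int offset) {
    NumericMatrix counts(ng, ng);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int lv = levels[lin(x, y, z, nx, ny)];
                if (lv == 0) continue;
                for (int d = 0; d < 13; ++d) {
                    int xx = x + DIR13[d][0] * offset;
                    int yy = y + DIR13[d][1] * offset;
                    int zz = z + DIR13[d][2] * offset;
                    if (!inb(xx, yy, zz, nx, ny, nz)) continue;
                    int lw = levels[lin(xx, yy, zz, nx, ny)];
                    if (lw == 0) continue;
                    counts(lv - 1, lw - 1) += 1.0;
                    counts(lw - 1, lv - 1) += 1.0;
                }
            }
    return counts;
}

// Run-length counts merged over the 13 unique directions. Runs are maximal
// same-level segments; out-of-mask voxels break runs.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector levels, int nx, int ny, int nz, int ng) {
    int maxlen = std::max(nx, std::max(ny, nz));
    NumericMatrix counts(ng, maxlen);
    for (int d = 0; d < 13; ++d) {
        int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int lv = levels[lin(x, y, z, nx, ny)];
                    if (lv == 0) continue;
                    int px = x - dx, py = y - dy, pz = z - dz;
                    if (inb(px, py, pz, nx, ny, nz) &&
                        levels[lin(px, py, pz, nx, ny)] == lv)
                        continue;  // not a run start
                    int len = 1;
                    int cx = x + dx, cy = y + dy, cz = z + dz;
                    while (inb(cx, cy, cz, nx, ny, nz) &&
                           levels[lin(cx, cy, cz, nx, ny)] == lv) {
                        ++len; cx += dx; cy += dy; cz += dz;
                    }
                    counts(lv - 1, len - 1) += 1.0;
                }
    }
    return counts;
}

// Connected zones of equal gray level under 26-connectivity.
// Returns a 2-column matrix: level, zone size.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, int nx, int ny, int nz) {
    std::vector<char> visited(levels.size(), 0);
    std::vector<int> zl, zs, stack;
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int i0 = lin(x, y, z, nx, ny);
                int lv = levels[i0];
                if (lv == 0 || visited[i0]) continue;
                int size = 0;
                stack.clear();
                stack.push_back(i0);
                visited[i0] = 1;
                while (!stack.empty()) {
                    int i = stack.back(); stack.pop_back();
                    ++size;
                    int cx = i % nx, cy = (i / nx) % ny, cz = i / (nx * ny);
                    for (int dz = -1; dz <= 1; ++dz)
                        for (int dy = -1; dy <= 1; ++dy)
                            for (int dx = -1; dx <= 1; ++dx) {
                                if (dx == 0 && dy == 0 && dz == 0) continue;
                                int xx = cx + dx, yy = cy + dy, zz = cz + dz;
                                if (!inb(xx, yy, zz, nx, ny, nz)) continue;
                                int j = lin(xx, yy, zz, nx, ny);
                                if (!visited[j] && levels[j] == lv) {
                                    visited[j] = 1;
                                    stack.push_back(j);
                                }
                            }
                }
                zl.push_back(lv);
                zs.push_back(size);
            }
    IntegerMatrix out(zl.size(), 2);
    for (size_t i = 0; i < zl.size(); ++i) {
        out(i, 0) = zl[i];
        out(i, 1) = zs[i];
    }
    return out;
}

// Neighborhood gray-tone difference accumulators: for each level i,
// s[i] = sum over voxels of that level of |i - mean(26-neighborhood)|,
// n[i] = number of contributing voxels. Voxels with no in-mask neighbor are
// excluded.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, int nx, int ny, int nz, int ng) {
    NumericVector s(ng);
    NumericVector n(ng);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int lv = levels[lin(x, y, z, nx, ny)];
                if (lv == 0) continue;
                double sum = 0.0;
                int cnt = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (dx == 0 && dy == 0 && dz == 0) continue;
                            int xx = x + dx, yy = y + dy, zz = z + dz;
                            if (!inb(xx, yy, zz, nx, ny, nz)) continue;
                            int lw = levels[lin(xx, yy, zz, nx, ny)];
                            if (lw == 0) continue;
                            sum += lw;
                            ++cnt;
                        }
                if (cnt == 0) continue;
                s[lv - 1] += std::abs(lv - sum / cnt);
                n[lv - 1] += 1.0;
            }
    return List::create(_["s"] = s, _["n"] = n);
}

// Gray-level dependence counts: dependence of a voxel is the number of
// 26-neighbors whose level differs from the center by at most alpha.
// Column j holds dependence j-1 (0..26 -> 27 columns).
// [[Rcpp::export]]
NumericMatrix cpp_ngldm(IntegerVector levels, int nx, int ny, int nz,
                        int ng, int alpha) {
    NumericMatrix counts(ng, 27);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int lv = levels[lin(x, y, z, nx, ny)];
                if (lv == 0) continue;
                int dep = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (dx == 0 && dy == 0 && dz == 0) continue;
                            int xx = x + dx, yy = y + dy, zz = z + dz;
                            if (!inb(xx, yy, zz, nx, ny, nz)) continue;
                            int lw = levels[lin(xx, yy, zz, nx, ny)];
                            if (lw == 0) continue;
                            if (std::abs(lw - lv) <= alpha) ++dep;
                        }
                counts(lv - 1, dep) += 1.0;
            }
    return counts;
}

// ---- Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h) {
    std::vector<int> v(n);
    std::vector<double> zb(n + 1);
    int k = 0;
    v[0] = 0;
    zb[0] = -1e300;
    zb[1] = 1e300;
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            double xq = q * h, xv = v[k] * h;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
            if (s <= zb[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        zb[k] = s;
        zb[k + 1] = 1e300;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * h;
        while (zb[k + 1] < xq) ++k;
        double xv = v[k] * h;
        d[q] = (xq - xv) * (xq - xv) + f[v[k]];
    }
}

// Squared anisotropic Euclidean distance to the nearest foreground voxel.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, int nx, int ny, int nz,
                         NumericVector spacing) {
    const double INF = 1e300;
    NumericVector d(fg.size());
    for (R_xlen_t i = 0; i < fg.size(); ++i) d[i] = fg[i] ? 0.0 : INF;
    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), out(nmax);
    // x
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
            for (int x = 0; x < nx; ++x) f[x] = d[lin(x, y, z, nx, ny)];
            dt1d(f, out, nx, spacing[0]);
            for (int x = 0; x < nx; ++x) d[lin(x, y, z, nx, ny)] = out[x];
        }
    // y
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
            for (int y = 0; y < ny; ++y) f[y] = d[lin(x, y, z, nx, ny)];
            dt1d(f, out, ny, spacing[1]);
            for (int y = 0; y < ny; ++y) d[lin(x, y, z, nx, ny)] = out[y];
        }
    // z
    for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
            for (int z = 0; z < nz; ++z) f[z] = d[lin(x, y, z, nx, ny)];
            dt1d(f, out, nz, spacing[2]);
            for (int z = 0; z < nz; ++z) d[lin(x, y, z, nx, ny)] = out[z];
        }
    return d;
}
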