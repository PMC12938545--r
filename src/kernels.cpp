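#include <Rcpp.h>
#include <cfloat>
#include <cmath>
#include <vector>
#include <queue>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared), anisotropic spacing.
// Felzenszwalb & Huttenlocher lower-envelope algorithm, one pass per axis.
// ---------------------------------------------------------------------------

static const double DT_INF = DBL_MAX / 4.0;

// 1-D squared distance transform along a line of n sites with spacing^2 = h2.
// f: input costs; d: output; v, z: scratch (size n, n+1).
static void dt1d(const double *f, double *d, int *v, double *z, int n, double h2) {
    int k = 0;
    v[0] = 0;
    z[0] = -DT_INF;
    z[1] = DT_INF;
    for (int q = 1; q < n; ++q) {
        double s;
        for (;;) {
            int p = v[k];
            s = ((f[q] + h2 * q * (double)q) - (f[p] + h2 * p * (double)p)) /
                (2.0 * h2 * (q - p));
            if (s <= z[k] && k > 0) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = DT_INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        double dq = (double)q - v[k];
        d[q] = h2 * dq * dq + f[v[k]];
    }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest source
// voxel. Voxels with source == TRUE get 0. If no source exists, all Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector source, IntegerVector dim,
                         NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = source[i] ? 0.0 : DT_INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (stride 1)
    double h2 = spacing[0] * spacing[0];
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            for (int i = 0; i < nx; ++i) f[i] = out[base + i];
            dt1d(f.data(), d.data(), v.data(), z.data(), nx, h2);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    // pass along y (stride nx)
    h2 = spacing[1] * spacing[1];
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + (R_xlen_t)nx * ny * k;
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
            dt1d(f.data(), d.data(), v.data(), z.data(), ny, h2);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
        }
    // pass along z (stride nx*ny)
    h2 = spacing[2] * spacing[2];
    const R_xlen_t sz = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + (R_xlen_t)nx * j;
            for (int k = 0; k < nz; ++k) f[k] = out[base + sz * k];
            dt1d(f.data(), d.data(), v.data(), z.data(), nz, h2);
            for (int k = 0; k < nz; ++k) out[base + sz * k] = d[k];
        }
    for (R_xlen_t i = 0; i < n; ++i)
        if (out[i] >= DT_INF / 2) out[i] = R_PosInf;
    return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling of a 3-D binary mask (6 or 26 connectivity).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector labels(n, 0);

    std::vector<int> off_i, off_j, off_k;
    for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
                if (di == 0 && dj == 0 && dk == 0) continue;
                int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
                if (connectivity == 6 && manh > 1) continue;
                off_i.push_back(di);
                off_j.push_back(dj);
                off_k.push_back(dk);
            }

    int cur = 0;
    std::vector<R_xlen_t> stack;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || labels[s] != 0) continue;
        ++cur;
        labels[s] = cur;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t p = stack.back();
            stack.pop_back();
            int i = (int)(p % nx);
            int j = (int)((p / nx) % ny);
            int k = (int)(p / ((R_xlen_t)nx * ny));
            for (size_t m = 0; m < off_i.size(); ++m) {
                int ii = i + off_i[m], jj = j + off_j[m], kk = k + off_k[m];
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                    continue;
                R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
                if (mask[q] && labels[q] == 0) {
                    labels[q] = cur;
                    stack.push_back(q);
                }
            }
        }
    }
    return labels;
}

// ---------------------------------------------------------------------------
// Rasterize a set of tapered tube segments (truncated cones) into a volume.
// For each voxel, record min over segments of (distance to axis - radius)
// and the id of the minimizing segment. Only voxels within max radius + pad
// of a segment's bounding box are touched; others stay +Inf / 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_rasterize_tubes(IntegerVector dim, NumericVector spacing,
                         NumericVector origin, NumericMatrix segs, double pad) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector excess(n, R_PosInf);
    IntegerVector id(n, 0);

    for (int s = 0; s < segs.nrow(); ++s) {
        double p0[3] = {segs(s, 0), segs(s, 1), segs(s, 2)};
        double p1[3] = {segs(s, 3), segs(s, 4), segs(s, 5)};
        double r0 = segs(s, 6), r1 = segs(s, 7);
        int sid = (int)segs(s, 8);
        double rmax = std::max(r0, r1) + pad;

        int lo[3], hi[3];
        for (int a = 0; a < 3; ++a) {
            double wmin = std::min(p0[a], p1[a]) - rmax;
            double wmax = std::max(p0[a], p1[a]) + rmax;
            lo[a] = std::max(0, (int)std::floor((wmin - origin[a]) / spacing[a]));
            hi[a] = std::min(dim[a] - 1,
                             (int)std::ceil((wmax - origin[a]) / spacing[a]));
        }
        if (lo[0] > hi[0] || lo[1] > hi[1] || lo[2] > hi[2]) continue;

        double v[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
        double vv = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];

        for (int k = lo[2]; k <= hi[2]; ++k) {
            double cz = origin[2] + k * spacing[2];
            for (int j = lo[1]; j <= hi[1]; ++j) {
                double cy = origin[1] + j * spacing[1];
                for (int i = lo[0]; i <= hi[0]; ++i) {
                    double cx = origin[0] + i * spacing[0];
                    double w[3] = {cx - p0[0], cy - p0[1], cz - p0[2]};
                    double t = 0.0;
                    if (vv > 0)
                        t = (w[0] * v[0] + w[1] * v[1] + w[2] * v[2]) / vv;
                    if (t < 0) t = 0;
                    if (t > 1) t = 1;
                    double dx = w[0] - t * v[0];
                    double dy = w[1] - t * v[1];
                    double dz = w[2] - t * v[2];
                    double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
                    double e = dist - (r0 + t * (r1 - r0));
                    R_xlen_t p = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
                    if (e < excess[p]) {
                        excess[p] = e;
                        id[p] = sid;
                    }
                }
            }
        }
    }
    excess.attr("dim") = dim;
    id.attr("dim") = dim;
    return List::create(_["excess"] = excess, _["id"] = id);
}

// ---------------------------------------------------------------------------
// For each query point, index (1-based) of the nearest sample point and the
// Euclidean distance. Both matrices are N x 3 in world mm.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_nearest_sample(NumericMatrix pts, NumericMatrix samples) {
    int np = pts.nrow(), ns = samples.nrow();
    IntegerVector idx(np);
    NumericVector dist(np);
    for (int p = 0; p < np; ++p) {
        double best = R_PosInf;
        int bi = 0;
        for (int s = 0; s < ns; ++s) {
            double dx = pts(p, 0) - samples(s, 0);
            double dy = pts(p, 1) - samples(s, 1);
            double dz = pts(p, 2) - samples(s, 2);
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < best) {
                best = d2;
                bi = s;
            }
        }
        idx[p] = bi + 1;
        dist[p] = std::sqrt(best);
    }
    return List::create(_["index"] = idx, _["distance"] = dist);
}
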