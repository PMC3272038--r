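// Performance-critical primitives for ALE meta-analysis:
//  - stamping Gaussian kernels onto a voxel grid (MA maps)
//  - union-convolution of MA value histograms (exact permutation null)
//  - the relocation (permutation) loop for the max-cluster-extent null
//  - 3-D connected-component labelling under 6/18/26 connectivity
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighbour offsets for the requested connectivity. 6 = faces,
// 18 = faces + edges, 26 = faces + edges + corners.
static std::vector<int> neighbour_offsets(int nx, int ny, int connectivity,
                                          std::vector<int>& di,
                                          std::vector<int>& dj,
                                          std::vector<int>& dk) {
    std::vector<int> off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                off.push_back(dx + nx * (dy + ny * dz));
                di.push_back(dx); dj.push_back(dy); dk.push_back(dz);
            }
    return off;
}

// Stamp one kernel (cube of side 2*krad+1, column-major, x fastest) centred
// at voxel (ci,cj,ck), combining into `ma` by the union or max rule and
// recording first-touched voxel indices.
static inline void stamp_kernel(std::vector<double>& ma,
                                std::vector<int>& touched,
                                const double* kern, int krad,
                                int ci, int cj, int ck,
                                int nx, int ny, int nz, bool union_rule) {
    const int side = 2 * krad + 1;
    for (int dz = -krad; dz <= krad; ++dz) {
        int k = ck + dz;
        if (k < 0 || k >= nz) continue;
        for (int dy = -krad; dy <= krad; ++dy) {
            int j = cj + dy;
            if (j < 0 || j >= ny) continue;
            const double* krow = kern + side * ((dy + krad) + side * (dz + krad));
            int base = nx * (j + ny * k);
            for (int dx = -krad; dx <= krad; ++dx) {
                int i = ci + dx;
                if (i < 0 || i >= nx) continue;
                double kv = krow[dx + krad];
                if (kv <= 0.0) continue;
                int t = i + base;
                double cur = ma[t];
                if (cur == 0.0) {
                    touched.push_back(t);
                    ma[t] = kv;          // exact on first touch
                } else if (union_rule) {
                    ma[t] = 1.0 - (1.0 - cur) * (1.0 - kv);
                } else if (kv > cur) {
                    ma[t] = kv;
                }
            }
        }
    }
}

// [[Rcpp::export]]
NumericVector cpp_stamp_foci(IntegerVector dim, IntegerMatrix ijk0,
                             NumericVector kernel, int krad, bool union_rule) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
    std::vector<double> ma((size_t)nvox, 0.0);
    std::vector<int> touched;
    for (int f = 0; f < ijk0.nrow(); ++f)
        stamp_kernel(ma, touched, REAL(kernel), krad,
                     ijk0(f, 0), ijk0(f, 1), ijk0(f, 2), nx, ny, nz, union_rule);
    return NumericVector(ma.begin(), ma.end());
}

// Exact null of the union statistic by iterative histogram combination.
// Each map's masked MA values arrive as (bin index, probability) pairs on a
// common grid of width `binw`; the accumulated distribution is dense over bin
// indices. Union with a zero-valued draw leaves the accumulated value
// unchanged, so the zero bin contributes a plain scaling term.
// [[Rcpp::export]]
NumericVector cpp_null_union(List bin_idx, List bin_w, double binw,
                             int max_bins) {
    std::vector<double> acc((size_t)max_bins, 0.0), nxt((size_t)max_bins, 0.0);
    acc[0] = 1.0;
    int accmax = 0;
    const int nmaps = bin_idx.size();
    const double inv = 1.0 / binw;
    // Survival probabilities below TAIL_EPS are irrelevant at any reportable
    // p-value resolution; lumping that far tail into the current top bin
    // keeps the total mass exact and caps the accumulator size.
    const double TAIL_EPS = 1e-13;
    for (int m = 0; m < nmaps; ++m) {
        IntegerVector bi = bin_idx[m];
        NumericVector bw = bin_w[m];
        std::fill(nxt.begin(), nxt.begin() + std::min(max_bins, accmax + 1 +
                  (bi.size() ? bi[bi.size() - 1] : 0) + 2), 0.0);
        int newmax = accmax;
        for (int j = 0; j < bi.size(); ++j) {
            const double wj = bw[j];
            if (wj <= 0.0) continue;
            const int b = bi[j];
            if (b == 0) {
                for (int a = 0; a <= accmax; ++a)
                    if (acc[a] != 0.0) nxt[a] += wj * acc[a];
                continue;
            }
            // union value u = va + vb - va*vb is affine in va, so the target
            // bin is base + step*a without a division per iteration
            const double vb = b * binw;
            const double base = vb * inv + 0.5;
            const double step = 1.0 - vb;
            for (int a = 0; a <= accmax; ++a) {
                const double wa = acc[a];
                if (wa == 0.0) continue;
                int ui = (int)(base + step * a);
                if (ui >= max_bins) ui = max_bins - 1;
                nxt[ui] += wj * wa;
                if (ui > newmax) newmax = ui;
            }
        }
        if (newmax >= max_bins) newmax = max_bins - 1;
        acc.swap(nxt);
        accmax = newmax;
        while (accmax > 0 && acc[accmax] == 0.0) --accmax;
        double tail = 0.0;
        int top = accmax;
        while (top > 0 && tail + acc[top] < TAIL_EPS) {
            tail += acc[top];
            acc[top] = 0.0;
            --top;
        }
        if (top < accmax) {
            acc[top] += tail;
            accmax = top;
        }
    }
    return NumericVector(acc.begin(), acc.begin() + accmax + 1);
}

// Sparse kernel representation: contiguous non-zero x-runs per (dy, dz) row
// of the truncation sphere.
struct KernelRow { int dy, dz, x0, len, off; };
struct SparseKernel {
    std::vector<KernelRow> rows;
    std::vector<double> vals;
};

static SparseKernel sparsify_kernel(const NumericVector& kern, int krad) {
    SparseKernel sk;
    const int side = 2 * krad + 1;
    const double* k = REAL(kern);
    for (int dz = -krad; dz <= krad; ++dz)
        for (int dy = -krad; dy <= krad; ++dy) {
            const double* row = k + side * ((dy + krad) + side * (dz + krad));
            int lo = -1, hi = -2;
            for (int x = 0; x < side; ++x)
                if (row[x] > 0.0) { if (lo < 0) lo = x; hi = x; }
            if (lo < 0) continue;
            KernelRow kr;
            kr.dy = dy; kr.dz = dz; kr.x0 = lo - krad; kr.len = hi - lo + 1;
            kr.off = (int)sk.vals.size();
            for (int x = lo; x <= hi; ++x) sk.vals.push_back(row[x]);
            sk.rows.push_back(kr);
        }
    return sk;
}

static inline void stamp_sparse(std::vector<double>& ma,
                                std::vector<int>& touched,
                                const SparseKernel& sk,
                                int ci, int cj, int ck,
                                int nx, int ny, int nz, bool union_rule) {
    for (size_t r = 0; r < sk.rows.size(); ++r) {
        const KernelRow& kr = sk.rows[r];
        const int j = cj + kr.dy, k = ck + kr.dz;
        if (j < 0 || j >= ny || k < 0 || k >= nz) continue;
        int xs = ci + kr.x0;
        int lo = xs < 0 ? 0 : xs;
        int hi = xs + kr.len - 1;
        if (hi > nx - 1) hi = nx - 1;
        if (lo > hi) continue;
        const double* kv = sk.vals.data() + kr.off + (lo - xs);
        const int base = nx * (j + ny * k);
        double* mrow = ma.data() + base;
        for (int x = lo; x <= hi; ++x, ++kv) {
            const double cur = mrow[x];
            if (cur == 0.0) {
                touched.push_back(x + base);
                mrow[x] = *kv;
            } else if (union_rule) {
                mrow[x] = 1.0 - (1.0 - cur) * (1.0 - *kv);
            } else if (*kv > cur) {
                mrow[x] = *kv;
            }
        }
    }
}

// Label connected components of a binary volume. Components are numbered in
// order of their first voxel in column-major scan order, so labelling is
// deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector binary, IntegerVector dim,
                                   int connectivity) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
    IntegerVector labels((R_xlen_t)nvox);
    std::vector<int> di, dj, dk;
    std::vector<int> off = neighbour_offsets(nx, ny, connectivity, di, dj, dk);
    std::vector<R_xlen_t> stack;
    int next_label = 0;
    const int* bin = LOGICAL(binary);
    for (R_xlen_t s = 0; s < nvox; ++s) {
        if (bin[s] != TRUE || labels[s] != 0) continue;
        ++next_label;
        labels[s] = next_label;
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t v = stack.back();
            stack.pop_back();
            int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
            for (size_t n = 0; n < off.size(); ++n) {
                int ii = i + di[n], jj = j + dj[n], kk = k + dk[n];
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                    continue;
                R_xlen_t w = v + off[n];
                if (bin[w] == TRUE && labels[w] == 0) {
                    labels[w] = next_label;
                    stack.push_back(w);
                }
            }
        }
    }
    return labels;
}

// Max cluster extent among supra-threshold voxels (flat indices in `supra`),
// using a dense flag array owned by the caller loop.
static int max_extent(const std::vector<int>& supra, std::vector<char>& flag,
                      int nx, int ny, int nz,
                      const std::vector<int>& di, const std::vector<int>& dj,
                      const std::vector<int>& dk, const std::vector<int>& off) {
    int best = 0;
    std::vector<int> stack;
    std::vector<char> seen_reset;
    for (size_t s0 = 0; s0 < supra.size(); ++s0) {
        int s = supra[s0];
        if (flag[s] != 1) continue;   // 1 = supra & unvisited, 2 = visited
        int size = 0;
        flag[s] = 2;
        stack.push_back(s);
        while (!stack.empty()) {
            int v = stack.back();
            stack.pop_back();
            ++size;
            int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
            for (size_t n = 0; n < off.size(); ++n) {
                int ii = i + di[n], jj = j + dj[n], kk = k + dk[n];
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                    continue;
                int w = v + off[n];
                if (flag[w] == 1) {
                    flag[w] = 2;
                    stack.push_back(w);
                }
            }
        }
        if (size > best) best = size;
    }
    return best;
}

// Permutation null of the maximum cluster extent: per permutation each
// experiment's foci are relocated to masked voxels drawn independently and
// uniformly (focus counts and per-experiment kernels preserved), the ALE map
// is rebuilt, thresholded at `crit` (the ALE value whose null survival equals
// the cluster-forming p), and the largest supra-threshold cluster recorded.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_fwe_perm(IntegerVector dim, IntegerVector mask_idx0,
                           LogicalVector in_mask, IntegerVector foci_per_exp,
                           List kernels, IntegerVector kernel_of_exp,
                           double crit, int connectivity, int n_perm,
                           bool union_rule) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int nvox = nx * ny * nz;
    const int nmask = mask_idx0.size();
    const int nexp = foci_per_exp.size();
    std::vector<SparseKernel> sparse;
    for (int u = 0; u < kernels.size(); ++u) {
        NumericVector kern = kernels[u];
        int side = (int)std::lround(std::cbrt((double)kern.size()));
        sparse.push_back(sparsify_kernel(kern, (side - 1) / 2));
    }
    std::vector<double> prod((size_t)nvox, 1.0), ma((size_t)nvox, 0.0);
    std::vector<char> flag((size_t)nvox, 0), touched_flag((size_t)nvox, 0);
    std::vector<int> touched_exp, touched_all, supra;
    touched_exp.reserve(65536);
    touched_all.reserve((size_t)nvox);
    std::vector<int> di, dj, dk;
    std::vector<int> off = neighbour_offsets(nx, ny, connectivity, di, dj, dk);
    IntegerVector out(n_perm);
    const int* maskl = LOGICAL(in_mask);
    for (int p = 0; p < n_perm; ++p) {
        touched_all.clear();
        for (int e = 0; e < nexp; ++e) {
            touched_exp.clear();
            const SparseKernel& sk = sparse[kernel_of_exp[e]];
            for (int f = 0; f < foci_per_exp[e]; ++f) {
                int r = (int)(unif_rand() * nmask);
                if (r >= nmask) r = nmask - 1;
                int flat = mask_idx0[r];
                int ci = flat % nx, cj = (flat / nx) % ny, ck = flat / (nx * ny);
                stamp_sparse(ma, touched_exp, sk, ci, cj, ck,
                             nx, ny, nz, union_rule);
            }
            for (size_t t0 = 0; t0 < touched_exp.size(); ++t0) {
                int t = touched_exp[t0];
                prod[t] *= (1.0 - ma[t]);
                ma[t] = 0.0;
                if (!touched_flag[t]) {
                    touched_flag[t] = 1;
                    touched_all.push_back(t);
                }
            }
        }
        supra.clear();
        for (size_t t0 = 0; t0 < touched_all.size(); ++t0) {
            int t = touched_all[t0];
            if (maskl[t] == TRUE && (1.0 - prod[t]) >= crit) {
                supra.push_back(t);
                flag[t] = 1;
            }
        }
        out[p] = max_extent(supra, flag, nx, ny, nz, di, dj, dk, off);
        for (size_t t0 = 0; t0 < supra.size(); ++t0) flag[supra[t0]] = 0;
        for (size_t t0 = 0; t0 < touched_all.size(); ++t0) {
            int t = touched_all[t0];
            prod[t] = 1.0;
            touched_flag[t] = 0;
        }
    }
    return out;
}
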