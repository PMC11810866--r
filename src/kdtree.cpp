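#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Exact 3D nearest-neighbour search via a k-d tree (median split on the
// widest axis, small leaves scanned linearly). Used for the Hausdorff /
// per-vertex distance fields and for the ICP correspondence step.

namespace {

struct Node {
    int axis;    // -1 for a leaf
    double split;
    int left, right;
    int begin, end;  // range into the permutation for leaves
};

class KDTree3 {
public:
    KDTree3(const NumericMatrix &pts)
        : p(pts), n(pts.nrow()), idx(pts.nrow()) {
        for (int i = 0; i < n; ++i) idx[i] = i;
        nodes.reserve(2 * n / LEAF + 4);
        root = build(0, n);
    }

    void nearest(const double q[3], int &best, double &bestd2) const {
        best = -1;
        bestd2 = std::numeric_limits<double>::infinity();
        search(root, q, best, bestd2);
    }

    // k smallest, kept sorted ascending in bi/bd (caller initialises to
    // -1 / +inf)
    void kNearest(const double q[3], int k, int *bi, double *bd) const {
        searchK(root, q, k, bi, bd);
    }

private:
    static const int LEAF = 8;
    const NumericMatrix &p;
    int n;
    std::vector<int> idx;
    std::vector<Node> nodes;
    int root;

    inline double coord(int i, int a) const { return p(i, a); }

    int build(int begin, int end) {
        Node nd;
        nd.begin = begin;
        nd.end = end;
        nd.left = nd.right = -1;
        if (end - begin <= LEAF) {
            nd.axis = -1;
            nd.split = 0.0;
            nodes.push_back(nd);
            return (int)nodes.size() - 1;
        }
        double lo[3], hi[3];
        for (int a = 0; a < 3; ++a) {
            lo[a] = std::numeric_limits<double>::infinity();
            hi[a] = -lo[a];
        }
        for (int i = begin; i < end; ++i)
            for (int a = 0; a < 3; ++a) {
                double v = coord(idx[i], a);
                if (v < lo[a]) lo[a] = v;
                if (v > hi[a]) hi[a] = v;
            }
        int axis = 0;
        for (int a = 1; a < 3; ++a)
            if (hi[a] - lo[a] > hi[axis] - lo[axis]) axis = a;
        int mid = (begin + end) / 2;
        const NumericMatrix &pref = p;
        std::nth_element(idx.begin() + begin, idx.begin() + mid,
                         idx.begin() + end,
                         [&pref, axis](int a, int b) {
                             return pref(a, axis) < pref(b, axis);
                         });
        nd.axis = axis;
        nd.split = coord(idx[mid], axis);
        int self = (int)nodes.size();
        nodes.push_back(nd);
        int l = build(begin, mid);
        int r = build(mid, end);
        nodes[self].left = l;
        nodes[self].right = r;
        return self;
    }

    void search(int ni, const double q[3], int &best, double &bestd2) const {
        const Node &nd = nodes[ni];
        if (nd.axis < 0) {
            for (int i = nd.begin; i < nd.end; ++i) {
                int j = idx[i];
                double d2 = 0.0;
                for (int a = 0; a < 3; ++a) {
                    double d = q[a] - coord(j, a);
                    d2 += d * d;
                }
                if (d2 < bestd2) {
                    bestd2 = d2;
                    best = j;
                }
            }
            return;
        }
        double diff = q[nd.axis] - nd.split;
        int nearSide = diff <= 0 ? nd.left : nd.right;
        int farSide = diff <= 0 ? nd.right : nd.left;
        search(nearSide, q, best, bestd2);
        if (diff * diff < bestd2) search(farSide, q, best, bestd2);
    }

    void searchK(int ni, const double q[3], int k, int *bi,
                 double *bd) const {
        const Node &nd = nodes[ni];
        if (nd.axis < 0) {
            for (int i = nd.begin; i < nd.end; ++i) {
                int j = idx[i];
                double d2 = 0.0;
                for (int a = 0; a < 3; ++a) {
                    double d = q[a] - coord(j, a);
                    d2 += d * d;
                }
                if (d2 < bd[k - 1]) {  // insertion into the sorted list
                    int pos = k - 1;
                    while (pos > 0 && bd[pos - 1] > d2) {
                        bd[pos] = bd[pos - 1];
                        bi[pos] = bi[pos - 1];
                        --pos;
                    }
                    bd[pos] = d2;
                    bi[pos] = j;
                }
            }
            return;
        }
        double diff = q[nd.axis] - nd.split;
        int nearSide = diff <= 0 ? nd.left : nd.right;
        int farSide = diff <= 0 ? nd.right : nd.left;
        searchK(nearSide, q, k, bi, bd);
        if (diff * diff < bd[k - 1]) searchK(farSide, q, k, bi, bd);
    }
};

// Closest point on a triangle (Ericson, Real-Time Collision Detection).
static void closestOnTriangle(const double p[3], const double a[3],
                              const double b[3], const double c[3],
                              double out[3]) {
    double ab[3], ac[3], ap[3];
    for (int i = 0; i < 3; ++i) {
        ab[i] = b[i] - a[i];
        ac[i] = c[i] - a[i];
        ap[i] = p[i] - a[i];
    }
    double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
    double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
    if (d1 <= 0.0 && d2 <= 0.0) {
        for (int i = 0; i < 3; ++i) out[i] = a[i];
        return;
    }
    double bp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
        for (int i = 0; i < 3; ++i) out[i] = b[i];
        return;
    }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
        return;
    }
    double cp[3];
    for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d6 >= 0.0 && d5 <= d6) {
        for (int i = 0; i < 3; ++i) out[i] = c[i];
        return;
    }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
        double w = d2 / (d2 - d6);
        for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
        return;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
        double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        for (int i = 0; i < 3; ++i)
            out[i] = b[i] + w * (c[i] - b[i]);
        return;
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    for (int i = 0; i < 3; ++i)
        out[i] = a[i] + ab[i] * v + ac[i] * w;
}

}  // namespace

// [[Rcpp::export(name = ".nnSearch")]]
List nnSearch(NumericMatrix target, NumericMatrix query) {
    if (target.nrow() == 0)
        stop("nearest-neighbour search against an empty point set");
    if (target.ncol() != 3 || query.ncol() != 3)
        stop("point matrices must have 3 columns");
    KDTree3 tree(target);
    int m = query.nrow();
    IntegerVector index(m);
    NumericVector dist(m);
    double q[3];
    for (int i = 0; i < m; ++i) {
        q[0] = query(i, 0);
        q[1] = query(i, 1);
        q[2] = query(i, 2);
        int best;
        double d2;
        tree.nearest(q, best, d2);
        index[i] = best + 1;
        dist[i] = std::sqrt(d2);
    }
    return List::create(_["index"] = index, _["distance"] = dist);
}

// Closest point on a triangulated surface for each query point. The
// k-d tree over the mesh vertices proposes the kCandidates nearest
// vertices; the closest point is searched over every triangle incident
// to any of them (on a dense mesh the true closest triangle always
// touches one of the nearest vertices; isolated vertices fall back to
// vertex distance).
// [[Rcpp::export(name = ".nnSearchMesh")]]
List nnSearchMesh(NumericMatrix verts, IntegerMatrix tris,
                  NumericMatrix query, int kCandidates = 8) {
    int nv = verts.nrow(), nt = tris.nrow(), m = query.nrow();
    if (nv == 0) stop("closest-point search against an empty mesh");
    if (tris.ncol() != 3 || verts.ncol() != 3 || query.ncol() != 3)
        stop("vertices/triangles/query must have 3 columns");
    int k = std::min(kCandidates, nv);
    // vertex -> incident triangles (CSR, 1-based triangle indices in)
    std::vector<int> cnt(nv + 1, 0);
    for (int t = 0; t < nt; ++t)
        for (int c = 0; c < 3; ++c) cnt[tris(t, c) - 1]++;
    std::vector<int> off(nv + 1, 0);
    for (int v = 0; v < nv; ++v) off[v + 1] = off[v] + cnt[v];
    std::vector<int> inc(off[nv]);
    std::vector<int> fill(nv, 0);
    for (int t = 0; t < nt; ++t)
        for (int c = 0; c < 3; ++c) {
            int v = tris(t, c) - 1;
            inc[off[v] + fill[v]++] = t;
        }
    KDTree3 tree(verts);
    NumericMatrix closest(m, 3);
    NumericVector dist(m);
    IntegerVector nearVertex(m);
    std::vector<int> stamp(nt, -1);
    std::vector<int> bi(k);
    std::vector<double> bd(k);
    double q[3], a[3], b[3], c[3], cp[3];
    for (int i = 0; i < m; ++i) {
        q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
        for (int j = 0; j < k; ++j) {
            bi[j] = -1;
            bd[j] = std::numeric_limits<double>::infinity();
        }
        tree.kNearest(q, k, bi.data(), bd.data());
        // fallback: the nearest vertex itself
        double bestd2 = bd[0];
        int nv0 = bi[0];
        cp[0] = verts(nv0, 0); cp[1] = verts(nv0, 1); cp[2] = verts(nv0, 2);
        double best[3] = {cp[0], cp[1], cp[2]};
        for (int j = 0; j < k; ++j) {
            if (bi[j] < 0) break;
            int v = bi[j];
            for (int e = off[v]; e < off[v + 1]; ++e) {
                int t = inc[e];
                if (stamp[t] == i) continue;
                stamp[t] = i;
                for (int d = 0; d < 3; ++d) {
                    a[d] = verts(tris(t, 0) - 1, d);
                    b[d] = verts(tris(t, 1) - 1, d);
                    c[d] = verts(tris(t, 2) - 1, d);
                }
                closestOnTriangle(q, a, b, c, cp);
                double d2 = 0.0;
                for (int d = 0; d < 3; ++d) {
                    double dd = q[d] - cp[d];
                    d2 += dd * dd;
                }
                if (d2 < bestd2) {
                    bestd2 = d2;
                    best[0] = cp[0]; best[1] = cp[1]; best[2] = cp[2];
                }
            }
        }
        closest(i, 0) = best[0];
        closest(i, 1) = best[1];
        closest(i, 2) = best[2];
        dist[i] = std::sqrt(bestd2);
        nearVertex[i] = nv0 + 1;
    }
    return List::create(_["point"] = closest, _["distance"] = dist,
                        _["index"] = nearVertex);
}
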