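#include <Rcpp.h>
#include <vector>
#include <limits>
#include <functional>
using namespace Rcpp;

// Optimal leaf ordering for an agglomerative tree (Bar-Joseph style dynamic
// program).  Given the merge matrix of an hclust object and the full m x m
// distance matrix, returns the leaf permutation minimizing the sum of
// distances between adjacent leaves among all orders consistent with the
// tree (each internal node may flip its children).
//
// cost[node](u, w) = minimal adjacent-distance sum of an ordering of the
// node's leaves that starts at leaf u and ends at leaf w.  For a node with
// children L and R and u in L, w in R:
//   cost(u, w) = min_{v in L, z in R} costL(u, v) + d(v, z) + costR(z, w)
// computed as two min-plus products.  Ties are resolved by first-found
// minima in fixed index order, so the result is deterministic.

namespace {

struct NodeInfo {
    std::vector<int> leaves;          // 0-based leaf indices
    std::vector<double> cost;         // |leaves|^2, cost(u, w) by local index
    int left, right;                  // merge-matrix children (hclust coding)
};

inline double &C(std::vector<double> &m, int n, int i, int j) {
    return m[(size_t)i * n + j];
}

} // namespace

// [[Rcpp::export(name = ".Call_olo_order")]]
IntegerVector olo_order(IntegerMatrix merge, NumericMatrix dist) {
    const int m = dist.nrow();
    const int nmerge = merge.nrow();
    if (nmerge != m - 1)
        stop("merge matrix does not match distance matrix size");
    const double INF = std::numeric_limits<double>::infinity();

    std::vector<NodeInfo> nodes(nmerge);
    // leaf lookup: position of leaf within a node's leaves vector
    std::vector<std::vector<int>> pos_of(nmerge, std::vector<int>());

    auto child_leaves = [&](int code, std::vector<int> &out) {
        if (code < 0) {
            out.push_back(-code - 1);
        } else {
            const std::vector<int> &lv = nodes[code - 1].leaves;
            out.insert(out.end(), lv.begin(), lv.end());
        }
    };

    for (int t = 0; t < nmerge; ++t) {
        NodeInfo &nd = nodes[t];
        nd.left = merge(t, 0);
        nd.right = merge(t, 1);
        std::vector<int> L, R;
        child_leaves(nd.left, L);
        child_leaves(nd.right, R);
        nd.leaves = L;
        nd.leaves.insert(nd.leaves.end(), R.begin(), R.end());
        const int nl = (int)L.size(), nr = (int)R.size(), n = nl + nr;
        nd.cost.assign((size_t)n * n, INF);

        // child cost matrices (leaf -> singleton cost 0)
        auto child_cost = [&](int code, int i, int j) -> double {
            if (code < 0) return 0.0; // single leaf, i == j == 0
            NodeInfo &c = nodes[code - 1];
            return C(c.cost, (int)c.leaves.size(), i, j);
        };

        // T1(u, z) = min_v costL(u, v) + d(L[v], R[z])
        std::vector<double> T1((size_t)nl * nr, INF);
        for (int u = 0; u < nl; ++u)
            for (int z = 0; z < nr; ++z) {
                double best = INF;
                for (int v = 0; v < nl; ++v) {
                    double cl = child_cost(nd.left, u, v);
                    if (cl == INF) continue;
                    double cand = cl + dist(L[v], R[z]);
                    if (cand < best) best = cand;
                }
                T1[(size_t)u * nr + z] = best;
            }
        // cost(u, w) = min_z T1(u, z) + costR(z, w)
        for (int u = 0; u < nl; ++u)
            for (int w = 0; w < nr; ++w) {
                double best = INF;
                for (int z = 0; z < nr; ++z) {
                    double t1 = T1[(size_t)u * nr + z];
                    if (t1 == INF) continue;
                    double cr = child_cost(nd.right, z, w);
                    if (cr == INF) continue;
                    double cand = t1 + cr;
                    if (cand < best) best = cand;
                }
                // store symmetric pair (u in L, w in R)
                C(nd.cost, n, u, nl + w) = best;
                C(nd.cost, n, nl + w, u) = best;
            }
    }

    // root optimum
    NodeInfo &root = nodes[nmerge - 1];
    const int n = (int)root.leaves.size();
    int bu = -1, bw = -1;
    double best = INF;
    for (int u = 0; u < n; ++u)
        for (int w = 0; w < n; ++w) {
            double c = C(root.cost, n, u, w);
            if (c < best) { best = c; bu = u; bw = w; }
        }
    if (bu < 0) stop("optimal leaf ordering failed");

    // backtracking: recover order of node given (start leaf, end leaf),
    // both as global leaf indices
    std::vector<int> order;
    order.reserve(m);

    std::function<void(int, int, int)> rec = [&](int code, int uleaf, int wleaf) {
        if (code < 0) { order.push_back(-code - 1); return; }
        NodeInfo &nd = nodes[code - 1];
        std::vector<int> L, R;
        child_leaves(nd.left, L);
        child_leaves(nd.right, R);
        const int nl = (int)L.size(), nr = (int)R.size();
        auto child_cost = [&](int ccode, int i, int j) -> double {
            if (ccode < 0) return 0.0;
            NodeInfo &c = nodes[ccode - 1];
            return C(c.cost, (int)c.leaves.size(), i, j);
        };
        // locate uleaf / wleaf in children; possibly swap children roles
        int ui = -1, wi = -1;
        bool u_in_L = false, w_in_R = false;
        for (int i = 0; i < nl; ++i) if (L[i] == uleaf) { ui = i; u_in_L = true; }
        for (int i = 0; i < nr; ++i) if (R[i] == wleaf) { wi = i; w_in_R = true; }
        int first = nd.left, second = nd.right;
        std::vector<int> *F = &L, *S = &R;
        if (!(u_in_L && w_in_R)) {
            // reversed orientation: u in R, w in L
            ui = -1; wi = -1;
            for (int i = 0; i < nr; ++i) if (R[i] == uleaf) ui = i;
            for (int i = 0; i < nl; ++i) if (L[i] == wleaf) wi = i;
            if (ui < 0 || wi < 0) stop("backtrack failure");
            first = nd.right; second = nd.left;
            F = &R; S = &L;
        }
        const int nf = (int)F->size(), ns = (int)S->size();
        double target = INF; int bv = -1, bz = -1;
        for (int v = 0; v < nf; ++v) {
            double cf = child_cost(first, ui, v);
            if (cf == INF) continue;
            for (int z = 0; z < ns; ++z) {
                double cs = child_cost(second, z, wi);
                if (cs == INF) continue;
                double cand = cf + dist((*F)[v], (*S)[z]) + cs;
                if (cand < target) { target = cand; bv = v; bz = z; }
            }
        }
        if (bv < 0) stop("backtrack failure");
        rec(first, uleaf, (*F)[bv]);
        rec(second, (*S)[bz], wleaf);
    };

    rec(nmerge, root.leaves[bu], root.leaves[bw]);
    IntegerVector out(m);
    for (int i = 0; i < m; ++i) out[i] = order[i] + 1; // 1-based
    return out;
}
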