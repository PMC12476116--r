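#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static int uf_find(std::vector<int> &parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

static void uf_union(std::vector<int> &parent, std::vector<int> &size, int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra == rb) return;
    if (size[ra] < size[rb]) std::swap(ra, rb);
    parent[rb] = ra;
    size[ra] += size[rb];
}

// Threshold-free cluster enhancement over an arbitrary adjacency graph.
// t: non-negative statistic per node; edges: m x 2 one-based node pairs;
// score(v) = sum over thresholds h = dh, 2dh, ... <= t_v of e(h,v)^E * h^H * dh,
// where e(h,v) is the size of the connected component containing v among
// nodes with t >= h. Thresholds are processed from high to low with an
// incremental union-find, so the cost is O(n_steps * (V + m)).
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector t, IntegerMatrix edges, double E, double H, double dh) {
    const int V = t.size();
    NumericVector out(V);
    double tmax = 0.0;
    for (int i = 0; i < V; ++i) if (t[i] > tmax) tmax = t[i];
    if (tmax <= 0.0 || dh <= 0.0) return out;

    const int nsteps = (int)std::floor(tmax / dh + 1e-12);
    if (nsteps < 1) return out;

    // nodes sorted by decreasing t, activated as thresholds descend
    std::vector<int> ord(V);
    for (int i = 0; i < V; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return t[a] > t[b]; });

    const int m = edges.nrow();
    std::vector<int> parent(V), csize(V, 0);
    for (int i = 0; i < V; ++i) parent[i] = i;
    std::vector<bool> active(V, false);

    // adjacency lists
    std::vector<int> deg(V, 0);
    for (int e = 0; e < m; ++e) {
        ++deg[edges(e, 0) - 1];
        ++deg[edges(e, 1) - 1];
    }
    std::vector<int> offs(V + 1, 0);
    for (int i = 0; i < V; ++i) offs[i + 1] = offs[i] + deg[i];
    std::vector<int> adj(offs[V]);
    std::vector<int> fill(V, 0);
    for (int e = 0; e < m; ++e) {
        int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
        adj[offs[a] + fill[a]++] = b;
        adj[offs[b] + fill[b]++] = a;
    }

    int next = 0;
    for (int k = nsteps; k >= 1; --k) {
        double h = k * dh;
        while (next < V && t[ord[next]] >= h) {
            int v = ord[next++];
            active[v] = true;
            csize[v] = 1;
            for (int j = offs[v]; j < offs[v + 1]; ++j) {
                int w = adj[j];
                if (active[w]) uf_union(parent, csize, v, w);
            }
        }
        double hh = std::pow(h, H) * dh;
        for (int i = 0; i < next; ++i) {
            int v = ord[i];
            int e_hv = csize[uf_find(parent, v)];
            out[v] += std::pow((double)e_hv, E) * hh;
        }
    }
    return out;
}

// Connected-component labels (1..k) of a graph on n nodes given one-based
// edge pairs; isolated nodes get their own label.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(int n, IntegerMatrix edges) {
    std::vector<int> parent(n), size(n, 1);
    for (int i = 0; i < n; ++i) parent[i] = i;
    for (int e = 0; e < edges.nrow(); ++e)
        uf_union(parent, size, edges(e, 0) - 1, edges(e, 1) - 1);
    IntegerVector lab(n);
    std::vector<int> remap(n, 0);
    int k = 0;
    for (int i = 0; i < n; ++i) {
        int r = uf_find(parent, i);
        if (remap[r] == 0) remap[r] = ++k;
        lab[i] = remap[r];
    }
    return lab;
}
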