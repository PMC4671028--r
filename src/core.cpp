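#include <Rcpp.h>
#include <vector>
#include <queue>
#include <stack>
using namespace Rcpp;

// Internal: adjacency matrix (0/1) -> adjacency lists (0-based).
static std::vector< std::vector<int> > adj_list(const IntegerMatrix& A) {
    const int n = A.nrow();
    std::vector< std::vector<int> > adj(n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            if (i != j && A(i, j) != 0) adj[i].push_back(j);
    return adj;
}

// BFS geodesic distances between all node pairs; -1 marks unreachable pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_all_pairs_dist(IntegerMatrix A) {
    const int n = A.nrow();
    std::vector< std::vector<int> > adj = adj_list(A);
    IntegerMatrix D(n, n);
    std::fill(D.begin(), D.end(), -1);
    std::vector<int> dist(n);
    for (int s = 0; s < n; ++s) {
        std::fill(dist.begin(), dist.end(), -1);
        dist[s] = 0;
        std::queue<int> q;
        q.push(s);
        while (!q.empty()) {
            int v = q.front(); q.pop();
            for (size_t t = 0; t < adj[v].size(); ++t) {
                int w = adj[v][t];
                if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
            }
        }
        for (int j = 0; j < n; ++j) D(s, j) = dist[j];
    }
    return D;
}

// Brandes betweenness centrality on an unweighted undirected graph.
// Unnormalized, endpoints excluded, each unordered pair credited once.
// [[Rcpp::export]]
NumericVector cpp_betweenness(IntegerMatrix A) {
    const int n = A.nrow();
    std::vector< std::vector<int> > adj = adj_list(A);
    NumericVector bc(n);
    std::vector<double> sigma(n), delta(n);
    std::vector<int> dist(n);
    std::vector< std::vector<int> > pred(n);
    for (int s = 0; s < n; ++s) {
        std::stack<int> S;
        for (int i = 0; i < n; ++i) { pred[i].clear(); sigma[i] = 0.0; dist[i] = -1; }
        sigma[s] = 1.0; dist[s] = 0;
        std::queue<int> q;
        q.push(s);
        while (!q.empty()) {
            int v = q.front(); q.pop();
            S.push(v);
            for (size_t t = 0; t < adj[v].size(); ++t) {
                int w = adj[v][t];
                if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
                if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
            }
        }
        std::fill(delta.begin(), delta.end(), 0.0);
        while (!S.empty()) {
            int w = S.top(); S.pop();
            for (size_t t = 0; t < pred[w].size(); ++t) {
                int v = pred[w][t];
                delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
            }
            if (w != s) bc[w] += delta[w];
        }
    }
    // each unordered pair was accumulated from both endpoints
    for (int i = 0; i < n; ++i) bc[i] /= 2.0;
    return bc;
}

// Connected-component labels, 1-based, in node order of first discovery.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerMatrix A) {
    const int n = A.nrow();
    std::vector< std::vector<int> > adj = adj_list(A);
    IntegerVector comp(n, 0);
    int label = 0;
    for (int s = 0; s < n; ++s) {
        if (comp[s] != 0) continue;
        comp[s] = ++label;
        std::queue<int> q;
        q.push(s);
        while (!q.empty()) {
            int v = q.front(); q.pop();
            for (size_t t = 0; t < adj[v].size(); ++t) {
                int w = adj[v][t];
                if (comp[w] == 0) { comp[w] = label; q.push(w); }
            }
        }
    }
    return comp;
}

// mean clustering over the largest component's nodes and characteristic
// path length within the largest component, straight from an edge list.
static void cl_stats(const std::vector<int>& u, const std::vector<int>& v,
                     int n, double& C, double& L) {
    std::vector< std::vector<int> > adj(n);
    std::vector<char> A((size_t)n * n, 0);
    const int E = (int)u.size();
    for (int e = 0; e < E; ++e) {
        adj[u[e]].push_back(v[e]);
        adj[v[e]].push_back(u[e]);
        A[(size_t)u[e] * n + v[e]] = 1;
        A[(size_t)v[e] * n + u[e]] = 1;
    }
    // components by BFS
    std::vector<int> comp(n, -1);
    int ncomp = 0;
    std::vector<int> comp_size;
    for (int s = 0; s < n; ++s) {
        if (comp[s] >= 0) continue;
        comp[s] = ncomp;
        int size = 1;
        std::queue<int> q;
        q.push(s);
        while (!q.empty()) {
            int x = q.front(); q.pop();
            for (size_t t = 0; t < adj[x].size(); ++t) {
                int w = adj[x][t];
                if (comp[w] < 0) { comp[w] = ncomp; ++size; q.push(w); }
            }
        }
        comp_size.push_back(size);
        ++ncomp;
    }
    int big = 0;
    for (int c = 1; c < ncomp; ++c) if (comp_size[c] > comp_size[big]) big = c;
    // clustering over LCC nodes
    double csum = 0.0;
    int cn = 0;
    for (int i = 0; i < n; ++i) {
        if (comp[i] != big) continue;
        ++cn;
        int k = (int)adj[i].size();
        if (k < 2) continue;
        int tri = 0;
        for (int a = 0; a < k; ++a)
            for (int b = a + 1; b < k; ++b)
                if (A[(size_t)adj[i][a] * n + adj[i][b]]) ++tri;
        csum += 2.0 * tri / ((double)k * (k - 1));
    }
    C = cn > 0 ? csum / cn : 0.0;
    // mean BFS distance over pairs within LCC
    if (comp_size[big] < 2) { L = NA_REAL; return; }
    double dsum = 0.0;
    long long pairs = 0;
    std::vector<int> dist(n);
    for (int s = 0; s < n; ++s) {
        if (comp[s] != big) continue;
        std::fill(dist.begin(), dist.end(), -1);
        dist[s] = 0;
        std::queue<int> q;
        q.push(s);
        while (!q.empty()) {
            int x = q.front(); q.pop();
            for (size_t t = 0; t < adj[x].size(); ++t) {
                int w = adj[x][t];
                if (dist[w] < 0) { dist[w] = dist[x] + 1; q.push(w); }
            }
        }
        for (int j = s + 1; j < n; ++j)
            if (comp[j] == big) { dsum += dist[j]; ++pairs; }
    }
    L = dsum / pairs;
}

// Null-ensemble fast path: rewires the edge list `reps` times (fresh copy
// each time) and returns C and L of every rewired graph. Equivalent to
// repeated rewire + clustering_coefficient + characteristic_path_length.
// [[Rcpp::export]]
NumericMatrix cpp_null_cl(IntegerMatrix edges, int n, int attempts, int reps) {
    const int E = edges.nrow();
    NumericMatrix out(reps, 2);
    std::vector<int> u0(E), v0(E);
    for (int e = 0; e < E; ++e) { u0[e] = edges(e, 0) - 1; v0[e] = edges(e, 1) - 1; }
    std::vector<char> present0((size_t)n * n, 0);
    for (int e = 0; e < E; ++e) {
        present0[(size_t)u0[e] * n + v0[e]] = 1;
        present0[(size_t)v0[e] * n + u0[e]] = 1;
    }
    for (int r = 0; r < reps; ++r) {
        std::vector<int> u(u0), v(v0);
        std::vector<char> present(present0);
        for (int it = 0; it < attempts; ++it) {
            int e1 = (int)(unif_rand() * E);
            int e2 = (int)(unif_rand() * E);
            if (e1 >= E) e1 = E - 1;
            if (e2 >= E) e2 = E - 1;
            if (e1 == e2) continue;
            int a = u[e1], b = v[e1], c = u[e2], d = v[e2];
            if (unif_rand() < 0.5) { int tmp = c; c = d; d = tmp; }
            if (a == d || c == b || a == c || b == d) continue;
            if (present[(size_t)a * n + d] || present[(size_t)c * n + b]) continue;
            present[(size_t)a * n + b] = present[(size_t)b * n + a] = 0;
            present[(size_t)c * n + d] = present[(size_t)d * n + c] = 0;
            v[e1] = d; u[e2] = c; v[e2] = b;
            present[(size_t)a * n + d] = present[(size_t)d * n + a] = 1;
            present[(size_t)c * n + b] = present[(size_t)b * n + c] = 1;
        }
        double C, L;
        cl_stats(u, v, n, C, L);
        out(r, 0) = C;
        out(r, 1) = L;
    }
    return out;
}

// Degree-preserving latticization: the same double-edge-swap walk as the
// randomization, but a swap is accepted only when it does not increase the
// total ring distance sum(min(|i-j|, n-|i-j|)) of the affected edges, so the
// edge set migrates toward the ring diagonal while every degree is kept.
// [[Rcpp::export]]
IntegerMatrix cpp_latticize(IntegerMatrix edges, int n, int attempts) {
    const int E = edges.nrow();
    std::vector<int> u(E), v(E);
    std::vector<char> present((size_t)n * n, 0);
    for (int e = 0; e < E; ++e) {
        u[e] = edges(e, 0) - 1;
        v[e] = edges(e, 1) - 1;
        present[(size_t)u[e] * n + v[e]] = 1;
        present[(size_t)v[e] * n + u[e]] = 1;
    }
    #define RINGD(i, j) (std::abs(i - j) < n - std::abs(i - j) ? std::abs(i - j) : n - std::abs(i - j))
    for (int it = 0; it < attempts; ++it) {
        int e1 = (int)(unif_rand() * E);
        int e2 = (int)(unif_rand() * E);
        if (e1 >= E) e1 = E - 1;
        if (e2 >= E) e2 = E - 1;
        if (e1 == e2) continue;
        int a = u[e1], b = v[e1], c = u[e2], d = v[e2];
        if (unif_rand() < 0.5) { int tmp = c; c = d; d = tmp; }
        if (a == d || c == b || a == c || b == d) continue;
        if (present[(size_t)a * n + d] || present[(size_t)c * n + b]) continue;
        if (RINGD(a, d) + RINGD(c, b) > RINGD(a, b) + RINGD(c, d)) continue;
        present[(size_t)a * n + b] = present[(size_t)b * n + a] = 0;
        present[(size_t)c * n + d] = present[(size_t)d * n + c] = 0;
        v[e1] = d; u[e2] = c; v[e2] = b;
        present[(size_t)a * n + d] = present[(size_t)d * n + a] = 1;
        present[(size_t)c * n + b] = present[(size_t)b * n + c] = 1;
    }
    #undef RINGD
    IntegerMatrix out(E, 2);
    for (int e = 0; e < E; ++e) { out(e, 0) = u[e] + 1; out(e, 1) = v[e] + 1; }
    return out;
}

// Maslov-Sneppen double-edge swaps. edges: E x 2 (1-based); returns rewired
// edge list with the degree sequence untouched. `attempts` swap attempts are
// made; candidates creating self-loops or multi-edges are rejected. Uses R's
// RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_rewire(IntegerMatrix edges, int n, int attempts) {
    const int E = edges.nrow();
    std::vector<int> u(E), v(E);
    std::vector<char> present((size_t)n * n, 0);
    for (int e = 0; e < E; ++e) {
        u[e] = edges(e, 0) - 1;
        v[e] = edges(e, 1) - 1;
        present[(size_t)u[e] * n + v[e]] = 1;
        present[(size_t)v[e] * n + u[e]] = 1;
    }
    for (int it = 0; it < attempts; ++it) {
        int e1 = (int)(unif_rand() * E);
        int e2 = (int)(unif_rand() * E);
        if (e1 >= E) e1 = E - 1;
        if (e2 >= E) e2 = E - 1;
        if (e1 == e2) continue;
        int a = u[e1], b = v[e1], c = u[e2], d = v[e2];
        // randomly choose swap orientation: (a-d, c-b) or (a-c, b-d)
        if (unif_rand() < 0.5) { int tmp = c; c = d; d = tmp; }
        // proposed new edges: a-d and c-b  (original orientation case)
        if (a == d || c == b) continue;
        if (a == c || b == d) continue; // shared endpoint, swap is a no-op or loop
        if (present[(size_t)a * n + d] || present[(size_t)c * n + b]) continue;
        present[(size_t)a * n + b] = present[(size_t)b * n + a] = 0;
        present[(size_t)c * n + d] = present[(size_t)d * n + c] = 0;
        v[e1] = d; u[e2] = c; v[e2] = b;
        // u[e1] stays a
        present[(size_t)a * n + d] = present[(size_t)d * n + a] = 1;
        present[(size_t)c * n + b] = present[(size_t)b * n + c] = 1;
    }
    IntegerMatrix out(E, 2);
    for (int e = 0; e < E; ++e) { out(e, 0) = u[e] + 1; out(e, 1) = v[e] + 1; }
    return out;
}
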