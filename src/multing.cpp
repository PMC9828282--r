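#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Unweighted Brandes edge-betweenness accumulation from a single source.
// Scores are accumulated (per ordered source) into ebc for edges with
// id < n_scored (the removable intra-layer edges); higher-id edges (the
// inter-layer couplings) propagate dependencies but are never scored.
// Caller divides accumulated totals by 2 to obtain unordered-pair counts.
static void brandes_from_source(int s,
                                const std::vector<std::vector<std::pair<int, int> > > &adj,
                                const std::vector<char> &active,
                                int n_scored,
                                std::vector<double> &ebc,
                                std::vector<int> &dist,
                                std::vector<double> &sigma,
                                std::vector<double> &delta,
                                std::vector<int> &order) {
    const int N = (int) adj.size();
    for (int v = 0; v < N; ++v) {
        dist[v] = -1;
        sigma[v] = 0.0;
        delta[v] = 0.0;
    }
    order.clear();
    std::queue<int> q;
    dist[s] = 0;
    sigma[s] = 1.0;
    q.push(s);
    while (!q.empty()) {
        int v = q.front();
        q.pop();
        order.push_back(v);
        for (size_t t = 0; t < adj[v].size(); ++t) {
            int w = adj[v][t].first;
            int eid = adj[v][t].second;
            if (!active[eid]) continue;
            if (dist[w] < 0) {
                dist[w] = dist[v] + 1;
                q.push(w);
            }
            if (dist[w] == dist[v] + 1) sigma[w] += sigma[v];
        }
    }
    // reverse BFS order: accumulate dependencies onto predecessor edges
    for (int t = (int) order.size() - 1; t >= 0; --t) {
        int w = order[t];
        for (size_t u = 0; u < adj[w].size(); ++u) {
            int v = adj[w][u].first;
            int eid = adj[w][u].second;
            if (!active[eid]) continue;
            if (dist[v] == dist[w] - 1) {
                double c = (sigma[v] / sigma[w]) * (1.0 + delta[w]);
                if (eid < n_scored) ebc[eid] += c;
                delta[v] += c;
            }
        }
    }
}

// Edge betweenness (shortest-path, unit lengths, unordered-pair counting)
// for an arbitrary undirected graph given as a 1-based edge list.
// [[Rcpp::export]]
NumericVector cpp_edge_betweenness(int n_nodes, IntegerVector from, IntegerVector to) {
    int M = from.size();
    std::vector<std::vector<std::pair<int, int> > > adj(n_nodes);
    for (int e = 0; e < M; ++e) {
        int u = from[e] - 1, v = to[e] - 1;
        adj[u].push_back(std::make_pair(v, e));
        adj[v].push_back(std::make_pair(u, e));
    }
    std::vector<char> active(M, 1);
    std::vector<double> ebc(M, 0.0), sigma(n_nodes), delta(n_nodes);
    std::vector<int> dist(n_nodes), order;
    order.reserve(n_nodes);
    for (int s = 0; s < n_nodes; ++s)
        brandes_from_source(s, adj, active, M, ebc, dist, sigma, delta, order);
    NumericVector out(M);
    for (int e = 0; e < M; ++e) out[e] = ebc[e] / 2.0;
    return out;
}

// union-find with path halving
static int uf_find(std::vector<int> &parent, int x) {
    while (parent[x] != x) {
        parent[x] = parent[parent[x]];
        x = parent[x];
    }
    return x;
}

// Multiplex Girvan-Newman removal loop.
//
// n organisms, L layers; intra-layer edges (1-based: layer, from, to with
// from < to) must arrive sorted lexicographically by (layer, from, to) --
// tie-breaking on equal maximal betweenness picks the first edge in that
// order. The inter-layer coupling is the full clique over each organism's
// L replicas and is never removed. Betweenness is computed on the global
// graph (intra + inter, unit lengths) and recomputed after every removal,
// restricted to the connected component(s) touched by the last removal.
//
// Modularity after each removal is the multilayer modularity (resolution
// gamma, coupling omega) of the current organism-level partition evaluated
// on the ORIGINAL thresholded layers.
//
// stop_communities > 0: stop once the organism community count reaches it.
// stop_group non-empty: stop once no community contains both a member and a
// non-member of the group.
// [[Rcpp::export]]
List cpp_multing(int n, int L,
                 IntegerVector e_layer, IntegerVector e_from, IntegerVector e_to,
                 double gamma, double omega,
                 int stop_communities,
                 IntegerVector stop_group) {
    const int M = e_layer.size();
    const int N = n * L;
    const int n_inter = n * L * (L - 1) / 2;

    // adjacency over global nodes; edge ids: 0..M-1 intra, M.. inter
    std::vector<std::vector<std::pair<int, int> > > adj(N);
    for (int e = 0; e < M; ++e) {
        int a = e_layer[e] - 1;
        int u = a * n + (e_from[e] - 1);
        int v = a * n + (e_to[e] - 1);
        adj[u].push_back(std::make_pair(v, e));
        adj[v].push_back(std::make_pair(u, e));
    }
    {
        int eid = M;
        for (int i = 0; i < n; ++i)
            for (int a = 0; a < L; ++a)
                for (int b = a + 1; b < L; ++b) {
                    int u = a * n + i, v = b * n + i;
                    adj[u].push_back(std::make_pair(v, eid));
                    adj[v].push_back(std::make_pair(u, eid));
                    ++eid;
                }
    }
    std::vector<char> active(M + n_inter, 1);

    // original per-layer degrees and edge counts (for modularity)
    std::vector<double> k_orig(N, 0.0), m_layer(L, 0.0);
    for (int e = 0; e < M; ++e) {
        int a = e_layer[e] - 1;
        k_orig[a * n + (e_from[e] - 1)] += 1.0;
        k_orig[a * n + (e_to[e] - 1)] += 1.0;
        m_layer[a] += 1.0;
    }
    double two_mu = omega * (double) n * L * (L - 1);
    for (int a = 0; a < L; ++a) two_mu += 2.0 * m_layer[a];
    const double coupling_term = omega * (double) n * L * (L - 1);

    std::vector<char> in_group(n, 0);
    for (int t = 0; t < stop_group.size(); ++t) in_group[stop_group[t] - 1] = 1;
    const bool use_group = stop_group.size() > 0;

    // organism partition from active intra edges (canonical min-member labels)
    std::vector<int> memb(n), parent(n);
    std::vector<double> ebc(M, 0.0), sigma(N), delta(N);
    std::vector<int> dist(N), order;
    order.reserve(N);
    std::vector<int> comp(N, -1);

    // outputs
    std::vector<int> out_layer, out_from, out_to, out_ncomm;
    std::vector<double> out_btw, out_q;
    out_layer.reserve(M);
    out_from.reserve(M);
    out_to.reserve(M);
    out_ncomm.reserve(M);
    out_btw.reserve(M);
    out_q.reserve(M);
    std::vector<int> ev_step, ev_parent;
    std::vector<std::vector<int> > ev_children;
    std::vector<std::vector<int> > memb_snapshots;

    // helper lambdas ------------------------------------------------------
    // current organism partition via union-find over active intra edges
    std::vector<double> kc(0);            // scratch for modularity (n_comm x L won't exceed n*L)
    std::vector<int> label_of_root(n);

    // compute partition into memb; returns community count
    // (absent/isolated organisms are their own singleton communities)
    // canonical label: smallest organism index in the community
    // -- defined as a plain function via lambda-free loop each call

    int n_comm = 0;
    {
        // initial partition
        for (int i = 0; i < n; ++i) parent[i] = i;
        for (int e = 0; e < M; ++e) {
            if (!active[e]) continue;
            int ru = uf_find(parent, e_from[e] - 1), rv = uf_find(parent, e_to[e] - 1);
            if (ru != rv) parent[std::max(ru, rv)] = std::min(ru, rv);
        }
        for (int i = 0; i < n; ++i) memb[i] = uf_find(parent, i);
        n_comm = 0;
        for (int i = 0; i < n; ++i) if (memb[i] == i) ++n_comm;
        memb_snapshots.push_back(memb);
    }

    std::vector<int> prev_memb = memb;
    int prev_ncomm = n_comm;
    int last_u = -1, last_v = -1;   // endpoints of last removed edge (global ids)
    int removed = 0;
    int step = 0;
    int remaining = M;
    bool stopped_early = false;

    while (remaining > 0) {
        ++step;
        // --- global components, for betweenness caching ---
        std::fill(comp.begin(), comp.end(), -1);
        int n_gcomp = 0;
        for (int s = 0; s < N; ++s) {
            if (comp[s] >= 0) continue;
            comp[s] = n_gcomp;
            std::queue<int> q;
            q.push(s);
            while (!q.empty()) {
                int v = q.front();
                q.pop();
                for (size_t t = 0; t < adj[v].size(); ++t) {
                    int w = adj[v][t].first;
                    if (!active[adj[v][t].second]) continue;
                    if (comp[w] < 0) {
                        comp[w] = n_gcomp;
                        q.push(w);
                    }
                }
            }
            ++n_gcomp;
        }
        // dirty components: all on first pass, else those of last removal
        std::vector<char> dirty(n_gcomp, 0);
        if (last_u < 0) {
            std::fill(dirty.begin(), dirty.end(), 1);
        } else {
            dirty[comp[last_u]] = 1;
            dirty[comp[last_v]] = 1;
        }
        for (int e = 0; e < M; ++e) {
            if (!active[e]) continue;
            int a = e_layer[e] - 1;
            int u = a * n + (e_from[e] - 1);
            if (dirty[comp[u]]) ebc[e] = 0.0;
        }
        for (int s = 0; s < N; ++s)
            if (dirty[comp[s]])
                brandes_from_source(s, adj, active, M, ebc, dist, sigma, delta, order);

        // --- pick removal: max betweenness, lexicographic tie-break ---
        double best = -1.0;
        for (int e = 0; e < M; ++e)
            if (active[e] && ebc[e] > best) best = ebc[e];
        double tol = 1e-9 * std::max(1.0, best);
        int pick = -1;
        for (int e = 0; e < M; ++e)
            if (active[e] && ebc[e] >= best - tol) { pick = e; break; }

        active[pick] = 0;
        --remaining;
        ++removed;
        int a = e_layer[pick] - 1;
        last_u = a * n + (e_from[pick] - 1);
        last_v = a * n + (e_to[pick] - 1);

        // --- organism partition after removal ---
        for (int i = 0; i < n; ++i) parent[i] = i;
        for (int e = 0; e < M; ++e) {
            if (!active[e]) continue;
            int ru = uf_find(parent, e_from[e] - 1), rv = uf_find(parent, e_to[e] - 1);
            if (ru != rv) parent[std::max(ru, rv)] = std::min(ru, rv);
        }
        for (int i = 0; i < n; ++i) memb[i] = uf_find(parent, i);
        n_comm = 0;
        for (int i = 0; i < n; ++i) if (memb[i] == i) ++n_comm;

        // --- multilayer modularity of current partition on original layers ---
        double q_intra = 0.0;
        for (int e = 0; e < M; ++e)
            if (memb[e_from[e] - 1] == memb[e_to[e] - 1]) q_intra += 2.0;
        double q_null = 0.0;
        {
            // sum of squared community degree per layer
            // kc indexed by community root (memb label) per layer, sparse walk
            kc.assign((size_t) n * L, 0.0);
            for (int aa = 0; aa < L; ++aa)
                for (int i = 0; i < n; ++i)
                    kc[(size_t) aa * n + memb[i]] += k_orig[aa * n + i];
            for (int aa = 0; aa < L; ++aa) {
                if (m_layer[aa] <= 0.0) continue;
                double acc = 0.0;
                for (int i = 0; i < n; ++i) {
                    double kcv = kc[(size_t) aa * n + i];
                    if (kcv > 0.0) acc += kcv * kcv;
                }
                q_null += gamma * acc / (2.0 * m_layer[aa]);
            }
        }
        double Q = (q_intra - q_null + coupling_term) / two_mu;

        out_layer.push_back(a + 1);
        out_from.push_back(e_from[pick]);
        out_to.push_back(e_to[pick]);
        out_btw.push_back(ebc[pick] / 2.0);
        out_ncomm.push_back(n_comm);
        out_q.push_back(Q);

        // --- split event detection ---
        if (n_comm > prev_ncomm) {
            int par = prev_memb[e_from[pick] - 1];
            std::vector<int> children;
            for (int i = 0; i < n; ++i)
                if (prev_memb[i] == par && memb[i] == i) children.push_back(i + 1);
            ev_step.push_back(step);
            ev_parent.push_back(par + 1);
            ev_children.push_back(children);
            memb_snapshots.push_back(memb);
        }
        prev_memb = memb;
        prev_ncomm = n_comm;

        // --- stop conditions ---
        if (stop_communities > 0 && n_comm >= stop_communities) {
            stopped_early = remaining > 0;
            break;
        }
        if (use_group) {
            // group separated <=> no community holds both group and non-group
            std::vector<char> has_g(n, 0), has_o(n, 0);
            bool mixed = false;
            for (int i = 0; i < n; ++i) {
                int c = memb[i];
                if (in_group[i]) {
                    if (has_o[c]) { mixed = true; break; }
                    has_g[c] = 1;
                } else {
                    if (has_g[c]) { mixed = true; break; }
                    has_o[c] = 1;
                }
            }
            if (!mixed) {
                stopped_early = remaining > 0;
                break;
            }
        }
    }

    int n_steps = (int) out_layer.size();
    IntegerVector r_step(n_steps);
    for (int i = 0; i < n_steps; ++i) r_step[i] = i + 1;
    List events(ev_step.size());
    for (size_t i = 0; i < ev_step.size(); ++i)
        events[i] = List::create(_["step"] = ev_step[i],
                                 _["parent"] = ev_parent[i],
                                 _["children"] = wrap(ev_children[i]));
    IntegerMatrix snaps(n, (int) memb_snapshots.size());
    for (size_t j = 0; j < memb_snapshots.size(); ++j)
        for (int i = 0; i < n; ++i) snaps(i, (int) j) = memb_snapshots[j][i] + 1;
    IntegerVector snap_steps((int) memb_snapshots.size());
    snap_steps[0] = 0;
    for (size_t i = 0; i < ev_step.size(); ++i) snap_steps[(int) i + 1] = ev_step[i];

    return List::create(
        _["step"] = r_step,
        _["layer"] = wrap(out_layer),
        _["from"] = wrap(out_from),
        _["to"] = wrap(out_to),
        _["betweenness"] = wrap(out_btw),
        _["n_communities"] = wrap(out_ncomm),
        _["modularity"] = wrap(out_q),
        _["events"] = events,
        _["memberships"] = snaps,
        _["membership_steps"] = snap_steps,
        _["completed"] = !stopped_early && remaining == 0);
}
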