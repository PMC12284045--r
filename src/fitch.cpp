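#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Binary-state Fitch machinery. State sets are bit codes over {0,1}:
//   1 = {0}, 2 = {1}, 3 = {0,1} (missing data enters as the full set).
// Trees are unrooted and held as edge lists over node ids
//   0..n_tips-1            tips
//   n_tips..2*n_tips-3     internal nodes (degree 3 when the tree is binary)
// Scoring roots the tree at tip 0, which leaves the Fitch length unchanged.

namespace {

struct EdgeList {
    std::vector<int> u, v;
    int n_nodes;
};

// Fitch length of (a possibly partial) unrooted tree. tip_codes: n_tips x n_char.
// Works for any multifurcating tree via sequential pairwise set combination.
int fitch_length(const std::vector<int>& eu, const std::vector<int>& ev,
                 int n_nodes, const IntegerMatrix& tip_codes) {
    const int n_tips = tip_codes.nrow();
    const int n_char = tip_codes.ncol();
    const int n_edges = (int)eu.size();

    // adjacency
    std::vector<int> deg(n_nodes, 0);
    for (int e = 0; e < n_edges; ++e) { deg[eu[e]]++; deg[ev[e]]++; }
    std::vector<int> off(n_nodes + 1, 0);
    for (int i = 0; i < n_nodes; ++i) off[i + 1] = off[i] + deg[i];
    std::vector<int> adj(2 * n_edges);
    std::vector<int> pos(n_nodes, 0);
    for (int e = 0; e < n_edges; ++e) {
        adj[off[eu[e]] + pos[eu[e]]++] = ev[e];
        adj[off[ev[e]] + pos[ev[e]]++] = eu[e];
    }

    // iterative DFS postorder from tip 0
    std::vector<int> order; order.reserve(n_nodes);
    std::vector<int> parent(n_nodes, -1);
    std::vector<int> stack; stack.reserve(n_nodes);
    std::vector<char> seen(n_nodes, 0);
    stack.push_back(0); seen[0] = 1;
    while (!stack.empty()) {
        int nd = stack.back(); stack.pop_back();
        order.push_back(nd);
        for (int k = off[nd]; k < off[nd + 1]; ++k) {
            int nb = adj[k];
            if (!seen[nb]) { seen[nb] = 1; parent[nb] = nd; stack.push_back(nb); }
        }
    }

    // state codes per node, chars flattened
    std::vector<unsigned char> code((size_t)n_nodes * n_char, 0);
    int cost = 0;
    for (int oi = (int)order.size() - 1; oi >= 0; --oi) {
        int nd = order[oi];
        unsigned char* me = &code[(size_t)nd * n_char];
        if (nd < n_tips) {
            for (int c = 0; c < n_char; ++c) me[c] = (unsigned char)tip_codes(nd, c);
        } else {
            for (int c = 0; c < n_char; ++c) me[c] = 3;
        }
        // combine children (neighbours already processed, i.e. not the parent)
        for (int k = off[nd]; k < off[nd + 1]; ++k) {
            int nb = adj[k];
            if (nb == parent[nd]) continue;
            const unsigned char* ch = &code[(size_t)nb * n_char];
            for (int c = 0; c < n_char; ++c) {
                unsigned char inter = me[c] & ch[c];
                if (inter) me[c] = inter;
                else { me[c] = me[c] | ch[c]; ++cost; }
            }
        }
    }
    return cost;
}

struct SearchState {
    const IntegerMatrix* tip_codes;
    int n_tips;
    bool prune;
    int best;
    double examined;                 // complete topologies scored
    bool found;                      // a tree attaining `best` has been stored
    std::vector<std::vector<int>> best_eu, best_ev;
    int max_store;
    bool overflow;                   // co-optimal trees beyond max_store exist
};

void search_rec(std::vector<int>& eu, std::vector<int>& ev, int next_tip,
                SearchState& st) {
    const int n_tips = st.n_tips;
    if (next_tip == n_tips) {
        st.examined += 1.0;
        int s = fitch_length(eu, ev, n_tips + (n_tips - 2), *st.tip_codes);
        if (s < st.best || (s == st.best && !st.found)) {
            if (s < st.best) { st.best_eu.clear(); st.best_ev.clear(); st.overflow = false; }
            st.best = s; st.found = true;
            st.best_eu.push_back(eu); st.best_ev.push_back(ev);
        } else if (s == st.best) {
            if ((int)st.best_eu.size() < st.max_store) {
                st.best_eu.push_back(eu); st.best_ev.push_back(ev);
            } else st.overflow = true;
        }
        return;
    }
    if (st.prune && next_tip > 3) {
        // the score of a partial tree never decreases as taxa are added
        int s = fitch_length(eu, ev, n_tips + (next_tip - 2), *st.tip_codes);
        if (s > st.best) return;
    }
    int new_internal = n_tips + next_tip - 2;
    int n_edges = (int)eu.size();
    for (int e = 0; e < n_edges; ++e) {
        int a = eu[e], b = ev[e];
        eu[e] = a; ev[e] = new_internal;
        eu.push_back(new_internal); ev.push_back(b);
        eu.push_back(new_internal); ev.push_back(next_tip);
        search_rec(eu, ev, next_tip + 1, st);
        eu.pop_back(); ev.pop_back();
        eu.pop_back(); ev.pop_back();
        eu[e] = a; ev[e] = b;
    }
}

} // namespace

// [[Rcpp::export]]
int cpp_fitch_score(IntegerMatrix edges, IntegerMatrix tip_codes, int n_nodes) {
    int n_edges = edges.nrow();
    std::vector<int> eu(n_edges), ev(n_edges);
    for (int e = 0; e < n_edges; ++e) { eu[e] = edges(e, 0); ev[e] = edges(e, 1); }
    return fitch_length(eu, ev, n_nodes, tip_codes);
}

// Stepwise-addition enumeration over all unrooted binary topologies, visiting
// each exactly once; with prune=TRUE the partial-tree score bound makes it a
// branch-and-bound search. init_upper (if >= 0) seeds the bound with the score
// of a heuristic tree so that only trees at or below it are retained.
// [[Rcpp::export]]
List cpp_mp_search(IntegerMatrix tip_codes, bool prune, int init_upper,
                   int max_store = 100000) {
    const int n_tips = tip_codes.nrow();
    if (n_tips < 3) stop("need at least 3 taxa");

    SearchState st;
    st.tip_codes = &tip_codes;
    st.n_tips = n_tips;
    st.prune = prune;
    st.best = (init_upper >= 0) ? init_upper : INT_MAX;
    st.examined = 0.0;
    st.found = false;
    st.max_store = max_store;
    st.overflow = false;

    // initial unrooted star on tips 0,1,2 joined at internal node n_tips
    std::vector<int> eu = {0, 1, 2};
    std::vector<int> ev = {n_tips, n_tips, n_tips};
    search_rec(eu, ev, 3, st);

    List trees((int)st.best_eu.size());
    for (int i = 0; i < (int)st.best_eu.size(); ++i) {
        int ne = (int)st.best_eu[i].size();
        IntegerMatrix em(ne, 2);
        for (int e = 0; e < ne; ++e) { em(e, 0) = st.best_eu[i][e]; em(e, 1) = st.best_ev[i][e]; }
        trees[i] = em;
    }
    return List::create(_["best_score"] = st.best,
                        _["trees"] = trees,
                        _["examined"] = st.examined,
                        _["overflow"] = st.overflow);
}
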