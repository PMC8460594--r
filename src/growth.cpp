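#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Parent-array tree representation shared with the R side:
//   parent[v], lchild[v], rchild[v] (1-based ids, 0 = none), root == 1.
// Rooted trees keep the degree-one root rho explicit, so every non-root
// vertex identifies the edge (parent[v], v) and there are 2n-1 edges.
// Unrooted trees are handle-rooted at a leaf: the root vertex is itself a
// leaf, giving 2n-3 edges (vertices 2..nv).

namespace {

struct Tree {
    std::vector<int> parent, lchild, rchild;
    int root;
    bool rooted;
    int nleaf;
    std::vector<int> pend;     // vertices identifying pendant edges
    std::vector<int> pend_pos; // position in pend, 0 = absent (1-based)

    int nv() const { return static_cast<int>(parent.size()) - 1; }

    bool is_leaf(int v) const {
        if (rooted) return v != root && lchild[v] == 0;
        return v == root || lchild[v] == 0;
    }

    int sibling(int v) const {
        const int p = parent[v];
        return lchild[p] == v ? rchild[p] : lchild[p];
    }

    bool is_pendant_edge(int v) const {
        if (rooted) return is_leaf(v);
        return is_leaf(v) || parent[v] == root;
    }

    void pend_add(int v) {
        pend.push_back(v);
        pend_pos[v] = static_cast<int>(pend.size());
    }

    void pend_remove(int v) {
        const int pos = pend_pos[v];
        const int last = pend.back();
        pend[pos - 1] = last;
        pend_pos[last] = pos;
        pend.pop_back();
        pend_pos[v] = 0;
    }

    void init_pendants() {
        pend.clear();
        pend_pos.assign(parent.size() + 4, 0);
        for (int v = 2; v <= nv(); ++v)
            if (is_pendant_edge(v)) pend_add(v);
    }

    // attach a new leaf to edge (parent[v], v): subdivide with w, hang x
    void attach(int v) {
        const int w = nv() + 1, x = nv() + 2;
        parent.resize(parent.size() + 2, 0);
        lchild.resize(lchild.size() + 2, 0);
        rchild.resize(rchild.size() + 2, 0);
        if (static_cast<size_t>(x) + 4 > pend_pos.size()) pend_pos.resize(x + 5, 0);
        const int p = parent[v];
        if (lchild[p] == v) lchild[p] = w; else rchild[p] = w;
        parent[w] = p;
        lchild[w] = v;
        rchild[w] = x;
        parent[v] = w;
        parent[x] = w;
        ++nleaf;
        // pendant bookkeeping
        if (!rooted && p == root) {
            pend_add(w);                       // the handle edge is now w
            if (pend_pos[v] && !is_leaf(v)) pend_remove(v);
        }
        pend_add(x);
    }

    int n_leaf_nbrs(int w) const {
        int c = 0;
        if (parent[w] && is_leaf(parent[w])) ++c;
        if (lchild[w] && is_leaf(lchild[w])) ++c;
        if (rchild[w] && is_leaf(rchild[w])) ++c;
        return c;
    }

    int nonleaf_nbr(int w, int skip) const {
        const int nb[3] = { parent[w], lchild[w], rchild[w] };
        for (int k = 0; k < 3; ++k)
            if (nb[k] && nb[k] != skip && !is_leaf(nb[k])) return nb[k];
        return 0;
    }

    bool cherry_vertex(int w) const { return !is_leaf(w) && n_leaf_nbrs(w) == 2; }

    // Edge types 1-6 for the edge identified by vertex v (v != root).
    int classify(int v) const {
        if (rooted) return classify_rooted(v);
        return classify_unrooted(v);
    }

    int classify_rooted(int v) const {
        const int p = parent[v];
        if (is_leaf(v)) {
            const int s = sibling(v);
            if (is_leaf(s)) { // cherry rooted at p
                if (parent[p] == root) return 2;
                const int u = sibling(p);
                return is_leaf(u) ? 1 : 2;
            }
            // sibling is interior: in a pitchfork iff it roots a cherry
            return (is_leaf(lchild[s]) && is_leaf(rchild[s])) ? 3 : 4;
        }
        // internal edge
        if (lchild[v] && is_leaf(lchild[v]) && is_leaf(rchild[v])) { // v roots a cherry
            if (p == root) return 5;
            return is_leaf(sibling(v)) ? 6 : 5;
        }
        return 6;
    }

    int classify_unrooted(int v) const {
        const int p = parent[v];
        const bool lv = is_leaf(v), lp = is_leaf(p);
        if (lv || lp) { // pendant edge
            const int w = lv ? p : v; // interior endpoint (n >= 3)
            if (n_leaf_nbrs(w) == 2) { // the leaf is in a cherry at w
                const int x = nonleaf_nbr(w, 0);
                return (x && n_leaf_nbrs(x) > 0) ? 1 : 2;
            }
            // sole leaf at w: in a pitchfork iff w has a cherry-vertex nbr
            const int nb[3] = { parent[w], lchild[w], rchild[w] };
            for (int k = 0; k < 3; ++k)
                if (nb[k] && cherry_vertex(nb[k])) return 3;
            return 4;
        }
        // internal edge
        if (cherry_vertex(v)) return n_leaf_nbrs(p) > 0 ? 6 : 5;
        if (cherry_vertex(p)) return n_leaf_nbrs(v) > 0 ? 6 : 5;
        return 6;
    }

    void count_ab(int& A, int& B) const {
        A = 0; B = 0;
        if (rooted) {
            for (int v = 2; v <= nv(); ++v) {
                if (is_leaf(v)) continue;
                const bool lc = is_leaf(lchild[v]), rc = is_leaf(rchild[v]);
                if (lc && rc) { ++B; continue; }
                if (lc && cherry_vertex(rchild[v])) ++A;
                else if (rc && cherry_vertex(lchild[v])) ++A;
            }
        } else {
            for (int v = 1; v <= nv(); ++v) {
                if (is_leaf(v)) continue;
                const int ln = n_leaf_nbrs(v);
                if (ln == 2) { ++B; continue; }
                if (ln == 1) {
                    const int nb[3] = { parent[v], lchild[v], rchild[v] };
                    for (int k = 0; k < 3; ++k)
                        if (nb[k] && cherry_vertex(nb[k])) ++A;
                }
            }
        }
    }
};

Tree tree_from_r(IntegerVector parent, IntegerVector lchild,
                 IntegerVector rchild, bool rooted, int nleaf) {
    Tree t;
    const int nv = parent.size();
    t.parent.assign(nv + 1, 0);
    t.lchild.assign(nv + 1, 0);
    t.rchild.assign(nv + 1, 0);
    for (int i = 0; i < nv; ++i) {
        t.parent[i + 1] = parent[i];
        t.lchild[i + 1] = lchild[i];
        t.rchild[i + 1] = rchild[i];
    }
    t.root = 1;
    t.rooted = rooted;
    t.nleaf = nleaf;
    return t;
}

inline int unif_index(int n) {
    int k = static_cast<int>(unif_rand() * n);
    return k >= n ? n - 1 : k;
}

void grow_inner(Tree& t, int model, int n_target,
                std::vector<int>* types_out) {
    while (t.nleaf < n_target) {
        int v;
        if (model == 0) { // YHK: uniform pendant edge
            v = t.pend[unif_index(static_cast<int>(t.pend.size()))];
        } else {          // PDA: uniform edge (vertices 2..nv)
            v = 2 + unif_index(t.nv() - 1);
        }
        if (types_out) {
            const bool typed = t.rooted || t.nleaf >= 6;
            types_out->push_back(typed ? t.classify(v) : NA_INTEGER);
        }
        t.attach(v);
    }
}

} // namespace

// [[Rcpp::export]]
List grow_cpp(IntegerVector parent, IntegerVector lchild, IntegerVector rchild,
              bool rooted, int nleaf, int model, int n_target,
              bool record_types) {
    Tree t = tree_from_r(parent, lchild, rchild, rooted, nleaf);
    t.init_pendants();
    std::vector<int> types;
    grow_inner(t, model, n_target, record_types ? &types : 0);
    const int nv = t.nv();
    IntegerVector p(nv), l(nv), r(nv);
    for (int i = 0; i < nv; ++i) {
        p[i] = t.parent[i + 1];
        l[i] = t.lchild[i + 1];
        r[i] = t.rchild[i + 1];
    }
    List out = List::create(_["parent"] = p, _["lchild"] = l, _["rchild"] = r,
                            _["nleaf"] = t.nleaf);
    if (record_types) out["step_types"] = wrap(types);
    return out;
}

// [[Rcpp::export]]
IntegerMatrix sample_joint_cpp(IntegerVector parent, IntegerVector lchild,
                               IntegerVector rchild, bool rooted, int nleaf,
                               int model, int n_target, int reps) {
    const Tree start = tree_from_r(parent, lchild, rchild, rooted, nleaf);
    IntegerMatrix out(reps, 2);
    for (int rep = 0; rep < reps; ++rep) {
        Tree t = start;
        t.init_pendants();
        grow_inner(t, model, n_target, 0);
        int A, B;
        t.count_ab(A, B);
        out(rep, 0) = A;
        out(rep, 1) = B;
        if (rep % 256 == 0) Rcpp::checkUserInterrupt();
    }
    colnames(out) = CharacterVector::create("A", "B");
    return out;
}

// [[Rcpp::export]]
IntegerVector classify_edges_cpp(IntegerVector parent, IntegerVector lchild,
                                 IntegerVector rchild, bool rooted, int nleaf) {
    Tree t = tree_from_r(parent, lchild, rchild, rooted, nleaf);
    IntegerVector out(t.nv());
    out[0] = NA_INTEGER; // the root identifies no edge
    for (int v = 2; v <= t.nv(); ++v) out[v - 1] = t.classify(v);
    return out;
}

// [[Rcpp::export]]
IntegerVector count_ab_cpp(IntegerVector parent, IntegerVector lchild,
                           IntegerVector rchild, bool rooted, int nleaf) {
    Tree t = tree_from_r(parent, lchild, rchild, rooted, nleaf);
    int A, B;
    t.count_ab(A, B);
    return IntegerVector::create(_["A"] = A, _["B"] = B);
}
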