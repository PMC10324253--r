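#include <Rcpp.h>
using namespace Rcpp;

// lexicographic comparison of node sets encoded as bitmasks: compare the
// ascending member index sequences element-wise; a strict prefix is smaller
static bool lex_less(unsigned a, unsigned b) {
    while (a && b) {
        int ia = __builtin_ctz(a), ib = __builtin_ctz(b);
        if (ia != ib) return ia < ib;
        a &= a - 1;
        b &= b - 1;
    }
    return a == 0 && b != 0;
}

// Enumerate all connected induced subgraphs of a graph on <= 16 nodes and
// return the maximum-weight one.  adj[i] is the neighbor bitmask of node i.
// [[Rcpp::export]]
List mwcs_exact_cpp(IntegerVector adj, NumericVector w) {
    const int n = adj.size();
    if (n < 1 || n > 16) stop("node count must be between 1 and 16");
    const unsigned full = 1u << n;
    double best_w = -std::numeric_limits<double>::infinity();
    unsigned best_mask = 0;

    for (unsigned mask = 1; mask < full; ++mask) {
        // flood-fill from the lowest member, restricted to the mask
        unsigned comp = mask & (~mask + 1u);
        for (;;) {
            unsigned frontier = 0, rem = comp;
            while (rem) {
                int i = __builtin_ctz(rem);
                rem &= rem - 1;
                frontier |= (unsigned)adj[i];
            }
            unsigned grown = (comp | frontier) & mask;
            if (grown == comp) break;
            comp = grown;
        }
        if (comp != mask) continue;  // not connected

        double tw = 0;
        unsigned rem = mask;
        while (rem) {
            int i = __builtin_ctz(rem);
            rem &= rem - 1;
            tw += w[i];
        }
        if (tw > best_w + 1e-12) {
            best_w = tw;
            best_mask = mask;
        } else if (tw > best_w - 1e-12 && lex_less(mask, best_mask)) {
            best_mask = mask;
        }
    }

    IntegerVector members;
    unsigned rem = best_mask;
    double tw = 0;
    while (rem) {
        int i = __builtin_ctz(rem);
        rem &= rem - 1;
        members.push_back(i + 1);
        tw += w[i];
    }
    return List::create(_["members"] = members, _["weight"] = tw);
}
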