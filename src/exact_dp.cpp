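#include <Rcpp.h>
#include <map>
#include <vector>
#include "bignum.h"
using namespace Rcpp;

// Exact forward recursion for the edge-type urn.  All state probabilities at
// step k share the denominator D_k = prod_{j<k} t_j (the urn is balanced, so
// t_j is deterministic); the DP therefore only needs bignum numerators with
// add and multiply-by-small, and gcd reduction happens once per reported
// quantity at the end.

typedef std::map<std::vector<int>, BigNat> StateMap;

static void moments_from_states(const StateMap& states, const BigNat& D,
                                double* out) {
    // numeric moments of (A, B) with A = s1/2, B = (s1 + s2)/2
    double eA = 0, eB = 0, eA2 = 0, eB2 = 0, eAB = 0;
    for (StateMap::const_iterator it = states.begin(); it != states.end(); ++it) {
        const double p = bn_ratio(it->second, D);
        const double A = it->first[0] / 2.0;
        const double B = (it->first[0] + it->first[1]) / 2.0;
        eA += p * A; eB += p * B;
        eA2 += p * A * A; eB2 += p * B * B; eAB += p * A * B;
    }
    out[0] = eA; out[1] = eB;
    out[2] = eA2 - eA * eA;
    out[3] = eB2 - eB * eB;
    out[4] = eAB - eA * eB;
}

// [[Rcpp::export]]
List dp_evolve_cpp(IntegerVector C0, IntegerMatrix Rmat, int steps,
                   bool want_pmf, bool per_step) {
    const int d = C0.size();
    if (Rmat.nrow() != d || Rmat.ncol() != d)
        stop("replacement matrix does not match configuration length");
    std::vector<int> s0(C0.begin(), C0.end());
    long t0 = 0;
    for (int i = 0; i < d; ++i) {
        if (s0[i] < 0) stop("negative initial configuration");
        t0 += s0[i];
    }
    if (t0 <= 0) stop("initial configuration is empty");
    long bal = 0;
    for (int j = 0; j < d; ++j) bal += Rmat(0, j);
    for (int i = 1; i < d; ++i) {
        long rs = 0;
        for (int j = 0; j < d; ++j) rs += Rmat(i, j);
        if (rs != bal) stop("replacement matrix is not balanced");
    }

    StateMap cur;
    cur[s0] = BigNat(1);
    BigNat D(1);
    NumericMatrix traj(per_step ? steps + 1 : 0, 5);
    if (per_step) {
        double m[5];
        moments_from_states(cur, D, m);
        for (int c = 0; c < 5; ++c) traj(0, c) = m[c];
    }

    for (int k = 0; k < steps; ++k) {
        const long t = t0 + static_cast<long>(k) * bal;
        if (t <= 0) stop("urn exhausted: total count is not positive");
        StateMap nxt;
        for (StateMap::const_iterator it = cur.begin(); it != cur.end(); ++it) {
            const std::vector<int>& st = it->first;
            for (int i = 0; i < d; ++i) {
                if (st[i] <= 0) continue;
                std::vector<int> ns(st);
                for (int j = 0; j < d; ++j) ns[j] += Rmat(i, j);
                for (int j = 0; j < d; ++j)
                    if (ns[j] < 0) stop("tenability violated: colour count went negative");
                const BigNat contrib = bn_mul(it->second, BigNat(static_cast<uint64_t>(st[i])));
                StateMap::iterator jt = nxt.find(ns);
                if (jt == nxt.end()) nxt.insert(std::make_pair(ns, contrib));
                else bn_add_inplace(jt->second, contrib);
            }
        }
        cur.swap(nxt);
        D = bn_mul(D, BigNat(static_cast<uint64_t>(t)));
        if (per_step) {
            double m[5];
            moments_from_states(cur, D, m);
            for (int c = 0; c < 5; ++c) traj(k + 1, c) = m[c];
        }
        Rcpp::checkUserInterrupt();
    }

    // exact moments of (A, B): accumulate integer-weighted numerator sums.
    // Type vectors have even first/second entries so 2A and 2B are integers;
    // work with 2A, 2B and divide by shifting the denominator.
    BigNat S_A, S_B, S_A2, S_B2, S_AB;
    for (StateMap::const_iterator it = cur.begin(); it != cur.end(); ++it) {
        const uint64_t a2 = static_cast<uint64_t>(it->first[0]);            // 2A
        const uint64_t b2 = static_cast<uint64_t>(it->first[0] + it->first[1]); // 2B
        const BigNat& num = it->second;
        bn_add_inplace(S_A, bn_mul(num, BigNat(a2)));
        bn_add_inplace(S_B, bn_mul(num, BigNat(b2)));
        bn_add_inplace(S_A2, bn_mul(num, BigNat(a2 * a2)));
        bn_add_inplace(S_B2, bn_mul(num, BigNat(b2 * b2)));
        bn_add_inplace(S_AB, bn_mul(num, BigNat(a2 * b2)));
    }
    const BigNat D2 = bn_mul(D, BigNat(2));  // denominator of E[2A]/2 etc.
    const BigNat D4 = bn_mul(D, BigNat(4));
    BigRat E_A = rat_make(1, S_A, D2);
    BigRat E_B = rat_make(1, S_B, D2);
    BigRat E_A2 = rat_make(1, S_A2, D4);
    BigRat E_B2 = rat_make(1, S_B2, D4);
    BigRat E_AB = rat_make(1, S_AB, D4);
    BigRat V_A = rat_sub(E_A2, rat_mul(E_A, E_A));
    BigRat V_B = rat_sub(E_B2, rat_mul(E_B, E_B));
    BigRat C_AB = rat_sub(E_AB, rat_mul(E_A, E_B));

    CharacterVector mom_exact = CharacterVector::create(
        rat_to_string(E_A), rat_to_string(E_B), rat_to_string(V_A),
        rat_to_string(V_B), rat_to_string(C_AB));
    NumericVector mom_num = NumericVector::create(
        rat_to_double(E_A), rat_to_double(E_B), rat_to_double(V_A),
        rat_to_double(V_B), rat_to_double(C_AB));
    mom_exact.names() = CharacterVector::create("E_A", "E_B", "V_A", "V_B", "Cov_AB");
    mom_num.names() = mom_exact.names();

    List out = List::create(_["moments_exact"] = mom_exact,
                            _["moments"] = mom_num,
                            _["n_states"] = static_cast<int>(cur.size()));
    if (want_pmf) {
        const int ns = static_cast<int>(cur.size());
        IntegerMatrix states(ns, d);
        CharacterVector probs(ns);
        NumericVector pnum(ns);
        int row = 0;
        for (StateMap::const_iterator it = cur.begin(); it != cur.end(); ++it, ++row) {
            for (int j = 0; j < d; ++j) states(row, j) = it->first[j];
            probs[row] = rat_to_string(rat_make(1, it->second, D));
            pnum[row] = bn_ratio(it->second, D);
        }
        out["states"] = states;
        out["prob_exact"] = probs;
        out["prob"] = pnum;
    }
    if (per_step) {
        colnames(traj) = CharacterVector::create("E_A", "E_B", "V_A", "V_B", "Cov_AB");
        out["trajectory"] = traj;
    }
    return out;
}
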