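#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Max-product Viterbi in log space. Ties broken toward the lowest state
// index so decoded paths are reproducible bit-for-bit.
//
// Two entry points share the same update rule:
//  - viterbi_mat_cpp: dense per-position log-emission matrix (small models,
//    oracle tests).
//  - viterbi_track_cpp: emissions computed on the fly from the joint
//    depth (Poisson) + mate-pair distance model, so a chromosome-length
//    decode never materialises an S x T matrix.

struct SparseTrans {
    // incoming edges per destination state
    std::vector<std::vector<int> > pred;
    std::vector<std::vector<double> > logp;
};

static SparseTrans sparsify(const NumericMatrix &logT) {
    int S = logT.nrow();
    SparseTrans st;
    st.pred.resize(S);
    st.logp.resize(S);
    for (int j = 0; j < S; ++j) {
        for (int i = 0; i < S; ++i) {
            double v = logT(i, j);
            if (v > R_NegInf) {
                st.pred[j].push_back(i);
                st.logp[j].push_back(v);
            }
        }
    }
    return st;
}

// core DP step: given prev scores, fill cur scores and backpointers
static inline void step(const std::vector<double> &prev,
                        std::vector<double> &cur,
                        uint8_t *bp,
                        const SparseTrans &st,
                        const double *emis, int S) {
    for (int j = 0; j < S; ++j) {
        double best = R_NegInf;
        int arg = 0;
        const std::vector<int> &pr = st.pred[j];
        const std::vector<double> &lp = st.logp[j];
        for (size_t k = 0; k < pr.size(); ++k) {
            double v = prev[pr[k]] + lp[k];
            if (v > best) { best = v; arg = pr[k]; }
        }
        cur[j] = best + emis[j];
        bp[j] = (uint8_t) arg;
    }
}

static List traceback(const std::vector<double> &last,
                      const std::vector<uint8_t> &bp, int S, int T) {
    double best = R_NegInf;
    int arg = 0;
    for (int j = 0; j < S; ++j)
        if (last[j] > best) { best = last[j]; arg = j; }
    IntegerVector path(T);
    int cur = arg;
    for (int t = T - 1; t >= 0; --t) {
        path[t] = cur + 1;  // 1-based state index for R
        if (t > 0) cur = bp[(size_t)(t) * S + cur];
    }
    return List::create(_["path"] = path, _["loglik"] = best);
}

// [[Rcpp::export]]
List viterbi_mat_cpp(NumericMatrix logE, NumericMatrix logT,
                     NumericVector logInit) {
    int S = logE.nrow(), T = logE.ncol();
    if (S > 255) stop("more than 255 states not supported");
    if (T == 0)
        return List::create(_["path"] = IntegerVector(0),
                            _["loglik"] = 0.0);
    SparseTrans st = sparsify(logT);
    std::vector<double> prev(S), cur(S);
    std::vector<uint8_t> bp((size_t) T * S, 0);
    for (int j = 0; j < S; ++j) prev[j] = logInit[j] + logE(j, 0);
    std::vector<double> ecol(S);
    for (int t = 1; t < T; ++t) {
        for (int j = 0; j < S; ++j) ecol[j] = logE(j, t);
        step(prev, cur, &bp[(size_t) t * S], st, ecol.data(), S);
        std::swap(prev, cur);
    }
    return traceback(prev, bp, S, T);
}

// Emissions for the chromosome-scale decode.
//
//  depth term:    log Poisson(n_t ; mu) with mu = max((C/2) lambda G_t,
//                 eps_frac * lambda * G_t)  (the floor keeps the
//                 copy-0 state finite under mismapped reads)
//  distance term: sum over outer-distances d attached at t of
//                 log p_state(d), precomputed per state in logPd
//                 (rows = distance 1..cutoff, cols = states)
//  masked positions (reference N runs) emit 0 for every state.
//
// gbin maps each position to one of a small number of GC adjustment
// levels gvals (so Poisson log-pmf terms are table lookups).
// [[Rcpp::export]]
List viterbi_track_cpp(IntegerVector n, IntegerVector gbin,
                       NumericVector gvals, LogicalVector mask,
                       IntegerVector dist_pos, IntegerVector dist_val,
                       NumericMatrix logPd, NumericVector stateC,
                       double lambda, double eps_frac,
                       NumericMatrix logT, NumericVector logInit) {
    int T = n.size();
    int S = stateC.size();
    int B = gvals.size();
    int cutoff = logPd.nrow();
    if (S > 255) stop("more than 255 states not supported");
    if (T == 0)
        return List::create(_["path"] = IntegerVector(0),
                            _["loglik"] = 0.0);

    // Poisson log-pmf lookup: [state][bin][n], n capped; larger n computed
    // directly (rare at low-pass depth).
    int nmax = 0;
    for (int t = 0; t < T; ++t) if (n[t] > nmax) nmax = n[t];
    int ncap = nmax < 64 ? nmax : 64;
    std::vector<double> mu((size_t) S * B), logmu((size_t) S * B);
    for (int s = 0; s < S; ++s)
        for (int b = 0; b < B; ++b) {
            double m = 0.5 * stateC[s] * lambda * gvals[b];
            double floorm = eps_frac * lambda * gvals[b];
            if (m < floorm) m = floorm;
            mu[(size_t) s * B + b] = m;
            logmu[(size_t) s * B + b] = std::log(m);
        }
    std::vector<double> ptab((size_t) S * B * (ncap + 1));
    for (int s = 0; s < S; ++s)
        for (int b = 0; b < B; ++b) {
            double m = mu[(size_t) s * B + b], lm = logmu[(size_t) s * B + b];
            for (int k = 0; k <= ncap; ++k)
                ptab[((size_t) s * B + b) * (ncap + 1) + k] =
                    -m + k * lm - std::lgamma((double) k + 1.0);
        }

    SparseTrans st = sparsify(logT);
    std::vector<double> prev(S), cur(S), emis(S);
    std::vector<uint8_t> bp((size_t) T * S, 0);

    int nd = dist_pos.size();
    int di = 0;  // cursor over distance records (sorted by position)

    for (int t = 0; t < T; ++t) {
        // emission vector at position t (0-based; dist_pos is 1-based)
        if (mask[t]) {
            for (int j = 0; j < S; ++j) emis[j] = 0.0;
            while (di < nd && dist_pos[di] == t + 1) ++di;
        } else {
            int b = gbin[t], k = n[t];
            if (k <= ncap) {
                for (int j = 0; j < S; ++j)
                    emis[j] = ptab[((size_t) j * B + b) * (ncap + 1) + k];
            } else {
                for (int j = 0; j < S; ++j) {
                    double m = mu[(size_t) j * B + b];
                    emis[j] = -m + k * logmu[(size_t) j * B + b] -
                              std::lgamma((double) k + 1.0);
                }
            }
            while (di < nd && dist_pos[di] == t + 1) {
                int d = dist_val[di];
                if (d >= 1 && d <= cutoff)
                    for (int j = 0; j < S; ++j) emis[j] += logPd(d - 1, j);
                ++di;
            }
        }
        if (t == 0) {
            for (int j = 0; j < S; ++j) prev[j] = logInit[j] + emis[j];
        } else {
            step(prev, cur, &bp[(size_t) t * S], st, emis.data(), S);
            std::swap(prev, cur);
        }
    }
    return traceback(prev, bp, S, T);
}
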