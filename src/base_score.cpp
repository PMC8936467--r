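#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Signed maximum deviation of f - b over the ranked profile, where
//   f(i) = sum_{k<=i} g_k w_k / sum_k g_k w_k
//   b(i) = sum_{k<=i} g_k (1 - w_k) / sum_k g_k (1 - w_k)
// g is taken in the order induced by perm (perm[k] = index into g for rank k)
// while the weights stay attached to the ranks.
static double maxDev(const NumericVector& g, const NumericVector& w,
                     const int* perm) {
    const int n = g.size();
    double s1 = 0.0, s0 = 0.0;
    for (int k = 0; k < n; ++k) {
        const double gk = perm ? g[perm[k]] : g[k];
        s1 += gk * w[k];
        s0 += gk * (1.0 - w[k]);
    }
    if (s1 <= 0.0 || s0 <= 0.0) return 0.0;
    double cf = 0.0, cb = 0.0, best = 0.0, bestAbs = 0.0;
    for (int k = 0; k < n; ++k) {
        const double gk = perm ? g[perm[k]] : g[k];
        cf += gk * w[k] / s1;
        cb += gk * (1.0 - w[k]) / s0;
        const double d = cf - cb;
        const double a = d < 0 ? -d : d;
        if (a > bestAbs) { bestAbs = a; best = d; }
    }
    return best;
}

// [[Rcpp::export]]
double cppBaseDev(NumericVector g, NumericVector w) {
    return maxDev(g, w, nullptr);
}

// 1-based random permutations of 1..n, one per column (mt19937 Fisher-Yates)
// [[Rcpp::export]]
IntegerMatrix cppGenPerms(int n, int nPerm, int seed) {
    IntegerMatrix out(n, nPerm);
    std::mt19937 gen(static_cast<unsigned int>(seed));
    std::vector<int> idx(n);
    for (int p = 0; p < nPerm; ++p) {
        for (int k = 0; k < n; ++k) idx[k] = k;
        for (int k = n - 1; k > 0; --k) {
            const int j = static_cast<int>(gen() % (k + 1));
            std::swap(idx[k], idx[j]);
        }
        for (int k = 0; k < n; ++k) out(k, p) = idx[k] + 1;
    }
    return out;
}

// Permutation null deviations for the wPlus and wMinus vectors, sharing one
// shuffled ordering of g per iteration. If `perms` has nrow == length(g) its
// columns are used as 1-based permutations (shared-stream testing);
// otherwise permutations are generated internally from `seed` (mt19937
// Fisher-Yates). Both weight vectors are accumulated in the same two passes;
// the background cumulative sum is the total minus the foreground one.
// [[Rcpp::export]]
NumericMatrix cppBaseNull(NumericVector g, NumericVector wplus,
                          NumericVector wminus, int nPerm, int seed,
                          IntegerMatrix perms) {
    const int n = g.size();
    const bool given = perms.nrow() == n;
    const int P = given ? perms.ncol() : nPerm;
    NumericMatrix out(P, 2);
    std::vector<int> idx(n);
    std::vector<double> gp(n);
    double sumG = 0.0;
    for (int k = 0; k < n; ++k) sumG += g[k];
    std::mt19937 gen(static_cast<unsigned int>(seed));
    for (int p = 0; p < P; ++p) {
        if (given) {
            for (int k = 0; k < n; ++k) gp[k] = g[perms(k, p) - 1];
        } else {
            for (int k = 0; k < n; ++k) idx[k] = k;
            for (int k = n - 1; k > 0; --k) {
                const int j = static_cast<int>(gen() % (k + 1));
                std::swap(idx[k], idx[j]);
            }
            for (int k = 0; k < n; ++k) gp[k] = g[idx[k]];
        }
        double s1p = 0.0, s1m = 0.0;
        for (int k = 0; k < n; ++k) {
            s1p += gp[k] * wplus[k];
            s1m += gp[k] * wminus[k];
        }
        const double s0p = sumG - s1p, s0m = sumG - s1m;
        const bool doP = s1p > 0.0 && s0p > 0.0;
        const bool doM = s1m > 0.0 && s0m > 0.0;
        double cg = 0.0, cp = 0.0, cm = 0.0;
        double bestP = 0.0, bestPa = 0.0, bestM = 0.0, bestMa = 0.0;
        for (int k = 0; k < n; ++k) {
            const double gk = gp[k];
            cg += gk;
            if (doP) {
                cp += gk * wplus[k];
                const double d = cp / s1p - (cg - cp) / s0p;
                const double a = d < 0 ? -d : d;
                if (a > bestPa) { bestPa = a; bestP = d; }
            }
            if (doM) {
                cm += gk * wminus[k];
                const double d = cm / s1m - (cg - cm) / s0m;
                const double a = d < 0 ? -d : d;
                if (a > bestMa) { bestMa = a; bestM = d; }
            }
        }
        out(p, 0) = doP ? bestP : 0.0;
        out(p, 1) = doM ? bestM : 0.0;
    }
    return out;
}
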