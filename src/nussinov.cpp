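#include <Rcpp.h>
using namespace Rcpp;

// Weighted base-pair maximisation (Nussinov-style) with a minimum hairpin
// loop constraint.  Bases are encoded 0=A, 1=C, 2=G, 3=T.  Pair weights:
// G-C, A-T, G-T; all other pairs score 0 and are disallowed.

static inline double pairWeight(int a, int b, double wGC, double wAU, double wGU) {
    if ((a == 2 && b == 1) || (a == 1 && b == 2)) return wGC;
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return wAU;
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return wGU;
    return 0.0;
}

static int traceback(const std::vector<std::vector<double> >& M,
                     const IntegerVector& s, int i, int j, int minLoop,
                     double wGC, double wAU, double wGU) {
    if (j - i <= minLoop) return 0;
    if (M[i][j] == M[i + 1][j])
        return traceback(M, s, i + 1, j, minLoop, wGC, wAU, wGU);
    for (int k = i + minLoop + 1; k <= j; ++k) {
        double w = pairWeight(s[i], s[k], wGC, wAU, wGU);
        if (w <= 0) continue;
        double left = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0.0;
        double right = (k + 1 <= j) ? M[k + 1][j] : 0.0;
        if (M[i][j] == w + left + right)
            return 1 + traceback(M, s, i + 1, k - 1, minLoop, wGC, wAU, wGU)
                     + (k + 1 <= j ? traceback(M, s, k + 1, j, minLoop, wGC, wAU, wGU) : 0);
    }
    return traceback(M, s, i + 1, j, minLoop, wGC, wAU, wGU); // numeric fallback
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(IntegerVector seq, int minLoop, double wGC, double wAU, double wGU) {
    int n = seq.size();
    if (n == 0) return List::create(_["weight"] = 0.0, _["n_bp"] = 0);
    std::vector<std::vector<double> > M(n, std::vector<double>(n, 0.0));
    for (int len = minLoop + 1; len < n; ++len) {
        for (int i = 0; i + len < n; ++i) {
            int j = i + len;
            double best = M[i + 1][j];
            for (int k = i + minLoop + 1; k <= j; ++k) {
                double w = pairWeight(seq[i], seq[k], wGC, wAU, wGU);
                if (w <= 0) continue;
                double left = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0.0;
                double right = (k + 1 <= j) ? M[k + 1][j] : 0.0;
                double cand = w + left + right;
                if (cand > best) best = cand;
            }
            M[i][j] = best;
        }
    }
    int nbp = traceback(M, seq, 0, n - 1, minLoop, wGC, wAU, wGU);
    return List::create(_["weight"] = M[0][n - 1], _["n_bp"] = nbp);
}
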