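#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Mutation kernels on internal integer codes.
// STR codes are repeat counts in tenths (9.3 -> 93) so a one-repeat step is
// exactly 10; non-unit steps have probability zero. POLY codes are negative
// integers; bc maps -code-1 to a base class (0=A, 1=G, 2=C, 3=T, 4=other),
// transitions (A<->G, C<->T) carry 9/10 of the mutation rate, everything
// else 1/10. A missing allele on either side contributes factor 1 (the
// marker carries no mutation information, recombination still chains).
static inline bool is_transition(int ca, int cb) {
    return (ca == 0 && cb == 1) || (ca == 1 && cb == 0) ||
           (ca == 2 && cb == 3) || (ca == 3 && cb == 2);
}

static inline double pstar(int a, int b, double mu, int type,
                           const std::vector<int>& bc) {
    if (a == NA_INTEGER || b == NA_INTEGER) return 1.0;
    if (a == b) return 1.0 - mu;
    if (type == 0) {
        int d = a - b;
        if (d < 0) d = -d;
        return d == 10 ? mu : 0.0;
    }
    int ca = bc[-a - 1], cb = bc[-b - 1];
    return is_transition(ca, cb) ? 0.9 * mu : 0.1 * mu;
}

static std::vector< std::vector<int> > unpack_bclass(const List& bclass) {
    std::vector< std::vector<int> > out(bclass.size());
    for (R_xlen_t j = 0; j < bclass.size(); ++j) {
        IntegerVector v = bclass[j];
        out[j].assign(v.begin(), v.end());
    }
    return out;
}

// Forward (dynamic-programming) pass over one child's maternal haplotype.
// State s in {1,2} tracks which maternal haplotype marker i descends from;
// per-marker rescaling keeps the pass in linear space while the log of the
// scale factors accumulates, so 10,000-marker likelihoods neither underflow
// nor overflow. Returns the log-likelihood (-Inf when incompatible).
static double child_forward(const int* c, const int* m1, const int* m2,
                            int n, const NumericVector& theta,
                            const NumericVector& mu,
                            const IntegerVector& type,
                            const std::vector< std::vector<int> >& bc) {
    double f1 = pstar(m1[0], c[0], mu[0], type[0], bc[0]);
    double f2 = pstar(m2[0], c[0], mu[0], type[0], bc[0]);
    double s = f1 + f2;
    if (s <= 0.0) return R_NegInf;
    double ll = std::log(s);
    f1 /= s; f2 /= s;
    for (int i = 1; i < n; ++i) {
        double th = theta[i - 1];
        double e1 = pstar(m1[i], c[i], mu[i], type[i], bc[i]);
        double e2 = pstar(m2[i], c[i], mu[i], type[i], bc[i]);
        double g1 = e1 * (f1 * (1.0 - th) + f2 * th);
        double g2 = e2 * (f2 * (1.0 - th) + f1 * th);
        s = g1 + g2;
        if (s <= 0.0) return R_NegInf;
        ll += std::log(s);
        f1 = g1 / s; f2 = g2 / s;
    }
    return ll;
}

// [[Rcpp::export]]
double cpp_child_loglik(IntegerVector child, IntegerVector m1,
                        IntegerVector m2, NumericVector theta,
                        NumericVector mu, IntegerVector type, List bclass) {
    int n = child.size();
    if (m1.size() != n || m2.size() != n || mu.size() != n ||
        theta.size() != n - 1 || type.size() != n) {
        stop("length mismatch in likelihood inputs");
    }
    std::vector< std::vector<int> > bc = unpack_bclass(bclass);
    return child_forward(&child[0], &m1[0], &m2[0], n, theta, mu, type, bc);
}

// [[Rcpp::export]]
double cpp_typeI_loglik(IntegerMatrix children, IntegerVector m1,
                        IntegerVector m2, NumericVector theta,
                        NumericVector mu, IntegerVector type, List bclass) {
    int n = m1.size(), k = children.nrow();
    if (children.ncol() != n) stop("length mismatch in likelihood inputs");
    std::vector< std::vector<int> > bc = unpack_bclass(bclass);
    std::vector<int> row(n);
    double ll = 0.0;
    for (int j = 0; j < k; ++j) {
        for (int i = 0; i < n; ++i) row[i] = children(j, i);
        double l = child_forward(row.data(), &m1[0], &m2[0], n,
                                 theta, mu, type, bc);
        if (!R_FINITE(l)) return R_NegInf;
        ll += l;
    }
    return ll;
}

// Type II: sum over the 2^(h-1) maternal phasings (phase anchored at the
// first heterozygous marker) of the type I likelihood, by depth-first
// branching over heterozygous markers. All children share the partial
// forward states of a branch, and a branch is pruned as soon as any child's
// forward vector is identically zero (its family product is zero for every
// phasing extending the branch). Streaming log-sum-exp accumulates the
// per-branch log-likelihoods.
struct Type2DFS {
    const IntegerMatrix& ch;
    const IntegerVector& g1, &g2;
    const NumericVector& theta, &mu;
    const IntegerVector& type;
    const std::vector< std::vector<int> >& bc;
    int n, k;
    bool seen_het;
    double lse_max, lse_sum;

    Type2DFS(const IntegerMatrix& ch_, const IntegerVector& g1_,
             const IntegerVector& g2_, const NumericVector& th_,
             const NumericVector& mu_, const IntegerVector& ty_,
             const std::vector< std::vector<int> >& bc_)
        : ch(ch_), g1(g1_), g2(g2_), theta(th_), mu(mu_), type(ty_),
          bc(bc_), n(g1_.size()), k(ch_.nrow()), seen_het(false),
          lse_max(R_NegInf), lse_sum(0.0) {}

    void add_branch(double ll) {
        if (ll == R_NegInf) return;
        if (ll > lse_max) {
            lse_sum = lse_sum * std::exp(lse_max - ll) + 1.0;
            lse_max = ll;
        } else {
            lse_sum += std::exp(ll - lse_max);
        }
    }

    // f holds (f1, f2) per child; logsc is the summed log scale over children
    void step(int i, std::vector<double> f, double logsc, int a, int b) {
        for (int j = 0; j < k; ++j) {
            int c = ch(j, i);
            double e1 = pstar(a, c, mu[i], type[i], bc[i]);
            double e2 = pstar(b, c, mu[i], type[i], bc[i]);
            double nf1, nf2;
            if (i == 0) {
                nf1 = e1; nf2 = e2;
            } else {
                double th = theta[i - 1];
                nf1 = e1 * (f[2 * j] * (1.0 - th) + f[2 * j + 1] * th);
                nf2 = e2 * (f[2 * j + 1] * (1.0 - th) + f[2 * j] * th);
            }
            double s = nf1 + nf2;
            if (s <= 0.0) return;  // prune: this child kills the branch
            logsc += std::log(s);
            f[2 * j] = nf1 / s;
            f[2 * j + 1] = nf2 / s;
        }
        descend(i + 1, f, logsc);
    }

    void descend(int i, const std::vector<double>& f, double logsc) {
        if (i == n) { add_branch(logsc); return; }
        bool het = (g1[i] != NA_INTEGER) && (g2[i] != NA_INTEGER) &&
                   (g1[i] != g2[i]);
        if (!het) {
            step(i, f, logsc, g1[i], g2[i]);
        } else if (!seen_het) {
            // anchor the phase at the first heterozygous marker: the two
            // orderings are haplotype relabelings of each other and Eq-style
            // summation is over unordered phasings, so only one is taken
            seen_het = true;
            step(i, f, logsc, g1[i], g2[i]);
            seen_het = false;
        } else {
            step(i, f, logsc, g1[i], g2[i]);
            step(i, f, logsc, g2[i], g1[i]);
        }
    }
};

// [[Rcpp::export]]
double cpp_typeII_loglik(IntegerMatrix children, IntegerVector g1,
                         IntegerVector g2, NumericVector theta,
                         NumericVector mu, IntegerVector type, List bclass) {
    int n = g1.size();
    if (children.ncol() != n || g2.size() != n || mu.size() != n ||
        theta.size() != n - 1 || type.size() != n) {
        stop("length mismatch in likelihood inputs");
    }
    std::vector< std::vector<int> > bc = unpack_bclass(bclass);
    Type2DFS dfs(children, g1, g2, theta, mu, type, bc);
    std::vector<double> f(2 * children.nrow(), 1.0);
    dfs.descend(0, f, 0.0);
    if (dfs.lse_max == R_NegInf) return R_NegInf;
    return dfs.lse_max + std::log(dfs.lse_sum);
}
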