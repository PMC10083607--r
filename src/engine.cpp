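#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Population state as parallel vectors; `type` is a 0-based index into the
// per-type parameter vectors (at most two competing types in practice, but the
// engine is agnostic).
struct Pop {
    std::vector<double> B;
    std::vector<int> mA;
    std::vector<int> mN;
    std::vector<int> type;
    size_t size() const { return B.size(); }
};

struct TypeParams {
    std::vector<double> p0, dE, Etr, nu;
    std::vector<int> divmode; // 1 symmetric, 2 random, 3 ge_random, 4 ge_binomial, 5 ge_symmetric
};

struct GeParams {
    double rA, rN, dA, dN, Ec;
    int K;
    int mut_class; // 0 autonomous, 1 nonautonomous
};

// li = floor(B / Ec), the number of replication events the cell's balance can
// still pay for; 0 below one unit of cost. The small epsilon guards against
// binary round-off in B after repeated +-Ec updates.
static inline long capacity_li(double B, double Ec) {
    if (B < Ec) return 0;
    return (long)std::floor(B / Ec + 1e-9);
}

static inline void propensities(int mA, int mN, long li,
                                const GeParams& g, double* k) {
    k[0] = g.rA * (double)li * (double)mA * (double)(mA - 1) / 2.0;
    k[1] = g.rN * (double)mN * (double)mA * (double)li;
    k[2] = g.dA * (double)mA;
    k[3] = g.dN * (double)mN;
}

// One propensity-sampled elementary event (waiting times are not tracked:
// exactly one event per call, a zero-total-propensity draw is a no-op).
static inline void ge_event(double& B, int& mA, int& mN, const GeParams& g) {
    double k[4];
    long li = capacity_li(B, g.Ec);
    propensities(mA, mN, li, g, k);
    double tot = k[0] + k[1] + k[2] + k[3];
    if (tot <= 0.0) return;
    double eps = unif_rand() * tot;
    if (eps <= k[0])                  { mA += 1; B -= g.Ec; }
    else if (eps <= k[0] + k[1])      { mN += 1; B -= g.Ec; }
    else if (eps <= k[0] + k[1] + k[2]) { mA -= 1; }
    else                              { mN -= 1; }
}

static inline void ge_round(double& B, int& mA, int& mN, const GeParams& g) {
    for (int e = 0; e < g.K; ++e) ge_event(B, mA, mN, g);
}

// Successful-reproduction probability: p0 scaled by one plus the mutualist
// fraction, capped at 1; bare p0 for cells without genetic elements.
static inline double repro_prob(int mA, int mN, double p0, int mut_class) {
    int tot = mA + mN;
    if (tot == 0) return p0;
    double mut = (mut_class == 0) ? (double)mA : (double)mN;
    double p = p0 * (1.0 + mut / (double)tot);
    return (p > 1.0) ? 1.0 : p;
}

static inline int unif_int(int m) { // discrete Uniform{0, ..., m}
    int x = (int)(unif_rand() * (double)(m + 1));
    return (x > m) ? m : x;
}

// Division of a mother into two daughters. Resources and element counts are
// conserved exactly in every mode. A genetic-element mode applied to a cell
// that currently has no elements falls back to the plain resource split of the
// matching style (uniform for ge_random/ge_binomial, halving for ge_symmetric).
static inline void divide_cell(double B, int mA, int mN, int mode,
                               double& B1, double& B2,
                               int& mA1, int& mA2, int& mN1, int& mN2) {
    int tot = mA + mN;
    if (tot == 0) {
        mA1 = mA2 = mN1 = mN2 = 0;
        if (mode == 1 || mode == 5) { B1 = B / 2.0; }
        else                        { B1 = unif_rand() * B; }
        B2 = B - B1;
        return;
    }
    if (mode == 1) mode = 5; // plain modes on element-carrying cells map to
    if (mode == 2) mode = 3; // their element-aware counterparts
    if (mode == 3) {               // uniform counts, proportional resources
        mA1 = unif_int(mA);
        mN1 = unif_int(mN);
        B1 = B * (double)(mA1 + mN1) / (double)tot;
    } else if (mode == 4) {        // uniform resources, binomial counts
        B1 = unif_rand() * B;
        double p = B1 / B;
        mA1 = (int)R::rbinom((double)mA, p);
        mN1 = (int)R::rbinom((double)mN, p);
    } else {                       // symmetric: halved counts, proportional B
        mA1 = mA / 2;
        mN1 = mN / 2;
        B1 = B * (double)(mA1 + mN1) / (double)tot;
    }
    mA2 = mA - mA1;
    mN2 = mN - mN1;
    B2 = B - B1;
}

// ---- round phases ----------------------------------------------------------

// Feeding: each cell may acquire at most one resource unit per round; when the
// population exceeds the supply R, the R fed cells are a uniform random subset
// (random permutation, first R in permuted order). Leftover supply is
// discarded. Returns the fed indicator for introspection.
static std::vector<char> feed_phase(Pop& pop, int R) {
    size_t n = pop.size();
    std::vector<char> fed(n, 0);
    if (n == 0) return fed;
    if ((int)n <= R) {
        for (size_t i = 0; i < n; ++i) { pop.B[i] += 1.0; fed[i] = 1; }
        return fed;
    }
    std::vector<int> idx(n);
    for (size_t i = 0; i < n; ++i) idx[i] = (int)i;
    for (int i = 0; i < R; ++i) { // partial Fisher-Yates
        int j = i + (int)(unif_rand() * (double)(n - i));
        if (j > (int)n - 1) j = (int)n - 1;
        std::swap(idx[i], idx[j]);
        pop.B[idx[i]] += 1.0;
        fed[idx[i]] = 1;
    }
    return fed;
}

// Housekeeping: every cell pays its type's cost; a cell whose balance is no
// longer positive is removed.
static void housekeep_phase(Pop& pop, const TypeParams& tp) {
    size_t keep = 0;
    for (size_t i = 0; i < pop.size(); ++i) {
        double b = pop.B[i] - tp.dE[pop.type[i]];
        if (b > 0.0) {
            pop.B[keep] = b;
            pop.mA[keep] = pop.mA[i];
            pop.mN[keep] = pop.mN[i];
            pop.type[keep] = pop.type[i];
            ++keep;
        }
    }
    pop.B.resize(keep); pop.mA.resize(keep);
    pop.mN.resize(keep); pop.type.resize(keep);
}

static void ge_phase(Pop& pop, const GeParams& g) {
    for (size_t i = 0; i < pop.size(); ++i) {
        if (pop.mA[i] + pop.mN[i] > 0)
            ge_round(pop.B[i], pop.mA[i], pop.mN[i], g);
    }
}

// Reproduction: every cell at or above its threshold attempts division once;
// on success it is replaced by two daughters (which first act next round), on
// failure it dies with all its contents.
static void reproduction_phase(Pop& pop, const TypeParams& tp,
                               const GeParams* g) {
    int mut_class = g ? g->mut_class : 0;
    Pop next;
    next.B.reserve(pop.size() * 2);
    next.mA.reserve(pop.size() * 2);
    next.mN.reserve(pop.size() * 2);
    next.type.reserve(pop.size() * 2);
    for (size_t i = 0; i < pop.size(); ++i) {
        int ty = pop.type[i];
        if (pop.B[i] < tp.Etr[ty]) {
            next.B.push_back(pop.B[i]); next.mA.push_back(pop.mA[i]);
            next.mN.push_back(pop.mN[i]); next.type.push_back(ty);
            continue;
        }
        double p = repro_prob(pop.mA[i], pop.mN[i], tp.p0[ty], mut_class);
        if (unif_rand() < p) {
            double B1, B2; int mA1, mA2, mN1, mN2;
            divide_cell(pop.B[i], pop.mA[i], pop.mN[i], tp.divmode[ty],
                        B1, B2, mA1, mA2, mN1, mN2);
            next.B.push_back(B1); next.mA.push_back(mA1);
            next.mN.push_back(mN1); next.type.push_back(ty);
            next.B.push_back(B2); next.mA.push_back(mA2);
            next.mN.push_back(mN2); next.type.push_back(ty);
        }
        // failed reproduction: mother removed, nothing pushed
    }
    pop = next;
}

// Stochastic death applies to every cell present after reproduction,
// daughters included.
static void death_phase(Pop& pop, const TypeParams& tp) {
    bool any = false;
    for (size_t t = 0; t < tp.nu.size(); ++t) if (tp.nu[t] > 0.0) any = true;
    if (!any) return;
    size_t keep = 0;
    for (size_t i = 0; i < pop.size(); ++i) {
        double nu = tp.nu[pop.type[i]];
        bool dies = (nu > 0.0) && (unif_rand() < nu);
        if (!dies) {
            pop.B[keep] = pop.B[i]; pop.mA[keep] = pop.mA[i];
            pop.mN[keep] = pop.mN[i]; pop.type[keep] = pop.type[i];
            ++keep;
        }
    }
    pop.B.resize(keep); pop.mA.resize(keep);
    pop.mN.resize(keep); pop.type.resize(keep);
}

static void one_round(Pop& pop, const TypeParams& tp, const GeParams* g,
                      int R) {
    feed_phase(pop, R);
    housekeep_phase(pop, tp);
    if (g) ge_phase(pop, *g);
    reproduction_phase(pop, tp, g);
    death_phase(pop, tp);
}

// ---- conversion helpers ----------------------------------------------------

static Pop as_pop(NumericVector B, IntegerVector mA, IntegerVector mN,
                  IntegerVector type) {
    Pop p;
    size_t n = B.size();
    p.B.assign(B.begin(), B.end());
    p.mA.assign(mA.begin(), mA.end());
    p.mN.assign(mN.begin(), mN.end());
    p.type.resize(n);
    for (size_t i = 0; i < n; ++i) p.type[i] = type[i] - 1; // to 0-based
    return p;
}

static List pop_to_list(const Pop& p) {
    size_t n = p.size();
    IntegerVector type(n);
    for (size_t i = 0; i < n; ++i) type[i] = p.type[i] + 1;
    return List::create(_["B"] = NumericVector(p.B.begin(), p.B.end()),
                        _["mA"] = IntegerVector(p.mA.begin(), p.mA.end()),
                        _["mN"] = IntegerVector(p.mN.begin(), p.mN.end()),
                        _["type"] = type);
}

static TypeParams as_type_params(NumericVector p0, NumericVector dE,
                                 NumericVector Etr, NumericVector nu,
                                 IntegerVector divmode) {
    TypeParams tp;
    tp.p0.assign(p0.begin(), p0.end());
    tp.dE.assign(dE.begin(), dE.end());
    tp.Etr.assign(Etr.begin(), Etr.end());
    tp.nu.assign(nu.begin(), nu.end());
    tp.divmode.assign(divmode.begin(), divmode.end());
    return tp;
}

static GeParams as_ge_params(List g) {
    GeParams gp;
    gp.rA = as<double>(g["rA"]); gp.rN = as<double>(g["rN"]);
    gp.dA = as<double>(g["dA"]); gp.dN = as<double>(g["dN"]);
    gp.Ec = as<double>(g["Ec"]); gp.K = as<int>(g["K"]);
    gp.mut_class = as<int>(g["mut_class"]);
    return gp;
}

static void summarise(const Pop& pop, int n_types, int round, double* row) {
    // columns: round, n1, meanB1, n2, meanB2, ng, no, sum_mA, sum_mN
    double nT[2] = {0, 0}, sB[2] = {0, 0};
    double ng = 0, no = 0, smA = 0, smN = 0;
    for (size_t i = 0; i < pop.size(); ++i) {
        int t = pop.type[i];
        nT[t] += 1; sB[t] += pop.B[i];
        if (pop.mA[i] + pop.mN[i] > 0) ng += 1; else no += 1;
        smA += pop.mA[i]; smN += pop.mN[i];
    }
    row[0] = round;
    row[1] = nT[0];
    row[2] = nT[0] > 0 ? sB[0] / nT[0] : NA_REAL;
    row[3] = n_types > 1 ? nT[1] : NA_REAL;
    row[4] = (n_types > 1 && nT[1] > 0) ? sB[1] / nT[1] : NA_REAL;
    row[5] = ng; row[6] = no; row[7] = smA; row[8] = smN;
}

// ---- exported wrappers -----------------------------------------------------

// [[Rcpp::export]]
List cpp_feed_round(NumericVector B, IntegerVector mA, IntegerVector mN,
                    IntegerVector type, int R) {
    Pop pop = as_pop(B, mA, mN, type);
    std::vector<char> fed = feed_phase(pop, R);
    List out = pop_to_list(pop);
    LogicalVector f(fed.size());
    for (size_t i = 0; i < fed.size(); ++i) f[i] = fed[i] != 0;
    out["fed"] = f;
    return out;
}

// [[Rcpp::export]]
List cpp_housekeep_round(NumericVector B, IntegerVector mA, IntegerVector mN,
                         IntegerVector type, NumericVector p0, NumericVector dE,
                         NumericVector Etr, NumericVector nu,
                         IntegerVector divmode) {
    Pop pop = as_pop(B, mA, mN, type);
    TypeParams tp = as_type_params(p0, dE, Etr, nu, divmode);
    housekeep_phase(pop, tp);
    return pop_to_list(pop);
}

// [[Rcpp::export]]
List cpp_ge_round(double B, int mA, int mN, List ge, int n_events) {
    GeParams g = as_ge_params(ge);
    g.K = n_events;
    ge_round(B, mA, mN, g);
    return List::create(_["B"] = B, _["mA"] = mA, _["mN"] = mN);
}

// [[Rcpp::export]]
List cpp_ge_event(double B, int mA, int mN, List ge) {
    GeParams g = as_ge_params(ge);
    ge_event(B, mA, mN, g);
    return List::create(_["B"] = B, _["mA"] = mA, _["mN"] = mN);
}

// [[Rcpp::export]]
NumericVector cpp_propensities(int mA, int mN, double li, List ge) {
    GeParams g = as_ge_params(ge);
    double k[4];
    propensities(mA, mN, (long)li, g, k);
    return NumericVector::create(k[0], k[1], k[2], k[3]);
}

// [[Rcpp::export]]
double cpp_capacity(double B, double Ec) {
    return (double)capacity_li(B, Ec);
}

// [[Rcpp::export]]
double cpp_repro_prob(int mA, int mN, double p0, int mut_class) {
    return repro_prob(mA, mN, p0, mut_class);
}

// [[Rcpp::export]]
List cpp_divide(double B, int mA, int mN, int mode) {
    double B1, B2; int mA1, mA2, mN1, mN2;
    divide_cell(B, mA, mN, mode, B1, B2, mA1, mA2, mN1, mN2);
    return List::create(_["B1"] = B1, _["B2"] = B2,
                        _["mA1"] = mA1, _["mA2"] = mA2,
                        _["mN1"] = mN1, _["mN2"] = mN2);
}

// [[Rcpp::export]]
List cpp_ge_phase_round(NumericVector B, IntegerVector mA, IntegerVector mN,
                        IntegerVector type, List ge) {
    Pop pop = as_pop(B, mA, mN, type);
    GeParams g = as_ge_params(ge);
    ge_phase(pop, g);
    return pop_to_list(pop);
}

// [[Rcpp::export]]
List cpp_reproduction_round(NumericVector B, IntegerVector mA,
                            IntegerVector mN, IntegerVector type,
                            NumericVector p0, NumericVector dE,
                            NumericVector Etr, NumericVector nu,
                            IntegerVector divmode, Nullable<List> ge) {
    Pop pop = as_pop(B, mA, mN, type);
    TypeParams tp = as_type_params(p0, dE, Etr, nu, divmode);
    GeParams g;
    const GeParams* gp = 0;
    if (ge.isNotNull()) { g = as_ge_params(ge.get()); gp = &g; }
    reproduction_phase(pop, tp, gp);
    return pop_to_list(pop);
}

// [[Rcpp::export]]
List cpp_death_round(NumericVector B, IntegerVector mA, IntegerVector mN,
                     IntegerVector type, NumericVector p0, NumericVector dE,
                     NumericVector Etr, NumericVector nu,
                     IntegerVector divmode) {
    Pop pop = as_pop(B, mA, mN, type);
    TypeParams tp = as_type_params(p0, dE, Etr, nu, divmode);
    death_phase(pop, tp);
    return pop_to_list(pop);
}

// Full multi-round run: same phase functions as the stepwise wrappers, looped
// in C++, with a per-round summary matrix. `record_every` thins the summary;
// the final round is always recorded.
// [[Rcpp::export]]
List cpp_run(NumericVector B, IntegerVector mA, IntegerVector mN,
             IntegerVector type, int n_types, int R, int rounds,
             NumericVector p0, NumericVector dE, NumericVector Etr,
             NumericVector nu, IntegerVector divmode, Nullable<List> ge,
             int record_every) {
    Pop pop = as_pop(B, mA, mN, type);
    TypeParams tp = as_type_params(p0, dE, Etr, nu, divmode);
    GeParams g;
    const GeParams* gp = 0;
    if (ge.isNotNull()) { g = as_ge_params(ge.get()); gp = &g; }

    int nrec = 0;
    for (int t = 1; t <= rounds; ++t)
        if (t % record_every == 0 || t == rounds) ++nrec;
    NumericMatrix hist(nrec, 9);
    colnames(hist) = CharacterVector::create(
        "round", "n1", "mean_B1", "n2", "mean_B2",
        "ng", "no", "sum_mA", "sum_mN");

    int r = 0;
    double row[9];
    for (int t = 1; t <= rounds; ++t) {
        one_round(pop, tp, gp, R);
        if (t % record_every == 0 || t == rounds) {
            summarise(pop, n_types, t, row);
            for (int c = 0; c < 9; ++c) hist(r, c) = row[c];
            ++r;
        }
    }
    List out = pop_to_list(pop);
    out["history"] = hist;
    return out;
}
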