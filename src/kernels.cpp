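#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted beta mean nearest taxon distance for all sample pairs.
// D: n_otu x n_otu patristic distances; F: n_otu x n_samp relative
// abundances (columns sum to 1); perm: 0-based tip permutation mapping OTU
// row i to tip perm[i] (identity for the observed value, shuffled for
// nulls). For taxon i in sample k, the nearest-taxon distance to sample l
// is min over j present in l of D(perm[i], perm[j]); a taxon present in
// both contributes 0 via j = i.
static void bmntd_fill(const NumericMatrix& D, const NumericMatrix& F,
                       const IntegerVector& perm,
                       const std::vector<std::vector<int> >& present,
                       const std::vector<int>& active,
                       NumericMatrix& out) {
    const int S = F.ncol();
    // M(i, l): nearest-taxon distance from active OTU i to community l
    std::vector<double> M((size_t)active.size() * S);
    for (int l = 0; l < S; ++l) {
        const std::vector<int>& pl = present[l];
        for (size_t a = 0; a < active.size(); ++a) {
            const int pi = perm[active[a]];
            const double* dcol = &D(0, pi);  // column pi (symmetric)
            double mn = R_PosInf;
            for (size_t b = 0; b < pl.size(); ++b) {
                const double v = dcol[perm[pl[b]]];
                if (v < mn) mn = v;
            }
            M[a * S + l] = mn;
        }
    }
    // A(k, l) = sum_i F(i, k) * M(i, l); bMNTD = (A + A^T) / 2
    for (int k = 0; k < S; ++k) {
        for (int l = 0; l < S; ++l) {
            double acc = 0.0;
            const std::vector<int>& pk = present[k];
            for (size_t b = 0; b < pk.size(); ++b) {
                const int i = pk[b];
                // position of i in active: active is sorted, binary search
                const size_t a = std::lower_bound(active.begin(),
                    active.end(), i) - active.begin();
                acc += F(i, k) * M[a * S + l];
            }
            out(k, l) = acc;
        }
    }
    for (int k = 0; k < S; ++k)
        for (int l = 0; l < k; ++l) {
            const double v = 0.5 * (out(k, l) + out(l, k));
            out(k, l) = v;
            out(l, k) = v;
        }
    for (int k = 0; k < S; ++k) out(k, k) = 0.0;
}

static void presence_lists(const NumericMatrix& F,
                           std::vector<std::vector<int> >& present,
                           std::vector<int>& active) {
    const int n = F.nrow(), S = F.ncol();
    present.assign(S, std::vector<int>());
    std::vector<bool> act(n, false);
    for (int l = 0; l < S; ++l)
        for (int i = 0; i < n; ++i)
            if (F(i, l) > 0) { present[l].push_back(i); act[i] = true; }
    active.clear();
    for (int i = 0; i < n; ++i) if (act[i]) active.push_back(i);
}

// [[Rcpp::export]]
NumericMatrix cpp_bmntd(NumericMatrix D, NumericMatrix F) {
    std::vector<std::vector<int> > present;
    std::vector<int> active;
    presence_lists(F, present, active);
    IntegerVector perm(F.nrow());
    for (int i = 0; i < F.nrow(); ++i) perm[i] = i;
    NumericMatrix out(F.ncol(), F.ncol());
    bmntd_fill(D, F, perm, present, active, out);
    return out;
}

// Observed bMNTD plus null mean/sd over n_null tip-label shuffles.
// Uses the R RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_bmntd_null(NumericMatrix D, NumericMatrix F, int n_null) {
    const int S = F.ncol(), n = F.nrow();
    std::vector<std::vector<int> > present;
    std::vector<int> active;
    presence_lists(F, present, active);

    IntegerVector id(n);
    for (int i = 0; i < n; ++i) id[i] = i;
    NumericMatrix obs(S, S), work(S, S);
    bmntd_fill(D, F, id, present, active, obs);

    NumericMatrix msum(S, S), msq(S, S);
    for (int r = 0; r < n_null; ++r) {
        IntegerVector perm = sample(id, n, false);
        bmntd_fill(D, F, perm, present, active, work);
        for (int k = 0; k < S; ++k)
            for (int l = 0; l < S; ++l) {
                msum(k, l) += work(k, l);
                msq(k, l) += work(k, l) * work(k, l);
            }
        if (r % 50 == 0) Rcpp::checkUserInterrupt();
    }
    NumericMatrix mu(S, S), sd(S, S);
    for (int k = 0; k < S; ++k)
        for (int l = 0; l < S; ++l) {
            mu(k, l) = msum(k, l) / n_null;
            double var = (msq(k, l) - msum(k, l) * msum(k, l) / n_null) /
                         (n_null - 1);
            sd(k, l) = var > 0 ? std::sqrt(var) : 0.0;
        }
    return List::create(_["obs"] = obs, _["null_mean"] = mu,
                        _["null_sd"] = sd);
}

// Individual-based neutral community simulator (Hubbell drift with
// immigration): each sample is a local community of `depth` individuals;
// per event one individual dies and is replaced from the metacommunity
// with probability m, otherwise by reproduction within the local
// community. Uses the R RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_neutral_sim(NumericVector meta, int n_samples, int depth,
                              double m, int burnin) {
    const int n = meta.size();
    std::vector<double> cum(n);
    double tot = 0.0;
    for (int i = 0; i < n; ++i) { tot += meta[i]; cum[i] = tot; }
    for (int i = 0; i < n; ++i) cum[i] /= tot;

    IntegerMatrix out(n, n_samples);
    std::vector<double> probs(meta.begin(), meta.end());
    for (int i = 0; i < n; ++i) probs[i] /= tot;
    std::vector<int> counts(n);

    for (int s = 0; s < n_samples; ++s) {
        // initialise with a metacommunity draw, then let drift act
        rmultinom(depth, probs.data(), n, counts.data());
        for (int e = 0; e < burnin; ++e) {
            // death: uniform individual
            double u = unif_rand() * depth;
            int dead = 0;
            for (double acc = counts[0]; acc < u; acc += counts[++dead]) {}
            counts[dead]--;
            // birth: immigrant or local offspring
            int born;
            if (unif_rand() < m) {
                const double v = unif_rand();
                born = std::lower_bound(cum.begin(), cum.end(), v) -
                       cum.begin();
            } else {
                double v = unif_rand() * (depth - 1);
                born = 0;
                for (double acc = counts[0]; acc < v;
                     acc += counts[++born]) {}
            }
            counts[born]++;
        }
        for (int i = 0; i < n; ++i) out(i, s) = counts[i];
        Rcpp::checkUserInterrupt();
    }
    return out;
}
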