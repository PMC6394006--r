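#include <Rcpp.h>
using namespace Rcpp;

// 5'-anchored ungapped scoring: both the sequenced reads and every reference
// category (full product, barcode-forward stem, forward, reverse) begin at the
// same structural position, so matches are counted from position 0 over the
// overlap min(len(read), len(ref)). Identity/length gating happens in R.

static inline int count_matches(const char *a, int la, const char *b, int lb) {
    int L = la < lb ? la : lb;
    int m = 0;
    for (int k = 0; k < L; ++k)
        if (a[k] == b[k]) ++m;
    return m;
}

// [[Rcpp::export]]
IntegerMatrix cpp_anchored_counts(CharacterVector reads, CharacterVector refs) {
    int nr = reads.size(), nf = refs.size();
    IntegerMatrix out(nr, nf);
    std::vector<const char *> rp(nf);
    std::vector<int> rl(nf);
    for (int j = 0; j < nf; ++j) {
        rp[j] = CHAR(STRING_ELT(refs, j));
        rl[j] = LENGTH(STRING_ELT(refs, j));
    }
    for (int i = 0; i < nr; ++i) {
        const char *a = CHAR(STRING_ELT(reads, i));
        int la = LENGTH(STRING_ELT(reads, i));
        for (int j = 0; j < nf; ++j)
            out(i, j) = count_matches(a, la, rp[j], rl[j]);
    }
    return out;
}

// Full-product assignment exploiting the product structure
// product(s, j) = stem_s || rev_j with stems ordered barcode-major then
// forward probe, revs in probe order; product index p = (s-1)*n_rev + j
// (1-based). Reverse-homology match counts are cached per distinct stem
// length (the only thing the offset depends on).
//
// Returns, per read: the 1-based index of the best gated product (0 if no
// gated hit), the number of gated products attaining the top score, the match
// count and aligned length of the best product.
// [[Rcpp::export]]
List cpp_assign_full(CharacterVector reads, CharacterVector stems,
                     CharacterVector revs, int min_match, double min_identity) {
    int nr = reads.size(), ns = stems.size(), nv = revs.size();
    std::vector<const char *> sp(ns), vp(nv);
    std::vector<int> sl(ns), vl(nv);
    for (int s = 0; s < ns; ++s) {
        sp[s] = CHAR(STRING_ELT(stems, s));
        sl[s] = LENGTH(STRING_ELT(stems, s));
    }
    for (int j = 0; j < nv; ++j) {
        vp[j] = CHAR(STRING_ELT(revs, j));
        vl[j] = LENGTH(STRING_ELT(revs, j));
    }
    // distinct stem lengths -> offset classes
    std::vector<int> offs;
    std::vector<int> off_of(ns);
    for (int s = 0; s < ns; ++s) {
        int k = -1;
        for (size_t q = 0; q < offs.size(); ++q)
            if (offs[q] == sl[s]) { k = (int)q; break; }
        if (k < 0) { offs.push_back(sl[s]); k = (int)offs.size() - 1; }
        off_of[s] = k;
    }
    int no = offs.size();

    IntegerVector best_idx(nr), n_top(nr), best_m(nr), best_al(nr);
    std::vector<int> sm(ns);
    std::vector<int> rm(no * nv);

    for (int i = 0; i < nr; ++i) {
        const char *a = CHAR(STRING_ELT(reads, i));
        int la = LENGTH(STRING_ELT(reads, i));
        for (int s = 0; s < ns; ++s)
            sm[s] = count_matches(a, la, sp[s], sl[s]);
        for (int q = 0; q < no; ++q) {
            int o = offs[q];
            int rem = la - o;
            if (rem < 0) rem = 0;
            for (int j = 0; j < nv; ++j)
                rm[q * nv + j] = rem > 0 ? count_matches(a + o, rem, vp[j], vl[j]) : 0;
        }
        int bi = 0, nt = 0, bm = -1, bal = 0;
        for (int s = 0; s < ns; ++s) {
            int q = off_of[s];
            for (int j = 0; j < nv; ++j) {
                int plen = sl[s] + vl[j];
                int al = la < plen ? la : plen;
                if (al < min_match) continue;
                int m = sm[s] + rm[q * nv + j];
                if ((double)m + 1e-9 < min_identity * (double)al) continue;
                if (m > bm) {
                    bm = m; nt = 1; bi = s * nv + j + 1; bal = al;
                } else if (m == bm) {
                    ++nt;
                }
            }
        }
        best_idx[i] = bi;
        n_top[i] = nt;
        best_m[i] = bm < 0 ? 0 : bm;
        best_al[i] = bal;
    }
    return List::create(_["best_idx"] = best_idx, _["n_top"] = n_top,
                        _["matches"] = best_m, _["aligned"] = best_al);
}
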