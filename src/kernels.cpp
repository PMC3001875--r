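#include <Rcpp.h>
using namespace Rcpp;

// Mismatch count between equal-length string pairs (vectorised).
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
    int n = a.size();
    if (b.size() != n) stop("length mismatch");
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        const char *x = CHAR(STRING_ELT(a, i));
        const char *y = CHAR(STRING_ELT(b, i));
        int la = LENGTH(STRING_ELT(a, i));
        if (la != LENGTH(STRING_ELT(b, i))) stop("unequal string lengths at %d", i + 1);
        int d = 0;
        for (int j = 0; j < la; ++j) if (x[j] != y[j]) ++d;
        out[i] = d;
    }
    return out;
}

// Longest prefix / suffix run of each pair staying within max_mm mismatches.
// Returns an n x 4 matrix (prefix_len, prefix_mm, suffix_len, suffix_mm).
// [[Rcpp::export]]
IntegerMatrix cpp_prefix_suffix(CharacterVector a, CharacterVector b, int max_mm) {
    int n = a.size();
    if (b.size() != n) stop("length mismatch");
    IntegerMatrix out(n, 4);
    for (int i = 0; i < n; ++i) {
        const char *x = CHAR(STRING_ELT(a, i));
        const char *y = CHAR(STRING_ELT(b, i));
        int la = LENGTH(STRING_ELT(a, i));
        int lb = LENGTH(STRING_ELT(b, i));
        int L = la < lb ? la : lb;
        int mm = 0, pref = 0, pref_mm = 0;
        for (int j = 0; j < L; ++j) {
            if (x[j] != y[j]) { ++mm; if (mm > max_mm) break; }
            pref = j + 1; pref_mm = mm;
        }
        mm = 0;
        int suf = 0, suf_mm = 0;
        for (int j = 0; j < L; ++j) {
            if (x[la - 1 - j] != y[lb - 1 - j]) { ++mm; if (mm > max_mm) break; }
            suf = j + 1; suf_mm = mm;
        }
        out(i, 0) = pref; out(i, 1) = pref_mm;
        out(i, 2) = suf;  out(i, 3) = suf_mm;
    }
    return out;
}

// Smith-Waterman local alignment with linear gap penalty and full traceback.
// Scoring: +match_score per match, -mismatch_pen per mismatch, -gap_pen per
// gapped base.  Returns (score, n_match, aln_len, a_start, a_end, b_start,
// b_end), coordinates 1-based inclusive on each sequence; all zeros when the
// best local score is 0.
// [[Rcpp::export]]
IntegerVector cpp_sw_local(std::string a, std::string b,
                           int match_score = 1, int mismatch_pen = 2,
                           int gap_pen = 3) {
    int n = a.size(), m = b.size();
    std::vector<int> H((n + 1) * (m + 1), 0);
    std::vector<unsigned char> tb((n + 1) * (m + 1), 0); // 0 stop, 1 diag, 2 up, 3 left
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            int diag = H[(i - 1) * (m + 1) + j - 1] +
                (a[i - 1] == b[j - 1] ? match_score : -mismatch_pen);
            int up = H[(i - 1) * (m + 1) + j] - gap_pen;
            int left = H[i * (m + 1) + j - 1] - gap_pen;
            int s = diag; unsigned char t = 1;
            if (up > s) { s = up; t = 2; }
            if (left > s) { s = left; t = 3; }
            if (s <= 0) { s = 0; t = 0; }
            H[i * (m + 1) + j] = s;
            tb[i * (m + 1) + j] = t;
            if (s > best) { best = s; bi = i; bj = j; }
        }
    }
    IntegerVector out(7);
    if (best == 0) return out;
    int i = bi, j = bj, nmatch = 0, len = 0;
    while (i > 0 && j > 0 && tb[i * (m + 1) + j] != 0) {
        unsigned char t = tb[i * (m + 1) + j];
        ++len;
        if (t == 1) { if (a[i - 1] == b[j - 1]) ++nmatch; --i; --j; }
        else if (t == 2) { --i; }
        else { --j; }
    }
    out[0] = best; out[1] = nmatch; out[2] = len;
    out[3] = i + 1; out[4] = bi; out[5] = j + 1; out[6] = bj;
    return out;
}

// Majority-vote consensus over sequences laid out at given 0-based offsets.
// Ties resolved in A < C < G < T order for determinism.
// [[Rcpp::export]]
std::string cpp_consensus(CharacterVector seqs, IntegerVector offsets) {
    int n = seqs.size();
    int total = 0;
    for (int i = 0; i < n; ++i) {
        int e = offsets[i] + LENGTH(STRING_ELT(seqs, i));
        if (e > total) total = e;
    }
    const char bases[4] = {'A', 'C', 'G', 'T'};
    std::vector<int> votes(4 * total, 0);
    for (int i = 0; i < n; ++i) {
        const char *s = CHAR(STRING_ELT(seqs, i));
        int L = LENGTH(STRING_ELT(seqs, i));
        for (int j = 0; j < L; ++j) {
            int p = offsets[i] + j;
            switch (s[j]) {
            case 'A': ++votes[4 * p]; break;
            case 'C': ++votes[4 * p + 1]; break;
            case 'G': ++votes[4 * p + 2]; break;
            case 'T': ++votes[4 * p + 3]; break;
            default: break;
            }
        }
    }
    std::string cons(total, 'N');
    for (int p = 0; p < total; ++p) {
        int bestv = 0, bestk = -1;
        for (int k = 0; k < 4; ++k)
            if (votes[4 * p + k] > bestv) { bestv = votes[4 * p + k]; bestk = k; }
        if (bestk >= 0) cons[p] = bases[bestk];
    }
    return cons;
}
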