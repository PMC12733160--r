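#include <Rcpp.h>
#include <unordered_map>
#include <cstring>
using namespace Rcpp;

// Perfect tandem-repeat scanner (MISA-style semantics: perfect repeats only,
// reported once at their primitive unit, complete copies only).
//
// For unit length u, a maximal run of positions where s[i] == s[i+u]
// of length L yields a tandem array of total extent L+u starting at the
// left edge; copies = floor((L+u)/u).

static bool is_primitive(const std::string& motif) {
    const int u = (int) motif.size();
    for (int d = 1; d < u; ++d) {
        if (u % d != 0) continue;
        bool periodic = true;
        for (int k = d; k < u; ++k)
            if (motif[k] != motif[k - d]) { periodic = false; break; }
        if (periodic) return false;
    }
    return true;
}

// [[Rcpp::export]]
DataFrame ssr_scan_cpp(std::string seq, IntegerVector min_copies) {
    const int n = (int) seq.size();
    const int max_u = min_copies.size();
    std::vector<int> start, unit, copies;
    std::vector<std::string> motifs;
    for (int u = 1; u <= max_u; ++u) {
        int i = 0;
        while (i + u < n) {
            if (seq[i] == seq[i + u]) {
                int j = i;                      // run of matches [i, j]
                while (j + u < n && seq[j] == seq[j + u]) ++j;
                int ext = (j - i) + u;          // total tandem extent
                int cp = ext / u;
                if (cp >= min_copies[u - 1]) {
                    std::string m = seq.substr(i, u);
                    if (is_primitive(m) && m.find('N') == std::string::npos) {
                        start.push_back(i);
                        unit.push_back(u);
                        copies.push_back(cp);
                        motifs.push_back(m);
                    }
                }
                i = j + 1;                      // jump past this run
            } else {
                ++i;
            }
        }
    }
    return DataFrame::create(_["start0"] = start, _["unit_len"] = unit,
                             _["copies"] = copies, _["motif"] = motifs,
                             _["stringsAsFactors"] = false);
}

// Longest exact reverse-complement repeat on the circular sequence.
// Works on the doubled sequence T = S+S and U = revcomp(T); a common
// substring of T and U of length L is a segment whose reverse complement
// also occurs on the circle.  Binary search on L with rolling hashes,
// candidates verified by direct comparison.  Returns the maximal L and all
// (posA, posB) circle offsets (0-based) with segment(posA) == revcomp(segment(posB)).

static char comp(char c) {
    switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'G': return 'C'; case 'C': return 'G';
    default:  return 'N';
    }
}

typedef unsigned long long u64;

// collect circle-start positions in U matching some L-substring of T
static void ir_candidates(const std::string& T, const std::string& U, int n, int L,
                          std::vector<std::pair<int,int> >& out) {
    out.clear();
    const u64 B = 1313331ULL;
    u64 pw = 1; for (int k = 1; k < L; ++k) pw *= B;
    std::unordered_multimap<u64, int> tab;
    tab.reserve(n * 2);
    u64 h = 0;
    for (int k = 0; k < L; ++k) h = h * B + (u64) T[k];
    for (int i = 0; i < n; ++i) {
        tab.insert(std::make_pair(h, i));
        h = (h - (u64) T[i] * pw) * B + (u64) T[i + L];
    }
    h = 0;
    for (int k = 0; k < L; ++k) h = h * B + (u64) U[k];
    for (int j = 0; j < n; ++j) {
        auto range = tab.equal_range(h);
        for (auto it = range.first; it != range.second; ++it) {
            int i = it->second;
            if (std::memcmp(T.data() + i, U.data() + j, L) == 0)
                out.push_back(std::make_pair(i, j));
        }
        h = (h - (u64) U[j] * pw) * B + (u64) U[j + L];
    }
}

// circle-disjointness of [a, a+L) and [b, b+L) taken modulo n
static bool circ_disjoint(int a, int b, int L, int n) {
    if (2 * L > n) return false;
    int d1 = ((b - a) % n + n) % n;      // offset of b after a
    int d2 = ((a - b) % n + n) % n;
    return d1 >= L && d2 >= L;
}

// [[Rcpp::export]]
List longest_ir_cpp(std::string seq, int min_len) {
    const int n = (int) seq.size();
    std::string T = seq + seq;
    std::string U(T.rbegin(), T.rend());
    for (size_t k = 0; k < U.size(); ++k) U[k] = comp(U[k]);
    int max_L = n / 2;                  // two disjoint copies cannot exceed this
    if (max_L < min_len)
        return List::create(_["len"] = 0);
    std::vector<std::pair<int,int> > cand;
    int lo = min_len, hi = max_L, best = 0;
    while (lo <= hi) {
        int mid = (lo + hi) / 2;
        ir_candidates(T, U, n, mid, cand);
        bool any = false;
        for (size_t k = 0; k < cand.size(); ++k) {
            // map U position to circle start of the reverse-complemented segment
            int j = cand[k].second;
            int posB = ((2 * n - j - mid) % n + n) % n;
            int posA = cand[k].first % n;
            if (circ_disjoint(posA, posB, mid, n)) { any = true; break; }
        }
        if (any) { best = mid; lo = mid + 1; } else { hi = mid - 1; }
    }
    if (best == 0) return List::create(_["len"] = 0);
    ir_candidates(T, U, n, best, cand);
    std::vector<int> pa, pb;
    for (size_t k = 0; k < cand.size(); ++k) {
        int j = cand[k].second;
        int posB = ((2 * n - j - best) % n + n) % n;
        int posA = cand[k].first % n;
        if (circ_disjoint(posA, posB, best, n)) { pa.push_back(posA); pb.push_back(posB); }
    }
    return List::create(_["len"] = best, _["pos_a"] = wrap(pa), _["pos_b"] = wrap(pb));
}

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps.
// Cost of a gap of length L is open + L*ext (penalties passed positive).
// Traceback preference on ties: diagonal > up (gap in b) > left (gap in a).
// Sequences are integer-coded; returns 1-based aligned indices, 0 = gap.

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, double match, double mismatch,
                  double gap_open, double gap_ext) {
    const int n = a.size(), m = b.size();
    const double NEG = -1e30;
    NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
    // X: gap in b (consume a, move up); Y: gap in a (consume b, move left)
    M(0, 0) = 0; X(0, 0) = Y(0, 0) = NEG;
    for (int i = 1; i <= n; ++i) {
        M(i, 0) = Y(i, 0) = NEG;
        X(i, 0) = -(gap_open + i * gap_ext);
    }
    for (int j = 1; j <= m; ++j) {
        M(0, j) = X(0, j) = NEG;
        Y(0, j) = -(gap_open + j * gap_ext);
    }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
            double dm = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
            M(i, j) = dm + s;
            X(i, j) = std::max(M(i - 1, j) - gap_open - gap_ext,
                      std::max(X(i - 1, j) - gap_ext,
                               Y(i - 1, j) - gap_open - gap_ext));
            Y(i, j) = std::max(M(i, j - 1) - gap_open - gap_ext,
                      std::max(X(i, j - 1) - gap_open - gap_ext,
                               Y(i, j - 1) - gap_ext));
        }
    }
    std::vector<int> ra, rb;
    int i = n, j = m;
    int state;                           // 0 = M, 1 = X, 2 = Y; prefer M > X > Y
    double sc = M(n, m); state = 0;
    if (X(n, m) > sc) { sc = X(n, m); state = 1; }
    if (Y(n, m) > sc) { sc = Y(n, m); state = 2; }
    const double EPS = 1e-9;
    while (i > 0 || j > 0) {
        if (state == 0) {
            double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
            double need = M(i, j) - s;
            ra.push_back(i); rb.push_back(j); --i; --j;
            if (std::abs(M(i, j) - need) < EPS) state = 0;
            else if (std::abs(X(i, j) - need) < EPS) state = 1;
            else state = 2;
        } else if (state == 1) {
            double v = X(i, j);
            ra.push_back(i); rb.push_back(0); --i;
            if (std::abs(M(i, j) - gap_open - gap_ext - v) < EPS) state = 0;
            else if (std::abs(X(i, j) - gap_ext - v) < EPS) state = 1;
            else state = 2;
        } else {
            double v = Y(i, j);
            ra.push_back(0); rb.push_back(j); --j;
            if (std::abs(M(i, j) - gap_open - gap_ext - v) < EPS) state = 0;
            else if (std::abs(X(i, j) - gap_open - gap_ext - v) < EPS) state = 1;
            else state = 2;
        }
        if (i == 0 && j > 0) state = 2;
        if (j == 0 && i > 0) state = 1;
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return List::create(_["a"] = wrap(ra), _["b"] = wrap(rb), _["score"] = sc);
}
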