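// Split alignment of amplicon reads: best local alignment under a model of
// one or two collinear ungapped segments separated by a single free
// reference gap (the deletion junction). Scoring is match +1 / mismatch -1;
// the junction costs nothing, so the optimum over two-segment chains equals
// a brute-force maximization over all (deletion start, length) placements.
//
// Three O(n*m) passes per read orientation:
//   S  (reverse): best diagonal run starting at (i,j)
//   P  (forward): best diagonal run ending at (i,j), fused with the
//      running row maximum RC[i][j] = max_{j'<=j} P[i][j'] and with the
//      two-segment combination  RC[i-1][j-2] + S[i][j].
// Segment extents and match counts are recovered afterwards by walking the
// two diagonals (O(n) per read).

#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <climits>
using namespace Rcpp;

static inline int encRead(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;               // read N: never equals a ref code
    }
}

static inline int encRef(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 5;               // ref N: never equals a read code
    }
}

struct AlnResult {
    int score = 0;
    int nseg = 1;
    int r1s = 0, r1e = 0, f1s = 0, f1e = 0, m1 = 0;
    int r2s = 0, r2e = 0, f2s = 0, f2e = 0, m2 = 0;
    int junction = 0;
};

// Work buffers reused across reads.
struct Work {
    std::vector<int> S;              // n*m suffix matrix
    std::vector<int> curP, prevRCv, curRCv;
    std::vector<int> prevRCj, curRCj;
    std::vector<int> prevP;
};

// Walk a diagonal backwards from inclusive cell (i1, j1) and return the
// length (and matches) of the shortest run ending there whose score equals
// `target` (the Kadane optimum ending at that cell).
static void walkBack(const std::vector<int>& rd, const std::vector<int>& rf,
                     int i1, int j1, int target, int& len, int& mat) {
    int sum = 0, nmat = 0, bestLen = 1, bestMat = 0;
    for (int k = 0; ; ++k) {
        int i = i1 - k, j = j1 - k;
        if (i < 0 || j < 0) break;
        int s = (rd[i] == rf[j]) ? 1 : -1;
        sum += s;
        nmat += (s > 0);
        if (sum == target) { bestLen = k + 1; bestMat = nmat; break; }
    }
    len = bestLen; mat = bestMat;
}

// Forward walk from inclusive cell (i0, j0): shortest run starting there
// whose score equals `target`.
static void walkFwd(const std::vector<int>& rd, const std::vector<int>& rf,
                    int i0, int j0, int target, int& len, int& mat) {
    const int n = (int) rd.size(), m = (int) rf.size();
    int sum = 0, nmat = 0, bestLen = 1, bestMat = 0;
    for (int k = 0; ; ++k) {
        int i = i0 + k, j = j0 + k;
        if (i >= n || j >= m) break;
        int s = (rd[i] == rf[j]) ? 1 : -1;
        sum += s;
        nmat += (s > 0);
        if (sum == target) { bestLen = k + 1; bestMat = nmat; break; }
    }
    len = bestLen; mat = bestMat;
}

static AlnResult align_core(const std::vector<int>& rd,
                            const std::vector<int>& rf, Work& w) {
    const int n = (int) rd.size(), m = (int) rf.size();
    w.S.resize((size_t) n * m);
    w.curP.assign(m, 0);
    w.prevP.assign(m, 0);
    w.prevRCv.assign(m, 0);
    w.curRCv.assign(m, 0);
    w.prevRCj.assign(m, 0);
    w.curRCj.assign(m, 0);
    int* S = w.S.data();

    // reverse pass: S[i][j] = best run starting at (i,j)
    for (int i = n - 1; i >= 0; --i) {
        const int rb = rd[i];
        int* Si = S + (size_t) i * m;
        const int* Sn = (i + 1 < n) ? S + (size_t) (i + 1) * m : nullptr;
        for (int j = m - 1; j >= 0; --j) {
            const int s = (rb == rf[j]) ? 1 : -1;
            int nxt = (Sn && j + 1 < m) ? Sn[j + 1] : 0;
            Si[j] = s + (nxt > 0 ? nxt : 0);
        }
    }

    // forward pass: P, RC, best single, best two-segment combination
    int best1 = INT_MIN, b1i = 0, b1j = 0;
    long best2 = LONG_MIN;
    int b2junc = 0, b2j1 = 0, b2i = 0, b2j = 0, b2first = 0, b2second = 0;

    int* prevP = w.prevP.data();
    int* curP = w.curP.data();
    int* prevRCv = w.prevRCv.data();
    int* curRCv = w.curRCv.data();
    int* prevRCj = w.prevRCj.data();
    int* curRCj = w.curRCj.data();

    for (int i = 0; i < n; ++i) {
        const int rb = rd[i];
        const int* Si = S + (size_t) i * m;
        int rcv = INT_MIN, rcj = -1;
        for (int j = 0; j < m; ++j) {
            const int s = (rb == rf[j]) ? 1 : -1;
            const int p = (i > 0 && j > 0) ? prevP[j - 1] : 0;
            const int cur = s + (p > 0 ? p : 0);
            curP[j] = cur;
            if (cur > best1) { best1 = cur; b1i = i; b1j = j; }
            if (cur >= rcv) { rcv = cur; rcj = j; }
            curRCv[j] = rcv; curRCj[j] = rcj;
            if (i > 0 && j >= 2 && prevRCv[j - 2] > 0) {
                const long tot = (long) prevRCv[j - 2] + Si[j];
                if (tot >= best2) {
                    const int j1 = prevRCj[j - 2];
                    const int junc = j - j1 - 1;
                    if (tot > best2 || junc < b2junc ||
                        (junc == b2junc && j1 < b2j1)) {
                        best2 = tot; b2junc = junc; b2j1 = j1;
                        b2i = i; b2j = j;
                        b2first = prevRCv[j - 2]; b2second = Si[j];
                    }
                }
            }
        }
        std::swap(prevP, curP);
        std::swap(prevRCv, curRCv);
        std::swap(prevRCj, curRCj);
    }

    AlnResult res;
    if (best2 > best1) {
        res.score = (int) best2; res.nseg = 2;
        int len1, mat1, len2, mat2;
        walkBack(rd, rf, b2i - 1, b2j1, b2first, len1, mat1);
        walkFwd(rd, rf, b2i, b2j, b2second, len2, mat2);
        res.r1s = b2i - len1; res.r1e = b2i;
        res.f1s = b2j1 + 1 - len1; res.f1e = b2j1 + 1;
        res.m1 = mat1;
        res.r2s = b2i; res.r2e = b2i + len2;
        res.f2s = b2j; res.f2e = b2j + len2;
        res.m2 = mat2;
        res.junction = b2junc;
    } else {
        res.score = best1; res.nseg = 1;
        int len, mat;
        walkBack(rd, rf, b1i, b1j, best1, len, mat);
        res.r1s = b1i + 1 - len; res.r1e = b1i + 1;
        res.f1s = b1j + 1 - len; res.f1e = b1j + 1;
        res.m1 = mat;
        res.junction = 0;
    }
    return res;
}

// [[Rcpp::export]]
IntegerMatrix cpp_align_batch(CharacterVector reads, std::string ref,
                              bool tryMinus = true) {
    const int m = (int) ref.size();
    if (m == 0) stop("empty reference");
    std::vector<int> rf(m);
    for (int j = 0; j < m; ++j) rf[j] = encRef(ref[j]);

    const int nr = reads.size();
    IntegerMatrix out(nr, 17);
    colnames(out) = CharacterVector::create(
        "score", "nseg", "strand", "r1_start", "r1_end", "f1_start",
        "f1_end", "m1", "r2_start", "r2_end", "f2_start", "f2_end", "m2",
        "junction_size", "aligned_bases", "matches", "read_length");

    Work w;
    std::vector<int> rd, rc;
    for (int k = 0; k < nr; ++k) {
        const char* rs = CHAR(STRING_ELT(reads, k));
        const int n = (int) std::strlen(rs);
        if (n == 0) stop("empty read at index ", k + 1);
        rd.resize(n);
        for (int i = 0; i < n; ++i) rd[i] = encRead(rs[i]);

        AlnResult best = align_core(rd, rf, w);
        int strand = 0;
        // a full-length perfect match cannot be beaten on the other strand
        if (tryMinus && best.score < n) {
            rc.resize(n);
            for (int i = 0; i < n; ++i) {
                const int b = rd[n - 1 - i];
                rc[i] = (b < 4) ? 3 - b : 4;
            }
            AlnResult mres = align_core(rc, rf, w);
            if (mres.score > best.score) {   // ties prefer the + strand
                best = mres;
                strand = 1;
            }
        }

        const int aligned = (best.r1e - best.r1s) +
            (best.nseg == 2 ? best.r2e - best.r2s : 0);
        const int matches = best.m1 + (best.nseg == 2 ? best.m2 : 0);
        out(k, 0) = best.score;  out(k, 1) = best.nseg;
        out(k, 2) = strand;
        out(k, 3) = best.r1s;    out(k, 4) = best.r1e;
        out(k, 5) = best.f1s;    out(k, 6) = best.f1e;
        out(k, 7) = best.m1;
        out(k, 8) = best.r2s;    out(k, 9) = best.r2e;
        out(k, 10) = best.f2s;   out(k, 11) = best.f2e;
        out(k, 12) = best.m2;
        out(k, 13) = best.junction;
        out(k, 14) = aligned;
        out(k, 15) = matches;
        out(k, 16) = n;
    }
    return out;
}
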