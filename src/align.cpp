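#include <Rcpp.h>
#include <cstring>
#include <unordered_map>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---- amino-acid alphabet handling -------------------------------------------

struct SubstMatrix {
    int lookup[256];
    std::vector<int> mat;   // n x n scores
    int n;
    SubstMatrix(const NumericMatrix &m, const std::vector<std::string> &alpha) {
        n = (int) alpha.size();
        for (int i = 0; i < 256; ++i) lookup[i] = -1;
        for (int i = 0; i < n; ++i) lookup[(unsigned char) alpha[i][0]] = i;
        mat.resize((size_t) n * n);
        for (int i = 0; i < n; ++i)
            for (int j = 0; j < n; ++j)
                mat[(size_t) i * n + j] = (int) m(i, j);
    }
    inline int score(int a, int b) const { return mat[(size_t) a * n + b]; }
};

static std::vector<int> encode_aa(const std::string &s, const SubstMatrix &sm,
                                  int fallback) {
    std::vector<int> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) {
        int c = sm.lookup[(unsigned char) s[i]];
        v[i] = (c >= 0) ? c : fallback;
    }
    return v;
}

// ---- affine-gap local alignment ---------------------------------------------

struct Hsp {
    int score, qstart, qend, sstart, send, matches, alncols;
    Hsp() : score(0), qstart(0), qend(0), sstart(0), send(0),
            matches(0), alncols(0) {}
};

// Full Smith-Waterman with affine gaps (open + extend per gap base, so a
// length-1 gap costs go + ge).  Traceback recovers endpoints and identity.
// bandLo/bandHi restrict diagonals d = j - i; pass INT_MIN/INT_MAX for full.
static Hsp sw_align(const std::vector<int> &q, const std::vector<int> &s,
                    const SubstMatrix &sm, int go, int ge,
                    int bandLo, int bandHi) {
    const int m = (int) q.size(), n = (int) s.size();
    Hsp best;
    if (m == 0 || n == 0) return best;
    bandLo = std::max(bandLo, -m);
    bandHi = std::min(bandHi, n);
    if (bandLo > bandHi) return best;
    const int W = bandHi - bandLo + 1;
    // banded storage: cell (i, j) lives at column k = j - i - bandLo
    std::vector<int> H((size_t) (m + 1) * W, 0), E((size_t) (m + 1) * W, INT_MIN / 4),
        F((size_t) (m + 1) * W, INT_MIN / 4);
    // traceback codes: 0 stop, 1 diag, 2 from E (gap in query), 3 from F
    std::vector<unsigned char> TB((size_t) (m + 1) * W, 0),
        TE((size_t) (m + 1) * W, 0), TF((size_t) (m + 1) * W, 0);
    int bi = 0, bk = 0;
    for (int i = 1; i <= m; ++i) {
        const int jlo = std::max(1, i + bandLo), jhi = std::min(n, i + bandHi);
        for (int j = jlo; j <= jhi; ++j) {
            const size_t idx = (size_t) i * W + (j - i - bandLo);
            // E: gap in query (consume s[j-1]); cell (i, j-1) is k+... j-1-i-bandLo
            int e = INT_MIN / 4; unsigned char te = 0;
            if (j - 1 >= i + bandLo && j - 1 >= 1) {
                const size_t left = (size_t) i * W + (j - 1 - i - bandLo);
                const int openv = H[left] - go - ge, extv = E[left] - ge;
                if (openv >= extv) { e = openv; te = 0; }
                else { e = extv; te = 1; }
            }
            // F: gap in subject (consume q[i-1]); cell (i-1, j)
            int f = INT_MIN / 4; unsigned char tf = 0;
            if (j <= (i - 1) + bandHi && i - 1 >= 1) {
                const size_t up = (size_t) (i - 1) * W + (j - (i - 1) - bandLo);
                const int openv = H[up] - go - ge, extv = F[up] - ge;
                if (openv >= extv) { f = openv; tf = 0; }
                else { f = extv; tf = 1; }
            }
            // diag
            int d = 0;
            {
                const size_t dg = (size_t) (i - 1) * W + (j - i - bandLo);
                // (i-1, j-1) has same k; valid when i-1 >= 0 (H row 0 is zeros)
                d = H[dg] + sm.score(q[i - 1], s[j - 1]);
            }
            int h = 0; unsigned char tb = 0;
            if (d > h) { h = d; tb = 1; }
            if (e > h) { h = e; tb = 2; }
            if (f > h) { h = f; tb = 3; }
            H[idx] = h; E[idx] = e; F[idx] = f;
            TB[idx] = tb; TE[idx] = te; TF[idx] = tf;
            if (h > best.score) { best.score = h; bi = i; bk = j - i - bandLo; }
        }
    }
    if (best.score <= 0) return best;
    // traceback
    int i = bi, j = bi + bk + bandLo;
    best.qend = i; best.send = j;
    int state = 0; // 0 = in H, 2 = in E, 3 = in F
    while (true) {
        const size_t idx = (size_t) i * W + (j - i - bandLo);
        if (state == 0) {
            unsigned char tb = TB[idx];
            if (tb == 0) break;
            if (tb == 1) {
                ++best.alncols;
                if (q[i - 1] == s[j - 1]) ++best.matches;
                --i; --j;
            } else state = tb;
        } else if (state == 2) {
            ++best.alncols;
            state = TE[idx] ? 2 : 0;
            --j;
        } else {
            ++best.alncols;
            state = TF[idx] ? 3 : 0;
            --i;
        }
        if (i < 0 || j < 0) break;
    }
    best.qstart = i + 1; best.sstart = j + 1;
    return best;
}

// [[Rcpp::export(name = ".C_sw_align")]]
NumericVector C_sw_align(std::string q, std::string s, NumericMatrix mat,
                         CharacterVector alphabet, double gapOpen,
                         double gapExtend) {
    std::vector<std::string> alpha(alphabet.size());
    for (int i = 0; i < alphabet.size(); ++i)
        alpha[i] = as<std::string>(alphabet[i]);
    SubstMatrix sm(mat, alpha);
    int fb = sm.lookup['X'] >= 0 ? sm.lookup['X'] : 0;
    Hsp h = sw_align(encode_aa(q, sm, fb), encode_aa(s, sm, fb), sm,
                     (int) gapOpen, (int) gapExtend, INT_MIN / 8, INT_MAX / 8);
    return NumericVector::create(h.score, h.qstart, h.qend, h.sstart, h.send,
                                 h.matches, h.alncols);
}

// ---- word-seeded translated search ------------------------------------------

struct WordIndex {
    std::unordered_multimap<int, int> pos; // word hash -> 0-based position
    int w, n;
    std::vector<bool> seedable;            // residue usable in a seed word
    WordIndex(const std::vector<int> &s, int w_, int nsym,
              const std::vector<bool> &ok_res) : w(w_), n(nsym),
                                                 seedable(ok_res) {
        int L = (int) s.size();
        for (int p = 0; p + w <= L; ++p) {
            int h = 0; bool ok = true;
            for (int t = 0; t < w; ++t) {
                if (s[p + t] < 0 || !seedable[s[p + t]]) { ok = false; break; }
                h = h * n + s[p + t];
            }
            if (ok) pos.insert({h, p});
        }
    }
};

// residues excluded from seeding: stops and ambiguity codes never anchor a
// word seed (they still score inside extensions)
static std::vector<bool> seedable_residues(const SubstMatrix &sm,
                                           const std::vector<std::string> &alpha) {
    std::vector<bool> ok(sm.n, true);
    for (int i = 0; i < sm.n; ++i) {
        char c = alpha[i][0];
        if (c == '*' || c == 'X' || c == 'B' || c == 'Z' || c == 'J' ||
            c == 'U' || c == 'O')
            ok[i] = false;
    }
    return ok;
}

// Best HSP for one (query frame, subject frame) pair using two-hit word
// seeding and banded extension around the seed diagonals.
static Hsp seeded_pair(const std::vector<int> &q, const std::vector<int> &s,
                       const WordIndex &ix, const SubstMatrix &sm,
                       int go, int ge, int minHits, int bandPad) {
    Hsp best;
    const int w = ix.w, m = (int) q.size();
    if (m < w) return best;
    // collect seed hits as (diagonal, qpos)
    std::vector<std::pair<int, int> > hits;
    for (int p = 0; p + w <= m; ++p) {
        int h = 0; bool ok = true;
        for (int t = 0; t < w; ++t) {
            if (!ix.seedable[q[p + t]]) { ok = false; break; }
            h = h * sm.n + q[p + t];
        }
        if (!ok) continue;
        auto range = ix.pos.equal_range(h);
        for (auto it = range.first; it != range.second; ++it)
            hits.push_back(std::make_pair(it->second - p, p));
    }
    if ((int) hits.size() < minHits) return best;
    std::sort(hits.begin(), hits.end());
    // cluster by diagonal proximity
    size_t c0 = 0;
    std::vector<std::pair<int, int> > clusters; // diagLo, diagHi per cluster
    for (size_t i = 1; i <= hits.size(); ++i) {
        if (i == hits.size() || hits[i].first - hits[i - 1].first > bandPad) {
            if (i - c0 >= (size_t) minHits)
                clusters.push_back(std::make_pair(hits[c0].first,
                                                  hits[i - 1].first));
            c0 = i;
        }
    }
    for (size_t c = 0; c < clusters.size(); ++c) {
        Hsp h = sw_align(q, s, sm, go, ge,
                         clusters[c].first - bandPad,
                         clusters[c].second + bandPad);
        if (h.score > best.score) best = h;
    }
    return best;
}

// Batch translated search: for every query (rows of qframes, 6 peptide
// frames each) against the 6 subject frame peptides, report the best HSP per
// (query, qframe, sframe) with score > 0.  mode: 0 auto, 1 full, 2 seeded.
// [[Rcpp::export(name = ".C_translated_batch")]]
NumericMatrix C_translated_batch(CharacterMatrix qframes,
                                 CharacterVector sframes, NumericMatrix mat,
                                 CharacterVector alphabet, double gapOpen,
                                 double gapExtend, int wordSize, int mode,
                                 double fullLimit, int minHits, int bandPad,
                                 double minScore) {
    std::vector<std::string> alpha(alphabet.size());
    for (int i = 0; i < alphabet.size(); ++i)
        alpha[i] = as<std::string>(alphabet[i]);
    SubstMatrix sm(mat, alpha);
    const int fb = sm.lookup['X'] >= 0 ? sm.lookup['X'] : 0;
    const int go = (int) gapOpen, ge = (int) gapExtend;

    std::vector<bool> ok_res = seedable_residues(sm, alpha);
    std::vector<std::vector<int> > sencoded(6);
    std::vector<WordIndex *> sindex(6, (WordIndex *) 0);
    for (int f = 0; f < 6; ++f) {
        sencoded[f] = encode_aa(as<std::string>(sframes[f]), sm, fb);
        if (mode != 1)
            sindex[f] = new WordIndex(sencoded[f], wordSize, sm.n, ok_res);
    }
    std::vector<double> out; // rows of 11
    const int nq = qframes.nrow();
    for (int r = 0; r < nq; ++r) {
        for (int qf = 0; qf < 6; ++qf) {
            std::vector<int> q = encode_aa(as<std::string>(qframes(r, qf)),
                                           sm, fb);
            if (q.empty()) continue;
            for (int sf = 0; sf < 6; ++sf) {
                const std::vector<int> &s = sencoded[sf];
                if (s.empty()) continue;
                bool full = (mode == 1) ||
                    (mode == 0 &&
                     (double) q.size() * (double) s.size() <= fullLimit);
                Hsp h = full
                    ? sw_align(q, s, sm, go, ge, INT_MIN / 8, INT_MAX / 8)
                    : seeded_pair(q, s, *sindex[sf], sm, go, ge, minHits,
                                  bandPad);
                if (h.score > 0 && h.score >= minScore) {
                    double row[11] = {(double) (r + 1), (double) (qf + 1),
                                      (double) (sf + 1), (double) h.score,
                                      (double) h.qstart, (double) h.qend,
                                      (double) h.sstart, (double) h.send,
                                      (double) h.matches, (double) h.alncols,
                                      (double) q.size()};
                    out.insert(out.end(), row, row + 11);
                }
            }
        }
    }
    for (int f = 0; f < 6; ++f) delete sindex[f];
    const int nr = (int) (out.size() / 11);
    NumericMatrix res(nr, 11);
    for (int i = 0; i < nr; ++i)
        for (int j = 0; j < 11; ++j) res(i, j) = out[(size_t) i * 11 + j];
    colnames(res) = CharacterVector::create("query", "qframe", "sframe",
        "score", "qstart_aa", "qend_aa", "sstart_aa", "send_aa", "matches",
        "aln_cols", "qlen_aa");
    return res;
}

// ---- gapless seeded nucleotide placement ------------------------------------

static inline int nt_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static std::string revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) {
        switch (r[i]) {
        case 'A': r[i] = 'T'; break; case 'T': r[i] = 'A'; break;
        case 'C': r[i] = 'G'; break; case 'G': r[i] = 'C'; break;
        case 'a': r[i] = 't'; break; case 't': r[i] = 'a'; break;
        case 'c': r[i] = 'g'; break; case 'g': r[i] = 'c'; break;
        default: break;
        }
    }
    return r;
}

struct NtIndex {
    std::unordered_multimap<uint32_t, int> pos;
    int k;
    NtIndex(const std::string &s, int k_) : k(k_) {
        const int L = (int) s.size();
        uint32_t h = 0; int run = 0;
        const uint32_t mask = (k >= 16) ? 0xffffffffu
            : ((uint32_t(1) << (2 * k)) - 1);
        for (int i = 0; i < L; ++i) {
            int c = nt_code(s[i]);
            if (c < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint32_t) c) & mask;
            if (++run >= k) pos.insert({h, i - k + 1});
        }
    }
};

struct Placement {
    bool found; int strand; long offset, matches, overlap; double identity;
    Placement() : found(false), strand(0), offset(0), matches(0), overlap(0),
                  identity(0) {}
};

static void count_overlap(const std::string &r, const std::string &c,
                          long offset, long &matches, long &overlap) {
    const long rl = (long) r.size(), cl = (long) c.size();
    const long lo = std::max(0L, -offset), hi = std::min(rl, cl - offset);
    matches = 0; overlap = std::max(0L, hi - lo);
    for (long i = lo; i < hi; ++i)
        if (r[(size_t) i] == c[(size_t) (i + offset)] &&
            nt_code(r[(size_t) i]) >= 0) ++matches;
}

// best gapless placement of read (given orientation) on contig via seed
// votes; query k-mers are sampled every `stride` positions (a shared k-mer
// inside the overlap is still guaranteed for overlaps >= k + stride - 1)
static void best_offset(const std::string &r, const std::string &c,
                        const NtIndex &ix, int strand, long minOverlap,
                        double minIdentity, int stride, Placement &best) {
    const int k = ix.k, rl = (int) r.size();
    std::unordered_map<long, int> votes;
    uint32_t h = 0; int run = 0;
    const uint32_t mask = (k >= 16) ? 0xffffffffu
        : ((uint32_t(1) << (2 * k)) - 1);
    for (int i = 0; i < rl; ++i) {
        int cc = nt_code(r[i]);
        if (cc < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint32_t) cc) & mask;
        if (run + 1 >= k && ((i - k + 1) % stride) == 0) {
            auto range = ix.pos.equal_range(h);
            for (auto it = range.first; it != range.second; ++it)
                ++votes[(long) it->second - (i - k + 1)];
        }
        ++run;
    }
    // evaluate offsets ordered deterministically (votes desc, offset asc)
    std::vector<std::pair<long, int> > offs(votes.begin(), votes.end());
    std::sort(offs.begin(), offs.end(),
              [](const std::pair<long, int> &a, const std::pair<long, int> &b) {
                  if (a.second != b.second) return a.second > b.second;
                  return a.first < b.first;
              });
    const long cl = (long) c.size();
    const size_t cap = std::min(offs.size(), (size_t) 24);
    for (size_t t = 0; t < cap; ++t) {
        const long off = offs[t].first;
        // geometric overlap bound: skip before the base-level count
        if (std::min((long) rl, cl - off) - std::max(0L, -off) < minOverlap)
            continue;
        long matches, overlap;
        count_overlap(r, c, off, matches, overlap);
        if (overlap < minOverlap) continue;
        double id = (double) matches / (double) overlap;
        if (id < minIdentity) continue;
        bool better = false;
        if (!best.found) better = true;
        else if (matches != best.matches) better = matches > best.matches;
        else if (id != best.identity) better = id > best.identity;
        else if (strand != best.strand) better = strand < best.strand;
        else better = offs[t].first < best.offset;
        if (better) {
            best.found = true; best.strand = strand;
            best.offset = offs[t].first; best.matches = matches;
            best.overlap = overlap; best.identity = id;
        }
    }
}

// Map reads onto a contig, both orientations, gapless.  Returns one row per
// qualifying read: read, strand (1 fwd / -1 rc), offset (0-based signed
// position of read base 1 on the contig), matches, overlap, identity.
// [[Rcpp::export(name = ".C_map_reads")]]
NumericMatrix C_map_reads(CharacterVector reads, std::string contig, int k,
                          double minOverlap, double minIdentity,
                          int stride = 4) {
    NtIndex ix(contig, k);
    std::vector<double> out;
    for (int r = 0; r < reads.size(); ++r) {
        std::string fwd = as<std::string>(reads[r]);
        std::string rc = revcomp(fwd);
        Placement best;
        best_offset(fwd, contig, ix, 0, (long) minOverlap, minIdentity,
                    stride, best);
        best_offset(rc, contig, ix, 1, (long) minOverlap, minIdentity,
                    stride, best);
        if (best.found) {
            double row[6] = {(double) (r + 1), best.strand == 0 ? 1.0 : -1.0,
                             (double) best.offset, (double) best.matches,
                             (double) best.overlap, best.identity};
            out.insert(out.end(), row, row + 6);
        }
    }
    const int nr = (int) (out.size() / 6);
    NumericMatrix res(nr, 6);
    for (int i = 0; i < nr; ++i)
        for (int j = 0; j < 6; ++j) res(i, j) = out[(size_t) i * 6 + j];
    colnames(res) = CharacterVector::create("read", "strand", "offset",
                                            "matches", "overlap", "identity");
    return res;
}

// Best overlap placement of b relative to a (either orientation of b).
// Returns c(found, orient (1/-1), offset, overlap, matches, identity).
// [[Rcpp::export(name = ".C_best_overlap")]]
NumericVector C_best_overlap(std::string a, std::string b, int k,
                             double minOverlap, double minIdentity,
                             int stride = 1) {
    NtIndex ix(a, k);
    Placement best;
    std::string brc = revcomp(b);
    best_offset(b, a, ix, 0, (long) minOverlap, minIdentity, stride, best);
    best_offset(brc, a, ix, 1, (long) minOverlap, minIdentity, stride, best);
    return NumericVector::create(best.found ? 1 : 0,
                                 best.strand == 0 ? 1 : -1,
                                 (double) best.offset, (double) best.overlap,
                                 (double) best.matches, best.identity);
}

// Pile base votes of placed reads into a 4 x width count matrix.
// offsets are 0-based positions of read base 1 relative to column `lo`
// (i.e. column index = offset - lo + i for read base i, 0-based).
// [[Rcpp::export(name = ".C_pileup")]]
IntegerMatrix C_pileup(CharacterVector reads, IntegerVector strands,
                       IntegerVector offsets, int lo, int width) {
    IntegerMatrix votes(4, width);
    for (int r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        if (strands[r] < 0) s = revcomp(s);
        const int off = offsets[r] - lo;
        for (int i = 0; i < (int) s.size(); ++i) {
            const int col = off + i;
            if (col < 0 || col >= width) continue;
            const int c = nt_code(s[i]);
            if (c >= 0) ++votes(c, col);
        }
    }
    return votes;
}

// ---- terminal direct repeats -------------------------------------------------

// KMP prefix-function borders of s (longest proper prefix == suffix chain)
// [[Rcpp::export(name = ".C_borders")]]
IntegerVector C_borders(std::string s) {
    const int n = (int) s.size();
    std::vector<int> pi(n, 0);
    for (int i = 1; i < n; ++i) {
        int j = pi[i - 1];
        while (j > 0 && s[i] != s[j]) j = pi[j - 1];
        if (s[i] == s[j]) ++j;
        pi[i] = j;
    }
    std::vector<int> chain;
    int b = n ? pi[n - 1] : 0;
    while (b > 0) { chain.push_back(b); b = pi[b - 1]; }
    return wrap(chain);
}

// Longest terminal repeat with mismatch fraction <= maxMM (0 = exact).
// [[Rcpp::export(name = ".C_terminal_repeat")]]
int C_terminal_repeat(std::string s, int minLen, double maxMM) {
    const int n = (int) s.size();
    if (maxMM <= 0) {
        IntegerVector ch = C_borders(s);
        for (int i = 0; i < ch.size(); ++i)
            if (ch[i] >= minLen && ch[i] < n) return ch[i];
        return 0;
    }
    for (int L = n - 1; L >= minLen; --L) {
        const int allowed = (int) (maxMM * L);
        int mm = 0; bool ok = true;
        for (int i = 0; i < L; ++i) {
            if (s[i] != s[n - L + i] && ++mm > allowed) { ok = false; break; }
        }
        if (ok) return L;
    }
    return 0;
}
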