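#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// 2-bit base code; anything outside ACGT (upper case) is -1 and always
// counts as a mismatch, including N-vs-N.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static void revcomp_into(const char* s, int n, std::vector<char>& out) {
  out.resize(n);
  for (int i = 0; i < n; ++i) out[n - 1 - i] = comp_base(s[i]);
}

struct Placement {
  int pos;   // 0-based leftmost coordinate on the genome
  int mm;    // Hamming distance over the full read length
};

// k-mer position index over the genome: chained flat hash (power-of-two
// buckets, int links) for cache-friendly lookups.  k-mers containing
// non-ACGT are skipped - they can never anchor a mismatch-free seed.
class GenomeIndex {
public:
  const char* seq;
  int glen;
  int k;
  uint32_t mask_buckets;
  std::vector<int> head;         // bucket -> first entry (-1 = empty)
  std::vector<int> next;         // entry chain
  std::vector<int> pos;          // entry -> genome position
  std::vector<uint64_t> key;     // entry -> full k-mer (collision check)

  static inline uint32_t hash64(uint64_t x) {
    x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
    x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
    x ^= x >> 33;
    return (uint32_t) x;
  }

  GenomeIndex(const char* s, int n, int k_) : seq(s), glen(n), k(k_) {
    size_t nb = 64;
    while (nb < (size_t) (2 * (n > 0 ? n : 1))) nb <<= 1;
    mask_buckets = (uint32_t) (nb - 1);
    head.assign(nb, -1);
    if (n < k) return;
    next.reserve(n); pos.reserve(n); key.reserve(n);
    const uint64_t kmask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t cur = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { valid = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint64_t) c) & kmask;
      if (++valid >= k) {
        const uint32_t b = hash64(cur) & mask_buckets;
        next.push_back(head[b]);
        pos.push_back(i - k + 1);
        key.push_back(cur);
        head[b] = (int) pos.size() - 1;
      }
    }
  }

  inline void lookup(uint64_t kmer, std::vector<int>& hits) const {
    for (int e = head[hash64(kmer) & mask_buckets]; e >= 0; e = next[e])
      if (key[e] == kmer) hits.push_back(pos[e]);
  }
};

// All full-length ungapped placements of `read` with Hamming distance
// <= max_mm.  Exact: with max_mm+1 disjoint seed segments, any
// qualifying placement has at least one mismatch-free segment whose
// first k bases must hit the k-mer index (pigeonhole).  Reads too short
// to carry the seeds fall back to scanning every offset.
static void find_placements(const GenomeIndex& gi, const char* read, int L,
                            int max_mm, std::vector<int>& scratch,
                            std::vector<Placement>& out) {
  const int G = gi.glen;
  if (L > G) stop("read (%d bp) longer than genome (%d bp)", L, G);
  const int nseed = max_mm + 1;
  scratch.clear();

  if (L >= nseed * gi.k) {
    for (int s = 0; s < nseed; ++s) {
      const int off = (int) ((long long) s * L / nseed);
      uint64_t kmer = 0;
      bool ok = true;
      for (int j = 0; j < gi.k; ++j) {
        const int c = base_code(read[off + j]);
        if (c < 0) { ok = false; break; }
        kmer = (kmer << 2) | (uint64_t) c;
      }
      if (!ok) continue;
      const size_t before = scratch.size();
      gi.lookup(kmer, scratch);
      for (size_t h = before; h < scratch.size(); ++h) scratch[h] -= off;
    }
    std::sort(scratch.begin(), scratch.end());
    scratch.erase(std::unique(scratch.begin(), scratch.end()),
                  scratch.end());
  } else {
    scratch.resize(G - L + 1);
    for (int i = 0; i <= G - L; ++i) scratch[i] = i;
  }

  for (size_t ci = 0; ci < scratch.size(); ++ci) {
    const int cand = scratch[ci];
    if (cand < 0 || cand + L > G) continue;
    int mm = 0;
    const char* g = gi.seq + cand;
    for (int j = 0; j < L; ++j) {
      const char a = read[j];
      if (a != g[j] || base_code(a) < 0) {
        if (++mm > max_mm) break;
      }
    }
    if (mm <= max_mm) {
      Placement p; p.pos = cand; p.mm = mm;
      out.push_back(p);
    }
  }
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  std::vector<char> buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    const int n = (int) LENGTH(STRING_ELT(seqs, i));
    revcomp_into(s, n, buf);
    out[i] = std::string(buf.begin(), buf.end());
  }
  return out;
}

// [[Rcpp::export]]
DataFrame enumerate_placements_cpp(std::string genome, CharacterVector reads,
                                   int max_mm, int k) {
  GenomeIndex gi(genome.c_str(), (int) genome.size(), k);
  std::vector<int> r_read, r_pos, r_mm;
  std::vector<std::string> r_strand;
  std::vector<int> scratch;
  std::vector<char> rc;
  std::vector<Placement> pf, pr;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* fwd = CHAR(STRING_ELT(reads, i));
    const int L = (int) LENGTH(STRING_ELT(reads, i));
    revcomp_into(fwd, L, rc);
    pf.clear(); pr.clear();
    find_placements(gi, fwd, L, max_mm, scratch, pf);
    find_placements(gi, rc.data(), L, max_mm, scratch, pr);
    for (size_t j = 0; j < pf.size(); ++j) {
      r_read.push_back((int) i + 1); r_pos.push_back(pf[j].pos);
      r_mm.push_back(pf[j].mm); r_strand.push_back("+");
    }
    for (size_t j = 0; j < pr.size(); ++j) {
      r_read.push_back((int) i + 1); r_pos.push_back(pr[j].pos);
      r_mm.push_back(pr[j].mm); r_strand.push_back("-");
    }
  }
  return DataFrame::create(_["read"] = r_read, _["pos"] = r_pos,
                           _["strand"] = r_strand, _["mismatches"] = r_mm,
                           _["stringsAsFactors"] = false);
}

// Competitive paired-end alignment of all pairs against one genome.
// Proper pair: forward-reverse orientation, forward mate upstream, inner
// insert (gap between mate ends) within [min_insert, max_insert].
// Pair score: sum over mates of (matches - mismatches).
// [[Rcpp::export]]
DataFrame align_pairs_cpp(std::string genome,
                          CharacterVector mate1, CharacterVector mate2,
                          int max_mm, int min_insert, int max_insert, int k) {
  if (mate1.size() != mate2.size()) stop("mate1 and mate2 differ in length");
  const R_xlen_t n = mate1.size();
  GenomeIndex gi(genome.c_str(), (int) genome.size(), k);

  LogicalVector any_mapped(n), properly_paired(n), perfect(n);
  IntegerVector score(n, NA_INTEGER), mapped_bases(n, NA_INTEGER);
  IntegerVector mm1(n, NA_INTEGER), mm2(n, NA_INTEGER);
  IntegerVector pos1(n, NA_INTEGER), pos2(n, NA_INTEGER);
  IntegerVector n_best(n, 0);
  CharacterVector strand1(n, NA_STRING);

  std::vector<int> scratch;
  std::vector<char> rc;
  std::vector<Placement> f1, r1, f2, r2;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* m1 = CHAR(STRING_ELT(mate1, i));
    const int L1 = (int) LENGTH(STRING_ELT(mate1, i));
    const char* m2 = CHAR(STRING_ELT(mate2, i));
    const int L2 = (int) LENGTH(STRING_ELT(mate2, i));
    f1.clear(); r1.clear(); f2.clear(); r2.clear();
    find_placements(gi, m1, L1, max_mm, scratch, f1);
    revcomp_into(m1, L1, rc);
    find_placements(gi, rc.data(), L1, max_mm, scratch, r1);
    find_placements(gi, m2, L2, max_mm, scratch, f2);
    revcomp_into(m2, L2, rc);
    find_placements(gi, rc.data(), L2, max_mm, scratch, r2);
    any_mapped[i] = !(f1.empty() && r1.empty() && f2.empty() && r2.empty());

    int best = INT_MIN, nb = 0;
    // primary = co-best combo with the smallest fragment start,
    // mate1-forward orientation first, then smaller reverse-mate pos
    int b_pos1 = 0, b_pos2 = 0, b_mm1 = 0, b_mm2 = 0;
    bool b_m1fwd = true, have = false;

    // orientation A: mate1 forward, mate2 reverse
    for (size_t a = 0; a < f1.size(); ++a) {
      for (size_t b = 0; b < r2.size(); ++b) {
        const int inner = r2[b].pos - (f1[a].pos + L1);
        if (inner < min_insert || inner > max_insert) continue;
        const int sc = (L1 - 2 * f1[a].mm) + (L2 - 2 * r2[b].mm);
        if (!have || sc > best) {
          best = sc; nb = 1; have = true;
          b_pos1 = f1[a].pos; b_pos2 = r2[b].pos;
          b_mm1 = f1[a].mm; b_mm2 = r2[b].mm; b_m1fwd = true;
        } else if (sc == best) {
          ++nb;
          if (f1[a].pos < b_pos1 ||
              (f1[a].pos == b_pos1 && r2[b].pos < b_pos2)) {
            b_pos1 = f1[a].pos; b_pos2 = r2[b].pos;
            b_mm1 = f1[a].mm; b_mm2 = r2[b].mm; b_m1fwd = true;
          }
        }
      }
    }
    // orientation B: mate2 forward, mate1 reverse
    for (size_t a = 0; a < f2.size(); ++a) {
      for (size_t b = 0; b < r1.size(); ++b) {
        const int inner = r1[b].pos - (f2[a].pos + L2);
        if (inner < min_insert || inner > max_insert) continue;
        const int sc = (L2 - 2 * f2[a].mm) + (L1 - 2 * r1[b].mm);
        const int frag_start = f2[a].pos;
        const int cur_start = b_m1fwd ? b_pos1 : b_pos2;
        if (!have || sc > best) {
          best = sc; nb = 1; have = true;
          b_pos1 = r1[b].pos; b_pos2 = f2[a].pos;
          b_mm1 = r1[b].mm; b_mm2 = f2[a].mm; b_m1fwd = false;
        } else if (sc == best) {
          ++nb;
          if (frag_start < cur_start ||
              (frag_start == cur_start && !b_m1fwd &&
               r1[b].pos < b_pos1)) {
            b_pos1 = r1[b].pos; b_pos2 = f2[a].pos;
            b_mm1 = r1[b].mm; b_mm2 = f2[a].mm; b_m1fwd = false;
          }
        }
      }
    }

    if (have) {
      properly_paired[i] = true;
      score[i] = best;
      perfect[i] = (best == L1 + L2);
      mapped_bases[i] = L1 + L2;
      mm1[i] = b_mm1; mm2[i] = b_mm2;
      pos1[i] = b_pos1; pos2[i] = b_pos2;
      strand1[i] = b_m1fwd ? "+" : "-";
      n_best[i] = nb;
    }
  }

  return DataFrame::create(
    _["any_mapped"] = any_mapped, _["properly_paired"] = properly_paired,
    _["score"] = score, _["perfect"] = perfect,
    _["mapped_bases"] = mapped_bases,
    _["mm1"] = mm1, _["mm2"] = mm2,
    _["pos1"] = pos1, _["pos2"] = pos2,
    _["strand1"] = strand1, _["n_best"] = n_best,
    _["stringsAsFactors"] = false);
}

// Substitution errors: replace read[pos] with a base drawn uniformly from
// the three alternatives, using R's RNG so a set.seed() upstream fixes
// the outcome.
// [[Rcpp::export]]
CharacterVector inject_substitutions_cpp(CharacterVector reads, List pos) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  RNGScope scope;
  CharacterVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    IntegerVector p = pos[i];
    for (int j = 0; j < p.size(); ++j) {
      const int at = p[j] - 1;  // 1-based in
      if (at < 0 || at >= (int) r.size()) stop("error position out of range");
      const char orig = r[at];
      char nb;
      do {
        nb = bases[(int) std::floor(unif_rand() * 4.0) & 3];
      } while (nb == orig);
      r[at] = nb;
    }
    out[i] = r;
  }
  return out;
}
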