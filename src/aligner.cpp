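// k-mer seed-and-extend local aligner used for exon lift-over.
// Seeds: exact k-mer matches against a sorted seed table of the target
// genome; candidate loci are diagonal clusters of seeds; extension is a
// windowed affine-gap Smith-Waterman with full traceback so that matches,
// mismatches, gap opens and alignment columns are reported exactly.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char baseComp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = baseComp(c);
  return r;
}

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // parallel arrays sorted by key
  std::vector<uint64_t> keys;
  std::vector<uint32_t> chrom;
  std::vector<uint32_t> pos;  // 0-based
};

// encode a k-mer; returns false if it contains a non-ACGT base
bool encodeKmer(const std::string& s, size_t from, int k, uint64_t& out) {
  uint64_t val = 0;
  for (int i = 0; i < k; ++i) {
    int code = baseCode(s[from + i]);
    if (code < 0) return false;
    val = (val << 2) | static_cast<uint64_t>(code);
  }
  out = val;
  return true;
}

struct EqualRange {
  size_t lo, hi;  // [lo, hi)
};

EqualRange lookupKey(const SeedIndex& idx, uint64_t key) {
  auto lo = std::lower_bound(idx.keys.begin(), idx.keys.end(), key);
  auto hi = std::upper_bound(lo, idx.keys.end(), key);
  return {static_cast<size_t>(lo - idx.keys.begin()),
          static_cast<size_t>(hi - idx.keys.begin())};
}

// ---- affine-gap local alignment with traceback --------------------------

struct Aln {
  long score = -1;
  int matches = 0, mismatches = 0, gapOpens = 0, columns = 0;
  int qstart = 0, qend = -1;  // 0-based inclusive, in the oriented query
  long gstart = 0, gend = -1; // 0-based inclusive, window coordinates
  bool valid = false;
};

Aln localAlign(const std::string& q, const std::string& g,
               int matchS, int mismatchS, int gapOpenS, int gapExtS) {
  const int n = static_cast<int>(q.size());
  const int m = static_cast<int>(g.size());
  const long NEG = -1000000000L;
  const long gapFirst = static_cast<long>(gapOpenS) + gapExtS;

  // H: best local score at (i,j); E: gap consuming genome; F: gap consuming
  // query. Traceback codes — tbH: 0 stop, 1 diag, 2 from E, 3 from F;
  // tbE/tbF: 0 opened from H, 1 extended.
  std::vector<long> H(static_cast<size_t>(n + 1) * (m + 1), 0);
  std::vector<long> E(static_cast<size_t>(n + 1) * (m + 1), NEG);
  std::vector<long> F(static_cast<size_t>(n + 1) * (m + 1), NEG);
  std::vector<uint8_t> tbH(H.size(), 0), tbE(H.size(), 0), tbF(H.size(), 0);
  auto at = [m](int i, int j) {
    return static_cast<size_t>(i) * (m + 1) + j;
  };

  long best = 0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = at(i, j);
      long eOpen = H[at(i, j - 1)] + gapFirst;
      long eExt = E[at(i, j - 1)] + gapExtS;
      if (eOpen >= eExt) { E[c] = eOpen; tbE[c] = 0; } else { E[c] = eExt; tbE[c] = 1; }
      long fOpen = H[at(i - 1, j)] + gapFirst;
      long fExt = F[at(i - 1, j)] + gapExtS;
      if (fOpen >= fExt) { F[c] = fOpen; tbF[c] = 0; } else { F[c] = fExt; tbF[c] = 1; }
      bool isMatch = baseCode(q[i - 1]) >= 0 && baseCode(q[i - 1]) == baseCode(g[j - 1]);
      long diag = H[at(i - 1, j - 1)] + (isMatch ? matchS : mismatchS);
      long h = 0; uint8_t tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[c] > h) { h = E[c]; tb = 2; }
      if (F[c] > h) { h = F[c]; tb = 3; }
      H[c] = h; tbH[c] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  Aln a;
  if (best <= 0) return a;
  a.valid = true;
  a.score = best;
  a.qend = bi - 1;
  a.gend = bj - 1;

  int i = bi, j = bj;
  int state = 0;  // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 && j > 0) {
    const size_t c = at(i, j);
    if (state == 0) {
      uint8_t tb = tbH[c];
      if (tb == 0) break;
      if (tb == 1) {
        bool isMatch = baseCode(q[i - 1]) >= 0 && baseCode(q[i - 1]) == baseCode(g[j - 1]);
        if (isMatch) ++a.matches; else ++a.mismatches;
        ++a.columns;
        --i; --j;
      } else if (tb == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // gap consuming genome base
      ++a.columns;
      if (tbE[c] == 0) { ++a.gapOpens; state = 0; }
      --j;
    } else {  // gap consuming query base
      ++a.columns;
      if (tbF[c] == 0) { ++a.gapOpens; state = 0; }
      --i;
    }
  }
  a.qstart = i;
  a.gstart = j;
  return a;
}

struct Seed {
  uint32_t chrom;
  long diag;
  int qpos;
  long gpos;
};

struct Candidate {
  uint32_t chrom;
  long wstart, wend;  // 0-based half-open window on the chromosome
  int nseeds;
};

struct Hit {
  bool valid = false;
  uint32_t chrom = 0;
  long gstart = 0, gend = -1;  // 0-based inclusive, chromosome coords
  char strand = '+';
  long score = -1;
  int matches = 0, mismatches = 0, gapOpens = 0, columns = 0;
  int qstart = 0, qend = -1;   // 0-based inclusive, oriented query
};

// true if a is a better hit than b, with deterministic tie-breaking:
// (score, identity, columns) maximized, then lowest (chrom name, start),
// then '+' before '-'.
bool betterHit(const Hit& a, const Hit& b, const std::vector<std::string>& names) {
  if (!b.valid) return a.valid;
  if (!a.valid) return false;
  if (a.score != b.score) return a.score > b.score;
  double ia = a.columns > 0 ? static_cast<double>(a.matches) / a.columns : 0.0;
  double ib = b.columns > 0 ? static_cast<double>(b.matches) / b.columns : 0.0;
  if (ia != ib) return ia > ib;
  if (a.columns != b.columns) return a.columns > b.columns;
  int cmp = names[a.chrom].compare(names[b.chrom]);
  if (cmp != 0) return cmp < 0;
  if (a.gstart != b.gstart) return a.gstart < b.gstart;
  return a.strand == '+' && b.strand == '-';
}

}  // namespace

// [[Rcpp::export(name = ".seed_index_build")]]
SEXP seed_index_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::vector<std::string> names, ss;
  CharacterVector nm = seqs.names();
  size_t maxLen = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    names.push_back(as<std::string>(nm[i]));
    ss.push_back(as<std::string>(seqs[i]));
    maxLen = std::max(maxLen, ss.back().size());
  }
  if (ss.empty()) stop("genome is empty");
  if (static_cast<size_t>(k) > maxLen)
    stop("k (%d) is larger than every genome sequence", k);

  XPtr<SeedIndex> xp(new SeedIndex(), true);
  xp->k = k;
  xp->names = names;
  xp->seqs = ss;

  std::vector<std::pair<uint64_t, uint64_t>> recs;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (size_t ci = 0; ci < ss.size(); ++ci) {
    const std::string& s = ss[ci];
    uint64_t val = 0;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int code = baseCode(s[i]);
      if (code < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | static_cast<uint64_t>(code)) & mask;
      if (++run >= k)
        recs.emplace_back(val, (static_cast<uint64_t>(ci) << 32) |
                                   static_cast<uint64_t>(i - k + 1));
    }
  }
  std::sort(recs.begin(), recs.end());
  xp->keys.reserve(recs.size());
  xp->chrom.reserve(recs.size());
  xp->pos.reserve(recs.size());
  for (const auto& r : recs) {
    xp->keys.push_back(r.first);
    xp->chrom.push_back(static_cast<uint32_t>(r.second >> 32));
    xp->pos.push_back(static_cast<uint32_t>(r.second & 0xffffffffULL));
  }
  return xp;
}

// [[Rcpp::export(name = ".seed_index_info")]]
List seed_index_info(SEXP xpsexp) {
  XPtr<SeedIndex> xp(xpsexp);
  return List::create(_["k"] = xp->k,
                      _["names"] = wrap(xp->names),
                      _["n_seeds"] = static_cast<double>(xp->keys.size()));
}

// Positions (0-based) of an exact k-mer; strand "-" looks up its reverse
// complement.
// [[Rcpp::export(name = ".seed_index_lookup")]]
List seed_index_lookup(SEXP xpsexp, std::string kmer, std::string strand) {
  XPtr<SeedIndex> xp(xpsexp);
  if (static_cast<int>(kmer.size()) != xp->k)
    stop("query k-mer length (%d) does not match index k (%d)",
         static_cast<int>(kmer.size()), xp->k);
  std::string q = (strand == "-") ? revcomp(kmer) : kmer;
  std::vector<int> chroms;
  std::vector<double> poss;
  uint64_t key;
  if (encodeKmer(q, 0, xp->k, key)) {
    EqualRange r = lookupKey(*xp, key);
    for (size_t i = r.lo; i < r.hi; ++i) {
      chroms.push_back(static_cast<int>(xp->chrom[i]));
      poss.push_back(static_cast<double>(xp->pos[i]));
    }
  }
  return List::create(_["chrom"] = wrap(chroms), _["pos"] = wrap(poss));
}

// Best single local alignment of `query` against the indexed genome.
// Returns an empty list when no seed matches or the best alignment covers
// less than min_coverage of the query.
// [[Rcpp::export(name = ".seed_align_query")]]
List seed_align_query(SEXP xpsexp, std::string query, double min_coverage,
                      int band, int max_clusters, int max_kmer_hits,
                      int match, int mismatch, int gap_open, int gap_ext) {
  XPtr<SeedIndex> xp(xpsexp);
  const int k = xp->k;
  const int qlen = static_cast<int>(query.size());
  if (qlen < k) return List::create();

  Hit best;
  const int pad = band + 8;

  for (int si = 0; si < 2; ++si) {
    const char strand = (si == 0) ? '+' : '-';
    const std::string q = (si == 0) ? query : revcomp(query);

    // collect seeds
    std::vector<Seed> seeds;
    for (int qpos = 0; qpos + k <= qlen; ++qpos) {
      uint64_t key;
      if (!encodeKmer(q, qpos, k, key)) continue;
      EqualRange r = lookupKey(*xp, key);
      if (r.hi - r.lo > static_cast<size_t>(max_kmer_hits)) continue;
      for (size_t i = r.lo; i < r.hi; ++i) {
        Seed s;
        s.chrom = xp->chrom[i];
        s.gpos = static_cast<long>(xp->pos[i]);
        s.qpos = qpos;
        s.diag = s.gpos - qpos;
        seeds.push_back(s);
      }
    }
    if (seeds.empty()) continue;
    std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      if (a.diag != b.diag) return a.diag < b.diag;
      return a.gpos < b.gpos;
    });

    // cluster seeds whose diagonals are within `band` of their neighbour
    std::vector<Candidate> cands;
    size_t i0 = 0;
    for (size_t i = 1; i <= seeds.size(); ++i) {
      bool brk = (i == seeds.size()) || seeds[i].chrom != seeds[i0].chrom ||
                 (seeds[i].diag - seeds[i - 1].diag) > band;
      if (!brk) continue;
      long dmin = seeds[i0].diag, dmax = seeds[i - 1].diag;
      Candidate c;
      c.chrom = seeds[i0].chrom;
      c.nseeds = static_cast<int>(i - i0);
      const long slen = static_cast<long>(xp->seqs[c.chrom].size());
      c.wstart = std::max(0L, dmin - pad);
      c.wend = std::min(slen, dmax + qlen + pad);
      if (c.wend > c.wstart) cands.push_back(c);
      i0 = i;
    }
    if (static_cast<int>(cands.size()) > max_clusters) {
      std::stable_sort(cands.begin(), cands.end(),
                       [](const Candidate& a, const Candidate& b) {
                         return a.nseeds > b.nseeds;
                       });
      cands.resize(max_clusters);
    }

    for (const Candidate& c : cands) {
      const std::string window =
          xp->seqs[c.chrom].substr(c.wstart, c.wend - c.wstart);
      Aln a = localAlign(q, window, match, mismatch, gap_open, gap_ext);
      if (!a.valid) continue;
      if (a.qend - a.qstart + 1 < min_coverage * qlen) continue;
      Hit h;
      h.valid = true;
      h.chrom = c.chrom;
      h.gstart = c.wstart + a.gstart;
      h.gend = c.wstart + a.gend;
      h.strand = strand;
      h.score = a.score;
      h.matches = a.matches;
      h.mismatches = a.mismatches;
      h.gapOpens = a.gapOpens;
      h.columns = a.columns;
      h.qstart = a.qstart;
      h.qend = a.qend;
      if (betterHit(h, best, xp->names)) best = h;
    }
  }

  if (!best.valid) return List::create();
  double identity = 100.0 * best.matches / best.columns;
  return List::create(
      _["chrom"] = xp->names[best.chrom],
      _["start"] = static_cast<double>(best.gstart + 1),  // 1-based
      _["end"] = static_cast<double>(best.gend + 1),
      _["strand"] = std::string(1, best.strand),
      _["score"] = static_cast<double>(best.score),
      _["matches"] = best.matches,
      _["mismatches"] = best.mismatches,
      _["gap_opens"] = best.gapOpens,
      _["columns"] = best.columns,
      _["percent_identity"] = identity,
      _["query_start"] = best.qstart + 1,
      _["query_end"] = best.qend + 1);
}
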