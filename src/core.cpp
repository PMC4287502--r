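#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// Quality-scaled mismatch penalty: interpolates between mm_min and mm_max by
// base quality, capped at Q40. N (in read or genome) costs n_pen.
static inline int mm_penalty(int q, int mm_min, int mm_max) {
  if (q > 40) q = 40;
  if (q < 0) q = 0;
  return (int)std::lround(mm_min + (mm_max - mm_min) * (double)q / 40.0);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// Score an ungapped placement of `read` at genome offset `off` (0-based).
// Returns the (non-positive) alignment score, or INT_MIN-ish sentinel when the
// accumulated penalty exceeds `budget` (score would fall below the minimum).
static inline int score_at(const std::string& g, const std::string& rd,
                           const std::string& qu, size_t off, int budget,
                           int mm_min, int mm_max, int n_pen) {
  int pen = 0;
  const size_t L = rd.size();
  for (size_t i = 0; i < L; ++i) {
    const char rb = rd[i], gb = g[off + i];
    if (rb != gb) {
      if (rb == 'N' || gb == 'N')
        pen += n_pen;
      else
        pen += mm_penalty((int)qu[i] - 33, mm_min, mm_max);
      if (pen > budget) return INT_MIN / 2;
    } else if (rb == 'N') {  // N==N still carries the N penalty
      pen += n_pen;
      if (pen > budget) return INT_MIN / 2;
    }
  }
  return -pen;
}

// Batch ungapped scan of reads against one contig (one fixed orientation; the
// caller reverse-complements reads for the opposite orientation).
//
// Exact k-mer seeding: a placement with total penalty <= budget can have at
// most maxMM mismatching positions, where maxMM is the largest count of
// per-base minimum mismatch costs (sorted ascending) fitting in the budget.
// With floor(L/k) disjoint k-seeds and k <= L/(maxMM+1), at least one seed is
// mismatch-free, so every offset meeting the score threshold is recovered
// from an exact seed hit. Reads too short for that guarantee, or scans where
// use_index is FALSE (e.g. genomes containing N), take the full O(G) scan.
//
// [[Rcpp::export]]
List cpp_scan_batch(std::string genome, std::vector<std::string> reads,
                    std::vector<std::string> quals, NumericVector min_scores,
                    int mm_max, int mm_min, int n_pen, bool use_index, int k,
                    bool keep_hits) {
  const size_t n = reads.size();
  const size_t glen = genome.size();

  // CSR k-mer index of the contig
  std::vector<int> cnt, off_tab, pos_tab;
  const size_t tab = (size_t)1 << (2 * k);
  if (use_index && glen >= (size_t)k) {
    cnt.assign(tab + 1, 0);
    // rolling encode with reset on non-ACGT
    std::vector<uint32_t> codes(glen >= (size_t)k ? glen - k + 1 : 0);
    std::vector<char> ok(codes.size(), 0);
    uint32_t code = 0;
    int run = 0;
    const uint32_t mask = (uint32_t)(tab - 1);
    for (size_t i = 0; i < glen; ++i) {
      int b = base_code(genome[i]);
      if (b < 0) {
        run = 0;
        code = 0;
      } else {
        code = ((code << 2) | (uint32_t)b) & mask;
        ++run;
      }
      if (run >= k) {
        size_t start = i - k + 1;
        codes[start] = code;
        ok[start] = 1;
      }
    }
    for (size_t i = 0; i < codes.size(); ++i)
      if (ok[i]) cnt[codes[i] + 1]++;
    off_tab.assign(tab + 1, 0);
    for (size_t i = 1; i <= tab; ++i) off_tab[i] = off_tab[i - 1] + cnt[i];
    pos_tab.assign(off_tab[tab], 0);
    std::vector<int> fill(off_tab.begin(), off_tab.end());
    for (size_t i = 0; i < codes.size(); ++i)
      if (ok[i]) pos_tab[fill[codes[i]]++] = (int)i;
  }

  IntegerVector best_pos(n, NA_INTEGER), best_score(n, NA_INTEGER),
      second_score(n, NA_INTEGER), n_hits(n, 0);
  std::vector<int> hr, hp, hs;

  std::vector<size_t> cand;
  std::vector<int> costs;
  for (size_t r = 0; r < n; ++r) {
    const std::string& rd = reads[r];
    const std::string& qu = quals[r];
    const size_t L = rd.size();
    if (L == 0 || L > glen) continue;
    const int budget = (int)std::floor(-min_scores[r] + 1e-9);
    if (budget < 0) continue;

    bool seeded = use_index && (size_t)k <= L;
    if (seeded) {
      // max mismatches affordable: sorted per-base minimum mismatch costs
      costs.clear();
      for (size_t i = 0; i < L; ++i)
        costs.push_back(rd[i] == 'N' ? n_pen
                                     : mm_penalty((int)qu[i] - 33, mm_min, mm_max));
      std::sort(costs.begin(), costs.end());
      int acc = 0;
      size_t maxmm = 0;
      while (maxmm < L && acc + costs[maxmm] <= budget) acc += costs[maxmm++];
      if ((size_t)k * (maxmm + 1) > L) seeded = false;
    }

    int b1 = INT_MIN, b2 = INT_MIN;  // best, second-best scores
    size_t b1pos = 0;
    int nh = 0;
    size_t hits_start = hr.size();

    if (seeded) {
      cand.clear();
      const size_t nseed = L / (size_t)k;
      for (size_t s = 0; s < nseed; ++s) {
        const size_t o = s * (size_t)k;
        uint32_t code = 0;
        bool good = true;
        for (size_t i = 0; i < (size_t)k; ++i) {
          int b = base_code(rd[o + i]);
          if (b < 0) { good = false; break; }
          code = (code << 2) | (uint32_t)b;
        }
        if (!good) continue;
        for (int j = off_tab[code]; j < off_tab[code + 1]; ++j) {
          long long offc = (long long)pos_tab[j] - (long long)o;
          if (offc >= 0 && (size_t)offc + L <= glen) cand.push_back((size_t)offc);
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        int sc = score_at(genome, rd, qu, cand[ci], budget, mm_min, mm_max, n_pen);
        if (sc >= min_scores[r]) {
          ++nh;
          if (keep_hits) {
            hr.push_back((int)r + 1);
            hp.push_back((int)cand[ci] + 1);
            hs.push_back(sc);
          }
          if (sc > b1 || (sc == b1 && cand[ci] < b1pos)) {
            if (sc > b1) { b2 = b1; b1 = sc; b1pos = cand[ci]; }
            else { b2 = std::max(b2, sc); b1pos = cand[ci]; }
          } else {
            b2 = std::max(b2, sc);
          }
        }
      }
    } else {
      for (size_t offc = 0; offc + L <= glen; ++offc) {
        int sc = score_at(genome, rd, qu, offc, budget, mm_min, mm_max, n_pen);
        if (sc >= min_scores[r]) {
          ++nh;
          if (keep_hits) {
            hr.push_back((int)r + 1);
            hp.push_back((int)offc + 1);
            hs.push_back(sc);
          }
          if (sc > b1) { b2 = b1; b1 = sc; b1pos = offc; }
          else b2 = std::max(b2, sc);
        }
      }
    }

    if (nh > 0) {
      best_pos[r] = (int)b1pos + 1;  // 1-based
      best_score[r] = b1;
      if (b2 > INT_MIN) second_score[r] = b2;
      n_hits[r] = nh;
    } else if (keep_hits) {
      hr.resize(hits_start);
      hp.resize(hits_start);
      hs.resize(hits_start);
    }
  }

  return List::create(_["best_pos"] = best_pos, _["best_score"] = best_score,
                      _["second_score"] = second_score, _["n_hits"] = n_hits,
                      _["hit_read"] = wrap(hr), _["hit_pos"] = wrap(hp),
                      _["hit_score"] = wrap(hs));
}

struct CigarOp {
  int len;
  char op;
};

static std::vector<CigarOp> parse_cigar(const std::string& cig) {
  std::vector<CigarOp> out;
  int len = 0;
  for (char c : cig) {
    if (c >= '0' && c <= '9') {
      len = len * 10 + (c - '0');
    } else {
      out.push_back({len, c});
      len = 0;
    }
  }
  return out;
}

// Methylation context of the cytosine whose top-strand coordinate is `ref`
// (0-based). For xg_ct the relevant base is a top-strand C read 5'->3' on top;
// for the bottom strand it is a top-strand G whose context reads 5'->3' on the
// bottom strand (i.e. leftwards on top, complemented). Returns 'Z' (CpG),
// 'X' (CHG), 'H' (CHH) or '.' when undefined (N nearby or contig edge).
static inline char context_at(const std::string& g, long long ref, bool xg_ct) {
  const long long glen = (long long)g.size();
  if (xg_ct) {
    if (ref + 1 >= glen) return '.';
    char n1 = g[ref + 1];
    if (n1 == 'G') return 'Z';
    if (n1 == 'N') return '.';
    if (ref + 2 >= glen) return '.';
    char n2 = g[ref + 2];
    if (n2 == 'G') return 'X';
    if (n2 == 'N') return '.';
    return 'H';
  } else {
    if (ref - 1 < 0) return '.';
    char n1 = g[ref - 1];
    if (n1 == 'C') return 'Z';
    if (n1 == 'N') return '.';
    if (ref - 2 < 0) return '.';
    char n2 = g[ref - 2];
    if (n2 == 'C') return 'X';
    if (n2 == 'N') return '.';
    return 'H';
  }
}

// Per-base methylation-call strings for alignments on one contig.
// seqs are in SAM (reference-forward) orientation; xg_ct[i] says whether the
// record derives from the top (C->T converted, TRUE) or bottom (G->A, FALSE)
// strand of the reference.
// [[Rcpp::export]]
CharacterVector cpp_xm_strings(std::string contig, IntegerVector pos,
                               CharacterVector seqs, CharacterVector cigars,
                               LogicalVector xg_ct) {
  const size_t n = seqs.size();
  CharacterVector out(n);
  for (size_t r = 0; r < n; ++r) {
    const std::string sq = as<std::string>(seqs[r]);
    const std::string cig = as<std::string>(cigars[r]);
    const bool ct = xg_ct[r];
    std::string xm(sq.size(), '.');
    long long ref = (long long)pos[r] - 1;  // 0-based
    size_t qi = 0;
    for (const CigarOp& co : parse_cigar(cig)) {
      switch (co.op) {
      case 'M': case '=': case 'X':
        for (int j = 0; j < co.len; ++j, ++qi, ++ref) {
          if (ref < 0 || ref >= (long long)contig.size()) continue;
          const char gb = contig[ref];
          const char rb = sq[qi];
          if (ct && gb == 'C') {
            char ctx = context_at(contig, ref, true);
            if (ctx == '.') continue;
            if (rb == 'C') xm[qi] = ctx;                  // methylated
            else if (rb == 'T') xm[qi] = (char)tolower(ctx);  // converted
            // any other base: mismatch, no call
          } else if (!ct && gb == 'G') {
            char ctx = context_at(contig, ref, false);
            if (ctx == '.') continue;
            if (rb == 'G') xm[qi] = ctx;
            else if (rb == 'A') xm[qi] = (char)tolower(ctx);
          }
        }
        break;
      case 'I': case 'S':
        qi += co.len;  // read-only ops: no call
        break;
      case 'D': case 'N':
        ref += co.len;
        break;
      default:  // H, P consume neither
        break;
      }
    }
    out[r] = xm;
  }
  return out;
}

// Expand XM strings into one row per methylation call (symbol != '.'),
// reporting the reference coordinate (1-based), the position within the
// original read (1-based, 5'->3' in sequencing orientation) and the base
// Phred score. `rev` flags reverse-orientation SAM records.
// [[Rcpp::export]]
List cpp_expand_calls(IntegerVector pos, CharacterVector cigars,
                      CharacterVector xm, CharacterVector qual,
                      LogicalVector rev) {
  std::vector<int> rec, refpos, readpos, phred;
  std::vector<char> call;
  const size_t n = xm.size();
  for (size_t r = 0; r < n; ++r) {
    const std::string x = as<std::string>(xm[r]);
    const std::string qu = as<std::string>(qual[r]);
    const std::string cig = as<std::string>(cigars[r]);
    const int L = (int)x.size();
    long long ref = (long long)pos[r] - 1;
    int qi = 0;
    for (const CigarOp& co : parse_cigar(cig)) {
      switch (co.op) {
      case 'M': case '=': case 'X':
        for (int j = 0; j < co.len; ++j, ++qi, ++ref) {
          const char sym = x[qi];
          if (sym != '.') {
            rec.push_back((int)r + 1);
            refpos.push_back((int)ref + 1);
            readpos.push_back(rev[r] ? (L - qi) : (qi + 1));
            call.push_back(sym);
            phred.push_back((int)qu[qi] - 33);
          }
        }
        break;
      case 'I': case 'S': qi += co.len; break;
      case 'D': case 'N': ref += co.len; break;
      default: break;
      }
    }
  }
  CharacterVector callv(call.size());
  for (size_t i = 0; i < call.size(); ++i) callv[i] = std::string(1, call[i]);
  return List::create(_["rec"] = wrap(rec), _["refpos"] = wrap(refpos),
                      _["readpos"] = wrap(readpos), _["call"] = callv,
                      _["phred"] = wrap(phred));
}

// Soft-clip-adjusted 5' coordinates (1-based): for forward records the leftmost
// mapped base minus leading soft clips; for reverse records the rightmost
// mapped base plus trailing soft clips.
// [[Rcpp::export]]
IntegerVector cpp_clip5(IntegerVector pos, CharacterVector cigars,
                        LogicalVector rev) {
  const size_t n = pos.size();
  IntegerVector out(n);
  for (size_t r = 0; r < n; ++r) {
    if (pos[r] == NA_INTEGER) { out[r] = NA_INTEGER; continue; }
    std::vector<CigarOp> ops = parse_cigar(as<std::string>(cigars[r]));
    int lead = 0, trail = 0, refcons = 0;
    size_t i = 0;
    while (i < ops.size() && (ops[i].op == 'H' || ops[i].op == 'S')) {
      if (ops[i].op == 'S') lead += ops[i].len;
      ++i;
    }
    size_t j = ops.size();
    while (j > i && (ops[j - 1].op == 'H' || ops[j - 1].op == 'S')) {
      if (ops[j - 1].op == 'S') trail += ops[j - 1].len;
      --j;
    }
    for (const CigarOp& co : ops)
      if (co.op == 'M' || co.op == 'D' || co.op == 'N' || co.op == '=' ||
          co.op == 'X')
        refcons += co.len;
    out[r] = rev[r] ? pos[r] + refcons - 1 + trail : pos[r] - lead;
  }
  return out;
}
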