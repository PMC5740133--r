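// Core alignment engine: w-mer seed index, greedy diagonal chaining,
// gapped x-drop extension, banded global/fitting DP, and pileup counting.
// Linear gap penalties throughout (one score per gap column).

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
#include <climits>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// ---------------------------------------------------------------------------
// Seed index
// ---------------------------------------------------------------------------

struct SeedIndex {
  std::vector<std::string> ids;
  std::vector<std::string> seqs;
  int w;
  double total_len;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> post;
};

// [[Rcpp::export(name = "C_build_index")]]
SEXP C_build_index(CharacterVector ids, CharacterVector seqs, int w) {
  if (w < 4 || w > 31) stop("word size must be between 4 and 31");
  SeedIndex* idx = new SeedIndex();
  idx->w = w;
  idx->total_len = 0.0;
  const uint64_t mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1ULL);
  for (int r = 0; r < ids.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    idx->ids.push_back(as<std::string>(ids[r]));
    idx->seqs.push_back(s);
    idx->total_len += (double)s.size();
    int64_t n = (int64_t)s.size();
    uint64_t key = 0;
    int run = 0;  // length of current valid (ACGT) run
    for (int64_t i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= w)
        idx->post[key].push_back({(int32_t)r, (int32_t)(i - w + 1)});
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = "C_index_valid")]]
bool C_index_valid(SEXP xp) {
  XPtr<SeedIndex> ptr(xp);
  return ptr.get() != NULL;
}

// [[Rcpp::export(name = "C_index_info")]]
List C_index_info(SEXP xp) {
  XPtr<SeedIndex> ptr(xp);
  if (!ptr) stop("stale index pointer");
  double npost = 0;
  for (const auto& kv : ptr->post) npost += (double)kv.second.size();
  return List::create(_["word_size"] = ptr->w,
                      _["total_db_length"] = ptr->total_len,
                      _["n_records"] = (int)ptr->ids.size(),
                      _["n_postings"] = npost,
                      _["record_ids"] = wrap(ptr->ids));
}

// ---------------------------------------------------------------------------
// Gapped x-drop extension (one direction) with traceback for statistics
// ---------------------------------------------------------------------------

struct ExtRes {
  int score = 0;
  int alen = 0, blen = 0;          // consumed lengths of A (query) and B
  int matches = 0, mism = 0, gaps = 0;
};

// Extend aligning prefixes of A against prefixes of B (both already oriented
// in the direction of extension). H(i,j) = best score aligning A[0..i) with
// B[0..j); cells more than xdrop below the running best are pruned.
static ExtRes xdrop_extend(const char* A, int lenA, const char* B, int lenB,
                           int match, int mismatch, int gap, int xdrop) {
  ExtRes res;
  if (lenA <= 0 || lenB <= 0) return res;
  std::vector<int> row_lo;                 // leftmost active j per row
  std::vector<std::vector<int>> rows;      // scores
  std::vector<std::vector<uint8_t>> dirs;  // 1=diag 2=up(gap in B) 3=left(gap in A)

  int best = 0, bi = 0, bj = 0;
  // row 0: H(0,j) = gap*j while within the drop-off
  {
    std::vector<int> r0; std::vector<uint8_t> d0;
    for (int j = 0; j <= lenB; ++j) {
      int v = gap * j;
      if (v < best - xdrop) break;
      r0.push_back(v); d0.push_back(j == 0 ? 0 : 3);
    }
    row_lo.push_back(0); rows.push_back(std::move(r0)); dirs.push_back(std::move(d0));
  }
  for (int i = 1; i <= lenA; ++i) {
    const std::vector<int>& prev = rows[i - 1];
    int plo = row_lo[i - 1];
    int phi = plo + (int)prev.size() - 1;
    std::vector<int> cur; std::vector<uint8_t> dcur;
    int clo = -1;
    int jmax = std::min(lenB, phi + 1);
    for (int j = std::max(0, plo); ; ++j) {
      if (j > lenB) break;
      int vdiag = NEG, vup = NEG, vleft = NEG;
      if (j >= 1 && j - 1 >= plo && j - 1 <= phi) {
        int s = (base_code(A[i - 1]) >= 0 && base_code(A[i - 1]) == base_code(B[j - 1]))
                  ? match : mismatch;
        vdiag = prev[j - 1 - plo] + s;
      }
      if (j >= plo && j <= phi) vup = prev[j - plo] + gap;
      if (clo >= 0 && j - 1 >= clo && !cur.empty() && cur.back() > NEG)
        vleft = cur.back() + gap;
      int v = std::max(vdiag, std::max(vup, vleft));
      uint8_t d = 0;
      if (v == vdiag) d = 1; else if (v == vup) d = 2; else d = 3;
      if (v < best - xdrop) { v = NEG; d = 0; }
      if (clo < 0) {
        if (v == NEG) {
          if (j >= jmax) break;  // nothing active yet and no predecessors left
          continue;
        }
        clo = j;
      }
      cur.push_back(v); dcur.push_back(v == NEG ? 0 : d);
      if (v > best) { best = v; bi = i; bj = j; }
      if (v == NEG && j > jmax) break;  // past predecessor window and pruned
    }
    // trim trailing pruned cells
    while (!cur.empty() && cur.back() == NEG) { cur.pop_back(); dcur.pop_back(); }
    while (!cur.empty() && cur.front() == NEG) {
      cur.erase(cur.begin()); dcur.erase(dcur.begin()); ++clo;
    }
    if (cur.empty()) break;
    row_lo.push_back(clo); rows.push_back(std::move(cur)); dirs.push_back(std::move(dcur));
  }
  // traceback from (bi, bj)
  res.score = best; res.alen = bi; res.blen = bj;
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    uint8_t d = dirs[i][j - row_lo[i]];
    if (d == 1) {
      bool eq = base_code(A[i - 1]) >= 0 && base_code(A[i - 1]) == base_code(B[j - 1]);
      if (eq) ++res.matches; else ++res.mism;
      --i; --j;
    } else if (d == 2) { ++res.gaps; --i; }
    else if (d == 3) { ++res.gaps; --j; }
    else break;  // pruned origin: should not happen on the best path
  }
  return res;
}

// ---------------------------------------------------------------------------
// align_read: seeds -> diagonal chains -> anchored two-sided x-drop extension
// ---------------------------------------------------------------------------

struct Hsp {
  int rec; int strand;  // 0 = '+', 1 = '-'
  int score;
  int qs, qe, ss, se;   // 0-based half-open, query in oriented coordinates
  int matches, mism, gaps;
};

static void align_one_orientation(const SeedIndex& idx, const std::string& q,
                                  int strand, int match, int mismatch, int gap,
                                  int xdrop, int max_seed_gap, int diag_slack,
                                  int max_posting, std::vector<Hsp>& out) {
  int w = idx.w;
  int lq = (int)q.size();
  if (lq < w) return;
  const uint64_t mask = (1ULL << (2 * w)) - 1ULL;
  // seeds grouped by (record, diagonal), diagonal = s_off - q_off
  std::map<std::pair<int32_t, int64_t>, std::vector<int32_t>> by_diag;
  uint64_t key = 0; int run = 0;
  for (int i = 0; i < lq; ++i) {
    int c = base_code(q[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run < w) continue;
    auto it = idx.post.find(key);
    if (it == idx.post.end()) continue;
    if ((int)it->second.size() > max_posting) continue;  // repeat filter
    int qoff = i - w + 1;
    for (const auto& p : it->second)
      by_diag[{p.first, (int64_t)p.second - qoff}].push_back(qoff);
  }
  // chains: runs of seeds on one diagonal with gaps <= max_seed_gap
  struct Chain { int rec; int64_t diag; int qs, qe, n, anchor; };
  std::vector<Chain> chains;
  for (auto& kv : by_diag) {
    std::vector<int32_t>& pos = kv.second;
    std::sort(pos.begin(), pos.end());
    size_t s0 = 0;
    for (size_t k = 1; k <= pos.size(); ++k) {
      if (k == pos.size() || pos[k] - pos[k - 1] > max_seed_gap) {
        Chain ch;
        ch.rec = kv.first.first; ch.diag = kv.first.second;
        ch.qs = pos[s0]; ch.qe = pos[k - 1] + w; ch.n = (int)(k - s0);
        int mid = (ch.qs + ch.qe) / 2;
        // seed start closest to the chain midpoint
        int bestd = INT_MAX, anchor = pos[s0];
        for (size_t t = s0; t < k; ++t) {
          int d = std::abs((int)pos[t] - mid);
          if (d < bestd) { bestd = d; anchor = pos[t]; }
        }
        ch.anchor = anchor;
        chains.push_back(ch);
        s0 = k;
      }
    }
  }
  std::stable_sort(chains.begin(), chains.end(), [](const Chain& a, const Chain& b) {
    if (a.n != b.n) return a.n > b.n;
    if (a.rec != b.rec) return a.rec < b.rec;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qs < b.qs;
  });
  std::vector<Hsp> acc;
  for (const Chain& ch : chains) {
    int ai = ch.anchor;
    int64_t aj64 = (int64_t)ai + ch.diag;
    if (aj64 < 0) continue;
    const std::string& S = idx.seqs[ch.rec];
    int aj = (int)aj64;
    if (aj + w > (int)S.size()) continue;
    bool contained = false;
    for (const Hsp& h : acc) {
      if (h.rec != ch.rec) continue;
      if (ai >= h.qs && ai < h.qe && aj >= h.ss && aj < h.se) {
        int64_t hdiag = ((int64_t)h.ss - h.qs + (int64_t)h.se - h.qe) / 2;
        if (std::llabs(ch.diag - hdiag) <= diag_slack) { contained = true; break; }
      }
    }
    if (contained) continue;
    // rightward from the anchor seed start; leftward over reversed prefixes
    ExtRes right = xdrop_extend(q.c_str() + ai, lq - ai, S.c_str() + aj,
                                (int)S.size() - aj, match, mismatch, gap, xdrop);
    std::string qa(q.rbegin() + (lq - ai), q.rend());
    std::string sa(S.rbegin() + ((int)S.size() - aj), S.rend());
    ExtRes left = xdrop_extend(qa.c_str(), ai, sa.c_str(), aj,
                               match, mismatch, gap, xdrop);
    Hsp h;
    h.rec = ch.rec; h.strand = strand;
    h.score = left.score + right.score;
    h.qs = ai - left.alen; h.qe = ai + right.alen;
    h.ss = aj - left.blen; h.se = aj + right.blen;
    h.matches = left.matches + right.matches;
    h.mism = left.mism + right.mism;
    h.gaps = left.gaps + right.gaps;
    if (h.score > 0 && h.qe > h.qs) acc.push_back(h);
  }
  out.insert(out.end(), acc.begin(), acc.end());
}

// [[Rcpp::export(name = "C_align_read")]]
DataFrame C_align_read(SEXP xp, std::string read, int match, int mismatch,
                       int gap, int xdrop, int max_seed_gap, int diag_slack,
                       int max_posting) {
  XPtr<SeedIndex> ptr(xp);
  if (!ptr) stop("stale index pointer; rebuild the index");
  std::vector<Hsp> hsps;
  align_one_orientation(*ptr, read, 0, match, mismatch, gap, xdrop,
                        max_seed_gap, diag_slack, max_posting, hsps);
  std::string rc = revcomp(read);
  align_one_orientation(*ptr, rc, 1, match, mismatch, gap, xdrop,
                        max_seed_gap, diag_slack, max_posting, hsps);
  // convert '-' strand query coordinates back to the original read
  int lq = (int)read.size();
  for (Hsp& h : hsps) {
    if (h.strand == 1) {
      int qs = lq - h.qe, qe = lq - h.qs;
      h.qs = qs; h.qe = qe;
    }
  }
  // merge: overlapping hits on one record keep the highest raw score
  std::stable_sort(hsps.begin(), hsps.end(), [](const Hsp& a, const Hsp& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.rec != b.rec) return a.rec < b.rec;
    if (a.ss != b.ss) return a.ss < b.ss;
    return a.qs < b.qs;
  });
  std::vector<Hsp> kept;
  for (const Hsp& h : hsps) {
    bool dup = false;
    for (const Hsp& k : kept) {
      if (k.rec == h.rec && h.qs < k.qe && k.qs < h.qe && h.ss < k.se && k.ss < h.se) {
        dup = true; break;
      }
    }
    if (!dup) kept.push_back(h);
  }
  int n = (int)kept.size();
  IntegerVector rec(n), score(n), qs(n), qe(n), ss(n), se(n),
      matches(n), mism(n), gaps(n);
  CharacterVector strand(n), rid(n);
  for (int i = 0; i < n; ++i) {
    const Hsp& h = kept[i];
    rec[i] = h.rec + 1;
    rid[i] = ptr->ids[h.rec];
    strand[i] = h.strand == 0 ? "+" : "-";
    score[i] = h.score; qs[i] = h.qs; qe[i] = h.qe; ss[i] = h.ss; se[i] = h.se;
    matches[i] = h.matches; mism[i] = h.mism; gaps[i] = h.gaps;
  }
  return DataFrame::create(
      _["record_id"] = rid, _["record"] = rec, _["strand"] = strand,
      _["raw_score"] = score, _["q_start"] = qs, _["q_end"] = qe,
      _["s_start"] = ss, _["s_end"] = se, _["matches"] = matches,
      _["mismatches"] = mism, _["gap_columns"] = gaps,
      _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Banded global / fitting alignment with traceback -> CIGAR
// ---------------------------------------------------------------------------

// Query a is always aligned end-to-end; if free_b_ends, leading/trailing
// unaligned subject is cost-free (fitting alignment, used for read mapping).
// Band: |j - i - diag0| <= band.
// [[Rcpp::export(name = "C_banded_align")]]
List C_banded_align(std::string a, std::string b, int match, int mismatch,
                    int gap, int band, bool free_b_ends, int diag0) {
  int la = (int)a.size(), lb = (int)b.size();
  auto jlo = [&](int i) { return std::max(0, i + diag0 - band); };
  auto jhi = [&](int i) { return std::min(lb, i + diag0 + band); };
  if (jlo(0) > 0 && !free_b_ends)
    return List::create(_["valid"] = false);
  if (jhi(la) < lb && !free_b_ends)
    return List::create(_["valid"] = false);
  if (jlo(la) > lb || jhi(0) < 0)
    return List::create(_["valid"] = false);
  std::vector<std::vector<int>> H(la + 1);
  std::vector<std::vector<uint8_t>> D(la + 1);
  for (int i = 0; i <= la; ++i) {
    int lo = jlo(i), hi = jhi(i);
    if (lo > hi) return List::create(_["valid"] = false);
    H[i].assign(hi - lo + 1, NEG);
    D[i].assign(hi - lo + 1, 0);
    for (int j = lo; j <= hi; ++j) {
      int v = NEG; uint8_t d = 0;
      if (i == 0) {
        v = free_b_ends ? 0 : gap * j;
        d = (j == 0) ? 0 : 3;
        if (free_b_ends) d = 0;
      } else {
        int plo = jlo(i - 1), phi = jhi(i - 1);
        if (j >= 1 && j - 1 >= plo && j - 1 <= phi && H[i - 1][j - 1 - plo] > NEG) {
          int s = (base_code(a[i - 1]) >= 0 &&
                   base_code(a[i - 1]) == base_code(b[j - 1])) ? match : mismatch;
          int cand = H[i - 1][j - 1 - plo] + s;
          if (cand > v) { v = cand; d = 1; }
        }
        if (j >= plo && j <= phi && H[i - 1][j - plo] > NEG) {
          int cand = H[i - 1][j - plo] + gap;
          if (cand > v) { v = cand; d = 2; }
        }
        if (j - 1 >= lo && H[i][j - 1 - lo] > NEG) {
          int cand = H[i][j - 1 - lo] + gap;
          if (cand > v) { v = cand; d = 3; }
        }
      }
      H[i][j - lo] = v; D[i][j - lo] = d;
    }
  }
  // terminal cell
  int lo_end = jlo(la), hi_end = jhi(la);
  int ti = la, tj;
  if (free_b_ends) {
    tj = lo_end; int bestv = NEG;
    for (int j = lo_end; j <= hi_end; ++j)
      if (H[la][j - lo_end] > bestv) { bestv = H[la][j - lo_end]; tj = j; }
  } else {
    tj = lb;
    if (tj < lo_end || tj > hi_end || H[la][tj - lo_end] <= NEG)
      return List::create(_["valid"] = false);
  }
  int score = H[ti][tj - jlo(ti)];
  if (score <= NEG) return List::create(_["valid"] = false);
  // traceback
  std::string ops;  // reversed op-per-column string
  int i = ti, j = tj;
  int matches = 0, mism = 0, gaps = 0;
  bool touched = false;
  int b_end = tj;
  while (i > 0 || (j > 0 && !free_b_ends)) {
    if (j > 0 && j < lb && (j == i + diag0 - band || j == i + diag0 + band))
      touched = true;
    uint8_t d = D[i][j - jlo(i)];
    if (d == 0) break;
    if (d == 1) {
      bool eq = base_code(a[i - 1]) >= 0 && base_code(a[i - 1]) == base_code(b[j - 1]);
      if (eq) ++matches; else ++mism;
      ops.push_back('M'); --i; --j;
    } else if (d == 2) { ++gaps; ops.push_back('I'); --i; }
    else { ++gaps; ops.push_back('D'); --j; }
  }
  int b_start = j;
  std::reverse(ops.begin(), ops.end());
  // run-length encode to CIGAR
  std::string cigar;
  for (size_t k = 0; k < ops.size();) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    cigar += std::to_string(k2 - k); cigar.push_back(ops[k]);
    k = k2;
  }
  return List::create(
      _["valid"] = true, _["score"] = score, _["cigar"] = cigar,
      _["matches"] = matches, _["mismatches"] = mism, _["gap_columns"] = gaps,
      _["columns"] = (int)ops.size(), _["b_start"] = b_start,
      _["b_end"] = b_end, _["touched_band_edge"] = touched);
}

// ---------------------------------------------------------------------------
// Pileup counting over CIGAR alignments against one reference
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = "C_pileup")]]
List C_pileup(std::string ref, CharacterVector qseqs, CharacterVector cigars,
              IntegerVector sstarts) {
  int L = (int)ref.size();
  int n = qseqs.size();
  IntegerMatrix counts(5, L);  // rows: A C G T del
  IntegerVector depth(L);
  std::vector<int> ins_pos; std::vector<std::string> ins_seq;
  std::vector<int> ins_read;
  for (int r = 0; r < n; ++r) {
    std::string q = as<std::string>(qseqs[r]);
    std::string cg = as<std::string>(cigars[r]);
    int sp = sstarts[r], qp = 0;
    int s0 = sp;
    size_t k = 0;
    while (k < cg.size()) {
      int len = 0;
      while (k < cg.size() && isdigit(cg[k])) len = len * 10 + (cg[k++] - '0');
      char op = cg[k++];
      if (op == 'M') {
        for (int t = 0; t < len; ++t) {
          if (sp >= 0 && sp < L) {
            int c = base_code(q[qp]);
            if (c >= 0) counts(c, sp) += 1;
          }
          ++sp; ++qp;
        }
      } else if (op == 'D') {
        for (int t = 0; t < len; ++t) {
          if (sp >= 0 && sp < L) counts(4, sp) += 1;
          ++sp;
        }
      } else if (op == 'I') {
        if (sp > s0 && sp < L) {  // interior junction only
          ins_pos.push_back(sp);
          ins_seq.push_back(q.substr(qp, len));
          ins_read.push_back(r + 1);
        }
        qp += len;
      } else stop("unsupported CIGAR op");
    }
    for (int j = std::max(0, s0); j < std::min(L, sp); ++j) depth[j] += 1;
  }
  return List::create(
      _["counts"] = counts, _["depth"] = depth,
      _["insertions"] = DataFrame::create(
          _["junction"] = wrap(ins_pos), _["read"] = wrap(ins_read),
          _["seq"] = wrap(ins_seq), _["stringsAsFactors"] = false));
}

// [[Rcpp::export(name = "C_revcomp")]]
std::string C_revcomp(std::string s) { return revcomp(s); }
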