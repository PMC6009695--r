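// Core sequence machinery: banded affine pairwise alignment, a seed-and-extend
// short-read mapper, local all-hits search, and a single-k de Bruijn assembler
// with trusted/untrusted guide-contig threading.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <map>
#include <array>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string rc_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector rc_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    out[i] = rc_str(s);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Banded affine-gap dynamic programming.
//
// Modes: "glocal" (query end-to-end, reference ends free), "local"
// (Smith-Waterman on both), "global" (both end-to-end).  Band restricts the
// diagonal j - i to [dlo, dhi].  Gap of length L costs gap_open + gap_ext * L.
// ---------------------------------------------------------------------------

struct Aln {
  bool ok = false;
  int score = 0;
  int q_start = 0, q_end = 0;   // 0-based half-open, in the query as given
  int r_start = 0, r_end = 0;
  int matches = 0, columns = 0; // columns counts M + I + D positions
  std::string cigar;
  std::vector<int> sub_q, sub_r; // mismatch coordinates
};

static const int NEG = -100000000;

static Aln band_dp(const std::string &Q, const std::string &R,
                   int mode, // 0 glocal, 1 local, 2 global
                   int dlo, int dhi,
                   int match = 1, int mismatch = -1,
                   int gap_open = 3, int gap_ext = 1) {
  Aln res;
  const int m = (int)Q.size(), n = (int)R.size();
  if (m == 0 || n == 0) return res;
  if (dlo > dhi) std::swap(dlo, dhi);
  dlo = std::max(dlo, -m);
  dhi = std::min(dhi, n);
  const int W = dhi - dlo + 1;
  if (W <= 0) return res;
  const int go = gap_open, ge = gap_ext;

  std::vector<int> M((size_t)(m + 1) * W, NEG), I((size_t)(m + 1) * W, NEG),
      D((size_t)(m + 1) * W, NEG);
  // traceback: 2 bits per state packed in a byte: M src (0 M,1 I,2 D,3 start),
  // I src (0 M, 1 I), D src (0 M, 1 D)
  std::vector<unsigned char> tb((size_t)(m + 1) * W, 0);

  auto IDX = [&](int i, int w) { return (size_t)i * W + w; };

  // row 0
  for (int w = 0; w < W; ++w) {
    int j = 0 + dlo + w;
    if (j < 0 || j > n) continue;
    if (mode == 2) { // global: leading ref gap penalised
      M[IDX(0, w)] = (j == 0) ? 0 : NEG;
      D[IDX(0, w)] = (j == 0) ? NEG : -(go + ge * j);
      if (j > 0) tb[IDX(0, w)] |= (j == 1 ? 0 : 1) << 4; // D from M at j==1
    } else {
      M[IDX(0, w)] = 0; // free start anywhere along the reference
      tb[IDX(0, w)] |= 3; // start
    }
  }

  int best = (mode == 1) ? 0 : NEG;
  int best_i = -1, best_w = -1, best_state = 0;

  for (int i = 1; i <= m; ++i) {
    const char qc = Q[i - 1];
    for (int w = 0; w < W; ++w) {
      int j = i + dlo + w;
      if (j < 0 || j > n) continue;
      size_t id = IDX(i, w);
      // I: consume query (gap in reference); predecessor (i-1, j) -> w+1
      if (w + 1 < W) {
        size_t up = IDX(i - 1, w + 1);
        int fromM = (M[up] <= NEG / 2) ? NEG : M[up] - (go + ge);
        int fromI = (I[up] <= NEG / 2) ? NEG : I[up] - ge;
        if (fromM >= fromI) { I[id] = fromM; }
        else { I[id] = fromI; tb[id] |= 1 << 2; }
      }
      if (j >= 1) {
        // M: diagonal predecessor (i-1, j-1) -> same w
        size_t di = IDX(i - 1, w);
        int sc = (qc == R[j - 1] && qc != 'N') ? match : mismatch;
        int bm = M[di], src = 0;
        if (I[di] > bm) { bm = I[di]; src = 1; }
        if (D[di] > bm) { bm = D[di]; src = 2; }
        if (bm > NEG / 2) {
          M[id] = bm + sc;
          tb[id] |= src;
        }
        if (mode == 1 && M[id] < 0) { M[id] = 0; tb[id] = (tb[id] & ~3) | 3; }
        // D: consume reference; predecessor (i, j-1) -> w-1
        if (w - 1 >= 0) {
          size_t lf = IDX(i, w - 1);
          int fromM = (M[lf] <= NEG / 2) ? NEG : M[lf] - (go + ge);
          int fromD = (D[lf] <= NEG / 2) ? NEG : D[lf] - ge;
          if (fromM >= fromD) { D[id] = fromM; }
          else { D[id] = fromD; tb[id] |= 1 << 4; }
        }
      }
      if (mode == 1) { // local: best anywhere, M state only
        if (M[id] > best) { best = M[id]; best_i = i; best_w = w; best_state = 0; }
      }
    }
  }

  if (mode == 1) {
    if (best <= 0 || best_i < 0) return res;
  } else if (mode == 2) {
    int w = n - m - dlo;
    if (w < 0 || w >= W) return res;
    size_t id = IDX(m, w);
    best = M[id]; best_state = 0;
    if (I[id] > best) { best = I[id]; best_state = 1; }
    if (D[id] > best) { best = D[id]; best_state = 2; }
    if (best <= NEG / 2) return res;
    best_i = m; best_w = w;
  } else { // glocal: query fully consumed, end anywhere on reference
    for (int w = 0; w < W; ++w) {
      int j = m + dlo + w;
      if (j < 0 || j > n) continue;
      size_t id = IDX(m, w);
      if (M[id] > best) { best = M[id]; best_i = m; best_w = w; best_state = 0; }
      if (I[id] > best) { best = I[id]; best_i = m; best_w = w; best_state = 1; }
    }
    if (best_i < 0 || best <= NEG / 2) return res;
  }

  // traceback
  std::vector<char> ops;
  int i = best_i, w = best_w, state = best_state;
  res.q_end = i;
  res.r_end = i + dlo + w;
  while (i > 0) {
    size_t id = IDX(i, w);
    if (state == 0) {
      unsigned char src = tb[id] & 3;
      if (mode == 1 && src == 3 && !ops.empty()) break; // local start
      if (i == 0) break;
      int j = i + dlo + w;
      if (j >= 1 && Q[i - 1] != R[j - 1]) {
        res.sub_q.push_back(i - 1);
        res.sub_r.push_back(j - 1);
      } else if (j >= 1 && Q[i - 1] == R[j - 1] && Q[i - 1] != 'N') {
        res.matches++;
      }
      ops.push_back('M');
      i -= 1; // j -= 1 too: same w
      if (src == 3) { state = 0; if (mode != 2) break; }
      else state = src;
    } else if (state == 1) {
      ops.push_back('I');
      unsigned char src = (tb[id] >> 2) & 1;
      i -= 1; w += 1;
      state = src == 0 ? 0 : 1;
    } else {
      ops.push_back('D');
      unsigned char src = (tb[id] >> 4) & 1;
      w -= 1;
      state = src == 0 ? 0 : 2;
    }
    if (w < 0 || w >= W) break;
  }
  // consume leading global-mode D run
  if (mode == 2) {
    int j = i + dlo + w;
    while (j > 0) { ops.push_back('D'); --j; }
  }
  res.q_start = i;
  res.r_start = i + dlo + w;
  std::reverse(ops.begin(), ops.end());
  std::reverse(res.sub_q.begin(), res.sub_q.end());
  std::reverse(res.sub_r.begin(), res.sub_r.end());
  res.columns = (int)ops.size();

  // compress to CIGAR, with soft clips for local mode
  std::string cig;
  auto add_op = [&](char op, int len) {
    if (len > 0) { cig += std::to_string(len); cig += op; }
  };
  add_op('S', res.q_start);
  int run = 0; char cur = 0;
  for (char o : ops) {
    if (o == cur) run++;
    else { add_op(cur, run); cur = o; run = 1; }
  }
  add_op(cur, run);
  add_op('S', m - res.q_end);
  res.cigar = cig;
  res.score = best;
  res.ok = true;
  return res;
}

static List aln_to_list(const Aln &a) {
  return List::create(
      _["ok"] = a.ok, _["score"] = a.score, _["q_start"] = a.q_start,
      _["q_end"] = a.q_end, _["r_start"] = a.r_start, _["r_end"] = a.r_end,
      _["matches"] = a.matches, _["columns"] = a.columns,
      _["identity"] = a.columns > 0 ? (double)a.matches / a.columns : 0.0,
      _["cigar"] = a.cigar,
      _["sub_q"] = IntegerVector(a.sub_q.begin(), a.sub_q.end()),
      _["sub_r"] = IntegerVector(a.sub_r.begin(), a.sub_r.end()));
}

// [[Rcpp::export]]
List align_pair_cpp(std::string query, std::string ref,
                    std::string mode = "glocal",
                    int band = 100, int match = 1, int mismatch = -1,
                    int gap_open = 3, int gap_ext = 1) {
  int md = mode == "local" ? 1 : (mode == "global" ? 2 : 0);
  int n = (int)ref.size(), m = (int)query.size();
  int dlo = std::min(0, n - m) - band;
  int dhi = std::max(0, n - m) + band;
  Aln a = band_dp(query, ref, md, dlo, dhi, match, mismatch, gap_open, gap_ext);
  return aln_to_list(a);
}

// ---------------------------------------------------------------------------
// k-mer index over a set of reference sequences (2-bit encoded, forward only)
// ---------------------------------------------------------------------------

struct RefIndex {
  int k;
  std::string cat;                 // concatenated records, 'X' sentinels
  std::vector<long> rec_start, rec_end; // global half-open per record
  std::unordered_map<uint64_t, std::vector<uint32_t>> pos;
};

static bool encode_kmer(const char *s, int k, uint64_t &code) {
  uint64_t c = 0;
  for (int i = 0; i < k; ++i) {
    int b;
    switch (s[i]) {
    case 'A': b = 0; break; case 'C': b = 1; break;
    case 'G': b = 2; break; case 'T': b = 3; break;
    default: return false;
    }
    c = (c << 2) | (uint64_t)b;
  }
  code = c;
  return true;
}

static void build_index(RefIndex &ix, const std::vector<std::string> &seqs, int k) {
  ix.k = k;
  ix.cat.clear();
  ix.rec_start.clear();
  ix.rec_end.clear();
  for (const auto &s : seqs) {
    ix.rec_start.push_back((long)ix.cat.size());
    ix.cat += s;
    ix.rec_end.push_back((long)ix.cat.size());
    ix.cat += 'X';
  }
  const long N = (long)ix.cat.size();
  ix.pos.reserve((size_t)N);
  for (size_t r = 0; r < ix.rec_start.size(); ++r) {
    for (long p = ix.rec_start[r]; p + k <= ix.rec_end[r]; ++p) {
      uint64_t code;
      if (encode_kmer(ix.cat.c_str() + p, k, code))
        ix.pos[code].push_back((uint32_t)p);
    }
  }
}

static int rec_of(const RefIndex &ix, long gpos) {
  // binary search for record containing gpos (clamped)
  int lo = 0, hi = (int)ix.rec_start.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (ix.rec_start[mid] <= gpos) lo = mid; else hi = mid - 1;
  }
  return lo;
}

// [[Rcpp::export]]
List kmer_lookup_cpp(CharacterVector ref_seqs, int k, CharacterVector queries) {
  std::vector<std::string> seqs;
  for (R_xlen_t i = 0; i < ref_seqs.size(); ++i)
    seqs.push_back(as<std::string>(ref_seqs[i]));
  RefIndex ix;
  build_index(ix, seqs, k);
  List out(queries.size());
  for (R_xlen_t q = 0; q < queries.size(); ++q) {
    std::string Q = as<std::string>(queries[q]);
    std::vector<int> rec, p;
    std::vector<std::string> strand;
    if ((int)Q.size() == k) {
      std::string Qr = rc_str(Q);
      bool palin = (Q == Qr);
      uint64_t code;
      if (encode_kmer(Q.c_str(), k, code)) {
        auto it = ix.pos.find(code);
        if (it != ix.pos.end())
          for (uint32_t gp : it->second) {
            int r = rec_of(ix, gp);
            rec.push_back(r + 1);
            p.push_back((int)(gp - ix.rec_start[r]));
            strand.push_back(palin ? "both" : "+");
          }
      }
      if (!palin && encode_kmer(Qr.c_str(), k, code)) {
        auto it = ix.pos.find(code);
        if (it != ix.pos.end())
          for (uint32_t gp : it->second) {
            int r = rec_of(ix, gp);
            rec.push_back(r + 1);
            p.push_back((int)(gp - ix.rec_start[r]));
            strand.push_back("-");
          }
      }
    }
    out[q] = DataFrame::create(_["record"] = wrap(rec), _["pos"] = wrap(p),
                               _["strand"] = wrap(strand),
                               _["stringsAsFactors"] = false);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Read mapper: seed by k-mer diagonal voting, extend by banded DP, mate
// rescue within the insert window.
// ---------------------------------------------------------------------------

struct Placement {
  bool mapped = false;
  long gpos = 0;
  int rec = -1;
  int score = NEG;
  double identity = 0;
  bool fwd = true;
  int rlen = 0;
  std::string cigar;
};

static void evaluate_candidate(const RefIndex &ix, const std::string &Q,
                               long diag, double min_identity,
                               std::vector<Placement> &out, bool fwd) {
  const int m = (int)Q.size();
  const int pad = 16;
  int r = rec_of(ix, std::max(diag, (long)0));
  long ws = std::max(ix.rec_start[r], diag - pad);
  long we = std::min(ix.rec_end[r], diag + m + pad);
  if (we - ws < std::min(m / 2, 30)) return;
  // fast path: pure hamming at the exact diagonal
  if (diag >= ix.rec_start[r] && diag + m <= ix.rec_end[r]) {
    int mis = 0;
    for (int i = 0; i < m; ++i)
      if (Q[i] != ix.cat[diag + i]) ++mis;
    if (mis == 0) {
      Placement p;
      p.mapped = true; p.gpos = diag; p.rec = r; p.score = m;
      p.identity = 1.0; p.fwd = fwd; p.rlen = m;
      p.cigar = std::to_string(m) + "M";
      out.push_back(p);
      return;
    }
  }
  std::string R = ix.cat.substr(ws, we - ws);
  int n = (int)R.size();
  Aln a = band_dp(Q, R, 0, -6, std::max(0, n - m) + 6);
  if (!a.ok) return;
  double ident = a.columns > 0 ? (double)a.matches / a.columns : 0.0;
  if (ident < min_identity) return;
  Placement p;
  p.mapped = true; p.gpos = ws + a.r_start; p.rec = r; p.score = a.score;
  p.identity = ident; p.fwd = fwd; p.rlen = a.r_end - a.r_start;
  p.cigar = a.cigar;
  out.push_back(p);
}

// [[Rcpp::export]]
List map_reads_cpp(CharacterVector ref_seqs, CharacterVector read_seqs,
                   IntegerVector pair_id, IntegerVector mate,
                   int k = 21, double min_identity = 0.8,
                   int max_seed_hits = 50, int max_candidates = 6,
                   double rescue_min_identity = 0.5, bool do_rescue = true,
                   int max_ties = 8) {
  std::vector<std::string> seqs;
  for (R_xlen_t i = 0; i < ref_seqs.size(); ++i)
    seqs.push_back(as<std::string>(ref_seqs[i]));
  RefIndex ix;
  build_index(ix, seqs, k);
  const R_xlen_t NR = read_seqs.size();

  std::vector<std::vector<Placement>> ties(NR);
  std::vector<Placement> primary(NR);

  for (R_xlen_t ri = 0; ri < NR; ++ri) {
    std::string fwd = as<std::string>(read_seqs[ri]);
    const int m = (int)fwd.size();
    if (m < k) continue;
    std::vector<Placement> cands;
    for (int ori = 0; ori < 2; ++ori) {
      std::string Q = ori == 0 ? fwd : rc_str(fwd);
      std::unordered_map<long, int> votes;
      for (int off = 0; off + k <= m; ++off) {
        uint64_t code;
        if (!encode_kmer(Q.c_str() + off, k, code)) continue;
        auto it = ix.pos.find(code);
        if (it == ix.pos.end()) continue;
        if ((int)it->second.size() > max_seed_hits) continue;
        for (uint32_t gp : it->second) votes[(long)gp - off]++;
      }
      if (votes.empty()) continue;
      std::vector<std::pair<long, int>> vv(votes.begin(), votes.end());
      std::sort(vv.begin(), vv.end(), [](const std::pair<long,int> &a,
                                         const std::pair<long,int> &b) {
        if (a.second != b.second) return a.second > b.second;
        return a.first < b.first;
      });
      std::vector<long> chosen;
      for (auto &pr : vv) {
        if ((int)chosen.size() >= max_candidates) break;
        bool near = false;
        for (long c : chosen)
          if (std::labs(c - pr.first) <= 12) { near = true; break; }
        if (near) continue;
        if (pr.second < std::max(2, vv[0].second / 4)) break;
        chosen.push_back(pr.first);
      }
      if (chosen.empty() && !vv.empty()) chosen.push_back(vv[0].first);
      for (long diag : chosen)
        evaluate_candidate(ix, Q, diag, min_identity, cands, ori == 0);
    }
    if (cands.empty()) continue;
    int bs = NEG;
    for (auto &c : cands) bs = std::max(bs, c.score);
    std::vector<Placement> tied;
    for (auto &c : cands)
      if (c.score == bs) tied.push_back(c);
    std::sort(tied.begin(), tied.end(), [](const Placement &a, const Placement &b) {
      if (a.gpos != b.gpos) return a.gpos < b.gpos;
      return a.fwd > b.fwd;
    });
    // dedupe identical loci
    std::vector<Placement> ded;
    for (auto &c : tied) {
      bool dup = false;
      for (auto &d : ded)
        if (std::labs(d.gpos - c.gpos) <= 4 && d.fwd == c.fwd) { dup = true; break; }
      if (!dup) ded.push_back(c);
      if ((int)ded.size() >= max_ties) break;
    }
    ties[ri] = ded;
    primary[ri] = ded[0];
  }

  // insert-size statistics from both-mapped FR pairs
  std::unordered_map<int, std::vector<R_xlen_t>> by_pair;
  for (R_xlen_t i = 0; i < NR; ++i)
    if (pair_id[i] != NA_INTEGER) by_pair[pair_id[i]].push_back(i);
  std::vector<double> tlens;
  for (auto &kv : by_pair) {
    if (kv.second.size() != 2) continue;
    const Placement &a = primary[kv.second[0]], &b = primary[kv.second[1]];
    if (!a.mapped || !b.mapped || a.rec != b.rec || a.fwd == b.fwd) continue;
    const Placement &lw = a.gpos <= b.gpos ? a : b;
    const Placement &rw = a.gpos <= b.gpos ? b : a;
    if (!lw.fwd || rw.fwd) continue;
    double tl = (double)(rw.gpos + rw.rlen - lw.gpos);
    if (tl > 0 && tl <= 2000) tlens.push_back(tl);
  }
  double imean = 0, isd = 0;
  if (!tlens.empty()) {
    for (double t : tlens) imean += t;
    imean /= tlens.size();
    for (double t : tlens) isd += (t - imean) * (t - imean);
    isd = tlens.size() > 1 ? std::sqrt(isd / (tlens.size() - 1)) : 0.0;
  }

  // proper-pair flags and mate rescue
  std::vector<bool> proper(NR, false), rescued(NR, false);
  double lo = imean - 4 * isd, hi = imean + 4 * isd;
  for (auto &kv : by_pair) {
    if (kv.second.size() != 2) continue;
    R_xlen_t i1 = kv.second[0], i2 = kv.second[1];
    Placement &a = primary[i1], &b = primary[i2];
    if (a.mapped && b.mapped) {
      if (a.rec == b.rec && a.fwd != b.fwd) {
        const Placement &lw = a.gpos <= b.gpos ? a : b;
        const Placement &rw = a.gpos <= b.gpos ? b : a;
        double tl = (double)(rw.gpos + rw.rlen - lw.gpos);
        if (lw.fwd && !rw.fwd && tl >= std::max(1.0, lo) && tl <= hi) {
          proper[i1] = proper[i2] = true;
        }
      }
    } else if (do_rescue && imean > 0 && (a.mapped != b.mapped)) {
      R_xlen_t ia = a.mapped ? i1 : i2; // anchor
      R_xlen_t iu = a.mapped ? i2 : i1;
      Placement &anc = primary[ia];
      std::string seq = as<std::string>(read_seqs[iu]);
      int m2 = (int)seq.size();
      long ws, we;
      std::string Q;
      bool qfwd;
      if (anc.fwd) {
        Q = rc_str(seq); qfwd = false;
        ws = anc.gpos + (long)(imean - 4 * isd) - m2 - 8;
        we = anc.gpos + (long)(imean + 4 * isd) + 8;
      } else {
        Q = seq; qfwd = true;
        ws = anc.gpos + anc.rlen - (long)(imean + 4 * isd) - 8;
        we = anc.gpos + anc.rlen - (long)(imean - 4 * isd) + m2 + 8;
      }
      int r = anc.rec;
      ws = std::max(ws, ix.rec_start[r]);
      we = std::min(we, ix.rec_end[r]);
      if (we - ws >= m2 / 2) {
        std::string R = ix.cat.substr(ws, we - ws);
        Aln al = band_dp(Q, R, 0, -6, std::max(0, (int)R.size() - m2) + 6);
        double ident = al.ok && al.columns > 0 ?
          (double)al.matches / al.columns : 0.0;
        if (al.ok && ident >= rescue_min_identity) {
          Placement p;
          p.mapped = true; p.gpos = ws + al.r_start; p.rec = r;
          p.score = al.score; p.identity = ident; p.fwd = qfwd;
          p.rlen = al.r_end - al.r_start; p.cigar = al.cigar;
          primary[iu] = p;
          ties[iu] = {p};
          rescued[iu] = true;
          proper[iu] = proper[ia] = true;
        }
      }
    }
  }

  // flatten placements
  std::vector<int> o_read, o_rec, o_pos, o_score, o_rlen;
  std::vector<double> o_ident;
  std::vector<bool> o_mapped, o_primary, o_proper, o_rescued;
  std::vector<std::string> o_strand, o_cigar;
  for (R_xlen_t i = 0; i < NR; ++i) {
    if (ties[i].empty()) {
      o_read.push_back((int)i + 1); o_mapped.push_back(false);
      o_rec.push_back(NA_INTEGER); o_pos.push_back(NA_INTEGER);
      o_strand.push_back("*"); o_cigar.push_back("*");
      o_ident.push_back(NA_REAL); o_score.push_back(NA_INTEGER);
      o_rlen.push_back(NA_INTEGER);
      o_primary.push_back(true); o_proper.push_back(false);
      o_rescued.push_back(false);
      continue;
    }
    for (size_t t = 0; t < ties[i].size(); ++t) {
      const Placement &p = ties[i][t];
      o_read.push_back((int)i + 1); o_mapped.push_back(true);
      o_rec.push_back(p.rec + 1);
      o_pos.push_back((int)(p.gpos - ix.rec_start[p.rec]));
      o_strand.push_back(p.fwd ? "+" : "-");
      o_cigar.push_back(p.cigar);
      o_ident.push_back(p.identity); o_score.push_back(p.score);
      o_rlen.push_back(p.rlen);
      o_primary.push_back(t == 0);
      o_proper.push_back(t == 0 ? (bool)proper[i] : false);
      o_rescued.push_back(t == 0 ? (bool)rescued[i] : false);
    }
  }
  DataFrame df = DataFrame::create(
      _["read"] = wrap(o_read), _["mapped"] = wrap(o_mapped),
      _["record"] = wrap(o_rec), _["pos"] = wrap(o_pos),
      _["strand"] = wrap(o_strand), _["cigar"] = wrap(o_cigar),
      _["identity"] = wrap(o_ident), _["score"] = wrap(o_score),
      _["rlen"] = wrap(o_rlen), _["primary"] = wrap(o_primary),
      _["proper"] = wrap(o_proper), _["rescued"] = wrap(o_rescued),
      _["stringsAsFactors"] = false);
  return List::create(_["placements"] = df, _["insert_mean"] = imean,
                      _["insert_sd"] = isd);
}

// ---------------------------------------------------------------------------
// All-hits local search of one query against reference records (flank
// matching, syntenic-contig search, region SNP enumeration).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List local_hits_cpp(std::string query, CharacterVector ref_seqs,
                    int k = 21, double min_identity = 0.9,
                    double min_coverage = 0.0, int band = 100,
                    int min_votes = 3) {
  std::vector<std::string> seqs;
  for (R_xlen_t i = 0; i < ref_seqs.size(); ++i)
    seqs.push_back(as<std::string>(ref_seqs[i]));
  RefIndex ix;
  build_index(ix, seqs, k);
  const int qlen = (int)query.size();

  struct Hit {
    int rec; int r_start, r_end, q_start, q_end;
    bool fwd; double identity, coverage; int score;
    std::vector<int> sub_q, sub_r;
    int n_ins, n_del;
  };
  std::vector<Hit> hits;

  for (int ori = 0; ori < 2; ++ori) {
    std::string Q = ori == 0 ? query : rc_str(query);
    std::unordered_map<long, int> votes;
    int stride = qlen > 4000 ? 3 : 1;
    for (int off = 0; off + k <= qlen; off += stride) {
      uint64_t code;
      if (!encode_kmer(Q.c_str() + off, k, code)) continue;
      auto it = ix.pos.find(code);
      if (it == ix.pos.end()) continue;
      if ((int)it->second.size() > 200) continue;
      for (uint32_t gp : it->second) votes[(long)gp - off]++;
    }
    if (votes.empty()) continue;
    std::vector<std::pair<long, int>> vv(votes.begin(), votes.end());
    std::sort(vv.begin(), vv.end());
    // chain nearby diagonals into clusters
    std::vector<std::array<long, 3>> clusters; // dmin, dmax, votes
    for (auto &pr : vv) {
      if (!clusters.empty() && pr.first - clusters.back()[1] <= band) {
        clusters.back()[1] = pr.first;
        clusters.back()[2] += pr.second;
      } else {
        clusters.push_back({pr.first, pr.first, (long)pr.second});
      }
    }
    for (auto &cl : clusters) {
      if (cl[2] < min_votes) continue;
      long diag = cl[0];
      int r = rec_of(ix, std::max(diag, (long)0));
      long ws = std::max(ix.rec_start[r], cl[0] - band);
      long we = std::min(ix.rec_end[r], cl[1] + qlen + band);
      if (we - ws < k) continue;
      std::string R = ix.cat.substr(ws, we - ws);
      int n = (int)R.size();
      int dlo = std::min(0, n - qlen) - band, dhi = std::max(0, n - qlen) + band;
      Aln a = band_dp(Q, R, 1, dlo, dhi);
      if (!a.ok) continue;
      double ident = a.columns > 0 ? (double)a.matches / a.columns : 0.0;
      double cov = (double)(a.q_end - a.q_start) / qlen;
      if (ident < min_identity || cov < min_coverage) continue;
      Hit h;
      h.rec = r;
      h.r_start = (int)(ws + a.r_start - ix.rec_start[r]);
      h.r_end = (int)(ws + a.r_end - ix.rec_start[r]);
      h.fwd = ori == 0;
      h.identity = ident; h.coverage = cov; h.score = a.score;
      // coordinates back in the original query frame
      if (h.fwd) { h.q_start = a.q_start; h.q_end = a.q_end; }
      else { h.q_start = qlen - a.q_end; h.q_end = qlen - a.q_start; }
      h.sub_q = a.sub_q; h.sub_r = a.sub_r;
      if (!h.fwd)
        for (auto &x : h.sub_q) x = qlen - 1 - x;
      for (auto &x : h.sub_r) x = (int)(ws + x - ix.rec_start[r]);
      int ni = 0, nd = 0;
      { // count indel columns from cigar-free op reconstruction
        ni = (a.q_end - a.q_start) - (a.matches + (int)a.sub_q.size());
        nd = (a.r_end - a.r_start) - (a.matches + (int)a.sub_q.size());
      }
      h.n_ins = ni; h.n_del = nd;
      hits.push_back(h);
    }
  }
  // dedupe: overlapping reference intervals on same record keep best score
  std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
    return a.score > b.score;
  });
  std::vector<Hit> keep;
  for (auto &h : hits) {
    bool dup = false;
    for (auto &kk : keep) {
      if (kk.rec != h.rec) continue;
      int ov = std::min(kk.r_end, h.r_end) - std::max(kk.r_start, h.r_start);
      int len = std::min(kk.r_end - kk.r_start, h.r_end - h.r_start);
      if (len > 0 && ov > len / 2) { dup = true; break; }
    }
    if (!dup) keep.push_back(h);
  }
  std::sort(keep.begin(), keep.end(), [](const Hit &a, const Hit &b) {
    if (a.rec != b.rec) return a.rec < b.rec;
    return a.r_start < b.r_start;
  });

  std::vector<int> rec, rs, re, qs, qe, score, nins, ndel;
  std::vector<double> ident, cov;
  std::vector<std::string> strand;
  List subs(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) {
    const Hit &h = keep[i];
    rec.push_back(h.rec + 1); rs.push_back(h.r_start); re.push_back(h.r_end);
    qs.push_back(h.q_start); qe.push_back(h.q_end);
    strand.push_back(h.fwd ? "+" : "-");
    ident.push_back(h.identity); cov.push_back(h.coverage);
    score.push_back(h.score); nins.push_back(h.n_ins); ndel.push_back(h.n_del);
    subs[i] = DataFrame::create(_["q_pos"] = wrap(h.sub_q),
                                _["r_pos"] = wrap(h.sub_r),
                                _["stringsAsFactors"] = false);
  }
  DataFrame df = DataFrame::create(
      _["record"] = wrap(rec), _["r_start"] = wrap(rs), _["r_end"] = wrap(re),
      _["q_start"] = wrap(qs), _["q_end"] = wrap(qe),
      _["strand"] = wrap(strand), _["identity"] = wrap(ident),
      _["coverage"] = wrap(cov), _["score"] = wrap(score),
      _["n_ins"] = wrap(nins), _["n_del"] = wrap(ndel),
      _["stringsAsFactors"] = false);
  return List::create(_["hits"] = df, _["subs"] = subs);
}

// ---------------------------------------------------------------------------
// de Bruijn assembler (edge-centric, both strands materialised) with
// trusted/untrusted guide-contig threading.
// ---------------------------------------------------------------------------

typedef std::unordered_map<std::string, int> KmerMap;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

struct DBG {
  int k;
  KmerMap edges; // k-mer -> coverage (canonical count, both orientations kept)

  bool has(const std::string &e) const { return edges.count(e) > 0; }
  int outdeg(const std::string &node) const {
    int d = 0;
    std::string e = node + "A";
    for (int i = 0; i < 4; ++i) { e[k - 1] = BASES[i]; d += has(e); }
    return d;
  }
  int indeg(const std::string &node) const {
    int d = 0;
    std::string e = "A" + node;
    for (int i = 0; i < 4; ++i) { e[0] = BASES[i]; d += has(e); }
    return d;
  }
  char unique_out(const std::string &node) const {
    char r = 0;
    std::string e = node + "A";
    for (int i = 0; i < 4; ++i) {
      e[k - 1] = BASES[i];
      if (has(e)) { if (r) return 0; r = BASES[i]; }
    }
    return r;
  }
  char unique_in(const std::string &node) const {
    char r = 0;
    std::string e = "A" + node;
    for (int i = 0; i < 4; ++i) {
      e[0] = BASES[i];
      if (has(e)) { if (r) return 0; r = BASES[i]; }
    }
    return r;
  }
  void erase_edge(const std::string &e) {
    edges.erase(e);
    edges.erase(rc_str(e));
  }
};

struct Unitig {
  std::string seq;
  double cov;
  std::string entry_node, exit_node;
  std::vector<std::string> path; // edges
};

// extract unitigs over edges passing `keep` (empty set = all)
static std::vector<Unitig> extract_unitigs(const DBG &g,
    const std::unordered_set<std::string> *exclude = nullptr) {
  const int k = g.k;
  auto usable = [&](const std::string &e) {
    return g.has(e) && (!exclude || !exclude->count(e));
  };
  // one pass to precompute node degrees (in-degree high nibble, out low)
  std::unordered_map<std::string, unsigned char> deg;
  deg.reserve(g.edges.size() * 2);
  for (auto &kv : g.edges) {
    if (exclude && exclude->count(kv.first)) continue;
    const std::string &e = kv.first;
    unsigned char &dp = deg[e.substr(0, k - 1)];
    if ((dp & 0x0f) < 0x0f) dp += 1;               // out-degree
    unsigned char &ds = deg[e.substr(1)];
    if ((ds >> 4) < 0x0f) ds += 0x10;              // in-degree
  }
  auto node_simple = [&](const std::string &node) {
    auto it = deg.find(node);
    return it != deg.end() && it->second == 0x11;
  };
  auto succ = [&](const std::string &e, std::string &nxt) {
    std::string node = e.substr(1);
    if (!node_simple(node)) return false;
    std::string cand = node + "A";
    for (int i = 0; i < 4; ++i) {
      cand[k - 1] = BASES[i];
      if (usable(cand)) { nxt = cand; return true; }
    }
    return false;
  };
  auto is_start = [&](const std::string &e) {
    return !node_simple(e.substr(0, k - 1));
  };
  std::vector<std::string> all;
  all.reserve(g.edges.size());
  for (auto &kv : g.edges)
    if (usable(kv.first)) all.push_back(kv.first);
  std::unordered_set<std::string> visited;
  std::vector<Unitig> out;
  auto walk = [&](const std::string &start) {
    Unitig u;
    u.seq = start;
    u.path.push_back(start);
    visited.insert(start);
    double cv = g.edges.at(start);
    std::string cur = start, nxt;
    while (succ(cur, nxt)) {
      if (visited.count(nxt)) break;
      u.seq += nxt[k - 1];
      u.path.push_back(nxt);
      visited.insert(nxt);
      cv += g.edges.at(nxt);
      cur = nxt;
    }
    u.cov = cv / u.path.size();
    u.entry_node = u.path.front().substr(0, k - 1);
    u.exit_node = u.path.back().substr(1);
    out.push_back(u);
  };
  for (auto &e : all)
    if (!visited.count(e) && is_start(e)) walk(e);
  for (auto &e : all) // cycles
    if (!visited.count(e)) walk(e);
  return out;
}

static void count_reads_into(KmerMap &cnt, CharacterVector reads, int k) {
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() < k) continue;
    for (int off = 0; off + k <= (int)s.size(); ++off) {
      std::string km = s.substr(off, k);
      if (km.find('N') != std::string::npos) continue;
      std::string rcm = rc_str(km);
      cnt[km <= rcm ? km : rcm]++;
    }
  }
}

struct Proposal {
  std::string node;
  char cin, cout;
  int source;
  bool trusted;
  bool accepted;
};

// [[Rcpp::export]]
List assemble_cpp(CharacterVector reads, int k, int min_count = 2,
                  int tip_bp = -1, double bubble_identity = 0.9,
                  CharacterVector trusted = CharacterVector(),
                  CharacterVector untrusted = CharacterVector(),
                  int untrusted_min_support = 5, int max_patch = 2) {
  if (tip_bp < 0) tip_bp = 2 * k;
  DBG g;
  g.k = k;
  std::vector<std::string> warnings;

  // 1. canonical counting, then materialise both orientations
  KmerMap canon;
  count_reads_into(canon, reads, k);
  size_t raw = canon.size();
  for (auto &kv : canon) {
    if (kv.second < min_count) continue;
    g.edges[kv.first] = kv.second;
    g.edges[rc_str(kv.first)] = kv.second;
  }
  size_t kept = g.edges.size();
  if (g.edges.empty()) {
    warnings.push_back("no k-mers survive filtering");
    return List::create(_["contigs"] = CharacterVector(),
                        _["coverage"] = NumericVector(),
                        _["kind"] = CharacterVector(),
                        _["pairings"] = R_NilValue,
                        _["stats"] = List::create(_["raw_kmers"] = (double)raw,
                                                  _["kept_kmers"] = 0.0),
                        _["warnings"] = wrap(warnings));
  }

  // 2. tip clipping
  int tips_removed = 0;
  for (int round = 0; round < 3; ++round) {
    std::vector<Unitig> us = extract_unitigs(g);
    int removed = 0;
    for (auto &u : us) {
      if ((int)u.seq.size() >= tip_bp) continue;
      bool dead_in = g.indeg(u.entry_node) == 0;
      bool dead_out = g.outdeg(u.exit_node) == 0;
      if (dead_in == dead_out) continue; // isolated or internal: keep
      // the attached end must have alternatives (graph continues without us)
      if (dead_in) {
        // attached at exit: exit node must have other in-edges
        if (g.indeg(u.exit_node) < 2) continue;
      } else {
        if (g.outdeg(u.entry_node) < 2) continue;
      }
      for (auto &e : u.path) g.erase_edge(e);
      removed++;
    }
    tips_removed += removed;
    if (removed == 0) break;
  }

  // 3. bubble popping
  int bubbles = 0;
  {
    std::vector<Unitig> us = extract_unitigs(g);
    std::map<std::pair<std::string, std::string>, std::vector<int>> by_ends;
    for (size_t i = 0; i < us.size(); ++i)
      by_ends[{us[i].entry_node, us[i].exit_node}].push_back((int)i);
    for (auto &kv : by_ends) {
      auto &v = kv.second;
      if (v.size() < 2) continue;
      std::sort(v.begin(), v.end(), [&](int a, int b) {
        return us[a].cov > us[b].cov;
      });
      for (size_t j = 1; j < v.size(); ++j) {
        const Unitig &hi = us[v[0]], &lo = us[v[j]];
        if (std::abs((int)hi.seq.size() - (int)lo.seq.size()) > 10) continue;
        Aln a = band_dp(lo.seq, hi.seq, 2, -12, 12);
        double ident = a.ok && a.columns ? (double)a.matches / a.columns : 0.0;
        if (ident < bubble_identity) continue;
        bool still = true;
        for (auto &e : lo.path) if (!g.has(e)) { still = false; break; }
        if (!still) continue;
        for (auto &e : lo.path) g.erase_edge(e);
        bubbles++;
      }
    }
  }

  // 4. guide-contig threading
  struct Source {
    std::string seq;
    bool trusted;
    std::vector<std::string> spine; // longest present run of edges
    int n_segments = 0;
  };
  std::vector<Source> sources;
  for (R_xlen_t i = 0; i < trusted.size(); ++i)
    sources.push_back({as<std::string>(trusted[i]), true, {}, 0});
  for (R_xlen_t i = 0; i < untrusted.size(); ++i)
    sources.push_back({as<std::string>(untrusted[i]), false, {}, 0});

  std::vector<Proposal> proposals;
  std::vector<std::vector<std::vector<std::string>>> segs_by_source;

  for (size_t si = 0; si < sources.size(); ++si) {
    Source &S = sources[si];
    const std::string &seq = S.seq;
    int nk = (int)seq.size() - k + 1;
    std::vector<std::vector<std::string>> segments;
    if (nk < 2) {
      warnings.push_back("guide contig shorter than two k-mers; ignored");
      segs_by_source.push_back(segments);
      continue;
    }
    std::vector<std::string> kms(nk);
    std::vector<char> present(nk, 0);
    for (int i = 0; i < nk; ++i) {
      kms[i] = seq.substr(i, k);
      present[i] = kms[i].find('N') == std::string::npos && g.has(kms[i]);
    }
    if (S.trusted) { // patch short gaps with the contig's own sequence
      int i = 0;
      while (i < nk) {
        if (present[i]) { ++i; continue; }
        int j = i;
        while (j < nk && !present[j]) ++j;
        bool interior = i > 0 && j < nk;
        if (interior && j - i <= max_patch) {
          for (int t = i; t < j; ++t) {
            if (kms[t].find('N') != std::string::npos) continue;
            if (!g.has(kms[t])) {
              g.edges[kms[t]] = 1;
              g.edges[rc_str(kms[t])] = 1;
            }
            present[t] = 1;
          }
        }
        i = j;
      }
    }
    { // segments of consecutive present k-mers
      int i = 0;
      while (i < nk) {
        if (!present[i]) { ++i; continue; }
        int j = i;
        while (j < nk && present[j]) ++j;
        if (j - i >= 2) {
          std::vector<std::string> seg(kms.begin() + i, kms.begin() + j);
          segments.push_back(seg);
        }
        i = j;
      }
    }
    if (segments.empty())
      warnings.push_back("guide contig shares fewer than 2 consecutive k-mers with the graph");
    S.n_segments = (int)segments.size();
    // junction proposals along every segment (both strands)
    for (auto &seg : segments) {
      for (size_t t = 0; t + 1 < seg.size(); ++t) {
        const std::string &e1 = seg[t], &e2 = seg[t + 1];
        std::string node = e1.substr(1);
        if (g.indeg(node) > 1 || g.outdeg(node) > 1) {
          proposals.push_back({node, e1[0], e2[k - 1], (int)si, S.trusted, true});
          proposals.push_back({rc_str(node), comp_base(e2[k - 1]),
                               comp_base(e1[0]), (int)si, S.trusted, true});
        }
      }
    }
    segs_by_source.push_back(segments);
  }

  // read support for untrusted junction checks ((k+1)-mer occurrences)
  if (!proposals.empty()) {
    bool any_untrusted = false;
    for (auto &p : proposals) if (!p.trusted) any_untrusted = true;
    std::unordered_map<std::string, int> support;
    if (any_untrusted) {
      std::unordered_set<std::string> queries;
      for (auto &p : proposals) {
        if (p.trusted) continue;
        std::string alt = std::string(1, p.cin) + p.node + "A";
        for (int i = 0; i < 4; ++i) {
          alt[k] = BASES[i];
          std::string e = p.node + BASES[i];
          if (g.has(e)) { queries.insert(alt); queries.insert(rc_str(alt)); }
        }
      }
      for (auto &q : queries) support[q] = 0;
      for (R_xlen_t i = 0; i < reads.size(); ++i) {
        std::string s = as<std::string>(reads[i]);
        for (int off = 0; off + k + 1 <= (int)s.size(); ++off) {
          std::string w = s.substr(off, k + 1);
          auto it = support.find(w);
          if (it != support.end()) it->second++;
        }
      }
      // merge strand counts
      for (auto &p : proposals) {
        if (p.trusted) continue;
        std::string self = std::string(1, p.cin) + p.node + std::string(1, p.cout);
        int self_sup = support.count(self) ? support[self] : 0;
        self_sup += support.count(rc_str(self)) ? support[rc_str(self)] : 0;
        int max_alt = 0;
        std::string alt = std::string(1, p.cin) + p.node + "A";
        for (int i = 0; i < 4; ++i) {
          if (BASES[i] == p.cout) continue;
          alt[k] = BASES[i];
          if (!g.has(p.node + BASES[i])) continue;
          int a = (support.count(alt) ? support[alt] : 0) +
                  (support.count(rc_str(alt)) ? support[rc_str(alt)] : 0);
          max_alt = std::max(max_alt, a);
        }
        if (self_sup == 0 && max_alt >= untrusted_min_support)
          p.accepted = false; // contradicted by spanning reads
      }
    }
  }

  // unique pairing maps; conflicting pairings dropped
  std::unordered_map<std::string, char> fwd_map, bwd_map;
  {
    std::unordered_map<std::string, std::unordered_set<char>> fmm, bmm;
    for (auto &p : proposals) {
      if (!p.accepted) continue;
      fmm[p.node + "|" + p.cin].insert(p.cout);
      bmm[p.node + "|" + p.cout].insert(p.cin);
    }
    for (auto &kv : fmm)
      if (kv.second.size() == 1) fwd_map[kv.first] = *kv.second.begin();
    for (auto &kv : bmm)
      if (kv.second.size() == 1) bwd_map[kv.first] = *kv.second.begin();
  }

  // guided super-contigs
  std::unordered_set<std::string> covered;
  std::vector<std::string> super_seqs;
  for (size_t si = 0; si < sources.size(); ++si) {
    if (segs_by_source[si].empty()) continue;
    // spine = longest segment
    const std::vector<std::string> *spine = nullptr;
    for (auto &seg : segs_by_source[si])
      if (!spine || seg.size() > spine->size()) spine = &seg;
    std::vector<std::string> path(spine->begin(), spine->end());
    std::unordered_set<std::string> inpath(path.begin(), path.end());
    // extend right
    size_t guard = g.edges.size() + 16;
    while (path.size() < guard) {
      const std::string &cur = path.back();
      std::string node = cur.substr(1);
      char nxt = 0;
      auto it = fwd_map.find(node + "|" + cur[0]);
      if (it != fwd_map.end()) nxt = it->second;
      else if (g.indeg(node) == 1 && g.outdeg(node) == 1)
        nxt = g.unique_out(node);
      if (!nxt) break;
      std::string ne = node + nxt;
      if (!g.has(ne) || inpath.count(ne)) break;
      path.push_back(ne);
      inpath.insert(ne);
    }
    // extend left
    std::vector<std::string> left;
    while (path.size() + left.size() < guard) {
      const std::string &cur = left.empty() ? path.front() : left.back();
      std::string node = cur.substr(0, k - 1);
      char prv = 0;
      auto it = bwd_map.find(node + "|" + cur[k - 1]);
      if (it != bwd_map.end()) prv = it->second;
      else if (g.indeg(node) == 1 && g.outdeg(node) == 1)
        prv = g.unique_in(node);
      if (!prv) break;
      std::string pe = prv + node;
      if (!g.has(pe) || inpath.count(pe)) break;
      left.push_back(pe);
      inpath.insert(pe);
    }
    std::vector<std::string> full(left.rbegin(), left.rend());
    full.insert(full.end(), path.begin(), path.end());
    std::string seq = full.front();
    for (size_t t = 1; t < full.size(); ++t) seq += full[t][k - 1];
    super_seqs.push_back(seq);
    for (auto &e : full) { covered.insert(e); covered.insert(rc_str(e)); }
  }

  // residual unitigs over uncovered edges
  std::vector<Unitig> resid = extract_unitigs(g, covered.empty() ? nullptr : &covered);

  // assemble final contig list, canonical-deduped, sorted by length
  struct OutC { std::string seq; double cov; std::string kind; };
  std::vector<OutC> outc;
  std::unordered_set<std::string> seen;
  auto push = [&](const std::string &s, double cv, const std::string &kind) {
    std::string r = rc_str(s);
    const std::string &can = s <= r ? s : r;
    if (seen.count(can)) return;
    seen.insert(can);
    outc.push_back({can, cv, kind});
  };
  for (auto &s : super_seqs) push(s, 0.0, "guided");
  for (auto &u : resid) push(u.seq, u.cov, "unitig");
  std::sort(outc.begin(), outc.end(), [](const OutC &a, const OutC &b) {
    if (a.seq.size() != b.seq.size()) return a.seq.size() > b.seq.size();
    return a.seq < b.seq;
  });

  CharacterVector cseq(outc.size()), ckind(outc.size());
  NumericVector ccov(outc.size());
  for (size_t i = 0; i < outc.size(); ++i) {
    cseq[i] = outc[i].seq;
    ckind[i] = outc[i].kind;
    ccov[i] = outc[i].cov;
  }

  // pairing report
  std::vector<int> p_src;
  std::vector<bool> p_tr, p_acc;
  std::vector<std::string> p_node;
  std::vector<std::string> p_cin, p_cout;
  for (auto &p : proposals) {
    p_src.push_back(p.source + 1);
    p_tr.push_back(p.trusted);
    p_acc.push_back(p.accepted);
    p_node.push_back(p.node);
    p_cin.push_back(std::string(1, p.cin));
    p_cout.push_back(std::string(1, p.cout));
  }
  DataFrame pair_df = DataFrame::create(
      _["source"] = wrap(p_src), _["trusted"] = wrap(p_tr),
      _["accepted"] = wrap(p_acc), _["node"] = wrap(p_node),
      _["in_base"] = wrap(p_cin), _["out_base"] = wrap(p_cout),
      _["stringsAsFactors"] = false);

  return List::create(
      _["contigs"] = cseq, _["coverage"] = ccov, _["kind"] = ckind,
      _["pairings"] = pair_df,
      _["stats"] = List::create(
          _["raw_kmers"] = (double)raw, _["kept_kmers"] = (double)kept,
          _["tips_removed"] = tips_removed, _["bubbles_popped"] = bubbles),
      _["warnings"] = wrap(warnings));
}
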