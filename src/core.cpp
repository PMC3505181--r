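#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Affine-gap alignment (local and global) with traceback.
//
// Gap of length L costs gap_open + L * gap_extend.  'N' never scores as a
// match.  Traceback prefers the diagonal (match/mismatch) state on ties so
// that co-optimal alignments resolve toward fewer gaps; among equal-scoring
// end cells the leftmost target end (then query end) is taken.
// ---------------------------------------------------------------------------

static inline int subst_score(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return -mismatch;
  return (a == b) ? match : -mismatch;
}

// state codes for traceback
// tbM: 0 = start here, 1 = from M, 2 = from E (gap in query/D), 3 = from F (I)
// tbE/tbF: 1 = opened from M, 2 = extended

struct AlnRes {
  int score, qstart, qend, tstart, tend, ngaps, nmm;
  std::string cigar;
};

struct AlnBuffers {
  std::vector<int> M, E, F;
  std::vector<unsigned char> tbM, tbE, tbF;
};

static void affine_align(const char* q, int m, const char* t, int n,
                         int match, int mismatch, int gap_open,
                         int gap_extend, bool global, AlnRes& res,
                         AlnBuffers& buf) {
  const int NEG = -1000000000;
  int W = n + 1;
  size_t need = (size_t) (m + 1) * W;
  buf.M.assign(need, NEG); buf.E.assign(need, NEG); buf.F.assign(need, NEG);
  buf.tbM.assign(need, 0); buf.tbE.assign(need, 0); buf.tbF.assign(need, 0);
  std::vector<int>& M = buf.M; std::vector<int>& E = buf.E;
  std::vector<int>& F = buf.F;
  std::vector<unsigned char>& tbM = buf.tbM;
  std::vector<unsigned char>& tbE = buf.tbE;
  std::vector<unsigned char>& tbF = buf.tbF;
  int go = gap_open + gap_extend;

  M[0] = 0;
  if (global) {
    for (int j = 1; j <= n; ++j) { E[j] = -(gap_open + j * gap_extend); tbE[j] = (j == 1) ? 1 : 2; }
    for (int i = 1; i <= m; ++i) { F[i * W] = -(gap_open + i * gap_extend); tbF[i * W] = (i == 1) ? 1 : 2; }
  } else {
    for (int j = 1; j <= n; ++j) M[j] = 0;
    for (int i = 1; i <= m; ++i) M[i * W] = 0;
  }

  int best = global ? NEG : 0, bi = 0, bj = 0; unsigned char bstate = 1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int idx = i * W + j, up = (i - 1) * W + j, left = idx - 1, diag = up - 1;
      // E: gap consuming target (deletion w.r.t. query)
      int eOpen = (M[left] == NEG) ? NEG : M[left] - go;
      int eExt  = (E[left] == NEG) ? NEG : E[left] - gap_extend;
      if (eOpen >= eExt) { E[idx] = eOpen; tbE[idx] = 1; } else { E[idx] = eExt; tbE[idx] = 2; }
      // F: gap consuming query (insertion w.r.t. target)
      int fOpen = (M[up] == NEG) ? NEG : M[up] - go;
      int fExt  = (F[up] == NEG) ? NEG : F[up] - gap_extend;
      if (fOpen >= fExt) { F[idx] = fOpen; tbF[idx] = 1; } else { F[idx] = fExt; tbF[idx] = 2; }
      // M
      int s = subst_score(q[i - 1], t[j - 1], match, mismatch);
      int prevM = M[diag], prevE = E[diag], prevF = F[diag];
      int pbest; unsigned char pstate;
      if (prevM >= prevE && prevM >= prevF) { pbest = prevM; pstate = 1; }
      else if (prevE >= prevF) { pbest = prevE; pstate = 2; }
      else { pbest = prevF; pstate = 3; }
      if (!global && pbest <= 0) {
        // start a new local alignment when nothing positive to extend
        if (pbest < 0) { pbest = 0; pstate = 0; }
        else if (pbest == 0) pstate = 0;
      }
      M[idx] = (pbest == NEG) ? NEG : pbest + s;
      tbM[idx] = pstate;
      if (!global && M[idx] > best) { best = M[idx]; bi = i; bj = j; bstate = 1; }
    }
  }

  if (global) {
    int idx = m * W + n;
    best = M[idx]; bstate = 1;
    if (E[idx] > best) { best = E[idx]; bstate = 2; }
    if (F[idx] > best) { best = F[idx]; bstate = 3; }
    bi = m; bj = n;
  }

  // traceback
  std::vector<std::pair<char, int> > ops; // reversed
  int i = bi, j = bj; unsigned char st = bstate;
  int nmm = 0, ngaps = 0;
  auto push_op = [&ops](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  bool done = (!global && best == 0);
  while (!done && (i > 0 || j > 0)) {
    int idx = i * W + j;
    if (st == 1) {
      unsigned char from = tbM[idx];
      push_op('M');
      if (q[i - 1] != t[j - 1] || q[i - 1] == 'N' || t[j - 1] == 'N') nmm++;
      i--; j--;
      if (from == 0) done = true; else st = from;
    } else if (st == 2) { // E: consumes target -> D
      unsigned char from = tbE[idx];
      push_op('D');
      j--;
      if (from == 1) { st = 1; ngaps++; }
    } else { // F: consumes query -> I
      unsigned char from = tbF[idx];
      push_op('I');
      i--;
      if (from == 1) { st = 1; ngaps++; }
    }
  }
  int qstart = i, tstart = j;
  std::reverse(ops.begin(), ops.end());
  std::string cig;
  for (size_t k2 = 0; k2 < ops.size(); ++k2)
    cig += std::to_string(ops[k2].second) + ops[k2].first;

  res.score = best; res.cigar = cig;
  res.qstart = qstart; res.qend = bi; res.tstart = tstart; res.tend = bj;
  res.ngaps = ngaps; res.nmm = nmm;
}

// [[Rcpp::export]]
List sw_affine_cpp(std::string q, std::string t,
                   int match, int mismatch, int gap_open, int gap_extend,
                   bool global = false) {
  int m = (int) q.size(), n = (int) t.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if ((double) m * (double) n > 3e7)
    stop("alignment problem too large (%d x %d)", m, n);
  AlnRes res; AlnBuffers buf;
  affine_align(q.c_str(), m, t.c_str(), n, match, mismatch, gap_open,
               gap_extend, global, res, buf);
  return List::create(_["score"] = res.score, _["cigar"] = res.cigar,
                      _["qstart"] = res.qstart, _["qend"] = res.qend,
                      _["tstart"] = res.tstart, _["tend"] = res.tend,
                      _["n_gaps"] = res.ngaps, _["n_mismatch"] = res.nmm);
}

// ---------------------------------------------------------------------------
// k-mer seed index
// ---------------------------------------------------------------------------

struct SeedIndex {
  int k;
  int max_hits; // K: lookups returning more are repetitive
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > table;
};

static inline bool encode_kmer(const char* s, int k, uint64_t& key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c;
    switch (s[i]) {
      case 'A': c = 0; break; case 'C': c = 1; break;
      case 'G': c = 2; break; case 'T': c = 3; break;
      default: return false;
    }
    v = (v << 2) | (uint64_t) c;
  }
  key = v;
  return true;
}

// [[Rcpp::export]]
SEXP seed_index_build_cpp(CharacterVector names, CharacterVector seqs,
                          int k, int max_hits) {
  if (k < 4 || k > 20) stop("seed_length must be in [4, 20]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k; idx->max_hits = max_hits;
  for (int i = 0; i < names.size(); ++i) {
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(as<std::string>(seqs[i]));
  }
  for (int ci = 0; ci < (int) idx->seqs.size(); ++ci) {
    const std::string& s = idx->seqs[ci];
    int L = (int) s.size();
    for (int p = 0; p + k <= L; ++p) {
      uint64_t key;
      if (!encode_kmer(s.c_str() + p, k, key)) continue;
      idx->table[key].push_back(std::make_pair(ci, p));
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List seed_index_lookup_cpp(SEXP xp, std::string seed) {
  XPtr<SeedIndex> idx(xp);
  if ((int) seed.size() != idx->k) stop("seed length does not match index k");
  uint64_t key;
  IntegerVector ci, pos;
  bool repetitive = false;
  if (encode_kmer(seed.c_str(), idx->k, key)) {
    auto it = idx->table.find(key);
    if (it != idx->table.end()) {
      repetitive = (int) it->second.size() > idx->max_hits;
      if (!repetitive) {
        for (size_t i = 0; i < it->second.size(); ++i) {
          ci.push_back(it->second[i].first + 1);
          pos.push_back(it->second[i].second);
        }
      } else {
        // still report the count via attribute-free route: caller sees flag
      }
    }
  }
  return List::create(_["contig"] = ci, _["pos"] = pos,
                      _["repetitive"] = repetitive);
}

// [[Rcpp::export]]
List seed_index_info_cpp(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  CharacterVector nm(idx->names.size());
  IntegerVector len(idx->names.size());
  for (size_t i = 0; i < idx->names.size(); ++i) {
    nm[i] = idx->names[i];
    len[i] = (int) idx->seqs[i].size();
  }
  return List::create(_["k"] = idx->k, _["max_hits"] = idx->max_hits,
                      _["contig"] = nm, _["length"] = len);
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break; case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break; case 'T': r[i] = 'A'; break;
      default: r[i] = 'N';
    }
  }
  return r;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  out.attr("names") = x.attr("names");
  return out;
}

struct CandAln {
  int ci; int pos; bool minus; std::string cigar;
  int score; int ngaps; int nmm; bool full;
};

// [[Rcpp::export]]
List map_reads_cpp(SEXP xp, CharacterVector read_ids, CharacterVector read_seqs,
                   CharacterVector read_quals,
                   int max_candidates, int match, int mismatch,
                   int gap_open, int gap_extend, int pad = 8,
                   int mapq_slope = 6) {
  XPtr<SeedIndex> idx(xp);
  int k = idx->k, K = idx->max_hits;
  int nr = read_ids.size();
  CharacterVector o_id(nr), o_rname(nr), o_cigar(nr), o_seq(nr), o_qual(nr);
  IntegerVector o_flag(nr), o_pos(nr), o_mapq(nr), o_nm(nr), o_score(nr);
  AlnRes al; AlnBuffers buf;
  std::vector<long long> seen;
  std::vector<CandAln> results;

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    std::string qual = as<std::string>(read_quals[r]);
    int len = (int) fwd.size();
    std::string rev = revcomp(fwd);

    // collect candidate (contig, start, strand), dedupe
    seen.clear();
    bool capped = false;
    for (int strand = 0; strand < 2 && !capped; ++strand) {
      const std::string& s = (strand == 0) ? fwd : rev;
      for (int o = 0; o + k <= len && !capped; ++o) {
        uint64_t key;
        if (!encode_kmer(s.c_str() + o, k, key)) continue;
        auto it = idx->table.find(key);
        if (it == idx->table.end()) continue;
        if ((int) it->second.size() > K) continue; // repetitive lookup ignored
        for (size_t h = 0; h < it->second.size(); ++h) {
          int ci = it->second[h].first;
          long long start = (long long) it->second[h].second - o;
          long long packed = ((long long) ci << 34) | ((start + 1000) << 1) | (long long) strand;
          if (std::find(seen.begin(), seen.end(), packed) != seen.end())
            continue;
          seen.push_back(packed);
          if ((int) seen.size() >= max_candidates) { capped = true; break; }
        }
      }
    }

    results.clear();
    for (size_t c = 0; c < seen.size(); ++c) {
      long long packed = seen[c];
      bool minus = (packed & 1LL) != 0;
      long long start = ((packed >> 1) & ((1LL << 33) - 1)) - 1000;
      int ci = (int) (packed >> 34);
      const std::string& contig = idx->seqs[ci];
      int clen = (int) contig.size();
      const std::string& s = minus ? rev : fwd;
      CandAln ca; ca.ci = ci; ca.minus = minus;
      // quick exact check
      if (start >= 0 && start + len <= clen &&
          memcmp(contig.c_str() + start, s.c_str(), len) == 0) {
        ca.pos = (int) start; ca.cigar = std::to_string(len) + "M";
        ca.score = len * match; ca.ngaps = 0; ca.nmm = 0; ca.full = true;
        results.push_back(ca);
        continue;
      }
      int ws = (int) std::max(0LL, start - pad);
      int we = (int) std::min((long long) clen, start + len + pad);
      if (we - ws < k) continue;
      affine_align(s.c_str(), len, contig.c_str() + ws, we - ws,
                   match, mismatch, gap_open, gap_extend, false, al, buf);
      ca.pos = ws + al.tstart;
      ca.cigar = al.cigar;
      ca.score = al.score; ca.ngaps = al.ngaps; ca.nmm = al.nmm;
      ca.full = (al.qstart == 0 && al.qend == len);
      if (!ca.full) {
        // represent clipping in the cigar for bookkeeping
        std::string cg;
        if (al.qstart > 0) cg += std::to_string(al.qstart) + "S";
        cg += ca.cigar;
        if (al.qend < len) cg += std::to_string(len - al.qend) + "S";
        ca.cigar = cg;
      }
      if (ca.score > 0) results.push_back(ca);
    }

    // dedupe identical placements
    std::sort(results.begin(), results.end(), [](const CandAln& a, const CandAln& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.full != b.full) return a.full;
      if (a.ngaps != b.ngaps) return a.ngaps < b.ngaps;
      if (a.ci != b.ci) return a.ci < b.ci;
      if (a.pos != b.pos) return a.pos < b.pos;
      if (a.minus != b.minus) return !a.minus;
      return a.cigar < b.cigar;
    });
    std::vector<CandAln> uniq;
    for (size_t c = 0; c < results.size(); ++c) {
      bool dup = false;
      for (size_t u = 0; u < uniq.size(); ++u) {
        if (uniq[u].ci == results[c].ci && uniq[u].pos == results[c].pos &&
            uniq[u].minus == results[c].minus && uniq[u].cigar == results[c].cigar) {
          dup = true; break;
        }
      }
      if (!dup) uniq.push_back(results[c]);
    }

    o_id[r] = read_ids[r];
    if (uniq.empty() || !uniq[0].full) {
      o_flag[r] = 4; o_rname[r] = "*"; o_pos[r] = 0; o_mapq[r] = 0;
      o_cigar[r] = "*"; o_seq[r] = fwd; o_qual[r] = qual; o_nm[r] = NA_INTEGER;
      o_score[r] = uniq.empty() ? NA_INTEGER : uniq[0].score;
      continue;
    }
    const CandAln& bst = uniq[0];
    // second-best among full-length placements
    int second = NA_INTEGER;
    for (size_t u = 1; u < uniq.size(); ++u) {
      if (uniq[u].full) { second = uniq[u].score; break; }
    }
    int mapq;
    if (second == NA_INTEGER) mapq = 60;
    else if (second >= bst.score) mapq = 0;
    else mapq = std::min(60, mapq_slope * (bst.score - second));
    o_flag[r] = bst.minus ? 16 : 0;
    o_rname[r] = idx->names[bst.ci];
    o_pos[r] = bst.pos + 1; // SAM 1-based
    o_mapq[r] = mapq;
    o_cigar[r] = bst.cigar;
    o_seq[r] = bst.minus ? rev : fwd;
    std::string qq = qual;
    if (bst.minus) std::reverse(qq.begin(), qq.end());
    o_qual[r] = qq;
    o_nm[r] = bst.nmm;
    o_score[r] = bst.score;
  }

  return List::create(_["qname"] = o_id, _["flag"] = o_flag, _["rname"] = o_rname,
                      _["pos"] = o_pos, _["mapq"] = o_mapq, _["cigar"] = o_cigar,
                      _["seq"] = o_seq, _["qual"] = o_qual, _["nm"] = o_nm,
                      _["score"] = o_score);
}

// ---------------------------------------------------------------------------
// CIGAR parsing, indel event extraction (left-aligned), pileup columns
// ---------------------------------------------------------------------------

static bool parse_cigar(const std::string& cg, std::vector<std::pair<char, int> >& ops) {
  ops.clear();
  if (cg == "*" || cg.empty()) return false;
  size_t i = 0;
  while (i < cg.size()) {
    int L = 0; bool any = false;
    while (i < cg.size() && isdigit(cg[i])) { L = L * 10 + (cg[i] - '0'); i++; any = true; }
    if (!any || i >= cg.size()) return false;
    char op = cg[i++];
    if (op != 'M' && op != 'I' && op != 'D' && op != 'S') return false;
    if (L <= 0) return false;
    ops.push_back(std::make_pair(op, L));
  }
  return !ops.empty();
}

// [[Rcpp::export]]
List cigar_span_cpp(CharacterVector cigars) {
  int n = cigars.size();
  IntegerVector qlen(n), rlen(n);
  LogicalVector ok(n);
  std::vector<std::pair<char, int> > ops;
  for (int i = 0; i < n; ++i) {
    std::string cg = as<std::string>(cigars[i]);
    if (!parse_cigar(cg, ops)) { ok[i] = false; qlen[i] = NA_INTEGER; rlen[i] = NA_INTEGER; continue; }
    int ql = 0, rl = 0;
    for (auto& o : ops) {
      if (o.first == 'M') { ql += o.second; rl += o.second; }
      else if (o.first == 'I' || o.first == 'S') ql += o.second;
      else if (o.first == 'D') rl += o.second;
    }
    ok[i] = true; qlen[i] = ql; rlen[i] = rl;
  }
  return List::create(_["ok"] = ok, _["qlen"] = qlen, _["rlen"] = rlen);
}

// Extract left-aligned indel events from alignments.
// pos0: 0-based leftmost reference positions. Returns one row per I/D event.
// [[Rcpp::export]]
DataFrame indel_events_cpp(CharacterVector rname, IntegerVector pos0,
                           CharacterVector cigar, CharacterVector seq,
                           CharacterVector qual,
                           CharacterVector contig_names, CharacterVector contig_seqs) {
  std::unordered_map<std::string, int> cmap;
  for (int i = 0; i < contig_names.size(); ++i)
    cmap[as<std::string>(contig_names[i])] = i;
  std::vector<std::string> ctg;
  for (int i = 0; i < contig_seqs.size(); ++i)
    ctg.push_back(as<std::string>(contig_seqs[i]));

  std::vector<int> e_row, e_anchor, e_qual, e_left, e_right;
  std::vector<std::string> e_contig, e_kind, e_alt;

  std::vector<std::pair<char, int> > ops;
  for (int r = 0; r < rname.size(); ++r) {
    std::string rn = as<std::string>(rname[r]);
    if (rn == "*") continue;
    auto it = cmap.find(rn);
    if (it == cmap.end()) stop("alignment references unknown contig '%s'", rn.c_str());
    const std::string& ref = ctg[it->second];
    std::string cg = as<std::string>(cigar[r]);
    if (!parse_cigar(cg, ops)) continue;
    std::string sq = as<std::string>(seq[r]);
    std::string qu = as<std::string>(qual[r]);
    int len = (int) sq.size();
    int rpos = pos0[r], qpos = 0;
    for (size_t oi = 0; oi < ops.size(); ++oi) {
      char op = ops[oi].first; int L = ops[oi].second;
      if (op == 'M') { rpos += L; qpos += L; }
      else if (op == 'S') { qpos += L; }
      else if (op == 'I') {
        std::string S = sq.substr(qpos, L);
        int r0 = rpos, s = 0;
        while (r0 > 0 && S[L - 1] == ref[r0 - 1]) {
          S = std::string(1, ref[r0 - 1]) + S.substr(0, L - 1);
          r0--; s++;
        }
        int anchor = r0 - 1;
        if (anchor >= 0) {
          int qi = qpos - s;
          int evq = 127;
          for (int b = 0; b < L; ++b) {
            int qv = (int) qu[qi + b] - 33;
            if (qv < evq) evq = qv;
          }
          int left = qi, right = len - qi - L;
          e_row.push_back(r + 1); e_contig.push_back(rn); e_anchor.push_back(anchor);
          e_kind.push_back("insertion"); e_alt.push_back(S);
          e_qual.push_back(evq); e_left.push_back(left); e_right.push_back(right);
        }
        qpos += L;
      } else if (op == 'D') {
        int r0 = rpos, s = 0;
        std::string S = ref.substr(r0, L);
        while (r0 > 0 && ref[r0 - 1] == ref[r0 + L - 1]) { r0--; s++; }
        S = ref.substr(r0, L);
        int anchor = r0 - 1;
        if (anchor >= 0) {
          int qleft = qpos - s; // read bases before the (shifted) deletion
          int evq = 127;
          if (qleft - 1 >= 0) evq = std::min(evq, (int) qu[qleft - 1] - 33);
          if (qleft < len) evq = std::min(evq, (int) qu[qleft] - 33);
          e_row.push_back(r + 1); e_contig.push_back(rn); e_anchor.push_back(anchor);
          e_kind.push_back("deletion"); e_alt.push_back(S);
          e_qual.push_back(evq); e_left.push_back(qleft); e_right.push_back(len - qleft);
        }
        rpos += L;
      }
    }
  }
  return DataFrame::create(_["row"] = e_row, _["contig"] = e_contig,
                           _["anchor"] = e_anchor, _["kind"] = e_kind,
                           _["alt"] = e_alt, _["event_qual"] = e_qual,
                           _["left_bases"] = e_left, _["right_bases"] = e_right,
                           _["stringsAsFactors"] = false);
}

// Per-read entries at requested reference positions.
// Returns one row per (position, covering read): op M (aligned base) or D.
// [[Rcpp::export]]
DataFrame pileup_entries_cpp(CharacterVector rname, IntegerVector pos0,
                             CharacterVector cigar, CharacterVector seq,
                             CharacterVector qual,
                             CharacterVector at_contig, IntegerVector at_pos) {
  int nr = rname.size();
  std::vector<std::pair<char, int> > ops;
  // precompute reference spans
  std::vector<int> rend(nr);
  {
    for (int r = 0; r < nr; ++r) {
      std::string cg = as<std::string>(cigar[r]);
      if (as<std::string>(rname[r]) == "*" || !parse_cigar(cg, ops)) { rend[r] = -1; continue; }
      int rl = 0;
      for (auto& o : ops) if (o.first == 'M' || o.first == 'D') rl += o.second;
      rend[r] = pos0[r] + rl;
    }
  }
  std::vector<int> o_site, o_row, o_baseq;
  std::vector<std::string> o_op, o_base;
  for (int a = 0; a < at_pos.size(); ++a) {
    std::string ac = as<std::string>(at_contig[a]);
    int ap = at_pos[a];
    for (int r = 0; r < nr; ++r) {
      if (rend[r] < 0) continue;
      if (pos0[r] > ap || rend[r] <= ap) continue;
      if (as<std::string>(rname[r]) != ac) continue;
      std::string cg = as<std::string>(cigar[r]);
      parse_cigar(cg, ops);
      std::string sq = as<std::string>(seq[r]);
      std::string qu = as<std::string>(qual[r]);
      int rpos = pos0[r], qpos = 0;
      for (auto& o : ops) {
        if (o.first == 'M') {
          if (ap >= rpos && ap < rpos + o.second) {
            int qi = qpos + (ap - rpos);
            o_site.push_back(a + 1); o_row.push_back(r + 1);
            o_op.push_back("M"); o_base.push_back(std::string(1, sq[qi]));
            o_baseq.push_back((int) qu[qi] - 33);
            break;
          }
          rpos += o.second; qpos += o.second;
        } else if (o.first == 'D') {
          if (ap >= rpos && ap < rpos + o.second) {
            int evq = 127;
            if (qpos - 1 >= 0) evq = std::min(evq, (int) qu[qpos - 1] - 33);
            if (qpos < (int) qu.size()) evq = std::min(evq, (int) qu[qpos] - 33);
            o_site.push_back(a + 1); o_row.push_back(r + 1);
            o_op.push_back("D"); o_base.push_back("*");
            o_baseq.push_back(evq);
            break;
          }
          rpos += o.second;
        } else if (o.first == 'I' || o.first == 'S') {
          qpos += o.second;
        }
        if (rpos > ap) break;
      }
    }
  }
  return DataFrame::create(_["site"] = o_site, _["row"] = o_row, _["op"] = o_op,
                           _["base"] = o_base, _["base_qual"] = o_baseq,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Read error / base-quality simulation (uses R's RNG stream so results are
// a pure function of set.seed in the caller)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List apply_errors_cpp(CharacterVector seqs, double error_rate,
                      int q_high, int q_low, double p_low,
                      double p_low_on_error) {
  int n = seqs.size();
  CharacterVector out_seq(n), out_qual(n);
  IntegerVector n_err(n);
  const char* bases = "ACGT";
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::string qual(s.size(), '!');
    int ne = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      bool err = (error_rate > 0) && (unif_rand() < error_rate);
      if (err) {
        ne++;
        char orig = s[i];
        char nb = orig;
        while (nb == orig) nb = bases[(int) (unif_rand() * 4) % 4];
        s[i] = nb;
      }
      double pl = err ? p_low_on_error : p_low;
      int q = (unif_rand() < pl) ? q_low : q_high;
      qual[i] = (char) (q + 33);
    }
    out_seq[r] = s;
    out_qual[r] = qual;
    n_err[r] = ne;
  }
  return List::create(_["seq"] = out_seq, _["qual"] = out_qual,
                      _["n_errors"] = n_err);
}

// ---------------------------------------------------------------------------
// Gapless alignment scanners (used by the false-positive filters)
// ---------------------------------------------------------------------------

// Offsets (0-based) where the full query matches target with <= max_mm
// mismatches.
// [[Rcpp::export]]
DataFrame ungapped_full_hits_cpp(std::string query, std::string target, int max_mm) {
  int nq = (int) query.size(), nt = (int) target.size();
  std::vector<int> offs, mms;
  for (int off = 0; off + nq <= nt; ++off) {
    int mm = 0;
    for (int i = 0; i < nq; ++i) {
      char a = query[i], b = target[off + i];
      if (a != b || a == 'N') { mm++; if (mm > max_mm) break; }
    }
    if (mm <= max_mm) { offs.push_back(off); mms.push_back(mm); }
  }
  return DataFrame::create(_["offset"] = offs, _["mismatches"] = mms);
}

// Best ungapped local segment (Kadane per diagonal, +1 match / -penalty
// mismatch). Ties resolve to the longer segment, then smaller target start.
// [[Rcpp::export]]
List ungapped_best_segment_cpp(std::string query, std::string target,
                               int mismatch_penalty = 3) {
  int nq = (int) query.size(), nt = (int) target.size();
  int bscore = 0, bqs = 0, bqe = 0, bts = 0, bte = 0, bmm = 0;
  for (int d = -(nq - 1); d <= nt - 1; ++d) {
    int qs = std::max(0, -d), ts = qs + d;
    int run = 0, runmm = 0, rqs = qs;
    for (int q = qs, t = ts; q < nq && t < nt; ++q, ++t) {
      int s = (query[q] == target[t] && query[q] != 'N') ? 1 : -mismatch_penalty;
      if (run + s < 0) { run = 0; runmm = 0; rqs = q + 1; continue; }
      run += s;
      if (s < 0) runmm++;
      int L = q - rqs + 1, bL = bqe - bqs;
      if (run > bscore || (run == bscore && L > bL) ||
          (run == bscore && L == bL && rqs + d < bts)) {
        bscore = run; bqs = rqs; bqe = q + 1; bts = rqs + d; bte = t + 1; bmm = runmm;
      }
    }
  }
  return List::create(_["score"] = bscore, _["qstart"] = bqs, _["qend"] = bqe,
                      _["tstart"] = bts, _["tend"] = bte, _["mismatches"] = bmm);
}
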