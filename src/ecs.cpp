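#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Reverse complement of DNA strings; characters outside ACGT map to N
// (qualities are reversed separately on the R side).
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(STRING_ELT(x, i));
    size_t m = std::strlen(s);
    buf.assign(m, 'N');
    for (size_t j = 0; j < m; ++j) {
      char c = s[m - 1 - j];
      switch (c) {
      case 'A': buf[j] = 'T'; break;
      case 'C': buf[j] = 'G'; break;
      case 'G': buf[j] = 'C'; break;
      case 'T': buf[j] = 'A'; break;
      default:  buf[j] = 'N'; break;
      }
    }
    out[i] = buf;
  }
  return out;
}

// Substitution errors injected at (read, position); `rot` in 1..3 selects the
// replacement among the three non-reference bases in alphabetical order.
// Positions holding non-ACGT characters are left untouched.
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector seqs, IntegerVector read,
                                  IntegerVector pos, IntegerVector rot) {
  CharacterVector out = clone(seqs);
  R_xlen_t ne = read.size();
  std::string buf;
  R_xlen_t k = 0;
  while (k < ne) {
    int ri = read[k] - 1;
    buf.assign(CHAR(STRING_ELT(out, ri)));
    // edits for one read arrive consecutively (callers emit them grouped)
    while (k < ne && read[k] - 1 == ri) {
      int p = pos[k] - 1;
      if (p >= 0 && p < (int)buf.size()) {
        int b = base_code(buf[p]);
        if (b >= 0) {
          int r = rot[k], cnt = 0;
          for (int j = 0; j < 4; ++j) {
            if (j == b) continue;
            if (++cnt == r) { buf[p] = BASES[j]; break; }
          }
        }
      }
      ++k;
    }
    out[ri] = buf;
  }
  return out;
}

// fast "<prefix>:<i>" name generation
// [[Rcpp::export]]
CharacterVector cpp_int_names(std::string prefix, int n) {
  CharacterVector out(n);
  std::string buf;
  prefix.push_back(':');
  for (int i = 0; i < n; ++i) {
    buf = prefix;
    buf += std::to_string(i + 1);
    out[i] = buf;
  }
  return out;
}

// Mismatch counts of equal-placement sequences against a reference window.
// starts are 0-based offsets into ref. Returns a 2-column matrix:
// col 0 = mismatches among ACGT-vs-ACGT columns, col 1 = non-ACGT (N) count.
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_to_ref(CharacterVector seqs, std::string ref,
                                 IntegerVector starts) {
  R_xlen_t n = seqs.size();
  IntegerMatrix out(n, 2);
  int rl = (int)ref.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int m = (int)std::strlen(s);
    int st = starts[i];
    int mm = 0, nn = 0;
    for (int j = 0; j < m; ++j) {
      int rp = st + j;
      char c = s[j];
      if (base_code(c) < 0) { ++nn; continue; }
      if (rp < 0 || rp >= rl || ref[rp] != c) ++mm;
    }
    out(i, 0) = mm;
    out(i, 1) = nn;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-family consensus
// ---------------------------------------------------------------------------
// Reads are oriented to the amplicon top strand before the call. side = 0
// means the read is anchored at the molecule's left end (starts at template
// position 1), side = 1 means it is anchored at the right end (ends at the
// template's last position). The molecule length can differ from amp_len when
// the molecule carries an indel, so the offset of the right-anchored block is
// reconciled per family by a bounded shift scan that maximises agreement
// between the modal left and modal right member over their overlap.
//
// fam must be sorted ascending; reads of one family are contiguous.
// [[Rcpp::export]]
List cpp_consensus(CharacterVector seqs, IntegerVector side, IntegerVector fam,
                   int amp_len, double min_agreement, int min_depth,
                   int max_member_edits, int max_shift, bool collect_support) {
  R_xlen_t n = seqs.size();
  std::vector<int> fstart;
  for (R_xlen_t i = 0; i < n; ++i)
    if (i == 0 || fam[i] != fam[i - 1]) fstart.push_back((int)i);
  int nf = (int)fstart.size();
  fstart.push_back((int)n);

  CharacterVector cons(nf);
  IntegerVector fam_id(nf), start0(nf), n_reads(nf), n_used(nf),
      n_outlier(nf), n_N(nf), cons_len(nf);
  List support_l(collect_support ? nf : 0), depth_l(collect_support ? nf : 0);

  std::vector<const char*> ss;
  std::vector<int> sl;
  std::vector<int> cntA, cntC, cntG, cntT;

  for (int f = 0; f < nf; ++f) {
    int a = fstart[f], b = fstart[f + 1];
    int nm = b - a;
    fam_id[f] = fam[a];
    n_reads[f] = nm;
    ss.resize(nm); sl.resize(nm);
    for (int i = 0; i < nm; ++i) {
      ss[i] = CHAR(STRING_ELT(seqs, a + i));
      sl[i] = (int)std::strlen(ss[i]);
    }
    // modal member per side (ties -> lexicographically smallest); families
    // are small, so distinct members are found by direct comparison
    const char* modal[2] = {nullptr, nullptr};
    int modal_len[2] = {0, 0};
    {
      std::vector<int> d_idx, d_cnt;  // distinct member -> count
      for (int sd = 0; sd < 2; ++sd) {
        d_idx.clear(); d_cnt.clear();
        for (int i = 0; i < nm; ++i) {
          if (side[a + i] != sd) continue;
          bool found = false;
          for (size_t u = 0; u < d_idx.size(); ++u) {
            int j = d_idx[u];
            if (sl[j] == sl[i] && std::memcmp(ss[j], ss[i], sl[i]) == 0) {
              ++d_cnt[u]; found = true; break;
            }
          }
          if (!found) { d_idx.push_back(i); d_cnt.push_back(1); }
        }
        int best = -1, besti = -1;
        for (size_t u = 0; u < d_idx.size(); ++u) {
          int j = d_idx[u];
          bool take = (int)d_cnt[u] > best;
          if ((int)d_cnt[u] == best && besti >= 0) {
            int c = std::memcmp(ss[j], ss[besti],
                                std::min(sl[j], sl[besti]));
            take = c < 0 || (c == 0 && sl[j] < sl[besti]);
          }
          if (take) { best = d_cnt[u]; besti = j; }
        }
        if (besti >= 0) { modal[sd] = ss[besti]; modal_len[sd] = sl[besti]; }
      }
    }

    // molecule span: left block starts at 0; right block end position
    int right_end = -1;
    if (modal[1]) {
      int r0 = amp_len - modal_len[1];  // nominal 0-based offset
      if (modal[0]) {
        int best_d = 0, best_score = -1;
        for (int d = -max_shift; d <= max_shift; ++d) {
          int o = r0 + d;
          int lo = std::max(0, o);
          int hi = std::min(modal_len[0], o + modal_len[1]);
          if (hi - lo < 10) continue;  // demand a usable overlap
          int sc = 0;
          for (int p = lo; p < hi; ++p)
            if (modal[0][p] == modal[1][p - o]) ++sc;
          if (sc > best_score ||
              (sc == best_score && std::abs(d) < std::abs(best_d)) ||
              (sc == best_score && std::abs(d) == std::abs(best_d) && d < best_d)) {
            best_score = sc; best_d = d;
          }
        }
        if (best_score < 0) best_d = 0;
        right_end = r0 + best_d + modal_len[1];
      } else {
        right_end = amp_len;  // right-only family: assume reference length
      }
    }
    int Lm;                       // span length of the consensus
    int origin;                   // 0-based template coordinate of column 0
    if (modal[0] && modal[1]) {
      Lm = std::max(modal_len[0], right_end);
      origin = 0;
    } else if (modal[0]) {
      int mx = 0;
      for (int i = 0; i < nm; ++i) if (side[a+i]==0) mx = std::max(mx, sl[i]);
      Lm = mx; origin = 0;
    } else {
      int mx = 0;
      for (int i = 0; i < nm; ++i) if (side[a+i]==1) mx = std::max(mx, sl[i]);
      Lm = mx; origin = std::max(0, right_end - mx);
    }

    // member filtering + voting
    cntA.assign(Lm, 0); cntC.assign(Lm, 0); cntG.assign(Lm, 0); cntT.assign(Lm, 0);
    int used = 0, outl = 0;
    for (int i = 0; i < nm; ++i) {
      int sd = side[a + i];
      const char* s = ss[i];
      int m = sl[i];
      // discordance vs side modal, compared from the anchored end
      if (modal[sd]) {
        int ov = std::min(m, modal_len[sd]);
        int mm = 0;
        for (int j = 0; j < ov; ++j) {
          char c1 = sd == 0 ? s[j] : s[m - 1 - j];
          char c2 = sd == 0 ? modal[sd][j] : modal[sd][modal_len[sd] - 1 - j];
          if (base_code(c1) >= 0 && base_code(c2) >= 0 && c1 != c2) ++mm;
        }
        if (mm > max_member_edits) { ++outl; continue; }
      }
      int off = sd == 0 ? -origin : (right_end - m) - origin;
      for (int j = 0; j < m; ++j) {
        int p = off + j;
        if (p < 0 || p >= Lm) continue;
        switch (s[j]) {
        case 'A': ++cntA[p]; break;
        case 'C': ++cntC[p]; break;
        case 'G': ++cntG[p]; break;
        case 'T': ++cntT[p]; break;
        default: break;
        }
      }
      ++used;
    }

    std::string cs(Lm, 'N');
    int nN = 0;
    IntegerVector supv(collect_support ? Lm : 0), depv(collect_support ? Lm : 0);
    for (int p = 0; p < Lm; ++p) {
      int c[4] = {cntA[p], cntC[p], cntG[p], cntT[p]};
      int depth = c[0] + c[1] + c[2] + c[3];
      int mx = 0, arg = -1; bool tie = false;
      for (int j = 0; j < 4; ++j) {
        if (c[j] > mx) { mx = c[j]; arg = j; tie = false; }
        else if (c[j] == mx && mx > 0) tie = true;
      }
      char base = 'N';
      if (depth >= min_depth && arg >= 0 && !tie &&
          (double)mx / depth + 1e-9 >= min_agreement)
        base = BASES[arg];
      cs[p] = base;
      if (base == 'N') ++nN;
      if (collect_support) { supv[p] = mx; depv[p] = depth; }
    }
    cons[f] = cs;
    start0[f] = origin;
    n_used[f] = used;
    n_outlier[f] = outl;
    n_N[f] = nN;
    cons_len[f] = Lm;
    if (collect_support) { support_l[f] = supv; depth_l[f] = depv; }
  }

  List out = List::create(
      _["fam"] = fam_id, _["consensus"] = cons, _["start"] = start0,
      _["length"] = cons_len, _["n_reads"] = n_reads, _["n_used"] = n_used,
      _["n_outliers"] = n_outlier, _["n_N"] = n_N);
  if (collect_support) {
    out["support"] = support_l;
    out["depth"] = depth_l;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fitting (glocal) alignment of a consensus sequence to its amplicon
// ---------------------------------------------------------------------------
// Unit edit costs (match 0, mismatch 1, gap 1); leading/trailing reference
// bases are free, so the query finds its best placement within the amplicon.
// Indels are left-normalised after traceback (a deletion of ref[i..j] shifts
// to ref[i-1..j-1] while ref[i-1] == ref[j]; an insertion anchored after ref
// position p rotates leftwards while ref[p] equals its last base), giving one
// canonical position for indels in repeat context.

struct AlnResult {
  int status;        // 0 ok, 1 unalignable
  int ref_start;     // 1-based first covered ref position
  int ref_end;       // 1-based last covered ref position
  std::string aligned;   // per covered ref position: base, N, or '-'
  std::vector<int> ins_pos;       // 1-based ref pos each insertion anchors after
  std::vector<std::string> ins_seq;
  int n_match, n_col;
};

static AlnResult fit_align_one(const char* q, int m, const std::string& ref,
                               double min_identity) {
  int n = (int)ref.size();
  AlnResult res; res.status = 1; res.ref_start = NA_INTEGER; res.ref_end = NA_INTEGER;
  res.n_match = 0; res.n_col = 0;
  if (m == 0) return res;
  // DP over query rows i (0..m), ref cols j (0..n); free ref prefix/suffix.
  std::vector<int> prev(n + 1), cur(n + 1);
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1));  // 0 diag,1 up(ins),2 left(del)
  for (int j = 0; j <= n; ++j) { prev[j] = 0; tb[j] = 2; }
  for (int i = 1; i <= m; ++i) {
    cur[0] = i; tb[(size_t)i * (n + 1)] = 1;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (q[i - 1] == ref[j - 1] ? 0 : 1);
      int up = prev[j] + 1;     // insertion in query (consumes query)
      int left = cur[j - 1] + 1;  // deletion (consumes ref)
      // preference on ties: deletion, then insertion, then diagonal, so gaps
      // are pushed toward the start during traceback; final left-shift below
      // makes the choice canonical regardless.
      int best = sub; unsigned char dir = 0;
      if (up < best) { best = up; dir = 1; }
      if (left < best) { best = left; dir = 2; }
      cur[j] = best; tb[(size_t)i * (n + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  // best end column on the last row (free ref suffix); ties -> smallest j
  int best_j = 0, best_cost = prev[0];
  for (int j = 1; j <= n; ++j)
    if (prev[j] < best_cost) { best_cost = prev[j]; best_j = j; }
  // traceback
  std::vector<unsigned char> ops;  // 0 M/X, 1 I, 2 D
  int i = m, j = best_j;
  while (i > 0) {
    unsigned char d = tb[(size_t)i * (n + 1) + j];
    if (j == 0) d = 1;
    ops.push_back(d);
    if (d == 0) { --i; --j; }
    else if (d == 1) --i;
    else --j;
  }
  int ref_start0 = j;  // 0-based first consumed ref index
  std::reverse(ops.begin(), ops.end());
  // build op runs into explicit records
  // query segments for insertions
  struct Ins { int anchor; std::string seq; };  // anchor: 0-based ref idx it follows (can be ref_start0-1)
  std::vector<Ins> inss;
  std::string aligned;  // over ref positions ref_start0..best_j-1
  int qi = 0, rj = ref_start0;
  int n_match = 0, n_col = 0, n_qN = 0;
  for (size_t k = 0; k < ops.size();) {
    if (ops[k] == 0) {
      char qc = q[qi];
      aligned.push_back(qc);
      ++n_col;
      if (base_code(qc) < 0) ++n_qN;
      else if (qc == ref[rj]) ++n_match;
      ++qi; ++rj; ++k;
    } else if (ops[k] == 2) {
      aligned.push_back('-');
      ++n_col;
      ++rj; ++k;
    } else {
      Ins in; in.anchor = rj - 1; in.seq.clear();
      while (k < ops.size() && ops[k] == 1) { in.seq.push_back(q[qi]); ++qi; ++k; ++n_col; }
      inss.push_back(in);
    }
  }
  // identity excludes query-N columns (no-calls are not errors)
  int eff = n_col - n_qN;
  double ident = eff > 0 ? (double)n_match / eff : 0.0;
  if (ident < min_identity) return res;

  // left-normalise deletions within the aligned string
  int alen = (int)aligned.size();
  bool moved = true;
  while (moved) {
    moved = false;
    for (int p = 0; p < alen; ++p) {
      if (aligned[p] != '-') continue;
      int e = p;
      while (e + 1 < alen && aligned[e + 1] == '-') ++e;
      // block [p..e] deletes ref[ref_start0+p .. ref_start0+e]
      if (p > 0 && aligned[p - 1] != '-' &&
          ref[ref_start0 + p - 1] == ref[ref_start0 + e] &&
          aligned[p - 1] == ref[ref_start0 + p - 1]) {
        // shift block one left: the matched base re-pairs with ref[e]
        char mv = aligned[p - 1];
        aligned[p - 1] = '-';
        aligned[e] = mv;
        moved = true;
      }
      p = e;
    }
  }
  // left-normalise insertions
  for (auto& in : inss) {
    while (in.anchor >= ref_start0 && !in.seq.empty() &&
           ref[in.anchor] == in.seq.back() &&
           in.anchor - ref_start0 < (int)aligned.size() &&
           aligned[in.anchor - ref_start0] == ref[in.anchor]) {
      in.seq = std::string(1, ref[in.anchor]) + in.seq.substr(0, in.seq.size() - 1);
      in.anchor -= 1;
    }
  }

  res.status = 0;
  res.ref_start = ref_start0 + 1;
  res.ref_end = ref_start0 + alen;
  res.aligned = aligned;
  res.n_match = n_match;
  res.n_col = n_col;
  for (auto& in : inss) {
    res.ins_pos.push_back(in.anchor + 1);  // 1-based ref pos it follows; 0 = before ref
    res.ins_seq.push_back(in.seq);
  }
  return res;
}

// [[Rcpp::export]]
List cpp_align_batch(CharacterVector queries, std::string ref,
                     double min_identity) {
  R_xlen_t n = queries.size();
  IntegerVector status(n), ref_start(n), ref_end(n), n_match(n), n_col(n);
  CharacterVector aligned(n);
  List ins(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(queries, i));
    AlnResult r = fit_align_one(q, (int)std::strlen(q), ref, min_identity);
    status[i] = r.status;
    ref_start[i] = r.ref_start;
    ref_end[i] = r.ref_end;
    n_match[i] = r.n_match;
    n_col[i] = r.n_col;
    aligned[i] = r.status == 0 ? r.aligned : std::string();
    if (r.ins_pos.empty()) ins[i] = R_NilValue;
    else ins[i] = List::create(_["pos"] = wrap(r.ins_pos), _["seq"] = wrap(r.ins_seq));
  }
  return List::create(_["status"] = status, _["ref_start"] = ref_start,
                      _["ref_end"] = ref_end, _["aligned"] = aligned,
                      _["n_match"] = n_match, _["n_col"] = n_col,
                      _["insertions"] = ins);
}

// Weighted per-reference-position base counts from aligned strings.
// Rows: A, C, G, T, N, gap. ref_start is 1-based.
// [[Rcpp::export]]
NumericMatrix cpp_column_counts(CharacterVector aligned, IntegerVector ref_start,
                                NumericVector weight, int amp_len) {
  NumericMatrix out(6, amp_len);
  R_xlen_t n = aligned.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(aligned, i));
    int m = (int)std::strlen(s);
    int st = ref_start[i] - 1;
    double w = weight[i];
    for (int j = 0; j < m; ++j) {
      int p = st + j;
      if (p < 0 || p >= amp_len) continue;
      int row;
      switch (s[j]) {
      case 'A': row = 0; break;
      case 'C': row = 1; break;
      case 'G': row = 2; break;
      case 'T': row = 3; break;
      case '-': row = 5; break;
      default:  row = 4; break;
      }
      out(row, p) += w;
    }
  }
  return out;
}
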