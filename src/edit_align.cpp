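#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// N never matches anything, including another N.
static inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

//' Semi-global edit-distance scan with start tracking.
//'
//' Aligns \code{pattern} against every substring of \code{text}
//' (free start and end in the text, whole pattern consumed) and reports,
//' for every end position whose best alignment has at most
//' \code{max_edits} edits, the 0-based half-open interval and edit count.
//' Intended for short texts (reads); cost is O(|pattern| * |text|).
//'
//' @param pattern,text upper-case DNA strings; N counts as a mismatch.
//' @param max_edits maximum Levenshtein distance reported.
//' @return data.frame with columns start, end, edits (0-based half-open).
//' @keywords internal
// [[Rcpp::export]]
DataFrame edit_locate_cpp(std::string pattern, std::string text, int max_edits) {
  const int m = (int) pattern.size();
  const int n = (int) text.size();
  if (m == 0) stop("pattern must be non-empty");
  std::vector<int> dp(m + 1), st(m + 1), dp_prev(m + 1), st_prev(m + 1);
  std::vector<int> out_start, out_end, out_ed;
  for (int i = 0; i <= m; ++i) { dp_prev[i] = i; st_prev[i] = 0; }
  if (dp_prev[m] <= max_edits) {
    out_start.push_back(0); out_end.push_back(0); out_ed.push_back(dp_prev[m]);
  }
  for (int j = 1; j <= n; ++j) {
    dp[0] = 0; st[0] = j;
    const char tc = text[j - 1];
    for (int i = 1; i <= m; ++i) {
      int best = dp_prev[i - 1] + (base_match(pattern[i - 1], tc) ? 0 : 1);
      int bs = st_prev[i - 1];
      const int ins = dp_prev[i] + 1;  // text base unmatched
      if (ins < best || (ins == best && st_prev[i] < bs)) { best = ins; bs = st_prev[i]; }
      const int del = dp[i - 1] + 1;   // pattern base unmatched
      if (del < best || (del == best && st[i - 1] < bs)) { best = del; bs = st[i - 1]; }
      dp[i] = best; st[i] = bs;
    }
    if (dp[m] <= max_edits) {
      out_start.push_back(st[m]); out_end.push_back(j); out_ed.push_back(dp[m]);
    }
    std::swap(dp, dp_prev); std::swap(st, st_prev);
  }
  return DataFrame::create(_["start"] = out_start, _["end"] = out_end,
                           _["edits"] = out_ed);
}

//' Non-overlapping approximate occurrences, greedy by (edits, position).
//'
//' Runs the semi-global DP, then selects candidate matches greedily by
//' ascending edit distance (ties: leftmost start, then shortest end) under
//' a non-overlap constraint. Returns matches sorted by start.
//'
//' @keywords internal
// [[Rcpp::export]]
DataFrame repeat_locate_cpp(std::string pattern, std::string text,
                            int max_edits) {
  DataFrame cand = edit_locate_cpp(pattern, text, max_edits);
  IntegerVector cs = cand["start"], ce = cand["end"], cd = cand["edits"];
  const int nc = cs.size();
  std::vector<int> idx(nc);
  for (int i = 0; i < nc; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (cd[a] != cd[b]) return cd[a] < cd[b];
    if (cs[a] != cs[b]) return cs[a] < cs[b];
    return ce[a] < ce[b];
  });
  std::vector<bool> taken(text.size() + 1, false);
  std::vector<int> os, oe, od;
  for (int t = 0; t < nc; ++t) {
    const int i = idx[t];
    if (ce[i] <= cs[i]) continue;   // zero-length: cannot happen for DNA
    bool free_span = true;
    for (int p = cs[i]; p < ce[i]; ++p) {
      if (taken[p]) { free_span = false; break; }
    }
    if (!free_span) continue;
    for (int p = cs[i]; p < ce[i]; ++p) taken[p] = true;
    os.push_back(cs[i]); oe.push_back(ce[i]); od.push_back(cd[i]);
  }
  std::vector<int> ord(os.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int) i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return os[a] < os[b]; });
  IntegerVector rs(os.size()), re(os.size()), rd(os.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    rs[i] = os[ord[i]]; re[i] = oe[ord[i]]; rd[i] = od[ord[i]];
  }
  return DataFrame::create(_["start"] = rs, _["end"] = re, _["edits"] = rd);
}

//' All exact occurrences of a pattern (0-based starts).
//'
//' @keywords internal
// [[Rcpp::export]]
IntegerVector find_exact_cpp(std::string pattern, std::string text) {
  std::vector<int> out;
  if (!pattern.empty() && pattern.size() <= text.size()) {
    size_t pos = text.find(pattern, 0);
    while (pos != std::string::npos) {
      out.push_back((int) pos);
      pos = text.find(pattern, pos + 1);
    }
  }
  return wrap(out);
}

//' Myers bit-parallel approximate search (pattern length <= 64).
//'
//' Computes, for every end position in \code{text}, the minimum edit
//' distance of \code{pattern} against a substring ending there (semi-global,
//' text start free). Returns end positions scoring at most \code{max_edits}
//' plus the global minimum. O(|text|) with 64-bit words; used to scan
//' chromosome/plasmid references.
//'
//' @keywords internal
// [[Rcpp::export]]
List myers_scan_cpp(std::string pattern, std::string text, int max_edits) {
  const int m = (int) pattern.size();
  const int n = (int) text.size();
  if (m < 1 || m > 64) stop("pattern length must be in 1..64");
  uint64_t Peq[256];
  std::fill(Peq, Peq + 256, 0ULL);
  for (int i = 0; i < m; ++i) {
    const char c = pattern[i];
    if (c == 'A' || c == 'C' || c == 'G' || c == 'T')
      Peq[(unsigned char) c] |= (1ULL << i);
    // N in the pattern matches nothing: leave all masks clear.
  }
  const uint64_t hbit = 1ULL << (m - 1);
  uint64_t Pv = ~0ULL, Mv = 0ULL;
  int score = m, best = m + max_edits + 1;
  std::vector<int> ends, scores;
  for (int j = 0; j < n; ++j) {
    const uint64_t Eq = Peq[(unsigned char) text[j]];
    const uint64_t Xv = Eq | Mv;
    const uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
    uint64_t Ph = Mv | ~(Xh | Pv);
    uint64_t Mh = Pv & Xh;
    if (Ph & hbit) ++score; else if (Mh & hbit) --score;
    Ph <<= 1;            // first text row is all zero: no carry-in
    Mh <<= 1;
    Pv = Mh | ~(Xv | Ph);
    Mv = Ph & Xv;
    if (score <= max_edits) { ends.push_back(j + 1); scores.push_back(score); }
    if (score < best) best = score;
  }
  return List::create(_["end"] = wrap(ends), _["score"] = wrap(scores),
                      _["best"] = best);
}
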