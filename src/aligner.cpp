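#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Ungapped seed-and-extend scan between two encoded sequences.
//
// q, s: integer codes >= 0 indexing into `score`; codes >= n_seed_codes are
// legal residues (e.g. ambiguity codes, X) that may be extended through but
// never seed. Seeds are exact matches of `word` consecutive codes, all
// < n_seed_codes. Extension is ungapped in both directions with an X-drop
// cut-off on the raw score. Extensions starting inside a region already
// covered by an extension on the same diagonal are skipped; remaining
// same-diagonal overlaps are resolved afterwards by keeping the higher score.
//
// Returns a matrix with columns: q_start, q_end (half-open, 0-based),
// s_start, s_end, raw_score, length, identities.
// [[Rcpp::export]]
IntegerMatrix hsp_scan_cpp(IntegerVector q, IntegerVector s,
                           IntegerMatrix score, int word, int xdrop,
                           int n_seed_codes) {
  const int lq = q.size(), ls = s.size();
  std::vector<long> rows; // flattened results, 7 per HSP

  if (lq >= word && ls >= word) {
    // hash every word of the subject (counting sort into buckets)
    long n_hash = 1;
    for (int k = 0; k < word; ++k) n_hash *= n_seed_codes;

    const int ns_words = ls - word + 1;
    std::vector<long> s_hash(ns_words, -1);
    {
      long h = 0, top = n_hash / n_seed_codes;
      for (int i = 0; i < ls; ++i) {
        int c = s[i];
        bool ok = (c >= 0 && c < n_seed_codes);
        h = (h % top) * n_seed_codes + (ok ? c : 0);
        if (i < word - 1) continue;
        int start = i + 1 - word;
        bool valid = true;
        for (int k = start; k < start + word; ++k) {
          int ck = s[k];
          if (ck < 0 || ck >= n_seed_codes) { valid = false; break; }
        }
        if (valid) s_hash[start] = h;
      }
    }
    std::vector<int> counts((size_t)n_hash + 1, 0);
    for (int i = 0; i < ns_words; ++i)
      if (s_hash[i] >= 0) counts[s_hash[i] + 1]++;
    for (long h = 0; h < n_hash; ++h) counts[h + 1] += counts[h];
    std::vector<int> bucket(counts[n_hash]);
    {
      std::vector<int> fill(counts.begin(), counts.end() - 1);
      for (int i = 0; i < ns_words; ++i)
        if (s_hash[i] >= 0) bucket[fill[s_hash[i]]++] = i;
    }

    // per-diagonal coverage: furthest query end reached by an extension
    std::vector<int> diag_end((size_t)lq + ls + 1, -1);

    long qh = 0, top = n_hash / n_seed_codes;
    for (int j = 0; j < lq; ++j) {
      int c = q[j];
      bool ok = (c >= 0 && c < n_seed_codes);
      qh = (qh % top) * n_seed_codes + (ok ? c : 0);
      if (j < word - 1) continue;
      int start = j + 1 - word;
      bool valid = true;
      for (int k = start; k < start + word; ++k) {
        int ck = q[k];
        if (ck < 0 || ck >= n_seed_codes) { valid = false; break; }
      }
      if (!valid) continue;

      for (int b = counts[qh]; b < counts[qh + 1]; ++b) {
        const int i = bucket[b];          // subject seed start
        const int jj0 = start;            // query seed start
        const long d = (long)jj0 - i + ls;
        if (jj0 < diag_end[d]) continue;  // inside a previous extension

        // seed score
        int cur = 0;
        for (int k = 0; k < word; ++k) cur += score(q[jj0 + k], s[i + k]);
        int best = cur, bq_end = jj0 + word;
        // extend right
        for (int a = jj0 + word, bpos = i + word; a < lq && bpos < ls;
             ++a, ++bpos) {
          cur += score(q[a], s[bpos]);
          if (cur > best) { best = cur; bq_end = a + 1; }
          if (cur < best - xdrop) break;
        }
        // extend left
        int bq_start = jj0;
        cur = best;
        for (int a = jj0 - 1, bpos = i - 1; a >= 0 && bpos >= 0; --a, --bpos) {
          cur += score(q[a], s[bpos]);
          if (cur > best) { best = cur; bq_start = a; }
          if (cur < best - xdrop) break;
        }
        const int len = bq_end - bq_start;
        const int ss = i - (jj0 - bq_start);
        int ident = 0;
        for (int k = 0; k < len; ++k)
          if (q[bq_start + k] == s[ss + k]) ++ident;
        rows.push_back(bq_start); rows.push_back(bq_end);
        rows.push_back(ss); rows.push_back(ss + len);
        rows.push_back(best); rows.push_back(len); rows.push_back(ident);
        if (bq_end > diag_end[d]) diag_end[d] = bq_end;
      }
    }
  }

  // resolve residual overlaps on the same diagonal: keep the higher score
  const int n = rows.size() / 7;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  auto diag_of = [&](int i) { return rows[7 * i] - rows[7 * i + 2]; };
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    long da = diag_of(a), db = diag_of(b);
    if (da != db) return da < db;
    return rows[7 * a] < rows[7 * b];
  });
  std::vector<bool> keep(n, true);
  for (int k = 1, prev = 0; k < n; ++k) {
    int a = idx[k], p = idx[prev];
    if (diag_of(a) == diag_of(p) && rows[7 * a] < rows[7 * p + 1]) {
      if (rows[7 * a + 4] > rows[7 * p + 4]) { keep[p] = false; prev = k; }
      else keep[a] = false;
    } else prev = k;
  }

  int n_keep = 0;
  for (int i = 0; i < n; ++i) if (keep[i]) ++n_keep;
  IntegerMatrix out(n_keep, 7);
  for (int i = 0, r = 0; i < n; ++i) {
    if (!keep[i]) continue;
    for (int c = 0; c < 7; ++c) out(r, c) = (int)rows[7 * i + c];
    ++r;
  }
  colnames(out) = CharacterVector::create("q_start", "q_end", "s_start",
                                          "s_end", "raw_score", "length",
                                          "identities");
  return out;
}
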