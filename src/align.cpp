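#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3, anything else (N) = -1 and never matches.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

struct Hit {
  int start, end, matches, alen, score;
};

// Smith-Waterman of `primer` against read[w0, w1), linear gap penalty.
// Returns the single best local alignment in the window (deterministic
// tie-break: the DP keeps the first-seen maximum in row-major order, and the
// traceback prefers diagonal, then up, then left).
static bool sw_window(const std::string& read, int w0, int w1,
                      const std::string& primer,
                      int ma, int mi, int gp, Hit& out) {
  const int m = (int) primer.size();
  const int n = w1 - w0;
  if (n <= 0 || m <= 0) return false;
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  const int stride = n + 1;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const char a = primer[i - 1];
    const bool a_ok = base_code(a) >= 0;
    for (int j = 1; j <= n; ++j) {
      const char b = read[w0 + j - 1];
      const int s = (a_ok && a == b) ? ma : mi;
      int v = H[(size_t)(i - 1) * stride + (j - 1)] + s;
      const int up = H[(size_t)(i - 1) * stride + j] + gp;
      const int lf = H[(size_t)i * stride + (j - 1)] + gp;
      if (up > v) v = up;
      if (lf > v) v = lf;
      if (v < 0) v = 0;
      H[(size_t)i * stride + j] = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  // traceback
  int i = bi, j = bj, matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    const int h = H[(size_t)i * stride + j];
    if (h == 0) break;
    const char a = primer[i - 1];
    const char b = read[w0 + j - 1];
    const int s = (base_code(a) >= 0 && a == b) ? ma : mi;
    if (h == H[(size_t)(i - 1) * stride + (j - 1)] + s) {
      if (s == ma) ++matches;
      ++cols; --i; --j;
    } else if (h == H[(size_t)(i - 1) * stride + j] + gp) {
      ++cols; --i;
    } else {
      ++cols; --j;
    }
  }
  out.start = w0 + j;       // 0-based inclusive
  out.end = w0 + bj;        // 0-based exclusive
  out.matches = matches;
  out.alen = cols;
  out.score = best;
  return true;
}

// Seed index of a primer: kmer code -> positions in primer.
static void build_seed_index(const std::string& primer, int k,
                             std::unordered_map<uint32_t, std::vector<int> >& idx) {
  const int m = (int) primer.size();
  for (int p = 0; p + k <= m; ++p) {
    uint32_t code = 0;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      const int c = base_code(primer[p + t]);
      if (c < 0) { ok = false; break; }
      code = (code << 2) | (uint32_t) c;
    }
    if (ok) idx[code].push_back(p);
  }
}

//' @noRd
// [[Rcpp::export(name = ".scan_primers_cpp")]]
DataFrame scan_primers_cpp(CharacterVector reads, CharacterVector primers,
                           int seed_len, int min_len, double min_identity,
                           int match, int mismatch, int gap) {
  const int np = primers.size();
  std::vector<std::string> prim(np);
  std::vector<std::unordered_map<uint32_t, std::vector<int> > > seed_idx(np);
  int max_plen = 0;
  for (int p = 0; p < np; ++p) {
    prim[p] = as<std::string>(primers[p]);
    build_seed_index(prim[p], seed_len, seed_idx[p]);
    max_plen = std::max(max_plen, (int) prim[p].size());
  }
  const int pad = 8;
  const int band = 6;
  const uint32_t mask = (seed_len >= 16) ? 0xFFFFFFFFu
                                         : ((1u << (2 * seed_len)) - 1u);

  std::vector<int> o_read, o_primer, o_start, o_end, o_matches, o_alen, o_score;

  for (int r = 0; r < (int) reads.size(); ++r) {
    const std::string rd = as<std::string>(reads[r]);
    const int n = (int) rd.size();
    if (n < seed_len) continue;
    // rolling kmer codes over the read, with N handling
    std::vector<uint32_t> codes(n, 0);
    std::vector<char> valid(n, 0);
    uint32_t code = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      const int c = base_code(rd[i]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t) c) & mask;
      ++run;
      if (run >= seed_len) { codes[i - seed_len + 1] = code; valid[i - seed_len + 1] = 1; }
    }
    for (int p = 0; p < np; ++p) {
      const int plen = (int) prim[p].size();
      // collect seeds as (diag, read_pos)
      std::vector<std::pair<int, int> > seeds;
      const std::unordered_map<uint32_t, std::vector<int> >& idx = seed_idx[p];
      for (int i = 0; i + seed_len <= n; ++i) {
        if (!valid[i]) continue;
        std::unordered_map<uint32_t, std::vector<int> >::const_iterator it =
          idx.find(codes[i]);
        if (it == idx.end()) continue;
        for (size_t t = 0; t < it->second.size(); ++t)
          seeds.push_back(std::make_pair(i - it->second[t], i));
      }
      if (seeds.empty()) continue;
      std::sort(seeds.begin(), seeds.end());
      std::vector<Hit> hits;
      size_t s0 = 0;
      while (s0 < seeds.size()) {
        size_t s1 = s0 + 1;
        int dmin = seeds[s0].first, dmax = seeds[s0].first;
        int rlast = seeds[s0].second;
        while (s1 < seeds.size()) {
          const int d = seeds[s1].first, rp = seeds[s1].second;
          if (d - dmin > band) break;
          if (d == seeds[s1 - 1].first && rp - rlast > plen + pad) break;
          dmax = std::max(dmax, d);
          rlast = std::max(rlast, rp);
          ++s1;
        }
        int w0 = dmin - pad, w1 = dmax + plen + pad;
        if (w0 < 0) w0 = 0;
        if (w1 > n) w1 = n;
        Hit h;
        if (sw_window(rd, w0, w1, prim[p], match, mismatch, gap, h)) {
          if (h.alen >= min_len &&
              (double) h.matches / (double) h.alen >= min_identity - 1e-12)
            hits.push_back(h);
        }
        s0 = s1;
      }
      // neighbouring seed clusters can re-discover (or clip) the same
      // occurrence: keep only the best-scoring hit among heavily
      // overlapping ones (same primer, same strand)
      std::sort(hits.begin(), hits.end(),
                [](const Hit& a, const Hit& b) {
                  if (a.score != b.score) return a.score > b.score;
                  if (a.start != b.start) return a.start < b.start;
                  return a.end < b.end;
                });
      std::vector<Hit> kept;
      for (size_t t = 0; t < hits.size(); ++t) {
        bool dup = false;
        for (size_t u = 0; u < kept.size(); ++u) {
          const int ov = std::min(kept[u].end, hits[t].end) -
                         std::max(kept[u].start, hits[t].start);
          if (ov > 5) { dup = true; break; }
        }
        if (!dup) kept.push_back(hits[t]);
      }
      std::sort(kept.begin(), kept.end(),
                [](const Hit& a, const Hit& b) {
                  if (a.start != b.start) return a.start < b.start;
                  return a.end < b.end;
                });
      std::vector<Hit>& hits2 = kept;
      for (size_t t = 0; t < hits2.size(); ++t) {
        o_read.push_back(r + 1);
        o_primer.push_back(p + 1);
        o_start.push_back(hits2[t].start);
        o_end.push_back(hits2[t].end);
        o_matches.push_back(hits2[t].matches);
        o_alen.push_back(hits2[t].alen);
        o_score.push_back(hits2[t].score);
      }
    }
  }
  return DataFrame::create(
    _["read"] = o_read, _["primer"] = o_primer,
    _["start"] = o_start, _["end"] = o_end,
    _["matches"] = o_matches, _["aligned_len"] = o_alen,
    _["score"] = o_score);
}

//' @noRd
// [[Rcpp::export(name = ".trim_polya_cpp")]]
IntegerVector trim_polya_cpp(CharacterVector seqs, int window, double min_frac) {
  const int ns = seqs.size();
  IntegerVector out(ns);
  for (int s = 0; s < ns; ++s) {
    const std::string sq = as<std::string>(seqs[s]);
    const int n = (int) sq.size();
    int L = 0;
    if (n >= window) {
      // prefix counts of A
      std::vector<int> pa(n + 1, 0);
      for (int i = 0; i < n; ++i) pa[i + 1] = pa[i] + (sq[i] == 'A' ? 1 : 0);
      const double need = min_frac * window - 1e-9;
      int st = n - window;          // 0-based window start, last window
      int s_last = -1;
      while (st >= 0 && (double)(pa[st + window] - pa[st]) >= need) {
        s_last = st;
        --st;
      }
      if (s_last >= 0) L = n - s_last;
    }
    if (L == 0) {
      // suffixes shorter than one window: the suffix itself must pass
      const int top = std::min(n, window - 1);
      for (int len = top; len >= 1; --len) {
        int a = 0;
        for (int i = n - len; i < n; ++i) a += (sq[i] == 'A' ? 1 : 0);
        if ((double) a >= min_frac * len - 1e-9) { L = len; break; }
      }
    }
    // retract so the innermost trimmed base is an A
    while (L > 0 && sq[n - L] != 'A') --L;
    out[s] = L;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".mutate_seqs_cpp")]]
List mutate_seqs_cpp(CharacterVector seqs, double sub_rate, double ins_rate,
                     double del_rate, double mean_q) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  const int ns = seqs.size();
  CharacterVector out_seq(ns), out_qual(ns);
  IntegerVector out_err(ns);
  RNGScope scope;
  for (int s = 0; s < ns; ++s) {
    const std::string sq = as<std::string>(seqs[s]);
    const int n = (int) sq.size();
    std::string res, qual;
    res.reserve(n + 16);
    qual.reserve(n + 16);
    int nerr = 0;
    const double p_event = sub_rate + del_rate;
    for (int i = 0; i < n; ++i) {
      const double u = R::runif(0.0, 1.0);
      char b = sq[i];
      bool emit = true;
      if (u < del_rate) {
        emit = false;
        ++nerr;
      } else if (u < p_event) {
        const int c0 = base_code(b);
        int alt = (int) (R::runif(0.0, 1.0) * 3.0);
        if (alt > 2) alt = 2;
        b = BASES[(c0 < 0 ? alt : (c0 + 1 + alt) % 4)];
        ++nerr;
      }
      if (emit) {
        res.push_back(b);
        int q = (int) std::lround(mean_q + R::runif(-2.0, 2.0));
        if (q < 2) q = 2;
        if (q > 41) q = 41;
        qual.push_back((char) (33 + q));
      }
      if (R::runif(0.0, 1.0) < ins_rate) {
        int c = (int) (R::runif(0.0, 1.0) * 4.0);
        if (c > 3) c = 3;
        res.push_back(BASES[c]);
        int q = (int) std::lround(mean_q + R::runif(-2.0, 2.0));
        if (q < 2) q = 2;
        if (q > 41) q = 41;
        qual.push_back((char) (33 + q));
        ++nerr;
      }
    }
    out_seq[s] = res;
    out_qual[s] = qual;
    out_err[s] = nerr;
  }
  return List::create(_["sequence"] = out_seq, _["qualities"] = out_qual,
                      _["n_errors"] = out_err);
}
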