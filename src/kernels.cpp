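#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>

using namespace Rcpp;

// Hamming distance with early exit once the count exceeds `cap`.
// Returns cap + 1 when the true distance is larger than cap.
static inline int hamming_capped(const char* a, const char* b, int L, int cap) {
  int d = 0;
  for (int i = 0; i < L; ++i) {
    if (a[i] != b[i]) {
      if (++d > cap) return cap + 1;
    }
  }
  return d;
}

static void check_equal_lengths(const std::vector<std::string>& s) {
  if (s.empty()) return;
  size_t L = s[0].size();
  for (size_t i = 1; i < s.size(); ++i)
    if (s[i].size() != L) stop("all sequences must have identical length");
}

static std::vector<std::string> to_std(const CharacterVector& x) {
  std::vector<std::string> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = as<std::string>(x[i]);
  return out;
}

// Segment boundaries for the pigeonhole filter: any pair within Hamming
// distance <= max_d must agree exactly on at least one of max_d + 1 segments.
static std::vector<std::pair<int,int>> segments(int L, int max_d) {
  int k = max_d + 1;
  if (k > L) k = L;
  std::vector<std::pair<int,int>> seg;
  int base = L / k, rem = L % k, pos = 0;
  for (int i = 0; i < k; ++i) {
    int len = base + (i < rem ? 1 : 0);
    seg.push_back(std::make_pair(pos, len));
    pos += len;
  }
  return seg;
}

// All unordered pairs (i, j), i < j, with Hamming(seqs[i], seqs[j]) <= max_d.
// 1-based indices. Sequences must be equal length.
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_edges(CharacterVector seqs, int max_d) {
  std::vector<std::string> s = to_std(seqs);
  check_equal_lengths(s);
  int n = (int)s.size();
  std::vector<int> ei, ej, ed;
  if (n >= 2) {
    int L = (int)s[0].size();
    if ((double)n * n <= 4e6) {  // small inputs: direct scan
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          int d = hamming_capped(s[i].c_str(), s[j].c_str(), L, max_d);
          if (d <= max_d) { ei.push_back(i + 1); ej.push_back(j + 1); ed.push_back(d); }
        }
    } else {
      std::vector<std::pair<int,int>> seg = segments(L, max_d);
      std::unordered_set<long long> seen;
      for (size_t si = 0; si < seg.size(); ++si) {
        std::unordered_map<std::string, std::vector<int>> buckets;
        buckets.reserve(n * 2);
        for (int i = 0; i < n; ++i)
          buckets[s[i].substr(seg[si].first, seg[si].second)].push_back(i);
        for (std::unordered_map<std::string, std::vector<int>>::iterator it = buckets.begin();
             it != buckets.end(); ++it) {
          std::vector<int>& v = it->second;
          for (size_t a = 0; a < v.size(); ++a)
            for (size_t b = a + 1; b < v.size(); ++b) {
              int i = v[a], j = v[b];
              long long key = (long long)i * n + j;
              if (!seen.insert(key).second) continue;
              int d = hamming_capped(s[i].c_str(), s[j].c_str(), L, max_d);
              if (d <= max_d) { ei.push_back(i + 1); ej.push_back(j + 1); ed.push_back(d); }
            }
        }
      }
    }
  }
  IntegerMatrix out((int)ei.size(), 3);
  for (size_t k = 0; k < ei.size(); ++k) {
    out(k, 0) = ei[k]; out(k, 1) = ej[k]; out(k, 2) = ed[k];
  }
  colnames(out) = CharacterVector::create("i", "j", "d");
  return out;
}

// For each query, the unique nearest target within Hamming <= max_d.
// Ties across distinct targets at the minimal distance yield NA (the read is
// discarded by the caller). Returns 1-based target indices and distances.
// [[Rcpp::export]]
List cpp_assign_nearest(CharacterVector queries, CharacterVector targets, int max_d) {
  std::vector<std::string> q = to_std(queries), t = to_std(targets);
  check_equal_lengths(t);
  int nq = (int)q.size(), nt = (int)t.size();
  IntegerVector idx(nq, NA_INTEGER), dist(nq, NA_INTEGER);
  if (nt == 0 || nq == 0) return List::create(_["idx"] = idx, _["dist"] = dist);
  int L = (int)t[0].size();
  std::vector<std::pair<int,int>> seg = segments(L, max_d);
  std::vector<std::unordered_map<std::string, std::vector<int>>> buckets(seg.size());
  for (size_t si = 0; si < seg.size(); ++si) {
    buckets[si].reserve(nt * 2);
    for (int i = 0; i < nt; ++i)
      buckets[si][t[i].substr(seg[si].first, seg[si].second)].push_back(i);
  }
  std::vector<int> stamp(nt, -1);
  for (int r = 0; r < nq; ++r) {
    if ((int)q[r].size() != L) stop("query length differs from target length");
    int best = max_d + 1, best_i = -1;
    bool tie = false;
    for (size_t si = 0; si < seg.size(); ++si) {
      std::unordered_map<std::string, std::vector<int>>::iterator it =
        buckets[si].find(q[r].substr(seg[si].first, seg[si].second));
      if (it == buckets[si].end()) continue;
      std::vector<int>& cand = it->second;
      for (size_t c = 0; c < cand.size(); ++c) {
        int i = cand[c];
        if (stamp[i] == r) continue;
        stamp[i] = r;
        int d = hamming_capped(q[r].c_str(), t[i].c_str(), L, best);
        if (d < best) { best = d; best_i = i; tie = false; }
        else if (d == best && best <= max_d && i != best_i) { tie = true; }
      }
    }
    if (best <= max_d && !tie) { idx[r] = best_i + 1; dist[r] = best; }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Overlap-merge a trimmed read pair. `rrc` is the reverse-complemented reverse
// read and `rrc_qual` its quality string reversed in step. The longest overlap
// between the 3' end of `fwd` and the 5' end of `rrc` whose mismatch fraction
// is <= max_mismatch_frac wins; within the overlap each position takes the
// base with the higher phred quality (tie -> forward base). Entries with no
// qualifying overlap come back NA.
// [[Rcpp::export]]
List cpp_merge_overlap(CharacterVector fwd, CharacterVector rrc,
                       CharacterVector fwd_qual, CharacterVector rrc_qual,
                       int min_overlap, double max_mismatch_frac) {
  int n = fwd.size();
  CharacterVector merged(n, NA_STRING);
  IntegerVector ovl(n, NA_INTEGER);
  for (int k = 0; k < n; ++k) {
    std::string f = as<std::string>(fwd[k]), r = as<std::string>(rrc[k]);
    std::string fq = as<std::string>(fwd_qual[k]), rq = as<std::string>(rrc_qual[k]);
    int nf = (int)f.size(), nr = (int)r.size();
    int omax = std::min(nf, nr);
    int chosen = -1;
    for (int o = omax; o >= min_overlap; --o) {  // longest qualifying overlap
      int cap = (int)std::floor(max_mismatch_frac * o);
      int d = hamming_capped(f.c_str() + (nf - o), r.c_str(), o, cap);
      if (d <= cap) { chosen = o; break; }
    }
    if (chosen < 0) continue;
    std::string out = f.substr(0, nf - chosen);
    for (int p = 0; p < chosen; ++p) {
      char bf = f[nf - chosen + p], br = r[p];
      char qf = fq[nf - chosen + p], qr = rq[p];
      out.push_back(qr > qf ? br : bf);
    }
    out += r.substr(chosen);
    merged[k] = out;
    ovl[k] = chosen;
  }
  return List::create(_["merged"] = merged, _["overlap"] = ovl);
}

static inline int base_code(char b) {
  switch (b) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
               case 'T': return 3; default: return 4; }
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Per-tag variant-site discovery and per-sample allelic-depth counting for
// reads already assigned to tags (ungapped, equal lengths). A column is a
// variant site when at least two bases reach pooled depth >= min_site_depth
// and the most frequent non-reference base reaches min_alt_frac of the pooled
// column depth. ref allele = the tag's base; alt = most frequent other base
// (tie -> alphabetical). N bases are ignored in depth counts.
// [[Rcpp::export]]
List cpp_count_alleles(CharacterVector reads, IntegerVector read_tag,
                       IntegerVector sample_idx, CharacterVector tags,
                       int n_samples, int min_site_depth, double min_alt_frac) {
  std::vector<std::string> rd = to_std(reads), tg = to_std(tags);
  int n_tags = (int)tg.size();
  check_equal_lengths(tg);
  int L = n_tags ? (int)tg[0].size() : 0;
  // reads grouped by tag
  std::vector<std::vector<int>> by_tag(n_tags);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (read_tag[r] == NA_INTEGER) continue;
    int ti = read_tag[r] - 1;
    if (ti < 0 || ti >= n_tags) stop("read_tag index out of range");
    if ((int)rd[r].size() != L) stop("read length differs from tag length");
    by_tag[ti].push_back((int)r);
  }
  std::vector<int> out_tag, out_off;
  std::vector<char> out_ref, out_alt;
  std::vector<std::vector<int>> out_adr, out_ada;
  std::vector<int> cnt(5 * L);
  for (int ti = 0; ti < n_tags; ++ti) {
    std::vector<int>& rr = by_tag[ti];
    if (rr.empty()) continue;
    std::fill(cnt.begin(), cnt.end(), 0);
    const char* tseq = tg[ti].c_str();
    for (size_t k = 0; k < rr.size(); ++k) {
      const char* rs = rd[rr[k]].c_str();
      for (int c = 0; c < L; ++c) cnt[5 * c + base_code(rs[c])]++;
    }
    for (int c = 0; c < L; ++c) {
      int refb = base_code(tseq[c]);
      if (refb == 4) continue;
      int tot = 0, n_ge = 0;
      for (int b = 0; b < 4; ++b) {
        tot += cnt[5 * c + b];
        if (cnt[5 * c + b] >= min_site_depth) n_ge++;
      }
      if (n_ge < 2 || tot == 0) continue;
      int altb = -1, altc = -1;
      for (int b = 0; b < 4; ++b) {
        if (b == refb) continue;
        if (cnt[5 * c + b] > altc) { altc = cnt[5 * c + b]; altb = b; }
      }
      if (altc < min_site_depth) continue;
      if ((double)altc < min_alt_frac * tot) continue;
      out_tag.push_back(ti + 1);
      out_off.push_back(c);
      out_ref.push_back(BASES[refb]);
      out_alt.push_back(BASES[altb]);
      std::vector<int> adr(n_samples, 0), ada(n_samples, 0);
      for (size_t k = 0; k < rr.size(); ++k) {
        char b = rd[rr[k]][c];
        int s = sample_idx[rr[k]] - 1;
        if (s < 0 || s >= n_samples) stop("sample index out of range");
        if (b == BASES[refb]) adr[s]++;
        else if (b == BASES[altb]) ada[s]++;
      }
      out_adr.push_back(adr);
      out_ada.push_back(ada);
    }
  }
  int ns = (int)out_tag.size();
  IntegerMatrix adr(ns, n_samples), ada(ns, n_samples);
  CharacterVector refv(ns), altv(ns);
  IntegerVector tagv(ns), offv(ns);
  for (int i = 0; i < ns; ++i) {
    tagv[i] = out_tag[i];
    offv[i] = out_off[i];
    refv[i] = std::string(1, out_ref[i]);
    altv[i] = std::string(1, out_alt[i]);
    for (int s = 0; s < n_samples; ++s) { adr(i, s) = out_adr[i][s]; ada(i, s) = out_ada[i][s]; }
  }
  return List::create(_["tag_idx"] = tagv, _["offset"] = offv,
                      _["ref"] = refv, _["alt"] = altv,
                      _["ad_ref"] = adr, _["ad_alt"] = ada);
}

// Plain Hamming distance between two equal-length strings (utility).
// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) d++;
  return d;
}
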