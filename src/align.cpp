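#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Nucleotide encoding: A=0 C=1 G=2 T=3, anything else (incl. N)=4.
// Code 4 never scores as a match.

static inline std::vector<uint8_t> encode_seq(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': v[i] = 3; break;
      default: v[i] = 4;
    }
  }
  return v;
}

static inline std::vector<uint8_t> revcomp_enc(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (3 - b) : 4;
  }
  return r;
}

struct Hit {
  int score = -1;
  int matches = 0;
  int columns = 0;
  int qs = 0, qe = 0, ss = 0, se = 0; // 0-based half-open on the aligned (possibly rc) query
  bool valid = false;
};

// traceback codes packed per cell:
//   bits 0-1: H source (0 stop, 1 diag, 2 from E [gap in query, consume subject], 3 from F)
//   bit 2: E extended (came from E[i][j-1]) ; bit 3: F extended (came from F[i-1][j])
static const int NEG = -1000000000;

// Full affine local DP with traceback.
static Hit sw_full(const std::vector<uint8_t> &q, const std::vector<uint8_t> &s,
                   int match, int mismatch, int go, int ge) {
  int m = (int)q.size(), n = (int)s.size();
  Hit best;
  if (m == 0 || n == 0) return best;
  std::vector<int> Hp(n + 1, 0), Hc(n + 1, 0), Ep(n + 1, NEG), Ec(n + 1, NEG),
      Fp(n + 1, NEG), Fc(n + 1, NEG);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  int bi = 0, bj = 0, bscore = 0;
  for (int i = 1; i <= m; ++i) {
    Hc[0] = 0; Ec[0] = NEG; Fc[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      uint8_t flags = 0;
      int e_open = Hc[j - 1] - go - ge;
      int e_ext = Ec[j - 1] - ge;
      int e = e_open;
      if (e_ext > e) { e = e_ext; flags |= 4; }
      Ec[j] = e;
      int f_open = Hp[j] - go - ge;
      int f_ext = Fp[j] - ge;
      int f = f_open;
      if (f_ext > f) { f = f_ext; flags |= 8; }
      Fc[j] = f;
      int sub = (q[i - 1] == s[j - 1] && q[i - 1] < 4) ? match : mismatch;
      int d = Hp[j - 1] + sub;
      int h = 0; uint8_t src = 0;
      if (d > h) { h = d; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      Hc[j] = h;
      tb[(size_t)i * (n + 1) + j] = (uint8_t)(flags | src);
      if (h > bscore) { bscore = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }
  if (bscore <= 0) return best;
  best.valid = true; best.score = bscore;
  // traceback: explicit H/E/F state machine
  int i = bi, j = bj, matches = 0, columns = 0;
  int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
  while (i > 0 && j > 0) {
    uint8_t cell = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      uint8_t src = cell & 3;
      if (src == 0) break;
      if (src == 1) {
        ++columns;
        if (q[i - 1] == s[j - 1] && q[i - 1] < 4) ++matches;
        --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++columns; // gap column consuming subject base j
      state = (cell & 4) ? 1 : 0;
      --j;
    } else {
      ++columns; // gap column consuming query base i
      state = (cell & 8) ? 2 : 0;
      --i;
    }
  }
  best.qs = i; best.qe = bi; best.ss = j; best.se = bj;
  best.matches = matches; best.columns = columns;
  return best;
}

// Banded affine local DP: diagonals d = j - i restricted to [dlo, dhi].
static Hit sw_banded(const std::vector<uint8_t> &q, const std::vector<uint8_t> &s,
                     int match, int mismatch, int go, int ge, int dlo, int dhi) {
  int m = (int)q.size(), n = (int)s.size();
  Hit best;
  if (m == 0 || n == 0) return best;
  if (dlo < -(m - 1)) dlo = -(m - 1);
  if (dhi > n - 1) dhi = n - 1;
  if (dlo > dhi) return best;
  int w = dhi - dlo + 1;
  std::vector<int> Hp(w, 0), Hc(w, 0), Ep(w, NEG), Ec(w, NEG), Fp(w, NEG), Fc(w, NEG);
  std::vector<uint8_t> tb((size_t)(m + 1) * w, 0);
  int bi = 0, bd = 0, bscore = 0;
  // row i = 0: H = 0 where j in [0, n] valid, E/F = NEG
  for (int i = 1; i <= m; ++i) {
    for (int x = 0; x < w; ++x) { Hc[x] = 0; Ec[x] = NEG; Fc[x] = NEG; }
    int x_lo = std::max(0, 1 - i - dlo);
    int x_hi = std::min(w - 1, n - i - dlo);
    for (int x = x_lo; x <= x_hi; ++x) {
      int j = i + dlo + x;
      uint8_t flags = 0;
      // E: from (i, j-1) -> same row, x-1
      int e = NEG;
      if (x > 0) {
        int e_open = Hc[x - 1] - go - ge;
        int e_ext = Ec[x - 1] - ge;
        e = e_open;
        if (e_ext > e) { e = e_ext; flags |= 4; }
      } else if (j - 1 >= 0) {
        // (i, j-1) is off-band low; opening from H would need that cell: treat as
        // opening from score 0 only if j-1 aligns... off-band: disallow.
        e = NEG;
      }
      // F: from (i-1, j) -> previous row, x+1
      int f = NEG;
      if (x + 1 < w) {
        int f_open = Hp[x + 1] - go - ge;
        int f_ext = Fp[x + 1] - ge;
        f = f_open;
        if (f_ext > f) { f = f_ext; flags |= 8; }
      }
      // diag: from (i-1, j-1) -> previous row, same x
      int hp = (j - 1 >= 0) ? Hp[x] : 0;
      if (i - 1 == 0 || j - 1 == 0) hp = 0; // boundary cells have H=0
      int sub = (q[i - 1] == s[j - 1] && q[i - 1] < 4) ? match : mismatch;
      int d = hp + sub;
      int h = 0; uint8_t src = 0;
      if (d > h) { h = d; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      Hc[x] = h;
      tb[(size_t)i * w + x] = (uint8_t)(flags | src);
      if (h > bscore) { bscore = h; bi = i; bd = x; }
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }
  if (bscore <= 0) return best;
  best.valid = true; best.score = bscore;
  int i = bi, x = bd, matches = 0, columns = 0;
  int state = 0; // 0 = H, 1 = E (gap in query: j-1, x-1), 2 = F (gap in subject: i-1, x+1)
  while (i > 0 && x >= 0 && x < w) {
    int j = i + dlo + x;
    if (j <= 0) break;
    uint8_t cell = tb[(size_t)i * w + x];
    if (state == 0) {
      uint8_t src = cell & 3;
      if (src == 0) break;
      if (src == 1) {
        ++columns;
        if (q[i - 1] == s[j - 1] && q[i - 1] < 4) ++matches;
        --i; // diagonal step keeps the band offset x
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++columns; // gap column consuming subject base j
      state = (cell & 4) ? 1 : 0;
      --x;
    } else {
      ++columns; // gap column consuming query base i
      state = (cell & 8) ? 2 : 0;
      --i; ++x;
    }
  }
  int j = i + dlo + x;
  best.qs = i; best.qe = bi; best.ss = j; best.se = bi + dlo + bd;
  best.matches = matches; best.columns = columns;
  return best;
}

static inline bool kmer_code(const std::vector<uint8_t> &s, int pos, int k, uint64_t &code) {
  uint64_t c = 0;
  for (int t = 0; t < k; ++t) {
    uint8_t b = s[pos + t];
    if (b >= 4) return false;
    c = (c << 2) | b;
  }
  code = c;
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector queries, CharacterVector subjects,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int k, int min_score, double max_cells_full,
                          int band_extra, int seed_step) {
  int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<uint8_t>> subj(ns);
  for (int s = 0; s < ns; ++s) subj[s] = encode_seq(as<std::string>(subjects[s]));

  // exhaustive mode (full DP on every pair, both strands) only when the
  // whole problem fits the cell budget; otherwise seed-and-extend throughout
  double total_q = 0, total_s = 0;
  for (int i = 0; i < nq; ++i) total_q += LENGTH(STRING_ELT(queries, i));
  for (int s = 0; s < ns; ++s) total_s += (double)subj[s].size();
  bool exhaustive = 2.0 * total_q * total_s <= max_cells_full;

  // k-mer index over subjects
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  if (!exhaustive && k > 0 && k <= 31) {
    for (int s = 0; s < ns; ++s) {
      int L = (int)subj[s].size();
      for (int p = 0; p + k <= L; ++p) {
        uint64_t code;
        if (kmer_code(subj[s], p, k, code)) index[code].push_back({s, p});
      }
    }
  }

  std::vector<int> out_q, out_s, out_score, out_matches, out_cols,
      out_qs, out_qe, out_ss, out_se;
  std::vector<int> out_strand; // 1 = '+', -1 = '-'

  std::vector<std::pair<int, int>> seeds; // (subject, diagonal), reused
  std::vector<int> dv;                    // diagonals of one subject, reused
  for (int qi = 0; qi < nq; ++qi) {
    std::vector<uint8_t> qf = encode_seq(as<std::string>(queries[qi]));
    int m = (int)qf.size();
    if (m == 0) continue;
    std::vector<uint8_t> qr = revcomp_enc(qf);
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<uint8_t> &q = strand == 0 ? qf : qr;
      auto report = [&](int s, const Hit &h) {
        if (!h.valid || h.score < min_score) return;
        int qs = h.qs, qe = h.qe;
        if (strand == 1) { qs = m - h.qe; qe = m - h.qs; }
        out_q.push_back(qi + 1); out_s.push_back(s + 1);
        out_score.push_back(h.score); out_matches.push_back(h.matches);
        out_cols.push_back(h.columns);
        out_qs.push_back(qs); out_qe.push_back(qe);
        out_ss.push_back(h.ss); out_se.push_back(h.se);
        out_strand.push_back(strand == 0 ? 1 : -1);
      };
      if (exhaustive) {
        for (int s = 0; s < ns; ++s) {
          if (subj[s].empty()) continue;
          report(s, sw_full(q, subj[s], match, mismatch, gap_open, gap_extend));
        }
        continue;
      }
      // collect (subject, diagonal) seed pairs, then process per subject
      seeds.clear();
      for (int p = 0; p + k <= m; p += seed_step) {
        uint64_t code;
        if (!kmer_code(q, p, k, code)) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        for (auto &pr : it->second)
          seeds.push_back({pr.first, pr.second - p});
      }
      if (seeds.empty()) continue;
      std::sort(seeds.begin(), seeds.end());
      size_t b0 = 0;
      for (size_t t = 1; t <= seeds.size(); ++t) {
        if (t == seeds.size() || seeds[t].first != seeds[b0].first) {
          int s = seeds[b0].first;
          dv.clear();
          for (size_t u = b0; u < t; ++u)
            if (dv.empty() || dv.back() != seeds[u].second)
              dv.push_back(seeds[u].second);
          // cluster diagonals; one banded DP per cluster, keep best
          Hit h;
          size_t c0 = 0;
          for (size_t v = 1; v <= dv.size(); ++v) {
            if (v == dv.size() || dv[v] - dv[v - 1] > 2 * band_extra) {
              Hit hc = sw_banded(q, subj[s], match, mismatch, gap_open,
                                 gap_extend, dv[c0] - band_extra,
                                 dv[v - 1] + band_extra);
              if (hc.valid && hc.score > h.score) h = hc;
              c0 = v;
            }
          }
          report(s, h);
          b0 = t;
        }
      }
    }
  }
  return DataFrame::create(
      _["query"] = out_q, _["subject"] = out_s, _["score"] = out_score,
      _["matches"] = out_matches, _["columns"] = out_cols,
      _["q_start"] = out_qs, _["q_end"] = out_qe,
      _["s_start"] = out_ss, _["s_end"] = out_se,
      _["strand_sign"] = out_strand);
}

// Extract read substrings (with optional reverse complement) from genome strings.
// genome_idx 1-based, pos 0-based.
// [[Rcpp::export]]
CharacterVector cpp_extract_reads(CharacterVector genomes, IntegerVector genome_idx,
                                  IntegerVector pos, int read_length,
                                  LogicalVector revcomp) {
  int nr = genome_idx.size();
  std::vector<std::string> gs(genomes.size());
  for (int i = 0; i < genomes.size(); ++i) gs[i] = as<std::string>(genomes[i]);
  CharacterVector out(nr);
  std::string buf(read_length, 'N');
  for (int r = 0; r < nr; ++r) {
    const std::string &g = gs[genome_idx[r] - 1];
    int p = pos[r];
    if (p < 0 || p + read_length > (int)g.size())
      stop("read position out of range for genome %d", genome_idx[r]);
    if (!revcomp[r]) {
      out[r] = g.substr(p, read_length);
    } else {
      for (int t = 0; t < read_length; ++t) {
        char b = g[p + read_length - 1 - t];
        switch (b) {
          case 'A': buf[t] = 'T'; break; case 'C': buf[t] = 'G'; break;
          case 'G': buf[t] = 'C'; break; case 'T': buf[t] = 'A'; break;
          default: buf[t] = 'N';
        }
      }
      out[r] = buf;
    }
  }
  return out;
}

// Per-base substitution errors using R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  RNGScope scope;
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      if (unif_rand() < rate) {
        char cur = s[p];
        char nb;
        do { nb = bases[(int)(unif_rand() * 4) & 3]; } while (nb == cur);
        s[p] = nb;
      }
    }
    out[i] = s;
  }
  return out;
}

// PERMANOVA pseudo-F for a matrix of label permutations.
// d2: n x n squared-dissimilarity matrix; perms: n x P integer labels in 1..g.
// [[Rcpp::export]]
NumericVector cpp_permanova_f(NumericMatrix d2, IntegerMatrix perms, int n_groups) {
  int n = d2.nrow(), P = perms.ncol();
  double ss_total = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) ss_total += d2(i, j);
  ss_total /= n;
  NumericVector out(P);
  std::vector<double> gsum(n_groups);
  std::vector<int> gn(n_groups);
  for (int p = 0; p < P; ++p) {
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gn.begin(), gn.end(), 0);
    for (int i = 0; i < n; ++i) gn[perms(i, p) - 1]++;
    for (int i = 0; i < n; ++i) {
      int gi = perms(i, p) - 1;
      for (int j = i + 1; j < n; ++j)
        if (perms(j, p) - 1 == gi) gsum[gi] += d2(i, j);
    }
    double ss_within = 0.0;
    for (int g = 0; g < n_groups; ++g)
      if (gn[g] > 0) ss_within += gsum[g] / gn[g];
    double ss_between = ss_total - ss_within;
    out[p] = (ss_between / (n_groups - 1)) / (ss_within / (n - n_groups));
  }
  return out;
}
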