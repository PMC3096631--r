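// Ungapped alignment core: pigeonhole seed-and-extend mapping with a whole-read
// Hamming-distance budget, plus pileup / error-matrix tallies over alignments.
#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // N or anything else: mismatches every base
  }
}

static inline char comp_char(char c) {
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
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_char(r[i]);
  return r;
}

// Hamming distance with early exit once > budget; -1 codes never match.
static inline int mm_count(const std::vector<int>& ref, int start,
                           const std::vector<int>& rd, int budget) {
  int mm = 0;
  const int L = (int) rd.size();
  for (int j = 0; j < L; ++j) {
    if (rd[j] < 0 || rd[j] != ref[start + j]) {
      if (++mm > budget) return mm;
    }
  }
  return mm;
}

struct Placement {
  int start;   // 0-based
  bool minus;
  int mm;
};

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, std::string ref, int max_mm) {
  const int G = (int) ref.size();
  std::vector<int> R(G);
  for (int i = 0; i < G; ++i) R[i] = base_code(ref[i]);

  // 8-mer index over the reference (2 bits/base, 16-bit keys)
  const int K = 8;
  const int NKEY = 1 << (2 * K);
  std::vector<int> bucket_n(NKEY, 0);
  std::vector<int> bucket_start(NKEY + 1, 0);
  std::vector<int> bucket_pos;
  bool have_index = G >= K;
  if (have_index) {
    int key = 0, valid = 0;
    for (int i = 0; i < G; ++i) {
      key = ((key << 2) | (R[i] & 3)) & (NKEY - 1);
      valid = (R[i] >= 0) ? valid + 1 : 0;
      if (valid >= K) bucket_n[key]++;
    }
    for (int k = 0; k < NKEY; ++k) bucket_start[k + 1] = bucket_start[k] + bucket_n[k];
    bucket_pos.resize(bucket_start[NKEY]);
    std::vector<int> fill(NKEY, 0);
    key = 0; valid = 0;
    for (int i = 0; i < G; ++i) {
      key = ((key << 2) | (R[i] & 3)) & (NKEY - 1);
      valid = (R[i] >= 0) ? valid + 1 : 0;
      if (valid >= K) bucket_pos[bucket_start[key] + fill[key]++] = i - K + 1;
    }
  }

  const int n_reads = reads.size();
  std::vector<int> out_read, out_start, out_mm;
  std::vector<bool> out_minus;
  std::vector<std::string> out_seq;
  IntegerVector n_hits(n_reads, 0);

  // per-start "seen" stamps, one per strand
  std::vector<int> stamp_p(G > 0 ? G : 1, -1), stamp_m(G > 0 ? G : 1, -1);

  std::vector<Placement> plc;
  for (int r = 0; r < n_reads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int L = (int) fwd.size();
    if (L == 0 || L > G) { n_hits[r] = 0; continue; }
    std::string rev = revcomp(fwd);
    std::vector<int> qf(L), qr(L);
    for (int j = 0; j < L; ++j) { qf[j] = base_code(fwd[j]); qr[j] = base_code(rev[j]); }

    plc.clear();
    const int nseg = max_mm + 1;
    bool seeded = have_index && L >= nseg * K;

    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<int>& q = strand ? qr : qf;
      std::vector<int>& stamp = strand ? stamp_m : stamp_p;
      if (!seeded) {
        // brute force: short reads or tiny references
        for (int s = 0; s + L <= G; ++s) {
          int mm = mm_count(R, s, q, max_mm);
          if (mm <= max_mm) plc.push_back({s, strand == 1, mm});
        }
      } else {
        const int chunk = L / nseg;
        for (int seg = 0; seg < nseg; ++seg) {
          const int off = seg * chunk;
          int key = 0; bool ok = true;
          for (int j = 0; j < K; ++j) {
            if (q[off + j] < 0) { ok = false; break; }
            key = (key << 2) | q[off + j];
          }
          if (!ok) continue;
          for (int bi = bucket_start[key]; bi < bucket_start[key + 1]; ++bi) {
            int s = bucket_pos[bi] - off;
            if (s < 0 || s + L > G) continue;
            if (stamp[s] == r) continue;
            stamp[s] = r;
            int mm = mm_count(R, s, q, max_mm);
            if (mm <= max_mm) plc.push_back({s, strand == 1, mm});
          }
        }
      }
    }
    if (plc.empty()) { n_hits[r] = 0; continue; }
    int best = max_mm + 1;
    for (size_t i = 0; i < plc.size(); ++i) if (plc[i].mm < best) best = plc[i].mm;
    int nb = 0;
    for (size_t i = 0; i < plc.size(); ++i) if (plc[i].mm == best) nb++;
    n_hits[r] = nb;
    for (size_t i = 0; i < plc.size(); ++i) {
      if (plc[i].mm != best) continue;
      out_read.push_back(r + 1);
      out_start.push_back(plc[i].start);
      out_minus.push_back(plc[i].minus);
      out_mm.push_back(plc[i].mm);
      out_seq.push_back(plc[i].minus ? rev : fwd);
    }
  }

  const int n_out = (int) out_read.size();
  // mismatch offsets (0-based, within the reference-oriented sequence)
  List mm_off(n_out);
  for (int i = 0; i < n_out; ++i) {
    const std::string& s = out_seq[i];
    std::vector<int> off;
    for (int j = 0; j < (int) s.size(); ++j) {
      int c = base_code(s[j]);
      if (c < 0 || c != R[out_start[i] + j]) off.push_back(j);
    }
    mm_off[i] = wrap(off);
  }
  LogicalVector minus(n_out);
  for (int i = 0; i < n_out; ++i) minus[i] = out_minus[i];
  return List::create(
    _["read"] = wrap(out_read), _["start"] = wrap(out_start),
    _["minus"] = minus, _["mismatches"] = wrap(out_mm),
    _["mm_offsets"] = mm_off, _["seq"] = wrap(out_seq),
    _["n_hits"] = n_hits);
}

// [[Rcpp::export]]
IntegerMatrix cpp_pileup(IntegerVector starts, CharacterVector seqs, int ref_len) {
  IntegerMatrix counts(4, ref_len);
  const int n = starts.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int st = starts[i];
    for (int j = 0; j < (int) s.size(); ++j) {
      int c = base_code(s[j]);
      if (c >= 0) counts(c, st + j)++;  // N bases contribute no count
    }
  }
  return counts;
}

// [[Rcpp::export]]
IntegerMatrix cpp_error_counts(IntegerVector starts, CharacterVector seqs,
                               std::string ref) {
  IntegerMatrix m(4, 4); // rows: reference base b, cols: read base b'
  const int n = starts.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int st = starts[i];
    for (int j = 0; j < (int) s.size(); ++j) {
      int rb = base_code(ref[st + j]);
      int qb = base_code(s[j]);
      if (rb >= 0 && qb >= 0) m(rb, qb)++;
    }
  }
  return m;
}

// [[Rcpp::export]]
List cpp_recompute_mismatches(IntegerVector starts, CharacterVector seqs,
                              std::string ref) {
  const int n = starts.size();
  IntegerVector mm(n);
  List off(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int st = starts[i];
    std::vector<int> o;
    for (int j = 0; j < (int) s.size(); ++j) {
      int qb = base_code(s[j]);
      if (qb < 0 || qb != base_code(ref[st + j])) o.push_back(j);
    }
    mm[i] = (int) o.size();
    off[i] = wrap(o);
  }
  return List::create(_["mismatches"] = mm, _["mm_offsets"] = off);
}
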