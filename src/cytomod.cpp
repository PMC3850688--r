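// Hot paths of the pipeline: genome-wide context scan, bisulfite read
// simulation, reduced-alphabet seed-and-extend mapping, and pileup
// accumulation. All randomness goes through R's RNG so set.seed() on the
// R side makes every simulation reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstring>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline char comp_base(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// Reduced alphabets: bisulfite conversion makes C and T indistinguishable on
// the strand being interrogated (C->T space); on the opposite strand the
// same ambiguity appears as G vs A (G->A space). Codes < 0 mark N.
static inline int enc_ct(char b) {
  switch (b) {
  case 'A': return 0;
  case 'C': return 3;  // C collapses onto T
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline int enc_ga(char b) {
  switch (b) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 0;  // G collapses onto A
  case 'T': return 3;
  default:  return -1;
  }
}

// Context codes per position: 0 = not a cytosine site on that strand,
// 1 = CG, 2 = CHG, 3 = CHH, -1 = cytosine whose trinucleotide window runs
// off the chromosome or contains an N (excluded from all denominators).
// plus[i] applies when the reference base at i is C; minus[i] when it is G
// (a cytosine on the minus strand).
// [[Rcpp::export]]
List context_codes_cpp(std::string seq) {
  int L = (int) seq.size();
  IntegerVector plus(L, 0), minus(L, 0);
  for (int i = 0; i < L; i++) {
    char b = seq[i];
    if (b == 'C') {
      if (i + 2 >= L) { plus[i] = -1; continue; }
      char b1 = seq[i + 1], b2 = seq[i + 2];
      if (b1 == 'N' || b2 == 'N') { plus[i] = -1; continue; }
      if (b1 == 'G') plus[i] = 1;
      else if (b2 == 'G') plus[i] = 2;
      else plus[i] = 3;
    } else if (b == 'G') {
      if (i - 2 < 0) { minus[i] = -1; continue; }
      char b1 = seq[i - 1], b2 = seq[i - 2];
      if (b1 == 'N' || b2 == 'N') { minus[i] = -1; continue; }
      if (b1 == 'C') minus[i] = 1;        // next base on minus strand is G
      else if (b2 == 'C') minus[i] = 2;   // base after next on minus is G
      else minus[i] = 3;
    }
  }
  return List::create(_["plus"] = plus, _["minus"] = minus);
}

// Bisulfite read simulator for one chromosome. Molecule-level model: at a
// cytosine on the read's origin strand the molecule is modified with
// probability = planted level; an unmodified cytosine converts to T with
// probability 1 - conv_fail; every emitted base then suffers a symmetric
// miscall with probability seq_error.
// [[Rcpp::export]]
List simulate_reads_cpp(std::string seq, NumericVector level_plus,
                        NumericVector level_minus, int n_reads, int read_len,
                        double conv_fail, double seq_error) {
  int L = (int) seq.size();
  if (read_len > L) stop("read length exceeds chromosome length");
  std::vector<std::string> out((size_t) n_reads);
  IntegerVector start(n_reads), strand(n_reads);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int r = 0; r < n_reads; r++) {
    int s = (int) std::floor(unif_rand() * (L - read_len + 1));
    if (s > L - read_len) s = L - read_len;
    int st = (unif_rand() < 0.5) ? 0 : 1;  // 0 = plus origin, 1 = minus
    std::string rd((size_t) read_len, 'N');
    for (int j = 0; j < read_len; j++) {
      char b; double lev = 0.0; bool is_c = false;
      if (st == 0) {
        b = seq[s + j];
        if (b == 'C') { is_c = true; lev = level_plus[s + j]; }
      } else {
        int p = s + read_len - 1 - j;   // read 5'->3' on the minus strand
        b = comp_base(seq[p]);
        if (b == 'C') { is_c = true; lev = level_minus[p]; }
      }
      if (is_c) {
        bool modified = unif_rand() < lev;
        if (!modified && unif_rand() < (1.0 - conv_fail)) b = 'T';
      }
      rd[(size_t) j] = b;
    }
    if (seq_error > 0) {
      for (int j = 0; j < read_len; j++) {
        char cur = rd[(size_t) j];
        if (cur == 'N') continue;
        if (unif_rand() < seq_error) {
          int ci = 0;
          while (bases[ci] != cur) ci++;
          int k = (int) std::floor(unif_rand() * 3.0);
          if (k > 2) k = 2;
          rd[(size_t) j] = bases[(ci + 1 + k) % 4];
        }
      }
    }
    out[(size_t) r] = rd;
    start[r] = s;
    strand[r] = st;
  }
  return List::create(_["seq"] = wrap(out), _["start"] = start,
                      _["strand"] = strand);
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void build_index(const std::string &ref, int k, bool ct, KmerIndex &idx) {
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int valid = 0;
  int L = (int) ref.size();
  for (int p = 0; p < L; p++) {
    int e = ct ? enc_ct(ref[p]) : enc_ga(ref[p]);
    if (e < 0) { valid = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t) e) & mask;
    valid++;
    if (valid >= k) idx[cur].push_back(p - k + 1);
  }
}

static inline bool encode_seed(const std::string &s, int k, bool ct, uint64_t &key) {
  uint64_t cur = 0;
  for (int j = 0; j < k; j++) {
    int e = ct ? enc_ct(s[(size_t) j]) : enc_ga(s[(size_t) j]);
    if (e < 0) return false;
    cur = (cur << 2) | (uint64_t) e;
  }
  key = cur;
  return true;
}

static inline int count_mm(const std::string &ref, int p, const std::string &rd,
                           bool ct, int cap) {
  int mm = 0;
  int l = (int) rd.size();
  for (int j = 0; j < l; j++) {
    int a = ct ? enc_ct(rd[(size_t) j]) : enc_ga(rd[(size_t) j]);
    int b = ct ? enc_ct(ref[(size_t)(p + j)]) : enc_ga(ref[(size_t)(p + j)]);
    if (a < 0 || b < 0 || a != b) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// Seed-and-extend bisulfite mapping against a concatenated reference.
// chrom_start/chrom_end give the [start, end) span of each chromosome in
// the concatenation; candidate placements crossing a boundary are rejected.
// strand 0 = read interrogates plus-strand cytosines (C->T space, forward
// orientation), 1 = minus (G->A space, read reverse-complemented first).
// A read is reported only when exactly one location attains the best
// mismatch count and that count is <= max_mm.
// [[Rcpp::export]]
List map_reads_cpp(std::string ref, CharacterVector reads,
                   IntegerVector chrom_start, IntegerVector chrom_end,
                   int k, int max_mm) {
  if (k < 1 || k > 31) stop("seed length k must be in [1, 31]");
  KmerIndex idx_ct, idx_ga;
  build_index(ref, k, true, idx_ct);
  build_index(ref, k, false, idx_ga);
  int n = reads.size();
  int nchrom = chrom_start.size();
  IntegerVector pos(n, NA_INTEGER), mm_out(n, NA_INTEGER),
      strand(n, NA_INTEGER), nbest(n, 0);
  LogicalVector mapped(n, false);

  for (int r = 0; r < n; r++) {
    std::string rd = as<std::string>(reads[r]);
    int l = (int) rd.size();
    if (l < k) continue;
    std::string rc(rd.rbegin(), rd.rend());
    for (size_t j = 0; j < rc.size(); j++) rc[j] = comp_base(rc[j]);

    int best_mm = max_mm + 1, best_pos = -1, best_strand = -1, best_n = 0;
    for (int probe = 0; probe < 2; probe++) {
      const std::string &q = (probe == 0) ? rd : rc;
      bool ct = (probe == 0);
      uint64_t key;
      if (!encode_seed(q, k, ct, key)) continue;
      KmerIndex &idx = ct ? idx_ct : idx_ga;
      KmerIndex::iterator it = idx.find(key);
      if (it == idx.end()) continue;
      const std::vector<int> &cands = it->second;
      for (size_t ci = 0; ci < cands.size(); ci++) {
        int p = cands[ci];
        if (p + l > (int) ref.size()) continue;
        // locate chromosome, reject boundary-spanning placements
        int lo = 0, hi = nchrom - 1, chrom = -1;
        while (lo <= hi) {
          int mid = (lo + hi) / 2;
          if (p < chrom_start[mid]) hi = mid - 1;
          else if (p >= chrom_end[mid]) lo = mid + 1;
          else { chrom = mid; break; }
        }
        if (chrom < 0 || p + l > chrom_end[chrom]) continue;
        int m = count_mm(ref, p, q, ct, max_mm);
        if (m > max_mm) continue;
        if (m < best_mm) {
          best_mm = m; best_pos = p; best_strand = probe; best_n = 1;
        } else if (m == best_mm) {
          best_n++;
        }
      }
    }
    if (best_mm <= max_mm) {
      nbest[r] = best_n;
      if (best_n == 1) {
        pos[r] = best_pos;
        strand[r] = best_strand;
        mm_out[r] = best_mm;
        mapped[r] = true;
      }
    }
  }
  return List::create(_["pos"] = pos, _["strand"] = strand, _["mm"] = mm_out,
                      _["nbest"] = nbest, _["mapped"] = mapped);
}

// Pileup accumulation over one chromosome. Reads are reference-oriented
// (minus-interrogation reads already reverse-complemented). Observations
// are classified C-retained vs converted on the interrogated strand; an
// observation is dropped when the read has a reduced-alphabet mismatch
// within +/- ctx_win bases of the cytosine; optionally an entire read is
// dropped when >= 3 consecutive CHH cytosines on it are all C-retained.
// Output is aggregated per (pos, strand, base quality).
// [[Rcpp::export]]
DataFrame pileup_cpp(std::string ref, IntegerVector code_plus,
                     IntegerVector code_minus, IntegerVector starts,
                     IntegerVector strands, CharacterVector seqs,
                     CharacterVector quals, bool chh_filter, int ctx_win,
                     int phred_offset) {
  std::unordered_map<uint64_t, std::pair<int, int> > acc;
  int n = starts.size();
  int L = (int) ref.size();
  std::vector<char> mm;
  for (int r = 0; r < n; r++) {
    int s = starts[r];
    int strand = strands[r];  // 0 plus interrogation, 1 minus
    const char *rd = CHAR(STRING_ELT(seqs, r));
    const char *qu = CHAR(STRING_ELT(quals, r));
    int l = (int) std::strlen(rd);
    if (s < 0 || s + l > L)
      stop("alignment beyond chromosome bounds (start %d, length %d)", s, l);
    mm.assign((size_t) l, 0);
    for (int j = 0; j < l; j++) {
      int a, b;
      if (strand == 0) { a = enc_ct(rd[j]); b = enc_ct(ref[(size_t)(s + j)]); }
      else             { a = enc_ga(rd[j]); b = enc_ga(ref[(size_t)(s + j)]); }
      mm[(size_t) j] = (a < 0 || b < 0 || a != b) ? 1 : 0;
    }
    if (chh_filter) {
      int run = 0; bool drop = false;
      for (int j = 0; j < l; j++) {
        bool site = (strand == 0) ? (code_plus[s + j] == 3)
                                  : (code_minus[s + j] == 3);
        if (!site) continue;
        bool retained = (strand == 0)
            ? (rd[j] == 'C' && ref[(size_t)(s + j)] == 'C')
            : (rd[j] == 'G' && ref[(size_t)(s + j)] == 'G');
        if (retained) { if (++run >= 3) { drop = true; break; } }
        else run = 0;
      }
      if (drop) continue;
    }
    for (int j = 0; j < l; j++) {
      int code = (strand == 0) ? code_plus[s + j] : code_minus[s + j];
      if (code < 1) continue;  // not a cytosine site, or undefined context
      char rb = rd[j], gb = ref[(size_t)(s + j)];
      int ev;
      if (strand == 0) {
        if (gb != 'C') continue;
        if (rb == 'C') ev = 0; else if (rb == 'T') ev = 1; else continue;
      } else {
        if (gb != 'G') continue;
        if (rb == 'G') ev = 0; else if (rb == 'A') ev = 1; else continue;
      }
      bool bad = false;
      for (int w = -ctx_win; w <= ctx_win && !bad; w++) {
        if (w == 0) continue;
        int jj = j + w;
        if (jj < 0 || jj >= l) continue;
        if (mm[(size_t) jj]) bad = true;
      }
      if (bad) continue;
      int q = (int) qu[j] - phred_offset;
      if (q < 0) q = 0;
      if (q > 93) q = 93;
      uint64_t key = (((uint64_t)(s + j)) * 2ULL + (uint64_t) strand) * 128ULL
          + (uint64_t) q;
      std::pair<int, int> &pr = acc[key];
      if (ev == 0) pr.first++; else pr.second++;
    }
  }
  size_t m = acc.size();
  IntegerVector pos(m), strand_o(m), qv(m), cc(m), tt(m);
  size_t i = 0;
  for (std::unordered_map<uint64_t, std::pair<int, int> >::iterator it =
           acc.begin(); it != acc.end(); ++it, ++i) {
    uint64_t key = it->first;
    qv[i] = (int)(key % 128ULL);
    uint64_t rest = key / 128ULL;
    strand_o[i] = (int)(rest % 2ULL);
    pos[i] = (int)(rest / 2ULL);
    cc[i] = it->second.first;
    tt[i] = it->second.second;
  }
  return DataFrame::create(_["pos"] = pos, _["strand"] = strand_o,
                           _["qual"] = qv, _["c_count"] = cc,
                           _["t_count"] = tt);
}
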