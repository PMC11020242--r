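// Sequence simulators: random genomes, site mutation, short reads
// (substitution errors, random or deterministic tiling placement) and long
// reads (substitution + indel errors, truncated-Gaussian lengths).
// All randomness comes from the R RNG, so set.seed() governs everything.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline char random_base() {
  int b = (int)(unif_rand() * 4.0);
  if (b > 3) b = 3;
  return BASES[b];
}

static inline char random_other_base(char c) {
  char b;
  do { b = random_base(); } while (b == c);
  return b;
}

// distance to the next error site under per-base rate r (geometric skipping);
// returns a huge value when r == 0
static inline long geom_gap(double r) {
  if (r <= 0) return (long)1e15;
  double u = unif_rand();
  if (u <= 0) u = 1e-300;
  return (long)std::floor(std::log(u) / std::log1p(-r));
}

// [[Rcpp::export]]
std::string random_dna_cpp(int n) {
  std::string s(n, 'A');
  for (int i = 0; i < n; ++i) s[i] = random_base();
  return s;
}

// substitute each site independently with probability `rate`;
// returns mutated sequence plus 1-based positions touched
// [[Rcpp::export]]
List mutate_seq_cpp(std::string seq, double rate) {
  std::vector<int> pos;
  long n = (long)seq.size();
  long i = geom_gap(rate);
  while (i < n) {
    seq[i] = random_other_base(seq[i]);
    pos.push_back((int)(i + 1));
    i += 1 + geom_gap(rate);
  }
  return List::create(_["seq"] = seq, _["pos"] = wrap(pos));
}

// [[Rcpp::export]]
std::string apply_snps_cpp(std::string seq, IntegerVector pos, CharacterVector alt) {
  if (pos.size() != alt.size()) stop("pos and alt lengths differ");
  for (R_xlen_t i = 0; i < pos.size(); ++i) {
    long p = pos[i] - 1;
    if (p < 0 || p >= (long)seq.size()) stop("SNP position %d out of range", (int)pos[i]);
    seq[p] = CHAR(STRING_ELT(alt, i))[0];
  }
  return seq;
}

static inline void add_read_with_errors(const std::string& src, long start, int len,
                                        double r, std::vector<std::string>& out) {
  std::string rd = src.substr(start, len);
  long i = geom_gap(r);
  while (i < (long)rd.size()) {
    rd[i] = random_other_base(rd[i]);
    i += 1 + geom_gap(r);
  }
  out.push_back(rd);
}

// Short reads from a set of sequences with per-sequence copy numbers.
// depth is per haploid copy; read count per copy = round(depth * len / l).
// systematic = TRUE tiles reads at stride l - k_guard + 1 and emits every
// read twice, guaranteeing every k-window (k <= k_guard) is covered >= 2x.
// [[Rcpp::export]]
CharacterVector sim_short_reads_cpp(CharacterVector seqs, IntegerVector copies,
                                    double depth, int l, double r,
                                    bool systematic, int k_guard) {
  std::vector<std::string> out;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string src = as<std::string>(seqs[si]);
    long len = (long)src.size();
    if (len == 0) continue;
    int rl = (int)std::min((long)l, len);
    for (int cp = 0; cp < copies[si]; ++cp) {
      if (systematic) {
        long stride = std::max(1L, (long)(rl - k_guard + 1));
        for (long s = 0; s <= len - rl; s += stride) {
          add_read_with_errors(src, s, rl, r, out);
          add_read_with_errors(src, s, rl, r, out);
        }
        if ((len - rl) % stride != 0) {  // terminal read so the tail is covered
          add_read_with_errors(src, len - rl, rl, r, out);
          add_read_with_errors(src, len - rl, rl, r, out);
        }
      } else {
        long n_reads = (long)std::llround(depth * (double)len / (double)rl);
        for (long j = 0; j < n_reads; ++j) {
          long s = (long)(unif_rand() * (double)(len - rl + 1));
          if (s > len - rl) s = len - rl;
          add_read_with_errors(src, s, rl, r, out);
        }
      }
    }
  }
  return wrap(out);
}

// Long reads with substitution/insertion/deletion errors.
// depths: per-sequence target depth; reads are drawn until depth*len template
// bases are consumed. Returns origin index (1-based), template start/end
// (1-based, inclusive) and the read sequences.
// [[Rcpp::export]]
List sim_long_reads_cpp(CharacterVector seqs, NumericVector depths,
                        double mean_len, double sd_len, int min_len,
                        double sub, double ins, double del) {
  if (seqs.size() != depths.size()) stop("seqs and depths lengths differ");
  double p_tot = sub + ins + del;
  std::vector<int> origin;
  std::vector<double> start_v, end_v;
  std::vector<std::string> reads;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string src = as<std::string>(seqs[si]);
    long len = (long)src.size();
    double target = depths[si] * (double)len;
    if (len == 0 || target <= 0) continue;
    double consumed = 0;
    while (consumed < target) {
      long L = (long)std::llround(norm_rand() * sd_len + mean_len);
      if (L < min_len) L = min_len;
      if (L > len) L = len;
      long s = (long)(unif_rand() * (double)(len - L + 1));
      if (s > len - L) s = len - L;
      // walk the template applying errors
      std::string rd;
      rd.reserve((size_t)(L * 1.05) + 16);
      long j = s;
      long gap = geom_gap(p_tot);
      while (j < s + L) {
        if (gap > 0) {
          long chunk = std::min(gap, s + L - j);
          rd.append(src, j, chunk);
          j += chunk;
          gap -= chunk;
          if (j >= s + L) break;
        }
        // error event at template position j
        double u = unif_rand() * p_tot;
        if (u < sub) {
          rd.push_back(random_other_base(src[j]));
          ++j;
        } else if (u < sub + ins) {
          rd.push_back(random_base());
          rd.push_back(src[j]);
          ++j;
        } else {
          ++j;  // deletion: template base skipped
        }
        gap = geom_gap(p_tot);  // distance from the next template base
      }
      origin.push_back((int)(si + 1));
      start_v.push_back((double)(s + 1));
      end_v.push_back((double)(s + L));
      reads.push_back(rd);
      consumed += (double)L;
    }
  }
  return List::create(_["origin"] = wrap(origin), _["start"] = wrap(start_v),
                      _["end"] = wrap(end_v), _["seq"] = wrap(reads));
}
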