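// Core k-mer machinery: canonical encoding, exact counting, sorted-table I/O,
// streaming merge-join marker selection, and marker-density scanning.
//
// k <= 31 uses a 2-bit packed uint64 representation (A=0,C=1,G=2,T=3, first
// base most significant), so numeric order on codes equals lexicographic
// order on the strings. 33..63 fall back to a std::string path.

#include <Rcpp.h>
#include <zlib.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = CODE2BASE[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// encode; returns false if a non-ACGT symbol is present
static inline bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  out = code;
  return true;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static inline std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline std::string upper_str(const std::string& s) {
  std::string u(s);
  for (auto& c : u) c = (char)toupper((unsigned char)c);
  return u;
}

// [[Rcpp::export]]
CharacterVector canonical_kmer_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = upper_str(as<std::string>(seqs[i]));
    bool ok = true;
    for (char c : s) if (base_code(c) < 0) { ok = false; break; }
    if (!ok || s.empty()) { out[i] = NA_STRING; continue; }
    std::string rc = revcomp_str(s);
    out[i] = (rc < s) ? rc : s;
  }
  return out;
}

// ---- counting ---------------------------------------------------------------

struct CountResult {
  // exactly one of these is populated depending on k
  std::vector<std::pair<uint64_t, uint32_t> > num;
  std::vector<std::pair<std::string, uint32_t> > str;
  double total_windows = 0;  // number of valid k-windows consumed
  bool numeric_path = true;
};

static void count_into(const CharacterVector& reads, int k, CountResult& res) {
  double window_bound = 0;
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri)
    if (reads[ri] != NA_STRING) window_bound += (double)LENGTH(STRING_ELT(reads, ri));
  size_t reserve_n = (size_t)std::min(window_bound, 4.0e7);
  if (k <= 31) {
    res.numeric_path = true;
    std::unordered_map<uint64_t, uint32_t> tab;
    tab.reserve(reserve_n);
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift_rc = 2 * (k - 1);
    for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
      if (reads[ri] == NA_STRING) continue;
      const char* s = CHAR(STRING_ELT(reads, ri));
      int len = (int)LENGTH(STRING_ELT(reads, ri));
      uint64_t fwd = 0, rc = 0;
      int run = 0;  // valid bases in current window
      for (int i = 0; i < len; ++i) {
        int b = base_code(s[i]);
        if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
        if (++run >= k) {
          uint64_t canon = std::min(fwd, rc);
          ++tab[canon];
          res.total_windows += 1;
        }
      }
    }
    res.num.assign(tab.begin(), tab.end());
    std::sort(res.num.begin(), res.num.end());
  } else {
    res.numeric_path = false;
    std::unordered_map<std::string, uint32_t> tab;
    for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
      if (reads[ri] == NA_STRING) continue;
      std::string s = upper_str(as<std::string>(reads[ri]));
      int len = (int)s.size();
      for (int i = 0; i + k <= len; ++i) {
        bool ok = true;
        for (int j = i; j < i + k; ++j)
          if (base_code(s[j]) < 0) { ok = false; i = j; break; }  // skip past bad base
        if (!ok) continue;
        std::string w = s.substr(i, k);
        std::string rc = revcomp_str(w);
        ++tab[(rc < w) ? rc : w];
        res.total_windows += 1;
      }
    }
    res.str.assign(tab.begin(), tab.end());
    std::sort(res.str.begin(), res.str.end());
  }
}

// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector reads, int k, int min_count) {
  CountResult res;
  count_into(reads, k, res);
  std::vector<std::string> keys;
  std::vector<int> cnts;
  if (res.numeric_path) {
    for (auto& kv : res.num)
      if ((int)kv.second >= min_count) { keys.push_back(decode_kmer(kv.first, k)); cnts.push_back((int)kv.second); }
  } else {
    for (auto& kv : res.str)
      if ((int)kv.second >= min_count) { keys.push_back(kv.first); cnts.push_back((int)kv.second); }
  }
  return List::create(_["kmer"] = wrap(keys), _["count"] = wrap(cnts),
                      _["total_windows"] = res.total_windows);
}

// gz-backed line writer (gzopen with "wT" writes transparently uncompressed)
struct OutFile {
  gzFile f;
  OutFile(const std::string& path) {
    bool gz = path.size() > 3 && path.compare(path.size() - 3, 3, ".gz") == 0;
    f = gzopen(path.c_str(), gz ? "wb1" : "wT");
    if (!f) stop("cannot open '%s' for writing", path.c_str());
  }
  void line(const std::string& key, uint32_t cnt) {
    char buf[96];
    int n = snprintf(buf, sizeof(buf), "%s\t%u\n", key.c_str(), cnt);
    gzwrite(f, buf, (unsigned)n);
  }
  ~OutFile() { if (f) gzclose(f); }
};

// [[Rcpp::export]]
List count_kmers_file_cpp(CharacterVector reads, int k, int min_count, std::string path) {
  CountResult res;
  count_into(reads, k, res);
  double n_out = 0;
  {
    OutFile out(path);
    if (res.numeric_path) {
      for (auto& kv : res.num)
        if ((int)kv.second >= min_count) { out.line(decode_kmer(kv.first, k), kv.second); ++n_out; }
    } else {
      for (auto& kv : res.str)
        if ((int)kv.second >= min_count) { out.line(kv.first, kv.second); ++n_out; }
    }
  }
  return List::create(_["n_kmers"] = n_out, _["total_windows"] = res.total_windows);
}

// [[Rcpp::export]]
void write_table_lines_cpp(CharacterVector kmer, IntegerVector count, std::string path) {
  OutFile out(path);
  for (R_xlen_t i = 0; i < kmer.size(); ++i)
    out.line(as<std::string>(kmer[i]), (uint32_t)count[i]);
}

// ---- sorted-table reader & streaming merge ----------------------------------

struct TableStream {
  gzFile f;
  std::string path;
  long line_no = 0;
  int k = -1;                // inferred from the first record if not forced
  bool numeric = true;       // k <= 31
  bool has = false;
  uint64_t code = 0;
  std::string kmer;
  long cnt = 0;
  char buf[4096];

  TableStream(const std::string& p, int k_expect) : path(p), k(k_expect) {
    f = gzopen(p.c_str(), "rb");
    if (!f) stop("cannot open k-mer table '%s'", p.c_str());
    advance();
  }
  ~TableStream() { if (f) gzclose(f); }

  void fail(const std::string& what) {
    stop("malformed k-mer table '%s' line %ld: %s", path.c_str(), line_no, what.c_str());
  }

  void advance() {
    std::string prev = has ? kmer : std::string();
    while (true) {
      if (gzgets(f, buf, sizeof(buf)) == NULL) { has = false; return; }
      ++line_no;
      std::string line(buf);
      while (!line.empty() && (line.back() == '\n' || line.back() == '\r')) line.pop_back();
      if (line.empty()) continue;
      size_t tab = line.find('\t');
      if (tab == std::string::npos) fail("expected two TAB-separated columns");
      if (line.find('\t', tab + 1) != std::string::npos) fail("expected exactly two columns");
      kmer = line.substr(0, tab);
      std::string cs = line.substr(tab + 1);
      if (k < 0) { k = (int)kmer.size(); numeric = (k <= 31); }
      if ((int)kmer.size() != k) fail("k-mer length differs from k=" + std::to_string(k));
      if (cs.empty()) fail("missing count");
      cnt = 0;
      for (char c : cs) {
        if (c < '0' || c > '9') fail("count is not a non-negative integer");
        cnt = cnt * 10 + (c - '0');
        if (cnt > 2000000000L) fail("count overflows");
      }
      if (numeric) {
        if (!encode_kmer(kmer.c_str(), k, code)) fail("k-mer contains a non-ACGT symbol");
        // canonical strings encode/decode round-trip; enforce uppercase ACGT
        kmer = decode_kmer(code, k);
      } else {
        for (char& c : kmer) {
          if (base_code(c) < 0) fail("k-mer contains a non-ACGT symbol");
          c = (char)toupper((unsigned char)c);
        }
      }
      if (!prev.empty() && kmer <= prev) fail("k-mers not strictly increasing (table must be sorted, duplicate-free)");
      has = true;
      return;
    }
  }
};

// [[Rcpp::export]]
List read_table_cpp(std::string path) {
  TableStream ts(path, -1);
  std::vector<std::string> keys;
  std::vector<int> cnts;
  while (ts.has) {
    keys.push_back(ts.kmer);
    cnts.push_back((int)ts.cnt);
    ts.advance();
  }
  return List::create(_["kmer"] = wrap(keys), _["count"] = wrap(cnts),
                      _["k"] = ts.k < 0 ? NA_INTEGER : ts.k);
}

// Streaming merge-join over per-individual sorted count tables.
// A k-mer is selected iff present (count >= min_count) in >= m male tables,
// present in 0 female tables, and (optionally) its pooled male count lies in
// [band_lo, band_hi].
// [[Rcpp::export]]
CharacterVector msk_select_files_cpp(CharacterVector male_paths,
                                     CharacterVector female_paths,
                                     int min_count, int m,
                                     double band_lo, double band_hi) {
  std::vector<TableStream*> st;
  int n_m = (int)male_paths.size(), n_f = (int)female_paths.size();
  for (int i = 0; i < n_m; ++i) st.push_back(new TableStream(as<std::string>(male_paths[i]), -1));
  for (int i = 0; i < n_f; ++i) st.push_back(new TableStream(as<std::string>(female_paths[i]), -1));
  int k = -1;
  for (auto* s : st) if (s->has) { if (k < 0) k = s->k; else if (s->k != k)
      { for (auto* t : st) delete t; stop("k-mer tables disagree on k"); } }
  bool numeric = (k > 0 && k <= 31);

  std::vector<std::string> out;
  while (true) {
    // find the minimal current key across streams
    bool any = false;
    uint64_t min_code = ~0ULL;
    std::string min_str;
    for (auto* s : st) {
      if (!s->has) continue;
      if (!any) { any = true; min_code = s->code; min_str = s->kmer; }
      else if (numeric ? (s->code < min_code) : (s->kmer < min_str)) { min_code = s->code; min_str = s->kmer; }
    }
    if (!any) break;
    int males_present = 0, females_present = 0;
    double pooled = 0;
    for (int i = 0; i < (int)st.size(); ++i) {
      TableStream* s = st[i];
      if (!s->has) continue;
      bool match = numeric ? (s->code == min_code) : (s->kmer == min_str);
      if (!match) continue;
      if (i < n_m) {
        if (s->cnt >= min_count) { ++males_present; pooled += (double)s->cnt; }
      } else {
        if (s->cnt >= min_count) ++females_present;
      }
      s->advance();
    }
    if (females_present == 0 && males_present >= m && pooled >= band_lo && pooled <= band_hi)
      out.push_back(numeric ? decode_kmer(min_code, k) : min_str);
  }
  for (auto* s : st) delete s;
  return wrap(out);
}

// ---- marker scanning ---------------------------------------------------------

// Number of k-window positions in each sequence whose canonical k-mer is in
// `markers` (occurrences; `distinct` counts distinct markers per sequence).
// [[Rcpp::export]]
IntegerVector scan_hits_cpp(CharacterVector seqs, int k, CharacterVector markers, bool distinct) {
  R_xlen_t n = seqs.size();
  IntegerVector hits(n);
  if (k <= 31) {
    std::unordered_set<uint64_t> set;
    set.reserve((size_t)markers.size() * 2 + 16);
    for (R_xlen_t i = 0; i < markers.size(); ++i) {
      uint64_t code;
      const char* s = CHAR(STRING_ELT(markers, i));
      if ((int)LENGTH(STRING_ELT(markers, i)) != k) stop("marker %ld does not have length k", (long)(i + 1));
      if (!encode_kmer(s, k, code)) stop("marker %ld contains a non-ACGT symbol", (long)(i + 1));
      uint64_t rc = 0;
      for (int j = 0; j < k; ++j) rc = (rc << 2) | (3 - ((code >> (2 * j)) & 3ULL));
      set.insert(std::min(code, rc));
    }
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    const int shift_rc = 2 * (k - 1);
    for (R_xlen_t ri = 0; ri < n; ++ri) {
      if (seqs[ri] == NA_STRING) { hits[ri] = 0; continue; }
      const char* s = CHAR(STRING_ELT(seqs, ri));
      int len = (int)LENGTH(STRING_ELT(seqs, ri));
      uint64_t fwd = 0, rc = 0;
      int run = 0, h = 0;
      std::unordered_set<uint64_t> seen;
      for (int i = 0; i < len; ++i) {
        int b = base_code(s[i]);
        if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
        if (++run >= k) {
          uint64_t canon = std::min(fwd, rc);
          if (set.count(canon)) {
            if (distinct) { if (seen.insert(canon).second) ++h; }
            else ++h;
          }
        }
      }
      hits[ri] = h;
    }
  } else {
    std::unordered_set<std::string> set;
    for (R_xlen_t i = 0; i < markers.size(); ++i) {
      std::string s = upper_str(as<std::string>(markers[i]));
      if ((int)s.size() != k) stop("marker %ld does not have length k", (long)(i + 1));
      std::string rc = revcomp_str(s);
      set.insert(std::min(s, rc));
    }
    for (R_xlen_t ri = 0; ri < n; ++ri) {
      if (seqs[ri] == NA_STRING) { hits[ri] = 0; continue; }
      std::string s = upper_str(as<std::string>(seqs[ri]));
      int len = (int)s.size(), h = 0;
      std::unordered_set<std::string> seen;
      for (int i = 0; i + k <= len; ++i) {
        bool ok = true;
        for (int j = i; j < i + k; ++j) if (base_code(s[j]) < 0) { ok = false; i = j; break; }
        if (!ok) continue;
        std::string w = s.substr(i, k);
        std::string rc = revcomp_str(w);
        std::string canon = std::min(w, rc);
        if (set.count(canon)) {
          if (distinct) { if (seen.insert(canon).second) ++h; }
          else ++h;
        }
      }
      hits[ri] = h;
    }
  }
  return hits;
}

// Canonical k-mer set of a group of sequences minus that of another group.
// [[Rcpp::export]]
CharacterVector kmer_set_diff_cpp(CharacterVector target_seqs, CharacterVector other_seqs, int k) {
  CountResult tgt, oth;
  count_into(target_seqs, k, tgt);
  count_into(other_seqs, k, oth);
  std::vector<std::string> out;
  if (tgt.numeric_path) {
    std::unordered_set<uint64_t> bad;
    bad.reserve(oth.num.size() * 2 + 16);
    for (auto& kv : oth.num) bad.insert(kv.first);
    for (auto& kv : tgt.num)
      if (!bad.count(kv.first)) out.push_back(decode_kmer(kv.first, k));
  } else {
    std::unordered_set<std::string> bad;
    for (auto& kv : oth.str) bad.insert(kv.first);
    for (auto& kv : tgt.str)
      if (!bad.count(kv.first)) out.push_back(kv.first);
  }
  return wrap(out);
}
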