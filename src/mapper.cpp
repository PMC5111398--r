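// Seed-and-verify read mapper for circular mitogenome references.
//
// Contract: a hit is a full-length, ungapped alignment of the read (either
// strand) with at most floor(read_length * max_mismatch_rate) mismatches;
// N counts as a mismatch on either side. A read is `unique` when all hits
// fall on a single reference, `multi_reference` when hits span two or more
// references, `unmapped` otherwise. Circularity is handled by extending each
// reference with read_length - 1 wrap bases; positions are reported modulo
// the achieved length.
//
// Index: exact k-mers (k = min(31, floor(read_length / (m + 1)))) at every
// start position of every (wrap-extended) reference, 2-bit packed. By the
// pigeonhole principle any alignment with <= m mismatches contains at least
// one exact block of length floor(L / (m + 1)) >= k, so looking up the
// k-prefix of each of the m + 1 read blocks finds every hit. Reads too short
// for the guarantee fall back to a full scan.

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N and anything else: never matches
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

struct RefEntry {
  std::string name;
  std::string ext;   // sequence + first (read_length - 1) wrap bases
  int len;           // achieved length
};

struct MitoIndex {
  std::vector<RefEntry> refs;
  int read_length;
  double max_mm_rate;
  int k;
  // key: 2-bit packed k-mer; value: packed (ref << 32) | pos
  std::unordered_map<uint64_t, std::vector<uint64_t> > table;
};

static inline int budget_for(int len, double rate) {
  return (int)std::floor((double)len * rate + 1e-9);
}

// mismatches of s against ref.ext starting at `start`; early exit above cap
static inline int count_mm(const std::string& s, const std::string& ext,
                           int start, int cap) {
  int mm = 0;
  const int L = (int)s.size();
  for (int j = 0; j < L; ++j) {
    char a = s[j], b = ext[start + j];
    if (a != b || base_code(a) < 0) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct Hit {
  int ref, pos, mm;
  char strand;
};

static void verify_candidate(const MitoIndex& idx, const std::string& s,
                             char strand, int ref, int pos, int cap,
                             std::vector<Hit>& hits) {
  const RefEntry& r = idx.refs[ref];
  const int L = (int)s.size();
  if (L > r.len) return;                       // read longer than the circle
  if (pos < 0) pos += r.len;
  if (pos < 0 || pos >= r.len) return;
  if (pos + L > (int)r.ext.size()) return;     // wrap extension too short
  for (std::size_t i = 0; i < hits.size(); ++i)
    if (hits[i].ref == ref && hits[i].pos == pos && hits[i].strand == strand)
      return;                                  // already verified
  int mm = count_mm(s, r.ext, pos, cap);
  if (mm <= cap) {
    Hit h; h.ref = ref; h.pos = pos; h.mm = mm; h.strand = strand;
    hits.push_back(h);
  }
}

static void search_oriented(const MitoIndex& idx, const std::string& s,
                            char strand, int cap, std::vector<Hit>& hits) {
  const int L = (int)s.size();
  const int nblock = cap + 1;
  const int block = L / nblock;
  if (block >= idx.k) {
    // pigeonhole seeding
    for (int t = 0; t < nblock; ++t) {
      const int off = t * block;
      uint64_t key = 0;
      bool ok = true;
      for (int j = 0; j < idx.k; ++j) {
        int c = base_code(s[off + j]);
        if (c < 0) { ok = false; break; }      // block with N can't be exact
        key = (key << 2) | (uint64_t)c;
      }
      if (!ok) continue;
      std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
        idx.table.find(key);
      if (it == idx.table.end()) continue;
      const std::vector<uint64_t>& cands = it->second;
      for (std::size_t i = 0; i < cands.size(); ++i) {
        int ref = (int)(cands[i] >> 32);
        int pos = (int)(cands[i] & 0xffffffffu) - off;
        verify_candidate(idx, s, strand, ref, pos, cap, hits);
      }
    }
  } else {
    // read too short for the seeding guarantee: exhaustive scan
    for (std::size_t r = 0; r < idx.refs.size(); ++r)
      for (int p = 0; p < idx.refs[r].len; ++p)
        verify_candidate(idx, s, strand, (int)r, p, cap, hits);
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (std::size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// [[Rcpp::export(name = ".mapper_build_index")]]
SEXP mapper_build_index(CharacterVector sequences, CharacterVector names,
                        int read_length, double max_mismatch_rate) {
  MitoIndex* idx = new MitoIndex();
  idx->read_length = read_length;
  idx->max_mm_rate = max_mismatch_rate;
  int m = budget_for(read_length, max_mismatch_rate);
  int block = read_length / (m + 1);
  idx->k = std::min(31, block);
  if (idx->k < 8) {
    delete idx;
    stop("read_length %d gives seed length %d (< 8): too short for indexing",
         read_length, block);
  }
  for (int r = 0; r < sequences.size(); ++r) {
    RefEntry e;
    e.name = as<std::string>(names[r]);
    std::string seq = as<std::string>(sequences[r]);
    e.len = (int)seq.size();
    e.ext = seq;
    // wrap extension; repeat the sequence if it is shorter than the read
    while ((int)e.ext.size() < e.len + read_length - 1 &&
           (int)e.ext.size() < 2 * (e.len + read_length)) {
      e.ext += seq;
    }
    if ((int)e.ext.size() > e.len + read_length - 1)
      e.ext.resize(e.len + read_length - 1);
    idx->refs.push_back(e);
  }
  // index every start position of every reference (forward strand only;
  // minus-strand hits are found by searching the reverse complement read)
  for (std::size_t r = 0; r < idx->refs.size(); ++r) {
    const RefEntry& e = idx->refs[r];
    const uint64_t mask = (idx->k >= 32) ? ~(uint64_t)0
      : (((uint64_t)1 << (2 * idx->k)) - 1);
    uint64_t key = 0;
    int run = 0;  // number of valid bases accumulated
    for (int p = 0; p < (int)e.ext.size(); ++p) {
      int c = base_code(e.ext[p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= idx->k) {
        int start = p - idx->k + 1;
        if (start < e.len)
          idx->table[key].push_back(((uint64_t)r << 32) | (uint64_t)start);
      }
    }
  }
  XPtr<MitoIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".mapper_index_info")]]
List mapper_index_info(SEXP xp) {
  XPtr<MitoIndex> idx(xp);
  CharacterVector nm(idx->refs.size());
  IntegerVector len(idx->refs.size());
  for (std::size_t r = 0; r < idx->refs.size(); ++r) {
    nm[r] = idx->refs[r].name;
    len[r] = idx->refs[r].len;
  }
  return List::create(_["reference_id"] = nm, _["length"] = len,
                      _["read_length"] = idx->read_length,
                      _["max_mismatch_rate"] = idx->max_mm_rate,
                      _["seed_length"] = idx->k,
                      _["n_kmers"] = (double)idx->table.size());
}

// number of indexed locations holding an exact k-mer (diagnostic)
// [[Rcpp::export(name = ".mapper_seed_hits")]]
int mapper_seed_hits(SEXP xp, std::string seed) {
  XPtr<MitoIndex> idx(xp);
  if ((int)seed.size() != idx->k)
    stop("seed must have the index k-mer length (%d)", idx->k);
  uint64_t key = 0;
  for (int j = 0; j < idx->k; ++j) {
    int c = base_code(seed[j]);
    if (c < 0) return 0;
    key = (key << 2) | (uint64_t)c;
  }
  std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
    idx->table.find(key);
  return it == idx->table.end() ? 0 : (int)it->second.size();
}

// statuses: 0 = unique, 1 = multi_reference, 2 = unmapped
// [[Rcpp::export(name = ".mapper_map_reads")]]
List mapper_map_reads(SEXP xp, CharacterVector reads, bool accumulate_depth) {
  XPtr<MitoIndex> idx(xp);
  const int n = reads.size();
  IntegerVector status(n), ref(n, NA_INTEGER), pos(n, NA_INTEGER),
    mism(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING);
  std::vector<std::vector<int> > depth;
  if (accumulate_depth) {
    depth.resize(idx->refs.size());
    for (std::size_t r = 0; r < idx->refs.size(); ++r)
      depth[r].assign(idx->refs[r].len, 0);
  }
  std::vector<Hit> hits;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    const int L = (int)s.size();
    int cap = budget_for(L, idx->max_mm_rate);
    hits.clear();
    search_oriented(*idx, s, '+', cap, hits);
    std::string rc = revcomp(s);
    search_oriented(*idx, rc, '-', cap, hits);
    if (hits.empty()) { status[i] = 2; continue; }
    int first_ref = hits[0].ref;
    bool multi = false;
    for (std::size_t h = 1; h < hits.size(); ++h)
      if (hits[h].ref != first_ref) { multi = true; break; }
    if (multi) { status[i] = 1; continue; }
    // best hit: fewest mismatches, then smallest position, then '+' strand
    std::size_t best = 0;
    for (std::size_t h = 1; h < hits.size(); ++h) {
      const Hit& a = hits[h];
      const Hit& b = hits[best];
      if (a.mm < b.mm ||
          (a.mm == b.mm && (a.pos < b.pos ||
                            (a.pos == b.pos && a.strand == '+' &&
                             b.strand == '-'))))
        best = h;
    }
    status[i] = 0;
    ref[i] = hits[best].ref + 1;  // 1-based into reference table
    pos[i] = hits[best].pos;      // 0-based on the circle
    strand[i] = (hits[best].strand == '+') ? "+" : "-";
    mism[i] = hits[best].mm;
    if (accumulate_depth) {
      const int rl = idx->refs[first_ref].len;
      std::vector<int>& d = depth[first_ref];
      int p = hits[best].pos;
      for (int j = 0; j < L; ++j) d[(p + j) % rl]++;
    }
  }
  List out = List::create(_["status"] = status, _["ref"] = ref,
                          _["position"] = pos, _["strand"] = strand,
                          _["mismatches"] = mism);
  if (accumulate_depth) {
    List dl(depth.size());
    for (std::size_t r = 0; r < depth.size(); ++r)
      dl[r] = IntegerVector(depth[r].begin(), depth[r].end());
    out["depth"] = dl;
  }
  return out;
}
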