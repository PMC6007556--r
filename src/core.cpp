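#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <fstream>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Hashing primitives
//
// Canonical k-mers are hashed to 64 bits.  For k <= 32 the k-mer is packed
// 2 bits/base (A=0,C=1,G=2,T=3, first base in the most significant position,
// so numeric order == lexicographic order) and the canonical form is the
// numeric minimum of the forward and reverse-complement packing; the packed
// value is then finalised through splitmix64, a 64-bit bijection, so the
// hash is collision-free at these k.  For k > 32 the canonical string is
// hashed with FNV-1a.  Fingerprints are the low 16 bits of an xor-shift
// remix of the key hash; the slot used for absent-key emulation comes from
// an independent splitmix64 remix.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// xor-shift remix used for the 16-bit fingerprint (constants 13/7/17)
static inline uint16_t fingerprint16(uint64_t h) {
  uint64_t x = h ^ 0xA24BAED4963EE407ULL;
  x ^= x << 13;
  x ^= x >> 7;
  x ^= x << 17;
  return (uint16_t)(x & 0xFFFFULL);
}

// slot an absent key would fall into (emulates an arbitrary MPHF slot)
static inline uint64_t absent_slot(uint64_t h, uint64_t n) {
  return splitmix64(h ^ 0xD6E8FEB86659FD93ULL) % n;
}

static inline uint64_t fnv1a(const char* s, size_t n) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 0x100000001B3ULL;
  }
  return h;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_packed(uint64_t v, int k) {
  uint64_t rc = 0;
  for (int j = 0; j < k; ++j) {
    uint64_t b = (v >> (2 * (k - 1 - j))) & 3ULL;
    rc |= (3ULL - b) << (2 * j);
  }
  return rc;
}

static std::string decode_packed(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int j = 0; j < k; ++j)
    s[j] = BASES[(v >> (2 * (k - 1 - j))) & 3ULL];
  return s;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': case 'a': c = 'T'; break;
      case 'C': case 'c': c = 'G'; break;
      case 'G': case 'g': c = 'C'; break;
      case 'T': case 't': c = 'A'; break;
    }
  }
  return r;
}

// Visit every valid k-mer of `s`, calling f(offset, hash, fwd_is_canonical).
// Rolling (amortised O(1)/offset) for k <= 32; per-window otherwise.
template <typename F>
static void each_canonical(const std::string& s, int k, F f) {
  int len = (int)s.size();
  if (len < k) return;
  if (k <= 32) {
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    uint64_t fcode = 0, rcode = 0;
    int run = 0;
    for (int i = 0; i < len; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; fcode = rcode = 0; continue; }
      fcode = ((fcode << 2) | (uint64_t)c) & mask;
      rcode = (rcode >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++run >= k) {
        bool fwd = fcode <= rcode;
        uint64_t canon = fwd ? fcode : rcode;
        f(i - k + 1, splitmix64(canon), fwd);
      }
    }
  } else {
    // prefix count of invalid bases for O(1) window validity
    std::vector<int> bad(len + 1, 0);
    for (int i = 0; i < len; ++i)
      bad[i + 1] = bad[i] + (base_code(s[i]) < 0 ? 1 : 0);
    for (int i = 0; i + k <= len; ++i) {
      if (bad[i + k] - bad[i] > 0) continue;
      std::string w = s.substr(i, k);
      for (auto& c : w) c = BASES[base_code(c)];
      std::string rc = revcomp_str(w);
      bool fwd = w <= rc;
      const std::string& canon = fwd ? w : rc;
      f(i, fnv1a(canon.c_str(), canon.size()), fwd);
    }
  }
}

// canonical hash of a single k-mer; returns false if it contains non-ACGT
static bool kmer_hash(const std::string& w, int k, uint64_t* h, bool* fwd) {
  if ((int)w.size() != k) stop("k-mer length %d does not match k = %d", (int)w.size(), k);
  bool got = false;
  each_canonical(w, k, [&](int, uint64_t hh, bool ff) { *h = hh; *fwd = ff; got = true; });
  return got;
}

// ---------------------------------------------------------------------------
// Index structure
// ---------------------------------------------------------------------------

struct KmerIndex {
  int k;
  int fp_bits;  // fixed at 16
  std::vector<std::string> contig_names;
  std::vector<uint32_t> contig_lengths;
  std::vector<uint64_t> keys;      // canonical key hash per slot (sorted)
  std::vector<uint16_t> fps;       // fingerprint per slot
  std::vector<uint32_t> contig;    // 0-based contig index per slot
  std::vector<uint32_t> pos;       // 0-based k-mer start per slot
  std::vector<uint8_t> strand;     // 1 = canonical form equals contig forward k-mer
  std::unordered_map<uint64_t, uint32_t> slot_of;

  size_t n() const { return keys.size(); }

  void finalise_slots() {
    slot_of.clear();
    slot_of.reserve(keys.size() * 2);
    for (size_t i = 0; i < keys.size(); ++i) slot_of[keys[i]] = (uint32_t)i;
  }

  // lookup: record index, or -1 absent; *collision set when a fingerprint
  // false positive produced the answer
  long long lookup_hash(uint64_t h, bool* collision) const {
    *collision = false;
    auto it = slot_of.find(h);
    if (it != slot_of.end()) return (long long)it->second;
    if (keys.empty()) return -1;
    uint64_t s = absent_slot(h, keys.size());
    if (fingerprint16(h) == fps[s]) { *collision = true; return (long long)s; }
    return -1;
  }
};

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k,
                     double chunk_size) {
  if (k < 15 || k > 256) stop("k must be between 15 and 256");
  int nc = seqs.size();
  if (nc == 0) stop("at least one contig is required");
  if (nc > 2147483647) stop("contig count exceeds 32-bit id space");
  size_t cs = chunk_size < (double)k ? (size_t)5000000 : (size_t)chunk_size;

  std::vector<std::string> sv(nc);
  for (int i = 0; i < nc; ++i) {
    sv[i] = as<std::string>(seqs[i]);
    if (sv[i].size() > 4294967295.0) stop("contig '%s' exceeds 32-bit coordinate space",
                                          as<std::string>(names[i]).c_str());
  }

  // step 1-2: count canonical k-mers, chunked (overlap k-1 so no window is
  // lost; each start position is owned by exactly one chunk)
  std::unordered_map<uint64_t, uint32_t> counts;
  for (int i = 0; i < nc; ++i) {
    const std::string& s = sv[i];
    if (s.size() < (size_t)k) continue;
    for (size_t c0 = 0; c0 < s.size(); c0 += cs) {
      size_t c1 = std::min(s.size(), c0 + cs + (size_t)k - 1);
      std::string chunk = s.substr(c0, c1 - c0);
      each_canonical(chunk, k, [&](int off, uint64_t h, bool) {
        if ((size_t)off < cs) {  // start positions owned by this chunk
          auto it = counts.find(h);
          if (it == counts.end()) counts.emplace(h, 1);
          else if (it->second < 0xFFFFFFFFu) it->second++;
        }
      });
      if (c1 == s.size()) break;
    }
  }

  size_t nun = 0;
  for (auto& kv : counts) if (kv.second == 1) ++nun;
  if (nun == 0) stop("no unique %d-mers found in the input contigs; try a larger k", k);

  XPtr<KmerIndex> idx(new KmerIndex(), true);
  idx->k = k;
  idx->fp_bits = 16;
  idx->contig_names.resize(nc);
  idx->contig_lengths.resize(nc);
  for (int i = 0; i < nc; ++i) {
    idx->contig_names[i] = as<std::string>(names[i]);
    idx->contig_lengths[i] = (uint32_t)sv[i].size();
  }

  // steps 3-5: second pass storing (contig, coordinate, strand) for
  // frequency-1 keys; slots sorted by key hash so construction is
  // independent of contig/chunk order
  std::vector<uint64_t> uk;
  uk.reserve(nun);
  for (auto& kv : counts) if (kv.second == 1) uk.push_back(kv.first);
  std::sort(uk.begin(), uk.end());
  idx->keys = std::move(uk);
  idx->fps.resize(nun);
  idx->contig.resize(nun);
  idx->pos.resize(nun);
  idx->strand.resize(nun);
  idx->finalise_slots();
  for (size_t i = 0; i < nun; ++i) idx->fps[i] = fingerprint16(idx->keys[i]);

  for (int i = 0; i < nc; ++i) {
    each_canonical(sv[i], k, [&](int off, uint64_t h, bool fwd) {
      auto it = idx->slot_of.find(h);
      if (it != idx->slot_of.end()) {
        uint32_t s = it->second;
        idx->contig[s] = (uint32_t)i;
        idx->pos[s] = (uint32_t)off;
        idx->strand[s] = fwd ? 1 : 0;
      }
    });
  }
  return idx;
}

// [[Rcpp::export(name = ".cpp_index_info")]]
List cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return List::create(_["k"] = idx->k, _["fingerprint_bits"] = idx->fp_bits,
                      _["n_keys"] = (double)idx->n(),
                      _["contig"] = wrap(idx->contig_names),
                      _["length"] = IntegerVector(idx->contig_lengths.begin(),
                                                  idx->contig_lengths.end()));
}

// [[Rcpp::export(name = ".cpp_hash_stream")]]
List cpp_hash_stream(std::string s, int k) {
  std::vector<int> off;
  std::vector<std::string> hex;
  std::vector<bool> fwd;
  char buf[17];
  each_canonical(s, k, [&](int o, uint64_t h, bool f) {
    off.push_back(o);
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    hex.push_back(buf);
    fwd.push_back(f);
  });
  return List::create(_["offset"] = wrap(off), _["hash"] = wrap(hex),
                      _["forward_canonical"] = wrap(fwd));
}

// [[Rcpp::export(name = ".cpp_count_kmers")]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  int nc = seqs.size();
  std::vector<std::string> sv(nc);
  for (int i = 0; i < nc; ++i) sv[i] = as<std::string>(seqs[i]);
  struct Occ { uint32_t count, contig, pos; uint8_t fwd; };
  std::unordered_map<uint64_t, Occ> counts;
  for (int i = 0; i < nc; ++i) {
    each_canonical(sv[i], k, [&](int off, uint64_t h, bool fwd) {
      auto it = counts.find(h);
      if (it == counts.end())
        counts.emplace(h, Occ{1, (uint32_t)i, (uint32_t)off, (uint8_t)(fwd ? 1 : 0)});
      else
        it->second.count++;
    });
  }
  size_t n = counts.size();
  std::vector<std::string> kmer(n);
  IntegerVector count(n), contig(n), posn(n);
  LogicalVector fwd(n);
  size_t j = 0;
  for (auto& kv : counts) {
    const Occ& o = kv.second;
    std::string w = sv[o.contig].substr(o.pos, k);
    for (auto& c : w) c = BASES[base_code(c)];
    if (!o.fwd) w = revcomp_str(w);
    kmer[j] = w;
    count[j] = (int)o.count;
    contig[j] = (int)o.contig + 1;
    posn[j] = (int)o.pos;
    fwd[j] = o.fwd != 0;
    ++j;
  }
  return List::create(_["kmer"] = wrap(kmer), _["count"] = count,
                      _["contig_id"] = contig, _["position"] = posn,
                      _["forward"] = fwd);
}

// [[Rcpp::export(name = ".cpp_lookup")]]
List cpp_lookup(SEXP xp, CharacterVector kmers) {
  XPtr<KmerIndex> idx(xp);
  int n = kmers.size();
  LogicalVector found(n), qfwd(n), coll(n);
  IntegerVector contig(n), posn(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    std::string w = as<std::string>(kmers[i]);
    uint64_t h;
    bool fw;
    if (!kmer_hash(w, idx->k, &h, &fw)) {
      found[i] = false; qfwd[i] = NA_LOGICAL; coll[i] = false;
      contig[i] = NA_INTEGER; posn[i] = NA_INTEGER; strand[i] = NA_STRING;
      continue;
    }
    bool c;
    long long s = idx->lookup_hash(h, &c);
    qfwd[i] = fw;
    coll[i] = c;
    if (s < 0) {
      found[i] = false;
      contig[i] = NA_INTEGER; posn[i] = NA_INTEGER; strand[i] = NA_STRING;
    } else {
      found[i] = true;
      contig[i] = (int)idx->contig[s] + 1;
      posn[i] = (int)idx->pos[s];
      strand[i] = idx->strand[s] ? "+" : "-";
    }
  }
  return List::create(_["found"] = found, _["contig_id"] = contig,
                      _["position"] = posn, _["strand"] = strand,
                      _["query_forward"] = qfwd, _["fp_collision"] = coll);
}

// [[Rcpp::export(name = ".cpp_collect_hits")]]
List cpp_collect_hits(SEXP xp, std::string read, int capacity) {
  XPtr<KmerIndex> idx(xp);
  std::vector<int> contig, coord, roff;
  std::vector<bool> fwd;
  int stored = 0;
  // manual loop so we can stop early once `capacity` hits are stored
  int k = idx->k, len = (int)read.size();
  if (len >= k && capacity > 0) {
    if (k <= 32) {
      uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
      uint64_t fc = 0, rc = 0;
      int run = 0;
      for (int i = 0; i < len && stored < capacity; ++i) {
        int c = base_code(read[i]);
        if (c < 0) { run = 0; continue; }
        fc = ((fc << 2) | (uint64_t)c) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
        if (++run >= k) {
          bool f = fc <= rc;
          uint64_t h = splitmix64(f ? fc : rc);
          bool coll;
          long long s = idx->lookup_hash(h, &coll);
          if (s >= 0) {
            contig.push_back((int)idx->contig[s] + 1);
            coord.push_back((int)idx->pos[s]);
            // match orientation of read k-mer vs contig
            fwd.push_back((idx->strand[s] != 0) == f);
            roff.push_back(i - k + 1);
            ++stored;
          }
        }
      }
    } else {
      for (int i = 0; i + k <= len && stored < capacity; ++i) {
        std::string w = read.substr(i, k);
        uint64_t h;
        bool f;
        bool ok = true;
        for (auto ch : w) if (base_code(ch) < 0) { ok = false; break; }
        if (!ok) continue;
        kmer_hash(w, k, &h, &f);
        bool coll;
        long long s = idx->lookup_hash(h, &coll);
        if (s >= 0) {
          contig.push_back((int)idx->contig[s] + 1);
          coord.push_back((int)idx->pos[s]);
          fwd.push_back((idx->strand[s] != 0) == f);
          roff.push_back(i);
          ++stored;
        }
      }
    }
  }
  return List::create(_["contig_id"] = wrap(contig), _["coordinate"] = wrap(coord),
                      _["forward"] = wrap(fwd), _["read_offset"] = wrap(roff));
}

// Window scoring: hits grouped by (contig, strand); inferred read start per
// hit; score = max hits within any window of width read_len.  Windows tying
// at distinct genomic locations mark the read ambiguous.
// [[Rcpp::export(name = ".cpp_score_read")]]
List cpp_score_read(IntegerVector contig, LogicalVector forward,
                    IntegerVector coordinate, IntegerVector read_offset,
                    int k, int read_len) {
  int n = contig.size();
  if (n == 0)
    return List::create(_["score"] = 0, _["ambiguous"] = false,
                        _["contig_id"] = NA_INTEGER,
                        _["strand"] = CharacterVector::create(NA_STRING),
                        _["start"] = NA_INTEGER, _["rep_offset"] = NA_INTEGER,
                        _["rep_coordinate"] = NA_INTEGER);
  std::vector<long long> start(n);
  for (int i = 0; i < n; ++i)
    start[i] = forward[i] ? (long long)coordinate[i] - read_offset[i]
                          : (long long)coordinate[i] + read_offset[i] + k - read_len;
  // anchored windows: left edge at each hit's start
  int best = 0;
  std::vector<int> cnt(n, 0);
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = 0; j < n; ++j)
      if (contig[j] == contig[i] && forward[j] == forward[i] &&
          start[j] >= start[i] && start[j] < start[i] + read_len)
        ++c;
    cnt[i] = c;
    if (c > best) best = c;
  }
  // cluster maximal anchors into genomic locations
  std::vector<int> anchors;
  for (int i = 0; i < n; ++i) if (cnt[i] == best) anchors.push_back(i);
  std::sort(anchors.begin(), anchors.end(), [&](int a, int b) {
    if (contig[a] != contig[b]) return contig[a] < contig[b];
    if (forward[a] != forward[b]) return (int)forward[a] < (int)forward[b];
    return start[a] < start[b];
  });
  int n_loc = 1;
  for (size_t i = 1; i < anchors.size(); ++i) {
    int a = anchors[i - 1], b = anchors[i];
    bool same = contig[a] == contig[b] && forward[a] == forward[b] &&
                start[b] - start[a] < read_len;
    if (!same) ++n_loc;
  }
  bool ambiguous = n_loc > 1;
  // winning window: maximal anchor with smallest (contig, strand, start);
  // representative hit: smallest read_offset inside that window
  int w = anchors[0];
  int rep = -1;
  for (int j = 0; j < n; ++j) {
    if (contig[j] == contig[w] && forward[j] == forward[w] &&
        start[j] >= start[w] && start[j] < start[w] + read_len) {
      if (rep < 0 || read_offset[j] < read_offset[rep]) rep = j;
    }
  }
  return List::create(
      _["score"] = best, _["ambiguous"] = ambiguous,
      _["contig_id"] = contig[w],
      _["strand"] = forward[w] ? "+" : "-",
      _["start"] = (int)start[rep], _["rep_offset"] = read_offset[rep],
      _["rep_coordinate"] = coordinate[rep]);
}

// ---------------------------------------------------------------------------
// False-positive experiment: query n uniformly random k-mers (own xorshift
// RNG, independent of R's) and count fingerprint false positives among the
// truly absent ones.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_fp_experiment")]]
List cpp_fp_experiment(SEXP xp, double n, int seed) {
  XPtr<KmerIndex> idx(xp);
  int k = idx->k;
  if (k > 32) stop("false-positive experiment supports k <= 32 only");
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t s0 = splitmix64((uint64_t)(uint32_t)seed);
  uint64_t s1 = splitmix64(s0);
  double n_present = 0, n_absent = 0, n_fp = 0;
  long long nn = (long long)n;
  for (long long i = 0; i < nn; ++i) {
    // xorshift128+
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    uint64_t r = (s1 + y) & mask;
    uint64_t rc = revcomp_packed(r, k);
    uint64_t h = splitmix64(r < rc ? r : rc);
    if (idx->slot_of.count(h)) {
      n_present += 1;
    } else {
      n_absent += 1;
      uint64_t s = absent_slot(h, idx->n());
      if (fingerprint16(h) == idx->fps[s]) n_fp += 1;
    }
  }
  return List::create(_["n_queries"] = n, _["n_present"] = n_present,
                      _["n_absent"] = n_absent, _["n_false_positive"] = n_fp);
}

// ---------------------------------------------------------------------------
// Binary persistence with a versioned header
// ---------------------------------------------------------------------------

static const char MAGIC[8] = {'K', 'M', 'L', 'I', 'D', 'X', '0', '1'};

// [[Rcpp::export(name = ".cpp_save_index")]]
void cpp_save_index(SEXP xp, std::string path) {
  XPtr<KmerIndex> idx(xp);
  std::ofstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  f.write(MAGIC, 8);
  int32_t k = idx->k, fb = idx->fp_bits;
  uint64_t n = idx->n(), nc = idx->contig_names.size();
  f.write((char*)&k, 4);
  f.write((char*)&fb, 4);
  f.write((char*)&n, 8);
  f.write((char*)&nc, 8);
  for (size_t i = 0; i < nc; ++i) {
    uint32_t ln = (uint32_t)idx->contig_names[i].size();
    f.write((char*)&ln, 4);
    f.write(idx->contig_names[i].c_str(), ln);
    f.write((char*)&idx->contig_lengths[i], 4);
  }
  f.write((char*)idx->keys.data(), 8 * n);
  f.write((char*)idx->fps.data(), 2 * n);
  f.write((char*)idx->contig.data(), 4 * n);
  f.write((char*)idx->pos.data(), 4 * n);
  f.write((char*)idx->strand.data(), 1 * n);
  if (!f) stop("write to '%s' failed", path.c_str());
}

// [[Rcpp::export(name = ".cpp_load_index")]]
SEXP cpp_load_index(std::string path) {
  std::ifstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s'", path.c_str());
  char magic[8];
  f.read(magic, 8);
  if (!f || std::memcmp(magic, MAGIC, 8) != 0)
    stop("'%s' is not a k-mer index file (bad magic)", path.c_str());
  XPtr<KmerIndex> idx(new KmerIndex(), true);
  int32_t k, fb;
  uint64_t n, nc;
  f.read((char*)&k, 4);
  f.read((char*)&fb, 4);
  f.read((char*)&n, 8);
  f.read((char*)&nc, 8);
  idx->k = k;
  idx->fp_bits = fb;
  idx->contig_names.resize(nc);
  idx->contig_lengths.resize(nc);
  for (size_t i = 0; i < nc; ++i) {
    uint32_t ln;
    f.read((char*)&ln, 4);
    std::string nm(ln, ' ');
    f.read(&nm[0], ln);
    idx->contig_names[i] = nm;
    f.read((char*)&idx->contig_lengths[i], 4);
  }
  idx->keys.resize(n);
  idx->fps.resize(n);
  idx->contig.resize(n);
  idx->pos.resize(n);
  idx->strand.resize(n);
  f.read((char*)idx->keys.data(), 8 * n);
  f.read((char*)idx->fps.data(), 2 * n);
  f.read((char*)idx->contig.data(), 4 * n);
  f.read((char*)idx->pos.data(), 4 * n);
  f.read((char*)idx->strand.data(), 1 * n);
  if (!f) stop("'%s' is truncated", path.c_str());
  idx->finalise_slots();
  return idx;
}
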