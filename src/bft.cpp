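// Bloom Filter Trie core: 2-bit DNA codec, Bloom filters with
// restricted-domain hashing, compressed/uncompressed vertex containers,
// the trie itself (lookup, insertion with false-positive recycling,
// bursting), per-k-mer color sets with lossless compression, implicit-edge
// graph traversal, and binary serialization.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <fstream>
#include <map>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 2-bit DNA codec
// ---------------------------------------------------------------------------

static inline int base_code(char ch) {
  switch (ch) {
    case 'a': case 'A': return 0;
    case 'c': case 'C': return 1;
    case 'g': case 'G': return 2;
    case 't': case 'T': return 3;
    default: return -1;
  }
}

static inline char code_base(int c) { return "acgt"[c & 3]; }

static std::string dna_lower(const std::string& s, const char* what) {
  std::string out(s);
  for (size_t i = 0; i < out.size(); ++i) {
    int c = base_code(out[i]);
    if (c < 0)
      stop("invalid DNA character at position %d of %s", (int)(i + 1), what);
    out[i] = code_base(c);
  }
  return out;
}

// 1-based integer value of the concatenated 2-bit codes (first char most
// significant), so "gt" -> 1011b = 11 -> 12.
static int prefix_value(const std::string& a) {
  if (a.empty()) stop("prefix must be non-empty");
  if (a.size() > 14) stop("prefix longer than 14 characters not supported");
  int v = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int c = base_code(a[i]);
    if (c < 0) stop("invalid DNA character at position %d of prefix", (int)(i + 1));
    v = (v << 2) | c;
  }
  return v + 1;
}

static std::string decode_prefix(int alpha, int la) {
  int v = alpha - 1;
  std::string out(la, 'a');
  for (int i = la - 1; i >= 0; --i) { out[i] = code_base(v & 3); v >>= 2; }
  return out;
}

// ---------------------------------------------------------------------------
// Bit array helpers (1-based positions, packed in 64-bit words)
// ---------------------------------------------------------------------------

static inline void bit_set(std::vector<uint64_t>& w, int pos) {
  w[(pos - 1) >> 6] |= 1ULL << ((pos - 1) & 63);
}
static inline bool bit_get(const std::vector<uint64_t>& w, int pos) {
  return (w[(pos - 1) >> 6] >> ((pos - 1) & 63)) & 1ULL;
}

// popcount of the first `alpha` bits (word-wise)
static int popcount_prefix(const std::vector<uint64_t>& w, int alpha) {
  int full = alpha >> 6, rem = alpha & 63, n = 0;
  for (int i = 0; i < full; ++i) n += __builtin_popcountll(w[i]);
  if (rem) n += __builtin_popcountll(w[full] & ((1ULL << rem) - 1));
  return n;
}

static int next_set_bit(const std::vector<uint64_t>& w, int from, int nbits) {
  for (int p = from; p <= nbits; ++p) if (bit_get(w, p)) return p;
  return nbits + 1;
}

// ---------------------------------------------------------------------------
// Hashing (deterministic, seeded; double hashing h_A + i*h_B mod m)
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// hash of the 2-bit-packed substring s[from..to) (0-based, half-open)
static uint64_t dna_hash(const std::string& s, int from, int to, uint64_t seed) {
  uint64_t h = splitmix64(seed);
  uint64_t acc = 0;
  int nb = 0;
  for (int i = from; i < to; ++i) {
    acc = (acc << 2) | (uint64_t)base_code(s[i]);
    if (++nb == 32) { h = splitmix64(h ^ acc); acc = 0; nb = 0; }
  }
  return splitmix64(h ^ acc ^ ((uint64_t)(to - from) << 56));
}

// ---------------------------------------------------------------------------
// Bloom filter
// ---------------------------------------------------------------------------

struct Bloom {
  int m = 256;
  int f = 1;
  uint64_t seed = 1;
  bool restricted = false;  // hash only positions 2..l-1 of the input
  std::vector<uint64_t> bits;

  void init() { bits.assign((size_t)((m + 63) / 64), 0ULL); }

  void positions(const std::string& e, std::vector<int>& out) const {
    int from = 0, to = (int)e.size();
    if (restricted) { from = 1; to = (int)e.size() - 1; }
    uint64_t hA = dna_hash(e, from, to, seed);
    uint64_t hB = dna_hash(e, from, to, seed ^ 0x5bd1e9955bd1e995ULL) | 1ULL;
    out.clear();
    for (int i = 0; i < f; ++i)
      out.push_back((int)((hA + (uint64_t)i * hB) % (uint64_t)m) + 1);
  }
  void insert(const std::string& e) {
    std::vector<int> p;
    positions(e, p);
    for (int x : p) bit_set(bits, x);
  }
  bool may_contain(const std::string& e) const {
    std::vector<int> p;
    positions(e, p);
    for (int x : p) if (!bit_get(bits, x)) return false;
    return true;
  }
};

static int default_f(int m, int c) {
  int f = (int)std::lround(0.6931471805599453 * (double)m / (double)c);
  if (f < 1) f = 1;
  if (f > 4) f = 4;
  return f;
}

// ---------------------------------------------------------------------------
// Containers
// ---------------------------------------------------------------------------

struct ContainsRes { bool found; int cluster; int pos; };

// Compressed container: quartet (quer, pref, suf, clust) plus links that are
// child vertex ids (internal) or color slot ids (terminal / maximal depth).
struct CComp {
  Bloom quer;
  int l = 4;
  int la = 2;               // |a| in characters; |b| = l - la
  bool terminal = false;
  std::vector<uint64_t> pref;   // 2^(2*la) bits
  std::vector<std::string> suf; // q suffix parts b
  std::vector<uint8_t> clust;   // q cluster-start bits
  std::vector<int> link;        // parallel to suf

  int lb() const { return l - la; }
  int q() const { return (int)suf.size(); }
  int pref_bits() const { return 1 << (2 * la); }
  void init_pref() { pref.assign((size_t)((pref_bits() + 63) / 64), 0ULL); }
  long footprint_bits() const {
    return (long)quer.m + (long)pref_bits() + (long)q() * (2L * lb() + 1);
  }
};

static int rank_impl(int i, const std::vector<uint8_t>& clust) {
  int seen = 0;
  for (size_t p = 0; p < clust.size(); ++p)
    if (clust[p] && ++seen == i) return (int)p + 1;
  return (int)clust.size() + 1;
}

// Exact membership of a (stored-form) suffix prefix: pref bit, Hamming
// weight -> cluster index, Rank -> cluster start, linear scan of the cluster.
static ContainsRes cc_contains_impl(const CComp& cc, const std::string& sp) {
  std::string a = sp.substr(0, cc.la), b = sp.substr(cc.la);
  int alpha = prefix_value(a);
  if (!bit_get(cc.pref, alpha)) {
    int i = popcount_prefix(cc.pref, alpha) + 1;  // would-be cluster index
    return ContainsRes{false, i, rank_impl(i, cc.clust)};
  }
  int i = popcount_prefix(cc.pref, alpha);
  int start = rank_impl(i, cc.clust);
  int j = start;
  while (j <= cc.q() && (j == start || cc.clust[j - 1] == 0)) {
    if (cc.suf[j - 1] == b) return ContainsRes{true, i, j};
    if (cc.suf[j - 1] > b) return ContainsRes{false, i, j};
    ++j;
  }
  return ContainsRes{false, i, j};
}

// Insert a (stored-form) suffix prefix; quer is deliberately untouched
// (false-positive recycling; bursts call quer.insert separately).
static std::pair<int, int> cc_insert_impl(CComp& cc, const std::string& sp, int link) {
  std::string a = sp.substr(0, cc.la), b = sp.substr(cc.la);
  int alpha = prefix_value(a);
  int i, pos;
  if (!bit_get(cc.pref, alpha)) {
    bit_set(cc.pref, alpha);
    i = popcount_prefix(cc.pref, alpha);
    pos = rank_impl(i, cc.clust);
    cc.suf.insert(cc.suf.begin() + (pos - 1), b);
    cc.clust.insert(cc.clust.begin() + (pos - 1), 1);
    cc.link.insert(cc.link.begin() + (pos - 1), link);
  } else {
    ContainsRes r = cc_contains_impl(cc, sp);
    if (r.found) stop("duplicate suffix prefix insertion into compressed container");
    i = r.cluster;
    pos = r.pos;
    int start = rank_impl(i, cc.clust);
    cc.suf.insert(cc.suf.begin() + (pos - 1), b);
    if (pos == start) {
      // b becomes the new cluster head; the old head shifts one right
      cc.clust.insert(cc.clust.begin() + (pos - 1), 1);
      cc.clust[pos] = 0;
    } else {
      cc.clust.insert(cc.clust.begin() + (pos - 1), 0);
    }
    cc.link.insert(cc.link.begin() + (pos - 1), link);
  }
  return std::make_pair(i, pos);
}

// Reconstruct the stored suffix prefixes (in array order).
static std::vector<std::string> cc_strings_impl(const CComp& cc) {
  std::vector<std::string> out;
  out.reserve(cc.q());
  int a_pos = 0;
  for (int j = 1; j <= cc.q(); ++j) {
    if (cc.clust[j - 1]) a_pos = next_set_bit(cc.pref, a_pos + 1, cc.pref_bits());
    out.push_back(decode_prefix(a_pos, cc.la) + cc.suf[j - 1]);
  }
  return out;
}

// Recompute (pref, suf, clust) under larger |a| / smaller |b| while
// 2^lambda' + q*mu' < 2^lambda + q*mu and |b| >= 2 hold. No-op otherwise.
static bool cc_resize_impl(CComp& cc) {
  bool changed = false;
  for (;;) {
    int q = cc.q();
    if (cc.la + 1 > cc.l - 2) break;       // minimum suffix length of two
    long lam = 2L * cc.la, lam2 = lam + 2;
    if (lam2 > 28) break;
    if ((1L << lam2) - (1L << lam) >= 2L * q) break;  // strict decrease required
    std::vector<std::string> full = cc_strings_impl(cc);
    std::vector<int> links = cc.link;
    cc.la += 1;
    cc.init_pref();
    cc.suf.clear();
    cc.clust.clear();
    cc.link.clear();
    for (int j = 0; j < (int)full.size(); ++j) cc_insert_impl(cc, full[j], links[j]);
    changed = true;
  }
  return changed;
}

// Smallest |a| with |b| >= 2 satisfying the burst size bound
// m + 2^lambda <= q*(lambda - 1); fallback |a| = l/2 (capped to keep |b| >= 2).
static int choose_la(int l, int q, int m) {
  for (int la = 1; la <= l - 2; ++la) {
    long lam = 2L * la;
    if (lam > 28) break;
    if ((long)m + (1L << lam) <= (long)q * (lam - 1)) return la;
  }
  int la = l / 2;
  if (la > l - 2) la = l - 2;
  if (la < 1) la = 1;
  return la;
}

// Uncompressed container: sorted (suffix, color slot) tuples.
struct UComp {
  std::vector<std::string> s;
  std::vector<int> col;
};

struct Vertexx {
  std::vector<CComp> cc;
  bool has_uc = false;
  UComp uc;
};

// ---------------------------------------------------------------------------
// Color sets
// ---------------------------------------------------------------------------

struct ColorEntry {
  std::vector<uint64_t> bits;  // inline set (when ext < 0)
  int32_t ext = -1;            // index into the external table (0-based)
};

static void cs_add(std::vector<uint64_t>& bits, int i_color) {
  size_t need = (size_t)((i_color + 63) / 64);
  if (bits.size() < need) bits.resize(need, 0ULL);
  bit_set(bits, i_color);
}

static std::vector<uint64_t> cs_trim(std::vector<uint64_t> w) {
  while (!w.empty() && w.back() == 0ULL) w.pop_back();
  return w;
}

static int cs_width(const std::vector<uint64_t>& w) {
  if (w.empty()) return 0;
  uint64_t top = w.back();
  int hb = 64 - __builtin_clzll(top);
  return (int)(64 * (w.size() - 1)) + hb;
}

static std::vector<int> cs_indices(const std::vector<uint64_t>& w) {
  std::vector<int> out;
  for (int p = 1; p <= (int)(64 * w.size()); ++p)
    if (bit_get(w, p)) out.push_back(p);
  return out;
}

// bit-lexicographic order: first differing bit, 0 before 1
static bool cs_bitlex_less(const std::vector<uint64_t>& a, const std::vector<uint64_t>& b) {
  int wa = cs_width(a), wb = cs_width(b);
  int n = std::max(wa, wb);
  for (int p = 1; p <= n; ++p) {
    bool ba = p <= wa && bit_get(a, p);
    bool bb = p <= wb && bit_get(b, p);
    if (ba != bb) return !ba;
  }
  return false;
}

// stored size of a color set: trimmed width rounded up to whole bytes
static long cs_size_bits(const std::vector<uint64_t>& w) {
  int width = cs_width(w);
  if (width < 1) width = 1;
  return 8L * ((width + 7) / 8);
}

static long index_cost_bits(size_t position_1based) {
  int need = 1;
  while ((1ULL << need) < position_1based + 1) ++need;
  return 8L * ((need + 7) / 8);
}

// ---------------------------------------------------------------------------
// The trie
// ---------------------------------------------------------------------------

struct BFT {
  int k = 12, l = 4, c = 5;
  bool graph_mode = true;
  int m = 256, f = 1;
  uint64_t seed = 1;
  double resize_factor = 8.0;
  long n_kmers = 0;
  int n_colors = 0;
  std::vector<Vertexx> V;
  std::vector<ColorEntry> slots;           // one per stored k-mer
  std::vector<std::vector<uint64_t>> ext_table;
  std::vector<long> ext_cost;              // index cost charged per table entry
  std::vector<std::string> color_names;

  BFT() { V.emplace_back(); }

  std::string stored(const std::string& sp) const {
    if (!graph_mode) return sp;
    return sp.substr(1) + sp[0];           // s'_pref = s_pref[2..l] s_pref[1]
  }
  std::string unstored(const std::string& sp) const {
    if (!graph_mode) return sp;
    return sp.substr(sp.size() - 1) + sp.substr(0, sp.size() - 1);
  }
  void slot_add_color(int slot, int i_color) {
    ColorEntry& e = slots[slot];
    if (e.ext >= 0) {  // copy-on-write out of the external table
      e.bits = ext_table[e.ext];
      e.ext = -1;
    }
    cs_add(e.bits, i_color);
    if (i_color > n_colors) n_colors = i_color;
  }
  const std::vector<uint64_t>& slot_bits(int slot) const {
    const ColorEntry& e = slots[slot];
    return e.ext >= 0 ? ext_table[e.ext] : e.bits;
  }
};

static void bft_burst(BFT& t, int v);

static void uc_sorted_insert(BFT& t, int v, const std::string& s, int i_color) {
  Vertexx& vx = t.V[v];
  if (!vx.has_uc) { vx.has_uc = true; vx.uc.s.clear(); vx.uc.col.clear(); }
  UComp& uc = vx.uc;
  std::vector<std::string>::iterator it =
      std::lower_bound(uc.s.begin(), uc.s.end(), s);
  size_t idx = (size_t)(it - uc.s.begin());
  if (it != uc.s.end() && *it == s) {
    t.slot_add_color(uc.col[idx], i_color);
    return;
  }
  int slot = (int)t.slots.size();
  t.slots.emplace_back();
  t.slot_add_color(slot, i_color);
  uc.s.insert(it, s);
  uc.col.insert(uc.col.begin() + idx, slot);
  t.n_kmers += 1;
  if ((int)uc.s.size() > t.c) bft_burst(t, v);
}

static void maybe_resize(BFT& t, CComp& cc) {
  if ((double)cc.q() * (2.0 * cc.lb() + 1.0) >
      t.resize_factor * ((double)cc.quer.m + (double)cc.pref_bits()))
    cc_resize_impl(cc);
}

// Burst: the overflowing uncompressed container (c+1 suffixes) becomes a
// compressed container; suffix remainders move into new child vertices.
static void bft_burst(BFT& t, int v) {
  // move the tuples out before mutating the vertex vector
  std::vector<std::string> ss;
  std::vector<int> cols;
  {
    Vertexx& vx = t.V[v];
    ss.swap(vx.uc.s);
    cols.swap(vx.uc.col);
    vx.has_uc = false;
  }
  int L = (int)ss[0].size();
  bool terminal = (L == t.l);

  // group by stored-form first chunk
  struct Item { std::string key, sp, rest; int col; };
  std::vector<Item> items;
  items.reserve(ss.size());
  for (size_t i = 0; i < ss.size(); ++i) {
    std::string sp = ss[i].substr(0, (size_t)t.l);
    items.push_back(Item{t.stored(sp), sp, ss[i].substr((size_t)t.l), cols[i]});
  }
  std::sort(items.begin(), items.end(),
            [](const Item& a, const Item& b) {
              return a.key != b.key ? a.key < b.key : a.rest < b.rest;
            });
  int q = 0;
  for (size_t i = 0; i < items.size(); ++i)
    if (i == 0 || items[i].key != items[i - 1].key) ++q;

  CComp cc;
  cc.l = t.l;
  cc.la = choose_la(t.l, q, t.m);
  cc.terminal = terminal;
  cc.quer.m = t.m;
  cc.quer.f = t.f;
  cc.quer.seed = t.seed;
  cc.quer.restricted = t.graph_mode;
  cc.quer.init();
  cc.init_pref();

  std::vector<int> children;  // collect first, then attach (vertex vector moves)
  size_t i = 0;
  while (i < items.size()) {
    size_t j = i;
    while (j < items.size() && items[j].key == items[i].key) ++j;
    cc.quer.insert(items[i].sp);
    if (terminal) {
      // at maximal depth each chunk is a full distinct suffix
      cc_insert_impl(cc, items[i].key, items[i].col);
    } else {
      int w = (int)t.V.size();
      t.V.emplace_back();
      Vertexx& child = t.V[w];
      child.has_uc = true;
      for (size_t r = i; r < j; ++r) {
        child.uc.s.push_back(items[r].rest);
        child.uc.col.push_back(items[r].col);
      }
      cc_insert_impl(cc, items[i].key, w);
      children.push_back(w);
    }
    i = j;
  }
  t.V[v].cc.push_back(cc);
  // a child may itself overflow (all c+1 suffixes sharing one chunk)
  for (int w : children)
    if ((int)t.V[w].uc.s.size() > t.c) bft_burst(t, w);
}

// index (1-based) of the first compressed container of v whose quer fires
// for sp (unrotated form); 0 when none fires
static int first_firing(const BFT& t, int v, const std::string& sp) {
  const Vertexx& vx = t.V[v];
  for (size_t i = 0; i < vx.cc.size(); ++i)
    if (vx.cc[i].quer.may_contain(sp)) return (int)i + 1;
  return 0;
}

// walk from vertex v with a k-mer suffix; returns color slot or -1;
// visited counts trie vertices touched (including v)
static int lookup_from(const BFT& t, int v, const std::string& suffix, long* visited) {
  int cur = v;
  size_t pos = 0;
  for (;;) {
    if (visited) *visited += 1;
    std::string suf = suffix.substr(pos);
    std::string sp = suf.substr(0, (size_t)t.l);
    int ci = first_firing(t, cur, sp);
    if (ci > 0) {
      const CComp& cc = t.V[cur].cc[ci - 1];
      ContainsRes r = cc_contains_impl(cc, t.stored(sp));
      if (!r.found) return -1;  // stopping container lacks it => absent
      if (cc.terminal) return suf.size() == (size_t)t.l ? cc.link[r.pos - 1] : -1;
      cur = cc.link[r.pos - 1];
      pos += (size_t)t.l;
      continue;
    }
    const Vertexx& vx = t.V[cur];
    if (vx.has_uc) {
      std::vector<std::string>::const_iterator it =
          std::lower_bound(vx.uc.s.begin(), vx.uc.s.end(), suf);
      if (it != vx.uc.s.end() && *it == suf)
        return vx.uc.col[it - vx.uc.s.begin()];
    }
    return -1;
  }
}

static int bft_find_slot(const BFT& t, const std::string& x) {
  return lookup_from(t, 0, x, nullptr);
}

static void bft_insert_one(BFT& t, const std::string& x, int i_color) {
  int v = 0;
  size_t pos = 0;
  for (;;) {
    std::string suf = x.substr(pos);
    std::string sp = suf.substr(0, (size_t)t.l);
    int ci = first_firing(t, v, sp);
    if (ci > 0) {
      CComp& cc = t.V[v].cc[ci - 1];
      ContainsRes r = cc_contains_impl(cc, t.stored(sp));
      if (r.found) {
        if (cc.terminal) {  // k-mer already stored
          t.slot_add_color(cc.link[r.pos - 1], i_color);
          return;
        }
        v = cc.link[r.pos - 1];
        pos += (size_t)t.l;
        continue;
      }
      // false-positive recycling: insert into the first firing container
      if (cc.terminal) {
        int slot = (int)t.slots.size();
        t.slots.emplace_back();
        t.slot_add_color(slot, i_color);
        cc_insert_impl(cc, t.stored(sp), slot);
        t.n_kmers += 1;
        maybe_resize(t, cc);
        return;
      }
      int w = (int)t.V.size();
      t.V.emplace_back();
      CComp& cc2 = t.V[v].cc[ci - 1];  // re-acquire (vector may have moved)
      cc_insert_impl(cc2, t.stored(sp), w);
      maybe_resize(t, cc2);
      uc_sorted_insert(t, w, suf.substr((size_t)t.l), i_color);
      return;
    }
    uc_sorted_insert(t, v, suf, i_color);
    return;
  }
}

static void check_kmer(const BFT& t, const std::string& x) {
  if ((int)x.size() != t.k)
    stop("k-mer has length %d but the index was built with k = %d",
         (int)x.size(), t.k);
}

// enumerate stored k-mers (and slots) by trie walk
static void bft_enumerate(const BFT& t, int v, std::string prefix,
                          std::vector<std::string>& kmers, std::vector<int>& slots) {
  const Vertexx& vx = t.V[v];
  for (size_t i = 0; i < vx.cc.size(); ++i) {
    const CComp& cc = vx.cc[i];
    std::vector<std::string> sps = cc_strings_impl(cc);
    for (int j = 0; j < cc.q(); ++j) {
      std::string sp = t.unstored(sps[j]);
      if (cc.terminal) {
        kmers.push_back(prefix + sp);
        slots.push_back(cc.link[j]);
      } else {
        bft_enumerate(t, cc.link[j], prefix + sp, kmers, slots);
      }
    }
  }
  if (vx.has_uc)
    for (size_t i = 0; i < vx.uc.s.size(); ++i) {
      kmers.push_back(prefix + vx.uc.s[i]);
      slots.push_back(vx.uc.col[i]);
    }
}

// ---------------------------------------------------------------------------
// XPtr plumbing
// ---------------------------------------------------------------------------

static BFT* get_bft(SEXP xp) {
  XPtr<BFT> p(xp);
  if (!p) stop("invalid (null) BFT pointer; rebuild or reload the index");
  return p.get();
}
static CComp* get_cc(SEXP xp) {
  XPtr<CComp> p(xp);
  if (!p) stop("invalid (null) compressed-container pointer");
  return p.get();
}
static Bloom* get_bloom(SEXP xp) {
  XPtr<Bloom> p(xp);
  if (!p) stop("invalid (null) Bloom filter pointer");
  return p.get();
}

// ---------------------------------------------------------------------------
// Exports: DNA encoding
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector encode_base_cpp(CharacterVector ch) {
  IntegerVector out(ch.size());
  for (R_xlen_t i = 0; i < ch.size(); ++i) {
    std::string s = as<std::string>(ch[i]);
    if (s.size() != 1 || base_code(s[0]) < 0)
      stop("invalid DNA character at position %d", (int)(i + 1));
    out[i] = base_code(s[0]);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector decode_base_cpp(IntegerVector code) {
  CharacterVector out(code.size());
  for (R_xlen_t i = 0; i < code.size(); ++i) {
    if (code[i] < 0 || code[i] > 3) stop("2-bit code must be in 0..3");
    out[i] = std::string(1, code_base(code[i]));
  }
  return out;
}

// [[Rcpp::export]]
int prefix_index_cpp(std::string a) { return prefix_value(dna_lower(a, "prefix")); }

// [[Rcpp::export]]
std::string decode_prefix_cpp(int alpha, int width) {
  if (width < 1 || width > 14) stop("prefix width must be in 1..14");
  if (alpha < 1 || alpha > (1 << (2 * width))) stop("alpha out of range");
  return decode_prefix(alpha, width);
}

// ---------------------------------------------------------------------------
// Exports: Bloom filter
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP bloom_new_cpp(int m, int f, double seed, bool restricted) {
  if (m < 1) stop("Bloom filter length m must be positive");
  if (f < 1) stop("number of hash functions f must be positive");
  Bloom* b = new Bloom();
  b->m = m;
  b->f = f;
  b->seed = (uint64_t)seed;
  b->restricted = restricted;
  b->init();
  XPtr<Bloom> xp(b, true);
  xp.attr("class") = "bloom_filter";
  return xp;
}

// [[Rcpp::export]]
void bloom_insert_cpp(SEXP xp, std::string e) {
  get_bloom(xp)->insert(dna_lower(e, "element"));
}

// [[Rcpp::export]]
bool bloom_may_contain_cpp(SEXP xp, std::string e) {
  return get_bloom(xp)->may_contain(dna_lower(e, "element"));
}

// [[Rcpp::export]]
IntegerVector bloom_positions_cpp(SEXP xp, std::string e) {
  std::vector<int> p;
  get_bloom(xp)->positions(dna_lower(e, "element"), p);
  return wrap(p);
}

// [[Rcpp::export]]
IntegerVector bloom_set_bits_cpp(SEXP xp) {
  Bloom* b = get_bloom(xp);
  std::vector<int> out;
  for (int p = 1; p <= b->m; ++p) if (bit_get(b->bits, p)) out.push_back(p);
  return wrap(out);
}

// [[Rcpp::export]]
List bloom_params_cpp(SEXP xp) {
  Bloom* b = get_bloom(xp);
  return List::create(_["m"] = b->m, _["f"] = b->f,
                      _["seed"] = (double)b->seed,
                      _["restricted"] = b->restricted);
}

// ---------------------------------------------------------------------------
// Exports: container helpers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int hamming_weight_cpp(int alpha, LogicalVector pref) {
  if (alpha < 1 || alpha > pref.size())
    stop("alpha must be in 1..%d", (int)pref.size());
  int n = 0;
  for (int i = 0; i < alpha; ++i) if (pref[i] == TRUE) ++n;
  return n;
}

// [[Rcpp::export]]
int rank_cluster_cpp(int i, LogicalVector clust) {
  if (i < 1) stop("cluster index must be >= 1");
  std::vector<uint8_t> c(clust.size());
  for (R_xlen_t j = 0; j < clust.size(); ++j) c[j] = clust[j] == TRUE ? 1 : 0;
  return rank_impl(i, c);
}

// [[Rcpp::export]]
List uc_binary_search_cpp(CharacterVector sorted_suffixes, std::string s) {
  std::vector<std::string> v(sorted_suffixes.size());
  for (R_xlen_t i = 0; i < sorted_suffixes.size(); ++i)
    v[i] = as<std::string>(sorted_suffixes[i]);
  if (!v.empty() && v[0].size() != s.size())
    stop("suffix has length %d but container stores suffixes of length %d",
         (int)s.size(), (int)v[0].size());
  std::vector<std::string>::iterator it = std::lower_bound(v.begin(), v.end(), s);
  bool found = it != v.end() && *it == s;
  return List::create(_["found"] = found,
                      _["pos"] = (int)(it - v.begin()) + 1);
}

// ---------------------------------------------------------------------------
// Exports: standalone compressed container (testing / worked-example surface)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cc_new_cpp(int l, int prefix_len, int m, int f, double seed, bool restricted) {
  if (l < 3) stop("chunk length l must be >= 3");
  if (prefix_len < 1 || prefix_len > l - 2)
    stop("prefix length |a| must leave a suffix of at least two characters");
  CComp* cc = new CComp();
  cc->l = l;
  cc->la = prefix_len;
  cc->quer.m = m;
  cc->quer.f = f;
  cc->quer.seed = (uint64_t)seed;
  cc->quer.restricted = restricted;
  cc->quer.init();
  cc->init_pref();
  XPtr<CComp> xp(cc, true);
  xp.attr("class") = "bft_cc";
  return xp;
}

// [[Rcpp::export]]
List cc_contains_cpp(SEXP xp, std::string s_pref) {
  CComp* cc = get_cc(xp);
  std::string sp = dna_lower(s_pref, "suffix prefix");
  if ((int)sp.size() != cc->l)
    stop("suffix prefix must have length %d", cc->l);
  ContainsRes r = cc_contains_impl(*cc, sp);
  return List::create(_["found"] = r.found, _["cluster"] = r.cluster,
                      _["pos"] = r.pos);
}

// [[Rcpp::export]]
List cc_insert_cpp(SEXP xp, std::string s_pref) {
  CComp* cc = get_cc(xp);
  std::string sp = dna_lower(s_pref, "suffix prefix");
  if ((int)sp.size() != cc->l)
    stop("suffix prefix must have length %d", cc->l);
  cc->quer.insert(sp);
  std::pair<int, int> r = cc_insert_impl(*cc, sp, cc->q());
  return List::create(_["cluster"] = r.first, _["pos"] = r.second);
}

// [[Rcpp::export]]
List cc_inspect_cpp(SEXP xp) {
  CComp* cc = get_cc(xp);
  std::vector<int> prefset;
  for (int p = 1; p <= cc->pref_bits(); ++p)
    if (bit_get(cc->pref, p)) prefset.push_back(p);
  IntegerVector clust(cc->q());
  for (int j = 0; j < cc->q(); ++j) clust[j] = cc->clust[j];
  return List::create(
      _["q"] = cc->q(), _["prefix_len"] = cc->la, _["suffix_len"] = cc->lb(),
      _["pref_set"] = wrap(prefset), _["suf"] = wrap(cc->suf),
      _["clust"] = clust, _["terminal"] = cc->terminal,
      _["footprint_bits"] = (double)cc->footprint_bits(),
      _["m"] = cc->quer.m, _["f"] = cc->quer.f);
}

// [[Rcpp::export]]
CharacterVector cc_strings_cpp(SEXP xp) {
  return wrap(cc_strings_impl(*get_cc(xp)));
}

// [[Rcpp::export]]
bool cc_resize_cpp(SEXP xp) { return cc_resize_impl(*get_cc(xp)); }

// ---------------------------------------------------------------------------
// Exports: trie
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP bft_new_cpp(int k, int l, int capacity, bool graph_mode, int bf_bits,
                 int bf_hashes, double seed, double resize_factor) {
  if (l < 3) stop("chunk length l must be >= 3");
  if (k < l || k % l != 0) stop("k (%d) must be a positive multiple of l (%d)", k, l);
  if (capacity < 1) stop("capacity c must be positive");
  if (bf_bits < 8) stop("Bloom filter size must be at least 8 bits");
  BFT* t = new BFT();
  t->k = k;
  t->l = l;
  t->c = capacity;
  t->graph_mode = graph_mode;
  t->m = bf_bits;
  t->f = bf_hashes > 0 ? std::min(bf_hashes, 4) : default_f(bf_bits, capacity);
  t->seed = (uint64_t)seed;
  t->resize_factor = resize_factor;
  XPtr<BFT> xp(t, true);
  xp.attr("class") = "bft_ptr";
  return xp;
}

// [[Rcpp::export]]
void bft_insert_cpp(SEXP xp, CharacterVector kmers, IntegerVector colors) {
  BFT* t = get_bft(xp);
  if (colors.size() != 1 && colors.size() != kmers.size())
    stop("colors must have length 1 or length(kmers)");
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string x = dna_lower(as<std::string>(kmers[i]), "k-mer");
    check_kmer(*t, x);
    int col = colors.size() == 1 ? colors[0] : colors[i];
    if (col < 1) stop("color indices must be >= 1");
    bft_insert_one(*t, x, col);
  }
}

// [[Rcpp::export]]
LogicalVector bft_contains_cpp(SEXP xp, CharacterVector kmers) {
  BFT* t = get_bft(xp);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string x = dna_lower(as<std::string>(kmers[i]), "k-mer");
    check_kmer(*t, x);
    out[i] = bft_find_slot(*t, x) >= 0;
  }
  return out;
}

// [[Rcpp::export]]
List bft_colors_cpp(SEXP xp, CharacterVector kmers) {
  BFT* t = get_bft(xp);
  List out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string x = dna_lower(as<std::string>(kmers[i]), "k-mer");
    check_kmer(*t, x);
    int slot = bft_find_slot(*t, x);
    if (slot < 0) out[i] = IntegerVector(0);
    else out[i] = wrap(cs_indices(t->slot_bits(slot)));
  }
  return out;
}

// [[Rcpp::export]]
List bft_info_cpp(SEXP xp) {
  BFT* t = get_bft(xp);
  long n_cc = 0, n_uc = 0, max_uc = 0;
  double cc_bits = 0, uc_bits = 0, color_bits = 0;
  for (size_t v = 0; v < t->V.size(); ++v) {
    n_cc += (long)t->V[v].cc.size();
    for (size_t i = 0; i < t->V[v].cc.size(); ++i)
      cc_bits += (double)t->V[v].cc[i].footprint_bits();
    if (t->V[v].has_uc) {
      n_uc += 1;
      if ((long)t->V[v].uc.s.size() > max_uc) max_uc = (long)t->V[v].uc.s.size();
      for (size_t i = 0; i < t->V[v].uc.s.size(); ++i)
        uc_bits += 2.0 * (double)t->V[v].uc.s[i].size();
    }
  }
  for (size_t i = 0; i < t->slots.size(); ++i) {
    const ColorEntry& e = t->slots[i];
    color_bits += e.ext >= 0 ? (double)t->ext_cost[e.ext]
                             : (double)cs_size_bits(e.bits);
  }
  for (size_t i = 0; i < t->ext_table.size(); ++i)
    color_bits += (double)cs_size_bits(t->ext_table[i]);
  return List::create(
      _["k"] = t->k, _["l"] = t->l, _["capacity"] = t->c,
      _["graph_mode"] = t->graph_mode, _["bf_bits"] = t->m,
      _["bf_hashes"] = t->f, _["seed"] = (double)t->seed,
      _["n_kmers"] = (double)t->n_kmers, _["n_colors"] = t->n_colors,
      _["n_vertices"] = (double)t->V.size(),
      _["n_compressed"] = (double)n_cc, _["n_uncompressed"] = (double)n_uc,
      _["max_uc_load"] = (double)max_uc,
      _["n_external_color_sets"] = (double)t->ext_table.size(),
      _["container_bits"] = cc_bits + uc_bits, _["color_bits"] = color_bits);
}

// [[Rcpp::export]]
List bft_root_structure_cpp(SEXP xp) {
  BFT* t = get_bft(xp);
  const Vertexx& root = t->V[0];
  List out;
  for (size_t i = 0; i < root.cc.size(); ++i) {
    const CComp& cc = root.cc[i];
    out.push_back(List::create(
        _["type"] = "compressed", _["q"] = cc.q(), _["prefix_len"] = cc.la,
        _["suffix_len"] = cc.lb(), _["terminal"] = cc.terminal,
        _["footprint_bits"] = (double)cc.footprint_bits()));
  }
  if (root.has_uc)
    out.push_back(List::create(_["type"] = "uncompressed",
                               _["n"] = (int)root.uc.s.size()));
  return out;
}

// [[Rcpp::export]]
SEXP bft_root_container_cpp(SEXP xp, int i) {
  BFT* t = get_bft(xp);
  if (i < 1 || i > (int)t->V[0].cc.size())
    stop("the root has %d compressed container(s)", (int)t->V[0].cc.size());
  CComp* copy = new CComp(t->V[0].cc[i - 1]);
  XPtr<CComp> out(copy, true);
  out.attr("class") = "bft_cc";
  return out;
}

// [[Rcpp::export]]
int bft_stop_container_cpp(SEXP xp, std::string s_pref) {
  BFT* t = get_bft(xp);
  std::string sp = dna_lower(s_pref, "suffix prefix");
  if ((int)sp.size() != t->l) stop("suffix prefix must have length %d", t->l);
  return first_firing(*t, 0, sp);
}

// [[Rcpp::export]]
List bft_dump_cpp(SEXP xp) {
  BFT* t = get_bft(xp);
  std::vector<std::string> kmers;
  std::vector<int> slots;
  bft_enumerate(*t, 0, "", kmers, slots);
  List colors(kmers.size());
  for (size_t i = 0; i < kmers.size(); ++i)
    colors[i] = wrap(cs_indices(t->slot_bits(slots[i])));
  return List::create(_["kmer"] = wrap(kmers), _["colors"] = colors);
}

// ---------------------------------------------------------------------------
// Exports: color compression
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List bft_compress_colors_cpp(SEXP xp) {
  BFT* t = get_bft(xp);
  // materialize all sets inline, then rebuild the table from scratch
  for (size_t i = 0; i < t->slots.size(); ++i) {
    ColorEntry& e = t->slots[i];
    if (e.ext >= 0) { e.bits = t->ext_table[e.ext]; e.ext = -1; }
    e.bits = cs_trim(e.bits);
  }
  t->ext_table.clear();
  t->ext_cost.clear();

  std::map<std::vector<uint64_t>, long> census;
  for (size_t i = 0; i < t->slots.size(); ++i) census[t->slots[i].bits] += 1;

  struct Entry { std::vector<uint64_t> bits; long count; long size; };
  std::vector<Entry> entries;
  entries.reserve(census.size());
  double bits_before = 0;
  for (std::map<std::vector<uint64_t>, long>::iterator it = census.begin();
       it != census.end(); ++it) {
    long size = cs_size_bits(it->first);
    entries.push_back(Entry{it->first, it->second, size});
    bits_before += (double)it->second * (double)size;
  }
  // decreasing total size (count x size); ties: bit-lexicographically smaller first
  std::sort(entries.begin(), entries.end(), [](const Entry& a, const Entry& b) {
    long ta = a.count * a.size, tb = b.count * b.size;
    if (ta != tb) return ta > tb;
    return cs_bitlex_less(a.bits, b.bits);
  });

  std::map<std::vector<uint64_t>, int> placed;
  for (size_t i = 0; i < entries.size(); ++i) {
    size_t p = t->ext_table.size() + 1;
    long cost = index_cost_bits(p);
    // paper's rule (index cheaper than the set) plus a net-saving guard so the
    // one-time table copy can never increase the total footprint
    if (cost < entries[i].size &&
        entries[i].size + entries[i].count * cost <= entries[i].count * entries[i].size) {
      placed[entries[i].bits] = (int)t->ext_table.size();
      t->ext_table.push_back(entries[i].bits);
      t->ext_cost.push_back(cost);
    }
  }
  long n_replaced = 0;
  for (size_t i = 0; i < t->slots.size(); ++i) {
    std::map<std::vector<uint64_t>, int>::iterator hit = placed.find(t->slots[i].bits);
    if (hit != placed.end()) {
      t->slots[i].ext = hit->second;
      t->slots[i].bits.clear();
      n_replaced += 1;
    }
  }
  double bits_after = 0;
  for (size_t i = 0; i < t->ext_table.size(); ++i)
    bits_after += (double)cs_size_bits(t->ext_table[i]);
  for (size_t i = 0; i < t->slots.size(); ++i)
    bits_after += t->slots[i].ext >= 0
                      ? (double)t->ext_cost[t->slots[i].ext]
                      : (double)cs_size_bits(t->slots[i].bits);
  return List::create(
      _["n_distinct"] = (double)entries.size(),
      _["n_external"] = (double)t->ext_table.size(),
      _["n_replaced"] = (double)n_replaced,
      _["bits_before"] = bits_before, _["bits_after"] = bits_after);
}

// ---------------------------------------------------------------------------
// Exports: graph traversal
// ---------------------------------------------------------------------------

static List neighborhood_result(const BFT& t, const std::vector<std::string>& kmers,
                                const std::vector<int>& slots, long visited) {
  List colors(kmers.size());
  for (size_t i = 0; i < kmers.size(); ++i)
    colors[i] = wrap(cs_indices(t.slot_bits(slots[i])));
  return List::create(_["kmers"] = wrap(kmers), _["colors"] = colors,
                      _["visited"] = (double)visited);
}

// [[Rcpp::export]]
List bft_successors_cpp(SEXP xp, std::string x) {
  BFT* t = get_bft(xp);
  if (!t->graph_mode)
    stop("graph traversal requires an index built with graph_mode = TRUE");
  std::string xs = dna_lower(x, "k-mer");
  check_kmer(*t, xs);
  std::string core = xs.substr(1);  // x[2..k], shared by all successors
  std::vector<std::string> kmers;
  std::vector<int> slots;
  int v = 0;
  size_t pos = 0;
  long visited = 1;
  for (;;) {
    size_t remlen = core.size() - pos;
    if (remlen >= (size_t)t->l) {
      // chunk fully determined by x: single shared path
      std::string sp = core.substr(pos, (size_t)t->l);
      int ci = first_firing(*t, v, sp);
      if (ci > 0) {
        const CComp& cc = t->V[v].cc[ci - 1];
        ContainsRes r = cc_contains_impl(cc, t->stored(sp));
        if (!r.found) break;
        v = cc.link[r.pos - 1];
        pos += (size_t)t->l;
        visited += 1;
        continue;
      }
      const Vertexx& vx = t->V[v];
      if (vx.has_uc) {
        for (int b = 0; b < 4; ++b) {
          std::string cand = core.substr(pos) + code_base(b);
          std::vector<std::string>::const_iterator it =
              std::lower_bound(vx.uc.s.begin(), vx.uc.s.end(), cand);
          if (it != vx.uc.s.end() && *it == cand) {
            kmers.push_back(core + code_base(b));
            slots.push_back(vx.uc.col[it - vx.uc.s.begin()]);
          }
        }
      }
      break;
    }
    // terminal chunk: the four candidates differ only in their last
    // character; restricted hashing makes them fire the same containers
    std::string probe = core.substr(pos) + 'a';
    int ci = first_firing(*t, v, probe);
    if (ci > 0) {
      const CComp& cc = t->V[v].cc[ci - 1];
      for (int b = 0; b < 4; ++b) {
        std::string sp = core.substr(pos) + code_base(b);
        ContainsRes r = cc_contains_impl(cc, t->stored(sp));
        if (r.found) {
          kmers.push_back(core + code_base(b));
          slots.push_back(cc.link[r.pos - 1]);
        }
      }
    } else if (t->V[v].has_uc) {
      const Vertexx& vx = t->V[v];
      for (int b = 0; b < 4; ++b) {
        std::string cand = core.substr(pos) + code_base(b);
        std::vector<std::string>::const_iterator it =
            std::lower_bound(vx.uc.s.begin(), vx.uc.s.end(), cand);
        if (it != vx.uc.s.end() && *it == cand) {
          kmers.push_back(core + code_base(b));
          slots.push_back(vx.uc.col[it - vx.uc.s.begin()]);
        }
      }
    }
    break;
  }
  return neighborhood_result(*t, kmers, slots, visited);
}

// [[Rcpp::export]]
List bft_predecessors_cpp(SEXP xp, std::string x) {
  BFT* t = get_bft(xp);
  if (!t->graph_mode)
    stop("graph traversal requires an index built with graph_mode = TRUE");
  std::string xs = dna_lower(x, "k-mer");
  check_kmer(*t, xs);
  std::string core = xs.substr(0, xs.size() - 1);  // x[1..k-1]
  std::vector<std::string> kmers;
  std::vector<int> slots;
  long visited = 1;
  // first chunks c + x[1..l-1] share the hashed middle x[1..l-2]
  std::string probe = std::string(1, 'a') + core.substr(0, (size_t)(t->l - 1));
  int ci = first_firing(*t, 0, probe);
  if (ci > 0) {
    const CComp& cc = t->V[0].cc[ci - 1];
    if (cc.terminal) {  // k == l
      for (int b = 0; b < 4; ++b) {
        std::string sp = std::string(1, code_base(b)) + core;
        ContainsRes r = cc_contains_impl(cc, t->stored(sp));
        if (r.found) {
          kmers.push_back(sp);
          slots.push_back(cc.link[r.pos - 1]);
        }
      }
    } else {
      std::string rest = core.substr((size_t)(t->l - 1));  // shared below the root
      for (int b = 0; b < 4; ++b) {
        std::string sp = std::string(1, code_base(b)) + core.substr(0, (size_t)(t->l - 1));
        ContainsRes r = cc_contains_impl(cc, t->stored(sp));
        if (!r.found) continue;
        long vis2 = 0;
        int slot = lookup_from(*t, cc.link[r.pos - 1], rest, &vis2);
        visited += vis2;
        if (slot >= 0) {
          kmers.push_back(std::string(1, code_base(b)) + core);
          slots.push_back(slot);
        }
      }
    }
  } else if (t->V[0].has_uc) {
    const Vertexx& vx = t->V[0];
    for (int b = 0; b < 4; ++b) {
      std::string cand = std::string(1, code_base(b)) + core;
      std::vector<std::string>::const_iterator it =
          std::lower_bound(vx.uc.s.begin(), vx.uc.s.end(), cand);
      if (it != vx.uc.s.end() && *it == cand) {
        kmers.push_back(cand);
        slots.push_back(vx.uc.col[it - vx.uc.s.begin()]);
      }
    }
  }
  return neighborhood_result(*t, kmers, slots, visited);
}

// ---------------------------------------------------------------------------
// Exports: k-mer counting
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector seqs, int k, int min_occ) {
  if (k < 1) stop("k must be positive");
  if (min_occ < 1) stop("min_occ must be >= 1");
  std::unordered_map<std::string, int> counts;
  std::string window;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int n = (int)s.size();
    int run_start = 0;
    for (int p = 0; p <= n; ++p) {
      int c = p < n ? base_code(s[p]) : -1;
      if (c < 0) {
        // close the ACGT-only run [run_start, p)
        for (int w = run_start; w + k <= p; ++w) {
          window.assign(s, (size_t)w, (size_t)k);
          for (int j = 0; j < k; ++j) window[j] = code_base(base_code(window[j]));
          counts[window] += 1;
        }
        run_start = p + 1;
      }
    }
  }
  std::vector<std::pair<std::string, int>> kept;
  kept.reserve(counts.size());
  for (std::unordered_map<std::string, int>::iterator it = counts.begin();
       it != counts.end(); ++it)
    if (it->second >= min_occ) kept.push_back(*it);
  std::sort(kept.begin(), kept.end());
  CharacterVector km(kept.size());
  IntegerVector ct(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    km[i] = kept[i].first;
    ct[i] = kept[i].second;
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// ---------------------------------------------------------------------------
// Exports: serialization (native-endian binary, versioned magic)
// ---------------------------------------------------------------------------

static void wr_u8(std::ostream& o, uint8_t x) { o.write((const char*)&x, 1); }
static void wr_i32(std::ostream& o, int32_t x) { o.write((const char*)&x, 4); }
static void wr_u64(std::ostream& o, uint64_t x) { o.write((const char*)&x, 8); }
static void wr_f64(std::ostream& o, double x) { o.write((const char*)&x, 8); }
static void wr_str(std::ostream& o, const std::string& s) {
  wr_i32(o, (int32_t)s.size());
  o.write(s.data(), (std::streamsize)s.size());
}
static void wr_words(std::ostream& o, const std::vector<uint64_t>& w) {
  wr_i32(o, (int32_t)w.size());
  for (size_t i = 0; i < w.size(); ++i) wr_u64(o, w[i]);
}
static uint8_t rd_u8(std::istream& in) { uint8_t x; in.read((char*)&x, 1); return x; }
static int32_t rd_i32(std::istream& in) { int32_t x; in.read((char*)&x, 4); return x; }
static uint64_t rd_u64(std::istream& in) { uint64_t x; in.read((char*)&x, 8); return x; }
static double rd_f64(std::istream& in) { double x; in.read((char*)&x, 8); return x; }
static std::string rd_str(std::istream& in) {
  int32_t n = rd_i32(in);
  if (n < 0) stop("corrupt index file");
  std::string s((size_t)n, '\0');
  in.read(&s[0], n);
  return s;
}
static std::vector<uint64_t> rd_words(std::istream& in) {
  int32_t n = rd_i32(in);
  if (n < 0) stop("corrupt index file");
  std::vector<uint64_t> w((size_t)n);
  for (int32_t i = 0; i < n; ++i) w[i] = rd_u64(in);
  return w;
}

static const char kMagic[9] = "BFTRIE01";

// [[Rcpp::export]]
void bft_save_cpp(SEXP xp, std::string path) {
  BFT* t = get_bft(xp);
  std::ofstream o(path.c_str(), std::ios::binary);
  if (!o) stop("cannot open '%s' for writing", path.c_str());
  o.write(kMagic, 8);
  wr_i32(o, t->k); wr_i32(o, t->l); wr_i32(o, t->c);
  wr_u8(o, t->graph_mode ? 1 : 0);
  wr_i32(o, t->m); wr_i32(o, t->f);
  wr_u64(o, t->seed); wr_f64(o, t->resize_factor);
  wr_u64(o, (uint64_t)t->n_kmers); wr_i32(o, t->n_colors);
  wr_i32(o, (int32_t)t->V.size());
  for (size_t v = 0; v < t->V.size(); ++v) {
    const Vertexx& vx = t->V[v];
    wr_i32(o, (int32_t)vx.cc.size());
    for (size_t i = 0; i < vx.cc.size(); ++i) {
      const CComp& cc = vx.cc[i];
      wr_i32(o, cc.la);
      wr_u8(o, cc.terminal ? 1 : 0);
      wr_i32(o, cc.quer.m); wr_i32(o, cc.quer.f);
      wr_u64(o, cc.quer.seed); wr_u8(o, cc.quer.restricted ? 1 : 0);
      wr_words(o, cc.quer.bits);
      wr_words(o, cc.pref);
      wr_i32(o, cc.q());
      for (int j = 0; j < cc.q(); ++j) wr_str(o, cc.suf[j]);
      for (int j = 0; j < cc.q(); ++j) wr_u8(o, cc.clust[j]);
      for (int j = 0; j < cc.q(); ++j) wr_i32(o, cc.link[j]);
    }
    wr_u8(o, vx.has_uc ? 1 : 0);
    if (vx.has_uc) {
      wr_i32(o, (int32_t)vx.uc.s.size());
      for (size_t j = 0; j < vx.uc.s.size(); ++j) {
        wr_str(o, vx.uc.s[j]);
        wr_i32(o, vx.uc.col[j]);
      }
    }
  }
  wr_i32(o, (int32_t)t->slots.size());
  for (size_t i = 0; i < t->slots.size(); ++i) {
    wr_i32(o, t->slots[i].ext);
    wr_words(o, t->slots[i].bits);
  }
  wr_i32(o, (int32_t)t->ext_table.size());
  for (size_t i = 0; i < t->ext_table.size(); ++i) {
    wr_words(o, t->ext_table[i]);
    wr_i32(o, (int32_t)t->ext_cost[i]);
  }
  wr_i32(o, (int32_t)t->color_names.size());
  for (size_t i = 0; i < t->color_names.size(); ++i) wr_str(o, t->color_names[i]);
  if (!o) stop("write to '%s' failed", path.c_str());
}

// [[Rcpp::export]]
SEXP bft_load_cpp(std::string path) {
  std::ifstream in(path.c_str(), std::ios::binary);
  if (!in) stop("cannot open '%s'", path.c_str());
  char magic[8];
  in.read(magic, 8);
  if (!in || std::string(magic, 8) != std::string(kMagic, 8))
    stop("'%s' is not a BFT index file", path.c_str());
  BFT* t = new BFT();
  t->k = rd_i32(in); t->l = rd_i32(in); t->c = rd_i32(in);
  t->graph_mode = rd_u8(in) != 0;
  t->m = rd_i32(in); t->f = rd_i32(in);
  t->seed = rd_u64(in); t->resize_factor = rd_f64(in);
  t->n_kmers = (long)rd_u64(in); t->n_colors = rd_i32(in);
  int32_t nV = rd_i32(in);
  t->V.assign((size_t)nV, Vertexx());
  for (int32_t v = 0; v < nV; ++v) {
    Vertexx& vx = t->V[(size_t)v];
    int32_t ncc = rd_i32(in);
    for (int32_t i = 0; i < ncc; ++i) {
      CComp cc;
      cc.l = t->l;
      cc.la = rd_i32(in);
      cc.terminal = rd_u8(in) != 0;
      cc.quer.m = rd_i32(in); cc.quer.f = rd_i32(in);
      cc.quer.seed = rd_u64(in); cc.quer.restricted = rd_u8(in) != 0;
      cc.quer.bits = rd_words(in);
      cc.pref = rd_words(in);
      int32_t q = rd_i32(in);
      for (int32_t j = 0; j < q; ++j) cc.suf.push_back(rd_str(in));
      for (int32_t j = 0; j < q; ++j) cc.clust.push_back(rd_u8(in));
      for (int32_t j = 0; j < q; ++j) cc.link.push_back(rd_i32(in));
      vx.cc.push_back(cc);
    }
    vx.has_uc = rd_u8(in) != 0;
    if (vx.has_uc) {
      int32_t n = rd_i32(in);
      for (int32_t j = 0; j < n; ++j) {
        vx.uc.s.push_back(rd_str(in));
        vx.uc.col.push_back(rd_i32(in));
      }
    }
  }
  int32_t nslots = rd_i32(in);
  for (int32_t i = 0; i < nslots; ++i) {
    ColorEntry e;
    e.ext = rd_i32(in);
    e.bits = rd_words(in);
    t->slots.push_back(e);
  }
  int32_t next = rd_i32(in);
  for (int32_t i = 0; i < next; ++i) {
    t->ext_table.push_back(rd_words(in));
    t->ext_cost.push_back(rd_i32(in));
  }
  int32_t nnames = rd_i32(in);
  for (int32_t i = 0; i < nnames; ++i) t->color_names.push_back(rd_str(in));
  if (!in) stop("'%s' is truncated or corrupt", path.c_str());
  XPtr<BFT> xp(t, true);
  xp.attr("class") = "bft_ptr";
  return xp;
}

// [[Rcpp::export]]
CharacterVector bft_color_names_cpp(SEXP xp) {
  return wrap(get_bft(xp)->color_names);
}

// [[Rcpp::export]]
void bft_set_color_names_cpp(SEXP xp, CharacterVector names) {
  BFT* t = get_bft(xp);
  t->color_names.clear();
  for (R_xlen_t i = 0; i < names.size(); ++i)
    t->color_names.push_back(as<std::string>(names[i]));
}
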