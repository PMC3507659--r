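// String-graph assembly core: strand-aware suffix handling, SPM-relevant
// suffix indexing (counting/insertion phases with buffered merges and
// partitioning), per-bucket sorting with lcp tables, bottom-up traversal of
// the lcp-interval tree, and suffix-prefix match (SPM) enumeration with
// transitivity classification via left-context dictionaries.
//
// Conventions used throughout:
//  - strand indices are 1-based: 1..m forward reads, m+1..2m reverse
//    complements (when `both` is true).
//  - read offsets q are 0-based; q == 0 denotes the whole read.
//  - every strand is virtually padded by a sentinel $_i, with
//    A < C < G < T < $_1 < ... < $_2m. Sentinels are never stored; the
//    comparison routines realize them: where one string is a proper prefix
//    of another, the LONGER string is the lexicographically smaller one,
//    and ties between identical strings are broken by strand index.

#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;
typedef uint64_t u64;
typedef long long ll;

static inline int bcode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char bcomp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

// ------------------------------------------------------------------ strands

struct StrandSet {
  int m;                        // number of forward reads
  bool both;                    // reverse complements present
  std::vector<std::string> s;   // m or 2m strand sequences
  int n_strands() const { return both ? 2 * m : m; }
  const std::string& str(int idx1) const { return s[idx1 - 1]; }
  int len(int idx1) const { return (int)s[idx1 - 1].size(); }
};

static StrandSet make_strands(const CharacterVector& reads, bool both) {
  StrandSet S;
  S.m = reads.size();
  S.both = both;
  S.s.reserve(both ? 2 * S.m : S.m);
  for (int i = 0; i < S.m; ++i) {
    std::string r = as<std::string>(reads[i]);
    for (size_t j = 0; j < r.size(); ++j)
      if (bcode(r[j]) < 0) stop("read %d contains a non-ACGT symbol", i + 1);
    if (r.empty()) stop("read %d is empty", i + 1);
    S.s.push_back(r);
  }
  if (both) {
    for (int i = 0; i < S.m; ++i) {
      const std::string& r = S.s[i];
      std::string rc(r.size(), 'N');
      for (size_t j = 0; j < r.size(); ++j) rc[j] = bcomp(r[r.size() - 1 - j]);
      S.s.push_back(rc);
    }
  }
  return S;
}

// Compare suffix (sa, qa) against suffix (sb, qb) under the virtual-sentinel
// rule; *lcpOut receives the length of the longest common prefix.
static int suffix_cmp(const StrandSet& S, int sa, int qa, int sb, int qb,
                      int* lcpOut) {
  const std::string& A = S.s[sa - 1];
  const std::string& B = S.s[sb - 1];
  int la = (int)A.size() - qa, lb = (int)B.size() - qb;
  int mi = std::min(la, lb);
  int i = 0;
  for (; i < mi; ++i) {
    char ca = A[qa + i], cb = B[qb + i];
    if (ca != cb) { *lcpOut = i; return ca < cb ? -1 : 1; }
  }
  *lcpOut = mi;
  if (la != lb) return la > lb ? -1 : 1;  // sentinel > base: longer is smaller
  if (sa != sb) return sa < sb ? -1 : 1;  // $_i < $_j iff i < j
  return 0;
}

// ---------------------------------------------------------------- k-mer codes

static inline u64 kmask(int k) {
  return k >= 32 ? ~0ULL : ((1ULL << (2 * k)) - 1);
}

static u64 code_at(const std::string& s, int pos0, int k) {
  u64 c = 0;
  for (int i = 0; i < k; ++i) c = (c << 2) | (u64)bcode(s[pos0 + i]);
  return c;
}

// Exact membership over k'-mer / k''-mer codes: bit vector when small, an
// open-addressing hash set (linear probing, power-of-two capacity)
// otherwise. Both are exact with respect to the inserted code set.
struct CodeSet {
  bool useBits = false;
  std::vector<bool> bits;
  std::vector<u64> table;
  std::vector<bool> used;
  size_t hmask = 0;
  static inline size_t mix(u64 x) {
    x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
    x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
    x ^= x >> 33;
    return (size_t)x;
  }
  void build(const std::vector<u64>& codes, int mer) {
    if (2 * mer <= 26) {
      useBits = true;
      bits.assign((size_t)1 << (2 * mer), false);
      for (u64 c : codes) bits[c] = true;
    } else {
      size_t cap = 16;
      while (cap < 2 * codes.size() + 1) cap <<= 1;
      table.assign(cap, 0);
      used.assign(cap, false);
      hmask = cap - 1;
      for (u64 c : codes) {
        size_t i = mix(c) & hmask;
        while (used[i]) {
          if (table[i] == c) break;
          i = (i + 1) & hmask;
        }
        table[i] = c;
        used[i] = true;
      }
    }
  }
  bool contains(u64 c) const {
    if (useBits) return bits[c];
    size_t i = mix(c) & hmask;
    while (used[i]) {
      if (table[i] == c) return true;
      i = (i + 1) & hmask;
    }
    return false;
  }
};

// Hash map from k-mer code to key index in K (exact; used by the insertion
// phase to locate a candidate's bucket in constant time).
struct CodeIndex {
  std::vector<u64> keys;
  std::vector<int> vals;
  std::vector<bool> used;
  size_t hmask = 0;
  void build(const std::vector<u64>& K) {
    size_t cap = 16;
    while (cap < 2 * K.size() + 1) cap <<= 1;
    keys.assign(cap, 0);
    vals.assign(cap, -1);
    used.assign(cap, false);
    hmask = cap - 1;
    for (size_t j = 0; j < K.size(); ++j) {
      size_t i = CodeSet::mix(K[j]) & hmask;
      while (used[i]) i = (i + 1) & hmask;
      keys[i] = K[j];
      vals[i] = (int)j;
      used[i] = true;
    }
  }
  int find(u64 c) const {
    size_t i = CodeSet::mix(c) & hmask;
    while (used[i]) {
      if (keys[i] == c) return vals[i];
      i = (i + 1) & hmask;
    }
    return -1;
  }
};

// ------------------------------------------------------------- index tables

struct IndexTables {
  int k, kp, kpp, lmin;
  std::vector<u64> K;    // sorted distinct initial k-mer codes
  std::vector<ll> C;     // counts per key
  CodeSet P, Q;          // k'-prefix / k''-suffix filters
};

static std::vector<u64> collect_initial(const StrandSet& S, int k) {
  std::vector<u64> v;
  v.reserve(S.n_strands());
  for (int i = 1; i <= S.n_strands(); ++i) {
    if (S.len(i) < k) stop("strand %d shorter than k", i);
    v.push_back(code_at(S.str(i), 0, k));
  }
  std::sort(v.begin(), v.end());
  return v;
}

static IndexTables dedup_count(const std::vector<u64>& sortedCodes, int k,
                               int kp, int kpp, int lmin) {
  IndexTables T;
  T.k = k; T.kp = kp; T.kpp = kpp; T.lmin = lmin;
  for (size_t i = 0; i < sortedCodes.size(); ++i) {
    if (i == 0 || sortedCodes[i] != sortedCodes[i - 1]) {
      T.K.push_back(sortedCodes[i]);
      T.C.push_back(1);
    } else {
      T.C.back()++;
    }
  }
  std::vector<u64> pc, qc;
  pc.reserve(T.K.size());
  qc.reserve(T.K.size());
  for (u64 u : T.K) {
    pc.push_back(u >> (2 * (k - kp)));
    qc.push_back(u & kmask(kpp));
  }
  T.P.build(pc, kp);
  T.Q.build(qc, kpp);
  return T;
}

// Enumerate proper candidate suffixes (q in 1..|r|-lmin) passing the P/Q
// filters, with initial k-mer code in [lo, hi]. Codes are maintained by a
// rolling window.
template <class F>
static void enum_candidates(const StrandSet& S, const IndexTables& T,
                            u64 lo, u64 hi, F f) {
  const int k = T.k;
  const u64 mask = kmask(k);
  const int pshift = 2 * (k - T.kp);
  const u64 qmask = kmask(T.kpp);
  for (int p = 1; p <= S.n_strands(); ++p) {
    const std::string& r = S.str(p);
    int L = (int)r.size();
    int qmax = L - T.lmin;
    if (qmax < 1) continue;
    u64 c = code_at(r, 0, k);
    for (int q = 1; q <= qmax; ++q) {
      c = ((c << 2) & mask) | (u64)bcode(r[q + k - 1]);
      if (c < lo || c > hi) continue;
      if (!T.P.contains(c >> pshift)) continue;
      if (!T.Q.contains(c & qmask)) continue;
      f(p, q, c);
    }
  }
}

// Counting phase: buffered batches of candidate codes are sorted, then a
// single binary search locates the smallest batch element in K and a
// simultaneous linear scan increments the matching counters.
static void counting_phase(const StrandSet& S, IndexTables& T, int bufcap) {
  if (bufcap < 1) bufcap = 1;
  std::vector<u64> buf;
  buf.reserve(bufcap);
  auto flush = [&]() {
    if (buf.empty()) return;
    std::sort(buf.begin(), buf.end());
    size_t e = std::lower_bound(T.K.begin(), T.K.end(), buf[0]) - T.K.begin();
    size_t i = 0;
    while (i < buf.size() && e < T.K.size()) {
      if (buf[i] < T.K[e]) ++i;            // candidate not a key: dropped
      else if (buf[i] > T.K[e]) ++e;
      else { T.C[e]++; ++i; }
    }
    buf.clear();
  };
  enum_candidates(S, T, 0, ~0ULL, [&](int, int, u64 c) {
    buf.push_back(c);
    if ((int)buf.size() >= bufcap) flush();
  });
  flush();
}

// Partial sums exactly as printed: pi[0] = C[0], pi[i] = pi[i-1] + C[i] for
// 1 <= i <= d-1, pi[d] = pi[d-1]. Bucket i is addressed as
// [pi[i-1], pi[i]) with pi[-1] := 0.
static std::vector<ll> partial_sums(const std::vector<ll>& C) {
  size_t d = C.size();
  std::vector<ll> pi(d + 1, 0);
  if (d == 0) return pi;
  pi[0] = C[0];
  for (size_t i = 1; i <= d - 1; ++i) pi[i] = pi[i - 1] + C[i];
  pi[d] = pi[d - 1];
  return pi;
}

// Greedy contiguous partition of bucket indices into parts of roughly equal
// total size (or the minimal number of parts fitting a memory limit under a
// simplified entries-times-word size model).
static std::vector<std::pair<int, int>> plan_parts(const std::vector<ll>& C,
                                                   int qParts,
                                                   double memLimitBytes) {
  std::vector<std::pair<int, int>> parts;
  int d = (int)C.size();
  if (d == 0) { parts.push_back({0, -1}); return parts; }
  ll g = 0;
  for (ll c : C) g += c;
  const double perEntry = 16.0, perBucket = 8.0;
  if (memLimitBytes > 0) {
    for (int i = 0; i < d; ++i)
      if (C[i] * perEntry + perBucket > memLimitBytes)
        stop("memory limit below the requirement of a single bucket");
    int lo = 0;
    double acc = 0;
    for (int i = 0; i < d; ++i) {
      double cost = C[i] * perEntry + perBucket;
      if (acc > 0 && acc + cost > memLimitBytes) {
        parts.push_back({lo, i - 1});
        lo = i;
        acc = 0;
      }
      acc += cost;
    }
    parts.push_back({lo, d - 1});
  } else {
    if (qParts < 1) qParts = 1;
    if (qParts > d) qParts = d;
    ll target = (g + qParts - 1) / qParts;
    if (target < 1) target = 1;
    int lo = 0;
    ll acc = 0;
    for (int i = 0; i < d; ++i) {
      acc += C[i];
      bool last = (i == d - 1);
      int remainingParts = qParts - (int)parts.size();
      int remainingBuckets = d - 1 - i;
      if (!last && (acc >= target || remainingBuckets <= remainingParts - 1)) {
        parts.push_back({lo, i});
        lo = i + 1;
        acc = 0;
      }
    }
    parts.push_back({lo, d - 1});
  }
  return parts;
}

// One part's segment of table S: (strand, offset) entries laid out bucket by
// bucket, filled by the decrementing-cursor insertion of the counting-sort
// scheme. Whole reads (q = 0) are inserted unconditionally; proper
// candidates are validated against K during the buffered merge.
struct Segment {
  int loIdx, hiIdx;                        // bucket index range (0-based)
  ll base;                                 // global S offset of the segment
  std::vector<std::pair<int, int>> entries;
  std::vector<ll> bstart;                  // per-bucket start, relative
};

static Segment insert_part(const StrandSet& S, const IndexTables& T,
                           const CodeIndex& KI, const std::vector<ll>& pi,
                           int lo, int hi, int bufcap) {
  Segment seg;
  seg.loIdx = lo; seg.hiIdx = hi;
  seg.base = (lo == 0) ? 0 : pi[lo - 1];
  ll size = (hi < lo) ? 0 : pi[hi] - seg.base;
  seg.entries.assign((size_t)size, {0, 0});
  seg.bstart.resize(hi - lo + 2);
  for (int i = lo; i <= hi; ++i)
    seg.bstart[i - lo] = ((i == 0) ? 0 : pi[i - 1]) - seg.base;
  if (hi >= lo) seg.bstart[hi - lo + 1] = pi[hi] - seg.base;
  if (hi < lo) return seg;

  std::vector<ll> cursor(hi - lo + 1);
  for (int i = lo; i <= hi; ++i) cursor[i - lo] = pi[i] - seg.base;

  struct Trip { u64 u; int p, q; };
  if (bufcap < 1) bufcap = 1;
  std::vector<Trip> buf;
  buf.reserve(bufcap);
  auto place = [&](const Trip& t, bool mustMatch) {
    int idx = KI.find(t.u);
    if (idx < lo || idx > hi) {
      if (mustMatch) stop("internal error: whole-read k-mer missing from K");
      return;
    }
    ll pos = --cursor[idx - lo];
    if (pos < seg.bstart[idx - lo])
      stop("internal consistency error: bucket overflow (counting/insertion mismatch)");
    seg.entries[(size_t)pos] = {t.p, t.q};
  };
  auto flush = [&]() {
    if (buf.empty()) return;
    std::stable_sort(buf.begin(), buf.end(),
                     [](const Trip& a, const Trip& b) { return a.u < b.u; });
    for (const Trip& t : buf) place(t, false);
    buf.clear();
  };

  u64 loCode = T.K[lo], hiCode = T.K[hi];
  for (int p = 1; p <= S.n_strands(); ++p) {   // whole reads, q = 0
    u64 u = code_at(S.str(p), 0, T.k);
    if (u < loCode || u > hiCode) continue;
    place({u, p, 0}, true);
  }
  enum_candidates(S, T, loCode, hiCode, [&](int p, int q, u64 c) {
    buf.push_back({c, p, q});
    if ((int)buf.size() >= bufcap) flush();
  });
  flush();
  return seg;
}

// Sort one bucket of SPM-relevant suffixes (all sharing the initial k-mer)
// under the full lexicographic order with virtual sentinels, and compute the
// lcp table L (L[j] >= k within a bucket).
static void sort_bucket_entries(const StrandSet& S,
                                std::vector<std::pair<int, int>>& H,
                                int k, std::vector<int>& L) {
  std::sort(H.begin(), H.end(),
            [&](const std::pair<int, int>& a, const std::pair<int, int>& b) {
              int l;
              return suffix_cmp(S, a.first, a.second + k, b.first,
                                b.second + k, &l) < 0;
            });
  L.assign(H.size() > 0 ? H.size() - 1 : 0, 0);
  for (size_t j = 1; j < H.size(); ++j) {
    int l;
    suffix_cmp(S, H[j - 1].first, H[j - 1].second + k, H[j].first,
               H[j].second + k, &l);
    L[j - 1] = k + l;
  }
}

// ------------------------------------------------- lcp-interval tree traversal

struct Itv {
  int lcp, lb, rb;
  ll firstinW;
  bool hasEdge;
};

// Bottom-up traversal (stack-based, push on rising lcp / pop-complete on
// falling lcp) extended to deliver leaf edges: every singleton is delivered
// exactly once, attached to the deepest lcp-interval containing it, before
// that interval completes. A handler H provides:
//   leaf(Itv&, bool firstedge, int j)           -- singleton H[j]
//   branch(Itv& parent, bool firstedge, const Itv& child)
//   interval(const Itv&)                        -- completed, rb defined
// For beta == 1 a pseudo-root (lcp = k, lb = rb = 0) carries the single
// leaf so that every bucket delivers its suffixes; it is not an lcp-interval
// in the strict sense (which requires lb < rb).
template <class H>
static void traverse_tree(const std::vector<int>& L, int beta, int k, H& h) {
  if (beta <= 0) return;
  if (beta == 1) {
    Itv root{k, 0, -1, -1, false};
    h.leaf(root, true, 0);
    root.hasEdge = true;
    root.rb = 0;
    h.interval(root);
    return;
  }
  std::vector<Itv> stack;
  stack.reserve(64);
  stack.push_back({-1, 0, -1, -1, false});  // bottom, never delivered
  auto emit_leaf = [&](Itv& itv, int j) {
    h.leaf(itv, !itv.hasEdge, j);
    itv.hasEdge = true;
  };
  for (int e = 1; e < beta; ++e) {
    int v = L[e - 1];  // lcp between H[e-1] and H[e]
    if (v > stack.back().lcp) {
      stack.push_back({v, e - 1, -1, -1, false});
      emit_leaf(stack.back(), e - 1);
    } else {
      emit_leaf(stack.back(), e - 1);
      while (v < stack.back().lcp) {
        Itv child = stack.back();
        stack.pop_back();
        child.rb = e - 1;
        h.interval(child);
        if (v > stack.back().lcp)
          stack.push_back({v, child.lb, -1, -1, false});
        Itv& par = stack.back();
        h.branch(par, !par.hasEdge, child);
        par.hasEdge = true;
      }
    }
  }
  emit_leaf(stack.back(), beta - 1);
  while (stack.size() > 1) {
    Itv child = stack.back();
    stack.pop_back();
    child.rb = beta - 1;
    h.interval(child);
    if (stack.size() > 1) {
      Itv& par = stack.back();
      h.branch(par, !par.hasEdge, child);
      par.hasEdge = true;
    }
  }
}

// ------------------------------------------------------------ SPM enumeration

// Conditions for a non-redundant SPM over strands of R-bar (forward read
// indices compared by the input order ≺):
//   (src fwd, dst fwd), or (src fwd, dst rc, src ≺ dst's read), or
//   (src rc, dst fwd, dst ≺ src's read).
static inline bool spm_nonredundant(int src, int dst, int m) {
  bool sf = src <= m, df = dst <= m;
  if (sf && df) return true;
  if (sf && !df) return src < dst - m;
  if (!sf && df) return dst < src - m;
  return false;
}

struct SpmRec { int src, dst, len, irreducible; };

// Pass 1 handler: flag internally contained reads. A whole-read leaf whose
// suffix ends exactly at the depth of a real enclosing interval (terminal
// whole-read leaf) means some other SPM-relevant suffix has the read as a
// proper prefix, i.e. the read occurs internally in another read.
struct ContainHandler {
  const StrandSet* S;
  const std::vector<std::pair<int, int>>* H;
  int beta;
  std::vector<bool>* contained;
  void leaf(Itv& itv, bool, int j) {
    int p = (*H)[j].first, q = (*H)[j].second;
    if (q == 0 && beta > 1 && S->len(p) == itv.lcp) {
      int read = p > S->m ? p - S->m : p;
      (*contained)[read - 1] = true;
    }
  }
  void branch(Itv&, bool, const Itv&) {}
  void interval(const Itv&) {}
};

// Pass 2 handler: Algorithm-2 style enumeration. Whole-read leaves are
// collected in W (each with a left-context dictionary), terminal edges in T;
// at each completed interval of lcp >= lmin the cartesian product
// T x W[firstinW..] yields the SPMs of that length. Transitivity is decided
// per destination by a suffix search among the stored left contexts of the
// irreducible SPMs already found on the same whole-read path.
struct SpmHandler {
  const StrandSet* S;
  const std::vector<std::pair<int, int>>* H;
  int beta, lmin, m;
  std::vector<int> T;                        // pending terminal-edge strands
  struct WEntry { int strand; std::vector<std::string> lcs; };
  std::vector<WEntry> W;
  std::vector<SpmRec>* out;
  ll nLeaf = 0, nBranch = 0, nItv = 0;

  void leaf(Itv& itv, bool first, int j) {
    ++nLeaf;
    if (first) itv.firstinW = (ll)W.size();
    int p = (*H)[j].first, q = (*H)[j].second;
    bool terminal = (beta > 1) && (S->len(p) - q == itv.lcp);
    if (q == 0) {
      if (!terminal) W.push_back({p, {}});
      // terminal whole-read leaves signal containment; with contained reads
      // removed beforehand they do not occur, but tolerate them on
      // non-prefiltered input by contributing nothing.
    } else if (terminal) {
      T.push_back(p);
    }
  }
  void branch(Itv& par, bool first, const Itv& child) {
    ++nBranch;
    if (first) par.firstinW = child.firstinW;
  }
  void interval(const Itv& itv) {
    ++nItv;
    if (itv.lcp >= lmin) {
      if (!T.empty() && itv.firstinW >= 0) {
        for (size_t wi = (size_t)itv.firstinW; wi < W.size(); ++wi) {
          for (int src : T) emit(src, wi, itv.lcp);
        }
      }
      T.clear();
    } else {
      W.clear();
      T.clear();
    }
  }
  void emit(int src, size_t wi, int len) {
    int dst = W[wi].strand;
    int srcRead = src > m ? src - m : src;
    int dstRead = dst > m ? dst - m : dst;
    if (srcRead == dstRead) return;  // self-overlaps excluded throughout
    // classify before the redundancy filter: every SPM on the path takes
    // part in transitivity suppression
    const std::string& rs = S->str(src);
    std::string lc = rs.substr(0, rs.size() - (size_t)len);
    bool transitive = false;
    for (const std::string& t : W[wi].lcs) {
      if (t.size() <= lc.size() &&
          std::equal(t.begin(), t.end(), lc.end() - t.size())) {
        transitive = true;
        break;
      }
    }
    if (!transitive) W[wi].lcs.push_back(lc);
    if (spm_nonredundant(src, dst, m) || !S->both)
      out->push_back({src, dst, len, transitive ? 0 : 1});
  }
  void finish() { W.clear(); T.clear(); }
};

// Filter a sorted bucket down to non-contained reads, min-folding the lcp
// table across removed entries.
static void filter_bucket(const StrandSet& S, const std::vector<bool>& contained,
                          std::vector<std::pair<int, int>>& H,
                          std::vector<int>& L) {
  size_t n = H.size();
  std::vector<std::pair<int, int>> H2;
  std::vector<int> L2;
  H2.reserve(n);
  int pend = -1;  // min lcp accumulated across removed entries
  for (size_t j = 0; j < n; ++j) {
    int p = H[j].first;
    int read = p > S.m ? p - S.m : p;
    int lin = (j == 0) ? -1 : L[j - 1];
    if (pend < 0) pend = lin;
    else pend = std::min(pend, lin);
    if (!contained[read - 1]) {
      if (!H2.empty()) L2.push_back(pend);
      H2.push_back(H[j]);
      pend = -1;
    }
  }
  H = std::move(H2);
  L = std::move(L2);
}

// ------------------------------------------------------------------ exports

// [[Rcpp::export(name = ".cpp_sort_strands")]]
List cpp_sort_strands(CharacterVector reads, bool both) {
  StrandSet S = make_strands(reads, both);
  int n = S.n_strands();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i + 1;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    int l;
    return suffix_cmp(S, a, 0, b, 0, &l) < 0;
  });
  IntegerVector lcp(n > 0 ? n - 1 : 0);
  for (int t = 1; t < n; ++t) {
    int l;
    suffix_cmp(S, ord[t - 1], 0, ord[t], 0, &l);
    lcp[t - 1] = l;
  }
  return List::create(_["order"] = wrap(ord), _["lcp"] = lcp);
}

// [[Rcpp::export(name = ".cpp_collect_initial_kmers")]]
NumericVector cpp_collect_initial_kmers(CharacterVector reads, int k, bool both) {
  StrandSet S = make_strands(reads, both);
  std::vector<u64> v = collect_initial(S, k);
  NumericVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = (double)v[i];
  return out;
}

static void check_params(int lmin, int k, int kp, int kpp) {
  if (lmin < 1) stop("l_min must be >= 1");
  if (k < 1 || k > 32) stop("k must be in 1..32");
  if (k > lmin) stop("k must not exceed l_min");
  if (kp < 1 || kp > k) stop("k' must satisfy 1 <= k' <= k");
  if (kpp < 1 || kpp > kp) stop("k'' must satisfy 1 <= k'' <= k'");
}

// [[Rcpp::export(name = ".cpp_dedup_count")]]
List cpp_dedup_count(CharacterVector reads, int lmin, int k, int kp, int kpp,
                     bool both) {
  check_params(lmin, k, kp, kpp);
  StrandSet S = make_strands(reads, both);
  IndexTables T = dedup_count(collect_initial(S, k), k, kp, kpp, lmin);
  NumericVector K(T.K.size()), C(T.C.size());
  for (size_t i = 0; i < T.K.size(); ++i) { K[i] = (double)T.K[i]; C[i] = (double)T.C[i]; }
  std::vector<u64> pv, qv;
  for (u64 u : T.K) { pv.push_back(u >> (2 * (k - kp))); qv.push_back(u & kmask(kpp)); }
  std::sort(pv.begin(), pv.end()); pv.erase(std::unique(pv.begin(), pv.end()), pv.end());
  std::sort(qv.begin(), qv.end()); qv.erase(std::unique(qv.begin(), qv.end()), qv.end());
  NumericVector P(pv.size()), Q(qv.size());
  for (size_t i = 0; i < pv.size(); ++i) P[i] = (double)pv[i];
  for (size_t i = 0; i < qv.size(); ++i) Q[i] = (double)qv[i];
  return List::create(_["K"] = K, _["C_init"] = C, _["P"] = P, _["Q"] = Q);
}

// [[Rcpp::export(name = ".cpp_enumerate_candidates")]]
List cpp_enumerate_candidates(CharacterVector reads, int lmin, int k, int kp,
                              int kpp, bool both, double loCode, double hiCode) {
  check_params(lmin, k, kp, kpp);
  StrandSet S = make_strands(reads, both);
  IndexTables T = dedup_count(collect_initial(S, k), k, kp, kpp, lmin);
  std::vector<int> ps, qs;
  std::vector<double> cs;
  u64 lo = (loCode < 0) ? 0 : (u64)loCode;
  u64 hi = (hiCode < 0) ? ~0ULL : (u64)hiCode;
  enum_candidates(S, T, lo, hi, [&](int p, int q, u64 c) {
    ps.push_back(p); qs.push_back(q); cs.push_back((double)c);
  });
  return List::create(_["strand"] = wrap(ps), _["offset"] = wrap(qs),
                      _["code"] = wrap(cs));
}

// [[Rcpp::export(name = ".cpp_counting_phase")]]
List cpp_counting_phase(CharacterVector reads, int lmin, int k, int kp, int kpp,
                        bool both, int buffer) {
  check_params(lmin, k, kp, kpp);
  StrandSet S = make_strands(reads, both);
  IndexTables T = dedup_count(collect_initial(S, k), k, kp, kpp, lmin);
  counting_phase(S, T, buffer);
  NumericVector K(T.K.size()), C(T.C.size());
  ll g = 0;
  for (size_t i = 0; i < T.K.size(); ++i) {
    K[i] = (double)T.K[i];
    C[i] = (double)T.C[i];
    g += T.C[i];
  }
  return List::create(_["K"] = K, _["C"] = C, _["g"] = (double)g);
}

// [[Rcpp::export(name = ".cpp_partial_sums")]]
NumericVector cpp_partial_sums(NumericVector C) {
  std::vector<ll> c(C.size());
  for (int i = 0; i < C.size(); ++i) c[i] = (ll)C[i];
  std::vector<ll> pi = partial_sums(c);
  NumericVector out(pi.size());
  for (size_t i = 0; i < pi.size(); ++i) out[i] = (double)pi[i];
  return out;
}

// [[Rcpp::export(name = ".cpp_plan_partitions")]]
IntegerMatrix cpp_plan_partitions(NumericVector C, int qParts, double memLimit) {
  std::vector<ll> c(C.size());
  for (int i = 0; i < C.size(); ++i) c[i] = (ll)C[i];
  auto parts = plan_parts(c, qParts, memLimit);
  IntegerMatrix out(parts.size(), 2);
  for (size_t i = 0; i < parts.size(); ++i) {
    out(i, 0) = parts[i].first + 1;   // 1-based bucket index ranges
    out(i, 1) = parts[i].second + 1;
  }
  colnames(out) = CharacterVector::create("lo", "hi");
  return out;
}

// [[Rcpp::export(name = ".cpp_insertion_phase")]]
List cpp_insertion_phase(CharacterVector reads, int lmin, int k, int kp,
                         int kpp, bool both, int buffer, int qParts,
                         double memLimit) {
  check_params(lmin, k, kp, kpp);
  StrandSet S = make_strands(reads, both);
  IndexTables T = dedup_count(collect_initial(S, k), k, kp, kpp, lmin);
  counting_phase(S, T, buffer);
  std::vector<ll> pi = partial_sums(T.C);
  auto parts = plan_parts(T.C, qParts, memLimit);
  CodeIndex KI;
  KI.build(T.K);
  std::vector<int> strand, offset, bucket;
  for (auto& pr : parts) {
    Segment seg = insert_part(S, T, KI, pi, pr.first, pr.second, std::max(1, buffer / 2));
    for (int b = pr.first; b <= pr.second; ++b) {
      for (ll j = seg.bstart[b - pr.first]; j < seg.bstart[b - pr.first + 1]; ++j) {
        strand.push_back(seg.entries[(size_t)j].first);
        offset.push_back(seg.entries[(size_t)j].second);
        bucket.push_back(b + 1);
      }
    }
  }
  return List::create(_["strand"] = wrap(strand), _["offset"] = wrap(offset),
                      _["bucket"] = wrap(bucket));
}

// [[Rcpp::export(name = ".cpp_sort_bucket")]]
List cpp_sort_bucket(CharacterVector reads, bool both, IntegerVector strand,
                     IntegerVector offset, int k) {
  StrandSet S = make_strands(reads, both);
  size_t n = strand.size();
  std::vector<std::pair<int, int>> H(n);
  std::vector<size_t> perm(n);
  for (size_t i = 0; i < n; ++i) {
    H[i] = {strand[i], offset[i]};
    perm[i] = i;
  }
  std::sort(perm.begin(), perm.end(), [&](size_t a, size_t b) {
    int l;
    return suffix_cmp(S, H[a].first, H[a].second + k, H[b].first,
                      H[b].second + k, &l) < 0;
  });
  std::vector<std::pair<int, int>> Hs(n);
  for (size_t i = 0; i < n; ++i) Hs[i] = H[perm[i]];
  IntegerVector ord(n), L(n > 0 ? n - 1 : 0);
  for (size_t i = 0; i < n; ++i) ord[i] = (int)perm[i] + 1;
  for (size_t j = 1; j < n; ++j) {
    int l;
    suffix_cmp(S, Hs[j - 1].first, Hs[j - 1].second + k, Hs[j].first,
               Hs[j].second + k, &l);
    L[j - 1] = k + l;
  }
  return List::create(_["order"] = ord, _["L"] = L);
}

// Event-log handler used to expose the traversal to R callbacks.
struct LogHandler {
  const StrandSet* S;
  const std::vector<std::pair<int, int>>* H;
  std::vector<int> type, firstedge, lcp, lb, rb, leafStrand, leafOffset,
      childLcp, childLb, childRb;
  void row(int ty, int fe, const Itv& itv, int ls, int lo, const Itv* child) {
    type.push_back(ty);
    firstedge.push_back(fe);
    lcp.push_back(itv.lcp);
    lb.push_back(itv.lb);
    rb.push_back(itv.rb);  // -1 while undefined
    leafStrand.push_back(ls);
    leafOffset.push_back(lo);
    childLcp.push_back(child ? child->lcp : -1);
    childLb.push_back(child ? child->lb : -1);
    childRb.push_back(child ? child->rb : -1);
  }
  void leaf(Itv& itv, bool first, int j) {
    row(1, first ? 1 : 0, itv, (*H)[j].first, (*H)[j].second, nullptr);
  }
  void branch(Itv& par, bool first, const Itv& child) {
    row(2, first ? 1 : 0, par, -1, -1, &child);
  }
  void interval(const Itv& itv) { row(3, 0, itv, -1, -1, nullptr); }
};

// [[Rcpp::export(name = ".cpp_traverse_bucket")]]
DataFrame cpp_traverse_bucket(CharacterVector reads, bool both,
                              IntegerVector strand, IntegerVector offset,
                              IntegerVector L, int k) {
  StrandSet S = make_strands(reads, both);
  int beta = strand.size();
  if (L.size() != std::max(0, beta - 1))
    stop("lcp table must have length beta - 1");
  for (int j = 0; j < L.size(); ++j)
    if (L[j] < k) stop("malformed lcp table: L[%d] = %d < k", j + 1, L[j]);
  std::vector<std::pair<int, int>> H(beta);
  for (int i = 0; i < beta; ++i) H[i] = {strand[i], offset[i]};
  std::vector<int> Lv(L.begin(), L.end());
  LogHandler h;
  h.S = &S;
  h.H = &H;
  traverse_tree(Lv, beta, k, h);
  return DataFrame::create(
      _["type"] = wrap(h.type), _["firstedge"] = wrap(h.firstedge),
      _["lcp"] = wrap(h.lcp), _["lb"] = wrap(h.lb), _["rb"] = wrap(h.rb),
      _["leaf_strand"] = wrap(h.leafStrand),
      _["leaf_offset"] = wrap(h.leafOffset), _["child_lcp"] = wrap(h.childLcp),
      _["child_lb"] = wrap(h.childLb), _["child_rb"] = wrap(h.childRb));
}

// Full overlap pipeline: counting phase, partial sums, partitioned insertion,
// per-bucket sorting, pass-1 containment flags, pass-2 SPM enumeration with
// transitivity classification. Returns the non-redundant SPM set (status
// column: 1 = irreducible, 0 = transitive), the contained-read flags, and
// summary statistics (optionally per-bucket callback counts).
// [[Rcpp::export(name = ".cpp_overlap")]]
List cpp_overlap(CharacterVector reads, int lmin, int k, int kp, int kpp,
                 bool both, int buffer, int qParts, double memLimit,
                 bool withStats) {
  check_params(lmin, k, kp, kpp);
  StrandSet S = make_strands(reads, both);
  for (int i = 1; i <= S.n_strands(); ++i)
    if (S.len(i) < lmin)
      stop("all reads must have length >= l_min at the overlap stage");
  IndexTables T = dedup_count(collect_initial(S, k), k, kp, kpp, lmin);
  counting_phase(S, T, buffer);
  std::vector<ll> pi = partial_sums(T.C);
  auto parts = plan_parts(T.C, qParts, memLimit);
  CodeIndex KI;
  KI.build(T.K);
  int insBuf = std::max(1, buffer / 2);
  ll g = pi.empty() ? 0 : pi.back();

  // pass 1: containment flags over all buckets
  std::vector<bool> contained(S.m, false);
  for (auto& pr : parts) {
    Segment seg = insert_part(S, T, KI, pi, pr.first, pr.second, insBuf);
    for (int b = pr.first; b <= pr.second; ++b) {
      ll s0 = seg.bstart[b - pr.first], s1 = seg.bstart[b - pr.first + 1];
      std::vector<std::pair<int, int>> H(seg.entries.begin() + s0,
                                         seg.entries.begin() + s1);
      std::vector<int> L;
      sort_bucket_entries(S, H, T.k, L);
      ContainHandler h{&S, &H, (int)H.size(), &contained};
      traverse_tree(L, (int)H.size(), T.k, h);
    }
  }

  // pass 2: SPM enumeration on buckets with contained reads' entries removed
  std::vector<SpmRec> spms;
  std::vector<int> statBeta, statLeaf, statBranch, statItv;
  for (auto& pr : parts) {
    Segment seg = insert_part(S, T, KI, pi, pr.first, pr.second, insBuf);
    for (int b = pr.first; b <= pr.second; ++b) {
      ll s0 = seg.bstart[b - pr.first], s1 = seg.bstart[b - pr.first + 1];
      std::vector<std::pair<int, int>> H(seg.entries.begin() + s0,
                                         seg.entries.begin() + s1);
      std::vector<int> L;
      sort_bucket_entries(S, H, T.k, L);
      filter_bucket(S, contained, H, L);
      SpmHandler h;
      h.S = &S; h.H = &H; h.beta = (int)H.size(); h.lmin = lmin; h.m = S.m;
      h.out = &spms;
      traverse_tree(L, (int)H.size(), T.k, h);
      h.finish();
      if (withStats && !H.empty()) {
        statBeta.push_back((int)H.size());
        statLeaf.push_back((int)h.nLeaf);
        statBranch.push_back((int)h.nBranch);
        statItv.push_back((int)h.nItv);
      }
    }
  }

  size_t z = spms.size();
  IntegerVector src(z), dst(z), len(z), irr(z);
  for (size_t i = 0; i < z; ++i) {
    src[i] = spms[i].src; dst[i] = spms[i].dst;
    len[i] = spms[i].len; irr[i] = spms[i].irreducible;
  }
  LogicalVector cont(S.m);
  for (int i = 0; i < S.m; ++i) cont[i] = contained[i];
  List stats = List::create(
      _["d"] = (double)T.K.size(), _["g"] = (double)g,
      _["n_parts"] = (int)parts.size());
  if (withStats) {
    stats["bucket_beta"] = wrap(statBeta);
    stats["bucket_leaf_calls"] = wrap(statLeaf);
    stats["bucket_branch_calls"] = wrap(statBranch);
    stats["bucket_interval_calls"] = wrap(statItv);
  }
  return List::create(_["src"] = src, _["dst"] = dst, _["length"] = len,
                      _["irreducible"] = irr, _["contained"] = cont,
                      _["stats"] = stats);
}

// [[Rcpp::export(name = ".cpp_detect_contained")]]
LogicalVector cpp_detect_contained(CharacterVector reads, int lmin, int k,
                                   int kp, int kpp, bool both, int buffer) {
  check_params(lmin, k, kp, kpp);
  StrandSet S = make_strands(reads, both);
  IndexTables T = dedup_count(collect_initial(S, k), k, kp, kpp, lmin);
  counting_phase(S, T, buffer);
  std::vector<ll> pi = partial_sums(T.C);
  auto parts = plan_parts(T.C, 1, -1);
  CodeIndex KI;
  KI.build(T.K);
  std::vector<bool> contained(S.m, false);
  for (auto& pr : parts) {
    Segment seg = insert_part(S, T, KI, pi, pr.first, pr.second,
                              std::max(1, buffer / 2));
    for (int b = pr.first; b <= pr.second; ++b) {
      ll s0 = seg.bstart[b - pr.first], s1 = seg.bstart[b - pr.first + 1];
      std::vector<std::pair<int, int>> H(seg.entries.begin() + s0,
                                         seg.entries.begin() + s1);
      std::vector<int> L;
      sort_bucket_entries(S, H, T.k, L);
      ContainHandler h{&S, &H, (int)H.size(), &contained};
      traverse_tree(L, (int)H.size(), T.k, h);
    }
  }
  LogicalVector out(S.m);
  for (int i = 0; i < S.m; ++i) out[i] = contained[i];
  return out;
}
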