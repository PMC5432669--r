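// Compiled core: per-VP random streams, the adaptive connection store with
// its allocation ledger, the wiring loops in both orders, and the occupancy
// Monte Carlo. Gids are carried as long long (passed from R as doubles,
// exact below 2^53).

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 streams, one per virtual process.
// Seed derivation mixes (master_seed, stream index) through the 64-bit
// finalizer twice so that nearby seeds and stream ids decorrelate.

static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RngStream {
  uint64_t state;
  void seed(uint64_t master, uint64_t idx) {
    state = mix64(master + 0x9E3779B97F4A7C15ULL * (idx + 1));
  }
  uint64_t next() {
    state += 0x9E3779B97F4A7C15ULL;
    return mix64(state);
  }
  // unbiased draw in [0, n) by rejection
  uint64_t bounded(uint64_t n) {
    uint64_t t = (-n) % n;  // 2^64 mod n
    uint64_t r;
    do { r = next(); } while (r < t);
    return r % n;
  }
  // double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // Poisson by Knuth's product method (lambda is small in all uses)
  int poisson(double lambda) {
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

struct RngSuite {
  uint64_t master;
  std::vector<RngStream> streams;
};

// [[Rcpp::export]]
SEXP cpp_suite_new(double master_seed, int n_streams) {
  RngSuite* s = new RngSuite();
  s->master = (uint64_t)master_seed;
  s->streams.resize(n_streams);
  for (int i = 0; i < n_streams; ++i) s->streams[i].seed(s->master, (uint64_t)i);
  XPtr<RngSuite> p(s, true);
  return p;
}

static RngStream& stream_of(SEXP suite, int vp) {
  XPtr<RngSuite> s(suite);
  if (vp < 0 || vp >= (int)s->streams.size())
    stop("stream index out of range");
  return s->streams[vp];
}

// [[Rcpp::export]]
NumericVector cpp_suite_draw_index(SEXP suite, int vp, int n_draws, double upper) {
  if (upper < 1) stop("empty source population: upper must be >= 1");
  RngStream& st = stream_of(suite, vp);
  NumericVector out(n_draws);
  for (int i = 0; i < n_draws; ++i) out[i] = (double)st.bounded((uint64_t)upper);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_suite_draw_poisson(SEXP suite, int vp, int n_draws, double lambda) {
  RngStream& st = stream_of(suite, vp);
  IntegerVector out(n_draws);
  for (int i = 0; i < n_draws; ++i) out[i] = st.poisson(lambda);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_suite_draw_unif(SEXP suite, int vp, int n_draws) {
  RngStream& st = stream_of(suite, vp);
  NumericVector out(n_draws);
  for (int i = 0; i < n_draws; ++i) out[i] = st.unif();
  return out;
}

// [[Rcpp::export]]
double cpp_derive_seed(double master_seed, int idx) {
  RngStream st;
  st.seed((uint64_t)master_seed, (uint64_t)idx);
  // expose the derived state truncated to 53 bits (documentation/testing aid)
  return (double)(st.state >> 11);
}

// ---------------------------------------------------------------------------
// Connection store. One VpStore per virtual process held by this store
// (all VPs for a full build, one rank's share for a dryrun).
//
// Connector state per (source, synapse type):
//   count < K_cutoff : homogeneous fixed-size connector (capacity == count)
//   count >= K_cutoff: homogeneous dynamic connector, capacity K_cutoff * 2^j
// Two or more types : heterogeneous connector of homogeneous sub-connectors.
//
// Ledger rules (modeled allocations/frees, not the host heap):
//   first connection of a source: 1 alloc (one-element connector)
//                                 + 1 alloc + 1 free (sparse-table registration)
//   growth below K_cutoff:        1 alloc + 1 free (replace fixed connector)
//   transition to dynamic:        1 alloc + 1 free
//   each capacity doubling:       1 alloc + 1 free
//   first connection of an additional type:
//     heterogeneous conversion (1 alloc + 1 free, only on 1 -> 2 types)
//     + new one-element sub-connector (1 alloc)

struct Rec {
  long long target;
  int type;
  double weight, delay;
};

struct SubConn {
  int type;
  long long count, cap;
};

struct Conn {
  std::vector<SubConn> subs;
  long long total = 0;
  std::vector<Rec> recs;  // only when retain_records
};

struct VpStore {
  std::unordered_map<long long, Conn> table;
  long long n_alloc = 0, n_free = 0;
  std::vector<unsigned char> events;  // 1 = alloc, 0 = free (retain_events)
  // cumulative phase counters
  long long outer_iterations = 0, nonlocal_skips = 0, source_draws = 0,
            connect_calls = 0, membership_tests = 0;
};

struct Store {
  int VP;
  long long k_cutoff;
  bool retain_records, retain_events;
  std::vector<int> vp_ids;            // ascending
  std::unordered_map<int, int> slot;  // vp id -> index in stores
  std::vector<VpStore> stores;
};

static inline void ev(Store& S, VpStore& st, bool alloc) {
  if (alloc) st.n_alloc++; else st.n_free++;
  if (S.retain_events) st.events.push_back(alloc ? 1 : 0);
}

static void add_conn(Store& S, VpStore& st, long long source, long long target,
                     int type, double weight, double delay) {
  auto it = st.table.find(source);
  if (it == st.table.end()) {
    Conn c;
    c.total = 1;
    c.subs.push_back({type, 1, 1});
    ev(S, st, true);              // one-element connector
    ev(S, st, true); ev(S, st, false);  // sparse-table registration
    it = st.table.emplace(source, std::move(c)).first;
  } else {
    Conn& c = it->second;
    int si = -1;
    for (size_t i = 0; i < c.subs.size(); ++i)
      if (c.subs[i].type == type) { si = (int)i; break; }
    if (si < 0) {
      if (c.subs.size() == 1) { ev(S, st, true); ev(S, st, false); }  // het conversion
      c.subs.push_back({type, 1, 1});
      ev(S, st, true);  // new one-element sub-connector
      c.total++;
    } else {
      SubConn& sc = c.subs[si];
      long long k = sc.count + 1;
      if (k < S.k_cutoff) {
        ev(S, st, true); ev(S, st, false);  // replace fixed connector
        sc.cap = k;
      } else if (k == S.k_cutoff) {
        ev(S, st, true); ev(S, st, false);  // fixed -> dynamic
        sc.cap = S.k_cutoff;
      } else if (k > sc.cap) {
        sc.cap *= 2;                        // capacity doubling
        ev(S, st, true); ev(S, st, false);
      }
      sc.count = k;
      c.total++;
    }
  }
  if (S.retain_records) it->second.recs.push_back({target, type, weight, delay});
}

// [[Rcpp::export]]
SEXP cpp_store_new(IntegerVector vp_ids, int VP, double k_cutoff,
                   bool retain_records, bool retain_events) {
  Store* s = new Store();
  s->VP = VP;
  s->k_cutoff = (long long)k_cutoff;
  s->retain_records = retain_records;
  s->retain_events = retain_events;
  s->vp_ids.assign(vp_ids.begin(), vp_ids.end());
  std::sort(s->vp_ids.begin(), s->vp_ids.end());
  s->stores.resize(s->vp_ids.size());
  for (size_t i = 0; i < s->vp_ids.size(); ++i) s->slot[s->vp_ids[i]] = (int)i;
  XPtr<Store> p(s, true);
  return p;
}

static VpStore& vp_store(Store& S, int vp) {
  auto it = S.slot.find(vp);
  if (it == S.slot.end()) stop("virtual process %d not held by this store", vp);
  return S.stores[it->second];
}

// [[Rcpp::export]]
void cpp_store_add(SEXP store, double source, double target, int type,
                   double weight, double delay) {
  XPtr<Store> S(store);
  long long tgt = (long long)target;
  int vp = (int)(tgt % S->VP);
  auto it = S->slot.find(vp);
  if (it == S->slot.end())
    stop("locality violation: target %.0f belongs to virtual process %d, not held by this store",
         target, vp);
  add_conn(*S, S->stores[it->second], (long long)source, tgt, type, weight, delay);
}

// [[Rcpp::export]]
NumericVector cpp_store_ledger(SEXP store, int vp) {
  XPtr<Store> S(store);
  VpStore& st = vp_store(*S, vp);
  return NumericVector::create(_["n_alloc"] = (double)st.n_alloc,
                               _["n_free"] = (double)st.n_free);
}

// [[Rcpp::export]]
IntegerVector cpp_store_events(SEXP store, int vp) {
  XPtr<Store> S(store);
  VpStore& st = vp_store(*S, vp);
  return IntegerVector(st.events.begin(), st.events.end());
}

// [[Rcpp::export]]
NumericMatrix cpp_store_counters(SEXP store) {
  XPtr<Store> S(store);
  int n = (int)S->vp_ids.size();
  NumericMatrix m(n, 6);
  for (int i = 0; i < n; ++i) {
    VpStore& st = S->stores[i];
    m(i, 0) = S->vp_ids[i];
    m(i, 1) = (double)st.outer_iterations;
    m(i, 2) = (double)st.nonlocal_skips;
    m(i, 3) = (double)st.source_draws;
    m(i, 4) = (double)st.connect_calls;
    m(i, 5) = (double)st.membership_tests;
  }
  colnames(m) = CharacterVector::create("vp", "outer_iterations", "nonlocal_skips",
                                        "source_draws", "connect_calls",
                                        "membership_tests");
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_store_census(SEXP store, int vp, double total_sources) {
  XPtr<Store> S(store);
  VpStore& st = vp_store(*S, vp);
  long long lim = (long long)total_sources, n1 = 0, nm = 0;
  for (auto& kv : st.table) {
    if (kv.first >= lim) continue;
    if (kv.second.total == 1) n1++; else nm++;
  }
  return NumericVector::create(_["n0"] = (double)(lim - n1 - nm),
                               _["n1"] = (double)n1,
                               _["n_more"] = (double)nm);
}

// [[Rcpp::export]]
List cpp_store_connector(SEXP store, int vp, double source) {
  XPtr<Store> S(store);
  VpStore& st = vp_store(*S, vp);
  auto it = st.table.find((long long)source);
  if (it == st.table.end())
    return List::create(_["kind"] = "absent", _["K_old"] = 0.0);
  Conn& c = it->second;
  std::string kind;
  if (c.subs.size() >= 2) kind = "heterogeneous";
  else if (c.subs[0].count < S->k_cutoff) kind = "hom_fixed";
  else kind = "hom_dynamic";
  int n = (int)c.subs.size();
  IntegerVector types(n);
  NumericVector counts(n), caps(n);
  for (int i = 0; i < n; ++i) {
    types[i] = c.subs[i].type;
    counts[i] = (double)c.subs[i].count;
    caps[i] = (double)c.subs[i].cap;
  }
  return List::create(_["kind"] = kind, _["K_old"] = (double)c.total,
                      _["types"] = types, _["counts"] = counts,
                      _["capacities"] = caps);
}

// [[Rcpp::export]]
NumericVector cpp_store_sources(SEXP store, int vp) {
  XPtr<Store> S(store);
  VpStore& st = vp_store(*S, vp);
  std::vector<long long> keys;
  keys.reserve(st.table.size());
  for (auto& kv : st.table) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  NumericVector out(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) out[i] = (double)keys[i];
  return out;
}

// [[Rcpp::export]]
double cpp_store_n_records(SEXP store) {
  XPtr<Store> S(store);
  long long n = 0;
  for (auto& st : S->stores)
    for (auto& kv : st.table) n += kv.second.total;
  return (double)n;
}

// [[Rcpp::export]]
List cpp_store_targets_of(SEXP store, int vp, double source, int type) {
  XPtr<Store> S(store);
  if (!S->retain_records) stop("store was built without retained records");
  VpStore& st = vp_store(*S, vp);
  auto it = st.table.find((long long)source);
  std::vector<double> tg, wt, dl;
  std::vector<int> ty;
  if (it != st.table.end()) {
    for (auto& r : it->second.recs) {
      if (type >= 0 && r.type != type) continue;
      tg.push_back((double)r.target);
      ty.push_back(r.type);
      wt.push_back(r.weight);
      dl.push_back(r.delay);
    }
  }
  return List::create(_["target"] = tg, _["type"] = ty,
                      _["weight"] = wt, _["delay"] = dl);
}

// [[Rcpp::export]]
List cpp_store_edges(SEXP store, int vp) {
  XPtr<Store> S(store);
  if (!S->retain_records) stop("store was built without retained records");
  VpStore& st = vp_store(*S, vp);
  std::vector<long long> keys;
  keys.reserve(st.table.size());
  for (auto& kv : st.table) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  std::vector<double> src, tg, wt, dl;
  std::vector<int> ty;
  for (long long k : keys) {
    Conn& c = st.table[k];
    for (auto& r : c.recs) {
      src.push_back((double)k);
      tg.push_back((double)r.target);
      ty.push_back(r.type);
      wt.push_back(r.weight);
      dl.push_back(r.delay);
    }
  }
  return List::create(_["source"] = src, _["target"] = tg, _["type"] = ty,
                      _["weight"] = wt, _["delay"] = dl);
}

// ---------------------------------------------------------------------------
// Wiring loops. Gid sets are either a contiguous half-open range
// [first, first + count) or an explicit ascending list (targets) /
// as-given list (sources; list order defines the draw index mapping).

struct GidSet {
  bool is_range;
  long long first, count;
  std::vector<long long> list;
  long long size() const { return is_range ? count : (long long)list.size(); }
  long long at(long long i) const { return is_range ? first + i : list[i]; }
  bool contains(long long g) const {
    if (is_range) return g >= first && g < first + count;
    return std::binary_search(list.begin(), list.end(), g);
  }
};

static GidSet make_set(double first, double count, NumericVector list,
                       bool is_range) {
  GidSet s;
  s.is_range = is_range;
  s.first = (long long)first;
  s.count = (long long)count;
  if (!is_range) {
    s.list.reserve(list.size());
    for (double v : list) s.list.push_back((long long)v);
  }
  return s;
}

// first gid >= lo owned by vp (round-robin over VP)
static inline long long first_local(long long lo, int vp, int VP) {
  long long r = lo % VP;
  long long off = ((long long)vp - r) % VP;
  if (off < 0) off += VP;
  return lo + off;
}

// [[Rcpp::export]]
void cpp_connect_fixed_indegree(SEXP store, SEXP suite,
                                double src_first, double src_count,
                                NumericVector src_list, bool src_is_range,
                                double tgt_first, double tgt_count,
                                NumericVector tgt_list, bool tgt_is_range,
                                double uni_first, double uni_count,
                                int K, int type, double weight, double delay,
                                bool local_scan) {
  XPtr<Store> S(store);
  XPtr<RngSuite> Rs(suite);
  GidSet src = make_set(src_first, src_count, src_list, src_is_range);
  GidSet tgt = make_set(tgt_first, tgt_count, tgt_list, tgt_is_range);
  long long nsrc = src.size();
  if (nsrc < 1 && K > 0) stop("empty source set with K > 0");
  int VP = S->VP;
  for (size_t s = 0; s < S->vp_ids.size(); ++s) {
    int vp = S->vp_ids[s];
    VpStore& st = S->stores[s];
    RngStream& rng = Rs->streams[vp];
    if (!local_scan) {
      // target scan: iterate every target, skip non-local ones
      long long nt = tgt.size();
      st.outer_iterations += nt;
      for (long long j = 0; j < nt; ++j) {
        long long t = tgt.at(j);
        if (t % VP != vp) { st.nonlocal_skips++; continue; }
        for (int k = 0; k < K; ++k) {
          long long srcgid = src.at((long long)rng.bounded((uint64_t)nsrc));
          add_conn(*S, st, srcgid, t, type, weight, delay);
          st.source_draws++;
          st.connect_calls++;
        }
      }
    } else {
      // local scan: iterate this VP's nodes of the universe, test membership
      long long lo = (long long)uni_first, n = (long long)uni_count;
      for (long long g = first_local(lo, vp, VP); g < lo + n; g += VP) {
        st.outer_iterations++;
        st.membership_tests++;
        if (!tgt.contains(g)) { st.nonlocal_skips++; continue; }
        for (int k = 0; k < K; ++k) {
          long long srcgid = src.at((long long)rng.bounded((uint64_t)nsrc));
          add_conn(*S, st, srcgid, g, type, weight, delay);
          st.source_draws++;
          st.connect_calls++;
        }
      }
    }
  }
}

// [[Rcpp::export]]
void cpp_connect_all_to_all(SEXP store,
                            double src_first, double src_count,
                            NumericVector src_list, bool src_is_range,
                            double tgt_first, double tgt_count,
                            NumericVector tgt_list, bool tgt_is_range,
                            double uni_first, double uni_count,
                            int type, double weight, double delay,
                            bool local_scan) {
  XPtr<Store> S(store);
  GidSet src = make_set(src_first, src_count, src_list, src_is_range);
  GidSet tgt = make_set(tgt_first, tgt_count, tgt_list, tgt_is_range);
  long long nsrc = src.size();
  int VP = S->VP;
  for (size_t s = 0; s < S->vp_ids.size(); ++s) {
    int vp = S->vp_ids[s];
    VpStore& st = S->stores[s];
    if (!local_scan) {
      long long nt = tgt.size();
      st.outer_iterations += nt;
      for (long long j = 0; j < nt; ++j) {
        long long t = tgt.at(j);
        if (t % VP != vp) { st.nonlocal_skips++; continue; }
        for (long long i = 0; i < nsrc; ++i) {
          add_conn(*S, st, src.at(i), t, type, weight, delay);
          st.connect_calls++;
        }
      }
    } else {
      long long lo = (long long)uni_first, n = (long long)uni_count;
      for (long long g = first_local(lo, vp, VP); g < lo + n; g += VP) {
        st.outer_iterations++;
        st.membership_tests++;
        if (!tgt.contains(g)) { st.nonlocal_skips++; continue; }
        for (long long i = 0; i < nsrc; ++i) {
          add_conn(*S, st, src.at(i), g, type, weight, delay);
          st.connect_calls++;
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Single-VP occupancy Monte Carlo: `draws` uniform source draws over
// [0, N); tally sources hit 0 / 1 / >1 times. Replicate r uses stream
// index r of a suite seeded with master_seed.

// [[Rcpp::export]]
NumericMatrix cpp_occupancy_mc(double N, double draws, int replicates,
                               double master_seed) {
  NumericMatrix out(replicates, 3);
  colnames(out) = CharacterVector::create("n0", "n1", "n_more");
  long long n = (long long)N, d = (long long)draws;
  for (int r = 0; r < replicates; ++r) {
    RngStream st;
    st.seed((uint64_t)master_seed, (uint64_t)r);
    std::unordered_map<long long, int> hits;
    hits.reserve((size_t)std::min<long long>(d, n) * 2);
    for (long long i = 0; i < d; ++i) hits[(long long)st.bounded((uint64_t)n)]++;
    long long n1 = 0, nm = 0;
    for (auto& kv : hits) {
      if (kv.second == 1) n1++; else nm++;
    }
    out(r, 0) = (double)(n - n1 - nm);
    out(r, 1) = (double)n1;
    out(r, 2) = (double)nm;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
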