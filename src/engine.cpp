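// Core compression engine: order-k finite-context models (FCM), substitution-
// tolerant context models (STCM), repeat/copy models with a bounded k-mer
// cache-table, soft-blending mixture, and a 32-bit arithmetic coder.
//
// The same model pipeline runs on the encoder and the decoder; all floating
// point is evaluated in an identical order on both sides, which together with
// the 16-bit quantization of the blended distribution gives bit-exact
// encoder/decoder symmetry.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Bit I/O
// ---------------------------------------------------------------------------

struct BitWriter {
  std::vector<uint8_t> bytes;
  uint8_t cur = 0;
  int nfill = 0;
  void put(int b) {
    cur = (uint8_t)((cur << 1) | (b & 1));
    if (++nfill == 8) { bytes.push_back(cur); cur = 0; nfill = 0; }
  }
  void flush() { while (nfill != 0) put(0); }
};

struct BitReader {
  const uint8_t *data;
  size_t nbytes;
  size_t bitpos = 0;
  BitReader(const uint8_t *d, size_t n) : data(d), nbytes(n) {}
  int get() {
    if (bitpos >= nbytes * 8) { bitpos++; return 0; } // zero-padding past end
    int b = (data[bitpos >> 3] >> (7 - (bitpos & 7))) & 1;
    bitpos++;
    return b;
  }
};

// ---------------------------------------------------------------------------
// 32-bit arithmetic coder (carry-less renormalization via pending bits).
// Cumulative frequencies cl < ch <= tot, tot <= 1<<16.
// ---------------------------------------------------------------------------

static const uint32_t AC_HALF = 0x80000000u;
static const uint32_t AC_QTR  = 0x40000000u;
static const uint32_t AC_3QTR = 0xC0000000u;

struct ArEncoder {
  uint32_t low = 0, high = 0xFFFFFFFFu;
  uint64_t pending = 0;
  BitWriter bw;
  void emit(int b) {
    bw.put(b);
    while (pending > 0) { bw.put(!b); pending--; }
  }
  void encode(uint32_t cl, uint32_t ch, uint32_t tot) {
    uint64_t range = (uint64_t)high - low + 1;
    high = low + (uint32_t)((range * ch) / tot) - 1;
    low  = low + (uint32_t)((range * cl) / tot);
    for (;;) {
      if (high < AC_HALF) {
        emit(0);
      } else if (low >= AC_HALF) {
        emit(1); low -= AC_HALF; high -= AC_HALF;
      } else if (low >= AC_QTR && high < AC_3QTR) {
        pending++; low -= AC_QTR; high -= AC_QTR;
      } else break;
      low <<= 1;
      high = (high << 1) | 1;
    }
  }
  std::vector<uint8_t> finish() {
    pending++;
    emit(low >= AC_QTR ? 1 : 0);
    bw.flush();
    return bw.bytes;
  }
};

struct ArDecoder {
  uint32_t low = 0, high = 0xFFFFFFFFu, value = 0;
  BitReader br;
  ArDecoder(const uint8_t *d, size_t n) : br(d, n) {
    for (int i = 0; i < 32; i++) value = (value << 1) | br.get();
  }
  uint32_t target(uint32_t tot) {
    uint64_t range = (uint64_t)high - low + 1;
    return (uint32_t)((((uint64_t)(value - low) + 1) * tot - 1) / range);
  }
  void update(uint32_t cl, uint32_t ch, uint32_t tot) {
    uint64_t range = (uint64_t)high - low + 1;
    high = low + (uint32_t)((range * ch) / tot) - 1;
    low  = low + (uint32_t)((range * cl) / tot);
    for (;;) {
      if (high < AC_HALF) {
        // nothing
      } else if (low >= AC_HALF) {
        low -= AC_HALF; high -= AC_HALF; value -= AC_HALF;
      } else if (low >= AC_QTR && high < AC_3QTR) {
        low -= AC_QTR; high -= AC_QTR; value -= AC_QTR;
      } else break;
      low <<= 1;
      high = (high << 1) | 1;
      value = (value << 1) | br.get();
    }
  }
};

// ---------------------------------------------------------------------------
// Quantization of a 4-symbol double distribution to 16-bit frequencies.
// Deterministic: f[s] = floor(p[s]*65532)+1 for s<3, f[3] takes the remainder
// (always >= 1 when sum(p) == 1), so every symbol stays codable.
// ---------------------------------------------------------------------------

static const uint32_t QTOT = 65536u;

static inline void quantize4(const double *p, uint32_t *f) {
  uint32_t acc = 0;
  for (int s = 0; s < 3; s++) {
    f[s] = (uint32_t)(p[s] * 65532.0) + 1u;
    acc += f[s];
  }
  f[3] = QTOT - acc;
}

// ---------------------------------------------------------------------------
// Count tables (8-bit counters, halve-on-saturation at width 255).
// Direct-indexed when 2k <= max_table_bits, multiplicative hash otherwise
// (fixed odd constant, power-of-two table, collisions silently shared).
// ---------------------------------------------------------------------------

static const uint64_t HASH_MULT = 0x9E3779B97F4A7C15ull;

struct CountTable {
  int k;
  int table_bits;      // log2 of number of context slots
  bool hashed;
  uint8_t counter_width;
  std::vector<uint8_t> counts; // 4 per context slot

  void init(int k_, int max_table_bits, int width) {
    k = k_;
    counter_width = (uint8_t)width;
    if (2 * k <= max_table_bits) {
      hashed = false;
      table_bits = 2 * k;
    } else {
      hashed = true;
      table_bits = max_table_bits;
    }
    counts.assign(((size_t)1 << table_bits) * 4, 0);
  }
  inline size_t slot(uint64_t ctx) const {
    if (!hashed) return (size_t)ctx;
    return (size_t)((ctx * HASH_MULT) >> (64 - table_bits));
  }
  inline const uint8_t *row(uint64_t ctx) const { return &counts[slot(ctx) * 4]; }
  inline void update(uint64_t ctx, int sym) {
    uint8_t *r = &counts[slot(ctx) * 4];
    r[sym]++;
    if (r[sym] >= counter_width) {
      r[0] >>= 1; r[1] >>= 1; r[2] >>= 1; r[3] >>= 1;
    }
  }
};

static inline void fcm_dist(const CountTable &tab, uint64_t ctx, double alpha,
                            double *p) {
  const uint8_t *r = tab.row(ctx);
  double tot = (double)r[0] + r[1] + r[2] + r[3] + 4.0 * alpha;
  p[0] = (r[0] + alpha) / tot;
  p[1] = (r[1] + alpha) / tot;
  p[2] = (r[2] + alpha) / tot;
  p[3] = (r[3] + alpha) / tot;
}

static inline int table_argmax(const CountTable &tab, uint64_t ctx) {
  const uint8_t *r = tab.row(ctx);
  int best = 0;
  for (int s = 1; s < 4; s++) if (r[s] > r[best]) best = s;
  return best; // ties broken toward the lowest symbol index
}

// ---------------------------------------------------------------------------
// Engine configuration
// ---------------------------------------------------------------------------

struct FcmCfg  { int k; double alpha; bool ir; };
struct StcmCfg { int k; double alpha; int t; int share; }; // share: 0-based fcm idx, -1 private

struct RmCfg {
  bool enabled = false;
  int k = 13, c = 8;
  double beta = 0.9, limit = 7.0;
  int lut_max = 200;
  int n_models = 1;
  uint32_t lcg_seed = 1;
};

struct EngineCfg {
  std::vector<FcmCfg> fcms;
  std::vector<StcmCfg> stcms;
  RmCfg rm;
  std::vector<double> gammas;
  double weight_floor = 1e-6;
  double prob_floor = 1.0 / 65536.0;
  int max_table_bits = 24;
  int counter_width = 255;
};

// ---------------------------------------------------------------------------
// Repeat-model machinery
// ---------------------------------------------------------------------------

struct RepeatSlot {
  bool active = false;
  uint64_t ptr = 0;
  uint32_t Nh = 0, Nm = 0;
  double Y = 0.0;
};

struct HitLut {
  int lut_max;
  std::vector<double> p_hit, p_other; // indexed Nh*(lut_max+1)+Nm
  void build(int m) {
    lut_max = m;
    p_hit.assign((size_t)(m + 1) * (m + 1), 0.0);
    p_other.assign((size_t)(m + 1) * (m + 1), 0.0);
    for (int nh = 0; nh <= m; nh++)
      for (int nm = 0; nm + nh <= m; nm++) {
        double ph = (nh + 1.0) / (nh + nm + 2.0);
        p_hit[(size_t)nh * (m + 1) + nm] = ph;
        p_other[(size_t)nh * (m + 1) + nm] = (1.0 - ph) / 3.0;
      }
  }
  inline void get(uint32_t nh, uint32_t nm, double &ph, double &po) const {
    if ((int)(nh + nm) <= lut_max) {
      ph = p_hit[(size_t)nh * (lut_max + 1) + nm];
      po = p_other[(size_t)nh * (lut_max + 1) + nm];
    } else { // beyond the table bound: analytic, same closed form
      ph = (nh + 1.0) / (nh + nm + 2.0);
      po = (1.0 - ph) / 3.0;
    }
  }
};

struct Lcg {
  uint32_t state;
  uint32_t next() {
    state = 1664525u * state + 1013904223u; // classic Numerical-Recipes LCG, mod 2^32
    return state;
  }
};

// ---------------------------------------------------------------------------
// The engine proper
// ---------------------------------------------------------------------------

struct Engine {
  EngineCfg cfg;
  int nf, ns, nr, M;

  std::vector<CountTable> fcm_tabs;
  std::vector<uint64_t> fcm_ctx, fcm_mask;
  std::vector<uint64_t> fcm_irctx; // reverse-complement rolling context

  std::vector<CountTable> stcm_priv;          // private tables (share == -1)
  std::vector<int> stcm_tab;                  // index into fcm_tabs, or -1
  std::vector<uint64_t> stcm_ctx, stcm_true, stcm_mask;
  std::vector<int> stcm_subs;

  HitLut lut;
  std::vector<RepeatSlot> slots;
  std::unordered_map<uint32_t, std::vector<uint32_t>> cache;
  Lcg lcg;
  uint64_t rm_kmer = 0, rm_mask = 0;

  std::vector<double> w;          // mixer weights
  std::vector<double> dists;      // M x 4 scratch
  double blend[4];

  std::vector<int> hist;          // recent symbols for IR updates
  size_t hist_len = 0;
  int hist_cap = 0;

  std::vector<int> seq;           // symbols seen/decoded so far (repeat pointers)
  uint64_t pos = 0;

  void init(const EngineCfg &c, uint64_t n_expected) {
    cfg = c;
    nf = (int)cfg.fcms.size();
    ns = (int)cfg.stcms.size();
    nr = cfg.rm.enabled ? cfg.rm.n_models : 0;
    M = nf + ns + nr;
    if (M == 0) stop("engine needs at least one model");
    if ((int)cfg.gammas.size() != M) stop("gammas length must equal model count");

    fcm_tabs.resize(nf);
    fcm_ctx.assign(nf, 0); fcm_irctx.assign(nf, 0); fcm_mask.resize(nf);
    int max_k = 0;
    for (int i = 0; i < nf; i++) {
      fcm_tabs[i].init(cfg.fcms[i].k, cfg.max_table_bits, cfg.counter_width);
      fcm_mask[i] = (cfg.fcms[i].k >= 32) ? ~0ull : (((uint64_t)1 << (2 * cfg.fcms[i].k)) - 1);
      if (cfg.fcms[i].k > max_k) max_k = cfg.fcms[i].k;
    }
    stcm_tab.assign(ns, -1);
    stcm_ctx.assign(ns, 0); stcm_true.assign(ns, 0); stcm_mask.resize(ns);
    stcm_subs.assign(ns, 0);
    for (int i = 0; i < ns; i++) {
      stcm_mask[i] = (((uint64_t)1 << (2 * cfg.stcms[i].k)) - 1);
      if (cfg.stcms[i].share >= 0) {
        if (cfg.stcms[i].share >= nf) stop("stcm share index out of range");
        if (cfg.fcms[cfg.stcms[i].share].k != cfg.stcms[i].k)
          stop("stcm must share a table with an fcm of the same order");
        stcm_tab[i] = cfg.stcms[i].share;
      } else {
        stcm_priv.emplace_back();
        stcm_priv.back().init(cfg.stcms[i].k, cfg.max_table_bits, cfg.counter_width);
        stcm_tab[i] = -(int)stcm_priv.size(); // -1 -> priv[0], -2 -> priv[1], ...
      }
    }
    if (cfg.rm.enabled) {
      if (cfg.rm.k > 15) stop("repeat-model k > 15 is not supported (cache-table bound)");
      lut.build(cfg.rm.lut_max);
      slots.assign(nr, RepeatSlot());
      lcg.state = cfg.rm.lcg_seed;
      rm_mask = (((uint64_t)1 << (2 * cfg.rm.k)) - 1);
      cache.reserve(std::min<uint64_t>(n_expected, 1u << 20));
    }
    w.assign(M, 1.0 / M);
    dists.assign((size_t)M * 4, 0.0);
    hist_cap = max_k + 2;
    hist.assign(std::max(hist_cap, 1), 0);
    seq.reserve(n_expected);
  }

  inline const CountTable &stcm_table(int i) const {
    int t = stcm_tab[i];
    return t >= 0 ? fcm_tabs[t] : stcm_priv[-t - 1];
  }

  // fill dists (M x 4) for the current position and compute the blend
  void predict() {
    for (int i = 0; i < nf; i++)
      fcm_dist(fcm_tabs[i], fcm_ctx[i] & fcm_mask[i], cfg.fcms[i].alpha,
               &dists[(size_t)i * 4]);
    for (int i = 0; i < ns; i++)
      fcm_dist(stcm_table(i), stcm_ctx[i] & stcm_mask[i], cfg.stcms[i].alpha,
               &dists[(size_t)(nf + i) * 4]);
    for (int j = 0; j < nr; j++) {
      double *d = &dists[(size_t)(nf + ns + j) * 4];
      RepeatSlot &rs = slots[j];
      if (cfg.rm.enabled && rs.active) {
        int pred = seq[(size_t)rs.ptr];
        double ph, po;
        lut.get(rs.Nh, rs.Nm, ph, po);
        d[0] = po; d[1] = po; d[2] = po; d[3] = po;
        d[pred] = ph;
      } else {
        d[0] = d[1] = d[2] = d[3] = 0.25; // idle slot: uninformative
      }
    }
    double tot = 0.0;
    for (int s = 0; s < 4; s++) {
      double acc = 0.0;
      for (int m = 0; m < M; m++) acc += w[m] * dists[(size_t)m * 4 + s];
      blend[s] = acc;
      tot += acc;
    }
    for (int s = 0; s < 4; s++) {
      blend[s] /= tot;
      if (blend[s] < cfg.prob_floor) blend[s] = cfg.prob_floor;
    }
    tot = blend[0] + blend[1] + blend[2] + blend[3];
    for (int s = 0; s < 4; s++) blend[s] /= tot;
  }

  void update(int sym) {
    // mixer: w <- w^gamma * P_m(sym); normalize; floor; renormalize
    double tot = 0.0;
    for (int m = 0; m < M; m++) {
      w[m] = std::pow(w[m], cfg.gammas[m]) * dists[(size_t)m * 4 + sym];
      tot += w[m];
    }
    for (int m = 0; m < M; m++) {
      w[m] /= tot;
      if (w[m] < cfg.weight_floor) w[m] = cfg.weight_floor;
    }
    tot = 0.0;
    for (int m = 0; m < M; m++) tot += w[m];
    for (int m = 0; m < M; m++) w[m] /= tot;

    // FCM updates (+ inverted-repeat event folded into the same table)
    for (int i = 0; i < nf; i++) {
      int k = cfg.fcms[i].k;
      fcm_tabs[i].update(fcm_ctx[i] & fcm_mask[i], sym);
      if (cfg.fcms[i].ir) {
        fcm_irctx[i] = ((fcm_irctx[i] >> 2) |
                        ((uint64_t)(3 - sym) << (2 * (k - 1)))) & fcm_mask[i];
        if (pos >= (uint64_t)k) {
          int out = hist[(hist_len - k) % hist_cap]; // x[i-k]
          fcm_tabs[i].update(fcm_irctx[i], 3 - out);
        }
      }
      fcm_ctx[i] = ((fcm_ctx[i] << 2) | (uint64_t)sym) & fcm_mask[i];
    }

    // STCM updates
    for (int i = 0; i < ns; i++) {
      uint64_t newtrue = ((stcm_true[i] << 2) | (uint64_t)sym) & stcm_mask[i];
      const CountTable &tab = stcm_table(i);
      int amax = table_argmax(tab, stcm_ctx[i] & stcm_mask[i]);
      if (stcm_tab[i] < 0) // private table: learn the propagated symbol
        stcm_priv[-stcm_tab[i] - 1].update(stcm_ctx[i] & stcm_mask[i],
                                           sym == amax ? sym : amax);
      if (sym == amax) {
        if (stcm_subs[i] > 0) stcm_subs[i]--;
        stcm_ctx[i] = ((stcm_ctx[i] << 2) | (uint64_t)sym) & stcm_mask[i];
      } else {
        stcm_subs[i]++;
        if (stcm_subs[i] > cfg.stcms[i].t) {
          stcm_ctx[i] = newtrue;
          stcm_subs[i] = 0;
        } else {
          stcm_ctx[i] = ((stcm_ctx[i] << 2) | (uint64_t)amax) & stcm_mask[i];
        }
      }
      stcm_true[i] = newtrue;
    }

    // repeat models: hit/miss bookkeeping, Eq. 3 decay, stop rule
    if (cfg.rm.enabled) {
      for (int j = 0; j < nr; j++) {
        RepeatSlot &rs = slots[j];
        if (!rs.active) continue;
        bool hit = (seq[(size_t)rs.ptr] == sym);
        if (hit) rs.Nh++; else rs.Nm++;
        rs.ptr++;
        rs.Y = (hit ? 0.0 : 1.0) + cfg.rm.beta * rs.Y;
        if (rs.Y > cfg.rm.limit) rs.active = false;
      }
    }

    // bookkeeping shared by models
    seq.push_back(sym);
    hist[hist_len % hist_cap] = sym;
    hist_len++;
    pos++;

    // cache-table + possible repeat-model start on the k-mer ending here
    if (cfg.rm.enabled) {
      rm_kmer = ((rm_kmer << 2) | (uint64_t)sym) & rm_mask;
      if (pos >= (uint64_t)cfg.rm.k) {
        uint32_t key = (uint32_t)rm_kmer;
        int free_slot = -1;
        for (int j = 0; j < nr; j++)
          if (!slots[j].active) { free_slot = j; break; }
        if (free_slot >= 0) {
          auto it = cache.find(key);
          if (it != cache.end() && !it->second.empty()) {
            uint32_t pick = lcg.next() % (uint32_t)it->second.size();
            RepeatSlot &rs = slots[free_slot];
            rs.active = true;
            rs.ptr = (uint64_t)it->second[pick] + 1;
            rs.Nh = 0; rs.Nm = 0; rs.Y = 0.0;
          }
        }
        std::vector<uint32_t> &ring = cache[key];
        if ((int)ring.size() >= cfg.rm.c) ring.erase(ring.begin());
        ring.push_back((uint32_t)(pos - 1));
      }
    }
  }
};

// ---------------------------------------------------------------------------
// Config parsing from R
// ---------------------------------------------------------------------------

static EngineCfg parse_cfg(List cfg) {
  EngineCfg ec;
  if (cfg.containsElementNamed("fcm") && !Rf_isNull(cfg["fcm"])) {
    List f(cfg["fcm"]);
    IntegerVector k = f["k"];
    NumericVector alpha = f["alpha"];
    LogicalVector ir = f["ir"];
    for (int i = 0; i < k.size(); i++) {
      FcmCfg fc; fc.k = k[i]; fc.alpha = alpha[i]; fc.ir = ir[i];
      if (fc.k < 1 || fc.k > 28) stop("fcm order out of range");
      ec.fcms.push_back(fc);
    }
  }
  if (cfg.containsElementNamed("stcm") && !Rf_isNull(cfg["stcm"])) {
    List s(cfg["stcm"]);
    IntegerVector k = s["k"];
    NumericVector alpha = s["alpha"];
    IntegerVector t = s["t"];
    IntegerVector share = s["share"]; // 1-based into fcm, 0 = private
    for (int i = 0; i < k.size(); i++) {
      StcmCfg sc; sc.k = k[i]; sc.alpha = alpha[i]; sc.t = t[i];
      sc.share = share[i] - 1;
      ec.stcms.push_back(sc);
    }
  }
  if (cfg.containsElementNamed("rm") && !Rf_isNull(cfg["rm"])) {
    List r(cfg["rm"]);
    ec.rm.enabled = true;
    ec.rm.k = as<int>(r["k"]);
    ec.rm.c = as<int>(r["c"]);
    ec.rm.beta = as<double>(r["beta"]);
    ec.rm.limit = as<double>(r["limit"]);
    ec.rm.lut_max = as<int>(r["lut_max"]);
    ec.rm.n_models = as<int>(r["n_models"]);
    ec.rm.lcg_seed = (uint32_t)as<double>(r["lcg_seed"]);
  }
  ec.gammas = as<std::vector<double>>(cfg["gammas"]);
  if (cfg.containsElementNamed("weight_floor"))
    ec.weight_floor = as<double>(cfg["weight_floor"]);
  if (cfg.containsElementNamed("prob_floor"))
    ec.prob_floor = as<double>(cfg["prob_floor"]);
  if (cfg.containsElementNamed("max_table_bits"))
    ec.max_table_bits = as<int>(cfg["max_table_bits"]);
  return ec;
}

// ---------------------------------------------------------------------------
// Exported entry points: encode / decode / bits for the DNA symbol channel
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cx_engine_encode(IntegerVector syms, List cfg, bool want_bits = false) {
  Engine eng;
  eng.init(parse_cfg(cfg), syms.size());
  ArEncoder enc;
  double bits_sum = 0.0;
  NumericVector bits(want_bits ? syms.size() : 0);
  uint32_t f[4];
  for (R_xlen_t i = 0; i < syms.size(); i++) {
    int sym = syms[i];
    if (sym < 0 || sym > 3) stop("symbol out of alphabet at position %d", (int)(i + 1));
    eng.predict();
    quantize4(eng.blend, f);
    uint32_t cl = 0;
    for (int s = 0; s < sym; s++) cl += f[s];
    enc.encode(cl, cl + f[sym], QTOT);
    double b = -std::log2(eng.blend[sym]);
    bits_sum += b;
    if (want_bits) bits[i] = b;
    eng.update(sym);
  }
  std::vector<uint8_t> payload = enc.finish();
  RawVector out(payload.size());
  std::copy(payload.begin(), payload.end(), out.begin());
  List res = List::create(_["payload"] = out, _["bits_sum"] = bits_sum);
  if (want_bits) res["bits"] = bits;
  return res;
}

// [[Rcpp::export]]
List cx_engine_decode(RawVector payload, int n, List cfg) {
  Engine eng;
  eng.init(parse_cfg(cfg), n);
  ArDecoder dec(payload.size() ? (const uint8_t *)RAW(payload) : (const uint8_t *)"",
                payload.size());
  IntegerVector out(n);
  double bits_sum = 0.0;
  uint32_t f[4];
  for (int i = 0; i < n; i++) {
    eng.predict();
    quantize4(eng.blend, f);
    uint32_t tgt = dec.target(QTOT);
    uint32_t cl = 0;
    int sym = 0;
    while (sym < 3 && cl + f[sym] <= tgt) { cl += f[sym]; sym++; }
    dec.update(cl, cl + f[sym], QTOT);
    bits_sum += -std::log2(eng.blend[sym]);
    out[i] = sym;
    eng.update(sym);
  }
  return List::create(_["symbols"] = out, _["bits_sum"] = bits_sum);
}

// [[Rcpp::export]]
NumericVector cx_engine_bits(IntegerVector syms, List cfg) {
  Engine eng;
  eng.init(parse_cfg(cfg), syms.size());
  NumericVector bits(syms.size());
  for (R_xlen_t i = 0; i < syms.size(); i++) {
    int sym = syms[i];
    if (sym < 0 || sym > 3) stop("symbol out of alphabet at position %d", (int)(i + 1));
    eng.predict();
    bits[i] = -std::log2(eng.blend[sym]);
    eng.update(sym);
  }
  return bits;
}

// ---------------------------------------------------------------------------
// Generic adaptive order-k byte coder for side channels (headers, qualities,
// exceptions, case-mask, layout). Hashed contexts, lazily allocated counts.
// ---------------------------------------------------------------------------

struct ByteModel {
  int order;
  int hash_bits;
  uint32_t inc = 24;
  uint32_t max_total = 60000;
  std::unordered_map<uint32_t, std::vector<uint16_t>> tabs;
  std::unordered_map<uint32_t, uint32_t> totals;
  std::vector<uint8_t> hist;

  ByteModel(int o, int hb) : order(o), hash_bits(hb) { hist.assign(o > 0 ? o : 1, 0); }

  uint32_t ctx_key(size_t npast) const {
    uint64_t h = 0;
    int take = order < (int)npast ? order : (int)npast;
    for (int j = 0; j < take; j++)
      h = h * 131 + hist[(npast - 1 - j) % hist.size()];
    return (uint32_t)(((h + 1) * HASH_MULT) >> (64 - hash_bits));
  }
  std::vector<uint16_t> &freqs(uint32_t key, uint32_t &tot) {
    auto it = tabs.find(key);
    if (it == tabs.end()) {
      it = tabs.emplace(key, std::vector<uint16_t>(256, 1)).first;
      totals[key] = 256;
    }
    tot = totals[key];
    return it->second;
  }
  void learn(uint32_t key, int byte, size_t npast) {
    auto &fr = tabs[key];
    fr[byte] = (uint16_t)(fr[byte] + inc);
    uint32_t &tot = totals[key];
    tot += inc;
    if (tot > max_total) {
      uint32_t nt = 0;
      for (int s = 0; s < 256; s++) { fr[s] = (uint16_t)((fr[s] + 1) >> 1); nt += fr[s]; }
      tot = nt;
    }
    if (order > 0) hist[npast % hist.size()] = (uint8_t)byte;
  }
};

// [[Rcpp::export]]
RawVector cx_bytes_encode(RawVector data, int order, int hash_bits = 18) {
  ByteModel bm(order, hash_bits);
  ArEncoder enc;
  for (R_xlen_t i = 0; i < data.size(); i++) {
    int byte = data[i];
    uint32_t key = bm.ctx_key((size_t)i);
    uint32_t tot;
    std::vector<uint16_t> &fr = bm.freqs(key, tot);
    uint32_t cl = 0;
    for (int s = 0; s < byte; s++) cl += fr[s];
    enc.encode(cl, cl + fr[byte], tot);
    bm.learn(key, byte, (size_t)i);
  }
  std::vector<uint8_t> payload = enc.finish();
  RawVector out(payload.size());
  std::copy(payload.begin(), payload.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
RawVector cx_bytes_decode(RawVector payload, int n, int order, int hash_bits = 18) {
  ByteModel bm(order, hash_bits);
  ArDecoder dec(payload.size() ? (const uint8_t *)RAW(payload) : (const uint8_t *)"",
                payload.size());
  RawVector out(n);
  for (int i = 0; i < n; i++) {
    uint32_t key = bm.ctx_key((size_t)i);
    uint32_t tot;
    std::vector<uint16_t> &fr = bm.freqs(key, tot);
    uint32_t tgt = dec.target(tot);
    uint32_t cl = 0;
    int sym = 0;
    while (sym < 255 && cl + fr[sym] <= tgt) { cl += fr[sym]; sym++; }
    dec.update(cl, cl + fr[sym], tot);
    out[i] = (uint8_t)sym;
    bm.learn(key, sym, (size_t)i);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Coding with an externally supplied fixed distribution (coder tests)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector cx_fixed_encode(IntegerVector syms, NumericVector p) {
  int A = p.size();
  if (A < 2 || A > 256) stop("alphabet size out of range");
  std::vector<uint32_t> f(A);
  uint32_t spare = QTOT - (uint32_t)A, acc = 0;
  for (int s = 0; s < A - 1; s++) { f[s] = (uint32_t)(p[s] * spare) + 1; acc += f[s]; }
  f[A - 1] = QTOT - acc;
  ArEncoder enc;
  for (R_xlen_t i = 0; i < syms.size(); i++) {
    int sym = syms[i];
    uint32_t cl = 0;
    for (int s = 0; s < sym; s++) cl += f[s];
    enc.encode(cl, cl + f[sym], QTOT);
  }
  std::vector<uint8_t> payload = enc.finish();
  RawVector out(payload.size());
  std::copy(payload.begin(), payload.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
IntegerVector cx_fixed_decode(RawVector payload, int n, NumericVector p) {
  int A = p.size();
  std::vector<uint32_t> f(A);
  uint32_t spare = QTOT - (uint32_t)A, acc = 0;
  for (int s = 0; s < A - 1; s++) { f[s] = (uint32_t)(p[s] * spare) + 1; acc += f[s]; }
  f[A - 1] = QTOT - acc;
  ArDecoder dec(payload.size() ? (const uint8_t *)RAW(payload) : (const uint8_t *)"",
                payload.size());
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    uint32_t tgt = dec.target(QTOT);
    uint32_t cl = 0;
    int sym = 0;
    while (sym < A - 1 && cl + f[sym] <= tgt) { cl += f[sym]; sym++; }
    dec.update(cl, cl + f[sym], QTOT);
    out[i] = sym;
  }
  return out;
}

// ---------------------------------------------------------------------------
// CRC-32 (IEEE) for container integrity
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cx_crc32(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; i++) {
      uint32_t c = i;
      for (int j = 0; j < 8; j++) c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); i++)
    crc = table[(crc ^ data[i]) & 0xFF] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}

// ---------------------------------------------------------------------------
// Sequential samplers for the synthetic generator (use R's RNG so set.seed()
// governs reproducibility)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cx_markov_sample(NumericMatrix trans, int n, int order) {
  int nctx = trans.nrow();
  if (nctx != (1 << (2 * order))) stop("transition matrix must have 4^order rows");
  IntegerVector out(n);
  uint64_t ctx = 0;
  uint64_t mask = ((uint64_t)1 << (2 * order)) - 1;
  GetRNGstate();
  for (int i = 0; i < n; i++) {
    double u = unif_rand();
    double acc = 0.0;
    int sym = 3; // numerical guard: last symbol absorbs rounding slack
    for (int s = 0; s < 4; s++) {
      acc += trans((int)ctx, s);
      if (u < acc) { sym = s; break; }
    }
    out[i] = sym;
    ctx = ((ctx << 2) | (uint64_t)sym) & mask;
  }
  PutRNGstate();
  return out;
}
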