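// Core UMI deduplication engine: 3-bit equidistant nucleotide encoding with
// word-parallel Hamming distance, eight interchangeable near-neighbor index
// backends implementing the remove_near/contains contract, and the three
// network-based grouping algorithms (cluster, adjacency, directional).

#include <Rcpp.h>
#include <functional>
#include <cstdint>
#include <climits>
#include <unordered_map>
#include <algorithm>
#include <memory>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Encoding
//
// Pairwise-equidistant 3-bit codes: e_A = 110, e_T = 011, e_C = 101,
// e_G = 000.  Any two distinct codes differ in exactly 2 bits, so for N-free
// sequences popcount(a XOR b) == 2 * Hamming distance.  N positions carry the
// canonical pattern 000 in the coded bits and are tracked in a separate
// 1-bit-per-position mask; N is treated as a fifth letter (mismatch against
// A/C/G/T, match against N).

static const char ALPHA[5] = {'A', 'C', 'G', 'T', 'N'};
static const uint64_t CODE3[5] = {6ull, 5ull, 0ull, 3ull, 0ull}; // A C G T N
static const int PER_WORD = 21; // floor(64 / 3) positions per 64-bit word

static inline int letter_index(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return 4;
  }
  return -1;
}

struct Enc {
  std::vector<uint64_t> code;  // 3 bits per position, position 1 in the
                               // highest-order 3 bits of word 0
  std::vector<uint64_t> mask3; // 111 at N positions, aligned with code
  std::vector<uint64_t> mask1; // 1 bit per position (N flag)
  int len = 0;
};

static Enc encode_seq(const std::string& s) {
  Enc e;
  e.len = (int)s.size();
  if (e.len == 0) stop("UMI sequence must be non-empty");
  int w3 = (e.len + PER_WORD - 1) / PER_WORD;
  int w1 = (e.len + 63) / 64;
  e.code.assign(w3, 0);
  e.mask3.assign(w3, 0);
  e.mask1.assign(w1, 0);
  for (int p = 0; p < e.len; p++) {
    int li = letter_index(s[p]);
    if (li < 0)
      stop("invalid character '%c' at position %d (alphabet is A/C/G/T/N)",
           s[p], p + 1);
    int shift = (PER_WORD - 1 - p % PER_WORD) * 3;
    e.code[p / PER_WORD] |= CODE3[li] << shift;
    if (li == 4) {
      e.mask3[p / PER_WORD] |= 7ull << shift;
      e.mask1[p / 64] |= 1ull << (p % 64);
    }
  }
  return e;
}

static inline int ham_enc(const Enc& a, const Enc& b) {
  int m = 0;
  for (size_t w = 0; w < a.code.size(); w++)
    m += __builtin_popcountll((a.code[w] ^ b.code[w]) &
                              ~(a.mask3[w] | b.mask3[w]));
  m >>= 1; // each non-N mismatch contributes exactly 2 bits
  for (size_t w = 0; w < a.mask1.size(); w++)
    m += __builtin_popcountll(a.mask1[w] ^ b.mask1[w]);
  return m;
}

static std::string upper_seq(const std::string& s) {
  std::string u(s);
  for (auto& c : u) c = (char)toupper((unsigned char)c);
  return u;
}

// [[Rcpp::export]]
List cpp_encode(std::string seq) {
  Enc e = encode_seq(seq);
  CharacterVector words(e.code.size());
  for (size_t w = 0; w < e.code.size(); w++) {
    char buf[17];
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)e.code[w]);
    words[w] = buf;
  }
  std::string bits;
  bits.reserve(3 * e.len);
  std::vector<int> npos;
  for (int p = 0; p < e.len; p++) {
    int shift = (PER_WORD - 1 - p % PER_WORD) * 3;
    uint64_t c = (e.code[p / PER_WORD] >> shift) & 7ull;
    for (int b = 2; b >= 0; b--) bits.push_back(((c >> b) & 1) ? '1' : '0');
    if ((e.mask1[p / 64] >> (p % 64)) & 1) npos.push_back(p + 1);
  }
  return List::create(_["words"] = words, _["bits"] = bits,
                      _["n_positions"] = wrap(npos), _["length"] = e.len,
                      _["sequence"] = upper_seq(seq));
}

// [[Rcpp::export]]
std::string cpp_decode(CharacterVector words, IntegerVector n_positions,
                       int len) {
  std::vector<uint64_t> code(words.size());
  for (int w = 0; w < words.size(); w++) {
    std::string h = as<std::string>(words[w]);
    uint64_t v = 0;
    for (char c : h) {
      int d = (c >= '0' && c <= '9') ? c - '0'
            : (c >= 'a' && c <= 'f') ? c - 'a' + 10
            : (c >= 'A' && c <= 'F') ? c - 'A' + 10 : -1;
      if (d < 0) stop("corrupted encoding: non-hex word '%s'", h.c_str());
      v = (v << 4) | (uint64_t)d;
    }
    code[w] = v;
  }
  std::vector<char> isn(len, 0);
  for (int i = 0; i < n_positions.size(); i++) {
    int p = n_positions[i];
    if (p < 1 || p > len) stop("N position %d outside 1..%d", p, len);
    isn[p - 1] = 1;
  }
  std::string out(len, '?');
  for (int p = 0; p < len; p++) {
    int shift = (PER_WORD - 1 - p % PER_WORD) * 3;
    uint64_t c = (code[p / PER_WORD] >> shift) & 7ull;
    if (isn[p]) {
      if (c != 0)
        stop("corrupted encoding: N position %d has non-canonical bits", p + 1);
      out[p] = 'N';
    } else {
      switch (c) {
        case 6: out[p] = 'A'; break;
        case 5: out[p] = 'C'; break;
        case 0: out[p] = 'G'; break;
        case 3: out[p] = 'T'; break;
        default:
          stop("corrupted encoding: invalid 3-bit group at position %d", p + 1);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  int n = std::max(a.size(), b.size());
  if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
    stop("arguments must have equal length or length 1");
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    std::string sa = as<std::string>(a[a.size() == 1 ? 0 : i]);
    std::string sb = as<std::string>(b[b.size() == 1 ? 0 : i]);
    if (sa.size() != sb.size())
      stop("sequences must have equal length (got %d and %d)", (int)sa.size(),
           (int)sb.size());
    out[i] = ham_enc(encode_seq(sa), encode_seq(sb));
  }
  return out;
}

// Raw popcount of the XOR of the coded bits (no N masking); for N-free pairs
// this equals exactly twice the Hamming distance.
// [[Rcpp::export]]
IntegerVector cpp_xor_popcount(CharacterVector a, CharacterVector b) {
  int n = std::max(a.size(), b.size());
  if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
    stop("arguments must have equal length or length 1");
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    Enc ea = encode_seq(as<std::string>(a[a.size() == 1 ? 0 : i]));
    Enc eb = encode_seq(as<std::string>(b[b.size() == 1 ? 0 : i]));
    if (ea.len != eb.len) stop("sequences must have equal length");
    int m = 0;
    for (size_t w = 0; w < ea.code.size(); w++)
      m += __builtin_popcountll(ea.code[w] ^ eb.code[w]);
    out[i] = m;
  }
  return out;
}

// ---------------------------------------------------------------------------
// String decompositions shared by the hashing backends

static std::vector<std::pair<int, int>> ngram_spans(int M, int k) {
  if (M < k + 1)
    stop("UMI length %d cannot be split into %d n-grams", M, k + 1);
  int n = M / (k + 1);
  std::vector<std::pair<int, int>> spans; // (start, length), 0-based
  for (int s = 0; s <= k; s++)
    spans.push_back({s * n, s == k ? M - k * n : n});
  return spans;
}

// [[Rcpp::export]]
DataFrame cpp_split_ngrams(std::string seq, int k) {
  std::string s = upper_seq(seq);
  auto spans = ngram_spans((int)s.size(), k);
  IntegerVector slot(spans.size()), start(spans.size()), len(spans.size());
  CharacterVector gram(spans.size());
  for (size_t i = 0; i < spans.size(); i++) {
    slot[i] = (int)i;
    start[i] = spans[i].first + 1;
    len[i] = spans[i].second;
    gram[i] = s.substr(spans[i].first, spans[i].second);
  }
  return DataFrame::create(_["slot"] = slot, _["start"] = start,
                           _["length"] = len, _["gram"] = gram,
                           _["stringsAsFactors"] = false);
}

static void mask_rec(std::string& s, int start, int rem, char ph,
                     std::vector<std::string>& out) {
  if (rem == 0) {
    out.push_back(s);
    return;
  }
  for (int p = start; p + rem <= (int)s.size(); p++) {
    char orig = s[p];
    s[p] = ph;
    mask_rec(s, p + 1, rem - 1, ph, out);
    s[p] = orig;
  }
}

// [[Rcpp::export]]
CharacterVector cpp_mask_subsequences(std::string seq, int k,
                                      std::string placeholder = "*") {
  std::string s = upper_seq(seq);
  if (k > (int)s.size())
    stop("k = %d exceeds UMI length %d", k, (int)s.size());
  if (placeholder.size() != 1) stop("placeholder must be a single character");
  std::vector<std::string> out;
  mask_rec(s, 0, k, placeholder[0], out);
  return wrap(out);
}

static void gen_rec(std::string& s, int start, int rem,
                    const std::string& alpha,
                    std::vector<std::string>& out) {
  out.push_back(s);
  if (rem == 0) return;
  for (int p = start; p < (int)s.size(); p++) {
    char orig = s[p];
    for (char c : alpha) {
      if (c == orig) continue;
      s[p] = c;
      gen_rec(s, p + 1, rem - 1, alpha, out);
    }
    s[p] = orig;
  }
}

// [[Rcpp::export]]
CharacterVector cpp_generate_within(std::string seq, int k,
                                    std::string alphabet = "ACGTN") {
  if (k < 0) stop("k must be non-negative");
  std::string s = upper_seq(seq);
  std::vector<std::string> out;
  gen_rec(s, 0, k, alphabet, out);
  return wrap(out);
}

// ---------------------------------------------------------------------------
// Engine and backends

class Engine;

struct Backend {
  Engine* E = nullptr;
  virtual ~Backend() {}
  virtual void build() = 0;
  // Collect every alive v with d(q, v) <= k and f(v) <= F, marking each one
  // removed as it is collected (so shared-membership structures never return
  // duplicates).  The query need not itself be a table member.
  virtual void collect(const std::string& qs, const Enc& qe, double F,
                       std::vector<int>& out) = 0;
  virtual void on_kill(int) {} // notification for exact-maintenance backends
};

class Engine {
public:
  int M = 0, k = 0, N = 0;
  long long ham_evals = 0;
  bool consumed = false; // any removal happened
  std::vector<std::string> seqs;
  std::vector<Enc> encs;
  std::vector<int> freq;
  std::vector<char> alive;
  std::unordered_map<std::string, int> lookup;
  std::unique_ptr<Backend> backend;
  std::string backend_name;
  // flat single-word mirror of encs for M <= 21 (one cache line per UMI
  // triple instead of three heap vectors); the generic path handles the rest
  bool one_word = false;
  std::vector<uint64_t> fc, fm3, fm1;

  void finalize_encodings() {
    one_word = (M <= PER_WORD);
    if (!one_word) return;
    fc.resize(N); fm3.resize(N); fm1.resize(N);
    for (int i = 0; i < N; i++) {
      fc[i] = encs[i].code[0];
      fm3[i] = encs[i].mask3[0];
      fm1[i] = encs[i].mask1[0];
    }
  }
  inline int ham(int i, int j) {
    ham_evals++;
    if (one_word) {
      int m = __builtin_popcountll((fc[i] ^ fc[j]) & ~(fm3[i] | fm3[j])) >> 1;
      return m + __builtin_popcountll(fm1[i] ^ fm1[j]);
    }
    return ham_enc(encs[i], encs[j]);
  }
  inline int ham_q(const Enc& q, int j) {
    ham_evals++;
    if (one_word) {
      int m = __builtin_popcountll((q.code[0] ^ fc[j]) &
                                   ~(q.mask3[0] | fm3[j])) >> 1;
      return m + __builtin_popcountll(q.mask1[0] ^ fm1[j]);
    }
    return ham_enc(q, encs[j]);
  }
  void kill(int i) {
    alive[i] = 0;
    consumed = true;
    backend->on_kill(i);
  }

  std::vector<int> remove_near_idx(const std::string& qs, double F,
                                   bool strict) {
    auto it = lookup.find(qs);
    int uidx = (it == lookup.end()) ? -1 : it->second;
    if (uidx < 0 && strict)
      stop("query UMI '%s' was never present in the table", qs.c_str());
    if ((int)qs.size() != M)
      stop("query UMI length %d does not match table length %d",
           (int)qs.size(), M);
    std::vector<int> out;
    Enc qe = encode_seq(qs);
    backend->collect(qs, qe, F, out);
    // the queried UMI is always included when it is alive, regardless of F
    if (uidx >= 0 && alive[uidx]) {
      kill(uidx);
      out.push_back(uidx);
    }
    return out;
  }
};

// --- naive linear scan (the reference backend / oracle) --------------------

struct NaiveBackend : Backend {
  void build() override {}
  void collect(const std::string&, const Enc& qe, double F,
               std::vector<int>& out) override {
    for (int i = 0; i < E->N; i++) {
      if (!E->alive[i] || E->freq[i] > F) continue;
      if (E->ham_q(qe, i) <= E->k) {
        out.push_back(i);
        E->kill(i);
      }
    }
  }
};

// --- combinations: generate-and-probe --------------------------------------

struct ComboBackend : Backend {
  std::string alphabet = "ACGTN";
  void build() override {}
  void probe(const std::string& s, double F, std::vector<int>& out) {
    auto it = E->lookup.find(s);
    if (it == E->lookup.end()) return;
    int i = it->second;
    if (E->alive[i] && E->freq[i] <= F) {
      out.push_back(i);
      E->kill(i);
    }
  }
  void gen(std::string& s, int start, int rem, double F,
           std::vector<int>& out) {
    probe(s, F, out);
    if (rem == 0) return;
    for (int p = start; p < (int)s.size(); p++) {
      char orig = s[p];
      for (char c : alphabet) {
        if (c == orig) continue;
        s[p] = c;
        gen(s, p + 1, rem - 1, F, out);
      }
      s[p] = orig;
    }
  }
  void collect(const std::string& qs, const Enc&, double F,
               std::vector<int>& out) override {
    std::string s(qs);
    gen(s, 0, E->k, F, out);
  }
};

// --- shared bin scanning with lazy compaction -------------------------------

static void scan_bin(Engine* E, std::vector<int>& bin, double F, bool verify,
                     const Enc& qe, std::vector<int>& out) {
  int dead = 0;
  for (int idx : bin) {
    if (!E->alive[idx]) {
      dead++;
      continue;
    }
    if (E->freq[idx] > F) continue;
    if (verify && E->ham_q(qe, idx) > E->k) continue;
    out.push_back(idx);
    E->kill(idx);
    dead++;
  }
  if (2 * dead > (int)bin.size()) { // compact once most members are gone
    std::vector<int> keep;
    keep.reserve(bin.size() - dead);
    for (int idx : bin)
      if (E->alive[idx]) keep.push_back(idx);
    bin.swap(keep);
  }
}

// --- subsequences: placeholder masks (no distance verification needed) ------

struct SubseqBackend : Backend {
  std::unordered_map<std::string, std::vector<int>> bins;
  void add_masks(const std::string& s, int i) {
    std::string t(s);
    std::vector<std::string> keys;
    mask_rec(t, 0, E->k, '*', keys);
    for (auto& key : keys) bins[key].push_back(i);
  }
  void build() override {
    if (E->k > E->M) stop("k = %d exceeds UMI length %d", E->k, E->M);
    for (int i = 0; i < E->N; i++) add_masks(E->seqs[i], i);
  }
  void collect(const std::string& qs, const Enc& qe, double F,
               std::vector<int>& out) override {
    std::string t(qs);
    std::vector<std::string> keys;
    mask_rec(t, 0, E->k, '*', keys);
    for (auto& key : keys) {
      auto it = bins.find(key);
      if (it != bins.end()) scan_bin(E, it->second, F, false, qe, out);
    }
  }
};

// --- n-grams: inverted index filter + distance verification -----------------

struct NgramBackend : Backend {
  std::vector<std::pair<int, int>> spans;
  std::unordered_map<std::string, std::vector<int>> bins;
  static std::string key_of(int slot, const std::string& s, int start,
                            int len) {
    std::string key(1, (char)('0' + slot));
    key.append(s, start, len);
    return key;
  }
  void build() override {
    spans = ngram_spans(E->M, E->k);
    for (int i = 0; i < E->N; i++)
      for (size_t s = 0; s < spans.size(); s++)
        bins[key_of((int)s, E->seqs[i], spans[s].first, spans[s].second)]
            .push_back(i);
  }
  void collect(const std::string& qs, const Enc& qe, double F,
               std::vector<int>& out) override {
    for (size_t s = 0; s < spans.size(); s++) {
      auto it = bins.find(key_of((int)s, qs, spans[s].first, spans[s].second));
      if (it != bins.end()) scan_bin(E, it->second, F, true, qe, out);
    }
  }
};

// --- trie with prefix pruning (exact flag maintenance) -----------------------

struct TrieBackend : Backend {
  struct Node {
    int ch[5];
    int parent;
    int umi; // leaf only
    char rem;
    int minf;
  };
  std::vector<Node> nodes;
  std::vector<int> leaf_of;

  int new_node(int parent) {
    Node nd;
    for (int l = 0; l < 5; l++) nd.ch[l] = -1;
    nd.parent = parent;
    nd.umi = -1;
    nd.rem = 0;
    nd.minf = INT_MAX;
    nodes.push_back(nd);
    return (int)nodes.size() - 1;
  }
  void build() override {
    nodes.clear();
    leaf_of.assign(E->N, -1);
    new_node(-1); // root
    for (int i = 0; i < E->N; i++) {
      int cur = 0;
      nodes[0].minf = std::min(nodes[0].minf, E->freq[i]);
      for (int p = 0; p < E->M; p++) {
        int l = letter_index(E->seqs[i][p]);
        if (nodes[cur].ch[l] < 0) {
          int nn = new_node(cur);
          nodes[cur].ch[l] = nn;
        }
        cur = nodes[cur].ch[l];
        nodes[cur].minf = std::min(nodes[cur].minf, E->freq[i]);
      }
      nodes[cur].umi = i;
      leaf_of[i] = cur;
    }
  }
  void on_kill(int i) override {
    int cur = leaf_of[i];
    nodes[cur].rem = 1;
    nodes[cur].minf = INT_MAX;
    cur = nodes[cur].parent;
    while (cur >= 0) {
      char rem = 1;
      int mf = INT_MAX;
      for (int l = 0; l < 5; l++) {
        int c = nodes[cur].ch[l];
        if (c < 0) continue;
        rem = rem && nodes[c].rem;
        if (!nodes[c].rem) mf = std::min(mf, nodes[c].minf);
      }
      if (nodes[cur].rem == rem && nodes[cur].minf == mf) break;
      nodes[cur].rem = rem;
      nodes[cur].minf = mf;
      cur = nodes[cur].parent;
    }
  }
  void dfs(int node, int depth, int budget, const std::vector<int>& qi,
           double F, std::vector<int>& out) {
    const Node& nd = nodes[node];
    if (nd.rem || nd.minf > F) return;
    if (depth == E->M) {
      int i = nd.umi;
      if (i >= 0 && E->alive[i] && E->freq[i] <= F) {
        out.push_back(i);
        E->kill(i); // updates flags up the path via on_kill
      }
      return;
    }
    for (int l = 0; l < 5; l++) { // fixed alphabet order A,C,G,T,N
      int c = nd.ch[l];
      if (c < 0) continue;
      int b = budget - (l != qi[depth]);
      if (b >= 0) dfs(c, depth + 1, b, qi, F, out);
    }
  }
  void collect(const std::string& qs, const Enc&, double F,
               std::vector<int>& out) override {
    std::vector<int> qi(E->M);
    for (int p = 0; p < E->M; p++) qi[p] = letter_index(qs[p]);
    dfs(0, 0, E->k, qi, F, out);
  }
};

// --- BK-tree (shared by three backends) -------------------------------------

struct BKTree {
  Engine* E = nullptr;
  struct Node {
    int umi;
    char sub_rem;
    int sub_minf;
  };
  std::vector<Node> nodes;
  std::vector<std::vector<int>> kids; // kids[n][d], d in 0..M
  int root = -1;

  int new_node(int i) {
    nodes.push_back({i, 0, E->freq[i]});
    kids.emplace_back(E->M + 1, -1);
    return (int)nodes.size() - 1;
  }
  void insert(int i) {
    if (root < 0) {
      root = new_node(i);
      return;
    }
    int c = root;
    for (;;) {
      int d = E->ham(i, nodes[c].umi);
      if (d == 0)
        stop("duplicate UMI inserted into BK-tree: %s", E->seqs[i].c_str());
      nodes[c].sub_minf = std::min(nodes[c].sub_minf, E->freq[i]);
      int& slot = kids[c][d];
      if (slot < 0) {
        slot = new_node(i);
        return;
      }
      c = slot;
    }
  }
  // Algorithm: DFS with the triangle-inequality window [delta-k, delta+k],
  // skipping fully-removed subtrees and subtrees whose minimum alive
  // frequency exceeds F; flags are refreshed on the return path (lazily
  // converging when membership is shared across several trees).
  void dfs(int c, const Enc& qe, double F, std::vector<int>& out) {
    int i = nodes[c].umi;
    int delta = E->ham_q(qe, i);
    if (E->alive[i] && delta <= E->k && E->freq[i] <= F) {
      out.push_back(i);
      E->kill(i);
    }
    int lo = std::max(1, delta - E->k), hi = std::min(E->M, delta + E->k);
    for (int d = lo; d <= hi; d++) {
      int v = kids[c][d];
      if (v < 0) continue;
      if (nodes[v].sub_rem) continue;             // pruning by removed nodes
      if (nodes[v].sub_minf > F) continue;        // pruning by frequency
      dfs(v, qe, F, out);
    }
    bool rem = !E->alive[i];
    int mf = rem ? INT_MAX : E->freq[i];
    for (int d = 1; d <= E->M; d++) {
      int v = kids[c][d];
      if (v < 0) continue;
      rem = rem && nodes[v].sub_rem;
      if (!nodes[v].sub_rem) mf = std::min(mf, nodes[v].sub_minf);
    }
    nodes[c].sub_rem = rem;
    nodes[c].sub_minf = mf;
  }
  void query(const Enc& qe, double F, std::vector<int>& out) {
    if (root >= 0) dfs(root, qe, F, out);
  }
};

// Build a BK-tree over the given sequences in the given order and report
// each node's parent and edge distance (structural test hook).
// [[Rcpp::export]]
DataFrame cpp_bk_build_trace(CharacterVector umis) {
  Engine E;
  E.N = umis.size();
  for (int i = 0; i < E.N; i++) {
    std::string s = upper_seq(as<std::string>(umis[i]));
    if (i == 0) E.M = (int)s.size();
    E.seqs.push_back(s);
    E.encs.push_back(encode_seq(s));
    E.freq.push_back(1);
  }
  E.alive.assign(E.N, 1);
  E.finalize_encodings();
  BKTree T;
  T.E = &E;
  for (int i = 0; i < E.N; i++) T.insert(i);
  // recover parents by walking the structure
  std::vector<std::string> umi(E.N), parent(E.N, "");
  std::vector<int> dist(E.N, NA_INTEGER);
  for (size_t n = 0; n < T.nodes.size(); n++)
    umi[n] = E.seqs[T.nodes[n].umi];
  for (size_t n = 0; n < T.nodes.size(); n++)
    for (int d = 1; d <= E.M; d++)
      if (T.kids[n][d] >= 0) {
        parent[T.kids[n][d]] = umi[n];
        dist[T.kids[n][d]] = d;
      }
  return DataFrame::create(_["umi"] = wrap(umi), _["parent"] = wrap(parent),
                           _["dist"] = wrap(dist),
                           _["stringsAsFactors"] = false);
}

// build-time insertion order: increasing frequency, ties broken by
// lexicographic sequence order (low-frequency UMIs near the root)
static std::vector<int> freq_increasing_order(Engine* E) {
  std::vector<int> ord(E->N);
  for (int i = 0; i < E->N; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [E](int a, int b) {
    if (E->freq[a] != E->freq[b]) return E->freq[a] < E->freq[b];
    return E->seqs[a] < E->seqs[b];
  });
  return ord;
}

struct BKBackend : Backend {
  BKTree tree;
  void build() override {
    tree.E = E;
    for (int i : freq_increasing_order(E)) tree.insert(i);
  }
  void collect(const std::string&, const Enc& qe, double F,
               std::vector<int>& out) override {
    tree.query(qe, F, out);
  }
};

// --- Fenwick (binary indexed) tree over BK-trees -----------------------------

struct FenwickBKBackend : Backend {
  std::vector<int> vals; // distinct frequency values, ascending (ranks 1..R)
  std::vector<BKTree> trees; // 1-based
  int rank_of(double F) { // largest rank with value <= F (0 if none)
    int lo = 0, hi = (int)vals.size();
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if ((double)vals[mid - 1] <= F) lo = mid; else hi = mid - 1;
    }
    return lo;
  }
  void build() override {
    vals.assign(E->freq.begin(), E->freq.end());
    std::sort(vals.begin(), vals.end());
    vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
    int R = (int)vals.size();
    trees.assign(R + 1, BKTree());
    for (int t = 0; t <= R; t++) trees[t].E = E;
    for (int i : freq_increasing_order(E)) {
      int r = (int)(std::lower_bound(vals.begin(), vals.end(), E->freq[i]) -
                    vals.begin()) + 1;
      for (int t = r; t <= R; t += t & (-t)) trees[t].insert(i);
    }
  }
  void collect(const std::string&, const Enc& qe, double F,
               std::vector<int>& out) override {
    for (int t = rank_of(F); t > 0; t -= t & (-t)) trees[t].query(qe, F, out);
  }
};

// [[Rcpp::export]]
List cpp_fenwick_decompose(NumericVector freq_values, double F) {
  std::vector<double> vals(freq_values.begin(), freq_values.end());
  for (size_t i = 1; i < vals.size(); i++)
    if (vals[i] <= vals[i - 1])
      stop("frequency values must be strictly increasing");
  int R = (int)vals.size();
  int r = 0;
  for (int i = 0; i < R; i++)
    if (vals[i] <= F) r = i + 1;
  std::vector<int> ids, lo, hi;
  for (int t = r; t > 0; t -= t & (-t)) {
    ids.push_back(t);
    lo.push_back(t - (t & (-t)) + 1);
    hi.push_back(t);
  }
  return List::create(_["node"] = wrap(ids), _["rank_lo"] = wrap(lo),
                      _["rank_hi"] = wrap(hi), _["rank_of_f"] = r);
}

// --- n-grams BK-trees hybrid -------------------------------------------------

struct NgramBKBackend : Backend {
  std::vector<std::pair<int, int>> spans;
  std::unordered_map<std::string, BKTree> bins;
  void build() override {
    spans = ngram_spans(E->M, E->k);
    for (int i : freq_increasing_order(E)) {
      for (size_t s = 0; s < spans.size(); s++) {
        std::string key =
            NgramBackend::key_of((int)s, E->seqs[i], spans[s].first,
                                 spans[s].second);
        auto it = bins.find(key);
        if (it == bins.end()) {
          it = bins.emplace(key, BKTree()).first;
          it->second.E = E;
        }
        it->second.insert(i);
      }
    }
  }
  void collect(const std::string& qs, const Enc& qe, double F,
               std::vector<int>& out) override {
    for (size_t s = 0; s < spans.size(); s++) {
      auto it = bins.find(
          NgramBackend::key_of((int)s, qs, spans[s].first, spans[s].second));
      if (it != bins.end()) it->second.query(qe, F, out);
    }
  }
};

// ---------------------------------------------------------------------------
// Engine construction

static std::unique_ptr<Backend> make_backend(const std::string& name) {
  if (name == "naive") return std::make_unique<NaiveBackend>();
  if (name == "combo") return std::make_unique<ComboBackend>();
  if (name == "subseq") return std::make_unique<SubseqBackend>();
  if (name == "ngram") return std::make_unique<NgramBackend>();
  if (name == "trie") return std::make_unique<TrieBackend>();
  if (name == "bktree") return std::make_unique<BKBackend>();
  if (name == "fenwickbk") return std::make_unique<FenwickBKBackend>();
  if (name == "ngrambk") return std::make_unique<NgramBKBackend>();
  stop("unknown index backend '%s'", name.c_str());
}

static Engine* make_engine(CharacterVector umis, IntegerVector counts, int k,
                           std::string backend) {
  if (umis.size() != counts.size())
    stop("umis and counts must have equal length");
  if (k < 0) stop("k must be non-negative");
  std::unique_ptr<Engine> E(new Engine());
  E->N = umis.size();
  E->k = k;
  E->backend_name = backend;
  E->seqs.reserve(E->N);
  E->encs.reserve(E->N);
  for (int i = 0; i < E->N; i++) {
    std::string s = upper_seq(as<std::string>(umis[i]));
    if (i == 0) E->M = (int)s.size();
    if ((int)s.size() != E->M)
      stop("all UMIs must share one length (UMI %d has length %d, expected %d)",
           i + 1, (int)s.size(), E->M);
    if (counts[i] < 1) stop("all frequencies must be >= 1");
    if (!E->lookup.emplace(s, i).second)
      stop("duplicate UMI in frequency table: %s", s.c_str());
    E->seqs.push_back(s);
    E->encs.push_back(encode_seq(s));
    E->freq.push_back(counts[i]);
  }
  E->alive.assign(E->N, 1);
  E->finalize_encodings();
  E->backend = make_backend(backend);
  E->backend->E = E.get();
  E->backend->build();
  return E.release();
}

// ---------------------------------------------------------------------------
// Grouping algorithms over the remove_near/contains contract

static List run_grouping(Engine* E, std::string algorithm, double epsilon) {
  if (E->consumed)
    stop("index has already served remove_near queries; build a fresh one");
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]");
  const double INF = R_PosInf;
  // canonical visiting order: decreasing frequency, ties by sequence
  std::vector<int> ord(E->N);
  for (int i = 0; i < E->N; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [E](int a, int b) {
    if (E->freq[a] != E->freq[b]) return E->freq[a] > E->freq[b];
    return E->seqs[a] < E->seqs[b];
  });

  std::vector<int> group(E->N, -1);
  std::vector<int> reps;
  int ngroups = 0;
  std::vector<int> stack, members;

  for (int u : ord) {
    if (!E->alive[u]) continue;
    int gid = ngroups++;
    members.clear();
    stack.clear();
    if (algorithm == "adjacency") {
      std::vector<int> S = E->remove_near_idx(E->seqs[u], INF, true);
      members = S;
    } else if (algorithm == "cluster") {
      std::vector<int> S = E->remove_near_idx(E->seqs[u], INF, true);
      for (int v : S) {
        members.push_back(v);
        if (v != u) stack.push_back(v);
      }
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        std::vector<int> S2 = E->remove_near_idx(E->seqs[v], INF, true);
        for (int w : S2) {
          members.push_back(w);
          stack.push_back(w);
        }
      }
    } else if (algorithm == "directional") {
      double F = epsilon * (E->freq[u] + 1.0);
      std::vector<int> S = E->remove_near_idx(E->seqs[u], F, true);
      for (int v : S) {
        members.push_back(v);
        if (v != u) stack.push_back(v);
      }
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        double Fv = epsilon * (E->freq[v] + 1.0);
        std::vector<int> S2 = E->remove_near_idx(E->seqs[v], Fv, true);
        for (int w : S2) {
          members.push_back(w);
          stack.push_back(w);
        }
      }
    } else {
      stop("unknown algorithm '%s'", algorithm.c_str());
    }
    int rep = members[0];
    for (int m : members) {
      group[m] = gid;
      if (E->freq[m] > E->freq[rep] ||
          (E->freq[m] == E->freq[rep] && E->seqs[m] < E->seqs[rep]))
        rep = m;
    }
    reps.push_back(rep);
  }
  IntegerVector g(E->N), r(ngroups);
  for (int i = 0; i < E->N; i++) g[i] = group[i] + 1;
  for (int i = 0; i < ngroups; i++) r[i] = reps[i] + 1;
  return List::create(_["group"] = g, _["representative"] = r,
                      _["n_groups"] = ngroups,
                      _["hamming_evals"] = (double)E->ham_evals);
}

// [[Rcpp::export]]
List cpp_dedup(CharacterVector umis, IntegerVector counts, int k,
               std::string algorithm, std::string backend, double epsilon) {
  std::unique_ptr<Engine> E(make_engine(umis, counts, k, backend));
  return run_grouping(E.get(), algorithm, epsilon);
}

// ---------------------------------------------------------------------------
// External-pointer index interface

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector umis, IntegerVector counts, int k,
                     std::string backend) {
  XPtr<Engine> xp(make_engine(umis, counts, k, backend), true);
  return xp;
}

// [[Rcpp::export]]
CharacterVector cpp_index_remove_near(SEXP xp_, std::string umi, int k,
                                      double f_max, bool strict) {
  XPtr<Engine> xp(xp_);
  if (k != xp->k)
    stop("index was built with k = %d; querying with k = %d is not allowed",
         xp->k, k);
  std::vector<int> out =
      xp->remove_near_idx(upper_seq(umi), f_max, strict);
  CharacterVector res(out.size());
  for (size_t i = 0; i < out.size(); i++) res[i] = xp->seqs[out[i]];
  return res;
}

// [[Rcpp::export]]
bool cpp_index_contains(SEXP xp_, std::string umi) {
  XPtr<Engine> xp(xp_);
  auto it = xp->lookup.find(upper_seq(umi));
  return it != xp->lookup.end() && xp->alive[it->second];
}

// [[Rcpp::export]]
CharacterVector cpp_index_alive(SEXP xp_) {
  XPtr<Engine> xp(xp_);
  std::vector<std::string> out;
  for (int i = 0; i < xp->N; i++)
    if (xp->alive[i]) out.push_back(xp->seqs[i]);
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp_) {
  XPtr<Engine> xp(xp_);
  return List::create(_["k"] = xp->k, _["m"] = xp->M, _["n"] = xp->N,
                      _["backend"] = xp->backend_name,
                      _["fresh"] = !xp->consumed,
                      _["hamming_evals"] = (double)xp->ham_evals);
}

// [[Rcpp::export]]
List cpp_dedup_on_index(SEXP xp_, std::string algorithm, double epsilon) {
  XPtr<Engine> xp(xp_);
  return run_grouping(xp.get(), algorithm, epsilon);
}

// ---------------------------------------------------------------------------
// Structural audits (used by property tests) and index statistics

static void bk_audit(Engine* E, BKTree& T, bool& child_ok, bool& flag_ok,
                     std::vector<int>& membership) {
  if (T.root < 0) return;
  // recursive audit returning (any_alive, min_alive_freq)
  std::function<std::pair<bool, int>(int)> rec = [&](int c) {
    int i = T.nodes[c].umi;
    membership[i]++;
    bool any_alive = E->alive[i] != 0;
    int minf = any_alive ? E->freq[i] : INT_MAX;
    for (int d = 1; d <= E->M; d++) {
      int v = T.kids[c][d];
      if (v < 0) continue;
      if (ham_enc(E->encs[i], E->encs[T.nodes[v].umi]) != d) child_ok = false;
      auto sub = rec(v);
      any_alive = any_alive || sub.first;
      minf = std::min(minf, sub.second);
    }
    // stored flags must be conservative: sub_rem true only if truly empty;
    // stored min frequency must not exceed the true alive minimum
    if (T.nodes[c].sub_rem && any_alive) flag_ok = false;
    if (any_alive && T.nodes[c].sub_minf > minf) flag_ok = false;
    return std::make_pair(any_alive, minf);
  };
  rec(T.root);
}

// [[Rcpp::export]]
List cpp_index_audit(SEXP xp_) {
  XPtr<Engine> xp(xp_);
  Engine* E = xp.get();
  bool child_ok = true, flag_ok = true;
  std::vector<int> membership(E->N, 0);
  if (auto* b = dynamic_cast<BKBackend*>(E->backend.get())) {
    bk_audit(E, b->tree, child_ok, flag_ok, membership);
  } else if (auto* b = dynamic_cast<FenwickBKBackend*>(E->backend.get())) {
    for (auto& t : b->trees) bk_audit(E, t, child_ok, flag_ok, membership);
  } else if (auto* b = dynamic_cast<NgramBKBackend*>(E->backend.get())) {
    for (auto& kv : b->bins) bk_audit(E, kv.second, child_ok, flag_ok,
                                      membership);
  } else if (auto* b = dynamic_cast<TrieBackend*>(E->backend.get())) {
    // audit trie flags against a full scan
    std::function<std::pair<bool, int>(int)> rec = [&](int c) {
      auto& nd = b->nodes[c];
      bool any_alive = nd.umi >= 0 && E->alive[nd.umi];
      if (nd.umi >= 0) membership[nd.umi]++;
      int minf = any_alive ? E->freq[nd.umi] : INT_MAX;
      for (int l = 0; l < 5; l++) {
        if (nd.ch[l] < 0) continue;
        auto sub = rec(nd.ch[l]);
        any_alive = any_alive || sub.first;
        minf = std::min(minf, sub.second);
      }
      if (nd.rem && any_alive) flag_ok = false;
      if (any_alive && nd.minf > minf) flag_ok = false;
      return std::make_pair(any_alive, minf);
    };
    rec(0);
  } else {
    return List::create(_["supported"] = false);
  }
  return List::create(_["supported"] = true, _["child_distances_ok"] = child_ok,
                      _["flags_ok"] = flag_ok,
                      _["membership"] = wrap(membership));
}

static void bk_depths(const BKTree& T, int M, int node, int depth,
                      std::vector<int>& depths) {
  depths.push_back(depth);
  for (int d = 1; d <= M; d++)
    if (T.kids[node][d] >= 0) bk_depths(T, M, T.kids[node][d], depth + 1,
                                        depths);
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xp_) {
  XPtr<Engine> xp(xp_);
  Engine* E = xp.get();
  List out = List::create(_["backend"] = E->backend_name, _["n"] = E->N,
                          _["m"] = E->M, _["k"] = E->k);
  if (auto* b = dynamic_cast<NgramBackend*>(E->backend.get())) {
    double tot = 0; int mx = 0;
    for (auto& kv : b->bins) {
      tot += kv.second.size();
      mx = std::max(mx, (int)kv.second.size());
    }
    out["n_bins"] = (double)b->bins.size();
    out["avg_bin_size"] = b->bins.empty() ? 0.0 : tot / b->bins.size();
    out["max_bin_size"] = mx;
  } else if (auto* b = dynamic_cast<SubseqBackend*>(E->backend.get())) {
    double tot = 0; int mx = 0;
    for (auto& kv : b->bins) {
      tot += kv.second.size();
      mx = std::max(mx, (int)kv.second.size());
    }
    out["n_bins"] = (double)b->bins.size();
    out["avg_bin_size"] = b->bins.empty() ? 0.0 : tot / b->bins.size();
    out["max_bin_size"] = mx;
  } else if (auto* b = dynamic_cast<TrieBackend*>(E->backend.get())) {
    out["n_nodes"] = (double)b->nodes.size();
  } else if (auto* b = dynamic_cast<BKBackend*>(E->backend.get())) {
    std::vector<int> depths;
    if (b->tree.root >= 0) bk_depths(b->tree, E->M, b->tree.root, 1, depths);
    double tot = 0; int mx = 0;
    for (int d : depths) { tot += d; mx = std::max(mx, d); }
    out["avg_depth"] = depths.empty() ? 0.0 : tot / depths.size();
    out["max_depth"] = mx;
  } else if (auto* b = dynamic_cast<NgramBKBackend*>(E->backend.get())) {
    out["n_bins"] = (double)b->bins.size();
    std::vector<int> depths;
    for (auto& kv : b->bins)
      if (kv.second.root >= 0)
        bk_depths(kv.second, E->M, kv.second.root, 1, depths);
    double tot = 0; int mx = 0;
    for (int d : depths) { tot += d; mx = std::max(mx, d); }
    out["avg_depth"] = depths.empty() ? 0.0 : tot / depths.size();
    out["max_depth"] = mx;
  } else if (auto* b = dynamic_cast<FenwickBKBackend*>(E->backend.get())) {
    int pop = 0;
    for (auto& t : b->trees) if (t.root >= 0) pop++;
    out["n_frequency_ranks"] = (double)b->vals.size();
    out["n_populated_nodes"] = pop;
  }
  return out;
}
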