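#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Weisfeiler-Lehman subtree relabeling over residue-contact graphs.
// Iteration 0 emits each node's initial label verbatim; iteration i emits a
// digest of (own iteration-(i-1) label, sorted multiset of neighbour labels).
// The digest is a 64-bit FNV-1a hash rendered as 16 lowercase hex characters,
// which is stable across runs and platforms.

static inline uint64_t fnv1a64(const std::string& s) {
  uint64_t h = 14695981039346656037ULL;
  for (unsigned char c : s) {
    h ^= (uint64_t)c;
    h *= 1099511628211ULL;
  }
  return h;
}

static inline std::string hex16(uint64_t h) {
  static const char* digits = "0123456789abcdef";
  std::string out(16, '0');
  for (int i = 15; i >= 0; --i) {
    out[i] = digits[h & 0xF];
    h >>= 4;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_wl_digest(std::string signature) {
  return hex16(fnv1a64(signature));
}

// [[Rcpp::export]]
std::string cpp_fnv_raw(RawVector bytes) {
  uint64_t h = 14695981039346656037ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= 1099511628211ULL;
  }
  return hex16(h);
}

// WL token stream for a single graph: (k+1) * n tokens, iteration-major,
// nodes in input order within each iteration.
static void wl_tokens_one(const std::vector<std::string>& init_labels,
                          const std::vector<std::vector<int>>& adj,
                          int k, std::vector<std::string>& out) {
  const int n = (int)init_labels.size();
  std::vector<std::string> cur = init_labels;
  for (int v = 0; v < n; ++v) out.push_back(cur[v]);
  std::vector<std::string> nxt(n);
  for (int it = 1; it <= k; ++it) {
    for (int v = 0; v < n; ++v) {
      std::vector<std::string> nb;
      nb.reserve(adj[v].size());
      for (int u : adj[v]) nb.push_back(cur[u]);
      std::sort(nb.begin(), nb.end());
      std::string sig = cur[v];
      sig += '|';
      for (size_t q = 0; q < nb.size(); ++q) {
        if (q) sig += ',';
        sig += nb[q];
      }
      nxt[v] = hex16(fnv1a64(sig));
      out.push_back(nxt[v]);
    }
    cur = nxt;
  }
}

// [[Rcpp::export]]
CharacterVector cpp_wl_document(CharacterVector labels, IntegerMatrix edges,
                                int k) {
  const int n = labels.size();
  std::vector<std::string> init(n);
  for (int v = 0; v < n; ++v) init[v] = as<std::string>(labels[v]);
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    const int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (a < 0 || a >= n || b < 0 || b >= n)
      stop("edge endpoint outside node set");
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  std::vector<std::string> out;
  out.reserve((size_t)(k + 1) * n);
  wl_tokens_one(init, adj, k, out);
  return wrap(out);
}

// Build the WL token corpus for a stack of frame graphs sharing one node set
// and one edge vocabulary. `occupancy` is frames x edges (0/1); `edge_ends`
// gives the two node indices (1-based) of each vocabulary edge. Tokens are
// interned to integer ids by order of first appearance, which is
// deterministic for a fixed input.
// [[Rcpp::export]]
List cpp_wl_corpus(CharacterVector labels, IntegerMatrix edge_ends,
                   IntegerMatrix occupancy, int k) {
  const int n = labels.size();
  const int nE = edge_ends.nrow();
  const int nF = occupancy.nrow();
  if (occupancy.ncol() != nE) stop("occupancy/edge vocabulary mismatch");
  std::vector<std::string> init(n);
  for (int v = 0; v < n; ++v) init[v] = as<std::string>(labels[v]);

  std::unordered_map<std::string, int> intern;
  std::vector<std::string> vocab;
  std::vector<int> counts;
  std::vector<int> tokens;
  tokens.reserve((size_t)nF * (k + 1) * n);
  std::vector<int> offsets(nF + 1);
  offsets[0] = 0;

  std::vector<std::vector<int>> adj(n);
  std::vector<std::string> toks;
  for (int f = 0; f < nF; ++f) {
    for (int v = 0; v < n; ++v) adj[v].clear();
    for (int e = 0; e < nE; ++e) {
      if (occupancy(f, e)) {
        const int a = edge_ends(e, 0) - 1, b = edge_ends(e, 1) - 1;
        adj[a].push_back(b);
        adj[b].push_back(a);
      }
    }
    toks.clear();
    wl_tokens_one(init, adj, k, toks);
    for (const std::string& t : toks) {
      auto it = intern.find(t);
      int id;
      if (it == intern.end()) {
        id = (int)vocab.size();
        intern.emplace(t, id);
        vocab.push_back(t);
        counts.push_back(0);
      } else {
        id = it->second;
      }
      counts[id] += 1;
      tokens.push_back(id);
    }
    offsets[f + 1] = (int)tokens.size();
  }
  return List::create(_["tokens"] = wrap(tokens),
                      _["offsets"] = wrap(offsets),
                      _["vocab"] = wrap(vocab),
                      _["counts"] = wrap(counts));
}
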