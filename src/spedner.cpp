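#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Character-level cost model: substitutions that only change letter case or
// swap one separator for another are cheap; separator indels are cheaper
// than letter indels. Costs are symmetric by construction.
struct CostModel {
  double sub_def, sub_case, sub_sep, ind_def, ind_sep;
  static bool is_sep(char c) { return c == '-' || c == ' ' || c == '_'; }
  static char lower(char c) {
    return (c >= 'A' && c <= 'Z') ? static_cast<char>(c + 32) : c;
  }
  double sub(char a, char b) const {
    if (a == b) return 0.0;
    if (lower(a) == lower(b)) return sub_case;
    if (is_sep(a) && is_sep(b)) return sub_sep;
    return sub_def;
  }
  double ind(char c) const { return is_sep(c) ? ind_sep : ind_def; }
};

static CostModel cost_model(List costs) {
  CostModel cm;
  cm.sub_def = as<double>(costs["substitute_default"]);
  cm.sub_case = as<double>(costs["substitute_case_only"]);
  cm.sub_sep = as<double>(costs["substitute_separator"]);
  cm.ind_def = as<double>(costs["indel_default"]);
  cm.ind_sep = as<double>(costs["indel_separator"]);
  return cm;
}

// [[Rcpp::export(name = ".wed_cpp")]]
double wed_cpp(std::string a, std::string b, List costs) {
  CostModel cm = cost_model(costs);
  const size_t n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  prev[0] = 0.0;
  for (size_t j = 1; j <= m; ++j) prev[j] = prev[j - 1] + cm.ind(b[j - 1]);
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = prev[0] + cm.ind(a[i - 1]);
    for (size_t j = 1; j <= m; ++j) {
      double d = prev[j - 1] + cm.sub(a[i - 1], b[j - 1]);
      double del = prev[j] + cm.ind(a[i - 1]);
      double ins = cur[j - 1] + cm.ind(b[j - 1]);
      cur[j] = std::min(d, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Trie over dictionary keys; std::map children keep traversal order
// deterministic. Terminal nodes carry the 1-based index of their key.
struct TrieNode {
  std::map<char, int> children;
  int key_id = 0;  // 0 = not terminal
};

struct Trie {
  std::vector<TrieNode> nodes;
  Trie() { nodes.emplace_back(); }
  void insert(const std::string& key, int id) {
    int cur = 0;
    for (char c : key) {
      auto it = nodes[cur].children.find(c);
      if (it == nodes[cur].children.end()) {
        nodes.emplace_back();
        int nxt = static_cast<int>(nodes.size()) - 1;
        nodes[cur].children[c] = nxt;
        cur = nxt;
      } else {
        cur = it->second;
      }
    }
    nodes[cur].key_id = id;
  }
};

// [[Rcpp::export(name = ".trie_build_cpp")]]
SEXP trie_build_cpp(CharacterVector keys) {
  Trie* t = new Trie();
  for (int i = 0; i < keys.size(); ++i) {
    t->insert(as<std::string>(keys[i]), i + 1);
  }
  XPtr<Trie> ptr(t, true);
  return ptr;
}

static const double EPS = 1e-9;

static void trie_dfs(const Trie& t, int node, const std::string& q,
                     const CostModel& cm, double max_cost,
                     std::vector<double>& row, std::vector<int>& out_id,
                     std::vector<double>& out_cost) {
  const size_t m = q.size();
  if (t.nodes[node].key_id && row[m] <= max_cost + EPS) {
    out_id.push_back(t.nodes[node].key_id);
    out_cost.push_back(row[m]);
  }
  for (const auto& kv : t.nodes[node].children) {
    char c = kv.first;
    std::vector<double> nrow(m + 1);
    nrow[0] = row[0] + cm.ind(c);
    double rmin = nrow[0];
    for (size_t j = 1; j <= m; ++j) {
      double d = row[j - 1] + cm.sub(c, q[j - 1]);
      double del = row[j] + cm.ind(c);
      double ins = nrow[j - 1] + cm.ind(q[j - 1]);
      nrow[j] = std::min(d, std::min(del, ins));
      if (nrow[j] < rmin) rmin = nrow[j];
    }
    // all costs are non-negative, so the row minimum never decreases with
    // depth: subtrees past the threshold cannot recover
    if (rmin <= max_cost + EPS) {
      trie_dfs(t, kv.second, q, cm, max_cost, nrow, out_id, out_cost);
    }
  }
}

// [[Rcpp::export(name = ".trie_lookup_cpp")]]
DataFrame trie_lookup_cpp(SEXP trie_ptr, std::string query, double max_cost,
                          List costs) {
  XPtr<Trie> t(trie_ptr);
  CostModel cm = cost_model(costs);
  const size_t m = query.size();
  std::vector<double> row(m + 1);
  row[0] = 0.0;
  for (size_t j = 1; j <= m; ++j) row[j] = row[j - 1] + cm.ind(query[j - 1]);
  std::vector<int> ids;
  std::vector<double> dist;
  trie_dfs(*t, 0, query, cm, max_cost, row, ids, dist);
  return DataFrame::create(_["key_id"] = ids, _["cost"] = dist);
}

// Shortest source -> bottom-right path over the alignment grid.
// dist[i][j] uses 1-based grid coordinates; the source sits above-left of
// (1,1) and connects to it by a diagonal edge of weight scores(1,1).
// Among minimum-weight paths the one with the most edges is reported, which
// minimizes the edge-normalized score.
// [[Rcpp::export(name = ".grid_shortest_path_cpp")]]
List grid_shortest_path_cpp(NumericMatrix scores, double gap) {
  const int m = scores.nrow(), n = scores.ncol();
  std::vector<std::vector<double>> dist(m + 1,
      std::vector<double>(n + 1, std::numeric_limits<double>::infinity()));
  std::vector<std::vector<int>> edges(m + 1, std::vector<int>(n + 1, 0));
  dist[1][1] = scores(0, 0);
  edges[1][1] = 1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      if (i == 1 && j == 1) continue;
      double bw = std::numeric_limits<double>::infinity();
      int be = 0;
      // diagonal (substitution/match), horizontal (deletion),
      // vertical (insertion)
      struct { double w; int e; } cand[3];
      int nc = 0;
      if (i > 1 && j > 1) {
        cand[nc].w = dist[i - 1][j - 1] + scores(i - 1, j - 1);
        cand[nc].e = edges[i - 1][j - 1] + 1; ++nc;
      }
      if (j > 1) {
        cand[nc].w = dist[i][j - 1] + gap;
        cand[nc].e = edges[i][j - 1] + 1; ++nc;
      }
      if (i > 1) {
        cand[nc].w = dist[i - 1][j] + gap;
        cand[nc].e = edges[i - 1][j] + 1; ++nc;
      }
      for (int k = 0; k < nc; ++k) {
        if (cand[k].w < bw - EPS ||
            (cand[k].w <= bw + EPS && cand[k].e > be)) {
          if (cand[k].w < bw) bw = cand[k].w;
          be = cand[k].e;
        }
      }
      dist[i][j] = bw;
      edges[i][j] = be;
    }
  }
  double w = dist[m][n];
  int e = edges[m][n];
  return List::create(_["weight"] = w, _["edge_count"] = e,
                      _["normalized"] = w / e);
}
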