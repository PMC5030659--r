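#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
#include <queue>
using namespace Rcpp;

// Aho-Corasick multi-pattern exact matching over the DNA alphabet.
// Patterns are restricted to A/C/G/T; any other character in the scanned text
// (N in particular) matches nothing and resets the automaton to the root.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

struct ACAutomaton {
  // goto function: states x 4; -1 = undefined (filled to full goto after build)
  std::vector<std::array<int, 4>> go;
  std::vector<int> fail;
  // per-state list of pattern indices ending here (after output-link merge)
  std::vector<std::vector<int>> out;

  ACAutomaton() {
    go.push_back({-1, -1, -1, -1});
    fail.push_back(0);
    out.emplace_back();
  }

  void add(const std::string &pat, int id) {
    int s = 0;
    for (char c : pat) {
      int b = base_code(c);
      if (b < 0) stop("pattern contains a non-ACGT character");
      if (go[s][b] < 0) {
        go.push_back({-1, -1, -1, -1});
        fail.push_back(0);
        out.emplace_back();
        go[s][b] = (int)go.size() - 1;
      }
      s = go[s][b];
    }
    out[s].push_back(id);
  }

  void build() {
    std::queue<int> q;
    for (int b = 0; b < 4; ++b) {
      if (go[0][b] < 0) go[0][b] = 0;
      else { fail[go[0][b]] = 0; q.push(go[0][b]); }
    }
    while (!q.empty()) {
      int s = q.front(); q.pop();
      for (int b = 0; b < 4; ++b) {
        int t = go[s][b];
        if (t < 0) { go[s][b] = go[fail[s]][b]; continue; }
        fail[t] = go[fail[s]][b];
        const std::vector<int> &fo = out[fail[t]];
        out[t].insert(out[t].end(), fo.begin(), fo.end());
        q.push(t);
      }
    }
  }
};

// Returns a data.frame(pattern = 1-based index into `patterns`,
//                      text    = 1-based index into `texts`,
//                      pos     = 0-based start of the exact occurrence).
// [[Rcpp::export(name = ".ac_search_cpp")]]
DataFrame ac_search_cpp(CharacterVector patterns, CharacterVector texts) {
  ACAutomaton ac;
  std::vector<int> plen(patterns.size());
  for (int i = 0; i < patterns.size(); ++i) {
    std::string p = as<std::string>(patterns[i]);
    plen[i] = (int)p.size();
    if (p.empty()) stop("empty pattern");
    ac.add(p, i);
  }
  ac.build();
  std::vector<int> r_pat, r_txt, r_pos;
  for (int t = 0; t < texts.size(); ++t) {
    const char *s = CHAR(STRING_ELT(texts, t));
    int state = 0;
    for (int i = 0; s[i] != '\0'; ++i) {
      int b = base_code(s[i]);
      if (b < 0) { state = 0; continue; }
      state = ac.go[state][b];
      for (int id : ac.out[state]) {
        r_pat.push_back(id + 1);
        r_txt.push_back(t + 1);
        r_pos.push_back(i - plen[id] + 1);
      }
    }
  }
  return DataFrame::create(_["pattern"] = r_pat, _["text"] = r_txt,
                           _["pos"] = r_pos);
}
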