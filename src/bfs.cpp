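// Exhaustive bidirectional breadth-first search over the rearrangement
// operation set (reversal, translocation, fusion, fission) on small
// multichromosomal signed genomes.  States are canonicalised up to
// chromosome order and whole-chromosome flips.  Serves as the independent
// ground-truth oracle for the analytic distance.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> Chrom;
typedef std::vector<Chrom> Genome;

static Chrom flipped(const Chrom& x) {
  Chrom y(x.rbegin(), x.rend());
  for (size_t i = 0; i < y.size(); ++i) y[i] = -y[i];
  return y;
}

static Genome canon(const Genome& g) {
  Genome h;
  h.reserve(g.size());
  for (const Chrom& ch : g) {
    Chrom f = flipped(ch);
    h.push_back(std::lexicographical_compare(f.begin(), f.end(), ch.begin(), ch.end()) ? f : ch);
  }
  std::sort(h.begin(), h.end());
  return h;
}

static std::string key_of(const Genome& g) {
  std::string s;
  for (const Chrom& ch : g) {
    for (int v : ch) {
      s += std::to_string(v);
      s += ',';
    }
    s += ';';
  }
  return s;
}

static void neighbors(const Genome& g, std::vector<Genome>& out) {
  out.clear();
  int nc = (int)g.size();
  // reversals
  for (int c = 0; c < nc; ++c) {
    int l = (int)g[c].size();
    for (int i = 0; i < l; ++i)
      for (int j = i; j < l; ++j) {
        if (i == 0 && j == l - 1) continue;  // whole-chromosome flip: no-op
        Genome h = g;
        std::reverse(h[c].begin() + i, h[c].begin() + j + 1);
        for (int k = i; k <= j; ++k) h[c][k] = -h[c][k];
        out.push_back(std::move(h));
      }
  }
  // translocations (both reconnection types)
  for (int c1 = 0; c1 < nc; ++c1)
    for (int c2 = c1 + 1; c2 < nc; ++c2) {
      int l1 = (int)g[c1].size(), l2 = (int)g[c2].size();
      // terminal gaps allowed: translocations include tail transfers
      // (one empty exchanged piece), as in the capped HP/GRIMM model
      for (int s1 = 0; s1 <= l1; ++s1)
        for (int s2 = 0; s2 <= l2; ++s2) {
          Chrom a1(g[c1].begin(), g[c1].begin() + s1), a2(g[c1].begin() + s1, g[c1].end());
          Chrom b1(g[c2].begin(), g[c2].begin() + s2), b2(g[c2].begin() + s2, g[c2].end());
          if (s1 + (l2 - s2) > 0 && s2 + (l1 - s1) > 0 &&
              !(s1 == 0 && s2 == 0) && !(s1 == l1 && s2 == l2)) {
            Genome h = g;
            h[c1] = a1; h[c1].insert(h[c1].end(), b2.begin(), b2.end());
            h[c2] = b1; h[c2].insert(h[c2].end(), a2.begin(), a2.end());
            out.push_back(std::move(h));
          }
          if (s1 + s2 > 0 && (l1 - s1) + (l2 - s2) > 0 &&
              !(s1 == 0 && s2 == l2) && !(s1 == l1 && s2 == 0)) {
            Genome h = g;
            Chrom fb1 = flipped(b1), fa2 = flipped(a2);
            h[c1] = a1; h[c1].insert(h[c1].end(), fb1.begin(), fb1.end());
            h[c2] = fa2; h[c2].insert(h[c2].end(), b2.begin(), b2.end());
            out.push_back(std::move(h));
          }
        }
    }
  // fusions (all four junctions)
  for (int c1 = 0; c1 < nc; ++c1)
    for (int c2 = c1 + 1; c2 < nc; ++c2) {
      for (int v = 0; v < 4; ++v) {
        Chrom a = g[c1], b = g[c2];
        if (v == 1) b = flipped(b);
        if (v == 2) a = flipped(a);
        if (v == 3) { a = flipped(a); b = flipped(b); }
        Chrom j = a;
        j.insert(j.end(), b.begin(), b.end());
        Genome h;
        for (int c = 0; c < nc; ++c)
          if (c != c1 && c != c2) h.push_back(g[c]);
        h.push_back(std::move(j));
        out.push_back(std::move(h));
      }
    }
  // fissions
  for (int c = 0; c < nc; ++c) {
    int l = (int)g[c].size();
    for (int gp = 1; gp < l; ++gp) {
      Genome h;
      for (int cc = 0; cc < nc; ++cc)
        if (cc != c) h.push_back(g[cc]);
      h.push_back(Chrom(g[c].begin(), g[c].begin() + gp));
      h.push_back(Chrom(g[c].begin() + gp, g[c].end()));
      out.push_back(std::move(h));
    }
  }
}

static Genome from_list(const List& l) {
  Genome g;
  for (int i = 0; i < l.size(); ++i) {
    IntegerVector ch = l[i];
    g.push_back(Chrom(ch.begin(), ch.end()));
  }
  return g;
}

// [[Rcpp::export]]
int bfs_oracle_cpp(List a, List b, double max_states) {
  Genome ga = canon(from_list(a)), gb = canon(from_list(b));
  std::string ka = key_of(ga), kb = key_of(gb);
  if (ka == kb) return 0;

  // visited[side]: canonical key -> depth; frontier[side]: genomes at depth r
  std::unordered_map<std::string, int> vis[2];
  std::vector<Genome> frontier[2];
  int radius[2] = {0, 0};
  vis[0][ka] = 0; frontier[0].push_back(ga);
  vis[1][kb] = 0; frontier[1].push_back(gb);

  int best = -1;
  std::vector<Genome> nb;
  while (!frontier[0].empty() && !frontier[1].empty()) {
    int side = frontier[0].size() <= frontier[1].size() ? 0 : 1;
    int other = 1 - side;
    std::vector<Genome> next;
    int depth = radius[side] + 1;
    for (const Genome& g : frontier[side]) {
      neighbors(g, nb);
      for (Genome& h : nb) {
        Genome ch = canon(h);
        std::string k = key_of(ch);
        std::unordered_map<std::string, int>::iterator hit = vis[other].find(k);
        if (hit != vis[other].end()) {
          int cand = depth + hit->second;
          if (best < 0 || cand < best) best = cand;
        }
        if (vis[side].find(k) == vis[side].end()) {
          vis[side][k] = depth;
          next.push_back(std::move(ch));
        }
      }
      if ((double)(vis[0].size() + vis[1].size()) > max_states) return -1;
    }
    radius[side] = depth;
    frontier[side] = std::move(next);
    if (best >= 0 && best <= radius[0] + radius[1] + 1) return best;
  }
  return best;  // exhausted one side: best (or -1, unreachable: cannot happen)
}
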