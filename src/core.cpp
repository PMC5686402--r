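// Core graph machinery: canonical certificates, automorphism groups,
// orderly generation of constitutional isomers, a plain brute-force
// enumerator used as test oracle, and labeled subgraph matching.
//
// Molecules are element-labeled multigraphs with bond orders 1..3 and
// implicit hydrogens: every heavy atom carries (valence - bond order sum)
// hydrogens. The serialization of a graph under an atom ordering is the
// column-major upper triangle of its bond-order matrix, i.e. for atom k the
// segment A[0][k], A[1][k], ..., A[k-1][k]. The canonical form is the
// lexicographically maximal serialization over all element-preserving atom
// permutations; this prefix-extends under vertex addition, which is what
// makes orderly generation sound.

#include <Rcpp.h>
#include <functional>
#include <string>
#include <vector>
#include <set>
#include <algorithm>
using namespace Rcpp;

namespace {

struct MG {
  int n;
  std::vector<int> val;          // valence per atom
  std::vector<std::string> sym;  // element symbol per atom
  std::vector<int> A;            // n*n bond-order matrix, flattened
  int at(int i, int j) const { return A[i * n + j]; }
  int& at(int i, int j) { return A[i * n + j]; }
};

MG fromR(const CharacterVector& sym, const IntegerVector& val,
         const IntegerMatrix& A) {
  MG g;
  g.n = sym.size();
  g.val.resize(g.n);
  g.sym.resize(g.n);
  for (int i = 0; i < g.n; ++i) {
    g.val[i] = val[i];
    g.sym[i] = as<std::string>(sym[i]);
  }
  g.A.assign(g.n * g.n, 0);
  for (int i = 0; i < g.n; ++i)
    for (int j = 0; j < g.n; ++j) g.at(i, j) = A(i, j);
  return g;
}

// Atom ordering used for canonical forms: valence descending, then symbol
// ascending. Atoms with equal (valence, symbol) form one class; the
// canonical search permutes atoms only within classes.
struct ClassOrder {
  std::vector<int> order;   // position -> original atom index (sorted)
  std::vector<int> cls;     // position -> class id (non-decreasing)
  std::string symline;      // symbols in sorted order, concatenated
};

ClassOrder classOrder(const MG& g) {
  ClassOrder co;
  co.order.resize(g.n);
  for (int i = 0; i < g.n; ++i) co.order[i] = i;
  std::stable_sort(co.order.begin(), co.order.end(), [&](int a, int b) {
    if (g.val[a] != g.val[b]) return g.val[a] > g.val[b];
    return g.sym[a] < g.sym[b];
  });
  co.cls.resize(g.n);
  for (int p = 0; p < g.n; ++p) {
    if (p == 0)
      co.cls[p] = 0;
    else {
      int a = co.order[p - 1], b = co.order[p];
      bool same = (g.val[a] == g.val[b]) && (g.sym[a] == g.sym[b]);
      co.cls[p] = same ? co.cls[p - 1] : co.cls[p - 1] + 1;
    }
  }
  for (int p = 0; p < g.n; ++p) co.symline += g.sym[co.order[p]];
  return co;
}

// Maximal-serialization search. best is the running maximum; -1 entries mean
// "undecided, smaller than any digit". perm[pos] = original atom placed at
// canonical position pos.
struct MaxSearch {
  const MG* g;
  const ClassOrder* co;
  int n, L;
  std::vector<int> best;
  std::vector<int> perm;
  std::vector<char> used;

  void run(const MG& graph, const ClassOrder& order) {
    g = &graph;
    co = &order;
    n = g->n;
    L = n * (n - 1) / 2;
    best.assign(L, -1);
    perm.assign(n, -1);
    used.assign(n, 0);
    dfs(0, 0);
  }

  void dfs(int pos, int off) {
    if (pos == n) return;
    // candidates: original atoms in the class of this position
    for (int p = 0; p < n; ++p) {
      if (co->cls[p] != co->cls[pos]) continue;
      int cand = co->order[p];
      if (used[cand]) continue;
      // segment = bonds from already-placed atoms to cand
      int cmp = 0;
      for (int j = 0; j < pos && cmp == 0; ++j) {
        int v = g->at(perm[j], cand);
        int b = best[off + j];
        if (v > b) cmp = 1;
        else if (v < b) cmp = -1;
      }
      if (cmp < 0) continue;
      if (cmp > 0) {
        for (int j = 0; j < pos; ++j) best[off + j] = g->at(perm[j], cand);
        for (int t = off + pos; t < L; ++t) best[t] = -1;
      }
      perm[pos] = cand;
      used[cand] = 1;
      dfs(pos + 1, off + pos);
      used[cand] = 0;
      perm[pos] = -1;
    }
  }
};

std::string certCore(const MG& g) {
  ClassOrder co = classOrder(g);
  if (g.n == 1) return co.symline + ":";
  MaxSearch ms;
  ms.run(g, co);
  std::string digits(ms.L, '0');
  for (int t = 0; t < ms.L; ++t) digits[t] = char('0' + ms.best[t]);
  return co.symline + ":" + digits;
}

// ---- connectivity -------------------------------------------------------

bool connectedUpTo(const MG& g, int k) {
  // connectivity of the induced subgraph on atoms 0..k
  if (k == 0) return true;
  std::vector<char> seen(k + 1, 0);
  std::vector<int> stack{0};
  seen[0] = 1;
  int cnt = 1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    for (int v = 0; v <= k; ++v) {
      if (!seen[v] && g.at(u, v) > 0) {
        seen[v] = 1;
        ++cnt;
        stack.push_back(v);
      }
    }
  }
  return cnt == k + 1;
}

// ---- patterns -----------------------------------------------------------

struct Pat {
  int m;
  std::vector<std::string> sym;  // element symbol or "*"
  std::vector<int> minH;
  std::vector<int> B;            // m*m bond matrix; -1 none, 0 any, 1..3 order
  int at(int i, int j) const { return B[i * m + j]; }
  std::vector<int> order;        // connected matching order
};

Pat patFromList(const List& lst) {
  Pat p;
  CharacterVector es = lst["elements"];
  IntegerVector mh = lst["min_h"];
  IntegerMatrix bm = lst["bonds"];  // rows: i, j, order (1-based atoms)
  p.m = es.size();
  p.sym.resize(p.m);
  p.minH.resize(p.m);
  for (int i = 0; i < p.m; ++i) {
    p.sym[i] = as<std::string>(es[i]);
    p.minH[i] = mh[i];
  }
  p.B.assign(p.m * p.m, -1);
  for (int r = 0; r < bm.nrow(); ++r) {
    int i = bm(r, 0) - 1, j = bm(r, 1) - 1, o = bm(r, 2);
    p.B[i * p.m + j] = o;
    p.B[j * p.m + i] = o;
  }
  // BFS order so each pattern atom (after the first) touches a placed one
  p.order.clear();
  std::vector<char> placed(p.m, 0);
  p.order.push_back(0);
  placed[0] = 1;
  while ((int)p.order.size() < p.m) {
    bool found = false;
    for (int i = 0; i < p.m && !found; ++i) {
      if (placed[i]) continue;
      for (int j : p.order) {
        if (p.at(i, j) >= 0) {
          p.order.push_back(i);
          placed[i] = 1;
          found = true;
          break;
        }
      }
    }
    if (!found) stop("pattern graph is not connected");
  }
  return p;
}

bool matchRec(const Pat& p, const MG& g, const std::vector<int>& H,
              std::vector<int>& asg, std::vector<char>& used, size_t step) {
  if (step == p.order.size()) return true;
  int a = p.order[step];
  for (int u = 0; u < g.n; ++u) {
    if (used[u]) continue;
    if (p.sym[a] != "*" && p.sym[a] != g.sym[u]) continue;
    if (H[u] < p.minH[a]) continue;
    bool ok = true;
    for (size_t s = 0; s < step && ok; ++s) {
      int b = p.order[s];
      int po = p.at(a, b);
      if (po < 0) continue;  // no pattern bond: subgraph (not induced) match
      int go = g.at(u, asg[b]);
      if (go == 0) ok = false;
      else if (po > 0 && go != po) ok = false;
    }
    if (!ok) continue;
    asg[a] = u;
    used[u] = 1;
    if (matchRec(p, g, H, asg, used, step + 1)) {
      used[u] = 0;
      return true;
    }
    used[u] = 0;
    asg[a] = -1;
  }
  return false;
}

std::vector<int> implicitH(const MG& g) {
  std::vector<int> H(g.n, 0);
  for (int i = 0; i < g.n; ++i) {
    int s = 0;
    for (int j = 0; j < g.n; ++j) s += g.at(i, j);
    H[i] = g.val[i] - s;
  }
  return H;
}

bool patMatches(const Pat& p, const MG& g) {
  if (p.m > g.n) return false;
  std::vector<int> H = implicitH(g);
  std::vector<int> asg(p.m, -1);
  std::vector<char> used(g.n, 0);
  return matchRec(p, g, H, asg, used, 0);
}

}  // namespace

// ---- exported: certificate / automorphisms ------------------------------

// [[Rcpp::export]]
std::string cpp_certificate(CharacterVector sym, IntegerVector val,
                            IntegerMatrix A) {
  MG g = fromR(sym, val, A);
  return certCore(g);
}

// [[Rcpp::export]]
IntegerMatrix cpp_automorphisms(CharacterVector sym, IntegerVector val,
                                IntegerMatrix A) {
  MG g = fromR(sym, val, A);
  int n = g.n;
  std::vector<std::vector<int>> auts;
  std::vector<int> perm(n, -1);
  std::vector<char> used(n, 0);
  // recursive search: perm maps atom i -> image, element-preserving,
  // bond-preserving on all decided pairs
  std::function<void(int)> rec = [&](int pos) {
    if (pos == n) {
      auts.push_back(perm);
      return;
    }
    for (int u = 0; u < n; ++u) {
      if (used[u]) continue;
      if (g.sym[u] != g.sym[pos] || g.val[u] != g.val[pos]) continue;
      bool ok = true;
      for (int j = 0; j < pos && ok; ++j)
        if (g.at(perm[j], u) != g.at(j, pos)) ok = false;
      if (!ok) continue;
      perm[pos] = u;
      used[u] = 1;
      rec(pos + 1);
      used[u] = 0;
      perm[pos] = -1;
    }
  };
  rec(0);
  IntegerMatrix out(auts.size(), n);
  for (size_t r = 0; r < auts.size(); ++r)
    for (int c = 0; c < n; ++c) out(r, c) = auts[r][c] + 1;
  return out;
}

// ---- exported: subgraph matching ----------------------------------------

// [[Rcpp::export]]
bool cpp_match(List pattern, CharacterVector sym, IntegerVector val,
               IntegerMatrix A) {
  Pat p = patFromList(pattern);
  MG g = fromR(sym, val, A);
  return patMatches(p, g);
}

// ---- exported: orderly generation ---------------------------------------

namespace {

struct Gen {
  MG g;                 // working graph; atoms pre-sorted by class order
  std::vector<int> cls; // class id per position
  int n, T, nH;
  std::vector<int> res; // residual valence per atom
  int curT;
  std::vector<Pat> bad, good;
  double maxEmit;
  std::vector<std::string> out;       // serializations of survivors
  long long nCanonical = 0;           // canonical structures before filters
  std::vector<long long> badHits;     // first-match counts per bad pattern
  long long goodFail = 0;
  long long nodes = 0;

  // serialization prefix compare under transposition sigma(i)<->sigma(j),
  // over the first k+1 atoms. Returns +1 if transposed > original.
  int transposedCmp(int i, int j, int k) const {
    for (int b = 1; b <= k; ++b) {
      for (int a = 0; a < b; ++a) {
        int oa = a == i ? j : (a == j ? i : a);
        int ob = b == i ? j : (b == j ? i : b);
        int vOrig = g.at(a, b);
        int vSwap = g.at(oa, ob);
        if (vSwap > vOrig) return 1;
        if (vSwap < vOrig) return -1;
      }
    }
    return 0;
  }

  // full canonicity at leaf: no element-preserving permutation yields a
  // strictly larger serialization
  bool leafCanonical() {
    std::vector<int> perm(n, -1);
    std::vector<char> used(n, 0);
    bool bigger = false;
    std::function<void(int)> rec = [&](int pos) {
      if (bigger) return;
      if (pos == n) return;
      for (int u = 0; u < n && !bigger; ++u) {
        if (used[u] || cls[u] != cls[pos]) continue;
        int cmp = 0;
        for (int j = 0; j < pos && cmp == 0; ++j) {
          int v = g.at(perm[j], u);
          int t = g.at(j, pos);
          if (v > t) cmp = 1;
          else if (v < t) cmp = -1;
        }
        if (cmp < 0) continue;
        if (cmp > 0) { bigger = true; return; }
        perm[pos] = u;
        used[u] = 1;
        rec(pos + 1);
        used[u] = 0;
        perm[pos] = -1;
      }
    };
    rec(0);
    return !bigger;
  }

  std::string serialize() const {
    std::string s(n * (n - 1) / 2, '0');
    int t = 0;
    for (int b = 1; b < n; ++b)
      for (int a = 0; a < b; ++a) s[t++] = char('0' + g.at(a, b));
    return s;
  }

  void atLeaf() {
    if (curT != T) return;
    if (!connectedUpTo(g, n - 1)) return;
    if (!leafCanonical()) return;
    ++nCanonical;
    for (size_t b = 0; b < bad.size(); ++b) {
      if (patMatches(bad[b], g)) {
        ++badHits[b];
        return;
      }
    }
    for (const Pat& p : good) {
      if (!patMatches(p, g)) {
        ++goodFail;
        return;
      }
    }
    if ((double)out.size() >= maxEmit)
      stop("generation exceeded the configured structure cap");
    out.push_back(serialize());
  }

  // dead-component prune: a connected component among atoms 0..k whose
  // residual sum is zero can never be joined to the rest
  bool deadComponent(int k) const {
    std::vector<int> comp(k + 1, -1);
    int nc = 0;
    for (int s = 0; s <= k; ++s) {
      if (comp[s] >= 0) continue;
      std::vector<int> stack{s};
      comp[s] = nc;
      int rsum = 0, size = 0;
      while (!stack.empty()) {
        int u = stack.back();
        stack.pop_back();
        rsum += res[u];
        ++size;
        for (int v = 0; v <= k; ++v)
          if (comp[v] < 0 && g.at(u, v) > 0) {
            comp[v] = nc;
            stack.push_back(v);
          }
      }
      if (rsum == 0 && size < n) return true;
      ++nc;
    }
    return false;
  }

  void afterColumn(int k) {
    ++nodes;
    if ((nodes & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    // residual feasibility: remaining bonds can only use residual valence
    int resSum = 0;
    for (int i = 0; i < n; ++i) resSum += res[i];
    if (curT + resSum / 2 < T) return;
    if (deadComponent(k)) return;
    // semicanonicity: transposing a same-class earlier atom with atom k must
    // not increase the serialization prefix
    for (int i = 0; i < k; ++i) {
      if (cls[i] != cls[k]) continue;
      if (transposedCmp(i, k, k) > 0) return;
    }
    if (k == n - 1) {
      atLeaf();
      return;
    }
    fillColumn(k + 1, 0);
  }

  // choose bond orders for cells (j, k), j = row .. k-1
  void fillColumn(int k, int row) {
    if (row == k) {
      afterColumn(k);
      return;
    }
    int cap = std::min(3, std::min(res[row], res[k]));
    cap = std::min(cap, T - curT);
    for (int o = cap; o >= 0; --o) {
      g.at(row, k) = o;
      g.at(k, row) = o;
      res[row] -= o;
      res[k] -= o;
      curT += o;
      fillColumn(k, row + 1);
      curT -= o;
      res[row] += o;
      res[k] += o;
      g.at(row, k) = 0;
      g.at(k, row) = 0;
    }
  }

  void run() {
    if (n == 1) {
      if (nH == g.val[0]) {
        curT = 0;
        atLeaf();
      }
      return;
    }
    afterColumn(0);
  }
};

}  // namespace

// sym/val must arrive sorted by (valence desc, symbol asc); the emitted
// serializations are certificates digits under exactly that atom order.
// [[Rcpp::export]]
List cpp_enumerate(CharacterVector sym, IntegerVector val, int nH,
                   List bad, List good, double maxEmit) {
  Gen gen;
  gen.n = sym.size();
  gen.g.n = gen.n;
  gen.g.val.resize(gen.n);
  gen.g.sym.resize(gen.n);
  for (int i = 0; i < gen.n; ++i) {
    gen.g.val[i] = val[i];
    gen.g.sym[i] = as<std::string>(sym[i]);
  }
  for (int i = 1; i < gen.n; ++i) {
    bool okOrder = (gen.g.val[i - 1] > gen.g.val[i]) ||
                   (gen.g.val[i - 1] == gen.g.val[i] &&
                    gen.g.sym[i - 1] <= gen.g.sym[i]);
    if (!okOrder) stop("atoms must be sorted by decreasing valence");
  }
  gen.g.A.assign(gen.n * gen.n, 0);
  ClassOrder co = classOrder(gen.g);  // atoms already sorted: order = id
  gen.cls = co.cls;
  int vsum = 0;
  for (int i = 0; i < gen.n; ++i) vsum += gen.g.val[i];
  if ((vsum - nH) % 2 != 0 || vsum < nH)
    return List::create(_["serializations"] = CharacterVector(0),
                        _["n_canonical"] = 0.0,
                        _["bad_hits"] = NumericVector(bad.size()),
                        _["good_fail"] = 0.0, _["nodes"] = 0.0);
  gen.T = (vsum - nH) / 2;
  gen.nH = nH;
  gen.res = gen.g.val;
  gen.curT = 0;
  gen.maxEmit = maxEmit;
  for (int i = 0; i < bad.size(); ++i) gen.bad.push_back(patFromList(bad[i]));
  for (int i = 0; i < good.size(); ++i) gen.good.push_back(patFromList(good[i]));
  gen.badHits.assign(gen.bad.size(), 0);
  gen.run();
  NumericVector bh(gen.bad.size());
  for (size_t i = 0; i < gen.bad.size(); ++i) bh[i] = (double)gen.badHits[i];
  return List::create(_["serializations"] = wrap(gen.out),
                      _["n_canonical"] = (double)gen.nCanonical,
                      _["bad_hits"] = bh,
                      _["good_fail"] = (double)gen.goodFail,
                      _["nodes"] = (double)gen.nodes);
}

// ---- exported: brute-force oracle ---------------------------------------

// Plain exhaustive enumeration: every symmetric bond-order matrix satisfying
// the valences, connected graphs kept, deduplicated by certificate. No
// canonicity pruning; used as the independent oracle in tests.
// [[Rcpp::export]]
CharacterVector cpp_brute_force(CharacterVector sym, IntegerVector val,
                                int nH, int maxHeavy) {
  int n = sym.size();
  if (n > maxHeavy) stop("brute-force oracle capped at %d heavy atoms", maxHeavy);
  MG g;
  g.n = n;
  g.val.resize(n);
  g.sym.resize(n);
  for (int i = 0; i < n; ++i) {
    g.val[i] = val[i];
    g.sym[i] = as<std::string>(sym[i]);
  }
  g.A.assign(n * n, 0);
  int vsum = 0;
  for (int i = 0; i < n; ++i) vsum += g.val[i];
  std::set<std::string> certs;
  if ((vsum - nH) % 2 != 0 || vsum < nH)
    return CharacterVector(0);
  int T = (vsum - nH) / 2;
  if (n == 1) {
    if (nH == g.val[0]) certs.insert(certCore(g));
  } else {
    // iterate all upper-triangle cells in row-major order
    std::vector<std::pair<int, int>> cells;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) cells.push_back({i, j});
    std::vector<int> res = g.val;
    int curT = 0;
    std::function<void(size_t)> rec = [&](size_t c) {
      if (c == cells.size()) {
        if (curT != T) return;
        if (!connectedUpTo(g, n - 1)) return;
        certs.insert(certCore(g));
        return;
      }
      int i = cells[c].first, j = cells[c].second;
      int cap = std::min(3, std::min(res[i], res[j]));
      cap = std::min(cap, T - curT);
      for (int o = 0; o <= cap; ++o) {
        g.at(i, j) = o;
        g.at(j, i) = o;
        res[i] -= o;
        res[j] -= o;
        curT += o;
        rec(c + 1);
        curT -= o;
        res[i] += o;
        res[j] += o;
        g.at(i, j) = 0;
        g.at(j, i) = 0;
      }
    };
    rec(0);
  }
  return wrap(std::vector<std::string>(certs.begin(), certs.end()));
}
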