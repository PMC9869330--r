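// Chinese-restaurant-franchise state and Gibbs sweeps for the HDP mixture
// model over mutation catalogs.
//
// Representation: each observed mutation ("item") of class c in sample j is a
// customer at the leaf restaurant for j. Each table at a non-root node is
// itself a customer ("virtual customer") at its parent restaurant; tables at
// the root draw dishes directly from the base distribution H, a symmetric
// Dirichlet(1) over the C mutation classes. A dish is a global mutation
// cluster; its class counts give the Dirichlet-multinomial posterior
// predictive (n_kc + 1) / (n_k. + C).
//
// The RNG (xoshiro256++) lives inside the chain state so that runs are
// reproducible and checkpoint resume is bit-exact; R's global RNG is never
// touched.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <vector>
#include <map>
#include <functional>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 seeding + xoshiro256++
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];

  void seed(uint64_t x) {
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1): never exactly 0, safe for log()
  inline double unif_pos() { return ((next() >> 11) + 1.0) * 0x1.0p-53; }

  double normal() {
    double u1 = unif_pos(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  // Gamma(shape a, scale 1), Marsaglia & Tsang; boosting for a < 1
  double gamma(double a) {
    if (a < 1.0) {
      double u = unif_pos();
      return gamma(a + 1.0) * std::pow(u, 1.0 / a);
    }
    double d = a - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do { x = normal(); v = 1.0 + c * x; } while (v <= 0.0);
      v = v * v * v;
      double u = unif_pos();
      if (std::log(u) < 0.5 * x * x + d - d * v + d * std::log(v))
        return d * v;
    }
  }
  double beta(double a, double b) {
    double x = gamma(a), y = gamma(b);
    return x / (x + y);
  }
  // integer in [0, n)
  inline int below(int n) { return (int)(next() % (uint64_t)n); }
};

// ---------------------------------------------------------------------------
// State
// ---------------------------------------------------------------------------
struct Tbl {
  int node;
  int dishid;
  int n;            // customers (items at leaves; child tables otherwise)
  int parent_table; // table id where this table's virtual customer sits (-1 at root)
  int pos;          // index within nodeT[node]
  bool alive;
};

struct Dsh {
  std::vector<int> cc; // class counts (length C)
  long long tot;
  int ntab;            // number of alive tables (any level) serving this dish
  int pos;             // index within aliveD
  bool alive;
};

struct Crf {
  int C, J, nN, nG, nItems;
  std::vector<int> parent;     // per node, -1 at root
  std::vector<int> nodeSample; // per node, sample index of leaf, else -1
  std::vector<int> cpg;        // per node, concentration-parameter group
  double shape, rate;          // gamma prior for alphas (rate == "beta")
  bool resampleAlpha;
  std::vector<double> alpha;   // per cp group

  std::vector<int> itNode, itCls, itTab;

  std::vector<Tbl> tab;
  std::vector<int> freeT;
  std::vector<std::vector<int>> nodeT; // alive table ids per node
  std::vector<long long> nodeN;        // customers per node

  std::vector<Dsh> dishv;
  std::vector<int> freeD;
  std::vector<int> aliveD;

  Xoshiro rng;
  double sweeps;

  std::vector<int> perm;       // scratch for sweep order
  std::vector<double> wbuf;    // scratch weights

  // ---- dish / table management -------------------------------------------
  int newDish() {
    int d;
    if (!freeD.empty()) { d = freeD.back(); freeD.pop_back(); }
    else { d = (int)dishv.size(); dishv.push_back(Dsh()); dishv[d].cc.resize(C); }
    std::fill(dishv[d].cc.begin(), dishv[d].cc.end(), 0);
    dishv[d].tot = 0; dishv[d].ntab = 0; dishv[d].alive = true;
    dishv[d].pos = (int)aliveD.size();
    aliveD.push_back(d);
    return d;
  }
  void freeDish(int d) {
    int p = dishv[d].pos;
    int last = aliveD.back();
    aliveD[p] = last; dishv[last].pos = p;
    aliveD.pop_back();
    dishv[d].alive = false;
    freeD.push_back(d);
  }
  int newTable(int v, int d, int pt) {
    int t;
    if (!freeT.empty()) { t = freeT.back(); freeT.pop_back(); }
    else { t = (int)tab.size(); tab.push_back(Tbl()); }
    tab[t].node = v; tab[t].dishid = d; tab[t].n = 0;
    tab[t].parent_table = pt; tab[t].alive = true;
    tab[t].pos = (int)nodeT[v].size();
    nodeT[v].push_back(t);
    dishv[d].ntab++;
    return t;
  }
  void freeTable(int t) {
    int v = tab[t].node, p = tab[t].pos;
    int last = nodeT[v].back();
    nodeT[v][p] = last; tab[last].pos = p;
    nodeT[v].pop_back();
    tab[t].alive = false;
    freeT.push_back(t);
  }

  // ---- predictive probabilities ------------------------------------------
  inline double fpred(int d, int c) const {
    return (dishv[d].cc[c] + 1.0) / (double)(dishv[d].tot + C);
  }
  double parentPred(int v, int c) const {
    if (v < 0) return 1.0 / C;
    double s = 0.0;
    const std::vector<int>& ts = nodeT[v];
    for (size_t i = 0; i < ts.size(); i++)
      s += tab[ts[i]].n * fpred(tab[ts[i]].dishid, c);
    double a = alpha[cpg[v]];
    return (s + a * parentPred(parent[v], c)) / (nodeN[v] + a);
  }

  // ---- seating ------------------------------------------------------------
  // Seat one customer of class c at node v; returns the table id.
  int seat(int v, int c) {
    const std::vector<int>& ts = nodeT[v];
    int m = (int)ts.size();
    if ((int)wbuf.size() < m + 1) wbuf.resize(m + 1);
    double tot = 0.0;
    for (int i = 0; i < m; i++) {
      double w = tab[ts[i]].n * fpred(tab[ts[i]].dishid, c);
      wbuf[i] = w; tot += w;
    }
    double a = alpha[cpg[v]];
    double wnew = a * parentPred(parent[v], c);
    wbuf[m] = wnew; tot += wnew;
    double u = rng.unif() * tot;
    int idx = m;
    double acc = 0.0;
    for (int i = 0; i <= m; i++) { acc += wbuf[i]; if (u < acc) { idx = i; break; } }
    if (idx < m) {
      int t = ts[idx];
      tab[t].n++; nodeN[v]++;
      return t;
    }
    // open a new table; its virtual customer is seated at the parent by the
    // same class-conditional rule; a new table at the root opens a new dish
    int d, pt = -1;
    if (parent[v] < 0) {
      d = newDish();
    } else {
      pt = seat(parent[v], c);
      d = tab[pt].dishid;
    }
    int t = newTable(v, d, pt);
    tab[t].n = 1; nodeN[v]++;
    return t;
  }
  // Remove one customer from table t; cascades upward when the table empties.
  void unseat(int t) {
    int v = tab[t].node;
    tab[t].n--; nodeN[v]--;
    if (tab[t].n == 0) {
      int d = tab[t].dishid, pt = tab[t].parent_table;
      freeTable(t);
      dishv[d].ntab--;
      if (pt >= 0) unseat(pt); // may itself release the dish
      if (dishv[d].alive && dishv[d].ntab == 0)
        freeDish(d); // by then its counts are zero
    }
  }

  void reseat(int i) {
    int t = itTab[i], c = itCls[i];
    int d = tab[t].dishid;
    dishv[d].cc[c]--; dishv[d].tot--;
    if (dishv[d].cc[c] < 0) stop("negative dish class count (state corrupt)");
    unseat(t);
    int t2 = seat(itNode[i], c);
    itTab[i] = t2;
    int d2 = tab[t2].dishid;
    dishv[d2].cc[c]++; dishv[d2].tot++;
  }

  // ---- concentration parameters ------------------------------------------
  // Auxiliary-variable update for a gamma(shape, rate) prior: per restaurant
  // with n_j customers and t_j tables draw w_j ~ Beta(alpha+1, n_j) and
  // s_j ~ Bernoulli(n_j / (n_j + alpha)); then
  // alpha' ~ Gamma(shape + sum t_j - sum s_j, rate - sum log w_j).
  void resampleGroup(int g) {
    double a = alpha[g];
    double sumT = 0.0, sumS = 0.0, sumLW = 0.0;
    bool any = false;
    for (int v = 0; v < nN; v++) {
      if (cpg[v] != g) continue;
      long long n = nodeN[v];
      if (n <= 0) continue;
      any = true;
      sumT += (double)nodeT[v].size();
      double w = rng.beta(a + 1.0, (double)n);
      sumLW += std::log(w);
      if (rng.unif() < (double)n / ((double)n + a)) sumS += 1.0;
    }
    double sh = any ? (shape + sumT - sumS) : shape;
    double rt = any ? (rate - sumLW) : rate;
    if (rt <= 0.0) stop("non-positive rate in concentration update");
    double na = rng.gamma(sh) / rt;
    alpha[g] = std::max(na, 1e-12);
  }

  void sweep() {
    // fixed shuffled reseating order per sweep, from the chain RNG;
    // the shuffle starts from identity so the order depends only on the
    // RNG state (checkpoint restore reproduces it exactly)
    for (int i = 0; i < nItems; i++) perm[i] = i;
    for (int i = nItems - 1; i > 0; i--) {
      int j = rng.below(i + 1);
      int tmp = perm[i]; perm[i] = perm[j]; perm[j] = tmp;
    }
    for (int i = 0; i < nItems; i++) reseat(perm[i]);
    if (resampleAlpha)
      for (int g = 0; g < nG; g++) resampleGroup(g);
    sweeps += 1.0;
  }
};

static Crf* get(SEXP p) {
  XPtr<Crf> x(p);
  if (!x) stop("invalid CRF state pointer");
  return x.get();
}

// ---------------------------------------------------------------------------
// Construction
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP crf_init(IntegerMatrix counts, IntegerVector parent, IntegerVector node_sample,
              IntegerVector cp_group, double prior_shape, double prior_rate,
              int init_dishes, double alpha_init, bool resample_alpha,
              double seed) {
  Crf* s = new Crf();
  s->C = counts.nrow();
  s->J = counts.ncol();
  s->nN = parent.size();
  s->parent.assign(parent.begin(), parent.end());
  s->nodeSample.assign(node_sample.begin(), node_sample.end());
  s->cpg.assign(cp_group.begin(), cp_group.end());
  int ng = 0;
  for (int v = 0; v < s->nN; v++) ng = std::max(ng, s->cpg[v] + 1);
  s->nG = ng;
  s->shape = prior_shape; s->rate = prior_rate;
  s->resampleAlpha = resample_alpha;
  s->alpha.assign(ng, alpha_init);
  s->nodeT.assign(s->nN, std::vector<int>());
  s->nodeN.assign(s->nN, 0);
  s->sweeps = 0.0;
  s->rng.seed((uint64_t)seed);

  // leaf node of each sample
  std::vector<int> leafOf(s->J, -1);
  for (int v = 0; v < s->nN; v++)
    if (s->nodeSample[v] >= 0) leafOf[s->nodeSample[v]] = v;
  for (int j = 0; j < s->J; j++)
    if (leafOf[j] < 0) stop("sample %d has no leaf node", j + 1);

  // items
  for (int j = 0; j < s->J; j++)
    for (int c = 0; c < s->C; c++) {
      int n = counts(c, j);
      if (n < 0) stop("negative catalog count");
      for (int r = 0; r < n; r++) {
        s->itNode.push_back(leafOf[j]);
        s->itCls.push_back(c);
      }
    }
  s->nItems = (int)s->itNode.size();
  if (s->nItems == 0) stop("catalog contains no mutations");
  s->itTab.assign(s->nItems, -1);
  s->perm.resize(s->nItems);
  for (int i = 0; i < s->nItems; i++) s->perm[i] = i;

  // dispersed init: round-robin over items among init_dishes dishes,
  // one table per (node, dish) pair along each leaf-to-root path
  int D = std::min(std::max(1, init_dishes), s->nItems);
  std::vector<int> dishIds(D);
  for (int d = 0; d < D; d++) dishIds[d] = s->newDish();

  std::vector<std::map<int, int>> nodeDishTab(s->nN); // (node, dish) -> table

  // recursive creation of the table chain for dish d starting at node v
  std::function<int(int, int)> getTab = [&](int v, int d) -> int {
    std::map<int, int>& m = nodeDishTab[v];
    std::map<int, int>::iterator it = m.find(d);
    if (it != m.end()) return it->second;
    int pt = -1;
    if (s->parent[v] >= 0) {
      pt = getTab(s->parent[v], d);
      s->tab[pt].n++;               // this table is a customer at the parent
      s->nodeN[s->parent[v]]++;
    }
    int t = s->newTable(v, d, pt);
    m[d] = t;
    return t;
  };

  for (int i = 0; i < s->nItems; i++) {
    int d = dishIds[i % D];
    int v = s->itNode[i];
    int t = getTab(v, d);
    s->tab[t].n++; s->nodeN[v]++;
    s->itTab[i] = t;
    s->dishv[d].cc[s->itCls[i]]++; s->dishv[d].tot++;
  }

  XPtr<Crf> ptr(s, true);
  return ptr;
}

// ---------------------------------------------------------------------------
// Running
// ---------------------------------------------------------------------------

// Run nsweeps Gibbs sweeps. If record_items, returns an nsweeps x nItems
// integer matrix of per-item dish labels after each sweep (labels are
// arbitrary but consistent within a row).
// [[Rcpp::export]]
IntegerMatrix crf_run(SEXP p, int nsweeps, bool record_items = false) {
  Crf* s = get(p);
  IntegerMatrix rec;
  if (record_items) rec = IntegerMatrix(nsweeps, s->nItems);
  for (int k = 0; k < nsweeps; k++) {
    s->sweep();
    if (record_items)
      for (int i = 0; i < s->nItems; i++)
        rec(k, i) = s->tab[s->itTab[i]].dishid;
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return record_items ? rec : IntegerMatrix(0, 0);
}

// Snapshot the current clusters: per non-empty dish, class counts and
// per-sample counts ("clusters of category counts").
// [[Rcpp::export]]
List crf_snapshot(SEXP p) {
  Crf* s = get(p);
  std::vector<int> keep;
  for (size_t i = 0; i < s->aliveD.size(); i++)
    if (s->dishv[s->aliveD[i]].tot > 0) keep.push_back(s->aliveD[i]);
  int K = (int)keep.size();
  IntegerMatrix cc(s->C, K), sc(s->J, K);
  std::vector<int> colOf(s->dishv.size(), -1);
  for (int k = 0; k < K; k++) {
    colOf[keep[k]] = k;
    for (int c = 0; c < s->C; c++) cc(c, k) = s->dishv[keep[k]].cc[c];
  }
  for (int i = 0; i < s->nItems; i++) {
    int d = s->tab[s->itTab[i]].dishid;
    int j = s->nodeSample[s->itNode[i]];
    sc(j, colOf[d])++;
  }
  return List::create(_["class_counts"] = cc, _["sample_counts"] = sc);
}

// [[Rcpp::export]]
NumericVector crf_alpha(SEXP p) {
  Crf* s = get(p);
  return NumericVector(s->alpha.begin(), s->alpha.end());
}

// [[Rcpp::export]]
double crf_sweeps_done(SEXP p) { return get(p)->sweeps; }

// [[Rcpp::export]]
int crf_n_dishes(SEXP p) {
  Crf* s = get(p);
  int n = 0;
  for (size_t i = 0; i < s->aliveD.size(); i++)
    if (s->dishv[s->aliveD[i]].tot > 0) n++;
  return n;
}

// ---------------------------------------------------------------------------
// Invariant checks (assertion contract; used heavily by tests)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
bool crf_check(SEXP p) {
  Crf* s = get(p);
  // dish class counts re-derived from items
  std::vector<std::vector<long long>> cc(s->dishv.size(),
                                         std::vector<long long>(s->C, 0));
  std::vector<long long> itemsAtTable(s->tab.size(), 0);
  for (int i = 0; i < s->nItems; i++) {
    int t = s->itTab[i];
    if (t < 0 || !s->tab[t].alive) stop("item seated at dead table");
    itemsAtTable[t]++;
    cc[s->tab[t].dishid][s->itCls[i]]++;
  }
  std::vector<long long> childTables(s->tab.size(), 0);
  std::vector<long long> ntabOfDish(s->dishv.size(), 0);
  long long totalDish = 0;
  for (int v = 0; v < s->nN; v++) {
    long long ncust = 0;
    for (size_t q = 0; q < s->nodeT[v].size(); q++) {
      int t = s->nodeT[v][q];
      if (!s->tab[t].alive || s->tab[t].node != v || s->tab[t].pos != (int)q)
        stop("table bookkeeping corrupt");
      ncust += s->tab[t].n;
      ntabOfDish[s->tab[t].dishid]++;
      if (s->tab[t].parent_table >= 0)
        childTables[s->tab[t].parent_table]++;
    }
    if (ncust != s->nodeN[v]) stop("node customer count mismatch");
  }
  for (size_t t = 0; t < s->tab.size(); t++) {
    if (!s->tab[t].alive) continue;
    if (s->tab[t].n != itemsAtTable[t] + childTables[t])
      stop("table occupancy != items + child tables");
    if (s->tab[t].n <= 0) stop("empty table left alive");
  }
  for (size_t d = 0; d < s->dishv.size(); d++) {
    if (!s->dishv[d].alive) continue;
    long long tot = 0;
    for (int c = 0; c < s->C; c++) {
      if (cc[d][c] != s->dishv[d].cc[c]) stop("dish class count mismatch");
      tot += cc[d][c];
    }
    if (tot != s->dishv[d].tot) stop("dish total mismatch");
    if (ntabOfDish[d] != s->dishv[d].ntab) stop("dish table count mismatch");
    totalDish += tot;
  }
  if (totalDish != s->nItems) stop("dish totals do not sum to item count");
  for (int g = 0; g < s->nG; g++)
    if (!(s->alpha[g] > 0)) stop("non-positive concentration parameter");
  return true;
}

// ---------------------------------------------------------------------------
// Serialization (checkpointing). Tables and dishes are renumbered densely.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List crf_serialize(SEXP p) {
  Crf* s = get(p);
  // dense table ids
  std::vector<int> tmap(s->tab.size(), -1);
  std::vector<int> tlist;
  for (int v = 0; v < s->nN; v++)
    for (size_t q = 0; q < s->nodeT[v].size(); q++) {
      tmap[s->nodeT[v][q]] = (int)tlist.size();
      tlist.push_back(s->nodeT[v][q]);
    }
  // dense dish ids
  std::vector<int> dmap(s->dishv.size(), -1);
  for (size_t q = 0; q < s->aliveD.size(); q++) dmap[s->aliveD[q]] = (int)q;
  int nT = (int)tlist.size(), nD = (int)s->aliveD.size();

  IntegerVector tNode(nT), tDish(nT), tN(nT), tPar(nT);
  for (int q = 0; q < nT; q++) {
    const Tbl& t = s->tab[tlist[q]];
    tNode[q] = t.node; tDish[q] = dmap[t.dishid]; tN[q] = t.n;
    tPar[q] = t.parent_table >= 0 ? tmap[t.parent_table] : -1;
  }
  IntegerMatrix dcc(s->C, nD);
  for (int q = 0; q < nD; q++)
    for (int c = 0; c < s->C; c++) dcc(c, q) = s->dishv[s->aliveD[q]].cc[c];

  IntegerVector itT(s->nItems);
  for (int i = 0; i < s->nItems; i++) itT[i] = tmap[s->itTab[i]];

  RawVector rngRaw(32);
  std::memcpy(RAW(rngRaw), s->rng.s, 32);

  return List::create(
    _["version"] = 1L,
    _["C"] = s->C, _["J"] = s->J,
    _["parent"] = IntegerVector(s->parent.begin(), s->parent.end()),
    _["node_sample"] = IntegerVector(s->nodeSample.begin(), s->nodeSample.end()),
    _["cp_group"] = IntegerVector(s->cpg.begin(), s->cpg.end()),
    _["shape"] = s->shape, _["rate"] = s->rate,
    _["resample_alpha"] = s->resampleAlpha,
    _["alpha"] = NumericVector(s->alpha.begin(), s->alpha.end()),
    _["item_node"] = IntegerVector(s->itNode.begin(), s->itNode.end()),
    _["item_class"] = IntegerVector(s->itCls.begin(), s->itCls.end()),
    _["item_table"] = itT,
    _["table_node"] = tNode, _["table_dish"] = tDish,
    _["table_n"] = tN, _["table_parent"] = tPar,
    _["dish_cc"] = dcc,
    _["rng"] = rngRaw,
    _["sweeps"] = s->sweeps);
}

// [[Rcpp::export]]
SEXP crf_restore(List st) {
  if (as<int>(st["version"]) != 1)
    stop("incompatible checkpoint version");
  Crf* s = new Crf();
  s->C = as<int>(st["C"]); s->J = as<int>(st["J"]);
  IntegerVector parent = st["parent"], nodeSample = st["node_sample"],
    cpg = st["cp_group"];
  s->nN = parent.size();
  s->parent.assign(parent.begin(), parent.end());
  s->nodeSample.assign(nodeSample.begin(), nodeSample.end());
  s->cpg.assign(cpg.begin(), cpg.end());
  int ng = 0;
  for (int v = 0; v < s->nN; v++) ng = std::max(ng, s->cpg[v] + 1);
  s->nG = ng;
  s->shape = as<double>(st["shape"]); s->rate = as<double>(st["rate"]);
  s->resampleAlpha = as<bool>(st["resample_alpha"]);
  NumericVector al = st["alpha"];
  s->alpha.assign(al.begin(), al.end());
  IntegerVector itN = st["item_node"], itC = st["item_class"],
    itT = st["item_table"];
  s->nItems = itN.size();
  s->itNode.assign(itN.begin(), itN.end());
  s->itCls.assign(itC.begin(), itC.end());
  s->itTab.assign(itT.begin(), itT.end());
  s->perm.resize(s->nItems);
  for (int i = 0; i < s->nItems; i++) s->perm[i] = i;

  IntegerMatrix dcc = st["dish_cc"];
  int nD = dcc.ncol();
  s->dishv.resize(nD);
  for (int d = 0; d < nD; d++) {
    s->dishv[d].cc.assign(s->C, 0);
    long long tot = 0;
    for (int c = 0; c < s->C; c++) { s->dishv[d].cc[c] = dcc(c, d); tot += dcc(c, d); }
    s->dishv[d].tot = tot; s->dishv[d].ntab = 0; s->dishv[d].alive = true;
    s->dishv[d].pos = d;
    s->aliveD.push_back(d);
  }
  IntegerVector tNode = st["table_node"], tDish = st["table_dish"],
    tN = st["table_n"], tPar = st["table_parent"];
  int nT = tNode.size();
  s->tab.resize(nT);
  s->nodeT.assign(s->nN, std::vector<int>());
  s->nodeN.assign(s->nN, 0);
  for (int t = 0; t < nT; t++) {
    s->tab[t].node = tNode[t]; s->tab[t].dishid = tDish[t];
    s->tab[t].n = tN[t]; s->tab[t].parent_table = tPar[t];
    s->tab[t].alive = true;
    s->tab[t].pos = (int)s->nodeT[tNode[t]].size();
    s->nodeT[tNode[t]].push_back(t);
    s->nodeN[tNode[t]] += tN[t];
    s->dishv[tDish[t]].ntab++;
  }
  RawVector rngRaw = st["rng"];
  std::memcpy(s->rng.s, RAW(rngRaw), 32);
  s->sweeps = as<double>(st["sweeps"]);
  XPtr<Crf> ptr(s, true);
  return ptr;
}
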