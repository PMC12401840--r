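// Compiled core of the hierarchical graph-network classifier: average-linkage
// clustering, BFS hop distances, the fused forward pass with analytic
// backpropagation, Adam training loop and batch prediction. The R functions in
// R/model-ops.R define the same semantics operation by operation; tests check
// the two routes against each other.
#include <RcppArmadillo.h>
#include <random>
#include <functional>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline mat lrelu(const mat& x, double s) {
  mat y = x;
  y.transform([s](double v) { return v > 0 ? v : s * v; });
  return y;
}

static inline mat lrelu_grad(const mat& x, double s) {
  mat y = x;
  y.transform([s](double v) { return v > 0 ? 1.0 : s; });
  return y;
}

// Cephes-style double-precision exp (~1 ulp): exp(x) = 2^n * R(r) with
// |r| <= 0.5 ln 2. Branch-light, ~3x faster than libm in this hot path.
static inline double fast_exp(double x) {
  if (x < -708.0) return 0.0;
  static const double LOG2E = 1.4426950408889634074;
  static const double C1 = 6.93145751953125e-1;
  static const double C2 = 1.42860682030941723212e-6;
  double n = std::nearbyint(x * LOG2E);
  double r = x - n * C1 - n * C2;
  double r2 = r * r;
  double px = r * (9.99999999999999999910e-1 +
                   r2 * (3.02994407707441961300e-2 +
                         r2 * 1.26177193074810590878e-4));
  double qx = 2.00000000000000000005e0 +
              r2 * (2.27265548208155028766e-1 +
                    r2 * (2.52448340349684104192e-3 +
                          r2 * 3.00198505138664455042e-6));
  double e = 1.0 + 2.0 * px / (qx - px);
  return std::ldexp(e, (int)n);
}

static mat softmax_rows(const mat& m) {
  const uword nr = m.n_rows, nc = m.n_cols;
  mat e(nr, nc);
  vec mx = max(m, 1);
  for (uword j = 0; j < nc; ++j)
    for (uword i = 0; i < nr; ++i)
      e(i, j) = fast_exp(m(i, j) - mx(i));
  vec s = sum(e, 1);
  e.each_col() /= s;
  return e;
}

// ---------------------------------------------------------------------------
// Shortest-path hop counts on the binarized graph (edge iff A > 0 off the
// diagonal); unreachable pairs get (max finite hop + 1).
static mat bfs_hops(const mat& A) {
  const int n = A.n_rows;
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && A(i, j) > 0) adj[i].push_back(j);
  mat D(n, n);
  D.fill(-1.0);
  std::vector<int> queue(n);
  for (int s = 0; s < n; ++s) {
    D(s, s) = 0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      for (int v : adj[u]) {
        if (D(s, v) < 0) {
          D(s, v) = D(s, u) + 1;
          queue[tail++] = v;
        }
      }
    }
  }
  double mx = D.max();  // max finite hop (unreached are -1)
  D.transform([mx](double v) { return v < 0 ? mx + 1 : v; });
  return D;
}

static mat scale01_offdiag(const mat& M) {
  const int n = M.n_rows;
  if (n < 2) return zeros<mat>(n, n);
  double lo = datum::inf, hi = -datum::inf;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) {
        lo = std::min(lo, M(i, j));
        hi = std::max(hi, M(i, j));
      }
  mat out(n, n, fill::zeros);
  if (hi > lo)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j) out(i, j) = (M(i, j) - lo) / (hi - lo);
  return out;
}

// ---------------------------------------------------------------------------
// Agglomerative average-linkage (UPGMA) clustering with deterministic
// lowest-index tie-breaking. Clusters merge into the lower slot, so active
// slots stay ordered by smallest member index; the cut labels read off in
// ascending slot order are therefore already canonical.
struct HCResult {
  imat merge;
  vec height;
  uvec labels;  // 1-based, canonical, at the cut into C clusters
};

// Nearest-neighbour-chain agglomeration (valid because average linkage is
// reducible: no dendrogram inversions, so sorting the discovered merges by
// height reproduces the naive smallest-pair order). Merged clusters keep the
// lower slot index, so every cluster's slot is its smallest member and labels
// read off in ascending root order are canonical.
static HCResult hc_average(const mat& Din, int C) {
  const int n = Din.n_rows;
  HCResult out;
  out.labels.set_size(n);
  if (n == 1) {
    out.merge.set_size(0, 2);
    out.height.set_size(0);
    out.labels.fill(1);
    return out;
  }
  mat d = Din;
  d.diag().fill(datum::inf);
  std::vector<double> sz(n, 1.0);
  std::vector<bool> active(n, true);
  struct MRec { int a, b; double h; };
  std::vector<MRec> recs;
  recs.reserve(n - 1);
  std::vector<int> chain;
  chain.reserve(n + 1);
  int seek = 0;
  while ((int)recs.size() < n - 1) {
    if (chain.empty()) {
      while (!active[seek]) ++seek;
      chain.push_back(seek);
    }
    int top = chain.back();
    uword j = d.row(top).index_min();
    double mind = d(top, j);
    if (chain.size() >= 2) {
      int prev = chain[chain.size() - 2];
      if (d(top, prev) <= mind) { j = prev; mind = d(top, prev); }
    }
    if (chain.size() >= 2 && (int)j == chain[chain.size() - 2]) {
      int a = std::min(top, (int)j), b = std::max(top, (int)j);
      recs.push_back({a, b, mind});
      double sa = sz[a], sb = sz[b];
      for (int t = 0; t < n; ++t)
        if (active[t] && t != a && t != b) {
          double nv = (sa * d(a, t) + sb * d(b, t)) / (sa + sb);
          d(a, t) = nv; d(t, a) = nv;
        }
      sz[a] = sa + sb;
      active[b] = false;
      d.row(b).fill(datum::inf);
      d.col(b).fill(datum::inf);
      d(a, a) = datum::inf;
      chain.pop_back();
      chain.pop_back();
    } else {
      chain.push_back((int)j);
    }
  }
  // replay merges in height order through a union-find whose root is always
  // the smallest member index
  std::vector<int> ord(n - 1);
  for (int i = 0; i < n - 1; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&recs](int x, int y) { return recs[x].h < recs[y].h; });
  std::vector<int> uf(n), code(n);
  for (int i = 0; i < n; ++i) { uf[i] = i; code[i] = -(i + 1); }
  std::function<int(int)> find = [&](int x) {
    while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
    return x;
  };
  out.merge.set_size(n - 1, 2);
  out.height.set_size(n - 1);
  bool snapped = false;
  if (C >= n) {
    for (int i = 0; i < n; ++i) out.labels[i] = i + 1;
    snapped = true;
  }
  for (int k = 0; k < n - 1; ++k) {
    const MRec& r = recs[ord[k]];
    int ra = find(r.a), rb = find(r.b);
    out.merge(k, 0) = code[ra];
    out.merge(k, 1) = code[rb];
    out.height[k] = r.h;
    int rmin = std::min(ra, rb), rmax = std::max(ra, rb);
    uf[rmax] = rmin;
    code[rmin] = k + 1;
    if (!snapped && n - k - 2 == C - 1) {
      // n - (k+1) clusters remain == C: snapshot canonical labels
      std::vector<int> root_lab(n, 0);
      int lab = 0;
      for (int t = 0; t < n; ++t)
        if (find(t) == t) root_lab[t] = ++lab;
      for (int t = 0; t < n; ++t) out.labels[t] = root_lab[find(t)];
      snapped = true;
    }
  }
  if (!snapped) out.labels.fill(1);
  return out;
}

// [[Rcpp::export]]
List hc_average_cpp(const arma::mat& D, int C) {
  if (C < 1 || C > (int)D.n_rows)
    Rcpp::stop("C must lie in [1, nrow(D)]");
  HCResult r = hc_average(D, C);
  return List::create(Named("labels") = Rcpp::wrap(conv_to<ivec>::from(r.labels)),
                      Named("merge") = Rcpp::wrap(r.merge),
                      Named("height") = Rcpp::wrap(r.height));
}

// [[Rcpp::export]]
arma::mat bfs_hops_cpp(const arma::mat& A) { return bfs_hops(A); }

// ---------------------------------------------------------------------------
// Parameters and configuration

struct Params {
  mat W_in, W_t, Wq_node, Wk_node, Wv_node;
  mat Wq1, Wk1, Wg1, Wq2, Wk2, Wg2;
  mat W_ct, W_cg, W_out;
  rowvec b_in, b_t, b_ct, b_cg, b_out;

  void load(const List& p) {
    W_in = Rcpp::as<mat>(p["W_in"]); W_t = Rcpp::as<mat>(p["W_t"]);
    Wq_node = Rcpp::as<mat>(p["Wq_node"]);
    Wk_node = Rcpp::as<mat>(p["Wk_node"]);
    Wv_node = Rcpp::as<mat>(p["Wv_node"]);
    Wq1 = Rcpp::as<mat>(p["Wq1"]); Wk1 = Rcpp::as<mat>(p["Wk1"]);
    Wg1 = Rcpp::as<mat>(p["Wg1"]);
    Wq2 = Rcpp::as<mat>(p["Wq2"]); Wk2 = Rcpp::as<mat>(p["Wk2"]);
    Wg2 = Rcpp::as<mat>(p["Wg2"]);
    W_ct = Rcpp::as<mat>(p["W_ct"]); W_cg = Rcpp::as<mat>(p["W_cg"]);
    W_out = Rcpp::as<mat>(p["W_out"]);
    b_in = Rcpp::as<rowvec>(p["b_in"]); b_t = Rcpp::as<rowvec>(p["b_t"]);
    b_ct = Rcpp::as<rowvec>(p["b_ct"]); b_cg = Rcpp::as<rowvec>(p["b_cg"]);
    b_out = Rcpp::as<rowvec>(p["b_out"]);
  }
  List save() const {
    return List::create(
      Named("W_in") = W_in, Named("b_in") = b_in,
      Named("W_t") = W_t, Named("b_t") = b_t,
      Named("Wq_node") = Wq_node, Named("Wk_node") = Wk_node,
      Named("Wv_node") = Wv_node,
      Named("Wq1") = Wq1, Named("Wk1") = Wk1, Named("Wg1") = Wg1,
      Named("Wq2") = Wq2, Named("Wk2") = Wk2, Named("Wg2") = Wg2,
      Named("W_ct") = W_ct, Named("b_ct") = b_ct,
      Named("W_cg") = W_cg, Named("b_cg") = b_cg,
      Named("W_out") = W_out, Named("b_out") = b_out);
  }
  std::vector<mat*> slots() {
    return { &W_in, &W_t, &Wq_node, &Wk_node, &Wv_node, &Wq1, &Wk1, &Wg1,
             &Wq2, &Wk2, &Wg2, &W_ct, &W_cg, &W_out };
  }
  std::vector<rowvec*> bslots() {
    return { &b_in, &b_t, &b_ct, &b_cg, &b_out };
  }
  void zero() {
    for (mat* w : slots()) w->zeros();
    for (rowvec* b : bslots()) b->zeros();
  }
  void zero_like(const Params& p) {
    W_in = zeros<mat>(size(p.W_in)); W_t = zeros<mat>(size(p.W_t));
    Wq_node = zeros<mat>(size(p.Wq_node));
    Wk_node = zeros<mat>(size(p.Wk_node));
    Wv_node = zeros<mat>(size(p.Wv_node));
    Wq1 = zeros<mat>(size(p.Wq1)); Wk1 = zeros<mat>(size(p.Wk1));
    Wg1 = zeros<mat>(size(p.Wg1));
    Wq2 = zeros<mat>(size(p.Wq2)); Wk2 = zeros<mat>(size(p.Wk2));
    Wg2 = zeros<mat>(size(p.Wg2));
    W_ct = zeros<mat>(size(p.W_ct)); W_cg = zeros<mat>(size(p.W_cg));
    W_out = zeros<mat>(size(p.W_out));
    b_in = zeros<rowvec>(p.b_in.n_elem); b_t = zeros<rowvec>(p.b_t.n_elem);
    b_ct = zeros<rowvec>(p.b_ct.n_elem); b_cg = zeros<rowvec>(p.b_cg.n_elem);
    b_out = zeros<rowvec>(p.b_out.n_elem);
  }
};

struct Cfg {
  int Dh, H, Dk, C, epochs, sched_step;
  double alpha, tau, dropout, lr, sched_gamma, slope, augment;
  bool node_att, edge_att, clustering, link_loss, ent_loss, track_best;

  void load(const List& c) {
    Dh = Rcpp::as<int>(c["D_h"]); H = Rcpp::as<int>(c["H"]);
    Dk = Rcpp::as<int>(c["D_k"]); C = Rcpp::as<int>(c["C"]);
    epochs = Rcpp::as<int>(c["epochs"]);
    sched_step = Rcpp::as<int>(c["scheduler_step"]);
    alpha = Rcpp::as<double>(c["alpha"]); tau = Rcpp::as<double>(c["tau"]);
    dropout = Rcpp::as<double>(c["dropout_p"]);
    lr = Rcpp::as<double>(c["lr"]);
    sched_gamma = Rcpp::as<double>(c["scheduler_gamma"]);
    slope = Rcpp::as<double>(c["leaky_slope"]);
    augment = Rcpp::as<double>(c["augment_sd"]);
    node_att = Rcpp::as<bool>(c["use_node_attention"]);
    edge_att = Rcpp::as<bool>(c["use_edge_attention"]);
    clustering = Rcpp::as<bool>(c["use_clustering"]);
    link_loss = Rcpp::as<bool>(c["use_link_loss"]);
    ent_loss = Rcpp::as<bool>(c["use_entropy_loss"]);
    track_best = Rcpp::as<bool>(c["track_best_epoch"]);
  }
};

// ---------------------------------------------------------------------------
// Forward cache (everything backprop needs)

struct LayerCache {
  mat Xin, Aprev;
  cube E;            // per-head attention, n x n x H
  cube Qc, Kc;       // per-head projections, n x Dk x H
  mat Alearn, Aref;
  mat M, XW, Z, Xg;
  vec dvec;          // row sums of A* = Aref + I
  bool pooled = false;
  uvec labels;       // 0-based cluster labels
  vec nc;
  mat cent, Ssoft, Rlink, Xp, Ap;
  double l_link = 0, l_ent = 0;
};

struct FwdCache {
  mat Xn, X0, K, V, X1;
  rowvec clin, ft_pre, ft, q, a;
  LayerCache L1, L2;
  rowvec g, gf, mask, prob;
  int y;
  double l_cls = 0, l_link = 0, l_ent = 0, l_total = 0;
};

static void forward_layer(LayerCache& L, const mat& Xin, const mat& Aprev,
                          const mat& Wq, const mat& Wk, const mat& Wg,
                          int C_target, const Cfg& cfg,
                          const mat* Dpath_pre) {
  const int n = Xin.n_rows;
  L.Xin = Xin;
  L.Aprev = Aprev;
  if (cfg.edge_att) {
    L.E.set_size(n, n, cfg.H);
    L.Qc.set_size(n, cfg.Dk, cfg.H);
    L.Kc.set_size(n, cfg.Dk, cfg.H);
    L.Alearn.zeros(n, n);
    for (int h = 0; h < cfg.H; ++h) {
      const uword c0 = h * cfg.Dk, c1 = (h + 1) * cfg.Dk - 1;
      L.Qc.slice(h) = Xin * Wq.cols(c0, c1);
      L.Kc.slice(h) = Xin * Wk.cols(c0, c1);
      mat Eh = softmax_rows(L.Qc.slice(h) * L.Kc.slice(h).t() /
                            std::sqrt((double)cfg.Dk));
      L.E.slice(h) = Eh;
      L.Alearn += Eh;
    }
    L.Alearn /= cfg.H;
    mat raw = L.Alearn % Aprev;
    L.Aref = (raw + raw.t()) / 2;
  } else {
    L.Aref = Aprev;
  }
  mat Astar = L.Aref;
  Astar.diag() += 1.0;
  L.dvec = sum(Astar, 1);
  vec dm = 1.0 / sqrt(L.dvec);
  L.M = Astar % (dm * dm.t());
  L.XW = Xin * Wg;
  L.Z = L.M * L.XW;
  L.Xg = lrelu(L.Z, cfg.slope);

  if (cfg.clustering) {
    const int C = std::min(C_target, n);
    mat Dp = Dpath_pre ? *Dpath_pre : bfs_hops(Aprev);
    vec xs = sum(square(L.Xg), 1);
    mat Df = repmat(xs, 1, n) + repmat(xs.t(), n, 1) - 2 * L.Xg * L.Xg.t();
    mat Dc = cfg.alpha * scale01_offdiag(Dp) +
             (1 - cfg.alpha) * scale01_offdiag(Df);
    HCResult hc = hc_average(Dc, C);
    L.labels = hc.labels - 1;
    L.nc = zeros<vec>(C);
    L.Xp = zeros<mat>(C, L.Xg.n_cols);
    for (int i = 0; i < n; ++i) {
      L.nc[L.labels[i]] += 1;
      L.Xp.row(L.labels[i]) += L.Xg.row(i);
    }
    L.cent = L.Xp.each_col() / L.nc;
    vec cs = sum(square(L.cent), 1);
    mat d2 = repmat(xs, 1, C) + repmat(cs.t(), n, 1) -
             2 * L.Xg * L.cent.t();
    L.Ssoft = softmax_rows(-d2 / cfg.tau);
    L.Ap = zeros<mat>(C, C);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        L.Ap(L.labels[i], L.labels[j]) += L.Aref(i, j);
    L.Ap.diag().zeros();
    if (cfg.link_loss) {
      L.Rlink = L.Aref - L.Ssoft * L.Ssoft.t();
      L.l_link = accu(square(L.Rlink)) / ((double)n * n);
    }
    if (cfg.ent_loss) {
      mat logS = log(clamp(L.Ssoft, 1e-300, 1.0));
      L.l_ent = -accu(L.Ssoft % logS) / n;
    }
    L.pooled = true;
  } else {
    L.Xp = L.Xg;
    L.Ap = L.Aref;
    L.pooled = false;
  }
}

static void forward_pass(FwdCache& c, const mat& Xn, const mat& Aprior,
                         const rowvec& clin, int y, const Params& P,
                         const Cfg& cfg, bool training, std::mt19937_64* gen,
                         const mat* Dpath1) {
  const int n = Xn.n_rows;
  c.Xn = Xn;
  c.clin = clin;
  c.y = y;
  c.X0 = Xn * P.W_in;
  c.X0.each_row() += P.b_in;
  c.ft_pre = clin * P.W_t + P.b_t;
  c.ft = lrelu(c.ft_pre, cfg.slope);
  if (cfg.node_att) {
    c.q = c.ft * P.Wq_node;
    c.K = c.X0 * P.Wk_node;
    c.V = c.X0 * P.Wv_node;
    rowvec s = c.q * c.K.t() / std::sqrt((double)cfg.Dk);
    rowvec e = exp(s - s.max());
    c.a = e / accu(e);
    c.X1 = c.V.each_col() % (n * c.a.t());
  } else {
    c.X1 = c.X0;
    c.a = rowvec(n, fill::value(1.0 / n));
  }
  int C1 = cfg.clustering ? std::min(cfg.C, n) : n;
  forward_layer(c.L1, c.X1, Aprior, P.Wq1, P.Wk1, P.Wg1, C1, cfg, Dpath1);
  int C2 = cfg.clustering ? std::max(1, C1 / 2) : C1;
  forward_layer(c.L2, c.L1.Xp, c.L1.Ap, P.Wq2, P.Wk2, P.Wg2, C2, cfg,
                nullptr);
  c.g = mean(c.L2.Xp, 0);
  rowvec u = c.ft * P.W_ct + P.b_ct;
  rowvec v = c.g * P.W_cg + P.b_cg;
  c.gf = join_rows(u, v);
  if (training && cfg.dropout > 0 && gen) {
    std::bernoulli_distribution keep(1.0 - cfg.dropout);
    c.mask.set_size(c.gf.n_elem);
    for (uword i = 0; i < c.gf.n_elem; ++i)
      c.mask[i] = keep(*gen) ? 1.0 / (1.0 - cfg.dropout) : 0.0;
    c.gf %= c.mask;
  } else {
    c.mask = ones<rowvec>(c.gf.n_elem);
  }
  rowvec logits = c.gf * P.W_out + P.b_out;
  rowvec e2 = exp(logits - logits.max());
  c.prob = e2 / accu(e2);
  c.l_cls = -std::log(std::max(c.prob[y], 1e-12));
  c.l_link = cfg.link_loss ? c.L1.l_link + c.L2.l_link : 0.0;
  c.l_ent = cfg.ent_loss ? c.L1.l_ent + c.L2.l_ent : 0.0;
  c.l_total = c.l_cls + c.l_link + c.l_ent;
}

// Backward through one edge-attention + GCN + pooling layer. Returns the
// gradients w.r.t. the layer input features and the previous-layer adjacency;
// accumulates parameter gradients in gWq/gWk/gWg. Cluster assignments are
// discrete and receive no gradient; the soft assignment gives the pooling
// losses their gradient path through the node features.
static void backward_layer(const LayerCache& L, mat dXp, mat dAp,
                           const mat& Wq, const mat& Wk, const mat& Wg,
                           mat& gWq, mat& gWk, mat& gWg, const Cfg& cfg,
                           mat& dXin_out, mat& dAprev_out) {
  const int n = L.Xin.n_rows;
  mat dXg(n, L.Xg.n_cols, fill::zeros);
  mat dAref(n, n, fill::zeros);
  if (L.pooled) {
    const int C = L.Xp.n_rows;
    dAp.diag().zeros();
    for (int i = 0; i < n; ++i) dXg.row(i) += dXp.row(L.labels[i]);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        dAref(i, j) += dAp(L.labels[i], L.labels[j]);
    if (cfg.link_loss || cfg.ent_loss) {
      mat dS(n, C, fill::zeros);
      if (cfg.link_loss) {
        dS += (-4.0 / ((double)n * n)) * (L.Rlink * L.Ssoft);
        dAref += (2.0 / ((double)n * n)) * L.Rlink;
      }
      if (cfg.ent_loss) {
        mat logS = log(clamp(L.Ssoft, 1e-300, 1.0));
        dS += -(logS + 1.0) / n;
      }
      mat dz = L.Ssoft % (dS.each_col() - sum(dS % L.Ssoft, 1));
      vec sdz = sum(dz, 1);
      dXg += (-2.0 / cfg.tau) *
             ((L.Xg.each_col() % sdz) - dz * L.cent);
      rowvec csum = sum(dz, 0);
      mat dM = (2.0 / cfg.tau) *
               (dz.t() * L.Xg - (L.cent.each_col() % csum.t()));
      mat dMn = dM.each_col() / L.nc;
      for (int i = 0; i < n; ++i) dXg.row(i) += dMn.row(L.labels[i]);
    }
  } else {
    dXg += dXp;
    dAref += dAp;
  }
  // GCN backward
  mat dZ = dXg % lrelu_grad(L.Z, cfg.slope);
  mat dMmat = dZ * L.XW.t();
  mat dXW = L.M.t() * dZ;
  gWg += L.Xin.t() * dXW;
  mat dXin = dXW * Wg.t();
  // normalized adjacency backward: M = A* o (d^-1/2 d^-1/2'), d = rowsums(A*)
  vec dm = 1.0 / sqrt(L.dvec);
  mat T = L.M % dMmat;
  vec dd = -0.5 * (sum(T, 1) + sum(T, 0).t()) / L.dvec;
  mat dAstar = dMmat % (dm * dm.t());
  dAstar.each_col() += dd;
  dAref += dAstar;
  mat dAprev(n, n, fill::zeros);
  if (cfg.edge_att) {
    mat dRaw = (dAref + dAref.t()) / 2;
    mat dAlearn = dRaw % L.Aprev;
    dAprev += dRaw % L.Alearn;
    const double inv_sq = 1.0 / std::sqrt((double)cfg.Dk);
    mat dE = dAlearn / cfg.H;
    for (int h = 0; h < cfg.H; ++h) {
      const uword c0 = h * cfg.Dk, c1 = (h + 1) * cfg.Dk - 1;
      const mat& E = L.E.slice(h);
      mat dSc = E % (dE.each_col() - sum(dE % E, 1));
      dSc *= inv_sq;
      const mat& Qh = L.Qc.slice(h);
      const mat& Kh = L.Kc.slice(h);
      mat dQ = dSc * Kh;
      mat dK = dSc.t() * Qh;
      gWq.cols(c0, c1) += L.Xin.t() * dQ;
      gWk.cols(c0, c1) += L.Xin.t() * dK;
      dXin += dQ * Wq.cols(c0, c1).t() + dK * Wk.cols(c0, c1).t();
    }
  } else {
    dAprev += dAref;
  }
  dXin_out = dXin;
  dAprev_out = dAprev;
}

static void backward_pass(const FwdCache& c, const Params& P, Params& G,
                          const Cfg& cfg) {
  const int n = c.Xn.n_rows;
  // classification head
  rowvec dlogits = c.prob;
  dlogits[c.y] -= 1.0;
  G.W_out += c.gf.t() * dlogits;
  G.b_out += dlogits;
  rowvec dgf = dlogits * P.W_out.t();
  dgf %= c.mask;
  rowvec du = dgf.cols(0, cfg.Dh - 1);
  rowvec dv = dgf.cols(cfg.Dh, 2 * cfg.Dh - 1);
  rowvec dft = du * P.W_ct.t();
  G.W_ct += c.ft.t() * du;
  G.b_ct += du;
  rowvec dg = dv * P.W_cg.t();
  G.W_cg += c.g.t() * dv;
  G.b_cg += dv;
  const int C2 = c.L2.Xp.n_rows;
  mat dXp2 = repmat(dg / C2, C2, 1);
  mat dAp2(C2, C2, fill::zeros);
  mat dXp1, dAp1, dX1, dAprior;
  backward_layer(c.L2, dXp2, dAp2, P.Wq2, P.Wk2, P.Wg2,
                 G.Wq2, G.Wk2, G.Wg2, cfg, dXp1, dAp1);
  backward_layer(c.L1, dXp1, dAp1, P.Wq1, P.Wk1, P.Wg1,
                 G.Wq1, G.Wk1, G.Wg1, cfg, dX1, dAprior);
  mat dX0;
  if (cfg.node_att) {
    vec na = n * c.a.t();
    mat dV = dX1.each_col() % na;
    vec da = n * sum(dX1 % c.V, 1);
    double adot = dot(c.a.t(), da);
    vec ds = c.a.t() % (da - adot);
    ds /= std::sqrt((double)cfg.Dk);
    rowvec dq = ds.t() * c.K;
    mat dK = ds * c.q;
    G.Wq_node += c.ft.t() * dq;
    dft += dq * P.Wq_node.t();
    G.Wk_node += c.X0.t() * dK;
    G.Wv_node += c.X0.t() * dV;
    dX0 = dK * P.Wk_node.t() + dV * P.Wv_node.t();
  } else {
    dX0 = dX1;
  }
  rowvec dftp = dft % lrelu_grad(c.ft_pre, cfg.slope);
  G.W_t += c.clin.t() * dftp;
  G.b_t += dftp;
  G.W_in += c.Xn.t() * dX0;
  G.b_in += sum(dX0, 0);
}

// ---------------------------------------------------------------------------
// R-facing single-graph forward (evaluation diagnostics) and gradient

static Cfg parse_cfg(const List& cfg_list) {
  Cfg cfg;
  cfg.load(cfg_list);
  return cfg;
}

// [[Rcpp::export]]
List mdhc_forward_cpp(const arma::mat& X, const arma::mat& Aprior,
                      const arma::rowvec& clin, int y, const List& params,
                      const List& cfg_list, bool training = false,
                      int seed = 0) {
  Params P;
  P.load(params);
  Cfg cfg = parse_cfg(cfg_list);
  FwdCache c;
  std::mt19937_64 gen(seed);
  forward_pass(c, X, Aprior, clin, y, P, cfg, training,
               training ? &gen : nullptr, nullptr);
  return List::create(
    Named("prob") = c.prob,
    Named("L_cls") = c.l_cls, Named("L_link") = c.l_link,
    Named("L_entropy") = c.l_ent, Named("L_total") = c.l_total,
    Named("A_node") = c.a,
    Named("labels1") = c.L1.pooled
      ? Rcpp::wrap(conv_to<ivec>::from(c.L1.labels + 1))
      : Rcpp::wrap(R_NilValue),
    Named("labels2") = c.L2.pooled
      ? Rcpp::wrap(conv_to<ivec>::from(c.L2.labels + 1))
      : Rcpp::wrap(R_NilValue));
}

// [[Rcpp::export]]
List mdhc_grad_cpp(const arma::mat& X, const arma::mat& Aprior,
                   const arma::rowvec& clin, int y, const List& params,
                   const List& cfg_list) {
  Params P;
  P.load(params);
  Cfg cfg = parse_cfg(cfg_list);
  FwdCache c;
  forward_pass(c, X, Aprior, clin, y, P, cfg, false, nullptr, nullptr);
  Params G;
  G.zero_like(P);
  backward_pass(c, P, G, cfg);
  List out = G.save();
  out["loss"] = c.l_total;
  return out;
}

// ---------------------------------------------------------------------------
// Adam training loop (batch size 1, shuffled presentation order)

struct Adam {
  std::vector<mat> m, v;
  std::vector<rowvec> mb, vb;
  long t = 0;
  void init(Params& p) {
    for (mat* w : p.slots()) {
      m.push_back(zeros<mat>(size(*w)));
      v.push_back(zeros<mat>(size(*w)));
    }
    for (rowvec* b : p.bslots()) {
      mb.push_back(zeros<rowvec>(b->n_elem));
      vb.push_back(zeros<rowvec>(b->n_elem));
    }
  }
  void step(Params& p, Params& g, double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    ++t;
    const double c1 = 1 - std::pow(b1, (double)t);
    const double c2 = 1 - std::pow(b2, (double)t);
    auto ps = p.slots(); auto gs = g.slots();
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * (*gs[i]);
      v[i] = b2 * v[i] + (1 - b2) * square(*gs[i]);
      *ps[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
    auto pb = p.bslots(); auto gb = g.bslots();
    for (size_t i = 0; i < pb.size(); ++i) {
      mb[i] = b1 * mb[i] + (1 - b1) * (*gb[i]);
      vb[i] = b2 * vb[i] + (1 - b2) * square(*gb[i]);
      *pb[i] -= lr * (mb[i] / c1) / (sqrt(vb[i] / c2) + eps);
    }
  }
};

struct GraphData {
  mat X, Aprior, Dpath1;
  rowvec clin;
  int y;
};

static std::vector<GraphData> load_graphs(const List& graphs) {
  std::vector<GraphData> out(graphs.size());
  for (int i = 0; i < graphs.size(); ++i) {
    List g = graphs[i];
    out[i].X = Rcpp::as<mat>(g["X"]);
    out[i].Aprior = Rcpp::as<mat>(g["Aprior"]);
    out[i].clin = Rcpp::as<rowvec>(g["clin"]);
    out[i].y = Rcpp::as<int>(g["y"]);
    out[i].Dpath1 = bfs_hops(out[i].Aprior);
  }
  return out;
}

// [[Rcpp::export]]
List mdhc_train_cpp(const List& graphs, const List& params,
                    const List& cfg_list, int seed,
                    Rcpp::Nullable<List> val_graphs = R_NilValue) {
  Params P;
  P.load(params);
  Cfg cfg = parse_cfg(cfg_list);
  std::vector<GraphData> train = load_graphs(graphs);
  std::vector<GraphData> val;
  if (val_graphs.isNotNull()) val = load_graphs(val_graphs.get());
  std::mt19937_64 gen((uint64_t)seed);
  std::normal_distribution<double> noise(0.0, 1.0);
  Adam opt;
  opt.init(P);
  const int n_train = train.size();
  std::vector<int> order(n_train);
  for (int i = 0; i < n_train; ++i) order[i] = i;
  vec epoch_loss(cfg.epochs, fill::zeros);
  vec val_loss(cfg.track_best && !val.empty() ? cfg.epochs : 0);
  double best_val = datum::inf;
  int best_epoch = cfg.epochs;
  List best_params = R_NilValue;

  Params G;
  G.zero_like(P);
  for (int ep = 0; ep < cfg.epochs; ++ep) {
    double lr = cfg.lr * std::pow(cfg.sched_gamma, ep / cfg.sched_step);
    std::shuffle(order.begin(), order.end(), gen);
    double tot = 0;
    for (int idx : order) {
      GraphData& gd = train[idx];
      FwdCache c;
      if (cfg.augment > 0) {
        mat Xuse = gd.X;
        Xuse.for_each([&](double& v) { v += cfg.augment * noise(gen); });
        // feature noise does not touch the adjacency, so hops stay valid
        forward_pass(c, Xuse, gd.Aprior, gd.clin, gd.y, P, cfg, true, &gen,
                     &gd.Dpath1);
      } else {
        forward_pass(c, gd.X, gd.Aprior, gd.clin, gd.y, P, cfg, true, &gen,
                     &gd.Dpath1);
      }
      if (!std::isfinite(c.l_total))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      G.zero();
      backward_pass(c, P, G, cfg);
      opt.step(P, G, lr);
      tot += c.l_total;
    }
    epoch_loss[ep] = tot / n_train;
    if (cfg.track_best && !val.empty()) {
      double vtot = 0;
      for (GraphData& gd : val) {
        FwdCache c;
        forward_pass(c, gd.X, gd.Aprior, gd.clin, gd.y, P, cfg, false,
                     nullptr, &gd.Dpath1);
        vtot += c.l_cls;
      }
      vtot /= val.size();
      val_loss[ep] = vtot;
      if (vtot < best_val) {
        best_val = vtot;
        best_epoch = ep + 1;
        best_params = P.save();
      }
    }
    Rcpp::checkUserInterrupt();
  }
  List final_params = P.save();
  return List::create(
    Named("params") = final_params,
    Named("best_params") = (cfg.track_best && !val.empty())
      ? best_params : final_params,
    Named("best_epoch") = best_epoch,
    Named("train_loss") = epoch_loss,
    Named("val_loss") = val_loss);
}

// [[Rcpp::export]]
arma::mat mdhc_predict_cpp(const List& graphs, const List& params,
                           const List& cfg_list) {
  Params P;
  P.load(params);
  Cfg cfg = parse_cfg(cfg_list);
  std::vector<GraphData> gs = load_graphs(graphs);
  mat probs(gs.size(), 2);
  for (size_t i = 0; i < gs.size(); ++i) {
    FwdCache c;
    forward_pass(c, gs[i].X, gs[i].Aprior, gs[i].clin, gs[i].y, P, cfg,
                 false, nullptr, &gs[i].Dpath1);
    probs.row(i) = c.prob;
  }
  return probs;
}
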