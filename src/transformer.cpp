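// Minimal transformer encoder (pre-LN) with masked-token and sequence
// classification heads, manual backprop, and AdamW. Parameters travel as an
// ordered list of matrices built by init_transformer() on the R side:
//   [0] tok_emb (V x d), [1] pos_emb (Tmax x d),
//   per layer: ln1_g, ln1_b, Wq, bq, Wk, bk, Wv, bv, Wo, bo,
//              ln2_g, ln2_b, W1, b1, W2, b2            (16 each)
//   tail: lnf_g, lnf_b, mlm_W (d x V), mlm_b, cls_W (d x C), cls_b
// Vectors are stored as n x 1 matrices. All token ids are 0-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
// single precision: the kernel is memory- and transcendental-bound, and
// float is ample for SGD-family training
typedef arma::fmat mat;
typedef arma::fvec vec;
typedef arma::frowvec rowvec;

static const float LN_EPS = 1e-5f;

struct Dims {
  int V, d, ff, C, L, H, T;
};

static Dims infer_dims(const std::vector<mat>& p, int n_layers, int n_heads, int T) {
  Dims dm;
  dm.V = p[0].n_rows;
  dm.d = p[0].n_cols;
  dm.L = n_layers;
  dm.H = n_heads;
  dm.ff = p[2 + 0 * 16 + 12].n_cols;
  dm.C = p[2 + 16 * n_layers + 4].n_cols;
  dm.T = T;
  return dm;
}

static std::vector<mat> list_to_params(const List& lst) {
  std::vector<mat> p(lst.size());
  for (int i = 0; i < lst.size(); ++i)
    p[i] = arma::conv_to<mat>::from(as<arma::mat>(lst[i]));
  return p;
}

static List params_to_list(const std::vector<mat>& p, const List& tmpl) {
  List out(p.size());
  for (size_t i = 0; i < p.size(); ++i)
    out[i] = wrap(arma::conv_to<arma::mat>::from(p[i]));
  out.attr("names") = tmpl.attr("names");
  return out;
}

static rowvec as_rowvec(const mat& v) { return arma::conv_to<rowvec>::from(v.col(0)); }

// LayerNorm over the feature dimension (columns), rows are positions.
static mat ln_fwd(const mat& x, const mat& g, const mat& b, mat& xhat, vec& invstd) {
  vec mu = arma::mean(x, 1);
  vec va = arma::var(x, 1, 1);  // population variance per row
  invstd = 1.0 / arma::sqrt(va + LN_EPS);
  xhat = x.each_col() - mu;
  xhat.each_col() %= invstd;
  mat y = xhat;
  y.each_row() %= as_rowvec(g);
  y.each_row() += as_rowvec(b);
  return y;
}

static mat ln_bwd(const mat& dy, const mat& xhat, const vec& invstd, const mat& g,
                  mat& dg, mat& db) {
  dg += arma::sum(dy % xhat, 0).t();
  db += arma::sum(dy, 0).t();
  mat dxhat = dy;
  dxhat.each_row() %= as_rowvec(g);
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= invstd;
  return dx;
}

static const float GELU_C = 0.7978845608028654f;  // sqrt(2/pi)
static const float GELU_A = 0.044715f;

// tanh(u) is cached in the forward pass and reused by the backward pass
static mat gelu(const mat& x, mat& tanh_u) {
  mat u = GELU_C * (x + GELU_A * (x % x % x));
  tanh_u = arma::tanh(u);
  return 0.5f * x % (1.0f + tanh_u);
}

static mat gelu_grad(const mat& x, const mat& t) {
  mat du = GELU_C * (1.0f + 3.0f * GELU_A * arma::square(x));
  return 0.5f * (1.0f + t) + 0.5f * x % (1.0f - arma::square(t)) % du;
}

struct LayerCache {
  mat a, xhat1;             // LN1 output + normalized input
  vec invstd1;
  mat Q, K, V, ctx;         // projections and attention context
  std::vector<mat> P;       // per-head attention probabilities (T x T)
  mat drop1;                // dropout mask after attention output
  mat bn, xhat2;            // LN2 output + normalized
  vec invstd2;
  mat Hpre, Htanh, Hact;    // FFN pre-activation, cached tanh, activation
  mat drop2;                // dropout mask after FFN output
};

struct SeqCache {
  mat emb_drop;             // dropout mask on embeddings
  std::vector<LayerCache> layers;
  mat h, xhatF;             // final hidden (post LN) + normalized
  vec invstdF;
  mat x_top;                // input to the final LN
};

static mat make_dropout(int nr, int nc, double p, std::mt19937_64& rng) {
  mat m(nr, nc);
  if (p <= 0.0) { m.ones(); return m; }
  std::uniform_real_distribution<double> U(0.0, 1.0);
  float scale = 1.0f / (float)(1.0 - p);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) m(i, j) = (U(rng) < p) ? 0.0f : scale;
  return m;
}

// Forward pass for one sequence; fills cache when `train_cache` is true.
static void forward_seq(const std::vector<mat>& p, const Dims& dm,
                        const int* ids, const int* attn, double dropout,
                        std::mt19937_64* rng, SeqCache& sc, bool keep_cache) {
  const int T = dm.T, d = dm.d, H = dm.H;
  const int dh = d / H;
  const float scale = 1.0f / std::sqrt((float)dh);

  mat x(T, d);
  for (int t = 0; t < T; ++t)
    x.row(t) = p[0].row(ids[t]) + p[1].row(t);

  if (rng) {
    sc.emb_drop = make_dropout(T, d, dropout, *rng);
    x %= sc.emb_drop;
  }

  rowvec key_bias(T, arma::fill::zeros);
  for (int t = 0; t < T; ++t) if (!attn[t]) key_bias(t) = -1e9f;

  sc.layers.assign(dm.L, LayerCache());
  for (int l = 0; l < dm.L; ++l) {
    LayerCache& lc = sc.layers[l];
    int b = 2 + 16 * l;

    lc.a = ln_fwd(x, p[b + 0], p[b + 1], lc.xhat1, lc.invstd1);
    lc.Q = lc.a * p[b + 2]; lc.Q.each_row() += as_rowvec(p[b + 3]);
    lc.K = lc.a * p[b + 4]; lc.K.each_row() += as_rowvec(p[b + 5]);
    lc.V = lc.a * p[b + 6]; lc.V.each_row() += as_rowvec(p[b + 7]);

    lc.ctx.set_size(T, d);
    lc.P.assign(H, mat());
    for (int hh = 0; hh < H; ++hh) {
      int c0 = hh * dh, c1 = c0 + dh - 1;
      mat S = lc.Q.cols(c0, c1) * lc.K.cols(c0, c1).t() * scale;
      S.each_row() += key_bias;
      vec mx = arma::max(S, 1);
      S.each_col() -= mx;
      mat P = arma::exp(S);
      vec rs = arma::sum(P, 1);
      P.each_col() /= rs;
      lc.ctx.cols(c0, c1) = P * lc.V.cols(c0, c1);
      if (keep_cache) lc.P[hh] = std::move(P);
    }

    mat O = lc.ctx * p[b + 8];
    O.each_row() += as_rowvec(p[b + 9]);
    if (rng) { lc.drop1 = make_dropout(T, d, dropout, *rng); O %= lc.drop1; }
    x += O;

    lc.bn = ln_fwd(x, p[b + 10], p[b + 11], lc.xhat2, lc.invstd2);
    lc.Hpre = lc.bn * p[b + 12];
    lc.Hpre.each_row() += as_rowvec(p[b + 13]);
    lc.Hact = gelu(lc.Hpre, lc.Htanh);
    mat F = lc.Hact * p[b + 14];
    F.each_row() += as_rowvec(p[b + 15]);
    if (rng) { lc.drop2 = make_dropout(T, d, dropout, *rng); F %= lc.drop2; }
    x += F;

    if (!keep_cache) { lc.a.reset(); lc.xhat1.reset(); lc.Q.reset(); lc.K.reset();
      lc.V.reset(); lc.ctx.reset(); lc.bn.reset(); lc.xhat2.reset();
      lc.Hpre.reset(); lc.Htanh.reset(); lc.Hact.reset(); }
  }

  int bf = 2 + 16 * dm.L;
  if (keep_cache) sc.x_top = x;
  sc.h = ln_fwd(x, p[bf], p[bf + 1], sc.xhatF, sc.invstdF);
}

// Backward from d(h) through the whole stack, accumulating into `g`.
static void backward_seq(const std::vector<mat>& p, const Dims& dm,
                         const int* ids, const mat& dh_final,
                         const SeqCache& sc, std::vector<mat>& g) {
  const int T = dm.T, d = dm.d, H = dm.H;
  const int dh = d / H;
  const float scale = 1.0f / std::sqrt((float)dh);
  int bf = 2 + 16 * dm.L;

  mat dx = ln_bwd(dh_final, sc.xhatF, sc.invstdF, p[bf], g[bf], g[bf + 1]);

  for (int l = dm.L - 1; l >= 0; --l) {
    const LayerCache& lc = sc.layers[l];
    int b = 2 + 16 * l;

    // FFN block
    mat dF = dx;
    if (lc.drop2.n_elem) dF %= lc.drop2;
    mat dHact = dF * p[b + 14].t();
    g[b + 14] += lc.Hact.t() * dF;
    g[b + 15] += arma::sum(dF, 0).t();
    mat dHpre = dHact % gelu_grad(lc.Hpre, lc.Htanh);
    mat dbn = dHpre * p[b + 12].t();
    g[b + 12] += lc.bn.t() * dHpre;
    g[b + 13] += arma::sum(dHpre, 0).t();
    dx += ln_bwd(dbn, lc.xhat2, lc.invstd2, p[b + 10], g[b + 10], g[b + 11]);

    // attention block
    mat dO = dx;
    if (lc.drop1.n_elem) dO %= lc.drop1;
    mat dctx = dO * p[b + 8].t();
    g[b + 8] += lc.ctx.t() * dO;
    g[b + 9] += arma::sum(dO, 0).t();

    mat dQ(T, d), dK(T, d), dV(T, d);
    for (int hh = 0; hh < H; ++hh) {
      int c0 = hh * dh, c1 = c0 + dh - 1;
      const mat& P = lc.P[hh];
      mat dP = dctx.cols(c0, c1) * lc.V.cols(c0, c1).t();
      dV.cols(c0, c1) = P.t() * dctx.cols(c0, c1);
      mat dS = P % dP;
      vec rs = arma::sum(dS, 1);
      dS -= P.each_col() % rs;
      dQ.cols(c0, c1) = dS * lc.K.cols(c0, c1) * scale;
      dK.cols(c0, c1) = dS.t() * lc.Q.cols(c0, c1) * scale;
    }

    mat da = dQ * p[b + 2].t() + dK * p[b + 4].t() + dV * p[b + 6].t();
    g[b + 2] += lc.a.t() * dQ; g[b + 3] += arma::sum(dQ, 0).t();
    g[b + 4] += lc.a.t() * dK; g[b + 5] += arma::sum(dK, 0).t();
    g[b + 6] += lc.a.t() * dV; g[b + 7] += arma::sum(dV, 0).t();
    dx += ln_bwd(da, lc.xhat1, lc.invstd1, p[b + 0], g[b + 0], g[b + 1]);
  }

  if (sc.emb_drop.n_elem) dx %= sc.emb_drop;
  for (int t = 0; t < T; ++t) {
    g[0].row(ids[t]) += dx.row(t);
    g[1].row(t) += dx.row(t);
  }
}

// Loss and gradients for a batch of row indices into `ids`.
// objective: 0 = masked-token prediction (targets: n x T, -1 = not masked),
//            1 = sequence classification  (targets: n x 1, 0-based labels).
static double batch_loss_grads(const std::vector<mat>& p, const Dims& dm,
                               const IntegerMatrix& ids, const IntegerMatrix& attn,
                               const IntegerMatrix& targets, int objective,
                               const std::vector<int>& rows, double dropout,
                               std::mt19937_64* rng, std::vector<mat>* g) {
  const int T = dm.T, V = dm.V, C = dm.C;
  int bf = 2 + 16 * dm.L;

  // normalization constant over the batch
  double denom = 0.0;
  if (objective == 0) {
    for (int r : rows)
      for (int t = 0; t < T; ++t)
        if (targets(r, t) >= 0) denom += 1.0;
  } else {
    denom = rows.size();
  }
  if (denom == 0) return 0.0;

  double loss = 0.0;
  std::vector<int> id_buf(T), at_buf(T);
  for (int r : rows) {
    for (int t = 0; t < T; ++t) { id_buf[t] = ids(r, t); at_buf[t] = attn(r, t); }
    SeqCache sc;
    forward_seq(p, dm, id_buf.data(), at_buf.data(), dropout, rng, sc, g != nullptr);

    mat dh(T, dm.d, arma::fill::zeros);
    if (objective == 0) {
      for (int t = 0; t < T; ++t) {
        int tgt = targets(r, t);
        if (tgt < 0) continue;
        rowvec logit = sc.h.row(t) * p[bf + 2] + as_rowvec(p[bf + 3]);
        float mx = logit.max();
        rowvec e = arma::exp(logit - mx);
        float Z = arma::accu(e);
        rowvec prob = e / Z;
        loss -= std::log(std::max((double)prob(tgt), 1e-12)) / denom;
        if (g) {
          rowvec dlogit = prob / denom;
          dlogit(tgt) -= 1.0 / denom;
          (*g)[bf + 2] += sc.h.row(t).t() * dlogit;
          (*g)[bf + 3] += dlogit.t();
          dh.row(t) += dlogit * p[bf + 2].t();
        }
      }
    } else {
      int tgt = targets(r, 0);
      rowvec logit = sc.h.row(0) * p[bf + 4] + as_rowvec(p[bf + 5]);
      float mx = logit.max();
      rowvec e = arma::exp(logit - mx);
      rowvec prob = e / arma::accu(e);
      loss -= std::log(std::max((double)prob(tgt), 1e-12)) / denom;
      if (g) {
        rowvec dlogit = prob / denom;
        dlogit(tgt) -= 1.0 / denom;
        (*g)[bf + 4] += sc.h.row(0).t() * dlogit;
        (*g)[bf + 5] += dlogit.t();
        dh.row(0) += dlogit * p[bf + 4].t();
      }
    }
    if (g) backward_seq(p, dm, id_buf.data(), dh, sc, *g);
  }
  return loss;
}

// [[Rcpp::export]]
List tf_batch_grads(List params, IntegerMatrix ids, IntegerMatrix attn,
                    IntegerMatrix targets, int objective, int n_layers,
                    int n_heads) {
  std::vector<mat> p = list_to_params(params);
  Dims dm = infer_dims(p, n_layers, n_heads, ids.ncol());
  std::vector<mat> g(p.size());
  for (size_t i = 0; i < p.size(); ++i) g[i] = arma::zeros<mat>(p[i].n_rows, p[i].n_cols);
  std::vector<int> rows(ids.nrow());
  for (int i = 0; i < ids.nrow(); ++i) rows[i] = i;
  double loss = batch_loss_grads(p, dm, ids, attn, targets, objective, rows,
                                 0.0, nullptr, &g);
  return List::create(_["loss"] = loss, _["grads"] = params_to_list(g, params));
}

// [[Rcpp::export]]
double tf_eval_loss(List params, IntegerMatrix ids, IntegerMatrix attn,
                    IntegerMatrix targets, int objective, int n_layers,
                    int n_heads) {
  std::vector<mat> p = list_to_params(params);
  Dims dm = infer_dims(p, n_layers, n_heads, ids.ncol());
  std::vector<int> rows(ids.nrow());
  for (int i = 0; i < ids.nrow(); ++i) rows[i] = i;
  return batch_loss_grads(p, dm, ids, attn, targets, objective, rows,
                          0.0, nullptr, nullptr);
}

// One epoch of AdamW over pre-shuffled data. `order` is a 1-based permutation
// of rows; `m`, `v` carry optimizer state; `step` the global step counter.
// Weight decay is applied to genuine weight matrices only (ncol > 1).
// [[Rcpp::export]]
List tf_epoch(List params, List m_state, List v_state, int step,
              IntegerMatrix ids, IntegerMatrix attn, IntegerMatrix targets,
              int objective, IntegerVector order, int batch_size, double lr,
              double weight_decay, double dropout, int n_layers, int n_heads,
              int seed) {
  std::vector<mat> p = list_to_params(params);
  std::vector<mat> m = list_to_params(m_state);
  std::vector<mat> v = list_to_params(v_state);
  Dims dm = infer_dims(p, n_layers, n_heads, ids.ncol());
  std::mt19937_64 rng((uint64_t)seed);

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  int n = order.size();
  double loss_sum = 0.0;
  int n_batches = 0;

  std::vector<mat> g(p.size());
  for (int start = 0; start < n; start += batch_size) {
    int end = std::min(start + batch_size, n);
    std::vector<int> rows;
    rows.reserve(end - start);
    for (int i = start; i < end; ++i) rows.push_back(order[i] - 1);

    for (size_t i = 0; i < p.size(); ++i) g[i] = arma::zeros<mat>(p[i].n_rows, p[i].n_cols);
    std::mt19937_64* rp = dropout > 0 ? &rng : nullptr;
    double loss = batch_loss_grads(p, dm, ids, attn, targets, objective, rows,
                                   dropout, rp, &g);
    loss_sum += loss;
    ++n_batches;
    ++step;

    double c1 = 1.0 - std::pow(b1, step);
    double c2 = 1.0 - std::pow(b2, step);
    for (size_t i = 0; i < p.size(); ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * g[i];
      v[i] = b2 * v[i] + (1.0 - b2) * arma::square(g[i]);
      mat update = (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
      if (weight_decay > 0 && p[i].n_cols > 1) update += weight_decay * p[i];
      p[i] -= lr * update;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["params"] = params_to_list(p, params),
      _["m"] = params_to_list(m, m_state),
      _["v"] = params_to_list(v, v_state),
      _["step"] = step,
      _["loss"] = n_batches ? loss_sum / n_batches : NA_REAL);
}

// Class probabilities (n x C), deterministic (no dropout).
// [[Rcpp::export]]
NumericMatrix tf_predict(List params, IntegerMatrix ids, IntegerMatrix attn,
                         int n_layers, int n_heads) {
  std::vector<mat> p = list_to_params(params);
  Dims dm = infer_dims(p, n_layers, n_heads, ids.ncol());
  int bf = 2 + 16 * dm.L;
  int n = ids.nrow();
  NumericMatrix out(n, dm.C);
  std::vector<int> id_buf(dm.T), at_buf(dm.T);
  for (int r = 0; r < n; ++r) {
    for (int t = 0; t < dm.T; ++t) { id_buf[t] = ids(r, t); at_buf[t] = attn(r, t); }
    SeqCache sc;
    forward_seq(p, dm, id_buf.data(), at_buf.data(), 0.0, nullptr, sc, false);
    rowvec logit = sc.h.row(0) * p[bf + 4] + as_rowvec(p[bf + 5]);
    double mx = logit.max();
    rowvec e = arma::exp(logit - mx);
    rowvec prob = e / arma::accu(e);
    for (int c = 0; c < dm.C; ++c) out(r, c) = prob(c);
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
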