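// Minimal 1D-CNN engine backing the two-branch ensemble classifier.
//
// Activations are (length x channels) float matrices, one per sample.
// A branch is a flat op list (conv / relu / maxpool2 / save / add) compiled
// on the R side; residual blocks lower to save .. convs .. add(+proj) relu.
// After each branch: global average pooling over the spatial axis, then a
// dense layer to the branch feature vector; the two feature vectors are
// concatenated and fed to a dense softmax head.
//
// Single precision throughout: the training signal (arm-level mean shifts)
// is far above float round-off and sgemm doubles throughput on one CPU.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

typedef std::vector<fmat> Batch;

enum OpType { OP_CONV = 0, OP_RELU = 1, OP_POOL = 2, OP_SAVE = 3, OP_ADD = 4 };

struct LayerOp {
  int type;
  int k = 0;      // conv kernel height
  bool same = false;  // zero-pad to preserve length (residual interior)
  int w = -1;     // 0-based weight index (conv, or add-projection; -1 = identity)
};

struct Weights {
  std::vector<fmat> W;
  std::vector<frowvec> b;
};

static std::vector<LayerOp> parse_plan(const Rcpp::List& plan) {
  std::vector<LayerOp> ops;
  ops.reserve(plan.size());
  for (R_xlen_t i = 0; i < plan.size(); ++i) {
    Rcpp::List o = plan[i];
    std::string t = Rcpp::as<std::string>(o["op"]);
    LayerOp op;
    if (t == "conv") {
      op.type = OP_CONV;
      op.k = Rcpp::as<int>(o["k"]);
      op.same = Rcpp::as<bool>(o["same"]);
      op.w = Rcpp::as<int>(o["w"]) - 1;
    } else if (t == "relu") {
      op.type = OP_RELU;
    } else if (t == "pool") {
      op.type = OP_POOL;
    } else if (t == "save") {
      op.type = OP_SAVE;
    } else if (t == "add") {
      op.type = OP_ADD;
      op.w = Rcpp::as<int>(o["w"]) - 1;  // R sends 0 for identity shortcut
    } else {
      Rcpp::stop("unknown op '%s' in layer plan", t);
    }
    ops.push_back(op);
  }
  return ops;
}

static Weights parse_weights(const Rcpp::List& wl) {
  Weights w;
  w.W.reserve(wl.size());
  w.b.reserve(wl.size());
  for (R_xlen_t i = 0; i < wl.size(); ++i) {
    Rcpp::List e = wl[i];
    w.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(e["W"])));
    w.b.push_back(conv_to<frowvec>::from(Rcpp::as<rowvec>(e["b"])));
  }
  return w;
}

static Rcpp::List weights_to_r(const Weights& w) {
  Rcpp::List out(w.W.size());
  for (size_t i = 0; i < w.W.size(); ++i) {
    out[i] = Rcpp::List::create(
        Rcpp::Named("W") = conv_to<mat>::from(w.W[i]),
        Rcpp::Named("b") = conv_to<rowvec>::from(w.b[i]));
  }
  return out;
}

// ---- layer primitives -------------------------------------------------

static fmat pad_same(const fmat& X, int k) {
  int pl = (k - 1) / 2, pr = k - 1 - pl;
  fmat Xp(X.n_rows + pl + pr, X.n_cols, fill::zeros);
  Xp.rows(pl, pl + X.n_rows - 1) = X;
  return Xp;
}

static fmat im2col(const fmat& X, int k, int Lout) {
  const int Cin = X.n_cols;
  fmat Xcol(Lout, k * Cin);
  for (int j = 0; j < k; ++j)
    Xcol.cols(j * Cin, (j + 1) * Cin - 1) = X.rows(j, j + Lout - 1);
  return Xcol;
}

static fmat conv_fwd(const fmat& X, const fmat& W, const frowvec& b,
                     int k, bool same) {
  fmat Y;
  if (k == 1) {
    Y = X * W;
  } else {
    fmat Xp = same ? pad_same(X, k) : X;
    const int Lout = (int)Xp.n_rows - k + 1;
    if (Lout < 1) Rcpp::stop("conv kernel %d larger than signal length %d",
                             k, (int)X.n_rows);
    Y = im2col(Xp, k, Lout) * W;
  }
  Y.each_row() += b;
  return Y;
}

static fmat conv_bwd(const fmat& X, const fmat& W, const fmat& dY,
                     int k, bool same, fmat& dW, frowvec& db) {
  db += sum(dY, 0);
  if (k == 1) {
    dW += X.t() * dY;
    return dY * W.t();
  }
  fmat Xp = same ? pad_same(X, k) : X;
  const int Lout = dY.n_rows;
  const int Cin = X.n_cols;
  dW += im2col(Xp, k, Lout).t() * dY;
  fmat dXcol = dY * W.t();
  fmat dXp(Xp.n_rows, Cin, fill::zeros);
  for (int j = 0; j < k; ++j)
    dXp.rows(j, j + Lout - 1) += dXcol.cols(j * Cin, (j + 1) * Cin - 1);
  if (same) {
    int pl = (k - 1) / 2;
    return dXp.rows(pl, pl + X.n_rows - 1);
  }
  return dXp;
}

static fmat pool_fwd(const fmat& X) {
  const int Lout = (int)X.n_rows / 2;
  fmat Y(Lout, X.n_cols);
  for (uword c = 0; c < X.n_cols; ++c)
    for (int t = 0; t < Lout; ++t)
      Y(t, c) = std::max(X(2 * t, c), X(2 * t + 1, c));
  return Y;
}

static fmat pool_bwd(const fmat& X, const fmat& dY) {
  fmat dX(X.n_rows, X.n_cols, fill::zeros);
  const int Lout = dY.n_rows;
  for (uword c = 0; c < X.n_cols; ++c)
    for (int t = 0; t < Lout; ++t) {
      // ties route to the earlier position
      if (X(2 * t, c) >= X(2 * t + 1, c)) dX(2 * t, c) += dY(t, c);
      else dX(2 * t + 1, c) += dY(t, c);
    }
  return dX;
}

// ---- branch forward / backward ---------------------------------------

struct BranchCache {
  std::vector<Batch> in;          // per-op input activations
  std::vector<Batch> saved;       // stack snapshots, in push order
};

static Batch branch_forward(const std::vector<LayerOp>& ops, const Weights& w,
                            Batch act, BranchCache* cache) {
  std::vector<Batch> stack;
  for (const LayerOp& op : ops) {
    if (cache) cache->in.push_back(act);
    switch (op.type) {
      case OP_CONV: {
        for (fmat& a : act) a = conv_fwd(a, w.W[op.w], w.b[op.w], op.k, op.same);
        break;
      }
      case OP_RELU: {
        for (fmat& a : act) a = clamp(a, 0.0f, std::numeric_limits<float>::max());
        break;
      }
      case OP_POOL: {
        for (fmat& a : act) a = pool_fwd(a);
        break;
      }
      case OP_SAVE: {
        stack.push_back(act);
        if (cache) cache->saved.push_back(act);
        break;
      }
      case OP_ADD: {
        const Batch& S = stack.back();
        for (size_t i = 0; i < act.size(); ++i) {
          if (op.w >= 0)
            act[i] += conv_fwd(S[i], w.W[op.w], w.b[op.w], 1, false);
          else
            act[i] += S[i];
        }
        stack.pop_back();
        break;
      }
    }
  }
  return act;
}

static Batch branch_backward(const std::vector<LayerOp>& ops, const Weights& w,
                             const BranchCache& cache, Batch dact,
                             Weights& grad) {
  std::vector<Batch> gstack;  // shortcut grads waiting for their SAVE
  size_t save_seen = cache.saved.size();
  for (int oi = (int)ops.size() - 1; oi >= 0; --oi) {
    const LayerOp& op = ops[oi];
    const Batch& X = cache.in[oi];
    switch (op.type) {
      case OP_CONV: {
        for (size_t i = 0; i < dact.size(); ++i)
          dact[i] = conv_bwd(X[i], w.W[op.w], dact[i], op.k, op.same,
                             grad.W[op.w], grad.b[op.w]);
        break;
      }
      case OP_RELU: {
        for (size_t i = 0; i < dact.size(); ++i)
          dact[i] %= conv_to<fmat>::from(X[i] > 0.0f);
        break;
      }
      case OP_POOL: {
        for (size_t i = 0; i < dact.size(); ++i)
          dact[i] = pool_bwd(X[i], dact[i]);
        break;
      }
      case OP_ADD: {
        --save_seen;
        const Batch& S = cache.saved[save_seen];
        Batch dS(dact.size());
        for (size_t i = 0; i < dact.size(); ++i) {
          if (op.w >= 0)
            dS[i] = conv_bwd(S[i], w.W[op.w], dact[i], 1, false,
                             grad.W[op.w], grad.b[op.w]);
          else
            dS[i] = dact[i];
        }
        gstack.push_back(std::move(dS));
        break;
      }
      case OP_SAVE: {
        Batch dS = std::move(gstack.back());
        gstack.pop_back();
        for (size_t i = 0; i < dact.size(); ++i) dact[i] += dS[i];
        break;
      }
    }
  }
  return dact;
}

// ---- full model -------------------------------------------------------

struct Model {
  std::vector<LayerOp> plan1, plan2;
  int d1, d2, head;  // 0-based dense weight indices
};

static Model parse_model(const Rcpp::List& net) {
  Model m;
  m.plan1 = parse_plan(net["plan1"]);
  m.plan2 = parse_plan(net["plan2"]);
  m.d1 = Rcpp::as<int>(net["d1"]) - 1;
  m.d2 = Rcpp::as<int>(net["d2"]) - 1;
  m.head = Rcpp::as<int>(net["head"]) - 1;
  return m;
}

static Batch rows_to_batch(const fmat& X, const uvec& idx) {
  Batch b;
  b.reserve(idx.n_elem);
  for (uword i = 0; i < idx.n_elem; ++i)
    b.push_back(X.row(idx(i)).t());  // (L x 1)
  return b;
}

static fmat gap(const Batch& act) {
  fmat G(act.size(), act[0].n_cols);
  for (size_t i = 0; i < act.size(); ++i)
    G.row(i) = mean(act[i], 0);
  return G;
}

struct FwdCache {
  BranchCache bc1, bc2;
  Batch out1, out2;        // branch activations after op plan
  fmat G1, G2, F1, F2, Z, P;
};

static fmat model_forward(const Model& m, const Weights& w,
                          const fmat& X1, const fmat& X2, const uvec& idx,
                          FwdCache* cache) {
  Batch a1 = branch_forward(m.plan1, w, rows_to_batch(X1, idx),
                            cache ? &cache->bc1 : nullptr);
  Batch a2 = branch_forward(m.plan2, w, rows_to_batch(X2, idx),
                            cache ? &cache->bc2 : nullptr);
  fmat G1 = gap(a1), G2 = gap(a2);
  fmat F1 = G1 * w.W[m.d1]; F1.each_row() += w.b[m.d1];
  fmat F2 = G2 * w.W[m.d2]; F2.each_row() += w.b[m.d2];
  F1 = clamp(F1, 0.0f, std::numeric_limits<float>::max());
  F2 = clamp(F2, 0.0f, std::numeric_limits<float>::max());
  fmat Z = join_rows(F1, F2);
  fmat logits = Z * w.W[m.head];
  logits.each_row() += w.b[m.head];
  fmat P = exp(logits.each_col() - max(logits, 1));
  P.each_col() /= sum(P, 1);
  if (cache) {
    cache->out1 = std::move(a1); cache->out2 = std::move(a2);
    cache->G1 = std::move(G1); cache->G2 = std::move(G2);
    cache->F1 = std::move(F1); cache->F2 = std::move(F2);
    cache->Z = std::move(Z); cache->P = P;
  }
  return P;
}

static Weights zero_like(const Weights& w) {
  Weights g;
  for (size_t i = 0; i < w.W.size(); ++i) {
    g.W.push_back(fmat(w.W[i].n_rows, w.W[i].n_cols, fill::zeros));
    g.b.push_back(frowvec(w.b[i].n_elem, fill::zeros));
  }
  return g;
}

// cross-entropy loss + full gradient for the samples in idx; if `correct`
// is given, accumulates the number of correct argmax predictions
static double model_backward(const Model& m, const Weights& w,
                             const fmat& X1, const fmat& X2,
                             const ivec& y, const uvec& idx, Weights& grad,
                             int* correct = nullptr) {
  FwdCache c;
  model_forward(m, w, X1, X2, idx, &c);
  const int n = idx.n_elem;
  double loss = 0.0;
  fmat dlog = c.P;
  for (int i = 0; i < n; ++i) {
    int yi = y(idx(i));
    loss -= std::log(std::max(c.P(i, yi), 1e-12f));
    if (correct && (c.P(i, 1) >= c.P(i, 0) ? 1 : 0) == yi) ++(*correct);
    dlog(i, yi) -= 1.0f;
  }
  loss /= n;
  dlog /= (float)n;

  grad.W[m.head] += c.Z.t() * dlog;
  grad.b[m.head] += sum(dlog, 0);
  fmat dZ = dlog * w.W[m.head].t();
  fmat dF1 = dZ.cols(0, c.F1.n_cols - 1);
  fmat dF2 = dZ.cols(c.F1.n_cols, dZ.n_cols - 1);
  dF1 %= conv_to<fmat>::from(c.F1 > 0.0f);
  dF2 %= conv_to<fmat>::from(c.F2 > 0.0f);
  grad.W[m.d1] += c.G1.t() * dF1;
  grad.b[m.d1] += sum(dF1, 0);
  grad.W[m.d2] += c.G2.t() * dF2;
  grad.b[m.d2] += sum(dF2, 0);
  fmat dG1 = dF1 * w.W[m.d1].t();
  fmat dG2 = dF2 * w.W[m.d2].t();

  Batch dact1(n), dact2(n);
  for (int i = 0; i < n; ++i) {
    const float L1 = c.out1[i].n_rows, L2 = c.out2[i].n_rows;
    dact1[i] = repmat(dG1.row(i) / L1, c.out1[i].n_rows, 1);
    dact2[i] = repmat(dG2.row(i) / L2, c.out2[i].n_rows, 1);
  }
  branch_backward(m.plan1, w, c.bc1, std::move(dact1), grad);
  branch_backward(m.plan2, w, c.bc2, std::move(dact2), grad);
  return loss;
}

// ---- exported entry points -------------------------------------------

// [[Rcpp::export]]
Rcpp::NumericMatrix nn_predict_cpp(Rcpp::List net, Rcpp::List weights,
                                   Rcpp::NumericMatrix X1,
                                   Rcpp::NumericMatrix X2,
                                   int batch_size = 32) {
  Model m = parse_model(net);
  Weights w = parse_weights(weights);
  fmat x1 = conv_to<fmat>::from(Rcpp::as<mat>(X1));
  fmat x2 = conv_to<fmat>::from(Rcpp::as<mat>(X2));
  const int n = x1.n_rows;
  mat P(n, 2);
  for (int s = 0; s < n; s += batch_size) {
    int e = std::min(s + batch_size, n) - 1;
    uvec idx = regspace<uvec>(s, e);
    P.rows(s, e) = conv_to<mat>::from(model_forward(m, w, x1, x2, idx, nullptr));
  }
  return Rcpp::wrap(P);
}

// [[Rcpp::export]]
Rcpp::List nn_loss_grad_cpp(Rcpp::List net, Rcpp::List weights,
                            Rcpp::NumericMatrix X1, Rcpp::NumericMatrix X2,
                            Rcpp::IntegerVector y) {
  Model m = parse_model(net);
  Weights w = parse_weights(weights);
  fmat x1 = conv_to<fmat>::from(Rcpp::as<mat>(X1));
  fmat x2 = conv_to<fmat>::from(Rcpp::as<mat>(X2));
  ivec yy = Rcpp::as<ivec>(y);
  Weights grad = zero_like(w);
  uvec idx = regspace<uvec>(0, x1.n_rows - 1);
  double loss = model_backward(m, w, x1, x2, yy, idx, grad);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = weights_to_r(grad));
}

static double eval_loss_acc(const Model& m, const Weights& w, const fmat& x1,
                            const fmat& x2, const ivec& y, double& acc) {
  const int n = x1.n_rows;
  double loss = 0.0;
  int correct = 0;
  const int bs = 32;
  for (int s = 0; s < n; s += bs) {
    int e = std::min(s + bs, n) - 1;
    uvec idx = regspace<uvec>(s, e);
    fmat P = model_forward(m, w, x1, x2, idx, nullptr);
    for (uword i = 0; i < idx.n_elem; ++i) {
      int yi = y(idx(i));
      loss -= std::log(std::max(P(i, yi), 1e-12f));
      if ((P(i, 1) >= P(i, 0) ? 1 : 0) == yi) ++correct;
    }
  }
  acc = (double)correct / n;
  return loss / n;
}

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(Rcpp::List net, Rcpp::List weights,
                        Rcpp::NumericMatrix X1, Rcpp::NumericMatrix X2,
                        Rcpp::IntegerVector y,
                        Rcpp::NumericMatrix X1v, Rcpp::NumericMatrix X2v,
                        Rcpp::IntegerVector yv,
                        Rcpp::List hyper) {
  Model m = parse_model(net);
  Weights w = parse_weights(weights);
  fmat x1 = conv_to<fmat>::from(Rcpp::as<mat>(X1));
  fmat x2 = conv_to<fmat>::from(Rcpp::as<mat>(X2));
  ivec yy = Rcpp::as<ivec>(y);
  fmat x1v = conv_to<fmat>::from(Rcpp::as<mat>(X1v));
  fmat x2v = conv_to<fmat>::from(Rcpp::as<mat>(X2v));
  ivec yyv = Rcpp::as<ivec>(yv);

  const int epochs = Rcpp::as<int>(hyper["epochs"]);
  const int batch = Rcpp::as<int>(hyper["batch_size"]);
  const float lr = Rcpp::as<double>(hyper["learning_rate"]);
  const int patience = Rcpp::as<int>(hyper["patience"]);
  const double min_delta = Rcpp::as<double>(hyper["min_delta"]);
  const unsigned seed = (unsigned)Rcpp::as<int>(hyper["seed"]);
  const bool verbose = Rcpp::as<bool>(hyper["verbose"]);
  const bool has_val = x1v.n_rows > 0;

  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  Weights mom = zero_like(w), vel = zero_like(w);
  std::mt19937 rng(seed);
  const int n = x1.n_rows;

  std::vector<double> h_tl, h_ta, h_vl, h_va;
  Weights best = w;
  double best_metric = std::numeric_limits<double>::infinity();
  int best_epoch = 0, wait = 0, step = 0, epochs_run = 0;

  for (int ep = 1; ep <= epochs; ++ep) {
    Rcpp::checkUserInterrupt();
    uvec perm = regspace<uvec>(0, n - 1);
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0.0;
    int nb = 0, n_correct = 0;
    for (int s = 0; s < n; s += batch) {
      uvec idx = perm.subvec(s, std::min(s + batch, n) - 1);
      Weights grad = zero_like(w);
      ep_loss += model_backward(m, w, x1, x2, yy, idx, grad, &n_correct) *
                 idx.n_elem;
      ++nb;
      ++step;
      const float bc1 = 1.0f - std::pow(b1, (float)step);
      const float bc2 = 1.0f - std::pow(b2, (float)step);
      for (size_t i = 0; i < w.W.size(); ++i) {
        mom.W[i] = b1 * mom.W[i] + (1 - b1) * grad.W[i];
        vel.W[i] = b2 * vel.W[i] + (1 - b2) * square(grad.W[i]);
        w.W[i] -= lr * (mom.W[i] / bc1) / (sqrt(vel.W[i] / bc2) + eps);
        mom.b[i] = b1 * mom.b[i] + (1 - b1) * grad.b[i];
        vel.b[i] = b2 * vel.b[i] + (1 - b2) * square(grad.b[i]);
        w.b[i] -= lr * (mom.b[i] / bc1) / (sqrt(vel.b[i] / bc2) + eps);
      }
    }
    (void)nb;
    double tr_loss = ep_loss / n;          // running loss over the epoch
    double tr_acc = (double)n_correct / n;
    double va_acc = NA_REAL, va_loss = NA_REAL;
    if (has_val) va_loss = eval_loss_acc(m, w, x1v, x2v, yyv, va_acc);
    h_tl.push_back(tr_loss); h_ta.push_back(tr_acc);
    h_vl.push_back(va_loss); h_va.push_back(va_acc);
    epochs_run = ep;
    if (verbose)
      Rcpp::Rcout << "epoch " << ep << " train_loss " << tr_loss
                  << " train_acc " << tr_acc
                  << (has_val ? " val_loss " : "")
                  << (has_val ? std::to_string(va_loss) : "") << std::endl;

    const double metric = has_val ? va_loss : tr_loss;
    if (metric < best_metric - min_delta) {
      best_metric = metric;
      best = w;
      best_epoch = ep;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
    // cross-entropy is bounded below by 0: once the monitored loss sits at
    // the floor no later epoch can improve by more than min_delta
    if (best_metric <= min_delta) break;
  }

  Rcpp::DataFrame hist = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = Rcpp::seq(1, epochs_run),
      Rcpp::Named("train_loss") = h_tl, Rcpp::Named("train_acc") = h_ta,
      Rcpp::Named("val_loss") = h_vl, Rcpp::Named("val_acc") = h_va);
  return Rcpp::List::create(Rcpp::Named("weights") = weights_to_r(best),
                            Rcpp::Named("history") = hist,
                            Rcpp::Named("best_epoch") = best_epoch);
}
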