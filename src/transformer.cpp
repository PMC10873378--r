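// Fast engine for the encoder-decoder Transformer: forward pass, loss and
// analytic gradients, mirroring the base-R reference implementation in
// R/transformer.R. Layout convention matches the R code: a batch of B
// sequences of length L is a (B*L) x d matrix of row blocks. Dropout draws
// come from R's RNG so set.seed() governs reproducibility.
//
// The R reference and this engine are checked against each other (dropout
// off) to 1e-10 in the test suite; numerical gradient checks cover both.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double LN_EPS = 1e-5;

struct Cfg {
  int d, ff, n_enc, n_dec, heads;
  double dropout;
  bool pre_ln;
  bool train;
};

struct Grads {
  std::map<std::string, mat> g;
  void add(const std::string& nm, const mat& m) {
    auto it = g.find(nm);
    if (it == g.end()) g[nm] = m; else it->second += m;
  }
};

static mat getm(const List& p, const std::string& nm) {
  return as<mat>(p[nm]);
}
static rowvec getv(const List& p, const std::string& nm) {
  return as<rowvec>(as<NumericVector>(p[nm]));
}

// ---- primitives ------------------------------------------------------------

struct LinCache { mat X; };

static mat linear_fwd(const mat& X, const mat& W, const rowvec& b,
                      LinCache& c) {
  c.X = X;
  mat Y = X * W;
  Y.each_row() += b;
  return Y;
}

static mat linear_bwd(const mat& dY, const LinCache& c, const mat& W,
                      Grads& gr, const std::string& wn,
                      const std::string& bn) {
  gr.add(wn, c.X.t() * dY);
  gr.add(bn, arma::sum(dY, 0));
  return dY * W.t();
}

struct LNCache { mat xhat; vec invstd; };

static mat ln_fwd(const mat& X, const rowvec& g, const rowvec& b,
                  LNCache& c) {
  vec mu = arma::mean(X, 1);
  mat xc = X.each_col() - mu;
  vec v = arma::mean(xc % xc, 1);
  c.invstd = 1.0 / arma::sqrt(v + LN_EPS);
  c.xhat = xc.each_col() % c.invstd;
  mat Y = c.xhat;
  Y.each_row() %= g;
  Y.each_row() += b;
  return Y;
}

static mat ln_bwd(const mat& dY, const LNCache& c, const rowvec& g,
                  Grads& gr, const std::string& gn, const std::string& bn) {
  gr.add(gn, arma::sum(dY % c.xhat, 0));
  gr.add(bn, arma::sum(dY, 0));
  mat dxhat = dY;
  dxhat.each_row() %= g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % c.xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.invstd;
  return dX;
}

struct DropCache { mat mask; bool active = false; };

static mat drop_fwd(const mat& X, const Cfg& cfg, DropCache& c) {
  if (!cfg.train || cfg.dropout <= 0) { c.active = false; return X; }
  c.active = true;
  NumericVector u = runif(X.n_elem);
  c.mask.set_size(X.n_rows, X.n_cols);
  double keep = 1.0 - cfg.dropout;
  // column-major fill to match R's matrix(runif(n), ...) semantics
  for (arma::uword k = 0; k < X.n_elem; ++k)
    c.mask(k) = (u[k] >= cfg.dropout) ? 1.0 / keep : 0.0;
  return X % c.mask;
}

static mat drop_bwd(const mat& dY, const DropCache& c) {
  return c.active ? mat(dY % c.mask) : dY;
}

static void softmax_rows_inplace(mat& S) {
  for (arma::uword i = 0; i < S.n_rows; ++i) {
    double mx = S.row(i).max();
    if (!std::isfinite(mx)) mx = 0.0;
    rowvec e = arma::exp(S.row(i) - mx);
    e.replace(arma::datum::nan, 0.0);
    e.replace(arma::datum::inf, 0.0);
    double s = arma::accu(e);
    if (s == 0) s = 1.0;
    S.row(i) = e / s;
  }
}

// ---- attention -------------------------------------------------------------

struct MHACache {
  mat Q, K, V, O, Xq, Xkv;
  std::vector<mat> A;
  int B, Lq, Lk;
};

static mat mha_fwd(const mat& Xq, const mat& Xkv, const List& p,
                   const std::string& prefix, const Cfg& cfg,
                   int B, int Lq, int Lk,
                   const arma::umat* key_mask, bool causal,
                   MHACache& c) {
  int d = cfg.d, H = cfg.heads, dh = d / H;
  mat Wq = getm(p, prefix + "_Wq"), Wk = getm(p, prefix + "_Wk"),
      Wv = getm(p, prefix + "_Wv"), Wo = getm(p, prefix + "_Wo");
  c.Q = Xq * Wq;  c.Q.each_row() += getv(p, prefix + "_bq");
  c.K = Xkv * Wk; c.K.each_row() += getv(p, prefix + "_bk");
  c.V = Xkv * Wv; c.V.each_row() += getv(p, prefix + "_bv");
  c.Xq = Xq; c.Xkv = Xkv; c.B = B; c.Lq = Lq; c.Lk = Lk;
  c.O.zeros(c.Q.n_rows, d);
  c.A.assign((size_t)B * H, mat());
  double scale = 1.0 / std::sqrt((double)dh);
  for (int b = 0; b < B; ++b) {
    arma::uword q0 = (arma::uword)b * Lq, k0 = (arma::uword)b * Lk;
    for (int h = 0; h < H; ++h) {
      arma::uword c0 = (arma::uword)h * dh;
      mat Qb = c.Q.submat(q0, c0, q0 + Lq - 1, c0 + dh - 1);
      mat Kb = c.K.submat(k0, c0, k0 + Lk - 1, c0 + dh - 1);
      mat S = (Qb * Kb.t()) * scale;
      if (key_mask)
        for (int j = 0; j < Lk; ++j)
          if (!(*key_mask)(b, j)) S.col(j).fill(-arma::datum::inf);
      if (causal)
        for (int i = 0; i < Lq; ++i)
          for (int j = i + 1; j < Lk; ++j) S(i, j) = -arma::datum::inf;
      softmax_rows_inplace(S);
      c.A[(size_t)b * H + h] = S;
      c.O.submat(q0, c0, q0 + Lq - 1, c0 + dh - 1) =
        S * c.V.submat(k0, c0, k0 + Lk - 1, c0 + dh - 1);
    }
  }
  mat out = c.O * Wo;
  out.each_row() += getv(p, prefix + "_bo");
  return out;
}

// returns dXq; adds dXkv into dXkv_out
static mat mha_bwd(const mat& dY, const MHACache& c, const List& p,
                   const std::string& prefix, const Cfg& cfg,
                   Grads& gr, mat& dXkv_out) {
  int d = cfg.d, H = cfg.heads, dh = d / H;
  int B = c.B, Lq = c.Lq, Lk = c.Lk;
  mat Wq = getm(p, prefix + "_Wq"), Wk = getm(p, prefix + "_Wk"),
      Wv = getm(p, prefix + "_Wv"), Wo = getm(p, prefix + "_Wo");
  gr.add(prefix + "_Wo", c.O.t() * dY);
  gr.add(prefix + "_bo", arma::sum(dY, 0));
  mat dO = dY * Wo.t();
  mat dQ(c.Q.n_rows, d, arma::fill::zeros);
  mat dK(c.K.n_rows, d, arma::fill::zeros);
  mat dV(c.V.n_rows, d, arma::fill::zeros);
  double scale = 1.0 / std::sqrt((double)dh);
  for (int b = 0; b < B; ++b) {
    arma::uword q0 = (arma::uword)b * Lq, k0 = (arma::uword)b * Lk;
    for (int h = 0; h < H; ++h) {
      arma::uword c0 = (arma::uword)h * dh;
      const mat& A = c.A[(size_t)b * H + h];
      mat dOb = dO.submat(q0, c0, q0 + Lq - 1, c0 + dh - 1);
      mat Vb = c.V.submat(k0, c0, k0 + Lk - 1, c0 + dh - 1);
      mat dA = dOb * Vb.t();
      dV.submat(k0, c0, k0 + Lk - 1, c0 + dh - 1) += A.t() * dOb;
      vec rs = arma::sum(dA % A, 1);
      mat dS = A % (dA.each_col() - rs);
      dQ.submat(q0, c0, q0 + Lq - 1, c0 + dh - 1) =
        (dS * c.K.submat(k0, c0, k0 + Lk - 1, c0 + dh - 1)) * scale;
      dK.submat(k0, c0, k0 + Lk - 1, c0 + dh - 1) +=
        (dS.t() * c.Q.submat(q0, c0, q0 + Lq - 1, c0 + dh - 1)) * scale;
    }
  }
  gr.add(prefix + "_Wq", c.Xq.t() * dQ);
  gr.add(prefix + "_bq", arma::sum(dQ, 0));
  gr.add(prefix + "_Wk", c.Xkv.t() * dK);
  gr.add(prefix + "_bk", arma::sum(dK, 0));
  gr.add(prefix + "_Wv", c.Xkv.t() * dV);
  gr.add(prefix + "_bv", arma::sum(dV, 0));
  dXkv_out += dK * Wk.t() + dV * Wv.t();
  return dQ * Wq.t();
}

// ---- feed-forward ----------------------------------------------------------

struct FFCache { LinCache l1, l2; arma::umat relu_mask; };

static mat ff_fwd(const mat& X, const List& p, const std::string& prefix,
                  FFCache& c) {
  mat H1 = linear_fwd(X, getm(p, prefix + "_W1"), getv(p, prefix + "_b1"),
                      c.l1);
  c.relu_mask = H1 > 0;
  mat R = H1 % arma::conv_to<mat>::from(c.relu_mask);
  return linear_fwd(R, getm(p, prefix + "_W2"), getv(p, prefix + "_b2"),
                    c.l2);
}

static mat ff_bwd(const mat& dY, const FFCache& c, const List& p,
                  const std::string& prefix, Grads& gr) {
  mat dR = linear_bwd(dY, c.l2, getm(p, prefix + "_W2"), gr,
                      prefix + "_W2", prefix + "_b2");
  dR %= arma::conv_to<mat>::from(c.relu_mask);
  return linear_bwd(dR, c.l1, getm(p, prefix + "_W1"), gr,
                    prefix + "_W1", prefix + "_b1");
}

// ---- sublayer wiring (residual + LN, post or pre placement) ---------------

struct SubCache { LNCache ln; DropCache dp; };

template <typename FwdFn>
static mat sublayer_fwd(const mat& X, const List& p,
                        const std::string& ln_prefix, const Cfg& cfg,
                        SubCache& c, FwdFn inner) {
  if (!cfg.pre_ln) {
    mat Y = inner(X);
    Y = drop_fwd(Y, cfg, c.dp);
    return ln_fwd(X + Y, getv(p, ln_prefix + "_g"),
                  getv(p, ln_prefix + "_b"), c.ln);
  } else {
    mat Xn = ln_fwd(X, getv(p, ln_prefix + "_g"),
                    getv(p, ln_prefix + "_b"), c.ln);
    mat Y = inner(Xn);
    Y = drop_fwd(Y, cfg, c.dp);
    return X + Y;
  }
}

template <typename BwdFn>
static mat sublayer_bwd(const mat& dY, const List& p,
                        const std::string& ln_prefix, const Cfg& cfg,
                        const SubCache& c, Grads& gr, BwdFn inner_bwd) {
  if (!cfg.pre_ln) {
    mat dsum = ln_bwd(dY, c.ln, getv(p, ln_prefix + "_g"), gr,
                      ln_prefix + "_g", ln_prefix + "_b");
    mat dinner = drop_bwd(dsum, c.dp);
    mat dX = inner_bwd(dinner);
    return dsum + dX;
  } else {
    mat dinner = drop_bwd(dY, c.dp);
    mat dXn = inner_bwd(dinner);
    mat dX = ln_bwd(dXn, c.ln, getv(p, ln_prefix + "_g"), gr,
                    ln_prefix + "_g", ln_prefix + "_b");
    return dY + dX;
  }
}

// ---- embedding -------------------------------------------------------------

struct EmbCache { arma::uvec idx; DropCache dp; int B, L; };

static mat embed_fwd(const IntegerMatrix& ids, const mat& emb, const mat& pe,
                     const Cfg& cfg, EmbCache& c) {
  int B = ids.nrow(), L = ids.ncol(), d = cfg.d;
  c.B = B; c.L = L;
  c.idx.set_size((arma::uword)B * L);
  mat X((arma::uword)B * L, d);
  double s = std::sqrt((double)d);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l) {
      arma::uword r = (arma::uword)b * L + l;
      c.idx(r) = (arma::uword)ids(b, l);
      X.row(r) = emb.row(c.idx(r)) * s + pe.row(l);
    }
  return drop_fwd(X, cfg, c.dp);
}

static mat embed_bwd(const mat& dY, const EmbCache& c, int vocab, int d) {
  mat dX = drop_bwd(dY, c.dp);
  double s = std::sqrt((double)d);
  mat demb(vocab, d, arma::fill::zeros);
  for (arma::uword r = 0; r < dX.n_rows; ++r)
    demb.row(c.idx(r)) += dX.row(r) * s;
  return demb;
}

// ---- encoder / decoder -----------------------------------------------------

struct EncLayerCache { SubCache att_s, ff_s; MHACache att; FFCache ff; };
struct EncCache {
  EmbCache emb;
  std::vector<EncLayerCache> layers;
  LNCache final_ln;
  arma::umat key_mask;
  int B, Ls;
};

static mat encoder_fwd_cpp(const List& p, const Cfg& cfg,
                           const IntegerMatrix& src, const mat& emb,
                           const mat& pe, int pad_id, EncCache& c) {
  int B = src.nrow(), Ls = src.ncol();
  c.B = B; c.Ls = Ls;
  c.key_mask.set_size(B, Ls);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < Ls; ++l) c.key_mask(b, l) = src(b, l) != pad_id;
  mat X = embed_fwd(src, emb, pe, cfg, c.emb);
  c.layers.resize(cfg.n_enc);
  for (int l = 0; l < cfg.n_enc; ++l) {
    std::string pre = "enc_l" + std::to_string(l + 1);
    EncLayerCache& lc = c.layers[l];
    X = sublayer_fwd(X, p, pre + "_ln1", cfg, lc.att_s, [&](const mat& Xi) {
      return mha_fwd(Xi, Xi, p, pre + "_att", cfg, B, Ls, Ls,
                     &c.key_mask, false, lc.att);
    });
    X = sublayer_fwd(X, p, pre + "_ln2", cfg, lc.ff_s, [&](const mat& Xi) {
      return ff_fwd(Xi, p, pre + "_ff", lc.ff);
    });
  }
  if (cfg.pre_ln)
    X = ln_fwd(X, getv(p, "enc_final_ln_g"), getv(p, "enc_final_ln_b"),
               c.final_ln);
  return X;
}

static void encoder_bwd_cpp(const mat& dmem, const List& p, const Cfg& cfg,
                            const EncCache& c, int src_vocab, Grads& gr) {
  mat dX = dmem;
  if (cfg.pre_ln)
    dX = ln_bwd(dX, c.final_ln, getv(p, "enc_final_ln_g"), gr,
                "enc_final_ln_g", "enc_final_ln_b");
  for (int l = cfg.n_enc - 1; l >= 0; --l) {
    std::string pre = "enc_l" + std::to_string(l + 1);
    const EncLayerCache& lc = c.layers[l];
    dX = sublayer_bwd(dX, p, pre + "_ln2", cfg, lc.ff_s, gr,
                      [&](const mat& dI) {
      return ff_bwd(dI, lc.ff, p, pre + "_ff", gr);
    });
    dX = sublayer_bwd(dX, p, pre + "_ln1", cfg, lc.att_s, gr,
                      [&](const mat& dI) {
      mat dXkv(dI.n_rows, cfg.d, arma::fill::zeros);
      mat dXq = mha_bwd(dI, lc.att, p, pre + "_att", cfg, gr, dXkv);
      return mat(dXq + dXkv);
    });
  }
  gr.add("src_emb", embed_bwd(dX, c.emb, src_vocab, cfg.d));
}

struct DecLayerCache {
  SubCache self_s, cross_s, ff_s;
  MHACache self, cross;
  FFCache ff;
};
struct DecCache {
  EmbCache emb;
  std::vector<DecLayerCache> layers;
  LNCache final_ln;
  LinCache out;
  int B, Lt;
};

static mat decoder_fwd_cpp(const List& p, const Cfg& cfg,
                           const IntegerMatrix& tgt_in, const mat& memory,
                           const arma::umat& src_key_mask, const mat& emb,
                           const mat& pe, DecCache& c) {
  int B = tgt_in.nrow(), Lt = tgt_in.ncol();
  int Ls = src_key_mask.n_cols;
  c.B = B; c.Lt = Lt;
  mat X = embed_fwd(tgt_in, emb, pe, cfg, c.emb);
  c.layers.resize(cfg.n_dec);
  for (int l = 0; l < cfg.n_dec; ++l) {
    std::string pre = "dec_l" + std::to_string(l + 1);
    DecLayerCache& lc = c.layers[l];
    X = sublayer_fwd(X, p, pre + "_ln1", cfg, lc.self_s, [&](const mat& Xi) {
      return mha_fwd(Xi, Xi, p, pre + "_self", cfg, B, Lt, Lt,
                     nullptr, true, lc.self);
    });
    X = sublayer_fwd(X, p, pre + "_ln2", cfg, lc.cross_s, [&](const mat& Xi) {
      return mha_fwd(Xi, memory, p, pre + "_cross", cfg, B, Lt, Ls,
                     &src_key_mask, false, lc.cross);
    });
    X = sublayer_fwd(X, p, pre + "_ln3", cfg, lc.ff_s, [&](const mat& Xi) {
      return ff_fwd(Xi, p, pre + "_ff", lc.ff);
    });
  }
  if (cfg.pre_ln)
    X = ln_fwd(X, getv(p, "dec_final_ln_g"), getv(p, "dec_final_ln_b"),
               c.final_ln);
  return linear_fwd(X, getm(p, "out_W"), getv(p, "out_b"), c.out);
}

static mat decoder_bwd_cpp(const mat& dlogits, const List& p, const Cfg& cfg,
                           const DecCache& c, int tgt_vocab, Grads& gr) {
  mat dX = linear_bwd(dlogits, c.out, getm(p, "out_W"), gr, "out_W", "out_b");
  if (cfg.pre_ln)
    dX = ln_bwd(dX, c.final_ln, getv(p, "dec_final_ln_g"), gr,
                "dec_final_ln_g", "dec_final_ln_b");
  mat dmem;
  bool have_dmem = false;
  for (int l = cfg.n_dec - 1; l >= 0; --l) {
    std::string pre = "dec_l" + std::to_string(l + 1);
    const DecLayerCache& lc = c.layers[l];
    dX = sublayer_bwd(dX, p, pre + "_ln3", cfg, lc.ff_s, gr,
                      [&](const mat& dI) {
      return ff_bwd(dI, lc.ff, p, pre + "_ff", gr);
    });
    mat dmem_l;
    dX = sublayer_bwd(dX, p, pre + "_ln2", cfg, lc.cross_s, gr,
                      [&](const mat& dI) {
      dmem_l.zeros(lc.cross.Xkv.n_rows, cfg.d);
      return mha_bwd(dI, lc.cross, p, pre + "_cross", cfg, gr, dmem_l);
    });
    if (have_dmem) dmem += dmem_l; else { dmem = dmem_l; have_dmem = true; }
    dX = sublayer_bwd(dX, p, pre + "_ln1", cfg, lc.self_s, gr,
                      [&](const mat& dI) {
      mat dXkv(dI.n_rows, cfg.d, arma::fill::zeros);
      mat dXq = mha_bwd(dI, lc.self, p, pre + "_self", cfg, gr, dXkv);
      return mat(dXq + dXkv);
    });
  }
  gr.add("tgt_emb", embed_bwd(dX, c.emb, tgt_vocab, cfg.d));
  return dmem;
}

static Cfg make_cfg(const List& cfgl, bool train) {
  Cfg c;
  c.d = as<int>(cfgl["d_model"]);
  c.ff = as<int>(cfgl["d_ff"]);
  c.n_enc = as<int>(cfgl["n_layers_enc"]);
  c.n_dec = as<int>(cfgl["n_layers_dec"]);
  c.heads = as<int>(cfgl["n_heads"]);
  c.dropout = as<double>(cfgl["dropout"]);
  c.pre_ln = as<std::string>(cfgl["norm_placement"]) == "pre_ln";
  c.train = train;
  return c;
}

// ---- exported entry points -------------------------------------------------

// forward + loss + gradients over one batch (teacher forcing)
// [[Rcpp::export(name = "cpp_loss_grads")]]
List cpp_loss_grads(List params, List cfgl, NumericMatrix pe,
                    IntegerMatrix src, IntegerMatrix tgt,
                    int pad_id, bool train,
                    int src_vocab, int tgt_vocab) {
  Cfg cfg = make_cfg(cfgl, train);
  mat pem = as<mat>(pe);
  int B = tgt.nrow(), Lt = tgt.ncol();
  IntegerMatrix tgt_in(B, Lt - 1);
  std::vector<int> tgt_out;
  tgt_out.reserve((size_t)B * (Lt - 1));
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < Lt - 1; ++l) tgt_in(b, l) = tgt(b, l);
  for (int b = 0; b < B; ++b)
    for (int l = 1; l < Lt; ++l) tgt_out.push_back(tgt(b, l));

  EncCache ec;
  mat memory = encoder_fwd_cpp(params, cfg, src, getm(params, "src_emb"),
                               pem, pad_id, ec);
  DecCache dc;
  mat logits = decoder_fwd_cpp(params, cfg, tgt_in, memory, ec.key_mask,
                               getm(params, "tgt_emb"), pem, dc);

  // masked mean cross-entropy + dlogits
  arma::uword N = logits.n_rows;
  int n_tok = 0;
  for (size_t i = 0; i < tgt_out.size(); ++i)
    if (tgt_out[i] != pad_id) ++n_tok;
  if (n_tok == 0) stop("all target positions are padding");
  double loss = 0.0;
  mat dlogits(N, logits.n_cols, arma::fill::zeros);
  bool bad = !logits.is_finite();
  if (bad) {
    return List::create(_["loss"] = NumericVector::create(NA_REAL),
                        _["grads"] = R_NilValue,
                        _["n_tokens"] = n_tok);
  }
  for (arma::uword i = 0; i < N; ++i) {
    if (tgt_out[i] == pad_id) continue;
    rowvec row = logits.row(i);
    double mx = row.max();
    rowvec e = arma::exp(row - mx);
    double s = arma::accu(e);
    rowvec pr = e / s;
    loss += -std::log(std::max(pr((arma::uword)tgt_out[i]), 1e-300));
    dlogits.row(i) = pr;
    dlogits(i, (arma::uword)tgt_out[i]) -= 1.0;
  }
  loss /= n_tok;
  dlogits /= (double)n_tok;

  Grads gr;
  mat dmem = decoder_bwd_cpp(dlogits, params, cfg, dc, tgt_vocab, gr);
  encoder_bwd_cpp(dmem, params, cfg, ec, src_vocab, gr);

  List gl;
  for (auto& kv : gr.g) gl[kv.first] = wrap(kv.second);
  return List::create(_["loss"] = loss, _["grads"] = gl,
                      _["n_tokens"] = n_tok);
}

// forward-only encoder (no dropout): returns memory matrix
// [[Rcpp::export(name = "cpp_encode")]]
NumericMatrix cpp_encode(List params, List cfgl, NumericMatrix pe,
                         IntegerMatrix src, int pad_id) {
  Cfg cfg = make_cfg(cfgl, false);
  EncCache ec;
  mat memory = encoder_fwd_cpp(params, cfg, src, getm(params, "src_emb"),
                               as<mat>(pe), pad_id, ec);
  return wrap(memory);
}

// forward-only decoder logits given precomputed memory
// [[Rcpp::export(name = "cpp_decode_logits")]]
NumericMatrix cpp_decode_logits(List params, List cfgl, NumericMatrix pe,
                                IntegerMatrix tgt_in, NumericMatrix memory,
                                IntegerMatrix src, int pad_id) {
  Cfg cfg = make_cfg(cfgl, false);
  int B = src.nrow(), Ls = src.ncol();
  arma::umat key_mask(B, Ls);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < Ls; ++l) key_mask(b, l) = src(b, l) != pad_id;
  DecCache dc;
  mat logits = decoder_fwd_cpp(params, cfg, tgt_in, as<mat>(memory),
                               key_mask, getm(params, "tgt_emb"),
                               as<mat>(pe), dc);
  return wrap(logits);
}
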