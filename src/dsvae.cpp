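// Sequential VAE cores: bidirectional-GRU encoders, autoregressive GRU local
// prior, MLP decoder (DSVAE / IDSVAE / LVAE) and a convolutional context-only
// model (CVAE).  Forward passes and hand-derived reverse-mode gradients; all
// stochasticity (reparameterization noise, batching) is injected from R so
// that every entry point here is a deterministic function of its arguments.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const double LOG2PI = 1.837877066409345483560659472811;
static const double LV_MIN = -10.0, LV_MAX = 10.0;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static mat getM(const List& p, const std::string& k) {
  return Rcpp::as<mat>(p[k]);
}
static vec getV(const List& p, const std::string& k) {
  return Rcpp::as<vec>(p[k]);
}

// ---------------------------------------------------------------- GRU cell --

struct Gru { mat Wx, Wh; vec bx, bh; };

static Gru getGru(const List& p, const std::string& pre) {
  Gru g;
  g.Wx = getM(p, pre + "_Wx"); g.Wh = getM(p, pre + "_Wh");
  g.bx = getV(p, pre + "_bx"); g.bh = getV(p, pre + "_bh");
  return g;
}

struct GruGrad {
  mat dWx, dWh; vec dbx, dbh;
  void init(const Gru& g) {
    dWx = zeros(size(g.Wx)); dWh = zeros(size(g.Wh));
    dbx = zeros<vec>(g.bx.n_elem); dbh = zeros<vec>(g.bh.n_elem);
  }
  void emit(List& out, const std::string& pre) const {
    out[pre + "_Wx"] = dWx; out[pre + "_Wh"] = dWh;
    out[pre + "_bx"] = dbx; out[pre + "_bh"] = dbh;
  }
};

struct GruCache { std::vector<mat> r, z, n, ahn, h; };

// X[t]: D x B inputs; h0: H x B initial state.  Fills C with gates + states.
// The input-side affine map is computed for all timesteps in one GEMM; only
// the recurrent part is stepped.
static void gruFwd(const Gru& P, const std::vector<mat>& X, const mat& h0,
                   GruCache& C) {
  const int T = (int) X.size();
  const int H = (int) P.Wh.n_cols;
  const int D = (int) X[0].n_rows;
  const int B = (int) X[0].n_cols;
  C.r.resize(T); C.z.resize(T); C.n.resize(T); C.ahn.resize(T); C.h.resize(T);
  mat Xall(D, T * B);
  for (int t = 0; t < T; ++t) Xall.cols(t * B, t * B + B - 1) = X[t];
  mat AX = P.Wx * Xall;
  AX.each_col() += P.bx;
  mat h = h0;
  for (int t = 0; t < T; ++t) {
    mat ax = AX.cols(t * B, t * B + B - 1);
    mat ah = P.Wh * h;    ah.each_col() += P.bh;
    mat r  = sigm(ax.rows(0, H - 1)         + ah.rows(0, H - 1));
    mat z  = sigm(ax.rows(H, 2 * H - 1)     + ah.rows(H, 2 * H - 1));
    mat ahn = ah.rows(2 * H, 3 * H - 1);
    mat n  = tanh(ax.rows(2 * H, 3 * H - 1) + r % ahn);
    h = (1.0 - z) % n + z % h;
    C.r[t] = r; C.z[t] = z; C.n[t] = n; C.ahn[t] = ahn; C.h[t] = h;
  }
}

// dH[t]: gradient wrt the state emitted at step t (may be all-zero).
static void gruBwd(const Gru& P, const std::vector<mat>& X, const mat& h0,
                   const GruCache& C, const std::vector<mat>& dH,
                   GruGrad& G, std::vector<mat>& dX, mat& dh0) {
  const int T = (int) X.size();
  const int H = (int) P.Wh.n_cols;
  const int B = (int) h0.n_cols;
  G.init(P);
  dX.assign(T, mat());
  const int D = (int) X[0].n_rows;
  mat Xall(D, T * B), HprevAll(H, T * B);
  mat DAX(3 * H, T * B), DAH(3 * H, T * B);
  for (int t = 0; t < T; ++t) {
    Xall.cols(t * B, t * B + B - 1) = X[t];
    HprevAll.cols(t * B, t * B + B - 1) = (t == 0) ? h0 : C.h[t - 1];
  }
  mat dh = zeros(H, B);
  for (int t = T - 1; t >= 0; --t) {
    dh += dH[t];
    const mat& hprev = (t == 0) ? h0 : C.h[t - 1];
    mat dz = dh % (hprev - C.n[t]) % C.z[t] % (1.0 - C.z[t]);
    mat du = dh % (1.0 - C.z[t]) % (1.0 - square(C.n[t]));
    mat dr = du % C.ahn[t] % C.r[t] % (1.0 - C.r[t]);
    mat dah = join_cols(dr, dz, du % C.r[t]);
    DAX.cols(t * B, t * B + B - 1) = join_cols(dr, dz, du);
    DAH.cols(t * B, t * B + B - 1) = dah;
    dh = dh % C.z[t] + P.Wh.t() * dah;
  }
  dh0 = dh;
  G.dWx = DAX * Xall.t();
  G.dWh = DAH * HprevAll.t();
  G.dbx = sum(DAX, 1);
  G.dbh = sum(DAH, 1);
  mat dXall = P.Wx.t() * DAX;
  for (int t = 0; t < T; ++t) dX[t] = dXall.cols(t * B, t * B + B - 1);
}

// ------------------------------------------------------------------ conv1d --

// Wk: Cout x (Cin*K), column block k = kernel tap k; zero 'same' padding.
static mat convFwd(const mat& Wk, const vec& b, const mat& X, int K) {
  const int Cin = (int) X.n_rows, W = (int) X.n_cols;
  const int Cout = (int) Wk.n_rows;
  const int pad = (K - 1) / 2;
  mat Xp = zeros(Cin, W + K - 1);
  Xp.cols(pad, pad + W - 1) = X;
  mat out(Cout, W, fill::zeros);
  for (int k = 0; k < K; ++k)
    out += Wk.cols(k * Cin, (k + 1) * Cin - 1) * Xp.cols(k, k + W - 1);
  out.each_col() += b;
  return out;
}

static void convBwd(const mat& Wk, const mat& X, const mat& dOut, int K,
                    mat& dWk, vec& db, mat& dX) {
  const int Cin = (int) X.n_rows, W = (int) X.n_cols;
  const int pad = (K - 1) / 2;
  mat Xp = zeros(Cin, W + K - 1);
  Xp.cols(pad, pad + W - 1) = X;
  mat dXp = zeros(size(Xp));
  for (int k = 0; k < K; ++k) {
    dWk.cols(k * Cin, (k + 1) * Cin - 1) += dOut * Xp.cols(k, k + W - 1).t();
    dXp.cols(k, k + W - 1) += Wk.cols(k * Cin, (k + 1) * Cin - 1).t() * dOut;
  }
  db += sum(dOut, 1);
  dX = dXp.cols(pad, pad + W - 1);
}

// ----------------------------------------------------------- small helpers --

static mat clampLv(const mat& raw, mat& mask) {
  mask = conv_to<mat>::from((raw > LV_MIN) % (raw < LV_MAX));
  return clamp(raw, LV_MIN, LV_MAX);
}

// Convert N x W x B cube into per-timestep N x B matrices.
static void cubeToSteps(const cube& x, std::vector<mat>& Xs) {
  const int N = (int) x.n_rows, W = (int) x.n_cols, B = (int) x.n_slices;
  Xs.assign(W, mat(N, B));
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < W; ++t)
      Xs[t].col(b) = x.slice(b).col(t);
}

// Conv context encoder (shared by CVAE and the conv context-arch): two conv
// layers with ReLU, global average pooling over time.
struct ConvEncCache {
  std::vector<mat> a1, h1, a2, h2;   // per batch element
  mat P;                              // C2 x B pooled features
};

static void convEncFwd(const List& p, const std::vector<mat>& Xb, int K,
                       ConvEncCache& C) {
  mat W1 = getM(p, "ce_c1_W"); vec b1 = getV(p, "ce_c1_b");
  mat W2 = getM(p, "ce_c2_W"); vec b2 = getV(p, "ce_c2_b");
  const int B = (int) Xb.size();
  const int C2 = (int) W2.n_rows;
  C.a1.resize(B); C.h1.resize(B); C.a2.resize(B); C.h2.resize(B);
  C.P.set_size(C2, B);
  for (int b = 0; b < B; ++b) {
    C.a1[b] = convFwd(W1, b1, Xb[b], K);
    C.h1[b] = C.a1[b] % (C.a1[b] > 0);
    C.a2[b] = convFwd(W2, b2, C.h1[b], K);
    C.h2[b] = C.a2[b] % (C.a2[b] > 0);
    C.P.col(b) = mean(C.h2[b], 1);
  }
}

static void convEncBwd(const List& p, const std::vector<mat>& Xb, int K,
                       const ConvEncCache& C, const mat& dP, List& G) {
  mat W1 = getM(p, "ce_c1_W");
  mat W2 = getM(p, "ce_c2_W");
  mat dW1 = zeros(size(W1)), dW2 = zeros(size(W2));
  vec db1 = zeros<vec>(getV(p, "ce_c1_b").n_elem);
  vec db2 = zeros<vec>(getV(p, "ce_c2_b").n_elem);
  const int B = (int) Xb.size();
  for (int b = 0; b < B; ++b) {
    const int W = (int) Xb[b].n_cols;
    mat dh2 = repmat(dP.col(b) / (double) W, 1, W);
    mat da2 = dh2 % (C.a2[b] > 0);
    mat dh1;
    convBwd(W2, C.h1[b], da2, K, dW2, db2, dh1);
    mat da1 = dh1 % (C.a1[b] > 0);
    mat dX;
    convBwd(W1, Xb[b], da1, K, dW1, db1, dX);
  }
  G["ce_c1_W"] = dW1; G["ce_c1_b"] = db1;
  G["ce_c2_W"] = dW2; G["ce_c2_b"] = db2;
}

// ============================================================== seq models ==
//
// variant: "dsvae" (context fed to local encoder + prior), "idsvae"
// (independent factorization), "lvae" (no context channel at all).
// x: N x W x B; eps_c: CS x B; eps_l: LS x B x W (slice t = step-t noise).

// [[Rcpp::export]]
List cpp_seq_step(const List& params, const arma::cube& x,
                  const arma::mat& eps_c, const arma::cube& eps_l,
                  const std::string& variant, const std::string& ctx_arch,
                  double beta, double gamma, int conv_kernel,
                  bool want_grads) {
  const bool hasCtx = (variant != "lvae");
  const bool ctxInLocal = (variant == "dsvae");
  const int N = (int) x.n_rows, W = (int) x.n_cols, B = (int) x.n_slices;
  const int K = conv_kernel;

  std::vector<mat> Xs;
  cubeToSteps(x, Xs);

  // --- context encoder -------------------------------------------------
  mat mu_c, lv_c, lvc_mask, z_c;
  int CS = 0;
  Gru cf, cb; GruCache Ccf, Ccb; mat Ucat;           // rnn arch caches
  ConvEncCache Ccv;                                   // conv arch cache
  mat ce_mu_W, ce_lv_W;
  if (hasCtx) {
    ce_mu_W = getM(params, "ce_mu_W");
    ce_lv_W = getM(params, "ce_lv_W");
    CS = (int) ce_mu_W.n_rows;
    mat feat;
    if (ctx_arch == "rnn") {
      cf = getGru(params, "ce_f"); cb = getGru(params, "ce_b");
      const int H = (int) cf.Wh.n_cols;
      mat h0 = zeros(H, B);
      std::vector<mat> Xrev(W);
      for (int t = 0; t < W; ++t) Xrev[t] = Xs[W - 1 - t];
      gruFwd(cf, Xs, h0, Ccf);
      gruFwd(cb, Xrev, h0, Ccb);
      Ucat = join_cols(Ccf.h[W - 1], Ccb.h[W - 1]);  // final states, both dirs
      feat = Ucat;
    } else {
      std::vector<mat> Xb(B);
      for (int b = 0; b < B; ++b) Xb[b] = x.slice(b);
      convEncFwd(params, Xb, K, Ccv);
      feat = Ccv.P;
    }
    mu_c = ce_mu_W * feat; mu_c.each_col() += getV(params, "ce_mu_b");
    mat lv_raw = ce_lv_W * feat; lv_raw.each_col() += getV(params, "ce_lv_b");
    lv_c = clampLv(lv_raw, lvc_mask);
    z_c = mu_c + exp(0.5 * lv_c) % eps_c;
  }

  // --- local encoder ----------------------------------------------------
  Gru lf = getGru(params, "le_f"), lb = getGru(params, "le_b");
  mat le_mu_W = getM(params, "le_mu_W"), le_lv_W = getM(params, "le_lv_W");
  vec le_mu_b = getV(params, "le_mu_b"), le_lv_b = getV(params, "le_lv_b");
  const int H = (int) lf.Wh.n_cols;
  const int LS = (int) le_mu_W.n_rows;

  std::vector<mat> Lin(W);
  for (int t = 0; t < W; ++t)
    Lin[t] = ctxInLocal ? join_cols(Xs[t], z_c) : Xs[t];
  std::vector<mat> LinRev(W);
  for (int t = 0; t < W; ++t) LinRev[t] = Lin[W - 1 - t];
  mat h0l = zeros(H, B);
  GruCache Clf, Clb;
  gruFwd(lf, Lin, h0l, Clf);
  gruFwd(lb, LinRev, h0l, Clb);

  std::vector<mat> Hcat(W), mu_l(W), lv_l(W), lvl_mask(W), z_l(W);
  for (int t = 0; t < W; ++t) {
    Hcat[t] = join_cols(Clf.h[t], Clb.h[W - 1 - t]);
    mu_l[t] = le_mu_W * Hcat[t]; mu_l[t].each_col() += le_mu_b;
    mat raw = le_lv_W * Hcat[t]; raw.each_col() += le_lv_b;
    lv_l[t] = clampLv(raw, lvl_mask[t]);
    z_l[t] = mu_l[t] + exp(0.5 * lv_l[t]) % eps_l.slice(t);
  }

  // --- autoregressive local prior --------------------------------------
  Gru pr = getGru(params, "pr");
  mat pr_mu_W = getM(params, "pr_mu_W"), pr_lv_W = getM(params, "pr_lv_W");
  vec pr_mu_b = getV(params, "pr_mu_b"), pr_lv_b = getV(params, "pr_lv_b");
  const int Hp = (int) pr.Wh.n_cols;

  mat h0p_pre, h0p;
  if (ctxInLocal) {  // dsvae: conditioned on the context sample
    h0p_pre = getM(params, "pr_h0_W") * z_c;
    h0p_pre.each_col() += getV(params, "pr_h0_b");
  } else {           // idsvae / lvae: conditioned on a learnable vector
    h0p_pre = repmat(getV(params, "pr_h0_v"), 1, B);
  }
  h0p = tanh(h0p_pre);

  std::vector<mat> Pin(W);
  Pin[0] = zeros(LS, B);
  for (int t = 1; t < W; ++t) Pin[t] = z_l[t - 1];
  GruCache Cpr;
  gruFwd(pr, Pin, h0p, Cpr);

  std::vector<mat> mu_p(W), lv_p(W), lvp_mask(W);
  for (int t = 0; t < W; ++t) {
    mu_p[t] = pr_mu_W * Cpr.h[t]; mu_p[t].each_col() += pr_mu_b;
    mat raw = pr_lv_W * Cpr.h[t]; raw.each_col() += pr_lv_b;
    lv_p[t] = clampLv(raw, lvp_mask[t]);
  }

  // --- decoder ----------------------------------------------------------
  mat de_W1 = getM(params, "de_W1"), de_W2 = getM(params, "de_W2");
  vec de_b1 = getV(params, "de_b1"), de_b2 = getV(params, "de_b2");
  const int WB = W * B;
  mat Z(hasCtx ? CS + LS : LS, WB), Xf(N, WB);
  for (int t = 0; t < W; ++t) {
    Z.cols(t * B, t * B + B - 1) = hasCtx ? join_cols(z_c, z_l[t]) : z_l[t];
    Xf.cols(t * B, t * B + B - 1) = Xs[t];
  }
  mat A1 = de_W1 * Z; A1.each_col() += de_b1;
  mat D1 = A1 % (A1 > 0);
  mat Xhat = de_W2 * D1; Xhat.each_col() += de_b2;

  // --- loss -------------------------------------------------------------
  mat diff = Xhat - Xf;
  double recon = 0.5 * accu(square(diff)) / (double) WB + 0.5 * N * LOG2PI;

  double local_kl = 0.0;
  std::vector<mat> vq(W), vp(W), dm(W);
  for (int t = 0; t < W; ++t) {
    vq[t] = exp(lv_l[t]); vp[t] = exp(lv_p[t]); dm[t] = mu_l[t] - mu_p[t];
    local_kl += accu(0.5 * (lv_p[t] - lv_l[t]
                            + (vq[t] + square(dm[t])) / vp[t] - 1.0));
  }
  local_kl /= (double) WB;

  double context_kl = 0.0;
  if (hasCtx)
    context_kl = accu(0.5 * (exp(lv_c) + square(mu_c) - 1.0 - lv_c))
                 / (double) B;

  double total = recon + beta * local_kl + gamma * context_kl;

  List out = List::create(
    Named("reconstruction") = recon, Named("local_kl") = local_kl,
    Named("context_kl") = context_kl, Named("total") = total,
    Named("window_count") = B);
  if (!want_grads) return out;

  // ===================================================== backward pass ==
  List G;

  // decoder
  mat dXhat = diff / (double) WB;
  mat dD1 = de_W2.t() * dXhat;
  mat dA1 = dD1 % (A1 > 0);
  mat dZ = de_W1.t() * dA1;
  G["de_W2"] = dXhat * D1.t();
  G["de_b2"] = vec(sum(dXhat, 1));
  G["de_W1"] = dA1 * Z.t();
  G["de_b1"] = vec(sum(dA1, 1));

  mat dz_c = hasCtx ? zeros(CS, B) : mat();
  std::vector<mat> dz_l(W);
  for (int t = 0; t < W; ++t) {
    mat blk = dZ.cols(t * B, t * B + B - 1);
    if (hasCtx) {
      dz_c += blk.rows(0, CS - 1);
      dz_l[t] = blk.rows(CS, CS + LS - 1);
    } else {
      dz_l[t] = blk;
    }
  }

  // local KL gradients
  const double sL = beta / (double) WB;
  std::vector<mat> dmu_l(W), dlv_l(W), dmu_p(W), dlv_p(W);
  for (int t = 0; t < W; ++t) {
    dmu_l[t] = sL * dm[t] / vp[t];
    dmu_p[t] = -dmu_l[t];
    dlv_l[t] = sL * 0.5 * (vq[t] / vp[t] - 1.0);
    dlv_p[t] = sL * 0.5 * (1.0 - (vq[t] + square(dm[t])) / vp[t]);
  }

  // prior backward (readouts then GRU); adds path gradients into dz_l
  {
    GruGrad Gp;
    std::vector<mat> dHp(W);
    mat dpmW = zeros(size(pr_mu_W)), dpvW = zeros(size(pr_lv_W));
    vec dpmb = zeros<vec>(pr_mu_b.n_elem), dpvb = zeros<vec>(pr_lv_b.n_elem);
    for (int t = 0; t < W; ++t) {
      mat dlvRaw = dlv_p[t] % lvp_mask[t];
      dHp[t] = pr_mu_W.t() * dmu_p[t] + pr_lv_W.t() * dlvRaw;
      dpmW += dmu_p[t] * Cpr.h[t].t(); dpmb += sum(dmu_p[t], 1);
      dpvW += dlvRaw * Cpr.h[t].t();   dpvb += sum(dlvRaw, 1);
    }
    G["pr_mu_W"] = dpmW; G["pr_mu_b"] = dpmb;
    G["pr_lv_W"] = dpvW; G["pr_lv_b"] = dpvb;
    std::vector<mat> dPin;
    mat dh0p;
    gruBwd(pr, Pin, h0p, Cpr, dHp, Gp, dPin, dh0p);
    Gp.emit(G, "pr");
    for (int t = 0; t + 1 < W; ++t) dz_l[t] += dPin[t + 1];
    mat dh0pre = dh0p % (1.0 - square(h0p));
    if (ctxInLocal) {
      G["pr_h0_W"] = mat(dh0pre * z_c.t());
      G["pr_h0_b"] = vec(sum(dh0pre, 1));
      dz_c += getM(params, "pr_h0_W").t() * dh0pre;
    } else {
      G["pr_h0_v"] = vec(sum(dh0pre, 1));
    }
  }

  // local encoder backward
  {
    std::vector<mat> dHcat(W);
    mat dmuW = zeros(size(le_mu_W)), dlvW = zeros(size(le_lv_W));
    vec dmub = zeros<vec>(le_mu_b.n_elem), dlvb = zeros<vec>(le_lv_b.n_elem);
    for (int t = 0; t < W; ++t) {
      mat dmu = dmu_l[t] + dz_l[t];
      mat dlv = (dlv_l[t] + dz_l[t] % eps_l.slice(t) % (0.5 * exp(0.5 * lv_l[t])))
                % lvl_mask[t];
      dHcat[t] = le_mu_W.t() * dmu + le_lv_W.t() * dlv;
      dmuW += dmu * Hcat[t].t(); dmub += sum(dmu, 1);
      dlvW += dlv * Hcat[t].t(); dlvb += sum(dlv, 1);
    }
    G["le_mu_W"] = dmuW; G["le_mu_b"] = dmub;
    G["le_lv_W"] = dlvW; G["le_lv_b"] = dlvb;

    std::vector<mat> dHf(W), dHb(W);
    for (int t = 0; t < W; ++t) {
      dHf[t] = dHcat[t].rows(0, H - 1);
      dHb[W - 1 - t] = dHcat[t].rows(H, 2 * H - 1);
    }
    GruGrad Gf, Gb;
    std::vector<mat> dInF, dInBrev;
    mat dh0f, dh0b;
    gruBwd(lf, Lin, h0l, Clf, dHf, Gf, dInF, dh0f);
    gruBwd(lb, LinRev, h0l, Clb, dHb, Gb, dInBrev, dh0b);
    Gf.emit(G, "le_f"); Gb.emit(G, "le_b");
    if (ctxInLocal) {
      for (int t = 0; t < W; ++t) {
        mat dIn = dInF[t] + dInBrev[W - 1 - t];
        dz_c += dIn.rows(N, N + CS - 1);
      }
    }
  }

  // context encoder backward
  if (hasCtx) {
    mat dmu_c = dz_c
      + (gamma / (double) B) * mu_c;
    mat dlv_c = (dz_c % eps_c % (0.5 * exp(0.5 * lv_c))
                 + (gamma / (double) B) * 0.5 * (exp(lv_c) - 1.0))
                % lvc_mask;
    mat feat = (ctx_arch == "rnn") ? Ucat : Ccv.P;
    G["ce_mu_W"] = mat(dmu_c * feat.t());
    G["ce_mu_b"] = vec(sum(dmu_c, 1));
    G["ce_lv_W"] = mat(dlv_c * feat.t());
    G["ce_lv_b"] = vec(sum(dlv_c, 1));
    mat dfeat = ce_mu_W.t() * dmu_c + ce_lv_W.t() * dlv_c;
    if (ctx_arch == "rnn") {
      const int Hc = (int) cf.Wh.n_cols;
      std::vector<mat> dHf(W, zeros(Hc, B)), dHb(W, zeros(Hc, B));
      dHf[W - 1] = dfeat.rows(0, Hc - 1);
      dHb[W - 1] = dfeat.rows(Hc, 2 * Hc - 1);
      std::vector<mat> Xrev(W);
      for (int t = 0; t < W; ++t) Xrev[t] = Xs[W - 1 - t];
      GruGrad Gf, Gb;
      std::vector<mat> dXF, dXB;
      mat dh0f, dh0b, h0 = zeros(Hc, B);
      gruBwd(cf, Xs, h0, Ccf, dHf, Gf, dXF, dh0f);
      gruBwd(cb, Xrev, h0, Ccb, dHb, Gb, dXB, dh0b);
      Gf.emit(G, "ce_f"); Gb.emit(G, "ce_b");
    } else {
      // conv arch: rebuild per-batch inputs
      std::vector<mat> Xb(B);
      for (int b = 0; b < B; ++b) Xb[b] = x.slice(b);
      convEncBwd(params, Xb, K, Ccv, dfeat, G);
    }
  }

  out["grads"] = G;
  return out;
}

// Forward-only encode: context posterior and (optionally) per-step local
// posteriors.  For the DSVAE the local encoder is conditioned on the context
// posterior mean (the deterministic embedding convention).

// [[Rcpp::export]]
List cpp_seq_encode(const List& params, const arma::cube& x,
                    const std::string& variant, const std::string& ctx_arch,
                    int conv_kernel, bool want_local) {
  const bool hasCtx = (variant != "lvae");
  const bool ctxInLocal = (variant == "dsvae");
  const int N = (int) x.n_rows, W = (int) x.n_cols, B = (int) x.n_slices;

  std::vector<mat> Xs;
  cubeToSteps(x, Xs);

  mat mu_c, lv_c, mask;
  if (hasCtx) {
    mat feat;
    if (ctx_arch == "rnn") {
      Gru cf = getGru(params, "ce_f"), cb = getGru(params, "ce_b");
      const int H = (int) cf.Wh.n_cols;
      mat h0 = zeros(H, B);
      std::vector<mat> Xrev(W);
      for (int t = 0; t < W; ++t) Xrev[t] = Xs[W - 1 - t];
      GruCache Cf, Cb;
      gruFwd(cf, Xs, h0, Cf);
      gruFwd(cb, Xrev, h0, Cb);
      feat = join_cols(Cf.h[W - 1], Cb.h[W - 1]);
    } else {
      std::vector<mat> Xb(B);
      for (int b = 0; b < B; ++b) Xb[b] = x.slice(b);
      ConvEncCache C;
      convEncFwd(params, Xb, conv_kernel, C);
      feat = C.P;
    }
    mu_c = getM(params, "ce_mu_W") * feat;
    mu_c.each_col() += getV(params, "ce_mu_b");
    mat raw = getM(params, "ce_lv_W") * feat;
    raw.each_col() += getV(params, "ce_lv_b");
    lv_c = clampLv(raw, mask);
  }

  List out = List::create(Named("ctx_mu") = mu_c, Named("ctx_lv") = lv_c);
  if (!want_local) return out;

  Gru lf = getGru(params, "le_f"), lb = getGru(params, "le_b");
  mat le_mu_W = getM(params, "le_mu_W"), le_lv_W = getM(params, "le_lv_W");
  vec le_mu_b = getV(params, "le_mu_b"), le_lv_b = getV(params, "le_lv_b");
  const int H = (int) lf.Wh.n_cols;
  const int LS = (int) le_mu_W.n_rows;

  std::vector<mat> Lin(W);
  for (int t = 0; t < W; ++t)
    Lin[t] = ctxInLocal ? join_cols(Xs[t], mu_c) : Xs[t];
  std::vector<mat> LinRev(W);
  for (int t = 0; t < W; ++t) LinRev[t] = Lin[W - 1 - t];
  GruCache Clf, Clb;
  mat h0l = zeros(H, B);
  gruFwd(lf, Lin, h0l, Clf);
  gruFwd(lb, LinRev, h0l, Clb);

  cube loc_mu(LS, B, W), loc_lv(LS, B, W);
  for (int t = 0; t < W; ++t) {
    mat Hcat = join_cols(Clf.h[t], Clb.h[W - 1 - t]);
    mat mu = le_mu_W * Hcat; mu.each_col() += le_mu_b;
    mat raw = le_lv_W * Hcat; raw.each_col() += le_lv_b;
    mat msk;
    loc_mu.slice(t) = mu;
    loc_lv.slice(t) = clampLv(raw, msk);
  }
  out["loc_mu"] = loc_mu;
  out["loc_lv"] = loc_lv;
  return out;
}

// ==================================================================== CVAE ==
// Convolutional context-only model: conv encoder -> z_c -> linear feature
// map -> conv decoder reconstructing the whole window.

// [[Rcpp::export]]
List cpp_cvae_step(const List& params, const arma::cube& x,
                   const arma::mat& eps_c, double gamma, int conv_kernel,
                   bool want_grads) {
  const int N = (int) x.n_rows, W = (int) x.n_cols, B = (int) x.n_slices;
  const int K = conv_kernel;

  std::vector<mat> Xb(B);
  for (int b = 0; b < B; ++b) Xb[b] = x.slice(b);

  ConvEncCache Ce;
  convEncFwd(params, Xb, K, Ce);
  mat ce_mu_W = getM(params, "ce_mu_W"), ce_lv_W = getM(params, "ce_lv_W");
  mat mu_c = ce_mu_W * Ce.P; mu_c.each_col() += getV(params, "ce_mu_b");
  mat raw = ce_lv_W * Ce.P; raw.each_col() += getV(params, "ce_lv_b");
  mat lvc_mask;
  mat lv_c = clampLv(raw, lvc_mask);
  mat z_c = mu_c + exp(0.5 * lv_c) % eps_c;

  mat de_W0 = getM(params, "de_W0"); vec de_b0 = getV(params, "de_b0");
  mat de_cv_W = getM(params, "de_cv_W"); vec de_cv_b = getV(params, "de_cv_b");
  const int Cd = (int) de_W0.n_rows / W;

  mat F0 = de_W0 * z_c; F0.each_col() += de_b0;     // (Cd*W) x B
  std::vector<mat> Mb(B), Ab(B), Xhat(B);
  double sse = 0.0;
  for (int b = 0; b < B; ++b) {
    Mb[b] = reshape(F0.col(b), Cd, W);
    Ab[b] = Mb[b] % (Mb[b] > 0);
    Xhat[b] = convFwd(de_cv_W, de_cv_b, Ab[b], K);
    sse += accu(square(Xhat[b] - Xb[b]));
  }
  double recon = 0.5 * sse / (double) (W * B) + 0.5 * N * LOG2PI;
  double context_kl =
    accu(0.5 * (exp(lv_c) + square(mu_c) - 1.0 - lv_c)) / (double) B;
  double total = recon + gamma * context_kl;

  List out = List::create(
    Named("reconstruction") = recon, Named("local_kl") = 0.0,
    Named("context_kl") = context_kl, Named("total") = total,
    Named("window_count") = B);
  if (!want_grads) return out;

  List G;
  mat dF0(size(F0));
  mat d_cv_W = zeros(size(de_cv_W));
  vec d_cv_b = zeros<vec>(de_cv_b.n_elem);
  for (int b = 0; b < B; ++b) {
    mat dXhat = (Xhat[b] - Xb[b]) / (double) (W * B);
    mat dA;
    convBwd(de_cv_W, Ab[b], dXhat, K, d_cv_W, d_cv_b, dA);
    mat dM = dA % (Mb[b] > 0);
    dF0.col(b) = vectorise(dM);
  }
  G["de_cv_W"] = d_cv_W; G["de_cv_b"] = d_cv_b;
  G["de_W0"] = mat(dF0 * z_c.t());
  G["de_b0"] = vec(sum(dF0, 1));
  mat dz_c = de_W0.t() * dF0;

  mat dmu_c = dz_c + (gamma / (double) B) * mu_c;
  mat dlv_c = (dz_c % eps_c % (0.5 * exp(0.5 * lv_c))
               + (gamma / (double) B) * 0.5 * (exp(lv_c) - 1.0)) % lvc_mask;
  G["ce_mu_W"] = mat(dmu_c * Ce.P.t());
  G["ce_mu_b"] = vec(sum(dmu_c, 1));
  G["ce_lv_W"] = mat(dlv_c * Ce.P.t());
  G["ce_lv_b"] = vec(sum(dlv_c, 1));
  mat dP = ce_mu_W.t() * dmu_c + ce_lv_W.t() * dlv_c;
  convEncBwd(params, Xb, K, Ce, dP, G);

  out["grads"] = G;
  return out;
}

// [[Rcpp::export]]
List cpp_cvae_encode(const List& params, const arma::cube& x,
                     int conv_kernel) {
  const int B = (int) x.n_slices;
  std::vector<mat> Xb(B);
  for (int b = 0; b < B; ++b) Xb[b] = x.slice(b);
  ConvEncCache Ce;
  convEncFwd(params, Xb, conv_kernel, Ce);
  mat mu_c = getM(params, "ce_mu_W") * Ce.P;
  mu_c.each_col() += getV(params, "ce_mu_b");
  mat raw = getM(params, "ce_lv_W") * Ce.P;
  raw.each_col() += getV(params, "ce_lv_b");
  mat mask;
  mat lv_c = clampLv(raw, mask);
  return List::create(Named("ctx_mu") = mu_c, Named("ctx_lv") = lv_c);
}
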