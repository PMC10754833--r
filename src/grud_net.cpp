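// Generator network: one-hot encoding -> sequential feature layer
// (linear, leaky ReLU, batch norm) -> stacked bidirectional GRU with
// residual skip-connections -> per-target linear heads -> softmax.
//
// Parameters live in one flat vector (non-owning arma views) so the
// optimiser on the R side can treat the model as a single theta vector.
// Forward caches activations; backward produces d(loss)/d(theta) given
// d(loss)/d(p_alt) supplied by the caller, so any loss expressed through
// the alternate-allele probability channel can drive training.
//
// Performance notes: the input-side GRU products (W * x_t for all t) are
// batched into one GEMM per layer by viewing the (dim, B, T) activation
// cube as a (dim, B*T) matrix; only the recurrent product (U * a_{t-1})
// stays inside the sequential loop, with the three gate matrices fused.
// Output heads are grouped by runs of targets sharing the same
// forward/backward anchor pair, giving one GEMM pair per anchor pair
// instead of one per target.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif

using namespace arma;
using Rcpp::List;
using Rcpp::XPtr;

// Non-owning views into one GRU layer's slab of the flat parameter vector.
// Constructed in place so writes through the views hit the flat vector.
struct GruView {
  mat Wz, Wr, Wh, Uz, Ur, Uh;
  vec bz, br, bh;
  GruView(double* p, uword H, uword din)
    : Wz(p, H, din, false, true),
      Wr(p + H * din, H, din, false, true),
      Wh(p + 2 * H * din, H, din, false, true),
      Uz(p + 3 * H * din, H, H, false, true),
      Ur(p + 3 * H * din + H * H, H, H, false, true),
      Uh(p + 3 * H * din + 2 * H * H, H, H, false, true),
      bz(p + 3 * H * din + 3 * H * H, H, false, true),
      br(p + 3 * H * din + 3 * H * H + H, H, false, true),
      bh(p + 3 * H * din + 3 * H * H + 2 * H, H, false, true) {}
};

class GrudNet {
public:
  uword T, F, H, L, U;
  double slope;
  uvec left, right; // per unobserved target: observed-sequence indices feeding it

  vec theta, grad;

  // batch-norm buffers (not optimised)
  vec bn_rmean, bn_rvar;
  double bn_eps, bn_momentum;
  long long bn_batches;

  // flat layout offsets
  uword off_Wf, off_bf, off_bng, off_bnb, off_gru, off_Wo, off_bo, ntheta;
  std::vector<uword> layer_off; // per layer, relative to off_gru (per direction block)
  uword dir_block;

  // head groups: runs of consecutive targets sharing (left, right)
  uvec grp_lo, grp_hi, grp_left, grp_right;

  // forward cache
  bool has_cache;
  uword B;
  mat Xc;                        // B x T alt-allele probabilities (0/1 for hard calls)
  cube lin;                      // F x B x T, feature linear pre-activation
  vec mu_c, var_c;               // normalisation stats used in cached forward
  bool used_batch_stats;
  cube feat;                     // F x B x T
  std::vector<cube> zc[2], rc[2], hcc[2], ac[2], qc[2];
  cube Sf, Sb;                   // H x B x T residual-summed top outputs
  mat Palt;                      // U x B
  mat WL, WR;                    // 2U x H stacked head weights of last forward
  // reusable workspaces (persist across calls to avoid allocator churn)
  cube act_b, dSf_b, dSb_b, dfeat_b, dlin_b, xhat_b;
  cube dGin_b, dGrec_b, dX_b, dX0_b, Xin_b, Scur_b, a_eval_b;
  mat z_tmp, r_tmp, hc_tmp, q_tmp;

  GrudNet(uword T_, uword F_, uword H_, uword L_, uword U_,
          const uvec& left_, const uvec& right_, double slope_)
    : T(T_), F(F_), H(H_), L(L_), U(U_), slope(slope_),
      left(left_), right(right_),
      bn_eps(1e-5), bn_momentum(0.1), bn_batches(0), has_cache(false) {
    off_Wf = 0;
    off_bf = off_Wf + F * 2;
    off_bng = off_bf + F;
    off_bnb = off_bng + F;
    off_gru = off_bnb + F;
    layer_off.resize(L);
    uword acc = 0;
    for (uword l = 0; l < L; ++l) {
      layer_off[l] = acc;
      uword din = (l == 0) ? F : H;
      acc += 3 * H * din + 3 * H * H + 3 * H;
    }
    dir_block = acc;
    off_Wo = off_gru + 2 * dir_block;
    off_bo = off_Wo + 2 * (2 * H) * U;
    ntheta = off_bo + 2 * U;
    theta.zeros(ntheta);
    grad.zeros(ntheta);
    bn_rmean.zeros(F);
    bn_rvar.ones(F);

    if (left.max() >= T || right.max() >= T)
      Rcpp::stop("target anchor index out of range");
    std::vector<uword> lo, hi;
    for (uword u = 0; u < U; ++u) {
      if (u == 0 || left(u) != left(u - 1) || right(u) != right(u - 1)) {
        lo.push_back(u);
        hi.push_back(u);
      } else hi.back() = u;
    }
    grp_lo = uvec(lo); grp_hi = uvec(hi);
    grp_left.set_size(grp_lo.n_elem);
    grp_right.set_size(grp_lo.n_elem);
    for (uword g = 0; g < grp_lo.n_elem; ++g) {
      grp_left(g) = left(grp_lo(g));
      grp_right(g) = right(grp_lo(g));
    }
  }

  // non-owning views ------------------------------------------------------
  mat vWf(vec& v) { return mat(v.memptr() + off_Wf, F, 2, false, true); }
  vec vbf(vec& v) { return vec(v.memptr() + off_bf, F, false, true); }
  vec vbng(vec& v) { return vec(v.memptr() + off_bng, F, false, true); }
  vec vbnb(vec& v) { return vec(v.memptr() + off_bnb, F, false, true); }
  cube vWo(vec& v) { return cube(v.memptr() + off_Wo, 2, 2 * H, U, false, true); }
  mat vbo(vec& v) { return mat(v.memptr() + off_bo, 2, U, false, true); }

  // GRU parameter block: Wz Wr Wh (H x Din), Uz Ur Uh (H x H), bz br bh (H)
  double* gru_base(vec& v, uword dir, uword l) {
    return v.memptr() + off_gru + dir * dir_block + layer_off[l];
  }
  GruView gru_views(vec& v, uword dir, uword l) {
    uword din = (l == 0) ? F : H;
    return GruView(gru_base(v, dir, l), H, din);
  }

  // stack the per-target head weights into 2U x H left/right blocks
  void stack_heads() {
    cube Wo = vWo(theta);
    WL.set_size(2 * U, H);
    WR.set_size(2 * U, H);
    for (uword u = 0; u < U; ++u) {
      WL.rows(2 * u, 2 * u + 1) = Wo.slice(u).cols(0, H - 1);
      WR.rows(2 * u, 2 * u + 1) = Wo.slice(u).cols(H, 2 * H - 1);
    }
  }

  // forward ---------------------------------------------------------------
  // X: B x T alt-allele probabilities in [0,1] (exact 0/1 for hard calls);
  // the one-hot encoding of entry x is (1-x, x). Returns alt-prob matrix
  // U x B, caches activations for backward.
  // logits_out: optional 2 x B x U cube receiver.
  mat forward(const mat& X, bool train, cube* logits_out = nullptr) {
    B = X.n_rows;
    Xc = X;
    mat Wf = vWf(theta);
    vec bf = vbf(theta), bng = vbng(theta), bnb = vbnb(theta);

    lin.set_size(F, B, T);
    for (uword t = 0; t < T; ++t) {
      vec xt = X.col(t);
      mat M = Wf.col(0) * (1.0 - xt).t() + Wf.col(1) * xt.t();
      M.each_col() += bf;
      lin.slice(t) = M;
    }
    // leaky ReLU
    cube& act = act_b;
    act.set_size(F, B, T);
    for (uword t = 0; t < T; ++t)
      act.slice(t) = arma::max(lin.slice(t), slope * lin.slice(t));

    // batch norm over (B * T) per channel
    double n = double(B) * double(T);
    vec s1(F, fill::zeros), s2(F, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      s1 += sum(act.slice(t), 1);
      s2 += sum(square(act.slice(t)), 1);
    }
    vec mu_b = s1 / n;
    vec var_b = s2 / n - square(mu_b);
    var_b = clamp(var_b, 0.0, datum::inf);
    used_batch_stats = train || bn_batches == 0;
    mu_c = used_batch_stats ? mu_b : bn_rmean;
    var_c = used_batch_stats ? var_b : bn_rvar;
    if (train) {
      double unb = (n > 1.5) ? n / (n - 1.0) : 1.0;
      bn_rmean = (1.0 - bn_momentum) * bn_rmean + bn_momentum * mu_b;
      bn_rvar = (1.0 - bn_momentum) * bn_rvar + bn_momentum * (var_b * unb);
      bn_batches++;
    }
    vec istd = 1.0 / sqrt(var_c + bn_eps);
    feat.set_size(F, B, T);
    for (uword t = 0; t < T; ++t) {
      mat M = act.slice(t);
      M.each_col() -= mu_c;
      M.each_col() %= istd % bng;
      M.each_col() += bnb;
      feat.slice(t) = M;
    }

    // bidirectional residual GRU stacks
    for (uword d = 0; d < 2; ++d) {
      if (zc[d].size() != L) {
        zc[d].resize(L); rc[d].resize(L); hcc[d].resize(L);
        ac[d].resize(L); qc[d].resize(L);
      }
      cube& S = Scur_b;
      S = feat;
      for (uword l = 0; l < L; ++l) {
        // only training needs per-layer activation caches for backward
        cube& a = train ? ac[d][l] : a_eval_b;
        a.set_size(H, B, T);
        gru_layer_forward(d, l, S, zc[d][l], rc[d][l], hcc[d][l], qc[d][l], a,
                          train);
        if (l == 0) S = a; else S += a;
      }
      if (d == 0) Sf = S; else Sb = S;
    }

    // grouped per-target heads + softmax
    stack_heads();
    mat bo = vbo(theta);
    vec bov(bo.memptr(), 2 * U, false, true);
    Palt.set_size(U, B);
    if (logits_out) logits_out->set_size(2, B, U);
    for (uword g = 0; g < grp_lo.n_elem; ++g) {
      uword u0 = grp_lo(g), u1 = grp_hi(g);
      uword r0 = 2 * u0, r1 = 2 * u1 + 1;
      mat logit = WL.rows(r0, r1) * Sf.slice(grp_left(g)) +
                  WR.rows(r0, r1) * Sb.slice(grp_right(g));
      logit.each_col() += bov.subvec(r0, r1);
      for (uword u = u0; u <= u1; ++u) {
        rowvec l0 = logit.row(2 * (u - u0));
        rowvec l1 = logit.row(2 * (u - u0) + 1);
        if (logits_out) {
          logits_out->slice(u).row(0) = l0;
          logits_out->slice(u).row(1) = l1;
        }
        rowvec m = arma::max(l0, l1);
        rowvec e0 = exp(l0 - m), e1 = exp(l1 - m);
        Palt.row(u) = e1 / (e0 + e1);
      }
    }
    has_cache = train;
    return Palt;
  }

  void gru_layer_forward(uword d, uword l, const cube& Xin,
                         cube& z, cube& r, cube& hc, cube& q, cube& a,
                         bool cache) {
    GruView P = gru_views(theta, d, l);
    uword din = (l == 0) ? F : H;
    if (cache) {
      z.set_size(H, B, T); r.set_size(H, B, T);
      hc.set_size(H, B, T); q.set_size(H, B, T);
    } else {
      z_tmp.set_size(H, B); r_tmp.set_size(H, B);
      hc_tmp.set_size(H, B); q_tmp.set_size(H, B);
    }
    mat Wall = join_cols(P.Wz, P.Wr, P.Wh);      // 3H x din
    mat Uall = join_cols(P.Uz, P.Ur, P.Uh);      // 3H x H
    const mat Xmat(const_cast<double*>(Xin.memptr()), din, B * T, false, true);
    mat Gin = Wall * Xmat;                       // 3H x BT, one GEMM
    Gin.rows(0, H - 1).each_col() += P.bz;
    Gin.rows(H, 2 * H - 1).each_col() += P.br;
    Gin.rows(2 * H, 3 * H - 1).each_col() += P.bh;
    mat R(3 * H, B);
    mat aprev(H, B, fill::zeros);
    for (uword step = 0; step < T; ++step) {
      uword t = (d == 0) ? step : (T - 1 - step);
      R = Uall * aprev;                          // 3H x B, one GEMM
      const mat G(Gin.colptr(t * B), 3 * H, B, false, true);
      // gate views writing straight into the caches (or scratch in eval)
      mat zt(cache ? z.slice_memptr(t) : z_tmp.memptr(), H, B, false, true);
      mat rt(cache ? r.slice_memptr(t) : r_tmp.memptr(), H, B, false, true);
      mat qt(cache ? q.slice_memptr(t) : q_tmp.memptr(), H, B, false, true);
      mat ht(cache ? hc.slice_memptr(t) : hc_tmp.memptr(), H, B, false, true);
      mat at(a.slice_memptr(t), H, B, false, true);
      zt = 1.0 / (1.0 + exp(-(G.rows(0, H - 1) + R.rows(0, H - 1))));
      rt = 1.0 / (1.0 + exp(-(G.rows(H, 2 * H - 1) + R.rows(H, 2 * H - 1))));
      qt = R.rows(2 * H, 3 * H - 1);
      ht = tanh(G.rows(2 * H, 3 * H - 1) + rt % qt);
      at = zt % ht + (1.0 - zt) % aprev;
      aprev = at;
    }
  }

  // backward --------------------------------------------------------------
  // dP: U x B gradient of the loss wrt alt probabilities.
  vec backward(const mat& dP) {
    if (!has_cache) Rcpp::stop("backward called without a cached forward pass");
    grad.zeros();
    cube gWo = vWo(grad);
    mat gbo = vbo(grad);
    vec gbov(gbo.memptr(), 2 * U, false, true);

    // heads: dlogit rows (-g, g) per target, grouped GEMMs
    mat Gd = dP % Palt % (1.0 - Palt);           // U x B
    mat DL(2 * U, B);
    for (uword u = 0; u < U; ++u) {
      DL.row(2 * u) = -Gd.row(u);
      DL.row(2 * u + 1) = Gd.row(u);
    }
    mat gWL(2 * U, H, fill::zeros), gWR(2 * U, H, fill::zeros);
    cube &dSf = dSf_b, &dSb = dSb_b;
    dSf.zeros(H, B, T);
    dSb.zeros(H, B, T);
    for (uword g = 0; g < grp_lo.n_elem; ++g) {
      uword r0 = 2 * grp_lo(g), r1 = 2 * grp_hi(g) + 1;
      const mat DLg = DL.rows(r0, r1);
      gWL.rows(r0, r1) = DLg * Sf.slice(grp_left(g)).t();
      gWR.rows(r0, r1) = DLg * Sb.slice(grp_right(g)).t();
      dSf.slice(grp_left(g)) += WL.rows(r0, r1).t() * DLg;
      dSb.slice(grp_right(g)) += WR.rows(r0, r1).t() * DLg;
    }
    gbov = sum(DL, 1);
    for (uword u = 0; u < U; ++u) {
      gWo.slice(u).cols(0, H - 1) = gWL.rows(2 * u, 2 * u + 1);
      gWo.slice(u).cols(H, 2 * H - 1) = gWR.rows(2 * u, 2 * u + 1);
    }

    cube& dfeat = dfeat_b;
    dfeat.zeros(F, B, T);
    for (uword d = 0; d < 2; ++d) {
      cube& dS = (d == 0) ? dSf : dSb;     // consumed in place
      cube& SL = (d == 0) ? Sf : Sb;       // rewound to lower layers in place
      for (uword l = L; l-- > 0;) {
        if (l > 0) {
          SL -= ac[d][l];                  // SL now holds s_(l-1)
          cube& dX = gru_layer_backward(d, l, SL, dS);
          dS += dX;
        } else {
          cube& dX = gru_layer_backward(d, l, feat, dS);
          dfeat += dX;
        }
      }
    }

    // batch norm backward
    vec bng = vbng(theta);
    vec istd = 1.0 / sqrt(var_c + bn_eps);
    double n = double(B) * double(T);
    cube& act = act_b;
    act.set_size(F, B, T);
    for (uword t = 0; t < T; ++t)
      act.slice(t) = arma::max(lin.slice(t), slope * lin.slice(t));
    vec gG = vbng(grad), gB = vbnb(grad);
    vec sum_d(F, fill::zeros), sum_dx(F, fill::zeros);
    cube& xhat = xhat_b;
    xhat.set_size(F, B, T);
    for (uword t = 0; t < T; ++t) {
      mat xh = act.slice(t);
      xh.each_col() -= mu_c;
      xh.each_col() %= istd;
      xhat.slice(t) = xh;
      sum_d += sum(dfeat.slice(t), 1);
      sum_dx += sum(dfeat.slice(t) % xh, 1);
    }
    gG += sum_dx;
    gB += sum_d;
    cube& dlin = dlin_b;
    dlin.set_size(F, B, T);
    for (uword t = 0; t < T; ++t) {
      mat dxh = dfeat.slice(t);
      dxh.each_col() %= bng;
      mat da;
      if (used_batch_stats) {
        da = dxh;
        da.each_col() -= (bng % sum_d) / n;
        da -= xhat.slice(t).each_col() % ((bng % sum_dx) / n);
        da.each_col() %= istd;
      } else {
        da = dxh.each_col() % istd;
      }
      // leaky ReLU backward
      mat m = conv_to<mat>::from(lin.slice(t) > 0.0);
      dlin.slice(t) = da % (m + slope * (1.0 - m));
    }
    mat gWf = vWf(grad);
    vec gbf = vbf(grad);
    for (uword t = 0; t < T; ++t) {
      const mat& dl = dlin.slice(t);
      vec xt = Xc.col(t);
      gWf.col(0) += dl * (1.0 - xt);
      gWf.col(1) += dl * xt;
      gbf += sum(dl, 1);
    }
    return grad;
  }

  cube& gru_layer_backward(uword d, uword l, const cube& Xin, const cube& dS) {
    GruView P = gru_views(theta, d, l);
    GruView G = gru_views(grad, d, l);
    const cube &z = zc[d][l], &r = rc[d][l], &hc = hcc[d][l], &q = qc[d][l],
               &a = ac[d][l];
    uword din = (l == 0) ? F : H;
    mat Wall = join_cols(P.Wz, P.Wr, P.Wh);
    mat Uall = join_cols(P.Uz, P.Ur, P.Uh);
    cube& dGin = dGin_b;   // gradients wrt input-side pre-activations
    cube& dGrec = dGrec_b; // gradients wrt recurrent-side products
    dGin.set_size(3 * H, B, T);
    dGrec.set_size(3 * H, B, T);
    mat dcarry(H, B, fill::zeros);
    mat zeros_a(H, B, fill::zeros);
    mat da(H, B), dh(H, B), UallT = Uall.t();
    for (uword step = T; step-- > 0;) {
      uword t = (d == 0) ? step : (T - 1 - step);
      uword tprev = (d == 0) ? (t - 1) : (t + 1); // valid only when step > 0
      const mat& aprev = (step == 0) ? zeros_a : a.slice(tprev);
      da = dS.slice(t);
      da += dcarry;
      const mat zt(const_cast<double*>(z.slice_memptr(t)), H, B, false, true);
      const mat rt(const_cast<double*>(r.slice_memptr(t)), H, B, false, true);
      const mat ht(const_cast<double*>(hc.slice_memptr(t)), H, B, false, true);
      const mat qt(const_cast<double*>(q.slice_memptr(t)), H, B, false, true);
      mat DR(dGrec.slice_memptr(t), 3 * H, B, false, true);
      mat DI(dGin.slice_memptr(t), 3 * H, B, false, true);
      mat dz = da % (ht - aprev) % zt % (1.0 - zt);
      dh = da % zt % (1.0 - square(ht));
      mat dr = dh % qt % rt % (1.0 - rt);
      DI.rows(0, H - 1) = dz;
      DI.rows(H, 2 * H - 1) = dr;
      DI.rows(2 * H, 3 * H - 1) = dh;
      DR.rows(0, H - 1) = std::move(dz);
      DR.rows(H, 2 * H - 1) = std::move(dr);
      DR.rows(2 * H, 3 * H - 1) = dh % rt;
      dcarry = da % (1.0 - zt);
      dcarry += UallT * DR;                       // one GEMM per step
    }
    const mat dGin_m(dGin.memptr(), 3 * H, B * T, false, true);
    const mat Xmat(const_cast<double*>(Xin.memptr()), din, B * T, false, true);
    const mat amat(const_cast<double*>(a.memptr()), H, B * T, false, true);
    const mat dGrec_m(dGrec.memptr(), 3 * H, B * T, false, true);
    mat gW_all = dGin_m * Xmat.t();              // one GEMM
    vec gb_all = sum(dGin_m, 1);
    mat gU_all(3 * H, H, fill::zeros);
    if (T > 1) {
      // pair each step's recurrent gradient with its a_{t-1}
      if (d == 0)
        gU_all = dGrec_m.cols(B, B * T - 1) * amat.cols(0, B * (T - 1) - 1).t();
      else
        gU_all = dGrec_m.cols(0, B * (T - 1) - 1) * amat.cols(B, B * T - 1).t();
    }
    G.Wz += gW_all.rows(0, H - 1);
    G.Wr += gW_all.rows(H, 2 * H - 1);
    G.Wh += gW_all.rows(2 * H, 3 * H - 1);
    G.Uz += gU_all.rows(0, H - 1);
    G.Ur += gU_all.rows(H, 2 * H - 1);
    G.Uh += gU_all.rows(2 * H, 3 * H - 1);
    G.bz += gb_all.subvec(0, H - 1);
    G.br += gb_all.subvec(H, 2 * H - 1);
    G.bh += gb_all.subvec(2 * H, 3 * H - 1);
    cube& dX = (l == 0) ? dX0_b : dX_b;
    dX.set_size(din, B, T);
    mat dXm(dX.memptr(), din, B * T, false, true);
    dXm = Wall.t() * dGin_m;                     // one GEMM
    return dX;
  }
};

// [[Rcpp::export]]
SEXP grud_net_create(int T, int F, int H, int L, int U,
                     Rcpp::IntegerVector left, Rcpp::IntegerVector right,
                     double slope) {
  uvec lv(U), rv(U);
  for (int u = 0; u < U; ++u) {
    if (left[u] < 0 || right[u] < 0 || left[u] >= T || right[u] >= T)
      Rcpp::stop("anchor index out of range");
    lv(u) = left[u]; rv(u) = right[u];
  }
#ifdef __GLIBC__
  // the training loop cycles multi-megabyte activation caches every batch;
  // keep them on the heap instead of mmap/munmap round trips
  static bool allocator_tuned = [] {
    mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
    return true;
  }();
  (void)allocator_tuned;
#endif
  XPtr<GrudNet> p(new GrudNet(T, F, H, L, U, lv, rv, slope), true);
  return p;
}

// [[Rcpp::export]]
int grud_net_nparams(SEXP ptr) {
  XPtr<GrudNet> p(ptr);
  return int(p->ntheta);
}

// [[Rcpp::export]]
Rcpp::NumericVector grud_net_get_theta(SEXP ptr) {
  XPtr<GrudNet> p(ptr);
  return Rcpp::wrap(p->theta);
}

// [[Rcpp::export]]
void grud_net_set_theta(SEXP ptr, Rcpp::NumericVector th) {
  XPtr<GrudNet> p(ptr);
  if (uword(th.size()) != p->ntheta) Rcpp::stop("theta length mismatch");
  std::copy(th.begin(), th.end(), p->theta.memptr());
}

// [[Rcpp::export]]
List grud_net_get_bn(SEXP ptr) {
  XPtr<GrudNet> p(ptr);
  return List::create(Rcpp::Named("mean") = Rcpp::wrap(p->bn_rmean),
                      Rcpp::Named("var") = Rcpp::wrap(p->bn_rvar),
                      Rcpp::Named("batches") = double(p->bn_batches));
}

// [[Rcpp::export]]
void grud_net_set_bn(SEXP ptr, Rcpp::NumericVector mean, Rcpp::NumericVector var,
                     double batches) {
  XPtr<GrudNet> p(ptr);
  std::copy(mean.begin(), mean.end(), p->bn_rmean.memptr());
  std::copy(var.begin(), var.end(), p->bn_rvar.memptr());
  p->bn_batches = (long long)batches;
}

// [[Rcpp::export]]
List grud_net_forward(SEXP ptr, Rcpp::NumericMatrix X, bool train,
                      bool want_logits = false) {
  XPtr<GrudNet> p(ptr);
  mat Xm(X.begin(), X.nrow(), X.ncol(), true);
  if (uword(X.ncol()) != p->T) Rcpp::stop("input has wrong number of variants");
  if (Xm.has_nan() || Xm.min() < 0.0 || Xm.max() > 1.0)
    Rcpp::stop("input allele probabilities must lie in [0, 1]");
  cube logits;
  mat P = p->forward(Xm, train, want_logits ? &logits : nullptr);
  List out = List::create(Rcpp::Named("p_alt") = Rcpp::wrap(mat(P.t())));
  if (want_logits) out["logits"] = Rcpp::wrap(logits);
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector grud_net_backward(SEXP ptr, Rcpp::NumericMatrix dP) {
  XPtr<GrudNet> p(ptr);
  mat d(dP.begin(), dP.nrow(), dP.ncol(), true);
  return Rcpp::wrap(p->backward(mat(d.t())));
}
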