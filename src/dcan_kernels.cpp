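// Compute kernels for the sequence model: LSTM and multi-head scaled
// dot-product attention, forward and backward. Sequences are passed as
// (B*T) x D matrices in batch-major row order (row = b*T + t, 0-based).
// Backward passes consume the caches produced by the forward passes;
// gradient correctness is checked against finite differences in the
// package test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Layout conversion: R passes sequences batch-major (row = b*T + t);
// the recurrence kernels work time-major (row = t*B + b) so each
// timestep is a contiguous B-row block and the per-step GEMMs need no
// strided gathers.
static arma::mat to_time_major(const arma::mat& X, int B, int T) {
  arma::mat out(X.n_rows, X.n_cols);
  for (int bi = 0; bi < B; ++bi)
    for (int t = 0; t < T; ++t)
      out.row(t * B + bi) = X.row(bi * T + t);
  return out;
}
static arma::mat to_batch_major(const arma::mat& X, int B, int T) {
  arma::mat out(X.n_rows, X.n_cols);
  for (int bi = 0; bi < B; ++bi)
    for (int t = 0; t < T; ++t)
      out.row(bi * T + t) = X.row(t * B + bi);
  return out;
}

// Gate layout in the 4h-wide pre-activation: [input, forget, cell, output].
// Returns H batch-major for the R layers plus time-major caches (Ht, C, G)
// consumed by the backward kernel.
// [[Rcpp::export(name = ".lstm_forward_cpp")]]
List lstm_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                      const arma::mat& Wh, const arma::rowvec& b,
                      int B, int T, bool reverse) {
  const int h = Wh.n_rows;
  arma::mat Xm = to_time_major(X, B, T);
  arma::mat Hm(B * T, h), Cm(B * T, h), Gm(B * T, 4 * h);
  arma::mat Hprev(B, h, arma::fill::zeros);
  arma::mat Cprev(B, h, arma::fill::zeros);
  // input-side projections for every timestep in one GEMM
  arma::mat XW = Xm * Wx;
  XW.each_row() += b;

  for (int s = 0; s < T; ++s) {
    const int t = reverse ? (T - 1 - s) : s;
    const int r0 = t * B, r1 = t * B + B - 1;
    arma::mat Z = XW.rows(r0, r1) + Hprev * Wh;
    Gm.submat(r0, 0, r1, h - 1) =
        1.0 / (1.0 + arma::exp(-Z.cols(0, h - 1)));
    Gm.submat(r0, h, r1, 2 * h - 1) =
        1.0 / (1.0 + arma::exp(-Z.cols(h, 2 * h - 1)));
    Gm.submat(r0, 2 * h, r1, 3 * h - 1) =
        arma::tanh(Z.cols(2 * h, 3 * h - 1));
    Gm.submat(r0, 3 * h, r1, 4 * h - 1) =
        1.0 / (1.0 + arma::exp(-Z.cols(3 * h, 4 * h - 1)));
    Cm.rows(r0, r1) = Gm.submat(r0, h, r1, 2 * h - 1) % Cprev +
        Gm.submat(r0, 0, r1, h - 1) % Gm.submat(r0, 2 * h, r1, 3 * h - 1);
    Hm.rows(r0, r1) = Gm.submat(r0, 3 * h, r1, 4 * h - 1) %
        arma::tanh(Cm.rows(r0, r1));
    Hprev = Hm.rows(r0, r1);
    Cprev = Cm.rows(r0, r1);
  }
  return List::create(_["H"] = to_batch_major(Hm, B, T), _["Ht"] = Hm,
                      _["C"] = Cm, _["G"] = Gm);
}

// [[Rcpp::export(name = ".lstm_backward_cpp")]]
List lstm_backward_cpp(const arma::mat& dH, const arma::mat& X,
                       const arma::mat& Wx, const arma::mat& Wh,
                       const arma::mat& Ht, const arma::mat& C,
                       const arma::mat& G, int B, int T, bool reverse) {
  const int h = Wh.n_rows;
  const int D = Wx.n_rows;
  arma::mat Xm = to_time_major(X, B, T);
  arma::mat dHm = to_time_major(dH, B, T);
  arma::mat dZm(B * T, 4 * h);
  arma::mat dWh(h, 4 * h, arma::fill::zeros);
  arma::mat dHnext(B, h, arma::fill::zeros);
  arma::mat dCnext(B, h, arma::fill::zeros);

  for (int s = T - 1; s >= 0; --s) {
    const int t = reverse ? (T - 1 - s) : s;
    const int tprev = reverse ? (t + 1) : (t - 1);
    const bool has_prev = (s > 0);
    const int r0 = t * B, r1 = t * B + B - 1;
    const int p0 = has_prev ? tprev * B : 0;
    const int p1 = has_prev ? tprev * B + B - 1 : B - 1;

    arma::mat gi = G.submat(r0, 0, r1, h - 1);
    arma::mat gf = G.submat(r0, h, r1, 2 * h - 1);
    arma::mat gg = G.submat(r0, 2 * h, r1, 3 * h - 1);
    arma::mat go = G.submat(r0, 3 * h, r1, 4 * h - 1);
    arma::mat tc = arma::tanh(C.rows(r0, r1));
    arma::mat dh = dHm.rows(r0, r1) + dHnext;
    arma::mat dgo = dh % tc;
    arma::mat dc = dCnext + dh % go % (1.0 - tc % tc);
    arma::mat dgi = dc % gg;
    arma::mat dgf = has_prev ? arma::mat(dc % C.rows(p0, p1))
                             : arma::mat(B, h, arma::fill::zeros);
    arma::mat dgg = dc % gi;
    dCnext = dc % gf;

    arma::mat dZ(B, 4 * h);
    dZ.cols(0, h - 1) = dgi % gi % (1.0 - gi);
    dZ.cols(h, 2 * h - 1) = dgf % gf % (1.0 - gf);
    dZ.cols(2 * h, 3 * h - 1) = dgg % (1.0 - gg % gg);
    dZ.cols(3 * h, 4 * h - 1) = dgo % go % (1.0 - go);

    dZm.rows(r0, r1) = dZ;
    if (has_prev) dWh += Ht.rows(p0, p1).t() * dZ;
    dHnext = dZ * Wh.t();
  }
  // input-side gradients in single GEMMs over all timesteps
  arma::mat dXm = dZm * Wx.t();
  arma::mat dWx = Xm.t() * dZm;
  arma::rowvec db = arma::sum(dZm, 0);
  return List::create(_["dX"] = to_batch_major(dXm, B, T), _["dWx"] = dWx,
                      _["dWh"] = dWh, _["db"] = db);
}

// Exact GELU x * Phi(x) with the CDF returned for the backward pass.
// [[Rcpp::export(name = ".gelu_fwd_cpp")]]
List gelu_fwd_cpp(const arma::mat& X) {
  arma::mat Phi = 0.5 * arma::erfc(-X / std::sqrt(2.0));
  return List::create(_["Y"] = X % Phi, _["Phi"] = Phi);
}

// [[Rcpp::export(name = ".gelu_bwd_cpp")]]
arma::mat gelu_bwd_cpp(const arma::mat& dY, const arma::mat& X,
                       const arma::mat& Phi) {
  const double inv_sqrt_2pi = 0.3989422804014327;
  return dY % (Phi + X % (inv_sqrt_2pi * arma::exp(-0.5 * X % X)));
}

// Multi-head scaled dot-product attention over already-projected Q, K, V.
// mask(b, t) == 0 marks a padded timestep: it is never attended to as a
// key, and a padded query row yields a zero output row. causal == true
// additionally forbids keys j > i. Rows whose key set is empty produce
// zeros (the documented fully-masked convention).
// [[Rcpp::export(name = ".mha_forward_cpp")]]
List mha_forward_cpp(const arma::mat& Q, const arma::mat& K,
                     const arma::mat& V, int B, int T, int nh,
                     bool causal, const arma::mat& mask) {
  const int h = Q.n_cols;
  const int dk = h / nh;
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::mat O(B * T, h, arma::fill::zeros);
  arma::cube A(T, T, B * nh, arma::fill::zeros);

  for (int bi = 0; bi < B; ++bi) {
    for (int hd = 0; hd < nh; ++hd) {
      arma::mat Qs = Q.submat(bi * T, hd * dk, bi * T + T - 1, (hd + 1) * dk - 1);
      arma::mat Ks = K.submat(bi * T, hd * dk, bi * T + T - 1, (hd + 1) * dk - 1);
      arma::mat Vs = V.submat(bi * T, hd * dk, bi * T + T - 1, (hd + 1) * dk - 1);
      arma::mat S = scale * (Qs * Ks.t());
      arma::mat Ah(T, T, arma::fill::zeros);
      for (int i = 0; i < T; ++i) {
        if (mask(bi, i) == 0) continue;  // padded query: zero output row
        double mx = -arma::datum::inf;
        for (int j = 0; j < T; ++j) {
          const bool ok = mask(bi, j) != 0 && (!causal || j <= i);
          if (ok && S(i, j) > mx) mx = S(i, j);
        }
        if (!std::isfinite(mx)) continue;  // fully masked row
        double denom = 0.0;
        for (int j = 0; j < T; ++j) {
          const bool ok = mask(bi, j) != 0 && (!causal || j <= i);
          if (ok) {
            Ah(i, j) = std::exp(S(i, j) - mx);
            denom += Ah(i, j);
          }
        }
        for (int j = 0; j < T; ++j) Ah(i, j) /= denom;
      }
      O.submat(bi * T, hd * dk, bi * T + T - 1, (hd + 1) * dk - 1) = Ah * Vs;
      A.slice(bi * nh + hd) = Ah;
    }
  }
  return List::create(_["O"] = O, _["A"] = A);
}

// [[Rcpp::export(name = ".mha_backward_cpp")]]
List mha_backward_cpp(const arma::mat& dO, const arma::mat& Q,
                      const arma::mat& K, const arma::mat& V,
                      const arma::cube& A, int B, int T, int nh) {
  const int h = Q.n_cols;
  const int dk = h / nh;
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::mat dQ(B * T, h, arma::fill::zeros);
  arma::mat dK(B * T, h, arma::fill::zeros);
  arma::mat dV(B * T, h, arma::fill::zeros);

  for (int bi = 0; bi < B; ++bi) {
    for (int hd = 0; hd < nh; ++hd) {
      arma::mat Qs = Q.submat(bi * T, hd * dk, bi * T + T - 1, (hd + 1) * dk - 1);
      arma::mat Ks = K.submat(bi * T, hd * dk, bi * T + T - 1, (hd + 1) * dk - 1);
      arma::mat Vs = V.submat(bi * T, hd * dk, bi * T + T - 1, (hd + 1) * dk - 1);
      arma::mat dOs = dO.submat(bi * T, hd * dk, bi * T + T - 1, (hd + 1) * dk - 1);
      const arma::mat& Ah = A.slice(bi * nh + hd);

      arma::mat dA = dOs * Vs.t();
      arma::mat dVs = Ah.t() * dOs;
      arma::mat dS(T, T, arma::fill::zeros);
      for (int i = 0; i < T; ++i) {
        const double dot = arma::dot(dA.row(i), Ah.row(i));
        dS.row(i) = Ah.row(i) % (dA.row(i) - dot);
      }
      dQ.submat(bi * T, hd * dk, bi * T + T - 1, (hd + 1) * dk - 1) =
          scale * (dS * Ks);
      dK.submat(bi * T, hd * dk, bi * T + T - 1, (hd + 1) * dk - 1) =
          scale * (dS.t() * Qs);
      dV.submat(bi * T, hd * dk, bi * T + T - 1, (hd + 1) * dk - 1) = dVs;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
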