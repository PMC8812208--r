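// Training loop for the skip-connection multilayer perceptron.
//
// The network maps a sparse per-patient feature vector x (quarterly one-hot
// code counts plus numeric features) through n_hidden ReLU layers of width h;
// the last hidden vector is concatenated with the raw input and fed to a
// linear output layer with k outputs (one per cost category).  With
// n_hidden = 0 the model degenerates to a plain linear map, which is how the
// stochastic-gradient ridge solver reuses this loop (l2 penalty `lambda` on
// the weights, bias unpenalized).
//
// Optimisation: ADAM, global gradient-norm clipping, inverted dropout on the
// hidden activations only (never on the raw-input skip branch), minibatches
// drawn in a freshly shuffled order each epoch.  All randomness (shuffle,
// dropout masks) comes from R's RNG so results are reproducible from
// set.seed() on the R side.  Single-threaded by construction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Extract columns idx of a sparse matrix (arma lacks non-contiguous sparse
// submatrix views).  Xt is stored features x patients so a minibatch is a
// set of columns.
static sp_mat take_cols(const sp_mat& Xt, const uvec& idx) {
  uword total = 0;
  for (uword k = 0; k < idx.n_elem; ++k)
    total += Xt.col_ptrs[idx[k] + 1] - Xt.col_ptrs[idx[k]];
  umat locs(2, total);
  vec vals(total);
  uword pos = 0;
  for (uword k = 0; k < idx.n_elem; ++k) {
    for (sp_mat::const_col_iterator it = Xt.begin_col(idx[k]);
         it != Xt.end_col(idx[k]); ++it) {
      locs(0, pos) = it.row();
      locs(1, pos) = k;
      vals(pos) = *it;
      ++pos;
    }
  }
  return sp_mat(locs, vals, Xt.n_rows, idx.n_elem);
}

// Fisher-Yates shuffle driven by R's RNG.
static uvec r_shuffle(uword n) {
  uvec out = regspace<uvec>(0, n - 1);
  for (uword i = n - 1; i > 0; --i) {
    uword j = (uword)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(out[i], out[j]);
  }
  return out;
}

struct Adam {
  mat m, v;
  void init(uword r, uword c) { m.zeros(r, c); v.zeros(r, c); }
  void step(mat& w, const mat& g, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * square(g);
    double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    w -= (lr / c1) * (m / (sqrt(v / c2) + eps));
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_train_skipmlp(const arma::sp_mat& Xt,
                             const arma::mat& Y,
                             Rcpp::List weights,
                             double lr,
                             double clip,
                             int epochs,
                             int batch,
                             double dropout,
                             double lambda) {
  const uword n = Xt.n_cols, p = Xt.n_rows, k = Y.n_cols;
  if (Y.n_rows != n) Rcpp::stop("X and Y are not row-aligned");

  Rcpp::List Wh_in = weights["W_hidden"];   // list: [p x h, h x h, ...]
  Rcpp::List bh_in = weights["b_hidden"];
  const uword L = Wh_in.size();
  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  for (uword l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(Wh_in[l]);
    b[l] = Rcpp::as<rowvec>(bh_in[l]);
  }
  mat W_top = L > 0 ? Rcpp::as<mat>(weights["W_top"]) : mat();
  mat W_skip = Rcpp::as<mat>(weights["W_skip"]);      // p x k
  rowvec b_out = Rcpp::as<rowvec>(weights["b_out"]);

  std::vector<Adam> aW(L), ab(L);
  for (uword l = 0; l < L; ++l) {
    aW[l].init(W[l].n_rows, W[l].n_cols);
    ab[l].init(1, b[l].n_elem);
  }
  Adam aTop, aSkip, aBout;
  if (L > 0) aTop.init(W_top.n_rows, W_top.n_cols);
  aSkip.init(p, k);
  aBout.init(1, k);

  const double keep = 1.0 - dropout;
  double t = 0.0;
  vec loss_hist(std::max(epochs, 0), fill::zeros);

  Rcpp::RNGScope rng;

  std::vector<mat> Z(L), H(L), M(L), dZ(L), gW(L);
  std::vector<rowvec> gb(L);
  mat Out, E, dOut, gTop, gSkip;
  rowvec gBout;

  for (int ep = 0; ep < epochs; ++ep) {
    uvec ord = r_shuffle(n);
    double ep_loss = 0.0;
    uword nb = 0;
    for (uword start = 0; start < n; start += batch) {
      uword stop = std::min<uword>(start + batch - 1, n - 1);
      uvec idx = ord.subvec(start, stop);
      const double bsz = (double)idx.n_elem;
      sp_mat Xb = take_cols(Xt, idx);            // p x b
      mat Yb = Y.rows(idx);

      // forward
      const mat* prev = nullptr;
      for (uword l = 0; l < L; ++l) {
        if (l == 0) Z[0] = mat(Xb.t() * W[0]);
        else        Z[l] = (*prev) * W[l];
        Z[l].each_row() += b[l];
        H[l] = clamp(Z[l], 0.0, datum::inf);
        if (dropout > 0.0) {
          M[l].set_size(H[l].n_rows, H[l].n_cols);
          for (uword q = 0; q < M[l].n_elem; ++q)
            M[l][q] = (unif_rand() < keep) ? 1.0 / keep : 0.0;
          H[l] %= M[l];
        }
        prev = &H[l];
      }
      Out = mat(Xb.t() * W_skip);
      if (L > 0) Out += H[L - 1] * W_top;
      Out.each_row() += b_out;

      E = Out - Yb;
      double loss = accu(square(E)) / bsz;
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
      ep_loss += loss;
      ++nb;

      // backward
      dOut = (2.0 / bsz) * E;
      gSkip = mat(Xb * dOut);                    // p x k
      gBout = sum(dOut, 0);
      if (lambda > 0.0) gSkip += 2.0 * lambda * W_skip;
      if (L > 0) {
        gTop = H[L - 1].t() * dOut;
        if (lambda > 0.0) gTop += 2.0 * lambda * W_top;
        mat dH = dOut * W_top.t();
        for (uword l = L; l-- > 0;) {
          dZ[l] = dH;
          if (dropout > 0.0) dZ[l] %= M[l];
          dZ[l] %= conv_to<mat>::from(Z[l] > 0.0);
          gb[l] = sum(dZ[l], 0);
          if (l == 0) gW[0] = mat(Xb * dZ[0]);
          else        gW[l] = H[l - 1].t() * dZ[l];
          if (lambda > 0.0) gW[l] += 2.0 * lambda * W[l];
          if (l > 0) dH = dZ[l] * W[l].t();
        }
      }

      // global gradient-norm clipping
      if (clip > 0.0) {
        double sq = accu(square(gSkip)) + accu(square(gBout));
        if (L > 0) sq += accu(square(gTop));
        for (uword l = 0; l < L; ++l)
          sq += accu(square(gW[l])) + accu(square(gb[l]));
        double nrm = std::sqrt(sq);
        if (nrm > clip) {
          double s = clip / nrm;
          gSkip *= s; gBout *= s;
          if (L > 0) gTop *= s;
          for (uword l = 0; l < L; ++l) { gW[l] *= s; gb[l] *= s; }
        }
      }

      t += 1.0;
      aSkip.step(W_skip, gSkip, lr, t);
      { mat bo = b_out; aBout.step(bo, gBout, lr, t); b_out = bo.row(0); }
      if (L > 0) aTop.step(W_top, gTop, lr, t);
      for (uword l = 0; l < L; ++l) {
        aW[l].step(W[l], gW[l], lr, t);
        mat bl = b[l]; ab[l].step(bl, gb[l], lr, t); b[l] = bl.row(0);
      }
    }
    loss_hist[ep] = ep_loss / std::max<uword>(nb, 1);
  }

  Rcpp::List Wh_out(L), bh_out(L);
  for (uword l = 0; l < L; ++l) {
    Wh_out[l] = W[l];
    bh_out[l] = Rcpp::wrap(b[l]);
  }
  return Rcpp::List::create(
    Rcpp::Named("W_hidden") = Wh_out,
    Rcpp::Named("b_hidden") = bh_out,
    Rcpp::Named("W_top") = W_top,
    Rcpp::Named("W_skip") = W_skip,
    Rcpp::Named("b_out") = Rcpp::wrap(b_out),
    Rcpp::Named("loss") = loss_hist);
}
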