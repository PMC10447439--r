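// ConvBiLSTM per-node sequence classifier: four 1-D convolution layers
// ('same' padding, stride 1, ReLU) feeding one bidirectional LSTM whose
// forward/backward hidden states are combined linearly into per-node
// softmax scores over the label classes.  Trained with Adam on the
// categorical cross-entropy, full BPTT, batch-averaged gradients.
//
// Minibatches are processed as batched matrix operations: the conv stack
// works on (nb*L x C) row-block matrices (one GEMM per layer) and the
// LSTM recurrences on (H x nb) slabs per timestep, so the per-sample
// work is BLAS-bound rather than loop-bound.
//
// All randomness (initial weights, shuffle orders) is supplied by the R
// caller, so given identical inputs these routines are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const char *PARAM_NAMES[] = {
  "W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4",
  "Wx_f", "Wh_f", "b_f", "Wx_b", "Wh_b", "b_b",
  "Wy_f", "Wy_b", "b_y"};
const int N_PARAMS = 17;
const int N_CONV = 4;

std::vector<mat> unpack_params(const Rcpp::List &params) {
  std::vector<mat> P;
  P.reserve(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i)
    P.push_back(Rcpp::as<mat>(params[PARAM_NAMES[i]]));
  return P;
}

Rcpp::List pack_params(const std::vector<mat> &P) {
  Rcpp::List out(N_PARAMS);
  Rcpp::CharacterVector nm(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i) {
    out[i] = P[i];
    nm[i] = PARAM_NAMES[i];
  }
  out.attr("names") = nm;
  return out;
}

// gather k zero-padded shifts of each beat's L x C block into the
// corresponding rows of M ((nb*L) x (k*C)); column block o holds the
// input shifted by o - pad rows (within-beat, no bleed across beats)
mat im2col_blocks(const mat &S, int k, int L, int nb) {
  const int C = S.n_cols, pad = (k - 1) / 2;
  mat M(S.n_rows, k * C, fill::zeros);
  for (int b = 0; b < nb; ++b) {
    const int base = b * L;
    for (int o = 0; o < k; ++o) {
      int d = o - pad;  // source row = dest row + d
      int r0 = std::max(0, -d), r1 = std::min(L, L - d);
      if (r1 > r0)
        M.submat(base + r0, o * C, base + r1 - 1, o * C + C - 1) =
          S.rows(base + r0 + d, base + r1 - 1 + d);
    }
  }
  return M;
}

void col2im_blocks_accum(const mat &dM, int k, int L, int nb, mat &dS) {
  const int C = dS.n_cols, pad = (k - 1) / 2;
  for (int b = 0; b < nb; ++b) {
    const int base = b * L;
    for (int o = 0; o < k; ++o) {
      int d = o - pad;
      int r0 = std::max(0, -d), r1 = std::min(L, L - d);
      if (r1 > r0)
        dS.rows(base + r0 + d, base + r1 - 1 + d) +=
          dM.submat(base + r0, o * C, base + r1 - 1, o * C + C - 1);
    }
  }
}

inline mat sigmoid(const mat &a) { return 1.0 / (1.0 + exp(-a)); }

struct LstmCache {
  cube i, f, g, o, c, tc, h;  // each H x nb x L
};

// one LSTM direction over the batched inputs Xs (C x nb x L);
// reverse = scan right-to-left
LstmCache lstm_forward(const cube &Xs, const mat &Wx, const mat &Wh,
                       const vec &b, bool reverse) {
  const int nb = Xs.n_cols, L = Xs.n_slices, H = Wh.n_cols;
  LstmCache cc;
  cc.i.set_size(H, nb, L); cc.f.set_size(H, nb, L);
  cc.g.set_size(H, nb, L); cc.o.set_size(H, nb, L);
  cc.c.set_size(H, nb, L); cc.tc.set_size(H, nb, L);
  cc.h.set_size(H, nb, L);
  mat h(H, nb, fill::zeros), c(H, nb, fill::zeros);
  for (int s = 0; s < L; ++s) {
    int t = reverse ? L - 1 - s : s;
    mat A = Wx * Xs.slice(t) + Wh * h;
    A.each_col() += b;
    mat ig = sigmoid(A.rows(0, H - 1));
    mat fg = sigmoid(A.rows(H, 2 * H - 1));
    mat gg = tanh(A.rows(2 * H, 3 * H - 1));
    mat og = sigmoid(A.rows(3 * H, 4 * H - 1));
    c = fg % c + ig % gg;
    mat tc = tanh(c);
    h = og % tc;
    cc.i.slice(t) = ig; cc.f.slice(t) = fg; cc.g.slice(t) = gg;
    cc.o.slice(t) = og; cc.c.slice(t) = c; cc.tc.slice(t) = tc;
    cc.h.slice(t) = h;
  }
  return cc;
}

// BPTT through one direction; dH (H x nb x L) is dLoss/dh_t; accumulates
// parameter grads and dLoss/dXs
void lstm_backward(const cube &Xs, const mat &Wx, const mat &Wh,
                   const LstmCache &cc, const cube &dH, bool reverse,
                   mat &dWx, mat &dWh, vec &db, cube &dXs) {
  const int nb = Xs.n_cols, L = Xs.n_slices, H = Wh.n_cols;
  mat dh_next(H, nb, fill::zeros), dc_next(H, nb, fill::zeros);
  mat da(4 * H, nb);
  for (int s = L - 1; s >= 0; --s) {
    int t = reverse ? L - 1 - s : s;
    int t_prev = reverse ? t + 1 : t - 1;
    bool has_prev = reverse ? (t + 1 < L) : (t - 1 >= 0);
    mat dh = dH.slice(t) + dh_next;
    mat dog = dh % cc.tc.slice(t);
    mat dc = dh % cc.o.slice(t) % (1.0 - square(cc.tc.slice(t))) + dc_next;
    mat dig = dc % cc.g.slice(t);
    mat dgg = dc % cc.i.slice(t);
    mat dfg = has_prev ? mat(dc % cc.c.slice(t_prev))
                       : mat(H, nb, fill::zeros);
    dc_next = dc % cc.f.slice(t);
    da.rows(0, H - 1)         = dig % cc.i.slice(t) % (1.0 - cc.i.slice(t));
    da.rows(H, 2 * H - 1)     = dfg % cc.f.slice(t) % (1.0 - cc.f.slice(t));
    da.rows(2 * H, 3 * H - 1) = dgg % (1.0 - square(cc.g.slice(t)));
    da.rows(3 * H, 4 * H - 1) = dog % cc.o.slice(t) % (1.0 - cc.o.slice(t));
    dWx += da * Xs.slice(t).t();
    if (has_prev) dWh += da * cc.h.slice(t_prev).t();
    db += sum(da, 1);
    dh_next = Wh.t() * da;
    dXs.slice(t) += Wx.t() * da;
  }
}

struct ForwardCache {
  std::vector<mat> M;   // im2col inputs per conv layer
  std::vector<mat> S;   // activations: S[0] = input, S[1..4] conv outputs
  cube Xs;              // LSTM input, C4 x nb x L
  LstmCache fwd, bwd;
  cube prob;            // K x nb x L softmax output
};

// forward pass over a batch; rows of Xb are beats
ForwardCache forward_batch(const mat &Xb, const std::vector<mat> &P,
                           int k, int K) {
  const int nb = Xb.n_rows, L = Xb.n_cols;
  ForwardCache fc;
  fc.S.resize(N_CONV + 1);
  fc.M.resize(N_CONV);
  fc.S[0] = mat(vectorise(Xb.t()));  // (nb*L) x 1, beat-major blocks
  for (int l = 0; l < N_CONV; ++l) {
    fc.M[l] = im2col_blocks(fc.S[l], k, L, nb);
    mat Z = fc.M[l] * P[2 * l];
    Z.each_row() += P[2 * l + 1].col(0).t();
    fc.S[l + 1] = clamp(Z, 0.0, datum::inf);  // ReLU
  }
  const mat &S4 = fc.S[N_CONV];
  const int C4 = S4.n_cols;
  fc.Xs.set_size(C4, nb, L);
  for (int b = 0; b < nb; ++b)
    for (int t = 0; t < L; ++t)
      fc.Xs.slice(t).col(b) = S4.row(b * L + t).t();
  fc.fwd = lstm_forward(fc.Xs, P[8], P[9], P[10].col(0), false);
  fc.bwd = lstm_forward(fc.Xs, P[11], P[12], P[13].col(0), true);
  fc.prob.set_size(K, nb, L);
  for (int t = 0; t < L; ++t) {
    mat Yt = P[14] * fc.fwd.h.slice(t) + P[15] * fc.bwd.h.slice(t);
    Yt.each_col() += P[16].col(0);
    Yt.each_row() -= max(Yt, 0);
    mat E = exp(Yt);
    fc.prob.slice(t) = E.each_row() / sum(E, 0);
  }
  return fc;
}

// cross-entropy (mean over nodes, summed over beats) and correct-node
// count for a batch; Yb rows are beats with 1-based class codes
void batch_metrics(const cube &prob, const imat &Yb, double &loss,
                   double &n_correct) {
  const int nb = Yb.n_rows, L = Yb.n_cols;
  for (int b = 0; b < nb; ++b) {
    double ll = 0.0;
    for (int t = 0; t < L; ++t) {
      const int y = Yb(b, t) - 1;
      ll -= std::log(std::max(prob(y, b, t), 1e-12));
      if ((int)index_max(prob.slice(t).col(b)) == y) n_correct += 1.0;
    }
    loss += ll / L;
  }
}

// backward for a batch; accumulates grads into G (averaged over beats)
void backward_batch(const ForwardCache &fc, const imat &Yb,
                    const std::vector<mat> &P, int k,
                    std::vector<mat> &G) {
  const int K = fc.prob.n_rows, nb = Yb.n_rows, L = Yb.n_cols;
  const double scale = 1.0 / ((double)L * nb);
  cube dHf(size(fc.fwd.h), fill::zeros), dHb(size(fc.bwd.h), fill::zeros);
  for (int t = 0; t < L; ++t) {
    mat dYt = fc.prob.slice(t);
    for (int b = 0; b < nb; ++b) dYt(Yb(b, t) - 1, b) -= 1.0;
    dYt *= scale;  // mean CE over nodes, mean over batch
    G[14] += dYt * fc.fwd.h.slice(t).t();
    G[15] += dYt * fc.bwd.h.slice(t).t();
    G[16].col(0) += sum(dYt, 1);
    dHf.slice(t) = P[14].t() * dYt;
    dHb.slice(t) = P[15].t() * dYt;
  }
  cube dXs(size(fc.Xs), fill::zeros);
  {
    vec dbf(P[10].n_rows, fill::zeros), dbb(P[13].n_rows, fill::zeros);
    mat dWxf(size(P[8]), fill::zeros), dWhf(size(P[9]), fill::zeros);
    mat dWxb(size(P[11]), fill::zeros), dWhb(size(P[12]), fill::zeros);
    lstm_backward(fc.Xs, P[8], P[9], fc.fwd, dHf, false, dWxf, dWhf, dbf,
                  dXs);
    lstm_backward(fc.Xs, P[11], P[12], fc.bwd, dHb, true, dWxb, dWhb, dbb,
                  dXs);
    G[8] += dWxf; G[9] += dWhf; G[10].col(0) += dbf;
    G[11] += dWxb; G[12] += dWhb; G[13].col(0) += dbb;
  }
  // scatter dXs back into row-block layout
  mat dS(fc.S[N_CONV].n_rows, fc.S[N_CONV].n_cols);
  for (int b = 0; b < nb; ++b)
    for (int t = 0; t < L; ++t)
      dS.row(b * L + t) = dXs.slice(t).col(b).t();
  // conv stack
  for (int l = N_CONV - 1; l >= 0; --l) {
    mat dZ = dS % (fc.S[l + 1] > 0);
    G[2 * l] += fc.M[l].t() * dZ;
    G[2 * l + 1].col(0) += sum(dZ, 0).t();
    if (l > 0) {
      mat dM = dZ * P[2 * l].t();
      dS.zeros(fc.S[l].n_rows, fc.S[l].n_cols);
      col2im_blocks_accum(dM, k, L, nb, dS);
    }
  }
}

// chunked forward-only evaluation (bounded memory)
void eval_set(const mat &X, const imat &Y, const std::vector<mat> &P,
              int k, int K, int chunk, double &loss, double &acc) {
  const int n = X.n_rows, L = X.n_cols;
  double tot_loss = 0.0, correct = 0.0;
  for (int start = 0; start < n; start += chunk) {
    int stop = std::min(start + chunk, n);
    ForwardCache fc = forward_batch(X.rows(start, stop - 1), P, k, K);
    batch_metrics(fc.prob, Y.rows(start, stop - 1), tot_loss, correct);
  }
  loss = tot_loss / n;
  acc = correct / ((double)n * L);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cb_train_cpp(const arma::mat &X, const arma::imat &Y,
                        const Rcpp::List &params, int kernel, int n_classes,
                        int epochs, int batch_size, double lr,
                        const arma::imat &shuffle,
                        Rcpp::Nullable<Rcpp::NumericMatrix> val_x,
                        Rcpp::Nullable<Rcpp::IntegerMatrix> val_y,
                        double beta1 = 0.9, double beta2 = 0.999,
                        double eps = 1e-8) {
  std::vector<mat> P = unpack_params(params);
  const int n = X.n_rows, L = X.n_cols;
  bool has_val = val_x.isNotNull();
  mat Xv;
  imat Yv;
  if (has_val) {
    Xv = Rcpp::as<mat>(val_x.get());
    Yv = Rcpp::as<imat>(val_y.get());
  }
  std::vector<mat> M(N_PARAMS), V(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i) {
    M[i] = mat(size(P[i]), fill::zeros);
    V[i] = mat(size(P[i]), fill::zeros);
  }
  long adam_t = 0;
  std::vector<double> h_loss, h_acc, h_vloss, h_vacc;
  std::vector<mat> G(N_PARAMS);
  for (int e = 0; e < epochs; ++e) {
    double ep_loss = 0.0, ep_correct = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(start + batch_size, n);
      int nb = stop - start;
      mat Xb(nb, L);
      imat Yb(nb, L);
      for (int b = start; b < stop; ++b) {
        int idx = shuffle(e, b) - 1;  // 1-based from R
        Xb.row(b - start) = X.row(idx);
        Yb.row(b - start) = Y.row(idx);
      }
      ForwardCache fc = forward_batch(Xb, P, kernel, n_classes);
      batch_metrics(fc.prob, Yb, ep_loss, ep_correct);
      for (int i = 0; i < N_PARAMS; ++i)
        G[i] = mat(size(P[i]), fill::zeros);
      backward_batch(fc, Yb, P, kernel, G);
      ++adam_t;
      double corr = std::sqrt(1.0 - std::pow(beta2, (double)adam_t)) /
                    (1.0 - std::pow(beta1, (double)adam_t));
      for (int i = 0; i < N_PARAMS; ++i) {
        M[i] = beta1 * M[i] + (1.0 - beta1) * G[i];
        V[i] = beta2 * V[i] + (1.0 - beta2) * square(G[i]);
        P[i] -= lr * corr * M[i] / (sqrt(V[i]) + eps);
      }
      Rcpp::checkUserInterrupt();
    }
    double tl = ep_loss / n;
    if (!std::isfinite(tl))
      Rcpp::stop("training diverged: non-finite loss at epoch %d", e + 1);
    h_loss.push_back(tl);
    h_acc.push_back(ep_correct / ((double)n * L));
    if (has_val) {
      double vl, va;
      eval_set(Xv, Yv, P, kernel, n_classes, batch_size, vl, va);
      h_vloss.push_back(vl);
      h_vacc.push_back(va);
    } else {
      h_vloss.push_back(NA_REAL);
      h_vacc.push_back(NA_REAL);
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = pack_params(P),
    Rcpp::Named("loss") = h_loss, Rcpp::Named("accuracy") = h_acc,
    Rcpp::Named("val_loss") = h_vloss, Rcpp::Named("val_accuracy") = h_vacc);
}

// [[Rcpp::export]]
arma::cube cb_forward_cpp(const arma::mat &X, const Rcpp::List &params,
                          int kernel, int n_classes, int chunk = 32) {
  std::vector<mat> P = unpack_params(params);
  const int n = X.n_rows, L = X.n_cols;
  cube prob(L, n_classes, n);
  for (int start = 0; start < n; start += chunk) {
    int stop = std::min(start + chunk, n);
    ForwardCache fc = forward_batch(X.rows(start, stop - 1), P, kernel,
                                    n_classes);
    for (int b = start; b < stop; ++b)
      for (int t = 0; t < L; ++t)
        prob.slice(b).row(t) = fc.prob.slice(t).col(b - start).t();
  }
  return prob;
}
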