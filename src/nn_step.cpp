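// Fused forward/backward pass of the two-stage emulator for a batch of
// conductance points, each evaluated on its own row of a (batch x time)
// matrix of evaluation times.  Computes the half-mean-squared-error loss
// against a target matrix and, on request, gradients with respect to
// network parameters, normalized conductances, and a per-sample time
// shift.  The decoder's first layer is evaluated in factored form (latent
// block per sample, time-feature block per row) so the full cross-product
// input matrix is never materialized.  The core is templated on the
// floating-point type: double for exact/reference work and gradient
// checks, single for the training loop (the usual precision for neural-
// network fitting).  It mirrors the reference R implementation in
// R/nn.R / R/emulator.R; the paths are cross-checked in the test suite.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

template <typename MT>
static inline void apply_act(MT &Z, const std::string &act) {
  if (act == "linear") return;
  if (act == "tanh") { Z = arma::tanh(Z); return; }
  for (arma::uword i = 0; i < Z.n_elem; ++i)       // elu
    if (Z[i] <= 0.0) Z[i] = std::expm1(Z[i]);
}

template <typename MT>
static inline MT act_deriv_from_out(const MT &A, const std::string &act) {
  if (act == "tanh") return 1.0 - arma::square(A);
  MT D(A.n_rows, A.n_cols);
  for (arma::uword i = 0; i < A.n_elem; ++i) D[i] = A[i] > 0.0 ? 1.0 : A[i] + 1.0;
  return D;                                        // elu
}

static inline double softplus1(double x) {
  return x > 0.0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}
static inline double sigmoid1(double x) { return 1.0 / (1.0 + std::exp(-x)); }

template <typename MT, typename VT>
struct Net {
  std::vector<MT> W;
  std::vector<VT> b;
  std::vector<std::string> act;
};

template <typename MT, typename VT>
static Net<MT, VT> parse_net(List net) {
  Net<MT, VT> out;
  for (int l = 0; l < net.size(); ++l) {
    List ly = net[l];
    out.W.push_back(arma::conv_to<MT>::from(as<arma::mat>(ly["W"])));
    out.b.push_back(arma::conv_to<VT>::from(as<arma::vec>(ly["b"])));
    out.act.push_back(as<std::string>(ly["act"]));
  }
  return out;
}

template <typename MT, typename VT>
static List emu_eval_core(List theta1, List theta2, const arma::mat &X_,
                          const arma::mat &times_,
                          Nullable<NumericMatrix> target_,
                          double vm_scale, double t_center, double t_scale,
                          bool want_grads, bool want_x_grad,
                          bool want_t_grad) {
  const Net<MT, VT> n1 = parse_net<MT, VT>(theta1),
                    n2 = parse_net<MT, VT>(theta2);
  const MT X = arma::conv_to<MT>::from(X_);
  const MT times = arma::conv_to<MT>::from(times_);
  const int B = X.n_rows, Tn = times.n_cols;
  if ((int)times.n_rows != B) stop("times must have one row per sample");
  const int ld = n1.W.back().n_cols - 3;
  const bool need_back = want_grads || want_x_grad || want_t_grad;

  // ---- encoder forward ----
  std::vector<MT> c1;
  MT encA = X;
  for (size_t l = 0; l < n1.W.size(); ++l) {
    if (need_back) c1.push_back(encA);
    encA = encA * n1.W[l];
    encA.each_row() += n1.b[l].t();
    apply_act(encA, n1.act[l]);
    if (need_back) c1.push_back(encA);
  }
  const MT lat = encA.cols(0, ld - 1);
  const VT raw1 = encA.col(ld), d2 = encA.col(ld + 1), raw3 = encA.col(ld + 2);
  arma::vec d1(B), d3(B);
  for (int i = 0; i < B; ++i) {
    d1[i] = softplus1(raw1[i]);
    d3[i] = vm_scale * softplus1(raw3[i]);
  }

  // ---- decoder forward, first layer factored; rows r = i * Tn + k ----
  MT feats(B * Tn, 8);
  for (int i = 0; i < B; ++i)
    for (int k = 0; k < Tn; ++k) {
      double ttv = (times(i, k) - t_center) / t_scale, p = 1.0;
      for (int q = 0; q < 8; ++q) { p *= ttv; feats(i * Tn + k, q) = p; }
    }
  const MT W0_lat = n2.W[0].rows(0, ld - 1);
  const MT W0_time = n2.W[0].rows(ld, ld + 7);
  const int h = n2.W[0].n_cols;
  MT Hlat = lat * W0_lat;                        // B x h
  Hlat.each_row() += n2.b[0].t();
  MT A = feats * W0_time;                        // (B*Tn) x h
  for (int i = 0; i < B; ++i)
    A.rows(i * Tn, (i + 1) * Tn - 1).each_row() += Hlat.row(i);
  apply_act(A, n2.act[0]);
  std::vector<MT> c2;                            // outputs of layers 0..L-1
  if (need_back) c2.push_back(A);
  for (size_t l = 1; l < n2.W.size(); ++l) {
    A = A * n2.W[l];
    A.each_row() += n2.b[l].t();
    apply_act(A, n2.act[l]);
    if (need_back) c2.push_back(A);
  }

  // ---- prediction with depolarization helper ----
  arma::mat pred(B, Tn), th(B, Tn);
  for (int i = 0; i < B; ++i)
    for (int k = 0; k < Tn; ++k) {
      th(i, k) = std::tanh(0.5 * d1[i] * ((double)times(i, k) - (double)d2[i]));
      pred(i, k) = vm_scale * (double)A(i * Tn + k, 0) + 0.5 * d3[i] * th(i, k);
    }

  List out;
  out["pred"] = pred;
  out["d1"] = d1;
  out["d2"] = arma::conv_to<arma::vec>::from(d2);
  out["d3"] = d3;
  if (!need_back) return out;
  if (target_.isNull()) stop("gradients require a target matrix");
  arma::mat target = as<arma::mat>(NumericMatrix(target_));
  if ((int)target.n_rows != B || (int)target.n_cols != Tn)
    stop("target must be a %d x %d matrix", B, Tn);

  arma::mat err = pred - target;
  out["loss"] = arma::accu(arma::square(err)) / (2.0 * Tn);
  arma::mat dPred = err / Tn;

  // ---- decoder backward ----
  const size_t L2 = n2.W.size();
  MT dA(B * Tn, 1);
  for (int i = 0; i < B; ++i)
    for (int k = 0; k < Tn; ++k) dA(i * Tn + k, 0) = dPred(i, k) * vm_scale;
  List grads2(L2);
  for (size_t l = L2 - 1; l >= 1; --l) {
    MT dZ = (n2.act[l] == "linear") ? dA
      : MT(dA % act_deriv_from_out(c2[l], n2.act[l]));
    if (want_grads)
      grads2[l] = List::create(
        _["W"] = arma::conv_to<arma::mat>::from(MT(c2[l - 1].t() * dZ)),
        _["b"] = arma::conv_to<arma::vec>::from(VT(arma::sum(dZ, 0).t())));
    dA = dZ * n2.W[l].t();
  }
  MT dZ0 = dA % act_deriv_from_out(c2[0], n2.act[0]);   // (B*Tn) x h
  MT S(B, h);                                    // sum over times, per sample
  for (int i = 0; i < B; ++i)
    S.row(i) = arma::sum(dZ0.rows(i * Tn, (i + 1) * Tn - 1), 0);
  if (want_grads) {
    MT gW0(ld + 8, h);
    gW0.rows(0, ld - 1) = lat.t() * S;
    gW0.rows(ld, ld + 7) = feats.t() * dZ0;
    grads2[0] = List::create(
      _["W"] = arma::conv_to<arma::mat>::from(gW0),
      _["b"] = arma::conv_to<arma::vec>::from(VT(arma::sum(S, 0).t())));
  }
  MT dLatent = S * W0_lat.t();                   // B x ld

  // ---- depolarization-parameter gradients ----
  MT dEnc(B, ld + 3, arma::fill::zeros);
  dEnc.cols(0, ld - 1) = dLatent;
  for (int i = 0; i < B; ++i) {
    double gd1 = 0, gd2 = 0, gd3 = 0;
    for (int k = 0; k < Tn; ++k) {
      double s2 = 1.0 - th(i, k) * th(i, k);
      double g = dPred(i, k);
      gd3 += g * 0.5 * th(i, k);
      gd1 += g * 0.5 * d3[i] * s2 * 0.5 * ((double)times(i, k) - (double)d2[i]);
      gd2 += g * 0.5 * d3[i] * s2 * (-0.5 * d1[i]);
    }
    dEnc(i, ld)     = gd1 * sigmoid1(raw1[i]);
    dEnc(i, ld + 1) = gd2;
    dEnc(i, ld + 2) = gd3 * vm_scale * sigmoid1(raw3[i]);
  }

  // ---- encoder backward ----
  const size_t L1 = n1.W.size();
  List grads1(L1);
  MT dA1 = dEnc;
  for (int l = (int)L1 - 1; l >= 0; --l) {
    MT dZ = (n1.act[l] == "linear") ? dA1
      : MT(dA1 % act_deriv_from_out(c1[2 * l + 1], n1.act[l]));
    if (want_grads)
      grads1[l] = List::create(
        _["W"] = arma::conv_to<arma::mat>::from(MT(c1[2 * l].t() * dZ)),
        _["b"] = arma::conv_to<arma::vec>::from(VT(arma::sum(dZ, 0).t())));
    dA1 = dZ * n1.W[l].t();
  }
  if (want_grads) { out["grads1"] = grads1; out["grads2"] = grads2; }
  if (want_x_grad) out["dX"] = arma::conv_to<arma::mat>::from(dA1);

  if (want_t_grad) {
    // dVm/dt through the polynomial features and the tanh helper
    MT dFeats = dZ0 * W0_time.t();               // (B*Tn) x 8
    arma::vec dt(B, arma::fill::zeros);
    for (int i = 0; i < B; ++i) {
      double acc = 0;
      for (int k = 0; k < Tn; ++k) {
        double ttv = ((double)times(i, k) - t_center) / t_scale, p = 1.0;
        for (int q = 0; q < 8; ++q) {
          acc += (double)dFeats(i * Tn + k, q) * (q + 1) * p / t_scale;
          p *= ttv;
        }
        double s2 = 1.0 - th(i, k) * th(i, k);
        acc += dPred(i, k) * 0.5 * d3[i] * s2 * 0.5 * d1[i];
      }
      dt[i] = acc;
    }
    out["dt"] = dt;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_emu_eval")]]
List cpp_emu_eval(List theta1, List theta2, const arma::mat &X,
                  const arma::mat &times, Nullable<NumericMatrix> target_,
                  double vm_scale, double t_center, double t_scale,
                  bool want_grads, bool want_x_grad, bool want_t_grad,
                  bool single_precision = false) {
  if (single_precision)
    return emu_eval_core<arma::fmat, arma::fvec>(
      theta1, theta2, X, times, target_, vm_scale, t_center, t_scale,
      want_grads, want_x_grad, want_t_grad);
  return emu_eval_core<arma::mat, arma::vec>(
    theta1, theta2, X, times, target_, vm_scale, t_center, t_scale,
    want_grads, want_x_grad, want_t_grad);
}
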