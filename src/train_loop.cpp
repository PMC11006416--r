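// Fused training loop: runs a block of epochs of the emulator's Adam
// optimization entirely in compiled code.  Master weights and Adam moments
// are kept in double precision; the forward/backward pass of each step
// runs in single precision (refreshed from the master weights every step),
// the customary arrangement for network fitting.  All batch shuffles and
// time-subset draws use R's RNG, so training remains reproducible under
// set.seed().  The per-step mathematics mirrors nn_step.cpp (shared time
// vector across the batch); the two paths are cross-checked in the tests.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

typedef arma::fmat FM;
typedef arma::fvec FV;

static inline void elu_ip(FM &Z) {
  for (arma::uword i = 0; i < Z.n_elem; ++i)
    if (Z[i] <= 0.0f) Z[i] = std::expm1(Z[i]);
}
static inline FM elu_deriv(const FM &A) {
  FM D(A.n_rows, A.n_cols);
  for (arma::uword i = 0; i < A.n_elem; ++i)
    D[i] = A[i] > 0.0f ? 1.0f : A[i] + 1.0f;
  return D;
}
static inline double softplus1(double x) {
  return x > 0.0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}
static inline double sigmoid1(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// partial Fisher-Yates draw of k of n (0-based indices) using R's RNG
static arma::uvec r_sample(int n, int k, std::vector<int> &pool) {
  if ((int)pool.size() != n) {
    pool.resize(n);
    for (int i = 0; i < n; ++i) pool[i] = i;
  }
  arma::uvec out(k);
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
  return out;
}

struct DNet {                       // double master + float working copies
  std::vector<arma::mat> W, mW, vW;
  std::vector<arma::vec> b, mb, vb;
  std::vector<FM> fW;
  std::vector<FV> fb;
  std::vector<std::string> act;
  void load(List net, List m, List v) {
    int L = net.size();
    for (int l = 0; l < L; ++l) {
      List ly = net[l], lm = m[l], lv = v[l];
      W.push_back(as<arma::mat>(ly["W"]));
      b.push_back(as<arma::vec>(ly["b"]));
      act.push_back(as<std::string>(ly["act"]));
      mW.push_back(as<arma::mat>(lm["W"]));
      mb.push_back(as<arma::vec>(lm["b"]));
      vW.push_back(as<arma::mat>(lv["W"]));
      vb.push_back(as<arma::vec>(lv["b"]));
      fW.push_back(arma::conv_to<FM>::from(W.back()));
      fb.push_back(arma::conv_to<FV>::from(b.back()));
    }
  }
  void refresh() {
    for (size_t l = 0; l < W.size(); ++l) {
      fW[l] = arma::conv_to<FM>::from(W[l]);
      fb[l] = arma::conv_to<FV>::from(b[l]);
    }
  }
  void adam(size_t l, const FM &gW, const FV &gb, double lr, double b1,
            double b2, double c1, double c2) {
    arma::mat g = arma::conv_to<arma::mat>::from(gW);
    arma::vec gv = arma::conv_to<arma::vec>::from(gb);
    mW[l] = b1 * mW[l] + (1 - b1) * g;
    vW[l] = b2 * vW[l] + (1 - b2) * arma::square(g);
    W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + 1e-8);
    mb[l] = b1 * mb[l] + (1 - b1) * gv;
    vb[l] = b2 * vb[l] + (1 - b2) * arma::square(gv);
    b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + 1e-8);
  }
  List dump_net() const {
    List out(W.size());
    for (size_t l = 0; l < W.size(); ++l)
      out[l] = List::create(_["W"] = W[l], _["b"] = b[l], _["act"] = act[l]);
    return out;
  }
  List dump_mom(bool second) const {
    List out(W.size());
    for (size_t l = 0; l < W.size(); ++l)
      out[l] = second
        ? List::create(_["W"] = vW[l], _["b"] = vb[l])
        : List::create(_["W"] = mW[l], _["b"] = mb[l]);
    return out;
  }
};

// [[Rcpp::export(name = ".cpp_train_epochs")]]
List cpp_train_epochs(List theta1, List theta2, List m1, List v1, List m2,
                      List v2, int t_step,
                      const arma::mat &Xn, const arma::mat &vm,
                      const arma::vec &grid,
                      const arma::ivec &batch_sizes,
                      const arma::ivec &nt_sizes,
                      const arma::vec &lrs,
                      double vm_scale, double t_center, double t_scale,
                      double beta1, double beta2) {
  RNGScope rng;
  DNet n1, n2;
  n1.load(theta1, m1, v1);
  n2.load(theta2, m2, v2);
  const int n = Xn.n_rows, Tn = grid.n_elem;
  const int ld = n1.W.back().n_cols - 3;
  const int h = n2.W[0].n_cols;
  const int epochs = batch_sizes.n_elem;
  const FM Xf = arma::conv_to<FM>::from(Xn);
  arma::vec epoch_loss(epochs, arma::fill::zeros);
  std::vector<int> pool_n, pool_t;
  bool diverged = false;

  for (int e = 0; e < epochs && !diverged; ++e) {
    const int bs = std::min<int>(batch_sizes[e], n);
    const int nt = std::max<int>(1, std::min<int>(nt_sizes[e], Tn));
    const double lr = lrs[e];
    arma::uvec perm = r_sample(n, n, pool_n);
    double lsum = 0; int nsteps = 0;
    for (int start = 0; start < n; start += bs) {
      const int B = std::min(bs, n - start);
      const arma::uvec idx = perm.subvec(start, start + B - 1);
      arma::uvec tsel = arma::sort(r_sample(Tn, nt, pool_t));
      // gather batch inputs and targets
      FM X(B, 9);
      for (int i = 0; i < B; ++i)
        for (int j = 0; j < 9; ++j) X(i, j) = Xf(idx[i], j);
      arma::mat tgt(B, nt);
      arma::vec tv(nt);
      for (int k = 0; k < nt; ++k) tv[k] = grid[tsel[k]];
      for (int i = 0; i < B; ++i)
        for (int k = 0; k < nt; ++k) tgt(i, k) = vm(idx[i], tsel[k]);

      // ---- encoder forward ----
      std::vector<FM> c1;
      FM encA = X;
      for (size_t l = 0; l < n1.fW.size(); ++l) {
        c1.push_back(encA);
        encA = encA * n1.fW[l];
        encA.each_row() += n1.fb[l].t();
        if (n1.act[l] == "elu") elu_ip(encA);
        c1.push_back(encA);
      }
      const FM lat = encA.cols(0, ld - 1);
      arma::vec raw1(B), d2(B), raw3(B), d1(B), d3(B);
      for (int i = 0; i < B; ++i) {
        raw1[i] = encA(i, ld); d2[i] = encA(i, ld + 1); raw3[i] = encA(i, ld + 2);
        d1[i] = softplus1(raw1[i]);
        d3[i] = vm_scale * softplus1(raw3[i]);
      }

      // ---- decoder forward (factored first layer, shared times) ----
      FM feats(nt, 8);
      for (int k = 0; k < nt; ++k) {
        float ttv = (float)((tv[k] - t_center) / t_scale), p = 1.0f;
        for (int q = 0; q < 8; ++q) { p *= ttv; feats(k, q) = p; }
      }
      const FM W0_lat = n2.fW[0].rows(0, ld - 1);
      const FM W0_time = n2.fW[0].rows(ld, ld + 7);
      FM Hlat = lat * W0_lat;
      Hlat.each_row() += n2.fb[0].t();
      const FM Htime = feats * W0_time;
      FM A(B * nt, h);
      for (int i = 0; i < B; ++i) {
        FM blk = Htime;
        blk.each_row() += Hlat.row(i);
        A.rows(i * nt, (i + 1) * nt - 1) = blk;
      }
      elu_ip(A);
      std::vector<FM> c2;
      c2.push_back(A);
      for (size_t l = 1; l < n2.fW.size(); ++l) {
        A = A * n2.fW[l];
        A.each_row() += n2.fb[l].t();
        if (n2.act[l] == "elu") elu_ip(A);
        else if (n2.act[l] == "tanh") A = arma::tanh(A);
        c2.push_back(A);
      }

      // ---- loss and output gradient ----
      arma::mat pred(B, nt), th(B, nt);
      for (int i = 0; i < B; ++i)
        for (int k = 0; k < nt; ++k) {
          th(i, k) = std::tanh(0.5 * d1[i] * (tv[k] - d2[i]));
          pred(i, k) = vm_scale * (double)A(i * nt + k, 0) +
                       0.5 * d3[i] * th(i, k);
        }
      arma::mat err = pred - tgt;
      double loss = arma::accu(arma::square(err)) / (2.0 * nt);
      if (!std::isfinite(loss)) { diverged = true; break; }
      lsum += loss; ++nsteps;
      arma::mat dPred = err / nt;

      // ---- decoder backward ----
      const size_t L2 = n2.fW.size();
      FM dA(B * nt, 1);
      for (int i = 0; i < B; ++i)
        for (int k = 0; k < nt; ++k)
          dA(i * nt + k, 0) = (float)(dPred(i, k) * vm_scale);
      std::vector<FM> gW2(L2);
      std::vector<FV> gb2(L2);
      for (size_t l = L2 - 1; l >= 1; --l) {
        FM dZ;
        if (n2.act[l] == "linear") dZ = dA;
        else if (n2.act[l] == "tanh") dZ = dA % (1.0f - arma::square(c2[l]));
        else dZ = dA % elu_deriv(c2[l]);
        gW2[l] = c2[l - 1].t() * dZ;
        gb2[l] = arma::sum(dZ, 0).t();
        dA = dZ * n2.fW[l].t();
      }
      FM dZ0 = dA % elu_deriv(c2[0]);
      FM S(B, h);
      FM Q(nt, h, arma::fill::zeros);
      for (int i = 0; i < B; ++i) {
        const FM blk = dZ0.rows(i * nt, (i + 1) * nt - 1);
        S.row(i) = arma::sum(blk, 0);
        Q += blk;
      }
      FM gW0(ld + 8, h);
      gW0.rows(0, ld - 1) = lat.t() * S;
      gW0.rows(ld, ld + 7) = feats.t() * Q;
      gW2[0] = gW0;
      gb2[0] = arma::sum(S, 0).t();
      FM dLatent = S * W0_lat.t();

      FM dEnc(B, ld + 3, arma::fill::zeros);
      dEnc.cols(0, ld - 1) = dLatent;
      for (int i = 0; i < B; ++i) {
        double gd1 = 0, gd2 = 0, gd3 = 0;
        for (int k = 0; k < nt; ++k) {
          double s2 = 1.0 - th(i, k) * th(i, k);
          double g = dPred(i, k);
          gd3 += g * 0.5 * th(i, k);
          gd1 += g * 0.5 * d3[i] * s2 * 0.5 * (tv[k] - d2[i]);
          gd2 += g * 0.5 * d3[i] * s2 * (-0.5 * d1[i]);
        }
        dEnc(i, ld)     = (float)(gd1 * sigmoid1(raw1[i]));
        dEnc(i, ld + 1) = (float)gd2;
        dEnc(i, ld + 2) = (float)(gd3 * vm_scale * sigmoid1(raw3[i]));
      }

      // ---- encoder backward ----
      const size_t L1 = n1.fW.size();
      std::vector<FM> gW1(L1);
      std::vector<FV> gb1(L1);
      FM dA1 = dEnc;
      for (int l = (int)L1 - 1; l >= 0; --l) {
        FM dZ = (n1.act[l] == "linear") ? dA1
          : FM(dA1 % elu_deriv(c1[2 * l + 1]));
        gW1[l] = c1[2 * l].t() * dZ;
        gb1[l] = arma::sum(dZ, 0).t();
        dA1 = dZ * n1.fW[l].t();
      }

      // ---- Adam update on the double master weights ----
      ++t_step;
      double c1c = 1 - std::pow(beta1, t_step);
      double c2c = 1 - std::pow(beta2, t_step);
      for (size_t l = 0; l < L1; ++l)
        n1.adam(l, gW1[l], gb1[l], lr, beta1, beta2, c1c, c2c);
      for (size_t l = 0; l < L2; ++l)
        n2.adam(l, gW2[l], gb2[l], lr, beta1, beta2, c1c, c2c);
      n1.refresh();
      n2.refresh();
    }
    epoch_loss[e] = nsteps ? lsum / nsteps : NA_REAL;
  }

  return List::create(_["theta1"] = n1.dump_net(), _["theta2"] = n2.dump_net(),
                      _["m1"] = n1.dump_mom(false), _["v1"] = n1.dump_mom(true),
                      _["m2"] = n2.dump_mom(false), _["v2"] = n2.dump_mom(true),
                      _["t_step"] = t_step, _["epoch_loss"] = epoch_loss,
                      _["diverged"] = diverged);
}
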