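// CNN + BiLSTM sequence classifier over one-hot DNA windows.
//
// Layer order: conv(ReLU) -> conv(ReLU) -> max-pool -> BiLSTM -> dense(ReLU,
// dropout) -> softmax(2).  Implemented directly with Armadillo GEMM kernels:
// convolutions via im2col, LSTM as an explicit loop over pooled time steps
// with full backpropagation through time, Adam updates, early stopping on a
// monitored validation loss.  All randomness (init, shuffling, dropout) comes
// from one std::mt19937_64 stream so a seed fixes the whole run.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::uword;

namespace {

struct Spec {
  int L, C0, F1, K1, F2, K2, pool, H, D;
  int L1() const { return L - K1 + 1; }
  int L2() const { return L1() - K2 + 1; }
  int T() const { return L2() / pool; }
};

Spec as_spec(const List& s) {
  Spec sp;
  sp.L = as<int>(s["input_len"]); sp.C0 = 4;
  sp.F1 = as<int>(s["conv1_filters"]); sp.K1 = as<int>(s["conv1_width"]);
  sp.F2 = as<int>(s["conv2_filters"]); sp.K2 = as<int>(s["conv2_width"]);
  sp.pool = as<int>(s["pool"]);
  sp.H = as<int>(s["lstm_units"]); sp.D = as<int>(s["dense_units"]);
  if (sp.T() < 2) stop("sequence too short for this architecture");
  return sp;
}

struct Params {
  mat W1; vec b1; mat W2; vec b2;
  mat fWx, fWh; vec fb;
  mat bWx, bWh; vec bb;
  mat Wd; vec bd; mat Wo; vec bo;
  std::vector<mat*> mats() {
    return {&W1, &W2, &fWx, &fWh, &bWx, &bWh, &Wd, &Wo};
  }
  std::vector<vec*> vecs() { return {&b1, &b2, &fb, &bb, &bd, &bo}; }
};

Params zeros_like(const Spec& sp) {
  Params p;
  p.W1.zeros(sp.F1, sp.C0 * sp.K1); p.b1.zeros(sp.F1);
  p.W2.zeros(sp.F2, sp.F1 * sp.K2); p.b2.zeros(sp.F2);
  p.fWx.zeros(4 * sp.H, sp.F2); p.fWh.zeros(4 * sp.H, sp.H); p.fb.zeros(4 * sp.H);
  p.bWx.zeros(4 * sp.H, sp.F2); p.bWh.zeros(4 * sp.H, sp.H); p.bb.zeros(4 * sp.H);
  p.Wd.zeros(sp.D, 2 * sp.H); p.bd.zeros(sp.D);
  p.Wo.zeros(2, sp.D); p.bo.zeros(2);
  return p;
}

List params_to_list(const Params& p) {
  return List::create(
      _["W1"] = p.W1, _["b1"] = p.b1, _["W2"] = p.W2, _["b2"] = p.b2,
      _["fWx"] = p.fWx, _["fWh"] = p.fWh, _["fb"] = p.fb,
      _["bWx"] = p.bWx, _["bWh"] = p.bWh, _["bb"] = p.bb,
      _["Wd"] = p.Wd, _["bd"] = p.bd, _["Wo"] = p.Wo, _["bo"] = p.bo);
}

Params params_from_list(const List& l) {
  Params p;
  p.W1 = as<mat>(l["W1"]); p.b1 = as<vec>(l["b1"]);
  p.W2 = as<mat>(l["W2"]); p.b2 = as<vec>(l["b2"]);
  p.fWx = as<mat>(l["fWx"]); p.fWh = as<mat>(l["fWh"]); p.fb = as<vec>(l["fb"]);
  p.bWx = as<mat>(l["bWx"]); p.bWh = as<mat>(l["bWh"]); p.bb = as<vec>(l["bb"]);
  p.Wd = as<mat>(l["Wd"]); p.bd = as<vec>(l["bd"]);
  p.Wo = as<mat>(l["Wo"]); p.bo = as<vec>(l["bo"]);
  return p;
}

void glorot(mat& W, std::mt19937_64& rng) {
  double lim = std::sqrt(6.0 / (W.n_rows + W.n_cols));
  std::uniform_real_distribution<double> u(-lim, lim);
  for (uword i = 0; i < W.n_elem; ++i) W(i) = u(rng);
}

mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// im2col over a batch: columns ordered position-fastest within sample.
void im2col0(const cube& X, const arma::uvec& idx, const Spec& sp, mat& A) {
  const int L1 = sp.L1(), C0 = sp.C0, K1 = sp.K1;
  const int B = (int)idx.n_elem;
  A.set_size(C0 * K1, (uword)L1 * B);
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(idx[s]);
    for (int p = 0; p < L1; ++p) {
      double* dst = A.colptr((uword)s * L1 + p);
      for (int k = 0; k < K1; ++k)
        std::memcpy(dst + (size_t)k * C0, Xs.colptr(p + k), sizeof(double) * C0);
    }
  }
}

void im2col1(const mat& H1, const Spec& sp, int B, mat& A) {
  const int L1 = sp.L1(), L2 = sp.L2(), F1 = sp.F1, K2 = sp.K2;
  A.set_size((uword)F1 * K2, (uword)L2 * B);
  for (int s = 0; s < B; ++s) {
    for (int p = 0; p < L2; ++p) {
      double* dst = A.colptr((uword)s * L2 + p);
      for (int k = 0; k < K2; ++k)
        std::memcpy(dst + (size_t)k * F1, H1.colptr((uword)s * L1 + p + k),
                    sizeof(double) * F1);
    }
  }
}

struct Cache {
  mat A1, Z1, A2, Z2, Pm;
  arma::umat amax;
  cube fI, fF, fG, fO, fC, fHs;  // gate/state tensors, (H x B x T)
  cube bI, bF, bG, bO, bC, bHs;
  mat hcat, Zd, Hdd, Mask, P;
  arma::uvec tf, tb;  // time index per processing step, per direction
};

void lstm_forward(const mat& Pm, const mat& Wx, const mat& Wh, const vec& b,
                  const Spec& sp, int B, const arma::uvec& ts, cube& I, cube& F,
                  cube& G, cube& O, cube& C, cube& Hs) {
  const int H = sp.H, F2 = sp.F2, T = sp.T();
  I.set_size(H, B, T); F.set_size(H, B, T); G.set_size(H, B, T);
  O.set_size(H, B, T); C.set_size(H, B, T); Hs.set_size(H, B, T);
  mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  for (int st = 0; st < T; ++st) {
    int t = ts[st];
    mat z = Wx * Pm.rows((uword)t * F2, (uword)(t + 1) * F2 - 1) + Wh * h;
    z.each_col() += b;
    mat gi = sigmoid(z.rows(0, H - 1));
    mat gf = sigmoid(z.rows(H, 2 * H - 1));
    mat gg = arma::tanh(z.rows(2 * H, 3 * H - 1));
    mat go = sigmoid(z.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % arma::tanh(c);
    I.slice(st) = gi; F.slice(st) = gf; G.slice(st) = gg; O.slice(st) = go;
    C.slice(st) = c; Hs.slice(st) = h;
  }
}

void lstm_backward(const mat& Pm, const mat& Wx, const mat& Wh, const Spec& sp,
                   int B, const arma::uvec& ts, const cube& I, const cube& F,
                   const cube& G, const cube& O, const cube& C, const cube& Hs,
                   const mat& dh_final, mat& dWx, mat& dWh, vec& db, mat& dPm) {
  const int H = sp.H, F2 = sp.F2, T = sp.T();
  mat dh = dh_final, dc(H, B, arma::fill::zeros);
  for (int st = T - 1; st >= 0; --st) {
    int t = ts[st];
    const mat& gi = I.slice(st); const mat& gf = F.slice(st);
    const mat& gg = G.slice(st); const mat& go = O.slice(st);
    mat tc = arma::tanh(C.slice(st));
    mat cprev = (st == 0) ? mat(H, B, arma::fill::zeros) : C.slice(st - 1);
    mat hprev = (st == 0) ? mat(H, B, arma::fill::zeros) : Hs.slice(st - 1);
    mat dct = dc + dh % go % (1.0 - tc % tc);
    mat dzo = (dh % tc) % go % (1.0 - go);
    mat dzi = (dct % gg) % gi % (1.0 - gi);
    mat dzf = (dct % cprev) % gf % (1.0 - gf);
    mat dzg = (dct % gi) % (1.0 - gg % gg);
    dc = dct % gf;
    mat dz = arma::join_cols(arma::join_cols(dzi, dzf), arma::join_cols(dzg, dzo));
    dWx += dz * Pm.rows((uword)t * F2, (uword)(t + 1) * F2 - 1).t();
    dWh += dz * hprev.t();
    db += arma::sum(dz, 1);
    dh = Wh.t() * dz;
    dPm.rows((uword)t * F2, (uword)(t + 1) * F2 - 1) += Wx.t() * dz;
  }
}

// Forward pass for a batch; fills cache when `train` (dropout applied then).
mat forward(const cube& X, const arma::uvec& idx, const Params& p,
            const Spec& sp, bool train, double dropout, std::mt19937_64& rng,
            Cache* cc) {
  const int B = (int)idx.n_elem, L1 = sp.L1(), L2 = sp.L2(), T = sp.T();
  Cache local; Cache& c = cc ? *cc : local;
  im2col0(X, idx, sp, c.A1);
  c.Z1 = p.W1 * c.A1; c.Z1.each_col() += p.b1;
  mat H1 = arma::clamp(c.Z1, 0.0, arma::datum::inf);
  im2col1(H1, sp, B, c.A2);
  c.Z2 = p.W2 * c.A2; c.Z2.each_col() += p.b2;
  mat H2 = arma::clamp(c.Z2, 0.0, arma::datum::inf);
  // max pool, stride = window = sp.pool
  c.Pm.set_size((uword)sp.F2 * T, B);
  c.amax.set_size((uword)sp.F2 * T, B);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < T; ++t) {
      for (int f = 0; f < sp.F2; ++f) {
        double best = -arma::datum::inf; int bj = 0;
        for (int j = 0; j < sp.pool; ++j) {
          double v = H2(f, (uword)s * L2 + t * sp.pool + j);
          if (v > best) { best = v; bj = j; }
        }
        c.Pm((uword)t * sp.F2 + f, s) = best;
        c.amax((uword)t * sp.F2 + f, s) = bj;
      }
    }
  }
  c.tf = arma::regspace<arma::uvec>(0, T - 1);
  c.tb = arma::reverse(c.tf);
  lstm_forward(c.Pm, p.fWx, p.fWh, p.fb, sp, B, c.tf, c.fI, c.fF, c.fG, c.fO,
               c.fC, c.fHs);
  lstm_forward(c.Pm, p.bWx, p.bWh, p.bb, sp, B, c.tb, c.bI, c.bF, c.bG, c.bO,
               c.bC, c.bHs);
  c.hcat = arma::join_cols(c.fHs.slice(T - 1), c.bHs.slice(T - 1));
  c.Zd = p.Wd * c.hcat; c.Zd.each_col() += p.bd;
  mat Hd = arma::clamp(c.Zd, 0.0, arma::datum::inf);
  if (train && dropout > 0.0) {
    std::uniform_real_distribution<double> u(0.0, 1.0);
    c.Mask.set_size(sp.D, B);
    double keep = 1.0 - dropout;
    for (uword i = 0; i < c.Mask.n_elem; ++i)
      c.Mask(i) = (u(rng) < keep) ? 1.0 / keep : 0.0;
    c.Hdd = Hd % c.Mask;
  } else {
    c.Mask.ones(sp.D, B);
    c.Hdd = Hd;
  }
  mat logits = p.Wo * c.Hdd; logits.each_col() += p.bo;
  logits.each_row() -= arma::max(logits, 0);
  mat e = arma::exp(logits);
  c.P = e.each_row() / arma::sum(e, 0);
  return c.P;
}

double backward(const cube& X, const arma::uvec& idx, const arma::ivec& y,
                const Params& p, const Spec& sp, Cache& c, Params& g,
                int denom) {
  const int B = (int)idx.n_elem, L1 = sp.L1(), L2 = sp.L2(), T = sp.T();
  double loss = 0.0;
  mat dlog = c.P;
  for (int s = 0; s < B; ++s) {
    int ys = y[idx[s]];
    loss -= std::log(std::max(c.P(ys, s), 1e-12));
    dlog(ys, s) -= 1.0;
  }
  dlog /= (double)denom;
  g.Wo += dlog * c.Hdd.t(); g.bo += arma::sum(dlog, 1);
  mat dHd = (p.Wo.t() * dlog) % c.Mask;
  mat dZd = dHd % arma::conv_to<mat>::from(c.Zd > 0.0);
  g.Wd += dZd * c.hcat.t(); g.bd += arma::sum(dZd, 1);
  mat dhcat = p.Wd.t() * dZd;
  mat dPm((uword)sp.F2 * T, B, arma::fill::zeros);
  lstm_backward(c.Pm, p.fWx, p.fWh, sp, B, c.tf, c.fI, c.fF, c.fG, c.fO, c.fC,
                c.fHs, dhcat.rows(0, sp.H - 1), g.fWx, g.fWh, g.fb, dPm);
  lstm_backward(c.Pm, p.bWx, p.bWh, sp, B, c.tb, c.bI, c.bF, c.bG, c.bO, c.bC,
                c.bHs, dhcat.rows(sp.H, 2 * sp.H - 1), g.bWx, g.bWh, g.bb, dPm);
  mat dH2(sp.F2, (uword)L2 * B, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < T; ++t)
      for (int f = 0; f < sp.F2; ++f) {
        uword pcol = (uword)s * L2 + t * sp.pool + c.amax((uword)t * sp.F2 + f, s);
        dH2(f, pcol) += dPm((uword)t * sp.F2 + f, s);
      }
  mat dZ2 = dH2 % arma::conv_to<mat>::from(c.Z2 > 0.0);
  g.W2 += dZ2 * c.A2.t(); g.b2 += arma::sum(dZ2, 1);
  mat dA2 = p.W2.t() * dZ2;
  mat dH1(sp.F1, (uword)L1 * B, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int pz = 0; pz < L2; ++pz)
      for (int k = 0; k < sp.K2; ++k)
        dH1.col((uword)s * L1 + pz + k) +=
            dA2.submat((uword)k * sp.F1, (uword)s * L2 + pz,
                       (uword)(k + 1) * sp.F1 - 1, (uword)s * L2 + pz);
  mat dZ1 = dH1 % arma::conv_to<mat>::from(c.Z1 > 0.0);
  g.W1 += dZ1 * c.A1.t(); g.b1 += arma::sum(dZ1, 1);
  return loss;
}

// chunk a batch so the im2col workspaces stay bounded
int chunk_size(const Spec& sp) {
  double per_sample = (double)sp.F1 * sp.K2 * sp.L2() * 8.0 * 4.0;
  int ch = (int)std::max(16.0, 2.5e8 / per_sample);
  return std::min(ch, 512);
}

double eval_loss(const cube& X, const arma::ivec& y, const Params& p,
                 const Spec& sp, std::mt19937_64& rng) {
  const int N = (int)X.n_slices;
  int ch = chunk_size(sp);
  double loss = 0.0;
  for (int at = 0; at < N; at += ch) {
    int to = std::min(N, at + ch);
    arma::uvec idx = arma::regspace<arma::uvec>(at, to - 1);
    mat P = forward(X, idx, p, sp, false, 0.0, rng, nullptr);
    for (int s = 0; s < to - at; ++s)
      loss -= std::log(std::max(P(y[at + s], s), 1e-12));
  }
  return loss / N;
}

void adam_step(Params& p, const Params& g, Params& m, Params& v, double lr,
               int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  auto upd = [&](auto& P, const auto& G, auto& M, auto& V) {
    M = b1 * M + (1.0 - b1) * G;
    V = b2 * V + (1.0 - b2) * (G % G);
    P -= lr * (M / c1) / (arma::sqrt(V / c2) + eps);
  };
  Params* gp = const_cast<Params*>(&g);
  auto pm = p.mats(), gm = gp->mats(), mm = m.mats(), vm = v.mats();
  for (size_t i = 0; i < pm.size(); ++i) upd(*pm[i], *gm[i], *mm[i], *vm[i]);
  auto pv = p.vecs(), gv = gp->vecs(), mv = m.vecs(), vv = v.vecs();
  for (size_t i = 0; i < pv.size(); ++i) upd(*pv[i], *gv[i], *mv[i], *vv[i]);
}

void zero(Params& g) {
  for (mat* m : g.mats()) m->zeros();
  for (vec* v : g.vecs()) v->zeros();
}

}  // namespace

// [[Rcpp::export]]
List cpp_pasnet_init(List spec, int seed) {
  Spec sp = as_spec(spec);
  std::mt19937_64 rng((uint64_t)seed);
  Params p = zeros_like(sp);
  for (mat* m : p.mats()) glorot(*m, rng);
  p.fb.subvec(sp.H, 2 * sp.H - 1).ones();  // forget-gate bias
  p.bb.subvec(sp.H, 2 * sp.H - 1).ones();
  return params_to_list(p);
}

// [[Rcpp::export]]
arma::mat cpp_pasnet_forward(const arma::cube& X, List params, List spec) {
  Spec sp = as_spec(spec);
  Params p = params_from_list(params);
  std::mt19937_64 rng(0);
  const int N = (int)X.n_slices;
  mat out(N, 2);
  int ch = chunk_size(sp);
  for (int at = 0; at < N; at += ch) {
    int to = std::min(N, at + ch);
    arma::uvec idx = arma::regspace<arma::uvec>(at, to - 1);
    mat P = forward(X, idx, p, sp, false, 0.0, rng, nullptr);
    out.rows(at, to - 1) = P.t();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_pasnet_loss_grad(const arma::cube& X, IntegerVector y, List params,
                          List spec) {
  Spec sp = as_spec(spec);
  Params p = params_from_list(params);
  Params g = zeros_like(sp);
  arma::ivec yy(y.size());
  for (int i = 0; i < y.size(); ++i) yy[i] = y[i];
  std::mt19937_64 rng(0);
  const int N = (int)X.n_slices;
  arma::uvec idx = arma::regspace<arma::uvec>(0, N - 1);
  Cache c;
  forward(X, idx, p, sp, false, 0.0, rng, &c);
  double loss = backward(X, idx, yy, p, sp, c, g, N);
  return List::create(_["loss"] = loss / N, _["grads"] = params_to_list(g));
}

// [[Rcpp::export]]
List cpp_pasnet_train(const arma::cube& X, IntegerVector y,
                      const arma::cube& Xval, IntegerVector yval, List params,
                      List spec, double lr, int batch_size, int max_epochs,
                      int patience, double dropout, int seed, bool verbose) {
  Spec sp = as_spec(spec);
  Params p = params_from_list(params);
  Params g = zeros_like(sp), m = zeros_like(sp), v = zeros_like(sp);
  Params best = p;
  std::mt19937_64 rng((uint64_t)seed);
  const int N = (int)X.n_slices;
  arma::ivec yy(y.size());
  for (int i = 0; i < y.size(); ++i) yy[i] = y[i];
  arma::ivec yv(yval.size());
  for (int i = 0; i < yval.size(); ++i) yv[i] = yval[i];
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  int ch = chunk_size(sp);
  std::vector<double> tr_hist, val_hist;
  double best_val = arma::datum::inf;
  int best_epoch = 0, bad = 0, adam_t = 0;
  Cache c;
  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(ord.begin(), ord.end(), rng);
    double tr_loss = 0.0;
    for (int at = 0; at < N; at += batch_size) {
      int to = std::min(N, at + batch_size);
      int bsz = to - at;
      zero(g);
      for (int cat = at; cat < to; cat += ch) {
        int cto = std::min(to, cat + ch);
        arma::uvec idx(cto - cat);
        for (int i = cat; i < cto; ++i) idx[i - cat] = ord[i];
        forward(X, idx, p, sp, true, dropout, rng, &c);
        tr_loss += backward(X, idx, yy, p, sp, c, g, bsz);
      }
      adam_step(p, g, m, v, lr, ++adam_t);
    }
    tr_loss /= N;
    double val_loss = eval_loss(Xval, yv, p, sp, rng);
    tr_hist.push_back(tr_loss);
    val_hist.push_back(val_loss);
    if (verbose)
      Rcout << "epoch " << epoch << " train_loss " << tr_loss << " val_loss "
            << val_loss << "\n";
    if (val_loss < best_val) {
      best_val = val_loss; best = p; best_epoch = epoch; bad = 0;
    } else if (++bad >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = params_to_list(best),
                      _["best_epoch"] = best_epoch,
                      _["best_val_loss"] = best_val,
                      _["train_loss"] = wrap(tr_hist),
                      _["val_loss"] = wrap(val_hist));
}

// Per sequence and first-layer filter: position and value of the maximal
// convolution response (pre-activation) -- used for motif extraction.
// [[Rcpp::export]]
List cpp_conv1_scan(const arma::cube& X, const arma::mat& W1,
                    const arma::vec& b1, List spec) {
  Spec sp = as_spec(spec);
  const int N = (int)X.n_slices, L1 = sp.L1();
  arma::imat pos(N, sp.F1);
  mat act(N, sp.F1);
  std::mt19937_64 rng(0);
  mat A;
  int ch = 256;
  for (int at = 0; at < N; at += ch) {
    int to = std::min(N, at + ch);
    arma::uvec idx = arma::regspace<arma::uvec>(at, to - 1);
    im2col0(X, idx, sp, A);
    mat Z = W1 * A; Z.each_col() += b1;
    for (int s = 0; s < to - at; ++s)
      for (int f = 0; f < sp.F1; ++f) {
        double bv = -arma::datum::inf; int bp = 0;
        for (int pz = 0; pz < L1; ++pz) {
          double vz = Z(f, (uword)s * L1 + pz);
          if (vz > bv) { bv = vz; bp = pz; }
        }
        pos(at + s, f) = bp;
        act(at + s, f) = bv;
      }
  }
  return List::create(_["pos"] = pos, _["act"] = act);
}

// One-hot encode sequences (channels A,T,G,C; N -> all-zero column).
// [[Rcpp::export]]
arma::cube cpp_encode_onehot(CharacterVector seqs, int L) {
  const int N = seqs.size();
  cube X(4, L, N, arma::fill::zeros);
  for (int s = 0; s < N; ++s) {
    const char* q = CHAR(STRING_ELT(seqs, s));
    if ((int)std::strlen(q) != L)
      stop("sequence %d has length %d, expected %d", s + 1,
           (int)std::strlen(q), L);
    for (int i = 0; i < L; ++i) {
      switch (q[i]) {
        case 'A': case 'a': X(0, i, s) = 1.0; break;
        case 'T': case 't': X(1, i, s) = 1.0; break;
        case 'G': case 'g': X(2, i, s) = 1.0; break;
        case 'C': case 'c': X(3, i, s) = 1.0; break;
        case 'N': case 'n': break;
        default:
          stop("invalid character '%c' in sequence %d", q[i], s + 1);
      }
    }
  }
  return X;
}
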