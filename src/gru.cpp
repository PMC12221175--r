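// Gated recurrent unit reducer: a flat pair-feature vector is consumed as a
// univariate sequence (one scalar per timestep) by one or two GRUs of width h;
// the final hidden state(s) are the reduced representation.  Training attaches
// a single sigmoid unit and minimises binary cross-entropy with Adam under
// global-norm gradient clipping.  All arithmetic is single precision; all
// randomness (initial parameters, epoch shuffles) is injected from R, so runs
// are bit-reproducible for a given seed.  Activation traces and work buffers
// are allocated once per training call: the recurrence is bandwidth-bound and
// per-step allocation would dominate the runtime.

#include <RcppArmadillo.h>
#include <xmmintrin.h>
#include <pmmintrin.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerMatrix;
using Rcpp::as;

namespace {

struct DirParams {
  fvec wx;   // 3h  input weights (univariate input)
  fvec bi;   // 3h  input-side bias
  fvec bh;   // 3h  hidden-side bias (kept separate: the n-gate hidden term
             //     is gated by r before the nonlinearity)
  fmat Wh;   // h x 3h  recurrent weights, gate layout [r | z | n]
  void zeros(int h) {
    wx.zeros(3 * h); bi.zeros(3 * h); bh.zeros(3 * h); Wh.zeros(h, 3 * h);
  }
};

struct Head {
  fvec w;    // ndir*h
  float b;
};

DirParams dir_from_list(const List& p) {
  DirParams d;
  d.wx = as<fvec>(as<NumericVector>(p["wx"]));
  d.bi = as<fvec>(as<NumericVector>(p["bi"]));
  d.bh = as<fvec>(as<NumericVector>(p["bh"]));
  d.Wh = as<fmat>(as<NumericMatrix>(p["Wh"]));
  return d;
}

List dir_to_list(const DirParams& d) {
  return List::create(
      Rcpp::Named("wx") = NumericVector(d.wx.begin(), d.wx.end()),
      Rcpp::Named("bi") = NumericVector(d.bi.begin(), d.bi.end()),
      Rcpp::Named("bh") = NumericVector(d.bh.begin(), d.bh.end()),
      Rcpp::Named("Wh") = Rcpp::wrap(conv_to<mat>::from(d.Wh)));
}

inline int step_index(int k, int T, bool backward) {
  return backward ? (T - 1 - k) : k;
}

// Stored activations for one direction over one batch.
struct Trace {
  fcube H;              // B x h x (T+1); slice 0 is the zero initial state
  fcube r, z, n, ghn;   // B x h x T (ghn: hidden-side n-gate pre-activation)
  void alloc(int B, int h, int T) {
    H.set_size(B, h, T + 1);
    r.set_size(B, h, T); z.set_size(B, h, T);
    n.set_size(B, h, T); ghn.set_size(B, h, T);
  }
};

// Work buffers shared across timesteps for one batch size.
struct Workspace {
  fmat A;               // B x 3h   gate pre-activations
  fmat dG;              // B x 3h   gate gradients
  fmat gtmp;            // h x 3h   per-step recurrent-weight gradient
  fmat dH, dH2;         // B x h    hidden-state gradient (ping-pong)
  fmat dz, dn, dr;      // B x h
  void alloc(int B, int h) {
    A.set_size(B, 3 * h); dG.set_size(B, 3 * h); gtmp.set_size(h, 3 * h);
    dH.set_size(B, h); dH2.set_size(B, h);
    dz.set_size(B, h); dn.set_size(B, h); dr.set_size(B, h);
  }
};

// Forward pass over the batch, writing activations into tr (if given);
// returns nothing, final state is tr.H.slice(T) / Hout.
void forward_dir(const DirParams& P, const fmat& Xb, int h, bool backward,
                 Trace* tr, Workspace* ws, fmat& Hout) {
  const int B = Xb.n_rows, T = Xb.n_cols;
  const frowvec wxr = P.wx.t(), bir = P.bi.t(), bhr = P.bh.t();
  fmat Hlocal;
  if (!tr) { Hlocal.zeros(B, h); }
  else { tr->H.slice(0).zeros(); }
  fmat Alocal;
  fmat& A = ws ? ws->A : Alocal;
  if (!ws) Alocal.set_size(B, 3 * h);
  for (int k = 0; k < T; ++k) {
    const int t = step_index(k, T, backward);
    const fmat& Hprev = tr ? tr->H.slice(k) : Hlocal;
    A = Hprev * P.Wh;
    A.each_row() += bhr;
    fmat ghn_loc;
    if (tr) tr->ghn.slice(k) = A.cols(2 * h, 3 * h - 1);
    else ghn_loc = A.cols(2 * h, 3 * h - 1);
    const fmat& ghn = tr ? tr->ghn.slice(k) : ghn_loc;
    A += Xb.col(t) * wxr;
    A.each_row() += bir;
    fmat r_loc, z_loc, n_loc;
    fmat& r = tr ? tr->r.slice(k) : r_loc;
    fmat& z = tr ? tr->z.slice(k) : z_loc;
    fmat& n = tr ? tr->n.slice(k) : n_loc;
    r = 1.0f / (1.0f + exp(-A.cols(0, h - 1)));
    z = 1.0f / (1.0f + exp(-A.cols(h, 2 * h - 1)));
    // the n-block of A carries ghn un-gated; correct it to r % ghn
    n = tanh(A.cols(2 * h, 3 * h - 1) + (r - 1.0f) % ghn);
    if (tr) tr->H.slice(k + 1) = (1.0f - z) % n + z % Hprev;
    else Hlocal = (1.0f - z) % n + z % Hlocal;
  }
  Hout = tr ? tr->H.slice(T) : Hlocal;
}

// Backpropagate dHlast through the stored trace; accumulate into g.
void backward_dir(const DirParams& P, const fmat& Xb, int h, bool backward,
                  const Trace& tr, Workspace& ws, const fmat& dHlast,
                  DirParams& g) {
  const int T = Xb.n_cols;
  ws.dH = dHlast;
  for (int k = T - 1; k >= 0; --k) {
    const int t = step_index(k, T, backward);
    const fmat& Hprev = tr.H.slice(k);
    const fmat& r = tr.r.slice(k);
    const fmat& z = tr.z.slice(k);
    const fmat& n = tr.n.slice(k);
    const fmat& ghn = tr.ghn.slice(k);
    ws.dz = ws.dH % (Hprev - n) % z % (1.0f - z);
    ws.dn = ws.dH % (1.0f - z) % (1.0f - n % n);
    ws.dr = ws.dn % ghn % r % (1.0f - r);
    ws.dG.cols(0, h - 1) = ws.dr;
    ws.dG.cols(h, 2 * h - 1) = ws.dz;
    ws.dG.cols(2 * h, 3 * h - 1) = ws.dn % r;        // dghn
    ws.gtmp = Hprev.t() * ws.dG;
    g.Wh += ws.gtmp;
    g.bh += sum(ws.dG, 0).t();
    ws.dH2 = ws.dH % z;
    ws.dH2 += ws.dG * P.Wh.t();
    // input-side gradient shares the r/z blocks; n block uses dn, not dghn
    ws.dG.cols(2 * h, 3 * h - 1) = ws.dn;
    g.wx += ws.dG.t() * Xb.col(t);
    g.bi += sum(ws.dG, 0).t();
    std::swap(ws.dH, ws.dH2);
  }
}

void adam_step(fvec& p, const fvec& g, fvec& m, fvec& v,
               float lr, float b1, float b2, float eps, float c1, float c2) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * (g % g);
  p -= lr * (m / c1) / (sqrt(v / c2) + eps);
}
void adam_step(fmat& p, const fmat& g, fmat& m, fmat& v,
               float lr, float b1, float b2, float eps, float c1, float c2) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * (g % g);
  p -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

// Gradients shrink geometrically along long backpropagation chains and fall
// into the denormal range, where every SSE operation takes a microcode
// penalty; flushing denormals to zero is numerically inconsequential here
// (they are below float resolution of the parameters) and several-fold
// faster.  The previous FPU state is restored on scope exit.
struct FlushDenormals {
  unsigned int old_csr;
  FlushDenormals() : old_csr(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() { _mm_setcsr(old_csr); }
};

} // namespace

// Final hidden states for all rows of X (n x d), no training machinery.
// [[Rcpp::export]]
arma::mat cpp_gru_hidden(List params, const arma::mat& X,
                         std::string direction, int chunk = 256) {
  FlushDenormals ftz;
  const int h = as<int>(params["h"]);
  List dirs = params["dirs"];
  const bool bi = direction == "bidirectional";
  const bool bwd_only = direction == "backward";
  const int ndir = bi ? 2 : 1;
  std::vector<DirParams> P;
  for (int j = 0; j < ndir; ++j) P.push_back(dir_from_list(dirs[j]));
  const int n = X.n_rows;
  mat out(n, ndir * h);
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(n, s + chunk);
    fmat Xb = conv_to<fmat>::from(X.rows(s, e - 1));
    for (int j = 0; j < ndir; ++j) {
      const bool backward = bi ? (j == 1) : bwd_only;
      fmat Hlast;
      forward_dir(P[j], Xb, h, backward, nullptr, nullptr, Hlast);
      out.submat(s, j * h, e - 1, (j + 1) * h - 1) = conv_to<mat>::from(Hlast);
    }
  }
  return out;
}

// Train for `epochs` epochs; perms (n x epochs, 0-based row indices from R)
// fixes the shuffling.  Returns updated parameters and the per-epoch mean
// binary cross-entropy.
// [[Rcpp::export]]
List cpp_gru_train(List params, const arma::mat& X, const arma::vec& y,
                   std::string direction, int epochs, double lr_,
                   double clip_, int batch, const IntegerMatrix& perms) {
  FlushDenormals ftz;
  const int h = as<int>(params["h"]);
  List dirs = params["dirs"];
  const bool bi = direction == "bidirectional";
  const bool bwd_only = direction == "backward";
  const int ndir = bi ? 2 : 1;
  const float lr = (float)lr_, clip = (float)clip_;
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;

  std::vector<DirParams> P;
  for (int j = 0; j < ndir; ++j) P.push_back(dir_from_list(dirs[j]));
  Head head;
  head.w = as<fvec>(as<NumericVector>(params["head_w"]));
  head.b = (float)as<double>(params["head_b"]);

  const int n = X.n_rows, T = X.n_cols;
  if (batch > n) batch = n;
  fvec yf = conv_to<fvec>::from(y);

  // Adam state
  std::vector<DirParams> M(ndir), V(ndir), G(ndir);
  for (int j = 0; j < ndir; ++j) { M[j].zeros(h); V[j].zeros(h); }
  fvec mw(ndir * h, fill::zeros), vw(ndir * h, fill::zeros);
  float mb = 0.0f, vb = 0.0f;
  long step = 0;

  // one trace per direction at the regular batch size, plus (if the last
  // batch is smaller) a second, smaller set
  const int nfull_rows = (n / batch) * batch;
  const int last_B = n - nfull_rows;
  std::vector<Trace> trace_full(ndir), trace_last(ndir);
  Workspace ws_full, ws_last;
  for (int j = 0; j < ndir; ++j) trace_full[j].alloc(batch, h, T);
  ws_full.alloc(batch, h);
  if (last_B > 0) {
    for (int j = 0; j < ndir; ++j) trace_last[j].alloc(last_B, h, T);
    ws_last.alloc(last_B, h);
  }

  std::vector<double> epoch_loss(epochs, 0.0);
  fmat Xb; fmat Hcat; fmat dHlast;
  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    for (int s = 0; s < n; s += batch) {
      const int e = std::min(n, s + batch);
      const int B = e - s;
      const bool full = (B == batch);
      std::vector<Trace>& tr = full ? trace_full : trace_last;
      Workspace& ws = full ? ws_full : ws_last;
      uvec idx(B);
      for (int i = 0; i < B; ++i) idx[i] = (uword)perms(s + i, ep);
      Xb = conv_to<fmat>::from(X.rows(idx));
      fvec yb = yf.elem(idx);

      Hcat.set_size(B, ndir * h);
      for (int j = 0; j < ndir; ++j) {
        const bool backward = bi ? (j == 1) : bwd_only;
        fmat Hlast;
        forward_dir(P[j], Xb, h, backward, &tr[j], &ws, Hlast);
        Hcat.cols(j * h, (j + 1) * h - 1) = Hlast;
      }
      fvec logit = Hcat * head.w + head.b;
      // stable BCE: log(1+e^-|l|) + max(l,0) - y*l
      fvec lmax = clamp(logit, 0.0f, std::numeric_limits<float>::max());
      loss_sum += accu(log1p(exp(-abs(logit))) + lmax - yb % logit);
      fvec dlogit = (1.0f / (1.0f + exp(-logit)) - yb) / (float)B;

      for (int j = 0; j < ndir; ++j) G[j].zeros(h);
      fvec gw = Hcat.t() * dlogit;
      float gb = accu(dlogit);
      for (int j = 0; j < ndir; ++j) {
        const bool backward = bi ? (j == 1) : bwd_only;
        dHlast = dlogit * head.w.subvec(j * h, (j + 1) * h - 1).t();
        backward_dir(P[j], Xb, h, backward, tr[j], ws, dHlast, G[j]);
      }

      // global-norm clipping over every parameter gradient
      double sq = dot(gw, gw) + (double)gb * gb;
      for (int j = 0; j < ndir; ++j) {
        sq += dot(G[j].wx, G[j].wx) + dot(G[j].bi, G[j].bi) +
              dot(G[j].bh, G[j].bh) + accu(G[j].Wh % G[j].Wh);
      }
      const float norm = (float)std::sqrt(sq);
      if (norm > clip) {
        const float sc = clip / norm;
        gw *= sc; gb *= sc;
        for (int j = 0; j < ndir; ++j) {
          G[j].wx *= sc; G[j].bi *= sc; G[j].bh *= sc; G[j].Wh *= sc;
        }
      }

      ++step;
      const float c1 = 1.0f - std::pow(b1, (float)step);
      const float c2 = 1.0f - std::pow(b2, (float)step);
      for (int j = 0; j < ndir; ++j) {
        adam_step(P[j].wx, G[j].wx, M[j].wx, V[j].wx, lr, b1, b2, eps, c1, c2);
        adam_step(P[j].bi, G[j].bi, M[j].bi, V[j].bi, lr, b1, b2, eps, c1, c2);
        adam_step(P[j].bh, G[j].bh, M[j].bh, V[j].bh, lr, b1, b2, eps, c1, c2);
        adam_step(P[j].Wh, G[j].Wh, M[j].Wh, V[j].Wh, lr, b1, b2, eps, c1, c2);
      }
      adam_step(head.w, gw, mw, vw, lr, b1, b2, eps, c1, c2);
      mb = b1 * mb + (1.0f - b1) * gb;
      vb = b2 * vb + (1.0f - b2) * gb * gb;
      head.b -= lr * (mb / c1) / (std::sqrt(vb / c2) + eps);
    }
    epoch_loss[ep] = loss_sum / n;
    Rcpp::checkUserInterrupt();
  }

  List dl(ndir);
  for (int j = 0; j < ndir; ++j) dl[j] = dir_to_list(P[j]);
  return List::create(
      Rcpp::Named("dirs") = dl,
      Rcpp::Named("head_w") = NumericVector(head.w.begin(), head.w.end()),
      Rcpp::Named("head_b") = (double)head.b,
      Rcpp::Named("h") = h,
      Rcpp::Named("loss") = epoch_loss);
}
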