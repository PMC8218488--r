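// Convolutional variational autoencoder for binary contact/dynamism tensors.
//
// Input samples are (C channels x R rows x M columns) binary tensors; all
// convolutions use a 1 x kernel window (rows are never mixed -- the contact
// and dynamism rows stay separate spatially), stride `stride` along the
// column (protein-atom) axis, valid padding, no pooling. Four conv layers
// with f filters feed two affine heads (latent mean / log-variance of size
// d); the decoder mirrors the encoder with transposed convolutions whose
// output lengths are taken from the encoder's shape trace, sigmoid output.
// Loss = summed binary cross-entropy + KL(q(z|x) || N(0,I)); optimizer is
// RMSprop. All randomness (init, shuffling, reparameterization noise) comes
// from R's RNG so results are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

const float LV_CLAMP = 10.0f;   // log-variance clamp
const float P_EPS = 1e-6f;      // BCE probability clamp

struct Shape {
  int C, R, M, f, d, K, S, L;   // L = number of conv layers
  std::vector<int> len;         // len[0] = M, len[l] = positions after layer l
  int feat() const { return f * R * len[L]; }
};

Shape make_shape(int C, int R, int M, int f, int d, int K, int S, int L) {
  Shape sh; sh.C = C; sh.R = R; sh.M = M; sh.f = f; sh.d = d; sh.K = K; sh.S = S; sh.L = L;
  sh.len.resize(L + 1);
  sh.len[0] = M;
  for (int l = 1; l <= L; ++l) {
    int prev = sh.len[l - 1];
    if (prev < K) stop("input length too small for %d valid conv layers", L);
    sh.len[l] = (prev - K) / S + 1;
  }
  return sh;
}

// Gather: A (C x L*Beff) -> Xcol (C*K x P*Beff), column p + P*br.
// Xcol rows are ordered c + C*k so each (k, column) block is one contiguous
// channel vector of A and the inner copy is a straight memcpy.
void im2col(const fmat& A, int C, int L, int Beff, int K, int S, int P, fmat& Xcol) {
  Xcol.set_size(C * K, P * Beff);
  const float* a = A.memptr();
  float* xc = Xcol.memptr();
  const size_t ck = (size_t)C * K;
  for (int br = 0; br < Beff; ++br) {
    const size_t a0 = (size_t)L * br;
    float* col = xc + ck * (size_t)P * br;
    for (int p = 0; p < P; ++p, col += ck) {
      const float* src = a + (size_t)C * (S * p + a0);
      for (int k = 0; k < K; ++k)
        std::memcpy(col + (size_t)C * k, src + (size_t)C * k, C * sizeof(float));
    }
  }
}

// Scatter-add transpose of im2col: Xcol (C*K x P*Beff) += into Y (C x L*Beff).
void col2im_add(const fmat& Xcol, int C, int L, int Beff, int K, int S, int P, fmat& Y) {
  const float* xc = Xcol.memptr();
  float* y = Y.memptr();
  const size_t ck = (size_t)C * K;
  for (int br = 0; br < Beff; ++br) {
    const size_t a0 = (size_t)L * br;
    const float* col = xc + ck * (size_t)P * br;
    for (int p = 0; p < P; ++p, col += ck) {
      float* dst = y + (size_t)C * (S * p + a0);
      for (int k = 0; k < K; ++k) {
        const float* s = col + (size_t)C * k;
        float* d = dst + (size_t)C * k;
        for (int c = 0; c < C; ++c) d[c] += s[c];
      }
    }
  }
}

fmat as_fmat(SEXP s) {
  NumericMatrix m(s);
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

NumericMatrix as_Rmat(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}

struct Params {
  std::vector<fmat> W;   // conv weights, W[l]: (f_out x C_in*K)
  std::vector<fvec> b;
  fmat Wmu, Wlv, Wd;     // heads (d x F), decoder dense (F x d)
  fvec bmu, blv, bd;
  std::vector<fmat> G;   // deconv weights, G[l]: same shape as W[l]
  std::vector<fvec> g;   // deconv bias over C_in channels of layer l
};

float glorot_limit(int fan_in, int fan_out) {
  return std::sqrt(6.0f / (float)(fan_in + fan_out));
}

fmat rand_mat(int r, int c, float lim) {
  fmat m(r, c);
  for (int j = 0; j < c; ++j)
    for (int i = 0; i < r; ++i) m(i, j) = (float)((unif_rand() * 2.0 - 1.0) * lim);
  return m;
}

Params init_params(const Shape& sh) {
  Params P;
  P.W.resize(sh.L); P.b.resize(sh.L); P.G.resize(sh.L); P.g.resize(sh.L);
  for (int l = 0; l < sh.L; ++l) {
    int cin = (l == 0 ? sh.C : sh.f);
    float lim = glorot_limit(cin * sh.K, sh.f * sh.K);
    P.W[l] = rand_mat(sh.f, cin * sh.K, lim);
    P.b[l] = fvec(sh.f, arma::fill::zeros);
    P.G[l] = rand_mat(sh.f, cin * sh.K, lim);
    P.g[l] = fvec(cin, arma::fill::zeros);
  }
  int F = sh.feat();
  float liml = glorot_limit(F, sh.d);
  P.Wmu = rand_mat(sh.d, F, liml); P.bmu = fvec(sh.d, arma::fill::zeros);
  P.Wlv = rand_mat(sh.d, F, liml); P.blv = fvec(sh.d, arma::fill::zeros);
  P.Wd  = rand_mat(F, sh.d, liml); P.bd  = fvec(F, arma::fill::zeros);
  return P;
}

List params_to_list(const Params& P) {
  List out;
  for (size_t l = 0; l < P.W.size(); ++l) {
    out[std::string("W") + std::to_string(l + 1)] = as_Rmat(P.W[l]);
    out[std::string("b") + std::to_string(l + 1)] = NumericVector(P.b[l].begin(), P.b[l].end());
    out[std::string("G") + std::to_string(l + 1)] = as_Rmat(P.G[l]);
    out[std::string("g") + std::to_string(l + 1)] = NumericVector(P.g[l].begin(), P.g[l].end());
  }
  out["Wmu"] = as_Rmat(P.Wmu); out["bmu"] = NumericVector(P.bmu.begin(), P.bmu.end());
  out["Wlv"] = as_Rmat(P.Wlv); out["blv"] = NumericVector(P.blv.begin(), P.blv.end());
  out["Wd"]  = as_Rmat(P.Wd);  out["bd"]  = NumericVector(P.bd.begin(), P.bd.end());
  return out;
}

fvec as_fvec(SEXP s) {
  NumericVector v(s);
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = (float)v[i];
  return out;
}

Params params_from_list(const List& w, int L) {
  Params P;
  P.W.resize(L); P.b.resize(L); P.G.resize(L); P.g.resize(L);
  for (int l = 0; l < L; ++l) {
    std::string i = std::to_string(l + 1);
    P.W[l] = as_fmat(w["W" + i]); P.b[l] = as_fvec(w["b" + i]);
    P.G[l] = as_fmat(w["G" + i]); P.g[l] = as_fvec(w["g" + i]);
  }
  P.Wmu = as_fmat(w["Wmu"]); P.bmu = as_fvec(w["bmu"]);
  P.Wlv = as_fmat(w["Wlv"]); P.blv = as_fvec(w["blv"]);
  P.Wd  = as_fmat(w["Wd"]);  P.bd  = as_fvec(w["bd"]);
  return P;
}

// Load samples `idx` of the R array (dims T,C,R,M) as A0 (C x M*R*B).
void load_batch(const double* x, int T, const Shape& sh,
                const std::vector<int>& idx, fmat& A0) {
  const int B = (int)idx.size();
  A0.set_size(sh.C, sh.M * sh.R * B);
  for (int b = 0; b < B; ++b) {
    const int t = idx[b];
    for (int r = 0; r < sh.R; ++r) {
      const int col0 = sh.M * (r + sh.R * b);
      for (int m = 0; m < sh.M; ++m)
        for (int c = 0; c < sh.C; ++c)
          A0(c, col0 + m) = (float)x[t + (R_xlen_t)T * (c + sh.C * (r + sh.R * m))];
    }
  }
}

struct Cache {
  std::vector<fmat> A;      // encoder activations, A[0] = input
  std::vector<fmat> Xcol;   // encoder im2col per layer
  fmat H, mu, lv, eps, z;   // flatten, heads, noise, sample
  fmat Hd;                  // decoder dense activation
  std::vector<fmat> U;      // decoder activations per layer (U[L] = reshape(Hd))
  fmat recon;               // sigmoid output (C x M*R*B)
};

// flatten index: rows of H ordered as c + f*(p + P*r)
void flatten(const fmat& AL, const Shape& sh, int B, fmat& H) {
  const int P = sh.len[sh.L];
  H.set_size(sh.feat(), B);
  for (int b = 0; b < B; ++b)
    for (int r = 0; r < sh.R; ++r) {
      const int col0 = P * (r + sh.R * b);
      for (int p = 0; p < P; ++p)
        for (int c = 0; c < sh.f; ++c)
          H(c + sh.f * (p + P * r), b) = AL(c, col0 + p);
    }
}

void unflatten(const fmat& H, const Shape& sh, int B, fmat& AL) {
  const int P = sh.len[sh.L];
  AL.set_size(sh.f, P * sh.R * B);
  for (int b = 0; b < B; ++b)
    for (int r = 0; r < sh.R; ++r) {
      const int col0 = P * (r + sh.R * b);
      for (int p = 0; p < P; ++p)
        for (int c = 0; c < sh.f; ++c)
          AL(c, col0 + p) = H(c + sh.f * (p + P * r), b);
    }
}

void forward(const Params& P, const Shape& sh, const fmat& A0, int B,
             bool sample, Cache& cc) {
  const int Beff = sh.R * B;
  cc.A.assign(sh.L + 1, fmat());
  cc.Xcol.assign(sh.L, fmat());
  cc.A[0] = A0;
  for (int l = 0; l < sh.L; ++l) {
    const int cin = (l == 0 ? sh.C : sh.f);
    im2col(cc.A[l], cin, sh.len[l], Beff, sh.K, sh.S, sh.len[l + 1], cc.Xcol[l]);
    fmat Z = P.W[l] * cc.Xcol[l];
    Z.each_col() += P.b[l];
    cc.A[l + 1] = arma::clamp(Z, 0.0f, std::numeric_limits<float>::max());   // ReLU
  }
  flatten(cc.A[sh.L], sh, B, cc.H);
  cc.mu = P.Wmu * cc.H; cc.mu.each_col() += P.bmu;
  cc.lv = P.Wlv * cc.H; cc.lv.each_col() += P.blv;
  cc.lv = arma::clamp(cc.lv, -LV_CLAMP, LV_CLAMP);
  if (sample) {
    cc.eps.set_size(sh.d, B);
    for (int b = 0; b < B; ++b)
      for (int j = 0; j < sh.d; ++j) cc.eps(j, b) = (float)norm_rand();
    cc.z = cc.mu + arma::exp(0.5f * cc.lv) % cc.eps;
  } else {
    cc.z = cc.mu;
  }
  fmat Hd = P.Wd * cc.z; Hd.each_col() += P.bd;
  cc.Hd = arma::clamp(Hd, 0.0f, std::numeric_limits<float>::max());
  cc.U.assign(sh.L + 1, fmat());
  unflatten(cc.Hd, sh, B, cc.U[sh.L]);
  for (int l = sh.L - 1; l >= 0; --l) {
    const int cin = (l == 0 ? sh.C : sh.f);
    fmat XT = P.G[l].t() * cc.U[l + 1];                 // (cin*K x P*Beff)
    fmat Y(cin, sh.len[l] * Beff, arma::fill::zeros);   // tail cells stay bias-only
    col2im_add(XT, cin, sh.len[l], Beff, sh.K, sh.S, sh.len[l + 1], Y);
    Y.each_col() += P.g[l];
    if (l > 0) {
      cc.U[l] = arma::clamp(Y, 0.0f, std::numeric_limits<float>::max());
    } else {
      cc.recon = 1.0f / (1.0f + arma::exp(-Y));         // sigmoid
    }
  }
}

double bce_loss(const fmat& X, const fmat& Pr) {
  double s = 0.0;
  for (arma::uword i = 0; i < X.n_elem; ++i) {
    double p = std::min(std::max((double)Pr(i), (double)P_EPS), 1.0 - (double)P_EPS);
    s -= X(i) > 0.5f ? std::log(p) : std::log(1.0 - p);
  }
  return s;
}

double kl_loss(const fmat& mu, const fmat& lv) {
  double s = 0.0;
  for (arma::uword i = 0; i < mu.n_elem; ++i)
    s += -0.5 * (1.0 + lv(i) - mu(i) * mu(i) - std::exp((double)lv(i)));
  return s;
}

struct Grads {
  std::vector<fmat> W; std::vector<fvec> b;
  fmat Wmu, Wlv, Wd; fvec bmu, blv, bd;
  std::vector<fmat> G; std::vector<fvec> g;
};

void backward(const Params& P, const Shape& sh, const fmat& A0, int B,
              const Cache& cc, Grads& gr) {
  const int Beff = sh.R * B;
  const float invB = 1.0f / (float)B;
  gr.W.assign(sh.L, fmat()); gr.b.assign(sh.L, fvec());
  gr.G.assign(sh.L, fmat()); gr.g.assign(sh.L, fvec());

  // output layer: BCE + sigmoid -> dPre = (p - x)/B
  fmat dY = (cc.recon - A0) * invB;
  fmat dU;                                    // grad wrt decoder activation above
  for (int l = 0; l < sh.L; ++l) {
    const int cin = (l == 0 ? sh.C : sh.f);
    if (l > 0) {                              // ReLU gate (pre-act sign == act sign)
      dY = dU;
      dY.elem(arma::find(cc.U[l] <= 0)).zeros();
    }
    gr.g[l] = arma::sum(dY, 1);
    fmat dXT;
    im2col(dY, cin, sh.len[l], Beff, sh.K, sh.S, sh.len[l + 1], dXT);
    gr.G[l] = cc.U[l + 1] * dXT.t();
    dU = P.G[l] * dXT;
  }
  // dU now holds grad wrt U[L] (reshape of Hd after ReLU)
  fmat dHd(sh.feat(), B);
  {
    fmat tmp;
    flatten(dU, sh, B, tmp);
    tmp.elem(arma::find(cc.Hd <= 0)).zeros();
    dHd = tmp;
  }
  gr.Wd = dHd * cc.z.t();
  gr.bd = arma::sum(dHd, 1);
  fmat dz = P.Wd.t() * dHd;

  // KL grads (mean over batch)
  fmat dmu = cc.mu * invB + dz;
  fmat dlv = 0.5f * (arma::exp(cc.lv) - 1.0f) * invB;
  if (cc.eps.n_elem > 0)
    dlv += dz % cc.eps % (0.5f * arma::exp(0.5f * cc.lv));

  gr.Wmu = dmu * cc.H.t(); gr.bmu = arma::sum(dmu, 1);
  gr.Wlv = dlv * cc.H.t(); gr.blv = arma::sum(dlv, 1);
  fmat dH = P.Wmu.t() * dmu + P.Wlv.t() * dlv;

  fmat dA;                                    // grad wrt encoder activation
  unflatten(dH, sh, B, dA);
  for (int l = sh.L - 1; l >= 0; --l) {
    const int cin = (l == 0 ? sh.C : sh.f);
    fmat dZ = dA;
    dZ.elem(arma::find(cc.A[l + 1] <= 0)).zeros();
    gr.W[l] = dZ * cc.Xcol[l].t();
    gr.b[l] = arma::sum(dZ, 1);
    if (l > 0) {
      fmat dXcol = P.W[l].t() * dZ;
      dA.zeros(cin, sh.len[l] * Beff);
      col2im_add(dXcol, cin, sh.len[l], Beff, sh.K, sh.S, sh.len[l + 1], dA);
    }
  }
}

struct RmsState { fmat m; bool init = false; };

void rms_update(fmat& w, const fmat& g, RmsState& st, float lr, float rho, float eps) {
  if (!st.init) { st.m.zeros(w.n_rows, w.n_cols); st.init = true; }
  st.m = rho * st.m + (1.0f - rho) * (g % g);
  w -= lr * g / (arma::sqrt(st.m) + eps);
}

void rms_update_v(fvec& w, const fvec& g, fvec& m, float lr, float rho, float eps) {
  if (m.n_elem != w.n_elem) m.zeros(w.n_elem);
  m = rho * m + (1.0f - rho) * (g % g);
  w -= lr * g / (arma::sqrt(m) + eps);
}

} // namespace

// [[Rcpp::export]]
List cpp_cvae_init(int C, int R, int M, int f, int d,
                   int kernel = 7, int stride = 2, int nlayers = 4) {
  Shape sh = make_shape(C, R, M, f, d, kernel, stride, nlayers);
  Params P = init_params(sh);
  return params_to_list(P);
}

// [[Rcpp::export]]
List cpp_cvae_forward(NumericVector x, List weights,
                      int kernel = 7, int stride = 2, int nlayers = 4) {
  IntegerVector dims = x.attr("dim");
  const int T = dims[0], C = dims[1], R = dims[2], M = dims[3];
  Params P = params_from_list(weights, nlayers);
  Shape sh = make_shape(C, R, M, P.W[0].n_rows, P.Wmu.n_rows, kernel, stride, nlayers);
  std::vector<int> idx(T);
  for (int t = 0; t < T; ++t) idx[t] = t;
  fmat A0; load_batch(REAL(x), T, sh, idx, A0);
  Cache cc;
  forward(P, sh, A0, T, false, cc);
  NumericVector recon(x.size());
  recon.attr("dim") = dims;
  double* rp = REAL(recon);
  for (int b = 0; b < T; ++b)
    for (int r = 0; r < sh.R; ++r)
      for (int m = 0; m < sh.M; ++m)
        for (int c = 0; c < sh.C; ++c)
          rp[b + (R_xlen_t)T * (c + sh.C * (r + sh.R * m))] =
            cc.recon(c, m + sh.M * (r + sh.R * b));
  return List::create(_["mu"] = as_Rmat(cc.mu.t()),
                      _["logvar"] = as_Rmat(cc.lv.t()),
                      _["recon"] = recon);
}

// [[Rcpp::export]]
List cpp_cvae_train(NumericVector x, List weights, double lr = 0.005,
                    int max_epochs = 600, int patience = 10, int batch = 64,
                    int kernel = 7, int stride = 2, int nlayers = 4) {
  IntegerVector dims = x.attr("dim");
  const int T = dims[0], C = dims[1], R = dims[2], M = dims[3];
  Params P = params_from_list(weights, nlayers);
  Shape sh = make_shape(C, R, M, P.W[0].n_rows, P.Wmu.n_rows, kernel, stride, nlayers);
  const double* xp = REAL(x);
  const float rho = 0.9f, eps = 1e-8f;

  std::vector<RmsState> sW(sh.L), sG(sh.L);
  RmsState sWmu, sWlv, sWd;
  std::vector<fvec> sb(sh.L), sg(sh.L);
  fvec sbmu, sblv, sbd;

  std::vector<double> hist_total, hist_bce, hist_kl;
  double best = R_PosInf;
  int wait = 0, epochs_run = 0;

  std::vector<int> perm(T);
  for (int t = 0; t < T; ++t) perm[t] = t;

  for (int ep = 0; ep < max_epochs; ++ep) {
    // Fisher-Yates with R's RNG
    for (int i = T - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double tot = 0.0, tot_bce = 0.0, tot_kl = 0.0;
    for (int start = 0; start < T; start += batch) {
      const int B = std::min(batch, T - start);
      std::vector<int> idx(perm.begin() + start, perm.begin() + start + B);
      fmat A0; load_batch(xp, T, sh, idx, A0);
      Cache cc;
      forward(P, sh, A0, B, true, cc);
      double lb = bce_loss(A0, cc.recon), lk = kl_loss(cc.mu, cc.lv);
      tot_bce += lb; tot_kl += lk; tot += lb + lk;
      Grads gr;
      backward(P, sh, A0, B, cc, gr);
      for (int l = 0; l < sh.L; ++l) {
        rms_update(P.W[l], gr.W[l], sW[l], (float)lr, rho, eps);
        rms_update(P.G[l], gr.G[l], sG[l], (float)lr, rho, eps);
        rms_update_v(P.b[l], gr.b[l], sb[l], (float)lr, rho, eps);
        rms_update_v(P.g[l], gr.g[l], sg[l], (float)lr, rho, eps);
      }
      rms_update(P.Wmu, gr.Wmu, sWmu, (float)lr, rho, eps);
      rms_update(P.Wlv, gr.Wlv, sWlv, (float)lr, rho, eps);
      rms_update(P.Wd, gr.Wd, sWd, (float)lr, rho, eps);
      rms_update_v(P.bmu, gr.bmu, sbmu, (float)lr, rho, eps);
      rms_update_v(P.blv, gr.blv, sblv, (float)lr, rho, eps);
      rms_update_v(P.bd, gr.bd, sbd, (float)lr, rho, eps);
    }
    hist_total.push_back(tot); hist_bce.push_back(tot_bce); hist_kl.push_back(tot_kl);
    epochs_run = ep + 1;
    if (tot < best) { best = tot; wait = 0; } else if (++wait >= patience) break;
    if (ep % 50 == 0) Rcpp::checkUserInterrupt();
  }

  // deterministic embedding: latent means over all frames, in chunks
  fmat mu_all(sh.d, T);
  const int chunk = 256;
  for (int start = 0; start < T; start += chunk) {
    const int B = std::min(chunk, T - start);
    std::vector<int> idx(B);
    for (int b = 0; b < B; ++b) idx[b] = start + b;
    fmat A0; load_batch(xp, T, sh, idx, A0);
    Cache cc;
    forward(P, sh, A0, B, false, cc);
    mu_all.cols(start, start + B - 1) = cc.mu;
  }
  return List::create(_["weights"] = params_to_list(P),
                      _["loss"] = wrap(hist_total),
                      _["bce"] = wrap(hist_bce),
                      _["kl"] = wrap(hist_kl),
                      _["mu"] = as_Rmat(mu_all.t()),
                      _["epochs"] = epochs_run);
}
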