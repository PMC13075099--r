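// 1-D convolutional IMF classifier: five conv-BN-ReLU-pool blocks and three
// fully connected layers, trained with Adam on binary cross-entropy logits.
// Implemented directly over BLAS (im2col + GEMM) in single precision.
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const float BN_EPS = 1e-5f;
static const int NBLOCK = 5;

enum PoolMode { HYBRID = 0, PURE_MAX = 1, PURE_ADAPTIVE = 2 };

struct Geom {
  std::vector<int> k, cin, cout, stride, pad, Lin, Lconv, Lpool;
  int A, flatten;
  std::vector<int> fc_in, fc_out;
  int pooling;
};

static Geom make_geom(const IntegerVector &kernels, const IntegerVector &channels,
                      int input_len, int adaptive_out, const IntegerVector &fc_dims,
                      int first_stride, int pooling) {
  Geom g;
  g.A = adaptive_out;
  g.pooling = pooling;
  int L = input_len;
  for (int i = 0; i < NBLOCK; ++i) {
    g.k.push_back(kernels[i]);
    g.cin.push_back(i == 0 ? 1 : channels[i - 1]);
    g.cout.push_back(channels[i]);
    g.stride.push_back(i == 0 ? first_stride : 1);
    g.pad.push_back(kernels[i] / 2);
    g.Lin.push_back(L);
    int lc = (L + 2 * g.pad[i] - g.k[i]) / g.stride[i] + 1;
    if (lc < 1) stop("input_len too short for the convolution stack");
    g.Lconv.push_back(lc);
    int lp = (i == NBLOCK - 1) ? adaptive_out : lc / 2;
    if (lp < 1) stop("input_len too short for the pooling stack");
    g.Lpool.push_back(lp);
    L = lp;
  }
  g.flatten = g.cout[NBLOCK - 1] * g.A;
  int fin = g.flatten;
  for (int j = 0; j < 3; ++j) {
    g.fc_in.push_back(fin);
    g.fc_out.push_back(fc_dims[j]);
    fin = fc_dims[j];
  }
  return g;
}

struct Weights {
  std::vector<arma::fmat> conv_w;   // Cout x Cin*k, row layout j*Cin + c
  std::vector<arma::fvec> conv_b, gamma, beta, rmean, rvar;
  std::vector<arma::fmat> fc_w;
  std::vector<arma::fvec> fc_b;
};

static Weights weights_from_list(const List &wl) {
  Weights w;
  List cw = wl["conv_w"], cb = wl["conv_b"], ga = wl["gamma"], be = wl["beta"],
       rm = wl["rmean"], rv = wl["rvar"], fw = wl["fc_w"], fb = wl["fc_b"];
  for (int i = 0; i < NBLOCK; ++i) {
    w.conv_w.push_back(arma::conv_to<arma::fmat>::from(as<arma::mat>(cw[i])));
    w.conv_b.push_back(arma::conv_to<arma::fvec>::from(as<arma::vec>(cb[i])));
    w.gamma.push_back(arma::conv_to<arma::fvec>::from(as<arma::vec>(ga[i])));
    w.beta.push_back(arma::conv_to<arma::fvec>::from(as<arma::vec>(be[i])));
    w.rmean.push_back(arma::conv_to<arma::fvec>::from(as<arma::vec>(rm[i])));
    w.rvar.push_back(arma::conv_to<arma::fvec>::from(as<arma::vec>(rv[i])));
  }
  for (int j = 0; j < 3; ++j) {
    w.fc_w.push_back(arma::conv_to<arma::fmat>::from(as<arma::mat>(fw[j])));
    w.fc_b.push_back(arma::conv_to<arma::fvec>::from(as<arma::vec>(fb[j])));
  }
  return w;
}

static List weights_to_list(const Weights &w) {
  List cw(NBLOCK), cb(NBLOCK), ga(NBLOCK), be(NBLOCK), rm(NBLOCK), rv(NBLOCK);
  for (int i = 0; i < NBLOCK; ++i) {
    cw[i] = wrap(arma::conv_to<arma::mat>::from(w.conv_w[i]));
    cb[i] = wrap(arma::conv_to<arma::vec>::from(w.conv_b[i]));
    ga[i] = wrap(arma::conv_to<arma::vec>::from(w.gamma[i]));
    be[i] = wrap(arma::conv_to<arma::vec>::from(w.beta[i]));
    rm[i] = wrap(arma::conv_to<arma::vec>::from(w.rmean[i]));
    rv[i] = wrap(arma::conv_to<arma::vec>::from(w.rvar[i]));
  }
  List fw(3), fb(3);
  for (int j = 0; j < 3; ++j) {
    fw[j] = wrap(arma::conv_to<arma::mat>::from(w.fc_w[j]));
    fb[j] = wrap(arma::conv_to<arma::vec>::from(w.fc_b[j]));
  }
  return List::create(_["conv_w"] = cw, _["conv_b"] = cb, _["gamma"] = ga,
                      _["beta"] = be, _["rmean"] = rm, _["rvar"] = rv,
                      _["fc_w"] = fw, _["fc_b"] = fb);
}

// ---- primitive ops ----------------------------------------------------

static void im2col(const arma::fmat &x, int k, int stride, int pad, arma::fmat &col) {
  const int Cin = x.n_rows, Lin = x.n_cols;
  const int Lout = (Lin + 2 * pad - k) / stride + 1;
  col.zeros(Cin * k, Lout);
  for (int t = 0; t < Lout; ++t) {
    const int s0 = t * stride - pad;
    for (int j = 0; j < k; ++j) {
      const int s = s0 + j;
      if (s < 0 || s >= Lin) continue;
      std::memcpy(col.colptr(t) + (size_t)j * Cin, x.colptr(s), Cin * sizeof(float));
    }
  }
}

static void col2im(const arma::fmat &dcol, int k, int stride, int pad,
                   int Cin, int Lin, arma::fmat &dx) {
  const int Lout = dcol.n_cols;
  dx.zeros(Cin, Lin);
  for (int t = 0; t < Lout; ++t) {
    const int s0 = t * stride - pad;
    for (int j = 0; j < k; ++j) {
      const int s = s0 + j;
      if (s < 0 || s >= Lin) continue;
      float *dst = dx.colptr(s);
      const float *src = dcol.colptr(t) + (size_t)j * Cin;
      for (int c = 0; c < Cin; ++c) dst[c] += src[c];
    }
  }
}

static inline void adaptive_bins(int L, int O, int t, int &s, int &e) {
  s = (int)std::floor((double)t * L / O);
  e = (int)std::ceil((double)(t + 1) * L / O);
  if (e > L) e = L;
  if (e <= s) e = s + 1;
}

// ---- forward (inference, running BN stats, per-sample) ----------------

// [[Rcpp::export]]
NumericVector cnn_forward_cpp(const List &wl, const IntegerVector &kernels,
                              const IntegerVector &channels, int input_len,
                              int adaptive_out, const IntegerVector &fc_dims,
                              int first_stride, int pooling,
                              const arma::mat &X) {
  Geom g = make_geom(kernels, channels, input_len, adaptive_out, fc_dims,
                     first_stride, pooling);
  Weights w = weights_from_list(wl);
  const int n = X.n_rows;
  if ((int)X.n_cols != input_len) stop("input rows must have length input_len");
  NumericVector out(n);
  arma::fmat col;
  for (int s = 0; s < n; ++s) {
    arma::fmat a(1, input_len);
    for (int t = 0; t < input_len; ++t) a(0, t) = (float)X(s, t);
    for (int i = 0; i < NBLOCK; ++i) {
      im2col(a, g.k[i], g.stride[i], g.pad[i], col);
      arma::fmat z = w.conv_w[i] * col;
      z.each_col() += w.conv_b[i];
      for (int c = 0; c < g.cout[i]; ++c) {
        const float inv = 1.0f / std::sqrt(w.rvar[i][c] + BN_EPS);
        z.row(c) = (z.row(c) - w.rmean[i][c]) * inv * w.gamma[i][c] + w.beta[i][c];
      }
      z.transform([](float v) { return v > 0 ? v : 0.0f; });
      const bool last = (i == NBLOCK - 1);
      const bool max_pool =
          (g.pooling == PURE_MAX) || (g.pooling == HYBRID && !last);
      const int O = g.Lpool[i];
      arma::fmat p(g.cout[i], O);
      if (last || g.pooling == PURE_ADAPTIVE) {
        for (int t = 0; t < O; ++t) {
          int s0, e0;
          adaptive_bins(g.Lconv[i], O, t, s0, e0);
          if (max_pool)
            p.col(t) = arma::max(z.cols(s0, e0 - 1), 1);
          else
            p.col(t) = arma::mean(z.cols(s0, e0 - 1), 1);
        }
      } else {
        for (int t = 0; t < O; ++t)
          p.col(t) = arma::max(z.col(2 * t), z.col(2 * t + 1));
      }
      a = p;
    }
    arma::fvec f((float *)a.memptr(), g.flatten, true);
    for (int j = 0; j < 3; ++j) {
      arma::fvec h = w.fc_w[j] * f + w.fc_b[j];
      if (j < 2) h.transform([](float v) { return v > 0 ? v : 0.0f; });
      f = h;
    }
    out[s] = (double)f[0];
  }
  return out;
}

// ---- initialization ---------------------------------------------------

// [[Rcpp::export]]
List cnn_init_cpp(const IntegerVector &kernels, const IntegerVector &channels,
                  int input_len, int adaptive_out, const IntegerVector &fc_dims,
                  int first_stride, int pooling, int seed) {
  Geom g = make_geom(kernels, channels, input_len, adaptive_out, fc_dims,
                     first_stride, pooling);
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  Weights w;
  for (int i = 0; i < NBLOCK; ++i) {
    const int fan_in = g.cin[i] * g.k[i];
    const double bound = std::sqrt(1.0 / fan_in);
    arma::fmat W(g.cout[i], fan_in);
    for (auto &v : W) v = (float)(bound * unif(rng));
    w.conv_w.push_back(W);
    arma::fvec b(g.cout[i]);
    for (auto &v : b) v = (float)(bound * unif(rng));
    w.conv_b.push_back(b);
    w.gamma.push_back(arma::fvec(g.cout[i], arma::fill::ones));
    w.beta.push_back(arma::fvec(g.cout[i], arma::fill::zeros));
    w.rmean.push_back(arma::fvec(g.cout[i], arma::fill::zeros));
    w.rvar.push_back(arma::fvec(g.cout[i], arma::fill::ones));
  }
  for (int j = 0; j < 3; ++j) {
    const double bound = std::sqrt(1.0 / g.fc_in[j]);
    arma::fmat W(g.fc_out[j], g.fc_in[j]);
    for (auto &v : W) v = (float)(bound * unif(rng));
    w.fc_w.push_back(W);
    arma::fvec b(g.fc_out[j]);
    for (auto &v : b) v = (float)(bound * unif(rng));
    w.fc_b.push_back(b);
  }
  return weights_to_list(w);
}

// ---- training ---------------------------------------------------------

struct Adam {
  std::vector<arma::fmat> mW, vW;
  std::vector<arma::fvec> mb, vb;
  long t = 0;
};

static void adam_step_mat(arma::fmat &w, const arma::fmat &g, arma::fmat &m,
                          arma::fmat &v, double lr, double wd, long t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  arma::fmat grad = g + (float)wd * w;
  m = b1 * m + (1 - b1) * grad;
  v = b2 * v + (1 - b2) * (grad % grad);
  const float c1 = 1.0f / (1.0f - std::pow(b1, (float)t));
  const float c2 = 1.0f / (1.0f - std::pow(b2, (float)t));
  w -= (float)lr * (m * c1) / (arma::sqrt(v * c2) + eps);
}

static void adam_step_vec(arma::fvec &w, const arma::fvec &g, arma::fvec &m,
                          arma::fvec &v, double lr, double wd, long t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  arma::fvec grad = g + (float)wd * w;
  m = b1 * m + (1 - b1) * grad;
  v = b2 * v + (1 - b2) * (grad % grad);
  const float c1 = 1.0f / (1.0f - std::pow(b1, (float)t));
  const float c2 = 1.0f / (1.0f - std::pow(b2, (float)t));
  w -= (float)lr * (m * c1) / (arma::sqrt(v * c2) + eps);
}

// [[Rcpp::export]]
List cnn_train_cpp(const List &wl, const IntegerVector &kernels,
                   const IntegerVector &channels, int input_len,
                   int adaptive_out, const IntegerVector &fc_dims,
                   int first_stride, int pooling, const arma::mat &X,
                   const arma::vec &y, int epochs, int batch, double lr,
                   double weight_decay, double dropout, int seed) {
  Geom g = make_geom(kernels, channels, input_len, adaptive_out, fc_dims,
                     first_stride, pooling);
  Weights w = weights_from_list(wl);
  const int n = X.n_rows;
  if ((int)X.n_cols != input_len) stop("input rows must have length input_len");

  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X); // n x L

  Adam ad;
  for (int i = 0; i < NBLOCK; ++i) {
    ad.mW.push_back(arma::fmat(arma::size(w.conv_w[i]), arma::fill::zeros));
    ad.vW.push_back(arma::fmat(arma::size(w.conv_w[i]), arma::fill::zeros));
    ad.mb.push_back(arma::fvec(arma::size(w.conv_b[i]), arma::fill::zeros));
    ad.vb.push_back(arma::fvec(arma::size(w.conv_b[i]), arma::fill::zeros));
    // gamma/beta states appended after convs to keep indexing simple
  }
  std::vector<arma::fvec> mg(NBLOCK), vg(NBLOCK), mbe(NBLOCK), vbe(NBLOCK);
  for (int i = 0; i < NBLOCK; ++i) {
    mg[i].zeros(g.cout[i]); vg[i].zeros(g.cout[i]);
    mbe[i].zeros(g.cout[i]); vbe[i].zeros(g.cout[i]);
  }
  std::vector<arma::fmat> mfW(3), vfW(3);
  std::vector<arma::fvec> mfb(3), vfb(3);
  for (int j = 0; j < 3; ++j) {
    mfW[j].zeros(arma::size(w.fc_w[j])); vfW[j].zeros(arma::size(w.fc_w[j]));
    mfb[j].zeros(arma::size(w.fc_b[j])); vfb[j].zeros(arma::size(w.fc_b[j]));
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector epoch_loss(epochs);
  arma::fmat col, dcol, dx;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with explicit draws for cross-library determinism
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      std::swap(order[i], order[u(rng)]);
    }
    double loss_sum = 0.0;
    int nb = 0;
    for (int b0 = 0; b0 < n; b0 += batch) {
      const int B = std::min(batch, n - b0);
      // caches
      std::vector<arma::fcube> xin(NBLOCK), xhat(NBLOCK), pooled(NBLOCK);
      std::vector<arma::Cube<arma::uword>> argmax(NBLOCK);
      std::vector<arma::fvec> bmean(NBLOCK), binvstd(NBLOCK);

      arma::fcube a(1, input_len, B);
      for (int s = 0; s < B; ++s)
        for (int t = 0; t < input_len; ++t) a(0, t, s) = Xf(order[b0 + s], t);

      for (int i = 0; i < NBLOCK; ++i) {
        xin[i] = a;
        arma::fcube z(g.cout[i], g.Lconv[i], B);
        for (int s = 0; s < B; ++s) {
          im2col(a.slice(s), g.k[i], g.stride[i], g.pad[i], col);
          z.slice(s) = w.conv_w[i] * col;
          z.slice(s).each_col() += w.conv_b[i];
        }
        // batch norm over (L, B) per channel
        const double N = (double)g.Lconv[i] * B;
        arma::fvec mu(g.cout[i]), var(g.cout[i]);
        for (int c = 0; c < g.cout[i]; ++c) {
          double sum = 0, sq = 0;
          for (int s = 0; s < B; ++s) {
            const float *p = z.slice(s).memptr();
            for (int t = 0; t < g.Lconv[i]; ++t) {
              const float v = p[(size_t)t * g.cout[i] + c];
              sum += v; sq += (double)v * v;
            }
          }
          const double m = sum / N, vv = sq / N - m * m;
          mu[c] = (float)m;
          var[c] = (float)std::max(vv, 0.0);
          w.rmean[i][c] = 0.9f * w.rmean[i][c] + 0.1f * mu[c];
          const float unb = (N > 1) ? var[c] * (float)(N / (N - 1)) : var[c];
          w.rvar[i][c] = 0.9f * w.rvar[i][c] + 0.1f * unb;
        }
        binvstd[i] = 1.0f / arma::sqrt(var + BN_EPS);
        bmean[i] = mu;
        xhat[i].set_size(arma::size(z));
        for (int s = 0; s < B; ++s) {
          arma::fmat &zs = z.slice(s);
          arma::fmat xh = zs;
          xh.each_col() -= mu;
          xh.each_col() %= binvstd[i];
          xhat[i].slice(s) = xh;
          zs = xh;
          zs.each_col() %= w.gamma[i];
          zs.each_col() += w.beta[i];
          zs.transform([](float v) { return v > 0 ? v : 0.0f; });
        }
        // pooling
        const bool last = (i == NBLOCK - 1);
        const bool adaptive = last || g.pooling == PURE_ADAPTIVE;
        const bool max_pool =
            (g.pooling == PURE_MAX) || (g.pooling == HYBRID && !last);
        const int O = g.Lpool[i];
        arma::fcube p(g.cout[i], O, B);
        if (max_pool) argmax[i].set_size(g.cout[i], O, B);
        for (int s = 0; s < B; ++s) {
          const arma::fmat &zs = z.slice(s);
          for (int t = 0; t < O; ++t) {
            int s0, e0;
            if (adaptive) adaptive_bins(g.Lconv[i], O, t, s0, e0);
            else { s0 = 2 * t; e0 = 2 * t + 2; }
            if (max_pool) {
              for (int c = 0; c < g.cout[i]; ++c) {
                int best = s0;
                float bv = zs(c, s0);
                for (int q = s0 + 1; q < e0; ++q)
                  if (zs(c, q) > bv) { bv = zs(c, q); best = q; }
                p(c, t, s) = bv;
                argmax[i](c, t, s) = best;
              }
            } else {
              p.slice(s).col(t) = arma::mean(zs.cols(s0, e0 - 1), 1);
            }
          }
        }
        pooled[i] = p;
        a = p;
      }

      // fully connected head
      arma::fmat F(g.flatten, B);
      for (int s = 0; s < B; ++s)
        std::memcpy(F.colptr(s), a.slice(s).memptr(), g.flatten * sizeof(float));
      std::vector<arma::fmat> hin(3), hout(3), dmask(2);
      arma::fmat h = F;
      for (int j = 0; j < 3; ++j) {
        hin[j] = h;
        arma::fmat z = w.fc_w[j] * h;
        z.each_col() += w.fc_b[j];
        if (j < 2) {
          z.transform([](float v) { return v > 0 ? v : 0.0f; });
          // inverted dropout
          dmask[j].set_size(arma::size(z));
          if (dropout > 0) {
            std::uniform_real_distribution<double> ur(0.0, 1.0);
            const float scale = 1.0f / (1.0f - (float)dropout);
            for (auto &v : dmask[j]) v = (ur(rng) < dropout) ? 0.0f : scale;
            z %= dmask[j];
          } else {
            dmask[j].ones();
          }
        }
        hout[j] = z;
        h = z;
      }

      // loss and gradient on logits
      arma::fvec zlog = hout[2].row(0).t();
      double lsum = 0;
      arma::fmat dz(1, B);
      for (int s = 0; s < B; ++s) {
        const double zv = zlog[s], yv = y(order[b0 + s]);
        lsum += std::max(zv, 0.0) - zv * yv + std::log1p(std::exp(-std::abs(zv)));
        const double sig = 1.0 / (1.0 + std::exp(-zv));
        dz(0, s) = (float)((sig - yv) / B);
      }
      loss_sum += lsum / B;
      ++nb;
      ++ad.t;

      // FC backward
      arma::fmat dh = dz;
      std::vector<arma::fmat> dfW(3);
      std::vector<arma::fvec> dfb(3);
      for (int j = 2; j >= 0; --j) {
        dfW[j] = dh * hin[j].t();
        dfb[j] = arma::sum(dh, 1);
        arma::fmat dprev = w.fc_w[j].t() * dh;
        if (j > 0) {
          dprev %= dmask[j - 1];
          // relu mask: hout[j-1] holds post-relu(+dropout); >0 iff pre-relu>0 and kept
          arma::fmat &ho = hout[j - 1];
          for (size_t q = 0; q < ho.n_elem; ++q)
            if (ho[q] <= 0) dprev[q] = 0;
        }
        dh = dprev;
      }

      // back through blocks
      arma::fcube da(g.cout[NBLOCK - 1], g.A, B);
      for (int s = 0; s < B; ++s)
        std::memcpy(da.slice(s).memptr(), dh.colptr(s), g.flatten * sizeof(float));

      for (int i = NBLOCK - 1; i >= 0; --i) {
        const bool last = (i == NBLOCK - 1);
        const bool adaptive = last || g.pooling == PURE_ADAPTIVE;
        const bool max_pool =
            (g.pooling == PURE_MAX) || (g.pooling == HYBRID && !last);
        const int O = g.Lpool[i];
        // pool backward -> dz (post-activation grad)
        arma::fcube dzc(g.cout[i], g.Lconv[i], B, arma::fill::zeros);
        for (int s = 0; s < B; ++s) {
          for (int t = 0; t < O; ++t) {
            int s0, e0;
            if (adaptive) adaptive_bins(g.Lconv[i], O, t, s0, e0);
            else { s0 = 2 * t; e0 = 2 * t + 2; }
            if (max_pool) {
              for (int c = 0; c < g.cout[i]; ++c)
                dzc(c, argmax[i](c, t, s), s) += da(c, t, s);
            } else {
              const float inv = 1.0f / (e0 - s0);
              for (int q = s0; q < e0; ++q)
                dzc.slice(s).col(q) += da.slice(s).col(t) * inv;
            }
          }
        }
        // relu backward: activation = relu(gamma*xhat+beta)
        for (int s = 0; s < B; ++s) {
          arma::fmat act = xhat[i].slice(s);
          act.each_col() %= w.gamma[i];
          act.each_col() += w.beta[i];
          arma::fmat &d = dzc.slice(s);
          for (size_t q = 0; q < act.n_elem; ++q)
            if (act[q] <= 0) d[q] = 0;
        }
        // batch norm backward
        const double N = (double)g.Lconv[i] * B;
        arma::fvec dgamma(g.cout[i], arma::fill::zeros),
            dbeta(g.cout[i], arma::fill::zeros),
            sum_dxhat(g.cout[i], arma::fill::zeros),
            sum_dxhat_xhat(g.cout[i], arma::fill::zeros);
        for (int s = 0; s < B; ++s) {
          dgamma += arma::sum(dzc.slice(s) % xhat[i].slice(s), 1);
          dbeta += arma::sum(dzc.slice(s), 1);
        }
        // dxhat = dzc * gamma
        for (int s = 0; s < B; ++s) {
          arma::fmat dxh = dzc.slice(s);
          dxh.each_col() %= w.gamma[i];
          sum_dxhat += arma::sum(dxh, 1);
          sum_dxhat_xhat += arma::sum(dxh % xhat[i].slice(s), 1);
          dzc.slice(s) = dxh; // reuse storage: now holds dxhat
        }
        for (int s = 0; s < B; ++s) {
          arma::fmat &dxh = dzc.slice(s);
          arma::fmat term = xhat[i].slice(s);
          term.each_col() %= (sum_dxhat_xhat / (float)N);
          dxh -= term;
          dxh.each_col() -= (sum_dxhat / (float)N);
          dxh.each_col() %= binvstd[i]; // now holds d(conv out)
        }
        // conv backward
        arma::fmat dW(arma::size(w.conv_w[i]), arma::fill::zeros);
        arma::fvec db(g.cout[i], arma::fill::zeros);
        arma::fcube dprev;
        if (i > 0) dprev.set_size(g.cin[i], g.Lin[i], B);
        for (int s = 0; s < B; ++s) {
          im2col(xin[i].slice(s), g.k[i], g.stride[i], g.pad[i], col);
          dW += dzc.slice(s) * col.t();
          db += arma::sum(dzc.slice(s), 1);
          if (i > 0) {
            dcol = w.conv_w[i].t() * dzc.slice(s);
            col2im(dcol, g.k[i], g.stride[i], g.pad[i], g.cin[i], g.Lin[i], dx);
            dprev.slice(s) = dx;
          }
        }
        // updates
        adam_step_mat(w.conv_w[i], dW, ad.mW[i], ad.vW[i], lr, weight_decay, ad.t);
        adam_step_vec(w.conv_b[i], db, ad.mb[i], ad.vb[i], lr, weight_decay, ad.t);
        adam_step_vec(w.gamma[i], dgamma, mg[i], vg[i], lr, weight_decay, ad.t);
        adam_step_vec(w.beta[i], dbeta, mbe[i], vbe[i], lr, weight_decay, ad.t);
        if (i > 0) da = dprev;
      }
      for (int j = 0; j < 3; ++j) {
        adam_step_mat(w.fc_w[j], dfW[j], mfW[j], vfW[j], lr, weight_decay, ad.t);
        adam_step_vec(w.fc_b[j], dfb[j], mfb[j], vfb[j], lr, weight_decay, ad.t);
      }
      Rcpp::checkUserInterrupt();
    }
    epoch_loss[ep] = loss_sum / std::max(nb, 1);
  }
  return List::create(_["weights"] = weights_to_list(w), _["loss"] = epoch_loss);
}
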