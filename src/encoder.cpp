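// Fused forward/backward kernels for the shared convolutional instance
// encoder: five same-padded conv+ReLU stages, non-overlapping max-pooling
// after the first four, global average pooling at the end. A bag of L
// patches is processed as a batch; the backward pass touches only the
// instances with a nonzero upstream gradient (with sparse attention most
// instances receive none).
//
// Internally everything runs in single precision: each convolution is an
// im2col + SGEMM, and the activations cached for backpropagation live in a
// C++ structure handed to R as an external pointer, so no large arrays
// cross the R boundary. Weights and results are exchanged as doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int N_STAGE = 5;
static const int FILT[N_STAGE] = {16, 32, 64, 128, 128};
static const int KSZ[N_STAGE] = {5, 3, 3, 3, 3};
static const int POOL[N_STAGE - 1] = {3, 2, 2, 2};

struct EncCache {
  int L = 0;
  int inSide[N_STAGE];                 // spatial side entering each stage
  int inC[N_STAGE];                    // channels entering each stage
  arma::fmat input[N_STAGE];           // (side^2 * C) x L stage inputs
  arma::fmat convOut[N_STAGE];         // (side^2 * F) x L conv+ReLU outputs
  arma::Mat<int> poolIdx[N_STAGE - 1]; // argmax h + side*w, per pooled cell
  void release() {
    for (int i = 0; i < N_STAGE; ++i) {
      input[i].reset();
      convOut[i].reset();
      if (i < N_STAGE - 1) poolIdx[i].reset();
    }
  }
};

static void im2colSameF(const float* x, int H, int W, int C,
                        int k, arma::fmat& col) {
  const int p = k / 2;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (std::size_t)H * W * c;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int j = dh + k * dw + k * k * c;
        float* colj = col.colptr(j);
        const int hlo = std::max(0, p - dh);
        const int hhi = std::min(H, H + p - dh);
        if (hhi <= hlo) continue;
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw - p;
          if (iw < 0 || iw >= W) continue;
          std::memcpy(colj + (std::size_t)H * w + hlo,
                      xc + (std::size_t)H * iw + hlo + dh - p,
                      (std::size_t)(hhi - hlo) * sizeof(float));
        }
      }
    }
  }
}

static void col2imSameF(const arma::fmat& col, int H, int W, int C,
                        int k, float* dx) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    float* dxc = dx + (std::size_t)H * W * c;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int j = dh + k * dw + k * k * c;
        const float* colj = col.colptr(j);
        const int hlo = std::max(0, p - dh);
        const int hhi = std::min(H, H + p - dh);
        if (hhi <= hlo) continue;
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw - p;
          if (iw < 0 || iw >= W) continue;
          float* dst = dxc + (std::size_t)H * iw + hlo + dh - p;
          const float* src = colj + (std::size_t)H * w + hlo;
          for (int h = 0; h < hhi - hlo; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// Convert the R weight list (doubles, kernels (kh, kw, Cin, F)) into
// per-stage float matrices (kh*kw*Cin) x F plus bias rows.
static void loadWeights(const List& W, const List& b,
                        arma::fmat* Wf, arma::frowvec* bf) {
  for (int i = 0; i < N_STAGE; ++i) {
    NumericVector wi = W[i];
    NumericVector bi = b[i];
    Wf[i].set_size(KSZ[i] * KSZ[i] * (i == 0 ? 3 : FILT[i - 1]), FILT[i]);
    std::copy(wi.begin(), wi.end(), Wf[i].memptr());
    bf[i].set_size(FILT[i]);
    std::copy(bi.begin(), bi.end(), bf[i].memptr());
  }
}

// [[Rcpp::export]]
List cppEncoderForward(NumericVector x, List W, List b, bool wantCache) {
  IntegerVector xd = x.attr("dim");
  const int side = xd[0], C = xd[2], L = xd[3];
  if (xd[1] != side) stop("patches must be square");
  if (C != 3) stop("patches must have 3 channels");
  arma::fmat Wf[N_STAGE];
  arma::frowvec bf[N_STAGE];
  loadWeights(W, b, Wf, bf);

  EncCache* cc = new EncCache();
  cc->L = L;
  cc->input[0].set_size((std::size_t)side * side * C, L);
  std::copy(x.begin(), x.end(), cc->input[0].memptr());

  int s = side;
  arma::fmat col;
  for (int i = 0; i < N_STAGE; ++i) {
    const int cIn = (i == 0) ? 3 : FILT[i - 1];
    const int F = FILT[i];
    const int sp = s * s;
    cc->inSide[i] = s;
    cc->inC[i] = cIn;
    col.set_size(sp, KSZ[i] * KSZ[i] * cIn);
    cc->convOut[i].set_size((std::size_t)sp * F, L);
    for (int l = 0; l < L; ++l) {
      im2colSameF(cc->input[i].colptr(l), s, s, cIn, KSZ[i], col);
      arma::fmat o(cc->convOut[i].colptr(l), sp, F, false, true);
      o = col * Wf[i];
      o.each_row() += bf[i];
      o.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    }
    if (i < N_STAGE - 1) {
      const int k = POOL[i];
      const int so = s / k;
      if (so < 1) { delete cc; stop("patch side collapses in the encoder"); }
      cc->poolIdx[i].set_size((std::size_t)so * so * F, L);
      cc->input[i + 1].set_size((std::size_t)so * so * F, L);
      for (int l = 0; l < L; ++l) {
        const float* xin = cc->convOut[i].colptr(l);
        float* xout = cc->input[i + 1].colptr(l);
        int* pidx = cc->poolIdx[i].colptr(l);
        std::size_t o = 0;
        for (int c = 0; c < F; ++c) {
          const float* plane = xin + (std::size_t)sp * c;
          for (int wo = 0; wo < so; ++wo) {
            for (int ho = 0; ho < so; ++ho, ++o) {
              float best = -1e30f;
              int bi2 = 0;
              for (int dw = 0; dw < k; ++dw) {
                const int iw = wo * k + dw;
                for (int dh = 0; dh < k; ++dh) {
                  const int ih = ho * k + dh;
                  const float v = plane[ih + (std::size_t)s * iw];
                  if (v > best) { best = v; bi2 = ih + s * iw; }
                }
              }
              xout[o] = best;
              pidx[o] = bi2;
            }
          }
        }
      }
      s = so;
    }
  }

  // global average pooling over the last conv output: E is L x 128
  const int sp5 = s * s;
  NumericMatrix E(L, FILT[N_STAGE - 1]);
  for (int l = 0; l < L; ++l) {
    const float* v = cc->convOut[N_STAGE - 1].colptr(l);
    for (int f = 0; f < FILT[N_STAGE - 1]; ++f) {
      double acc = 0;
      for (int i = 0; i < sp5; ++i) acc += v[(std::size_t)sp5 * f + i];
      E(l, f) = acc / sp5;
    }
  }

  List out = List::create(_["E"] = E, _["finalSide"] = s);
  if (wantCache) {
    XPtr<EncCache> ptr(cc, true);
    out["cache"] = ptr;
  } else {
    delete cc;
  }
  return out;
}

// dE: nAct x 128 upstream gradient for the active instances (1-based
// indices in `active`). Returns conv weight/bias gradients (doubles, summed
// over the active instances) and releases the cache buffers.
// [[Rcpp::export]]
List cppEncoderBackward(SEXP cachePtr, List W, List b,
                        NumericMatrix dE, IntegerVector active) {
  XPtr<EncCache> cc(cachePtr);
  if (cc->L == 0) stop("encoder cache was already consumed");
  arma::fmat Wf[N_STAGE];
  arma::frowvec bf[N_STAGE];
  loadWeights(W, b, Wf, bf);

  arma::fmat dWf[N_STAGE];
  arma::fvec dbf[N_STAGE];
  for (int i = 0; i < N_STAGE; ++i) {
    dWf[i].zeros(Wf[i].n_rows, Wf[i].n_cols);
    dbf[i].zeros(FILT[i]);
  }

  const int sFinal = cc->inSide[N_STAGE - 1];
  const int sp5 = sFinal * sFinal;
  arma::fmat col, dcol, dY;
  arma::fvec dcur, dprev;

  for (int a = 0; a < active.size(); ++a) {
    const int l = active[a] - 1;
    // seed: GAP backward spreads dE evenly over the final spatial cells
    dcur.set_size((std::size_t)sp5 * FILT[N_STAGE - 1]);
    for (int f = 0; f < FILT[N_STAGE - 1]; ++f) {
      const float g = (float)(dE(a, f) / sp5);
      float* d = dcur.memptr() + (std::size_t)sp5 * f;
      for (int i = 0; i < sp5; ++i) d[i] = g;
    }
    for (int i = N_STAGE - 1; i >= 0; --i) {
      const int s = cc->inSide[i];
      const int sp = s * s;
      const int cIn = cc->inC[i];
      const int F = FILT[i];
      // ReLU mask from the stored conv output
      const float* co = cc->convOut[i].colptr(l);
      dY.set_size(sp, F);
      float* dm = dY.memptr();
      const float* dc = dcur.memptr();
      for (std::size_t j = 0; j < (std::size_t)sp * F; ++j)
        dm[j] = co[j] > 0.0f ? dc[j] : 0.0f;
      col.set_size(sp, KSZ[i] * KSZ[i] * cIn);
      im2colSameF(cc->input[i].colptr(l), s, s, cIn, KSZ[i], col);
      dWf[i] += col.t() * dY;
      dbf[i] += arma::sum(dY, 0).t();
      if (i > 0) {
        dcol = dY * Wf[i].t();
        dprev.zeros((std::size_t)sp * cIn);     // gradient wrt pooled input
        col2imSameF(dcol, s, s, cIn, KSZ[i], dprev.memptr());
        // max-pool backward: scatter into the previous conv output grid
        const int sPrev = cc->inSide[i - 1];
        const int spPrev = sPrev * sPrev;
        dcur.zeros((std::size_t)spPrev * cIn);
        const int* pidx = cc->poolIdx[i - 1].colptr(l);
        const float* dp = dprev.memptr();
        for (int c = 0; c < cIn; ++c) {
          float* dst = dcur.memptr() + (std::size_t)spPrev * c;
          const std::size_t off = (std::size_t)sp * c;
          for (int j = 0; j < sp; ++j) dst[pidx[off + j]] += dp[off + j];
        }
      }
    }
  }

  List dWout(N_STAGE), dbout(N_STAGE);
  for (int i = 0; i < N_STAGE; ++i) {
    const int cIn = (i == 0) ? 3 : FILT[i - 1];
    NumericVector dw((R_xlen_t)KSZ[i] * KSZ[i] * cIn * FILT[i]);
    dw.attr("dim") = IntegerVector::create(KSZ[i], KSZ[i], cIn, FILT[i]);
    std::copy(dWf[i].begin(), dWf[i].end(), dw.begin());
    NumericVector db(FILT[i]);
    std::copy(dbf[i].begin(), dbf[i].end(), db.begin());
    dWout[i] = dw;
    dbout[i] = db;
  }
  cc->release();
  cc->L = 0;
  return List::create(_["W"] = dWout, _["b"] = dbout);
}
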