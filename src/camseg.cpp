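#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dense fully-connected CRF, mean-field inference with a Potts model.
//
// unary: N x L matrix of per-pixel class probabilities (rows sum to 1),
//        pixel order column-major over an H x W grid (row index fastest).
// img:   N x 3 matrix of RGB values on the 0..255 scale.
// Pairwise potential between pixels i, j:
//   w1 * exp(-|pi-pj|^2 / (2 sg^2))                        (smoothness)
// + w2 * exp(-|pi-pj|^2 / (2 sa^2) - |ci-cj|^2 / (2 sb^2)) (appearance)
// Exact O(N^2) message passing; spatial factors are precomputed per offset
// and the appearance colour factor is read from a binned exp() table.
// [[Rcpp::export]]
NumericMatrix cpp_crf_inference(NumericMatrix unary, NumericMatrix img,
                                int H, int W, int iters,
                                double sigma_gamma, double w1,
                                double sigma_alpha, double sigma_beta,
                                double w2) {
  const int N = unary.nrow(), L = unary.ncol();
  // spatial tables indexed by (dy + H - 1) + (dx + W - 1) * (2H - 1)
  const int TH = 2 * H - 1, TW = 2 * W - 1;
  std::vector<double> gauss(TH * TW), bilat_sp(TH * TW);
  for (int dx = -(W - 1); dx <= W - 1; ++dx)
    for (int dy = -(H - 1); dy <= H - 1; ++dy) {
      double d2 = (double)dy * dy + (double)dx * dx;
      int t = (dy + H - 1) + (dx + W - 1) * TH;
      gauss[t] = w1 * std::exp(-d2 / (2.0 * sigma_gamma * sigma_gamma));
      bilat_sp[t] = w2 * std::exp(-d2 / (2.0 * sigma_alpha * sigma_alpha));
    }
  // colour table: exp(-c2 / (2 sb^2)) for c2 in [0, 3*255^2]
  const int NB = 4096;
  const double c2max = 3.0 * 255.0 * 255.0;
  std::vector<double> ctab(NB);
  for (int t = 0; t < NB; ++t) {
    double c2 = (t + 0.5) * c2max / NB;
    ctab[t] = std::exp(-c2 / (2.0 * sigma_beta * sigma_beta));
  }
  const double cscale = (NB - 1.0) / c2max;

  // negative unary energy; clamp away from zero probability
  std::vector<double> U(N * L);
  for (int k = 0; k < L; ++k)
    for (int i = 0; i < N; ++i)
      U[i + k * N] = -std::log(std::max(unary(i, k), 1e-8));

  std::vector<double> Q(N * L), M(N * L), logq(L);
  for (int k = 0; k < L; ++k)
    for (int i = 0; i < N; ++i) Q[i + k * N] = unary(i, k);

  // For moderate N the full symmetric kernel matrix fits in memory; build it
  // once so every mean-field iteration is a plain matrix-vector accumulate.
  const bool cacheW = (double)N * (double)N <= 3.2e7;
  std::vector<float> Wm;
  if (cacheW) {
    Wm.assign((size_t)N * N, 0.0f);
    for (int i = 0; i < N; ++i) {
      const int yi = i % H, xi = i / H;
      const double r0 = img(i, 0), g0 = img(i, 1), b0 = img(i, 2);
      for (int j = i + 1; j < N; ++j) {
        const int yj = j % H, xj = j / H;
        const int t = (yi - yj + H - 1) + (xi - xj + W - 1) * TH;
        double dr = r0 - img(j, 0), dg = g0 - img(j, 1), db = b0 - img(j, 2);
        double c2 = dr * dr + dg * dg + db * db;
        float w = (float)(gauss[t] + bilat_sp[t] * ctab[(int)(c2 * cscale)]);
        Wm[(size_t)i + (size_t)j * N] = w;
        Wm[(size_t)j + (size_t)i * N] = w;
      }
    }
  }

  for (int it = 0; it < iters; ++it) {
    std::fill(M.begin(), M.end(), 0.0);
    if (cacheW) {
      for (int j = 0; j < N; ++j) {
        const float *col = &Wm[(size_t)j * N];
        for (int k = 0; k < L; ++k) {
          const double qjk = Q[j + k * N];
          double *mk = &M[k * N];
          for (int i = 0; i < N; ++i) mk[i] += col[i] * qjk;
        }
      }
    } else {
    // message passing, symmetric kernel: visit unordered pairs once
    for (int i = 0; i < N; ++i) {
      const int yi = i % H, xi = i / H;
      const double r0 = img(i, 0), g0 = img(i, 1), b0 = img(i, 2);
      for (int j = i + 1; j < N; ++j) {
        const int yj = j % H, xj = j / H;
        const int t = (yi - yj + H - 1) + (xi - xj + W - 1) * TH;
        double dr = r0 - img(j, 0), dg = g0 - img(j, 1), db = b0 - img(j, 2);
        double c2 = dr * dr + dg * dg + db * db;
        double w = gauss[t] + bilat_sp[t] * ctab[(int)(c2 * cscale)];
        if (w < 1e-12) continue;
        for (int k = 0; k < L; ++k) {
          M[i + k * N] += w * Q[j + k * N];
          M[j + k * N] += w * Q[i + k * N];
        }
      }
    }
    }
    // Potts compatibility + unary, then normalise
    for (int i = 0; i < N; ++i) {
      double msum = 0.0;
      for (int k = 0; k < L; ++k) msum += M[i + k * N];
      double mx = -1e300;
      for (int k = 0; k < L; ++k) {
        logq[k] = -U[i + k * N] - (msum - M[i + k * N]);
        if (logq[k] > mx) mx = logq[k];
      }
      double z = 0.0;
      for (int k = 0; k < L; ++k) { logq[k] = std::exp(logq[k] - mx); z += logq[k]; }
      for (int k = 0; k < L; ++k) Q[i + k * N] = logq[k] / z;
    }
  }
  NumericMatrix out(N, L);
  for (int k = 0; k < L; ++k)
    for (int i = 0; i < N; ++i) out(i, k) = Q[i + k * N];
  return out;
}

// Dense pairwise (Gaussian) energy loss over ordered pixel pairs within a
// square neighbourhood of radius r, with a per-pixel soft filter S, plus its
// exact gradient w.r.t. the class probabilities P (S treated as constant).
//
// P:   N x L class probabilities (pixel order column-major over H x W)
// img: N x 3 RGB on the [0,1] scale
// loss = norm * sum_{i != j, |pi-pj|_inf <= r} S_i G(i,j)
//                 * sum_{k1 != k2} P_{k1}(i) P_{k2}(j)
// with G = exp(-d2pos/(2 sp^2) - d2rgb/(2 sr^2)); norm = 1/N if normalize.
// [[Rcpp::export]]
List cpp_dense_energy(NumericMatrix P, NumericMatrix img, NumericVector S,
                      int H, int W, int r,
                      double sigma_pos, double sigma_rgb, bool normalize) {
  const int N = P.nrow(), L = P.ncol();
  NumericMatrix dP(N, L);
  std::vector<double> rs(N, 0.0);          // row sums of P
  for (int k = 0; k < L; ++k)
    for (int i = 0; i < N; ++i) rs[i] += P(i, k);
  // spatial factor per offset
  const int D = 2 * r + 1;
  std::vector<double> sp(D * D);
  for (int dx = -r; dx <= r; ++dx)
    for (int dy = -r; dy <= r; ++dy)
      sp[(dy + r) + (dx + r) * D] =
        std::exp(-((double)dy * dy + dx * dx) / (2.0 * sigma_pos * sigma_pos));
  double loss = 0.0;
  const double inv2sr = 1.0 / (2.0 * sigma_rgb * sigma_rgb);
  for (int i = 0; i < N; ++i) {
    const int yi = i % H, xi = i / H;
    const double r0 = img(i, 0), g0 = img(i, 1), b0 = img(i, 2);
    for (int dx = -r; dx <= r; ++dx) {
      const int xj = xi + dx;
      if (xj < 0 || xj >= W) continue;
      for (int dy = -r; dy <= r; ++dy) {
        if (dy == 0 && dx == 0) continue;
        const int yj = yi + dy;
        if (yj < 0 || yj >= H) continue;
        const int j = yj + xj * H;
        double dr = r0 - img(j, 0), dg = g0 - img(j, 1), db = b0 - img(j, 2);
        double g = sp[(dy + r) + (dx + r) * D] *
                   std::exp(-(dr * dr + dg * dg + db * db) * inv2sr);
        // sum_{k1 != k2} P_{k1}(i) P_{k2}(j) = rs_i * rs_j - <P_i, P_j>
        double dot = 0.0;
        for (int k = 0; k < L; ++k) dot += P(i, k) * P(j, k);
        const double Si = S[i];
        loss += Si * g * (rs[i] * rs[j] - dot);
        const double wi = Si * g;
        for (int k = 0; k < L; ++k) {
          dP(i, k) += wi * (rs[j] - P(j, k));
          dP(j, k) += wi * (rs[i] - P(i, k));
        }
      }
    }
  }
  double norm = normalize ? 1.0 / (double)N : 1.0;
  if (norm != 1.0) {
    loss *= norm;
    for (int k = 0; k < L; ++k)
      for (int i = 0; i < N; ++i) dP(i, k) *= norm;
  }
  return List::create(_["loss"] = loss, _["dP"] = dP);
}
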