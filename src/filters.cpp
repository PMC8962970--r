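#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <climits>
using namespace Rcpp;

// Reflect-pad an image by `pad` pixels on every side (symmetric, edge pixel
// not repeated at the fold: index -1 maps to 0? No -- classic "reflect"
// maps -1 -> 1?  We use half-sample symmetric padding (edge repeated),
// i.e. -1 -> 0, -2 -> 1, matching mirrored zero-flux boundaries.
static NumericMatrix reflect_pad(const NumericMatrix& img, int pad) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H + 2 * pad, W + 2 * pad);
  for (int i = 0; i < H + 2 * pad; ++i) {
    int ii = i - pad;
    if (ii < 0) ii = -ii - 1;
    if (ii >= H) ii = 2 * H - 1 - ii;
    for (int j = 0; j < W + 2 * pad; ++j) {
      int jj = j - pad;
      if (jj < 0) jj = -jj - 1;
      if (jj >= W) jj = 2 * W - 1 - jj;
      out(i, j) = img(ii, jj);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_reflect_pad(NumericMatrix img, int pad) {
  return reflect_pad(img, pad);
}

// Non-local means with an s x s search window and p x p patches.
// Weights w = exp(-||patch_i - patch_k||^2 / h^2), normalised to sum 1.
// [[Rcpp::export]]
NumericMatrix cpp_nlm(NumericMatrix img, int search, int patch, double h) {
  const int H = img.nrow(), W = img.ncol();
  const int m = (search - 1) / 2;   // search radius
  const int pr = (patch - 1) / 2;   // patch radius
  const int pad = m + pr;
  NumericMatrix P = reflect_pad(img, pad);
  const int PH = P.nrow(), PW = P.ncol();

  NumericMatrix wsum(H, W), acc(H, W);
  const double inv_h2 = 1.0 / (h * h);

  // scratch: squared-difference image for one offset, and its box sums
  NumericMatrix d2(PH, PW), colsum(PH, PW), box(PH, PW);

  for (int dy = -m; dy <= m; ++dy) {
    for (int dx = -m; dx <= m; ++dx) {
      // squared differences on the valid band of the padded image
      int i0 = std::max(0, -dy), i1 = std::min(PH, PH - dy);
      int j0 = std::max(0, -dx), j1 = std::min(PW, PW - dx);
      for (int j = j0; j < j1; ++j)
        for (int i = i0; i < i1; ++i) {
          double d = P(i, j) - P(i + dy, j + dx);
          d2(i, j) = d * d;
        }
      // p x p box sum of d2: vertical pass, then horizontal pass
      for (int j = j0; j < j1; ++j)
        for (int i = i0 + pr; i < i1 - pr; ++i) {
          double s = 0.0;
          for (int t = -pr; t <= pr; ++t) s += d2(i + t, j);
          colsum(i, j) = s;
        }
      for (int j = j0 + pr; j < j1 - pr; ++j)
        for (int i = i0 + pr; i < i1 - pr; ++i) {
          double s = 0.0;
          for (int t = -pr; t <= pr; ++t) s += colsum(i, j + t);
          box(i, j) = s;
        }
      for (int x = 0; x < W; ++x) {
        int j = x + pad;
        for (int y = 0; y < H; ++y) {
          int i = y + pad;       // padded row of pixel centre
          double w = std::exp(-box(i, j) * inv_h2);
          wsum(y, x) += w;
          acc(y, x) += w * P(i + dy, j + dx);
        }
      }
    }
  }
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) out(y, x) = acc(y, x) / wsum(y, x);
  return out;
}

// Weighted-mean cosine-similarity field q: for every pixel, the cosine
// similarity between its centred p x p patch and the patches centred at
// each position of the (s-p+1) x (s-p+1) grid inside its s x s search box,
// spatially weighted by G and normalised by sum(G).
// `exact_cosine = false` reproduces the no-square-root denominator variant.
// [[Rcpp::export]]
NumericMatrix cpp_variation_field(NumericMatrix img, int search, int patch,
                                  NumericMatrix G, bool exact_cosine = true) {
  const int H = img.nrow(), W = img.ncol();
  const int pr = (patch - 1) / 2;
  const int m = (search - patch) / 2;   // patch-centre offset radius
  const int noff = 2 * m + 1;
  if (G.nrow() != noff || G.ncol() != noff)
    stop("spatial weight kernel G must be %d x %d", noff, noff);
  const int pad = m + pr;
  NumericMatrix P = reflect_pad(img, pad);
  const int PH = P.nrow(), PW = P.ncol();

  double Gsum = 0.0;
  for (int i = 0; i < noff * noff; ++i) Gsum += G[i];

  // patch self-energy sum(I^2) over p x p, on the padded grid
  NumericMatrix sq(PH, PW), rowsum(PH, PW), norm2(PH, PW);
  for (int j = 0; j < PW; ++j)
    for (int i = 0; i < PH; ++i) sq(i, j) = P(i, j) * P(i, j);
  for (int j = 0; j < PW; ++j)
    for (int i = pr; i < PH - pr; ++i) {
      double s = 0.0;
      for (int t = -pr; t <= pr; ++t) s += sq(i + t, j);
      rowsum(i, j) = s;
    }
  for (int j = pr; j < PW - pr; ++j)
    for (int i = pr; i < PH - pr; ++i) {
      double s = 0.0;
      for (int t = -pr; t <= pr; ++t) s += rowsum(i, j + t);
      norm2(i, j) = s;
    }
  // reciprocal norms (negative marks an all-zero patch)
  NumericMatrix rnorm(PH, PW);
  for (int j = pr; j < PW - pr; ++j)
    for (int i = pr; i < PH - pr; ++i)
      rnorm(i, j) = norm2(i, j) > 0.0 ?
        (exact_cosine ? 1.0 / std::sqrt(norm2(i, j)) : 1.0 / norm2(i, j))
        : -1.0;

  NumericMatrix q(H, W);
  const double* Pp = P.begin();
  const double* rn = rnorm.begin();

  for (int dy = -m; dy <= m; ++dy) {
    for (int dx = -m; dx <= m; ++dx) {
      double g = G(dy + m, dx + m);
      const int off = dy + dx * PH;      // column-major offset of (dy, dx)
      for (int x = 0; x < W; ++x) {
        int j = x + pad;
        for (int y = 0; y < H; ++y) {
          int c = (y + pad) + j * PH;    // padded linear index
          double ra = rn[c], rb = rn[c + off];
          double d;
          if (ra > 0.0 && rb > 0.0) {
            double dot = 0.0;
            for (int v = -pr; v <= pr; ++v) {
              int b = c + v * PH;
              for (int u = -pr; u <= pr; ++u)
                dot += Pp[b + u] * Pp[b + u + off];
            }
            d = dot * ra * rb;
          } else if (ra < 0.0 && rb < 0.0) d = 1.0;  // two empty patches
          else d = 0.0;                              // one empty patch
          q(y, x) += g * d;
        }
      }
    }
  }
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) q(y, x) /= Gsum;
  return q;
}

// Histogram peak of the rounded image with sub-bin resolution: the modal
// integer bin (ties toward ref_mean) refined by parabolic interpolation
// through the two neighbouring bin counts.  The raw integer mode has a
// resolution of one gray level, which cannot support a +/-0.5 criterion;
// the interpolated vertex recovers where the underlying density actually
// peaks.
static double hist_peak_cpp(const NumericMatrix& img, double ref_mean) {
  int lo = INT_MAX, hi = INT_MIN;
  const int n = img.size();
  for (int i = 0; i < n; ++i) {
    int v = (int)std::lround(img[i]);
    if (v < lo) lo = v;
    if (v > hi) hi = v;
  }
  std::vector<int> counts(hi - lo + 1, 0);
  for (int i = 0; i < n; ++i) counts[(int)std::lround(img[i]) - lo]++;
  int cmax = 0;
  for (size_t k = 0; k < counts.size(); ++k)
    if (counts[k] > cmax) cmax = counts[k];
  double best = NA_REAL, bestdist = R_PosInf;
  int bestk = -1;
  for (size_t k = 0; k < counts.size(); ++k)
    if (counts[k] == cmax) {
      double val = lo + (double)k, d = std::fabs(val - ref_mean);
      if (d < bestdist) { bestdist = d; best = val; bestk = (int)k; }
    }
  // parabolic refinement through (m-1, m, m+1)
  if (bestk > 0 && bestk < (int)counts.size() - 1) {
    double cl = counts[bestk - 1], cm = counts[bestk],
           cr = counts[bestk + 1];
    double denom = cl - 2.0 * cm + cr;
    if (denom < 0) {
      double shift = 0.5 * (cl - cr) / denom;
      if (shift > 0.5) shift = 0.5;
      if (shift < -0.5) shift = -0.5;
      best += shift;
    }
  }
  return best;
}

// [[Rcpp::export]]
double cpp_hist_peak(NumericMatrix img, double ref_mean) {
  return hist_peak_cpp(img, ref_mean);
}

// One gray-value-compression sweep in place: pixels at or above the
// reference step down by gamma*I/div, below it step up, with
// gamma = exp(-I/ref) recomputed from the current image.
static void gvc_sweep(NumericMatrix& I, const NumericMatrix& ref,
                      double div) {
  const int n = I.size();
  for (int i = 0; i < n; ++i) {
    double step = std::exp(-I[i] / ref[i]) * I[i] / div;
    I[i] += (I[i] >= ref[i]) ? -step : step;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_gvc_run(NumericMatrix img, NumericMatrix ref, int k_max,
                          double step_divisor) {
  NumericMatrix I = clone(img);
  for (int k = 0; k < k_max; ++k) gvc_sweep(I, ref, step_divisor);
  return I;
}

// Smallest k at which compression is complete: mean |I - ref| at or below
// floor_tol and the histogram peak within peak_tol of `gray`.  Returns the
// compressed image and the k found (cap if never satisfied).
// [[Rcpp::export]]
List cpp_gvc_floor_k(NumericMatrix img, NumericMatrix ref, int cap,
                     double step_divisor, double floor_tol, double peak_tol,
                     double gray) {
  NumericMatrix I = clone(img);
  const int n = I.size();
  int k_found = cap;
  if (cap == 0) return List::create(_["k"] = 0, _["image"] = I);
  for (int k = 1; k <= cap; ++k) {
    gvc_sweep(I, ref, step_divisor);
    double mad = 0.0;
    for (int i = 0; i < n; ++i) mad += std::fabs(I[i] - ref[i]);
    mad /= n;
    if (mad <= floor_tol &&
        std::fabs(hist_peak_cpp(I, gray) - gray) <= peak_tol) {
      k_found = k;
      break;
    }
  }
  return List::create(_["k"] = k_found, _["image"] = I);
}

// Type-2 fuzzy membership gate.  Per pixel: mu = mean-of-k-middle (k = 2)
// of its 3x3 neighbourhood, UMF/LMF = Gaussian memberships of the centre
// value with standard deviations delta_u / delta_l, U = (UMF + LMF) / 2.
// [[Rcpp::export]]
NumericMatrix cpp_type2_gate(NumericMatrix img, double delta_u, double delta_l,
                             int k = 2, int radius = 1) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix P = reflect_pad(img, radius);
  const int side = 2 * radius + 1, n = side * side;
  const int hmid = (n + 1) / 2;            // n odd: n = 2h - 1
  if (k < 1 || k > hmid) stop("k must lie in [1, %d]", hmid);
  std::vector<double> buf(n);
  NumericMatrix U(H, W);
  const double cu = 2.0 * delta_u * delta_u, cl = 2.0 * delta_l * delta_l;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int b = 0;
      for (int dx = 0; dx < side; ++dx)
        for (int dy = 0; dy < side; ++dy)
          buf[b++] = P(y + dy, x + dx);
      // insertion sort; windows are tiny
      for (int a = 1; a < n; ++a) {
        double v = buf[a]; int c = a - 1;
        while (c >= 0 && buf[c] > v) { buf[c + 1] = buf[c]; --c; }
        buf[c + 1] = v;
      }
      // central 2k-1 order statistics (n odd)
      double mu = 0.0;
      for (int t = hmid - k; t <= hmid + k - 2; ++t) mu += buf[t];
      mu /= (2 * k - 1);
      double e = img(y, x) - mu, e2 = e * e;
      U(y, x) = 0.5 * (std::exp(-e2 / cu) + std::exp(-e2 / cl));
    }
  }
  return U;
}

// One explicit diffusion step:
// I+ = I + dt*(1-U)/4 * sum_{4-neighbours} c_n * (I_n - I),
// zero-flux (mirrored) boundary.
// [[Rcpp::export]]
NumericMatrix cpp_cnlad_step(NumericMatrix img, NumericMatrix cf,
                             NumericMatrix U, double dt) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      double I0 = img(y, x), flux = 0.0;
      int yn[4] = {y - 1, y + 1, y, y};
      int xn[4] = {x, x, x - 1, x + 1};
      for (int t = 0; t < 4; ++t) {
        int yy = yn[t], xx = xn[t];
        if (yy < 0) yy = 0; if (yy >= H) yy = H - 1;
        if (xx < 0) xx = 0; if (xx >= W) xx = W - 1;
        flux += cf(yy, xx) * (img(yy, xx) - I0);
      }
      out(y, x) = I0 + dt * (1.0 - U(y, x)) * 0.25 * flux;
    }
  }
  return out;
}

// Full diffusion loop: per iteration recompute the variation field and the
// type-2 gate from the current image, take one explicit step, and stop
// early once the mean absolute update drops below tol.  Identical
// arithmetic to composing the exported building blocks.
// [[Rcpp::export]]
List cpp_cnlad_run(NumericMatrix img, int search, int patch, NumericMatrix G,
                   bool exact_cosine, double delta_u, double delta_l, int k,
                   double gate_scale, double dt, int n_iter, double tol) {
  NumericMatrix I = clone(img);
  std::vector<double> updates;
  int iters = 0;
  const int n = I.size();
  for (int it = 0; it < n_iter; ++it) {
    NumericMatrix q = cpp_variation_field(I, search, patch, G, exact_cosine);
    double T = 0.0;
    for (int i = 0; i < n; ++i) T += q[i];
    T /= n;
    NumericMatrix cf(I.nrow(), I.ncol());
    for (int i = 0; i < n; ++i) {
      double d = q[i] - T;
      cf[i] = 1.0 / (1.0 + d * d);
    }
    NumericMatrix Iscaled(I.nrow(), I.ncol());
    for (int i = 0; i < n; ++i) Iscaled[i] = I[i] / gate_scale;
    NumericMatrix U = cpp_type2_gate(Iscaled, delta_u, delta_l, k, 1);
    NumericMatrix In = cpp_cnlad_step(I, cf, U, dt);
    double upd = 0.0;
    for (int i = 0; i < n; ++i) upd += std::fabs(In[i] - I[i]);
    upd /= n;
    I = In;
    ++iters;
    updates.push_back(upd);
    if (upd < tol) break;
  }
  return List::create(_["image"] = I, _["iters"] = iters,
                      _["updates"] = NumericVector(updates.begin(),
                                                   updates.end()));
}
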