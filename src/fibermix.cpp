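#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted-packet Monte Carlo photon transport on a voxel grid.
// MCML-style scheme: exponential free paths with mu_t = mu_a + mu_s, a
// fraction mu_a/mu_t of the packet weight deposited at each interaction,
// Henyey-Greenstein scattering otherwise, Russian roulette below w_min.
// Fluence uses the track-length estimator: weight x path length accumulated
// per voxel along every traversed segment. Uses R's RNG (seed via set.seed).

static inline double hg_cosine(double g) {
  double u = unif_rand();
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Rotate incoming unit vector d by polar angle with cosine ct and uniform
// azimuth (standard Monte Carlo scattering rotation).
static inline void scatter_dir(double ct, double *dx, double *dy, double *dz) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = *dx, uy = *dy, uz = *dz;
  if (std::fabs(uz) > 0.99999) {
    *dx = st * cp;
    *dy = st * sp;
    *dz = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    *dx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    *dy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    *dz = -st * cp * den + uz * ct;
  }
  double n = std::sqrt((*dx) * (*dx) + (*dy) * (*dy) + (*dz) * (*dz));
  *dx /= n; *dy /= n; *dz /= n;
}

// Truncated half-normal launch polar angle: |N(0, sigma^2)| resampled until
// < pi/2; azimuth uniform.
static inline void launch_dir(double sigma, double *dx, double *dy, double *dz) {
  double theta;
  if (sigma <= 0.0) {
    theta = 0.0;
  } else {
    do {
      theta = std::fabs(norm_rand() * sigma);
    } while (theta >= M_PI_2);
  }
  double phi = 2.0 * M_PI * unif_rand();
  double st = std::sin(theta);
  *dx = st * std::cos(phi);
  *dy = st * std::sin(phi);
  *dz = std::cos(theta);
}

// March a ray from (x,y,z) along unit (dx,dy,dz) up to distance s, adding
// w * segment_length to each traversed voxel. Returns distance actually
// travelled (< s means the packet left the grid). Grid origin at `org`,
// isotropic voxel size h, dims nx,ny,nz.
static double march(double *x, double *y, double *z,
                    double dx, double dy, double dz, double s, double w,
                    double orgx, double orgy, double orgz, double h,
                    int nx, int ny, int nz, double *tally, bool *escaped) {
  double px = *x, py = *y, pz = *z;
  int ix = (int)std::floor((px - orgx) / h);
  int iy = (int)std::floor((py - orgy) / h);
  int iz = (int)std::floor((pz - orgz) / h);
  if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
    *escaped = true;
    return 0.0;
  }
  const double BIG = 1e30;
  int stepx = dx > 0 ? 1 : (dx < 0 ? -1 : 0);
  int stepy = dy > 0 ? 1 : (dy < 0 ? -1 : 0);
  int stepz = dz > 0 ? 1 : (dz < 0 ? -1 : 0);
  double tdx = stepx != 0 ? h / std::fabs(dx) : BIG;
  double tdy = stepy != 0 ? h / std::fabs(dy) : BIG;
  double tdz = stepz != 0 ? h / std::fabs(dz) : BIG;
  // distance to first crossing on each axis
  double tx = stepx > 0 ? ((orgx + (ix + 1) * h) - px) / dx
            : (stepx < 0 ? ((orgx + ix * h) - px) / dx : BIG);
  double ty = stepy > 0 ? ((orgy + (iy + 1) * h) - py) / dy
            : (stepy < 0 ? ((orgy + iy * h) - py) / dy : BIG);
  double tz = stepz > 0 ? ((orgz + (iz + 1) * h) - pz) / dz
            : (stepz < 0 ? ((orgz + iz * h) - pz) / dz : BIG);
  double t = 0.0;
  *escaped = false;
  while (true) {
    double tnext = tx < ty ? (tx < tz ? tx : tz) : (ty < tz ? ty : tz);
    if (tnext >= s) {
      tally[(size_t)ix + nx * ((size_t)iy + (size_t)ny * iz)] += w * (s - t);
      t = s;
      break;
    }
    tally[(size_t)ix + nx * ((size_t)iy + (size_t)ny * iz)] += w * (tnext - t);
    t = tnext;
    if (tx <= ty && tx <= tz) { ix += stepx; tx += tdx; }
    else if (ty <= tz)        { iy += stepy; ty += tdy; }
    else                      { iz += stepz; tz += tdz; }
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
      *escaped = true;
      break;
    }
  }
  *x = px + dx * t;
  *y = py + dy * t;
  *z = pz + dz * t;
  return t;
}

// [[Rcpp::export(name = ".mc_fluence")]]
List mc_fluence(int n_packets, double mu_a, double mu_s,
                double g, double sigma_theta,
                double tip_x, double tip_y, double tip_z,
                double core_radius,
                double org_x, double org_y, double org_z,
                double voxel, int nx, int ny, int nz,
                double w_min, double rr_survive) {
  NumericVector values((size_t)nx * ny * nz);
  double *tally = REAL(values);
  double mu_t = mu_a + mu_s;
  double deposited = 0.0, escaped_w = 0.0, rr_killed = 0.0, rr_boost = 0.0;
  RNGScope scope;
  for (int p = 0; p < n_packets; p++) {
    // launch from a uniform point on the fiber core face
    double r = core_radius * std::sqrt(unif_rand());
    double a = 2.0 * M_PI * unif_rand();
    double x = tip_x + r * std::cos(a);
    double y = tip_y + r * std::sin(a);
    double z = tip_z;
    double dx, dy, dz;
    launch_dir(sigma_theta, &dx, &dy, &dz);
    double w = 1.0;
    bool esc = false;
    if (mu_t <= 1e-12) {
      // ballistic medium: straight to the grid boundary
      march(&x, &y, &z, dx, dy, dz, 1e9, w,
            org_x, org_y, org_z, voxel, nx, ny, nz, tally, &esc);
      escaped_w += w;
      continue;
    }
    while (true) {
      double s = -std::log(unif_rand()) / mu_t;
      march(&x, &y, &z, dx, dy, dz, s, w,
            org_x, org_y, org_z, voxel, nx, ny, nz, tally, &esc);
      if (esc) { escaped_w += w; break; }
      double dep = w * mu_a / mu_t;
      deposited += dep;
      w -= dep;
      scatter_dir(hg_cosine(g), &dx, &dy, &dz);
      if (w < w_min) {
        if (unif_rand() < rr_survive) {
          rr_boost += w * (1.0 / rr_survive - 1.0);
          w /= rr_survive;
        } else {
          rr_killed += w;
          break;
        }
      }
    }
  }
  return List::create(_["values"] = values,
                      _["launched"] = (double)n_packets,
                      _["deposited"] = deposited,
                      _["escaped"] = escaped_w,
                      _["rr_killed"] = rr_killed,
                      _["rr_boost"] = rr_boost);
}

// Trilinear interpolation of a voxel field (values at voxel centers) at
// arbitrary points; zero outside the grid volume.
// [[Rcpp::export(name = ".trilinear_lookup")]]
NumericVector trilinear_lookup(const NumericVector& values, int nx, int ny, int nz,
                               double org_x, double org_y, double org_z,
                               double voxel, NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector out(n);
  double ext_x = nx * voxel, ext_y = ny * voxel, ext_z = nz * voxel;
  const double *v = REAL(values);
  for (int i = 0; i < n; i++) {
    double x = pts(i, 0) - org_x;
    double y = pts(i, 1) - org_y;
    double z = pts(i, 2) - org_z;
    if (x < 0 || x > ext_x || y < 0 || y > ext_y || z < 0 || z > ext_z) {
      out[i] = 0.0;
      continue;
    }
    double u = x / voxel - 0.5, w = y / voxel - 0.5, q = z / voxel - 0.5;
    int i0 = (int)std::floor(u), j0 = (int)std::floor(w), k0 = (int)std::floor(q);
    double fu = u - i0, fw = w - j0, fq = q - k0;
    if (i0 < 0) { i0 = 0; fu = 0.0; } if (i0 > nx - 2) { i0 = nx - 2; fu = 1.0; }
    if (j0 < 0) { j0 = 0; fw = 0.0; } if (j0 > ny - 2) { j0 = ny - 2; fw = 1.0; }
    if (k0 < 0) { k0 = 0; fq = 0.0; } if (k0 > nz - 2) { k0 = nz - 2; fq = 1.0; }
    double acc = 0.0;
    for (int dk = 0; dk < 2; dk++)
      for (int dj = 0; dj < 2; dj++)
        for (int di = 0; di < 2; di++) {
          double wt = (di ? fu : 1.0 - fu) * (dj ? fw : 1.0 - fw) *
                      (dk ? fq : 1.0 - fq);
          acc += wt * v[(size_t)(i0 + di) +
                        nx * ((size_t)(j0 + dj) + (size_t)ny * (k0 + dk))];
        }
    out[i] = acc;
  }
  return out;
}

// Causal convolution of binary spike trains (given as sparse source/bin
// indices, 1-based) with an indicator kernel sampled at the spike bin width,
// followed by block-mean downsampling to frames. Equivalent to dense
// convolution at the fine rate then averaging `factor` bins per frame.
// [[Rcpp::export(name = ".spikes_to_frames")]]
NumericMatrix spikes_to_frames(IntegerVector src, IntegerVector bin,
                               int n_src, int n_bins, NumericVector kernel,
                               int factor) {
  int n_frames = n_bins / factor;
  NumericMatrix out(n_src, n_frames);
  int K = kernel.size();
  for (R_xlen_t s = 0; s < src.size(); s++) {
    int i = src[s] - 1;
    int t0 = bin[s] - 1;
    for (int l = 0; l < K; l++) {
      int b = t0 + l;
      if (b >= n_bins) break;
      int f = b / factor;
      out(i, f) += kernel[l] / factor;
    }
  }
  return out;
}

// Row-wise causal deconvolution by back-substitution: solves
// conv(s, k)[1..T] = y for each row (k[0] != 0).
// [[Rcpp::export(name = ".deconv_rows")]]
NumericMatrix deconv_rows(NumericMatrix Y, NumericVector k) {
  int n = Y.nrow(), T = Y.ncol(), L = k.size();
  NumericMatrix S(n, T);
  for (int i = 0; i < n; i++) {
    for (int t = 0; t < T; t++) {
      double acc = 0.0;
      int mmax = t < L - 1 ? t : L - 1;
      for (int m = 1; m <= mmax; m++) acc += k[m] * S(i, t - m);
      S(i, t) = (Y(i, t) - acc) / k[0];
    }
  }
  return S;
}
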