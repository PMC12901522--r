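#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// density (g/cm^3) from Hounsfield units by the linear map -1000 -> 0, 0 -> 1
static inline double hu_to_density(double hu) {
  double rho = (hu + 1000.0) / 1000.0;
  return rho > 0.0 ? rho : 0.0;
}

// entry parameter t0 of the segment s + t*(r-s), t in [0,1], into the grid
// bounding box; returns 1.0 if the segment never enters the box
static double box_entry(const double s[3], const double d[3],
                        const double lo[3], const double hi[3]) {
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (d[a] == 0.0) {
      if (s[a] < lo[a] || s[a] > hi[a]) return 1.0;
    } else {
      double ta = (lo[a] - s[a]) / d[a];
      double tb = (hi[a] - s[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return (t0 < t1) ? t0 : 1.0;
}

// march one ray from source to target accumulating density * path length
static double march_ray(const NumericVector& hu, const int dim[3],
                        const double vox[3], const double orig[3],
                        const double src[3], const double tgt[3],
                        double max_step) {
  double d[3] = { tgt[0] - src[0], tgt[1] - src[1], tgt[2] - src[2] };
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L <= 0.0) return NA_REAL;
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = orig[a] - 0.5 * vox[a];
    hi[a] = lo[a] + dim[a] * vox[a];
  }
  double t0 = box_entry(src, d, lo, hi);
  double seg = (1.0 - t0) * L;
  if (seg <= 0.0) return 0.0;
  int nstep = (int)std::ceil(seg / max_step);
  double dt = (1.0 - t0) / nstep;
  double dl = seg / nstep;
  double acc = 0.0;
  for (int j = 0; j < nstep; ++j) {
    double t = t0 + (j + 0.5) * dt;
    int idx[3];
    bool inside = true;
    for (int a = 0; a < 3; ++a) {
      double p = src[a] + t * d[a];
      int i = (int)std::floor((p - lo[a]) / vox[a]);
      if (i < 0 || i >= dim[a]) { inside = false; break; }
      idx[a] = i;
    }
    if (!inside) continue;
    acc += hu_to_density(hu[idx[0] + dim[0] * (idx[1] + dim[1] * idx[2])]) * dl;
  }
  return acc;
}

// [[Rcpp::export(name = ".rad_depth_single")]]
double rad_depth_single(NumericVector hu, IntegerVector dim3, NumericVector vox,
                        NumericVector orig, NumericVector source,
                        NumericVector target, double max_step) {
  int dim[3] = { dim3[0], dim3[1], dim3[2] };
  double v[3] = { vox[0], vox[1], vox[2] };
  double o[3] = { orig[0], orig[1], orig[2] };
  double s[3] = { source[0], source[1], source[2] };
  double t[3] = { target[0], target[1], target[2] };
  return march_ray(hu, dim, v, o, s, t, max_step);
}

// radiological depth from one point source to every voxel centre
// [[Rcpp::export(name = ".rad_depth_field")]]
NumericVector rad_depth_field(NumericVector hu, IntegerVector dim3,
                              NumericVector vox, NumericVector orig,
                              NumericVector source, double max_step) {
  int dim[3] = { dim3[0], dim3[1], dim3[2] };
  double v[3] = { vox[0], vox[1], vox[2] };
  double o[3] = { orig[0], orig[1], orig[2] };
  double s[3] = { source[0], source[1], source[2] };
  R_xlen_t n = (R_xlen_t)dim[0] * dim[1] * dim[2];
  NumericVector out(n);
  R_xlen_t q = 0;
  for (int k = 0; k < dim[2]; ++k) {
    double tz = o[2] + k * v[2];
    for (int j = 0; j < dim[1]; ++j) {
      double ty = o[1] + j * v[1];
      for (int i = 0; i < dim[0]; ++i, ++q) {
        double t[3] = { o[0] + i * v[0], ty, tz };
        out[q] = march_ray(hu, dim, v, o, s, t, max_step);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// gamma analysis: reference-point-centred search over the evaluated
// distribution, offsets sorted by distance with early termination
// ---------------------------------------------------------------------------

struct Offset {
  double dx, dy, dz; // voxel units per axis
  double dist2;      // mm^2
};

static inline bool trilinear(const NumericVector& vol, const int dim[3],
                             double x, double y, double z, double* out) {
  // x, y, z in 0-based voxel coordinates
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > dim[0] - 1.0 || y > dim[1] - 1.0 || z > dim[2] - 1.0) return false;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > dim[0] - 2) i0 = dim[0] - 2;
  if (j0 > dim[1] - 2) j0 = dim[1] - 2;
  if (k0 > dim[2] - 2) k0 = dim[2] - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  R_xlen_t b = i0 + (R_xlen_t)dim[0] * (j0 + (R_xlen_t)dim[1] * k0);
  R_xlen_t sx = 1, sy = dim[0], sz = (R_xlen_t)dim[0] * dim[1];
  double c00 = vol[b] * (1 - fx) + vol[b + sx] * fx;
  double c10 = vol[b + sy] * (1 - fx) + vol[b + sy + sx] * fx;
  double c01 = vol[b + sz] * (1 - fx) + vol[b + sz + sx] * fx;
  double c11 = vol[b + sz + sy] * (1 - fx) + vol[b + sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  *out = c0 * (1 - fz) + c1 * fz;
  return true;
}

// [[Rcpp::export(name = ".gamma_core")]]
NumericVector gamma_core(NumericVector ref, NumericVector eval,
                         IntegerVector dim3, NumericVector voxel_mm,
                         double dose_crit_frac, double dta_mm,
                         double threshold_frac, double search_radius_mm,
                         double step_mm, double max_gamma) {
  int dim[3] = { dim3[0], dim3[1], dim3[2] };
  double vmm[3] = { voxel_mm[0], voxel_mm[1], voxel_mm[2] };
  R_xlen_t n = (R_xlen_t)dim[0] * dim[1] * dim[2];

  double dmax = 0.0;
  for (R_xlen_t q = 0; q < n; ++q) if (ref[q] > dmax) dmax = ref[q];
  if (dmax <= 0.0) stop("reference distribution is all zero");
  double dD = dose_crit_frac * dmax;
  double thresh = threshold_frac * dmax;
  double dta2 = dta_mm * dta_mm;

  // offset grid in steps of step_mm within the search radius, sorted by
  // distance so that the scan can stop as soon as the distance term alone
  // exceeds the running minimum
  std::vector<Offset> offs;
  int nst = (int)std::floor(search_radius_mm / step_mm);
  double r2max = search_radius_mm * search_radius_mm;
  for (int a = -nst; a <= nst; ++a)
    for (int b = -nst; b <= nst; ++b)
      for (int c = -nst; c <= nst; ++c) {
        double ox = a * step_mm, oy = b * step_mm, oz = c * step_mm;
        double d2 = ox * ox + oy * oy + oz * oz;
        if (d2 > r2max) continue;
        Offset o;
        o.dx = ox / vmm[0]; o.dy = oy / vmm[1]; o.dz = oz / vmm[2];
        o.dist2 = d2;
        offs.push_back(o);
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.dist2 < b.dist2; });
  size_t noff = offs.size();

  // capping the search at max_gamma never changes pass/fail classification
  // (any candidate with gamma <= 1 lies within dta of the voxel, hence
  // within the capped scan), it only leaves gamma values above the cap as
  // the best capped-scan value
  double cap2 = (max_gamma < R_PosInf) ? max_gamma * max_gamma : R_PosInf;
  NumericVector out(n, NA_REAL);
  R_xlen_t q = 0;
  for (int k = 0; k < dim[2]; ++k)
    for (int j = 0; j < dim[1]; ++j)
      for (int i = 0; i < dim[0]; ++i, ++q) {
        double dref = ref[q];
        if (dref < thresh) continue;
        double best = R_PosInf;
        for (size_t m = 0; m < noff; ++m) {
          double dterm = offs[m].dist2 / dta2;
          if (dterm >= best || dterm >= cap2) break;
          double dv;
          if (!trilinear(eval, dim, i + offs[m].dx, j + offs[m].dy,
                         k + offs[m].dz, &dv)) continue;
          double dd = (dv - dref) / dD;
          double g2 = dterm + dd * dd;
          if (g2 < best) best = g2;
        }
        out[q] = std::sqrt(best);
      }
  return out;
}
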