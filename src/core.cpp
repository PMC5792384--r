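#include <Rcpp.h>
using namespace Rcpp;

// Image convention used throughout: an R matrix with nrow = ny rows and
// ncol = nx columns.  Physical coordinates (mm): x = (col - (nx+1)/2) * h
// (increasing to the right), y = ((ny+1)/2 - row) * h (increasing upward,
// so row 1 is the top of the image).  A projection ray for (angle, s) is
// the line {p : p.x*cos(angle) + p.y*sin(angle) = s}.

struct RayHit {
  std::vector<int> idx;      // 0-based column-major pixel index
  std::vector<double> len;   // intersection length, mm
};

// Amanatides–Woo style traversal of the pixel grid.
static RayHit trace_ray(int nx, int ny, double h, double angle, double s) {
  RayHit out;
  const double cx = std::cos(angle), sx = std::sin(angle);
  // point on ray closest to origin, direction along the ray
  const double px = s * cx, py = s * sx;
  const double dx = -sx, dy = cx;
  const double Lx = 0.5 * nx * h, Ly = 0.5 * ny * h;
  const double eps = 1e-12;

  double tmin = -1e18, tmax = 1e18;
  if (std::fabs(dx) < eps) {
    if (px <= -Lx || px >= Lx) return out;
  } else {
    double t1 = (-Lx - px) / dx, t2 = (Lx - px) / dx;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
  }
  if (std::fabs(dy) < eps) {
    if (py <= -Ly || py >= Ly) return out;
  } else {
    double t1 = (-Ly - py) / dy, t2 = (Ly - py) / dy;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
  }
  if (tmax <= tmin) return out;

  // entry point, nudged inside
  double t = tmin;
  double ex = px + (t + 1e-9) * dx;
  double ey = py + (t + 1e-9) * dy;
  int ix = (int)std::floor((ex + Lx) / h);   // 0..nx-1, column index
  int iy = (int)std::floor((ey + Ly) / h);   // 0 at bottom
  if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
  if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;

  const int stepx = (dx > 0) ? 1 : -1;
  const int stepy = (dy > 0) ? 1 : -1;
  const double tdx = (std::fabs(dx) < eps) ? 1e18 : h / std::fabs(dx);
  const double tdy = (std::fabs(dy) < eps) ? 1e18 : h / std::fabs(dy);

  double txnext, tynext;
  if (std::fabs(dx) < eps) txnext = 1e18;
  else {
    double xb = -Lx + (dx > 0 ? (ix + 1) : ix) * h;
    txnext = (xb - px) / dx;
  }
  if (std::fabs(dy) < eps) tynext = 1e18;
  else {
    double yb = -Ly + (dy > 0 ? (iy + 1) : iy) * h;
    tynext = (yb - py) / dy;
  }

  while (t < tmax - 1e-12) {
    double tnext = std::min(std::min(txnext, tynext), tmax);
    double seg = tnext - t;
    if (seg > 1e-12 && ix >= 0 && ix < nx && iy >= 0 && iy < ny) {
      int row = ny - 1 - iy;           // row 1 (index 0) is top
      out.idx.push_back(row + ix * ny);
      out.len.push_back(seg);
    }
    t = tnext;
    if (txnext <= tynext) { ix += stepx; txnext += tdx; }
    else                  { iy += stepy; tynext += tdy; }
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_siddon_ray(int nx, int ny, double h, double angle, double s) {
  RayHit r = trace_ray(nx, ny, h, angle, s);
  IntegerVector idx(r.idx.begin(), r.idx.end());
  NumericVector len(r.len.begin(), r.len.end());
  return List::create(_["idx"] = idx + 1, _["len"] = len);
}

// Forward projection: line integrals (value * mm) over all (bin, angle) rays.
// Returns an nbins x nangles matrix.
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericMatrix img, double h, NumericVector angles,
                          int nbins, double ds) {
  const int ny = img.nrow(), nx = img.ncol(), na = angles.size();
  NumericMatrix sino(nbins, na);
  const double s0 = 0.5 * (nbins + 1);
  for (int a = 0; a < na; ++a) {
    const double ang = angles[a];
    for (int b = 0; b < nbins; ++b) {
      const double s = ((b + 1) - s0) * ds;
      RayHit r = trace_ray(nx, ny, h, ang, s);
      double acc = 0.0;
      for (size_t k = 0; k < r.idx.size(); ++k) acc += img[r.idx[k]] * r.len[k];
      sino(b, a) = acc;
    }
  }
  return sino;
}

// Pixel-driven backprojection of a (filtered) sinogram with linear
// interpolation between radial bins.  Includes the pi/n_angles factor.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector angles,
                              int nx, int ny, double h, double ds) {
  const int nbins = sino.nrow(), na = angles.size();
  NumericMatrix img(ny, nx);
  const double s0 = 0.5 * (nbins + 1);
  std::vector<double> ca(na), sa(na);
  for (int a = 0; a < na; ++a) { ca[a] = std::cos(angles[a]); sa[a] = std::sin(angles[a]); }
  for (int c = 0; c < nx; ++c) {
    const double x = ((c + 1) - 0.5 * (nx + 1)) * h;
    for (int r = 0; r < ny; ++r) {
      const double y = (0.5 * (ny + 1) - (r + 1)) * h;
      double acc = 0.0;
      for (int a = 0; a < na; ++a) {
        const double s = x * ca[a] + y * sa[a];
        const double bf = s / ds + s0 - 1.0;   // 0-based bin position
        const int b0 = (int)std::floor(bf);
        const double w = bf - b0;
        if (b0 >= 0 && b0 < nbins - 1)
          acc += (1.0 - w) * sino(b0, a) + w * sino(b0 + 1, a);
        else if (b0 == nbins - 1 && w < 1e-9)
          acc += sino(b0, a);
      }
      img(r, c) = acc * M_PI / na;
    }
  }
  return img;
}

// Backward (pull-back) warp: out(r, c) = img(r + dr(r,c), c + dc(r,c)),
// displacements in pixel units, bilinear interpolation, `fill` outside.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix img, NumericMatrix dr,
                                NumericMatrix dc, double fill) {
  const int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  for (int c = 0; c < nx; ++c) {
    for (int r = 0; r < ny; ++r) {
      const double rs = r + dr(r, c);
      const double cs = c + dc(r, c);
      const int r0 = (int)std::floor(rs), c0 = (int)std::floor(cs);
      if (r0 < 0 || c0 < 0 || r0 >= ny - 1 || c0 >= nx - 1) {
        // allow exact boundary hits
        if (rs >= 0 && cs >= 0 && rs <= ny - 1 && cs <= nx - 1) {
          const int ri = (int)std::lround(rs), ci = (int)std::lround(cs);
          out(r, c) = img(ri, ci);
        } else out(r, c) = fill;
        continue;
      }
      const double fr = rs - r0, fc = cs - c0;
      out(r, c) =
        (1 - fr) * (1 - fc) * img(r0, c0) +
        (1 - fr) * fc       * img(r0, c0 + 1) +
        fr       * (1 - fc) * img(r0 + 1, c0) +
        fr       * fc       * img(r0 + 1, c0 + 1);
    }
  }
  return out;
}

// Nearest-neighbour pull-back warp (for label maps).
// [[Rcpp::export]]
NumericMatrix cpp_warp_nearest(NumericMatrix img, NumericMatrix dr,
                               NumericMatrix dc, double fill) {
  const int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  for (int c = 0; c < nx; ++c) {
    for (int r = 0; r < ny; ++r) {
      const int rs = (int)std::lround(r + dr(r, c));
      const int cs = (int)std::lround(c + dc(r, c));
      out(r, c) = (rs < 0 || cs < 0 || rs >= ny || cs >= nx) ? fill : img(rs, cs);
    }
  }
  return out;
}

// Separable Gaussian blur, zero-padded boundary, kernel normalized to sum 1.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma_px) {
  const int ny = img.nrow(), nx = img.ncol();
  if (sigma_px <= 0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(4.0 * sigma_px));
  std::vector<double> k(2 * rad + 1);
  double ksum = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma_px * sigma_px));
    ksum += k[i + rad];
  }
  for (auto &v : k) v /= ksum;

  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int c = 0; c < nx; ++c)            // blur along rows (vertical)
    for (int r = 0; r < ny; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        const int rr = r + i;
        if (rr >= 0 && rr < ny) acc += k[i + rad] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nx; ++c)            // blur along columns (horizontal)
    for (int r = 0; r < ny; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        const int cc = c + i;
        if (cc >= 0 && cc < nx) acc += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  return out;
}
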