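#include <Rcpp.h>
using namespace Rcpp;

// Volumes are stored as R arrays with dim = (nz, ny, nx), i.e. z runs fastest
// in memory. All index arithmetic below is 0-based and in the (z, y, x) order
// used throughout the package. A target voxel index i maps to a continuous
// source index j = A * i + b; the caller assembles A and b from the grids and
// the (inverted) world transform so this file never sees physical units.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".sampleAffine3D")]]
List sampleAffine3D(NumericVector vox, IntegerVector srcDim,
                    NumericMatrix A, NumericVector b,
                    IntegerVector outDim, int interp, double fill) {
  const int snz = srcDim[0], sny = srcDim[1], snx = srcDim[2];
  const int nz = outDim[0], ny = outDim[1], nx = outDim[2];
  const double eps = 1e-9;
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  LogicalVector inside(n);
  const double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2);
  const double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2);
  const double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2);
  R_xlen_t t = 0;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      // hoist the x/y part of the affine map out of the z loop
      const double pz = a01 * y + a02 * x + b[0];
      const double py = a11 * y + a12 * x + b[1];
      const double px = a21 * y + a22 * x + b[2];
      for (int z = 0; z < nz; ++z, ++t) {
        const double jz = a00 * z + pz;
        const double jy = a10 * z + py;
        const double jx = a20 * z + px;
        bool in;
        double val = fill;
        if (interp == 0) {
          in = jz >= -eps && jz <= snz - 1 + eps &&
               jy >= -eps && jy <= sny - 1 + eps &&
               jx >= -eps && jx <= snx - 1 + eps;
          if (in) {
            const double cz = clampd(jz, 0.0, (double)(snz - 1));
            const double cy = clampd(jy, 0.0, (double)(sny - 1));
            const double cx = clampd(jx, 0.0, (double)(snx - 1));
            int z0 = (int)cz, y0 = (int)cy, x0 = (int)cx;
            if (z0 == snz - 1 && snz > 1) --z0;
            if (y0 == sny - 1 && sny > 1) --y0;
            if (x0 == snx - 1 && snx > 1) --x0;
            const int z1 = snz > 1 ? z0 + 1 : z0;
            const int y1 = sny > 1 ? y0 + 1 : y0;
            const int x1 = snx > 1 ? x0 + 1 : x0;
            const double fz = cz - z0, fy = cy - y0, fx = cx - x0;
            const R_xlen_t s00 = (R_xlen_t)snz * (y0 + (R_xlen_t)sny * x0);
            const R_xlen_t s01 = (R_xlen_t)snz * (y0 + (R_xlen_t)sny * x1);
            const R_xlen_t s10 = (R_xlen_t)snz * (y1 + (R_xlen_t)sny * x0);
            const R_xlen_t s11 = (R_xlen_t)snz * (y1 + (R_xlen_t)sny * x1);
            const double v000 = vox[z0 + s00], v100 = vox[z1 + s00];
            const double v010 = vox[z0 + s10], v110 = vox[z1 + s10];
            const double v001 = vox[z0 + s01], v101 = vox[z1 + s01];
            const double v011 = vox[z0 + s11], v111 = vox[z1 + s11];
            const double c00 = v000 * (1 - fz) + v100 * fz;
            const double c10 = v010 * (1 - fz) + v110 * fz;
            const double c01 = v001 * (1 - fz) + v101 * fz;
            const double c11 = v011 * (1 - fz) + v111 * fz;
            const double c0 = c00 * (1 - fy) + c10 * fy;
            const double c1 = c01 * (1 - fy) + c11 * fy;
            val = c0 * (1 - fx) + c1 * fx;
          }
        } else {
          // nearest neighbour over the half-open voxel boxes [k-0.5, k+0.5)
          in = jz >= -0.5 && jz < snz - 0.5 &&
               jy >= -0.5 && jy < sny - 0.5 &&
               jx >= -0.5 && jx < snx - 0.5;
          if (in) {
            const int kz = (int)std::floor(jz + 0.5);
            const int ky = (int)std::floor(jy + 0.5);
            const int kx = (int)std::floor(jx + 0.5);
            val = vox[kz + (R_xlen_t)snz * (ky + (R_xlen_t)sny * kx)];
          }
        }
        out[t] = val;
        inside[t] = in;
      }
    }
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// [[Rcpp::export(name = ".sampleAffine2D")]]
List sampleAffine2D(NumericVector img, IntegerVector srcDim,
                    NumericMatrix A, NumericVector b,
                    IntegerVector outDim, int interp, double fill) {
  const int snr = srcDim[0], snc = srcDim[1];
  const int nr = outDim[0], nc = outDim[1];
  const double eps = 1e-9;
  const R_xlen_t n = (R_xlen_t)nr * nc;
  NumericVector out(n);
  LogicalVector inside(n);
  const double a00 = A(0,0), a01 = A(0,1), a10 = A(1,0), a11 = A(1,1);
  R_xlen_t t = 0;
  for (int c = 0; c < nc; ++c) {
    const double pr = a01 * c + b[0];
    const double pc = a11 * c + b[1];
    for (int r = 0; r < nr; ++r, ++t) {
      const double jr = a00 * r + pr;
      const double jc = a10 * r + pc;
      bool in;
      double val = fill;
      if (interp == 0 || interp == 2) {
        // interp 2: bilinear with edge replication (always inside)
        in = interp == 2 ||
             (jr >= -eps && jr <= snr - 1 + eps &&
              jc >= -eps && jc <= snc - 1 + eps);
        if (in) {
          const double cr = clampd(jr, 0.0, (double)(snr - 1));
          const double cc = clampd(jc, 0.0, (double)(snc - 1));
          int r0 = (int)cr, c0 = (int)cc;
          if (r0 == snr - 1 && snr > 1) --r0;
          if (c0 == snc - 1 && snc > 1) --c0;
          const int r1 = snr > 1 ? r0 + 1 : r0;
          const int c1 = snc > 1 ? c0 + 1 : c0;
          const double fr = cr - r0, fc = cc - c0;
          const double v00 = img[r0 + (R_xlen_t)snr * c0];
          const double v10 = img[r1 + (R_xlen_t)snr * c0];
          const double v01 = img[r0 + (R_xlen_t)snr * c1];
          const double v11 = img[r1 + (R_xlen_t)snr * c1];
          val = (v00 * (1 - fr) + v10 * fr) * (1 - fc) +
                (v01 * (1 - fr) + v11 * fr) * fc;
        }
      } else {
        in = jr >= -0.5 && jr < snr - 0.5 && jc >= -0.5 && jc < snc - 0.5;
        if (in) {
          const int kr = (int)std::floor(jr + 0.5);
          const int kc = (int)std::floor(jc + 0.5);
          val = img[kr + (R_xlen_t)snr * kc];
        }
      }
      out[t] = val;
      inside[t] = in;
    }
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Factor-2 mean pooling along all axes of a (nz, ny, nx) array; trailing
// odd slices are dropped. Used to build the registration pyramid.
// [[Rcpp::export(name = ".meanPool3D")]]
NumericVector meanPool3D(NumericVector vox, IntegerVector srcDim) {
  const int snz = srcDim[0], sny = srcDim[1], snx = srcDim[2];
  const int nz = std::max(snz / 2, 1), ny = std::max(sny / 2, 1),
            nx = std::max(snx / 2, 1);
  NumericVector out((R_xlen_t)nz * ny * nx);
  const int dz = snz >= 2 ? 2 : 1, dy = sny >= 2 ? 2 : 1, dx = snx >= 2 ? 2 : 1;
  R_xlen_t t = 0;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z, ++t) {
        double s = 0.0;
        int cnt = 0;
        for (int ox = 0; ox < dx; ++ox)
          for (int oy = 0; oy < dy; ++oy)
            for (int oz = 0; oz < dz; ++oz) {
              s += vox[(dz * z + oz) +
                       (R_xlen_t)snz * ((dy * y + oy) +
                                        (R_xlen_t)sny * (dx * x + ox))];
              ++cnt;
            }
        out[t] = s / cnt;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, ny, nx);
  return out;
}
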