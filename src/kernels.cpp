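#include <Rcpp.h>
using namespace Rcpp;

// Foreground pixel indices (1-based, column-major) of depth background
// subtraction: valid in the frame and closer than the background by more
// than tau_mm, or valid where the background has no reference.
// [[Rcpp::export(name = ".fg_indices")]]
IntegerVector fg_indices(NumericMatrix frame, NumericMatrix bg, double tau_mm) {
  if (frame.nrow() != bg.nrow() || frame.ncol() != bg.ncol())
    stop("frame and background dimensions differ");
  R_xlen_t n = frame.size();
  std::vector<int> out;
  out.reserve(4096);
  const double *f = frame.begin();
  const double *b = bg.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double fi = f[i];
    if (fi <= 0) continue;
    double bi = b[i];
    if (bi == 0 || bi - fi > tau_mm) out.push_back((int)(i + 1));
  }
  return wrap(out);
}

// Entering-intersection depths of rays with the body primitives (leg and
// torso elliptic cylinder segments plus the head sphere), all in the
// body-local frame. Rays share one origin; directions are given per ray.
// Returns +Inf where a ray misses the body.
// [[Rcpp::export(name = ".cast_body")]]
NumericVector cast_body(NumericVector origin, NumericVector dx,
                        NumericVector dy, NumericVector dz,
                        NumericVector legs, NumericVector torso,
                        NumericVector head) {
  R_xlen_t n = dx.size();
  NumericVector out(n, R_PosInf);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double la = legs[0], lb = legs[1], lz0 = legs[2], lz1 = legs[3];
  const double ta = torso[0], tb = torso[1], tz0 = torso[2], tz1 = torso[3];
  const double hcx = head[0], hcz = head[1], hr = head[2];
  const double la2 = la * la, lb2 = lb * lb, ta2 = ta * ta, tb2 = tb * tb;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double Dx = dx[i], Dy = dy[i], Dz = dz[i];
    double best = R_PosInf;
    // leg cylinder
    {
      double qa = Dx * Dx / la2 + Dy * Dy / lb2;
      double qb = 2.0 * (ox * Dx / la2 + oy * Dy / lb2);
      double qc = ox * ox / la2 + oy * oy / lb2 - 1.0;
      double disc = qb * qb - 4.0 * qa * qc;
      if (disc > 0 && qa > 0) {
        double t = (-qb - std::sqrt(disc)) / (2.0 * qa);
        double z = oz + t * Dz;
        if (t > 0 && z >= lz0 && z <= lz1 && t < best) best = t;
      }
    }
    // torso cylinder
    {
      double qa = Dx * Dx / ta2 + Dy * Dy / tb2;
      double qb = 2.0 * (ox * Dx / ta2 + oy * Dy / tb2);
      double qc = ox * ox / ta2 + oy * oy / tb2 - 1.0;
      double disc = qb * qb - 4.0 * qa * qc;
      if (disc > 0 && qa > 0) {
        double t = (-qb - std::sqrt(disc)) / (2.0 * qa);
        double z = oz + t * Dz;
        if (t > 0 && z >= tz0 && z <= tz1 && t < best) best = t;
      }
    }
    // head sphere
    {
      double sx = ox - hcx, sy = oy, sz = oz - hcz;
      double qa = Dx * Dx + Dy * Dy + Dz * Dz;
      double qb = 2.0 * (sx * Dx + sy * Dy + sz * Dz);
      double qc = sx * sx + sy * sy + sz * sz - hr * hr;
      double disc = qb * qb - 4.0 * qa * qc;
      if (disc > 0) {
        double t = (-qb - std::sqrt(disc)) / (2.0 * qa);
        if (t > 0 && t < best) best = t;
      }
    }
    out[i] = best;
  }
  return out;
}
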