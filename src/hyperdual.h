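#ifndef MTMD_HYPERDUAL_H
#define MTMD_HYPERDUAL_H

#include <cmath>

// Hyper-dual number carrying a value, two directional first derivatives and
// the mixed second derivative. Evaluating f(x + e1 h1 + e2 h2) with e1^2 =
// e2^2 = 0 yields exact d f/da, df/db and d2 f/dadb for the two probe
// directions, so no truncation error enters the Wilson-B or d2q tensors.
struct HD {
  double f, d1, d2, d12;
  HD() : f(0), d1(0), d2(0), d12(0) {}
  HD(double v) : f(v), d1(0), d2(0), d12(0) {}
  HD(double v, double a, double b, double ab) : f(v), d1(a), d2(b), d12(ab) {}
};

inline HD operator+(const HD &a, const HD &b) {
  return HD(a.f + b.f, a.d1 + b.d1, a.d2 + b.d2, a.d12 + b.d12);
}
inline HD operator-(const HD &a, const HD &b) {
  return HD(a.f - b.f, a.d1 - b.d1, a.d2 - b.d2, a.d12 - b.d12);
}
inline HD operator-(const HD &a) { return HD(-a.f, -a.d1, -a.d2, -a.d12); }
inline HD operator*(const HD &a, const HD &b) {
  return HD(a.f * b.f,
            a.d1 * b.f + a.f * b.d1,
            a.d2 * b.f + a.f * b.d2,
            a.d12 * b.f + a.d1 * b.d2 + a.d2 * b.d1 + a.f * b.d12);
}
inline HD operator*(double s, const HD &a) { return HD(s) * a; }
inline HD operator*(const HD &a, double s) { return HD(s) * a; }

// chain rule through a scalar function g with derivatives g1 = g'(x), g2 = g''(x)
inline HD hd_chain(const HD &x, double g0, double g1, double g2) {
  return HD(g0, g1 * x.d1, g1 * x.d2, g1 * x.d12 + g2 * x.d1 * x.d2);
}

inline HD hd_inv(const HD &x) {
  double i = 1.0 / x.f;
  return hd_chain(x, i, -i * i, 2.0 * i * i * i);
}
inline HD operator/(const HD &a, const HD &b) { return a * hd_inv(b); }
inline HD hd_sqrt(const HD &x) {
  double r = std::sqrt(x.f);
  return hd_chain(x, r, 0.5 / r, -0.25 / (r * x.f));
}
inline HD hd_acos(const HD &x) {
  double s = 1.0 - x.f * x.f;
  double rs = std::sqrt(s);
  return hd_chain(x, std::acos(x.f), -1.0 / rs, -x.f / (s * rs));
}

// two-argument composition for atan2(y, x); smooth away from the origin
inline HD hd_atan2(const HD &y, const HD &x) {
  double r2 = x.f * x.f + y.f * y.f;
  double gx = -y.f / r2, gy = x.f / r2;
  double r4 = r2 * r2;
  double hxx = 2.0 * x.f * y.f / r4;
  double hyy = -hxx;
  double hxy = (y.f * y.f - x.f * x.f) / r4;
  HD out;
  out.f = std::atan2(y.f, x.f);
  out.d1 = gx * x.d1 + gy * y.d1;
  out.d2 = gx * x.d2 + gy * y.d2;
  out.d12 = gx * x.d12 + gy * y.d12 + hxx * x.d1 * x.d2 + hyy * y.d1 * y.d2 +
            hxy * (x.d1 * y.d2 + x.d2 * y.d1);
  return out;
}

struct HD3 {
  HD x, y, z;
};
inline HD3 hd3_sub(const HD3 &a, const HD3 &b) {
  return HD3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline HD hd3_dot(const HD3 &a, const HD3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline HD3 hd3_cross(const HD3 &a, const HD3 &b) {
  return HD3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline HD hd3_norm(const HD3 &a) { return hd_sqrt(hd3_dot(a, a)); }

#endif
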