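#ifndef CM_COMMON_H
#define CM_COMMON_H

#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>
#include <stdexcept>

namespace cm {

constexpr double MONOMER_NM   = 2.7;    // length added per (de)polymerization event
constexpr double SITE_SPACING = 27.0;   // one binding site per 27 nm of filament
constexpr double NA_CONV      = 6.022e-7; // molecules per (nm^3 * uM)
constexpr double INF_TIME     = std::numeric_limits<double>::infinity();

struct Vec3 {
    double x = 0, y = 0, z = 0;
    Vec3() = default;
    Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
    Vec3 operator+(const Vec3& o) const { return {x + o.x, y + o.y, z + o.z}; }
    Vec3 operator-(const Vec3& o) const { return {x - o.x, y - o.y, z - o.z}; }
    Vec3 operator*(double s) const { return {x * s, y * s, z * s}; }
    Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
    Vec3& operator-=(const Vec3& o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
};
inline Vec3 operator*(double s, const Vec3& v) { return v * s; }
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
    return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

// xoshiro256++ with splitmix64 seeding: fast, reproducible across platforms.
struct Rng {
    uint64_t s[4];
    explicit Rng(uint64_t seed = 1) { reseed(seed); }
    void reseed(uint64_t seed) {
        uint64_t x = seed;
        for (int i = 0; i < 4; ++i) {
            x += 0x9e3779b97f4a7c15ULL;
            uint64_t z = x;
            z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
            z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
    uint64_t next() {
        uint64_t r = rotl(s[0] + s[3], 23) + s[0];
        uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return r;
    }
    double unif() { // in (0,1)
        return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }
    double expo(double rate) { return -std::log(unif()) / rate; }
    int unifInt(int lo, int hi) { // inclusive
        return lo + static_cast<int>(next() % static_cast<uint64_t>(hi - lo + 1));
    }
};

// Forward-mode differentiation over six independent variables; used to obtain
// exact partial derivatives of the analytic excluded-volume kernel.
struct Dual6 {
    double v;
    double d[6];
    Dual6() : v(0) { for (double& k : d) k = 0; }
    Dual6(double val) : v(val) { for (double& k : d) k = 0; } // NOLINT implicit
    static Dual6 var(double val, int i) { Dual6 r(val); r.d[i] = 1.0; return r; }
};
inline Dual6 operator+(const Dual6& a, const Dual6& b) {
    Dual6 r(a.v + b.v);
    for (int i = 0; i < 6; ++i) r.d[i] = a.d[i] + b.d[i];
    return r;
}
inline Dual6 operator-(const Dual6& a, const Dual6& b) {
    Dual6 r(a.v - b.v);
    for (int i = 0; i < 6; ++i) r.d[i] = a.d[i] - b.d[i];
    return r;
}
inline Dual6 operator-(const Dual6& a) {
    Dual6 r(-a.v);
    for (int i = 0; i < 6; ++i) r.d[i] = -a.d[i];
    return r;
}
inline Dual6 operator*(const Dual6& a, const Dual6& b) {
    Dual6 r(a.v * b.v);
    for (int i = 0; i < 6; ++i) r.d[i] = a.d[i] * b.v + a.v * b.d[i];
    return r;
}
inline Dual6 operator/(const Dual6& a, const Dual6& b) {
    Dual6 r(a.v / b.v);
    double ib2 = 1.0 / (b.v * b.v);
    for (int i = 0; i < 6; ++i) r.d[i] = (a.d[i] * b.v - a.v * b.d[i]) * ib2;
    return r;
}
inline Dual6 sqrt(const Dual6& a) {
    Dual6 r(std::sqrt(a.v));
    double g = 0.5 / r.v;
    for (int i = 0; i < 6; ++i) r.d[i] = g * a.d[i];
    return r;
}
inline Dual6 log(const Dual6& a) {
    Dual6 r(std::log(a.v));
    double g = 1.0 / a.v;
    for (int i = 0; i < 6; ++i) r.d[i] = g * a.d[i];
    return r;
}
inline Dual6 atan(const Dual6& a) {
    Dual6 r(std::atan(a.v));
    double g = 1.0 / (1.0 + a.v * a.v);
    for (int i = 0; i < 6; ++i) r.d[i] = g * a.d[i];
    return r;
}
inline double val(double x) { return x; }
inline double val(const Dual6& x) { return x.v; }

} // namespace cm

#endif
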