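#ifndef CM_EXCLVOL_H
#define CM_EXCLVOL_H

// Analytic segment-segment excluded-volume potential.
//
// Pair kernel dU = 1/|r_i - r_j|^4 integrated in closed form over both
// segments (arc-length measure):
//
//   U = K_vol * L_i * L_j * E,   E = int_0^1 int_0^1 dt ds / q(t,s)^2,
//   q(t,s) = |c0 + t u - s v|^2 = a t^2 - 2 b t s + c s^2 + 2 d t - 2 e s + f
//
// with u = xi2-xi1, v = xj2-xj1, c0 = xi1-xj1 and invariants
// a = u.u, b = u.v, c = v.v, d = u.c0, e = v.c0, f = c0.c0.
//
// The s-integral is elementary (rational + arctan); the remaining t-integral
// reduces, after integrating the arctan terms by parts against
// d/dt[(At+B)/(K sqrt(Delta))] = Delta^{-3/2}, to integrals of rational
// functions with denominator Delta(t) * q(t,{0,1}), handled by partial
// fractions. Delta(t) = A t^2 + 2 B t + C with A = ac-b^2, B = cd-be,
// C = cf-e^2 is the (positive) discriminant quadratic.
//
// The kernel is templated so that evaluating it on Dual6 numbers yields the
// exact partial derivatives dE/d(a..f); endpoint forces follow by chain rule.
// Degenerate geometries (parallel or intersecting support lines, and the
// measure-zero configurations where the partial-fraction system becomes
// singular) are detected via pivot/positivity checks and handled by a
// documented 1e-3 nm perturbation, so the evaluation never returns
// non-finite values.

#include "cm_common.h"
#include "cm_exclvol_gen.h"

namespace cm {

struct Quad { // Q(t) = Q2 t^2 + 2 Qb t + Q0
    template<class T> struct Of { T Q2, Qb, Q0; };
};

// int_0^1 (al t + be) / (Q2 t^2 + 2 Qb t + Q0) dt for a positive-definite
// quadratic. Fails (returns false) if the discriminant is not safely positive.
template<class T>
bool lintQ(const T& al, const T& be, const T& Q2, const T& Qb, const T& Q0, T& out) {
    using std::sqrt; using std::log; using std::atan;
    T k = Q2 * Q0 - Qb * Qb;
    double scale = std::abs(val(Q2) * val(Q0)) + val(Qb) * val(Qb);
    if (!(val(k) > 1e-14 * scale)) return false;
    T sk = sqrt(k);
    T logpart = (al / (T(2.0) * Q2)) * log((Q2 + T(2.0) * Qb + Q0) / Q0);
    T atanpart = (be - al * Qb / Q2) * (atan((Q2 + Qb) / sk) - atan(Qb / sk)) / sk;
    out = logpart + atanpart;
    return true;
}

// int_0^1 (n2 t^2 + n1 t + n0) / (P(t) Q(t)) dt via partial fractions:
// solve N = (al t + be) Q + (ga t + de) P, then integrate each piece.
template<class T>
bool rintPQ(const T& n2, const T& n1, const T& n0,
            const T& P2, const T& Pb, const T& P0,
            const T& Q2, const T& Qb, const T& Q0, T& out) {
    T M[4][5] = {
        {Q2,          T(0.0), P2,          T(0.0), T(0.0)},
        {T(2.0) * Qb, Q2,     T(2.0) * Pb, P2,     n2},
        {Q0,          T(2.0) * Qb, P0,     T(2.0) * Pb, n1},
        {T(0.0),      Q0,     T(0.0),      P0,     n0}};
    // Gaussian elimination with partial pivoting; reject near-singular systems
    // (P and Q share a root only in degenerate geometries).
    double msc = 0;
    for (auto& row : M) for (int j = 0; j < 4; ++j) msc = std::max(msc, std::abs(val(row[j])));
    for (int col = 0; col < 4; ++col) {
        int piv = col;
        for (int r = col + 1; r < 4; ++r)
            if (std::abs(val(M[r][col])) > std::abs(val(M[piv][col]))) piv = r;
        if (std::abs(val(M[piv][col])) < 1e-10 * msc) return false;
        if (piv != col) for (int j = col; j < 5; ++j) std::swap(M[piv][j], M[col][j]);
        for (int r = col + 1; r < 4; ++r) {
            T fac = M[r][col] / M[col][col];
            for (int j = col; j < 5; ++j) M[r][j] = M[r][j] - fac * M[col][j];
        }
    }
    T sol[4];
    for (int r = 3; r >= 0; --r) {
        T acc = M[r][4];
        for (int j = r + 1; j < 4; ++j) acc = acc - M[r][j] * sol[j];
        sol[r] = acc / M[r][r];
    }
    T i1, i2;
    if (!lintQ(sol[0], sol[1], P2, Pb, P0, i1)) return false;
    if (!lintQ(sol[2], sol[3], Q2, Qb, Q0, i2)) return false;
    out = i1 + i2;
    return true;
}

// E = int int dt ds / q^2 given the six invariants. Returns false on
// (near-)degenerate geometry; caller perturbs and retries.
template<class T>
bool exclKernelE(const T& a, const T& b, const T& c, const T& d, const T& e,
                 const T& f, T& out) {
    using std::sqrt; using std::atan;
    T A = a * c - b * b;
    T B = c * d - b * e;
    T C = c * f - e * e;
    if (!(val(A) > 1e-12 * (std::abs(val(a) * val(c)) + val(b) * val(b))))
        return false; // parallel support lines
    if (!(val(C) > 0.0) || !(val(c) > 0.0) || !(val(a) > 0.0)) return false;
    // minimum of Delta over [0,1] ~ c * (squared gap); reject near contact
    double tstar = -val(B) / val(A);
    double dmin = (tstar > 0 && tstar < 1)
        ? val(C) - val(B) * val(B) / val(A)
        : std::min(val(C), val(A) + 2 * val(B) + val(C));
    if (dmin < 1e-4 * val(c)) return false; // support lines closer than ~1e-2 nm
    T K = A * C - B * B;
    if (!(val(K) > 1e-14 * (std::abs(val(A) * val(C)) + val(B) * val(B)))) return false;
    T m1 = b * d - a * e;
    T m2 = b * f - d * e;
    // q0 = q(t,0), q1 = q(t,1), Delta as (Q2, Qb, Q0) triples
    T q0_2 = a, q0_b = d, q0_0 = f;
    T q1_2 = a, q1_b = d - b, q1_0 = c - T(2.0) * e + f;
    T D_2 = A, D_b = B, D_0 = C;

    T T1, T2, Ra, Rb;
    if (!rintPQ(T(0.0), -b, c - e, D_2, D_b, D_0, q1_2, q1_b, q1_0, T1)) return false;
    if (!rintPQ(T(0.0), b, e, D_2, D_b, D_0, q0_2, q0_b, q0_0, T2)) return false;
    if (!rintPQ(A * m1, A * m2 + B * m1, B * m2,
                D_2, D_b, D_0, q0_2, q0_b, q0_0, Ra)) return false;
    if (!rintPQ(A * (A + m1), A * (B + m2) + B * (A + m1), B * (B + m2),
                D_2, D_b, D_0, q1_2, q1_b, q1_0, Rb)) return false;

    // boundary term [ (At+B) g(t) / (K sqrt(Delta)) ]_0^1,
    // g(t) = atan((c-p)/sqrt(Delta)) + atan(p/sqrt(Delta)), p = b t + e
    T sD1 = sqrt(A + T(2.0) * B + C);
    T sD0 = sqrt(C);
    T g1 = atan((c - b - e) / sD1) + atan((b + e) / sD1);
    T g0 = atan((c - e) / sD0) + atan(e / sD0);
    T bnd = ((A + B) * g1 / sD1 - B * g0 / sD0) / K;

    out = T(0.5) * (T1 + T2) + T(0.5) * c * (bnd - Ra / K + Rb / K);
    if (!std::isfinite(val(out)) || val(out) < 0.0) return false;
    return true;
}

// Smooth conservative cap on a pair energy: U -> Ucap tanh(U / Ucap).
// Leaves physical-scale energies untouched (relative error (U/Ucap)^2/3,
// ~3e-9 at U = 100 pN nm) while keeping the deep-overlap forces that can
// arise transiently mid-burst bounded. A monotone transform of a
// conservative potential is itself conservative.
constexpr double EV_UCAP = 1e5; // pN nm

// Energy (and optionally endpoint gradients, accumulated into g[0..3] for
// xi1, xi2, xj1, xj2) of one cylinder pair. Never returns non-finite values.
//
// rSoft > 0 replaces the pair kernel by 1/(r^2 + rSoft^2)^2 — the identical
// closed form with f -> f + rSoft^2 — bounding the contact force (the
// regularized evaluation used by the network force field; rSoft = 0 is the
// pure inverse-quartic of the defining integral).
inline double exclVolPair(Vec3 xi1, Vec3 xi2, Vec3 xj1, Vec3 xj2,
                          double Kvol, Vec3* g, bool wantGrad,
                          double rSoft = 0.0) {
    const double eps = 1e-3; // nm, documented degeneracy perturbation
    for (int attempt = 0; attempt < 4; ++attempt) {
        Vec3 u = xi2 - xi1, v = xj2 - xj1, c0 = xi1 - xj1;
        double a = dot(u, u), b = dot(u, v), c = dot(v, v);
        double d = dot(u, c0), e = dot(v, c0);
        double f = dot(c0, c0) + rSoft * rSoft;
        bool ok;
        if (!wantGrad) {
            double E;
            ok = (a > 0 && c > 0) && exclKernelE(a, b, c, d, e, f, E);
            if (ok) {
                double U = Kvol * std::sqrt(a) * std::sqrt(c) * E;
                return EV_UCAP * std::tanh(U / EV_UCAP);
            }
        } else {
            double Eval;
            ok = (a > 0 && c > 0) && exclKernelE(a, b, c, d, e, f, Eval);
            if (ok) {
                // fast path: generated closed-form partials, validated
                // against the reference value; dual-number fallback
                double Ev, dE[6];
                double out[7];
                exclKernelGen(a, b, c, d, e, f, out);
                bool genOk = std::isfinite(out[0]);
                for (int i = 1; i < 7 && genOk; ++i)
                    genOk = std::isfinite(out[i]);
                if (genOk)
                    genOk = std::abs(out[0] - Eval) <=
                            1e-8 * std::abs(Eval) + 1e-300;
                if (genOk) {
                    Ev = out[0];
                    for (int i = 0; i < 6; ++i) dE[i] = out[i + 1];
                } else {
                    Dual6 Ed;
                    if (!exclKernelE(Dual6::var(a, 0), Dual6::var(b, 1),
                                     Dual6::var(c, 2), Dual6::var(d, 3),
                                     Dual6::var(e, 4), Dual6::var(f, 5), Ed))
                        { ok = false; }
                    else {
                        Ev = Ed.v;
                        for (int i = 0; i < 6; ++i) dE[i] = Ed.d[i];
                    }
                }
                if (ok) {
                    double sa = std::sqrt(a), sc = std::sqrt(c);
                    double L = Kvol * sa * sc;
                    double U = L * Ev;
                    double Ua = Kvol * (sc / (2 * sa)) * Ev + L * dE[0];
                    double Ub = L * dE[1];
                    double Uc = Kvol * (sa / (2 * sc)) * Ev + L * dE[2];
                    double Ud = L * dE[3], Ue = L * dE[4], Uf = L * dE[5];
                    double th = std::tanh(U / EV_UCAP);
                    double dcap = 1.0 - th * th; // d/dU of the capped energy
                    U = EV_UCAP * th;
                    Ua *= dcap; Ub *= dcap; Uc *= dcap;
                    Ud *= dcap; Ue *= dcap; Uf *= dcap;
                    g[0] += Ua * (-2.0) * u + Ub * (-1.0) * v + Ud * (u - c0) +
                            Ue * v + Uf * 2.0 * c0;
                    g[1] += Ua * 2.0 * u + Ub * v + Ud * c0;
                    g[2] += Ub * (-1.0) * u + Uc * (-2.0) * v + Ud * (-1.0) * u +
                            Ue * ((-1.0) * c0 - v) + Uf * (-2.0) * c0;
                    g[3] += Ub * u + Uc * 2.0 * v + Ue * c0;
                    return U;
                }
            }
        }
        // Degenerate: perturb along the mutual normal (or any perpendicular),
        // first tilting cylinder j, then shifting it rigidly.
        Vec3 n = cross(u, v);
        if (norm(n) < 1e-12 * std::sqrt(a * c)) {
            Vec3 any = std::abs(u.x) < 0.9 * norm(u) ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
            n = cross(u, any);
        }
        double nn = norm(n);
        Vec3 dn = nn > 0 ? n * (eps / nn) : Vec3{eps, 0, 0};
        if (attempt == 0) { xj2 += dn; }
        else if (attempt == 1) { xj1 += dn; xj2 += dn; }
        else { Vec3 du = u * (eps / std::max(norm(u), 1e-12)); xj1 += du; xj2 += dn; }
    }
    return 0.0; // unreachable for sane inputs; keeps the contract "finite"
}

} // namespace cm

#endif
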