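// Coarse-grained force field for semi-flexible filament networks:
// harmonic cylinder stretching, angular bending between consecutive
// cylinders, analytic segment-segment excluded volume, branch junction
// (stretch + angle + dihedral), harmonic motor/linker bonds attached at
// fractional positions (lever rule), and exponential boundary repulsion.
// Conjugate-gradient equilibration with backtracking line search.

#include "cm_mech.h"
#include "cm_exclvol.h"
#include <algorithm>
#include <unordered_map>

namespace cm {

double stretchTerm(const Vec3& x1, const Vec3& x2, double K, double l0,
                   Vec3* g1, Vec3* g2) {
    Vec3 l = x2 - x1;
    double ln = norm(l);
    if (ln < 1e-12) throw std::runtime_error("zero-length cylinder");
    double dl = ln - l0;
    if (g1) {
        Vec3 f = l * (K * dl / ln);
        *g2 += f;
        *g1 -= f;
    }
    return 0.5 * K * dl * dl;
}

// eps (1 - cos(theta - theta0)) between vectors li, lj; gradients w.r.t. the
// raw vectors (caller maps to beads). theta0 = 0 is the smooth special case
// used for filament bending.
double angleTerm(const Vec3& li, const Vec3& lj, double eps, double theta0,
                 Vec3* gli, Vec3* glj) {
    double ni = norm(li), nj = norm(lj);
    if (ni < 1e-12 || nj < 1e-12) throw std::runtime_error("zero-length cylinder");
    double ct = dot(li, lj) / (ni * nj);
    ct = std::min(1.0, std::max(-1.0, ct));
    Vec3 dci = lj * (1.0 / (ni * nj)) - li * (ct / (ni * ni));
    Vec3 dcj = li * (1.0 / (ni * nj)) - lj * (ct / (nj * nj));
    if (theta0 == 0.0) {
        if (gli) { *gli -= dci * eps; *glj -= dcj * eps; }
        return eps * (1.0 - ct);
    }
    double th = std::acos(ct);
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double dU_dth = eps * std::sin(th - theta0);
    if (gli && st > 1e-8) { // degenerate frame: finite fallback (no gradient)
        double fac = -dU_dth / st;
        *gli += dci * fac;
        *glj += dcj * fac;
    }
    return eps * (1.0 - std::cos(th - theta0));
}

double bendTerm(const Vec3& x0, const Vec3& x1, const Vec3& x2, double eps,
                Vec3* g0, Vec3* g1, Vec3* g2) {
    Vec3 u = x1 - x0, v = x2 - x1;
    Vec3 gu{}, gv{};
    double U = angleTerm(u, v, eps, 0.0, g0 ? &gu : nullptr, g0 ? &gv : nullptr);
    if (g0) {
        *g0 -= gu;
        *g1 += gu - gv;
        *g2 += gv;
    }
    return U;
}

double bondTerm(const Vec3& xi1, const Vec3& xi2, const Vec3& xj1, const Vec3& xj2,
                double alpha, double beta, double K, double l0,
                Vec3* gi1, Vec3* gi2, Vec3* gj1, Vec3* gj2) {
    Vec3 xim = xi1 * (1 - alpha) + xi2 * alpha;
    Vec3 xjm = xj1 * (1 - beta) + xj2 * beta;
    Vec3 m = xjm - xim;
    double mn = norm(m);
    double dl = mn - l0;
    if (gi1 && mn > 1e-12) {
        Vec3 f = m * (K * dl / mn); // dU/dxjm
        *gj1 += f * (1 - beta);
        *gj2 += f * beta;
        *gi1 -= f * (1 - alpha);
        *gi2 -= f * alpha;
    }
    return 0.5 * K * dl * dl;
}

// Branch junction, mother cylinder i (fractional anchor gamma), daughter
// cylinder j attached at its minus bead xj1:
//   U = K_br (|d| - d0)^2 + eps_ang (1 - cos(theta_ij - theta0))
//     + eps_dihed (1 - cos(phi - phi0))
// with d = xj1 - xib, xib = (1-gamma) xi1 + gamma xi2; theta_ij the angle
// between the cylinder axes; phi the dihedral around d between the planes
// spanned by (xi2 - xib, d) and (lj, d). Mother-side gradients distributed
// by the lever rule at gamma.
double branchTerm(const Vec3& xi1, const Vec3& xi2, double gamma,
                  const Vec3& xj1, const Vec3& xj2, const FFParams& ff,
                  Vec3* gi1, Vec3* gi2, Vec3* gj1, Vec3* gj2) {
    const bool wantG = gi1 != nullptr;
    Vec3 xib = xi1 * (1 - gamma) + xi2 * gamma;
    Vec3 d = xj1 - xib;
    Vec3 li = xi2 - xi1, lj = xj2 - xj1;
    double U = 0;
    Vec3 gib{}, gj1v{}, gj2v{}, gi1v{}, gi2v{};

    // stretch (note: no 1/2, quadratic as written with constant K_br)
    double dn = norm(d);
    if (dn > 1e-12) {
        double dl = dn - ff.d0;
        U += ff.KbrStr * dl * dl;
        if (wantG) {
            Vec3 f = d * (2.0 * ff.KbrStr * dl / dn); // dU/dxj1
            gj1v += f;
            gib -= f;
        }
    } else {
        U += ff.KbrStr * ff.d0 * ff.d0;
    }

    // angle between the two cylinder axes
    Vec3 gli{}, glj{};
    U += angleTerm(li, lj, ff.epsBrAng, ff.theta0, wantG ? &gli : nullptr,
                   wantG ? &glj : nullptr);
    if (wantG) {
        gi1v -= gli; gi2v += gli;
        gj1v -= glj; gj2v += glj;
    }

    // dihedral around d between planes (a, d) and (lj, d), a = xi2 - xib
    Vec3 a = xi2 - xib;
    Vec3 n1 = cross(a, d), n2 = cross(lj, d);
    double m1 = norm(n1), m2 = norm(n2);
    if (m1 > 1e-9 && m2 > 1e-9) {
        double cp = dot(n1, n2) / (m1 * m2);
        cp = std::min(1.0, std::max(-1.0, cp));
        double phi = std::acos(cp);
        U += ff.epsBrDihed * (1.0 - std::cos(phi - ff.phi0));
        if (wantG) {
            double sp = std::sqrt(std::max(0.0, 1.0 - cp * cp));
            double dU_dcp;
            if (ff.phi0 == 0.0) dU_dcp = -ff.epsBrDihed;
            else if (sp > 1e-8)
                dU_dcp = -ff.epsBrDihed * std::sin(phi - ff.phi0) / sp;
            else dU_dcp = 0.0; // degenerate dihedral frame: finite fallback
            Vec3 w1 = n2 * (1.0 / (m1 * m2)) - n1 * (cp / (m1 * m1));
            Vec3 w2 = n1 * (1.0 / (m1 * m2)) - n2 * (cp / (m2 * m2));
            Vec3 dc_da = cross(d, w1);
            Vec3 dc_dlj = cross(d, w2);
            Vec3 dc_dd = cross(w1, a) + cross(w2, lj);
            // a = xi2 - xib, d = xj1 - xib, lj = xj2 - xj1
            gi2v += dc_da * dU_dcp;
            gib -= (dc_da + dc_dd) * dU_dcp;
            gj1v += (dc_dd - dc_dlj) * dU_dcp;
            gj2v += dc_dlj * dU_dcp;
        }
    }

    if (wantG) {
        // lever rule for the mother anchor
        gi1v += gib * (1 - gamma);
        gi2v += gib * gamma;
        *gi1 += gi1v; *gi2 += gi2v; *gj1 += gj1v; *gj2 += gj2v;
    }
    return U;
}

double boundaryTerm(const Vec3& x1, const Vec3& x2, const Boundary& b,
                    Vec3* g1, Vec3* g2) {
    double d1 = b.dist(x1), d2 = b.dist(x2);
    const Vec3& xn = d1 <= d2 ? x1 : x2;
    Vec3* gn = d1 <= d2 ? g1 : g2;
    double d = std::min(d1, d2);
    double U = b.eps * std::exp(-d / b.lambda);
    if (g1) *gn += b.distGrad(xn) * (-U / b.lambda);
    return U;
}

// closest distance between segments [p1,p2] and [q1,q2]
static double segSegDist(const Vec3& p1, const Vec3& p2, const Vec3& q1,
                         const Vec3& q2) {
    Vec3 d1 = p2 - p1, d2 = q2 - q1, r = p1 - q1;
    double a = dot(d1, d1), e = dot(d2, d2), f = dot(d2, r);
    double s = 0, t = 0;
    if (a <= 1e-12 && e <= 1e-12) return norm(r);
    if (a <= 1e-12) {
        t = std::min(1.0, std::max(0.0, f / e));
    } else {
        double c = dot(d1, r);
        if (e <= 1e-12) {
            s = std::min(1.0, std::max(0.0, -c / a));
        } else {
            double b = dot(d1, d2);
            double den = a * e - b * b;
            if (den > 1e-12) s = std::min(1.0, std::max(0.0, (b * f - c * e) / den));
            t = (b * s + f) / e;
            if (t < 0) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
            else if (t > 1) { t = 1; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
        }
    }
    return norm(p1 + d1 * s - (q1 + d2 * t));
}

std::vector<std::pair<int, int>> evPairs(const SimState& S, double skin) {
    std::vector<int> live;
    for (size_t i = 0; i < S.cyls.size(); ++i)
        if (S.cyls[i].fil >= 0 && S.fils[S.cyls[i].fil].alive) {
            bool inFil = false;
            for (int ci : S.fils[S.cyls[i].fil].cyls)
                if (ci == static_cast<int>(i)) { inFil = true; break; }
            if (inFil) live.push_back(static_cast<int>(i));
        }
    // branch-junction partners excluded from excluded volume
    std::set<std::pair<int, int>> branchSkip;
    for (const auto& e : S.elems)
        if (e.alive && e.kind == EL_BRANCH && e.filB >= 0 && S.fils[e.filB].alive) {
            int ci; double fr;
            S.materialToCyl(e.filA, e.posA, ci, fr);
            int cj = S.fils[e.filB].cyls.front();
            branchSkip.insert({std::min(ci, cj), std::max(ci, cj)});
        }
    std::vector<Vec3> mid(live.size());
    double maxLen = 0;
    for (size_t i = 0; i < live.size(); ++i) {
        const Cyl& c = S.cyls[live[i]];
        mid[i] = (S.pos[c.b1] + S.pos[c.b2]) * 0.5;
        maxLen = std::max(maxLen, norm(S.pos[c.b2] - S.pos[c.b1]));
    }
    double reach = S.ff.evCutoff + maxLen + skin; // midpoint-distance criterion
    std::vector<std::pair<int, int>> out;
    // simple O(n^2) scan with early distance rejection; n is a few hundred
    // at the scales this package targets, so this beats cell bookkeeping.
    for (size_t i = 0; i < live.size(); ++i) {
        const Cyl& ci = S.cyls[live[i]];
        for (size_t j = i + 1; j < live.size(); ++j) {
            const Cyl& cj = S.cyls[live[j]];
            Vec3 dm = mid[i] - mid[j];
            if (dot(dm, dm) > reach * reach) continue;
            if (ci.fil == cj.fil &&
                (ci.b1 == cj.b1 || ci.b1 == cj.b2 || ci.b2 == cj.b1 ||
                 ci.b2 == cj.b2))
                continue; // adjacent cylinders within one filament
            if (branchSkip.count({std::min(live[i], live[j]),
                                  std::max(live[i], live[j])}))
                continue;
            // exact segment-segment distance: keep only pairs that can
            // reach the interaction cutoff within the skin margin
            if (segSegDist(S.pos[ci.b1], S.pos[ci.b2], S.pos[cj.b1],
                           S.pos[cj.b2]) > S.ff.evCutoff + skin)
                continue;
            out.push_back({live[i], live[j]});
        }
    }
    return out;
}

double computeEnergyForces(SimState& S, bool wantForces, EnergyTerms* terms,
                           const std::vector<std::pair<int, int>>* pairCache) {
    EnergyTerms T;
    if (wantForces)
        for (auto& f : S.frc) f = {0, 0, 0};
    auto G = [&](int b) { return wantForces ? &S.frc[b] : nullptr; };
    // NOTE: S.frc accumulates +gradient here; flipped to forces at the end.

    const double L0FULL = 40 * MONOMER_NM; // 108 nm reference cylinder
    const double LBENDMIN = 5 * MONOMER_NM; // joints need a defined direction
    for (size_t fi = 0; fi < S.fils.size(); ++fi) {
        const Fil& fl = S.fils[fi];
        if (!fl.alive) continue;
        for (size_t k = 0; k < fl.cyls.size(); ++k) {
            const Cyl& c = S.cyls[fl.cyls[k]];
            // constant extensional modulus: K scales as 1/l0 (springs in
            // series), so variable-length tip cylinders are not spuriously
            // compliant
            double Kc = S.ff.Kstr * (L0FULL / c.l0);
            T.stretch += stretchTerm(S.pos[c.b1], S.pos[c.b2], Kc, c.l0,
                                     G(c.b1), G(c.b2));
            T.boundary += boundaryTerm(S.pos[c.b1], S.pos[c.b2], S.bnd,
                                       G(c.b1), G(c.b2));
            if (k + 1 < fl.cyls.size()) {
                const Cyl& c2 = S.cyls[fl.cyls[k + 1]];
                // a freshly promoted few-monomer tip has no meaningful
                // bending direction of its own yet; the joint stiffness
                // scales as lp kBT / l (eps_bend is referenced to 108 nm)
                if (c.l0 >= LBENDMIN && c2.l0 >= LBENDMIN) {
                    double epsJ = S.ff.epsBend * (L0FULL / (0.5 * (c.l0 + c2.l0)));
                    T.bend += bendTerm(S.pos[c.b1], S.pos[c.b2], S.pos[c2.b2],
                                       epsJ, G(c.b1), G(c.b2), G(c2.b2));
                }
            }
        }
    }

    for (const auto& e : S.elems) {
        if (!e.alive) continue;
        if (e.kind == EL_BRANCH) {
            int ci; double gm;
            S.materialToCyl(e.filA, e.posA, ci, gm);
            const Cyl& cm = S.cyls[ci];
            const Cyl& cd = S.cyls[S.fils[e.filB].cyls.front()];
            T.branch += branchTerm(S.pos[cm.b1], S.pos[cm.b2], gm,
                                   S.pos[cd.b1], S.pos[cd.b2], S.ff,
                                   G(cm.b1), G(cm.b2), G(cd.b1), G(cd.b2));
        } else {
            int ca, cb; double al, be;
            S.materialToCyl(e.filA, e.posA, ca, al);
            S.materialToCyl(e.filB, e.posB, cb, be);
            const Cyl& A = S.cyls[ca];
            const Cyl& B = S.cyls[cb];
            double U = bondTerm(S.pos[A.b1], S.pos[A.b2], S.pos[B.b1], S.pos[B.b2],
                                al, be, e.K, e.l0,
                                G(A.b1), G(A.b2), G(B.b1), G(B.b2));
            if (e.kind == EL_MOTOR) T.motor += U; else T.linker += U;
        }
    }

    if (S.ff.Kvol > 0) {
        std::vector<std::pair<int, int>> local;
        if (!pairCache) local = evPairs(S);
        const auto& pairs = pairCache ? *pairCache : local;
        for (auto& pr : pairs) {
            const Cyl& ci = S.cyls[pr.first];
            const Cyl& cj = S.cyls[pr.second];
            if (wantForces) {
                Vec3 g[4] = {};
                T.exclvol += exclVolPair(S.pos[ci.b1], S.pos[ci.b2],
                                         S.pos[cj.b1], S.pos[cj.b2],
                                         S.ff.Kvol, g, true, S.ff.evSoft);
                S.frc[ci.b1] += g[0]; S.frc[ci.b2] += g[1];
                S.frc[cj.b1] += g[2]; S.frc[cj.b2] += g[3];
            } else {
                T.exclvol += exclVolPair(S.pos[ci.b1], S.pos[ci.b2],
                                         S.pos[cj.b1], S.pos[cj.b2],
                                         S.ff.Kvol, nullptr, false,
                                         S.ff.evSoft);
            }
        }
    }

    if (wantForces)
        for (auto& f : S.frc) f = f * (-1.0); // force = -gradient
    if (terms) *terms = T;
    double tot = T.total();
    if (!std::isfinite(tot)) throw std::runtime_error("non-finite energy");
    return tot;
}

double maxForce(const SimState& S) {
    double m = 0;
    std::vector<bool> used(S.pos.size(), false);
    for (const auto& c : S.cyls)
        if (c.fil >= 0 && S.fils[c.fil].alive) { used[c.b1] = used[c.b2] = true; }
    for (size_t i = 0; i < S.pos.size(); ++i)
        if (used[i]) m = std::max(m, norm(S.frc[i]));
    return m;
}

// Diagonal stiffness estimate per bead (pN/nm): sum of spring constants of
// attached cylinders and bonds plus a soft-mode floor. Used to precondition
// the conjugate gradient, which otherwise crawls on the wide spread between
// stiff stretch modes and soft bending/orientational modes.
static std::vector<double> diagStiffness(const SimState& S) {
    std::vector<double> M(S.pos.size(), 0.0);
    const double L0FULL = 40 * MONOMER_NM;
    for (const auto& c : S.cyls) {
        if (c.fil < 0 || !S.fils[c.fil].alive) continue;
        double Kc = S.ff.Kstr * (L0FULL / c.l0);
        M[c.b1] += Kc;
        M[c.b2] += Kc;
    }
    for (const auto& e : S.elems) {
        if (!e.alive || e.kind == EL_BRANCH) continue;
        int ca, cb; double al, be;
        S.materialToCyl(e.filA, e.posA, ca, al);
        S.materialToCyl(e.filB, e.posB, cb, be);
        M[S.cyls[ca].b1] += e.K; M[S.cyls[ca].b2] += e.K;
        M[S.cyls[cb].b1] += e.K; M[S.cyls[cb].b2] += e.K;
    }
    for (auto& m : M) m = std::max(m, 1.0);
    return M;
}

// Mechanical equilibration until the max per-bead force drops below tol.
// Two direction strategies share the quadratic/backtracking line search:
//  - L-BFGS (default): limited-memory quasi-Newton with the diagonal
//    stiffness estimate as the initial metric; far fewer iterations on the
//    stiff stretch/soft bending spectrum of these networks.
//  - Preconditioned Polak-Ribiere+ conjugate gradient with restarts.
// Energy is non-increasing across accepted steps by construction.
MinimizeResult minimize(SimState& S, double tol, int maxIter, int method) {
    MinimizeResult R;
    std::vector<int> act;
    {
        std::vector<bool> used(S.pos.size(), false);
        for (const auto& c : S.cyls)
            if (c.fil >= 0 && S.fils[c.fil].alive) used[c.b1] = used[c.b2] = true;
        for (size_t i = 0; i < used.size(); ++i)
            if (used[i]) act.push_back(static_cast<int>(i));
    }
    if (act.empty()) { R.converged = true; return R; }

    // excluded-volume pair list cached with a 30 nm skin, rebuilt once the
    // accumulated displacement could bring new pairs inside the cutoff
    const double SKIN = 30.0;
    std::vector<std::pair<int, int>> pairs = evPairs(S, SKIN);
    double dispAcc = 0;
    auto maybeRebuild = [&]() {
        if (dispAcc > SKIN / 2) { pairs = evPairs(S, SKIN); dispAcc = 0; }
    };

    std::vector<double> M = diagStiffness(S);
    double U = computeEnergyForces(S, true, nullptr, &pairs);
    R.U0 = U;
    R.energyTrace.push_back(U);
    std::vector<Vec3> g(act.size()), gOld(act.size()), dir(act.size());
    std::vector<double> Mi(act.size());
    for (size_t i = 0; i < act.size(); ++i) Mi[i] = 1.0 / M[act[i]];
    auto pullG = [&]() {
        for (size_t i = 0; i < act.size(); ++i) g[i] = S.frc[act[i]] * (-1.0);
    };
    pullG();
    // L-BFGS memory
    const int MEM = 8;
    std::vector<std::vector<Vec3>> sMem, yMem;
    std::vector<double> rhoMem;
    std::vector<Vec3> xPrevIt(act.size()), gPrevIt(act.size());
    auto lbfgsDir = [&]() {
        // two-loop recursion with H0 = gamma * diag(Mi)
        for (size_t i = 0; i < act.size(); ++i) dir[i] = g[i];
        int m = static_cast<int>(sMem.size());
        std::vector<double> alphaM(m);
        for (int k = m - 1; k >= 0; --k) {
            double sq = 0;
            for (size_t i = 0; i < act.size(); ++i) sq += dot(sMem[k][i], dir[i]);
            alphaM[k] = rhoMem[k] * sq;
            for (size_t i = 0; i < act.size(); ++i)
                dir[i] -= yMem[k][i] * alphaM[k];
        }
        double gamma = 1.0;
        if (m > 0) {
            double sy = 0, yy = 0;
            for (size_t i = 0; i < act.size(); ++i) {
                sy += dot(sMem[m - 1][i], yMem[m - 1][i]);
                yy += dot(yMem[m - 1][i], yMem[m - 1][i]);
            }
            if (yy > 0) gamma = sy / yy;
        }
        for (size_t i = 0; i < act.size(); ++i)
            dir[i] = dir[i] * (gamma * Mi[i] * M[act[0]]); // scale-free-ish
        for (int k = 0; k < m; ++k) {
            double yr = 0;
            for (size_t i = 0; i < act.size(); ++i) yr += dot(yMem[k][i], dir[i]);
            double beta = rhoMem[k] * yr;
            for (size_t i = 0; i < act.size(); ++i)
                dir[i] += sMem[k][i] * (alphaM[k] - beta);
        }
        for (size_t i = 0; i < act.size(); ++i) dir[i] = dir[i] * (-1.0);
    };
    if (method == 0) lbfgsDir();
    else for (size_t i = 0; i < act.size(); ++i) dir[i] = g[i] * (-Mi[i]);
    double alphaPrev = -1;
    std::vector<Vec3> xSave(act.size());
    int it = 0;
    int stall = 0;
    for (; it < maxIter; ++it) {
        double mf = 0;
        for (auto& gi : g) mf = std::max(mf, norm(gi));
        R.maxF = mf;
        if (mf < tol) { R.converged = true; break; }
        double gd = 0, dmax = 0;
        for (size_t i = 0; i < act.size(); ++i) {
            gd += dot(g[i], dir[i]);
            dmax = std::max(dmax, norm(dir[i]));
        }
        if (gd >= 0) { // not a descent direction: restart (preconditioned SD)
            sMem.clear(); yMem.clear(); rhoMem.clear();
            gd = 0;
            dmax = 0;
            for (size_t i = 0; i < act.size(); ++i) {
                dir[i] = g[i] * (-Mi[i]);
                gd += dot(g[i], dir[i]);
                dmax = std::max(dmax, norm(dir[i]));
            }
        }
        // cap displacement per step; tighten when forces are pathological
        // (deep transient overlaps) so trials stay on resolvable scales
        double dispCap = mf > 1e4 ? 0.5 : 10.0; // nm
        double alphaCap = dispCap / std::max(dmax, 1e-12);
        // L-BFGS directions carry their own scale: try the full step first
        double alpha = method == 0
            ? std::min(1.0, alphaCap)
            : (alphaPrev > 0 ? std::min(2 * alphaPrev, alphaCap)
                             : std::min(1.0, alphaCap));
        for (size_t i = 0; i < act.size(); ++i) xSave[i] = S.pos[act[i]];
        double aLast = -1;
        auto evalAt = [&](double a) {
            for (size_t i = 0; i < act.size(); ++i)
                S.pos[act[i]] = xSave[i] + dir[i] * a;
            aLast = a;
            return computeEnergyForces(S, false, nullptr, &pairs);
        };
        // two-evaluation quadratic line search with backtracking fallback
        bool accepted = false;
        double aBest = alpha, uBest = evalAt(alpha);
        if (method == 0 && uBest <= U + 1e-4 * alpha * gd) {
            // quasi-Newton unit step accepted as-is
        } else {
            double denom = 2.0 * (uBest - U - gd * alpha);
            double aq = denom > 0
                ? std::min(std::max(-gd * alpha * alpha / denom, 0.05 * alpha),
                           alphaCap)
                : std::min(4.0 * alpha, alphaCap);
            if (std::abs(aq - alpha) > 1e-3 * alpha &&
                !(uBest <= U + 1e-4 * alpha * gd && aq < alpha)) {
                double uq = evalAt(aq);
                if (uq < uBest) { aBest = aq; uBest = uq; }
            }
        }
        if (uBest <= U + 1e-4 * aBest * gd) {
            accepted = true;
        } else {
            double a = std::min(aBest, alpha);
            for (int bt = 0; bt < 45; ++bt) {
                a *= 0.5;
                double ub = evalAt(a);
                if (ub <= U + 1e-4 * a * gd) {
                    aBest = a; uBest = ub; accepted = true;
                    break;
                }
            }
        }
        if (!accepted) {
            for (size_t i = 0; i < act.size(); ++i) S.pos[act[i]] = xSave[i];
            bool wasSD = true;
            for (size_t i = 0; i < act.size() && wasSD; ++i)
                wasSD = norm(dir[i] + g[i] * Mi[i]) <
                        1e-10 * (norm(g[i]) * Mi[i] + 1e-300);
            if (wasSD) break; // line search exhausted on steepest descent
            sMem.clear(); yMem.clear(); rhoMem.clear();
            for (size_t i = 0; i < act.size(); ++i) dir[i] = g[i] * (-Mi[i]);
            alphaPrev = -1;
            continue;
        }
        if (aLast != aBest) evalAt(aBest); // leave positions at the accepted point
        U = uBest;
        alphaPrev = aBest;
        dispAcc += aBest * dmax;
        maybeRebuild();
        double dU = R.energyTrace.back() - U;
        R.energyTrace.push_back(U);
        if (dU < 1e-8 * std::max(std::abs(U), 1.0)) {
            if (++stall >= 8) break; // no meaningful progress: give up
        } else {
            stall = 0;
        }
        gOld.swap(g);
        computeEnergyForces(S, true, nullptr, &pairs);
        pullG();
        if (method == 0) {
            std::vector<Vec3> sv(act.size()), yv(act.size());
            double sy = 0;
            double snrm = 0, ynrm = 0;
            for (size_t i = 0; i < act.size(); ++i) {
                sv[i] = S.pos[act[i]] - xSave[i];
                yv[i] = g[i] - gOld[i];
                sy += dot(sv[i], yv[i]);
                snrm += dot(sv[i], sv[i]);
                ynrm += dot(yv[i], yv[i]);
            }
            if (sy > 1e-10 * std::sqrt(snrm * ynrm)) {
                sMem.push_back(std::move(sv));
                yMem.push_back(std::move(yv));
                rhoMem.push_back(1.0 / sy);
                if (static_cast<int>(sMem.size()) > MEM) {
                    sMem.erase(sMem.begin());
                    yMem.erase(yMem.begin());
                    rhoMem.erase(rhoMem.begin());
                }
            }
            lbfgsDir();
        } else {
            double num = 0, den = 0;
            for (size_t i = 0; i < act.size(); ++i) {
                num += Mi[i] * dot(g[i], g[i] - gOld[i]);
                den += Mi[i] * dot(gOld[i], gOld[i]);
            }
            double beta = den > 0 ? std::max(0.0, num / den) : 0.0;
            if ((it + 1) % 100 == 0) beta = 0; // periodic restart
            for (size_t i = 0; i < act.size(); ++i)
                dir[i] = g[i] * (-Mi[i]) + dir[i] * beta;
        }
    }
    R.iters = it;
    computeEnergyForces(S, true, nullptr);
    R.maxF = maxForce(S);
    if (R.maxF < tol) R.converged = true;
    R.U1 = U;
    return R;
}

// Fig-4 step 4: rates updated from post-equilibration forces.
//  - filament tips: Brownian ratchet exp(-F delta / kBT) on polymerization,
//    F = compressive boundary+excluded-volume load along the tip tangent
//  - linkers: slip bond exp(+F x_slip / kBT) on unbinding
//  - motor ensembles: walk rate v0 (1 - F/F_stall)+, unbinding
//    k0 exp(-F/F_char) (stress-stabilized attachment)
void updateMechanochemistry(SimState& S) {
    for (auto& e : S.elems) {
        if (!e.alive || e.kind == EL_BRANCH) continue;
        int ca, cb; double al, be;
        S.materialToCyl(e.filA, e.posA, ca, al);
        S.materialToCyl(e.filB, e.posB, cb, be);
        Vec3 xim = S.pos[S.cyls[ca].b1] * (1 - al) + S.pos[S.cyls[ca].b2] * al;
        Vec3 xjm = S.pos[S.cyls[cb].b1] * (1 - be) + S.pos[S.cyls[cb].b2] * be;
        double F = std::max(0.0, e.K * (norm(xjm - xim) - e.l0)); // tension
        e.load = F;
        if (!S.mc.enabled) {
            e.multUnbind = e.multWalkA = e.multWalkB = 1.0;
            continue;
        }
        if (e.kind == EL_LINKER) {
            e.multUnbind = std::exp(F * S.mc.xSlip / S.mc.kBT);
        } else {
            double Fstall = e.nheads * S.mc.fStallPerHead;
            e.multUnbind = std::exp(-F / S.mc.fChar);
            e.multWalkA = e.multWalkB = std::max(0.0, 1.0 - F / Fstall);
        }
    }
    // tip loads: boundary + excluded-volume forces projected on tip tangents
    std::vector<Vec3> bv(S.pos.size(), Vec3{});
    for (const auto& c : S.cyls) {
        if (c.fil < 0 || !S.fils[c.fil].alive) continue;
        Vec3 g1{}, g2{};
        boundaryTerm(S.pos[c.b1], S.pos[c.b2], S.bnd, &g1, &g2);
        bv[c.b1] -= g1; bv[c.b2] -= g2; // forces
    }
    if (S.ff.Kvol > 0) {
        for (auto& pr : evPairs(S)) {
            const Cyl& ci = S.cyls[pr.first];
            const Cyl& cj = S.cyls[pr.second];
            Vec3 g[4] = {};
            exclVolPair(S.pos[ci.b1], S.pos[ci.b2], S.pos[cj.b1], S.pos[cj.b2],
                        S.ff.Kvol, g, true, S.ff.evSoft);
            bv[ci.b1] -= g[0]; bv[ci.b2] -= g[1];
            bv[cj.b1] -= g[2]; bv[cj.b2] -= g[3];
        }
    }
    for (auto& fl : S.fils) {
        if (!fl.alive) continue;
        if (!S.mc.enabled) { fl.polyMult = 1.0; continue; }
        const Cyl& tip = S.cyls[fl.cyls.back()];
        Vec3 u = S.pos[tip.b2] - S.pos[tip.b1];
        double un = norm(u);
        if (un < 1e-12) { fl.polyMult = 1.0; continue; }
        u = u * (1.0 / un);
        double Fload = std::max(0.0, -dot(bv[tip.b2], u));
        fl.polyMult = std::exp(-Fload * S.mc.delta / S.mc.kBT);
    }
}

} // namespace cm
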