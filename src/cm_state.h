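#ifndef CM_STATE_H
#define CM_STATE_H

// Geometric + chemical state of a mechanochemical network simulation.
// Units throughout: nm, s, pN, pN nm.

#include "cm_common.h"
#include <array>
#include <map>
#include <set>
#include <string>

namespace cm {

enum Species { SP_ACTIN = 0, SP_LINKER = 1, SP_MOTOR = 2, N_SPECIES = 3 };

struct FFParams {
    double epsBend = 380.0;    // pN nm, from actin persistence length ~10 um at l0=108
    double Kstr    = 100.0;    // pN/nm per cylinder
    double Kvol    = 280.0;    // pN nm^3, arc-length-normalized repulsion scale
    double evCutoff = 60.0;   // nm, neighbor-list cutoff for excluded volume
    double evSoft  = 2.0;      // nm, contact-softening length of the pair kernel
    double KbrStr  = 100.0;    // pN/nm
    double d0      = 6.0;      // nm, branch tether rest length
    double epsBrAng = 100.0;   // pN nm
    double theta0  = 70.0 * M_PI / 180.0; // rad, Arp2/3 equilibrium branch angle
    double epsBrDihed = 50.0;  // pN nm
    double phi0    = 0.0;      // rad
    double Kmotor  = 2.5;      // pN/nm, NMIIA mini-filament
    double l0motor = 200.0;    // nm
    double Klinker = 8.0;      // pN/nm, alpha-actinin
    double l0linker = 35.0;    // nm
    double epsBound = 100.0;   // pN nm
    double lambdaBound = 2.7;  // nm
};

struct ChemParams {
    // actin kinetics (defaults: standard literature values, flagged `default`)
    double kPolyPlus  = 11.6;  // uM^-1 s^-1
    double kPolyMinus = 1.3;   // uM^-1 s^-1
    double kDepolyPlus  = 1.4; // s^-1
    double kDepolyMinus = 0.8; // s^-1
    double chi = 1.0;          // turnover factor on all four actin rates
    double D[N_SPECIES] = {2.5e6, 1.0e6, 2.0e5}; // nm^2/s
    double kOnLinker = 0.7;    // uM^-1 s^-1 per candidate site pair
    double kOffLinker = 0.3;   // s^-1
    double kOnMotor = 0.2;     // uM^-1 s^-1 per candidate site pair
    double kOffMotor0 = 0.2;   // s^-1 (1 / 5 s unloaded attachment time)
    double v0Walk = 15.0;      // steps/s per attached ensemble end (6 nm steps)
    double nucRate = 0.0;      // s^-1 per compartment per actin pair (fixtures)
    double motorRange = 200.0, motorTol = 25.0; // nm binding window
    double linkerRange = 35.0, linkerTol = 5.0; // nm binding window
};

struct MechChemParams {
    double delta = 2.7;        // nm, Brownian ratchet distance (one monomer)
    double xSlip = 0.35;       // nm, alpha-actinin slip distance
    double fStallPerHead = 2.5;// pN per myosin head
    double fChar = 12.5;       // pN, motor ensemble catch-bond scale
    double kBT = 4.1;          // pN nm
    bool enabled = true;
};

enum BoundaryShape { B_CUBE = 0, B_SPHERE = 1, B_CAPSULE = 2 };

struct Boundary {
    int shape = B_CUBE;
    double lx = 1000, ly = 1000, lz = 1000; // nm (sphere: lx = diameter)
    double eps = 100.0;   // pN nm
    double lambda = 2.7;  // nm

    // signed distance to the wall, positive inside
    double dist(const Vec3& p) const {
        if (shape == B_CUBE) {
            double d = p.x;
            d = std::min(d, lx - p.x);
            d = std::min(d, p.y); d = std::min(d, ly - p.y);
            d = std::min(d, p.z); d = std::min(d, lz - p.z);
            return d;
        }
        Vec3 c{lx / 2, ly / 2, lz / 2};
        if (shape == B_SPHERE) return lx / 2 - norm(p - c);
        // capsule: axis along x, radius ly/2, hemispherical caps
        double r = ly / 2;
        double ax0 = r, ax1 = lx - r;
        double px = std::min(std::max(p.x, ax0), ax1);
        Vec3 axisPt{px, c.y, c.z};
        return r - norm(p - axisPt);
    }
    // gradient of dist w.r.t. p
    Vec3 distGrad(const Vec3& p) const {
        if (shape == B_CUBE) {
            // gradient of the active wall
            double d = p.x; Vec3 g{1, 0, 0};
            if (lx - p.x < d) { d = lx - p.x; g = {-1, 0, 0}; }
            if (p.y < d) { d = p.y; g = {0, 1, 0}; }
            if (ly - p.y < d) { d = ly - p.y; g = {0, -1, 0}; }
            if (p.z < d) { d = p.z; g = {0, 0, 1}; }
            if (lz - p.z < d) { g = {0, 0, -1}; }
            return g;
        }
        Vec3 c{lx / 2, ly / 2, lz / 2};
        if (shape == B_SPHERE) {
            Vec3 rv = p - c; double r = norm(rv);
            return r > 1e-12 ? rv * (-1.0 / r) : Vec3{0, 0, 0};
        }
        double r0 = ly / 2;
        double px = std::min(std::max(p.x, r0), lx - r0);
        Vec3 rv = p - Vec3{px, c.y, c.z}; double r = norm(rv);
        return r > 1e-12 ? rv * (-1.0 / r) : Vec3{0, 0, 0};
    }
};

struct Cyl {
    int fil = -1;
    int b1 = -1, b2 = -1;  // bead indices, minus side / plus side
    int nmono = 0;
    double l0 = 0;         // nm, = nmono * 2.7
};

struct Fil {
    std::vector<int> cyls; // ordered minus -> plus
    long minusAbs = 0;     // absolute monomer index of the minus end (sticky sites)
    bool alive = false;
    double polyMult = 1.0; // Brownian-ratchet multiplier (plus end)
};

enum ElemKind { EL_LINKER = 0, EL_MOTOR = 1, EL_BRANCH = 2 };

struct Elem {
    int kind = EL_LINKER;
    bool alive = false;
    int filA = -1; double posA = 0; // absolute material coordinate, nm
    int filB = -1; double posB = 0; // branch: B = daughter filament, posB unused
    long siteA = -1, siteB = -1;    // anchor binding-site indices
    double K = 0, l0 = 0;
    int nheads = 0;                 // motors only
    double load = 0;                // pN, tension after last equilibration
    double multUnbind = 1.0, multWalkA = 1.0, multWalkB = 1.0;
};

struct BulkReaction { // well-mixed mass-action test reactions, per compartment
    int nr = 0;                       // number of reactant slots (0..2)
    int react[2] = {-1, -1};          // species
    int prod[3] = {-1, -1, -1};
    int np = 0;
    double k = 0;                     // s^-1 (order 0/1) or uM^-1 s^-1 (order 2)
};

struct SiteRef { long k; int cyl; double frac; double contour; };

struct SimState;
struct ChemEngine; // defined in cm_chem.cpp

struct SimState {
    FFParams ff;
    ChemParams chem;
    MechChemParams mc;
    Boundary bnd;
    double h = 500;               // compartment side, nm
    int nx = 2, ny = 2, nz = 2;
    bool exclusiveSites = false;  // linker/motor mutual exclusion on a site
    int maxMono = 40;             // monomers per full cylinder (l0 = 2.7 * maxMono)
    bool useNRM = true;
    double time = 0;
    Rng rng{1};

    std::vector<Vec3> pos, frc;
    std::vector<int> beadFree;
    std::vector<Cyl> cyls;
    std::vector<int> cylFree;
    std::vector<Fil> fils;
    std::vector<Elem> elems;
    std::vector<int> elemFree;
    std::vector<std::array<long, N_SPECIES>> counts; // per compartment copy numbers
    std::vector<BulkReaction> bulk;
    std::set<std::pair<int, long>> occLinker, occMotor;

    ChemEngine* eng = nullptr;
    ~SimState();

    int ncomp() const { return nx * ny * nz; }
    double vcomp() const { return h * h * h; }

    int compIndex(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }
    // half-open intervals [k h, (k+1) h); throws on out-of-bounds
    int compartmentOf(const Vec3& p, bool clamp = false) const {
        int ix = static_cast<int>(std::floor(p.x / h));
        int iy = static_cast<int>(std::floor(p.y / h));
        int iz = static_cast<int>(std::floor(p.z / h));
        if (clamp) {
            ix = std::min(std::max(ix, 0), nx - 1);
            iy = std::min(std::max(iy, 0), ny - 1);
            iz = std::min(std::max(iz, 0), nz - 1);
        } else if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
            throw std::runtime_error("point outside compartment grid");
        }
        return compIndex(ix, iy, iz);
    }

    int newBead(const Vec3& p) {
        int i;
        if (!beadFree.empty()) { i = beadFree.back(); beadFree.pop_back(); pos[i] = p; }
        else { i = static_cast<int>(pos.size()); pos.push_back(p); frc.push_back({}); }
        return i;
    }
    int newCyl(const Cyl& c) {
        int i;
        if (!cylFree.empty()) { i = cylFree.back(); cylFree.pop_back(); cyls[i] = c; }
        else { i = static_cast<int>(cyls.size()); cyls.push_back(c); }
        return i;
    }
    int newElem(const Elem& e) {
        int i;
        if (!elemFree.empty()) { i = elemFree.back(); elemFree.pop_back(); elems[i] = e; }
        else { i = static_cast<int>(elems.size()); elems.push_back(e); }
        return i;
    }

    long filMonomers(int f) const {
        long m = 0;
        for (int ci : fils[f].cyls) m += cyls[ci].nmono;
        return m;
    }
    double filMinusNm(int f) const { return fils[f].minusAbs * MONOMER_NM; }
    double filPlusNm(int f) const {
        return (fils[f].minusAbs + filMonomers(f)) * MONOMER_NM;
    }
    // material coordinate (absolute, nm) -> cylinder + fractional position
    void materialToCyl(int f, double posNm, int& cylOut, double& fracOut) const {
        const Fil& fl = fils[f];
        double start = filMinusNm(f);
        for (size_t i = 0; i < fl.cyls.size(); ++i) {
            double len = cyls[fl.cyls[i]].l0;
            if (posNm <= start + len || i + 1 == fl.cyls.size()) {
                cylOut = fl.cyls[i];
                fracOut = std::min(1.0, std::max(0.0, (posNm - start) / len));
                return;
            }
            start += len;
        }
        throw std::runtime_error("empty filament");
    }
    Vec3 pointAt(int f, double posNm) const {
        int ci; double fr;
        materialToCyl(f, posNm, ci, fr);
        return pos[cyls[ci].b1] * (1 - fr) + pos[cyls[ci].b2] * fr;
    }
    // whole-filament minus->plus direction (Eq-style unit vector)
    Vec3 filDirection(int f) const {
        const Fil& fl = fils[f];
        Vec3 d = pos[cyls[fl.cyls.back()].b2] - pos[cyls[fl.cyls.front()].b1];
        double n = norm(d);
        return n > 1e-12 ? d * (1.0 / n) : Vec3{0, 0, 0};
    }

    // Binding sites: one per 27 nm of filament, centered on the midpoints of
    // consecutive 27 nm intervals measured from the minus end; anchored to
    // absolute monomer positions so occupied sites never relocate.
    std::vector<SiteRef> bindingSites(int f) const {
        std::vector<SiteRef> out;
        double lo = filMinusNm(f), hi = filPlusNm(f);
        long kmin = static_cast<long>(std::ceil(lo / SITE_SPACING - 1e-9));
        for (long k = kmin;; ++k) {
            double start = k * SITE_SPACING;
            if (start + SITE_SPACING > hi + 1e-9) break;
            double center = start + SITE_SPACING / 2;
            int ci; double fr;
            materialToCyl(f, center, ci, fr);
            out.push_back({k, ci, fr, center - lo});
        }
        return out;
    }

    bool siteFree(int kind, int f, long k) const {
        if (kind == EL_LINKER) {
            if (occLinker.count({f, k})) return false;
            if (exclusiveSites && occMotor.count({f, k})) return false;
        } else {
            if (occMotor.count({f, k})) return false;
            if (exclusiveSites && occLinker.count({f, k})) return false;
        }
        return true;
    }

    int addFilamentBeads(const std::vector<Vec3>& beads,
                         const std::vector<int>& nmono, long minusAbs = 0) {
        if (beads.size() != nmono.size() + 1 || nmono.empty())
            throw std::runtime_error("bad filament spec");
        Fil fl; fl.alive = true; fl.minusAbs = minusAbs;
        int f = -1;
        for (size_t i = 0; i < fils.size(); ++i)
            if (!fils[i].alive) { f = static_cast<int>(i); break; }
        if (f < 0) { f = static_cast<int>(fils.size()); fils.push_back({}); }
        std::vector<int> bid(beads.size());
        for (size_t i = 0; i < beads.size(); ++i) bid[i] = newBead(beads[i]);
        for (size_t i = 0; i < nmono.size(); ++i) {
            Cyl c; c.fil = f; c.b1 = bid[i]; c.b2 = bid[i + 1];
            c.nmono = nmono[i]; c.l0 = nmono[i] * MONOMER_NM;
            fl.cyls.push_back(newCyl(c));
        }
        fils[f] = fl;
        return f;
    }

    long totalActin() const {
        long t = 0;
        for (const auto& c : counts) t += c[SP_ACTIN];
        for (size_t f = 0; f < fils.size(); ++f)
            if (fils[f].alive) t += filMonomers(static_cast<int>(f));
        return t;
    }
};

} // namespace cm

#endif
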