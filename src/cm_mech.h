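#ifndef CM_MECH_H
#define CM_MECH_H

#include "cm_state.h"

namespace cm {

// Per-term energy breakdown, in pN nm
struct EnergyTerms {
    double stretch = 0, bend = 0, exclvol = 0, motor = 0, linker = 0,
           branch = 0, boundary = 0;
    double total() const {
        return stretch + bend + exclvol + motor + linker + branch + boundary;
    }
};

// Stateless term evaluators (shared between the assembly loop and the
// R-level term interface). Gradients are ACCUMULATED into the g pointers.
double stretchTerm(const Vec3& x1, const Vec3& x2, double K, double l0,
                   Vec3* g1, Vec3* g2);
double bendTerm(const Vec3& x0, const Vec3& x1, const Vec3& x2, double eps,
                Vec3* g0, Vec3* g1, Vec3* g2);
double angleTerm(const Vec3& li, const Vec3& lj, double eps, double theta0,
                 Vec3* gli, Vec3* glj); // eps(1 - cos(theta - theta0))
double bondTerm(const Vec3& xi1, const Vec3& xi2, const Vec3& xj1, const Vec3& xj2,
                double alpha, double beta, double K, double l0,
                Vec3* gi1, Vec3* gi2, Vec3* gj1, Vec3* gj2);
double branchTerm(const Vec3& xi1, const Vec3& xi2, double gamma,
                  const Vec3& xj1, const Vec3& xj2, const FFParams& ff,
                  Vec3* gi1, Vec3* gi2, Vec3* gj1, Vec3* gj2);
double boundaryTerm(const Vec3& x1, const Vec3& x2, const Boundary& b,
                    Vec3* g1, Vec3* g2);

// Excluded-volume neighbor list: pairs of alive cylinders, excluding
// same-cylinder, bead-sharing neighbors within a filament, and
// branch-junction partners.
std::vector<std::pair<int, int>> evPairs(const SimState& S, double skin = 0.0);

// Total energy; if wantForces, fills S.frc with -gradient. An optional
// precomputed pair list (built with a skin margin) avoids re-running the
// neighbor search on every line-search evaluation.
double computeEnergyForces(SimState& S, bool wantForces, EnergyTerms* terms,
                           const std::vector<std::pair<int, int>>* pairCache
                               = nullptr);
double maxForce(const SimState& S);

struct MinimizeResult {
    bool converged = false;
    int iters = 0;
    double U0 = 0, U1 = 0, maxF = 0;
    std::vector<double> energyTrace; // accepted energies, non-increasing
};
// method: 0 = L-BFGS (default), 1 = Polak-Ribiere+ CG
MinimizeResult minimize(SimState& S, double tol, int maxIter, int method = 0);

// Fig-4 step 4: map post-equilibration forces to rate multipliers.
void updateMechanochemistry(SimState& S);

} // namespace cm

#endif
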