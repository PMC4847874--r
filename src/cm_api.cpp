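// R interface. The mutable simulation state lives behind an external
// pointer; all heavy loops (chemistry events, force evaluation, conjugate
// gradient) run in C++.

#include <Rcpp.h>
#include "cm_state.h"
#include "cm_mech.h"
#include "cm_chem.h"
#include "cm_exclvol.h"

using namespace Rcpp;
using namespace cm;

typedef XPtr<SimState> StatePtr;

static Vec3 asVec3(const NumericVector& v) {
    if (v.size() != 3) stop("expected a 3-vector");
    return {v[0], v[1], v[2]};
}

template <typename T>
static T getOr(const List& l, const char* name, T def) {
    if (l.containsElementNamed(name)) return as<T>(l[name]);
    return def;
}

static void fillParams(SimState& S, const List& ff, const List& chem,
                       const List& mc) {
    FFParams& F = S.ff;
    F.epsBend = getOr(ff, "eps_bend", F.epsBend);
    F.Kstr = getOr(ff, "k_str", F.Kstr);
    F.Kvol = getOr(ff, "k_vol", F.Kvol);
    F.evCutoff = getOr(ff, "ev_cutoff", F.evCutoff);
    F.evSoft = getOr(ff, "ev_soft", F.evSoft);
    F.KbrStr = getOr(ff, "k_branch_str", F.KbrStr);
    F.d0 = getOr(ff, "d0", F.d0);
    F.epsBrAng = getOr(ff, "eps_branch_ang", F.epsBrAng);
    F.theta0 = getOr(ff, "theta0", F.theta0);
    F.epsBrDihed = getOr(ff, "eps_branch_dihed", F.epsBrDihed);
    F.phi0 = getOr(ff, "phi0", F.phi0);
    F.Kmotor = getOr(ff, "k_motor", F.Kmotor);
    F.l0motor = getOr(ff, "l0_motor", F.l0motor);
    F.Klinker = getOr(ff, "k_linker", F.Klinker);
    F.l0linker = getOr(ff, "l0_linker", F.l0linker);

    ChemParams& C = S.chem;
    C.kPolyPlus = getOr(chem, "k_poly_plus", C.kPolyPlus);
    C.kPolyMinus = getOr(chem, "k_poly_minus", C.kPolyMinus);
    C.kDepolyPlus = getOr(chem, "k_depoly_plus", C.kDepolyPlus);
    C.kDepolyMinus = getOr(chem, "k_depoly_minus", C.kDepolyMinus);
    C.chi = getOr(chem, "chi", C.chi);
    C.D[SP_ACTIN] = getOr(chem, "d_actin", C.D[SP_ACTIN]);
    C.D[SP_LINKER] = getOr(chem, "d_linker", C.D[SP_LINKER]);
    C.D[SP_MOTOR] = getOr(chem, "d_motor", C.D[SP_MOTOR]);
    C.kOnLinker = getOr(chem, "k_on_linker", C.kOnLinker);
    C.kOffLinker = getOr(chem, "k_off_linker", C.kOffLinker);
    C.kOnMotor = getOr(chem, "k_on_motor", C.kOnMotor);
    C.kOffMotor0 = getOr(chem, "k_off_motor", C.kOffMotor0);
    C.v0Walk = getOr(chem, "v0_walk", C.v0Walk);
    C.nucRate = getOr(chem, "nucleation_rate", C.nucRate);
    C.motorRange = getOr(chem, "motor_range", C.motorRange);
    C.motorTol = getOr(chem, "motor_tol", C.motorTol);
    C.linkerRange = getOr(chem, "linker_range", C.linkerRange);
    C.linkerTol = getOr(chem, "linker_tol", C.linkerTol);

    MechChemParams& M = S.mc;
    M.delta = getOr(mc, "ratchet_delta", M.delta);
    M.xSlip = getOr(mc, "x_slip", M.xSlip);
    M.fStallPerHead = getOr(mc, "f_stall_per_head", M.fStallPerHead);
    M.fChar = getOr(mc, "f_char", M.fChar);
    M.kBT = getOr(mc, "kBT", M.kBT);
    M.enabled = getOr(mc, "enabled", M.enabled);
}

// [[Rcpp::export]]
SEXP cmNewState(NumericVector box, double h, List boundary, List ff,
                List chem, List mc, List flags, double seed) {
    SimState* S = new SimState();
    S->bnd.lx = box[0]; S->bnd.ly = box[1]; S->bnd.lz = box[2];
    std::string shape = getOr<std::string>(boundary, "shape", "cube");
    S->bnd.shape = shape == "sphere" ? B_SPHERE
                 : shape == "capsule" ? B_CAPSULE : B_CUBE;
    S->bnd.eps = getOr(boundary, "eps", S->bnd.eps);
    S->bnd.lambda = getOr(boundary, "lambda", S->bnd.lambda);
    S->h = h;
    S->nx = std::max(1, static_cast<int>(std::round(box[0] / h)));
    S->ny = std::max(1, static_cast<int>(std::round(box[1] / h)));
    S->nz = std::max(1, static_cast<int>(std::round(box[2] / h)));
    S->counts.assign(S->ncomp(), {0, 0, 0});
    fillParams(*S, ff, chem, mc);
    S->exclusiveSites = getOr(flags, "binding_site_exclusive", false);
    S->maxMono = getOr(flags, "monomers_per_cylinder", 40);
    S->useNRM = getOr<std::string>(flags, "algorithm", "nrm") != "direct";
    S->rng.reseed(static_cast<uint64_t>(seed));
    S->eng = new ChemEngine(*S);
    return StatePtr(S, true);
}

// [[Rcpp::export]]
int cmAddFilament(SEXP sp, NumericMatrix beads, IntegerVector nmono) {
    StatePtr S(sp);
    std::vector<Vec3> b;
    for (int i = 0; i < beads.nrow(); ++i)
        b.push_back({beads(i, 0), beads(i, 1), beads(i, 2)});
    std::vector<int> nm(nmono.begin(), nmono.end());
    return S->addFilamentBeads(b, nm);
}

// [[Rcpp::export]]
int cmAddBoundElement(SEXP sp, std::string kind, int filA, double posA,
                      int filB, double posB, int nheads) {
    StatePtr S(sp);
    Elem e;
    e.alive = true;
    e.filA = filA; e.posA = posA; e.filB = filB; e.posB = posB;
    e.siteA = static_cast<long>(std::floor(posA / SITE_SPACING));
    e.siteB = static_cast<long>(std::floor(posB / SITE_SPACING));
    if (kind == "linker") {
        e.kind = EL_LINKER; e.K = S->ff.Klinker; e.l0 = S->ff.l0linker;
        S->occLinker.insert({e.filA, e.siteA});
        S->occLinker.insert({e.filB, e.siteB});
    } else if (kind == "motor") {
        e.kind = EL_MOTOR; e.K = S->ff.Kmotor; e.l0 = S->ff.l0motor;
        e.nheads = nheads > 0 ? nheads : 20;
        S->occMotor.insert({e.filA, e.siteA});
        S->occMotor.insert({e.filB, e.siteB});
    } else stop("unknown element kind");
    return S->newElem(e);
}

// [[Rcpp::export]]
int cmAddBranch(SEXP sp, int filMother, double posA, int filDaughter) {
    StatePtr S(sp);
    Elem e;
    e.alive = true; e.kind = EL_BRANCH;
    e.filA = filMother; e.posA = posA; e.filB = filDaughter;
    e.siteA = static_cast<long>(std::floor(posA / SITE_SPACING));
    return S->newElem(e);
}

// [[Rcpp::export]]
void cmSetSpeciesCounts(SEXP sp, IntegerMatrix counts) {
    StatePtr S(sp);
    if (counts.nrow() != S->ncomp() || counts.ncol() != N_SPECIES)
        stop("counts must be ncomp x 3");
    for (int i = 0; i < counts.nrow(); ++i)
        for (int j = 0; j < N_SPECIES; ++j) {
            if (counts(i, j) < 0) stop("negative copy number");
            S->counts[i][j] = counts(i, j);
        }
}

// [[Rcpp::export]]
IntegerMatrix cmGetSpeciesCounts(SEXP sp) {
    StatePtr S(sp);
    IntegerMatrix m(S->ncomp(), N_SPECIES);
    for (int i = 0; i < S->ncomp(); ++i)
        for (int j = 0; j < N_SPECIES; ++j)
            m(i, j) = static_cast<int>(S->counts[i][j]);
    colnames(m) = CharacterVector::create("actin", "linker", "motor");
    return m;
}

// [[Rcpp::export]]
void cmAddBulkReaction(SEXP sp, IntegerVector react, IntegerVector prod,
                       double k) {
    StatePtr S(sp);
    if (react.size() > 2 || prod.size() > 3) stop("at most 2 reactants, 3 products");
    BulkReaction r;
    r.nr = react.size();
    for (int i = 0; i < r.nr; ++i) r.react[i] = react[i];
    r.np = prod.size();
    for (int i = 0; i < r.np; ++i) r.prod[i] = prod[i];
    r.k = k;
    S->bulk.push_back(r);
}

// [[Rcpp::export]]
List cmBindingSites(SEXP sp, int fil) {
    StatePtr S(sp);
    if (fil < 0 || fil >= static_cast<int>(S->fils.size()) || !S->fils[fil].alive)
        stop("no such filament");
    auto sites = S->bindingSites(fil);
    int n = static_cast<int>(sites.size());
    IntegerVector k(n), cyl(n);
    NumericVector frac(n), contour(n);
    LogicalVector occL(n), occM(n);
    for (int i = 0; i < n; ++i) {
        k[i] = static_cast<int>(sites[i].k);
        cyl[i] = sites[i].cyl;
        frac[i] = sites[i].frac;
        contour[i] = sites[i].contour;
        occL[i] = S->occLinker.count({fil, sites[i].k}) > 0;
        occM[i] = S->occMotor.count({fil, sites[i].k}) > 0;
    }
    return DataFrame::create(_["site"] = k, _["cylinder"] = cyl,
                             _["frac"] = frac, _["contour"] = contour,
                             _["linker_bound"] = occL, _["motor_bound"] = occM);
}

// [[Rcpp::export]]
List cmPairCandidates(SEXP sp) {
    StatePtr S(sp);
    auto cands = S->eng->findCandidates();
    int n = static_cast<int>(cands.size());
    IntegerVector fa(n), fb(n), comp(n);
    IntegerVector sa(n), sb(n);
    NumericVector d(n);
    CharacterVector kind(n);
    for (int i = 0; i < n; ++i) {
        fa[i] = cands[i].filA; sa[i] = static_cast<int>(cands[i].siteA);
        fb[i] = cands[i].filB; sb[i] = static_cast<int>(cands[i].siteB);
        comp[i] = cands[i].comp;
        d[i] = cands[i].dist;
        kind[i] = cands[i].kind == EL_LINKER ? "linker" : "motor";
    }
    return DataFrame::create(_["kind"] = kind, _["filA"] = fa, _["siteA"] = sa,
                             _["filB"] = fb, _["siteB"] = sb,
                             _["compartment"] = comp, _["dist"] = d);
}

// [[Rcpp::export]]
IntegerVector cmCompartmentOf(SEXP sp, NumericVector point) {
    StatePtr S(sp);
    Vec3 p = asVec3(point);
    int lin = S->compartmentOf(p); // throws when outside
    int iz = lin / (S->nx * S->ny);
    int iy = (lin / S->nx) % S->ny;
    int ix = lin % S->nx;
    return IntegerVector::create(_["ix"] = ix, _["iy"] = iy, _["iz"] = iz,
                                 _["linear"] = lin);
}

// [[Rcpp::export]]
double cmTotalActin(SEXP sp) {
    StatePtr S(sp);
    return static_cast<double>(S->totalActin());
}

// [[Rcpp::export]]
double cmTime(SEXP sp) { return StatePtr(sp)->time; }

// [[Rcpp::export]]
List cmSnapshot(SEXP sp) {
    StatePtr S(sp);
    List fl;
    for (size_t f = 0; f < S->fils.size(); ++f) {
        if (!S->fils[f].alive) continue;
        const Fil& F = S->fils[f];
        int nc = static_cast<int>(F.cyls.size());
        NumericMatrix beads(nc + 1, 3);
        IntegerVector nm(nc);
        for (int i = 0; i < nc; ++i) {
            const Cyl& c = S->cyls[F.cyls[i]];
            beads(i, 0) = S->pos[c.b1].x;
            beads(i, 1) = S->pos[c.b1].y;
            beads(i, 2) = S->pos[c.b1].z;
            if (i == nc - 1) {
                beads(nc, 0) = S->pos[c.b2].x;
                beads(nc, 1) = S->pos[c.b2].y;
                beads(nc, 2) = S->pos[c.b2].z;
            }
            nm[i] = c.nmono;
        }
        fl.push_back(List::create(_["id"] = static_cast<int>(f),
                                  _["beads"] = beads, _["nmono"] = nm,
                                  _["minus_abs"] = static_cast<double>(F.minusAbs)));
    }
    int ne = 0;
    for (const auto& e : S->elems) if (e.alive) ++ne;
    CharacterVector ekind(ne);
    IntegerVector efa(ne), efb(ne), enh(ne);
    NumericVector eposA(ne), eposB(ne), eload(ne);
    int j = 0;
    for (const auto& e : S->elems) {
        if (!e.alive) continue;
        ekind[j] = e.kind == EL_LINKER ? "linker"
                 : e.kind == EL_MOTOR ? "motor" : "branch";
        efa[j] = e.filA; efb[j] = e.filB;
        eposA[j] = e.posA; eposB[j] = e.posB;
        enh[j] = e.nheads; eload[j] = e.load;
        ++j;
    }
    DataFrame elems = DataFrame::create(
        _["kind"] = ekind, _["filA"] = efa, _["posA"] = eposA,
        _["filB"] = efb, _["posB"] = eposB, _["nheads"] = enh,
        _["load"] = eload);
    return List::create(_["time"] = S->time, _["filaments"] = fl,
                        _["elements"] = elems,
                        _["species"] = cmGetSpeciesCounts(sp));
}

// [[Rcpp::export]]
void cmRegister(SEXP sp) { StatePtr(sp)->eng->registerAll(); }

// [[Rcpp::export]]
List cmChannels(SEXP sp) {
    StatePtr S(sp);
    const char* names[] = {"diffusion", "poly_plus", "poly_minus", "depoly_plus",
                           "depoly_minus", "linker_bind", "motor_bind",
                           "linker_unbind", "motor_unbind", "motor_walk_a",
                           "motor_walk_b", "nucleation", "bulk"};
    std::vector<int> ids;
    for (size_t i = 0; i < S->eng->ch.size(); ++i)
        if (S->eng->ch[i].alive) ids.push_back(static_cast<int>(i));
    int n = static_cast<int>(ids.size());
    CharacterVector kind(n);
    IntegerVector i1(n), comp(n), id(n);
    NumericVector rate(n), a(n), afresh(n);
    for (int i = 0; i < n; ++i) {
        const Channel& c = S->eng->ch[ids[i]];
        id[i] = ids[i];
        kind[i] = names[c.kind];
        i1[i] = c.i1;
        comp[i] = c.comp;
        rate[i] = c.rate;
        a[i] = c.a;
        afresh[i] = S->eng->computeProp(c);
    }
    return DataFrame::create(_["id"] = id, _["kind"] = kind, _["target"] = i1,
                             _["compartment"] = comp, _["rate"] = rate,
                             _["a"] = a, _["a_fresh"] = afresh);
}

// [[Rcpp::export]]
List cmRun(SEXP sp, double nMech, double tStop, double maxEvents, bool record,
           double nPoly) {
    StatePtr S(sp);
    ChemEngine* E = S->eng;
    E->record = record;
    E->events.clear();
    long n = E->run(static_cast<long>(nMech), tStop,
                    maxEvents < 0 ? -1 : static_cast<long>(maxEvents),
                    nPoly < 0 ? -1 : static_cast<long>(nPoly));
    List out = List::create(_["time"] = S->time,
                            _["n_events"] = static_cast<double>(n));
    if (record) {
        const char* names[] = {"diffusion", "poly_plus", "poly_minus",
                               "depoly_plus", "depoly_minus", "linker_bind",
                               "motor_bind", "linker_unbind", "motor_unbind",
                               "motor_walk_a", "motor_walk_b", "nucleation",
                               "bulk"};
        int m = static_cast<int>(E->events.size());
        NumericVector t(m);
        CharacterVector k(m);
        IntegerVector cid(m);
        for (int i = 0; i < m; ++i) {
            t[i] = E->events[i].t;
            k[i] = names[E->events[i].kind];
            cid[i] = E->events[i].chan;
        }
        out["events"] = DataFrame::create(_["time"] = t, _["kind"] = k,
                                          _["channel"] = cid);
        E->record = false;
        E->events.clear();
    }
    return out;
}

// [[Rcpp::export]]
List cmEnergy(SEXP sp) {
    StatePtr S(sp);
    EnergyTerms T;
    double tot = computeEnergyForces(*S, false, &T);
    return List::create(_["total"] = tot, _["stretch"] = T.stretch,
                        _["bend"] = T.bend, _["exclvol"] = T.exclvol,
                        _["motor"] = T.motor, _["linker"] = T.linker,
                        _["branch"] = T.branch, _["boundary"] = T.boundary);
}

// [[Rcpp::export]]
List cmForces(SEXP sp) {
    StatePtr S(sp);
    computeEnergyForces(*S, true, nullptr);
    std::vector<bool> used(S->pos.size(), false);
    for (const auto& c : S->cyls)
        if (c.fil >= 0 && S->fils[c.fil].alive) used[c.b1] = used[c.b2] = true;
    std::vector<int> ids;
    for (size_t i = 0; i < used.size(); ++i)
        if (used[i]) ids.push_back(static_cast<int>(i));
    NumericMatrix f(static_cast<int>(ids.size()), 3);
    IntegerVector bid(static_cast<int>(ids.size()));
    for (size_t i = 0; i < ids.size(); ++i) {
        bid[i] = ids[i];
        f(i, 0) = S->frc[ids[i]].x;
        f(i, 1) = S->frc[ids[i]].y;
        f(i, 2) = S->frc[ids[i]].z;
    }
    return List::create(_["bead"] = bid, _["force"] = f,
                        _["max_force"] = maxForce(*S));
}

// [[Rcpp::export]]
List cmBeadPositions(SEXP sp) {
    StatePtr S(sp);
    std::vector<bool> used(S->pos.size(), false);
    for (const auto& c : S->cyls)
        if (c.fil >= 0 && S->fils[c.fil].alive) used[c.b1] = used[c.b2] = true;
    std::vector<int> ids;
    for (size_t i = 0; i < used.size(); ++i)
        if (used[i]) ids.push_back(static_cast<int>(i));
    NumericMatrix m(static_cast<int>(ids.size()), 3);
    IntegerVector bid(static_cast<int>(ids.size()));
    for (size_t i = 0; i < ids.size(); ++i) {
        bid[i] = ids[i];
        m(i, 0) = S->pos[ids[i]].x;
        m(i, 1) = S->pos[ids[i]].y;
        m(i, 2) = S->pos[ids[i]].z;
    }
    return List::create(_["bead"] = bid, _["pos"] = m);
}

// [[Rcpp::export]]
void cmSetBeadPositions(SEXP sp, IntegerVector bead, NumericMatrix posm) {
    StatePtr S(sp);
    for (int i = 0; i < bead.size(); ++i) {
        int b = bead[i];
        if (b < 0 || b >= static_cast<int>(S->pos.size())) stop("bad bead id");
        S->pos[b] = {posm(i, 0), posm(i, 1), posm(i, 2)};
    }
}

// [[Rcpp::export]]
List cmMinimize(SEXP sp, double tol, int maxIter, std::string method) {
    StatePtr S(sp);
    MinimizeResult R = minimize(*S, tol, maxIter, method == "cg" ? 1 : 0);
    return List::create(_["converged"] = R.converged, _["iters"] = R.iters,
                        _["U0"] = R.U0, _["U1"] = R.U1, _["max_force"] = R.maxF,
                        _["energy_trace"] = NumericVector(R.energyTrace.begin(),
                                                          R.energyTrace.end()));
}

// [[Rcpp::export]]
List cmUpdateRates(SEXP sp) {
    StatePtr S(sp);
    updateMechanochemistry(*S);
    int ne = 0;
    for (const auto& e : S->elems) if (e.alive && e.kind != EL_BRANCH) ++ne;
    CharacterVector kind(ne);
    NumericVector load(ne), mu(ne), mwa(ne), mwb(ne);
    int j = 0;
    for (const auto& e : S->elems) {
        if (!e.alive || e.kind == EL_BRANCH) continue;
        kind[j] = e.kind == EL_LINKER ? "linker" : "motor";
        load[j] = e.load;
        mu[j] = e.multUnbind;
        mwa[j] = e.multWalkA;
        mwb[j] = e.multWalkB;
        ++j;
    }
    int nf = 0;
    for (const auto& f : S->fils) if (f.alive) ++nf;
    NumericVector pm(nf);
    IntegerVector fid(nf);
    j = 0;
    for (size_t f = 0; f < S->fils.size(); ++f) {
        if (!S->fils[f].alive) continue;
        fid[j] = static_cast<int>(f);
        pm[j] = S->fils[f].polyMult;
        ++j;
    }
    return List::create(
        _["elements"] = DataFrame::create(_["kind"] = kind, _["load"] = load,
                                          _["mult_unbind"] = mu,
                                          _["mult_walk_a"] = mwa,
                                          _["mult_walk_b"] = mwb),
        _["filaments"] = DataFrame::create(_["fil"] = fid, _["poly_mult"] = pm));
}

// ---- stateless term evaluators (testing surface) ----

static List termOut(double U, std::initializer_list<Vec3> gs) {
    NumericMatrix g(static_cast<int>(gs.size()), 3);
    int i = 0;
    for (const Vec3& v : gs) {
        g(i, 0) = v.x; g(i, 1) = v.y; g(i, 2) = v.z;
        ++i;
    }
    return List::create(_["U"] = U, _["grad"] = g);
}

// [[Rcpp::export]]
List cmTermStretch(NumericVector x1, NumericVector x2, double K, double l0) {
    Vec3 g1{}, g2{};
    double U = stretchTerm(asVec3(x1), asVec3(x2), K, l0, &g1, &g2);
    return termOut(U, {g1, g2});
}

// [[Rcpp::export]]
List cmTermBend(NumericVector x0, NumericVector x1, NumericVector x2,
                double eps) {
    Vec3 g0{}, g1{}, g2{};
    double U = bendTerm(asVec3(x0), asVec3(x1), asVec3(x2), eps, &g0, &g1, &g2);
    return termOut(U, {g0, g1, g2});
}

// [[Rcpp::export]]
List cmTermExclVol(NumericVector xi1, NumericVector xi2, NumericVector xj1,
                   NumericVector xj2, double Kvol, double rSoft) {
    Vec3 g[4] = {};
    double U = exclVolPair(asVec3(xi1), asVec3(xi2), asVec3(xj1), asVec3(xj2),
                           Kvol, g, true, rSoft);
    return termOut(U, {g[0], g[1], g[2], g[3]});
}

// [[Rcpp::export]]
List cmTermBond(NumericVector xi1, NumericVector xi2, NumericVector xj1,
                NumericVector xj2, double alpha, double beta, double K,
                double l0) {
    Vec3 g1{}, g2{}, g3{}, g4{};
    double U = bondTerm(asVec3(xi1), asVec3(xi2), asVec3(xj1), asVec3(xj2),
                        alpha, beta, K, l0, &g1, &g2, &g3, &g4);
    return termOut(U, {g1, g2, g3, g4});
}

// [[Rcpp::export]]
List cmTermBranch(NumericVector xi1, NumericVector xi2, double gamma,
                  NumericVector xj1, NumericVector xj2, List ff) {
    FFParams F;
    F.KbrStr = getOr(ff, "k_branch_str", F.KbrStr);
    F.d0 = getOr(ff, "d0", F.d0);
    F.epsBrAng = getOr(ff, "eps_branch_ang", F.epsBrAng);
    F.theta0 = getOr(ff, "theta0", F.theta0);
    F.epsBrDihed = getOr(ff, "eps_branch_dihed", F.epsBrDihed);
    F.phi0 = getOr(ff, "phi0", F.phi0);
    Vec3 g1{}, g2{}, g3{}, g4{};
    double U = branchTerm(asVec3(xi1), asVec3(xi2), gamma, asVec3(xj1),
                          asVec3(xj2), F, &g1, &g2, &g3, &g4);
    return termOut(U, {g1, g2, g3, g4});
}

// [[Rcpp::export]]
List cmTermBoundary(NumericVector x1, NumericVector x2, NumericVector box,
                    std::string shape, double eps, double lambda) {
    Boundary b;
    b.lx = box[0]; b.ly = box[1]; b.lz = box[2];
    b.shape = shape == "sphere" ? B_SPHERE
            : shape == "capsule" ? B_CAPSULE : B_CUBE;
    b.eps = eps; b.lambda = lambda;
    Vec3 g1{}, g2{};
    double U = boundaryTerm(asVec3(x1), asVec3(x2), b, &g1, &g2);
    return termOut(U, {g1, g2});
}
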