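// Compartmentalized stochastic reaction-diffusion engine.
//
// Channels: diffusion jumps between neighboring compartments (rate D/h^2 per
// face), (de)polymerization at both filament ends, dynamically registered
// linker/motor pair-binding channels (one per geometric candidate site pair),
// per-element unbinding and motor walking, optional nucleation and generic
// bulk mass-action reactions. Propensities are always recomputed from state
// by computeProp(), so incrementally maintained values can never drift from
// a from-scratch evaluation; the engines only decide WHICH channels to
// refresh after an event.
//
// NRM: indexed min-heap on putative firing times with Gibson-Bruck
// rescaling of unfired channels; channels reactivated from zero propensity
// redraw a fresh exponential (exact by memorylessness).

#include "cm_chem.h"
#include "cm_mech.h"
#include <algorithm>

namespace cm {

SimState::~SimState() { delete eng; }

double ChemEngine::computeProp(const Channel& c) const {
    if (!c.alive) return 0;
    switch (c.kind) {
    case CH_DIFF:
        return c.rate * S.counts[c.comp][c.i1];
    case CH_POLY_P: case CH_POLY_M: {
        const Fil& fl = S.fils[c.i1];
        if (!fl.alive) return 0;
        long n = S.counts[c.comp][SP_ACTIN];
        double mult = (c.kind == CH_POLY_P) ? fl.polyMult : 1.0;
        return c.rate * n * mult;
    }
    case CH_DEP_P: case CH_DEP_M: {
        const Fil& fl = S.fils[c.i1];
        if (!fl.alive) return 0;
        if (S.filMonomers(c.i1) <= 2) return 0; // keep the nucleated seed
        return c.rate;
    }
    case CH_LBIND: case CH_MBIND: {
        const PairCand& pc = cands[c.i1];
        int kind = (c.kind == CH_LBIND) ? EL_LINKER : EL_MOTOR;
        if (!S.fils[pc.filA].alive || !S.fils[pc.filB].alive) return 0;
        if (!S.siteFree(kind, pc.filA, pc.siteA) ||
            !S.siteFree(kind, pc.filB, pc.siteB)) return 0;
        int spec = (kind == EL_LINKER) ? SP_LINKER : SP_MOTOR;
        return c.rate * S.counts[c.comp][spec];
    }
    case CH_LUNBIND: case CH_MUNBIND: {
        const Elem& e = S.elems[c.i1];
        if (!e.alive) return 0;
        return c.rate * e.multUnbind;
    }
    case CH_WALK_A: case CH_WALK_B: {
        const Elem& e = S.elems[c.i1];
        if (!e.alive) return 0;
        int f = (c.kind == CH_WALK_A) ? e.filA : e.filB;
        double p = (c.kind == CH_WALK_A) ? e.posA : e.posB;
        if (p + 6.0 > S.filPlusNm(f) + 1e-9) return 0; // stalled at the tip
        // stall-linear walk rate against the instantaneous bond strain, so
        // an ensemble cannot overshoot its stall force between
        // equilibrations (the unbinding/ratchet factors are still updated
        // only after each minimization)
        Vec3 xa = S.pointAt(e.filA, e.posA);
        Vec3 xb = S.pointAt(e.filB, e.posB);
        double F = std::max(0.0, e.K * (norm(xb - xa) - e.l0));
        double mult = std::max(0.0, 1.0 - F / (e.nheads * S.mc.fStallPerHead));
        if (!S.mc.enabled) mult = 1.0;
        return c.rate * mult;
    }
    case CH_NUC:
        return (S.counts[c.comp][SP_ACTIN] >= 2) ? c.rate : 0;
    case CH_BULK: {
        const BulkReaction& r = S.bulk[c.i1];
        if (r.nr == 0) return r.k;
        long n1 = S.counts[c.comp][r.react[0]];
        if (r.nr == 1) return r.k * n1;
        long n2 = S.counts[c.comp][r.react[1]];
        double vol = S.vcomp();
        if (r.react[0] == r.react[1])
            return r.k * n1 * (n1 - 1) * 0.5 / (NA_CONV * vol);
        return r.k * n1 * n2 / (NA_CONV * vol);
    }
    }
    return 0;
}

// All unoccupied site pairs on distinct filaments within the configured
// distance window whose midpoint falls in a grid compartment.
std::vector<PairCand> ChemEngine::findCandidates() const {
    struct SiteRec { int fil; long k; Vec3 p; };
    std::vector<SiteRec> sites;
    for (size_t f = 0; f < S.fils.size(); ++f) {
        if (!S.fils[f].alive) continue;
        for (const auto& sr : S.bindingSites(static_cast<int>(f)))
            sites.push_back({static_cast<int>(f), sr.k,
                             S.pointAt(static_cast<int>(f),
                                       sr.k * SITE_SPACING + SITE_SPACING / 2)});
    }
    std::vector<PairCand> out;
    const double wins[2][2] = {
        {S.chem.linkerRange - S.chem.linkerTol, S.chem.linkerRange + S.chem.linkerTol},
        {S.chem.motorRange - S.chem.motorTol, S.chem.motorRange + S.chem.motorTol}};
    double rmax = wins[1][1];
    for (size_t i = 0; i < sites.size(); ++i) {
        for (size_t j = i + 1; j < sites.size(); ++j) {
            if (sites[i].fil == sites[j].fil) continue; // bridge distinct filaments
            Vec3 dv = sites[i].p - sites[j].p;
            double d2 = dot(dv, dv);
            if (d2 > rmax * rmax) continue;
            double d = std::sqrt(d2);
            Vec3 midp = (sites[i].p + sites[j].p) * 0.5;
            for (int kind = 0; kind < 2; ++kind) { // EL_LINKER, EL_MOTOR
                if (d < wins[kind][0] || d > wins[kind][1]) continue;
                if (!S.siteFree(kind, sites[i].fil, sites[i].k) ||
                    !S.siteFree(kind, sites[j].fil, sites[j].k)) continue;
                int comp;
                try { comp = S.compartmentOf(midp); }
                catch (...) { comp = S.compartmentOf(midp, true); }
                out.push_back({sites[i].fil, sites[i].k, sites[j].fil, sites[j].k,
                               comp, kind, d, -1});
            }
        }
    }
    return out;
}

int ChemEngine::addChannel(const Channel& c) {
    int id;
    if (!freeCh.empty()) { id = freeCh.back(); freeCh.pop_back(); ch[id] = c; }
    else { id = static_cast<int>(ch.size()); ch.push_back(c); }
    ch[id].alive = true;
    ch[id].heap = -1;
    linkChannel(id);
    ch[id].a = computeProp(ch[id]);
    double tau = ch[id].a > 0 ? S.time + S.rng.expo(ch[id].a) : INF_TIME;
    ch[id].tau = tau;
    heap.push_back(id);
    ch[id].heap = static_cast<int>(heap.size()) - 1;
    siftUp(ch[id].heap);
    return id;
}

void ChemEngine::linkChannel(int cid) {
    Channel& c = ch[cid];
    switch (c.kind) {
    case CH_DIFF:
        bySpecComp[c.comp * N_SPECIES + c.i1].push_back(cid);
        break;
    case CH_POLY_P: case CH_POLY_M:
        bySpecComp[c.comp * N_SPECIES + SP_ACTIN].push_back(cid);
        byFil[c.i1].push_back(cid);
        break;
    case CH_DEP_P: case CH_DEP_M:
        byFil[c.i1].push_back(cid);
        break;
    case CH_LBIND:
    case CH_MBIND: {
        const PairCand& pc = cands[c.i1];
        int spec = (c.kind == CH_LBIND) ? SP_LINKER : SP_MOTOR;
        bySpecComp[c.comp * N_SPECIES + spec].push_back(cid);
        bySite[{pc.filA, pc.siteA}].push_back(cid);
        bySite[{pc.filB, pc.siteB}].push_back(cid);
        break;
    }
    case CH_LUNBIND: case CH_MUNBIND: case CH_WALK_A: case CH_WALK_B:
        byElem[c.i1].push_back(cid);
        break;
    case CH_NUC:
        bySpecComp[c.comp * N_SPECIES + SP_ACTIN].push_back(cid);
        break;
    case CH_BULK: {
        const BulkReaction& r = S.bulk[c.i1];
        for (int s = 0; s < r.nr; ++s)
            bySpecComp[c.comp * N_SPECIES + r.react[s]].push_back(cid);
        break;
    }
    }
}

void ChemEngine::unlinkChannel(int cid) {
    auto drop = [cid](std::vector<int>& v) {
        v.erase(std::remove(v.begin(), v.end(), cid), v.end());
    };
    Channel& c = ch[cid];
    switch (c.kind) {
    case CH_DIFF: drop(bySpecComp[c.comp * N_SPECIES + c.i1]); break;
    case CH_POLY_P: case CH_POLY_M:
        drop(bySpecComp[c.comp * N_SPECIES + SP_ACTIN]);
        drop(byFil[c.i1]);
        break;
    case CH_DEP_P: case CH_DEP_M: drop(byFil[c.i1]); break;
    case CH_LBIND: case CH_MBIND: {
        const PairCand& pc = cands[c.i1];
        int spec = (c.kind == CH_LBIND) ? SP_LINKER : SP_MOTOR;
        drop(bySpecComp[c.comp * N_SPECIES + spec]);
        drop(bySite[{pc.filA, pc.siteA}]);
        drop(bySite[{pc.filB, pc.siteB}]);
        break;
    }
    case CH_LUNBIND: case CH_MUNBIND: case CH_WALK_A: case CH_WALK_B:
        drop(byElem[c.i1]);
        break;
    case CH_NUC: drop(bySpecComp[c.comp * N_SPECIES + SP_ACTIN]); break;
    case CH_BULK: {
        const BulkReaction& r = S.bulk[c.i1];
        for (int s = 0; s < r.nr; ++s)
            drop(bySpecComp[c.comp * N_SPECIES + r.react[s]]);
        break;
    }
    }
}

void ChemEngine::killChannel(int cid) {
    if (!ch[cid].alive) return;
    unlinkChannel(cid);
    ch[cid].alive = false;
    ch[cid].a = 0;
    // remove from the indexed heap (slots are recycled, so a stale entry
    // would corrupt position tracking)
    int pos = ch[cid].heap;
    if (pos >= 0) {
        int last = static_cast<int>(heap.size()) - 1;
        if (pos != last) {
            heapSwap(pos, last);
            heap.pop_back();
            ch[cid].heap = -1;
            siftDown(pos);
            siftUp(pos);
        } else {
            heap.pop_back();
            ch[cid].heap = -1;
        }
    }
    ch[cid].tau = INF_TIME;
    freeCh.push_back(cid);
}

void ChemEngine::heapSwap(int a, int b) {
    std::swap(heap[a], heap[b]);
    ch[heap[a]].heap = a;
    ch[heap[b]].heap = b;
}
void ChemEngine::siftUp(int i) {
    while (i > 0) {
        int p = (i - 1) / 2;
        if (ch[heap[p]].tau <= ch[heap[i]].tau) break;
        heapSwap(p, i);
        i = p;
    }
}
void ChemEngine::siftDown(int i) {
    int n = static_cast<int>(heap.size());
    for (;;) {
        int l = 2 * i + 1, r = l + 1, m = i;
        if (l < n && ch[heap[l]].tau < ch[heap[m]].tau) m = l;
        if (r < n && ch[heap[r]].tau < ch[heap[m]].tau) m = r;
        if (m == i) break;
        heapSwap(m, i);
        i = m;
    }
}
void ChemEngine::setTau(int cid, double tau) {
    double old = ch[cid].tau;
    ch[cid].tau = tau;
    if (ch[cid].heap < 0) return;
    if (tau < old) siftUp(ch[cid].heap);
    else siftDown(ch[cid].heap);
}

// Gibson-Bruck propensity/putative-time refresh
void ChemEngine::updateChannel(int cid, bool fired) {
    Channel& c = ch[cid];
    double aold = c.a;
    double anew = c.alive ? computeProp(c) : 0;
    c.a = anew;
    if (!S.useNRM) return;
    if (anew <= 0) { setTau(cid, INF_TIME); return; }
    if (fired || aold <= 0 || !std::isfinite(c.tau))
        setTau(cid, S.time + S.rng.expo(anew));
    else
        setTau(cid, S.time + (aold / anew) * (c.tau - S.time));
}

void ChemEngine::registerAll() {
    // full rebuild: clears all channels and candidate pairs, re-derives the
    // dynamic binding channels from current geometry, redraws putative times
    ch.clear(); freeCh.clear(); heap.clear(); cands.clear();
    byFil.clear(); bySite.clear(); byElem.clear();
    bySpecComp.assign(static_cast<size_t>(S.ncomp()) * N_SPECIES, {});

    const int nx = S.nx, ny = S.ny, nz = S.nz;
    const double h2 = S.h * S.h;
    for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy)
            for (int ix = 0; ix < nx; ++ix) {
                int from = S.compIndex(ix, iy, iz);
                const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
                for (auto& dd : d) {
                    int jx = ix + dd[0], jy = iy + dd[1], jz = iz + dd[2];
                    if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
                        continue;
                    for (int s = 0; s < N_SPECIES; ++s) {
                        if (S.chem.D[s] <= 0) continue;
                        Channel c;
                        c.kind = CH_DIFF; c.i1 = s; c.comp = from;
                        c.i2 = S.compIndex(jx, jy, jz);
                        c.rate = S.chem.D[s] / h2;
                        addChannel(c);
                    }
                }
                if (S.chem.nucRate > 0) {
                    Channel c;
                    c.kind = CH_NUC; c.comp = from; c.rate = S.chem.nucRate;
                    addChannel(c);
                }
                for (size_t r = 0; r < S.bulk.size(); ++r) {
                    Channel c;
                    c.kind = CH_BULK; c.i1 = static_cast<int>(r); c.comp = from;
                    addChannel(c);
                }
            }

    const double biconv = 1.0 / (NA_CONV * S.vcomp()); // uM per molecule
    for (size_t f = 0; f < S.fils.size(); ++f) {
        if (!S.fils[f].alive) continue;
        const Fil& fl = S.fils[f];
        int plusBead = S.cyls[fl.cyls.back()].b2;
        int minusBead = S.cyls[fl.cyls.front()].b1;
        Channel c;
        c.i1 = static_cast<int>(f);
        c.kind = CH_POLY_P; c.comp = S.compartmentOf(S.pos[plusBead], true);
        c.rate = S.chem.kPolyPlus * S.chem.chi * biconv;
        addChannel(c);
        c.kind = CH_POLY_M; c.comp = S.compartmentOf(S.pos[minusBead], true);
        c.rate = S.chem.kPolyMinus * S.chem.chi * biconv;
        addChannel(c);
        c.kind = CH_DEP_P; c.comp = S.compartmentOf(S.pos[plusBead], true);
        c.rate = S.chem.kDepolyPlus * S.chem.chi;
        addChannel(c);
        c.kind = CH_DEP_M; c.comp = S.compartmentOf(S.pos[minusBead], true);
        c.rate = S.chem.kDepolyMinus * S.chem.chi;
        addChannel(c);
    }

    cands = findCandidates();
    for (size_t i = 0; i < cands.size(); ++i) {
        Channel c;
        c.kind = (cands[i].kind == EL_LINKER) ? CH_LBIND : CH_MBIND;
        c.i1 = static_cast<int>(i);
        c.comp = cands[i].comp;
        c.rate = ((cands[i].kind == EL_LINKER) ? S.chem.kOnLinker
                                               : S.chem.kOnMotor) * biconv;
        cands[i].chan = addChannel(c);
    }

    for (size_t e = 0; e < S.elems.size(); ++e) {
        const Elem& el = S.elems[e];
        if (!el.alive || el.kind == EL_BRANCH) continue;
        Channel c;
        c.i1 = static_cast<int>(e);
        Vec3 midp = (S.pointAt(el.filA, el.posA) + S.pointAt(el.filB, el.posB)) * 0.5;
        c.comp = S.compartmentOf(midp, true);
        if (el.kind == EL_LINKER) {
            c.kind = CH_LUNBIND; c.rate = S.chem.kOffLinker;
            addChannel(c);
        } else {
            c.kind = CH_MUNBIND; c.rate = S.chem.kOffMotor0;
            addChannel(c);
            c.kind = CH_WALK_A; c.rate = S.chem.v0Walk; addChannel(c);
            c.kind = CH_WALK_B; c.rate = S.chem.v0Walk; addChannel(c);
        }
    }
}

void ChemEngine::releaseSpecies(int spec, const Vec3& where) {
    int comp = S.compartmentOf(where, true);
    S.counts[comp][spec] += 1;
    for (int cid : bySpecComp[comp * N_SPECIES + spec]) updateChannel(cid, false);
}

// unbind any element whose anchor left the filament's material span
void ChemEngine::forceUnbindOutOfRange(int fil) {
    double lo = S.filMinusNm(fil), hi = S.filPlusNm(fil);
    for (size_t e = 0; e < S.elems.size(); ++e) {
        Elem& el = S.elems[e];
        if (!el.alive) continue;
        bool gone = false;
        if (el.kind == EL_BRANCH) {
            if (el.filA == fil && (el.posA < lo - 1e-9 || el.posA > hi + 1e-9))
                gone = true;
        } else {
            if (el.filA == fil && (el.posA < lo - 1e-9 || el.posA > hi + 1e-9))
                gone = true;
            if (el.filB == fil && (el.posB < lo - 1e-9 || el.posB > hi + 1e-9))
                gone = true;
        }
        if (!gone) continue;
        if (el.kind != EL_BRANCH) {
            Vec3 at = S.pointAt(el.filA, std::min(std::max(el.posA, lo), hi));
            S.occLinker.erase({el.filA, el.siteA});
            S.occLinker.erase({el.filB, el.siteB});
            S.occMotor.erase({el.filA, el.siteA});
            S.occMotor.erase({el.filB, el.siteB});
            releaseSpecies(el.kind == EL_LINKER ? SP_LINKER : SP_MOTOR, at);
        }
        el.alive = false;
        S.elemFree.push_back(static_cast<int>(e));
        auto it = byElem.find(static_cast<int>(e));
        if (it != byElem.end()) {
            std::vector<int> lst = it->second;
            for (int cid : lst) killChannel(cid);
        }
    }
}

void ChemEngine::execute(int cid) {
    Channel& c = ch[cid];
    const double biconv = 1.0 / (NA_CONV * S.vcomp());
    switch (c.kind) {
    case CH_DIFF: {
        if (S.counts[c.comp][c.i1] < 1) break;
        S.counts[c.comp][c.i1] -= 1;
        S.counts[c.i2][c.i1] += 1;
        for (int k : bySpecComp[c.comp * N_SPECIES + c.i1]) updateChannel(k, k == cid);
        for (int k : bySpecComp[c.i2 * N_SPECIES + c.i1]) updateChannel(k, false);
        break;
    }
    case CH_POLY_P: case CH_POLY_M: {
        int f = c.i1;
        Fil& fl = S.fils[f];
        if (S.counts[c.comp][SP_ACTIN] < 1) break;
        S.counts[c.comp][SP_ACTIN] -= 1;
        bool plus = (c.kind == CH_POLY_P);
        int ci = plus ? fl.cyls.back() : fl.cyls.front();
        Cyl& cyl = S.cyls[ci];
        Vec3 u = S.pos[cyl.b2] - S.pos[cyl.b1];
        double un = norm(u);
        u = un > 1e-12 ? u * (1.0 / un) : Vec3{1, 0, 0};
        const int MAXM = S.maxMono; // monomers per full cylinder
        if (cyl.nmono >= MAXM) {
            // promote: fresh variable-length tip cylinder with the new monomer
            if (plus) {
                int nb = S.newBead(S.pos[cyl.b2] + u * MONOMER_NM);
                Cyl nc; nc.fil = f; nc.b1 = cyl.b2; nc.b2 = nb;
                nc.nmono = 1; nc.l0 = MONOMER_NM;
                fl.cyls.push_back(S.newCyl(nc));
            } else {
                int nb = S.newBead(S.pos[cyl.b1] - u * MONOMER_NM);
                Cyl nc; nc.fil = f; nc.b1 = nb; nc.b2 = cyl.b1;
                nc.nmono = 1; nc.l0 = MONOMER_NM;
                fl.cyls.insert(fl.cyls.begin(), S.newCyl(nc));
            }
        } else {
            cyl.nmono += 1;
            cyl.l0 += MONOMER_NM;
            if (plus) S.pos[cyl.b2] += u * MONOMER_NM;
            else S.pos[cyl.b1] -= u * MONOMER_NM;
        }
        if (!plus) fl.minusAbs -= 1;
        for (int k : bySpecComp[c.comp * N_SPECIES + SP_ACTIN]) updateChannel(k, k == cid);
        // tip may have crossed a compartment face: re-link the fil's channels
        for (int k : std::vector<int>(byFil[f])) {
            Channel& fc = ch[k];
            int bead = (fc.kind == CH_POLY_P || fc.kind == CH_DEP_P)
                ? S.cyls[S.fils[f].cyls.back()].b2
                : S.cyls[S.fils[f].cyls.front()].b1;
            int nc = S.compartmentOf(S.pos[bead], true);
            if (nc != fc.comp) { unlinkChannel(k); fc.comp = nc; linkChannel(k); }
            updateChannel(k, k == cid);
        }
        break;
    }
    case CH_DEP_P: case CH_DEP_M: {
        int f = c.i1;
        Fil& fl = S.fils[f];
        if (S.filMonomers(f) <= 2) break;
        bool plus = (c.kind == CH_DEP_P);
        int ci = plus ? fl.cyls.back() : fl.cyls.front();
        Cyl& cyl = S.cyls[ci];
        Vec3 tipPos = plus ? S.pos[cyl.b2] : S.pos[cyl.b1];
        Vec3 u = S.pos[cyl.b2] - S.pos[cyl.b1];
        double un = norm(u);
        u = un > 1e-12 ? u * (1.0 / un) : Vec3{1, 0, 0};
        if (cyl.nmono <= 1) {
            // demote: drop the exhausted tip cylinder
            if (plus) {
                S.beadFree.push_back(cyl.b2);
                fl.cyls.pop_back();
            } else {
                S.beadFree.push_back(cyl.b1);
                fl.cyls.erase(fl.cyls.begin());
            }
            cyl.fil = -1;
            S.cylFree.push_back(ci);
        } else {
            cyl.nmono -= 1;
            cyl.l0 -= MONOMER_NM;
            if (plus) S.pos[cyl.b2] -= u * MONOMER_NM;
            else S.pos[cyl.b1] += u * MONOMER_NM;
        }
        if (!plus) fl.minusAbs += 1;
        int comp = S.compartmentOf(tipPos, true);
        S.counts[comp][SP_ACTIN] += 1;
        forceUnbindOutOfRange(f);
        for (int k : bySpecComp[comp * N_SPECIES + SP_ACTIN]) updateChannel(k, k == cid);
        for (int k : std::vector<int>(byFil[f])) {
            Channel& fc = ch[k];
            int bead = (fc.kind == CH_POLY_P || fc.kind == CH_DEP_P)
                ? S.cyls[S.fils[f].cyls.back()].b2
                : S.cyls[S.fils[f].cyls.front()].b1;
            int nc = S.compartmentOf(S.pos[bead], true);
            if (nc != fc.comp) { unlinkChannel(k); fc.comp = nc; linkChannel(k); }
            updateChannel(k, k == cid);
        }
        break;
    }
    case CH_LBIND: case CH_MBIND: {
        const PairCand pc = cands[c.i1];
        int kind = (c.kind == CH_LBIND) ? EL_LINKER : EL_MOTOR;
        int spec = (kind == EL_LINKER) ? SP_LINKER : SP_MOTOR;
        if (S.counts[c.comp][spec] < 1) break;
        if (!S.siteFree(kind, pc.filA, pc.siteA) ||
            !S.siteFree(kind, pc.filB, pc.siteB)) break;
        S.counts[c.comp][spec] -= 1;
        Elem e;
        e.kind = kind; e.alive = true;
        e.filA = pc.filA; e.siteA = pc.siteA;
        e.posA = pc.siteA * SITE_SPACING + SITE_SPACING / 2;
        e.filB = pc.filB; e.siteB = pc.siteB;
        e.posB = pc.siteB * SITE_SPACING + SITE_SPACING / 2;
        if (kind == EL_LINKER) {
            e.K = S.ff.Klinker; e.l0 = S.ff.l0linker;
            S.occLinker.insert({e.filA, e.siteA});
            S.occLinker.insert({e.filB, e.siteB});
        } else {
            e.K = S.ff.Kmotor; e.l0 = S.ff.l0motor;
            e.nheads = S.rng.unifInt(10, 30);
            S.occMotor.insert({e.filA, e.siteA});
            S.occMotor.insert({e.filB, e.siteB});
        }
        int eid = S.newElem(e);
        Channel nc;
        nc.i1 = eid; nc.comp = c.comp;
        if (kind == EL_LINKER) {
            nc.kind = CH_LUNBIND; nc.rate = S.chem.kOffLinker; addChannel(nc);
        } else {
            nc.kind = CH_MUNBIND; nc.rate = S.chem.kOffMotor0; addChannel(nc);
            nc.kind = CH_WALK_A; nc.rate = S.chem.v0Walk; addChannel(nc);
            nc.kind = CH_WALK_B; nc.rate = S.chem.v0Walk; addChannel(nc);
        }
        // occupancy changed: refresh other bind channels touching these sites
        for (auto key : {std::make_pair(pc.filA, pc.siteA),
                         std::make_pair(pc.filB, pc.siteB)}) {
            auto it = bySite.find(key);
            if (it == bySite.end()) continue;
            for (int k : std::vector<int>(it->second)) updateChannel(k, false);
        }
        for (int k : bySpecComp[c.comp * N_SPECIES + spec]) updateChannel(k, k == cid);
        break;
    }
    case CH_LUNBIND: case CH_MUNBIND: {
        Elem& e = S.elems[c.i1];
        if (!e.alive) break;
        Vec3 midp = (S.pointAt(e.filA, e.posA) + S.pointAt(e.filB, e.posB)) * 0.5;
        int spec = (e.kind == EL_LINKER) ? SP_LINKER : SP_MOTOR;
        if (e.kind == EL_LINKER) {
            S.occLinker.erase({e.filA, e.siteA});
            S.occLinker.erase({e.filB, e.siteB});
        } else {
            S.occMotor.erase({e.filA, e.siteA});
            S.occMotor.erase({e.filB, e.siteB});
        }
        e.alive = false;
        S.elemFree.push_back(c.i1);
        auto it = byElem.find(c.i1);
        if (it != byElem.end())
            for (int k : std::vector<int>(it->second)) killChannel(k);
        // freed sites: refresh candidate channels anchored there
        for (auto key : {std::make_pair(e.filA, e.siteA),
                         std::make_pair(e.filB, e.siteB)}) {
            auto its = bySite.find(key);
            if (its == bySite.end()) continue;
            for (int k : std::vector<int>(its->second)) updateChannel(k, false);
        }
        releaseSpecies(spec, midp);
        break;
    }
    case CH_WALK_A: case CH_WALK_B: {
        Elem& e = S.elems[c.i1];
        if (!e.alive) break;
        bool A = (c.kind == CH_WALK_A);
        int f = A ? e.filA : e.filB;
        double& p = A ? e.posA : e.posB;
        if (p + 6.0 > S.filPlusNm(f) + 1e-9) break; // stalled
        p += 6.0; // one 6 nm ensemble step toward the plus end
        auto it = byElem.find(c.i1);
        if (it != byElem.end())
            for (int k : std::vector<int>(it->second)) updateChannel(k, k == cid);
        break;
    }
    case CH_NUC: {
        if (S.counts[c.comp][SP_ACTIN] < 2) break;
        S.counts[c.comp][SP_ACTIN] -= 2;
        int iz = c.comp / (S.nx * S.ny);
        int iy = (c.comp / S.nx) % S.ny;
        int ix = c.comp % S.nx;
        Vec3 p{(ix + S.rng.unif()) * S.h, (iy + S.rng.unif()) * S.h,
               (iz + S.rng.unif()) * S.h};
        double cth = 2 * S.rng.unif() - 1, phi = 2 * M_PI * S.rng.unif();
        double sth = std::sqrt(1 - cth * cth);
        Vec3 u{sth * std::cos(phi), sth * std::sin(phi), cth};
        int f = S.addFilamentBeads({p, p + u * (2 * MONOMER_NM)}, {2});
        Channel nc;
        nc.i1 = f;
        int plusBead = S.cyls[S.fils[f].cyls.back()].b2;
        int minusBead = S.cyls[S.fils[f].cyls.front()].b1;
        nc.kind = CH_POLY_P; nc.comp = S.compartmentOf(S.pos[plusBead], true);
        nc.rate = S.chem.kPolyPlus * S.chem.chi * biconv; addChannel(nc);
        nc.kind = CH_POLY_M; nc.comp = S.compartmentOf(S.pos[minusBead], true);
        nc.rate = S.chem.kPolyMinus * S.chem.chi * biconv; addChannel(nc);
        nc.kind = CH_DEP_P; nc.comp = S.compartmentOf(S.pos[plusBead], true);
        nc.rate = S.chem.kDepolyPlus * S.chem.chi; addChannel(nc);
        nc.kind = CH_DEP_M; nc.comp = S.compartmentOf(S.pos[minusBead], true);
        nc.rate = S.chem.kDepolyMinus * S.chem.chi; addChannel(nc);
        for (int k : bySpecComp[c.comp * N_SPECIES + SP_ACTIN]) updateChannel(k, k == cid);
        break;
    }
    case CH_BULK: {
        const BulkReaction& r = S.bulk[c.i1];
        for (int s = 0; s < r.nr; ++s) {
            if (S.counts[c.comp][r.react[s]] < 1) return;
            S.counts[c.comp][r.react[s]] -= 1;
        }
        for (int s = 0; s < r.np; ++s) S.counts[c.comp][r.prod[s]] += 1;
        std::set<int> specs;
        for (int s = 0; s < r.nr; ++s) specs.insert(r.react[s]);
        for (int s = 0; s < r.np; ++s) specs.insert(r.prod[s]);
        for (int sp : specs)
            for (int k : bySpecComp[c.comp * N_SPECIES + sp])
                updateChannel(k, k == cid);
        updateChannel(cid, true);
        break;
    }
    }
}

static bool isPolyKind(int k) {
    return k == CH_POLY_P || k == CH_POLY_M || k == CH_DEP_P ||
           k == CH_DEP_M || k == CH_NUC;
}

bool ChemEngine::stepNRM() {
    if (heap.empty()) return false;
    int cid = heap[0];
    double tau = ch[cid].tau;
    if (!std::isfinite(tau)) return false;
    S.time = tau;
    if (record) events.push_back({tau, ch[cid].kind, cid});
    if (ch[cid].kind != CH_DIFF) ++nMechExecuted;
    if (isPolyKind(ch[cid].kind)) ++nPolyExecuted;
    execute(cid);
    if (ch[cid].alive) updateChannel(cid, true);
    return true;
}

bool ChemEngine::stepDirect(double tStop) {
    double total = 0;
    for (auto& c : ch)
        if (c.alive) { c.a = computeProp(c); total += c.a; }
    if (total <= 0) return false;
    double dt = S.rng.expo(total);
    if (S.time + dt > tStop) { S.time = tStop; return false; }
    double u = S.rng.unif() * total;
    int pick = -1;
    double acc = 0;
    for (size_t i = 0; i < ch.size(); ++i) {
        if (!ch[i].alive || ch[i].a <= 0) continue;
        acc += ch[i].a;
        pick = static_cast<int>(i);
        if (acc >= u) break;
    }
    if (pick < 0) return false;
    S.time += dt;
    if (record) events.push_back({S.time, ch[pick].kind, pick});
    if (ch[pick].kind != CH_DIFF) ++nMechExecuted;
    if (isPolyKind(ch[pick].kind)) ++nPolyExecuted;
    execute(pick);
    return true;
}

long ChemEngine::run(long nMech, double tStop, long maxEvents, long nPoly) {
    long n = 0;
    long mech0 = nMechExecuted;
    long poly0 = nPolyExecuted;
    for (;;) {
        if (maxEvents >= 0 && n >= maxEvents) break;
        if (nMech >= 0 && nMechExecuted - mech0 >= nMech) break;
        if (nPoly >= 0 && nPolyExecuted - poly0 >= nPoly) break;
        if (S.useNRM) {
            if (heap.empty() || !std::isfinite(ch[heap[0]].tau)) {
                if (std::isfinite(tStop)) S.time = tStop;
                break;
            }
            if (ch[heap[0]].tau > tStop) { S.time = tStop; break; }
            if (!stepNRM()) { if (std::isfinite(tStop)) S.time = tStop; break; }
        } else {
            if (!stepDirect(tStop)) {
                if (std::isfinite(tStop) && S.time < tStop) S.time = tStop;
                break;
            }
        }
        ++n;
    }
    return n;
}

} // namespace cm
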