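#ifndef CM_CHEM_H
#define CM_CHEM_H

#include "cm_state.h"
#include <map>

namespace cm {

enum ChKind {
    CH_DIFF = 0, CH_POLY_P, CH_POLY_M, CH_DEP_P, CH_DEP_M,
    CH_LBIND, CH_MBIND, CH_LUNBIND, CH_MUNBIND,
    CH_WALK_A, CH_WALK_B, CH_NUC, CH_BULK
};

struct Channel {
    int kind = CH_DIFF;
    bool alive = false;
    int i1 = -1;   // species / filament / element / candidate / reaction index
    int i2 = -1;   // destination compartment (diffusion)
    int comp = -1; // home compartment (propensity-linked)
    double rate = 0; // precomputed rate factor
    double a = 0;    // current propensity, 1/s
    double tau = INF_TIME; // putative firing time (NRM)
    int heap = -1;
};

struct PairCand {
    int filA; long siteA; int filB; long siteB;
    int comp; int kind; // EL_LINKER or EL_MOTOR
    double dist;
    int chan = -1;
};

struct EventRec { double t; int kind; int chan; };

// Event-driven engine over the channel set: Gibson-Bruck next-reaction
// method (indexed priority queue + dependency updates) or the Gillespie
// direct method, selected by SimState::useNRM.
struct ChemEngine {
    SimState& S;
    std::vector<Channel> ch;
    std::vector<int> freeCh;
    std::vector<PairCand> cands;
    std::vector<std::vector<int>> bySpecComp;          // (comp, spec) -> channels
    std::map<int, std::vector<int>> byFil;             // filament -> channels
    std::map<std::pair<int, long>, std::vector<int>> bySite; // site -> bind chans
    std::map<int, std::vector<int>> byElem;            // element -> channels
    std::vector<int> heap; // channel ids, min-heap on tau
    bool record = false;
    std::vector<EventRec> events;
    long nMechExecuted = 0;
    long nPolyExecuted = 0; // monomer-changing events (poly/depoly/nucleation)

    explicit ChemEngine(SimState& s) : S(s) {}

    double computeProp(const Channel& c) const;
    std::vector<PairCand> findCandidates() const;
    void registerAll();
    // executes events until `nMech` mechanically relevant events or `nPoly`
    // monomer-changing events have fired, or time reaches tStop; returns the
    // number of events executed
    long run(long nMech, double tStop, long maxEvents = -1, long nPoly = -1);

    // internal
    void heapSwap(int a, int b);
    void siftUp(int i);
    void siftDown(int i);
    void setTau(int cid, double tau);
    void updateChannel(int cid, bool fired);
    int addChannel(const Channel& c);
    void killChannel(int cid);
    void linkChannel(int cid);
    void unlinkChannel(int cid);
    bool stepNRM();
    bool stepDirect(double tStop);
    void execute(int cid);
    void forceUnbindOutOfRange(int fil);
    void releaseSpecies(int spec, const Vec3& where);
};

} // namespace cm

#endif
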