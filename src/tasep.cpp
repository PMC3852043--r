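#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Continuous-time TASEP with extended particles (footprint ell >= 1 sites).
// A ribosome at position p occupies sites p .. p+ell-1.  Initiation places a
// ribosome at site 1 when sites 1..ell are all free; the hop p -> p+1
// requires site p+ell to be free; the ribosome on the last site exits at
// rate beta.  Gillespie scheduling with exponential waiting times; a
// self-contained xorshift generator keeps gene-level seeding independent of
// R's global RNG stream.

static inline uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
}

struct Rng {
    uint64_t s0, s1;
    explicit Rng(uint64_t seed) {
        uint64_t sm = seed;
        s0 = splitmix64(sm);
        s1 = splitmix64(sm);
    }
    uint64_t next() {
        uint64_t x = s0, y = s1;
        s0 = y;
        x ^= x << 23;
        s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
        return s1 + y;
    }
    double unif() { // in (0,1)
        return (next() >> 11) * (1.0 / 9007199254740992.0) + 5.0e-324;
    }
    double rexp(double rate) { return -std::log(unif()) / rate; }
};

// [[Rcpp::export(name = ".tasep_sim_cpp")]]
List tasep_sim_cpp(NumericVector rates, double alpha, double beta, int ell,
                   double burninEvents, double sampleEvents, double seed,
                   int nBatches, bool trackDensity) {
    int n = rates.size();
    Rng rng(static_cast<uint64_t>(seed));
    std::vector<int> pos;            // ribosome positions, ascending (rear .. lead)
    std::vector<double> occTime(trackDensity ? n : 0, 0.0);
    double t = 0.0, tSample = 0.0;
    double nTerm = 0.0;
    std::vector<double> batchTerm(nBatches, 0.0), batchTime(nBatches, 0.0);
    double totalEvents = burninEvents + sampleEvents;
    double eventsPerBatch = sampleEvents / nBatches;

    for (double ev = 0; ev < totalEvents; ++ev) {
        int nr = pos.size();
        bool canInit = nr == 0 || pos[0] > ell;
        double total = canInit ? alpha : 0.0;
        // movable ribosomes: pos ascending, ribosome i blocked unless
        // pos[i+1] - pos[i] > ell; the lead ribosome exits from site n at beta
        std::vector<double> prop(nr, 0.0);
        for (int i = 0; i < nr; ++i) {
            int p = pos[i];
            if (p == n) {
                prop[i] = beta;
            } else if (i == nr - 1 || pos[i + 1] - p > ell) {
                prop[i] = rates[p - 1];
            }
            total += prop[i];
        }
        if (total <= 0.0) break; // frozen configuration (e.g. zero rates)
        double dt = rng.rexp(total);
        bool sampling = ev >= burninEvents;
        int batch = sampling ? std::min((int)((ev - burninEvents) / eventsPerBatch), nBatches - 1) : 0;
        if (sampling) {
            tSample += dt;
            batchTime[batch] += dt;
            if (trackDensity) {
                for (int i = 0; i < nr; ++i) {
                    int hi = std::min(pos[i] + ell - 1, n);
                    for (int s = pos[i]; s <= hi; ++s) occTime[s - 1] += dt;
                }
            }
        }
        t += dt;
        double r = rng.unif() * total;
        if (canInit) {
            if (r < alpha) {
                pos.insert(pos.begin(), 1);
                continue;
            }
            r -= alpha;
        }
        for (int i = 0; i < nr; ++i) {
            if (prop[i] <= 0.0) continue;
            if (r < prop[i]) {
                if (pos[i] == n) {
                    pos.erase(pos.begin() + i);
                    if (sampling) { nTerm += 1.0; batchTerm[batch] += 1.0; }
                } else {
                    pos[i] += 1;
                }
                break;
            }
            r -= prop[i];
        }
    }

    double J = tSample > 0 ? nTerm / tSample : 0.0;
    // batch-means standard error of the current
    double mean = 0.0; int nb = 0;
    std::vector<double> bJ;
    for (int b = 0; b < nBatches; ++b)
        if (batchTime[b] > 0) { bJ.push_back(batchTerm[b] / batchTime[b]); }
    nb = bJ.size();
    for (int b = 0; b < nb; ++b) mean += bJ[b];
    if (nb > 0) mean /= nb;
    double var = 0.0;
    for (int b = 0; b < nb; ++b) var += (bJ[b] - mean) * (bJ[b] - mean);
    double se = (nb > 1) ? std::sqrt(var / (nb - 1) / nb) : NA_REAL;

    NumericVector dens(trackDensity ? n : 0);
    if (trackDensity && tSample > 0)
        for (int s = 0; s < n; ++s) dens[s] = occTime[s] / tSample;

    return List::create(_["current"] = J, _["se"] = se, _["n_term"] = nTerm,
                        _["time"] = tSample, _["density"] = dens);
}
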