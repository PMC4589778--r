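#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// PRNG: xoshiro256++ seeded via splitmix64. A dedicated generator keeps the
// inner loop independent of R's RNG state and makes trajectories bit-exact
// reproducible from a single integer seed.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
};

static inline double u53(uint64_t r) {
  return (double)(r >> 11) * (1.0 / 9007199254740992.0);  // 2^-53
}

// ---------------------------------------------------------------------------
// Coupled two-layer model. Layer 0 carries the snowdrift game, layer 1 the
// prisoner's dilemma; site i on one layer is partnered with site i on the
// other. Strategy encoding: 1 = cooperator (C), 0 = defector (D).
// ---------------------------------------------------------------------------

struct Model {
  int L, N;
  std::vector<uint8_t> g0, g1;  // layer grids, column-major site index
  uint8_t *g[2];
  std::vector<int> nbr;         // 4*N neighbor indices (shared geometry)
  double pay[2][2][5];          // [layer][strategy][#C neighbors]
  double W[2][10][10];          // Fermi adoption prob, index = strat*5 + #C
  double s, noise;
  int noise_mode;               // 0 uniform {C,D}, 1 keep own, 2 random group member
  long long nc[2], ncc;         // cooperator counts per layer, C-C pair count
};

static void build_model(Model &m, const IntegerMatrix &sd,
                        const IntegerMatrix &pd, double b, double R, double S,
                        double Ppd, double Psd, double K, double s,
                        double noise, int noise_mode) {
  m.L = sd.nrow();
  m.N = m.L * m.L;
  m.s = s;
  m.noise = noise;
  m.noise_mode = noise_mode;
  m.g0.resize(m.N);
  m.g1.resize(m.N);
  for (int i = 0; i < m.N; ++i) {
    m.g0[i] = (uint8_t)sd[i];
    m.g1[i] = (uint8_t)pd[i];
  }
  m.g[0] = m.g0.data();
  m.g[1] = m.g1.data();

  // von Neumann neighbors on the torus; column-major: site = row + col*L
  m.nbr.resize(4 * m.N);
  int L = m.L;
  for (int col = 0; col < L; ++col) {
    for (int row = 0; row < L; ++row) {
      int i = row + col * L;
      int up = (row == 0 ? L - 1 : row - 1) + col * L;
      int dn = (row == L - 1 ? 0 : row + 1) + col * L;
      int lf = row + (col == 0 ? L - 1 : col - 1) * L;
      int rt = row + (col == L - 1 ? 0 : col + 1) * L;
      m.nbr[4 * i] = up;
      m.nbr[4 * i + 1] = dn;
      m.nbr[4 * i + 2] = lf;
      m.nbr[4 * i + 3] = rt;
    }
  }

  // accumulated payoff of a player with given strategy and k cooperating
  // neighbors; only the punishment P differs between layers
  for (int l = 0; l < 2; ++l) {
    double P = (l == 0) ? Psd : Ppd;
    for (int k = 0; k <= 4; ++k) {
      m.pay[l][0][k] = k * b + (4 - k) * P;  // defector
      m.pay[l][1][k] = k * R + (4 - k) * S;  // cooperator
    }
  }
  for (int l = 0; l < 2; ++l) {
    for (int a = 0; a < 10; ++a) {
      for (int y = 0; y < 10; ++y) {
        double px = m.pay[l][a / 5][a % 5];
        double py = m.pay[l][y / 5][y % 5];
        double z = (px - py) / K;
        if (z > 500.0) z = 500.0;
        if (z < -500.0) z = -500.0;
        m.W[l][a][y] = 1.0 / (1.0 + std::exp(z));
      }
    }
  }

  m.nc[0] = m.nc[1] = m.ncc = 0;
  for (int i = 0; i < m.N; ++i) {
    m.nc[0] += m.g0[i];
    m.nc[1] += m.g1[i];
    m.ncc += (m.g0[i] & m.g1[i]);
  }
}

static inline int count_c(const Model &m, int layer, int site) {
  const int *nb = &m.nbr[4 * site];
  const uint8_t *g = m.g[layer];
  return g[nb[0]] + g[nb[1]] + g[nb[2]] + g[nb[3]];
}

// One elementary update: draws layer, site and branch, then either the
// social-influence rule (conformity noise / majority of the partner group on
// the other layer) or Fermi imitation of a random same-layer neighbor.
// Returns the proposed strategy without mutating the state.
static inline void propose_update(const Model &m, Xoshiro &rng, int &layer,
                                  int &site, int &news) {
  uint64_t r1 = rng.next();
  layer = (int)(r1 & 1);
  site = (int)((((r1 >> 1) & 0xFFFFFFFFULL) * (uint64_t)m.N) >> 32);
  double ub = (double)(r1 >> 33) * (1.0 / 2147483648.0);
  uint8_t sx = m.g[layer][site];
  news = sx;
  if (ub < m.s) {
    // social influence: conformity noise, else partner-group majority
    uint64_t r2 = rng.next();
    int ol = 1 - layer;
    const int *nb = &m.nbr[4 * site];
    const uint8_t *g = m.g[ol];
    if (u53(r2) < m.noise) {
      if (m.noise_mode == 0) {
        news = (int)(r2 & 1);             // uniform random strategy
      } else if (m.noise_mode == 1) {
        news = sx;                        // abstain: keep current strategy
      } else if (m.noise_mode == 2) {
        // copy a uniformly chosen member of the partner group
        uint64_t r3 = rng.next();
        int k = (int)(((r3 >> 32) * 5ULL) >> 32);
        news = (k == 0) ? g[site] : g[nb[k - 1]];
      } else {
        // uniform over the distinct strategies present in the partner group
        int c = g[site] + g[nb[0]] + g[nb[1]] + g[nb[2]] + g[nb[3]];
        if (c == 0) news = 0;
        else if (c == 5) news = 1;
        else news = (int)(r2 & 1);
      }
    } else {
      int c = g[site] + g[nb[0]] + g[nb[1]] + g[nb[2]] + g[nb[3]];
      news = (c >= 3) ? 1 : 0;
    }
  } else {
    // Fermi imitation of a random von Neumann neighbor, payoffs recomputed
    uint64_t r2 = rng.next();
    int ysite = m.nbr[4 * site + (int)(r2 & 3)];
    uint8_t sy = m.g[layer][ysite];
    if (sy != sx) {
      int ax = sx * 5 + count_c(m, layer, site);
      int ay = sy * 5 + count_c(m, layer, ysite);
      if (u53(r2) < m.W[layer][ax][ay]) news = sy;
    }
  }
}

static inline void apply_update(Model &m, int layer, int site, int news) {
  uint8_t old = m.g[layer][site];
  if (old == (uint8_t)news) return;
  m.g[layer][site] = (uint8_t)news;
  int d = news - (int)old;
  m.nc[layer] += d;
  if (m.g[1 - layer][site]) m.ncc += d;
}

static IntegerMatrix grid_out(const Model &m, int layer) {
  IntegerMatrix out(m.L, m.L);
  for (int i = 0; i < m.N; ++i) out[i] = m.g[layer][i];
  return out;
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// Run `steps` full Monte Carlo steps (2*L^2 elementary updates each) and
// record cooperator / C-C pair counts after every step. snap_steps: sorted MC
// step indices (0 = initial state) at which to keep full grid snapshots.
// [[Rcpp::export]]
List run_engine(IntegerMatrix sd, IntegerMatrix pd, double b, double R,
                double S, double Ppd, double Psd, double K, double s,
                double noise, int noise_mode, int steps, int seed,
                IntegerVector snap_steps) {
  Model m;
  build_model(m, sd, pd, b, R, S, Ppd, Psd, K, s, noise, noise_mode);
  Xoshiro rng((uint64_t)seed);

  IntegerMatrix counts(steps + 1, 3);
  List snaps;
  CharacterVector snap_names;
  int nsnap = snap_steps.size(), isnap = 0;

  counts(0, 0) = (int)m.nc[0];
  counts(0, 1) = (int)m.nc[1];
  counts(0, 2) = (int)m.ncc;
  while (isnap < nsnap && snap_steps[isnap] == 0) {
    snaps.push_back(List::create(_["sd"] = grid_out(m, 0),
                                 _["pd"] = grid_out(m, 1)));
    snap_names.push_back("0");
    ++isnap;
  }

  // Unanimous states are absorbing whenever the conformity noise cannot
  // introduce a strategy absent from the whole system (any mode except the
  // unconditional uniform draw, or no noise at all, or pure imitation).
  // Reaching one lets us stop simulating: the trajectory is constant after.
  bool can_absorb = (noise_mode != 0) || (noise == 0.0) || (s == 0.0);

  long long per_step = 2LL * m.N;
  int layer, site, news;
  for (int t = 1; t <= steps; ++t) {
    for (long long k = 0; k < per_step; ++k) {
      propose_update(m, rng, layer, site, news);
      apply_update(m, layer, site, news);
    }
    counts(t, 0) = (int)m.nc[0];
    counts(t, 1) = (int)m.nc[1];
    counts(t, 2) = (int)m.ncc;
    while (isnap < nsnap && snap_steps[isnap] == t) {
      snaps.push_back(List::create(_["sd"] = grid_out(m, 0),
                                   _["pd"] = grid_out(m, 1)));
      snap_names.push_back(std::to_string(t));
      ++isnap;
    }
    long long tot = m.nc[0] + m.nc[1];
    if (can_absorb && (tot == 0 || tot == 2LL * m.N)) {
      for (int u = t + 1; u <= steps; ++u) {
        counts(u, 0) = (int)m.nc[0];
        counts(u, 1) = (int)m.nc[1];
        counts(u, 2) = (int)m.ncc;
        while (isnap < nsnap && snap_steps[isnap] == u) {
          snaps.push_back(List::create(_["sd"] = grid_out(m, 0),
                                       _["pd"] = grid_out(m, 1)));
          snap_names.push_back(std::to_string(u));
          ++isnap;
        }
      }
      break;
    }
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  if (snaps.size() > 0) snaps.attr("names") = snap_names;

  return List::create(_["counts"] = counts, _["sd"] = grid_out(m, 0),
                      _["pd"] = grid_out(m, 1), _["snapshots"] = snaps);
}

// Sample `ndraws` independent elementary updates from a *fixed* state and
// tally the successor: slot 0 = unchanged, slot 1 + layer*N + site = the
// given site flipped. Used to compare the engine against the exact
// enumeration oracle.
// [[Rcpp::export]]
IntegerVector tally_updates(IntegerMatrix sd, IntegerMatrix pd, double b,
                            double R, double S, double Ppd, double Psd,
                            double K, double s, double noise, int noise_mode,
                            int ndraws, int seed) {
  Model m;
  build_model(m, sd, pd, b, R, S, Ppd, Psd, K, s, noise, noise_mode);
  Xoshiro rng((uint64_t)seed);
  IntegerVector tally(2 * m.N + 1);
  int layer, site, news;
  for (int k = 0; k < ndraws; ++k) {
    propose_update(m, rng, layer, site, news);
    if (news == (int)m.g[layer][site])
      ++tally[0];
    else
      ++tally[1 + layer * m.N + site];
  }
  return tally;
}

// ---------------------------------------------------------------------------
// Independent single-lattice comparator: one L x L lattice, Fermi imitation
// only (no interlayer coupling). Written as a straight transcription of the
// update rule -- payoffs summed pair by pair, Fermi function evaluated
// directly -- so it shares no tables with the coupled engine.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_lattice_engine(IntegerMatrix grid, double b, double R, double S,
                        double P, double K, int steps, int seed) {
  int L = grid.nrow(), N = L * L;
  std::vector<int> g(N);
  for (int i = 0; i < N; ++i) g[i] = grid[i];
  Xoshiro rng((uint64_t)seed);

  IntegerVector nc(steps + 1);
  int c0 = 0;
  for (int i = 0; i < N; ++i) c0 += g[i];
  nc[0] = c0;

  auto wrap = [L](int a) { return a < 0 ? a + L : (a >= L ? a - L : a); };
  auto at = [&](int r, int c) { return g[wrap(r) + wrap(c) * L]; };
  auto payoff = [&](int mine, int other) {
    if (mine == 1) return other == 1 ? R : S;
    return other == 1 ? b : P;
  };
  auto acc = [&](int r, int c) {
    int mine = at(r, c);
    return payoff(mine, at(r - 1, c)) + payoff(mine, at(r + 1, c)) +
           payoff(mine, at(r, c - 1)) + payoff(mine, at(r, c + 1));
  };

  for (int t = 1; t <= steps; ++t) {
    for (int k = 0; k < N; ++k) {
      uint64_t r1 = rng.next();
      int site = (int)(((r1 >> 1) & 0xFFFFFFFFULL) * (uint64_t)N >> 32);
      int row = site % L, col = site / L;
      uint64_t r2 = rng.next();
      int dir = (int)(r2 & 3);
      int yr = row, yc = col;
      if (dir == 0) yr = wrap(row - 1);
      else if (dir == 1) yr = wrap(row + 1);
      else if (dir == 2) yc = wrap(col - 1);
      else yc = wrap(col + 1);
      int sx = at(row, col), sy = at(yr, yc);
      if (sx == sy) continue;
      double px = acc(row, col), py = acc(yr, yc);
      double z = (px - py) / K;
      if (z > 500.0) z = 500.0;
      if (z < -500.0) z = -500.0;
      double w = 1.0 / (1.0 + std::exp(z));
      if (u53(r2) < w) {
        g[site] = sy;
        c0 += sy - sx;
      }
    }
    nc[t] = c0;
    if (c0 == 0 || c0 == N) {  // absorbing under pure imitation
      for (int u = t + 1; u <= steps; ++u) nc[u] = c0;
      break;
    }
    if ((t & 4095) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix out(L, L);
  for (int i = 0; i < N; ++i) out[i] = g[i];
  return List::create(_["counts"] = nc, _["grid"] = out);
}
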