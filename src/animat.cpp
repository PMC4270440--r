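#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Genome decoding
//
// Gene layout (28 loci, read circularly): start codon (42, 213), one locus
// for the number of inputs, one for outputs (n = 1 + locus %% 4), 4 input
// address loci, 4 output address loci, 16 table loci (always reserved for the
// maximal 2^4 rows; only the first 2^n_in are active).  Input addresses map
// onto the 6 elements that may feed a gate (2 sensors + 4 hidden), output
// addresses onto the 6 elements a gate may write (4 hidden + 2 motors).
// ---------------------------------------------------------------------------

struct Gate {
  std::vector<int> inputs;   // 0-based element ids, sorted ascending
  std::vector<int> outputs;  // 0-based element ids, sorted ascending
  std::vector<int> table;    // 2^n_in output patterns (bit k -> outputs[k])
};

template <typename V>
static std::vector<Gate> decode_gates(const V& loci) {
  const int L = loci.size();
  std::vector<Gate> gates;
  if (L < 2) return gates;
  for (int p = 0; p < L; ++p) {
    if (loci[p] != 42 || loci[(p + 1) % L] != 213) continue;
    Gate g;
    int n_in  = 1 + loci[(p + 2) % L] % 4;
    int n_out = 1 + loci[(p + 3) % L] % 4;
    for (int k = 0; k < n_in; ++k)
      g.inputs.push_back(loci[(p + 4 + k) % L] % 6);        // sensors+hidden
    for (int k = 0; k < n_out; ++k)
      g.outputs.push_back(2 + loci[(p + 8 + k) % L] % 6);   // hidden+motors
    std::sort(g.inputs.begin(), g.inputs.end());
    std::sort(g.outputs.begin(), g.outputs.end());
    int rows = 1 << n_in;
    for (int r = 0; r < rows; ++r)
      g.table.push_back(loci[(p + 12 + r) % L] % (1 << n_out));
    gates.push_back(g);
  }
  return gates;
}

// [[Rcpp::export]]
List cpp_decode_genome(IntegerVector loci) {
  std::vector<Gate> gates = decode_gates(loci);
  List out(gates.size());
  for (size_t i = 0; i < gates.size(); ++i) {
    out[i] = List::create(
      _["inputs"]  = IntegerVector(gates[i].inputs.begin(),  gates[i].inputs.end()),
      _["outputs"] = IntegerVector(gates[i].outputs.begin(), gates[i].outputs.end()),
      _["table"]   = IntegerVector(gates[i].table.begin(),   gates[i].table.end()));
  }
  return out;
}

// Build the deterministic 256-state TPM (next-state integers) and the 8x8
// connectivity matrix from a gate list.  Multiple writers OR-combine;
// elements written by no gate go to 0; sensors are never written.
static void tpm_from_gates(const std::vector<Gate>& gates,
                           std::vector<int>& next, IntegerMatrix& cm) {
  next.assign(256, 0);
  for (int s = 0; s < 256; ++s) {
    int ns = 0;
    for (const Gate& g : gates) {
      int row = 0;
      for (size_t k = 0; k < g.inputs.size(); ++k)
        if (s & (1 << g.inputs[k])) row |= 1 << k;
      int pat = g.table[row];
      for (size_t k = 0; k < g.outputs.size(); ++k)
        if (pat & (1 << k)) ns |= 1 << g.outputs[k];
    }
    next[s] = ns;
  }
  for (const Gate& g : gates)
    for (int i : g.inputs)
      for (int j : g.outputs) cm(i, j) = 1;
}

// [[Rcpp::export]]
List cpp_build_brain(List gates_r) {
  std::vector<Gate> gates;
  for (int i = 0; i < gates_r.size(); ++i) {
    List gl = gates_r[i];
    Gate g;
    IntegerVector in = gl["inputs"], out = gl["outputs"], tab = gl["table"];
    g.inputs  = std::vector<int>(in.begin(), in.end());
    g.outputs = std::vector<int>(out.begin(), out.end());
    g.table   = std::vector<int>(tab.begin(), tab.end());
    gates.push_back(g);
  }
  IntegerMatrix cm(8, 8);
  std::vector<int> next;
  tpm_from_gates(gates, next, cm);
  return List::create(_["next_state"] = IntegerVector(next.begin(), next.end()),
                      _["cm"] = cm);
}

// ---------------------------------------------------------------------------
// Task environment: 16-column world with periodic boundaries, blocks falling
// for 36 steps while moving sideways one unit per step.  The animat occupies
// three columns, sensors on the outer two.  Motor pattern 01 moves right,
// 10 left, 00/11 stay.
// ---------------------------------------------------------------------------

struct TaskDef {
  std::vector<int> sizes;      // 4 block-size slots
  std::vector<int> is_catch;   // 1 = catch, 0 = avoid, per slot
  int disabled_sensor;         // -1 none, else 0/1
  int disabled_motor;          // -1 none, else 0/1 (element 6/7)
  double sensor_noise;
  int noise_reps;
};

static const int WORLD = 16;
static const int FALL_STEPS = 36;

// Simulate one trial.  Optionally records the 36 experienced brain states
// (sensor bits written in, hidden/motor bits carried from the last update)
// and the animat's column after each step.
static void run_one_trial(const std::vector<int>& next, const TaskDef& td,
                          int size, int dir, int start,
                          bool record, int* traj, int* pos_out,
                          bool& caught, std::vector<int>* state_counts) {
  int animat = 0;           // leftmost of 3 columns; sensors at 0 and +2
  int block = start;        // leftmost block column
  int state = 0;            // hidden/motor bits from previous update
  for (int t = 0; t < FALL_STEPS; ++t) {
    int s1 = 0, s2 = 0;
    int c1 = animat % WORLD, c2 = (animat + 2) % WORLD;
    for (int u = 0; u < size; ++u) {
      int bc = ((block + u) % WORLD + WORLD) % WORLD;
      if (bc == c1) s1 = 1;
      if (bc == c2) s2 = 1;
    }
    if (td.sensor_noise > 0) {
      if (unif_rand() < td.sensor_noise) s1 ^= 1;
      if (unif_rand() < td.sensor_noise) s2 ^= 1;
    }
    if (td.disabled_sensor == 0) s1 = 0;
    if (td.disabled_sensor == 1) s2 = 0;
    int cur = (state & ~3) | s1 | (s2 << 1);
    if (record) traj[t] = cur;
    if (state_counts) (*state_counts)[cur] += 1;
    state = next[cur];
    int m1 = (state >> 6) & 1, m2 = (state >> 7) & 1;
    if (td.disabled_motor == 0) m1 = 0;
    if (td.disabled_motor == 1) m2 = 0;
    if (m2 && !m1) animat += 1;
    else if (m1 && !m2) animat -= 1;
    animat = ((animat % WORLD) + WORLD) % WORLD;
    if (record) pos_out[t] = animat;
    block += dir;
  }
  caught = false;
  int bfin = ((block % WORLD) + WORLD) % WORLD;
  for (int u = 0; u < size && !caught; ++u) {
    int bc = (bfin + u) % WORLD;
    for (int a = 0; a < 3; ++a)
      if (bc == (animat + a) % WORLD) { caught = true; break; }
  }
}

// Evaluate a brain on all 128 trials (x noise_reps when noisy).
// [[Rcpp::export]]
List cpp_evaluate(IntegerVector next_state, List task, bool record = true) {
  std::vector<int> next(next_state.begin(), next_state.end());
  TaskDef td;
  IntegerVector sz = task["sizes"], ct = task["is_catch"];
  td.sizes = std::vector<int>(sz.begin(), sz.end());
  td.is_catch = std::vector<int>(ct.begin(), ct.end());
  td.disabled_sensor = as<int>(task["disabled_sensor"]);
  td.disabled_motor  = as<int>(task["disabled_motor"]);
  td.sensor_noise    = as<double>(task["sensor_noise"]);
  td.noise_reps      = as<int>(task["noise_reps"]);
  int reps = (td.sensor_noise > 0) ? td.noise_reps : 1;

  const int NT = 128;
  IntegerMatrix traj(record ? NT : 0, record ? FALL_STEPS : 0);
  IntegerMatrix pos(record ? NT : 0, record ? FALL_STEPS : 0);
  NumericVector correct(NT), caught_frac(NT);
  IntegerVector trial_size(NT), trial_dir(NT), trial_start(NT);
  std::vector<int> counts(256, 0);

  for (int rep = 0; rep < reps; ++rep) {
    int ti = 0;
    for (int slot = 0; slot < 4; ++slot) {
      for (int d = 0; d < 2; ++d) {
        int dir = d == 0 ? 1 : -1;
        for (int b0 = 0; b0 < WORLD; ++b0, ++ti) {
          bool caught;
          bool rec = record && rep == 0;
          std::vector<int> tr(FALL_STEPS), ps(FALL_STEPS);
          run_one_trial(next, td, td.sizes[slot], dir, b0, rec,
                        tr.data(), ps.data(), caught, &counts);
          if (rec) {
            for (int t = 0; t < FALL_STEPS; ++t) {
              traj(ti, t) = tr[t]; pos(ti, t) = ps[t];
            }
            trial_size[ti] = td.sizes[slot];
            trial_dir[ti] = dir;
            trial_start[ti] = b0;
          }
          bool corr = td.is_catch[slot] ? caught : !caught;
          correct[ti] += corr ? 1.0 : 0.0;
          caught_frac[ti] += caught ? 1.0 : 0.0;
        }
      }
    }
  }
  for (int i = 0; i < NT; ++i) { correct[i] /= reps; caught_frac[i] /= reps; }
  double n_correct = std::accumulate(correct.begin(), correct.end(), 0.0);
  List out = List::create(
    _["n_correct"] = n_correct,
    _["F"] = n_correct / NT,
    _["correct"] = correct,
    _["caught"] = caught_frac,
    _["state_counts"] = IntegerVector(counts.begin(), counts.end()),
    _["size"] = trial_size, _["direction"] = trial_dir, _["start"] = trial_start,
    _["trajectories"] = traj, _["positions"] = pos);
  return out;
}

// Lazily evaluated TPM: the 256-state table is filled only for states the
// trials actually visit, which is much cheaper for the evolution inner loop.
struct LazyTPM {
  const std::vector<Gate>* gates;
  int cache[256];
  explicit LazyTPM(const std::vector<Gate>& g) : gates(&g) {
    std::fill(cache, cache + 256, -1);
  }
  int next(int s) {
    if (cache[s] >= 0) return cache[s];
    int ns = 0;
    for (const Gate& g : *gates) {
      int row = 0;
      for (size_t k = 0; k < g.inputs.size(); ++k)
        if (s & (1 << g.inputs[k])) row |= 1 << k;
      int pat = g.table[row];
      for (size_t k = 0; k < g.outputs.size(); ++k)
        if (pat & (1 << k)) ns |= 1 << g.outputs[k];
    }
    cache[s] = ns;
    return ns;
  }
};

// Sensor masks over the block-minus-animat offset (mod 16): bit r of
// s1_mask is set iff a block of this size at offset r sits above sensor 1.
static inline int sensor_mask(int size, int sensor_col) {
  int m = 0;
  for (int r = 0; r < WORLD; ++r)
    for (int u = 0; u < size; ++u)
      if ((r + u) % WORLD == sensor_col) { m |= 1 << r; break; }
  return m;
}

// One trial against a lazy TPM (fitness-only path), tracking only the
// relative offset between block and animat.
static bool lazy_trial_caught(LazyTPM& tpm, const TaskDef& td,
                              int size, int dir, int start) {
  const int m1mask = sensor_mask(size, 0);
  const int m2mask = sensor_mask(size, 2);
  int rel = start, state = 0;
  const bool noisy = td.sensor_noise > 0;
  for (int t = 0; t < FALL_STEPS; ++t) {
    int s1 = (m1mask >> rel) & 1, s2 = (m2mask >> rel) & 1;
    if (noisy) {
      if (unif_rand() < td.sensor_noise) s1 ^= 1;
      if (unif_rand() < td.sensor_noise) s2 ^= 1;
    }
    if (td.disabled_sensor == 0) s1 = 0;
    else if (td.disabled_sensor == 1) s2 = 0;
    state = tpm.next((state & ~3) | s1 | (s2 << 1));
    int m = state >> 6;
    if (td.disabled_motor == 0) m &= ~1;
    else if (td.disabled_motor == 1) m &= ~2;
    int delta = (m == 2) ? 1 : (m == 1 ? -1 : 0);
    rel = (rel + dir - delta + 2 * WORLD) & (WORLD - 1);
  }
  // overlap iff some block unit lands on one of the animat's 3 columns
  int catch_mask = 0;
  for (int a = 0; a < 3; ++a)
    catch_mask |= sensor_mask(size, a);
  return ((catch_mask >> rel) & 1) != 0;
}

// Fitness only (no recording) -- used in the evolution inner loop.
static double eval_fitness(const std::vector<Gate>& gates, const TaskDef& td) {
  int reps = (td.sensor_noise > 0) ? td.noise_reps : 1;
  LazyTPM tpm(gates);
  double ncorr = 0.0;
  for (int rep = 0; rep < reps; ++rep) {
    for (int slot = 0; slot < 4; ++slot)
      for (int d = 0; d < 2; ++d)
        for (int b0 = 0; b0 < WORLD; ++b0) {
          bool caught = lazy_trial_caught(tpm, td, td.sizes[slot],
                                          d == 0 ? 1 : -1, b0);
          bool corr = td.is_catch[slot] ? caught : !caught;
          if (corr) ncorr += 1.0;
        }
  }
  return ncorr / reps;
}

// ---------------------------------------------------------------------------
// Mutation: point mutations (rate per locus), one possible deletion and one
// possible duplication per genome, fragment lengths uniform in
// [frag_min, frag_max]; operations that would push the genome outside
// [len_min, len_max] are suppressed.
// ---------------------------------------------------------------------------

static std::vector<int> mutate_vec(const std::vector<int>& g,
                                   double point_rate, double del_prob,
                                   double dup_prob, int frag_min, int frag_max,
                                   int len_min, int len_max) {
  std::vector<int> out = g;
  int L = out.size();
  if (point_rate > 0) {
    // geometric skipping over loci
    double log1m = std::log(1.0 - point_rate);
    if (point_rate >= 1.0) {
      for (int i = 0; i < L; ++i)
        out[i] = (int)std::floor(unif_rand() * 256.0) % 256;
    } else {
      double u = unif_rand();
      int i = (int)std::floor(std::log(u) / log1m);
      while (i < L) {
        out[i] = (int)std::floor(unif_rand() * 256.0) % 256;
        u = unif_rand();
        i += 1 + (int)std::floor(std::log(u) / log1m);
      }
    }
  }
  if (del_prob > 0 && unif_rand() < del_prob) {
    int flen = frag_min + (int)std::floor(unif_rand() * (frag_max - frag_min + 1));
    if (flen > frag_max) flen = frag_max;
    int Lc = out.size();
    if (Lc - flen >= len_min && flen < Lc) {
      int start = (int)std::floor(unif_rand() * (Lc - flen + 1));
      out.erase(out.begin() + start, out.begin() + start + flen);
    }
  }
  if (dup_prob > 0 && unif_rand() < dup_prob) {
    int flen = frag_min + (int)std::floor(unif_rand() * (frag_max - frag_min + 1));
    if (flen > frag_max) flen = frag_max;
    int Lc = out.size();
    if (Lc + flen <= len_max && flen <= Lc) {
      int src = (int)std::floor(unif_rand() * (Lc - flen + 1));
      int ins = (int)std::floor(unif_rand() * (Lc + 1));
      std::vector<int> frag(out.begin() + src, out.begin() + src + flen);
      out.insert(out.begin() + ins, frag.begin(), frag.end());
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_mutate(IntegerVector genome, double point_rate,
                         double del_prob, double dup_prob,
                         int frag_min, int frag_max,
                         int len_min, int len_max) {
  std::vector<int> g(genome.begin(), genome.end());
  std::vector<int> out = mutate_vec(g, point_rate, del_prob, dup_prob,
                                    frag_min, frag_max, len_min, len_max);
  return IntegerVector(out.begin(), out.end());
}

// ---------------------------------------------------------------------------
// Genetic algorithm: fitness-proportional (roulette-wheel) selection on the
// exponential score S = base^(number of correct trials), no elitism.
// Population snapshots are kept every `snapshot_interval` generations (and at
// the final generation) so that any line of descent can be reconstructed.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_evolution(List task, int generations, int pop_size,
                       double selection_base, int genome_length,
                       double point_rate, double del_prob, double dup_prob,
                       int frag_min, int frag_max, int len_min, int len_max,
                       int snapshot_interval) {
  TaskDef td;
  IntegerVector sz = task["sizes"], ct = task["is_catch"];
  td.sizes = std::vector<int>(sz.begin(), sz.end());
  td.is_catch = std::vector<int>(ct.begin(), ct.end());
  td.disabled_sensor = as<int>(task["disabled_sensor"]);
  td.disabled_motor  = as<int>(task["disabled_motor"]);
  td.sensor_noise    = as<double>(task["sensor_noise"]);
  td.noise_reps      = as<int>(task["noise_reps"]);

  std::vector<std::vector<int>> pop(pop_size, std::vector<int>(genome_length, 0));
  NumericMatrix fitness(generations + 1, pop_size);
  IntegerMatrix parents(generations, pop_size);
  std::vector<int> snap_gens;
  List snapshots;

  std::vector<double> ncorr(pop_size);

  for (int g = 0; g <= generations; ++g) {
    for (int i = 0; i < pop_size; ++i) {
      std::vector<Gate> gates = decode_gates(pop[i]);
      ncorr[i] = eval_fitness(gates, td);
      fitness(g, i) = ncorr[i] / 128.0;
    }
    if (g % snapshot_interval == 0 || g == generations) {
      List snap(pop_size);
      for (int i = 0; i < pop_size; ++i)
        snap[i] = IntegerVector(pop[i].begin(), pop[i].end());
      snapshots.push_back(snap);
      snap_gens.push_back(g);
    }
    if (g == generations) break;
    // roulette-wheel selection on S = base^(n_correct)
    std::vector<double> cum(pop_size);
    double tot = 0;
    for (int i = 0; i < pop_size; ++i) {
      tot += std::pow(selection_base, ncorr[i]);
      cum[i] = tot;
    }
    std::vector<int> chosen(pop_size);
    for (int i = 0; i < pop_size; ++i) {
      double u = unif_rand() * tot;
      chosen[i] = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
      if (chosen[i] >= pop_size) chosen[i] = pop_size - 1;
      parents(g, i) = chosen[i] + 1;  // 1-based for R
    }
    std::vector<std::vector<int>> newpop(pop_size);
    for (int i = 0; i < pop_size; ++i)
      newpop[i] = mutate_vec(pop[chosen[i]], point_rate, del_prob, dup_prob,
                             frag_min, frag_max, len_min, len_max);
    pop = std::move(newpop);
    if (g % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["fitness"] = fitness, _["parents"] = parents,
                      _["snapshot_generations"] = IntegerVector(snap_gens.begin(), snap_gens.end()),
                      _["snapshots"] = snapshots);
}

// ---------------------------------------------------------------------------
// Exact earth-mover's distance via successive-shortest-path min-cost flow.
// Shared mass is cancelled first (optimal under a metric ground distance).
// ---------------------------------------------------------------------------

static double emd_flow(const std::vector<double>& a, const std::vector<double>& b,
                       const std::vector<std::vector<double>>& C) {
  int n1 = a.size(), n2 = b.size();
  std::vector<double> supply = a, demand = b;
  std::vector<std::vector<double>> flow(n1, std::vector<double>(n2, 0.0));
  std::vector<double> potS(n1, 0.0), potD(n2, 0.0);
  const double EPS = 1e-12;
  double total_left = 0;
  for (double v : supply) total_left += v;

  while (total_left > 1e-10) {
    // Dijkstra over bipartite residual graph with potentials
    std::vector<double> distS(n1, std::numeric_limits<double>::infinity());
    std::vector<double> distD(n2, std::numeric_limits<double>::infinity());
    std::vector<int> prevD(n2, -1);       // source feeding this sink
    std::vector<int> prevS(n1, -2);       // sink feeding this source (residual), -1 = origin
    typedef std::pair<double, int> PDI;   // (dist, node); node < n1: source, else sink
    std::priority_queue<PDI, std::vector<PDI>, std::greater<PDI>> pq;
    for (int i = 0; i < n1; ++i)
      if (supply[i] > EPS) { distS[i] = 0; prevS[i] = -1; pq.push({0.0, i}); }
    while (!pq.empty()) {
      PDI top = pq.top(); pq.pop();
      double d = top.first; int node = top.second;
      if (node < n1) {
        if (d > distS[node] + EPS) continue;
        for (int j = 0; j < n2; ++j) {
          double rc = C[node][j] + potS[node] - potD[j];
          if (rc < 0) rc = 0;  // guard tiny negatives
          if (distS[node] + rc < distD[j] - EPS) {
            distD[j] = distS[node] + rc;
            prevD[j] = node;
            pq.push({distD[j], n1 + j});
          }
        }
      } else {
        int j = node - n1;
        if (d > distD[j] + EPS) continue;
        for (int i = 0; i < n1; ++i) {
          if (flow[i][j] > EPS) {  // residual backward edge
            double rc = -(C[i][j] + potS[i] - potD[j]);
            if (rc < 0) rc = 0;
            if (distD[j] + rc < distS[i] - EPS) {
              distS[i] = distD[j] + rc;
              prevS[i] = j;
              pq.push({distS[i], i});
            }
          }
        }
      }
    }
    // pick reachable sink with remaining demand
    int best = -1;
    for (int j = 0; j < n2; ++j)
      if (demand[j] > EPS && prevD[j] >= 0 &&
          (best < 0 || distD[j] < distD[best])) best = j;
    if (best < 0) break;  // numerically drained
    // bottleneck along path
    double push = demand[best];
    int j = best;
    while (true) {
      int i = prevD[j];
      if (prevS[i] == -1) { push = std::min(push, supply[i]); break; }
      j = prevS[i];
      push = std::min(push, flow[i][j]);
    }
    // apply
    j = best;
    while (true) {
      int i = prevD[j];
      flow[i][j] += push;
      if (prevS[i] == -1) { supply[i] -= push; break; }
      int j2 = prevS[i];
      flow[i][j2] -= push;
      j = j2;
    }
    demand[best] -= push;
    total_left -= push;
    // update potentials
    for (int i = 0; i < n1; ++i)
      if (std::isfinite(distS[i])) potS[i] += distS[i];
    for (int jj = 0; jj < n2; ++jj)
      if (std::isfinite(distD[jj])) potD[jj] += distD[jj];
  }
  double cost = 0;
  for (int i = 0; i < n1; ++i)
    for (int jj = 0; jj < n2; ++jj) cost += flow[i][jj] * C[i][jj];
  return cost;
}

// [[Rcpp::export]]
double cpp_emd(NumericVector p, NumericVector q, NumericMatrix cost) {
  int n = p.size();
  // cancel shared mass (valid for metric costs)
  std::vector<double> pr, qr;
  std::vector<int> pi, qi;
  for (int i = 0; i < n; ++i) {
    double m = std::min(p[i], q[i]);
    double pe = p[i] - m, qe = q[i] - m;
    if (pe > 1e-14) { pr.push_back(pe); pi.push_back(i); }
    if (qe > 1e-14) { qr.push_back(qe); qi.push_back(i); }
  }
  if (pr.empty() || qr.empty()) return 0.0;
  std::vector<std::vector<double>> C(pr.size(), std::vector<double>(qr.size()));
  for (size_t i = 0; i < pr.size(); ++i)
    for (size_t j = 0; j < qr.size(); ++j)
      C[i][j] = cost(pi[i], qi[j]);
  return emd_flow(pr, qr, C);
}

// EMD between distributions over k-bit states with Hamming ground metric.
// [[Rcpp::export]]
double cpp_emd_hamming(NumericVector p, NumericVector q) {
  int n = p.size();
  std::vector<double> pr, qr;
  std::vector<int> pi, qi;
  for (int i = 0; i < n; ++i) {
    double m = std::min(p[i], q[i]);
    double pe = p[i] - m, qe = q[i] - m;
    if (pe > 1e-14) { pr.push_back(pe); pi.push_back(i); }
    if (qe > 1e-14) { qr.push_back(qe); qi.push_back(i); }
  }
  if (pr.empty() || qr.empty()) return 0.0;
  std::vector<std::vector<double>> C(pr.size(), std::vector<double>(qr.size()));
  for (size_t i = 0; i < pr.size(); ++i)
    for (size_t j = 0; j < qr.size(); ++j) {
      int x = pi[i] ^ qi[j];
      int h = 0;
      while (x) { h += x & 1; x >>= 1; }
      C[i][j] = h;
    }
  return emd_flow(pr, qr, C);
}

// General transport cost between two mass vectors (not necessarily equal
// totals handled by caller). Used for the extended (concept-level) EMD.
// [[Rcpp::export]]
double cpp_transport(NumericVector supply, NumericVector demand,
                     NumericMatrix cost) {
  std::vector<double> a(supply.begin(), supply.end());
  std::vector<double> b(demand.begin(), demand.end());
  std::vector<std::vector<double>> C(a.size(), std::vector<double>(b.size()));
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j) C[i][j] = cost(i, j);
  return emd_flow(a, b, C);
}
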