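#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Sequential Rosenbluth growth of confined self-avoiding chains of tangent
// hard spheres. Bond length is exactly one bead diameter; at each step
// n_candidates directions are proposed uniformly on the sphere, the set of
// feasible ones (whole bead inside the confinement sphere, no overlap with
// any previously placed non-bonded bead) is counted, one feasible candidate
// is chosen uniformly, and the chain's weight accumulates the factor
// n_feasible / n_candidates. Weighted averages over the ensemble are then
// unbiased estimates of uniform-ensemble expectations.
//
// For long chains the weights degenerate, so the population can be grown
// as a sequential Monte Carlo sampler: whenever the effective sample size
// falls below resample_threshold * n_chains, chains are resampled
// systematically according to their weights and the weights reset.
//
// Uses R's RNG (unif_rand / norm_rand) so set.seed() on the R side makes
// every draw reproducible.

static inline void rand_unit(double &x, double &y, double &z) {
  double n2;
  do {
    x = norm_rand(); y = norm_rand(); z = norm_rand();
    n2 = x * x + y * y + z * z;
  } while (n2 < 1e-300);
  double inv = 1.0 / std::sqrt(n2);
  x *= inv; y *= inv; z *= inv;
}

struct Pop {
  int n_chains, n_beads;
  // coords laid out chain-major: chain k, bead i -> [k][3*i + dim]
  std::vector<std::vector<double>> X;
  Pop(int n_chains, int n_beads)
      : n_chains(n_chains), n_beads(n_beads),
        X(n_chains, std::vector<double>(3 * (size_t)n_beads)) {}
};

static inline void place_first_bead(std::vector<double> &chain, double r_max) {
  double u = unif_rand();
  double r0 = r_max * std::cbrt(u);
  double ux, uy, uz;
  rand_unit(ux, uy, uz);
  chain[0] = r0 * ux; chain[1] = r0 * uy; chain[2] = r0 * uz;
}

// one growth step for one chain; returns n_feasible (0 = dead end)
static int grow_step(std::vector<double> &chain, int i, double diam,
                     double r_max, int n_candidates,
                     std::vector<double> &cx, std::vector<double> &cy,
                     std::vector<double> &cz) {
  const double d2 = diam * diam;
  const double rmax2 = r_max * r_max;
  const double px = chain[3 * (i - 1)];
  const double py = chain[3 * (i - 1) + 1];
  const double pz = chain[3 * (i - 1) + 2];
  int n_feas = 0;
  double ux, uy, uz;
  for (int c = 0; c < n_candidates; ++c) {
    rand_unit(ux, uy, uz);
    const double x = px + diam * ux;
    const double y = py + diam * uy;
    const double z = pz + diam * uz;
    if (x * x + y * y + z * z > rmax2) continue;
    bool ok = true;
    for (int j = i - 2; j >= 0; --j) { // newest non-bonded beads clash most
      const double dx = x - chain[3 * j];
      const double dy = y - chain[3 * j + 1];
      const double dz = z - chain[3 * j + 2];
      if (dx * dx + dy * dy + dz * dz < d2) { ok = false; break; }
    }
    if (ok) { cx[n_feas] = x; cy[n_feas] = y; cz[n_feas] = z; ++n_feas; }
  }
  if (n_feas == 0) return 0;
  int pick = (int)(unif_rand() * n_feas);
  if (pick >= n_feas) pick = n_feas - 1;
  chain[3 * i] = cx[pick]; chain[3 * i + 1] = cy[pick]; chain[3 * i + 2] = cz[pick];
  return n_feas;
}

// systematic resampling of chain indices proportional to weights w (sum 1)
static std::vector<int> systematic_indices(const std::vector<double> &w) {
  const int n = (int)w.size();
  std::vector<int> idx(n);
  double u = unif_rand() / n;
  double cum = w[0];
  int j = 0;
  for (int k = 0; k < n; ++k) {
    const double target = u + (double)k / n;
    while (cum < target && j < n - 1) { ++j; cum += w[j]; }
    idx[k] = j;
  }
  return idx;
}

// [[Rcpp::export]]
List cpp_sample_chains(int n_chains, int n_beads, double bead_diameter,
                       double confinement_radius, int n_candidates,
                       int retry_budget, double resample_threshold) {
  const double r_max = confinement_radius - bead_diameter / 2.0;
  if (r_max <= 0)
    stop("infeasible geometry: confinement radius too small to place a bead");
  if (n_beads < 1 || n_chains < 1)
    stop("n_beads and n_chains must be >= 1");

  RNGScope scope;
  Pop pop(n_chains, n_beads);
  std::vector<double> logw(n_chains, 0.0);
  std::vector<double> cx(n_candidates), cy(n_candidates), cz(n_candidates);
  int n_resamples = 0, n_restarts = 0;

  if (resample_threshold <= 0.0) {
    // independent Rosenbluth growth with per-chain restart on dead ends
    for (int k = 0; k < n_chains; ++k) {
      int tries = 0;
      bool done = false;
      while (!done) {
        if (tries >= retry_budget)
          stop("chain abandoned: growth dead-end persisted for %d retries (chain %d of %d)",
               retry_budget, k + 1, n_chains);
        ++tries;
        place_first_bead(pop.X[k], r_max);
        double lw = 0.0;
        done = true;
        for (int i = 1; i < n_beads; ++i) {
          int nf = grow_step(pop.X[k], i, bead_diameter, r_max, n_candidates, cx, cy, cz);
          if (nf == 0) { done = false; break; }
          lw += std::log((double)nf / n_candidates);
        }
        if (done) logw[k] = lw;
      }
      n_restarts += tries - 1;
      if ((k & 255) == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    // sequential Monte Carlo: grow the population in lockstep, resample
    // systematically when the effective sample size degenerates
    std::vector<bool> alive(n_chains, true);
    for (int k = 0; k < n_chains; ++k) place_first_bead(pop.X[k], r_max);
    std::vector<double> w(n_chains);
    for (int i = 1; i < n_beads; ++i) {
      for (int k = 0; k < n_chains; ++k) {
        if (!alive[k]) continue;
        int nf = grow_step(pop.X[k], i, bead_diameter, r_max, n_candidates, cx, cy, cz);
        if (nf == 0) { alive[k] = false; logw[k] = R_NegInf; }
        else logw[k] += std::log((double)nf / n_candidates);
      }
      double mx = R_NegInf;
      for (int k = 0; k < n_chains; ++k) if (logw[k] > mx) mx = logw[k];
      if (mx == R_NegInf)
        stop("growth dead-end: every chain in the population died at bead %d", i + 1);
      double sum = 0.0;
      for (int k = 0; k < n_chains; ++k) { w[k] = std::exp(logw[k] - mx); sum += w[k]; }
      double ess_inv = 0.0;
      for (int k = 0; k < n_chains; ++k) { w[k] /= sum; ess_inv += w[k] * w[k]; }
      const double ess = 1.0 / ess_inv;
      // resample when degenerate; always resample away chains that died at
      // the final bead (weight zero, incomplete coordinates)
      bool any_dead = false;
      for (int k = 0; k < n_chains; ++k) if (!alive[k]) { any_dead = true; break; }
      if ((ess < resample_threshold * n_chains && i < n_beads - 1) ||
          (any_dead && i == n_beads - 1)) {
        std::vector<int> idx = systematic_indices(w);
        std::vector<std::vector<double>> Xnew(n_chains);
        for (int k = 0; k < n_chains; ++k) Xnew[k] = pop.X[idx[k]];
        pop.X.swap(Xnew);
        std::fill(logw.begin(), logw.end(), 0.0);
        std::fill(alive.begin(), alive.end(), true);
        ++n_resamples;
      }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericVector coords(Dimension(n_beads, 3, n_chains));
  NumericVector log_weights(n_chains);
  for (int k = 0; k < n_chains; ++k) {
    log_weights[k] = logw[k];
    for (int i = 0; i < n_beads; ++i) {
      coords[i + (size_t)n_beads * 0 + (size_t)3 * n_beads * k] = pop.X[k][3 * i];
      coords[i + (size_t)n_beads * 1 + (size_t)3 * n_beads * k] = pop.X[k][3 * i + 1];
      coords[i + (size_t)n_beads * 2 + (size_t)3 * n_beads * k] = pop.X[k][3 * i + 2];
    }
  }
  return List::create(_["coords"] = coords, _["log_weights"] = log_weights,
                      _["n_resamples"] = n_resamples, _["n_restarts"] = n_restarts);
}

// [[Rcpp::export]]
NumericMatrix cpp_contact_matrix(NumericVector coords, NumericVector weights,
                                 double threshold) {
  IntegerVector dims = coords.attr("dim");
  const int n_beads = dims[0];
  const int n_chains = dims[2];
  if (weights.size() != n_chains) stop("one weight per chain required");
  const double t2 = threshold * threshold;
  NumericMatrix M(n_beads, n_beads);
  for (int k = 0; k < n_chains; ++k) {
    const double w = weights[k];
    const double *X = &coords[(size_t)3 * n_beads * k];
    const double *Y = X + n_beads;
    const double *Z = Y + n_beads;
    for (int i = 0; i < n_beads; ++i) {
      for (int j = i + 1; j < n_beads; ++j) {
        const double dx = X[i] - X[j];
        const double dy = Y[i] - Y[j];
        const double dz = Z[i] - Z[j];
        if (dx * dx + dy * dy + dz * dz <= t2) {
          M(i, j) += w;
        }
      }
    }
    if ((k & 255) == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < n_beads; ++i)
    for (int j = i + 1; j < n_beads; ++j)
      M(j, i) = M(i, j);
  return M;
}

// weighted per-stratum contact fractions accumulated over blocks of chains;
// block means give a sampling-error estimate for the distance-decay curve
// [[Rcpp::export]]
List cpp_decay_blocks(NumericVector coords, NumericVector weights,
                      double threshold, int n_blocks) {
  IntegerVector dims = coords.attr("dim");
  const int n_beads = dims[0];
  const int n_chains = dims[2];
  const double t2 = threshold * threshold;
  const int n_strata = n_beads - 1;
  NumericMatrix block_sum(n_blocks, n_strata); // weighted contact fraction sums
  NumericVector block_w(n_blocks);
  std::vector<int> npairs(n_strata + 1);
  for (int s = 1; s <= n_strata; ++s) npairs[s] = n_beads - s;
  for (int k = 0; k < n_chains; ++k) {
    const int b = (int)(((double)k * n_blocks) / n_chains);
    const double w = weights[k];
    block_w[b] += w;
    const double *X = &coords[(size_t)3 * n_beads * k];
    const double *Y = X + n_beads;
    const double *Z = Y + n_beads;
    for (int s = 1; s <= n_strata; ++s) {
      int hits = 0;
      for (int i = 0; i + s < n_beads; ++i) {
        const double dx = X[i] - X[i + s];
        const double dy = Y[i] - Y[i + s];
        const double dz = Z[i] - Z[i + s];
        if (dx * dx + dy * dy + dz * dz <= t2) ++hits;
      }
      block_sum(b, s - 1) += w * (double)hits / npairs[s];
    }
    if ((k & 127) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["block_sum"] = block_sum, _["block_weight"] = block_w);
}

// minimum non-bonded pair distance, maximum bead norm and bond-length range
// per chain; used by fast invariant checks over whole ensembles
// [[Rcpp::export]]
NumericMatrix cpp_chain_invariants(NumericVector coords) {
  IntegerVector dims = coords.attr("dim");
  const int n_beads = dims[0];
  const int n_chains = dims[2];
  NumericMatrix out(n_chains, 4); // min nonbonded dist, max norm, min bond, max bond
  for (int k = 0; k < n_chains; ++k) {
    const double *X = &coords[(size_t)3 * n_beads * k];
    const double *Y = X + n_beads;
    const double *Z = Y + n_beads;
    double min_nb = R_PosInf, max_norm = 0.0, min_bond = R_PosInf, max_bond = 0.0;
    for (int i = 0; i < n_beads; ++i) {
      const double nrm = std::sqrt(X[i] * X[i] + Y[i] * Y[i] + Z[i] * Z[i]);
      if (nrm > max_norm) max_norm = nrm;
      for (int j = i + 1; j < n_beads; ++j) {
        const double dx = X[i] - X[j];
        const double dy = Y[i] - Y[j];
        const double dz = Z[i] - Z[j];
        const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (j == i + 1) {
          if (d < min_bond) min_bond = d;
          if (d > max_bond) max_bond = d;
        } else if (d < min_nb) {
          min_nb = d;
        }
      }
    }
    out(k, 0) = min_nb;
    out(k, 1) = max_norm;
    out(k, 2) = min_bond;
    out(k, 3) = max_bond;
  }
  return out;
}
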