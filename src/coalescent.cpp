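// Structured-coalescent engine: independent (unlinked) genealogies across
// demes with piecewise-constant diploid sizes, lineage-movement events
// (population joins = forward-time splits, admixture pulses, size changes)
// and continuous backward migration.  Times are in generations before
// present; events must be supplied sorted by time.
//
// Event rows: (time, type, a, b, param)
//   type 0: join   -- all lineages currently in deme a move to deme b
//   type 1: size   -- deme a gets diploid size param
//   type 2: pulse  -- each lineage in deme a moves to deme b with prob param
//   type 3: migset -- backward migration rate a -> b set to param
//
// Uses R's RNG so set.seed() in R gives full determinism.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Reusable buffers: one allocation across all genealogies of a call.
struct Genealogy {
  std::vector<double> time;   // node times, length 2n-1
  std::vector<int> parent;    // -1 for root
  int n;                      // number of leaves
  int root;
  std::vector<std::vector<int>> act;
  std::vector<double> rc, popN, mig;
};

// Simulate one genealogy into g (buffers reused between calls).
void sim_genealogy(Genealogy &g, const std::vector<int> &samp,
                   const std::vector<double> &popN0,
                   const NumericMatrix &events,
                   const NumericMatrix &mig0) {
  const int ndeme = popN0.size();
  g.popN.assign(popN0.begin(), popN0.end());
  std::vector<double> &popN = g.popN;
  g.mig.resize(ndeme * ndeme);
  std::vector<double> &mig = g.mig;
  bool has_mig = false;
  for (int i = 0; i < ndeme; ++i)
    for (int j = 0; j < ndeme; ++j) {
      mig[i * ndeme + j] = mig0(i, j);
      if (mig0(i, j) > 0) has_mig = true;
    }
  int n = 0;
  for (int d = 0; d < ndeme; ++d) n += samp[d];
  g.n = n;
  g.time.assign(2 * n - 1, 0.0);
  g.parent.assign(2 * n - 1, -1);

  g.act.resize(ndeme);
  std::vector<std::vector<int>> &act = g.act;
  {
    int id = 0;
    for (int d = 0; d < ndeme; ++d) {
      act[d].clear();
      for (int k = 0; k < samp[d]; ++k) act[d].push_back(id++);
    }
  }
  int nact = n, next_node = n, ev = 0;
  const int n_ev = events.nrow();
  double t = 0.0;

  g.rc.assign(ndeme, 0.0);
  std::vector<double> &rc = g.rc;
  while (nact > 1) {
    double R = 0.0;
    for (int d = 0; d < ndeme; ++d) {
      double k = (double)act[d].size();
      rc[d] = (k > 1 && popN[d] > 0) ? k * (k - 1.0) / (4.0 * popN[d]) : 0.0;
      R += rc[d];
    }
    double rm_tot = 0.0;
    if (has_mig) {
      for (int d = 0; d < ndeme; ++d) {
        double k = (double)act[d].size();
        if (k == 0) continue;
        for (int j = 0; j < ndeme; ++j)
          if (j != d) rm_tot += k * mig[d * ndeme + j];
      }
      R += rm_tot;
    }
    double t_ev = (ev < n_ev) ? events(ev, 0) : R_PosInf;
    double dt = (R > 0) ? exp_rand() / R : R_PosInf;
    if (t + dt >= t_ev) {
      if (!R_FINITE(t_ev))
        stop("lineages cannot reach a common ancestor: zero rates and no remaining events");
      t = t_ev;
      int type = (int)events(ev, 1);
      int a = (int)events(ev, 2), b = (int)events(ev, 3);
      double par = events(ev, 4);
      if (type == 0) {           // join a -> b
        for (size_t i = 0; i < act[a].size(); ++i) act[b].push_back(act[a][i]);
        act[a].clear();
      } else if (type == 1) {    // size change
        popN[a] = par;
      } else if (type == 3) {    // migration rate change
        mig[a * ndeme + b] = par;
        has_mig = false;
        for (size_t i = 0; i < mig.size(); ++i)
          if (mig[i] > 0) { has_mig = true; break; }
      } else {                   // pulse a -> b with prob par
        for (int i = (int)act[a].size() - 1; i >= 0; --i) {
          if (unif_rand() < par) {
            act[b].push_back(act[a][i]);
            act[a][i] = act[a].back();
            act[a].pop_back();
          }
        }
      }
      ++ev;
      continue;
    }
    t += dt;
    double u = unif_rand() * R;
    bool done = false;
    for (int d = 0; d < ndeme && !done; ++d) {
      if (u < rc[d]) {           // coalescence in deme d
        int k = (int)act[d].size();
        int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
        int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        int ni = act[d][i], nj = act[d][j];
        int v = next_node++;
        g.time[v] = t;
        g.parent[ni] = v;
        g.parent[nj] = v;
        // replace i with v, swap-remove j
        act[d][i] = v;
        act[d][j] = act[d].back();
        act[d].pop_back();
        --nact;
        done = true;
      } else u -= rc[d];
    }
    if (!done && has_mig) {      // migration
      for (int d = 0; d < ndeme && !done; ++d) {
        double k = (double)act[d].size();
        if (k == 0) continue;
        for (int j = 0; j < ndeme && !done; ++j) {
          if (j == d) continue;
          double r = k * mig[d * ndeme + j];
          if (u < r) {
            int i = (int)(unif_rand() * k); if (i >= (int)k) i = (int)k - 1;
            act[j].push_back(act[d][i]);
            act[d][i] = act[d].back();
            act[d].pop_back();
            done = true;
          } else u -= r;
        }
      }
    }
    if (!done) {
      // numerical edge: attribute to the last positive-rate coalescence
      for (int d = ndeme - 1; d >= 0; --d) {
        if (rc[d] > 0) {
          int k = (int)act[d].size();
          int ni = act[d][k - 1], nj = act[d][k - 2];
          int v = next_node++;
          g.time[v] = t;
          g.parent[ni] = v; g.parent[nj] = v;
          act[d][k - 2] = v; act[d].pop_back();
          --nact;
          break;
        }
      }
    }
  }
  g.root = 2 * n - 2;
}

// leaves below node v (leaf ids < n)
void leaves_under(const Genealogy &g,
                  const std::vector<std::vector<int>> &child,
                  int v, std::vector<int> &out) {
  out.clear();
  std::vector<int> stack(1, v);
  while (!stack.empty()) {
    int x = stack.back(); stack.pop_back();
    if (x < g.n) out.push_back(x);
    else for (size_t c = 0; c < child[x].size(); ++c) stack.push_back(child[x][c]);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_coal_genotypes(IntegerVector sample_hap, NumericVector pop_sizes,
                        NumericMatrix events, NumericMatrix mig,
                        int n_loci, double mu_locus, bool condition_one) {
  RNGScope scope;
  const int ndeme = pop_sizes.size();
  std::vector<int> samp(sample_hap.begin(), sample_hap.end());
  std::vector<double> N0(pop_sizes.begin(), pop_sizes.end());

  int n = 0;
  for (int d = 0; d < ndeme; ++d) n += samp[d];
  if (n < 2) stop("need at least 2 sampled haploid genomes");

  std::vector<std::vector<int>> carriers;  // per SNP
  std::vector<int> locus_of;

  std::vector<std::vector<int>> child(2 * n - 1);
  std::vector<double> blen(2 * n - 1);
  std::vector<int> lv;

  Genealogy g;
  for (int loc = 0; loc < n_loci; ++loc) {
    sim_genealogy(g, samp, N0, events, mig);
    for (int v = 0; v < 2 * n - 1; ++v) child[v].clear();
    double TL = 0.0;
    for (int v = 0; v < g.root; ++v) {
      child[g.parent[v]].push_back(v);
      blen[v] = g.time[g.parent[v]] - g.time[v];
      TL += blen[v];
    }
    int nmut = condition_one ? 1 : (int)R::rpois(mu_locus * TL);
    for (int m = 0; m < nmut; ++m) {
      double u = unif_rand() * TL;
      int v = 0;
      for (; v < g.root; ++v) { if (u < blen[v]) break; u -= blen[v]; }
      if (v >= g.root) v = g.root - 1;
      leaves_under(g, child, v, lv);
      if ((int)lv.size() == n || lv.empty()) { // non-segregating (shouldn't happen)
        if (condition_one) { --m; continue; }
        else continue;
      }
      carriers.push_back(lv);
      locus_of.push_back(loc + 1);
    }
  }

  const int S = (int)carriers.size();
  IntegerMatrix geno(n, S);
  for (int s = 0; s < S; ++s)
    for (size_t i = 0; i < carriers[s].size(); ++i)
      geno(carriers[s][i], s) = 1;
  return List::create(_["haplotypes"] = geno,
                      _["locus"] = IntegerVector(locus_of.begin(), locus_of.end()));
}

// Mean branch length (same time units as pop_sizes' generations) subtending
// each (i demes[0]-leaves, j demes[1]-leaves) class, averaged over n_reps
// independent genealogies.  With one sampled deme returns an (n+1) x 1 matrix.
// [[Rcpp::export]]
NumericMatrix cpp_branch_spectrum(IntegerVector sample_hap, NumericVector pop_sizes,
                                  NumericMatrix events, NumericMatrix mig,
                                  int n_reps) {
  RNGScope scope;
  const int ndeme = pop_sizes.size();
  std::vector<int> samp(sample_hap.begin(), sample_hap.end());
  std::vector<double> N0(pop_sizes.begin(), pop_sizes.end());

  // leaf group: 0 for the first deme with samples, 1 for the second
  std::vector<int> grp_of_deme(ndeme, -1);
  int ngrp = 0;
  for (int d = 0; d < ndeme; ++d)
    if (samp[d] > 0) grp_of_deme[d] = ngrp++;
  if (ngrp < 1 || ngrp > 2) stop("branch spectrum supports 1 or 2 sampled demes");

  int n = 0, n1 = 0, n2 = 0;
  for (int d = 0; d < ndeme; ++d) {
    n += samp[d];
    if (grp_of_deme[d] == 0) n1 += samp[d];
    if (grp_of_deme[d] == 1) n2 += samp[d];
  }
  NumericMatrix spec(n1 + 1, n2 + 1);
  std::vector<int> c1(2 * n - 1), c2(2 * n - 1);

  Genealogy g;
  for (int rep = 0; rep < n_reps; ++rep) {
    sim_genealogy(g, samp, N0, events, mig);
    std::fill(c1.begin(), c1.end(), 0);
    std::fill(c2.begin(), c2.end(), 0);
    {
      int id = 0;
      for (int d = 0; d < ndeme; ++d)
        for (int k = 0; k < samp[d]; ++k) {
          if (grp_of_deme[d] == 0) c1[id] = 1; else c2[id] = 1;
          ++id;
        }
    }
    // node ids are in increasing time order, so one ascending pass suffices
    for (int v = 0; v < g.root; ++v) {
      double len = g.time[g.parent[v]] - g.time[v];
      spec(c1[v], c2[v]) += len;
      c1[g.parent[v]] += c1[v];
      c2[g.parent[v]] += c2[v];
    }
  }
  for (int i = 0; i < spec.nrow() * spec.ncol(); ++i) spec[i] /= n_reps;
  return spec;
}
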