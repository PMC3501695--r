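#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured-coalescent simulator for a one-dimensional stepping stone of
// n_demes demes split into two halves by a barrier that is closed (no
// migration across) more recently than tau.
//
// Time is measured in units of 4N generations (the ms convention): the
// pairwise coalescence rate within a deme is 2 and the per-lineage migration
// rate to each open adjacent deme is mig (mig = 4Nm/2 under the
// Kimura-Weiss convention where m is a deme's total migrant fraction,
// half exchanged with each neighbour).
//
// Each site is an independent coalescent tree carrying exactly one mutation
// dropped uniformly on the total branch length (the ms "-s 1" device), so
// every site segregates in the sample of haplotypes. Uses R's RNG, so
// results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix sim_stepping_stone_cpp(int n_demes, double mig, double tau,
                                     int samples_per_deme, int n_snps,
                                     int ploidy) {
  if (n_demes < 2 || n_demes % 2 != 0)
    stop("n_demes must be an even number >= 2");
  if (samples_per_deme < 1 || n_snps < 1 || ploidy < 1)
    stop("samples_per_deme, n_snps and ploidy must be >= 1");
  if (mig <= 0.0) stop("migration rate must be positive");

  const int n_ind = n_demes * samples_per_deme;
  const int n_lin0 = ploidy * n_ind;
  const int barrier = n_demes / 2;   // demes [0,barrier) vs [barrier,n_demes)
  const int max_nodes = 2 * n_lin0 - 1;

  IntegerMatrix G(n_ind, n_snps);

  std::vector<int> deme_of(n_lin0), node_of(n_lin0), pos_in_deme(n_lin0);
  std::vector<std::vector<int>> slots(n_demes);
  std::vector<double> node_time(max_nodes), blen(max_nodes);
  std::vector<int> parent(max_nodes), child1(max_nodes), child2(max_nodes);
  std::vector<int> stack; stack.reserve(max_nodes);
  std::vector<char> hap(n_lin0);

  RNGScope scope;

  for (int s = 0; s < n_snps; ++s) {
    for (int d = 0; d < n_demes; ++d) slots[d].clear();
    int lin = 0;
    for (int d = 0; d < n_demes; ++d)
      for (int k = 0; k < ploidy * samples_per_deme; ++k) {
        deme_of[lin] = d; node_of[lin] = lin;
        pos_in_deme[lin] = (int)slots[d].size();
        slots[d].push_back(lin);
        ++lin;
      }
    int n_live = n_lin0;
    int next_node = n_lin0;
    for (int v = 0; v < max_nodes; ++v) parent[v] = -1;
    for (int v = 0; v < n_lin0; ++v) node_time[v] = 0.0;

    double t = 0.0;
    bool open = (tau <= 0.0);
    double sum_k2 = 0.0;               // sum over demes of k(k-1)
    for (int d = 0; d < n_demes; ++d) {
      double k = (double)slots[d].size();
      sum_k2 += k * (k - 1.0);
    }

    while (n_live > 1) {
      double Rc = sum_k2;              // total coalescence rate (pair rate 2)
      double Rm = 2.0 * mig * n_live;  // migration attempts; edges/barrier reject
      double R = Rc + Rm;
      double dt = ::Rf_rexp(1.0) / R;
      if (!open && t + dt >= tau) { t = tau; open = true; continue; }
      t += dt;
      if (::unif_rand() * R < Rm) {
        int a = (int)(::unif_rand() * n_live); if (a >= n_live) a = n_live - 1;
        int d = deme_of[a];
        int nd = d + ((::unif_rand() < 0.5) ? -1 : 1);
        if (nd < 0 || nd >= n_demes) continue;
        if (!open && ((d == barrier - 1 && nd == barrier) ||
                      (d == barrier && nd == barrier - 1))) continue;
        int kd = (int)slots[d].size();
        int p = pos_in_deme[a];
        int last = slots[d][kd - 1];
        slots[d][p] = last; pos_in_deme[last] = p; slots[d].pop_back();
        int knd = (int)slots[nd].size();
        pos_in_deme[a] = knd; slots[nd].push_back(a); deme_of[a] = nd;
        sum_k2 += -2.0 * (kd - 1) + 2.0 * knd;
      } else {
        // choose deme proportional to k(k-1), then an unordered pair in it
        double u = ::unif_rand() * sum_k2, acc = 0.0;
        int d = n_demes - 1;
        for (int j = 0; j < n_demes; ++j) {
          double k = (double)slots[j].size();
          acc += k * (k - 1.0);
          if (u < acc) { d = j; break; }
        }
        int kd = (int)slots[d].size();
        if (kd < 2) continue;          // guard against rounding at the boundary
        int ia = (int)(::unif_rand() * kd); if (ia >= kd) ia = kd - 1;
        int ib = (int)(::unif_rand() * (kd - 1)); if (ib >= kd - 1) ib = kd - 2;
        if (ib >= ia) ++ib;
        int a = slots[d][ia], b = slots[d][ib];
        int v = next_node++;
        node_time[v] = t;
        child1[v] = node_of[a]; child2[v] = node_of[b];
        parent[node_of[a]] = v; parent[node_of[b]] = v;
        blen[node_of[a]] = t - node_time[node_of[a]];
        blen[node_of[b]] = t - node_time[node_of[b]];
        node_of[a] = v;
        int pb = pos_in_deme[b];
        int last = slots[d][kd - 1];
        slots[d][pb] = last; pos_in_deme[last] = pb; slots[d].pop_back();
        int m = n_live - 1;            // compact the flat lineage arrays
        if (b != m) {
          deme_of[b] = deme_of[m]; node_of[b] = node_of[m];
          pos_in_deme[b] = pos_in_deme[m];
          slots[deme_of[m]][pos_in_deme[m]] = b;
        }
        --n_live;
        sum_k2 -= 2.0 * (kd - 1);
      }
    }

    // one mutation, uniform on total branch length (root branch excluded)
    double total = 0.0;
    for (int v = 0; v < next_node; ++v) if (parent[v] >= 0) total += blen[v];
    double u = ::unif_rand() * total, acc = 0.0;
    int mut = -1;
    for (int v = 0; v < next_node; ++v) {
      if (parent[v] < 0) continue;
      acc += blen[v];
      if (u < acc) { mut = v; break; }
    }
    if (mut < 0) mut = 0;              // numerical fallback, P -> 0
    std::fill(hap.begin(), hap.end(), 0);
    stack.clear(); stack.push_back(mut);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v < n_lin0) { hap[v] = 1; continue; }
      stack.push_back(child1[v]); stack.push_back(child2[v]);
    }
    for (int i = 0; i < n_ind; ++i) {
      int gi = 0;
      for (int p = 0; p < ploidy; ++p) gi += hap[ploidy * i + p];
      G(i, s) = gi;
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return G;
}
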