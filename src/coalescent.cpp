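// Structured-coalescent core: two contemporary demes with backwards-in-time
// migration, a divergence time at which lineages merge into a single
// ancestral deme, and piecewise-constant ancestral sizes.  Sizes are HAPLOID
// lineage counts throughout: a pair of lineages sharing a deme of haploid
// size N coalesces at rate 1/N per generation.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Model {
  double N1, N2;      // contemporary haploid sizes (deme 1, deme 2)
  double m12, m21;    // backwards migration: lineage in deme i jumps to j
  double Tdiv;        // generations before present; 0 = single deme
  std::vector<double> ancN;  // ancestral sizes, first applies from Tdiv
  std::vector<double> ancT;  // size-change times (> Tdiv), increasing
};

struct Lineage {
  int node;
  int deme;
  int d1, d2;    // descendant leaves per deme
  double birth;  // time the lineage appeared (0 for leaves)
};

const long MAX_EVENTS = 4000000;

// Simulate one genealogy.  parent/ntime are 0-based arrays over 2n-1 nodes
// (leaves 0..n-1: deme-1 leaves first).  If tally != NULL, each lineage's
// lifetime is accrued into tally(d1, d2); a lineage's descendant
// configuration is fixed from birth to its own coalescence, so one update
// at the merge suffices.
void sim_one(const Model& M, int n1, int n2,
             std::vector<int>& parent, std::vector<double>& ntime,
             NumericMatrix* tally) {
  const int n = n1 + n2;
  parent.assign(2 * n - 1, -1);
  ntime.assign(2 * n - 1, 0.0);
  static std::vector<Lineage> act;
  static std::vector<int> idx;
  act.clear();
  act.reserve(n);
  for (int i = 0; i < n1; ++i) act.push_back({i, 0, 1, 0, 0.0});
  for (int j = 0; j < n2; ++j) act.push_back({n1 + j, 1, 0, 1, 0.0});
  int next_node = n;
  int k1 = n1, k2 = n2;
  double t = 0.0;
  long ev = 0;

  while ((int)act.size() > 1) {
    if (++ev > MAX_EVENTS) {
      stop("genealogy failed to coalesce within the event cap (N1=%g, N2=%g, "
           "m12=%g, m21=%g, Tdiv=%g): check that migration connects the demes "
           "before the split or that Tdiv is finite", M.N1, M.N2, M.m12,
           M.m21, M.Tdiv);
    }
    const int k = (int)act.size();
    double c1 = 0, c2 = 0, mig1 = 0, mig2 = 0, coalA = 0, boundary;
    const bool split_phase = (t < M.Tdiv);
    if (split_phase) {
      c1 = k1 * (k1 - 1.0) / (2.0 * M.N1);
      c2 = k2 * (k2 - 1.0) / (2.0 * M.N2);
      mig1 = k1 * M.m12;
      mig2 = k2 * M.m21;
      boundary = M.Tdiv;
    } else {
      size_t e = 0;
      while (e < M.ancT.size() && t >= M.ancT[e]) ++e;
      coalA = k * (k - 1.0) / (2.0 * M.ancN[e]);
      boundary = (e < M.ancT.size()) ? M.ancT[e] : R_PosInf;
    }
    const double Rtot = c1 + c2 + mig1 + mig2 + coalA;
    double dt;
    bool hit_boundary = false;
    if (Rtot <= 0) {
      if (!R_finite(boundary)) {
        stop("total event rate is zero with no upcoming epoch boundary "
             "(N1=%g, N2=%g, m12=%g, m21=%g, Tdiv=%g)", M.N1, M.N2, M.m12,
             M.m21, M.Tdiv);
      }
      dt = boundary - t;
      hit_boundary = true;
    } else {
      dt = R::exp_rand() / Rtot;
      if (R_finite(boundary) && t + dt >= boundary) {
        dt = boundary - t;
        hit_boundary = true;
      }
    }
    t += dt;
    if (hit_boundary) {
      if (split_phase) {
        for (Lineage& L : act) L.deme = 0;  // merge demes at Tdiv
        k1 += k2;
        k2 = 0;
      }
      continue;
    }
    const double u = unif_rand() * Rtot;
    if (u < c1 + c2 + coalA) {
      // coalescence: pick the deme, then a uniform pair within it
      int d = 0;
      if (split_phase && u >= c1) d = 1;
      idx.clear();
      for (int i = 0; i < k; ++i) {
        if (!split_phase || act[i].deme == d) idx.push_back(i);
      }
      const int kk = (int)idx.size();
      int a = (int)(unif_rand() * kk);
      if (a >= kk) a = kk - 1;
      int b = (int)(unif_rand() * (kk - 1));
      if (b >= kk - 1) b = kk - 2;
      if (b >= a) ++b;
      int ia = idx[a], ib = idx[b];
      if (ia > ib) std::swap(ia, ib);
      const int id = next_node++;
      parent[act[ia].node] = id;
      parent[act[ib].node] = id;
      ntime[id] = t;
      if (tally) {
        (*tally)(act[ia].d1, act[ia].d2) += t - act[ia].birth;
        (*tally)(act[ib].d1, act[ib].d2) += t - act[ib].birth;
      }
      Lineage merged = {id, act[ia].deme, act[ia].d1 + act[ib].d1,
                        act[ia].d2 + act[ib].d2, t};
      if (act[ia].deme == 0) --k1; else --k2;
      act[ia] = merged;
      act[ib] = act.back();  // swap-and-pop removal
      act.pop_back();
    } else {
      // migration: move one uniform lineage of the source deme
      const int d = (u < c1 + c2 + coalA + mig1) ? 0 : 1;
      idx.clear();
      for (int i = 0; i < k; ++i) {
        if (act[i].deme == d) idx.push_back(i);
      }
      int a = (int)(unif_rand() * idx.size());
      if (a >= (int)idx.size()) a = (int)idx.size() - 1;
      act[idx[a]].deme = 1 - d;
      if (d == 0) { --k1; ++k2; } else { ++k1; --k2; }
    }
  }
}

Model build_model(double N1, double N2, double m12, double m21, double Tdiv,
                  NumericVector ancN, NumericVector ancT) {
  Model M;
  M.N1 = N1;
  M.N2 = N2;
  M.m12 = m12;
  M.m21 = m21;
  M.Tdiv = Tdiv;
  M.ancN = as<std::vector<double>>(ancN);
  M.ancT = as<std::vector<double>>(ancT);
  if (M.ancN.empty()) stop("at least one ancestral size is required");
  if (M.ancT.size() != M.ancN.size() - 1)
    stop("ancT must have one fewer entry than ancN");
  return M;
}

double total_length(const std::vector<int>& parent,
                    const std::vector<double>& ntime) {
  double L = 0;
  for (size_t i = 0; i < parent.size(); ++i) {
    if (parent[i] >= 0) L += ntime[parent[i]] - ntime[i];
  }
  return L;
}

}  // namespace

// Expected-branch-length tally over descendant configurations (i, j):
// accumulated length (generations) of branches subtending i deme-1 and j
// deme-2 leaves, summed over n_trees independent genealogies.  Dividing by
// the grand total gives infinite-sites SNP cell probabilities conditioned on
// polymorphism.
// [[Rcpp::export]]
NumericMatrix cpp_sfs_branch_tally(int n1, int n2, double N1, double N2,
                                   double m12, double m21, double Tdiv,
                                   NumericVector ancN, NumericVector ancT,
                                   int n_trees) {
  Model M = build_model(N1, N2, m12, m21, Tdiv, ancN, ancT);
  NumericMatrix tally(n1 + 1, n2 + 1);
  std::vector<int> parent;
  std::vector<double> ntime;
  for (int r = 0; r < n_trees; ++r) {
    sim_one(M, n1, n2, parent, ntime, &tally);
  }
  return tally;
}

// Full genealogies: per tree, 1-based parent pointers, node times
// (generations before present; leaves at 0), and leaf deme labels.
// [[Rcpp::export]]
List cpp_sim_trees(int n1, int n2, double N1, double N2, double m12,
                   double m21, double Tdiv, NumericVector ancN,
                   NumericVector ancT, int n_trees) {
  Model M = build_model(N1, N2, m12, m21, Tdiv, ancN, ancT);
  List out(n_trees);
  std::vector<int> parent;
  std::vector<double> ntime;
  IntegerVector leaf_deme(n1 + n2);
  for (int i = 0; i < n1; ++i) leaf_deme[i] = 1;
  for (int j = 0; j < n2; ++j) leaf_deme[n1 + j] = 2;
  for (int r = 0; r < n_trees; ++r) {
    sim_one(M, n1, n2, parent, ntime, nullptr);
    const int m = (int)parent.size();
    IntegerVector p(m);
    NumericVector tt(m);
    for (int i = 0; i < m; ++i) {
      p[i] = (parent[i] < 0) ? NA_INTEGER : parent[i] + 1;
      tt[i] = ntime[i];
    }
    out[r] = List::create(_["parent"] = p, _["node_time"] = tt,
                          _["leaf_deme"] = leaf_deme,
                          _["n_leaves"] = n1 + n2,
                          _["total_length"] = total_length(parent, ntime),
                          _["height"] = ntime[m - 1]);
  }
  return out;
}

// Fast path for dataset simulation: genealogy + infinite-sites mutations per
// locus.  mu_len is the per-generation mutation rate for the whole locus
// (per-site rate times locus length).  Returns, per locus, a 0/1 haplotype
// matrix (rows = leaves, columns = segregating sites; 0 columns possible).
// [[Rcpp::export]]
List cpp_sim_snp_loci(int n1, int n2, double N1, double N2, double m12,
                      double m21, double Tdiv, NumericVector ancN,
                      NumericVector ancT, int n_loci, double mu_len) {
  Model M = build_model(N1, N2, m12, m21, Tdiv, ancN, ancT);
  const int n = n1 + n2;
  List out(n_loci);
  std::vector<int> parent;
  std::vector<double> ntime;
  for (int r = 0; r < n_loci; ++r) {
    sim_one(M, n1, n2, parent, ntime, nullptr);
    const int m = (int)parent.size();
    const double L = total_length(parent, ntime);
    const int S = (int)R::rpois(mu_len * L);
    IntegerMatrix G(n, S);
    if (S > 0) {
      // cumulative branch lengths over non-root nodes
      std::vector<double> cum(m, 0.0);
      double acc = 0;
      for (int i = 0; i < m; ++i) {
        if (parent[i] >= 0) acc += ntime[parent[i]] - ntime[i];
        cum[i] = acc;
      }
      // children lists for descendant retrieval
      std::vector<std::vector<int>> kids(m);
      for (int i = 0; i < m; ++i) {
        if (parent[i] >= 0) kids[parent[i]].push_back(i);
      }
      std::vector<int> stack;
      for (int s = 0; s < S; ++s) {
        const double u = unif_rand() * acc;
        int node = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                         cum.begin());
        if (node >= m) node = m - 1;
        stack.clear();
        stack.push_back(node);
        while (!stack.empty()) {
          const int v = stack.back();
          stack.pop_back();
          if (v < n) {
            G(v, s) = 1;
          } else {
            for (int c : kids[v]) stack.push_back(c);
          }
        }
      }
    }
    out[r] = G;
  }
  return out;
}
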