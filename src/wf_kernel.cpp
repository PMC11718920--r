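#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// Forward Wright-Fisher core. Haplotypes are integer vectors of derived
// mutation positions (unordered). All randomness goes through R's RNG, so
// set.seed() in R governs reproducibility. Generations are absolute indices
// (gen0 .. gen0 + n_gens - 1): the sweep mutation is injected after
// reproduction at generation sweep_start, and fixed mutations are purged on
// a fixed absolute cadence so phased restarts stay consistent.
// Returns R_NilValue if the selected allele is lost.
// [[Rcpp::export]]
SEXP wf_evolve_cpp(List pop_in, LogicalVector occupied_in, int gen0,
                   int n_gens, int n_diploids, int seq_length,
                   double mu, double rho, double s, double h,
                   int sweep_pos, int sweep_start, bool select) {
  const int n_hap = 2 * n_diploids;
  std::vector<std::vector<int>> pop(n_hap), newpop(n_hap);
  for (int i = 0; i < n_hap; ++i) {
    IntegerVector v = pop_in[i];
    pop[i].assign(v.begin(), v.end());
  }
  std::vector<char> occupied(occupied_in.begin(), occupied_in.end());

  const double mut_rate = (double)n_hap * mu * seq_length;
  const double rec_mean = rho * seq_length;
  std::vector<double> cw(n_diploids);
  std::vector<double> bp;

  for (int gi = 0; gi < n_gens; ++gi) {
    const int gen = gen0 + gi;

    // cumulative fitness over diploids
    double tot = 0.0;
    for (int d = 0; d < n_diploids; ++d) {
      double w = 1.0;
      if (select) {
        int g = 0;
        for (int c = 0; c < 2; ++c) {
          const std::vector<int>& hh = pop[2 * d + c];
          if (std::find(hh.begin(), hh.end(), sweep_pos) != hh.end()) ++g;
        }
        if (g == 1) w = 1.0 + h * s;
        else if (g == 2) w = 1.0 + s;
      }
      tot += w;
      cw[d] = tot;
    }

    for (int i = 0; i < n_hap; ++i) {
      // weighted parent choice
      const double u = unif_rand() * tot;
      const int pa = (int)(std::upper_bound(cw.begin(), cw.end(), u) -
                           cw.begin());
      const std::vector<int>& h1 = pop[2 * pa];
      const std::vector<int>& h2 = pop[2 * pa + 1];
      const int k = (int)R::rpois(rec_mean);
      std::vector<int>& gam = newpop[i];
      gam.clear();
      if (k == 0) {
        gam = (unif_rand() < 0.5) ? h1 : h2;
      } else {
        bp.resize(k);
        for (int b = 0; b < k; ++b) bp[b] = unif_rand() * seq_length;
        std::sort(bp.begin(), bp.end());
        const int phase = (unif_rand() < 0.5) ? 0 : 1;
        for (size_t t = 0; t < h1.size(); ++t) {
          const int seg = (int)(std::upper_bound(bp.begin(), bp.end(),
                                                 (double)h1[t]) - bp.begin());
          if (seg % 2 == phase) gam.push_back(h1[t]);
        }
        for (size_t t = 0; t < h2.size(); ++t) {
          const int seg = (int)(std::upper_bound(bp.begin(), bp.end(),
                                                 (double)h2[t]) - bp.begin());
          if (seg % 2 != phase) gam.push_back(h2[t]);
        }
      }
    }

    // new mutations at unoccupied uniform positions (infinite sites)
    const int n_new = (int)R::rpois(mut_rate);
    for (int t = 0; t < n_new; ++t) {
      int posn;
      do {
        posn = 1 + (int)(unif_rand() * seq_length);
        if (posn > seq_length) posn = seq_length;
      } while (occupied[posn - 1]);
      occupied[posn - 1] = 1;
      const int who = (int)(unif_rand() * n_hap);
      newpop[who < n_hap ? who : n_hap - 1].push_back(posn);
    }

    if (select && gen == sweep_start) {
      const int i0 = (int)(unif_rand() * n_hap);
      newpop[i0 < n_hap ? i0 : n_hap - 1].push_back(sweep_pos);
    }

    pop.swap(newpop);

    if (select && gen >= sweep_start) {
      int nc = 0;
      for (int i = 0; i < n_hap; ++i)
        if (std::find(pop[i].begin(), pop[i].end(), sweep_pos) != pop[i].end())
          ++nc;
      if (nc == 0) return R_NilValue;           // lost: caller retries
    }

    if (gen % 25 == 0 || gi == n_gens - 1) {
      std::unordered_map<int, int> cnt;
      for (int i = 0; i < n_hap; ++i)
        for (size_t t = 0; t < pop[i].size(); ++t) cnt[pop[i][t]]++;
      for (int i = 0; i < n_hap; ++i) {
        std::vector<int>& hh = pop[i];
        hh.erase(std::remove_if(hh.begin(), hh.end(), [&](int m) {
          return cnt[m] == n_hap && m != sweep_pos;
        }), hh.end());
      }
    }
  }

  List pop_out(n_hap);
  for (int i = 0; i < n_hap; ++i)
    pop_out[i] = IntegerVector(pop[i].begin(), pop[i].end());
  return List::create(_["pop"] = pop_out,
                      _["occupied"] = LogicalVector(occupied.begin(),
                                                    occupied.end()));
}
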