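#include <Rcpp.h>
using namespace Rcpp;

// Walk outward from a core site among carrier haplotypes, refining the
// partition of carriers by their extended haplotype at every step and
// recording EHH = sum_h C(n_h,2) / C(n_c,2). Missing alleles put their
// haplotype into a singleton group from that site on. Stops below the EHH
// cutoff, at the chromosome end, at an inter-site gap > max_gap, or once
// the extension exceeds max_extend bp from the core.
// status: 0 = chrom_end, 1 = cutoff, 2 = gap, 3 = max_extend.
// [[Rcpp::export(rng = false)]]
List ehh_walk(const IntegerMatrix& A, const IntegerVector& carriers,
              int core, int dir, const NumericVector& pos,
              double cutoff, double max_gap, double max_extend) {
  const int nc = carriers.size();
  const int m = A.ncol();
  const long long base = nc + 3;
  const double denom = (double)nc * (nc - 1) / 2.0;

  std::vector<int> gid(nc, 0), cnt(nc, 0);
  // stamped key -> new-group-id table; keys fit in nc * base slots
  std::vector<long long> slot_stamp((size_t)nc * base, -1);
  std::vector<int> slot_id((size_t)nc * base, 0);
  std::vector<double> dist(1, 0.0), val(1, 1.0);
  int status = 0;
  int j = core - 1;
  const int last = (dir > 0) ? m - 1 : 0;
  const double corepos = pos[core - 1];
  long long stamp = 0;

  while (j != last) {
    const int nxt = j + dir;
    if (std::abs(pos[nxt] - pos[j]) > max_gap) { status = 2; break; }
    if (std::abs(pos[nxt] - corepos) > max_extend) { status = 3; break; }
    j = nxt;
    ++stamp;
    int ngroups = 0;
    for (int i = 0; i < nc; ++i) {
      const int a = A(carriers[i] - 1, j);
      const long long code = (a == NA_INTEGER) ? (long long)(3 + i) : a;
      const size_t key = (size_t)gid[i] * base + code;
      if (slot_stamp[key] != stamp) {
        slot_stamp[key] = stamp;
        slot_id[key] = ngroups++;
      }
      gid[i] = slot_id[key];
    }
    std::fill(cnt.begin(), cnt.begin() + ngroups, 0);
    for (int i = 0; i < nc; ++i) cnt[gid[i]]++;
    double s = 0.0;
    for (int g = 0; g < ngroups; ++g)
      s += (double)cnt[g] * (cnt[g] - 1) / 2.0;
    const double e = s / denom;
    dist.push_back(std::abs(pos[j] - corepos));
    val.push_back(e);
    if (e < cutoff) { status = 1; break; }
  }
  return List::create(_["distance_bp"] = dist, _["ehh"] = val,
                      _["status"] = status);
}
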