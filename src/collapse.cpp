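#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapse per-site direction calls into regions.
//
// dirs: one entry per classifiable site in positional order on one
// chromosome; 0 = not qualifying, 1 = maternal-methylated qualifying,
// 2 = paternal-methylated qualifying.
//
// Regions are maximal runs of same-direction qualifying sites. When
// merge_single_discordant is true, two same-direction regions separated by
// exactly one classifiable site (non-qualifying, or a lone qualifying site
// of the opposite direction) are combined, left to right, until no merge
// applies; the intervening discordant site is absorbed into the region span
// but never counts toward n_sites. A lone opposite-direction site consumed
// as a separator does not surface as a region of its own.
//
// Returns a list with:
//   region:  integer vector, per input site, region id (1-based) of the
//            region the site is a *member* of, 0 otherwise
//   first:   per region, index (1-based) of first member site
//   last:    per region, index of last member site
//   dir:     per region, 1 or 2
//   n_sites: per region, number of member (qualifying, same-direction) sites
// [[Rcpp::export]]
List collapse_runs_cpp(IntegerVector dirs, bool merge_single_discordant) {
  const int n = dirs.size();
  struct Run { int s, e, dir; std::vector<std::pair<int,int>> segs; };
  std::vector<Run> runs;

  for (int i = 0; i < n; ) {
    int d = dirs[i];
    if (d == 1 || d == 2) {
      int j = i;
      while (j + 1 < n && dirs[j + 1] == d) ++j;
      Run r; r.s = i; r.e = j; r.dir = d;
      r.segs.push_back(std::make_pair(i, j));
      runs.push_back(r);
      i = j + 1;
    } else {
      ++i;
    }
  }

  if (merge_single_discordant) {
    size_t i = 0;
    while (runs.size() > 1 && i + 1 < runs.size()) {
      Run &a = runs[i];
      Run &b = runs[i + 1];
      if (b.dir == a.dir && b.s - a.e == 2) {
        // one non-qualifying site strictly between
        a.e = b.e;
        a.segs.insert(a.segs.end(), b.segs.begin(), b.segs.end());
        runs.erase(runs.begin() + i + 1);
        continue; // re-check the grown region against its new neighbour
      }
      if (i + 2 < runs.size()) {
        Run &c = runs[i + 2];
        if (c.dir == a.dir && b.dir != a.dir && b.s == b.e &&
            c.s - a.e == 2) {
          // lone opposite-direction site is the single separator; absorb it
          a.e = c.e;
          a.segs.insert(a.segs.end(), c.segs.begin(), c.segs.end());
          runs.erase(runs.begin() + i + 1, runs.begin() + i + 3);
          continue;
        }
      }
      ++i;
    }
  }

  const int nr = (int) runs.size();
  IntegerVector region(n, 0), first(nr), last(nr), dir(nr), n_sites(nr);
  for (int r = 0; r < nr; ++r) {
    const Run &run = runs[r];
    first[r] = run.s + 1;
    last[r] = run.e + 1;
    dir[r] = run.dir;
    int cnt = 0;
    for (size_t k = 0; k < run.segs.size(); ++k) {
      for (int idx = run.segs[k].first; idx <= run.segs[k].second; ++idx) {
        region[idx] = r + 1;
        ++cnt;
      }
    }
    n_sites[r] = cnt;
  }
  return List::create(_["region"] = region, _["first"] = first,
                      _["last"] = last, _["dir"] = dir,
                      _["n_sites"] = n_sites);
}
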