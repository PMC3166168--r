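#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Checkerboard swap chain on a group-by-individual matrix.
//
// Each proposal picks a first row uniformly; the second row is picked
// uniformly among the other rows of the same block (sampling period or
// study day; block < 0 disables the restriction and any other row may be
// drawn). Two distinct columns are then picked uniformly. If the 2x2
// submatrix is a checkerboard ([[1,0],[0,1]] or [[0,1],[1,0]]) it is
// flipped -- for same-period rows this exchanges two individuals between
// two groups of one scan. Row and column sums are invariant under every
// proposal.
//
// When count_successes is true the chain runs until n_flips checkerboards
// have actually been flipped (up to a generous attempt cap); otherwise
// n_flips proposals are made regardless of success. Uses R's RNG so
// seeded runs are reproducible from R.
// [[Rcpp::export(name = ".swap_chain_cpp")]]
List swap_chain_cpp(IntegerMatrix gbi, IntegerVector block, int n_flips,
                    bool count_successes) {
  IntegerMatrix m = clone(gbi);
  const int nr = m.nrow(), nc = m.ncol();
  long successes = 0, attempts = 0;
  if (nr < 2 || nc < 2)
    return List::create(_["gbi"] = m, _["successes"] = 0, _["attempts"] = 0);

  const bool restricted = block[0] >= 0;
  // rows of each block, for the restricted second-row draw
  std::vector<std::vector<int> > rows_of;
  std::vector<int> bidx(nr, 0);
  if (restricted) {
    int nb = 0;
    std::map<int, int> seen;
    for (int r = 0; r < nr; ++r) {
      std::map<int, int>::iterator it = seen.find(block[r]);
      if (it == seen.end()) { seen[block[r]] = nb; bidx[r] = nb; ++nb; }
      else bidx[r] = it->second;
    }
    rows_of.resize(nb);
    for (int r = 0; r < nr; ++r) rows_of[bidx[r]].push_back(r);
  }

  const long target = n_flips;
  const long cap = count_successes ? 20000L * (long)n_flips : (long)n_flips;
  while (attempts < cap) {
    ++attempts;
    if (!count_successes && attempts > target) break;
    int r1 = (int)(unif_rand() * nr);
    int r2;
    if (restricted) {
      const std::vector<int>& peers = rows_of[bidx[r1]];
      const int np = (int)peers.size();
      if (np < 2) continue;
      // uniform among peers excluding r1 (r1's slot maps to the last peer)
      int k = (int)(unif_rand() * (np - 1));
      r2 = peers[k];
      if (r2 == r1) r2 = peers[np - 1];
    } else {
      r2 = (int)(unif_rand() * (nr - 1));
      if (r2 >= r1) ++r2;
    }
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) ++c2;
    const int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
    if ((a == 1 && d == 1 && b == 0 && c == 0) ||
        (a == 0 && d == 0 && b == 1 && c == 1)) {
      m(r1, c1) = 1 - a;
      m(r1, c2) = 1 - b;
      m(r2, c1) = 1 - c;
      m(r2, c2) = 1 - d;
      ++successes;
      if (count_successes && successes >= target) break;
    }
  }
  return List::create(_["gbi"] = m, _["successes"] = (double)successes,
                      _["attempts"] = (double)attempts);
}
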