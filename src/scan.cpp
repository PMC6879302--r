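#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Maximal perfect tandem runs of `unit` in each sequence.
//
// A window of width u = |unit| at offset i "matches" when seq[i, i+u) equals
// some cyclic rotation of unit. A run is a maximal stretch of consecutive
// matching windows [a, c]; it spans [a, c + u) in the sequence, which covers
// leading/trailing partial copies at either end (any window inside a periodic
// stretch is itself a rotation). copies = floor(span / u): complete copies
// only. Characters outside ACGT (including N) never match.
//
// Coordinates returned 1-based inclusive.
// [[Rcpp::export]]
DataFrame scan_runs_cpp(CharacterVector seqs, std::string unit, int min_copies) {
  const int u = (int) unit.size();
  std::vector<std::string> rots;
  for (int r = 0; r < u; ++r)
    rots.push_back(unit.substr(r) + unit.substr(0, r));
  std::sort(rots.begin(), rots.end());
  rots.erase(std::unique(rots.begin(), rots.end()), rots.end());
  const int nrot = (int) rots.size();

  std::vector<int> o_seq, o_start, o_end, o_copies;

  for (int s = 0; s < seqs.size(); ++s) {
    if (seqs[s] == NA_STRING) continue;
    const char *str = CHAR(STRING_ELT(seqs, s));
    const int n = (int) LENGTH(STRING_ELT(seqs, s));
    if (n < u) continue;

    int run_start = -1, last_ok = -2;
    for (int i = 0; i + u <= n; ++i) {
      bool ok = false;
      for (int r = 0; r < nrot && !ok; ++r) {
        const char *rot = rots[r].c_str();
        int j = 0;
        while (j < u && str[i + j] == rot[j]) ++j;
        ok = (j == u);
      }
      if (ok) {
        if (i != last_ok + 1) {
          if (run_start >= 0) {
            int len = last_ok + u - run_start;
            if (len / u >= min_copies) {
              o_seq.push_back(s + 1);
              o_start.push_back(run_start + 1);
              o_end.push_back(last_ok + u);
              o_copies.push_back(len / u);
            }
          }
          run_start = i;
        }
        last_ok = i;
      }
    }
    if (run_start >= 0) {
      int len = last_ok + u - run_start;
      if (len / u >= min_copies) {
        o_seq.push_back(s + 1);
        o_start.push_back(run_start + 1);
        o_end.push_back(last_ok + u);
        o_copies.push_back(len / u);
      }
    }
  }

  return DataFrame::create(_["seq"] = o_seq, _["start"] = o_start,
                           _["end"] = o_end, _["copies"] = o_copies);
}
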