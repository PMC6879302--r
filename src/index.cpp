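#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Exact k-mer index over the forward strand of a genome, plus ungapped
// seed-and-extend alignment with an X-drop rule. Scoring: match +1,
// mismatch -2. Reverse-strand hits come from aligning the reverse
// complement of the query; genomic coordinates are always forward-strand.

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static std::string revcomp_str2(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N'; break;
    }
  }
  return r;
}

class GenomeIndex {
public:
  int k;
  std::vector<std::string> names, seqs;
  double total_len;
  double n_positions;
  // code -> (chrom, pos0)
  std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> kmap;

  GenomeIndex(const std::vector<std::string> &nm,
              const std::vector<std::string> &sq, int k_)
      : k(k_), names(nm), seqs(sq), total_len(0), n_positions(0) {
    for (size_t c = 0; c < seqs.size(); ++c) {
      const std::string &s = seqs[c];
      total_len += (double) s.size();
      if ((int) s.size() < k) continue;
      uint32_t code = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
      int valid = 0;
      for (int i = 0; i < (int) s.size(); ++i) {
        int b = base_code(s[i]);
        if (b < 0) {
          valid = 0;
          code = 0;
          continue;
        }
        code = ((code << 2) | (uint32_t) b) & mask;
        if (++valid >= k) {
          kmap[code].push_back(std::make_pair((int) c, i - k + 1));
          n_positions += 1;
        }
      }
    }
  }
};

// [[Rcpp::export]]
SEXP build_index_cpp(CharacterVector seqs, CharacterVector names, int k) {
  std::vector<std::string> nm, sq;
  for (int i = 0; i < seqs.size(); ++i) {
    nm.push_back(as<std::string>(names[i]));
    sq.push_back(as<std::string>(seqs[i]));
  }
  GenomeIndex *gi = new GenomeIndex(nm, sq, k);
  XPtr<GenomeIndex> ptr(gi, true);
  return ptr;
}

// [[Rcpp::export]]
List index_info_cpp(SEXP ptr) {
  XPtr<GenomeIndex> gi(ptr);
  CharacterVector nm(gi->names.size());
  NumericVector ln(gi->names.size());
  for (size_t i = 0; i < gi->names.size(); ++i) {
    nm[i] = gi->names[i];
    ln[i] = (double) gi->seqs[i].size();
  }
  return List::create(_["k"] = gi->k, _["chrom"] = nm, _["length"] = ln,
                      _["total_len"] = gi->total_len,
                      _["n_positions"] = gi->n_positions);
}

// [[Rcpp::export]]
DataFrame index_lookup_cpp(SEXP ptr, std::string kmer) {
  XPtr<GenomeIndex> gi(ptr);
  std::vector<std::string> chrom;
  std::vector<int> pos;
  if ((int) kmer.size() == gi->k) {
    uint32_t code = 0;
    bool ok = true;
    for (int i = 0; i < gi->k && ok; ++i) {
      int b = base_code(kmer[i]);
      if (b < 0) ok = false;
      else code = (code << 2) | (uint32_t) b;
    }
    if (ok) {
      auto it = gi->kmap.find(code);
      if (it != gi->kmap.end()) {
        for (auto &pc : it->second) {
          chrom.push_back(gi->names[pc.first]);
          pos.push_back(pc.second + 1);  // 1-based
        }
      }
    }
  }
  return DataFrame::create(_["chrom"] = chrom, _["pos"] = pos,
                           _["stringsAsFactors"] = false);
}

struct RawHit {
  int chrom, gstart, gend, qstart, qend;  // 0-based half-open
  int matches, mismatches, score, strand; // strand 0 '+', 1 '-'
};

// extend a seed (qp, gp, length k exact) ungapped both ways with X-drop
static RawHit extend_seed(const std::string &q, const std::string &g, int qp,
                          int gp, int k, int xdrop) {
  int score = k, best = k;
  // right
  int rbest = 0, cur = 0, step = 0;
  for (int i = 0; qp + k + i < (int) q.size() && gp + k + i < (int) g.size();
       ++i) {
    char cq = q[qp + k + i], cg = g[gp + k + i];
    cur += (cq == cg && cq != 'N') ? 1 : -2;
    ++step;
    if (cur > rbest) { rbest = cur; }
    if (cur < rbest - xdrop) break;
  }
  // find extent achieving rbest (first time it is reached)
  int rext = 0;
  cur = 0;
  for (int i = 0; i < step && rext == 0 && rbest > 0; ++i) {
    char cq = q[qp + k + i], cg = g[gp + k + i];
    cur += (cq == cg && cq != 'N') ? 1 : -2;
    if (cur == rbest) rext = i + 1;
  }
  // left
  int lbest = 0;
  cur = 0;
  step = 0;
  for (int i = 1; qp - i >= 0 && gp - i >= 0; ++i) {
    char cq = q[qp - i], cg = g[gp - i];
    cur += (cq == cg && cq != 'N') ? 1 : -2;
    ++step;
    if (cur > lbest) lbest = cur;
    if (cur < lbest - xdrop) break;
  }
  int lext = 0;
  cur = 0;
  for (int i = 1; i <= step && lext == 0 && lbest > 0; ++i) {
    char cq = q[qp - i], cg = g[gp - i];
    cur += (cq == cg && cq != 'N') ? 1 : -2;
    if (cur == lbest) lext = i;
  }
  RawHit h;
  h.qstart = qp - lext;
  h.qend = qp + k + rext;
  h.gstart = gp - lext;
  h.gend = gp + k + rext;
  h.matches = 0;
  h.mismatches = 0;
  for (int i = 0; i < h.qend - h.qstart; ++i) {
    char cq = q[h.qstart + i], cg = g[h.gstart + i];
    if (cq == cg && cq != 'N') ++h.matches;
    else ++h.mismatches;
  }
  h.score = h.matches - 2 * h.mismatches;
  (void) score; (void) best;
  return h;
}

// [[Rcpp::export]]
DataFrame map_seed_extend_cpp(SEXP ptr, std::string query, int xdrop) {
  XPtr<GenomeIndex> gi(ptr);
  const int k = gi->k;
  std::vector<RawHit> hits;
  // best hit per (chrom, strand, diagonal)
  std::map<std::tuple<int, int, int>, int> best_on_diag;

  for (int strand = 0; strand < 2; ++strand) {
    std::string q = strand ? revcomp_str2(query) : query;
    if ((int) q.size() < k) continue;
    uint32_t code = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
    int valid = 0;
    for (int i = 0; i < (int) q.size(); ++i) {
      int b = base_code(q[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t) b) & mask;
      if (++valid < k) continue;
      int qp = i - k + 1;
      auto it = gi->kmap.find(code);
      if (it == gi->kmap.end()) continue;
      for (auto &pc : it->second) {
        int c = pc.first, gp = pc.second;
        std::tuple<int, int, int> key(c, strand, gp - qp);
        auto fit = best_on_diag.find(key);
        if (fit != best_on_diag.end()) {
          const RawHit &prev = hits[fit->second];
          if (qp >= prev.qstart && qp + k <= prev.qend) continue;  // covered
        }
        RawHit h = extend_seed(q, gi->seqs[c], qp, gp, k, xdrop);
        h.chrom = c;
        h.strand = strand;
        if (fit == best_on_diag.end()) {
          hits.push_back(h);
          best_on_diag[key] = (int) hits.size() - 1;
        } else if (h.score > hits[fit->second].score) {
          hits[fit->second] = h;
        }
      }
    }
  }

  // collect the per-diagonal winners
  std::vector<int> keep;
  for (auto &kv : best_on_diag) keep.push_back(kv.second);
  std::sort(keep.begin(), keep.end());

  int nh = (int) keep.size();
  CharacterVector chrom(nh), strand(nh);
  IntegerVector gstart(nh), gend(nh), qstart(nh), qend(nh), matches(nh),
      mismatches(nh), score(nh);
  int qlen = (int) query.size();
  for (int i = 0; i < nh; ++i) {
    const RawHit &h = hits[keep[i]];
    chrom[i] = gi->names[h.chrom];
    strand[i] = h.strand ? "-" : "+";
    gstart[i] = h.gstart + 1;  // 1-based inclusive
    gend[i] = h.gend;
    // report query coords on the forward query
    if (h.strand) {
      qstart[i] = qlen - h.qend + 1;
      qend[i] = qlen - h.qstart;
    } else {
      qstart[i] = h.qstart + 1;
      qend[i] = h.qend;
    }
    matches[i] = h.matches;
    mismatches[i] = h.mismatches;
    score[i] = h.score;
  }
  return DataFrame::create(
      _["chrom"] = chrom, _["start"] = gstart, _["end"] = gend,
      _["strand"] = strand, _["matches"] = matches,
      _["mismatches"] = mismatches, _["score"] = score, _["qstart"] = qstart,
      _["qend"] = qend, _["stringsAsFactors"] = false);
}
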