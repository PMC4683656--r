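// Seed-and-extend unique-read mapper.
//
// Candidate placements are found by exact k-mer seeds taken at three fixed
// offsets of the read (both orientations), then scored by ungapped match
// counting against the reference.  A read is retained only when a single
// best placement exists and its score exceeds the runner-up by at least
// minMargin matching bases -- the in-repo analogue of keeping only unique
// hits above a MAPQ floor.  Windows containing non-ACGT letters (the N
// spacers of the minimal map) are never indexed and never count as matches.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

struct Hit {
  int ref;
  long start;  // 0-based, may run off either reference end
  int strand;  // 0 = forward, 1 = reverse-complement
  bool operator<(const Hit& o) const {
    if (ref != o.ref) return ref < o.ref;
    if (start != o.start) return start < o.start;
    return strand < o.strand;
  }
  bool operator==(const Hit& o) const {
    return ref == o.ref && start == o.start && strand == o.strand;
  }
};

static inline bool acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector refSeqs, CharacterVector reads,
                   CharacterVector readsRC, int k, int minMargin,
                   int maxMismatches) {
  const int nref = refSeqs.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(refSeqs[i]);

  std::unordered_map<std::string, std::vector<std::pair<int, int> > > index;
  index.reserve(1 << 18);
  for (int r = 0; r < nref; ++r) {
    const std::string& s = refs[r];
    const int n = (int)s.size();
    if (n < k) continue;
    int bad = 0;  // non-ACGT letters inside the current window
    for (int i = 0; i < k - 1; ++i) if (!acgt(s[i])) ++bad;
    for (int i = 0; i + k <= n; ++i) {
      if (!acgt(s[i + k - 1])) ++bad;
      if (bad == 0) index[s.substr(i, k)].push_back(std::make_pair(r, i));
      if (!acgt(s[i])) --bad;
    }
  }

  const int nreads = reads.size();
  std::vector<int> outRead, outRef, outStart, outStrand, outScore, outMargin;
  long nDiscarded = 0, nUnseeded = 0;

  for (int i = 0; i < nreads; ++i) {
    const std::string fwd = as<std::string>(reads[i]);
    const std::string rc = as<std::string>(readsRC[i]);
    const int L = (int)fwd.size();
    if (L < k) { ++nUnseeded; continue; }
    int offsets[3] = {0, (L - k) / 2, L - k};

    std::vector<Hit> cand;
    for (int ori = 0; ori < 2; ++ori) {
      const std::string& rs = ori ? rc : fwd;
      for (int oi = 0; oi < 3; ++oi) {
        const int off = offsets[oi];
        std::unordered_map<std::string,
          std::vector<std::pair<int, int> > >::const_iterator it =
            index.find(rs.substr(off, k));
        if (it == index.end()) continue;
        const std::vector<std::pair<int, int> >& places = it->second;
        for (size_t p = 0; p < places.size(); ++p) {
          Hit h;
          h.ref = places[p].first;
          h.start = (long)places[p].second - off;
          h.strand = ori;
          cand.push_back(h);
        }
      }
    }
    if (cand.empty()) { ++nUnseeded; continue; }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    int best = -1, second = 0, bestCount = 0;
    Hit bestHit = cand[0];
    for (size_t c = 0; c < cand.size(); ++c) {
      const Hit& h = cand[c];
      const std::string& rs = h.strand ? rc : fwd;
      const std::string& ref = refs[h.ref];
      const long rlen = (long)ref.size();
      int score = 0;
      for (int j = 0; j < L; ++j) {
        const long p = h.start + j;
        if (p < 0 || p >= rlen) continue;
        if (ref[p] == rs[j] && acgt(rs[j])) ++score;
      }
      if (score > best) {
        second = best < 0 ? 0 : best;
        best = score;
        bestCount = 1;
        bestHit = h;
      } else if (score == best) {
        ++bestCount;
        second = best;
      } else if (score > second) {
        second = score;
      }
      if (bestCount > 1 && best == L) break;  // cannot become unique
    }
    // a retained alignment must be near-perfect over its in-reference
    // span: the uniqueness margin alone cannot reject a moderately
    // diverged placement that happens to have no competitor
    int inBounds = 0;
    if (bestCount == 1) {
      const std::string& ref = refs[bestHit.ref];
      const long rlen = (long)ref.size();
      for (int j = 0; j < L; ++j) {
        const long p = bestHit.start + j;
        if (p >= 0 && p < rlen && acgt(ref[p])) ++inBounds;
      }
    }
    if (bestCount == 1 && best - second >= minMargin &&
        inBounds - best <= maxMismatches) {
      outRead.push_back(i + 1);
      outRef.push_back(bestHit.ref + 1);
      outStart.push_back((int)bestHit.start + 1);
      outStrand.push_back(bestHit.strand);
      outScore.push_back(best);
      outMargin.push_back(best - second);
    } else {
      ++nDiscarded;
    }
  }

  return List::create(
    _["read"] = outRead, _["ref"] = outRef, _["start"] = outStart,
    _["strand"] = outStrand, _["score"] = outScore, _["margin"] = outMargin,
    _["nDiscarded"] = nDiscarded, _["nUnseeded"] = nUnseeded);
}
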