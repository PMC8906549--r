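#include <Rcpp.h>
#include <vector>
#include <string>
#include <cctype>
using namespace Rcpp;

// Semi-global affine-gap alignment of a short barcode against a read prefix:
// the barcode is aligned end-to-end, gaps before/after the aligned read
// segment are free. Cell values are compared lexicographically
// (score desc, match_start asc, matches desc) so the reported alignment is
// deterministic: ties in score resolve to the leftmost start, then to the
// alignment with the most matched bases. A gap of length L costs
// open + (L-1)*extend.

namespace {

struct Cell {
  int score;
  int start;    // read offset where the aligned segment begins
  int matches;  // matched bases accumulated along the path
  int ins;      // read bases inserted against a gap in the barcode
  bool valid;
};

inline bool better(const Cell &a, const Cell &b) {
  if (!b.valid) return a.valid;
  if (!a.valid) return false;
  if (a.score != b.score) return a.score > b.score;
  if (a.start != b.start) return a.start < b.start;
  if (a.matches != b.matches) return a.matches > b.matches;
  return a.ins < b.ins;
}

inline Cell step(const Cell &c, int dscore, int dmatch, int dins = 0) {
  Cell out = c;
  out.score += dscore;
  out.matches += dmatch;
  out.ins += dins;
  return out;
}

} // namespace

// [[Rcpp::export(name = ".semiglobal_align")]]
DataFrame semiglobal_align(CharacterVector reads, std::string barcode,
                           int match, int mismatch, int gap_open,
                           int gap_extend, int window) {
  const int m = barcode.size();
  if (m < 1) stop("barcode must be non-empty");
  std::string bc(barcode);
  for (auto &c : bc) c = std::toupper(static_cast<unsigned char>(c));

  const int nreads = reads.size();
  NumericVector identity(nreads);
  IntegerVector mstart(nreads), mend(nreads), score(nreads), nmatch(nreads);

  const Cell invalid{0, 0, 0, 0, false};

  for (int r = 0; r < nreads; ++r) {
    std::string s = as<std::string>(reads[r]);
    for (auto &c : s) c = std::toupper(static_cast<unsigned char>(c));
    const int n = std::min<int>(s.size(), window);

    // Three-state DP over rows i = 0..m (barcode consumed), cols j = 0..n.
    // M: barcode char aligned to read char; D: gap in read (barcode char
    // deleted); I: gap in barcode (read char inserted).
    std::vector<Cell> Mprev(n + 1), Dprev(n + 1), Iprev(n + 1);
    std::vector<Cell> Mcur(n + 1), Dcur(n + 1), Icur(n + 1);

    for (int j = 0; j <= n; ++j) {
      Mprev[j] = Cell{0, j, 0, 0, true};  // free leading read gap: start at j
      Dprev[j] = invalid;
      Iprev[j] = invalid;
    }

    for (int i = 1; i <= m; ++i) {
      Mcur[0] = invalid;
      Icur[0] = invalid;
      {
        Cell open_ = Mprev[0].valid ? step(Mprev[0], gap_open, 0) : invalid;
        Cell ext_ = Dprev[0].valid ? step(Dprev[0], gap_extend, 0) : invalid;
        Dcur[0] = better(open_, ext_) ? open_ : ext_;
      }
      for (int j = 1; j <= n; ++j) {
        const bool is_match = bc[i - 1] == s[j - 1];
        const int sub = is_match ? match : mismatch;
        const int dm = is_match ? 1 : 0;
        // M from any state at (i-1, j-1)
        Cell best = invalid;
        if (Mprev[j - 1].valid) best = step(Mprev[j - 1], sub, dm);
        if (Dprev[j - 1].valid) {
          Cell c = step(Dprev[j - 1], sub, dm);
          if (better(c, best)) best = c;
        }
        if (Iprev[j - 1].valid) {
          Cell c = step(Iprev[j - 1], sub, dm);
          if (better(c, best)) best = c;
        }
        Mcur[j] = best;
        // D: consume barcode char against a gap
        Cell dbest = invalid;
        if (Mprev[j].valid) dbest = step(Mprev[j], gap_open, 0);
        if (Dprev[j].valid) {
          Cell c = step(Dprev[j], gap_extend, 0);
          if (better(c, dbest)) dbest = c;
        }
        if (Iprev[j].valid) {
          Cell c = step(Iprev[j], gap_open, 0);
          if (better(c, dbest)) dbest = c;
        }
        Dcur[j] = dbest;
        // I: consume read char against a gap in the barcode
        Cell ibest = invalid;
        if (Mcur[j - 1].valid) ibest = step(Mcur[j - 1], gap_open, 0, 1);
        if (Icur[j - 1].valid) {
          Cell c = step(Icur[j - 1], gap_extend, 0, 1);
          if (better(c, ibest)) ibest = c;
        }
        if (Dcur[j - 1].valid) {
          Cell c = step(Dcur[j - 1], gap_open, 0, 1);
          if (better(c, ibest)) ibest = c;
        }
        Icur[j] = ibest;
      }
      std::swap(Mprev, Mcur);
      std::swap(Dprev, Dcur);
      std::swap(Iprev, Icur);
    }

    // Final: barcode fully consumed; trailing read bases are free. An
    // alignment never usefully ends in state I (a penalised insertion
    // adjacent to the free suffix), so the end is the M/D cell; ties keep
    // the smallest end offset (scanned ascending, strict improvement).
    Cell best = invalid;
    int bestj = 0;
    for (int j = 0; j <= n; ++j) {
      if (better(Mprev[j], best)) { best = Mprev[j]; bestj = j; }
      if (better(Dprev[j], best)) { best = Dprev[j]; bestj = j; }
    }
    // identity over alignment columns: barcode length plus read insertions,
    // so gap-heavy alignments cannot inflate identity
    identity[r] = 100.0 * best.matches / (m + best.ins);
    mstart[r] = best.start;
    mend[r] = bestj;
    score[r] = best.score;
    nmatch[r] = best.matches;
  }

  return DataFrame::create(_["identity_pct"] = identity,
                           _["match_start"] = mstart,
                           _["match_end"] = mend,
                           _["score"] = score,
                           _["n_match"] = nmatch);
}
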