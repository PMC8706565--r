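#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Full-length ungapped placement of each read on an ordered reference set,
// keeping the best hit with Hamming distance <= maxMismatch. Tie order:
// fewer mismatches, then smaller start (compared across references), then
// earlier reference. Returns 0 in `ref` for reads with no qualifying hit.
// Coordinates are 0-based half-open.
// [[Rcpp::export(name = ".scanReads")]]
DataFrame scanReads(CharacterVector reads, CharacterVector refs,
                    int maxMismatch) {
  const int n = reads.size(), nref = refs.size();
  std::vector<const char*> refPtr(nref);
  std::vector<int> refLen(nref);
  for (int j = 0; j < nref; ++j) {
    refPtr[j] = CHAR(STRING_ELT(refs, j));
    refLen[j] = std::strlen(refPtr[j]);
  }
  IntegerVector outRef(n), outStart(n), outMM(n);
  for (int i = 0; i < n; ++i) {
    const char* r = CHAR(STRING_ELT(reads, i));
    const int len = std::strlen(r);
    int bestRef = 0, bestStart = -1, bestMM = maxMismatch + 1;
    for (int j = 0; j < nref; ++j) {
      const char* s = refPtr[j];
      const int lastStart = refLen[j] - len;
      for (int st = 0; st <= lastStart; ++st) {
        int mm = 0;
        const char* w = s + st;
        for (int k = 0; k < len; ++k) {
          if (r[k] != w[k] && ++mm > maxMismatch) break;
        }
        // lexicographic (mm, start, ref); refs iterate in order so a
        // later ref never displaces an equal (mm, start)
        if (mm <= maxMismatch &&
            (mm < bestMM || (mm == bestMM && st < bestStart))) {
          bestMM = mm;
          bestStart = st;
          bestRef = j + 1;
        }
      }
    }
    outRef[i] = bestRef;
    outStart[i] = bestRef ? bestStart : NA_INTEGER;
    outMM[i] = bestRef ? bestMM : NA_INTEGER;
  }
  return DataFrame::create(_["ref"] = outRef, _["start0"] = outStart,
                           _["mm"] = outMM);
}

// All qualifying placements of a single read (used by the exported
// single-read operation, which applies the same tie order in R).
// [[Rcpp::export(name = ".scanAllHits")]]
DataFrame scanAllHits(std::string read, CharacterVector refs,
                      int maxMismatch) {
  const int len = read.size(), nref = refs.size();
  const char* r = read.c_str();
  std::vector<int> hRef, hStart, hMM;
  for (int j = 0; j < nref; ++j) {
    const char* s = CHAR(STRING_ELT(refs, j));
    const int lastStart = (int)std::strlen(s) - len;
    for (int st = 0; st <= lastStart; ++st) {
      int mm = 0;
      const char* w = s + st;
      for (int k = 0; k < len; ++k) {
        if (r[k] != w[k] && ++mm > maxMismatch) break;
      }
      if (mm <= maxMismatch) {
        hRef.push_back(j + 1);
        hStart.push_back(st);
        hMM.push_back(mm);
      }
    }
  }
  return DataFrame::create(_["ref"] = wrap(hRef), _["start0"] = wrap(hStart),
                           _["mm"] = wrap(hMM));
}
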