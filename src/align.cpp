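#include <Rcpp.h>
using namespace Rcpp;

// Exact alignment of short reads to pre-miRNA hairpins.
//
// A read aligns at offset `start` (1-based on the precursor) when it splits
// into a templated body carrying at most `maxMismatch` substitutions followed
// by a 3' tail of at most `maxTail` bases. The body is maximal: it is
// extended while the mismatch budget holds and the precursor has sequence
// left, so a non-empty tail either overhangs the precursor 3' end or starts
// with a base that disagrees with the templated continuation. All admissible
// offsets are reported (multi-mapping is resolved later by cross-mapping
// weights). No 5' overhang and no gaps: sRNA reads are precursor substrings
// up to substitutions and terminal additions.

// [[Rcpp::export(name = ".alignReadsCpp")]]
DataFrame alignReadsCpp(CharacterVector reads,
                        CharacterVector precursors,
                        int maxMismatch = 1,
                        int maxTail = 3) {
  std::vector<int> outRead, outPrec, outStart, outBodyLen, outMmPos;
  std::vector<std::string> outMmRef, outMmAlt, outTail;

  std::vector<std::string> precs(precursors.size());
  for (int p = 0; p < precursors.size(); ++p)
    precs[p] = as<std::string>(precursors[p]);

  for (int r = 0; r < reads.size(); ++r) {
    const std::string read = as<std::string>(reads[r]);
    const int L = (int) read.size();
    const int minBody = L - maxTail;
    if (minBody < 1) continue;
    for (size_t p = 0; p < precs.size(); ++p) {
      const std::string& prec = precs[p];
      const int P = (int) prec.size();
      // body needs at least minBody templated bases
      const int maxStart = P - minBody + 1;
      for (int s = 1; s <= maxStart; ++s) {
        int mm = 0, b = 0;
        const int bCap = std::min(L, P - s + 1);
        while (b < bCap) {
          if (read[b] != prec[s - 1 + b]) {
            if (mm == maxMismatch) break;
            ++mm;
          }
          ++b;
        }
        // terminal mismatches belong to the tail, not the body: a 3'
        // non-templated addition must not consume the mismatch budget
        while (b > 0 && read[b - 1] != prec[s - 1 + b - 1]) --b;
        const int tailLen = L - b;
        if (tailLen > maxTail || b == 0) continue;
        // re-locate the (single) surviving body mismatch
        mm = 0;
        int mmPos = -1;
        for (int j = 0; j < b; ++j) {
          if (read[j] != prec[s - 1 + j]) {
            ++mm;
            mmPos = s + j; // 1-based precursor position
          }
        }
        outRead.push_back(r + 1);
        outPrec.push_back((int) p + 1);
        outStart.push_back(s);
        outBodyLen.push_back(b);
        if (mm > 0) {
          outMmPos.push_back(mmPos);
          outMmRef.push_back(std::string(1, prec[mmPos - 1]));
          outMmAlt.push_back(std::string(1, read[mmPos - s]));
        } else {
          outMmPos.push_back(NA_INTEGER);
          outMmRef.push_back("");
          outMmAlt.push_back("");
        }
        outTail.push_back(read.substr(b));
      }
    }
  }

  return DataFrame::create(
    _["readIdx"] = outRead,
    _["precIdx"] = outPrec,
    _["start"] = outStart,
    _["bodyLen"] = outBodyLen,
    _["mmPos"] = outMmPos,
    _["mmRef"] = outMmRef,
    _["mmAlt"] = outMmAlt,
    _["tail"] = outTail,
    _["stringsAsFactors"] = false);
}
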