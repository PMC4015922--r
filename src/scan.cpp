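#include <Rcpp.h>
using namespace Rcpp;

// Encode DNA strings as integer codes A=0,C=1,G=2,T=3, anything else -1.
// [[Rcpp::export]]
List encode_dna(CharacterVector seqs) {
  List out(seqs.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *p = CHAR(STRING_ELT(seqs, s));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, s));
    IntegerVector code(n);
    for (R_xlen_t i = 0; i < n; ++i) {
      switch (p[i]) {
        case 'A': case 'a': code[i] = 0; break;
        case 'C': case 'c': code[i] = 1; break;
        case 'G': case 'g': code[i] = 2; break;
        case 'T': case 't': code[i] = 3; break;
        default: code[i] = -1;
      }
    }
    out[s] = code;
  }
  return out;
}

// Slide a log-odds matrix (4 x w, column-major) over one encoded sequence.
// Returns one score per window start; windows containing a non-ACGT code
// score -Inf. `mat` rows are A,C,G,T.
static void scan_one(const IntegerVector &code, const NumericMatrix &mat,
                     NumericVector &scores) {
  int w = mat.ncol();
  R_xlen_t nwin = code.size() - w + 1;
  for (R_xlen_t i = 0; i < nwin; ++i) {
    double s = 0.0;
    bool ok = true;
    for (int k = 0; k < w; ++k) {
      int b = code[i + k];
      if (b < 0) { ok = false; break; }
      s += mat(b, k);
    }
    scores[i] = ok ? s : R_NegInf;
  }
}

// Scan every sequence on both strands with one motif.
// Returns list(seq = 1-based sequence index, offset = 0-based window start on
// the forward sequence, strand = 0 forward / 1 reverse, score).
// Reverse-strand windows are scored on the reverse complement, implemented by
// scanning with the reverse-complemented matrix. Sequences shorter than the
// motif contribute no windows. Strand is an integer code (not a string):
// the full window set is large and per-element CHARSXP allocation dominates
// the scan otherwise.
// [[Rcpp::export]]
List scan_motif_cpp(List encoded, NumericMatrix logodds, bool both_strands) {
  int w = logodds.ncol();
  NumericMatrix rcmat(4, w);
  for (int k = 0; k < w; ++k)
    for (int b = 0; b < 4; ++b)
      rcmat(3 - b, w - 1 - k) = logodds(b, k);

  R_xlen_t total = 0;
  for (R_xlen_t s = 0; s < encoded.size(); ++s) {
    IntegerVector code = encoded[s];
    if (code.size() >= w) total += (code.size() - w + 1) * (both_strands ? 2 : 1);
  }
  IntegerVector seq_idx(total), offset(total), strand(total);
  NumericVector score(total);
  R_xlen_t pos = 0;
  for (R_xlen_t s = 0; s < encoded.size(); ++s) {
    IntegerVector code = encoded[s];
    if (code.size() < w) continue;
    R_xlen_t nwin = code.size() - w + 1;
    NumericVector fwd(nwin);
    scan_one(code, logodds, fwd);
    for (R_xlen_t i = 0; i < nwin; ++i) {
      seq_idx[pos] = (int)s + 1;
      offset[pos] = (int)i;
      strand[pos] = 0;
      score[pos] = fwd[i];
      ++pos;
    }
    if (both_strands) {
      NumericVector rev(nwin);
      scan_one(code, rcmat, rev);
      for (R_xlen_t i = 0; i < nwin; ++i) {
        seq_idx[pos] = (int)s + 1;
        offset[pos] = (int)i;
        strand[pos] = 1;
        score[pos] = rev[i];
        ++pos;
      }
    }
  }
  return List::create(_["seq"] = seq_idx, _["offset"] = offset,
                      _["strand"] = strand, _["score"] = score);
}
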