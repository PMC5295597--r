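#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ungapped placement of short reads on small references.
// Slides each read (and its reverse complement) over every reference at
// every offset, counting mismatches with early exit beyond max_mm.
// Desk-scale by design: references total <= 1e6 nt, reads 19-29 nt.

static char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export(name = ".match_reads_cpp")]]
List match_reads_cpp(CharacterVector seqs, CharacterVector refs,
                     int max_mm) {
  std::vector<int> out_seq, out_ref, out_start, out_mm;
  std::vector<int> out_strand;  // 0 = plus, 1 = minus
  std::vector<std::string> ref_str(refs.size());
  for (int j = 0; j < refs.size(); ++j) ref_str[j] = as<std::string>(refs[j]);

  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int len = (int)s.size();
    std::string rc(len, 'N');
    for (int k = 0; k < len; ++k) rc[k] = comp(s[len - 1 - k]);
    for (int j = 0; j < (int)ref_str.size(); ++j) {
      const std::string &R = ref_str[j];
      int L = (int)R.size();
      for (int strand = 0; strand < 2; ++strand) {
        const std::string &p = strand == 0 ? s : rc;
        for (int off = 0; off + len <= L; ++off) {
          int mm = 0;
          for (int k = 0; k < len; ++k) {
            if (R[off + k] != p[k] && ++mm > max_mm) break;
          }
          if (mm <= max_mm) {
            out_seq.push_back(i + 1);
            out_ref.push_back(j + 1);
            out_start.push_back(off);
            out_strand.push_back(strand);
            out_mm.push_back(mm);
          }
        }
      }
    }
  }
  return List::create(_["seq_idx"] = wrap(out_seq),
                      _["ref_idx"] = wrap(out_ref),
                      _["start"] = wrap(out_start),
                      _["strand"] = wrap(out_strand),
                      _["mismatches"] = wrap(out_mm));
}
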