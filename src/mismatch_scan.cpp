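#include <Rcpp.h>
using namespace Rcpp;

// Scan `subject` for windows of length |query| whose Hamming distance to
// `query` is <= max_mm and that are immediately preceded (5', i.e. the three
// characters before the window start) by a TTV PAM. Early exit on the
// mismatch count keeps the expected cost per window near-constant.
//
// Window starts considered: [start_min, start_max] (0-based, inclusive);
// callers arrange padding so that start_min >= 3.
// [[Rcpp::export(name = ".pam_mismatch_scan")]]
DataFrame pam_mismatch_scan(std::string subject, std::string query,
                            int max_mm, int start_min, int start_max) {
  const int k = (int)query.size();
  const int n = (int)subject.size();
  std::vector<int> starts;
  std::vector<int> mms;
  if (start_min < 3) start_min = 3;
  if (start_max > n - k) start_max = n - k;
  const char *s = subject.c_str();
  const char *q = query.c_str();
  for (int p = start_min; p <= start_max; ++p) {
    // TTV PAM at [p-3, p)
    if (s[p - 3] != 'T' || s[p - 2] != 'T') continue;
    const char v = s[p - 1];
    if (v != 'A' && v != 'C' && v != 'G') continue;
    int mm = 0;
    const char *w = s + p;
    int i = 0;
    for (; i < k; ++i) {
      if (w[i] != q[i]) {
        // any non-ACGT character disqualifies the window outright
        char c = w[i];
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { mm = max_mm + 1; break; }
        if (++mm > max_mm) break;
      }
    }
    if (i == k && mm <= max_mm) {
      starts.push_back(p);
      mms.push_back(mm);
    }
  }
  return DataFrame::create(_["start"] = starts, _["mismatches"] = mms);
}
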