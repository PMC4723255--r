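#include <Rcpp.h>
#include <map>
#include <string>
#include <cctype>
using namespace Rcpp;

// Decode the bases column of samtools pileup/mpileup lines.
//
// Conventions implemented:
//   '.' ','            reference match
//   ACGTacgt           mismatch of that base
//   '+n<seq>' '-n<seq>' insertion/deletion attached to the preceding
//                      read observation (does not consume depth)
//   '^X'               read start, X is mapping quality (consumed)
//   '$'                read end (consumed)
//   '*' '>' '<' N/n    skipped observations
//
// When min_base_q >= 0 and a quality string is supplied, each
// base-level observation consumes one Phred+33 quality character and
// observations below the threshold are reclassified as skipped (an
// indel attached to a masked observation is dropped).
// [[Rcpp::export(name = ".decode_pileup_cpp")]]
List decode_pileup_cpp(CharacterVector bases, CharacterVector ref,
                       CharacterVector quals, int min_base_q, bool full) {
  const int n = bases.size();
  const bool use_q = min_base_q >= 0 && quals.size() == n;
  IntegerVector n_ref(n), n_skip(n), n_obs(n), n_mis(n),
      mut_count(n), mut_total(n);
  CharacterVector mut_allele(n), allele_str(full ? n : 0), err(n);

  for (int k = 0; k < n; ++k) {
    const char *s = CHAR(STRING_ELT(bases, k));
    const char *q = use_q ? CHAR(STRING_ELT(quals, k)) : NULL;
    const int qlen = use_q ? LENGTH(STRING_ELT(quals, k)) : 0;
    char refb = toupper(CHAR(STRING_ELT(ref, k))[0]);
    int cnt[4] = {0, 0, 0, 0};  // A C G T mismatch counts
    std::map<std::string, int> indels;
    int nref = 0, nskip = 0, qi = 0;
    bool last_masked = false;
    std::string bad;

    for (int i = 0; s[i] != '\0';) {
      char c = s[i];
      if (c == '^') { i += (s[i + 1] ? 2 : 1); continue; }
      if (c == '$') { ++i; continue; }
      if (c == '+' || c == '-') {
        int len = 0, j = i + 1;
        while (isdigit((unsigned char)s[j])) { len = len * 10 + (s[j] - '0'); ++j; }
        if (len == 0) { bad = "malformed indel length"; break; }
        std::string seq;
        for (int t = 0; t < len && s[j]; ++t, ++j) seq += (char)toupper((unsigned char)s[j]);
        if ((int)seq.size() != len) { bad = "truncated indel sequence"; break; }
        if (!last_masked)
          indels[std::string(c == '+' ? "ins:" : "del:") + seq] += 1;
        i = j;
        continue;
      }
      // base-level observation
      int cls;  // 0 ref, 1..4 mismatch ACGT, 5 skip
      char u = toupper((unsigned char)c);
      if (c == '.' || c == ',') cls = 0;
      else if (u == 'A' || u == 'C' || u == 'G' || u == 'T') {
        if (u == refb) cls = 0;
        else cls = (u == 'A') ? 1 : (u == 'C') ? 2 : (u == 'G') ? 3 : 4;
      } else if (u == 'N' || c == '*' || c == '>' || c == '<') cls = 5;
      else { bad = std::string("unexpected character '") + c + "'"; break; }

      bool masked = false;
      if (use_q) {
        if (qi < qlen) masked = (q[qi] - 33) < min_base_q;
        ++qi;
      }
      last_masked = masked;
      if (masked || cls == 5) ++nskip;
      else if (cls == 0) ++nref;
      else ++cnt[cls - 1];
      ++i;
    }
    if (!bad.empty()) { err[k] = bad; continue; }

    int nmis = cnt[0] + cnt[1] + cnt[2] + cnt[3];
    int tot = nmis;
    for (std::map<std::string, int>::iterator it = indels.begin();
         it != indels.end(); ++it) tot += it->second;

    // dominant non-reference allele: highest count; ties favour SNP
    // bases (A<C<G<T) over indel alleles, then lexicographic keys
    const char *bn = "ACGT";
    int best = 0; std::string bestname = "";
    for (int b = 0; b < 4; ++b)
      if (cnt[b] > best) { best = cnt[b]; bestname = std::string(1, bn[b]); }
    for (std::map<std::string, int>::iterator it = indels.begin();
         it != indels.end(); ++it)
      if (it->second > best) { best = it->second; bestname = it->first; }

    n_ref[k] = nref; n_skip[k] = nskip; n_mis[k] = nmis;
    n_obs[k] = nref + nmis + nskip;
    mut_total[k] = tot;
    mut_count[k] = best;
    if (best > 0) mut_allele[k] = bestname; else mut_allele[k] = NA_STRING;
    if (full) {
      std::string ser;
      if (cnt[0]) ser += "A=" + std::to_string(cnt[0]) + ";";
      if (cnt[1]) ser += "C=" + std::to_string(cnt[1]) + ";";
      if (cnt[2]) ser += "G=" + std::to_string(cnt[2]) + ";";
      if (cnt[3]) ser += "T=" + std::to_string(cnt[3]) + ";";
      for (std::map<std::string, int>::iterator it = indels.begin();
           it != indels.end(); ++it)
        ser += it->first + "=" + std::to_string(it->second) + ";";
      if (!ser.empty()) ser.erase(ser.size() - 1);
      allele_str[k] = ser;
    }
  }

  List out = List::create(
      _["n_ref"] = n_ref, _["n_mismatch"] = n_mis, _["n_skipped"] = n_skip,
      _["n_obs"] = n_obs, _["mut_allele"] = mut_allele,
      _["mut_count"] = mut_count, _["mut_total"] = mut_total,
      _["error"] = err);
  if (full) out["alleles"] = allele_str;
  return out;
}
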