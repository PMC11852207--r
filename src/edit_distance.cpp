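#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <vector>
#include <string>

// Bit-parallel global Levenshtein distance (Myers 1999, multi-word form
// following Hyyro 2003). The pattern is processed in 64-bit blocks; the
// text is scanned once per pattern, propagating a horizontal delta carry
// between blocks. 'N' and any non-ACGT character match nothing.
//
// Used by the exhaustive read classifier, where each read is compared
// against every reference. The batch entry point supports best-so-far
// early abandonment: a comparison is aborted once even the most
// favourable completion (final >= score - columns_remaining) exceeds the
// current minimum; aborted comparisons therefore have distance strictly
// greater than the final minimum and can never tie it. Correctness of
// the exact distance is cross-checked against utils::adist in the test
// suite.

static inline int char_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<int8_t> text_codes(const std::string &text) {
  std::vector<int8_t> out(text.size());
  for (size_t j = 0; j < text.size(); ++j) out[j] = (int8_t)char_code(text[j]);
  return out;
}

// Returns the edit distance, or -1 if it provably exceeds abandon_above.
static int myers_one(const std::string &pattern,
                     const std::vector<int8_t> &tcode,
                     int abandon_above) {
  const size_t m = pattern.size(), n = tcode.size();
  if (m == 0) return ((int)n > abandon_above) ? -1 : (int)n;
  if (n == 0) return ((int)m > abandon_above) ? -1 : (int)m;
  const int W = 64;
  const size_t nb = (m + W - 1) / W;
  std::vector<uint64_t> buf(7 * nb, 0);
  uint64_t *Peq = buf.data();
  uint64_t *VP = Peq + 5 * nb;
  uint64_t *VN = VP + nb;
  for (size_t i = 0; i < m; ++i) {
    int c = char_code(pattern[i]);
    if (c < 4) Peq[(size_t)c * nb + i / W] |= (uint64_t)1 << (i % W);
  }
  for (size_t b = 0; b < nb; ++b) VP[b] = ~(uint64_t)0;
  int score = (int)m;
  const size_t last = nb - 1;
  const unsigned last_shift = (unsigned)((m - 1) % W);
  for (size_t j = 0; j < n; ++j) {
    const int c = tcode[j];
    const uint64_t *pc = (c < 4) ? Peq + (size_t)c * nb : 0;
    int hin = 1;  // row 0 holds D[0][j] = j: +1 per text column
    for (size_t b = 0; b < nb; ++b) {
      uint64_t Eq = pc ? pc[b] : 0;
      const uint64_t Pv = VP[b], Mv = VN[b];
      const uint64_t Xv = Eq | Mv;
      Eq |= (uint64_t)(hin < 0);
      const uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
      uint64_t Ph = Mv | ~(Xh | Pv);
      uint64_t Mh = Pv & Xh;
      if (b == last) {
        score += (int)((Ph >> last_shift) & 1) - (int)((Mh >> last_shift) & 1);
      }
      const int hout = (int)((Ph >> 63) & 1) - (int)((Mh >> 63) & 1);
      Ph = (Ph << 1) | (uint64_t)(hin > 0);
      Mh = (Mh << 1) | (uint64_t)(hin < 0);
      VP[b] = Mh | ~(Xv | Ph);
      VN[b] = Ph & Xv;
      hin = hout;
    }
    if (score - (int)(n - 1 - j) > abandon_above) return -1;
  }
  return score;
}

// [[Rcpp::export]]
int myers_distance(std::string a, std::string b) {
  return myers_one(a, text_codes(b), INT_MAX);
}

// [[Rcpp::export]]
Rcpp::IntegerVector myers_distance_many(std::string text,
                                        Rcpp::CharacterVector patterns) {
  const std::vector<int8_t> tc = text_codes(text);
  const int np = patterns.size();
  Rcpp::IntegerVector out(np);
  for (int i = 0; i < np; ++i) {
    out[i] = myers_one(Rcpp::as<std::string>(patterns[i]), tc, INT_MAX);
  }
  return out;
}

// Batch with early abandonment: NA marks comparisons whose distance
// provably exceeds the running minimum (seeded by init_best).
// [[Rcpp::export]]
Rcpp::IntegerVector myers_distance_best(std::string text,
                                        Rcpp::CharacterVector patterns,
                                        int init_best) {
  const std::vector<int8_t> tc = text_codes(text);
  const int np = patterns.size();
  Rcpp::IntegerVector out(np);
  int best = init_best;
  for (int i = 0; i < np; ++i) {
    int d = myers_one(Rcpp::as<std::string>(patterns[i]), tc, best);
    if (d < 0) {
      out[i] = NA_INTEGER;
    } else {
      out[i] = d;
      if (d < best) best = d;
    }
  }
  return out;
}
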