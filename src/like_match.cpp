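#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Character-level matching of one screening-line segment (no '*') at a fixed
// position of the text. '?' matches any character, '#' any digit, everything
// else (key letters, literal digits, '.') matches itself.
static bool seg_match_at(const std::string& seg, const std::string& text,
                         size_t pos) {
  if (pos + seg.size() > text.size()) return false;
  for (size_t i = 0; i < seg.size(); ++i) {
    char m = seg[i], t = text[pos + i];
    if (m == '?') continue;
    if (m == '#') {
      if (t < '0' || t > '9') return false;
      continue;
    }
    if (m != t) return false;
  }
  return true;
}

// First position >= from at which seg matches; npos if none.
static size_t seg_find(const std::string& seg, const std::string& text,
                       size_t from) {
  if (seg.empty()) return from <= text.size() ? from : std::string::npos;
  if (text.size() < seg.size()) return std::string::npos;
  for (size_t pos = from; pos + seg.size() <= text.size(); ++pos) {
    if (seg_match_at(seg, text, pos)) return pos;
  }
  return std::string::npos;
}

static void split_segments(const std::string& line,
                           std::vector<std::string>& segs) {
  segs.clear();
  std::string cur;
  for (char c : line) {
    if (c == '*') {
      segs.push_back(cur);
      cur.clear();
    } else {
      cur.push_back(c);
    }
  }
  segs.push_back(cur);
}

// Substring semantics (implicit '*' at both ends): the leftmost-start match
// is found by anchoring the first segment at each candidate position in
// increasing order and placing the remaining segments greedily as early as
// possible. Returns {start, end} 1-based, or {NA, NA}.
static void like_match_one(const std::vector<std::string>& segs,
                           const std::string& text, int* start, int* end) {
  *start = NA_INTEGER;
  *end = NA_INTEGER;
  size_t first = 0;
  // skip empty leading segments (from a leading '*')
  while (first < segs.size() && segs[first].empty()) ++first;
  if (first == segs.size()) {  // motif was all '*' (or empty): matches anywhere
    *start = 1;
    *end = 0;
    return;
  }
  for (size_t s0 = seg_find(segs[first], text, 0); s0 != std::string::npos;
       s0 = seg_find(segs[first], text, s0 + 1)) {
    size_t pos = s0 + segs[first].size();
    bool ok = true;
    size_t last_end = pos;
    for (size_t k = first + 1; k < segs.size(); ++k) {
      if (segs[k].empty()) continue;
      size_t p = seg_find(segs[k], text, pos);
      if (p == std::string::npos) {
        ok = false;
        break;
      }
      pos = p + segs[k].size();
      last_end = pos;
    }
    if (ok) {
      *start = (int)(s0 + 1);
      *end = (int)last_end;
      return;
    }
  }
}

// [[Rcpp::export(name = ".cpp_like_match")]]
IntegerMatrix cpp_like_match(std::string line, CharacterVector texts) {
  std::vector<std::string> segs;
  split_segments(line, segs);
  IntegerMatrix out(texts.size(), 2);
  for (R_xlen_t i = 0; i < texts.size(); ++i) {
    int s, e;
    like_match_one(segs, std::string(texts[i]), &s, &e);
    out(i, 0) = s;
    out(i, 1) = e;
  }
  colnames(out) = CharacterVector::create("start", "end");
  return out;
}
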