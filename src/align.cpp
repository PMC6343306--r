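#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Base codes used throughout: A=0 C=1 G=2 T=3, N=4 (never matches).
// bs_mode: 0 = exact, 1 = C2T space (ref C matched by read T),
//          2 = G2A space (ref G matched by read A).
static inline bool base_match(int rb, int fb, int bs_mode) {
  if (rb > 3 || fb > 3) return false;
  if (rb == fb) return true;
  if (bs_mode == 1 && fb == 1 && rb == 3) return true; // read T over ref C
  if (bs_mode == 2 && fb == 2 && rb == 0) return true; // read A over ref G
  return false;
}

// Verify a (converted-space) seed against a converted reference view around
// candidate start c0.  Allows up to max_mm mismatches and at most one gap
// (insertion or deletion) of length 1..max_gap_len; the seed start may be
// shifted by [shift_lo, shift_hi] relative to c0.  Cost = mm + 1.5 * gaps.
// Returns [found, start, mm, ngap, gap_offset, gap_len, gap_type]
// (gap_type: 0 none, 1 insertion-in-read, 2 deletion-from-ref).
// [[Rcpp::export]]
IntegerVector cpp_seed_verify(IntegerVector seed, IntegerVector ref,
                              int c0, int shift_lo, int shift_hi,
                              int max_mm, int max_gap_len, bool allow_gap) {
  const int L = seed.size(), n = ref.size();
  double best_cost = 1e18;
  int b_start = -1, b_mm = 0, b_ngap = 0, b_goff = 0, b_glen = 0, b_gtyp = 0;
  std::vector<int> pre(L + 1), suf(L + 1);
  for (int sh = shift_lo; sh <= shift_hi; ++sh) {
    const int c = c0 + sh;
    if (c < 0) continue;
    // ungapped: straight Hamming on the diagonal
    if (c + L <= n) {
      int mm = 0;
      for (int i = 0; i < L && mm <= max_mm; ++i)
        if (seed[i] != ref[c + i] || seed[i] > 3) ++mm;
      if (mm <= max_mm && (double)mm < best_cost) {
        best_cost = mm; b_start = c; b_mm = mm; b_ngap = 0;
        b_goff = 0; b_glen = 0; b_gtyp = 0;
      }
    }
    if (!allow_gap) continue;
    // prefix mismatches along diagonal c
    pre[0] = 0;
    for (int i = 0; i < L; ++i) {
      bool ok = (c + i < n) && seed[i] <= 3 && seed[i] == ref[c + i];
      pre[i + 1] = pre[i] + (ok ? 0 : 1);
    }
    for (int g = 1; g <= max_gap_len; ++g) {
      // deletion of g reference bases after read offset s:
      // read[s..L) aligns to ref[c+s+g ..)
      suf[L] = 0;
      for (int i = L - 1; i >= 0; --i) {
        bool ok = (c + i + g < n) && seed[i] <= 3 && seed[i] == ref[c + i + g];
        suf[i] = suf[i + 1] + (ok ? 0 : 1);
      }
      for (int s = 1; s < L; ++s) { // gap strictly inside the seed
        int mm = pre[s] + suf[s];
        double cost = mm + 1.5;
        if (mm <= max_mm && cost < best_cost) {
          best_cost = cost; b_start = c; b_mm = mm; b_ngap = 1;
          b_goff = s; b_glen = g; b_gtyp = 2;
        }
      }
      // insertion of g read bases at offset s: read[0..s) at diag 0,
      // read[s..s+g) unaligned, read[s+g..L) aligns to ref[c+s ..)
      suf[L] = 0;
      for (int i = L - 1; i >= 0; --i) {
        bool ok = (c + i - g >= 0) && (c + i - g < n) && seed[i] <= 3 &&
                  seed[i] == ref[c + i - g];
        suf[i] = suf[i + 1] + (ok ? 0 : 1);
      }
      for (int s = 1; s + g < L; ++s) {
        int mm = pre[s] + suf[s + g];
        double cost = mm + 1.5;
        if (mm <= max_mm && cost < best_cost) {
          best_cost = cost; b_start = c; b_mm = mm; b_ngap = 1;
          b_goff = s; b_glen = g; b_gtyp = 1;
        }
      }
    }
  }
  return IntegerVector::create(b_start >= 0 ? 1 : 0, b_start, b_mm, b_ngap,
                               b_goff, b_glen, b_gtyp);
}

// Ungapped extension of the full read along the diagonal starting at ref
// position `start`.  Score: match +Q, mismatch -Q.  With clip=true the
// best-scoring contiguous read segment is kept (Kadane) and the flanks are
// soft-clipped; otherwise the whole read is scored.
// Returns list(score, pos, clip_left, clip_right, n_mismatch, valid).
// [[Rcpp::export]]
List cpp_ungapped_extend(IntegerVector read, IntegerVector quals,
                         IntegerVector ref, int start, int bs_mode,
                         bool clip) {
  const int m = read.size(), n = ref.size();
  if (start < 0 || start + m > n)
    return List::create(_["valid"] = false);
  std::vector<int> s(m);
  std::vector<bool> mk(m);
  for (int i = 0; i < m; ++i) {
    bool ok = base_match(read[i], ref[start + i], bs_mode);
    mk[i] = ok;
    s[i] = ok ? quals[i] : -quals[i];
  }
  int i1 = 0, i2 = m - 1;
  long score = 0;
  if (!clip) {
    for (int i = 0; i < m; ++i) score += s[i];
  } else {
    long best = -1, cur = 0; int cs = 0; i1 = 0; i2 = -1;
    for (int i = 0; i < m; ++i) {
      if (cur <= 0) { cur = s[i]; cs = i; } else cur += s[i];
      if (cur > best) { best = cur; i1 = cs; i2 = i; }
    }
    if (i2 < 0) return List::create(_["valid"] = false);
    score = best;
  }
  int mm = 0;
  for (int i = i1; i <= i2; ++i) if (!mk[i]) ++mm;
  return List::create(_["valid"] = true, _["score"] = (double)score,
                      _["pos"] = start + i1, _["clip_left"] = i1,
                      _["clip_right"] = m - 1 - i2, _["n_mismatch"] = mm,
                      _["match_len"] = i2 - i1 + 1);
}

// Affine-gap DP of the full read against the reference window
// [win_start, win_end) of `ref`.  Global in the read (every read base is
// consumed by M/I, or soft-clipped at the ends when clip=true), free start
// and end in the window.  Match +Q(i), mismatch -Q(i), first gap base
// -(gap_open + gap_extend), each further base -gap_extend.
// max_gap_events <= 0 means unlimited; a positive value caps the number of
// gap openings along the path (the pipeline uses the seed model's gap
// allowance here, which prevents score-positive "gap wandering" across
// random sequence; the unlimited DP is the oracle-checked contract).
// Returns list(score, pos, cigar, n_mismatch, touched_left, touched_right).
// [[Rcpp::export]]
List cpp_affine_extend(IntegerVector read, IntegerVector quals,
                       IntegerVector ref, int win_start, int win_end,
                       int bs_mode, int gap_open, int gap_extend,
                       bool clip, int max_gap_events = 0) {
  const int m = read.size();
  if (win_start < 0) win_start = 0;
  if (win_end > ref.size()) win_end = ref.size();
  const int w = win_end - win_start;
  if (w <= 0 || m == 0) return List::create(_["valid"] = false);
  const int G = (max_gap_events <= 0) ? (m + w) : max_gap_events;
  const double NEG = -1e15;
  const double open1 = -(double)(gap_open + gap_extend), ext = -(double)gap_extend;
  // layered H/E/F, (G+1) x (m+1) x (w+1); layer g = at most g gap events.
  // E = gap in read (D op), F = gap in ref (I op)
  const size_t sz = (size_t)(G + 1) * (m + 1) * (w + 1);
  std::vector<double> H(sz), E(sz), F(sz);
  std::vector<unsigned char> tbH(sz), tbE(sz), tbF(sz);
  // tbH: 0 = start here, 1 = diag from H, 2 = from E, 3 = from F
  // tbE: 0 = opened from H (layer g-1), 1 = extended;  tbF likewise
  auto at = [m, w](int g, int i, int j) {
    return ((size_t)g * (m + 1) + i) * (w + 1) + j;
  };
  for (int g = 0; g <= G; ++g) {
    for (int j = 0; j <= w; ++j) {
      H[at(g, 0, j)] = 0.0; E[at(g, 0, j)] = NEG; F[at(g, 0, j)] = NEG;
      tbH[at(g, 0, j)] = 0;
    }
    for (int i = 1; i <= m; ++i) {
      // column 0: read prefix must be inserted (a gap event) or clipped
      double fo = (g > 0 && i == 1) ? open1
                  : (g > 0 && H[at(g - 1, i - 1, 0)] > NEG / 2)
                      ? H[at(g - 1, i - 1, 0)] + open1 : NEG;
      double fe = (i > 1) ? F[at(g, i - 1, 0)] + ext : NEG;
      F[at(g, i, 0)] = std::max(fo, fe);
      tbF[at(g, i, 0)] = (fo >= fe) ? 0 : 1;
      E[at(g, i, 0)] = NEG;
      double h0 = F[at(g, i, 0)];
      if (clip && h0 < 0.0) {
        H[at(g, i, 0)] = 0.0; tbH[at(g, i, 0)] = 0;
      } else {
        H[at(g, i, 0)] = h0; tbH[at(g, i, 0)] = 3;
      }
      for (int j = 1; j <= w; ++j) {
        const int q = quals[i - 1];
        const bool ok = base_match(read[i - 1], ref[win_start + j - 1], bs_mode);
        const double sub = ok ? (double)q : -(double)q;
        // E: deletion (consumes ref); opening uses one event
        double eo = (g > 0) ? H[at(g - 1, i, j - 1)] + open1 : NEG;
        double ee = E[at(g, i, j - 1)] + ext;
        E[at(g, i, j)] = std::max(eo, ee);
        tbE[at(g, i, j)] = (eo >= ee) ? 0 : 1;
        // F: insertion (consumes read)
        double fo2 = (g > 0) ? H[at(g - 1, i - 1, j)] + open1 : NEG;
        double fe2 = F[at(g, i - 1, j)] + ext;
        F[at(g, i, j)] = std::max(fo2, fe2);
        tbF[at(g, i, j)] = (fo2 >= fe2) ? 0 : 1;
        // H
        double dprev = H[at(g, i - 1, j - 1)];
        if (clip && dprev < 0.0) dprev = 0.0; // fresh start: clip prefix
        double dm = dprev + sub;
        double best = dm; unsigned char tb = 1;
        if (E[at(g, i, j)] > best) { best = E[at(g, i, j)]; tb = 2; }
        if (F[at(g, i, j)] > best) { best = F[at(g, i, j)]; tb = 3; }
        H[at(g, i, j)] = best;
        tbH[at(g, i, j)] = tb;
      }
    }
  }
  // choose end cell in the top layer (at-most semantics)
  int bi = m, bj = 0; double best = NEG;
  if (clip) {
    for (int i = 1; i <= m; ++i)
      for (int j = 0; j <= w; ++j)
        if (H[at(G, i, j)] > best) { best = H[at(G, i, j)]; bi = i; bj = j; }
    if (best <= 0.0) return List::create(_["valid"] = false);
  } else {
    // leftmost maximal end column for determinism
    for (int j = 0; j <= w; ++j)
      if (H[at(G, m, j)] > best) { best = H[at(G, m, j)]; bi = m; bj = j; }
    if (best < NEG / 2) return List::create(_["valid"] = false);
  }
  // traceback
  std::vector<std::pair<char, int> > ops; // reversed
  int clip_right = m - bi;
  int i = bi, j = bj, g = G;
  int state = 0; // 0 = H, 1 = E, 2 = F
  int n_mm = 0;
  auto push = [&ops](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  // drop to the lowest layer with the same H score (ties favor fewer gaps)
  while (g > 0 && state == 0 && H[at(g - 1, i, j)] == H[at(g, i, j)]) --g;
  while (i > 0) {
    if (state == 0) {
      unsigned char tb = tbH[at(g, i, j)];
      if (tb == 0) break; // fresh start (clip) or row 0
      if (tb == 1) {
        double dprev = H[at(g, i - 1, j - 1)];
        bool ok = base_match(read[i - 1], ref[win_start + j - 1], bs_mode);
        if (!ok) ++n_mm;
        push('M');
        --i; --j;
        if (clip && dprev < 0.0) break; // restarted here: prefix clipped
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char tb = tbE[at(g, i, j)];
      push('D');
      --j;
      if (tb == 0) { state = 0; --g; }
    } else {
      unsigned char tb = tbF[at(g, i, j)];
      push('I');
      --i;
      if (tb == 0) { state = 0; --g; }
    }
  }
  int clip_left = i;
  int ref_pos = win_start + j;
  // assemble CIGAR string (ops are reversed)
  std::string cig;
  if (clip_left > 0) cig += std::to_string(clip_left) + "S";
  for (int t = (int)ops.size() - 1; t >= 0; --t)
    cig += std::to_string(ops[t].second) + ops[t].first;
  if (clip_right > 0) cig += std::to_string(clip_right) + "S";
  // window-edge contact: alignment start/end at the window boundary
  int ref_len = 0;
  for (size_t t = 0; t < ops.size(); ++t)
    if (ops[t].first != 'I') ref_len += ops[t].second;
  bool tl = (j == 0 && win_start > 0);
  bool tr = (ref_pos + ref_len == win_end) && (win_end < ref.size());
  return List::create(_["valid"] = true, _["score"] = best,
                      _["pos"] = ref_pos, _["cigar"] = cig,
                      _["n_mismatch"] = n_mm,
                      _["touched_left"] = tl, _["touched_right"] = tr);
}

// Count exact occurrences of pattern in text (both integer-coded); N never
// matches.  Returns 0-based positions (used for 0-mismatch clip realignment).
// [[Rcpp::export]]
IntegerVector cpp_exact_scan(IntegerVector pattern, IntegerVector text) {
  const int L = pattern.size(), n = text.size();
  std::vector<int> out;
  for (int c = 0; c + L <= n; ++c) {
    bool ok = true;
    for (int i = 0; i < L; ++i)
      if (pattern[i] > 3 || pattern[i] != text[c + i]) { ok = false; break; }
    if (ok) out.push_back(c);
  }
  return wrap(out);
}
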