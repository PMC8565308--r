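#include <Rcpp.h>
using namespace Rcpp;

// Pileup accumulation over aligned reads of one reference.
//
// counts: ref_len x 16 matrix, column = cell * 4 + base with
//   cell in {0=R1F, 1=R1R, 2=R2F, 3=R2R} and base in {0=A, 1=C, 2=G, 3=T}.
// depth:  ref_len x 4 matrix (per cell), counting every aligned base
//   regardless of base quality; bases below min_bq contribute depth only.
// The first sequencing cycle (5'-most raw base; the last aligned base of a
// reverse-mapped read) is skipped entirely when skip_first_cycle is set.
//
// CIGAR ops: M/=/X consume both and are counted; I and S consume the query;
// D and N consume the reference; H and P consume nothing.
// [[Rcpp::export]]
List cpp_pileup(CharacterVector seq, CharacterVector qual, IntegerVector pos,
                CharacterVector cigar, IntegerVector cell,
                LogicalVector reverse, int ref_len, int min_bq,
                bool skip_first_cycle) {
  int n = seq.size();
  IntegerMatrix counts(ref_len, 16);
  IntegerMatrix depth(ref_len, 4);
  int *cnt = INTEGER(counts);
  int *dep = INTEGER(depth);

  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seq, r));
    const char *q = CHAR(STRING_ELT(qual, r));
    const char *cg = CHAR(STRING_ELT(cigar, r));
    int qlen = LENGTH(STRING_ELT(seq, r));
    if ((int) LENGTH(STRING_ELT(qual, r)) != qlen)
      stop("SEQ/QUAL length mismatch in record %d", r + 1);
    int rpos = pos[r] - 1;  // 0-based reference position
    int qpos = 0;           // 0-based query position
    int c = cell[r];
    bool rev = reverse[r];
    int skip_q = -1;
    if (skip_first_cycle) skip_q = rev ? qlen - 1 : 0;

    const char *p = cg;
    while (*p) {
      long len = 0;
      while (*p >= '0' && *p <= '9') { len = len * 10 + (*p - '0'); ++p; }
      char op = *p ? *p++ : '\0';
      if (op == '\0') break;
      switch (op) {
      case 'M': case '=': case 'X': {
        if (qpos + len > qlen)
          stop("CIGAR/SEQ length mismatch in record %d", r + 1);
        for (long i = 0; i < len; ++i) {
          int rp = rpos + i, qp = qpos + i;
          if (rp < 0 || rp >= ref_len)
            stop("alignment outside reference in record %d", r + 1);
          if (qp == skip_q) continue;
          dep[(size_t) c * ref_len + rp] += 1;
          if (q[qp] - 33 >= min_bq) {
            int b;
            switch (s[qp]) {
            case 'A': case 'a': b = 0; break;
            case 'C': case 'c': b = 1; break;
            case 'G': case 'g': b = 2; break;
            case 'T': case 't': b = 3; break;
            default: b = -1;
            }
            if (b >= 0) cnt[(size_t) (c * 4 + b) * ref_len + rp] += 1;
          }
        }
        rpos += len; qpos += len;
        break;
      }
      case 'I': case 'S': qpos += len; break;
      case 'D': case 'N': rpos += len; break;
      case 'H': case 'P': break;
      default: stop("unsupported CIGAR op '%c' in record %d", op, r + 1);
      }
    }
    if (qpos != qlen)
      stop("CIGAR does not consume SEQ in record %d", r + 1);
  }
  return List::create(_["counts"] = counts, _["depth"] = depth);
}

// Slide an IUPAC motif (4-bit base masks; text bases are single bits, masked
// or N positions are 0 and never match) over every offset of every window.
//
// win: n x W integer matrix of text masks.  Returns total occurrence count,
// a histogram over start offsets (length W - k + 1), and optionally the
// matched (window, start) pairs for masking.
// [[Rcpp::export]]
List cpp_motif_scan(IntegerMatrix win, IntegerVector motif,
                    bool collect_positions = false) {
  int n = win.nrow(), W = win.ncol(), k = motif.size();
  if (k > W) stop("motif longer than windows");
  int noff = W - k + 1;
  IntegerVector hist(noff);
  long long occ = 0;
  std::vector<int> hit_win, hit_start;
  const int *w = INTEGER(win);
  const int *m = INTEGER(motif);
  for (int i = 0; i < n; ++i) {
    for (int o = 0; o < noff; ++o) {
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        // column-major: element (i, o + j)
        if ((w[(size_t) (o + j) * n + i] & m[j]) == 0) { ok = false; break; }
      }
      if (ok) {
        ++occ;
        hist[o] += 1;
        if (collect_positions) { hit_win.push_back(i + 1); hit_start.push_back(o); }
      }
    }
  }
  List out = List::create(_["occurrences"] = (double) occ, _["hist"] = hist);
  if (collect_positions) {
    out["window"] = wrap(hit_win);
    out["start"] = wrap(hit_start);
  }
  return out;
}
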