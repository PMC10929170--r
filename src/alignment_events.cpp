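#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Column indices of the result matrix.
enum { C_MM = 0, C_HQMM, C_GO, C_GE, C_INS, C_HQINS, C_DEL, C_HQDEL,
       C_MAT, C_ALN, C_SPAN, C_MBASES, C_ERR, N_COL };

// Error codes (column ERR): 0 ok, 1 MD inconsistent with CIGAR,
// 2 invalid CIGAR or CIGAR/quality-length disagreement.
static const int ERR_MD = 1;
static const int ERR_CIGAR = 2;

struct CigOp {
  char op;
  int len;
};

static bool parse_cigar(const std::string &cig, std::vector<CigOp> &ops) {
  ops.clear();
  if (cig.empty() || cig == "*") return false;
  long num = 0;
  bool have = false;
  for (size_t i = 0; i < cig.size(); ++i) {
    char c = cig[i];
    if (c >= '0' && c <= '9') {
      num = num * 10 + (c - '0');
      have = true;
    } else {
      if (!have || num <= 0) return false;
      switch (c) {
      case 'M': case 'I': case 'D': case 'N': case 'S':
      case 'H': case 'P': case '=': case 'X':
        ops.push_back({c, (int)num});
        break;
      default:
        return false;
      }
      num = 0;
      have = false;
    }
  }
  return !have && !ops.empty();
}

// Count alignment events for one record from its CIGAR, MD, and quality
// string.  Mismatch read positions are located through the MD string
// within M runs; '=' and 'X' ops are folded into M semantics.  Soft
// clipped bases are counted as aligned-and-mismatched (never matched),
// so MM can exceed the NM tag.  A deletion is high-quality only when
// both flanking read bases carry the maximal quality character; a
// deletion at the alignment edge is never high-quality.  When MD is
// absent the mismatch count falls back to max(0, NM - INS - DEL) with
// the high-quality mismatch count undefined-as-zero.
//
// [[Rcpp::export]]
IntegerMatrix parse_events_cpp(CharacterVector cigar, CharacterVector md,
                               CharacterVector qual, IntegerVector nm,
                               std::string max_q) {
  if (max_q.size() != 1)
    stop("max_q must be a single character");
  const char mq = max_q[0];
  const int n = cigar.size();
  if (md.size() != n || qual.size() != n || nm.size() != n)
    stop("cigar, md, qual and nm must have equal length");

  IntegerMatrix out(n, N_COL);
  colnames(out) = CharacterVector::create(
      "MM", "HQMM", "GO", "GE", "INS", "HQINS", "DEL", "HQDEL",
      "MAT", "ALN", "SPAN", "MBASES", "ERR");

  std::vector<CigOp> ops;
  std::vector<int> m_read_pos;  // read position (0-based) of each M base
  std::vector<int> d_lens;      // deletion run lengths in reference order

  for (int i = 0; i < n; ++i) {
    int err = 0;
    long MM = 0, HQMM = 0, GO = 0, GE = 0, INS = 0, HQINS = 0;
    long DEL = 0, HQDEL = 0, MAT = 0, ALN = 0, SPAN = 0, MBASES = 0;

    std::string cig = cigar[i] == NA_STRING ? "" : as<std::string>(cigar[i]);
    if (!parse_cigar(cig, ops)) {
      out(i, C_ERR) = ERR_CIGAR;
      continue;
    }

    std::string q = qual[i] == NA_STRING ? "" : as<std::string>(qual[i]);
    const bool hasq = !q.empty() && q != "*";

    long readlen = 0;
    for (const CigOp &o : ops)
      if (o.op == 'M' || o.op == 'I' || o.op == 'S' || o.op == '=' ||
          o.op == 'X')
        readlen += o.len;
    if (hasq && (long)q.size() != readlen) {
      out(i, C_ERR) = ERR_CIGAR;
      continue;
    }

    m_read_pos.clear();
    d_lens.clear();
    long readpos = 0, s_mm = 0, s_hq = 0;

    for (const CigOp &o : ops) {
      switch (o.op) {
      case 'M': case '=': case 'X':
        for (int k = 0; k < o.len; ++k) m_read_pos.push_back(readpos + k);
        MBASES += o.len;
        ALN += o.len;
        SPAN += o.len;
        readpos += o.len;
        break;
      case 'I':
        INS += o.len;
        GO += 1;
        GE += o.len;
        if (hasq)
          for (int k = 0; k < o.len; ++k)
            if (q[readpos + k] == mq) HQINS += 1;
        ALN += o.len;
        readpos += o.len;
        break;
      case 'D': {
        DEL += o.len;
        GO += 1;
        GE += o.len;
        SPAN += o.len;
        d_lens.push_back(o.len);
        bool hq = hasq && readpos > 0 && readpos < readlen &&
                  q[readpos - 1] == mq && q[readpos] == mq;
        if (hq) HQDEL += o.len;
        break;
      }
      case 'N':
        SPAN += o.len;
        break;
      case 'S':
        s_mm += o.len;
        if (hasq)
          for (int k = 0; k < o.len; ++k)
            if (q[readpos + k] == mq) s_hq += 1;
        ALN += o.len;
        readpos += o.len;
        break;
      default:  // H, P consume nothing we track
        break;
      }
    }

    long mm_md = 0, hq_md = 0;
    std::string mdstr = md[i] == NA_STRING ? "" : as<std::string>(md[i]);
    if (!mdstr.empty()) {
      size_t p = 0, midx = 0, didx = 0;
      while (p < mdstr.size() && err == 0) {
        char c = mdstr[p];
        if (c >= '0' && c <= '9') {
          long run = 0;
          while (p < mdstr.size() && mdstr[p] >= '0' && mdstr[p] <= '9') {
            run = run * 10 + (mdstr[p] - '0');
            ++p;
          }
          midx += run;
          if (midx > (size_t)MBASES) err = ERR_MD;
        } else if (c == '^') {
          ++p;
          long dl = 0;
          while (p < mdstr.size() &&
                 ((mdstr[p] >= 'A' && mdstr[p] <= 'Z') ||
                  (mdstr[p] >= 'a' && mdstr[p] <= 'z'))) {
            ++dl;
            ++p;
          }
          if (didx >= d_lens.size() || d_lens[didx] != dl) err = ERR_MD;
          ++didx;
        } else if ((c >= 'A' && c <= 'Z') || (c >= 'a' && c <= 'z')) {
          if (midx >= (size_t)MBASES) {
            err = ERR_MD;
          } else {
            int rp = m_read_pos[midx];
            mm_md += 1;
            if (hasq && q[rp] == mq) hq_md += 1;
            ++midx;
          }
          ++p;
        } else {
          err = ERR_MD;
        }
      }
      if (midx != (size_t)MBASES || didx != d_lens.size()) err = ERR_MD;
    } else {
      // MD absent: NM-consistent fallback, HQ mismatches unknowable.
      int nmv = nm[i] == NA_INTEGER ? 0 : nm[i];
      mm_md = nmv - INS - DEL;
      if (mm_md < 0) mm_md = 0;
      hq_md = 0;
    }

    MAT = MBASES - mm_md;
    MM = mm_md + s_mm;
    HQMM = hq_md + s_hq;

    out(i, C_MM) = (int)MM;
    out(i, C_HQMM) = (int)HQMM;
    out(i, C_GO) = (int)GO;
    out(i, C_GE) = (int)GE;
    out(i, C_INS) = (int)INS;
    out(i, C_HQINS) = (int)HQINS;
    out(i, C_DEL) = (int)DEL;
    out(i, C_HQDEL) = (int)HQDEL;
    out(i, C_MAT) = (int)MAT;
    out(i, C_ALN) = (int)ALN;
    out(i, C_SPAN) = (int)SPAN;
    out(i, C_MBASES) = (int)MBASES;
    out(i, C_ERR) = err;
  }
  return out;
}
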