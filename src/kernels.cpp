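// Compiled kernels: fuzzy infix matching, semi-global alignment,
// paired-read merging and trimming, UMI-family voting, and the
// reference-standard read simulator. All randomness goes through R's RNG.

#include <Rcpp.h>
#include <zlib.h>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

static const int NEG_INF = -100000000;

// ---------------------------------------------------------------------------
// fuzzy infix search: substring of `text` minimising Levenshtein distance to
// `pattern`; ties broken by smallest start, then smallest end.
// ---------------------------------------------------------------------------

struct FuzzyHit {
  int start, end, edits; // 0-based, end exclusive
  bool found;
};

static FuzzyHit fuzzy_core(const char *pat, int m, const char *txt, int n,
                           int max_edits) {
  // dp over pattern rows; free leading/trailing text (infix alignment).
  // Each cell carries (edits, start); lexicographic minimum is propagated.
  std::vector<int> d_prev(n + 1), d_cur(n + 1);
  std::vector<int> s_prev(n + 1), s_cur(n + 1);
  for (int j = 0; j <= n; ++j) { d_prev[j] = 0; s_prev[j] = j; }
  for (int i = 1; i <= m; ++i) {
    d_cur[0] = i; s_cur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int sub = d_prev[j - 1] + (pat[i - 1] == txt[j - 1] ? 0 : 1);
      int ssub = s_prev[j - 1];
      int del = d_prev[j] + 1;        // skip pattern char
      int sdel = s_prev[j];
      int ins = d_cur[j - 1] + 1;     // skip text char
      int sins = s_cur[j - 1];
      int best = sub, bs = ssub;
      if (del < best || (del == best && sdel < bs)) { best = del; bs = sdel; }
      if (ins < best || (ins == best && sins < bs)) { best = ins; bs = sins; }
      d_cur[j] = best; s_cur[j] = bs;
    }
    std::swap(d_prev, d_cur);
    std::swap(s_prev, s_cur);
  }
  FuzzyHit h; h.found = false; h.edits = max_edits + 1; h.start = 0; h.end = 0;
  for (int j = 0; j <= n; ++j) {
    int e = d_prev[j], s = s_prev[j];
    if (e < h.edits || (e == h.edits && h.found &&
        (s < h.start || (s == h.start && j < h.end)))) {
      if (e <= max_edits) { h.found = true; h.edits = e; h.start = s; h.end = j; }
    }
  }
  return h;
}

// [[Rcpp::export]]
SEXP cpp_fuzzy_find(std::string pattern, std::string text, int max_edits) {
  if (pattern.empty()) stop("pattern must be non-empty");
  FuzzyHit h = fuzzy_core(pattern.c_str(), (int)pattern.size(),
                          text.c_str(), (int)text.size(), max_edits);
  if (!h.found) return R_NilValue;
  return IntegerVector::create(_["start"] = h.start, _["end"] = h.end,
                               _["edits"] = h.edits);
}

// ---------------------------------------------------------------------------
// semi-global alignment: query aligned end-to-end, reference end-gaps free.
// Affine gaps (a gap of length k costs gap_open + (k-1)*gap_extend); a linear
// model is the special case gap_open == gap_extend. Deterministic traceback:
// diagonal > up (query gap-insertion) > left (reference deletion).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_semi_global(std::string query, std::string ref, int match,
                     int mismatch, int gap_open, int gap_extend) {
  int m = (int)query.size(), n = (int)ref.size();
  if (m == 0 || n == 0) stop("query and reference must be non-empty");
  const char *q = query.c_str(), *r = ref.c_str();

  std::vector<int> M((m + 1) * (n + 1), NEG_INF);
  std::vector<int> Ix((m + 1) * (n + 1), NEG_INF); // gap in ref, consumes query
  std::vector<int> Iy((m + 1) * (n + 1), NEG_INF); // gap in query, consumes ref
  // traceback: for M, which state fed the diagonal (0=M,1=Ix,2=Iy);
  // for Ix/Iy, whether the gap was opened (0, from M) or extended (1).
  std::vector<unsigned char> tbM((m + 1) * (n + 1), 0), tbX((m + 1) * (n + 1), 0),
      tbY((m + 1) * (n + 1), 0);
  #define IDX(i, j) ((i) * (n + 1) + (j))

  for (int j = 0; j <= n; ++j) M[IDX(0, j)] = 0; // free leading reference
  Ix[IDX(0, 0)] = NEG_INF;
  for (int i = 1; i <= m; ++i) {
    Ix[IDX(i, 0)] = gap_open + (i - 1) * gap_extend;
    tbX[IDX(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      // M: preference M > Ix > Iy on ties (diagonal-first traceback)
      int dM = M[IDX(i - 1, j - 1)], dX = Ix[IDX(i - 1, j - 1)],
          dY = Iy[IDX(i - 1, j - 1)];
      int best = dM; unsigned char who = 0;
      if (dX > best) { best = dX; who = 1; }
      if (dY > best) { best = dY; who = 2; }
      if (best > NEG_INF / 2) { M[IDX(i, j)] = best + s; tbM[IDX(i, j)] = who; }
      // Ix (up): open from M preferred on ties
      int op = M[IDX(i - 1, j)] > NEG_INF / 2 ? M[IDX(i - 1, j)] + gap_open : NEG_INF;
      int ex = Ix[IDX(i - 1, j)] > NEG_INF / 2 ? Ix[IDX(i - 1, j)] + gap_extend : NEG_INF;
      if (op >= ex) { Ix[IDX(i, j)] = op; tbX[IDX(i, j)] = 0; }
      else          { Ix[IDX(i, j)] = ex; tbX[IDX(i, j)] = 1; }
      // Iy (left)
      op = M[IDX(i, j - 1)] > NEG_INF / 2 ? M[IDX(i, j - 1)] + gap_open : NEG_INF;
      ex = Iy[IDX(i, j - 1)] > NEG_INF / 2 ? Iy[IDX(i, j - 1)] + gap_extend : NEG_INF;
      if (op >= ex) { Iy[IDX(i, j)] = op; tbY[IDX(i, j)] = 0; }
      else          { Iy[IDX(i, j)] = ex; tbY[IDX(i, j)] = 1; }
    }
  }
  // terminal: free trailing reference; never end in Iy (a trailing deletion
  // is dominated by stopping earlier). Smallest j wins ties; M preferred.
  int bestScore = NEG_INF, bestJ = -1; unsigned char bestState = 0;
  for (int j = 0; j <= n; ++j) {
    if (M[IDX(m, j)] > bestScore) { bestScore = M[IDX(m, j)]; bestJ = j; bestState = 0; }
    if (Ix[IDX(m, j)] > bestScore) { bestScore = Ix[IDX(m, j)]; bestJ = j; bestState = 1; }
  }
  if (bestJ < 0) stop("alignment failed");

  std::string ops;
  int i = m, j = bestJ; unsigned char st = bestState;
  while (i > 0) {
    if (st == 0) {
      ops.push_back(q[i - 1] == r[j - 1] ? 'M' : 'X');
      st = tbM[IDX(i, j)]; --i; --j;
    } else if (st == 1) {
      ops.push_back('I');
      st = (tbX[IDX(i, j)] == 0) ? 0 : 1; --i;
      if (st == 1) st = 1; // stay in Ix
      else st = 0;
    } else {
      ops.push_back('D');
      st = (tbY[IDX(i, j)] == 0) ? 0 : 2; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = bestScore, _["ops"] = ops,
                      _["ref_start"] = j, _["ref_end"] = bestJ);
  #undef IDX
}

// ---------------------------------------------------------------------------
// paired-read merging
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
    case 'T': return 'A'; case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a'; default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[i] = comp_base(s[s.size() - 1 - i]);
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// merge one pair; returns true on success.
static bool merge_core(const std::string &s1, const std::string &q1,
                       const std::string &s2, const std::string &q2,
                       int umi_len, int min_phred, int min_overlap,
                       double max_mm_frac, std::string &mseq,
                       std::string &mqual) {
  int l1 = (int)s1.size(), l2 = (int)s2.size();
  std::string s2rc = revcomp(s2);
  std::string q2r(q2.rbegin(), q2.rend());
  int best_o = -1;
  int omax = std::min(l1, l2);
  for (int o = omax; o >= min_overlap; --o) {
    int allowed = (int)std::floor(max_mm_frac * o);
    int mm = 0;
    const char *a = s1.c_str() + (l1 - o), *b = s2rc.c_str();
    for (int k = 0; k < o; ++k) {
      if (a[k] != b[k] && ++mm > allowed) break;
    }
    if (mm <= allowed) { best_o = o; break; } // longest overlap first
  }
  if (best_o < 0) return false;
  int o = best_o, L = l1 + l2 - o;
  mseq.assign(L, 'N'); mqual.assign(L, '!');
  for (int k = 0; k < l1 - o; ++k) { mseq[k] = s1[k]; mqual[k] = q1[k]; }
  for (int k = o; k < l2; ++k) { mseq[l1 - o + k] = s2rc[k]; mqual[l1 - o + k] = q2r[k]; }
  int lo = min_phred + 33;
  for (int k = 0; k < o; ++k) {
    int pos = l1 - o + k;
    char b1 = s1[pos], c1 = q1[pos];
    char b2 = s2rc[k], c2 = q2r[k];
    bool umi_zone = pos >= L - umi_len;
    if (!umi_zone) {
      // read1 primary; a low-quality call is overwritten from read2
      if (c1 < lo && c2 >= lo) { mseq[pos] = b2; mqual[pos] = c2; }
      else { mseq[pos] = b1; mqual[pos] = c1; }
    } else {
      // terminal UMI: read2 primary, correction inverted
      if (c2 < lo && c1 >= lo) { mseq[pos] = b1; mqual[pos] = c1; }
      else { mseq[pos] = b2; mqual[pos] = c2; }
    }
  }
  return true;
}

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector s1, CharacterVector q1, CharacterVector s2,
                     CharacterVector q2, int umi_len, int min_phred,
                     int min_overlap, double max_mm_frac) {
  int n = s1.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    std::string ms, mq;
    bool good = merge_core(as<std::string>(s1[i]), as<std::string>(q1[i]),
                           as<std::string>(s2[i]), as<std::string>(q2[i]),
                           umi_len, min_phred, min_overlap, max_mm_frac, ms, mq);
    ok[i] = good;
    if (good) { mseq[i] = ms; mqual[i] = mq; }
    else { mseq[i] = NA_STRING; mqual[i] = NA_STRING; }
  }
  return List::create(_["ok"] = ok, _["sequence"] = mseq, _["qualities"] = mqual);
}

// ---------------------------------------------------------------------------
// primer / constant-region / UMI identification and trimming
// ---------------------------------------------------------------------------

struct TrimResult {
  int status; // 0 ok, 2 primer_unassigned, 3 umi_undetermined
  int primer_idx; // 0-based
  std::string umi, insert, qual;
};

static TrimResult trim_core(const std::string &seq, const std::string &qual,
                            const std::vector<std::string> &primers,
                            int umi_len, const std::string &cr,
                            double max_edit_frac, int primer_window) {
  TrimResult res; res.status = 0; res.primer_idx = -1;
  int L = (int)seq.size();
  // primer: exact prefix fast path, panel order
  int p_end = -1;
  for (size_t p = 0; p < primers.size(); ++p) {
    const std::string &pr = primers[p];
    if ((int)pr.size() <= L &&
        std::memcmp(seq.c_str(), pr.c_str(), pr.size()) == 0) {
      res.primer_idx = (int)p; p_end = (int)pr.size(); break;
    }
  }
  if (res.primer_idx < 0) {
    int win = std::min(primer_window, L);
    int best_edits = 1 << 29;
    for (size_t p = 0; p < primers.size(); ++p) {
      const std::string &pr = primers[p];
      int max_e = (int)std::floor(max_edit_frac * pr.size());
      FuzzyHit h = fuzzy_core(pr.c_str(), (int)pr.size(), seq.c_str(), win, max_e);
      if (h.found && h.edits < best_edits) {
        best_edits = h.edits; res.primer_idx = (int)p; p_end = h.end;
      }
    }
    if (res.primer_idx < 0) { res.status = 2; return res; }
  }
  // UMI: terminal umi_len bases
  if (L < p_end + umi_len + 1) { res.status = 3; return res; }
  res.umi = seq.substr(L - umi_len, umi_len);
  for (char c : res.umi)
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { res.status = 3; return res; }
  // constant region adjacent to the UMI, if present
  int insert_end = L - umi_len;
  if (!cr.empty()) {
    int crl = (int)cr.size();
    int w0 = std::max(p_end, insert_end - crl - 2);
    if (insert_end - w0 >= crl - (int)std::floor(max_edit_frac * crl)) {
      std::string window = seq.substr(w0, insert_end - w0);
      FuzzyHit h = fuzzy_core(cr.c_str(), crl, window.c_str(),
                              (int)window.size(), (int)std::floor(max_edit_frac * crl));
      if (h.found) insert_end = w0 + h.start;
    }
  }
  if (insert_end <= p_end) { res.status = 3; return res; }
  res.insert = seq.substr(p_end, insert_end - p_end);
  res.qual = qual.substr(p_end, insert_end - p_end);
  return res;
}

// [[Rcpp::export]]
List cpp_identify_trim(CharacterVector seq, CharacterVector qual,
                       CharacterVector primers, int umi_len, std::string cr,
                       double max_edit_frac, int primer_window) {
  int n = seq.size();
  std::vector<std::string> pv(primers.size());
  for (int i = 0; i < primers.size(); ++i) pv[i] = as<std::string>(primers[i]);
  IntegerVector status(n), pidx(n);
  CharacterVector umi(n), insert(n), iqual(n);
  for (int i = 0; i < n; ++i) {
    TrimResult t = trim_core(as<std::string>(seq[i]), as<std::string>(qual[i]),
                             pv, umi_len, cr, max_edit_frac, primer_window);
    status[i] = t.status;
    pidx[i] = t.primer_idx + 1; // 1-based for R
    if (t.status == 0) { umi[i] = t.umi; insert[i] = t.insert; iqual[i] = t.qual; }
    else { umi[i] = NA_STRING; insert[i] = NA_STRING; iqual[i] = NA_STRING; }
  }
  return List::create(_["status"] = status, _["primer_idx"] = pidx,
                      _["umi"] = umi, _["insert"] = insert,
                      _["qualities"] = iqual);
}

// ---------------------------------------------------------------------------
// streaming FASTQ pair processing (gzip-transparent)
// ---------------------------------------------------------------------------

static bool gz_getline(gzFile f, std::string &out) {
  char buf[4096];
  out.clear();
  for (;;) {
    if (gzgets(f, buf, sizeof(buf)) == Z_NULL) return !out.empty();
    out += buf;
    if (!out.empty() && out.back() == '\n') {
      out.pop_back();
      if (!out.empty() && out.back() == '\r') out.pop_back();
      return true;
    }
  }
}

// [[Rcpp::export]]
List cpp_process_fastq(std::string r1_path, std::string r2_path,
                       CharacterVector primers, int umi_len, std::string cr,
                       int min_phred, int min_overlap, double max_mm_frac,
                       double max_edit_frac, int primer_window) {
  gzFile f1 = gzopen(r1_path.c_str(), "rb");
  if (!f1) stop("cannot open %s", r1_path);
  gzFile f2 = gzopen(r2_path.c_str(), "rb");
  if (!f2) { gzclose(f1); stop("cannot open %s", r2_path); }
  gzbuffer(f1, 1 << 20); gzbuffer(f2, 1 << 20);

  std::vector<std::string> pv(primers.size());
  for (int i = 0; i < primers.size(); ++i) pv[i] = as<std::string>(primers[i]);

  std::vector<int> k_pidx;
  std::vector<std::string> k_umi, k_insert, k_qual;
  std::vector<std::string> rej_id, rej_stage, rej_reason;
  long n_pairs = 0;

  std::string h1, s1, p1, q1, h2, s2, p2, q2;
  for (;;) {
    bool have1 = gz_getline(f1, h1);
    bool have2 = gz_getline(f2, h2);
    if (!have1 && !have2) break;
    if (have1 != have2) { gzclose(f1); gzclose(f2);
      stop("FASTQ files have different numbers of records"); }
    if (h1.empty() && h2.empty()) continue;
    if (h1.empty() || h1[0] != '@' || h2.empty() || h2[0] != '@') {
      gzclose(f1); gzclose(f2);
      stop("malformed FASTQ header at record %ld", n_pairs + 1);
    }
    if (!gz_getline(f1, s1) || !gz_getline(f1, p1) || !gz_getline(f1, q1) ||
        !gz_getline(f2, s2) || !gz_getline(f2, p2) || !gz_getline(f2, q2)) {
      gzclose(f1); gzclose(f2);
      stop("truncated FASTQ record %ld", n_pairs + 1);
    }
    if (s1.size() != q1.size() || s2.size() != q2.size()) {
      gzclose(f1); gzclose(f2);
      stop("sequence/quality length mismatch at record %ld", n_pairs + 1);
    }
    ++n_pairs;
    std::string id = h1.substr(1);
    size_t sp = id.find_first_of(" /\t");
    if (sp != std::string::npos) id = id.substr(0, sp);

    std::string ms, mq;
    if (!merge_core(s1, q1, s2, q2, umi_len, min_phred, min_overlap,
                    max_mm_frac, ms, mq)) {
      rej_id.push_back(id); rej_stage.push_back("merge");
      rej_reason.push_back("no_overlap");
      continue;
    }
    TrimResult t = trim_core(ms, mq, pv, umi_len, cr, max_edit_frac,
                             primer_window);
    if (t.status == 2) {
      rej_id.push_back(id); rej_stage.push_back("trim");
      rej_reason.push_back("primer_unassigned");
    } else if (t.status == 3) {
      rej_id.push_back(id); rej_stage.push_back("trim");
      rej_reason.push_back("umi_undetermined");
    } else {
      k_pidx.push_back(t.primer_idx + 1);
      k_umi.push_back(t.umi);
      k_insert.push_back(t.insert);
      k_qual.push_back(t.qual);
    }
  }
  gzclose(f1); gzclose(f2);
  return List::create(
      _["n_pairs"] = (double)n_pairs,
      _["primer_idx"] = wrap(k_pidx), _["umi"] = wrap(k_umi),
      _["insert"] = wrap(k_insert), _["qualities"] = wrap(k_qual),
      _["reject_id"] = wrap(rej_id), _["reject_stage"] = wrap(rej_stage),
      _["reject_reason"] = wrap(rej_reason));
}

// ---------------------------------------------------------------------------
// UMI-family consensus voting
// ---------------------------------------------------------------------------

static inline int base_idx(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
               case 'T': return 3; default: return 4; }
}
static const char BASES[5] = {'A', 'C', 'G', 'T', 'N'};

// seqs/quals are sorted so that each family occupies a contiguous run given
// by fam_sizes. Families below min_size are discarded (keep = FALSE).
// [[Rcpp::export]]
List cpp_vote_families(CharacterVector seqs, CharacterVector quals,
                       IntegerVector fam_sizes, int min_size) {
  int nf = fam_sizes.size();
  LogicalVector keep(nf);
  CharacterVector consensus(nf);
  int off = 0;
  for (int f = 0; f < nf; ++f) {
    int sz = fam_sizes[f];
    if (sz < min_size) { keep[f] = false; consensus[f] = NA_STRING; off += sz; continue; }
    // modal member length; tie -> shorter
    std::vector<int> lens(sz);
    for (int k = 0; k < sz; ++k) lens[k] = LENGTH(STRING_ELT(seqs, off + k));
    std::vector<int> uniq(lens); std::sort(uniq.begin(), uniq.end());
    uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
    int modal = uniq[0], modal_n = 0;
    for (int u : uniq) {
      int c = 0;
      for (int l : lens) if (l == u) ++c;
      if (c > modal_n) { modal_n = c; modal = u; } // ties keep smaller u
    }
    std::string cons(modal, 'N');
    std::vector<int> cnt(5), qsum(5);
    for (int pos = 0; pos < modal; ++pos) {
      std::fill(cnt.begin(), cnt.end(), 0);
      std::fill(qsum.begin(), qsum.end(), 0);
      for (int k = 0; k < sz; ++k) {
        if (lens[k] != modal) continue;
        const char *s = CHAR(STRING_ELT(seqs, off + k));
        const char *q = CHAR(STRING_ELT(quals, off + k));
        int b = base_idx(s[pos]);
        cnt[b] += 1;
        qsum[b] += (int)q[pos] - 33;
      }
      int best = -1, bc = -1, bq = -1; bool tie_unresolved = false;
      for (int b = 0; b < 5; ++b) {
        if (cnt[b] == 0) continue;
        if (cnt[b] > bc || (cnt[b] == bc && qsum[b] > bq)) {
          best = b; bc = cnt[b]; bq = qsum[b]; tie_unresolved = false;
        } else if (cnt[b] == bc && qsum[b] == bq) {
          tie_unresolved = true;
        }
      }
      cons[pos] = (best < 0 || tie_unresolved) ? 'N' : BASES[best];
    }
    keep[f] = true;
    consensus[f] = cons;
    off += sz;
  }
  return List::create(_["keep"] = keep, _["consensus"] = consensus);
}

// ---------------------------------------------------------------------------
// reference-standard simulator
// ---------------------------------------------------------------------------

static inline char random_base() {
  int k = (int)(unif_rand() * 4.0);
  if (k > 3) k = 3;
  return "ACGT"[k];
}

static inline char mutate_base(char c) {
  char b = random_base();
  while (b == c) b = random_base();
  return b;
}

static void apply_random_subs(std::string &s, double rate) {
  if (rate <= 0) return;
  int k = (int)R::rbinom((double)s.size(), rate);
  for (int e = 0; e < k; ++e) {
    int pos = (int)(unif_rand() * s.size());
    if (pos >= (int)s.size()) pos = (int)s.size() - 1;
    s[pos] = mutate_base(s[pos]);
  }
}

// sequencing errors under a position-dependent error profile, applied by
// thinning: draw a Binomial(len, pmax) number of candidate positions, accept
// each with p[pos]/pmax.
static void apply_seq_errors(std::string &s, const std::vector<double> &perr,
                             double pmax) {
  if (pmax <= 0) return;
  int len = (int)s.size();
  int k = (int)R::rbinom((double)len, pmax);
  for (int e = 0; e < k; ++e) {
    int pos = (int)(unif_rand() * len);
    if (pos >= len) pos = len - 1;
    if (unif_rand() * pmax < perr[pos]) s[pos] = mutate_base(s[pos]);
  }
}

// [[Rcpp::export]]
List cpp_simulate_run(std::string r1_path, std::string r2_path,
                      CharacterVector locus_id, CharacterVector primer_seq,
                      CharacterVector wt_source, CharacterVector var_source,
                      NumericVector vaf_pct, IntegerVector n_molecules,
                      int frag_min, int frag_max, int read_len, int umi_len,
                      std::string cr, double pcr_lambda, double pol_rate,
                      IntegerVector qual_profile) {
  int nloci = locus_id.size();
  if (read_len != qual_profile.size()) stop("quality profile length must equal read length");
  std::vector<double> perr(read_len);
  std::string qstr(read_len, '!');
  double pmax = 0.0;
  for (int i = 0; i < read_len; ++i) {
    perr[i] = std::pow(10.0, -qual_profile[i] / 10.0);
    if (perr[i] > pmax) pmax = perr[i];
    qstr[i] = (char)(qual_profile[i] + 33);
  }
  gzFile f1 = gzopen(r1_path.c_str(), "wb1");
  if (!f1) stop("cannot open %s for writing", r1_path);
  gzFile f2 = gzopen(r2_path.c_str(), "wb1");
  if (!f2) { gzclose(f1); stop("cannot open %s for writing", r2_path); }
  gzbuffer(f1, 1 << 20); gzbuffer(f2, 1 << 20);

  IntegerVector n_variant(nloci);
  double total_pairs = 0;
  int crl = (int)cr.size();
  char header[128];

  for (int li = 0; li < nloci; ++li) {
    std::string lid = as<std::string>(locus_id[li]);
    std::string primer = as<std::string>(primer_seq[li]);
    std::string wt = as<std::string>(wt_source[li]);
    std::string var = as<std::string>(var_source[li]);
    double p_var = vaf_pct[li] / 100.0;
    int plen = (int)primer.size();
    int nmol = n_molecules[li];
    int nv = 0;
    for (int mi = 0; mi < nmol; ++mi) {
      int L = frag_min + (int)(unif_rand() * (frag_max - frag_min + 1));
      if (L > frag_max) L = frag_max;
      bool is_var = unif_rand() < p_var;
      if (is_var) ++nv;
      int ins_len = L - plen - crl - umi_len;
      const std::string &src = is_var ? var : wt;
      if (ins_len < 1 || ins_len > (int)src.size())
        stop("fragment length range incompatible with panel geometry");
      std::string mol;
      mol.reserve(L);
      mol += primer;
      mol.append(src, 0, ins_len);
      mol += cr;
      for (int u = 0; u < umi_len; ++u) mol.push_back(random_base());
      // first-cycle polymerase errors propagate to every copy (jackpot)
      apply_random_subs(mol, pol_rate);
      int ncopies = 1 + (int)R::rpois(pcr_lambda);
      for (int ci = 0; ci < ncopies; ++ci) {
        std::string copy = mol;
        apply_random_subs(copy, pol_rate);
        int rl = std::min(read_len, L);
        std::string r1 = copy.substr(0, rl);
        std::string r2 = revcomp(copy).substr(0, rl);
        apply_seq_errors(r1, perr, pmax);
        apply_seq_errors(r2, perr, pmax);
        std::string qv = qstr.substr(0, rl);
        snprintf(header, sizeof(header), "@%s:%d:%d", lid.c_str(), mi, ci);
        gzputs(f1, header); gzputc(f1, '\n');
        gzputs(f1, r1.c_str()); gzputs(f1, "\n+\n");
        gzputs(f1, qv.c_str()); gzputc(f1, '\n');
        gzputs(f2, header); gzputc(f2, '\n');
        gzputs(f2, r2.c_str()); gzputs(f2, "\n+\n");
        gzputs(f2, qv.c_str()); gzputc(f2, '\n');
        total_pairs += 1;
      }
    }
    n_variant[li] = nv;
  }
  gzclose(f1); gzclose(f2);
  return List::create(_["n_variant"] = n_variant, _["n_pairs"] = total_pairs);
}
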