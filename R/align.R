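# Semi-global alignment under multiple scoring schemes, least-variants
# selection, variant extraction, whitelist filtering, and the long-indel
# string search.

#' Define a scoring scheme
#'
#' @param scheme_id Short identifier (reported in alignment results).
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_model `"linear"` or `"affine"`.
#' @param gap_open For affine schemes the cost of the first gap base; for
#'   linear schemes the per-base gap cost (must be < 0).
#' @param gap_extend Cost of each additional gap base (affine only; a gap of
#'   length k costs `gap_open + (k - 1) * gap_extend`).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(scheme_id, match, mismatch,
                           gap_model = c("linear", "affine"),
                           gap_open, gap_extend = gap_open) {
  gap_model <- match.arg(gap_model)
  stopifnot(match > 0, mismatch < 0, gap_open < 0)
  if (gap_model == "affine") stopifnot(gap_extend < 0)
  if (gap_model == "linear") gap_extend <- gap_open
  structure(list(scheme_id = scheme_id, match = as.integer(match),
                 mismatch = as.integer(mismatch), gap_model = gap_model,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Default scoring-scheme set
#'
#' Three schemes spanning the linear/affine and gap-tolerant/
#' mismatch-tolerant space; list order is the tie-break priority. All are
#' configurable via [run_config()].
#'
#' @return List of [scoring_scheme()] objects: S1 linear (+1/-1, gap -2),
#'   S2 affine (+1/-1, open -6, extend -1), S3 affine (+2/-3, open -5,
#'   extend -2).
#' @export
default_schemes <- function() {
  list(scoring_scheme("S1", 1, -1, "linear", -2),
       scoring_scheme("S2", 1, -1, "affine", -6, -1),
       scoring_scheme("S3", 2, -3, "affine", -5, -2))
}

#' Semi-global alignment of a fragment to its reference window
#'
#' The query (consensus fragment) is aligned end-to-end while end-gaps on
#' the reference window are free — appropriate because primer anchoring
#' guarantees the fragment lies inside its window. Traceback is
#' deterministic (diagonal > up > left on equal scores).
#'
#' @param query Fragment sequence (non-empty).
#' @param ref_window Reference window (non-empty).
#' @param scheme A [scoring_scheme()].
#' @return An `alignment_result` list: `scheme_id`, `score`, `ops`
#'   (per-base operation string over M/X/I/D), `ref_start`/`ref_end`
#'   (0-based window offsets of the aligned reference span), `events`
#'   (data frame of raw variant events in window coordinates) and
#'   `n_variants` (number of events, counting one MNP or one indel run as
#'   one variant).
#' @export
semi_global_align <- function(query, ref_window, scheme) {
  stopifnot(nchar(query) > 0, nchar(ref_window) > 0)
  a <- cpp_semi_global(query, ref_window, scheme$match, scheme$mismatch,
                       scheme$gap_open, scheme$gap_extend)
  events <- parse_alignment_events(a$ops, query, ref_window, a$ref_start)
  structure(list(scheme_id = scheme$scheme_id, score = a$score,
                 ops = a$ops, ref_start = a$ref_start, ref_end = a$ref_end,
                 query = query, ref_window = ref_window, events = events,
                 n_variants = nrow(events)),
            class = "alignment_result")
}

# Parse an operation string into raw events in window coordinates.
# Maximal runs of X become one substitution event (MNP when length > 1);
# maximal runs of I/D become one insertion/deletion event. `pos` is the
# 1-based window position of the first reference base involved (for
# insertions, of the reference base before which the bases are inserted).
parse_alignment_events <- function(ops, query, ref_window, ref_start) {
  op <- strsplit(ops, "")[[1]]
  n <- length(op)
  ev_type <- character(0); ev_pos <- integer(0)
  ev_ref <- character(0); ev_alt <- character(0)
  qi <- 0L                 # query bases consumed
  rj <- as.integer(ref_start)  # reference bases consumed (window offset)
  k <- 1L
  while (k <= n) {
    o <- op[k]
    if (o == "M") { qi <- qi + 1L; rj <- rj + 1L; k <- k + 1L; next }
    j <- k
    while (j < n && op[j + 1L] == o) j <- j + 1L
    len <- j - k + 1L
    if (o == "X") {
      ev_type <- c(ev_type, "sub")
      ev_pos <- c(ev_pos, rj + 1L)
      ev_ref <- c(ev_ref, substr(ref_window, rj + 1L, rj + len))
      ev_alt <- c(ev_alt, substr(query, qi + 1L, qi + len))
      qi <- qi + len; rj <- rj + len
    } else if (o == "I") {
      ev_type <- c(ev_type, "ins")
      ev_pos <- c(ev_pos, rj + 1L)
      ev_ref <- c(ev_ref, "")
      ev_alt <- c(ev_alt, substr(query, qi + 1L, qi + len))
      qi <- qi + len
    } else { # D
      ev_type <- c(ev_type, "del")
      ev_pos <- c(ev_pos, rj + 1L)
      ev_ref <- c(ev_ref, substr(ref_window, rj + 1L, rj + len))
      ev_alt <- c(ev_alt, "")
      rj <- rj + len
    }
    k <- j + 1L
  }
  data.frame(type = ev_type, pos = ev_pos, ref = ev_ref, alt = ev_alt,
             stringsAsFactors = FALSE)
}

#' Select the least-variants alignment across scoring schemes
#'
#' Runs every configured scheme and keeps the alignment with the fewest
#' variant events; ties go to the higher score, then to scheme order. A
#' winner with more than `max_variants` events is considered too disparate
#' and the fragment is discarded.
#'
#' @inheritParams semi_global_align
#' @param schemes List of [scoring_scheme()] objects (priority order).
#' @param max_variants Disparity cap (default 12; one MNP or one indel run
#'   counts as one variant).
#' @return The winning `alignment_result`, or `NULL` when the fragment is
#'   discarded as too disparate.
#' @export
best_alignment <- function(query, ref_window, schemes = default_schemes(),
                           max_variants = 12L) {
  stopifnot(length(schemes) >= 1)
  best <- NULL
  for (sc in schemes) {
    a <- semi_global_align(query, ref_window, sc)
    if (is.null(best) || a$n_variants < best$n_variants ||
        (a$n_variants == best$n_variants && a$score > best$score)) {
      best <- a
    }
  }
  if (best$n_variants > max_variants) return(NULL)
  best
}

# Left-align an indel event against the reference window (VCF convention:
# shift left while the base before the event equals its last base).
left_align_event <- function(type, pos, seq, ref_window) {
  if (type == "ins") {
    while (pos > 1L &&
           substr(ref_window, pos - 1L, pos - 1L) ==
           substr(seq, nchar(seq), nchar(seq))) {
      seq <- paste0(substr(ref_window, pos - 1L, pos - 1L),
                    substr(seq, 1L, nchar(seq) - 1L))
      pos <- pos - 1L
    }
  } else { # del
    len <- nchar(seq)
    while (pos > 1L &&
           substr(ref_window, pos - 1L, pos - 1L) ==
           substr(ref_window, pos + len - 1L, pos + len - 1L)) {
      pos <- pos - 1L
      seq <- substr(ref_window, pos, pos + len - 1L)
    }
  }
  list(pos = pos, seq = seq)
}

#' Extract whitelist-comparable variants from an alignment
#'
#' Converts the raw alignment events into genomic variants: adjacent
#' substitutions are one MNP; indels are left-aligned against the reference
#' and reported VCF-style with a one-base anchor; indels longer than 10 bp
#' are dropped from this path (they are long-indel territory, see
#' [long_indel_scan()]); events whose alternate allele contains `N` never
#' support a call and are dropped. Genomic positions are computed from the
#' segment start plus the window offset.
#'
#' @param alignment An `alignment_result` from [semi_global_align()] or
#'   [best_alignment()].
#' @param segment The segment row the window was cut from.
#' @param insert_offset 0-based segment offset where the window begins.
#' @return Data frame with `chrom`, `pos` (1-based genomic), `ref`, `alt`,
#'   `vclass` (`SNV`, `MNP`, `INS`, `DEL`).
#' @export
extract_variants <- function(alignment, segment, insert_offset) {
  ev <- alignment$events
  out <- list()
  win <- alignment$ref_window
  for (k in seq_len(nrow(ev))) {
    type <- ev$type[k]
    if (type == "sub") {
      if (grepl("N", ev$alt[k], fixed = TRUE)) next
      len <- nchar(ev$ref[k])
      out[[length(out) + 1L]] <- data.frame(
        wpos = ev$pos[k], ref = ev$ref[k], alt = ev$alt[k],
        vclass = if (len == 1L) "SNV" else "MNP", stringsAsFactors = FALSE)
    } else {
      indel_seq <- if (type == "ins") ev$alt[k] else ev$ref[k]
      if (nchar(indel_seq) > MAX_SHORT_INDEL) next
      if (grepl("N", indel_seq, fixed = TRUE)) next
      la <- left_align_event(type, ev$pos[k], indel_seq, win)
      if (la$pos > 1L) {
        anchor <- substr(win, la$pos - 1L, la$pos - 1L)
        if (type == "ins") {
          out[[length(out) + 1L]] <- data.frame(
            wpos = la$pos - 1L, ref = anchor,
            alt = paste0(anchor, la$seq), vclass = "INS",
            stringsAsFactors = FALSE)
        } else {
          out[[length(out) + 1L]] <- data.frame(
            wpos = la$pos - 1L, ref = paste0(anchor, la$seq), alt = anchor,
            vclass = "DEL", stringsAsFactors = FALSE)
        }
      } else {
        # event at the window edge: anchor on the following base
        after <- la$pos + if (type == "del") nchar(la$seq) else 0L
        anchor <- substr(win, after, after)
        if (type == "ins") {
          out[[length(out) + 1L]] <- data.frame(
            wpos = la$pos, ref = anchor, alt = paste0(la$seq, anchor),
            vclass = "INS", stringsAsFactors = FALSE)
        } else {
          out[[length(out) + 1L]] <- data.frame(
            wpos = la$pos, ref = paste0(la$seq, anchor), alt = anchor,
            vclass = "DEL", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      vclass = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  data.frame(chrom = segment$chrom,
             pos = segment$start + insert_offset + out$wpos - 1L,
             ref = out$ref, alt = out$alt, vclass = out$vclass,
             stringsAsFactors = FALSE)
}

#' Keep only whitelisted variants
#'
#' @param raw Data frame of variants (`chrom`, `pos`, `ref`, `alt`).
#' @param whitelist The panel whitelist data frame.
#' @return `raw` rows matching a whitelist entry on (chrom, pos, ref, alt),
#'   with a `target_id` column prepended.
#' @export
whitelist_filter <- function(raw, whitelist) {
  if (nrow(raw) == 0) {
    return(cbind(data.frame(target_id = character(),
                            stringsAsFactors = FALSE), raw))
  }
  key <- paste(raw$chrom, raw$pos, raw$ref, raw$alt, sep = "\r")
  wkey <- paste(whitelist$chrom, whitelist$pos, whitelist$ref,
                whitelist$alt, sep = "\r")
  m <- match(key, wkey)
  keep <- !is.na(m)
  cbind(data.frame(target_id = whitelist$target_id[m[keep]],
                   stringsAsFactors = FALSE),
        raw[keep, , drop = FALSE])
}

#' Scan fragments for predefined long indels
#'
#' Long indels are identified by an exact (hard-coded) substring search of
#' each prebuilt search string (see [build_search_string()]) in the
#' fragment sequence; a single mismatch defeats the search by design.
#'
#' @param fragment_sequence Character vector of fragment sequences.
#' @param search_strings Named character vector (names = target ids) of
#'   prebuilt search strings.
#' @return Data frame with `fragment` (index) and `target_id` for each hit.
#' @export
long_indel_scan <- function(fragment_sequence, search_strings) {
  hits <- list()
  for (tid in names(search_strings)) {
    idx <- which(grepl(search_strings[[tid]], fragment_sequence,
                       fixed = TRUE))
    if (length(idx) > 0) {
      hits[[length(hits) + 1L]] <- data.frame(
        fragment = idx, target_id = tid, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(fragment = integer(), target_id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Align and call all fragments of a sample
#'
#' Bulk driver: each fragment is aligned to the window of its assigned
#' primer (segment slice from the insert offset, padded by `config$pad`
#' bases to tolerate indels). Fragments identical to the reference slice
#' take a fast path with zero variants. Variants are extracted from the
#' least-variants alignment and filtered against the whitelist; the
#' long-indel string search runs on all surviving fragments.
#'
#' @param fragments Fragment data frame from [collapse_reads()].
#' @param bundle A `panel_bundle`.
#' @param config A [run_config()].
#' @return A list with `observations` (one row per fragment x whitelist
#'   variant: `fragment`, `target_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `vclass`), `spans` (per surviving fragment: `fragment`, `primer_id`,
#'   `segment_id`, `span_start`, `span_end` in 1-based segment
#'   coordinates), `long_hits` (fragment x long-indel target) and
#'   `n_too_disparate`.
#' @export
call_fragments <- function(fragments, bundle, config = run_config()) {
  nfrag <- nrow(fragments)
  seg_of_primer <- match(bundle$primers$segment_id,
                         bundle$segments$segment_id)
  pidx <- match(fragments$primer_id, bundle$primers$primer_id)
  if (anyNA(pidx)) stop("fragment with unknown primer_id", call. = FALSE)

  obs <- list(); spans <- list(); n_disparate <- 0L
  for (p in sort(unique(pidx))) {
    rows <- which(pidx == p)
    seg <- bundle$segments[seg_of_primer[p], ]
    off <- bundle$primers$insert_offset[p]
    seqs <- fragments$sequence[rows]
    lens <- nchar(seqs)
    seg_len <- nchar(seg$sequence)
    expected <- substr(rep(seg$sequence, length(rows)), off + 1L, off + lens)
    fast <- seqs == expected
    # fast path: exact reference match, zero variants
    if (any(fast)) {
      spans[[length(spans) + 1L]] <- data.frame(
        fragment = rows[fast], primer_id = fragments$primer_id[rows[fast]],
        segment_id = seg$segment_id, span_start = off + 1L,
        span_end = off + lens[fast], stringsAsFactors = FALSE)
    }
    for (i in which(!fast)) {
      win_end <- min(off + lens[i] + config$pad, seg_len)
      win <- substr(seg$sequence, off + 1L, win_end)
      a <- best_alignment(seqs[i], win, config$schemes,
                          config$max_variants_per_fragment)
      if (is.null(a)) { n_disparate <- n_disparate + 1L; next }
      spans[[length(spans) + 1L]] <- data.frame(
        fragment = rows[i], primer_id = fragments$primer_id[rows[i]],
        segment_id = seg$segment_id, span_start = off + a$ref_start + 1L,
        span_end = off + a$ref_end, stringsAsFactors = FALSE)
      v <- extract_variants(a, seg, off)
      v <- whitelist_filter(v, bundle$whitelist)
      if (nrow(v) > 0) {
        obs[[length(obs) + 1L]] <- cbind(
          data.frame(fragment = rows[i], stringsAsFactors = FALSE), v)
      }
    }
  }
  spans <- if (length(spans) > 0) do.call(rbind, spans) else
    data.frame(fragment = integer(), primer_id = character(),
               segment_id = character(), span_start = integer(),
               span_end = integer(), stringsAsFactors = FALSE)
  observations <- if (length(obs) > 0) do.call(rbind, obs) else
    data.frame(fragment = integer(), target_id = character(),
               chrom = character(), pos = integer(), ref = character(),
               alt = character(), vclass = character(),
               stringsAsFactors = FALSE)

  long_hits <- data.frame(fragment = integer(), target_id = character(),
                          stringsAsFactors = FALSE)
  if (nrow(bundle$long_indels) > 0 && nfrag > 0) {
    ss <- vapply(seq_len(nrow(bundle$long_indels)), function(k) {
      def <- bundle$long_indels[k, ]
      seg <- bundle$segments[match(def$segment_id,
                                   bundle$segments$segment_id), ]
      build_search_string(def, seg)
    }, character(1))
    names(ss) <- bundle$long_indels$target_id
    keep_idx <- spans$fragment
    lh <- long_indel_scan(fragments$sequence[keep_idx], ss)
    if (nrow(lh) > 0) {
      lh$fragment <- keep_idx[lh$fragment]
      long_hits <- lh
    }
  }
  rownames(observations) <- NULL; rownames(spans) <- NULL
  list(observations = observations, spans = spans, long_hits = long_hits,
       n_too_disparate = n_disparate)
}
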