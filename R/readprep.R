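# Read preparation: pair merging with quality-based correction, then fuzzy
# identification and trimming of primer, constant region and UMI.

#' Fuzzy (edit-distance) substring search
#'
#' Finds the substring of `text` with minimal Levenshtein distance to
#' `pattern` (substitutions, insertions and deletions all count as one
#' edit). A match is accepted when its edit count is at most
#' `floor(max_edit_frac * nchar(pattern))` — by default up to 10% of the
#' pattern's letters may be altered, so patterns shorter than 10 nt must
#' match exactly. Ties are broken by the smallest start, then the smallest
#' end.
#'
#' @param pattern Non-empty DNA string to search for.
#' @param text Text to search in.
#' @param max_edit_frac Maximum fraction of pattern letters that may be
#'   edited (default 0.10).
#' @return A list with 0-based `start`, exclusive `end` and `edits`, or
#'   `NULL` when no acceptable match exists.
#' @examples
#' fuzzy_find("ACGTACGTAC", "TTACGTACGTACTT")
#' @export
fuzzy_find <- function(pattern, text, max_edit_frac = 0.10) {
  stopifnot(nchar(pattern) > 0)
  max_edits <- floor(max_edit_frac * nchar(pattern))
  hit <- cpp_fuzzy_find(pattern, text, as.integer(max_edits))
  if (is.null(hit)) return(NULL)
  list(start = unname(hit["start"]), end = unname(hit["end"]),
       edits = unname(hit["edits"]))
}

#' Merge a read pair into a quality-corrected consensus read
#'
#' Read 2 is reverse-complemented and anchored to read 1 by the longest
#' suffix-prefix overlap of at least `min_overlap` bases with at most 10%
#' mismatches; non-overlapping tails are concatenated. Within the overlap
#' read 1 is the primary source: a read-1 base below `min_phred` is
#' overwritten by the read-2 base when that base is at or above `min_phred`
#' (the corrected position inherits the donor's quality). In the terminal
#' UMI segment (the last `umi_length` bases, best covered by read 2) the
#' roles are inverted. When both mates are below `min_phred` the primary
#' base is kept at its observed quality — downstream family voting is the
#' error filter.
#'
#' @param read1_seq,read1_qual,read2_seq,read2_qual Mate sequences and
#'   Phred+33 quality strings.
#' @param bundle A `panel_bundle` (supplies `umi_length`).
#' @param min_phred Minimum Phred score considered reliable (default 20).
#' @param min_overlap Minimum acceptable mate overlap in bases (default 20).
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return A list with `sequence` and `qualities`, or `NULL` when no
#'   acceptable overlap exists (reason `no_overlap`).
#' @export
merge_pair <- function(read1_seq, read1_qual, read2_seq, read2_qual, bundle,
                       min_phred = 20L, min_overlap = 20L,
                       max_mismatch_frac = 0.10) {
  stopifnot(nchar(read1_seq) == nchar(read1_qual),
            nchar(read2_seq) == nchar(read2_qual),
            nchar(read1_seq) > 0, nchar(read2_seq) > 0)
  out <- cpp_merge_pairs(read1_seq, read1_qual, read2_seq, read2_qual,
                         bundle$umi_length, as.integer(min_phred),
                         as.integer(min_overlap), max_mismatch_frac)
  if (!out$ok[1]) return(NULL)
  list(sequence = as.character(out$sequence[1]),
       qualities = as.character(out$qualities[1]))
}

#' Identify primer and UMI, trim to the insert
#'
#' The panel primer is located within the first 44 bases of the merged read
#' (the maximum primer length) by [fuzzy_find()]; among acceptable primers
#' the one with fewest edits wins (ties: panel order). The UMI is the
#' terminal `umi_length` bases; the constant region, when present adjacent
#' to the UMI, is located by fuzzy matching and removed. The returned
#' sequence is the insert only.
#'
#' @param merged A list with `sequence` and `qualities` (from
#'   [merge_pair()]).
#' @param bundle A `panel_bundle`.
#' @param max_edit_frac Fuzzy-match edit budget (default 0.10).
#' @return A list with `sequence`, `qualities`, `primer_id`, `umi`, or a
#'   character scalar naming the rejection reason (`"primer_unassigned"`,
#'   `"umi_undetermined"`).
#' @export
identify_and_trim <- function(merged, bundle, max_edit_frac = 0.10) {
  out <- cpp_identify_trim(merged$sequence, merged$qualities,
                           bundle$primers$sequence, bundle$umi_length,
                           bundle$constant_region, max_edit_frac,
                           MAX_PRIMER_LEN)
  st <- out$status[1]
  if (st == 2L) return("primer_unassigned")
  if (st != 0L) return("umi_undetermined")
  list(sequence = as.character(out$insert[1]),
       qualities = as.character(out$qualities[1]),
       primer_id = bundle$primers$primer_id[out$primer_idx[1]],
       umi = as.character(out$umi[1]))
}

#' Process a paired FASTQ sample into consensus reads
#'
#' Streams a (optionally gzipped) FASTQ pair through merging and trimming
#' and returns the surviving consensus reads plus a per-pair rejection log.
#'
#' @param r1_path,r2_path Paths to the mate FASTQ files.
#' @param bundle A `panel_bundle`.
#' @param config A [run_config()] list (supplies `min_phred`,
#'   `min_overlap`, `max_mismatch_frac`, `max_edit_frac`).
#' @return A list with `reads` (data frame: `primer_id`, `umi`, `sequence`,
#'   `qualities`), `rejects` (data frame: `pair_id`, `stage`, `reason`) and
#'   `n_pairs`.
#' @export
process_fastq <- function(r1_path, r2_path, bundle, config = run_config()) {
  if (!file.exists(r1_path)) stop("file not found: ", r1_path, call. = FALSE)
  if (!file.exists(r2_path)) stop("file not found: ", r2_path, call. = FALSE)
  out <- cpp_process_fastq(r1_path, r2_path, bundle$primers$sequence,
                           bundle$umi_length, bundle$constant_region,
                           as.integer(config$min_phred),
                           as.integer(config$min_overlap),
                           config$max_mismatch_frac, config$max_edit_frac,
                           MAX_PRIMER_LEN)
  reads <- data.frame(
    primer_id = bundle$primers$primer_id[out$primer_idx],
    umi = out$umi, sequence = out$insert, qualities = out$qualities,
    stringsAsFactors = FALSE)
  rejects <- data.frame(pair_id = out$reject_id, stage = out$reject_stage,
                        reason = out$reject_reason, stringsAsFactors = FALSE)
  list(reads = reads, rejects = rejects, n_pairs = out$n_pairs)
}
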