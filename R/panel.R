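# Panel bundle: reference segments, primers, whitelist, long-indel
# definitions. All user-facing coordinates are 1-based inclusive.

MAX_PRIMER_LEN <- 44L
MAX_SHORT_INDEL <- 10L
LONG_INDEL_FLANK <- 5L

#' Load and cross-validate a panel bundle
#'
#' Reads the four panel files — reference segments (FASTA, one record per
#' segment), primer definitions, the variant whitelist, and long-indel
#' search definitions — and returns a fully cross-validated bundle.
#'
#' Primer sequences are at most 44 nt (the screening window used during
#' trimming); whitelist insertions/deletions are at most 10 bp — longer
#' events belong in the long-indel table, where they are detected by exact
#' string search rather than alignment.
#'
#' @param reference_fasta Path to the reference-segment FASTA.
#' @param primers_tsv Path to a TSV with columns
#'   `primer_id, sequence, segment_id, insert_offset` (`insert_offset` is
#'   the 0-based offset on the segment where the insert begins).
#' @param whitelist_tsv Path to a TSV with columns
#'   `target_id, chrom, pos, ref, alt, vclass, gene`.
#' @param long_indels_tsv Path to a TSV with columns
#'   `target_id, segment_id, kind, event_sequence, anchor_pos`, or `NULL`
#'   for a panel without long-indel targets.
#' @param constant_region Constant-region sequence between insert and UMI
#'   (may be `""` for chemistries without one).
#' @param umi_length UMI length in bases.
#' @return An object of class `panel_bundle`: a list with elements
#'   `segments`, `primers`, `whitelist`, `long_indels` (data frames),
#'   `constant_region` and `umi_length`.
#' @seealso [demo_panel()], [write_panel()], [build_search_string()]
#' @export
load_panel <- function(reference_fasta, primers_tsv, whitelist_tsv,
                       long_indels_tsv = NULL,
                       constant_region = "ATTGGAGTCCT", umi_length = 12L) {
  segments <- read_segment_fasta(reference_fasta)
  primers <- read_tsv_strict(primers_tsv,
                             c("primer_id", "sequence", "segment_id",
                               "insert_offset"))
  whitelist <- read_tsv_strict(whitelist_tsv,
                               c("target_id", "chrom", "pos", "ref", "alt",
                                 "vclass", "gene"))
  long_indels <- if (is.null(long_indels_tsv)) {
    data.frame(target_id = character(), segment_id = character(),
               kind = character(), event_sequence = character(),
               anchor_pos = integer(), stringsAsFactors = FALSE)
  } else {
    read_tsv_strict(long_indels_tsv,
                    c("target_id", "segment_id", "kind", "event_sequence",
                      "anchor_pos"))
  }
  primers$insert_offset <- as.integer(primers$insert_offset)
  whitelist$pos <- as.integer(whitelist$pos)
  long_indels$anchor_pos <- as.integer(long_indels$anchor_pos)
  bundle <- structure(
    list(segments = segments, primers = primers, whitelist = whitelist,
         long_indels = long_indels,
         constant_region = toupper(constant_region),
         umi_length = as.integer(umi_length)),
    class = "panel_bundle")
  validate_panel(bundle)
  bundle
}

read_segment_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ends <- c(hdr[-1] - 1L, length(lines))
  ids <- character(length(hdr)); chrom <- character(length(hdr))
  start <- integer(length(hdr)); strand <- character(length(hdr))
  seqs <- character(length(hdr))
  for (k in seq_along(hdr)) {
    # header: >segment_id chrom:start:strand (description optional)
    fields <- strsplit(sub("^>", "", lines[hdr[k]]), "\\s+")[[1]]
    ids[k] <- fields[1]
    loc <- if (length(fields) >= 2) strsplit(fields[2], ":")[[1]] else character()
    chrom[k] <- if (length(loc) >= 1) loc[1] else ids[k]
    start[k] <- if (length(loc) >= 2) as.integer(loc[2]) else 1L
    strand[k] <- if (length(loc) >= 3) loc[3] else "+"
    seqs[k] <- toupper(paste0(lines[(hdr[k] + 1L):ends[k]], collapse = ""))
  }
  data.frame(segment_id = ids, chrom = chrom, start = start, strand = strand,
             sequence = seqs, stringsAsFactors = FALSE)
}

validate_panel <- function(bundle) {
  seg <- bundle$segments
  if (anyDuplicated(seg$segment_id))
    stop("duplicate segment_id in reference", call. = FALSE)
  bad <- !is_dna(seg$sequence) | nchar(seg$sequence) == 0
  if (any(bad))
    stop("segment(s) with empty or non-ACGTN sequence: ",
         paste(seg$segment_id[bad], collapse = ", "), call. = FALSE)
  if (any(seg$start < 1)) stop("segment start must be >= 1", call. = FALSE)
  if (!all(seg$strand %in% c("+", "-")))
    stop("segment strand must be '+' or '-'", call. = FALSE)

  pr <- bundle$primers
  too_long <- nchar(pr$sequence) > MAX_PRIMER_LEN
  if (any(too_long))
    stop(sprintf("primer(s) longer than %d nt: %s", MAX_PRIMER_LEN,
                 paste(pr$primer_id[too_long], collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(pr$sequence))
    stop("primer sequences must be unique", call. = FALSE)
  dangling <- !(pr$segment_id %in% seg$segment_id)
  if (any(dangling))
    stop("primer(s) referencing unknown segment_id: ",
         paste(pr$primer_id[dangling], collapse = ", "), call. = FALSE)
  seg_len <- nchar(seg$sequence)[match(pr$segment_id, seg$segment_id)]
  if (any(pr$insert_offset < 0 | pr$insert_offset >= seg_len))
    stop("primer insert_offset outside its segment", call. = FALSE)

  wl <- bundle$whitelist
  if (anyDuplicated(wl$target_id))
    stop("duplicate whitelist target_id", call. = FALSE)
  if (any(wl$ref == wl$alt))
    stop("whitelist ref and alt alleles must differ", call. = FALSE)
  if (!all(wl$vclass %in% c("SNV", "MNP", "INS", "DEL")))
    stop("whitelist vclass must be SNV, MNP, INS or DEL", call. = FALSE)
  indel_len <- abs(nchar(wl$ref) - nchar(wl$alt))
  too_big <- indel_len > MAX_SHORT_INDEL
  if (any(too_big))
    stop(sprintf(paste0("whitelist entry with indel longer than %d bp ",
                        "(move to long_indels): %s"), MAX_SHORT_INDEL,
                 paste(wl$target_id[too_big], collapse = ", ")),
         call. = FALSE)

  li <- bundle$long_indels
  if (nrow(li) > 0) {
    if (!all(li$kind %in% c("long_insertion", "long_deletion")))
      stop("long-indel kind must be long_insertion or long_deletion",
           call. = FALSE)
    if (any(nchar(li$event_sequence) <= MAX_SHORT_INDEL))
      stop(sprintf("long-indel event must exceed %d bp (shorter events ",
                   MAX_SHORT_INDEL) %+% "belong on the whitelist",
           call. = FALSE)
    dangling <- !(li$segment_id %in% seg$segment_id)
    if (any(dangling))
      stop("long-indel definition(s) referencing unknown segment_id: ",
           paste(li$target_id[dangling], collapse = ", "), call. = FALSE)
    sl <- nchar(seg$sequence)[match(li$segment_id, seg$segment_id)]
    if (any(li$anchor_pos < 1 | li$anchor_pos > sl))
      stop("long-indel anchor_pos outside its segment", call. = FALSE)
  }
  if (bundle$umi_length < 1) stop("umi_length must be positive", call. = FALSE)
  invisible(bundle)
}

`%+%` <- function(a, b) paste0(a, b)

#' Write a panel bundle back to disk
#'
#' Serialises a [load_panel()] bundle into the same four-file layout, such
#' that reloading yields an identical bundle.
#'
#' @param bundle A `panel_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths written.
#' @export
write_panel <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "reference.fasta")
  con <- file(fa, "w")
  seg <- bundle$segments
  for (k in seq_len(nrow(seg))) {
    writeLines(sprintf(">%s %s:%d:%s", seg$segment_id[k], seg$chrom[k],
                       seg$start[k], seg$strand[k]), con)
    writeLines(seg$sequence[k], con)
  }
  close(con)
  paths <- list(
    reference_fasta = fa,
    primers_tsv = write_tsv(bundle$primers, file.path(dir, "primers.tsv")),
    whitelist_tsv = write_tsv(bundle$whitelist,
                              file.path(dir, "whitelist.tsv")),
    long_indels_tsv = write_tsv(bundle$long_indels,
                                file.path(dir, "long_indels.tsv")))
  invisible(paths)
}

#' @export
print.panel_bundle <- function(x, ...) {
  cat("panel_bundle:",
      nrow(x$segments), "segments,",
      nrow(x$primers), "primers,",
      nrow(x$whitelist), "whitelist targets,",
      nrow(x$long_indels), "long-indel definitions\n")
  cat("  constant region:", if (nzchar(x$constant_region))
    x$constant_region else "(none)",
    " UMI length:", x$umi_length, "\n")
  invisible(x)
}

#' Build the exact search string for a predefined long indel
#'
#' Long indels (> 10 bp) are detected by exact substring search rather than
#' by alignment. For an insertion the search string is the inserted sequence
#' with 5 bp of reference flank on each side; for a deletion the two 5-bp
#' flanks are merged directly (the deleted span is cut out), so a deletion
#' search string always has length 10.
#'
#' @param def One row of the long-indel table (list or single-row data
#'   frame with `kind`, `event_sequence`, `anchor_pos`). For insertions
#'   `anchor_pos` is the 1-based position of the reference base immediately
#'   before the insertion point; for deletions it is the first deleted base.
#' @param segment The matching segment row (with `sequence`).
#' @return The search string (DNA).
#' @export
build_search_string <- function(def, segment) {
  seq <- segment$sequence
  anchor <- as.integer(def$anchor_pos)
  ev <- def$event_sequence
  fl <- LONG_INDEL_FLANK
  if (def$kind == "long_insertion") {
    if (anchor < fl || anchor + fl > nchar(seq))
      stop("insufficient flank around insertion anchor for target ",
           def$target_id, call. = FALSE)
    left <- substr(seq, anchor - fl + 1L, anchor)
    right <- substr(seq, anchor + 1L, anchor + fl)
    paste0(left, ev, right)
  } else if (def$kind == "long_deletion") {
    del_end <- anchor + nchar(ev) - 1L
    if (anchor <= fl || del_end + fl > nchar(seq))
      stop("insufficient flank around deletion span for target ",
           def$target_id, call. = FALSE)
    if (substr(seq, anchor, del_end) != ev)
      stop("deletion event_sequence does not match the reference span ",
           "for target ", def$target_id, call. = FALSE)
    left <- substr(seq, anchor - fl, anchor - 1L)
    right <- substr(seq, del_end + 1L, del_end + fl)
    paste0(left, right)
  } else {
    stop("unknown long-indel kind: ", def$kind, call. = FALSE)
  }
}

#' Path to the bundled demonstration panel
#'
#' The package ships a small, entirely synthetic 20-target demonstration
#' panel (the production panel of the assay this emulates is not public):
#' 20 reference segments across 15 gene labels carrying 16 SNV, 2 MNP,
#' 1 short-insertion and 1 short-deletion whitelist targets, plus one long
#' insertion and one long deletion definition.
#'
#' @return Directory containing `reference.fasta`, `primers.tsv`,
#'   `whitelist.tsv` and `long_indels.tsv`.
#' @export
demo_panel_dir <- function() {
  system.file("extdata", "demo_panel", package = "umivar", mustWork = TRUE)
}

#' Load the bundled demonstration panel
#'
#' @inheritParams load_panel
#' @return A `panel_bundle` (see [load_panel()]).
#' @examples
#' panel <- demo_panel()
#' panel
#' @export
demo_panel <- function(constant_region = "ATTGGAGTCCT", umi_length = 12L) {
  d <- demo_panel_dir()
  load_panel(file.path(d, "reference.fasta"),
             file.path(d, "primers.tsv"),
             file.path(d, "whitelist.tsv"),
             file.path(d, "long_indels.tsv"),
             constant_region = constant_region, umi_length = umi_length)
}
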