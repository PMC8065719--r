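# Mutation-table aggregation: per-variant count, coverage, frequency and
# the global VAF threshold flag.

#' Pipeline run configuration
#'
#' @param vaf_threshold_pct Global VAF threshold in percent (default 0.09);
#'   a variant passes when its frequency is greater than or equal to the
#'   threshold (inclusive — calls are made down to the threshold itself).
#' @param min_family_size Minimum UMI-family size (default 3).
#' @param max_variants_per_fragment Disparity cap per fragment (default 12).
#' @param min_phred Minimum reliable Phred score (default 20).
#' @param min_overlap Minimum mate overlap during merging (default 20).
#' @param max_mismatch_frac Maximum mismatch fraction in the mate overlap.
#' @param max_edit_frac Fuzzy-match edit budget for primer/constant-region
#'   identification (default 0.10).
#' @param pad Reference-window padding in bases (default 15).
#' @param schemes List of [scoring_scheme()]s (default [default_schemes()]).
#' @param seed Optional integer seed recorded in run manifests.
#' @return A list of class `umivar_config`.
#' @export
run_config <- function(vaf_threshold_pct = 0.09, min_family_size = 3L,
                       max_variants_per_fragment = 12L, min_phred = 20L,
                       min_overlap = 20L, max_mismatch_frac = 0.10,
                       max_edit_frac = 0.10, pad = 15L,
                       schemes = default_schemes(), seed = NULL) {
  stopifnot(vaf_threshold_pct >= 0, min_family_size > 0,
            max_variants_per_fragment > 0, min_phred > 0)
  structure(list(vaf_threshold_pct = vaf_threshold_pct,
                 min_family_size = as.integer(min_family_size),
                 max_variants_per_fragment =
                   as.integer(max_variants_per_fragment),
                 min_phred = as.integer(min_phred),
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_frac = max_mismatch_frac,
                 max_edit_frac = max_edit_frac, pad = as.integer(pad),
                 schemes = schemes, seed = seed),
            class = "umivar_config")
}

#' Aggregate per-fragment observations into the mutation table
#'
#' One row per whitelist target and per long-indel target, always — absent
#' targets get count 0. For a whitelist variant, coverage is the number of
#' emitted (post-UMI-filter, post-disparity-filter) fragments whose aligned
#' span covers its position, and count is the number of those fragments
#' supporting the alternate allele; frequency is count/coverage x 100. A
#' fragment whose consensus carries `N` at the position contributes to
#' coverage but never to count. Long-indel rows use fragments assigned to
#' the primer window containing the event anchor as the coverage
#' denominator.
#'
#' @param calls Result of [call_fragments()].
#' @param bundle A `panel_bundle`.
#' @param config A [run_config()] (supplies the VAF threshold).
#' @return The mutation table: `target_id`, `gene`, `chrom`, `pos`, `ref`,
#'   `alt`, `class`, `count`, `coverage`, `frequency_pct`, `pass`.
#' @export
aggregate_calls <- function(calls, bundle, config = run_config()) {
  wl <- bundle$whitelist
  spans <- calls$spans
  seg_start <- bundle$segments$start[match(spans$segment_id,
                                           bundle$segments$segment_id)]
  g_start <- seg_start + spans$span_start - 1L
  g_end <- seg_start + spans$span_end - 1L
  span_chrom <- bundle$segments$chrom[match(spans$segment_id,
                                            bundle$segments$segment_id)]

  rows <- lapply(seq_len(nrow(wl)), function(k) {
    cov <- sum(span_chrom == wl$chrom[k] & g_start <= wl$pos[k] &
                 g_end >= wl$pos[k])
    cnt <- length(unique(
      calls$observations$fragment[calls$observations$target_id ==
                                    wl$target_id[k]]))
    data.frame(target_id = wl$target_id[k], gene = wl$gene[k],
               chrom = wl$chrom[k], pos = wl$pos[k], ref = wl$ref[k],
               alt = wl$alt[k], class = wl$vclass[k], count = cnt,
               coverage = cov, stringsAsFactors = FALSE)
  })

  li <- bundle$long_indels
  if (nrow(li) > 0) {
    seg_idx <- match(li$segment_id, bundle$segments$segment_id)
    for (k in seq_len(nrow(li))) {
      # denominator: fragments assigned to primers whose window contains
      # the event anchor on this segment
      pr <- bundle$primers[bundle$primers$segment_id == li$segment_id[k] &
                             bundle$primers$insert_offset < li$anchor_pos[k], ]
      cov <- sum(spans$primer_id %in% pr$primer_id)
      cnt <- length(unique(
        calls$long_hits$fragment[calls$long_hits$target_id ==
                                   li$target_id[k]]))
      seg <- bundle$segments[seg_idx[k], ]
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = li$target_id[k], gene = "", chrom = seg$chrom,
        pos = seg$start + li$anchor_pos[k] - 1L,
        ref = if (li$kind[k] == "long_deletion") li$event_sequence[k] else "",
        alt = if (li$kind[k] == "long_insertion") li$event_sequence[k] else "",
        class = li$kind[k], count = cnt, coverage = cov,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$frequency_pct <- ifelse(tab$coverage > 0,
                              tab$count / tab$coverage * 100, 0)
  apply_threshold(tab, config)
}

#' Apply the global VAF threshold
#'
#' Sets `pass` to `TRUE` exactly when the unrounded frequency is greater
#' than or equal to the configured threshold (inclusive comparison).
#'
#' @param rows Mutation table (with `frequency_pct` and `coverage`).
#' @param config A [run_config()].
#' @return `rows` with the `pass` column set.
#' @export
apply_threshold <- function(rows, config = run_config()) {
  rows$pass <- rows$coverage > 0 &
    rows$frequency_pct >= config$vaf_threshold_pct
  rows
}

#' Write / read the mutation table
#'
#' The TSV reports frequencies to 4 decimal places; thresholding is always
#' applied to the unrounded value before writing.
#'
#' @param rows Mutation table from [aggregate_calls()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(rows, path) {
  out <- rows
  out$frequency_pct <- sprintf("%.4f", out$frequency_pct)
  write_tsv(out, path)
}

#' @rdname write_mutation_table
#' @export
read_mutation_table <- function(path) {
  df <- read_tsv_strict(path, c("target_id", "gene", "chrom", "pos", "ref",
                                "alt", "class", "count", "coverage",
                                "frequency_pct", "pass"))
  df$frequency_pct <- as.numeric(df$frequency_pct)
  df$pass <- as.logical(df$pass)
  df$gene[is.na(df$gene)] <- ""
  df$ref[is.na(df$ref)] <- ""
  df$alt[is.na(df$alt)] <- ""
  df
}

#' Write calls as VCF 4.2
#'
#' Emits one record per mutation-table row with INFO fields `COUNT`,
#' `COVERAGE` and `FREQ_PCT`; rows failing the VAF threshold carry
#' `FILTER=lowVAF`, uncovered rows `FILTER=no_coverage`.
#'
#' @param rows Mutation table.
#' @param path Output VCF path.
#' @param sample_id Sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(rows, path, sample_id = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=umivar %s",
            as.character(utils::packageVersion("umivar"))),
    sprintf("##sample=%s", sample_id),
    "##INFO=<ID=COUNT,Number=1,Type=Integer,Description=\"Supporting consensus fragments\">",
    "##INFO=<ID=COVERAGE,Number=1,Type=Integer,Description=\"Covering consensus fragments\">",
    "##INFO=<ID=FREQ_PCT,Number=1,Type=Float,Description=\"Variant allele frequency in percent\">",
    "##FILTER=<ID=lowVAF,Description=\"Frequency below the global VAF threshold\">",
    "##FILTER=<ID=no_coverage,Description=\"No covering fragments\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  snv <- rows[rows$class %in% c("SNV", "MNP", "INS", "DEL"), , drop = FALSE]
  for (k in seq_len(nrow(snv))) {
    filt <- if (snv$coverage[k] == 0) "no_coverage" else
      if (snv$pass[k]) "PASS" else "lowVAF"
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\tCOUNT=%d;COVERAGE=%d;FREQ_PCT=%.4f",
                       snv$chrom[k], snv$pos[k], snv$target_id[k],
                       snv$ref[k], snv$alt[k], filt, snv$count[k],
                       snv$coverage[k], snv$frequency_pct[k]), con)
  }
  invisible(path)
}
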