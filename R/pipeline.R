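# End-to-end sample processing: FASTQ pair -> mutation table + run log.

#' Call variants on one sample
#'
#' Runs the full pipeline — pair merging, primer/UMI trimming, UMI-family
#' collapsing, multi-scheme alignment, whitelist calling, long-indel search
#' and tabulation — on one paired FASTQ sample. Deterministic for fixed
#' input: no step uses randomness.
#'
#' @param r1_path,r2_path Paired FASTQ files (gzip-transparent).
#' @param bundle A `panel_bundle`.
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given,
#'   `mutation_table.tsv`, `calls.vcf`, `run_log.json` and `rejects.tsv`
#'   are written there.
#' @param sample_id Sample name used in outputs.
#' @return A list with `mutation_table`, `run_log` (named list of filter
#'   counts and depth summaries) and `rejects` (per-pair rejection log).
#' @examples
#' \donttest{
#' panel <- demo_panel()
#' cfg <- sim_config(seed = 1)
#' sim <- simulate_standard(panel, cfg, tempfile(fileext = "_R1.fastq.gz"),
#'                          tempfile(fileext = "_R2.fastq.gz"),
#'                          n_molecules = 200)
#' res <- call_sample(sim$r1_path, sim$r2_path, panel)
#' head(res$mutation_table)
#' }
#' @export
call_sample <- function(r1_path, r2_path, bundle, config = run_config(),
                        out_dir = NULL, sample_id = "sample") {
  prep <- process_fastq(r1_path, r2_path, bundle, config)
  collapsed <- collapse_reads(prep$reads, config$min_family_size)
  calls <- call_fragments(collapsed$fragments, bundle, config)
  tab <- aggregate_calls(calls, bundle, config)

  reason_counts <- table(factor(prep$rejects$reason,
                                levels = c("no_overlap", "primer_unassigned",
                                           "umi_undetermined")))
  run_log <- list(
    sample_id = sample_id,
    n_pairs = prep$n_pairs,
    n_rejected_pairs = nrow(prep$rejects),
    rejected_no_overlap = unname(reason_counts[["no_overlap"]]),
    rejected_primer_unassigned =
      unname(reason_counts[["primer_unassigned"]]),
    rejected_umi_undetermined =
      unname(reason_counts[["umi_undetermined"]]),
    n_consensus_reads = nrow(prep$reads),
    n_families = collapsed$n_families,
    n_families_discarded = collapsed$n_discarded,
    n_fragments = nrow(collapsed$fragments),
    n_too_disparate = calls$n_too_disparate,
    mean_collapsed_depth = if (nrow(bundle$whitelist) > 0)
      mean(tab$coverage[tab$class %in% c("SNV", "MNP", "INS", "DEL")])
    else 0,
    vaf_threshold_pct = config$vaf_threshold_pct,
    seed = config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mutation_table(tab, file.path(out_dir, "mutation_table.tsv"))
    write_vcf(tab, file.path(out_dir, "calls.vcf"), sample_id)
    jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tsv(prep$rejects, file.path(out_dir, "rejects.tsv"))
  }
  list(mutation_table = tab, run_log = run_log, rejects = prep$rejects)
}
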