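# Synthetic reference standards: UMI-tagged paired-end amplicon libraries
# with spiked whitelist variants at configured VAFs, plus the matching
# truth set.

#' Simulator configuration
#'
#' Defaults emulate a spiked-variant cfDNA reference standard sequenced on
#' a short-read instrument: 200-300 nt fragments, 2x150 reads, 12-nt UMIs,
#' a Poisson PCR-duplication model and a declining position-dependent
#' quality profile.
#'
#' @param vaf_level_pct Spiked VAF in percent: a single value for all
#'   targets or a named vector per target id.
#' @param input_mass_ng cfDNA input mass in ng (default 20).
#' @param copies_per_ng Haploid genome equivalents per ng (default 300;
#'   one haploid human genome is about 3.3 pg).
#' @param fragment_length_range Fragment length range in nt (default
#'   c(200, 300), cfDNA-like).
#' @param read_length Read length per mate (default 150).
#' @param pcr_lambda Mean number of extra PCR copies per molecule (family
#'   size is 1 + Poisson(`pcr_lambda`); default 5).
#' @param polymerase_error_rate Substitution rate per base per PCR stage
#'   (default 1e-5). Applied once to the molecule template (errors shared
#'   by all copies — the PCR jackpot) and once independently per copy.
#' @param qual_profile Integer vector of per-cycle Phred scores (length
#'   `read_length`); default: plateau at Q37 for the first half, linear
#'   decay to Q25 at the last cycle.
#' @param seed Integer seed; every simulation call sets the R RNG from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(vaf_level_pct = 0.5, input_mass_ng = 20,
                       copies_per_ng = 300,
                       fragment_length_range = c(200L, 300L),
                       read_length = 150L, pcr_lambda = 5,
                       polymerase_error_rate = 1e-5, qual_profile = NULL,
                       seed = NULL) {
  stopifnot(all(vaf_level_pct >= 0), all(vaf_level_pct <= 100),
            input_mass_ng > 0, copies_per_ng > 0, pcr_lambda >= 0,
            polymerase_error_rate >= 0, polymerase_error_rate <= 1,
            length(fragment_length_range) == 2,
            fragment_length_range[1] <= fragment_length_range[2])
  if (is.null(qual_profile)) {
    qual_profile <- default_qual_profile(read_length)
  }
  stopifnot(length(qual_profile) == read_length)
  structure(list(vaf_level_pct = vaf_level_pct,
                 input_mass_ng = input_mass_ng,
                 copies_per_ng = copies_per_ng,
                 fragment_length_range = as.integer(fragment_length_range),
                 read_length = as.integer(read_length),
                 pcr_lambda = pcr_lambda,
                 polymerase_error_rate = polymerase_error_rate,
                 qual_profile = as.integer(qual_profile), seed = seed),
            class = "sim_config")
}

#' Default per-cycle quality profile
#'
#' Base-call quality declines towards the end of a read under sequencing
#' by synthesis; the default profile holds Q37 over the first half of the
#' read and decays linearly to Q25 at the final cycle.
#'
#' @param read_length Read length.
#' @return Integer vector of Phred scores.
#' @export
default_qual_profile <- function(read_length = 150L) {
  half <- floor(read_length / 2)
  tail_len <- read_length - half
  c(rep(37L, half),
    as.integer(round(seq(37, 25, length.out = tail_len))))
}

# Resolve per-target simulation inputs from the panel: for each whitelist
# target, the segment, primer, wild-type and variant-applied insert source
# sequences (both starting at the primer's insert offset).
target_sim_inputs <- function(bundle) {
  wl <- bundle$whitelist
  seg <- bundle$segments
  pr <- bundle$primers
  inputs <- lapply(seq_len(nrow(wl)), function(k) {
    si <- which(seg$chrom == wl$chrom[k] &
                  seg$start <= wl$pos[k] &
                  seg$start + nchar(seg$sequence) - 1L >= wl$pos[k])
    if (length(si) != 1)
      stop("whitelist target ", wl$target_id[k],
           " does not map to exactly one segment", call. = FALSE)
    pj <- which(pr$segment_id == seg$segment_id[si])
    if (length(pj) < 1)
      stop("no primer on segment ", seg$segment_id[si], call. = FALSE)
    pj <- pj[1]
    segpos <- wl$pos[k] - seg$start[si] + 1L
    if (segpos <= pr$insert_offset[pj])
      stop("whitelist target ", wl$target_id[k],
           " lies inside the primer region", call. = FALSE)
    sseq <- seg$sequence[si]
    if (substr(sseq, segpos, segpos + nchar(wl$ref[k]) - 1L) != wl$ref[k])
      stop("whitelist ref allele mismatches the reference segment for ",
           wl$target_id[k], call. = FALSE)
    var_seq <- paste0(substr(sseq, 1L, segpos - 1L), wl$alt[k],
                      substr(sseq, segpos + nchar(wl$ref[k]), nchar(sseq)))
    off <- pr$insert_offset[pj]
    list(target_id = wl$target_id[k], primer = pr$sequence[pj],
         wt_source = substr(sseq, off + 1L, nchar(sseq)),
         var_source = substr(var_seq, off + 1L, nchar(var_seq)))
  })
  inputs
}

#' Simulate one reference standard into a FASTQ pair
#'
#' For each whitelist target locus, `n_molecules` original molecules are
#' drawn; each is assigned variant status by a Bernoulli draw at the
#' target's VAF, given a random UMI and a fragment length uniform in the
#' configured range, amplified into 1 + Poisson(`pcr_lambda`) copies with
#' polymerase errors (template errors propagate to all copies), and each
#' copy is sequenced into a read pair under the position-dependent error
#' profile.
#'
#' @param bundle A `panel_bundle`.
#' @param cfg A [sim_config()].
#' @param r1_path,r2_path Output FASTQ paths (gzipped).
#' @param n_molecules Molecules per locus; default
#'   `round(input_mass_ng * copies_per_ng)`.
#' @return A list with `truth` (data frame: `target_id`, `true_vaf_pct`,
#'   `n_molecules_total`, `n_molecules_variant` — the variant count exactly
#'   as drawn), `r1_path`, `r2_path`, `n_pairs`.
#' @export
simulate_standard <- function(bundle, cfg = sim_config(), r1_path, r2_path,
                              n_molecules = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(n_molecules)) {
    n_molecules <- round(cfg$input_mass_ng * cfg$copies_per_ng)
  }
  inputs <- target_sim_inputs(bundle)
  ids <- vapply(inputs, `[[`, character(1), "target_id")
  vafs <- if (length(cfg$vaf_level_pct) == 1) {
    rep(cfg$vaf_level_pct, length(ids))
  } else {
    v <- cfg$vaf_level_pct[ids]
    if (anyNA(v)) stop("per-target vaf_level_pct must name every target",
                       call. = FALSE)
    as.numeric(v)
  }
  min_insert <- cfg$fragment_length_range[1] -
    max(nchar(vapply(inputs, `[[`, character(1), "primer"))) -
    nchar(bundle$constant_region) - bundle$umi_length
  if (min_insert < 1)
    stop("fragment_length_range too short for the panel geometry",
         call. = FALSE)
  out <- cpp_simulate_run(
    r1_path, r2_path, ids,
    vapply(inputs, `[[`, character(1), "primer"),
    vapply(inputs, `[[`, character(1), "wt_source"),
    vapply(inputs, `[[`, character(1), "var_source"),
    vafs, rep(as.integer(n_molecules), length(ids)),
    cfg$fragment_length_range[1], cfg$fragment_length_range[2],
    cfg$read_length, bundle$umi_length, bundle$constant_region,
    cfg$pcr_lambda, cfg$polymerase_error_rate, cfg$qual_profile)
  truth <- data.frame(target_id = ids, true_vaf_pct = vafs,
                      n_molecules_total = as.integer(n_molecules),
                      n_molecules_variant = out$n_variant,
                      stringsAsFactors = FALSE)
  list(truth = truth, r1_path = r1_path, r2_path = r2_path,
       n_pairs = out$n_pairs)
}

#' Simulate a full validation design
#'
#' One FASTQ pair per (VAF level, replicate), with per-run seeds derived
#' deterministically from the master seed, plus the matching
#' `truth_set.tsv` and a `sim_manifest.json` capturing the resolved
#' configuration.
#'
#' @param bundle A `panel_bundle`.
#' @param levels VAF levels in percent (e.g. `c(0, 0.125, 0.25, 0.5)`).
#' @param replicates Number of replicates per level.
#' @param cfg A [sim_config()]; its `seed` is the master seed.
#' @param out_dir Output directory.
#' @param n_molecules Molecules per locus (default from `cfg`).
#' @return A list with `runs` (data frame: `vaf_level_pct`, `replicate`,
#'   `r1_path`, `r2_path`, `seed`), `truth_path`, `manifest_path`.
#' @export
simulate_panel_run <- function(bundle, levels, replicates,
                               cfg = sim_config(), out_dir,
                               n_molecules = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  master <- if (is.null(cfg$seed)) 1L else cfg$seed
  runs <- list()
  for (li in seq_along(levels)) {
    for (r in seq_len(replicates)) {
      run_seed <- derive_seed(master, li, r)
      tag <- sprintf("L%s_rep%d", gsub("\\.", "p", format(levels[li])), r)
      r1 <- file.path(out_dir, paste0(tag, "_R1.fastq.gz"))
      r2 <- file.path(out_dir, paste0(tag, "_R2.fastq.gz"))
      run_cfg <- cfg
      run_cfg$vaf_level_pct <- levels[li]
      run_cfg$seed <- run_seed
      sim <- simulate_standard(bundle, run_cfg, r1, r2, n_molecules)
      runs[[length(runs) + 1L]] <- data.frame(
        vaf_level_pct = levels[li], replicate = r, r1_path = r1,
        r2_path = r2, seed = run_seed, stringsAsFactors = FALSE)
    }
  }
  runs <- if (length(runs) > 0) do.call(rbind, runs) else
    data.frame(vaf_level_pct = numeric(), replicate = integer(),
               r1_path = character(), r2_path = character(),
               seed = integer(), stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(levels, function(lv) {
    data.frame(target_id = bundle$whitelist$target_id,
               vaf_level_pct = lv, expected_present = lv > 0,
               expected_vaf_pct = lv, stringsAsFactors = FALSE)
  }))
  truth_path <- file.path(out_dir, "truth_set.tsv")
  write_truth_set(truth, truth_path)
  manifest_path <- file.path(out_dir, "sim_manifest.json")
  jsonlite::write_json(
    list(levels = levels, replicates = replicates, master_seed = master,
         config = unclass(cfg)[setdiff(names(cfg), "qual_profile")],
         qual_profile = cfg$qual_profile,
         runs = runs),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(runs = runs, truth_path = truth_path, manifest_path = manifest_path)
}
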