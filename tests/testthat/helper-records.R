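# Shared builders for detection records and the filter-bookkeeping sample.

# reconstruct a records/truth pair with the given per-level detection
# counts (n_targets x n_reps trials per level)
mk_records <- function(det = c("0" = 3, "0.125" = 46, "0.25" = 59,
                               "0.5" = 59),
                       n_targets = 20, n_reps = 3) {
  levels <- as.numeric(names(det))
  grid <- expand.grid(target_id = sprintf("t%02d", seq_len(n_targets)),
                      replicate = seq_len(n_reps),
                      vaf_level_pct = levels, stringsAsFactors = FALSE)
  records <- do.call(rbind, lapply(levels, function(lv) {
    g <- grid[grid$vaf_level_pct == lv, ]
    g <- g[order(g$target_id, g$replicate), ]
    k <- det[[as.character(lv)]]
    g$detected <- rep(c(TRUE, FALSE), c(k, nrow(g) - k))
    g$measured_freq_pct <- ifelse(g$detected, pmax(lv, 0.1), 0)
    g
  }))
  truth <- expand.grid(target_id = sprintf("t%02d", seq_len(n_targets)),
                       vaf_level_pct = levels, stringsAsFactors = FALSE)
  truth$expected_present <- truth$vaf_level_pct > 0
  truth$expected_vaf_pct <- truth$vaf_level_pct
  list(records = records, truth = truth)
}

# a 30-pair toy sample exercising every rejection path, with its exact
# expected filter accounting
build_bookkeeping_sample <- function(bundle, dir = tempfile("book")) {
  dir.create(dir)
  set.seed(81)
  seg <- bundle$segments[1, ]
  pr <- bundle$primers[1, ]
  off <- pr$insert_offset
  insert_wt <- substr(seg$sequence, off + 1, off + 80)
  # 13 isolated substitutions: too disparate under every scheme
  insert_bad <- insert_wt
  for (p in seq(3, 75, by = 6)[1:13]) {
    b <- substr(insert_bad, p, p)
    substr(insert_bad, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  pairs <- list(); ids <- character()
  add <- function(p, id) {
    pairs[[length(pairs) + 1]] <<- p
    ids[length(ids) + 1] <<- id
  }
  mk <- function(insert, umi) {
    perfect_pair(make_molecule(bundle, pr$primer_id, insert, umi),
                 read_len = 80L)
  }
  for (i in 1:6) add(mk(insert_wt, "AAAAAAAAAAAA"), paste0("famA_", i))
  for (i in 1:3) add(mk(insert_wt, "CCCCCCCCCCCC"), paste0("famB_", i))
  for (i in 1:2) add(mk(insert_wt, "GGGGGGGGGGGG"), paste0("famC_", i))
  for (i in 1:4) add(mk(insert_bad, "TTTTTTTTTTTT"), paste0("famD_", i))
  for (i in 1:3) add(mk(insert_wt, "ACACACACACAC"), paste0("famE_", i))
  for (i in 1:5) {
    add(list(r1 = rand_dna(80), q1 = strrep("I", 80),
             r2 = rand_dna(80), q2 = strrep("I", 80)),
        paste0("noover_", i))
  }
  for (i in 1:4) {
    mol <- paste0(rand_dna(30), insert_wt, bundle$constant_region,
                  rand_dna(12))
    add(perfect_pair(mol, read_len = 80L), paste0("noprimer_", i))
  }
  for (i in 1:3) {
    add(mk(insert_wt, paste0(rand_dna(5), "N", rand_dna(6))),
        paste0("badumi_", i))
  }
  stopifnot(length(pairs) == 30)
  r1 <- file.path(dir, "book_R1.fastq")
  r2 <- file.path(dir, "book_R2.fastq")
  write_fastq_pair(pairs, ids, r1, r2)
  list(r1 = r1, r2 = r2,
       expected = list(n_pairs = 30, no_overlap = 5, primer_unassigned = 4,
                       umi_undetermined = 3, consensus_reads = 18,
                       families = 5, families_discarded = 1,
                       fragments = 4, too_disparate = 1))
}
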