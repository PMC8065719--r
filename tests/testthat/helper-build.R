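# In-code construction of small panels, molecules, read pairs and FASTQ
# fixtures; everything is generated at test time.

CR_TEST <- "ATTGGAGTCCT"

# write a panel to a temp dir and load it; seqs/primers etc. given as
# data frames so invalid panels can be constructed for error-path tests
build_panel_files <- function(segments, primers, whitelist,
                              long_indels = NULL, dir = withr_tempdir()) {
  fa <- file.path(dir, "reference.fasta")
  con <- file(fa, "w")
  for (k in seq_len(nrow(segments))) {
    writeLines(sprintf(">%s %s:%d:%s", segments$segment_id[k],
                       segments$chrom[k], segments$start[k],
                       segments$strand[k]), con)
    writeLines(segments$sequence[k], con)
  }
  close(con)
  tsv <- function(df, f) {
    p <- file.path(dir, f)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  list(reference_fasta = fa,
       primers_tsv = tsv(primers, "primers.tsv"),
       whitelist_tsv = tsv(whitelist, "whitelist.tsv"),
       long_indels_tsv = if (is.null(long_indels)) NULL else
         tsv(long_indels, "long_indels.tsv"))
}

withr_tempdir <- function() {
  d <- tempfile("panel")
  dir.create(d)
  d
}

# deterministic two-locus toy panel used across tests (segments 200 nt,
# primers 20 and 24 nt, one SNV target per segment)
toy_panel <- function(seed = 7, umi_length = 12L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  s1 <- rand_dna(200); s2 <- rand_dna(200)
  segments <- data.frame(
    segment_id = c("segA", "segB"), chrom = c("chr1", "chr2"),
    start = c(1000L, 5000L), strand = "+", sequence = c(s1, s2),
    stringsAsFactors = FALSE)
  primers <- data.frame(
    primer_id = c("pA", "pB"),
    sequence = c(substr(s1, 1, 20), substr(s2, 1, 24)),
    segment_id = c("segA", "segB"), insert_offset = c(20L, 24L),
    stringsAsFactors = FALSE)
  refA <- substr(s1, 80, 80)
  altA <- setdiff(c("A", "C", "G", "T"), refA)[1]
  refB <- substr(s2, 90, 90)
  altB <- setdiff(c("A", "C", "G", "T"), refB)[1]
  whitelist <- data.frame(
    target_id = c("tA", "tB"), chrom = c("chr1", "chr2"),
    pos = c(1000L + 79L, 5000L + 89L), ref = c(refA, refB),
    alt = c(altA, altB), vclass = "SNV", gene = c("GENEA", "GENEB"),
    stringsAsFactors = FALSE)
  paths <- build_panel_files(segments, primers, whitelist)
  load_panel(paths$reference_fasta, paths$primers_tsv, paths$whitelist_tsv,
             constant_region = CR_TEST, umi_length = umi_length)
}

# molecule on the sequenced strand: primer + insert + CR + UMI
make_molecule <- function(bundle, primer_id, insert, umi) {
  pr <- bundle$primers[bundle$primers$primer_id == primer_id, ]
  paste0(pr$sequence, insert, bundle$constant_region, umi)
}

# error-free read pair from a molecule (Phred 40 throughout)
perfect_pair <- function(molecule, read_len = 80L, q = 40L) {
  L <- nchar(molecule)
  rl <- min(read_len, L)
  r1 <- substr(molecule, 1, rl)
  r2 <- substr(revcomp(molecule), 1, rl)
  qc <- strrep(rawToChar(as.raw(q + 33L)), rl)
  list(r1 = r1, q1 = qc, r2 = r2, q2 = qc)
}

write_fastq_pair <- function(pairs, ids, r1_path, r2_path, gz = FALSE) {
  open_out <- function(p) if (gz) gzfile(p, "w") else file(p, "w")
  c1 <- open_out(r1_path); c2 <- open_out(r2_path)
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    writeLines(c(paste0("@", ids[k]), p$r1, "+", p$q1), c1)
    writeLines(c(paste0("@", ids[k]), p$r2, "+", p$q2), c2)
  }
  close(c1); close(c2)
  invisible(c(r1_path, r2_path))
}

# near-noiseless simulator settings: polymerase errors off and Phred 90
# per cycle (error probability 1e-9)
quiet_sim_config <- function(...) {
  args <- list(...)
  rl <- if (!is.null(args$read_length)) args$read_length else 150L
  defaults <- list(polymerase_error_rate = 0,
                   qual_profile = rep(90L, rl))
  do.call(sim_config, utils::modifyList(defaults, args))
}
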