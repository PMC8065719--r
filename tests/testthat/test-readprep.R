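test_that("fuzzy_find handles exact, tolerated and over-budget matches", {
  # exact prefix
  hit <- fuzzy_find("ACGTACGTAC", "ACGTACGTACTTTT")
  expect_equal(hit$start, 0)
  expect_equal(hit$edits, 0)
  # one substitution in a 10-nt pattern is within the 10% budget
  hit <- fuzzy_find("ACGTACGTAC", "TTACGTACTTACGG")
  expect_equal(hit$edits, 1)
  # a 9-nt pattern allows floor(0.9) = 0 edits
  expect_null(fuzzy_find("ACGTACGTA", "TTACGTACTAGG"))
  # missing and inserted nucleotides also count as single edits
  hit <- fuzzy_find("ACGTACGTAC", "GGACGTACGTTACGG")  # one insertion
  expect_equal(hit$edits, 1)
})

test_that("fuzzy_find agrees with the brute-force edit-distance oracle", {
  set.seed(421)
  ff <- function(p, t) {
    h <- fuzzy_find(p, t, max_edit_frac = 2)  # generous budget: raw optimum
    c(h$start, h$end, h$edits)
  }
  for (i in 1:250) {
    p <- rand_dna(sample(3:30, 1))
    t <- rand_dna(sample(5:60, 1))
    o <- oracle_fuzzy_find(p, t)
    expect_equal(ff(p, t), as.numeric(c(o$start, o$end, o$edits)),
                 info = paste(p, t))
  }
})

test_that("merging identical high-quality mates reproduces read 1", {
  bundle <- toy_panel()
  mol <- make_molecule(bundle, "pA", rand_dna(60), rand_dna(12))
  pr <- perfect_pair(mol, read_len = nchar(mol))
  m <- merge_pair(pr$r1, pr$q1, pr$r2, pr$q2, bundle)
  expect_identical(m$sequence, mol)
  expect_identical(m$qualities, pr$q1)
})

test_that("a low-quality read-1 base is overwritten from read 2", {
  bundle <- toy_panel()
  set.seed(11)
  mol <- make_molecule(bundle, "pA", rand_dna(60), rand_dna(12))
  pr <- perfect_pair(mol, read_len = nchar(mol))
  # corrupt read1 at an overlap position with Phred 10; read2 keeps truth
  pos <- 50L
  truth <- substr(pr$r1, pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), truth)[1]
  r1 <- pr$r1; substr(r1, pos, pos) <- wrong
  q1 <- pr$q1; substr(q1, pos, pos) <- rawToChar(as.raw(10L + 33L))
  m <- merge_pair(r1, q1, pr$r2, pr$q2, bundle)
  expect_identical(substr(m$sequence, pos, pos), truth)
  expect_identical(substr(m$qualities, pos, pos),
                   rawToChar(as.raw(40L + 33L)))
})

test_that("read 1 stays primary when both mates are confident", {
  bundle <- toy_panel()
  set.seed(12)
  mol <- make_molecule(bundle, "pA", rand_dna(60), rand_dna(12))
  pr <- perfect_pair(mol, read_len = nchar(mol))
  pos <- 50L
  b1 <- substr(pr$r1, pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), b1)[1]
  # discordant base, both at Phred 40: read 1 wins outside the UMI zone
  r2rc_pos <- pos  # full overlap, same coordinate
  r2 <- pr$r2
  rc_pos <- nchar(mol) - r2rc_pos + 1L
  substr(r2, rc_pos, rc_pos) <- revcomp(wrong)
  m <- merge_pair(pr$r1, pr$q1, r2, pr$q2, bundle)
  expect_identical(substr(m$sequence, pos, pos), b1)
})

test_that("read 2 is primary inside the terminal UMI segment", {
  bundle <- toy_panel()
  set.seed(13)
  umi <- rand_dna(12)
  mol <- make_molecule(bundle, "pA", rand_dna(60), umi)
  pr <- perfect_pair(mol, read_len = nchar(mol))
  L <- nchar(mol)
  pos <- L - 3L  # inside the UMI zone
  b1 <- substr(pr$r1, pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), b1)[1]
  r1 <- pr$r1; substr(r1, pos, pos) <- wrong  # read-1 discordant, Phred 40
  m <- merge_pair(r1, pr$q1, pr$r2, pr$q2, bundle)
  expect_identical(substr(m$sequence, pos, pos), b1)  # read 2 wins
})

test_that("pairs without an acceptable overlap are rejected", {
  bundle <- toy_panel()
  set.seed(14)
  expect_null(merge_pair(rand_dna(80), strrep("I", 80),
                         rand_dna(80), strrep("I", 80), bundle))
})

test_that("merging is idempotent on its own output", {
  bundle <- toy_panel()
  set.seed(15)
  mol <- make_molecule(bundle, "pA", rand_dna(60), rand_dna(12))
  pr <- perfect_pair(mol, read_len = 80L)
  m1 <- merge_pair(pr$r1, pr$q1, pr$r2, pr$q2, bundle)
  m2 <- merge_pair(m1$sequence, m1$qualities,
                   revcomp(m1$sequence), paste(rev(strsplit(
                     m1$qualities, "")[[1]]), collapse = ""), bundle)
  expect_identical(m2$sequence, m1$sequence)
})

test_that("identify_and_trim recovers the constructed insert exactly", {
  bundle <- toy_panel()
  set.seed(16)
  insert <- rand_dna(70)
  umi <- rand_dna(12)
  mol <- make_molecule(bundle, "pB", insert, umi)
  m <- list(sequence = mol, qualities = strrep("I", nchar(mol)))
  out <- identify_and_trim(m, bundle)
  expect_identical(out$sequence, insert)
  expect_identical(out$primer_id, "pB")
  expect_identical(out$umi, umi)
})

test_that("a primer with two substitutions in 24 nt is still assigned", {
  bundle <- toy_panel()
  set.seed(17)
  insert <- rand_dna(70); umi <- rand_dna(12)
  mol <- make_molecule(bundle, "pB", insert, umi)  # pB is 24 nt
  for (pos in c(3L, 10L)) {
    b <- substr(mol, pos, pos)
    substr(mol, pos, pos) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  out <- identify_and_trim(list(sequence = mol,
                                qualities = strrep("I", nchar(mol))),
                           bundle)
  expect_identical(out$primer_id, "pB")
  expect_identical(out$umi, umi)
})

test_that("reads matching no primer are rejected as primer_unassigned", {
  bundle <- toy_panel()
  set.seed(18)
  mol <- paste0(rand_dna(30), rand_dna(60), CR_TEST, rand_dna(12))
  out <- identify_and_trim(list(sequence = mol,
                                qualities = strrep("I", nchar(mol))),
                           bundle)
  expect_identical(out, "primer_unassigned")
})

test_that("an N inside the UMI rejects the read as umi_undetermined", {
  bundle <- toy_panel()
  set.seed(19)
  umi <- paste0(rand_dna(5), "N", rand_dna(6))
  mol <- make_molecule(bundle, "pA", rand_dna(60), umi)
  out <- identify_and_trim(list(sequence = mol,
                                qualities = strrep("I", nchar(mol))),
                           bundle)
  expect_identical(out, "umi_undetermined")
})

test_that("simulator-generated error-free pairs are fully recovered", {
  panel <- demo_panel()
  cfg <- quiet_sim_config(vaf_level_pct = 0, seed = 31,
                          fragment_length_range = c(200L, 270L))
  r1 <- tempfile(fileext = ".fastq.gz"); r2 <- tempfile(fileext = ".fastq.gz")
  sim <- simulate_standard(panel, cfg, r1, r2, n_molecules = 30)
  prep <- process_fastq(r1, r2, panel)
  expect_equal(nrow(prep$rejects), 0)
  expect_equal(nrow(prep$reads), sim$n_pairs)
  expect_true(all(prep$reads$primer_id %in% panel$primers$primer_id))
  expect_true(all(nchar(prep$reads$umi) == panel$umi_length))
})
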