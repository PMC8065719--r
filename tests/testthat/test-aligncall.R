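S1 <- function() scoring_scheme("S1", 1, -1, "linear", -2)
S2 <- function() scoring_scheme("S2", 1, -1, "affine", -6, -1)

test_that("aligning a fragment to itself scores match x length with no variants", {
  set.seed(31)
  q <- rand_dna(30)
  a <- semi_global_align(q, q, S1())
  expect_equal(a$score, 30)
  expect_equal(a$n_variants, 0)
  expect_identical(a$ops, strrep("M", 30))
})

test_that("a single substitution against a 30-nt window scores 28 with one SNV", {
  set.seed(32)
  ref <- rand_dna(30)
  q <- ref
  b <- substr(q, 14, 14)
  substr(q, 14, 14) <- setdiff(c("A", "C", "G", "T"), b)[1]
  a <- semi_global_align(q, ref, S1())
  expect_equal(a$score, 28)  # 29 matches - 1 mismatch
  expect_equal(a$score,
               oracle_semi_global_score(q, ref, 1, -1, -2, -2))
  expect_equal(a$n_variants, 1)
  expect_identical(a$events$type, "sub")
  expect_equal(nchar(a$events$ref), 1)
})

test_that("a 2-nt deletion is recovered under both gap models with scheme-specific scores", {
  # fixed instance whose 2-nt deletion has a unique least-variants
  # representation under both gap models
  ref <- "ATGACAGGCCGGAAACCCCGAGAAA"
  q <- paste0(substr(ref, 1, 10), substr(ref, 13, 25))
  lin <- semi_global_align(q, ref, S1())
  aff <- semi_global_align(q, ref, S2())
  expect_equal(lin$n_variants, 1)
  expect_equal(aff$n_variants, 1)
  expect_identical(lin$events$type, "del")
  expect_identical(aff$events$type, "del")
  expect_equal(lin$score, 23 - 2 * 2)        # 23 matches, 2 linear gap bases
  expect_equal(aff$score, 23 - (6 + 1))      # open -6, one extension -1
  expect_equal(lin$score,
               oracle_semi_global_score(q, ref, 1, -1, -2, -2))
  expect_equal(aff$score,
               oracle_semi_global_score(q, ref, 1, -1, -6, -1))
})

test_that("alignment scores equal the exhaustive DP oracle on random pairs", {
  set.seed(34)
  schemes <- default_schemes()
  for (i in 1:150) {
    q <- rand_dna(sample(5:30, 1))
    r <- rand_dna(sample(5:30, 1))
    for (sc in schemes) {
      a <- semi_global_align(q, r, sc)
      expect_equal(a$score,
                   oracle_semi_global_score(q, r, sc$match, sc$mismatch,
                                            sc$gap_open, sc$gap_extend),
                   info = paste(sc$scheme_id, q, r))
    }
  }
})

test_that("alignment operations reconstruct both sequences exactly", {
  set.seed(35)
  for (i in 1:60) {
    q <- rand_dna(sample(8:30, 1))
    r <- rand_dna(sample(8:30, 1))
    for (sc in default_schemes()) {
      a <- semi_global_align(q, r, sc)
      ops <- strsplit(a$ops, "")[[1]]
      qi <- 0L; rj <- a$ref_start
      for (o in ops) {
        if (o %in% c("M", "X")) {
          qi <- qi + 1L; rj <- rj + 1L
          same <- substr(q, qi, qi) == substr(r, rj, rj)
          expect_identical(o == "M", same)
        } else if (o == "I") qi <- qi + 1L else rj <- rj + 1L
      }
      expect_equal(qi, nchar(q))
      expect_equal(rj, a$ref_end)
    }
  }
})

test_that("best_alignment selects the least-variants scheme and applies the cap", {
  set.seed(36)
  ref <- rand_dna(40)
  # perfect fragment: zero variants under every scheme
  expect_equal(best_alignment(ref, ref)$n_variants, 0)
  # never more variants than any single scheme produced
  for (i in 1:40) {
    q <- rand_dna(sample(10:35, 1)); r <- rand_dna(sample(10:35, 1))
    per_scheme <- vapply(default_schemes(), function(sc)
      semi_global_align(q, r, sc)$n_variants, integer(1))
    best <- best_alignment(q, r, max_variants = 1000L)
    expect_equal(best$n_variants, min(per_scheme))
  }
})

test_that("fragments with more than twelve variants are discarded", {
  set.seed(37)
  ref <- rand_dna(80)
  q <- ref
  # 13 isolated substitutions, spaced to avoid MNP merging
  pos <- seq(3, 75, by = 6)[1:13]
  for (p in pos) {
    b <- substr(q, p, p)
    substr(q, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  per_scheme <- vapply(default_schemes(), function(sc)
    semi_global_align(q, ref, sc)$n_variants, integer(1))
  expect_true(all(per_scheme >= 13))
  expect_null(best_alignment(q, ref))
  # twelve variants is still acceptable
  q12 <- ref
  for (p in pos[1:12]) {
    b <- substr(q12, p, p)
    substr(q12, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  expect_equal(best_alignment(q12, ref)$n_variants, 12)
})

test_that("adjacent substitutions merge into one MNP", {
  set.seed(38)
  seg <- list(chrom = "chr1", start = 1000L, sequence = rand_dna(60))
  off <- 10L
  win <- substr(seg$sequence, off + 1, 60)
  q <- win
  for (p in c(20L, 21L)) {
    b <- substr(q, p, p)
    substr(q, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  a <- best_alignment(q, win)
  expect_equal(a$n_variants, 1)
  v <- extract_variants(a, seg, off)
  expect_identical(v$vclass, "MNP")
  expect_equal(nchar(v$ref), 2)
  expect_equal(v$pos, 1000L + off + 20L - 1L)
})

test_that("deletions in homopolymers are reported left-aligned", {
  seg <- list(chrom = "chr1", start = 500L,
              sequence = "GGTCAAAATCGGTCGATTACGGATCCGGAT")
  off <- 0L
  win <- seg$sequence
  # delete one A of the AAAA run (positions 5-8): any single-A deletion is
  # equivalent; the report must anchor at the leftmost position
  q <- paste0(substr(win, 1, 5), substr(win, 7, nchar(win)))
  a <- best_alignment(q, win)
  v <- extract_variants(a, seg, off)
  expect_identical(v$vclass, "DEL")
  expect_equal(v$pos, 500L + 4L - 1L)  # anchor base C at window pos 4
  expect_identical(v$ref, "CA")
  expect_identical(v$alt, "C")
})

test_that("indels longer than ten bases are excluded from short-variant output", {
  set.seed(39)
  seg <- list(chrom = "chr1", start = 100L, sequence = rand_dna(80))
  off <- 0L
  win <- seg$sequence
  ins <- rand_dna(11)
  q <- paste0(substr(win, 1, 30), ins, substr(win, 31, 80))
  a <- best_alignment(q, win)
  expect_gte(a$n_variants, 1)  # the event still counts toward disparity
  v <- extract_variants(a, seg, off)
  expect_equal(nrow(v), 0)     # but is not reported as a short variant
})

test_that("round trip: simulated variants are recovered exactly", {
  set.seed(40)
  for (i in 1:25) {
    seg <- list(chrom = "chr9", start = 2000L, sequence = rand_dna(120))
    off <- 15L
    win <- substr(seg$sequence, off + 1, 120)
    # plant one SNV and one short indel at well-separated positions
    q <- win
    b <- substr(q, 20, 20)
    alt_snv <- setdiff(c("A", "C", "G", "T"), b)[1]
    substr(q, 20, 20) <- alt_snv
    if (i %% 2 == 0) {
      q <- paste0(substr(q, 1, 60), rand_dna(3), substr(q, 61, nchar(q)))
    } else {
      q <- paste0(substr(q, 1, 60), substr(q, 64, nchar(q)))
    }
    a <- best_alignment(q, win)
    v <- extract_variants(a, seg, off)
    v_snv <- v[v$vclass == "SNV", ]
    expect_equal(nrow(v_snv), 1)
    expect_equal(v_snv$pos, 2000L + off + 20L - 1L)
    expect_identical(v_snv$alt, alt_snv)
    expect_equal(sum(v$vclass %in% c("INS", "DEL")), 1)
  }
})

test_that("whitelist filtering keeps exact allele matches only", {
  wl <- data.frame(target_id = "t1", chrom = "chr1", pos = 100L,
                   ref = "A", alt = "G", vclass = "SNV", gene = "G",
                   stringsAsFactors = FALSE)
  raw <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(100L, 100L, 101L, 100L),
    ref = c("A", "A", "C", "A"), alt = c("G", "T", "G", "G"),
    vclass = "SNV", stringsAsFactors = FALSE)
  kept <- whitelist_filter(raw, wl)
  expect_equal(nrow(kept), 1)
  expect_identical(kept$target_id, "t1")
  expect_identical(kept$alt, "G")
})

test_that("the long-indel string search is exact", {
  bundle <- demo_panel()
  def <- bundle$long_indels[bundle$long_indels$kind == "long_deletion", ]
  seg <- bundle$segments[match(def$segment_id, bundle$segments$segment_id), ]
  ss <- build_search_string(def, seg)
  off <- bundle$primers$insert_offset[
    match(def$segment_id, bundle$primers$segment_id)]
  # fragment carrying the deletion: reference with the span cut out
  a0 <- def$anchor_pos
  carrier <- paste0(substr(seg$sequence, off + 1, a0 - 1),
                    substr(seg$sequence, a0 + nchar(def$event_sequence),
                           nchar(seg$sequence)))
  wildtype <- substr(seg$sequence, off + 1, nchar(seg$sequence))
  hits <- long_indel_scan(c(carrier, wildtype), setNames(ss, def$target_id))
  expect_equal(hits$fragment, 1L)
  # one mismatch inside the search string defeats the exact search
  m <- regexpr(ss, carrier, fixed = TRUE)[1]
  mut <- carrier
  b <- substr(mut, m + 4L, m + 4L)
  substr(mut, m + 4L, m + 4L) <- setdiff(c("A", "C", "G", "T"), b)[1]
  expect_equal(nrow(long_indel_scan(mut, setNames(ss, def$target_id))), 0)
})
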