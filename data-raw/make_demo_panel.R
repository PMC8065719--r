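# Generates inst/extdata/demo_panel deterministically.
set.seed(424213)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

genes <- c("EGFR", "EGFR", "KRAS", "KRAS", "TP53", "TP53", "PIK3CA",
           "PIK3CA", "FGFR3", "FGFR3", "BRAF", "NRAS", "ALK", "MET",
           "ERBB2", "IDH1", "KIT", "PDGFRA", "APC", "PTEN")
stopifnot(length(genes) == 20, length(unique(genes)) == 15)
tcount <- ave(seq_along(genes), genes, FUN = seq_along)
target_ids <- paste0(genes, "_", tcount)

chroms <- c("chr7", "chr7", "chr12", "chr12", "chr17", "chr17", "chr3",
            "chr3", "chr4", "chr4", "chr7", "chr1", "chr2", "chr7",
            "chr17", "chr2", "chr4", "chr4", "chr5", "chr10")
starts <- c(55242300, 55259200, 25398100, 25380150, 7577400, 7578150,
            178936000, 178952000, 1803500, 1806050, 140453050, 115256400,
            29443550, 116412000, 37880900, 209113000, 55599200, 55152000,
            112175200, 89692700)

seg_len <- 400L
classes <- c(rep("SNV", 16), "MNP", "MNP", "INS", "DEL")
# shuffle classes over targets deterministically so indels/MNPs are not all
# on the same genes
classes <- classes[order(rep(seq_len(20)))]  # keep order: 17/18 MNP, 19 INS, 20 DEL

seg <- list(); primers <- list(); wl <- list()
used_primers <- character()
for (k in 1:20) {
  repeat {
    s <- rand_dna(seg_len)
    plen <- sample(22:24, 1)
    primer <- substr(s, 1, plen)
    if (primer %in% used_primers) next
    off <- plen                       # insert starts right after the primer
    vrel <- sample(80:140, 1)         # variant offset within the insert
    segpos <- off + vrel              # 1-based segment position
    cls <- classes[k]
    ok <- TRUE
    if (cls == "SNV") {
      ref <- substr(s, segpos, segpos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    } else if (cls == "MNP") {
      ref <- substr(s, segpos, segpos + 1)
      a1 <- sample(setdiff(c("A", "C", "G", "T"), substr(ref, 1, 1)), 1)
      a2 <- sample(setdiff(c("A", "C", "G", "T"), substr(ref, 2, 2)), 1)
      alt <- paste0(a1, a2)
    } else if (cls == "INS") {
      anchor <- substr(s, segpos, segpos)
      ins <- rand_dna(2)
      # already left-aligned iff the anchor differs from the last inserted
      # base and the inserted seq's own tail does not extend a repeat
      if (substr(ins, 2, 2) == anchor) ok <- FALSE
      ref <- anchor
      alt <- paste0(anchor, ins)
    } else { # DEL of 3 bases
      anchor <- substr(s, segpos, segpos)
      delspan <- substr(s, segpos + 1, segpos + 3)
      if (substr(delspan, 3, 3) == anchor) ok <- FALSE
      ref <- paste0(anchor, delspan)
      alt <- anchor
    }
    if (!ok) next
    used_primers <- c(used_primers, primer)
    seg[[k]] <- data.frame(segment_id = paste0("seg_", target_ids[k]),
                           chrom = chroms[k], start = starts[k],
                           strand = "+", sequence = s)
    primers[[k]] <- data.frame(primer_id = paste0("pr_", target_ids[k]),
                               sequence = primer,
                               segment_id = paste0("seg_", target_ids[k]),
                               insert_offset = off)
    wl[[k]] <- data.frame(target_id = target_ids[k], chrom = chroms[k],
                          pos = starts[k] + segpos - 1L, ref = ref,
                          alt = alt, vclass = cls, gene = genes[k])
    break
  }
}
seg <- do.call(rbind, seg); primers <- do.call(rbind, primers)
wl <- do.call(rbind, wl)

# long-indel definitions on the first two segments, anchored well past the
# whitelist sites
li <- list()
s1 <- seg$sequence[1]
ins12 <- rand_dna(12)
anchor_ins <- 250L
# the insertion search string (flank5 + ins + flank5) must not occur in the
# wild-type segment
ss_ins <- paste0(substr(s1, anchor_ins - 4, anchor_ins), ins12,
                 substr(s1, anchor_ins + 1, anchor_ins + 5))
stopifnot(!grepl(ss_ins, s1, fixed = TRUE))
li[[1]] <- data.frame(target_id = "EGFR_longins", segment_id = seg$segment_id[1],
                      kind = "long_insertion", event_sequence = ins12,
                      anchor_pos = anchor_ins)
s2 <- seg$sequence[2]
anchor_del <- 250L
del12 <- substr(s2, anchor_del, anchor_del + 11)
ss_del <- paste0(substr(s2, anchor_del - 5, anchor_del - 1),
                 substr(s2, anchor_del + 12, anchor_del + 16))
stopifnot(!grepl(ss_del, s2, fixed = TRUE))
li[[2]] <- data.frame(target_id = "EGFR_longdel", segment_id = seg$segment_id[2],
                      kind = "long_deletion", event_sequence = del12,
                      anchor_pos = anchor_del)
li <- do.call(rbind, li)

dir <- "/root/pkg/inst/extdata/demo_panel"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)
con <- file(file.path(dir, "reference.fasta"), "w")
for (k in seq_len(nrow(seg))) {
  writeLines(sprintf(">%s %s:%d:%s", seg$segment_id[k], seg$chrom[k],
                     seg$start[k], seg$strand[k]), con)
  writeLines(seg$sequence[k], con)
}
close(con)
wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
wt(primers, "primers.tsv")
wt(wl, "whitelist.tsv")
wt(li, "long_indels.tsv")
cat("classes:", table(wl$vclass), "\n")
cat("wrote", dir, "\n")
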