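# Independent oracles, deliberately implemented apart from the package
# kernels: plain-R dynamic programming for alignment scores, utils::adist
# enumeration for fuzzy matching, and a direct R re-statement of the
# family-voting rule.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# optimal semi-global score (query end-to-end, reference end-gaps free)
# by explicit three-state DP over full matrices
oracle_semi_global_score <- function(q, r, match, mismatch, gap_open,
                                     gap_extend) {
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  m <- length(qs); n <- length(rs); NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0
  for (i in 2:(m + 1)) X[i, 1] <- gap_open + (i - 2) * gap_extend
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (qs[i - 1] == rs[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend)
      Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_extend)
    }
  }
  max(M[m + 1, ], X[m + 1, ])
}

# brute-force fuzzy search: Levenshtein distance (via adist) to every
# substring of text, minimum edits, ties by smallest start then end
oracle_fuzzy_find <- function(pattern, text) {
  n <- nchar(text)
  starts <- integer(0); ends <- integer(0)
  for (s in 0:(n - 1)) {
    starts <- c(starts, rep(s, n - s))
    ends <- c(ends, (s + 1):n)
  }
  ed <- drop(utils::adist(pattern, substring(text, starts + 1, ends)))
  starts <- c(starts, 0:n); ends <- c(ends, 0:n)
  ed <- c(ed, rep(nchar(pattern), n + 1))
  o <- order(ed, starts, ends)
  list(start = starts[o[1]], end = ends[o[1]], edits = ed[o[1]])
}

# family-vote rule restated directly: members of modal length (tie ->
# shorter) vote per position; plurality base wins, ties by summed Phred,
# unresolved ties give N
oracle_vote <- function(seqs, quals) {
  lens <- nchar(seqs)
  tab <- table(lens)
  modal <- as.integer(names(tab)[tab == max(tab)])[1]  # smallest on ties
  use <- lens == modal
  sm <- do.call(rbind, strsplit(seqs[use], ""))
  qm <- do.call(rbind, lapply(quals[use],
                              function(q) as.integer(charToRaw(q)) - 33L))
  out <- character(modal)
  for (p in seq_len(modal)) {
    cnt <- tapply(rep(1L, nrow(sm)), sm[, p], sum)
    qs <- tapply(qm[, p], sm[, p], sum)
    best <- max(cnt)
    cand <- names(cnt)[cnt == best]
    if (length(cand) > 1) {
      qbest <- max(qs[cand])
      cand <- cand[qs[cand] == qbest]
    }
    out[p] <- if (length(cand) == 1) cand else "N"
  }
  paste(out, collapse = "")
}

# exact logistic MLE on aggregated detection counts, independent of
# lod_fit: direct Newton iterations on the binomial log-likelihood
oracle_logistic_mle <- function(x, k, n) {
  beta <- c(0, 0)
  for (it in 1:200) {
    eta <- beta[1] + beta[2] * x
    p <- 1 / (1 + exp(-eta))
    g <- c(sum(k - n * p), sum(x * (k - n * p)))
    w <- n * p * (1 - p)
    H <- -matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2, 2)
    step <- solve(H, g)
    beta <- beta - step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}
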