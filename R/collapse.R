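# UMI-family collapsing: exact grouping on (primer_id, UMI) and
# majority-vote consensus; families with fewer than three copies are
# discarded.

#' Group consensus reads into UMI families
#'
#' Partitions reads exactly on the key (primer_id, UMI); no UMI
#' error-correction or network clustering is applied.
#'
#' @param reads Data frame with columns `primer_id`, `umi`, `sequence`,
#'   `qualities` (as returned by [process_fastq()]).
#' @return A list of families, each a list with `primer_id`, `umi`, `size`
#'   and `members` (data frame of the member reads).
#' @export
group_families <- function(reads) {
  if (nrow(reads) == 0) return(list())
  key <- paste(reads$primer_id, reads$umi, sep = "\r")
  idx <- split(seq_len(nrow(reads)), key)
  lapply(idx, function(i) {
    list(primer_id = reads$primer_id[i[1]], umi = reads$umi[i[1]],
         size = length(i), members = reads[i, , drop = FALSE])
  })
}

#' Vote the consensus sequence of one UMI family
#'
#' Families with fewer than `min_family_size` members (default 3) are
#' discarded: a consensus must be supported by at least three copies of the
#' original molecule. Voting is restricted to members of the family's modal
#' length (ties towards the shorter length, since indel sequencing errors
#' are rarer than substitutions); each position takes the plurality base.
#' Vote ties are broken by the larger summed Phred for the tied base, and a
#' still-unresolved tie yields `N`, which never supports a variant call
#' downstream.
#'
#' @param family A family as returned by [group_families()].
#' @param min_family_size Minimum number of copies (default 3).
#' @return A list with `primer_id`, `umi`, `sequence`, `family_size`, or
#'   `NULL` when the family is discarded.
#' @export
vote_consensus <- function(family, min_family_size = 3L) {
  if (family$size < min_family_size) return(NULL)
  v <- cpp_vote_families(family$members$sequence, family$members$qualities,
                         family$size, as.integer(min_family_size))
  list(primer_id = family$primer_id, umi = family$umi,
       sequence = as.character(v$consensus[1]), family_size = family$size)
}

#' Collapse consensus reads into voted fragments (bulk path)
#'
#' Vectorised equivalent of [group_families()] + [vote_consensus()] for
#' whole samples.
#'
#' @inheritParams group_families
#' @param min_family_size Minimum family size (default 3).
#' @return A list with `fragments` (data frame: `primer_id`, `umi`,
#'   `sequence`, `family_size`), `n_families`, `n_discarded` (families below
#'   the size threshold) and `family_sizes` (integer vector over all
#'   families, for QC histograms).
#' @export
collapse_reads <- function(reads, min_family_size = 3L) {
  if (nrow(reads) == 0) {
    return(list(fragments = data.frame(primer_id = character(),
                                       umi = character(),
                                       sequence = character(),
                                       family_size = integer(),
                                       stringsAsFactors = FALSE),
                n_families = 0L, n_discarded = 0L,
                family_sizes = integer()))
  }
  ord <- order(reads$primer_id, reads$umi, method = "radix")
  reads <- reads[ord, , drop = FALSE]
  key <- paste(reads$primer_id, reads$umi, sep = "\r")
  sizes <- rle(key)$lengths
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  v <- cpp_vote_families(reads$sequence, reads$qualities,
                         as.integer(sizes), as.integer(min_family_size))
  keep <- v$keep
  fragments <- data.frame(
    primer_id = reads$primer_id[starts[keep]],
    umi = reads$umi[starts[keep]],
    sequence = as.character(v$consensus[keep]),
    family_size = sizes[keep],
    stringsAsFactors = FALSE)
  list(fragments = fragments, n_families = length(sizes),
       n_discarded = sum(!keep), family_sizes = sizes)
}
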