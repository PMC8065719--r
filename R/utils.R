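# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

is_dna <- function(x, allow_n = TRUE) {
  alpha <- if (allow_n) "ACGTN" else "ACGT"
  grepl(paste0("^[", alpha, "]+$"), x)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  vapply(as.character(x), cpp_revcomp, character(1), USE.NAMES = FALSE)
}

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

# derive a reproducible sub-seed below 2^31 from a master seed and indices
derive_seed <- function(master, i, j = 0L) {
  as.integer((as.double(master) * 48271 + i * 30269 + j * 65537) %%
               2147483647)
}
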