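# Small sequence and checking helpers shared across modules.

#' Reverse complement of a nucleotide string
#'
#' Vectorised over `x`. Ambiguity codes other than A/C/G/T/N are mapped to N
#' on the way through, matching the package-wide alphabet policy.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# normalize a sequence to the package alphabet: uppercase, non-ACGTN -> N
clean_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

# 1-based inclusive substring of a sequence string
subseq_chr <- function(seq, start, end) {
  if (end < start) return("")
  substr(seq, start, end)
}

# fetch one sequence from a sequence tibble (name, sequence) by name
seq_lookup <- function(seqs, name) {
  i <- match(name, seqs$name)
  if (is.na(i)) abort(paste0("sequence '", name, "' not found"))
  seqs$sequence[[i]]
}

# stop unless `x` is a sequence tibble
check_seq_tbl <- function(x, arg = "sequences") {
  if (!is.data.frame(x) || !all(c("name", "sequence") %in% names(x))) {
    abort(paste0("`", arg, "` must be a data frame with columns name, sequence"))
  }
  invisible(x)
}

# deterministic per-task seed derived from a master seed (kept < 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}
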