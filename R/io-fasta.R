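#' Read a FASTA file into a sequence tibble
#'
#' One row per record, in file order. Sequences are uppercased and any
#' character outside A, C, G, T, N is mapped to N.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `name` (first whitespace-delimited token of
#'   the header) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(set) == 0L) abort(paste0("empty FASTA: ", path))
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) abort("FASTA record with empty name")
  tibble(name = nm, sequence = unname(clean_seq(as.character(set))))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs tibble with columns `name`, `sequence`.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  check_seq_tbl(seqs)
  set <- Biostrings::BStringSet(setNames(seqs$sequence, seqs$name))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
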