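# Deterministic pairwise alignment kernels (affine gaps, Rcpp backend).
# These stand behind breakpoint realignment, ancestral-state measurement,
# repeat-library matching and novel-sequence filtering.

#' Default alignment scoring scheme
#'
#' Match +1, mismatch -2, gap open -4, gap extension -1; a gap of length L
#' scores `gap_open + L * gap_ext`.
#'
#' @param match,mismatch,gap_open,gap_ext numeric scores (penalties negative).
#' @return named list of the four scores.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = -4, gap_ext = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_ext <= 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open, gap_ext = gap_ext)
}

align_result <- function(raw, a, b) {
  cols <- max(raw$columns, 1L)
  tibble(
    score = raw$score,
    identity = raw$matches / cols,
    aligned_ratio = raw$a_aligned / max(nchar(a), 1L),
    ops = raw$ops,
    a_start = raw$a_start, a_end = raw$a_end,
    b_start = raw$b_start, b_end = raw$b_end,
    matches = raw$matches, columns = raw$columns
  )
}

#' Optimal global (Needleman-Wunsch) alignment with affine gaps
#'
#' Traceback tie-breaking is deterministic: aligned pair over deletion over
#' insertion.
#'
#' @param a,b nonempty nucleotide strings (`a` is the query for
#'   `aligned_ratio` purposes).
#' @param scoring scoring scheme from [align_scoring()].
#' @return one-row tibble: `score`, `identity` (matches / alignment columns),
#'   `aligned_ratio` (query bases in match/mismatch columns / query length),
#'   `ops` (column string over M/X/D/I; D consumes `a` only), spans on both
#'   sequences (0-based half-open), `matches`, `columns`.
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  if (!nzchar(a) || !nzchar(b)) abort("global_align requires nonempty sequences")
  raw <- .align_pair_cpp(a, b, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_ext, FALSE)
  align_result(raw, a, b)
}

#' Best local (Smith-Waterman) alignment with affine gaps
#'
#' An all-negative score surface yields the empty alignment with score 0.
#'
#' @inheritParams global_align
#' @return one-row tibble as in [global_align()].
#' @export
local_align <- function(a, b, scoring = align_scoring()) {
  if (!nzchar(a) || !nzchar(b)) abort("local_align requires nonempty sequences")
  raw <- .align_pair_cpp(a, b, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_ext, TRUE)
  align_result(raw, a, b)
}

#' Identity and aligned ratio of a query against a target
#'
#' Measured on the best local alignment: identity = matches / alignment
#' columns, aligned ratio = query bases in aligned (match or mismatch)
#' columns / query length. This is the similarity measure behind the
#' ancestral-state and novel-sequence 0.95/0.95 thresholds.
#'
#' @param query,target nonempty nucleotide strings.
#' @param scoring scoring scheme.
#' @return named numeric vector `c(identity=, aligned_ratio=)`.
#' @export
identity_and_aligned_ratio <- function(query, target, scoring = align_scoring()) {
  hit <- local_align(query, target, scoring)
  c(identity = hit$identity, aligned_ratio = hit$aligned_ratio)
}

#' Align-gap-excise local realignment
#'
#' Splits each window into prefix + excised middle + suffix so that the sum
#' of the global alignment scores of the 5' prefixes and of the 3' suffixes
#' is maximal; the excised middles are the variant alleles. Ties push the
#' split 3' (identical windows give empty excisions with breakpoints at the
#' window ends) and then minimize the excision; final leftmost placement is
#' the job of left-shift normalization downstream.
#'
#' @param ref_window,alt_window windows containing the candidate variant plus
#'   flanks (length >= 2).
#' @param scoring scoring scheme.
#' @return list with `left_ref`, `right_ref`, `left_alt`, `right_alt`
#'   (0-based split positions: prefix is `[0, left)`, suffix `[right, n)`),
#'   `excised_ref`, `excised_alt`, `score`.
#' @export
age_realign <- function(ref_window, alt_window, scoring = align_scoring()) {
  if (nchar(ref_window) < 2 || nchar(alt_window) < 2) {
    abort("age_realign windows must be at least 2 bp")
  }
  s <- .age_split_cpp(ref_window, alt_window, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_ext)
  list(
    left_ref = s$i, right_ref = s$k,
    left_alt = s$j, right_alt = s$l,
    excised_ref = substr(ref_window, s$i + 1L, s$k),
    excised_alt = substr(alt_window, s$j + 1L, s$l),
    score = s$score
  )
}
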