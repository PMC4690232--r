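# Pedigree, BED, intensity-count and feature tables.

#' Read a 6-column PED-like pedigree file
#'
#' Columns: family, individual, father, mother, sex, phenotype. `0` or `.`
#' in the parent columns means unknown.
#'
#' @param path TSV path (no header, or a header starting with `#`).
#' @return tibble with `family`, `individual`, `father`, `mother`, `sex`,
#'   `phenotype`; parent columns are NA when unknown.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- do.call(rbind, strsplit(lines, "\\s+"))
  if (ncol(f) < 6L) abort("pedigree file needs 6 columns")
  ped <- tibble(
    family = f[, 1], individual = f[, 2],
    father = ifelse(f[, 3] %in% c("0", "."), NA_character_, f[, 3]),
    mother = ifelse(f[, 4] %in% c("0", "."), NA_character_, f[, 4]),
    sex = f[, 5], phenotype = f[, 6]
  )
  ped
}

#' Founders (unrelated individuals) of a pedigree
#'
#' Individuals with both parents unknown; used for allele-frequency and
#' inbreeding-coefficient computations.
#'
#' @param ped pedigree tibble from [read_pedigree()].
#' @return character vector of individual ids.
#' @export
pedigree_founders <- function(ped) {
  ped$individual[is.na(ped$father) & is.na(ped$mother)]
}

#' Trios of a pedigree
#'
#' @param ped pedigree tibble.
#' @return tibble with `child`, `father`, `mother` (complete trios only).
#' @export
pedigree_trios <- function(ped) {
  tr <- ped[!is.na(ped$father) & !is.na(ped$mother),
            c("individual", "father", "mother")]
  names(tr)[1] <- "child"
  as_tibble(tr)
}

#' Write genomic intervals as BED
#'
#' @param intervals tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  nm <- if ("name" %in% names(intervals)) intervals$name else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end),
                     nm), path)
  invisible(path)
}

#' Read a per-variant per-sample allele read-count table
#'
#' @param path TSV with header columns `variant_id`, `sample`, `r_count`,
#'   `a_count`, `depth`.
#' @return tibble with those columns.
#' @export
read_intensity_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("variant_id", "sample", "r_count", "a_count", "depth")
  if (!all(need %in% names(x))) {
    abort(paste0("intensity table needs columns: ", paste(need, collapse = ", ")))
  }
  as_tibble(x[need])
}

RECAL_FEATURES <- c("gap_ratio", "alt_depth", "neither_depth", "misalign_prob",
                    "align_score", "local_identity", "scaffold_position",
                    "proper_read_ratio", "improper_read_ratio")

#' Read a recalibration feature table
#'
#' @param path TSV with header `variant_id` plus any subset of the nine
#'   feature columns (`gap_ratio`, `alt_depth`, `neither_depth`,
#'   `misalign_prob`, `align_score`, `local_identity`, `scaffold_position`,
#'   `proper_read_ratio`, `improper_read_ratio`).
#' @return tibble.
#' @export
read_feature_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"variant_id" %in% names(x)) abort("feature table needs a variant_id column")
  feats <- intersect(RECAL_FEATURES, names(x))
  if (length(feats) == 0L) abort("feature table has none of the nine recognised features")
  as_tibble(x[c("variant_id", feats)])
}
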