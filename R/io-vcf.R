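# VCF 4.2 writer/reader for the package's variant data model.
#
# Dialect: bi-allelic records only; full allele sequences, never symbolic
# ALTs; for non-SNP records the first base is the shared anchor base;
# END = POS + len(REF) - 1. Haploid GT (0/1) marks per-assembly presence
# before genotyping; diploid GT:GQ:PL appears after genotyping.

# registry of INFO keys <-> variant-table columns
INFO_KEYS <- tibble::tribble(
  ~column,       ~key,        ~type,      ~desc,
  "svtype",      "SVTYPE",    "String",   "Variant class (SNP/DEL/INS/INV/BSUB/LAR)",
  "svlen",       "SVLEN",     "Integer",  "len(ALT) - len(REF)",
  "end",         "END",       "Integer",  "POS + len(REF) - 1",
  "ncarrier",    "NCARRIER",  "Integer",  "Individuals in which the variant was assembled",
  "double_hit",  "DOUBLEHIT", "Flag",     "Assembled independently in >= threshold individuals",
  "aa_state",    "AA_STATE",  "String",   "Ancestral state call",
  "mechanism",   "MECHANISM", "String",   "Formation mechanism call",
  "mech_evidence","MECHEV",   "String",   "Evidence for the mechanism call",
  "orig_category","ORIGCAT",  "String",   "Discovery-time category before rectification",
  "f_coef",      "F",         "Float",    "Inbreeding coefficient among unrelated individuals",
  "recal_score", "RECALQ",    "Float",    "Recalibrated quality score"
)

category_to_svtype <- function(category) {
  map <- c(SNP = "SNP", deletion = "DEL", insertion = "INS", inversion = "INV",
           block_substitution = "BSUB", length_asymmetric_replacement = "LAR")
  out <- unname(map[category])
  out[is.na(out)] <- "LAR"
  out
}

gt_to_vcf <- function(gt) {
  map <- c(RR = "0/0", RA = "0/1", AA = "1/1")
  out <- unname(map[gt])
  out[is.na(out)] <- "./."
  out
}

vcf_to_gt <- function(code) {
  code <- sub("\\|", "/", code)
  map <- c(`0/0` = "RR", `0/1` = "RA", `1/0` = "RA", `1/1` = "AA")
  unname(map[code])
}

#' Write a variant tibble (plus optional genotypes) as VCF 4.2
#'
#' Records must be sorted by (chrom, pos). Per-sample columns are written
#' either from `carriers` (a list-column of individual names; haploid
#' presence GT) or from `calls` (diploid GT:GQ:PL after genotyping).
#'
#' @param variants tibble with at least `chrom`, `pos`, `ref`, `alt`;
#'   optional `id`, `qual`, `filter` and any column in the INFO registry
#'   (`svtype`, `svlen`, `end`, `ncarrier`, `double_hit`, `aa_state`,
#'   `mechanism`, `mech_evidence`, `orig_category`, `f_coef`, `recal_score`).
#' @param path output path.
#' @param samples character vector defining the sample column order. Required
#'   when genotype information is written.
#' @param calls optional long tibble of genotype calls: `id`, `sample`,
#'   `gt` (RR/RA/AA/NA), `gq`, `pl` (comma-joined Phred-scaled likelihoods).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, samples = NULL, calls = NULL) {
  v <- as_tibble(variants)
  if (nrow(v) > 0) {
    ord <- order(v$chrom, v$pos)
    if (!identical(ord, seq_len(nrow(v)))) abort("records must be sorted by (chrom, pos)")
    if (any(!nzchar(v$ref)) || any(!nzchar(v$alt))) abort("empty REF/ALT allele")
  }
  known_cols <- c("chrom", "pos", "id", "ref", "alt", "qual", "filter",
                  "category", "carriers", "q_name", "q_pos", INFO_KEYS$column)
  extra <- setdiff(names(v), known_cols)
  if (length(extra) > 0) {
    abort(paste0("no INFO key registered for column(s): ", paste(extra, collapse = ", ")))
  }
  if (!"id" %in% names(v)) v$id <- sprintf("var%05d", seq_len(nrow(v)))
  if (!"qual" %in% names(v)) v$qual <- NA_real_
  if (!"filter" %in% names(v)) v$filter <- "."
  if (!"svtype" %in% names(v) && "category" %in% names(v)) {
    v$svtype <- category_to_svtype(v$category)
  }
  v$end <- v$pos + nchar(v$ref) - 1L
  if (!"svlen" %in% names(v)) v$svlen <- nchar(v$alt) - nchar(v$ref)

  info_cols <- intersect(INFO_KEYS$column, names(v))
  hdr <- c("##fileformat=VCFv4.2", "##source=asmsv")
  for (cc in info_cols) {
    k <- INFO_KEYS[INFO_KEYS$column == cc, ]
    num <- if (k$type == "Flag") "0" else "1"
    hdr <- c(hdr, sprintf('##INFO=<ID=%s,Number=%s,Type=%s,Description="%s">',
                          k$key, num, k$type, k$desc))
  }
  have_calls <- !is.null(calls) && nrow(calls) > 0
  have_carriers <- is.null(calls) && "carriers" %in% names(v)
  if (have_calls || have_carriers) {
    if (is.null(samples)) abort("`samples` required when writing genotype columns")
    hdr <- c(hdr,
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
    if (have_calls) {
      hdr <- c(hdr,
        '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Phred-scale genotype quality">',
        '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">')
    }
  }
  cols9 <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (have_calls) cols9 <- c(cols9, "FORMAT", samples)
  if (have_carriers) cols9 <- c(cols9, "FORMAT", samples)
  hdr <- c(hdr, paste(cols9, collapse = "\t"))

  body <- character(nrow(v))
  if (have_calls) {
    calls <- as_tibble(calls)
    key <- paste(calls$id, calls$sample, sep = "\r")
  }
  for (i in seq_len(nrow(v))) {
    info <- character(0)
    for (cc in info_cols) {
      k <- INFO_KEYS[INFO_KEYS$column == cc, ]
      val <- v[[cc]][i]
      if (k$type == "Flag") {
        if (isTRUE(val)) info <- c(info, k$key)
      } else if (!is.na(val)) {
        if (k$type == "Integer") val <- as.integer(val)
        info <- c(info, paste0(k$key, "=", val))
      }
    }
    fields <- c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i],
                ifelse(is.na(v$qual[i]), ".", format(v$qual[i], digits = 6)),
                v$filter[i],
                if (length(info)) paste(info, collapse = ";") else ".")
    if (have_calls) {
      idx <- match(paste(v$id[i], samples, sep = "\r"), key)
      gcol <- vapply(idx, function(j) {
        if (is.na(j)) return("./.:.:.")
        gt <- gt_to_vcf(calls$gt[j])
        gq <- if (is.na(calls$gq[j])) "." else as.character(as.integer(round(calls$gq[j])))
        pl <- if (is.na(calls$pl[j])) "." else calls$pl[j]
        paste(gt, gq, pl, sep = ":")
      }, character(1))
      fields <- c(fields, "GT:GQ:PL", gcol)
    } else if (have_carriers) {
      pres <- samples %in% v$carriers[[i]]
      fields <- c(fields, "GT", ifelse(pres, "1", "0"))
    }
    body[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file written by this package
#'
#' Inverse of [write_vcf()] on the package data model.
#'
#' @param path path to a VCF file.
#' @return list with `variants` (tibble; INFO keys unpacked back into their
#'   columns), `calls` (long genotype tibble or NULL), and `samples`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  chrom_line <- hdr[startsWith(hdr, "#CHROM")]
  if (length(chrom_line) != 1L) abort("missing #CHROM header line")
  cols <- strsplit(chrom_line, "\t")[[1]]
  samples <- if (length(cols) > 9) cols[10:length(cols)] else NULL

  if (length(body) == 0L) {
    return(list(variants = tibble(chrom = character(), pos = integer(),
                                  id = character(), ref = character(),
                                  alt = character(), qual = numeric(),
                                  filter = character()),
                calls = NULL, samples = samples))
  }
  f <- do.call(rbind, strsplit(body, "\t"))
  v <- tibble(
    chrom = f[, 1], pos = as.integer(f[, 2]), id = f[, 3],
    ref = f[, 4], alt = f[, 5],
    qual = suppressWarnings(as.numeric(ifelse(f[, 6] == ".", NA, f[, 6]))),
    filter = f[, 7]
  )
  # unpack INFO
  info <- f[, 8]
  for (r in seq_len(nrow(INFO_KEYS))) {
    k <- INFO_KEYS[r, ]
    if (k$type == "Flag") {
      v[[k$column]] <- grepl(paste0("(^|;)", k$key, "($|;)"), info)
      if (!any(v[[k$column]])) v[[k$column]] <- NULL
    } else {
      pat <- paste0("(?:^|;)", k$key, "=([^;]+)")
      m <- regmatches(info, regexpr(pat, info, perl = TRUE))
      has <- grepl(pat, info, perl = TRUE)
      if (!any(has)) next
      val <- rep(NA_character_, nrow(v))
      val[has] <- sub(pat, "\\1", regmatches(info, regexpr(pat, info, perl = TRUE)), perl = TRUE)
      v[[k$column]] <- switch(k$type,
        Integer = as.integer(val), Float = as.numeric(val), val)
    }
  }
  if ("svtype" %in% names(v)) {
    back <- c(SNP = "SNP", DEL = "deletion", INS = "insertion",
              INV = "inversion", BSUB = "block_substitution",
              LAR = "length_asymmetric_replacement")
    v$category <- unname(back[v$svtype])
  }
  calls <- NULL
  if (!is.null(samples) && ncol(f) > 9) {
    fmt <- f[, 9]
    if (any(fmt == "GT:GQ:PL")) {
      recs <- lapply(seq_len(nrow(f)), function(i) {
        parts <- strsplit(f[i, 10:(9 + length(samples))], ":")
        tibble(id = v$id[i], sample = samples,
               gt = vapply(parts, function(p) {
                 g <- vcf_to_gt(p[1]); if (is.null(g) || is.na(g)) NA_character_ else g
               }, character(1)),
               gq = vapply(parts, function(p) {
                 suppressWarnings(as.numeric(ifelse(p[2] == ".", NA, p[2])))
               }, numeric(1)),
               pl = vapply(parts, function(p) {
                 ifelse(length(p) < 3 || p[3] == ".", NA_character_, p[3])
               }, character(1)))
      })
      calls <- dplyr::bind_rows(recs)
    } else if (all(fmt == "GT")) {
      carr <- lapply(seq_len(nrow(f)), function(i) {
        samples[f[i, 10:(9 + length(samples))] == "1"]
      })
      v$carriers <- carr
      v$ncarrier <- lengths(carr)
    }
  }
  list(variants = v, calls = calls, samples = samples)
}
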