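# Variant discovery from assembly-versus-reference alignment blocks.
#
# Scaffolds are traversed 5'->3' (forward scaffold coordinates). Differences
# inside one alignment block become SNPs and small indels; breakpoints
# between adjacent blocks become deletions, insertions, simultaneous gaps,
# inversions or translocations. Variant positions are 1-based anchored (the
# VCF convention); block coordinates are 0-based half-open.

variant_cols <- function() {
  tibble(individual = character(), chrom = character(), pos = integer(),
         ref = character(), alt = character(), category = character(),
         q_name = character(), q_pos = integer())
}

#' Call variants inside one alignment block
#'
#' Every mismatch column becomes a SNP; runs of query-gap columns become
#' deletions and runs of reference-gap columns become insertions, each with
#' the preceding reference base attached as anchor. A run with no preceding
#' reference base in the block is emitted as `no_solution`.
#'
#' @param block one-row block tibble (see [read_maf()]).
#' @param ref_seqs,query_seqs sequence tibbles for the reference and the
#'   assembly scaffolds.
#' @param individual individual/assembly label stored with each call.
#' @return variant tibble (`individual`, `chrom`, `pos`, `ref`, `alt`,
#'   `category`, `q_name`, `q_pos`).
#' @export
call_within_block <- function(block, ref_seqs, query_seqs, individual = "sample") {
  b <- as.list(block[1, ])
  rseq <- seq_lookup(ref_seqs, b$ref_chrom)
  qseq <- seq_lookup(query_seqs, b$q_name)
  rplain <- gsub("-", "", b$ref_text)
  qplain <- gsub("-", "", b$q_text)
  if (rplain != substr(rseq, b$ref_start + 1L, b$ref_end)) {
    abort("block reference row inconsistent with reference sequence")
  }
  qfwd <- substr(qseq, b$q_start + 1L, b$q_end)
  if (qplain != (if (b$strand == "+") qfwd else revcomp(qfwd))) {
    abort("block query row inconsistent with scaffold sequence")
  }
  rch <- strsplit(b$ref_text, "")[[1]]
  qch <- strsplit(b$q_text, "")[[1]]
  if (length(rch) != length(qch)) abort("gapped rows differ in length")
  rgap <- rch == "-"; qgap <- qch == "-"
  if (any(rgap & qgap)) abort("column gapped in both sequences")
  rpos <- b$ref_start + cumsum(!rgap)         # 1-based ref position per column
  qcnt <- cumsum(!qgap)
  qpos <- if (b$strand == "+") b$q_start + qcnt else b$q_end - qcnt + 1L

  out <- list()
  snp <- which(!rgap & !qgap & rch != qch)
  if (length(snp) > 0) {
    out$snp <- tibble(individual = individual, chrom = b$ref_chrom,
                      pos = as.integer(rpos[snp]), ref = rch[snp],
                      alt = qch[snp], category = "SNP",
                      q_name = b$q_name, q_pos = as.integer(qpos[snp]))
  }
  runs <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  del <- runs(qgap)
  if (nrow(del) > 0) {
    out$del <- purrr::map_dfr(seq_len(nrow(del)), function(k) {
      c1 <- del[k, 1]; c2 <- del[k, 2]
      anchor_pos <- rpos[c1] - 1L
      if (anchor_pos <= b$ref_start) {
        return(tibble(individual = individual, chrom = b$ref_chrom,
                      pos = as.integer(rpos[c1]), ref = NA_character_,
                      alt = NA_character_, category = "no_solution",
                      q_name = b$q_name, q_pos = as.integer(qpos[c1])))
      }
      tibble(individual = individual, chrom = b$ref_chrom,
             pos = as.integer(anchor_pos),
             ref = substr(rseq, anchor_pos, rpos[c2]),
             alt = substr(rseq, anchor_pos, anchor_pos),
             category = "deletion",
             q_name = b$q_name, q_pos = as.integer(qpos[c1]))
    })
  }
  ins <- runs(rgap)
  if (nrow(ins) > 0) {
    out$ins <- purrr::map_dfr(seq_len(nrow(ins)), function(k) {
      c1 <- ins[k, 1]; c2 <- ins[k, 2]
      anchor_pos <- rpos[c1]                  # last ref base before the run
      if (anchor_pos <= b$ref_start) {
        return(tibble(individual = individual, chrom = b$ref_chrom,
                      pos = as.integer(anchor_pos), ref = NA_character_,
                      alt = NA_character_, category = "no_solution",
                      q_name = b$q_name, q_pos = as.integer(qpos[c1])))
      }
      inserted <- paste(qch[c1:c2], collapse = "")
      anchor <- substr(rseq, anchor_pos, anchor_pos)
      tibble(individual = individual, chrom = b$ref_chrom,
             pos = as.integer(anchor_pos), ref = anchor,
             alt = paste0(anchor, inserted), category = "insertion",
             q_name = b$q_name, q_pos = as.integer(qpos[c1]))
    })
  }
  res <- dplyr::bind_rows(c(list(variant_cols()), unname(out)))
  dplyr::arrange(res, .data$pos)
}

#' Call variants at breakpoints between adjacent alignment blocks
#'
#' Blocks of one scaffold, ordered 5'->3' on the scaffold. Adjacent pairs are
#' classified: query gap only -> insertion; reference gap only -> deletion;
#' gaps on both sides -> simultaneous_gap; a strand-flipped interior block
#' flanked by same-strand collinear blocks -> inversion; a reference
#' chromosome change -> inter_translocation; non-collinear reference order ->
#' intra_translocation; everything else -> no_solution. Small query/reference
#' overlaps (duplicated repeat edges from split aligners) are clamped up to
#' `tol`; larger overlaps give `no_solution`.
#'
#' @param blocks block tibble of one scaffold (one individual).
#' @param ref_seqs,query_seqs sequence tibbles.
#' @param individual label stored with each call.
#' @param tol overlap tolerance in bp (default 20).
#' @param max_gap simultaneous-gap/size cap in bp (default 50000); larger
#'   events become `no_solution`.
#' @return variant tibble; translocation rows carry `mate_chrom`/`mate_pos`
#'   and NA alleles.
#' @export
call_between_blocks <- function(blocks, ref_seqs, query_seqs,
                                individual = "sample", tol = 20L,
                                max_gap = 50000L) {
  blocks <- dplyr::arrange(blocks, .data$q_start)
  n <- nrow(blocks)
  out <- list()
  emit <- function(...) out[[length(out) + 1L]] <<- tibble(...)
  qseq <- if (n > 0) seq_lookup(query_seqs, blocks$q_name[1]) else ""
  i <- 1L
  while (i < n) {
    A <- as.list(blocks[i, ]); B <- as.list(blocks[i + 1L, ])
    anchor_q <- as.integer(A$q_end)          # 1-based last scaffold base of A
    if (B$ref_chrom != A$ref_chrom) {
      emit(individual = individual, chrom = A$ref_chrom,
           pos = as.integer(if (A$strand == "+") A$ref_end else A$ref_start + 1L),
           ref = NA_character_, alt = NA_character_,
           category = "inter_translocation", q_name = A$q_name, q_pos = anchor_q,
           mate_chrom = B$ref_chrom,
           mate_pos = as.integer(if (B$strand == "+") B$ref_start + 1L else B$ref_end))
      i <- i + 1L; next
    }
    if (B$strand != A$strand) {
      C <- if (i + 2L <= n) as.list(blocks[i + 2L, ]) else NULL
      collinear_flanks <- !is.null(C) && C$ref_chrom == A$ref_chrom &&
        C$strand == A$strand &&
        ((A$strand == "+" && C$ref_start >= A$ref_end - tol) ||
         (A$strand == "-" && C$ref_end <= A$ref_start + tol)) &&
        B$ref_start >= min(A$ref_start, C$ref_start) - tol &&
        B$ref_end <= max(A$ref_end, C$ref_end) + tol
      if (collinear_flanks) {
        anchor_pos <- as.integer(B$ref_start)      # 1-based base before segment
        if (anchor_pos >= 1L) {
          rseq <- seq_lookup(ref_seqs, B$ref_chrom)
          seg_alt <- substr(qseq, B$q_start + 1L, B$q_end)
          emit(individual = individual, chrom = B$ref_chrom, pos = anchor_pos,
               ref = substr(rseq, anchor_pos, B$ref_end),
               alt = paste0(substr(rseq, anchor_pos, anchor_pos), seg_alt),
               category = "inversion", q_name = B$q_name,
               q_pos = as.integer(B$q_start + 1L),
               mate_chrom = NA_character_, mate_pos = NA_integer_)
        }
        i <- i + 2L; next
      }
      emit(individual = individual, chrom = A$ref_chrom,
           pos = as.integer(if (A$strand == "+") A$ref_end else A$ref_start + 1L),
           ref = NA_character_, alt = NA_character_, category = "no_solution",
           q_name = A$q_name, q_pos = anchor_q,
           mate_chrom = NA_character_, mate_pos = NA_integer_)
      i <- i + 1L; next
    }
    # same chromosome, same strand
    plus <- A$strand == "+"
    rgap <- if (plus) B$ref_start - A$ref_end else A$ref_start - B$ref_end
    qgap <- B$q_start - A$q_end
    if (qgap < -tol) {
      emit(individual = individual, chrom = A$ref_chrom,
           pos = as.integer(if (plus) A$ref_end else A$ref_start + 1L),
           ref = NA_character_, alt = NA_character_, category = "no_solution",
           q_name = A$q_name, q_pos = anchor_q,
           mate_chrom = NA_character_, mate_pos = NA_integer_)
      i <- i + 1L; next
    }
    if (rgap < -tol) {
      emit(individual = individual, chrom = A$ref_chrom,
           pos = as.integer(if (plus) A$ref_end else A$ref_start + 1L),
           ref = NA_character_, alt = NA_character_,
           category = "intra_translocation", q_name = A$q_name, q_pos = anchor_q,
           mate_chrom = B$ref_chrom,
           mate_pos = as.integer(if (plus) B$ref_start + 1L else B$ref_end))
      i <- i + 1L; next
    }
    rgap <- max(rgap, 0); qgap <- max(qgap, 0)
    if (rgap > max_gap || qgap > max_gap) {
      emit(individual = individual, chrom = A$ref_chrom,
           pos = as.integer(if (plus) A$ref_end else A$ref_start + 1L),
           ref = NA_character_, alt = NA_character_, category = "no_solution",
           q_name = A$q_name, q_pos = anchor_q,
           mate_chrom = NA_character_, mate_pos = NA_integer_)
      i <- i + 1L; next
    }
    if (rgap > 0 || qgap > 0) {
      rseq <- seq_lookup(ref_seqs, A$ref_chrom)
      gap_lo <- if (plus) A$ref_end else B$ref_end     # 0-based gap interval
      gap_hi <- if (plus) B$ref_start else A$ref_start # [gap_lo, gap_hi)
      anchor_pos <- as.integer(gap_lo)                 # 1-based base before gap
      q_int <- substr(qseq, A$q_end + 1L, B$q_start)
      if (!plus) q_int <- revcomp(q_int)
      if (anchor_pos >= 1L) {
        anchor <- substr(rseq, anchor_pos, anchor_pos)
        category <- if (qgap == 0) "deletion"
                    else if (rgap == 0) "insertion" else "simultaneous_gap"
        emit(individual = individual, chrom = A$ref_chrom, pos = anchor_pos,
             ref = substr(rseq, anchor_pos, gap_hi),
             alt = paste0(anchor, q_int), category = category,
             q_name = A$q_name, q_pos = as.integer(A$q_end + 1L),
             mate_chrom = NA_character_, mate_pos = NA_integer_)
      }
    }
    i <- i + 1L
  }
  res <- dplyr::bind_rows(c(list(variant_cols()), unname(out)))
  if (!"mate_chrom" %in% names(res)) {
    res$mate_chrom <- character(0); res$mate_pos <- integer(0)
  }
  res
}

#' Refine simultaneous gaps into block substitutions and replacements
#'
#' Equal-length interiors (the alleles without their anchor base) become
#' `block_substitution`; unequal become `length_asymmetric_replacement`;
#' identical interiors are dropped (not a variant).
#'
#' @param variants variant tibble.
#' @return variant tibble with `simultaneous_gap` rows refined.
#' @export
split_simultaneous_gap <- function(variants) {
  sg <- variants$category == "simultaneous_gap"
  if (!any(sg)) return(variants)
  ri <- substr(variants$ref[sg], 2L, nchar(variants$ref[sg]))
  ai <- substr(variants$alt[sg], 2L, nchar(variants$alt[sg]))
  refined <- ifelse(ri == ai, NA_character_,
                    ifelse(nchar(ri) == nchar(ai), "block_substitution",
                           "length_asymmetric_replacement"))
  variants$category[sg] <- refined
  variants[!is.na(variants$category), , drop = FALSE]
}

# left-shift one (pos, ref, alt) against its chromosome sequence
left_shift_one <- function(rseq, pos, ref, alt) {
  repeat {
    changed <- FALSE
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 &&
        substr(ref, nr, nr) == substr(alt, na, na) && (nr > 1 || na > 1)) {
      ref <- substr(ref, 1L, nr - 1L); alt <- substr(alt, 1L, na - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0 || nchar(alt) == 0) {
      if (pos <= 1L) { # cannot extend further left; restore an anchor
        base <- substr(rseq, pos, pos)
        ref <- paste0(ref, base); alt <- paste0(alt, base)
        break
      }
      pos <- pos - 1L
      base <- substr(rseq, pos, pos)
      ref <- paste0(base, ref); alt <- paste0(base, alt)
      changed <- TRUE
    }
    if (!changed) break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         substr(ref, 2L, 2L) == substr(alt, 2L, 2L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Normalize variant representations
#'
#' Indels and replacements are parsimony-trimmed and shifted to their
#' leftmost equivalent position against the reference; complex variants
#' (`block_substitution`, `length_asymmetric_replacement`) are first
#' re-anchored by align-gap-excise realignment of the alleles in their
#' reference context. SNPs and inversions pass through unchanged. The
#' operation is idempotent.
#'
#' @param variants variant tibble.
#' @param ref_seqs reference sequence tibble.
#' @param realign re-anchor complex variants via [age_realign()] (default
#'   TRUE).
#' @param flank flank width used for realignment windows.
#' @return normalized variant tibble, sorted by (chrom, pos).
#' @export
normalize_variants <- function(variants, ref_seqs, realign = TRUE, flank = 20L) {
  if (nrow(variants) == 0) return(variants)
  skip <- variants$category %in% c("SNP", "inversion", "no_solution",
                                   "intra_translocation", "inter_translocation") |
          is.na(variants$ref)
  for (k in which(!skip)) {
    rseq <- seq_lookup(ref_seqs, variants$chrom[k])
    pos <- variants$pos[k]; ref <- variants$ref[k]; alt <- variants$alt[k]
    if (realign &&
        variants$category[k] %in% c("simultaneous_gap", "block_substitution",
                                    "length_asymmetric_replacement")) {
      lo <- max(1L, pos - flank)
      hi <- min(nchar(rseq), pos + nchar(ref) - 1L + flank)
      lflank <- substr(rseq, lo, pos - 1L)
      rflank <- substr(rseq, pos + nchar(ref), hi)
      win_ref <- paste0(lflank, ref, rflank)
      win_alt <- paste0(lflank, alt, rflank)
      sp <- age_realign(win_ref, win_alt)
      new_pos <- lo + sp$left_ref - 1L       # 1-based base before excision
      if (new_pos >= 1L && nzchar(sp$excised_ref) + nzchar(sp$excised_alt) > 0) {
        anchor <- substr(rseq, new_pos, new_pos)
        pos <- as.integer(new_pos)
        ref <- paste0(anchor, sp$excised_ref)
        alt <- paste0(anchor, sp$excised_alt)
      }
    }
    sh <- left_shift_one(rseq, pos, ref, alt)
    variants$pos[k] <- sh$pos
    variants$ref[k] <- sh$ref
    variants$alt[k] <- sh$alt
  }
  dplyr::arrange(variants, .data$chrom, .data$pos)
}

#' Classify unaligned scaffold sequence
#'
#' Unaligned spans of a scaffold at least `min_len` long are emitted as
#' `clipped` segments (the scaffold has other aligned blocks) or a single
#' `nomadic` segment (no block aligns anywhere on the scaffold).
#'
#' @param scaffold_name,scaffold_len scaffold id and length.
#' @param blocks block tibble of that scaffold (possibly empty).
#' @param min_len minimum emitted segment length (default 100).
#' @return tibble `q_name`, `start`, `end` (0-based half-open), `kind`.
#' @export
classify_unaligned <- function(scaffold_name, scaffold_len, blocks,
                               min_len = 100L) {
  if (nrow(blocks) == 0) {
    if (scaffold_len < min_len) {
      return(tibble(q_name = character(), start = integer(),
                    end = integer(), kind = character()))
    }
    return(tibble(q_name = scaffold_name, start = 0L,
                  end = as.integer(scaffold_len), kind = "nomadic"))
  }
  cov <- IRanges::reduce(IRanges::IRanges(blocks$q_start + 1L, blocks$q_end))
  gaps <- IRanges::setdiff(IRanges::IRanges(1L, as.integer(scaffold_len)), cov)
  # clipped = unaligned scaffold END; interior unaligned spans are insertion
  # interiors already handled by between-block calling
  at_end <- IRanges::start(gaps) == 1L |
    IRanges::end(gaps) == as.integer(scaffold_len)
  gaps <- gaps[at_end & IRanges::width(gaps) >= min_len]
  tibble(q_name = rep(scaffold_name, length(gaps)),
         start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps),
         kind = rep("clipped", length(gaps)))
}

#' Find reference regions not covered by one individual's assembly
#'
#' Uncovered reference intervals are `intra_scaffold` gaps when the covered
#' intervals flanking them on both sides come from the same scaffold, else
#' `inter_scaffold` (chromosome ends count as inter).
#'
#' @param blocks all blocks of one individual.
#' @param ref_lengths tibble `name`, `length` of reference chromosomes.
#' @return tibble `chrom`, `start`, `end` (0-based half-open), `kind`.
#' @export
find_reference_gaps <- function(blocks, ref_lengths) {
  out <- list()
  for (i in seq_len(nrow(ref_lengths))) {
    chrom <- ref_lengths$name[i]; len <- as.integer(ref_lengths$length[i])
    cb <- blocks[blocks$ref_chrom == chrom, , drop = FALSE]
    if (nrow(cb) == 0) {
      out[[chrom]] <- tibble(chrom = chrom, start = 0L, end = len,
                             kind = "inter_scaffold")
      next
    }
    cov <- IRanges::reduce(IRanges::IRanges(cb$ref_start + 1L, cb$ref_end))
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, len), cov)
    if (length(gaps) == 0) next
    kind <- vapply(seq_along(gaps), function(g) {
      s <- IRanges::start(gaps)[g]; e <- IRanges::end(gaps)[g]
      lcand <- cb[cb$ref_end <= s, , drop = FALSE]      # 0-based end <= gap start
      lscaf <- if (nrow(lcand) == 0) NA_character_
               else lcand$q_name[which.max(lcand$ref_end)]
      rcand <- cb[cb$ref_start >= e, , drop = FALSE]
      rscaf <- if (nrow(rcand) == 0) NA_character_
               else rcand$q_name[which.min(rcand$ref_start)]
      if (!is.na(lscaf) && !is.na(rscaf) && lscaf == rscaf) "intra_scaffold"
      else "inter_scaffold"
    }, character(1))
    out[[chrom]] <- tibble(chrom = chrom, start = IRanges::start(gaps) - 1L,
                           end = IRanges::end(gaps), kind = kind)
  }
  dplyr::bind_rows(c(list(tibble(chrom = character(), start = integer(),
                               end = integer(), kind = character())),
                     unname(out)))
}

#' Merge normalized per-individual variants into population records
#'
#' Variants with identical normalized (chrom, pos, ref, alt) collapse into
#' one bi-allelic record carrying the individuals it was assembled in;
#' distinct overlapping variants stay separate records. Records from prior
#' call sets (e.g. previously published assemblies) can be supplied as
#' additional variant tibbles and are flagged `known`.
#'
#' @param variants long variant tibble with an `individual` column
#'   (translocations/no_solution rows are excluded from merging).
#' @param prior optional variant tibble of known records (same columns, or
#'   at least chrom/pos/ref/alt).
#' @return merged tibble: `chrom`, `pos`, `id`, `ref`, `alt`, `category`,
#'   `carriers` (list-column), `ncarrier`, `known`, sorted by (chrom, pos).
#' @export
merge_population <- function(variants, prior = NULL) {
  keep <- !variants$category %in% c("no_solution", "intra_translocation",
                                    "inter_translocation") & !is.na(variants$ref)
  v <- variants[keep, , drop = FALSE]
  merged <- v |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(category = dplyr::first(.data$category),
                     carriers = list(sort(unique(.data$individual))),
                     .groups = "drop") |>
    dplyr::mutate(ncarrier = lengths(.data$carriers), known = FALSE)
  if (!is.null(prior) && nrow(prior) > 0) {
    key <- paste(merged$chrom, merged$pos, merged$ref, merged$alt)
    pkey <- paste(prior$chrom, prior$pos, prior$ref, prior$alt)
    merged$known <- key %in% pkey
    new <- !(pkey %in% key)
    if (any(new)) {
      add <- tibble(chrom = prior$chrom[new], pos = as.integer(prior$pos[new]),
                    ref = prior$ref[new], alt = prior$alt[new],
                    category = if ("category" %in% names(prior))
                      prior$category[new] else NA_character_,
                    carriers = rep(list(character(0)), sum(new)),
                    ncarrier = 0L, known = TRUE)
      merged <- dplyr::bind_rows(merged, add)
    }
  }
  # reference alleles at one site must agree (shorter allele = prefix of longer)
  bad <- merged |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(ok = {
      rr <- unique(.data$ref); rr <- rr[order(nchar(rr))]
      all(vapply(seq_along(rr), function(i) {
        startsWith(rr[length(rr)], rr[i])
      }, logical(1)))
    }, .groups = "drop")
  if (any(!bad$ok)) {
    abort(paste0("conflicting reference alleles at ",
                 paste(bad$chrom[!bad$ok], bad$pos[!bad$ok], sep = ":",
                       collapse = ", ")))
  }
  merged <- dplyr::arrange(merged, .data$chrom, .data$pos, .data$ref, .data$alt)
  merged$id <- sprintf("var%05d", seq_len(nrow(merged)))
  dplyr::relocate(merged, "chrom", "pos", "id", "ref", "alt")
}

#' Flag double-hit variants
#'
#' Records whose identical-breakpoint carrier count reaches `threshold`
#' (default 2 independent assemblies) are flagged; these are the default
#' positive-training candidates for quality recalibration.
#'
#' @param merged merged record tibble from [merge_population()].
#' @param threshold minimum carrier count (default 2).
#' @return `merged` with a logical `double_hit` column.
#' @export
find_double_hits <- function(merged, threshold = 2L) {
  merged$double_hit <- merged$ncarrier >= threshold
  merged
}

#' Discover variants for one individual from a MAF block table
#'
#' Runs within-block and between-block calling over every scaffold
#' (traversed 5'->3'), refines simultaneous gaps, and normalizes.
#'
#' @param blocks block tibble (one individual).
#' @param ref_seqs,query_seqs sequence tibbles.
#' @param individual label.
#' @param ... passed to [call_between_blocks()].
#' @return list with `variants` (normalized variant tibble),
#'   `unaligned` (segment tibble), `ref_gaps` (gap tibble).
#' @export
discover_individual <- function(blocks, ref_seqs, query_seqs,
                                individual = "sample", ...) {
  per_scaffold <- split(blocks, blocks$q_name)
  within <- purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    call_within_block(blocks[i, ], ref_seqs, query_seqs, individual)
  })
  between <- purrr::map_dfr(per_scaffold, function(bs) {
    call_between_blocks(bs, ref_seqs, query_seqs, individual, ...)
  })
  variants <- dplyr::bind_rows(within, between) |>
    split_simultaneous_gap() |>
    normalize_variants(ref_seqs)
  unaligned <- purrr::map_dfr(query_seqs$name, function(sc) {
    classify_unaligned(sc, nchar(seq_lookup(query_seqs, sc)),
                       blocks[blocks$q_name == sc, , drop = FALSE])
  })
  ref_gaps <- find_reference_gaps(
    blocks, tibble(name = ref_seqs$name, length = nchar(ref_seqs$sequence)))
  list(variants = variants, unaligned = unaligned, ref_gaps = ref_gaps)
}
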