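# Ancestral state, type rectification and formation mechanism.
#
# Ancestral state: both alleles (with 500 bp flanks) are measured against
# each outgroup genome by identity and aligned ratio of the best local
# alignment; the allele resembling the outgroup is the ancestral allele.
# Mechanism: repeats in and around the variant sequence, tested in the
# precedence CCC > TEI > VNTR > NAHR > NHR.

#' Build the two allele sequences of a variant with flanks
#'
#' Each allele is the 500 bp (default) left flank + allele + 500 bp right
#' flank, truncated at sequence ends. Flanks come from the reference for
#' the reference allele and from the carrying scaffold for the alternative
#' allele; when no scaffold is supplied, reference flanks are used for both
#' (exact for isolated variants).
#'
#' @param variant one-row variant tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param ref_seqs reference sequence tibble.
#' @param flank flank width (default 500).
#' @return list `ref_allele_seq`, `alt_allele_seq`.
#' @export
build_alleles <- function(variant, ref_seqs, flank = 500L) {
  v <- as.list(variant[1, ])
  rseq <- seq_lookup(ref_seqs, v$chrom)
  if (v$pos < 1 || v$pos + nchar(v$ref) - 1L > nchar(rseq)) {
    abort("variant outside the reference sequence")
  }
  lo <- max(1L, v$pos - flank)
  hi <- min(nchar(rseq), v$pos + nchar(v$ref) - 1L + flank)
  lflank <- substr(rseq, lo, v$pos - 1L)
  rflank <- substr(rseq, v$pos + nchar(v$ref), hi)
  list(ref_allele_seq = paste0(lflank, v$ref, rflank),
       alt_allele_seq = paste0(lflank, v$alt, rflank))
}

#' Classify the ancestral state of a variant
#'
#' Per outgroup, each allele sequence is measured by
#' [identity_and_aligned_ratio()]; an allele "passes" an outgroup when both
#' identity and aligned ratio exceed the thresholds (default 0.95/0.95).
#' States:
#' * `NONE`: no allele aligns to any outgroup (empty local alignment);
#' * `NA`: alignment exists but no allele passes for any outgroup;
#' * `Common`: both alleles pass for all outgroups;
#' * `Deletion`: for >= 1 outgroup the longer allele passes and the shorter
#'   fails (the ancestral sequence is present; the derived event removed it);
#' * `Insertion`: the shorter allele passes and the longer fails (the
#'   derived event added sequence);
#' * `Conflict`: outgroups disagree between Deletion and Insertion.
#'
#' @param ref_allele_seq,alt_allele_seq allele sequences from
#'   [build_alleles()].
#' @param outgroups sequence tibble of outgroup (orthologous) sequences.
#' @param id_thr,ratio_thr thresholds (default 0.95 each).
#' @param align_floor an allele with aligned ratio below this floor counts
#'   as not aligned at all (default 0.3); NONE requires every allele to be
#'   below it for every outgroup.
#' @param scoring alignment scoring.
#' @return list with `state` and `measurements` (per-outgroup per-allele
#'   identity/aligned-ratio tibble).
#' @export
classify_ancestral <- function(ref_allele_seq, alt_allele_seq, outgroups,
                               id_thr = 0.95, ratio_thr = 0.95,
                               align_floor = 0.3,
                               scoring = align_scoring()) {
  check_seq_tbl(outgroups, "outgroups")
  if (nrow(outgroups) == 0) abort("empty outgroup set")
  longer_is_ref <- nchar(ref_allele_seq) >= nchar(alt_allele_seq)
  meas <- purrr::map_dfr(seq_len(nrow(outgroups)), function(i) {
    og <- outgroups$sequence[[i]]
    mr <- identity_and_aligned_ratio(ref_allele_seq, og, scoring)
    ma <- identity_and_aligned_ratio(alt_allele_seq, og, scoring)
    tibble(outgroup = outgroups$name[i],
           allele = c("ref", "alt"),
           identity = c(mr["identity"], ma["identity"]),
           aligned_ratio = c(mr["aligned_ratio"], ma["aligned_ratio"]))
  })
  passes <- meas$identity > id_thr & meas$aligned_ratio > ratio_thr
  aligns <- meas$aligned_ratio >= align_floor
  per_og <- split(seq_len(nrow(meas)), meas$outgroup)
  verdict <- vapply(per_og, function(idx) {
    ref_pass <- passes[idx[meas$allele[idx] == "ref"]]
    alt_pass <- passes[idx[meas$allele[idx] == "alt"]]
    long_pass <- if (longer_is_ref) ref_pass else alt_pass
    short_pass <- if (longer_is_ref) alt_pass else ref_pass
    if (ref_pass && alt_pass) "Common"
    else if (long_pass && !short_pass) "Deletion"
    else if (short_pass && !long_pass) "Insertion"
    else "NA"
  }, character(1))
  state <- if (!any(aligns)) "NONE"
    else if (any(verdict == "Deletion") && any(verdict == "Insertion")) "Conflict"
    else if (any(verdict == "Deletion")) "Deletion"
    else if (any(verdict == "Insertion")) "Insertion"
    else if (all(verdict == "Common")) "Common"
    else "NA"
  list(state = state, measurements = meas)
}

#' Rectify a variant's type from its ancestral state
#'
#' A discovered insertion whose ancestral state is Deletion (the longer,
#' assembly allele is ancestral) is re-annotated as a deletion, and
#' symmetrically. The discovery-time category is retained in
#' `orig_category`.
#'
#' @param variants variant tibble with `category` and `aa_state` columns.
#' @return variants with rectified `category` and `orig_category`.
#' @export
rectify_type <- function(variants) {
  v <- as_tibble(variants)
  if (!"orig_category" %in% names(v)) v$orig_category <- v$category
  flip_to_del <- v$category == "insertion" & v$aa_state %in% "Deletion"
  flip_to_ins <- v$category == "deletion" & v$aa_state %in% "Insertion"
  v$category[flip_to_del] <- "deletion"
  v$category[flip_to_ins] <- "insertion"
  v
}

# longest shared prefix length of two strings
shared_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  ac <- strsplit(substr(a, 1, n), "")[[1]]
  bc <- strsplit(substr(b, 1, n), "")[[1]]
  d <- which(ac != bc)
  if (length(d) == 0) n else d[1] - 1L
}

#' Classify the formation mechanism of a structural variant
#'
#' Variants shorter than `min_sv` (default 50 bp) are `UNSURE`. Otherwise
#' tests run in precedence order, first match wins:
#' * `CCC` (copy count change): the variant sequence is exactly identical to
#'   the equal-length sequence immediately 3' of the right breakpoint
#'   (polymerase slippage);
#' * `TEI`: best local hit against a mobile-element library record with
#'   identity >= `rep_id` covering >= `rep_cov` of the variant;
#' * `VNTR`: likewise against simple-repeat library records;
#' * `NAHR`: reciprocal alignment of the left and right breakpoint flanks
#'   with identity > 0.85;
#' * `NHR`: microhomology of >= 2 bp (shared prefix of the variant sequence
#'   and the 3' flank, or shared suffix with the 5' flank), shorter than the
#'   variant;
#' * else `NA`.
#'
#' @param variant_seq inserted/deleted allele interior (anchor excluded).
#' @param left_flank,right_flank breakpoint flank sequences (5' and 3';
#'   200 bp windows by convention).
#' @param repeat_library sequence tibble whose names carry a class tag
#'   (`mobile_element` or `simple_repeat`), e.g. `AluY#mobile_element`.
#' @param min_sv minimum size for a confident call (default 50).
#' @param nahr_id NAHR breakpoint identity threshold (default 0.85).
#' @param rep_id,rep_cov repeat-hit identity and coverage thresholds
#'   (default 0.80 each).
#' @param scoring alignment scoring.
#' @return list with `mechanism` and `evidence` (named character).
#' @export
classify_mechanism <- function(variant_seq, left_flank, right_flank,
                               repeat_library = NULL, min_sv = 50L,
                               nahr_id = 0.85, rep_id = 0.80, rep_cov = 0.80,
                               scoring = align_scoring()) {
  if (is.na(variant_seq) || !nzchar(variant_seq)) {
    abort("empty variant sequence")
  }
  len <- nchar(variant_seq)
  if (len < min_sv) {
    return(list(mechanism = "UNSURE", evidence = c(reason = "variant < 50 bp")))
  }
  # CCC: exact copy of the sequence immediately 3' of the right breakpoint
  if (nchar(right_flank) >= len &&
      substr(right_flank, 1L, len) == variant_seq) {
    return(list(mechanism = "CCC",
                evidence = c(copy_len = as.character(len))))
  }
  # TEI / VNTR against the repeat library
  if (!is.null(repeat_library) && nrow(repeat_library) > 0) {
    cls <- ifelse(grepl("mobile_element", repeat_library$name), "TEI",
                  ifelse(grepl("simple_repeat", repeat_library$name), "VNTR",
                         NA_character_))
    for (want in c("TEI", "VNTR")) {
      idx <- which(cls == want)
      best <- NULL
      for (i in idx) {
        hit <- local_align(variant_seq, repeat_library$sequence[[i]], scoring)
        if (hit$identity >= rep_id && hit$aligned_ratio >= rep_cov &&
            (is.null(best) || hit$score > best$score)) {
          best <- hit; best$name <- repeat_library$name[i]
        }
      }
      if (!is.null(best)) {
        return(list(mechanism = want,
                    evidence = c(repeat_name = best$name,
                                 identity = sprintf("%.3f", best$identity),
                                 coverage = sprintf("%.3f", best$aligned_ratio))))
      }
    }
  }
  # NAHR: reciprocal breakpoint-flank alignment
  if (nzchar(left_flank) && nzchar(right_flank)) {
    rec <- local_align(left_flank, right_flank, scoring)
    min_flank_hit <- 0.5 * min(nchar(left_flank), nchar(right_flank))
    if (rec$columns >= min_flank_hit && rec$identity > nahr_id) {
      return(list(mechanism = "NAHR",
                  evidence = c(breakpoint_identity = sprintf("%.3f", rec$identity))))
    }
  }
  # NHR: microhomology at a junction
  mh <- max(shared_prefix_len(variant_seq, right_flank),
            shared_prefix_len(stringi_rev(variant_seq), stringi_rev(left_flank)))
  if (mh >= 2 && mh < len) {
    return(list(mechanism = "NHR",
                evidence = c(microhomology = as.character(mh))))
  }
  list(mechanism = "NA", evidence = c(reason = "no repeat or homology signature"))
}

stringi_rev <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

#' Annotate a record set with ancestral state and mechanism
#'
#' Convenience wrapper: per record, builds alleles, classifies the ancestral
#' state against per-variant outgroup windows (or whole outgroup sequences),
#' classifies the mechanism of insertions/deletions/replacements, and
#' rectifies types.
#'
#' @param records merged record tibble (with `id`).
#' @param ref_seqs reference sequences.
#' @param outgroups either a sequence tibble used for every variant or a
#'   tibble `variant_id`, `outgroup`, `sequence` of per-variant orthologous
#'   windows.
#' @param repeat_library repeat library sequence tibble (see
#'   [classify_mechanism()]).
#' @param flank allele flank width (default 500).
#' @param mech_flank breakpoint flank window for mechanism tests (default
#'   200).
#' @param min_sv UNSURE size threshold (default 50).
#' @return records with `aa_state`, `mechanism`, `mech_evidence`,
#'   rectified `category` and `orig_category`.
#' @export
annotate_variants <- function(records, ref_seqs, outgroups = NULL,
                              repeat_library = NULL, flank = 500L,
                              mech_flank = 200L, min_sv = 50L) {
  v <- as_tibble(records)
  per_variant_og <- !is.null(outgroups) && "variant_id" %in% names(outgroups)
  v$aa_state <- NA_character_
  v$mechanism <- NA_character_
  v$mech_evidence <- NA_character_
  for (i in seq_len(nrow(v))) {
    al <- build_alleles(v[i, ], ref_seqs, flank)
    if (!is.null(outgroups)) {
      og <- if (per_variant_og) {
        w <- outgroups[outgroups$variant_id == v$id[i], , drop = FALSE]
        tibble(name = w$outgroup, sequence = w$sequence)
      } else outgroups
      if (nrow(og) > 0) {
        v$aa_state[i] <- classify_ancestral(al$ref_allele_seq,
                                            al$alt_allele_seq, og)$state
      }
    }
    if (v$category[i] %in% c("deletion", "insertion", "block_substitution",
                             "length_asymmetric_replacement", "inversion")) {
      rseq <- seq_lookup(ref_seqs, v$chrom[i])
      interior <- if (nchar(v$ref[i]) >= nchar(v$alt[i])) {
        substr(v$ref[i], 2L, nchar(v$ref[i]))
      } else {
        substr(v$alt[i], 2L, nchar(v$alt[i]))
      }
      lf <- substr(rseq, max(1L, v$pos[i] - mech_flank + 1L), v$pos[i])
      r0 <- v$pos[i] + nchar(v$ref[i])
      rf <- substr(rseq, r0, min(nchar(rseq), r0 + mech_flank - 1L))
      if (nzchar(interior)) {
        mc <- classify_mechanism(interior, lf, rf, repeat_library,
                                 min_sv = min_sv)
        v$mechanism[i] <- mc$mechanism
        v$mech_evidence[i] <- paste(names(mc$evidence), mc$evidence,
                                    sep = "=", collapse = ",")
      }
    }
  }
  rectify_type(v)
}
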