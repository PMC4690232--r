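# Novel sequence: insertion alleles absent from the reference, and nomadic
# scaffolds corroborated by other genomes.

#' Find novel sequence insertions
#'
#' Insertion alleles whose interior is longer than `min_len` (default 100)
#' and fails to align anywhere in the reference at identity >= 0.95 AND
#' aligned ratio >= 0.95 become novel-insertion records anchored at the
#' breakpoint.
#'
#' @param variants normalized variant tibble (insertions are used).
#' @param ref_seqs reference sequence tibble.
#' @param min_len novel-interior length threshold (default 100, exclusive).
#' @param id_thr,ratio_thr similarity thresholds (default 0.95, inclusive:
#'   reaching both excludes the sequence as already present).
#' @return tibble `kind` ("novel_insertion"), `sequence`, `length`,
#'   `chrom`, `pos` (anchor), `id` (when present in `variants`).
#' @export
find_novel_insertions <- function(variants, ref_seqs, min_len = 100L,
                                  id_thr = 0.95, ratio_thr = 0.95) {
  ins <- variants[variants$category == "insertion" & !is.na(variants$alt), ,
                  drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ins))) {
    interior <- substr(ins$alt[i], 2L, nchar(ins$alt[i]))
    if (nchar(interior) <= min_len) next
    present <- FALSE
    for (k in seq_len(nrow(ref_seqs))) {
      m <- identity_and_aligned_ratio(interior, ref_seqs$sequence[[k]])
      if (m["identity"] >= id_thr && m["aligned_ratio"] >= ratio_thr) {
        present <- TRUE; break
      }
    }
    if (!present) {
      out[[length(out) + 1L]] <- tibble(
        kind = "novel_insertion", sequence = interior,
        length = nchar(interior), chrom = ins$chrom[i],
        pos = as.integer(ins$pos[i]),
        id = if ("id" %in% names(ins)) ins$id[i] else NA_character_)
    }
  }
  dplyr::bind_rows(c(list(tibble(kind = character(), sequence = character(),
                               length = integer(), chrom = character(),
                               pos = integer(), id = character())),
                     unname(out)))
}

#' Classify nomadic novel-sequence candidates
#'
#' Unaligned segments longer than `min_len` are kept as nomadic novel
#' sequence when they reach identity >= 0.95 and aligned ratio >= 0.95
#' against at least one corroborating genome (other human or primate
#' assemblies); the rest -- contamination, assembly error or other
#' artifacts -- are discarded with a machine-readable reason.
#'
#' @param segments unaligned-segment tibble from [classify_unaligned()]
#'   with a `sequence` column (or supply `query_seqs` to extract it).
#' @param other_genomes sequence tibble of corroborating genomes.
#' @param query_seqs optional scaffold sequences to slice segments from.
#' @param min_len length threshold (default 100, exclusive).
#' @param id_thr,ratio_thr similarity thresholds (default 0.95, inclusive).
#' @return list with `kept` (novel-sequence tibble: `kind` = "nomadic",
#'   `sequence`, `length`, `q_name`, `matched_genome`) and `discarded`
#'   (tibble with `q_name`, `reason`).
#' @export
classify_nomadic <- function(segments, other_genomes, query_seqs = NULL,
                             min_len = 100L, id_thr = 0.95, ratio_thr = 0.95) {
  seg <- as_tibble(segments)
  if (!"sequence" %in% names(seg)) {
    if (is.null(query_seqs)) abort("segments need a sequence column or query_seqs")
    seg$sequence <- vapply(seq_len(nrow(seg)), function(i) {
      substr(seq_lookup(query_seqs, seg$q_name[i]), seg$start[i] + 1L, seg$end[i])
    }, character(1))
  }
  kept <- list(); disc <- list()
  for (i in seq_len(nrow(seg))) {
    s <- seg$sequence[i]
    if (nchar(s) <= min_len) {
      disc[[length(disc) + 1L]] <- tibble(q_name = seg$q_name[i],
                                          reason = "below length threshold")
      next
    }
    if (is.null(other_genomes) || nrow(other_genomes) == 0) {
      disc[[length(disc) + 1L]] <- tibble(q_name = seg$q_name[i],
                                          reason = "no corroborating genome")
      next
    }
    matched <- NA_character_
    for (k in seq_len(nrow(other_genomes))) {
      m <- identity_and_aligned_ratio(s, other_genomes$sequence[[k]])
      if (m["identity"] >= id_thr && m["aligned_ratio"] >= ratio_thr) {
        matched <- other_genomes$name[k]; break
      }
    }
    if (!is.na(matched)) {
      kept[[length(kept) + 1L]] <- tibble(kind = "nomadic", sequence = s,
                                          length = nchar(s),
                                          q_name = seg$q_name[i],
                                          matched_genome = matched)
    } else {
      disc[[length(disc) + 1L]] <- tibble(q_name = seg$q_name[i],
                                          reason = "no similar genome above threshold")
    }
  }
  list(
    kept = dplyr::bind_rows(c(list(
      tibble(kind = character(), sequence = character(), length = integer(),
             q_name = character(), matched_genome = character())),
      unname(kept))),
    discarded = dplyr::bind_rows(c(list(tibble(q_name = character(),
                                               reason = character())),
                                   unname(disc))))
}

#' Link novel sequences to their closest known assembly
#'
#' For each novel sequence, the assembly maximizing the identity of the best
#' local alignment becomes `closest_relative` (ties broken by assembly name
#' order); identities at or below `floor` leave the relative absent.
#'
#' @param novel novel-sequence tibble (with `sequence`).
#' @param assemblies named sequence sets: tibble `assembly`, `name`,
#'   `sequence` (one row per scaffold) or a sequence tibble whose `name` is
#'   the assembly.
#' @param floor minimum identity (default 0.5, exclusive).
#' @return `novel` with `closest_relative` and `closest_identity`.
#' @export
link_closest_relative <- function(novel, assemblies, floor = 0.5) {
  asm_col <- if ("assembly" %in% names(assemblies)) "assembly" else "name"
  asms <- sort(unique(assemblies[[asm_col]]))
  novel$closest_relative <- NA_character_
  novel$closest_identity <- NA_real_
  for (i in seq_len(nrow(novel))) {
    best_eff <- floor; best_id <- NA_real_; best_asm <- NA_character_
    for (a in asms) {
      seqs <- assemblies$sequence[assemblies[[asm_col]] == a]
      for (s in seqs) {
        hit <- local_align(novel$sequence[i], s)
        # weight identity by query coverage so a trivial exact 2-mer never wins
        eff <- hit$identity * hit$aligned_ratio
        if (eff > best_eff) {
          best_eff <- eff; best_id <- hit$identity; best_asm <- a
        }
      }
    }
    novel$closest_relative[i] <- best_asm
    novel$closest_identity[i] <- best_id
  }
  novel
}
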