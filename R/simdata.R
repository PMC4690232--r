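# Synthetic-data generator: every input the pipeline consumes, with known
# ground truth. Deterministic given the config seed.
#
# The generator emulates the statistical structure the method assumes:
# a reference with mobile-element copies (Alu-like 300 bp, LINE-like 6 kb),
# tandem-repeat arrays and duplicated (homologous) segment pairs; a
# population of individuals carrying planted variants at Hardy-Weinberg
# genotype frequencies (trios inherit Mendelianly); error-free split
# alignments of each individual assembly against the reference; binomial
# read sampling for genotyping intensities; and outgroup genomes carrying
# the designated ancestral allele plus background substitution divergence.
#
# Variants are planted in left-shift-stable representations (the base
# before each interior differs from the interior's last base), so the
# planted record IS the normalized record and discovery must reproduce the
# truth record-for-record.

#' Simulation configuration
#'
#' Counts are per category; `scale` multiplies all of them. Mobile-element
#' insertion sizes follow the Alu-like (300 bp) / LINE-like (6 kb) mix, so
#' the planted size spectrum peaks where transposition puts it.
#'
#' @param seed master seed.
#' @param scale multiplier applied to all variant/scaffold counts.
#' @param ... overrides for any config field (see Details in the package
#'   vignette).
#' @return config list.
#' @export
sim_config <- function(seed = 1L, scale = 1, ...) {
  cfg <- list(
    seed = as.integer(seed), scale = scale,
    n_chrom = 2L, gc = 0.41, edge_pad = 1500L, margin = 300L,
    # variant counts (multiplied by scale)
    n_snp = 120L, n_small_del = 50L, n_small_ins = 50L,
    small_indel_range = c(1L, 30L),
    n_tei_ins = 8L, n_tei_del = 8L, tei_line_frac = 0.2,
    n_nahr_del = 8L, nahr_x_range = c(300L, 800L), nahr_h_len = 200L,
    nahr_h_divergence = 0.05,
    n_vntr_del = 6L, n_vntr_ins = 6L, vntr_unit_len = 25L,
    vntr_units = 10L, vntr_copy_divergence = 0.04,
    n_ccc_ins = 8L, ccc_range = c(60L, 150L),
    n_nhr_ins = 8L, nhr_range = c(60L, 300L), nhr_mh_range = c(2L, 5L),
    n_novel_ins = 6L, novel_range = c(150L, 500L),
    n_plain_del = 8L, plain_del_range = c(60L, 400L),
    n_bsub = 10L, bsub_range = c(10L, 50L),
    n_lar = 10L, lar_range = c(5L, 40L),
    n_inv = 5L, inv_range = c(100L, 400L),
    n_inter_trans = 2L, n_intra_trans = 2L, trans_piece = c(2000L, 4000L),
    n_clipped = 2L, clipped_len = 300L,
    n_nomadic = 2L, n_contaminant = 2L, nomadic_range = c(500L, 1500L),
    # repeats
    alu_len = 300L, line_len = 6000L, repeat_divergence = 0.02,
    # population
    n_trios = 2L, n_unrelated = 2L, af_range = c(0.2, 0.8),
    # reads
    depth = 30, neither_frac = 0.02, mismap_frac = 0.01,
    # structure thresholds shared with discovery
    inblock_max = 50L,
    # outgroups
    n_outgroups = 2L, divergence = 0.02, ancestral_flank = 500L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) abort(paste0("unknown config field: ", nm))
    cfg[[nm]] <- over[[nm]]
  }
  count_fields <- grep("^n_", names(cfg), value = TRUE)
  count_fields <- setdiff(count_fields, c("n_chrom", "n_trios", "n_unrelated",
                                          "n_outgroups"))
  for (nm in count_fields) cfg[[nm]] <- as.integer(round(cfg[[nm]] * cfg$scale))
  cfg
}

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n, gc = 0.41) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute bases at `rate`, always to a different base
mutate_seq <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

other_base <- function(b) sample(setdiff(BASES, b), 1)

#' Simulate a reference genome with planted repeat structure
#'
#' Background sequence interleaved with the sites later variants need:
#' mobile-element copies (for element-deletion events), duplicated-segment
#' pairs H-X-H' (for NAHR deletions of X) and tandem-repeat arrays of
#' diverged unit copies (for VNTR events). Site counts follow the config's
#' variant counts.
#'
#' @param config from [sim_config()] (its `seed` is used).
#' @return list: `ref` (sequence tibble), `sites` (coordinate tibble),
#'   `repeat_library` (consensus tibble, class tags in names),
#'   `repeats` (planted repeat-copy annotation).
#' @export
simulate_reference <- function(config = sim_config()) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 1L))
  alu <- rand_dna(cfg$alu_len, cfg$gc)
  line <- rand_dna(cfg$line_len, cfg$gc)
  unit <- rand_dna(cfg$vntr_unit_len, cfg$gc)
  repeat_library <- tibble(
    name = c("ALUSIM#mobile_element", "LINESIM#mobile_element",
             "TRSIM#simple_repeat"),
    sequence = c(alu, line, strrep(unit, 10L)))

  # one site request per site-backed variant
  reqs <- c(rep("repeat_copy", cfg$n_tei_del),
            rep("dup_pair", cfg$n_nahr_del),
            rep("tandem_array", cfg$n_vntr_del + cfg$n_vntr_ins))
  reqs <- sample(reqs)
  chrom_of <- sort(rep_len(seq_len(cfg$n_chrom), length(reqs)))

  # background space needed for phase-B (position-free) variants
  free_needed <- sum(
    cfg$n_snp * 2, (cfg$n_small_del + cfg$n_small_ins) * 40,
    cfg$n_tei_ins * 10, cfg$n_ccc_ins * 300, cfg$n_nhr_ins * 100,
    cfg$n_novel_ins * 100, cfg$n_plain_del * 500, cfg$n_bsub * 100,
    cfg$n_lar * 100, cfg$n_inv * 600) +
    (cfg$n_snp + cfg$n_small_del + cfg$n_small_ins + cfg$n_tei_ins +
     cfg$n_ccc_ins + cfg$n_nhr_ins + cfg$n_novel_ins + cfg$n_plain_del +
     cfg$n_bsub + cfg$n_lar + cfg$n_inv) * 3 * cfg$margin
  # head-room: inter-site gaps cannot be packed perfectly
  bg_per_chrom <- as.integer(free_needed * 2.4 / cfg$n_chrom) + 2L * cfg$edge_pad

  refs <- list(); sites <- list(); repeats <- list()
  for (ci in seq_len(cfg$n_chrom)) {
    chrom <- paste0("chr", ci)
    my_reqs <- reqs[chrom_of == ci]
    parts <- list(rand_dna(cfg$edge_pad, cfg$gc))
    pos <- cfg$edge_pad
    bg_left <- bg_per_chrom - 2L * cfg$edge_pad
    n_gaps <- length(my_reqs) + 1L
    gap_len <- as.integer(bg_left / n_gaps)
    for (rq in my_reqs) {
      if (rq == "repeat_copy") {
        fam <- if (runif(1) < cfg$tei_line_frac) "LINESIM" else "ALUSIM"
        cons <- if (fam == "LINESIM") line else alu
        copy <- mutate_seq(cons, cfg$repeat_divergence)
        # keep the copy left-shift stable as a deletion interior
        prev <- substr(parts[[length(parts)]],
                       nchar(parts[[length(parts)]]), 10^9)
        if (substr(copy, nchar(copy), nchar(copy)) == prev) {
          parts[[length(parts)]] <- paste0(
            substr(parts[[length(parts)]], 1, nchar(parts[[length(parts)]]) - 1),
            other_base(prev))
        }
        parts[[length(parts) + 1L]] <- copy
        sites[[length(sites) + 1L]] <- tibble(
          chrom = chrom, type = "repeat_copy", family = fam,
          start = pos + 1L, end = pos + nchar(copy),
          x_start = NA_integer_, x_end = NA_integer_,
          unit_len = NA_integer_, n_units = NA_integer_)
        repeats[[length(repeats) + 1L]] <- tibble(
          chrom = chrom, start = pos + 1L, end = pos + nchar(copy),
          family = fam)
        pos <- pos + nchar(copy)
      } else if (rq == "dup_pair") {
        h <- rand_dna(cfg$nahr_h_len, cfg$gc)
        h2 <- mutate_seq(h, cfg$nahr_h_divergence)
        xlen <- sample(cfg$nahr_x_range[1]:cfg$nahr_x_range[2], 1)
        x <- rand_dna(xlen, cfg$gc)
        # X must be stable as a deletion interior (base before X = H's last)
        if (substr(x, xlen, xlen) == substr(h, nchar(h), nchar(h))) {
          x <- paste0(substr(x, 1, xlen - 1),
                      other_base(substr(h, nchar(h), nchar(h))))
        }
        parts[[length(parts) + 1L]] <- paste0(h, x, h2)
        sites[[length(sites) + 1L]] <- tibble(
          chrom = chrom, type = "dup_pair", family = NA_character_,
          start = pos + 1L, end = pos + nchar(h) + xlen + nchar(h2),
          x_start = pos + nchar(h) + 1L, x_end = pos + nchar(h) + xlen,
          unit_len = NA_integer_, n_units = NA_integer_)
        pos <- pos + nchar(h) + xlen + nchar(h2)
      } else { # tandem_array
        copies <- vapply(seq_len(cfg$vntr_units), function(i) {
          mutate_seq(unit, cfg$vntr_copy_divergence)
        }, character(1))
        arr <- paste(copies, collapse = "")
        parts[[length(parts) + 1L]] <- arr
        sites[[length(sites) + 1L]] <- tibble(
          chrom = chrom, type = "tandem_array", family = "TRSIM",
          start = pos + 1L, end = pos + nchar(arr),
          x_start = NA_integer_, x_end = NA_integer_,
          unit_len = cfg$vntr_unit_len, n_units = cfg$vntr_units)
        pos <- pos + nchar(arr)
      }
      parts[[length(parts) + 1L]] <- rand_dna(gap_len, cfg$gc)
      pos <- pos + gap_len
    }
    parts[[length(parts) + 1L]] <- rand_dna(gap_len + cfg$edge_pad, cfg$gc)
    refs[[ci]] <- tibble(name = chrom, sequence = paste(unlist(parts), collapse = ""))
  }
  list(ref = dplyr::bind_rows(refs),
       sites = dplyr::bind_rows(sites),
       repeat_library = repeat_library,
       repeats = dplyr::bind_rows(c(list(
         tibble(chrom = character(), start = integer(), end = integer(),
                family = character())), unname(repeats))))
}

# interval bookkeeping for position allocation
new_blocklist <- function(sites, cfg) {
  bl <- list()
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, ]
    bl[[ch]] <- cbind(s$start - cfg$margin, s$end + cfg$margin)
  }
  bl
}

is_free <- function(bl, chrom, lo, hi) {
  m <- bl[[chrom]]
  if (is.null(m) || nrow(m) == 0) return(TRUE)
  !any(lo <= m[, 2] & hi >= m[, 1])
}

add_block <- function(bl, chrom, lo, hi) {
  bl[[chrom]] <- rbind(bl[[chrom]], c(lo, hi))
  bl
}

#' Plant variants and derive the population
#'
#' Draws positions, alleles and mechanism signatures; assigns each variant
#' an allele frequency and the designated ancestral allele; draws founder
#' genotypes under Hardy-Weinberg (redrawn until the variant has at least
#' one carrier) and transmits to trio children Mendelianly. All planted
#' representations are left-shift stable.
#'
#' @param refdata output of [simulate_reference()].
#' @param config the same config.
#' @return list: `truth` (variant tibble with `category`, `mechanism`,
#'   `ancestral`, `af`), `genotypes` (long tibble `variant_id`, `sample`,
#'   `gt`), `pedigree`, `individuals` (character).
#' @export
plant_variants <- function(refdata, config = sim_config()) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 2L))
  ref <- refdata$ref
  sites <- refdata$sites
  bl <- new_blocklist(sites, cfg)
  chrom_len <- setNames(nchar(ref$sequence), ref$name)
  rows <- list()
  addv <- function(chrom, pos, refa, alta, category, mechanism) {
    row <- tibble(individual = "truth", chrom = chrom, pos = as.integer(pos),
                  ref = refa, alt = alta, category = category,
                  q_name = NA_character_, q_pos = NA_integer_)
    # commit only representations that are fixed points of normalization,
    # so the planted record IS the canonical record
    if (!category %in% c("SNP", "inversion")) {
      nn <- normalize_variants(row, ref)
      if (nn$pos != pos || nn$ref != refa || nn$alt != alta) return(invisible(FALSE))
    }
    rows[[length(rows) + 1L]] <<- tibble(
      chrom = chrom, pos = as.integer(pos), ref = refa, alt = alta,
      category = category, mechanism = mechanism)
    invisible(TRUE)
  }
  draw_pos <- function(footprint) {
    for (try in 1:400) {
      chrom <- sample(ref$name, 1)
      p <- sample(cfg$edge_pad:(chrom_len[[chrom]] - cfg$edge_pad - footprint), 1)
      if (is_free(bl, chrom, p - cfg$margin, p + footprint + cfg$margin)) {
        bl <<- add_block(bl, chrom, p - cfg$margin, p + footprint + cfg$margin)
        return(list(chrom = chrom, pos = p))
      }
    }
    NULL
  }
  base_at <- function(chrom, p) substr(seq_lookup(ref, chrom), p, p)
  seg_at <- function(chrom, a, b) substr(seq_lookup(ref, chrom), a, b)

  # --- SNPs
  for (k in seq_len(cfg$n_snp)) {
    loc <- draw_pos(1L); if (is.null(loc)) next
    b <- base_at(loc$chrom, loc$pos)
    addv(loc$chrom, loc$pos, b, other_base(b), "SNP", NA_character_)
  }
  # --- small indels (within-block)
  for (k in seq_len(cfg$n_small_del)) {
    for (attempt in 1:8) {
      L <- sample(cfg$small_indel_range[1]:cfg$small_indel_range[2], 1)
      loc <- draw_pos(L + 1L); if (is.null(loc)) next
      p <- loc$pos
      interior <- seg_at(loc$chrom, p + 1L, p + L)
      if (substr(interior, L, L) == base_at(loc$chrom, p)) next
      if (addv(loc$chrom, p, paste0(base_at(loc$chrom, p), interior),
               base_at(loc$chrom, p), "deletion", NA_character_)) break
    }
  }
  for (k in seq_len(cfg$n_small_ins)) {
    L <- sample(cfg$small_indel_range[1]:cfg$small_indel_range[2], 1)
    loc <- draw_pos(1L); if (is.null(loc)) next
    p <- loc$pos
    interior <- rand_dna(L, cfg$gc)
    if (substr(interior, L, L) == base_at(loc$chrom, p)) {
      interior <- paste0(substr(interior, 1, L - 1),
                         other_base(base_at(loc$chrom, p)))
    }
    addv(loc$chrom, p, base_at(loc$chrom, p),
         paste0(base_at(loc$chrom, p), interior), "insertion", NA_character_)
  }
  # --- TEI insertions (diverged consensus copies)
  lib <- refdata$repeat_library
  for (k in seq_len(cfg$n_tei_ins)) {
    fam <- if (runif(1) < cfg$tei_line_frac) "LINESIM" else "ALUSIM"
    cons <- lib$sequence[grepl(fam, lib$name)]
    interior <- mutate_seq(cons, cfg$repeat_divergence)
    loc <- draw_pos(1L); if (is.null(loc)) next
    p <- loc$pos
    if (substr(interior, nchar(interior), nchar(interior)) == base_at(loc$chrom, p)) {
      interior <- paste0(substr(interior, 1, nchar(interior) - 1),
                         other_base(base_at(loc$chrom, p)))
    }
    addv(loc$chrom, p, base_at(loc$chrom, p),
         paste0(base_at(loc$chrom, p), interior), "insertion", "TEI")
  }
  # --- TEI deletions (planted repeat copies)
  rc <- sites[sites$type == "repeat_copy", ]
  for (k in seq_len(min(cfg$n_tei_del, nrow(rc)))) {
    p <- rc$start[k] - 1L
    interior <- seg_at(rc$chrom[k], rc$start[k], rc$end[k])
    addv(rc$chrom[k], p, paste0(base_at(rc$chrom[k], p), interior),
         base_at(rc$chrom[k], p), "deletion", "TEI")
  }
  # --- NAHR deletions (X between homologous H / H')
  dp <- sites[sites$type == "dup_pair", ]
  for (k in seq_len(min(cfg$n_nahr_del, nrow(dp)))) {
    p <- dp$x_start[k] - 1L
    interior <- seg_at(dp$chrom[k], dp$x_start[k], dp$x_end[k])
    addv(dp$chrom[k], p, paste0(base_at(dp$chrom[k], p), interior),
         base_at(dp$chrom[k], p), "deletion", "NAHR")
  }
  # --- VNTR deletions / insertions on tandem arrays
  ta <- sites[sites$type == "tandem_array", ]
  ta_i <- 0L
  for (k in seq_len(cfg$n_vntr_del)) {
    ta_i <- ta_i + 1L; if (ta_i > nrow(ta)) break
    s <- ta[ta_i, ]
    ncp <- sample(3:4, 1)                       # units removed (>= 50 bp)
    for (first in 2:(s$n_units - ncp)) {
      a <- s$start + (first - 1L) * s$unit_len
      b <- a + ncp * s$unit_len - 1L
      p <- a - 1L
      interior <- seg_at(s$chrom, a, b)
      # unit-copy deletions are inherently ambiguous in a tandem array;
      # plant the left-normalized representation
      row <- tibble(individual = "truth", chrom = s$chrom,
                    pos = as.integer(p),
                    ref = paste0(base_at(s$chrom, p), interior),
                    alt = base_at(s$chrom, p), category = "deletion",
                    q_name = NA_character_, q_pos = NA_integer_)
      nn <- normalize_variants(row, ref)
      if (substr(seg_at(s$chrom, nn$pos + nchar(nn$ref),
                        nn$pos + nchar(nn$ref) + nchar(nn$ref) - 2L), 1,
                 nchar(nn$ref) - 1L) ==
          substr(nn$ref, 2L, nchar(nn$ref))) next   # CCC-exact: pick another
      if (addv(nn$chrom, nn$pos, nn$ref, nn$alt, "deletion", "VNTR")) break
    }
  }
  for (k in seq_len(cfg$n_vntr_ins)) {
    ta_i <- ta_i + 1L; if (ta_i > nrow(ta)) break
    s <- ta[ta_i, ]
    ncp <- sample(3:4, 1)
    unit <- lib$sequence[grepl("TRSIM", lib$name)]
    unit <- substr(unit, 1, s$unit_len)
    interior <- paste(vapply(seq_len(ncp), function(i) {
      mutate_seq(unit, cfg$vntr_copy_divergence)
    }, character(1)), collapse = "")
    p <- s$start + 2L * s$unit_len - 1L         # insert after copy 2
    if (substr(interior, nchar(interior), nchar(interior)) == base_at(s$chrom, p)) {
      interior <- paste0(substr(interior, 1, nchar(interior) - 1),
                         other_base(base_at(s$chrom, p)))
    }
    if (substr(seg_at(s$chrom, p + 1L, p + nchar(interior)), 1,
               nchar(interior)) == interior) next   # would be CCC-exact: skip
    addv(s$chrom, p, base_at(s$chrom, p),
         paste0(base_at(s$chrom, p), interior), "insertion", "VNTR")
  }
  # --- CCC insertions (exact tandem duplication of the 3' sequence)
  for (k in seq_len(cfg$n_ccc_ins)) {
    for (attempt in 1:8) {
      L <- sample(cfg$ccc_range[1]:cfg$ccc_range[2], 1)
      loc <- draw_pos(L + 6L); if (is.null(loc)) next
      # scan a few offsets for a left-shift-stable anchor
      ok <- FALSE
      for (d in 0:5) {
        p <- loc$pos + d
        if (base_at(loc$chrom, p + L) != base_at(loc$chrom, p)) { ok <- TRUE; break }
      }
      if (!ok) next
      interior <- seg_at(loc$chrom, p + 1L, p + L)
      if (addv(loc$chrom, p, base_at(loc$chrom, p),
               paste0(base_at(loc$chrom, p), interior), "insertion", "CCC")) break
    }
  }
  # --- NHR insertions (microhomology junction)
  for (k in seq_len(cfg$n_nhr_ins)) {
    L <- sample(cfg$nhr_range[1]:cfg$nhr_range[2], 1)
    mh <- sample(cfg$nhr_mh_range[1]:cfg$nhr_mh_range[2], 1)
    loc <- draw_pos(1L); if (is.null(loc)) next
    p <- loc$pos
    interior <- paste0(seg_at(loc$chrom, p + 1L, p + mh),
                       rand_dna(L - mh, cfg$gc))
    if (substr(interior, L, L) == base_at(loc$chrom, p)) {
      interior <- paste0(substr(interior, 1, L - 1),
                         other_base(base_at(loc$chrom, p)))
    }
    if (substr(seg_at(loc$chrom, p + 1L, p + L), 1, L) == interior) next
    addv(loc$chrom, p, base_at(loc$chrom, p),
         paste0(base_at(loc$chrom, p), interior), "insertion", "NHR")
  }
  # --- novel insertions (random interiors absent from the reference)
  for (k in seq_len(cfg$n_novel_ins)) {
    L <- sample(cfg$novel_range[1]:cfg$novel_range[2], 1)
    loc <- draw_pos(1L); if (is.null(loc)) next
    p <- loc$pos
    interior <- rand_dna(L, cfg$gc)
    if (substr(interior, L, L) == base_at(loc$chrom, p)) {
      interior <- paste0(substr(interior, 1, L - 1),
                         other_base(base_at(loc$chrom, p)))
    }
    addv(loc$chrom, p, base_at(loc$chrom, p),
         paste0(base_at(loc$chrom, p), interior), "insertion", "novel")
  }
  # --- plain large deletions (no planted signature)
  for (k in seq_len(cfg$n_plain_del)) {
    for (attempt in 1:8) {
      L <- sample(cfg$plain_del_range[1]:cfg$plain_del_range[2], 1)
      loc <- draw_pos(L + 1L); if (is.null(loc)) next
      p <- loc$pos
      interior <- seg_at(loc$chrom, p + 1L, p + L)
      if (substr(interior, L, L) == base_at(loc$chrom, p)) next
      if (addv(loc$chrom, p, paste0(base_at(loc$chrom, p), interior),
               base_at(loc$chrom, p), "deletion", NA_character_)) break
    }
  }
  # --- block substitutions and length-asymmetric replacements
  for (k in seq_len(cfg$n_bsub + cfg$n_lar)) {
    bsub <- k <= cfg$n_bsub
    rl <- sample((if (bsub) cfg$bsub_range else cfg$lar_range)[1]:
                 (if (bsub) cfg$bsub_range else cfg$lar_range)[2], 1)
    al <- if (bsub) rl else {
      repeat { al <- sample(cfg$lar_range[1]:cfg$lar_range[2], 1)
               if (al != rl) break }
      al
    }
    loc <- draw_pos(rl + 1L); if (is.null(loc)) next
    p <- loc$pos
    ri <- seg_at(loc$chrom, p + 1L, p + rl)
    ai <- rand_dna(al, cfg$gc)
    # differ at both ends so the representation is trim- and shift-stable
    if (substr(ai, 1, 1) == substr(ri, 1, 1)) {
      ai <- paste0(other_base(substr(ri, 1, 1)), substr(ai, 2, al))
    }
    if (substr(ai, al, al) == substr(ri, rl, rl)) {
      ai <- paste0(substr(ai, 1, al - 1), other_base(substr(ri, rl, rl)))
    }
    if (ai == ri) next
    addv(loc$chrom, p, paste0(base_at(loc$chrom, p), ri),
         paste0(base_at(loc$chrom, p), ai),
         if (bsub) "block_substitution" else "length_asymmetric_replacement",
         NA_character_)
  }
  # --- inversions
  for (k in seq_len(cfg$n_inv)) {
    S <- sample(cfg$inv_range[1]:cfg$inv_range[2], 1)
    loc <- draw_pos(S + 1L); if (is.null(loc)) next
    p <- loc$pos
    seg <- seg_at(loc$chrom, p + 1L, p + S)
    rc <- revcomp(seg)
    if (rc == seg) next
    addv(loc$chrom, p, paste0(base_at(loc$chrom, p), seg),
         paste0(base_at(loc$chrom, p), rc), "inversion", NA_character_)
  }

  truth <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$chrom, .data$pos)
  truth$id <- sprintf("sim%05d", seq_len(nrow(truth)))
  truth$af <- runif(nrow(truth), cfg$af_range[1], cfg$af_range[2])
  truth$ancestral <- sample(c("ref", "alt"), nrow(truth), replace = TRUE)
  truth <- dplyr::relocate(truth, "id")

  # population: founders under HWE, children by Mendelian transmission
  fams <- seq_len(cfg$n_trios)
  ped <- dplyr::bind_rows(
    purrr::map_dfr(fams, function(f) {
      tibble(family = paste0("fam", f),
             individual = paste0("fam", f, c("_father", "_mother", "_child")),
             father = c(NA, NA, paste0("fam", f, "_father")),
             mother = c(NA, NA, paste0("fam", f, "_mother")),
             sex = c("1", "2", "0"), phenotype = "0")
    }),
    tibble(family = paste0("u", seq_len(cfg$n_unrelated)),
           individual = paste0("ind", seq_len(cfg$n_unrelated)),
           father = NA_character_, mother = NA_character_,
           sex = "0", phenotype = "0"))
  founders <- pedigree_founders(ped)
  children <- setdiff(ped$individual, founders)
  gts <- list()
  for (i in seq_len(nrow(truth))) {
    af <- truth$af[i]
    repeat {
      fo <- vapply(founders, function(s) sum(runif(2) < af), numeric(1))
      g <- setNames(c("RR", "RA", "AA")[fo + 1], founders)
      for (ch in children) {
        fa <- g[[ped$father[ped$individual == ch]]]
        mo <- g[[ped$mother[ped$individual == ch]]]
        pick <- function(x) {
          switch(x, RR = "R", AA = "A", RA = sample(c("R", "A"), 1))
        }
        al <- sort(c(pick(fa), pick(mo)))
        g[[ch]] <- paste(al, collapse = "")
        g[[ch]] <- sub("AR", "RA", g[[ch]])
      }
      if (any(g != "RR")) break
    }
    gts[[i]] <- tibble(variant_id = truth$id[i], sample = names(g),
                       gt = unname(g))
  }
  list(truth = truth, genotypes = dplyr::bind_rows(gts), pedigree = ped,
       individuals = ped$individual)
}

# walk one chromosome of one individual: build the assembly sequence and,
# optionally, the exact (error-free) alignment blocks
walk_individual_chrom <- function(ref_seq, chrom, vars, scaffold,
                                  inblock_max = 50L) {
  vars <- vars[order(vars$pos), , drop = FALSE]
  qparts <- character(0)
  qlen <- 0L
  blocks <- list()
  cur <- NULL
  add_q <- function(s) { qparts <<- c(qparts, s); qlen <<- qlen + nchar(s) }
  open_block <- function(ref0) {
    cur <<- list(ref0 = ref0, q0 = qlen, rt = character(0), qt = character(0),
                 rlen = 0L, qb = 0L)
  }
  put <- function(rt, qt, rconsumed, qconsumed) {
    cur$rt <<- c(cur$rt, rt); cur$qt <<- c(cur$qt, qt)
    cur$rlen <<- cur$rlen + rconsumed; cur$qb <<- cur$qb + qconsumed
  }
  flush_block <- function() {
    if (!is.null(cur) && cur$rlen > 0L) {
      blocks[[length(blocks) + 1L]] <<- tibble(
        ref_chrom = chrom, ref_start = cur$ref0,
        ref_end = cur$ref0 + cur$rlen, ref_srcsize = nchar(ref_seq),
        q_name = scaffold, q_start = cur$q0, q_end = cur$q0 + cur$qb,
        q_srcsize = NA_real_, strand = "+", score = cur$rlen,
        ref_text = paste(cur$rt, collapse = ""),
        q_text = paste(cur$qt, collapse = ""))
    }
    cur <<- NULL
  }
  r <- 1L
  open_block(0L)
  copy_to <- function(p) {      # copy identical ref[r..p] into block and query
    if (p >= r) {
      seg <- substr(ref_seq, r, p)
      put(seg, seg, nchar(seg), nchar(seg))
      add_q(seg)
      r <<- p + 1L
    }
  }
  for (i in seq_len(nrow(vars))) {
    v <- as.list(vars[i, ])
    ri <- substr(v$ref, 2L, nchar(v$ref))   # interiors (anchor removed)
    ai <- substr(v$alt, 2L, nchar(v$alt))
    if (v$category == "SNP") {
      copy_to(v$pos - 1L)
      put(v$ref, v$alt, 1L, 1L)
      add_q(v$alt)
      r <- v$pos + 1L
    } else if (v$category == "deletion" && nchar(ri) <= inblock_max) {
      copy_to(v$pos)
      put(ri, strrep("-", nchar(ri)), nchar(ri), 0L)
      r <- v$pos + nchar(ri) + 1L
    } else if (v$category == "insertion" && nchar(ai) <= inblock_max) {
      copy_to(v$pos)
      put(strrep("-", nchar(ai)), ai, 0L, nchar(ai))
      add_q(ai)
      r <- v$pos + 1L
    } else if (v$category == "deletion") {
      copy_to(v$pos); flush_block()
      r <- v$pos + nchar(ri) + 1L
      open_block(r - 1L)
    } else if (v$category == "insertion") {
      copy_to(v$pos); flush_block()
      add_q(ai)
      open_block(v$pos)
    } else if (v$category %in% c("block_substitution",
                                 "length_asymmetric_replacement")) {
      copy_to(v$pos); flush_block()
      add_q(ai)
      r <- v$pos + nchar(ri) + 1L
      open_block(r - 1L)
    } else if (v$category == "inversion") {
      copy_to(v$pos); flush_block()
      qpiece <- revcomp(ri)
      blocks[[length(blocks) + 1L]] <- tibble(
        ref_chrom = chrom, ref_start = v$pos, ref_end = v$pos + nchar(ri),
        ref_srcsize = nchar(ref_seq), q_name = scaffold, q_start = qlen,
        q_end = qlen + nchar(ri), q_srcsize = NA_real_, strand = "-",
        score = nchar(ri), ref_text = ri, q_text = ri)
      add_q(qpiece)
      r <- v$pos + nchar(ri) + 1L
      open_block(r - 1L)
    } else {
      abort(paste0("cannot plant category ", v$category))
    }
  }
  copy_to(nchar(ref_seq))
  flush_block()
  list(sequence = paste(qparts, collapse = ""),
       blocks = dplyr::bind_rows(c(list(empty_block_tbl()),
                                   unname(blocks))))
}

#' Simulate assemblies and their error-free split alignments
#'
#' For each individual, applies the variants it carries (genotype RA or AA:
#' the collapsed assembly shows the alternative allele) chromosome by
#' chromosome, emitting the assembly scaffold and the exact alignment
#' blocks: small variants are embedded as mismatch/gap columns within
#' blocks, large ones split blocks, inversions become minus-strand middle
#' blocks. Optionally adds translocation scaffolds, unaligned clipped
#' tails, nomadic scaffolds (present in a corroborating genome) and
#' contaminant scaffolds.
#'
#' @param refdata from [simulate_reference()].
#' @param planted from [plant_variants()].
#' @param config the same config.
#' @return list: `assemblies` (tibble `individual`, `name`, `sequence`),
#'   `blocks` (block tibble across individuals; scaffold names are
#'   `<individual>_<chrom>`), `trans_truth` (expected translocation calls),
#'   `clipped_truth`, `nomadic` (tibble incl. `in_other_genome`),
#'   `other_genome` (sequence tibble).
#' @export
simulate_assembly_alignment <- function(refdata, planted,
                                        config = sim_config()) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 3L))
  ref <- refdata$ref
  carriers <- planted$genotypes[planted$genotypes$gt != "RR", , drop = FALSE]
  asms <- list(); blocks <- list()
  for (ind in planted$individuals) {
    my <- planted$truth[planted$truth$id %in%
                        carriers$variant_id[carriers$sample == ind], ,
                        drop = FALSE]
    for (ci in seq_len(nrow(ref))) {
      chrom <- ref$name[ci]
      scaf <- paste0(ind, "_", chrom)
      w <- walk_individual_chrom(ref$sequence[ci], chrom,
                                 my[my$chrom == chrom, , drop = FALSE],
                                 scaf, cfg$inblock_max)
      asms[[scaf]] <- tibble(individual = ind, name = scaf,
                             sequence = w$sequence)
      blocks[[scaf]] <- w$blocks
    }
  }
  assemblies <- dplyr::bind_rows(unname(asms))
  blocks <- dplyr::bind_rows(unname(blocks))

  # translocation scaffolds (attributed to the first individual)
  trans_truth <- list()
  ind1 <- planted$individuals[1]
  piece <- function(lo_frac, hi_frac, chrom_idx) {
    len <- nchar(ref$sequence[chrom_idx])
    plen <- sample(cfg$trans_piece[1]:cfg$trans_piece[2], 1)
    start <- sample(as.integer(len * lo_frac):as.integer(len * hi_frac - plen), 1)
    list(chrom = ref$name[chrom_idx], start = start, len = plen,
         seq = substr(ref$sequence[chrom_idx], start + 1L, start + plen))
  }
  make_trans_scaffold <- function(k, inter) {
    p1 <- piece(0.05, 0.45, 1L)
    p2 <- if (inter && nrow(ref) > 1) piece(0.05, 0.45, 2L)
          else { # intra: jump backwards on the same chromosome
            repeat {
              cand <- piece(0.55, 0.95, 1L)
              if (cand$start > p1$start + p1$len + 200) break
            }
            # swap so the second block maps 5' of the first (non-collinear)
            tmp <- p1; p1 <- cand; p2 <- tmp
            p2
          }
    scaf <- paste0(ind1, "_trans", if (inter) "I" else "A", k)
    seqs <- paste0(p1$seq, p2$seq)
    b <- tibble(
      ref_chrom = c(p1$chrom, p2$chrom),
      ref_start = c(p1$start, p2$start),
      ref_end = c(p1$start + p1$len, p2$start + p2$len),
      ref_srcsize = nchar(ref$sequence[match(c(p1$chrom, p2$chrom), ref$name)]),
      q_name = scaf, q_start = c(0L, p1$len),
      q_end = c(p1$len, p1$len + p2$len), q_srcsize = NA_real_,
      strand = "+", score = c(p1$len, p2$len),
      ref_text = c(p1$seq, p2$seq), q_text = c(p1$seq, p2$seq))
    truth <- tibble(category = if (inter) "inter_translocation"
                               else "intra_translocation",
                    chrom = p1$chrom, pos = as.integer(p1$start + p1$len),
                    q_name = scaf)
    list(seq = tibble(individual = ind1, name = scaf, sequence = seqs),
         blocks = b, truth = truth)
  }
  for (k in seq_len(cfg$n_inter_trans)) {
    tr <- make_trans_scaffold(k, TRUE)
    assemblies <- dplyr::bind_rows(assemblies, tr$seq)
    blocks <- dplyr::bind_rows(blocks, tr$blocks)
    trans_truth[[length(trans_truth) + 1L]] <- tr$truth
  }
  for (k in seq_len(cfg$n_intra_trans)) {
    tr <- make_trans_scaffold(k, FALSE)
    assemblies <- dplyr::bind_rows(assemblies, tr$seq)
    blocks <- dplyr::bind_rows(blocks, tr$blocks)
    trans_truth[[length(trans_truth) + 1L]] <- tr$truth
  }

  # clipped tails on the first scaffolds (unaligned ends)
  clipped_truth <- list()
  for (k in seq_len(min(cfg$n_clipped, nrow(assemblies)))) {
    tail_seq <- rand_dna(cfg$clipped_len, cfg$gc)
    old_len <- nchar(assemblies$sequence[k])
    assemblies$sequence[k] <- paste0(assemblies$sequence[k], tail_seq)
    clipped_truth[[k]] <- tibble(q_name = assemblies$name[k],
                                 start = old_len,
                                 end = old_len + cfg$clipped_len)
  }

  # nomadic + contaminant scaffolds; a corroborating "other genome" carries
  # the nomadic sequences
  nomadic <- list()
  other_parts <- list(rand_dna(2000, cfg$gc))
  for (k in seq_len(cfg$n_nomadic)) {
    L <- sample(cfg$nomadic_range[1]:cfg$nomadic_range[2], 1)
    s <- rand_dna(L, cfg$gc)
    nm <- paste0(ind1, "_nomadic", k)
    assemblies <- dplyr::bind_rows(assemblies,
      tibble(individual = ind1, name = nm, sequence = s))
    other_parts[[length(other_parts) + 1L]] <- s
    other_parts[[length(other_parts) + 1L]] <- rand_dna(1000, cfg$gc)
    nomadic[[length(nomadic) + 1L]] <- tibble(q_name = nm, length = L,
                                              in_other_genome = TRUE)
  }
  for (k in seq_len(cfg$n_contaminant)) {
    L <- sample(cfg$nomadic_range[1]:cfg$nomadic_range[2], 1)
    nm <- paste0(ind1, "_contam", k)
    assemblies <- dplyr::bind_rows(assemblies,
      tibble(individual = ind1, name = nm,
             sequence = rand_dna(L, cfg$gc)))
    nomadic[[length(nomadic) + 1L]] <- tibble(q_name = nm, length = L,
                                              in_other_genome = FALSE)
  }
  other_genome <- tibble(name = "otherasm",
                         sequence = paste(unlist(other_parts), collapse = ""))

  blocks$q_srcsize <- nchar(assemblies$sequence)[match(blocks$q_name,
                                                       assemblies$name)]
  list(assemblies = assemblies, blocks = blocks,
       trans_truth = dplyr::bind_rows(c(list(
         tibble(category = character(), chrom = character(), pos = integer(),
                q_name = character())), unname(trans_truth))),
       clipped_truth = dplyr::bind_rows(c(list(
         tibble(q_name = character(), start = integer(), end = integer())),
         unname(clipped_truth))),
       nomadic = dplyr::bind_rows(c(list(
         tibble(q_name = character(), length = integer(),
                in_other_genome = logical())), unname(nomadic))),
       other_genome = other_genome)
}

#' Simulate per-variant per-sample read counts
#'
#' Depth is Poisson around the configured mean; reads support R/A/neither
#' multinomially given the true genotype, a `neither_frac` background and a
#' `mismap_frac` of reads supporting the wrong allele. Depth 0 gives a
#' missing observation.
#'
#' @param genotypes long truth genotype tibble (`variant_id`, `sample`,
#'   `gt`).
#' @param config the config (fields `depth`, `neither_frac`, `mismap_frac`,
#'   `seed`).
#' @param depth overrides the config depth when given.
#' @return counts tibble (`variant_id`, `sample`, `r_count`, `a_count`,
#'   `depth`).
#' @export
simulate_intensities <- function(genotypes, config = sim_config(),
                                 depth = NULL) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 4L))
  dmean <- if (is.null(depth)) cfg$depth else depth
  eps <- cfg$neither_frac; dl <- cfg$mismap_frac
  probs <- list(
    RR = c((1 - eps) * (1 - dl), (1 - eps) * dl, eps),
    RA = c((1 - eps) / 2, (1 - eps) / 2, eps),
    AA = c((1 - eps) * dl, (1 - eps) * (1 - dl), eps))
  n <- nrow(genotypes)
  dep <- stats::rpois(n, dmean)
  r <- integer(n); a <- integer(n)
  for (i in seq_len(n)) {
    if (dep[i] == 0) next
    cnt <- stats::rmultinom(1, dep[i], probs[[genotypes$gt[i]]])
    r[i] <- cnt[1]; a[i] <- cnt[2]
  }
  tibble(variant_id = genotypes$variant_id, sample = genotypes$sample,
         r_count = r, a_count = a, depth = dep)
}

#' Simulate recalibration features for two classes
#'
#' Positive and negative classes are drawn from distinct multivariate
#' normals over the nine features (diagonal covariance), with ratio
#' features clamped to the unit interval and depths to >= 0.
#'
#' @param n_pos,n_neg class sizes.
#' @param seed seed.
#' @param separation multiplier on the class mean difference (1 = default;
#'   0 = identical classes).
#' @return tibble `variant_id`, `label` (1 positive / 0 negative) + the
#'   nine feature columns.
#' @export
simulate_features <- function(n_pos = 200L, n_neg = 200L, seed = 1L,
                              separation = 1) {
  set.seed(derive_seed(seed, 5L))
  mu_pos <- c(gap_ratio = 0.02, alt_depth = 15, neither_depth = 1,
              misalign_prob = 0.01, align_score = 800, local_identity = 0.99,
              scaffold_position = 0.5, proper_read_ratio = 0.95,
              improper_read_ratio = 0.05)
  mu_neg_full <- c(gap_ratio = 0.10, alt_depth = 6, neither_depth = 6,
                   misalign_prob = 0.06, align_score = 450,
                   local_identity = 0.93, scaffold_position = 0.5,
                   proper_read_ratio = 0.80, improper_read_ratio = 0.20)
  mu_neg <- mu_pos + separation * (mu_neg_full - mu_pos)
  sd_pos <- c(0.02, 4, 1, 0.01, 120, 0.01, 0.25, 0.03, 0.03)
  sd_neg <- sd_pos * 1.5
  draw <- function(n, mu, sdv) {
    x <- MASS::mvrnorm(n, mu, diag(sdv^2))
    x[, c(1, 4, 6, 7, 8, 9)] <- pmin(pmax(x[, c(1, 4, 6, 7, 8, 9)], 0), 1)
    x[, c(2, 3, 5)] <- pmax(x[, c(2, 3, 5)], 0)
    as_tibble(as.data.frame(x))
  }
  pos <- draw(n_pos, mu_pos, sd_pos)
  neg <- draw(n_neg, mu_neg, sd_neg)
  out <- dplyr::bind_rows(pos, neg)
  out$variant_id <- sprintf("feat%05d", seq_len(nrow(out)))
  out$label <- c(rep(1L, n_pos), rep(0L, n_neg))
  dplyr::relocate(out, "variant_id", "label")
}

#' Simulate outgroup genomes and orthologous windows
#'
#' Each outgroup carries the designated ancestral allele of every variant
#' plus background substitution divergence. Whole outgroup genomes are
#' emitted, together with per-variant orthologous windows (ancestral allele
#' with reference flanks, diverged) that the annotation wrapper consumes
#' directly.
#'
#' @param refdata from [simulate_reference()].
#' @param truth truth variant tibble (with `ancestral`).
#' @param config the config (`n_outgroups`, `divergence`,
#'   `ancestral_flank`, `seed`).
#' @return list: `genomes` (sequence tibble), `windows` (tibble
#'   `variant_id`, `outgroup`, `sequence`).
#' @export
simulate_outgroups <- function(refdata, truth, config = sim_config()) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 6L))
  ref <- refdata$ref
  genomes <- list(); windows <- list()
  for (g in seq_len(cfg$n_outgroups)) {
    og_name <- paste0("outgroup", g)
    for (ci in seq_len(nrow(ref))) {
      chrom <- ref$name[ci]
      s <- ref$sequence[ci]
      my <- truth[truth$chrom == chrom & truth$ancestral == "alt", , drop = FALSE]
      my <- my[order(-my$pos), , drop = FALSE]
      for (i in seq_len(nrow(my))) {   # apply ancestral=alt alleles 3'->5'
        v <- my[i, ]
        s <- paste0(substr(s, 1, v$pos - 1L), v$alt,
                    substr(s, v$pos + nchar(v$ref), nchar(s)))
      }
      genomes[[paste(og_name, chrom)]] <-
        tibble(name = paste0(og_name, "_", chrom),
               sequence = mutate_seq(s, cfg$divergence))
    }
    fl <- cfg$ancestral_flank
    for (i in seq_len(nrow(truth))) {
      v <- truth[i, ]
      rs <- seq_lookup(ref, v$chrom)
      lo <- max(1L, v$pos - fl)
      hi <- min(nchar(rs), v$pos + nchar(v$ref) - 1L + fl)
      mid <- if (v$ancestral == "ref") v$ref else v$alt
      win <- paste0(substr(rs, lo, v$pos - 1L), mid,
                    substr(rs, v$pos + nchar(v$ref), hi))
      windows[[paste(og_name, v$id)]] <-
        tibble(variant_id = v$id, outgroup = og_name,
               sequence = mutate_seq(win, cfg$divergence))
    }
  }
  list(genomes = dplyr::bind_rows(unname(genomes)),
       windows = dplyr::bind_rows(unname(windows)))
}

#' Run the full simulation
#'
#' Orchestrates reference, variants, population, alignments, intensities
#' and outgroups; everything needed to exercise the pipeline end-to-end.
#'
#' @param config from [sim_config()].
#' @return named list with all generator outputs.
#' @export
simulate_study <- function(config = sim_config()) {
  refdata <- simulate_reference(config)
  planted <- plant_variants(refdata, config)
  aln <- simulate_assembly_alignment(refdata, planted, config)
  counts <- simulate_intensities(planted$genotypes, config)
  outgroups <- simulate_outgroups(refdata, planted$truth, config)
  c(list(config = config, refdata = refdata), planted, aln,
    list(intensity_counts = counts, outgroups = outgroups))
}
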