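# Variant discovery: within-block and between-block calling, normalization,
# unaligned/uncovered accounting, population merging.

empty_block_tbl_test <- function() {
  tibble::tibble(ref_chrom = character(), ref_start = numeric(),
                 ref_end = numeric(), ref_srcsize = numeric(),
                 q_name = character(), q_start = numeric(),
                 q_end = numeric(), q_srcsize = numeric(),
                 strand = character(), score = numeric(),
                 ref_text = character(), q_text = character())
}

mini_ref <- function(seq) tibble::tibble(name = "chr1", sequence = seq)

make_block <- function(ref_seq, q_seq, ref_text, q_text, ref_start = 0,
                       q_start = 0, strand = "+", q_name = "scaf1") {
  tibble::tibble(
    ref_chrom = "chr1", ref_start = ref_start,
    ref_end = ref_start + nchar(gsub("-", "", ref_text)),
    ref_srcsize = nchar(ref_seq), q_name = q_name, q_start = q_start,
    q_end = q_start + nchar(gsub("-", "", q_text)),
    q_srcsize = nchar(q_seq), strand = strand, score = 1,
    ref_text = ref_text, q_text = q_text)
}

test_that("within-block calling emits SNPs and anchored indels", {
  ref <- mini_ref("GGACGTCC")
  q <- tibble::tibble(name = "scaf1", sequence = "GGACTTCC")
  b <- make_block(ref$sequence, q$sequence[1], "ACGT", "ACTT", ref_start = 2,
                  q_start = 2)
  v <- call_within_block(b, ref, q)
  expect_equal(nrow(v), 1L)
  expect_equal(v$category, "SNP")
  expect_equal(v$pos, 5L)         # 1-based position of the mismatch column
  expect_equal(v$ref, "G"); expect_equal(v$alt, "T")

  # ACGGT / AC-GT : 1-bp deletion anchored on the preceding base
  ref <- mini_ref("TTACGGTTT")
  q <- tibble::tibble(name = "scaf1", sequence = "TTACGTTT")
  b <- make_block(ref$sequence, q$sequence[1], "ACGGT", "AC-GT",
                  ref_start = 2, q_start = 2)
  v <- call_within_block(b, ref, q)
  expect_equal(v$category, "deletion")
  expect_equal(v$pos, 4L)
  expect_equal(v$ref, "CG"); expect_equal(v$alt, "C")

  # insertion
  ref <- mini_ref("TTACGTTT")
  q <- tibble::tibble(name = "scaf1", sequence = "TTACGGTTT")
  b <- make_block(ref$sequence, q$sequence[1], "AC-GT", "ACGGT",
                  ref_start = 2, q_start = 2)
  v <- call_within_block(b, ref, q)
  expect_equal(v$category, "insertion")
  expect_equal(v$ref, "C"); expect_equal(v$alt, "CG")
})

test_that("within-block calls equal an independent column-scanning oracle", {
  set.seed(31)
  for (case in 1:20) {
    # random gapped alignment over a random reference
    n <- 120
    rseq <- test_dna(n + 20)
    rpiece <- substr(rseq, 11, 10 + n)
    rt <- character(0); qt <- character(0)
    qparts <- character(0)
    for (i in seq_len(n)) {
      b <- substr(rpiece, i, i)
      u <- runif(1)
      if (u < 0.03 && i > 1) {            # SNP
        alt <- setdiff(c("A", "C", "G", "T"), b)[1]
        rt <- c(rt, b); qt <- c(qt, alt); qparts <- c(qparts, alt)
      } else if (u < 0.05 && i > 1) {     # 1-2 bp insertion after this base
        ins <- test_dna(sample(1:2, 1))
        rt <- c(rt, b, strrep("-", nchar(ins)))
        qt <- c(qt, b, ins)
        qparts <- c(qparts, b, ins)
      } else if (u < 0.07 && i > 1) {     # delete this base
        rt <- c(rt, b); qt <- c(qt, "-")
      } else {
        rt <- c(rt, b); qt <- c(qt, b); qparts <- c(qparts, b)
      }
    }
    ref <- mini_ref(rseq)
    qseq <- paste0("GGGG", paste(qparts, collapse = ""), "GGGG")
    q <- tibble::tibble(name = "scaf1", sequence = qseq)
    blk <- make_block(rseq, qseq, paste(rt, collapse = ""),
                      paste(qt, collapse = ""), ref_start = 10, q_start = 4)
    got <- call_within_block(blk, ref, q)
    # oracle: scan columns independently
    rch <- strsplit(blk$ref_text, "")[[1]]; qch <- strsplit(blk$q_text, "")[[1]]
    rpos <- 10 + cumsum(rch != "-")
    n_snp <- sum(rch != "-" & qch != "-" & rch != qch)
    runs <- function(m) { r <- rle(m); sum(r$values) }
    expect_equal(sum(got$category == "SNP"), n_snp)
    expect_equal(sum(got$category == "deletion"), runs(qch == "-"))
    expect_equal(sum(got$category == "insertion"), runs(rch == "-"))
    # every REF allele verifies against the reference
    for (i in seq_len(nrow(got))) {
      expect_equal(substr(rseq, got$pos[i], got$pos[i] + nchar(got$ref[i]) - 1),
                   got$ref[i])
    }
  }
})

test_that("between-block gaps classify as deletion/insertion/simultaneous", {
  set.seed(5)
  rseq <- test_dna(3000)
  # scaffold = ref with [1001..1500] deleted
  qseq <- paste0(substr(rseq, 1, 1000), substr(rseq, 1501, 3000))
  ref <- mini_ref(rseq)
  q <- tibble::tibble(name = "scaf1", sequence = qseq)
  blocks <- dplyr::bind_rows(
    make_block(rseq, qseq, substr(rseq, 1, 1000), substr(rseq, 1, 1000)),
    make_block(rseq, qseq, substr(rseq, 1501, 3000), substr(rseq, 1501, 3000),
               ref_start = 1500, q_start = 1000))
  v <- call_between_blocks(blocks, ref, q)
  expect_equal(v$category, "deletion")
  expect_equal(v$pos, 1000L)
  expect_equal(nchar(v$ref), 501L)      # anchor + 500 deleted bases
  expect_equal(v$ref, substr(rseq, 1000, 1500))

  # inter-chromosomal translocation: second block on another chromosome
  b2 <- blocks; b2$ref_chrom[2] <- "chr9"
  v <- call_between_blocks(b2, ref, q)
  expect_equal(v$category, "inter_translocation")
  expect_equal(v$mate_chrom, "chr9")
})

test_that("a strand-flipped interior block flanked by collinear blocks is an inversion", {
  set.seed(6)
  rseq <- test_dna(3000)
  seg <- substr(rseq, 1001, 1400)
  qseq <- paste0(substr(rseq, 1, 1000), revcomp(seg), substr(rseq, 1401, 3000))
  ref <- mini_ref(rseq)
  q <- tibble::tibble(name = "scaf1", sequence = qseq)
  blocks <- dplyr::bind_rows(
    make_block(rseq, qseq, substr(rseq, 1, 1000), substr(rseq, 1, 1000)),
    make_block(rseq, qseq, seg, seg, ref_start = 1000, q_start = 1000,
               strand = "-"),
    make_block(rseq, qseq, substr(rseq, 1401, 3000), substr(rseq, 1401, 3000),
               ref_start = 1400, q_start = 1400))
  v <- call_between_blocks(blocks, ref, q)
  expect_equal(v$category, "inversion")
  expect_equal(v$pos, 1000L)
  expect_equal(v$alt, paste0(substr(rseq, 1000, 1000), revcomp(seg)))
})

test_that("simultaneous gaps refine into substitutions and replacements", {
  v <- tibble::tibble(
    individual = "s", chrom = "chr1", pos = c(10L, 20L, 30L),
    ref = c("AACGT", "AAC", "ATTTT"),
    alt = c("ATTTT", "ATTTTT", "ATTTT"),
    category = "simultaneous_gap",
    q_name = "q", q_pos = 1L)
  out <- split_simultaneous_gap(v)
  expect_equal(out$category,
               c("block_substitution", "length_asymmetric_replacement"))
  expect_equal(nrow(out), 2L)   # identical interiors dropped
})

test_that("normalization left-shifts homopolymer indels and is idempotent", {
  ref <- mini_ref("GATTTTC")
  # deletion of one T reported at position 4 -> anchored at position 2
  v <- tibble::tibble(individual = "s", chrom = "chr1", pos = 4L,
                      ref = "TT", alt = "T", category = "deletion",
                      q_name = "q", q_pos = 1L)
  n1 <- normalize_variants(v, ref)
  expect_equal(n1$pos, 2L)
  expect_equal(n1$ref, "AT"); expect_equal(n1$alt, "A")
  expect_equal(normalize_variants(n1, ref), n1)
})

test_that("normalized positions equal an exhaustive shift oracle", {
  set.seed(17)
  for (case in 1:25) {
    # build a repetitive reference and delete/insert inside a repeat tract
    unit <- test_dna(sample(1:3, 1))
    tract <- strrep(unit, sample(4:8, 1))
    rseq <- paste0(test_dna(30), tract, test_dna(30))
    del <- runif(1) < 0.5
    L <- nchar(unit)
    p <- 30 + sample(seq_len(nchar(tract) - L), 1)   # anchor inside tract
    if (del) {
      v <- tibble::tibble(individual = "s", chrom = "chr1", pos = p,
                          ref = substr(rseq, p, p + L), alt = substr(rseq, p, p),
                          category = "deletion", q_name = "q", q_pos = 1L)
    } else {
      ins <- substr(tract, 1, L)
      v <- tibble::tibble(individual = "s", chrom = "chr1", pos = p,
                          ref = substr(rseq, p, p),
                          alt = paste0(substr(rseq, p, p), ins),
                          category = "insertion", q_name = "q", q_pos = 1L)
    }
    got <- normalize_variants(v, mini_ref(rseq))
    # oracle: brute-force leftmost equivalent representation by rebuilding
    # the mutated sequence from every candidate anchor
    apply_var <- function(pos, ref, alt) {
      paste0(substr(rseq, 1, pos - 1), alt,
             substr(rseq, pos + nchar(ref), nchar(rseq)))
    }
    target <- apply_var(v$pos, v$ref, v$alt)
    best <- NULL
    for (pp in 1:got$pos) {
      rr <- substr(rseq, pp, pp + abs(nchar(v$ref) - nchar(v$alt)))
      aa <- substr(rseq, pp, pp)
      if (del && identical(apply_var(pp, rr, aa), target)) { best <- pp; break }
      if (!del) {
        # at anchor pp the inserted interior is forced to be
        # target[pp+1 .. pp+L]; equivalent iff the remaining suffixes agree
        cand <- substr(target, pp + 1, pp + L)
        if (identical(apply_var(pp, aa, paste0(aa, cand)), target)) {
          best <- pp; break
        }
      }
    }
    expect_equal(got$pos, best)
    expect_identical(apply_var(got$pos, got$ref, got$alt), target)
  }
})

test_that("unaligned scaffold sequence classifies as clipped or nomadic", {
  expect_equal(classify_unaligned("s1", 5000, empty_block_tbl_test())$kind,
               "nomadic")
  b <- tibble::tibble(ref_chrom = "chr1", ref_start = 0, ref_end = 3000,
                      ref_srcsize = 10000, q_name = "s1", q_start = 0,
                      q_end = 3000, q_srcsize = 5000, strand = "+", score = 1,
                      ref_text = "x", q_text = "x")
  seg <- classify_unaligned("s1", 5000, b)
  expect_equal(seg$kind, "clipped")
  expect_equal(seg$start, 3000); expect_equal(seg$end, 5000)
  # short leftovers below the threshold are not emitted
  expect_equal(nrow(classify_unaligned("s1", 3050, b)), 0L)
})

test_that("reference gaps tile the genome and classify by flanking scaffold", {
  b <- tibble::tibble(
    ref_chrom = "chr1", ref_start = c(0, 20000, 40000),
    ref_end = c(10000, 30000, 50000), ref_srcsize = 50000,
    q_name = c("s1", "s1", "s2"), q_start = 0, q_end = 10000,
    q_srcsize = 60000, strand = "+", score = 1, ref_text = "x", q_text = "x")
  gaps <- find_reference_gaps(b, tibble::tibble(name = "chr1", length = 50000))
  expect_equal(gaps$kind, c("intra_scaffold", "inter_scaffold"))
  # union of gaps and covered spans is the whole chromosome, disjoint
  cov <- IRanges::IRanges(b$ref_start + 1, b$ref_end)
  gp <- IRanges::IRanges(gaps$start + 1, gaps$end)
  un <- IRanges::reduce(c(cov, gp))
  expect_equal(IRanges::start(un), 1L)
  expect_equal(IRanges::end(un), 50000L)
  expect_equal(sum(IRanges::width(cov)) + sum(IRanges::width(gp)), 50000L)
})

test_that("population merge collapses identical records and keeps distinct ALTs", {
  v <- tibble::tibble(
    individual = c("a", "b", "c", "a"),
    chrom = "chr1", pos = c(100L, 100L, 100L, 100L),
    ref = "AT", alt = c("A", "A", "A", "ATT"),
    category = "deletion", q_name = "q", q_pos = 1L)
  m <- merge_population(v)
  expect_equal(nrow(m), 2L)
  expect_equal(m$ncarrier, c(3L, 1L))          # sorted by alt: A < ATT
  expect_setequal(m$carriers[[which(m$alt == "A")]], c("a", "b", "c"))

  flagged <- find_double_hits(m)
  expect_equal(flagged$double_hit, c(TRUE, FALSE))
  # tabulation oracle
  expect_equal(sum(flagged$double_hit),
               sum(table(paste(v$chrom, v$pos, v$ref, v$alt)) >= 2))
})

test_that("merge is invariant to input order and flags reference conflicts", {
  sim <- small_sim()
  disc <- small_discovery()
  pv <- disc$per_individual
  set.seed(2)
  m1 <- merge_population(pv)
  m2 <- merge_population(pv[sample(nrow(pv)), ])
  expect_equal(m1[c("chrom", "pos", "ref", "alt", "ncarrier")],
               m2[c("chrom", "pos", "ref", "alt", "ncarrier")])

  bad <- tibble::tibble(individual = c("a", "b"), chrom = "chr1",
                        pos = 10L, ref = c("AT", "AG"), alt = c("A", "A"),
                        category = "deletion", q_name = "q", q_pos = 1L)
  expect_error(merge_population(bad), "conflicting reference")
})

test_that("prior call sets mark known records and add novel ones", {
  v <- tibble::tibble(individual = "a", chrom = "chr1", pos = 100L,
                      ref = "AT", alt = "A", category = "deletion",
                      q_name = "q", q_pos = 1L)
  prior <- tibble::tibble(chrom = "chr1", pos = c(100L, 900L),
                          ref = c("AT", "C"), alt = c("A", "CGG"))
  m <- merge_population(v, prior)
  expect_equal(nrow(m), 2L)
  expect_true(all(m$known))
  expect_equal(m$ncarrier[m$pos == 900], 0L)
})

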