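# Ancestral-state classification, type rectification, mechanism calling.

test_that("allele construction takes 500 bp flanks, truncated at ends", {
  set.seed(41)
  ref <- tibble::tibble(name = "chr1", sequence = test_dna(5000))
  v <- tibble::tibble(chrom = "chr1", pos = 2500L, ref = "A", alt = "T")
  al <- build_alleles(v, ref)
  expect_equal(nchar(al$ref_allele_seq), 1001L)
  expect_equal(nchar(al$alt_allele_seq), 1001L)
  expect_equal(substr(al$alt_allele_seq, 501, 501), "T")

  # left flank truncated near the chromosome start
  v2 <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T")
  expect_equal(nchar(build_alleles(v2, ref)$ref_allele_seq), 600L)

  # deletion: ref allele longer by the deleted length
  v3 <- tibble::tibble(chrom = "chr1", pos = 2000L,
                       ref = substr(ref$sequence, 2000, 2300), alt = "G")
  al3 <- build_alleles(v3, ref)
  expect_equal(nchar(al3$ref_allele_seq) - nchar(al3$alt_allele_seq), 300L)

  expect_error(build_alleles(tibble::tibble(chrom = "chr1", pos = 6000L,
                                            ref = "A", alt = "T"), ref),
               "outside")
})

# build a deletion fixture: ref allele (long) carries segment S; alt lacks it
ancestral_fixture <- function(seed = 50) {
  set.seed(seed)
  lf <- test_dna(400); rf <- test_dna(400); seg <- test_dna(300)
  list(long = paste0(lf, seg, rf), short = paste0(lf, rf),
       lf = lf, rf = rf, seg = seg)
}

test_that("ancestral state follows the outgroup rule table", {
  fx <- ancestral_fixture()
  og_long <- tibble::tibble(name = "og1", sequence = fx$long)
  og_short <- tibble::tibble(name = "og1", sequence = fx$short)

  # outgroup carries the longer allele -> Deletion event
  expect_equal(classify_ancestral(fx$long, fx$short, og_long)$state, "Deletion")
  # outgroup carries the shorter allele -> Insertion event
  expect_equal(classify_ancestral(fx$long, fx$short, og_short)$state, "Insertion")
  # both alleles verbatim in the outgroup (tandem context) -> Common
  og_both <- tibble::tibble(name = "og1",
                            sequence = paste0(fx$long, strrep("T", 50), fx$short))
  expect_equal(classify_ancestral(fx$long, fx$short, og_both)$state, "Common")
  # nothing aligns -> NONE
  set.seed(51)
  og_none <- tibble::tibble(name = "og1", sequence = test_dna(800))
  expect_equal(classify_ancestral(fx$long, fx$short, og_none)$state, "NONE")
  # disagreement between outgroups -> Conflict
  og2 <- tibble::tibble(name = c("og1", "og2"),
                        sequence = c(fx$long, fx$short))
  expect_equal(classify_ancestral(fx$long, fx$short, og2)$state, "Conflict")
  expect_error(classify_ancestral(fx$long, fx$short,
                                  tibble::tibble(name = character(),
                                                 sequence = character())),
               "empty outgroup")
})

test_that("heavily diverged outgroups give NA", {
  fx <- ancestral_fixture(52)
  # ~15 % divergence: alignment exists but neither allele passes 0.95
  div <- mutate_k(fx$long, round(nchar(fx$long) * 0.15), seed = 53)
  og <- tibble::tibble(name = "og1", sequence = div)
  expect_equal(classify_ancestral(fx$long, fx$short, og)$state, "NA")
})

test_that("classification is invariant to outgroup order except Conflict", {
  fx <- ancestral_fixture(54)
  og <- tibble::tibble(name = c("og1", "og2"),
                       sequence = c(fx$long, mutate_k(fx$long, 5, seed = 55)))
  s1 <- classify_ancestral(fx$long, fx$short, og)$state
  s2 <- classify_ancestral(fx$long, fx$short, og[2:1, ])$state
  expect_equal(s1, s2)
})

test_that("rectification flips types against the ancestral evidence", {
  v <- tibble::tibble(category = c("insertion", "deletion", "deletion",
                                   "insertion"),
                      aa_state = c("Deletion", "Insertion", "NA", "Common"))
  out <- rectify_type(v)
  expect_equal(out$category, c("deletion", "insertion", "deletion",
                               "insertion"))
  expect_equal(out$orig_category, v$category)
  # involution on the insertion/deletion pair given a fixed ancestral call
  out2 <- rectify_type(dplyr::mutate(out, category = out$orig_category))
  expect_equal(out2$category, out$category)
})

test_that("mechanism precedence and thresholds behave on constructed fixtures", {
  set.seed(61)
  lf <- test_dna(200); rf <- test_dna(200)

  # variants below 50 bp are UNSURE
  expect_equal(classify_mechanism(test_dna(30), lf, rf)$mechanism, "UNSURE")

  # CCC: 60-bp variant equal to the next 60 bp 3' of the right breakpoint
  seg <- substr(rf, 1, 60)
  expect_equal(classify_mechanism(seg, lf, rf)$mechanism, "CCC")

  # TEI: 300-bp variant at ~95 % identity to a mobile-element record
  alu <- test_dna(300)
  lib <- tibble::tibble(name = c("ALU#mobile_element", "TR#simple_repeat"),
                        sequence = c(alu, strrep(test_dna(25), 10)))
  tei <- mutate_k(alu, 15, seed = 62)
  got <- classify_mechanism(tei, lf, rf, lib)
  expect_equal(got$mechanism, "TEI")
  expect_equal(got$evidence[["repeat_name"]], "ALU#mobile_element")

  # VNTR: diverged tandem units matching the simple-repeat record
  unit <- lib$sequence[2]
  vntr <- paste0(mutate_k(substr(unit, 1, 25), 1, seed = 63),
                 mutate_k(substr(unit, 1, 25), 1, seed = 64),
                 mutate_k(substr(unit, 1, 25), 1, seed = 65))
  expect_equal(classify_mechanism(vntr, lf, rf, lib)$mechanism, "VNTR")

  # NAHR: breakpoint flanks aligning reciprocally at 90 %+
  h <- test_dna(200)
  h2 <- mutate_k(h, 10, seed = 66)
  expect_equal(classify_mechanism(test_dna(2000), h, h2, lib)$mechanism,
               "NAHR")

  # NHR: >= 2 bp microhomology with the 3' flank
  mh_var <- paste0(substr(rf, 1, 3), test_dna(100))
  got_nhr <- classify_mechanism(mh_var, lf, rf)
  expect_equal(got_nhr$mechanism, "NHR")
  expect_gte(as.integer(got_nhr$evidence[["microhomology"]]), 3L)

  # nothing matches -> NA
  bare <- test_dna(80)
  while (substr(bare, 1, 2) == substr(rf, 1, 2) ||
         substr(bare, 79, 80) == substr(lf, 199, 200)) bare <- test_dna(80)
  expect_equal(classify_mechanism(bare, lf, rf)$mechanism, "NA")

  expect_error(classify_mechanism("", lf, rf), "empty")
})

test_that("every identity/ratio configuration maps to exactly one state", {
  # grid property: synthetic measurement tables pushed through the rule
  fx <- ancestral_fixture(70)
  for (id_l in c(0.9, 0.96)) for (id_s in c(0.9, 0.96)) {
    # construct one outgroup realizing (approximately) the target pattern
    og_seq <- if (id_l > 0.95 && id_s > 0.95) paste0(fx$long, "T", fx$short)
      else if (id_l > 0.95) fx$long
      else if (id_s > 0.95) fx$short
      else mutate_k(fx$long, round(nchar(fx$long) * 0.2), seed = 71)
    st <- classify_ancestral(fx$long, fx$short,
                             tibble::tibble(name = "og", sequence = og_seq))$state
    expect_length(st, 1)
    expect_true(st %in% c("NONE", "NA", "Common", "Deletion", "Insertion",
                          "Conflict"))
  }
})

test_that("annotate_variants drives rules end-to-end on generator fixtures", {
  cfg <- sim_config(seed = 19, scale = 0.5, n_snp = 0, n_small_del = 0,
                    n_small_ins = 0, n_bsub = 0, n_lar = 0, n_inv = 0,
                    n_novel_ins = 0, n_plain_del = 0)
  refdata <- simulate_reference(cfg)
  planted <- plant_variants(refdata, cfg)
  og <- simulate_outgroups(refdata, planted$truth, cfg)
  ann <- annotate_variants(planted$truth, refdata$ref, outgroups = og$windows,
                           repeat_library = refdata$repeat_library)
  big <- pmax(nchar(ann$ref), nchar(ann$alt)) - 1 >= 50
  expected <- ifelse(ann$orig_category == "deletion",
                     ifelse(ann$ancestral == "ref", "Deletion", "Insertion"),
                     ifelse(ann$ancestral == "ref", "Insertion", "Deletion"))
  expect_true(all(ann$aa_state[big] == expected[big]))
  mech_truth <- planted$truth$mechanism
  has_mech <- !is.na(mech_truth) & big
  expect_true(all(ann$mechanism[has_mech] == mech_truth[has_mech]))
})
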