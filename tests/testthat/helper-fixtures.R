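# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# small full simulation shared across discovery/report/novelseq tests
small_sim <- function() {
  if (is.null(fixture_env$sim)) {
    fixture_env$sim <- simulate_study(sim_config(seed = 11, scale = 0.4))
  }
  fixture_env$sim
}

small_discovery <- function() {
  if (is.null(fixture_env$disc)) {
    sim <- small_sim()
    fixture_env$disc <- discover_population(sim$blocks, sim$refdata$ref,
                                            sim$assemblies)
  }
  fixture_env$disc
}

record_key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)

# deterministic random DNA for constructed fixtures
test_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate exactly k positions of a sequence (never the first/last base),
# returning the mutated sequence; used for counted-identity fixtures
mutate_k <- function(s, k, seed = 1) {
  set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  idx <- sample(2:(length(ch) - 1), k)
  for (i in idx) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  paste(ch, collapse = "")
}

# Biostrings-based global/local score oracle (independent of the package DP)
biostrings_score <- function(a, b, type) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = type, substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1))
}
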