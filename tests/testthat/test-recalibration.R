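# Quality recalibration: features, class mixtures, scoring, threshold,
# cross-validation, inbreeding filter.

test_that("feature extraction covers the documented operationalizations", {
  q <- tibble::tibble(name = "scafA",
                      sequence = paste0(strrep("A", 450), strrep("N", 100),
                                        strrep("C", 450)))
  v <- tibble::tibble(id = "v1", chrom = "chr1", pos = 10L, ref = "A",
                      alt = "AT", q_name = "scafA", q_pos = 500L)
  f <- extract_features(v, query_seqs = q)
  expect_equal(f$scaffold_position, 0.5)
  expect_equal(f$gap_ratio, 100 / 1000, tolerance = 1e-6)  # window clipped at the scaffold start

  # no N in the window -> gap ratio 0
  q2 <- tibble::tibble(name = "scafA", sequence = strrep("A", 1000))
  f2 <- extract_features(v, query_seqs = q2)
  expect_equal(f2$gap_ratio, 0)

  rs <- tibble::tibble(variant_id = "v1", alt_depth = 12, neither_depth = 0,
                       proper_read_ratio = 1.0, improper_read_ratio = 0.0)
  f3 <- extract_features(v, query_seqs = q, read_summary = rs)
  expect_equal(f3$proper_read_ratio, 1.0)
  expect_equal(f3$improper_read_ratio, 0.0)

  expect_error(extract_features(v), "no recalibration features")
})

test_that("BIC selects one cluster for one cloud and two for two", {
  set.seed(9)
  one <- tibble::tibble(f1 = rnorm(150, 0, 0.3), f2 = rnorm(150, 0, 0.3))
  expect_equal(fit_class_mixture(one)$G, 1L)
  two <- tibble::tibble(f1 = c(rnorm(100, -4), rnorm(100, 4)),
                        f2 = c(rnorm(100, -4), rnorm(100, 4)))
  expect_equal(fit_class_mixture(two)$G, 2L)
  w <- fit_class_mixture(two)$parameters$pro
  expect_equal(sum(w), 1)
  expect_error(fit_class_mixture(one[1:5, ]), ">= 10")
})

test_that("the log-odds score follows the stated arithmetic", {
  # P_pos = 0.99, P_neg = 0.9 -> -lg(0.01) + lg(0.1) = 1
  expect_equal(asmsv:::log_odds_score(0.99, 0.9), 1)
  expect_equal(asmsv:::log_odds_score(0.7, 0.7), 0)
  # monotone increasing in P_pos at fixed P_neg, finite after clamping
  grid <- seq(0.01, 0.999999, length.out = 50)
  sc <- asmsv:::log_odds_score(grid, 0.5)
  expect_true(all(diff(sc) > 0))
  expect_true(all(is.finite(asmsv:::log_odds_score(c(0, 1), c(1, 0)))))
})

test_that("scores separate simulated classes and threshold transfers", {
  f <- simulate_features(250, 250, seed = 3)
  train <- f[c(1:150, 251:400), ]
  test <- f[c(151:250, 401:500), ]
  model <- fit_recalibrator(train[, -2],
                            positive_ids = train$variant_id[train$label == 1],
                            negative_ids = train$variant_id[train$label == 0])
  expect_gte(model$auc, 0.99)
  sc <- score_variants(test[, -2], model)
  pred <- sc$score >= model$threshold
  expect_gte(mean(pred[test$label == 1]), 0.90)
  expect_lte(mean(pred[test$label == 0]), 0.10)
})

test_that("known variants get the higher positive prior", {
  f <- simulate_features(100, 100, seed = 5)
  model <- fit_recalibrator(f[, -2],
                            positive_ids = f$variant_id[f$label == 1],
                            negative_ids = f$variant_id[f$label == 0])
  # a borderline point (componentwise midpoint of the two classes) so that
  # neither class density saturates the clamp
  mid <- f[1, -2]
  for (cc in model$features) mid[[cc]] <- mean(f[[cc]])
  model$known_ids <- mid$variant_id
  s_known <- score_variants(mid, model)$score
  model$known_ids <- character(0)
  s_novel <- score_variants(mid, model)$score
  expect_gt(s_known, s_novel)
})

test_that("ROC threshold maximizes Youden J and AUC matches rank statistic", {
  # perfectly separated scores
  thr <- choose_threshold(c(1:10, 21:30), rep(c(0, 1), each = 10))
  expect_equal(thr$auc, 1)
  j <- thr$roc$tpr - thr$roc$fpr
  expect_equal(max(j), 1)

  set.seed(11)
  scores <- c(rnorm(150, 0), rnorm(150, 1))
  labels <- rep(c(0, 1), each = 150)
  thr2 <- choose_threshold(scores, labels)
  # Mann-Whitney U oracle
  u <- wilcox.test(scores[labels == 1], scores[labels == 0])$statistic
  expect_equal(thr2$auc, unname(u) / (150 * 150), tolerance = 1e-9)

  # labels independent of scores -> AUC ~ 0.5
  set.seed(12)
  thr3 <- choose_threshold(rnorm(800), rbinom(800, 1, 0.5))
  expect_lt(abs(thr3$auc - 0.5), 0.06)
  expect_error(choose_threshold(1:5, rep(1, 5)), "both")
})

test_that("cross-validation partitions exactly and tracks separability", {
  f <- simulate_features(60, 60, seed = 21)
  pos <- f$variant_id[f$label == 1]; neg <- f$variant_id[f$label == 0]
  cv <- cross_validate(f[, -2], pos, neg, k = 3, seed = 2)
  expect_equal(sum(cv$folds$n), 120L)
  expect_lt(cv$error_rate, 0.05)

  # shuffled labels -> error near 0.5
  set.seed(3)
  shuf <- sample(f$variant_id)
  cv2 <- suppressWarnings(cross_validate(f[, -2], shuf[1:60], shuf[61:120],
                                         k = 3, seed = 2))
  expect_gt(cv2$error_rate, 0.3)

  expect_warning(cross_validate(f[c(1:15, 61:120), -2], pos[1:15], neg,
                                k = 20, seed = 1), "reducing k")
})

test_that("inbreeding coefficient reproduces the worked examples", {
  # p = q = 0.5, N = 20, N_het = 10 -> F = 0 (Hardy-Weinberg expectation)
  x <- inbreeding_coefficient(c(rep("RA", 10), rep("RR", 5), rep("AA", 5)))
  expect_equal(x$f, 0)
  expect_equal(x$p, 0.5)
  # N_het = 0 -> F = 1
  expect_equal(inbreeding_coefficient(c(rep("RR", 10), rep("AA", 10)))$f, 1)
  # N_het = 15 at p = q = 0.5, N = 20 -> F = -0.5
  expect_equal(inbreeding_coefficient(n = 20, n_het = 15, p = 0.5)$f, -0.5)
  # monomorphic locus -> undefined
  expect_true(is.na(inbreeding_coefficient(rep("RR", 20))$f))
  expect_error(inbreeding_coefficient(character(0)), ">= 2")
})

test_that("HWE-simulated loci have F centered at zero", {
  set.seed(6)
  fs <- replicate(1000, {
    p <- runif(1, 0.2, 0.8)
    gt <- c("RR", "RA", "AA")[rbinom(20, 2, 1 - p) + 1]
    inbreeding_coefficient(gt)$f
  })
  expect_lt(abs(mean(fs, na.rm = TRUE)), 0.05)
})

test_that("the inbreeding filter uses strict bounds", {
  recs <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L),
                         id = c("a", "b", "c"), ref = "A", alt = "T",
                         filter = ".")
  mk <- function(id, n_rr, n_ra, n_aa) {
    tibble::tibble(id = id,
                   sample = sprintf("s%02d", seq_len(n_rr + n_ra + n_aa)),
                   gt = c(rep("RR", n_rr), rep("RA", n_ra), rep("AA", n_aa)))
  }
  calls <- dplyr::bind_rows(mk("a", 5, 10, 5),     # F = 0 -> retained
                            mk("b", 2, 15, 3),     # F < -0.4 -> filtered
                            mk("c", 8, 0, 8))      # F = 1 -> filtered
  out <- filter_by_inbreeding(recs, calls, unrelated = unique(calls$sample))
  expect_equal(out$filter, c(".", "inbreeding_coef", "inbreeding_coef"))
  expect_equal(out$f_coef[1], 0)
  # F exactly at the upper bound is retained (strict inequality)
  out2 <- filter_by_inbreeding(recs[1, ], mk("a", 5, 10, 5),
                               unrelated = sprintf("s%02d", 1:20),
                               high = 0)
  expect_equal(out2$filter, ".")
})

test_that("applying recalibration writes PASS/FALSE exhaustively", {
  f <- simulate_features(80, 80, seed = 31)
  model <- fit_recalibrator(f[, -2],
                            positive_ids = f$variant_id[f$label == 1],
                            negative_ids = f$variant_id[f$label == 0])
  recs <- tibble::tibble(chrom = "chr1", pos = seq_len(nrow(f)) * 10L,
                         id = f$variant_id, ref = "A", alt = "T")
  out <- apply_recalibration(recs, f[, -2], model)
  expect_true(all(out$filter %in% c("PASS", "FALSE")))
  expect_true(all(is.finite(out$recal_score)))
  expect_equal(out$filter == "PASS", out$recal_score >= model$threshold)
})
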