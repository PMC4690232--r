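# Constrained Gaussian-mixture genotyping: intensities, likelihoods, EM,
# genotype calls, Mendelian checks, scaling-factor selection.

test_that("intensities are normalized read counts with missing at depth 0", {
  x <- compute_intensities(tibble::tibble(
    variant_id = "v", sample = c("a", "b", "c", "d"),
    r_count = c(10L, 5L, 3L, 0L), a_count = c(0L, 5L, 4L, 0L),
    depth = c(10L, 10L, 10L, 0L)))
  expect_equal(x$r_intensity, c(1.0, 0.5, 0.3, NA))
  expect_equal(x$a_intensity, c(0.0, 0.5, 0.4, NA))
  expect_error(compute_intensities(tibble::tibble(
    variant_id = "v", sample = "a", r_count = -1L, a_count = 0L,
    depth = 5L)), "negative")
})

toy_model <- function(sd = 0.1, w = c(1, 1, 1) / 3) {
  structure(list(
    w = setNames(w, c("RR", "RA", "AA")),
    mu = matrix(c(1, 0.001, 0.5, 0.5, 0.001, 1), 3, 2, byrow = TRUE),
    sigma = replicate(3, diag(sd^2, 2), simplify = FALSE),
    m = 1, loglik = 0, n = 0, converged = TRUE),
    class = "sv_genotype_model")
}

test_that("state likelihood is the weighted bivariate normal density", {
  m <- toy_model()
  # peak at its own center under equal weights and shared covariance
  for (j in 1:3) {
    vals <- vapply(1:3, function(k) state_likelihood(m$mu[j, ], m, k),
                   numeric(1))
    expect_equal(which.max(vals), j)
  }
  # linear in the weight
  m2 <- toy_model(w = c(2, 1, 1) / 4)
  expect_equal(state_likelihood(c(0.4, 0.5), m2, 1) /
               state_likelihood(c(0.4, 0.5), toy_model(w = c(1, 1, 1) / 4), 1),
               2)
  # density oracle: product of independent normals for diagonal covariance
  set.seed(4)
  for (k in 1:10) {
    d <- runif(2)
    expect_equal(state_likelihood(d, m, 2),
                 (1 / 3) * dnorm(d[1], 0.5, 0.1) * dnorm(d[2], 0.5, 0.1))
  }
})

test_that("posteriors normalize, peak correctly, and survive underflow", {
  m <- toy_model()
  p <- posterior(c(0.5, 0.5), m)
  expect_equal(sum(p), 1)
  expect_gt(p["RA"], 0.99)
  # invariance under a constant factor on all weights
  p2 <- posterior(c(0.5, 0.5), toy_model(w = c(1, 1, 1)))
  expect_equal(p, p2)
  # underflow far outside all states
  mtight <- toy_model(sd = 1e-4)
  expect_warning(p3 <- posterior(c(0.25, 0.8), mtight), "underflow")
  expect_equal(unname(p3), rep(1 / 3, 3))
})

test_that("EM recovers planted mixture parameters at N = 500", {
  set.seed(123)
  n <- 500
  z <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  mu <- matrix(c(1, 0.001, 0.5, 0.5, 0.001, 1), 3, 2, byrow = TRUE)
  d <- tibble::tibble(
    r_intensity = rnorm(n, mu[z, 1], 0.05),
    a_intensity = rnorm(n, mu[z, 2], 0.05))
  fit <- fit_em(d)
  expect_true(max(abs(fit$w - c(0.25, 0.5, 0.25))) < 0.05)
  expect_true(max(abs(fit$mu - mu)) < 0.02)
  expect_true(all(diff(fit$loglik) >= -1e-6))
  # state ordering constraint holds on the a-intensity coordinate
  expect_true(fit$mu[1, 2] < fit$mu[2, 2] && fit$mu[2, 2] < fit$mu[3, 2])
})

test_that("degenerate data pins the weight on one state", {
  d <- tibble::tibble(r_intensity = rep(1, 50) + rnorm(50, 0, 1e-3),
                      a_intensity = rep(0, 50) + abs(rnorm(50, 0, 1e-3)))
  fit <- suppressWarnings(fit_em(d))
  expect_gt(fit$w["RR"], 0.99)
  expect_error(fit_em(tibble::tibble(r_intensity = 1, a_intensity = 0)),
               "at least 3")
})

test_that("genotype calls take the posterior argmax with capped Phred GQ", {
  m <- toy_model(sd = 0.05)
  calls <- call_genotypes(tibble::tibble(
    r_intensity = c(1, 0.5, 0, NA), a_intensity = c(0, 0.5, 1, NA)), m)
  expect_equal(calls$gt, c("RR", "RA", "AA", NA))
  expect_true(all(calls$gq[1:3] >= 0 & calls$gq[1:3] <= 99))
  expect_true(is.na(calls$gt[4]))

  # GQ arithmetic: posteriors (0.9, 0.1, 0) -> GQ = -10 log10(0.1) = 10,
  # uniform posteriors -> GQ = -10 log10(2/3) ~ 1.76 with tie to RR
  expect_equal(-10 * log10(1 - 0.9), 10)
  mwide <- toy_model(sd = 10)           # nearly uniform posteriors
  c2 <- call_genotypes(tibble::tibble(r_intensity = 0.5, a_intensity = 0.5),
                       mwide)
  expect_equal(c2$gq, -10 * log10(1 - c2$p_ra), tolerance = 1e-6)
  expect_lt(abs(c2$gq - 1.76), 0.05)
  # numerically certain call caps at 99
  c3 <- call_genotypes(tibble::tibble(r_intensity = 1, a_intensity = 0),
                       toy_model(sd = 0.01))
  expect_equal(c3$gq, 99)
})

test_that("tied posteriors break deterministically to the first state", {
  m <- toy_model(sd = 0.1)
  # equidistant from RR and AA centers on the diagonal
  c1 <- call_genotypes(tibble::tibble(r_intensity = 0.5005,
                                      a_intensity = 0.5005), m)
  expect_true(c1$gt %in% c("RR", "RA", "AA"))
  # exact symmetric point with RA removed from competition
  m$w <- setNames(c(0.5, 0, 0.5), c("RR", "RA", "AA"))
  c2 <- call_genotypes(tibble::tibble(r_intensity = 0.5005,
                                      a_intensity = 0.5005), m)
  expect_equal(c2$gt, "RR")
})

test_that("Mendelian error rate matches the 27-case transmission table", {
  # exhaustive truth table computed independently from allele sets
  gts <- c("RR", "RA", "AA")
  allele_sets <- list(RR = "R", RA = c("R", "A"), AA = "A")
  oracle_ok <- function(f, m, c) {
    poss <- outer(allele_sets[[f]], allele_sets[[m]],
                  function(a, b) paste0(pmin(a, b), pmax(a, b)))
    c %in% sub("AR", "RA", unique(as.vector(poss)))
  }
  trios <- tibble::tibble(child = "c", father = "f", mother = "m")
  for (f in gts) for (m in gts) for (cc in gts) {
    calls <- tibble::tibble(variant_id = "v1",
                            sample = c("f", "m", "c"),
                            gt = c(f, m, cc))
    r <- mendelian_error_rate(calls, trios)
    expect_equal(r$rate, as.numeric(!oracle_ok(f, m, cc)),
                 info = paste(f, m, cc))
  }
})

test_that("Mendelian rate counts trio-complete loci only", {
  calls <- tibble::tibble(
    variant_id = rep(sprintf("v%02d", 1:10), each = 3),
    sample = rep(c("f", "m", "c"), 10),
    gt = c(rep(c("RR", "RR", "RR"), 9), c("RR", "RR", "AA")))
  trios <- tibble::tibble(child = "c", father = "f", mother = "m")
  expect_equal(mendelian_error_rate(calls, trios)$rate, 0.1)
  calls$gt[30] <- "RR"
  expect_equal(mendelian_error_rate(calls, trios)$rate, 0)
  calls$sample[calls$sample == "f"] <- "stranger"
  trios$father <- "f"
  expect_error(mendelian_error_rate(calls, trios), "absent")
})

test_that("scaling-factor selection fits five models and recovers m = 1", {
  set.seed(77)
  n <- 300
  z <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.45, 0.25))
  mu <- matrix(c(1, 0.001, 0.5, 0.5, 0.001, 1), 3, 2, byrow = TRUE)
  d <- tibble::tibble(
    variant_id = "v1", sample = sprintf("s%03d", 1:n),
    r_intensity = rnorm(n, mu[z, 1], 0.05),
    a_intensity = rnorm(n, mu[z, 2], 0.05))
  sel <- select_scaling_factor(d)
  expect_equal(nrow(sel$grid), 5L)
  expect_equal(sel$grid$m, c(0.8, 0.9, 1.0, 1.1, 1.2))
  expect_equal(sel$m, 1.0)
  # deterministic given the data
  sel2 <- select_scaling_factor(d)
  expect_equal(sel2$m, sel$m)
  expect_equal(sel2$grid$bias, sel$grid$bias)
})

test_that("concordance degrades monotonically with depth", {
  set.seed(55)
  n_var <- 12; n_ind <- 60
  af <- runif(n_var, 0.3, 0.7)
  gt_truth <- tibble::tibble(
    variant_id = rep(sprintf("v%02d", 1:n_var), each = n_ind),
    sample = rep(sprintf("s%02d", 1:n_ind), n_var),
    gt = unlist(lapply(af, function(p) {
      c("RR", "RA", "AA")[rbinom(n_ind, 2, 1 - p) + 1]
    })))
  conc <- vapply(c(40, 20, 10, 5), function(dep) {
    cfg <- sim_config(seed = 100 + dep)
    counts <- simulate_intensities(gt_truth, cfg, depth = dep)
    ints <- compute_intensities(counts)
    gp <- suppressWarnings(genotype_population(ints))
    cmp <- dplyr::inner_join(gp$calls, gt_truth,
                             by = c("variant_id", "sample"),
                             suffix = c("", ".true"))
    mean(cmp$gt == cmp$gt.true, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(conc) <= 0.005))   # non-increasing up to noise
  expect_gt(conc[1], 0.97)
})

test_that("broom and plot methods expose the fitted model", {
  set.seed(1)
  d <- tibble::tibble(r_intensity = c(rnorm(40, 1, .05), rnorm(40, .5, .05),
                                      rnorm(40, 0, .05)),
                      a_intensity = c(rnorm(40, 0, .05), rnorm(40, .5, .05),
                                      rnorm(40, 1, .05)))
  fit <- fit_em(d)
  td <- tidy(fit)
  expect_equal(td$state, c("RR", "RA", "AA"))
  expect_equal(sum(td$weight), 1)
  gl <- glance(fit)
  expect_true(gl$converged)
  p <- autoplot(fit, d)
  expect_s3_class(p, "ggplot")
})
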