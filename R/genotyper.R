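# Population genotyping of bi-allelic structural variants.
#
# Observation per individual per variant: d = (r, a), the fractions of
# uniquely-aligned reads supporting the reference and the alternative
# allele. A three-state Gaussian mixture (RR, RA, AA) with linear
# constraints on the state centers is fitted by EM across the population;
# genotypes are the posterior argmax, with Phred-scale quality
# GQ = -10 log10(1 - p_best), capped at 99.

GT_STATES <- c("RR", "RA", "AA")

# expected (r, a) centers before m-scaling
expected_centers <- function() {
  matrix(c(1.0, 0.001,
           0.5, 0.5,
           0.001, 1.0), nrow = 3, byrow = TRUE,
         dimnames = list(GT_STATES, c("r", "a")))
}

#' Allele intensities from unique read counts
#'
#' @param counts tibble with `variant_id`, `sample`, `r_count`, `a_count`,
#'   `depth` (reads overlapping the locus).
#' @return tibble with added `r_intensity`, `a_intensity` (NA when depth 0;
#'   reads supporting neither allele leave `r + a < 1`).
#' @export
compute_intensities <- function(counts) {
  x <- as_tibble(counts)
  if (any(x$r_count < 0 | x$a_count < 0 | x$depth < 0)) {
    abort("negative read counts")
  }
  if (any(x$r_count + x$a_count > x$depth + 1e-9)) {
    abort("allele-supporting reads exceed total depth")
  }
  dplyr::mutate(x,
    r_intensity = ifelse(.data$depth > 0, .data$r_count / .data$depth, NA_real_),
    a_intensity = ifelse(.data$depth > 0, .data$a_count / .data$depth, NA_real_))
}

# bivariate normal density with diagonal or full 2x2 covariance
dmvnorm2 <- function(x, mu, sigma) {
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  if (det_s <= 0) abort("singular covariance matrix")
  inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[2, 1], sigma[1, 1]),
                2, 2) / det_s
  dx <- sweep(x, 2, mu)
  q <- rowSums((dx %*% inv) * dx)
  exp(-0.5 * q) / (2 * pi * sqrt(det_s))
}

#' Weighted state likelihood of one observation
#'
#' `w_j * N(d | mu_j, Sigma_j)` for genotype state `j`.
#'
#' @param d numeric length-2 vector (r, a) or 2-column matrix.
#' @param model fitted genotype model (see [fit_em()]).
#' @param j state index 1..3 or one of "RR","RA","AA".
#' @return numeric likelihood(s).
#' @export
state_likelihood <- function(d, model, j) {
  if (is.character(j)) j <- match(j, GT_STATES)
  x <- if (is.matrix(d)) d else matrix(d, ncol = 2)
  unname(model$w[j]) * dmvnorm2(x, model$mu[j, ], model$sigma[[j]])
}

#' Genotype posterior probabilities for one observation
#'
#' State likelihoods normalized over the three states. If all three
#' likelihoods underflow to zero, a uniform posterior is returned with a
#' warning.
#'
#' @inheritParams state_likelihood
#' @return numeric 3-vector (RR, RA, AA) summing to 1.
#' @export
posterior <- function(d, model) {
  lik <- vapply(1:3, function(j) state_likelihood(d, model, j), numeric(1))
  s <- sum(lik)
  if (!is.finite(s) || s <= 0) {
    warn("all state likelihoods underflow; returning uniform posterior")
    return(setNames(rep(1 / 3, 3), GT_STATES))
  }
  setNames(lik / s, GT_STATES)
}

project_centers <- function(mu, m, box = 0.3, eps = 1e-3) {
  exp_mu <- m * expected_centers()
  mu <- pmin(pmax(mu, exp_mu - box), exp_mu + box)
  # ordering constraint on the a-intensity coordinate: RR < RA < AA
  a <- mu[, 2]
  if (a[2] <= a[1]) a[2] <- a[1] + eps
  if (a[3] <= a[2]) a[3] <- a[2] + eps
  mu[, 2] <- a
  mu
}

#' Fit the constrained three-state Gaussian mixture by EM
#'
#' Centers are initialized at `m` times the expected (r, a) centers
#' RR = (1, 0.001), RA = (0.5, 0.5), AA = (0.001, 1); weights start uniform
#' at 1/3. Each M-step projects the centers back into the linear constraints
#' (per-coordinate box of half-width 0.3 around the m-scaled expected
#' centers, plus the ordering of the a-intensity coordinate). EM stops when
#' the mixture log-likelihood improves by less than `tol` or after
#' `max_iter` iterations. A state that loses all responsibility mass keeps
#' its initial center (with a warning).
#'
#' @param d tibble with `r_intensity`, `a_intensity` (missing rows dropped),
#'   one row per individual.
#' @param m scaling factor in \{0.8, 0.9, 1.0, 1.1, 1.2\}.
#' @param init_sd initial per-coordinate standard deviation.
#' @param diagonal use diagonal covariances (default TRUE).
#' @param tol,max_iter convergence controls.
#' @return an object of class `sv_genotype_model`: list with `w`, `mu`,
#'   `sigma` (list of 2x2), `m`, `loglik` (trace), `n`, `converged`.
#' @export
fit_em <- function(d, m = 1.0, init_sd = 0.1, diagonal = TRUE,
                   tol = 1e-6, max_iter = 200L) {
  x <- cbind(d$r_intensity, d$a_intensity)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3) abort("need at least 3 non-missing observations")
  mu <- project_centers(m * expected_centers(), m)
  w <- rep(1 / 3, 3)
  sigma <- replicate(3, diag(init_sd^2, 2), simplify = FALSE)
  mu0 <- mu
  ll_trace <- numeric(0)
  var_floor <- 1e-4
  frozen_warned <- FALSE
  for (it in seq_len(max_iter)) {
    lik <- vapply(1:3, function(j) w[j] * dmvnorm2(x, mu[j, ], sigma[[j]]),
                  numeric(n))
    lik <- matrix(lik, nrow = n)
    tot <- rowSums(lik)
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol) break
    resp <- lik / tot
    nk <- colSums(resp)
    w <- nk / n
    for (j in 1:3) {
      if (nk[j] < 1e-8) {
        if (!frozen_warned) {
          warn(paste0("state ", GT_STATES[j],
                      " has no responsibility mass; center frozen"))
          frozen_warned <- TRUE
        }
        mu[j, ] <- mu0[j, ]
        next
      }
      mu[j, ] <- colSums(resp[, j] * x) / nk[j]
    }
    mu <- project_centers(mu, m)
    for (j in 1:3) {
      if (nk[j] < 1e-8) next
      dx <- sweep(x, 2, mu[j, ])
      if (diagonal) {
        v <- colSums(resp[, j] * dx^2) / nk[j]
        sigma[[j]] <- diag(pmax(v, var_floor), 2)
      } else {
        s <- crossprod(dx * resp[, j], dx) / nk[j]
        diag(s) <- pmax(diag(s), var_floor)
        sigma[[j]] <- s
      }
    }
  }
  structure(list(w = setNames(w, GT_STATES), mu = mu, sigma = sigma, m = m,
                 loglik = ll_trace, n = n,
                 converged = length(ll_trace) < max_iter),
            class = "sv_genotype_model")
}

#' @export
print.sv_genotype_model <- function(x, ...) {
  cat("Constrained 3-state Gaussian mixture genotype model\n")
  cat(sprintf("  n = %d individuals, scaling factor m = %.1f, %s\n", x$n, x$m,
              if (x$converged) "converged" else "max iterations reached"))
  cat(sprintf("  weights: RR %.3f  RA %.3f  AA %.3f\n",
              x$w[1], x$w[2], x$w[3]))
  invisible(x)
}

#' @export
tidy.sv_genotype_model <- function(x, ...) {
  tibble(state = GT_STATES, weight = unname(x$w),
         mu_r = x$mu[, 1], mu_a = x$mu[, 2],
         sd_r = vapply(x$sigma, function(s) sqrt(s[1, 1]), numeric(1)),
         sd_a = vapply(x$sigma, function(s) sqrt(s[2, 2]), numeric(1)))
}

#' @export
glance.sv_genotype_model <- function(x, ...) {
  tibble(n = x$n, m = x$m, loglik = tail(x$loglik, 1),
         iterations = length(x$loglik), converged = x$converged)
}

#' Call genotypes from a fitted model
#'
#' The genotype is the posterior argmax (ties broken in the fixed state
#' order RR < RA < AA); GQ = -10 log10(1 - p_best) on normalized posteriors,
#' capped at 99 and stored unrounded (it is rounded to an integer at VCF
#' emission). PL is the usual Phred-scaled likelihood triple, 0 at the best
#' state. Missing intensities give a missing call.
#'
#' @param d tibble with `r_intensity`, `a_intensity` (and optionally
#'   `variant_id`, `sample`, carried through).
#' @param model fitted `sv_genotype_model`.
#' @return tibble with `gt` (RR/RA/AA or NA), `gq`, `p_rr`, `p_ra`, `p_aa`,
#'   `pl` (comma-joined string).
#' @export
call_genotypes <- function(d, model) {
  x <- as_tibble(d)
  n <- nrow(x)
  res <- tibble(gt = rep(NA_character_, n), gq = rep(NA_real_, n),
                p_rr = NA_real_, p_ra = NA_real_, p_aa = NA_real_,
                pl = NA_character_)
  ok <- !is.na(x$r_intensity) & !is.na(x$a_intensity)
  for (i in which(ok)) {
    p <- posterior(c(x$r_intensity[i], x$a_intensity[i]), model)
    best <- which.max(p)                    # which.max takes the first on ties
    gq <- -10 * log10(max(1 - p[best], 1e-10))
    lik <- vapply(1:3, function(j) {
      state_likelihood(c(x$r_intensity[i], x$a_intensity[i]), model, j)
    }, numeric(1))
    lik[lik <= 0 | !is.finite(lik)] <- .Machine$double.xmin
    phred <- -10 * log10(lik / max(lik))
    res$gt[i] <- GT_STATES[best]
    res$gq[i] <- min(gq, 99)
    res$p_rr[i] <- p[1]; res$p_ra[i] <- p[2]; res$p_aa[i] <- p[3]
    res$pl[i] <- paste(as.integer(round(pmin(phred, 255))), collapse = ",")
  }
  dplyr::bind_cols(x[intersect(c("variant_id", "sample"), names(x))], res)
}

#' Mendelian error rate across trios
#'
#' Fraction of trio-complete (all three genotypes non-missing) locus-trio
#' combinations where the child genotype is impossible given the parents
#' under bi-allelic transmission (e.g. RR x RR cannot give RA or AA).
#'
#' @param calls long tibble with `variant_id`, `sample`, `gt`.
#' @param trios tibble with `child`, `father`, `mother`.
#' @return list with `rate` (NA when no complete trio-locus), `n_checked`,
#'   `n_errors`.
#' @export
mendelian_error_rate <- function(calls, trios) {
  known <- unique(calls$sample)
  ids <- unique(c(trios$child, trios$father, trios$mother))
  if (!all(ids %in% known)) {
    abort(paste0("pedigree ids absent from calls: ",
                 paste(setdiff(ids, known), collapse = ", ")))
  }
  alleles <- list(RR = c("R"), RA = c("R", "A"), AA = c("A"))
  n_checked <- 0L; n_err <- 0L
  wide <- tidyr::pivot_wider(calls[, c("variant_id", "sample", "gt")],
                             names_from = "sample", values_from = "gt")
  for (t in seq_len(nrow(trios))) {
    cg <- wide[[trios$child[t]]]
    fg <- wide[[trios$father[t]]]
    mg <- wide[[trios$mother[t]]]
    complete <- !is.na(cg) & !is.na(fg) & !is.na(mg)
    for (i in which(complete)) {
      poss <- unique(c(outer(alleles[[fg[i]]], alleles[[mg[i]]],
                             function(a, b) {
                               paste0(pmin(a, b), pmax(a, b))
                             })))
      poss <- sub("AR", "RA", poss)
      n_checked <- n_checked + 1L
      if (!(cg[i] %in% poss)) n_err <- n_err + 1L
    }
  }
  list(rate = if (n_checked > 0) n_err / n_checked else NA_real_,
       n_checked = n_checked, n_errors = n_err)
}

#' Select the center scaling factor m
#'
#' Fits the mixture for each m in \{0.8, 0.9, 1.0, 1.1, 1.2\} (five rounds of
#' training) and picks the m minimizing the rank-sum of (i) the constraint
#' bias, the L1 distance of the fitted centers from the m-scaled expected
#' centers, and (ii) the Mendelian error rate of the resulting genotype
#' calls (omitted when no trios are supplied). Ties go to the m closest to
#' 1.0, then to the smaller m.
#'
#' @param d intensity tibble for one variant (or pooled training variants):
#'   `variant_id`, `sample`, `r_intensity`, `a_intensity`.
#' @param trios optional trio tibble (`child`, `father`, `mother`).
#' @param ... passed to [fit_em()].
#' @return list with `m`, `model` (for the best m), and `grid` (tibble of
#'   m, bias, mendelian error, rank sum).
#' @export
select_scaling_factor <- function(d, trios = NULL, ...) {
  grid <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  fits <- lapply(grid, function(m) fit_em(d, m = m, ...))
  bias <- vapply(seq_along(grid), function(k) {
    sum(abs(fits[[k]]$mu - grid[k] * expected_centers()))
  }, numeric(1))
  mend <- rep(NA_real_, length(grid))
  if (!is.null(trios) && nrow(trios) > 0) {
    for (k in seq_along(grid)) {
      calls <- call_genotypes(d, fits[[k]])
      mend[k] <- mendelian_error_rate(calls, trios)$rate
    }
  }
  ranks <- rank(bias, ties.method = "average")
  if (!all(is.na(mend))) ranks <- ranks + rank(mend, ties.method = "average")
  ord <- order(ranks, abs(grid - 1.0), grid)
  best <- ord[1]
  list(m = grid[best], model = fits[[best]],
       grid = tibble(m = grid, bias = bias, mendelian = mend,
                     rank_sum = ranks))
}

#' Genotype every variant of a population call set
#'
#' Per variant: fit the constrained mixture across individuals (optionally
#' selecting m) and call genotypes.
#'
#' @param intensities tibble `variant_id`, `sample`, `r_intensity`,
#'   `a_intensity` (from [compute_intensities()]).
#' @param trios optional trio tibble; enables m selection by Mendelian error.
#' @param select_m fit the five-point m grid per variant (default FALSE:
#'   m = 1).
#' @param ... passed to [fit_em()].
#' @return list with `calls` (long tibble incl. `gt`, `gq`, `pl`) and
#'   `models` (named list of fitted models per variant).
#' @export
genotype_population <- function(intensities, trios = NULL, select_m = FALSE, ...) {
  out_calls <- list(); models <- list()
  for (vid in unique(intensities$variant_id)) {
    d <- intensities[intensities$variant_id == vid, , drop = FALSE]
    model <- if (select_m) select_scaling_factor(d, trios, ...)$model
             else fit_em(d, ...)
    models[[vid]] <- model
    out_calls[[vid]] <- call_genotypes(d, model)
  }
  list(calls = dplyr::bind_rows(unname(out_calls)), models = models)
}

#' @describeIn fit_em scatter of the intensity plane colored by posterior
#'   genotype, with the fitted state centers.
#' @param object fitted model; `d` the intensity tibble it was fitted to.
#' @export
autoplot.sv_genotype_model <- function(object, d, ...) {
  calls <- call_genotypes(d, object)
  df <- dplyr::bind_cols(d[c("r_intensity", "a_intensity")], gt = calls$gt)
  cen <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$r_intensity, .data$a_intensity,
                                   colour = .data$gt)) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_point(data = cen, ggplot2::aes(.data$mu_r, .data$mu_a),
                        colour = "black", shape = 3, size = 3,
                        inherit.aes = FALSE) +
    ggplot2::labs(x = "R intensity", y = "A intensity", colour = "genotype")
}
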