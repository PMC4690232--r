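# Variant quality score recalibration.
#
# Two Gaussian mixtures -- one over a positive (trusted) training class and
# one over a negative (artifact) class -- are fitted to up to nine technical
# features. Each variant's recalibrated score is the base-10 log odds
# contrast of the two class probabilities; the PASS threshold is picked on
# the training ROC. An inbreeding-coefficient filter removes loci with
# excessive hetero-/homozygosity.

#' Extract the nine recalibration features for each variant
#'
#' Operationalizations (each overridable by supplying a feature table
#' directly, see [read_feature_table()]):
#' * `gap_ratio`: N-base fraction of the carrying scaffold within +-500 bp
#'   of the variant.
#' * `alt_depth`, `neither_depth`: reads supporting the alternative allele /
#'   neither allele (from the intensity counts).
#' * `misalign_prob`: 10^(-mapq/10) of the carrying alignment block score
#'   interpreted as a mapping quality, or supplied directly.
#' * `align_score`: score of the carrying alignment block.
#' * `local_identity`: identity of the enclosing alignment block.
#' * `scaffold_position`: variant position on its scaffold, normalized to
#'   0..1.
#' * `proper_read_ratio`, `improper_read_ratio`: fraction of properly /
#'   improperly paired reads at the locus (from read summaries).
#'
#' @param variants merged variant tibble (needs `id`, `q_name`, `q_pos` when
#'   scaffold-derived features are wanted).
#' @param blocks block tibble (for `align_score`, `local_identity`,
#'   `misalign_prob`).
#' @param query_seqs scaffold sequences (for `gap_ratio`,
#'   `scaffold_position`).
#' @param read_summary optional tibble `variant_id`, `alt_depth`,
#'   `neither_depth`, `proper_read_ratio`, `improper_read_ratio`.
#' @param window flank width for `gap_ratio` (default 500).
#' @return tibble `variant_id` + available feature columns; missing inputs
#'   leave features NA. Errors if every feature is missing.
#' @export
extract_features <- function(variants, blocks = NULL, query_seqs = NULL,
                             read_summary = NULL, window = 500L) {
  v <- as_tibble(variants)
  out <- tibble(variant_id = v$id)
  if (!is.null(query_seqs) && all(c("q_name", "q_pos") %in% names(v))) {
    out$gap_ratio <- vapply(seq_len(nrow(v)), function(i) {
      if (is.na(v$q_name[i]) || is.na(v$q_pos[i])) return(NA_real_)
      s <- seq_lookup(query_seqs, v$q_name[i])
      lo <- max(1L, v$q_pos[i] - window)
      hi <- min(nchar(s), v$q_pos[i] + window)
      win <- substr(s, lo, hi)
      stringr::str_count(win, "N") / nchar(win)
    }, numeric(1))
    out$scaffold_position <- vapply(seq_len(nrow(v)), function(i) {
      if (is.na(v$q_name[i]) || is.na(v$q_pos[i])) return(NA_real_)
      v$q_pos[i] / nchar(seq_lookup(query_seqs, v$q_name[i]))
    }, numeric(1))
  }
  if (!is.null(blocks) && all(c("q_name", "q_pos") %in% names(v))) {
    feat <- vapply(seq_len(nrow(v)), function(i) {
      cand <- blocks[blocks$q_name == v$q_name[i] &
                     blocks$q_start < v$q_pos[i] &
                     blocks$q_end >= v$q_pos[i], , drop = FALSE]
      if (nrow(cand) == 0) {
        cand <- blocks[blocks$q_name == v$q_name[i], , drop = FALSE]
      }
      if (nrow(cand) == 0) return(c(NA_real_, NA_real_, NA_real_))
      b <- cand[which.max(cand$score), ]
      cols <- nchar(b$ref_text)
      matches <- sum(strsplit(b$ref_text, "")[[1]] ==
                     strsplit(b$q_text, "")[[1]] &
                     strsplit(b$ref_text, "")[[1]] != "-")
      mapq <- pmax(pmin(b$score / 10, 60), 0)
      c(b$score, matches / cols, 10^(-mapq / 10))
    }, numeric(3))
    out$align_score <- feat[1, ]
    out$local_identity <- feat[2, ]
    out$misalign_prob <- feat[3, ]
  }
  if (!is.null(read_summary)) {
    rs <- as_tibble(read_summary)
    idx <- match(out$variant_id, rs$variant_id)
    for (cc in intersect(c("alt_depth", "neither_depth", "proper_read_ratio",
                           "improper_read_ratio"), names(rs))) {
      out[[cc]] <- rs[[cc]][idx]
    }
  }
  feats <- setdiff(names(out), "variant_id")
  if (length(feats) == 0 || all(vapply(out[feats], function(x) all(is.na(x)),
                                       logical(1)))) {
    abort("no recalibration features could be computed")
  }
  out
}

#' Fit a class-conditional Gaussian mixture over feature vectors
#'
#' Component count chosen by BIC over 1..`max_clusters` (mclust backend;
#' deterministic given data).
#'
#' @param features numeric feature matrix or tibble (rows = variants of one
#'   training class; non-feature columns dropped).
#' @param max_clusters maximum components (default 8; reduced with a warning
#'   when there are fewer points than clusters).
#' @return `densityMclust` fit with the selected number of components.
#' @export
fit_class_mixture <- function(features, max_clusters = 8L) {
  x <- as.data.frame(features)
  x$variant_id <- NULL
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 10) abort("need >= 10 training points per class")
  gmax <- max_clusters
  if (nrow(x) <= gmax) {
    warn("fewer training points than clusters; reducing max_clusters")
    gmax <- max(1L, nrow(x) - 1L)
  }
  fit <- mclust::densityMclust(x, G = 1:gmax, verbose = FALSE, plot = FALSE)
  if (is.null(fit)) abort("class mixture fit failed")
  fit
}

# base-10 log-odds score from the two class probabilities (Eq-9 arithmetic)
log_odds_score <- function(p_pos, p_neg) {
  p_pos <- pmin(p_pos, 1 - 1e-10)
  p_neg <- pmin(p_neg, 1 - 1e-10)
  -log10(1 - p_pos) + log10(1 - p_neg)
}

#' Train a recalibration model
#'
#' Fits positive- and negative-class mixtures (BIC over 1..8 components) on
#' the labelled training variants and picks the PASS threshold on the
#' training ROC (Youden's J: the cutoff maximizing TPR - FPR, keeping most
#' known positives while minimizing known negatives).
#'
#' @param features feature tibble (`variant_id` + feature columns).
#' @param positive_ids,negative_ids training variant ids.
#' @param known_ids optional ids treated as known variants (prior 0.6 of
#'   being positive instead of 0.4).
#' @param max_clusters per-class component cap (default 8).
#' @return object of class `sv_recal_model`: mixtures, feature names,
#'   priors, `threshold`, `roc` (tibble), `auc`.
#' @export
fit_recalibrator <- function(features, positive_ids, negative_ids,
                             known_ids = character(0), max_clusters = 8L) {
  feats <- setdiff(names(features), "variant_id")
  keep <- stats::complete.cases(features[feats])
  f <- features[keep, , drop = FALSE]
  pos <- f[f$variant_id %in% positive_ids, , drop = FALSE]
  neg <- f[f$variant_id %in% negative_ids, , drop = FALSE]
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    abort("both positive and negative training variants are required")
  }
  model <- structure(list(
    pos_fit = fit_class_mixture(pos, max_clusters),
    neg_fit = fit_class_mixture(neg, max_clusters),
    features = feats,
    priors = c(p01_known = 0.6, p01_novel = 0.4,
               p02_known = 0.4, p02_novel = 0.6),
    known_ids = known_ids
  ), class = "sv_recal_model")
  tr_scores <- score_variants(dplyr::bind_rows(pos, neg), model)
  labels <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
  thr <- choose_threshold(tr_scores$score, labels)
  model$threshold <- thr$threshold
  model$roc <- thr$roc
  model$auc <- thr$auc
  model
}

#' @export
print.sv_recal_model <- function(x, ...) {
  cat("Variant quality recalibration model\n")
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  components: %d positive / %d negative\n",
              x$pos_fit$G, x$neg_fit$G))
  cat(sprintf("  threshold %.3f (training AUC %.3f)\n", x$threshold, x$auc))
  invisible(x)
}

#' @export
glance.sv_recal_model <- function(x, ...) {
  tibble(pos_components = x$pos_fit$G, neg_components = x$neg_fit$G,
         n_features = length(x$features), threshold = x$threshold,
         auc = x$auc)
}

#' @export
tidy.sv_recal_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble(class = "positive", component = seq_len(x$pos_fit$G),
           weight = x$pos_fit$parameters$pro),
    tibble(class = "negative", component = seq_len(x$neg_fit$G),
           weight = x$neg_fit$parameters$pro))
}

#' Score variants under a recalibration model
#'
#' Class mixture densities are combined with the known/novel priors into
#' two-class normalized probabilities
#' `P_pos = p01 L_pos / (p01 L_pos + p02 L_neg)`, `P_neg = 1 - P_pos`, then
#' `score = -lg(1 - P_pos) + lg(1 - P_neg)` (probabilities clamped at
#' 1 - 1e-10, so every score is finite). Higher means more likely true.
#'
#' @param features feature tibble (`variant_id` + the model's features).
#' @param model fitted `sv_recal_model`.
#' @return tibble `variant_id`, `score` (NA for incomplete feature rows).
#' @export
score_variants <- function(features, model) {
  x <- as.data.frame(features[model$features])
  out <- tibble(variant_id = features$variant_id, score = NA_real_)
  ok <- stats::complete.cases(x)
  if (!any(ok)) return(out)
  xm <- as.matrix(x[ok, , drop = FALSE])
  l_pos <- stats::predict(model$pos_fit, xm)
  l_neg <- stats::predict(model$neg_fit, xm)
  known <- features$variant_id[ok] %in% model$known_ids
  p01 <- ifelse(known, model$priors["p01_known"], model$priors["p01_novel"])
  p02 <- ifelse(known, model$priors["p02_known"], model$priors["p02_novel"])
  denom <- p01 * l_pos + p02 * l_neg
  denom[denom <= 0] <- .Machine$double.xmin
  p_pos <- p01 * l_pos / denom
  out$score[ok] <- log_odds_score(p_pos, 1 - p_pos)
  out
}

#' Choose the PASS threshold on a labelled score set
#'
#' Computes the full ROC over all score cutoffs and returns the cutoff
#' maximizing Youden's J = TPR - FPR, together with the ROC table and the
#' AUC.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) labels; both classes must be present.
#' @return list with `threshold`, `roc` (tibble `threshold`, `tpr`, `fpr`),
#'   `auc`.
#' @export
choose_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels[!is.na(scores)])) < 2) {
    abort("both positive and negative labels are required")
  }
  r <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]
  list(threshold = as.numeric(best$threshold),
       roc = tibble(threshold = r$thresholds, tpr = r$sensitivities,
                    fpr = 1 - r$specificities),
       auc = as.numeric(pROC::auc(r)))
}

#' Cross-validated error rate of the recalibrator
#'
#' Stratified k-fold: each fold is held out, the mixtures and threshold are
#' refitted on the rest, and the held-out misclassification rate at the
#' refitted threshold is averaged.
#'
#' @param features feature tibble.
#' @param positive_ids,negative_ids training labels.
#' @param k folds (default 5; reduced with a warning when a class has fewer
#'   members).
#' @param seed fold-assignment seed.
#' @param ... passed to [fit_recalibrator()].
#' @return list with `error_rate` and `folds` (per-fold tibble).
#' @export
cross_validate <- function(features, positive_ids, negative_ids, k = 5L,
                           seed = 1L, ...) {
  if (k < 2) abort("k must be >= 2")
  ids <- features$variant_id
  lab <- ifelse(ids %in% positive_ids, 1L,
                ifelse(ids %in% negative_ids, 0L, NA_integer_))
  use <- !is.na(lab)
  ids <- ids[use]; lab <- lab[use]
  minc <- min(table(lab))
  if (minc < k) {
    warn(sprintf("class with %d members < k; reducing k to %d", minc, minc))
    k <- max(2L, as.integer(minc))
  }
  set.seed(seed)
  fold <- integer(length(ids))
  for (cl in c(0L, 1L)) {
    idx <- which(lab == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  res <- purrr::map_dfr(seq_len(k), function(f) {
    test_ids <- ids[fold == f]
    train_pos <- setdiff(intersect(ids[lab == 1L], ids), test_ids)
    train_neg <- setdiff(intersect(ids[lab == 0L], ids), test_ids)
    m <- fit_recalibrator(features[features$variant_id %in% c(train_pos, train_neg), ],
                          train_pos, train_neg, ...)
    sc <- score_variants(features[features$variant_id %in% test_ids, ], m)
    truth <- lab[match(sc$variant_id, ids)]
    pred <- as.integer(sc$score >= m$threshold)
    tibble(fold = f, n = length(truth),
           error = mean(pred != truth, na.rm = TRUE))
  })
  list(error_rate = mean(res$error), folds = res)
}

#' Inbreeding coefficient at one locus
#'
#' `F = 1 - N_het / (2 p q N)` over the unrelated individuals, where p and q
#' are the sample frequencies of the reference and alternative alleles.
#' Monomorphic loci (p q = 0) give `F = NA` (the filter skips them).
#'
#' @param gt character vector of genotypes (RR/RA/AA; NA dropped) of
#'   unrelated individuals. Alternatively supply the summary statistics
#'   `n`, `n_het`, `p` directly (and leave `gt` NULL).
#' @param n,n_het,p explicit unrelated-individual count, heterozygote count
#'   and reference-allele frequency.
#' @return one-row tibble `p`, `q`, `n`, `n_het`, `f`.
#' @export
inbreeding_coefficient <- function(gt = NULL, n = NULL, n_het = NULL,
                                   p = NULL) {
  if (!is.null(gt)) {
    gt <- gt[!is.na(gt)]
    n <- length(gt)
    if (n < 2) abort("need >= 2 unrelated individuals with genotypes")
    n_het <- sum(gt == "RA")
    p <- (2 * sum(gt == "RR") + n_het) / (2 * n)
  } else if (is.null(n) || is.null(n_het) || is.null(p)) {
    abort("supply either genotypes or (n, n_het, p)")
  }
  q <- 1 - p
  f <- if (p <= 0 || q <= 0) NA_real_ else 1.0 - (n_het / (2.0 * p * q * n))
  tibble(p = p, q = q, n = n, n_het = n_het, f = f)
}

#' Filter records by inbreeding coefficient
#'
#' Computes F per variant over the unrelated individuals and sets the
#' filter flag for `F < low` or `F > high` (defaults -0.4 / 0.7, strict
#' inequalities: F = 0.7 exactly is retained). Loci with undefined F are
#' skipped by the filter.
#'
#' @param records merged record tibble (with `id`).
#' @param calls long genotype tibble (`id` or `variant_id`, `sample`, `gt`).
#' @param unrelated character vector of unrelated individual ids (e.g.
#'   [pedigree_founders()]).
#' @param low,high filter bounds.
#' @return `records` with added `f_coef` and updated `filter` column
#'   (`inbreeding_coef` appended for failing records).
#' @export
filter_by_inbreeding <- function(records, calls, unrelated,
                                 low = -0.4, high = 0.7) {
  idcol <- if ("variant_id" %in% names(calls)) "variant_id" else "id"
  cc <- calls[calls$sample %in% unrelated, , drop = FALSE]
  fvals <- vapply(records$id, function(vid) {
    g <- cc$gt[cc[[idcol]] == vid]
    g <- g[!is.na(g)]
    if (length(g) < 2) return(NA_real_)
    inbreeding_coefficient(g)$f
  }, numeric(1))
  fvals <- unname(fvals)
  records$f_coef <- fvals
  fail <- !is.na(fvals) & (fvals < low | fvals > high)
  if (!"filter" %in% names(records)) records$filter <- "."
  records$filter <- ifelse(fail,
    ifelse(records$filter %in% c(".", "PASS"), "inbreeding_coef",
           paste0(records$filter, ";inbreeding_coef")),
    records$filter)
  records
}

#' Apply a recalibration model to a record set
#'
#' Writes the recalibrated score into `recal_score`/`qual` and sets
#' `filter` to PASS or FALSE by the model threshold.
#'
#' @param records merged record tibble.
#' @param features feature tibble covering the records.
#' @param model fitted `sv_recal_model`.
#' @return updated records tibble.
#' @export
apply_recalibration <- function(records, features, model) {
  sc <- score_variants(features, model)
  idx <- match(records$id, sc$variant_id)
  records$recal_score <- sc$score[idx]
  records$qual <- sc$score[idx]
  records$filter <- ifelse(is.na(records$recal_score), ".",
                           ifelse(records$recal_score >= model$threshold,
                                  "PASS", "FALSE"))
  records
}
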