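#' Area under the ROC curve
#'
#' Computed via the rank statistic: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties credited 1/2
#' (equivalently, the Wilcoxon-Mann-Whitney statistic).
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Binary labels: logical, \{0, 1\} or \{-1, +1\}.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  lab <- as.character(labels)
  if (!all(lab %in% c("0", "1", "-1", "+1", "TRUE", "FALSE"))) {
    stop("labels must be binary (0/1, -1/+1 or logical)")
  }
  lab %in% c("1", "+1", "TRUE")
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over distinct score thresholds (no interpolation
#' between PR points): with thresholds descending, the area is
#' `sum over steps of (recall_i - recall_{i-1}) * precision_i`. Tied scores
#' enter as one threshold step. A perfect ranker scores 1; a constant ranker
#' scores the positive prevalence.
#'
#' @inheritParams auc_score
#' @return AUPR in `(0, 1]`.
#' @export
aupr_score <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  np <- sum(pos)
  if (np == 0L) stop("no positive labels")
  ord <- order(scores, decreasing = TRUE)
  y <- pos[ord]
  s <- scores[ord]
  # indices closing each distinct-threshold group
  step_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[step_end]
  n_pred <- step_end
  precision <- tp / n_pred
  recall <- tp / np
  sum(diff(c(0, recall)) * precision)
}

#' Normal-fit confidence interval for repeated run statistics
#'
#' Fits a normal distribution to the per-run statistics (e.g. ten AUC
#' values) and reports its central `level` interval, i.e.
#' `mean +/- z * sd` with the sample standard deviation.
#'
#' @param stats Numeric vector of at least two finite run statistics.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
confidence_interval <- function(stats, level = 0.95) {
  if (length(stats) < 2L || !all(is.finite(stats))) {
    stop("need at least two finite values")
  }
  m <- mean(stats)
  s <- stats::sd(stats)
  if (s == 0) {
    warning("constant run statistics: degenerate confidence interval")
    return(c(low = m, high = m))
  }
  z <- stats::qnorm((1 + level) / 2)
  c(low = m - z * s, high = m + z * s)
}

#' Balanced repeated cross-validation of a pair classifier
#'
#' The evaluation protocol: stratified tenfold cross-validation repeated ten
#' times. Positive and negative pairs are each shuffled and split into
#' folds; for every fold the classifier is trained on the other nine folds
#' using all their positives and an equal-size uniform sample of their
#' negatives (class-balanced training), then scores the held-out fold.
#' Held-out folds are scored unbalanced by default (all their negatives),
#' which gives honest AUC/AUPR under the true class ratio; set
#' `balanced_test = TRUE` to subsample held-out negatives to the positive
#' count instead. Held-out scores are pooled within a repetition, giving one
#' AUC and one AUPR per repetition.
#'
#' @param features Numeric matrix with rownames `"tf\ttarget"` covering all
#'   positive and negative pairs.
#' @param positives,negatives Data frames of pairs (`tf`, `target`).
#' @param folds,reps Cross-validation shape (defaults 10 x 10).
#' @param seed Integer seed; repetition `r` uses `seed + r` for its shuffle
#'   and negative subsampling.
#' @param backend,hyperparameters Passed to [train_classifier()].
#' @param balanced_test Subsample held-out negatives to balance test folds.
#' @param keep_scores Retain the pooled held-out score table per repetition
#'   (needed for [per_tf_auc_distribution()]).
#' @return Object of class `gradis_eval`: list with `per_run` (data frame
#'   `run`, `auc`, `aupr`), `mean_auc`, `mean_aupr`, `ci_auc`, `ci_aupr`,
#'   and (if `keep_scores`) `scores`, a list of per-repetition data frames
#'   (`tf`, `target`, `score`, `label`).
#' @export
balanced_cv_evaluate <- function(features, positives, negatives,
                                 folds = 10L, reps = 10L, seed = 1L,
                                 backend = "svm", hyperparameters = list(),
                                 balanced_test = FALSE, keep_scores = TRUE) {
  folds <- assert_scalar_int(folds, "folds", min = 2L)
  reps <- assert_scalar_int(reps, "reps", min = 1L)
  pos_keys <- pairs_to_keys(positives)
  neg_keys <- pairs_to_keys(negatives)
  if (length(neg_keys) < length(pos_keys)) {
    stop("need at least as many negatives (", length(neg_keys),
         ") as positives (", length(pos_keys), ")")
  }
  if (length(pos_keys) < folds || length(neg_keys) < folds) {
    stop("cannot stratify ", folds, "-fold CV: every test fold needs both ",
         "classes (", length(pos_keys), " positives, ", length(neg_keys),
         " negatives); reduce `folds`")
  }
  missing <- setdiff(c(pos_keys, neg_keys), rownames(features))
  if (length(missing) > 0L) {
    stop("features missing for ", length(missing), " pair(s)")
  }
  per_run <- data.frame(run = seq_len(reps), auc = NA_real_, aupr = NA_real_)
  score_tables <- vector("list", reps)
  for (r in seq_len(reps)) {
    tabs <- with_seed(seed + r, {
      fold_pos <- sample(rep_len(seq_len(folds), length(pos_keys)))
      fold_neg <- sample(rep_len(seq_len(folds), length(neg_keys)))
      lapply(seq_len(folds), function(f) {
        tr_pos <- pos_keys[fold_pos != f]
        tr_neg_pool <- neg_keys[fold_neg != f]
        n_tr_neg <- min(length(tr_pos), length(tr_neg_pool))
        tr_neg <- sample(tr_neg_pool, n_tr_neg)
        te_pos <- pos_keys[fold_pos == f]
        te_neg <- neg_keys[fold_neg == f]
        if (balanced_test && length(te_neg) > length(te_pos)) {
          te_neg <- sample(te_neg, length(te_pos))
        }
        model <- train_classifier(
          features[c(tr_pos, tr_neg), , drop = FALSE],
          rep(c(1, -1), c(length(tr_pos), length(tr_neg))),
          backend = backend, hyperparameters = hyperparameters,
          seed = seed + r)
        te <- c(te_pos, te_neg)
        data.frame(key = te,
                   score = unname(decision_scores(model, features[te, , drop = FALSE])),
                   label = rep(c(1L, 0L), c(length(te_pos), length(te_neg))),
                   stringsAsFactors = FALSE)
      })
    })
    pooled <- do.call(rbind, tabs)
    per_run$auc[r] <- auc_score(pooled$score, pooled$label)
    per_run$aupr[r] <- aupr_score(pooled$score, pooled$label)
    if (keep_scores) {
      df <- keys_to_pairs(pooled$key)
      df$score <- pooled$score
      df$label <- pooled$label
      score_tables[[r]] <- df
    }
  }
  out <- list(per_run = per_run,
              mean_auc = mean(per_run$auc),
              mean_aupr = mean(per_run$aupr),
              ci_auc = if (reps >= 2L) {
                suppressWarnings(confidence_interval(per_run$auc))
              } else c(low = per_run$auc, high = per_run$auc),
              ci_aupr = if (reps >= 2L) {
                suppressWarnings(confidence_interval(per_run$aupr))
              } else c(low = per_run$aupr, high = per_run$aupr),
              folds = folds, reps = reps, seed = seed, backend = backend)
  if (keep_scores) out$scores <- score_tables
  structure(out, class = "gradis_eval")
}

#' @export
print.gradis_eval <- function(x, ...) {
  cat(sprintf("gradis_eval: %d-fold CV x %d repetitions (%s backend)\n",
              x$folds, x$reps, x$backend))
  cat(sprintf("  AUC  %.3f (%.3f-%.3f)\n", x$mean_auc,
              x$ci_auc[["low"]], x$ci_auc[["high"]]))
  cat(sprintf("  AUPR %.3f (%.3f-%.3f)\n", x$mean_aupr,
              x$ci_aupr[["low"]], x$ci_aupr[["high"]]))
  invisible(x)
}

#' Per-TF (local) AUC distribution
#'
#' Recomputes the AUC separately for each transcription factor from the
#' pooled held-out scores of every repetition, summarising each TF by the
#' minimum, mean and maximum AUC over the repetitions in which both a
#' positive and a negative test pair for that TF were present. TFs never
#' evaluable in any repetition are absent from the output.
#'
#' @param rep_scores List of per-repetition score tables (`tf`, `target`,
#'   `score`, `label`), as stored in a `gradis_eval` object's `scores`.
#' @return Data frame with columns `tf`, `min`, `mean`, `max`, `n_reps`.
#' @export
per_tf_auc_distribution <- function(rep_scores) {
  if (inherits(rep_scores, "gradis_eval")) rep_scores <- rep_scores$scores
  if (is.null(rep_scores)) {
    stop("no retained scores; run balanced_cv_evaluate(keep_scores = TRUE)")
  }
  acc <- list()
  for (df in rep_scores) {
    for (tf in unique(df$tf)) {
      sub <- df[df$tf == tf, , drop = FALSE]
      if (length(unique(sub$label)) < 2L) next
      acc[[tf]] <- c(acc[[tf]], auc_score(sub$score, sub$label))
    }
  }
  if (length(acc) == 0L) {
    return(data.frame(tf = character(0), min = numeric(0), mean = numeric(0),
                      max = numeric(0), n_reps = integer(0)))
  }
  tfs <- sort(names(acc))
  data.frame(tf = tfs,
             min = vapply(acc[tfs], min, numeric(1)),
             mean = vapply(acc[tfs], mean, numeric(1)),
             max = vapply(acc[tfs], max, numeric(1)),
             n_reps = vapply(acc[tfs], length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation of the vectorised off-diagonal triangles of two
#' distance matrices over the same objects, with a permutation p-value
#' obtained by simultaneously permuting the rows and columns of one matrix
#' (the standard Mantel test, computed via \pkg{vegan}).
#'
#' @param dist_a,dist_b Square symmetric matrices with zero diagonals and
#'   identical dimensions.
#' @param n_perm Number of permutations for the p-value.
#' @param seed Integer seed for the permutations.
#' @return List with `r` (Mantel statistic) and `p_value`.
#' @export
mantel_correlation <- function(dist_a, dist_b, n_perm = 999L, seed = 1L) {
  check_dist <- function(m, name) {
    if (!is.matrix(m) || nrow(m) != ncol(m)) stop(name, " must be square")
    if (max(abs(m - t(m))) > 1e-8) stop(name, " must be symmetric")
    if (max(abs(diag(m))) > 1e-8) stop(name, " must have a zero diagonal")
  }
  check_dist(dist_a, "dist_a"); check_dist(dist_b, "dist_b")
  if (nrow(dist_a) != nrow(dist_b)) stop("matrices must have the same dimension")
  fit <- with_seed(seed, vegan::mantel(stats::as.dist(dist_a),
                                       stats::as.dist(dist_b),
                                       method = "pearson",
                                       permutations = n_perm))
  list(r = unname(fit$statistic), p_value = fit$signif)
}

#' Combine score matrices by the wisdom-of-crowds conjunction
#'
#' Each method's TF x gene score matrix is scaled by its global maximum;
#' an interaction counts as present at threshold `t` when all scaled
#' matrices exceed `t`, which is exactly the minimum over matrices of the
#' scaled scores. The returned combined matrix therefore supports ordinary
#' ROC/PR threshold sweeps.
#'
#' @param matrices List of numeric matrices with identical dimnames,
#'   non-negative finite entries and a positive maximum each.
#' @return Combined matrix with entries in `[0, 1]`.
#' @export
combine_score_matrices <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("`matrices` must be a nonempty list")
  }
  ref <- dimnames(matrices[[1L]])
  scaled <- lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    if (!is.matrix(m) || !is.numeric(m)) stop("element ", i, " is not a numeric matrix")
    if (!identical(dim(m), dim(matrices[[1L]])) || !identical(dimnames(m), ref)) {
      stop("matrix ", i, " has mismatching axes")
    }
    if (!all(is.finite(m)) || any(m < 0)) stop("matrix ", i, " has invalid entries")
    mx <- max(m)
    if (mx <= 0) stop("matrix ", i, " is all zero")
    m / mx
  })
  Reduce(pmin, scaled)
}
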