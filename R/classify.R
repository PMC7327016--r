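#' Train the pair classifier
#'
#' Fits the final TF-gene pair classifier on a labelled training set of
#' graph-distance features. The primary backend is a support vector machine
#' with a Gaussian (RBF) kernel, whose decision function is
#' `f(p) = sum_i alpha_i K(p_i, p)`; a random-forest backend is provided for
#' comparison. Features are used as-is (they are already bounded by the unit
#' square geometry), with no additional standardisation.
#'
#' @param features Numeric matrix, pairs x features, no missing values.
#' @param labels Vector over \{+1, -1\} (numeric, or factor/character with
#'   those levels), one per feature row.
#' @param backend `"svm"` (RBF-kernel SVM, default) or `"rf"` (random
#'   forest).
#' @param hyperparameters For `"svm"`: `cost` (default 1) and `gamma`
#'   (default `1 / (n_features * var(features))`); for `"rf"`: `ntree`
#'   (default 500) and `mtry` (default `floor(sqrt(n_features))`).
#' @param seed Integer seed (consumed by the random-forest backend; the SVM
#'   fit is deterministic).
#' @return Object of class `gradis_model` with fields `backend`, `fit`,
#'   `hyperparameters`, `feature_dim`, `metric`, `k`.
#' @export
train_classifier <- function(features, labels, backend = c("svm", "rf"),
                             hyperparameters = list(), seed = 1L) {
  backend <- match.arg(backend)
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("`features` must be a numeric matrix")
  }
  if (anyNA(features) || !all(is.finite(features))) {
    stop("features contain missing or non-finite values")
  }
  if (length(labels) != nrow(features)) {
    stop("length(labels) (", length(labels), ") != nrow(features) (",
         nrow(features), ")")
  }
  lab <- as.character(labels)
  if (!all(lab %in% c("1", "-1", "+1"))) {
    stop("labels must be +1 or -1")
  }
  lab[lab == "+1"] <- "1"
  if (length(unique(lab)) < 2L) {
    stop("training set contains a single class (", unique(lab), ")")
  }
  y <- factor(lab, levels = c("-1", "1"))
  d <- ncol(features)
  hp <- hyperparameters
  if (backend == "svm") {
    cost <- hp$cost %||% 1
    gamma <- hp$gamma
    if (is.null(gamma)) {
      v <- stats::var(as.vector(features))
      gamma <- if (is.finite(v) && v > 0) 1 / (d * v) else 1 / d
    }
    fit <- e1071::svm(features, y, kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    hp <- list(cost = cost, gamma = gamma)
  } else {
    ntree <- hp$ntree %||% 500L
    mtry <- hp$mtry %||% max(1L, floor(sqrt(d)))
    fit <- with_seed(seed, randomForest::randomForest(
      features, y, ntree = ntree, mtry = mtry))
    hp <- list(ntree = ntree, mtry = mtry)
  }
  structure(list(backend = backend, fit = fit, hyperparameters = hp,
                 feature_dim = d,
                 metric = attr(features, "metric"),
                 k = attr(features, "k")),
            class = "gradis_model")
}

#' @export
print.gradis_model <- function(x, ...) {
  cat("gradis_model:", x$backend, "backend,", x$feature_dim, "features")
  if (!is.null(x$k)) cat(" (k =", x$k, ",", x$metric, "metric)")
  cat("\n")
  invisible(x)
}

#' Continuous decision scores for pairs
#'
#' Returns the classifier's continuous score per feature row: the signed
#' margin for the SVM backend (positive = predicted interaction) and the
#' class-probability difference `P(+1) - P(-1)` for the random forest. The
#' scores order candidate edges for ROC/PR analysis; their sign is the
#' predicted label.
#'
#' @param model A `gradis_model`.
#' @param features Numeric matrix with `ncol == model$feature_dim`.
#' @return Numeric vector, named by the feature rownames if present.
#' @export
decision_scores <- function(model, features) {
  stopifnot(inherits(model, "gradis_model"))
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  if (ncol(features) != model$feature_dim) {
    stop("feature dimension ", ncol(features),
         " does not match the model (", model$feature_dim, ")")
  }
  if (model$backend == "svm") {
    pred <- stats::predict(model$fit, features, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    s <- dv[, 1L]
    # libsvm orients the margin toward whichever class it saw first
    if (colnames(dv)[1L] == "-1/1") s <- -s
  } else {
    prob <- stats::predict(model$fit, features, type = "prob")
    s <- prob[, "1"] - prob[, "-1"]
  }
  stats::setNames(as.numeric(s), rownames(features))
}

#' Score all TF-gene pairs and return a ranked network
#'
#' Featurises every ordered pair (tf, gene) over the given regulator set and
#' gene universe (self-pairs and explicit exclusions removed), scores them
#' with the trained classifier, and returns a ranked edge list. Because the
#' graph-distance feature is symmetric in its arguments, (A, B) and (B, A)
#' receive the same score when both genes are TFs; directionality comes from
#' restricting edge sources to `tf_ids`.
#'
#' @param model A `gradis_model` trained on graph-distance features.
#' @param centroids The `centroid_profiles` the model's features were built
#'   from (same `k` and metric).
#' @param tf_ids Character vector of regulator ids.
#' @param gene_universe Candidate target ids; defaults to all genes in
#'   `centroids`.
#' @param exclusions Optional data frame of pairs to omit (e.g. the training
#'   positives).
#' @param include_self Score self-pairs (off by default).
#' @return Data frame (`tf`, `target`, `score`) sorted by decreasing score.
#' @export
predict_network <- function(model, centroids, tf_ids, gene_universe = NULL,
                            exclusions = NULL, include_self = FALSE) {
  stopifnot(inherits(model, "gradis_model"), inherits(centroids, "centroid_profiles"))
  if (!is.null(model$k) && model$k != centroids$k) {
    stop("model was trained with k = ", model$k, " but centroids have k = ",
         centroids$k)
  }
  if (is.null(gene_universe)) gene_universe <- rownames(centroids$centroids)
  pairs <- expand.grid(tf = tf_ids, target = gene_universe,
                       stringsAsFactors = FALSE)
  if (!include_self) pairs <- pairs[pairs$tf != pairs$target, , drop = FALSE]
  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    drop <- pairs_to_keys(pairs) %in% pairs_to_keys(exclusions)
    pairs <- pairs[!drop, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("no pairs left to score after exclusions")
  metric <- model$metric %||% "euclidean"
  feats <- featurize_pairs(centroids, pairs, metric = metric)
  pairs$score <- unname(decision_scores(model, feats))
  ord <- order(pairs$score, pairs$tf, pairs$target,
               decreasing = c(TRUE, FALSE, FALSE), method = "radix")
  out <- pairs[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
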