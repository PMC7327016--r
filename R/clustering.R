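#' Compress samples by k-means clustering
#'
#' Groups the samples (columns) of an expression matrix into `k` clusters by
#' k-means in gene-dimensional space, and summarises each gene by its mean
#' expression within every cluster. The resulting genes x k centroid matrix
#' is the reduced data set all downstream graph-distance features are built
#' from; one clustering is computed per dataset and shared by every pair.
#'
#' Raw k-means labels are arbitrary, but feature coordinates are indexed by
#' cluster, so clusters are relabelled canonically: decreasing cluster size,
#' ties broken by the lexicographically smallest member sample id. This makes
#' feature indices reproducible across runs with the same seed.
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param k Number of clusters, `2 <= k <= ncol(expr)`.
#' @param seed Integer seed controlling the k-means initialisations.
#' @param restarts Number of random initialisations; the best by total
#'   within-cluster sum of squares is kept.
#' @param iter_max Maximum Lloyd iterations per start.
#' @param standardize_samples Standardise each sample vector (zero mean, unit
#'   variance across genes) before clustering. Centroids are always computed
#'   on the raw expression values.
#' @return An object of class `centroid_profiles`: list with `centroids`
#'   (genes x k numeric matrix, columns `c1..ck`), `assignment` (named
#'   integer vector, sample id to cluster index), `k`, `seed` and `wcss`.
#' @export
cluster_samples <- function(expr, k, seed = 1L, restarts = 10L,
                            iter_max = 300L, standardize_samples = FALSE) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("`expr` must be a numeric matrix")
  if (!all(is.finite(expr))) stop("expression matrix contains non-finite values")
  n_samples <- ncol(expr)
  k <- assert_scalar_int(k, "k")
  if (k < 2L) stop("k must be at least 2")
  if (k > n_samples) stop("k (", k, ") exceeds the number of samples (", n_samples, ")")
  restarts <- assert_scalar_int(restarts, "restarts", min = 1L)
  if (is.null(colnames(expr))) colnames(expr) <- sprintf("S%03d", seq_len(n_samples))
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("G%03d", seq_len(nrow(expr)))

  if (k == n_samples) {
    # degenerate case: every sample is its own cluster
    assignment <- seq_len(n_samples)
    names(assignment) <- colnames(expr)
  } else {
    pts <- t(expr)
    if (standardize_samples) {
      pts <- t(scale(expr))
      pts[is.nan(pts)] <- 0  # constant sample vectors
    }
    fit <- with_seed(seed, {
      tryCatch(
        stats::kmeans(pts, centers = k, nstart = restarts, iter.max = iter_max),
        error = function(e) stats::kmeans(pts, centers = k, nstart = restarts,
                                          iter.max = iter_max,
                                          algorithm = "MacQueen")
      )
    })
    assignment <- fit$cluster
    names(assignment) <- colnames(expr)
  }

  sizes <- tabulate(assignment, nbins = max(assignment))
  if (any(sizes[sort(unique(assignment))] == 0L) || length(unique(assignment)) != k) {
    stop("k-means produced fewer than ", k, " nonempty clusters")
  }
  # canonical relabelling: size desc, tie by smallest member sample id
  first_member <- vapply(seq_len(k), function(j) {
    min(names(assignment)[assignment == j])
  }, character(1))
  new_order <- order(-sizes, first_member, method = "radix")
  relabel <- integer(k)
  relabel[new_order] <- seq_len(k)
  assignment <- relabel[assignment]
  names(assignment) <- colnames(expr)

  centroids <- vapply(seq_len(k), function(j) {
    rowMeans(expr[, assignment == j, drop = FALSE])
  }, numeric(nrow(expr)))
  dimnames(centroids) <- list(rownames(expr), paste0("c", seq_len(k)))
  wcss <- sum(vapply(seq_len(k), function(j) {
    block <- expr[, assignment == j, drop = FALSE]
    sum((block - rowMeans(block))^2)
  }, numeric(1)))

  structure(list(centroids = centroids, assignment = assignment,
                 k = k, seed = seed, wcss = wcss),
            class = "centroid_profiles")
}

#' @export
print.centroid_profiles <- function(x, ...) {
  cat("centroid_profiles:", nrow(x$centroids), "genes x", x$k,
      "clusters (seed", x$seed, ")\n")
  cat("cluster sizes:", paste(tabulate(x$assignment, x$k), collapse = " "), "\n")
  invisible(x)
}

#' Write centroid profiles as TSV
#'
#' @param centroids A `centroid_profiles` object.
#' @param path Output path; genes as rows, columns `c1..ck`.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(centroids, path) {
  stopifnot(inherits(centroids, "centroid_profiles"))
  utils::write.table(
    data.frame(gene = rownames(centroids$centroids), centroids$centroids,
               check.names = FALSE, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Advisory sweep over the number of clusters
#'
#' Runs a reduced-repetition evaluation of the full pipeline for each
#' candidate `k` and reports the mean cross-validated AUC, to help pick the
#' cluster count. The AUC saturates as `k` grows; the package default,
#' `min(50, floor(n_samples / 2))`, reflects where the gain levels off.
#'
#' Failures for individual `k` values (e.g. `k` larger than the sample
#' count) are recorded in the output rather than aborting the sweep.
#'
#' @param expr Expression matrix, genes x samples.
#' @param gold A [gold_standard()] object.
#' @param k_grid Integer vector of candidate cluster counts.
#' @param folds,reps Cross-validation shape (reduced defaults for a sweep).
#' @param seed Integer seed.
#' @param metric Distance metric for the features.
#' @param backend Classifier backend.
#' @param negatives Optional data frame of negative pairs; when `NULL`,
#'   negatives are sampled uniformly from the uncharacterized pairs (the
#'   sweep is advisory, so the cheap sampling stand-in is used rather than
#'   the full iterative selection per `k`).
#' @return Data frame with columns `k`, `mean_auc`, `error` (NA on success).
#' @export
choose_k_report <- function(expr, gold, k_grid, folds = 5L, reps = 2L,
                            seed = 1L, metric = "euclidean",
                            backend = "svm", negatives = NULL) {
  res <- lapply(k_grid, function(k) {
    out <- tryCatch({
      cp <- cluster_samples(expr, k, seed = seed)
      pos <- gold$positives
      neg <- negatives
      if (is.null(neg)) {
        unc <- uncharacterized_pairs(gold, rownames(expr))
        n_neg <- min(nrow(unc), max(2L * nrow(pos), folds))
        idx <- with_seed(seed + k, sample.int(nrow(unc), n_neg))
        neg <- unc[idx, , drop = FALSE]
      }
      feats <- featurize_pairs(cp, rbind(pos, neg), metric = metric)
      ev <- balanced_cv_evaluate(feats, pos, neg, folds = folds, reps = reps,
                                 seed = seed, backend = backend,
                                 keep_scores = FALSE)
      data.frame(k = k, mean_auc = ev$mean_auc, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(k = k, mean_auc = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    out
  })
  do.call(rbind, res)
}
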