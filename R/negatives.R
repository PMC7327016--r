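#' Partition the uncharacterized pairs into training subsets
#'
#' Splits the unlabelled TF-gene pairs into `floor(|U| / |P|)` disjoint
#' random subsets, each of the size of the positive class; the last subset
#' absorbs any remainder. One subset per iteration serves as the provisional
#' negative class in [iterative_negative_scoring()].
#'
#' @param uncharacterized Data frame of unlabelled pairs (`tf`, `target`).
#' @param n_positives Size of the positive class.
#' @param seed Integer seed for the random permutation.
#' @return List of data frames, disjoint, whose union is the input.
#' @export
partition_uncharacterized <- function(uncharacterized, n_positives, seed = 1L) {
  n_positives <- assert_scalar_int(n_positives, "n_positives", min = 1L)
  n <- nrow(uncharacterized)
  n_subsets <- n %/% n_positives
  if (n_subsets < 2L) {
    stop("too few uncharacterized pairs (", n, ") for positives (",
         n_positives, "): need at least 2 subsets; consider sampling ",
         "negatives uniformly at random instead")
  }
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n_positives, n_subsets)
  sizes[n_subsets] <- sizes[n_subsets] + (n - n_subsets * n_positives)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_subsets), function(t) {
    df <- uncharacterized[perm[starts[t]:ends[t]], , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

# Default per-iteration classifier: RBF-kernel SVM, fixed hyperparameters.
svm_classify_fun <- function(cost = 1, gamma = NULL) {
  function(train_x, train_y, test_x) {
    g <- gamma
    if (is.null(g)) {
      v <- stats::var(as.vector(train_x))
      g <- if (is.finite(v) && v > 0) 1 / (ncol(train_x) * v) else 1 / ncol(train_x)
    }
    fit <- e1071::svm(train_x, train_y, kernel = "radial", cost = cost,
                      gamma = g, scale = FALSE)
    as.character(stats::predict(fit, test_x))
  }
}

# Grid-search (C, gamma) by 10-fold CV accuracy, then refit; the slow path
# behind `inner_cv = TRUE`.
svm_classify_fun_cv <- function(costs = c(0.1, 1, 10),
                                gamma_mult = c(0.1, 1, 10), folds = 10L) {
  function(train_x, train_y, test_x) {
    v <- stats::var(as.vector(train_x))
    g0 <- if (is.finite(v) && v > 0) 1 / (ncol(train_x) * v) else 1 / ncol(train_x)
    tune <- e1071::tune.svm(train_x, train_y, kernel = "radial",
                            cost = costs, gamma = g0 * gamma_mult,
                            scale = FALSE,
                            tunecontrol = e1071::tune.control(cross = folds))
    as.character(stats::predict(tune$best.model, test_x))
  }
}

#' Score uncharacterized pairs by iterative positive-unlabelled learning
#'
#' In each iteration one subset of the unlabelled pairs stands in as the
#' negative class; a fresh classifier is trained on the positives (+1)
#' against that subset (-1) and applied to every unlabelled pair outside the
#' subset. A pair predicted positive has its integer score incremented. After
#' all iterations a low score marks a pair that classifiers consistently
#' call negative, making it a trustworthy negative-training candidate; a
#' high score flags a plausible (still uncharacterized) interaction.
#'
#' Under the default convention a pair is not assessed in the one iteration
#' where it is the training negative class, so the maximum attainable score
#' is `length(subsets) - 1`. Set `score_own_iteration = TRUE` to also have
#' each iteration-specific classifier score its own negative subset, making
#' the maximum equal to the number of iterations.
#'
#' @param features Numeric matrix with rownames `"tf\ttarget"` covering all
#'   positive and unlabelled pairs (see [featurize_pairs()]).
#' @param positives Data frame of positive pairs.
#' @param subsets List of data frames from [partition_uncharacterized()].
#' @param svm_config List with elements `cost` and `gamma` (`NULL` gamma =
#'   `1 / (n_features * var(features))` heuristic).
#' @param inner_cv Select (C, gamma) per iteration by tenfold
#'   cross-validation on that iteration's training pairs (slow; default off,
#'   one fixed-hyperparameter fit per iteration).
#' @param score_own_iteration See Details.
#' @param classify_fun Optional override: `function(train_x, train_y,
#'   test_x)` returning predicted labels (`"1"` / `"-1"`). Used for testing
#'   and for alternative backends.
#' @param verbose Print per-iteration progress.
#' @return Object of class `pair_score_table`: data frame with columns `tf`,
#'   `target`, `score`, `subset` (which iteration used the pair as a
#'   negative), with attributes `n_iterations` and `max_score`.
#' @export
iterative_negative_scoring <- function(features, positives, subsets,
                                       svm_config = list(cost = 1, gamma = NULL),
                                       inner_cv = FALSE,
                                       score_own_iteration = FALSE,
                                       classify_fun = NULL,
                                       verbose = FALSE) {
  pos_keys <- pairs_to_keys(positives)
  subset_keys <- lapply(subsets, pairs_to_keys)
  all_unc <- unlist(subset_keys, use.names = FALSE)
  need <- c(pos_keys, all_unc)
  missing <- setdiff(need, rownames(features))
  if (length(missing) > 0L) {
    stop("features missing for ", length(missing), " pair(s), e.g. ",
         gsub("\t", "->", missing[1L]))
  }
  if (is.null(classify_fun)) {
    classify_fun <- if (inner_cv) {
      svm_classify_fun_cv()
    } else {
      svm_classify_fun(cost = svm_config$cost %||% 1, gamma = svm_config$gamma)
    }
  }
  n_iter <- length(subsets)
  scores <- stats::setNames(integer(length(all_unc)), all_unc)
  subset_of <- stats::setNames(rep(seq_len(n_iter), lengths(subset_keys)), all_unc)
  pos_x <- features[pos_keys, , drop = FALSE]
  for (t in seq_len(n_iter)) {
    neg_keys <- subset_keys[[t]]
    test_keys <- if (score_own_iteration) all_unc else setdiff(all_unc, neg_keys)
    train_x <- rbind(pos_x, features[neg_keys, , drop = FALSE])
    train_y <- factor(rep(c("1", "-1"), c(length(pos_keys), length(neg_keys))),
                      levels = c("-1", "1"))
    pred <- tryCatch(
      classify_fun(train_x, train_y, features[test_keys, , drop = FALSE]),
      error = function(e) stop("classifier failed in iteration ", t, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    hit <- test_keys[pred == "1"]
    scores[hit] <- scores[hit] + 1L
    if (verbose) {
      message("iteration ", t, "/", n_iter, ": ", length(hit),
              " pairs predicted positive")
    }
  }
  out <- keys_to_pairs(all_unc)
  out$score <- unname(scores)
  out$subset <- unname(subset_of)
  structure(out, class = c("pair_score_table", "data.frame"),
            n_iterations = n_iter,
            max_score = n_iter - 1L + as.integer(score_own_iteration))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the negative training class from a score table
#'
#' Selects the pairs with score at or below `threshold` (default 0: pairs
#' never predicted positive by any iteration classifier). If a minimum pool
#' size is requested and too few pairs qualify, the threshold is relaxed
#' upward one unit at a time, with a message per relaxation.
#'
#' @param table A `pair_score_table` from [iterative_negative_scoring()].
#' @param threshold Initial score cutoff (inclusive).
#' @param required_n Minimum number of negatives needed, or `NULL` for
#'   "all pairs at the initial threshold" (at least one).
#' @param quiet Suppress relaxation messages.
#' @return Data frame of pairs (`tf`, `target`) with attribute
#'   `threshold_used`.
#' @export
extract_negative_class <- function(table, threshold = 0L, required_n = NULL,
                                   quiet = FALSE) {
  stopifnot(inherits(table, "pair_score_table"))
  max_score <- attr(table, "max_score")
  need <- if (is.null(required_n)) 1L else assert_scalar_int(required_n, "required_n", min = 1L)
  thr <- assert_scalar_int(threshold, "threshold", min = 0L)
  repeat {
    sel <- table$score <= thr
    if (sum(sel) >= need) break
    if (thr >= max_score) {
      stop("cannot assemble ", need, " negatives even at the maximum ",
           "score threshold (", max_score, "); pool has ", sum(sel))
    }
    thr <- thr + 1L
    if (!quiet) {
      message("negative pool too small; relaxing score threshold to ", thr)
    }
  }
  out <- data.frame(tf = table$tf[sel], target = table$target[sel],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold_used") <- thr
  out
}

#' Permutation enrichment test for high-scoring pairs
#'
#' Tests whether a set of pairs (e.g. those with top plausibility scores)
#' contains more known true interactions than expected by chance, by drawing
#' `n_random` uniform same-size sets from the pair universe and counting
#' their overlaps with the truth set.
#'
#' @param high_score_pairs Data frame of pairs to test.
#' @param truth_edges Data frame of true interactions.
#' @param universe Data frame: the pair universe the set was drawn from.
#' @param n_random Number of null draws.
#' @param seed Integer seed.
#' @return List with `observed` (hit count), `null` (integer vector of null
#'   hit counts), `null_max`, and `p_value = (1 + #{null >= observed}) /
#'   (n_random + 1)`.
#' @export
enrichment_null_test <- function(high_score_pairs, truth_edges, universe,
                                 n_random = 1000L, seed = 1L) {
  hs <- unique(pairs_to_keys(high_score_pairs))
  uni <- unique(pairs_to_keys(universe))
  truth <- unique(pairs_to_keys(truth_edges))
  if (!all(hs %in% uni)) stop("high-score pairs must be a subset of the universe")
  m <- length(hs)
  if (m > length(uni)) stop("set size exceeds the universe")
  if (m == 0L) stop("empty high-score set")
  observed <- sum(hs %in% truth)
  is_true <- uni %in% truth
  null <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) sum(is_true[sample.int(length(uni), m)]),
           integer(1))
  })
  list(observed = observed, null = null, null_max = max(null),
       p_value = (1 + sum(null >= observed)) / (n_random + 1))
}
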