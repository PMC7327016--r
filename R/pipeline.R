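#' Run the full network-inference pipeline
#'
#' Executes, in order: sample clustering, pair featurisation, iterative
#' negative selection, balanced cross-validated evaluation, final training
#' on all labelled pairs, and whole-network prediction. Every stage's seed
#' is derived from `seed` and recorded in the manifest, so two runs with the
#' same inputs and configuration produce identical outputs.
#'
#' When `outdir` is given, stage outputs are written as they complete:
#' `centroids.tsv`, `pair_scores.tsv`, `negatives.tsv`, `evaluation.json`,
#' `predictions.tsv` and `manifest.json` (parameters, seeds, versions and
#' per-file checksums). A stage failure aborts with the stage name; files
#' already written are preserved.
#'
#' @param expr Expression matrix, genes x samples (see [read_expression()]).
#' @param gold A [gold_standard()] object.
#' @param k Number of sample clusters; default `min(50, floor(n_samples/2))`,
#'   where the cross-validated AUC has been found to saturate.
#' @param metric `"euclidean"` or `"manhattan"` graph distance.
#' @param backend `"svm"` or `"rf"` classifier backend.
#' @param folds,reps Cross-validation shape.
#' @param seed Master seed; clustering uses `seed`, subset partitioning
#'   `seed + 1`, cross-validation `seed + 2`, final training `seed + 3`.
#' @param restarts k-means restarts.
#' @param score_own_iteration,inner_cv Passed to
#'   [iterative_negative_scoring()].
#' @param negatives_threshold,required_negatives Passed to
#'   [extract_negative_class()].
#' @param target_ids Optional restriction of the candidate target universe.
#' @param outdir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return Object of class `gradis_run`: list with `centroids`,
#'   `score_table`, `negatives`, `evaluation`, `model`, `ranked` and
#'   `manifest`.
#' @export
run_gradis <- function(expr, gold, k = NULL, metric = "euclidean",
                       backend = "svm", folds = 10L, reps = 10L, seed = 1L,
                       restarts = 10L, score_own_iteration = FALSE,
                       inner_cv = FALSE, negatives_threshold = 0L,
                       required_negatives = NULL, target_ids = NULL,
                       outdir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  seeds <- list(clustering = seed, partition = seed + 1L,
                cv = seed + 2L, model = seed + 3L)
  if (is.null(k)) k <- min(50L, floor(ncol(expr) / 2))
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  say("stage cluster: k = ", k)
  centroids <- stage("cluster",
    cluster_samples(expr, k, seed = seeds$clustering, restarts = restarts))
  if (!is.null(outdir)) {
    files["centroids"] <- file.path(outdir, "centroids.tsv")
    write_centroids(centroids, files[["centroids"]])
  }

  say("stage featurize (", metric, " metric)")
  featurized <- stage("featurize", {
    unc <- uncharacterized_pairs(gold, rownames(expr), targets = target_ids)
    feats <- featurize_pairs(centroids, rbind(gold$positives,
                                              gold$known_negatives, unc),
                             metric = metric)
    list(features = feats, uncharacterized = unc)
  })

  say("stage select-negatives")
  negsel <- stage("select-negatives", {
    subsets <- partition_uncharacterized(featurized$uncharacterized,
                                         nrow(gold$positives),
                                         seed = seeds$partition)
    tab <- iterative_negative_scoring(featurized$features, gold$positives,
                                      subsets, inner_cv = inner_cv,
                                      score_own_iteration = score_own_iteration,
                                      verbose = !quiet)
    negs <- extract_negative_class(tab, threshold = negatives_threshold,
                                   required_n = required_negatives %||%
                                     max(nrow(gold$positives), folds),
                                   quiet = quiet)
    list(table = tab, negatives = negs)
  })
  if (!is.null(outdir)) {
    files["pair_scores"] <- file.path(outdir, "pair_scores.tsv")
    utils::write.table(as.data.frame(negsel$table)[, c("tf", "target", "score")],
                       files[["pair_scores"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files["negatives"] <- file.path(outdir, "negatives.tsv")
    utils::write.table(negsel$negatives, files[["negatives"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  say("stage evaluate: ", folds, "-fold CV x ", reps, " repetitions")
  evaluation <- stage("evaluate",
    balanced_cv_evaluate(featurized$features, gold$positives,
                         negsel$negatives, folds = folds, reps = reps,
                         seed = seeds$cv, backend = backend))
  per_tf <- per_tf_auc_distribution(evaluation)
  if (!is.null(outdir)) {
    files["evaluation"] <- file.path(outdir, "evaluation.json")
    jsonlite::write_json(
      list(per_run = evaluation$per_run,
           mean_auc = evaluation$mean_auc, mean_aupr = evaluation$mean_aupr,
           ci_auc = as.list(evaluation$ci_auc),
           ci_aupr = as.list(evaluation$ci_aupr),
           folds = folds, reps = reps, backend = backend, per_tf = per_tf),
      files[["evaluation"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  say("stage train")
  model <- stage("train", {
    pos_keys <- pairs_to_keys(gold$positives)
    neg_keys <- pairs_to_keys(negsel$negatives)
    n_neg <- min(length(neg_keys), length(pos_keys))
    neg_keys <- with_seed(seeds$model, sample(neg_keys, n_neg))
    train_classifier(featurized$features[c(pos_keys, neg_keys), , drop = FALSE],
                     rep(c(1, -1), c(length(pos_keys), n_neg)),
                     backend = backend, seed = seeds$model)
  })

  say("stage predict")
  ranked <- stage("predict",
    predict_network(model, centroids, gold$tf_ids,
                    gene_universe = if (is.null(target_ids)) NULL else target_ids))
  if (!is.null(outdir)) {
    files["predictions"] <- file.path(outdir, "predictions.tsv")
    write_ranked_edges(ranked, files[["predictions"]])
  }

  manifest <- list(
    package = "gradis",
    version = as.character(utils::packageVersion("gradis")),
    parameters = list(k = k, metric = metric, backend = backend,
                      folds = folds, reps = reps, restarts = restarts,
                      score_own_iteration = score_own_iteration,
                      inner_cv = inner_cv,
                      negatives_threshold = negatives_threshold,
                      n_genes = nrow(expr), n_samples = ncol(expr),
                      n_tfs = length(gold$tf_ids),
                      n_positives = nrow(gold$positives),
                      n_uncharacterized = nrow(featurized$uncharacterized),
                      n_negatives = nrow(negsel$negatives)),
    seeds = seeds,
    stages = c("cluster", "featurize", "select-negatives", "evaluate",
               "train", "predict"),
    mean_auc = evaluation$mean_auc,
    mean_aupr = evaluation$mean_aupr)
  if (!is.null(outdir)) {
    manifest$files <- lapply(stats::setNames(as.list(files), names(files)),
                             function(p) list(path = basename(p),
                                              md5 = unname(tools::md5sum(p))))
    files["manifest"] <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  structure(list(centroids = centroids, score_table = negsel$table,
                 negatives = negsel$negatives, evaluation = evaluation,
                 per_tf = per_tf, model = model, ranked = ranked,
                 manifest = manifest, files = files),
            class = "gradis_run")
}

#' @export
print.gradis_run <- function(x, ...) {
  p <- x$manifest$parameters
  cat("gradis_run: ", p$n_genes, " genes, ", p$n_tfs, " TFs, ",
      p$n_positives, " positives; k = ", p$k, ", ", p$metric, " metric, ",
      p$backend, " backend\n", sep = "")
  cat(sprintf("  mean AUC %.3f, mean AUPR %.3f over %d repetitions\n",
              x$evaluation$mean_auc, x$evaluation$mean_aupr, p$reps))
  cat("  ", nrow(x$negatives), " selected negatives, ", nrow(x$ranked),
      " ranked candidate edges\n", sep = "")
  invisible(x)
}
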