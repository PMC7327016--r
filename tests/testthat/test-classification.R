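make_clouds <- function(n = 30, sep = 3, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2, mean = sep, sd = 0.3), ncol = 2),
             matrix(rnorm(n * 2, mean = 0, sd = 0.3), ncol = 2))
  list(x = x, y = rep(c(1, -1), each = n))
}

test_that("a separable toy problem is fit perfectly and scores carry the labels", {
  d <- make_clouds()
  m <- train_classifier(d$x, d$y, backend = "svm", seed = 1)
  s <- decision_scores(m, d$x)
  expect_true(all(sign(s) == d$y))
  expect_true(all(s[d$y == 1] > 0))
  # a point midway between the symmetric clouds scores near zero
  mid <- matrix(c(1.5, 1.5), nrow = 1)
  expect_lt(abs(decision_scores(m, mid)), 0.3)
})

test_that("degenerate training inputs are rejected", {
  d <- make_clouds()
  expect_error(train_classifier(d$x, rep(1, nrow(d$x))), "single class")
  expect_error(train_classifier(d$x, d$y[-1]), "nrow")
  bad <- d$x; bad[1, 1] <- NA
  expect_error(train_classifier(bad, d$y), "missing")
  expect_error(train_classifier(d$x, rep(c(2, 3), each = 30)), "labels")
})

test_that("the RBF kernel separates XOR-patterned data", {
  set.seed(13)
  n <- 40
  x <- matrix(runif(n * 2, -1, 1), ncol = 2)
  y <- ifelse(x[, 1] * x[, 2] > 0, 1, -1)
  m <- train_classifier(x, y, backend = "svm",
                        hyperparameters = list(cost = 10, gamma = 2), seed = 1)
  acc <- mean(sign(decision_scores(m, x)) == y)
  expect_gt(acc, 0.95)
})

test_that("the random-forest backend trains, scores, and is seed-reproducible", {
  d <- make_clouds()
  m1 <- train_classifier(d$x, d$y, backend = "rf", seed = 7)
  m2 <- train_classifier(d$x, d$y, backend = "rf", seed = 7)
  s1 <- decision_scores(m1, d$x)
  expect_identical(s1, decision_scores(m2, d$x))
  expect_true(all(sign(s1[s1 != 0]) == d$y[s1 != 0]))
  expect_equal(m1$hyperparameters$ntree, 500L)
})

test_that("score dimension mismatches are caught", {
  d <- make_clouds()
  m <- train_classifier(d$x, d$y, seed = 1)
  expect_error(decision_scores(m, matrix(0, 2, 5)), "dimension")
})

test_that("serialized models reproduce decision scores bit for bit", {
  d <- make_clouds()
  m <- train_classifier(d$x, d$y, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, path)
  m2 <- readRDS(path)
  expect_identical(decision_scores(m2, d$x), decision_scores(m, d$x))
})

test_that("network prediction counts pairs and symmetrises TF-TF scores", {
  gold <- tiny_ds$gold
  pos <- gold$positives
  negs <- tiny_unc[seq_len(nrow(pos)), ]
  feats <- tiny_feats[c(paste(pos$tf, pos$target, sep = "\t"),
                        paste(negs$tf, negs$target, sep = "\t")), ]
  attr(feats, "metric") <- "euclidean"; attr(feats, "k") <- tiny_cp$k
  m <- train_classifier(feats, rep(c(1, -1), c(nrow(pos), nrow(negs))), seed = 1)

  tfs3 <- gold$tf_ids[1:3]
  genes10 <- rownames(tiny_ds$expr)[1:10]
  ranked <- predict_network(m, tiny_cp, tfs3, gene_universe = genes10)
  expect_equal(nrow(ranked), 27L)  # 3 x 10 minus 3 self-pairs
  expect_true(!is.unsorted(rev(ranked$score)))

  # symmetric scores for ordered TF-TF pairs
  ab <- ranked[ranked$tf %in% tfs3 & ranked$target %in% tfs3, ]
  key <- paste(pmin(ab$tf, ab$target), pmax(ab$tf, ab$target))
  for (k in unique(key)) {
    expect_equal(diff(ab$score[key == k]), 0, tolerance = 1e-12)
  }

  expect_error(predict_network(m, tiny_cp, tfs3, gene_universe = genes10,
                               exclusions = ranked), "no pairs left")
})

test_that("random forests do not beat the SVM on the shared graph features", {
  pos <- tiny_ds$gold$positives
  negs <- tiny_unc[1:40, ]
  feats <- tiny_feats
  ev_svm <- balanced_cv_evaluate(feats, pos, negs, folds = 5, reps = 3,
                                 seed = 2, backend = "svm", keep_scores = FALSE)
  ev_rf <- balanced_cv_evaluate(feats, pos, negs, folds = 5, reps = 3,
                                seed = 2, backend = "rf", keep_scores = FALSE)
  # soft regression guard: allow a small tolerance on a small fixture
  expect_gte(ev_svm$mean_auc, ev_rf$mean_auc - 0.05)
})
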