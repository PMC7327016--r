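test_that("AUC matches brute-force concordance counting on random fixtures", {
  expect_equal(auc_score(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(c(0.9, 0.3, 0.8, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_score(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    expect_equal(auc_score(scores, labels), auc_brute(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUPR has the perfect and constant-ranker fixed points", {
  expect_equal(aupr_score(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  # constant scores: area = prevalence
  expect_equal(aupr_score(rep(1, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_error(aupr_score(1:3, c(0, 0, 0)), "positive")
})

test_that("AUPR equals the hand-computed step sum on a toy with one inversion", {
  # scores descending: labels 1,1,0,1,0,0; P = 3
  # steps: (tp,n) = (1,1),(2,2),(2,3),(3,4),(3,5),(3,6)
  # area = (1/3)(1) + (1/3)(1) + 0 + (1/3)(3/4) + 0 + 0 = 2/3 + 1/4
  scores <- c(6, 5, 4, 3, 2, 1) / 10
  labels <- c(1, 1, 0, 1, 0, 0)
  expect_equal(aupr_score(scores, labels), 2 / 3 + 1 / 4, tolerance = 1e-12)
})

test_that("normal-fit confidence intervals follow mean +/- z * sd", {
  expect_warning(ci <- confidence_interval(rep(0.8, 5)), "degenerate")
  expect_equal(unname(ci), c(0.8, 0.8))
  ci2 <- confidence_interval(c(0.7, 0.9))
  s <- sd(c(0.7, 0.9))
  expect_equal(unname(ci2), c(0.8 - qnorm(0.975) * s, 0.8 + qnorm(0.975) * s))
  # width shrinks monotonically with sd
  widths <- sapply(c(0.2, 0.1, 0.05), function(s) {
    ci <- confidence_interval(c(0.5 - s, 0.5 + s))
    ci[["high"]] - ci[["low"]]
  })
  expect_true(all(diff(widths) < 0))
  expect_error(confidence_interval(0.5), "two")
})

test_that("balanced CV produces one statistic per repetition and is deterministic", {
  pos <- tiny_ds$gold$positives
  negs <- tiny_unc[1:45, ]
  ev <- balanced_cv_evaluate(tiny_feats, pos, negs, folds = 5, reps = 4,
                             seed = 3)
  expect_equal(nrow(ev$per_run), 4L)
  expect_true(all(ev$per_run$auc >= 0 & ev$per_run$auc <= 1))
  expect_true(all(ev$per_run$aupr >= 0 & ev$per_run$aupr <= 1))
  expect_lte(ev$ci_auc[["low"]], ev$mean_auc)
  expect_gte(ev$ci_auc[["high"]], ev$mean_auc)

  ev2 <- balanced_cv_evaluate(tiny_feats, pos, negs, folds = 5, reps = 4,
                              seed = 3)
  expect_identical(ev$per_run, ev2$per_run)
  expect_identical(ev$scores, ev2$scores)
})

test_that("every labelled pair is held out exactly once per repetition", {
  pos <- tiny_ds$gold$positives
  negs <- tiny_unc[1:45, ]
  ev <- balanced_cv_evaluate(tiny_feats, pos, negs, folds = 5, reps = 2,
                             seed = 8)
  want <- sort(c(paste(pos$tf, pos$target, sep = "\t"),
                 paste(negs$tf, negs$target, sep = "\t")))
  for (df in ev$scores) {
    expect_identical(sort(paste(df$tf, df$target, sep = "\t")), want)
  }
})

test_that("shuffled labels drive the CV AUC to chance level", {
  pos <- tiny_ds$gold$positives
  negs <- tiny_unc[1:45, ]
  all_pairs <- rbind(pos, negs)
  set.seed(17)
  idx <- sample(nrow(all_pairs), nrow(pos))
  ev <- balanced_cv_evaluate(tiny_feats, all_pairs[idx, ], all_pairs[-idx, ],
                             folds = 5, reps = 4, seed = 5,
                             keep_scores = FALSE)
  expect_lt(abs(ev$mean_auc - 0.5), 0.12)
})

test_that("fold counts beyond the class sizes are rejected", {
  pos <- tiny_ds$gold$positives[1:4, ]
  negs <- tiny_unc[1:45, ]
  expect_error(balanced_cv_evaluate(tiny_feats, pos, negs, folds = 10,
                                    reps = 1, seed = 1), "stratify")
})

test_that("per-TF AUCs summarise repetitions and bound the extremes", {
  pos <- tiny_ds$gold$positives
  negs <- tiny_unc[1:45, ]
  ev <- balanced_cv_evaluate(tiny_feats, pos, negs, folds = 5, reps = 3,
                             seed = 6)
  tf_auc <- per_tf_auc_distribution(ev)
  expect_true(all(tf_auc$min <= tf_auc$mean & tf_auc$mean <= tf_auc$max))
  expect_true(all(tf_auc$n_reps >= 1 & tf_auc$n_reps <= 3))
  expect_true(all(tf_auc$tf %in% pos$tf))

  # a TF with perfectly ranked targets in every evaluable repetition
  fake <- lapply(1:3, function(r) {
    data.frame(tf = "TX", target = paste0("g", 1:4),
               score = c(0.9, 0.8, 0.2, 0.1), label = c(1, 1, 0, 0))
  })
  got <- per_tf_auc_distribution(fake)
  expect_equal(got[got$tf == "TX", c("min", "mean", "max")],
               data.frame(min = 1, mean = 1, max = 1),
               ignore_attr = TRUE)
})

test_that("Mantel correlation is scale-invariant and near zero under independence", {
  set.seed(23)
  pts <- matrix(runif(20), ncol = 2)
  d <- as.matrix(dist(pts))
  res <- mantel_correlation(d, 2 * d, n_perm = 99, seed = 1)
  expect_equal(res$r, 1.0, tolerance = 1e-12)

  d2 <- as.matrix(dist(matrix(runif(20), ncol = 2)))
  res2 <- mantel_correlation(d, d2, n_perm = 199, seed = 2)
  expect_lt(abs(res2$r), 0.45)
  expect_gt(res2$p_value, 0.05)

  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(mantel_correlation(bad, d), "symmetric")
})

test_that("the wisdom-of-crowds combiner is the scaled conjunction", {
  a <- matrix(c(4, 0, 2, 1), 2, dimnames = list(c("T1", "T2"), c("g1", "g2")))
  expect_equal(combine_score_matrices(list(a)), a / 4)
  expect_equal(combine_score_matrices(list(a, a)), a / 4)

  b <- matrix(c(1, 1, 0, 1), 2, dimnames = dimnames(a))
  comb <- combine_score_matrices(list(a, b))
  # pair above threshold 0.4 in a (T1,g2: 0.5) but zero in b drops out
  expect_equal(comb["T1", "g2"], 0)
  expect_true(all(comb >= 0 & comb <= 1))

  expect_error(combine_score_matrices(list(a, b[, 2:1])), "axes")
  expect_error(combine_score_matrices(list(a, 0 * b)), "zero")
})
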