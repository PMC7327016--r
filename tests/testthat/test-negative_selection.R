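fake_pairs <- function(n) pairs_df(rep("T1", n), paste0("g", seq_len(n)))

test_that("the unlabelled pool partitions into positive-sized subsets", {
  subs <- partition_uncharacterized(fake_pairs(12), 4, seed = 1)
  expect_length(subs, 3L)
  expect_equal(vapply(subs, nrow, integer(1)), c(4L, 4L, 4L))

  subs2 <- partition_uncharacterized(fake_pairs(14), 4, seed = 1)
  expect_equal(vapply(subs2, nrow, integer(1)), c(4L, 4L, 6L))

  # disjoint and exhaustive
  all_targets <- sort(unlist(lapply(subs2, `[[`, "target")))
  expect_identical(all_targets, sort(fake_pairs(14)$target))

  expect_error(partition_uncharacterized(fake_pairs(7), 4, seed = 1),
               "sampling")
})

test_that("an E. coli-shaped pool yields 80 subsets", {
  n_pos <- 2066L
  n_unc <- 80L * n_pos + 1234L  # floor(|U|/|P|) = 80
  unc <- pairs_df(rep("T1", n_unc), as.character(seq_len(n_unc)))
  subs <- partition_uncharacterized(unc, n_pos, seed = 2)
  expect_length(subs, 80L)
  expect_equal(nrow(subs[[80]]), n_pos + 1234L)
})

test_that("scoring counts iterations correctly under both conventions", {
  # stub classifier that always predicts positive
  always_pos <- function(train_x, train_y, test_x) rep("1", nrow(test_x))
  pos <- fake_pairs(3)
  unc <- pairs_df(rep("T2", 9), paste0("u", 1:9))
  feats <- matrix(runif(12 * 4), nrow = 12,
                  dimnames = list(c(paste(pos$tf, pos$target, sep = "\t"),
                                    paste(unc$tf, unc$target, sep = "\t")),
                                  NULL))
  subs <- partition_uncharacterized(unc, 3, seed = 1)
  tab <- iterative_negative_scoring(feats, pos, subs, classify_fun = always_pos)
  # each pair is assessed in all iterations except its own: max = 2
  expect_true(all(tab$score == 2L))
  expect_identical(attr(tab, "max_score"), 2L)
  expect_identical(attr(tab, "n_iterations"), 3L)

  tab2 <- iterative_negative_scoring(feats, pos, subs, classify_fun = always_pos,
                                     score_own_iteration = TRUE)
  expect_true(all(tab2$score == 3L))
  expect_identical(attr(tab2, "max_score"), 3L)
})

test_that("pairs identical to every training negative score zero", {
  # 1-nearest-neighbour stub: an exact duplicate of a training point gets
  # that point's label
  nn1 <- function(train_x, train_y, test_x) {
    as.character(train_y[apply(test_x, 1, function(p) {
      which.min(colSums((t(train_x) - p)^2))
    })])
  }
  pos <- fake_pairs(2)
  unc <- pairs_df(rep("T2", 6), paste0("u", 1:6))
  neg_point <- c(0, 0, 0)
  feats <- rbind(matrix(5, nrow = 2, ncol = 3),
                 matrix(rep(neg_point, 6), nrow = 6, byrow = TRUE))
  rownames(feats) <- c(paste(pos$tf, pos$target, sep = "\t"),
                       paste(unc$tf, unc$target, sep = "\t"))
  subs <- partition_uncharacterized(unc, 2, seed = 3)
  tab <- iterative_negative_scoring(feats, pos, subs, classify_fun = nn1)
  expect_true(all(tab$score == 0L))
})

test_that("classifier failures abort with the iteration index", {
  boom <- local({
    count <- 0
    function(train_x, train_y, test_x) {
      count <<- count + 1
      if (count == 2) stop("singular kernel")
      rep("-1", nrow(test_x))
    }
  })
  pos <- fake_pairs(3)
  unc <- pairs_df(rep("T2", 9), paste0("u", 1:9))
  feats <- matrix(runif(48), nrow = 12,
                  dimnames = list(c(paste(pos$tf, pos$target, sep = "\t"),
                                    paste(unc$tf, unc$target, sep = "\t")), NULL))
  subs <- partition_uncharacterized(unc, 3, seed = 1)
  expect_error(iterative_negative_scoring(feats, pos, subs, classify_fun = boom),
               "iteration 2")
})

test_that("negative extraction honours the threshold and relaxes when required", {
  tab <- structure(
    data.frame(tf = rep("T1", 14), target = paste0("g", 1:14),
               score = c(rep(0L, 10), 1L, 1L, 2L, 3L),
               subset = rep(1:2, 7), stringsAsFactors = FALSE),
    class = c("pair_score_table", "data.frame"),
    n_iterations = 4L, max_score = 3L)
  expect_equal(nrow(extract_negative_class(tab, quiet = TRUE)), 10L)

  tab$score <- c(1L, 2L, rep(3L, 10), 0L, 0L)
  got <- extract_negative_class(tab, required_n = 5, quiet = TRUE)
  expect_equal(nrow(got), 14L)
  expect_equal(attr(got, "threshold_used"), 3L)

  expect_error(extract_negative_class(tab, required_n = 100, quiet = TRUE),
               "cannot assemble")
})

test_that("enrichment p-value is minimal for a fully recovered truth set", {
  universe <- fake_pairs(200)
  truth <- universe[1:8, ]
  res <- enrichment_null_test(truth, truth, universe, n_random = 199, seed = 4)
  expect_equal(res$observed, 8L)
  expect_equal(res$p_value, 1 / 200)
})

test_that("a uniform draw shows hypergeometric-level overlap and a large p", {
  universe <- fake_pairs(500)
  truth <- universe[1:100, ]
  set.seed(11)
  draw <- universe[sample(500, 50), ]
  res <- enrichment_null_test(draw, truth, universe, n_random = 500, seed = 12)
  # null mean matches the closed-form hypergeometric expectation m*K/N
  expect_equal(mean(res$null), 50 * 100 / 500, tolerance = 0.1)
  expect_gt(res$p_value, 0.05)
  expect_error(enrichment_null_test(fake_pairs(600), truth, universe),
               "subset")
})
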