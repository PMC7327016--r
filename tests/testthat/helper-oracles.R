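# Independent brute-force oracles. These stay deliberately naive (double
# loops, exhaustive enumeration) so they can vouch for the vectorised
# implementations they are compared against.

# All pairwise point distances, row-major i < j, one subtraction at a time.
pair_feature_brute <- function(tf, g, metric) {
  k <- length(tf)
  out <- numeric(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- if (metric == "euclidean") {
        sqrt((tf[i] - tf[j])^2 + (g[i] - g[j])^2)
      } else {
        abs(tf[i] - tf[j]) + abs(g[i] - g[j])
      }
      out <- c(out, d)
    }
  }
  out
}

# AUC by counting concordant positive/negative pairs, ties worth 1/2.
auc_brute <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# Exact 2-means on <= 10 points by enumerating every 2-partition.
exact_two_means <- function(pts) {
  n <- nrow(pts)
  stopifnot(n <= 10)
  wcss_of <- function(idx) {
    sum(vapply(unique(idx), function(c) {
      block <- pts[idx == c, , drop = FALSE]
      sum(sweep(block, 2, colMeans(block))^2)
    }, numeric(1)))
  }
  best <- NULL
  best_w <- Inf
  for (code in 0:(2^(n - 1) - 1)) {
    member <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2)))))
    if (all(member)) next
    idx <- ifelse(member, 1L, 2L)
    w <- wcss_of(idx)
    if (w < best_w) {
      best_w <- w
      best <- idx
    }
  }
  list(assignment = best, wcss = best_w)
}
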