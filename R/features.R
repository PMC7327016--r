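#' Min-max rescale a profile to the unit interval
#'
#' Affine map of a gene's centroid-expression profile onto `[0, 1]`, so that
#' TF and target profiles of very different magnitude become comparable. A
#' constant profile carries no shape information and maps to all 0.5 (the
#' centre of the interval) rather than fabricating an extreme coordinate.
#'
#' @param x Numeric vector (a gene's expression over the k centroids).
#' @return Numeric vector of the same length with values in `[0, 1]`.
#' @export
rescale_profile <- function(x) {
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("profile must be finite numeric")
  }
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(0.5, length(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

# Row-wise min-max rescaling of a genes x k matrix (cached scaled profiles).
rescale_rows <- function(m) {
  lo <- apply(m, 1L, min)
  hi <- apply(m, 1L, max)
  span <- hi - lo
  const <- span == 0
  span[const] <- 1
  out <- (m - lo) / span
  out[const, ] <- 0.5
  out
}

#' Graph distance profile of a TF-gene pair
#'
#' The scaled k-dimensional profiles of a TF and a candidate target gene
#' define k points `(x_TF^i, x_G^i)` in the unit square, one per sample
#' cluster. The feature vector is the upper triangle (diagonal excluded) of
#' the complete weighted graph over those points, with edge weights
#' `w(n_i, n_j) = sqrt((x_TF^i - x_TF^j)^2 + (x_G^i - x_G^j)^2)` (Euclidean)
#' or `w_m(n_i, n_j) = |x_TF^i - x_TF^j| + |x_G^i - x_G^j|` (Manhattan),
#' vectorised row-major: (1,2), (1,3), ..., (1,k), (2,3), ..., (k-1,k).
#'
#' The feature is symmetric in its two arguments; edge direction in the
#' inferred network comes solely from which ordered pairs are labelled, not
#' from the feature itself.
#'
#' @param tf,g Numeric vectors of equal length `k >= 2`, expected in
#'   `[0, 1]` (see [rescale_profile()]).
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return Numeric vector of length `k * (k - 1) / 2`; entries lie in
#'   `[0, sqrt(2)]` (Euclidean) or `[0, 2]` (Manhattan).
#' @export
pair_feature <- function(tf, g, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (length(tf) != length(g)) {
    stop("profiles have different lengths: ", length(tf), " vs ", length(g))
  }
  k <- length(tf)
  if (k < 2L) stop("need at least k = 2 cluster coordinates")
  dtf <- outer(tf, tf, "-")
  dg <- outer(g, g, "-")
  w <- if (metric == "euclidean") sqrt(dtf^2 + dg^2) else abs(dtf) + abs(dg)
  # row-major upper triangle of a symmetric matrix = column-major lower triangle
  w[lower.tri(w)]
}

#' Expression-concatenation baseline feature
#'
#' The baseline pair representation used for comparison with the graph
#' distance profile: the raw (full-sample, not centroid) expression profiles
#' of the TF and the gene, each min-max rescaled independently, concatenated
#' to a length-`2m` vector. Unlike [pair_feature()], this representation is
#' not symmetric under swapping the arguments.
#'
#' @param tf_raw,g_raw Numeric vectors of equal length `m` (expression over
#'   all samples).
#' @return Numeric vector of length `2 * m`.
#' @export
expression_pair_feature <- function(tf_raw, g_raw) {
  if (length(tf_raw) != length(g_raw)) {
    stop("profiles have different lengths: ", length(tf_raw), " vs ",
         length(g_raw))
  }
  c(rescale_profile(tf_raw), rescale_profile(g_raw))
}

#' Build the feature matrix for a list of pairs
#'
#' Computes the graph distance profile for every (tf, target) pair. Each
#' gene's scaled profile is computed once from the centroid matrix and
#' reused across pairs.
#'
#' @param centroids A `centroid_profiles` object from [cluster_samples()].
#' @param pairs Data frame with columns `tf` and `target`.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return Numeric matrix, `nrow(pairs)` x `k(k-1)/2`, rows in input pair
#'   order with rownames `"tf\ttarget"`; attributes `metric` and `k`.
#' @export
featurize_pairs <- function(centroids, pairs, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  stopifnot(inherits(centroids, "centroid_profiles"))
  ids <- unique(c(pairs$tf, pairs$target))
  missing <- setdiff(ids, rownames(centroids$centroids))
  if (length(missing) > 0L) {
    stop("gene id(s) absent from the centroid profiles: ",
         paste(missing, collapse = ", "))
  }
  k <- centroids$k
  scaled <- rescale_rows(centroids$centroids[ids, , drop = FALSE])
  out <- matrix(NA_real_, nrow = nrow(pairs), ncol = (k * (k - 1L)) %/% 2L)
  for (i in seq_len(nrow(pairs))) {
    out[i, ] <- pair_feature(scaled[pairs$tf[i], ], scaled[pairs$target[i], ],
                             metric = metric)
  }
  rownames(out) <- pair_key(pairs$tf, pairs$target)
  attr(out, "metric") <- metric
  attr(out, "k") <- k
  out
}
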