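#' Generate a planted TF-to-gene regulatory network
#'
#' Draws a sparse directed network in which edges run only from regulator
#' (TF) genes to other genes, with a cap on each gene's in-degree. Edges
#' into TF-coding genes are only allowed from TFs with a smaller index, so
#' the network is acyclic and expression can be simulated in one pass in
#' gene order. Every pair that is not an edge is a true non-interaction, so
#' the generator provides complete ground truth for evaluating
#' negative-selection and classification.
#'
#' @param n_genes Total number of genes; ids `G001, G002, ...` with the
#'   first `n_tfs` being TFs.
#' @param n_tfs Number of regulator genes (`< n_genes`).
#' @param n_edges Number of planted interactions.
#' @param max_in_degree Maximum regulators per target gene.
#' @param seed Integer seed.
#' @return A [gold_standard()] with the planted edges as positives and the
#'   full gene universe in `$genes`.
#' @export
generate_network <- function(n_genes, n_tfs, n_edges, max_in_degree = 3L,
                             seed = 1L) {
  n_genes <- assert_scalar_int(n_genes, "n_genes", min = 2L)
  n_tfs <- assert_scalar_int(n_tfs, "n_tfs", min = 1L, max = n_genes - 1L)
  n_edges <- assert_scalar_int(n_edges, "n_edges", min = 1L)
  max_in_degree <- assert_scalar_int(max_in_degree, "max_in_degree", min = 1L)
  if (n_edges > n_tfs * (n_genes - 1L)) {
    stop("n_edges (", n_edges, ") exceeds the number of possible TF-gene pairs (",
         n_tfs * (n_genes - 1L), ")")
  }
  width <- max(3L, nchar(as.character(n_genes)))
  genes <- sprintf(paste0("G%0", width, "d"), seq_len(n_genes))
  tfs <- genes[seq_len(n_tfs)]
  # allowed pairs: TF -> non-TF freely; TF -> later TF (keeps the graph acyclic)
  src_idx <- rep(seq_len(n_tfs), each = n_genes)
  tgt_idx <- rep(seq_len(n_genes), times = n_tfs)
  ok <- tgt_idx > n_tfs | tgt_idx > src_idx
  src_idx <- src_idx[ok]; tgt_idx <- tgt_idx[ok]
  capacity <- sum(pmin(max_in_degree, tabulate(tgt_idx, n_genes)))
  if (capacity < n_edges) {
    stop("cannot place ", n_edges, " edges with max_in_degree = ",
         max_in_degree, " (capacity ", capacity, ")")
  }
  edges <- with_seed(seed, {
    perm <- sample.int(length(src_idx))
    in_deg <- integer(n_genes)
    keep <- integer(0)
    for (e in perm) {
      tg <- tgt_idx[e]
      if (in_deg[tg] < max_in_degree) {
        in_deg[tg] <- in_deg[tg] + 1L
        keep <- c(keep, e)
        if (length(keep) == n_edges) break
      }
    }
    keep
  })
  if (length(edges) < n_edges) {
    stop("could not place ", n_edges, " edges under the in-degree cap")
  }
  gold_standard(tfs,
                positives = data.frame(tf = genes[src_idx[edges]],
                                       target = genes[tgt_idx[edges]],
                                       stringsAsFactors = FALSE),
                genes = genes)
}

#' Simulate expression over a planted network
#'
#' Per sample, unregulated TFs receive independent standard-normal levels.
#' Each regulated gene's level is a saturating function of its regulators,
#' `tanh(sum_r beta_r * x_r)`, plus Gaussian noise of standard deviation
#' `noise_sd`; the effect size `beta_r` has magnitude uniform in
#' `effect_range` and is positive (activation) with probability
#' `activation_fraction`. Unregulated non-TF genes are standard-normal
#' noise. The matrix is shifted so all values are non-negative, mimicking
#' abundance-style expression data.
#'
#' Because the planted network is acyclic with regulators preceding their
#' targets in gene order (see [generate_network()]), genes are simulated in
#' id order and regulated TFs propagate their (regulated) observed levels
#' downstream.
#'
#' @param gold A [gold_standard()] whose `$genes` (or `gene_ids`) names the
#'   full gene universe.
#' @param n_samples Number of samples (columns).
#' @param noise_sd Noise standard deviation for regulated genes (>= 0).
#' @param effect_range Length-2 positive vector, magnitude range of the
#'   regulatory effects.
#' @param activation_fraction Probability that an effect is activating.
#' @param seed Integer seed.
#' @param gene_ids Optional explicit gene universe, overriding `gold$genes`.
#' @return Numeric matrix, genes x samples.
#' @export
simulate_expression <- function(gold, n_samples, noise_sd = 0.3,
                                effect_range = c(0.5, 2.0),
                                activation_fraction = 0.7, seed = 1L,
                                gene_ids = NULL) {
  stopifnot(inherits(gold, "gold_standard"))
  n_samples <- assert_scalar_int(n_samples, "n_samples", min = 2L)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be a non-negative number")
  }
  if (length(effect_range) != 2L || any(effect_range <= 0) ||
      effect_range[1L] > effect_range[2L]) {
    stop("`effect_range` must be an increasing pair of positive numbers")
  }
  if (activation_fraction < 0 || activation_fraction > 1) {
    stop("`activation_fraction` must lie in [0, 1]")
  }
  genes <- gene_ids %||% gold$genes
  if (is.null(genes)) {
    genes <- sort(unique(c(gold$tf_ids, gold$positives$target)))
  }
  edges <- gold$positives
  regulators <- split(edges$tf, edges$target)
  betas <- with_seed(seed, {
    b <- stats::runif(nrow(edges), effect_range[1L], effect_range[2L])
    sign <- ifelse(stats::runif(nrow(edges)) < activation_fraction, 1, -1)
    stats::setNames(b * sign, pair_key(edges$tf, edges$target))
  })
  x <- matrix(NA_real_, nrow = length(genes), ncol = n_samples,
              dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
  with_seed(seed + 1L, {
    for (g in genes) {
      regs <- regulators[[g]]
      if (is.null(regs)) {
        # unregulated: intrinsic variation only
        x[g, ] <- stats::rnorm(n_samples)
      } else {
        drive <- rep(0, n_samples)
        for (r in regs) drive <- drive + betas[[pair_key(r, g)]] * x[r, ]
        x[g, ] <- tanh(drive) +
          if (noise_sd > 0) stats::rnorm(n_samples, sd = noise_sd) else 0
      }
    }
  })
  x - min(x)
}

#' Build a named synthetic benchmark dataset
#'
#' Convenience profiles shaped like the standard network-inference
#' benchmarks: `dream4_like` (100 genes, 40 TFs, 150 edges, 210 samples),
#' `dream5_like` (1643 genes, 178 TFs, 4012 edges, 805 samples) and `tiny`
#' (20 genes, 8 TFs, 15 edges, 30 samples) for fast unit tests. The
#' generator is a minimal dependence-planting model, not a replica of the
#' kinetic simulators behind the published benchmarks: AUCs measured on
#' these fixtures validate the pipeline, not benchmark performance.
#'
#' @param profile One of `"dream4_like"`, `"dream5_like"`, `"tiny"`.
#' @param seed Integer seed (drives both network and expression draws).
#' @param noise_sd,effect_range,activation_fraction Passed to
#'   [simulate_expression()].
#' @return Object of class `synthetic_dataset`: list with `expr` (matrix),
#'   `gold` ([gold_standard()]) and `params`.
#' @export
make_benchmark_fixture <- function(profile = c("dream4_like", "dream5_like", "tiny"),
                                   seed = 1L, noise_sd = 0.3,
                                   effect_range = c(0.5, 2.0),
                                   activation_fraction = 0.7) {
  profile <- tryCatch(match.arg(profile), error = function(e) {
    stop("unknown profile ", shQuote(profile[1L]),
         "; choices: dream4_like, dream5_like, tiny", call. = FALSE)
  })
  shape <- switch(profile,
    dream4_like = list(n_genes = 100L, n_tfs = 40L, n_edges = 150L,
                       n_samples = 210L, max_in_degree = 3L),
    dream5_like = list(n_genes = 1643L, n_tfs = 178L, n_edges = 4012L,
                       n_samples = 805L, max_in_degree = 6L),
    tiny = list(n_genes = 20L, n_tfs = 8L, n_edges = 15L,
                n_samples = 30L, max_in_degree = 3L))
  gold <- generate_network(shape$n_genes, shape$n_tfs, shape$n_edges,
                           max_in_degree = shape$max_in_degree, seed = seed)
  expr <- simulate_expression(gold, shape$n_samples, noise_sd = noise_sd,
                              effect_range = effect_range,
                              activation_fraction = activation_fraction,
                              seed = seed + 1000L)
  structure(list(expr = expr, gold = gold,
                 params = c(shape, list(profile = profile, seed = seed,
                                        noise_sd = noise_sd,
                                        effect_range = effect_range,
                                        activation_fraction = activation_fraction))),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset (", x$params$profile, "): ",
      nrow(x$expr), " genes x ", ncol(x$expr), " samples, ",
      length(x$gold$tf_ids), " TFs, ", nrow(x$gold$positives),
      " planted edges\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the standard input triplet: `expression.tsv` (genes x samples,
#' header of sample ids, first column of gene ids), `tf_list.txt` (one id
#' per line) and `gold_standard.tsv` (tf, target, label 1).
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             tfs = file.path(dir, "tf_list.txt"),
             gold = file.path(dir, "gold_standard.tsv"))
  utils::write.table(
    data.frame(gene = rownames(dataset$expr), dataset$expr,
               check.names = FALSE, stringsAsFactors = FALSE),
    paths[["expression"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(dataset$gold$tf_ids, paths[["tfs"]])
  pos <- dataset$gold$positives
  utils::write.table(
    data.frame(tf = pos$tf, target = pos$target, label = 1L),
    paths[["gold"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
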