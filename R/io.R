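#' Read a gene expression matrix
#'
#' Reads a delimited expression table into a numeric matrix with genes as
#' rows and samples as columns. The expected layout is the DREAM convention:
#' one header row of sample identifiers and a first column of gene
#' identifiers; set `genes_as_rows = FALSE` if the file is transposed
#' (samples as rows).
#'
#' @param path Path to the delimited file.
#' @param genes_as_rows Logical; does the file store genes as rows (default)?
#' @param sep Field separator; tab by default, pass `","` for CSV input.
#' @param na_action What to do with missing cells: `"error"` (default)
#'   rejects the file, `"impute_mean"` replaces each missing value with its
#'   gene's mean over the remaining samples.
#' @param quiet Suppress the dimension message.
#' @return A numeric matrix, genes x samples, with unique `rownames` (gene
#'   ids) and `colnames` (sample ids).
#' @export
read_expression <- function(path, genes_as_rows = TRUE, sep = "\t",
                            na_action = c("error", "impute_mean"),
                            quiet = FALSE) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs an id column and at least one data column")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicated ", if (genes_as_rows) "gene" else "sample",
         " ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells) & cells != "" &
                 toupper(cells) != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop("non-numeric value ", shQuote(cells[i, j]), " at row id ",
         shQuote(ids[i]), ", column ", shQuote(colnames(cells)[j]))
  }
  dimnames(num) <- list(ids, colnames(cells))
  if (!genes_as_rows) num <- t(num)
  if (anyNA(num)) {
    if (na_action == "error") {
      miss <- which(is.na(num), arr.ind = TRUE)[1L, ]
      stop("missing value at gene ", shQuote(rownames(num)[miss[1L]]),
           ", sample ", shQuote(colnames(num)[miss[2L]]),
           " (use na_action = \"impute_mean\" to impute)")
    }
    for (i in which(rowSums(is.na(num)) > 0L)) {
      row <- num[i, ]
      if (all(is.na(row))) stop("gene ", shQuote(rownames(num)[i]), " is entirely missing")
      row[is.na(row)] <- mean(row, na.rm = TRUE)
      num[i, ] <- row
    }
  }
  if (!quiet) {
    message("read expression matrix: ", nrow(num), " genes x ",
            ncol(num), " samples")
  }
  num
}

#' Read a transcription-factor list
#'
#' @param path Plain-text file, one regulator gene id per line.
#' @return Character vector of unique TF ids in file order.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stop("TF list not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) stop("TF list is empty: ", path)
  if (anyDuplicated(ids)) {
    warning("duplicated TF ids dropped: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids <- unique(ids)
  }
  ids
}

#' Construct a gold standard of regulatory interactions
#'
#' A gold standard holds the declared regulator (TF) set, the experimentally
#' supported TF-to-target interactions (positives), and optionally pairs
#' known not to interact. Pairs are stored as sets: duplicated rows collapse
#' and the stored order is canonical, so loading is order-independent.
#'
#' @param tf_ids Character vector of regulator gene ids.
#' @param positives Data frame with columns `tf` and `target`.
#' @param known_negatives Optional data frame with the same columns.
#' @param genes Optional character vector naming the full gene universe the
#'   network was defined over (used by the synthetic generator).
#' @param allow_self Permit self-pairs (tf regulating itself)?
#' @return An object of class `gold_standard` with fields `tf_ids`,
#'   `positives`, `known_negatives` and `genes`.
#' @export
gold_standard <- function(tf_ids, positives, known_negatives = NULL,
                          genes = NULL, allow_self = FALSE) {
  tf_ids <- unique(as.character(tf_ids))
  positives <- canonical_pairs(positives)
  known_negatives <- if (is.null(known_negatives) || nrow(known_negatives) == 0L) {
    keys_to_pairs(character(0))
  } else {
    canonical_pairs(known_negatives)
  }
  both <- intersect(pairs_to_keys(positives), pairs_to_keys(known_negatives))
  if (length(both) > 0L) {
    stop("pairs labelled both positive and negative: ",
         paste(gsub("\t", "->", both[seq_len(min(5L, length(both)))]),
               collapse = ", "))
  }
  for (df in list(positives, known_negatives)) {
    if (nrow(df) == 0L) next
    unknown <- setdiff(unique(df$tf), tf_ids)
    if (length(unknown) > 0L) {
      stop("pair source(s) not in the TF list: ",
           paste(unknown, collapse = ", "))
    }
    if (!allow_self && any(df$tf == df$target)) {
      stop("self-pairs present (set allow_self = TRUE to permit): ",
           paste(df$tf[df$tf == df$target], collapse = ", "))
    }
  }
  structure(list(tf_ids = tf_ids, positives = positives,
                 known_negatives = known_negatives, genes = genes),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("gold_standard:", length(x$tf_ids), "TFs,", nrow(x$positives),
      "positive pairs,", nrow(x$known_negatives), "known negatives\n")
  invisible(x)
}

#' Read a gold-standard edge list
#'
#' Accepts the DREAM dialect: a headerless tab-separated file with columns
#' `(tf, target, label)` where label is 1 (interaction) or 0 (verified
#' non-interaction), or just `(tf, target)` meaning every row is a positive.
#'
#' @param path Path to the edge-list file.
#' @param tf_list_path Optional path to a TF list file; alternatively pass
#'   `tf_ids` directly.
#' @param tf_ids Character vector of regulator ids (ignored when
#'   `tf_list_path` is given). When neither is supplied the TF set is taken
#'   as the set of source ids in the file.
#' @param strict If `TRUE` (default) a pair whose source is absent from the
#'   TF list is an error; otherwise such pairs are dropped with a warning.
#' @param sep Field separator.
#' @param allow_self Permit self-pairs.
#' @return A [gold_standard()] object.
#' @export
read_gold_standard <- function(path, tf_list_path = NULL, tf_ids = NULL,
                               strict = TRUE, sep = "\t", allow_self = FALSE) {
  if (!file.exists(path)) stop("gold standard file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!ncol(tab) %in% c(2L, 3L)) {
    stop("edge list must have 2 or 3 columns, found ", ncol(tab))
  }
  if (!is.null(tf_list_path)) tf_ids <- read_tf_list(tf_list_path)
  edges <- data.frame(tf = tab[[1L]], target = tab[[2L]],
                      stringsAsFactors = FALSE)
  if (ncol(tab) == 3L) {
    lab <- tab[[3L]]
    if (!all(lab %in% c("0", "1"))) {
      stop("labels must be 0 or 1, found: ",
           paste(unique(setdiff(lab, c("0", "1"))), collapse = ", "))
    }
    lab <- as.integer(lab)
  } else {
    lab <- rep(1L, nrow(edges))
  }
  keys <- pair_key(edges$tf, edges$target)
  contradict <- unique(keys[keys %in% keys[lab == 1L] & keys %in% keys[lab == 0L]])
  if (length(contradict) > 0L) {
    stop("contradictory labels for pair(s): ",
         paste(gsub("\t", "->", contradict), collapse = ", "))
  }
  if (is.null(tf_ids)) {
    tf_ids <- unique(edges$tf)
  } else {
    unknown <- !(edges$tf %in% tf_ids)
    if (any(unknown)) {
      msg <- paste0(sum(unknown), " pair(s) reference TFs absent from the TF list: ",
                    paste(unique(edges$tf[unknown]), collapse = ", "))
      if (strict) stop(msg)
      warning(msg, "; dropping them")
      edges <- edges[!unknown, , drop = FALSE]
      lab <- lab[!unknown]
    }
  }
  gold_standard(tf_ids,
                positives = edges[lab == 1L, , drop = FALSE],
                known_negatives = edges[lab == 0L, , drop = FALSE],
                allow_self = allow_self)
}

#' Write a ranked edge list
#'
#' Writes predictions in the DREAM dialect: tab-separated `(tf, target,
#' score)`, no header, sorted by decreasing score.
#'
#' @param ranked Data frame with columns `tf`, `target`, `score`.
#' @param path Output path.
#' @param digits Number of decimal places for the score column.
#' @return `path`, invisibly.
#' @export
write_ranked_edges <- function(ranked, path, digits = 6L) {
  if (is.null(ranked) || nrow(ranked) == 0L) stop("ranked edge list is empty")
  if (!all(is.finite(ranked$score))) {
    stop("non-finite score(s) in ranked edge list")
  }
  ord <- order(ranked$score, ranked$tf, ranked$target,
               decreasing = c(TRUE, FALSE, FALSE), method = "radix")
  out <- data.frame(tf = ranked$tf[ord], target = ranked$target[ord],
                    score = sprintf(paste0("%.", digits, "f"),
                                    ranked$score[ord]),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a ranked edge list written by [write_ranked_edges()]
#'
#' @param path Path to the ranked TSV.
#' @return Data frame with columns `tf`, `target`, `score`, sorted by
#'   decreasing score.
#' @export
read_ranked_edges <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = c("character", "character", "numeric"),
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  names(tab) <- c("tf", "target", "score")
  tab[order(tab$score, decreasing = TRUE), , drop = FALSE]
}

#' Enumerate uncharacterized TF-gene pairs
#'
#' The uncharacterized (unlabelled) pair universe is every ordered pair
#' (tf, gene) with the tf in the gold standard's regulator set and the gene
#' in the gene universe, excluding self-pairs, the known positives, and any
#' known negatives. The gene universe defaults to all genes but can be
#' restricted to a target list.
#'
#' @param gold A [gold_standard()] object.
#' @param gene_ids Character vector: the gene universe (e.g. rownames of the
#'   expression matrix).
#' @param targets Optional character vector restricting the target universe.
#' @return Data frame with columns `tf`, `target`, in canonical order.
#' @export
uncharacterized_pairs <- function(gold, gene_ids, targets = NULL) {
  stopifnot(inherits(gold, "gold_standard"))
  universe <- if (is.null(targets)) gene_ids else intersect(gene_ids, targets)
  if (length(universe) == 0L) stop("empty target universe")
  all_pairs <- expand.grid(tf = gold$tf_ids, target = universe,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$tf != all_pairs$target, , drop = FALSE]
  keys <- pair_key(all_pairs$tf, all_pairs$target)
  known <- c(pairs_to_keys(gold$positives), pairs_to_keys(gold$known_negatives))
  keys_to_pairs(sort(setdiff(keys, known)))
}
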