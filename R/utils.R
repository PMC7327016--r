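# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Pairs are carried around as two-column data frames (tf, target); keys give
# them set semantics. Tab never occurs in ids read by the io layer.
pair_key <- function(tf, target) paste(tf, target, sep = "\t")

pairs_to_keys <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(character(0))
  pair_key(pairs[[1L]], pairs[[2L]])
}

keys_to_pairs <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(tf = character(0), target = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\t", fixed = TRUE)
  data.frame(tf = vapply(parts, `[[`, character(1), 1L),
             target = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

# Canonical (sorted, de-duplicated) pair data frame.
canonical_pairs <- function(pairs) {
  keys <- sort(unique(pairs_to_keys(pairs)))
  df <- keys_to_pairs(keys)
  rownames(df) <- NULL
  df
}

assert_scalar_int <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != round(x)) {
    stop("`", name, "` must be a single integer", call. = FALSE)
  }
  if (x < min || x > max) {
    stop("`", name, "` must be in [", min, ", ", max, "], got ", x,
         call. = FALSE)
  }
  as.integer(x)
}
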