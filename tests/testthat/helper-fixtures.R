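# Shared small fixtures, built once per test run.

tiny_ds <- make_benchmark_fixture("tiny", seed = 101)
tiny_cp <- cluster_samples(tiny_ds$expr, k = 8, seed = 1)
tiny_unc <- uncharacterized_pairs(tiny_ds$gold, rownames(tiny_ds$expr))
tiny_feats <- featurize_pairs(tiny_cp,
                              rbind(tiny_ds$gold$positives, tiny_unc),
                              metric = "euclidean")

# A pair data frame from two id vectors.
pairs_df <- function(tf, target) {
  data.frame(tf = tf, target = target, stringsAsFactors = FALSE)
}
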