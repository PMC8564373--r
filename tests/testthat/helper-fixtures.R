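# Shared fixtures built in code. Expensive synthetic runs are computed once
# per session and cached, so unit and acceptance checks reuse the same data.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Biased 15-bit distribution from the preset module frequencies.
biased_dist_15 <- function() {
  fixture("dist15", function() {
    build_code_distribution(gen_module_frequencies(15L, seed = 2L))
  })
}

# Biased 5-bit distribution.
biased_dist_5 <- function() {
  fixture("dist5", function() {
    build_code_distribution(gen_module_frequencies(5L, seed = 2L))
  })
}

# 200-cell labeled volume with 20% bleed-through and 5% noise, called
# end to end with automatic thresholds.
noisy_volume_run <- function() {
  fixture("noisy_volume", function() {
    vol <- gen_labeled_volume(n_cells = 200L, bleed = 0.2, noise_sd = 0.05,
                              seed = 7L)
    calls <- call_codes_from_volume(vol$volume, vol$traces, vol$mixing)
    list(truth = vol$truth, calls = calls)
  })
}

# Noiseless counterpart (smaller; the noiseless limit is deterministic).
noiseless_volume_run <- function() {
  fixture("noiseless_volume", function() {
    vol <- gen_labeled_volume(n_cells = 60L, bleed = 0.2, noise_sd = 0,
                              seed = 8L)
    calls <- call_codes_from_volume(vol$volume, vol$traces, vol$mixing)
    list(truth = vol$truth, calls = calls)
  })
}

# Arbitrary-probability toy distribution (padded with zero-probability
# codes up to the pool capacity) for oracle comparisons.
new_toy_distribution <- function(probs) {
  n_bits <- max(1L, ceiling(log2(length(probs) + 1)))
  cap <- code_capacity(n_bits)
  bits <- enumerate_codes(n_bits)
  p <- c(probs, rep(0, cap - length(probs)))
  bitbowr:::new_code_distribution(bits_to_string(bits, group_size = n_bits),
                                  p, n_bits)
}

# Large synthetic cluster table (~50,000 clusters) for parameter recovery.
recovery_cluster_table <- function() {
  fixture("recovery_clusters", function() {
    freqs <- gen_module_frequencies(5L, seed = 3L)
    clusters <- gen_cluster_table(freqs, brains = 10L,
                                  lineages_per_brain = 10000L,
                                  activation_rate = 0.5, seed = 4L)
    list(freqs = freqs, clusters = clusters)
  })
}
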