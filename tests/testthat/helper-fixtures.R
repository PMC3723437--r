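# Shared fixtures, memoized so expensive synthetic sessions are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

montage8 <- function() c("Cz", "FCz", "C1", "C2", "C3", "C4", "Fz", "Pz")

# a preprocessed full-band spectral trial set from a synthetic session
fixture_trials <- function(rho, seed, channels = montage8(),
                           kmi = "Cz", n_epochs = 20, epoch_len = 30) {
  key <- paste("trials", rho, seed, length(channels), kmi[1], n_epochs,
               epoch_len, sep = "_")
  memo(key, {
    cfg <- synth_config(channels = channels, kmi_channels = kmi,
                        erd_factor = rho, n_epochs = n_epochs,
                        epoch_len = epoch_len, seed = seed)
    preprocess_session(generate_session(cfg), seed = seed + 1000L)
  })
}

# small Monte Carlo null ensembles reused across evaluate tests
fixture_mc <- function(TI, TW, n, seed) {
  key <- paste("mc", TI, TW, n, seed, sep = "_")
  memo(key, monte_carlo(n, thresholds(TI, TW), seed = seed))
}

angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}
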