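# Referencing, filtering, artifact rejection, trial extraction, binning.

make_session <- function(samples, labels = NULL) {
  n <- ncol(samples)
  eeg_session(samples, 256, paste0("ch", seq_len(nrow(samples))),
              labels %||% rep("idle", n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("common average reference zeroes the cross-channel mean", {
  # [+5, -5] already zero-mean -> unchanged; [10, 0] -> [5, -5]
  s <- make_session(matrix(c(5, -5, 10, 0), 2))
  out <- common_average_reference(s)
  expect_equal(out$samples[, 1], c(ch1 = 5, ch2 = -5))
  expect_equal(out$samples[, 2], c(ch1 = 5, ch2 = -5))
  # random frame: column means 0 afterwards
  set.seed(1)
  r <- common_average_reference(make_session(matrix(rnorm(63 * 50), 63)))
  expect_lt(max(abs(colMeans(r$samples))), 1e-12)
  expect_error(common_average_reference(make_session(matrix(1:10, 1))),
               "2 retained")
})

test_that("band-pass keeps 10 Hz within 1 dB, kills 60 Hz by 40 dB and DC", {
  t <- seq(1 / 256, 30, by = 1 / 256)
  s <- make_session(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 60 * t),
                          rep(100, length(t))))
  out <- bandpass(s)
  mid <- 2000:5500                    # away from filter edges
  g10 <- 20 * log10(sd(out$samples[1, mid]) / sd(s$samples[1, mid]))
  g60 <- 20 * log10(sd(out$samples[2, mid]) / sd(s$samples[2, mid]))
  expect_lt(abs(g10), 1)
  expect_lt(g60, -40)
  expect_lt(abs(mean(out$samples[3, ])), 1e-6)
  expect_error(bandpass(s, lo = 50, hi = 40), "corner")
  expect_error(bandpass(s, lo = 0, hi = 200), "corner")
})

test_that("artifact rejection removes exactly the injected channels", {
  ses <- memo("artifact_session", {
    cfg <- synth_config(channels = montage8(), kmi_channels = "Cz",
                        erd_factor = 0.4, artifact_channels = c("C4", "Pz"),
                        seed = 3)
    bandpass(generate_session(cfg))
  })
  rej <- reject_artifact_channels(ses)
  expect_setequal(rej$rejected, c("C4", "Pz"))
  expect_false(any(c("C4", "Pz") %in%
                     rej$session$channels[rej$session$retained]))
  # z_max = Inf never rejects
  expect_length(reject_artifact_channels(ses, z_max = Inf)$rejected, 0)
})

test_that("a clean session yields an empty rejection list", {
  ses <- bandpass(generate_session(synth_config(seed = 21)))  # 63 channels
  expect_length(reject_artifact_channels(ses)$rejected, 0)
})

test_that("trial extraction yields 100 balanced trials that respect boundaries", {
  s <- memo("session_rho0.5_seed7", generate_session(
    synth_config(channels = montage8(), erd_factor = 0.5,
                 kmi_channels = "Cz", seed = 7)))
  tr <- extract_trials(s, seed = 42)
  expect_length(tr$windows, 100)
  expect_equal(as.vector(table(tr$labels)), c(50, 50))
  expect_true(all(vapply(tr$windows, ncol, 1L) == 1024))
  # windows never straddle a label boundary
  seg <- rep(seq_len(20), each = 30 * 256)
  expect_true(all(seg[tr$starts] == seg[tr$starts + 1023]))
  # determinism
  expect_identical(extract_trials(s, seed = 42)$starts, tr$starts)
})

test_that("zero-slack segments force the unique tiling; short ones are skipped", {
  cfg <- synth_config(channels = montage8(), epoch_len = 20, n_epochs = 4,
                      seed = 9)
  s <- generate_session(cfg)
  tr <- extract_trials(s, seed = 1)
  # 20-s segments tile exactly: offsets 0, 4, ..., 16 s in each segment
  rel <- (tr$starts - 1) %% (20 * 256)
  expect_equal(rel, rep(seq(0, 16, by = 4) * 256, 4))
  # segment below 5 x 4 s is skipped with a warning naming it
  set.seed(2)
  labs <- rep(c("idle", "walk", "idle"), c(15, 30, 30) * 256)
  short <- eeg_session(matrix(rnorm(2 * length(labs)), 2), 256,
                       c("Cz", "Pz"), labs)
  expect_warning(tr2 <- extract_trials(short, seed = 1), "segment 1")
  expect_length(tr2$windows, 10L)
  # nothing usable at all is an error
  tiny <- eeg_session(matrix(rnorm(2 * 10 * 256), 2), 256, c("Cz", "Pz"),
                      rep("idle", 10 * 256))
  expect_error(suppressWarnings(extract_trials(tiny)), "no usable")
})

test_that("spectral bins integrate the periodogram into half-open 2-Hz bins", {
  t <- seq(1 / 256, 4, by = 1 / 256)
  tone <- sin(2 * pi * 10 * t)
  d <- spectral_bins(tone, 256, c(0, 40))
  expect_equal(nrow(d), 20)
  expect_equal(rownames(d)[which.max(d)], "10-12Hz")
  expect_lt(1 - max(d) / sum(d), 0.01)        # leakage < 1% (on-grid tone)
  expect_equal(max(d), 0.5, tolerance = 1e-10) # unit amplitude -> power 1/2
  expect_equal(nrow(spectral_bins(tone, 256, c(8, 16))), 4)
  expect_error(spectral_bins(tone, 256, c(0, 80)), "band")
  expect_error(spectral_bins(tone, 256, c(3, 7)), "band")
  expect_error(spectral_bins(tone[1:100], 256), "0.5 s")
})

test_that("binned power obeys Parseval over the pass band", {
  set.seed(4)
  x <- rnorm(1024)
  # ideal band limitation: zero DC and everything at/above 40 Hz
  X <- fft(x)
  f <- pmin(0:1023, 1024 - 0:1023) * 256 / 1024
  X[f >= 40 | f == 0] <- 0
  xf <- Re(fft(X, inverse = TRUE)) / 1024
  d <- spectral_bins(xf, 256, c(0, 40))
  expect_equal(sum(d), mean(xf^2), tolerance = 1e-10)
})

test_that("the pipeline is equivariant under channel relabeling", {
  s <- memo("session_rho0.5_seed7", generate_session(
    synth_config(channels = montage8(), erd_factor = 0.5,
                 kmi_channels = "Cz", seed = 7)))
  w <- s$samples[, 1:1024]
  d <- spectral_bins(w, 256)
  perm <- c(3, 1, 2, 5, 4, 8, 7, 6)
  dp <- spectral_bins(w[perm, ], 256)
  expect_equal(dp, d[, perm], ignore_attr = TRUE)
  expect_equal(colnames(dp), colnames(d)[perm])
})
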