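# Sliding windows, posterior smoothing, hysteresis transitions,
# threshold calibration, and the online decoding path.

test_that("stream windows are 0.75 s at 2 Hz with 0.25-s overlap", {
  x <- matrix(seq_len(2560), 1)              # 10 s at 256 Hz
  sw <- stream_windows(x, 256)
  expect_length(sw$windows, 19)              # first block emits no window
  expect_true(all(vapply(sw$windows, ncol, 1L) == 192))
  expect_equal(sw$times, seq(1, 10, by = 0.5))
  # consecutive windows share exactly 0.25 s = 64 samples
  expect_equal(sw$windows[[2]][, 1:64, drop = FALSE],
               sw$windows[[1]][, 129:192, drop = FALSE])
  # under 2 blocks there is no window
  expect_length(stream_windows(matrix(1:200, 1), 256)$windows, 0)
})

test_that("posterior smoothing averages the three most recent ticks", {
  expect_equal(smooth_posteriors(c(0.2, 0.4, 0.9)), 0.5)
  expect_equal(smooth_posteriors(rep(0.7, 50)), 0.7)
  expect_equal(smooth_posteriors(c(0.1, 0.1, 0.1, 0.95)),
               mean(c(0.1, 0.1, 0.95)))
  expect_equal(smooth_posteriors(c(0.3, 0.5)), 0.4)  # warm-up
})

test_that("state transitions follow the hysteresis rules, holding on equality", {
  th <- thresholds(0.4, 0.9)
  expect_equal(update_state("idle", 0.95, th), "walk")
  expect_equal(update_state("walk", 0.5, th), "walk")
  expect_equal(update_state("walk", 0.39, th), "idle")
  expect_equal(update_state("idle", 0.9, th), "idle")   # equality holds
  expect_equal(update_state("walk", 0.4, th), "walk")
  expect_error(thresholds(0.9, 0.4), "TI <= TW")
})

test_that("the vectorized trajectory equals tick-by-tick updates", {
  set.seed(3)
  p <- runif(500)
  th <- thresholds(0.3, 0.7)
  vec <- bciwalk:::hysteresis_states(p, th, warmup = 3)
  st <- "idle"
  seqw <- logical(500)
  for (i in seq_along(p)) {
    pb <- smooth_posteriors(p[seq_len(i)])
    st <- if (i <= 3) "idle" else update_state(st, pb, th)
    seqw[i] <- st == "walk"
  }
  expect_identical(vec, seqw)
})

test_that("a balanced threshold splits a uniform stream evenly", {
  set.seed(2)
  w <- bciwalk:::hysteresis_states(runif(1e4), thresholds(0.5, 0.5))
  expect_lt(abs(mean(w) - 0.5), 0.05)
})

test_that("threshold calibration takes class-conditional medians", {
  st <- posterior_stream(rep(c(0.2, 0.6, 0.9, 0.1, 0.2, 0.3), each = 10),
                         state = rep(rep(c("walk", "idle"), each = 30)))
  th <- calibrate_thresholds(st)
  expect_equal(th$TW, 0.6)
  expect_equal(th$TI, 0.2)
  # beta emissions land near the analytic medians
  sch <- data.frame(state = rep(c("idle", "walk"), 3), duration = 20)
  stb <- generate_posterior_stream(sch, rate = 2, seed = 5)
  thb <- calibrate_thresholds(stb)
  expect_lt(abs(thb$TI - qbeta(0.5, 2, 8)), 0.1)
  expect_lt(abs(thb$TW - qbeta(0.5, 8, 2)), 0.1)
  # inverted medians fail with a diagnostic
  bad <- posterior_stream(rep(c(0.9, 0.1), each = 20),
                          state = rep(c("idle", "walk"), each = 20))
  expect_error(calibrate_thresholds(bad), "inverted")
  expect_error(calibrate_thresholds(posterior_stream(runif(20))), "state")
})

test_that("the reference threshold table has valid hysteresis pairs with the documented averages", {
  rt <- reference_thresholds()
  expect_equal(nrow(rt), 25)
  expect_true(all(rt$TI <= rt$TW))           # every pair is a valid hysteresis
  expect_lt(abs(mean(rt$TI) - 0.40), 0.02)
  expect_lt(abs(mean(rt$TW) - 0.62), 0.02)
})

test_that("one model serves offline trials and the online stream alike", {
  tr <- fixture_trials(rho = 0.3, seed = 4)
  m <- fit_decoding_model(tr, c(8, 16), "LDA")
  cal <- generate_session(synth_config(channels = montage8(),
                                       kmi_channels = "Cz",
                                       erd_factor = 0.3, epoch_len = 20,
                                       n_epochs = 6, seed = 8))
  calf <- common_average_reference(bandpass(cal))
  st <- decode_stream(calf, m, filter = FALSE)
  # path consistency: decode_stream == stream_windows + spectral_bins +
  # posterior_walk on the same filtered, referenced samples
  ci <- match(m$channels, calf$channels)
  sw <- stream_windows(calf$samples[ci, , drop = FALSE], calf$rate)
  p_manual <- vapply(sw$windows[1:5], function(w)
    posterior_walk(m, spectral_bins(w, calf$rate, m$band)), numeric(1))
  expect_equal(st$p[1:5], p_manual)
  # the decoded stream separates the two intents
  expect_lt(median(st$p[st$state == "idle"]),
            median(st$p[st$state == "walk"]))
  th <- calibrate_thresholds(st)
  expect_s3_class(th, "thresholds")
})
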