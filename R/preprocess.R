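# From a labeled EEG session to the binned spectral trial set:
# band-pass filter -> iterative artifact-channel rejection -> common average
# reference -> 5 random non-overlapping 4-s trials per ~30-s segment ->
# one-shot periodogram integrated in 2-Hz bins.

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across retained
#' channels from each retained channel.
#'
#' @param session an [eeg_session()].
#' @return the re-referenced session.
#' @export
common_average_reference <- function(session) {
  stopifnot(inherits(session, "eeg_session"))
  idx <- which(session$retained)
  if (length(idx) < 2) stop("need at least 2 retained channels", call. = FALSE)
  m <- colMeans(session$samples[idx, , drop = FALSE])
  session$samples[idx, ] <- sweep(session$samples[idx, , drop = FALSE], 2, m)
  session
}

#' Zero-phase band-pass filter
#'
#' Butterworth high-pass (2nd order at `lo`) and low-pass (6th order at
#' `hi`) applied forward-backward ([signal::filtfilt()]) to every channel.
#' The zero-phase cascade passes 10 Hz within 1 dB and attenuates 60 Hz by
#' more than 40 dB at the default corners.
#'
#' @param session an [eeg_session()].
#' @param lo,hi corner frequencies in Hz, `0 <= lo < hi < rate/2`.
#' @return the filtered session (all channels, retained or not).
#' @export
bandpass <- function(session, lo = 0.01, hi = 40) {
  stopifnot(inherits(session, "eeg_session"))
  nyq <- session$rate / 2
  if (!(lo >= 0 && lo < hi && hi < nyq)) {
    stop("invalid corner frequencies: need 0 <= lo < hi < rate/2",
         call. = FALSE)
  }
  lp <- signal::butter(6, hi / nyq, type = "low")
  hp <- if (lo > 0) signal::butter(2, lo / nyq, type = "high") else NULL
  for (i in seq_len(nrow(session$samples))) {
    # demean first: the sample mean is the DC component the high-pass is
    # meant to remove, and subtracting it avoids the corner's long
    # (~1/lo s) edge transient on finite records
    x <- session$samples[i, ] - mean(session$samples[i, ])
    x <- signal::filtfilt(lp, x)
    if (!is.null(hp)) x <- signal::filtfilt(hp, x)
    session$samples[i, ] <- x
  }
  attr(session, "band") <- c(lo, hi)
  session
}

#' Iterative artifact channel rejection
#'
#' Removes channels with excessive electromyogram-like artifacts. The
#' per-channel amplitude statistic is a high quantile (default 99.9th
#' percentile) of the absolute amplitude over the session; a channel is an
#' outlier when its statistic exceeds `median + z_max * 1.4826 * MAD`
#' across currently retained channels (robust z-score). Flagged channels
#' are dropped and the rule re-applied until no channel qualifies or
#' `max_iter` is reached. A high quantile rather than the plain maximum is
#' used because the session maximum of a clean channel is extreme-value
#' distributed with a tail heavy enough that some clean channels of a full
#' montage would almost always be flagged; the quantile statistic
#' concentrates tightly while intermittent high-amplitude bursts still
#' dominate it.
#'
#' @param session an [eeg_session()] (ideally band-pass filtered first).
#' @param z_max robust z-score threshold; `Inf` disables rejection.
#' @param max_iter maximum number of rejection passes.
#' @param amp_quantile quantile of |amplitude| used as the channel
#'   statistic (1 = session maximum).
#' @return list with elements `session` (updated retained mask) and
#'   `rejected` (character vector of rejected channel labels, in order).
#' @export
reject_artifact_channels <- function(session, z_max = 3, max_iter = 10,
                                     amp_quantile = 0.999) {
  stopifnot(inherits(session, "eeg_session"))
  if (sum(session$retained) < 3) {
    stop("need at least 3 retained channels", call. = FALSE)
  }
  rejected <- character(0)
  for (it in seq_len(max_iter)) {
    idx <- which(session$retained)
    stat <- apply(abs(session$samples[idx, , drop = FALSE]), 1,
                  stats::quantile, probs = amp_quantile, names = FALSE)
    med <- stats::median(stat)
    mad_raw <- stats::median(abs(stat - med))
    if (mad_raw == 0) break  # no spread -> no outliers
    out <- stat > med + z_max * 1.4826 * mad_raw
    if (!any(out)) break
    if (sum(session$retained) - sum(out) < 2) {
      stop("artifact rejection would leave fewer than 2 channels; ",
           "data quality insufficient", call. = FALSE)
    }
    rejected <- c(rejected, session$channels[idx[out]])
    session$retained[idx[out]] <- FALSE
  }
  list(session = session, rejected = rejected)
}

#' Extract randomly placed non-overlapping trials from labeled segments
#'
#' Splits the session at label boundaries into ~30-s segments and places,
#' within each segment, `trials_per_segment` non-overlapping windows of
#' `trial_len` seconds uniformly at random (sorted-uniform spacings over the
#' slack, so a zero-slack segment yields the unique tiling). Remaining data
#' in each segment are discarded. Segments shorter than
#' `trials_per_segment * trial_len` are skipped with a warning naming the
#' segment; windows never straddle a label boundary.
#'
#' @param session an [eeg_session()] (referenced and filtered).
#' @param trials_per_segment trials per segment.
#' @param trial_len trial duration, seconds.
#' @param seed RNG seed for the placement.
#' @return object of class `trial_set`: list with `windows` (list of
#'   retained-channels x samples matrices), `labels`, `starts` (sample index
#'   of each window), `channels`, `rate`, `seed`.
#' @export
extract_trials <- function(session, trials_per_segment = 5, trial_len = 4,
                           seed = NULL) {
  stopifnot(inherits(session, "eeg_session"))
  len <- round(trial_len * session$rate)
  need <- trials_per_segment * len
  runs <- rle(as.character(session$labels))
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  chans <- which(session$retained)
  windows <- list(); labels <- character(0); w_starts <- integer(0)
  with_seed(seed, {
    for (si in seq_along(runs$lengths)) {
      L <- runs$lengths[si]
      if (L < need) {
        warning(sprintf(
          "segment %d (%s, %.1f s) shorter than %d x %g s; skipped",
          si, runs$values[si], L / session$rate, trials_per_segment,
          trial_len), call. = FALSE)
        next
      }
      slack <- L - need
      offs <- sort(floor(stats::runif(trials_per_segment) * (slack + 1)))
      offs <- pmin(offs, slack)
      w0 <- starts[si] + offs + (seq_len(trials_per_segment) - 1L) * len
      for (w in w0) {
        windows[[length(windows) + 1L]] <-
          session$samples[chans, w:(w + len - 1L), drop = FALSE]
        labels <- c(labels, runs$values[si])
        w_starts <- c(w_starts, w)
      }
    }
  })
  if (!length(windows)) stop("no usable segments", call. = FALSE)
  structure(list(windows = windows,
                 labels = factor(labels, levels = c("idle", "walk")),
                 starts = w_starts,
                 channels = session$channels[chans],
                 rate = session$rate, seed = seed),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials (%s), %d channels at %g Hz\n",
              length(x$windows),
              paste(sprintf("%d %s", table(x$labels), names(table(x$labels))),
                    collapse = " / "),
              length(x$channels), x$rate))
  if (!is.null(x$d)) {
    be <- attr(x, "bin_edges")
    cat(sprintf("  spectra: %d bins of 2 Hz over %g-%g Hz\n",
                nrow(x$d[[1]]), min(be), max(be)))
  }
  invisible(x)
}

#' Integrated 2-Hz band power of one trial window
#'
#' One-shot periodogram (rectangular window, one-sided) of each channel,
#' integrated by summing the power of FFT points whose frequency falls in
#' each half-open 2-Hz bin `[k, k+2)`. DC is excluded. Works for any window
#' length >= 0.5 s, including the 0.75-s online windows whose native
#' resolution is 4/3 Hz.
#'
#' @param window channels x samples numeric matrix (or a vector for one
#'   channel).
#' @param rate sampling rate, Hz.
#' @param band frequency interval in Hz; edges must be multiples of 2 within
#'   `[0, 40]`.
#' @return B x C matrix of integrated power (microvolt^2), B = bins,
#'   C = channels, with `bin_edges` attribute.
#' @export
spectral_bins <- function(window, rate, band = c(0, 40)) {
  if (is.null(dim(window))) window <- matrix(window, nrow = 1)
  L <- ncol(window)
  if (L < 0.5 * rate) stop("window shorter than 0.5 s", call. = FALSE)
  if (length(band) != 2 || band[1] >= band[2] || band[1] < 0 ||
      band[2] > 40 || any(band %% 2 != 0)) {
    stop("band edges must be multiples of 2 Hz within [0, 40]", call. = FALSE)
  }
  X <- stats::mvfft(t(window))              # L x C
  half <- floor(L / 2)
  k <- seq_len(half)                        # exclude DC
  f <- k * rate / L
  pw <- (2 / L^2) * abs(X[k + 1L, , drop = FALSE])^2
  if (L %% 2 == 0) pw[half, ] <- pw[half, ] / 2   # Nyquist is not doubled
  edges <- seq(band[1], band[2], by = 2)
  bin <- findInterval(f, edges, left.open = FALSE, rightmost.closed = FALSE)
  keep <- f >= band[1] & f < band[2]
  B <- length(edges) - 1L
  d <- matrix(0, B, ncol(pw))
  if (any(keep)) {
    g <- factor(bin[keep], levels = seq_len(B))
    d[] <- apply(pw[keep, , drop = FALSE], 2,
                 function(col) tapply(col, g, sum, default = 0))
  }
  rownames(d) <- sprintf("%g-%gHz", edges[-length(edges)], edges[-1])
  if (!is.null(rownames(window))) colnames(d) <- rownames(window)
  attr(d, "bin_edges") <- edges
  d
}

#' Attach binned spectra to a trial set
#'
#' Applies [spectral_bins()] to every time-domain trial window, yielding the
#' B x C single-trial matrices the decoder consumes.
#'
#' @param trials a `trial_set` from [extract_trials()].
#' @param band frequency interval (Hz), 2-Hz-aligned.
#' @return the trial set with a `d` element (list of B x C matrices) and a
#'   `bin_edges` attribute.
#' @export
spectral_trial_set <- function(trials, band = c(0, 40)) {
  stopifnot(inherits(trials, "trial_set"))
  trials$d <- lapply(trials$windows, spectral_bins, rate = trials$rate,
                     band = band)
  attr(trials, "bin_edges") <- attr(trials$d[[1]], "bin_edges")
  trials
}

#' Full offline preprocessing pipeline
#'
#' Band-pass filter, artifact-channel rejection, common average reference
#' over the retained channels, trial extraction, and spectral binning over
#' the full 0-40 Hz range.
#'
#' @param session a raw [eeg_session()].
#' @param seed RNG seed for trial placement.
#' @param z_max rejection threshold (see [reject_artifact_channels()]).
#' @param lo,hi band-pass corners, Hz.
#' @return a spectral `trial_set`; rejected channel labels are stored in the
#'   `rejected` attribute.
#' @export
preprocess_session <- function(session, seed = NULL, z_max = 3,
                               lo = 0.01, hi = 40) {
  session <- bandpass(session, lo, hi)
  rej <- reject_artifact_channels(session, z_max = z_max)
  session <- common_average_reference(rej$session)
  trials <- extract_trials(session, seed = seed)
  trials <- spectral_trial_set(trials, band = c(0, 40))
  attr(trials, "rejected") <- rej$rejected
  trials
}
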