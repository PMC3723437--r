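# Synthetic EEG sessions and posterior streams.
#
# The generator emulates the training recordings the decoder is built from:
# alternating 30-s epochs of idling and walking kinesthetic motor imagery
# (KMI) over a 10-min session, where walking KMI attenuates a narrow-band
# (default 8-16 Hz) sensorimotor rhythm over mid-frontal/central channels
# (event-related desynchronization, ERD) on top of 1/f background noise.

#' Extended 10-20 montage labels
#'
#' A 63-channel extended international 10-20 montage. Shorter montages take
#' the first `n` labels; tests and examples typically use a small central
#' subset passed explicitly.
#'
#' @param n number of channels (<= 63).
#' @return character vector of channel labels.
#' @export
eeg_montage <- function(n = 63) {
  labs <- c(
    "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "TP9", "TP10"
  )
  stopifnot(n >= 1, n <= length(labs))
  # Keep the default KMI channels (Cz, FCz, C1, C2) in any montage of >= 4.
  if (n < length(labs)) {
    kmi <- c("Cz", "FCz", "C1", "C2")
    if (n >= length(kmi)) {
      rest <- setdiff(labs, kmi)
      return(c(kmi, rest[seq_len(n - length(kmi))]))
    }
    return(labs[seq_len(n)])
  }
  labs
}

#' Configuration of the synthetic EEG session generator
#'
#' @param channels channel labels (extended 10-20 names).
#' @param rate sampling rate in Hz.
#' @param epoch_len epoch duration in seconds.
#' @param n_epochs number of epochs; they strictly alternate idle, walk,
#'   idle, ... starting with idle.
#' @param kmi_channels channels carrying the sensorimotor rhythm whose power
#'   is attenuated during walking-KMI epochs.
#' @param rhythm_band frequency interval (Hz) of the rhythm.
#' @param erd_factor rho in `[0, 1]`: amplitude attenuation applied to the
#'   rhythm during walk epochs, so walk-epoch band power is `rho^2` times
#'   idle-epoch band power in expectation. `rho = 1` means no effect.
#' @param noise_exponent slope alpha of the 1/f^alpha background noise.
#' @param noise_rms background noise RMS per channel, microvolts.
#' @param rhythm_rms rhythm RMS on KMI channels during idling, microvolts.
#' @param artifact_channels channels carrying high-amplitude EMG-like bursts.
#' @param artifact_amplitude burst peak amplitude as a multiple of
#'   `noise_rms` (>= 10 so rejection ground truth is unambiguous).
#' @param seed RNG seed; a fixed seed gives a bit-identical session.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(channels = eeg_montage(63),
                         rate = 256,
                         epoch_len = 30,
                         n_epochs = 20,
                         kmi_channels = c("Cz", "FCz", "C1", "C2"),
                         rhythm_band = c(8, 16),
                         erd_factor = 0.5,
                         noise_exponent = 1,
                         noise_rms = 10,
                         rhythm_rms = 20,
                         artifact_channels = character(),
                         artifact_amplitude = 15,
                         seed = 1L) {
  stopifnot(rate > 0, epoch_len > 0, n_epochs >= 1,
            length(rhythm_band) == 2, rhythm_band[1] < rhythm_band[2])
  if (erd_factor < 0 || erd_factor > 1) {
    stop("erd_factor must lie in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(c(kmi_channels, artifact_channels), channels)
  if (length(bad)) {
    stop("unknown channel label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    channels = channels, rate = rate, epoch_len = epoch_len,
    n_epochs = n_epochs, kmi_channels = kmi_channels,
    rhythm_band = rhythm_band, erd_factor = erd_factor,
    noise_exponent = noise_exponent, noise_rms = noise_rms,
    rhythm_rms = rhythm_rms, artifact_channels = artifact_channels,
    artifact_amplitude = artifact_amplitude, seed = seed
  ), class = "synth_config")
}

#' Labeled multichannel EEG recording
#'
#' @param samples channels x time numeric matrix, microvolts.
#' @param rate sampling rate, Hz.
#' @param channels channel labels (length = nrow(samples)).
#' @param labels per-sample state, factor with levels `idle`, `walk`.
#' @param retained per-channel logical mask (post artifact rejection).
#' @return object of class `eeg_session`.
#' @export
eeg_session <- function(samples, rate, channels, labels,
                        retained = rep(TRUE, nrow(samples))) {
  samples <- as.matrix(samples)
  labels <- factor(labels, levels = c("idle", "walk"))
  stopifnot(ncol(samples) == length(labels),
            nrow(samples) == length(channels),
            length(retained) == nrow(samples), rate > 0)
  rownames(samples) <- channels
  structure(list(samples = samples, rate = rate, channels = channels,
                 labels = labels, retained = retained),
            class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("<eeg_session> %d channels x %d samples (%.1f s at %g Hz), %d retained\n",
              nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$rate,
              x$rate, sum(x$retained)))
  invisible(x)
}

# 1/f^alpha Gaussian noise via spectral shaping, unit RMS. The amplitude
# response is flat below 1 Hz (a low-frequency shoulder) so total power is
# finite without modeling drifts the 0.01-Hz high-pass would remove anyway.
pink_noise <- function(n, rate, alpha = 1) {
  x <- stats::rnorm(n)
  if (alpha == 0) return(x)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * rate / n
  w <- pmax(f, 1)^(-alpha / 2)
  w[1] <- 0
  y <- Re(stats::fft(X * w, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Band-limited Gaussian noise (ideal FFT brick-wall), unit RMS.
narrowband_noise <- function(n, rate, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * rate / n
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Raised-cosine smoothing of a per-sample envelope over `ramp_s` seconds,
# avoiding discontinuities (hence FFT leakage) at epoch boundaries.
smooth_envelope <- function(env, rate, ramp_s = 0.5) {
  k <- max(1L, round(ramp_s * rate))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(k) / (k + 1)))
  w <- w / sum(w)
  sm <- stats::filter(env, w, sides = 2)
  sm <- as.numeric(sm)
  # fill filter edges with the nearest defined value
  idx <- which(!is.na(sm))
  sm[seq_len(idx[1] - 1)] <- sm[idx[1]]
  sm[seq((idx[length(idx)] + 1), length.out = length(sm) - idx[length(idx)])] <-
    sm[idx[length(idx)]]
  sm
}

#' Generate a synthetic labeled EEG session
#'
#' Draws per-channel 1/f^alpha background noise plus an independent
#' band-limited sensorimotor rhythm on every channel; on the KMI channels
#' the rhythm amplitude is modulated by the idle/walk schedule (attenuated
#' by `erd_factor` during walk epochs, with 0.5-s raised-cosine ramps at
#' epoch boundaries), while elsewhere it is stationary, keeping channel
#' amplitudes homogeneous. Optionally adds 22-Hz tone bursts on artifact
#' channels. Deterministic under the seed in `cfg`.
#'
#' @param cfg a [synth_config()].
#' @return an [eeg_session()].
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n_ep <- cfg$n_epochs
    len <- round(cfg$epoch_len * cfg$rate)
    n <- n_ep * len
    ep_lab <- rep(c("idle", "walk"), length.out = n_ep)
    labels <- rep(ep_lab, each = len)

    base_env <- ifelse(labels == "walk", cfg$erd_factor, 1)
    env <- smooth_envelope(base_env, cfg$rate)

    C <- length(cfg$channels)
    samples <- matrix(0, C, n, dimnames = list(cfg$channels, NULL))
    for (ci in seq_len(C)) {
      ch <- cfg$channels[ci]
      x <- cfg$noise_rms * pink_noise(n, cfg$rate, cfg$noise_exponent)
      # every channel carries an independent stationary rhythm (as real EEG
      # does), so channel amplitudes are homogeneous and amplitude-based
      # artifact rejection has unambiguous ground truth; only the KMI
      # channels are ERD-modulated by the idle/walk schedule
      rhythm <- cfg$rhythm_rms * narrowband_noise(n, cfg$rate,
                                                  cfg$rhythm_band)
      x <- x + if (ch %in% cfg$kmi_channels) rhythm * env else rhythm
      if (ch %in% cfg$artifact_channels) {
        x <- x + burst_train(n, cfg$rate,
                             peak = cfg$artifact_amplitude * cfg$noise_rms)
      }
      samples[ci, ] <- x
    }
    eeg_session(samples, cfg$rate, cfg$channels, labels)
  })
}

# Intermittent 0.5-s raised-cosine-windowed 22-Hz tone bursts, one burst per
# ~10 s on average (~5% duty cycle). The 22-Hz carrier survives the 40-Hz
# low-pass, so rejection operates on the filtered amplitudes it will see.
burst_train <- function(n, rate, peak, burst_s = 0.5, period_s = 10) {
  x <- numeric(n)
  blen <- round(burst_s * rate)
  n_bursts <- max(1L, round(n / (period_s * rate)))
  starts <- sort(sample.int(max(1L, n - blen), n_bursts))
  tt <- seq_len(blen) / rate
  win <- 0.5 * (1 - cos(2 * pi * seq_len(blen) / (blen + 1)))
  carrier <- sin(2 * pi * 22 * tt + stats::runif(1, 0, 2 * pi))
  for (s in starts) {
    idx <- s:(s + blen - 1)
    x[idx] <- x[idx] + peak * win * carrier
  }
  x
}

#' Generate a labeled stream of walking posterior probabilities
#'
#' Emulates the 2-Hz online pipeline output for controller and calibration
#' tests: at each tick the posterior P(W|f*) is an i.i.d. draw from the
#' emission distribution of the state active at that time.
#'
#' @param schedule data.frame with columns `state` (`"idle"`/`"walk"`) and
#'   `duration` (seconds, > 0), in temporal order.
#' @param emission named list mapping each state to `c(shape1, shape2)` of a
#'   Beta distribution; `c(1, 1)` reproduces the uniform random-walk null.
#' @param rate tick rate, Hz (2 = two posterior updates per second).
#' @param seed RNG seed.
#' @return object of class `posterior_stream`: data.frame with columns
#'   `time`, `p`, `state` and attribute `rate`.
#' @export
generate_posterior_stream <- function(schedule,
                                      emission = list(idle = c(2, 8),
                                                      walk = c(8, 2)),
                                      rate = 2, seed = NULL) {
  stopifnot(is.data.frame(schedule), all(c("state", "duration") %in%
                                           names(schedule)))
  if (any(schedule$duration <= 0)) stop("durations must be > 0", call. = FALSE)
  for (st in unique(schedule$state)) {
    pars <- emission[[st]]
    if (is.null(pars) || length(pars) != 2 || any(!is.finite(pars)) ||
        any(pars <= 0)) {
      stop("invalid beta parameters for state '", st, "'", call. = FALSE)
    }
  }
  with_seed(seed, {
    state <- rep(schedule$state, times = round(schedule$duration * rate))
    p <- numeric(length(state))
    for (st in unique(schedule$state)) {
      idx <- which(state == st)
      pars <- emission[[st]]
      p[idx] <- stats::rbeta(length(idx), pars[1], pars[2])
    }
    posterior_stream(p, rate = rate, state = state)
  })
}

#' Construct a posterior stream object
#'
#' @param p posterior probabilities P(W|f*) per tick.
#' @param rate tick rate in Hz.
#' @param state optional per-tick generating/true state labels.
#' @param time optional tick times (s); defaults to `1:n / rate`.
#' @return a `posterior_stream` data.frame.
#' @export
posterior_stream <- function(p, rate = 2, state = NULL, time = NULL) {
  stopifnot_prob(p, "posterior probabilities")
  out <- data.frame(time = time %||% (seq_along(p) / rate), p = p)
  if (!is.null(state)) out$state <- state
  attr(out, "rate") <- rate
  class(out) <- c("posterior_stream", "data.frame")
  out
}
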