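# Simulated-online pipeline: sliding 0.75-s analysis windows at two blocks
# per second, 1.5-s posterior averaging, median-based threshold calibration
# and the binary idle/walk hysteresis state machine.

#' Hysteresis threshold pair
#'
#' `TW` initiates avatar ambulation, `TI` stops it; `TI <= TW` makes the
#' state machine sticky (hysteresis).
#'
#' @param TI,TW probabilities with `0 <= TI <= TW <= 1`.
#' @return object of class `thresholds`.
#' @export
thresholds <- function(TI, TW) {
  stopifnot_prob(c(TI, TW), "thresholds")
  if (TI > TW) stop("need TI <= TW (hysteresis)", call. = FALSE)
  structure(list(TI = TI, TW = TW), class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("<thresholds> TI = %.3g, TW = %.3g\n", x$TI, x$TW))
  invisible(x)
}

#' Slice a continuous EEG stream into online analysis windows
#'
#' Data arrive in 0.5-s blocks at two blocks per second; each analysis
#' window is the most recent block plus the trailing half of the previous
#' block (0.75 s = 192 samples at 256 Hz). The first block has no history
#' and emits no window.
#'
#' @param samples channels x time matrix (or an [eeg_session()]).
#' @param rate sampling rate in Hz (taken from the session if given).
#' @param block block duration, seconds.
#' @param history extra trailing history, seconds.
#' @return list with `windows` (list of channels x samples matrices) and
#'   `times` (window end times, seconds).
#' @export
stream_windows <- function(samples, rate = 256, block = 0.5,
                           history = 0.25) {
  if (inherits(samples, "eeg_session")) {
    rate <- samples$rate
    samples <- samples$samples
  }
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  bs <- round(block * rate)
  hs <- round(history * rate)
  n_blocks <- floor(ncol(samples) / bs)
  if (n_blocks < 2) {
    return(list(windows = list(), times = numeric(0)))
  }
  ks <- 2:n_blocks
  windows <- lapply(ks, function(k) {
    samples[, ((k - 1) * bs - hs + 1):(k * bs), drop = FALSE]
  })
  list(windows = windows, times = ks * block)
}

#' Average the most recent posterior probabilities
#'
#' Arithmetic mean of the `span * rate` most recent posteriors (three ticks
#' for the default 1.5 s at 2 Hz). During warm-up, fewer than three ticks
#' are averaged as-is.
#'
#' @param p numeric vector of posteriors, most recent last.
#' @param span smoothing span in seconds.
#' @param rate tick rate, Hz.
#' @return the smoothed posterior (scalar).
#' @export
smooth_posteriors <- function(p, span = 1.5, rate = 2) {
  k <- max(1L, round(span * rate))
  mean(utils::tail(p, k))
}

#' One step of the binary hysteresis state machine
#'
#' Idle switches to Walk only when the smoothed posterior strictly exceeds
#' `TW`; Walk switches to Idle only when it falls strictly below `TI`;
#' otherwise (including equality) the current state is held.
#'
#' @param state `"idle"` or `"walk"`.
#' @param pbar smoothed posterior of walking.
#' @param th a [thresholds()] pair.
#' @return the next state.
#' @export
update_state <- function(state, pbar, th) {
  stopifnot(state %in% c("idle", "walk"))
  if (state == "idle" && pbar > th$TW) return("walk")
  if (state == "walk" && pbar < th$TI) return("idle")
  state
}

# Vectorized trajectory of the state machine over a whole posterior stream:
# smoothing, then "the most recent threshold crossing decides the state".
# Events during the first `warmup` ticks are ignored (the controller starts,
# and stays, idle until the smoother has full history). Returns logical
# `walk` per tick. Equivalent to iterating update_state(); see tests.
hysteresis_states <- function(p, th, warmup = 3L, span_ticks = 3L) {
  pbar <- rolling_mean(p, span_ticks)
  e <- integer(length(p))
  e[pbar > th$TW] <- 1L
  e[pbar < th$TI] <- -1L
  if (warmup > 0L) e[seq_len(min(warmup, length(e)))] <- 0L
  idx <- seq_along(e)
  last <- cummax(ifelse(e != 0L, idx, 0L))
  state <- ifelse(last == 0L, -1L, e[pmax(last, 1L)])
  state == 1L
}

#' Calibrate hysteresis thresholds from a labeled posterior stream
#'
#' Initial thresholds are the class-conditional medians of the walking
#' posterior: `TW = median P(W|f* in W)`, `TI = median P(W|f* in I)`. If the
#' idle median exceeds the walk median the classes are inverted or unusable
#' and calibration fails. Manual post-calibration adjustment is a deliberate
#' config override, never automatic.
#'
#' @param stream a `posterior_stream` with a `state` column, at least 10
#'   ticks per state.
#' @return a [thresholds()] pair.
#' @export
calibrate_thresholds <- function(stream) {
  stopifnot(inherits(stream, "posterior_stream"))
  if (is.null(stream$state)) stop("stream has no state labels", call. = FALSE)
  n_i <- sum(stream$state == "idle")
  n_w <- sum(stream$state == "walk")
  if (n_i < 10 || n_w < 10) {
    stop("need at least 10 ticks of each state for calibration",
         call. = FALSE)
  }
  TI <- stats::median(stream$p[stream$state == "idle"])
  TW <- stats::median(stream$p[stream$state == "walk"])
  if (TI > TW) {
    stop(sprintf(paste0(
      "calibration failed: idle median (%.3f) exceeds walk median (%.3f); ",
      "posterior classes are inverted or inseparable"), TI, TW),
      call. = FALSE)
  }
  thresholds(TI, TW)
}

#' Decode a continuous EEG stream into a posterior stream
#'
#' The online analog of the offline path, served by the same fitted model:
#' band-pass filter, common average reference over all incoming channels
#' (the real-time order), selection of the model's retained channels,
#' 0.75-s windows at 2 Hz, periodogram power integrated over the model's
#' 2-Hz bins (points assigned to bins by frequency, no interpolation), and
#' the model posterior per window.
#'
#' @param session an [eeg_session()] carrying the streamed data; its labels
#'   (state at each window's end time) are attached to the output when
#'   available.
#' @param model a fitted `decoding_model`.
#' @param filter band-pass filter first (set `FALSE` if already filtered).
#' @return a `posterior_stream` at 2 Hz.
#' @export
decode_stream <- function(session, model, filter = TRUE) {
  stopifnot(inherits(session, "eeg_session"),
            inherits(model, "decoding_model"))
  if (filter) session <- bandpass(session)
  session <- common_average_reference(session)
  ci <- match(model$channels, session$channels)
  if (anyNA(ci)) stop("stream lacks model channels", call. = FALSE)
  sw <- stream_windows(session$samples[ci, , drop = FALSE], session$rate)
  p <- vapply(sw$windows, function(w) {
    d <- spectral_bins(w, session$rate, band = model$band)
    posterior_walk(model, d)
  }, numeric(1))
  state <- NULL
  if (!is.null(session$labels)) {
    samp <- pmin(round(sw$times * session$rate), length(session$labels))
    state <- as.character(session$labels[samp])
  }
  posterior_stream(p, rate = 2, state = state, time = sw$times)
}
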