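# End-to-end workflow and file plumbing: synthesize -> preprocess -> train
# -> calibrate -> simulated online sessions -> Monte Carlo null ->
# certification, all hanging off one master seed. Sessions, models and
# reports interchange as plain CSV/TSV/JSON.

#' Run the whole pipeline end to end
#'
#' Mirrors one experimental day: generate a training session, preprocess it
#' into 100 spectral trials, fit the decoding model with frequency-band and
#' method selection, calibrate hysteresis thresholds on a short alternating
#' calibration run decoded by the same model, simulate online sessions with
#' a closed-loop user whose posteriors are resampled from the calibration
#' distributions, build the random-walk null, and certify purposefulness.
#' Deterministic under `config$seed`.
#'
#' @param config nested list of overrides (or a path to a YAML file with
#'   the same structure): `seed`; `synth` (arguments of [synth_config()]);
#'   `train` (`runs`, `folds`, `variance_kept`, `restarts`); `calibration`
#'   (`epoch_len`, `n_epochs`); `thresholds` (explicit `TI`/`TW` override);
#'   `adjust` (`TI_min`, `TW_max` post-calibration bounds); `sessions`
#'   (count); `mc_n` (null ensemble size); `task` (arguments of
#'   [task_config()]).
#' @param out optional path; the report (without bulky traces) is written
#'   there as JSON.
#' @return list with the fitted model summary, thresholds, per-session
#'   verdict table, Monte Carlo summary and every seed used.
#' @export
run_end_to_end <- function(config = list(), out = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "synth", "train", "calibration", "thresholds",
             "adjust", "sessions", "mc_n", "task")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  seed <- config$seed %||% 1L
  seeds <- derive_seeds(seed, 6)
  n_sessions <- config$sessions %||% 5L
  mc_n <- config$mc_n %||% 1000L
  task <- do.call(task_config, config$task %||% list())

  # -- training session -> spectral trials -> decoding model
  syn_args <- config$synth %||% list()
  if (is.null(syn_args$channels) && is.null(syn_args$n_channels)) {
    syn_args$channels <- eeg_montage(24)
  }
  if (!is.null(syn_args$n_channels)) {
    syn_args$channels <- eeg_montage(syn_args$n_channels)
    syn_args$n_channels <- NULL
  }
  syn_args$seed <- seeds[1]
  cfg <- do.call(synth_config, syn_args)
  session <- generate_session(cfg)
  trials <- preprocess_session(session, seed = seeds[2])
  tr <- config$train %||% list()
  model <- search_frequency_band(
    trials, seed = seeds[3],
    runs = tr$runs %||% 10, folds = tr$folds %||% 10,
    variance_kept = tr$variance_kept %||% 0.9,
    restarts = tr$restarts %||% 4)

  # -- ~2-min alternating calibration run decoded by the fitted model
  cal <- config$calibration %||% list()
  cal_cfg <- synth_config(
    channels = cfg$channels, rate = cfg$rate,
    epoch_len = cal$epoch_len %||% 20, n_epochs = cal$n_epochs %||% 6,
    kmi_channels = cfg$kmi_channels, rhythm_band = cfg$rhythm_band,
    erd_factor = cfg$erd_factor, noise_exponent = cfg$noise_exponent,
    noise_rms = cfg$noise_rms, rhythm_rms = cfg$rhythm_rms,
    seed = seeds[4])
  cal_stream <- decode_stream(generate_session(cal_cfg), model)
  # post-calibration adjustment (the operator's manual step, as explicit
  # config): a perfectly confident classifier drives the class-conditional
  # medians to exactly 0/1, where the strict transition rules can never
  # fire; the bounds pull the thresholds into usable territory. A full
  # `thresholds` override wins and replaces calibration entirely (e.g. for
  # chance-level models whose medians may be inverted).
  if (!is.null(config$thresholds)) {
    th <- thresholds(config$thresholds$TI, config$thresholds$TW)
  } else {
    th <- calibrate_thresholds(cal_stream)
    adj <- config$adjust %||% list()
    tw_max <- adj$TW_max %||% 0.98
    ti_min <- adj$TI_min %||% 0.02
    tw <- min(th$TW, tw_max)
    th <- thresholds(min(max(th$TI, ti_min), tw), tw)
  }

  # -- simulated online sessions: closed-loop user resampling the
  #    calibration posterior pools of the intended state
  pool_idle <- cal_stream$p[cal_stream$state == "idle"]
  pool_walk <- cal_stream$p[cal_stream$state == "walk"]
  sess_seeds <- derive_seeds(seeds[5], n_sessions)
  sessions <- lapply(seq_len(n_sessions), function(i) {
    with_seed(sess_seeds[i], {
      ctrl <- function(ctx) {
        wants_walk <- !(ctx$in_zone && ctx$target_points < 1)
        pool <- if (wants_walk) pool_walk else pool_idle
        pool[sample.int(length(pool), 1)]
      }
      run_session(controller = ctrl, thresholds = th, cfg = task)
    })
  })

  # -- null ensemble and certification
  mc <- monte_carlo(mc_n, th, task, seed = seeds[6])
  pdf <- fit_parzen_pdf(mc, support = list(
    s = c(0, task$n_npcs), t = c(0, task$time_limit)))
  verdicts <- certify_purposeful(sessions, pdf)

  report <- list(
    package_version = as.character(utils::packageVersion("bciwalk")),
    master_seed = seed,
    stage_seeds = stats::setNames(as.list(seeds),
                                  c("synth", "trials", "train",
                                    "calibration", "sessions", "monte_carlo")),
    rejected_channels = attr(trials, "rejected"),
    model = list(band = model$band, method = model$method,
                 cv_accuracy = unname(model$cv_accuracy["mean"]),
                 cv_sd = unname(model$cv_accuracy["sd"]),
                 p_value = model$p_value, significant = model$significant),
    thresholds = list(TI = th$TI, TW = th$TW),
    sessions = verdicts,
    first_purposeful = attr(verdicts, "first_purposeful"),
    random_walk = as.list(attr(mc, "summary")))
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  report
}

# ---- interchange formats ---------------------------------------------------

#' Write / read an EEG session as CSV + events TSV
#'
#' The sample matrix goes to `file` as a plain CSV (one column per channel,
#' one row per sample); the idle/walk schedule goes to `events_file` as a
#' BIDS-style TSV with columns `onset`, `duration`, `trial_type`. The
#' sampling rate is stored in a `# rate:` header comment of the CSV.
#'
#' @param session an [eeg_session()].
#' @param file CSV path for the samples.
#' @param events_file TSV path for the label events; defaults to
#'   `file` with an `_events.tsv` suffix.
#' @return `file`, invisibly.
#' @export
write_session <- function(session, file,
                          events_file = sub("\\.csv$", "_events.tsv", file)) {
  stopifnot(inherits(session, "eeg_session"))
  con <- file(file, "w")
  writeLines(sprintf("# rate: %g", session$rate), con)
  utils::write.csv(as.data.frame(t(session$samples)), con,
                   row.names = FALSE)
  close(con)
  runs <- rle(as.character(session$labels))
  ends <- cumsum(runs$lengths)
  ev <- data.frame(
    onset = c(0, utils::head(ends, -1)) / session$rate,
    duration = runs$lengths / session$rate,
    trial_type = runs$values)
  utils::write.table(ev, events_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_session
#' @export
read_session <- function(file,
                         events_file = sub("\\.csv$", "_events.tsv", file)) {
  first <- readLines(file, n = 1)
  rate <- as.numeric(sub("# rate: *", "", first))
  dat <- utils::read.csv(file, comment.char = "#", check.names = FALSE)
  ev <- utils::read.table(events_file, sep = "\t", header = TRUE)
  labels <- rep(ev$trial_type, times = round(ev$duration * rate))
  eeg_session(t(as.matrix(dat)), rate, colnames(dat), labels)
}

#' Write / read hysteresis thresholds as JSON
#'
#' @param th a [thresholds()] pair.
#' @param file JSON path (`{"TI": x, "TW": y}`).
#' @return `file` invisibly / a [thresholds()] object.
#' @export
write_thresholds <- function(th, file) {
  stopifnot(inherits(th, "thresholds"))
  jsonlite::write_json(list(TI = th$TI, TW = th$TW), file,
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(file) {
  x <- jsonlite::read_json(file)
  thresholds(x$TI, x$TW)
}

#' Reference calibration thresholds
#'
#' A reference table of 25 hysteresis threshold pairs (5 participants over
#' 5 experimental days) shipped with the package for cross-checking the
#' calibration conventions; their group averages are TI = 0.40, TW = 0.62.
#'
#' @return data.frame with columns `participant`, `day`, `TI`, `TW`.
#' @export
reference_thresholds <- function() {
  utils::read.csv(system.file("extdata", "reference_thresholds.csv",
                              package = "bciwalk"))
}
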