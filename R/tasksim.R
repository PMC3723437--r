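# Stand-in for the virtual environment: a 1-D course with 10 NPC stops.
# The avatar advances at constant speed while the state machine is in Walk;
# contiguous idle dwell inside a 2-body-length stop zone converts to
# (fractional) stop points; the session ends when the last NPC is resolved
# or at the 20-min limit. Random-walk Monte Carlo ensembles provide the
# null distribution of (stops, completion time).

#' Virtual course and scoring configuration
#'
#' Geometry is calibrated so the ideal run reproduces the reference timing:
#' body length = 1 unit, walking speed = 1 unit/s, NPCs every 19.1 units, so
#' walking the full course takes 191 s and a perfect run with ten 2-s stops
#' takes 211 s.
#'
#' @param n_npcs number of NPC stops.
#' @param npc_spacing distance between consecutive NPCs, body lengths.
#' @param stop_radius half-width of a stop zone, body lengths.
#' @param walk_speed avatar speed while walking, body lengths per second.
#' @param dwell_full dwell time earning a full point, seconds.
#' @param dwell_min dwell time below which no point is earned, seconds.
#' @param time_limit session cap, seconds (20 min).
#' @param tick controller period, seconds (two updates per second).
#' @param warmup number of initial ticks forced to Idle while the posterior
#'   smoother fills its history.
#' @param dwell_rule `"ramp"`: points rise linearly from 0 at `dwell_min` to
#'   1 at `dwell_full` (continuous at both ends); `"proportional"`:
#'   `dwell / dwell_full`, the alternative reading.
#' @return object of class `task_config`.
#' @export
task_config <- function(n_npcs = 10, npc_spacing = 19.1, stop_radius = 2,
                        walk_speed = 1, dwell_full = 2, dwell_min = 0.5,
                        time_limit = 1200, tick = 0.5, warmup = 3L,
                        dwell_rule = c("ramp", "proportional")) {
  stopifnot(n_npcs >= 1, npc_spacing > 0, stop_radius > 0, walk_speed > 0,
            dwell_min < dwell_full, time_limit > 0, tick > 0)
  structure(list(
    n_npcs = n_npcs, npc_spacing = npc_spacing, stop_radius = stop_radius,
    walk_speed = walk_speed, dwell_full = dwell_full, dwell_min = dwell_min,
    time_limit = time_limit, tick = tick, warmup = as.integer(warmup),
    dwell_rule = match.arg(dwell_rule),
    npc_positions = npc_spacing * seq_len(n_npcs),
    total_walk_time = npc_spacing * n_npcs / walk_speed
  ), class = "task_config")
}

#' Convert a dwell duration into stop points
#'
#' One point for dwelling at least `dwell_full` seconds, nothing below
#' `dwell_min`, and a linearly increasing fraction in between (or the
#' proportional variant, see [task_config()]).
#'
#' @param dwell dwell duration(s), seconds.
#' @param cfg a [task_config()].
#' @return points in `[0, 1]`, vectorized.
#' @export
score_dwell <- function(dwell, cfg = task_config()) {
  stopifnot(all(dwell >= 0))
  if (cfg$dwell_rule == "ramp") {
    pts <- (dwell - cfg$dwell_min) / (cfg$dwell_full - cfg$dwell_min)
  } else {
    pts <- dwell / cfg$dwell_full
  }
  pts[dwell < cfg$dwell_min] <- 0
  pmin(pmax(pts, 0), 1)
}

#' Ideal (oracle) controller state schedule
#'
#' Walks to each NPC in turn, idles exactly `dwell_full` seconds inside its
#' stop zone, and resumes; optionally skips listed stops. Used as the
#' ground-truth upper bound of the course geometry.
#'
#' @param cfg a [task_config()].
#' @param skip integer indices of NPCs to walk past without stopping.
#' @return logical vector, `TRUE` = walk tick.
#' @export
oracle_states <- function(cfg = task_config(), skip = integer(0)) {
  step <- cfg$walk_speed * cfg$tick
  dwell_ticks <- ceiling(cfg$dwell_full / cfg$tick)
  states <- logical(0)
  pos <- 0
  for (k in seq_len(cfg$n_npcs)) {
    npc <- cfg$npc_positions[k]
    n_walk <- ceiling(max(0, npc - pos) / step - 1e-9)
    states <- c(states, rep(TRUE, n_walk))
    pos <- pos + n_walk * step
    if (!(k %in% skip)) states <- c(states, rep(FALSE, dwell_ticks))
  }
  if (cfg$n_npcs %in% skip) {
    # resolve the last NPC by exiting its zone
    n_walk <- ceiling(cfg$stop_radius / step + 1e-9)
    states <- c(states, rep(TRUE, n_walk))
  }
  states
}

#' Random-walk posterior source
#'
#' Uniform(0, 1) posterior draws per tick; fed through the same smoothing
#' and state-transition rules as real sessions, this is the null controller
#' of the Monte Carlo control experiments. With a seed, replay is
#' deterministic.
#'
#' @param seed RNG seed, or `NULL`.
#' @return function of `n` returning `n` posterior draws.
#' @export
random_walk_controller <- function(seed = NULL) {
  function(n) with_seed(seed, stats::runif(n))
}

# Score a full state trajectory. states: logical walk per tick (may be
# shorter than the cap, e.g. oracle schedules). Returns the session result.
score_states <- function(states, cfg) {
  n_max <- ceiling(cfg$time_limit / cfg$tick)
  n <- min(length(states), n_max)
  states <- states[seq_len(n)]
  step <- cfg$walk_speed * cfg$tick
  pos <- cumsum(states) * step
  r <- cfg$stop_radius
  need <- ceiling(cfg$dwell_full / cfg$tick)

  resolve_last <- Inf
  dwell <- numeric(cfg$n_npcs)
  dwell_at <- function(upto) {
    dw <- numeric(cfg$n_npcs)
    for (k in seq_len(cfg$n_npcs)) {
      npc <- cfg$npc_positions[k]
      i1 <- findInterval(npc - r - 1e-9, pos[seq_len(upto)]) + 1L
      i2 <- findInterval(npc + r + 1e-9, pos[seq_len(upto)])
      if (i1 > i2) next
      idle <- !states[i1:i2]
      if (!any(idle)) next
      rl <- rle(idle)
      dw[k] <- max(rl$lengths[rl$values]) * cfg$tick
    }
    dw
  }

  # resolution tick of the last NPC: zone exit, or contiguous dwell >= full
  npc_last <- cfg$npc_positions[cfg$n_npcs]
  exit_tick <- match(TRUE, pos > npc_last + r + 1e-9)
  done_tick <- NA_integer_
  i1 <- findInterval(npc_last - r - 1e-9, pos) + 1L
  i2 <- findInterval(npc_last + r + 1e-9, pos)
  if (i1 <= i2) {
    idle <- !states[i1:i2]
    rl <- rle(idle)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    ok <- which(rl$values & rl$lengths >= need)
    if (length(ok)) done_tick <- i1 - 1L + starts[ok[1]] + need - 1L
  }
  end_tick <- suppressWarnings(min(exit_tick, done_tick, na.rm = TRUE))

  if (is.finite(end_tick) && end_tick <= n_max) {
    finished <- TRUE
    t_done <- end_tick * cfg$tick
    dwell <- dwell_at(end_tick)
    trace_n <- end_tick
  } else {
    finished <- FALSE
    t_done <- cfg$time_limit
    dwell <- dwell_at(n)
    trace_n <- n
  }
  pts <- score_dwell(dwell, cfg)
  structure(list(
    s = sum(pts), t = t_done, finished = finished,
    per_npc_dwell = dwell, per_npc_points = pts,
    state_trace = data.frame(
      time = seq_len(trace_n) * cfg$tick,
      state = ifelse(states[seq_len(trace_n)], "walk", "idle"),
      position = pos[seq_len(trace_n)])
  ), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %.2f stops in %g s (%s)\n", x$s, x$t,
              if (x$finished) "finished" else "time limit reached"))
  invisible(x)
}

#' Simulate one online session on the virtual course
#'
#' Drives the avatar from a per-tick posterior source through 1.5-s
#' smoothing and the hysteresis state machine (or directly from a supplied
#' state schedule). A Walk tick advances the avatar by
#' `walk_speed * tick`; contiguous idle time inside a stop zone accumulates
#' dwell (re-entries are impossible on the monotone course, and the best
#' single contiguous interval counts). The session ends when the last NPC
#' is resolved - its zone exited forward or a full dwell achieved - or at
#' the time limit, in which case the score so far is kept.
#'
#' @param posteriors numeric vector of per-tick posteriors, a function of
#'   `n` returning one (e.g. [random_walk_controller()]), or `NULL` when
#'   `states` or `controller` is given.
#' @param thresholds a [thresholds()] pair (required with posteriors).
#' @param cfg a [task_config()].
#' @param states optional logical walk/idle schedule overriding the state
#'   machine (e.g. [oracle_states()]).
#' @param controller optional closed-loop controller
#'   `function(ctx) -> posterior`, called every tick with a context list
#'   (`tick`, `time`, `state`, `position`, `target`, `in_zone`,
#'   `target_dwell`, `target_points`).
#' @param seed RNG seed (applies to a `posteriors` function).
#' @return a `session_result` with stop score `s`, completion time `t`,
#'   `finished`, per-NPC dwell and the (time, state, position) trace.
#' @export
run_session <- function(posteriors = NULL, thresholds = NULL,
                        cfg = task_config(), states = NULL,
                        controller = NULL, seed = NULL) {
  n_max <- ceiling(cfg$time_limit / cfg$tick)
  if (!is.null(states)) {
    return(score_states(as.logical(states), cfg))
  }
  if (!is.null(controller)) {
    return(run_session_closed_loop(controller, thresholds, cfg))
  }
  if (is.function(posteriors)) {
    posteriors <- with_seed(seed, posteriors(n_max))
  }
  stopifnot(is.numeric(posteriors), !is.null(thresholds))
  stopifnot_prob(posteriors, "posteriors")
  p <- posteriors[seq_len(min(length(posteriors), n_max))]
  score_states(hysteresis_states(p, thresholds, warmup = cfg$warmup), cfg)
}

# Sequential closed-loop variant: the controller sees the live task state
# (avatar position, current target, accumulated dwell) and emits the next
# posterior; smoothing and transitions are identical to the open-loop path.
run_session_closed_loop <- function(controller, th, cfg) {
  n_max <- ceiling(cfg$time_limit / cfg$tick)
  step <- cfg$walk_speed * cfg$tick
  r <- cfg$stop_radius
  p_hist <- numeric(0)
  state <- "idle"
  pos <- 0
  states <- logical(n_max)
  target <- 1L
  run_dwell <- 0
  best_pts <- numeric(cfg$n_npcs)
  end_tick <- n_max
  finished <- FALSE
  for (i in seq_len(n_max)) {
    in_zone <- target <= cfg$n_npcs &&
      abs(pos - cfg$npc_positions[target]) <= r
    ctx <- list(tick = i, time = i * cfg$tick, state = state, position = pos,
                target = target, in_zone = in_zone,
                target_dwell = run_dwell,
                target_points = if (target <= cfg$n_npcs)
                  best_pts[target] else NA_real_)
    pnew <- controller(ctx)
    p_hist <- c(p_hist, pnew)
    pbar <- smooth_posteriors(p_hist)
    state <- if (i <= cfg$warmup) "idle" else update_state(state, pbar, th)
    states[i] <- state == "walk"
    if (state == "walk") {
      pos <- pos + step
      run_dwell <- 0
    } else if (target <= cfg$n_npcs &&
               abs(pos - cfg$npc_positions[target]) <= r) {
      run_dwell <- run_dwell + cfg$tick
      best_pts[target] <- max(best_pts[target], score_dwell(run_dwell, cfg))
    }
    # advance the target past resolved NPCs
    while (target <= cfg$n_npcs &&
           (pos > cfg$npc_positions[target] + r ||
            run_dwell >= cfg$dwell_full)) {
      target <- target + 1L
      run_dwell <- 0
      if (target > cfg$n_npcs) { finished <- TRUE; end_tick <- i }
    }
    if (finished) break
  }
  score_states(states[seq_len(end_tick)], cfg)
}

#' Random-walk Monte Carlo ensemble
#'
#' Runs `n` independent random-walk sessions (uniform posteriors through the
#' same smoothing and state machine) and logs stop score and completion
#' time, with the time limit enforced as in real sessions.
#'
#' @param n number of runs.
#' @param thresholds a [thresholds()] pair.
#' @param cfg a [task_config()].
#' @param seed master seed; each run uses a derived child seed.
#' @return object of class `mc_ensemble`: data.frame with columns `run`,
#'   `stops`, `time`, `finished`, plus a `summary` attribute (mean and sd of
#'   both measures).
#' @export
monte_carlo <- function(n = 1000, thresholds, cfg = task_config(),
                        seed = NULL) {
  stopifnot(n >= 1)
  seeds <- derive_seeds(seed, n)
  n_max <- ceiling(cfg$time_limit / cfg$tick)
  res <- vapply(seq_len(n), function(i) {
    p <- with_seed(seeds[i], stats::runif(n_max))
    sr <- score_states(hysteresis_states(p, thresholds, warmup = cfg$warmup),
                       cfg)
    c(sr$s, sr$t, as.numeric(sr$finished))
  }, numeric(3))
  out <- data.frame(run = seq_len(n), stops = res[1, ], time = res[2, ],
                    finished = res[3, ] > 0)
  attr(out, "summary") <- c(
    stops_mean = mean(out$stops), stops_sd = stats::sd(out$stops),
    time_mean = mean(out$time), time_sd = stats::sd(out$time))
  attr(out, "thresholds") <- thresholds
  class(out) <- c("mc_ensemble", "data.frame")
  out
}

#' @export
print.mc_ensemble <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "<mc_ensemble> %d random-walk runs: %.2f +/- %.2f stops, %.0f +/- %.0f s (%d finished)\n",
    nrow(x), s["stops_mean"], s["stops_sd"], s["time_mean"], s["time_sd"],
    sum(x$finished)))
  invisible(x)
}
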