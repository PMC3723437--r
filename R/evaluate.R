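# Statistical certification of purposeful control: a Parzen-Rosenblatt
# (kernel density) estimate of the 2-D random-walk performance distribution
# over (stops, completion time), the constant-density-contour p-value, the
# composite score, and the purposefulness verdict.

#' Fit a Parzen-Rosenblatt 2-D performance density
#'
#' Product-Gaussian kernel density over (stop score, completion time) with
#' per-dimension Silverman bandwidths and floors to handle degenerate capped
#' ensembles (e.g. every run at the time limit).
#'
#' @param ensemble an `mc_ensemble` from [monte_carlo()], or a data.frame
#'   with columns `stops` and `time`.
#' @param bw optional bandwidths `c(h_s, h_t)`, overriding Silverman.
#' @param bw_floor bandwidth floors `c(stops, seconds)`.
#' @param support list with numeric ranges `s` and `t` over which the
#'   density is defined (and renormalized after boundary truncation).
#' @param grid grid resolution `c(n_s, n_t)` for integration.
#' @return object of class `performance_pdf`.
#' @export
fit_parzen_pdf <- function(ensemble, bw = NULL, bw_floor = c(0.25, 5),
                           support = list(s = c(0, 10), t = c(0, 1200)),
                           grid = c(201, 601)) {
  stopifnot(all(c("stops", "time") %in% names(ensemble)))
  s <- ensemble$stops
  t <- ensemble$time
  n <- length(s)
  if (n < 10) stop("need an ensemble of at least 10 runs", call. = FALSE)
  silverman <- function(x) {
    spread <- min(stats::sd(x), stats::IQR(x) / 1.349)
    0.9 * spread * length(x)^(-1 / 5)
  }
  if (is.null(bw)) bw <- c(silverman(s), silverman(t))
  low <- !is.finite(bw) | bw < bw_floor
  if (any(low)) {
    message("degenerate ensemble dimension(s); bandwidth floor applied")
    bw[low] <- bw_floor[low]
  }
  structure(list(s = s, t = t, n = n, bw = bw, support = support,
                 grid = grid, cache = new.env(parent = emptyenv())),
            class = "performance_pdf",
            thresholds = attr(ensemble, "thresholds"))
}

#' Evaluate the fitted performance density
#'
#' @param pdf a `performance_pdf`.
#' @param s,t coordinates (vectorized, recycled).
#' @param renormalized divide by the mass inside the support (so the density
#'   integrates to 1 over the support).
#' @return density values.
#' @export
parzen_density <- function(pdf, s, t, renormalized = FALSE) {
  stopifnot(inherits(pdf, "performance_pdf"))
  k <- mapply(function(si, ti) {
    mean(stats::dnorm(si, pdf$s, pdf$bw[1]) *
           stats::dnorm(ti, pdf$t, pdf$bw[2]))
  }, s, t)
  if (renormalized) k <- k / parzen_grid(pdf)$Z
  k
}

# Cached grid evaluation: density on a tensor grid over the support,
# trapezoidal weights, and total mass Z for boundary renormalization.
parzen_grid <- function(pdf) {
  cache <- pdf$cache
  if (!is.null(cache$grid)) return(cache$grid)
  gs <- seq(pdf$support$s[1], pdf$support$s[2], length.out = pdf$grid[1])
  gt <- seq(pdf$support$t[1], pdf$support$t[2], length.out = pdf$grid[2])
  A <- outer(gs, pdf$s, function(a, b) stats::dnorm(a, b, pdf$bw[1]))
  B <- outer(gt, pdf$t, function(a, b) stats::dnorm(a, b, pdf$bw[2]))
  F <- (A %*% t(B)) / pdf$n                   # n_s x n_t density values
  trap <- function(g) {
    w <- diff(g)
    c(w, 0) / 2 + c(0, w) / 2
  }
  W <- outer(trap(gs), trap(gt))
  Z <- sum(F * W)
  cache$grid <- list(gs = gs, gt = gt, F = F, W = W, Z = Z)
  cache$grid
}

#' Constant-density-contour p-value of an observed performance
#'
#' Draws the constant-value density contour through the observed
#' (stops, time) point and returns the fraction of the probability mass
#' lying outside that contour, i.e. the integral of the density over the
#' region where it is below its value at the observation (trapezoidal grid
#' integration, boundary-truncation renormalized). Small p means the
#' observation sits far outside the bulk of the random-walk distribution.
#'
#' @param pdf a `performance_pdf` fitted to the null ensemble.
#' @param s,t observed stop score and completion time (scalars).
#' @return p-value in `[0, 1]`.
#' @export
purposefulness_pvalue <- function(pdf, s, t) {
  stopifnot(inherits(pdf, "performance_pdf"), length(s) == 1,
            length(t) == 1)
  cl_s <- min(max(s, pdf$support$s[1]), pdf$support$s[2])
  cl_t <- min(max(t, pdf$support$t[1]), pdf$support$t[2])
  if (cl_s != s || cl_t != t) {
    warning("observation outside the density support; clamped to the edge",
            call. = FALSE)
  }
  g <- parzen_grid(pdf)
  f_obs <- parzen_density(pdf, cl_s, cl_t)
  sum(g$W * g$F * (g$F < f_obs)) / g$Z
}

#' Composite performance score
#'
#' Geometric mean of the normalized stop score and normalized completion
#' time, in percent: `c_s = s / s_max`,
#' `c_t = (t_max - t) / (t_max - t_min)`, `c = sqrt(c_s * c_t)`. A perfect
#' run (all stops, minimum time) scores 100%; completion times below
#' `t_min` clamp `c_t` to 100%. The geometric mean favors balanced
#' performances over sacrificing one measure for the other.
#'
#' @param s number of successful stops (vectorized).
#' @param t completion time, seconds (vectorized).
#' @param s_max maximum stop score.
#' @param t_max maximum allowed time, seconds.
#' @param t_min minimum time to complete the course with all stops, seconds
#'   (a configured constant of the reference course, kept as given).
#' @return data.frame with columns `c_s`, `c_t`, `c`, all in percent.
#' @export
composite_score <- function(s, t, s_max = 10, t_max = 1200,
                            t_min = 201.52) {
  stopifnot(all(s >= 0), all(s <= s_max), all(t > 0), all(t <= t_max))
  c_s <- s / s_max
  c_t <- pmin((t_max - pmax(t, t_min)) / (t_max - t_min), 1)
  data.frame(c_s = 100 * c_s, c_t = 100 * c_t,
             c = 100 * sqrt(c_s * c_t))
}

#' Certify purposeful control of online sessions
#'
#' A session is purposeful when it finishes within the time limit and its
#' (stops, time) point differs from the random-walk null at `p < alpha`.
#' The verdict table also reports the first purposeful session (control is
#' deemed attained once a single session is purposeful).
#'
#' @param results list of `session_result`s, or a data.frame with columns
#'   `stops`, `time`, `finished`.
#' @param pdf a `performance_pdf` of the matching random-walk ensemble; if
#'   both carry `thresholds` attributes they must agree.
#' @param alpha significance level.
#' @return data.frame with per-session `stops`, `time`, `c_s`, `c_t`, `c`,
#'   `p`, `purposeful`; the index of the first purposeful session is in the
#'   `first_purposeful` attribute (NA when none).
#' @export
certify_purposeful <- function(results, pdf, alpha = 0.01) {
  stopifnot(inherits(pdf, "performance_pdf"))
  if (inherits(results, "session_result")) results <- list(results)
  if (is.data.frame(results)) {
    df <- results
  } else {
    df <- data.frame(
      stops = vapply(results, `[[`, numeric(1), "s"),
      time = vapply(results, `[[`, numeric(1), "t"),
      finished = vapply(results, `[[`, logical(1), "finished"))
  }
  th_pdf <- attr(pdf, "thresholds")
  th_res <- attr(results, "thresholds")
  if (!is.null(th_pdf) && !is.null(th_res) &&
      !isTRUE(all.equal(unclass(th_pdf), unclass(th_res)))) {
    stop("null ensemble and sessions use different thresholds", call. = FALSE)
  }
  cs <- composite_score(df$stops, df$time)
  p <- vapply(seq_len(nrow(df)), function(i)
    purposefulness_pvalue(pdf, df$stops[i], df$time[i]), numeric(1))
  out <- cbind(df, cs, p = p,
               purposeful = df$finished & p < alpha)
  attr(out, "first_purposeful") <-
    if (any(out$purposeful)) which(out$purposeful)[1] else NA_integer_
  out
}
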