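# Participant-specific decoding model: classwise PCA (CPCA) piecewise
# subspaces, a 1-D discriminant transform (Fisher LDA or approximate
# information discriminant analysis, AIDA), and a linear Bayesian classifier
# with pooled variance in the 1-D feature domain. Model selection runs a
# greedy contiguous frequency-band search under 10x10 stratified
# cross-validation and picks LDA or AIDA by CV accuracy.

# ---- CPCA ------------------------------------------------------------------

#' Fit classwise principal component subspaces
#'
#' One PCA subspace per class on the vectorized B x C trials, retaining the
#' smallest number of leading components explaining at least `variance_kept`
#' of that class's variance. Maps are orthonormal.
#'
#' @param x n x D matrix of vectorized trials (rows = trials).
#' @param labels factor with levels `idle`, `walk`.
#' @param variance_kept fraction of per-class variance to retain.
#' @return list with one element per class: `mean` (D), `basis` (D x m_k).
#' @export
fit_cpca <- function(x, labels, variance_kept = 0.9) {
  labels <- factor(labels, levels = c("idle", "walk"))
  stopifnot(nrow(x) == length(labels), all(table(labels) >= 2))
  lapply(stats::setNames(levels(labels), levels(labels)), function(cl) {
    xi <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(xi)
    xc <- sweep(xi, 2, mu)
    sv <- svd(xc, nu = 0)
    ev <- sv$d^2
    pos <- ev > max(ev) * 1e-12
    if (!any(pos)) stop("rank-deficient class '", cl, "': no variance",
                        call. = FALSE)
    ev <- ev[pos]
    m <- which(cumsum(ev) / sum(ev) >= variance_kept - 1e-12)[1]
    list(mean = mu, basis = sv$v[, seq_len(m), drop = FALSE])
  })
}

# ---- 1-D discriminant transforms ------------------------------------------

aida_objective <- function(t, St, Sk, priors) {
  qt <- drop(t %*% St %*% t)
  if (qt <= 0) return(-Inf)
  val <- log(qt)
  for (k in seq_along(Sk)) {
    qk <- drop(t %*% Sk[[k]] %*% t)
    if (qk <= 0) return(-Inf)
    val <- val - priors[k] * log(qk)
  }
  val / 2
}

aida_gradient <- function(t, St, Sk, priors) {
  g <- drop(St %*% t) / drop(t %*% St %*% t)
  for (k in seq_along(Sk)) {
    g <- g - priors[k] * drop(Sk[[k]] %*% t) / drop(t %*% Sk[[k]] %*% t)
  }
  g / 2
}

#' Fit a unit-norm 1-D discriminant transform
#'
#' `method = "LDA"` maximizes the Fisher ratio in closed form:
#' `t` proportional to `Sw^-1 (mu_walk - mu_idle)` with the pooled
#' within-class covariance `Sw` (ridge-regularized when singular).
#' `method = "AIDA"` maximizes the Gaussian-entropy approximation of the
#' mutual information between class label and 1-D feature,
#' `J(t) = (1/2)[log t'St t - sum_k p_k log t'S_k t]` (total scatter `St`,
#' per-class scatters `S_k`), by quasi-Newton ascent from the LDA direction
#' plus random restarts; for equal class covariances both criteria are
#' maximized along the same Fisher direction.
#'
#' @param x n x m matrix of subspace features.
#' @param labels factor with levels `idle`, `walk` (both present).
#' @param method `"LDA"` or `"AIDA"`.
#' @param restarts number of random restarts for AIDA (in addition to the
#'   LDA warm start).
#' @return unit-norm numeric vector of length m, oriented so walk-class
#'   features score higher than idle-class features.
#' @export
fit_transform_1d <- function(x, labels, method = c("LDA", "AIDA"),
                             restarts = 4) {
  method <- match.arg(method)
  labels <- factor(labels, levels = c("idle", "walk"))
  stopifnot(nrow(x) == length(labels), all(table(labels) >= 1))
  m <- ncol(x)
  if (m == 1) return(1)
  mu <- lapply(levels(labels), function(cl)
    colMeans(x[labels == cl, , drop = FALSE]))
  Sk <- lapply(levels(labels), function(cl) {
    xi <- x[labels == cl, , drop = FALSE]
    crossprod(sweep(xi, 2, colMeans(xi))) / max(1, nrow(xi) - 1)
  })
  n_k <- as.numeric(table(labels))
  priors <- n_k / sum(n_k)
  Sw <- priors[1] * Sk[[1]] + priors[2] * Sk[[2]]
  dmu <- mu[[2]] - mu[[1]]
  t_lda <- tryCatch(solve(Sw, dmu), error = function(e) {
    message("singular within-class scatter; ridge-regularized LDA fallback")
    solve(Sw + diag(mean(diag(Sw)) * 1e-6 + 1e-12, m), dmu)
  })
  t_lda <- t_lda / sqrt(sum(t_lda^2))
  if (method == "LDA") {
    t_out <- t_lda
  } else {
    St <- crossprod(sweep(x, 2, colMeans(x))) / max(1, nrow(x) - 1)
    starts <- c(list(t_lda),
                lapply(seq_len(restarts), function(i) {
                  v <- stats::rnorm(m); v / sqrt(sum(v^2))
                }))
    best <- NULL; best_val <- -Inf
    for (s0 in starts) {
      opt <- stats::optim(s0, fn = function(t) -aida_objective(t, St, Sk, priors),
                          gr = function(t) -aida_gradient(t, St, Sk, priors),
                          method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-10))
      if (-opt$value > best_val) { best_val <- -opt$value; best <- opt$par }
    }
    t_out <- best / sqrt(sum(best^2))
  }
  if (sum(t_out * dmu) < 0) t_out <- -t_out
  t_out
}

# ---- Bayes classifier ------------------------------------------------------

#' Fit the 1-D linear Bayesian classifier
#'
#' Gaussian class-conditionals with pooled (shared) variance, so the
#' decision rule is linear in the feature; priors are the empirical class
#' frequencies. A tied posterior is classified as walking.
#'
#' @param f numeric vector of 1-D features.
#' @param labels factor with levels `idle`, `walk` (both present).
#' @return object of class `bayes_1d`: list with `mu` (named), `sigma2`,
#'   `priors` (named).
#' @export
fit_bayes <- function(f, labels) {
  labels <- factor(labels, levels = c("idle", "walk"))
  stopifnot(length(f) == length(labels), all(table(labels) >= 1))
  mu <- vapply(stats::setNames(levels(labels), levels(labels)),
               function(cl) mean(f[labels == cl]), numeric(1))
  n_k <- table(labels)
  ss <- tapply(f, labels, function(v) sum((v - mean(v))^2))
  sigma2 <- sum(ss) / max(1, sum(n_k) - 2)
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop("zero pooled variance in the feature domain", call. = FALSE)
  }
  priors <- stats::setNames(as.numeric(n_k) / sum(n_k), levels(labels))
  structure(list(mu = mu, sigma2 = sigma2, priors = priors),
            class = "bayes_1d")
}

bayes_posterior_walk <- function(bayes, f) {
  s <- sqrt(bayes$sigma2)
  lw <- stats::dnorm(f, bayes$mu[["walk"]], s) * bayes$priors[["walk"]]
  li <- stats::dnorm(f, bayes$mu[["idle"]], s) * bayes$priors[["idle"]]
  tot <- lw + li
  ifelse(tot > 0, lw / tot, 0.5)
}

# ---- piecewise extractor + model ------------------------------------------

# Fit CPCA pieces, one 1-D transform and one Bayes classifier per piece.
# Each piece's subspace is the class's principal subspace augmented with the
# (orthogonalized) between-class mean-difference direction: a class may have
# next to no variance along the direction that separates it from the other
# class (strong ERD makes walk-trial band power small *and* stable), and
# without the augmentation that direction would be truncated from the piece.
# For an unseen trial, each piece produces a candidate feature; the piece
# whose own-class conditional likelihood of that feature is higher wins and
# supplies the posterior (ties go to the idle piece, deterministically).
fit_extractor <- function(x, labels, method, variance_kept = 0.9,
                          restarts = 4, augment_mean = TRUE) {
  cp <- fit_cpca(x, labels, variance_kept)
  dmu <- cp$walk$mean - cp$idle$mean
  pieces <- lapply(stats::setNames(names(cp), names(cp)), function(cl) {
    b <- cp[[cl]]$basis
    if (augment_mean) {
      resid <- dmu - b %*% crossprod(b, dmu)
      nr <- sqrt(sum(resid^2))
      if (nr > 1e-8 * sqrt(sum(dmu^2))) b <- cbind(b, resid / nr)
    }
    proj <- sweep(x, 2, cp[[cl]]$mean) %*% b
    tvec <- fit_transform_1d(proj, labels, method, restarts = restarts)
    feat <- drop(proj %*% tvec)
    list(mean = cp[[cl]]$mean, basis = b, t = tvec,
         bayes = fit_bayes(feat, labels))
  })
  structure(list(pieces = pieces, method = method), class = "cpca_extractor")
}

extractor_posterior <- function(ex, x) {
  # x: n x D matrix of vectorized trials -> P(W|f*) per trial
  n <- nrow(x)
  feats <- own_lik <- matrix(NA_real_, n, length(ex$pieces))
  post <- matrix(NA_real_, n, length(ex$pieces))
  for (k in seq_along(ex$pieces)) {
    pc <- ex$pieces[[k]]
    cl <- names(ex$pieces)[k]
    f <- drop(sweep(x, 2, pc$mean) %*% pc$basis %*% pc$t)
    feats[, k] <- f
    own_lik[, k] <- stats::dnorm(f, pc$bayes$mu[[cl]],
                                 sqrt(pc$bayes$sigma2)) *
      pc$bayes$priors[[cl]]
    post[, k] <- bayes_posterior_walk(pc$bayes, f)
  }
  pick <- max.col(own_lik, ties.method = "first")  # idle piece first on ties
  post[cbind(seq_len(n), pick)]
}

trials_matrix <- function(tset, rows = NULL) {
  d <- tset$d
  if (is.null(d)) stop("trial set has no spectra; run spectral_trial_set()",
                       call. = FALSE)
  if (!is.null(rows)) d <- lapply(d, function(m) m[rows, , drop = FALSE])
  do.call(rbind, lapply(d, as.vector))
}

band_rows <- function(bin_edges, band) {
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  which(lo >= band[1] & hi <= band[2])
}

#' Fit a decoding model at a fixed band and method
#'
#' @param tset spectral `trial_set` (full-band, from
#'   [spectral_trial_set()]).
#' @param band 2-Hz-aligned frequency interval within the trial set's bins.
#' @param method `"LDA"` or `"AIDA"`.
#' @param variance_kept CPCA variance fraction.
#' @param cv result of [cross_validate()] to attach, or `NULL`.
#' @param restarts AIDA random restarts.
#' @return object of class `decoding_model`.
#' @export
fit_decoding_model <- function(tset, band, method = "LDA",
                               variance_kept = 0.9, cv = NULL, restarts = 4) {
  stopifnot(inherits(tset, "trial_set"))
  edges <- attr(tset, "bin_edges")
  rows <- band_rows(edges, band)
  if (!length(rows)) stop("band outside the trial set's spectra",
                          call. = FALSE)
  x <- trials_matrix(tset, rows)
  ex <- fit_extractor(x, tset$labels, method, variance_kept,
                      restarts = restarts)
  structure(list(
    band = band, method = method, channels = tset$channels,
    bin_edges = edges, rows = rows, n_bins = length(rows),
    extractor = ex, variance_kept = variance_kept,
    cv_accuracy = cv, n_trials = length(tset$labels),
    p_value = if (!is.null(cv)) accuracy_pvalue(cv[["mean"]],
                                                length(tset$labels)) else NA,
    rate = tset$rate
  ), class = "decoding_model")
}

#' @export
print.decoding_model <- function(x, ...) {
  cat(sprintf("<decoding_model> band %g-%g Hz, %s, %d channels\n",
              x$band[1], x$band[2], x$method, length(x$channels)))
  if (!is.null(x$cv_accuracy)) {
    cat(sprintf("  CV accuracy %.1f +/- %.1f %% (n = %d trials, p = %.3g)\n",
                x$cv_accuracy[["mean"]], x$cv_accuracy[["sd"]], x$n_trials,
                x$p_value))
  }
  invisible(x)
}

#' Posterior probability of walking for one spectral trial
#'
#' @param model a fitted `decoding_model`.
#' @param d a B x C spectral trial: either the model band's bins or a
#'   full-band matrix matching the model's bin edges (subset internally).
#' @return P(walk | f*) in `[0, 1]`.
#' @export
posterior_walk <- function(model, d) {
  stopifnot(inherits(model, "decoding_model"))
  d <- as.matrix(d)
  if (ncol(d) != length(model$channels)) {
    stop("channel count mismatch with the model", call. = FALSE)
  }
  full_b <- length(model$bin_edges) - 1L
  if (nrow(d) == model$n_bins) {
    # already band-subset
  } else if (nrow(d) == full_b) {
    d <- d[model$rows, , drop = FALSE]
  } else {
    stop("bin count mismatch with the model", call. = FALSE)
  }
  drop(extractor_posterior(model$extractor, matrix(as.vector(d), nrow = 1)))
}

# ---- cross-validation and band search -------------------------------------

#' Repeated stratified k-fold cross-validation accuracy
#'
#' All fitting (CPCA, discriminant transform, Bayes classifier) is redone
#' inside each training fold. Fold assignment is stratified by class and
#' seeded; the runs use seeds derived from `seed`.
#'
#' @param tset spectral `trial_set`.
#' @param band frequency interval, 2-Hz-aligned.
#' @param method `"LDA"` or `"AIDA"`.
#' @param runs,folds number of CV repetitions and folds.
#' @param seed master seed for fold assignment.
#' @param variance_kept CPCA variance fraction.
#' @param restarts AIDA random restarts.
#' @return named numeric `c(mean, sd)` of percent accuracy over the run
#'   averages, with per-run accuracies in the `runs` attribute.
#' @export
cross_validate <- function(tset, band = c(0, 40), method = "LDA",
                           runs = 10, folds = 10, seed = NULL,
                           variance_kept = 0.9, restarts = 4) {
  stopifnot(inherits(tset, "trial_set"))
  labels <- tset$labels
  if (any(table(labels) < folds)) {
    stop("need at least `folds` trials per class", call. = FALSE)
  }
  rows <- band_rows(attr(tset, "bin_edges"), band)
  x <- trials_matrix(tset, rows)
  seeds <- derive_seeds(seed, runs)
  acc <- vapply(seq_len(runs), function(r) {
    fold <- integer(length(labels))
    with_seed(seeds[r], {
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    })
    correct <- logical(length(labels))
    for (k in seq_len(folds)) {
      tr <- fold != k
      ex <- fit_extractor(x[tr, , drop = FALSE], labels[tr], method,
                          variance_kept, restarts = restarts)
      p <- extractor_posterior(ex, x[!tr, , drop = FALSE])
      pred <- ifelse(p >= 0.5, "walk", "idle")  # tie -> walk
      correct[!tr] <- pred == as.character(labels[!tr])
    }
    100 * mean(correct)
  }, numeric(1))
  out <- c(mean = mean(acc), sd = stats::sd(acc))
  attr(out, "runs") <- acc
  out
}

#' Greedy contiguous frequency-band and method search
#'
#' Starting from the full band, the lower edge is raised in 2-Hz steps while
#' the cross-validated accuracy strictly improves, stopping at the first
#' non-improvement; the upper edge is then lowered likewise. At every step
#' both LDA and AIDA are evaluated and the better one kept; ties prefer the
#' wider band, then LDA over AIDA.
#'
#' @param tset full-band spectral `trial_set`.
#' @param seed master seed for fold assignment (shared across candidate
#'   bands so accuracies are comparable).
#' @param runs,folds cross-validation layout.
#' @param variance_kept CPCA variance fraction.
#' @param restarts AIDA random restarts.
#' @param alpha significance level for the chance-level test on the final
#'   accuracy.
#' @return the best `decoding_model`, with elements `cv_accuracy`,
#'   `p_value`, and `significant`.
#' @export
search_frequency_band <- function(tset, seed = NULL, runs = 10, folds = 10,
                                  variance_kept = 0.9, restarts = 4,
                                  alpha = 0.01) {
  stopifnot(inherits(tset, "trial_set"))
  edges <- attr(tset, "bin_edges")
  full <- c(min(edges), max(edges))
  cache <- new.env(parent = emptyenv())
  eval_band <- function(band) {
    key <- paste(band, collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- lapply(c("LDA", "AIDA"), function(me)
      cross_validate(tset, band, me, runs = runs, folds = folds, seed = seed,
                     variance_kept = variance_kept, restarts = restarts))
    accs <- vapply(res, `[[`, numeric(1), "mean")
    best <- which.max(accs)                 # LDA first -> tie prefers LDA
    out <- list(band = band, method = c("LDA", "AIDA")[best],
                cv = res[[best]], acc = accs[best])
    cache[[key]] <- out
    out
  }
  cur <- eval_band(full)
  repeat {                                  # raise the lower edge
    cand_band <- c(cur$band[1] + 2, cur$band[2])
    if (cand_band[1] >= cand_band[2]) break
    cand <- eval_band(cand_band)
    if (cand$acc > cur$acc) cur <- cand else break
  }
  repeat {                                  # lower the upper edge
    cand_band <- c(cur$band[1], cur$band[2] - 2)
    if (cand_band[2] <= cand_band[1]) break
    cand <- eval_band(cand_band)
    if (cand$acc > cur$acc) cur <- cand else break
  }
  model <- fit_decoding_model(tset, cur$band, cur$method,
                              variance_kept = variance_kept, cv = cur$cv,
                              restarts = restarts)
  model$significant <- model$p_value < alpha
  model
}

#' Exact binomial significance of a classification accuracy
#'
#' One-sided tail probability that a chance (p = 0.5) classifier reaches at
#' least the observed number of correct trials:
#' `p = P(Bin(n, 0.5) >= ceiling(n * accuracy / 100))`.
#'
#' @param accuracy percent correct in `[0, 100]`.
#' @param n_trials number of trials.
#' @return the p-value (vectorized over `accuracy`).
#' @export
accuracy_pvalue <- function(accuracy, n_trials = 100) {
  stopifnot(all(accuracy >= 0), all(accuracy <= 100), n_trials >= 1)
  k <- ceiling(n_trials * accuracy / 100)
  stats::pbinom(k - 1, n_trials, 0.5, lower.tail = FALSE)
}

#' Spatio-spectral feature-extraction map
#'
#' Back-projects the composite 1-D discriminant map of each CPCA piece into
#' input coordinates and combines the pieces by their class priors, giving
#' the per-channel, per-bin magnitude of the weights responsible for
#' encoding the idle/walk difference (the topographic-map analog).
#'
#' @param model a fitted `decoding_model`.
#' @param file optional path; if given the map is also written as a labeled
#'   CSV.
#' @return C x B matrix (channels x frequency bins) of non-negative weights.
#' @export
feature_map <- function(model, file = NULL) {
  stopifnot(inherits(model, "decoding_model"))
  B <- model$n_bins
  C <- length(model$channels)
  w <- numeric(B * C)
  for (k in seq_along(model$extractor$pieces)) {
    pc <- model$extractor$pieces[[k]]
    cl <- names(model$extractor$pieces)[k]
    a <- drop(pc$basis %*% pc$t)
    w <- w + pc$bayes$priors[[cl]] * abs(a)
  }
  m <- t(matrix(w, nrow = B, ncol = C))
  rownames(m) <- model$channels
  lo <- model$bin_edges[model$rows]
  colnames(m) <- sprintf("%g-%gHz", lo, lo + 2)
  if (!is.null(file)) utils::write.csv(m, file)
  m
}
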