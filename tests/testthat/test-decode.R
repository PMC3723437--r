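# CPCA, discriminant transforms, Bayes classifier, cross-validation,
# frequency-band search, significance, feature maps.

test_that("classwise PCA recovers known generating planes", {
  set.seed(10)
  orth <- function(m) qr.Q(qr(m))
  U_i <- orth(matrix(rnorm(10 * 2), 10))
  U_w <- orth(matrix(rnorm(10 * 2), 10))
  x_i <- t(U_i %*% matrix(rnorm(2 * 40), 2))
  x_w <- t(U_w %*% matrix(rnorm(2 * 40), 2)) +
    matrix(rep(rnorm(10), each = 40), 40)   # offset mean, same plane shape
  x <- rbind(x_i, x_w)
  lab <- factor(rep(c("idle", "walk"), each = 40),
                levels = c("idle", "walk"))
  cp <- fit_cpca(x, lab, variance_kept = 0.9)
  expect_equal(ncol(cp$idle$basis), 2)
  expect_equal(ncol(cp$walk$basis), 2)
  # principal angles ~ 0 between fitted and generating planes
  expect_gt(min(svd(crossprod(U_i, cp$idle$basis))$d), 0.999)
  expect_gt(min(svd(crossprod(U_w, cp$walk$basis))$d), 0.999)
  # orthonormal maps
  expect_equal(crossprod(cp$idle$basis), diag(2), tolerance = 1e-12)

  # identical classes -> identical subspaces
  cp2 <- fit_cpca(rbind(x_i, x_i), lab, variance_kept = 0.9)
  expect_equal(cp2$idle$basis, cp2$walk$basis)

  # variance_kept = 1 on full-rank data -> m = min(n_k - 1, D)
  set.seed(11)
  xf <- matrix(rnorm(10 * 4), 10)
  labf <- factor(rep(c("idle", "walk"), each = 5),
                 levels = c("idle", "walk"))
  cpf <- fit_cpca(xf, labf, variance_kept = 1)
  expect_equal(ncol(cpf$idle$basis), 4)
})

test_that("LDA matches the closed form (MASS::lda as independent oracle)", {
  set.seed(12)
  n <- 200
  A <- matrix(c(1, 0.6, 0, 0.8), 2)          # shared covariance factor
  x <- rbind(t(A %*% matrix(rnorm(2 * n), 2)),
             t(A %*% matrix(rnorm(2 * n), 2)) +
               matrix(rep(c(2, 1), each = n), n))
  lab <- factor(rep(c("idle", "walk"), each = n),
                levels = c("idle", "walk"))
  t_lda <- fit_transform_1d(x, lab, "LDA")
  expect_equal(sum(t_lda^2), 1, tolerance = 1e-12)
  oracle <- MASS::lda(x, lab)$scaling[, 1]
  expect_lt(angle_deg(t_lda, oracle), 0.5)
})

test_that("AIDA agrees with LDA on equal-covariance Gaussians and with a grid oracle", {
  set.seed(13)
  n <- 300
  A <- matrix(c(1, 0.5, 0, 0.7), 2)
  x <- rbind(t(A %*% matrix(rnorm(2 * n), 2)),
             t(A %*% matrix(rnorm(2 * n), 2)) +
               matrix(rep(c(1.5, 0.5), each = n), n))
  lab <- factor(rep(c("idle", "walk"), each = n),
                levels = c("idle", "walk"))
  t_lda <- fit_transform_1d(x, lab, "LDA")
  set.seed(14)
  t_aida <- fit_transform_1d(x, lab, "AIDA")
  expect_lt(angle_deg(t_aida, t_lda), 5)

  # brute-force 1-degree grid search over directions maximizing the same
  # approximate-information criterion
  Sk <- lapply(levels(lab), function(cl) cov(x[lab == cl, ]))
  St <- cov(x)
  J <- function(th) {
    v <- c(cos(th), sin(th))
    (log(drop(v %*% St %*% v)) - 0.5 * log(drop(v %*% Sk[[1]] %*% v)) -
        0.5 * log(drop(v %*% Sk[[2]] %*% v))) / 2
  }
  grid <- seq(0, pi, length.out = 181)
  v_star <- grid[which.max(vapply(grid, J, 1))]
  expect_lt(angle_deg(t_aida, c(cos(v_star), sin(v_star))), 2)

  # m = 1: the only direction
  expect_equal(fit_transform_1d(matrix(c(rnorm(10), rnorm(10) + 3)),
                                lab[c(1:10, 301:310)], "AIDA"), 1)
})

test_that("the pooled-variance Bayes classifier places boundaries correctly", {
  # equal priors, mu = 0 / 2, sigma2 = 1 -> boundary at 1
  h <- sqrt(0.5)                       # each class ss = 1, pooled var = 1
  b <- fit_bayes(c(-h, h, 2 - h, 2 + h),
                 factor(c("idle", "idle", "walk", "walk"),
                        levels = c("idle", "walk")))
  expect_equal(unname(b$mu), c(0, 2))
  expect_equal(b$sigma2, 1, tolerance = 1e-9)
  expect_equal(bciwalk:::bayes_posterior_walk(b, 1), 0.5, tolerance = 1e-9)
  # at the walk mean: logistic in the Mahalanobis gap, 1/(1 + e^-2)
  expect_equal(bciwalk:::bayes_posterior_walk(b, 2), 1 / (1 + exp(-2)),
               tolerance = 1e-9)

  # priors 0.9/0.1 shift the boundary by sigma2 * ln(9) / (mu_W - mu_I)
  set.seed(15)
  fi <- rep(c(-1, 1), each = 45)               # 90 idle, mean 0, ss = 90
  fw <- 2 + c(rep(0.8944271910, 5), rep(-0.8944271910, 5))  # ss = 8
  bb <- fit_bayes(c(fi, fw),
                  factor(rep(c("idle", "walk"), c(90, 10)),
                         levels = c("idle", "walk")))
  expect_equal(bb$sigma2, 1, tolerance = 1e-9)
  boundary <- 1 + log(9) / 2
  expect_equal(bciwalk:::bayes_posterior_walk(bb, boundary), 0.5,
               tolerance = 1e-6)
  expect_error(fit_bayes(rep(1, 10),
                         factor(rep(c("idle", "walk"), 5),
                                levels = c("idle", "walk"))),
               "variance")
})

test_that("the exact binomial rule reproduces the printed significance pairs", {
  # independent oracle: direct binomial tail sum
  tail_sum <- function(k, n) sum(choose(n, k:n)) / 2^n
  expect_equal(accuracy_pvalue(60.5, 100), tail_sum(61, 100))
  expect_equal(round(accuracy_pvalue(60.5, 100), 4), 0.0176)
  expect_equal(round(accuracy_pvalue(62.0, 100), 4), 0.0105)
  expect_equal(round(accuracy_pvalue(62.2, 100), 4), 0.0060)
  expect_equal(accuracy_pvalue(50, 100), 0.5398, tolerance = 1e-4)
  # monotonically decreasing in accuracy
  acc <- seq(50, 100, by = 0.5)
  expect_true(all(diff(accuracy_pvalue(acc, 100)) <= 0))
})

test_that("cross-validation separates strong ERD and is honest under shuffling", {
  tr <- fixture_trials(rho = 0.3, seed = 4)
  cv <- cross_validate(tr, c(0, 40), "LDA", runs = 2, folds = 10, seed = 9)
  expect_gt(cv[["mean"]], 85)
  # same seed -> identical result
  cv_b <- cross_validate(tr, c(0, 40), "LDA", runs = 2, folds = 10, seed = 9)
  expect_identical(cv, cv_b)
  # label shuffling -> chance within 3 binomial sd (5% at n = 100)
  trs <- tr
  set.seed(30)
  trs$labels <- sample(trs$labels)
  cvs <- cross_validate(trs, c(0, 40), "LDA", runs = 2, folds = 10,
                        seed = 9)
  expect_lt(abs(cvs[["mean"]] - 50), 15)
})

test_that("band search keeps the generating band and flags flat noise", {
  tr <- fixture_trials(rho = 0.3, seed = 4)
  m <- search_frequency_band(tr, seed = 11, runs = 2, folds = 10)
  expect_true(m$band[1] <= 8 && m$band[2] >= 16)
  expect_true(m$significant)
  expect_s3_class(m, "decoding_model")
  fm <- feature_map(m)
  expect_equal(rownames(fm)[which.max(apply(fm, 1, max))], "Cz")
  expect_equal(dim(fm), c(length(m$channels), m$n_bins))

  # flat noise (rho = 1): chance accuracy, not significant
  tr1 <- fixture_trials(rho = 1, seed = 6)
  m1 <- search_frequency_band(tr1, seed = 11, runs = 2, folds = 5)
  expect_false(m1$significant)
  expect_lt(abs(m1$cv_accuracy[["mean"]] - 50), 15)
})

test_that("posteriors are probabilities and the model serves single trials", {
  tr <- fixture_trials(rho = 0.3, seed = 4)
  m <- fit_decoding_model(tr, c(8, 16), "LDA")
  p_walk <- vapply(which(tr$labels == "walk")[1:10],
                   function(i) posterior_walk(m, tr$d[[i]]), numeric(1))
  p_idle <- vapply(which(tr$labels == "idle")[1:10],
                   function(i) posterior_walk(m, tr$d[[i]]), numeric(1))
  expect_true(all(p_walk >= 0 & p_walk <= 1))
  expect_gt(min(p_walk), max(p_idle))        # strong ERD separates fully
  # full-band input is band-subset internally; band-subset input accepted
  d_full <- tr$d[[1]]
  d_band <- d_full[5:8, , drop = FALSE]
  expect_equal(posterior_walk(m, d_full), posterior_walk(m, d_band))
  expect_error(posterior_walk(m, d_full[, 1:2]), "channel")
  expect_error(posterior_walk(m, d_full[1:7, ]), "bin")
})

test_that("feature maps are equivariant under channel permutation", {
  tr <- fixture_trials(rho = 0.3, seed = 4)
  perm <- rev(seq_along(tr$channels))
  trp <- tr
  trp$channels <- tr$channels[perm]
  trp$d <- lapply(tr$d, function(d) d[, perm])
  m <- fit_decoding_model(tr, c(8, 16), "LDA")
  mp <- fit_decoding_model(trp, c(8, 16), "LDA")
  expect_equal(feature_map(mp), feature_map(m)[perm, ], tolerance = 1e-8)
})
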