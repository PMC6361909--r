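test_that("average-linkage HCA on squared distances separates point clouds", {
  set.seed(21)
  cloud1 <- matrix(rnorm(40, 0), 10, 4)
  cloud2 <- matrix(rnorm(40, 8), 10, 4)
  x <- rbind(cloud1, cloud2)
  rownames(x) <- paste0("S", 1:20)
  res <- hca(x, k = 2)
  expect_length(unique(res$labels[1:10]), 1)
  expect_length(unique(res$labels[11:20]), 1)
  expect_false(res$labels[1] == res$labels[20])

  # identical rows merge at height zero
  same <- matrix(1, 5, 3, dimnames = list(paste0("S", 1:5), NULL))
  res <- hca(same, k = 1)
  expect_equal(res$tree$height, rep(0, 4))
  expect_error(hca(rbind(same, NA)), "missing")
})

test_that("HCA recovers the planted manufacturer groups", {
  sim <- simulate_fingerprints(seed = 1)
  res <- hca(sim$fps$channels[["220nm"]], k = 3)
  rep <- truth_report(sim$truth, cluster_labels = res$labels)
  expect_gte(rep$ari, 0.9)
  # leaf order is deterministic given input order
  res2 <- hca(sim$fps$channels[["220nm"]], k = 3)
  expect_identical(res$order, res2$order)
})

test_that("Latin partition folds are balanced and response-stratified", {
  set.seed(31)
  y28 <- rnorm(28)
  f <- blp_split(y28, 4, seed = 9)
  expect_equal(as.integer(table(f)), rep(7L, 4))
  expect_identical(f, blp_split(y28, 4, seed = 9))  # reproducible
  expect_equal(as.integer(table(blp_split(rnorm(8), 4, seed = 1))), rep(2L, 4))
  # remainder spread across folds: sizes differ by at most one
  f10 <- blp_split(rnorm(10), 4, seed = 2)
  expect_lte(diff(range(table(f10))), 1)
  expect_error(blp_split(rnorm(3), 5), "q <= n")

  # stratification: per-fold means hug the overall mean
  y <- rnorm(28, 10, 2)
  dev <- replicate(200, {
    f <- blp_split(y, 4)
    max(abs(tapply(y, f, mean) - mean(y)))
  })
  expect_lt(mean(dev), 0.5 * sd(y))
  dev_plain <- replicate(200, {
    f <- blp_split(y, 4, stratified = FALSE)
    max(abs(tapply(y, f, mean) - mean(y)))
  })
  expect_lt(mean(dev), mean(dev_plain))
})

test_that("PLS1 recovers a noiseless two-factor response exactly", {
  # two latent factors spread over ten observed peaks: rank-2 X keeps the
  # fit exact in two components for every subsample, so cross-validation can
  # see the true rank
  set.seed(41)
  t_lat <- matrix(rnorm(28 * 2), 28, 2)
  p_load <- matrix(rnorm(20), 10, 2)
  x <- t_lat %*% t(p_load)
  dimnames(x) <- list(paste0("S", 1:28), paste0("P", 1:10))
  y <- 2 * t_lat[, 1] - 1.5 * t_lat[, 2] + 5
  fit <- fit_pls(x, y, 2)
  expect_equal(unname(fit$fitted), unname(y), tolerance = 1e-8)
  m <- pls_metrics(fit, x)
  expect_equal(m$r2, 100, tolerance = 1e-8)
  expect_equal(m$rmsee, 0, tolerance = 1e-6)
  expect_lt(pls_metrics(fit_pls(x, y, 1), x)$r2, 99.9)
  expect_error(fit_pls(x, y, 0), "ncomp")
  expect_error(fit_pls(x, y, 28), "ncomp")
  # a generous component budget truncates to the informative two and still
  # reproduces the OLS predictions on this full-rank noiseless design
  expect_warning(fit_full <- fit_pls(x, y, 10), "truncated")
  expect_equal(fit_full$ncomp, 2L)
  ols <- lm(y ~ x)
  expect_equal(unname(fit_full$fitted), unname(fitted(ols)), tolerance = 1e-6)
  # component selection finds the true rank
  a <- select_components(x, y, 6)
  expect_equal(as.integer(a), 2L)
  expect_true(attr(a, "predictive"))
})

test_that("zero-variance predictors are dropped with a warning", {
  set.seed(42)
  x <- cbind(matrix(rnorm(60), 20, 3), dead = 1)
  colnames(x) <- c("P1", "P2", "P3", "dead")
  y <- x[, 1] + rnorm(20, 0, 0.1)
  expect_warning(fit <- fit_pls(x, y, 2), "dead")
  expect_equal(fit$dropped, "dead")
  expect_length(fit$coef, 3)
})

test_that("permuted responses collapse the fit and destroy predictivity", {
  # with p = 39 > n = 28 a 3-component PLS can always fit some apparent
  # structure, so the permutation check is on the gap to the real fit and on
  # the cross-validated Q2, which has no capacity to overfit
  set.seed(43)
  sim <- simulate_fingerprints(seed = 8)
  x <- sim$fps$channels[["220nm"]][1:28, ]
  y <- sim$activity$asae_mM[1:28]
  r2_real <- pls_metrics(fit_pls(x, y, 3), x)$r2
  perm <- replicate(50, {
    ys <- sample(y)
    m <- pls_metrics(fit_pls(x, ys, 3), x)
    c(m$r2, m$q2)
  })
  expect_lt(median(perm[1, ]), r2_real - 30)
  expect_lt(median(perm[2, ]), 0)
  # pure-noise response: no component count is predictive
  a <- select_components(x, rnorm(28), 5)
  expect_false(attr(a, "predictive"))
  expect_equal(as.integer(a), 1L)
})

test_that("metric definitions behave at their edge cases", {
  set.seed(44)
  x <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  fit <- fit_pls(x, y, 2)
  m <- pls_metrics(fit, x, x_test = x, y_test = y)
  expect_equal(m$rmsep, sqrt(mean((y - fit$fitted)^2)))
  expect_gte(m$r2, m$q2)   # CV never looks better than the fit here
  expect_true(all(c(m$rmsee, m$rmsecv, m$rmsep) >= 0))
  expect_error(pls_metrics(fit_pls(x[1:3, ], y[1:3], 2), x[1:3, ]),
               "RMSEE undefined")
})

test_that("estimation error tracks the planted noise level", {
  set.seed(45)
  sigma <- 0.3
  ratio <- replicate(200, {
    x <- matrix(rnorm(28 * 8), 28, 8)
    y <- x %*% rnorm(8) + rnorm(28, 0, sigma)
    fit <- fit_pls(x, drop(y), 4)
    sqrt(sum(fit$residuals^2) / (28 - 1 - 4)) / sigma
  })
  expect_equal(mean(ratio), 1, tolerance = 0.25)
})

test_that("VIP satisfies its normalization and symmetry identities", {
  set.seed(46)
  x <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(NULL, paste0("P", 1:12)))
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(30, 0, 0.2)
  v <- vip(fit_pls(x, y, 3))
  expect_equal(sum(v^2), 12, tolerance = 1e-8)
  # identical predictors share identical VIP = 1
  base <- rnorm(25)
  x_same <- matrix(rep(base, 6), 25, 6,
                   dimnames = list(NULL, paste0("P", 1:6)))
  v_same <- vip(fit_pls(x_same + 0, base + rnorm(25, 0, 0.1), 1))
  expect_equal(unname(v_same), rep(1, 6), tolerance = 1e-10)
  # a single informative predictor among noise earns the top VIP
  hits <- sapply(1:100, function(s) {
    set.seed(s)
    x <- matrix(rnorm(30 * 15), 30, 15,
                dimnames = list(NULL, paste0("P", 1:15)))
    y <- 3 * x[, 5] + rnorm(30, 0, 0.3)
    names(which.max(vip(fit_pls(x, y, 2)))) == "P5"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("PLS agrees with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(47)
  x <- matrix(rnorm(25 * 8), 25, 8,
              dimnames = list(paste0("S", 1:25), paste0("P", 1:8)))
  y <- x[, 2] - 2 * x[, 6] + rnorm(25, 0, 0.5)
  fit <- fit_pls(x, y, 3)
  ref <- mixOmics::pls(x, y, ncomp = 3, mode = "regression",
                       scale = TRUE, near.zero.var = FALSE)
  pred_ref <- predict(ref, x)$predict[, 1, 3]
  expect_equal(unname(fit$fitted), unname(pred_ref), tolerance = 1e-6)
  expect_equal(unname(vip(fit)), unname(mixOmics::vip(ref)[, 3]),
               tolerance = 1e-6)
})

test_that("Hotelling screening flags at the nominal rate and catches gross outliers", {
  # all-identical scores: nothing to flag
  z <- matrix(1, 10, 2)
  h <- hotelling_outliers(z)
  expect_equal(h$t2, rep(0, 10))
  expect_false(any(h$flags))

  # the F limit is calibrated for scores not used to estimate the variances
  set.seed(48)
  rates <- replicate(500, {
    s <- matrix(rnorm(28 * 3), 28, 3)
    fresh <- matrix(rnorm(28 * 3), 28, 3)
    mean(hotelling_outliers(s, alpha = 0.05, newdata = fresh)$flags)
  })
  se <- sd(rates) / sqrt(500)
  expect_lt(abs(mean(rates) - 0.05), 2 * se + 0.005)
  # applied in-sample it is conservative, never anti-conservative
  in_rates <- replicate(200, {
    mean(hotelling_outliers(matrix(rnorm(28 * 3), 28, 3))$flags)
  })
  expect_lte(mean(in_rates), 0.05)

  caught <- replicate(100, {
    s <- matrix(rnorm(28 * 3), 28, 3)
    s[7, ] <- 10
    hotelling_outliers(s)$flags[7]
  })
  expect_equal(mean(caught), 1)
})

test_that("measured-vs-predicted regression returns slope, intercept, R2", {
  set.seed(49)
  pred <- runif(20, 0.1, 0.3)
  meas <- pred
  r <- prediction_regression(meas, pred)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r2, 1)
  expect_error(prediction_regression(meas, rep(0.2, 20)), "constant")
  expect_error(prediction_regression(meas[1:2], pred[1:2]), ">= 3")
})

test_that("the full spectrum-effect workflow runs end to end", {
  sim <- simulate_fingerprints(seed = 10, n_outliers = 2)
  y <- setNames(sim$activity$asae_mM, sim$activity$sample_id)
  res <- spectrum_effect_pls(sim$fps$channels[["220nm"]], y, q = 4, seed = 7)
  expect_s3_class(res, "pls_summary")
  expect_equal(sum(vip(res$fit)^2), nrow(res$fit$W), tolerance = 1e-8)
  n_kept <- nrow(sim$fps$channels[["220nm"]]) - length(res$outliers)
  expect_equal(length(res$partition), n_kept)
  expect_equal(length(res$test_ids), sum(res$partition == 1))
  expect_true(all(c("r2", "q2", "rmsee", "rmsecv", "rmsep") %in%
                  names(res$metrics)))
  expect_false(is.na(res$metrics$rmsep))
  # determinism under the same seed
  res2 <- spectrum_effect_pls(sim$fps$channels[["220nm"]], y, q = 4, seed = 7)
  expect_equal(res$metrics, res2$metrics)
})

test_that("active peaks carry more VIP weight and positive coefficients", {
  gap <- signs <- numeric(25)
  for (i in seq_along(gap)) {
    sim <- simulate_fingerprints(seed = 100 + i)
    x <- sim$fps$channels[["220nm"]]
    y <- setNames(sim$activity$asae_mM, sim$activity$sample_id)[rownames(x)]
    fit <- fit_pls(x, y, 3)
    v <- vip(fit)
    act <- sim$truth$active_peaks
    gap[i] <- mean(v[act]) - mean(v[setdiff(names(v), act)])
    signs[i] <- mean(fit$coef_std[act] > 0)
  }
  expect_gt(mean(gap), 0)
  expect_gte(mean(signs), 0.9)
})
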