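#' Hierarchical clustering of a peak-area matrix
#'
#' Between-groups (average) linkage agglomeration on squared Euclidean
#' distances, the convention of classical chemometrics software. No variable
#' standardization is applied by default (clustering acts on raw areas); a
#' z-score option exists for display parity with heat maps.
#'
#' @param x samples x peaks numeric matrix, no missing values
#' @param k requested number of flat clusters (optional)
#' @param standardize z-score the peak columns first
#' @return object of class `hca_result`: list with `tree` (an
#'   [stats::hclust] object), `labels` (integer cluster labels when `k`
#'   given), `order` (leaf order for display)
#' @export
hca <- function(x, k = NULL, standardize = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("matrix contains missing values", call. = FALSE)
  if (standardize) x <- scale(x)
  d2 <- stats::dist(x)^2
  tree <- stats::hclust(d2, method = "average")
  labels <- if (!is.null(k)) stats::cutree(tree, k = k) else NULL
  structure(list(tree = tree, labels = labels, order = tree$order),
            class = "hca_result")
}

#' @export
print.hca_result <- function(x, ...) {
  cat(sprintf("<hca_result: %d leaves%s>\n", length(x$order),
              if (is.null(x$labels)) ""
              else sprintf(", %d clusters", length(unique(x$labels)))))
  invisible(x)
}

#' Bootstrap Latin partition of samples into folds
#'
#' Response-stratified random partition: samples are sorted by `y`,
#' consecutive blocks of `q` samples are formed, and within each block one
#' sample is assigned to each fold uniformly at random (a remainder block
#' spreads its samples over a random subset of distinct folds). Each fold
#' therefore samples the whole response range.
#'
#' @param y response values, one per sample
#' @param q number of folds (>= 2, <= length(y))
#' @param seed optional integer seed for reproducibility
#' @param stratified set `FALSE` for a plain unstratified random partition
#' @return integer fold labels in 1..q, in the original sample order
#' @export
blp_split <- function(y, q, seed = NULL, stratified = TRUE) {
  n <- length(y)
  if (q < 2L || q > n) stop("need 2 <= q <= n", call. = FALSE)
  run <- function() {
    folds <- integer(n)
    if (!stratified) {
      folds <- sample(rep_len(seq_len(q), n))
    } else {
      ord <- order(y)
      for (start in seq(1L, n, by = q)) {
        block <- ord[start:min(start + q - 1L, n)]
        folds[block] <- sample(seq_len(q), length(block))
      }
    }
    folds
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# ---- PLS1 (NIPALS) ---------------------------------------------------------

#' Fit a univariate PLS regression (NIPALS)
#'
#' PLS1 on autoscaled predictors (zero mean, unit variance; zero-variance
#' columns are dropped with a warning) and a centered response. Regression
#' coefficients are reported both on the standardized scale (`coef_std`,
#' comparable across predictors) and on the original scale (`coef`,
#' `intercept`).
#'
#' When the residual covariance vanishes before `ncomp` components (the
#' response is already fitted exactly), the fit is truncated at the last
#' informative component with a warning; `$ncomp` records the achieved count.
#'
#' @param x samples x predictors matrix
#' @param y numeric response, one value per sample
#' @param ncomp number of latent components A, `1 <= A <= min(n - 1, p)`
#' @return object of class `pls_fit` with weights `W`, loadings `P`,
#'   y-loadings `q`, scores `scores`, standardized coefficients, fitted
#'   values and residuals
#' @export
fit_pls <- function(x, y, ncomp) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) stop("x and y disagree on sample count", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance predictor(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  p <- ncol(x)
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must be in 1..min(n - 1, p)", call. = FALSE)
  x_center <- colMeans(x)
  xs <- scale(x, center = x_center, scale = sds)
  y_center <- mean(y)
  e <- unclass(xs)
  f <- y - y_center
  W <- P <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  qv <- numeric(ncomp)
  scores <- matrix(0, n, ncomp, dimnames = list(rownames(x), NULL))
  f0 <- sum(f^2)
  nw0 <- NULL
  achieved <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(e, f)
    nw <- sqrt(sum(w^2))
    if (is.null(nw0)) nw0 <- nw
    if (nw <= 1e-10 * nw0 || sum(f^2) <= 1e-20 * f0) {
      warning(sprintf(
        "residual covariance vanished: fit truncated at %d component(s)", achieved))
      break
    }
    w <- w / nw
    t_a <- drop(e %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(e, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    e <- e - tcrossprod(t_a, p_a)
    f <- f - t_a * q_a
    W[, a] <- w
    P[, a] <- p_a
    qv[a] <- q_a
    scores[, a] <- t_a
    achieved <- a
  }
  if (achieved == 0L)
    stop("no informative component: cov(X, y) is zero", call. = FALSE)
  ncomp <- achieved
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  qv <- qv[seq_len(ncomp)]
  scores <- scores[, seq_len(ncomp), drop = FALSE]
  coef_std <- drop(W %*% solve(crossprod(P, W), qv))
  names(coef_std) <- colnames(x)
  coef <- coef_std / sds
  intercept <- y_center - sum(coef * x_center)
  fitted <- drop(x %*% coef) + intercept
  structure(list(
    ncomp = ncomp, W = W, P = P, q = qv, scores = scores,
    x_center = x_center, x_scale = sds, y_center = y_center,
    coef_std = coef_std, coef = coef, intercept = intercept,
    fitted = fitted, residuals = y - fitted, y = y,
    dropped = dropped
  ), class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit: %d components, %d predictors, %d samples>\n",
              x$ncomp, nrow(x$W), nrow(x$scores)))
  invisible(x)
}

#' Predict from a PLS fit
#' @param object a [fit_pls()] result
#' @param newdata samples x predictors matrix with the fitted predictor
#'   columns
#' @param ncomp predict with the first `ncomp` components (default: all)
#' @param ... unused
#' @return numeric predictions on the original response scale
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(names(object$coef) %in% colnames(newdata)))
    newdata <- newdata[, names(object$coef), drop = FALSE]
  if (ncol(newdata) != length(object$coef))
    stop("newdata does not carry the fitted predictors", call. = FALSE)
  ncomp <- min(ncomp, object$ncomp)
  if (ncomp == object$ncomp) {
    coef <- object$coef
    intercept <- object$intercept
  } else {
    W <- object$W[, seq_len(ncomp), drop = FALSE]
    P <- object$P[, seq_len(ncomp), drop = FALSE]
    coef_std <- drop(W %*% solve(crossprod(P, W), object$q[seq_len(ncomp)]))
    coef <- coef_std / object$x_scale
    intercept <- object$y_center - sum(coef * object$x_center)
  }
  drop(newdata %*% coef) + intercept
}

press_by_ncomp <- function(x, y, max_ncomp, folds) {
  press <- matrix(NA_real_, length(unique(folds)), max_ncomp)
  for (f in sort(unique(folds))) {
    idx <- folds == f
    a_max <- min(max_ncomp, sum(!idx) - 1L, ncol(x))
    fit <- suppressWarnings(
      fit_pls(x[!idx, , drop = FALSE], y[!idx], a_max))
    for (a in seq_len(a_max)) {
      pred <- predict(fit, x[idx, , drop = FALSE], ncomp = a)
      press[f, a] <- sum((y[idx] - pred)^2)
    }
  }
  colSums(press[, seq_len(min(max_ncomp, ncol(press))), drop = FALSE])
}

#' Select the number of PLS components by cross-validated Q2
#'
#' Fits models with 1..`max_ncomp` components and returns the component count
#' maximizing `Q2 = 100 * (1 - PRESS/SS_tot)` under the requested
#' cross-validation (leave-one-out by default). When no component count
#' achieves a positive Q2 the model is flagged non-predictive and A = 1 is
#' returned.
#'
#' @param x,y as in [fit_pls()]
#' @param max_ncomp largest component count to consider
#' @param cv `"loo"` or `"kfold"`
#' @param folds number of folds for `cv = "kfold"` (default 7)
#' @param seed seed for the k-fold partition
#' @return integer component count with attributes `q2` (Q2 per candidate A,
#'   percent) and `predictive` (logical)
#' @export
select_components <- function(x, y, max_ncomp = 10L, cv = c("loo", "kfold"),
                              folds = 7L, seed = NULL) {
  cv <- match.arg(cv)
  x <- as.matrix(x)
  n <- nrow(x)
  max_ncomp <- min(max_ncomp, n - 2L, ncol(x))
  fold_id <- if (cv == "loo") seq_len(n) else blp_split(y, folds, seed = seed)
  press <- press_by_ncomp(x, y, max_ncomp, fold_id)
  q2 <- 100 * (1 - press / sum((y - mean(y))^2))
  predictive <- any(q2 > 0, na.rm = TRUE)
  # smallest component count within numerical reach of the best Q2
  a <- if (predictive) min(which(q2 >= max(q2) - 1e-6)) else 1L
  structure(as.integer(a), q2 = q2, predictive = predictive)
}

#' Fit and cross-validation metrics of a PLS model
#'
#' `R2 = 100 * (1 - SS_res/SS_tot)` on the training fit;
#' `Q2 = 100 * (1 - PRESS/SS_tot)` under the requested cross-validation;
#' `RMSEE = sqrt(SS_res/(n - 1 - A))` (estimation error with the
#' degrees-of-freedom denominator); `RMSECV = sqrt(PRESS/n)`; and, when a
#' test set is supplied, `RMSEP = sqrt(mean((y_test - pred)^2))`.
#'
#' @param fit a [fit_pls()] result
#' @param x the training predictor matrix used for `fit`
#' @param x_test,y_test optional held-out test set
#' @param cv `"loo"` (default) or `"kfold"`
#' @param folds,seed k-fold options, as in [select_components()]
#' @return list with `r2`, `q2`, `rmsee`, `rmsecv`, `rmsep` (NA without a
#'   test set)
#' @export
pls_metrics <- function(fit, x, x_test = NULL, y_test = NULL,
                        cv = c("loo", "kfold"), folds = 7L, seed = NULL) {
  stopifnot(inherits(fit, "pls_fit"))
  cv <- match.arg(cv)
  y <- fit$y
  n <- length(y)
  a <- fit$ncomp
  if (n <= a + 1L) stop("RMSEE undefined: n <= A + 1", call. = FALSE)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && all(names(fit$coef) %in% colnames(x)))
    x <- x[, names(fit$coef), drop = FALSE]
  fold_id <- if (cv == "loo") seq_len(n) else blp_split(y, folds, seed = seed)
  press <- press_by_ncomp(x, y, a, fold_id)[a]
  rmsep <- NA_real_
  if (!is.null(x_test)) {
    pred <- predict(fit, x_test)
    rmsep <- sqrt(mean((y_test - pred)^2))
  }
  list(r2 = 100 * (1 - ss_res / ss_tot),
       q2 = 100 * (1 - press / ss_tot),
       rmsee = sqrt(ss_res / (n - 1 - a)),
       rmsecv = sqrt(press / n),
       rmsep = rmsep)
}

#' Variable influence on projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a(w_ja^2 * SSY_a) / sum_a(SSY_a))` with `w` the
#' normalized X-weights and `SSY_a = q_a^2 * t_a't_a` the response variance
#' captured by component `a`. The scores satisfy `sum_j VIP_j^2 = p`, so VIP
#' values spread around 1; predictors with VIP above a chosen threshold
#' (0.5-1 in common use) are retained as relevant.
#'
#' @param fit a [fit_pls()] result
#' @return named numeric vector of VIP scores, one per retained predictor
#' @export
vip <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  ssy <- fit$q^2 * colSums(fit$scores^2)
  p <- nrow(fit$W)
  v <- sqrt(p * drop(fit$W^2 %*% ssy) / sum(ssy))
  names(v) <- rownames(fit$W)
  v
}

#' Hotelling's T2 outlier screening on PLS scores
#'
#' Mahalanobis distance of each sample's scores from the score center,
#' `T2_i = (t_i - t̄)' S^-1 (t_i - t̄)` with `S` the sample covariance of the
#' scores, against the critical value
#' `A (n^2 - 1) / (n (n - A)) * F(1 - alpha; A, n - A)`. PLS scores are
#' centered with mutually orthogonal columns, so in-sample this reduces to
#' the familiar `sum_a t_ia^2 / var(t_a)` score-plot ellipse. The F limit is
#' derived for an observation not used in estimating `S`; applied in-sample
#' it flags conservatively (below the nominal rate), while its calibration
#' is exact for held-out scores supplied via `newdata`.
#'
#' @param scores samples x components score matrix defining the model center
#'   and score covariance
#' @param alpha significance level of the control limit (default 0.05)
#' @param newdata optional score matrix of further samples to screen against
#'   the limit defined by `scores`
#' @return list with `t2` (per screened sample), `critical`, and logical
#'   `flags`
#' @export
hotelling_outliers <- function(scores, alpha = 0.05, newdata = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  a <- ncol(scores)
  if (n <= a) stop("need more samples than components", call. = FALSE)
  center <- colMeans(scores)
  s_cov <- stats::cov(scores)
  eval_scores <- if (is.null(newdata)) scores else as.matrix(newdata)
  dev <- sweep(eval_scores, 2L, center)
  t2 <- if (all(diag(s_cov) == 0)) rep(0, nrow(eval_scores))
        else rowSums(dev * t(solve(s_cov, t(dev))))
  crit <- a * (n^2 - 1) / (n * (n - a)) * stats::qf(1 - alpha, a, n - a)
  list(t2 = t2, critical = crit, flags = t2 > crit)
}

#' Regression of measured on predicted response
#'
#' OLS of the measured values on the model predictions, the standard check of
#' a calibration model's predictive agreement.
#'
#' @param measured,predicted numeric vectors, >= 3 pairs, non-constant
#' @return list with `slope`, `intercept`, `r2` (squared Pearson)
#' @export
prediction_regression <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 3L)
    stop("need >= 3 pairs", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(measured) == 0)
    stop("constant series", call. = FALSE)
  fit <- stats::lm(measured ~ predicted)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = stats::cor(measured, predicted)^2)
}

#' Full spectrum-effect PLS workflow
#'
#' The complete fingerprint-activity modeling pass: (1) an initial PLS fit on
#' all samples with the component count chosen by cross-validated Q2;
#' (2) Hotelling's T2 screening of the score space at level `alpha`, with one
#' refit after removing flagged samples (one pass, not iterative);
#' (3) a bootstrap Latin partition of the retained samples into `q` folds,
#' one fold held out as the test set; (4) the final fit on the training set
#' with Q2-selected components, reporting R2, Q2, RMSEE, RMSECV, RMSEP,
#' standardized coefficients, VIP, and the measured-vs-predicted regression
#' on the training fit.
#'
#' @param x samples x predictors peak-area matrix (row names = sample ids)
#' @param y named response vector (same samples)
#' @param q folds for the Latin partition (default 4; fold 1 is the test set)
#' @param max_ncomp largest component count considered
#' @param cv `"loo"` or `"kfold"` for Q2/RMSECV
#' @param alpha Hotelling significance level
#' @param seed seed driving the Latin partition
#' @return object of class `pls_summary`: list with the final `fit`, `ncomp`,
#'   `metrics`, `vip`, `coef_std`, `outliers` (ids), `partition`
#'   (fold labels of retained samples), `regression`
#'   (measured-vs-predicted on the training fit) and `q2_by_ncomp`
#' @export
spectrum_effect_pls <- function(x, y, q = 4L, max_ncomp = 10L,
                                cv = c("loo", "kfold"), alpha = 0.05,
                                seed = NULL) {
  cv <- match.arg(cv)
  x <- as.matrix(x)
  if (!is.null(names(y))) {
    if (!setequal(rownames(x), names(y)))
      stop("x and y disagree on sample ids", call. = FALSE)
    y <- y[rownames(x)]
  }
  a0 <- select_components(x, y, max_ncomp, cv = cv, seed = seed)
  fit0 <- fit_pls(x, y, as.integer(a0))
  screen <- hotelling_outliers(fit0$scores, alpha = alpha)
  outliers <- rownames(x)[screen$flags]
  keep <- !screen$flags
  x1 <- x[keep, , drop = FALSE]
  y1 <- y[keep]
  folds <- blp_split(y1, q, seed = seed)
  test <- folds == 1L
  x_train <- x1[!test, , drop = FALSE]
  y_train <- y1[!test]
  a <- select_components(x_train, y_train, max_ncomp, cv = cv, seed = seed)
  fit <- fit_pls(x_train, y_train, as.integer(a))
  metrics <- pls_metrics(fit, x_train,
                         x_test = x1[test, , drop = FALSE],
                         y_test = y1[test], cv = cv, seed = seed)
  structure(list(
    fit = fit, ncomp = as.integer(a), metrics = metrics,
    vip = vip(fit), coef_std = fit$coef_std,
    outliers = outliers, t2 = screen,
    partition = folds, test_ids = rownames(x1)[test],
    regression = prediction_regression(y_train, fit$fitted),
    q2_by_ncomp = attr(a, "q2"), predictive = attr(a, "predictive")
  ), class = "pls_summary")
}

#' @export
print.pls_summary <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    paste0("<pls_summary: A = %d | R2 %.1f%%, Q2 %.1f%%, RMSEE %.4g, ",
           "RMSECV %.4g, RMSEP %.4g | outliers: %s>\n"),
    x$ncomp, m$r2, m$q2, m$rmsee, m$rmsecv, m$rmsep,
    if (length(x$outliers)) paste(x$outliers, collapse = ", ") else "none"))
  invisible(x)
}
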