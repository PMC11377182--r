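#' Random normal projection matrix for a Convolutional Kitchen Sink
#'
#' Draws a `w` x `f` matrix of i.i.d. standard-normal entries. The matrix is
#' regenerated exactly from `seed`, so models can be serialized without
#' storing it.
#'
#' @param w Window size (rows).
#' @param f Feature count (columns).
#' @param seed Integer seed.
#' @return A `w` x `f` matrix of class `cks_norms` with attributes `w`, `f`
#'   and `seed`.
#' @examples
#' norms <- make_norms(6, 10, seed = 1)
#' @export
make_norms <- function(w, f, seed) {
  stopifnot(w >= 1, f >= 1)
  set.seed(seed)
  m <- matrix(stats::rnorm(w * f), nrow = w, ncol = f)
  structure(m, w = as.integer(w), f = as.integer(f),
            seed = as.integer(seed), class = c("cks_norms", "matrix", "array"))
}

#' Gather all sliding windows of an observation
#'
#' Returns the `(length(x) - w + 1)` x `w` matrix whose i-th row is
#' `x[i:(i + w - 1)]`; no padding is applied.
#'
#' @param x Numeric observation vector.
#' @param w Window size (<= `length(x)`).
#' @return The window matrix.
#' @export
gather_windows <- function(x, w) {
  l <- length(x)
  if (w > l) stop("window size w exceeds the observation length")
  if (w == 1) return(matrix(x, ncol = 1))
  stats::embed(x, w)[, w:1, drop = FALSE]
}

#' Rectified linear clamp
#'
#' Sets negative entries to 0 (the ReLU activation), elementwise.
#'
#' @param M Numeric vector or matrix.
#' @return `M` with negatives replaced by 0.
#' @export
clamp <- function(M) {
  pmax(M, 0)
}

#' The Convolutional Kitchen Sink transform
#'
#' For each observation (row of `X`): gather all sliding windows of size `w`,
#' project them through the shared random normal matrix, rectify with
#' [clamp()], and average each feature across windows. All rows use the same
#' normal matrix, so the transform of new data is comparable to that of
#' training data.
#'
#' @param X An n x l numeric matrix of observations (a single observation may
#'   be passed as a vector).
#' @param norms A `w` x `f` projection matrix from [make_norms()].
#' @return An n x f matrix of random convolutional features.
#' @export
kitchen_sink <- function(X, norms) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  stopifnot(is.matrix(X), all(is.finite(X)))
  w <- nrow(norms)
  f <- ncol(norms)
  l <- ncol(X)
  if (w > l) stop("window size w exceeds the observation length")
  nwin <- l - w + 1L
  acc <- matrix(0, nrow(X), f)
  for (p in seq_len(nwin)) {
    acc <- acc + clamp(X[, p:(p + w - 1L), drop = FALSE] %*% norms)
  }
  acc / nwin
}

# Closed-form ridge regression of y on centered features via SVD.
# penalty = NULL selects the penalty by generalized cross-validation over a
# log-spaced grid anchored to the singular-value spectrum.
ridge_svd <- function(Fc, yc, penalty = NULL) {
  sv <- svd(Fc)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)
  n <- nrow(Fc)
  if (is.null(penalty)) {
    base <- mean(d2[d2 > 0])
    grid <- base * 10^seq(-8, 2, length.out = 45)
    gcv <- vapply(grid, function(lam) {
      sh <- d2 / (d2 + lam)
      rss <- sum((yc - sv$u %*% (sh * uty))^2)
      df <- sum(sh) + 1
      n * rss / (n - df)^2
    }, numeric(1))
    penalty <- grid[which.min(gcv)]
  }
  shrink <- ifelse(d2 > (1e-12 * max(d2, 1))^1 | penalty > 0,
                   sv$d / (d2 + penalty), 0)
  beta <- sv$v %*% (shrink * uty)
  list(beta = as.numeric(beta), penalty = penalty)
}

#' Fit a Convolutional Kitchen Sink regression model
#'
#' Transforms the training observations with [kitchen_sink()] and fits a
#' ridge regression of `y` on the (mean-centered, optionally scaled)
#' features. When `penalty` is `NULL` it is chosen by generalized
#' cross-validation on the training features. The training target range is
#' stored so predictions can be clamped to it.
#'
#' @param X Training observation matrix (n x l).
#' @param y Numeric training targets of length n.
#' @param norms A projection matrix from [make_norms()]; alternatively supply
#'   `w`, `f` and `seed` and it is created internally.
#' @param w,f,seed Used to build `norms` when it is not supplied.
#' @param penalty Fixed ridge penalty, or `NULL` for GCV selection.
#' @param center,scale Center (default) and/or scale features before ridge.
#' @return An object of class `cks_model`.
#' @export
fit_cks <- function(X, y, norms = NULL, w = NULL, f = NULL, seed = NULL,
                    penalty = NULL, center = TRUE, scale = FALSE) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  stopifnot(nrow(X) >= 2, length(y) == nrow(X))
  if (is.null(norms)) {
    stopifnot(!is.null(w), !is.null(f), !is.null(seed))
    norms <- make_norms(w, f, seed)
  }
  feats <- kitchen_sink(X, norms)
  centers <- if (center) colMeans(feats) else rep(0, ncol(feats))
  Fc <- sweep(feats, 2, centers)
  scales <- rep(1, ncol(feats))
  if (scale) {
    scales <- apply(Fc, 2, stats::sd)
    scales[scales < 1e-12] <- 1
    Fc <- sweep(Fc, 2, scales, "/")
  }
  ybar <- mean(y)
  if (stats::sd(y) < 1e-14) {
    fit <- list(beta = rep(0, ncol(feats)), penalty = penalty %||% 0)
  } else {
    fit <- ridge_svd(Fc, y - ybar, penalty = penalty)
  }
  structure(list(norms = norms,
                 beta = fit$beta,
                 intercept = ybar - sum((centers / scales) * fit$beta),
                 penalty = fit$penalty,
                 centers = centers,
                 scales = scales,
                 y_range = range(y),
                 input_length = ncol(X)),
            class = "cks_model")
}

#' Predict from a fitted Convolutional Kitchen Sink model
#'
#' New observations are passed through the kitchen sink with the model's own
#' normal matrix and predicted with the fitted ridge coefficients. Outlier
#' predictions beyond the training-target range are clamped to its maximum or
#' minimum unless `clamp_range = FALSE`.
#'
#' @param model A `cks_model` from [fit_cks()].
#' @param X New observation matrix (same width as the training data).
#' @param clamp_range Clamp predictions to the training-target range.
#' @return Numeric predictions, one per row of `X`.
#' @export
kitchen_predict <- function(model, X, clamp_range = TRUE) {
  stopifnot(inherits(model, "cks_model"))
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$input_length) {
    stop("observation length ", ncol(X), " does not match training length ",
         model$input_length)
  }
  feats <- kitchen_sink(X, model$norms)
  feats <- sweep(feats, 2, model$scales, "/")
  pred <- as.numeric(feats %*% model$beta) + model$intercept
  if (clamp_range) {
    pred <- pmin(pmax(pred, model$y_range[1]), model$y_range[2])
  }
  pred
}

#' Hyperparameter sweep over window sizes and feature counts
#'
#' Fits one kitchen sink model per `(w, f)` cell on the training data,
#' predicts the validation data, regresses the true validation targets on the
#' predictions, and records the adjusted R-squared of that regression. Each
#' cell uses its own normal matrix derived deterministically from
#' `base_seed` and the cell index. Cells whose fit fails are skipped with a
#' message.
#'
#' @param X_train,y_train Training observations and targets.
#' @param X_val,y_val Validation observations and targets.
#' @param w_grid,f_grid Window sizes and feature counts to sweep.
#' @param base_seed Seed from which per-cell normal matrices are derived.
#' @param penalty Fixed ridge penalty or `NULL` for GCV.
#' @param center,scale Passed to [fit_cks()].
#' @return An object of class `cks_sweep`: list with the result `table`
#'   (w, f, seed, r2, adj_r2, slope), the `best` cell and its fitted `model`.
#' @export
kitchen_sweep <- function(X_train, y_train, X_val, y_val,
                          w_grid, f_grid, base_seed = 1, penalty = NULL,
                          center = TRUE, scale = FALSE) {
  stopifnot(length(w_grid) >= 1, length(f_grid) >= 1)
  if (any(w_grid > ncol(X_train))) {
    stop("all window sizes must be <= the observation length")
  }
  cells <- expand.grid(w = w_grid, f = f_grid, KEEP.OUT.ATTRS = FALSE)
  res <- data.frame(w = cells$w, f = cells$f,
                    seed = NA_integer_, r2 = NA_real_,
                    adj_r2 = NA_real_, slope = NA_real_)
  models <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sd_i <- derive_seed(base_seed, i)
    res$seed[i] <- sd_i
    fit <- tryCatch({
      m <- fit_cks(X_train, y_train,
                   w = cells$w[i], f = cells$f[i], seed = sd_i,
                   penalty = penalty, center = center, scale = scale)
      pred <- kitchen_predict(m, X_val)
      ev <- evaluate(y_val, pred)
      list(model = m, ev = ev)
    }, error = function(e) {
      message("sweep cell (w=", cells$w[i], ", f=", cells$f[i],
              ") failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(fit)) next
    models[[i]] <- fit$model
    res$r2[i] <- fit$ev$r2
    res$adj_r2[i] <- fit$ev$adj_r2
    res$slope[i] <- fit$ev$slope
  }
  if (all(is.na(res$adj_r2))) stop("every sweep cell failed")
  best <- which.max(res$adj_r2)
  structure(list(table = res,
                 best = res[best, , drop = FALSE],
                 model = models[[best]]),
            class = "cks_sweep")
}

#' Bootstrap point estimate and confidence interval for an observed community
#'
#' Retrains the kitchen sink model `B` times on training rows resampled with
#' replacement (keeping the same normal matrix) and predicts the observed
#' vector with each refit. The point estimate is the mean of the bootstrap
#' predictions and the 95% interval their 2.5/97.5 percentiles. The ridge
#' penalty is chosen once on the full training features and reused across
#' resamples. Because the normal matrix is fixed, features are computed once
#' and only the ridge refits are repeated.
#'
#' @param X_train,y_train Training observations and targets.
#' @param x_observed The observed vector (same length as training rows).
#' @param norms Projection matrix from [make_norms()] (or supply `w`, `f`,
#'   `norm_seed`).
#' @param w,f,norm_seed Used to build `norms` when it is not supplied.
#' @param B Number of bootstrap resamples (default 100).
#' @param penalty Fixed ridge penalty or `NULL` for GCV on the full data.
#' @param seed Optional integer seed for the resampling.
#' @param center Mean-center features before ridge.
#' @return List with `estimate`, `ci` (2.5/97.5 percentiles) and the vector
#'   of bootstrap `predictions`.
#' @export
bootstrap_estimate <- function(X_train, y_train, x_observed, norms = NULL,
                               w = NULL, f = NULL, norm_seed = NULL,
                               B = 100, penalty = NULL, seed = NULL,
                               center = TRUE) {
  stopifnot(B >= 2)
  if (is.null(norms)) {
    stopifnot(!is.null(w), !is.null(f), !is.null(norm_seed))
    norms <- make_norms(w, f, norm_seed)
  }
  feats <- kitchen_sink(X_train, norms)
  fobs <- kitchen_sink(matrix(x_observed, nrow = 1), norms)
  n <- nrow(feats)
  if (is.null(penalty)) {
    centers <- if (center) colMeans(feats) else rep(0, ncol(feats))
    if (stats::sd(y_train) < 1e-14) {
      penalty <- 0
    } else {
      penalty <- ridge_svd(sweep(feats, 2, centers), y_train - mean(y_train))$penalty
    }
  }
  preds <- numeric(B)
  for (b in seq_len(B)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, b))
    idx <- sample.int(n, n, replace = TRUE)
    Fb <- feats[idx, , drop = FALSE]
    yb <- y_train[idx]
    cb <- if (center) colMeans(Fb) else rep(0, ncol(Fb))
    Fbc <- sweep(Fb, 2, cb)
    if (stats::sd(yb) < 1e-14) {
      preds[b] <- yb[1]
      next
    }
    beta <- solve(crossprod(Fbc) + diag(penalty, ncol(Fbc)),
                  crossprod(Fbc, yb - mean(yb)))
    p <- sum((fobs[1, ] - cb) * beta) + mean(yb)
    preds[b] <- min(max(p, min(yb)), max(yb))
  }
  list(estimate = mean(preds),
       ci = unname(stats::quantile(preds, c(0.025, 0.975))),
       predictions = preds)
}
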