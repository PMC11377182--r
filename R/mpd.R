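#' Transformation-parameter grids for MPD curves
#'
#' `eb_grid()` is the default gradient of exponential transformations from
#' stemmy to tippy: a from -3 to 3, stepped by 0.1 outside \[-1, 1\] and by
#' 0.05 inside, 81 values in total. `delta_grid()` maps the same gradient
#' through `exp()` so delta spans `exp(-3)` to `exp(3)` (delta must be
#' positive); `transform_grid()` builds a grid from arbitrary values.
#'
#' @param model `"EB"` or `"delta"`.
#' @param values Strictly increasing parameter values.
#' @return An object of class `transform_grid` with elements `model` and
#'   `values`.
#' @export
transform_grid <- function(model = c("EB", "delta"), values) {
  model <- match.arg(model)
  stopifnot(is.numeric(values), length(values) >= 1, !is.unsorted(values, strictly = TRUE))
  if (model == "delta" && any(values <= 0)) stop("delta grid values must be > 0")
  structure(list(model = model, values = as.numeric(values)),
            class = "transform_grid")
}

#' @rdname transform_grid
#' @export
eb_grid <- function() {
  v <- c(seq(-3, -1.1, by = 0.1), seq(-1, 1, by = 0.05), seq(1.1, 3, by = 0.1))
  transform_grid("EB", round(v, 10))
}

#' @rdname transform_grid
#' @export
delta_grid <- function() {
  g <- eb_grid()
  transform_grid("delta", exp(g$values))
}

#' Mean pairwise phylogenetic distance of a community
#'
#' The mean of the patristic distances over all unordered pairs of species
#' present in the community.
#'
#' @param dist A symmetric patristic distance matrix in tip order (see
#'   [cophenetic_distances()]).
#' @param community A 0/1 vector in tip order (or named by tip) with at least
#'   two species present.
#' @return The mean pairwise distance.
#' @export
mpd <- function(dist, community) {
  community <- align_community(community, rownames(dist) %||%
                                 paste0("V", seq_len(nrow(dist))))
  idx <- which(community == 1L)
  if (length(idx) < 2) stop("community must contain at least 2 species")
  sub <- dist[idx, idx]
  mean(sub[upper.tri(sub)])
}

# Exact mean and sd of the MPD of a uniform random k-subset of the n tips,
# from closed-form sampling moments of a mean over pairs:
#   E = mean of all off-diagonal distances;
#   E[S^2] for S = sum of within-sample pair distances decomposes over pairs
#   of tip-pairs sharing 2, 1 or 0 tips, with joint inclusion probabilities
#   pi_j = k(k-1)...(k-j+1) / (n(n-1)...(n-j+1)).
mpd_null_moments <- function(dist, k) {
  n <- nrow(dist)
  stopifnot(k >= 2, k <= n)
  m <- k * (k - 1) / 2
  S1 <- sum(dist) / 2
  S2 <- sum(dist^2) / 2
  r <- rowSums(dist)
  s <- rowSums(dist^2)
  A3 <- sum(r^2 - s)           # ordered pairs of tip-pairs sharing one tip
  A4 <- S1^2 - S2 - A3         # ordered pairs of disjoint tip-pairs
  pi2 <- k * (k - 1) / (n * (n - 1))
  pi3 <- pi2 * (k - 2) / (n - 2)
  pi4 <- if (n >= 4) pi3 * (k - 3) / (n - 3) else 0
  mu <- pi2 * S1 / m
  ex2 <- (pi2 * S2 + pi3 * A3 + pi4 * A4) / m^2
  v <- max(ex2 - mu^2, 0)
  list(mean = mu, sd = sqrt(v))
}

#' Standardized mean pairwise distance (SES-MPD)
#'
#' Standardizes the observed community MPD against the null distribution of
#' the MPD of `k` species drawn uniformly at random from the species pool:
#' `(observed - null mean) / null sd`. Negative values indicate phylogenetic
#' clustering. The null can be estimated by permutation draws (`n_null`
#' random same-size communities) or computed from exact closed-form sampling
#' moments (`null = "analytic"`, no Monte Carlo error, much faster).
#'
#' @inheritParams mpd
#' @param n_null Number of random draws for the permutation null.
#' @param seed Optional integer seed for the permutation null.
#' @param null `"permutation"` or `"analytic"`.
#' @return The standardized effect size; 0 with a warning if the null has
#'   zero standard deviation (e.g. a star tree).
#' @export
ses_mpd <- function(dist, community, n_null = 499, seed = NULL,
                    null = c("permutation", "analytic")) {
  null <- match.arg(null)
  community <- align_community(community, rownames(dist) %||%
                                 paste0("V", seq_len(nrow(dist))))
  k <- sum(community)
  if (k < 2) stop("community must contain at least 2 species")
  obs <- mpd(dist, community)
  if (null == "analytic") {
    mom <- mpd_null_moments(dist, k)
    null_mean <- mom$mean; null_sd <- mom$sd
  } else {
    stopifnot(n_null >= 1)
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(dist)
    draws <- vapply(seq_len(n_null), function(i) {
      idx <- sample.int(n, k)
      sub <- dist[idx, idx]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    null_mean <- mean(draws); null_sd <- stats::sd(draws)
  }
  if (!is.finite(null_sd) || null_sd < 1e-12) {
    warning("null standard deviation is zero; returning SES-MPD = 0")
    return(0)
  }
  (obs - null_mean) / null_sd
}

#' MPD curve across a gradient of tree transformations
#'
#' Computes the SES-MPD of a community on each transformed tree of the grid,
#' producing the curve whose shape reflects how clustering changes from
#' stemmy to tippy effective trees. With the permutation null, the same null
#' draws are shared across all grid points so curve shape reflects the
#' transformation rather than null noise; the analytic null is exact at every
#' point.
#'
#' @param tree An ultrametric `phylo` object.
#' @param community A 0/1 vector in tip order.
#' @param grid A [transform_grid()] (default [eb_grid()], 81 points).
#' @param n_null Draws for the permutation null.
#' @param seed Optional integer seed.
#' @param null `"analytic"` (default) or `"permutation"`.
#' @return An object of class `mpd_curve`: list with `grid` and `values`.
#' @export
mpd_curve <- function(tree, community, grid = eb_grid(), n_null = 499,
                      seed = NULL, null = c("analytic", "permutation")) {
  null <- match.arg(null)
  community <- align_community(community, tree$tip.label)
  M <- mpd_curves(tree, matrix(community, nrow = 1,
                               dimnames = list(NULL, tree$tip.label)),
                  grid = grid, n_null = n_null, seed = seed, null = null)
  structure(list(grid = grid, values = as.numeric(M[1, ])),
            class = "mpd_curve")
}

#' MPD curves for a batch of communities
#'
#' Vectorized computation of [mpd_curve()] for every row of a community
#' matrix: each grid point costs one matrix product, and the null moments of
#' each transformed tree are computed once and shared by all communities of
#' the same size.
#'
#' @inheritParams mpd_curve
#' @param communities An n_sims x n_tips 0/1 matrix, columns in tip order.
#' @return An n_sims x length(grid) matrix of SES-MPD values with a
#'   `"grid"` attribute.
#' @export
mpd_curves <- function(tree, communities, grid = eb_grid(), n_null = 499,
                       seed = NULL, null = c("analytic", "permutation")) {
  null <- match.arg(null)
  stopifnot(inherits(grid, "transform_grid"))
  if (!is.matrix(communities)) communities <- matrix(communities, nrow = 1)
  if (!is.null(colnames(communities))) {
    communities <- communities[, tree$tip.label, drop = FALSE]
  } else if (ncol(communities) != length(tree$tip.label)) {
    stop("community matrix width must equal the number of tips")
  }
  C <- communities != 0
  storage.mode(C) <- "double"
  k <- rowSums(C)
  if (any(k < 2)) stop("all communities must contain at least 2 species")
  uk <- sort(unique(k))
  n <- length(tree$tip.label)
  np <- length(grid$values)
  out <- matrix(NA_real_, nrow(C), np)
  null_idx <- NULL
  if (null == "permutation") {
    stopifnot(n_null >= 1)
    if (!is.null(seed)) set.seed(seed)
    # shared null draws (per community size) reused across all grid points
    null_idx <- lapply(uk, function(kk) {
      t(vapply(seq_len(n_null), function(i) sample.int(n, kk), integer(kk)))
    })
    names(null_idx) <- as.character(uk)
  }
  for (g in seq_len(np)) {
    D <- cophenetic_distances(
      apply_transform(tree, transform_param(grid$model, grid$values[g])))
    obs <- rowSums((C %*% D) * C) / (k * (k - 1))
    for (kk in uk) {
      rows <- which(k == kk)
      if (null == "analytic") {
        mom <- mpd_null_moments(D, kk)
        mu <- mom$mean; sdv <- mom$sd
      } else {
        idx <- null_idx[[as.character(kk)]]
        nulls <- vapply(seq_len(nrow(idx)), function(i) {
          sub <- D[idx[i, ], idx[i, ]]
          mean(sub[upper.tri(sub)])
        }, numeric(1))
        mu <- mean(nulls); sdv <- stats::sd(nulls)
      }
      if (!is.finite(sdv) || sdv < 1e-12) {
        warning("null standard deviation is zero at grid value ",
                grid$values[g], "; returning 0")
        out[rows, g] <- 0
      } else {
        out[rows, g] <- (obs[rows] - mu) / sdv
      }
    }
  }
  attr(out, "grid") <- grid
  out
}

#' Grid location of the curve minimum
#'
#' The transformation-parameter value at which the community is maximally
#' clustered (minimal SES-MPD); ties resolve to the smallest grid value.
#'
#' @param curve An `mpd_curve` or a numeric vector with a `transform_grid`
#'   supplied via its `"grid"` attribute.
#' @return The grid value at the argmin.
#' @export
curve_minimum <- function(curve) {
  if (inherits(curve, "mpd_curve")) {
    grid <- curve$grid; v <- curve$values
  } else {
    grid <- attr(curve, "grid")
    v <- as.numeric(curve)
  }
  stopifnot(!is.null(grid), length(v) >= 1)
  grid$values[which.min(v)]
}

#' Linear model mapping MPD curves to evolutionary parameters
#'
#' Ordinary least squares of the known transformation parameter on the curve
#' values. A determined OLS fit needs more training curves than grid points;
#' with fewer, or with rank-deficient curves, the fit falls back to ridge
#' regression with a small penalty and a warning.
#'
#' @param curves A matrix of curves (rows = simulations) as returned by
#'   [mpd_curves()], or a list of `mpd_curve` objects.
#' @param a_true Numeric vector of known parameters, one per curve.
#' @param ridge_penalty Penalty used by the rank-deficiency fallback;
#'   `NULL` (default) selects it by generalized cross-validation.
#' @return An object of class `mpd_model` with `intercept`, `coefficients`
#'   and `grid`.
#' @export
fit_mpd_model <- function(curves, a_true, ridge_penalty = NULL) {
  if (is.list(curves) && !is.matrix(curves)) {
    grid <- curves[[1]]$grid
    curves <- do.call(rbind, lapply(curves, function(cv) cv$values))
    attr(curves, "grid") <- grid
  }
  grid <- attr(curves, "grid")
  stopifnot(is.matrix(curves), length(a_true) == nrow(curves))
  p <- ncol(curves)
  X <- cbind(1, curves)
  fit <- NULL
  if (nrow(curves) >= p + 2) {
    fit <- stats::lm.fit(X, a_true)
    if (fit$rank < p + 1) fit <- NULL
  }
  if (is.null(fit)) {
    warning("rank-deficient or under-determined curve matrix; ",
            "falling back to ridge regression")
    cm <- colMeans(curves)
    rr <- ridge_svd(sweep(curves, 2, cm), a_true - mean(a_true),
                    penalty = ridge_penalty)
    coefs <- rr$beta
    intercept <- mean(a_true) - sum(cm * coefs)
  } else {
    intercept <- fit$coefficients[1]
    coefs <- fit$coefficients[-1]
  }
  structure(list(intercept = unname(intercept),
                 coefficients = unname(coefs),
                 grid = grid),
            class = "mpd_model")
}

#' @rdname fit_mpd_model
#' @param model A fitted `mpd_model`.
#' @param curve An `mpd_curve`, a numeric curve vector, or a matrix of curves.
#' @return `predict_mpd_model()`: predicted parameter value(s).
#' @export
predict_mpd_model <- function(model, curve) {
  stopifnot(inherits(model, "mpd_model"))
  v <- if (inherits(curve, "mpd_curve")) curve$values else curve
  if (is.matrix(v)) {
    stopifnot(ncol(v) == length(model$coefficients))
    return(as.numeric(model$intercept + v %*% model$coefficients))
  }
  stopifnot(length(v) == length(model$coefficients))
  model$intercept + sum(v * model$coefficients)
}
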