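#' Regression-based evaluation of parameter predictions
#'
#' Regresses the true parameter values on the predicted values and reports
#' R-squared, adjusted R-squared (one predictor) and the slope of that
#' regression, the standard summary of estimator performance used throughout
#' the package.
#'
#' @param true Known parameter values (length >= 3).
#' @param predicted Predicted values of the same length.
#' @return List with `r2`, `adj_r2`, `slope` and `n`.
#' @export
evaluate <- function(true, predicted) {
  stopifnot(length(true) == length(predicted), length(true) >= 3,
            all(is.finite(true)), all(is.finite(predicted)))
  if (stats::sd(predicted) < 1e-14) {
    warning("predictions have zero variance; R-squared set to 0")
    return(list(r2 = 0, adj_r2 = 0, slope = NA_real_, n = length(true)))
  }
  fit <- stats::lm(true ~ predicted)
  sm <- summary(fit)
  list(r2 = unname(sm$r.squared),
       adj_r2 = unname(sm$adj.r.squared),
       slope = unname(stats::coef(fit)[2]),
       n = length(true))
}

# Draw n values from Normal(mean, sd), bounded either by exact rejection
# sampling or by clamping to the bounds.
draw_a <- function(n, mean, sd, bounds = NULL,
                   bound_method = c("reject", "clamp"), seed = NULL) {
  bound_method <- match.arg(bound_method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bounds)) return(stats::rnorm(n, mean, sd))
  if (bound_method == "clamp") {
    return(pmin(pmax(stats::rnorm(n, mean, sd), bounds[1]), bounds[2]))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n + 10, mean, sd)
    out <- c(out, x[x >= bounds[1] & x <= bounds[2]])
  }
  out[seq_len(n)]
}

#' Simulate a training/validation dataset of trait-filtered communities
#'
#' For each simulation: draw an exponential transformation parameter `a` from
#' the configured (optionally truncated) normal distribution, evolve traits
#' by Brownian motion on the `a`-transformed effective tree, choose a trait
#' optimum, and assemble a community of size `k` by the chosen process. All
#' randomness derives from `seed`, so the dataset is bit-reproducible, and
#' per-simulation streams are shared across configurations that differ only
#' in the assembly intensity `lambda` (common random numbers).
#'
#' @param tree An ultrametric `phylo` object in canonical tip order.
#' @param n_sims Number of simulations.
#' @param k Community size.
#' @param assembly `"deterministic"`, `"probabilistic"` or
#'   `"limiting_similarity"`.
#' @param lambda Exponential rate for probabilistic assembly.
#' @param a_mean,a_sd Mean and sd of the parameter distribution; `a_sd = NULL`
#'   applies the depth rule sd = 5 / tree depth.
#' @param a_bounds Optional `c(lo, hi)` truncation bounds.
#' @param bound_method `"reject"` (exact truncation) or `"clamp"`.
#' @param n_traits Number of traits (default 10).
#' @param sigma2 Brownian rate.
#' @param covarying Evolve one trait replicated `n_traits` times instead of
#'   independent traits.
#' @param n_effective Number of independent effective trees; `n_traits` must
#'   be divisible by it, and each tree receives its own `a` draw.
#' @param optimum `"random_species"` or `"trait_means"`.
#' @param seed Master integer seed.
#' @return List with `community` (n_sims x n_tips 0/1 matrix, columns in tip
#'   order), `a_true` (vector, or matrix when `n_effective > 1`), `tree` and
#'   the configuration in `params`.
#' @export
simulate_dataset <- function(tree, n_sims, k,
                             assembly = c("deterministic", "probabilistic",
                                          "limiting_similarity"),
                             lambda = NULL,
                             a_mean = 0, a_sd = NULL, a_bounds = NULL,
                             bound_method = c("reject", "clamp"),
                             n_traits = 10, sigma2 = 1,
                             covarying = FALSE, n_effective = 1,
                             optimum = c("random_species", "trait_means"),
                             seed = 1) {
  assembly <- match.arg(assembly)
  optimum <- match.arg(optimum)
  bound_method <- match.arg(bound_method)
  stopifnot(inherits(tree, "phylo"), n_sims >= 1)
  if (assembly == "probabilistic" && is.null(lambda)) {
    stop("probabilistic assembly requires lambda")
  }
  if (n_effective > 1 && n_traits %% n_effective != 0) {
    stop("n_traits must be divisible by n_effective")
  }
  if (is.null(a_sd)) a_sd <- 5 / tree_depth(tree)
  ntip <- length(tree$tip.label)
  comm <- matrix(0L, n_sims, ntip, dimnames = list(NULL, tree$tip.label))
  a_mat <- matrix(NA_real_, n_sims, n_effective)
  for (i in seq_len(n_sims)) {
    si <- derive_seed(seed, i)
    a <- draw_a(n_effective, a_mean, a_sd, a_bounds, bound_method,
                seed = derive_seed(si, 1))
    traits <- if (n_effective > 1) {
      simulate_multi_a(tree, a, traits_per_a = n_traits / n_effective,
                       sigma2 = sigma2, seed = derive_seed(si, 2))
    } else if (covarying) {
      simulate_covarying(eb_rescale(tree, a), n_traits = n_traits,
                         sigma2 = sigma2, seed = derive_seed(si, 2))
    } else {
      simulate_on_effective_tree(tree, transform_param("EB", a),
                                 n_traits = n_traits, sigma2 = sigma2,
                                 seed = derive_seed(si, 2))
    }
    opt <- choose_optimum(traits, optimum, seed = derive_seed(si, 3))
    comm[i, ] <- switch(assembly,
      deterministic = filter_deterministic(traits, opt, k),
      probabilistic = filter_probabilistic(traits, opt, k, lambda,
                                           seed = derive_seed(si, 4)),
      limiting_similarity = limiting_similarity(traits, k))
    a_mat[i, ] <- a
  }
  list(community = comm,
       a_true = if (n_effective == 1) a_mat[, 1] else a_mat,
       tree = tree,
       params = list(n_sims = n_sims, k = k, assembly = assembly,
                     lambda = lambda, a_mean = a_mean, a_sd = a_sd,
                     a_bounds = a_bounds, bound_method = bound_method,
                     n_traits = n_traits, sigma2 = sigma2,
                     covarying = covarying, n_effective = n_effective,
                     optimum = optimum, seed = seed))
}

default_w_grid <- function(ntip) {
  w <- 4
  out <- integer(0)
  while (w <= ntip) {
    out <- c(out, w)
    w <- w * 4
  }
  out
}

#' Train and compare the CKS and MPD-curve estimators on one dataset
#'
#' Splits the simulations into the first `n_train` (training) and the rest
#' (validation), fits a kitchen sink model via [kitchen_sweep()] and a linear
#' MPD-curve model via [fit_mpd_model()] on the training split, and evaluates
#' both on the validation split with [evaluate()].
#'
#' @param dataset Output of [simulate_dataset()] (with scalar `a_true`), or a
#'   compatible list.
#' @param n_train Number of training simulations.
#' @param w_grid,f_grid CKS sweep grids; `w_grid = NULL` uses powers of 4 up
#'   to the tree size.
#' @param base_seed Seed for the sweep's normal matrices.
#' @param grid Transformation grid for the MPD curves.
#' @param penalty Ridge penalty passed to the sweep (`NULL` = GCV).
#' @param estimators Which estimators to run (`"cks"`, `"mpd"` or both).
#' @return List with per-estimator sweep/model, evaluation and prediction
#'   table.
#' @export
run_comparison <- function(dataset, n_train, w_grid = NULL,
                           f_grid = c(64, 256), base_seed = 1,
                           grid = eb_grid(), penalty = NULL,
                           estimators = c("cks", "mpd")) {
  comm <- dataset$community
  a <- dataset$a_true
  stopifnot(is.numeric(a), n_train < nrow(comm), n_train >= 1)
  idx_tr <- seq_len(n_train)
  idx_va <- (n_train + 1):nrow(comm)
  X <- comm; storage.mode(X) <- "double"
  out <- list(n_train = n_train, n_val = length(idx_va))
  if ("cks" %in% estimators) {
    if (is.null(w_grid)) w_grid <- default_w_grid(ncol(comm))
    sw <- kitchen_sweep(X[idx_tr, ], a[idx_tr], X[idx_va, ], a[idx_va],
                        w_grid = w_grid, f_grid = f_grid,
                        base_seed = base_seed, penalty = penalty)
    pred <- kitchen_predict(sw$model, X[idx_va, ])
    out$cks <- list(sweep = sw,
                    eval = evaluate(a[idx_va], pred),
                    predictions = data.frame(true = a[idx_va],
                                             predicted = pred))
  }
  if ("mpd" %in% estimators) {
    curves <- mpd_curves(dataset$tree, comm, grid = grid)
    tr_curves <- curves[idx_tr, , drop = FALSE]
    attr(tr_curves, "grid") <- grid
    mm <- fit_mpd_model(tr_curves, a[idx_tr])
    predm <- predict_mpd_model(mm, curves[idx_va, , drop = FALSE])
    out$mpd <- list(model = mm,
                    eval = evaluate(a[idx_va], predm),
                    predictions = data.frame(true = a[idx_va],
                                             predicted = predm))
  }
  out
}

#' Sensitivity experiments for alternative assembly and trait models
#'
#' Reproduces the sensitivity study designs at configurable scale:
#' \describe{
#'   \item{`"probabilistic"`}{communities of `k = 32` assembled with weight
#'     `exp(-lambda * d)` across a grid of `lambda` values (a ~ Normal(0, 1));
#'     reports the best CKS validation R-squared per `lambda`. All `lambda`
#'     levels share simulation random streams (common random numbers).}
#'   \item{`"covariance"`}{independent versus perfectly covarying traits,
#'     `k = 64`, probabilistic assembly with `lambda = 0.5`, trait-means
#'     optimum; reports both CKS evaluations.}
#'   \item{`"multi_a_mean"`/`"multi_a_max"`}{traits evolved on `n_effective`
#'     distinct effective trees (`lambda = 3`, `k = 32`); the estimator
#'     targets the mean or the max of the per-tree parameters.}
#'   \item{`"limiting_similarity"`}{a ~ Normal(0, 0.5), `k = 32`; both CKS
#'     and MPD-curve estimators.}
#' }
#'
#' @param variant One of the scenario names above.
#' @param tree Phylogeny to simulate on.
#' @param n_sims Simulations per condition.
#' @param n_train Training-split size.
#' @param lambda_grid Grid of exponential parameters (probabilistic variant).
#' @param n_effective Number of effective trees (multi-a variants).
#' @param w_grid,f_grid,base_seed,penalty CKS sweep settings.
#' @param seed Master seed for the simulations.
#' @return Variant-specific result list (see Details).
#' @export
run_sensitivity <- function(variant = c("probabilistic", "covariance",
                                        "multi_a_mean", "multi_a_max",
                                        "limiting_similarity"),
                            tree, n_sims = 4000, n_train = NULL,
                            lambda_grid = c(0.02, 0.08, 0.3, 1, 4),
                            n_effective = 2,
                            w_grid = c(4, 16, 64), f_grid = c(64, 256),
                            base_seed = 1, penalty = NULL, seed = 1) {
  variant <- match.arg(variant)
  if (variant == "probabilistic") {
    n_train <- n_train %||% round(0.75 * n_sims)
    rows <- lapply(lambda_grid, function(lam) {
      ds <- simulate_dataset(tree, n_sims, k = 32,
                             assembly = "probabilistic", lambda = lam,
                             a_sd = 1, optimum = "trait_means", seed = seed)
      rep <- run_comparison(ds, n_train, w_grid = w_grid, f_grid = f_grid,
                            base_seed = base_seed, penalty = penalty,
                            estimators = "cks")
      data.frame(lambda = lam, best_r2 = rep$cks$eval$r2,
                 adj_r2 = rep$cks$eval$adj_r2,
                 w = rep$cks$sweep$best$w, f = rep$cks$sweep$best$f)
    })
    return(list(variant = variant, table = do.call(rbind, rows)))
  }
  if (variant == "covariance") {
    n_train <- n_train %||% round(0.75 * n_sims)
    fit_one <- function(cov) {
      ds <- simulate_dataset(tree, n_sims, k = 64,
                             assembly = "probabilistic", lambda = 0.5,
                             a_sd = 1, covarying = cov,
                             optimum = "trait_means", seed = seed)
      run_comparison(ds, n_train, w_grid = w_grid, f_grid = f_grid,
                     base_seed = base_seed, penalty = penalty,
                     estimators = "cks")
    }
    return(list(variant = variant,
                independent = fit_one(FALSE),
                covarying = fit_one(TRUE)))
  }
  if (variant %in% c("multi_a_mean", "multi_a_max")) {
    n_train <- n_train %||% round(0.75 * n_sims)
    ds <- simulate_dataset(tree, n_sims, k = 32,
                           assembly = "probabilistic", lambda = 3,
                           a_sd = 1, n_effective = n_effective,
                           optimum = "trait_means", seed = seed)
    target <- if (variant == "multi_a_mean") rowMeans(ds$a_true)
              else apply(ds$a_true, 1, max)
    ds2 <- list(community = ds$community, a_true = target, tree = tree)
    rep <- run_comparison(ds2, n_train, w_grid = w_grid, f_grid = f_grid,
                          base_seed = base_seed, penalty = penalty,
                          estimators = "cks")
    return(list(variant = variant, n_effective = n_effective, report = rep))
  }
  # limiting similarity
  n_sims_ls <- if (missing(n_sims)) 2000 else n_sims
  n_train <- n_train %||% round(0.675 * n_sims_ls)
  ds <- simulate_dataset(tree, n_sims_ls, k = 32,
                         assembly = "limiting_similarity",
                         a_sd = 0.5, seed = seed)
  rep <- run_comparison(ds, n_train, w_grid = w_grid, f_grid = f_grid,
                        base_seed = base_seed, penalty = penalty,
                        estimators = c("cks", "mpd"))
  list(variant = variant, report = rep)
}

#' Estimate the evolutionary parameter of an observed community
#'
#' The empirical workflow: simulate trait-filtered training/validation
#' communities on the supplied tree with `k` equal to the observed community
#' size, sweep the kitchen sink hyperparameters, bootstrap the best model on
#' the observed presence/absence vector for a point estimate and 95%
#' interval, and fit an MPD-curve model for comparison.
#'
#' @param tree A `phylo` object or path to a Newick file; canonically
#'   ladderized before use.
#' @param membership A named 0/1 vector (or two-column data frame of tip
#'   label and state) covering every tip; 1 = community member.
#' @param n_sims Total simulations; the first `n_train` train the models.
#' @param n_train Training-split size (default 80% of `n_sims`).
#' @param a_mean,a_sd,a_bounds,bound_method Parameter distribution for the
#'   simulations (defaults follow the narrow, clamped regime appropriate for
#'   deep empirical trees).
#' @param n_traits,sigma2 Trait simulation settings.
#' @param w_grid,f_grid,base_seed,penalty CKS sweep settings.
#' @param B Bootstrap replicates for the confidence interval.
#' @param grid Transformation grid for MPD curves.
#' @param seed Master seed.
#' @return List with `cks` (sweep, bootstrap estimate and CI), `mpd`
#'   (model, validation evaluation and observed-community estimate), `k` and
#'   the simulated dataset parameters.
#' @export
estimate_empirical <- function(tree, membership, n_sims = 1000,
                               n_train = NULL, a_mean = 0, a_sd = 0.08,
                               a_bounds = c(-0.2, 0.2),
                               bound_method = "clamp",
                               n_traits = 10, sigma2 = 1,
                               w_grid = NULL, f_grid = c(64, 256),
                               base_seed = 1, penalty = NULL, B = 100,
                               grid = eb_grid(), seed = 1) {
  if (is.character(tree)) tree <- read_newick(tree)
  tree <- canonical_ladderize(tree)
  if (is.data.frame(membership)) {
    membership <- stats::setNames(membership[[2]], membership[[1]])
  }
  if (is.null(names(membership))) {
    stop("membership must be named by tip label")
  }
  unknown <- setdiff(names(membership), tree$tip.label)
  if (length(unknown) > 0) {
    stop("membership labels not in the tree: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  }
  obs <- align_community(membership, tree$tip.label)
  k <- sum(obs)
  if (k == 0 || k == length(obs)) {
    stop("degenerate community: all species ",
         if (k == 0) "absent" else "present")
  }
  if (k < 2) stop("observed community must contain at least 2 species")
  n_train <- n_train %||% round(0.8 * n_sims)
  ds <- simulate_dataset(tree, n_sims, k = k, assembly = "deterministic",
                         a_mean = a_mean, a_sd = a_sd, a_bounds = a_bounds,
                         bound_method = bound_method, n_traits = n_traits,
                         sigma2 = sigma2, optimum = "random_species",
                         seed = seed)
  X <- ds$community; storage.mode(X) <- "double"
  idx_tr <- seq_len(n_train)
  idx_va <- (n_train + 1):n_sims
  if (is.null(w_grid)) w_grid <- default_w_grid(length(tree$tip.label))
  sw <- kitchen_sweep(X[idx_tr, ], ds$a_true[idx_tr],
                      X[idx_va, ], ds$a_true[idx_va],
                      w_grid = w_grid, f_grid = f_grid,
                      base_seed = base_seed, penalty = penalty)
  boot <- bootstrap_estimate(X[idx_tr, ], ds$a_true[idx_tr],
                             as.numeric(obs),
                             norms = sw$model$norms, B = B,
                             penalty = sw$model$penalty,
                             seed = derive_seed(seed, 999))
  curves <- mpd_curves(tree, ds$community, grid = grid)
  tr_curves <- curves[idx_tr, , drop = FALSE]
  attr(tr_curves, "grid") <- grid
  mm <- fit_mpd_model(tr_curves, ds$a_true[idx_tr])
  mpd_val <- evaluate(ds$a_true[idx_va],
                      predict_mpd_model(mm, curves[idx_va, , drop = FALSE]))
  obs_curve <- mpd_curve(tree, obs, grid = grid)
  list(k = k,
       cks = list(sweep = sw, estimate = boot$estimate, ci = boot$ci,
                  bootstrap = boot),
       mpd = list(model = mm, eval = mpd_val,
                  estimate = predict_mpd_model(mm, obs_curve),
                  observed_curve = obs_curve),
       params = ds$params)
}
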