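#' Choose a trait-space optimum for community filtering
#'
#' Either the trait row of a uniformly drawn species (`"random_species"`) or
#' the per-trait means across all species (`"trait_means"`).
#'
#' @param traits A species x traits matrix.
#' @param mode `"random_species"` or `"trait_means"`.
#' @param seed Optional integer seed (used by `"random_species"`).
#' @return A numeric vector of length `ncol(traits)`.
#' @export
choose_optimum <- function(traits, mode = c("random_species", "trait_means"),
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(traits), nrow(traits) >= 1)
  if (mode == "trait_means") return(colMeans(traits))
  if (!is.null(seed)) set.seed(seed)
  as.numeric(traits[sample.int(nrow(traits), 1L), ])
}

euclid_to_optimum <- function(traits, optimum) {
  stopifnot(length(optimum) == ncol(traits))
  sqrt(colSums((t(traits) - optimum)^2))
}

#' Deterministic trait filtering
#'
#' The `k` species whose traits lie closest (Euclidean distance) to the
#' optimum are present; distance ties are broken by tip order.
#'
#' @param traits A species x traits matrix in tip order.
#' @param optimum Numeric optimum vector of length `ncol(traits)`.
#' @param k Community size (<= number of species).
#' @return A named 0/1 integer vector in tip order summing to `k`.
#' @export
filter_deterministic <- function(traits, optimum, k) {
  n <- nrow(traits)
  if (k > n) stop("k exceeds the number of species")
  d <- euclid_to_optimum(traits, optimum)
  sel <- order(d, seq_len(n))[seq_len(k)]
  membership <- integer(n)
  membership[sel] <- 1L
  names(membership) <- rownames(traits)
  membership
}

#' Probabilistic trait filtering
#'
#' Samples `k` species without replacement with selection weight
#' `exp(-lam * distance)` to the optimum, by sequential weighted sampling
#' (draw proportional to weight, remove, renormalize). Implemented as an
#' exponential race in the log domain (keys `log(E_i) + lam * d_i`, take the
#' `k` smallest, with `E_i` i.i.d. standard exponentials), which is exactly
#' equivalent and immune to weight underflow. `lam = 0` gives uniform
#' sampling; large `lam` converges to [filter_deterministic()].
#'
#' @inheritParams filter_deterministic
#' @param lam Exponential rate on trait distance (>= 0).
#' @param seed Optional integer seed.
#' @return A named 0/1 integer vector in tip order summing to `k`.
#' @export
filter_probabilistic <- function(traits, optimum, k, lam, seed = NULL) {
  n <- nrow(traits)
  if (k > n) stop("k exceeds the number of species")
  if (!is.finite(lam) || lam < 0) stop("lam must be finite and >= 0")
  d <- euclid_to_optimum(traits, optimum)
  logpen <- lam * d
  if (any(!is.finite(logpen))) {
    stop("non-finite selection weights; truncate the transformation ",
         "parameters or trait distances")
  }
  if (!is.null(seed)) set.seed(seed)
  key <- log(stats::rexp(n)) + logpen
  sel <- order(key, seq_len(n))[seq_len(k)]
  membership <- integer(n)
  membership[sel] <- 1L
  names(membership) <- rownames(traits)
  membership
}

#' Limiting-similarity community assembly
#'
#' Sequentially removes the species most similar in trait space to the
#' remaining species until `k` remain, producing trait (and, for conserved
#' traits, phylogenetic) overdispersion. The similarity criterion is either
#' the summed Euclidean distance to all remaining species (default,
#' `"sum"`: the species with the smallest sum is removed) or the
#' nearest-neighbour distance (`"nearest"`). The criterion is recomputed
#' after every removal; ties are broken by tip order.
#'
#' @inheritParams filter_deterministic
#' @param k Number of surviving species (< number of species).
#' @param criterion `"sum"` or `"nearest"`.
#' @return A named 0/1 integer vector in tip order summing to `k`.
#' @export
limiting_similarity <- function(traits, k, criterion = c("sum", "nearest")) {
  criterion <- match.arg(criterion)
  n <- nrow(traits)
  if (k >= n) stop("k must be smaller than the number of species")
  D <- as.matrix(stats::dist(traits))
  alive <- rep(TRUE, n)
  if (criterion == "sum") {
    crit <- rowSums(D)
    for (drop in seq_len(n - k)) {
      i <- which(alive)[which.min(crit[alive])]
      alive[i] <- FALSE
      crit <- crit - D[, i]
    }
  } else {
    diag(D) <- Inf
    for (drop in seq_len(n - k)) {
      idx <- which(alive)
      nn <- apply(D[idx, idx, drop = FALSE], 1, min)
      i <- idx[which.min(nn)]
      alive[i] <- FALSE
    }
  }
  membership <- as.integer(alive)
  names(membership) <- rownames(traits)
  membership
}
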