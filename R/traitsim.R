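#' Simulate continuous traits under Brownian motion on a phylogeny
#'
#' Each trait is an independent Brownian-motion realization along the tree:
#' a child's value is its parent's value plus a Normal(0, `sigma2` * branch
#' length) increment. Traits use independent random streams derived from
#' `seed`, so increasing `n_traits` leaves earlier columns unchanged.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param n_traits Number of independent traits (>= 1).
#' @param sigma2 Brownian rate (variance accumulated per unit branch length).
#' @param root_state Trait value at the root.
#' @param seed Optional integer seed.
#' @return A numeric matrix (tips x traits) with row names equal to
#'   `tree$tip.label`, in tip order.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' simulate_bm(tr, n_traits = 3, seed = 1)
#' @export
simulate_bm <- function(tree, n_traits = 1, sigma2 = 1, root_state = 0,
                        seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_traits >= 1, sigma2 > 0)
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  ne <- nrow(tr$edge)
  Z <- matrix(0, ne, n_traits)
  for (j in seq_len(n_traits)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, j))
    Z[, j] <- stats::rnorm(ne)
  }
  Z <- Z * sqrt(sigma2 * tr$edge.length)
  X <- matrix(root_state, n + tr$Nnode, n_traits)
  ep <- tr$edge[, 1]; ec <- tr$edge[, 2]
  for (e in seq_len(ne)) {
    X[ec[e], ] <- X[ep[e], ] + Z[e, ]
  }
  out <- X[seq_len(n), , drop = FALSE]
  rownames(out) <- tr$tip.label
  out
}

#' Simulate traits on an effective (transformed) tree
#'
#' Composition of [apply_transform()] and [simulate_bm()]: the tree is first
#' rescaled by the given transformation parameter and traits are then evolved
#' by Brownian motion on the transformed branch lengths.
#'
#' @inheritParams simulate_bm
#' @param transform A [transform_param()] describing the effective tree.
#' @return A tips x traits matrix in tip order.
#' @export
simulate_on_effective_tree <- function(tree, transform, n_traits = 1,
                                       sigma2 = 1, root_state = 0,
                                       seed = NULL) {
  simulate_bm(apply_transform(tree, transform), n_traits = n_traits,
              sigma2 = sigma2, root_state = root_state, seed = seed)
}

#' Simulate perfectly covarying traits
#'
#' Evolves a single Brownian trait and replicates it `n_traits` times, so a
#' species carries `n_traits` identical values: the extreme of trait
#' covariance. Inter-species Euclidean distances are then `sqrt(n_traits)`
#' times the single-trait distances.
#'
#' @inheritParams simulate_bm
#' @return A tips x traits matrix whose columns are identical.
#' @export
simulate_covarying <- function(tree, n_traits = 1, sigma2 = 1,
                               root_state = 0, seed = NULL) {
  x <- simulate_bm(tree, n_traits = 1, sigma2 = sigma2,
                   root_state = root_state, seed = seed)
  out <- x[, rep(1, n_traits), drop = FALSE]
  colnames(out) <- NULL
  out
}

#' Simulate trait blocks on multiple effective trees
#'
#' Evolves `traits_per_a` traits on each of several exponentially transformed
#' effective trees, one block per value of `a_values`, and binds the blocks
#' column-wise. Used to study communities structured by traits with
#' heterogeneous evolutionary histories.
#'
#' @inheritParams simulate_bm
#' @param a_values Vector of exponential transformation parameters.
#' @param traits_per_a Number of traits per effective tree.
#' @return A tips x (`length(a_values)` * `traits_per_a`) matrix with an
#'   `"a_values"` attribute recording the block parameters.
#' @export
simulate_multi_a <- function(tree, a_values, traits_per_a, sigma2 = 1,
                             root_state = 0, seed = NULL) {
  stopifnot(length(a_values) >= 1, traits_per_a >= 1)
  blocks <- lapply(seq_along(a_values), function(b) {
    simulate_on_effective_tree(
      tree, transform_param("EB", a_values[b]),
      n_traits = traits_per_a, sigma2 = sigma2, root_state = root_state,
      seed = if (is.null(seed)) NULL else derive_seed(seed, 1000 + b))
  })
  out <- do.call(cbind, blocks)
  attr(out, "a_values") <- a_values
  out
}
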