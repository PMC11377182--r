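#' Simulate a birth-death phylogeny with a fixed number of extant tips
#'
#' Runs a forward (Gillespie) birth-death simulation until the number of
#' extant lineages first reaches `n_tips`, places the present just before the
#' next would-be event, prunes extinct lineages, and returns the resulting
#' ultrametric tree in canonical tip order (see [canonical_ladderize()]).
#' Simulations that go extinct before reaching `n_tips` are retried up to
#' `max_tries` times.
#'
#' @param n_tips Number of extant tips required (>= 3).
#' @param birth Speciation rate (> death).
#' @param death Extinction rate (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @param max_tries Maximum number of restart attempts after extinction.
#' @return An ultrametric `phylo` object with exactly `n_tips` tips.
#' @examples
#' tr <- simulate_birth_death(16, birth = 0.8, death = 0.2, seed = 1)
#' @export
simulate_birth_death <- function(n_tips, birth, death = 0, seed = NULL,
                                 max_tries = 1000) {
  stopifnot(n_tips >= 3, birth > death, death >= 0)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    tr <- bd_forward_once(n_tips, birth, death)
    if (!is.null(tr)) return(canonical_ladderize(tr))
  }
  stop("birth-death simulation went extinct in all ", max_tries, " attempts")
}

# One forward pass; returns NULL if the process dies before reaching n_tips.
# Lineages are recorded as (parent lineage, start time, end time); each
# lineage maps to one edge of the final tree.
bd_forward_once <- function(n_tips, birth, death) {
  cap <- 20L * n_tips + 200L
  parent <- integer(cap)      # parent lineage id (0 for the two crown lineages)
  t_start <- numeric(cap)
  t_end <- rep(NA_real_, cap)
  is_split <- logical(cap)    # TRUE if the lineage ended by speciating
  # crown start: two lineages from the root at time 0
  n_lin <- 2L
  parent[1:2] <- 0L
  alive <- c(1L, 2L)
  t <- 0
  max_events <- 500L * n_tips + 5000L
  for (ev in seq_len(max_events)) {
    n_alive <- length(alive)
    if (n_alive == 0L) return(NULL)
    dt <- stats::rexp(1, (birth + death) * n_alive)
    if (n_alive == n_tips) {
      # stop just before the next event would occur
      t_end[alive] <- t + dt
      return(bd_build_phylo(parent[1:n_lin], t_start[1:n_lin],
                            t_end[1:n_lin], is_split[1:n_lin], alive))
    }
    t <- t + dt
    who <- alive[sample.int(n_alive, 1L)]
    if (stats::runif(1) < birth / (birth + death)) {
      # speciation: lineage `who` ends, two children begin
      t_end[who] <- t
      is_split[who] <- TRUE
      if (n_lin + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(t_start) <- cap
        t_end <- c(t_end, rep(NA_real_, cap - length(t_end)))
        length(is_split) <- cap
      }
      kids <- n_lin + 1:2
      parent[kids] <- who
      t_start[kids] <- t
      n_lin <- n_lin + 2L
      alive <- c(alive[alive != who], kids)
    } else {
      t_end[who] <- t
      alive <- alive[alive != who]
    }
  }
  NULL
}

bd_build_phylo <- function(parent, t_start, t_end, is_split, alive) {
  n_lin <- length(parent)
  is_tip <- !is_split
  tip_ids <- which(is_tip)
  n_tip <- length(tip_ids)
  # node numbering: tips 1..n_tip, root n_tip+1, then one node per split lineage
  node_of <- integer(n_lin)          # node at the *end* of each lineage
  node_of[tip_ids] <- seq_len(n_tip)
  split_ids <- which(is_split)
  node_of[split_ids] <- n_tip + 1L + seq_along(split_ids)
  root_node <- n_tip + 1L
  start_node <- ifelse(parent == 0L, root_node, node_of[pmax(parent, 1L)])
  edge <- cbind(start_node, node_of)
  edge_length <- t_end - t_start
  labels <- character(n_tip)
  labels[node_of[tip_ids]] <- ifelse(tip_ids %in% alive,
                                     paste0("t", node_of[tip_ids]),
                                     paste0("x", node_of[tip_ids]))
  tr <- list(edge = edge, edge.length = edge_length,
             tip.label = labels, Nnode = length(split_ids) + 1L)
  class(tr) <- "phylo"
  extinct <- grep("^x", labels, value = TRUE)
  if (length(extinct) > 0) {
    tr <- ape::drop.tip(tr, extinct)
    if (is.null(tr)) return(NULL)
  }
  tr$tip.label <- paste0("t", seq_along(tr$tip.label))
  tr
}

#' Canonical ladderization of a phylogeny
#'
#' Rotates every internal node so children are ordered by descendant tip count
#' (smallest clade first), breaking ties by the smallest tip label in the
#' clade, and renumbers tips left-to-right in the resulting traversal. Any two
#' representations of the same tree (e.g. Newick strings with rotated clades)
#' yield an identical tip ordering, so community vectors aligned to tip order
#' are reproducible across runs and file round trips.
#'
#' @param tree A `phylo` object.
#' @return The same tree with canonically ordered and renumbered tips.
#' @export
canonical_ladderize <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  elen <- rep(NA_real_, nn)
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  # postorder accumulation of clade size and smallest tip label
  size <- integer(nn); minlab <- character(nn)
  size[1:n] <- 1L; minlab[1:n] <- tree$tip.label
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    size[p] <- size[p] + size[ch]
    minlab[p] <- if (minlab[p] == "" || is.na(minlab[p]) || nchar(minlab[p]) == 0) {
      minlab[ch]
    } else {
      min(minlab[p], minlab[ch])
    }
  }
  root <- n + 1L
  # iterative DFS with children sorted by (size, minlab)
  new_edge <- matrix(0L, nrow(tree$edge), 2)
  new_len <- numeric(nrow(tree$edge))
  new_id <- integer(nn)
  tip_seq <- character(n)
  next_tip <- 1L; next_int <- n + 1L; next_edge <- 1L
  new_id[root] <- next_int; next_int <- next_int + 1L
  stack <- list(list(node = root, ki = 0L))
  order_kids <- function(v) v[order(size[v], minlab[v], method = "radix")]
  sorted <- vector("list", nn)
  sorted[[root]] <- order_kids(kids[[root]])
  depth <- 1L
  while (depth > 0L) {
    fr <- stack[[depth]]
    node <- fr$node
    if (fr$ki >= length(sorted[[node]])) { depth <- depth - 1L; next }
    stack[[depth]]$ki <- fr$ki + 1L
    ch <- sorted[[node]][fr$ki + 1L]
    if (ch <= n) {
      new_id[ch] <- next_tip
      tip_seq[next_tip] <- tree$tip.label[ch]
      next_tip <- next_tip + 1L
    } else {
      new_id[ch] <- next_int; next_int <- next_int + 1L
      sorted[[ch]] <- order_kids(kids[[ch]])
      depth <- depth + 1L
      if (depth > length(stack)) stack[[depth]] <- list(node = ch, ki = 0L)
      else stack[[depth]] <- list(node = ch, ki = 0L)
    }
    new_edge[next_edge, ] <- c(new_id[node], new_id[ch])
    new_len[next_edge] <- elen[ch]
    next_edge <- next_edge + 1L
  }
  out <- list(edge = new_edge,
              tip.label = tip_seq,
              Nnode = tree$Nnode)
  if (!is.null(tree$edge.length)) out$edge.length <- new_len
  class(out) <- "phylo"
  attr(out, "order") <- "cladewise"
  out
}

#' Maximum root-to-tip path length of a rooted tree
#'
#' @param tree A `phylo` object.
#' @return The depth (time units) of the deepest tip.
#' @export
tree_depth <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  h <- ape::node.depth.edgelength(tree)
  max(h[seq_along(tree$tip.label)])
}

#' Exponential (early/late burst) branch-length transformation
#'
#' Rescales each branch spanning absolute times `[t1, t2]` from the root to
#' length `(exp(a*t2) - exp(a*t1)) / a`, i.e. the accumulated variance of a
#' Brownian process whose rate changes through time as `exp(a*t)`. Negative
#' `a` concentrates evolution early (a stemmy, early-burst tree), positive `a`
#' late (a tippy, late-burst tree), and `a = 0` (or `|a| < 1e-12`) returns the
#' tree unchanged.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param a Exponential rate-change parameter (any finite real).
#' @return The transformed tree (topology unchanged).
#' @export
eb_rescale <- function(tree, a) {
  stopifnot(inherits(tree, "phylo"), is.finite(a))
  if (abs(a) < 1e-12) return(tree)
  h <- ape::node.depth.edgelength(tree)
  t1 <- h[tree$edge[, 1]]
  t2 <- h[tree$edge[, 2]]
  # (exp(a*t2) - exp(a*t1))/a, written via expm1 so tiny |a| stays accurate
  tree$edge.length <- exp(a * t1) * expm1(a * (t2 - t1)) / a
  tree
}

#' Delta (node-depth power) branch-length transformation
#'
#' Raises node heights measured from the root to the power `delta`. With
#' `rescale_depth = TRUE` (default) all heights are then multiplied by a
#' common factor so the total depth equals the original depth; `delta = 1` is
#' the identity, `delta < 1` yields a stemmy tree and `delta > 1` a tippy
#' tree. Requires an ultrametric tree.
#'
#' @param tree An ultrametric `phylo` object.
#' @param delta Positive power applied to node heights.
#' @param rescale_depth Rescale so total depth is preserved (default `TRUE`).
#' @return The transformed tree (topology unchanged).
#' @export
delta_rescale <- function(tree, delta, rescale_depth = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(delta) || delta <= 0) stop("delta must be > 0")
  h <- ape::node.depth.edgelength(tree)
  n <- length(tree$tip.label)
  H <- max(h[1:n])
  if (max(abs(h[1:n] - H)) > 1e-6 * max(H, 1)) {
    stop("delta_rescale requires an ultrametric tree")
  }
  hh <- h^delta
  if (rescale_depth) hh <- hh * H^(1 - delta)
  tree$edge.length <- hh[tree$edge[, 2]] - hh[tree$edge[, 1]]
  tree
}

#' Transformation parameter for effective trees
#'
#' A small container pairing a transformation model (`"EB"` or `"delta"`)
#' with its parameter value.
#'
#' @param model `"EB"` (exponential rate change, any real value) or `"delta"`
#'   (node-depth power, value > 0).
#' @param value The parameter value.
#' @return An object of class `transform_param`.
#' @export
transform_param <- function(model = c("EB", "delta"), value) {
  model <- match.arg(model)
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  if (model == "delta" && value <= 0) stop("delta must be > 0")
  structure(list(model = model, value = value), class = "transform_param")
}

#' Apply a transformation parameter to a tree
#'
#' @param tree A `phylo` object.
#' @param transform A [transform_param()].
#' @return The transformed tree.
#' @export
apply_transform <- function(tree, transform) {
  stopifnot(inherits(transform, "transform_param"))
  switch(transform$model,
         EB = eb_rescale(tree, transform$value),
         delta = delta_rescale(tree, transform$value))
}

#' Patristic (cophenetic) distance matrix in tip order
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return A symmetric matrix of path-length distances between tips, rows and
#'   columns ordered as `tree$tip.label`.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Read and write Newick trees
#'
#' `read_newick()` accepts a Newick string or a path to a file containing one;
#' tips keep their left-to-right order of appearance. `write_newick()` emits a
#' Newick string (and optionally writes it to `file`); a write/read/write
#' round trip is exact.
#'
#' @param x A Newick string or path to a Newick file.
#' @param tree A `phylo` object.
#' @param file Optional output path.
#' @param digits Number of significant digits for branch lengths on write.
#' @return `read_newick()` a `phylo`; `write_newick()` the Newick string,
#'   invisibly when `file` is given.
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  text <- if (!grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  validate_newick(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick: parser failed on input")
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length)) {
    stop("malformed newick: missing branch length")
  }
  tr
}

# Cheap structural scan so parse errors can name a character position.
validate_newick <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed newick: unbalanced ')' at character ", i)
    }
  }
  if (in_quote) stop("malformed newick: unterminated quoted label")
  if (depth != 0L) {
    stop("malformed newick: ", depth, " unclosed '(' at character ",
         length(chars))
  }
  if (!grepl(";", text)) stop("malformed newick: missing terminating ';'")
  invisible(TRUE)
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
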