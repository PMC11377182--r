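# Independent oracle implementations used to cross-check the package. These
# deliberately use naive algorithms and data structures distinct from the
# implementation paths they validate.

# Brute-force patristic distances: walk each tip's edge path to the root and
# sum the symmetric difference of the two paths.
brute_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- n + 1L
  path_edges <- function(tip) {
    out <- integer(0)
    node <- tip
    while (node != root) {
      out <- c(out, node)
      node <- parent[node]
    }
    out
  }
  paths <- lapply(seq_len(n), path_edges)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(paths[[i]], paths[[j]])
      d <- sum(elen[setdiff(paths[[i]], shared)]) +
           sum(elen[setdiff(paths[[j]], shared)])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

brute_depth <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- n + 1L
  max(vapply(seq_len(n), function(tip) {
    s <- 0; node <- tip
    while (node != root) { s <- s + elen[node]; node <- parent[node] }
    s
  }, numeric(1)))
}

# Independent forward birth-death run reporting the crown depth of the pruned
# (extant-only) tree; mirrors the package's stop convention (present placed at
# the would-be next event once n extant lineages exist) but shares no code:
# it tracks lineages as rows of a grow-as-needed data frame and finds the
# pruned crown by checking which splits have extant descendants on both sides.
oracle_bd_depth <- function(n_tips, birth, death) {
  repeat {
    lin <- data.frame(parent = c(0L, 0L), t0 = c(0, 0), t1 = NA_real_,
                      kind = NA_character_, stringsAsFactors = FALSE)
    alive <- c(1L, 2L)
    t <- 0
    ok <- TRUE
    while (TRUE) {
      if (length(alive) == 0L) { ok <- FALSE; break }
      dt <- stats::rexp(1, (birth + death) * length(alive))
      if (length(alive) == n_tips) {
        lin$t1[alive] <- t + dt
        lin$kind[alive] <- "extant"
        break
      }
      t <- t + dt
      who <- alive[sample.int(length(alive), 1L)]
      lin$t1[who] <- t
      if (stats::runif(1) < birth / (birth + death)) {
        lin$kind[who] <- "split"
        lin <- rbind(lin, data.frame(parent = c(who, who), t0 = t,
                                     t1 = NA_real_, kind = NA_character_))
        alive <- c(setdiff(alive, who), nrow(lin) - 1L, nrow(lin))
      } else {
        lin$kind[who] <- "extinct"
        alive <- setdiff(alive, who)
      }
    }
    if (!ok) next
    present <- max(lin$t1[lin$kind == "extant"])
    # does lineage i have at least one extant descendant (incl. itself)?
    has_extant <- lin$kind == "extant"
    repeat {
      up <- unique(lin$parent[has_extant & lin$parent > 0L])
      newly <- setdiff(up, which(has_extant))
      if (length(newly) == 0L) break
      has_extant[newly] <- TRUE
    }
    # pruned crown = earliest split whose two children both lead to extant tips
    kids_of <- split(seq_len(nrow(lin)), lin$parent)
    crown_t <- 0
    node <- 0L  # start at the origin (the two initial lineages)
    repeat {
      kids <- kids_of[[as.character(node)]]
      live <- kids[has_extant[kids]]
      if (length(live) >= 2L) break
      node <- live
      crown_t <- lin$t1[node]
      if (lin$kind[node] == "extant") break
    }
    return(present - crown_t)
  }
}

# Naive triple-loop Convolutional Kitchen Sink.
naive_kitchen_sink <- function(X, norms) {
  w <- nrow(norms); f <- ncol(norms)
  n <- nrow(X); l <- ncol(X)
  nwin <- l - w + 1
  out <- matrix(0, n, f)
  for (i in seq_len(n)) {
    for (j in seq_len(f)) {
      acc <- 0
      for (p in seq_len(nwin)) {
        v <- sum(X[i, p:(p + w - 1)] * norms[, j])
        acc <- acc + max(v, 0)
      }
      out[i, j] <- acc / nwin
    }
  }
  out
}

# Exact inclusion probabilities of sequential weighted sampling without
# replacement (draw proportional to w, remove, renormalize), by enumerating
# every ordered selection of k items.
enum_seq_sampling <- function(w, k) {
  n <- length(w)
  incl <- numeric(n)
  recurse <- function(remaining, prob, chosen) {
    if (length(chosen) == k) {
      incl[chosen] <<- incl[chosen] + prob
      return(invisible(NULL))
    }
    tot <- sum(w[remaining])
    for (i in remaining) {
      recurse(setdiff(remaining, i), prob * w[i] / tot, c(chosen, i))
    }
  }
  recurse(seq_len(n), 1, integer(0))
  incl
}

# A small fixed ultrametric test tree.
toy_tree <- function() read_newick("((A:1,B:1):1,C:2);")
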