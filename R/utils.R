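# Internal helpers shared across modules.

# Mix a master seed with one or more stream indices into a new 32-bit seed.
# Uses the minstd multiplier for cheap, well-spread mixing; values stay in
# [0, 2^31 - 2] so they are always valid `set.seed()` inputs.
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) {
    h <- (h * 48271 + (as.numeric(k) %% 2147483647) + 11) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a community to a named 0/1 integer vector aligned with `tip_labels`.
align_community <- function(community, tip_labels) {
  if (!is.null(names(community))) {
    missing <- setdiff(tip_labels, names(community))
    if (length(missing) > 0) {
      stop("community is missing tips: ", paste(missing, collapse = ", "))
    }
    community <- community[tip_labels]
  } else if (length(community) != length(tip_labels)) {
    stop("unnamed community vector must have one entry per tip")
  }
  out <- as.integer(community != 0)
  names(out) <- tip_labels
  out
}
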