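test_that("mpd matches hand values and a brute-force pair loop", {
  D2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(mpd(D2, c(A = 1, B = 1)), 2)
  D <- cophenetic_distances(toy_tree())
  expect_equal(mpd(D, c(A = 1, B = 1, C = 1)), 10 / 3)
  expect_error(mpd(D, c(A = 1, B = 0, C = 0)), "at least 2")
  set.seed(1)
  for (i in 1:20) {
    tr <- simulate_birth_death(12, 0.8, 0.2, seed = 300 + i)
    Dr <- cophenetic_distances(tr)
    comm <- as.integer(seq_len(12) %in% sample(12, 5))
    names(comm) <- tr$tip.label
    idx <- which(comm == 1)
    acc <- 0; np <- 0
    for (a in idx) for (b in idx) if (a < b) { acc <- acc + Dr[a, b]; np <- np + 1 }
    expect_equal(mpd(Dr, comm), acc / np, tolerance = 1e-12)
  }
  # invariance under consistent permutation of tips
  tr <- simulate_birth_death(10, 0.8, 0.2, seed = 5)
  Dr <- cophenetic_distances(tr)
  comm <- stats::setNames(as.integer(seq_len(10) <= 4), tr$tip.label)
  perm <- sample(10)
  expect_equal(mpd(Dr[perm, perm], comm[perm]), mpd(Dr, comm))
})

test_that("mpd agrees with picante on a community matrix", {
  skip_if_not_installed("picante")
  tr <- simulate_birth_death(16, 0.8, 0.2, seed = 7)
  D <- cophenetic_distances(tr)
  comm <- matrix(0, 3, 16, dimnames = list(NULL, tr$tip.label))
  set.seed(2)
  for (r in 1:3) comm[r, sample(16, 6)] <- 1
  mine <- apply(comm, 1, function(v) mpd(D, v))
  theirs <- picante::mpd(comm, D)
  expect_equal(unname(mine), unname(theirs), tolerance = 1e-10)
})

test_that("ses-mpd standardizes against the random-draw null with both null modes", {
  tr <- simulate_birth_death(12, 0.8, 0.2, seed = 9)
  D <- cophenetic_distances(tr)
  k <- 5
  mom <- phylosink:::mpd_null_moments(D, k)
  set.seed(3)
  draws <- vapply(1:20000, function(i) {
    idx <- sample(12, k); sub <- D[idx, idx]; mean(sub[upper.tri(sub)])
  }, numeric(1))
  expect_lt(abs(mom$mean - mean(draws)), 4 * stats::sd(draws) / sqrt(20000))
  expect_lt(abs(mom$sd - stats::sd(draws)) / mom$sd, 0.05)
  comm <- stats::setNames(as.integer(seq_len(12) <= k), tr$tip.label)
  z_an <- ses_mpd(D, comm, null = "analytic")
  z_pe <- ses_mpd(D, comm, n_null = 5000, seed = 4, null = "permutation")
  expect_lt(abs(z_an - z_pe), 0.25)
  # star tree: zero null variance
  Ds <- cophenetic_distances(read_newick("(A:1,B:1,C:1,D:1);"))
  expect_warning(z0 <- ses_mpd(Ds, c(A = 1, B = 1, C = 0, D = 0)), "zero")
  expect_equal(z0, 0)
  # whole-pool community equals every null draw
  full <- stats::setNames(rep(1L, 12), tr$tip.label)
  expect_warning(zf <- ses_mpd(D, full, n_null = 50, seed = 5), "zero")
  expect_equal(zf, 0)
})

test_that("a clustered cherry pair is detected as phylogenetically clustered", {
  tr <- simulate_birth_death(16, 0.8, 0.2, seed = 13)
  D <- cophenetic_distances(tr)
  # the two tips with the smallest pairwise distance
  off <- D; diag(off) <- Inf
  pair <- which(off == min(off), arr.ind = TRUE)[1, ]
  comm <- integer(16); comm[pair] <- 1L; names(comm) <- tr$tip.label
  expect_lt(ses_mpd(D, comm, null = "analytic"), 0)
  neg <- mean(vapply(1:50, function(i) {
    ses_mpd(D, comm, n_null = 199, seed = i) < 0
  }, logical(1)))
  expect_gte(neg, 0.95)
})

test_that("ses-mpd of uniformly random communities is centered on zero", {
  tr <- simulate_birth_death(16, 0.8, 0.2, seed = 17)
  D <- cophenetic_distances(tr)
  set.seed(6)
  z <- vapply(1:800, function(i) {
    comm <- integer(16); comm[sample(16, 6)] <- 1L
    names(comm) <- tr$tip.label
    ses_mpd(D, comm, null = "analytic")
  }, numeric(1))
  expect_lt(abs(mean(z)), 3 * stats::sd(z) / sqrt(800))
})

test_that("mpd curves follow the default 81-point grid and the identity grid point", {
  g <- eb_grid()
  expect_length(g$values, 81)
  expect_true(!is.unsorted(g$values, strictly = TRUE))
  expect_equal(sum(abs(g$values) <= 1 + 1e-9), 41)  # 0.05 steps inside [-1, 1]
  tr <- simulate_birth_death(24, 0.8, 0.2, seed = 19)
  comm <- stats::setNames(as.integer(seq_len(24) <= 8), tr$tip.label)
  cv <- mpd_curve(tr, comm)
  expect_s3_class(cv, "mpd_curve")
  expect_length(cv$values, 81)
  i0 <- which(cv$grid$values == 0)
  expect_equal(cv$values[i0],
               ses_mpd(cophenetic_distances(tr), comm, null = "analytic"),
               tolerance = 1e-10)
  # batch curves equal per-community curves
  comm2 <- stats::setNames(as.integer(seq_len(24) > 16), tr$tip.label)
  M <- mpd_curves(tr, rbind(comm, comm2))
  expect_equal(M[1, ], cv$values, tolerance = 1e-12)
  expect_equal(M[2, ], mpd_curve(tr, comm2)$values, tolerance = 1e-12)
  # delta grid is positive and the delta identity point matches too
  dg <- delta_grid()
  expect_true(all(dg$values > 0))
  cvd <- mpd_curve(tr, comm, grid = dg)
  i1 <- which(abs(dg$values - 1) < 1e-9)
  expect_equal(cvd$values[i1], cv$values[i0], tolerance = 1e-10)
})

test_that("curve minimum location shifts with the generating parameter", {
  tr <- simulate_birth_death(64, 0.8, 0.2, seed = 5)
  argmin_at <- function(a, i) {
    traits <- simulate_on_effective_tree(tr, transform_param("EB", a), 10,
                                         seed = 100 + i)
    comm <- filter_deterministic(traits,
                                 choose_optimum(traits, "random_species",
                                                seed = 200 + i), 30)
    curve_minimum(mpd_curve(tr, comm))
  }
  lo <- vapply(1:15, function(i) argmin_at(-1, i), numeric(1))
  hi <- vapply(1:15, function(i) argmin_at(1, i), numeric(1))
  expect_lt(mean(lo), mean(hi))
  expect_gt(mean(hi > 0), 0.6)
})

test_that("curve minimum obeys the tie rule and matches an exhaustive scan", {
  g <- transform_grid("EB", c(-1, 0, 1, 2))
  cv <- structure(list(grid = g, values = c(3, 1, 2, 4)), class = "mpd_curve")
  expect_equal(curve_minimum(cv), 0)
  flat <- structure(list(grid = g, values = rep(2, 4)), class = "mpd_curve")
  expect_equal(curve_minimum(flat), -1)
  set.seed(8)
  for (i in 1:20) {
    v <- rnorm(81)
    cv <- structure(list(grid = eb_grid(), values = v), class = "mpd_curve")
    expect_equal(curve_minimum(cv), eb_grid()$values[which.min(v)])
  }
})

test_that("the linear curve model recovers an exact linear functional and round-trips", {
  set.seed(9)
  n <- 120; p <- 81
  curves <- matrix(rnorm(n * p), n, p)
  attr(curves, "grid") <- eb_grid()
  beta <- rnorm(p, sd = 0.1)
  a <- drop(0.3 + curves %*% beta)
  m <- fit_mpd_model(curves, a)
  expect_lt(max(abs(predict_mpd_model(m, curves) - a)), 1e-6)
  newc <- rnorm(p)
  expect_equal(predict_mpd_model(m, newc), 0.3 + sum(newc * beta),
               tolerance = 1e-6)
  # under-determined fits fall back to ridge with a warning
  expect_warning(fit_mpd_model(curves[1:40, ], a[1:40]), "ridge")
  # serialization round trip
  f <- tempfile(fileext = ".tsv")
  write_mpd_model(m, f)
  m2 <- read_mpd_model(f)
  expect_equal(predict_mpd_model(m2, newc), predict_mpd_model(m, newc),
               tolerance = 1e-10)
})
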