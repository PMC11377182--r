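test_that("normal matrices are reproducible with standard-normal entries", {
  n1 <- make_norms(6, 10, seed = 1)
  expect_equal(dim(n1), c(6L, 10L))
  expect_identical(unclass(n1), unclass(make_norms(6, 10, seed = 1)))
  expect_false(identical(unclass(n1), unclass(make_norms(6, 10, seed = 2))))
  big <- make_norms(1000, 1000, seed = 3)
  expect_lt(abs(mean(big)), 4e-3)
  expect_lt(abs(stats::sd(big) - 1), 4e-3)
})

test_that("window gathering produces overlapping unpadded windows", {
  x <- 1:8
  w6 <- gather_windows(x, 6)
  expect_equal(dim(w6), c(3L, 6L))
  expect_equal(w6[1, ], 1:6)
  expect_equal(w6[2, ], 2:7)
  expect_equal(w6[3, ], 3:8)
  expect_equal(gather_windows(x, 8), matrix(1:8, nrow = 1))
  expect_equal(gather_windows(x, 1), matrix(1:8, ncol = 1))
  expect_error(gather_windows(x, 9), "exceeds")
})

test_that("clamp is an idempotent rectifier", {
  expect_equal(clamp(c(-1, 2, 0)), c(0, 2, 0))
  m <- matrix(c(1, 5, 0, 3), 2)
  expect_equal(clamp(m), m)
  r <- matrix(rnorm(30), 5)
  expect_equal(clamp(clamp(r)), clamp(r))
})

test_that("kitchen sink matches hand values and the naive triple-loop oracle", {
  ones <- matrix(1, 4, 5)
  X1 <- matrix(1, 3, 10)
  expect_equal(kitchen_sink(X1, ones), matrix(4, 3, 5))
  expect_equal(kitchen_sink(matrix(0, 2, 10), make_norms(4, 6, 1)),
               matrix(0, 2, 6))
  set.seed(10)
  for (i in 1:100) {
    n <- sample(1:20, 1); l <- sample(4:64, 1)
    w <- sample(seq_len(min(16, l)), 1); f <- sample(1:32, 1)
    X <- matrix(rnorm(n * l), n, l)
    nm <- matrix(rnorm(w * f), w, f)
    expect_equal(kitchen_sink(X, nm), naive_kitchen_sink(X, nm),
                 tolerance = 1e-10)
  }
})

test_that("ridge fitting reduces to ols at zero penalty and to the mean at huge penalty", {
  set.seed(11)
  X <- matrix(rnorm(60 * 12), 60, 12)
  y <- rnorm(60)
  nm <- make_norms(3, 8, seed = 5)
  m0 <- fit_cks(X, y, norms = nm, penalty = 0)
  feats <- kitchen_sink(X, nm)
  ols <- stats::lm(y ~ feats)
  expect_equal(m0$beta, unname(stats::coef(ols)[-1]), tolerance = 1e-6)
  expect_equal(kitchen_predict(m0, X, clamp_range = FALSE),
               unname(stats::fitted(ols)), tolerance = 1e-6)
  mInf <- fit_cks(X, y, norms = nm, penalty = 1e12)
  expect_equal(kitchen_predict(mInf, X, clamp_range = FALSE),
               rep(mean(y), 60), tolerance = 1e-4)
  yc <- rep(2.5, 60)
  mc <- fit_cks(X, yc, norms = nm)
  expect_equal(kitchen_predict(mc, X), rep(2.5, 60))
})

test_that("predictions are clamped to the training-target range", {
  set.seed(12)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rowSums(X[, 1:3])
  m <- fit_cks(X, y, w = 4, f = 32, seed = 6, penalty = 1e-6)
  Xfar <- matrix(rnorm(20 * 10, sd = 25), 20, 10)
  raw <- kitchen_predict(m, Xfar, clamp_range = FALSE)
  cl <- kitchen_predict(m, Xfar)
  expect_true(all(cl >= min(y) & cl <= max(y)))
  out <- raw > max(y) | raw < min(y)
  expect_true(any(out))  # the far inputs do overflow the range
  expect_equal(cl[raw > max(y)], rep(max(y), sum(raw > max(y))))
  expect_equal(cl[!out], raw[!out])
  expect_error(kitchen_predict(m, matrix(0, 2, 9)), "length")
  expect_identical(kitchen_predict(m, Xfar), kitchen_predict(m, Xfar))
})

test_that("the hyperparameter sweep scores cells by the validation regression", {
  set.seed(13)
  X <- matrix(rnorm(160 * 16), 160, 16)
  y <- rowMeans(X) + rnorm(160, sd = 0.1)
  sw <- kitchen_sweep(X[1:120, ], y[1:120], X[121:160, ], y[121:160],
                      w_grid = c(2, 4), f_grid = c(8, 32), base_seed = 7)
  expect_equal(nrow(sw$table), 4)
  expect_equal(sw$best$adj_r2, max(sw$table$adj_r2))
  expect_s3_class(sw$model, "cks_model")
  one <- kitchen_sweep(X[1:120, ], y[1:120], X[121:160, ], y[121:160],
                       w_grid = 4, f_grid = 8, base_seed = 7)
  expect_equal(nrow(one$table), 1)
  expect_equal(one$best$w, 4)
  expect_error(kitchen_sweep(X[1:120, ], y[1:120], X[121:160, ], y[121:160],
                             w_grid = 20, f_grid = 8), "<=")
  # sweeps are reproducible
  sw2 <- kitchen_sweep(X[1:120, ], y[1:120], X[121:160, ], y[121:160],
                       w_grid = c(2, 4), f_grid = c(8, 32), base_seed = 7)
  expect_equal(sw$table, sw2$table)
})

test_that("adjusted r-squared equals the single-predictor closed form", {
  set.seed(14)
  true <- rnorm(10)
  pred <- true + rnorm(10, sd = 0.4)
  ev <- evaluate(true, pred)
  expect_equal(ev$adj_r2, 1 - (1 - ev$r2) * (10 - 1) / (10 - 2),
               tolerance = 1e-12)
})

test_that("bootstrap estimation gives sensible intervals", {
  set.seed(15)
  X <- matrix(rnorm(400 * 12), 400, 12)
  y <- rowMeans(X) + rnorm(400, sd = 0.05)
  xobs <- rnorm(12)
  b <- bootstrap_estimate(X[1:60, ], y[1:60], xobs, w = 4, f = 16,
                          norm_seed = 8, B = 60, seed = 9)
  expect_length(b$predictions, 60)
  expect_true(b$ci[1] <= b$estimate && b$estimate <= b$ci[2])
  # degenerate targets collapse the interval
  bd <- bootstrap_estimate(X[1:30, ], rep(1.2, 30), xobs, w = 4, f = 16,
                           norm_seed = 8, B = 10, seed = 9)
  expect_equal(bd$estimate, 1.2)
  expect_equal(unname(diff(bd$ci)), 0)
  # more training data tightens the interval at fixed B
  blarge <- bootstrap_estimate(X, y, xobs, w = 4, f = 16,
                               norm_seed = 8, B = 60, seed = 9)
  expect_lt(diff(blarge$ci), diff(b$ci))
  # reproducibility
  b2 <- bootstrap_estimate(X[1:60, ], y[1:60], xobs, w = 4, f = 16,
                           norm_seed = 8, B = 60, seed = 9)
  expect_equal(b$predictions, b2$predictions)
})

test_that("cks models serialize to text and reload with identical predictions", {
  set.seed(16)
  X <- matrix(rnorm(50 * 10), 50, 10)
  y <- rowMeans(X)
  m <- fit_cks(X, y, w = 3, f = 12, seed = 17)
  f <- tempfile(fileext = ".tsv")
  write_cks_model(m, f)
  m2 <- read_cks_model(f)
  Xn <- matrix(rnorm(20 * 10), 20, 10)
  expect_equal(kitchen_predict(m2, Xn), kitchen_predict(m, Xn),
               tolerance = 1e-12)
  plain <- fit_cks(X, y, norms = matrix(rnorm(36), 3, 12))
  expect_error(write_cks_model(plain, f), "seed")
})
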