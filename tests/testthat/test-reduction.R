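test_that("dimension rule reproduces the published widths", {
  expect_identical(dimension_rule(56), 4L)
  expect_identical(dimension_rule(64), 8L)
  expect_identical(dimension_rule(c(546, 234, 686, 1260, 238)),
                   c(64L, 16L, 64L, 128L, 16L))
  expect_error(dimension_rule(15), "undefined")
})

test_that("dimension rule is non-decreasing and exact on powers of two", {
  d <- 16:3000
  h <- dimension_rule(d)
  expect_true(all(diff(h) >= 0))
  for (k in 4:11) expect_identical(dimension_rule(2^k), as.integer(2^(k - 3)))
})

test_that("pair widths at the default lags give the 584 merged width", {
  pair_dims <- c(pseaac = 56L, ad = 546L, ac = 234L, ct = 686L, ld = 1260L,
                 mmi = 238L)
  out <- 2L * dimension_rule(pair_dims)
  expect_identical(unname(out), c(8L, 128L, 32L, 128L, 256L, 32L))
  expect_identical(sum(out), 584L)
})

test_that("reducer construction is seeded and shape-correct", {
  r <- gru_reducer(56, direction = "bidirectional", seed = 3)
  expect_identical(r$hidden_dim, 4L)
  expect_identical(reducer_output_dim(r), 8L)
  r2 <- gru_reducer(56, direction = "bidirectional", seed = 3)
  expect_identical(r$params, r2$params)
  r3 <- gru_reducer(56, direction = "bidirectional", seed = 4)
  expect_false(identical(r$params, r3$params))
  expect_error(gru_reducer(56, epochs = 0), "epochs")
  f <- gru_reducer(56, hidden_dim = 8, direction = "forward")
  expect_identical(reducer_output_dim(f), 8L)
})

test_that("C++ hidden states match a plain-R GRU forward pass", {
  set.seed(12)
  r <- gru_reducer(30, hidden_dim = 5, direction = "bidirectional", seed = 9)
  X <- matrix(rnorm(8 * 30), 8, 30)
  got <- extract_hidden(r, X)$hidden_states
  want <- t(apply(X, 1, function(x) {
    c(oracle_gru_forward(r$params$dirs[[1]], x, 5),
      oracle_gru_forward(r$params$dirs[[2]], x, 5, backward = TRUE))
  }))
  expect_equal(unname(got), unname(want), tolerance = 1e-6)
})

test_that("backward GRU equals forward GRU on the reversed sequence", {
  set.seed(13)
  X <- matrix(rnorm(6 * 40), 6, 40)
  rb <- gru_reducer(40, hidden_dim = 6, direction = "backward", seed = 21)
  rf <- gru_reducer(40, hidden_dim = 6, direction = "forward", seed = 99)
  rf$params <- rb$params    # identical parameters, opposite reading direction
  hb <- extract_hidden(rb, X)$hidden_states
  hf <- extract_hidden(rf, X[, 40:1])$hidden_states
  expect_equal(unname(hb), unname(hf), tolerance = 1e-6)
})

test_that("training reduces the loss on separable data and is reproducible", {
  set.seed(14)
  n <- 120; d <- 30
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(n * d), n, d) + outer(y, rep(1.2, d))
  r <- gru_reducer(d, hidden_dim = 6, epochs = 5, seed = 7)
  t1 <- train_reducer(r, X, y)
  expect_length(t1$loss_history, 5L)
  expect_lt(t1$loss_history[5], t1$loss_history[1])
  t2 <- train_reducer(r, X, y)
  expect_identical(t1$params, t2$params)
  expect_error(train_reducer(r, X, rep(1, n)), "single-class")
  expect_error(train_reducer(r, X[, 1:10], y), "expects")
})

test_that("extraction works untrained (flagged) and output is informative once trained", {
  set.seed(15)
  n <- 100; d <- 24
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(n * d), n, d) + outer(y, rep(1.5, d))
  r <- gru_reducer(d, hidden_dim = 4, epochs = 5, seed = 2)
  h0 <- extract_hidden(r, X)
  expect_false(h0$trained)
  expect_identical(dim(h0$hidden_states), c(100L, 8L))
  rt <- train_reducer(r, X, y)
  h1 <- extract_hidden(rt, X)
  expect_true(h1$trained)
  expect_true(all(is.finite(h1$hidden_states)))
  # distinct inputs map to non-constant hidden states
  expect_gt(max(apply(h1$hidden_states, 2, sd)), 0)
})

test_that("ensemble strategies emit the same 584-wide representation", {
  set.seed(16)
  n <- 24
  dims <- c(pseaac = 56L, ad = 546L, ac = 234L, ct = 686L, ld = 1260L,
            mmi = 238L)
  blocks <- lapply(dims, function(d) matrix(rnorm(n * d), n, d))
  labels <- rep(c(0, 1), n / 2)
  ens <- reduce_multiens(blocks, labels, train = FALSE)
  expect_identical(ncol(ens$hidden_states), 584L)
  con <- reduce_multicon(blocks, labels, train = FALSE)
  expect_identical(con$reducers$all$hidden_dim, 292L)
  expect_identical(ncol(con$hidden_states), 584L)
  sep <- reduce_multisep(blocks, labels, train = FALSE)
  expect_identical(sep$reducers$svhehs$hidden_dim, 84L)
  expect_identical(sep$reducers$classes$hidden_dim, 208L)
  expect_identical(ncol(sep$hidden_states), 584L)
  expect_identical(84L + 208L, 292L)
  # dropping one technique drops exactly twice its rule width
  ens5 <- ens
  keep <- setdiff(names(blocks), "ld")
  parts <- lapply(keep, function(tech) {
    extract_hidden(ens$reducers[[tech]], blocks[[tech]])$hidden_states
  })
  expect_identical(ncol(do.call(cbind, parts)),
                   584L - 2L * dimension_rule(1260L))
})

test_that("consistent row permutation of the blocks permutes hidden rows identically", {
  set.seed(17)
  n <- 20
  dims <- c(pseaac = 56L, ad = 546L, ac = 234L, ct = 686L, ld = 1260L,
            mmi = 238L)
  blocks <- lapply(dims, function(d) matrix(rnorm(n * d), n, d))
  labels <- rep(c(0, 1), n / 2)
  perm <- sample(n)
  h1 <- reduce_multiens(blocks, labels, train = FALSE)$hidden_states
  h2 <- reduce_multiens(lapply(blocks, function(b) b[perm, , drop = FALSE]),
                        labels[perm], train = FALSE)$hidden_states
  # float32 kernel: a row's position in the batch can change which BLAS
  # micro-kernel computes it, so agreement is to single precision, not bitwise
  expect_equal(unname(h2), unname(h1[perm, ]), tolerance = 1e-5)
  # misaligned blocks are rejected
  bad <- blocks
  bad$ac <- bad$ac[1:10, ]
  expect_error(reduce_multiens(bad, labels), "row-aligned")
})
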