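test_that("stratified folds partition the data with balanced sizes and classes", {
  y <- rep(c(0, 1), each = 5)
  f <- stratified_kfold(y, k = 5, seed = 1)
  expect_identical(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))
  expect_true(all(table(f[y == 1]) == 1))
  expect_identical(stratified_kfold(y, k = 5, seed = 1), f)
  set.seed(31)
  y2 <- rbinom(103, 1, 0.4)
  f2 <- stratified_kfold(y2, k = 5, seed = 9)
  expect_lte(diff(range(table(f2))), 1)
  expect_lte(diff(range(table(f2[y2 == 1]))), 1)
  expect_lte(diff(range(table(f2[y2 == 0]))), 1)
  expect_error(stratified_kfold(c(0, 1), k = 5), "at least k")
})

test_that("metrics match the closed-form worked example", {
  # TP=3 FP=1 TN=4 FN=2
  truth <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  prob <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.4, 0.3, 0.2, 0.1)
  m <- compute_metrics(truth, prob)
  expect_identical(m$counts, list(TP = 3L, FP = 1L, TN = 4L, FN = 2L))
  expect_equal(m$ACC, 0.7)
  expect_equal(m$PRE, 0.75)
  expect_equal(m$SE, 0.6)
  expect_equal(m$SP, 0.8)
  expect_equal(m$MCC, 10 / sqrt(600))
  expect_equal(m$F1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
})

test_that("perfect and degenerate predictions hit the boundary conventions", {
  truth <- rep(c(0, 1), 10)
  perfect <- compute_metrics(truth, truth)
  for (k in c("ACC", "PRE", "SE", "SP", "F1", "MCC", "AUC", "AUPR")) {
    expect_equal(perfect[[k]], 1, info = k)
  }
  allpos <- compute_metrics(truth, rep(1, 20))
  expect_equal(allpos$SE, 1)
  expect_equal(allpos$SP, 0)
  expect_equal(allpos$ACC, 0.5)
  expect_equal(allpos$MCC, 0)
  expect_true("MCC" %in% allpos$degenerate)
  expect_error(compute_metrics(truth, c(0.2, 0.4)), "lengths differ")
})

test_that("metrics agree with the confusion-matrix oracle on random vectors", {
  set.seed(32)
  for (i in 1:250) {
    n <- sample(10:120, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    prob <- round(runif(n), sample(c(1, 2, 6), 1))   # induce ties sometimes
    m <- compute_metrics(truth, prob)
    o <- oracle_metrics(truth, prob)
    for (k in names(o)) expect_equal(m[[k]], o[[k]], info = k)
    expect_equal(m$AUC, oracle_auc_rank(truth, prob), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC library", {
  set.seed(35)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    prob <- round(runif(n), sample(c(2, 8), 1))
    m <- compute_metrics(truth, prob)
    ref <- as.numeric(suppressMessages(pROC::auc(truth, prob,
                                                 direction = "<",
                                                 quiet = TRUE)))
    expect_equal(m$AUC, ref, tolerance = 1e-12)
  }
})

test_that("AUPR equals average precision when scores are unique", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(20:100, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    prob <- sample(seq(0.001, 0.999, length.out = n))
    m <- compute_metrics(truth, prob)
    expect_equal(m$AUPR, oracle_aupr_unique(truth, prob), tolerance = 1e-12)
  }
})

test_that("lag scan returns the accuracy-optimal lag with smallest-lag ties", {
  set.seed(34)
  sim <- simulate_ppi_data(n_pairs = 40, length_range = c(20, 40),
                           effect = 0.5, seed = 11)
  scan <- optimize_lag(sim$seqs, sim$pairs, "ac", lag_range = 1:3,
                       config = classifier_config(n_iterations = 20))
  expect_s3_class(scan, "ppi_lag_scan")
  expect_true(scan$best_lag %in% 1:3)
  expect_identical(dim(scan$table), c(3L, 8L))
  # infeasible lag errors and names the shortest sequence
  shortest <- names(sim$seqs)[which.min(nchar(sim$seqs))]
  expect_error(optimize_lag(sim$seqs, sim$pairs, "ac", lag_range = 1:25),
               shortest)
  # tie-break: degenerate two-pair set gives identical ACC across lags
  tiny <- simulate_ppi_data(n_pairs = 10, length_range = c(30, 30),
                            effect = 0, seed = 1)
  scan2 <- optimize_lag(tiny$seqs, tiny$pairs, "pseaac", lag_range = 1:2,
                        config = classifier_config(n_iterations = 2))
  if (scan2$table[1, "ACC"] == scan2$table[2, "ACC"]) {
    expect_identical(scan2$best_lag, 1L)
  }
})

test_that("cross-validation runs end to end on a small signal dataset", {
  sim <- simulate_ppi_data(n_pairs = 50, length_range = c(25, 50),
                           effect = 0.5, seed = 21)
  cv <- run_cv(sim$seqs, sim$pairs, strategy = "multiens", seed = 1,
               epochs = 1, config = classifier_config(n_iterations = 30))
  expect_s3_class(cv, "ppi_cv")
  expect_identical(nrow(cv$per_fold), 5L)
  expect_identical(cv$merged_width, 584L)
  expect_true(all(is.finite(cv$per_fold[, "ACC"])))
  expect_true(all(cv$per_fold[, "ACC"] >= 0 & cv$per_fold[, "ACC"] <= 1))
})

test_that("a frozen model scores an external pair set, including positive-only", {
  sim <- simulate_ppi_data(n_pairs = 40, length_range = c(25, 50),
                           effect = 0.6, seed = 31)
  fit <- ppi_fit(sim$seqs, sim$pairs, epochs = 1, n_iterations = 30)
  ext <- simulate_ppi_data(n_pairs = 20, length_range = c(25, 50),
                           effect = 0.6, seed = 32)
  m <- cross_dataset_test(fit, ext$seqs, ext$pairs)
  expect_false(m$positive_only)
  expect_true(is.finite(m$ACC))
  pos <- ext$pairs[ext$pairs$label == 1, ]
  mp <- cross_dataset_test(fit, ext$seqs, pos)
  expect_true(mp$positive_only)
  expect_equal(mp$ACC, mp$SE)
  expect_true(is.na(mp$SP))
  expect_error(cross_dataset_test(fit, ext$seqs, ext$pairs[0, ]), "empty")
})
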