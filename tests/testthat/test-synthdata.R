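test_that("generation is reproducible and respects the configuration", {
  s1 <- simulate_ppi_data(n_pairs = 60, length_range = c(20, 60), effect = 0.2,
                          seed = 5)
  s2 <- simulate_ppi_data(n_pairs = 60, length_range = c(20, 60), effect = 0.2,
                          seed = 5)
  expect_identical(s1$seqs, s2$seqs)
  expect_identical(s1$pairs, s2$pairs)
  s3 <- simulate_ppi_data(n_pairs = 60, length_range = c(20, 60), effect = 0.2,
                          seed = 6)
  expect_false(identical(s1$seqs, s3$seqs))
  lens <- nchar(s1$seqs)
  expect_true(all(lens >= 20 & lens <= 60))
  expect_identical(nrow(s1$pairs), 60L)
  expect_true(all(s1$pairs$id_a != s1$pairs$id_b))   # no self-pairs
})

test_that("class balance matches the positive fraction within one pair", {
  for (pf in c(0.3, 0.5, 0.7)) {
    s <- simulate_ppi_data(n_pairs = 51, positive_fraction = pf,
                           length_range = c(15, 30), seed = 2)
    expect_lte(abs(sum(s$pairs$label) - pf * 51), 1)
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(simulate_ppi_data(n_pairs = 5), "n_pairs")
  expect_error(simulate_ppi_data(length_range = c(8, 20)), "minimum sequence length")
  expect_error(simulate_ppi_data(effect = 0.9), "effect too large")
  expect_error(simulate_ppi_data(positive_fraction = 1), "positive_fraction")
})

test_that("planted effect separates matched from mismatched pair compositions", {
  # the generator's contract, checked directly on class compositions:
  # at effect 0.3 interacting pairs have closer 7-class compositions than
  # non-interacting pairs; at effect 0 there is no such gap
  cmap <- default_class_map()
  comp7 <- function(seq) {
    tabulate(class_of(strsplit(seq, "")[[1]], cmap), 7) / nchar(seq)
  }
  gap <- function(sim) {
    d <- vapply(seq_len(nrow(sim$pairs)), function(i) {
      sum(abs(comp7(sim$seqs[[sim$pairs$id_a[i]]]) -
                comp7(sim$seqs[[sim$pairs$id_b[i]]])))
    }, numeric(1))
    mean(d[sim$pairs$label == 0]) - mean(d[sim$pairs$label == 1])
  }
  s_sig <- simulate_ppi_data(n_pairs = 200, length_range = c(50, 120),
                             effect = 0.3, seed = 3)
  expect_gt(gap(s_sig), 0.2)
  s_null <- simulate_ppi_data(n_pairs = 200, length_range = c(50, 120),
                              effect = 0, seed = 3)
  expect_lt(abs(gap(s_null)), 0.05)
})

test_that("downstream accuracy is non-decreasing in the planted effect", {
  # single-technique proxy pipeline (CT features straight into the
  # classifier) keeps this within test-suite scale; averaged over 3 seeds
  acc_at <- function(effect, seed) {
    sim <- simulate_ppi_data(n_pairs = 200, length_range = c(40, 80),
                             effect = effect, seed = seed)
    x <- featurize_pairs(sim$seqs, sim$pairs, "ct")
    y <- sim$pairs$label
    fold <- stratified_kfold(y, k = 5, seed = seed)
    mean(vapply(1:5, function(f) {
      clf <- fit_classifier(x[fold != f, , drop = FALSE], y[fold != f],
                            classifier_config(n_iterations = 60))
      mean(predict(clf, x[fold == f, , drop = FALSE])$label == y[fold == f])
    }, numeric(1)))
  }
  effects <- c(0, 0.1, 0.2, 0.3)
  acc <- vapply(effects, function(e) {
    mean(vapply(1:3, function(s) acc_at(e, s), numeric(1)))
  }, numeric(1))
  # monotone up to small fold noise
  expect_true(all(diff(acc) > -0.03))
  expect_gt(acc[4], acc[1])
})

test_that("worked fixtures encode as advertised", {
  fx <- worked_fixtures()
  ct <- encode_ct(fx$homopolymer$seq)
  expect_identical(sum(ct$vector != 0), 1L)
  pa <- encode_pseaac(fx$pseaac_pair$seq_a, lag = fx$pseaac_pair$lag)
  pb <- encode_pseaac(fx$pseaac_pair$seq_b, lag = fx$pseaac_pair$lag)
  expect_identical(encode_pair(pa, pb)$dim, 56L)
  two <- encode_mmi(fx$two_class$seq)
  expect_identical(two$dim, 119L)
})
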