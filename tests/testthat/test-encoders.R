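props <- default_property_table()
cmap <- default_class_map()

test_that("per-protein dimensions follow the technique formulas", {
  set.seed(11)
  for (L in c(12L, 25L, 60L, 137L, 500L)) {
    s <- random_protein(L)
    expect_identical(encode_pseaac(s, lag = 8, props = props)$dim, 28L)
    expect_identical(encode_ad(s, lag = 7, props = props)$dim, 273L)
    expect_identical(encode_ac(s, lag = 9, props = props)$dim, 117L)
    expect_identical(encode_ct(s, cmap)$dim, 343L)
    expect_identical(encode_ld(s, cmap)$dim, 630L)
    expect_identical(encode_mmi(s, cmap)$dim, 119L)
  }
  # dims scale with lag for the profile techniques
  s <- random_protein(40)
  expect_identical(encode_pseaac(s, lag = 3, props = props)$dim, 23L)
  expect_identical(encode_ad(s, lag = 2, props = props)$dim, 78L)
  expect_identical(encode_ac(s, lag = 4, props = props)$dim, 52L)
})

test_that("PseAAC is a probability vector with zero order terms on homopolymers", {
  set.seed(2)
  for (i in 1:10) {
    b <- encode_pseaac(random_protein(sample(20:80, 1)), lag = 8, props = props)
    expect_true(all(b$vector >= 0))
    expect_equal(sum(b$vector), 1, tolerance = 1e-9)
  }
  hp <- encode_pseaac(strrep("A", 10), lag = 2, props = props)
  expect_equal(unname(hp$vector[1]), 1)            # composition all on A
  expect_equal(unname(hp$vector[-1]), rep(0, 21))  # other residues and thetas
})

test_that("homopolymers zero the centred autocorrelation descriptors", {
  hp <- strrep("L", 20)
  ad <- encode_ad(hp, lag = 3, props = props)
  mb <- ad$vector[1:39]
  moran <- ad$vector[40:78]
  geary <- ad$vector[79:117]
  expect_equal(unname(moran), rep(0, 39))
  expect_equal(unname(geary), rep(0, 39))
  # Moreau-Broto on a constant profile is the squared standardized value
  pl <- props$values["L", ]
  expect_equal(unname(mb), unname(rep(pl^2, each = 3)), tolerance = 1e-12)
  ac <- encode_ac(hp, lag = 4, props = props)
  expect_equal(unname(ac$vector), rep(0, 52))
})

test_that("conjoint triads: single-class sequence has one unit entry", {
  b <- encode_ct("GAGAGA", cmap)   # G and A share a class
  expect_identical(sum(b$vector != 0), 1L)
  expect_equal(max(b$vector), 1)
  set.seed(3)
  s <- random_protein(30)
  v <- encode_ct(s, cmap)$vector
  expect_true(all(v >= 0 & v <= 1))
  expect_true(any(v == 1))
})

test_that("local descriptor blocks satisfy per-region structure", {
  set.seed(4)
  s <- random_protein(80)
  v <- encode_ld(s, cmap)$vector
  expect_true(all(v >= 0 & v <= 1))
  for (r in 0:9) {
    comp <- v[r * 63 + 1:7]
    expect_equal(sum(comp), 1, tolerance = 1e-12)
  }
})

test_that("MMI of a single-class sequence is all zero information", {
  b <- encode_mmi(strrep("K", 12), cmap)   # K alone in its class? K with R
  v <- b$vector
  # class frequency of the K/R class is 1, everything else 0
  expect_equal(sum(v[113:119] == 1), 1L)
  expect_equal(unname(v[1:112]), rep(0, 112))
})

test_that("every encoder matches its brute-force oracle", {
  set.seed(5)
  lags <- list(pseaac = 3L, ad = 2L, ac = 4L, ct = NA, ld = NA, mmi = NA)
  for (i in 1:10) {
    s <- random_protein(sample(15:50, 1))
    for (tech in c("pseaac", "ad", "ac", "ct", "ld", "mmi")) {
      got <- encode_one(tech, s, lags[[tech]], props, cmap)$vector
      want <- oracle_encoder(tech, s, lags[[tech]], props, cmap)
      expect_equal(unname(got), want, tolerance = 1e-10,
                   info = paste(tech, s))
    }
  }
})

test_that("AC and the centred AD descriptors ignore affine property rescaling", {
  raw <- default_property_table(standardized = FALSE)
  raw2 <- raw
  raw2$values[, 6] <- -2 * raw2$values[, 6] + 5     # sign flip + shift
  raw2$values[, 11] <- 0.1 * raw2$values[, 11]
  p1 <- standardize_table(raw)
  p2 <- standardize_table(raw2)
  set.seed(6)
  s <- random_protein(30)
  a1 <- encode_ac(s, lag = 4, props = p1)$vector
  a2 <- encode_ac(s, lag = 4, props = p2)$vector
  # covariance is even in the sign of the standardized profile
  expect_equal(abs(unname(a1)), abs(unname(a2)), tolerance = 1e-12)
  # positive rescaling alone changes nothing at all
  raw3 <- raw
  raw3$values[, 6] <- 3 * raw3$values[, 6] + 1
  p3 <- standardize_table(raw3)
  expect_equal(encode_ac(s, lag = 4, props = p3)$vector,
               encode_ac(s, lag = 4, props = p1)$vector, tolerance = 1e-12)
  expect_equal(encode_ad(s, lag = 3, props = p3)$vector,
               encode_ad(s, lag = 3, props = p1)$vector, tolerance = 1e-12)
})

test_that("encoders are deterministic and reject infeasible inputs", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  expect_identical(encode_mmi(s, cmap)$vector, encode_mmi(s, cmap)$vector)
  expect_error(encode_pseaac("ACDEF", lag = 5, props = props, id = "p1"),
               "'p1'.*lag 5")
  expect_error(encode_ct("AC", cmap), "too short")
  expect_error(encode_ld("ACDEFGHIK", cmap), "too short")
  expect_error(encode_mmi("AC", cmap), "too short")
  expect_error(encode_pseaac("ACXDEFGHIK", lag = 2, props = props, id = "px"),
               "non-canonical residue 'X' at position 3")
})

test_that("pair encoding concatenates first protein first and checks compatibility", {
  set.seed(7)
  a <- encode_pseaac(random_protein(30), lag = 8, props = props)
  b <- encode_pseaac(random_protein(25), lag = 8, props = props)
  p <- encode_pair(a, b)
  expect_identical(p$dim, 56L)
  expect_equal(unname(p$vector[1:28]), unname(a$vector))
  expect_equal(unname(p$vector[29:56]), unname(b$vector))
  pp <- encode_pair(a, a)
  expect_equal(unname(pp$vector[1:28]), unname(pp$vector[29:56]))
  expect_error(encode_pair(a, encode_ct(random_protein(30), cmap)),
               "technique mismatch")
  expect_error(encode_pair(a, encode_pseaac(random_protein(30), lag = 5,
                                            props = props)), "lag mismatch")
})

test_that("featurize_pairs builds row-aligned pair matrices", {
  set.seed(8)
  seqs <- c(p1 = random_protein(30), p2 = random_protein(40),
            p3 = random_protein(25))
  pairs <- data.frame(id_a = c("p1", "p2", "p1"), id_b = c("p2", "p3", "p1"),
                      label = c(1L, 0L, 1L))
  m <- featurize_pairs(seqs, pairs, "pseaac", lag = 8, props = props)
  expect_identical(dim(m), c(3L, 56L))
  expect_equal(unname(m[1, 1:28]),
               unname(encode_pseaac(seqs["p1"], lag = 8, props = props)$vector))
  expect_equal(unname(m[3, 1:28]), unname(m[3, 29:56]))
  expect_error(featurize_pairs(seqs, data.frame(id_a = "p9", id_b = "p1",
                                                label = 1), "ct"),
               "unknown sequence id")
})
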