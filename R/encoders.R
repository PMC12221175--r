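# Six sequence-to-vector feature coding techniques.
#
# Three descriptor-profile encoders (PseAAC, AD, AC) read residue-level
# physicochemical profiles from a standardized property table; three
# class-alphabet encoders (CT, LD, MMI) work on the 7-letter
# dipole/side-chain-volume alphabet.  All encoders are deterministic and every
# column ordering is frozen (alphabetical residues; lag-minor within property;
# lexicographic class tuples) so feature matrices are bit-reproducible.

TECHNIQUES <- c("pseaac", "ad", "ac", "ct", "ld", "mmi")

new_feature_block <- function(technique, vector, lag = NA_integer_) {
  structure(list(technique = technique, lag = lag,
                 vector = vector, dim = length(vector)),
            class = "ppi_feature_block")
}

#' @export
print.ppi_feature_block <- function(x, ...) {
  cat(sprintf("<%s feature block%s: %d features>\n", toupper(x$technique),
              if (!is.na(x$lag)) sprintf(" (lag %d)", x$lag) else "", x$dim))
  invisible(x)
}

# residue-indexed property profile (L x 13) for one sequence
prop_profile <- function(seq, props, id = "<sequence>") {
  stopifnot(inherits(props, "ppi_proptab"))
  if (!isTRUE(props$standardized)) {
    stop("property table must be standardized before encoding", call. = FALSE)
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(chars, props$residues)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("sequence '%s' has non-canonical residue '%s' at position %d",
                 id, chars[bad], bad), call. = FALSE)
  }
  props$values[idx, , drop = FALSE]
}

check_lag <- function(L, lag, id) {
  if (lag < 1L) stop("lag must be >= 1", call. = FALSE)
  if (L <= lag) {
    stop(sprintf("sequence '%s' (length %d) is too short for lag %d (need length >= lag + 1)",
                 id, L, lag), call. = FALSE)
  }
}

#' Pseudo amino acid composition (PseAAC)
#'
#' Encodes a sequence as 20 amino-acid composition terms plus `lag`
#' sequence-order correlation factors, jointly normalized so the whole vector
#' sums to 1.  The correlation factor at separation `j` averages, over all
#' residue pairs `(i, i+j)`, the mean squared difference of the 13
#' standardized property components of the two residues.
#'
#' @param seq Protein sequence (single character string, canonical residues).
#' @param lag Maximum residue separation (default 8); requires
#'   `nchar(seq) >= lag + 1`.
#' @param weight Weight of the sequence-order factors relative to composition
#'   (default 0.05).
#' @param props Standardized `ppi_proptab`.
#' @param id Sequence identifier used in error messages.
#' @return A `ppi_feature_block` of dimension `20 + lag`.
#' @export
encode_pseaac <- function(seq, lag = 8L, weight = 0.05,
                          props = default_property_table(), id = "<sequence>") {
  stopifnot(weight > 0)
  P <- prop_profile(seq, props, id)
  L <- nrow(P)
  lag <- as.integer(lag)
  check_lag(L, lag, id)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  comp <- tabulate(match(chars, aa_alphabet()), nbins = 20L) / L
  theta <- vapply(seq_len(lag), function(j) {
    d <- P[seq_len(L - j), , drop = FALSE] - P[(j + 1L):L, , drop = FALSE]
    mean(rowMeans(d * d))
  }, numeric(1L))
  den <- sum(comp) + weight * sum(theta)
  v <- c(comp, weight * theta) / den
  names(v) <- c(paste0("comp_", aa_alphabet()), paste0("theta_", seq_len(lag)))
  new_feature_block("pseaac", v, lag)
}

#' Autocorrelation descriptors (AD)
#'
#' Normalized Moreau-Broto, Moran and Geary autocorrelations of each of the 13
#' standardized property profiles at separations 1..`lag`.  For a profile with
#' zero within-sequence variance (homopolymers) Moran and Geary are defined as
#' 0.  Output ordering is descriptor-major (all Moreau-Broto, then Moran, then
#' Geary), property-major within descriptor, lag-minor.
#'
#' @inheritParams encode_pseaac
#' @param lag Maximum separation (default 7).
#' @return A `ppi_feature_block` of dimension `3 * 13 * lag`.
#' @export
encode_ad <- function(seq, lag = 7L, props = default_property_table(),
                      id = "<sequence>") {
  P <- prop_profile(seq, props, id)
  L <- nrow(P)
  lag <- as.integer(lag)
  check_lag(L, lag, id)
  pbar <- colMeans(P)
  Pc <- sweep(P, 2L, pbar)
  ss <- colSums(Pc * Pc)                   # sum of squared deviations
  mb <- mor <- gea <- matrix(0, nrow = N_PROPERTIES, ncol = lag)
  for (d in seq_len(lag)) {
    i1 <- seq_len(L - d)
    i2 <- (d + 1L):L
    mb[, d] <- colSums(P[i1, , drop = FALSE] * P[i2, , drop = FALSE]) / (L - d)
    num_m <- colSums(Pc[i1, , drop = FALSE] * Pc[i2, , drop = FALSE]) / (L - d)
    dd <- P[i1, , drop = FALSE] - P[i2, , drop = FALSE]
    num_g <- colSums(dd * dd) / (2 * (L - d))
    mor[, d] <- ifelse(ss > 0, num_m / (ss / L), 0)
    gea[, d] <- ifelse(ss > 0, num_g / (ss / (L - 1)), 0)
  }
  lab <- function(tag) paste0(tag, "_p", rep(seq_len(N_PROPERTIES), each = lag),
                              "_d", rep(seq_len(lag), N_PROPERTIES))
  v <- c(as.vector(t(mb)), as.vector(t(mor)), as.vector(t(gea)))
  names(v) <- c(lab("MB"), lab("Moran"), lab("Geary"))
  new_feature_block("ad", v, lag)
}

#' Autocovariance (AC)
#'
#' Covariance of each standardized property profile with itself at separations
#' 1..`lag`, centred on the sequence mean of that property.  Ordering is
#' property-major, lag-minor.
#'
#' @inheritParams encode_pseaac
#' @param lag Maximum separation (default 9).
#' @return A `ppi_feature_block` of dimension `13 * lag`.
#' @export
encode_ac <- function(seq, lag = 9L, props = default_property_table(),
                      id = "<sequence>") {
  P <- prop_profile(seq, props, id)
  L <- nrow(P)
  lag <- as.integer(lag)
  check_lag(L, lag, id)
  Pc <- sweep(P, 2L, colMeans(P))
  ac <- matrix(0, nrow = N_PROPERTIES, ncol = lag)
  for (d in seq_len(lag)) {
    ac[, d] <- colSums(Pc[seq_len(L - d), , drop = FALSE] *
                         Pc[(d + 1L):L, , drop = FALSE]) / (L - d)
  }
  v <- as.vector(t(ac))
  names(v) <- paste0("AC_p", rep(seq_len(N_PROPERTIES), each = lag),
                     "_d", rep(seq_len(lag), N_PROPERTIES))
  new_feature_block("ac", v, lag)
}

#' Conjoint triad (CT)
#'
#' Counts each of the 343 ordered class triads among the `L - 2` sliding
#' windows of the 7-letter class sequence, then normalizes the counts by
#' subtracting their minimum and dividing by their maximum, so entries lie in
#' `[0, 1]` with at least one entry equal to 1.
#'
#' @inheritParams encode_pseaac
#' @param cmap A `ppi_classmap`.
#' @return A `ppi_feature_block` of dimension 343.
#' @export
encode_ct <- function(seq, cmap = default_class_map(), id = "<sequence>") {
  s <- class_sequence(toupper(seq), cmap)
  L <- length(s)
  if (L < 3L) {
    stop(sprintf("sequence '%s' is too short for triads (length %d < 3)", id, L),
         call. = FALSE)
  }
  code <- 49L * (s[1:(L - 2L)] - 1L) + 7L * (s[2:(L - 1L)] - 1L) + s[3:L]
  f <- tabulate(code, nbins = 343L)
  v <- (f - min(f)) / max(f)
  g <- expand.grid(c3 = 1:7, c2 = 1:7, c1 = 1:7)[, 3:1]
  names(v) <- sprintf("CT_%d%d%d", g$c1, g$c2, g$c3)
  new_feature_block("ct", v)
}

# 1-based inclusive boundaries of the 10 canonical overlapping regions
ld_regions <- function(L) {
  b <- function(f) max(1L, round(f * L))
  r <- list(c(1L, b(0.25)), c(b(0.25) + 1L, b(0.50)), c(b(0.50) + 1L, b(0.75)),
            c(b(0.75) + 1L, L), c(1L, b(0.50)), c(b(0.50) + 1L, L),
            c(b(0.25) + 1L, b(0.75)), c(1L, b(0.75)), c(b(0.25) + 1L, L),
            c(b(0.125) + 1L, b(0.875)))
  lapply(r, function(x) c(min(x[1L], L), max(x[1L], min(x[2L], L))))
}

ld_region_features <- function(s) {
  n <- length(s)
  comp <- tabulate(s, nbins = N_CLASSES) / n
  tran <- numeric(21L)
  if (n >= 2L) {
    a <- pmin(s[-n], s[-1L]); b <- pmax(s[-n], s[-1L])
    diff <- a != b
    if (any(diff)) {
      # index of unordered pair (a<b) in lexicographic order
      pidx <- (a[diff] - 1L) * (14L - a[diff]) / 2L + (b[diff] - a[diff])
      cnt <- tabulate(pidx, nbins = 21L)
      tran <- cnt / (n - 1L)
    }
  }
  dist <- numeric(5L * N_CLASSES)
  for (k in seq_len(N_CLASSES)) {
    pos <- which(s == k)
    m <- length(pos)
    if (m > 0L) {
      picks <- c(1L, ceiling(0.25 * m), ceiling(0.5 * m), ceiling(0.75 * m), m)
      dist[(k - 1L) * 5L + 1:5] <- pos[picks] / n
    }
  }
  c(comp, tran, dist)
}

#' Local descriptor (LD)
#'
#' Splits the 7-letter class sequence into 10 overlapping regions (four
#' quarters, two halves, the central half, the first and last three quarters,
#' and the central three quarters) and computes, per region: class composition
#' (7), transition frequencies between distinct classes at adjacent positions
#' (21 unordered class pairs), and the distribution of each class -- the
#' relative positions of its first, 25th-, 50th-, 75th-percentile and last
#' occurrence (35); absent classes contribute zeros.
#'
#' @inheritParams encode_ct
#' @return A `ppi_feature_block` of dimension 630.
#' @export
encode_ld <- function(seq, cmap = default_class_map(), id = "<sequence>") {
  s <- class_sequence(toupper(seq), cmap)
  L <- length(s)
  if (L < 10L) {
    stop(sprintf("sequence '%s' is too short for local descriptors (length %d < 10)",
                 id, L), call. = FALSE)
  }
  regs <- ld_regions(L)
  v <- unlist(lapply(regs, function(r) ld_region_features(s[r[1L]:r[2L]])))
  tp <- do.call(rbind, lapply(1:6, function(a) cbind(a, (a + 1L):7L)))
  names(v) <- paste0("LD_r", rep(1:10, each = 63L), "_",
                     c(paste0("C", 1:7),
                       paste0("T", tp[, 1L], tp[, 2L]),
                       paste0("D", rep(1:7, each = 5L), "_", rep(1:5, 7L))))
  new_feature_block("ld", v)
}

# lexicographic multiset tables for the 7-class alphabet
mmi_pairs <- function() {
  g <- expand.grid(b = 1:7, a = 1:7)
  g <- g[g$a <= g$b, c("a", "b")]
  g[order(g$a, g$b), ]
}
mmi_triples <- function() {
  g <- expand.grid(c = 1:7, b = 1:7, a = 1:7)
  g <- g[g$a <= g$b & g$b <= g$c, c("a", "b", "c")]
  g[order(g$a, g$b, g$c), ]
}

#' Multivariate mutual information (MMI)
#'
#' Entropy-based co-occurrence features on the 7-letter class alphabet:
#' mutual information of the 84 order-insensitive adjacent 3-grams, mutual
#' information of the 28 order-insensitive adjacent 2-grams, and the 7 class
#' frequencies.  Natural logarithms are used throughout and every term obeys
#' the convention `0 * log(0) = 0`.
#'
#' @inheritParams encode_ct
#' @return A `ppi_feature_block` of dimension 119 (84 + 28 + 7).
#' @export
encode_mmi <- function(seq, cmap = default_class_map(), id = "<sequence>") {
  s <- class_sequence(toupper(seq), cmap)
  L <- length(s)
  if (L < 3L) {
    stop(sprintf("sequence '%s' is too short for 3-grams (length %d < 3)", id, L),
         call. = FALSE)
  }
  xlog <- function(p) ifelse(p > 0, log(p), 0)
  f1 <- tabulate(s, nbins = 7L) / L
  # pooled (order-insensitive) 2-gram frequencies
  a2 <- pmin(s[-L], s[-1L]); b2 <- pmax(s[-L], s[-1L])
  P2 <- mmi_pairs()
  key2 <- function(a, b) a * 10L + b
  c2 <- tabulate(match(key2(a2, b2), key2(P2$a, P2$b)), nbins = 28L)
  f2 <- c2 / (L - 1L)
  # pooled 3-gram frequencies
  tri <- rbind(s[1:(L - 2L)], s[2:(L - 1L)], s[3:L])
  tri <- apply(tri, 2L, sort)
  P3 <- mmi_triples()
  key3 <- function(a, b, c) (a * 10L + b) * 10L + c
  c3 <- tabulate(match(key3(tri[1L, ], tri[2L, ], tri[3L, ]),
                       key3(P3$a, P3$b, P3$c)), nbins = 84L)
  f3 <- c3 / (L - 2L)
  lookup2 <- function(a, b) f2[match(key2(pmin(a, b), pmax(a, b)), key2(P2$a, P2$b))]
  H1 <- function(a) -xlog(f1[a]) * f1[a]
  Hcond <- function(a, b) {            # H(a|b) = -f(a,b) ln(f(a,b)/f(b))
    fab <- lookup2(a, b)
    ifelse(fab > 0 & f1[b] > 0, -fab * log(fab / f1[b]), 0)
  }
  I2 <- function(a, b) H1(a) - Hcond(a, b)
  # 3-gram chain: I(a,b,c) = I(a,b) - [H(a|c) - H(a|b,c)]
  Habc <- ifelse(f3 > 0 & lookup2(P3$b, P3$c) > 0,
                 -f3 * log(f3 / lookup2(P3$b, P3$c)), 0)
  mi3 <- I2(P3$a, P3$b) - (Hcond(P3$a, P3$c) - Habc)
  mi2 <- I2(P2$a, P2$b)
  v <- c(mi3, mi2, f1)
  names(v) <- c(sprintf("MMI3_%d%d%d", P3$a, P3$b, P3$c),
                sprintf("MMI2_%d%d", P2$a, P2$b),
                sprintf("freq_%d", 1:7))
  new_feature_block("mmi", v)
}

#' Concatenate two per-protein feature blocks into a pair feature
#'
#' The two proteins of a candidate pair are encoded independently with the
#' same technique (and lag) and their vectors concatenated, first protein
#' first, doubling the dimension.
#'
#' @param a,b `ppi_feature_block`s of the same technique and lag.
#' @return A `ppi_pair_feature` (also a `ppi_feature_block`).
#' @export
encode_pair <- function(a, b) {
  stopifnot(inherits(a, "ppi_feature_block"), inherits(b, "ppi_feature_block"))
  if (!identical(a$technique, b$technique)) {
    stop(sprintf("technique mismatch: %s vs %s", a$technique, b$technique),
         call. = FALSE)
  }
  if (!identical(is.na(a$lag), is.na(b$lag)) ||
      (!is.na(a$lag) && a$lag != b$lag)) {
    stop("lag mismatch between pair members", call. = FALSE)
  }
  v <- c(a$vector, b$vector)
  names(v) <- c(paste0("a_", names(a$vector)), paste0("b_", names(b$vector)))
  structure(list(technique = a$technique, lag = a$lag, vector = v,
                 dim = length(v)),
            class = c("ppi_pair_feature", "ppi_feature_block"))
}

encode_one <- function(technique, seq, lag, props, cmap, weight = 0.05,
                       id = "<sequence>") {
  switch(technique,
         pseaac = encode_pseaac(seq, lag = lag, weight = weight, props = props, id = id),
         ad = encode_ad(seq, lag = lag, props = props, id = id),
         ac = encode_ac(seq, lag = lag, props = props, id = id),
         ct = encode_ct(seq, cmap = cmap, id = id),
         ld = encode_ld(seq, cmap = cmap, id = id),
         mmi = encode_mmi(seq, cmap = cmap, id = id),
         stop("unknown technique: ", technique, call. = FALSE))
}

#' Build a pair-feature matrix for one technique
#'
#' Encodes every distinct protein once, then assembles one row per pair by
#' concatenating the two member vectors (first id in the pair list first).
#'
#' @param seqs Named character vector of protein sequences.
#' @param pairs Data frame with columns `id_a`, `id_b` (and optionally
#'   `label`); ids must name elements of `seqs`.
#' @param technique One of `"pseaac"`, `"ad"`, `"ac"`, `"ct"`, `"ld"`, `"mmi"`.
#' @param lag Lag for the descriptor-profile techniques (ignored by CT/LD/MMI).
#' @param props Standardized property table.
#' @param cmap Class map.
#' @param weight PseAAC composition/order weight.
#' @return Numeric matrix, `nrow(pairs)` rows, named columns; attribute
#'   `technique` and `lag` record provenance.
#' @export
featurize_pairs <- function(seqs, pairs, technique,
                            lag = default_lags()[[technique]],
                            props = default_property_table(),
                            cmap = default_class_map(), weight = 0.05) {
  technique <- match.arg(technique, TECHNIQUES)
  ids <- unique(c(pairs$id_a, pairs$id_b))
  unknown <- setdiff(ids, names(seqs))
  if (length(unknown)) {
    stop("pair list references unknown sequence id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  enc <- vapply(ids, function(i) {
    encode_one(technique, seqs[[i]], lag, props, cmap, weight, id = i)$vector
  }, encode_one(technique, seqs[[ids[1L]]], lag, props, cmap, weight)$vector)
  enc <- t(enc)   # proteins x dim
  m <- cbind(enc[match(pairs$id_a, ids), , drop = FALSE],
             enc[match(pairs$id_b, ids), , drop = FALSE])
  colnames(m) <- c(paste0("a_", colnames(enc)), paste0("b_", colnames(enc)))
  rownames(m) <- NULL
  attr(m, "technique") <- technique
  attr(m, "lag") <- if (technique %in% c("pseaac", "ad", "ac")) as.integer(lag) else NA_integer_
  m
}

#' Default lags for the descriptor-profile techniques
#'
#' The package defaults are lag 8 for PseAAC, 7 for AD and 9 for AC, giving
#' per-protein dimensions 28, 273 and 117.
#'
#' @return Named list of integer lags.
#' @export
default_lags <- function() list(pseaac = 8L, ad = 7L, ac = 9L, ct = NA_integer_,
                                ld = NA_integer_, mmi = NA_integer_)
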