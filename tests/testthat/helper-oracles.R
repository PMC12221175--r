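# Independent brute-force oracles for the encoders and metrics: plain nested
# loops over the defining formulas, no vectorization, no shared code with the
# implementations under test.

random_protein <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# mean squared difference of property components between two residues
oracle_theta_term <- function(r1, r2, P) {
  s <- 0
  for (k in seq_len(ncol(P))) s <- s + (P[r1, k] - P[r2, k])^2
  s / ncol(P)
}

oracle_pseaac <- function(seq, lag, w, props) {
  ch <- seq_chars(seq)
  L <- length(ch)
  P <- props$values
  comp <- numeric(20)
  for (i in seq_len(L)) comp[match(ch[i], aa_alphabet())] <-
      comp[match(ch[i], aa_alphabet())] + 1
  comp <- comp / L
  theta <- numeric(lag)
  for (j in seq_len(lag)) {
    s <- 0
    for (i in seq_len(L - j)) s <- s + oracle_theta_term(ch[i], ch[i + j], P)
    theta[j] <- s / (L - j)
  }
  den <- sum(comp) + w * sum(theta)
  c(comp, w * theta) / den
}

oracle_ad <- function(seq, lag, props) {
  ch <- seq_chars(seq)
  L <- length(ch)
  P <- props$values
  mb <- moran <- geary <- c()
  for (k in seq_len(ncol(P))) {
    p <- numeric(L)
    for (i in seq_len(L)) p[i] <- P[ch[i], k]
    pbar <- mean(p)
    ss <- sum((p - pbar)^2)
    for (d in seq_len(lag)) {
      s1 <- s2 <- s3 <- 0
      for (i in seq_len(L - d)) {
        s1 <- s1 + p[i] * p[i + d]
        s2 <- s2 + (p[i] - pbar) * (p[i + d] - pbar)
        s3 <- s3 + (p[i] - p[i + d])^2
      }
      mb <- c(mb, s1 / (L - d))
      moran <- c(moran, if (ss > 0) (s2 / (L - d)) / (ss / L) else 0)
      geary <- c(geary, if (ss > 0) (s3 / (2 * (L - d))) / (ss / (L - 1)) else 0)
    }
  }
  c(mb, moran, geary)
}

oracle_ac <- function(seq, lag, props) {
  ch <- seq_chars(seq)
  L <- length(ch)
  P <- props$values
  out <- c()
  for (k in seq_len(ncol(P))) {
    p <- numeric(L)
    for (i in seq_len(L)) p[i] <- P[ch[i], k]
    pbar <- mean(p)
    for (d in seq_len(lag)) {
      s <- 0
      for (i in seq_len(L - d)) s <- s + (p[i] - pbar) * (p[i + d] - pbar)
      out <- c(out, s / (L - d))
    }
  }
  out
}

oracle_ct <- function(seq, cmap) {
  ch <- seq_chars(seq)
  L <- length(ch)
  cls <- integer(L)
  for (i in seq_len(L)) cls[i] <- unclass(cmap)[[ch[i]]]
  f <- numeric(343)
  for (i in seq_len(L - 2)) {
    idx <- (cls[i] - 1) * 49 + (cls[i + 1] - 1) * 7 + cls[i + 2]
    f[idx] <- f[idx] + 1
  }
  (f - min(f)) / max(f)
}

oracle_ld_boundaries <- function(L) {
  q1 <- max(1, round(0.25 * L)); q2 <- max(1, round(0.5 * L))
  q3 <- max(1, round(0.75 * L))
  e1 <- max(1, round(0.125 * L)); e2 <- max(1, round(0.875 * L))
  list(c(1, q1), c(q1 + 1, q2), c(q2 + 1, q3), c(q3 + 1, L),
       c(1, q2), c(q2 + 1, L), c(q1 + 1, q3), c(1, q3), c(q1 + 1, L),
       c(e1 + 1, e2))
}

oracle_ld <- function(seq, cmap) {
  ch <- seq_chars(seq)
  L <- length(ch)
  cls <- integer(L)
  for (i in seq_len(L)) cls[i] <- unclass(cmap)[[ch[i]]]
  out <- c()
  for (reg in oracle_ld_boundaries(L)) {
    s <- cls[reg[1]:reg[2]]
    n <- length(s)
    comp <- numeric(7)
    for (i in seq_len(n)) comp[s[i]] <- comp[s[i]] + 1
    comp <- comp / n
    tran <- c()
    for (a in 1:6) for (b in (a + 1):7) {
      cnt <- 0
      if (n >= 2) for (i in seq_len(n - 1)) {
        if ((s[i] == a && s[i + 1] == b) || (s[i] == b && s[i + 1] == a)) cnt <- cnt + 1
      }
      tran <- c(tran, if (n >= 2) cnt / (n - 1) else 0)
    }
    dist <- c()
    for (k in 1:7) {
      pos <- c()
      for (i in seq_len(n)) if (s[i] == k) pos <- c(pos, i)
      m <- length(pos)
      if (m == 0) dist <- c(dist, rep(0, 5))
      else dist <- c(dist, pos[1] / n, pos[ceiling(0.25 * m)] / n,
                     pos[ceiling(0.5 * m)] / n, pos[ceiling(0.75 * m)] / n,
                     pos[m] / n)
    }
    out <- c(out, comp, tran, dist)
  }
  out
}

oracle_mmi <- function(seq, cmap) {
  ch <- seq_chars(seq)
  L <- length(ch)
  cls <- integer(L)
  for (i in seq_len(L)) cls[i] <- unclass(cmap)[[ch[i]]]
  f1 <- numeric(7)
  for (i in seq_len(L)) f1[cls[i]] <- f1[cls[i]] + 1
  f1 <- f1 / L
  # order-insensitive 2-gram table
  pair_list <- list()
  for (a in 1:7) for (b in a:7) pair_list[[length(pair_list) + 1]] <- c(a, b)
  f2 <- numeric(28)
  for (i in seq_len(L - 1)) {
    ab <- sort(c(cls[i], cls[i + 1]))
    for (q in seq_along(pair_list)) {
      if (all(pair_list[[q]] == ab)) f2[q] <- f2[q] + 1
    }
  }
  f2 <- f2 / (L - 1)
  tri_list <- list()
  for (a in 1:7) for (b in a:7) for (cc in b:7) {
    tri_list[[length(tri_list) + 1]] <- c(a, b, cc)
  }
  f3 <- numeric(84)
  for (i in seq_len(L - 2)) {
    abc <- sort(c(cls[i], cls[i + 1], cls[i + 2]))
    for (q in seq_along(tri_list)) {
      if (all(tri_list[[q]] == abc)) f3[q] <- f3[q] + 1
    }
  }
  f3 <- f3 / (L - 2)
  get2 <- function(a, b) {
    ab <- sort(c(a, b))
    for (q in seq_along(pair_list)) if (all(pair_list[[q]] == ab)) return(f2[q])
  }
  H1 <- function(a) if (f1[a] > 0) -f1[a] * log(f1[a]) else 0
  Hc <- function(a, b) {
    fab <- get2(a, b)
    if (fab > 0 && f1[b] > 0) -fab * log(fab / f1[b]) else 0
  }
  I2 <- function(a, b) H1(a) - Hc(a, b)
  mi3 <- numeric(84)
  for (q in seq_along(tri_list)) {
    a <- tri_list[[q]][1]; b <- tri_list[[q]][2]; cc <- tri_list[[q]][3]
    fbc <- get2(b, cc)
    Habc <- if (f3[q] > 0 && fbc > 0) -f3[q] * log(f3[q] / fbc) else 0
    mi3[q] <- I2(a, b) - (Hc(a, cc) - Habc)
  }
  mi2 <- numeric(28)
  for (q in seq_along(pair_list)) {
    mi2[q] <- I2(pair_list[[q]][1], pair_list[[q]][2])
  }
  c(mi3, mi2, f1)
}

oracle_encoder <- function(technique, seq, lag, props, cmap, w = 0.05) {
  switch(technique,
         pseaac = oracle_pseaac(seq, lag, w, props),
         ad = oracle_ad(seq, lag, props),
         ac = oracle_ac(seq, lag, props),
         ct = oracle_ct(seq, cmap),
         ld = oracle_ld(seq, cmap),
         mmi = oracle_mmi(seq, cmap))
}

# confusion-matrix metric oracle: scalar loops and the closed-form definitions
oracle_metrics <- function(truth, prob, threshold = 0.5) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(truth)) {
    pred <- if (prob[i] >= threshold) 1 else 0
    if (truth[i] == 1 && pred == 1) tp <- tp + 1
    if (truth[i] == 0 && pred == 1) fp <- fp + 1
    if (truth[i] == 0 && pred == 0) tn <- tn + 1
    if (truth[i] == 1 && pred == 0) fn <- fn + 1
  }
  n <- length(truth)
  sdiv <- function(a, b) if (b == 0) 0 else a / b
  pre <- sdiv(tp, tp + fp); se <- sdiv(tp, tp + fn)
  list(ACC = (tp + tn) / n, PRE = pre, SE = se, SP = sdiv(tn, tn + fp),
       F1 = sdiv(2 * pre * se, pre + se),
       MCC = sdiv(tp * tn - fp * fn,
                  sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)))
}

# AUC via the rank-statistic identity (Mann-Whitney U with averaged tie ranks)
oracle_auc_rank <- function(truth, prob) {
  r <- rank(prob)   # average ties
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# average precision for tie-free scores: mean over positives of the precision
# at each positive's rank (equals the step-summed PR area when scores are
# unique)
oracle_aupr_unique <- function(truth, prob) {
  ord <- order(prob, decreasing = TRUE)
  truth <- truth[ord]
  npos <- sum(truth == 1)
  s <- 0; tp <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1) { tp <- tp + 1; s <- s + tp / i }
  }
  s / npos
}

# plain-R GRU forward (double precision) for cross-checking the C++ kernel
oracle_gru_forward <- function(dp, x, h, backward = FALSE) {
  sigmoid <- function(v) 1 / (1 + exp(-v))
  H <- rep(0, h)
  idx <- if (backward) rev(seq_along(x)) else seq_along(x)
  for (t in idx) {
    Gi <- x[t] * dp$wx + dp$bi
    Gh <- as.numeric(H %*% dp$Wh) + dp$bh
    r <- sigmoid(Gi[1:h] + Gh[1:h])
    z <- sigmoid(Gi[(h + 1):(2 * h)] + Gh[(h + 1):(2 * h)])
    n <- tanh(Gi[(2 * h + 1):(3 * h)] + r * Gh[(2 * h + 1):(3 * h)])
    H <- (1 - z) * n + z * H
  }
  H
}
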