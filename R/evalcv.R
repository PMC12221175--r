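# Stratified five-fold cross-validation, evaluation metrics, lag
# optimization, and the frozen-pipeline external-test protocol.

#' Stratified k-fold assignment
#'
#' Splits `n` samples into `k` mutually exclusive folds of sizes differing by
#' at most one, with each class spread across folds as evenly as possible
#' (per-fold class counts within one of proportionality).
#'
#' @param labels Binary label vector.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (n < k) stop("need at least k samples for k folds", call. = FALSE)
  if (length(unique(labels)) < 2L) stop("both classes must be present", call. = FALSE)
  set.seed(as.integer(seed))
  fold <- integer(n)
  offset <- sample.int(k, 1L) - 1L   # rotate so no class always starts at fold 1
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Confusion counts at a threshold
#'
#' @param truth Binary truth vector.
#' @param predicted Binary predicted-label vector.
#' @return Named list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  list(TP = sum(truth == 1 & predicted == 1),
       FP = sum(truth == 0 & predicted == 1),
       TN = sum(truth == 0 & predicted == 0),
       FN = sum(truth == 1 & predicted == 0))
}

# trapezoid area under the ROC curve; ties in score handled by grouping
# (equivalently: averaged tie ranks)
roc_auc <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  # cumulative TP/FP at each distinct threshold
  grp <- cumsum(!duplicated(score))
  tp <- cumsum(truth == 1); fp <- cumsum(truth == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

# area under the precision-recall curve by step summation over distinct
# score thresholds
pr_auc <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  npos <- sum(truth == 1)
  if (npos == 0L) return(NA_real_)
  grp <- cumsum(!duplicated(score))
  tp <- cumsum(truth == 1)
  n_at <- seq_along(truth)
  last <- !duplicated(grp, fromLast = TRUE)
  rec <- tp[last] / npos
  prec <- tp[last] / n_at[last]
  sum(diff(c(0, rec)) * prec)
}

#' Evaluation metrics for binary interaction predictions
#'
#' Computes accuracy, precision, sensitivity, specificity, F1, Matthews
#' correlation coefficient, and the areas under the ROC and precision-recall
#' curves.  Any ratio with a zero denominator is reported as 0 and flagged in
#' the `degenerate` field rather than propagating non-finite values.
#'
#' @param truth Binary truth vector.
#' @param predictions A `ppi_predictions` data frame (from
#'   [predict.ppi_classifier()]), or a numeric probability vector.
#' @param threshold Hard-label cutoff when `predictions` is a probability
#'   vector (default 0.5).
#' @return An object of class `ppi_metrics`: named list with `ACC`, `PRE`,
#'   `SE`, `SP`, `F1`, `MCC`, `AUC`, `AUPR`, the confusion `counts`, and
#'   `degenerate` (names of zero-denominator metrics).
#' @export
compute_metrics <- function(truth, predictions, threshold = 0.5) {
  if (inherits(predictions, "ppi_predictions") || is.data.frame(predictions)) {
    prob <- predictions$probability
    hard <- predictions$label
  } else {
    prob <- as.numeric(predictions)
    hard <- as.integer(prob >= threshold)
  }
  truth <- as.integer(truth)
  if (length(truth) != length(prob)) {
    stop("truth and prediction lengths differ", call. = FALSE)
  }
  cc <- confusion_counts(truth, hard)
  degenerate <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  n <- length(truth)
  ACC <- (cc$TP + cc$TN) / n
  PRE <- div(cc$TP, cc$TP + cc$FP, "PRE")
  SE <- div(cc$TP, cc$TP + cc$FN, "SE")
  SP <- div(cc$TN, cc$TN + cc$FP, "SP")
  F1 <- div(2 * PRE * SE, PRE + SE, "F1")
  mden <- sqrt(prod(c(cc$TP + cc$FP, cc$TP + cc$FN, cc$TN + cc$FP, cc$TN + cc$FN)))
  MCC <- div(cc$TP * cc$TN - cc$FP * cc$FN, mden, "MCC")
  structure(list(ACC = ACC, PRE = PRE, SE = SE, SP = SP, F1 = F1, MCC = MCC,
                 AUC = roc_auc(truth, prob), AUPR = pr_auc(truth, prob),
                 counts = cc, degenerate = degenerate),
            class = "ppi_metrics")
}

#' @export
print.ppi_metrics <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  PRE %.2f%%  SE %.2f%%  SP %.2f%%  F1 %.2f%%  MCC %.4f  AUC %.4f  AUPR %.4f\n",
              100 * x$ACC, 100 * x$PRE, 100 * x$SE, 100 * x$SP, 100 * x$F1,
              x$MCC, x$AUC, x$AUPR))
  if (length(x$degenerate)) {
    cat("  (zero-denominator, reported as 0:", paste(x$degenerate, collapse = ", "), ")\n")
  }
  invisible(x)
}

metric_names <- function() c("ACC", "PRE", "SE", "SP", "F1", "MCC", "AUC", "AUPR")

metrics_row <- function(m) {
  vapply(metric_names(), function(k) as.numeric(m[[k]]), numeric(1L))
}

reduce_blocks <- function(blocks, labels, strategy, direction, seed, epochs,
                          learning_rate, clip_norm, batch_size, train = TRUE) {
  switch(strategy,
         multiens = reduce_multiens(blocks, labels, direction, seed, epochs,
                                    learning_rate, clip_norm, batch_size, train),
         multicon = reduce_multicon(blocks, labels, direction, seed,
                                    epochs = epochs,
                                    learning_rate = learning_rate,
                                    clip_norm = clip_norm,
                                    batch_size = batch_size, train = train),
         multisep = reduce_multisep(blocks, labels, direction, seed, epochs,
                                    learning_rate, clip_norm, batch_size, train),
         stop("unknown strategy: ", strategy, call. = FALSE))
}

apply_reducers <- function(reducers, blocks, strategy) {
  if (strategy == "multiens") {
    parts <- lapply(TECHNIQUES, function(tech) {
      extract_hidden(reducers[[tech]], blocks[[tech]])$hidden_states
    })
  } else if (strategy == "multicon") {
    parts <- list(extract_hidden(reducers$all, do.call(cbind, blocks[TECHNIQUES]))$hidden_states)
  } else {
    parts <- list(
      extract_hidden(reducers$svhehs,
                     do.call(cbind, blocks[c("pseaac", "ad", "ac")]))$hidden_states,
      extract_hidden(reducers$classes,
                     do.call(cbind, blocks[c("ct", "ld", "mmi")]))$hidden_states)
  }
  do.call(cbind, parts)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs stratified five-fold cross-validation of encode -> GRU reduction ->
#' gradient-boosted classification.  Feature encoding is label-free and is
#' computed once for all pairs; by default the reducers (which are supervised)
#' are trained only on each fold's training split and applied to its held-out
#' split.  Setting `paper_mode = TRUE` instead trains the reducers once on the
#' complete pair set before cross-validation — a faithfulness variant that
#' leaks held-out labels into the reduction step and therefore tends to score
#' at least as high as the default.
#'
#' @param seqs Named character vector of protein sequences.
#' @param pairs Data frame with `id_a`, `id_b`, `label`.
#' @param lags Named lags for pseaac/ad/ac (default `default_lags()`).
#' @param strategy `"multiens"` (default), `"multicon"` or `"multisep"`.
#' @param direction GRU direction (default `"bidirectional"`).
#' @param k Folds (default 5).
#' @param seed Seed for fold assignment and (offset) reducer training.
#' @param paper_mode Train reducers once on the full set (default FALSE).
#' @param config Classifier configuration.
#' @param props,cmap Property table and class map.
#' @param epochs,learning_rate,clip_norm,batch_size Reducer hyperparameters.
#' @param blocks Optional precomputed feature blocks (named list as produced
#'   by [featurize_pairs()] for all six techniques); when supplied, `seqs`
#'   may be NULL.
#' @return An object of class `ppi_cv`: per-fold metric matrix, mean and sd
#'   per metric, fold assignment, and the configuration used.
#' @export
run_cv <- function(seqs, pairs, lags = default_lags(), strategy = "multiens",
                   direction = "bidirectional", k = 5L, seed = 1L,
                   paper_mode = FALSE, config = classifier_config(),
                   props = default_property_table(), cmap = default_class_map(),
                   epochs = 5L, learning_rate = 0.001, clip_norm = 1,
                   batch_size = 64L, blocks = NULL) {
  strategy <- match.arg(strategy, c("multiens", "multicon", "multisep"))
  labels <- as.integer(pairs$label)
  if (is.null(blocks)) {
    blocks <- stats::setNames(lapply(TECHNIQUES, function(tech) {
      featurize_pairs(seqs, pairs, tech, lag = lags[[tech]], props = props,
                      cmap = cmap)
    }), TECHNIQUES)
  }
  fold <- stratified_kfold(labels, k = k, seed = seed)

  full_red <- NULL
  if (paper_mode) {
    full_red <- reduce_blocks(blocks, labels, strategy, direction, seed,
                              epochs, learning_rate, clip_norm, batch_size)
  }

  per_fold <- matrix(NA_real_, nrow = k, ncol = length(metric_names()),
                     dimnames = list(paste0("fold", seq_len(k)), metric_names()))
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    if (paper_mode) {
      hs_tr <- full_red$hidden_states[tr, , drop = FALSE]
      hs_te <- full_red$hidden_states[te, , drop = FALSE]
    } else {
      btr <- lapply(blocks, function(b) b[tr, , drop = FALSE])
      red <- reduce_blocks(btr, labels[tr], strategy, direction,
                           seed + 1000L * f, epochs, learning_rate,
                           clip_norm, batch_size)
      hs_tr <- red$hidden_states
      bte <- lapply(blocks, function(b) b[te, , drop = FALSE])
      hs_te <- apply_reducers(red$reducers, bte, strategy)
    }
    clf <- fit_classifier(hs_tr, labels[tr], config = config)
    pred <- predict(clf, hs_te)
    per_fold[f, ] <- metrics_row(compute_metrics(labels[te], pred))
  }
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold),
                 sd = apply(per_fold, 2L, stats::sd),
                 fold = fold,
                 merged_width = if (paper_mode) ncol(full_red$hidden_states) else ncol(hs_tr),
                 config = list(lags = lags, strategy = strategy,
                               direction = direction, k = k, seed = seed,
                               paper_mode = paper_mode, epochs = epochs,
                               learning_rate = learning_rate,
                               clip_norm = clip_norm, batch_size = batch_size,
                               n_iterations = config$n_iterations)),
            class = "ppi_cv")
}

#' @export
print.ppi_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s, %s%s), merged width %d\n",
              x$config$k, x$config$strategy, x$config$direction,
              if (x$config$paper_mode) ", paper-mode reducers" else "",
              x$merged_width))
  m <- rbind(x$per_fold, mean = x$mean, sd = x$sd)
  print(round(m, 4))
  invisible(x)
}

#' Optimize the lag parameter of a descriptor-profile technique
#'
#' For each candidate lag, encodes all pairs with the single technique, feeds
#' the raw pair features directly to the gradient-boosted classifier (no GRU
#' reduction at this stage), and evaluates by stratified k-fold
#' cross-validation.  Returns the per-lag mean metrics and the accuracy-optimal
#' lag (ties broken towards the smallest lag, which gives the cheapest
#' features).
#'
#' @param seqs Named character vector of sequences.
#' @param pairs Pair data frame with `label`.
#' @param technique `"pseaac"`, `"ad"` or `"ac"`.
#' @param lag_range Candidate lags (default `1:11`).
#' @param k,seed Cross-validation folds and seed.
#' @param config Classifier configuration.
#' @param props Standardized property table.
#' @return An object of class `ppi_lag_scan`: list with `best_lag`, `table`
#'   (per-lag mean metrics), and `technique`.
#' @export
optimize_lag <- function(seqs, pairs, technique, lag_range = 1:11, k = 5L,
                         seed = 1L, config = classifier_config(),
                         props = default_property_table()) {
  technique <- match.arg(technique, c("pseaac", "ad", "ac"))
  used <- unique(c(pairs$id_a, pairs$id_b))
  lens <- nchar(seqs[used])
  shortest <- min(lens)
  if (max(lag_range) >= shortest) {
    off <- used[which.min(lens)]
    stop(sprintf("lag %d is infeasible: sequence '%s' has length %d (need length >= lag + 1)",
                 max(lag_range), off, shortest), call. = FALSE)
  }
  labels <- as.integer(pairs$label)
  fold <- stratified_kfold(labels, k = k, seed = seed)
  tab <- matrix(NA_real_, nrow = length(lag_range), ncol = length(metric_names()),
                dimnames = list(paste0("lag", lag_range), metric_names()))
  for (i in seq_along(lag_range)) {
    x <- featurize_pairs(seqs, pairs, technique, lag = lag_range[i], props = props)
    fm <- matrix(NA_real_, nrow = k, ncol = length(metric_names()))
    for (f in seq_len(k)) {
      tr <- fold != f
      clf <- fit_classifier(x[tr, , drop = FALSE], labels[tr], config = config)
      pred <- predict(clf, x[!tr, , drop = FALSE])
      fm[f, ] <- metrics_row(compute_metrics(labels[!tr], pred))
    }
    tab[i, ] <- colMeans(fm)
  }
  best <- lag_range[which.max(tab[, "ACC"])]   # which.max takes the first tie
  structure(list(best_lag = as.integer(best), table = tab,
                 technique = technique, lag_range = lag_range),
            class = "ppi_lag_scan")
}

#' @export
print.ppi_lag_scan <- function(x, ...) {
  cat(sprintf("lag scan for %s: best lag %d (mean CV accuracy)\n",
              toupper(x$technique), x$best_lag))
  print(round(x$table, 4))
  invisible(x)
}

#' Test a fitted model on an external pair set
#'
#' Applies a frozen fitted pipeline (see [ppi_fit()]) to an independent pair
#' set, as in cross-species evaluation.  For positive-only sets (every label
#' 1), specificity and related quantities are undefined; the report carries a
#' `positive_only` flag and accuracy equals sensitivity.  Sequences too short
#' for the trained lags are skipped with a recorded count.
#'
#' @param model A fitted `ppigru_model`.
#' @param seqs Named character vector of external sequences.
#' @param pairs External pair data frame with `id_a`, `id_b`, `label`.
#' @return A `ppi_metrics` object with extra fields `positive_only` and
#'   `n_skipped`.
#' @export
cross_dataset_test <- function(model, seqs, pairs) {
  stopifnot(inherits(model, "ppigru_model"))
  if (nrow(pairs) == 0L) stop("external test set is empty", call. = FALSE)
  min_len <- max(unlist(model$lags[c("pseaac", "ad", "ac")])) + 1L
  ok <- nchar(seqs[pairs$id_a]) >= min_len & nchar(seqs[pairs$id_b]) >= min_len
  n_skipped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no external pair satisfies the trained lag constraints",
                              call. = FALSE)
  pred <- predict(model, seqs = seqs, pairs = pairs)
  m <- compute_metrics(as.integer(pairs$label), pred)
  m$positive_only <- all(pairs$label == 1)
  m$n_skipped <- n_skipped
  if (m$positive_only) m$SP <- m$AUC <- m$AUPR <- NA_real_
  m
}
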