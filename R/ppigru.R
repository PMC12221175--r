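# Front-end model interface: fit the full pipeline on a labeled pair set and
# predict on new pairs.

#' Fit a sequence-based protein-protein interaction model
#'
#' Runs the complete pipeline on a labeled pair set: encodes every pair with
#' the six feature coding techniques (PseAAC, AD, AC at the given lags; CT,
#' LD, MMI on the 7-class alphabet), reduces each block with supervised GRU
#' reducers under the chosen ensemble strategy, and fits the gradient-boosted
#' classifier on the merged hidden states.  The fitted object freezes the
#' property table, class map, lags, trained reducers and classifier, so it
#' can score external pair sets ([predict.ppigru_model()],
#' [cross_dataset_test()]).
#'
#' @param seqs Named character vector of protein sequences.
#' @param pairs Data frame with columns `id_a`, `id_b`, `label`.
#' @param lags Named list of lags (defaults: pseaac 8, ad 7, ac 9).
#' @param strategy `"multiens"` (default), `"multicon"` or `"multisep"`.
#' @param direction `"bidirectional"` (default), `"forward"` or `"backward"`.
#' @param reducer_seed,classifier_seed Seeds for the two trained stages.
#' @param epochs,learning_rate,clip_norm,batch_size GRU training
#'   hyperparameters (defaults 5, 0.001, 1, 64).
#' @param n_iterations Boosting rounds (default 500).
#' @param props Standardized property table (packaged default).
#' @param cmap Class map (packaged default).
#' @param weight PseAAC weight (default 0.05).
#' @return An object of class `ppigru_model`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_ppi_data(n_pairs = 60, length_range = c(30, 60), seed = 7)
#' fit <- ppi_fit(sim$seqs, sim$pairs, epochs = 1, n_iterations = 20)
#' predict(fit, sim$seqs, sim$pairs[1:5, ])
#' }
ppi_fit <- function(seqs, pairs, lags = default_lags(),
                    strategy = c("multiens", "multicon", "multisep"),
                    direction = c("bidirectional", "forward", "backward"),
                    reducer_seed = 1L, classifier_seed = 1L, epochs = 5L,
                    learning_rate = 0.001, clip_norm = 1, batch_size = 64L,
                    n_iterations = 500L, props = default_property_table(),
                    cmap = default_class_map(), weight = 0.05) {
  strategy <- match.arg(strategy)
  direction <- match.arg(direction)
  labels <- as.integer(pairs$label)
  blocks <- stats::setNames(lapply(TECHNIQUES, function(tech) {
    featurize_pairs(seqs, pairs, tech, lag = lags[[tech]], props = props,
                    cmap = cmap, weight = weight)
  }), TECHNIQUES)
  red <- reduce_blocks(blocks, labels, strategy, direction, reducer_seed,
                       epochs, learning_rate, clip_norm, batch_size)
  clf <- fit_classifier(red$hidden_states, labels,
                        config = classifier_config(n_iterations = n_iterations,
                                                   seed = classifier_seed))
  structure(list(lags = lags, strategy = strategy, direction = direction,
                 props = props, cmap = cmap, weight = weight,
                 reducers = red$reducers, classifier = clf,
                 merged_width = ncol(red$hidden_states),
                 n_train_pairs = nrow(pairs),
                 reducer_loss = lapply(red$reducers, function(r) r$loss_history)),
            class = "ppigru_model")
}

#' Predict interactions for new protein pairs
#'
#' Encodes the given pairs with the model's frozen lags and tables, applies
#' the trained reducers, and scores with the trained classifier.
#'
#' @param object A `ppigru_model`.
#' @param seqs Named character vector covering all ids in `pairs`.
#' @param pairs Data frame with `id_a`, `id_b`.
#' @param threshold Hard-label cutoff (default 0.5).
#' @param ... Unused.
#' @return A `ppi_predictions` data frame with `id_a`, `id_b`,
#'   `probability`, `label`.
#' @export
predict.ppigru_model <- function(object, seqs, pairs, threshold = 0.5, ...) {
  blocks <- stats::setNames(lapply(TECHNIQUES, function(tech) {
    featurize_pairs(seqs, pairs, tech, lag = object$lags[[tech]],
                    props = object$props, cmap = object$cmap,
                    weight = object$weight)
  }), TECHNIQUES)
  hs <- apply_reducers(object$reducers, blocks, object$strategy)
  out <- predict(object$classifier, hs, threshold = threshold)
  out$id_a <- pairs$id_a
  out$id_b <- pairs$id_b
  out[, c("id_a", "id_b", "probability", "label")]
}

#' @export
print.ppigru_model <- function(x, ...) {
  cat(sprintf("Sequence-based PPI model (%s, %s GRU reducers -> %s)\n",
              x$strategy, x$direction, x$classifier$backend_name))
  cat(sprintf("  trained on %d pairs; merged reduced width %d\n",
              x$n_train_pairs, x$merged_width))
  cat(sprintf("  lags: PseAAC %d, AD %d, AC %d\n",
              x$lags$pseaac, x$lags$ad, x$lags$ac))
  invisible(x)
}

#' @export
summary.ppigru_model <- function(object, ...) {
  print(object)
  cat("  reducers:\n")
  for (nm in names(object$reducers)) {
    r <- object$reducers[[nm]]
    loss <- r$loss_history
    cat(sprintf("    %-8s %4d -> %3d  (final training loss %.4f)\n",
                nm, r$input_dim, reducer_output_dim(r),
                if (length(loss)) loss[length(loss)] else NA_real_))
  }
  invisible(object)
}

#' Plot a lag scan
#'
#' Mean cross-validated accuracy against the candidate lag, with the selected
#' lag marked.
#'
#' @param x A `ppi_lag_scan`.
#' @param ... Passed to [plot()].
#' @export
plot.ppi_lag_scan <- function(x, ...) {
  acc <- 100 * x$table[, "ACC"]
  plot(x$lag_range, acc, type = "b", pch = 16,
       xlab = "lag", ylab = "mean CV accuracy (%)",
       main = sprintf("Lag optimization: %s", toupper(x$technique)), ...)
  graphics::abline(v = x$best_lag, lty = 2)
  invisible(x)
}
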