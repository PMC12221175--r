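# Gradient-boosted tree classification of the reduced features, behind a
# pluggable fit/predict backend interface.

#' Classifier configuration
#'
#' @param n_iterations Boosting rounds (default 500).
#' @param seed Random seed handed to the backend (default 1).
#' @param extra_params Named list passed through to the backend untouched;
#'   everything not set here stays at the backend's defaults.
#' @return An object of class `ppi_classifier_config`.
#' @export
classifier_config <- function(n_iterations = 500L, seed = 1L,
                              extra_params = list()) {
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L) {
    stop("n_iterations must be >= 1", call. = FALSE)
  }
  structure(list(n_iterations = n_iterations, seed = as.integer(seed),
                 extra_params = extra_params),
            class = "ppi_classifier_config")
}

# Default backend: xgboost gradient-boosted decision trees (binary logistic
# objective, single thread for determinism, everything else at package
# defaults unless overridden through extra_params).
xgboost_backend <- function() {
  list(
    name = "xgboost",
    fit = function(x, y, config) {
      params <- utils::modifyList(
        list(objective = "binary:logistic", nthread = 1L,
             seed = config$seed),
        config$extra_params)
      set.seed(config$seed)
      booster <- xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
        nrounds = config$n_iterations, verbose = 0L)
      list(model = booster, params_used = params,
           importance = function() {
             xgboost::xgb.importance(model = booster)
           })
    },
    predict = function(fitted, x) {
      as.numeric(stats::predict(fitted$model,
                                xgboost::xgb.DMatrix(x, nthread = 1L)))
    })
}

#' Fit the interaction classifier
#'
#' Trains a gradient-boosted decision-tree model (xgboost backend by default)
#' on reduced features.  Any backend providing `fit(x, y, config)` and
#' `predict(fitted, x)` can be substituted, so alternative classifiers slot
#' in without touching the rest of the pipeline.
#'
#' @param features A `ppi_reduced` object, or a plain numeric matrix.
#' @param labels Binary labels; defaults to `features$labels`.
#' @param config A [classifier_config()].
#' @param backend A backend list (`name`, `fit`, `predict`); default xgboost.
#' @return An object of class `ppi_classifier`.
#' @export
fit_classifier <- function(features, labels = NULL,
                           config = classifier_config(),
                           backend = xgboost_backend()) {
  x <- if (inherits(features, "ppi_reduced")) features$hidden_states else features
  if (is.null(labels) && inherits(features, "ppi_reduced")) labels <- features$labels
  stopifnot(is.matrix(x), !is.null(labels))
  labels <- as.numeric(labels)
  if (length(labels) != nrow(x)) stop("label/row count mismatch", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to fit the classifier", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  fitted <- backend$fit(x, labels, config)
  structure(list(backend_name = backend$name, backend = backend,
                 fitted = fitted, config = config,
                 feature_names = colnames(x), n_features = ncol(x)),
            class = "ppi_classifier")
}

#' Predict interaction probabilities
#'
#' @param object A `ppi_classifier`.
#' @param newdata A `ppi_reduced` or numeric matrix with the training width.
#' @param threshold Hard-label cutoff (default 0.5).
#' @param ... Unused.
#' @return An object of class `ppi_predictions`: data frame with columns
#'   `probability` and `label` (`1` iff probability >= threshold), plus pair
#'   ids when available.
#' @export
predict.ppi_classifier <- function(object, newdata, threshold = 0.5, ...) {
  x <- if (inherits(newdata, "ppi_reduced")) newdata$hidden_states else newdata
  stopifnot(is.matrix(x))
  if (ncol(x) != object$n_features) {
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(x), object$n_features), call. = FALSE)
  }
  if (nrow(x) == 0L) {
    return(structure(data.frame(probability = numeric(0), label = integer(0)),
                     class = c("ppi_predictions", "data.frame")))
  }
  p <- object$backend$predict(object$fitted, x)
  structure(data.frame(probability = p, label = as.integer(p >= threshold)),
            class = c("ppi_predictions", "data.frame"))
}

#' @export
print.ppi_classifier <- function(x, ...) {
  cat(sprintf("<%s classifier: %d features, %d boosting rounds, seed %d>\n",
              x$backend_name, x$n_features, x$config$n_iterations,
              x$config$seed))
  invisible(x)
}
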