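# Supervised GRU feature reduction: the dimension rule, reducer construction
# and training, hidden-state extraction, and the three ensemble strategies.

#' Hidden width assigned to an input dimension
#'
#' The GRU layer width for a paired feature vector of dimension `d` is
#' `2^(floor(log2(d)) - 3)`: take the largest power of two not greater than
#' `d` and reduce the exponent by 3, so that the bidirectional output (twice
#' the width) still compresses the input at least fourfold.  For the paired
#' PseAAC vector (d = 56) this gives 4; for the six techniques at lags
#' (8, 7, 9) it gives 4, 64, 16, 64, 128 and 16.
#'
#' @param d Input (pair-vector) dimension, `d >= 16`.
#' @return Integer hidden width (per direction).
#' @export
#' @examples
#' dimension_rule(56)   # 4
#' dimension_rule(1260) # 128
dimension_rule <- function(d) {
  d <- as.integer(d)
  if (any(d < 16L)) {
    stop("dimension rule is undefined for d < 16 (exponent would drop below 1)",
         call. = FALSE)
  }
  as.integer(2L^(floor(log2(d)) - 3L))
}

#' Construct an (untrained) GRU reducer
#'
#' Builds a reducer that consumes a length-`input_dim` feature vector as a
#' univariate sequence, runs GRU(s) of width `hidden_dim` in the requested
#' direction(s), and exposes the concatenated final hidden states (width
#' `2 * hidden_dim` for bidirectional, `hidden_dim` otherwise).  A single
#' sigmoid unit is attached for supervised training ([train_reducer()]) and
#' discarded at extraction time ([extract_hidden()]).
#'
#' All parameters are initialized uniformly on
#' `[-1/sqrt(hidden_dim), 1/sqrt(hidden_dim)]` from `seed`; the same seed
#' always yields the same reducer.
#'
#' @param input_dim Length of the pair feature vector.
#' @param hidden_dim GRU width per direction; defaults to
#'   [dimension_rule()]`(input_dim)`.
#' @param direction `"bidirectional"` (default), `"forward"` or `"backward"`.
#' @param epochs Training epochs (default 5).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param clip_norm Global gradient-norm clip (default 1).
#' @param batch_size Minibatch size (default 64).
#' @param seed Integer seed for initialization and epoch shuffling.
#' @return An object of class `ppi_reducer`.
#' @export
gru_reducer <- function(input_dim, hidden_dim = dimension_rule(input_dim),
                        direction = c("bidirectional", "forward", "backward"),
                        epochs = 5L, learning_rate = 0.001, clip_norm = 1,
                        batch_size = 64L, seed = 1L) {
  direction <- match.arg(direction)
  input_dim <- as.integer(input_dim)
  hidden_dim <- as.integer(hidden_dim)
  epochs <- as.integer(epochs)
  stopifnot(input_dim >= 1L, hidden_dim >= 1L, clip_norm > 0, learning_rate > 0,
            batch_size >= 1L)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  h <- hidden_dim
  ndir <- if (direction == "bidirectional") 2L else 1L
  set.seed(as.integer(seed))
  bound <- 1 / sqrt(h)
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -bound, bound), nr, nc)
  dirs <- lapply(seq_len(ndir), function(j) {
    list(wx = as.numeric(rmat(3L * h, 1L)),
         bi = as.numeric(rmat(3L * h, 1L)),
         bh = as.numeric(rmat(3L * h, 1L)),
         Wh = rmat(h, 3L * h))
  })
  params <- list(dirs = dirs,
                 head_w = as.numeric(rmat(ndir * h, 1L)),
                 head_b = stats::runif(1L, -bound, bound),
                 h = h)
  structure(list(input_dim = input_dim, hidden_dim = h, direction = direction,
                 epochs = epochs, learning_rate = learning_rate,
                 clip_norm = clip_norm, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), params = params, trained = FALSE,
                 loss_history = NULL),
            class = "ppi_reducer")
}

#' Output width of a reducer's hidden-state vector
#' @param reducer A `ppi_reducer`.
#' @return Integer width (2h for bidirectional, h otherwise).
#' @export
reducer_output_dim <- function(reducer) {
  stopifnot(inherits(reducer, "ppi_reducer"))
  if (reducer$direction == "bidirectional") 2L * reducer$hidden_dim
  else reducer$hidden_dim
}

#' Train a GRU reducer
#'
#' Runs exactly `reducer$epochs` epochs of minibatch Adam (binary
#' cross-entropy on the sigmoid head, global-norm gradient clipping), with the
#' data reshuffled each epoch under the reducer's seed.
#'
#' @param reducer A `ppi_reducer`.
#' @param pairs Numeric matrix (`n` pairs x `input_dim`).
#' @param labels Binary vector of length `n`; both classes must be present.
#' @return The trained reducer, with `loss_history` (mean per-epoch loss).
#' @export
train_reducer <- function(reducer, pairs, labels) {
  stopifnot(inherits(reducer, "ppi_reducer"), is.matrix(pairs))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  if (length(labels) != nrow(pairs)) stop("label/row count mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training labels are single-class; the cross-entropy head cannot be supervised",
         call. = FALSE)
  }
  if (ncol(pairs) != reducer$input_dim) {
    stop(sprintf("input has %d columns but reducer expects %d",
                 ncol(pairs), reducer$input_dim), call. = FALSE)
  }
  if (any(!is.finite(pairs))) stop("non-finite feature values", call. = FALSE)
  n <- nrow(pairs)
  set.seed(reducer$seed + 1L)   # distinct stream from initialization
  perms <- vapply(seq_len(reducer$epochs), function(e) sample.int(n) - 1L,
                  integer(n))
  dim(perms) <- c(n, reducer$epochs)
  fit <- cpp_gru_train(reducer$params, pairs, labels, reducer$direction,
                       reducer$epochs, reducer$learning_rate,
                       reducer$clip_norm, reducer$batch_size, perms)
  reducer$params <- fit[c("dirs", "head_w", "head_b", "h")]
  reducer$loss_history <- as.numeric(fit$loss)
  reducer$trained <- TRUE
  reducer
}

#' Extract reduced features (final hidden states)
#'
#' Discards the training head and returns the final-timestep hidden states of
#' each direction, concatenated (forward state first).  An untrained reducer
#' still produces valid output -- a seeded random recurrent projection --
#' flagged in the result's metadata.
#'
#' @param reducer A `ppi_reducer`.
#' @param pairs Numeric matrix (`n` x `input_dim`).
#' @param labels Optional binary labels carried into the result.
#' @param technique Optional technique tag used for column names.
#' @return An object of class `ppi_reduced`: list with `hidden_states`
#'   (`n` x output width matrix), `labels`, `technique`, and `trained` flag.
#' @export
extract_hidden <- function(reducer, pairs, labels = NULL, technique = NA_character_) {
  stopifnot(inherits(reducer, "ppi_reducer"), is.matrix(pairs))
  if (ncol(pairs) != reducer$input_dim) {
    stop(sprintf("input has %d columns but reducer expects %d",
                 ncol(pairs), reducer$input_dim), call. = FALSE)
  }
  hs <- cpp_gru_hidden(reducer$params, pairs, reducer$direction)
  colnames(hs) <- paste0(if (is.na(technique)) "hid" else technique,
                         "_h", seq_len(ncol(hs)))
  structure(list(hidden_states = hs, labels = labels, technique = technique,
                 trained = reducer$trained),
            class = "ppi_reduced")
}

#' @export
print.ppi_reducer <- function(x, ...) {
  cat(sprintf("<GRU reducer: %d -> %d (%s, h = %d)%s>\n",
              x$input_dim, reducer_output_dim(x), x$direction, x$hidden_dim,
              if (x$trained) ", trained" else ""))
  invisible(x)
}

#' @export
print.ppi_reduced <- function(x, ...) {
  cat(sprintf("<reduced feature set: %d x %d%s%s>\n",
              nrow(x$hidden_states), ncol(x$hidden_states),
              if (!is.na(x$technique)) paste0(" (", x$technique, ")") else "",
              if (isTRUE(x$trained)) "" else ", untrained projection"))
  invisible(x)
}

check_blocks <- function(blocks) {
  stopifnot(is.list(blocks), setequal(names(blocks), TECHNIQUES))
  blocks <- blocks[TECHNIQUES]
  n <- unique(vapply(blocks, nrow, integer(1L)))
  if (length(n) != 1L) {
    stop("the six feature matrices must be row-aligned to the same pair list",
         call. = FALSE)
  }
  blocks
}

#' Ensemble reduction: one GRU per technique (MultiEns)
#'
#' Trains six independent reducers, each sized by the dimension rule on its
#' own pair-vector width, and concatenates their hidden states in the fixed
#' technique order PseAAC, AD, AC, CT, LD, MMI.  At the default lags the
#' merged width is 2 x (4 + 64 + 16 + 64 + 128 + 16) = 584.
#'
#' @param blocks Named list of the six pair-feature matrices (names
#'   `pseaac`, `ad`, `ac`, `ct`, `ld`, `mmi`), row-aligned.
#' @param labels Binary labels (length = pair count).
#' @param direction GRU direction (see [gru_reducer()]).
#' @param seed Base seed; reducer `i` uses `seed + i`.
#' @param epochs,learning_rate,clip_norm,batch_size Training
#'   hyperparameters, shared by all reducers.
#' @param train Train the reducers before extraction (default TRUE).
#' @return A merged `ppi_reduced`; element `reducers` holds the six trained
#'   reducers for later reuse on new data.
#' @export
reduce_multiens <- function(blocks, labels, direction = "bidirectional",
                            seed = 1L, epochs = 5L, learning_rate = 0.001,
                            clip_norm = 1, batch_size = 64L, train = TRUE) {
  blocks <- check_blocks(blocks)
  reducers <- vector("list", length(blocks))
  names(reducers) <- names(blocks)
  parts <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    d <- ncol(blocks[[i]])
    h <- dimension_rule(d)
    hd <- if (direction == "bidirectional") h else 2L * h  # width parity with BiGRU
    r <- gru_reducer(d, hidden_dim = hd, direction = direction,
                     epochs = epochs, learning_rate = learning_rate,
                     clip_norm = clip_norm, batch_size = batch_size,
                     seed = as.integer(seed) + i)
    reducers[[i]] <- if (train) train_reducer(r, blocks[[i]], labels) else r
    parts[[i]] <- extract_hidden(reducers[[i]], blocks[[i]])$hidden_states
    colnames(parts[[i]]) <- paste0(names(blocks)[i], "_h", seq_len(ncol(parts[[i]])))
  }
  structure(list(hidden_states = do.call(cbind, parts), labels = labels,
                 technique = "multiens", trained = isTRUE(train),
                 strategy = "multiens", reducers = reducers),
            class = "ppi_reduced")
}

#' Monolithic reduction: one GRU over the concatenated features (MultiCon)
#'
#' Concatenates all six pair-feature matrices column-wise and feeds the result
#' to a single GRU whose layer width is the fixed constant 292 (the sum of the
#' six rule-derived widths, so the merged output width, 584, matches the other
#' strategies rather than being rule-derived from the concatenated input).
#'
#' @inheritParams reduce_multiens
#' @param hidden_dim GRU width (default 292).
#' @return A merged `ppi_reduced` with element `reducers` (list of one).
#' @export
reduce_multicon <- function(blocks, labels, direction = "bidirectional",
                            seed = 1L, hidden_dim = 292L, epochs = 5L,
                            learning_rate = 0.001, clip_norm = 1,
                            batch_size = 64L, train = TRUE) {
  blocks <- check_blocks(blocks)
  x <- do.call(cbind, blocks)
  hd <- if (direction == "bidirectional") hidden_dim else 2L * hidden_dim
  r <- gru_reducer(ncol(x), hidden_dim = hd, direction = direction,
                   epochs = epochs, learning_rate = learning_rate,
                   clip_norm = clip_norm, batch_size = batch_size,
                   seed = as.integer(seed) + 1L)
  if (train) r <- train_reducer(r, x, labels)
  hs <- extract_hidden(r, x)$hidden_states
  colnames(hs) <- paste0("con_h", seq_len(ncol(hs)))
  structure(list(hidden_states = hs, labels = labels, technique = "multicon",
                 trained = isTRUE(train), strategy = "multicon",
                 reducers = list(all = r)),
            class = "ppi_reduced")
}

#' Two-group reduction (MultiSep)
#'
#' The three descriptor-profile blocks (PseAAC, AD, AC) are concatenated and
#' reduced by a GRU of width 84; the three class-alphabet blocks (CT, LD, MMI)
#' by a GRU of width 208 (84 + 208 = 292, preserving the 584 merged output
#' width).  Hidden states are merged profile group first.
#'
#' @inheritParams reduce_multiens
#' @return A merged `ppi_reduced` with element `reducers` (list of two).
#' @export
reduce_multisep <- function(blocks, labels, direction = "bidirectional",
                            seed = 1L, epochs = 5L, learning_rate = 0.001,
                            clip_norm = 1, batch_size = 64L, train = TRUE) {
  blocks <- check_blocks(blocks)
  groups <- list(
    svhehs = list(x = do.call(cbind, blocks[c("pseaac", "ad", "ac")]), h = 84L),
    classes = list(x = do.call(cbind, blocks[c("ct", "ld", "mmi")]), h = 208L))
  reducers <- list()
  parts <- list()
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    hd <- if (direction == "bidirectional") g$h else 2L * g$h
    r <- gru_reducer(ncol(g$x), hidden_dim = hd, direction = direction,
                     epochs = epochs, learning_rate = learning_rate,
                     clip_norm = clip_norm, batch_size = batch_size,
                     seed = as.integer(seed) + i)
    if (train) r <- train_reducer(r, g$x, labels)
    hs <- extract_hidden(r, g$x)$hidden_states
    colnames(hs) <- paste0(names(groups)[i], "_h", seq_len(ncol(hs)))
    reducers[[names(groups)[i]]] <- r
    parts[[i]] <- hs
  }
  structure(list(hidden_states = do.call(cbind, parts), labels = labels,
                 technique = "multisep", trained = isTRUE(train),
                 strategy = "multisep", reducers = reducers),
            class = "ppi_reduced")
}
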