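# Readers and writers: FASTA sequences, pair lists, feature matrices, and
# model archives.  All text outputs are tab-separated with '.' decimals and
# carry a '#config-hash=' header line so artifacts are traceable to the
# configuration that produced them.

config_hash <- function(config) rlang::hash(config)

#' Read protein sequences from FASTA
#'
#' Parses with Biostrings, then applies package-level validation: unique ids,
#' non-empty upper-cased sequences, and the residue policy for non-canonical
#' letters (B, J, O, U, X, Z and anything else outside the 20-letter
#' alphabet): `"strict"` rejects the file naming the record, `"drop"` removes
#' the offending letters with a warning.
#'
#' @param path FASTA file path.
#' @param residue_policy `"strict"` (default) or `"drop"`.
#' @return Named character vector of sequences (ids as names, file order
#'   preserved).
#' @export
read_fasta <- function(path, residue_policy = c("strict", "drop")) {
  residue_policy <- match.arg(residue_policy)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  canon <- paste(aa_alphabet(), collapse = "")
  bad <- grepl(sprintf("[^%s]", canon), seqs)
  if (any(bad)) {
    if (residue_policy == "strict") {
      stop("non-canonical residue(s) in record(s): ",
           paste(ids[bad], collapse = ", "),
           " (use residue_policy = \"drop\" to remove them)", call. = FALSE)
    }
    warning(sprintf("dropping non-canonical residues from %d record(s): %s",
                    sum(bad), paste(ids[bad], collapse = ", ")), call. = FALSE)
    seqs[bad] <- gsub(sprintf("[^%s]", canon), "", seqs[bad])
    if (any(nchar(seqs) == 0L)) {
      stop("record(s) empty after dropping non-canonical residues: ",
           paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a labeled pair list
#'
#' Tab-delimited `id_a<TAB>id_b<TAB>label` with labels in \{0, 1\}.  Every id
#' must resolve against `known_ids` when given.  Duplicated pairs are allowed
#' (and reported via a message); order is preserved.
#'
#' @param path Pair-list path (lines starting with `#` ignored; an optional
#'   header line `id_a id_b label` is skipped).
#' @param known_ids Optional character vector of valid sequence ids.
#' @return Data frame with columns `id_a`, `id_b`, `label`.
#' @export
read_pairs <- function(path, known_ids = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(parts) && identical(tolower(parts[[1]][1]), "id_a")) {
    parts <- parts[-1L]; lineno <- lineno[-1L]
  }
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    stop(sprintf("line %d: expected 3 tab-separated fields, found %d",
                 lineno[which(nf != 3L)[1L]], nf[nf != 3L][1L]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  lab <- suppressWarnings(as.integer(m[, 3L]))
  bad <- is.na(lab) | !(lab %in% c(0L, 1L)) | m[, 3L] != as.character(lab)
  if (any(bad)) {
    stop(sprintf("line %d: label '%s' is not 0 or 1",
                 lineno[which(bad)[1L]], m[bad, 3L][1L]), call. = FALSE)
  }
  if (!is.null(known_ids)) {
    unk <- !(m[, 1L] %in% known_ids) | !(m[, 2L] %in% known_ids)
    if (any(unk)) {
      i <- which(unk)[1L]
      id <- setdiff(c(m[i, 1L], m[i, 2L]), known_ids)[1L]
      stop(sprintf("line %d: unknown sequence id '%s'", lineno[i], id),
           call. = FALSE)
    }
  }
  df <- data.frame(id_a = m[, 1L], id_b = m[, 2L], label = lab,
                   stringsAsFactors = FALSE)
  ndup <- sum(duplicated(df))
  if (ndup > 0L) message(ndup, " duplicated pair(s) kept")
  df
}

#' Write a pair list
#' @param pairs Data frame with `id_a`, `id_b`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("id_a", "id_b", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a feature (or hidden-state) matrix
#'
#' Tab-separated text: a `#config-hash=` line, a header naming every column,
#' then one row per pair in pair-list order.  Values are written with full
#' precision (17 significant digits) so a write/read round trip is
#' bit-identical.
#'
#' @param m Numeric matrix with column names.
#' @param path Output path.
#' @param config List describing how `m` was produced (hashed into the header).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#config-hash=", config_hash(config)), con)
  writeLines(paste(colnames(m), collapse = "\t"), con)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path Input path.
#' @return Numeric matrix; the config hash is attached as attribute
#'   `config_hash`.
#' @export
read_feature_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  hash <- if (startsWith(first, "#config-hash=")) sub("^#config-hash=", "", first) else NA_character_
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df)
  attr(m, "config_hash") <- hash
  m
}

#' Save / load a fitted model archive
#'
#' A versioned RDS archive holding the fitted reducers, the serialized
#' classifier, the configuration, and the logged backend parameter set.
#'
#' @param model A `ppigru_model`.
#' @param path Archive path.
#' @return `path` invisibly ([save_model()]); the restored model
#'   ([load_model()]).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ppigru_model"))
  archive <- list(format = "ppigru_model_archive", version = 1L, model = model)
  if (model$classifier$backend_name == "xgboost") {
    archive$model$classifier$fitted$raw <-
      xgboost::xgb.save.raw(model$classifier$fitted$model)
  }
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  archive <- readRDS(path)
  if (!identical(archive$format, "ppigru_model_archive")) {
    stop("not a model archive", call. = FALSE)
  }
  model <- archive$model
  if (!is.null(model$classifier$fitted$raw)) {
    model$classifier$fitted$model <- xgboost::xgb.load.raw(model$classifier$fitted$raw)
    model$classifier$fitted$raw <- NULL
  }
  model
}
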