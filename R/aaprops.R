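# Amino-acid property table (20 x 13) and the 7-class physicochemical alphabet.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in alphabetical order. This
#' ordering is the fixed convention for every composition-style feature vector
#' produced by the package.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

N_PROPERTIES <- 13L
N_CLASSES <- 7L

#' Load an amino-acid property table
#'
#' Reads a tab-delimited table of physicochemical property components, one row
#' per canonical residue and 13 numeric columns.  The packaged default (see
#' [default_property_table()]) carries 13 AAindex scales spanning hydrophobic,
#' electronic, hydrogen-bond and steric character; any other 20 x 13 table in
#' the same format is accepted, so alternative descriptor sets (for example
#' raw-information variants) can be swapped in.
#'
#' Rows are reordered alphabetically by residue code regardless of file order.
#' The returned table is unstandardized; encoders require a standardized table
#' (see [standardize_table()]).
#'
#' @param path Path to a tab-delimited file with header
#'   `residue<TAB><13 component names>` and 20 data rows.  Lines starting with
#'   `#` are ignored.
#' @return An object of class `ppi_proptab`: a list with elements `residues`
#'   (character, length 20), `values` (20 x 13 numeric matrix) and
#'   `standardized` (logical flag).
#' @export
load_property_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) != N_PROPERTIES + 1L) {
    stop(sprintf("property table must have 1 residue column + %d components, found %d columns",
                 N_PROPERTIES, ncol(df)), call. = FALSE)
  }
  res <- toupper(as.character(df[[1L]]))
  if (anyDuplicated(res)) {
    stop("duplicate residue row(s): ",
         paste(unique(res[duplicated(res)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(aa_alphabet(), res)
  extra <- setdiff(res, aa_alphabet())
  if (length(missing) || length(extra)) {
    stop("property table residues must be exactly the 20 canonical codes",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(df[, -1L, drop = FALSE], as.numeric, numeric(nrow(df))))
  dim(vals) <- c(nrow(df), N_PROPERTIES)
  colnames(vals) <- names(df)[-1L]
  bad <- res[apply(vals, 1L, function(r) anyNA(r) || any(!is.finite(r)))]
  if (length(bad)) {
    stop("non-numeric or non-finite cell(s) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ord <- order(res)
  structure(
    list(residues = res[ord],
         values = `rownames<-`(vals[ord, , drop = FALSE], res[ord]),
         standardized = FALSE),
    class = "ppi_proptab")
}

#' Standardize a property table
#'
#' Z-scores each of the 13 property columns over the 20 residues (mean 0,
#' standard deviation 1, divisor n - 1).  Encoders consume standardized tables
#' only, so that descriptors are comparable across properties measured on
#' arbitrary scales; the result is invariant to any positive affine rescaling
#' of the raw columns.
#'
#' @param table A `ppi_proptab` with `standardized = FALSE`.
#' @return The standardized `ppi_proptab`.
#' @export
standardize_table <- function(table) {
  stopifnot(inherits(table, "ppi_proptab"))
  if (isTRUE(table$standardized)) {
    stop("table is already standardized", call. = FALSE)
  }
  sds <- apply(table$values, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance property column(s): ",
         paste(colnames(table$values)[sds == 0], collapse = ", "),
         " carry no information", call. = FALSE)
  }
  table$values <- scale(table$values)[, , drop = FALSE]
  attr(table$values, "scaled:center") <- NULL
  attr(table$values, "scaled:scale") <- NULL
  table$standardized <- TRUE
  table
}

#' Packaged default property table
#'
#' Loads the property table shipped with the package
#' (`extdata/property_table_synthetic.tsv`).  This file is a synthetic
#' stand-in for a published 20 x 13 PCA-derived descriptor matrix: its 13
#' columns are real AAindex scales chosen to cover the same four property
#' groups (hydrophobic, electronic, hydrogen-bond, steric); the AAindex
#' accession ids are recorded in the file header.
#'
#' @param standardized Return the z-scored table (default `TRUE`).
#' @return A `ppi_proptab`.
#' @export
default_property_table <- function(standardized = TRUE) {
  tab <- load_property_table(
    system.file("extdata", "property_table_synthetic.tsv", package = "ppigru",
                mustWork = TRUE))
  if (standardized) standardize_table(tab) else tab
}

#' Load a 7-class amino-acid class map
#'
#' Reads a tab-delimited `residue<TAB>class` file assigning each of the 20
#' canonical residues to one of seven classes.  The packaged default groups
#' residues by dipole and side-chain volume (the conjoint-triad classes of
#' Shen et al. 2007): \{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\}, \{H,N,Q,W\},
#' \{R,K\}, \{D,E\}, \{C\}.
#'
#' @param path Path to the class-map file; lines starting with `#` are ignored.
#' @return An object of class `ppi_classmap`: an integer vector of class ids
#'   (values in 1..7) named by residue, in alphabetical residue order.
#' @export
load_class_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2L) stop("class map must have exactly 2 columns", call. = FALSE)
  res <- toupper(as.character(df[[1L]]))
  cls <- suppressWarnings(as.integer(df[[2L]]))
  if (anyNA(cls) || any(cls < 1L) || any(cls > N_CLASSES)) {
    stop("class ids must be integers in 1..7", call. = FALSE)
  }
  if (anyDuplicated(res) || !setequal(res, aa_alphabet())) {
    stop("class map must assign each of the 20 canonical residues exactly once",
         call. = FALSE)
  }
  if (length(unique(cls)) != N_CLASSES) {
    stop("class map must use all 7 classes", call. = FALSE)
  }
  ord <- order(res)
  structure(stats::setNames(cls[ord], res[ord]), class = "ppi_classmap")
}

#' Packaged default class map
#'
#' @return The packaged dipole/side-chain-volume `ppi_classmap`
#'   (see [load_class_map()]).
#' @export
default_class_map <- function() {
  load_class_map(system.file("extdata", "class_map.tsv", package = "ppigru",
                             mustWork = TRUE))
}

#' Class id of a residue
#'
#' @param residue Character vector of one-letter residue codes.
#' @param cmap A `ppi_classmap` (default: packaged map).
#' @return Integer vector of class ids in 1..7.
#' @export
#' @examples
#' class_of("C")  # cysteine is the singleton class
class_of <- function(residue, cmap = default_class_map()) {
  stopifnot(inherits(cmap, "ppi_classmap"))
  id <- unname(unclass(cmap)[toupper(residue)])
  if (anyNA(id)) {
    bad <- which(is.na(id))
    stop(sprintf("unknown residue '%s' at position %d", residue[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  id
}

# Integer class sequence for a protein string; errors name the offending
# position so sequence-level validation messages stay informative.
class_sequence <- function(seq, cmap) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  class_of(chars, cmap)
}

#' @export
print.ppi_proptab <- function(x, ...) {
  cat(sprintf("Amino-acid property table: 20 residues x %d components (%s)\n",
              ncol(x$values), if (x$standardized) "standardized" else "raw"))
  invisible(x)
}

#' @export
print.ppi_classmap <- function(x, ...) {
  cat("7-class amino-acid alphabet:\n")
  for (k in seq_len(N_CLASSES)) {
    cat(sprintf("  class %d: %s\n", k,
                paste(names(x)[unclass(x) == k], collapse = " ")))
  }
  invisible(x)
}
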