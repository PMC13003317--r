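#' Construct a binary subject-by-column matrix
#'
#' The two inputs of a combined-phenotype search are a subjects x SNPs
#' genotype matrix (presence/absence coding) and a subjects x phenotypes
#' case/control matrix.  Both are plain 0/1 integer matrices carrying
#' unique subject ids as row names and unique SNP/phenotype ids as column
#' names; `binary_matrix()` validates and tags them.
#'
#' @param values a numeric or integer matrix containing only 0 and 1.
#' @param row_ids,col_ids character identifiers; default to the dimnames
#'   of `values`.
#' @param kind `"genotype"` or `"phenotype"`; informational only.
#' @return an integer matrix of class `bin_matrix` with `kind` attribute.
#' @export
binary_matrix <- function(values, row_ids = rownames(values),
                          col_ids = colnames(values),
                          kind = c("genotype", "phenotype")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "non-binary entry %s at row %s, column %s",
      format(values[bad[1]]),
      if (is.null(row_ids)) rc[1] else row_ids[rc[1]],
      if (is.null(col_ids)) rc[2] else col_ids[rc[2]]
    ), call. = FALSE)
  }
  if (is.null(row_ids)) row_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(col_ids)) col_ids <- paste0("C", seq_len(ncol(values)))
  if (anyDuplicated(row_ids)) stop("duplicate row ids", call. = FALSE)
  if (anyDuplicated(col_ids)) stop("duplicate column ids", call. = FALSE)
  storage.mode(values) <- "integer"
  dimnames(values) <- list(as.character(row_ids), as.character(col_ids))
  structure(values, class = c("bin_matrix", class(values)), kind = kind)
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("<bin_matrix [%s]> %d subjects x %d columns\n",
              attr(x, "kind") %||% "?", nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 10L)), drop = FALSE], 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a binary matrix from a tab-separated file
#'
#' Expects a header row of column ids and a first column of subject ids;
#' every body entry must be 0 or 1.  Row order in the file is preserved.
#'
#' @param path path to a TSV file.
#' @inheritParams binary_matrix
#' @return a [binary_matrix()].
#' @export
read_binary_matrix <- function(path, kind = c("genotype", "phenotype")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (ncol(df) < 2) stop("expected a subject-id column plus data columns", call. = FALSE)
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(is.na(vals) | !(vals %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(vals))
    stop(sprintf("non-binary entry at row '%s', column '%s' of %s",
                 ids[rc[1]], colnames(vals)[rc[2]], path), call. = FALSE)
  }
  binary_matrix(vals, row_ids = ids, col_ids = colnames(vals), kind = kind)
}

#' Write a binary matrix as TSV
#'
#' Emits the dialect read by [read_binary_matrix()]: header row of column
#' ids, first column of subject ids.
#'
#' @param x a [binary_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binary_matrix <- function(x, path) {
  df <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
  df <- tibble::add_column(df, subject_id = rownames(x), .before = 1)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# shared-subject check used by operations taking X and Y together
check_same_subjects <- function(X, Y) {
  if (nrow(X) != nrow(Y) || !identical(rownames(X), rownames(Y)))
    stop("genotype and phenotype matrices must have identical subject ids in identical order",
         call. = FALSE)
  invisible(TRUE)
}
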