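#' Construct a CNF combined phenotype
#'
#' A combined phenotype is an AND of OR-clauses over phenotype columns:
#' a subject has the combined phenotype iff, in every clause, it has at
#' least one of the clause's phenotypes.  A `(K, L)` search space
#' contains all CNFs with at most K clauses of at most L phenotypes
#' each (repeating a clause emulates using fewer clauses).
#'
#' @param clauses list of integer vectors (or a single vector, taken as
#'   one clause); each clause must be non-empty.
#' @param P optional number of phenotype columns, to validate indices.
#' @return an object of class `cnf_phenotype`.
#' @export
cnf_phenotype <- function(clauses, P = NULL) {
  if (!is.list(clauses)) clauses <- list(clauses)
  if (!length(clauses)) stop("a CNF needs at least one clause", call. = FALSE)
  clauses <- lapply(clauses, function(cl) {
    cl <- as.integer(cl)
    if (!length(cl)) stop("empty clause: OR over nothing is undefined", call. = FALSE)
    if (any(cl < 1)) stop("phenotype indices must be positive", call. = FALSE)
    if (!is.null(P) && any(cl > P))
      stop("clause refers to a phenotype column beyond P = ", P, call. = FALSE)
    sort(unique(cl))
  })
  structure(list(clauses = clauses), class = "cnf_phenotype")
}

#' @export
print.cnf_phenotype <- function(x, ...) {
  cat("<cnf_phenotype>", format_cnf(x), "\n")
  invisible(x)
}

#' Evaluate a CNF combined phenotype on a phenotype matrix
#'
#' @param cnf a [cnf_phenotype()].
#' @param Y a subjects x phenotypes 0/1 matrix (or [binary_matrix()]).
#' @return integer 0/1 vector: 1 for subjects carrying the combined
#'   phenotype (every clause satisfied).
#' @export
evaluate_cnf <- function(cnf, Y) {
  Y <- unclass(Y)
  P <- ncol(Y)
  out <- rep(1L, nrow(Y))
  for (cl in cnf$clauses) {
    if (any(cl > P)) stop("clause index exceeds phenotype count", call. = FALSE)
    sat <- rowSums(Y[, cl, drop = FALSE]) > 0
    out <- out & sat
  }
  as.integer(out)
}

#' Reduce a CNF to distinct set-minimal clauses
#'
#' Removes duplicated phenotype indices within clauses, drops duplicate
#' clauses, and drops any clause that is a superset of another clause
#' (a superset clause is implied by its subset).  The result evaluates
#' identically on every possible subject profile.
#'
#' @param cnf a [cnf_phenotype()].
#' @return a simplified [cnf_phenotype()].
#' @export
postprocess_cnf <- function(cnf) {
  cls <- lapply(cnf$clauses, function(cl) sort(unique(cl)))
  cls <- unique(cls)
  keep <- rep(TRUE, length(cls))
  for (i in seq_along(cls)) {
    for (j in seq_along(cls)) {
      if (i != j && keep[j] && all(cls[[j]] %in% cls[[i]]) &&
          length(cls[[j]]) < length(cls[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  canonicalize_cnf(cnf_phenotype(cls[keep]))
}

# stable order: clauses sorted lexicographically by their sorted indices
canonicalize_cnf <- function(cnf) {
  keys <- vapply(cnf$clauses, function(cl)
    paste(formatC(cl, width = 6, flag = "0"), collapse = ","), "")
  cnf$clauses <- cnf$clauses[order(keys)]
  cnf
}

#' Render a CNF in clause syntax
#'
#' Produces strings like `"(A|B)&(C|D)"` using the supplied phenotype
#' names (or raw indices).
#'
#' @param cnf a [cnf_phenotype()].
#' @param pheno_names optional character vector of phenotype names.
#' @return a single string.
#' @export
format_cnf <- function(cnf, pheno_names = NULL) {
  lab <- function(j) if (is.null(pheno_names)) as.character(j) else pheno_names[j]
  paste(vapply(cnf$clauses, function(cl)
    paste0("(", paste(lab(cl), collapse = "|"), ")"), ""), collapse = "&")
}

#' Parse clause syntax back into a CNF
#'
#' Inverse of [format_cnf()].
#'
#' @param s string such as `"(A|B)&(C)"`.
#' @param pheno_names phenotype names used to resolve labels; if `NULL`
#'   labels are taken as integer indices.
#' @return a [cnf_phenotype()].
#' @export
parse_cnf <- function(s, pheno_names = NULL) {
  parts <- strsplit(gsub("[()]", "", strsplit(s, "&", fixed = TRUE)[[1]]),
                    "|", fixed = TRUE)
  clauses <- lapply(parts, function(p) {
    if (is.null(pheno_names)) as.integer(p) else match(p, pheno_names)
  })
  if (any(vapply(clauses, anyNA, TRUE)))
    stop("unresolved phenotype label in: ", s, call. = FALSE)
  cnf_phenotype(clauses)
}
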