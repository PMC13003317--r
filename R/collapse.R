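#' Collapse subjects with identical phenotype profiles
#'
#' A lossless preprocessor: subjects sharing the same row of the
#' phenotype matrix are merged into one weighted pseudo-subject.  Every
#' association statistic used downstream depends only on the counts
#' `(nu, nv, nuv, M)`, all of which are recoverable from the collapsed
#' representation, so the reduction changes no result.  It pays off
#' whenever the number of phenotypes P is small relative to log2(M),
#' since at most `2^P` distinct profiles exist.
#'
#' The profile rows are returned in lexicographic order (first phenotype
#' column most significant), making the output deterministic.
#'
#' @param X genotype [binary_matrix()] (subjects x SNPs).
#' @param Y phenotype [binary_matrix()] (subjects x phenotypes), same
#'   subjects in the same order as `X`.
#' @return an object of class `collapsed_data`: a list with
#'   * `profiles`: U x P 0/1 matrix of distinct phenotype rows,
#'   * `carrier_counts`: U x N integer matrix, subjects per profile
#'     carrying each SNP,
#'   * `multiplicity`: length-U integer vector of profile sizes,
#'   * `subject_ids`: list of the subject ids behind each profile.
#' @export
collapse_subjects <- function(X, Y) {
  check_same_subjects(X, Y)
  Ym <- unclass(Y)
  ord <- do.call(order, as.data.frame(Ym))
  Ys <- Ym[ord, , drop = FALSE]
  # run-length encode adjacent identical rows
  if (nrow(Ys) > 1) {
    new_run <- c(TRUE, rowSums(abs(Ys[-1, , drop = FALSE] -
                                   Ys[-nrow(Ys), , drop = FALSE])) > 0)
  } else new_run <- TRUE
  grp <- cumsum(new_run)
  U <- grp[length(grp)]
  profiles <- Ys[new_run, , drop = FALSE]
  rownames(profiles) <- paste0("profile", seq_len(U))
  multiplicity <- as.integer(tabulate(grp, nbins = U))
  Xs <- unclass(X)[ord, , drop = FALSE]
  carrier_counts <- rowsum(Xs, grp, reorder = TRUE)
  storage.mode(carrier_counts) <- "integer"
  rownames(carrier_counts) <- rownames(profiles)
  structure(list(
    profiles = profiles,
    carrier_counts = carrier_counts,
    multiplicity = multiplicity,
    subject_ids = split(rownames(X)[ord], grp)
  ), class = "collapsed_data")
}

#' @export
print.collapsed_data <- function(x, ...) {
  cat(sprintf("<collapsed_data> %d profiles over %d phenotypes (%d subjects, %d SNP columns)\n",
              nrow(x$profiles), ncol(x$profiles), sum(x$multiplicity),
              ncol(x$carrier_counts)))
  invisible(x)
}

# number of subjects behind a collapsed_data
n_subjects <- function(collapsed) sum(collapsed$multiplicity)

# Wrap uncollapsed matrices in the collapsed interface (each subject its
# own profile, multiplicity 1); used to build formulations without the
# Algorithm-1 reduction for count checks and equivalence tests.
as_collapsed <- function(X, Y) {
  check_same_subjects(X, Y)
  structure(list(
    profiles = unclass(Y),
    carrier_counts = unclass(X),
    multiplicity = rep(1L, nrow(Y)),
    subject_ids = as.list(rownames(Y))
  ), class = "collapsed_data")
}

#' Contingency counts of a combined phenotype against one variant
#'
#' Evaluates a CNF on the collapsed profiles and accumulates the counts
#' sufficient for every supported association statistic.
#'
#' @param cnf a [cnf_phenotype()].
#' @param collapsed a [collapse_subjects()] result.
#' @param snp column name or index of the variant in `carrier_counts`.
#' @param negate if `TRUE`, use the complement of the variant.
#' @return a [contingency_summary()].
#' @export
cnf_contingency <- function(cnf, collapsed, snp, negate = FALSE) {
  ind <- evaluate_cnf(cnf, collapsed$profiles)
  xc <- collapsed$carrier_counts[, snp]
  m <- collapsed$multiplicity
  if (negate) xc <- m - xc
  contingency_summary(
    nu = sum(m[ind == 1L]),
    nv = sum(xc),
    nuv = sum(xc[ind == 1L]),
    M = sum(m)
  )
}
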