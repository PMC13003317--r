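#' Number of CNF combined phenotypes of a given shape
#'
#' With distinct phenotypes per clause and distinct clauses, there are
#' `choose(choose(P, L), K)` CNFs with exactly K clauses of exactly L
#' phenotypes.
#'
#' @param P phenotype count.
#' @param K,L clause count and clause size.
#' @return a number.
#' @export
count_cnf <- function(P, K, L) choose(choose(P, L), K)

# is value `a` a strictly stronger association than `b` for this stat?
stat_better <- function(name, a, b) {
  if (is.na(a)) return(FALSE)
  if (is.na(b)) return(TRUE)
  if (stat_spec(name)$higher_is_stronger) a > b else a < b
}

#' Exhaustive search over CNF combined phenotypes
#'
#' Scores every CNF with at most K distinct clauses of between 1 and L
#' phenotypes (or exactly K clauses of exactly L phenotypes when
#' `exact_size = TRUE`) and returns the global optimum of the statistic.
#' Serves as the independent verification oracle for the MILP route on
#' small instances; a combinatorial guard refuses explosive inputs.
#'
#' @param x_col binary variant vector over subjects.
#' @param Y phenotype matrix ([binary_matrix()] or plain 0/1 matrix).
#' @param K,L shape bounds.
#' @param stat statistic name, see [stat_spec()].
#' @param exact_size enumerate exactly-(K, L) shapes only.
#' @param guard refuse when more than this many CNFs would be scored.
#' @return list with `cnf` (canonical, tie-broken lexicographically),
#'   `value`, `n_enumerated`.
#' @export
enumerate_cnf_oracle <- function(x_col, Y, K, L, stat = "fisher_p",
                                 exact_size = FALSE, guard = 1e6) {
  Y <- unclass(Y)
  M <- nrow(Y); P <- ncol(Y)
  stopifnot(length(x_col) == M)
  sizes <- if (exact_size) L else seq_len(min(L, P))
  clauses <- unlist(lapply(sizes, function(s)
    utils::combn(P, s, simplify = FALSE)), recursive = FALSE)
  nC <- length(clauses)
  kk <- if (exact_size) K else seq_len(K)
  total <- sum(vapply(kk, function(k) choose(nC, k), 0))
  if (total > guard)
    stop(sprintf("combinatorial guard exceeded: %g CNFs > %g", total, guard),
         call. = FALSE)
  # per-clause satisfaction over subjects
  sat <- vapply(clauses, function(cl)
    as.integer(rowSums(Y[, cl, drop = FALSE]) > 0), integer(M))
  nv <- sum(x_col)
  best <- NULL; best_val <- NA_real_; best_key <- NULL; n_enum <- 0
  score_combo <- function(ix) {
    ind <- sat[, ix[1]]
    for (q in ix[-1]) ind <- ind * sat[, q]
    t <- contingency_summary(nu = sum(ind), nv = nv,
                             nuv = sum(ind * x_col), M = M)
    compute_stat(stat, t)
  }
  for (k in kk) {
    combos <- utils::combn(nC, k, simplify = FALSE)
    for (ix in combos) {
      n_enum <- n_enum + 1
      val <- score_combo(ix)
      take <- FALSE
      if (stat_better(stat, val, best_val)) {
        take <- TRUE
      } else if (!is.na(val) && !is.na(best_val) && val == best_val) {
        key <- format_cnf(canonicalize_cnf(cnf_phenotype(clauses[ix])))
        take <- key < best_key
      }
      if (take) {
        best <- clauses[ix]; best_val <- val
        best_key <- format_cnf(canonicalize_cnf(cnf_phenotype(best)))
      }
    }
  }
  list(cnf = canonicalize_cnf(cnf_phenotype(best)), value = best_val,
       n_enumerated = n_enum)
}
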