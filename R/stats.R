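#' Contingency summary of two binary vectors
#'
#' Every association statistic supported here depends on a pair of
#' binary vectors only through `(nu, nv, nuv, M)`: the number of
#' subjects with the combined phenotype, with the variant, with both,
#' and in total.  These determine the 2x2 table `a = nuv`,
#' `b = nu - nuv`, `c = nv - nuv`, `d = M - nu - nv + nuv`.
#'
#' @param nu,nv,nuv,M non-negative integer counts.
#' @return a list of class `contingency_summary` with fields
#'   `nu, nv, nuv, M, a, b, c, d`.
#' @export
contingency_summary <- function(nu, nv, nuv, M) {
  stopifnot(length(nu) == 1, length(nv) == 1, length(nuv) == 1, length(M) == 1)
  a <- nuv; b <- nu - nuv; c <- nv - nuv; d <- M - nu - nv + nuv
  if (nuv > min(nu, nv) || min(a, b, c, d) < 0)
    stop(sprintf("invalid contingency counts: nu=%d nv=%d nuv=%d M=%d",
                 nu, nv, nuv, M), call. = FALSE)
  structure(list(nu = nu, nv = nv, nuv = nuv, M = M,
                 a = a, b = b, c = c, d = d),
            class = "contingency_summary")
}

#' Summarise a phenotype/variant pair of binary vectors
#'
#' @param u,v equal-length binary vectors (combined phenotype, variant).
#' @return a [contingency_summary()].
#' @export
summarize_pair <- function(u, v) {
  stopifnot(length(u) == length(v))
  contingency_summary(nu = sum(u), nv = sum(v), nuv = sum(u * v),
                      M = length(u))
}

#' Properties of the supported association statistics
#'
#' Returns the statistic's direction (whether larger values mean a
#' stronger association) and its monotonicity in `nuv` for fixed
#' margins, which governs whether a significance threshold on it can be
#' turned into a piecewise-linear boundary constraint.  All statistics
#' except the chi-square coefficient are monotone in `nuv`; the
#' agreement, Hamming distance and covariance are additionally linear in
#' `(nu, nuv)` and can serve directly as MILP objectives.
#'
#' @param name one of `"agreement"`, `"hamming"`, `"covariance"`,
#'   `"correlation"`, `"chi2"`, `"odds_ratio"`, `"kappa"`, `"fisher_p"`.
#' @return a list with `name`, `higher_is_stronger`, `monotone_in_nuv`
#'   (`"increasing"`, `"decreasing"` or `"non-monotone"`) and `linear`.
#' @export
stat_spec <- function(name = c("agreement", "hamming", "covariance",
                               "correlation", "chi2", "odds_ratio",
                               "kappa", "fisher_p")) {
  name <- match.arg(name)
  specs <- list(
    agreement   = list(higher_is_stronger = TRUE,  monotone_in_nuv = "increasing", linear = TRUE),
    hamming     = list(higher_is_stronger = FALSE, monotone_in_nuv = "decreasing", linear = TRUE),
    covariance  = list(higher_is_stronger = TRUE,  monotone_in_nuv = "increasing", linear = TRUE),
    correlation = list(higher_is_stronger = TRUE,  monotone_in_nuv = "increasing", linear = FALSE),
    chi2        = list(higher_is_stronger = TRUE,  monotone_in_nuv = "non-monotone", linear = FALSE),
    odds_ratio  = list(higher_is_stronger = TRUE,  monotone_in_nuv = "increasing", linear = FALSE),
    kappa       = list(higher_is_stronger = TRUE,  monotone_in_nuv = "increasing", linear = FALSE),
    fisher_p    = list(higher_is_stronger = FALSE, monotone_in_nuv = "decreasing", linear = FALSE)
  )
  c(list(name = name), specs[[name]])
}

#' Compute an association statistic from contingency counts
#'
#' @param name statistic name, see [stat_spec()].
#' @param t a [contingency_summary()].
#' @param direction for `"fisher_p"`, `"over"` tests over-representation
#'   (upper hypergeometric tail, the default) and `"under"` the lower
#'   tail.
#' @return a single number.  Degenerate margins (`nu` or `nv` in
#'   `{0, M}`) make correlation, chi2 and kappa undefined: `NA` is
#'   returned.  An odds ratio with `b*c = 0` and `a*d > 0` is `Inf`.
#' @export
compute_stat <- function(name, t, direction = c("over", "under")) {
  direction <- match.arg(direction)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  M <- t$M; nu <- t$nu; nv <- t$nv; nuv <- t$nuv
  degenerate <- nu %in% c(0, M) || nv %in% c(0, M)
  switch(name,
    agreement = a + d,
    hamming = b + c,
    covariance = a / M - (nu * nv) / M^2,
    correlation = {
      if (degenerate) return(NA_real_)
      (a / M - nu * nv / M^2) /
        sqrt((nu / M) * (1 - nu / M) * (nv / M) * (1 - nv / M))
    },
    chi2 = {
      if (degenerate) return(NA_real_)
      M * (a * d - b * c)^2 / (nu * nv * (M - nu) * (M - nv))
    },
    odds_ratio = {
      if (b * c == 0) {
        if (a * d > 0) return(Inf)
        return(NA_real_)   # 0/0: no information
      }
      (a * d) / (b * c)
    },
    kappa = {
      if (degenerate) return(NA_real_)
      2 * (a * d - b * c) / (nu * (M - nv) + nv * (M - nu))
    },
    fisher_p = fisher_tail_p(nuv, nu, nv, M, direction),
    stop("unknown statistic: ", name, call. = FALSE)
  )
}

# One-sided Fisher exact p-value.  "over": P(X >= nuv) with
# X ~ Hypergeometric(M, nv, nu) -- the upper tail, computed through the
# log-scale hypergeometric CDF for numerical stability in small tails.
fisher_tail_p <- function(nuv, nu, nv, M, direction = "over") {
  if (direction == "over") {
    p <- stats::phyper(nuv - 1, nv, M - nv, nu, lower.tail = FALSE)
  } else {
    p <- stats::phyper(nuv, nv, M - nv, nu, lower.tail = TRUE)
  }
  pmin(pmax(p, 0), 1)
}

#' Check monotonicity of the one-sided Fisher p-value in nuv
#'
#' Scans the attainable range of `nuv` for fixed margins and reports
#' whether the upper-tail p-value is non-increasing throughout, the
#' property that justifies encoding a significance threshold as a lower
#' bound on the co-occurrence count.
#'
#' @param nu,nv,M margins, `0 <= nu, nv <= M`.
#' @return `TRUE` or `FALSE`.
#' @export
fisher_p_monotone_check <- function(nu, nv, M) {
  lo <- max(0, nu + nv - M); hi <- min(nu, nv)
  if (lo >= hi) return(TRUE)    # single-point domain, vacuously monotone
  p <- fisher_tail_p(lo:hi, nu, nv, M)
  all(diff(p) <= 1e-12)
}

#' Cochran-Mantel-Haenszel test of variant vs combined phenotype
#'
#' Tests the association of a variant with a combined phenotype while
#' stratifying on the best single phenotype, so that a small p-value
#' indicates a signal not explained by that single phenotype acting as a
#' confounder.  Uses the 1-df CMH chi-square without continuity
#' correction; a stratum with a zero margin contributes nothing to the
#' numerator or the denominator.
#'
#' @param x_col binary variant vector.
#' @param combined binary combined-phenotype vector.
#' @param best_single binary stratification vector (the single most
#'   associated phenotype).
#' @return the p-value, or `NA` if every stratum is degenerate.
#' @export
cmh_test <- function(x_col, combined, best_single) {
  stopifnot(length(x_col) == length(combined),
            length(combined) == length(best_single))
  num <- 0; den <- 0
  for (s in c(0L, 1L)) {
    idx <- best_single == s
    n <- sum(idx)
    if (n < 2) next
    a <- sum(x_col[idx] * combined[idx])
    r1 <- sum(combined[idx]); c1 <- sum(x_col[idx])
    if (r1 %in% c(0, n) || c1 %in% c(0, n)) next   # zero-margin stratum
    num <- num + (a - r1 * c1 / n)
    den <- den + r1 * (n - r1) * c1 * (n - c1) / (n^2 * (n - 1))
  }
  if (den == 0) return(NA_real_)
  stat <- num^2 / den
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
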