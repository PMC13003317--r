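# Orchestration across variants: triage (can any CNF meet a crude
# significance bound?), iterative optimisation of the Fisher p-value
# (doubling on -log p, then binary search, then an exact refinement
# that proves optimality), discovery/validation two-stage testing, and
# the single-phenotype GWAS baseline run on the same split.

# single-phenotype Fisher scan against one variant, from collapsed data;
# returns per-phenotype p-values
single_scan <- function(collapsed, snp, negate = FALSE,
                        direction = "over") {
  m <- collapsed$multiplicity
  xc <- if (length(snp) > 1) as.numeric(snp) else
    as.numeric(collapsed$carrier_counts[, snp])
  if (negate) xc <- m - xc
  M <- sum(m); nv <- sum(xc)
  nu <- colSums(collapsed$profiles * m)
  nuv <- colSums(collapsed$profiles * xc)
  stats::setNames(fisher_tail_p(nuv, nu, nv, M, direction),
                  colnames(collapsed$profiles))
}

# strongest p attainable by ANY binary phenotype vector against this
# variant: min over S of p(S, min(S, nv))
min_attainable_p <- function(nv, M) {
  S <- 0:M
  min(fisher_tail_p(pmin(S, nv), S, nv, M))
}

#' Triage variants: can any (K, L)-CNF meet the significance bound?
#'
#' For each variant (and, optionally, its complement) decides by a
#' feasibility MILP whether some CNF with at most K clauses of at most
#' L phenotypes attains a one-sided Fisher p-value of `p0` or better.
#' A variant whose best single phenotype already passes is accepted
#' without a solve (single phenotypes are inside the search space), and
#' `K = L = 1` reduces entirely to the single-phenotype scan.
#'
#' @param X,Y genotype and phenotype [binary_matrix()] objects over the
#'   same subjects.
#' @param K,L search-space shape.
#' @param p0 the crude bound, in `(0, 1)`; defaults in the pipeline to
#'   the final significance threshold.
#' @param negate also test each variant's complement.
#' @param backend,time_limit,delta solver and boundary controls, see
#'   [solve_milp()] and [simplify_boundary()].
#' @return a tibble: `snp_id`, `negated`, `status` (`"pass"`, `"fail"`
#'   or `"undetermined"` on solver timeout), `p_single_min`.
#' @export
triage <- function(X, Y, K, L, p0, negate = FALSE, backend = "highs",
                   time_limit = Inf, delta = 0.001) {
  stopifnot(p0 > 0, p0 < 1)
  collapsed <- collapse_subjects(X, Y)
  grid <- tidyr::expand_grid(snp_id = colnames(X),
                             negated = if (negate) c(FALSE, TRUE) else FALSE)
  res <- purrr::pmap(grid, function(snp_id, negated) {
    triage_one(collapsed, snp_id, K, L, p0, negated, backend,
               time_limit, delta)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

triage_one <- function(collapsed, snp, K, L, p0, negate, backend,
                       time_limit, delta) {
  ps <- single_scan(collapsed, snp, negate)
  pmin1 <- min(ps)
  if (pmin1 <= p0 || (K == 1 && L == 1)) {
    out <- tibble::tibble(
      status = if (pmin1 <= p0) "pass" else "fail", p_single_min = pmin1)
    return(out)
  }
  f <- build_formulation(collapsed, snp, K, L, objective = "feasibility",
                         threshold = list(p0 = p0, delta = delta),
                         negate = negate)
  if (threshold_unattainable(f))
    return(tibble::tibble(status = "fail", p_single_min = pmin1))
  sol <- solve_milp(f, backend = backend, time_limit = time_limit)
  status <- switch(sol$status, optimal = "pass", infeasible = "fail",
                   timeout = "undetermined", "undetermined")
  out <- tibble::tibble(status = status, p_single_min = pmin1)
  if (sol$status == "optimal")
    attr(out, "certificate") <- extract_cnf(sol, f)
  out
}

#' Optimise the association of one variant over CNF phenotypes
#'
#' Finds the (K, L)-CNF combined phenotype with the strongest one-sided
#' Fisher p-value against a variant.  Starting from the best single
#' phenotype, thresholds are tightened by doubling on `-log10 p`,
#' bracketed by binary search until the bracket ratio falls below
#' `tol_ratio`, and finally refined to a proven optimum: a last
#' feasibility probe strictly below the incumbent's p either improves
#' it or certifies optimality.  Each probe is a feasibility MILP with
#' the agreement objective; the reported p is always recomputed exactly
#' from the counts of the returned CNF.
#'
#' @param collapsed a [collapse_subjects()] result.
#' @param snp variant column in `carrier_counts`.
#' @param K,L search-space shape.
#' @param negate use the variant's complement.
#' @param stat objective statistic: `"fisher_p"` (iterative route) or a
#'   linear statistic (`"agreement"`, `"hamming"`, `"covariance"`; one
#'   solve).
#' @param backend,time_limit,delta solver and boundary controls.
#' @param doubling_base factor applied to `-log10 p` while probes stay
#'   feasible.
#' @param tol_ratio stop the binary search once the p bracket ratio is
#'   below this; the exact refinement then closes the remaining gap.
#' @param exact run the refinement loop to a proven optimum.
#' @param incumbent optional [cnf_phenotype()] to seed the search (for
#'   instance a triage feasibility certificate).
#' @return an object of class `cnf_fit`: list with `snp_id`, `negated`,
#'   `cnf`, `S`, `T`, `nv`, `M`, `p` (or `value` for linear
#'   statistics), `stat`, `status` and `n_solves`.
#' @export
optimize_variant <- function(collapsed, snp, K, L, negate = FALSE,
                             stat = "fisher_p", backend = "highs",
                             time_limit = Inf, delta = 0.001,
                             doubling_base = 2, tol_ratio = 1.05,
                             exact = TRUE, incumbent = NULL) {
  m <- collapsed$multiplicity
  M <- sum(m)
  xc <- as.numeric(collapsed$carrier_counts[, snp])
  if (negate) xc <- m - xc
  nv <- sum(xc)
  snp_id <- if (is.character(snp)) snp else colnames(collapsed$carrier_counts)[snp]

  if (stat %in% c("agreement", "hamming", "covariance")) {
    f <- build_formulation(collapsed, snp, K, L, objective = stat,
                           negate = negate)
    sol <- solve_milp(f, backend = backend, time_limit = time_limit)
    if (sol$status != "optimal")
      stop("linear-objective solve did not reach optimality: ", sol$status,
           call. = FALSE)
    cnf <- postprocess_cnf(extract_cnf(sol, f))
    t <- cnf_contingency(cnf, collapsed, snp, negate = negate)
    return(new_cnf_fit(snp_id, negate, cnf, t, stat,
                       value = compute_stat(stat, t),
                       status = "optimized", n_solves = 1L))
  }
  if (!identical(stat, "fisher_p"))
    stop("iterative optimisation supports 'fisher_p'; linear statistics ",
         "are optimised directly", call. = FALSE)

  # incumbent: best single phenotype, or a caller-supplied certificate
  ps <- single_scan(collapsed, snp, negate)
  j_best <- which.min(ps)
  cnf_cur <- cnf_phenotype(list(j_best))
  p_cur <- unname(ps[j_best])
  if (!is.null(incumbent)) {
    p_inc <- compute_stat("fisher_p",
                          cnf_contingency(incumbent, collapsed, snp,
                                          negate = negate))
    if (p_inc < p_cur) { p_cur <- p_inc; cnf_cur <- incumbent }
  }
  n_solves <- 0L
  status <- "optimized"
  p_floor <- min_attainable_p(nv, M)

  probe <- function(p_target) {
    f <- build_formulation(collapsed, snp, K, L, objective = "feasibility",
                           threshold = list(p0 = p_target, delta = delta),
                           negate = negate)
    if (threshold_unattainable(f)) return(list(status = "infeasible"))
    sol <- solve_milp(f, backend = backend, time_limit = time_limit)
    n_solves <<- n_solves + 1L
    if (sol$status == "optimal") {
      cnf <- extract_cnf(sol, f)
      t <- cnf_contingency(cnf, collapsed, snp, negate = negate)
      list(status = "feasible", cnf = cnf,
           p = compute_stat("fisher_p", t))
    } else list(status = sol$status)
  }

  if (!(K == 1 && L == 1) && p_cur > p_floor) {
    # doubling on -log10 p
    l_lo <- -log10(p_cur)                 # feasible side
    l_hi <- NA_real_                      # infeasible side
    l_cap <- -log10(p_floor)
    l_try <- max(l_lo * doubling_base, 1e-6)
    repeat {
      l_try <- min(l_try, l_cap)
      pr <- probe(10^(-l_try))
      if (pr$status == "feasible") {
        if (pr$p < p_cur) { p_cur <- pr$p; cnf_cur <- pr$cnf }
        l_lo <- max(l_lo, l_try, -log10(pr$p))
        if (l_try >= l_cap) break
        l_try <- l_try * doubling_base
      } else if (pr$status == "infeasible") {
        l_hi <- l_try; break
      } else { status <- "timeout"; break }
    }
    # binary search on -log10 p until the bracket ratio closes
    if (!is.na(l_hi) && status == "optimized") {
      while (l_hi - l_lo > log10(tol_ratio)) {
        l_mid <- (l_lo + l_hi) / 2
        pr <- probe(10^(-l_mid))
        if (pr$status == "feasible") {
          if (pr$p < p_cur) { p_cur <- pr$p; cnf_cur <- pr$cnf }
          l_lo <- max(l_mid, -log10(pr$p))
        } else if (pr$status == "infeasible") {
          l_hi <- l_mid
        } else { status <- "timeout"; break }
      }
    }
    # exact refinement: strictly-better probes until proven optimal
    if (exact && status == "optimized") {
      for (it in 1:100) {
        if (p_cur <= p_floor) break
        pr <- probe(p_cur * (1 - 1e-9))
        if (pr$status == "feasible") {
          if (pr$p >= p_cur) { status <- "bracket-open"; break }
          p_cur <- pr$p; cnf_cur <- pr$cnf
        } else if (pr$status == "infeasible") break
        else { status <- "timeout"; break }
        if (it == 100) status <- "bracket-open"
      }
    }
  }
  cnf_cur <- postprocess_cnf(cnf_cur)
  t <- cnf_contingency(cnf_cur, collapsed, snp, negate = negate)
  new_cnf_fit(snp_id, negate, cnf_cur, t, "fisher_p",
              value = compute_stat("fisher_p", t),
              status = status, n_solves = n_solves)
}

new_cnf_fit <- function(snp_id, negated, cnf, t, stat, value, status,
                        n_solves) {
  structure(list(snp_id = snp_id, negated = negated, cnf = cnf,
                 S = t$nu, T = t$nuv, nv = t$nv, M = t$M,
                 p = if (stat == "fisher_p") value else NA_real_,
                 value = value, stat = stat, status = status,
                 n_solves = n_solves),
            class = "cnf_fit")
}

#' @export
print.cnf_fit <- function(x, ...) {
  cat(sprintf("<cnf_fit> %s%s: %s  %s=%.3g (S=%d, T=%d, nv=%d, M=%d) [%s]\n",
              x$snp_id, if (x$negated) " (negated)" else "",
              format_cnf(x$cnf), x$stat, x$value, x$S, x$T, x$nv, x$M,
              x$status))
  invisible(x)
}

#' @rdname cnf_fit-tidiers
#' @export
tidy.cnf_fit <- function(x, ...) {
  tibble::tibble(
    clause = rep(seq_along(x$cnf$clauses), lengths(x$cnf$clauses)),
    phenotype = unlist(x$cnf$clauses))
}

#' Tidiers for fitted variant objects
#'
#' `tidy()` returns one row per clause membership; `glance()` a one-row
#' summary of the fit.
#'
#' @param x a `cnf_fit` from [optimize_variant()].
#' @param ... unused.
#' @name cnf_fit-tidiers
#' @export
glance.cnf_fit <- function(x, ...) {
  tibble::tibble(snp_id = x$snp_id, negated = x$negated,
                 cnf = format_cnf(x$cnf), S = x$S, T = x$T, nv = x$nv,
                 M = x$M, p = x$p, value = x$value, stat = x$stat,
                 status = x$status, n_solves = x$n_solves)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# deterministic equal split: first floor(M/2) of a seeded permutation
# go to discovery, the rest (including any odd subject) to validation
split_cohort <- function(M, split_seed) {
  perm <- withr::with_seed(split_seed, sample.int(M))
  list(discovery = sort(perm[seq_len(M %/% 2)]),
       validation = sort(perm[(M %/% 2 + 1):M]))
}

subset_bm <- function(B, rows) {
  binary_matrix(unclass(B)[rows, , drop = FALSE],
                kind = attr(B, "kind") %||% "genotype")
}

#' Two-stage discovery/validation search over all variants
#'
#' Splits the cohort into equal discovery and validation halves (any
#' odd subject joins validation), finds the best CNF combined phenotype
#' per variant on the discovery half for variants passing triage at
#' `p0`, then evaluates each discovered CNF unchanged on the validation
#' half.  A result is `"validated"` iff both halves meet `p0`.  The
#' Cochran-Mantel-Haenszel p-value against the best single phenotype
#' (chosen on discovery) is computed on the validation half.
#'
#' @inheritParams triage
#' @param split_seed integer seed controlling the subject permutation;
#'   identical seeds reproduce identical splits and results.
#' @param cmh compute the stratified confounding check.
#' @param exact,tol_ratio forwarded to [optimize_variant()]; with
#'   `exact = FALSE` the discovered CNF is only guaranteed optimal up
#'   to the bracket ratio, which leaves pass/fail decisions at `p0`
#'   unchanged whenever a passing CNF exists.
#' @return a tibble with one row per (variant, negation): `snp_id`,
#'   `negated`, `cnf`, `S`, `T`, `nv`, `p_discovery`, `p_validation`,
#'   `cmh_p`, `status` (`"failed"`, `"discovered"`, `"validated"`).
#' @export
two_stage <- function(X, Y, K, L, p0, split_seed = 1L, negate = FALSE,
                      backend = "highs", time_limit = Inf, delta = 0.001,
                      cmh = TRUE, exact = TRUE, tol_ratio = 1.05) {
  check_same_subjects(X, Y)
  M <- nrow(X)
  stopifnot(M >= 2)
  halves <- split_cohort(M, split_seed)
  Xd <- subset_bm(X, halves$discovery); Yd <- subset_bm(Y, halves$discovery)
  Xv <- subset_bm(X, halves$validation); Yv <- subset_bm(Y, halves$validation)
  cd <- collapse_subjects(Xd, Yd)
  grid <- tidyr::expand_grid(snp_id = colnames(X),
                             negated = if (negate) c(FALSE, TRUE) else FALSE)
  rows <- purrr::pmap(grid, function(snp_id, negated) {
    tri <- triage_one(cd, snp_id, K, L, p0, negated, backend,
                      time_limit, delta)
    if (tri$status != "pass") {
      return(tibble::tibble(
        cnf = NA_character_, S = NA_integer_, T = NA_integer_,
        nv = NA_integer_, p_discovery = NA_real_, p_validation = NA_real_,
        cmh_p = NA_real_, status = "failed"))
    }
    fit <- optimize_variant(cd, snp_id, K, L, negate = negated,
                            backend = backend, time_limit = time_limit,
                            delta = delta, exact = exact,
                            tol_ratio = tol_ratio,
                            incumbent = attr(tri, "certificate"))
    if (fit$p > p0) {
      return(tibble::tibble(
        cnf = format_cnf(fit$cnf, colnames(Y)), S = fit$S, T = fit$T,
        nv = fit$nv, p_discovery = fit$p, p_validation = NA_real_,
        cmh_p = NA_real_, status = "failed"))
    }
    # fixed evaluation on the validation half: no re-fitting
    uv <- evaluate_cnf(fit$cnf, Yv)
    xv <- unclass(Xv)[, snp_id]
    if (negated) xv <- 1L - xv
    tv <- summarize_pair(uv, xv)
    p_val <- compute_stat("fisher_p", tv)
    cmh_p <- NA_real_
    if (cmh) {
      ps <- single_scan(cd, snp_id, negated)
      best_single <- unclass(Yv)[, which.min(ps)]
      cmh_p <- cmh_test(xv, uv, best_single)
    }
    tibble::tibble(
      cnf = format_cnf(fit$cnf, colnames(Y)), S = fit$S, T = fit$T,
      nv = fit$nv, p_discovery = fit$p, p_validation = p_val,
      cmh_p = cmh_p,
      status = if (p_val <= p0) "validated" else "discovered")
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(rows))
}

#' Single-phenotype GWAS baseline on the same two-stage design
#'
#' For each variant, the single phenotype with the smallest one-sided
#' Fisher p-value on the discovery half is carried unchanged to the
#' validation half.  Shares the split with [two_stage()] through
#' `split_seed`, so the two methods are compared on identical cohorts.
#'
#' @inheritParams two_stage
#' @return a tibble: `snp_id`, `negated`, `phenotype`, `p_discovery`,
#'   `p_validation`, `status`.
#' @export
gwas_baseline <- function(X, Y, p0, split_seed = 1L, negate = FALSE) {
  check_same_subjects(X, Y)
  M <- nrow(X)
  halves <- split_cohort(M, split_seed)
  Xd <- subset_bm(X, halves$discovery); Yd <- subset_bm(Y, halves$discovery)
  Xv <- subset_bm(X, halves$validation); Yv <- subset_bm(Y, halves$validation)
  cd <- collapse_subjects(Xd, Yd)
  grid <- tidyr::expand_grid(snp_id = colnames(X),
                             negated = if (negate) c(FALSE, TRUE) else FALSE)
  rows <- purrr::pmap(grid, function(snp_id, negated) {
    ps <- single_scan(cd, snp_id, negated)
    j <- which.min(ps)
    p_disc <- unname(ps[j])
    uv <- unclass(Yv)[, j]
    xv <- unclass(Xv)[, snp_id]
    if (negated) xv <- 1L - xv
    p_val <- compute_stat("fisher_p", summarize_pair(uv, xv))
    tibble::tibble(
      phenotype = colnames(Y)[j], p_discovery = p_disc,
      p_validation = p_val,
      status = if (p_disc > p0) "failed"
               else if (p_val <= p0) "validated" else "discovered")
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(rows))
}

#' Write association results as TSV
#'
#' @param results a tibble from [two_stage()] or [gwas_baseline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}
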