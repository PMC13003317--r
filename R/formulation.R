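# MILP formulation of the best-combined-phenotype problem for a single
# variant.  Binary variables U[j,k] select phenotype j into clause k;
# P[i,k] is profile i's value for clause k; Pc[i] the overall combined
# phenotype; integer S and T count (with multiplicities) the subjects
# with the phenotype and with both phenotype and variant.  The or/and
# constraint families tie the layers together so that every feasible
# assignment is a valid (K, L)-CNF evaluation, and an optional boundary
# encoding enforces a significance threshold on a monotone statistic.

#' Build the MILP for one variant
#'
#' @param collapsed a [collapse_subjects()] (or internally wrapped
#'   uncollapsed) dataset.
#' @param snp variant column name/index in `carrier_counts`, or a
#'   numeric per-profile carrier-count vector.
#' @param K,L maximum clause count and clause size.
#' @param objective `"agreement"`, `"hamming"` or `"covariance"` (the
#'   statistics linear in `(S, T)`), or `"feasibility"`.  Agreement and
#'   Hamming distance share the integer objective `2T - S` (maximising
#'   agreement and minimising Hamming distance are the same ordering);
#'   covariance is optimised as the order-equivalent integer `M*T -
#'   nv*S`.  Non-linear statistics are optimised through the threshold
#'   machinery, see [optimize_variant()].
#' @param threshold optional `list(p0 =, stat = "fisher_p", delta =
#'   0.001)`: adds the boundary constraint that the statistic passes
#'   `p0`.
#' @param negate use the variant's complement.
#' @param forbid_empty_clause require at least one phenotype per clause
#'   (a repeated clause still emulates a smaller K).
#' @return an object of class `milp_formulation`.
#' @export
build_formulation <- function(collapsed, snp, K, L,
                              objective = c("agreement", "hamming",
                                            "covariance", "feasibility"),
                              threshold = NULL, negate = FALSE,
                              forbid_empty_clause = TRUE) {
  objective <- match.arg(objective)
  stopifnot(K >= 1, L >= 1)
  Yp <- collapsed$profiles
  m <- collapsed$multiplicity
  xc <- if (length(snp) > 1) as.numeric(snp) else
    as.numeric(collapsed$carrier_counts[, snp])
  if (negate) xc <- m - xc
  U <- nrow(Yp); P <- ncol(Yp)
  M <- sum(m); nv <- sum(xc)
  O <- sum(Yp * m)                     # total phenotype 1s over subjects
  nU <- P * K; nPik <- U * K
  iU <- function(j, k) (k - 1L) * P + j
  iPik <- function(i, k) nU + (k - 1L) * U + i
  iPi <- function(i) nU + nPik + i
  iS <- nU + nPik + U + 1L
  iT <- iS + 1L
  ncore <- iT

  nz <- which(Yp == 1, arr.ind = TRUE)   # (profile i, phenotype j) pairs
  nzi <- nz[, 1]; nzj <- nz[, 2]
  nnz <- length(nzi)

  ti <- list(); tj <- list(); tx <- list(); lo <- list(); hi <- list()
  families <- list()
  row0 <- 0L
  push <- function(fam, i, j, x, l, h, nrows) {
    ti[[length(ti) + 1]] <<- row0 + i
    tj[[length(tj) + 1]] <<- j
    tx[[length(tx) + 1]] <<- x
    lo[[length(lo) + 1]] <<- l
    hi[[length(hi) + 1]] <<- h
    families[[fam]] <<- (families[[fam]] %||% 0L) + nrows
    row0 <<- row0 + nrows
  }

  for (k in seq_len(K)) {
    # or (carrier side): U[j,k] - P[i,k] <= 0 for every Y[i,j] = 1
    push("or_carrier",
         i = rep(seq_len(nnz), 2L),
         j = c(iU(nzj, k), iPik(nzi, k)),
         x = c(rep(1, nnz), rep(-1, nnz)),
         l = rep(-Inf, nnz), h = rep(0, nnz), nrows = nnz)
    # or (cover side): P[i,k] - sum_{j: Y[i,j]=1} U[j,k] <= 0
    push("or_cover",
         i = c(seq_len(U), nzi),
         j = c(iPik(seq_len(U), k), iU(nzj, k)),
         x = c(rep(1, U), rep(-1, nnz)),
         l = rep(-Inf, U), h = rep(0, U), nrows = U)
  }
  for (k in seq_len(K)) {
    # and: Pc[i] - P[i,k] <= 0
    push("and_lower",
         i = rep(seq_len(U), 2L),
         j = c(iPi(seq_len(U)), iPik(seq_len(U), k)),
         x = c(rep(1, U), rep(-1, U)),
         l = rep(-Inf, U), h = rep(0, U), nrows = U)
  }
  # and: sum_k P[i,k] - Pc[i] <= K - 1
  push("and_upper",
       i = c(rep(seq_len(U), K), seq_len(U)),
       j = c(as.vector(vapply(seq_len(K), function(k) iPik(seq_len(U), k),
                              numeric(U))), iPi(seq_len(U))),
       x = c(rep(1, U * K), rep(-1, U)),
       l = rep(-Inf, U), h = rep(K - 1, U), nrows = U)
  # count equalities: S = sum m_i Pc_i, T = sum xc_i Pc_i
  push("count_eq", i = rep(1L, U + 1L), j = c(iS, iPi(seq_len(U))),
       x = c(1, -m), l = 0, h = 0, nrows = 1L)
  push("count_eq", i = rep(1L, U + 1L), j = c(iT, iPi(seq_len(U))),
       x = c(1, -xc), l = 0, h = 0, nrows = 1L)
  # clause sizes: sum_j U[j,k] <= L (lower bound 1 forbids empty clauses)
  push("clause_size",
       i = rep(seq_len(K), each = P),
       j = as.vector(vapply(seq_len(K), function(k) iU(seq_len(P), k),
                            numeric(P))),
       x = rep(1, P * K),
       l = rep(if (forbid_empty_clause) 1 else 0, K),
       h = rep(L, K), nrows = K)

  vars <- tibble::tibble(
    name = c(paste0("U", rep(seq_len(P), K), "_", rep(seq_len(K), each = P)),
             paste0("P", rep(seq_len(U), K), "_", rep(seq_len(K), each = U)),
             paste0("Pc", seq_len(U)), "S", "T"),
    lb = 0,
    ub = c(rep(1, nU + nPik + U), M, nv),
    integer = TRUE,
    obj = 0
  )

  enc <- NULL
  if (!is.null(threshold)) {
    stat <- threshold$stat %||% "fisher_p"
    delta <- threshold$delta %||% 0.001
    curve <- threshold_curve(nv, M, threshold$p0, stat = stat)
    R <- suppressWarnings(prune_boundary(curve))
    if (!nrow(R)) {
      enc <- list(mode = "unattainable", n_vars = 0L, n_constraints = 0L)
    } else {
      bs <- simplify_boundary(R, delta = delta)
      enc <- encode_lower_bound(bs)
      # S confined to the feasible domain by variable bounds
      vars$lb[iS] <- enc$S_min
      vars$ub[iS] <- enc$S_max
      if (nrow(enc$vars)) {
        vars <- dplyr::bind_rows(vars, tibble::tibble(
          name = enc$vars$name, lb = enc$vars$lb, ub = enc$vars$ub,
          integer = enc$vars$integer, obj = 0))
      }
      name_idx <- stats::setNames(seq_len(nrow(vars)), vars$name)
      for (cc in enc$constraints) {
        jj <- unname(name_idx[names(cc$coefs)])
        push("boundary", i = rep(1L, length(jj)), j = jj,
             x = unname(cc$coefs), l = cc$lo, h = cc$hi, nrows = 1L)
      }
    }
  }

  vars$obj <- 0
  obj_desc <- objective
  if (objective %in% c("agreement", "hamming")) {
    vars$obj[iT] <- 2; vars$obj[iS] <- -1      # 2T - S
  } else if (objective == "covariance") {
    vars$obj[iT] <- M; vars$obj[iS] <- -nv     # M*T - nv*S
  }
  # feasibility mode keeps a zero objective: the engine then accepts the
  # first incumbent and spends its effort on the infeasibility proof

  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(row0, nrow(vars)))
  structure(list(
    A = A, lo = unlist(lo), hi = unlist(hi), vars = vars, maximize = TRUE,
    K = K, L = L, U = U, P = P, M = M, nv = nv, O = O,
    objective = obj_desc, families = unlist(families),
    n_core_vars = ncore,
    idx = list(iU = iU, iPik = iPik, iPi = iPi, iS = iS, iT = iT),
    profiles = Yp, multiplicity = m, carriers = xc,
    encoding = enc,
    label = sprintf("K=%d L=%d U=%d P=%d objective=%s", K, L, U, P, obj_desc)
  ), class = "milp_formulation")
}

#' @export
print.milp_formulation <- function(x, ...) {
  cat(sprintf("<milp_formulation> %s: %d vars, %d constraints\n",
              x$label, nrow(x$vars), nrow(x$A)))
  if (!is.null(x$encoding) && !is.null(x$encoding$mode))
    cat(sprintf("  boundary encoding: %s (%d vars, %d constraints)\n",
                x$encoding$mode, x$encoding$n_vars, x$encoding$n_constraints))
  invisible(x)
}

# TRUE when a threshold was requested but no (S, T) can attain it
threshold_unattainable <- function(f) {
  identical(f$encoding$mode, "unattainable")
}

#' Read the CNF combined phenotype off a MILP solution
#'
#' Clause k collects the phenotypes with `U[j,k] = 1`.  The extracted
#' CNF is re-evaluated on the profiles and compared with the solution's
#' combined-phenotype variables; any mismatch (solver numerical noise)
#' or empty clause raises an error.
#'
#' @param solution a feasible [solve_milp()] result.
#' @param f the [build_formulation()] the solution came from.
#' @return a canonicalised [cnf_phenotype()].
#' @export
extract_cnf <- function(solution, f) {
  if (is.null(solution$x)) stop("solution carries no variable assignment",
                                call. = FALSE)
  x <- solution$x
  clauses <- lapply(seq_len(f$K), function(k)
    which(x[f$idx$iU(seq_len(f$P), k)] > 0.5))
  if (any(lengths(clauses) == 0))
    stop("solver returned an empty clause", call. = FALSE)
  cnf <- cnf_phenotype(clauses, P = f$P)
  pc <- as.integer(x[f$idx$iPi(seq_len(f$U))] > 0.5)
  ev <- evaluate_cnf(cnf, f$profiles)
  if (!identical(ev, pc))
    stop("extracted CNF does not reproduce the solution's combined phenotype",
         call. = FALSE)
  canonicalize_cnf(cnf)
}
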