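# fixtures are built in code: random binary matrices, planted-CNF
# instances, and independent brute-force oracles used across the suite

rand_bm <- function(M, P, prob = 0.3, kind = "phenotype", prefix = NULL) {
  if (is.null(prefix)) prefix <- if (kind == "genotype") "snp" else "phe"
  binary_matrix(
    matrix(rbinom(M * P, 1, prob), M, P,
           dimnames = list(paste0("S", seq_len(M)),
                           paste0(prefix, seq_len(P)))),
    kind = kind)
}

rand_instance <- function(M, P, N = 1, seed = NULL, py = 0.3, px = 0.4) {
  if (!is.null(seed)) set.seed(seed)
  list(X = rand_bm(M, N, px, kind = "genotype"),
       Y = rand_bm(M, P, py, kind = "phenotype"))
}

rand_cnf <- function(P, K, L) {
  cnf_phenotype(replicate(K, sample.int(P, sample.int(L, 1)),
                          simplify = FALSE))
}

# truth-table CNF evaluation, one subject at a time (independent of the
# vectorised implementation)
brute_eval_cnf <- function(cnf, Y) {
  Y <- unclass(Y)
  vapply(seq_len(nrow(Y)), function(i) {
    as.integer(all(vapply(cnf$clauses, function(cl)
      any(Y[i, cl] == 1), TRUE)))
  }, integer(1))
}

# upper-tail hypergeometric p by direct density summation
brute_fisher_p <- function(nuv, nu, nv, M) {
  hi <- min(nu, nv)
  if (nuv > hi) return(0)
  sum(dhyper(nuv:hi, nv, M - nv, nu))
}

# smallest passing T by linear scan (threshold-curve oracle)
brute_curve <- function(nv, M, p0) {
  vapply(0:M, function(S) {
    Ts <- max(0, S + nv - M):min(S, nv)
    ok <- vapply(Ts, function(T) brute_fisher_p(T, S, nv, M) <= p0, TRUE)
    if (!any(ok)) NA_integer_ else Ts[which(ok)[1]]
  }, integer(1))
}

# --- independent corridor-line feasibility + DP segmentation oracle ----
# a line l(x) = a x + b with y_i - w <= l(x_i) <= y_i for all i exists
# iff some candidate line through two corridor endpoints (or a
# horizontal line through one) satisfies every constraint
oracle_line_feasible <- function(x, y, w, tol = 1e-7) {
  n <- length(x)
  satisfies <- function(a, b) {
    v <- a * x + b
    all(v >= y - w - tol) && all(v <= y + tol)
  }
  if (n == 1) return(TRUE)
  for (i in seq_len(n)) for (yi in c(y[i], y[i] - w)) {
    if (satisfies(0, yi)) return(TRUE)
    for (j in seq_len(n)) {
      if (x[j] == x[i]) next
      for (yj in c(y[j], y[j] - w)) {
        a <- (yj - yi) / (x[j] - x[i]); b <- yi - a * x[i]
        if (satisfies(a, b)) return(TRUE)
      }
    }
  }
  FALSE
}

# dynamic programme: minimum number of corridor-feasible runs
oracle_min_segments <- function(x, y, w) {
  n <- length(x)
  dp <- rep(Inf, n + 1); dp[1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (is.finite(dp[j]) &&
          oracle_line_feasible(x[j:i], y[j:i], w))
        dp[i + 1] <- min(dp[i + 1], dp[j] + 1)
    }
  }
  dp[n + 1]
}

# integer feasibility of a boundary encoding at a fixed (S, T):
# brute-force over the binary auxiliaries, checking every constraint
fragment_feasible <- function(enc, S, T) {
  if (S < enc$S_min || S > enc$S_max) return(FALSE)
  k <- nrow(enc$vars)
  fixed <- c(S = S, T = T)
  zgrids <- if (k == 0) list(integer(0)) else
    asplit(as.matrix(expand.grid(rep(list(0:1), k))), 1)
  for (z in zgrids) {
    vals <- c(fixed, setNames(as.numeric(z), enc$vars$name))
    ok <- all(vapply(enc$constraints, function(cc) {
      s <- sum(cc$coefs * vals[names(cc$coefs)])
      s >= cc$lo - 1e-7 && s <= cc$hi + 1e-7
    }, TRUE))
    if (ok) return(TRUE)
  }
  FALSE
}

# planted-CNF instance: a pseudo-SNP equal to a CNF evaluation (with
# optional flips) among iid decoys
planted_instance <- function(M, P, K, L, n_decoys = 3, eps = 0,
                             py = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- rand_bm(M, P, py)
  repeat {
    cnf <- cnf_phenotype(replicate(K, sort(sample.int(P, L)),
                                   simplify = FALSE))
    ev <- evaluate_cnf(cnf, Y)
    if (var(ev) > 0) break
  }
  pseudo <- ev
  nf <- round(eps * M)
  if (nf > 0) {
    ix <- sample.int(M, nf)
    pseudo[ix] <- 1L - pseudo[ix]
  }
  X <- cbind(pseudo, matrix(rbinom(M * n_decoys, 1, mean(pseudo)),
                            M, n_decoys))
  colnames(X) <- paste0("snp", seq_len(n_decoys + 1))
  rownames(X) <- rownames(Y)
  list(X = binary_matrix(X, kind = "genotype"), Y = Y, cnf = cnf,
       pseudo_id = "snp1")
}
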