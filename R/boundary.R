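# Significance-threshold boundary machinery.
#
# For a monotone statistic and a fixed variant carrier count nv, the
# threshold "f at least as strong as p0" is equivalent, for each value
# of the combined-phenotype count S, to a lower bound T >= g(S) on the
# co-occurrence count.  g is computed by binary search, pruned to a
# small set of representative points, simplified to few linear segments
# within a width-(1 - delta) corridor, and finally emitted as linear
# constraints usable inside the MILP.  The chain preserves the integer
# feasible set exactly: an attainable integer (S, T) satisfies the
# encoded constraints iff it passes the original threshold.

# vectorised statistic evaluation in terms of (S, T) for fixed nv, M
stat_value_vec <- function(name, S, T, nv, M, direction = "over") {
  a <- T; b <- S - T; c <- nv - T; d <- M - S - nv + T
  switch(name,
    agreement = a + d,
    hamming = b + c,
    covariance = a / M - (S * nv) / M^2,
    correlation = (a / M - S * nv / M^2) /
      sqrt((S / M) * (1 - S / M) * (nv / M) * (1 - nv / M)),
    odds_ratio = (a * d) / (b * c),
    kappa = 2 * (a * d - b * c) / (S * (M - nv) + nv * (M - S)),
    fisher_p = fisher_tail_p(T, S, nv, M, direction),
    stop("unsupported statistic for threshold curves: ", name, call. = FALSE)
  )
}

# does the statistic value pass the threshold ("at least as strong")?
stat_passes <- function(name, value, threshold) {
  if (stat_spec(name)$higher_is_stronger) value >= threshold else value <= threshold
}

#' Level curve of a monotone statistic at a significance threshold
#'
#' For every combined-phenotype count `S` in `0:M`, finds by binary
#' search the smallest attainable co-occurrence count `T` at which the
#' statistic passes the threshold, or marks `S` infeasible when no
#' attainable `T` passes.
#'
#' @param nv variant carrier count.
#' @param M total subjects.
#' @param p0 the threshold value (for `fisher_p`, an upper bound on the
#'   p-value; for an increasing statistic, a lower bound on its value).
#' @param stat statistic name; must be monotone in `nuv` (the
#'   chi-square coefficient is rejected).
#' @param direction only `"over"` (over-representation) is meaningful
#'   here; protective associations are searched by negating the
#'   variant.
#' @return an object of class `threshold_curve`: list with `S = 0:M`,
#'   `g` (integer or `NA` where infeasible), and the inputs.
#' @export
threshold_curve <- function(nv, M, p0, stat = "fisher_p",
                            direction = "over") {
  # only the over-representation direction yields a LOWER bound in T;
  # protective associations are handled upstream by variant negation
  if (!identical(direction, "over"))
    stop("threshold curves are defined for the over-representation ",
         "direction; negate the variant for protective associations",
         call. = FALSE)
  spec <- stat_spec(stat)
  if (spec$monotone_in_nuv == "non-monotone")
    stop(sprintf(paste0(
      "statistic '%s' is not monotone in the co-occurrence count, so a ",
      "threshold on it is not a lower boundary in T; use a monotone ",
      "statistic such as 'fisher_p'"), stat), call. = FALSE)
  stopifnot(nv >= 0, nv <= M)
  S <- 0:M
  Tmin <- pmax(0L, S + nv - M)
  Tmax <- pmin(S, nv)
  pass_at <- function(Tq) stat_passes(
    stat, stat_value_vec(stat, S, Tq, nv, M, direction), p0)
  # the strongest attainable value sits at Tmax (statistic strengthens
  # with T for every supported monotone statistic)
  feasible <- pass_at(Tmax)
  feasible[is.na(feasible)] <- FALSE
  g <- rep(NA_integer_, M + 1)
  lo <- Tmin; hi <- Tmax
  active <- feasible
  while (any(active & lo < hi)) {
    mid <- (lo + hi) %/% 2
    ok <- active & lo < hi
    pm <- rep(FALSE, M + 1)
    pm[ok] <- pass_at(mid)[ok]
    pm[is.na(pm)] <- FALSE
    hi[ok & pm] <- mid[ok & pm]
    lo[ok & !pm] <- mid[ok & !pm] + 1L
  }
  g[feasible] <- as.integer(lo[feasible])
  structure(list(S = S, g = g, nv = nv, M = M, p0 = p0,
                 stat = stat, direction = direction),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  nf <- sum(!is.na(x$g))
  cat(sprintf("<threshold_curve> %s at %g, nv=%d, M=%d: %d feasible S values\n",
              x$stat, x$p0, x$nv, x$M, nf))
  invisible(x)
}

#' Prune a threshold boundary to its representative points
#'
#' Keeps the leftmost feasible point plus, for each distinct feasible
#' boundary level, the point with the largest `S` attaining it.  An
#' integer point lies below the original boundary iff it lies below the
#' step function these points span.
#'
#' @param curve a [threshold_curve()].
#' @return a tibble of points `(S, g)` sorted by `S`, of class
#'   `boundary_points`, carrying the curve as an attribute.  Empty, with
#'   a warning, when no `S` is feasible.
#' @export
prune_boundary <- function(curve) {
  feas <- which(!is.na(curve$g))
  if (!length(feas)) {
    warning("threshold is unattainable for every S; empty boundary")
    out <- tibble::tibble(S = integer(), g = integer())
    return(structure(out, class = c("boundary_points", class(out)),
                     curve = curve))
  }
  Sf <- curve$S[feas]; gf <- curve$g[feas]
  keep_max <- vapply(split(seq_along(Sf), gf),
                     function(ix) ix[which.max(Sf[ix])], 1L)
  keep <- sort(unique(c(1L, keep_max)))   # leftmost + max-S per level
  out <- tibble::tibble(S = Sf[keep], g = gf[keep])
  structure(out, class = c("boundary_points", class(out)), curve = curve)
}

# Classify a point against the pruned boundary's step function:
# level at S is the g of the first retained point with x >= S.
below_pruned <- function(R, S, T) {
  idx <- findInterval(S - 1, R$S) + 1   # first R$S >= S
  ifelse(S < min(R$S) | S > max(R$S), NA, T < R$g[pmin(idx, nrow(R))])
}

# ---- corridor line fitting -------------------------------------------------
# A run of points (x, y) admits a line l with y - w <= l(x) <= y for all
# points iff min_a h(a) <= 0, where h is convex piecewise linear:
#   h(a) = max_i(y_i - w - a x_i) - min_i(y_i - a x_i).
corridor_h <- function(a, x, y, w) {
  max(y - w - a * x) - min(y - a * x)
}

# minimise convex h by ternary search; returns list(a, h)
corridor_fit <- function(x, y, w) {
  if (length(x) == 1) return(list(a = 0, h = -w, b = y - w / 2))
  ch <- diff(y) / diff(x)
  lo <- min(ch) - 1; hi <- max(ch) + 1
  for (it in 1:90) {
    m1 <- lo + (hi - lo) / 3; m2 <- hi - (hi - lo) / 3
    if (corridor_h(m1, x, y, w) <= corridor_h(m2, x, y, w)) hi <- m2 else lo <- m1
  }
  a <- (lo + hi) / 2
  f1 <- max(y - w - a * x); f2 <- min(y - a * x)
  list(a = a, h = f1 - f2, b = (f1 + f2) / 2)
}

corridor_feasible <- function(x, y, w) corridor_fit(x, y, w)$h <= 1e-9

# greedy maximal-run partition; optimal segment count for partitions
# because feasibility is hereditary under taking sub-runs
greedy_runs <- function(x, y, w) {
  n <- length(x)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    # doubling then binary search for the largest feasible endpoint
    step <- 1L; j_ok <- i
    while (i + step <= n && corridor_feasible(x[i:(i + step)], y[i:(i + step)], w)) {
      j_ok <- i + step; step <- step * 2L
    }
    lo <- j_ok; hi <- min(n, i + step)
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      if (corridor_feasible(x[i:mid], y[i:mid], w)) lo <- mid else hi <- mid - 1L
    }
    starts <- c(starts, i); ends <- c(ends, lo)
    i <- lo + 1L
  }
  cbind(starts, ends)
}

# reconstruct the boundary level for every integer S in the domain
step_levels <- function(R, Smin, Smax) {
  S <- Smin:Smax
  idx <- findInterval(S - 1, R$S) + 1
  R$g[pmin(idx, nrow(R))]
}

#' Simplify a pruned boundary into few linear segments
#'
#' Fits a piecewise-linear function with the minimum number of segments
#' such that, at every integer `S` of the feasible domain, the segment
#' value lies in `(g(S) - 1, g(S)]` (a corridor of width `w = 1 -
#' delta` ending at the boundary point).  Consequently the integer
#' points with `T >= ghat(S)` are exactly those with `T >= g(S)`: the
#' simplified boundary separates the lattice exactly as the full one
#' does.  `delta` trades segment count against the numerical margin of
#' the separation.
#'
#' Internally the pruned points are augmented with each level's entry
#' point before fitting, and the fitted segments are verified against
#' every integer `S`; a per-level staircase is the (always exact)
#' fallback.
#'
#' @param R a [prune_boundary()] result (at least one point).
#' @param delta corridor margin in `(0, 1)`; default `0.001`.
#' @return an object of class `boundary_segments`: list with a
#'   `segments` tibble (`S_start`, `S_end`, `slope`, `intercept`), `k`,
#'   `delta`, `w`, the domain, and the per-integer boundary levels.
#' @export
simplify_boundary <- function(R, delta = 0.001) {
  stopifnot(delta > 0, delta < 1)
  if (!nrow(R)) stop("cannot simplify an empty boundary", call. = FALSE)
  w <- 1 - delta
  Smin <- min(R$S); Smax <- max(R$S)
  gS <- step_levels(R, Smin, Smax)
  # augment with level-entry points: the first S of each new level
  x <- R$S; y <- R$g
  if (nrow(R) > 1) {
    up <- which(diff(R$g) > 0)
    x <- c(x, R$S[up] + 1L); y <- c(y, R$g[up + 1L])
    o <- order(x); x <- x[o]; y <- y[o]
    dup <- duplicated(x); x <- x[!dup]; y <- y[!dup]
  }

  fit_once <- function(x, y) {
    runs <- greedy_runs(x, y, w)
    k <- nrow(runs)
    seg <- lapply(seq_len(k), function(r) {
      ix <- runs[r, 1]:runs[r, 2]
      f <- corridor_fit(x[ix], y[ix], w)
      tibble::tibble(
        S_start = if (r == 1) Smin else x[runs[r, 1]],
        S_end = if (r == k) Smax else x[runs[r + 1, 1]] - 1L,
        slope = f$a, intercept = f$b)
    })
    dplyr::bind_rows(seg)
  }

  verify <- function(segments) {
    S <- Smin:Smax
    idx <- findInterval(S, segments$S_start)
    lS <- segments$slope[idx] * S + segments$intercept[idx]
    ok <- lS <= gS + 1e-9 & lS > gS - 1 + 1e-9
    which(!ok)
  }

  segments <- fit_once(x, y)
  for (round in 1:5) {
    bad <- verify(segments)
    if (!length(bad)) break
    Sbad <- (Smin:Smax)[bad]
    x <- sort(unique(c(x, Sbad)))
    y <- gS[x - Smin + 1]
    segments <- fit_once(x, y)
  }
  if (length(verify(segments))) {
    # exact staircase: one horizontal segment per level
    lev_start <- c(Smin, (Smin:Smax)[which(diff(gS) > 0) + 1])
    lev_end <- c(lev_start[-1] - 1L, Smax)
    segments <- tibble::tibble(
      S_start = lev_start, S_end = lev_end, slope = 0,
      intercept = gS[lev_start - Smin + 1] - w / 2)
  }
  structure(list(segments = segments, k = nrow(segments), delta = delta,
                 w = w, S_min = Smin, S_max = Smax, gS = gS),
            class = "boundary_segments")
}

#' @export
print.boundary_segments <- function(x, ...) {
  cat(sprintf("<boundary_segments> k=%d segments over S in [%d, %d], delta=%g\n",
              x$k, x$S_min, x$S_max, x$delta))
  invisible(x)
}

# evaluate the simplified boundary at integer S (vectorised)
ghat_value <- function(bs, S) {
  idx <- findInterval(S, bs$segments$S_start)
  idx[idx < 1] <- 1
  bs$segments$slope[idx] * S + bs$segments$intercept[idx]
}

#' Emit the linear encoding of `T >= ghat(S)`
#'
#' Translates the simplified boundary into MILP variables and
#' constraints over existing integer variables `S` and `T`.  When the
#' max-of-lines upper envelope of the segments reproduces the boundary
#' levels exactly, the convex encoding (one constraint per segment, no
#' new variables) is used; otherwise one binary selector per segment
#' activates its segment's line and `S`-range through aggregated big-M
#' constraints, for `k` new variables and `k + 3` constraints.
#'
#' @param bs a [boundary_segments()] object.
#' @return a list of class `boundary_encoding` with `vars` (tibble:
#'   `name`, `lb`, `ub`, `integer`), `constraints` (list of
#'   `list(coefs =` named vector`, lo, hi)`), the `S` domain, and the
#'   encoding `mode`.
#' @export
encode_lower_bound <- function(bs) {
  if (is.null(bs$segments) || !nrow(bs$segments))
    stop("empty segment list: nothing to encode", call. = FALSE)
  seg <- bs$segments
  k <- nrow(seg)
  S_all <- bs$S_min:bs$S_max
  # try the convex (max-of-lines) encoding: exact iff the envelope still
  # separates every integer column correctly
  env <- apply(outer(seg$slope, S_all) + seg$intercept, 2, max)
  convex_ok <- all(env <= bs$gS + 1e-9 & env > bs$gS - 1 + 1e-9)
  if (convex_ok) {
    cons <- lapply(seq_len(k), function(r) list(
      coefs = c(T = 1, S = -seg$slope[r]), lo = seg$intercept[r], hi = Inf))
    out <- list(vars = tibble::tibble(name = character(), lb = numeric(),
                                      ub = numeric(), integer = logical()),
                constraints = cons, S_min = bs$S_min, S_max = bs$S_max,
                mode = "convex", n_vars = 0L, n_constraints = k)
    return(structure(out, class = "boundary_encoding"))
  }
  zn <- paste0("zseg", seq_len(k))
  vars <- tibble::tibble(name = zn, lb = 0, ub = 1, integer = TRUE)
  cons <- list()
  sel <- stats::setNames(rep(1, k), zn)
  cons[[1]] <- list(coefs = sel, lo = 1, hi = 1)
  cons[[2]] <- list(coefs = c(c(S = 1), stats::setNames(-seg$S_start, zn)),
                    lo = 0, hi = Inf)
  cons[[3]] <- list(coefs = c(c(S = 1), stats::setNames(-seg$S_end, zn)),
                    lo = -Inf, hi = 0)
  for (r in seq_len(k)) {
    bigM <- max(0, seg$slope[r] * bs$S_min + seg$intercept[r],
                seg$slope[r] * bs$S_max + seg$intercept[r])
    cons[[3 + r]] <- list(
      coefs = c(c(T = 1, S = -seg$slope[r]), stats::setNames(-bigM, zn[r])),
      lo = seg$intercept[r] - bigM, hi = Inf)
  }
  out <- list(vars = vars, constraints = cons, S_min = bs$S_min,
              S_max = bs$S_max, mode = "selector", n_vars = k,
              n_constraints = k + 3L)
  structure(out, class = "boundary_encoding")
}
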