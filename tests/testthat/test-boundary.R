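test_that("a vacuous threshold accepts every attainable table", {
  cv <- threshold_curve(nv = 6, M = 15, p0 = 1)
  expect_equal(cv$g, pmax(0L, (0:15) + 6L - 15L))
})

test_that("the level curve matches a direct tail computation at a spot check", {
  # M = 20, nv = 5, S = 4: P(X >= 3) passes 0.05, P(X >= 2) does not
  p3 <- brute_fisher_p(3, 4, 5, 20)
  p2 <- brute_fisher_p(2, 4, 5, 20)
  expect_lt(p3, 0.05)
  expect_gt(p2, 0.05)
  cv <- threshold_curve(nv = 5, M = 20, p0 = 0.05)
  expect_equal(cv$g[cv$S == 4], 3L)
})

test_that("binary search reproduces the linear-scan curve oracle", {
  set.seed(30)
  for (i in 1:12) {
    M <- sample(5:40, 1)
    nv <- sample(1:(M - 1), 1)
    p0 <- 10^runif(1, -4, -0.1)
    cv <- threshold_curve(nv, M, p0)
    expect_identical(cv$g, brute_curve(nv, M, p0))
  }
})

test_that("a threshold on a non-monotone statistic is rejected", {
  expect_error(threshold_curve(5, 20, 0.05, stat = "chi2"), "not monotone")
})

test_that("pruning keeps the leftmost point plus the level maxima", {
  const <- structure(list(S = 0:10, g = c(NA, rep(2L, 6), rep(NA, 4)),
                          nv = 5, M = 10, p0 = 0.5, stat = "fisher_p",
                          direction = "over"), class = "threshold_curve")
  R <- prune_boundary(const)
  expect_equal(nrow(R), 2L)               # leftmost + rightmost
  expect_equal(R$S, c(1L, 6L))

  step3 <- structure(list(S = 0:9,
                          g = c(NA, 1L, 1L, 2L, 2L, 2L, 3L, 3L, NA, NA),
                          nv = 5, M = 9, p0 = 0.5, stat = "fisher_p",
                          direction = "over"), class = "threshold_curve")
  R3 <- prune_boundary(step3)
  expect_equal(R3$S, c(1L, 2L, 5L, 7L))   # leftmost + 3 level maxima
  expect_equal(R3$g, c(1L, 1L, 2L, 3L))
})

test_that("a fully infeasible curve prunes to an empty set with a warning", {
  cv <- threshold_curve(nv = 3, M = 10, p0 = 1e-12)
  expect_warning(R <- prune_boundary(cv), "unattainable|empty")
  expect_equal(nrow(R), 0L)
})

test_that("below-boundary classification is preserved by pruning", {
  set.seed(31)
  for (i in 1:10) {
    M <- sample(10:50, 1)
    nv <- sample(2:(M - 1), 1)
    p0 <- 10^runif(1, -4, -0.5)
    cv <- threshold_curve(nv, M, p0)
    if (all(is.na(cv$g))) next
    R <- prune_boundary(cv)
    for (S in cv$S[!is.na(cv$g)]) {
      g <- cv$g[S + 1]
      for (T in max(0, S + nv - M):min(S, nv)) {
        expect_identical(unname(cnfgwas:::below_pruned(R, S, T)), T < g)
      }
    }
  }
})

test_that("collinear points simplify to a single segment", {
  R <- structure(tibble::tibble(S = 0:4, g = 0:4),
                 class = c("boundary_points", "tbl_df", "tbl", "data.frame"))
  bs <- simplify_boundary(R)
  expect_equal(bs$k, 1L)
})

test_that("segment counts match the dynamic-programming corridor oracle", {
  w <- 1 - 0.001
  pts <- list(
    list(x = c(0, 1, 2, 3), y = c(0, 0, 1, 1)),
    list(x = c(0, 2, 5, 6, 9), y = c(1, 2, 3, 5, 6)),
    list(x = c(0, 1, 3, 4, 8, 9), y = c(0, 2, 3, 3, 4, 8))
  )
  for (p in pts) {
    R <- structure(tibble::tibble(S = as.integer(p$x), g = as.integer(p$y)),
                   class = c("boundary_points", "tbl_df", "tbl", "data.frame"))
    bs <- simplify_boundary(R, delta = 0.001)
    expect_equal(bs$k, oracle_min_segments(p$x, p$y, w))
  }
})

test_that("narrowing delta widens the corridor and never adds segments", {
  cv <- threshold_curve(nv = 12, M = 60, p0 = 0.01)
  R <- prune_boundary(cv)
  ks <- vapply(c(0.5, 0.1, 0.001), function(d)
    simplify_boundary(R, delta = d)$k, 0L)
  expect_true(all(diff(ks) <= 0))
})

test_that("a single identity segment encodes the half-plane T >= S", {
  bs <- structure(list(
    segments = tibble::tibble(S_start = 0L, S_end = 20L, slope = 1,
                              intercept = 0),
    k = 1L, delta = 0.001, w = 0.999, S_min = 0L, S_max = 20L, gS = 0:20),
    class = "boundary_segments")
  enc <- encode_lower_bound(bs)
  expect_identical(enc$mode, "convex")
  for (S in 0:20) for (T in 0:20)
    expect_identical(fragment_feasible(enc, S, T), T >= S)
})

test_that("encoded fragments reproduce the exact integer feasible set", {
  # real curves exercise both the convex and the selector encodings
  set.seed(32)
  modes <- character(0)
  solver_checked <- 0
  for (i in 1:10) {
    M <- sample(20:60, 1)
    nv <- sample(3:(M - 2), 1)
    p0 <- 10^runif(1, -5, -1)
    cv <- threshold_curve(nv, M, p0)
    if (all(is.na(cv$g))) next
    R <- prune_boundary(cv)
    bs <- simplify_boundary(R)
    enc <- encode_lower_bound(bs)
    modes <- c(modes, enc$mode)
    expect_lte(enc$n_vars, 2 * bs$k)
    expect_lte(enc$n_constraints, bs$k + 3)
    for (S in 0:M) {
      attain_T <- max(0, S + nv - M):min(S, nv)
      g <- cv$g[S + 1]
      for (T in attain_T) {
        want <- !is.na(g) && T >= g
        expect_identical(fragment_feasible(enc, S, T), want)
      }
    }
    # spot-check the brute-force fragment checker against a real solve
    if (solver_checked < 2 && !all(is.na(cv$g))) {
      solver_checked <- solver_checked + 1
      Sq <- which(!is.na(cv$g))[1] - 1L
      gq <- cv$g[Sq + 1]
      for (Tq in unique(c(gq, max(0, gq - 1)))) {
        f <- list(
          A = local({
            nm <- c("S", "T", enc$vars$name)
            rows <- lapply(enc$constraints, function(cc) {
              r <- setNames(numeric(length(nm)), nm)
              r[names(cc$coefs)] <- cc$coefs
              r
            })
            Matrix::Matrix(do.call(rbind, rows), sparse = TRUE)
          }),
          lo = vapply(enc$constraints, `[[`, 0, "lo"),
          hi = vapply(enc$constraints, `[[`, 0, "hi"),
          vars = tibble::tibble(
            name = c("S", "T", enc$vars$name),
            lb = c(Sq, Tq, enc$vars$lb), ub = c(Sq, Tq, enc$vars$ub),
            integer = TRUE, obj = 0),
          maximize = TRUE)
        sol <- solve_milp(f)
        expect_identical(sol$status == "optimal",
                         fragment_feasible(enc, Sq, Tq))
      }
    }
  }
  expect_true(length(modes) > 0)
})
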