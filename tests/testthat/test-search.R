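test_that("a noiseless planted CNF pseudo-SNP passes triage", {
  inst <- planted_instance(M = 150, P = 5, K = 2, L = 2, seed = 50)
  tri <- triage(inst$X, inst$Y, K = 2, L = 2, p0 = 0.05 / 50)
  expect_identical(tri$status[tri$snp_id == inst$pseudo_id], "pass")
})

test_that("an unattainably small bound empties the triage pass list", {
  set.seed(51)
  inst <- rand_instance(M = 30, P = 4, N = 3)
  tri <- triage(inst$X, inst$Y, K = 2, L = 2, p0 = 1e-30)
  expect_true(all(tri$status == "fail"))
})

test_that("triage pass/fail agrees with the enumeration oracle", {
  set.seed(52)
  for (i in 1:5) {
    inst <- rand_instance(M = sample(20:35, 1), P = 4, N = 2)
    tri <- triage(inst$X, inst$Y, K = 2, L = 2, p0 = 0.1)
    for (r in seq_len(nrow(tri))) {
      orc <- enumerate_cnf_oracle(unclass(inst$X)[, tri$snp_id[r]],
                                  inst$Y, 2, 2)
      expect_identical(tri$status[r],
                       if (orc$value <= 0.1) "pass" else "fail")
    }
  }
})

test_that("a variant equal to one phenotype column is perfectly recovered", {
  set.seed(53)
  Y <- rand_bm(40, 4)
  X <- binary_matrix(matrix(unclass(Y)[, 2], ncol = 1,
                            dimnames = list(rownames(Y), "v")),
                     kind = "genotype")
  cd <- collapse_subjects(X, Y)
  fit <- optimize_variant(cd, "v", K = 2, L = 2)
  k <- sum(unclass(Y)[, 2])
  expect_equal(fit$p, compute_stat("fisher_p",
    contingency_summary(nu = k, nv = k, nuv = k, M = 40)))
  expect_identical(evaluate_cnf(fit$cnf, Y), unname(unclass(Y)[, 2]))
})

test_that("iterative optimisation attains the oracle minimum p", {
  set.seed(54)
  for (i in 1:5) {
    inst <- rand_instance(M = sample(20:40, 1), P = 4)
    cd <- collapse_subjects(inst$X, inst$Y)
    fit <- optimize_variant(cd, 1, K = 2, L = 2)
    orc <- enumerate_cnf_oracle(unclass(inst$X)[, 1], inst$Y, 2, 2)
    expect_identical(fit$status, "optimized")
    expect_equal(fit$p, orc$value, tolerance = 1e-12)
  }
})

test_that("the optimum is invariant to the probe schedule", {
  set.seed(55)
  inst <- rand_instance(M = 35, P = 4)
  cd <- collapse_subjects(inst$X, inst$Y)
  f2 <- optimize_variant(cd, 1, 2, 2, doubling_base = 2)
  f4 <- optimize_variant(cd, 1, 2, 2, doubling_base = 4)
  orc <- enumerate_cnf_oracle(unclass(inst$X)[, 1], inst$Y, 2, 2)
  expect_equal(f2$p, orc$value, tolerance = 1e-12)
  expect_equal(f4$p, orc$value, tolerance = 1e-12)
})

test_that("negated variants equal plain runs on the complement", {
  set.seed(56)
  inst <- rand_instance(M = 30, P = 4)
  cd <- collapse_subjects(inst$X, inst$Y)
  fit_neg <- optimize_variant(cd, 1, 2, 2, negate = TRUE)
  Xc <- binary_matrix(1L - unclass(inst$X), kind = "genotype")
  cdc <- collapse_subjects(Xc, inst$Y)
  fit_plain <- optimize_variant(cdc, 1, 2, 2)
  expect_equal(fit_neg$p, fit_plain$p, tolerance = 1e-12)
  expect_equal(fit_neg$S, fit_plain$S)
  expect_equal(fit_neg$T, fit_plain$T)
  expect_equal(fit_neg$nv, fit_plain$nv)
})

test_that("tidiers expose the fitted CNF as tables", {
  set.seed(57)
  inst <- rand_instance(M = 25, P = 4)
  fit <- optimize_variant(collapse_subjects(inst$X, inst$Y), 1, 2, 2)
  td <- tidy(fit)
  expect_true(all(c("clause", "phenotype") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_identical(gl$cnf, format_cnf(fit$cnf))
})

test_that("a strong planted signal survives the two-stage design", {
  inst <- planted_instance(M = 300, P = 5, K = 2, L = 2, seed = 58)
  res <- two_stage(inst$X, inst$Y, 2, 2, p0 = 0.001, split_seed = 9)
  expect_identical(res$status[res$snp_id == inst$pseudo_id], "validated")
})

test_that("pure-noise inputs validate (almost) nothing", {
  validated <- 0
  for (seed in 1:5) {
    set.seed(seed + 590)
    inst <- rand_instance(M = 80, P = 4, N = 3)
    res <- two_stage(inst$X, inst$Y, 2, 2, p0 = 0.001, split_seed = seed)
    validated <- validated + sum(res$status == "validated")
  }
  expect_lte(validated, 1)
})

test_that("the split and all downstream results are seed-reproducible", {
  inst <- planted_instance(M = 120, P = 4, K = 2, L = 2, seed = 60)
  a <- two_stage(inst$X, inst$Y, 2, 2, p0 = 0.01, split_seed = 4)
  b <- two_stage(inst$X, inst$Y, 2, 2, p0 = 0.01, split_seed = 4)
  expect_identical(a, b)
  h1 <- cnfgwas:::split_cohort(121, 17)
  h2 <- cnfgwas:::split_cohort(121, 17)
  expect_identical(h1, h2)
  expect_equal(length(h1$discovery), 60)     # odd subject joins validation
  expect_equal(length(h1$validation), 61)
})

test_that("with K = L = 1 the CNF search and the GWAS baseline coincide", {
  inst <- planted_instance(M = 200, P = 4, K = 1, L = 1, seed = 61)
  ts <- two_stage(inst$X, inst$Y, 1, 1, p0 = 0.01, split_seed = 3,
                  cmh = FALSE)
  gb <- gwas_baseline(inst$X, inst$Y, p0 = 0.01, split_seed = 3)
  expect_identical(ts$snp_id, gb$snp_id)
  done <- ts$status != "failed"
  expect_identical(ts$status[done], gb$status[done])
  expect_equal(ts$p_discovery[done],
               gb$p_discovery[done], tolerance = 1e-12)
  expect_equal(ts$p_validation[done], gb$p_validation[done],
               tolerance = 1e-12)
  expect_identical(ts$status == "validated", gb$status == "validated")
})

test_that("the baseline scan matches a brute-force single-phenotype scan", {
  set.seed(62)
  inst <- planted_instance(M = 150, P = 5, K = 1, L = 1, seed = 62)
  gb <- gwas_baseline(inst$X, inst$Y, p0 = 0.05, split_seed = 8)
  halves <- cnfgwas:::split_cohort(150, 8)
  Xd <- unclass(inst$X)[halves$discovery, , drop = FALSE]
  Yd <- unclass(inst$Y)[halves$discovery, , drop = FALSE]
  for (r in seq_len(nrow(gb))) {
    ps <- vapply(seq_len(ncol(Yd)), function(j)
      compute_stat("fisher_p", summarize_pair(Yd[, j], Xd[, gb$snp_id[r]])), 0)
    expect_equal(gb$p_discovery[r], min(ps), tolerance = 1e-12)
    expect_identical(gb$phenotype[r], colnames(inst$Y)[which.min(ps)])
  }
  # the planted single-phenotype signal is recovered
  expect_identical(gb$status[gb$snp_id == inst$pseudo_id], "validated")
})

test_that("validation p-values are recomputable from the stored CNF alone", {
  inst <- planted_instance(M = 200, P = 5, K = 2, L = 2, eps = 0.05,
                           seed = 63)
  res <- two_stage(inst$X, inst$Y, 2, 2, p0 = 0.01, split_seed = 5)
  halves <- cnfgwas:::split_cohort(200, 5)
  Yv <- unclass(inst$Y)[halves$validation, , drop = FALSE]
  Xv <- unclass(inst$X)[halves$validation, , drop = FALSE]
  for (r in which(!is.na(res$p_validation))) {
    cnf <- parse_cnf(res$cnf[r], colnames(inst$Y))
    p <- compute_stat("fisher_p",
                      summarize_pair(evaluate_cnf(cnf, Yv),
                                     Xv[, res$snp_id[r]]))
    expect_equal(res$p_validation[r], p, tolerance = 1e-12)
  }
})

test_that("results export to the documented TSV layout", {
  inst <- planted_instance(M = 100, P = 4, K = 1, L = 2, seed = 64)
  res <- two_stage(inst$X, inst$Y, 1, 2, p0 = 0.05, split_seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_true(all(c("snp_id", "negated", "cnf", "S", "T", "nv",
                    "p_discovery", "p_validation", "cmh_p", "status")
                  %in% names(back)))
  expect_equal(nrow(back), nrow(res))
})
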