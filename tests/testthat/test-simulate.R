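test_that("the study grid enumerates exactly 81 distinct settings", {
  g <- simulation_grid()
  expect_equal(nrow(g), 81L)
  expect_equal(nrow(dplyr::distinct(g)), 81L)
  expect_setequal(unique(g$K), 1:3)
  expect_setequal(unique(g$M), c(2000, 20000, 200000))
  expect_setequal(unique(g$eps), c(0, 0.1, 0.2))
})

test_that("a noiseless pseudo-SNP equals the planted CNF evaluation", {
  ds <- generate_dataset(simulation_spec(K = 2, L = 2, M = 400, eps = 0,
                                         P = 6, n_snps = 8, seed = 70))
  pseudo <- unclass(ds$X)[, ds$truth$pseudo_id]
  expect_identical(unname(pseudo),
                   evaluate_cnf(ds$truth$cnf, ds$Y))
  expect_length(ds$truth$flipped, 0L)
})

test_that("noise flips exactly round(eps * M) entries", {
  ds <- generate_dataset(simulation_spec(K = 2, L = 2, M = 500, eps = 0.1,
                                         P = 6, n_snps = 6, seed = 71))
  pseudo <- unclass(ds$X)[, ds$truth$pseudo_id]
  clean <- evaluate_cnf(ds$truth$cnf, ds$Y)
  expect_equal(sum(pseudo != clean), round(0.1 * 500))
  expect_equal(sum(pseudo != clean), length(ds$truth$flipped))
  expect_identical(unname(which(pseudo != clean)), ds$truth$flipped)
})

test_that("identical seeds give bit-identical datasets", {
  s <- simulation_spec(K = 3, L = 2, M = 300, eps = 0.2, P = 7,
                       n_snps = 10, seed = 72)
  a <- generate_dataset(s)
  b <- generate_dataset(s)
  expect_identical(unclass(a$X)[, ], unclass(b$X)[, ])
  expect_identical(unclass(a$Y)[, ], unclass(b$Y)[, ])
  expect_identical(a$truth$cnf$clauses, b$truth$cnf$clauses)
  expect_identical(a$truth$pseudo_id, b$truth$pseudo_id)
})

test_that("decoys are frequency-matched to the pseudo-SNP", {
  ds <- generate_dataset(simulation_spec(K = 1, L = 2, M = 5000, eps = 0,
                                         P = 8, n_snps = 20, seed = 73))
  f <- mean(unclass(ds$X)[, ds$truth$pseudo_id])
  decoys <- setdiff(colnames(ds$X), ds$truth$pseudo_id)
  fd <- colMeans(unclass(ds$X)[, decoys])
  # generating frequencies lie in f*(1 +/- 0.2); allow sampling noise
  slack <- 4 * sqrt(f * (1 - f) / 5000)
  expect_true(all(fd >= f * 0.8 - slack & fd <= f * 1.2 + slack))
})

test_that("a constant planted phenotype is reported after redraws fail", {
  expect_error(
    generate_dataset(simulation_spec(K = 1, L = 1, M = 50, eps = 0, P = 3,
                                     n_snps = 4,
                                     pheno_prevalences = rep(0, 3),
                                     seed = 74)),
    "constant")
})

test_that("outcome classification matches hand-counted labels", {
  results <- tibble::tibble(
    snp_id = c("snp1", "snp2", "snp3", "snp4"),
    status = c("validated", "discovered", "failed", "validated"))
  out <- classify_outcomes(results, pseudo_id = "snp2")
  expect_identical(out$outcome,
                   c("false_positive_validated", "true_positive_discovery",
                     "true_negative", "false_positive_validated"))
  expect_identical(out$is_pseudo, c(FALSE, TRUE, FALSE, FALSE))
  out2 <- classify_outcomes(results, pseudo_id = "snp3")
  expect_identical(out2$outcome[3], "false_negative")
})

test_that("the summariser reproduces degenerate and printed arithmetic", {
  # all-success fixture: every pseudo validated, no decoy discovered
  allwin <- tidyr::expand_grid(trial = 1:4, snp_id = paste0("snp", 1:5)) |>
    dplyr::mutate(method = "cnf",
                  is_pseudo = snp_id == "snp1",
                  discovered = is_pseudo,
                  validated = is_pseudo)
  sm <- summarize_grid(allwin)
  expect_equal(sm$tpr_two_stage, 1)
  expect_equal(sm$fp_discovery_rate, 0)
  expect_equal(sm$fnr, 0)

  # 2 validated decoys out of 39690 decoy tests
  fp <- tibble::tibble(method = "cnf",
                       is_pseudo = c(rep(FALSE, 39690), rep(TRUE, 810)),
                       discovered = c(rep(TRUE, 2), rep(FALSE, 39688),
                                      rep(TRUE, 659), rep(FALSE, 151)),
                       validated = c(rep(TRUE, 2), rep(FALSE, 39688),
                                     rep(TRUE, 568), rep(FALSE, 242)))
  sm2 <- summarize_grid(fp)
  expect_equal(sm2$fp_validated_rate, 2 / 39690)
  expect_equal(sm2$tpr_two_stage, 568 / 810)
  expect_gt(sm2$tpr_two_stage, 0.70)
  expect_equal(sm2$fnr, 151 / 810)
  expect_equal(sm2$validation_pass, 568 / 659)
})

test_that("trial seeds are a reproducible counter below the integer cap", {
  s1 <- trial_seed(1, 3, 2)
  expect_identical(s1, trial_seed(1, 3, 2))
  expect_true(s1 < .Machine$integer.max)
  seeds <- c(outer(1:5, 1:10, function(s, t) trial_seed(7, s, t)))
  expect_equal(anyDuplicated(seeds), 0L)
})

test_that("a tiny grid run returns classified outcomes for both methods", {
  out <- run_grid(trials_per_setting = 1,
                  settings = tibble::tibble(K = 1, L = 1, M = 300, eps = 0),
                  n_snps = 5, P = 4, seed = 75)
  expect_s3_class(out, "sim_outcomes")
  expect_setequal(unique(out$method), c("cnf", "gwas"))
  expect_equal(nrow(out), 2 * 5)
  # a noiseless single-phenotype signal is discovered with high probability
  expect_true(all(out$discovered[out$is_pseudo]))
  expect_length(attr(out, "errors"), 0)
})

test_that("plots build from outcomes and boundaries", {
  out <- run_grid(trials_per_setting = 1,
                  settings = tibble::tibble(K = 1, L = 1, M = 200, eps = 0),
                  n_snps = 4, P = 3, seed = 76)
  p <- autoplot(out)
  expect_s3_class(p, "ggplot")
  cv <- threshold_curve(nv = 10, M = 40, p0 = 0.05)
  bp <- plot_boundary(cv, simplify_boundary(prune_boundary(cv)))
  expect_s3_class(bp, "ggplot")
})

test_that("detection degrades with noise and improves with cohort size", {
  # reduced-scale monotonicity: 12 trials per cell of a (1,2) planted
  # shape, small line-up; discovery TPR averaged over trials
  eps_arm <- run_grid(trials_per_setting = 12,
                      settings = tidyr::expand_grid(K = 1, L = 2, M = 400,
                                                    eps = c(0.1, 0.45)),
                      n_snps = 6, P = 5, methods = "cnf", seed = 99)
  sme <- summarize_grid(eps_arm, by = "eps") |> dplyr::arrange(eps)
  expect_gte(sme$tpr_discovery[1], sme$tpr_discovery[2])
  expect_gt(sme$tpr_discovery[1] - sme$tpr_discovery[2], 0.2)

  m_arm <- run_grid(trials_per_setting = 12,
                    settings = tidyr::expand_grid(K = 1, L = 2,
                                                  M = c(100, 1000),
                                                  eps = 0.35),
                    n_snps = 6, P = 5, methods = "cnf", seed = 100)
  smm <- summarize_grid(m_arm, by = "M") |> dplyr::arrange(M)
  expect_gte(smm$tpr_discovery[2], smm$tpr_discovery[1])
  expect_gt(smm$tpr_discovery[2] - smm$tpr_discovery[1], 0.2)
})
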