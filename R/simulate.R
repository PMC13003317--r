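# Simulation study: planted-CNF pseudo-SNPs in a line-up of
# frequency-matched decoys.  A dataset carries P independent binary
# phenotypes at disease-code-like prevalences, a CNF combined phenotype
# planted at random, and a pseudo-SNP equal to that CNF's evaluation
# with a fraction eps of entries logically negated (adversarial noise:
# presence replaced by absence or vice versa).  Decoy SNPs are
# independent Bernoulli draws frequency-matched to the pseudo-SNP, so
# any decoy reaching significance is a false positive.

#' Specify one simulation setting
#'
#' @param K,L planted CNF shape (grid values 1-3).
#' @param M subject count (grid values 2000, 20000, 200000).
#' @param eps fraction of pseudo-SNP entries flipped (grid values 0,
#'   0.1, 0.2).
#' @param P phenotype count (default 11).
#' @param n_snps line-up size including the pseudo-SNP (default 50).
#' @param pheno_prevalences per-phenotype Bernoulli rates; `NULL` draws
#'   them once per dataset, uniformly in `[0.01, 0.2]`.
#' @param freq_band decoy frequencies are drawn uniformly within
#'   `pseudo-frequency * (1 +/- freq_band)`.
#' @param seed dataset seed.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(K = 2, L = 2, M = 2000, eps = 0.1, P = 11,
                            n_snps = 50, pheno_prevalences = NULL,
                            freq_band = 0.2, seed = 1L) {
  stopifnot(K >= 1, L >= 1, M >= 2, eps >= 0, eps < 1, P >= L,
            n_snps >= 1)
  structure(list(K = K, L = L, M = M, eps = eps, P = P, n_snps = n_snps,
                 pheno_prevalences = pheno_prevalences,
                 freq_band = freq_band, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate one simulated dataset
#'
#' Phenotypes are sampled independently at the requested prevalences; the
#' planted CNF is drawn uniformly over (K, L) structures with distinct
#' in-clause phenotypes and redrawn (at most 100 times) if its
#' evaluation is constant; the pseudo-SNP is the CNF evaluation with
#' exactly `round(eps * M)` uniformly chosen entries flipped; decoys
#' are i.i.d. Bernoulli at frequencies matched to the pseudo-SNP; SNP
#' column positions are shuffled.  Bit-identical reproducible from the
#' seed.
#'
#' @param spec a [simulation_spec()].
#' @return a list of class `simulation_dataset` with `X`, `Y`
#'   ([binary_matrix()] objects) and `truth` (planted `cnf`,
#'   `pseudo_id`, `flipped` index set, `prevalences`, `spec`).
#' @export
generate_dataset <- function(spec) {
  withr::with_seed(spec$seed, {
    P <- spec$P; M <- spec$M
    prev <- spec$pheno_prevalences %||% stats::runif(P, 0.01, 0.2)
    stopifnot(length(prev) == P)
    Y <- matrix(stats::rbinom(M * P, 1L, rep(prev, each = M)), M, P)
    colnames(Y) <- paste0("phe", seq_len(P))
    cnf <- NULL
    for (attempt in 1:100) {
      cand <- cnf_phenotype(replicate(spec$K,
        sort(sample.int(P, spec$L)), simplify = FALSE))
      ev <- evaluate_cnf(cand, Y)
      if (stats::var(ev) > 0) { cnf <- cand; break }
    }
    if (is.null(cnf))
      stop("planted CNF evaluated to a constant in 100 redraws; ",
           "prevalences leave no variation", call. = FALSE)
    pseudo <- ev
    n_flip <- round(spec$eps * M)
    flipped <- if (n_flip > 0) sort(sample.int(M, n_flip)) else integer(0)
    pseudo[flipped] <- 1L - pseudo[flipped]
    freq <- mean(pseudo)
    if (freq %in% c(0, 1))
      stop("pseudo-SNP is constant after flipping; increase M or adjust eps",
           call. = FALSE)
    n_decoy <- spec$n_snps - 1L
    decoy_freq <- pmin(pmax(stats::runif(n_decoy, freq * (1 - spec$freq_band),
                                         freq * (1 + spec$freq_band)),
                            1 / M), 1 - 1 / M)
    decoys <- matrix(stats::rbinom(M * n_decoy, 1L,
                                   rep(decoy_freq, each = M)), M, n_decoy)
    pos <- sample.int(spec$n_snps)
    X <- matrix(0L, M, spec$n_snps)
    X[, pos[1]] <- pseudo
    if (n_decoy > 0) X[, pos[-1]] <- decoys
    colnames(X) <- paste0("snp", seq_len(spec$n_snps))
    ids <- paste0("S", seq_len(M))
    rownames(X) <- ids; rownames(Y) <- ids
    structure(list(
      X = binary_matrix(X, kind = "genotype"),
      Y = binary_matrix(Y, kind = "phenotype"),
      truth = list(cnf = cnf, pseudo_id = paste0("snp", pos[1]),
                   flipped = flipped, prevalences = prev, spec = spec)
    ), class = "simulation_dataset")
  })
}

#' @export
print.simulation_dataset <- function(x, ...) {
  s <- x$truth$spec
  cat(sprintf(
    "<simulation_dataset> M=%d, P=%d, %d SNPs; planted (K=%d, L=%d) CNF %s as %s (eps=%g)\n",
    s$M, s$P, s$n_snps, s$K, s$L, format_cnf(x$truth$cnf), x$truth$pseudo_id,
    s$eps))
  invisible(x)
}

#' The full simulation parameter grid
#'
#' Crosses K, L in 1-3, M in {2000, 20000, 200000} and eps in
#' {0, 0.1, 0.2}: 81 settings.
#'
#' @param K,L,M,eps value sets to cross.
#' @return a tibble with one row per setting.
#' @export
simulation_grid <- function(K = 1:3, L = 1:3, M = c(2000, 20000, 200000),
                            eps = c(0, 0.1, 0.2)) {
  tidyr::expand_grid(K = K, L = L, M = M, eps = eps)
}

#' Classify per-SNP outcomes of one trial
#'
#' The pseudo-SNP passing discovery is a true positive (and a validated
#' true positive if it also passes validation); the pseudo-SNP failing
#' discovery is a false negative; any decoy passing a stage is a false
#' positive for that stage.
#'
#' @param results tibble with `snp_id` and `status` columns (from
#'   [two_stage()] or [gwas_baseline()]).
#' @param pseudo_id the planted variant's column name.
#' @return `results` with logical columns `is_pseudo`, `discovered`,
#'   `validated` and a label column `outcome`.
#' @export
classify_outcomes <- function(results, pseudo_id) {
  results |>
    dplyr::mutate(
      is_pseudo = .data$snp_id == pseudo_id,
      discovered = .data$status %in% c("discovered", "validated"),
      validated = .data$status == "validated",
      outcome = dplyr::case_when(
        is_pseudo & validated ~ "true_positive_validated",
        is_pseudo & discovered ~ "true_positive_discovery",
        is_pseudo ~ "false_negative",
        validated ~ "false_positive_validated",
        discovered ~ "false_positive_discovery",
        TRUE ~ "true_negative"))
}

#' Run the simulation grid
#'
#' For every setting and trial: generate a dataset, run the two-stage
#' CNF search and/or the single-phenotype GWAS baseline on a shared
#' discovery/validation split at `p0 = 0.05 / n_snps` (Bonferroni over
#' the line-up), and classify every SNP.  Per-trial failures are
#' recorded and never abort the grid.
#'
#' @param trials_per_setting independent trials per setting.
#' @param methods subset of `c("cnf", "gwas")`.
#' @param settings a tibble of (K, L, M, eps) rows, see
#'   [simulation_grid()].
#' @param n_snps,P line-up size and phenotype count per dataset.
#' @param p0 significance threshold for both stages.
#' @param seed master seed; per-trial seeds are derived by a counter so
#'   any single trial is re-runnable in isolation via
#'   [trial_seed()].
#' @param negate also test variant complements.
#' @param backend,time_limit,delta solver and boundary controls.
#' @param exact prove the discovered p-value optimal per variant;
#'   outcome classification compares p against `p0` only, so the
#'   default `FALSE` trades that proof for speed without changing
#'   pass/fail labels.
#' @param tol_ratio p-bracket ratio ending each variant's binary
#'   search, see [optimize_variant()].
#' @param out_dir if non-NULL, write one TSV per setting, an aggregate
#'   TSV and a plain-text config there.
#' @param verbose print per-trial progress.
#' @return a tibble of class `sim_outcomes`: one row per (setting,
#'   trial, method, SNP) with classification columns; trial errors are
#'   attached as attribute `"errors"`.
#' @export
run_grid <- function(trials_per_setting = 10, methods = c("cnf", "gwas"),
                     settings = simulation_grid(), n_snps = 50, P = 11,
                     p0 = 0.05 / n_snps, seed = 1L, negate = FALSE,
                     backend = "highs", time_limit = Inf, delta = 0.001,
                     exact = FALSE, tol_ratio = 1.05, out_dir = NULL,
                     verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(trials_per_setting >= 1)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  errors <- list()
  out <- list()
  for (s in seq_len(nrow(settings))) {
    set <- settings[s, ]
    setting_rows <- list()
    for (tr in seq_len(trials_per_setting)) {
      tseed <- trial_seed(seed, s, tr)
      res <- tryCatch({
        spec <- simulation_spec(K = set$K, L = set$L, M = set$M,
                                eps = set$eps, P = P, n_snps = n_snps,
                                seed = tseed)
        ds <- generate_dataset(spec)
        rows <- list()
        if ("cnf" %in% methods) {
          ts <- two_stage(ds$X, ds$Y, K = set$K, L = set$L, p0 = p0,
                          split_seed = tseed, negate = negate,
                          backend = backend, time_limit = time_limit,
                          delta = delta, cmh = FALSE, exact = exact,
                          tol_ratio = tol_ratio)
          rows$cnf <- classify_outcomes(ts, ds$truth$pseudo_id) |>
            dplyr::mutate(method = "cnf", .before = 1)
        }
        if ("gwas" %in% methods) {
          gb <- gwas_baseline(ds$X, ds$Y, p0 = p0, split_seed = tseed,
                              negate = negate)
          rows$gwas <- classify_outcomes(gb, ds$truth$pseudo_id) |>
            dplyr::mutate(method = "gwas", .before = 1)
        }
        dplyr::bind_rows(rows) |>
          dplyr::mutate(K = set$K, L = set$L, M = set$M, eps = set$eps,
                        trial = tr, .before = 1) |>
          dplyr::select(dplyr::all_of(c(
            "K", "L", "M", "eps", "trial", "method", "snp_id",
            "is_pseudo", "discovered", "validated", "outcome")))
      }, error = function(e) {
        errors[[length(errors) + 1]] <<- list(
          setting = s, trial = tr, message = conditionMessage(e))
        NULL
      })
      if (verbose)
        message(sprintf("setting %d/%d (K=%d L=%d M=%d eps=%g) trial %d: %s",
                        s, nrow(settings), set$K, set$L, set$M, set$eps, tr,
                        if (is.null(res)) "ERROR" else "ok"))
      if (!is.null(res)) setting_rows[[tr]] <- res
    }
    sr <- dplyr::bind_rows(setting_rows)
    if (!is.null(out_dir) && nrow(sr))
      readr::write_tsv(sr, file.path(out_dir, sprintf(
        "outcomes_K%d_L%d_M%d_eps%g.tsv", set$K, set$L, set$M, set$eps)),
        progress = FALSE)
    out[[s]] <- sr
  }
  outcomes <- dplyr::bind_rows(out)
  if (!is.null(out_dir)) {
    readr::write_tsv(outcomes, file.path(out_dir, "outcomes_all.tsv"),
                     progress = FALSE)
    writeLines(c(
      sprintf("trials_per_setting=%d", trials_per_setting),
      sprintf("methods=%s", paste(methods, collapse = ",")),
      sprintf("n_snps=%d", n_snps), sprintf("P=%d", P),
      sprintf("p0=%g", p0), sprintf("seed=%d", seed),
      sprintf("negate=%s", negate), sprintf("delta=%g", delta)),
      file.path(out_dir, "config.txt"))
  }
  structure(outcomes, class = c("sim_outcomes", class(outcomes)),
            errors = errors)
}

#' Per-trial seed derivation
#'
#' Seeds are a deterministic counter over (setting index, trial index)
#' offset by the master seed, so any trial can be reproduced alone.
#'
#' @param seed master seed.
#' @param setting_index,trial 1-based indices.
#' @return an integer seed.
#' @export
trial_seed <- function(seed, setting_index, trial) {
  as.integer((seed + 7919L * (setting_index - 1L) + trial) %% .Machine$integer.max)
}

#' Summarise simulation outcomes into rates
#'
#' Aggregates true-positive, false-negative and false-positive rates by
#' method, overall or per facet.
#'
#' @param outcomes a [run_grid()] result.
#' @param by optional character vector of facet columns (subset of
#'   `c("K", "L", "M", "eps")`).
#' @return a tibble with, per group and method: `n_trials`,
#'   `tpr_discovery` (pseudo-SNPs passing discovery), `tpr_two_stage`
#'   (passing both stages), `fnr` (pseudo-SNPs failing discovery),
#'   `validation_pass` (validated among discovered pseudo-SNPs),
#'   `fp_discovery_rate` and `fp_validated_rate` (per decoy SNP), and
#'   the underlying counts.
#' @export
summarize_grid <- function(outcomes, by = NULL) {
  grp <- c(by, "method")
  outcomes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_trials = sum(.data$is_pseudo),
      n_decoys = sum(!.data$is_pseudo),
      tp_discovery = sum(.data$is_pseudo & .data$discovered),
      tp_validated = sum(.data$is_pseudo & .data$validated),
      fn = sum(.data$is_pseudo & !.data$discovered),
      fp_discovery = sum(!.data$is_pseudo & .data$discovered),
      fp_validated = sum(!.data$is_pseudo & .data$validated),
      .groups = "drop") |>
    dplyr::mutate(
      tpr_discovery = .data$tp_discovery / .data$n_trials,
      tpr_two_stage = .data$tp_validated / .data$n_trials,
      fnr = .data$fn / .data$n_trials,
      validation_pass = ifelse(.data$tp_discovery > 0,
                               .data$tp_validated / .data$tp_discovery,
                               NA_real_),
      fp_discovery_rate = .data$fp_discovery / .data$n_decoys,
      fp_validated_rate = .data$fp_validated / .data$n_decoys)
}
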