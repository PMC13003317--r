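# Solver backend: a pluggable contract around mixed-integer linear
# programming.  The default backend drives the HiGHS branch-and-bound
# engine through scipy.optimize.milp (via reticulate); any backend
# function with the same signature that passes the enumeration-oracle
# test suite is acceptable.

the <- new.env(parent = emptyenv())

configure_python <- function() {
  if (!nzchar(Sys.getenv("RETICULATE_PYTHON"))) {
    py <- Sys.which("python3")
    if (!nzchar(py)) py <- Sys.which("python")
    if (nzchar(py)) Sys.setenv(RETICULATE_PYTHON = py)
  }
}

scipy_optimize <- function() {
  if (is.null(the$scipy_optimize)) {
    configure_python()
    the$scipy_optimize <- reticulate::import("scipy.optimize", delay_load = FALSE)
    the$numpy <- reticulate::import("numpy", delay_load = FALSE)
  }
  the$scipy_optimize
}

.onLoad <- function(libname, pkgname) {
  configure_python()
}

#' Solve a MILP formulation
#'
#' @param f a [build_formulation()] result.
#' @param backend `"highs"` (the default engine) or a function
#'   `function(f, time_limit, seed)` implementing the same contract.
#' @param time_limit wall-clock limit in seconds (`Inf` = none).
#' @param seed accepted for interface stability; the default engine is
#'   deterministic (single-threaded branch and bound), so the seed does
#'   not influence its result.
#' @return an object of class `milp_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"`, `"timeout"` or `"error"`),
#'   `objective`, named variable vector `x`, `S`, `T`, and `bound` (the
#'   best proven bound, reported on timeout).
#' @export
solve_milp <- function(f, backend = "highs", time_limit = Inf, seed = NULL) {
  if (is.function(backend)) return(backend(f, time_limit, seed))
  if (!identical(backend, "highs"))
    stop("unknown solver backend: ", backend, call. = FALSE)
  sp <- scipy_optimize()
  obj <- if (f$maximize) -f$vars$obj else f$vars$obj
  options <- list(presolve = TRUE, mip_rel_gap = 0)
  if (is.finite(time_limit)) options$time_limit <- as.numeric(time_limit)
  res <- sp$milp(
    c = obj,
    constraints = sp$LinearConstraint(reticulate::r_to_py(f$A), f$lo, f$hi),
    integrality = the$numpy$array(as.integer(f$vars$integer)),
    bounds = sp$Bounds(f$vars$lb, f$vars$ub),
    options = options
  )
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "timeout", "2" = "infeasible",
                   "3" = "infeasible", "error")
  x <- NULL; objective <- NA_real_; S <- NA_real_; T <- NA_real_
  if (!is.null(res$x)) {
    x <- round(as.numeric(res$x))
    names(x) <- f$vars$name
    objective <- sum(f$vars$obj * x)
    S <- unname(x["S"]); T <- unname(x["T"])
  }
  structure(list(status = status, objective = objective, x = x,
                 S = S, T = T,
                 bound = if (!is.null(res$mip_dual_bound) && f$maximize)
                   -res$mip_dual_bound else res$mip_dual_bound,
                 message = res$message),
            class = "milp_solution")
}

#' @export
print.milp_solution <- function(x, ...) {
  cat(sprintf("<milp_solution> %s", x$status))
  if (!is.na(x$objective))
    cat(sprintf(", objective %g (S=%g, T=%g)", x$objective, x$S, x$T))
  cat("\n")
  invisible(x)
}

#' Export a formulation in LP file format
#'
#' Writes the standard LP dialect for debugging with external solvers.
#'
#' @param f a [build_formulation()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(f, path) {
  A <- as(f$A, "TsparseMatrix")
  con <- file(path, "w"); on.exit(close(con))
  terms <- function(ridx) {
    ix <- which(A@i + 1 == ridx)
    paste(sprintf("%+g %s", A@x[ix], f$vars$name[A@j[ix] + 1]), collapse = " ")
  }
  writeLines(sprintf("\\ %s", f$label %||% "cnfgwas formulation"), con)
  writeLines(if (f$maximize) "Maximize" else "Minimize", con)
  nzo <- which(f$vars$obj != 0)
  writeLines(paste(" obj:", paste(sprintf("%+g %s", f$vars$obj[nzo],
                                          f$vars$name[nzo]), collapse = " ")), con)
  writeLines("Subject To", con)
  for (r in seq_len(nrow(f$A))) {
    t <- terms(r)
    if (is.finite(f$lo[r]) && f$lo[r] == f$hi[r]) {
      writeLines(sprintf(" c%d: %s = %g", r, t, f$lo[r]), con)
    } else {
      if (is.finite(f$lo[r])) writeLines(sprintf(" c%dl: %s >= %g", r, t, f$lo[r]), con)
      if (is.finite(f$hi[r])) writeLines(sprintf(" c%du: %s <= %g", r, t, f$hi[r]), con)
    }
  }
  writeLines("Bounds", con)
  for (v in seq_len(nrow(f$vars)))
    writeLines(sprintf(" %g <= %s <= %g", f$vars$lb[v], f$vars$name[v],
                       f$vars$ub[v]), con)
  writeLines("Generals", con)
  writeLines(paste("", paste(f$vars$name[f$vars$integer], collapse = " ")), con)
  writeLines("End", con)
  invisible(path)
}
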