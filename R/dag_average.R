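#' Model-averaged causal risk ratio over a DAG's adjustment sets
#'
#' The package's central fitter. From a causal diagram it enumerates the
#' (minimally) sufficient confounder adjustment sets, fits one risk-ratio
#' regression per set on that model's complete cases, and pools the per-set
#' exposure estimates by up to three averaging schemes:
#' \describe{
#'   \item{`ic`}{Akaike-weight averaging ([ic_average]); all models are
#'     refit on the rows complete for the union of all sets' covariates
#'     ([common_complete_rows]) so their information criteria are
#'     comparable.}
#'   \item{`iv`}{inverse-variance weighting ([iv_average]) of the
#'     per-model complete-case fits.}
#'   \item{`bootstrap`}{bootstrap pooling ([bootstrap_average]) of
#'     replicate-by-model estimates.}
#' }
#' Averaging over all sufficient sets, rather than selecting one, absorbs
#' the uncertainty of choosing among equally defensible candidate models
#' and removes the temptation to report the most agreeable single model.
#'
#' @param data a data.frame with one row per subject.
#' @param dag a [causal_dag], or the text/path accepted by [causal_dag];
#'   its exposure and outcome names must be columns of `data`.
#' @param minimal_only restrict to minimally sufficient sets (default
#'   `TRUE`).
#' @param methods subset of `c("ic", "iv", "bootstrap")`.
#' @param ic `"aic"` or `"bic"` for the IC weights.
#' @param B bootstrap replicate count (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param level confidence level (default 0.95).
#' @param measure effect-measure tag checked by [check_collapsible];
#'   only collapsible measures (risk ratios) are fit, but the guard
#'   documents the restriction.
#' @param override proceed despite a non-collapsible `measure`.
#' @return an object of class `dag_average` with components `dag`, `sets`,
#'   `models` (per-model complete-case fits), `models_common` (refits on
#'   the common observation set, when `ic` requested), `averages` (stacked
#'   `averaged_estimate` rows), `pool` (bootstrap pool or `NULL`), `level`,
#'   `call`. Methods: `print`, `summary`, `coef`, `confint`.
#' @examples
#' model <- cohort_preset("fig1-confounding")
#' d <- simulate_cohort(model, 2000, seed = 7)
#' fit <- dag_average(d, model$dag, methods = c("ic", "iv"))
#' fit
#' @export
dag_average <- function(data, dag, minimal_only = TRUE,
                        methods = c("ic", "iv", "bootstrap"),
                        ic = c("aic", "bic"), B = 1000L, seed = 1L,
                        level = 0.95, measure = "risk-ratio",
                        override = FALSE) {
  cl <- match.call()
  methods <- match.arg(methods, c("ic", "iv", "bootstrap"),
                       several.ok = TRUE)
  ic <- match.arg(ic)
  if (!inherits(dag, "causal_dag")) dag <- causal_dag(dag)
  stopifnot(is.data.frame(data), level > 0, level < 1)
  check_collapsible(measure, override = override)

  sets <- adjustment_sets(dag, minimal_only = minimal_only)
  if (length(sets) == 0L) {
    open <- open_backdoor_paths(dag)
    stop("no sufficient adjustment set exists among the measured ",
         "covariates; open backdoor path(s): ",
         paste(vapply(open, paste, character(1), collapse = " - "),
               collapse = "; "), call. = FALSE)
  }
  present <- names(data)
  for (s in sets) {
    miss <- setdiff(s$members, present)
    if (length(miss) > 0L)
      stop("adjustment covariate(s) not in data: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }

  exposure <- dag$exposure
  outcome <- dag$outcome
  models <- lapply(seq_along(sets), function(i)
    fit_rr_model(data, sets[[i]]$members, exposure, outcome, set_id = i))

  averages <- list()
  models_common <- NULL
  if ("ic" %in% methods) {
    rows <- common_complete_rows(data, sets, exposure, outcome)
    models_common <- lapply(seq_along(sets), function(i)
      fit_rr_model(data, sets[[i]]$members, exposure, outcome,
                   restrict_to = rows, set_id = i))
    averages$ic <- ic_average(models_common, ic = ic, level = level)
  }
  if ("iv" %in% methods)
    averages$iv <- iv_average(models, level = level)
  pool <- NULL
  if ("bootstrap" %in% methods) {
    bt <- bootstrap_average(data, sets, exposure, outcome, B = B,
                            seed = seed, level = level)
    pool <- bt$pool
    averages$bootstrap <- bt$average
  }
  avg <- do.call(rbind, lapply(averages, function(a) {
    a$median_rr <- if ("median_rr" %in% names(a)) a$median_rr else NA_real_
    a
  }))
  rownames(avg) <- NULL
  structure(
    list(dag = dag, sets = sets, models = models,
         models_common = models_common,
         averages = structure(avg,
                              weights = lapply(averages, attr, "weights"),
                              class = c("averaged_estimate", "data.frame")),
         pool = pool, level = level, ic = ic, call = cl),
    class = "dag_average")
}

# backdoor paths from exposure to outcome left open given the empty set
# (reported when identification fails)
open_backdoor_paths <- function(dag) {
  paths <- all_undirected_paths(dag, dag$exposure, dag$outcome)
  into_exposure <- dag$edges[dag$edges[, 2L] == dag$exposure, 1L]
  Filter(function(p) p[2L] %in% into_exposure &&
           !path_blocked(dag, p, character(0)), paths)
}

#' @export
print.dag_average <- function(x, digits = 2, ...) {
  cat("Model-averaged causal risk ratio:", x$dag$exposure, "->",
      x$dag$outcome, "\n")
  cat(length(x$sets), "adjustment set(s) averaged; per-model n:",
      paste(vapply(x$models, function(m) m$n, numeric(1)), collapse = ", "),
      "\n")
  fb <- vapply(x$models, function(m) m$family_used, character(1))
  if (any(fb != "log-binomial"))
    cat("  note:", sum(fb != "log-binomial"),
        "model(s) used the modified-Poisson fallback\n")
  print(x$averages, digits = digits)
  invisible(x)
}

#' @export
summary.dag_average <- function(object, ...) {
  structure(object, class = c("summary.dag_average", class(object)))
}

#' @export
print.summary.dag_average <- function(x, digits = 2, ...) {
  print.dag_average(x, digits = digits, ...)
  cat("\nPer-model fits:\n")
  for (i in seq_along(x$sets)) {
    cat(sprintf(" set %d ", i))
    print(x$models[[i]])
  }
  if (!is.null(x$models_common))
    cat("IC weighting refit on", x$models_common[[1L]]$n,
        "rows complete for all sets (", x$ic, "weights )\n")
  if (!is.null(x$pool)) print(x$pool)
  invisible(x)
}

#' @export
coef.dag_average <- function(object, ...) {
  a <- object$averages
  stats::setNames(a$log_rr, paste(a$method, a$contrast, sep = "."))
}

#' @export
confint.dag_average <- function(object, parm, level, ...) {
  a <- object$averages
  m <- cbind(lower = a$ci_lower, upper = a$ci_upper)
  rownames(m) <- paste(a$method, a$contrast, sep = ".")
  m
}
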