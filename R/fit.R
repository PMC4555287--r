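#' Fit one risk-ratio regression for a given adjustment set
#'
#' Fits a log-link binomial GLM of the binary outcome on exposure indicators
#' plus the adjustment covariates, on the complete cases of the columns
#' involved. Categorical covariates enter as reference-coded indicators and
#' continuous covariates enter untransformed. Exposure contrasts (log risk
#' ratio and standard error) are reported per non-reference exposure level.
#' When the log-binomial fit does not converge (a common failure mode of the
#' log link), the model is refit as a log-link Poisson regression with
#' robust (sandwich) standard errors — the "modified Poisson" estimator —
#' and the family actually used is recorded.
#'
#' @param data a data.frame; the outcome column must be coded 0/1 and the
#'   exposure column is coerced to a factor (its first level is the
#'   reference).
#' @param members character vector of adjustment covariate column names (may
#'   be empty).
#' @param exposure,outcome column names.
#' @param restrict_to optional integer vector of row indices; the fit is
#'   restricted to these rows (intersected with the complete cases). Used to
#'   refit all candidate models on a common observation set for
#'   information-criterion weighting.
#' @param set_id integer label carried into reports.
#' @param epsilon,maxit GLM convergence tolerance and iteration cap.
#' @return an object of class `rr_model_summary`: `set_id`, `members`,
#'   `contrasts` (data.frame with `contrast`, `log_rr`, `se`), `n`,
#'   `loglik`, `aic`, `bic`, `converged`, `family_used`
#'   (`"log-binomial"` or `"poisson-robust"`).
#' @examples
#' d <- data.frame(E = rep(c(1, 0), each = 100),
#'                 D = c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 85)))
#' m <- fit_rr_model(d, character(0), exposure = "E", outcome = "D")
#' exp(m$contrasts$log_rr)  # 2.0: (30/100) / (15/100)
#' @export
fit_rr_model <- function(data, members, exposure, outcome,
                         restrict_to = NULL, set_id = NA_integer_,
                         epsilon = 1e-8, maxit = 100L) {
  members <- as.character(members)
  cols <- c(exposure, outcome, members)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L)
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  rows <- which(stats::complete.cases(data[cols]))
  if (!is.null(restrict_to)) rows <- intersect(rows, restrict_to)
  if (length(rows) == 0L)
    stop("no complete cases for this adjustment set", call. = FALSE)
  d <- data[rows, cols, drop = FALSE]

  y <- d[[outcome]]
  if (!all(y %in% c(0, 1)))
    stop("outcome must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome is constant within the complete cases; fit is degenerate",
         call. = FALSE)
  if (!is.factor(d[[exposure]])) d[[exposure]] <- factor(d[[exposure]])
  d[[exposure]] <- droplevels(d[[exposure]])
  if (nlevels(d[[exposure]]) < 2L)
    stop("exposure has fewer than 2 observed levels", call. = FALSE)

  rhs <- paste(c(sprintf("`%s`", exposure),
                 if (length(members) > 0L) sprintf("`%s`", members)),
               collapse = " + ")
  form <- stats::as.formula(paste(sprintf("`%s`", outcome), "~", rhs))

  ctl <- stats::glm.control(epsilon = epsilon, maxit = maxit)
  fit <- NULL
  family_used <- "log-binomial"
  converged <- FALSE
  # log-binomial needs admissible starting values; start at the marginal
  # log-risk intercept with zero slopes
  nstart <- ncol(stats::model.matrix(form, data = d))
  start <- c(log(mean(y)), rep(0, nstart - 1L))
  fit <- tryCatch(
    suppressWarnings(stats::glm(form, data = d,
                                family = stats::binomial(link = "log"),
                                start = start, control = ctl)),
    error = function(e) NULL)
  if (!is.null(fit) && isTRUE(fit$converged) &&
      !any(is.na(stats::coef(fit)))) {
    converged <- TRUE
    vc <- stats::vcov(fit)
  }
  if (!converged) {
    family_used <- "poisson-robust"
    fit <- tryCatch(
      suppressWarnings(stats::glm(form, data = d,
                                  family = stats::poisson(link = "log"),
                                  control = ctl)),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged) ||
        any(is.na(stats::coef(fit))))
      stop("neither log-binomial nor modified-Poisson fit converged ",
           "(possible complete separation); n = ", length(rows),
           call. = FALSE)
    converged <- TRUE
    vc <- sandwich::vcovHC(fit, type = "HC0")
  }

  cf <- stats::coef(fit)
  k <- length(cf)
  ll <- as.numeric(stats::logLik(fit))
  n <- length(rows)
  exp_levels <- levels(d[[exposure]])[-1L]
  exp_terms <- paste0(sprintf("`%s`", exposure), exp_levels)
  # model.matrix may or may not keep backticks in term names
  exp_terms_plain <- paste0(exposure, exp_levels)
  idx <- ifelse(exp_terms %in% names(cf),
                match(exp_terms, names(cf)),
                match(exp_terms_plain, names(cf)))
  if (any(is.na(idx)))
    stop("internal error: exposure coefficients not found in fit",
         call. = FALSE)
  contrasts <- data.frame(
    contrast = exp_levels,
    log_rr = unname(cf[idx]),
    se = sqrt(diag(vc)[idx]),
    stringsAsFactors = FALSE
  )

  structure(
    list(set_id = set_id, members = members, contrasts = contrasts,
         n = n, loglik = ll, aic = -2 * ll + 2 * k,
         bic = -2 * ll + k * log(n), converged = converged,
         family_used = family_used, rows = rows),
    class = "rr_model_summary"
  )
}

#' @export
print.rr_model_summary <- function(x, ...) {
  lab <- if (length(x$members) == 0L) "{ }" else
    paste0("{", paste(x$members, collapse = ", "), "}")
  cat("Risk-ratio model, adjustment set", lab, "\n")
  cat(sprintf("  n = %d complete cases, family = %s, AIC = %.2f\n",
              x$n, x$family_used, x$aic))
  for (i in seq_len(nrow(x$contrasts)))
    cat(sprintf("  %s: RR = %.3f (log RR %.4f, SE %.4f)\n",
                x$contrasts$contrast[i], exp(x$contrasts$log_rr[i]),
                x$contrasts$log_rr[i], x$contrasts$se[i]))
  invisible(x)
}

#' Rows complete on every candidate model's variables
#'
#' Information-criterion weighting requires all candidate models to be fit
#' to the identical observation set, so likelihoods are comparable. This
#' returns the indices of rows complete on the exposure, the outcome, and
#' the union of all adjustment sets' members.
#'
#' @param data a data.frame.
#' @param sets an [adjustment_sets] object, or a list of character vectors
#'   of covariate names.
#' @param exposure,outcome column names.
#' @return integer vector of row indices.
#' @export
common_complete_rows <- function(data, sets, exposure, outcome) {
  members <- unique(unlist(lapply(sets, function(s)
    if (inherits(s, "adjustment_set")) s$members else as.character(s))))
  cols <- unique(c(exposure, outcome, members))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L)
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rows <- which(stats::complete.cases(data[cols]))
  if (length(rows) == 0L)
    stop("no rows complete on the union of all adjustment sets",
         call. = FALSE)
  rows
}

#' Recover the log-scale standard error from a ratio confidence interval
#'
#' Inverts a Wald interval on the ratio scale:
#' `se = (log(upper) - log(lower)) / (2 * z)` where `z` is the standard
#' normal quantile for the interval's coverage. Used to rebuild per-model
#' summaries from published tables that print only the ratio and its CI.
#'
#' @param lower,upper CI bounds on the ratio scale (must be positive).
#' @param level confidence level (default 0.95).
#' @return the standard error of the log estimate.
#' @examples
#' se_from_ci(1.32, 2.62)  # 0.1749
#' @export
se_from_ci <- function(lower, upper, level = 0.95) {
  if (any(lower <= 0) || any(upper <= 0))
    stop("CI bounds must be positive on the ratio scale", call. = FALSE)
  if (any(upper < lower))
    stop("upper bound below lower bound", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  (log(upper) - log(lower)) / (2 * z)
}
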