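#' Akaike weights from information-criterion values
#'
#' Computes relative model support as `w_i = exp(-Delta_i / 2) /
#' sum_j exp(-Delta_j / 2)` with `Delta_i = IC_i - min(IC)` (the
#' Burnham–Anderson weights). The weights are invariant to adding a
#' constant to every IC value, nonnegative, and sum to one. AIC and BIC
#' values are both admissible; the models must have been fit to the same
#' observation set for their criteria to be comparable.
#'
#' @param ic numeric vector of information-criterion values.
#' @return numeric weight vector of the same length.
#' @examples
#' round(ic_weights(c(552.56, 552.74, 555.12, 556.43)), 2)
#' @export
ic_weights <- function(ic) {
  if (length(ic) == 0L) stop("no information-criterion values", call. = FALSE)
  if (any(!is.finite(ic))) stop("non-finite information-criterion value",
                                call. = FALSE)
  delta <- ic - min(ic)
  w <- exp(-delta / 2)
  w / sum(w)
}

# coerce a list of rr_model_summary objects (or a ready-made table) to the
# canonical per-model-per-contrast data.frame used by the averagers
model_table <- function(models) {
  if (is.data.frame(models)) {
    need <- c("set_id", "contrast", "log_rr", "se", "n")
    miss <- setdiff(need, names(models))
    if (length(miss) > 0L)
      stop("model table lacks columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (!"aic" %in% names(models)) models$aic <- NA_real_
    if (!"bic" %in% names(models)) models$bic <- NA_real_
    return(models)
  }
  stopifnot(is.list(models), length(models) > 0L)
  do.call(rbind, lapply(models, function(m) {
    stopifnot(inherits(m, "rr_model_summary"))
    data.frame(set_id = m$set_id, contrast = m$contrasts$contrast,
               log_rr = m$contrasts$log_rr, se = m$contrasts$se,
               n = m$n, aic = m$aic, bic = m$bic,
               stringsAsFactors = FALSE)
  }))
}

check_contrast_structure <- function(tab) {
  split_tab <- split(tab, tab$set_id)
  contr <- lapply(split_tab, function(x) sort(x$contrast))
  if (length(unique(contr)) > 1L)
    stop("models report different exposure contrasts and cannot be averaged",
         call. = FALSE)
  sort(contr[[1L]])
}

averaged_row <- function(method, contrast, log_rr_bar, se_bar, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lower <- exp(log_rr_bar - z * se_bar)
  upper <- exp(log_rr_bar + z * se_bar)
  data.frame(method = method, contrast = contrast, rr = exp(log_rr_bar),
             ci_lower = lower, ci_upper = upper, clr = upper / lower,
             log_rr = log_rr_bar, se = se_bar, stringsAsFactors = FALSE)
}

#' Information-criterion-weighted model average
#'
#' Averages the per-model log risk ratios with Akaike weights computed from
#' AIC (or BIC) values, and reports the Burnham–Anderson *unconditional*
#' standard error, which adds the between-model spread of the estimates to
#' each model's own sampling variance:
#' `se_bar = sum_i w_i * sqrt(se_i^2 + (log_rr_i - log_rr_bar)^2)`.
#' The pooled CI is `exp(log_rr_bar +/- z * se_bar)`. All models must have
#' been fit to the identical observation set (see [common_complete_rows]).
#'
#' @param models a list of [fit_rr_model] summaries, or a data.frame with
#'   columns `set_id`, `contrast`, `log_rr`, `se`, `n`, `aic` (and `bic`).
#' @param ic `"aic"` (default) or `"bic"`.
#' @param weights optional explicit weight vector (one per model, summing
#'   to 1); overrides the IC-derived weights.
#' @param level confidence level.
#' @return an `averaged_estimate` data.frame, one row per exposure
#'   contrast, with columns `method`, `contrast`, `rr`, `ci_lower`,
#'   `ci_upper`, `clr`, `log_rr`, `se`; the per-model weights are attached
#'   as attribute `"weights"`.
#' @export
ic_average <- function(models, ic = c("aic", "bic"), weights = NULL,
                       level = 0.95) {
  ic <- match.arg(ic)
  tab <- model_table(models)
  contrasts <- check_contrast_structure(tab)
  ids <- unique(tab$set_id)
  if (is.null(weights)) {
    ic_vals <- vapply(ids, function(id)
      tab[[ic]][match(id, tab$set_id)], numeric(1))
    weights <- ic_weights(ic_vals)
  }
  if (length(weights) != length(ids))
    stop("need one weight per model", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)

  out <- do.call(rbind, lapply(contrasts, function(ct) {
    sub <- tab[tab$contrast == ct, ][match(ids, tab$set_id[tab$contrast == ct]), ]
    lbar <- sum(weights * sub$log_rr)
    sbar <- sum(weights * sqrt(sub$se^2 + (sub$log_rr - lbar)^2))
    averaged_row("ic", ct, lbar, sbar, level)
  }))
  structure(out, weights = stats::setNames(weights, ids),
            class = c("averaged_estimate", "data.frame"))
}

#' Inverse-variance-weighted model average
#'
#' Pools the per-model log risk ratios with weights proportional to the
#' reciprocal of each model's variance:
#' `log_rr_bar = sum(log_rr_i / se_i^2) / sum(1 / se_i^2)`. The pooled
#' standard error is the complete-case-sample-size-weighted arithmetic mean
#' of the per-model standard errors, `se_bar = sum(n_i * se_i) / sum(n_i)`
#' — each model keeps its own complete cases, and models fit to more
#' observations contribute more to the pooled uncertainty. (This is not the
#' classical fixed-effect meta-analytic `sqrt(1/sum(1/var))`, which assumes
#' independent samples and would be anti-conservative here, where every
#' model is fit to overlapping subsets of one cohort.)
#'
#' @inheritParams ic_average
#' @return an `averaged_estimate` data.frame (see [ic_average]); the
#'   per-model normalized inverse-variance weights per contrast are attached
#'   as attribute `"weights"`.
#' @export
iv_average <- function(models, level = 0.95) {
  tab <- model_table(models)
  contrasts <- check_contrast_structure(tab)
  ids <- unique(tab$set_id)
  if (any(tab$se <= 0)) stop("zero or negative standard error", call. = FALSE)
  wlist <- list()
  out <- do.call(rbind, lapply(contrasts, function(ct) {
    sub <- tab[tab$contrast == ct, ][match(ids, tab$set_id[tab$contrast == ct]), ]
    iv <- 1 / sub$se^2
    lbar <- sum(iv * sub$log_rr) / sum(iv)
    sbar <- sum(sub$n * sub$se) / sum(sub$n)
    wlist[[ct]] <<- stats::setNames(iv / sum(iv), ids)
    averaged_row("iv", ct, lbar, sbar, level)
  }))
  structure(out, weights = wlist,
            class = c("averaged_estimate", "data.frame"))
}

#' @export
print.averaged_estimate <- function(x, digits = 2, ...) {
  method_labels <- c(ic = "Information-criterion weighted",
                     iv = "Inverse-variance weighted",
                     bootstrap = "Bootstrap pooled")
  for (m in unique(x$method)) {
    cat(method_labels[[m]], "average:\n")
    sub <- x[x$method == m, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %s: RR %.*f (%.*f, %.*f), CLR %.*f\n",
                  sub$contrast[i], digits, sub$rr[i], digits,
                  sub$ci_lower[i], digits, sub$ci_upper[i], digits,
                  sub$clr[i]))
  }
  invisible(x)
}

#' Bootstrap model averaging of per-set causal estimates
#'
#' Draws `B` bootstrap replicates (rows sampled with replacement from the
#' full dataset, incomplete rows included), refits every candidate model to
#' its own complete cases within each replicate, and pools all finite log
#' risk ratios across the replicate-by-model matrix — so each exposure
#' contrast accumulates up to `B * M` values. The pooled summary reports
#' the exponentiated mean, median, and 2.5th/97.5th percentiles (linear
#' interpolation between order statistics, quantile type 7) of the pooled
#' draws. Fits that fail within a replicate are dropped and counted.
#'
#' @param data data.frame with one row per subject.
#' @param sets an [adjustment_sets] object or list of covariate-name
#'   vectors.
#' @param exposure,outcome column names.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed; the procedure is fully reproducible given it.
#' @param level interval coverage (default 0.95, i.e. the 2.5th and 97.5th
#'   percentiles).
#' @param resample optional function `(n, b) -> integer vector` returning
#'   the row indices of replicate `b`; defaults to sampling `n` rows with
#'   replacement. Supplying the identity makes replicate fits equal the
#'   plain fits.
#' @return a list with components `pool` (class `bootstrap_pool`: per
#'   contrast, the B-by-M matrix of replicate log RRs, plus `B`, `M`,
#'   `dropped`) and `average` (an `averaged_estimate` data.frame with
#'   `rr` = exponentiated pooled mean, `ci_lower`/`ci_upper` = percentile
#'   bounds, and extra columns `median_rr`).
#' @export
bootstrap_average <- function(data, sets, exposure, outcome, B = 1000L,
                              seed = 1L, level = 0.95, resample = NULL) {
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  member_list <- lapply(sets, function(s)
    if (inherits(s, "adjustment_set")) s$members else as.character(s))
  M <- length(member_list)
  if (M == 0L) stop("no adjustment sets supplied", call. = FALSE)
  n <- nrow(data)
  set.seed(seed)
  if (is.null(resample)) resample <- function(n, b) sample.int(n, n, replace = TRUE)

  draws <- list()   # contrast -> B x M matrix
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- resample(n, b)
    boot <- data[idx, , drop = FALSE]
    for (m in seq_len(M)) {
      fit <- tryCatch(
        fit_rr_model(boot, member_list[[m]], exposure, outcome, set_id = m),
        error = function(e) NULL)
      if (is.null(fit)) {
        dropped <- dropped + 1L
        next
      }
      for (i in seq_len(nrow(fit$contrasts))) {
        ct <- fit$contrasts$contrast[i]
        if (is.null(draws[[ct]]))
          draws[[ct]] <- matrix(NA_real_, nrow = B, ncol = M)
        draws[[ct]][b, m] <- fit$contrasts$log_rr[i]
      }
    }
  }
  if (length(draws) == 0L)
    stop("all bootstrap fits failed", call. = FALSE)

  alpha <- (1 - level) / 2
  avg <- do.call(rbind, lapply(sort(names(draws)), function(ct) {
    v <- draws[[ct]][is.finite(draws[[ct]])]
    if (length(v) == 0L)
      stop("all bootstrap fits failed for contrast ", ct, call. = FALSE)
    q <- stats::quantile(v, c(alpha, 1 - alpha), type = 7, names = FALSE)
    out <- data.frame(method = "bootstrap", contrast = ct,
                      rr = exp(mean(v)), ci_lower = exp(q[1]),
                      ci_upper = exp(q[2]), clr = exp(q[2]) / exp(q[1]),
                      log_rr = mean(v), se = stats::sd(v),
                      median_rr = exp(stats::median(v)),
                      stringsAsFactors = FALSE)
    out
  }))
  pool <- structure(list(draws = draws, B = B, M = M, dropped = dropped),
                    class = "bootstrap_pool")
  list(pool = pool,
       average = structure(avg, class = c("averaged_estimate", "data.frame")))
}

#' @export
print.bootstrap_pool <- function(x, ...) {
  cat(sprintf("Bootstrap pool: B = %d replicates x M = %d models", x$B, x$M))
  cat(sprintf(" (%d fit(s) dropped)\n", x$dropped))
  invisible(x)
}

#' Confidence limit ratio
#'
#' The upper confidence bound divided by the lower: a scale-free measure of
#' the precision of a ratio estimate, used to compare averaging approaches.
#'
#' @param lower lower CI bound on the ratio scale, or a length-2 vector
#'   `c(lower, upper)`.
#' @param upper upper CI bound (omit when `lower` holds both).
#' @return `upper / lower`.
#' @examples
#' confidence_limit_ratio(0.92, 2.04)
#' @export
confidence_limit_ratio <- function(lower, upper = NULL) {
  if (is.null(upper)) {
    stopifnot(length(lower) == 2L)
    upper <- lower[2L]; lower <- lower[1L]
  }
  if (any(lower <= 0)) stop("lower bound must be positive", call. = FALSE)
  if (any(upper < lower)) stop("upper bound below lower bound", call. = FALSE)
  upper / lower
}

#' Guard against averaging non-collapsible effect measures
#'
#' Risk ratios and risk differences are collapsible: a marginal effect is a
#' weighted average of stratum-specific effects, so estimates from
#' different (all sufficient) adjustment sets target the same quantity and
#' may be averaged. Odds ratios and hazard ratios are non-collapsible —
#' they genuinely differ across alternative adjustment sets even without
#' confounding — so averaging them mixes different estimands. This guard
#' passes silently for collapsible measures and emits a prominent warning
#' for non-collapsible ones; averaging proceeds only under an explicit
#' override.
#'
#' @param measure one of `"risk-ratio"`, `"risk-difference"`,
#'   `"odds-ratio"`, `"hazard-ratio"`.
#' @param override set `TRUE` to proceed despite the warning.
#' @return invisibly `TRUE` if averaging may proceed; stops otherwise.
#' @export
check_collapsible <- function(measure, override = FALSE) {
  measure <- match.arg(measure, c("risk-ratio", "risk-difference",
                                  "odds-ratio", "hazard-ratio"))
  if (measure %in% c("odds-ratio", "hazard-ratio")) {
    warning("'", measure, "' is a non-collapsible effect measure: ",
            "estimates from different adjustment sets target different ",
            "quantities, and their average has no single-model ",
            "interpretation", call. = FALSE)
    if (!override)
      stop("refusing to average non-collapsible '", measure,
           "' estimates; set override = TRUE to proceed anyway",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a per-model summary table
#'
#' Reads the averaging-only input format: a CSV with header columns
#' `set_id`, `contrast`, `rr`, `ci_lower`, `ci_upper`, `aic`, `n` (the
#' `aic` column may be empty when only inverse-variance averaging is
#' wanted). Log risk ratios and their standard errors are recovered from
#' the printed ratios and CI bounds via [se_from_ci], so published
#' per-model tables can be averaged without the raw data.
#'
#' @param path CSV file path, or a data.frame already in that layout.
#' @param level confidence level of the printed intervals (default 0.95).
#' @return a model table data.frame accepted by [ic_average] and
#'   [iv_average].
#' @export
read_model_summaries <- function(path, level = 0.95) {
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("set_id", "contrast", "rr", "ci_lower", "ci_upper", "n")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("summary table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tab$rr <= 0)) stop("risk ratios must be positive", call. = FALSE)
  tab$log_rr <- log(tab$rr)
  tab$se <- se_from_ci(tab$ci_lower, tab$ci_upper, level)
  if (!"aic" %in% names(tab)) tab$aic <- NA_real_
  if (!"bic" %in% names(tab)) tab$bic <- NA_real_
  tab
}

#' Average a table of pre-fitted model summaries
#'
#' The averaging-only entry point: combines published (or otherwise
#' pre-fitted) per-model risk-ratio summaries by information-criterion
#' and/or inverse-variance weighting, without access to the raw data.
#'
#' @param summaries CSV path or data.frame in the [read_model_summaries]
#'   layout.
#' @param methods subset of `c("ic", "iv")`.
#' @param ic `"aic"` or `"bic"` for the IC weights.
#' @param level confidence level.
#' @return an `averaged_estimate` data.frame stacking the requested
#'   methods.
#' @examples
#' path <- system.file("extdata", "bmi_cesarean_aic.csv", package = "causalMA")
#' average_summaries(path, methods = "ic")
#' @export
average_summaries <- function(summaries, methods = c("ic", "iv"),
                              ic = "aic", level = 0.95) {
  methods <- match.arg(methods, c("ic", "iv"), several.ok = TRUE)
  tab <- read_model_summaries(summaries, level = level)
  res <- list()
  if ("ic" %in% methods) {
    if (any(is.na(tab[[ic]])))
      stop("information-criterion column '", ic, "' has missing values",
           call. = FALSE)
    res$ic <- ic_average(tab, ic = ic, level = level)
  }
  if ("iv" %in% methods) res$iv <- iv_average(tab, level = level)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, weights = lapply(res, attr, "weights"),
            class = c("averaged_estimate", "data.frame"))
}
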