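#' Specify a structural data-generating model on a causal diagram
#'
#' Couples a [causal_dag] with one sampling mechanism per node so that
#' cohorts can be simulated with a *known* causal effect of the exposure on
#' the outcome. Supported mechanism families:
#' \describe{
#'   \item{`bernoulli-logit`}{binary node; `P(X=1) = plogis(intercept +
#'     sum(coef * parents))`.}
#'   \item{`bernoulli-log`}{binary node; `P(X=1) = exp(intercept +
#'     sum(coef * parents))`, clipped into (0, 1). Used for the outcome so
#'     that the exposure coefficients are exact conditional log risk
#'     ratios; because the log link is collapsible, they are also the
#'     marginal (interventional) log risk ratios.}
#'   \item{`categorical-logit`}{multinomial node with named `levels`; one
#'     linear predictor per non-reference level
#'     (`intercept` and `coef` are per-level lists).}
#'   \item{`gaussian-linear`}{continuous node; mean `intercept +
#'     sum(coef * parents)`, standard deviation `sd`.}
#' }
#' Parent values enter linear predictors numerically; categorical parents
#' contribute their 0-based level index. The exposure node must be
#' `categorical-logit` (2 or more levels) and the outcome `bernoulli-log`,
#' with the outcome's `beta` giving the true log risk ratio per
#' non-reference exposure level.
#'
#' @param dag a [causal_dag].
#' @param mechanisms named list, one entry per node (see Details).
#' @param missing named numeric vector of per-column missing-completely-at-
#'   random probabilities in `[0, 1)`; columns absent from it are fully
#'   observed.
#' @return an object of class `structural_model`.
#' @seealso [cohort_preset] for ready-made models, [simulate_cohort],
#'   [true_marginal_rr].
#' @export
structural_model <- function(dag, mechanisms, missing = numeric(0)) {
  stopifnot(inherits(dag, "causal_dag"))
  miss_nodes <- setdiff(dag$nodes, names(mechanisms))
  if (length(miss_nodes) > 0L)
    stop("no mechanism for node(s): ", paste(miss_nodes, collapse = ", "),
         call. = FALSE)
  if (length(missing) > 0L) {
    if (any(missing < 0 | missing >= 1))
      stop("missingness probabilities must lie in [0, 1)", call. = FALSE)
    check_nodes(dag, names(missing))
  }
  fam <- vapply(mechanisms, function(m) m$family, character(1))
  ok <- fam %in% c("bernoulli-logit", "bernoulli-log", "categorical-logit",
                   "gaussian-linear")
  if (any(!ok))
    stop("unknown mechanism family: ", paste(unique(fam[!ok]), collapse = ", "),
         call. = FALSE)
  if (fam[[dag$outcome]] != "bernoulli-log")
    stop("outcome mechanism must be 'bernoulli-log' so that its exposure ",
         "coefficients are true log risk ratios", call. = FALSE)
  if (fam[[dag$exposure]] != "categorical-logit")
    stop("exposure mechanism must be 'categorical-logit'", call. = FALSE)
  structure(list(dag = dag, mechanisms = mechanisms, missing = missing),
            class = "structural_model")
}

#' @export
print.structural_model <- function(x, ...) {
  cat("Structural model on", length(x$dag$nodes), "nodes;",
      "exposure", x$dag$exposure, "->", "outcome", x$dag$outcome, "\n")
  beta <- x$mechanisms[[x$dag$outcome]]$coef
  beta <- beta[grep(paste0("^", x$dag$exposure), names(beta))]
  if (length(beta) > 0L)
    cat("  true log RR per exposure level:",
        paste(sprintf("%s = %.3f", names(beta), beta), collapse = ", "), "\n")
  if (length(x$missing) > 0L)
    cat("  MCAR missingness:",
        paste(sprintf("%s = %.2f", names(x$missing), x$missing),
              collapse = ", "), "\n")
  invisible(x)
}

# numeric value a parent contributes to a linear predictor
parent_numeric <- function(values, mech) {
  if (mech$family == "categorical-logit")
    return(match(values, mech$levels) - 1)
  as.numeric(values)
}

# linear predictor for one mechanism given a data.frame of parent draws
linpred <- function(intercept, coef, parents_df, mechanisms) {
  eta <- rep(intercept, max(1L, nrow(parents_df)))
  for (p in names(coef)) {
    base <- sub("\\..*$", "", p)  # "Race.2" -> indicator for level index 2
    if (grepl("\\.", p)) {
      lev_idx <- as.integer(sub("^.*\\.", "", p))
      x <- as.numeric(parent_numeric(parents_df[[base]],
                                     mechanisms[[base]]) == lev_idx)
    } else {
      x <- parent_numeric(parents_df[[p]], mechanisms[[p]])
    }
    eta <- eta + coef[[p]] * x
  }
  eta
}

draw_node <- function(node, mech, parents_df, mechanisms, n) {
  switch(mech$family,
    "bernoulli-logit" = {
      p <- stats::plogis(linpred(mech$intercept, mech$coef, parents_df,
                                 mechanisms))
      stats::rbinom(n, 1L, p)
    },
    "bernoulli-log" = {
      p <- exp(linpred(mech$intercept, mech$coef, parents_df, mechanisms))
      clipped <- sum(p >= 1)
      if (clipped > 0.01 * n)
        stop("log-link outcome probability exceeds 1 for ",
             round(100 * clipped / n, 1), "% of subjects; use smaller ",
             "coefficients", call. = FALSE)
      if (clipped > 0)
        attr(p, "clipped") <- clipped
      pc <- pmin(p, 1 - 1e-12)
      out <- stats::rbinom(n, 1L, pc)
      attr(out, "clipped") <- clipped
      out
    },
    "categorical-logit" = {
      K <- length(mech$levels)
      eta <- matrix(0, nrow = n, ncol = K)
      for (k in 2:K) {
        ik <- mech$intercept[[k - 1L]]
        ck <- if (is.list(mech$coef)) mech$coef[[k - 1L]] else mech$coef
        eta[, k] <- linpred(ik, ck, parents_df, mechanisms)
      }
      pr <- exp(eta)
      pr <- pr / rowSums(pr)
      idx <- apply(pr, 1L, function(row) sample.int(K, 1L, prob = row))
      # vectorized inverse-cdf draw is faster; apply() kept for clarity at
      # the sizes used here
      mech$levels[idx]
    },
    "gaussian-linear" = {
      mu <- linpred(mech$intercept, mech$coef, parents_df, mechanisms)
      stats::rnorm(n, mu, mech$sd)
    })
}

#' Simulate a cohort from a structural model
#'
#' Samples every node in topological order from its mechanism, then applies
#' missing-completely-at-random masking per column. Fully reproducible
#' given the seed. If the log-link outcome mechanism produces fitted
#' probabilities above 1 they are clipped (the count is recorded in
#' attribute `"clipped"`); more than 1% of rows clipping is an error, as
#' the model is then badly parameterized.
#'
#' @param model a [structural_model].
#' @param n number of subjects.
#' @param seed integer seed.
#' @return a data.frame with one column per node (`n` rows); exposure
#'   column is a factor with the mechanism's level order, outcome is 0/1
#'   integer; masked entries are `NA`.
#' @export
simulate_cohort <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "structural_model"), n >= 1L)
  set.seed(seed)
  dag <- model$dag
  topo <- igraph::V(dag$graph)$name[
    as.integer(igraph::topo_sort(dag$graph, mode = "out"))]
  d <- as.data.frame(matrix(nrow = n, ncol = 0))
  clipped <- 0L
  for (v in topo) {
    mech <- model$mechanisms[[v]]
    parents <- dag$edges[dag$edges[, 2L] == v, 1L]
    vals <- draw_node(v, mech, d[, parents, drop = FALSE],
                      model$mechanisms, n)
    if (!is.null(attr(vals, "clipped"))) {
      clipped <- clipped + attr(vals, "clipped")
      attr(vals, "clipped") <- NULL
    }
    d[[v]] <- vals
  }
  if (is.character(d[[dag$exposure]]))
    d[[dag$exposure]] <- factor(d[[dag$exposure]],
                                levels = model$mechanisms[[dag$exposure]]$levels)
  for (col in names(model$missing)) {
    p <- model$missing[[col]]
    if (p > 0) d[[col]][stats::runif(n) < p] <- NA
  }
  attr(d, "clipped") <- clipped
  d
}

#' Monte-Carlo marginal (interventional) risk ratio of a structural model
#'
#' Computes the standardized risk ratio comparing the population with the
#' exposure set to `level` for everyone against everyone at the reference
#' level, under the structural model: all nodes are simulated in
#' topological order with the exposure *forced* to each level — so any
#' descendants of the exposure are re-drawn under the intervention — and
#' the outcome's event probability is averaged over the simulated
#' distribution. The two arms share random draws (the same seed), so the
#' risks are paired. When the exposure has no modelled descendants other
#' than the outcome, the log link makes this interventional ratio equal
#' `exp(beta_level)` exactly; the Monte-Carlo value and its standard error
#' provide the recovery target for estimator checks.
#'
#' @param model a [structural_model].
#' @param level exposure level to contrast against the reference.
#' @param n_mc Monte-Carlo sample size (default 100000).
#' @param seed integer seed.
#' @return a list with `rr`, `se_mc` (delta-method Monte-Carlo SE of the
#'   ratio), and the two standardized risks.
#' @export
true_marginal_rr <- function(model, level, n_mc = 1e5, seed = 1L) {
  stopifnot(inherits(model, "structural_model"), n_mc >= 1)
  dag <- model$dag
  exp_mech <- model$mechanisms[[dag$exposure]]
  if (!level %in% exp_mech$levels)
    stop("unknown exposure level '", level, "'", call. = FALSE)
  ref <- exp_mech$levels[1L]

  risk_under <- function(lev) {
    set.seed(seed)  # common random numbers across arms
    n <- as.integer(n_mc)
    topo <- igraph::V(dag$graph)$name[
      as.integer(igraph::topo_sort(dag$graph, mode = "out"))]
    d <- as.data.frame(matrix(nrow = n, ncol = 0))
    for (v in topo) {
      mech <- model$mechanisms[[v]]
      parents <- dag$edges[dag$edges[, 2L] == v, 1L]
      if (v == dag$exposure) {
        d[[v]] <- factor(rep(lev, n), levels = exp_mech$levels)
      } else if (v == dag$outcome) {
        p <- exp(linpred(mech$intercept, mech$coef,
                         d[, parents, drop = FALSE], model$mechanisms))
        return(pmin(p, 1))
      } else {
        vals <- draw_node(v, mech, d[, parents, drop = FALSE],
                          model$mechanisms, n)
        attr(vals, "clipped") <- NULL
        d[[v]] <- vals
      }
    }
    stop("outcome node was not reached in topological order")  # unreachable
  }
  p1 <- risk_under(level)
  p0 <- risk_under(ref)
  n_mc <- length(p1)
  r1 <- mean(p1); r0 <- mean(p0)
  if (r0 <= 0) stop("reference risk is zero", call. = FALSE)
  rr <- r1 / r0
  # delta method on log rr over the MC covariate draws
  v <- stats::var(p1) / (n_mc * r1^2) + stats::var(p0) / (n_mc * r0^2) -
    2 * stats::cov(p1, p0) / (n_mc * r1 * r0)
  list(rr = rr, se_mc = rr * sqrt(max(v, 0)), risk = r1, risk_ref = r0)
}

#' Ready-made structural cohort presets
#'
#' Named data-generating models used throughout the package's validation:
#' \describe{
#'   \item{`fig1-confounding`}{the canonical four-node diagram
#'     `A -> E`, `A -> B`, `B -> D`, `E -> D` with a binary exposure E,
#'     binary outcome D, and true causal risk ratio 2.0. Its sufficient
#'     adjustment sets are `{A}`, `{B}`, `{A, B}`; the first two are
#'     minimal. The empty set leaves the backdoor path `E <- A -> B -> D`
#'     open, so the crude estimate is confounded upward.}
#'   \item{`pin-shaped`}{a pregnancy-cohort-shaped model: a 3-level
#'     exposure (`normal`/`overweight`/`obese` pre-pregnancy BMI class,
#'     marginal proportions near 0.49/0.19/0.33), a binary cesarean-
#'     delivery-like outcome with prevalence near 0.23, and seven mixed
#'     covariates (binary hypertension and pre-eclampsia, continuous
#'     weight gain, age and height, 3-level race and education) with
#'     per-column MCAR missingness so per-model complete-case counts
#'     differ across adjustment sets. Two substitutable confounder chains
#'     yield four minimally sufficient sets of five covariates each. True
#'     risk ratios: 1.4 (overweight), 1.8 (obese).}
#' }
#'
#' @param name preset name.
#' @return a [structural_model].
#' @examples
#' m <- cohort_preset("fig1-confounding")
#' d <- simulate_cohort(m, 500, seed = 42)
#' table(d$E, d$D)
#' @export
cohort_preset <- function(name = c("fig1-confounding", "pin-shaped")) {
  name <- match.arg(name)
  if (name == "fig1-confounding") {
    dag <- causal_dag("A -> E; A -> B; B -> D; E -> D; exposure: E; outcome: D")
    mech <- list(
      A = list(family = "bernoulli-logit", intercept = 0, coef = numeric(0)),
      B = list(family = "bernoulli-logit", intercept = -0.5, coef = c(A = 1.2)),
      E = list(family = "categorical-logit", levels = c("0", "1"),
               intercept = list(-0.8), coef = list(c(A = 1.5))),
      D = list(family = "bernoulli-log", intercept = log(0.06),
               coef = c(E.1 = log(2), B = log(1.8)))
    )
    return(structural_model(dag, mech,
                            missing = c(A = 0.05, B = 0.08)))
  }
  # pin-shaped: Age, Race and Educ are direct common causes (in every
  # minimal set); two substitutable confounder chains mimic the worked
  # example's pattern of interchangeable covariates —
  #   BMI <- Htn -> Preeclampsia -> Delivery   (block with Htn OR Preecl)
  #   BMI <- Height -> WtGain -> Delivery      (block with Height OR WtGain)
  # giving four minimally sufficient sets of five covariates each
  dag <- causal_dag(paste(
    "Age -> BMI; Age -> Htn; Age -> Educ; Age -> Delivery",
    "Race -> BMI; Race -> Educ; Race -> Htn; Race -> Delivery",
    "Educ -> BMI; Educ -> Delivery",
    "Htn -> BMI; Htn -> Preeclampsia; Preeclampsia -> Delivery",
    "Height -> BMI; Height -> WtGain; WtGain -> Delivery",
    "BMI -> Delivery",
    "exposure: BMI; outcome: Delivery", sep = "; "))
  mech <- list(
    Age = list(family = "gaussian-linear", intercept = 27, coef = numeric(0),
               sd = 5),
    Race = list(family = "categorical-logit", levels = c("0", "1", "2"),
                intercept = list(-1.1, -1.4), coef = list(numeric(0),
                                                          numeric(0))),
    Height = list(family = "gaussian-linear", intercept = 64,
                  coef = numeric(0), sd = 2.5),
    Educ = list(family = "categorical-logit", levels = c("0", "1", "2"),
                intercept = list(-1.4, -1.5),
                coef = list(c(Age = 0.03, Race.1 = -0.3),
                            c(Age = 0.08, Race.1 = -0.6))),
    Htn = list(family = "bernoulli-logit", intercept = -3.4,
               coef = c(Age = 0.03, Race.1 = 0.5)),
    Preeclampsia = list(family = "bernoulli-logit", intercept = -2.9,
                        coef = c(Htn = 1.2)),
    WtGain = list(family = "gaussian-linear", intercept = 9.6,
                  coef = c(Height = 0.1), sd = 5),
    BMI = list(family = "categorical-logit",
               levels = c("normal", "overweight", "obese"),
               intercept = list(-1.6, -0.9),
               coef = list(c(Age = 0.02, Race.1 = 0.4, Educ.2 = -0.2,
                             Htn = 0.5, Height = 0.002),
                           c(Age = 0.015, Race.1 = 0.7, Educ.2 = -0.4,
                             Htn = 0.9, Height = 0.002))),
    Delivery = list(family = "bernoulli-log", intercept = log(0.11),
                    coef = c(BMI.1 = log(1.4), BMI.2 = log(1.8),
                             Age = 0.012, Race.1 = 0.10, Educ.2 = -0.05,
                             Preeclampsia = 0.35, WtGain = 0.006))
  )
  structural_model(dag, mech,
                   missing = c(WtGain = 0.08, Height = 0.05, Htn = 0.03,
                               Educ = 0.02, Preeclampsia = 0.06))
}
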