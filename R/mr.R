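# Two-stage Mendelian randomization with a single additive genetic
# instrument: stage 1 regresses the exposure on allele count, stage 2
# regresses the outcome on genetically predicted exposure. Stage-2 standard
# errors are the naive second-stage regression SEs (uncorrected for stage-1
# estimation); the joint-resampling bootstrap is the remedy for that and is
# the ladder's model 4.

new_mr_estimate <- function(estimate, se, ci_low, ci_high, p, scale, method,
                            model_id = NA_integer_, n = NA_integer_,
                            outcome = NA_character_, exposure = NA_character_,
                            B = NA_integer_, n_failed = NA_integer_,
                            stage1 = NULL) {
  exponentiate <- grepl("log-odds", scale)
  structure(
    list(
      scale = scale, method = method, model_id = model_id,
      estimate = estimate, se = se,
      point = if (exponentiate) exp(estimate) else estimate,
      ci_low = if (exponentiate) exp(ci_low) else ci_low,
      ci_high = if (exponentiate) exp(ci_high) else ci_high,
      p = p, n = n, outcome = outcome, exposure = exposure,
      B = B, n_failed = n_failed, stage1 = stage1
    ),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  lab <- if (grepl("log-odds", x$scale)) "OR" else "beta"
  cat(sprintf("<%s estimate> outcome: %s%s\n", x$method, x$outcome,
              if (!is.na(x$model_id)) sprintf(" (model %d)", x$model_id) else ""))
  cat(sprintf("  %s = %.3f (95%% CI %.3f, %.3f), p = %.3g, n = %s [%s]\n",
              lab, x$point, x$ci_low, x$ci_high, x$p,
              ifelse(is.na(x$n), "?", x$n), x$scale))
  if (!is.na(x$B)) {
    cat(sprintf("  bootstrap: B = %d, failed replicates dropped = %d\n", x$B, x$n_failed))
  }
  invisible(x)
}

#' @rdname mr_two_stage
#' @param x An `mr_estimate` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mr_estimate <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, exposure = x$exposure, method = x$method,
    model_id = x$model_id, scale = x$scale,
    estimate = x$point, conf.low = x$ci_low, conf.high = x$ci_high,
    std.error = x$se, p.value = x$p, n = x$n,
    B = x$B, n_failed = x$n_failed
  )
}

#' @rdname mr_two_stage
#' @exportS3Method generics::glance
glance.mr_estimate <- function(x, ...) tidy(x)

# stage 1 ---------------------------------------------------------------------

#' Stage 1: instrument-exposure regression
#'
#' Ordinary least squares of the exposure (triglyceride, mmol/L) on the
#' additive allele count, optionally with covariates, on the complete-case
#' subset. Reports the per-allele effect, its SE, the overall regression F
#' (for one predictor, F equals the squared t-statistic) and R^2. F > 10 is
#' the conventional gate against weak-instrument bias.
#'
#' @param data A cohort data frame with a `genotype` column (allele counts or
#'   TT/TC/CC labels).
#' @param exposure Name of the exposure column (default `"triglyceride"`).
#' @param covariates Character vector of covariate column names (default
#'   none).
#' @param genotype Name of the genotype column.
#' @return An object of class `mr_stage1` with elements `beta`, `se`,
#'   `intercept`, `f_stat`, `r2`, `n`, `weak_instrument` (logical, `f_stat <=
#'   10`) and the underlying `fit`.
#' @examples
#' cohort <- simulate_comparison_cohort(sim_params(n_controls = 500))
#' stage1_fit(cohort)
#' @export
stage1_fit <- function(data, exposure = "triglyceride", covariates = NULL,
                       genotype = "genotype") {
  check_data_frame(data)
  check_columns(data, c(exposure, covariates, genotype))
  data$g_add <- parse_genotype(data[[genotype]])
  vars <- c(exposure, "g_add", covariates)
  cc <- data[complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(cc)
  if (n < 3) abort("Stage 1 needs at least 3 complete-case subjects.")
  if (var(cc$g_add) == 0) {
    abort("Singular design: no genotype variation among complete cases.")
  }
  y <- cc[[exposure]]
  if (var(y) == 0) {
    fit <- lm(reformulate(c("g_add", covariates), response = exposure), data = cc)
    out <- list(beta = 0, se = NA_real_, intercept = y[1], f_stat = 0, r2 = 0,
                n = n, weak_instrument = TRUE, exposure = exposure,
                covariates = covariates, fit = fit)
    class(out) <- "mr_stage1"
    return(out)
  }
  fit <- lm(reformulate(c("g_add", covariates), response = exposure), data = cc)
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic["value"])
  if (is.null(fstat) || is.na(fstat)) fstat <- 0
  out <- list(
    beta = unname(coef(fit)["g_add"]),
    se = unname(sm$coefficients["g_add", "Std. Error"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    f_stat = fstat,
    r2 = sm$r.squared,
    n = n,
    weak_instrument = fstat <= 10,
    exposure = exposure,
    covariates = covariates,
    fit = fit
  )
  class(out) <- "mr_stage1"
  out
}

#' @export
print.mr_stage1 <- function(x, ...) {
  cat("<stage-1 instrument fit>\n")
  cat(sprintf("  %s = %.4f + %.4f * allele count  (SE %.4f)\n",
              x$exposure, x$intercept, x$beta, x$se))
  cat(sprintf("  F = %.1f, R^2 = %.4f, n = %d%s\n", x$f_stat, x$r2, x$n,
              if (x$weak_instrument) "  [weak instrument: F <= 10]" else ""))
  invisible(x)
}

#' @rdname stage1_fit
#' @param x An `mr_stage1` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mr_stage1 <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname stage1_fit
#' @exportS3Method generics::glance
glance.mr_stage1 <- function(x, ...) {
  tibble::tibble(beta = x$beta, std.error = x$se, intercept = x$intercept,
                 f_stat = x$f_stat, r.squared = x$r2, n = x$n,
                 weak_instrument = x$weak_instrument)
}

#' Genetically predicted exposure from a stage-1 fit
#'
#' Adds the stage-1 linear prediction (`intercept + beta * allele count`, plus
#' covariate terms if stage 1 was adjusted) to each subject. With a
#' covariate-free fit the prediction takes exactly three distinct values, one
#' per genotype; missing genotypes give missing predictions.
#'
#' @param data A cohort data frame.
#' @param stage1 An `mr_stage1` object (possibly fitted on a different subset,
#'   e.g. the comparison group only).
#' @param col Name of the appended column (default `"tg_genetic"`).
#' @param genotype Name of the genotype column in `data`.
#' @return `data` with the predicted-exposure column appended.
#' @export
predict_exposure <- function(data, stage1, col = "tg_genetic",
                             genotype = "genotype") {
  check_data_frame(data)
  stopifnot(inherits(stage1, "mr_stage1"))
  check_columns(data, genotype)
  nd <- data
  nd$g_add <- parse_genotype(data[[genotype]])
  data[[col]] <- as.numeric(predict(stage1$fit, newdata = nd))
  data
}

# stage 2 ---------------------------------------------------------------------

as_binary_outcome <- function(y, outcome) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(stats::na.omit(y) %in% c(0, 1))) {
    abort(sprintf("Outcome `%s` must be binary (logical, 0/1, or a two-level factor).", outcome))
  }
  as.integer(y)
}

check_glm_fit <- function(fit, context) {
  if (!fit$converged) {
    abort(sprintf("%s: logistic regression did not converge after %d IRLS iterations (deviance %.3g).",
                  context, fit$iter, fit$deviance))
  }
  mu <- fit$fitted.values
  if ((any(mu < 1e-8) || any(mu > 1 - 1e-8)) && max(abs(coef(fit)), na.rm = TRUE) > 12) {
    abort(sprintf("%s: (quasi-)separation detected (fitted probabilities at 0/1 with coefficient magnitude %.1f).",
                  context, max(abs(coef(fit)), na.rm = TRUE)))
  }
  invisible(fit)
}

fit_stage2 <- function(data, predictor, outcome, covariates, binary, model_id,
                       method, scale_suffix = "per mmol/L") {
  vars <- c(outcome, predictor, covariates)
  check_columns(data, vars)
  cc <- data[complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(cc)
  if (n < 3) abort("Stage 2 needs at least 3 complete-case subjects.")
  if (var(cc[[predictor]]) == 0) {
    abort(sprintf("Degenerate stage 2: `%s` is constant among complete cases; no estimate.", predictor))
  }
  fml <- reformulate(c(predictor, covariates), response = outcome)
  if (binary) {
    cc[[outcome]] <- as_binary_outcome(cc[[outcome]], outcome)
    if (length(unique(cc[[outcome]])) < 2) {
      abort(sprintf("Outcome `%s` has a single class among complete cases.", outcome))
    }
    fit <- glm(fml, data = cc, family = binomial(),
               control = glm.control(epsilon = 1e-8, maxit = 100))
    check_glm_fit(fit, "stage 2")
    sm <- summary(fit)$coefficients
    est <- sm[predictor, "Estimate"]
    se <- sm[predictor, "Std. Error"]
    ci <- est + c(-1, 1) * qnorm(0.975) * se
    p <- sm[predictor, "Pr(>|z|)"]
    scale <- paste("log-odds", scale_suffix)
  } else {
    fit <- lm(fml, data = cc)
    sm <- summary(fit)$coefficients
    est <- sm[predictor, "Estimate"]
    se <- sm[predictor, "Std. Error"]
    ci <- est + c(-1, 1) * stats::qt(0.975, df = fit$df.residual) * se
    p <- sm[predictor, "Pr(>|t|)"]
    scale <- paste("outcome units", scale_suffix)
  }
  new_mr_estimate(est, se, ci[1], ci[2], p, scale, method, model_id, n,
                  outcome = outcome, exposure = predictor)
}

#' Stage 2: outcome on genetically predicted exposure
#'
#' `stage2_binary()` fits logistic regression of a binary outcome (longevity,
#' frailty phenotype) on the predicted exposure plus covariates and reports
#' the odds ratio per 1 mmol/L with a Wald 95% CI. `stage2_continuous()` fits
#' OLS for a continuous outcome (frailty index) and reports the slope with a
#' t-based 95% CI. Both use the complete cases of that model's variable set
#' and report the n actually used. Logistic fits use IRLS with convergence
#' tolerance 1e-8 and at most 100 iterations; non-convergence and separation
#' raise errors with diagnostics.
#'
#' @param data A cohort data frame carrying the predicted-exposure column
#'   (see [predict_exposure()]).
#' @param outcome Name of the outcome column.
#' @param predictor Name of the predictor column (default `"tg_genetic"`).
#' @param covariates Character vector of covariate names.
#' @param model_id Adjustment-model label (1-4) recorded in the output.
#' @return An `mr_estimate` object.
#' @export
stage2_binary <- function(data, outcome, predictor = "tg_genetic",
                          covariates = NULL, model_id = NA_integer_) {
  check_data_frame(data)
  fit_stage2(data, predictor, outcome, covariates, binary = TRUE,
             model_id = model_id, method = "two-stage")
}

#' @rdname stage2_binary
#' @export
stage2_continuous <- function(data, outcome, predictor = "tg_genetic",
                              covariates = NULL, model_id = NA_integer_) {
  check_data_frame(data)
  fit_stage2(data, predictor, outcome, covariates, binary = FALSE,
             model_id = model_id, method = "two-stage")
}

# wrappers --------------------------------------------------------------------

#' Covariate sets of the adjustment-model ladder
#'
#' Model 1 is unadjusted; model 2 adjusts for sex (longevity design) or age
#' and sex (frailty design); model 3 additionally adjusts for education,
#' marital status, smoking, drinking, BMI and systolic/diastolic blood
#' pressure; model 4 is the bootstrap validation of model 2 and shares its
#' covariates.
#'
#' @param model_id Integer 1-4.
#' @param design `"longevity"` or `"frailty"`.
#' @return Character vector of covariate column names (possibly empty).
#' @export
mr_model_covariates <- function(model_id, design = c("longevity", "frailty")) {
  design <- match.arg(design)
  if (!model_id %in% 1:4) abort("`model_id` must be in 1:4.")
  base <- if (design == "longevity") "sex" else c("age", "sex")
  extra <- c("illiterate", "currently_married", "regular_smoker",
             "regular_drinker", "bmi", "sbp", "dbp")
  switch(model_id, character(0), base, c(base, extra), base)
}

#' Two-stage Mendelian randomization in one call
#'
#' Runs stage 1 (instrument-exposure OLS, by default on `stage1_data` so the
#' case-control design can fit it in the comparison group only), predicts the
#' exposure for every subject, and runs stage 2 on the outcome. Covariates
#' adjust stage 2 only by default; set `adjust_stage1 = TRUE` to also refit
#' stage 1 with them.
#'
#' @inheritParams stage1_fit
#' @inheritParams stage2_binary
#' @param outcome_type `"binary"` (logistic stage 2) or `"continuous"` (OLS).
#' @param stage1_data Data frame used for the stage-1 fit; defaults to
#'   `data`. For a case-control outcome pass the control subset.
#' @param adjust_stage1 Logical; include the covariates in stage 1 as well.
#' @return An `mr_estimate` whose `stage1` element holds the `mr_stage1` fit.
#' @export
mr_two_stage <- function(data, outcome,
                         outcome_type = c("binary", "continuous"),
                         covariates = NULL, model_id = NA_integer_,
                         exposure = "triglyceride", genotype = "genotype",
                         stage1_data = NULL, adjust_stage1 = FALSE) {
  check_data_frame(data)
  outcome_type <- match.arg(outcome_type)
  s1 <- stage1_fit(stage1_data %||% data, exposure = exposure,
                   covariates = if (adjust_stage1) covariates else NULL,
                   genotype = genotype)
  scored <- predict_exposure(data, s1, genotype = genotype)
  est <- fit_stage2(scored, "tg_genetic", outcome, covariates,
                    binary = outcome_type == "binary",
                    model_id = model_id, method = "two-stage")
  est$stage1 <- s1
  est
}

#' Single-instrument Wald ratio
#'
#' The ratio identity for one instrument: the causal effect of the exposure on
#' the outcome is the instrument-outcome association divided by the
#' instrument-exposure association. On the odds-ratio scale,
#' `OR_causal = OR_GY ^ (1 / beta_GX)`. The (first-order) delta-method SE is
#' reported when the component SEs are supplied.
#'
#' @param assoc_GY Per-allele instrument-outcome association: a log-odds for
#'   `scale = "log-odds"`, a slope for `scale = "linear"`.
#' @param stage1_beta Per-allele instrument-exposure effect (mmol/L); must be
#'   non-zero.
#' @param se_GY,se_stage1 Optional standard errors for the delta-method CI.
#' @param scale `"log-odds"` or `"linear"`.
#' @return An `mr_estimate` with `method = "wald-ratio"` (odds ratios
#'   exponentiated for reporting).
#' @examples
#' wald_ratio(log(0.86), 0.301, scale = "log-odds") # causal OR ~0.61
#' @export
wald_ratio <- function(assoc_GY, stage1_beta, se_GY = NULL, se_stage1 = NULL,
                       scale = c("linear", "log-odds")) {
  scale <- match.arg(scale)
  if (!is.numeric(stage1_beta) || length(stage1_beta) != 1 || is.na(stage1_beta) ||
      stage1_beta == 0) {
    abort("Undefined ratio: `stage1_beta` must be a single non-zero number.")
  }
  est <- assoc_GY / stage1_beta
  se <- NA_real_
  if (!is.null(se_GY)) {
    se2 <- se_GY^2 / stage1_beta^2
    if (!is.null(se_stage1)) se2 <- se2 + assoc_GY^2 * se_stage1^2 / stage1_beta^4
    se <- sqrt(se2)
  }
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else est + c(-1, 1) * qnorm(0.975) * se
  p <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(est / se))
  lab <- if (scale == "log-odds") "log-odds per mmol/L" else "outcome units per mmol/L"
  new_mr_estimate(est, se, ci[1], ci[2], p, lab, "wald-ratio")
}

#' Observational exposure-outcome association
#'
#' The same regression machinery as stage 2 but with the measured exposure:
#' logistic regression for a binary outcome (odds ratio per 1 mmol/L) or OLS
#' for a continuous one. Flagged `method = "observational"` so it cannot be
#' confused with a causal (instrumented) estimate.
#'
#' @inheritParams mr_two_stage
#' @export
observational_assoc <- function(data, outcome,
                                outcome_type = c("binary", "continuous"),
                                exposure = "triglyceride", covariates = NULL,
                                model_id = NA_integer_) {
  check_data_frame(data)
  outcome_type <- match.arg(outcome_type)
  est <- fit_stage2(data, exposure, outcome, covariates,
                    binary = outcome_type == "binary",
                    model_id = model_id, method = "observational")
  est
}

# bootstrap -------------------------------------------------------------------

#' Joint-resampling bootstrap of the two-stage estimator
#'
#' Resamples subjects with replacement and re-runs both stages per replicate
#' (so the stage-1 estimation uncertainty that the naive stage-2 SEs ignore is
#' propagated), then forms a percentile 95% CI from the replicate estimates.
#' For a binary outcome the resampling is stratified by outcome class,
#' preserving the case-control balance. Replicates where a stage fails (no
#' genotype variation, non-convergence, separation) are dropped and counted in
#' `n_failed`. The point estimate is the full-data two-stage fit.
#'
#' @inheritParams mr_two_stage
#' @param B Number of bootstrap replications (default 1000).
#' @param seed Integer seed making the resampling reproducible.
#' @return An `mr_estimate` with percentile `ci_low`/`ci_high`, the replicate
#'   count `B`, `n_failed`, and the replicate estimates in `$replicates`.
#' @export
bootstrap_mr <- function(data, outcome,
                         outcome_type = c("binary", "continuous"),
                         covariates = NULL, model_id = 4L,
                         exposure = "triglyceride", genotype = "genotype",
                         stage1_data = NULL, adjust_stage1 = FALSE,
                         B = 1000L, seed = 1L) {
  check_data_frame(data)
  outcome_type <- match.arg(outcome_type)
  if (!is.numeric(B) || B < 1) abort("`B` must be at least 1.")
  B <- as.integer(B)
  binary <- outcome_type == "binary"

  point <- mr_two_stage(data, outcome, outcome_type, covariates, model_id,
                        exposure, genotype, stage1_data, adjust_stage1)

  # flat complete-case working set for the fast replicate loop
  vars <- unique(c(exposure, genotype, outcome, covariates))
  check_columns(data, vars)
  work <- data[complete.cases(data[vars]), vars, drop = FALSE]
  g <- parse_genotype(work[[genotype]])
  y <- if (binary) as_binary_outcome(work[[outcome]], outcome) else work[[outcome]]
  x <- work[[exposure]]
  n <- nrow(work)
  s1_internal <- is.null(stage1_data)
  # stage-1 membership: with an external stage1_data the stage-1 subjects are
  # resampled separately from it
  if (!s1_internal) {
    sw <- stage1_data[complete.cases(stage1_data[c(exposure, genotype, if (adjust_stage1) covariates)]), , drop = FALSE]
    g1 <- parse_genotype(sw[[genotype]])
    x1 <- sw[[exposure]]
    Z1 <- if (adjust_stage1) stats::model.matrix(reformulate(covariates), data = sw) else NULL
    n1 <- length(g1)
  }
  Z2 <- if (length(covariates)) {
    stats::model.matrix(reformulate(covariates), data = work)[, -1, drop = FALSE]
  } else NULL
  if (binary) {
    idx_case <- which(y == 1L)
    idx_ctrl <- which(y == 0L)
  }

  set.seed(as.integer(seed))
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- if (binary) {
      c(sample(idx_case, length(idx_case), replace = TRUE),
        sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    res <- tryCatch({
      if (s1_internal) {
        gi <- g[idx]
        if (var(gi) == 0) stop("no genotype variation")
        X1 <- cbind(1, gi)
        if (adjust_stage1 && !is.null(Z2)) X1 <- cbind(X1, Z2[idx, , drop = FALSE])
        c1 <- stats::lm.fit(X1, x[idx])$coefficients
        pred <- drop(cbind(1, g[idx]) %*% c1[1:2])
        if (adjust_stage1 && !is.null(Z2)) pred <- pred + drop(Z2[idx, , drop = FALSE] %*% c1[-(1:2)])
      } else {
        j <- sample.int(n1, n1, replace = TRUE)
        gj <- g1[j]
        if (var(gj) == 0) stop("no genotype variation")
        X1 <- cbind(1, gj)
        if (adjust_stage1 && !is.null(Z1)) X1 <- cbind(X1, Z1[j, -1, drop = FALSE])
        c1 <- stats::lm.fit(X1, x1[j])$coefficients
        pred <- c1[1] + c1[2] * g[idx]
      }
      X2 <- cbind(1, pred)
      if (!is.null(Z2)) X2 <- cbind(X2, Z2[idx, , drop = FALSE])
      if (binary) {
        fit <- suppressWarnings(stats::glm.fit(X2, y[idx], family = binomial(),
                                               control = glm.control(epsilon = 1e-8, maxit = 100)))
        if (!fit$converged) stop("non-convergence")
        fit$coefficients[2]
      } else {
        stats::lm.fit(X2, y[idx])$coefficients[2]
      }
    }, error = function(e) NA_real_)
    reps[b] <- res
  }
  ok <- reps[is.finite(reps)]
  n_failed <- B - length(ok)
  if (length(ok) == 0) abort("All bootstrap replicates failed; no CI available.")
  ci <- if (length(ok) == 1) c(ok, ok) else unname(quantile(ok, c(0.025, 0.975), type = 7))
  out <- new_mr_estimate(point$estimate, stats::sd(ok), ci[1], ci[2], point$p,
                         point$scale, "two-stage", model_id, point$n,
                         outcome = outcome, exposure = "tg_genetic",
                         B = B, n_failed = n_failed, stage1 = point$stage1)
  out$replicates <- reps
  out
}

# confounder balance -----------------------------------------------------------

#' Confounder balance across genotype groups
#'
#' Tests each requested covariate for association with genotype (TT/TC/CC
#' groups): chi-squared test for categorical covariates (logical, character,
#' factor), Kruskal-Wallis rank test for continuous ones. Large p-values
#' support the instrument's independence from measured confounders.
#'
#' @param data A cohort data frame.
#' @param covariates Character vector of covariate columns to test.
#' @param genotype Name of the genotype column.
#' @return A tibble with one row per covariate: `variable`, `test`,
#'   `statistic`, `p.value`, `n`.
#' @export
confounder_balance <- function(data, covariates, genotype = "genotype") {
  check_data_frame(data)
  check_columns(data, c(covariates, genotype))
  g <- factor(parse_genotype(data[[genotype]]), levels = 0:2,
              labels = c("TT", "TC", "CC"))
  if (all(is.na(g))) abort("No genotyped subjects.")
  purrr::map_dfr(covariates, function(v) {
    x <- data[[v]]
    keep <- !is.na(x) & !is.na(g)
    if (!any(keep)) {
      return(tibble::tibble(variable = v, test = "missing",
                            statistic = NA_real_, p.value = NA_real_, n = 0L))
    }
    xv <- x[keep]
    gv <- droplevels(g[keep])
    categorical <- is.logical(xv) || is.character(xv) || is.factor(xv)
    if (categorical) {
      tab <- table(xv, gv)
      ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tibble::tibble(variable = v, test = "chi-squared",
                     statistic = unname(ht$statistic),
                     p.value = unname(ht$p.value), n = sum(keep))
    } else {
      ht <- kruskal.test(xv, gv)
      tibble::tibble(variable = v, test = "kruskal-wallis",
                     statistic = unname(ht$statistic),
                     p.value = unname(ht$p.value), n = sum(keep))
    }
  })
}
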