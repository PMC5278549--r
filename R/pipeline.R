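# End-to-end orchestration of the two study designs:
# simulate (or load) -> genotype QC -> frailty scoring -> two-stage MR ->
# delimited-text report, from a single config with one seed.

#' Analysis configuration
#'
#' @param design `"longevity-case-control"` or `"frailty-cross-sectional"`.
#' @param params A [sim_params()] object used when no `input_path` is given;
#'   its seed is overridden by `seed`.
#' @param input_path Optional path to a cohort file ([read_cohort()] layout);
#'   when given, no simulation is performed.
#' @param models Adjustment models to run, a subset of 1:4 (model 4 is the
#'   bootstrap validation of model 2).
#' @param bootstrap_B Bootstrap replications for model 4 (default 1000).
#' @param seed Integer seed for simulation and bootstrap streams.
#' @param control_set For the longevity design: `"longevity-arm-controls"`
#'   (the comparison group only) or `"combined-controls"` (sensitivity
#'   analysis merging the ageing arm into the control set).
#' @param output_dir Optional directory; when given, the report bundle is
#'   written there as delimited text.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(design = c("longevity-case-control",
                                       "frailty-cross-sectional"),
                            params = sim_params(), input_path = NULL,
                            models = 1:4, bootstrap_B = 1000L, seed = 1L,
                            control_set = c("longevity-arm-controls",
                                            "combined-controls"),
                            output_dir = NULL) {
  design <- match.arg(design)
  control_set <- match.arg(control_set)
  if (!all(models %in% 1:4) || length(models) == 0) {
    abort("`models` must be a non-empty subset of 1:4.")
  }
  if (4 %in% models && bootstrap_B < 1) {
    abort("`bootstrap_B` must be >= 1 when model 4 is requested.")
  }
  stopifnot(inherits(params, "sim_params"))
  params$seed <- as.integer(seed)
  structure(
    list(design = design, params = params, input_path = input_path,
         models = sort(unique(as.integer(models))),
         bootstrap_B = as.integer(bootstrap_B), seed = as.integer(seed),
         control_set = control_set, output_dir = output_dir),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Top-level keys are the [analysis_config()] arguments; simulation parameters
#' go under a `simulation:` mapping with [sim_params()] key names.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation %||% list()
  raw$simulation <- NULL
  known <- setdiff(names(formals(analysis_config)), "params")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key%s: %s.",
                  if (length(unknown) > 1) "s" else "", paste(unknown, collapse = ", ")))
  }
  do.call(analysis_config, c(raw, list(params = do.call(sim_params, sim))))
}

# per-allele instrument-outcome association, with optional percentile
# bootstrap (stratified by outcome class when binary)
per_allele_assoc <- function(data, outcome, binary, covariates = NULL,
                             model_id = NA_integer_, B = NULL, seed = 1L) {
  data$g_add <- parse_genotype(data$genotype)
  vars <- c(outcome, "g_add", covariates)
  cc <- data[complete.cases(data[vars]), vars, drop = FALSE]
  est <- fit_stage2(cc, "g_add", outcome, covariates, binary = binary,
                    model_id = model_id, method = "per-allele",
                    scale_suffix = "per C allele")
  if (!is.null(B)) {
    y <- if (binary) as_binary_outcome(cc[[outcome]], outcome) else cc[[outcome]]
    Z <- if (length(covariates)) {
      stats::model.matrix(reformulate(covariates), data = cc)[, -1, drop = FALSE]
    } else NULL
    g <- cc$g_add
    n <- nrow(cc)
    if (binary) { i1 <- which(y == 1L); i0 <- which(y == 0L) }
    set.seed(as.integer(seed))
    reps <- vapply(seq_len(B), function(b) {
      idx <- if (binary) {
        c(sample(i1, length(i1), replace = TRUE), sample(i0, length(i0), replace = TRUE))
      } else sample.int(n, n, replace = TRUE)
      X <- cbind(1, g[idx])
      if (!is.null(Z)) X <- cbind(X, Z[idx, , drop = FALSE])
      tryCatch({
        if (binary) {
          fit <- suppressWarnings(stats::glm.fit(X, y[idx], family = binomial(),
                                                 control = glm.control(epsilon = 1e-8, maxit = 100)))
          if (!fit$converged) NA_real_ else fit$coefficients[2]
        } else {
          stats::lm.fit(X, y[idx])$coefficients[2]
        }
      }, error = function(e) NA_real_)
    }, numeric(1))
    ok <- reps[is.finite(reps)]
    ci <- unname(quantile(ok, c(0.025, 0.975), type = 7))
    est <- new_mr_estimate(est$estimate, stats::sd(ok), ci[1], ci[2], est$p,
                           est$scale, "per-allele", model_id, est$n,
                           outcome = outcome, exposure = "g_add",
                           B = as.integer(B), n_failed = length(reps) - length(ok))
  }
  est
}

#' Genotype-lipid association table
#'
#' Per-genotype (n, mean, SD) for each lipid, with additive per-allele and
#' dummy-coded (heterozygote and effect-homozygote vs reference-homozygote)
#' regression coefficients - the shape of a published genotype-lipid table.
#'
#' @param data A cohort data frame.
#' @param lipids Character vector of lipid columns.
#' @return A tibble, one row per lipid and genotype, with coefficient columns.
#' @export
genotype_lipid_table <- function(data, lipids = c("triglyceride", "hdl_c", "ldl_c")) {
  check_data_frame(data)
  lipids <- intersect(lipids, names(data))
  coded <- code_genotype(code_genotype(data, "additive"), "dummy")
  purrr::map_dfr(lipids, function(lp) {
    grp <- group_lipid_summary(data, value = lp)
    add <- summary(lm(reformulate("g_add", lp), data = coded))$coefficients
    dum <- summary(lm(reformulate(c("g_het", "g_hom"), lp), data = coded))$coefficients
    grp |>
      dplyr::mutate(
        lipid = lp,
        beta_vs_TT = dplyr::case_when(
          genotype == 1 ~ dum["g_het", "Estimate"],
          genotype == 2 ~ dum["g_hom", "Estimate"],
          TRUE ~ NA_real_
        ),
        p_vs_TT = dplyr::case_when(
          genotype == 1 ~ dum["g_het", "Pr(>|t|)"],
          genotype == 2 ~ dum["g_hom", "Pr(>|t|)"],
          TRUE ~ NA_real_
        ),
        beta_additive = add["g_add", "Estimate"],
        se_additive = add["g_add", "Std. Error"],
        p_additive = add["g_add", "Pr(>|t|)"]
      ) |>
      dplyr::select("lipid", dplyr::everything())
  })
}

BALANCE_COVARIATES <- c("sex", "illiterate", "currently_married",
                        "regular_smoker", "regular_drinker", "bmi", "sbp", "dbp")

run_models <- function(data, outcome, binary, design, config, stage1_data = NULL) {
  outcome_type <- if (binary) "binary" else "continuous"
  purrr::map_dfr(config$models, function(mid) {
    covs <- mr_model_covariates(mid, design)
    covs <- intersect(covs, names(data))
    if (mid == 4L) {
      pa <- per_allele_assoc(data, outcome, binary, covs, mid,
                             B = config$bootstrap_B,
                             seed = derive_seed(config$seed, 10L + mid))
      mr <- bootstrap_mr(data, outcome, outcome_type, covs, mid,
                         stage1_data = stage1_data, B = config$bootstrap_B,
                         seed = derive_seed(config$seed, 20L + mid))
    } else {
      pa <- per_allele_assoc(data, outcome, binary, covs, mid)
      mr <- mr_two_stage(data, outcome, outcome_type, covs, mid,
                         stage1_data = stage1_data)
    }
    obs <- observational_assoc(data, outcome, outcome_type,
                               covariates = covs, model_id = mid)
    dplyr::bind_rows(tidy(pa), tidy(mr), tidy(obs))
  })
}

#' Run the case-control longevity analysis end to end
#'
#' Simulates (or loads) the longevity-arm cohort, runs genotype QC and the
#' genotype-lipid table in the control set, checks confounder balance across
#' genotype groups, and fits - for each requested adjustment model - the
#' per-allele association with longevity, the two-stage MR estimate (stage 1
#' in the controls), and the observational triglyceride association. Model 4
#' is the joint-resampling bootstrap. With
#' `control_set = "combined-controls"` the ageing arm is merged into the
#' control set (sensitivity analysis).
#'
#' @param config An [analysis_config()] with `design =
#'   "longevity-case-control"`.
#' @return A list of class `mr_report`: `design`, `qc`, `lipid_table`,
#'   `balance`, `stage1` (glance tibble), `estimates`, `log`. Written as
#'   delimited text to `config$output_dir` when set.
#' @export
run_longevity_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (config$design != "longevity-case-control") {
    abort("`config$design` must be 'longevity-case-control' for this entry point.")
  }
  cohort <- if (!is.null(config$input_path)) {
    read_cohort(config$input_path)
  } else {
    simulate_longevity_cohort(config$params)
  }
  check_columns(cohort, c("arm", "genotype", "triglyceride", "longevity"))
  if (config$control_set == "combined-controls") {
    if (!is.null(config$input_path)) {
      extra <- cohort[cohort$arm == "ageing", , drop = FALSE]
      cohort <- cohort[cohort$arm != "ageing", , drop = FALSE]
    } else {
      extra <- simulate_ageing_cohort(config$params)
    }
    extra$longevity <- FALSE
    cohort <- dplyr::bind_rows(cohort, extra)
  }
  controls <- cohort[!cohort$longevity, , drop = FALSE]
  qc <- qc_report(controls)
  lipid_table <- genotype_lipid_table(controls)
  balance <- confounder_balance(cohort, intersect(BALANCE_COVARIATES, names(cohort)))
  s1 <- stage1_fit(controls)
  estimates <- run_models(cohort, "longevity", binary = TRUE,
                          design = "longevity", config = config,
                          stage1_data = controls)
  report <- structure(
    list(design = config$design, qc = qc, lipid_table = lipid_table,
         balance = balance, stage1 = glance(s1), estimates = estimates,
         log = report_log(config, estimates, nrow(cohort), nrow(controls))),
    class = "mr_report"
  )
  maybe_write_report(report, config)
  report
}

#' Run the cross-sectional frailty analysis end to end
#'
#' Simulates (or loads) the ageing-arm cohort, scores the frailty index and
#' the Fried phenotype, runs genotype QC and confounder balance, and fits -
#' for each requested adjustment model and for both frailty outcomes (FI,
#' linear; phenotype, logistic) - the per-allele association, the two-stage MR
#' estimate, and the observational triglyceride association, with model 4 as
#' the joint-resampling bootstrap.
#'
#' @param config An [analysis_config()] with `design =
#'   "frailty-cross-sectional"`.
#' @return A list of class `mr_report` as in [run_longevity_analysis()], with
#'   `estimates` covering outcomes `fi` and `frail`.
#' @export
run_frailty_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (config$design != "frailty-cross-sectional") {
    abort("`config$design` must be 'frailty-cross-sectional' for this entry point.")
  }
  cohort <- if (!is.null(config$input_path)) {
    read_cohort(config$input_path)
  } else {
    simulate_ageing_cohort(config$params)
  }
  check_columns(cohort, c("genotype", "triglyceride", deficit_cols(),
                          FRIED_SELF_REPORT, "gait_time", "sex"))
  cohort <- score_frailty(cohort)
  cohort$frail <- cohort$phenotype == "frail"
  qc <- qc_report(cohort)
  balance <- confounder_balance(cohort, intersect(c("age", BALANCE_COVARIATES), names(cohort)))
  s1 <- stage1_fit(cohort)
  estimates <- dplyr::bind_rows(
    run_models(cohort, "fi", binary = FALSE, design = "frailty", config = config),
    run_models(cohort, "frail", binary = TRUE, design = "frailty", config = config)
  )
  report <- structure(
    list(design = config$design, qc = qc,
         lipid_table = genotype_lipid_table(cohort),
         balance = balance, stage1 = glance(s1), estimates = estimates,
         log = report_log(config, estimates, nrow(cohort), nrow(cohort))),
    class = "mr_report"
  )
  maybe_write_report(report, config)
  report
}

report_log <- function(config, estimates, n_cohort, n_stage1) {
  list(
    design = config$design, seed = config$seed,
    models = config$models, bootstrap_B = config$bootstrap_B,
    control_set = config$control_set,
    n_cohort = n_cohort, n_stage1 = n_stage1,
    n_by_model = estimates |>
      dplyr::distinct(.data$outcome, .data$model_id, .data$method, .data$n),
    dropped_replicates = sum(estimates$n_failed, na.rm = TRUE),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  )
}

maybe_write_report <- function(report, config) {
  dir <- config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$qc, file.path(dir, "qc.csv"), na = "NA")
  readr::write_csv(report$lipid_table, file.path(dir, "genotype_lipid_table.csv"), na = "NA")
  readr::write_csv(report$balance, file.path(dir, "balance.csv"), na = "NA")
  readr::write_csv(report$stage1, file.path(dir, "stage1.csv"), na = "NA")
  readr::write_csv(report$estimates, file.path(dir, "estimates.csv"), na = "NA")
  writeLines(format_report(report), file.path(dir, "summary.txt"))
  invisible(NULL)
}

format_report <- function(report) {
  est <- report$estimates
  lines <- c(
    sprintf("Design: %s (seed %d)", report$design, report$log$seed),
    sprintf("Cohort n = %d; stage-1 n = %d, F = %.1f, R^2 = %.4f, beta = %.3f mmol/L per allele",
            report$log$n_cohort, report$stage1$n, report$stage1$f_stat,
            report$stage1$r.squared, report$stage1$beta),
    sprintf("HWE p = %.3f", report$qc$value[report$qc$metric == "hwe_p"]),
    "",
    "Estimates (point [95% CI], p, n):"
  )
  for (i in seq_len(nrow(est))) {
    r <- est[i, ]
    lines <- c(lines, sprintf(
      "  %-9s model %s  %-13s %6.3f [%6.3f, %6.3f]  p=%.3g  n=%d%s",
      r$outcome, r$model_id, r$method, r$estimate, r$conf.low, r$conf.high,
      r$p.value, r$n,
      if (!is.na(r$B)) sprintf("  (B=%d, %d dropped)", r$B, r$n_failed) else ""
    ))
  }
  lines
}

#' @export
print.mr_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
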