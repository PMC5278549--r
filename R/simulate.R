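# Synthetic two-arm cohort generator: a case-control longevity arm and a
# cross-sectional ageing arm with the statistical structure the two-stage MR
# analysis assumes (HWE genotypes, additive genotype -> triglyceride effect
# calibrated to a target instrument R^2, switchable causal effects on the
# outcomes, covariates independent of genotype).

#' Simulation parameters for the two-arm cohort generator
#'
#' Collects every knob of the generator with defaults matching the published
#' summary statistics of the design being emulated: C-allele frequency 0.291
#' (longevity-arm comparison group) and 0.281 (ageing arm), per-allele
#' triglyceride effect 0.301 mmol/L, instrument R^2 0.040, TT-genotype mean
#' triglyceride 1.29 mmol/L, arm sizes 438 cases / 2294 comparison subjects /
#' 1750 ageing-arm subjects. Causal effects default to the point estimates of
#' the unadjusted two-stage models: log(0.61) per mmol/L on the longevity
#' log-odds scale, 0.007 FI units per mmol/L, and log(1.91) per mmol/L on the
#' frailty-phenotype component log-odds scale; set them to 0 for null
#' simulations.
#'
#' @param q_C C-allele frequency in the longevity-arm population, in \[0, 1\].
#' @param q_C_ageing C-allele frequency in the ageing arm.
#' @param beta_GX Per-allele triglyceride effect, mmol/L.
#' @param target_R2 Instrument R^2 in \[0, 1); together with `beta_GX` and
#'   `q_C` it determines the residual triglyceride SD (see
#'   [derive_residual_sd()]).
#' @param tg_mean_TT Mean triglyceride (mmol/L) in TT homozygotes.
#' @param tg_sd Residual SD used only in the degenerate case
#'   `beta_GX = 0, target_R2 = 0` (pure-noise exposure).
#' @param causal_logOR_longevity Log-odds of longevity per 1 mmol/L
#'   triglyceride.
#' @param causal_beta_FI Frailty-index units per 1 mmol/L triglyceride.
#' @param causal_logOR_frailty Log-odds applied to each self-reported Fried
#'   component per 1 mmol/L triglyceride.
#' @param n_cases,n_controls,n_ageing Arm sizes (non-negative integers).
#' @param fi_baseline Mean latent frailty index at the population mean
#'   triglyceride level.
#' @param fi_precision Precision of the per-subject Beta-distributed latent
#'   frailty (larger = less between-subject spread around the latent mean).
#' @param covariate_spec,case_covariate_spec Named lists of covariate
#'   distribution parameters for the comparison/ageing and long-lived groups
#'   (see [default_covariate_spec()]).
#' @param seed Single integer seed; all random streams derive from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(q_C = 0.291,
                       q_C_ageing = 0.281,
                       beta_GX = 0.301,
                       target_R2 = 0.040,
                       tg_mean_TT = 1.29,
                       tg_sd = 0.9,
                       causal_logOR_longevity = log(0.61),
                       causal_beta_FI = 0.007,
                       causal_logOR_frailty = log(1.91),
                       n_cases = 438L,
                       n_controls = 2294L,
                       n_ageing = 1750L,
                       fi_baseline = 0.12,
                       fi_precision = 30,
                       covariate_spec = default_covariate_spec("comparison"),
                       case_covariate_spec = default_covariate_spec("long-lived"),
                       seed = 1L) {
  check_scalar_prob(q_C, "q_C")
  check_scalar_prob(q_C_ageing, "q_C_ageing")
  check_scalar_prob(target_R2, "target_R2", open_right = TRUE)
  for (nm in c("n_cases", "n_controls", "n_ageing")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != trunc(v)) {
      abort(sprintf("`%s` must be a single non-negative integer.", nm))
    }
  }
  for (nm in c("beta_GX", "tg_mean_TT", "causal_logOR_longevity",
               "causal_beta_FI", "causal_logOR_frailty")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (abs(causal_logOR_longevity) > 20) {
    abort("`causal_logOR_longevity` is too extreme for case sampling to be meaningful.")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed != trunc(seed)) {
    abort("`seed` must be a single integer.")
  }
  if (tg_sd <= 0) abort("`tg_sd` must be positive.")
  check_scalar_prob(fi_baseline, "fi_baseline", open_right = TRUE)
  structure(
    list(
      q_C = q_C, q_C_ageing = q_C_ageing, beta_GX = beta_GX,
      target_R2 = target_R2, tg_mean_TT = tg_mean_TT, tg_sd = tg_sd,
      causal_logOR_longevity = causal_logOR_longevity,
      causal_beta_FI = causal_beta_FI,
      causal_logOR_frailty = causal_logOR_frailty,
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      n_ageing = as.integer(n_ageing),
      fi_baseline = fi_baseline, fi_precision = fi_precision,
      covariate_spec = covariate_spec,
      case_covariate_spec = case_covariate_spec,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Default covariate distributions for the generator
#'
#' Marginal distributions (proportions for binary traits, mean/SD for
#' continuous ones) matching the published socio-demographic profiles of the
#' comparison group and the long-lived group; covariates are drawn
#' independently of genotype, encoding the instrument's independence from
#' confounders.
#'
#' @param group `"comparison"`, `"long-lived"` or `"ageing"`.
#' @return A named list of distribution parameters.
#' @export
default_covariate_spec <- function(group = c("comparison", "long-lived", "ageing")) {
  group <- match.arg(group)
  switch(group,
    "comparison" = list(
      age_mean = 70.6, age_sd = 5.3, age_min = 60, age_max = 94,
      p_female = 0.623, p_illiterate = 0.512, p_married = 0.730,
      p_smoker = 0.266, p_drinker = 0.298,
      bmi_mean = 24.1, bmi_sd = 3.4,
      sbp_mean = 148.1, sbp_sd = 25.0, dbp_mean = 82.0, dbp_sd = 13.1
    ),
    "long-lived" = list(
      age_mean = 97.4, age_sd = 2.1, age_min = 95, age_max = 110,
      p_female = 0.783, p_illiterate = 0.820, p_married = 0.052,
      p_smoker = 0.196, p_drinker = 0.385,
      bmi_mean = 21.5, bmi_sd = 4.2,
      sbp_mean = 136.7, sbp_sd = 22.9, dbp_mean = 80.1, dbp_sd = 11.0
    ),
    "ageing" = list(
      age_mean = 77, age_sd = 4.3, age_min = 70, age_max = 84,
      p_female = 0.55, p_illiterate = 0.50, p_married = 0.73,
      p_smoker = 0.27, p_drinker = 0.30,
      bmi_mean = 24.1, bmi_sd = 3.4,
      sbp_mean = 148.1, sbp_sd = 25.0, dbp_mean = 82.0, dbp_sd = 13.1
    )
  )
}

#' Residual triglyceride SD implied by a target instrument R^2
#'
#' Under Hardy-Weinberg proportions the additive genotype has variance
#' `2 q (1 - q)`, so the population instrument R^2 is
#' `beta_GX^2 * 2q(1-q) / (beta_GX^2 * 2q(1-q) + sigma^2)`. This solves for
#' the residual SD `sigma` that calibrates the generator to `target_R2`.
#'
#' @param params A [sim_params()] object.
#' @param arm `"longevity"` (uses `q_C`) or `"ageing"` (uses `q_C_ageing`).
#' @return Residual SD in mmol/L.
#' @examples
#' derive_residual_sd(sim_params()) # ~0.947 at the defaults
#' @export
derive_residual_sd <- function(params, arm = c("longevity", "ageing")) {
  stopifnot(inherits(params, "sim_params"))
  arm <- match.arg(arm)
  q <- if (arm == "longevity") params$q_C else params$q_C_ageing
  r2 <- params$target_R2
  b <- params$beta_GX
  if (r2 == 0) {
    if (b != 0) {
      abort("Degenerate parameters: target_R2 = 0 requires beta_GX = 0.")
    }
    return(params$tg_sd)
  }
  if (r2 >= 1) abort("Degenerate parameters: target_R2 must be < 1.")
  if (b == 0 || q <= 0 || q >= 1) {
    abort("Degenerate parameters: a positive target_R2 requires beta_GX != 0 and 0 < q < 1.")
  }
  var_g <- 2 * q * (1 - q)
  sqrt(b^2 * var_g * (1 - r2) / r2)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% (.Machine$integer.max - 1))
}

draw_covariates <- function(n, spec) {
  age <- pmin(pmax(round(rnorm(n, spec$age_mean, spec$age_sd)), spec$age_min), spec$age_max)
  tibble::tibble(
    age = age,
    sex = factor(ifelse(runif(n) < spec$p_female, "female", "male"),
                 levels = c("female", "male")),
    illiterate = runif(n) < spec$p_illiterate,
    currently_married = runif(n) < spec$p_married,
    regular_smoker = runif(n) < spec$p_smoker,
    regular_drinker = runif(n) < spec$p_drinker,
    bmi = pmax(rnorm(n, spec$bmi_mean, spec$bmi_sd), 12),
    sbp = pmax(rnorm(n, spec$sbp_mean, spec$sbp_sd), 70),
    dbp = pmax(rnorm(n, spec$dbp_mean, spec$dbp_sd), 40)
  )
}

# Genotype, triglyceride and the side lipids for n subjects with allele
# frequency q. Per-genotype HDL-C / LDL-C means follow the published
# genotype-lipid table; the exposure model is tg = tg_mean_TT + beta * g + e.
draw_genetics_lipids <- function(n, q, params, sigma) {
  g <- rbinom(n, 2L, q)
  # exposure model kept exactly Gaussian so the population R^2 calibration
  # and slope recovery are exact; occasional non-positive values are a known
  # unrealism of the generator
  tg <- params$tg_mean_TT + params$beta_GX * g + rnorm(n, 0, sigma)
  hdl <- 1.48 - 0.067 * g + rnorm(n, 0, 0.32)
  ldl <- 2.78 + 0.042 * g + rnorm(n, 0, 0.75)
  tibble::tibble(
    genotype = as.integer(g),
    triglyceride = tg,
    hdl_c = hdl,
    ldl_c = ldl
  )
}

#' Simulate the comparison group of the longevity arm
#'
#' Draws `n_controls` subjects with Hardy-Weinberg genotypes at `q_C`,
#' triglyceride following the additive exposure model
#' `tg = tg_mean_TT + beta_GX * g + Normal(0, sigma)` with `sigma` from
#' [derive_residual_sd()], and covariates drawn independently of genotype.
#' Output is byte-identical for a fixed seed.
#'
#' @param params A [sim_params()] object.
#' @return A tibble of subject records, `arm = "comparison"`.
#' @export
simulate_comparison_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_controls <= 0) abort("`n_controls` must be positive.")
  set.seed(derive_seed(params$seed, 0L))
  n <- params$n_controls
  sigma <- derive_residual_sd(params, "longevity")
  out <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("cmp%04d", seq_len(n)), arm = "comparison"),
    draw_covariates(n, params$covariate_spec),
    draw_genetics_lipids(n, params$q_C, params, sigma)
  )
  out$longevity <- FALSE
  out
}

#' Simulate the case-control longevity arm
#'
#' Controls are a comparison cohort; long-lived cases are drawn from the case
#' distribution implied by a logistic (rare-outcome) model in which the
#' log-odds of longevity increase by `causal_logOR_longevity` per mmol/L of
#' triglyceride. Sampling is exact by exponential tilting: the case genotype
#' distribution is proportional to `HWE(g) * exp(b * beta_GX * g)` and, within
#' genotype, case triglyceride is `Normal(mu_g + b * sigma^2, sigma^2)` with
#' `b = causal_logOR_longevity`. Under `b = 0` genotype is independent of case
#' status; the induced per-allele case-control odds ratio is
#' `exp(b * beta_GX)`.
#'
#' @param params A [sim_params()] object.
#' @return A tibble of cases (`arm = "longevity-case"`, `longevity = TRUE`)
#'   followed by controls (`arm = "comparison"`).
#' @export
simulate_longevity_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  controls <- if (params$n_controls > 0) simulate_comparison_cohort(params) else NULL
  set.seed(derive_seed(params$seed, 1L))
  n <- params$n_cases
  if (n == 0) {
    return(dplyr::bind_rows(empty_longevity_cases(), controls))
  }
  sigma <- derive_residual_sd(params, "longevity")
  b <- params$causal_logOR_longevity
  q <- params$q_C
  p_g <- c((1 - q)^2, 2 * q * (1 - q), q^2) * exp(b * params$beta_GX * (0:2))
  p_g <- p_g / sum(p_g)
  g <- sample(0:2, n, replace = TRUE, prob = p_g)
  mu <- params$tg_mean_TT + params$beta_GX * g + b * sigma^2
  tg <- mu + rnorm(n, 0, sigma)
  hdl <- 1.38 - 0.067 * g + rnorm(n, 0, 0.32)
  ldl <- 2.51 + 0.042 * g + rnorm(n, 0, 0.70)
  cases <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("lli%04d", seq_len(n)), arm = "longevity-case"),
    draw_covariates(n, params$case_covariate_spec),
    tibble::tibble(
      genotype = as.integer(g),
      triglyceride = tg,
      hdl_c = hdl,
      ldl_c = ldl
    )
  )
  cases$longevity <- TRUE
  dplyr::bind_rows(cases, controls)
}

empty_longevity_cases <- function() {
  simulate_comparison_cohort(sim_params(n_controls = 1L))[0, ]
}

#' Simulate the cross-sectional ageing arm
#'
#' Draws `n_ageing` subjects aged 70-84 with Hardy-Weinberg genotypes at
#' `q_C_ageing` and the same additive triglyceride model as the comparison
#' group. Each subject then receives:
#'
#' * 45 deficit items: a latent frailty mean
#'   `m = fi_baseline + causal_beta_FI * (tg - mean(tg))` (clamped to (0, 1))
#'   gives a per-subject latent frailty `lambda ~ Beta(m * phi, (1 - m) * phi)`;
#'   36 dichotomous items are Bernoulli(`lambda`) and 9 polychotomous items are
#'   `Binomial(4, lambda) / 4` (five equally spaced grades), so the expected
#'   frailty index equals `m` and scoring the items recovers `causal_beta_FI`.
#' * 5 Fried components: the four self-report indicators are Bernoulli with
#'   log-odds increasing by `causal_logOR_frailty` per mmol/L triglyceride
#'   around realistic marginal frequencies; up-and-go `gait_time` is
#'   sex-specific log-normal, independent of triglyceride, so slowness is
#'   defined by the within-sample 80th-percentile time.
#'
#' @param params A [sim_params()] object.
#' @return A tibble of subject records with deficit columns `d01`..`d45` and
#'   Fried component columns, `arm = "ageing"`.
#' @export
simulate_ageing_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_ageing <= 0) abort("`n_ageing` must be positive.")
  set.seed(derive_seed(params$seed, 2L))
  n <- params$n_ageing
  sigma <- derive_residual_sd(params, "ageing")
  base <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("age%04d", seq_len(n)), arm = "ageing"),
    draw_covariates(n, default_covariate_spec("ageing")),
    draw_genetics_lipids(n, params$q_C_ageing, params, sigma)
  )
  tg_center <- params$tg_mean_TT + params$beta_GX * 2 * params$q_C_ageing
  m <- pmin(pmax(params$fi_baseline + params$causal_beta_FI * (base$triglyceride - tg_center),
                 0), 0.95)
  phi <- params$fi_precision
  lambda <- numeric(n)
  pos <- m > 0
  lambda[pos] <- rbeta(sum(pos), m[pos] * phi, (1 - m[pos]) * phi)
  n_dich <- 36L
  n_poly <- N_DEFICITS - n_dich
  dich <- matrix(rbinom(n * n_dich, 1L, rep(lambda, n_dich)), nrow = n)
  poly <- matrix(rbinom(n * n_poly, 4L, rep(lambda, n_poly)) / 4, nrow = n)
  deficits <- cbind(dich, poly)
  colnames(deficits) <- deficit_cols()
  tg_c <- base$triglyceride - tg_center
  bfr <- params$causal_logOR_frailty
  p0 <- c(weight_loss = 0.10, exhaustion = 0.20, low_activity = 0.08, weakness = 0.25)
  fried <- purrr::map(p0, function(p) {
    runif(n) < stats::plogis(stats::qlogis(p) + bfr * tg_c)
  })
  gait_meanlog <- ifelse(base$sex == "female", log(10.5), log(9.5))
  gait_time <- exp(rnorm(n, gait_meanlog, 0.25))
  dplyr::bind_cols(
    base,
    tibble::as_tibble(deficits),
    tibble::as_tibble(fried),
    tibble::tibble(gait_time = gait_time)
  )
}

# cohort file IO --------------------------------------------------------------

#' Write / read a cohort as delimited text
#'
#' Cohorts are stored as comma-separated text with a header row and `NA` for
#' missing values; deficit items as `d01`..`d45`, Fried components as named
#' columns. `read_cohort()` restores column types (logical indicators, factor
#' `sex`).
#'
#' @param data A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `data` invisibly; `read_cohort()` returns
#'   a tibble.
#' @export
write_cohort <- function(data, path) {
  check_data_frame(data)
  readr::write_csv(data, path, na = "NA")
  invisible(data)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  if ("sex" %in% names(out)) out$sex <- factor(out$sex, levels = c("female", "male"))
  out
}

#' Read simulation parameters from a YAML config
#'
#' Keys are the [sim_params()] argument names; unknown keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return A `sim_params` object.
#' @export
read_sim_params <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown simulation parameter key%s: %s.",
                  if (length(unknown) > 1) "s" else "", paste(unknown, collapse = ", ")))
  }
  do.call(sim_params, raw)
}
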