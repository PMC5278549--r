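test_that("residual SD calibration solves the R^2 identity", {
  # hand-solved closed form at the default calibration:
  # 0.301^2 * 2*0.291*0.709 = 0.0373865...; sigma^2 = that * (1 - 0.04) / 0.04
  p <- sim_params()
  sigma <- derive_residual_sd(p)
  expect_equal(sigma, sqrt(0.301^2 * 2 * 0.291 * 0.709 * 0.96 / 0.04),
               tolerance = 1e-12)
  expect_equal(sigma, 0.9472, tolerance = 1e-4)
  # the identity itself: implied population R^2 equals the target
  var_g <- 2 * p$q_C * (1 - p$q_C)
  expect_equal(p$beta_GX^2 * var_g / (p$beta_GX^2 * var_g + sigma^2),
               p$target_R2, tolerance = 1e-12)

  # symmetric case: genetic variance term 1, R^2 = 0.5 -> sigma = 1
  sym <- sim_params(q_C = 0.5, beta_GX = sqrt(2), target_R2 = 0.5)
  expect_equal(derive_residual_sd(sym), 1, tolerance = 1e-12)

  # pure-noise degenerate case: beta = 0 with target 0 returns tg_sd
  noise <- sim_params(beta_GX = 0, target_R2 = 0, tg_sd = 0.7)
  expect_equal(derive_residual_sd(noise), 0.7)

  expect_error(derive_residual_sd(sim_params(beta_GX = 0, target_R2 = 0.04)),
               "Degenerate")
  expect_error(sim_params(target_R2 = 1), "target_R2")
  expect_error(sim_params(q_C = 1.2), "q_C")
  expect_error(sim_params(n_controls = -1), "non-negative")
})

test_that("generators are byte-identical for a fixed seed", {
  p <- sim_params(n_controls = 200, n_cases = 50, n_ageing = 150, seed = 99)
  expect_identical(simulate_comparison_cohort(p), simulate_comparison_cohort(p))
  expect_identical(simulate_longevity_cohort(p), simulate_longevity_cohort(p))
  expect_identical(simulate_ageing_cohort(p), simulate_ageing_cohort(p))
  # a different seed changes the draw
  p2 <- sim_params(n_controls = 200, n_cases = 50, n_ageing = 150, seed = 100)
  expect_false(identical(simulate_comparison_cohort(p), simulate_comparison_cohort(p2)))
})

test_that("comparison-cohort genotypes match the target allele frequency", {
  p <- sim_params(seed = 3)
  cohort <- simulate_comparison_cohort(p)
  expect_equal(nrow(cohort), 2294)
  q_hat <- mean(cohort$genotype) / 2
  mc_sd <- sqrt(p$q_C * (1 - p$q_C) / (2 * nrow(cohort)))
  expect_lt(abs(q_hat - p$q_C), 3 * mc_sd)

  mono <- simulate_comparison_cohort(sim_params(q_C = 0, beta_GX = 0,
                                                target_R2 = 0, n_controls = 800,
                                                seed = 4))
  expect_true(all(mono$genotype == 0))
  expect_equal(var(mono$triglyceride), 0.9^2, tolerance = 0.15)
})

test_that("HWE p-values from generated cohorts are uniform over replicates", {
  p <- sim_params(n_controls = 400)
  pvals <- vapply(1:250, function(s) {
    p$seed <- s
    hwe_test(genotype_counts(simulate_comparison_cohort(p)))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a null instrument is rejected at the nominal 5% rate", {
  p <- sim_params(beta_GX = 0, target_R2 = 0, n_controls = 250)
  pvals <- vapply(1:200, function(s) {
    p$seed <- s
    s1 <- stage1_fit(simulate_comparison_cohort(p))
    summary(s1$fit)$coefficients["g_add", "Pr(>|t|)"]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("case sampling composes effects on the log-odds scale", {
  # causal log-OR of log(0.61) per mmol/L and 0.301 mmol/L per allele imply a
  # per-allele case-control OR of 0.61^0.301 ~ 0.862
  p <- sim_params(n_cases = 4000, n_controls = 4000, seed = 12)
  cohort <- simulate_longevity_cohort(p)
  fit <- glm(longevity ~ genotype, family = binomial(), data = cohort)
  or <- exp(coef(fit)["genotype"])
  expect_equal(unname(or), 0.61^0.301, tolerance = 0.06)

  # under a null causal effect the per-allele OR is ~1 and genotype is
  # independent of case status
  p0 <- sim_params(causal_logOR_longevity = 0, n_cases = 4000,
                   n_controls = 4000, seed = 13)
  fit0 <- glm(longevity ~ genotype, family = binomial(),
              data = simulate_longevity_cohort(p0))
  expect_equal(unname(exp(coef(fit0)["genotype"])), 1, tolerance = 0.06)

  # empty case set is a valid output
  none <- simulate_longevity_cohort(sim_params(n_cases = 0, n_controls = 50, seed = 1))
  expect_equal(sum(none$longevity), 0)
  expect_equal(nrow(none), 50)
})

test_that("scoring the generated deficits recovers the FI slope", {
  slopes <- vapply(1:40, function(s) {
    cohort <- simulate_ageing_cohort(sim_params(n_ageing = 1750, seed = s))
    scored <- frailty_index(cohort)
    coef(lm(fi ~ triglyceride, data = scored))["triglyceride"]
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.007), 3 * mc_se)
})

test_that("a null FI effect yields slopes centred on zero", {
  slopes <- vapply(1:25, function(s) {
    cohort <- simulate_ageing_cohort(sim_params(n_ageing = 800, causal_beta_FI = 0,
                                                seed = s))
    coef(lm(frailty_index(cohort)$fi ~ cohort$triglyceride))[2]
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("zero baseline with zero effect gives all-zero deficits and FI 0", {
  p <- sim_params(n_ageing = 200, fi_baseline = 0, causal_beta_FI = 0, seed = 2)
  cohort <- simulate_ageing_cohort(p)
  expect_true(all(as.matrix(cohort[sprintf("d%02d", 1:45)]) == 0))
  expect_true(all(frailty_index(cohort)$fi == 0))
})

test_that("cohort files round-trip through delimited text", {
  p <- sim_params(n_ageing = 60, seed = 8)
  cohort <- simulate_ageing_cohort(p)
  cohort$triglyceride[3] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
  expect_true(any(grepl(",NA,", readLines(path)[4])))
})

test_that("simulation params read from YAML with key validation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(q_C = 0.25, n_controls = 100, seed = 5), path)
  p <- read_sim_params(path)
  expect_s3_class(p, "sim_params")
  expect_equal(p$q_C, 0.25)
  expect_equal(p$n_controls, 100L)
  yaml::write_yaml(list(q = 0.25), path)
  expect_error(read_sim_params(path), "Unknown simulation parameter")
})
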