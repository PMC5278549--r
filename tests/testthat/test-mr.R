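test_that("stage 1 fits the exact line on a 3-point dataset", {
  df <- tibble::tibble(genotype = 0:2, triglyceride = c(1, 2, 3))
  s1 <- suppressWarnings(stage1_fit(df))
  expect_equal(s1$beta, 1, tolerance = 1e-10)
  expect_equal(s1$intercept, 1, tolerance = 1e-10)
  expect_equal(s1$r2, 1, tolerance = 1e-10)
  expect_equal(s1$n, 3L)
})

test_that("stage 1 handles degenerate designs", {
  const_y <- tibble::tibble(genotype = c(0, 1, 2, 1), triglyceride = rep(1.4, 4))
  s1 <- stage1_fit(const_y)
  expect_equal(s1$beta, 0)
  expect_equal(s1$r2, 0)
  expect_equal(s1$f_stat, 0)

  const_g <- tibble::tibble(genotype = rep(1, 10), triglyceride = rnorm(10))
  expect_error(stage1_fit(const_g), "Singular design")
  expect_error(stage1_fit(const_g[1:2, ]), "at least 3")
})

test_that("stage-1 F equals the squared t-statistic for one predictor", {
  set.seed(31)
  cohort <- random_cohort(400)
  s1 <- stage1_fit(cohort)
  tval <- summary(s1$fit)$coefficients["g_add", "t value"]
  expect_equal(s1$f_stat, tval^2, tolerance = 1e-10)
  expect_false(s1$weak_instrument)
})

test_that("stage 1 recovers the calibrated slope and R^2 over replicates", {
  p <- sim_params(n_controls = 2294)
  fits <- vapply(1:60, function(s) {
    p$seed <- s
    s1 <- stage1_fit(simulate_comparison_cohort(p))
    c(s1$beta, s1$r2)
  }, numeric(2))
  expect_lt(abs(mean(fits[1, ]) - 0.301), 3 * sd(fits[1, ]) / sqrt(ncol(fits)))
  expect_lt(abs(mean(fits[2, ]) - 0.040), 3 * sd(fits[2, ]) / sqrt(ncol(fits)))
})

test_that("predicted exposure is the stage-1 line with missingness propagated", {
  train <- tibble::tibble(genotype = rep(0:2, each = 2),
                          triglyceride = c(1.29, 1.29, 1.591, 1.591, 1.892, 1.892))
  s1 <- suppressWarnings(stage1_fit(train))
  newdata <- tibble::tibble(genotype = c(2, 0, NA))
  pred <- predict_exposure(newdata, s1)
  expect_equal(pred$tg_genetic, c(1.892, 1.29, NA), tolerance = 1e-10)
  # covariate-free predictions take exactly three distinct values
  set.seed(5)
  cohort <- random_cohort(200)
  expect_lte(length(unique(predict_exposure(cohort, s1)$tg_genetic)), 3)
  # a flat stage 1 predicts the intercept everywhere
  flat <- stage1_fit(tibble::tibble(genotype = c(0, 1, 2), triglyceride = rep(1.4, 3)))
  expect_equal(predict_exposure(newdata[1:2, ], flat)$tg_genetic, c(1.4, 1.4))
})

test_that("two-stage equals the Wald ratio exactly for continuous outcomes", {
  set.seed(41)
  for (i in 1:10) {
    cohort <- random_cohort(150 + 50 * i)
    cohort$fi <- 0.1 + 0.01 * cohort$triglyceride + rnorm(nrow(cohort), 0, 0.05)
    ts <- mr_two_stage(cohort, "fi", "continuous")
    gy <- coef(lm(fi ~ genotype, data = cohort))["genotype"]
    gx <- coef(lm(triglyceride ~ genotype, data = cohort))["genotype"]
    wr <- wald_ratio(unname(gy), unname(gx))
    expect_equal(ts$estimate, wr$estimate, tolerance = 1e-8)
  }
})

test_that("Wald ratio reproduces ratio arithmetic and error cases", {
  # odds-ratio scale: 0.86 per allele over 0.301 mmol/L per allele
  wr <- wald_ratio(log(0.86), 0.301, scale = "log-odds")
  expect_equal(wr$point, 0.86^(1 / 0.301), tolerance = 1e-12)
  expect_equal(round(wr$point, 2), 0.61)
  # a null association maps to the null for any instrument strength
  expect_equal(wald_ratio(log(1), 0.55, scale = "log-odds")$point, 1)
  # linear scale
  expect_equal(wald_ratio(0.003, 0.375)$estimate, 0.008, tolerance = 1e-12)
  expect_error(wald_ratio(0.1, 0), "Undefined ratio")
  # delta-method CI appears when SEs are supplied and brackets the point
  wr2 <- wald_ratio(log(0.86), 0.301, se_GY = 0.085, se_stage1 = 0.031,
                    scale = "log-odds")
  expect_true(wr2$ci_low < wr2$point && wr2$point < wr2$ci_high)
})

test_that("stage 2 validates outcomes and degenerate predictors", {
  set.seed(51)
  cohort <- random_cohort(200)
  cohort$y <- runif(200) < 0.3
  cohort$tg_genetic <- 1.5
  expect_error(stage2_binary(cohort, "y"), "constant")
  cohort$tg_genetic <- 1.3 + 0.3 * cohort$genotype
  cohort$y3 <- sample(0:2, 200, replace = TRUE)
  expect_error(stage2_binary(cohort, "y3"), "binary")
  cohort$y1 <- TRUE
  expect_error(stage2_binary(cohort, "y1"), "single class")
})

test_that("complete-case n is reported per model and never exceeds cohort size", {
  set.seed(61)
  cohort <- random_cohort(300)
  cohort$fi <- 0.1 + 0.007 * cohort$triglyceride + rnorm(300, 0, 0.05)
  cohort$sex <- factor(sample(c("female", "male"), 300, replace = TRUE))
  cohort$sex[1:30] <- NA
  m1 <- mr_two_stage(cohort, "fi", "continuous", model_id = 1L)
  m2 <- mr_two_stage(cohort, "fi", "continuous", covariates = "sex", model_id = 2L)
  expect_equal(m1$n, 300L)
  expect_equal(m2$n, 270L)
  expect_lte(m2$n, nrow(cohort))
})

test_that("bootstrap CIs are reproducible, bracket the estimate, and degrade at B = 1", {
  set.seed(71)
  cohort <- random_cohort(400)
  cohort$fi <- 0.1 + 0.01 * cohort$triglyceride + rnorm(400, 0, 0.05)
  b1 <- bootstrap_mr(cohort, "fi", "continuous", B = 200, seed = 5)
  b2 <- bootstrap_mr(cohort, "fi", "continuous", B = 200, seed = 5)
  expect_identical(b1$replicates, b2$replicates)
  expect_lt(b1$ci_low, b1$estimate)
  expect_gt(b1$ci_high, b1$estimate)
  expect_equal(b1$n_failed, 0L)

  single <- bootstrap_mr(cohort, "fi", "continuous", B = 1, seed = 9)
  expect_equal(single$ci_low, single$ci_high)

  # binary outcome path with an external stage-1 subset
  p <- sim_params(n_cases = 150, n_controls = 450, seed = 3)
  lc <- simulate_longevity_cohort(p)
  bb <- bootstrap_mr(lc, "longevity", "binary", B = 60, seed = 4,
                     stage1_data = lc[!lc$longevity, ])
  expect_true(bb$ci_low < bb$ci_high)
  expect_equal(bb$B, 60L)
})

test_that("observational estimates are flagged and contrast with MR under confounding", {
  # strong confounder, zero causal effect: the observational association is
  # biased while the instrumented one is centred on the null
  set.seed(81)
  n <- 3000
  u <- rnorm(n)
  g <- rbinom(n, 2, 0.3)
  cohort <- tibble::tibble(
    genotype = g,
    triglyceride = 1.3 + 0.3 * g + 0.6 * u + rnorm(n, 0, 0.7),
    y = runif(n) < stats::plogis(-1 + 1.2 * u)
  )
  obs <- observational_assoc(cohort, "y", "binary")
  mr <- mr_two_stage(cohort, "y", "binary")
  expect_equal(obs$method, "observational")
  expect_lt(obs$p, 1e-6)
  expect_gt(mr$p, 0.001)

  # exposure independent of outcome: OR ~ 1
  cohort$y2 <- runif(n) < 0.3
  null_obs <- observational_assoc(cohort, "y2", "binary")
  expect_true(null_obs$ci_low < 1 && 1 < null_obs$ci_high)
})

test_that("confounder balance picks the right test per covariate type", {
  # identical distributions across genotype groups: Kruskal-Wallis statistic 0
  toy <- tibble::tibble(genotype = rep(0:2, each = 3), x = rep(1:3, 3))
  bal <- confounder_balance(toy, "x")
  expect_equal(bal$test, "kruskal-wallis")
  expect_equal(bal$statistic, 0, tolerance = 1e-12)

  # covariate equal to genotype: near-zero p from the chi-squared test
  set.seed(91)
  g <- rbinom(500, 2, 0.3)
  df <- tibble::tibble(genotype = g, same = factor(g),
                       num = rnorm(500), gone = NA_real_)
  bal2 <- confounder_balance(df, c("same", "num", "gone"))
  expect_equal(bal2$test, c("chi-squared", "kruskal-wallis", "missing"))
  expect_lt(bal2$p.value[1], 1e-10)
  expect_gt(bal2$p.value[2], 0.001)
  expect_true(is.na(bal2$p.value[3]))
})

test_that("balance p-values are uniform when covariates are independent of genotype", {
  pvals <- vapply(1:120, function(s) {
    set.seed(s)
    df <- tibble::tibble(genotype = rbinom(300, 2, 0.3), x = rnorm(300))
    confounder_balance(df, "x")$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("tidiers return one-row summaries on the reporting scale", {
  set.seed(101)
  p <- sim_params(n_cases = 120, n_controls = 400, seed = 6)
  lc <- simulate_longevity_cohort(p)
  est <- mr_two_stage(lc, "longevity", "binary", model_id = 1L,
                      stage1_data = lc[!lc$longevity, ])
  td <- tidy(est)
  expect_equal(nrow(td), 1)
  expect_equal(td$estimate, exp(est$estimate))
  expect_true(td$conf.low <= td$estimate && td$estimate <= td$conf.high)
  g1 <- glance(est$stage1)
  expect_equal(g1$n, est$stage1$n)
  expect_s3_class(tidy(est$stage1), "tbl_df")
})
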