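test_that("frailty index is the mean of 45 deficits in [0, 1]", {
  expect_equal(frailty_index(deficit_row(rep(0, 45)))$fi, 0)
  expect_equal(frailty_index(deficit_row(rep(1, 45)))$fi, 1)
  expect_equal(frailty_index(deficit_row(c(rep(1, 9), rep(0, 36))))$fi, 0.2)
  expect_error(frailty_index(deficit_row(c(1.2, rep(0, 44)))), "\\[0, 1\\]")
  expect_error(frailty_index(deficit_row(rep(0, 45))[, 1:40]), "45 deficit columns")
})

test_that("missing deficits rescale the denominator only when >= 80% observed", {
  v <- rep(0.5, 45)
  v[1:9] <- NA # 36 observed: boundary of the 80% rule
  r <- frailty_index(deficit_row(v))
  expect_equal(r$fi, 0.5)
  expect_equal(r$n_deficits_used, 36L)

  v[1:10] <- NA # 35 observed: below the rule
  expect_true(is.na(frailty_index(deficit_row(v))$fi))

  # strict policy: any missing item voids the score
  v2 <- rep(0.2, 45); v2[45] <- NA
  expect_true(is.na(frailty_index(deficit_row(v2), policy = "strict")$fi))
  expect_equal(frailty_index(deficit_row(rep(0.2, 45)), policy = "strict")$fi, 0.2)
})

test_that("frailty index is permutation-invariant and monotone", {
  set.seed(11)
  for (i in 1:25) {
    v <- round(runif(45), 3)
    fi0 <- frailty_index(deficit_row(v))$fi
    expect_equal(frailty_index(deficit_row(sample(v)))$fi, fi0, tolerance = 1e-12)
    j <- sample(45, 1)
    w <- v
    w[j] <- min(1, v[j] + runif(1) * (1 - v[j]) + 1e-6)
    w[j] <- min(w[j], 1)
    expect_gte(frailty_index(deficit_row(w))$fi, fi0)
  }
})

test_that("slowness cutoff is the 80th-percentile time, ties non-slow", {
  x <- tibble::tibble(sex = rep("female", 10), gait_time = as.numeric(1:10))
  cut <- slowness_threshold(x)
  # brute-force type-7 quantile of 1..10 at 0.8: 1 + 0.8 * 9 = 8.2
  expect_equal(cut$cutoff, 8.2)
  flagged <- x$gait_time > cut$cutoff
  expect_equal(sum(flagged), 2)
  expect_equal(x$gait_time[flagged], c(9, 10))

  # all times equal: nobody strictly above the cutoff
  eq <- tibble::tibble(sex = rep("male", 8), gait_time = rep(7, 8))
  cut_eq <- slowness_threshold(eq)
  expect_equal(sum(eq$gait_time > cut_eq$cutoff), 0)

  # disjoint sexes get independent cutoffs
  two <- tibble::tibble(sex = rep(c("female", "male"), each = 10),
                        gait_time = c(1:10, 101:110))
  cuts <- slowness_threshold(two)
  expect_equal(sort(cuts$cutoff), c(8.2, 108.2))

  # an undersized stratum is signalled
  tiny <- tibble::tibble(sex = c(rep("female", 10), "male"),
                         gait_time = c(1:10, 5))
  expect_warning(cut_tiny <- slowness_threshold(tiny), "fewer than")
  expect_true(is.na(cut_tiny$cutoff[cut_tiny$sex == "male"]))
})

test_that("about 20% are flagged slow in large continuous samples, per sex", {
  set.seed(21)
  n <- 4000
  x <- tibble::tibble(sex = sample(c("female", "male"), n, replace = TRUE),
                      gait_time = exp(rnorm(n, log(10), 0.3)))
  cuts <- slowness_threshold(x)
  merged <- dplyr::left_join(x, cuts, by = "sex")
  frac <- tapply(merged$gait_time > merged$cutoff, merged$sex, mean)
  expect_true(all(abs(frac - 0.2) < 0.02))
})

test_that("Fried phenotype is frail iff >= 3 of 5 criteria, on all complete patterns", {
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(patterns) <- c("weight_loss", "exhaustion", "low_activity", "weakness", "slow")
  for (i in seq_len(nrow(patterns))) {
    p <- patterns[i, ]
    df <- fried_row(p$weight_loss, p$exhaustion, p$low_activity, p$weakness, p$slow)
    out <- fried_phenotype(df, cutoffs = fixed_cutoff)
    n_true <- sum(unlist(p))
    expect_equal(out$n_criteria_met, n_true)
    expect_equal(as.character(out$phenotype),
                 if (n_true >= 3) "frail" else "non-frail")
  }
})

test_that("Fried phenotype with missing components stays decidable when possible", {
  # 2 true, 2 false, 1 missing: could be 2 or 3 -> undecidable
  df <- fried_row(TRUE, TRUE, FALSE, FALSE, NA)
  expect_true(is.na(fried_phenotype(df, cutoffs = fixed_cutoff)$phenotype))

  # 3 observed-true with 2 missing: frail regardless of the missing ones
  df2 <- fried_row(TRUE, TRUE, NA, NA, TRUE)
  expect_equal(as.character(fried_phenotype(df2, cutoffs = fixed_cutoff)$phenotype), "frail")

  # 3 observed-false with 2 missing: cannot reach 3 true
  df3 <- fried_row(FALSE, FALSE, NA, NA, FALSE)
  expect_equal(as.character(fried_phenotype(df3, cutoffs = fixed_cutoff)$phenotype), "non-frail")
})

test_that("deficit codebooks read, validate and score raw levels", {
  path <- withr::local_tempfile(fileext = ".yaml")
  items <- lapply(1:45, function(i) {
    if (i <= 40) {
      list(name = sprintf("item_%02d", i), kind = "dichotomous",
           levels = list(no = 0, yes = 1))
    } else {
      list(name = sprintf("graded_%02d", i), kind = "polychotomous",
           levels = c("never", "sometimes", "often"))
    }
  })
  yaml::write_yaml(items, path)
  cb <- read_deficit_codebook(path)
  expect_s3_class(cb, "deficit_codebook")
  expect_equal(nrow(cb), 45)
  # label-only polychotomous items get equally spaced grades
  expect_equal(unname(cb$map[[45]]), c(0, 0.5, 1))

  raw <- deficit_row(rep("no", 45))
  raw[, 41:45] <- "often"
  scored <- apply_codebook(raw, cb)
  expect_equal(frailty_index(scored)$fi, 5 / 45)

  bad <- items
  bad[[1]]$levels <- list(no = 0.2, yes = 1)
  yaml::write_yaml(bad, path)
  expect_error(read_deficit_codebook(path), "include 0")
})

test_that("score_frailty appends fi and phenotype to a simulated ageing cohort", {
  cohort <- simulate_ageing_cohort(sim_params(n_ageing = 300, seed = 5))
  scored <- score_frailty(cohort)
  expect_true(all(scored$fi >= 0 & scored$fi <= 1))
  expect_true(all(scored$n_deficits_used == 45))
  expect_true(all(!is.na(scored$phenotype)))
  expect_equal(scored$phenotype == "frail", scored$n_criteria_met >= 3)
})
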