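# fixtures built in code, shared across test files

# a one-row tibble of 45 deficit columns from a length-45 numeric vector
deficit_row <- function(values) {
  stopifnot(length(values) == 45)
  tibble::tibble(!!!stats::setNames(as.list(values), sprintf("d%02d", 1:45)))
}

# several subjects: a matrix (rows = subjects) of 45 deficit values
deficit_rows <- function(mat) {
  colnames(mat) <- sprintf("d%02d", 1:45)
  tibble::as_tibble(mat)
}

# minimal Fried-component tibble; slow is induced by gait_time vs a cutoff of
# 10 s (sex constant), so gait_time 12 = slow, 8 = not slow
fried_row <- function(weight_loss, exhaustion, low_activity, weakness, slow) {
  tibble::tibble(
    weight_loss = weight_loss, exhaustion = exhaustion,
    low_activity = low_activity, weakness = weakness,
    gait_time = ifelse(is.na(slow), NA_real_, ifelse(slow, 12, 8)),
    sex = "female"
  )
}

fixed_cutoff <- tibble::tibble(sex = "female", cutoff = 10, n = 100L)

# small random genotype/exposure cohort for regression identities
random_cohort <- function(n, q = 0.3, beta = 0.3, sd = 0.9, intercept = 1.3) {
  g <- stats::rbinom(n, 2, q)
  tibble::tibble(
    genotype = g,
    triglyceride = intercept + beta * g + stats::rnorm(n, 0, sd)
  )
}
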