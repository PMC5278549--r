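# Reconstruction of regression and association quantities from per-genotype
# summary statistics (counts, means, SDs) - the bridge between a published
# genotype-lipid table and testable regression numbers. With an additive
# genotype taking only the values 0/1/2, count-weighted OLS of the group
# means on allele count is algebraically identical to individual-level OLS.

#' Regression from per-genotype summary statistics
#'
#' Recovers the per-allele slope, R^2 and regression F from a grouped summary
#' (one row per genotype with `n`, `mean`, `sd`). The slope is count-weighted
#' least squares of group means on allele count, exact because the predictor
#' takes only three values. R^2 pools the within-group variance from the SDs:
#' `r2 = SS_regression / (SS_regression + SS_between_residual + SS_within)`,
#' and `F = (N - 2) * r2 / (1 - r2)` (one predictor, N - 2 residual df).
#'
#' @param summary A data frame with columns `genotype` (0/1/2 allele counts or
#'   TT/TC/CC labels), `n`, `mean`, and (for `r2`/`f_stat`) `sd`.
#' @param within Within-group sum-of-squares convention: `"population"`
#'   (default) weights each group SD^2 by `n`; `"sample"` weights by `n - 1`.
#' @return A one-row tibble: `slope`, `intercept`, `r2`, `f_stat`, `n`.
#' @examples
#' tg <- tibble::tibble(genotype = c("TT", "TC", "CC"), n = c(1150, 953, 191),
#'                      mean = c(1.29, 1.46, 2.09), sd = c(0.82, 0.86, 1.70))
#' grouped_ols(tg)
#' @export
grouped_ols <- function(summary, within = c("population", "sample")) {
  check_data_frame(summary, "summary")
  within <- match.arg(within)
  check_columns(summary, c("genotype", "n", "mean"), arg = "summary")
  x <- as.numeric(parse_genotype(summary$genotype))
  w <- as.numeric(summary$n)
  m <- as.numeric(summary$mean)
  if (any(w < 0) || any(is.na(w))) abort("Group counts `n` must be non-negative.")
  keep <- w > 0
  if (sum(keep) < 2) abort("Undefined slope: at least two non-empty genotype groups are required.")
  x <- x[keep]; w <- w[keep]; m <- m[keep]
  N <- sum(w)
  xbar <- sum(w * x) / N
  ybar <- sum(w * m) / N
  slope <- sum(w * (x - xbar) * (m - ybar)) / sum(w * (x - xbar)^2)
  intercept <- ybar - slope * xbar
  r2 <- f_stat <- NA_real_
  if ("sd" %in% names(summary)) {
    s <- as.numeric(summary$sd)[keep]
    if (any(s < 0, na.rm = TRUE)) abort("Group SDs must be non-negative.")
    s[is.na(s) & w <= 1] <- 0 # a singleton group contributes no within-group spread
    ss_reg <- sum(w * (intercept + slope * x - ybar)^2)
    ss_between <- sum(w * (m - ybar)^2)
    ss_within <- if (within == "population") sum(w * s^2) else sum((w - 1) * s^2)
    ss_tot <- ss_between + ss_within
    r2 <- if (ss_tot > 0) ss_reg / ss_tot else 0
    f_stat <- if (r2 < 1) (N - 2) * r2 / (1 - r2) else Inf
  }
  tibble::tibble(slope = slope, intercept = intercept, r2 = r2,
                 f_stat = f_stat, n = N)
}

#' Summarise a cohort into the grouped per-genotype shape
#'
#' The inverse bridge: collapses individual-level data to the (genotype, n,
#' mean, sd) layout that [grouped_ols()] consumes, for round-trip checks and
#' for emitting genotype-lipid tables.
#'
#' @param data A cohort data frame.
#' @param value Name of the numeric column to summarise (default
#'   `"triglyceride"`).
#' @param genotype Name of the genotype column.
#' @return A tibble with one row per genotype: `genotype`, `n`, `mean`, `sd`.
#' @export
group_lipid_summary <- function(data, value = "triglyceride", genotype = "genotype") {
  check_data_frame(data)
  check_columns(data, c(value, genotype))
  g <- parse_genotype(data[[genotype]])
  keep <- !is.na(g) & !is.na(data[[value]])
  tibble::tibble(genotype = g[keep], value = data[[value]][keep]) |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")
}

#' Read a grouped per-genotype summary from delimited text
#'
#' Expects columns `genotype`, `n`, `mean`, `sd` (one row per genotype),
#' optionally with a `lipid` column distinguishing several analytes.
#'
#' @param path Path to a comma-separated file.
#' @return A tibble.
#' @export
read_grouped_summary <- function(path) {
  out <- readr::read_csv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  check_columns(out, c("genotype", "n", "mean"), arg = "grouped summary file")
  out
}

#' Per-allele odds ratio from case and control genotype counts
#'
#' Tallies alleles into a 2x2 table (effect/reference allele by case/control)
#' and returns the allelic odds ratio with a log-scale Wald 95% CI. Zero cells
#' receive the Haldane-Anscombe 0.5 correction and are flagged.
#'
#' @param case_counts,control_counts Genotype counts (see
#'   [allele_frequencies()] for accepted forms).
#' @return A one-row tibble: `or`, `conf.low`, `conf.high`, `log_or`,
#'   `std.error`, `p.value`, `corrected`.
#' @examples
#' allelic_or(c(243, 161, 34), c(1150, 953, 191))
#' @export
allelic_or <- function(case_counts, control_counts) {
  ca <- as_counts3(case_counts)
  co <- as_counts3(control_counts)
  a <- 2 * ca[3] + ca[2]  # effect alleles, cases
  b <- 2 * ca[1] + ca[2]  # reference alleles, cases
  c_ <- 2 * co[3] + co[2] # effect alleles, controls
  d <- 2 * co[1] + co[2]  # reference alleles, controls
  if ((a + c_) == 0 || (b + d) == 0) {
    abort("Both alleles must be observed in at least one group.")
  }
  cells <- c(a, b, c_, d)
  corrected <- any(cells == 0)
  if (corrected) {
    warn("Zero allele cell: Haldane-Anscombe 0.5 correction applied.")
    cells <- cells + 0.5
  }
  log_or <- log(cells[1] / cells[2]) - log(cells[3] / cells[4])
  se <- sqrt(sum(1 / cells))
  ci <- log_or + c(-1, 1) * qnorm(0.975) * se
  tibble::tibble(
    or = exp(log_or), conf.low = exp(ci[1]), conf.high = exp(ci[2]),
    log_or = log_or, std.error = se,
    p.value = 2 * pnorm(-abs(log_or / se)),
    corrected = corrected
  )
}
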