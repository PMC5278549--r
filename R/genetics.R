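# Genotype QC for a single biallelic variant: counts, allele frequencies,
# Hardy-Weinberg equilibrium, additive/dummy design coding.

#' Parse two-letter genotype labels into effect-allele counts
#'
#' Converts genotype strings such as `"TT"`, `"TC"`, `"CC"` into counts of the
#' effect allele (0, 1, 2). Heterozygotes may be written in either order.
#'
#' @param x Character vector of two-letter genotypes, or a numeric vector of
#'   allele counts (returned unchanged after validation).
#' @param effect_allele Single character, the allele to count (default `"C"`).
#' @param other_allele Single character, the non-effect allele (default `"T"`).
#' @return Integer vector of effect-allele counts with `NA` preserved.
#' @examples
#' parse_genotype(c("TT", "TC", "CT", "CC", NA))
#' @export
parse_genotype <- function(x, effect_allele = "C", other_allele = "T") {
  if (is.numeric(x)) {
    check_genotype_values(x)
    return(as.integer(x))
  }
  x <- toupper(as.character(x))
  x[x %in% c("", "NA")] <- NA_character_
  valid <- c(
    strrep(other_allele, 2),
    paste0(other_allele, effect_allele),
    paste0(effect_allele, other_allele),
    strrep(effect_allele, 2)
  )
  bad <- !is.na(x) & !(x %in% valid)
  if (any(bad)) {
    abort(sprintf(
      "Unrecognised genotype label%s: %s (expected combinations of '%s' and '%s').",
      if (sum(bad) > 1) "s" else "", paste(unique(x[bad]), collapse = ", "),
      other_allele, effect_allele
    ))
  }
  out <- rep(NA_integer_, length(x))
  out[x == valid[1]] <- 0L
  out[x %in% valid[2:3]] <- 1L
  out[x == valid[4]] <- 2L
  out
}

#' Tabulate genotype counts for one biallelic variant
#'
#' @param data A data frame with one row per subject.
#' @param genotype Column holding the genotype, either as an effect-allele
#'   count (0/1/2) or as two-letter labels. Tidy-eval: pass the bare column
#'   name.
#' @param effect_allele,other_allele Allele labels used when `genotype` holds
#'   strings, and used to name the count columns.
#' @return A one-row tibble of class `genotype_counts` with columns `n_TT`,
#'   `n_TC`, `n_CC` (named after the alleles), `n` (total non-missing) and
#'   `n_missing`.
#' @examples
#' cohort <- tibble::tibble(genotype = c(0, 0, 1, 2, NA))
#' genotype_counts(cohort)
#' @export
genotype_counts <- function(data, genotype = genotype,
                            effect_allele = "C", other_allele = "T") {
  check_data_frame(data)
  g_col <- as_name(enquo(genotype))
  check_columns(data, g_col)
  g <- parse_genotype(data[[g_col]], effect_allele, other_allele)
  out <- tibble::tibble(
    n_TT = sum(g == 0L, na.rm = TRUE),
    n_TC = sum(g == 1L, na.rm = TRUE),
    n_CC = sum(g == 2L, na.rm = TRUE),
    n = sum(!is.na(g)),
    n_missing = sum(is.na(g))
  )
  names(out)[1:3] <- c(
    paste0("n_", strrep(other_allele, 2)),
    paste0("n_", other_allele, effect_allele),
    paste0("n_", strrep(effect_allele, 2))
  )
  class(out) <- c("genotype_counts", class(out))
  out
}

# Accepts a genotype_counts tibble, a length-3 numeric (TT, het, CC), or a
# data frame of raw genotypes; returns c(n0, n1, n2).
as_counts3 <- function(counts) {
  if (inherits(counts, "genotype_counts") ||
      (is.data.frame(counts) && ncol(counts) >= 3 && all(startsWith(names(counts)[1:3], "n_")))) {
    out <- as.numeric(counts[1, 1:3])
  } else if (is.numeric(counts) && length(counts) == 3) {
    out <- as.numeric(counts)
  } else if (is.data.frame(counts) && "genotype" %in% names(counts)) {
    out <- as.numeric(genotype_counts(counts)[1, 1:3])
  } else {
    abort("`counts` must be a genotype_counts tibble, a length-3 numeric vector (homozygous reference, heterozygous, homozygous effect), or a cohort data frame with a `genotype` column.")
  }
  if (any(out < 0) || any(!is.finite(out))) abort("Genotype counts must be non-negative and finite.")
  out
}

#' Allele frequencies from genotype counts
#'
#' Computes effect- and reference-allele frequencies by gene counting:
#' `freq_C = (2 * n_CC + n_TC) / (2 * N)`.
#'
#' @param counts Genotype counts: a [genotype_counts()] tibble, a length-3
#'   numeric vector `(n_TT, n_TC, n_CC)`, or a cohort data frame with a
#'   `genotype` column.
#' @return A two-row tibble with columns `allele`, `count`, `freq`.
#' @examples
#' allele_frequencies(c(1150, 953, 191))
#' @export
allele_frequencies <- function(counts) {
  n <- as_counts3(counts)
  N <- sum(n)
  if (N < 1) abort("Empty cohort: at least one genotyped subject is required.")
  n_T <- 2 * n[1] + n[2]
  n_C <- 2 * n[3] + n[2]
  tibble::tibble(
    allele = c("T", "C"),
    count = c(n_T, n_C),
    freq = c(n_T, n_C) / (2 * N)
  )
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-squared test comparing observed genotype counts
#' to the counts expected under Hardy-Weinberg proportions
#' `N * (p^2, 2pq, q^2)`, with the allele frequency estimated from the sample
#' by gene counting. No continuity correction is applied. One degree of
#' freedom (3 genotype classes, minus 1, minus 1 estimated allele frequency).
#'
#' @inheritParams allele_frequencies
#' @return An object of class `hwe_test` with elements `chi2`, `df`, `p`,
#'   `observed`, `expected` and `n`. Use [tidy()] for a one-row tibble.
#' @examples
#' hwe_test(c(1150, 953, 191))
#' @export
hwe_test <- function(counts) {
  n <- as_counts3(counts)
  N <- sum(n)
  if (N < 1) abort("Empty cohort: at least one genotyped subject is required.")
  q <- (2 * n[3] + n[2]) / (2 * N)
  if (q == 0 || q == 1) {
    warn("Monomorphic variant: Hardy-Weinberg test is degenerate; p reported as 1.")
    expected <- N * c((1 - q)^2, 2 * q * (1 - q), q^2)
    out <- list(chi2 = 0, df = 1L, p = 1, observed = n, expected = expected, n = N)
    class(out) <- "hwe_test"
    return(out)
  }
  expected <- N * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((n - expected)^2 / expected)
  out <- list(
    chi2 = chi2,
    df = 1L,
    p = pchisq(chi2, df = 1, lower.tail = FALSE),
    observed = n,
    expected = expected,
    n = N
  )
  class(out) <- "hwe_test"
  out
}

#' @export
print.hwe_test <- function(x, ...) {
  cat("Hardy-Weinberg equilibrium test (1-df goodness of fit)\n")
  cat(sprintf("  observed: %s\n", paste(format(x$observed), collapse = " / ")))
  cat(sprintf("  expected: %s\n", paste(format(round(x$expected, 1)), collapse = " / ")))
  cat(sprintf("  chi-squared = %.4g, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' @rdname hwe_test
#' @param x An `hwe_test` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hwe_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$chi2, df = x$df, p.value = x$p,
    n = x$n,
    expected_TT = x$expected[1], expected_het = x$expected[2],
    expected_CC = x$expected[3]
  )
}

#' Add additive or dummy genotype coding columns
#'
#' Additive coding is the effect-allele count in a single column; dummy coding
#' is a pair of indicators contrasting heterozygotes and effect-homozygotes
#' against the reference homozygote. Missing genotypes propagate as `NA`.
#'
#' @inheritParams genotype_counts
#' @param scheme `"additive"` (one column `g_add`) or `"dummy"` (columns
#'   `g_het`, `g_hom`).
#' @return `data` with the coding column(s) appended.
#' @examples
#' cohort <- tibble::tibble(genotype = c("TT", "TC", "CC"))
#' code_genotype(cohort, scheme = "dummy")
#' @export
code_genotype <- function(data, scheme = c("additive", "dummy"),
                          genotype = genotype,
                          effect_allele = "C", other_allele = "T") {
  check_data_frame(data)
  scheme <- match.arg(scheme)
  g_col <- as_name(enquo(genotype))
  check_columns(data, g_col)
  g <- parse_genotype(data[[g_col]], effect_allele, other_allele)
  if (scheme == "additive") {
    data$g_add <- g
  } else {
    data$g_het <- as.integer(g == 1L)
    data$g_hom <- as.integer(g == 2L)
  }
  data
}

#' Genotype QC report for a cohort
#'
#' Bundles genotype counts, allele frequencies and the Hardy-Weinberg test for
#' a cohort (conventionally the comparison or ageing arm, not the cases) into
#' one long tibble suitable for writing as delimited text.
#'
#' @inheritParams genotype_counts
#' @return A tibble with columns `metric`, `level`, `value`.
#' @export
qc_report <- function(data, genotype = genotype,
                      effect_allele = "C", other_allele = "T") {
  counts <- genotype_counts(data, {{ genotype }}, effect_allele, other_allele)
  freqs <- allele_frequencies(counts)
  hwe <- hwe_test(counts)
  dplyr::bind_rows(
    tibble::tibble(
      metric = "genotype_count",
      level = sub("^n_", "", names(counts)[1:3]),
      value = as.numeric(counts[1, 1:3])
    ),
    tibble::tibble(metric = "allele_freq", level = freqs$allele, value = freqs$freq),
    tibble::tibble(
      metric = c("hwe_chi2", "hwe_p", "n_genotyped", "n_missing"),
      level = NA_character_,
      value = c(hwe$chi2, hwe$p, counts$n, counts$n_missing)
    )
  )
}
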