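# Frailty scoring: cumulative-deficit frailty index over 45 items in [0, 1],
# and the modified Fried phenotype (5 criteria, frail when >= 3 present).

N_DEFICITS <- 45L
FRIED_SELF_REPORT <- c("weight_loss", "exhaustion", "low_activity", "weakness")

deficit_cols <- function() sprintf("d%02d", seq_len(N_DEFICITS))

#' Cumulative-deficit frailty index
#'
#' Scores the frailty index (FI) as the mean of 45 health-deficit items, each
#' coded in \[0, 1\] (0 = deficit absent, 1 = fully expressed). With complete
#' data this is the sum of deficits divided by 45.
#'
#' Missing items are handled by `policy`:
#' * `"rescale"` (default): divide by the number of non-missing items, but
#'   only when at least `min_prop` of the 45 items (default 80%, i.e. 36) are
#'   observed; otherwise the FI is `NA`. This is the usual cumulative-deficit
#'   convention.
#' * `"strict"`: always divide by 45; any missing item makes the FI `NA`.
#'
#' @param data A data frame with one row per subject.
#' @param deficits Tidy-select specification of the 45 deficit columns
#'   (default `d01`--`d45`).
#' @param policy Missing-item policy, `"rescale"` or `"strict"`.
#' @param min_prop Minimum proportion of observed items required under the
#'   `"rescale"` policy.
#' @return `data` with columns `fi` (in \[0, 1\] or `NA`) and
#'   `n_deficits_used` appended.
#' @examples
#' x <- tibble::tibble(!!!stats::setNames(as.list(rep(0, 45)), sprintf("d%02d", 1:45)))
#' frailty_index(x)$fi
#' @export
frailty_index <- function(data, deficits = dplyr::any_of(deficit_cols()),
                          policy = c("rescale", "strict"), min_prop = 0.8) {
  check_data_frame(data)
  policy <- match.arg(policy)
  check_scalar_prob(min_prop, "min_prop")
  cols <- tidyselect_cols(data, {{ deficits }})
  if (length(cols) != N_DEFICITS) {
    abort(sprintf("Exactly %d deficit columns are required; got %d.", N_DEFICITS, length(cols)))
  }
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    abort("Deficit values must lie in [0, 1] (or be NA).")
  }
  n_obs <- rowSums(!is.na(m))
  total <- rowSums(m, na.rm = TRUE)
  if (policy == "strict") {
    fi <- ifelse(n_obs == N_DEFICITS, total / N_DEFICITS, NA_real_)
  } else {
    enough <- n_obs >= ceiling(min_prop * N_DEFICITS)
    fi <- ifelse(enough & n_obs > 0, total / n_obs, NA_real_)
  }
  data$fi <- fi
  data$n_deficits_used <- as.integer(n_obs)
  data
}

tidyselect_cols <- function(data, expr) {
  names(dplyr::select(utils::head(data, 0), {{ expr }}))
}

#' Sex-specific slowness cutoffs from timed up-and-go times
#'
#' Slowness is gait speed below the 20th sex-specific percentile, which for
#' completion times is a time above the sex-specific 80th percentile. The
#' cutoff is the empirical 80th-percentile time (linear interpolation,
#' `stats::quantile()` type 7); subjects are flagged slow only when strictly
#' above the cutoff, so ties at the cutoff are non-slow.
#'
#' @param data A data frame with one row per subject.
#' @param gait_time Column of up-and-go completion times in seconds.
#' @param sex Column giving the sex stratum.
#' @param prob Time percentile defining the cutoff (default 0.8, the
#'   complement of the 20th speed percentile).
#' @param min_n Minimum non-missing times required per stratum (default 5).
#' @return A tibble with one row per sex: `sex`, `cutoff`, `n`.
#' @examples
#' x <- tibble::tibble(sex = rep("female", 10), gait_time = 1:10)
#' slowness_threshold(x)
#' @export
slowness_threshold <- function(data, gait_time = gait_time, sex = sex,
                               prob = 0.8, min_n = 5) {
  check_data_frame(data)
  check_scalar_prob(prob, "prob", open_left = TRUE, open_right = TRUE)
  t_col <- as_name(enquo(gait_time))
  s_col <- as_name(enquo(sex))
  check_columns(data, c(t_col, s_col))
  tt <- data[[t_col]]
  if (any(!is.na(tt) & tt <= 0)) abort("`gait_time` must be positive (seconds).")
  out <- data |>
    dplyr::group_by(sex = .data[[s_col]]) |>
    dplyr::summarise(
      n = sum(!is.na(.data[[t_col]])),
      cutoff = if (.data$n[1] >= min_n)
        unname(quantile(.data[[t_col]], probs = prob, na.rm = TRUE, type = 7))
      else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::select("sex", "cutoff", "n")
  if (any(out$n < min_n)) {
    warn(sprintf(
      "Sex strat%s with fewer than %d gait times: cutoff reported as NA.",
      if (sum(out$n < min_n) > 1) "a" else "um", min_n
    ))
  }
  out
}

# Decide frail / non-frail / NA from criterion indicators with missingness:
# frail when >= 3 observed-true, non-frail when >= 3 observed-false,
# otherwise undecidable.
classify_fried <- function(crit_mat) {
  n_true <- rowSums(crit_mat, na.rm = TRUE)
  n_false <- rowSums(!crit_mat, na.rm = TRUE)
  out <- rep(NA_character_, nrow(crit_mat))
  out[n_true >= 3] <- "frail"
  out[n_true < 3 & n_false >= 3] <- "non-frail"
  list(
    phenotype = factor(out, levels = c("non-frail", "frail")),
    n_criteria_met = as.integer(n_true)
  )
}

#' Modified Fried frailty phenotype
#'
#' Classifies subjects as frail when three or more of five criteria are
#' present: unintentional weight loss, exhaustion, low activity, weakness
#' (self-report indicators) and slowness (timed up-and-go above the
#' sex-specific cutoff from [slowness_threshold()], i.e. gait speed below the
#' 20th sex-specific percentile).
#'
#' With missing components the classification is decided when possible: frail
#' if at least 3 criteria are observed true, non-frail if at least 3 are
#' observed false, otherwise `NA`.
#'
#' @param data A data frame with logical (or 0/1) columns `weight_loss`,
#'   `exhaustion`, `low_activity`, `weakness`, plus `gait_time` and `sex`.
#' @param cutoffs Optional tibble of sex-specific cutoffs as returned by
#'   [slowness_threshold()]; computed from `data` when `NULL`.
#' @inheritParams slowness_threshold
#' @return `data` with columns `slow`, `n_criteria_met` and `phenotype`
#'   (factor `non-frail`/`frail`, `NA` when undecidable) appended.
#' @export
fried_phenotype <- function(data, cutoffs = NULL, gait_time = gait_time,
                            sex = sex, prob = 0.8) {
  check_data_frame(data)
  check_columns(data, FRIED_SELF_REPORT)
  t_col <- as_name(enquo(gait_time))
  s_col <- as_name(enquo(sex))
  check_columns(data, c(t_col, s_col))
  if (is.null(cutoffs)) {
    cutoffs <- slowness_threshold(data, gait_time = {{ gait_time }},
                                  sex = {{ sex }}, prob = prob)
  }
  check_columns(cutoffs, c("sex", "cutoff"), arg = "cutoffs")
  cut_for <- setNames(cutoffs$cutoff, as.character(cutoffs$sex))[as.character(data[[s_col]])]
  data$slow <- data[[t_col]] > unname(cut_for)
  crit <- matrix(NA, nrow(data), 5L,
                 dimnames = list(NULL, c(FRIED_SELF_REPORT, "slow")))
  for (k in FRIED_SELF_REPORT) crit[, k] <- as.logical(data[[k]])
  crit[, "slow"] <- as.logical(data$slow)
  cls <- classify_fried(crit)
  data$n_criteria_met <- cls$n_criteria_met
  data$phenotype <- cls$phenotype
  data
}

#' Score a cohort: frailty index and Fried phenotype in one call
#'
#' Convenience wrapper applying [frailty_index()] and [fried_phenotype()] to a
#' cohort that carries the 45 deficit items and the five Fried components.
#'
#' @inheritParams frailty_index
#' @inheritParams fried_phenotype
#' @return `data` with `fi`, `n_deficits_used`, `slow`, `n_criteria_met` and
#'   `phenotype` appended.
#' @export
score_frailty <- function(data, policy = c("rescale", "strict"), cutoffs = NULL) {
  data |>
    frailty_index(policy = match.arg(policy)) |>
    fried_phenotype(cutoffs = cutoffs)
}

# deficit codebooks ----------------------------------------------------------

#' Read a 45-item deficit codebook from YAML
#'
#' The codebook defines, for each of the 45 deficits, how raw questionnaire
#' levels map onto the \[0, 1\] deficit scale. Each entry has a `name`, a
#' `kind` (`dichotomous` or `polychotomous`) and a `levels` mapping from raw
#' level to value. Dichotomous items map to \{0, 1\}; polychotomous items use
#' graded values which default to equally spaced points in \[0, 1\] when the
#' codebook lists level labels without values. Every item must include the
#' value 0 and reach a maximum of 1.
#'
#' @param path Path to the YAML codebook.
#' @return A tibble of class `deficit_codebook` with columns `item`, `name`,
#'   `kind` and a list-column `map` of named numeric vectors.
#' @export
read_deficit_codebook <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) != N_DEFICITS) {
    abort(sprintf("A deficit codebook must define exactly %d items; found %d.",
                  N_DEFICITS, length(raw)))
  }
  entries <- purrr::imap(raw, function(item, i) {
    kind <- item$kind %||% "dichotomous"
    lv <- item$levels
    if (is.null(names(lv)) || is.list(lv) && is.null(names(lv))) {
      # labels only: equally spaced grades in [0, 1]
      labels <- unlist(lv)
      vals <- seq(0, 1, length.out = length(labels))
      map <- setNames(vals, labels)
    } else {
      map <- unlist(lv)
      map <- setNames(as.numeric(map), names(map))
    }
    if (any(map < 0 | map > 1)) abort(sprintf("Item %s: mapped values must lie in [0, 1].", i))
    if (min(map) != 0 || max(map) != 1) {
      abort(sprintf("Item %s: mapping must include 0 and reach a maximum of 1.", i))
    }
    nm <- item$name %||% sprintf("deficit_%02d", as.integer(i))
    tibble::tibble(item = sprintf("d%02d", as.integer(i)),
                   name = nm, kind = kind, map = list(map))
  })
  out <- dplyr::bind_rows(entries)
  class(out) <- c("deficit_codebook", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map raw questionnaire levels to deficit scores with a codebook
#'
#' Applies a [read_deficit_codebook()] codebook to raw item columns
#' `d01`..`d45` holding level labels, replacing them with scored values in
#' \[0, 1\]. Unmapped levels become `NA` with a warning.
#'
#' @param data A data frame with raw level columns `d01`..`d45`.
#' @param codebook A `deficit_codebook`.
#' @return `data` with the deficit columns replaced by scores.
#' @export
apply_codebook <- function(data, codebook) {
  check_data_frame(data)
  if (!inherits(codebook, "deficit_codebook")) abort("`codebook` must come from read_deficit_codebook().")
  check_columns(data, codebook$item)
  unmapped <- 0L
  for (i in seq_len(nrow(codebook))) {
    col <- codebook$item[i]
    map <- codebook$map[[i]]
    raw <- as.character(data[[col]])
    val <- unname(map[raw])
    unmapped <- unmapped + sum(is.na(val) & !is.na(raw))
    data[[col]] <- val
  }
  if (unmapped > 0) warn(sprintf("%d raw level(s) not found in the codebook; scored as NA.", unmapped))
  data
}
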