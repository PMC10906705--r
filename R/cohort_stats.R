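#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null with both margins
#' fixed, using the conventional minimum-likelihood rule: the p-value sums
#' the probabilities of all tables (with the observed margins) whose point
#' probability does not exceed the observed table's. Probabilities are
#' evaluated in log space with `lchoose`, so large tables do not overflow.
#'
#' @param table A 2x2 matrix of non-negative integer counts (rows = arm,
#'   columns = category), or a length-4 vector `c(a, b, c, d)` filled by row.
#' @return The two-sided p-value. Degenerate margins (an all-zero row or
#'   column) return 1 with a warning, since the table carries no contrast.
#' @examples
#' fisher_exact_2x2(matrix(c(9, 2, 28, 16), nrow = 2))
#' @export
fisher_exact_2x2 <- function(table) {
  if (is.vector(table) && length(table) == 4) {
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    abort("`table` must be a 2x2 matrix of non-negative integers.")
  }
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); n <- sum(table)
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) {
    warn("Degenerate margins (an all-zero row or column); p = 1.")
    return(1)
  }
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  log_obs <- logp[k == table[1, 1]]
  # relative tolerance guards against ties lost to rounding in log space
  min(sum(exp(logp[logp <= log_obs + 1e-7])), 1)
}

#' Welch's t-test for continuous cohort variables
#'
#' Unequal-variance two-sample t-test with Satterthwaite degrees of freedom,
#' as used for comparing continuous demographics (age, BMI, procedure
#' duration, burp rate) between study arms.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`. When both groups have zero variance and equal
#'   means the contrast is empty and `p_value` is 1.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least 2 values for a Welch t-test.")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    equal <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(tibble(
      statistic = if (equal) 0 else Inf, df = NA_real_,
      p_value = if (equal) 1 else .Machine$double.xmin,
      mean_a = mean(group_a), mean_b = mean(group_b),
      n_a = length(group_a), n_b = length(group_b)
    ))
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(group_a), mean_b = mean(group_b),
    n_a = length(group_a), n_b = length(group_b)
  )
}

#' Burping rate standardised to 20 minutes
#'
#' Burp annotations (which include coughs and gags) counted over the
#' procedure and rescaled to events per 20 minutes, the cohort-table
#' convention.
#'
#' @param annotations Annotation tibble (`time_s`, `label`).
#' @param duration_min Procedure duration in minutes (> 0).
#' @return Burping events per 20 minutes.
#' @export
burp_rate <- function(annotations, duration_min) {
  if (!is.numeric(duration_min) || duration_min <= 0) {
    abort("`duration_min` must be positive.")
  }
  sum(annotations$label == "burp") * 20 / duration_min
}

#' Cohort comparison table for a two-arm study
#'
#' Summarises demographics, sedation, burping rate and duration per arm and
#' compares arms with Fisher's exact test (discrete variables) or Welch's
#' t-test (continuous variables).
#'
#' @param records List of [procedure_record()]s spanning both arms.
#' @return A tibble with one row per variable: `variable`, `EGD`,
#'   `Cytosponge` (formatted summaries) and `p_value` (NA where only one
#'   level is present).
#' @export
cohort_table <- function(records) {
  arm <- map_chr(records, "arm")
  demo <- function(field) map_dbl(records, ~ .x$demographics[[field]] %||%
                                    NA_real_)
  dur <- map_dbl(records, ~ (.x$procedure_end_s - .x$procedure_start_s) / 60)
  burps <- map_dbl(records, ~ burp_rate(.x$annotations,
                                        (.x$procedure_end_s -
                                           .x$procedure_start_s) / 60))
  rows <- list(tibble(variable = "n",
                      EGD = as.character(sum(arm == "EGD")),
                      Cytosponge = as.character(sum(arm == "Cytosponge")),
                      p_value = NA_real_))
  cont_row <- function(name, x) {
    a <- x[arm == "EGD"]; b <- x[arm == "Cytosponge"]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    tibble(variable = name,
           EGD = sprintf("mean %.2f", mean(a)),
           Cytosponge = sprintf("mean %.2f", mean(b)),
           p_value = welch_t(a, b)$p_value)
  }
  disc_row <- function(name, flag) {
    tab <- matrix(c(sum(flag & arm == "EGD", na.rm = TRUE),
                    sum(!flag & arm == "EGD", na.rm = TRUE),
                    sum(flag & arm == "Cytosponge", na.rm = TRUE),
                    sum(!flag & arm == "Cytosponge", na.rm = TRUE)),
                  nrow = 2, byrow = TRUE)
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
         else fisher_exact_2x2(tab)
    tibble(variable = name,
           EGD = sprintf("%d/%d", tab[1, 1], sum(tab[1, ])),
           Cytosponge = sprintf("%d/%d", tab[2, 1], sum(tab[2, ])),
           p_value = p)
  }
  sex <- map_chr(records, ~ as.character(.x$demographics$sex %||% NA))
  smoker <- map_lgl(records, ~ isTRUE(.x$demographics$smoker))
  spray <- map_chr(records, "sedation") %in%
    c("throat_spray_only", "midazolam_plus_spray")
  rows <- c(rows, list(
    cont_row("age_years", demo("age")),
    cont_row("bmi", demo("bmi")),
    if (!all(is.na(sex))) disc_row("sex_male", sex == "male"),
    disc_row("smoker", smoker),
    disc_row("throat_spray", spray),
    cont_row("burps_per_20min", burps),
    cont_row("duration_min", dur)
  ))
  bind_rows(rows[!map_lgl(rows, is.null)])
}
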