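#' Fold-change estimate container
#'
#' All comparisons in the package report a multiplicative fold change with a
#' 95% confidence interval and a two-sided p-value, plus the group sizes and
#' the method that produced them (`"log_t"` for Welch t-tests on log counts,
#' `"log_t_paired"` for the within-patient pairing, `"bootstrap"` for event
#' resampling).
#'
#' @param ratio Fold-change point estimate (> 0).
#' @param ci_low,ci_high 95% CI bounds on the ratio.
#' @param p_value Two-sided p-value in (0, 1].
#' @param n_a,n_b Group sizes.
#' @param method Estimation method label.
#' @param comparison,fraction,variant Optional labels describing what was
#'   compared.
#' @return A list of class `ratio_estimate`.
#' @export
ratio_estimate <- function(ratio, ci_low, ci_high, p_value, n_a, n_b,
                           method, comparison = NA_character_,
                           fraction = NA_character_,
                           variant = NA_character_) {
  p_value <- min(max(p_value, .Machine$double.xmin), 1)
  stopifnot(ratio > 0, ci_low <= ratio + 1e-12, ratio <= ci_high + 1e-12)
  structure(list(
    ratio = ratio, ci_low = ci_low, ci_high = ci_high,
    p_value = p_value, n_a = as.integer(n_a), n_b = as.integer(n_b),
    method = method, comparison = comparison, fraction = fraction,
    variant = variant
  ), class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  lab <- if (is.na(x$comparison)) "" else paste0(x$comparison, ": ")
  cat(sprintf(
    "%s%.3gx (95%% CI %.3gx-%.3gx), p = %.3g [%s, n = %d vs %d]\n",
    lab, x$ratio, x$ci_low, x$ci_high, x$p_value, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' Geometric-mean fold change between two groups of counts
#'
#' Particle counts are modelled as log-normal, so group comparison is a Welch
#' (unequal-variance) two-sample t-test on log-transformed counts. The
#' reported ratio is the geometric-mean ratio
#' `exp(mean(log(a + pc)) - mean(log(b + pc)))`; the CI is the Welch t
#' interval on the log scale, exponentiated. A pseudocount (default 1) is
#' added identically to both groups so zero counts remain in the analysis.
#'
#' @param group_a,group_b Numeric vectors of counts (>= 2 values each;
#'   `value + pseudocount` must be positive).
#' @param pseudocount Shift added before the log transform.
#' @param conf_level Confidence level for the interval.
#' @return A [ratio_estimate()] with `method = "log_t"`.
#' @export
log_ratio_test <- function(group_a, group_b, pseudocount = 1,
                           conf_level = 0.95) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least 2 values for the log-t comparison.")
  }
  la <- suppressWarnings(log(group_a + pseudocount))
  lb <- suppressWarnings(log(group_b + pseudocount))
  if (any(!is.finite(la)) || any(!is.finite(lb))) {
    abort("Non-finite log counts; check for values <= -pseudocount.")
  }
  ratio <- exp(mean(la) - mean(lb))
  if (sd(la) == 0 && sd(lb) == 0) {
    # degenerate: both groups constant on the log scale
    p <- if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else .Machine$double.xmin
    return(ratio_estimate(ratio, ratio, ratio, p,
                          length(group_a), length(group_b), "log_t"))
  }
  tt <- t.test(la, lb, var.equal = FALSE, conf.level = conf_level)
  ratio_estimate(
    ratio = ratio,
    ci_low = exp(tt$conf.int[1]), ci_high = exp(tt$conf.int[2]),
    p_value = tt$p.value,
    n_a = length(group_a), n_b = length(group_b),
    method = "log_t"
  )
}

#' Summarise one procedure's particle production
#'
#' Computes, per size fraction, the raw and spike-filtered count totals for
#' the procedure window and the pre-procedure reference window, each rescaled
#' to a 20-minute-equivalent effective count. The spike variant first
#' subtracts a running-median background from the whole aggregate trace
#' ([median_filter_subtract()]) and sums the positive residuals, suppressing
#' slowly varying room background.
#'
#' @param series An [aggregate_size_fractions()] series covering the
#'   recording.
#' @param record The matching [procedure_record()].
#' @param kernel_samples Running-median width for the spike variant.
#' @param reference_window_min Reference window length in minutes.
#' @param target_duration_min Effective-duration target in minutes.
#' @return A tibble with one row per fraction: `procedure_id`, `arm`,
#'   `sedation`, `fraction`, `duration_min`, `proc_raw`, `proc_spike`,
#'   `ref_raw`, `ref_spike` (all 20-minute-equivalent counts; reference
#'   columns `NA` when no valid reference window exists) and `reference_ok`.
#' @export
summarize_procedure <- function(series, record, kernel_samples = 11,
                                reference_window_min = 5,
                                target_duration_min = 20) {
  t <- series$time_s
  in_proc <- t >= record$procedure_start_s & t < record$procedure_end_s
  if (!any(in_proc)) {
    abort(sprintf("Procedure window of %s contains no samples.",
                  record$procedure_id))
  }
  duration_min <- (record$procedure_end_s - record$procedure_start_s) / 60
  ref <- tryCatch(reference_window(record, reference_window_min),
                  error = function(e) NULL)
  ref_ok <- !is.null(ref) && ref$valid
  in_ref <- if (ref_ok) t >= ref$start_s & t < ref$end_s else logical(0)
  map(c("aerosol", "droplet"), function(frac) {
    spike <- median_filter_subtract(series[[frac]], kernel_samples)$spike
    tibble::new_tibble(list(
      procedure_id = record$procedure_id, arm = record$arm,
      sedation = record$sedation, fraction = frac,
      duration_min = duration_min,
      proc_raw = normalize_to_duration(sum(series[[frac]][in_proc]),
                                       duration_min, target_duration_min),
      proc_spike = normalize_to_duration(sum(spike[in_proc]),
                                         duration_min, target_duration_min),
      ref_raw = if (ref_ok) {
        normalize_to_duration(sum(series[[frac]][in_ref]),
                              ref$duration_min, target_duration_min)
      } else NA_real_,
      ref_spike = if (ref_ok) {
        normalize_to_duration(sum(spike[in_ref]),
                              ref$duration_min, target_duration_min)
      } else NA_real_,
      reference_ok = ref_ok
    ), nrow = 1L)
  }) |> bind_rows()
}

summary_column <- function(variant = c("raw", "spike"),
                           window = c("proc", "ref")) {
  paste(match.arg(window), match.arg(variant), sep = "_")
}

#' Compare the two study arms on 20-minute-equivalent counts
#'
#' Applies [log_ratio_test()] to the duration-normalised counts of two arms
#' for one size fraction, on either the raw or the spike-filtered
#' (background-subtracted) variant. Optionally excludes procedures where
#' anesthetic throat spray was administered, for the comparison against
#' spray-free capsule-sponge procedures.
#'
#' @param summaries Row-bound output of [summarize_procedure()] over a study.
#' @param fraction `"aerosol"` or `"droplet"`.
#' @param variant `"raw"` or `"spike"`.
#' @param arm_a,arm_b Arms to compare (ratio is arm_a / arm_b).
#' @param exclude_throat_spray If `TRUE`, drop procedures whose sedation
#'   involved throat spray from the Cytosponge arm (`arm_b`). EGD patients
#'   all receive spray, so the spray-free comparison restricts only the
#'   capsule-sponge side.
#' @param pseudocount Passed to [log_ratio_test()].
#' @return A [ratio_estimate()].
#' @export
compare_arms <- function(summaries, fraction = "aerosol",
                         variant = c("raw", "spike"),
                         arm_a = "EGD", arm_b = "Cytosponge",
                         exclude_throat_spray = FALSE, pseudocount = 1) {
  variant <- match.arg(variant)
  col <- summary_column(variant, "proc")
  dat <- filter(summaries, .data$fraction == !!fraction)
  if (exclude_throat_spray) {
    dat <- filter(dat, .data$arm != "Cytosponge" |
                    !.data$sedation %in%
                    c("throat_spray_only", "midazolam_plus_spray"))
  }
  a <- dat[[col]][dat$arm == arm_a]
  b <- dat[[col]][dat$arm == arm_b]
  if (length(a) < 2 || length(b) < 2) {
    abort(sprintf(
      "Need >= 2 procedures per arm (%s: %d, %s: %d)%s.",
      arm_a, length(a), arm_b, length(b),
      if (exclude_throat_spray) " after excluding throat-spray procedures"
      else ""
    ))
  }
  est <- log_ratio_test(a, b, pseudocount = pseudocount)
  est$comparison <- sprintf("%s_vs_%s", arm_a, arm_b)
  est$fraction <- fraction
  est$variant <- variant
  est
}

#' Within-patient procedure-vs-reference fold change
#'
#' Pairs each procedure's 20-minute-equivalent counts with its own
#' pre-procedure reference window and applies a paired t-test to the log
#' differences; the ratio is the geometric mean of the per-patient
#' procedure/reference ratios.
#'
#' @inheritParams compare_arms
#' @param arm Optional arm filter (`NULL` keeps all procedures).
#' @return A [ratio_estimate()] with `method = "log_t_paired"`.
#' @export
procedure_vs_reference <- function(summaries, fraction = "aerosol",
                                   variant = c("raw", "spike"),
                                   arm = NULL, pseudocount = 1) {
  variant <- match.arg(variant)
  dat <- filter(summaries, .data$fraction == !!fraction, .data$reference_ok)
  if (!is.null(arm)) dat <- filter(dat, .data$arm == !!arm)
  proc <- dat[[summary_column(variant, "proc")]]
  ref <- dat[[summary_column(variant, "ref")]]
  if (length(proc) < 2) {
    abort("Need >= 2 procedures with valid reference windows.")
  }
  d <- log(proc + pseudocount) - log(ref + pseudocount)
  if (any(!is.finite(d))) abort("Non-finite paired log differences.")
  ratio <- exp(mean(d))
  tt <- if (sd(d) > 1e-12 * (abs(mean(d)) + 1)) {
    t.test(d)
  } else NULL  # constant paired differences: the t statistic degenerates
  if (is.null(tt)) {
    p <- if (isTRUE(all.equal(mean(d), 0))) 1 else .Machine$double.xmin
    est <- ratio_estimate(ratio, ratio, ratio, p, length(d), length(d),
                          "log_t_paired")
  } else {
    est <- ratio_estimate(ratio, exp(tt$conf.int[1]), exp(tt$conf.int[2]),
                          tt$p.value, length(d), length(d), "log_t_paired")
  }
  est$comparison <- "procedure_vs_reference"
  est$fraction <- fraction
  est$variant <- variant
  est
}
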