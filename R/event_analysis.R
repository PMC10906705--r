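#' Excess particle counts around an annotated event
#'
#' Quantifies the particles attributable to a single event by local
#' background subtraction: the counts summed over the event window
#' `[time_s, time_s + event_window_s)` minus the expected background over the
#' same span, estimated as the median per-interval count in the immediately
#' preceding baseline window `[time_s - baseline_window_s, time_s)` times the
#' number of event intervals. The excess is signed: subtraction can yield
#' negative values when the event window sits in a local dip, which is what
#' motivates the log-normal/normal mixture model downstream.
#'
#' @param series An [aggregate_size_fractions()] series.
#' @param time_s Event time in seconds since recording start.
#' @param label Event label ([event_labels()]).
#' @param event_window_s Event window length in seconds. Default 21 s
#'   (three 7-s intervals): events last seconds but the counter's averaging
#'   smears them across neighbouring intervals.
#' @param baseline_window_s Baseline window length in seconds (default 70 s,
#'   ten intervals).
#' @param procedure_id Optional identifier carried into the result.
#' @return A one-row tibble: `procedure_id`, `label`, `time_s`, and signed
#'   excess columns `aerosol` and `droplet`.
#' @export
extract_event_excess <- function(series, time_s, label = "null_reference",
                                 event_window_s = 21, baseline_window_s = 70,
                                 procedure_id = NA_character_) {
  t0 <- min(series$time_s)
  t_end <- max(series$time_s) + attr(series, "sample_period_s")
  if (time_s - baseline_window_s < t0) {
    abort(sprintf(
      "Event at %g s is too close to the recording start for a %g-s baseline window.",
      time_s, baseline_window_s
    ))
  }
  if (time_s + event_window_s > t_end) {
    abort(sprintf("Event window at %g s extends past the recording end.",
                  time_s))
  }
  t <- series$time_s
  in_ev <- t >= time_s & t < time_s + event_window_s
  in_base <- t >= time_s - baseline_window_s & t < time_s
  if (!any(in_ev) || !any(in_base)) {
    abort("Event or baseline window contains no samples.")
  }
  n_ev <- sum(in_ev)
  tibble::new_tibble(list(
    procedure_id = procedure_id, label = label, time_s = time_s,
    aerosol = sum(series$aerosol[in_ev]) -
      median(series$aerosol[in_base]) * n_ev,
    droplet = sum(series$droplet[in_ev]) -
      median(series$droplet[in_base]) * n_ev
  ), nrow = 1L)
}

#' Sample null-reference events from quiet stretches
#'
#' Null-reference events are pseudo-events placed where no annotated activity
#' occurs; their excess distribution is the comparator for real events. Start
#' times are drawn uniformly without replacement from interval starts that
#' are at least `min_gap_s` away from every annotation (and from each other)
#' and leave room for the baseline and event windows. Being activity-free is
#' enforced over the whole analysis span: an annotation's activity window
#' (`event_window_s` long) may not overlap the null's baseline-plus-event
#' span `[t - baseline_window_s, t + event_window_s)`, since activity inside
#' the baseline would corrupt the background estimate itself.
#'
#' @param series An [aggregate_size_fractions()] series.
#' @param annotations Annotation tibble (`time_s`, `label`).
#' @param n_events Number of null events to draw.
#' @param min_gap_s Minimum separation (s) from annotations and between
#'   sampled nulls.
#' @param seed Optional integer seed; the draw is reproducible given it.
#' @param avoid_times_s Additional time points (e.g. the procedure start and
#'   end, where activity levels step) that must not fall inside a null
#'   event's baseline-plus-event span.
#' @inheritParams extract_event_excess
#' @return Row-bound [extract_event_excess()] results with
#'   `label = "null_reference"`, sorted by time.
#' @export
sample_null_events <- function(series, annotations, n_events = 3,
                               min_gap_s = 60, seed = NULL,
                               event_window_s = 21, baseline_window_s = 70,
                               procedure_id = NA_character_,
                               avoid_times_s = numeric(0)) {
  t0 <- min(series$time_s)
  t_end <- max(series$time_s) + attr(series, "sample_period_s")
  starts <- series$time_s
  ok <- starts - baseline_window_s >= t0 &
    starts + event_window_s <= t_end
  for (ta in annotations$time_s) {
    ok <- ok & abs(starts - ta) >= min_gap_s &
      # the annotation's activity window must not touch the analysis span
      !(ta + event_window_s > starts - baseline_window_s &
          ta < starts + event_window_s)
  }
  for (tb in avoid_times_s) {
    ok <- ok & !(tb > starts - baseline_window_s &
                   tb < starts + event_window_s)
  }
  eligible <- starts[ok]
  draw <- function() {
    chosen <- numeric(0)
    pool <- eligible
    for (i in seq_len(n_events)) {
      if (length(pool) == 0) {
        abort(sprintf(
          "Insufficient annotation-free time: placed %d of %d null events (%d eligible interval(s) initially).",
          length(chosen), n_events, length(eligible)
        ))
      }
      pick <- pool[sample.int(length(pool), 1)]
      chosen <- c(chosen, pick)
      pool <- pool[abs(pool - pick) >= min_gap_s]
    }
    sort(chosen)
  }
  times <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  bind_rows(map(times, function(t) {
    extract_event_excess(series, t, label = "null_reference",
                         event_window_s = event_window_s,
                         baseline_window_s = baseline_window_s,
                         procedure_id = procedure_id)
  }))
}

positive_mean <- function(x) mean(pmax(x, 0))

excess_statistic <- function(x, stat) {
  switch(stat,
         mean_positive = positive_mean(x),
         mean = mean(x),
         median = median(x),
         abort(sprintf("Unknown statistic `%s`.", stat)))
}

#' Bootstrap fold change between two sets of event excesses
#'
#' The fold change is the ratio of the groups' mean positive excess (excess
#' values can be negative, so geometric means are unavailable; the mean of
#' the positive part is the headline statistic, with `mean` and `median`
#' available as alternatives). Uncertainty comes from a percentile bootstrap
#' over events: both groups are resampled with replacement `n_boot` times,
#' and the two-sided p-value is the proportion of bootstrap ratios crossing
#' 1, with a `+1/(n_boot+1)` continuity correction so p is never exactly 0.
#'
#' @param events_a,events_b Event-excess tibbles ([extract_event_excess()]).
#' @param fraction `"aerosol"` or `"droplet"`.
#' @param n_boot Number of bootstrap resamples (>= 1000; default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param stat Group summary statistic (see Details).
#' @param denom_floor Floor applied to the denominator statistic so the ratio
#'   stays finite when a resampled null group has no positive excess.
#' @return A [ratio_estimate()] with `method = "bootstrap"`.
#' @export
bootstrap_ratio <- function(events_a, events_b, fraction = "aerosol",
                            n_boot = 10000, seed = NULL,
                            stat = c("mean_positive", "mean", "median"),
                            denom_floor = 1e-6) {
  stat <- match.arg(stat)
  a <- events_a[[fraction]]
  b <- events_b[[fraction]]
  if (length(a) == 0 || length(b) == 0) {
    abort("Both event groups must be non-empty.")
  }
  if (n_boot < 1000) {
    abort("`n_boot` must be at least 1000 for stable percentile intervals.")
  }
  run <- function() {
    # both sides floored so the ratio stays positive and finite even when a
    # resampled group has no positive excess
    point <- max(excess_statistic(a, stat), denom_floor) /
      max(excess_statistic(b, stat), denom_floor)
    floored <- excess_statistic(b, stat) < denom_floor ||
      excess_statistic(a, stat) < denom_floor
    boots <- if (stat %in% c("mean_positive", "mean")) {
      # vectorised resampling: means of resampled rows
      av <- if (stat == "mean_positive") pmax(a, 0) else a
      bv <- if (stat == "mean_positive") pmax(b, 0) else b
      na <- length(av); nb <- length(bv)
      ma <- rowMeans(matrix(av[sample.int(na, na * n_boot, replace = TRUE)],
                            nrow = n_boot))
      mb <- rowMeans(matrix(bv[sample.int(nb, nb * n_boot, replace = TRUE)],
                            nrow = n_boot))
      pmax(ma, denom_floor) / pmax(mb, denom_floor)
    } else {
      vapply(seq_len(n_boot), function(i) {
        sa <- a[sample.int(length(a), replace = TRUE)]
        sb <- b[sample.int(length(b), replace = TRUE)]
        max(excess_statistic(sa, stat), denom_floor) /
          max(excess_statistic(sb, stat), denom_floor)
      }, numeric(1))
    }
    ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
    p_low <- (sum(boots <= 1) + 1) / (n_boot + 1)
    p_high <- (sum(boots >= 1) + 1) / (n_boot + 1)
    p <- min(1, 2 * min(p_low, p_high))
    est <- ratio_estimate(
      ratio = point,
      ci_low = min(ci[1], point), ci_high = max(ci[2], point),
      p_value = p, n_a = length(a), n_b = length(b), method = "bootstrap"
    )
    est$fraction <- fraction
    if (floored) est$denominator_floored <- TRUE
    est
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Event fold change over the null reference
#'
#' Convenience wrapper around [bootstrap_ratio()] with the null-reference
#' events as the denominator group; the comparison is labelled with the
#' event's label.
#'
#' @param events Event-excess tibble for one event type.
#' @param nulls Null-reference excess tibble.
#' @inheritParams bootstrap_ratio
#' @return A [ratio_estimate()].
#' @export
event_vs_null <- function(events, nulls, fraction = "aerosol",
                          n_boot = 10000, seed = NULL,
                          stat = c("mean_positive", "mean", "median"),
                          denom_floor = 1e-6) {
  est <- bootstrap_ratio(events, nulls, fraction = fraction, n_boot = n_boot,
                         seed = seed, stat = stat,
                         denom_floor = denom_floor)
  lab <- unique(events$label)
  est$comparison <- sprintf(
    "%s_vs_null", if (length(lab) == 1) lab else "events")
  est
}
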