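#' Aggregate channel counts into aerosol and droplet fractions
#'
#' Particles at or below the cutoff diameter (default 5 um) are aerosols:
#' they stay airborne for hours and are inhalable into the lower airways.
#' Particles above the cutoff are droplets: they settle quickly and
#' contaminate surfaces. Every channel must lie entirely on one side of the
#' cutoff, so the two fractions partition the bank and their per-interval sum
#' conserves the row sums of the source frame.
#'
#' @param frame A [particle_frame()].
#' @param cutoff_um Aerosol/droplet diameter cutoff in um.
#' @return A tibble of class `aggregate_series` with columns `time_s`,
#'   `aerosol`, `droplet`, carrying `sample_period_s` and `cutoff_um`
#'   attributes.
#' @export
aggregate_size_fractions <- function(frame, cutoff_um = 5) {
  bank <- classify_channels(attr(frame, "channels"), cutoff_um)
  counts <- frame_counts(frame)
  aero_cols <- bank$name[bank$fraction == "aerosol"]
  drop_cols <- bank$name[bank$fraction == "droplet"]
  out <- tibble::new_tibble(list(
    time_s = frame$time_s,
    aerosol = rowSums(counts[, aero_cols, drop = FALSE]),
    droplet = rowSums(counts[, drop_cols, drop = FALSE])
  ), nrow = nrow(frame))
  structure(out,
            class = c("aggregate_series", class(out)),
            sample_period_s = attr(frame, "sample_period_s"),
            cutoff_um = cutoff_um)
}

#' Rescale a count total to a target duration
#'
#' Procedures differ in length, so whole-procedure totals are normalised to
#' an effective count for a fixed-length (default 20-minute) procedure:
#' `total * target_min / duration_min`.
#'
#' @param total Count total(s) over the observed window.
#' @param duration_min Observed duration in minutes (> 0).
#' @param target_min Target duration in minutes.
#' @return Rescaled counts.
#' @examples
#' normalize_to_duration(100, duration_min = 10)  # 200
#' @export
normalize_to_duration <- function(total, duration_min, target_min = 20) {
  if (!is.numeric(duration_min) || any(duration_min <= 0)) {
    abort("`duration_min` must be positive.")
  }
  total * target_min / duration_min
}

#' Locate the pre-procedure reference window
#'
#' The within-patient background comparator is a fixed-length window (default
#' 5 minutes) ending at the procedure start:
#' `[procedure_start_s - 60 * length_min, procedure_start_s)`. The window is
#' flagged invalid when an annotated event falls inside it, since annotated
#' activity contaminates the background estimate.
#'
#' @param record A [procedure_record()].
#' @param length_min Window length in minutes.
#' @return A one-row tibble with `start_s`, `end_s`, `duration_min`, `valid`
#'   (FALSE when an annotation falls inside the window).
#' @export
reference_window <- function(record, length_min = 5) {
  start_s <- record$procedure_start_s - 60 * length_min
  if (start_s < 0) {
    abort(sprintf(
      "Insufficient pre-procedure recording: %.1f min available, %g min required.",
      record$procedure_start_s / 60, length_min
    ))
  }
  inside <- record$annotations$time_s >= start_s &
    record$annotations$time_s < record$procedure_start_s
  tibble(
    start_s = start_s,
    end_s = record$procedure_start_s,
    duration_min = length_min,
    valid = !any(inside)
  )
}

#' Running-median background subtraction ("spike" analysis)
#'
#' Room particle background varies slowly (ventilation, continuous patient
#' respiration), while procedure events produce sharp transient increases. A
#' running median of width `kernel_samples` estimates the slowly varying
#' background; subtracting it leaves a signed residual whose positive part
#' isolates the spikes. Edge samples use shrinking (truncated) windows rather
#' than padding, so no counts are fabricated outside the recording.
#'
#' @param series Numeric vector of per-interval counts.
#' @param kernel_samples Odd kernel width in samples, >= 3 and <= the series
#'   length. The default 11 (about 77 s at the 7-s sampling period) is long
#'   relative to seconds-scale events but short relative to room drift.
#' @return A tibble with columns `value` (input), `background` (running
#'   median), `residual` (signed) and `spike` (`pmax(residual, 0)`).
#' @export
median_filter_subtract <- function(series, kernel_samples = 11) {
  n <- length(series)
  k <- kernel_samples
  if (length(k) != 1 || k %% 2 != 1 || k < 3 || k > n) {
    abort(sprintf(
      "`kernel_samples` must be an odd integer in [3, %d]; got %s.",
      n, paste(k, collapse = ",")
    ))
  }
  h <- (k - 1) / 2
  bg <- as.numeric(runmed(series, k, endrule = "keep"))
  # shrinking windows at the edges: window [max(1, i-h), min(n, i+h)]
  for (i in c(seq_len(min(h, n)), seq.int(max(n - h + 1, 1), n))) {
    bg[i] <- median(series[max(1, i - h):min(n, i + h)])
  }
  residual <- series - bg
  tibble::new_tibble(list(value = as.numeric(series), background = bg,
                          residual = residual, spike = pmax(residual, 0)),
                     nrow = n)
}

window_slice <- function(series, start_s, end_s) {
  series[series$time_s >= start_s & series$time_s < end_s, , drop = FALSE]
}

window_sum <- function(time_s, values, start_s, end_s) {
  sum(values[time_s >= start_s & time_s < end_s])
}
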