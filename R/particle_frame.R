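#' Construct a particle frame
#'
#' A particle frame holds one recording session from a six-channel particle
#' counter: one row per averaging interval, one column per size channel.
#' Timestamps are interval starts in seconds since the recording began;
#' intervals are half-open `[t, t + sample_period_s)`.
#'
#' @param time_s Numeric vector of interval-start times (seconds), strictly
#'   increasing and regularly spaced at `sample_period_s` (1% tolerance).
#' @param counts Non-negative integer matrix or data frame, one column per
#'   channel in `channels`.
#' @param channels Channel bank tibble ([channel_bank()]).
#' @param sample_period_s Averaging interval in seconds (instrument default 7).
#' @param flow_rate_lpm Sampling flow rate in litres/minute (default 100).
#' @return A tibble of class `particle_frame` with columns `time_s` plus one
#'   count column per channel, carrying `sample_period_s`, `flow_rate_lpm`
#'   and `channels` as attributes.
#' @export
particle_frame <- function(time_s, counts, channels = channel_bank(),
                           sample_period_s = 7, flow_rate_lpm = 100) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != length(time_s)) {
    abort("`counts` must have one row per timestamp.")
  }
  if (ncol(counts) != nrow(channels)) {
    abort(sprintf("`counts` has %d columns but the bank defines %d channels.",
                  ncol(counts), nrow(channels)))
  }
  bad <- which(counts < 0 | !is.finite(counts) |
                 abs(counts - round(counts)) > 1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Counts must be non-negative integers; first violation at row %d, channel %s.",
      bad[1, 1], channels$name[bad[1, 2]]
    ))
  }
  if (length(time_s) > 1) {
    dt <- diff(time_s)
    if (any(dt <= 0)) abort("Timestamps must be strictly increasing.")
    if (any(abs(dt - sample_period_s) > 0.01 * sample_period_s)) {
      abort(sprintf(
        "Timestamps must be spaced by the sample period (%g s) within 1%%.",
        sample_period_s
      ))
    }
  }
  cols <- c(list(time_s = as.numeric(time_s)),
            lapply(seq_len(ncol(counts)), function(j) counts[, j]))
  names(cols) <- c("time_s", channels$name)
  out <- tibble::new_tibble(cols, nrow = length(time_s))
  structure(out,
            class = c("particle_frame", class(out)),
            sample_period_s = sample_period_s,
            flow_rate_lpm = flow_rate_lpm,
            channels = channels)
}

#' @export
print.particle_frame <- function(x, ...) {
  ch <- attr(x, "channels")
  cat(sprintf(
    "<particle_frame> %d intervals x %d channels, period %g s, flow %g L/min\n",
    nrow(x), nrow(ch), attr(x, "sample_period_s"), attr(x, "flow_rate_lpm")))
  NextMethod()
}

frame_counts <- function(frame) {
  as.matrix(frame[, attr(frame, "channels")$name, drop = FALSE])
}

#' Construct a procedure record
#'
#' One patient procedure: study arm, timing within its recording, sedation,
#' demographics and the annotated event log. A valid within-patient reference
#' window requires at least `5` minutes of recording before the procedure
#' start; records without one are flagged (`reference_ok = FALSE`), not
#' rejected, so recordings that started late can still enter the event
#' analysis.
#'
#' @param procedure_id Opaque identifier string.
#' @param arm `"EGD"` or `"Cytosponge"`.
#' @param procedure_start_s,procedure_end_s Procedure window bounds in seconds
#'   since recording start (half-open, start < end).
#' @param sedation One of `"none"`, `"throat_spray_only"`,
#'   `"midazolam_plus_spray"`.
#' @param demographics Optional list with elements `age` (years), `sex`,
#'   `bmi`, `smoker` (logical).
#' @param annotations Tibble with columns `time_s`, `label` (labels from
#'   [event_labels()]), or `NULL`.
#' @param recording_end_s Optional recording length in seconds; annotations
#'   must fall inside the recording span when given.
#' @return A list of class `procedure_record`.
#' @export
procedure_record <- function(procedure_id, arm,
                             procedure_start_s, procedure_end_s,
                             sedation = "none",
                             demographics = list(),
                             annotations = NULL,
                             recording_end_s = NULL) {
  arm <- arg_match0(arm, c("EGD", "Cytosponge"))
  sedation <- arg_match0(sedation,
                         c("none", "throat_spray_only", "midazolam_plus_spray"))
  if (!is.numeric(procedure_start_s) || !is.numeric(procedure_end_s) ||
      procedure_start_s >= procedure_end_s) {
    abort("Procedure start must precede procedure end.")
  }
  if (is.null(annotations)) {
    annotations <- tibble(time_s = numeric(), label = character())
  }
  annotations <- validate_annotations(annotations,
                                      recording_end_s = recording_end_s)
  structure(list(
    procedure_id = as.character(procedure_id),
    arm = arm,
    procedure_start_s = as.numeric(procedure_start_s),
    procedure_end_s = as.numeric(procedure_end_s),
    sedation = sedation,
    demographics = demographics,
    annotations = annotations,
    recording_end_s = if (is.null(recording_end_s)) NULL else
      as.numeric(recording_end_s),
    reference_ok = procedure_start_s >= 5 * 60
  ), class = "procedure_record")
}

validate_annotations <- function(annotations, recording_end_s = NULL) {
  annotations <- as_tibble(annotations)
  if (!all(c("time_s", "label") %in% names(annotations))) {
    abort("Annotations need columns `time_s` and `label`.")
  }
  unknown <- setdiff(unique(annotations$label), event_labels())
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unknown event label(s): %s. Accepted labels: %s. (Coughs and gags are recorded as `burp`.)",
      paste(unknown, collapse = ", "),
      paste(event_labels(), collapse = ", ")
    ))
  }
  if (any(annotations$time_s < 0)) {
    abort("Annotation times must be non-negative seconds since recording start.")
  }
  if (!is.null(recording_end_s) && any(annotations$time_s > recording_end_s)) {
    abort("Annotation times must lie within the recording span.")
  }
  ord <- order(annotations$time_s)
  tibble::new_tibble(list(time_s = as.numeric(annotations$time_s[ord]),
                          label = as.character(annotations$label[ord])),
                     nrow = nrow(annotations))
}

#' @export
print.procedure_record <- function(x, ...) {
  cat(sprintf(
    "<procedure_record> %s [%s], window [%g, %g) s, sedation %s, %d annotation(s)%s\n",
    x$procedure_id, x$arm, x$procedure_start_s, x$procedure_end_s,
    x$sedation, nrow(x$annotations),
    if (x$reference_ok) "" else " (no valid pre-procedure reference)"
  ))
  invisible(x)
}
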