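#' Read a particle-counter CSV
#'
#' Expects the canonical dialect `time_s,c0.5_0.7,...,c10.0_25.0`: one row per
#' averaging interval, one column per size channel named `c<lower>_<upper>` in
#' um. `time_s` is seconds since recording start (interval starts).
#'
#' @param path Path to a CSV file.
#' @param channels Channel bank the file must contain ([channel_bank()]).
#' @param cumulative If `TRUE`, columns are cumulative >=size counts as some
#'   instruments export them; adjacent columns are differenced into
#'   per-channel differential counts on read.
#' @param sample_period_s,flow_rate_lpm Instrument settings recorded on the
#'   returned frame.
#' @return A [particle_frame()].
#' @export
read_particle_csv <- function(path, channels = channel_bank(),
                              cumulative = FALSE,
                              sample_period_s = 7, flow_rate_lpm = 100) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("time_s", channels$name), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Particle CSV %s is missing column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  counts <- as.matrix(raw[, channels$name])
  if (cumulative) {
    # cumulative >= lower-bound counts: channel k = col k - col k+1, last as-is
    k <- ncol(counts)
    counts <- cbind(counts[, -k, drop = FALSE] - counts[, -1, drop = FALSE],
                    counts[, k])
    colnames(counts) <- channels$name
  }
  bad <- which(apply(counts, 1, function(r) any(!is.finite(r) | r < 0)))
  if (length(bad) > 0) {
    # +1 for the header line so the message points at the file line
    abort(sprintf(
      "Negative or non-finite counts in %s at data row(s): %s (file line(s) %s).",
      path, paste(head(bad, 5), collapse = ", "),
      paste(head(bad + 1, 5), collapse = ", ")
    ))
  }
  particle_frame(raw$time_s, counts, channels = channels,
                 sample_period_s = sample_period_s,
                 flow_rate_lpm = flow_rate_lpm)
}

#' Write a particle frame to CSV
#'
#' Inverse of [read_particle_csv()]; `read(write(x))` reproduces the counts
#' matrix exactly.
#'
#' @param frame A [particle_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_particle_csv <- function(frame, path) {
  readr::write_csv(as_tibble(as.data.frame(frame)), path, progress = FALSE)
  invisible(path)
}

#' Read an event-annotation log
#'
#' Dialect: `time_s,label` with labels from the closed vocabulary
#' ([event_labels()]). Coughing and gagging are recorded as `burp`.
#'
#' @param path Path to a CSV file (may be header-only).
#' @return Tibble with columns `time_s`, `label`, sorted by time.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           time_s = readr::col_double(),
                           label = readr::col_character()
                         ))
  validate_annotations(raw)
}

#' @rdname read_annotations
#' @param annotations Annotation tibble to write.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(validate_annotations(annotations), path, progress = FALSE)
  invisible(path)
}

#' Read or write procedure metadata JSON
#'
#' One JSON file per procedure with the [procedure_record()] fields;
#' annotations are embedded as an array of `{time_s, label}` objects.
#'
#' @param path Path to a JSON file.
#' @return A [procedure_record()].
#' @export
read_procedure_record <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ann <- if (is.null(x$annotations) || length(x$annotations) == 0) {
    NULL
  } else {
    as_tibble(x$annotations)
  }
  procedure_record(
    procedure_id = x$procedure_id,
    arm = x$arm,
    procedure_start_s = x$procedure_start_s,
    procedure_end_s = x$procedure_end_s,
    sedation = x$sedation %||% "none",
    demographics = x$demographics %||% list(),
    annotations = ann,
    recording_end_s = x$recording_end_s
  )
}

#' @rdname read_procedure_record
#' @param record A [procedure_record()] to write.
#' @export
write_procedure_record <- function(record, path) {
  x <- unclass(record)
  x$reference_ok <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write and read fold-change result tables
#'
#' Results are the tidied rows of [ratio_estimate()] objects: one comparison
#' per row with the estimate, 95% CI bounds, two-sided p and group sizes, in a
#' fixed column order. Numeric fields round-trip to at least 12 significant
#' digits.
#'
#' @param results A tibble of tidied ratio estimates, a single
#'   `ratio_estimate`, or a list of them.
#' @param path Output CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_results <- function(results, path) {
  results <- as_results_tibble(results)
  printable <- mutate(results,
                      across(dplyr::where(is.numeric),
                             ~ formatC(.x, digits = 15, format = "g")))
  tryCatch(
    readr::write_csv(printable, path, progress = FALSE),
    error = function(e) {
      abort(sprintf("Cannot write results to %s: %s", path,
                    conditionMessage(e)))
    }
  )
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

results_columns <- function() {
  c("comparison", "fraction", "variant", "ratio", "ci_low", "ci_high",
    "p_value", "n_a", "n_b", "method")
}

as_results_tibble <- function(results) {
  if (inherits(results, "ratio_estimate")) results <- list(results)
  if (is.list(results) && !is.data.frame(results)) {
    results <- bind_rows(map(results, tidy_ratio_row))
  }
  results <- as_tibble(results)
  for (col in results_columns()) {
    if (!col %in% names(results)) {
      results[[col]] <- if (col %in% c("ratio", "ci_low", "ci_high",
                                       "p_value", "n_a", "n_b")) {
        numeric(nrow(results))
      } else {
        rep(NA_character_, nrow(results))
      }
    }
  }
  results[, results_columns()]
}

tidy_ratio_row <- function(est) {
  tibble(
    comparison = est$comparison %||% NA_character_,
    fraction = est$fraction %||% NA_character_,
    variant = est$variant %||% NA_character_,
    ratio = est$ratio, ci_low = est$ci_low, ci_high = est$ci_high,
    p_value = est$p_value, n_a = est$n_a, n_b = est$n_b,
    method = est$method
  )
}
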