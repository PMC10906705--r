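#' Configuration for a synthetic two-arm particle study
#'
#' Defines the study conditions emulated by the generator: cohort sizes and
#' procedure durations matching the published two-arm design (37 EGD vs 18
#' capsule-sponge procedures, mean durations 7.2 and 8.1 min), a slowly
#' varying room background modelled as a first-order autoregressive process
#' on log intensity, per-patient in-procedure emission with a configurable
#' true fold difference between arms, and transient event spikes with
#' log-normally distributed amplitudes whose means are set as multiples of
#' the expected null-reference excess (see [expected_null_excess()]).
#'
#' @param n_egd,n_cytosponge Cohort sizes.
#' @param sample_period_s Counter averaging interval (s).
#' @param flow_rate_lpm Counter flow rate (L/min).
#' @param channels Channel bank ([channel_bank()]).
#' @param channel_weights Relative share of total intensity per channel;
#'   default a decreasing power law (most particles are small).
#' @param background List: `log_level` (log mean total counts/interval),
#'   `ar_coef` (lag-1 autoregressive coefficient in `[0,1)`), `innovation_sd`
#'   (log-scale innovation SD per interval), `drift_per_hour` (log-scale
#'   linear drift).
#' @param emission List: `aerosol_gm`, `droplet_gm` (geometric-mean
#'   in-procedure emission, counts/interval, for the Cytosponge arm),
#'   `sd_log` (between-patient log-scale SD).
#' @param arm_ratio Named vector: true EGD/Cytosponge fold difference in
#'   per-unit-time emission for `aerosol` and `droplet`.
#' @param event_ratios Tibble (`label`, `arm`, `aerosol`, `droplet`): true
#'   mean event excess as a multiple of the null-reference excess. Ratios
#'   <= 1 inject nothing.
#' @param event_sd_log Log-scale SD of event amplitudes between events.
#' @param event_decay Geometric decay factor of an event's contribution
#'   across successive intervals.
#' @param event_decay_intervals Number of intervals an event spreads over.
#' @param burp_rate_per_20min Named vector of mean burping events per 20
#'   minutes per arm.
#' @param duration_mean_min,duration_cv Procedure-duration model (log-normal;
#'   per-arm mean in minutes, common coefficient of variation).
#' @param pre_roll_min,post_roll_min Recording margin before the procedure
#'   start (must exceed the 5-min reference window) and after the end.
#' @param throat_spray_prob_cyto Probability a capsule-sponge patient
#'   receives throat spray (22% observed).
#' @param midazolam_prob_egd Probability an EGD patient is sedated with
#'   midazolam in addition to throat spray.
#' @param seed Integer seed making the whole study reproducible.
#' @param calibrate If `TRUE` (default), compute `null_excess` (the expected
#'   per-fraction null-reference positive excess under this background) by
#'   internal simulation; event amplitudes are expressed relative to it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_egd = 37, n_cytosponge = 18,
                             sample_period_s = 7, flow_rate_lpm = 100,
                             channels = channel_bank(),
                             channel_weights = (1:6)^(-1.5),
                             background = list(log_level = log(50),
                                               ar_coef = 0.9,
                                               innovation_sd = 0.05,
                                               drift_per_hour = 0),
                             emission = list(aerosol_gm = 600,
                                             droplet_gm = 60,
                                             sd_log = 0.6),
                             arm_ratio = c(aerosol = 2.16, droplet = 1.0),
                             event_ratios = default_event_ratios(),
                             event_sd_log = 1.0,
                             event_decay = 0.5,
                             event_decay_intervals = 3,
                             burp_rate_per_20min = c(EGD = 1.97,
                                                     Cytosponge = 1.46),
                             duration_mean_min = c(EGD = 7.2,
                                                   Cytosponge = 8.1),
                             duration_cv = 0.25,
                             pre_roll_min = 6, post_roll_min = 1,
                             throat_spray_prob_cyto = 4 / 18,
                             midazolam_prob_egd = 16 / 37,
                             seed = 1,
                             calibrate = TRUE) {
  if (n_egd < 2 || n_cytosponge < 2) abort("Cohort sizes must be >= 2.")
  if (background$ar_coef < 0 || background$ar_coef >= 1) {
    abort("`background$ar_coef` must lie in [0, 1).")
  }
  if (background$innovation_sd < 0 || emission$sd_log < 0 ||
      event_sd_log < 0) {
    abort("Scale parameters must be non-negative.")
  }
  if (length(channel_weights) != nrow(channels) || any(channel_weights <= 0)) {
    abort("`channel_weights` must be positive, one per channel.")
  }
  if (pre_roll_min < 5) {
    abort("`pre_roll_min` must be >= 5 so a reference window exists.")
  }
  cfg <- structure(list(
    n_egd = n_egd, n_cytosponge = n_cytosponge,
    sample_period_s = sample_period_s, flow_rate_lpm = flow_rate_lpm,
    channels = channels,
    channel_weights = channel_weights / sum(channel_weights),
    background = background, emission = emission, arm_ratio = arm_ratio,
    event_ratios = event_ratios, event_sd_log = event_sd_log,
    event_decay = event_decay,
    event_decay_intervals = event_decay_intervals,
    burp_rate_per_20min = burp_rate_per_20min,
    duration_mean_min = duration_mean_min, duration_cv = duration_cv,
    pre_roll_min = pre_roll_min, post_roll_min = post_roll_min,
    throat_spray_prob_cyto = throat_spray_prob_cyto,
    midazolam_prob_egd = midazolam_prob_egd,
    seed = seed
  ), class = "synthetic_config")
  cfg$null_excess <- if (calibrate) expected_null_excess(cfg) else
    c(aerosol = NA_real_, droplet = NA_real_)
  cfg
}

#' @rdname synthetic_config
#' @export
default_event_ratios <- function() {
  tibble(
    label = c("insertion", "removal", "throat_spray", "burp",
              "intubation", "extubation", "throat_spray", "burp"),
    arm = rep(c("Cytosponge", "EGD"), each = 4),
    aerosol = c(1, 14.6, 138.1, 3, 1, 14.6, 138.1, 8.46),
    droplet = c(1, 62.6, 16.2, 14.6, 1, 62.6, 158.8, 14.6)
  )
}

fraction_channel_split <- function(config, cutoff_um = 5) {
  bank <- classify_channels(config$channels, cutoff_um)
  w <- config$channel_weights
  list(
    aerosol = ifelse(bank$fraction == "aerosol",
                     w / sum(w[bank$fraction == "aerosol"]), 0),
    droplet = ifelse(bank$fraction == "droplet",
                     w / sum(w[bank$fraction == "droplet"]), 0)
  )
}

#' Simulate the slowly varying room background
#'
#' The room background is a first-order autoregressive process on log total
#' intensity (initialised at stationarity, with optional linear drift),
#' exponentiated, split across channels by the configured weight vector and
#' rounded to integer counts. With zero innovation SD and zero drift the
#' series is exactly constant.
#'
#' @param config A [synthetic_config()].
#' @param duration_s Recording length in seconds (>= 10 sampling intervals).
#' @return A [particle_frame()] carrying the unrounded per-channel intensity
#'   matrix as attribute `"lambda"`. Draws from the current RNG state; seed
#'   externally (e.g. [withr::with_seed()]) for reproducibility.
#' @export
generate_background <- function(config, duration_s) {
  p <- config$sample_period_s
  if (duration_s < 10 * p) {
    abort("`duration_s` must cover at least 10 sampling intervals.")
  }
  n <- floor(duration_s / p)
  bg <- config$background
  eps <- rnorm(n, 0, bg$innovation_sd)
  init <- if (bg$ar_coef > 0 && bg$innovation_sd > 0) {
    rnorm(1, 0, bg$innovation_sd / sqrt(1 - bg$ar_coef^2))
  } else 0
  ar <- as.numeric(stats::filter(eps, bg$ar_coef, method = "recursive",
                                 init = init))
  time_s <- (seq_len(n) - 1) * p
  l <- bg$log_level + ar + bg$drift_per_hour * time_s / 3600
  lambda <- exp(l) %o% config$channel_weights
  colnames(lambda) <- config$channels$name
  out <- particle_frame(time_s, round(lambda), channels = config$channels,
                        sample_period_s = p,
                        flow_rate_lpm = config$flow_rate_lpm)
  attr(out, "lambda") <- lambda
  out
}

refresh_counts <- function(frame) {
  lambda <- attr(frame, "lambda")
  counts <- round(lambda)
  for (j in seq_len(ncol(counts))) {
    frame[[colnames(counts)[j]]] <- counts[, j]
  }
  frame
}

#' Inject a transient event spike into a synthetic trace
#'
#' Adds a log-normally drawn amplitude to the intensity at the first interval
#' starting at or after `time_s`, decayed geometrically over
#' `event_decay_intervals` intervals, split between the aerosol and droplet
#' fractions according to the event's configured fold ratios over the
#' expected null excess (`mean amplitude = (ratio - 1) x null excess`, so
#' the expected measured excess -- amplitude plus subtraction noise -- is
#' `ratio x null excess`; ratios <= 1 inject nothing in that fraction).
#' Counts are re-rounded from the updated intensity, so repeated injections
#' compose before rounding.
#'
#' @param frame A [particle_frame()] from [generate_background()] (with the
#'   `"lambda"` intensity attribute).
#' @param time_s Event time (seconds, within the recording).
#' @param label Event label ([event_labels()]).
#' @param config A [synthetic_config()].
#' @param arm Study arm, selecting the event-ratio row.
#' @param amplitude Optional named vector `c(aerosol=, droplet=)` of exact
#'   total amplitudes, bypassing the ratio model (used for degenerate
#'   configurations and tests).
#' @return A list: `frame` (modified), `truth` (one-row tibble: `label`,
#'   `time_s`, `interval`, `aerosol_amp`, `droplet_amp`).
#' @export
inject_event <- function(frame, time_s, label, config, arm = "Cytosponge",
                         amplitude = NULL) {
  stopifnot(label %in% event_labels())
  lambda <- attr(frame, "lambda")
  n <- nrow(lambda)
  p <- attr(frame, "sample_period_s")
  if (time_s < frame$time_s[1] || time_s > frame$time_s[n] + p) {
    abort("`time_s` must lie within the recording.")
  }
  i0 <- which(frame$time_s >= time_s)[1]
  if (is.na(i0)) i0 <- n
  if (is.null(amplitude)) {
    er <- config$event_ratios
    row <- which(er$label == label & er$arm == arm)
    amplitude <- c(aerosol = 0, droplet = 0)
    for (frac in c("aerosol", "droplet")) {
      r <- if (length(row) == 1) er[[frac]][row] else 1
      if (r > 1) {
        if (!is.finite(config$null_excess[[frac]])) {
          abort(paste("Ratio-based event amplitudes need a calibrated",
                      "config (synthetic_config(calibrate = TRUE))."))
        }
        # measured event excess = amplitude + subtraction noise, and the
        # null level L is the mean positive part of that noise, so a mean
        # amplitude of (r - 1) * L makes the expected measured excess r * L:
        # exact at r = 1 (inject nothing), asymptotically exact for large r
        m <- (r - 1) * config$null_excess[[frac]]
        s <- config$event_sd_log
        amplitude[[frac]] <- rlnorm(1, log(m) - s^2 / 2, s)
      }
    }
  }
  k <- config$event_decay_intervals
  w <- config$event_decay^(seq_len(k) - 1)
  w <- w / sum(w)
  idx <- i0:min(i0 + k - 1, n)
  w <- w[seq_along(idx)] / sum(w[seq_along(idx)])
  split <- fraction_channel_split(config)
  for (frac in c("aerosol", "droplet")) {
    if (amplitude[[frac]] > 0) {
      lambda[idx, ] <- lambda[idx, , drop = FALSE] +
        (amplitude[[frac]] * w) %o% split[[frac]]
    }
  }
  attr(frame, "lambda") <- lambda
  list(
    frame = refresh_counts(frame),
    truth = tibble::new_tibble(list(
      label = label, time_s = time_s, interval = i0,
      aerosol_amp = unname(amplitude[["aerosol"]]),
      droplet_amp = unname(amplitude[["droplet"]])
    ), nrow = 1L)
  )
}

#' Expected null-reference positive excess under a study configuration
#'
#' Measures the expected mean positive null-reference excess per fraction by
#' simulating procedure-shaped recordings (autoregressive background plus a
#' constant in-procedure emission at the configured geometric mean, with a
#' typical annotation schedule but no injected event amplitudes) and running
#' the analysis-side null-sampling protocol ([sample_null_events()]) on
#' them. Event amplitudes in the generator are expressed as multiples of
#' this level, so a configured event-to-null fold ratio is a true parameter
#' of the quantity the event analysis estimates. Uses a fixed internal seed:
#' the level is a deterministic property of the configuration, independent
#' of the study seed.
#'
#' @param config A [synthetic_config()] (the `null_excess` field is ignored).
#' @param n_sim Number of simulated recordings (3 nulls sampled from each).
#' @param seed Internal calibration seed.
#' @return Named vector `c(aerosol=, droplet=)`.
#' @export
expected_null_excess <- function(config, n_sim = 500, seed = 104729) {
  split <- fraction_channel_split(config)
  withr::with_seed(seed, {
    ex <- map(seq_len(n_sim), function(i) {
      start_s <- config$pre_roll_min * 60
      dur_min <- sample_duration_min(config, "Cytosponge")
      end_s <- start_s + dur_min * 60
      frame <- generate_background(config,
                                   end_s + config$post_roll_min * 60)
      # constant emission at the configured geometric mean, so the count
      # level (hence the rounding regime) matches analysed recordings
      lambda <- attr(frame, "lambda")
      in_proc <- frame$time_s >= start_s & frame$time_s < end_s
      for (frac in c("aerosol", "droplet")) {
        gm <- config$emission[[paste0(frac, "_gm")]]
        lambda[in_proc, ] <- sweep(lambda[in_proc, , drop = FALSE], 2,
                                   gm * split[[frac]], "+")
      }
      attr(frame, "lambda") <- lambda
      frame <- refresh_counts(frame)
      ann <- schedule_events(config, "Cytosponge", start_s, end_s, "none")
      series <- aggregate_size_fractions(frame)
      tryCatch(
        sample_null_events(series, ann, n_events = 3,
                           avoid_times_s = c(start_s, end_s)),
        error = function(e) NULL
      )
    }) |> bind_rows()
    c(aerosol = positive_mean(ex$aerosol),
      droplet = positive_mean(ex$droplet))
  })
}

sample_duration_min <- function(config, arm) {
  m <- config$duration_mean_min[[arm]]
  s <- sqrt(log(1 + config$duration_cv^2))
  # floored at 5 min so the scheduled events cannot crowd each other
  max(rlnorm(1, log(m) - s^2 / 2, s), 5)
}

sample_demographics <- function(arm) {
  if (arm == "EGD") {
    list(age = round(runif(1, 24, 93)),
         sex = if (runif(1) < 23 / 37) "male" else "female",
         bmi = round(runif(1, 16.3, 38.2), 1),
         smoker = runif(1) < 9 / 37)
  } else {
    list(age = round(runif(1, 40, 78)),
         sex = if (runif(1) < 16 / 18) "male" else "female",
         bmi = round(runif(1, 22.7, 34.3), 1),
         smoker = runif(1) < 2 / 18)
  }
}

schedule_events <- function(config, arm, start_s, end_s, sedation,
                            min_sep_s = 35) {
  dur_min <- (end_s - start_s) / 60
  # device/scope events sit clear of the procedure-start boundary so their
  # 70-s baseline windows are homogeneous; all scheduled events keep
  # min_sep_s (> event window + decay span) apart so one event's activity
  # cannot leak into another's analysis window
  times <- c(start_s + runif(1, 130, 170), end_s - runif(1, 20, 60))
  labels <- if (arm == "Cytosponge") c("insertion", "removal") else
    c("intubation", "extubation")
  if (sedation != "none") {
    times <- c(times, start_s + runif(1, 75, 95))
    labels <- c(labels, "throat_spray")
  }
  n_burp <- rpois(1, config$burp_rate_per_20min[[arm]] * dur_min / 20)
  for (b in seq_len(n_burp)) {
    for (try in 1:100) {
      t_b <- runif(1, start_s + 75, end_s - 10)
      if (all(abs(t_b - times) >= min_sep_s)) {
        times <- c(times, t_b)
        labels <- c(labels, "burp")
        break
      }
    }
  }
  ord <- order(times)
  tibble::new_tibble(list(time_s = times[ord], label = labels[ord]),
                     nrow = length(times))
}

#' Generate one synthetic procedure
#'
#' Background trace, constant per-patient in-procedure emission (log-normal
#' across patients, with the configured arm fold difference), scheduled
#' events with injected spikes, demographics and metadata. Draws from the
#' current RNG state.
#'
#' @param config A [synthetic_config()].
#' @param arm `"EGD"` or `"Cytosponge"`.
#' @param procedure_id Identifier string.
#' @return A list: `frame` ([particle_frame()]), `record`
#'   ([procedure_record()]), `truth` (event-truth tibble with
#'   `procedure_id`), `emission` (named per-fraction counts/interval).
#' @export
generate_procedure <- function(config, arm, procedure_id) {
  p <- config$sample_period_s
  start_s <- config$pre_roll_min * 60
  dur_min <- sample_duration_min(config, arm)
  end_s <- start_s + dur_min * 60
  total_s <- end_s + config$post_roll_min * 60
  frame <- generate_background(config, total_s)

  sedation <- if (arm == "EGD") {
    if (runif(1) < config$midazolam_prob_egd) "midazolam_plus_spray"
    else "throat_spray_only"
  } else {
    if (runif(1) < config$throat_spray_prob_cyto) "throat_spray_only"
    else "none"
  }

  # constant per-patient emission during the procedure window
  s <- config$emission$sd_log
  split <- fraction_channel_split(config)
  lambda <- attr(frame, "lambda")
  in_proc <- frame$time_s >= start_s & frame$time_s < end_s
  emission <- c(aerosol = NA_real_, droplet = NA_real_)
  for (frac in c("aerosol", "droplet")) {
    gm <- config$emission[[paste0(frac, "_gm")]] *
      (if (arm == "EGD") config$arm_ratio[[frac]] else 1)
    emission[[frac]] <- rlnorm(1, log(gm), s)
    lambda[in_proc, ] <- sweep(lambda[in_proc, , drop = FALSE], 2,
                               emission[[frac]] * split[[frac]], "+")
  }
  attr(frame, "lambda") <- lambda
  frame <- refresh_counts(frame)

  ann <- schedule_events(config, arm, start_s, end_s, sedation)
  truth <- list()
  for (i in seq_len(nrow(ann))) {
    inj <- inject_event(frame, ann$time_s[i], ann$label[i], config,
                        arm = arm)
    frame <- inj$frame
    truth <- c(truth, list(inj$truth))
  }
  truth <- if (length(truth) > 0) {
    mutate(bind_rows(truth), procedure_id = procedure_id, .before = 1)
  } else {
    tibble(procedure_id = character(), label = character(),
           time_s = numeric(), interval = integer(),
           aerosol_amp = numeric(), droplet_amp = numeric())
  }
  record <- procedure_record(
    procedure_id = procedure_id, arm = arm,
    procedure_start_s = start_s, procedure_end_s = end_s,
    sedation = sedation,
    demographics = sample_demographics(arm),
    annotations = ann,
    recording_end_s = max(frame$time_s) + p
  )
  list(frame = frame, record = record, truth = truth, emission = emission)
}

#' Generate a complete synthetic two-arm study
#'
#' Produces `n_egd + n_cytosponge` procedures (traces, annotations,
#' metadata) with known ground truth, fully reproducible from the config
#' seed. When `dir` is given, writes the canonical on-disk layout consumed
#' by [read_study()]: per procedure `<id>_particles.csv`,
#' `<id>_annotations.csv`, `<id>_metadata.json`, plus
#' `truth_manifest.json` recording the seed, the calibrated null-excess
#' level, per-event true amplitudes and per-procedure emission.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory.
#' @return A list of class `synthetic_study`: `procedures` (list of
#'   [generate_procedure()] results), `truth` (combined event-truth tibble),
#'   `config`, and `dir` (when written).
#' @export
generate_study <- function(config, dir = NULL) {
  arms <- c(rep("EGD", config$n_egd), rep("Cytosponge", config$n_cytosponge))
  ids <- sprintf("p%03d", seq_along(arms))
  procedures <- withr::with_seed(config$seed, {
    map2(arms, ids, function(arm, id) generate_procedure(config, arm, id))
  })
  truth <- bind_rows(map(procedures, "truth"))
  study <- structure(
    list(procedures = procedures, truth = truth, config = config,
         dir = dir),
    class = "synthetic_study"
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (pr in procedures) {
      id <- pr$record$procedure_id
      write_particle_csv(pr$frame, file.path(dir,
                                             paste0(id, "_particles.csv")))
      write_annotations(pr$record$annotations,
                        file.path(dir, paste0(id, "_annotations.csv")))
      write_procedure_record(pr$record,
                             file.path(dir, paste0(id, "_metadata.json")))
    }
    manifest <- list(
      seed = config$seed,
      null_excess = as.list(config$null_excess),
      arm_ratio = as.list(config$arm_ratio),
      emission = map(procedures,
                     ~ c(list(procedure_id = .x$record$procedure_id),
                         as.list(.x$emission))),
      events = truth
    )
    jsonlite::write_json(manifest, file.path(dir, "truth_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  arms <- table(map_chr(x$procedures, ~ .x$record$arm))
  cat(sprintf(
    "<synthetic_study> %d procedures (%s), seed %d, %d true event(s)\n",
    length(x$procedures),
    paste(sprintf("%s: %d", names(arms), arms), collapse = ", "),
    x$config$seed, nrow(x$truth)))
  invisible(x)
}
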