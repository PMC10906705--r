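#' Read a study directory
#'
#' Loads every procedure from a directory in the canonical layout (one
#' `<id>_particles.csv`, `<id>_annotations.csv` and `<id>_metadata.json`
#' per procedure, as written by [generate_study()]).
#'
#' @param dir Study directory.
#' @param channels Channel bank expected in the particle CSVs.
#' @return A list of `list(frame, record)` per procedure.
#' @export
read_study <- function(dir, channels = channel_bank()) {
  if (!dir.exists(dir)) abort(sprintf("Study directory not found: %s", dir))
  meta <- sort(list.files(dir, pattern = "_metadata\\.json$",
                          full.names = TRUE))
  if (length(meta) == 0) {
    abort(sprintf("No *_metadata.json files in %s.", dir))
  }
  map(meta, function(m) {
    id <- sub("_metadata\\.json$", "", basename(m))
    record <- read_procedure_record(m)
    frame <- read_particle_csv(file.path(dir, paste0(id, "_particles.csv")),
                               channels = channels)
    ann_path <- file.path(dir, paste0(id, "_annotations.csv"))
    if (file.exists(ann_path)) {
      record$annotations <- read_annotations(ann_path)
    }
    list(frame = frame, record = record)
  })
}

#' Run the full two-arm analysis
#'
#' End-to-end orchestration over a study (a directory or an in-memory
#' [generate_study()] object): per-procedure summaries, whole-procedure arm
#' comparisons (raw and spike-filtered, both fractions, with and without
#' throat-spray exclusion), within-patient procedure-vs-reference ratios,
#' per-event-type fold changes over sampled null-reference events,
#' cross-arm event comparisons (insertion vs intubation, removal vs
#' extubation, throat spray and burping like-for-like), a cohort table, and
#' a run manifest with every parameter and the seed. All stochastic steps
#' (null sampling, bootstrap) consume one seeded RNG stream, so a rerun
#' with the same inputs and seed reproduces every number exactly.
#'
#' @param study A study directory path or a `synthetic_study`.
#' @param seed Integer seed for null sampling and bootstrap resampling.
#' @param cutoff_um Aerosol/droplet cutoff (um).
#' @param kernel_samples Running-median width for the spike variant.
#' @param reference_window_min,target_duration_min Whole-procedure analysis
#'   windows (minutes).
#' @param event_window_s,baseline_window_s Event-analysis windows (seconds).
#' @param nulls_per_procedure,min_gap_s Null-reference sampling settings.
#' @param n_boot Bootstrap resamples per event comparison.
#' @param pseudocount Log-transform shift for whole-procedure tests.
#' @return A list of class `study_results`: `comparisons` (tidy tibble of
#'   every fold-change estimate), `summaries`, `events` (all event
#'   excesses incl. sampled nulls), `cohort`, `mixture` (mixture fits to the
#'   pooled signed event excesses per fraction) and `manifest`.
#' @export
run_study <- function(study, seed = 1, cutoff_um = 5, kernel_samples = 11,
                      reference_window_min = 5, target_duration_min = 20,
                      event_window_s = 21, baseline_window_s = 70,
                      nulls_per_procedure = 3, min_gap_s = 60,
                      n_boot = 10000, pseudocount = 1) {
  procedures <- if (is.character(study)) read_study(study) else
    study$procedures
  if (length(procedures) < 4) {
    abort("A study needs at least 2 procedures per arm.")
  }
  withr::with_seed(seed, {
    series <- map(procedures, ~ aggregate_size_fractions(.x$frame,
                                                         cutoff_um))
    summaries <- bind_rows(map2(series, procedures, function(s, pr) {
      summarize_procedure(s, pr$record, kernel_samples = kernel_samples,
                          reference_window_min = reference_window_min,
                          target_duration_min = target_duration_min)
    }))

    comparisons <- list()
    for (frac in c("aerosol", "droplet")) {
      for (variant in c("raw", "spike")) {
        comparisons <- c(comparisons, list(
          compare_arms(summaries, frac, variant, pseudocount = pseudocount),
          procedure_vs_reference(summaries, frac, variant,
                                 arm = "Cytosponge",
                                 pseudocount = pseudocount)
        ))
        est <- compare_arms(summaries, frac, variant,
                            exclude_throat_spray = TRUE,
                            pseudocount = pseudocount)
        est$comparison <- paste0(est$comparison, "_no_spray")
        comparisons <- c(comparisons, list(est))
      }
    }

    events <- bind_rows(map2(series, procedures, function(s, pr) {
      rec <- pr$record
      ann <- filter(rec$annotations, .data$label != "null_reference")
      real <- map(seq_len(nrow(ann)), function(i) {
        tryCatch(
          extract_event_excess(s, ann$time_s[i], ann$label[i],
                               event_window_s = event_window_s,
                               baseline_window_s = baseline_window_s,
                               procedure_id = rec$procedure_id),
          error = function(e) NULL
        )
      })
      nulls <- tryCatch(
        sample_null_events(s, ann, n_events = nulls_per_procedure,
                           min_gap_s = min_gap_s,
                           event_window_s = event_window_s,
                           baseline_window_s = baseline_window_s,
                           procedure_id = rec$procedure_id,
                           avoid_times_s = c(rec$procedure_start_s,
                                             rec$procedure_end_s)),
        error = function(e) NULL
      )
      arm_tag <- rec$arm
      bind_rows(c(real, list(nulls))) |> mutate(arm = arm_tag)
    }))

    cyto_nulls <- filter(events, .data$arm == "Cytosponge",
                         .data$label == "null_reference")
    egd_nulls <- filter(events, .data$arm == "EGD",
                        .data$label == "null_reference")
    for (frac in c("aerosol", "droplet")) {
      for (lab in c("insertion", "removal", "throat_spray", "burp")) {
        ev <- filter(events, .data$arm == "Cytosponge", .data$label == lab)
        if (nrow(ev) > 0 && nrow(cyto_nulls) > 0) {
          comparisons <- c(comparisons, list(
            event_vs_null(ev, cyto_nulls, frac, n_boot = n_boot)))
        }
      }
      cross <- list(c("intubation", "insertion"),
                    c("extubation", "removal"),
                    c("throat_spray", "throat_spray"),
                    c("burp", "burp"))
      for (pair in cross) {
        a <- filter(events, .data$arm == "EGD", .data$label == pair[1])
        b <- filter(events, .data$arm == "Cytosponge",
                    .data$label == pair[2])
        if (nrow(a) > 0 && nrow(b) > 0) {
          est <- bootstrap_ratio(a, b, frac, n_boot = n_boot)
          est$comparison <- sprintf("EGD_%s_vs_Cytosponge_%s",
                                    pair[1], pair[2])
          comparisons <- c(comparisons, list(est))
        }
      }
    }

    mixture <- map(setNames(c("aerosol", "droplet"),
                            c("aerosol", "droplet")), function(frac) {
      x <- events[[frac]]
      if (length(x) >= 8 && any(x > 0)) {
        fit_lognormal_normal_mixture(x)
      } else NULL
    })

    cohort <- cohort_table(map(procedures, "record"))

    manifest <- list(
      seed = seed, cutoff_um = cutoff_um, kernel_samples = kernel_samples,
      reference_window_min = reference_window_min,
      target_duration_min = target_duration_min,
      event_window_s = event_window_s,
      baseline_window_s = baseline_window_s,
      nulls_per_procedure = nulls_per_procedure, min_gap_s = min_gap_s,
      n_boot = n_boot, pseudocount = pseudocount,
      n_procedures = length(procedures),
      input = if (is.character(study)) study else "in-memory synthetic study"
    )
    structure(list(
      comparisons = as_results_tibble(comparisons),
      summaries = summaries, events = events, cohort = cohort,
      mixture = mixture, manifest = manifest
    ), class = "study_results")
  })
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d procedures, %d comparisons, seed %d\n",
              x$manifest$n_procedures, nrow(x$comparisons),
              x$manifest$seed))
  print(x$comparisons, n = nrow(x$comparisons))
  invisible(x)
}

#' Write a study-results bundle to disk
#'
#' Emits the machine-readable comparison table (CSV, via [write_results()]),
#' the cohort table (CSV) and the run manifest (JSON) into a directory.
#'
#' @param results A `study_results` object from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_results(results$comparisons, file.path(dir, "comparisons.csv"))
  readr::write_csv(results$cohort, file.path(dir, "cohort.csv"),
                   progress = FALSE)
  jsonlite::write_json(results$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
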