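# Shared machinery for simulation-based calibration and recovery checks.

study_summaries <- function(study) {
  dplyr::bind_rows(lapply(study$procedures, function(pr) {
    s <- aggregate_size_fractions(pr$frame)
    summarize_procedure(s, pr$record)
  }))
}

# removal events vs sampled null references, Cytosponge arm, aerosol fraction
removal_vs_null_estimate <- function(study, n_boot = 1000,
                                     fraction = "aerosol") {
  ev <- list(); nu <- list()
  for (pr in study$procedures) {
    if (pr$record$arm != "Cytosponge") next
    s <- aggregate_size_fractions(pr$frame)
    ann <- pr$record$annotations
    for (k in which(ann$label == "removal")) {
      ev[[length(ev) + 1]] <- extract_event_excess(
        s, ann$time_s[k], "removal",
        procedure_id = pr$record$procedure_id)
    }
    nulls <- tryCatch(
      sample_null_events(
        s, ann, n_events = 3, procedure_id = pr$record$procedure_id,
        avoid_times_s = c(pr$record$procedure_start_s,
                          pr$record$procedure_end_s)),
      error = function(e) NULL)
    if (!is.null(nulls)) nu[[length(nu) + 1]] <- nulls
  }
  event_vs_null(dplyr::bind_rows(ev), dplyr::bind_rows(nu),
                fraction = fraction, n_boot = n_boot)
}
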