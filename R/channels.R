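#' Particle-size channel banks
#'
#' An optical particle counter reports counts in a bank of contiguous,
#' non-overlapping diameter ranges. The default bank is the six ranges of the
#' AeroTrak-class counters used for procedure monitoring: 0.5--0.7, 0.7--1.0,
#' 1.0--3.0, 3.0--5.0, 5.0--10.0 and 10.0--25.0 um. Channels at or below
#' 5 um diameter are the aerosol fraction (long airborne residence,
#' inhalable); channels above 5 um are the droplet fraction (settle quickly,
#' contaminate surfaces).
#'
#' @param lower_um,upper_um Numeric vectors of channel bounds in um.
#' @return A tibble with columns `lower_um`, `upper_um` and `name` (the
#'   canonical column name used in particle CSVs, e.g. `"c0.5_0.7"`).
#' @examples
#' channel_bank()
#' channel_bank(lower_um = c(0.3, 1), upper_um = c(1, 10))
#' @export
channel_bank <- function(lower_um = c(0.5, 0.7, 1.0, 3.0, 5.0, 10.0),
                         upper_um = c(0.7, 1.0, 3.0, 5.0, 10.0, 25.0)) {
  if (length(lower_um) != length(upper_um) || length(lower_um) == 0) {
    abort("`lower_um` and `upper_um` must be non-empty and the same length.")
  }
  if (any(!is.finite(lower_um)) || any(!is.finite(upper_um))) {
    abort("Channel bounds must be finite.")
  }
  if (any(lower_um >= upper_um)) {
    abort("Each channel must satisfy lower_um < upper_um.")
  }
  ord <- order(lower_um)
  lower_um <- lower_um[ord]
  upper_um <- upper_um[ord]
  if (length(lower_um) > 1 &&
      any(abs(lower_um[-1] - upper_um[-length(upper_um)]) > 1e-9)) {
    abort("Channels must be contiguous and non-overlapping.")
  }
  tibble(
    lower_um = lower_um,
    upper_um = upper_um,
    name = channel_names(lower_um, upper_um)
  )
}

channel_names <- function(lower_um, upper_um) {
  fmt <- function(x) sprintf("%.1f", x)
  paste0("c", fmt(lower_um), "_", fmt(upper_um))
}

#' Classify channels as aerosol or droplet under a diameter cutoff
#'
#' @param bank A channel bank tibble from [channel_bank()].
#' @param cutoff_um Diameter cutoff in um; channels with `upper_um <=
#'   cutoff_um` are aerosol, channels with `lower_um >= cutoff_um` are
#'   droplet. The default 5 um is the conventional aerosol/droplet boundary.
#' @return The bank with an added `fraction` factor column
#'   (`"aerosol"`/`"droplet"`).
#' @export
classify_channels <- function(bank, cutoff_um = 5) {
  straddle <- bank$lower_um < cutoff_um & bank$upper_um > cutoff_um
  if (any(straddle)) {
    abort(sprintf(
      "Channel(s) %s straddle the %g um cutoff; every channel must lie on one side.",
      paste(bank$name[straddle], collapse = ", "), cutoff_um
    ))
  }
  mutate(bank, fraction = factor(
    ifelse(.data$upper_um <= cutoff_um, "aerosol", "droplet"),
    levels = c("aerosol", "droplet")
  ))
}

#' The closed vocabulary of procedure event labels
#'
#' Annotated aerosol-generating events: device insertion and removal (for the
#' capsule-sponge arm), endoscope intubation and extubation (for the EGD arm),
#' anesthetic throat-spray application, burping (defined broadly: any
#' involuntary audible expulsion of air from the mouth, including coughing and
#' gagging), and the null-reference pseudo-event marking a quiet stretch with
#' no activity.
#'
#' @return Character vector of accepted event labels.
#' @export
event_labels <- function() {
  c("insertion", "removal", "intubation", "extubation",
    "throat_spray", "burp", "null_reference")
}
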