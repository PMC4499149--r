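# Construct presets: published FRET levels and default kinetics per
# partial-duplex DNA construct, bundled with matching detection settings.

.PRESET_NAMES <- c("pd-35T", "pd-50T", "pd-30ThGQ", "pd-12ThGQ",
                   "pd-28TCy3hGQ", "pd-30ThGQ-12bp")

#' Construct presets
#'
#' Bundles, per DNA construct, the published FRET peak levels as simulator
#' defaults, a matching detection configuration, default kinetics
#' (Table-1-style amplitudes and half-saturation constants), and the
#' detection mode the construct calls for:
#' \describe{
#'   \item{pd-35T, pd-50T}{poly-T overhangs (35/50 nt), no GQ; baseline
#'     peaks 0.35 +/- 0.06 and 0.19 +/- 0.04; reeling-event detection.}
#'   \item{pd-30ThGQ}{30T spacer + telomeric GQ; baseline 0.23 +/- 0.05;
#'     GQ-event-cluster detection. Its amplitude parameter is the
#'     initiation (reeling-attempt) rate; the measured GQ-event amplitude
#'     is \code{p_unfold} times it.}
#'   \item{pd-12ThGQ}{12T spacer (no reeling); folded peaks 0.46 +/- 0.04
#'     and 0.62 +/- 0.05, unfolded 0.26 +/- 0.09; unfolding-dip detection.
#'     The simulator uses the dominant 0.62 conformer as the folded level.}
#'   \item{pd-28TCy3hGQ}{internally labeled control, peak 0.79 +/- 0.05;
#'     histogram use only.}
#'   \item{pd-30ThGQ-12bp}{duplex-capped construct for the spot-count
#'     unwinding assay; carries movie defaults instead of trace kinetics.}
#' }
#'
#' @param name one of \code{"pd-35T"}, \code{"pd-50T"}, \code{"pd-30ThGQ"},
#'   \code{"pd-12ThGQ"}, \code{"pd-28TCy3hGQ"}, \code{"pd-30ThGQ-12bp"}.
#' @param total_intensity_mean total rendered intensity per frame.
#' @return A list of class \code{construct_preset} with \code{name},
#'   \code{mode} (\code{"reeling"}, \code{"gq"}, \code{"dips"},
#'   \code{"histogram"} or \code{"spots"}), \code{fsm}, \code{pp},
#'   \code{kp}, \code{det} and, for the spot construct, \code{movie}.
#' @export
construct_preset <- function(name, total_intensity_mean = 1000) {
  name <- match.arg(name, .PRESET_NAMES)
  mk <- function(mode, fsm, kp, det, movie = NULL) {
    pp <- photophysics_params(
      total_intensity_mean = total_intensity_mean,
      noise_sd_floor = noise_floor_for_sigma(fsm, total_intensity_mean),
      donor_bleach_rate = 5e-4, acceptor_bleach_rate = 0)
    structure(list(name = name, mode = mode, fsm = fsm, pp = pp, kp = kp,
                   det = det, movie = movie),
              class = "construct_preset")
  }
  switch(
    name,
    "pd-35T" = mk(
      "reeling",
      fret_state_map(baseline_mean = 0.35, baseline_sigma = 0.06,
                     bound_dip_mean = 0.30, high_mean = 0.75,
                     high_sigma = 0.05),
      kinetic_params(event_amp_A = 0.35, event_Keq = 86.2,
                     titrant = "BLM", fixed_cofactor_level = 20,
                     spacer_length = 35, gq_length = 0, conc_unit = "nM"),
      detection_config(baseline_mean = 0.35, baseline_sigma = 0.06)),
    "pd-50T" = mk(
      "reeling",
      fret_state_map(baseline_mean = 0.19, baseline_sigma = 0.04,
                     bound_dip_mean = 0.15, high_mean = 0.75,
                     high_sigma = 0.05),
      kinetic_params(event_amp_A = 0.17, event_Keq = 8.7,
                     titrant = "ATP", fixed_cofactor_level = 20,
                     spacer_length = 50, gq_length = 0, conc_unit = "uM"),
      detection_config(baseline_mean = 0.19, baseline_sigma = 0.04)),
    "pd-30ThGQ" = mk(
      "gq",
      fret_state_map(baseline_mean = 0.23, baseline_sigma = 0.05,
                     bound_dip_mean = 0.19, high_mean = 0.75,
                     high_sigma = 0.05, unfolded_dip_mean = 0.40,
                     unfolded_sigma = 0.06),
      kinetic_params(event_amp_A = 0.12 / 0.7, event_Keq = 13.3,
                     titrant = "ATP", fixed_cofactor_level = 20,
                     spacer_length = 30, gq_length = 23, p_unfold = 0.7,
                     conc_unit = "uM"),
      detection_config(baseline_mean = 0.23, baseline_sigma = 0.05,
                       unfolded_mean = 0.40, unfolded_sigma = 0.06)),
    "pd-12ThGQ" = mk(
      "dips",
      fret_state_map(baseline_mean = 0.62, baseline_sigma = 0.05,
                     bound_dip_mean = 0.62, high_mean = 0.65,
                     high_sigma = 0.05, unfolded_dip_mean = 0.26,
                     unfolded_sigma = 0.09),
      kinetic_params(event_amp_A = 0.48, event_Keq = 140.7,
                     titrant = "BLM", fixed_cofactor_level = 20,
                     spacer_length = 0, gq_length = 21, p_unfold = 0.7,
                     conc_unit = "nM"),
      detection_config(baseline_mean = 0.35, baseline_sigma = 0.06,
                       folded_mean = 0.62, folded_sigma = 0.05,
                       unfolded_mean = 0.26, unfolded_sigma = 0.09)),
    "pd-28TCy3hGQ" = mk(
      "histogram",
      fret_state_map(baseline_mean = 0.79, baseline_sigma = 0.05,
                     bound_dip_mean = 0.74, high_mean = 0.88,
                     high_sigma = 0.05),
      kinetic_params(event_amp_A = 0, event_Keq = 1, titrant = "BLM",
                     spacer_length = 0, gq_length = 0, conc_unit = "nM"),
      detection_config(baseline_mean = 0.35, baseline_sigma = 0.06,
                       folded_mean = 0.79, folded_sigma = 0.05)),
    "pd-30ThGQ-12bp" = mk(
      "spots",
      fret_state_map(baseline_mean = 0.23, baseline_sigma = 0.05),
      kinetic_params(event_amp_A = 0, event_Keq = 1, titrant = "BLM",
                     spacer_length = 30, gq_length = 23, conc_unit = "nM"),
      detection_config(baseline_mean = 0.23, baseline_sigma = 0.05),
      movie = list(unwind_rate = 0.01, bleach_rate = 0.002,
                   frame_interval = 5, psf_sigma = 1.3)))
}

#' @export
print.construct_preset <- function(x, ...) {
  cat(sprintf("construct preset %s (mode %s): baseline E = %.2f +/- %.2f\n",
              x$name, x$mode, x$fsm$baseline_mean, x$fsm$baseline_sigma))
  invisible(x)
}

#' Simulate baseline-only traces for a construct
#'
#' Renders traces with no helicase activity (zero initiation rate) at the
#' preset's baseline FRET level and noise; the input for histogram-peak
#' recovery checks.
#'
#' @param preset a \code{construct_preset} (or preset name).
#' @param n_traces number of traces.
#' @param duration trace duration (s).
#' @param seed integer seed.
#' @param frame_interval frame interval (s).
#' @return A list of \code{smfret_trace}.
#' @export
simulate_baseline_traces <- function(preset, n_traces = 300, duration = 10,
                                     seed = 1L, frame_interval = 0.032) {
  if (is.character(preset)) preset <- construct_preset(preset)
  stopifnot(inherits(preset, "construct_preset"))
  kp <- preset$kp
  kp$event_amp_A <- 0
  set.seed(seed)
  lapply(seq_len(n_traces), function(i) {
    path <- simulate_state_path(kp, 1, duration)
    render_trace(path, preset$fsm, preset$pp,
                 frame_interval = frame_interval, construct = preset$name)
  })
}
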