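# Continuous-time stochastic simulator of the helicase/GQ state model and
# the donor-acceptor emission layer.

.STATES <- c("UNBOUND_FOLDED", "BOUND", "REELING", "WAITING_AT_JUNCTION",
             "UNFOLDING_COLLAPSE", "UNFOLDED", "POST_UNFOLD_REELING",
             "RELEASED")

#' Kinetic parameters of the state model
#'
#' One object bundles every rate and probability of the mechanistic model:
#' a helicase arrives at the construct as a Poisson process in wall time
#' whose rate follows the Langmuir isotherm
#' \eqn{\lambda(c) = A c / (c + K_{eq})} in the titrated co-factor; an
#' arrival while the DNA is occupied binds as soon as the DNA is free, so the
#' realized event count per unit observation time equals the isotherm rate
#' (the quantity the event-rate analysis estimates). Each event then binds
#' (exponential dwell), reels the spacer at the ATP-dependent speed
#' \eqn{v = v_{max}[ATP]/([ATP]+K_{ATP})}, waits at the ss/dsDNA junction
#' (exponential dwell), and on each junction visit either unfolds the GQ
#' (probability \code{p_unfold}) or releases the DNA. An unfolding collapse
#' takes \code{unfold_collapse_time} seconds, refolding is exponential at
#' \code{refold_rate}, the freed GQ nucleotides are reeled back in, and after
#' each unfold/refold cycle the helicase dissociates with probability
#' \code{dissociation_prob_per_cycle} (geometric cycle count, "a few" cycles
#' per event at the default 0.3).
#'
#' @param event_amp_A saturating event-initiation rate A (events/s).
#' @param event_Keq half-saturation constant of the titrated co-factor
#'   (same units as the concentrations passed to the simulator).
#' @param titrant which co-factor the concentration argument titrates:
#'   \code{"BLM"} or \code{"ATP"}.
#' @param fixed_cofactor_level level of the non-titrated co-factor. Only the
#'   ATP level enters the mechanics (reeling speed); it is taken from the
#'   titrated concentration when \code{titrant = "ATP"} and from this field
#'   (in uM) when \code{titrant = "BLM"}.
#' @param reel_velocity_max maximal reeling speed (nt/s).
#' @param reel_K_ATP ATP half-saturation of the reeling speed (uM).
#' @param spacer_length single-stranded spacer reeled before the junction
#'   is reached (nt); 0 suppresses the reeling phase.
#' @param gq_length nucleotides sequestered in the GQ (0 for poly-T
#'   constructs, which then never unfold).
#' @param p_unfold probability that a junction encounter unfolds the GQ.
#' @param unfold_collapse_time duration of the unfolding collapse (s).
#' @param refold_rate GQ refolding rate while unfolded (1/s).
#' @param release_rate exit rate from the junction-waiting state (1/s).
#' @param dissociation_prob_per_cycle dissociation probability after each
#'   unfold/refold cycle.
#' @param bind_dwell_mean mean dwell in the bound, pre-reeling state (s).
#' @param release_relax_time fixed relaxation time at baseline after release
#'   or dissociation, before the construct can accept the next helicase (s).
#' @param conc_unit free-text unit tag for titrated concentrations
#'   (e.g. \code{"nM"} for BLM, \code{"uM"} for ATP); carried into outputs,
#'   never converted.
#' @return An object of class \code{kinetic_params}.
#' @export
kinetic_params <- function(event_amp_A, event_Keq,
                           titrant = c("BLM", "ATP"),
                           fixed_cofactor_level = 20,
                           reel_velocity_max = 100, reel_K_ATP = 10,
                           spacer_length = 35, gq_length = 0,
                           p_unfold = 0.7, unfold_collapse_time = 0.18,
                           refold_rate = 4, release_rate = 3,
                           dissociation_prob_per_cycle = 0.3,
                           bind_dwell_mean = 0.15,
                           release_relax_time = 0.6,
                           conc_unit = "nM") {
  titrant <- match.arg(titrant)
  kp <- list(event_amp_A = event_amp_A, event_Keq = event_Keq,
             titrant = titrant, fixed_cofactor_level = fixed_cofactor_level,
             reel_velocity_max = reel_velocity_max, reel_K_ATP = reel_K_ATP,
             spacer_length = spacer_length, gq_length = gq_length,
             p_unfold = p_unfold,
             unfold_collapse_time = unfold_collapse_time,
             refold_rate = refold_rate, release_rate = release_rate,
             dissociation_prob_per_cycle = dissociation_prob_per_cycle,
             bind_dwell_mean = bind_dwell_mean,
             release_relax_time = release_relax_time,
             conc_unit = conc_unit)
  num <- kp[!names(kp) %in% c("titrant", "conc_unit")]
  if (any(vapply(num, function(v) !is.numeric(v) || v < 0, logical(1))))
    stop("rates, times, lengths and probabilities must be nonnegative")
  if (kp$p_unfold > 1 || kp$dissociation_prob_per_cycle > 1)
    stop("probabilities must lie in [0, 1]")
  structure(kp, class = "kinetic_params")
}

#' FRET levels of the mechanistic states
#'
#' Maps each state of the model to a mean apparent FRET level for the
#' emission layer: the unbound baseline, a small binding dip, the reeled-in
#' high plateau, and the unfolded-GQ dip. Reeling renders as a linear ramp
#' from baseline to the plateau (fraction of spacer reeled maps linearly to
#' FRET); the collapse renders as a linear drop of the configured duration;
#' post-unfold reeling ramps back from the dip to the plateau.
#'
#' @param baseline_mean,baseline_sigma construct baseline E and peak width.
#' @param bound_dip_mean level of the pre-rise binding dip (defaults to
#'   baseline - 0.05).
#' @param high_mean,high_sigma reeled-in plateau level and width.
#' @param unfolded_dip_mean,unfolded_sigma unfolded-GQ level and width.
#' @return An object of class \code{fret_state_map}.
#' @export
fret_state_map <- function(baseline_mean, baseline_sigma = 0.05,
                           bound_dip_mean = baseline_mean - 0.05,
                           high_mean = 0.75, high_sigma = 0.05,
                           unfolded_dip_mean = 0.40, unfolded_sigma = 0.06) {
  if (baseline_mean >= high_mean)
    stop("baseline_mean must lie below high_mean")
  means <- c(baseline_mean, bound_dip_mean, high_mean, unfolded_dip_mean)
  if (any(means < 0 | means > 1))
    stop("state FRET means must lie in [0, 1]")
  structure(list(baseline_mean = baseline_mean,
                 baseline_sigma = baseline_sigma,
                 bound_dip_mean = bound_dip_mean,
                 high_mean = high_mean, high_sigma = high_sigma,
                 unfolded_dip_mean = unfolded_dip_mean,
                 unfolded_sigma = unfolded_sigma),
            class = "fret_state_map")
}

#' Photophysics of the emission layer
#'
#' Total emitted intensity is split between donor and acceptor by the
#' instantaneous FRET level; each channel gets Gaussian noise with
#' sd = \code{noise_sd_floor} + \code{shot_noise_scale} * sqrt(mean).
#' Donor photobleaching kills both channels (no energy input); acceptor
#' bleaching reverts all intensity to the donor.
#'
#' @param total_intensity_mean total signal per frame (camera units).
#' @param noise_sd_floor additive per-channel noise floor (camera units).
#' @param shot_noise_scale shot-like noise coefficient (unitless).
#' @param donor_bleach_rate,acceptor_bleach_rate bleach rates (1/s); 0
#'   disables.
#' @return An object of class \code{photophysics_params}.
#' @export
photophysics_params <- function(total_intensity_mean = 1000,
                                noise_sd_floor = 60, shot_noise_scale = 0,
                                donor_bleach_rate = 0,
                                acceptor_bleach_rate = 0) {
  vals <- c(total_intensity_mean, noise_sd_floor, shot_noise_scale,
            donor_bleach_rate, acceptor_bleach_rate)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("photophysics parameters must be nonnegative and finite")
  structure(list(total_intensity_mean = total_intensity_mean,
                 noise_sd_floor = noise_sd_floor,
                 shot_noise_scale = shot_noise_scale,
                 donor_bleach_rate = donor_bleach_rate,
                 acceptor_bleach_rate = acceptor_bleach_rate),
            class = "photophysics_params")
}

#' Noise floor that yields a target FRET peak width
#'
#' Inverts the first-order error propagation of the FRET ratio,
#' sd(E) = sd_int * sqrt(E^2 + (1-E)^2) / I, at the construct baseline, so
#' that rendered baseline traces reproduce the printed histogram width.
#'
#' @param fsm a \code{fret_state_map}; its baseline mean/sigma set the target.
#' @param total_intensity_mean total signal per frame.
#' @return The per-channel noise sd (camera units).
#' @export
noise_floor_for_sigma <- function(fsm, total_intensity_mean = 1000) {
  e <- fsm$baseline_mean
  fsm$baseline_sigma * total_intensity_mean / sqrt(e^2 + (1 - e)^2)
}

.langmuir_rate <- function(A, Keq, c) ifelse(c <= 0, 0, A * c / (c + Keq))

#' Expected event rate at a co-factor concentration
#'
#' Closed-form Langmuir isotherm \eqn{A c / (c + K_{eq})}; the analytic
#' oracle the simulated titrations are checked against.
#'
#' @param kp a \code{kinetic_params}.
#' @param concentration titrated co-factor concentration (>= 0, in
#'   \code{kp$conc_unit}).
#' @return Expected events per second.
#' @export
expected_event_rate <- function(kp, concentration) {
  stopifnot(inherits(kp, "kinetic_params"), all(concentration >= 0))
  .langmuir_rate(kp$event_amp_A, kp$event_Keq, concentration)
}

#' Simulate a continuous-time state path
#'
#' Draws helicase arrivals as a Poisson process at the Langmuir rate and
#' plays each event through the state graph
#' UNBOUND -> BOUND -> REELING -> WAITING -> (UNFOLDING_COLLAPSE ->
#' UNFOLDED -> POST_UNFOLD_REELING -> WAITING)* -> RELEASED, with the
#' failure route WAITING -> RELEASED. Uses the current RNG state; seed the
#' session (or use \code{\link{simulate_titration}}) for reproducibility.
#'
#' @param kp a \code{kinetic_params}.
#' @param concentration titrated co-factor concentration.
#' @param duration observation time (s), > 0.
#' @return An object of class \code{state_path}: a data frame of contiguous
#'   segments (\code{state}, \code{t_start}, \code{t_end}) in
#'   \code{$segments}, plus \code{$events}, a per-event data frame with
#'   \code{t_start}, \code{t_end}, \code{success} (>= 1 unfolding collapse),
#'   \code{n_cycles} and \code{complete} (not clipped by the trace end).
#' @export
simulate_state_path <- function(kp, concentration, duration) {
  stopifnot(inherits(kp, "kinetic_params"), duration > 0,
            concentration >= 0)
  atp <- if (kp$titrant == "ATP") concentration else kp$fixed_cofactor_level
  v <- kp$reel_velocity_max * atp / (atp + kp$reel_K_ATP)
  if (kp$spacer_length > 0 && v <= 0)
    stop("zero reeling velocity with a nonzero spacer")
  lambda <- .langmuir_rate(kp$event_amp_A, kp$event_Keq, concentration)
  arrivals <- if (lambda > 0) sort(runif(rpois(1L, lambda * duration),
                                         0, duration)) else numeric(0)

  seg_state <- character(0); seg_t0 <- numeric(0); seg_t1 <- numeric(0)
  ev_t0 <- numeric(0); ev_t1 <- numeric(0)
  ev_success <- logical(0); ev_cycles <- integer(0)
  ev_complete <- logical(0)
  t_free <- 0
  for (a in arrivals) {
    t0 <- max(a, t_free)
    if (t0 >= duration) break
    st <- character(0); dw <- numeric(0)
    push <- function(state, dwell) {
      st <<- c(st, state); dw <<- c(dw, dwell)
    }
    push("BOUND", rexp(1L, 1 / kp$bind_dwell_mean))
    if (kp$spacer_length > 0) push("REELING", kp$spacer_length / v)
    n_cycles <- 0L
    repeat {
      push("WAITING_AT_JUNCTION", rexp(1L, kp$release_rate))
      if (kp$gq_length > 0 && runif(1L) < kp$p_unfold) {
        push("UNFOLDING_COLLAPSE", kp$unfold_collapse_time)
        push("UNFOLDED", rexp(1L, kp$refold_rate))
        push("POST_UNFOLD_REELING", kp$gq_length / v)
        n_cycles <- n_cycles + 1L
        if (runif(1L) < kp$dissociation_prob_per_cycle) {
          push("RELEASED", kp$release_relax_time)
          break
        }
      } else {
        push("RELEASED", kp$release_relax_time)
        break
      }
    }
    bounds <- t0 + cumsum(dw)
    starts <- c(t0, head(bounds, -1L))
    complete <- bounds[length(bounds)] <= duration
    keep <- starts < duration
    seg_state <- c(seg_state, st[keep])
    seg_t0 <- c(seg_t0, starts[keep])
    seg_t1 <- c(seg_t1, pmin(bounds[keep], duration))
    ev_t0 <- c(ev_t0, t0)
    ev_t1 <- c(ev_t1, min(bounds[length(bounds)], duration))
    ev_success <- c(ev_success, any(st == "UNFOLDING_COLLAPSE"))
    ev_cycles <- c(ev_cycles, n_cycles)
    ev_complete <- c(ev_complete, complete)
    t_free <- bounds[length(bounds)]
    if (t_free >= duration) break
  }
  # fill unbound gaps so segments tile [0, duration]
  if (length(seg_t0)) {
    gap0 <- c(0, seg_t1)
    gap1 <- c(seg_t0, duration)
    has_gap <- gap1 - gap0 > 1e-12
    all_state <- c(rep("UNBOUND_FOLDED", sum(has_gap)), seg_state)
    all_t0 <- c(gap0[has_gap], seg_t0)
    all_t1 <- c(gap1[has_gap], seg_t1)
    o <- order(all_t0)
    segments <- data.frame(state = all_state[o], t_start = all_t0[o],
                           t_end = all_t1[o], stringsAsFactors = FALSE)
  } else {
    segments <- data.frame(state = "UNBOUND_FOLDED", t_start = 0,
                           t_end = duration, stringsAsFactors = FALSE)
  }
  events <- data.frame(t_start = ev_t0, t_end = ev_t1,
                       success = ev_success, n_cycles = ev_cycles,
                       complete = ev_complete)
  structure(list(segments = segments, events = events,
                 duration = duration, concentration = concentration,
                 params = kp),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("state path: %.1f s, %d segments, %d events (%d successful)\n",
              x$duration, nrow(x$segments), nrow(x$events),
              sum(x$events$success)))
  invisible(x)
}

# Per-frame mean FRET along a state path (start level, end level, linear in
# between; constant states have equal ends).
.state_levels <- function(fsm) {
  list(
    start = c(UNBOUND_FOLDED = fsm$baseline_mean,
              BOUND = fsm$bound_dip_mean,
              REELING = fsm$baseline_mean,
              WAITING_AT_JUNCTION = fsm$high_mean,
              UNFOLDING_COLLAPSE = fsm$high_mean,
              UNFOLDED = fsm$unfolded_dip_mean,
              POST_UNFOLD_REELING = fsm$unfolded_dip_mean,
              RELEASED = fsm$baseline_mean),
    end = c(UNBOUND_FOLDED = fsm$baseline_mean,
            BOUND = fsm$bound_dip_mean,
            REELING = fsm$high_mean,
            WAITING_AT_JUNCTION = fsm$high_mean,
            UNFOLDING_COLLAPSE = fsm$unfolded_dip_mean,
            UNFOLDED = fsm$unfolded_dip_mean,
            POST_UNFOLD_REELING = fsm$high_mean,
            RELEASED = fsm$baseline_mean))
}

#' Render a state path into a noisy donor/acceptor trace
#'
#' Converts the per-frame mean FRET implied by the path and state map into
#' donor and acceptor intensities at the configured total intensity, applies
#' photobleaching (exponential bleach times per fluorophore), and adds
#' Gaussian + shot-like channel noise. Frames sample the mean FRET at frame
#' midpoints. Ground-truth state labels are recorded per frame.
#'
#' @param path a \code{state_path}.
#' @param fsm a \code{fret_state_map}.
#' @param pp a \code{photophysics_params}.
#' @param frame_interval frame interval (s).
#' @param construct construct label carried into the trace.
#' @return An \code{smfret_trace} with \code{truth_states} and
#'   \code{truth_events} attached.
#' @export
render_trace <- function(path, fsm, pp, frame_interval = 0.032,
                         construct = "") {
  stopifnot(inherits(path, "state_path"), inherits(fsm, "fret_state_map"),
            inherits(pp, "photophysics_params"))
  n <- max(2L, floor(path$duration / frame_interval))
  tmid <- (seq_len(n) - 0.5) * frame_interval
  segs <- path$segments
  idx <- findInterval(tmid, segs$t_start)
  lev <- .state_levels(fsm)
  s <- segs$state[idx]
  frac <- (tmid - segs$t_start[idx]) /
    pmax(segs$t_end[idx] - segs$t_start[idx], 1e-12)
  efret <- lev$start[s] + (lev$end[s] - lev$start[s]) * pmin(frac, 1)

  I <- pp$total_intensity_mean
  mean_d <- I * (1 - efret)
  mean_a <- I * efret
  t_bl_d <- if (pp$donor_bleach_rate > 0)
    rexp(1L, pp$donor_bleach_rate) else Inf
  t_bl_a <- if (pp$acceptor_bleach_rate > 0)
    rexp(1L, pp$acceptor_bleach_rate) else Inf
  if (is.finite(t_bl_a) && t_bl_a < t_bl_d) {
    ab <- tmid >= t_bl_a
    mean_a[ab] <- 0
    mean_d[ab] <- I
  }
  if (is.finite(t_bl_d)) {
    db <- tmid >= t_bl_d
    mean_d[db] <- 0
    mean_a[db] <- 0
  }
  sd_d <- pp$noise_sd_floor + pp$shot_noise_scale * sqrt(pmax(mean_d, 0))
  sd_a <- pp$noise_sd_floor + pp$shot_noise_scale * sqrt(pmax(mean_a, 0))
  donor <- mean_d + if (any(sd_d > 0)) rnorm(n, 0, sd_d) else 0
  acceptor <- mean_a + if (any(sd_a > 0)) rnorm(n, 0, sd_a) else 0
  tr <- new_trace(donor, acceptor, frame_interval = frame_interval,
                  construct = construct, truth_states = unname(s),
                  truth_events = path$events)
  attr(tr, "bleach_times") <- c(donor = t_bl_d, acceptor = t_bl_a)
  tr
}

#' Simulate a labeled titration dataset
#'
#' Generates an independent set of ground-truth-labeled traces at each
#' concentration, fully reproducible for a fixed seed (each concentration
#' uses a sub-seed derived from \code{seed}).
#'
#' @param kp a \code{kinetic_params}.
#' @param fsm a \code{fret_state_map}.
#' @param pp a \code{photophysics_params}.
#' @param concentrations positive concentrations of the titrated co-factor.
#' @param n_traces traces per concentration.
#' @param duration trace duration (s).
#' @param seed integer seed.
#' @param frame_interval frame interval (s).
#' @param construct construct label.
#' @return A list of class \code{titration_dataset}; one element per
#'   concentration with \code{concentration}, \code{traces} (list of
#'   \code{smfret_trace}) and \code{truth_event_counts} (complete events per
#'   trace).
#' @export
simulate_titration <- function(kp, fsm, pp, concentrations, n_traces,
                               duration, seed = 1L, frame_interval = 0.032,
                               construct = "") {
  stopifnot(length(concentrations) > 0L, all(concentrations > 0),
            n_traces >= 1L, duration > 0)
  out <- vector("list", length(concentrations))
  for (i in seq_along(concentrations)) {
    set.seed((seed %% 1000003L) * 1000L + i)
    traces <- vector("list", n_traces)
    counts <- integer(n_traces)
    for (j in seq_len(n_traces)) {
      path <- simulate_state_path(kp, concentrations[i], duration)
      traces[[j]] <- render_trace(path, fsm, pp,
                                  frame_interval = frame_interval,
                                  construct = construct)
      counts[j] <- sum(path$events$complete)
    }
    out[[i]] <- list(concentration = concentrations[i], traces = traces,
                     truth_event_counts = counts)
  }
  structure(list(points = out, seed = seed, kp = kp, fsm = fsm, pp = pp,
                 duration = duration, n_traces = n_traces),
            class = "titration_dataset")
}
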