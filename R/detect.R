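# Threshold-based event detection and dwell-time measurement.
#
# Detection runs on a running-median-smoothed FRET trace; dwell boundaries
# are then refined on the smoothed trace and transition times measured on
# raw frames, honoring the two-frame timing-error convention.

#' Detection thresholds and bands
#'
#' Bundles the construct-specific levels the detectors use. The baseline
#' band is \code{baseline_mean +/- 2 * baseline_sigma} (the construct's
#' fitted histogram peak); an event must rise above \code{high_threshold}
#' (default 0.60) to count as a completed reeling; a significant in-event
#' dip must drop at least \code{dip_depth} below the local high plateau; on
#' short-spacer GQ constructs a dip counts as an unfolding only below
#' \code{unfold_cutoff} (default 0.35), while dips bottoming in the
#' nonproductive band (default 0.40-0.50) are recorded as binding events
#' that did not unfold the GQ and are excluded from event statistics.
#'
#' @param baseline_mean,baseline_sigma construct baseline peak.
#' @param high_threshold minimum FRET the rise must reach (default 0.60).
#' @param high_sigma width of the high plateau peak (default 0.05).
#' @param unfold_cutoff dip cut-off for a counted GQ unfolding (default
#'   0.35).
#' @param nonproductive_low,nonproductive_high FRET band of dips treated as
#'   non-unfolding binding events (defaults 0.40, 0.50).
#' @param dip_depth minimum drop below the local plateau for a significant
#'   in-event dip (default 0.25 FRET units).
#' @param smoothing_window running-median window, odd (default 3).
#' @param min_dwell_frames persistence required of dips and of the return to
#'   baseline (default 3 frames).
#' @param cluster_gap_max excursions separated by less than this many
#'   seconds belong to one event cluster (default 0.5 s).
#' @param derivative_window frames over which the systematic drop ending the
#'   waiting time is assessed (default 5).
#' @param folded_mean,folded_sigma folded-GQ level for short-spacer
#'   constructs (default: the baseline peak).
#' @param unfolded_mean,unfolded_sigma unfolded-GQ level for transition-time
#'   measurement (defaults 0.26, 0.09).
#' @param level_tol fraction of a state sigma within which a raw frame
#'   counts as "at" that level when measuring transition times (default
#'   0.25; see \code{\link{measure_transition_time}}).
#' @return An object of class \code{detection_config}.
#' @export
detection_config <- function(baseline_mean, baseline_sigma = 0.05,
                             high_threshold = 0.60, high_sigma = 0.05,
                             unfold_cutoff = 0.35,
                             nonproductive_low = 0.40,
                             nonproductive_high = 0.50,
                             dip_depth = 0.25,
                             smoothing_window = 3, min_dwell_frames = 3,
                             cluster_gap_max = 0.5, derivative_window = 5,
                             folded_mean = baseline_mean,
                             folded_sigma = baseline_sigma,
                             unfolded_mean = 0.26, unfolded_sigma = 0.09,
                             level_tol = 0.25) {
  if (smoothing_window %% 2 != 1 || smoothing_window < 1)
    stop("smoothing_window must be odd and >= 1")
  if (baseline_mean >= high_threshold)
    stop("baseline_mean must lie below high_threshold")
  if (!(unfold_cutoff < nonproductive_low &&
        nonproductive_low <= nonproductive_high &&
        nonproductive_high < high_threshold))
    stop("need unfold_cutoff < nonproductive band < high_threshold")
  structure(list(baseline_mean = baseline_mean,
                 baseline_sigma = baseline_sigma,
                 high_threshold = high_threshold, high_sigma = high_sigma,
                 unfold_cutoff = unfold_cutoff,
                 nonproductive_low = nonproductive_low,
                 nonproductive_high = nonproductive_high,
                 dip_depth = dip_depth,
                 smoothing_window = smoothing_window,
                 min_dwell_frames = min_dwell_frames,
                 cluster_gap_max = cluster_gap_max,
                 derivative_window = derivative_window,
                 folded_mean = folded_mean, folded_sigma = folded_sigma,
                 unfolded_mean = unfolded_mean,
                 unfolded_sigma = unfolded_sigma,
                 level_tol = level_tol),
            class = "detection_config")
}

#' Running-median smoothing of a FRET trace
#'
#' Level reading against thresholds is done on a running median, which
#' removes single-frame shot spikes without rounding step edges by more than
#' half the window. \code{window = 1} is the identity. Timing measurements
#' are subsequently refined on the unsmoothed trace.
#'
#' @param fret a \code{fret_trace}.
#' @param window odd window size in frames.
#' @return The smoothed \code{fret_trace}.
#' @export
smooth_fret <- function(fret, window = 3) {
  stopifnot(inherits(fret, "fret_trace"))
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  if (window > 1) {
    ef <- fret$efret
    ok <- !is.na(ef)
    if (sum(ok) >= window) {
      sm <- ef
      sm[ok] <- as.numeric(runmed(ef[ok], window, endrule = "median"))
      fret$efret <- sm
    }
  }
  fret
}

# TRUE-run extraction: data.frame(start, end) of maximal TRUE runs.
.runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

# Merge runs whose gaps are below gap_frames.
.merge_runs <- function(runs, gap_frames) {
  if (nrow(runs) <= 1L) return(runs)
  out_s <- runs$start[1L]; out_e <- runs$end[1L]
  for (i in 2L:nrow(runs)) {
    if (runs$start[i] - out_e[length(out_e)] - 1L < gap_frames) {
      out_e[length(out_e)] <- runs$end[i]
    } else {
      out_s <- c(out_s, runs$start[i]); out_e <- c(out_e, runs$end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

.empty_events <- function() {
  data.frame(kind = character(0), t_start = numeric(0), t_end = numeric(0),
             reeling_time = numeric(0), waiting_time = numeric(0),
             dt_uf = numeric(0), n_cycles = integer(0),
             reached_high = logical(0), binding_dip_seen = logical(0),
             nonproductive = logical(0), stringsAsFactors = FALSE)
}

.event_row <- function(kind, t_start, t_end, reeling_time = NA_real_,
                       waiting_time = NA_real_, dt_uf = NA_real_,
                       n_cycles = 0L, reached_high = FALSE,
                       binding_dip_seen = FALSE, nonproductive = FALSE) {
  data.frame(kind = kind, t_start = t_start, t_end = t_end,
             reeling_time = reeling_time, waiting_time = waiting_time,
             dt_uf = dt_uf, n_cycles = n_cycles,
             reached_high = reached_high,
             binding_dip_seen = binding_dip_seen,
             nonproductive = nonproductive, stringsAsFactors = FALSE)
}

# Shared excursion finder: maximal runs of smoothed FRET above the baseline
# band, cluster-merged, with runs touching the valid end or the trace start
# dropped (bleach/boundary ambiguity). Returns the smoothed series too.
.excursions <- function(fret, cfg) {
  n <- min(fret$valid_until, length(fret$efret))
  if (n < 2L) return(list(e = numeric(0), runs = .empty_events()[0, 1:2]))
  e <- smooth_fret(fret, cfg$smoothing_window)$efret[seq_len(n)]
  band_top <- cfg$baseline_mean + 2 * cfg$baseline_sigma
  above <- !is.na(e) & e > band_top
  runs <- .runs(above)
  if (nrow(runs)) {
    gap_frames <- max(1L, ceiling(cfg$cluster_gap_max / fret$frame_interval))
    runs <- .merge_runs(runs, gap_frames)
    # candidate events must persist above the band (noise blips are not
    # excursions) and not be clipped by the trace start or the valid end
    runs <- runs[runs$end - runs$start + 1L >= cfg$min_dwell_frames &
                   runs$start > 1L &
                   runs$end < n - cfg$min_dwell_frames + 1L,
                 , drop = FALSE]
  }
  list(e = e, runs = runs, n = n)
}

# Plateau statistics of one excursion: the local high level (a high
# quantile, robust to in-event dips and independent of the qualification
# threshold) and entry/exit indices of the plateau band. NULL when the
# excursion never reaches high_threshold.
.plateau <- function(e, lo, hi, cfg) {
  seg <- e[lo:hi]
  if (!any(!is.na(seg) & seg >= cfg$high_threshold)) return(NULL)
  plateau <- quantile(seg, 0.9, na.rm = TRUE, names = FALSE)
  at_plateau <- which(!is.na(seg) & seg >= plateau - cfg$high_sigma)
  list(level = plateau,
       entry = lo + at_plateau[1L] - 1L,
       exit = lo + at_plateau[length(at_plateau)] - 1L)
}

#' Detect reeling events on poly-T constructs
#'
#' A reeling event is a FRET excursion above the baseline band that reaches
#' the high plateau (max smoothed FRET >= \code{high_threshold}) and then
#' returns to baseline: a rapid rise, a brief wait at the high level, and a
#' return. Per event the detector measures the reeling time (last frame at
#' the baseline mean before the rise, to entry into the plateau band), the
#' waiting time (plateau entry to the last frame at the plateau level,
#' i.e. the onset of the systematic drop), and whether a pre-rise binding
#' dip below the baseline is visible. Events overlapping the photobleach
#' point or the trace boundaries are discarded.
#'
#' @param fret a \code{fret_trace}.
#' @param cfg a \code{detection_config}.
#' @return A data frame of events, time-ordered, with columns \code{kind}
#'   (\code{"REELING"}), \code{t_start}, \code{t_end}, \code{reeling_time},
#'   \code{waiting_time}, \code{dt_uf} (\code{NA}), \code{n_cycles},
#'   \code{reached_high}, \code{binding_dip_seen}, \code{nonproductive}.
#' @export
detect_reeling_events <- function(fret, cfg) {
  stopifnot(inherits(fret, "fret_trace"), inherits(cfg, "detection_config"))
  ex <- .excursions(fret, cfg)
  out <- .empty_events()
  if (!nrow(ex$runs)) return(out)
  dt <- fret$frame_interval
  lookback <- max(1L, ceiling(0.5 / dt))
  for (i in seq_len(nrow(ex$runs))) {
    lo <- ex$runs$start[i]; hi <- ex$runs$end[i]
    pl <- .plateau(ex$e, lo, hi, cfg)
    if (is.null(pl)) next  # plateau never reached: not a reeling event
    # rise onset: last frame at/below the baseline mean before plateau entry
    pre <- seq(max(1L, lo - lookback), pl$entry - 1L)
    base_pre <- pre[!is.na(ex$e[pre]) & ex$e[pre] <= cfg$baseline_mean]
    onset <- if (length(base_pre)) base_pre[length(base_pre)] else lo
    dip_pre <- pre[pre < onset + 1L]
    binding_dip <- length(dip_pre) > 0 &&
      any(ex$e[dip_pre] < cfg$baseline_mean - cfg$baseline_sigma,
          na.rm = TRUE)
    out <- rbind(out, .event_row(
      "REELING",
      t_start = (onset - 1L) * dt, t_end = hi * dt,
      reeling_time = (pl$entry - onset) * dt,
      waiting_time = (pl$exit - pl$entry) * dt,
      reached_high = TRUE, binding_dip_seen = binding_dip))
  }
  out
}

#' Detect GQ unfolding events and unsuccessful attempts
#'
#' On long-spacer GQ constructs an event is a cluster of FRET activity above
#' the baseline band (excursions separated by less than
#' \code{cluster_gap_max} belong to one cluster). A cluster qualifies as a
#' GQ unfolding event when the rise reaches \code{high_threshold} and at
#' least one significant dip-and-rise follows: a smoothed drop of at least
#' \code{dip_depth} below the local plateau, persisting
#' \code{min_dwell_frames}, with a subsequent recovery to the high level.
#' Clusters that never reach the high threshold, or that reach it without
#' any significant dip, are classified as unsuccessful attempts (the
#' helicase reeled some or all of the spacer but released or dissociated
#' without unfolding the GQ).
#'
#' @inheritParams detect_reeling_events
#' @return A data frame of events (\code{kind} is \code{"GQ_EVENT"} or
#'   \code{"UNSUCCESSFUL_ATTEMPT"}); \code{n_cycles} counts the
#'   dip-and-rise transitions of a GQ event.
#' @export
detect_gq_events <- function(fret, cfg) {
  stopifnot(inherits(fret, "fret_trace"), inherits(cfg, "detection_config"))
  ex <- .excursions(fret, cfg)
  out <- .empty_events()
  if (!nrow(ex$runs)) return(out)
  dt <- fret$frame_interval
  for (i in seq_len(nrow(ex$runs))) {
    lo <- ex$runs$start[i]; hi <- ex$runs$end[i]
    seg <- ex$e[lo:hi]
    pl <- .plateau(ex$e, lo, hi, cfg)
    t0 <- (lo - 1L) * dt; t1 <- hi * dt
    if (is.null(pl)) {
      out <- rbind(out, .event_row("UNSUCCESSFUL_ATTEMPT", t0, t1))
      next
    }
    # a significant dip departs the plateau band for >= min_dwell_frames and
    # reaches at least dip_depth below the local plateau at its bottom
    dip_floor <- pl$level - cfg$dip_depth
    below <- !is.na(seg) & seg < pl$level - 2 * cfg$high_sigma
    dips <- .runs(below)
    if (nrow(dips)) {
      depth_ok <- vapply(seq_len(nrow(dips)), function(d) {
        min(seg[dips$start[d]:dips$end[d]], na.rm = TRUE) <= dip_floor
      }, logical(1))
      dips <- dips[dips$end - dips$start + 1L >= cfg$min_dwell_frames &
                     depth_ok, , drop = FALSE]
    }
    n_cycles <- 0L
    if (nrow(dips)) {
      for (d in seq_len(nrow(dips))) {
        # a dip is an unfold cycle only when bracketed by the high level:
        # reached before the drop (excludes the initial reeling ramp) and
        # recovered after it (excludes the final release)
        before <- seg[seq_len(dips$start[d] - 1L)]
        after <- seg[seq(min(dips$end[d] + 1L, length(seg)), length(seg))]
        if (any(!is.na(before) & before >= cfg$high_threshold) &&
            any(!is.na(after) & after >= cfg$high_threshold))
          n_cycles <- n_cycles + 1L
      }
    }
    if (n_cycles >= 1L) {
      out <- rbind(out, .event_row("GQ_EVENT", t0, t1,
                                   n_cycles = n_cycles,
                                   reached_high = TRUE))
    } else {
      out <- rbind(out, .event_row("UNSUCCESSFUL_ATTEMPT", t0, t1,
                                   reached_high = TRUE))
    }
  }
  out
}

#' Detect GQ unfolding dips on short-spacer constructs
#'
#' With a spacer too short for reeling, the trace sits at the folded-GQ
#' level and GQ unfolding appears as dips. A dip is counted as an unfolding
#' when the smoothed FRET stays at or below \code{unfold_cutoff} for at
#' least \code{min_dwell_frames} and subsequently recovers above the folded
#' band. Dips bottoming in the nonproductive band are recorded (kind
#' \code{"UNSUCCESSFUL_ATTEMPT"}, \code{nonproductive = TRUE}) but carry no
#' dwell statistics and are excluded from event rates. The unfolding
#' transition time of each counted dip is measured on the raw trace by
#' \code{\link{measure_transition_time}}.
#'
#' @inheritParams detect_reeling_events
#' @return A data frame of events (\code{kind} \code{"UNFOLDING_DIP"} with
#'   \code{dt_uf}, or nonproductive \code{"UNSUCCESSFUL_ATTEMPT"} rows).
#' @export
detect_unfolding_dips <- function(fret, cfg) {
  stopifnot(inherits(fret, "fret_trace"), inherits(cfg, "detection_config"))
  n <- min(fret$valid_until, length(fret$efret))
  out <- .empty_events()
  if (n < 2L) return(out)
  e <- smooth_fret(fret, cfg$smoothing_window)$efret[seq_len(n)]
  dt <- fret$frame_interval
  folded_floor <- cfg$folded_mean - 2 * cfg$folded_sigma
  # candidate dips: below the nonproductive ceiling; counted dips must
  # bottom at or below the unfolding cut-off
  cand <- .runs(!is.na(e) & e <= cfg$nonproductive_high)
  cand <- cand[cand$end - cand$start + 1L >= cfg$min_dwell_frames &
                 cand$start > 1L & cand$end < n, , drop = FALSE]
  if (!nrow(cand)) return(out)
  for (i in seq_len(nrow(cand))) {
    lo <- cand$start[i]; hi <- cand$end[i]
    after <- e[seq(hi + 1L, n)]
    recovers <- any(!is.na(after) & after >= folded_floor)
    if (!recovers) next
    bottom <- min(e[lo:hi], na.rm = TRUE)
    t0 <- (lo - 1L) * dt; t1 <- hi * dt
    if (bottom <= cfg$unfold_cutoff) {
      deep <- which(!is.na(e[lo:hi]) & e[lo:hi] <= cfg$unfold_cutoff)
      if (length(deep) < cfg$min_dwell_frames) next
      row <- .event_row("UNFOLDING_DIP", t0, t1, reached_high = TRUE,
                        n_cycles = 1L)
      row$dt_uf <- measure_transition_time(fret, row, cfg)
      out <- rbind(out, row)
    } else if (bottom >= cfg$nonproductive_low) {
      out <- rbind(out, .event_row("UNSUCCESSFUL_ATTEMPT", t0, t1,
                                   nonproductive = TRUE))
    }
  }
  out
}

#' Measure the unfolding transition time of a dip
#'
#' The transition time is measured on the unsmoothed trace as the time
#' between the last frame still at the folded (top) level before the dip
#' bottom and the first frame at the unfolded (bottom) level. "At a level"
#' means within \code{level_tol} state standard deviations of the state
#' mean (default 0.25 sigma): the symmetric sub-sigma thresholds balance
#' frame quantization against noise-induced early and late level crossings,
#' making the measurement approximately unbiased for a linear collapse. The
#' resolution floor is one frame; the conventional reported uncertainty is
#' two frames (see \code{\link{timing_uncertainty}}).
#'
#' @param fret a \code{fret_trace}.
#' @param dip one event row (as returned by
#'   \code{\link{detect_unfolding_dips}}) with \code{t_start}/\code{t_end}.
#' @param cfg a \code{detection_config} (supplies the folded and unfolded
#'   levels).
#' @param max_lookback_s how far before the dip bottom the folded level may
#'   lie (default 3 s).
#' @return Transition time in seconds, or \code{NA} if no top-to-bottom
#'   bridge exists (the dip is then excluded from transition statistics).
#' @export
measure_transition_time <- function(fret, dip, cfg, max_lookback_s = 3) {
  stopifnot(inherits(fret, "fret_trace"), inherits(cfg, "detection_config"))
  dt <- fret$frame_interval
  n <- min(fret$valid_until, length(fret$efret))
  raw <- fret$efret[seq_len(n)]
  lo <- max(1L, floor(dip$t_start / dt))
  hi <- min(n, ceiling(dip$t_end / dt) + 1L)
  if (hi <= lo) return(NA_real_)
  m <- lo + which.min(raw[lo:hi]) - 1L
  top_lvl <- cfg$folded_mean - cfg$level_tol * cfg$folded_sigma
  bot_lvl <- cfg$unfolded_mean + cfg$level_tol * cfg$unfolded_sigma
  back0 <- max(1L, m - ceiling(max_lookback_s / dt))
  pre <- seq(back0, m)
  at_top <- pre[!is.na(raw[pre]) & raw[pre] >= top_lvl]
  if (!length(at_top)) return(NA_real_)
  i_top <- at_top[length(at_top)]
  span <- seq(i_top, m)
  at_bot <- span[!is.na(raw[span]) & raw[span] <= bot_lvl]
  if (!length(at_bot)) return(NA_real_)
  (at_bot[1L] - i_top) * dt
}

#' Two-data-point timing uncertainty
#'
#' Dwell-time boundaries are each uncertain by about one frame, so reported
#' times carry a conventional two-frame uncertainty: \code{2 *
#' frame_interval} raw, rounded up to the nearest 0.01 s for reporting
#' (0.032 s frames give 0.064 s, reported as 0.07 s).
#'
#' @param frame_interval frame interval in seconds, > 0.
#' @return A list with \code{raw} and \code{reported} (seconds).
#' @export
timing_uncertainty <- function(frame_interval) {
  stopifnot(is.numeric(frame_interval), frame_interval > 0)
  raw <- 2 * frame_interval
  list(raw = raw, reported = ceiling(round(raw * 100, 9)) / 100)
}

#' Match detected events to ground-truth events
#'
#' Pairs detected and truth intervals by time overlap (greedy, in time
#' order, one-to-one) and reports detection sensitivity and precision.
#'
#' @param detected data frame with \code{t_start}/\code{t_end} (detected).
#' @param truth data frame with \code{t_start}/\code{t_end} (ground truth).
#' @return A list with \code{n_matched}, \code{sensitivity} (matched /
#'   truth) and \code{precision} (matched / detected).
#' @export
match_events <- function(detected, truth) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L)
    return(list(n_matched = 0L,
                sensitivity = if (nt) 0 else NA_real_,
                precision = if (nd) 0 else NA_real_))
  used <- logical(nt)
  matched <- 0L
  for (i in seq_len(nd)) {
    ov <- pmin(detected$t_end[i], truth$t_end) -
      pmax(detected$t_start[i], truth$t_start)
    j <- which(!used & ov > 0)
    if (length(j)) {
      used[j[which.max(ov[j])]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_matched = matched, sensitivity = matched / nt,
       precision = matched / nd)
}
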