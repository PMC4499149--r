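# Shared fixtures: hand-built FRET traces and a generative noiseless-trace
# oracle for detector cross-checks. All fixtures are built in code.

DT <- 0.032

# Wrap a bare efret vector as a fret_trace.
mk_fret <- function(efret, frame_interval = DT) {
  structure(list(efret = as.numeric(efret), frame_interval = frame_interval,
                 valid_until = length(efret),
                 flagged = rep(FALSE, length(efret))),
            class = "fret_trace")
}

# Piecewise-linear efret from (level, n_frames) segments; ramps are inserted
# with ramp_frames frames between consecutive levels when ramp_frames > 0.
mk_levels <- function(levels, n_frames, ramp_frames = 0) {
  out <- c()
  for (i in seq_along(levels)) {
    if (i > 1 && ramp_frames > 0)
      out <- c(out, seq(levels[i - 1], levels[i],
                        length.out = ramp_frames + 2)[-c(1, ramp_frames + 2)])
    out <- c(out, rep(levels[i], n_frames[i]))
  }
  out
}

# Generative oracle: builds a random noiseless piecewise trace from an event
# list and returns both. The oracle's answer is the construction itself,
# classified by direct level rules (peak >= 0.60 -> completed; dips counted
# as inserted), independent of the production detector's scanning logic.
#
# mode "reeling": baseline 0.35 (pd-35T-like); events either reach the high
# plateau (counted) or stay sub-threshold (not counted).
# mode "gq": baseline 0.23 (pd-30ThGQ-like); events reach high with k >= 0
# dips (k >= 1 -> GQ_EVENT else UNSUCCESSFUL_ATTEMPT) or stay sub-threshold
# (UNSUCCESSFUL_ATTEMPT).
random_noiseless_trace <- function(mode = c("reeling", "gq")) {
  mode <- match.arg(mode)
  baseline <- if (mode == "reeling") 0.35 else 0.23
  high <- 0.78
  n_events <- sample(0:4, 1)
  ef <- rep(baseline, sample(25:60, 1))
  oracle <- data.frame(kind = character(0), t_start = numeric(0),
                       t_end = numeric(0), n_cycles = integer(0))
  for (k in seq_len(n_events)) {
    sub <- runif(1) < 0.3
    start <- length(ef) * DT
    if (sub) {
      peak <- runif(1, 0.42, 0.55)
      ramp <- sample(3:8, 1)
      ef <- c(ef, mk_levels(c(baseline, peak, baseline),
                            c(0, sample(6:15, 1), 0), ramp_frames = ramp))
      kind <- if (mode == "gq") "UNSUCCESSFUL_ATTEMPT" else NA_character_
      cycles <- 0L
    } else {
      ramp <- sample(3:12, 1)
      ef <- c(ef, mk_levels(c(baseline, high), c(0, sample(8:20, 1)),
                            ramp_frames = ramp))
      cycles <- if (mode == "gq") sample(0:3, 1) else 0L
      if (cycles > 0) for (d in seq_len(cycles))
        ef <- c(ef, rep(0.30, sample(4:10, 1)), rep(high, sample(6:14, 1)))
      ef <- c(ef, baseline)
      kind <- if (mode == "reeling") "REELING"
        else if (cycles >= 1) "GQ_EVENT" else "UNSUCCESSFUL_ATTEMPT"
    }
    if (!is.na(kind))
      oracle <- rbind(oracle, data.frame(kind = kind, t_start = start,
                                         t_end = length(ef) * DT,
                                         n_cycles = cycles))
    ef <- c(ef, rep(baseline, sample(25:60, 1)))  # > cluster gap
  }
  ef <- c(ef, rep(baseline, 10))
  list(fret = mk_fret(ef), oracle = oracle)
}

cfg_reeling <- detection_config(baseline_mean = 0.35, baseline_sigma = 0.06)
cfg_gq <- detection_config(baseline_mean = 0.23, baseline_sigma = 0.05)

# Truth event intervals observable before the bleach point.
observable_truth <- function(path, fret) {
  tvalid <- fret$valid_until * fret$frame_interval
  path$events[path$events$complete & path$events$t_end <= tvalid, ,
              drop = FALSE]
}
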