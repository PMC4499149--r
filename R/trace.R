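# Core trace containers and FRET-level operations.

#' Construct a two-channel smFRET intensity trace
#'
#' A trace holds synchronized donor and acceptor intensity series sampled at
#' a fixed frame interval. Intensities are in arbitrary camera units; negative
#' values are permitted (they arise after background subtraction).
#'
#' @param donor numeric vector of donor intensities.
#' @param acceptor numeric vector of acceptor intensities, same length.
#' @param frame_interval frame interval in seconds (default 0.032 s).
#' @param construct free-text construct label (e.g. \code{"pd-35T"}).
#' @param truth_states optional per-frame character vector of ground-truth
#'   mechanistic state labels (simulator output only).
#' @param truth_events optional data frame of ground-truth events
#'   (simulator output only).
#' @return An object of class \code{smfret_trace}.
#' @export
new_trace <- function(donor, acceptor, frame_interval = 0.032, construct = "",
                      truth_states = NULL, truth_events = NULL) {
  donor <- as.numeric(donor)
  acceptor <- as.numeric(acceptor)
  if (length(donor) != length(acceptor))
    stop("donor and acceptor series must have equal length")
  if (length(donor) < 2L)
    stop("trace must contain at least 2 frames")
  if (!all(is.finite(donor)) || !all(is.finite(acceptor)))
    stop("intensities must be finite")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("frame_interval must be a single positive number")
  if (!is.null(truth_states) && length(truth_states) != length(donor))
    stop("truth_states must align with the intensity series")
  structure(
    list(donor = donor, acceptor = acceptor,
         frame_interval = frame_interval, construct = construct,
         truth_states = truth_states, truth_events = truth_events),
    class = "smfret_trace")
}

#' @export
print.smfret_trace <- function(x, ...) {
  cat(sprintf("smFRET trace: %d frames @ %.4g s (%.1f s total)%s\n",
              length(x$donor), x$frame_interval,
              length(x$donor) * x$frame_interval,
              if (nzchar(x$construct)) paste0(", construct ", x$construct)
              else ""))
  invisible(x)
}

#' @export
length.smfret_trace <- function(x) length(x$donor)

#' Compute the apparent FRET efficiency trace
#'
#' Per frame, E = A' / (A' + gamma * D') with D' = donor - background_d and
#' A' = acceptor - background_a - leakage * D'. With the defaults
#' (gamma = 1, leakage = 0, zero backgrounds) this is the plain apparent
#' FRET ratio A / (A + D), which is what the analysis reports throughout;
#' correction parameters exist but default to the identity.
#'
#' Frames with non-positive total corrected intensity have undefined FRET and
#' are set to \code{NA} (not an error). Values outside [-0.2, 1.2] are
#' flagged.
#'
#' @param trace an \code{smfret_trace}.
#' @param leakage donor-to-acceptor leakage fraction in [0, 1).
#' @param gamma detection-efficiency ratio, > 0.
#' @param background_d,background_a per-channel backgrounds (camera units).
#' @return An object of class \code{fret_trace} with fields \code{efret}
#'   (numeric, possibly \code{NA}), \code{frame_interval},
#'   \code{valid_until} (number of usable leading frames; the full length
#'   until \code{\link{truncate_at_bleach}} shortens it) and \code{flagged}
#'   (logical, E outside [-0.2, 1.2]).
#' @export
compute_fret <- function(trace, leakage = 0, gamma = 1,
                         background_d = 0, background_a = 0) {
  stopifnot(inherits(trace, "smfret_trace"))
  if (leakage < 0 || leakage >= 1) stop("leakage must be in [0, 1)")
  if (gamma <= 0) stop("gamma must be > 0")
  d <- trace$donor - background_d
  a <- trace$acceptor - background_a - leakage * d
  tot <- a + gamma * d
  ef <- ifelse(tot > 0, a / tot, NA_real_)
  structure(
    list(efret = ef, frame_interval = trace$frame_interval,
         valid_until = length(ef),
         flagged = !is.na(ef) & (ef < -0.2 | ef > 1.2)),
    class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf(
    "FRET trace: %d frames @ %.4g s, valid through frame %d, %d flagged\n",
    length(x$efret), x$frame_interval, x$valid_until, sum(x$flagged)))
  invisible(x)
}

#' Truncate a FRET trace at the first photobleach
#'
#' Photobleaching removes the fluorescent signal irreversibly; frames past
#' the bleach carry no molecular information and must not enter event or
#' dwell statistics. The bleach point is the first frame at which the total
#' corrected intensity (donor + acceptor) stays below
#' \code{total_drop_fraction} times its initial median for at least
#' \code{min_frames} consecutive frames. \code{valid_until} is set to the
#' last usable frame (the frame before the sustained drop); traces without a
#' sustained drop keep \code{valid_until = length}.
#'
#' @param fret_trace a \code{fret_trace} from \code{\link{compute_fret}}.
#' @param trace the aligned \code{smfret_trace} the FRET was computed from.
#' @param total_drop_fraction fraction of the initial median total intensity
#'   below which the signal counts as bleached (default 0.5).
#' @param min_frames required persistence of the drop, in frames (default 5).
#' @param background_d,background_a backgrounds, as in
#'   \code{\link{compute_fret}}.
#' @param init_frames number of leading frames over which the initial median
#'   total intensity is taken (default 20, capped at the trace length).
#' @return The \code{fret_trace} with \code{valid_until} updated (never
#'   increased).
#' @export
truncate_at_bleach <- function(fret_trace, trace, total_drop_fraction = 0.5,
                               min_frames = 5, background_d = 0,
                               background_a = 0, init_frames = 20) {
  stopifnot(inherits(fret_trace, "fret_trace"),
            inherits(trace, "smfret_trace"))
  n <- length(trace$donor)
  if (length(fret_trace$efret) != n)
    stop("fret_trace and trace are not aligned")
  tot <- (trace$donor - background_d) + (trace$acceptor - background_a)
  ref <- median(tot[seq_len(min(init_frames, n))])
  below <- tot < total_drop_fraction * ref
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_frames)
  if (length(hit)) {
    fret_trace$valid_until <- min(fret_trace$valid_until, starts[hit[1L]] - 1L)
  }
  fret_trace
}

#' Histogram the initial FRET frames of a trace population
#'
#' Population FRET histograms are built from the first
#' \code{frames_per_trace} valid frames of each molecule, so every molecule
#' contributes equally and pre-event baselines dominate. Bins span
#' [-0.2, 1.2]; frames outside that range or undefined (\code{NA}) are
#' excluded and reported.
#'
#' @param fret_traces a list of \code{fret_trace} objects.
#' @param frames_per_trace frames contributed by each trace (default 10).
#' @param bin_width histogram bin width in FRET units (default 0.02).
#' @return An object of class \code{fret_histogram} with \code{bin_edges},
#'   \code{counts}, \code{n_traces}, \code{frames_per_trace} and
#'   \code{n_excluded}. \code{sum(counts) = n_traces * frames_per_trace -
#'   n_excluded}.
#' @export
histogram_fret <- function(fret_traces, frames_per_trace = 10,
                           bin_width = 0.02) {
  if (inherits(fret_traces, "fret_trace")) fret_traces <- list(fret_traces)
  stopifnot(frames_per_trace >= 1, bin_width > 0)
  edges <- seq(-0.2, 1.2 + bin_width / 2, by = bin_width)
  vals <- unlist(lapply(fret_traces, function(ft) {
    k <- min(frames_per_trace, ft$valid_until)
    head(ft$efret, k)
  }), use.names = FALSE)
  n_budget <- length(fret_traces) * frames_per_trace
  keep <- !is.na(vals) & vals >= edges[1] & vals < edges[length(edges)]
  n_excluded <- n_budget - sum(keep)
  idx <- findInterval(vals[keep], edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(
    list(bin_edges = edges, counts = counts,
         n_traces = length(fret_traces),
         frames_per_trace = frames_per_trace, n_excluded = n_excluded),
    class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  mode_bin <- which.max(x$counts)
  cat(sprintf(
    "FRET histogram: %d traces x %d frames, %d counts, mode near E = %.2f\n",
    x$n_traces, x$frames_per_trace, sum(x$counts),
    (x$bin_edges[mode_bin] + x$bin_edges[mode_bin + 1L]) / 2))
  invisible(x)
}

#' Bin centers of a FRET histogram
#' @param x a \code{fret_histogram}.
#' @return Numeric vector of bin midpoints.
#' @export
bin_centers <- function(x) {
  stopifnot(inherits(x, "fret_histogram"))
  (head(x$bin_edges, -1L) + tail(x$bin_edges, -1L)) / 2
}
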