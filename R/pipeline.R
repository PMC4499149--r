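# End-to-end titration pipeline: simulate -> detect -> rate -> fit, with
# seed-reproducible runs and on-disk artifacts.

#' Configure a titration run
#'
#' @param construct_profile preset name (see \code{\link{construct_preset}}).
#' @param concentrations titrated co-factor concentrations.
#' @param n_traces traces per concentration.
#' @param duration trace duration per molecule (s).
#' @param seed integer seed; every stage derives its randomness from it.
#' @param out_dir optional output directory; when given, every stage's
#'   outputs are written there.
#' @param kp optional \code{kinetic_params} overriding the preset kinetics
#'   (e.g. a different titrant or Table-1 row).
#' @param frame_interval frame interval (s).
#' @param write_traces write the rendered traces to the run directory
#'   (default \code{FALSE}; trace files are large).
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(construct_profile, concentrations, n_traces = 300,
                       duration = 200, seed = 1L, out_dir = NULL,
                       kp = NULL, frame_interval = 0.032,
                       write_traces = FALSE) {
  preset <- construct_preset(construct_profile)
  if (!is.null(kp)) stopifnot(inherits(kp, "kinetic_params"))
  stopifnot(length(concentrations) > 0L, all(concentrations > 0),
            n_traces >= 3L, duration > 0)
  structure(list(construct_profile = construct_profile,
                 concentrations = sort(concentrations),
                 n_traces = n_traces, duration = duration,
                 seed = as.integer(seed), out_dir = out_dir,
                 kp = if (is.null(kp)) preset$kp else kp,
                 frame_interval = frame_interval,
                 write_traces = write_traces),
            class = "run_config")
}

.detect_for_mode <- function(mode, fret, det) {
  switch(mode,
         reeling = detect_reeling_events(fret, det),
         gq = detect_gq_events(fret, det),
         dips = detect_unfolding_dips(fret, det),
         stop("construct mode '", mode, "' has no event detector"))
}

.counted_kind <- function(mode) {
  switch(mode, reeling = "REELING", gq = "GQ_EVENT",
         dips = "UNFOLDING_DIP")
}

#' Run a full simulated titration
#'
#' For each concentration: simulate state paths and render traces, compute
#' apparent FRET, truncate at photobleach, detect events with the
#' construct's detector, and form the event rate over the total valid
#' observation time (zero-event traces included) with a split-sample error.
#' Finally fit the Langmuir isotherm across concentrations. Deterministic
#' for a fixed config and seed; with \code{out_dir} set, the event table,
#' titration summary, fit report and config snapshot are written to disk.
#'
#' @param cfg a \code{run_config} (or preset name, with the remaining
#'   arguments passed to \code{\link{run_config}}).
#' @param ... passed to \code{\link{run_config}} when \code{cfg} is a name.
#' @return An object of class \code{titration_run}: \code{points} (data
#'   frame: concentration, unit, n_events, total_time_s, rate_per_s,
#'   rate_err_per_s), \code{fit} (an \code{isotherm_fit}), \code{events}
#'   (all detected events with trace and concentration ids; zero-event
#'   traces keep a row with \code{NA} kind so the table covers every
#'   analyzed trace), \code{trace_durations} (valid observation time per
#'   trace) and \code{cfg}.
#' @export
run_titration <- function(cfg, ...) {
  if (is.character(cfg)) cfg <- run_config(cfg, ...)
  stopifnot(inherits(cfg, "run_config"))
  preset <- construct_preset(cfg$construct_profile)
  kp <- cfg$kp
  mode <- preset$mode
  kind <- .counted_kind(mode)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  points <- vector("list", length(cfg$concentrations))
  all_events <- list()
  all_durations <- list()
  for (i in seq_along(cfg$concentrations)) {
    conc <- cfg$concentrations[i]
    set.seed((cfg$seed %% 1000003L) * 1000L + i)
    durations <- numeric(cfg$n_traces)
    ev_list <- vector("list", cfg$n_traces)
    traces_out <- if (isTRUE(cfg$write_traces))
      vector("list", cfg$n_traces) else NULL
    for (j in seq_len(cfg$n_traces)) {
      path <- simulate_state_path(kp, conc, cfg$duration)
      tr <- render_trace(path, preset$fsm, preset$pp,
                         frame_interval = cfg$frame_interval,
                         construct = preset$name)
      fret <- compute_fret(tr)
      fret <- truncate_at_bleach(fret, tr)
      ev <- tryCatch(.detect_for_mode(mode, fret, preset$det),
                     error = function(e)
                       stop("detection failed at concentration ", conc,
                            ", trace ", j, ": ", conditionMessage(e)))
      durations[j] <- fret$valid_until * cfg$frame_interval
      if (!nrow(ev))  # zero-event traces keep a row so the table is total
        ev <- .event_row(NA_character_, NA_real_, NA_real_)
      ev$trace_id <- j
      ev_list[[j]] <- ev
      if (!is.null(traces_out)) traces_out[[j]] <- tr
    }
    events <- do.call(rbind, ev_list)
    names(durations) <- as.character(seq_len(cfg$n_traces))
    tp <- event_rate(events, durations, kinds = kind,
                     concentration = conc, conc_unit = kp$conc_unit)
    tp$rate_error <- split_error(events, durations, k_splits = 3,
                                 seed = cfg$seed + i, kinds = kind)
    points[[i]] <- tp
    events$concentration <- conc
    all_events[[i]] <- events
    all_durations[[i]] <- data.frame(
      concentration = conc, trace_id = seq_len(cfg$n_traces),
      duration_s = unname(durations))
    if (!is.null(traces_out) && !is.null(out_dir))
      write_traces(traces_out,
                   file.path(out_dir, sprintf("traces_c%g.txt", conc)))
  }
  fit <- if (length(points) >= 3L)
    fit_langmuir(points, conc_unit = kp$conc_unit) else NULL
  summary_df <- data.frame(
    concentration = vapply(points, `[[`, numeric(1), "concentration"),
    unit = kp$conc_unit,
    n_events = vapply(points, `[[`, numeric(1), "n_events"),
    total_time_s = vapply(points, `[[`, numeric(1), "total_time"),
    rate_per_s = vapply(points, `[[`, numeric(1), "rate"),
    rate_err_per_s = vapply(points, `[[`, numeric(1), "rate_error"))
  events <- do.call(rbind, all_events)
  durations_df <- do.call(rbind, all_durations)
  run <- structure(list(points = summary_df, fit = fit, events = events,
                        trace_durations = durations_df,
                        cfg = cfg, mode = mode),
                   class = "titration_run")
  if (!is.null(out_dir)) {
    write.table(summary_df, file.path(out_dir, "titration_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(events, file.path(out_dir, "events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(durations_df, file.path(out_dir, "trace_durations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fit)) jsonlite::write_json(
      list(A = fit$A, A_err = fit$A_err, Keq = fit$Keq,
           Keq_err = fit$Keq_err, rss = fit$rss, n_points = fit$n_points,
           identifiable = fit$identifiable, conc_unit = fit$conc_unit),
      file.path(out_dir, "isotherm_fit.json"),
      auto_unbox = TRUE, digits = NA)
    snap <- cfg
    snap$out_dir <- NULL
    jsonlite::write_json(
      list(construct_profile = snap$construct_profile,
           concentrations = snap$concentrations,
           n_traces = snap$n_traces, duration = snap$duration,
           seed = snap$seed, frame_interval = snap$frame_interval,
           kinetics = unclass(snap$kp)),
      file.path(out_dir, "run_config.json"),
      auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.titration_run <- function(x, ...) {
  cat(sprintf("titration run: %s, %d concentrations x %d traces x %.0f s\n",
              x$cfg$construct_profile, nrow(x$points), x$cfg$n_traces,
              x$cfg$duration))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Summarize a completed run directory
#'
#' Reads the artifacts written by \code{\link{run_titration}} and prints a
#' one-row isotherm summary (titrant unit, K_eq +/- error, A +/- error) plus
#' the titration table. Regeneration is idempotent: the report is computed
#' from the on-disk artifacts alone.
#'
#' @param run_dir a run directory produced by \code{\link{run_titration}}.
#' @return A list with \code{summary} (one-row data frame) and
#'   \code{points}, invisibly; the report is printed.
#' @export
make_report <- function(run_dir) {
  need <- c("run_config.json", "titration_summary.tsv", "isotherm_fit.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("run directory ", run_dir, " is missing: ",
         paste(missing, collapse = ", "))
  cfgj <- jsonlite::read_json(file.path(run_dir, "run_config.json"),
                              simplifyVector = TRUE)
  fitj <- jsonlite::read_json(file.path(run_dir, "isotherm_fit.json"),
                              simplifyVector = TRUE)
  pts <- read.table(file.path(run_dir, "titration_summary.tsv"),
                    header = TRUE, sep = "\t")
  summary <- data.frame(
    construct = cfgj$construct_profile,
    titrant = cfgj$kinetics$titrant,
    Keq = fitj$Keq, Keq_err = fitj$Keq_err,
    A = fitj$A, A_err = fitj$A_err, unit = fitj$conc_unit)
  cat(sprintf("%s [%s]: Keq = %.4g +/- %.2g %s, A = %.4g +/- %.2g /s\n",
              summary$construct, summary$titrant, summary$Keq,
              summary$Keq_err, summary$unit, summary$A, summary$A_err))
  print(pts)
  invisible(list(summary = summary, points = pts))
}
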