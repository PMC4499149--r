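# Plain-text trace format, one file per movie/condition.
#
# Header lines:
#   # format_version=1
#   # frame_interval_s=0.032
#   # construct=<label>
# then one block per molecule:
#   # trace <id>
#   frame donor acceptor [state]
# Columns are whitespace-separated; the state column is optional and only
# written for simulated traces carrying ground-truth labels.

.FORMAT_VERSION <- 1L

#' Write traces to the native tabular text format
#'
#' Output is deterministic for fixed input: field order, numeric formatting
#' and line structure are fixed by the format version.
#'
#' @param traces a list of \code{smfret_trace} objects (or a single trace).
#' @param path output file path.
#' @param digits significant digits for intensities (default 17: doubles
#'   round-trip bit-exactly).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_traces}}
#' @export
write_traces <- function(traces, path, digits = 17) {
  if (inherits(traces, "smfret_trace")) traces <- list(traces)
  stopifnot(length(traces) > 0L,
            all(vapply(traces, inherits, logical(1), "smfret_trace")))
  fi <- unique(vapply(traces, `[[`, numeric(1), "frame_interval"))
  if (length(fi) != 1L)
    stop("all traces in one file must share a frame interval")
  construct <- traces[[1L]]$construct
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# format_version=%d", .FORMAT_VERSION),
               sprintf("# frame_interval_s=%.10g", fi),
               sprintf("# construct=%s", construct)), con)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    writeLines(sprintf("# trace %d", i), con)
    if (!is.null(tr$truth_states)) {
      writeLines(sprintf("%d %s %s %s", seq_along(tr$donor),
                         formatC(tr$donor, digits = digits, format = "g"),
                         formatC(tr$acceptor, digits = digits, format = "g"),
                         tr$truth_states), con)
    } else {
      writeLines(sprintf("%d %s %s", seq_along(tr$donor),
                         formatC(tr$donor, digits = digits, format = "g"),
                         formatC(tr$acceptor, digits = digits, format = "g")),
                 con)
    }
  }
  invisible(path)
}

#' Read traces from the native tabular text format
#'
#' @param path input file path.
#' @return A list of \code{smfret_trace} objects (possibly empty, with a
#'   warning, for a file holding no trace blocks).
#' @seealso \code{\link{write_traces}}
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    warning("empty trace file: ", path)
    return(list())
  }
  if (!grepl("^# format_version=", lines[1L]))
    stop("line 1: missing '# format_version=' header")
  ver <- as.integer(sub("^# format_version=", "", lines[1L]))
  if (is.na(ver) || ver != .FORMAT_VERSION)
    stop("line 1: unsupported format version")
  fi_line <- grep("^# frame_interval_s=", lines)
  if (!length(fi_line)) stop("missing '# frame_interval_s=' header")
  fi <- as.numeric(sub("^# frame_interval_s=", "", lines[fi_line[1L]]))
  if (!is.finite(fi) || fi <= 0)
    stop(sprintf("line %d: bad frame interval", fi_line[1L]))
  c_line <- grep("^# construct=", lines)
  construct <- if (length(c_line))
    sub("^# construct=", "", lines[c_line[1L]]) else ""

  starts <- grep("^# trace ", lines)
  if (!length(starts)) {
    warning("no trace blocks in ", path)
    return(list())
  }
  block_ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    rows <- lines[(starts[b] + 1L):block_ends[b]]
    rows <- rows[!grepl("^#", rows) & nzchar(trimws(rows))]
    if (!length(rows))
      stop(sprintf("line %d: empty trace block", starts[b]))
    fields <- strsplit(trimws(rows), "[[:space:]]+")
    ncol <- lengths(fields)
    if (length(unique(ncol)) != 1L || !(ncol[1L] %in% c(3L, 4L)))
      stop(sprintf("line %d: ragged or malformed columns in trace block",
                   starts[b] + which(ncol != ncol[1L])[1L]))
    m <- do.call(rbind, fields)
    donor <- as.numeric(m[, 2L])
    acceptor <- as.numeric(m[, 3L])
    if (anyNA(donor) || anyNA(acceptor))
      stop(sprintf("line %d: non-numeric intensity in trace block",
                   starts[b] + which(is.na(donor) | is.na(acceptor))[1L]))
    states <- if (ncol[1L] == 4L) m[, 4L] else NULL
    out[[b]] <- new_trace(donor, acceptor, frame_interval = fi,
                          construct = construct, truth_states = states)
  }
  out
}
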