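# Event-rate statistics, split-sample errors, Langmuir isotherm fitting and
# Gaussian peak fitting.

#' Event rate of a titration point
#'
#' The event rate is the total number of counted events divided by the total
#' observation time, where the total time includes every analyzed trace --
#' traces showing no events contribute observation time but no counts.
#' Dropping zero-event traces from the denominator would inflate the rate;
#' the function therefore takes the per-trace durations, not the event
#' table, as the source of total time.
#'
#' @param event_table data frame of detected events with a \code{trace_id}
#'   column (zero-event traces may appear as rows with \code{NA} kind).
#' @param trace_durations named (by trace id) or plain numeric vector of
#'   analyzed durations in seconds for every trace, including zero-event
#'   traces.
#' @param kinds which \code{kind} values count as events (default: all
#'   non-\code{NA}, non-nonproductive rows).
#' @param concentration,conc_unit optional annotation of the titration
#'   point.
#' @return An object of class \code{titration_point} with \code{n_events},
#'   \code{total_time}, \code{rate} and (if \code{\link{split_error}} is run)
#'   \code{rate_error}.
#' @export
event_rate <- function(event_table, trace_durations, kinds = NULL,
                       concentration = NA_real_, conc_unit = "") {
  total_time <- sum(trace_durations)
  if (!is.finite(total_time) || total_time <= 0)
    stop("total observation time must be positive")
  counted <- .counted_events(event_table, kinds)
  n <- nrow(counted)
  structure(list(concentration = concentration, conc_unit = conc_unit,
                 n_events = n, total_time = total_time,
                 rate = n / total_time, rate_error = NA_real_),
            class = "titration_point")
}

.counted_events <- function(event_table, kinds) {
  if (is.null(event_table) || !nrow(event_table))
    return(event_table[0, , drop = FALSE])
  keep <- !is.na(event_table$kind)
  if ("nonproductive" %in% names(event_table))
    keep <- keep & !event_table$nonproductive %in% TRUE
  if (!is.null(kinds)) keep <- keep & event_table$kind %in% kinds
  event_table[keep, , drop = FALSE]
}

#' @export
print.titration_point <- function(x, ...) {
  cat(sprintf("titration point: %s %s -> %d events / %.1f s = %.4g /s\n",
              format(x$concentration), x$conc_unit, x$n_events,
              x$total_time, x$rate))
  invisible(x)
}

#' Split-sample error of an event rate
#'
#' The rate uncertainty is estimated by dividing the complete set of traces
#' into \code{k_splits} near-equal random groups, computing the event rate
#' of each group, and taking the standard deviation of the group rates.
#'
#' @inheritParams event_rate
#' @param k_splits number of groups (default 3).
#' @param seed integer seed for the random partition.
#' @return The standard deviation of the group rates (events/s).
#' @export
split_error <- function(event_table, trace_durations, k_splits = 3,
                        seed = 1L, kinds = NULL) {
  n_traces <- length(trace_durations)
  if (n_traces < k_splits)
    stop("need at least as many traces as splits")
  ids <- names(trace_durations)
  if (is.null(ids)) ids <- as.character(seq_len(n_traces))
  counted <- .counted_events(event_table, kinds)
  counts <- table(factor(as.character(counted$trace_id), levels = ids))
  set.seed(seed)
  grp <- sample(rep_len(seq_len(k_splits), n_traces))
  rates <- vapply(seq_len(k_splits), function(g) {
    sum(counts[grp == g]) / sum(trace_durations[grp == g])
  }, numeric(1))
  sd(rates)
}

#' Langmuir binding isotherm
#'
#' \eqn{y = A c / (c + K_{eq})}: zero at zero concentration, half the
#' saturation amplitude A at \eqn{c = K_{eq}}, monotone nondecreasing and
#' bounded by A.
#'
#' @param c concentration(s), >= 0.
#' @param A saturation amplitude (events/s).
#' @param Keq half-saturation constant (concentration units of \code{c}).
#' @return Event rate(s).
#' @export
langmuir <- function(c, A, Keq) {
  stopifnot(all(c >= 0))
  .langmuir_rate(A, Keq, c)
}

#' Fit a Langmuir binding isotherm to titration points
#'
#' Nonlinear least squares of rate against concentration. Positivity of
#' both parameters is enforced by fitting in log-parameter space;
#' initialization takes A at the maximum observed rate and K_eq at the
#' concentration whose rate lies nearest A/2. Parameter standard errors come
#' from the local curvature of the least-squares objective (Gauss-Newton
#' covariance), mapped back through the delta method. The fit is flagged
#' unidentifiable when the K_eq error exceeds K_eq itself (e.g. all rates
#' equal).
#'
#' @param points a data frame with columns \code{concentration} and
#'   \code{rate} (optionally \code{rate_error}), or a list of
#'   \code{titration_point} objects.
#' @param weighted if \code{TRUE} and rate errors are available, weight by
#'   1/error^2 (default \code{FALSE}: the unweighted fit).
#' @param conc_unit unit tag carried into the result.
#' @return An object of class \code{isotherm_fit} with \code{A},
#'   \code{Keq}, \code{A_err}, \code{Keq_err}, \code{rss}, \code{n_points},
#'   \code{identifiable} and \code{conc_unit}.
#' @export
fit_langmuir <- function(points, weighted = FALSE, conc_unit = "") {
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, inherits, logical(1), "titration_point"))) {
    if (conc_unit == "" && length(points))
      conc_unit <- points[[1L]]$conc_unit
    points <- data.frame(
      concentration = vapply(points, `[[`, numeric(1), "concentration"),
      rate = vapply(points, `[[`, numeric(1), "rate"),
      rate_error = vapply(points, `[[`, numeric(1), "rate_error"))
  }
  stopifnot(is.data.frame(points),
            all(c("concentration", "rate") %in% names(points)))
  cc <- points$concentration
  y <- points$rate
  if (length(cc) < 3L)
    stop("need at least 3 titration points")
  if (max(y) <= 0) stop("all rates are zero; nothing to fit")
  w <- rep(1, length(y))
  if (weighted && "rate_error" %in% names(points) &&
      all(is.finite(points$rate_error)) && all(points$rate_error > 0))
    w <- 1 / points$rate_error^2
  A0 <- max(y)
  K0 <- cc[which.min(abs(y - A0 / 2))]
  if (K0 <= 0) K0 <- median(cc)
  half_lo <- min(y) < 0.45 * A0
  if (!half_lo)
    warning("titration points do not bracket the half-saturation region; ",
            "K_eq is poorly constrained")
  dat <- data.frame(cc = cc, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(la) * cc / (cc + exp(lk)), data = dat,
                      start = list(la = log(A0), lk = log(K0)),
                      weights = w,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    obj <- function(p) sum(w * (y - exp(p[1]) * cc / (cc + exp(p[2])))^2)
    op <- optim(c(log(A0), log(K0)), obj, hessian = TRUE,
                control = list(reltol = 1e-14, maxit = 2000))
    if (!is.finite(op$value))
      stop("Langmuir fit failed to converge (init A=", signif(A0, 4),
           ", Keq=", signif(K0, 4), ")")
    p <- op$par
    rss <- op$value
    dof <- max(1L, length(y) - 2L)
    cv <- tryCatch(solve(op$hessian / 2) * rss / dof,
                   error = function(e) matrix(NA_real_, 2, 2))
    se <- sqrt(pmax(diag(cv), 0))
  } else {
    p <- coef(fit)
    rss <- sum(w * resid(fit)^2)
    se <- tryCatch(sqrt(diag(vcov(fit))),
                   error = function(e) c(NA_real_, NA_real_))
  }
  A <- exp(p[[1]]); Keq <- exp(p[[2]])
  A_err <- A * se[1]; Keq_err <- Keq * se[2]
  # K_eq is unidentifiable when its error exceeds it or when it escapes the
  # concentration range of the design (e.g. all rates equal)
  identifiable <- is.finite(Keq_err) && Keq_err <= Keq &&
    Keq >= min(cc) / 10 && Keq <= max(cc) * 10
  structure(list(A = A, Keq = Keq, A_err = A_err, Keq_err = Keq_err,
                 rss = rss, n_points = length(y),
                 identifiable = identifiable, conc_unit = conc_unit),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf(
    "Langmuir fit: A = %.4g +/- %.2g /s, Keq = %.4g +/- %.2g %s (n=%d%s)\n",
    x$A, x$A_err, x$Keq, x$Keq_err, x$conc_unit, x$n_points,
    if (!x$identifiable) ", UNIDENTIFIABLE" else ""))
  invisible(x)
}

#' Fit Gaussian peaks to a histogram
#'
#' Least-squares Gaussian(s) on binned data, as used for FRET histograms
#' and for dwell-time histograms of 300-400 measurements. For two
#' components the initialization takes the two highest well-separated local
#' maxima and falls back to sample terciles when the maxima are closer than
#' one bin. Component weights are the normalized fitted areas.
#'
#' @param x numeric samples, or a \code{fret_histogram}.
#' @param n_components 1 or 2.
#' @param bin_width bin width when \code{x} is a sample vector (default
#'   0.02).
#' @return An object of class \code{gaussian_peaks}: a \code{components}
#'   data frame (\code{mean}, \code{sigma}, \code{weight}, ordered by mean)
#'   plus \code{n_samples}.
#' @export
fit_gaussians <- function(x, n_components = 1, bin_width = 0.02) {
  stopifnot(n_components %in% c(1L, 2L))
  if (inherits(x, "fret_histogram")) {
    cen <- bin_centers(x)
    cnt <- x$counts
    n_samples <- sum(cnt)
    bw <- diff(x$bin_edges[1:2])
    samples <- rep(cen, cnt)
  } else {
    samples <- x[is.finite(x)]
    n_samples <- length(samples)
    if (n_samples < 2L) stop("need at least 2 samples")
    bw <- bin_width
    # center the first bin on the sample minimum so that lattice-valued
    # samples (e.g. dwell times in whole frames) sit on bin centers
    edges <- seq(min(samples) - bw / 2, max(samples) + bw, by = bw)
    h <- hist(samples, breaks = c(edges, max(edges) + bw), plot = FALSE)
    cen <- h$mids
    cnt <- h$counts
  }
  if (n_samples < 50 * n_components)
    warning("fewer than 50 samples per expected component; ",
            "peak estimates may be unstable")
  nz <- cnt > 0
  if (sum(nz) <= 2L * n_components) {
    # delta-like histogram: report occupied-bin statistics directly
    mu <- sum(cen * cnt) / sum(cnt)
    sg <- sqrt(max(sum(cnt * (cen - mu)^2) / sum(cnt), (bw / 4)^2))
    comps <- data.frame(mean = mu, sigma = sg, weight = 1)
    return(structure(list(components = comps, n_samples = n_samples),
                     class = "gaussian_peaks"))
  }
  dat <- data.frame(cen = cen, cnt = cnt)
  if (n_components == 1L) {
    m0 <- cen[which.max(cnt)]
    s0 <- max(sqrt(sum(cnt * (cen - m0)^2) / sum(cnt)) / 1.5, bw / 2)
    a0 <- max(cnt)
    fit <- tryCatch(
      minpack.lm::nlsLM(cnt ~ a * exp(-(cen - m)^2 / (2 * s^2)), data = dat,
                        start = list(a = a0, m = m0, s = s0),
                        lower = c(0, min(cen), bw / 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      comps <- data.frame(mean = m0, sigma = s0, weight = 1)
    } else {
      cf <- coef(fit)
      comps <- data.frame(mean = cf[["m"]], sigma = abs(cf[["s"]]),
                          weight = 1)
    }
  } else {
    sm <- if (length(cnt) >= 3) as.numeric(runmed(cnt, 3)) else cnt
    locmax <- which(sm >= c(-Inf, head(sm, -1)) &
                      sm >= c(tail(sm, -1), Inf) & sm > 0)
    locmax <- locmax[order(sm[locmax], decreasing = TRUE)]
    init <- NULL
    for (i in seq_along(locmax)) {
      for (j in seq_along(locmax)) {
        if (j <= i) next
        if (abs(cen[locmax[i]] - cen[locmax[j]]) > bw) {
          init <- sort(c(cen[locmax[i]], cen[locmax[j]]))
          break
        }
      }
      if (!is.null(init)) break
    }
    if (is.null(init))
      init <- as.numeric(quantile(samples, c(1 / 3, 2 / 3)))
    s0 <- max(sd(samples) / 2, bw)
    a0 <- max(cnt)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        cnt ~ a1 * exp(-(cen - m1)^2 / (2 * s1^2)) +
          a2 * exp(-(cen - m2)^2 / (2 * s2^2)),
        data = dat,
        start = list(a1 = a0, m1 = init[1], s1 = s0,
                     a2 = a0, m2 = init[2], s2 = s0),
        lower = c(0, min(cen), bw / 10, 0, min(cen), bw / 10),
        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) {
      comps <- data.frame(mean = init, sigma = c(s0, s0),
                          weight = c(0.5, 0.5))
    } else {
      cf <- coef(fit)
      area <- c(cf[["a1"]] * abs(cf[["s1"]]), cf[["a2"]] * abs(cf[["s2"]]))
      comps <- data.frame(mean = c(cf[["m1"]], cf[["m2"]]),
                          sigma = abs(c(cf[["s1"]], cf[["s2"]])),
                          weight = area / sum(area))
      comps <- comps[order(comps$mean), ]
      rownames(comps) <- NULL
    }
  }
  structure(list(components = comps, n_samples = n_samples),
            class = "gaussian_peaks")
}

#' @export
print.gaussian_peaks <- function(x, ...) {
  cat(sprintf("Gaussian peaks (n=%d):\n", x$n_samples))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  mean %.3f, sigma %.3f, weight %.2f\n",
                x$components$mean[i], x$components$sigma[i],
                x$components$weight[i]))
  invisible(x)
}

#' Fraction of reeling events that unfold the GQ
#'
#' Ratio of fitted saturation amplitudes of a GQ-bearing construct and its
#' GQ-free reference under the same titration design: the amplitude of the
#' GQ construct counts only events that unfold the GQ, so the ratio is the
#' per-attempt unfolding success fraction.
#'
#' @param fit_gq \code{isotherm_fit} (or bare amplitude) of the GQ
#'   construct.
#' @param fit_ref \code{isotherm_fit} (or bare amplitude) of the reference
#'   construct.
#' @return The success fraction A_gq / A_ref.
#' @export
unfold_success_fraction <- function(fit_gq, fit_ref) {
  a_gq <- if (inherits(fit_gq, "isotherm_fit")) fit_gq$A else fit_gq
  a_ref <- if (inherits(fit_ref, "isotherm_fit")) fit_ref$A else fit_ref
  stopifnot(is.numeric(a_gq), is.numeric(a_ref))
  if (a_ref == 0) stop("reference amplitude is zero")
  a_gq / a_ref
}
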