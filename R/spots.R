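# TIRF spot-count assay: synthetic movies of surface-bound fluorophores and
# the fraction-of-remaining-spots readout for duplex unwinding.

#' Simulate a TIRF movie of disappearing spots
#'
#' Immobilized fluorophores render as static Gaussian point-spread
#' functions; each spot disappears at an exponential time with total rate
#' \code{unwind_rate + bleach_rate} (unwinding releases the dye, bleaching
#' silences it; the two are indistinguishable in one channel, which is why
#' the assay needs a no-ATP photobleaching control). Spots are placed no
#' closer than 4 PSF sigmas apart.
#'
#' @param n_spots number of spots, >= 1.
#' @param field_size image side length in pixels.
#' @param n_frames number of frames.
#' @param unwind_rate,bleach_rate disappearance rates (1/s).
#' @param frame_interval frame interval (s).
#' @param psf_sigma PSF standard deviation (pixels).
#' @param spot_intensity peak spot amplitude (camera units).
#' @param bg_mean,bg_sd background offset and noise sd (camera units).
#' @return An object of class \code{image_stack}: \code{frames} (array
#'   field_size x field_size x n_frames), \code{frame_interval}, and
#'   \code{truth} (data frame of spot x, y, lifetime in seconds).
#' @export
simulate_movie <- function(n_spots, field_size = 96, n_frames = 20,
                           unwind_rate = 0, bleach_rate = 0,
                           frame_interval = 5, psf_sigma = 1.3,
                           spot_intensity = 800, bg_mean = 100,
                           bg_sd = 15) {
  stopifnot(n_spots >= 1, field_size >= 16, n_frames >= 1,
            unwind_rate >= 0, bleach_rate >= 0, frame_interval > 0)
  margin <- ceiling(4 * psf_sigma)
  min_sep <- 4 * psf_sigma
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n_spots) {
    tries <- tries + 1L
    if (tries > 200L * n_spots)
      stop("could not place ", n_spots,
           " spots without overlap; enlarge field_size")
    x <- runif(1, margin + 1, field_size - margin)
    y <- runif(1, margin + 1, field_size - margin)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_sep^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  total_rate <- unwind_rate + bleach_rate
  lifetimes <- if (total_rate > 0) rexp(n_spots, total_rate)
    else rep(Inf, n_spots)
  r <- ceiling(4 * psf_sigma)
  frames <- array(0, dim = c(field_size, field_size, n_frames))
  t_frames <- (seq_len(n_frames) - 1L) * frame_interval
  for (f in seq_len(n_frames)) {
    img <- matrix(rnorm(field_size^2, bg_mean, bg_sd),
                  field_size, field_size)
    alive <- lifetimes > t_frames[f]
    for (s in which(alive)) {
      ix <- max(1L, round(xs[s]) - r):min(field_size, round(xs[s]) + r)
      iy <- max(1L, round(ys[s]) - r):min(field_size, round(ys[s]) + r)
      gx <- exp(-(ix - xs[s])^2 / (2 * psf_sigma^2))
      gy <- exp(-(iy - ys[s])^2 / (2 * psf_sigma^2))
      img[ix, iy] <- img[ix, iy] + spot_intensity * outer(gx, gy)
    }
    frames[, , f] <- img
  }
  structure(list(frames = frames, frame_interval = frame_interval,
                 truth = data.frame(x = xs, y = ys, lifetime = lifetimes)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image stack: %dx%d px, %d frames @ %.3g s, %d true spots\n",
              d[1], d[2], d[3], x$frame_interval, nrow(x$truth)))
  invisible(x)
}

#' Count diffraction-limited spots in one frame
#'
#' Spots are local maxima of a band-pass (difference-of-Gaussians) filtered
#' frame exceeding \code{snr_threshold} robust background standard
#' deviations, deduplicated within 2 detection sigmas (strongest detection
#' kept). Zero spots is a valid result.
#'
#' @param frame numeric matrix (one image).
#' @param detection_sigma expected spot sigma in pixels (default 1.3).
#' @param snr_threshold detection threshold in units of the robust (MAD)
#'   background sd of the filtered image (default 5).
#' @return A list with \code{count} and a \code{coords} data frame
#'   (\code{x}, \code{y}, \code{intensity}).
#' @export
count_spots <- function(frame, detection_sigma = 1.3, snr_threshold = 5) {
  stopifnot(is.matrix(frame), all(dim(frame) >= 8))
  bp <- EBImage::gblur(frame, sigma = detection_sigma) -
    EBImage::gblur(frame, sigma = 3 * detection_sigma)
  bg_sd <- mad(bp)
  thr <- snr_threshold * bg_sd
  nr <- nrow(bp); nc <- ncol(bp)
  # 8-neighborhood maximum via shifted copies (edges padded with -Inf)
  shift <- function(m, di, dj) {
    out <- matrix(-Inf, nr, nc)
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    out[ri, rj] <- m[ri - di, rj - dj]
    out
  }
  nbr_max <- matrix(-Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbr_max <- pmax(nbr_max, shift(bp, di, dj))
  }
  is_peak <- bp > nbr_max & bp > thr
  idx <- which(is_peak, arr.ind = TRUE)
  if (!nrow(idx))
    return(list(count = 0L,
                coords = data.frame(x = numeric(0), y = numeric(0),
                                    intensity = numeric(0))))
  val <- bp[idx]
  o <- order(val, decreasing = TRUE)
  idx <- idx[o, , drop = FALSE]; val <- val[o]
  keep <- rep(TRUE, nrow(idx))
  min_d2 <- (2 * detection_sigma)^2
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      j <- (i + 1L):nrow(idx)
      d2 <- (idx[j, 1] - idx[i, 1])^2 + (idx[j, 2] - idx[i, 2])^2
      keep[j][d2 < min_d2] <- FALSE
    }
  }
  coords <- data.frame(x = idx[keep, 1], y = idx[keep, 2],
                       intensity = val[keep])
  list(count = nrow(coords), coords = coords)
}

#' Fraction of remaining spots over a movie
#'
#' The spots detected in the first frame define the reference set; a
#' reference spot "remains" at a later time if a detection lies within
#' \code{match_radius} pixels of its position (spots are immobilized, so no
#' tracking is needed). The series is normalized to the first frame.
#'
#' @param stack an \code{image_stack} (>= 2 frames).
#' @param detection_sigma,snr_threshold passed to \code{\link{count_spots}}.
#' @param match_radius persistence match radius in pixels (default 2).
#' @return An object of class \code{spot_count_series}: data frame with
#'   \code{time}, \code{count}, \code{fraction_remaining}.
#' @export
fraction_remaining <- function(stack, detection_sigma = 1.3,
                               snr_threshold = 5, match_radius = 2) {
  stopifnot(inherits(stack, "image_stack"), dim(stack$frames)[3] >= 2)
  n_frames <- dim(stack$frames)[3]
  ref <- count_spots(stack$frames[, , 1], detection_sigma, snr_threshold)
  if (ref$count == 0L) stop("no spots detected in the first frame")
  counts <- integer(n_frames)
  counts[1] <- ref$count
  for (f in 2:n_frames) {
    det <- count_spots(stack$frames[, , f], detection_sigma, snr_threshold)
    if (det$count == 0L) { counts[f] <- 0L; next }
    remains <- vapply(seq_len(ref$count), function(s) {
      any((det$coords$x - ref$coords$x[s])^2 +
            (det$coords$y - ref$coords$y[s])^2 <= match_radius^2)
    }, logical(1))
    counts[f] <- sum(remains)
  }
  out <- data.frame(time = (seq_len(n_frames) - 1L) * stack$frame_interval,
                    count = counts,
                    fraction_remaining = counts / counts[1])
  class(out) <- c("spot_count_series", class(out))
  out
}

#' Exponential-decay summary of a spot-count series
#'
#' Convenience single-exponential fit with a floor,
#' f(t) = floor + (1 - floor) exp(-k t), of the fraction-remaining series.
#' With no rebinding and homogeneous spots the decay rate estimates
#' unwind_rate + bleach_rate; subtracting the rate of a no-ATP control
#' isolates the unwinding rate.
#'
#' @param series a \code{spot_count_series}.
#' @param floor fix the floor at this value (e.g. 0 for a pure exponential);
#'   \code{NULL} (default) fits it.
#' @return A list with \code{rate} (1/s) and \code{floor}.
#' @export
fit_spot_decay <- function(series, floor = NULL) {
  stopifnot(inherits(series, "spot_count_series"))
  dat <- data.frame(t = series$time, f = series$fraction_remaining)
  k0 <- if (any(dat$f < 0.7)) {
    t_half <- dat$t[which(dat$f < 0.7)[1]]
    log(2) / max(t_half, diff(range(dat$t)) / 100)
  } else 0.1 / max(dat$t[length(dat$t)], 1)
  fit <- if (is.null(floor)) tryCatch(
    minpack.lm::nlsLM(f ~ fl + (1 - fl) * exp(-k * t), data = dat,
                      start = list(fl = 0, k = k0),
                      lower = c(0, 0), upper = c(0.99, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  else tryCatch(
    minpack.lm::nlsLM(f ~ floor + (1 - floor) * exp(-k * t), data = dat,
                      start = list(k = k0), lower = 0,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(rate = NA_real_, floor = NA_real_))
  cf <- coef(fit)
  list(rate = cf[["k"]],
       floor = if (is.null(floor)) cf[["fl"]] else floor)
}
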