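#' Framewise displacement from rigid-motion parameters
#'
#' Power-style scalar motion summary: the sum of absolute frame-to-frame
#' differentials of the three translations (mm) plus the three rotations
#' (radians) converted to arc length at a given head radius. The first
#' frame has FD 0 by convention.
#'
#' @param motion `T x 6` matrix: columns 1-3 translations in mm, 4-6
#'   rotations in radians.
#' @param radius Rotation-to-translation conversion radius in mm
#'   (default 5, appropriate for the rat head).
#'
#' @return Numeric vector of length `T`.
#' @export
#' @examples
#' m <- matrix(0, 10, 6); m[6:10, 1] <- 0.03; m[6:10, 2] <- 0.04
#' framewise_displacement(m)[6]  # 0.07
framewise_displacement <- function(motion, radius = 5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stopf("motion must have 6 columns, got %d", ncol(motion))
  if (nrow(motion) < 2) stopf("need at least 2 frames")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Scrub motion-contaminated frames by spline interpolation
#'
#' Frames whose framewise displacement exceeds `threshold` are replaced,
#' per region, by a natural cubic spline fitted through the unflagged
#' frames. Flagged frames at the series boundary (before the first or
#' after the last clean frame) are replaced by the nearest clean value,
#' since splines extrapolate poorly.
#'
#' @param ts `regions x T` matrix of time courses.
#' @param fd Framewise displacement vector of length `T`.
#' @param threshold Scrub threshold in mm (default 0.05).
#' @param max_flag_fraction Fraction of flagged frames above which the
#'   result carries an `excess_motion` warning flag (default 0.10).
#'
#' @return List: `ts` (interpolated matrix), `flagged` (logical vector),
#'   `flag_fraction`, `excess_motion` (logical).
#' @export
scrub_interpolate <- function(ts, fd, threshold = 0.05,
                              max_flag_fraction = 0.10) {
  ts <- as.matrix(ts)
  if (length(fd) != ncol(ts)) stopf("fd length must match frame count")
  if (threshold <= 0) stopf("threshold must be positive")
  flagged <- fd > threshold
  frac <- mean(flagged)
  if (all(flagged)) stopf("all frames flagged; nothing to interpolate from")
  excess <- frac > max_flag_fraction
  if (excess) {
    warnf("%.1f%% of frames flagged, above the %.0f%% tolerance",
          100 * frac, 100 * max_flag_fraction)
  }
  out <- ts
  if (any(flagged)) {
    good <- which(!flagged)
    bad <- which(flagged)
    interior <- bad[bad > min(good) & bad < max(good)]
    before <- bad[bad < min(good)]
    after <- bad[bad > max(good)]
    for (i in seq_len(nrow(ts))) {
      if (length(interior)) {
        out[i, interior] <- spline(good, ts[i, good], xout = interior,
                                   method = "natural")$y
      }
      if (length(before)) out[i, before] <- ts[i, min(good)]
      if (length(after)) out[i, after] <- ts[i, max(good)]
    }
  }
  list(ts = out, flagged = flagged, flag_fraction = frac,
       excess_motion = excess)
}

#' Regress confound time series out of region signals
#'
#' Least-squares projection of each region's time course onto an intercept
#' plus the supplied nuisance regressors (motion parameters, CSF signal,
#' ...), returning the residuals. With no regressors this demeans each
#' region.
#'
#' @param ts `regions x T` matrix.
#' @param regressors `T x k` matrix (or `NULL` for intercept only).
#'
#' @return Residual matrix of the same shape as `ts`.
#' @export
regress_confounds <- function(ts, regressors = NULL) {
  ts <- as.matrix(ts)
  tt <- ncol(ts)
  x <- cbind(intercept = rep(1, tt))
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != tt) stopf("regressors must have T rows")
    if (is.null(colnames(regressors))) {
      colnames(regressors) <- paste0("reg", seq_len(ncol(regressors)))
    }
    x <- cbind(x, regressors)
  }
  if (tt <= ncol(x)) stopf("need T > k + 1 frames")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stopf("rank-deficient confound design; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  t(qr.resid(qx, t(ts)))
}

#' Band-pass filter region time courses
#'
#' Zero-phase (forward-backward) second-order Butterworth band-pass,
#' applied per region after demeaning. The default 0.01-0.1 Hz band keeps
#' the resting-state fluctuation range and removes drift and residual
#' physiological frequencies.
#'
#' @param ts `regions x T` matrix (a vector is treated as one region).
#' @param band Length-2 passband in Hz.
#' @param tr Repetition time in seconds (sampling interval).
#'
#' @return Filtered matrix of the same shape.
#' @export
bandpass <- function(ts, band = c(0.01, 0.1), tr = 1.5) {
  one <- is.null(dim(ts))
  ts <- rbind(as.matrix(if (one) t(ts) else ts))
  nyq <- 1 / (2 * tr)
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq) {
    stopf("band must satisfy 0 < low < high < Nyquist (%.4f Hz)", nyq)
  }
  if (ncol(ts) < 24) stopf("series too short to filter (T >= 24 required)")
  bf <- signal::butter(2, band / nyq, type = "pass")
  tt <- ncol(ts)
  # odd (antisymmetric) reflection padding suppresses filtfilt edge
  # transients; pad covers at least one slowest-passband period
  pad <- min(tt - 1, max(64, ceiling(1 / (band[1] * tr))))
  out <- t(apply(ts, 1, function(x) {
    x <- x - mean(x)
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[tt] - x[(tt - 1):(tt - pad)])
    signal::filtfilt(bf, xp)[(pad + 1):(pad + tt)]
  }))
  dimnames(out) <- dimnames(ts)
  if (one) drop(out) else out
}

#' Split a session into pre- and post-injection epochs
#'
#' Epochs are defined positionally: TP1 is the first `epoch_length` frames
#' (pre-injection baseline) and TP2 the last `epoch_length` frames
#' (capturing the drug or placebo effect), independent of TR metadata.
#'
#' @param ts `regions x T` matrix.
#' @param epoch_length Frames per epoch (default 340).
#'
#' @return List: `tp1`, `tp2` (matrices), `tp1_idx`, `tp2_idx`.
#' @export
split_epochs <- function(ts, epoch_length = 340) {
  ts <- as.matrix(ts)
  tt <- ncol(ts)
  if (tt < 2 * epoch_length) {
    stopf("need at least %d frames for two %d-frame epochs, got %d",
          2 * epoch_length, epoch_length, tt)
  }
  tp1_idx <- seq_len(epoch_length)
  tp2_idx <- seq(tt - epoch_length + 1, tt)
  list(tp1 = ts[, tp1_idx, drop = FALSE], tp2 = ts[, tp2_idx, drop = FALSE],
       tp1_idx = tp1_idx, tp2_idx = tp2_idx)
}

#' Run the desk-scale preprocessing chain on a session
#'
#' Framewise displacement, scrubbing with spline interpolation, regression
#' of the six motion parameters, band-pass filtering, and the TP1/TP2
#' epoch split, in that order.
#'
#' @param session A [simulate_session()] result, or a list with `roi_ts`,
#'   `motion`, `tr`.
#' @param fd_threshold Scrub threshold in mm.
#' @param band Passband in Hz.
#' @param radius Rotation radius in mm for FD.
#' @param epoch_length Frames per epoch.
#'
#' @return List: `tp1`, `tp2` (clean epoch matrices), `ts` (full cleaned
#'   series), `fd`, `flagged`, `excess_motion`.
#' @export
preprocess_session <- function(session, fd_threshold = 0.05,
                               band = c(0.01, 0.1), radius = 5,
                               epoch_length = 340) {
  fd <- framewise_displacement(session$motion, radius = radius)
  scr <- scrub_interpolate(session$roi_ts, fd, threshold = fd_threshold)
  res <- regress_confounds(scr$ts, session$motion)
  flt <- bandpass(res, band = band, tr = session$tr)
  ep <- split_epochs(flt, epoch_length = epoch_length)
  list(tp1 = ep$tp1, tp2 = ep$tp2, ts = flt, fd = fd,
       flagged = scr$flagged, excess_motion = scr$excess_motion)
}
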