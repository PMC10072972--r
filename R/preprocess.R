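#' @include AllGenerics.R
NULL

# RBJ biquad notch coefficients (audio-EQ cookbook design)
.notchCoefs <- function(f0, rate, Q = 30) {
  w0 <- 2 * pi * f0 / rate
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch and band-pass filter a recording
#'
#' Applies a 2nd-order IIR notch (quality factor 30) at \code{notch_hz} to
#' suppress line noise, then a 4th-order Butterworth band-pass over
#' \code{band}. Both filters are run forward-backward
#' (\code{signal::filtfilt}) for zero phase distortion, which matters
#' because downstream phase-lag-index estimation is a pure phase statistic.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param notch_hz notch centre frequency, Hz (default 50); NULL disables.
#' @param band length-2 pass band (low, high), Hz (default c(3, 50));
#'   NULL disables. Must lie strictly inside (0, rate/2).
#' @return The filtered \linkS4class{EEGRecording} (same shape and rate).
#' @export
applyFilters <- function(rec, notch_hz = 50, band = c(3, 50)) {
  stopifnot(is(rec, "EEGRecording"))
  nyq <- rec@rate / 2
  data <- rec@data
  if (!is.null(notch_hz)) {
    if (notch_hz <= 0 || notch_hz >= nyq)
      stop("notch frequency must lie inside (0, Nyquist)")
    nf <- .notchCoefs(notch_hz, rec@rate)
    for (ch in seq_len(nrow(data)))
      data[ch, ] <- signal::filtfilt(nf$b, nf$a, data[ch, ])
  }
  if (!is.null(band)) {
    if (length(band) != 2L || band[1] <= 0 || band[2] >= nyq ||
        band[1] >= band[2])
      stop("band edges must satisfy 0 < low < high < Nyquist (",
           nyq, " Hz)")
    bf <- signal::butter(4, band / nyq, type = "pass")
    for (ch in seq_len(nrow(data)))
      data[ch, ] <- signal::filtfilt(bf, data[ch, ])
  }
  EEGRecording(data, rec@rate, rec@channelNames, rec@regionMap)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean across all channels, so that the
#' across-channel mean is zero everywhere afterwards.
#'
#' @param rec an \linkS4class{EEGRecording} with at least 2 channels.
#' @return The re-referenced \linkS4class{EEGRecording}.
#' @export
rereferenceCAR <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (nrow(rec@data) < 2L)
    stop("common-average reference needs at least 2 channels")
  data <- sweep(rec@data, 2L, colMeans(rec@data), "-")
  EEGRecording(data, rec@rate, rec@channelNames, rec@regionMap)
}

#' Downsample by an integer factor
#'
#' Keeps every (rate/target_hz)-th sample. The signal must already be
#' low-passed below the target Nyquist (the 3-50 Hz band satisfies this for
#' a 500 Hz target), so plain decimation is alias-free.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param target_hz target rate, Hz; \code{rate/target_hz} must be integer.
#' @return The decimated \linkS4class{EEGRecording} with
#'   \code{floor(n/factor)} samples.
#' @export
downsampleRecording <- function(rec, target_hz = 500) {
  stopifnot(is(rec, "EEGRecording"))
  factor <- rec@rate / target_hz
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("rate (", rec@rate, ") must be an integer multiple of target_hz (",
         target_hz, ")")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  idx <- seq.int(1L, by = factor,
                 length.out = floor(ncol(rec@data) / factor))
  EEGRecording(rec@data[, idx, drop = FALSE], target_hz,
               rec@channelNames, rec@regionMap)
}

#' Pluggable cleaning hook
#'
#' Placeholder for component-level artifact removal (e.g. ICA with manual
#' component rejection on real data). The default cleaner is the identity:
#' synthetic recordings carry no structured artifacts.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param cleaner a function \code{EEGRecording -> EEGRecording}, or NULL.
#' @return The (possibly cleaned) recording.
#' @export
applyCleaner <- function(rec, cleaner = NULL) {
  if (is.null(cleaner)) return(rec)
  out <- cleaner(rec)
  stopifnot(is(out, "EEGRecording"))
  out
}

#' Extract event-locked epochs around RC
#'
#' Cuts one epoch per right-paw-contact (RC) event: the half-open window
#' [RC - pre_s, RC - pre_s + total_s), snapped to the nearest sample.
#' Epochs that would extend beyond the recording are skipped (counted in a
#' message). Each epoch inherits the condition of its event row.
#'
#' @param rec an \linkS4class{EEGRecording} (typically at 500 Hz).
#' @param events a \linkS4class{GaitEvents}.
#' @param pre_s seconds before RC at which the epoch starts (default 1.0).
#' @param total_s total epoch duration, seconds (default 2.5, i.e. 1250
#'   samples at 500 Hz: two preparation phases and one walking phase).
#' @return An \linkS4class{EpochSet}; empty (with a warning) when no RC
#'   event yields a complete epoch.
#' @export
extractEpochs <- function(rec, events, pre_s = 1.0, total_s = 2.5) {
  stopifnot(is(rec, "EEGRecording"), is(events, "GaitEvents"))
  rate <- rec@rate
  nSamp <- as.integer(round(total_s * rate))
  preSamp <- as.integer(round(pre_s * rate))
  ev <- gaitEvents(events)
  rc <- ev[ev$event == "RC", , drop = FALSE]
  emptySet <- function() {
    new("EpochSet",
        data = array(0, dim = c(0L, nrow(rec@data), nSamp)),
        rate = rate, t0Offset = -pre_s, condition = character(),
        channelNames = rec@channelNames, regionMap = rec@regionMap)
  }
  if (!nrow(rc)) {
    warning("no RC events; empty EpochSet")
    return(emptySet())
  }
  centre <- as.integer(round(rc$time_s * rate)) + 1L  # sample 1 is t = 0
  start <- centre - preSamp
  keep <- start >= 1L & (start + nSamp - 1L) <= ncol(rec@data)
  skipped <- sum(!keep)
  if (skipped)
    message(skipped, " RC event(s) too close to the recording edge; skipped")
  if (!any(keep)) {
    warning("no RC event admits a complete epoch; empty EpochSet")
    return(emptySet())
  }
  start <- start[keep]
  out <- array(0, dim = c(length(start), nrow(rec@data), nSamp))
  for (e in seq_along(start))
    out[e, , ] <- rec@data[, start[e]:(start[e] + nSamp - 1L)]
  new("EpochSet", data = out, rate = rate, t0Offset = -pre_s,
      condition = rc$condition[keep], channelNames = rec@channelNames,
      regionMap = rec@regionMap)
}

#' Standard preprocessing chain
#'
#' Notch (50 Hz) -> band-pass (3-50 Hz) -> common-average reference ->
#' downsample (500 Hz), in that order, then an optional cleaner hook.
#'
#' @param rec raw \linkS4class{EEGRecording}.
#' @param notch_hz,band,target_hz see the individual stages.
#' @param cleaner optional cleaner passed to \code{\link{applyCleaner}}.
#' @return The preprocessed \linkS4class{EEGRecording}.
#' @export
preprocessRecording <- function(rec, notch_hz = 50, band = c(3, 50),
                                target_hz = 500, cleaner = NULL) {
  rec <- applyFilters(rec, notch_hz = notch_hz, band = band)
  rec <- rereferenceCAR(rec)
  rec <- downsampleRecording(rec, target_hz)
  applyCleaner(rec, cleaner)
}
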