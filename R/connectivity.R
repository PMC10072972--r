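#' @include AllGenerics.R
NULL

# wrap phase differences into (-pi, pi]
.wrapPhase <- function(d) {
  w <- (d + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# analytic signal of a real vector via FFT (one-sided spectrum doubling)
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase via the analytic signal
#'
#' The instantaneous phase of each channel is the angle of its analytic
#' signal (real signal + i * Hilbert transform), computed over the full
#' segment. Amplitude scaling leaves phases unchanged.
#'
#' @param x numeric vector, or channels x samples matrix.
#' @return phases in radians, same shape as \code{x}.
#' @export
instantaneousPhase <- function(x) {
  if (!all(is.finite(x))) stop("input contains non-finite values")
  if (is.matrix(x)) {
    if (ncol(x) < 8L) stop("need at least 8 samples")
    t(apply(x, 1L, function(ch) Arg(.analytic(ch))))
  } else {
    if (length(x) < 8L) stop("need at least 8 samples")
    Arg(.analytic(x))
  }
}

#' Phase-lag index of one channel pair
#'
#' PLI = | mean_n sign(dphi(t_n)) | where dphi is the instantaneous phase
#' difference wrapped to (-pi, pi] and sign(0) = 0. PLI is 0 for phase
#' differences centred on 0 mod pi (including identical signals and pure
#' volume conduction) and 1 for complete phase locking at a nonzero lag.
#'
#' @param phase_x,phase_y equal-length phase series, radians.
#' @return PLI in [0, 1].
#' @export
pliPair <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y))
    stop("phase series must have equal length")
  if (length(phase_x) < 2L) stop("need at least 2 samples")
  abs(mean(sign(.wrapPhase(phase_x - phase_y))))
}

#' All-pairs PLI matrix from a phase block
#'
#' @param phases channels x samples matrix of instantaneous phases.
#' @return symmetric channels x channels PLI matrix with zero diagonal.
#' @export
pliMatrix <- function(phases) {
  nc <- nrow(phases)
  pairs <- which(upper.tri(diag(nc)), arr.ind = TRUE)
  d <- .wrapPhase(phases[pairs[, 1], , drop = FALSE] -
                  phases[pairs[, 2], , drop = FALSE])
  v <- abs(rowMeans(sign(d)))
  out <- matrix(0, nc, nc, dimnames = list(rownames(phases), rownames(phases)))
  out[pairs] <- v
  out[pairs[, 2:1, drop = FALSE]] <- v
  out
}

#' Sliding-window PLI tensor
#'
#' Computes the instantaneous phase of each epoch over its full length
#' (avoiding Hilbert edge artifacts inside short windows), then evaluates
#' the all-pairs PLI within each 250-ms window of the grid. A 2.5-s epoch
#' at 50\% overlap yields 19 windows.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param grid a \linkS4class{WindowGrid}; default: the standard
#'   250-ms/50\%-overlap grid over the epoch length.
#' @return A \linkS4class{ConnectivityTensor}
#'   (epochs x windows x channels x channels).
#' @export
slidingPLI <- function(epochs, grid = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  d <- dim(epochs@data)
  epochLen <- d[3] / epochs@rate
  if (is.null(grid)) grid <- windowGrid(epochLen)
  if (grid@winLen > epochLen + 1e-9)
    stop("window (", grid@winLen, " s) longer than epoch (", epochLen, " s)")
  winSamp <- as.integer(round(grid@winLen * epochs@rate))
  starts <- floor(grid@offsets * epochs@rate) + 1L
  nW <- length(starts)
  out <- array(0, dim = c(d[1], nW, d[2], d[2]))
  for (e in seq_len(d[1])) {
    ph <- instantaneousPhase(epochs@data[e, , ])
    for (w in seq_len(nW)) {
      sl <- starts[w]:(starts[w] + winSamp - 1L)
      out[e, w, , ] <- pliMatrix(ph[, sl, drop = FALSE])
    }
  }
  new("ConnectivityTensor", values = out, grid = grid,
      condition = epochs@condition, channelNames = epochs@channelNames)
}

#' Whole-span PLI per epoch
#'
#' One 32 x 32 PLI matrix per epoch over a single span relative to the
#' alignment event (default -1.0 to +0.5 s, the complete gait cycle used
#' for whole-time connectivity features).
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param span_s length-2 span relative to the alignment event, seconds.
#' @return numeric array, epochs x channels x channels.
#' @export
wholeEpochPLI <- function(epochs, span_s = c(-1.0, 0.5)) {
  stopifnot(is(epochs, "EpochSet"))
  d <- dim(epochs@data)
  i0 <- as.integer(round((span_s[1] - epochs@t0Offset) * epochs@rate)) + 1L
  i1 <- as.integer(round((span_s[2] - epochs@t0Offset) * epochs@rate))
  if (i0 < 1L || i1 > d[3] || i0 >= i1)
    stop("span outside the epoch")
  out <- array(0, dim = c(d[1], d[2], d[2]))
  for (e in seq_len(d[1])) {
    ph <- instantaneousPhase(epochs@data[e, , ])
    out[e, , ] <- pliMatrix(ph[, i0:i1, drop = FALSE])
  }
  out
}

# window indices of the standard 19-window grid that align with gait phases:
# preparation = non-overlapping windows 1, 3, 5 (0..750 ms of the epoch);
# walking sub-phases = windows starting exactly at 750, 1000, 1250 ms
.STD_PREP_WINDOWS <- c(1L, 3L, 5L)
.STD_WALK_WINDOWS <- c(7L, 9L, 11L)

#' Collapse a windowed tensor to the four gait phases
#'
#' Requires the standard grid (2.5-s epoch, 250-ms windows, 50\% overlap,
#' 19 windows). The preparation phase LC->RO is the element-wise mean of
#' the three non-overlapping windows 1, 3 and 5 (covering -1000..-250 ms
#' relative to RC); the walking sub-phases RO->RC, RC->LO and LO->LC are
#' the single windows starting exactly at -250, 0 and +250 ms, which at
#' 50\% overlap coincide with the 250-ms sub-phases.
#'
#' @param tensor a \linkS4class{ConnectivityTensor} on the standard grid.
#' @return A \linkS4class{PhaseConnectivity}
#'   (epochs x 4 x channels x channels).
#' @export
collapsePhases <- function(tensor) {
  stopifnot(is(tensor, "ConnectivityTensor"))
  g <- tensor@grid
  if (abs(g@winLen - 0.25) > 1e-9 || abs(g@step - 0.125) > 1e-9 ||
      abs(g@epochLen - 2.5) > 1e-9 || nWindows(g) != 19L)
    stop("collapsePhases expects the standard grid: 2.5-s epoch, ",
         "250-ms windows, 125-ms step (19 windows); got ",
         nWindows(g), " windows of ", g@winLen, " s over ", g@epochLen, " s")
  v <- tensor@values
  d <- dim(v)
  out <- array(0, dim = c(d[1], 4L, d[3], d[4]))
  out[, 1L, , ] <- (v[, 1L, , ] + v[, 3L, , ] + v[, 5L, , ]) / 3
  for (k in 1:3)
    out[, k + 1L, , ] <- v[, .STD_WALK_WINDOWS[k], , ]
  new("PhaseConnectivity", values = out, phases = GAIT_PHASES,
      condition = tensor@condition, channelNames = tensor@channelNames)
}

#' Average phase connectivity within conditions
#'
#' Element-wise mean over epochs sharing a condition, one matrix per
#' (condition, phase): with all three conditions present the result is the
#' 3 x 4 x 32 x 32 condition-average tensor.
#'
#' @param phase_conn a \linkS4class{PhaseConnectivity}.
#' @param conditions condition order (default FF, FU, UF); conditions with
#'   zero epochs are omitted with a warning.
#' @return numeric array, conditions x phases x channels x channels, with
#'   dimnames.
#' @export
conditionAverage <- function(phase_conn, conditions = CONDITIONS) {
  stopifnot(is(phase_conn, "PhaseConnectivity"))
  present <- conditions[conditions %in% phase_conn@condition]
  missing <- setdiff(conditions, present)
  if (length(missing))
    warning("condition(s) with zero epochs omitted: ",
            paste(missing, collapse = ", "))
  if (!length(present)) stop("no epochs in any requested condition")
  d <- dim(phase_conn@values)
  out <- array(0, dim = c(length(present), d[2], d[3], d[4]),
               dimnames = list(present, phase_conn@phases,
                               phase_conn@channelNames,
                               phase_conn@channelNames))
  for (ci in seq_along(present)) {
    idx <- which(phase_conn@condition == present[ci])
    sub <- phase_conn@values[idx, , , , drop = FALSE]
    out[ci, , , ] <- apply(sub, c(2, 3, 4), mean)
  }
  out
}
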