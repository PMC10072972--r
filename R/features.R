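#' @include AllGenerics.R
NULL

.GLOBAL_METRIC_NAMES <- c("global_efficiency", "transitivity",
                          "char_path_length")
.LOCAL_METRIC_NAMES <- c("local_efficiency", "strength", "clustering",
                         "eigenvector")

#' Build a classifier-ready feature set
#'
#' Six feature families over one complete gait cycle
#' (LC->RO->RC->LO->LC, i.e. -1000 to +500 ms around RC):
#' \describe{
#'   \item{raw}{flattened raw EEG segment, 32 x 750 samples = 24,000 dims.}
#'   \item{whole_pli}{one PLI matrix over the full span, 32 x 32 = 1,024.}
#'   \item{tv_pli}{the four gait-phase PLI matrices, 4 x 32 x 32 = 4,096.}
#'   \item{merged_phases}{the first \code{kPhases} phase matrices in gait
#'     order, k x 1,024 (k = 1..4; 3 phases give 3,072).}
#'   \item{global_metrics}{one global metric per phase, 4 dims.}
#'   \item{local_metrics}{one local metric per node per phase,
#'     4 x 32 = 128 dims.}
#' }
#'
#' @param family one of raw, whole_pli, tv_pli, merged_phases,
#'   global_metrics, local_metrics.
#' @param epochs \linkS4class{EpochSet} (families raw, whole_pli).
#' @param phase_conn \linkS4class{PhaseConnectivity} (families tv_pli,
#'   merged_phases).
#' @param metrics result of \code{\link{phaseMetrics}} (metric families).
#' @param kPhases number of leading gait phases for merged_phases (1..4).
#' @param metric which metric for the metric families (one of the three
#'   global or four local metric names).
#' @param span_s raw/whole-PLI span relative to RC (default c(-1, 0.5)).
#' @return A \linkS4class{FeatureSet}.
#' @export
buildFeatures <- function(family = c("raw", "whole_pli", "tv_pli",
                                     "merged_phases", "global_metrics",
                                     "local_metrics"),
                          epochs = NULL, phase_conn = NULL, metrics = NULL,
                          kPhases = 4L, metric = NULL,
                          span_s = c(-1.0, 0.5)) {
  family <- match.arg(family)
  flat <- function(a) {
    # epochs x ... -> epochs x prod(...), epoch-major
    d <- dim(a)
    matrix(a, nrow = d[1], ncol = prod(d[-1]))
  }
  needs <- function(ok, what)
    if (is.null(ok)) stop("family '", family, "' needs ", what)
  if (family == "raw") {
    needs(epochs, "epochs")
    i0 <- as.integer(round((span_s[1] - epochs@t0Offset) * epochs@rate)) + 1L
    i1 <- as.integer(round((span_s[2] - epochs@t0Offset) * epochs@rate))
    m <- flat(epochs@data[, , i0:i1, drop = FALSE])
    labels <- epochs@condition
  } else if (family == "whole_pli") {
    needs(epochs, "epochs")
    m <- flat(wholeEpochPLI(epochs, span_s))
    labels <- epochs@condition
  } else if (family == "tv_pli") {
    needs(phase_conn, "phase_conn")
    m <- flat(phase_conn@values)
    labels <- phase_conn@condition
  } else if (family == "merged_phases") {
    needs(phase_conn, "phase_conn")
    kPhases <- as.integer(kPhases)
    if (is.na(kPhases) || kPhases < 1L || kPhases > dim(phase_conn@values)[2])
      stop("kPhases must lie in 1..", dim(phase_conn@values)[2])
    m <- flat(phase_conn@values[, seq_len(kPhases), , , drop = FALSE])
    labels <- phase_conn@condition
    family <- sprintf("merged_phases(%d)", kPhases)
  } else if (family == "global_metrics") {
    needs(metrics, "metrics (phaseMetrics output)")
    if (is.null(metric)) metric <- .GLOBAL_METRIC_NAMES[1]
    metric <- match.arg(metric, .GLOBAL_METRIC_NAMES)
    m <- metrics$global[, , metric, drop = TRUE]
    m <- matrix(m, nrow = dim(metrics$global)[1])
    # disconnected networks have undefined path length; encode as 0
    m[!is.finite(m)] <- 0
    labels <- metrics$condition
    family <- sprintf("global_metrics(%s)", metric)
  } else {  # local_metrics
    needs(metrics, "metrics (phaseMetrics output)")
    if (is.null(metric)) metric <- .LOCAL_METRIC_NAMES[1]
    metric <- match.arg(metric, .LOCAL_METRIC_NAMES)
    m <- flat(metrics$local[, , , metric, drop = FALSE])
    labels <- metrics$condition
    family <- sprintf("local_metrics(%s)", metric)
  }
  new("FeatureSet", matrix = unname(m), labels = as.character(labels),
      family = family)
}
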