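#' @include AllGenerics.R
NULL

.checkWeights <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (any(W < 0)) stop("negative weights are not allowed")
  if (any(abs(W - t(W)) > 1e-12)) stop("weight matrix must be symmetric")
  diag(W) <- 0
  W
}

#' Threshold edges for display
#'
#' Removes every edge whose weight is at most \code{fraction} times the
#' strongest connection, keeping the surviving edges at their original
#' weight. Used only when exporting or visualizing networks; graph metrics
#' are computed on the full weighted matrix.
#'
#' @param W symmetric non-negative weight matrix.
#' @param fraction threshold fraction in [0, 1) (default 0.5).
#' @return The thresholded weight matrix.
#' @export
thresholdEdges <- function(W, fraction = 0.5) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  W <- .checkWeights(W)
  W[W <= fraction * max(W)] <- 0
  W
}

# all-pairs shortest-path distances on inverse-weight lengths (Dijkstra via
# igraph); returns Inf for disconnected pairs
.spDistances <- function(W) {
  n <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, n, n); diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                    algorithm = "dijkstra")
}

# per-node triangle intensity (Onnela): t_i = 1/2 sum_jh (w~ij w~jh w~hi)^(1/3)
# with weights normalized by the matrix maximum
.triangleIntensity <- function(W) {
  mx <- max(W)
  if (mx == 0) return(numeric(nrow(W)))
  Wr <- (W / mx)^(1 / 3)
  diag(Wr %*% Wr %*% Wr) / 2
}

#' Global metrics of a weighted graph
#'
#' Brain Connectivity Toolbox conventions: edge distances are inverse
#' weights (1/w, infinite for absent edges) with shortest paths by
#' Dijkstra. Global efficiency is the mean of 1/d over ordered node pairs
#' (0 for disconnected pairs); characteristic path length is the mean
#' shortest-path distance over connected ordered pairs; transitivity is
#' sum_i 2 t_i / sum_i k_i (k_i - 1) with t_i the Onnela triangle intensity
#' (geometric means of max-normalized weights) and k_i the binary degree.
#'
#' @param W symmetric non-negative weight matrix (n >= 2), weights <= 1 for
#'   the efficiency bound to hold.
#' @return list with \code{global_efficiency}, \code{transitivity},
#'   \code{char_path_length} (NA when no pair is connected) and
#'   \code{n_disconnected_pairs} (ordered pairs).
#' @export
globalMetrics <- function(W) {
  W <- .checkWeights(W)
  n <- nrow(W)
  if (n < 2L) stop("need at least 2 nodes")
  d <- .spDistances(W)
  off <- d[row(d) != col(d)]
  eff <- ifelse(is.finite(off), 1 / off, 0)
  connected <- is.finite(off)
  k <- rowSums(W > 0)
  denom <- sum(k * (k - 1))
  list(
    global_efficiency = mean(eff),
    transitivity = if (denom > 0) 2 * sum(.triangleIntensity(W)) / denom else 0,
    char_path_length = if (any(connected)) mean(off[connected]) else NA_real_,
    n_disconnected_pairs = sum(!connected)
  )
}

# power iteration for the leading eigenvector of a non-negative symmetric
# matrix; non-negative, unit Euclidean norm
.eigenCentrality <- function(W, tol = 1e-10, maxIter = 10000L) {
  n <- nrow(W)
  if (max(W) == 0) return(rep(0, n))
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(maxIter)) {
    v2 <- as.vector(W %*% v)
    nrm <- sqrt(sum(v2^2))
    if (nrm == 0) return(rep(0, n))
    v2 <- v2 / nrm
    if (max(abs(v2 - v)) < tol) { v <- v2; break }
    v <- v2
  }
  if (sum(v) < 0) v <- -v
  pmax(v, 0) / sqrt(sum(pmax(v, 0)^2))
}

#' Local metrics of a weighted graph
#'
#' Per node: strength (row sum of weights), Onnela weighted clustering
#' coefficient (2 t_i / (k_i (k_i - 1)), 0 for degree < 2), local
#' efficiency (global efficiency of the node's weighted neighborhood
#' subgraph, 0 for fewer than 2 neighbors) and eigenvector centrality
#' (leading eigenvector of the weight matrix by power iteration, tolerance
#' 1e-10, non-negative with unit Euclidean norm). Isolated nodes get 0 for
#' strength, clustering and local efficiency. When a region map is given,
#' per-region means of every metric are returned as well.
#'
#' @param W symmetric non-negative weight matrix.
#' @param regionMap optional channel -> region named character vector (or
#'   unnamed, matched by position).
#' @return list with \code{node} (data.frame: node, strength, clustering,
#'   local_efficiency, eigenvector) and, when regions are given,
#'   \code{region} (data.frame of per-region means).
#' @export
localMetrics <- function(W, regionMap = NULL) {
  W <- .checkWeights(W)
  n <- nrow(W)
  k <- rowSums(W > 0)
  t_i <- .triangleIntensity(W)
  cc <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  eloc <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2L) return(0)
    globalMetrics(W[nb, nb, drop = FALSE])$global_efficiency
  }, numeric(1))
  ec <- .eigenCentrality(W)
  labels <- rownames(W)
  if (is.null(labels)) labels <- sprintf("CH%02d", seq_len(n))
  node <- data.frame(node = labels, strength = rowSums(W), clustering = cc,
                     local_efficiency = eloc, eigenvector = ec,
                     stringsAsFactors = FALSE)
  out <- list(node = node)
  if (!is.null(regionMap)) {
    reg <- if (is.null(names(regionMap))) regionMap else
      regionMap[match(labels, names(regionMap))]
    agg <- stats::aggregate(node[, -1L], by = list(region = reg), FUN = mean)
    out$region <- agg
  }
  out
}

#' Per-epoch, per-phase graph metrics
#'
#' Computes the three global metrics and four local metrics on every
#' (epoch, gait phase) PLI matrix of a phase-collapsed tensor; these
#' per-network values feed both the condition ANOVA and the metric feature
#' families.
#'
#' @param phase_conn a \linkS4class{PhaseConnectivity}.
#' @return list with \code{global} (epochs x phases x 3, metrics
#'   global_efficiency/transitivity/char_path_length) and \code{local}
#'   (epochs x phases x channels x 4, metrics
#'   local_efficiency/strength/clustering/eigenvector), plus
#'   \code{condition} labels.
#' @export
phaseMetrics <- function(phase_conn) {
  stopifnot(is(phase_conn, "PhaseConnectivity"))
  v <- phase_conn@values
  d <- dim(v)
  gNames <- c("global_efficiency", "transitivity", "char_path_length")
  lNames <- c("local_efficiency", "strength", "clustering", "eigenvector")
  g <- array(NA_real_, dim = c(d[1], d[2], 3L),
             dimnames = list(NULL, phase_conn@phases, gNames))
  l <- array(NA_real_, dim = c(d[1], d[2], d[3], 4L),
             dimnames = list(NULL, phase_conn@phases,
                             phase_conn@channelNames, lNames))
  for (e in seq_len(d[1])) for (p in seq_len(d[2])) {
    W <- v[e, p, , ]
    gm <- globalMetrics(W)
    g[e, p, ] <- c(gm$global_efficiency, gm$transitivity,
                   gm$char_path_length)
    lm <- localMetrics(W)$node
    l[e, p, , ] <- as.matrix(lm[, c("local_efficiency", "strength",
                                    "clustering", "eigenvector")])
  }
  list(global = g, local = l, condition = phase_conn@condition)
}

#' Time course of global metrics
#'
#' Global efficiency, transitivity and characteristic path length of every
#' (epoch, window) network, averaged within condition per window, with the
#' 95\% confidence interval of the mean (t-based; NA and flagged when a
#' condition has a single epoch).
#'
#' @param tensor a \linkS4class{ConnectivityTensor}.
#' @return data.frame with columns condition, window, t_center_s, metric,
#'   mean, ci_lo, ci_hi, n.
#' @export
timecourseGlobal <- function(tensor) {
  stopifnot(is(tensor, "ConnectivityTensor"))
  d <- dim(tensor@values)
  if (d[1] == 0L) stop("empty tensor")
  gNames <- c("global_efficiency", "transitivity", "char_path_length")
  vals <- array(NA_real_, dim = c(d[1], d[2], 3L))
  for (e in seq_len(d[1])) for (w in seq_len(d[2])) {
    gm <- globalMetrics(tensor@values[e, w, , ])
    vals[e, w, ] <- c(gm$global_efficiency, gm$transitivity,
                      gm$char_path_length)
  }
  centers <- tensor@grid@offsets + tensor@grid@winLen / 2
  conds <- unique(tensor@condition)
  rows <- list()
  for (cond in conds) {
    idx <- which(tensor@condition == cond)
    for (w in seq_len(d[2])) for (m in 1:3) {
      x <- vals[idx, w, m]
      x <- x[is.finite(x)]
      nn <- length(x)
      mu <- if (nn) mean(x) else NA_real_
      if (nn >= 2L) {
        half <- stats::qt(0.975, nn - 1L) * stats::sd(x) / sqrt(nn)
        lo <- mu - half; hi <- mu + half
      } else {
        lo <- NA_real_; hi <- NA_real_  # CI undefined for n = 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, window = w, t_center_s = centers[w],
        metric = gNames[m], mean = mu, ci_lo = lo, ci_hi = hi, n = nn,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
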