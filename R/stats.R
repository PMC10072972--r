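#' @include AllGenerics.R
NULL

.checkGroups <- function(values, groups, minGroups = 2L) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < minGroups)
    stop("need at least ", minGroups, " groups")
  n <- table(groups)
  if (any(n < 2L)) stop("every group needs at least 2 observations")
  if (length(values) <= nlevels(groups))
    stop("total n must exceed the number of groups")
  groups
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA (between/within mean-square ratio,
#' equal variances assumed) across the locomotion conditions, via
#' \code{stats::oneway.test(var.equal = TRUE)}. The degenerate case of
#' equal group means with zero within-group variance is reported as F = 0,
#' p = 1 with a warning rather than NaN.
#'
#' @param values numeric observations (e.g. one network metric per epoch).
#' @param groups group label per observation (>= 2 groups, each n >= 2).
#' @return list with \code{F}, \code{df} (between, within) and \code{p}.
#' @export
anovaOneway <- function(values, groups) {
  groups <- .checkGroups(values, groups)
  k <- nlevels(groups)
  df <- c(between = k - 1L, within = length(values) - k)
  gm <- tapply(values, groups, mean)
  wv <- tapply(values, groups, stats::var)
  if (max(gm) - min(gm) < 1e-300 && all(wv < 1e-300)) {
    warning("zero between- and within-group variance; F defined as 0")
    return(list(F = 0, df = df, p = 1))
  }
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ft$statistic), df = df, p = unname(ft$p.value))
}

#' Tukey HSD post hoc pairwise comparisons
#'
#' All pairwise condition comparisons following a one-way ANOVA, via
#' \code{stats::TukeyHSD}; with the three locomotion conditions this yields
#' exactly the pairs FF-FU, FF-UF and FU-UF.
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 3 groups required).
#' @return data.frame with columns pair, diff, p_adj (Tukey-adjusted).
#' @export
posthocPairwise <- function(values, groups) {
  groups <- .checkGroups(values, groups, minGroups = 3L)
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Condition ANOVA over all metrics and gait phases
#'
#' Runs the one-way condition ANOVA (and, with three conditions, Tukey HSD
#' post hoc pairs) for every global and local-region metric in every gait
#' phase. P values are per-comparison and deliberately uncorrected across
#' metrics/phases (flagged in the \code{p_note} attribute).
#'
#' @param metrics result of \code{\link{phaseMetrics}}.
#' @param regionMap optional channel -> region map; when given, local
#'   metrics are averaged per region before testing.
#' @param alpha significance level for the star column (default 0.05).
#' @return data.frame with metric, phase, scope (global/region name), F,
#'   df1, df2, p, the three pairwise p values (NA with < 3 conditions) and
#'   a significance star at p < alpha.
#' @export
metricsAnova <- function(metrics, regionMap = NULL, alpha = 0.05) {
  cond <- metrics$condition
  nCond <- length(unique(cond))
  rows <- list()
  addRow <- function(metric, phase, scope, x) {
    ok <- is.finite(x)
    if (sum(ok) <= nCond || length(unique(cond[ok])) < 2L) return()
    a <- anovaOneway(x[ok], cond[ok])
    pr <- rep(NA_real_, 3L)
    if (length(unique(cond[ok])) >= 3L) {
      ph <- posthocPairwise(x[ok], cond[ok])
      pr <- ph$p_adj[match(c("FU-FF", "UF-FF", "UF-FU"), ph$pair)]
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, phase = phase, scope = scope,
      F = a$F, df1 = a$df[1], df2 = a$df[2], p = a$p,
      p_FF_FU = pr[1], p_FF_UF = pr[2], p_FU_UF = pr[3],
      sig = ifelse(a$p < alpha, "*", ""), stringsAsFactors = FALSE)
  }
  g <- metrics$global
  for (m in dimnames(g)[[3]]) for (ph in dimnames(g)[[2]])
    addRow(m, ph, "global", g[, ph, m])
  l <- metrics$local
  if (!is.null(regionMap)) {
    regs <- regionMap[match(dimnames(l)[[3]], names(regionMap))]
    for (m in dimnames(l)[[4]]) for (ph in dimnames(l)[[2]]) {
      for (r in unique(regs)) {
        x <- apply(l[, ph, regs == r, m, drop = FALSE], 1L, mean)
        addRow(m, ph, r, x)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "p_note") <- "per-comparison p values, uncorrected across metrics/phases"
  out
}
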