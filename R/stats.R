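#' @include AllClasses.R
NULL

#' Summarize replicate values with the study's reporting convention
#'
#' Median and interquartile range (type-7 linear-interpolation quantiles),
#' except for groups of exactly five values, which are reported as mean
#' +/- sample standard deviation.
#'
#' @param values numeric vector, length >= 2.
#' @return one-row data.frame with columns n, center, spread, q25, q75,
#'   summaryType.
#' @examples
#' summarizeValues(c(1, 2, 3, 4, 100))   # mean 22 +/- 43.6
#' summarizeValues(1:6)                  # median 3.5, IQR 2.25-4.75
#' @export
summarizeValues <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (length(values) == 5) {
    data.frame(n = 5L, center = mean(values), spread = stats::sd(values),
               q25 = NA_real_, q75 = NA_real_,
               summaryType = "mean +/- SD")
  } else {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    data.frame(n = length(values), center = q[2], spread = q[3] - q[1],
               q25 = q[1], q75 = q[3], summaryType = "median (IQR)")
  }
}

# Dunn's pairwise z-tests on pooled ranks with tie correction; the
# Kruskal-Wallis companion post hoc.
.dunnTest <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  r <- rank(values)
  Nn <- length(values)
  tieTab <- table(r)
  tieCorr <- sum(tieTab^3 - tieTab) / (12 * (Nn - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  mComp <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, pRaw = NA_real_,
                    pBonferroni = NA_real_, significant = NA)
  for (k in seq_len(mComp)) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    se <- sqrt((Nn * (Nn + 1) / 12 - tieCorr) *
                 (1 / n[[g1]] + 1 / n[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    out$z[k] <- z
    out$pRaw[k] <- p
    out$pBonferroni[k] <- min(1, p * mComp)
  }
  out$significant <- out$pBonferroni < alpha
  out
}

#' Compare metric replicates across groups
#'
#' The full comparison chain of the phantom study: per-group summaries
#' ([summarizeValues()]), Shapiro-Wilk normality and Levene
#' equal-variance screens (reported, never gating), the tie-corrected
#' Kruskal-Wallis omnibus test, and Dunn's pairwise post hoc with
#' Bonferroni correction over all group pairs at `alpha`.
#'
#' @param values numeric vector of metric values.
#' @param groups group labels, same length.
#' @param metric metric name for the report.
#' @param alpha significance level (default 0.05).
#' @return a [StatsReport-class]. Groups with fewer than 3 replicates are
#'   dropped with a warning.
#' @examples
#' set.seed(1)
#' compareGroups(c(rnorm(10), rnorm(10, 3)), rep(c("a", "b"), each = 10),
#'               metric = "demo")
#' @export
compareGroups <- function(values, groups, metric = "metric",
                          alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  n <- table(groups)
  small <- names(n)[n < 3]
  if (length(small)) {
    warning(sprintf("dropping groups with < 3 replicates: %s",
                    paste(small, collapse = ", ")))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2)
    stop("need at least 2 groups with >= 3 replicates")
  gs <- do.call(rbind, lapply(split(values, groups), summarizeValues))
  gs <- cbind(group = rownames(gs), gs)
  rownames(gs) <- NULL
  shap <- vapply(split(values, groups), function(v) {
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  lev <- tryCatch(
    car::leveneTest(values ~ factor(groups))[["Pr(>F)"]][1],
    error = function(e) NA_real_)
  kw <- stats::kruskal.test(values, factor(groups))
  dunn <- .dunnTest(values, groups, alpha = alpha)
  new("StatsReport", metric = metric, groupSummary = gs, shapiroP = shap,
      leveneP = as.numeric(lev), kruskalH = unname(kw$statistic),
      kruskalP = kw$p.value, dunn = dunn, alpha = alpha)
}
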