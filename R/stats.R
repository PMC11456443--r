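#' Omnibus comparison of a metric across laminar compartments
#'
#' Kruskal-Wallis rank test (tie-corrected), df = groups - 1, plus
#' per-group medians and mean +/- SE.
#'
#' @param values Numeric metric values.
#' @param groups Compartment label per value.
#' @return list of class `compartmentComparison`: `statistic` (H), `df`,
#'   `p`, `summary` (per-group data.frame), `test`.
#' @export
compartmentCompare <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")
  if (length(unique(values)) == 1L) {
    kw <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
               parameter = c(df = nlevels(groups) - 1), p.value = 1)
  } else {
    kw <- stats::kruskal.test(values, groups)
  }
  sm <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), median = stats::median(v),
               mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))
  structure(list(statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p = kw$p.value,
                 summary = sm, test = "Kruskal-Wallis"),
            class = "compartmentComparison")
}

#' @export
print.compartmentComparison <- function(x, ...) {
  cat(sprintf("%s: chi-squared(%d) = %.3f, p = %.3g\n",
              x$test, x$df, x$statistic, x$p))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Two-sample Wilcoxon comparison
#'
#' Two-tailed Wilcoxon rank-sum test for unpaired samples or signed-rank
#' test for paired ones (e.g. shuffled vs unshuffled accuracies). Exact
#' p-values below `exactMax` observations per sample, normal approximation
#' with continuity correction above. Identical paired vectors (all zero
#' differences) return p = 1 by convention.
#'
#' @param a,b Numeric samples (equal length when `paired`).
#' @param paired Signed-rank instead of rank-sum?
#' @param exactMax Sample-size limit for exact p-values.
#' @return list with `statistic`, `p`, `test`.
#' @export
pairwiseCompare <- function(a, b, paired = FALSE, exactMax = 25L) {
  if (paired && length(a) != length(b))
    stop("paired samples must have equal length")
  if (paired && all(a == b))
    return(list(statistic = NA_real_, p = 1,
                test = "Wilcoxon signed-rank (all differences zero)"))
  exact <- max(length(a), length(b)) < exactMax
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = paired, exact = exact,
                       correct = TRUE, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       test = if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum")
}

#' Correlation between Fano factor and decoding accuracy
#'
#' Correlates each subpopulation's (or neuron's) mean Fano factor with its
#' mean decoding accuracy; Pearson by default (Spearman available).
#'
#' @param ff Mean Fano factor per unit.
#' @param accuracy Mean decoding accuracy per unit.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n`, `method`.
#' @export
ffPerformanceCorrelation <- function(ff, accuracy, method = "pearson") {
  keep <- is.finite(ff) & is.finite(accuracy)
  ff <- ff[keep]; accuracy <- accuracy[keep]
  if (length(ff) < 3) stop("need at least 3 paired values")
  if (stats::sd(ff) == 0 || stats::sd(accuracy) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(ff, accuracy, method = method,
                        alternative = "two.sided", exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ff),
       method = method)
}

#' Running kurtosis along depth
#'
#' Sample kurtosis (Pearson, non-excess: `m4 / m2^2`; Gaussian reference 3)
#' of metric values in a sliding depth window. Windows with fewer than
#' `minN` values or zero variance are skipped (NA).
#'
#' @param values Metric values.
#' @param depths Depth (um) per value.
#' @param window Window width (um).
#' @param at Depths at which to evaluate (default each observed depth).
#' @param minN Minimum values per window.
#' @return data.frame: `depth`, `n`, `kurtosis`.
#' @export
runningKurtosis <- function(values, depths, window = 100, at = NULL,
                            minN = 4L) {
  stopifnot(length(values) == length(depths))
  if (is.null(at)) at <- sort(unique(depths))
  half <- window / 2
  out <- vapply(at, function(d) {
    v <- values[depths >= d - half & depths <= d + half]
    v <- v[is.finite(v)]
    if (length(v) < minN) return(c(length(v), NA_real_))
    m2 <- mean((v - mean(v))^2)
    if (m2 == 0) return(c(length(v), NA_real_))
    c(length(v), mean((v - mean(v))^4) / m2^2)
  }, numeric(2))
  data.frame(depth = at, n = out[1, ], kurtosis = out[2, ])
}

#' Compartment-level statistics report
#'
#' Bundles the standard comparisons: omnibus Kruskal-Wallis per metric,
#' pairwise 4C-vs-rest Wilcoxon rank-sum tests, and the Fano-factor vs
#' decoding-accuracy correlation.
#'
#' @param metrics [neuronMetrics()] table with a `compartment` column.
#' @param decodeResults Optional tidy results from [decodeSession()].
#' @param metricNames Metric columns to compare across compartments.
#' @return list with `omnibus`, `pairwise4C`, `ffAccuracy` (or NULL).
#' @export
laminarStatsReport <- function(metrics, decodeResults = NULL,
                               metricNames = c("maxRate", "modulationRatio",
                                               "di", "oi", "bandwidth",
                                               "fano")) {
  metrics <- metrics[metrics$responsive & metrics$compartment %in%
                       compartmentLabels(), , drop = FALSE]
  omnibus <- lapply(metricNames, function(m)
    tryCatch(compartmentCompare(metrics[[m]], metrics$compartment),
             error = function(e) NULL))
  names(omnibus) <- metricNames
  pairwise4C <- lapply(metricNames, function(m) {
    v4 <- metrics[[m]][metrics$compartment == "4C"]
    vo <- metrics[[m]][metrics$compartment != "4C"]
    v4 <- v4[is.finite(v4)]; vo <- vo[is.finite(vo)]
    if (length(v4) < 2 || length(vo) < 2) return(NULL)
    pairwiseCompare(v4, vo)
  })
  names(pairwise4C) <- metricNames
  ffAcc <- NULL
  if (!is.null(decodeResults)) {
    agg <- stats::aggregate(accuracy ~ subpop, decodeResults, mean)
    ffSub <- vapply(agg$subpop, function(s) {
      d <- decodeResults$centerDepth[decodeResults$subpop == s][1]
      # mean FF of the k nearest responsive neurons to the center depth
      mean(metrics$fano[order(abs(metrics$depth - d))[seq_len(min(10,
        nrow(metrics)))]], na.rm = TRUE)
    }, numeric(1))
    ffAcc <- tryCatch(ffPerformanceCorrelation(ffSub, agg$accuracy),
                      error = function(e) NULL)
  }
  list(omnibus = omnibus, pairwise4C = pairwise4C, ffAccuracy = ffAcc)
}
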