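#' Two-sample proportion z-test (pooled)
#'
#' Tests whether the proportion of cell couples showing a pattern differs
#' between two samples: `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the
#' pooled proportion `p = (x1 + x2)/(n1 + n2)`; two-sided p-value from the
#' normal distribution.
#'
#' @param x1,n1 successes and size of sample 1.
#' @param x2,n2 successes and size of sample 2.
#' @return object of class `stat_result` with `statistic`, `p`, `n`, `test`.
#' @export
proportion_ztest <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stopf("sample sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stopf("need 0 <= x <= n")
  p_pool <- (x1 + x2) / (n1 + n2)
  if (p_pool <= 0 || p_pool >= 1)
    stopf("z undefined: pooled proportion is %g", p_pool)
  z <- (x1 / n1 - x2 / n2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  structure(list(statistic = z, p = 2 * stats::pnorm(-abs(z)),
                 n = c(n1 = n1, n2 = n2), test = "two-sample proportion z"),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector.
#' @return list with `mean`, `sem` (sd with n-1 denominator over sqrt(n)),
#'   `n`.
#' @export
mean_sem <- function(values) {
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_, n = n)
}

#' Hierarchical clustering of sensors by occurrence timecourses
#'
#' Average-linkage clustering of sensors over their concatenated
#' pattern-occurrence vectors, with correlation distance
#' `d = 1 - Pearson(r)`. Ties are resolved deterministically by input order
#' (stats::hclust).
#'
#' @param occurrence_matrix numeric matrix, one row per sensor (rows are the
#'   concatenated per-pattern occurrence timecourses).
#' @return an [stats::hclust] object; leaf order in `$order`.
#' @export
cluster_timecourses <- function(occurrence_matrix) {
  m <- as.matrix(occurrence_matrix)
  if (nrow(m) < 2) stopf("need at least two sensors")
  d <- stats::as.dist(1 - stats::cor(t(m)))
  stats::hclust(d, method = "average")
}

#' Sensors with lamellal patterning as the dominant pattern
#'
#' A sensor counts as lamellal-dominant if, at one or more timepoints, the
#' lamellal pattern is the modal (most frequent) pattern among its cell
#' couples; alternatively (`mode = "threshold"`) if lamellal occurrence
#' reaches `threshold_pct` at some timepoint.
#'
#' @param occurrences list of [occurrence_table()] objects, one per sensor.
#' @param mode `"modal"` (default) or `"threshold"`.
#' @param threshold_pct occurrence threshold for the threshold mode.
#' @param pattern pattern of interest (default `"lamellum"`).
#' @return list with `count`, `total`, `percent` (rounded to integer).
#' @export
lamellal_dominance_summary <- function(occurrences, mode = c("modal",
                                       "threshold"), threshold_pct = 28,
                                       pattern = "lamellum") {
  mode <- match.arg(mode)
  dominant <- vapply(occurrences, function(occ) {
    scored <- rownames(occ) != "none"
    hit <- vapply(seq_len(ncol(occ)), function(j) {
      col <- occ[scored, j]
      if (mode == "modal") {
        max(col) > 0 && rownames(occ)[scored][which.max(col)] == pattern
      } else {
        occ[pattern, j] >= threshold_pct
      }
    }, TRUE)
    any(hit)
  }, TRUE)
  count <- sum(dominant)
  total <- length(dominant)
  list(count = count, total = total,
       percent = as.integer(round(100 * count / total)))
}
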