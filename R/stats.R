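#' Two-sided Mann-Whitney U test
#'
#' Nonparametric comparison of two groups, the test used for all EAE vs
#' control contrasts. The p-value is exact (full null distribution over rank
#' partitions) when the combined sample size is at most 14 and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is used. The method actually applied is recorded in the
#' result.
#'
#' @param a,b numeric samples (both non-empty).
#' @return a `stat_result` list: `statistic` (U, for the first sample),
#'   `p_value`, `n` (per-group sizes), `method`
#'   (`"mann_whitney_exact"` or `"mann_whitney_normal"`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value   # 0.1
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    # fully tied data carry no evidence; the normal approximation is 0/0 here
    return(structure(list(statistic = length(a) * length(b) / 2, p_value = 1,
                          n = c(n_a = length(a), n_b = length(b)),
                          method = "mann_whitney_normal"),
                     class = "stat_result"))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 14L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = min(wt$p.value, 1),
                 n = c(n_a = length(a), n_b = length(b)),
                 method = if (exact) "mann_whitney_exact" else "mann_whitney_normal"),
            class = "stat_result")
}

#' Spearman rank correlation
#'
#' Tie-aware rank correlation: Pearson correlation of average ranks, with a
#' two-sided p-value from the t approximation (recorded as approximate).
#' Used for clinical-score and SUVR vs SPIO-Vol correlations pooling both
#' groups.
#'
#' @param x,y numeric vectors of equal length (n >= 3); a constant input
#'   makes the correlation undefined and is returned flagged rather than as
#'   an error value.
#' @return a `stat_result` list: `statistic` (rho), `p_value`, `n`, `method`
#'   = `"spearman"`, `flagged`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("spearman correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(statistic = NA_real_, p_value = NA_real_, n = n,
                          method = "spearman", flagged = TRUE),
                     class = "stat_result"))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  structure(list(statistic = rho, p_value = min(max(p, .Machine$double.xmin), 1),
                 n = n, method = "spearman", flagged = FALSE),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g, n = %s\n",
              x$method, x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}
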