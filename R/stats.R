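## Descriptive statistics, Wilcoxon signed-rank, 2x2 chi-square.

#' Descriptive summary with optional per-newborn aggregation
#'
#' For parameters with repeated observations per newborn (for example one
#' value per suction event), each newborn is first reduced to the mean of
#' its own observations and the summary is computed over those per-newborn
#' means, so that newborns with many events do not dominate. Quartiles use
#' linear interpolation (the type-7 convention).
#'
#' @param values Numeric vector.
#' @param repeated_by_id Optional vector of newborn ids, same length as
#'   `values`; `NULL` summarizes the values directly.
#' @return A one-row `data.frame`: `n`, `mean`, `sd`, `median`, `q1`, `q3`.
#' @export
#' @examples
#' summarize_repeated(c(10, 20, 30), c("A", "A", "B"))  # means 15, 30
summarize_repeated <- function(values, repeated_by_id = NULL) {
  if (!length(values)) stop("summarize_repeated: empty input")
  if (!is.null(repeated_by_id)) {
    if (length(repeated_by_id) != length(values))
      stop("repeated_by_id must match values in length")
    values <- as.numeric(tapply(values, repeated_by_id, mean, na.rm = TRUE))
  }
  values <- values[!is.na(values)]
  if (!length(values)) stop("summarize_repeated: no non-missing values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(values), mean = mean(values),
             sd = if (length(values) > 1L) stats::sd(values) else 0,
             median = q[2], q1 = q[1], q3 = q[3])
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided test of symmetry of `x` about `mu0`. Values equal to `mu0` are
#' discarded (classic treatment). With 20 or fewer non-zero differences and
#' no ties among their absolute values, the exact signed-rank null
#' distribution is used; otherwise the normal approximation with midranks,
#' tie correction and continuity correction.
#'
#' @param x Numeric vector.
#' @param mu0 Hypothesized centre (default 0).
#' @param force_approx Logical; force the normal approximation (used to
#'   compare the two paths).
#' @return A list: `statistic` (V, the sum of positive ranks), `n` (after
#'   discarding zeros), `p` (two-sided), `method` (`"exact"` or
#'   `"approximation"`).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6))$p  # 0.0625
wilcoxon_signed_rank <- function(x, mu0 = 0, force_approx = FALSE) {
  d <- x[!is.na(x)] - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all values equal mu0; p = 1")
    return(list(statistic = 0, n = 0L, p = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))

  if (!force_approx && n <= 20L && !ties) {
    p <- 2 * min(stats::psignrank(v, n),
                 stats::psignrank(v - 1, n, lower.tail = FALSE))
    p <- min(p, 1)
    return(list(statistic = v, n = n, p = p, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  cc <- sign(v - mu) * 0.5
  z <- (v - mu - cc) / sqrt(sigma2)
  p <- min(2 * stats::pnorm(-abs(z)), 1)
  list(statistic = v, n = n, p = p, method = "approximation")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction, df = 1. This is the
#' variant whose p-values match the published mortality comparisons (with
#' the Yates correction both are larger). Requires all margins positive;
#' a zero margin raises an error suggesting an exact test.
#'
#' @param table 2x2 non-negative integer matrix (rows: exposure, columns:
#'   outcome).
#' @return A list: `statistic`, `df` (1), `p`.
#' @export
#' @examples
#' chi2_2x2(matrix(c(9, 11, 5, 29), 2))$p  # ~0.014
chi2_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("chi2_2x2 requires a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: chi-square undefined, consider an exact test")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1L, p = unname(ct$p.value))
}

#' Cohort-flow percentages
#'
#' From the screening counts of a delivery cohort, computes the number of
#' liveborn newborns at or above the gestational-age cutoff and the
#' percentages of liveborns who were stabilized, suctioned and ventilated,
#' each reported to one decimal place.
#'
#' @param births Total births in the period.
#' @param ga_ge34 Births with recorded gestational age >= 34 weeks.
#' @param stillborn Stillbirths among those.
#' @param stabilized,suctioned,ventilated Counts of liveborns receiving each
#'   intervention.
#' @return A list: `liveborn`, `stabilized_pct`, `suctioned_pct`,
#'   `ventilated_pct`.
#' @export
#' @examples
#' cohort_flow(12803, 11648, 236, 2300, 2178, 771)
cohort_flow <- function(births, ga_ge34, stillborn, stabilized, suctioned,
                        ventilated) {
  counts <- c(births, ga_ge34, stillborn, stabilized, suctioned, ventilated)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (stillborn > ga_ge34) stop("stillborn cannot exceed ga_ge34")
  liveborn <- ga_ge34 - stillborn
  if (liveborn == 0) stop("no liveborn newborns: percentages undefined")
  pct <- function(x) round(100 * x / liveborn, 1)
  list(liveborn = liveborn,
       stabilized_pct = pct(stabilized),
       suctioned_pct = pct(suctioned),
       ventilated_pct = pct(ventilated))
}
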