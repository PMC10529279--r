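## Restricted-cubic-spline logistic regression with cluster-robust
## (sandwich) covariance, Wald tests, odds ratios and predicted-probability
## curves. Point estimates come from standard IRLS (stats::glm.fit); the
## cluster sandwich is computed here because the covariance convention
## (G/(G-1) small-sample factor, no residual df adjustment) is part of the
## method.

#' Restricted cubic spline basis with three knots
#'
#' Returns the two-column basis of a restricted (natural) cubic spline with
#' knots `t1 < t2 < t3`: column 1 is `x` itself and column 2 the nonlinear
#' term
#' \deqn{R(x) = \frac{(x-t_1)_+^3 - (x-t_2)_+^3 (t_3-t_1)/(t_3-t_2) +
#'   (x-t_3)_+^3 (t_2-t_1)/(t_3-t_2)}{(t_3-t_1)^2},}
#' the truncated-power construction constrained to be linear beyond the
#' outer knots. Scaling by `(t3 - t1)^2` keeps both columns on the scale of
#' `x`.
#'
#' @param x Numeric vector.
#' @param knots Numeric vector of three strictly increasing knots.
#' @return Numeric matrix with columns `x` and `x_nl`.
#' @export
#' @examples
#' rcs_basis(3, knots = c(0, 1, 2))[, "x_nl"]  # 3: linear beyond t3
rcs_basis <- function(x, knots) {
  if (length(knots) != 3L) stop("exactly three knots required")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing (no duplicates)")
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  cube <- function(u) pmax(u, 0)^3
  nl <- (cube(x - t1) - cube(x - t2) * (t3 - t1) / (t3 - t2) +
           cube(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  cbind(x = x, x_nl = nl)
}

#' Default knot locations for a three-knot spline
#'
#' The 0.10 / 0.50 / 0.90 empirical quantiles (type 7), the common default
#' placement for three-knot restricted cubic splines.
#'
#' @param x Numeric vector with at least 10 distinct values.
#' @return Numeric vector of three knots.
#' @export
default_knots <- function(x) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 10L)
    stop("default_knots requires at least 10 distinct values")
  k <- stats::quantile(x, c(0.10, 0.50, 0.90), type = 7, names = FALSE)
  if (any(diff(k) <= 0))
    stop("degenerate knot placement: quantiles not distinct")
  k
}

#' Logistic regression with cluster-robust covariance
#'
#' Fits a binary logistic model by iteratively reweighted least squares and
#' replaces the model-based covariance with the cluster sandwich estimator
#' \deqn{V = A^{-1} B A^{-1}, \quad B = \frac{G}{G-1}\sum_g s_g s_g',}
#' where `A` is the observed information, `s_g` the summed score of cluster
#' `g`, and `G` the number of clusters. Observations from the same newborn
#' form a cluster, so repeated suction events within an infant may be
#' arbitrarily correlated. With one observation per cluster the estimator
#' reduces to the heteroskedasticity-robust (HC0) covariance times
#' `n/(n-1)`.
#'
#' @param y Binary response (0/1 or logical).
#' @param X Design matrix including the intercept column.
#' @param cluster_ids Cluster identifier per observation.
#' @return Object of class `ns_logit`: list with `coefficients`, `vcov`
#'   (cluster-robust), `vcov_model`, `n_obs`, `n_clusters`, `converged`,
#'   `fitted`, `X`, `y`, `cluster_ids`.
#' @export
fit_logit_cluster <- function(y, X, cluster_ids) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  if (length(unique(y)) < 2L)
    stop("y is constant: model is separated/degenerate")
  if (nrow(X) != length(y) || length(cluster_ids) != length(y))
    stop("y, X and cluster_ids must have matching lengths")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  G <- length(unique(cluster_ids))
  if (G < 2L) stop("at least 2 clusters required")

  fit <- suppressWarnings(  # separation is diagnosed explicitly below
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100)))
  beta <- fit$coefficients
  p <- fit$fitted.values
  if (!fit$converged || any(abs(beta) > 30) ||
      max(abs(crossprod(X, y - p))) > 1e-4 * max(1, nrow(X)))
    stop("logistic fit did not converge (possible perfect separation)")

  w <- p * (1 - p)
  A <- crossprod(X * w, X)
  scores <- X * (y - p)
  Sg <- rowsum(scores, group = as.character(cluster_ids))
  B <- crossprod(Sg) * G / (G - 1)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("b", seq_len(ncol(X)) - 1L)
  names(beta) <- cn
  dimnames(V) <- list(cn, cn)

  structure(list(coefficients = beta, vcov = V, vcov_model = Ainv,
                 n_obs = length(y), n_clusters = G, converged = TRUE,
                 fitted = p, X = X, y = y, cluster_ids = cluster_ids),
            class = "ns_logit")
}

#' @export
print.ns_logit <- function(x, ...) {
  cat(sprintf("<ns_logit> %d obs in %d clusters\n", x$n_obs, x$n_clusters))
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coefficients, robust_se = se,
                   z = x$coefficients / se))
  invisible(x)
}

#' Fit a three-knot spline logistic model for one continuous predictor
#'
#' Convenience wrapper: builds the design `(1, x, R(x))` with
#' [rcs_basis()] at [default_knots()] (or supplied knots) and fits
#' [fit_logit_cluster()]. The returned object carries the knots and the
#' observed range of `x` so that [probability_curve()] can rebuild the
#' basis and flag extrapolation.
#'
#' @param y Binary response.
#' @param x Continuous predictor.
#' @param cluster_ids Cluster identifier per observation.
#' @param knots Optional three knots; default from [default_knots()].
#' @return An `ns_logit` with elements `knots` and `x_range` added.
#' @export
fit_rcs_logit <- function(y, x, cluster_ids, knots = NULL) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]; cluster_ids <- cluster_ids[keep]
  if (is.null(knots)) knots <- default_knots(x)
  X <- cbind(`(Intercept)` = 1, rcs_basis(x, knots))
  fit <- fit_logit_cluster(y, X, cluster_ids)
  fit$knots <- knots
  fit$x_range <- range(x)
  fit
}

#' Wald test on a coefficient subset
#'
#' Quadratic-form Wald test `b' V^{-1} b` on the selected coefficients with
#' the cluster-robust covariance, referred to a chi-square distribution
#' with `df = length(subset)`. For a spline term, the subset of both spline
#' coefficients tests the overall effect and the nonlinear coefficient
#' alone tests nonlinearity; linearity is assumed when the nonlinearity
#' p-value exceeds 0.05.
#'
#' @param fit An `ns_logit`.
#' @param coefficient_subset Names or indices of coefficients to test.
#' @return A list: `statistic`, `df`, `p`.
#' @export
wald_test <- function(fit, coefficient_subset) {
  if (!length(coefficient_subset)) stop("empty coefficient subset")
  b <- fit$coefficients[coefficient_subset]
  V <- fit$vcov[coefficient_subset, coefficient_subset, drop = FALSE]
  if (any(is.na(b))) stop("subset includes unavailable coefficients")
  Vinv <- tryCatch(solve(V), error = function(e)
    stop("singular covariance for requested subset"))
  stat <- drop(t(b) %*% Vinv %*% b)
  df <- length(b)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Odds ratio with 95% confidence interval for a linear coefficient
#'
#' `OR = exp(beta * scale)` with `CI = exp((beta +/- 1.96 se) * scale)`
#' using the cluster-robust standard error. `scale` expresses the OR per so
#' many units (per 100 g birthweight, per 10 bpm, per 10 s, ...). Requesting
#' a spline nonlinear term is an error: a nonlinear effect has no single OR
#' and should be shown as a predicted-probability curve.
#'
#' @param fit An `ns_logit`.
#' @param coefficient Name or index of a linear (non-spline) coefficient.
#' @param unit_scale Units per reported OR (default 1).
#' @return A list: `or`, `ci_lo`, `ci_hi`, `scale`.
#' @export
odds_ratio <- function(fit, coefficient, unit_scale = 1) {
  nm <- if (is.numeric(coefficient)) names(fit$coefficients)[coefficient] else coefficient
  if (identical(nm, "x_nl"))
    stop("nonlinear spline term has no single odds ratio; use probability_curve()")
  b <- fit$coefficients[[nm]]
  se <- sqrt(fit$vcov[nm, nm])
  list(or = exp(b * unit_scale),
       ci_lo = exp((b - 1.96 * se) * unit_scale),
       ci_hi = exp((b + 1.96 * se) * unit_scale),
       scale = unit_scale)
}

#' Predicted-probability curve with 95% confidence band
#'
#' Pointwise inverse-logit of the linear predictor over a grid, with the
#' band obtained on the logit scale by the delta method using the
#' cluster-robust covariance (so the band always contains the point
#' estimate and stays inside `[0, 1]`). Grid points outside the observed
#' predictor range are computed but flagged as extrapolation.
#'
#' @param fit An `ns_logit` from [fit_rcs_logit()].
#' @param x_grid Numeric grid of predictor values.
#' @return `data.frame` with `x`, `p`, `lower`, `upper`, `extrapolated`.
#' @export
probability_curve <- function(fit, x_grid) {
  if (is.null(fit$knots))
    stop("probability_curve requires a fit from fit_rcs_logit()")
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  Xg <- cbind(1, rcs_basis(x_grid, fit$knots))
  eta <- drop(Xg %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((Xg %*% fit$vcov) * Xg), 0))
  inv_logit <- function(e) 1 / (1 + exp(-e))
  data.frame(
    x = x_grid,
    p = inv_logit(eta),
    lower = inv_logit(eta - 1.96 * se),
    upper = inv_logit(eta + 1.96 * se),
    extrapolated = x_grid < fit$x_range[1] | x_grid > fit$x_range[2]
  )
}
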