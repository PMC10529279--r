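test_that("restricted cubic spline basis follows the closed form", {
  k <- c(0, 1, 2)
  expect_equal(unname(rcs_basis(-1, k)[, "x_nl"]), 0)    # zero below the first knot
  expect_equal(unname(rcs_basis(0.5, k)[, "x_nl"]), (0.5^3) / 4)
  expect_equal(rcs_basis(c(3, 4, 5), k)[, "x_nl"], c(3, 4.5, 6))

  # linear beyond the outer knot: constant slope, zero curvature
  xs <- seq(2.5, 6, by = 0.25)
  nl <- rcs_basis(xs, k)[, "x_nl"]
  expect_equal(diff(diff(nl)), rep(0, length(xs) - 2), tolerance = 1e-12)

  expect_error(rcs_basis(1, c(0, 1, 1)), "strictly increasing")
  expect_error(rcs_basis(1, c(0, 1)), "three knots")
})

test_that("spline basis is twice continuously differentiable at the knots", {
  k <- c(10, 50, 90)
  h <- 1e-3
  d2 <- function(x) {
    f <- function(z) rcs_basis(z, k)[, "x_nl"]
    unname((f(x + h) - 2 * f(x) + f(x - h)) / h^2)
  }
  for (kn in k) {
    expect_lt(abs(d2(kn - 10 * h) - d2(kn + 10 * h)), 0.01)
  }
  # and zero curvature outside [t1, t3]
  expect_equal(d2(5), 0, tolerance = 1e-6)
  expect_equal(d2(95), 0, tolerance = 1e-4)
})

test_that("default knots sit at the 10/50/90 percent quantiles", {
  k <- default_knots(1:100)
  expect_equal(k, c(10.9, 50.5, 90.1))
  expect_equal(default_knots(c(1:10, 10:1))[2], 5.5)  # symmetric: median
  expect_error(default_knots(rep(3, 50)), "distinct")
})

test_that("cluster-robust logistic fit matches glm and the sandwich oracle", {
  set.seed(5)
  n <- 400
  cl <- rep(1:80, each = 5)
  x <- rnorm(n)
  u <- rnorm(80)[cl]
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x + u))
  X <- cbind(`(Intercept)` = 1, x = x)

  fit <- fit_logit_cluster(y, X, cl)
  ref <- glm(y ~ x, family = binomial)
  # clustering affects the covariance only, never the point estimates
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)

  V <- sandwich::vcovCL(ref, cluster = cl, type = "HC0", cadjust = TRUE)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-6)

  # one observation per cluster: sandwich reduces to HC0 times n/(n-1)
  fit_i <- fit_logit_cluster(y, X, seq_len(n))
  V_i <- sandwich::vcovHC(ref, type = "HC0") * n / (n - 1)
  expect_equal(unname(fit_i$vcov), unname(V_i), tolerance = 1e-6)
})

test_that("the fit recovers known coefficients and flags degeneracies", {
  set.seed(11)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * x))
  fit <- fit_logit_cluster(y, cbind(1, x = x), rep(1:200, each = 10))
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coefficients[[1]] - (-1)), 3 * se[1])
  expect_lt(abs(fit$coefficients[[2]] - 0.5), 3 * se[2])

  expect_error(fit_logit_cluster(rep(1, 50), cbind(1, rnorm(50)), rep(1:10, 5)),
               "constant")
  expect_error(fit_logit_cluster(rbinom(50, 1, 0.5), cbind(1, 1:50, 2 * (1:50)),
                                 rep(1:10, 5)), "rank deficient")
  # perfect separation
  xs <- c(rep(-1, 25), rep(1, 25))
  ys <- as.integer(xs > 0)
  expect_error(fit_logit_cluster(ys, cbind(1, xs), rep(1:25, 2)), "separation")
})

test_that("Wald tests behave at the null and under planted nonlinearity", {
  # hand-built fit with zero coefficients: statistic 0, p = 1
  fit0 <- structure(list(coefficients = c(a = 0, b = 0),
                         vcov = diag(2) * 0.1 + 0.01,
                         converged = TRUE), class = "ns_logit")
  dimnames(fit0$vcov) <- list(c("a", "b"), c("a", "b"))
  w0 <- wald_test(fit0, c("a", "b"))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)
  expect_error(wald_test(fit0, character(0)), "empty")

  # strong planted inverted-U: nonlinearity detected at n = 500
  set.seed(7)
  x <- runif(500, 50, 200)
  eta <- -3 + 4 * exp(-((x - 130) / 35)^2 / 2)
  y <- rbinom(500, 1, plogis(eta))
  fit <- fit_rcs_logit(y, x, cluster_ids = seq_along(y))
  expect_lt(wald_test(fit, "x_nl")$p, 0.01)
  expect_lt(wald_test(fit, c("x", "x_nl"))$p, 0.01)
})

test_that("odds ratios scale per unit and refuse spline terms", {
  fit <- structure(list(coefficients = c(`(Intercept)` = -1, x = 0.05, x_nl = 0.2),
                        vcov = diag(c(0.1, 1e-4, 1e-4)),
                        converged = TRUE), class = "ns_logit")
  nm <- c("(Intercept)", "x", "x_nl")
  dimnames(fit$vcov) <- list(nm, nm)
  o <- odds_ratio(fit, "x", unit_scale = 10)
  expect_equal(o$or, exp(0.5), tolerance = 1e-12)
  expect_true(o$ci_lo < o$or && o$or < o$ci_hi)
  expect_error(odds_ratio(fit, "x_nl"), "probability_curve")

  fit$coefficients[["x"]] <- 0
  o0 <- odds_ratio(fit, "x", unit_scale = 10)
  expect_equal(o0$or, 1)
  expect_true(o0$ci_lo <= 1 && 1 <= o0$ci_hi)
})

test_that("odds-ratio confidence intervals cover a known effect", {
  set.seed(31)
  covered <- 0L
  for (rep in 1:100) {
    n <- 300
    cl <- rep(1:60, each = 5)
    x <- rnorm(n, 0, 0.7)
    y <- rbinom(n, 1, plogis(-0.8 + log(2) * x))
    fit <- tryCatch(fit_logit_cluster(y, cbind(1, x = x), cl),
                    error = function(e) NULL)
    if (is.null(fit)) next
    o <- odds_ratio(fit, "x")
    if (o$ci_lo <= 2 && 2 <= o$ci_hi) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})

test_that("probability curves are proper and flag extrapolation", {
  # flat null curve at the implied prevalence
  fit0 <- structure(list(coefficients = c(`(Intercept)` = -1, x = 0, x_nl = 0),
                         vcov = diag(c(0.04, 0, 0)),
                         converged = TRUE, knots = c(10, 50, 90),
                         x_range = c(0, 100)), class = "ns_logit")
  nm <- c("(Intercept)", "x", "x_nl")
  dimnames(fit0$vcov) <- list(nm, nm)
  pc0 <- probability_curve(fit0, seq(0, 110, by = 10))
  expect_equal(pc0$p, rep(plogis(-1), nrow(pc0)))
  expect_true(all(pc0$lower <= pc0$p & pc0$p <= pc0$upper))
  expect_true(all(pc0$p >= 0 & pc0$upper <= 1 & pc0$lower >= 0))
  expect_true(pc0$extrapolated[nrow(pc0)])
  expect_false(any(pc0$extrapolated[-nrow(pc0)]))

  set.seed(13)
  x <- runif(400, 40, 220)
  y <- rbinom(400, 1, plogis(-2.5 + 3 * exp(-((x - 135) / 40)^2 / 2)))
  fit <- fit_rcs_logit(y, x, seq_along(x))
  pc <- probability_curve(fit, seq(40, 220, by = 1))
  expect_true(all(pc$lower <= pc$p & pc$p <= pc$upper))
  expect_true(all(pc$upper <= 1 & pc$lower >= 0))
})
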