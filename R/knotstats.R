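#' Binomial unknot-probability estimate with Wilson interval
#'
#' Point estimate `unknot_count / trials` with the Wilson 95% score
#' interval, which behaves sensibly at the boundaries (p near 0 or 1)
#' where the Wald interval fails.
#'
#' @param trials number of classified conformations (>= 1).
#' @param unknot_count number called trivially knotted.
#' @param conf confidence level (default 0.95).
#' @return list with `p0_hat`, `ci_low`, `ci_high`.
#' @export
estimate_p0 <- function(trials, unknot_count, conf = 0.95) {
  if (any(trials < 1)) stop("trials must be >= 1")
  if (any(unknot_count < 0) || any(unknot_count > trials))
    stop("unknot_count must lie in [0, trials]")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- unknot_count / trials
  den <- 1 + z^2 / trials
  ctr <- (p + z^2 / (2 * trials)) / den
  hw <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / den
  list(p0_hat = p, ci_low = pmax(0, ctr - hw), ci_high = pmin(1, ctr + hw))
}

#' Assemble a knotting curve from per-N Monte-Carlo counts
#'
#' A knotting curve records, for each chain length `N`, the number of
#' classified conformations and how many were unknotted, together with
#' the Wilson-interval estimate of the unknot probability `P0(N)`.
#'
#' @param N vector of chain lengths.
#' @param trials trials per length.
#' @param unknot_count unknotted calls per length.
#' @param d_f,d,seed provenance metadata.
#' @return object of class `"knotting_curve"` (a data.frame with columns
#'   `N`, `trials`, `unknot`, `p0`, `ci_low`, `ci_high` and metadata
#'   attributes).
#' @export
knotting_curve <- function(N, trials, unknot_count, d_f = NA_real_,
                           d = NA_integer_, seed = NA_integer_) {
  stopifnot(length(N) == length(trials), length(N) == length(unknot_count))
  if (anyDuplicated(N)) stop("duplicate N values in knotting curve")
  est <- estimate_p0(trials, unknot_count)
  df <- data.frame(N = N, trials = trials, unknot = unknot_count,
                   p0 = est$p0_hat, ci_low = est$ci_low, ci_high = est$ci_high)
  df <- df[order(df$N), ]
  rownames(df) <- NULL
  structure(df, class = c("knotting_curve", "data.frame"),
            d_f = d_f, d = d, seed = seed)
}

#' @export
print.knotting_curve <- function(x, ...) {
  cat(sprintf("Knotting curve (d_f = %s, d = %s, seed = %s)\n",
              format(attr(x, "d_f")), format(attr(x, "d")),
              format(attr(x, "seed"))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Synthetic Bernoulli knotting curve
#'
#' Draws binomial unknot counts from the exponential law
#' `p0(N) = min(1, C exp(-N / N0_true))`, the fixture used to validate
#' the exponential fitting machinery with a known ground truth.
#'
#' @param N0_true true knotting length (> 0).
#' @param N_grid chain lengths.
#' @param trials trials per length (recycled).
#' @param seed RNG seed.
#' @param C prefactor (default 1).
#' @return a `"knotting_curve"`.
#' @export
generate_bernoulli_curve <- function(N0_true, N_grid, trials, seed = NULL,
                                     C = 1) {
  stopifnot(N0_true > 0)
  trials <- rep_len(trials, length(N_grid))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  p0 <- pmin(1, C * exp(-N_grid / N0_true))
  k <- stats::rbinom(length(N_grid), trials, p0)
  knotting_curve(N_grid, trials, k, seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Fit the exponential unknotting law to a knotting curve
#'
#' The unknot probability of a self-similar ring polymer decays as
#' `P0(N) = C exp(-N / N0)`; `ln P0` is fitted against `N` by weighted
#' least squares with delta-method weights `trials * p0 / (1 - p0)`
#' (the inverse variance of `ln p0_hat`), giving the knotting length
#' `N0 = -1/slope` and `mu = ln N0`. The law is asymptotic in `N`, so
#' saturated points carry no slope information and are excluded from the
#' fit window: points with `p0 >= p_max` (default 0.99), `p0 <= p_min`
#' (default 0.01, which also removes `unknot == 0` points whose log is
#' undefined), and `N` below `n_min` (default 30, five times the trefoil
#' stick number, below which no chain is fractal in any meaningful
#' sense).
#'
#' @param curve a `"knotting_curve"`.
#' @param p_min,p_max fit-window probability floor and ceiling.
#' @param n_min smallest usable chain length.
#' @return object of class `"knot_expfit"`: list with `N0`, `mu`,
#'   `mu_stderr`, `N0_stderr`, `prefactor` (fitted `C`), `cov`
#'   (parameter covariance of intercept and slope), `chi2_red`,
#'   `window` (logical vector of used points), `curve`.
#' @export
fit_exponential <- function(curve, p_min = 0.01, p_max = 0.99, n_min = 30) {
  stopifnot(inherits(curve, "knotting_curve"))
  use <- curve$p0 > p_min & curve$p0 < p_max & curve$N >= n_min &
    curve$unknot > 0
  if (sum(use) < 3)
    stop(errorCondition("fewer than 3 usable points in the fit window",
                        class = c("ringknots_fit_insufficient", "error", "condition")))
  N <- curve$N[use]
  y <- log(curve$p0[use])
  w <- curve$trials[use] * curve$p0[use] / (1 - curve$p0[use])
  fit <- stats::lm(y ~ N, weights = w)
  beta <- stats::coef(fit)
  if (beta[2] >= 0)
    stop(errorCondition("non-negative slope: P0 does not decay over the fit window",
                        class = c("ringknots_fit_degenerate", "error", "condition")))
  N0 <- -1 / beta[2]
  # binomial errors are known, so the parameter covariance uses dispersion
  # fixed at 1 rather than the 2-dof residual estimate; when the residuals
  # overdisperse (physical curvature beyond the asymptotic law) the larger
  # empirical dispersion is kept — never claim better than the data allow
  chi2_red <- sum(w * stats::residuals(fit)^2) / (sum(use) - 2)
  X <- cbind(1, N)
  V <- solve(crossprod(X * sqrt(w))) * max(1, chi2_red)
  se_slope <- sqrt(V[2, 2])
  mu <- log(N0)
  structure(
    list(N0 = unname(N0), mu = unname(mu),
         mu_stderr = unname(se_slope / abs(beta[2])),
         N0_stderr = unname(se_slope * N0^2),
         prefactor = unname(exp(beta[1])),
         cov = V,
         chi2_red = chi2_red,
         window = use, n_used = sum(use),
         d_f = attr(curve, "d_f"),
         curve = curve),
    class = "knot_expfit")
}

#' @export
print.knot_expfit <- function(x, ...) {
  cat(sprintf("Exponential unknotting fit%s: N0 = %.4g +- %.2g (mu = %.4g +- %.2g)\n",
              if (is.na(x$d_f)) "" else sprintf(" (d_f = %.4g)", x$d_f),
              x$N0, x$N0_stderr, x$mu, x$mu_stderr))
  cat(sprintf("  prefactor C = %.4g, reduced chi^2 = %.3g over %d points\n",
              x$prefactor, x$chi2_red, x$n_used))
  invisible(x)
}

#' @export
summary.knot_expfit <- function(object, ...) {
  print(object)
  cat("Fit window:\n")
  print.data.frame(object$curve[object$window, ])
  invisible(object)
}

#' @export
coef.knot_expfit <- function(object, ...) {
  c(N0 = object$N0, mu = object$mu, prefactor = object$prefactor)
}

#' @export
predict.knot_expfit <- function(object, N, ...) {
  pmin(1, object$prefactor * exp(-N / object$N0))
}

#' @export
plot.knot_expfit <- function(x, ...) {
  cv <- x$curve
  plot(cv$N, cv$p0, log = "y", xlab = "N", ylab = "P0(N)",
       pch = ifelse(x$window, 19, 1), ...)
  grid_N <- seq(min(cv$N), max(cv$N), length.out = 200)
  graphics::lines(grid_N, predict(x, grid_N))
  invisible(x)
}

#' Collect knotting lengths into a mu(d_f) curve
#'
#' @param fits list of `"knot_expfit"` objects; fractal dimensions are
#'   taken from the fits (or from `names(fits)` when absent there).
#' @return object of class `"mu_curve"`: data.frame with columns `d_f`,
#'   `mu`, `mu_stderr`, `N0`, sorted by `d_f`, one row per fractal
#'   dimension.
#' @export
build_mu_curve <- function(fits) {
  stopifnot(length(fits) >= 1)
  d_f <- vapply(seq_along(fits), function(i) {
    v <- fits[[i]]$d_f
    if (is.null(v) || is.na(v)) as.numeric(names(fits)[i]) else v
  }, numeric(1))
  if (any(is.na(d_f))) stop("fractal dimension missing from fits and names")
  if (anyDuplicated(d_f)) stop("duplicate fractal dimensions")
  if (length(fits) < 4) warning("fewer than 4 fractal dimensions; mu-curve fits will be fragile")
  df <- data.frame(
    d_f = d_f,
    mu = vapply(fits, function(f) f$mu, numeric(1)),
    mu_stderr = vapply(fits, function(f) f$mu_stderr, numeric(1)),
    N0 = vapply(fits, function(f) f$N0, numeric(1)))
  df <- df[order(df$d_f), ]
  rownames(df) <- NULL
  structure(df, class = c("mu_curve", "data.frame"))
}

#' @export
print.mu_curve <- function(x, ...) {
  cat("Knotting length vs fractal dimension (mu = ln N0):\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Wald-Wolfowitz runs test on residual signs (normal approximation)
runs_test <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(list(runs = 1, p_value = 2 / choose(n1 + n2, min(1, n1 + n2))))
  r <- 1 + sum(diff(s) != 0)
  mu <- 1 + 2 * n1 * n2 / (n1 + n2)
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  z <- (r - mu) / sqrt(v)
  list(runs = r, p_value = 2 * stats::pnorm(-abs(z)))
}

# small-sample-corrected information criterion from weighted RSS
aicc_from_fit <- function(chi2, n, k) {
  n * log(chi2 / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-12)
}

#' Fit competing functional forms to a mu(d_f) curve
#'
#' Weighted nonlinear least squares of `mu` against `d_f` under one of
#' two models: the `"double_exponential"` law
#' `mu = c1 exp(c2 d_f) + c3` predicted by the analytical theory (the
#' knotting length itself then depends double-exponentially on `d_f`),
#' or the `"logarithmic"` scaling form `mu = c1 ln(d_f + c2) + c3`.
#'
#' For either model, fixing `c2` makes the remaining parameters linear,
#' so fitting proceeds by profiling: a deterministic grid of 16 `c2`
#' starts, each solved by weighted linear least squares and then polished
#' by full Levenberg-Marquardt (`minpack.lm::nlsLM`); the best converged
#' start by objective wins, ties broken by smallest `|c2|`.
#' Non-convergence of every start is an error, never silent. Model
#' comparison uses the small-sample-corrected information criterion
#' (AICc, computed from the weighted residual sum of squares) plus a
#' Wald-Wolfowitz runs test for structured residuals.
#'
#' @param curve a `"mu_curve"` with at least 4 points.
#' @param model `"double_exponential"` or `"logarithmic"`.
#' @param weighted use inverse-variance weights from `mu_stderr`
#'   (default `TRUE`); otherwise unweighted.
#' @return object of class `"knot_mufit"`: list with `model`,
#'   `coefficients` (c1, c2, c3), `residuals`, `chi2`, `aicc`,
#'   `runs_test`, `curve`.
#' @export
fit_mu <- function(curve, model = c("double_exponential", "logarithmic"),
                   weighted = TRUE) {
  stopifnot(inherits(curve, "mu_curve"))
  model <- match.arg(model)
  if (nrow(curve) < 4) stop("need at least 4 points to fit a 3-parameter law")
  if (any(!is.finite(curve$mu)) ||
      (weighted && any(!is.finite(curve$mu_stderr))))
    stop("non-finite mu values or errors")
  x <- curve$d_f
  y <- curve$mu
  w <- if (weighted) 1 / pmax(curve$mu_stderr, 1e-8)^2 else rep(1, length(y))
  basis <- switch(model,
    double_exponential = function(c2) exp(c2 * x),
    logarithmic = function(c2) log(x + c2))
  c2_starts <- switch(model,
    double_exponential = c(-4, -3, -2.5, -2, -1.6, -1.3, -1, -0.8, -0.6,
                           -0.45, -0.3, -0.2, -0.12, -0.07, -0.04, -0.02),
    logarithmic = {
      lo <- -min(x)
      lo + c(0.01, 0.05, 0.1, 0.2, 0.35, 0.5, 0.75, 1, 1.5, 2, 3, 5, 8,
             12, 20, 50)
    })
  profile_obj <- function(c2) {
    b <- basis(c2)
    if (any(!is.finite(b))) return(list(obj = Inf))
    fit <- stats::lm(y ~ b, weights = w)
    cf <- stats::coef(fit)
    list(obj = sum(w * stats::residuals(fit)^2),
         c1 = unname(cf[2]), c3 = unname(cf[1]))
  }
  form <- switch(model,
    double_exponential = y ~ c1 * exp(c2 * x) + c3,
    logarithmic = y ~ c1 * log(x + c2) + c3)
  best <- NULL
  for (c2 in c2_starts) {
    pr <- profile_obj(c2)
    if (!is.finite(pr$obj)) next
    polished <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(form, data = data.frame(x = x, y = y),
                          start = list(c1 = pr$c1, c2 = c2, c3 = pr$c3),
                          weights = w,
                          control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(polished)) next
    cf <- stats::coef(polished)
    if (model == "logarithmic" && min(x) + cf["c2"] <= 0) next
    obj <- sum(w * stats::residuals(polished)^2)
    if (is.null(best) || obj < best$obj - 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 && abs(cf["c2"]) < abs(best$coefficients["c2"]))) {
      best <- list(obj = obj, coefficients = cf,
                   residuals = as.numeric(stats::residuals(polished)))
    }
  }
  if (is.null(best))
    stop(errorCondition(
      sprintf("no start converged for the %s model", model),
      class = c("ringknots_fit_nonconvergence", "error", "condition")))
  n <- length(y)
  structure(
    list(model = model,
         coefficients = best$coefficients,
         residuals = best$residuals,
         chi2 = best$obj,
         aicc = aicc_from_fit(best$obj, n, 3L),
         runs_test = runs_test(best$residuals),
         weighted = weighted,
         curve = curve),
    class = "knot_mufit")
}

#' @export
print.knot_mufit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("mu(d_f) fit, model = %s%s\n", x$model,
              if (x$weighted) " (weighted)" else ""))
  cat(sprintf("  c1 = %.5g, c2 = %.5g, c3 = %.5g\n", cf["c1"], cf["c2"], cf["c3"]))
  cat(sprintf("  weighted RSS = %.4g, AICc = %.4g, runs-test p = %.3g\n",
              x$chi2, x$aicc, x$runs_test$p_value))
  if (x$model == "double_exponential")
    cat(sprintf("  implied large-d_f limit: N0 -> %.4g\n", exp(cf["c3"])))
  invisible(x)
}

#' @export
coef.knot_mufit <- function(object, ...) object$coefficients

#' @export
residuals.knot_mufit <- function(object, ...) object$residuals

#' @export
predict.knot_mufit <- function(object, d_f = NULL, ...) {
  if (is.null(d_f)) d_f <- object$curve$d_f
  cf <- object$coefficients
  switch(object$model,
    double_exponential = mu_closed_form(d_f, cf["c1"], cf["c2"], cf["c3"]),
    logarithmic = mu_log_form(d_f, cf["c1"], cf["c2"], cf["c3"]))
}

#' @export
plot.knot_mufit <- function(x, ...) {
  cv <- x$curve
  plot(cv$d_f, cv$mu, xlab = "d_f", ylab = "mu = ln N0", pch = 19, ...)
  graphics::arrows(cv$d_f, cv$mu - cv$mu_stderr, cv$d_f, cv$mu + cv$mu_stderr,
                   length = 0.02, angle = 90, code = 3)
  g <- seq(min(cv$d_f), max(cv$d_f), length.out = 200)
  graphics::lines(g, predict(x, g))
  invisible(x)
}

#' Thermodynamic estimator of d mu / d d_f from mode amplitudes
#'
#' The derivative of the log unknot probability with respect to the
#' spectral exponent follows from differentiating the constrained and
#' unconstrained partition functions:
#' \deqn{\frac{d \ln P_0}{d \chi} = \tfrac12 \sum_{q=1}^{N-1}
#'   \frac{\partial \lambda_q}{\partial \chi}
#'   \left[\langle |X_q|^2\rangle - \langle |X_q|^2\rangle_0 \right],}
#' with `d/dchi lambda_q = lambda_q ln sin(pi q / N)`; equipartition gives
#' the unconstrained average exactly, `d / lambda_q` per mode, while the
#' constrained (unknotted-subset) average is measured from the sampled
#' mode amplitudes. The identity is exact at every `N`. Conversion to
#' `d mu / d d_f` uses the exponential law (`d ln P0 / d mu = N / N0`,
#' neglecting the prefactor's drift, which is why the estimate approaches
#' the numerical derivative of the mu-curve from below as `N` grows) and
#' the chain rule `d chi / d d_f = -2 / d_f^2`.
#'
#' @param conformations list of classified conformations (or batch
#'   matrix) sampled from `spectrum`.
#' @param spectrum the `"mode_spectrum"` they were drawn from.
#' @param unknotted logical vector: the trivial/nontrivial call per
#'   conformation. Must contain both classes unless `constrained = FALSE`.
#' @param N0 knotting length used in the `ln P0 -> mu` conversion
#'   (typically from [fit_exponential()] at the same `d_f`).
#' @param constrained with `FALSE`, every sample is treated as unknotted
#'   (constraint disabled); the estimator is then zero within Monte-Carlo
#'   error, a built-in consistency check.
#' @return list with `dmu_dd_f`, `stderr`, `dlnP0_dchi` and its
#'   `dlnP0_stderr`, and `n_unknotted`.
#' @export
derivative_estimator <- function(conformations, spectrum, unknotted, N0,
                                 constrained = TRUE) {
  stopifnot(inherits(spectrum, "mode_spectrum"), N0 > 0)
  R <- conformation_matrix(conformations)
  d <- attr(R, "d")
  n <- ncol(R) / d
  stopifnot(length(unknotted) == n)
  if (!constrained) unknotted <- rep(TRUE, n)
  if (all(unknotted) && constrained)
    stop("all samples unknotted: constrained ensemble equals the full sample")
  if (!any(unknotted))
    stop("no unknotted samples: constrained average undefined")
  N <- spectrum$N
  Z <- beta_forward_transform(R)
  # per-sample |X_q|^2 summed over the d components, per mode slot
  Z2 <- Z^2
  dim(Z2) <- c(N - 1L, d, n)
  amp2 <- apply(Z2, c(1, 3), sum)            # (N-1) x n
  q <- seq_len(N - 1L)
  dldchi <- spectrum$lambda * log(sin(pi * q / N))
  # per-sample statistic T_s = 1/2 sum_q dlambda/dchi * (d/lambda_q - |X_q|^2)
  Tconst <- 0.5 * sum(dldchi * spectrum$d / spectrum$lambda)
  Ts <- Tconst - 0.5 * colSums(dldchi * amp2)
  sel <- Ts[unknotted]
  est <- mean(sel)
  se <- stats::sd(sel) / sqrt(length(sel))
  conv <- (N0 / N) * (-2 / spectrum$d_f^2)
  list(dmu_dd_f = conv * est,
       stderr = abs(conv) * se,
       dlnP0_dchi = est, dlnP0_stderr = se,
       n_unknotted = sum(unknotted))
}
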