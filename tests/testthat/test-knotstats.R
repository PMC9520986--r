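test_that("Wilson estimates are correct at the center and the boundary", {
  e <- estimate_p0(1000, 900)
  expect_equal(e$p0_hat, 0.9)
  expect_gt(e$ci_low, 0.87)
  expect_lt(e$ci_high, 0.92)

  b <- estimate_p0(50, 50)
  expect_equal(b$p0_hat, 1)
  expect_equal(b$ci_high, 1)
  expect_lt(b$ci_low, 1)

  expect_error(estimate_p0(0, 0), ">= 1")
  expect_error(estimate_p0(10, 11), "unknot_count")
})

test_that("Wilson intervals achieve nominal coverage", {
  set.seed(1)
  k <- rbinom(1e4, 200, 0.3)
  est <- estimate_p0(rep(200, 1e4), k)
  cover <- mean(est$ci_low <= 0.3 & est$ci_high >= 0.3)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("exponential fits recover known knotting lengths", {
  # noiseless log-linear data: N0 recovered essentially exactly
  Ng <- seq(100, 600, by = 100)
  p0 <- exp(-Ng / 250)
  cv <- knotting_curve(Ng, rep(1e6, 6), round(p0 * 1e6))
  f <- fit_exponential(cv)
  expect_equal(f$N0, 250, tolerance = 1e-3)
  expect_equal(f$mu, log(f$N0))

  # Bernoulli curves: truth within 2 standard errors in >= 93/100 replicates
  hits <- 0L
  for (r in 1:100) {
    cvr <- generate_bernoulli_curve(250, Ng, 5000, seed = r)
    fr <- fit_exponential(cvr)
    if (abs(fr$N0 - 250) <= 2 * fr$N0_stderr) hits <- hits + 1L
  }
  expect_gte(hits, 93L)

  # growing curve is flagged as degenerate
  bad <- knotting_curve(Ng, rep(1000, 6), round(seq(100, 900, length.out = 6)))
  expect_error(fit_exponential(bad), class = "ringknots_fit_degenerate")

  # too few usable points
  tiny <- knotting_curve(c(100, 200), c(100, 100), c(90, 50))
  expect_error(fit_exponential(tiny), class = "ringknots_fit_insufficient")

  # saturated points are excluded from the window
  sat <- knotting_curve(c(20, 40, 100, 200, 300, 400), rep(1e4, 6),
                        c(1e4, 1e4, round(1e4 * exp(-c(100, 200, 300, 400) / 150))))
  fs <- fit_exponential(sat)
  expect_false(any(fs$curve$p0[fs$window] >= 0.99))
  expect_equal(fs$N0, 150, tolerance = 0.05)
})

test_that("mu curves assemble with propagated errors", {
  # identity: N0 = e^3 gives mu = 3
  Ng <- c(30, 40, 50, 60, 70)
  p0 <- exp(-Ng / exp(3))
  cv <- knotting_curve(Ng, rep(1e6, 5), round(p0 * 1e6), d_f = 2)
  f <- fit_exponential(cv)
  expect_warning(mc <- build_mu_curve(list(f)), "fewer than 4")
  expect_equal(mc$mu, 3, tolerance = 1e-3)

  # doubling trials shrinks the mu standard error by ~ sqrt(2)
  cv2 <- knotting_curve(Ng, rep(2e6, 5), round(p0 * 2e6), d_f = 2)
  f2 <- fit_exponential(cv2)
  expect_equal(f$mu_stderr / f2$mu_stderr, sqrt(2), tolerance = 0.05)

  # duplicate fractal dimensions rejected
  expect_error(build_mu_curve(list(f, f2)), "duplicate")
})

test_that("mu fits recover exact double-exponential parameters", {
  x <- c(1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5)
  truth <- c(c1 = 19.4, c2 = -1.138, c3 = 3.703)
  mc <- make_mu_curve(x, mu_closed_form(x, truth[1], truth[2], truth[3]), 0.01)
  mf <- fit_mu(mc, "double_exponential")
  expect_equal(unname(coef(mf)), unname(truth), tolerance = 1e-6)
  expect_equal(length(residuals(mf)), nrow(mc))
  expect_equal(unname(predict(mf, 3)),
               unname(mu_closed_form(3, truth[1], truth[2], truth[3])),
               tolerance = 1e-6)
})

test_that("model comparison separates the double-exponential from the logarithmic", {
  x <- seq(1.2, 5, length.out = 16)
  mu <- mu_closed_form(x, 19.4, -1.138, 3.703)
  set.seed(5)
  mc <- make_mu_curve(x, mu + rnorm(16, 0, 0.005), 0.005)
  fd <- fit_mu(mc, "double_exponential")
  fl <- fit_mu(mc, "logarithmic")
  expect_lt(fd$aicc, fl$aicc)
  # logarithmic fit leaves structured residuals on double-exponential data
  expect_lt(fl$runs_test$p_value, 0.05)
  expect_gt(fd$runs_test$p_value, 0.05)
})

test_that("bernoulli curve generator respects its contracts", {
  Ng <- c(50, 100, 200)
  # infinite-trials limit approaches the exact exponential
  cv <- generate_bernoulli_curve(100, Ng, 2e5, seed = 9)
  expect_equal(cv$p0, exp(-Ng / 100), tolerance = 0.02)
  # prefactor capped at one
  cvc <- generate_bernoulli_curve(100, Ng, 1000, seed = 9, C = 50)
  expect_true(all(cvc$p0 <= 1))
  # a single trial per point is valid (wide intervals, no error)
  cv1 <- generate_bernoulli_curve(100, Ng, 1, seed = 9)
  expect_true(all(cv1$ci_high - cv1$ci_low > 0.5))
  # determinism
  expect_identical(generate_bernoulli_curve(100, Ng, 50, seed = 4)$unknot,
                   generate_bernoulli_curve(100, Ng, 50, seed = 4)$unknot)
})

test_that("the thermodynamic derivative estimator obeys its identities", {
  sp <- build_spectrum(100, 2.5, 3)
  R <- ringknots:::sample_ring_matrix(sp, 6000, seed = 41)
  res <- ringknots:::classify_stack(R, 6000, seed = 42)

  # constraint disabled: the constrained ensemble equals the unconstrained
  # one and the estimator is zero within Monte-Carlo error
  off <- derivative_estimator(R, sp, res$trivial, N0 = 100, constrained = FALSE)
  expect_lt(abs(off$dlnP0_dchi / off$dlnP0_stderr), 4)

  # degenerate sample sets are rejected
  expect_error(derivative_estimator(R, sp, rep(TRUE, 6000), N0 = 100),
               "all samples unknotted")
  expect_error(derivative_estimator(R, sp, rep(FALSE, 6000), N0 = 100),
               "no unknotted samples")

  # independent oracle: central finite difference of ln P0 in chi itself
  h <- 0.03
  chi0 <- sp$chi
  p_of_chi <- function(chi, seed) {
    spx <- build_spectrum(100, 2 / (chi - 1), 3)
    Rx <- ringknots:::sample_ring_matrix(spx, 12000, seed = seed)
    mean(ringknots:::classify_stack(Rx, 12000, seed = seed + 1)$trivial)
  }
  pm <- p_of_chi(chi0 - h, 101)
  pp <- p_of_chi(chi0 + h, 102)
  fd <- (log(pp) - log(pm)) / (2 * h)
  se_fd <- sqrt((1 - pm) / (12000 * pm) + (1 - pp) / (12000 * pp)) / (2 * h)
  on <- derivative_estimator(R, sp, res$trivial, N0 = 100)
  expect_gt(on$dlnP0_dchi, 0)
  expect_lt(abs(on$dlnP0_dchi - fd),
            3 * sqrt(se_fd^2 + on$dlnP0_stderr^2))
})
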