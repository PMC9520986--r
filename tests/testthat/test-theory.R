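test_that("chi and the Flory gamma take their exact special values", {
  expect_equal(chi_of(2), 2)
  expect_equal(chi_of(3), 5/3)
  expect_lt(abs(chi_of(1e9) - 1), 1e-8)
  expect_error(chi_of(0), "positive")

  # Flory/chi crossing at d_f = 3/2 is exact
  expect_equal(as.numeric(gamma_flory(3/2, 3)), chi_of(3/2), tolerance = 1e-15)
  expect_equal(as.numeric(gamma_flory(3/2, 3)), 7/3, tolerance = 1e-15)
  # classical Flory value nu = 3/5 at d_f = 2: gamma = 1 + 2 nu = 11/5
  expect_equal(as.numeric(gamma_flory(2, 3)), 11/5, tolerance = 1e-15)

  # gamma >= chi wherever excluded volume can only swell the chain
  grid <- seq(1.5, 8, by = 0.01)
  expect_true(all(as.numeric(gamma_flory(grid, 3)) >= chi_of(grid) - 1e-12))
  expect_true(all(as.numeric(gamma_flory(grid[-1], 3)) > chi_of(grid[-1])))

  # trusted-range flag, not refusal, below d_f = 1.7
  g <- gamma_flory(1.3, 3)
  expect_true(attr(g, "extrapolated"))
  expect_false(attr(gamma_flory(2.5, 3), "extrapolated"))
  expect_error(gamma_flory(0.9, 3), "> 1")
  expect_error(gamma_flory(2, 5), "2 or 3")
})

test_that("f1 and f2 match their defining integrals and printed constants", {
  # independent check of the closed forms against numerical quadrature:
  # A(delta) = int_0^1 ln(u) (1 - u^-delta) du, B(delta) = int_0^1 (1 - u^-delta) du
  for (df in c(2, 3, 4.5)) {
    delta <- as.numeric(gamma_flory(df, 3)) - chi_of(df)
    A_num <- integrate(function(u) log(u) * (1 - u^(-delta)), 0, 1,
                       rel.tol = 1e-10)$value
    B_num <- integrate(function(u) 1 - u^(-delta), 0, 1,
                       rel.tol = 1e-10)$value
    ff <- f_functions(df)
    expect_equal(ff$f1, B_num / df^2, tolerance = 1e-7)
    expect_equal(ff$f2, -(A_num + B_num * log(pi / 2)) / df^2,
                 tolerance = 1e-7)
  }

  # both vanish continuously at the Flory/chi crossing
  ffc <- f_functions(3/2)
  expect_equal(ffc$f1, 0, tolerance = 1e-12)
  expect_equal(ffc$f2, 0, tolerance = 1e-12)

  # roughly constant over the trusted grid
  tab <- representative_constants()$table
  expect_lt(max(tab$f1) / min(tab$f1), 1.7)
  expect_lt(max(tab$c3) / min(tab$c3), 1.7)

  expect_warning(f_functions(1.05), "treated range")
})

test_that("the two-regime amplitude model is continuous and collapses at delta = 0", {
  set.seed(6)
  for (r in 1:100) {
    N <- sample(50:2000, 1)
    N0 <- runif(1, 5, N / 4)
    df <- runif(1, 1.5, 5)
    tp <- theory_params(df, 3)
    qc <- N / (2 * N0)
    if (qc > N / 2) next
    lo <- mode_amplitude_model(qc * (1 - 1e-12), N, N0, tp)
    hi <- mode_amplitude_model(min(qc * (1 + 1e-12), N / 2), N, N0, tp)
    expect_equal(lo, hi, tolerance = 1e-9)
  }

  # far above the crossover the unconstrained spectrum is untouched
  tp <- theory_params(3, 3)
  q <- c(30, 50, 80)
  expect_equal(mode_amplitude_model(q, 200, 40, tp),
               (pi * q / 200)^(-tp$chi) / (4 * 3), tolerance = 1e-12)

  # delta = 0: both branches are the unconstrained spectrum everywhere
  tpc <- theory_params(3/2, 3)
  qs <- c(0.5, 1, 2, 20, 60)
  expect_equal(mode_amplitude_model(qs, 200, 40, tpc),
               (pi * qs / 200)^(-tpc$chi) / (4 * 3), tolerance = 1e-12)

  expect_error(mode_amplitude_model(150, 200, 40, tp), "q_prime")
})

test_that("the mu ODE with frozen coefficients equals the closed form", {
  f1 <- -0.0632; f2 <- -0.141
  grid <- seq(1.8, 5, by = 0.02)
  sol <- solve_mu_ode(grid, mu_initial = c(1.8, 6.2),
                      frozen = list(f1 = f1, f2 = f2))
  c3 <- -f2 / f1
  c1 <- (6.2 - c3) * exp(-f1 * 1.8)
  expect_equal(sol$mu, mu_closed_form(grid, c1, f1, c3), tolerance = 1e-6)

  # strictly decreasing for empirically relevant initial values
  for (mu0 in c(3, 5, 8)) {
    s <- solve_mu_ode(grid, c(1.8, mu0), frozen = list(f1 = f1, f2 = f2))
    expect_true(all(diff(s$mu) < 0))
  }
  # with the pointwise (non-frozen) coefficients as well
  sv <- solve_mu_ode(seq(1.8, 5, by = 0.05), c(1.8, 6.2))
  expect_true(all(diff(sv$mu) < 0))

  expect_error(solve_mu_ode(c(2, 1.9), c(2, 5)), "increasing")
  expect_error(solve_mu_ode(c(2, 3), c(2.5, 5)), "initial condition")
})

test_that("the closed form is self-consistent with the ODE right-hand side", {
  f1 <- -0.0651; f2 <- -0.1495
  c2 <- f1; c3 <- -f2 / f1; c1 <- 19
  x <- seq(2, 5, by = 0.25)
  mu <- mu_closed_form(x, c1, c2, c3)
  h <- 1e-6
  dmu_num <- (mu_closed_form(x + h, c1, c2, c3) -
              mu_closed_form(x - h, c1, c2, c3)) / (2 * h)
  expect_equal(dmu_num, f1 * mu + f2, tolerance = 1e-6)

  # strictly decreasing for c2 < 0, c1 > 0; finite large-d_f limit c3
  expect_true(all(diff(mu) < 0))
  expect_equal(mu_closed_form(1e8, c1, c2, c3), c3)
})

test_that("theory tables carry the full parameter set", {
  tab <- theory_table()
  expect_equal(nrow(tab), 12)
  expect_named(tab, c("d_f", "chi", "gamma", "delta", "f1", "f2", "c3",
                      "extrapolated"))
  expect_true(all(tab$delta[tab$d_f > 1.5] > 0))
  expect_equal(sum(tab$extrapolated), 3)  # 6/5, 3/2, 5/3 fall at or below 1.7
  tp <- theory_params(3, 3)
  expect_equal(tp$c2, tp$f1)
  expect_equal(tp$c3, -tp$f2 / tp$f1)
})
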