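#' Spectral exponent of the beta model
#'
#' `chi = 1 + 2/d_f` ties the mode spectrum to the fractal dimension:
#' mean-squared mode amplitudes scaling as `q^-chi` produce internal
#' distances `~ s^(2/d_f)`. `d_f = 2` gives `chi = 2`, the Rouse ring.
#'
#' @param d_f fractal dimension(s), positive.
#' @return chi value(s).
#' @export
chi_of <- function(d_f) {
  if (any(!is.finite(d_f)) || any(d_f <= 0)) stop("d_f must be positive and finite")
  1 + 2 / d_f
}

#' Swollen-chain spectral exponent from the generalized Flory argument
#'
#' Balancing the excluded-volume free energy of an interacting segment gas,
#' `F_int ~ v N^2 / R^d`, against the entropic elasticity of an ideal
#' fractal chain, `F_el ~ R^2 / N^(2/d_f)`, and minimizing over the size
#' `R` gives the swelling exponent `nu = (2 + 2/d_f) / (d + 2)` and hence
#' the spectral exponent of the swollen (topologically repelling) regime,
#' \deqn{\gamma = 1 + 2\nu = 1 + \frac{2(2 + 2/d_f)}{d + 2}.}
#' In three dimensions `gamma = (9 d_f + 4) / (5 d_f)`; it crosses
#' `chi(d_f)` exactly at `d_f = 3/2` (where `gamma = chi = 7/3`) and at
#' `d_f = 2` reduces to the classical Flory value `nu = 3/5`,
#' `gamma = 11/5`. Excluded volume can only swell the chain, so
#' `gamma >= chi` throughout the physically treated range `d_f >= 3/2`;
#' the Flory estimate is not expected to remain accurate below
#' `d_f ~ 1.7`, and values computed there carry an `"extrapolated"`
#' attribute rather than an error.
#'
#' @param d_f fractal dimension(s), > 1.
#' @param d spatial dimension, 2 or 3.
#' @return gamma value(s), with attribute `extrapolated` marking entries
#'   with `d_f <= 1.7` (in 3D) where the estimate is used outside its
#'   trusted range.
#' @export
gamma_flory <- function(d_f, d = 3) {
  if (any(!is.finite(d_f)) || any(d_f <= 1)) stop("d_f must be finite and > 1")
  if (!(d %in% c(2, 3))) stop("d must be 2 or 3")
  g <- 1 + 2 * (2 + 2 / d_f) / (d + 2)
  structure(g, extrapolated = d_f <= trusted_d_f_min(d))
}

# trusted-range floor for the Flory estimate (self-avoiding-ring dimension)
trusted_d_f_min <- function(d = 3) if (d == 3) 1.7 else 4 / 3

#' Analytical theory parameters for a given fractal dimension
#'
#' Collects the constants of the analytical knotting-length theory:
#' `chi`, the Flory exponent `gamma`, their difference
#' `delta = gamma - chi` (the spectral mismatch between the swollen
#' large-scale and unperturbed small-scale regimes), the algebraic
#' functions `f1`, `f2` entering the ODE for `mu = ln N0`, and the
#' derived constants `c2 = f1`, `c3 = -f2/f1` of its constant-coefficient
#' solution.
#'
#' @param d_f fractal dimension, > 1.
#' @param d spatial dimension, 2 or 3.
#' @return list of class `"theory_params"`.
#' @export
theory_params <- function(d_f, d = 3) {
  chi <- chi_of(d_f)
  gam <- as.numeric(gamma_flory(d_f, d))
  ff <- f_functions(d_f, d)
  structure(
    list(d_f = d_f, d = d, chi = chi, gamma = gam, delta = gam - chi,
         f1 = ff$f1, f2 = ff$f2,
         c2 = ff$f1,
         c3 = ifelse(ff$f1 != 0, -ff$f2 / ff$f1, NA_real_),
         extrapolated = d_f <= trusted_d_f_min(d)),
    class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat(sprintf("Theory parameters at d_f = %.4g (d = %d)%s\n", x$d_f, x$d,
              if (any(x$extrapolated)) "  [extrapolated below trusted range]" else ""))
  cat(sprintf("  chi = %.6g, gamma = %.6g, delta = %.6g\n",
              x$chi, x$gamma, x$delta))
  cat(sprintf("  f1 = %.6g, f2 = %.6g  ->  c2 = %.6g, c3 = %.6g\n",
              x$f1, x$f2, x$c2, x$c3))
  invisible(x)
}

#' Algebraic coefficient functions of the knotting-length ODE
#'
#' The statistical-mechanical derivative of the unknot probability with
#' respect to `chi`, evaluated with the two-regime mode-amplitude model
#' ([mode_amplitude_model]) in the large-`N` limit (mode sums approximated
#' by integrals), yields a first-order linear ODE for `mu = ln N0` as a
#' function of `x = d_f`:
#' \deqn{\frac{d\mu}{d x} = f_1(x)\,\mu + f_2(x),}
#' with, writing `delta(x) = gamma(x) - chi(x)`,
#' \deqn{f_1(x) = -\frac{1}{x^2}\,\frac{\delta}{1-\delta}, \qquad
#'       f_2(x) = -\frac{1}{x^2}\left[\frac{1}{(1-\delta)^2} - 1
#'                 - \frac{\delta}{1-\delta}\,\ln\frac{\pi}{2}\right].}
#' The `ln(pi/2)` term is the only model-dependent ingredient (it records
#' the crossover-mode prefactor of the specific ring spectrum); the
#' functional form of the ODE is universal for any two-fractal polymer
#' with a sharp crossover scale. Over the fractal dimensions where the
#' Flory estimate is trusted, `f1` and `f2` are roughly constant, which
#' is what licenses the constant-coefficient (double-exponential)
#' solution [mu_closed_form()].
#'
#' At `delta = 0` (the Flory/chi crossing `d_f = 3/2` in 3D) both
#' functions vanish continuously.
#'
#' @param d_f fractal dimension(s); a warning is issued outside the
#'   default treated range `6/5 <= d_f <= 5`.
#' @param d spatial dimension, 2 or 3.
#' @param range_warn range outside which a warning is issued.
#' @return list with vectors `f1` and `f2`.
#' @export
f_functions <- function(d_f, d = 3, range_warn = c(6 / 5, 5)) {
  if (any(d_f < range_warn[1] | d_f > range_warn[2]))
    warning("f_functions evaluated outside the treated range [6/5, 5]; theory untested there")
  x <- d_f
  delta <- as.numeric(gamma_flory(x, d)) - chi_of(x)
  if (any(delta >= 1)) stop("delta >= 1: integral representation diverges")
  A <- 1 / (1 - delta)^2 - 1          # int_0^1 ln(u) (1 - u^-delta) du
  B <- -delta / (1 - delta)           # int_0^1 (1 - u^-delta) du
  list(f1 = B / x^2, f2 = -(A + B * log(pi / 2)) / x^2)
}

#' Representative constant values of f1 and -f2/f1
#'
#' Collapses `f1(d_f)` and `-f2(d_f)/f1(d_f)` to single representative
#' numbers by averaging pointwise over the grid of studied fractal
#' dimensions restricted to the trusted range of the Flory estimate
#' (`d_f > 1.7` in 3D), where the functions are roughly constant. These
#' are the analytically predicted values of the fit constants `c2` and
#' `c3` of the double-exponential law.
#'
#' @param d_f_grid grid of fractal dimensions (default the 12 studied
#'   values `6/5, 3/2, 5/3, 9/5, 2, 11/5, 5/2, 3, 7/2, 4, 9/2, 5`).
#' @param d spatial dimension.
#' @return list with `c2` (mean f1), `c3` (mean -f2/f1), the retained
#'   grid, and the pointwise tables.
#' @export
representative_constants <- function(d_f_grid = default_d_f_grid(), d = 3) {
  keep <- d_f_grid > trusted_d_f_min(d)
  x <- d_f_grid[keep]
  ff <- f_functions(x, d)
  list(c2 = mean(ff$f1), c3 = mean(-ff$f2 / ff$f1),
       d_f_used = x,
       table = data.frame(d_f = x, f1 = ff$f1, f2 = ff$f2,
                          c3 = -ff$f2 / ff$f1))
}

#' The twelve studied fractal dimensions
#' @return numeric vector `6/5 ... 5`.
#' @export
default_d_f_grid <- function() {
  c(6/5, 3/2, 5/3, 9/5, 2, 11/5, 5/2, 3, 7/2, 4, 9/2, 5)
}

#' Two-regime mode-amplitude model of the unknotted ensemble
#'
#' Chain segments longer than the knotting length `N0` repel through the
#' topological excluded volume, so the unknotted ensemble is swollen on
#' large scales and unperturbed on small ones. Mode `q'` (with
#' `q' = min(q, N-q)`) describes structure on `N/2q'` segments, so the
#' postulated per-component amplitudes are
#' \deqn{\langle X_{q'}^2\rangle_0 = \frac{1}{4k}
#'   \left(\frac{\pi}{2N_0}\right)^{\delta}\left(\frac{\pi q'}{N}\right)^{-\gamma}
#'   \quad (q' \le N/2N_0), \qquad
#'   \langle X_{q'}^2\rangle_0 = \frac{1}{4k}\left(\frac{\pi q'}{N}\right)^{-\chi}
#'   \quad (q' > N/2N_0),}
#' the `(pi/2N0)^delta` prefactor making the two branches continuous at
#' the crossover `q' = N/2N0`. At `gamma = chi` (`delta = 0`) both
#' branches coincide with the unconstrained spectrum for every mode.
#'
#' @param q_prime reduced mode index (may be fractional for evaluating the
#'   crossover), `1 <= q_prime <= N/2`.
#' @param N chain length.
#' @param N0 knotting length (> 0).
#' @param params a `"theory_params"` object (fixes `chi`, `gamma`, `k`
#'   via the spatial dimension).
#' @return per-component mean-squared amplitude(s).
#' @export
mode_amplitude_model <- function(q_prime, N, N0, params) {
  stopifnot(inherits(params, "theory_params"), N0 > 0)
  if (any(q_prime < 0) || any(q_prime > N / 2))
    stop("q_prime must lie in [0, N/2]")
  k <- params$d
  qc <- N / (2 * N0)
  swollen <- q_prime <= qc
  amp <- numeric(length(q_prime))
  amp[!swollen] <- (pi * q_prime[!swollen] / N)^(-params$chi) / (4 * k)
  amp[swollen] <- (pi / (2 * N0))^(params$delta) *
    (pi * q_prime[swollen] / N)^(-params$gamma) / (4 * k)
  amp
}

#' Closed-form double-exponential law for the knotting length
#'
#' The constant-coefficient solution of the `mu` ODE:
#' \deqn{\mu(d_f) = c_1 e^{c_2 d_f} + c_3,}
#' so that `N0 = exp(mu)` depends double-exponentially on the fractal
#' dimension (and the knotting probability triple-exponentially). With
#' `c2 = f1 < 0` and `c1 > 0` the law is strictly decreasing with the
#' finite large-`d_f` limit `N0 -> exp(c3)`. The coefficients of the
#' frozen ODE correspond to `c2 = f1` and `c3 = -f2/f1`.
#'
#' @param d_f fractal dimension(s).
#' @param c1,c2,c3 coefficients.
#' @return mu value(s) = ln N0.
#' @export
mu_closed_form <- function(d_f, c1, c2, c3) {
  c1 * exp(c2 * d_f) + c3
}

#' Logarithmic alternative law (scaling-theory form)
#'
#' `mu = c1 ln(d_f + c2) + c3`, the form typical of power-law/scaling
#' arguments, used as the competing model in fits.
#'
#' @inheritParams mu_closed_form
#' @return mu value(s).
#' @export
mu_log_form <- function(d_f, c1, c2, c3) {
  c1 * log(d_f + c2) + c3
}

#' Numerically integrate the knotting-length ODE
#'
#' Solves `d mu / d d_f = f1(d_f) mu + f2(d_f)` with [f_functions()]
#' coefficients (or frozen constants) by an adaptive integrator
#' (`deSolve::ode`, relative tolerance `1e-8`). The theory fixes the ODE
#' but not an integration constant, so an initial condition
#' `(d_f0, mu0)` must be supplied; with frozen coefficients the solution
#' is exactly [mu_closed_form()] with `c1 = (mu0 - c3) exp(-f1 d_f0)`.
#'
#' @param d_f_grid increasing grid starting at the initial d_f.
#' @param mu_initial length-2 vector `c(d_f0, mu0)`; `d_f0` must equal
#'   `d_f_grid[1]`.
#' @param d spatial dimension.
#' @param frozen optional list with constants `f1`, `f2`; when supplied
#'   the coefficients are held fixed instead of evaluated pointwise.
#' @param rtol relative tolerance of the integrator.
#' @return data.frame with columns `d_f` and `mu`.
#' @export
solve_mu_ode <- function(d_f_grid, mu_initial, d = 3, frozen = NULL,
                         rtol = 1e-8) {
  stopifnot(length(mu_initial) == 2L, is.numeric(d_f_grid))
  if (abs(d_f_grid[1] - mu_initial[1]) > 1e-12)
    stop("d_f_grid must start at the initial condition's d_f")
  if (is.unsorted(d_f_grid, strictly = TRUE))
    stop("d_f_grid must be strictly increasing")
  rhs <- function(x, y, parms) {
    if (is.null(frozen)) {
      ff <- suppressWarnings(f_functions(x, d))
    } else ff <- frozen
    list(ff$f1 * y[1] + ff$f2)
  }
  sol <- deSolve::ode(y = c(mu = mu_initial[2]), times = d_f_grid,
                      func = rhs, parms = NULL, rtol = rtol, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) stop("ODE integration failed")
  data.frame(d_f = sol[, 1], mu = sol[, 2])
}

#' Tabulate the analytical theory over a grid
#'
#' Convenience table of `chi`, `gamma`, `delta`, `f1`, `f2`, `c3
#' = -f2/f1` and the extrapolation flag over a fractal-dimension grid.
#'
#' @param d_f_grid fractal dimensions.
#' @param d spatial dimension.
#' @return data.frame.
#' @export
theory_table <- function(d_f_grid = default_d_f_grid(), d = 3) {
  ff <- suppressWarnings(f_functions(d_f_grid, d))
  data.frame(
    d_f = d_f_grid,
    chi = chi_of(d_f_grid),
    gamma = as.numeric(gamma_flory(d_f_grid, d)),
    delta = as.numeric(gamma_flory(d_f_grid, d)) - chi_of(d_f_grid),
    f1 = ff$f1, f2 = ff$f2,
    c3 = ifelse(ff$f1 != 0, -ff$f2 / ff$f1, NA_real_),
    extrapolated = d_f_grid <= trusted_d_f_min(d))
}
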