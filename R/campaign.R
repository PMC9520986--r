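# Campaign orchestration: sample -> classify -> P0 curves -> N0 fits ->
# mu(d_f) curve -> competing mu fits, deterministically seeded throughout.

# Reference mu-curve used only to place default N grids so that each
# fractal dimension is sampled across its own decay range (roughly
# 0.25 N0 .. 2 N0). The constants are a package default chosen to span the
# empirically relevant window (mu ~ 3.7 at large d_f up to ~8.7 at
# d_f = 6/5); they parameterize grid placement, never results.
reference_mu <- function(d_f) mu_closed_form(d_f, 19.4, -1.138, 3.703)

#' Default chain-length grid for a fractal dimension
#'
#' Places `n_points` chain lengths across the expected decay range of
#' `P0(N)` at the given fractal dimension (factors 0.25-2 times a
#' reference knotting length), rounded and capped at `n_max`.
#'
#' @param d_f fractal dimension.
#' @param n_points number of lengths.
#' @param n_max cap on chain length (keeps desk-scale campaigns bounded).
#' @param n_min floor on chain length.
#' @return integer vector of chain lengths.
#' @export
default_n_grid <- function(d_f, n_points = 6, n_max = 2500, n_min = 32) {
  N0 <- exp(reference_mu(d_f))
  g <- round(N0 * seq(0.25, 2, length.out = n_points))
  g <- pmin(pmax(g, n_min), n_max)
  sort(unique(g))
}

#' Campaign configuration
#'
#' Bundles everything a knotting campaign needs: spatial dimension,
#' fractal-dimension grid, per-d_f chain-length grids, samples per
#' (d_f, N) point, and the master seed. At full scale, between 2e4 and
#' 1e5 configurations per point are collected; the desk-scale preset
#' (`scaled_down = TRUE`, the default) uses 2e3 and is flagged in all
#' output metadata.
#'
#' @param d spatial dimension (3: Alexander classification; 2: segment
#'   intersection).
#' @param d_f_grid fractal dimensions (default the 12 studied values).
#' @param n_grids optional named list (names = `d_f` values) of chain
#'   length vectors; defaults to [default_n_grid()] per d_f.
#' @param samples configurations per (d_f, N) point.
#' @param seed master seed; every output embeds it and per-point
#'   substream seeds derive from it deterministically.
#' @param scaled_down logical flag recorded in metadata.
#' @param eps_rel geometric degeneracy tolerance.
#' @return object of class `"campaign_config"`.
#' @export
campaign_config <- function(d = 3, d_f_grid = default_d_f_grid(),
                            n_grids = NULL, samples = 2000L, seed = 1L,
                            scaled_down = samples < 2e4, eps_rel = 1e-9) {
  stopifnot(d %in% c(2L, 3L), length(d_f_grid) >= 1, samples >= 1)
  if (anyDuplicated(d_f_grid)) stop("duplicate d_f values")
  if (is.null(n_grids)) {
    n_grids <- lapply(d_f_grid, default_n_grid)
    names(n_grids) <- as.character(d_f_grid)
  } else {
    if (!setequal(names(n_grids), as.character(d_f_grid)))
      stop("n_grids names must match d_f_grid")
    if (any(vapply(n_grids, length, integer(1)) == 0)) stop("empty N grid")
  }
  structure(
    list(d = as.integer(d), d_f_grid = sort(d_f_grid),
         n_grids = n_grids, samples = as.integer(samples),
         seed = as.integer(seed), scaled_down = scaled_down,
         eps_rel = eps_rel),
    class = "campaign_config")
}

#' @export
print.campaign_config <- function(x, ...) {
  cat(sprintf("Campaign config: d = %d, %d fractal dimensions, %d samples/point, seed = %d%s\n",
              x$d, length(x$d_f_grid), x$samples, x$seed,
              if (x$scaled_down) " [scaled-down preset]" else ""))
  for (df in x$d_f_grid)
    cat(sprintf("  d_f = %-5s N = {%s}\n", format(df),
                paste(x$n_grids[[as.character(df)]], collapse = ", ")))
  invisible(x)
}

# Deterministic substream seed for a (d_f, N) point, independent of
# evaluation order. Kept below 2^31.
point_seed <- function(master, i_df, i_n) {
  (as.double(master) * 48271 + i_df * 1299721 + i_n * 7919) %% 2147483629 + 1
}

#' Sample and classify one (d_f, N) campaign point
#'
#' Draws `samples` ring conformations from the beta model and classifies
#' each (Alexander determinant in 3D, segment intersection in 2D),
#' returning the unknot count.
#'
#' @param N chain length.
#' @param d_f fractal dimension.
#' @param d spatial dimension.
#' @param samples number of conformations.
#' @param seed substream seed.
#' @param eps_rel geometric tolerance.
#' @param chunk conformations sampled per batch (memory control).
#' @return list with `trials`, `unknot`, and mean crossing statistics
#'   (3D only).
#' @export
run_point <- function(N, d_f, d = 3, samples = 2000L, seed = 1L,
                      eps_rel = 1e-9, chunk = 2000L) {
  sp <- build_spectrum(N, d_f, d)
  done <- 0L
  unknot <- 0L
  crossings <- 0
  while (done < samples) {
    m <- min(chunk, samples - done)
    R <- sample_ring_matrix(sp, m, seed = seed + done)
    if (d == 3L) {
      res <- classify_stack(R, m, simplify = TRUE, eps_rel = eps_rel,
                            seed = seed + done)
      unknot <- unknot + sum(res$trivial)
      crossings <- crossings + sum(res$crossings)
    } else {
      knotted <- intersect_stack(R, m, eps_rel = max(eps_rel, 1e-12))
      unknot <- unknot + sum(!knotted)
    }
    done <- done + m
  }
  list(trials = samples, unknot = unknot,
       mean_crossings = if (d == 3L) crossings / samples else NA_real_)
}

#' Run a full knotting campaign
#'
#' For each fractal dimension and chain length in the configuration:
#' sample beta-model rings, classify their knotting, and assemble
#' knotting curves; then fit the exponential law per fractal dimension,
#' build the mu(d_f) curve, and fit both the double-exponential and the
#' logarithmic laws. Fully deterministic given the configuration seed.
#' Per-point failures (e.g. a fit window with too few usable points) are
#' recorded in `$failures` and surfaced as a warning, never dropped
#' silently.
#'
#' @param config a `"campaign_config"`.
#' @param progress print per-point progress lines.
#' @return object of class `"knot_campaign"`: list with `curves` (named
#'   by d_f), `fits`, `mu_curve`, `mu_fits` (both models), `failures`,
#'   `config`.
#' @export
run_campaign <- function(config, progress = interactive()) {
  stopifnot(inherits(config, "campaign_config"))
  curves <- list()
  fits <- list()
  failures <- list()
  for (i_df in seq_along(config$d_f_grid)) {
    d_f <- config$d_f_grid[i_df]
    key <- as.character(d_f)
    Ns <- config$n_grids[[key]]
    trials <- integer(length(Ns))
    unknot <- integer(length(Ns))
    for (i_n in seq_along(Ns)) {
      ps <- point_seed(config$seed, i_df, i_n)
      pt <- run_point(Ns[i_n], d_f, config$d, config$samples, ps,
                      config$eps_rel)
      trials[i_n] <- pt$trials
      unknot[i_n] <- pt$unknot
      if (progress)
        message(sprintf("d_f = %-5s N = %5d: %d/%d unknotted",
                        key, Ns[i_n], pt$unknot, pt$trials))
    }
    curves[[key]] <- knotting_curve(Ns, trials, unknot, d_f = d_f,
                                    d = config$d, seed = config$seed)
    fit <- tryCatch(fit_exponential(curves[[key]]), error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[key]] <- conditionMessage(fit)
    } else {
      fits[[key]] <- fit
    }
  }
  if (length(failures))
    warning(sprintf("exponential fit failed for d_f in {%s}",
                    paste(names(failures), collapse = ", ")))
  mu_cv <- if (length(fits) >= 1) build_mu_curve(fits) else NULL
  mu_fits <- NULL
  if (!is.null(mu_cv) && nrow(mu_cv) >= 4) {
    mu_fits <- list(
      double_exponential = tryCatch(fit_mu(mu_cv, "double_exponential"),
                                    error = function(e) e),
      logarithmic = tryCatch(fit_mu(mu_cv, "logarithmic"),
                             error = function(e) e))
  }
  structure(
    list(curves = curves, fits = fits, mu_curve = mu_cv, mu_fits = mu_fits,
         failures = failures, config = config),
    class = "knot_campaign")
}

#' @export
print.knot_campaign <- function(x, ...) {
  cat(sprintf("Knotting campaign: d = %d, %d fractal dimensions, seed = %d%s\n",
              x$config$d, length(x$config$d_f_grid), x$config$seed,
              if (x$config$scaled_down) " [scaled-down]" else ""))
  if (!is.null(x$mu_curve)) print(x$mu_curve)
  if (!is.null(x$mu_fits)) {
    for (m in x$mu_fits) if (!inherits(m, "error")) print(m)
    ok <- !vapply(x$mu_fits, inherits, logical(1), "error")
    if (all(ok)) {
      a <- vapply(x$mu_fits, function(f) f$aicc, numeric(1))
      cat(sprintf("Preferred model by AICc: %s (delta AICc = %.3g)\n",
                  names(which.min(a)), abs(diff(a))))
    }
  }
  if (length(x$failures)) cat("Failures:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
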