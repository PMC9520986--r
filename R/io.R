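# File I/O: XYZ conformations, CSV tables with metadata headers, JSON
# bundles. All writers embed (package version, seed, metadata) so any
# stage can be re-run reproducibly from its files.

#' Write ring conformations to an XYZ trajectory file
#'
#' Standard XYZ: per frame, a bead-count line, a comment line carrying
#' `N`, `d_f`, `seed` and the spatial dimension, then one `El x y z` line
#' per bead (element tag "C"; 2D rings are written with z = 0 and
#' `d=2` in the comment). Coordinates carry 15 significant digits, so a
#' write/read round trip is lossless at double precision.
#'
#' @param conformations a `"ring_conformation"` or list of them.
#' @param path output file.
#' @export
write_xyz <- function(conformations, path) {
  if (inherits(conformations, "ring_conformation"))
    conformations <- list(conformations)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in conformations) {
    P <- cf$positions
    if (ncol(P) == 2L) P <- cbind(P, 0)
    writeLines(as.character(nrow(P)), con)
    writeLines(sprintf("ringknots N=%d d=%d d_f=%s seed=%s", cf$N, cf$d,
                       format(cf$d_f, digits = 15),
                       format(cf$seed)), con)
    writeLines(sprintf("C %.15g %.15g %.15g", P[, 1], P[, 2], P[, 3]), con)
  }
  invisible(path)
}

#' Read ring conformations from an XYZ trajectory file
#'
#' Inverse of [write_xyz()]; restores `d_f`, `seed` and the spatial
#' dimension from the comment line (frames from other tools, lacking the
#' metadata, are read as 3D with unknown provenance). Malformed files
#' produce line-numbered diagnostics.
#'
#' @param path XYZ file.
#' @return list of `"ring_conformation"` objects.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("%s:%d: expected a bead count, got '%s'", path, i, lines[i]))
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines))
      stop(sprintf("%s:%d: truncated frame (%d beads declared)", path, i, n))
    comment <- lines[i + 1L]
    getf <- function(key) {
      m <- regmatches(comment, regexec(paste0(key, "=([^ ]+)"), comment))[[1]]
      if (length(m) == 2L) m[2] else NA_character_
    }
    d <- suppressWarnings(as.integer(getf("d")))
    d_f <- suppressWarnings(as.numeric(getf("d_f")))
    seed <- suppressWarnings(as.integer(getf("seed")))
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4L)
    if (length(bad))
      stop(sprintf("%s:%d: malformed coordinate line", path, i + 1L + bad[1]))
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("%s:%d: non-numeric coordinates in frame", path, i))
    if (!is.na(d) && d == 2L) xyz <- xyz[, 1:2, drop = FALSE]
    out[[length(out) + 1L]] <- ring_conformation(
      xyz, d_f = if (is.na(d_f)) NA_real_ else d_f,
      seed = if (is.na(seed)) NA_integer_ else seed)
    i <- i + 2L + n
  }
  out
}

# metadata header lines for CSV files: "# key=value"
meta_header <- function(meta) {
  meta <- c(list(package = sprintf("ringknots %s",
                                   as.character(utils::packageVersion("ringknots")))),
            meta)
  sprintf("# %s=%s", names(meta), vapply(meta, function(v) paste(format(v), collapse = ","), character(1)))
}

#' Write a data frame as CSV with a metadata header
#'
#' Plain CSV preceded by `# key=value` comment lines carrying at least
#' the package version and the campaign seed, so every table is
#' self-describing and reproducible.
#'
#' @param df data.frame.
#' @param path output file.
#' @param meta named list of metadata values.
#' @export
write_csv_table <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV table written by [write_csv_table()]
#'
#' @param path CSV file.
#' @param required_columns optional character vector; a header mismatch
#'   is an error naming the missing columns.
#' @return data.frame with attribute `meta` (named character list).
#' @export
read_csv_table <- function(path, required_columns = NULL) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  first_data <- which(!is_meta)[1]
  if (is.na(first_data)) stop(sprintf("%s: no data rows", path))
  meta_lines <- sub("^#\\s*", "", lines[is_meta & seq_along(lines) < first_data])
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(p) paste(p[-1], collapse = "=")),
    vapply(kv, `[`, character(1), 1))
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  if (!is.null(required_columns)) {
    missing <- setdiff(required_columns, names(df))
    if (length(missing))
      stop(sprintf("%s: missing required columns: %s", path,
                   paste(missing, collapse = ", ")))
  }
  attr(df, "meta") <- meta
  df
}

#' Write campaign results to a directory
#'
#' Emits the full result bundle: `curves.csv` (one row per (d_f, N)
#' point), `fits.csv` (per-d_f exponential fits), `mu_curve.csv`,
#' `mu_fits.csv` (both functional forms with AICc), and
#' `campaign.json`, a JSON mirror of every table plus the configuration.
#' All files embed the seed and grid metadata.
#'
#' @param campaign a `"knot_campaign"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "knot_campaign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- campaign$config
  meta <- list(seed = cfg$seed, d = cfg$d, samples = cfg$samples,
               scaled_down = cfg$scaled_down,
               d_f_grid = paste(cfg$d_f_grid, collapse = " "))
  curves <- do.call(rbind, lapply(names(campaign$curves), function(k) {
    cv <- campaign$curves[[k]]
    data.frame(d_f = as.numeric(k), N = cv$N, trials = cv$trials,
               unknot = cv$unknot, p0 = cv$p0, ci_lo = cv$ci_low,
               ci_hi = cv$ci_high)
  }))
  write_csv_table(curves, file.path(dir, "curves.csv"), meta)
  fits <- do.call(rbind, lapply(names(campaign$fits), function(k) {
    f <- campaign$fits[[k]]
    data.frame(d_f = as.numeric(k), N0 = f$N0, mu = f$mu,
               stderr = f$mu_stderr, chi2red = f$chi2_red,
               window = paste(f$curve$N[f$window], collapse = " "))
  }))
  if (!is.null(fits)) write_csv_table(fits, file.path(dir, "fits.csv"), meta)
  if (!is.null(campaign$mu_curve))
    write_csv_table(as.data.frame(campaign$mu_curve),
                    file.path(dir, "mu_curve.csv"), meta)
  if (!is.null(campaign$mu_fits)) {
    ok <- !vapply(campaign$mu_fits, inherits, logical(1), "error")
    mf <- do.call(rbind, lapply(campaign$mu_fits[ok], function(f) {
      cf <- f$coefficients
      data.frame(model = f$model, c1 = cf["c1"], c2 = cf["c2"],
                 c3 = cf["c3"], aicc = f$aicc,
                 runs_p = f$runs_test$p_value)
    }))
    if (!is.null(mf)) {
      rownames(mf) <- NULL
      write_csv_table(mf, file.path(dir, "mu_fits.csv"), meta)
    }
  }
  bundle <- list(
    meta = meta,
    curves = curves,
    fits = fits,
    mu_curve = if (!is.null(campaign$mu_curve)) as.data.frame(campaign$mu_curve),
    mu_fits = if (!is.null(campaign$mu_fits)) {
      ok <- !vapply(campaign$mu_fits, inherits, logical(1), "error")
      lapply(campaign$mu_fits[ok], function(f)
        list(model = f$model, coefficients = as.list(f$coefficients),
             aicc = f$aicc, runs_p = f$runs_test$p_value))
    },
    failures = campaign$failures)
  jsonlite::write_json(bundle, file.path(dir, "campaign.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a campaign configuration from a YAML file
#'
#' Recognized keys: `d`, `d_f_grid`, `samples`, `seed`, `scaled_down`,
#' `n_grids` (a map from d_f value to a list of chain lengths),
#' `eps_rel`. Missing keys take the [campaign_config()] defaults.
#'
#' @param path YAML file.
#' @return a `"campaign_config"`.
#' @export
read_campaign_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("d", "d_f_grid", "samples", "seed", "scaled_down", "eps_rel"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(y$n_grids))
    args$n_grids <- lapply(y$n_grids, function(v) as.integer(unlist(v)))
  if (!is.null(args$d_f_grid)) args$d_f_grid <- as.numeric(unlist(args$d_f_grid))
  do.call(campaign_config, args)
}
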