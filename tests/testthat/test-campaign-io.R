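test_that("a tiny smoke campaign completes and emits every schema", {
  cfg <- campaign_config(
    d = 3, d_f_grid = c(2.5, 5),
    n_grids = list(`2.5` = c(40, 80, 120), `5` = c(32, 64, 96)),
    samples = 200L, seed = 11L)
  camp <- suppressWarnings(run_campaign(cfg, progress = FALSE))
  expect_s3_class(camp, "knot_campaign")
  expect_length(camp$curves, 2L)
  expect_true(all(vapply(camp$curves, inherits, logical(1), "knotting_curve")))

  dir <- withr::local_tempdir()
  write_campaign(camp, dir)
  expect_true(all(file.exists(file.path(dir, c("curves.csv", "campaign.json")))))
  curves <- read_csv_table(file.path(dir, "curves.csv"),
                           required_columns = c("d_f", "N", "trials", "unknot",
                                                "p0", "ci_lo", "ci_hi"))
  expect_equal(nrow(curves), 6L)
  expect_equal(attr(curves, "meta")$seed, "11")
  js <- jsonlite::read_json(file.path(dir, "campaign.json"))
  expect_equal(js$meta$seed, 11L)
})

test_that("identical configurations give byte-identical outputs", {
  cfg <- campaign_config(d = 2, d_f_grid = c(1.5, 3),
                         n_grids = list(`1.5` = c(8, 12, 16, 20),
                                        `3` = c(6, 9, 12, 15)),
                         samples = 400L, seed = 7L)
  c1 <- suppressWarnings(run_campaign(cfg, progress = FALSE))
  c2 <- suppressWarnings(run_campaign(cfg, progress = FALSE))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_campaign(c1, d1); write_campaign(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("XYZ round trips are lossless and carry metadata", {
  sp <- build_spectrum(40, 2.7, 3)
  rings <- sample_rings(sp, 20, seed = 5)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(rings, path)
  back <- read_xyz(path)
  expect_length(back, 20L)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$positions, rings[[i]]$positions, tolerance = 1e-12)
    expect_equal(back[[i]]$d_f, 2.7)
    expect_equal(back[[i]]$seed, 5L)
  }

  # 2D rings survive with their dimension
  sp2 <- build_spectrum(12, 1.5, 2)
  r2 <- sample_rings(sp2, 3, seed = 2)
  p2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(r2, p2)
  b2 <- read_xyz(p2)
  expect_equal(b2[[2]]$d, 2L)
  expect_equal(b2[[2]]$positions, r2[[2]]$positions, tolerance = 1e-12)

  # malformed files produce line-numbered diagnostics
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "comment", "C 0 0 0", "C 1 1", "C 2 2 2"), bad)
  expect_error(read_xyz(bad), ":4")
  bad2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "comment", "C 0 0 0"), bad2)
  expect_error(read_xyz(bad2), "truncated")
})

test_that("CSV tables round trip with metadata and validate headers", {
  df <- data.frame(q = 1:3, lambda_q = c(0.1, 0.2, 0.3),
                   var_empirical = c(10, 5, 3.3), stderr = c(0.1, 0.05, 0.03))
  path <- withr::local_tempfile(fileext = ".csv")
  write_csv_table(df, path, meta = list(seed = 99, d_f = 2.5))
  back <- read_csv_table(path, required_columns = names(df))
  expect_equal(back$var_empirical, df$var_empirical)
  expect_equal(attr(back, "meta")$seed, "99")
  expect_match(attr(back, "meta")$package, "ringknots")
  expect_error(read_csv_table(path, required_columns = "no_such_column"),
               "no_such_column")
})

test_that("YAML configurations load with defaults and overrides", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("d: 2", "d_f_grid: [1.5, 2.0, 3.0]", "samples: 150",
               "seed: 31", "n_grids:", "  '1.5': [8, 12]", "  '2': [6, 10]",
               "  '3': [6, 8]"), path)
  cfg <- read_campaign_config(path)
  expect_equal(cfg$d, 2L)
  expect_equal(cfg$samples, 150L)
  expect_equal(cfg$seed, 31L)
  expect_equal(cfg$n_grids[["1.5"]], c(8L, 12L))
  expect_true(cfg$scaled_down)
})

test_that("configuration validation and default grids are sane", {
  expect_error(campaign_config(d = 4), "%in%")
  expect_error(campaign_config(d_f_grid = c(2, 2)), "duplicate")
  expect_error(campaign_config(d_f_grid = c(2, 3),
                               n_grids = list(`2` = c(10, 20))),
               "n_grids")
  g <- default_n_grid(5)
  expect_true(all(g >= 32) && all(diff(g) > 0))
  # slower-decaying systems get longer chains
  expect_gt(max(default_n_grid(3/2)), max(default_n_grid(5)))
})

test_that("the command-line interface classifies and tabulates", {
  cli <- file.path(find.package("ringknots"), "exec", "ringknots")
  skip_if_not(file.exists(cli), "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(list(make_knot_fixture("unknot", 40),
                 make_knot_fixture("trefoil", 60)), xyz)
  out <- withr::local_tempfile(fileext = ".csv")
  res <- system2(rscript, c(cli, "classify", "--in", xyz, "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  tab <- read_csv_table(out)
  expect_equal(tab$determinant, c(1, 3))
  expect_equal(tab$is_trivial, c(TRUE, FALSE))

  tout <- withr::local_tempfile(fileext = ".csv")
  system2(rscript, c(cli, "theory", "--out", tout), stdout = TRUE, stderr = TRUE)
  th <- read_csv_table(tout, required_columns = c("d_f", "chi", "gamma", "f1", "f2"))
  expect_equal(nrow(th), 12L)
})
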