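tiny_grid <- function(seed = 3L) {
  run_correlation_grid(
    cv_values = c(0.05, 0.15), h2_values = c(0.2, 0.4),
    base = small_config(cv = 0.05, h2 = 0.2, n = 1000L, reps = 2L, seed = seed)
  )
}

test_that("grid CSVs are deterministic byte for byte", {
  dir <- withr::local_tempdir()
  p1 <- write_grid_tables(tiny_grid(), file.path(dir, "a"))
  p2 <- write_grid_tables(tiny_grid(), file.path(dir, "b"))
  for (f in c("table", "se", "raw")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  header <- readLines(p1[["table"]], n = 2)
  expect_match(header[1], "^cv,h2_0.2,h2_0.4$")
  expect_match(header[2], "^0.05,[0-9.-]+,[0-9.-]+$")
  # rounded table shows 4 decimals
  expect_match(header[2], ",[0-9]+\\.[0-9]{4},")
})

test_that("a manifest regenerates its grid exactly", {
  dir <- withr::local_tempdir()
  grid <- tiny_grid(seed = 11L)
  paths <- write_grid_tables(grid, file.path(dir, "orig"))
  regen <- regenerate_grid(paths[["manifest"]])
  expect_equal(tidy(regen), tidy(grid))
  paths2 <- write_grid_tables(regen, file.path(dir, "regen"))
  expect_identical(readLines(paths[["table"]]), readLines(paths2[["table"]]))
  expect_identical(readLines(paths[["raw"]]), readLines(paths2[["raw"]]))
})

test_that("gcv grids round-trip through their manifest too", {
  dir <- withr::local_tempdir()
  grid <- run_gcv_grid(r_values = c(0.5, 1), cv_values = c(0.05, 0.1),
                       base = small_config(cv = 0.05, h2 = 0.25, n = 800L, reps = 2L))
  paths <- write_grid_tables(grid, file.path(dir, "g"))
  regen <- regenerate_grid(paths[["manifest"]])
  expect_equal(tidy(regen), tidy(grid))
  expect_equal(attr(regen, "statistic"), "mean_gcv")
})

test_that("verify_grid reports oracle agreement with the study tolerances", {
  grid <- run_correlation_grid(
    cv_values = 0.1, h2_values = c(0.2, 0.4),
    base = small_config(cv = 0.1, h2 = 0.2, n = 5000L, reps = 4L)
  )
  v <- verify_grid(grid)
  expect_named(v, c(names(tidy(grid)), "oracle", "tolerance", "abs_diff",
                    "within_tolerance"), ignore.order = TRUE)
  expect_equal(v$tolerance, pmax(0.02, 4 * v$se_rho))
  expect_true(all(v$within_tolerance))
})

cli_path <- function() system.file("cli", "scalefx.R", package = "scalefx")

run_cli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, c(cli_path(), args),
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("the bins subcommand summarises a CSV and honours error contracts", {
  dir <- withr::local_tempdir()
  input <- file.path(dir, "trait.csv")
  readr::write_csv(tibble::tibble(weight = as.numeric(1:10)), input)
  output <- file.path(dir, "bins.csv")

  ok <- run_cli(c("bins", "--input", input, "--column", "weight",
                  "--bins", "5", "--output", output))
  expect_equal(ok$status, 0L)
  got <- readr::read_csv(output, show_col_types = FALSE)
  expect_equal(got$mean, c(1.5, 3.5, 5.5, 7.5, 9.5))

  missing <- run_cli(c("bins", "--input", input, "--column", "height"))
  expect_equal(missing$status, 2L)
  expect_match(paste(missing$output, collapse = "\n"), "available columns.*weight")

  bad_bins <- run_cli(c("bins", "--input", input, "--bins", "1"))
  expect_equal(bad_bins$status, 2L)

  no_input <- run_cli("bins")
  expect_equal(no_input$status, 1L)
})

test_that("the scenario subcommand prints a one-row summary", {
  res <- run_cli(c("scenario", "--cv", "0.1", "--h2", "0.3",
                   "--n", "500", "--replicates", "2", "--seed", "9"))
  expect_equal(res$status, 0L)
  csv <- res$output[grepl("^(cv,|0\\.1,)", res$output)]
  parsed <- readr::read_csv(I(paste(csv, collapse = "\n")), show_col_types = FALSE)
  expect_equal(parsed$n_individuals, 500)
  expect_true(parsed$mean_rho > 0 && parsed$mean_rho < 1)
})
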