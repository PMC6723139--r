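#' Compare a simulated grid with the quadrature oracle
#'
#' Appends the deterministic oracle value to every cell of a grid and flags
#' cells whose Monte-Carlo mean falls outside the reproduction tolerance:
#' `max(0.02, 4 * SE)` for correlation grids and `max(0.03, 4 * SE)` for GCV
#' grids, tolerances motivated by the replicate standard-error ranges of the
#' default scheme.
#'
#' @param grid A `grid_table`.
#' @param n_nodes Quadrature resolution passed to the oracle. Default 128.
#' @return The grid's cells as a tibble with extra columns `oracle`,
#'   `abs_diff`, `tolerance` and `within_tolerance`.
#' @export
verify_grid <- function(grid, n_nodes = 128L) {
  stopifnot(inherits(grid, "grid_table"))
  stat <- attr(grid, "statistic")
  cells <- tidy(grid)
  if (stat == "mean_rho") {
    cells$oracle <- purrr::map2_dbl(cells$cv, cells$h2, function(cv, h2) {
      suppressWarnings(quadrature_correlation(cv, h2, n_nodes = n_nodes)$value)
    })
    cells$tolerance <- pmax(0.02, 4 * cells$se_rho)
  } else {
    cells$oracle <- purrr::map2_dbl(cells$cv, cells$r, function(cv, r) {
      suppressWarnings(quadrature_gcv(cv, r = r, n_nodes = n_nodes)$value)
    })
    cells$tolerance <- pmax(0.03, 4 * cells$se_gcv)
  }
  cells$abs_diff <- abs(cells[[stat]] - cells$oracle)
  cells$within_tolerance <- cells$abs_diff <= cells$tolerance
  cells
}

format_cells <- function(x, digits = 4L) {
  formatC(x, format = "f", digits = digits)
}

#' Write a grid to CSV files with a run manifest
#'
#' Serialises a grid the way the study tables are printed: a wide CSV of the
#' primary statistic rounded to 4 decimals (rows = row axis, columns = column
#' axis), a companion wide CSV of standard errors, a long CSV of raw
#' unrounded cells, and a JSON manifest recording every parameter needed to
#' regenerate the files byte for byte (see [regenerate_grid()]).
#'
#' @param grid A `grid_table`.
#' @param prefix Output path prefix; files are written as `<prefix>.csv`,
#'   `<prefix>_se.csv`, `<prefix>_raw.csv` and `<prefix>_manifest.json`.
#' @param digits Decimal places for the rounded table. Default 4.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_grid_tables <- function(grid, prefix, digits = 4L) {
  stopifnot(inherits(grid, "grid_table"))
  digits <- check_count(digits, "digits", min = 1L)
  stat <- attr(grid, "statistic")
  ra <- attr(grid, "row_axis")
  ca <- attr(grid, "col_axis")

  wide <- function(column) {
    m <- grid_matrix(grid, column)
    df <- as.data.frame(apply(m, 2, format_cells, digits = digits))
    names(df) <- paste0(ca$name, "_", colnames(m))
    df <- cbind(stats::setNames(list(rownames(m)), ra$name), df)
    df
  }

  paths <- c(
    table = paste0(prefix, ".csv"),
    se = paste0(prefix, "_se.csv"),
    raw = paste0(prefix, "_raw.csv"),
    manifest = paste0(prefix, "_manifest.json")
  )
  readr::write_csv(wide(stat), paths[["table"]])
  readr::write_csv(wide(sub("mean", "se", stat)), paths[["se"]])
  readr::write_csv(tidy(grid), paths[["raw"]])
  write_run_manifest(grid, paths[["manifest"]])
  invisible(paths)
}

grid_kind <- function(grid) {
  if (attr(grid, "statistic") == "mean_rho") "correlation" else "gcv"
}

#' Write the run manifest of a grid
#'
#' The manifest is a small JSON object holding the command kind, the resolved
#' parameters (axes, mean, heritability or strength, population sizes, seed,
#' negative-record convention), and the package version: enough to regenerate
#' the grid exactly.
#'
#' @param grid A `grid_table`.
#' @param path Output JSON path.
#' @return Invisibly, the manifest as a list.
#' @export
write_run_manifest <- function(grid, path) {
  stopifnot(inherits(grid, "grid_table"))
  base <- attr(grid, "base_config")
  manifest <- list(
    command = grid_kind(grid),
    parameters = list(
      row_axis = attr(grid, "row_axis"),
      col_axis = attr(grid, "col_axis"),
      mu = base$mu,
      h2 = base$h2,
      n_individuals = base$n_individuals,
      n_replicates = base$n_replicates,
      negative_handling = base$negative_handling
    ),
    seed = base$seed,
    version = as.character(utils::packageVersion("scalefx")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Regenerate a grid from its run manifest
#'
#' Re-runs the simulation described by a manifest written by
#' [write_run_manifest()]. Because all randomness flows from the recorded
#' seed through deterministic sub-streams, the regenerated grid (and any CSV
#' written from it) is identical to the original.
#'
#' @param manifest_path Path to a `*_manifest.json` file, or the manifest as
#'   a list.
#' @return A `grid_table`.
#' @export
regenerate_grid <- function(manifest_path) {
  manifest <- if (is.character(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    manifest_path
  }
  p <- manifest$parameters
  base <- scenario_config(
    cv = p$col_axis$values[1], h2 = p$h2 %||% 0.30, mu = p$mu,
    n_individuals = p$n_individuals, n_replicates = p$n_replicates,
    seed = manifest$seed, negative_handling = p$negative_handling
  )
  if (manifest$command == "correlation") {
    run_correlation_grid(
      cv_values = p$row_axis$values, h2_values = p$col_axis$values,
      base = base
    )
  } else {
    run_gcv_grid(
      r_values = p$row_axis$values, cv_values = p$col_axis$values,
      base = base
    )
  }
}
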