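#' Tidy a scenario result into replicate-level rows
#'
#' @param x A `scenario_result` from [run_scenario()].
#' @param ... Unused.
#' @return A tibble with one row per replicate: `replicate`, `rho`, `gcv`,
#'   `frac_negative`, `n`.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  x$replicates
}

#' One-row summary of a scenario result
#'
#' @param x A `scenario_result` from [run_scenario()].
#' @param ... Unused.
#' @return A one-row tibble with the scenario parameters and the replicate
#'   summaries (`mean_rho`, `se_rho`, `mean_gcv`, `se_gcv`,
#'   `max_frac_negative`).
#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  cfg <- x$config
  tibble(
    cv = cfg$cv,
    h2 = cfg$h2,
    r = cfg$r,
    mu = cfg$mu,
    n_individuals = cfg$n_individuals,
    n_replicates = cfg$n_replicates,
    mean_rho = x$mean_rho,
    se_rho = x$se_rho,
    mean_gcv = x$mean_gcv,
    se_gcv = x$se_gcv,
    max_frac_negative = x$max_frac_negative
  )
}

#' Tidy a grid table into long cell-level rows
#'
#' A `grid_table` is already tabular; `tidy()` strips the grid attributes and
#' returns a plain tibble of cells.
#'
#' @param x A `grid_table`.
#' @param ... Unused.
#' @return A tibble with one row per grid cell.
#' @method tidy grid_table
#' @export
tidy.grid_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "grid_table")
  attr(out, "statistic") <- NULL
  attr(out, "row_axis") <- NULL
  attr(out, "col_axis") <- NULL
  attr(out, "base_config") <- NULL
  as_tibble(out)
}

#' One-row summary of a grid table
#'
#' @param x A `grid_table`.
#' @param ... Unused.
#' @return A one-row tibble: axes, cell count, and the range of the grid's
#'   primary statistic.
#' @method glance grid_table
#' @export
glance.grid_table <- function(x, ...) {
  stat <- attr(x, "statistic")
  tibble(
    statistic = stat,
    row_axis = attr(x, "row_axis")$name,
    col_axis = attr(x, "col_axis")$name,
    n_cells = nrow(x),
    min_value = min(x[[stat]]),
    max_value = max(x[[stat]]),
    max_se = max(x[[sub("mean", "se", stat)]])
  )
}
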