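# Shared fixtures. Small configurations keep unit tests fast; the full-size
# default correlation grid used by the acceptance suite is computed once and
# cached for the session.

small_config <- function(cv, h2, r = 1, n = 2000L, reps = 3L, seed = 42L, ...) {
  scenario_config(cv = cv, h2 = h2, r = r, n_individuals = n,
                  n_replicates = reps, seed = seed, ...)
}

.grid_cache <- new.env(parent = emptyenv())

# Default study grid: CV and h2 from 0.05 to 0.50 in 0.05 steps,
# 10 replicates of 100,000 individuals, master seed 1.
default_correlation_grid <- function() {
  if (is.null(.grid_cache$table1)) {
    .grid_cache$table1 <- run_correlation_grid()
  }
  .grid_cache$table1
}
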