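#' Derive a reproducible RNG sub-stream
#'
#' Hierarchical stream derivation from a single master seed: the seed
#' initialises a L'Ecuyer-CMRG stream, `scenario_index` advances whole
#' streams ([parallel::nextRNGStream()]) and `replicate_index` advances
#' sub-streams within a scenario ([parallel::nextRNGSubStream()]). The same
#' `(seed, scenario_index, replicate_index)` triple always yields the same
#' stream, distinct triples yield distinct streams, and a grid of scenarios
#' is therefore reproducible in any execution order.
#'
#' @param seed Master seed (single integer-valued number).
#' @param scenario_index,replicate_index Non-negative 0-based indices.
#'
#' @return A `.Random.seed`-compatible integer vector (L'Ecuyer-CMRG state).
#' @examples
#' s1 <- derive_streams(1, 0, 0)
#' s2 <- derive_streams(1, 0, 1)
#' identical(s1, derive_streams(1, 0, 0))
#' identical(s1, s2)
#' @export
derive_streams <- function(seed, scenario_index = 0L, replicate_index = 0L) {
  check_scalar(seed, "seed")
  check_count(scenario_index + 1L, "scenario_index", min = 1L)
  check_count(replicate_index + 1L, "replicate_index", min = 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(scenario_index)) stream <- parallel::nextRNGStream(stream)
  for (j in seq_len(replicate_index)) stream <- parallel::nextRNGSubStream(stream)
  stream
}

# Evaluate `code` with the global RNG state set to `stream`, restoring the
# caller's state afterwards. Keeps stream-based draws from perturbing any
# user-level set.seed() context.
with_stream <- function(stream, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  assign(".Random.seed", stream, envir = globalenv())
  code
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
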