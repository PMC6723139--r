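# Input validation helpers. All user-facing domain errors carry the
# "scalefx_domain_error" class so callers (and the CLI) can distinguish bad
# parameter values (exit code 2) from usage errors (exit code 1).

stop_domain <- function(msg, ...) {
  abort(msg, class = "scalefx_domain_error", ...)
}

check_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

check_positive <- function(x, name = deparse(substitute(x))) {
  check_scalar(x, name)
  if (x <= 0) stop_domain(sprintf("`%s` must be strictly positive, got %g.", name, x))
  invisible(x)
}

# open unit interval, e.g. heritability
check_proportion <- function(x, name = deparse(substitute(x))) {
  check_scalar(x, name)
  if (x <= 0 || x >= 1) {
    stop_domain(sprintf("`%s` must lie strictly between 0 and 1, got %g.", name, x))
  }
  invisible(x)
}

# scale-effect strength: 0 < r <= 1
check_strength <- function(r) {
  check_scalar(r, "r")
  if (r <= 0 || r > 1) {
    stop_domain(sprintf("`r` must satisfy 0 < r <= 1, got %g.", r))
  }
  invisible(r)
}

check_count <- function(x, name = deparse(substitute(x)), min = 1L) {
  check_scalar(x, name)
  if (x < min || x != as.integer(x)) {
    stop_domain(sprintf("`%s` must be an integer >= %d, got %g.", name, min, x))
  }
  invisible(as.integer(x))
}

check_numeric_vector <- function(x, name = deparse(substitute(x)), min_length = 1L) {
  if (!is.numeric(x) || length(x) < min_length) {
    stop_domain(sprintf("`%s` must be a numeric vector of length >= %d.",
                        name, min_length))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_domain(sprintf("`%s` contains missing or non-finite values.", name))
  }
  invisible(x)
}

check_same_length <- function(x, y, name_x, name_y) {
  if (length(x) != length(y)) {
    stop_domain(sprintf("`%s` (length %d) and `%s` (length %d) must have equal lengths.",
                        name_x, length(x), name_y, length(y)))
  }
  invisible(NULL)
}
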