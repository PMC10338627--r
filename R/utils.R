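# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded generators never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# One sub-seed per simulated unit (cell, bead, replicate), drawn sequentially
# from the master seed.  Because the draws are sequential, growing `n` keeps
# the first seeds -- and therefore the first units -- bitwise identical.
derive_stream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n, replace = TRUE))
}

# Configuration validation that names the offending field.
check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Normalize a 2-vector to unit length; errors on the zero vector.
unit_vector <- function(v, field = "gradient_axis") {
  check_field(is.numeric(v) && length(v) == 2L && all(is.finite(v)),
              field, "must be a finite 2-vector")
  nrm <- sqrt(sum(v^2))
  check_field(nrm > 0, field, "must be nonzero")
  v / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
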