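# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed error so callers/tests can condition on failure kind without
# matching message text.
cs_stop <- function(msg, class, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "cellstream_error")))
}

cs_notice <- function(msg, ...) {
  message(sprintf(msg, ...))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library functions never disturb user-level randomness.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= min
}

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

as_point3 <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    cs_stop("`%s` must be a finite numeric 3-vector", "cellstream_parameter_error",
            what)
  }
  x
}

# Squared Euclidean distances between rows of a (m x 3) and rows of b
# (n x 3). Per-coordinate differences, not the |a|^2 + |b|^2 - 2ab
# expansion, so nearby points keep full precision.
cross_dist2 <- function(a, b) {
  outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2 +
    outer(a[, 3], b[, 3], `-`)^2
}

cross_dist <- function(a, b) {
  sqrt(cross_dist2(a, b))
}
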