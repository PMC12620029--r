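`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards. All generators in the package route
# their randomness through this so that identical configs give bit-identical
# output and library users' RNG is never disturbed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_fraction <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(name, " must be finite numeric", call. = FALSE)
  lo <- if (open) x > 0 else x >= 0
  hi <- if (open) x < 1 else x <= 1
  if (!all(lo & hi))
    stop(name, " must lie in ", if (open) "(0,1)" else "[0,1]", call. = FALSE)
  invisible(x)
}

# spawn a sub-seed for stage `k` from a master seed, kept below 2^31
sub_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483629L
}
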