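# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring
# whatever global .Random.seed existed before.  All package randomness
# flows through this: no function leaves the user's RNG state disturbed.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, positive = TRUE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stopf("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Strictly increasing integer frame indices, all inside [1, n_frames].
check_frames <- function(frames, n_frames, name = "frames") {
  if (length(frames) == 0L) return(integer())
  frames <- as.integer(frames)
  if (anyNA(frames)) stopf("'%s' contains NA", name)
  if (any(diff(frames) <= 0)) stopf("'%s' must be strictly increasing", name)
  if (frames[1L] < 1L || frames[length(frames)] > n_frames)
    stopf("'%s' must lie within [1, %d]; got range [%d, %d]",
          name, n_frames, frames[1L], frames[length(frames)])
  frames
}
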