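# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps all package randomness (weight
# init, shuffles, synthetic data) insulated from user code.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Stack a list of samples' images (or masks) into a batch array with dims
# (spatial..., C, N). Images carry a channel axis; masks do not, so masks
# get a singleton channel axis first.
stackImages <- function(samples) {
  d <- dim(samples[[1]]$image)
  n <- length(samples)
  out <- array(0, c(d, n))
  per <- prod(d)
  for (i in seq_len(n)) out[(i - 1) * per + seq_len(per)] <-
      samples[[i]]$image
  out
}

stackMasks <- function(samples) {
  d <- dim(samples[[1]]$mask)
  out <- array(0, c(d, 1L, length(samples)))
  n <- length(samples)
  per <- prod(d)
  for (i in seq_len(n)) out[(i - 1) * per + seq_len(per)] <- samples[[i]]$mask
  out
}

# spatial dims of an activation array (last two axes are channel, batch)
spatialDims <- function(x) {
  d <- dim(x)
  d[seq_len(length(d) - 2L)]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

isCount <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x >= 1
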