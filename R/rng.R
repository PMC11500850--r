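# Independent reproducible RNG streams.
#
# The simulator keeps world sampling, sensory noise and policy sampling on
# separate streams derived from one master seed, so e.g. turning the gaze
# controller on or off never perturbs the generated world geometry. A stream
# is an environment carrying a saved Mersenne-Twister state; draws swap the
# state into .Random.seed and save it back afterwards.

#' Create a reproducible RNG stream
#'
#' @param seed Integer seed for the stream.
#' @return An object of class `rng_stream`.
#' @examples
#' s <- rng_stream(1)
#' stream_runif(s, 3)
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed) %% 2147483647L, kind = "Mersenne-Twister")
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

#' @rdname rng_stream
#' @param stream An `rng_stream`.
#' @param n Number of draws.
#' @export
stream_runif <- function(stream, n, min = 0, max = 1) {
  with_stream(stream, runif(n, min, max))
}

#' @rdname rng_stream
#' @param min,max,mean,sd Distribution parameters.
#' @export
stream_rnorm <- function(stream, n, mean = 0, sd = 1) {
  with_stream(stream, rnorm(n, mean, sd))
}

#' @rdname rng_stream
#' @param x Vector to sample from.
#' @param size Number of elements to draw.
#' @param replace Sample with replacement?
#' @export
stream_sample <- function(stream, x, size = 1, replace = FALSE) {
  with_stream(stream, sample(x, size, replace = replace))
}

# Integer in [lo, hi], inclusive.
stream_int <- function(stream, lo, hi) {
  as.integer(lo + floor(stream_runif(stream, 1) * (hi - lo + 1L)))
}

# Deterministic child seeds below 2^31, spread by a large prime.
derive_seed <- function(master, offset) {
  (as.numeric(master) * 48271 + 7919 * offset) %% 2147483647
}

# The three named streams every simulation component draws from.
make_streams <- function(seed) {
  list(
    world = rng_stream(derive_seed(seed, 1)),
    noise = rng_stream(derive_seed(seed, 2)),
    policy = rng_stream(derive_seed(seed, 3))
  )
}
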