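#' Independent reproducible random-number streams
#'
#' Derives `n` statistically independent L'Ecuyer-CMRG streams from a single
#' root seed. Each component of the closed loop (truth plant, state particle
#' filter, backward ancestor sampler, control particle filter) owns one
#' stream, so that enabling or disabling one component never perturbs the
#' random draws consumed by another.
#'
#' @param seed integer root seed.
#' @param n number of streams to derive.
#' @param names optional character names for the streams.
#' @return A list of `rng_stream` objects.
#' @seealso [with_stream()]
#' @examples
#' s <- rng_streams(42, 2, c("truth", "filter"))
#' a <- with_stream(s$truth, rnorm(3))
#' b <- with_stream(s$truth, rnorm(3))   # continues the same stream
#' @export
rng_streams <- function(seed, n = 4L, names = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), n >= 1L)
  old <- get_random_seed()
  on.exit(set_random_seed(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647L), kind = "L'Ecuyer-CMRG")
  state <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    state <- parallel::nextRNGStream(state)
    streams[[i]] <- new_rng_stream(state)
  }
  if (!is.null(names)) names(streams) <- names
  streams
}

new_rng_stream <- function(state) {
  e <- new.env(parent = emptyenv())
  e$state <- state
  class(e) <- "rng_stream"
  e
}

get_random_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

set_random_seed <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
  invisible(seed)
}

#' Evaluate an expression under a given RNG stream
#'
#' Temporarily installs the stream's state as R's generator state, evaluates
#' `expr`, saves the advanced state back into the stream, and restores
#' whatever generator state was active before the call. With `stream = NULL`
#' the expression is evaluated under the ambient generator.
#'
#' @param stream an `rng_stream` from [rng_streams()], or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  if (is.null(stream)) {
    return(expr)
  }
  stopifnot(inherits(stream, "rng_stream"))
  old <- get_random_seed()
  set_random_seed(stream$state)
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    set_random_seed(old)
  }, add = TRUE)
  expr
}
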