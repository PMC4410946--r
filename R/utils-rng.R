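# RNG plumbing shared by the samplers and solvers.

# evaluate `expr` under a temporary seed, restoring the caller's RNG state
local_rng <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Stable string hash folded with the master seed, kept below 2^31 so the
#' result is a valid integer seed. Used to give every sampler (and every
#' chain within the population sampler) its own independent stream: adding a
#' sampler or chain never perturbs the draws of another.
#'
#' @param master Integer master seed.
#' @param ... Labels (coerced to character) identifying the stream.
#' @return A positive integer seed.
#' @export
#' @examples
#' seed_from(1, "chain", 2)
seed_from <- function(master, ...) {
  label <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  h <- (h + (as.numeric(master) %% 2147483647) * 7919) %% 2147483647
  as.integer(h + 1)
}

# mutable RNG stream: a saved .Random.seed advanced on demand
new_rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local_rng(seed, get(".Random.seed", envir = globalenv()))
  env
}

# run fn() under the stream's RNG state, saving the advanced state back;
# the ambient RNG state is untouched
stream_eval <- function(stream, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  res <- fn()
  stream$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  res
}
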