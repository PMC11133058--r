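# Deterministic named RNG substreams derived from one master seed.
#
# Every stochastic stage of list generation (clustering, per-list studied-item
# sampling, lure draws, target draws) owns its own stream, so running the
# feasibility simulation or reordering stages can never perturb the numbers a
# real generation run produces from the same master seed.

.fmg_hash <- function(name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  h
}

# seed arithmetic kept below 2^31 - 1 (and exact in doubles)
fmg_substream_seed <- function(master, name) {
  m <- as.numeric(master) %% 2147483647
  (((m * 16807) %% 2147483647) + .fmg_hash(name)) %% 2147483647
}

#' Create an independent random-number stream
#'
#' A stream captures the state of R's default generator seeded with
#' \code{seed}; draws taken through [with_stream()] advance the stream
#' without touching the global \code{.Random.seed}.
#'
#' @param seed integer scalar.
#' @return An object of class \code{fmg_rng}.
#' @keywords internal
new_rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "fmg_rng"
  e
}

#' Evaluate an expression under a stream's RNG state
#'
#' Swaps the stream state into the global generator for the duration of
#' \code{expr}, then swaps the (advanced) state back out, restoring whatever
#' global state existed before.
#'
#' @param stream an \code{fmg_rng} stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "fmg_rng"))
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
  expr
}

# coerce a bare integer seed into a stream where convenient
as_rng_stream <- function(rng) {
  if (inherits(rng, "fmg_rng")) rng else new_rng_stream(rng)
}
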