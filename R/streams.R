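#' Independent random-number substreams for reproducible replication
#'
#' Each Monte-Carlo replicate of a scenario draws from its own
#' L'Ecuyer-CMRG stream spawned deterministically from the master seed.
#' Within a replicate, a dataset discarded by the no-events rule advances
#' to the next *sub*stream of the same stream, so replicate r is
#' bit-reproducible no matter how many discards occur in other replicates
#' and results are invariant to execution order across workers.
#'
#' @param seed Master seed (integer).
#' @param n Number of streams to spawn.
#' @return A list of `n` L'Ecuyer-CMRG state vectors usable as
#'   `.Random.seed`.
#' @examples
#' s <- sw_streams(42, 3)
#' length(s)
#' @export
sw_streams <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  state <- local({
    okind <- RNGkind()
    oseed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      RNGkind(okind[1], okind[2], okind[3])
      if (!is.null(oseed)) assign(".Random.seed", oseed, envir = globalenv())
    })
    RNGkind("L'Ecuyer-CMRG")
    set.seed(as.integer(seed))
    get(".Random.seed", envir = globalenv())
  })
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    state <- parallel::nextRNGStream(state)
    streams[[i]] <- state
  }
  streams
}

# Evaluate `expr` with .Random.seed set to `stream`, restoring the caller's
# RNG state afterwards. Returns list(value, state) where state is the
# advanced stream, so a caller can continue consuming the same stream.
with_stream <- function(stream, expr) {
  oseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  okind <- RNGkind()
  on.exit({
    RNGkind(okind[1], okind[2], okind[3])
    if (!is.null(oseed)) assign(".Random.seed", oseed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  assign(".Random.seed", stream, envir = globalenv())
  value <- expr
  list(value = value,
       state = get(".Random.seed", envir = globalenv()))
}
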