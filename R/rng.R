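# Reproducible substreams: one master seed spawns independent L'Ecuyer-CMRG
# streams, one per replicate, so replicates are reproducible individually and
# give identical results whether run serially or in parallel.

#' Spawn independent RNG substreams from a master seed
#'
#' @param seed Master seed (integer).
#' @param n Number of substreams.
#' @return A list of `n` L'Ecuyer-CMRG `.Random.seed` states.
#' @keywords internal
make_rng_streams <- function(seed, n) {
  stopifnot(n >= 0)
  old <- globalenv()$.Random.seed
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  streams <- vector("list", n)
  s <- globalenv()$.Random.seed
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

#' Evaluate an expression under a given RNG state
#'
#' Restores the caller's RNG state afterwards.
#' @keywords internal
with_rng_stream <- function(stream, expr) {
  old <- globalenv()$.Random.seed
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  assign(".Random.seed", stream, envir = globalenv())
  expr
}
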