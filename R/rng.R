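# Seeding contract: one master seed; every replicate/block derives its own
# stream seed through a deterministic mix, so block-level parallelism or
# reordering cannot change results.

#' Derive a per-unit seed from a master seed
#'
#' Deterministic 31-bit mix of `(master, id)` (a Lehmer step plus a
#' Weyl-style offset).  Used for per-replicate and per-block streams.
#'
#' @param master Master seed (integer).
#' @param id Unit identifier (replicate or block index).
#' @return A positive integer < 2^31 suitable for `set.seed()`.
#' @export
derive_seed <- function(master, id) {
  m <- 2147483647
  x <- (as.double(master) %% m + 1) * 48271 %% m
  x <- (x + as.double(id) * 2654435761) %% m
  x <- (x * 48271) %% m
  as.integer(x %% (m - 1)) + 1L
}
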