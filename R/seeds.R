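# Seed plumbing: one master seed fans out deterministically to sub-streams so
# that e.g. herd sizes and gait draws do not share a stream.

derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # LCG-style mix kept below 2^31 so the result is a valid R integer seed
  as.integer((abs(seed) * 48271 + stream * 16807) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
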