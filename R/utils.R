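# Seed derivation: every source of randomness flows from the user seed, a
# replicate id and a named stream, so replicates are independent and capture
# decisions are reproducible separately from the thermal noise.
# Streams: 0 thermal (extrusion), 1 loading, 2 capture, 3 chain generation,
# 4 equilibration thermal.
derive_seed <- function(seed, replicate = 1, stream = 0) {
  s <- (as.numeric(seed) * 48271 + as.numeric(replicate) * 100003 +
          as.numeric(stream) * 7919) %% 2147483647
  as.integer(s) + 1L
}

# run code under a temporary R RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
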