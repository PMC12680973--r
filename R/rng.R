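# Named, independent RNG substreams so that, e.g., changing how negatives are
# sampled cannot perturb weight initialization. Each stream owns a saved
# .Random.seed; draws swap it in, run, and swap it back out.

new_streams <- function(seed, names) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  env <- new.env(parent = emptyenv())
  base <- as.integer(seed %% 1000003L)
  for (i in seq_along(names)) {
    set.seed(base * 277L + i * 7919L)
    assign(names[i], get(".Random.seed", envir = globalenv()), envir = env)
  }
  env
}

with_stream <- function(streams, name, expr) {
  if (!exists(name, envir = streams))
    abort(paste0("unknown RNG stream: ", name))
  had_seed <- exists(".Random.seed", envir = globalenv())
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}
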