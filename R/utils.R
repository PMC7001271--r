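`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state and restore the caller's state.
# One named, versioned generator is used for all simulation code so that
# seeds recorded in output metadata fully determine the draw.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

rng_description <- function() {
  "Mersenne-Twister/Inversion/Rejection"
}

# sample() without its length-1 surprise
sample_one <- function(x) {
  if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
}
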