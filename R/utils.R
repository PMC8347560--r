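# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used by every stochastic operation so outputs are reproducible from
# (inputs, seed) alone.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Uniform integer draw on [lo, hi]; `by` restricts to multiples of `by`
# measured from lo (used for CDS lengths, which must be multiples of 3).
sample_int_range <- function(n, lo, hi, by = 1L) {
  k <- (hi - lo) %/% by
  lo + by * sample.int(k + 1L, n, replace = TRUE) - by
}

motif_key <- function(x) paste(x$transcript_id, x$start, x$end, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
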