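#' @keywords internal
"_PACKAGE"

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  force(seed)  # evaluate before saving RNG state (the seed may itself be random)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a reproducible child seed from a base seed and a stream index,
## staying inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
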