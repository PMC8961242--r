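#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so library code never disturbs the session stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stopifnot3d <- function(x, what = "volume") {
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop(what, " must be a 3D array", call. = FALSE)
  invisible(x)
}

# Derive a stream of sub-seeds from one master seed, keeping values well
# inside the 32-bit integer range.
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max %/% 2L, n))
}
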