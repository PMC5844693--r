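# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# package-classed error so callers can test for named failures
err <- function(msg, class = "tiltnorm_error") {
  stop(errorCondition(msg, class = c(class, "tiltnorm_error")))
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards. All randomness in the package flows through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(abs(seed) %% (.Machine$integer.max - 1L)))
  force(code)
}

# derive a reproducible 31-bit sub-seed from a base seed and a stream label
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% (.Machine$integer.max - 1L))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
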