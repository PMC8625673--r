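# Internal validation and RNG helpers.

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper),
          class = "aldaphen_invalid_parameter")
  }
  invisible(x)
}

assert_proportion <- function(x, name) assert_scalar_number(x, name, 0, 1)

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, lower),
          class = "aldaphen_invalid_parameter")
  }
  invisible(as.integer(x))
}

# Round half away from zero (the Alda A continuum is an integer 0-10 scale;
# base round() would round halves to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Deterministic sub-stream seed derived from a global seed and a stream label.
# Keeps every derived seed inside the 32-bit integer range.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

with_substream <- function(seed, stream, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}
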