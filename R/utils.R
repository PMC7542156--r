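# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## All user-facing randomness in the package flows through this so that a
## single master seed pins an entire run.
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic child seed; kept below 2^31 - 1.
derive_seed <- function(base, i) {
  as.integer((as.numeric(base) + 1000 * as.numeric(i)) %% (.Machine$integer.max - 1L))
}

## Flags mark degenerate-input fallbacks (constant channels, no spectral peaks,
## entropy sentinels) without poisoning downstream numerics with NaN.
set_flag <- function(x, flag) {
  attr(x, "flags") <- unique(c(attr(x, "flags"), flag))
  x
}

get_flags <- function(x) attr(x, "flags") %||% character(0)

has_flag <- function(x, flag) flag %in% get_flags(x)

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

CHANNELS <- c("X", "Y", "Z")
## Cyclic channel->pair assignment for the two cross-channel features and
## cross-sample entropy: X pairs with Y, Y with Z, Z with X.
CHANNEL_PAIR <- c(X = "Y", Y = "Z", Z = "X")
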