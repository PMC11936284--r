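# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code with a temporary RNG state seeded at `seed`; the caller's
# .Random.seed is restored on exit so generation never leaks global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Half-up rounding to `digits` decimals (base round() is round-half-even;
# published descriptive tables use half-up).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Case-insensitive, whitespace/punctuation-collapsed key for drug matching.
normalize_drug_name <- function(x) {
  x <- toupper(x)
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

assert_prob_vector <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0))
    stop(sprintf("%s must be nonnegative and finite", what), call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)), call. = FALSE)
  invisible(p)
}
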