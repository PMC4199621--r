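# Internal helpers shared across modules.

# Scalar default operator that also treats a length-1 NA as missing.
`%||%` <- function(x, y) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) y else x
}

# Deterministic polynomial rolling hash of a character string, in
# [0, 2147483647). Kept in pure R double arithmetic: intermediate values stay
# below 2^53 so the modulo is exact.
str_hash <- function(s) {
  p <- 2147483647
  h <- 0
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% p
  }
  h
}

# Combine integer hash values order-independently sensitive to multiplicity:
# hash of the sorted, concatenated decimal representations.
hash_combine <- function(values) {
  str_hash(paste(values, collapse = ","))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be a whole number, got %s.", name, x))
  }
  invisible(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot_scalar_number(seed, "seed", integerish = TRUE)
  withr::with_seed(as.integer(seed), code)
}
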