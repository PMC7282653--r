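# Internal validation and seeding helpers.

stop_invalid <- function(msg) abort(msg, class = "fracret_invalid_parameter")
stop_domain <- function(msg) abort(msg, class = "fracret_domain_error")
stop_data <- function(msg) abort(msg, class = "fracret_data_error")

check_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

check_prob_open <- function(p, name) {
  check_scalar_finite(p, name)
  if (p <= 0 || p >= 1) {
    stop_domain(sprintf("`%s` must lie strictly between 0 and 1.", name))
  }
  invisible(p)
}

check_positive <- function(x, name) {
  check_scalar_finite(x, name)
  if (x <= 0) stop_invalid(sprintf("`%s` must be strictly positive.", name))
  invisible(x)
}

check_count <- function(n, name, min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < min ||
      n != trunc(n)) {
    stop_domain(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(n))
}

# Deterministic substream seeds from one user-facing seed. Arithmetic stays
# below 2^53 so the double-precision modular reduction is exact, and results
# stay below 2^31 - 1 as required by set.seed().
derive_seed <- function(seed, k) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  h <- (s * 69069 + 12345) %% m
  h <- (h * 2 + 1 + as.numeric(k) * 104729) %% m
  as.integer(h)
}

# Set the RNG from a substream seed, or leave the session RNG alone when the
# user supplied no seed.
seed_stream <- function(seed, k) {
  if (!is.null(seed)) set.seed(derive_seed(seed, k))
  invisible(NULL)
}
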