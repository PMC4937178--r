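# Internal helpers shared across modules.

# Validation failures carry class "cardiofit_validation_error" so the CLI can
# map them to exit status 2 without string-matching messages.
cf_abort <- function(message, class = "cardiofit_validation_error", ...) {
  rlang::abort(message, class = c(class, "cardiofit_error"), ...)
}

cf_assert <- function(cond, message) {
  if (!isTRUE(cond)) cf_abort(message)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards, so generators are pure functions of their seed.
with_seed <- function(seed, code) {
  cf_assert(is_number(seed) && seed == trunc(seed),
            "`seed` must be a single integer.")
  withr::with_seed(as.integer(seed), code)
}

# Fan a user seed out to per-component substreams so that adding a generator
# never perturbs an existing one. Keeps results within 32-bit integer range.
substream_seed <- function(seed, stream) {
  offsets <- c(bout = 11L, squat = 23L, treadmill = 37L, cohort = 51L,
               steps = 67L, persona = 83L)
  off <- offsets[[stream]]
  as.integer((as.double(seed) * 7919 + off * 104729) %% 2147483629)
}
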