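# RNG scoping: functions that take an explicit seed must not clobber the
# caller's RNG stream; seed = NULL means "use the current stream".
local_rng <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer or NULL")
  }
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}

# Derive a stream of child seeds from one master seed (32-bit signed range).
derive_seeds <- function(seed, n) {
  local_rng(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
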