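# internal helpers shared across modules

# Structured errors: every user-facing precondition failure carries a
# condition subclass so callers (and tests) can match on it.
eeg_abort <- function(subclass, msg, call = sys.call(-1)) {
  stop(structure(
    list(message = msg, call = call),
    class = c(subclass, "eegdwt_error", "error", "condition")
  ))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-participant substream seed, kept below 2^31 - 1.
participant_seed <- function(seed, participant_id) {
  as.integer((as.double(seed) * 1009 + as.double(participant_id) * 9973) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
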