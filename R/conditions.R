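# Classed conditions so callers/tests can distinguish validation failures
# from parse failures without matching message strings.

abort_reopairs <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "reopairs_error"), call = call))
}

abort_validation <- function(msg) abort_reopairs(msg, "reopairs_validation_error")
abort_parse <- function(msg) abort_reopairs(msg, "reopairs_parse_error")

# Seed handling: every stochastic operation runs under a local RNG state so
# package calls never clobber the caller's .Random.seed. Sub-streams are
# derived deterministically from a base seed, kept inside 32-bit range.
with_local_seed <- function(seed, expr) {
  if (!is.null(get0(".Random.seed", envir = globalenv()))) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (!is.null(get0(".Random.seed", envir = globalenv()))) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483647L)
}
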