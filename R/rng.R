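# Seeded random streams isolated from the caller's RNG state.
#
# Every stochastic operation in the package takes its randomness from an
# explicit stream object rather than the global generator, so simulations
# are reproducible given a seed and never disturb user code. A stream
# carries its own .Random.seed, swapped in around each draw.

local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed %% .Machine$integer.max)
  state_env <- new.env(parent = emptyenv())
  with_state <- function(fn) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    if (is.null(state_env$state)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", state_env$state, envir = globalenv())
    }
    on.exit({
      state_env$state <- get(".Random.seed", envir = globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    fn()
  }
  list(
    seed = seed,
    norm = function(n, mean = 0, sd = 1) {
      with_state(function() stats::rnorm(n, mean, sd))
    },
    lnorm = function(n, meanlog = 0, sdlog = 1) {
      with_state(function() stats::rlnorm(n, meanlog, sdlog))
    },
    int = function(n, max) {
      with_state(function() sample.int(max, n, replace = TRUE))
    }
  )
}

# Deterministic child seeds for independent sub-streams (one per animal).
derive_subseeds <- function(seed, n) {
  local_rng(seed)$int(n, .Machine$integer.max - 1L)
}
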