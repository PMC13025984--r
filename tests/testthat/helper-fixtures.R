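# Shared fixtures and independent oracles for the test suite.  Expensive
# objects (enumerated universes) are built once per run.

fixture_env <- new.env(parent = emptyenv())

default_universe <- function() {
  if (is.null(fixture_env$universe))
    fixture_env$universe <- enumerate_universe(micro_interpreter(), L = 22L)
  fixture_env$universe
}

default_pair_universe <- function() {
  if (is.null(fixture_env$pairs))
    fixture_env$pairs <- build_pair_universe(L_pair = 30L, horizon = 8L)
  fixture_env$pairs
}

# Direct implementation of the LZ76 exhaustive production history: each
# phrase is the shortest extension not reproducible (as a substring, with
# overlap) from everything before its last symbol; the terminal phrase is
# counted even if reproducible.  Quadratic and obviously correct -- the
# independent oracle for the C++ parser.
lz76_oracle <- function(s) {
  s <- paste(as_symbols(s), collapse = "")
  n <- nchar(s)
  p <- 1L
  cnt <- 0L
  while (p <= n) {
    m <- 1L
    while (p + m <= n &&
           grepl(substr(s, p, p + m - 1L),
                 substr(s, 1L, p + m - 2L), fixed = TRUE)) {
      m <- m + 1L
    }
    cnt <- cnt + 1L
    p <- p + m
  }
  cnt
}

# Random transducer pair with complementary alphabets, for property tests.
random_machine_pair <- function(max_states = 3L, max_alphabet = 3L) {
  S1 <- sample.int(max_states, 1L)
  S2 <- sample.int(max_states, 1L)
  a <- sample.int(max_alphabet, 1L)
  b <- sample.int(max_alphabet, 1L)
  mk <- function(S, ai, ao) {
    transducer(S, ai, ao,
               transition = sample.int(S, S * ai, replace = TRUE) - 1L,
               emission = sample.int(ao, S * ai, replace = TRUE) - 1L,
               initial_state = sample.int(S, 1L) - 1L,
               initial_emission = sample.int(ao, 1L) - 1L)
  }
  list(world = mk(S1, a, b), regulator = mk(S2, b, a))
}
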