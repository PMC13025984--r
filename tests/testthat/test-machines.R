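test_that("canonical code round-trips and is self-delimiting", {
  set.seed(101)
  for (i in 1:40) {
    spec <- random_machine_pair()$world
    bits <- encode_program(spec)
    expect_length(bits, program_length(spec))
    dec <- decode_program(c(bits, sample(0:1, 7, replace = TRUE)))
    expect_identical(dec$consumed, length(bits))      # prefix property
    expect_identical(encode_program(dec$spec), bits)  # round trip
  }
  # determinism: structurally identical specs encode identically
  a <- transducer(2, 2, 2, matrix(c(0L, 1L, 1L, 0L), 2), matrix(0:1, 2, 2))
  b <- transducer(2, 2, 2, matrix(c(0L, 1L, 1L, 0L), 2), matrix(0:1, 2, 2))
  expect_identical(encode_program(a), encode_program(b))
})

test_that("code length matches an independent hand count of the layout", {
  # 2-state binary machine: gamma(2) three times (3 bits each) + 1-bit
  # initial state + 1-bit initial emission + 4 table entries of (1+1) bits
  spec <- transducer(2, 2, 2, matrix(0L, 2, 2), matrix(0L, 2, 2))
  expect_identical(length(encode_program(spec)), 3L + 3L + 3L + 1L + 1L + 8L)
  # 1-state binary machine: 1 + 3 + 3 + 0 + 1 + 2 * (0 + 1)
  expect_identical(program_length(null_regulator(2)), 10L)
})

test_that("malformed codes give the invalid-program signal, never a crash", {
  expect_null(decode_program(integer(0)))
  bits <- encode_program(null_regulator(2))
  expect_null(decode_program(bits[1:4]))            # truncated
  for (i in seq_along(bits)) {                      # every 1-bit flip
    flipped <- bits
    flipped[i] <- 1L - flipped[i]
    res <- decode_program(flipped)
    if (!is.null(res)) expect_s3_class(res$spec, "transducer")
  }
})

test_that("oversized machines are rejected with the configured limit", {
  spec <- transducer(1, 1, 2, matrix(0L, 1, 1), matrix(0L, 1, 1))
  spec$output_alphabet_size <- 100000L
  expect_error(encode_program(spec), "64")
})

test_that("episode semantics are causal, deterministic and null-consistent", {
  # constant-0 world ignores any regulator
  set.seed(7)
  reg <- transducer(2, 2, 2, matrix(sample(0:1, 4, TRUE), 2),
                    matrix(sample(0:1, 4, TRUE), 2))
  const0 <- null_regulator(2)
  expect_identical(run_episode(const0, reg, 20)$w_out, rep(0L, 20))
  # echo world (emits last input) driven by the null regulator
  echo <- transducer(1, 2, 2, matrix(0L, 1, 2), matrix(0:1, 1, 2),
                     initial_emission = 1L)
  expect_identical(run_episode(echo, null_regulator(2), 6)$w_out,
                   c(1L, rep(0L, 5)))
  # determinism and causality: shorter horizons are exact prefixes
  for (i in 1:20) {
    p <- random_machine_pair()
    full <- run_episode(p$world, p$regulator, 30)
    expect_identical(run_episode(p$world, p$regulator, 30)$w_out, full$w_out)
    for (tcut in c(1L, 7L, 29L)) {
      part <- run_episode(p$world, p$regulator, tcut)
      expect_identical(part$w_out, full$w_out[seq_len(tcut)])
      expect_identical(part$r_out, full$r_out[seq_len(tcut)])
    }
  }
  expect_error(run_episode(null_regulator(3), null_regulator(2), 5),
               "alphabet mismatch")
})

test_that("null regulator is a minimal-length one-state machine", {
  for (ao in 1:3) {
    null_len <- program_length(null_regulator(ao))
    # every 1-state spec over the same alphabets has the same (fixed-width)
    # code length, so the null machine attains the minimum
    lens <- c()
    for (ie in 0:(ao - 1)) {
      em <- expand.grid(rep(list(0:(ao - 1)), ao))
      for (r in seq_len(nrow(em))) {
        s <- transducer(1, ao, ao, matrix(0L, 1, ao),
                        matrix(as.integer(em[r, ]), 1, ao),
                        initial_emission = ie)
        lens <- c(lens, program_length(s))
      }
    }
    expect_identical(min(lens), null_len)
  }
  set.seed(11)
  p <- random_machine_pair(max_alphabet = 2)
  off <- run_episode(p$world, null_regulator(p$world$input_alphabet_size,
                                             p$world$output_alphabet_size),
                     16)
  expect_identical(off$r_out, rep(0L, 16))
})

test_that("sample_program follows the prefix prior", {
  draws <- sample_program(13, rng_seed = 42, n = 50000,
                          max_states = 3, max_alphabet = 3)
  lens <- vapply(draws, program_length, integer(1))
  # two specific specs of equal length 10 must appear about equally often
  key <- vapply(draws, function(s)
    paste0(s$n_states, s$input_alphabet_size, s$output_alphabet_size, ":",
           s$initial_emission, paste(s$emission, collapse = "")), "")
  n1 <- sum(key == "122:000")
  n2 <- sum(key == "122:101")
  se <- sqrt(n1 + n2)
  expect_lt(abs(n1 - n2), 3 * se + 1)
  # length-l specs should outnumber length-(l+2) specs about 4:1
  f10 <- sum(lens == 10) / 8      # 8 specs of length 10 (shape 1,2,2)
  f12 <- sum(lens == 12) / 32     # 32 specs of length 12 (shape 2,2,1)
  expect_lt(abs(f10 / f12 - 4), 1)
  # seeded reproducibility
  again <- sample_program(13, rng_seed = 42, n = 50000,
                          max_states = 3, max_alphabet = 3)
  expect_identical(vapply(again, program_length, integer(1)), lens)
  expect_error(sample_program(2), "too small")
})

test_that("quantised thermostat world cycles with the bang-bang regulator", {
  w <- thermostat_world_spec(16, initial_level = 2)
  r <- bang_bang_spec(16, low = 6, high = 10)
  tr <- run_episode(w, r, 200)
  per <- tail_period(tr$w_out, max_period = 32)
  expect_false(is.na(per))
  expect_gte(per, 2)
  # the level stays inside the hysteresis corridor after burn-in
  expect_true(all(tr$w_out[100:200] >= 5 & tr$w_out[100:200] <= 11))
})

test_that("transcripts and machine specs round-trip through files", {
  p <- random_machine_pair(max_alphabet = 2)
  tr <- run_episode(p$world, p$regulator, 25)
  f <- tempfile(fileext = ".csv")
  write_transcript(tr, f, meta = list(seed = 1))
  back <- read_transcript(f)
  expect_identical(back$w_out, tr$w_out)
  expect_identical(back$r_out, tr$r_out)
  fj <- tempfile(fileext = ".json")
  transducer_to_json(p$world, fj)
  expect_identical(encode_program(transducer_from_json(fj)),
                   encode_program(p$world))
  fl <- tempfile(fileext = ".jsonl")
  write_transcript_jsonl(tr, fl)
  expect_identical(length(readLines(fl)), 26L)
})
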