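test_that("the pair universe has the closed-form product structure", {
  u <- default_pair_universe()
  # one-state binary machines: 2 initial emissions x 4 emission tables = 8
  # specs, hence 8 x 8 ordered pairs, all admitted at the default bound
  expect_identical(length(u$specs), 8L)
  expect_identical(nrow(u$pairs), 64L)
  expect_true(u$readouts$meta$total_units <= 2^u$L_pair)
  # stored ON readouts are reproduced by re-running the coupled episode
  for (p in sample.int(nrow(u$pairs), 20)) {
    row <- u$pairs[p, ]
    rerun <- run_episode(u$specs[[row$w]], u$specs[[row$r]], u$horizon)
    expect_identical(paste(rerun$w_out, collapse = ""), row$x)
  }
  # the OFF readout depends only on the world
  off_by_w <- tapply(u$pairs$y, u$pairs$w, unique)
  expect_true(all(lengths(off_by_w) == 1L))
})

test_that("posteriors match the closed form and sum to exactly one", {
  u <- default_pair_universe()
  for (x in readout_suite(u, 6)) {
    rec <- posterior_given_x(u, x)
    expect_gt(nrow(rec), 0)
    # normalisation is exact in integer mass units
    expect_identical(sum(rec$mass_units),
                     m_exact(u$readouts, x) * 2^u$L_pair)
    expect_equal(sum(rec$posterior), 1)
    # prior form: posterior ratios follow code-length differences (up to
    # the truncated prologue series, a relative 2^-(L_pair - |p|) effect)
    if (nrow(rec) >= 2) {
      i <- which.min(rec$joint_bits)
      j <- which.max(rec$joint_bits)
      expect_equal(rec$posterior[i] / rec$posterior[j],
                   2^(rec$joint_bits[j] - rec$joint_bits[i]),
                   tolerance = 1e-2)
    }
  }
  # a readout produced by a single pair carries the whole posterior
  singles <- u$readouts$entries$output[u$readouts$entries$n_programs == 1]
  if (length(singles) > 0)
    expect_equal(posterior_given_x(u, singles[1])$posterior, 1)
  expect_identical(nrow(posterior_given_x(u, "01001100")), 0L)
})

test_that("the tilt bound holds with a small, readout-stable constant", {
  u <- default_pair_universe()
  suite <- readout_suite(u, 12)
  expect_gte(length(suite), 10)
  cs <- vapply(suite, function(x) verify_theorem2(u, x)$C_star, 0)
  # the minimal constant is of one order across the suite
  expect_lte(max(cs) / min(cs), 4)
  # tautological check at C*: every pair obeys posterior <= C* 2^(M - D)
  v <- verify_theorem2(u, suite[1])
  expect_true(all(v$records$posterior <=
                    v$C_star * v$records$bound_rhs + 1e-12))
  # a pair with delta = 0 satisfies the bound already at C >= 1
  z <- v$records[v$records$delta_bits == 0, ]
  if (nrow(z) > 0)
    expect_true(all(z$posterior <= pmax(1, v$C_star) * 2^z$m_hat_bits))
  # raising delta at fixed M halves the reference bound per bit
  r1 <- v$records[1, ]
  expect_equal(2^(r1$m_hat_bits - (r1$delta_bits + 1)) / r1$bound_rhs, 0.5)
})

test_that("the posterior envelope halves per bit of (delta - m_hat)", {
  u <- default_pair_universe()
  pe <- posterior_envelope(u)
  expect_gte(nrow(pe$envelope), 2)
  expect_lte(pe$slope, -0.7)
  expect_gte(pe$slope, -1.3)
})

test_that("excess-length and mutual-information tails decay geometrically", {
  u <- default_pair_universe()
  for (x in readout_suite(u, 12)) {
    tc <- tail_curves(u, x)
    expect_lte(tc$excess$tail[1], 1)
    expect_equal(tc$excess$tail[1], 1)      # k = 0 includes everything
    expect_true(all(diff(tc$excess$tail) <= 1e-12))  # nested events
    expect_true(all(tc$mutual$tail >= 0 & tc$mutual$tail <= 1))
    expect_lte(tc$excess_slope, -0.8)
    expect_lte(tc$mutual_slope, -0.8)
  }
  # envelope form on the all-zero readout
  x0 <- strrep("0", u$horizon)
  cs <- verify_theorem2(u, x0)$C_star
  tc <- tail_curves(u, x0)
  expect_true(all(tc$excess$tail <= 2 * max(cs, 1) * 2^(-tc$excess$k)))
})

test_that("the Bayes-factor identity holds within the coding gap", {
  u <- default_pair_universe()
  suite <- readout_suite(u, 12)
  gaps <- coding_gap_report(u$readouts)
  for (x_on in suite[1:4]) {
    for (x_off in suite[1:4]) {
      bf <- bayes_factor(u, x_on, x_off)
      expect_lte(bf$residual, gaps$max_gap + 1e-9)
      if (identical(x_on, x_off)) expect_identical(bf$bits, 0)
    }
  }
  # antisymmetry under swapping ON and OFF
  b1 <- bayes_factor(u, suite[1], suite[3])
  b2 <- bayes_factor(u, suite[3], suite[1])
  expect_equal(b1$bits, -b2$bits)
  # absent readout gives the distinguished empty result
  expect_true(!is.null(bayes_factor(u, "01001100", suite[1])$absent))
})
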