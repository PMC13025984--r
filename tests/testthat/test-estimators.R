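test_that("LZ76 parser agrees with the direct exhaustive-history oracle", {
  expect_identical(lz76_complexity("0000000000"), 2L)
  expect_identical(lz76_complexity("01"), 2L)
  expect_identical(lz76_complexity("0101010101010101"), 3L)
  set.seed(202)
  for (i in 1:250) {
    n <- sample(1:60, 1)
    A <- sample(2:3, 1)
    s <- sample(0:(A - 1), n, replace = TRUE)
    expect_identical(lz76_complexity(s), lz76_oracle(s))
  }
  expect_error(lz76_complexity(integer(0)), "empty")
})

test_that("LZ76 phrase count is monotone under extension and relabeling-invariant", {
  set.seed(203)
  for (i in 1:200) {
    s <- sample(0:1, sample(2:80, 1), replace = TRUE)
    t <- sample(0:1, sample(1:40, 1), replace = TRUE)
    expect_lte(lz76_complexity(s), lz76_complexity(c(s, t)))
    expect_identical(lz76_complexity(s), lz76_complexity(1L - s))
  }
  # three-symbol relabeling
  s <- sample(0:2, 300, replace = TRUE)
  perm <- c(2L, 0L, 1L)
  expect_identical(lz76_complexity(s), lz76_complexity(perm[s + 1L]))
})

test_that("LZ76 codelength behaves at the compressible and trivial extremes", {
  cl <- lz76_codelength(rep(0L, 10000))
  expect_lte(cl$bits / 10000, 0.02)
  expect_gt(lz76_codelength(c(0L))$bits, 0)
  expect_gt(lz76_codelength(sample(0:1, 50, replace = TRUE))$bits, 0)
  # determinism of estimator + params + input
  s <- make_string("bernoulli", 500, seed = 9)
  expect_identical(lz76_codelength(s)$bits, lz76_codelength(s)$bits)
})

test_that("quantisation bins, clips and validates", {
  spec <- quantization_spec(4, 0, 1)
  expect_identical(quantize(rep(0.5, 6), spec), rep(2L, 6))
  expect_identical(quantize(c(0, 0.26, 0.51, 0.76), spec), c(0L, 1L, 2L, 3L))
  expect_identical(quantize(-5, spec), 0L)
  expect_identical(quantize(99, spec), 3L)
  expect_error(quantize(c(0.1, NaN), spec), "index 2")
  expect_error(quantization_spec(1), "levels")
})

test_that("closed-form entropy oracles evaluate correctly", {
  expect_identical(bernoulli_entropy(0.5), 1)
  expect_identical(bernoulli_entropy(0), 0)
  expect_identical(bernoulli_entropy(1), 0)
  expect_equal(bernoulli_entropy(0.1), 0.4690, tolerance = 1e-4)
  expect_error(bernoulli_entropy(1.2), "\\[0, 1\\]")
  expect_equal(gaussian_entropy_rate(1), 2.0471, tolerance = 1e-3)
  expect_equal(gaussian_entropy_rate(2) - gaussian_entropy_rate(1), 1)
  sig <- seq(0.2, 5, by = 0.3)
  expect_true(all(diff(gaussian_entropy_rate(sig)) > 0))
  expect_error(gaussian_entropy_rate(0), "positive")
})

test_that("codec adapter compresses deterministically through the registry", {
  zeros <- rep(0L, 10000)
  a <- codec_codelength(zeros, "gzip")
  expect_identical(a$bits, codec_codelength(zeros, "gzip")$bits)
  expect_lt(a$bits, 0.1 * 8 * length(zeros))
  set.seed(77)
  rnd <- sample(0:255, 10000, replace = TRUE)
  expect_gte(codec_codelength(rnd, "gzip")$bits, 0.9 * 8 * length(rnd))
  expect_error(codec_codelength(zeros, "nosuch"), "gzip")
  expect_identical(codelength(est_codec("xz"), zeros)$bits,
                   codec_codelength(zeros, "xz")$bits)
})

test_that("BDM reduces to the exact table at native size", {
  u <- default_universe()
  blk <- "01010101"
  kb <- k_exact(u, blk)
  one <- bdm_codelength(blk, u, block_size = 8)
  expect_identical(one$bits, as.numeric(kb))            # single block, + 0
  five <- bdm_codelength(strrep(blk, 5), u, block_size = 8)
  expect_equal(five$bits, kb + log2(5))                 # one distinct block
  # exhaustive: every native-size string scores exactly K_CTM
  outs <- u$entries$output[nchar(u$entries$output) == 8]
  expect_identical(length(outs), 256L)
  bd <- vapply(outs, function(x) bdm_codelength(x, u, 8)$bits, 0)
  expect_identical(unname(bd), as.numeric(k_exact(u, outs)))
  # trailing partial block is charged literally (flag + log2 A per symbol)
  with_tail <- bdm_codelength(paste0(blk, "001"), u, 8)
  expect_equal(with_tail$bits, kb + 1 + 3 * log2(2))
  expect_error(bdm_codelength("012", u, 3), "absent")
})
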