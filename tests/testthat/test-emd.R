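test_that("find_extrema locates interior extrema, plateaus and monotone cases", {
  # analytic extrema of a 2 Hz sine over 1 s
  t <- seq(0, 1, by = 1 / 100)
  ex <- find_extrema(sin(2 * pi * 2 * t))
  expect_length(ex$maxima, 2)
  expect_length(ex$minima, 2)

  expect_equal(find_extrema(seq_len(50)), list(maxima = integer(0), minima = integer(0)))

  # brute-force neighbour comparison on an alternating series
  ex <- find_extrema(c(0, 1, 0, -1, 0, 1, 0))
  expect_equal(ex$maxima, c(2L, 6L))
  expect_equal(ex$minima, 4L)

  # plateaus yield midpoint indices
  ex <- find_extrema(c(0, 2, 2, 2, 0, -1, -1, 0))
  expect_equal(ex$maxima, 3L)
  expect_equal(ex$minima, 6L)  # lower middle of the even run {6,7}

  # property: agrees with a brute-force scan on plateau-free random series
  set.seed(41)
  for (rep in 1:20) {
    x <- rnorm(60)
    ex <- find_extrema(x)
    brute_max <- which(vapply(2:59, function(i) {
      x[i] > x[i - 1] && x[i] > x[i + 1]
    }, logical(1))) + 1L
    brute_min <- which(vapply(2:59, function(i) {
      x[i] < x[i - 1] && x[i] < x[i + 1]
    }, logical(1))) + 1L
    expect_equal(ex$maxima, brute_max)
    expect_equal(ex$minima, brute_min)
  }
})

test_that("envelope mean is near zero for a sine and shifts with an offset", {
  t <- seq(0, 2, by = 1 / 128)[-1]
  s <- sin(2 * pi * 4 * t)
  m <- envelope_mean(s)
  inner <- seq.int(20, length(s) - 20)
  expect_lt(max(abs(m[inner])), 0.05)
  m2 <- envelope_mean(s + 3)
  expect_lt(max(abs(m2[inner] - 3)), 0.05)
})

test_that("envelope spline matches an independent dense not-a-knot solve", {
  set.seed(7)
  for (rep in 1:10) {
    xs <- sort(runif(10, 0, 20)) + seq(0, 9) * 0.5  # well-separated knots
    ys <- rnorm(10)
    xq <- seq(min(xs), max(xs), length.out = 41)
    mine <- ierp:::cpp_spline_nak(xs, ys, xq)
    oracle <- spline_nak_oracle(xs, ys, xq)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("envelope of a short alternating series is cross-checked pointwise", {
  x <- c(0, 1, 0, -1, 0, 1, 0, -1, 0)
  m <- envelope_mean(x)
  expect_length(m, length(x))
  # the two envelopes are splines through mirrored knots; check the mean is
  # bounded by the data range and symmetric about zero for this odd pattern
  expect_true(all(m <= 1 + 1e-9) && all(m >= -1 - 1e-9))
  expect_lt(max(abs(m + rev(m) - 0)), 1e-9)
  expect_error(envelope_mean(seq_len(20)), class = "ierp_insufficient_extrema")
})

test_that("sifting leaves a sine intact and separates a fast tone", {
  t <- seq(0, 2, by = 1 / 128)[-1]
  s <- sin(2 * pi * 4 * t)
  h <- sift_imf(s)
  expect_gt(cor(h, s), 0.999)
  expect_identical(attr(h, "sifts_used"), 10L)

  x <- sin(2 * pi * 8 * t) + sin(2 * pi * 1 * t)
  h <- sift_imf(x)
  n <- length(t)
  central <- seq.int(round(0.1 * n), round(0.9 * n))
  expect_gt(cor(h[central], sin(2 * pi * 8 * t)[central]), 0.95)
})

test_that("the extracted component oscillates faster than what remains", {
  set.seed(13)
  for (rep in 1:5) {
    x <- cumsum(rnorm(256)) + rnorm(256)
    h <- sift_imf(x)
    expect_lt(count_zero_crossings(x - h), count_zero_crossings(as.numeric(h)))
  }
})

test_that("emd reconstructs exactly and handles degenerate inputs", {
  set.seed(3)
  x <- rnorm(512)
  d <- emd(x)
  rec <- Reduce(`+`, d$imfs) + d$residue
  expect_lt(max(abs(rec - x)), 1e-9 * sd(x))
  expect_length(d$n_sifts_used, length(d$imfs))

  ramp <- seq(0, 1, length.out = 64)
  d <- emd(ramp)
  expect_length(d$imfs, 0)
  expect_equal(d$residue, ramp)

  expect_error(emd(1:4), class = "ierp_invalid_signal")
})

test_that("white noise decomposes into about log2(N) IMFs", {
  set.seed(17)
  counts <- replicate(25, length(emd(rnorm(1024))$imfs))
  expect_gte(mean(counts >= 8 & counts <= 11), 0.9)
})

test_that("a two-tone signal separates into its components", {
  t <- seq(0, 4, by = 1 / 256)[-1]
  x <- sin(2 * pi * 4 * t) + 0.3 * sin(2 * pi * 32 * t)
  d <- emd(x)
  expect_gte(length(d$imfs), 2)
  expect_gt(abs(cor(d$imfs[[1]], sin(2 * pi * 32 * t))), 0.9)
  c4 <- vapply(d$imfs, function(im) abs(cor(im, sin(2 * pi * 4 * t))), numeric(1))
  expect_gt(max(c4), 0.9)
  expect_gt(which.max(c4), 1)
})

test_that("IMF conditions hold approximately after 10 sifts on white noise", {
  set.seed(23)
  ok <- 0L; tot <- 0L
  for (rep in 1:10) {
    d <- emd(rnorm(512))
    for (im in d$imfs) {
      ex <- find_extrema(im)
      ne <- length(ex$maxima) + length(ex$minima)
      tot <- tot + 1L
      if (abs(ne - count_zero_crossings(im)) <= 1) ok <- ok + 1L
    }
  }
  expect_gte(ok / tot, 0.9)
})

test_that("emd_mode_k returns the k-th IMF, zeros past the last order", {
  t <- seq(0, 2, by = 1 / 128)[-1]
  s <- sin(2 * pi * 4 * t)
  expect_gt(cor(emd_mode_k(s, 1), s), 0.999)

  x <- sin(2 * pi * 4 * t) + 0.3 * sin(2 * pi * 32 * t)
  d <- emd(x)
  expect_equal(emd_mode_k(x, 2), d$imfs[[2]])

  expect_warning(z <- emd_mode_k(seq(0, 1, length.out = 64), 5), "zero")
  expect_equal(z, numeric(64))
  expect_error(emd_mode_k(s, 0), class = "ierp_invalid_argument")
})

test_that("emd is deterministic: same input, bit-identical output", {
  set.seed(29)
  x <- rnorm(300)
  expect_identical(emd(x), emd(x))
})
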