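test_that("noise ensembles store the EMD modes of each realization", {
  ens <- build_noise_ensemble(256, l = 3, K = 4, seed = 101)
  expect_length(ens$imfs, 3)
  # stored E_1..E_K match a re-run of emd on the raw realization
  for (i in 1:3) {
    d <- emd(ens$noise[, i])
    for (k in 1:4) expect_equal(ens$imfs[[i]][, k], d$imfs[[k]])
  }
  # complementary pair of raw realizations sums to zero exactly
  expect_equal(ens$noise + (-ens$noise), matrix(0, 256, 3))
  # explicit decomposition of -w agrees with the sign shortcut (odd symmetry)
  ens2 <- build_noise_ensemble(256, l = 3, K = 4, seed = 101, sign_shortcut = TRUE)
  expect_identical(ens$neg_imfs, ens2$neg_imfs)
  # seeded determinism
  ens3 <- build_noise_ensemble(256, l = 3, K = 4, seed = 101)
  expect_identical(ens$noise, ens3$noise)
})

test_that("realization means and stds look like N(0,1) white noise", {
  n <- 512
  ens <- build_noise_ensemble(n, l = 8, K = 3, seed = 7)
  tol <- 5 / sqrt(n)
  expect_true(all(abs(colMeans(ens$noise)) < tol))
  expect_true(all(abs(apply(ens$noise, 2, sd) - 1) < tol))
})

test_that("ceemdan output telescopes back to the input exactly", {
  set.seed(31)
  t <- seq(0, 2, by = 1 / 256)[-1]
  x <- sin(2 * pi * 4 * t) + 0.5 * rnorm(length(t))
  ens <- build_noise_ensemble(length(x), l = 5, K = 6, seed = 11)
  dec <- ceemdan_decompose(x, ens, ceemdan_config(K = 6, l = 5))
  rec <- rowSums(dec$imfs) + dec$residue
  expect_lt(max(abs(rec - x)), 1e-9 * sd(x))
})

test_that("ceemdan recovers the tones of a noisy two-tone mixture", {
  t <- seq(0, 4, by = 1 / 256)[-1]
  set.seed(37)
  x <- sin(2 * pi * 4 * t) + sin(2 * pi * 16 * t) + 0.1 * rnorm(length(t))
  ens <- build_noise_ensemble(length(x), l = 50, K = 8, seed = 13)
  dec <- ceemdan_decompose(x, ens, ceemdan_config(K = 8, l = 50))
  c4 <- apply(dec$imfs, 2, function(im) abs(cor(im, sin(2 * pi * 4 * t))))
  c16 <- apply(dec$imfs, 2, function(im) abs(cor(im, sin(2 * pi * 16 * t))))
  expect_gt(max(c4), 0.95)
  expect_gt(max(c16), 0.95)
  expect_gt(which.max(c4), which.max(c16))  # slower tone at a deeper order
})

test_that("the zero-noise limit reproduces plain EMD", {
  set.seed(43)
  t <- seq(0, 2, by = 1 / 256)[-1]
  x <- sin(2 * pi * 4 * t) + sin(2 * pi * 16 * t) + 0.1 * rnorm(length(t))
  ens <- build_noise_ensemble(length(x), l = 4, K = 5, seed = 3)
  dec <- ceemdan_decompose(x, ens, ceemdan_config(epsilon = 1e-12, K = 5, l = 4))
  ref <- emd(x)
  for (k in 1:5) expect_lt(max(abs(dec$imfs[, k] - ref$imfs[[k]])), 1e-6)
})

test_that("complementary pairing reduces first-mode residual noise", {
  # Noiseless deterministic input; the residual noise of a finite ensemble
  # is its fluctuation about the across-seed mean. Pairing cancels the part
  # of the sift response that is odd in the added noise, which dominates the
  # first extraction, so l pairs beat 2l independent realizations there
  # (deeper orders fluctuate mainly through mode-splitting choices that are
  # even in the noise, where antithetic pairing cannot help).
  t <- seq(0, 2, by = 1 / 128)[-1]
  x <- sin(2 * pi * 3 * t) + 0.6 * sin(2 * pi * 11 * t)
  d1_comp <- list(); d1_plain <- list()
  for (s in 1:20) {
    e1 <- build_noise_ensemble(length(x), l = 2, K = 1, seed = 1000 + s,
                               complementary = TRUE)
    e2 <- build_noise_ensemble(length(x), l = 4, K = 1, seed = 5000 + s,
                               complementary = FALSE)
    d1_comp[[s]] <- ceemdan_decompose(x, e1, ceemdan_config(K = 1))$imfs[, 1]
    d1_plain[[s]] <- ceemdan_decompose(x, e2, ceemdan_config(K = 1))$imfs[, 1]
  }
  Mc <- do.call(rbind, d1_comp); Mp <- do.call(rbind, d1_plain)
  dev_c <- rowSums(sweep(Mc, 2, colMeans(Mc))^2)
  dev_p <- rowSums(sweep(Mp, 2, colMeans(Mp))^2)
  expect_lt(median(dev_c), median(dev_p))
  expect_lt(wilcox.test(dev_c, dev_p, alternative = "less")$p.value, 0.05)
})

test_that("decompose_epochs yields a uniform-K, exactly reconstructing stack", {
  set.seed(47)
  dat <- array(rnorm(4 * 2 * 512), dim = c(4, 2, 512))
  ep <- epoch_set(dat, fs = 256, conditions = rep(c("A", "B"), 2))
  cfg <- ceemdan_config(l = 2, seed = 99)
  st <- decompose_epochs(ep, cfg)
  expect_equal(st$K, floor(log2(512)) - 2)
  expect_equal(dim(st$values), c(4, 2, st$K + 1, 512))
  for (tr in 1:4) {
    for (ch in 1:2) {
      rec <- colSums(st$values[tr, ch, , ])
      expect_lt(max(abs(rec - dat[tr, ch, ])), 1e-9 * sd(dat[tr, ch, ]))
    }
  }
  # bit-identical under the same master seed
  st2 <- decompose_epochs(ep, cfg)
  expect_identical(st$values, st2$values)
})
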