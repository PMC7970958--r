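fake_range <- function(p_min, trend_start, K,
                       medians = NULL) {
  structure(list(p_min = as.integer(p_min), trend_start = as.integer(trend_start),
                 hi_cut = 30, lo_cut = 2, medians = medians, K = as.integer(K)),
            class = "ierp_mode_range")
}

fake_stack <- function(values, fs = 128, conditions = NULL, t0 = 0) {
  dm <- dim(values)
  structure(list(values = values, fs = fs,
                 time = t0 + (seq_len(dm[4]) - 1) / fs, K = dm[3] - 1L,
                 conditions = conditions %||% rep("A", dm[1]),
                 subject = "S01", layout = NULL,
                 channels = paste0("ch", seq_len(dm[2])),
                 seed = NULL, config = NULL,
                 qc = data.frame()), class = "ierp_imfstack")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the mode lattice enumerates M(M+1)/2 labels in triangular order", {
  ml <- mode_labels(2, 6, K = 7)
  expect_equal(nrow(ml), 15)
  expect_equal(ml$label[1:5], c("2:2", "2:3", "2:4", "2:5", "2:6+"))
  expect_equal(ml$label[nrow(ml)], "6+")
  cons <- attr(ml, "constituents")
  # the trend block runs through the residue order K + 1
  expect_equal(cons[[5]], 2:8)
  expect_equal(cons[[15]], 6:8)
  # count formula for assorted ranges
  for (pm in 1:3) {
    for (ts in pm:(pm + 4)) {
      expect_equal(nrow(mode_labels(pm, ts, K = ts + 1)), (ts - pm + 1) * (ts - pm + 2) / 2)
    }
  }
})

test_that("composite modes equal the sums of their pure constituents exactly", {
  set.seed(61)
  vals <- array(rnorm(6 * 2 * 8 * 64), dim = c(6, 2, 8, 64))
  st <- fake_stack(vals, conditions = rep(c("A", "B"), 3))
  rng <- fake_range(2, 6, 7)
  modes <- form_ierp_modes(st, rng)
  expect_named(modes, c("A", "B"))
  m <- modes$A
  ml <- m$labels
  pure_idx <- which(ml$p == ml$q)
  for (i in seq_len(nrow(ml))) {
    ords <- seq.int(ml$p[i], ml$q[i])
    expect_equal(m$values[i, , ],
                 Reduce(`+`, lapply(ords, function(o) {
                   m$values[pure_idx[match(o, ml$p[pure_idx])], , ]
                 })),
                 tolerance = 1e-12)
  }
})

test_that("averaging commutes with summation and 2:K+ recovers the filtered average", {
  set.seed(67)
  vals <- array(rnorm(5 * 1 * 6 * 32), dim = c(5, 1, 6, 32))
  st <- fake_stack(vals)
  rng <- fake_range(2, 5, 5)
  m <- form_ierp_modes(st, rng)$A
  # mode 2:5+ equals the epoch average minus the average order-1 IMF
  full <- apply(vals[, 1, , ], 3, function(z) mean(rowSums(z)))
  imf1 <- apply(vals[, 1, 1, ], 2, mean)
  i25 <- which(m$labels$label == "2:5+")
  expect_equal(as.numeric(m$values[i25, 1, ]), full - imf1, tolerance = 1e-12)
  # single-trial condition: modes equal that trial's partial sums
  st1 <- fake_stack(vals[1, , , , drop = FALSE])
  m1 <- form_ierp_modes(st1, rng)$A
  expect_equal(as.numeric(m1$values[i25, 1, ]),
               colSums(vals[1, 1, 2:6, ]), tolerance = 1e-12)
})

test_that("baseline correction zeroes the window mean and keeps linearity", {
  set.seed(71)
  vals <- array(rnorm(4 * 2 * 6 * 64) + 2, dim = c(4, 2, 6, 64))
  st <- fake_stack(vals, t0 = -0.25)
  rng <- fake_range(2, 5, 5)
  m <- form_ierp_modes(st, rng)$A
  mb <- baseline_correct(m, c(-0.25, 0))
  sel <- mb$time >= -0.25 & mb$time <= 0
  base <- apply(mb$values[, , sel], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-12)
  # constant offset removed everywhere
  mc <- m
  mc$values <- mc$values * 0 + 5
  expect_lt(max(abs(baseline_correct(mc, c(-0.25, 0))$values)), 1e-12)
  # linearity survives correction
  ml <- mb$labels
  pure_idx <- which(ml$p == ml$q)
  i <- which(ml$label == "2:4")
  expect_equal(mb$values[i, , ],
               mb$values[pure_idx[1], , ] + mb$values[pure_idx[2], , ] +
                 mb$values[pure_idx[3], , ], tolerance = 1e-12)
  expect_error(baseline_correct(m, c(10, 11)), class = "ierp_invalid_argument")
})

test_that("time binning forms the expected bins and degenerate cases", {
  fs <- 200
  vals <- array(rnorm(2 * 1 * 3 * 200), dim = c(2, 1, 3, 200))
  st <- fake_stack(vals, fs = fs)
  rng <- fake_range(1, 2, 2)
  m <- form_ierp_modes(st, rng)$A
  mb <- time_bin(m, 0.06, span = c(0.02, 0.68))
  expect_equal(dim(mb$values)[3], 11)  # 11 bins of 60 ms over 20-680 ms
  # bin width of one sample is the identity on the span
  m1 <- time_bin(m, 1 / fs, span = c(0, 0.5))
  sel <- m$time >= 0 & m$time < 0.5 - 1e-12
  expect_equal(m1$values, m$values[, , sel, drop = FALSE], tolerance = 1e-12)
  # constant series stay constant
  mc <- m
  mc$values <- mc$values * 0 + 3
  expect_true(all(abs(time_bin(mc, 0.06)$values - 3) < 1e-12))
})

test_that("binning warns when bins are longer than an order's period", {
  vals <- array(rnorm(2 * 1 * 6 * 200), dim = c(2, 1, 6, 200))
  st <- fake_stack(vals, fs = 200)
  rng <- fake_range(2, 6, 5, medians = c(45, 22, 11, 5.5, 2.8, 1.4))
  m <- form_ierp_modes(st, rng)$A
  expect_warning(time_bin(m, 0.06), "2:2")
})
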