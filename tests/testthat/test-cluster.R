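mt_graph <- function(n_modes_range = c(2, 6), n_time = 8) {
  ml <- mode_labels(n_modes_range[1], n_modes_range[2], K = n_modes_range[2] + 1)
  build_lattice_adjacency(ml, NULL, n_time, dims = c("mode", "time"))
}

test_that("pointwise statistics match textbook formulas", {
  set.seed(79)
  X <- matrix(rnorm(4 * 6), 4, 6)
  # identical conditions give a flat zero paired-t map
  t0 <- pointwise_statistic(list(X, X), "paired-t")
  expect_equal(as.numeric(t0), rep(0, 6))
  # hand-computed 4-subject paired t at every node
  Y <- X + matrix(rnorm(24, 0.3), 4, 6)
  tv <- pointwise_statistic(list(X, Y), "paired-t")
  D <- X - Y
  oracle <- apply(D, 2, function(d) mean(d) / (sd(d) / sqrt(4)))
  expect_equal(as.numeric(tv), oracle, tolerance = 1e-12)
  expect_equal(attr(tv, "df"), 3)
  # two-condition repeated-measures F equals the squared paired t
  A <- array(0, dim = c(6, 2, 5))
  A[, 1, ] <- matrix(rnorm(30), 6, 5)
  A[, 2, ] <- matrix(rnorm(30, 0.4), 6, 5)
  Fv <- pointwise_statistic(A, "rm-anova-F")
  tp <- pointwise_statistic(list(A[, 1, ], A[, 2, ]), "paired-t")
  expect_equal(as.numeric(Fv), as.numeric(tp)^2, tolerance = 1e-9)
  # pearson r against cor()
  cv <- rnorm(6)
  rv <- pointwise_statistic(A[, 1, ], "pearson-r", covariate = cv)
  expect_equal(as.numeric(rv), apply(A[, 1, ], 2, cor, y = cv), tolerance = 1e-12)
  # zero-variance nodes flagged and zeroed
  Z <- X; Z[, 2] <- 1
  tz <- pointwise_statistic(list(Z, Z * 0 + outer(rep(1, 4), colMeans(Z))), "paired-t")
  expect_true(2 %in% attr(tz, "flagged"))
})

test_that("cluster formation matches an independent flood fill", {
  g <- mt_graph(c(2, 6), 8)  # 15 modes x 8 bins = 120 nodes (5 x 8 grid per spec scaled)
  adj <- as_adj_list(g)
  set.seed(83)
  for (rep in 1:25) {
    v <- rnorm(g$n_nodes)
    cl <- form_clusters(v, g, 1.2)
    lab_pkg <- integer(g$n_nodes)
    for (i in seq_along(cl)) if (cl[[i]]$sign > 0) lab_pkg[cl[[i]]$members] <- i
    expect_true(same_partition(lab_pkg, flood_fill(v, 1.2, adj)))
    lab_neg <- integer(g$n_nodes)
    for (i in seq_along(cl)) if (cl[[i]]$sign < 0) lab_neg[cl[[i]]$members] <- i
    expect_true(same_partition(lab_neg, flood_fill(-v, 1.2, adj)))
    for (i in seq_along(cl)) {
      expect_equal(cl[[i]]$mass, sum(v[cl[[i]]$members]))
    }
  }
  expect_length(form_clusters(rep(0.5, g$n_nodes), g, 1.2), 0)
})

test_that("two adjacent suprathreshold nodes form one cluster with summed mass", {
  g <- mt_graph(c(1, 2), 3)  # 3 modes x 3 times
  ml <- g$labels
  v <- numeric(g$n_nodes)
  i11 <- which(ml$label == "1:1"); i12 <- which(ml$label == "1:2+")
  v[i11] <- 2.5
  v[i12] <- 3.1  # same time, neighbouring modes
  cl <- form_clusters(v, g, 2)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$mass, 5.6)
  expect_setequal(cl[[1]]$members, c(i11, i12))
})

test_that("TFCE matches the closed form on plateaus and scales monotonically", {
  ml1 <- mode_labels(1, 1, K = 1)
  g <- build_lattice_adjacency(ml1, NULL, n_time = 60, dims = c("mode", "time"))
  for (case in list(c(a = 8, h0 = 2), c(a = 15, h0 = 1), c(a = 5, h0 = 3))) {
    v <- numeric(60)
    v[20 + seq_len(case["a"])] <- case["h0"]
    tf <- tfce_transform(v, g, tfce_params(E = 0.5, H = 2))
    expected <- sqrt(case[["a"]]) * case[["h0"]]^3 / 3
    expect_lt(abs(tf[25] - expected) / expected, 2 * 1 / 100 + 0.02)
  }
  expect_equal(tfce_transform(numeric(60), g), numeric(60))
  # scaling up strictly increases enhancement at every nonzero node
  set.seed(89)
  v <- rnorm(60)
  t1 <- tfce_transform(v, g)
  t2 <- tfce_transform(2 * v, g)
  # nodes below the first integration step enhance to zero; check the rest
  nz <- which(abs(v) > max(abs(v)) / 100)
  expect_true(all(abs(t2[nz]) > abs(t1[nz])))
  # sign structure is preserved
  expect_true(all(sign(t1[nz]) == sign(v[nz])))
})

test_that("cbnpp finds an injected lattice effect only in modes containing it", {
  ml <- mode_labels(2, 6, K = 7)
  cons <- attr(ml, "effective")
  g <- build_lattice_adjacency(ml, NULL, n_time = 30, dims = c("mode", "time"))
  set.seed(97)
  A <- lattice_subjects(12, cons, 2:6, 30)
  B <- lattice_subjects(12, cons, 2:6, 30, effect_order = 4, effect = 1.3,
                        effect_bins = 10:20)
  r <- cbnpp_test(list(B, A), "paired-t", g, n_perm = 400, seed = 7)
  sig <- which(r$clusters$p <= 0.05)
  expect_gt(length(sig), 0)
  win <- which.min(r$clusters$p)
  win_modes <- unique(g$nodes$mode[r$members[[win]]])
  expect_true(which(ml$label == "4:4") %in% win_modes)
  # every significant cluster touches modes that contain the critical order
  for (i in sig) {
    mm <- unique(g$nodes$mode[r$members[[i]]])
    expect_true(any(vapply(cons[mm], function(s) 4 %in% s, logical(1))))
  }
  # the effect vanishes when the critical order is excluded from the lattice:
  # rebuild the analysis on the sub-lattice of modes whose sets exclude 4
  keep <- which(!vapply(cons, function(s) 4 %in% s, logical(1)))
  ml_ex <- ml[keep, ]
  attr(ml_ex, "effective") <- cons[keep]
  g_ex <- build_lattice_adjacency(ml_ex, NULL, n_time = 30,
                                  dims = c("mode", "time"))
  cols <- as.vector(outer(keep, (0:29) * nrow(ml), `+`))
  r_ex <- cbnpp_test(list(B[, cols], A[, cols]), "paired-t", g_ex,
                     n_perm = 400, seed = 7)
  expect_false(any(r_ex$clusters$p <= 0.05))
})

test_that("permutation machinery is deterministic and notes exhaustive runs", {
  g <- mt_graph(c(1, 2), 4)
  set.seed(101)
  D <- matrix(rnorm(5 * g$n_nodes, 0.4), 5, g$n_nodes)
  r1 <- cbnpp_test(D, "one-sample-t", g, n_perm = 500, seed = 3)
  r2 <- cbnpp_test(D, "one-sample-t", g, n_perm = 500, seed = 3)
  expect_identical(r1$null_max, r2$null_max)
  expect_identical(r1$clusters, r2$clusters)
  # 2^5 = 32 < 500 -> exhaustive sign enumeration
  expect_true(r1$exhaustive)
  expect_equal(r1$n_perm, 32)
  expect_true(all(r1$clusters$p > 0 & r1$clusters$p <= 1))
  t1 <- tfce_test(D, "one-sample-t", g, n_perm = 500, seed = 3)
  t2 <- tfce_test(D, "one-sample-t", g, n_perm = 500, seed = 3)
  expect_identical(t1$p, t2$p)
  expect_identical(t1$null_max, t2$null_max)
})

test_that("node-wise TFCE p values agree with a direct null comparison", {
  g <- mt_graph(c(1, 3), 6)
  set.seed(103)
  D <- matrix(rnorm(8 * g$n_nodes, 0.3), 8, g$n_nodes)
  r <- tfce_test(D, "one-sample-t", g, n_perm = 300, seed = 11)
  direct <- vapply(abs(r$tfce), function(v) {
    (1 + sum(r$null_max >= v)) / (1 + r$n_perm)
  }, numeric(1))
  expect_equal(r$p, direct)
})

test_that("compact mode maps mark exactly the significant electrode-cluster cells", {
  ml <- mode_labels(3, 5, K = 5)  # 6 modes
  lay <- montage_1010(c("PO7", "PO5", "P7", "P5", "PO8", "PO6", "P8", "P6"))
  g <- build_lattice_adjacency(ml, lay, n_time = 3,
                               dims = c("channel", "mode", "time"))
  cons <- attr(ml, "effective")
  set.seed(107)
  n_sub <- 10
  base <- array(rnorm(n_sub * g$n_nodes), c(n_sub, g$n_nodes))
  # inject a strong effect at mode 4:5, channel PO7, bin 2
  i45 <- which(ml$label == "4:5")
  ch <- match("PO7", lay$label)
  node <- i45 + nrow(ml) * ((ch - 1) + nrow(lay) * (2 - 1))
  eff <- base
  eff[, node] <- eff[, node] + 3
  r <- cbnpp_test(eff, "one-sample-t", g, n_perm = 300, seed = 5)
  cm <- compact_mode_map(r, g, c("PO7", "PO5"), p_threshold = 0.05)
  if (any(r$clusters$p <= r$alpha)) {
    pi <- match(4, cm$p_orders); qi <- match(5, cm$q_orders)
    expect_true(cm$opaque[pi, qi, 2])
  }
  # with no significant clusters the map is fully transparent
  rnull <- r
  rnull$clusters$p <- 1
  cm0 <- compact_mode_map(rnull, g, c("PO7", "PO5"), p_threshold = 0.05)
  expect_false(any(cm0$opaque))
  # mask invariant to channel ordering within the electrode cluster
  cm2 <- compact_mode_map(r, g, c("PO5", "PO7"), p_threshold = 0.05)
  expect_identical(cm$opaque, cm2$opaque)
  expect_equal(cm$mean_t, cm2$mean_t)
})
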