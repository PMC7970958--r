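test_that("the XOR rule reproduces the worked mode pairs", {
  ml <- mode_labels(2, 7, K = 8)  # trend at 7 so 3:6 is an ordinary mode
  expect_true(modes_are_neighbors(ml, "2:5", "3:5"))
  expect_false(modes_are_neighbors(ml, "2:5", "3:6"))
  expect_false(modes_are_neighbors(ml, "2:5", "2:5"))  # XOR empty
  ml <- mode_labels(2, 6, K = 7)
  # trend block as a single pseudo-ordinal: 3:5 and 3:6+ are neighbours
  expect_true(modes_are_neighbors(ml, "3:5", "3:6+"))
  expect_false(modes_are_neighbors(ml, "3:5", "3:6+", trend_as_block = FALSE))
})

test_that("mode adjacency matches a brute-force symmetric-difference oracle", {
  for (pm in c(1, 2, 3)) {
    for (M in 2:6) {
      ts <- pm + M - 1
      ml <- mode_labels(pm, ts, K = ts + 2)
      if (ts - pm + 1 > 8) next
      adj <- mode_adjacency(ml)
      sets <- attr(ml, "effective")
      for (i in seq_len(nrow(ml))) {
        for (j in seq_len(nrow(ml))) {
          brute <- i != j &&
            length(union(setdiff(sets[[i]], sets[[j]]),
                         setdiff(sets[[j]], sets[[i]]))) == 1
          expect_identical(adj[i, j], brute)
        }
      }
      expect_true(isSymmetric(adj))
      expect_false(any(diag(adj)))
    }
  }
})

test_that("channel adjacency uses a strict 40 mm rule", {
  lay <- data.frame(label = c("a", "b", "c"),
                    x = c(0, 39, 79), y = 0, z = 0)
  adj <- channel_neighbors(lay)
  expect_true(adj["a", "b"])    # 39 mm apart
  expect_false(adj["b", "c"])   # 40 mm apart: strict "less than" excludes
  lay2 <- data.frame(label = c("a", "b"), x = c(0, 40), y = 0, z = 0)
  expect_false(any(channel_neighbors(lay2)))
  expect_equal(sum(channel_neighbors(lay[1, , drop = FALSE])), 0)
})

test_that("lattice adjacency joins points neighbouring in exactly one dimension", {
  ml <- mode_labels(1, 2, K = 2)[1:2, ]  # 1:1 and 1:2+ are neighbours
  attr(ml, "effective") <- attr(mode_labels(1, 2, K = 2), "effective")[1:2]
  g <- build_lattice_adjacency(ml, NULL, n_time = 3, dims = c("mode", "time"))
  expect_equal(g$n_nodes, 6)
  adj <- as_adj_list(g)
  deg <- lengths(adj)
  expect_true(all(deg %in% c(2, 3)))
  # exhaustive pairwise check against the definition
  nodes <- g$nodes
  for (u in 1:6) {
    for (v in 1:6) {
      du <- nodes[u, ]; dv <- nodes[v, ]
      mode_nb <- du$mode != dv$mode  # the two modes are neighbours
      time_nb <- abs(du$time - dv$time) == 1
      same_mode <- du$mode == dv$mode
      same_time <- du$time == dv$time
      truth <- (mode_nb && same_time) || (time_nb && same_mode)
      expect_identical(v %in% adj[[u]], truth && u != v)
    }
  }
})

test_that("diagonal lattice moves are not adjacent and 3D counts multiply", {
  ml <- mode_labels(2, 6, K = 7)
  lay <- montage_1010(c("Cz", "C1", "C2", "Pz"))
  g <- build_lattice_adjacency(ml, lay, n_time = 5,
                               dims = c("channel", "mode", "time"))
  expect_equal(g$n_nodes, 15 * 4 * 5)
  adj <- as_adj_list(g)
  id <- function(m, c, t) m + 15 * ((c - 1) + 4 * (t - 1))
  i25 <- which(ml$label == "2:5"); i35 <- which(ml$label == "3:5")
  # same channel, neighbour mode, neighbour time -> two dims differ -> not adjacent
  expect_false(id(i35, 1, 4) %in% adj[[id(i25, 1, 3)]])
  expect_true(id(i35, 1, 3) %in% adj[[id(i25, 1, 3)]])
  # symmetry and irreflexivity across a random sample of nodes
  set.seed(73)
  for (u in sample(g$n_nodes, 25)) {
    expect_false(u %in% adj[[u]])
    for (v in adj[[u]]) expect_true(u %in% adj[[v]])
  }
})

test_that("unknown dimensions and missing layouts are rejected", {
  ml <- mode_labels(1, 2, K = 2)
  expect_error(build_lattice_adjacency(ml, NULL, 3, dims = c("mode", "space")),
               class = "ierp_invalid_argument")
  expect_error(build_lattice_adjacency(ml, NULL, 3, dims = c("channel", "mode")),
               class = "ierp_invalid_argument")
  expect_error(build_lattice_adjacency(ml, NULL, 3, dims = "mode"),
               class = "ierp_invalid_argument")
})

test_that("the generated montage has plausible 10-10 geometry", {
  lay <- montage_1010()
  expect_false(any(duplicated(lay$label)))
  r <- sqrt(lay$x^2 + lay$y^2 + lay$z^2)
  expect_true(all(abs(r - 85) < 1e-6))
  d <- as.matrix(dist(lay[, c("x", "y", "z")]))
  dimnames(d) <- list(lay$label, lay$label)
  expect_lt(d["C3", "C1"], 40)    # one 10-10 step
  expect_gt(d["C3", "Cz"], 40)    # two steps
  expect_lt(d["PO7", "P7"], 40)
  expect_gt(d["Fp1", "O2"], 150)  # front-back extremes
  # left/right symmetry
  expect_equal(d["C3", "Cz"], d["C4", "Cz"], tolerance = 1e-9)
})
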