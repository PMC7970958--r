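# Pointwise statistics, cluster formation, the cluster-based nonparametric
# permutation (CBnPP) test and the TFCE transform/test, all on arbitrary
# iERP lattice graphs.

# ---- canonical data forms ---------------------------------------------------

# paired designs take list(A = subj x node, B = subj x node) or a
# subj x 2 x node array; one-sample a subj x node matrix; anova a
# subj x cond x node array; pearson a subj x node matrix plus covariate.
canon_data <- function(data, design, covariate = NULL) {
  if (design == "paired-t") {
    if (is.array(data) && length(dim(data)) == 3L) {
      stopifnot(dim(data)[2] == 2L)
      D <- data[, 1, ] - data[, 2, ]
    } else {
      stopifnot(is.list(data), length(data) == 2L)
      D <- data[[1]] - data[[2]]
    }
    list(D = as.matrix(D), n = nrow(D))
  } else if (design == "one-sample-t") {
    D <- as.matrix(data)
    list(D = D, n = nrow(D))
  } else if (design == "pearson-r") {
    D <- as.matrix(data)
    if (is.null(covariate) || length(covariate) != nrow(D)) {
      stop_ierp("pearson-r needs one covariate value per subject",
                "ierp_invalid_argument")
    }
    list(D = D, x = as.numeric(covariate), n = nrow(D))
  } else if (design == "rm-anova-F") {
    stopifnot(is.array(data), length(dim(data)) == 3L, dim(data)[2] >= 2L)
    list(Y = data, n = dim(data)[1], k = dim(data)[2])
  } else {
    stop_ierp(paste0("unknown design: ", design), "ierp_invalid_argument")
  }
}

stat_t <- function(D, signs = NULL) {
  n <- nrow(D)
  if (is.null(signs)) signs <- matrix(1, 1, n)
  M <- signs %*% D / n
  ss <- colSums(D^2)
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  V[V < 0] <- 0
  tval <- M / sqrt(V / n)
  tval[!is.finite(tval)] <- 0
  tval
}

stat_r <- function(D, x_orders) {
  n <- nrow(D)
  sdc <- apply(D, 2, sd)
  Dz <- sweep(D, 2, colMeans(D), "-")
  ok <- sdc > 0
  Dz[, ok] <- sweep(Dz[, ok, drop = FALSE], 2, sdc[ok], "/")
  Dz[, !ok] <- 0
  xz <- t(apply(x_orders, 1, function(v) (v - mean(v)) / sd(v)))
  R <- xz %*% Dz / (n - 1)
  R[!is.finite(R)] <- 0
  R
}

stat_F <- function(Y, perms = NULL) {
  n <- dim(Y)[1]; k <- dim(Y)[2]; p <- dim(Y)[3]
  Ymat <- matrix(Y, n * k, p)
  g <- colMeans(Ymat)
  ss_tot <- colSums(sweep(Ymat, 2, g, "-")^2)
  subj_means <- apply(Y, c(1, 3), mean)
  ss_subj <- k * colSums(sweep(subj_means, 2, g, "-")^2)
  one_F <- function(perm_idx) {
    # perm_idx: n x k matrix; row i holds the condition order for subject i
    ss_cond <- numeric(p)
    ms <- matrix(0, k, p)
    for (c in seq_len(k)) {
      rows <- seq_len(n) + n * (perm_idx[, c] - 1L)
      ms[c, ] <- colMeans(Ymat[rows, , drop = FALSE])
    }
    ss_cond <- n * colSums(sweep(ms, 2, g, "-")^2)
    ss_err <- pmax(ss_tot - ss_subj - ss_cond, 0)
    Fv <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
    Fv[!is.finite(Fv)] <- 0
    Fv
  }
  if (is.null(perms)) {
    id <- matrix(rep(seq_len(k), each = n), n, k)
    matrix(one_F(id), 1)
  } else {
    t(vapply(perms, one_F, numeric(p)))
  }
}

#' Node-wise parametric statistic over the iERP lattice
#'
#' Computes, at every lattice node, a paired t, one-sample t, Pearson r
#' against a subject-level behavioural covariate, or a one-way
#' repeated-measures ANOVA F (no sphericity correction; the permutation
#' inference does not require one). Zero-variance nodes yield statistic 0
#' and are flagged.
#'
#' @param data see Details in [cbnpp_test()]: matrices/arrays of
#'   subject-level values, nodes ordered as in the lattice graph.
#' @param design one of `"paired-t"`, `"one-sample-t"`, `"pearson-r"`,
#'   `"rm-anova-F"`.
#' @param covariate behavioural score per subject (for `"pearson-r"`).
#' @return Numeric vector of class `ierp_statmap` with attributes `kind`
#'   (`"t"`, `"r"`, `"F"`), `df`, `n`, `flagged` (zero-variance node
#'   indices).
#' @export
pointwise_statistic <- function(data, design = c("paired-t", "one-sample-t",
                                                 "pearson-r", "rm-anova-F"),
                                covariate = NULL) {
  design <- match.arg(design)
  cd <- canon_data(data, design, covariate)
  if (cd$n < 3L) stop_ierp("need at least 3 subjects", "ierp_invalid_argument")
  if (design %in% c("paired-t", "one-sample-t")) {
    v <- as.numeric(stat_t(cd$D))
    flagged <- which(apply(cd$D, 2, function(z) var(z) == 0))
    out <- structure(v, kind = "t", df = cd$n - 1, n = cd$n, flagged = flagged)
  } else if (design == "pearson-r") {
    v <- as.numeric(stat_r(cd$D, matrix(cd$x, 1)))
    flagged <- which(apply(cd$D, 2, function(z) var(z) == 0))
    out <- structure(v, kind = "r", df = cd$n - 2, n = cd$n, flagged = flagged)
  } else {
    v <- as.numeric(stat_F(cd$Y))
    flagged <- which(v == 0)
    out <- structure(v, kind = "F", df = c(cd$k - 1, (cd$n - 1) * (cd$k - 1)),
                     n = cd$n, flagged = flagged)
  }
  class(out) <- "ierp_statmap"
  out
}

default_threshold <- function(kind, df, n, alpha = 0.05) {
  if (kind == "t") {
    qt(1 - alpha / 2, df)
  } else if (kind == "r") {
    tc <- qt(1 - alpha / 2, n - 2)
    tc / sqrt(n - 2 + tc^2)
  } else {
    qf(1 - alpha, df[1], df[2])
  }
}

#' Threshold a statistic map into signed connected clusters
#'
#' Positive and negative excursions are thresholded separately at
#' `+threshold` / `-threshold` and grouped into connected sets via the
#' lattice adjacency; each cluster's mass is the sum of the statistic values
#' of its members.
#'
#' @param map numeric statistic map (one value per graph node).
#' @param graph an `ierp_graph`.
#' @param threshold positive uncorrected critical value.
#' @return List of clusters, each `list(members, mass, sign)`; empty when no
#'   node is suprathreshold.
#' @export
form_clusters <- function(map, graph, threshold) {
  stopifnot(threshold > 0, length(map) == graph$n_nodes)
  out <- list()
  for (sgn in c(1, -1)) {
    v <- sgn * as.numeric(map)
    lab <- cpp_components(v, threshold, graph$offsets, graph$indices)
    ncl <- max(lab)
    if (ncl > 0) {
      for (cl in seq_len(ncl)) {
        members <- which(lab == cl)
        out[[length(out) + 1L]] <- list(members = members,
                                        mass = sum(map[members]),
                                        sign = sgn)
      }
    }
  }
  out
}

# permutation scheme: returns list(mat = function(chunk of perm indices) ->
# n_chunk x n_nodes statistic matrix, n_perm actually used, exhaustive flag)
make_perm_scheme <- function(cd, design, n_perm, seed) {
  if (design %in% c("paired-t", "one-sample-t")) {
    n <- cd$n
    exhaustive <- n <= 20 && 2^n <= n_perm
    if (exhaustive) {
      n_perm <- 2^n
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      signs <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                      n_perm, n))
    }
    list(stats = function(rows) stat_t(cd$D, signs[rows, , drop = FALSE]),
         n_perm = n_perm, exhaustive = exhaustive)
  } else if (design == "pearson-r") {
    n <- cd$n
    nfact <- factorial(n)
    exhaustive <- n <= 7 && nfact <= n_perm
    if (exhaustive) {
      n_perm <- nfact
      perms <- all_permutations(n)
    } else {
      perms <- with_seed(seed, t(replicate(n_perm, sample.int(n))))
    }
    xo <- matrix(cd$x[perms], nrow(perms), n)
    list(stats = function(rows) stat_r(cd$D, xo[rows, , drop = FALSE]),
         n_perm = n_perm, exhaustive = exhaustive)
  } else {
    n <- cd$n; k <- cd$k
    exhaustive <- FALSE
    perms <- with_seed(seed, lapply(seq_len(n_perm), function(i) {
      t(vapply(seq_len(n), function(s) sample.int(k), integer(k)))
    }))
    list(stats = function(rows) stat_F(cd$Y, perms[rows]),
         n_perm = n_perm, exhaustive = exhaustive)
  }
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq.int(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' Cluster-based nonparametric permutation test
#'
#' The seven-step CBnPP procedure on the iERP lattice: node-wise parametric
#' statistics, thresholding at an uncorrected critical value (default: the
#' two-sided parametric critical value at `alpha`, e.g. the 97.5th T
#' quantile), connected-set clustering via the lattice adjacency, cluster
#' mass as the within-cluster sum, and a permutation null of the maximum
#' cluster mass. Permutations exchange condition labels within subject
#' (paired), flip signs (one-sample), shuffle the subject order of the
#' covariate (correlation), or permute condition labels within subject
#' (ANOVA). Cluster `P = (1 + #\{null >= |observed|\}) / (1 + n_perm)`, with
#' the null maximised over both signs (two-sided control). When all distinct
#' sign patterns number no more than `n_perm`, the enumeration is exhaustive
#' (noted in the result).
#'
#' @param data subject-level data with nodes ordered as in `graph`:
#'   paired — `list(condA, condB)` of subject x node matrices (or a
#'   subject x 2 x node array); one-sample — a subject x node matrix of
#'   within-subject differences; pearson — subject x node matrix plus
#'   `covariate`; ANOVA — subject x condition x node array.
#' @param design see [pointwise_statistic()].
#' @param graph an `ierp_graph` whose nodes match the data columns.
#' @param n_perm number of permutations (published example: 5000).
#' @param alpha two-sided alpha for the default cluster-forming threshold.
#' @param seed RNG seed for the permutation draw.
#' @param threshold override the cluster-forming threshold (positive).
#' @param covariate subject-level behavioural scores for `"pearson-r"`.
#' @return An `ierp_clusters` object: `statmap`, `clusters` (data frame with
#'   `id`, `sign`, `n_nodes`, `mass`, `p`), `members` (list), `null_max`,
#'   `threshold`, `n_perm`, `exhaustive`, `alpha`, `seed`, `design`.
#' @export
cbnpp_test <- function(data, design = c("paired-t", "one-sample-t",
                                        "pearson-r", "rm-anova-F"),
                       graph, n_perm = 5000L, alpha = 0.05, seed = NULL,
                       threshold = NULL, covariate = NULL) {
  design <- match.arg(design)
  cd <- canon_data(data, design, covariate)
  if (cd$n < 3L) stop_ierp("need at least 3 subjects", "ierp_invalid_argument")
  obs <- pointwise_statistic(data, design, covariate)
  if (length(obs) != graph$n_nodes) {
    stop_ierp("data nodes do not match the graph", "ierp_invalid_argument")
  }
  kind <- attr(obs, "kind")
  if (is.null(threshold)) {
    threshold <- default_threshold(kind, attr(obs, "df"), cd$n, alpha)
  }
  clusters <- form_clusters(as.numeric(obs), graph, threshold)
  scheme <- make_perm_scheme(cd, design, n_perm, seed)
  n_perm <- scheme$n_perm
  two_sided <- kind != "F"
  null_max <- numeric(n_perm)
  chunk <- 256L
  done <- 0L
  while (done < n_perm) {
    rows <- seq.int(done + 1L, min(done + chunk, n_perm))
    sm <- scheme$stats(rows)
    null_max[rows] <- cpp_perm_max_mass(t(sm), threshold, graph$offsets,
                                        graph$indices, two_sided)
    done <- done + length(rows)
  }
  pvals <- vapply(clusters, function(cl) {
    (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
  }, numeric(1))
  df <- data.frame(id = seq_along(clusters),
                   sign = vapply(clusters, `[[`, numeric(1), "sign"),
                   n_nodes = vapply(clusters, function(cl) length(cl$members), numeric(1)),
                   mass = vapply(clusters, `[[`, numeric(1), "mass"),
                   p = pvals)
  structure(list(statmap = obs, clusters = df,
                 members = lapply(clusters, `[[`, "members"),
                 null_max = null_max, threshold = threshold,
                 n_perm = n_perm, exhaustive = scheme$exhaustive,
                 alpha = alpha, seed = seed, design = design, graph_dims = graph$sizes),
            class = "ierp_clusters")
}

#' @export
print.ierp_clusters <- function(x, ...) {
  cat(sprintf("CBnPP test (%s): %d permutations%s, cluster-forming threshold %.3f\n",
              x$design, x$n_perm, if (x$exhaustive) " (exhaustive)" else "",
              x$threshold))
  if (nrow(x$clusters)) {
    print(x$clusters, row.names = FALSE)
  } else {
    cat("  no suprathreshold clusters\n")
  }
  invisible(x)
}

#' TFCE parameters
#'
#' Extent exponent `E`, height exponent `H` and integration step, following
#' the original TFCE defaults (E = 0.5, H = 2); `dh = NULL` uses
#' `max|stat| / n_steps`.
#'
#' @param E,H exponents (>= 0).
#' @param dh integration step (`NULL` for adaptive).
#' @param n_steps number of integration steps for the adaptive step.
#' @return A list of class `ierp_tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, n_steps = 100L) {
  stopifnot(E >= 0, H >= 0, is.null(dh) || dh > 0)
  structure(list(E = E, H = H, dh = dh, n_steps = as.integer(n_steps)),
            class = "ierp_tfce_params")
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' For each node, integrates `extent(h)^E * h^H dh` over heights from 0 to
#' the node's statistic value (per sign), where `extent(h)` is the size of
#' the connected component containing the node at threshold `h`. Avoids the
#' arbitrary cluster-forming threshold of the standard cluster test.
#'
#' @param map numeric statistic map.
#' @param graph an `ierp_graph`.
#' @param params a [tfce_params()] object.
#' @return Numeric vector of signed enhanced values.
#' @export
tfce_transform <- function(map, graph, params = tfce_params()) {
  stopifnot(length(map) == graph$n_nodes)
  dh <- if (is.null(params$dh)) -1 else params$dh
  cpp_tfce(as.numeric(map), graph$offsets, graph$indices,
           params$E, params$H, params$n_steps, dh)
}

#' TFCE permutation test
#'
#' As [cbnpp_test()], but the permutation null is the maximum of |TFCE| over
#' nodes, yielding node-wise familywise-corrected P values —
#' `P(node) = (1 + #\{null >= |TFCE(node)|\}) / (1 + n_perm)`.
#'
#' @inheritParams cbnpp_test
#' @param params a [tfce_params()] object.
#' @return An `ierp_tfce` object: `statmap`, `tfce`, `p` (node-wise
#'   corrected), `min_p`, `null_max`, `n_perm`, `exhaustive`, `alpha`,
#'   `seed`, `design`, `params`.
#' @export
tfce_test <- function(data, design = c("paired-t", "one-sample-t",
                                       "pearson-r", "rm-anova-F"),
                      graph, n_perm = 5000L, alpha = 0.05, seed = NULL,
                      params = tfce_params(), covariate = NULL) {
  design <- match.arg(design)
  cd <- canon_data(data, design, covariate)
  if (cd$n < 3L) stop_ierp("need at least 3 subjects", "ierp_invalid_argument")
  obs <- pointwise_statistic(data, design, covariate)
  if (length(obs) != graph$n_nodes) {
    stop_ierp("data nodes do not match the graph", "ierp_invalid_argument")
  }
  tf <- tfce_transform(as.numeric(obs), graph, params)
  scheme <- make_perm_scheme(cd, design, n_perm, seed)
  n_perm <- scheme$n_perm
  null_max <- numeric(n_perm)
  chunk <- 256L
  done <- 0L
  while (done < n_perm) {
    rows <- seq.int(done + 1L, min(done + chunk, n_perm))
    sm <- scheme$stats(rows)
    null_max[rows] <- cpp_perm_max_tfce(t(sm), graph$offsets, graph$indices,
                                        params$E, params$H, params$n_steps)
    done <- done + length(rows)
  }
  atf <- abs(tf)
  ord <- order(atf)
  snull <- sort(null_max)
  cnt <- length(null_max) - findInterval(atf, snull + 0, left.open = TRUE)
  # cnt = #{null >= |tfce|}; findInterval with left.open counts null < |tfce|
  p <- (1 + cnt) / (1 + n_perm)
  structure(list(statmap = obs, tfce = tf, p = p, min_p = min(p),
                 null_max = null_max, n_perm = n_perm,
                 exhaustive = scheme$exhaustive, alpha = alpha, seed = seed,
                 design = design, params = params, graph_dims = graph$sizes),
            class = "ierp_tfce")
}

#' @export
print.ierp_tfce <- function(x, ...) {
  cat(sprintf("TFCE test (%s): %d permutations%s, E = %g, H = %g\n",
              x$design, x$n_perm, if (x$exhaustive) " (exhaustive)" else "",
              x$params$E, x$params$H))
  cat(sprintf("  min corrected P = %.4g; %d node(s) below alpha = %g\n",
              x$min_p, sum(x$p <= x$alpha), x$alpha))
  invisible(x)
}

#' Compact triangular mode map of a 3D cluster result
#'
#' Reorganises a 3D `[channel, mode, time]` cluster result into, per time
#' bin, a triangular initial-order x end-order matrix of the mean T over an
#' electrode cluster, with an opacity mask: a mode is opaque iff any member
#' channel of the electrode cluster belongs to a significant cluster at that
#' mode/time and the parametric P of the cluster-mean T is below
#' `p_threshold`.
#'
#' @param result an `ierp_clusters` from a 3D analysis.
#' @param graph the `ierp_graph` the result was computed on.
#' @param electrode_cluster character vector of channel labels.
#' @param p_threshold threshold on the P of the mean T (default 0.025).
#' @return A list of class `ierp_compact`: `mean_t` and `opaque` arrays of
#'   dimension `initial order x end order x time bin`, plus `p_orders`,
#'   `q_orders`, `time_index`.
#' @export
compact_mode_map <- function(result, graph, electrode_cluster,
                             p_threshold = 0.025) {
  stopifnot(inherits(result, "ierp_clusters"), inherits(graph, "ierp_graph"))
  labels <- graph$labels
  lay <- graph$layout
  ch_idx <- match(electrode_cluster, lay$label)
  if (anyNA(ch_idx)) stop_ierp("electrode cluster contains unknown channels",
                               "ierp_invalid_argument")
  M <- graph$sizes["mode"]; C <- graph$sizes["channel"]; Tt <- graph$sizes["time"]
  df <- attr(result$statmap, "df")
  sig_nodes <- logical(graph$n_nodes)
  if (nrow(result$clusters)) {
    keep <- result$clusters$p <= result$alpha
    for (i in which(keep)) sig_nodes[result$members[[i]]] <- TRUE
  }
  ps <- sort(unique(labels$p))
  qs <- sort(unique(labels$q))
  mean_t <- array(NA_real_, dim = c(length(ps), length(qs), Tt))
  opaque <- array(FALSE, dim = c(length(ps), length(qs), Tt))
  node_id <- function(m, c, t) m + M * ((c - 1L) + C * (t - 1L))
  stat <- as.numeric(result$statmap)
  for (m in seq_len(M)) {
    pi <- match(labels$p[m], ps)
    qi <- match(labels$q[m], qs)
    for (t in seq_len(Tt)) {
      ids <- node_id(m, ch_idx, t)
      mt <- mean(stat[ids])
      mean_t[pi, qi, t] <- mt
      pv <- 2 * pt(-abs(mt), df)
      opaque[pi, qi, t] <- any(sig_nodes[ids]) && pv < p_threshold
    }
  }
  structure(list(mean_t = mean_t, opaque = opaque, p_orders = ps,
                 q_orders = qs, time_index = seq_len(Tt),
                 labels = labels$label),
            class = "ierp_compact")
}

#' Plot a compact mode map
#'
#' Heatmap of the triangular mean-T matrix for one time bin; opaque cells
#' are drawn saturated, transparent cells faded.
#'
#' @param x an `ierp_compact` object.
#' @param time_bin which bin to draw.
#' @param ... unused.
#' @return Invisibly, `x`.
#' @export
plot.ierp_compact <- function(x, time_bin = 1L, ...) {
  mt <- x$mean_t[, , time_bin]
  op <- x$opaque[, , time_bin]
  zlim <- max(abs(mt), na.rm = TRUE)
  if (!is.finite(zlim) || zlim == 0) zlim <- 1
  np <- length(x$p_orders); nq <- length(x$q_orders)
  graphics::plot(NULL, xlim = c(0.5, nq + 0.5), ylim = c(np + 0.5, 0.5),
                 xlab = "end IMF", ylab = "initial IMF", xaxt = "n", yaxt = "n",
                 main = sprintf("compact iERP map, bin %d", time_bin))
  graphics::axis(1, at = seq_len(nq), labels = x$q_orders)
  graphics::axis(2, at = seq_len(np), labels = x$p_orders)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  for (i in seq_len(np)) {
    for (j in seq_len(nq)) {
      v <- mt[i, j]
      if (is.na(v)) next
      col <- pal[1 + floor((v + zlim) / (2 * zlim) * 63)]
      if (!op[i, j]) col <- grDevices::adjustcolor(col, alpha.f = 0.25)
      graphics::rect(j - 0.5, i - 0.5, j + 0.5, i + 0.5, col = col, border = "grey")
    }
  }
  invisible(x)
}

#' Flatten subject-level iERP modes into a node matrix
#'
#' Stacks one subject's `ierp_modes` values into the node ordering used by
#' [build_lattice_adjacency()] (mode fastest, then channel, then time).
#'
#' @param modes_list list of `ierp_modes`, one per subject (same lattice).
#' @param channel optional single channel label to slice out (2D
#'   \[mode, time\] analyses).
#' @param window optional `c(t0, t1)` to average over (2D \[channel, mode\]).
#' @return Subject x node numeric matrix.
#' @export
modes_to_matrix <- function(modes_list, channel = NULL, window = NULL) {
  rows <- lapply(modes_list, function(m) {
    v <- m$values
    if (!is.null(channel)) {
      ci <- match(channel, m$channels)
      if (is.na(ci)) stop_ierp("unknown channel", "ierp_invalid_argument")
      v <- v[, ci, , drop = FALSE]
    }
    if (!is.null(window)) {
      sel <- m$time >= window[1] & m$time <= window[2]
      if (!any(sel)) stop_ierp("window contains no samples", "ierp_invalid_argument")
      v <- array(apply(v[, , sel, drop = FALSE], c(1, 2), mean),
                 dim = c(dim(v)[1], dim(v)[2], 1))
    }
    as.vector(v)
  })
  do.call(rbind, rows)
}
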