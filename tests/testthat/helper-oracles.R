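# Independent oracles used across the suite. These deliberately avoid the
# package's own C++ code paths: dense linear algebra for the spline, queue
# flood fill for components, explicit set algebra for mode neighbours.

# Not-a-knot cubic spline by solving the full second-derivative system with
# base R solve(); evaluates at xq (supports >= 4 knots).
spline_nak_oracle <- function(xs, ys, xq) {
  k <- length(xs)
  stopifnot(k >= 4)
  h <- diff(xs)
  A <- matrix(0, k, k)
  b <- numeric(k)
  for (i in 2:(k - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1])
  }
  # not-a-knot: third-derivative continuity at the 2nd and (k-1)th knots
  A[1, 1] <- h[2]; A[1, 2] <- -(h[1] + h[2]); A[1, 3] <- h[1]
  A[k, k - 2] <- h[k - 1]; A[k, k - 1] <- -(h[k - 2] + h[k - 1]); A[k, k] <- h[k - 2]
  M <- solve(A, b)
  vapply(xq, function(t) {
    seg <- max(1, min(k - 1, findInterval(t, xs)))
    hi <- h[seg]
    Aa <- xs[seg + 1] - t
    Bb <- t - xs[seg]
    M[seg] * Aa^3 / (6 * hi) + M[seg + 1] * Bb^3 / (6 * hi) +
      (ys[seg] / hi - M[seg] * hi / 6) * Aa +
      (ys[seg + 1] / hi - M[seg + 1] * hi / 6) * Bb
  }, numeric(1))
}

# Queue-based flood fill over an adjacency list; labels components of
# {v > thr}, 0 elsewhere.
flood_fill <- function(v, thr, adj) {
  n <- length(v)
  lab <- integer(n)
  ncl <- 0L
  for (s in seq_len(n)) {
    if (v[s] <= thr || lab[s] != 0L) next
    ncl <- ncl + 1L
    queue <- s
    lab[s] <- ncl
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (w in adj[[u]]) {
        if (v[w] > thr && lab[w] == 0L) {
          lab[w] <- ncl
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# TRUE when two labelings induce the same partition of the labelled nodes.
same_partition <- function(a, b) {
  ka <- unname(lapply(split(seq_along(a), a), sort))
  kb <- unname(lapply(split(seq_along(b), b), sort))
  ka <- ka[names(split(seq_along(a), a)) != "0"]
  kb <- kb[names(split(seq_along(b), b)) != "0"]
  length(ka) == length(kb) && setequal(ka, kb)
}

# zero-crossing count (sign changes, zeros ignored)
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

# Subject-level lattice data built from independent pure-mode series, so
# composite modes are exact partial sums (the structure the method assumes).
# orders: the lattice orders (e.g. 2:6); returns n_modes x n_bins.
lattice_subject <- function(cons, orders, n_bins, effect_order = NULL,
                            effect = 0, effect_bins = NULL) {
  pure <- matrix(rnorm(length(orders) * n_bins), length(orders), n_bins)
  if (!is.null(effect_order)) {
    row <- match(effect_order, orders)
    if (is.null(effect_bins)) effect_bins <- seq_len(n_bins)
    pure[row, effect_bins] <- pure[row, effect_bins] + effect
  }
  t(vapply(cons, function(s) colSums(pure[match(s, orders), , drop = FALSE]),
           numeric(n_bins)))
}

# stack subjects into a subjects x nodes matrix (nodes: mode fastest, then time)
lattice_subjects <- function(n_subj, cons, orders, n_bins, ...) {
  t(vapply(seq_len(n_subj),
           function(i) as.vector(lattice_subject(cons, orders, n_bins, ...)),
           numeric(length(cons) * n_bins)))
}
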