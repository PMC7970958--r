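# Instantaneous-frequency estimation and the mode-range selection that the
# iERP lattice is built from.

analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

#' Instantaneous frequency of an IMF
#'
#' Hilbert analytic-signal phase, unwrapped, differentiated by centred
#' differences and scaled to Hz; values are clipped to `[0, fs/2]`. An
#' all-zero input returns an all-zero series flagged with
#' `attr(, "degenerate")`.
#'
#' @param imf numeric series (one IMF).
#' @param fs sampling rate (Hz).
#' @return Numeric vector of per-sample frequencies (Hz).
#' @export
instantaneous_frequency <- function(imf, fs) {
  imf <- as.numeric(imf)
  if (any(!is.finite(imf))) stop_ierp("IMF must be finite", "ierp_invalid_signal")
  n <- length(imf)
  if (all(imf == 0)) {
    out <- numeric(n)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ph <- unwrap_phase(Arg(analytic_signal(imf)))
  d <- numeric(n)
  d[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) / 2
  d[1] <- ph[2] - ph[1]
  d[n] <- ph[n] - ph[n - 1]
  pmin(pmax(d * fs / (2 * pi), 0), fs / 2)
}

#' Log-spaced frequency bins used for representative frequencies
#'
#' 48 logarithmically spaced bins spanning 0.25-64 Hz (octave-uniform
#' resolution for a dyadic filter bank).
#'
#' @param lo,hi bin range (Hz).
#' @param n_bins number of bins.
#' @return List with `edges` (length `n_bins + 1`) and geometric `centers`.
#' @export
if_bins <- function(lo = 0.25, hi = 64, n_bins = 48L) {
  edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1L))
  list(edges = edges, centers = sqrt(edges[-1] * edges[-length(edges)]))
}

#' Representative frequency of an IF distribution
#'
#' The frequency with the maximum occurrence probability: a histogram of the
#' instantaneous-frequency values over log-spaced bins, returning the centre
#' of the fullest bin (ties resolved to the lower bin). Values outside the
#' bin range are clamped into the end bins, so very slow trend components
#' report the lowest bin centre.
#'
#' @param ifs numeric vector of instantaneous frequencies (Hz), possibly
#'   pooled over samples/trials.
#' @param bins from [if_bins()].
#' @return A single frequency (Hz).
#' @export
representative_frequency <- function(ifs, bins = if_bins()) {
  ifs <- ifs[is.finite(ifs)]
  if (!length(ifs)) stop_ierp("no finite IF values", "ierp_invalid_argument")
  lo <- bins$edges[1]
  hi <- bins$edges[length(bins$edges)]
  ifs <- pmin(pmax(ifs, lo), hi)
  idx <- findInterval(ifs, bins$edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(bins$centers))
  counts <- tabulate(idx, nbins = length(bins$centers))
  bins$centers[which.max(counts)]
}

rep_freq_table <- function(stack, orders = NULL, bins = if_bins()) {
  dm <- dim(stack$values)
  if (is.null(orders)) orders <- seq_len(stack$K)
  out <- array(NA_real_, dim = c(dm[1], dm[2], length(orders)))
  for (tr in seq_len(dm[1])) {
    for (ch in seq_len(dm[2])) {
      for (j in seq_along(orders)) {
        s <- stack$values[tr, ch, orders[j], ]
        if (all(s == 0)) next
        out[tr, ch, j] <- representative_frequency(
          instantaneous_frequency(s, stack$fs), bins)
      }
    }
  }
  out
}

#' Order/channel consistency table of representative frequencies
#'
#' For each IMF order and channel, the 5/25/50/75/95 percentiles of the
#' per-trial representative frequencies — the box-and-whisker diagnostic of
#' time-scale consistency in the order of IMFs.
#'
#' @param stack an `ierp_imfstack` from [decompose_epochs()].
#' @param bins from [if_bins()].
#' @return Tidy data frame with columns `order`, `channel`, `quantile`, `Hz`.
#' @export
if_consistency_summary <- function(stack, bins = if_bins()) {
  stopifnot(inherits(stack, "ierp_imfstack"))
  rf <- rep_freq_table(stack, bins = bins)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  rows <- list()
  for (k in seq_len(stack$K)) {
    for (ch in seq_len(dim(rf)[2])) {
      v <- rf[, ch, k]
      v <- v[is.finite(v)]
      if (!length(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        order = k, channel = stack$channels[ch], quantile = qs,
        Hz = as.numeric(quantile(v, qs, names = FALSE)))
    }
  }
  do.call(rbind, rows)
}

#' Select the iERP mode range from the decomposition
#'
#' `p_min` is the lowest IMF order whose dataset-wide median representative
#' frequency falls below `hi_cut` (default 30 Hz; faster orders are excluded
#' from the lattice). `trend_start` is the lowest order whose median falls
#' below `lo_cut` (default 2 Hz); that order and everything slower —
#' including the residue — are aggregated into one trend block (`"+"`).
#' When no order is below `lo_cut` the trend block is the residue alone
#' (`trend_start = K + 1`).
#'
#' @param x an `ierp_imfstack`, or a numeric vector of per-order median
#'   representative frequencies (Hz).
#' @param hi_cut,lo_cut cutoffs in Hz.
#' @param bins from [if_bins()].
#' @return A list of class `ierp_mode_range` with `p_min`, `trend_start`,
#'   `hi_cut`, `lo_cut`, `medians`, `K`.
#' @export
select_mode_range <- function(x, hi_cut = 30, lo_cut = 2, bins = if_bins()) {
  if (inherits(x, "ierp_imfstack")) {
    rf <- rep_freq_table(x, bins = bins)
    med <- apply(rf, 3, median, na.rm = TRUE)
    K <- x$K
  } else {
    med <- as.numeric(x)
    K <- length(med)
  }
  below_hi <- which(med < hi_cut)
  if (!length(below_hi)) {
    stop_ierp(sprintf("no IMF order has median representative frequency below %g Hz", hi_cut),
              "ierp_config_error")
  }
  p_min <- min(below_hi)
  below_lo <- which(med < lo_cut)
  trend_start <- if (length(below_lo)) min(below_lo) else K + 1L
  structure(list(p_min = as.integer(p_min),
                 trend_start = as.integer(trend_start),
                 hi_cut = hi_cut, lo_cut = lo_cut,
                 medians = med, K = as.integer(K)),
            class = "ierp_mode_range")
}

#' @export
print.ierp_mode_range <- function(x, ...) {
  cat(sprintf("iERP mode range: orders %d..%d+ (hi_cut %g Hz, lo_cut %g Hz)\n",
              x$p_min, x$trend_start, x$hi_cut, x$lo_cut))
  cat("  per-order median representative Hz:",
      paste(sprintf("%.2f", x$medians), collapse = ", "), "\n")
  invisible(x)
}
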