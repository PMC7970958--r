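#' Enumerate the iERP mode lattice labels
#'
#' All pure modes `p:p` and composite modes `p:q` for
#' `p_min <= p <= q <= trend_start`, where `q = trend_start` denotes the
#' trend block (rendered with a `"+"` suffix) that aggregates every order
#' from `trend_start` through the final residue. For `M = trend_start -
#' p_min + 1` lattice orders this yields `M * (M + 1) / 2` modes, ordered
#' lexicographically by `(p, q)` with the trend column last in each row.
#'
#' @param range an `ierp_mode_range` from [select_mode_range()], or the
#'   integer `p_min` when `trend_start`/`K` are given explicitly.
#' @param trend_start,K see [select_mode_range()]; `K` is the number of
#'   extracted IMFs (the residue is order `K + 1`).
#' @return A data frame of class `ierp_mode_labels` with columns `p`, `q`,
#'   `trend`, `label`, and attributes `constituents` (list of full
#'   constituent order sets) and `effective` (sets with the trend block
#'   collapsed to the single pseudo-ordinal `trend_start`).
#' @examples
#' mode_labels(2, 6, K = 7)$label
#' @export
mode_labels <- function(range, trend_start = NULL, K = NULL) {
  if (inherits(range, "ierp_mode_range")) {
    p_min <- range$p_min; trend_start <- range$trend_start; K <- range$K
  } else {
    p_min <- as.integer(range)
  }
  stopifnot(p_min >= 1L, trend_start >= p_min, K + 1L >= trend_start)
  block <- seq.int(trend_start, K + 1L)
  rows <- list(); cons <- list(); eff <- list()
  for (p in seq.int(p_min, trend_start)) {
    for (q in seq.int(p, trend_start)) {
      trend <- q == trend_start
      label <- if (trend && p == trend_start) {
        paste0(trend_start, "+")
      } else if (trend) {
        paste0(p, ":", trend_start, "+")
      } else {
        paste0(p, ":", q)
      }
      rows[[length(rows) + 1L]] <- data.frame(p = p, q = q, trend = trend,
                                              label = label)
      cons[[length(cons) + 1L]] <- if (trend) {
        c(if (p < trend_start) seq.int(p, trend_start - 1L), block)
      } else {
        seq.int(p, q)
      }
      eff[[length(eff) + 1L]] <- seq.int(p, q)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "constituents") <- cons
  attr(out, "effective") <- eff
  attr(out, "p_min") <- p_min
  attr(out, "trend_start") <- as.integer(trend_start)
  attr(out, "K") <- as.integer(K)
  class(out) <- c("ierp_mode_labels", "data.frame")
  out
}

#' Form trial-averaged iERP modes
#'
#' For each condition, averages every possible IMF (pure mode) and partial
#' sum of consecutive IMFs (composite mode) over that condition's trials.
#' Trend modes sum all orders from `trend_start` through the residue.
#' Because averaging is linear, each composite mode equals the sum of its
#' pure constituents exactly.
#'
#' @param stack an `ierp_imfstack` from [decompose_epochs()].
#' @param range an `ierp_mode_range`.
#' @param conditions optional per-trial labels (defaults to those carried by
#'   the stack).
#' @return Named list (one element per condition) of `ierp_modes` objects:
#'   `values` (mode x channel x time array), `labels`, `time`, `fs`,
#'   `n_trials`, `condition`, `range`, `channels`.
#' @export
form_ierp_modes <- function(stack, range, conditions = NULL) {
  stopifnot(inherits(stack, "ierp_imfstack"), inherits(range, "ierp_mode_range"))
  if (is.null(conditions)) conditions <- stack$conditions
  dm <- dim(stack$values)
  if (length(conditions) != dm[1]) {
    stop_ierp("condition labels must align with trials", "ierp_invalid_argument")
  }
  labels <- mode_labels(range)
  cons <- attr(labels, "constituents")
  out <- list()
  for (cond in unique(conditions)) {
    idx <- which(conditions == cond)
    if (!length(idx)) stop_ierp(sprintf("condition '%s' has no trials", cond),
                                "ierp_invalid_argument")
    # trial-average each order first (averaging commutes with summation)
    avg <- apply(stack$values[idx, , , , drop = FALSE], c(2, 3, 4), mean)
    # avg: channel x order x time
    vals <- array(0, dim = c(nrow(labels), dm[2], dm[4]))
    for (m in seq_len(nrow(labels))) {
      ords <- cons[[m]]
      if (length(ords) == 1L) {
        vals[m, , ] <- avg[, ords, ]
      } else {
        vals[m, , ] <- apply(avg[, ords, , drop = FALSE], c(1, 3), sum)
      }
    }
    out[[cond]] <- structure(
      list(values = vals, labels = labels, time = stack$time, fs = stack$fs,
           n_trials = length(idx), condition = cond, range = range,
           channels = stack$channels, layout = stack$layout),
      class = "ierp_modes")
  }
  out
}

#' @export
print.ierp_modes <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("iERP modes '%s': %d modes x %d channels x %d samples (%d trials)\n",
              x$condition, dm[1], dm[2], dm[3], x$n_trials))
  invisible(x)
}

#' Baseline-correct iERP modes
#'
#' Subtracts the per-mode, per-channel mean over a pre-onset window. Applied
#' after trial averaging; linearity makes the order immaterial.
#'
#' @param modes an `ierp_modes` object or a list of them.
#' @param window `c(t0, t1)` in seconds (inclusive); must overlap the axis.
#' @return Object(s) of the same shape, baseline-corrected.
#' @export
baseline_correct <- function(modes, window) {
  if (!inherits(modes, "ierp_modes") && is.list(modes)) {
    return(lapply(modes, baseline_correct, window = window))
  }
  stopifnot(inherits(modes, "ierp_modes"), length(window) == 2L)
  sel <- modes$time >= window[1] & modes$time <= window[2]
  if (!any(sel)) stop_ierp("baseline window contains no samples", "ierp_invalid_argument")
  base <- apply(modes$values[, , sel, drop = FALSE], c(1, 2), mean)
  modes$values <- sweep(modes$values, c(1, 2), base, "-")
  modes$baseline <- window
  modes
}

#' Average iERP modes into contiguous time bins
#'
#' Means within half-open bins `[t, t + bin_width)` laid from `span[1]`; a
#' partial trailing bin is dropped. When the bin width exceeds the period of
#' a lattice order's median representative frequency, a warning names the
#' affected modes (their oscillations average out within a bin); exclusion
#' remains the caller's choice.
#'
#' @param modes an `ierp_modes` object or a list of them.
#' @param bin_width bin width in seconds.
#' @param span `c(t0, t1)` in seconds (defaults to the full axis).
#' @return Object(s) with the binned time axis (bin centres).
#' @export
time_bin <- function(modes, bin_width, span = NULL) {
  if (!inherits(modes, "ierp_modes") && is.list(modes)) {
    return(lapply(modes, time_bin, bin_width = bin_width, span = span))
  }
  stopifnot(inherits(modes, "ierp_modes"), bin_width > 0)
  if (is.null(span)) span <- range(modes$time)
  n_bins <- floor((span[2] - span[1]) / bin_width + 1e-9)
  if (n_bins < 1L) stop_ierp("span shorter than one bin", "ierp_invalid_argument")
  dm <- dim(modes$values)
  out <- array(0, dim = c(dm[1], dm[2], n_bins))
  centers <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    t0 <- span[1] + (b - 1) * bin_width
    sel <- modes$time >= t0 - 1e-12 & modes$time < t0 + bin_width - 1e-12
    if (!any(sel)) stop_ierp("empty time bin (bin narrower than one sample?)",
                             "ierp_invalid_argument")
    out[, , b] <- apply(modes$values[, , sel, drop = FALSE], c(1, 2), mean)
    centers[b] <- t0 + bin_width / 2
  }
  med <- modes$range$medians
  if (!is.null(med)) {
    bad_orders <- which(is.finite(med) & (1 / med) < bin_width)
    aff <- modes$labels$label[modes$labels$p %in% bad_orders]
    if (length(aff)) {
      warning(sprintf("bin width %.3g s exceeds the period of order(s) %s; affected modes: %s",
                      bin_width, paste(bad_orders, collapse = ","),
                      paste(aff, collapse = ", ")))
    }
  }
  modes$values <- out
  modes$time <- centers
  modes$bin_width <- bin_width
  modes
}

#' Export iERP modes to a long-format data frame
#'
#' @param modes an `ierp_modes` object or named list of them.
#' @param subject subject id column value.
#' @return Data frame with columns `subject`, `condition`, `mode`, `channel`,
#'   `time`, `value`.
#' @export
modes_to_long <- function(modes, subject = "S01") {
  if (!inherits(modes, "ierp_modes") && is.list(modes)) {
    return(do.call(rbind, lapply(modes, modes_to_long, subject = subject)))
  }
  dm <- dim(modes$values)
  data.frame(subject = subject, condition = modes$condition,
             mode = rep(modes$labels$label, times = dm[2] * dm[3]),
             channel = rep(rep(modes$channels, each = dm[1]), times = dm[3]),
             time = rep(modes$time, each = dm[1] * dm[2]),
             value = as.vector(modes$values))
}
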