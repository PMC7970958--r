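#' Locate interior extrema of a signal
#'
#' Finds strictly interior local maxima and minima. Runs of equal values
#' (plateaus) contribute a single extremum at their midpoint index (the lower
#' middle for even-length plateaus), which keeps the decomposition
#' deterministic on quantised data.
#'
#' @param x numeric signal (finite values).
#' @return A list with integer vectors `maxima` and `minima` (ascending,
#'   1-based). Either may be empty.
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0, 1, 0))
#' @export
find_extrema <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) {
    stop_ierp("signal must be finite", "ierp_invalid_signal")
  }
  cpp_find_extrema(x)
}

#' Mean of the upper and lower cubic-spline envelopes
#'
#' Connects local maxima (minima) by a not-a-knot cubic spline to obtain the
#' upper (lower) envelope and returns the pointwise mean. Up to two extrema
#' are mirror-extended across each end of the signal before fitting, which
#' suppresses spline end swings; with fewer than four knots the envelope
#' degrades gracefully to a parabola or straight line.
#'
#' @param x numeric signal.
#' @param maxima,minima optional integer index vectors; located with
#'   [find_extrema()] when omitted.
#' @return Numeric vector of the same length as `x`.
#' @export
envelope_mean <- function(x, maxima = NULL, minima = NULL) {
  x <- as.numeric(x)
  if (is.null(maxima) || is.null(minima)) {
    ex <- find_extrema(x)
    if (is.null(maxima)) maxima <- ex$maxima
    if (is.null(minima)) minima <- ex$minima
  }
  if (length(maxima) < 1L || length(minima) < 1L) {
    stop_ierp("insufficient extrema for envelope construction",
              "ierp_insufficient_extrema")
  }
  cpp_envelope_from_extrema(x, as.integer(maxima), as.integer(minima))
}

#' Extract one IMF candidate by fixed-count sifting
#'
#' Repeatedly subtracts the envelope mean from the signal. The sift count is
#' fixed (default 10), the stopping rule that keeps empirical mode
#' decomposition a nearly dyadic filter for white noise; sifting stops early
#' (with attribute `early = TRUE`) if the candidate runs out of extrema.
#'
#' @param x numeric signal.
#' @param n_sifts number of sifting iterations (default 10).
#' @return Numeric vector (the IMF candidate) with attributes `sifts_used`
#'   and `early`.
#' @export
sift_imf <- function(x, n_sifts = 10L) {
  stopifnot(n_sifts >= 1L)
  x <- as.numeric(x)
  res <- cpp_sift(x, as.integer(n_sifts))
  out <- res$imf
  attr(out, "sifts_used") <- res$sifts_used
  attr(out, "early") <- res$sifts_used < n_sifts
  out
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions by iterating the sifting
#' process on successive residues until the residue retains no more than two
#' extrema. The components satisfy the exact reconstruction identity
#' `x = sum(imfs) + residue`.
#'
#' @param x numeric signal, length >= 8.
#' @param max_imf safety cap on the number of IMFs (default 64).
#' @param n_sifts sifts per IMF (default 10).
#' @return An object of class `ierp_imflist`: list with `imfs` (list of
#'   numeric vectors), `residue`, and `n_sifts_used` (integer per IMF).
#' @examples
#' d <- emd(sin(2 * pi * 4 * seq(0, 1, length.out = 256)))
#' length(d$imfs)
#' @export
emd <- function(x, max_imf = 64L, n_sifts = 10L) {
  x <- as.numeric(x)
  if (length(x) < 8L) stop_ierp("signal length must be >= 8", "ierp_invalid_signal")
  if (any(!is.finite(x))) stop_ierp("signal must be finite", "ierp_invalid_signal")
  res <- cpp_emd(x, as.integer(max_imf), as.integer(n_sifts))
  structure(list(imfs = res$imfs, residue = res$residue,
                 n_sifts_used = as.integer(res$n_sifts_used)),
            class = "ierp_imflist")
}

#' @export
print.ierp_imflist <- function(x, ...) {
  cat(sprintf("EMD decomposition: %d IMFs + residue (n = %d)\n",
              length(x$imfs), length(x$residue)))
  invisible(x)
}

#' The k-th EMD mode operator E_k(.)
#'
#' Returns the k-th intrinsic mode function of `x`, the operator used by the
#' CEEMDAN recursion to generate matched-order adaptive noise. When the
#' decomposition yields fewer than `k` IMFs a zero series is returned with a
#' warning.
#'
#' @param x numeric signal.
#' @param k mode order (>= 1).
#' @return Numeric vector of the same length as `x`.
#' @export
emd_mode_k <- function(x, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop_ierp("k must be a single integer >= 1", "ierp_invalid_argument")
  }
  d <- emd(x)
  if (length(d$imfs) < k) {
    warning(sprintf("signal has only %d IMFs; E_%d is zero", length(d$imfs), k))
    return(numeric(length(x)))
  }
  d$imfs[[k]]
}
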