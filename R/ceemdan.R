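#' CEEMDAN configuration
#'
#' Parameters for the improved complete-ensemble EMD with adaptive noise.
#' `epsilon` sets the amplitude coefficient of the added noise modes
#' (`beta_k = epsilon_k * sd(r_k) / sd(E_{k+1}(w))`, the published value is
#' 0.2); `l` is the number of complementary noise pairs (2*l realizations
#' enter every ensemble mean); `K` the number of IMFs to extract (default
#' `floor(log2(N)) - 2`, leaving headroom for a residue under the dyadic
#' filter-bank property so that K is identical across trials and channels).
#'
#' @param epsilon noise amplitude coefficient(s), recycled to `K`.
#' @param K number of IMFs; `NULL` to derive from the signal length.
#' @param l ensemble size in complementary pairs.
#' @param seed master seed; per-trial child seeds are split deterministically.
#' @param complementary use complementary noise pairs (recommended).
#' @param sign_shortcut reuse `-E_k(w)` for the complementary member instead
#'   of decomposing `-w` explicitly. The two are identical here because the
#'   sifting rules are odd-symmetric; the explicit route is the default.
#' @param noise_share `"trial"` shares one noise ensemble across channels
#'   within a trial (promotes interchannel order consistency); `"channel"`
#'   draws independent ensembles per channel.
#' @param n_sifts sifts per extracted mode (default 10).
#' @return A list of class `ierp_ceemdan_config`.
#' @export
ceemdan_config <- function(epsilon = 0.2, K = NULL, l = 50L, seed = NULL,
                           complementary = TRUE, sign_shortcut = FALSE,
                           noise_share = c("trial", "channel"),
                           n_sifts = 10L) {
  stopifnot(all(epsilon > 0), l >= 1L, is.null(K) || K >= 1L)
  structure(list(epsilon = epsilon, K = if (is.null(K)) NULL else as.integer(K),
                 l = as.integer(l), seed = seed,
                 complementary = isTRUE(complementary),
                 sign_shortcut = isTRUE(sign_shortcut),
                 noise_share = match.arg(noise_share),
                 n_sifts = as.integer(n_sifts)),
            class = "ierp_ceemdan_config")
}

#' Build a complementary white-noise ensemble
#'
#' Draws `l` realizations of N(0, 1) white Gaussian noise from the seeded
#' generator and EMD-decomposes each one to `K` modes, yielding the adaptive
#' noise `E_k(w)`. With `complementary = TRUE` each realization is paired
#' with its negation; the negated realization is decomposed explicitly
#' unless `sign_shortcut` opts into reusing `-E_k(w)`.
#'
#' @param n_samples signal length (>= 8).
#' @param l number of noise pairs.
#' @param K number of noise modes to keep.
#' @param seed RNG seed (restored on exit).
#' @param complementary,sign_shortcut see [ceemdan_config()].
#' @return A list of class `ierp_noise_ensemble` with elements `noise`
#'   (n x l matrix), `imfs` and `neg_imfs` (lists of n x K matrices,
#'   zero-padded past the last available mode), `l`, `K`, `seed`,
#'   `complementary`.
#' @export
build_noise_ensemble <- function(n_samples, l, K, seed = NULL,
                                 complementary = TRUE, sign_shortcut = FALSE) {
  stopifnot(n_samples >= 8L, l >= 1L, K >= 1L)
  W <- with_seed(seed, matrix(rnorm(n_samples * l), n_samples, l))
  decomp <- function(w) {
    d <- cpp_emd(w, as.integer(K), 10L)
    out <- matrix(0, n_samples, K)
    nm <- length(d$imfs)
    for (k in seq_len(min(nm, K))) out[, k] <- d$imfs[[k]]
    out
  }
  imfs <- lapply(seq_len(l), function(i) decomp(W[, i]))
  neg_imfs <- NULL
  if (complementary) {
    neg_imfs <- if (sign_shortcut) {
      lapply(imfs, function(m) -m)
    } else {
      lapply(seq_len(l), function(i) decomp(-W[, i]))
    }
  }
  structure(list(noise = W, imfs = imfs, neg_imfs = neg_imfs,
                 l = as.integer(l), K = as.integer(K), seed = seed,
                 complementary = complementary),
            class = "ierp_noise_ensemble")
}

#' Improved CEEMDAN decomposition of one signal
#'
#' Implements the improved complete-ensemble EMD with adaptive noise: at
#' stage k the ensemble of realizations `r_{k-1} +/- beta_{k-1} E_k(w)` is
#' sifted once (a full fixed-count sift extraction), the CEEMDAN residue is
#' the ensemble mean of the realization residues, and the k-th IMF is the
#' difference of consecutive residues. The telescoping construction makes
#' `sum(imfs) + residue == x` exact to machine precision. If a residue runs
#' out of extrema before `K` modes are extracted, the remaining orders are
#' zero and the event is flagged.
#'
#' @param x numeric signal.
#' @param ensemble a noise ensemble from [build_noise_ensemble()] built for
#'   the same length and at least `K` orders.
#' @param config an [ceemdan_config()] object.
#' @return A list of class `ierp_ceemdan` with `imfs` (n x K matrix,
#'   column k = mode k), `residue`, `K`, `flags` (character).
#' @export
ceemdan_decompose <- function(x, ensemble, config = ceemdan_config()) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(inherits(ensemble, "ierp_noise_ensemble"),
            nrow(ensemble$noise) == n)
  K <- if (is.null(config$K)) ensemble$K else min(config$K, ensemble$K)
  eps <- rep_len(config$epsilon, K)
  n_sifts <- config$n_sifts
  mats <- ensemble$imfs
  if (isTRUE(ensemble$complementary) && !is.null(ensemble$neg_imfs)) {
    mats <- c(mats, ensemble$neg_imfs)
  }
  nreal <- length(mats)
  imfs <- matrix(0, n, K)
  flags <- character(0)
  r <- x
  for (k in seq_len(K)) {
    ex <- cpp_find_extrema(r)
    if (length(ex$maxima) + length(ex$minima) <= 2L) {
      flags <- c(flags, sprintf("residue monotone before order %d; higher orders zero", k))
      break
    }
    sdr <- sd(r)
    acc <- numeric(n)
    for (i in seq_len(nreal)) {
      ek <- mats[[i]][, k]
      sde <- sd(ek)
      beta <- if (sde > 0) eps[k] * sdr / sde else 0
      xi <- r + beta * ek
      s <- cpp_sift(xi, n_sifts)
      if (s$sifts_used == 0L) {
        flags <- c(flags, sprintf("realization %d order %d: no sift possible", i, k))
        acc <- acc + xi
      } else {
        acc <- acc + (xi - s$imf)
      }
    }
    rk <- acc / nreal
    imfs[, k] <- r - rk
    r <- rk
  }
  structure(list(imfs = imfs, residue = r, K = K, flags = flags),
            class = "ierp_ceemdan")
}

#' Decompose every trial and channel of an epoch set
#'
#' Applies [ceemdan_decompose()] independently to each trial x channel
#' series. One noise ensemble per trial is shared across channels by default
#' (interchannel order consistency); per-trial child seeds are derived from
#' the master seed by a fixed splitting rule, so results do not depend on
#' the processing order.
#'
#' @param epochs an [epoch_set()].
#' @param config an [ceemdan_config()]; `config$K = NULL` selects
#'   `floor(log2(n_time)) - 2`.
#' @return An `ierp_imfstack`: list with `values`
#'   (trial x channel x order x time array, order `K + 1` holding the final
#'   residue), `fs`, `time`, `K`, `conditions`, `subject`, `layout`,
#'   `channels`, `seed`, and a `qc` data frame of per-trial/channel flags.
#' @export
decompose_epochs <- function(epochs, config = ceemdan_config()) {
  stopifnot(inherits(epochs, "ierp_epochs"))
  dm <- dim(epochs$data)
  n_trial <- dm[1]; n_chan <- dm[2]; n_time <- dm[3]
  K <- if (is.null(config$K)) max(1L, floor(log2(n_time)) - 2L) else config$K
  vals <- array(0, dim = c(n_trial, n_chan, K + 1L, n_time))
  qc <- list()
  for (tr in seq_len(n_trial)) {
    tr_seed <- if (is.null(config$seed)) NULL else child_seed(config$seed, tr)
    shared <- NULL
    if (config$noise_share == "trial") {
      shared <- build_noise_ensemble(n_time, config$l, K, seed = tr_seed,
                                     complementary = config$complementary,
                                     sign_shortcut = config$sign_shortcut)
    }
    for (ch in seq_len(n_chan)) {
      ens <- shared
      if (is.null(ens)) {
        ch_seed <- if (is.null(tr_seed)) NULL else child_seed(tr_seed, ch)
        ens <- build_noise_ensemble(n_time, config$l, K, seed = ch_seed,
                                    complementary = config$complementary,
                                    sign_shortcut = config$sign_shortcut)
      }
      cfgK <- config
      cfgK$K <- K
      dec <- ceemdan_decompose(epochs$data[tr, ch, ], ens, cfgK)
      vals[tr, ch, seq_len(K), ] <- t(dec$imfs)
      vals[tr, ch, K + 1L, ] <- dec$residue
      if (length(dec$flags)) {
        qc[[length(qc) + 1L]] <- data.frame(trial = tr, channel = ch,
                                            flag = dec$flags)
      }
    }
  }
  qc <- if (length(qc)) do.call(rbind, qc) else
    data.frame(trial = integer(0), channel = integer(0), flag = character(0))
  structure(list(values = vals, fs = epochs$fs, time = epochs$time, K = K,
                 conditions = epochs$conditions, subject = epochs$subject,
                 layout = epochs$layout, channels = epochs$channels,
                 seed = config$seed, config = config, qc = qc),
            class = "ierp_imfstack")
}

#' @export
print.ierp_imfstack <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("IMF stack: %d trials x %d channels x %d orders (K = %d + residue) x %d samples @ %g Hz\n",
              dm[1], dm[2], dm[3], x$K, dm[4], x$fs))
  if (nrow(x$qc)) cat(sprintf("  %d QC flags\n", nrow(x$qc)))
  invisible(x)
}
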