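# Synthetic epoch generator: oscillatory bursts phase-locked to the event at
# chosen time scales, condition gains, 1/f plus white noise, and the SNR-4
# pseudo-condition used for false-alarm checks.

#' Describe one oscillatory ERP-like component
#'
#' A Hann-windowed oscillatory burst with a controllable characteristic
#' scale (carrier frequency), latency and phase locking.
#'
#' @param freq carrier frequency (Hz).
#' @param amp amplitude (uV).
#' @param latency burst centre relative to the event (s).
#' @param cycles burst duration in carrier cycles.
#' @param locked `TRUE` for a phase-locked (deterministic) burst; `FALSE`
#'   draws a uniform random carrier phase per trial.
#' @param jitter_sd latency jitter SD per trial (s).
#' @param gain condition gain: condition `"B"` multiplies the amplitude by
#'   this factor (1 = null component).
#' @param channels channel indices carrying the component (`NULL` = all).
#' @return A list describing the component.
#' @export
sim_component <- function(freq, amp = 1, latency = 0.2, cycles = 3,
                          locked = TRUE, jitter_sd = 0, gain = 1,
                          channels = NULL) {
  stopifnot(freq > 0, amp >= 0, cycles > 0)
  list(freq = freq, amp = amp, latency = latency, cycles = cycles,
       locked = locked, jitter_sd = jitter_sd, gain = gain,
       channels = channels)
}

#' Specify a synthetic ERP experiment
#'
#' Defaults emulate a desk-scale two-condition ERP study: 16 subjects, 30
#' trials per condition, one posterior channel, 200 Hz sampling, epochs from
#' -0.5 to 1.2 s, an early 10 Hz burst (no condition effect) and a 6 Hz
#' component whose amplitude is 1.5x in condition B, both with 20 ms latency
#' jitter, over a 1/f background (exponent 1) plus white noise that dominates
#' the single trial (single-trial SNR well below 1, as in real EEG; the ERP
#' emerges through trial averaging).
#'
#' @param n_subjects,n_trials,n_channels,fs experiment dimensions.
#' @param epoch `c(t0, t1)` epoch span (s), event at 0.
#' @param components list of [sim_component()]s.
#' @param noise list with `pink_sd`, `pink_exponent`, `white_sd` (uV).
#' @param subject_sd between-subject amplitude scaling SD (multiplicative,
#'   around 1).
#' @param seed master seed.
#' @return A list of class `ierp_sim_spec`.
#' @export
sim_spec <- function(n_subjects = 16L, n_trials = 30L, n_channels = 1L,
                     fs = 200, epoch = c(-0.5, 1.2),
                     components = list(
                       sim_component(10, amp = 2, latency = 0.1,
                                     jitter_sd = 0.02, gain = 1),
                       sim_component(6, amp = 2, latency = 0.25,
                                     jitter_sd = 0.02, gain = 1.5)),
                     noise = list(pink_sd = 4, pink_exponent = 1, white_sd = 2),
                     subject_sd = 0.1, seed = NULL) {
  for (cmp in components) stopifnot(cmp$freq < fs / 2)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels), fs = fs, epoch = epoch,
                 components = components, noise = noise,
                 subject_sd = subject_sd, seed = seed),
            class = "ierp_sim_spec")
}

hann_burst <- function(time, freq, amp, latency, cycles, phase) {
  dur <- cycles / freq
  rel <- time - latency
  w <- ifelse(abs(rel) <= dur / 2, 0.5 * (1 + cos(2 * pi * rel / dur)), 0)
  amp * w * cos(2 * pi * freq * rel + phase)
}

pink_noise <- function(n, exponent, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  w <- rnorm(n)
  X <- fft(w)
  f <- c(1e-12, seq_len(floor(n / 2)), rev(seq_len(ceiling(n / 2) - 1L)))
  X <- X * f^(-exponent / 2)
  X[1] <- 0
  x <- Re(fft(X, inverse = TRUE) / n)
  x * sd_target / sd(x)
}

make_trial <- function(spec, time, cond, subj_scale) {
  n_time <- length(time)
  arr <- matrix(0, spec$n_channels, n_time)
  truth <- list()
  for (j in seq_along(spec$components)) {
    cmp <- spec$components[[j]]
    amp <- cmp$amp * subj_scale * if (cond == "B") cmp$gain else 1
    lat <- cmp$latency + if (cmp$jitter_sd > 0) rnorm(1, 0, cmp$jitter_sd) else 0
    phase <- if (cmp$locked) 0 else runif(1, 0, 2 * pi)
    burst <- hann_burst(time, cmp$freq, amp, lat, cmp$cycles, phase)
    chans <- if (is.null(cmp$channels)) seq_len(spec$n_channels) else cmp$channels
    for (ch in chans) arr[ch, ] <- arr[ch, ] + burst
    truth[[j]] <- burst
  }
  for (ch in seq_len(spec$n_channels)) {
    arr[ch, ] <- arr[ch, ] +
      pink_noise(n_time, spec$noise$pink_exponent, spec$noise$pink_sd) +
      rnorm(n_time, 0, spec$noise$white_sd)
  }
  list(data = arr, truth = truth)
}

#' Simulate a two-condition ERP experiment
#'
#' Each trial is the sum of the specified oscillatory bursts (with their
#' locking and latency rules), 1/f background and white noise; condition
#' `"B"` scales each component by its condition gain. Ground-truth component
#' time courses are attached as an attribute.
#'
#' @param spec an [sim_spec()].
#' @return List of [epoch_set()]s, one per subject, each holding `A` and `B`
#'   trials interleaved; `attr(, "truth")` holds the noiseless component
#'   courses per subject/trial.
#' @export
simulate_erp_experiment <- function(spec) {
  stopifnot(inherits(spec, "ierp_sim_spec"))
  time <- seq(spec$epoch[1], spec$epoch[2], by = 1 / spec$fs)
  n_time <- length(time)
  out <- vector("list", spec$n_subjects)
  truths <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    res <- with_seed(
      if (is.null(spec$seed)) NULL else child_seed(spec$seed, s), {
        subj_scale <- 1 + rnorm(1, 0, spec$subject_sd)
        conds <- rep(c("A", "B"), each = spec$n_trials)
        dat <- array(0, dim = c(length(conds), spec$n_channels, n_time))
        tr_truth <- vector("list", length(conds))
        for (tr in seq_along(conds)) {
          mt <- make_trial(spec, time, conds[tr], subj_scale)
          dat[tr, , ] <- mt$data
          tr_truth[[tr]] <- mt$truth
        }
        list(ep = epoch_set(dat, spec$fs, conds, time = time,
                            subject = sprintf("S%02d", s)),
             truth = tr_truth)
      })
    out[[s]] <- res$ep
    truths[[s]] <- res$truth
  }
  attr(out, "truth") <- truths
  out
}

#' Add an SNR-controlled pseudo-condition
#'
#' Duplicates the given trials, adds white Gaussian noise with variance
#' equal to the per-trial signal variance divided by `snr`, and labels the
#' copies `"pseudo"` — a null second condition by construction, used to
#' check that the analysis does not manufacture false alarms.
#'
#' @param epochs an [epoch_set()] (typically one condition's trials).
#' @param snr signal-to-noise ratio of the added noise (published check: 4).
#' @param seed RNG seed.
#' @return An [epoch_set()] with the original trials labelled `"orig"`
#'   followed by the noisy copies labelled `"pseudo"`.
#' @export
make_pseudo_condition <- function(epochs, snr = 4, seed = NULL) {
  stopifnot(inherits(epochs, "ierp_epochs"), snr > 0)
  dm <- dim(epochs$data)
  noisy <- with_seed(seed, {
    out <- epochs$data
    for (tr in seq_len(dm[1])) {
      for (ch in seq_len(dm[2])) {
        v <- var(epochs$data[tr, ch, ])
        out[tr, ch, ] <- out[tr, ch, ] + rnorm(dm[3], 0, sqrt(v / snr))
      }
    }
    out
  })
  dat <- array(0, dim = c(2 * dm[1], dm[2], dm[3]))
  dat[seq_len(dm[1]), , ] <- epochs$data
  dat[dm[1] + seq_len(dm[1]), , ] <- noisy
  epoch_set(dat, epochs$fs, rep(c("orig", "pseudo"), each = dm[1]),
            time = epochs$time, channels = epochs$channels,
            subject = epochs$subject, layout = epochs$layout)
}

#' Simulate pure-noise epochs
#'
#' White or 1/f noise epochs for calibration experiments.
#'
#' @param n_trials,n_channels,fs,n_time experiment dimensions.
#' @param noise list with `kind` (`"white"` or `"pink"`), `sd`, and for pink
#'   noise `exponent`.
#' @param t0 epoch start (s).
#' @param seed RNG seed.
#' @return An [epoch_set()] with all trials labelled `"null"`.
#' @export
simulate_null_trials <- function(n_trials, n_channels, fs, n_time,
                                 noise = list(kind = "white", sd = 1,
                                              exponent = 1),
                                 t0 = 0, seed = NULL) {
  dat <- with_seed(seed, {
    arr <- array(0, dim = c(n_trials, n_channels, n_time))
    for (tr in seq_len(n_trials)) {
      for (ch in seq_len(n_channels)) {
        arr[tr, ch, ] <- if (identical(noise$kind, "pink")) {
          pink_noise(n_time, noise$exponent, noise$sd)
        } else {
          rnorm(n_time, 0, noise$sd)
        }
      }
    }
    arr
  })
  epoch_set(dat, fs, rep("null", n_trials), t0 = t0)
}
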