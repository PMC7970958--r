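#' Construct an epoch set
#'
#' The canonical container for epoched EEG: a trials x channels x time array
#' in microvolts, with a uniform event-relative time axis (event at t = 0),
#' one condition label per trial, and an optional channel layout.
#'
#' @param data numeric array `[trial, channel, time]`.
#' @param fs sampling rate in Hz.
#' @param conditions character/factor vector, one label per trial.
#' @param time optional time axis in seconds (defaults to samples starting
#'   at `t0`, spaced `1/fs`).
#' @param t0 epoch start relative to the event (s); ignored when `time`
#'   is given.
#' @param channels channel labels (default `"ch1"...`).
#' @param subject subject identifier.
#' @param layout optional channel layout data frame (`label`, `x`, `y`, `z`
#'   in mm), e.g. from [montage_1010()].
#' @return An object of class `ierp_epochs`.
#' @export
epoch_set <- function(data, fs, conditions, time = NULL, t0 = 0,
                      channels = NULL, subject = "S01", layout = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0)
  if (anyNA(data) || any(!is.finite(data))) {
    stop_ierp("epoch data must be finite with no NA", "ierp_invalid_epochs")
  }
  dm <- dim(data)
  conditions <- as.character(conditions)
  if (length(conditions) != dm[1]) {
    stop_ierp("need one condition label per trial", "ierp_invalid_epochs")
  }
  if (any(!nzchar(conditions))) {
    stop_ierp("condition labels must be nonempty", "ierp_invalid_epochs")
  }
  if (is.null(time)) {
    time <- t0 + (seq_len(dm[3]) - 1L) / fs
  } else {
    if (length(time) != dm[3]) {
      stop_ierp("time axis length must match the data", "ierp_invalid_epochs")
    }
    dt <- diff(time)
    if (max(abs(dt - 1 / fs)) > 1e-6 / fs) {
      stop_ierp("time axis must be uniform at 1/fs", "ierp_invalid_epochs")
    }
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(dm[2]))
  if (length(channels) != dm[2]) {
    stop_ierp("need one channel label per channel", "ierp_invalid_epochs")
  }
  if (!is.null(layout)) {
    missing <- setdiff(channels, layout$label)
    if (length(missing)) {
      stop_ierp(paste0("channels absent from layout: ",
                       paste(missing, collapse = ", ")),
                "ierp_invalid_epochs")
    }
    layout <- layout[match(channels, layout$label), , drop = FALSE]
  }
  structure(list(data = data, fs = fs, time = as.numeric(time),
                 conditions = conditions, channels = as.character(channels),
                 subject = subject, layout = layout),
            class = "ierp_epochs")
}

#' @export
print.ierp_epochs <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("Epoch set '%s': %d trials x %d channels x %d samples @ %g Hz, t in [%.3f, %.3f] s\n",
              x$subject, dm[1], dm[2], dm[3], x$fs, min(x$time), max(x$time)))
  cat("  conditions:", paste(sprintf("%s (%d)", names(table(x$conditions)),
                                     table(x$conditions)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an epoch set by trial
#'
#' @param x an `ierp_epochs` object.
#' @param trials integer or logical trial selector.
#' @return An `ierp_epochs` with the selected trials.
#' @export
subset_trials <- function(x, trials) {
  stopifnot(inherits(x, "ierp_epochs"))
  epoch_set(x$data[trials, , , drop = FALSE], x$fs, x$conditions[trials],
            time = x$time, channels = x$channels, subject = x$subject,
            layout = x$layout)
}

#' Write an epoch set to a plain-text container
#'
#' The container is a directory holding `meta.json` (sampling rate, subject,
#' channel labels, time axis origin, conditions) and `data.csv` (long
#' format: trial, channel, time index, value). Values round-trip doubles
#' bit-exactly.
#'
#' @param epochs an [epoch_set()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "ierp_epochs"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(epochs$data)
  meta <- list(format = "ierp-epochs-v1", fs = epochs$fs,
               subject = epochs$subject, channels = epochs$channels,
               conditions = epochs$conditions, t0 = epochs$time[1],
               n_trial = dm[1], n_channel = dm[2], n_time = dm[3])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dt <- data.table::data.table(
    trial = rep(seq_len(dm[1]), times = dm[2] * dm[3]),
    channel = rep(rep(epochs$channels, each = dm[1]), times = dm[3]),
    sample = rep(seq_len(dm[3]), each = dm[1] * dm[2]),
    value = sprintf("%.17g", as.vector(epochs$data)))
  data.table::fwrite(dt, file.path(path, "data.csv"))
  if (!is.null(epochs$layout)) {
    data.table::fwrite(epochs$layout, file.path(path, "layout.tsv"), sep = "\t")
  }
  invisible(path)
}

#' Read epochs from a container or long-format CSV
#'
#' `format = "container"` reads the directory layout written by
#' [write_epochs()]. `format = "csv-long"` reads a single CSV with columns
#' `trial`, `channel`, `time` (s), `condition`, `value`; the sampling rate is
#' inferred from the time axis and validated for uniformity. EDF+/BDF input
#' is not supported by this build and raises a descriptive error.
#'
#' @param path directory (container) or file (csv-long).
#' @param format one of `"auto"`, `"container"`, `"csv-long"`, `"edf+"`.
#' @param subject subject id for csv-long input.
#' @param layout optional channel layout to attach.
#' @return An `ierp_epochs` object.
#' @export
read_epochs <- function(path, format = c("auto", "container", "csv-long", "edf+"),
                        subject = "S01", layout = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "container" else "csv-long"
  }
  if (format == "edf+") {
    stop_ierp("EDF+/BDF reading is not supported; convert to the csv-long or container format",
              "ierp_unsupported_format")
  }
  if (format == "container") {
    meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
    if (!identical(meta$format, "ierp-epochs-v1")) {
      stop_ierp("not an ierp epoch container", "ierp_invalid_format")
    }
    dt <- data.table::fread(file.path(path, "data.csv"))
    arr <- array(0, dim = c(meta$n_trial, meta$n_channel, meta$n_time))
    ch_idx <- match(dt$channel, meta$channels)
    if (anyNA(ch_idx)) {
      stop_ierp("data.csv contains channels absent from meta.json",
                "ierp_invalid_format")
    }
    arr[cbind(dt$trial, ch_idx, dt$sample)] <- dt$value
    lay <- layout
    lf <- file.path(path, "layout.tsv")
    if (is.null(lay) && file.exists(lf)) lay <- read_channel_layout(lf)
    return(epoch_set(arr, meta$fs, meta$conditions, t0 = meta$t0,
                     channels = meta$channels, subject = meta$subject,
                     layout = lay))
  }
  # csv-long
  dt <- data.table::fread(path)
  need <- c("trial", "channel", "time", "condition", "value")
  if (!all(need %in% names(dt))) {
    stop_ierp(paste0("csv-long input needs columns: ", paste(need, collapse = ", ")),
              "ierp_invalid_format")
  }
  trials <- sort(unique(dt$trial))
  channels <- unique(dt$channel)
  times <- sort(unique(dt$time))
  if (length(times) < 2L) stop_ierp("need at least 2 time points", "ierp_invalid_format")
  dtime <- diff(times)
  if (max(abs(dtime - dtime[1])) > 1e-6 * dtime[1]) {
    stop_ierp("non-uniform sampling in csv-long input", "ierp_invalid_format")
  }
  fs <- 1 / dtime[1]
  arr <- array(NA_real_, dim = c(length(trials), length(channels), length(times)))
  arr[cbind(match(dt$trial, trials), match(dt$channel, channels),
            match(dt$time, times))] <- dt$value
  if (anyNA(arr)) {
    stop_ierp("csv-long input has missing trial/channel/time cells (mismatched channel counts?)",
              "ierp_invalid_format")
  }
  cond <- dt$condition[match(trials, dt$trial)]
  epoch_set(arr, fs, cond, time = times, channels = as.character(channels),
            subject = subject, layout = layout)
}

#' Read a channel layout file
#'
#' Tab-delimited with columns `label`, `x`, `y`, `z` (mm). Standard 10-20 /
#' 10-10 montage names can instead be generated with [montage_1010()].
#'
#' @param path file path.
#' @return A data frame with columns `label`, `x`, `y`, `z`.
#' @export
read_channel_layout <- function(path) {
  lay <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(lay))) {
    stop_ierp("layout file needs columns label, x, y, z", "ierp_invalid_format")
  }
  if (anyDuplicated(lay$label)) {
    stop_ierp("duplicate channel labels in layout", "ierp_invalid_format")
  }
  lay[, need]
}
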