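# One-shot analysis pipeline: decompose -> select mode range -> form modes ->
# baseline -> (optional) time-bin -> adjacency -> cluster test -> reports.

#' Run the full iERP analysis pipeline
#'
#' Drives the whole analysis from a single configuration: decompose every
#' subject's epochs with CEEMDAN, select the mode range from the pooled
#' instantaneous-frequency medians, form and baseline-correct the mode
#' lattice, optionally bin time, build the lattice adjacency for the chosen
#' space, run the chosen cluster test, and write CSV/JSON reports. Every
#' stage is driven by the master seed through fixed child-seed splits, so a
#' rerun with the same configuration is bit-identical.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{input}{list of `ierp_epochs` (one per subject), or a list
#'       `list(simulate = sim_spec(...))`, or a character vector of epoch
#'       container paths.}
#'     \item{decompose}{arguments for [ceemdan_config()].}
#'     \item{range}{`hi_cut`, `lo_cut` (Hz).}
#'     \item{baseline}{`c(t0, t1)` or `NULL`.}
#'     \item{bin}{`list(width =, span =)` or `NULL`.}
#'     \item{space}{`"mode-time"`, `"channel-mode"` or
#'       `"channel-mode-time"`.}
#'     \item{apriori}{`list(channel =)` for mode-time;
#'       `list(window = c(t0, t1))` for channel-mode.}
#'     \item{test}{`design`, `method` (`"cbnpp"` or `"tfce"`), `n_perm`,
#'       `alpha`, optional `conditions` (two labels to contrast),
#'       `covariate`.}
#'     \item{seed}{master seed.}
#'     \item{output}{`list(dir =)` or `NULL` to skip writing.}
#'   }
#' @return A results bundle (list) with the decomposition QC, mode range,
#'   per-subject modes, graph, and the test result; written files are listed
#'   in `$files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed
  log_lines <- c(sprintf("ierp pipeline, seed = %s",
                         if (is.null(seed)) "NULL" else seed))
  # ---- input ----
  input <- config$input
  if (is.list(input) && !is.null(input$simulate)) {
    spec <- input$simulate
    if (!inherits(spec, "ierp_sim_spec")) spec <- do.call(sim_spec, spec)
    if (is.null(spec$seed)) spec$seed <- if (is.null(seed)) NULL else child_seed(seed, 1L)
    subjects <- simulate_erp_experiment(spec)
    log_lines <- c(log_lines, sprintf("simulated %d subjects (%d trials, %d ch, fs %g)",
                                      spec$n_subjects, 2L * spec$n_trials,
                                      spec$n_channels, spec$fs))
  } else if (is.character(input)) {
    subjects <- lapply(input, read_epochs)
  } else {
    subjects <- input
  }
  stopifnot(length(subjects) >= 1L, all(vapply(subjects, inherits, logical(1), "ierp_epochs")))
  # ---- decomposition ----
  dargs <- config$decompose
  if (is.null(dargs)) dargs <- list()
  stacks <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    da <- dargs
    da$seed <- if (is.null(seed)) NULL else child_seed(seed, 1000L + s)
    cfg <- do.call(ceemdan_config, da)
    stacks[[s]] <- decompose_epochs(subjects[[s]], cfg)
  }
  log_lines <- c(log_lines, sprintf("decomposed %d subjects, K = %d",
                                    length(stacks), stacks[[1]]$K))
  # ---- mode range from pooled medians ----
  hi <- config$range$hi_cut %||% 30
  lo <- config$range$lo_cut %||% 2
  med_all <- sapply(stacks, function(st) {
    apply(rep_freq_table(st), 3, median, na.rm = TRUE)
  })
  med <- apply(as.matrix(med_all), 1, median)
  rng <- select_mode_range(med, hi_cut = hi, lo_cut = lo)
  rng$K <- stacks[[1]]$K
  log_lines <- c(log_lines, sprintf("mode range: %d..%d+ (medians %s)",
                                    rng$p_min, rng$trend_start,
                                    paste(sprintf("%.2f", med), collapse = ", ")))
  # ---- modes ----
  modes <- lapply(stacks, function(st) form_ierp_modes(st, rng))
  if (!is.null(config$baseline)) {
    modes <- lapply(modes, baseline_correct, window = config$baseline)
  }
  if (!is.null(config$bin)) {
    modes <- lapply(modes, function(m) {
      suppressWarnings(time_bin(m, config$bin$width, config$bin$span))
    })
  }
  # ---- space & adjacency ----
  space <- config$space %||% "mode-time"
  labels <- modes[[1]][[1]]$labels
  layout <- subjects[[1]]$layout
  test_cfg <- config$test %||% list()
  conds <- test_cfg$conditions %||% names(modes[[1]])[1:2]
  chan <- NULL; window <- NULL
  if (space == "mode-time") {
    chan <- config$apriori$channel %||% subjects[[1]]$channels[1]
    n_time <- length(modes[[1]][[1]]$time)
    graph <- build_lattice_adjacency(labels, NULL, n_time, dims = c("mode", "time"))
  } else if (space == "channel-mode") {
    window <- config$apriori$window
    if (is.null(window)) stop_ierp("channel-mode space needs an a-priori window",
                                   "ierp_config_error")
    graph <- build_lattice_adjacency(labels, layout, 1L,
                                     dims = c("channel", "mode"))
  } else if (space == "channel-mode-time") {
    n_time <- length(modes[[1]][[1]]$time)
    graph <- build_lattice_adjacency(labels, layout, n_time,
                                     dims = c("channel", "mode", "time"))
  } else {
    stop_ierp(paste0("unknown space: ", space), "ierp_config_error")
  }
  # ---- test ----
  design <- test_cfg$design %||% "paired-t"
  method <- test_cfg$method %||% "cbnpp"
  n_perm <- test_cfg$n_perm %||% 1000L
  alpha <- test_cfg$alpha %||% 0.05
  test_seed <- if (is.null(seed)) NULL else child_seed(seed, 2L)
  dataA <- modes_to_matrix(lapply(modes, `[[`, conds[1]), channel = chan,
                           window = window)
  data <- if (design == "paired-t") {
    list(dataA, modes_to_matrix(lapply(modes, `[[`, conds[2]),
                                channel = chan, window = window))
  } else if (design == "one-sample-t" || design == "pearson-r") {
    if (length(conds) >= 2L && !is.null(modes[[1]][[conds[2]]])) {
      dataA - modes_to_matrix(lapply(modes, `[[`, conds[2]),
                              channel = chan, window = window)
    } else {
      dataA
    }
  } else {
    all_conds <- names(modes[[1]])
    arr <- array(0, dim = c(length(modes), length(all_conds), ncol(dataA)))
    for (ci in seq_along(all_conds)) {
      arr[, ci, ] <- modes_to_matrix(lapply(modes, `[[`, all_conds[ci]),
                                     channel = chan, window = window)
    }
    arr
  }
  result <- if (method == "tfce") {
    tfce_test(data, design, graph, n_perm = n_perm, alpha = alpha,
              seed = test_seed, covariate = test_cfg$covariate)
  } else {
    cbnpp_test(data, design, graph, n_perm = n_perm, alpha = alpha,
               seed = test_seed, covariate = test_cfg$covariate)
  }
  # ---- reports ----
  files <- character(0)
  outdir <- config$output$dir
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    long <- do.call(rbind, lapply(seq_along(modes), function(s) {
      modes_to_long(modes[[s]], subject = subjects[[s]]$subject)
    }))
    f_modes <- file.path(outdir, "modes_long.csv")
    data.table::fwrite(long, f_modes)
    cons <- do.call(rbind, lapply(seq_along(stacks), function(s) {
      cbind(subject = subjects[[s]]$subject, if_consistency_summary(stacks[[s]]))
    }))
    f_cons <- file.path(outdir, "if_consistency.csv")
    data.table::fwrite(cons, f_cons)
    nodes <- graph$nodes
    nodes$statistic <- as.numeric(result$statmap)
    nodes$mode_label <- labels$label[nodes$mode]
    if (inherits(result, "ierp_clusters")) {
      nodes$cluster <- 0L
      nodes$cluster_p <- NA_real_
      if (nrow(result$clusters)) {
        for (i in seq_len(nrow(result$clusters))) {
          nodes$cluster[result$members[[i]]] <- i
          nodes$cluster_p[result$members[[i]]] <- result$clusters$p[i]
        }
      }
    } else {
      nodes$tfce <- result$tfce
      nodes$p_corrected <- result$p
    }
    f_nodes <- file.path(outdir, "clusters.csv")
    data.table::fwrite(nodes, f_nodes)
    summ <- list(seed = seed, space = space, design = design, method = method,
                 n_perm = result$n_perm, alpha = alpha,
                 K = stacks[[1]]$K, p_min = rng$p_min,
                 trend_start = rng$trend_start,
                 n_modes = nrow(labels),
                 min_p = if (inherits(result, "ierp_tfce")) result$min_p
                         else if (nrow(result$clusters)) min(result$clusters$p)
                         else NA)
    f_sum <- file.path(outdir, "summary.json")
    jsonlite::write_json(summ, f_sum, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    f_log <- file.path(outdir, "log.txt")
    writeLines(log_lines, f_log)
    files <- c(f_modes, f_cons, f_nodes, f_sum, f_log)
  }
  list(stacks = stacks, range = rng, modes = modes, graph = graph,
       result = result, files = files, log = log_lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
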