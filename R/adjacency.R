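# Neighbour definitions over the [channel, mode, time] lattice. Two lattice
# points are adjacent iff they are neighbours in exactly one dimension and
# share coordinates in all others; the mode dimension uses an XOR rule on
# constituent-order sets.

mode_sets <- function(labels, trend_as_block = TRUE) {
  if (trend_as_block) attr(labels, "effective") else attr(labels, "constituents")
}

#' Are two iERP modes neighbours?
#'
#' Modes are mutual neighbours iff the symmetric difference (XOR) of their
#' constituent-order sets contains exactly one element. With
#' `trend_as_block = TRUE` (default) the trend block counts as a single
#' pseudo-ordinal, so e.g. `3:5` and `3:6+` are neighbours; with `FALSE` the
#' block expands to all of its orders and they are not.
#'
#' @param labels an `ierp_mode_labels` table from [mode_labels()].
#' @param a,b mode indices into `labels`, or label strings.
#' @param trend_as_block treat the trend block as one XOR element.
#' @return Logical.
#' @examples
#' ml <- mode_labels(2, 6, K = 7)
#' modes_are_neighbors(ml, "2:5", "3:5")  # TRUE
#' modes_are_neighbors(ml, "2:5", "3:6")  # FALSE
#' @export
modes_are_neighbors <- function(labels, a, b, trend_as_block = TRUE) {
  if (is.character(a)) a <- match(a, labels$label)
  if (is.character(b)) b <- match(b, labels$label)
  if (is.na(a) || is.na(b)) stop_ierp("unknown mode label", "ierp_invalid_argument")
  sets <- mode_sets(labels, trend_as_block)
  sym <- c(setdiff(sets[[a]], sets[[b]]), setdiff(sets[[b]], sets[[a]]))
  length(sym) == 1L
}

#' Mode-by-mode adjacency matrix
#'
#' @inheritParams modes_are_neighbors
#' @return Symmetric, irreflexive logical matrix.
#' @export
mode_adjacency <- function(labels, trend_as_block = TRUE) {
  sets <- mode_sets(labels, trend_as_block)
  M <- length(sets)
  adj <- matrix(FALSE, M, M, dimnames = list(labels$label, labels$label))
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i == j) next
      sym <- c(setdiff(sets[[i]], sets[[j]]), setdiff(sets[[j]], sets[[i]]))
      adj[i, j] <- length(sym) == 1L
    }
  }
  adj
}

#' Channel adjacency from electrode distances
#'
#' Channels are neighbours iff their Euclidean distance is strictly less
#' than the threshold (40 mm by default).
#'
#' @param layout data frame with `label`, `x`, `y`, `z` (mm).
#' @param threshold_mm distance threshold.
#' @return Symmetric, irreflexive logical matrix.
#' @export
channel_neighbors <- function(layout, threshold_mm = 40) {
  stopifnot(nrow(layout) >= 1L)
  xyz <- as.matrix(layout[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  adj <- d < threshold_mm
  diag(adj) <- FALSE
  dimnames(adj) <- list(layout$label, layout$label)
  adj
}

#' Build the lattice adjacency graph
#'
#' Nodes enumerate the active dimensions of the iERP space in the canonical
#' order (mode fastest, then channel, then time — matching how a
#' `mode x channel x time` array flattens), and two nodes are adjacent iff
#' they are neighbours in exactly one active dimension and identical in the
#' rest. Time neighbours are adjacent bins.
#'
#' @param labels an `ierp_mode_labels` table.
#' @param layout channel layout (required when `"channel"` is active; one
#'   virtual channel otherwise).
#' @param n_time number of time points/bins (1 for an a-priori window).
#' @param dims active dimensions, a subset of
#'   `c("channel", "mode", "time")` of size 2 or 3. Inactive dimensions of
#'   size 1 are allowed and carry no edges.
#' @param trend_as_block see [modes_are_neighbors()].
#' @param threshold_mm channel distance threshold.
#' @return An `ierp_graph`: CSR adjacency (`offsets`, `indices`, 0-based),
#'   `n_nodes`, `nodes` (data frame of mode/channel/time indices), `sizes`,
#'   `dims`, `labels`, `layout`.
#' @export
build_lattice_adjacency <- function(labels, layout = NULL, n_time,
                                    dims = c("mode", "time"),
                                    trend_as_block = TRUE, threshold_mm = 40) {
  known <- c("channel", "mode", "time")
  if (!all(dims %in% known)) {
    stop_ierp(paste0("unknown dimension(s): ",
                     paste(setdiff(dims, known), collapse = ", ")),
              "ierp_invalid_argument")
  }
  if (!(length(dims) %in% c(2L, 3L))) {
    stop_ierp("dims must name 2 or 3 dimensions", "ierp_invalid_argument")
  }
  M <- nrow(labels)
  C <- if (is.null(layout)) 1L else nrow(layout)
  if ("channel" %in% dims && is.null(layout)) {
    stop_ierp("channel dimension requires a layout", "ierp_invalid_argument")
  }
  Tt <- as.integer(n_time)
  n <- M * C * Tt
  node_id <- function(m, c, t) m + M * ((c - 1L) + C * (t - 1L))
  edges_from <- integer(0); edges_to <- integer(0)
  add_edges <- function(from, to) {
    edges_from <<- c(edges_from, from, to)
    edges_to <<- c(edges_to, to, from)
  }
  if ("mode" %in% dims && M > 1L) {
    madj <- mode_adjacency(labels, trend_as_block)
    pairs <- which(madj & upper.tri(madj), arr.ind = TRUE)
    if (nrow(pairs)) {
      ct <- expand.grid(c = seq_len(C), t = seq_len(Tt))
      for (r in seq_len(nrow(pairs))) {
        add_edges(node_id(pairs[r, 1], ct$c, ct$t), node_id(pairs[r, 2], ct$c, ct$t))
      }
    }
  }
  if ("channel" %in% dims && C > 1L) {
    cadj <- channel_neighbors(layout, threshold_mm)
    pairs <- which(cadj & upper.tri(cadj), arr.ind = TRUE)
    if (nrow(pairs)) {
      mt <- expand.grid(m = seq_len(M), t = seq_len(Tt))
      for (r in seq_len(nrow(pairs))) {
        add_edges(node_id(mt$m, pairs[r, 1], mt$t), node_id(mt$m, pairs[r, 2], mt$t))
      }
    }
  }
  if ("time" %in% dims && Tt > 1L) {
    mc <- expand.grid(m = seq_len(M), c = seq_len(C))
    for (t in seq_len(Tt - 1L)) {
      add_edges(node_id(mc$m, mc$c, t), node_id(mc$m, mc$c, t + 1L))
    }
  }
  # CSR (0-based)
  ord <- order(edges_from, edges_to)
  ef <- edges_from[ord]; et <- edges_to[ord]
  counts <- tabulate(ef, nbins = n)
  offsets <- c(0L, cumsum(counts))
  nodes <- expand.grid(mode = seq_len(M), channel = seq_len(C),
                       time = seq_len(Tt))
  structure(list(offsets = as.integer(offsets), indices = as.integer(et - 1L),
                 n_nodes = n, nodes = nodes,
                 sizes = c(mode = M, channel = C, time = Tt),
                 dims = dims, labels = labels, layout = layout,
                 trend_as_block = trend_as_block, threshold_mm = threshold_mm),
            class = "ierp_graph")
}

#' @export
print.ierp_graph <- function(x, ...) {
  cat(sprintf("iERP lattice graph: %d nodes (%d modes x %d channels x %d times), %d edges, dims: %s\n",
              x$n_nodes, x$sizes["mode"], x$sizes["channel"], x$sizes["time"],
              length(x$indices) / 2, paste(x$dims, collapse = ", ")))
  invisible(x)
}

#' Adjacency list view of a lattice graph
#'
#' @param graph an `ierp_graph`.
#' @return List of integer neighbour vectors (1-based), one per node.
#' @export
as_adj_list <- function(graph) {
  lapply(seq_len(graph$n_nodes), function(u) {
    idx <- seq.int(graph$offsets[u] + 1L, length.out = graph$offsets[u + 1L] - graph$offsets[u])
    sort(graph$indices[idx] + 1L)
  })
}

#' Approximate 10-20 / 10-10 electrode montage
#'
#' Generates 3D Cartesian coordinates (mm) on a spherical head by the
#' proportional construction of the 10-20 system: each electrode lies on the
#' great-circle arc from its midline row position to the corresponding point
#' on the horizontal (Fpz-T7-Oz-T8) ring, at its lateral fraction. This is a
#' synthetic approximation adequate for distance-based neighbourhoods, not a
#' digitised cap.
#'
#' @param labels electrode names to generate (default: a 71-channel 10-10
#'   superset including the parietal/parieto-occipital rows).
#' @param radius head radius in mm.
#' @return Data frame with columns `label`, `x` (right), `y` (anterior),
#'   `z` (up), in mm.
#' @export
montage_1010 <- function(labels = NULL, radius = 85) {
  rows <- list(Fp = 0.8, AF = 0.6, F = 0.4, FC = 0.2, C = 0, CP = -0.2,
               P = -0.4, PO = -0.6, O = -0.8)
  lat <- c("7" = 1, "5" = 0.75, "3" = 0.5, "1" = 0.25, z = 0,
           "2" = 0.25, "4" = 0.5, "6" = 0.75, "8" = 1)
  # T7/T8 and TP/FT rows use the temporal naming for the full-lateral column
  all_labels <- c(
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "O1", "Oz", "O2")
  if (is.null(labels)) labels <- all_labels
  parse_label <- function(lb) {
    if (lb %in% c("T7", "T8")) return(list(row = "C", col = substr(lb, 2, 2)))
    if (lb %in% c("TP7", "TP8")) return(list(row = "CP", col = substr(lb, 3, 3)))
    if (lb %in% c("FT7", "FT8")) return(list(row = "FC", col = substr(lb, 3, 3)))
    m <- regmatches(lb, regexec("^([A-Za-z]+)([0-9]+|z)$", lb))[[1]]
    if (length(m) != 3L) stop_ierp(paste0("cannot parse electrode label: ", lb),
                                   "ierp_invalid_argument")
    list(row = m[2], col = m[3])
  }
  # Fp and O rows only exist at the ring (columns 1/2 sit at lateral 18 deg)
  coords <- t(vapply(labels, function(lb) {
    pl <- parse_label(lb)
    if (!pl$row %in% names(rows)) {
      stop_ierp(paste0("unknown electrode row: ", lb), "ierp_invalid_argument")
    }
    a <- rows[[pl$row]]
    side <- if (pl$col == "z") 0 else if (as.integer(pl$col) %% 2 == 1) -1 else 1
    b <- if (pl$col == "z") 0 else if (pl$row %in% c("Fp", "O")) 1 else lat[[pl$col]]
    alpha <- a * pi / 2
    mid <- c(0, sin(alpha), cos(alpha))
    lam <- (1 - abs(a)) * pi / 2
    ring <- c(side * sin(lam), sign(a) * cos(lam), 0)
    if (a == 0 && side != 0) ring <- c(side, 0, 0)
    if (b == 0) {
      p <- mid
    } else if (b == 1) {
      p <- ring
    } else {
      ang <- acos(pmin(pmax(sum(mid * ring), -1), 1))
      p <- (sin((1 - b) * ang) * mid + sin(b * ang) * ring) / sin(ang)
    }
    radius * p
  }, numeric(3)))
  data.frame(label = labels, x = coords[, 1], y = coords[, 2], z = coords[, 3],
             row.names = NULL)
}
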