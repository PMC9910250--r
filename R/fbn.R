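#' Functional brain network
#'
#' A weighted undirected graph over the recording electrodes: a symmetric
#' weight matrix with entries in \[0, 1\] and an exactly zero diagonal.
#' Edge weights are absolute Pearson correlations between channel signals
#' (see [pearson_adjacency()]); negative correlations count as connectivity
#' strength under this convention.
#'
#' @param weights Symmetric numeric matrix, zero diagonal, entries in
#'   \[0, 1\], all finite.
#' @param node_labels Electrode names, one per row; defaults to existing
#'   dimnames or [fbn_channels()] for 8 nodes.
#' @param n_segments_aggregated How many per-segment networks this network
#'   averages (1 for a single segment).
#' @param subject_id,timepoint Provenance identifiers.
#' @return An object of class `fbn`.
#' @export
#' @examples
#' k8 <- fbn(matrix(1, 8, 8) - diag(8))  # binary complete graph
#' network_metrics(k8)
fbn <- function(weights, node_labels = NULL, n_segments_aggregated = 1L,
                subject_id = NA_character_, timepoint = NA_character_) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) {
    abort("`weights` must be square.", class = "sleepfbn_invariant_violation")
  }
  if (!isSymmetric(unname(weights), tol = 0)) {
    abort("`weights` must be exactly symmetric.",
          class = "sleepfbn_invariant_violation")
  }
  if (any(diag(weights) != 0)) {
    abort("`weights` must have an exactly zero diagonal.",
          class = "sleepfbn_invariant_violation")
  }
  if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1)) {
    abort("`weights` entries must be finite and in [0, 1].",
          class = "sleepfbn_invariant_violation")
  }
  if (is.null(node_labels)) {
    node_labels <- rownames(weights) %||%
      (if (n == 8) FBN_CHANNELS else sprintf("N%02d", seq_len(n)))
  }
  dimnames(weights) <- list(node_labels, node_labels)
  structure(
    list(weights = weights, node_labels = as.character(node_labels),
         n_segments_aggregated = as.integer(n_segments_aggregated),
         subject_id = subject_id, timepoint = timepoint),
    class = "fbn"
  )
}

#' @export
print.fbn <- function(x, ...) {
  ut <- x$weights[upper.tri(x$weights)]
  cat("<fbn> ", length(x$node_labels), " nodes (",
      paste(head(x$node_labels, 4), collapse = ", "), ", ...), ",
      sum(ut > 0), " edges, mean weight ",
      signif(mean(ut), 3), ", segments aggregated: ",
      x$n_segments_aggregated, "\n", sep = "")
  invisible(x)
}

#' Pearson-correlation adjacency of one EEG segment
#'
#' Builds the functional network of a single analysis window:
#' `weights[i, j] = |r(channel_i, channel_j)|`, the absolute Pearson
#' correlation between the two channel traces, with the diagonal set to
#' zero. Scale- and offset-invariant per channel.
#'
#' @param segment A `channels x samples` numeric matrix (>= 2 channels,
#'   >= 3 samples, no constant channel), or a [segment_set()] element.
#' @param node_labels Optional node names; defaults to the matrix rownames.
#' @param subject_id,timepoint Provenance identifiers.
#' @return An [fbn()].
#' @export
pearson_adjacency <- function(segment, node_labels = NULL,
                              subject_id = NA_character_,
                              timepoint = NA_character_) {
  segment <- as.matrix(segment)
  if (nrow(segment) < 2) {
    abort("need at least 2 channels.", class = "sleepfbn_insufficient_samples")
  }
  if (ncol(segment) < 3) {
    abort("need at least 3 samples per channel.",
          class = "sleepfbn_insufficient_samples")
  }
  sds <- apply(segment, 1, sd)
  if (any(sds == 0)) {
    labs <- node_labels %||% rownames(segment) %||% as.character(which(sds == 0))
    bad <- labs[which(sds == 0)]
    abort(paste0("degenerate (constant) channel(s): ",
                 paste(bad, collapse = ", ")),
          class = "sleepfbn_degenerate_channel")
  }
  w <- abs(cor(t(segment)))
  w <- (w + t(w)) / 2  # enforce exact symmetry against rounding
  w[w > 1] <- 1
  diag(w) <- 0
  fbn(w, node_labels = node_labels %||% rownames(segment),
      n_segments_aggregated = 1L, subject_id = subject_id,
      timepoint = timepoint)
}

#' Per-segment networks of a segment set
#'
#' @param segs A [segment_set()].
#' @return A list of [fbn()] objects, one per segment.
#' @export
segment_networks <- function(segs) {
  stopifnot(inherits(segs, "segment_set"))
  lapply(segs$segments, pearson_adjacency,
         node_labels = segs$channel_labels,
         subject_id = segs$subject_id, timepoint = segs$timepoint)
}

#' Aggregate per-segment networks into one network
#'
#' Element-wise mean of the weight matrices: the ten per-segment networks
#' of one subject and timepoint become a single functional brain network.
#' Symmetry and the zero diagonal are preserved exactly.
#'
#' @param nets Non-empty list of [fbn()] objects sharing node labels.
#' @return An [fbn()] with `n_segments_aggregated` equal to the sum of the
#'   inputs' aggregated-segment counts (the list length for per-segment
#'   inputs).
#' @export
aggregate_networks <- function(nets) {
  if (length(nets) == 0) {
    abort("`nets` must be a non-empty list.", class = "sleepfbn_incompatible_network")
  }
  stopifnot(all(vapply(nets, inherits, logical(1), "fbn")))
  labs <- nets[[1]]$node_labels
  same <- vapply(nets, function(x) identical(x$node_labels, labs), logical(1))
  if (!all(same)) {
    abort("all networks must share identical node labels.",
          class = "sleepfbn_incompatible_network")
  }
  w <- Reduce(`+`, lapply(nets, `[[`, "weights")) / length(nets)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  fbn(w, node_labels = labs,
      n_segments_aggregated = sum(vapply(nets, `[[`, integer(1),
                                         "n_segments_aggregated")),
      subject_id = nets[[1]]$subject_id, timepoint = nets[[1]]$timepoint)
}

#' Build the aggregated network of a segment set
#'
#' Convenience wrapper: per-segment Pearson adjacencies, averaged into one
#' network, with optional thresholding/binarization for sensitivity
#' analyses (both off by default; the trial analysis uses weighted,
#' unthresholded networks).
#'
#' @param segs A [segment_set()].
#' @param threshold Weights strictly below this are set to 0 (default 0:
#'   no thresholding).
#' @param binarize If `TRUE`, surviving edges are set to weight 1.
#' @return An [fbn()].
#' @export
build_fbn <- function(segs, threshold = 0, binarize = FALSE) {
  net <- aggregate_networks(segment_networks(segs))
  if (threshold > 0) net <- fbn_threshold(net, threshold)
  if (binarize) net <- fbn_binarize(net)
  net
}

#' Threshold or binarize a network
#'
#' @param net An [fbn()].
#' @param tau Edges with weight < `tau` are removed (set to 0).
#' @return The modified [fbn()].
#' @export
fbn_threshold <- function(net, tau) {
  stopifnot(inherits(net, "fbn"))
  w <- net$weights
  w[w < tau] <- 0
  fbn(w, net$node_labels, net$n_segments_aggregated, net$subject_id,
      net$timepoint)
}

#' @rdname fbn_threshold
#' @export
fbn_binarize <- function(net) {
  stopifnot(inherits(net, "fbn"))
  w <- (net$weights > 0) * 1
  diag(w) <- 0
  fbn(w, net$node_labels, net$n_segments_aggregated, net$subject_id,
      net$timepoint)
}

#' Tidy a functional brain network into an edge list
#'
#' @param x An [fbn()].
#' @param ... Unused.
#' @return A tibble with one row per unordered node pair: `from`, `to`,
#'   `weight`.
#' @export
tidy.fbn <- function(x, ...) {
  n <- length(x$node_labels)
  idx <- which(upper.tri(x$weights), arr.ind = TRUE)
  tibble::tibble(
    from = x$node_labels[idx[, 1]],
    to = x$node_labels[idx[, 2]],
    weight = x$weights[idx]
  )
}

#' One-line summary of a network
#'
#' @param x An [fbn()].
#' @param ... Unused.
#' @return A one-row tibble: node/edge counts, mean and max weight,
#'   segments aggregated.
#' @export
glance.fbn <- function(x, ...) {
  ut <- x$weights[upper.tri(x$weights)]
  tibble::tibble(
    n_nodes = length(x$node_labels),
    n_edges = sum(ut > 0),
    mean_weight = mean(ut),
    max_weight = max(ut),
    n_segments_aggregated = x$n_segments_aggregated
  )
}
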