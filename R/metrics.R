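# The five topological summaries of a functional brain network. Weighted
# conventions, stated explicitly because they matter:
#   * strength/degree: row sum of weights (edge count for binary graphs);
#   * clustering: geometric-mean triangle formulation on weights normalized
#     by the maximum weight; nodes with < 2 neighbours contribute 0;
#   * path length: edge distance 1/weight, shortest paths over all ordered
#     pairs, mean over reachable pairs (unreachable fraction reported);
#   * global efficiency: mean inverse shortest-path distance, 1/Inf = 0;
#   * network energy: sum of absolute eigenvalues of the weight matrix
#     (spectral graph energy).

as_fbn_weights <- function(net) {
  if (inherits(net, "fbn")) return(net$weights)
  fbn(as.matrix(net))$weights  # validates invariants for raw matrices
}

#' Node strength (weighted degree)
#'
#' Row sums of the weight matrix; for binary networks this is the per-node
#' edge count. The network-level degree `D` is the mean over nodes.
#'
#' @param net An [fbn()] or a valid weight matrix.
#' @return Named numeric vector of per-node strengths.
#' @seealso [network_metrics()]
#' @export
node_strength <- function(net) {
  w <- as_fbn_weights(net)
  rowSums(w)
}

#' Per-node weighted clustering coefficient
#'
#' Geometric-mean triangle formulation: with weights normalized by the
#' maximum weight, node `i` gets the mean of `(w_ij w_ih w_jh)^(1/3)` over
#' its neighbour pairs; nodes with fewer than two neighbours get 0. Equals
#' the classical transitivity-per-node on binary graphs. The network-level
#' `C` is the mean over nodes.
#'
#' @inheritParams node_strength
#' @return Named numeric vector of per-node clustering coefficients in
#'   \[0, 1\].
#' @export
node_clustering <- function(net) {
  w <- as_fbn_weights(net)
  mx <- max(w)
  out <- setNames(numeric(nrow(w)), rownames(w))
  if (mx == 0) return(out)
  wn <- (w / mx)^(1 / 3)
  tri <- diag(wn %*% wn %*% wn)  # 2 x sum of cube-root triangle products
  k <- rowSums(w > 0)
  ok <- k >= 2
  out[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  out
}

# All-pairs shortest path distances with edge length 1/weight
# (Floyd-Warshall; n = 8, so the cubic loop is immaterial).
fbn_distances <- function(w) {
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, via)
  }
  d
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all ordered node pairs with a finite
#' path, with edge distance `1/weight`. The fraction of unreachable pairs
#' is reported alongside so thresholded (possibly disconnected) networks
#' remain comparable.
#'
#' @inheritParams node_strength
#' @return A list with elements `L` (mean finite distance) and
#'   `unreachable_pair_fraction`. Errors (class
#'   `sleepfbn_disconnected`) if no pair is reachable.
#' @export
characteristic_path_length <- function(net) {
  w <- as_fbn_weights(net)
  d <- fbn_distances(w)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  if (!any(finite)) {
    abort("path length undefined: network has no connected node pair.",
          class = "sleepfbn_disconnected")
  }
  list(L = mean(off[finite]), unreachable_pair_fraction = mean(!finite))
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance,
#' with unreachable pairs contributing 0. Lies in \[0, 1\] for weights in
#' \[0, 1\].
#'
#' @inheritParams node_strength
#' @return A single number in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  w <- as_fbn_weights(net)
  d <- fbn_distances(w)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  mean(inv[row(inv) != col(inv)])
}

#' Brain network energy
#'
#' Spectral graph energy of the weight matrix: the sum of absolute
#' eigenvalues. Zero exactly when the network has no edges; equals
#' `2 (n - 1)` on the binary complete graph.
#'
#' @inheritParams node_strength
#' @return A single non-negative number.
#' @export
brain_network_energy <- function(net) {
  w <- as_fbn_weights(net)
  sum(abs(eigen(w, symmetric = TRUE, only.values = TRUE)$values))
}

#' Per-node metrics table
#'
#' @inheritParams node_strength
#' @return A tibble with columns `node`, `strength`, `clustering`.
#' @export
node_metrics <- function(net) {
  s <- node_strength(net)
  tibble::tibble(node = names(s), strength = unname(s),
                 clustering = unname(node_clustering(net)))
}

#' All five network summary metrics
#'
#' Computes the network-level degree `D` (mean strength), clustering
#' coefficient `C`, characteristic path length `L`, global efficiency `E`
#' and brain network energy `BNE` of one functional brain network. `L` is
#' `NA` when no node pair is connected (the unreachable fraction is then
#' 1); use [characteristic_path_length()] directly for the erroring
#' variant.
#'
#' @inheritParams node_strength
#' @return A one-row tibble: `subject_id`, `timepoint`, `D`, `C`, `L`,
#'   `E`, `BNE`, `unreachable_pair_fraction`.
#' @export
#' @examples
#' network_metrics(fbn(matrix(1, 8, 8) - diag(8)))
network_metrics <- function(net) {
  w <- as_fbn_weights(net)
  subject_id <- if (inherits(net, "fbn")) net$subject_id else NA_character_
  timepoint <- if (inherits(net, "fbn")) net$timepoint else NA_character_
  pl <- tryCatch(characteristic_path_length(w),
                 sleepfbn_disconnected = function(e) {
                   list(L = NA_real_, unreachable_pair_fraction = 1)
                 })
  tibble::tibble(
    subject_id = subject_id,
    timepoint = timepoint,
    D = mean(node_strength(w)),
    C = mean(node_clustering(w)),
    L = pl$L,
    E = global_efficiency(w),
    BNE = brain_network_energy(w),
    unreachable_pair_fraction = pl$unreachable_pair_fraction
  )
}
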