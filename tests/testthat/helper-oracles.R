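# Brute-force oracles, kept deliberately independent of the package's own
# implementations: naive loops and generic linear algebra only.

random_weight_matrix <- function(seed, n = 8, density = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    vals <- runif(sum(ut))
    if (density < 1) vals[runif(length(vals)) > density] <- 0
    w[ut] <- vals
    w + t(w)
  })
}

# per-node strength by explicit summation
oracle_strength <- function(w) {
  vapply(seq_len(nrow(w)), function(i) sum(w[i, ]), numeric(1))
}

# geometric-mean weighted clustering by exhaustive triple enumeration
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(numeric(n))
  wn <- w / mx
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
        }
      }
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# all-pairs shortest paths by Dijkstra from every source (binary heap-free
# naive version; n is tiny)
oracle_distances <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    done <- rep(FALSE, n)
    for (it in seq_len(n)) {
      u <- which(!done)[which.min(dist[!done])]
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      for (v in seq_len(n)) {
        if (!done[v] && is.finite(len[u, v]) &&
            dist[u] + len[u, v] < dist[v]) {
          dist[v] <- dist[u] + len[u, v]
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

oracle_path_length <- function(w) {
  d <- oracle_distances(w)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_efficiency <- function(w) {
  d <- oracle_distances(w)
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

# graph energy via singular values (coincides with sum |eigenvalue| for
# symmetric matrices)
oracle_energy <- function(w) sum(svd(w)$d)

# classical pooled-variance two-sample t statistic
oracle_pooled_t <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  df <- length(a) + length(b) - 2
  list(t = tt, p = 2 * pt(-abs(tt), df))
}
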