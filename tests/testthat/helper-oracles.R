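# First-principles oracles, independent of the package implementation and of
# igraph: exhaustive enumeration on small graphs, brute-force loops for the
# discriminability statistic. Used to freeze expected values and for the
# oracle-equivalence acceptance criterion.

# Brute-force discriminability: literal triple loop over Eq-style triples.
oracle_discriminability <- function(x, labels) {
  D <- as.matrix(dist(x))
  n <- length(labels)
  hits <- 0; total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i || labels[j] != labels[i]) next
      for (k in seq_len(n)) {
        if (labels[k] == labels[i]) next
        total <- total + 1
        if (D[i, j] <= D[i, k]) hits <- hits + 1
      }
    }
  }
  hits / total
}

# All-pairs shortest path lengths (1/weight edge lengths) by Floyd-Warshall.
oracle_distances <- function(W) {
  n <- nrow(W)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(W) {
  d <- oracle_distances(W)
  v <- d[upper.tri(d)]
  mean(ifelse(is.finite(v), 1 / v, 0))
}

oracle_mean_path_length <- function(W) {
  d <- oracle_distances(W)
  v <- d[upper.tri(d)]
  mean(v[is.finite(v)])
}

# Weighted betweenness by exhaustive simple-path enumeration: for every
# ordered pair, enumerate all simple paths, find the shortest length, and
# credit interior nodes of every shortest path with 1/(number of shortest
# paths). Feasible for n <= 8.
oracle_betweenness <- function(W, tol = 1e-10) {
  n <- nrow(W)
  bc <- numeric(n)
  paths_from <- function(s, t) {
    out <- list()
    walk <- function(path, len) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1]] <<- list(path = path, len = len); return() }
      for (u in which(W[v, ] > 0)) {
        if (u %in% path) next
        walk(c(path, u), len + 1 / W[v, u])
      }
    }
    walk(s, 0)
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      ps <- paths_from(s, t)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      best <- min(lens)
      sp <- ps[lens <= best * (1 + tol) + tol]
      for (p in sp) {
        interior <- setdiff(p$path, c(s, t))
        for (v in interior) bc[v] <- bc[v] + 1 / length(sp)
      }
    }
  }
  bc
}

# Barrat local clustering from the triangle definition (ordered neighbour
# pairs), written as an independent enumeration over triples.
oracle_barrat <- function(W) {
  n <- nrow(W)
  out <- rep(NaN, n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    acc <- 0
    for (j in nb) for (h in nb) {
      if (j != h && W[j, h] > 0) acc <- acc + (W[i, j] + W[i, h]) / 2
    }
    out[i] <- acc / (sum(W[i, ]) * (length(nb) - 1))
  }
  out
}

# Weighted modularity of a given partition from the defining formula
# Q = (1/2m) sum_ij (A_ij - s_i s_j / 2m) [c_i == c_j].
oracle_modularity <- function(W, membership) {
  two_m <- sum(W)
  s <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] != membership[j]) next
      q <- q + W[i, j] - s[i] * s[j] / two_m
    }
  }
  q / two_m
}

# Strength assortativity with explicitly accumulated moments.
oracle_assortativity <- function(W) {
  s <- rowSums(W)
  xs <- c(); ys <- c()
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0) { xs <- c(xs, s[i]); ys <- c(ys, s[j]) }
  }
  if (length(xs) < 2) return(NA_real_)
  mx <- mean(xs); my <- mean(ys)
  num <- sum((xs - mx) * (ys - my))
  den <- sqrt(sum((xs - mx)^2) * sum((ys - my)^2))
  if (den == 0) return(NaN)
  num / den
}
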