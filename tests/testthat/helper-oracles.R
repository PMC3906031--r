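# Independent brute-force oracles.

# all-pairs shortest directed path lengths by exhaustive simple-path
# enumeration (edge length = 1/w on existing edges)
oracle_paths <- function(a, w) {
  n <- nrow(a)
  len <- ifelse(a == 1, 1 / w, Inf)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  dfs <- function(start, node, visited, acc) {
    for (nxt in seq_len(n)) {
      if (visited[nxt] || is.infinite(len[node, nxt])) next
      d <- acc + len[node, nxt]
      if (d < best[start, nxt]) best[start, nxt] <<- d
      v2 <- visited
      v2[nxt] <- TRUE
      dfs(start, nxt, v2, d)
    }
  }
  for (s in seq_len(n)) {
    v <- rep(FALSE, n)
    v[s] <- TRUE
    dfs(s, s, v, 0)
  }
  best
}

oracle_E <- function(a, w) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- oracle_paths(a, w)
  eps <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  sum(eps) / (n * (n - 1))
}

# same definitional choices as the package documents: ideal graph has an
# edge wherever w > 0; neighbor set = union of in/out neighbors; < 2
# neighbors contribute 0
oracle_efficiency <- function(a, w) {
  n <- nrow(a)
  ideal <- (w > 0) * 1L
  diag(ideal) <- 0L
  e_id <- oracle_E(ideal, w)
  glob <- oracle_E(a, w) / e_id
  contrib <- vapply(seq_len(n), function(i) {
    nb <- which((a[i, ] == 1 | a[, i] == 1) & seq_len(n) != i)
    if (length(nb) < 2) return(0)
    asub <- a[nb, nb, drop = FALSE]
    wsub <- w[nb, nb, drop = FALSE]
    isub <- (wsub > 0) * 1L
    diag(isub) <- 0L
    ei <- oracle_E(isub, wsub)
    if (ei == 0) 0 else oracle_E(asub, wsub) / ei
  }, numeric(1))
  wo <- w
  diag(wo) <- 0
  list(global = glob, local = mean(contrib),
       cost = sum(a * wo) / sum(wo))
}

random_weighted_net <- function(n, p_edge = 0.5) {
  w <- matrix(exp(rnorm(n * n, 0, 0.7)), n, n)
  a <- matrix(rbinom(n * n, 1, p_edge), n, n)
  diag(a) <- 0L
  diag(w) <- 0
  structure(list(a = a, w = w, K = w), class = "weighted_network")
}

# Monte-Carlo solid-angle Voronoi weights of the canonical axes
oracle_axis_weights <- function(n = 1e6, seed = 7) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  axes <- orientation_axes()
  scores <- abs(u %*% t(axes))
  tabulate(max.col(scores), nrow(axes)) / n
}
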