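#' Shortest-path length matrix of a weighted directed network
#'
#' The length of an edge is the reciprocal of its weight (large weight =
#' short/strong connection); the length of a path is the sum of its edge
#' lengths; `d_ij` is the length of the shortest directed path from i to
#' j, `Inf` when j is unreachable.  Paths are computed by Dijkstra's
#' algorithm on the existing edges only.
#'
#' @param net a `weighted_network`, or any list with 0/1 matrix `a` and
#'   weight matrix `w`.
#' @return an `n` x `n` matrix of path lengths with zero diagonal.
#' @export
path_length_matrix <- function(net) {
  check_network(net)
  shortest_paths_d(net$a, net$w)
}

check_network <- function(net) {
  if (any(net$a == 1 & net$w <= 0))
    stop("invalid network: existing edge with non-positive weight",
         call. = FALSE)
  invisible(net)
}

# Dijkstra via igraph on edge lengths 1/w for present edges
shortest_paths_d <- function(a, w) {
  n <- nrow(a)
  len <- ifelse(a == 1 & w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
  d
}

# E(G) = mean over ordered pairs of 1/d_ij (0 for unreachable pairs)
efficiency_value <- function(a, w) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- shortest_paths_d(a, w)
  eps <- 1 / d
  diag(eps) <- 0
  eps[is.infinite(d)] <- 0
  sum(eps) / (n * (n - 1))
}

#' Global efficiency of a weighted directed network
#'
#' `E(G) = sum_{i != j} (1 / d_ij) / (N (N - 1))`, normalized by the
#' efficiency of the ideal graph `G_ideal` in which every connection is
#' present (`a_ij = 1` wherever `w_ij > 0`) with the same weight matrix
#' and its own shortest paths:
#' `E_glob = E(G) / E(G_ideal)`, a value in `[0, 1]`.
#'
#' @param net a `weighted_network`.
#' @return global efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  check_network(net)
  n <- nrow(net$a)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  e <- efficiency_value(net$a, net$w)
  ideal_a <- (net$w > 0) * 1L
  diag(ideal_a) <- 0L
  e_ideal <- efficiency_value(ideal_a, net$w)
  if (e_ideal == 0)
    stop("undefined efficiency: ideal graph has zero efficiency",
         call. = FALSE)
  e / e_ideal
}

#' Local efficiency of a weighted directed network
#'
#' For each vertex i, the subgraph `G_i` induced on its neighbors (the
#' union of in- and out-neighbors) is compared to its own ideal graph:
#' `E_loc = (1/N) sum_i E(G_i) / E(G_i_ideal)`.  Vertices with fewer than
#' two neighbors contribute 0.
#'
#' @param net a `weighted_network`.
#' @return local efficiency in `[0, 1]`.
#' @export
local_efficiency <- function(net) {
  check_network(net)
  a <- net$a; w <- net$w
  n <- nrow(a)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  contrib <- vapply(seq_len(n), function(i) {
    nb <- which((a[i, ] == 1 | a[, i] == 1) & seq_len(n) != i)
    if (length(nb) < 2) return(0)
    asub <- a[nb, nb, drop = FALSE]
    wsub <- w[nb, nb, drop = FALSE]
    e <- efficiency_value(asub, wsub)
    ia <- (wsub > 0) * 1L
    diag(ia) <- 0L
    ei <- efficiency_value(ia, wsub)
    if (ei == 0) 0 else e / ei
  }, numeric(1))
  mean(contrib)
}

#' Cost of a weighted directed network
#'
#' The weighted fraction of realized connections:
#' `Cost = sum_{i != j} a_ij w_ij / sum_{i != j} w_ij`, in `[0, 1]` (1
#' for the complete graph, 0 for the edgeless graph).
#'
#' @param net a `weighted_network`.
#' @return cost in `[0, 1]`.
#' @export
network_cost <- function(net) {
  check_network(net)
  w <- net$w
  diag(w) <- 0
  tot <- sum(w)
  if (tot <= 0)
    stop("undefined cost: all weights are zero", call. = FALSE)
  sum(net$a * w) / tot
}

#' Efficiency report of a network
#'
#' Convenience wrapper computing global efficiency, local efficiency and
#' cost; an economic small-world network scores high on both efficiencies
#' at low cost.
#'
#' @param net a `weighted_network`.
#' @return object of class `efficiency_report`: list with
#'   `global_efficiency`, `local_efficiency`, `cost`, `n`.
#' @export
efficiency_report <- function(net) {
  structure(list(global_efficiency = global_efficiency(net),
                 local_efficiency = local_efficiency(net),
                 cost = network_cost(net), n = nrow(net$a)),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("<efficiency_report> N = %d\n", x$n))
  cat(sprintf("  global efficiency %.4f\n  local efficiency  %.4f\n  cost              %.6g\n",
              x$global_efficiency, x$local_efficiency, x$cost))
  invisible(x)
}
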