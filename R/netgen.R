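#' Place somata uniformly in a cylinder with a minimum distance
#'
#' Uniform rejection sampling of `n` points inside a cylinder of radius
#' `R` and height `H` (centered on the origin, axis along z), honoring a
#' minimum pairwise distance `min_dist` (somata of ~10 um radius must not
#' overlap, hence the 20 um default).
#'
#' @param n number of somata.
#' @param R,H cylinder radius and height, micrometres.
#' @param min_dist minimum center-to-center distance, micrometres.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling budget per point (total attempts
#'   `n * max_attempts`); exceeding it, or requesting more spheres than
#'   the cylinder can pack, raises an infeasible-density error.
#' @return object of class `soma_layout`: list with `positions`
#'   (`n` x 3 matrix), `R`, `H`, `min_dist`, `seed`.
#' @export
place_somata <- function(n, R, H, min_dist = 20, seed = 1L,
                         max_attempts = 2000L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  # dense sphere packing bound: centers at min_dist <=> spheres of radius
  # min_dist/2 in the dilated cylinder
  vol <- pi * (R + min_dist / 2)^2 * (H + min_dist)
  cap <- 0.74 * vol / ((4 / 3) * pi * (min_dist / 2)^3)
  if (n > cap)
    stop("infeasible density: ", n, " somata exceed the packing capacity (~",
         round(cap), ") of the cylinder", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  pos <- matrix(NA_real_, n, 3)
  d2 <- min_dist^2
  attempts <- 0L
  budget <- n * max_attempts
  for (i in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > budget)
        stop("infeasible density: rejection sampling failed after ",
             budget, " attempts", call. = FALSE)
      r <- R * sqrt(runif(1))
      phi <- 2 * pi * runif(1)
      cand <- c(r * cos(phi), r * sin(phi), H * (runif(1) - 0.5))
      if (i == 1L) break
      dx <- pos[seq_len(i - 1L), 1L] - cand[1L]
      dy <- pos[seq_len(i - 1L), 2L] - cand[2L]
      dz <- pos[seq_len(i - 1L), 3L] - cand[3L]
      if (min(dx * dx + dy * dy + dz * dz) >= d2) break
    }
    pos[i, ] <- cand
  }
  structure(list(positions = pos, R = R, H = H, min_dist = min_dist,
                 seed = as.integer(seed)),
            class = "soma_layout")
}

#' @export
print.soma_layout <- function(x, ...) {
  cat(sprintf("<soma_layout> %d somata in cylinder R = %g um, H = %g um (min dist %g um)\n",
              nrow(x$positions), x$R, x$H, x$min_dist))
  invisible(x)
}

#' Edge probability and weight for an expected synapse count
#'
#' The connection from i to j exists with probability
#' `p = 1 - exp(-K)` (the probability of at least one potential synapse
#' under a Poisson count with mean `K`) and carries weight `w = K / p`,
#' the expected number of potential synapses *given* that the connection
#' exists, so that `E[a * w] = K` exactly: the realized weighted
#' connection strength is linear in the expected number of potential
#' synapses.  The weight is defined for every ordered pair whether or not
#' the connection is realized; as `K -> 0`, `p -> 0` while `w -> 1` (a
#' connection, were it to exist, would carry a single potential synapse),
#' which keeps the weight matrix fully defined for the ideal-graph
#' normalization and the cost denominator.
#'
#' @param K expected potential-synapse count(s), >= 0.
#' @return list with components `p` and `w`.
#' @export
edge_rule <- function(K) {
  p <- -expm1(-K)
  w <- ifelse(p > 0, K / p, 1)
  list(p = p, w = w)
}

#' Generate a random directed weighted network from a connectivity map
#'
#' For every ordered soma pair (i, j) the displacement
#' `(rho_ij, zeta_ij = z_j - z_i)` is looked up in the connectivity map
#' (bilinear interpolation, 0 beyond the lattice) giving `K_ij`; the
#' adjacency entry `a_ij` is a Bernoulli draw with success probability
#' `1 - exp(-K_ij)` and the weight matrix holds `w_ij = K_ij / p_ij` for
#' *all* ordered pairs, existing or not.  `a_ij` and `a_ji` are drawn
#' independently; `K` is asymmetric in general because `zeta` changes
#' sign.
#'
#' @param layout a [place_somata()] layout.
#' @param cg a `connectivity_map`.
#' @param seed integer seed for the Bernoulli draws.
#' @return object of class `weighted_network`: list with matrices `a`
#'   (0/1, zero diagonal), `w`, `K`, and the `layout`.
#' @export
build_network <- function(layout, cg, seed = 1L) {
  pos <- layout$positions
  n <- nrow(pos)
  dx <- outer(pos[, 1], pos[, 1], `-`)  # dx[i,j] = x_i - x_j
  dy <- outer(pos[, 2], pos[, 2], `-`)
  rho <- sqrt(dx^2 + dy^2)
  zeta <- outer(pos[, 3], pos[, 3], FUN = function(zi, zj) zj - zi)
  K <- matrix(interpolate_k(cg, as.numeric(rho), as.numeric(zeta)), n, n)
  diag(K) <- 0
  er <- edge_rule(K)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  a <- matrix(rbinom(n * n, 1L, as.numeric(er$p)), n, n)
  diag(a) <- 0L
  w <- matrix(er$w, n, n)
  diag(w) <- 0
  structure(list(a = a, w = w, K = K, layout = layout,
                 seed = as.integer(seed)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- nrow(x$a)
  cat(sprintf("<weighted_network> %d nodes, %d directed edges (density %.4f)\n",
              n, sum(x$a), sum(x$a) / (n * (n - 1))))
  invisible(x)
}

#' Write a network as a TSV edge table plus soma positions
#'
#' Writes `<path>` with columns `i, j, a, w, K` for all ordered pairs
#' with `K > 0` or `a = 1`, and `<path>.positions.tsv` with the soma
#' coordinates.
#'
#' @param net a `weighted_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  n <- nrow(net$a)
  idx <- which((net$K > 0 | net$a == 1) & row(net$a) != col(net$a))
  df <- data.frame(i = row(net$a)[idx], j = col(net$a)[idx],
                   a = net$a[idx], w = net$w[idx], K = net$K[idx])
  df <- df[order(df$i, df$j), ]
  con <- file(path, "w")
  writeLines("i\tj\ta\tw\tK", con)
  writeLines(sprintf("%d\t%d\t%d\t%.10g\t%.10g", df$i, df$j, df$a, df$w,
                     df$K), con)
  close(con)
  pos <- net$layout$positions
  con <- file(paste0(path, ".positions.tsv"), "w")
  writeLines("i\tx\ty\tz", con)
  writeLines(sprintf("%d\t%.6f\t%.6f\t%.6f", seq_len(n), pos[, 1], pos[, 2],
                     pos[, 3]), con)
  close(con)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path path passed to [write_network()] (the positions file is
#'   found at `<path>.positions.tsv`).
#' @return a `weighted_network` (pairs absent from the edge table have
#'   `K = w = 0`).
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  pos <- utils::read.table(paste0(path, ".positions.tsv"), header = TRUE,
                           sep = "\t")
  n <- nrow(pos)
  a <- matrix(0L, n, n); K <- matrix(0, n, n)
  idx <- cbind(df$i, df$j)
  a[idx] <- df$a
  K[idx] <- df$K
  # w is a deterministic function of K, defined for all pairs
  w <- matrix(edge_rule(K)$w, n, n)
  diag(w) <- 0
  layout <- structure(list(positions = as.matrix(pos[, c("x", "y", "z")]),
                           R = NA_real_, H = NA_real_, min_dist = NA_real_,
                           seed = NA_integer_),
                      class = "soma_layout")
  structure(list(a = a, w = w, K = K, layout = layout, seed = NA_integer_),
            class = "weighted_network")
}
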