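#' Variability of connectivity estimates versus sample size
#'
#' Replicated sparse-data experiment: for each ensemble size, grow
#' `n_replicates` independent ensembles, estimate the axonal/dendritic MDF
#' pair from each, and compute the expected potential-synapse count at
#' each displacement.  The spread of the replicate K values quantifies how
#' morphological sampling variability propagates into the connectivity
#' estimate; sampling theory predicts the standard deviation to scale as
#' `n^(-1/2)`.
#'
#' @param sizes ascending ensemble sizes.
#' @param n_replicates replicates per size (>= 2).
#' @param displacements list of `c(rho, zeta)` displacements.
#' @param params a [growth_params()] object.
#' @param seed master seed.
#' @param p a [synapse_params()] object.
#' @param h,extent MDF grid resolution and extent (see [estimate_mdf()]).
#' @return data frame of class `variability_table` with one row per
#'   (size, displacement): columns `n, rho, zeta, mean, std, min, max`;
#'   the raw replicate values are kept in `attr(, "values")`.
#' @export
variability_vs_sample_size <- function(sizes = c(10, 40, 160),
                                       n_replicates = 20,
                                       displacements = list(c(30, 0)),
                                       params = growth_params(), seed = 1L,
                                       p = synapse_params(),
                                       h = 2, extent = c(500, -500, 500)) {
  if (is.unsorted(sizes, strictly = TRUE))
    stop("sizes must be ascending", call. = FALSE)
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  vals <- array(NA_real_,
                dim = c(length(sizes), n_replicates, length(displacements)))
  rep_seed <- 0L
  for (si in seq_along(sizes)) {
    for (ri in seq_len(n_replicates)) {
      rep_seed <- rep_seed + 1L
      ens <- grow_ensemble(params, sizes[si], derive_seed(seed, rep_seed))
      ga <- suppressWarnings(estimate_mdf(ens, "axonal", h, extent))
      gd <- suppressWarnings(estimate_mdf(ens, "dendritic", h, extent))
      for (di in seq_along(displacements))
        vals[si, ri, di] <- k_uniform(ga, gd, displacements[[di]], p)
    }
  }
  rows <- expand.grid(si = seq_along(sizes), di = seq_along(displacements))
  out <- data.frame(
    n = sizes[rows$si],
    rho = vapply(displacements, `[`, 0, 1)[rows$di],
    zeta = vapply(displacements, `[`, 0, 2)[rows$di],
    mean = apply(vals, c(1, 3), mean)[cbind(rows$si, rows$di)],
    std = apply(vals, c(1, 3), sd)[cbind(rows$si, rows$di)],
    min = apply(vals, c(1, 3), min)[cbind(rows$si, rows$di)],
    max = apply(vals, c(1, 3), max)[cbind(rows$si, rows$di)])
  attr(out, "values") <- vals
  class(out) <- c("variability_table", "data.frame")
  out
}

#' Kernel-estimator variability across smoothing bandwidths
#'
#' Grows a pool of neurons; for each neuron the axonal inventory is paired
#' with the *same* neuron's dendritic inventory and the Gaussian-kernel
#' estimate is computed at every (displacement, sigma) combination.
#' Displacements sharing the same `(rho, zeta)` are cylindrically
#' equivalent regardless of their azimuth (optional third element) and are
#' pooled, so each sigma row aggregates `n_neurons *
#' length(displacements)` values.
#'
#' @param n_neurons pool size.
#' @param sigmas kernel standard deviations, micrometres.
#' @param displacements list of `c(rho, zeta)` or `c(rho, zeta, azimuth)`.
#' @inheritParams variability_vs_sample_size
#' @return data frame of class `variability_table`: one row per sigma with
#'   `mean, std, min, max` (std is `NA` for a single pooled value); raw
#'   values in `attr(, "values")` (neuron x displacement x sigma).
#' @export
kernel_sigma_sweep <- function(n_neurons = 10, sigmas = c(10, 20, 30),
                               displacements = list(c(30, 30, 0),
                                                    c(30, 30, pi / 2)),
                               params = growth_params(), seed = 1L,
                               p = synapse_params()) {
  if (any(sigmas <= 0)) stop("sigmas must be positive", call. = FALSE)
  ens <- grow_ensemble(params, n_neurons, seed)
  inv_a <- lapply(ens, segment_inventory, kind = "axonal")
  inv_d <- lapply(ens, segment_inventory, kind = "dendritic")
  vals <- array(NA_real_,
                dim = c(n_neurons, length(displacements), length(sigmas)))
  for (ni in seq_len(n_neurons))
    for (di in seq_along(displacements))
      for (si in seq_along(sigmas))
        vals[ni, di, si] <- k_kernel(inv_a[[ni]], inv_d[[ni]],
                                     displacements[[di]], p, sigmas[si])
  pooled <- apply(vals, 3, identity)  # (neuron x displacement) x sigma
  pooled <- matrix(pooled, ncol = length(sigmas))
  out <- data.frame(
    sigma = sigmas,
    mean = colMeans(pooled),
    std = if (nrow(pooled) > 1) apply(pooled, 2, sd) else NA_real_,
    min = apply(pooled, 2, min),
    max = apply(pooled, 2, max))
  attr(out, "values") <- vals
  class(out) <- c("variability_table", "data.frame")
  out
}

#' Economic small-world study across cylinder shapes
#'
#' Generates a random directed weighted network for each cylinder shape
#' (radius, height) from a common connectivity map and computes the
#' Latora-Marchiori efficiency report.  The default shapes are a tall
#' pipe, an intermediate cylinder and a flat disc of equal volume whose
#' full-scale population (2000 neurons) corresponds to a density of
#' 75,000 neurons/mm^3.
#'
#' @param shapes list of `c(R, H)` cylinder shapes, micrometres.
#' @param n neurons per network (2000 at full scale; smaller for desk
#'   runs).
#' @param cg a `connectivity_map`; if `NULL`, one is built from a freshly
#'   grown ensemble of `n_mdf` neurons.
#' @param density_check warn when the resulting density deviates more
#'   than 10% from 75,000 neurons/mm^3.
#' @param params growth parameters used when `cg` is `NULL`.
#' @param seed master seed (placement, wiring and, if needed, growth).
#' @param n_mdf ensemble size for map construction when `cg` is `NULL`.
#' @param min_dist minimum soma distance, micrometres.
#' @return data frame with one row per shape: `R, H, n, global_efficiency,
#'   local_efficiency, cost`; the networks are kept in
#'   `attr(, "networks")`.
#' @export
network_efficiency_experiment <- function(shapes = list(c(130, 500),
                                                        c(200, 212),
                                                        c(500, 34)),
                                          n = 200, cg = NULL,
                                          density_check = TRUE,
                                          params = growth_params(),
                                          seed = 1L, n_mdf = 200,
                                          min_dist = 20) {
  if (is.null(cg)) {
    ens <- grow_ensemble(params, n_mdf, derive_seed(seed, 101L))
    ga <- suppressWarnings(estimate_mdf(ens, "axonal", h = 2))
    gd <- suppressWarnings(estimate_mdf(ens, "dendritic", h = 2))
    cg <- connectivity_map(ga, gd, rho = seq(0, 240, by = 20),
                           zeta = seq(-360, 360, by = 30),
                           p = synapse_params(step = 4))
  }
  rows <- vector("list", length(shapes))
  nets <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    R <- shapes[[i]][1]; H <- shapes[[i]][2]
    if (density_check) {
      dens <- n / (pi * (R / 1000)^2 * (H / 1000))  # per mm^3
      if (abs(dens - 75000) / 75000 > 0.10)
        warning(sprintf(
          "density %.0f neurons/mm^3 in cylinder (R=%g, H=%g) deviates >10%% from 75,000",
          dens, R, H), call. = FALSE)
    }
    lay <- place_somata(n, R, H, min_dist, seed = derive_seed(seed, 10L + i))
    net <- build_network(lay, cg, seed = derive_seed(seed, 20L + i))
    rep <- efficiency_report(net)
    rows[[i]] <- data.frame(R = R, H = H, n = n,
                            global_efficiency = rep$global_efficiency,
                            local_efficiency = rep$local_efficiency,
                            cost = rep$cost)
    nets[[i]] <- net
  }
  out <- do.call(rbind, rows)
  attr(out, "networks") <- nets
  out
}
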