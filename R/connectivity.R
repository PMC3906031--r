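#' Potential-synapse parameters
#'
#' @param s contact threshold distance in micrometres: a potential synapse
#'   is a site where an axonal and a dendritic segment come within `s` of
#'   each other.  2 um is the conventional spine-reach distance.
#' @param step integration lattice spacing in micrometres for the overlap
#'   integrals ([k_uniform()], [k_template()]).
#' @return object of class `synapse_params`.
#' @export
synapse_params <- function(s = 2, step = 2) {
  if (s <= 0) stop("s must be > 0", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  structure(list(s = s, step = step), class = "synapse_params")
}

# displacement vector (rho, 0, zeta): the azimuth of the displacement is
# irrelevant under cylindrical symmetry and fixed to 0 by convention
d_vec <- function(d) {
  if (length(d) < 2) stop("displacement must be (rho, zeta)", call. = FALSE)
  c(d[1], 0, d[2])
}

# integration bounding box for two cylindrical supports displaced by
# (rho, 0, zeta): c(xlo, xhi, ylo, yhi, zlo, zhi)
overlap_box <- function(sup_a, sup_d, rho, zeta) {
  ra <- sup_a[1]; rd <- sup_d[1]
  c(max(-ra, rho - rd), min(ra, rho + rd),
    -min(ra, rd), min(ra, rd),
    max(sup_a[2], sup_d[2] + zeta), min(sup_a[3], sup_d[3] + zeta))
}

#' Expected potential synapses under uniform orientations
#'
#' Overlap integral of the axonal MDF of the pre-synaptic neuron and the
#' dendritic MDF of the post-synaptic neuron displaced by
#' `d = (rho, zeta)`:
#' `K_U = (pi/4) * 2s * sum_v rho_a(x_v) * rho_d(x_v - d) * dV`,
#' evaluated on a regular 3-D lattice (spacing `p$step`) restricted to the
#' overlap of the two supports.  The factor `pi/4` is the mean `|sin
#' theta|` of the crossing angle under orientations uniform on the unit
#' sphere.
#'
#' @param mdf_a axonal `mdf_grid` (pre-synaptic).
#' @param mdf_d dendritic `mdf_grid` (post-synaptic).
#' @param d displacement `c(rho, zeta)` in micrometres (`rho >= 0`
#'   horizontal, `zeta` vertical, post minus pre).
#' @param p a [synapse_params()] object.
#' @return expected number of potential synapses (dimensionless, >= 0);
#'   0 when the supports do not overlap.
#' @export
k_uniform <- function(mdf_a, mdf_d, d, p = synapse_params()) {
  if (d[1] < 0) stop("rho must be >= 0", call. = FALSE)
  box <- overlap_box(grid_support(mdf_a), grid_support(mdf_d), d[1], d[2])
  k_uniform_cpp(as.numeric(mdf_a$values), grid_meta(mdf_a),
                as.numeric(mdf_d$values), grid_meta(mdf_d),
                d[1], d[2], p$s, p$step, box)
}

#' Expected potential synapses from orientation templates
#'
#' Like [k_uniform()] but with the uniform-orientation constant replaced
#' by the actual crossing-angle weights between discretized orientations:
#' `K_O = 2s * sum_v sum_ij |sin theta_ij(v)| T_a(x_v, i) T_d(x_v - d, j)
#' dV`, where the canonical axes of each template are rotated into the
#' global frame by the local azimuth of the respective field at the
#' evaluation point.
#'
#' @param t_a axonal `orientation_template` (pre-synaptic).
#' @param t_d dendritic `orientation_template` (post-synaptic).
#' @inheritParams k_uniform
#' @return expected number of potential synapses.
#' @export
k_template <- function(t_a, t_d, d, p = synapse_params(step = 4)) {
  if (d[1] < 0) stop("rho must be >= 0", call. = FALSE)
  if (!identical(dim(t_a$values)[3], dim(t_d$values)[3]) ||
      !isTRUE(all.equal(t_a$axes, t_d$axes)))
    stop("templates have incompatible orientation axes", call. = FALSE)
  meta_a <- c(dim(t_a$values)[1:3], t_a$h, t_a$h, t_a$z_edges[1])
  meta_d <- c(dim(t_d$values)[1:3], t_d$h, t_d$h, t_d$z_edges[1])
  box <- overlap_box(grid_support(t_a), grid_support(t_d), d[1], d[2])
  k_template_cpp(as.numeric(t_a$values), meta_a, as.numeric(t_d$values),
                 meta_d, t_a$axes, d[1], d[2], p$s, p$step, box)
}

#' Expected potential synapses by Gaussian-kernel smoothing
#'
#' Kernel estimator operating on raw segment inventories: every segment is
#' represented by its midpoint, length and orientation; both the axonal
#' and dendritic clouds are notionally smoothed with an isotropic Gaussian
#' of standard deviation `sigma`, and the product integral collapses to a
#' pairwise sum with a Gaussian of per-axis standard deviation
#' `sqrt(2) * sigma`:
#' `K_S = 2s * sum_i sum_j l_i l_j |sin theta_ij| g(m_i - m_j - d)`.
#'
#' @param inv_a axonal segment inventory of the pre-synaptic neuron
#'   ([segment_inventory()] with `kind = "axonal"`).
#' @param inv_d dendritic segment inventory of the post-synaptic neuron.
#' @param d displacement `c(rho, zeta)`; an optional third element gives
#'   the azimuth (radians) of the horizontal displacement, default 0.
#' @param p a [synapse_params()] object (only `s` is used).
#' @param sigma kernel standard deviation in micrometres (10-30 um is the
#'   conventional range).
#' @return expected number of potential synapses; 0 for empty inventories.
#' @export
k_kernel <- function(inv_a, inv_d, d, p = synapse_params(), sigma = 20) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!nrow(inv_a) || !nrow(inv_d)) return(0)
  az <- if (length(d) >= 3) d[3] else 0
  dv <- c(d[1] * cos(az), d[1] * sin(az), d[2])
  k_kernel_cpp(as.matrix(inv_a[, c("x", "y", "z")]), inv_a$length,
               as.matrix(inv_a[, c("ux", "uy", "uz")]),
               as.matrix(inv_d[, c("x", "y", "z")]), inv_d$length,
               as.matrix(inv_d[, c("ux", "uy", "uz")]),
               dv, p$s, sigma)
}

#' Count potential synapses between two morphologies
#'
#' Brute-force counting oracle: translates the post-synaptic morphology by
#' `(rho, 0, zeta)` and finds every (axonal segment, dendritic segment)
#' pair whose minimum Euclidean distance (exact clamped closest-point
#' computation) is at most `s`.
#'
#' By default qualifying pairs are merged into *contact sites*: pairs
#' whose closest-approach midpoints lie within `2s` of each other (single
#' linkage) count as one site.  This makes the count independent of how
#' finely the neurites are discretized into segments - a single geometric
#' close approach between two neurites is one potential synapse no matter
#' how many short line pieces represent it - which is the quantity the
#' density-field estimators `K_U`, `K_O` and `K_S` estimate.  Set
#' `cluster = FALSE` for the raw pair count.
#'
#' @param m_a pre-synaptic `neuron_morphology` (its axon is used).
#' @param m_d post-synaptic `neuron_morphology` (its dendrites are used).
#' @inheritParams k_uniform
#' @param cluster merge qualifying pairs into contact sites (default) or
#'   return the raw pair count.
#' @return integer count.
#' @export
count_potential_synapses <- function(m_a, m_d, d, p = synapse_params(),
                                     cluster = TRUE) {
  sub <- function(m, kind) {
    keep <- which(if (kind == "axonal") m$segments$kind == "axon"
                  else m$segments$kind != "axon")
    seg <- m$segments[keep, , drop = FALSE]
    # remap parent links into the subset (parents stay within one arbor,
    # hence within one kind)
    par <- match(seg$parent, keep)
    par[is.na(par)] <- 0L
    list(xyz = as.matrix(seg[, c("x0", "y0", "z0", "x1", "y1", "z1")]),
         parent = as.integer(par))
  }
  a <- sub(m_a, "axonal")
  d_ <- sub(m_d, "dendritic")
  if (!nrow(a$xyz) || !nrow(d_$xyz)) return(0L)
  count_pairs_cpp(a$xyz, d_$xyz, a$parent, d_$parent, d_vec(d), p$s,
                  cluster, 2 * p$s)[1]
}

#' Tabulate expected potential synapses over a displacement lattice
#'
#' Evaluates [k_uniform()] (or [k_template()]) on a rectangular
#' `(rho, zeta)` lattice, producing a connectivity map that can later be
#' interpolated instead of re-running the overlap integral.
#'
#' @param mdf_a,mdf_d axonal and dendritic fields: `mdf_grid` objects for
#'   `method = "uniform"`, `orientation_template` objects for
#'   `method = "template"`.
#' @param rho,zeta strictly increasing lattice coordinates in micrometres
#'   (`rho >= 0`).
#' @param p a [synapse_params()] object.
#' @param method `"uniform"` or `"template"`.
#' @return object of class `connectivity_map`: list with `rho`, `zeta`,
#'   matrix `K` (`length(rho)` x `length(zeta)`) and `estimator` tag
#'   (`"U"` or `"O"`).
#' @export
connectivity_map <- function(mdf_a, mdf_d, rho, zeta, p = synapse_params(),
                             method = c("uniform", "template")) {
  method <- match.arg(method)
  if (any(diff(rho) <= 0) || any(diff(zeta) <= 0))
    stop("rho and zeta must be strictly increasing", call. = FALSE)
  if (any(rho < 0)) stop("rho must be >= 0", call. = FALSE)
  f <- if (method == "uniform") k_uniform else k_template
  K <- matrix(0, length(rho), length(zeta))
  for (i in seq_along(rho))
    for (j in seq_along(zeta))
      K[i, j] <- f(mdf_a, mdf_d, c(rho[i], zeta[j]), p)
  structure(list(rho = rho, zeta = zeta, K = K,
                 estimator = if (method == "uniform") "U" else "O",
                 s = p$s),
            class = "connectivity_map")
}

#' Interpolate a connectivity map
#'
#' Bilinear interpolation of the stored K surface; 0 beyond the lattice
#' hull.
#'
#' @param cg a `connectivity_map`.
#' @param rho,zeta query displacements (vectorized; `rho >= 0`).
#' @return expected potential-synapse counts.
#' @export
interpolate_k <- function(cg, rho, zeta) {
  if (any(rho < 0)) stop("rho must be >= 0", call. = FALSE)
  n <- max(length(rho), length(zeta))
  rho <- rep_len(rho, n); zeta <- rep_len(zeta, n)
  gr <- cg$rho; gz <- cg$zeta
  i <- findInterval(rho, gr)
  j <- findInterval(zeta, gz)
  out <- numeric(n)
  ok <- i >= 1 & i <= length(gr) & j >= 1 & j <= length(gz) &
    rho <= gr[length(gr)] & zeta <= gz[length(gz)]
  if (length(gr) < 2L || length(gz) < 2L)
    stop("connectivity map needs at least a 2 x 2 lattice", call. = FALSE)
  ii <- pmax(pmin(i[ok], length(gr) - 1L), 1L)
  jj <- pmax(pmin(j[ok], length(gz) - 1L), 1L)
  wr <- (rho[ok] - gr[ii]) / (gr[ii + 1L] - gr[ii])
  wz <- (zeta[ok] - gz[jj]) / (gz[jj + 1L] - gz[jj])
  out[ok] <- (1 - wr) * (1 - wz) * cg$K[cbind(ii, jj)] +
    wr * (1 - wz) * cg$K[cbind(ii + 1L, jj)] +
    (1 - wr) * wz * cg$K[cbind(ii, jj + 1L)] +
    wr * wz * cg$K[cbind(ii + 1L, jj + 1L)]
  out
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> estimator %s, %d x %d lattice, K in [%.3g, %.3g]\n",
              x$estimator, length(x$rho), length(x$zeta), min(x$K), max(x$K)))
  invisible(x)
}

#' Write / read a connectivity map as CSV
#'
#' Long-format CSV with columns `rho`, `zeta`, `K` and a `#` header
#' carrying the estimator tag and contact distance.
#'
#' @param cg a `connectivity_map`.
#' @param path file path.
#' @return `write_connectivity_map`: `path` invisibly;
#'   `read_connectivity_map`: a `connectivity_map`.
#' @export
write_connectivity_map <- function(cg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#estimator=%s", cg$estimator), con)
  writeLines(sprintf("#s=%.10g", cg$s), con)
  df <- expand.grid(rho = cg$rho, zeta = cg$zeta)
  df$K <- as.numeric(cg$K)
  writeLines("rho,zeta,K", con)
  writeLines(sprintf("%.10g,%.10g,%.10g", df$rho, df$zeta, df$K), con)
  invisible(path)
}

#' @rdname write_connectivity_map
#' @export
read_connectivity_map <- function(path) {
  raw <- readLines(path)
  hdr <- grep("^#", raw, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=")
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.table(text = raw[!grepl("^#", raw)], sep = ",",
                          header = TRUE)
  rho <- sort(unique(df$rho)); zeta <- sort(unique(df$zeta))
  K <- matrix(0, length(rho), length(zeta))
  K[cbind(match(df$rho, rho), match(df$zeta, zeta))] <- df$K
  structure(list(rho = rho, zeta = zeta, K = K,
                 estimator = meta[["estimator"]],
                 s = as.numeric(meta[["s"]])),
            class = "connectivity_map")
}
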