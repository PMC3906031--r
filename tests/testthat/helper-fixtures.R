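# Builders for tiny hand-made morphologies and lazily cached shared
# ensembles (grown once per test run).

seg_row <- function(kind, x0, y0, z0, x1, y1, z1, arbor = 1L, parent = 0L,
                    order = 0L) {
  data.frame(kind = kind, arbor = arbor, parent = parent, order = order,
             x0 = x0, y0 = y0, z0 = z0, x1 = x1, y1 = y1, z1 = z1,
             stringsAsFactors = FALSE)
}

# one axonal and one dendritic segment, for oracle examples
crossing_pair_morphs <- function() {
  list(a = morphology(seg_row("axon", -5, 0, 0, 5, 0, 0)),
       d = morphology(seg_row("basal", 0, 1, -5, 0, 1, 5)))
}

# a morphology whose segments all point along +z, stacked columns
vertical_morph <- function(kind = "basal", n = 5, x = 3, y = 0) {
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    seg_row(kind, x, y, i - 1, x, y, i, parent = i - 1L)))
  rows$arbor <- 1L
  morphology(rows)
}

# morphology with n_seg segments of i.i.d. uniform random orientation,
# scattered uniformly in a ball of the given radius
isotropic_morph <- function(n_seg = 200, radius = 60, len = 4,
                            kind = "basal", seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n_seg), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  m <- matrix(runif(3 * n_seg, -1, 1), ncol = 3)
  m <- m * radius * runif(n_seg)^(1 / 3) / sqrt(rowSums(m^2))
  rows <- data.frame(kind = kind, arbor = 1L, parent = 0L, order = 0L,
                     x0 = m[, 1] - len / 2 * u[, 1],
                     y0 = m[, 2] - len / 2 * u[, 2],
                     z0 = m[, 3] - len / 2 * u[, 3],
                     x1 = m[, 1] + len / 2 * u[, 1],
                     y1 = m[, 2] + len / 2 * u[, 2],
                     z1 = m[, 3] + len / 2 * u[, 3],
                     stringsAsFactors = FALSE)
  morphology(rows)
}

# uniform-density cylindrical grid: value inside r <= R, |z| <= Z
uniform_cylinder_grid <- function(value = 0.01, R = 10, Z = 5, h = 0.5,
                                  extent = c(2 * R, -2 * Z, 2 * Z)) {
  g <- estimate_mdf(list(vertical_morph()), "dendritic", h = h,
                    extent = extent)
  rc <- (g$r_edges[-1] + g$r_edges[-length(g$r_edges)]) / 2
  zc <- (g$z_edges[-1] + g$z_edges[-length(g$z_edges)]) / 2
  g$values <- outer(rc, zc, function(r, z) value * (r <= R & abs(z) <= Z))
  g
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# modest default-parameter ensemble shared by unit tests
small_ensemble <- function() {
  cached("small_ens", grow_ensemble(growth_params(), 60, seed = 101))
}

iso_params <- function() {
  growth_params(turning_concentration = 0, branch_concentration = 0)
}
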