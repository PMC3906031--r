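#' Estimate a morpho-density field from an ensemble
#'
#' Superimposes all morphologies (somata at the origin, +z parallel to the
#' apical dendrite), deposits every segment's length into cylindrical
#' (r, z) bins by exact line clipping against the ring and slab boundaries,
#' and normalizes by ensemble size and bin volume.  The result estimates
#' the expected segment length of the chosen arbor class per unit volume
#' (um of length per um^3, i.e. um^-2) as a function of horizontal distance
#' r from the apical axis and height z relative to the soma.
#'
#' Because bin membership depends only on (r, z), the estimate is exactly
#' invariant under rotations of the ensemble about the z axis, and total
#' deposited length is conserved exactly.
#'
#' @param ensemble a `neuron_ensemble` (or a single morphology).
#' @param kind `"axonal"` (axon segments) or `"dendritic"` (apical +
#'   basal segments).
#' @param h bin width in micrometres, used for both the radial width
#'   `dr` and the vertical width `dz`.
#' @param extent grid extent `c(r_max, z_min, z_max)` in micrometres; bin
#'   edges sit at integer multiples of `h`.  Mass falling outside is
#'   dropped with a warning reporting the clipped fraction.
#' @return object of class `mdf_grid`: list with `values` (`nr` x `nz`
#'   density matrix), `r_edges`, `z_edges`, `h`, `n_neurons`, `kind` and
#'   `clipped_fraction`.
#' @examples
#' m <- morphology(data.frame(kind = "basal", arbor = 1, parent = 0,
#'                            order = 0, x0 = 0.5, y0 = 0.5, z0 = 0.5,
#'                            x1 = 0.5, y1 = 0.5, z1 = 10.5))
#' g <- estimate_mdf(list(m), "dendritic", h = 1, extent = c(20, -20, 20))
#' total_mass(g)  # 10 um
#' @export
estimate_mdf <- function(ensemble, kind = c("axonal", "dendritic"), h = 1,
                         extent = c(500, -500, 500)) {
  kind <- match.arg(kind)
  ensemble <- as_ensemble(ensemble)
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  spec <- grid_spec(h, extent)
  segs <- lapply(ensemble, function(m)
    as.matrix(segments_of_kind(m, kind)[, c("x0", "y0", "z0",
                                            "x1", "y1", "z1")]))
  segs <- do.call(rbind, segs)
  dep <- deposit_cylindrical_cpp(segs, 0L, spec$dr, spec$dz, spec$nr,
                                 spec$nz, spec$zmin,
                                 matrix(numeric(0), 0, 0))
  n <- length(ensemble)
  lens <- array(dep$length_sums, dim = c(spec$nr, spec$nz))
  values <- lens / (n * bin_volumes(spec))
  clipped <- if (dep$total > 0) dep$clipped / dep$total else 0
  if (clipped > 0)
    warning(sprintf("%.3f%% of segment mass fell outside the grid extent %s",
                    100 * clipped,
                    "and was clipped"), call. = FALSE)
  structure(list(values = values, r_edges = spec$r_edges,
                 z_edges = spec$z_edges, h = h, n_neurons = n, kind = kind,
                 clipped_fraction = clipped),
            class = "mdf_grid")
}

grid_spec <- function(h, extent) {
  r_max <- extent[1]; z_min <- extent[2]; z_max <- extent[3]
  if (r_max <= 0 || z_max <= z_min)
    stop("invalid grid extent", call. = FALSE)
  nr <- as.integer(ceiling(r_max / h))
  # z edges at integer multiples of h spanning [z_min, z_max]
  z_lo <- floor(z_min / h) * h
  nz <- as.integer(ceiling((z_max - z_lo) / h))
  list(dr = h, dz = h, nr = nr, nz = nz, zmin = z_lo,
       r_edges = h * (0:nr), z_edges = z_lo + h * (0:nz))
}

# annulus volumes pi (r_{k+1}^2 - r_k^2) dz as an nr x nz matrix
bin_volumes <- function(spec) {
  ring <- pi * diff(spec$r_edges^2) * spec$dz
  matrix(ring, nrow = spec$nr, ncol = spec$nz)
}

spec_of <- function(g) {
  list(dr = g$h, dz = g$h, nr = nrow(g$values), nz = ncol(g$values),
       zmin = g$z_edges[1], r_edges = g$r_edges, z_edges = g$z_edges)
}

grid_meta <- function(g) {
  c(nrow(g$values), ncol(g$values), 1, g$h, g$h, g$z_edges[1])
}

#' Total mass of a density grid
#'
#' Sum over bins of density times bin volume: the mean per-neuron segment
#' length of the contributing arbor class (up to any clipped mass), in
#' micrometres.
#'
#' @param g an `mdf_grid` (or `orientation_template`).
#' @return total mass in micrometres of segment length.
#' @export
total_mass <- function(g) {
  v <- g$values
  if (length(dim(v)) == 3L) v <- apply(v, c(1, 2), sum)
  sum(v * bin_volumes(spec_of(g)))
}

#' Sample a cylindrical density field at 3-D points
#'
#' Converts `(x, y, z)` to `(r, z)` and interpolates the stored field
#' bilinearly on the bin centers.  The field is clamped to the innermost
#' bin value on the axis and tapers linearly to zero beyond the outermost
#' bin centers (zero from one bin width past the last center outward).
#'
#' @param g an `mdf_grid`.
#' @param x,y,z coordinates in micrometres (vectorized).
#' @return density values in um^-2.
#' @export
sample_density <- function(g, x, y, z) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  sample_density_cpp(as.numeric(g$values), grid_meta(g),
                     sqrt(x^2 + y^2), z)
}

#' @export
print.mdf_grid <- function(x, ...) {
  cat(sprintf("<mdf_grid> %s, %d x %d bins (h = %g um), %d neurons\n",
              x$kind, nrow(x$values), ncol(x$values), x$h, x$n_neurons))
  cat(sprintf("  total mass %.1f um/neuron; clipped fraction %.2g\n",
              total_mass(x), x$clipped_fraction))
  invisible(x)
}

#' Heatmap of the log-density of an MDF
#'
#' @param x an `mdf_grid`.
#' @param r_max,z_range optional axis limits in micrometres.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot.mdf_grid <- function(x, r_max = NULL, z_range = NULL, ...) {
  rc <- (x$r_edges[-1] + x$r_edges[-length(x$r_edges)]) / 2
  zc <- (x$z_edges[-1] + x$z_edges[-length(x$z_edges)]) / 2
  v <- log10(x$values + 1e-12)
  ri <- if (is.null(r_max)) seq_along(rc) else which(rc <= r_max)
  zi <- if (is.null(z_range)) seq_along(zc) else
    which(zc >= z_range[1] & zc <= z_range[2])
  graphics::image(rc[ri], zc[zi], v[ri, zi, drop = FALSE],
                  xlab = "r (um)", ylab = "z (um)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(v)
}

#' Write / read an MDF grid as self-describing CSV
#'
#' Plain-text container: `#key=value` header lines (bin width, extent,
#' ensemble size, kind, units) followed by the density matrix with radial
#' bins as rows.
#'
#' @param g an `mdf_grid`.
#' @param path file path.
#' @return `write_mdf`: `path` invisibly; `read_mdf`: an `mdf_grid`.
#' @export
write_mdf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(kind = g$kind, h = g$h, r_max = max(g$r_edges),
            z_min = min(g$z_edges), z_max = max(g$z_edges),
            n_neurons = g$n_neurons, clipped_fraction = g$clipped_fraction,
            units = "um_per_um3")
  writeLines(paste0("#", names(meta), "=", meta), con)
  utils::write.table(format(g$values, digits = 10, trim = TRUE,
                            scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_mdf
#' @export
read_mdf <- function(path) {
  raw <- readLines(path)
  hdr <- grep("^#", raw, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=")
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  vals <- as.matrix(utils::read.table(text = raw[!grepl("^#", raw)],
                                      sep = ","))
  dimnames(vals) <- NULL
  h <- as.numeric(meta[["h"]])
  spec <- grid_spec(h, c(as.numeric(meta[["r_max"]]),
                         as.numeric(meta[["z_min"]]),
                         as.numeric(meta[["z_max"]])))
  structure(list(values = vals, r_edges = spec$r_edges,
                 z_edges = spec$z_edges, h = h,
                 n_neurons = as.integer(as.numeric(meta[["n_neurons"]])),
                 kind = meta[["kind"]],
                 clipped_fraction = as.numeric(meta[["clipped_fraction"]])),
            class = "mdf_grid")
}

# nonzero support of a grid: c(r_hi, z_lo, z_hi) in um, for trimming
# integration lattices
grid_support <- function(g) {
  v <- g$values
  if (length(dim(v)) == 3L) v <- apply(v, c(1, 2), sum)
  nzr <- which(rowSums(v) > 0)
  nzz <- which(colSums(v) > 0)
  if (!length(nzr))
    return(c(0, 0, 0))
  c(g$r_edges[max(nzr) + 1L], g$z_edges[min(nzz)], g$z_edges[max(nzz) + 1L])
}
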