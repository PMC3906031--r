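#' Canonical orientation axes
#'
#' The seven principal directions used to discretize segment orientation,
#' expressed in the local cylindrical frame `(e_r, e_phi, e_z)`: the
#' vertical axis, three equatorial axes at azimuths 0, 60 and 120 degrees,
#' and three axes at polar angle 45 degrees and azimuths 0, 120 and 240
#' degrees.  Axes are orientation (sign-free) classes.
#'
#' @return a 7 x 3 matrix, one unit axis per row.
#' @export
orientation_axes <- function() {
  eq <- c(0, 60, 120) * pi / 180
  up <- c(0, 120, 240) * pi / 180
  rbind(c(0, 0, 1),
        cbind(cos(eq), sin(eq), 0),
        cbind(cos(up), sin(up), 1) / sqrt(2))
}

#' Build an orientation template from an ensemble
#'
#' Like [estimate_mdf()], but each segment's length is deposited into the
#' channel of the canonical axis closest (by `|u . c_i|`) to its direction
#' expressed in the local cylindrical frame at the deposition point's
#' azimuth.  Summing the channels recovers the plain MDF exactly.
#'
#' @inheritParams estimate_mdf
#' @return object of class `orientation_template`: as `mdf_grid` but with
#'   a 3-d `values` array (`nr` x `nz` x 7) and the `axes` matrix.
#' @export
build_template <- function(ensemble, kind = c("axonal", "dendritic"), h = 1,
                           extent = c(500, -500, 500)) {
  kind <- match.arg(kind)
  ensemble <- as_ensemble(ensemble)
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  spec <- grid_spec(h, extent)
  axes <- orientation_axes()
  segs <- lapply(ensemble, function(m)
    as.matrix(segments_of_kind(m, kind)[, c("x0", "y0", "z0",
                                            "x1", "y1", "z1")]))
  segs <- do.call(rbind, segs)
  dep <- deposit_cylindrical_cpp(segs, 0L, spec$dr, spec$dz, spec$nr,
                                 spec$nz, spec$zmin, axes)
  n <- length(ensemble)
  lens <- array(dep$length_sums, dim = c(spec$nr, spec$nz, nrow(axes)))
  vol <- bin_volumes(spec)
  values <- lens / (n * as.numeric(vol))  # volumes recycle over channels
  clipped <- if (dep$total > 0) dep$clipped / dep$total else 0
  if (clipped > 0)
    warning(sprintf("%.3f%% of segment mass fell outside the grid extent %s",
                    100 * clipped, "and was clipped"), call. = FALSE)
  structure(list(values = values, r_edges = spec$r_edges,
                 z_edges = spec$z_edges, h = h, n_neurons = n, kind = kind,
                 clipped_fraction = clipped, axes = axes),
            class = c("orientation_template", "mdf_grid"))
}

#' Collapse an orientation template to a plain MDF grid
#'
#' @param t an `orientation_template`.
#' @return an `mdf_grid` whose values are the channel sums.
#' @export
template_to_mdf <- function(t) {
  structure(list(values = apply(t$values, c(1, 2), sum),
                 r_edges = t$r_edges, z_edges = t$z_edges, h = t$h,
                 n_neurons = t$n_neurons, kind = t$kind,
                 clipped_fraction = t$clipped_fraction),
            class = "mdf_grid")
}

#' Per-channel mass of an orientation template
#'
#' @param t an `orientation_template`.
#' @return numeric vector of length 7: micrometres of segment length per
#'   neuron assigned to each canonical axis.
#' @export
channel_mass <- function(t) {
  vol <- bin_volumes(spec_of(t))
  apply(t$values, 3, function(v) sum(v * vol))
}

#' @export
print.orientation_template <- function(x, ...) {
  cat(sprintf(
    "<orientation_template> %s, %d x %d bins x %d axes (h = %g um), %d neurons\n",
    x$kind, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], x$h,
    x$n_neurons))
  invisible(x)
}
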