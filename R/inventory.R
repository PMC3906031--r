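#' Segment inventory of a morphology
#'
#' One row per segment: midpoint position, length and unit orientation,
#' the raw material of the Gaussian-kernel connectivity estimator and of
#' the orientation statistics.  The sum of the `length` column equals the
#' total arbor length exactly.
#'
#' @param m a `neuron_morphology`.
#' @param kind optionally restrict to one arbor class: `"axonal"` (axon
#'   segments) or `"dendritic"` (apical + basal); default all segments.
#' @return data frame with columns `x, y, z` (midpoint, um), `length`
#'   (um), `ux, uy, uz` (unit orientation) and `kind`.
#' @export
segment_inventory <- function(m, kind = NULL) {
  seg <- if (is.null(kind)) m$segments else segments_of_kind(m, kind)
  if (!nrow(seg)) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      length = numeric(0), ux = numeric(0), uy = numeric(0),
                      uz = numeric(0), kind = character(0),
                      stringsAsFactors = FALSE))
  }
  len <- segment_lengths(seg)
  data.frame(x = (seg$x0 + seg$x1) / 2, y = (seg$y0 + seg$y1) / 2,
             z = (seg$z0 + seg$z1) / 2, length = len,
             ux = (seg$x1 - seg$x0) / len, uy = (seg$y1 - seg$y0) / len,
             uz = (seg$z1 - seg$z0) / len, kind = seg$kind,
             stringsAsFactors = FALSE)
}

#' Orientation histograms of an ensemble
#'
#' Pools the azimuthal angle (on `[0, 2*pi)`) and polar angle (on
#' `[0, pi]`, measured from the +z apical axis) of every segment of the
#' requested class, one entry per segment.  Under orientations uniform on
#' the unit sphere the azimuth is uniform and the polar angle has the
#' sinusoidal density `sin(theta) / 2`.
#'
#' @param ensemble a `neuron_ensemble` (or list of morphologies).
#' @param kind `"axon"` or `"dendrite"`.
#' @param n_bins number of bins for each histogram.
#' @return object of class `orientation_histogram`: a list with data
#'   frames `azimuth` and `polar` (bin edges `lo`, `hi` and `count`) and
#'   the pooled angles as attributes for downstream tests.
#' @export
orientation_histogram <- function(ensemble, kind = c("axon", "dendrite"),
                                  n_bins = 18L) {
  kind <- match.arg(kind)
  ensemble <- as_ensemble(ensemble)
  invs <- lapply(ensemble, segment_inventory, kind = kind)
  inv <- do.call(rbind, invs)
  if (!nrow(inv)) stop("ensemble has no segments of kind ", kind,
                       call. = FALSE)
  az <- atan2(inv$uy, inv$ux) %% (2 * pi)
  pol <- acos(pmin(1, pmax(-1, inv$uz)))
  bin_table <- function(x, lo, hi) {
    br <- seq(lo, hi, length.out = n_bins + 1L)
    idx <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L),
                n_bins)
    data.frame(lo = br[-length(br)], hi = br[-1],
               count = tabulate(idx, n_bins))
  }
  out <- list(azimuth = bin_table(az, 0, 2 * pi),
              polar = bin_table(pol, 0, pi),
              n_segments = nrow(inv), kind = kind)
  attr(out, "azimuth_angles") <- az
  attr(out, "polar_angles") <- pol
  class(out) <- "orientation_histogram"
  out
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat("<orientation_histogram>", x$kind, "segments:", x$n_segments,
      "entries,", nrow(x$azimuth), "bins\n")
  invisible(x)
}
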