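#' Growth parameters for the stochastic outgrowth simulator
#'
#' Parameters of the phenomenological neurite outgrowth model.  Development
#' is simulated over `n_steps` fixed time increments; at every increment
#' each active growth cone elongates by `step_length` micrometres in a
#' direction drawn from a von Mises-Fisher perturbation (concentration
#' `turning_concentration`) of its current direction, and splits into two
#' daughter cones with probability
#' `branch_prob * 2^(-branch_decay * order)`, where `order` is the
#' centrifugal order (number of branch points between the cone and the
#' arbor root).  Each morphology consists of one axon rooted downward, one
#' apical dendrite rooted upward, and `n_basal_range` basal dendrites with
#' lateral-to-downward roots, all anchored at the soma surface.
#'
#' @param n_steps number of fixed time increments (default 180).
#' @param step_length elongation per increment, micrometres.
#' @param branch_prob per-terminal per-increment branching probability at
#'   centrifugal order 0.
#' @param branch_decay exponent `gamma` of the `2^(-gamma * order)`
#'   branching decay.
#' @param turning_concentration von Mises-Fisher concentration of the
#'   per-step direction perturbation (larger = straighter neurites; 0 =
#'   isotropic re-orientation at every step).
#' @param branch_concentration vMF concentration used to draw the two
#'   daughter directions at a branch point.
#' @param n_basal_range integer interval (length 2) for the number of basal
#'   dendrites.
#' @param axon_polar,apical_polar,basal_polar polar-angle intervals
#'   (radians from the +z apical axis) for the root directions of each
#'   arbor class.  Defaults give a downward axon root (z-component < 0), an
#'   upward apical root (z-component > 0) and lateral/downward basal roots
#'   (z-component <= 0).
#' @param soma_radius soma radius, micrometres; arbor roots start on the
#'   soma surface.
#' @return an object of class `growth_params`.
#' @examples
#' p <- growth_params(n_steps = 60)
#' m <- grow_neuron(p, seed = 1)
#' m
#' @export
growth_params <- function(n_steps = 180L,
                          step_length = 2.5,
                          branch_prob = 0.010,
                          branch_decay = 0.8,
                          turning_concentration = 12,
                          branch_concentration = 8,
                          n_basal_range = c(4L, 8L),
                          axon_polar = c(150, 180) * pi / 180,
                          apical_polar = c(0, 15) * pi / 180,
                          basal_polar = c(90, 140) * pi / 180,
                          soma_radius = 10) {
  p <- list(n_steps = as.integer(n_steps), step_length = step_length,
            branch_prob = branch_prob, branch_decay = branch_decay,
            turning_concentration = turning_concentration,
            branch_concentration = branch_concentration,
            n_basal_range = as.integer(n_basal_range),
            axon_polar = axon_polar, apical_polar = apical_polar,
            basal_polar = basal_polar, soma_radius = soma_radius)
  validate_growth_params(p)
  class(p) <- "growth_params"
  p
}

validate_growth_params <- function(p) {
  if (p$n_steps < 1L)
    stop("growth configuration error: n_steps must be >= 1", call. = FALSE)
  if (p$step_length <= 0)
    stop("growth configuration error: step_length must be > 0", call. = FALSE)
  if (p$branch_prob < 0 || p$branch_prob > 1)
    stop("growth configuration error: branch_prob must be in [0, 1]",
         call. = FALSE)
  if (p$turning_concentration < 0 || p$branch_concentration < 0)
    stop("growth configuration error: concentrations must be >= 0",
         call. = FALSE)
  if (length(p$n_basal_range) != 2L || p$n_basal_range[1] > p$n_basal_range[2] ||
      p$n_basal_range[1] < 1L)
    stop("growth configuration error: invalid n_basal_range", call. = FALSE)
  for (nm in c("axon_polar", "apical_polar", "basal_polar")) {
    b <- p[[nm]]
    if (length(b) != 2L || b[1] > b[2] || b[1] < 0 || b[2] > pi)
      stop("growth configuration error: invalid polar range ", nm,
           call. = FALSE)
  }
  if (p$soma_radius <= 0)
    stop("growth configuration error: soma_radius must be > 0", call. = FALSE)
  invisible(p)
}

kind_levels <- c("axon", "apical", "basal")

#' Construct a neuron morphology from a segment table
#'
#' Low-level constructor used by [grow_neuron()] and [read_swc()], also
#' handy for building small morphologies by hand.  Segments are straight
#' 3-D line pieces grouped into arbors; each arbor is a rooted tree
#' anchored at the soma surface.
#'
#' @param segments data frame with columns `kind` (one of `"axon"`,
#'   `"apical"`, `"basal"`), `arbor` (integer arbor id), `parent` (row
#'   index of the parent segment, 0 for an arbor root), `order`
#'   (centrifugal order) and the endpoint coordinates
#'   `x0,y0,z0,x1,y1,z1` in micrometres.
#' @param soma_center,soma_radius soma position (conventionally the origin)
#'   and radius in micrometres.
#' @return an object of class `neuron_morphology`.
#' @export
morphology <- function(segments, soma_center = c(0, 0, 0), soma_radius = 10) {
  need <- c("kind", "arbor", "parent", "order",
            "x0", "y0", "z0", "x1", "y1", "z1")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop("segment table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  segments <- as.data.frame(segments)[need]
  segments$kind <- as.character(segments$kind)
  if (!all(segments$kind %in% kind_levels))
    stop("unknown arbor kind; expected axon/apical/basal", call. = FALSE)
  len <- segment_lengths(segments)
  if (any(len <= 0))
    stop("zero-length segment in morphology", call. = FALSE)
  structure(list(segments = segments,
                 soma_center = as.numeric(soma_center),
                 soma_radius = soma_radius),
            class = "neuron_morphology")
}

segment_lengths <- function(seg) {
  sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
}

#' Grow a single pyramidal-like neuron morphology
#'
#' Runs the seeded stochastic outgrowth model.  Identical `(params, seed)`
#' give bitwise-identical morphologies.
#'
#' @param params a [growth_params()] object.
#' @param seed integer seed for this neuron.
#' @return a `neuron_morphology` whose soma sits at the origin, with one
#'   axon (root direction pointing down), one apical dendrite (root up) and
#'   4 to 8 basal dendrites (lateral/downward roots).
#' @export
grow_neuron <- function(params = growth_params(), seed = 1L) {
  validate_growth_params(params)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  n_basal <- sample.int(params$n_basal_range[2] - params$n_basal_range[1] + 1L,
                        1L) + params$n_basal_range[1] - 1L
  m <- grow_neuron_cpp(params$n_steps, params$step_length, params$branch_prob,
                       params$branch_decay, params$turning_concentration,
                       params$branch_concentration, n_basal,
                       params$soma_radius, params$axon_polar,
                       params$apical_polar, params$basal_polar)
  seg <- as.data.frame(m)
  seg$kind <- kind_levels[seg$kind]
  for (cc in c("arbor", "parent", "order")) seg[[cc]] <- as.integer(seg[[cc]])
  out <- morphology(seg, soma_center = c(0, 0, 0),
                    soma_radius = params$soma_radius)
  out$params <- params
  out$seed <- as.integer(seed)
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Deterministic, well-mixed seed streams derived from a master seed.
# Linear formulas are not good enough here: nested derivations (per-replicate
# master seeds feeding per-neuron seeds) must not produce overlapping
# streams, so the mixing goes through R's own RNG.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

derive_seed <- function(seed, i) {
  derive_seeds(seed, i)[i]
}

#' Grow an ensemble of morphologies
#'
#' Per-neuron seeds are derived deterministically from the master seed, so
#' `grow_ensemble(p, 1, s)` equals `grow_neuron(p, derived_seed)` and any
#' subset of the ensemble is reproducible independently of the rest.
#'
#' @inheritParams grow_neuron
#' @param n number of neurons (>= 1).
#' @param seed master seed.
#' @return a list of `neuron_morphology` objects, class `neuron_ensemble`.
#' @export
grow_ensemble <- function(params = growth_params(), n, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  seeds <- derive_seeds(seed, n)
  out <- vector("list", n)
  for (i in seq_len(n))
    out[[i]] <- grow_neuron(params, seeds[i])
  structure(out, class = c("neuron_ensemble", "list"))
}

#' @export
print.neuron_morphology <- function(x, ...) {
  seg <- x$segments
  len <- segment_lengths(seg)
  cat("<neuron_morphology>", nrow(seg), "segments,",
      length(unique(seg$arbor)), "arbors\n")
  for (k in kind_levels) {
    i <- seg$kind == k
    if (any(i))
      cat(sprintf("  %-6s %5d segments, total length %.1f um\n", k, sum(i),
                  sum(len[i])))
  }
  invisible(x)
}

#' @export
print.neuron_ensemble <- function(x, ...) {
  nseg <- vapply(x, function(m) nrow(m$segments), integer(1))
  cat("<neuron_ensemble>", length(x), "neurons,", sum(nseg),
      "segments total\n")
  invisible(x)
}

# segments of one arbor class; kind = "axonal"/"axon" or
# "dendritic"/"dendrite" (= apical + basal)
segments_of_kind <- function(m, kind) {
  seg <- m$segments
  kind <- match.arg(kind, c("axonal", "dendritic", "axon", "dendrite",
                            "apical", "basal"))
  keep <- switch(kind,
                 axonal = , axon = seg$kind == "axon",
                 dendritic = , dendrite = seg$kind %in% c("apical", "basal"),
                 apical = seg$kind == "apical",
                 basal = seg$kind == "basal")
  seg[keep, , drop = FALSE]
}

as_ensemble <- function(x) {
  if (inherits(x, "neuron_morphology")) x <- list(x)
  if (!length(x)) stop("empty ensemble", call. = FALSE)
  x
}
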