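---
title: "Estimating neural connectivity from morpho-density fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating neural connectivity from morpho-density fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdfconn)
```

## The problem

Whether two cortical neurons can form a synapse is first of all a geometric
question: an axonal branch of the pre-synaptic cell and a dendritic branch
of the post-synaptic cell must pass within a spine's reach of each other.
Such close appositions are called *potential synapses* — necessary, not
sufficient, for an actual synapse.  Counting them experimentally for many
neuron pairs is infeasible, so they are estimated from the statistics of
arbor shape.

A *morpho-density field* (MDF) summarizes those statistics: it is the
expected neurite length per unit volume (µm/µm³ = µm⁻²) at each position
relative to the soma, estimated separately for the axonal and the dendritic
(apical + basal) arbor.  Pyramidal-cell arbors are statistically symmetric
under rotation about the apical axis, so the field is stored on a
cylindrical `(r, z)` grid.  Given the axonal MDF of one neuron and the
dendritic MDF of another displaced by `d = (ρ, ζ)`, the expected number of
potential synapses is an overlap integral, and a whole network can be wired
from a lookup table of that integral.

## Estimators

Three estimators of the expected count `K(ρ, ζ)` are implemented.

**Uniform orientations** (`k_uniform()`).  If segment orientations are
uniform on the unit sphere, the expected number of close approaches between
two thin-fiber systems within distance `s` is

$$K_U(d) = \frac{\pi}{4}\, 2s \int \hat\rho_a(\mathbf{x})\,
  \hat\rho_d(\mathbf{x} - \mathbf{d})\, d\mathbf{x},$$

where π/4 is the mean |sin θ| of the crossing angle under isotropy.  The
integral is evaluated by midpoint summation on a regular 3-D lattice
restricted to the overlap of the two supports, sampling both fields
bilinearly on the `(r, z)` bin centers.

**Actual orientations** (`build_template()` / `k_template()`).  Segment
orientation is discretized onto seven canonical axes expressed in the local
cylindrical frame (vertical; three equatorial at azimuths 0°/60°/120°;
three at 45° polar and azimuths 0°/120°/240°), giving a 7-channel template
per arbor class whose channel sum is exactly the plain MDF.  The estimator
replaces π/4 by the actual |sin θᵢⱼ| between channel axes, rotated into the
global frame by each field's local azimuth at the evaluation point.

**Gaussian-kernel smoothing** (`k_kernel()`).  Working directly from a
single pair of segment inventories (midpoint, length, orientation per
segment), both clouds are notionally smoothed with an isotropic Gaussian of
standard deviation σ; the product integral collapses analytically so that

$$K_S(d) = 2s \sum_i \sum_j \ell_i \ell_j\, |\sin\theta_{ij}|\,
  g_{\sqrt{2}\sigma}(\mathbf{m}_i - \mathbf{m}_j - \mathbf{d}),$$

with `g` the trivariate normal density of per-axis standard deviation √2 σ.
Segment mass is collapsed to midpoints, which is accurate because σ (10–30
µm conventionally) is much larger than a segment.

## The counting oracle and what "one potential synapse" means

`count_potential_synapses()` is the ground truth the estimators are tested
against: it translates one morphology, computes exact clamped
closest-point distances between every (axonal, dendritic) segment pair,
and counts qualifying pairs.  Raw pair counts, however, depend on how
finely a neurite is digitized: one geometric crossing of two branches
represented by 2.5 µm line pieces with `s = 2` µm produces ~5–6 qualifying
pairs (endpoint caps plus double counts at shared joints; for piece length
ℓ the inflation is ≈ 1 + 4s/ℓ).  The density formulas above estimate the
number of *distinct close approaches*, which is the digitization-invariant
quantity.  The oracle therefore merges, by default, qualifying pairs that
represent the same approach: two pairs join the same *contact site* only
when their axonal segments share a tree node, their dendritic segments
share a tree node, and their closest-approach midpoints lie within `2s`.
Approaches made by unrelated branch pairs always remain distinct sites,
so genuinely separate potential synapses are never merged.  `cluster =
FALSE` returns the raw pair count for comparison.

With this definition the Monte-Carlo mean of the oracle over thousands of
random neuron pairs agrees with `k_uniform()` within Monte-Carlo error
(z ≈ −1.5 and −0.3 at displacements (30, 0) and (60, 0) µm in the
acceptance suite), jointly validating the (π/4)·2s constant, the field
estimation and the overlap integration.

## The generator

Full-scale studies of this kind use ensembles from dedicated morphological
simulators fitted to experimental reconstructions; fitting such a model is
out of scope here.  The bundled generator
(`grow_neuron()`, `grow_ensemble()`) is a deliberately minimal stochastic
stand-in that reproduces the qualitative constraints of layer-2/3
pyramidal morphology: one axon whose root points downward, one apical
dendrite rooted upward, 4–8 basal dendrites with lateral-to-downward
roots, all anchored on a 10 µm soma; growth proceeds in 180 fixed time
increments ("18 days") during which every growth cone elongates by
`step_length` along a von Mises–Fisher perturbation of its heading and
branches with probability `branch_prob · 2^(−γ·order)`.

Defaults (one-time choices, in µm where dimensional):

| parameter | default | rationale |
|---|---|---|
| `n_steps` | 180 | fixed increments over the simulated development |
| `step_length` | 2.5 | terminal paths ≤ 450 µm, matching juvenile arbor spans |
| `branch_prob`, `branch_decay` | 0.010, 0.8 | ~15–25 terminals/neuron, a few mm of dendrite |
| `turning_concentration` | 12 | ~16° per-step turns: tortuous but directed neurites |
| `branch_concentration` | 8 | 30–40° branch openings |
| polar bands (axon/apical/basal) | 150–180° / 0–15° / 90–140° | root orientation constraints above |

These defaults produce ≈ 0.9 mm of axon and ≈ 6 mm of dendrite per neuron
with arbors contained in a 500 µm neighborhood of the soma — a scaled-down
but shape-faithful emulation.  What the ensemble does *not* emulate:
fitted branching statistics of real reconstructions, diameter taper,
boutons/spines, tissue boundaries and curvature.  Passing tests therefore
certify the estimators and their mutual consistency on a realistic arbor
geometry class, not biological K values; all quantitative conclusions are
about the method, and `K` magnitudes change with generator settings.

Determinism: every neuron is grown from a derived seed obtained by proper
RNG mixing of the master seed (linear seed arithmetic is insufficient —
nested derivations produce overlapping streams that silently correlate
replicate experiments).

## Field estimation details

Segments are deposited into cylindrical bins by *exact clipping*: a
segment is split at its crossings of the ring radii (roots of the
quadratic r²(t)) and slab planes, and each sub-piece's length is credited
to the bin containing its midpoint.  Bin volumes are analytic annuli
π(r²ₖ₊₁ − r²ₖ)Δz.  Two properties follow exactly rather than
approximately: total deposited length per neuron is conserved (the basis
of `total_mass()` and the mass-conservation acceptance check at 1e-6), and
the estimate is invariant under any common rotation of the ensemble about
the apical axis, because bin membership depends only on (r, z).  A
Cartesian voxel pass with ring aggregation was considered and rejected:
boundary voxels re-assign between rings under rotation, breaking azimuth
invariance at the 10⁻³ level.

Numerical choices: bin width `h = 1` µm by default (`Δr = Δz = h`), grid
extent r ≤ 500, |z| ≤ 500 µm (the default arbors never clip; clipped mass
elsewhere triggers a warning with the clipped fraction);
`sample_density()` interpolates bilinearly on bin centers, clamps to the
innermost ring on the axis, and tapers to zero one bin beyond the last
center; overlap integrals use a 2 µm lattice by default (halving the step
moves K_U by < 0.3 % on default ensembles; template integrals default to
4 µm, matching the coarser grid that estimator warrants).

## Networks and efficiency

`place_somata()` distributes somata uniformly in a cylinder by rejection
sampling with a 20 µm minimum distance (soma radius ≈ 10 µm); requests
beyond a dense-packing bound, or that exhaust the attempt budget, raise an
infeasible-density error.  For each ordered pair, `build_network()` looks
up `K(ρᵢⱼ, ζᵢⱼ)` (ζ = post z − pre z) in a `connectivity_map()` and draws
the adjacency entry from a Bernoulli trial with `p = 1 − exp(−K)`, the
probability of at least one potential synapse under a Poisson count of
mean K.  The weight of every ordered pair — realized or not — is
`w = K/p`, the expected count *given* that the connection exists, so
`E[a·w] = K` exactly (linearity in the expected number of potential
synapses) and `w → 1` continuously as `K → 0`.  Defining w for absent
pairs matters: they populate the ideal graph and the cost denominator.
With `w = 0` for absent pairs instead, far pairs would vanish from the
cost normalization and the flat-disc network would paradoxically come out
*more* expensive than the tall pipe; with the continuous rule the disc is
the cheapest shape, as geometry dictates.

Efficiency follows the weighted-graph formalism: an edge's length is the
reciprocal of its weight, `d_ij` is the shortest directed path length
(Dijkstra), the efficiency of a graph is the mean of `1/d_ij` over ordered
pairs (0 for unreachable pairs), and the global efficiency is that value
normalized by the same quantity on the ideal graph in which every
connection is present with the same weights and its own shortest paths.
Local efficiency averages the same ratio over the subgraphs induced on
each vertex's neighbors (union of in- and out-neighbors; vertices with
fewer than two neighbors contribute 0 — both choices are ours, the
directed generalization being underdetermined).  Cost is the weighted
fraction of realized connections, Σaᵢⱼwᵢⱼ / Σwᵢⱼ, so the complete graph
costs 1.  On graphs of up to six nodes all three measures match an
exhaustive-path brute-force oracle exactly.

## Scripted experiments

Three seeded experiments reproduce the computational studies at
configurable scale:

* `variability_vs_sample_size()` — grows replicate ensembles per sample
  size, estimates an MDF pair from each and tabulates the spread of K.
  The replicate standard deviation falls roughly as n^(−1/2) (ratio ≈ 3.8
  between n = 10 and n = 160 at 20 replicates in the acceptance run,
  against the theoretical 4), the quantitative form of the claim that
  sparse data produce uncertain connectivity estimates.  Note that K from
  an n-neuron MDF pair also carries a small O(1/n) diagonal bias (the
  same neurons enter both fields), visible as a slightly elevated mean at
  n = 10.
* `kernel_sigma_sweep()` — pairs each neuron's axonal inventory with the
  same neuron's dendritic inventory and sweeps σ ∈ {10, 20, 30} µm,
  pooling cylindrically equivalent displacements; mean K_S decreases
  markedly with σ.
* `network_efficiency_experiment()` — tall pipe (130, 500), intermediate
  cylinder (200, 212) and flat disc (500, 34) µm; 2000 neurons at full
  scale corresponds to 75,000 neurons/mm³ (a density check warns on
  mismatch), desk runs default to n = 200.  All efficiencies land in
  [0, 1] and the disc is consistently the cheapest network.

Problem sizes used by the bundled acceptance script (`scripts/acceptance.R`)
are desk-scale choices: a 1000-neuron ensemble for field estimation, 1000
Monte-Carlo pairs for the oracle, 20 replicates for the variability study,
and 200-neuron networks.

## Known limitations

* The generator is phenomenological; K magnitudes are not biological
  predictions.
* MDFs are marginal densities: they carry no spatial correlation between
  segments of one neuron, so only *expected* counts over neuron pairs are
  estimable, not the pair-to-pair distribution.
* The 7-axis orientation discretization biases mean |sin θ| by about −1 %
  under isotropy; `k_template()` inherits that bias.
* The kernel estimator is intended for sparse data; its variance across
  neuron pairs is large (std of order the mean), which is the point the
  sweep experiment makes.
* Potential synapses are geometric appositions; no claim about realized
  synapses, axo-axonic or dendro-dendritic contacts is made.
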