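test_that("k_uniform matches the closed form for uniform overlapping fields", {
  # the sampled field has linear tapers of width h at the cylinder edge;
  # the squared-taper deficit in the product integral is ~ h/(6R), so the
  # comparison tightens as the grid is refined
  g <- uniform_cylinder_grid(value = 0.01, R = 10, Z = 5, h = 0.2)
  p <- synapse_params(s = 2, step = 0.25)
  k <- k_uniform(g, g, c(0, 0), p)
  expect_equal(k, 0.1 * pi^2, tolerance = 0.02)
  # displaced beyond any overlap
  expect_equal(k_uniform(g, g, c(30, 0), p), 0)
  expect_error(k_uniform(g, g, c(-1, 0), p), "rho")
})

test_that("halving the integration step barely changes K_U", {
  ens <- small_ensemble()
  ga <- estimate_mdf(ens, "axonal", h = 2)
  gd <- estimate_mdf(ens, "dendritic", h = 2)
  k4 <- k_uniform(ga, gd, c(30, 0), synapse_params(step = 4))
  k2 <- k_uniform(ga, gd, c(30, 0), synapse_params(step = 2))
  expect_lt(abs(k4 - k2) / k2, 0.01)
})

test_that("counting oracle resolves crossings at the threshold distance", {
  cp <- crossing_pair_morphs()
  expect_identical(count_potential_synapses(cp$a, cp$d, c(0, 0),
                                            synapse_params(s = 2)), 1L)
  expect_identical(count_potential_synapses(cp$a, cp$d, c(0, 0),
                                            synapse_params(s = 0.5)), 0L)
})

test_that("disjoint crossings count additively", {
  mk <- function(offsets, kind, horiz) {
    rows <- do.call(rbind, lapply(seq_along(offsets), function(i) {
      o <- offsets[i]
      if (horiz) seg_row(kind, o - 5, 0, 0, o + 5, 0, 0, arbor = i)
      else seg_row(kind, o, 1, -5, o, 1, 5, arbor = i)
    }))
    morphology(rows)
  }
  a <- mk(c(0, 50, 100), "axon", horiz = TRUE)
  d <- mk(c(0, 50, 100), "basal", horiz = FALSE)
  # three well-separated crossings, one per matching offset
  expect_identical(count_potential_synapses(a, d, c(0, 0)), 3L)
  expect_identical(count_potential_synapses(a, d, c(0, 0), cluster = FALSE),
                   3L)
})

test_that("site counting is invariant to segment subdivision", {
  # one geometric crossing digitized at two granularities
  coarse <- crossing_pair_morphs()
  fine_d <- morphology(do.call(rbind, lapply(1:10, function(i)
    seg_row("basal", 0, 1, -5 + i - 1, 0, 1, -5 + i, parent = i - 1L))))
  p <- synapse_params(s = 2)
  expect_identical(count_potential_synapses(coarse$a, fine_d, c(0, 0), p), 1L)
  raw <- count_potential_synapses(coarse$a, fine_d, c(0, 0), p,
                                  cluster = FALSE)
  expect_gt(raw, 1L)
})

test_that("k_kernel matches the closed-form single-pair value", {
  inv_a <- data.frame(x = 0, y = 0, z = 0, length = 1, ux = 1, uy = 0,
                      uz = 0, kind = "axon")
  inv_d <- data.frame(x = 0, y = 0, z = 0, length = 1, ux = 0, uy = 1,
                      uz = 0, kind = "basal")
  k <- k_kernel(inv_a, inv_d, c(0, 0), synapse_params(s = 2), sigma = 10)
  expect_equal(k, 4 * (2 * pi * 200)^(-3 / 2), tolerance = 1e-12)
  # parallel orientations: |sin theta| = 0
  inv_par <- inv_a
  expect_equal(k_kernel(inv_a, inv_par, c(0, 0), sigma = 10), 0)
  expect_equal(k_kernel(inv_a[0, ], inv_d, c(0, 0)), 0)
})

test_that("k_kernel respects cylindrical equivalence of displacements", {
  m <- small_ensemble()[[2]]
  inv_a <- segment_inventory(m, "axonal")
  inv_d <- segment_inventory(m, "dendritic")
  th <- 0.7
  rot <- function(inv) {
    out <- inv
    out$x <- cos(th) * inv$x - sin(th) * inv$y
    out$y <- sin(th) * inv$x + cos(th) * inv$y
    out$ux <- cos(th) * inv$ux - sin(th) * inv$uy
    out$uy <- sin(th) * inv$ux + cos(th) * inv$uy
    out
  }
  k0 <- k_kernel(inv_a, inv_d, c(30, 30, 0), sigma = 15)
  k1 <- k_kernel(rot(inv_a), rot(inv_d), c(30, 30, th), sigma = 15)
  expect_equal(k1, k0, tolerance = 1e-9)
})

test_that("k_template reduces to the plain overlap for orthogonal channels", {
  # axonal mass vertical, dendritic mass along the local azimuthal axis
  vert <- list(vertical_morph("axon", n = 20, x = 10, y = 0))
  ring <- morphology(do.call(rbind, lapply(1:20, function(i)
    seg_row("basal", 10, -2 + 0.2 * (i - 1), i / 2, 10, -2 + 0.2 * i,
            i / 2, arbor = i))))
  ext <- c(30, -10, 20)
  ta <- build_template(vert, "axonal", h = 2, extent = ext)
  td <- build_template(list(ring), "dendritic", h = 2, extent = ext)
  expect_gt(channel_mass(ta)[1], 0)      # e_z channel
  expect_gt(sum(channel_mass(td)[2:4]), 0)  # equatorial channels
  p <- synapse_params(s = 2, step = 1)
  ko <- k_template(ta, td, c(0, 0), p)
  ku <- k_uniform(template_to_mdf(ta), template_to_mdf(td), c(0, 0), p)
  # |sin theta| = 1 everywhere vs the uniform-orientation mean pi/4
  expect_equal(ko, ku * 4 / pi, tolerance = 1e-6)
})

test_that("templates with all mass vertical give zero crossing expectation", {
  va <- list(vertical_morph("axon", n = 10, x = 2))
  vd <- list(vertical_morph("basal", n = 10, x = 2))
  ext <- c(20, -10, 20)
  ta <- build_template(va, "axonal", h = 2, extent = ext)
  td <- build_template(vd, "dendritic", h = 2, extent = ext)
  expect_equal(k_template(ta, td, c(0, 0), synapse_params(step = 1)), 0)
})

test_that("connectivity maps interpolate bilinearly and reject bad queries", {
  ens <- small_ensemble()[1:20]
  ga <- estimate_mdf(ens, "axonal", h = 2)
  gd <- estimate_mdf(ens, "dendritic", h = 2)
  cg <- connectivity_map(ga, gd, rho = c(0, 30, 60), zeta = c(-30, 0, 30),
                         p = synapse_params(step = 4))
  expect_s3_class(cg, "connectivity_map")
  expect_true(all(cg$K >= 0))
  # lattice point: stored value exactly
  expect_equal(interpolate_k(cg, 30, 0), cg$K[2, 2], tolerance = 1e-12)
  # midway between rho nodes at fixed zeta: mean of the two stored values
  expect_equal(interpolate_k(cg, 45, 0), mean(cg$K[2:3, 2]),
               tolerance = 1e-12)
  # beyond the hull: zero
  expect_equal(interpolate_k(cg, 100, 0), 0)
  expect_error(interpolate_k(cg, -5, 0), "rho")
  expect_error(connectivity_map(ga, gd, c(30, 0), c(0, 30)),
               "increasing")
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectivity_map(cg, path)
  cg2 <- read_connectivity_map(path)
  expect_equal(cg2$K, cg$K, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(cg2$estimator, "U")
})
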