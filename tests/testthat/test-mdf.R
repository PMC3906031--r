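test_that("single axis-parallel segment deposits all mass in the inner ring", {
  m <- morphology(seg_row("basal", 0.5, 0.5, 0.5, 0.5, 0.5, 10.5))
  g <- estimate_mdf(list(m), "dendritic", h = 1, extent = c(20, -20, 20))
  expect_equal(total_mass(g), 10, tolerance = 1e-12)
  # the segment sits at radius sqrt(0.5), inside the first ring [0, 1)
  expect_equal(sum(g$values[-1, ]), 0)
  # z bins [0,1) and [10,11) receive 0.5 um, the interior bins 1 um each;
  # ring volume is pi * (1^2 - 0^2) * 1
  zc <- (g$z_edges[-1] + g$z_edges[-length(g$z_edges)]) / 2
  interior <- which(zc > 1 & zc < 10)
  expect_equal(unname(g$values[1, interior]), rep(1 / pi, length(interior)),
               tolerance = 1e-12)
  expect_equal(g$values[1, zc > 0 & zc < 1], 0.5 / pi, tolerance = 1e-12)
})

test_that("densities average per neuron across the ensemble", {
  m1 <- morphology(seg_row("basal", 0, 0, 0, 0, 0, 10))
  m2 <- morphology(seg_row("basal", 0, 0, 0, 0, 0, 20))
  g <- estimate_mdf(list(m1, m2), "dendritic", h = 1, extent = c(20, -20, 25))
  expect_equal(total_mass(g), 15, tolerance = 1e-12)
})

test_that("total mass equals independently summed mean arbor length", {
  ens <- small_ensemble()
  for (kind in c("axonal", "dendritic")) {
    g <- estimate_mdf(ens, kind, h = 2)
    direct <- mean(vapply(ens, function(m)
      sum(mdfconn:::segment_lengths(mdfconn:::segments_of_kind(m, kind))),
      numeric(1)))
    expect_equal(total_mass(g), direct, tolerance = 1e-9)
    expect_true(all(g$values >= 0))
  }
})

test_that("estimation is invariant under a common rotation about z", {
  ens <- small_ensemble()[1:15]
  th <- 1.1
  rot <- function(m) {
    s <- m$segments
    rx0 <- cos(th) * s$x0 - sin(th) * s$y0
    s$y0 <- sin(th) * s$x0 + cos(th) * s$y0
    s$x0 <- rx0
    rx1 <- cos(th) * s$x1 - sin(th) * s$y1
    s$y1 <- sin(th) * s$x1 + cos(th) * s$y1
    s$x1 <- rx1
    morphology(s)
  }
  g1 <- estimate_mdf(ens, "dendritic", h = 2)
  g2 <- estimate_mdf(lapply(ens, rot), "dendritic", h = 2)
  denom <- max(g1$values)
  expect_lt(max(abs(g1$values - g2$values)) / denom, 1e-6)
})

test_that("mass outside the grid extent is clipped with a warning", {
  m <- morphology(seg_row("basal", 0, 0, 0, 0, 0, 40))
  expect_warning(g <- estimate_mdf(list(m), "dendritic", h = 1,
                                   extent = c(10, -10, 10)),
                 "clipped")
  expect_equal(g$clipped_fraction, 0.75, tolerance = 1e-12)
  expect_equal(total_mass(g), 10, tolerance = 1e-12)
})

test_that("sample_density interpolates bilinearly and vanishes off-grid", {
  g <- estimate_mdf(list(vertical_morph(x = 0, n = 10)), "dendritic",
                    h = 1, extent = c(10, -10, 15))
  # at a bin center: that bin's value
  expect_equal(sample_density(g, 0.5, 0, 5.5), g$values[1, 16],
               tolerance = 1e-12)
  # midway between two radial centers at fixed z: arithmetic mean
  expect_equal(sample_density(g, 1.0, 0, 5.5),
               mean(g$values[1:2, 16]), tolerance = 1e-12)
  # beyond last bin center + dr: zero
  expect_equal(sample_density(g, 10.6, 0, 5.5), 0)
  expect_equal(sample_density(g, 0, 0, 20), 0)
})

test_that("grid values converge as the ensemble grows (~ n^-1/2)", {
  p <- growth_params(n_steps = 50)
  sds <- sapply(c(10, 40), function(n) {
    vals <- sapply(1:8, function(r) {
      ens <- grow_ensemble(p, n, seed = 5000 + 100 * r + n)
      g <- suppressWarnings(estimate_mdf(ens, "dendritic", h = 4,
                                         extent = c(200, -200, 200)))
      sample_density(g, 20, 0, -30)
    })
    sd(vals)
  })
  ratio <- sds[1] / sds[2]  # expect ~ sqrt(4) = 2
  expect_gt(ratio, 1)
  expect_lt(ratio, 4)
})

test_that("MDF CSV round trip preserves the grid", {
  g <- estimate_mdf(small_ensemble()[1:5], "axonal", h = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mdf(g, path)
  g2 <- read_mdf(path)
  expect_equal(g2$values, g$values, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(g2$r_edges, g$r_edges)
  expect_equal(g2$z_edges, g$z_edges)
  expect_identical(g2$n_neurons, g$n_neurons)
  expect_identical(g2$kind, g$kind)
})
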