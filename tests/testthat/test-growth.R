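test_that("growth is deterministic under (params, seed)", {
  p <- growth_params(n_steps = 40)
  m1 <- grow_neuron(p, seed = 3)
  m2 <- grow_neuron(p, seed = 3)
  expect_identical(m1$segments, m2$segments)
  m3 <- grow_neuron(p, seed = 4)
  expect_false(identical(m1$segments, m3$segments))
})

test_that("morphologies honor the arbor composition and root orientations", {
  p <- growth_params(n_steps = 30)
  for (seed in 1:8) {
    m <- grow_neuron(p, seed)
    seg <- m$segments
    roots <- seg[seg$parent == 0, ]
    expect_identical(sum(roots$kind == "axon"), 1L)
    expect_identical(sum(roots$kind == "apical"), 1L)
    n_basal <- sum(roots$kind == "basal")
    expect_gte(n_basal, 4)
    expect_lte(n_basal, 8)
    dirz <- (roots$z1 - roots$z0)
    expect_lt(dirz[roots$kind == "axon"], 0)
    expect_gt(dirz[roots$kind == "apical"], 0)
    expect_true(all(dirz[roots$kind == "basal"] <= 1e-9))
    # roots anchored on the soma surface
    r0 <- sqrt(roots$x0^2 + roots$y0^2 + roots$z0^2)
    expect_equal(r0, rep(p$soma_radius, nrow(roots)), tolerance = 1e-9)
  }
})

test_that("segments form rooted trees (parents precede children, connected)", {
  m <- grow_neuron(growth_params(n_steps = 60), seed = 5)
  seg <- m$segments
  idx <- seq_len(nrow(seg))
  expect_true(all(seg$parent < idx))  # acyclic by construction
  child <- seg[seg$parent > 0, ]
  par <- seg[child$parent, ]
  expect_equal(child$x0, par$x1, tolerance = 1e-12)
  expect_equal(child$y0, par$y1, tolerance = 1e-12)
  expect_equal(child$z0, par$z1, tolerance = 1e-12)
  expect_identical(child$arbor, par$arbor)
})

test_that("grow_ensemble derives per-neuron seeds consistently", {
  p <- growth_params(n_steps = 25)
  ens <- grow_ensemble(p, 3, seed = 9)
  expect_length(ens, 3)
  expect_false(identical(ens[[1]]$segments, ens[[2]]$segments))
  one <- grow_ensemble(p, 1, seed = 9)
  expect_identical(one[[1]]$segments,
                   grow_neuron(p, mdfconn:::derive_seed(9, 1))$segments)
  expect_error(grow_ensemble(p, 0, seed = 1), "n must be")
})

test_that("mean dendritic length is stable across master seeds", {
  p <- growth_params(n_steps = 60)
  means <- ses <- numeric(5)
  for (k in 1:5) {
    ens <- grow_ensemble(p, 80, seed = 1000 + k)
    lens <- vapply(ens, function(m)
      sum(mdfconn:::segment_lengths(mdfconn:::segments_of_kind(m, "dendritic"))),
      numeric(1))
    means[k] <- mean(lens)
    ses[k] <- sd(lens) / sqrt(length(lens))
  }
  grand <- mean(means)
  expect_true(all(abs(means - grand) < 3 * ses))
})

test_that("invalid growth parameters raise configuration errors", {
  expect_error(growth_params(n_steps = 0), "configuration error")
  expect_error(growth_params(branch_prob = 1.5), "configuration error")
  expect_error(growth_params(n_basal_range = c(8, 4)), "configuration error")
  expect_error(growth_params(axon_polar = c(2, 1)), "configuration error")
})
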