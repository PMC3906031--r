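test_that("soma placement honors spacing and containment, reproducibly", {
  lay <- place_somata(200, R = 130, H = 500, min_dist = 20, seed = 4)
  pos <- lay$positions
  expect_identical(nrow(pos), 200L)
  expect_true(all(sqrt(pos[, 1]^2 + pos[, 2]^2) <= 130))
  expect_true(all(abs(pos[, 3]) <= 250))
  dmin <- min(dist(pos))
  expect_gte(dmin, 20)
  lay2 <- place_somata(200, R = 130, H = 500, min_dist = 20, seed = 4)
  expect_identical(lay2$positions, pos)
})

test_that("infeasible packing densities raise the dedicated error", {
  expect_error(place_somata(1000, R = 30, H = 30, min_dist = 20, seed = 1),
               "infeasible density")
  # feasible by the packing bound but unreachable by rejection sampling
  expect_error(place_somata(60, R = 35, H = 45, min_dist = 20, seed = 1,
                            max_attempts = 50L),
               "infeasible density")
})

test_that("edge rule keeps E[a w] = K and extends continuously to K = 0", {
  er <- edge_rule(c(0, 0.5, 10))
  expect_equal(er$p, c(0, 1 - exp(-0.5), 1 - exp(-10)))
  expect_equal(er$w[1], 1)
  expect_equal(er$w[3], 10 / (1 - exp(-10)), tolerance = 1e-12)
  expect_equal(er$p * er$w, c(0, 0.5, 10), tolerance = 1e-12)
})

test_that("networks wire by Bernoulli draws on the interpolated K surface", {
  cg <- structure(list(rho = c(0, 50, 100), zeta = c(-100, 0, 100),
                       K = matrix(c(2, 2, 2, 2, 2, 2, 0, 0, 0), 3, 3),
                       estimator = "U", s = 2),
                  class = "connectivity_map")
  lay <- place_somata(40, R = 80, H = 160, min_dist = 20, seed = 2)
  net <- build_network(lay, cg, seed = 5)
  expect_identical(diag(net$a), rep(0L, 40))
  expect_true(all(net$a %in% 0:1))
  expect_true(all(net$w >= 0 & net$K >= 0))
  # K = 0 pairs never wire
  expect_true(all(net$a[net$K == 0] == 0))
  # zeta sign flip makes K directional in general
  expect_false(isTRUE(all.equal(net$K, t(net$K))))
  net2 <- build_network(lay, cg, seed = 5)
  expect_identical(net2$a, net$a)
})

test_that("network TSV round trip preserves a, w, K and positions", {
  cg <- structure(list(rho = c(0, 100), zeta = c(-100, 100),
                       K = matrix(1, 2, 2), estimator = "U", s = 2),
                  class = "connectivity_map")
  lay <- place_somata(15, R = 60, H = 120, min_dist = 20, seed = 3)
  net <- build_network(lay, cg, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  net2 <- read_network(path)
  expect_identical(net2$a, net$a)
  expect_equal(net2$w, net$w, tolerance = 1e-9)
  expect_equal(net2$K, net$K, tolerance = 1e-9)
  expect_equal(net2$layout$positions, lay$positions, tolerance = 1e-6,
               ignore_attr = TRUE)
})
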