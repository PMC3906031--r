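mk_net <- function(a, w, K = w) {
  structure(list(a = a, w = w, K = K), class = "weighted_network")
}

test_that("path lengths are reciprocal-weight shortest paths", {
  a <- matrix(0L, 2, 2); a[1, 2] <- 1L
  w <- matrix(1, 2, 2); w[1, 2] <- 4
  d <- path_length_matrix(mk_net(a, w))
  expect_equal(d[1, 2], 0.25)
  expect_true(is.infinite(d[2, 1]))
  # detour through the third node when the direct edge is absent
  a3 <- matrix(1L, 3, 3); diag(a3) <- 0L; a3[1, 2] <- 0L
  w3 <- matrix(1, 3, 3); diag(w3) <- 0
  d3 <- path_length_matrix(mk_net(a3, w3))
  expect_equal(d3[1, 2], 2)
  expect_error(path_length_matrix(mk_net(a, matrix(0, 2, 2))),
               "invalid network")
})

test_that("the three-node worked example matches hand-derived values", {
  a <- matrix(1L, 3, 3); diag(a) <- 0L; a[1, 2] <- 0L
  w <- matrix(1, 3, 3); diag(w) <- 0
  net <- mk_net(a, w)
  expect_equal(global_efficiency(net), (5.5 / 6) / 1, tolerance = 1e-12)
  expect_equal(local_efficiency(net), (1 + 1 + 0.5) / 3, tolerance = 1e-12)
  expect_equal(network_cost(net), 5 / 6, tolerance = 1e-12)
})

test_that("complete and edgeless graphs hit the efficiency extremes", {
  n <- 5
  a <- matrix(1L, n, n); diag(a) <- 0L
  w <- matrix(1, n, n); diag(w) <- 0
  full <- mk_net(a, w)
  expect_equal(global_efficiency(full), 1)
  expect_equal(local_efficiency(full), 1)
  expect_equal(network_cost(full), 1)
  empty <- mk_net(matrix(0L, n, n), w)
  expect_equal(global_efficiency(empty), 0)
  expect_equal(local_efficiency(empty), 0)
  expect_equal(network_cost(empty), 0)
  expect_error(network_cost(mk_net(matrix(0L, n, n), matrix(0, n, n))),
               "undefined cost")
})

test_that("adding an edge never decreases raw efficiency", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    net <- random_weighted_net(n)
    e0 <- mdfconn:::efficiency_value(net$a, net$w)
    off <- which(net$a == 0 & row(net$a) != col(net$a))
    if (!length(off)) next
    a2 <- net$a
    a2[sample(off, 1)] <- 1L
    e1 <- mdfconn:::efficiency_value(a2, net$w)
    expect_gte(e1, e0 - 1e-12)
  }
})

test_that("efficiency agrees with the exhaustive-path oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    net <- random_weighted_net(n, p_edge = runif(1, 0.2, 0.9))
    oracle <- oracle_efficiency(net$a, net$w)
    expect_equal(global_efficiency(net), oracle$global, tolerance = 1e-12)
    expect_equal(local_efficiency(net), oracle$local, tolerance = 1e-12)
    expect_equal(network_cost(net), oracle$cost, tolerance = 1e-12)
  }
})
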