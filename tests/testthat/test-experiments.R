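test_that("variability tables are well-formed with unbiased std", {
  p <- growth_params(n_steps = 40)
  tab <- variability_vs_sample_size(sizes = c(5, 10), n_replicates = 2,
                                    displacements = list(c(20, 0)),
                                    params = p, seed = 3, h = 4,
                                    extent = c(250, -250, 250),
                                    p = synapse_params(step = 6))
  expect_s3_class(tab, "variability_table")
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$min <= tab$mean & tab$mean <= tab$max))
  expect_true(all(tab$std >= 0))
  vals <- attr(tab, "values")
  # denominator n - 1
  expect_equal(tab$std[1], sd(vals[1, , 1]), tolerance = 1e-12)
  expect_equal(tab$std[1],
               sqrt(sum((vals[1, , 1] - mean(vals[1, , 1]))^2) / 1),
               tolerance = 1e-12)
  expect_error(variability_vs_sample_size(sizes = c(10, 5), params = p),
               "ascending")
})

test_that("kernel sweep pools equivalent displacements and tracks sigma", {
  p <- growth_params(n_steps = 50)
  tab <- kernel_sigma_sweep(n_neurons = 4, sigmas = c(10, 20, 30),
                            params = p, seed = 2)
  expect_identical(nrow(tab), 3L)
  expect_true(all(diff(tab$mean) < 0))
  vals <- attr(tab, "values")
  expect_identical(dim(vals), c(4L, 2L, 3L))
  # mean pools neurons x equivalent displacements
  expect_equal(tab$mean[1], mean(vals[, , 1]), tolerance = 1e-12)
  one <- kernel_sigma_sweep(n_neurons = 1, sigmas = 15,
                            displacements = list(c(30, 30)),
                            params = p, seed = 2)
  expect_identical(nrow(one), 1L)
  expect_true(is.na(one$std))
})

test_that("network experiment produces bounded reports for every shape", {
  cg <- structure(list(rho = c(0, 40, 80, 120), zeta = c(-120, 0, 120),
                       K = matrix(c(3, 2, 1, 0.2, 3, 2, 1, 0.2,
                                    0.5, 0.3, 0.1, 0), 4, 3),
                       estimator = "U", s = 2),
                  class = "connectivity_map")
  t0 <- Sys.time()
  tab <- network_efficiency_experiment(n = 12, cg = cg, seed = 5,
                                       density_check = FALSE)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$global_efficiency >= 0 & tab$global_efficiency <= 1))
  expect_true(all(tab$local_efficiency >= 0 & tab$local_efficiency <= 1))
  expect_true(all(tab$cost >= 0 & tab$cost <= 1))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
  expect_warning(network_efficiency_experiment(shapes = list(c(130, 500)),
                                               n = 12, cg = cg, seed = 5),
                 "density")
})

test_that("experiments are reproducible under (config, seed)", {
  p <- growth_params(n_steps = 30)
  t1 <- kernel_sigma_sweep(n_neurons = 2, sigmas = 20, params = p, seed = 7)
  t2 <- kernel_sigma_sweep(n_neurons = 2, sigmas = 20, params = p, seed = 7)
  expect_identical(t1$mean, t2$mean)
})
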