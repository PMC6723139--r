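vc_default <- derive_variance_components(mu = 100, cv = 0.15, h2 = 0.15)

test_that("base records follow y = mu + a + e", {
  pop <- simulate_base_records(vc_default, 100, z_a = rep(0, 5), z_e = rep(0, 5))
  expect_equal(pop$a, rep(0, 5))
  expect_equal(pop$e, rep(0, 5))
  expect_equal(pop$y, rep(100, 5))

  # sigma_u = 3, sigma_e = 4 comes from cv * mu = 5 with h2 = 0.36
  vc <- derive_variance_components(mu = 100, cv = 0.05, h2 = 0.36)
  pop <- simulate_base_records(vc, 100, z_a = 1, z_e = -1)
  expect_equal(pop$a, 3)
  expect_equal(pop$e, -4)
  expect_equal(pop$y, 99)

  expect_error(simulate_base_records(vc, 100, z_a = 1:3, z_e = 1:2),
               class = "scalefx_domain_error")
})

test_that("negative-record fraction at CV = 0.5 matches the normal tail", {
  vc <- derive_variance_components(mu = 100, cv = 0.5, h2 = 0.3)
  set.seed(99)
  pop <- simulate_base_records(vc, 100, rnorm(1e5), rnorm(1e5))
  frac <- mean(pop$y < 0)
  p <- pnorm(-2)
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / 1e5))
})

test_that("scaled deviations are proportional to the record", {
  sc <- scale_deviations(100, cv = 0.15, h2 = 0.15)
  expect_equal(sc$sigma_pi, 15)
  expect_equal(sc$sigma_ei, 15 * sqrt(0.85))
  expect_equal(sc$sigma_ui, 15 * sqrt(0.15))
  expect_equal(sc$n_negative, 0L)

  flipped <- scale_deviations(-100, cv = 0.15, h2 = 0.15)
  expect_equal(flipped$sigma_pi, sc$sigma_pi)
  expect_equal(flipped$sigma_ei, sc$sigma_ei)
  expect_equal(flipped$sigma_ui, sc$sigma_ui)
  expect_equal(flipped$n_negative, 1L)

  two <- scale_deviations(c(50, 200), cv = 0.1, h2 = 0.25)
  expect_equal(two$sigma_pi, c(5, 20))
  expect_equal(two$sigma_ei, c(5, 20) * sqrt(0.75))
  expect_equal(two$sigma_ui, c(5, 20) * 0.5)

  expect_error(scale_deviations(c(1, 0), 0.1, 0.5), class = "scalefx_domain_error")
})

test_that("the residual-only convention keeps record signs outside sigma_ei", {
  sc <- scale_deviations(c(-100, 100), cv = 0.2, h2 = 0.25,
                         negative_handling = "residual")
  expect_equal(sc$sigma_pi, c(-20, 20))
  expect_equal(sc$sigma_ei, c(20, 20) * sqrt(0.75))
  expect_equal(sc$sigma_ui, c(-10, 10))
  expect_equal(sc$n_negative, 1L)
})

test_that("environmental breeding values are 2 r log-ratios", {
  expect_equal(environmental_breeding_values(rep(4, 3), 4, r = 1), rep(0, 3))
  expect_equal(environmental_breeding_values(rep(4, 3), 4, r = 0.3), rep(0, 3))
  expect_equal(environmental_breeding_values(4 * exp(1), 4, r = 0.5), 1)

  sigma_ei <- c(1.3, 5, 0.2)
  expect_equal(environmental_breeding_values(sigma_ei, 2, r = 0.4),
               0.5 * environmental_breeding_values(sigma_ei, 2, r = 0.8))
  expect_error(environmental_breeding_values(c(1, -1), 2), class = "scalefx_domain_error")
  expect_error(environmental_breeding_values(1, 2, r = 1.5), class = "scalefx_domain_error")
})

test_that("trait breeding values rescale by the local variance ratio", {
  a <- c(-1, 0, 2.5)
  expect_equal(rescale_trait_breeding_values(a, rep(3, 3), 3), a)
  expect_equal(rescale_trait_breeding_values(2, 6, 3), 4)
  expect_equal(rescale_trait_breeding_values(rep(0, 4), 1:4, 2), rep(0, 4))
  expect_error(rescale_trait_breeding_values(1:2, 1:3, 1), class = "scalefx_domain_error")
  expect_error(rescale_trait_breeding_values(1, 1, 0), class = "scalefx_domain_error")
})

test_that("correlation and GCV summaries behave on edge cases", {
  x <- c(1, 4, 2, 8)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_error(pearson_correlation(rep(1, 4), x), class = "scalefx_domain_error")
  expect_error(pearson_correlation(x, 1:3), class = "scalefx_domain_error")

  expect_equal(gcv_from_v(rep(0.2, 10)), 0)
  w <- rnorm(50)
  expect_equal(gcv_from_v(3 * w), 3 * gcv_from_v(w))
  expect_error(gcv_from_v(0.5), class = "scalefx_domain_error")
})

test_that("the zero-deviate chain collapses to the homogeneous components", {
  cfg <- small_config(cv = 0.15, h2 = 0.15, n = 10L)
  pop <- simulate_population(cfg, z_a = rep(0, 10), z_e = rep(0, 10))
  vc <- derive_variance_components(cfg$mu, cfg$cv, cfg$h2)
  expect_equal(pop$y, rep(100, 10))
  expect_equal(pop$sigma_ei, rep(vc$sigma_e, 10))
  expect_equal(pop$sigma_ui, rep(vc$sigma_u, 10))
  expect_equal(pop$v, rep(0, 10))
  expect_equal(pop$u, pop$a)
  expect_identical(attr(pop, "n_negative"), 0L)
})

test_that("v vanishes where |y| equals the mean", {
  cfg <- small_config(cv = 0.3, h2 = 0.4, n = 4L)
  z_e <- c(0, -2 / 0.3 / sqrt(1 - 0.4), 1, -1)  # second record hits y = -mu
  pop <- simulate_population(cfg, z_a = rep(0, 4), z_e = z_e)
  expect_equal(pop$y[1], 100)
  expect_equal(pop$y[2], -100)
  expect_equal(pop$v[1:2], c(0, 0))
})

test_that("rho and gcv are invariant to mu on shared deviates", {
  set.seed(5)
  n <- 5000L
  z_a <- rnorm(n)
  z_e <- rnorm(n)
  summaries <- lapply(c(1, 100, 3.7), function(mu) {
    cfg <- scenario_config(cv = 0.2, h2 = 0.3, mu = mu, n_individuals = n)
    pop <- simulate_population(cfg, z_a, z_e)
    c(rho = pearson_correlation(pop$u, pop$v), gcv = gcv_from_v(pop$v))
  })
  for (s in summaries[-1]) {
    expect_equal(s[["rho"]], summaries[[1]][["rho"]], tolerance = 1e-10)
    expect_equal(s[["gcv"]], summaries[[1]][["gcv"]], tolerance = 1e-10)
  }
})

test_that("gcv is h2-invariant in distribution on shared deviates", {
  # the a/e split re-weights the shared deviates, so per-sample values agree
  # only to Monte-Carlo precision, not bitwise
  set.seed(6)
  n <- 20000L
  z_a <- rnorm(n)
  z_e <- rnorm(n)
  gcvs <- vapply(c(0.1, 0.3, 0.5, 0.9), function(h2) {
    cfg <- scenario_config(cv = 0.15, h2 = h2, n_individuals = n)
    gcv_from_v(simulate_population(cfg, z_a, z_e)$v)
  }, numeric(1))
  expect_lt(max(gcvs) / min(gcvs) - 1, 0.02)
})
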