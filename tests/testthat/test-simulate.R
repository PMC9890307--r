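test_that("generators are reproducible under a fixed seed", {
  cfg <- sim_config(seed = 11, grid_shape = c(24, 24),
                    covariate_lengthscale = 3)
  s1 <- simulate_covariates(cfg)
  s2 <- simulate_covariates(cfg)
  expect_identical(lapply(s1$grids, `[[`, "values"),
                   lapply(s2$grids, `[[`, "values"))
  s3 <- simulate_covariates(sim_config(seed = 12, grid_shape = c(24, 24),
                                        covariate_lengthscale = 3))
  expect_false(identical(s1$grids[[1]]$values, s3$grids[[1]]$values))

  l1 <- simulate_landscape(cfg)
  l2 <- simulate_landscape(cfg)
  expect_identical(l1$survey, l2$survey)
  expect_identical(l1$prevalence$values, l2$prevalence$values)
})

test_that("zero kernel length-scale yields white noise", {
  cfg <- sim_config(seed = 2, grid_shape = c(200, 200), n_covariates = 1,
                    covariate_lengthscale = 0)
  v <- simulate_covariates(cfg)$grids[[1]]$values
  lag1 <- cor(as.vector(v[, -1]), as.vector(v[, -200]))
  expect_lt(abs(lag1), 0.02)
  expect_error(simulate_covariates(
    sim_config(seed = 1, grid_shape = c(10, 10), covariate_lengthscale = 6)),
    "too small")
})

test_that("the latent spatial field carries the exponential covariance", {
  ## empirical covariance over replicate fields vs sigma2 * exp(-d/phi)
  tmpl <- grid_create(matrix(0, 25, 25))
  reps <- 200
  prods4 <- prods8 <- vars <- numeric(reps)
  podomap:::with_seed(42, {
    for (r in seq_len(reps)) {
      S <- podomap:::simulate_exp_gp(tmpl, sigma2 = 1, phi = 4)$values
      vars[r] <- (S[13, 13]^2 + S[5, 20]^2) / 2
      prods4[r] <- (S[13, 13] * S[13, 17] + S[5, 20] * S[9, 20]) / 2
      prods8[r] <- (S[13, 13] * S[13, 21] + S[5, 20] * S[13, 20]) / 2
    }
  })
  expect_equal(mean(vars), 1, tolerance = 0.15)
  expect_equal(mean(prods4), exp(-1), tolerance = 0.25)
  expect_equal(mean(prods8), exp(-2), tolerance = 0.6)
})

test_that("degenerate truth collapses prevalence to a constant", {
  cfg <- sim_config(seed = 3, grid_shape = c(20, 20),
                    covariate_lengthscale = 2, geostat_truth = list(alpha = -3, beta = 0, sigma2 = 1e-12,
                                         phi = 3, tau2 = 0))
  fl <- simulate_prevalence_field(simulate_covariates(cfg), cfg)
  expect_equal(max(abs(fl$prevalence$values - plogis(-3))), 0,
               tolerance = 1e-5)
  expect_true(all(fl$prevalence$values > 0 & fl$prevalence$values < 1))
  expect_true(all(fl$suitability$values >= 0 & fl$suitability$values <= 1))
})

test_that("survey sampling respects the prevalence surface", {
  cfg0 <- sim_config(seed = 4, grid_shape = c(20, 20), n_villages = 50,
                     geostat_truth = list(alpha = 0, beta = 0, sigma2 = 1,
                                          phi = 3, tau2 = 0))
  zero <- grid_create(matrix(0, 20, 20))
  one <- grid_create(matrix(1, 20, 20))
  expect_true(all(sample_survey(zero, cfg0)$n_cases == 0))
  sv1 <- sample_survey(one, cfg0)
  expect_true(all(sv1$n_cases == sv1$n_examined))
  expect_true(all(sv1$endemic == 1))

  cfg <- sim_config(seed = 5, grid_shape = c(20, 20), n_villages = 200,
                    examined_range = c(1000L, 1000L),
                    geostat_truth = list(alpha = 0, beta = 0, sigma2 = 1,
                                         phi = 3, tau2 = 0))
  sv <- sample_survey(grid_create(matrix(0.3, 20, 20)), cfg)
  pooled <- sum(sv$n_cases) / sum(sv$n_examined)
  se <- sqrt(0.3 * 0.7 / sum(sv$n_examined))
  expect_lt(abs(pooled - 0.3), 3 * se)

  tiny <- sim_config(seed = 6, grid_shape = c(4, 4), n_villages = 17)
  expect_error(sample_survey(grid_create(matrix(0.5, 4, 4)), tiny),
               "exceeds available cells")
})

test_that("population and admin generators partition the grid", {
  cfg1 <- sim_config(seed = 7, grid_shape = c(18, 18), n_admin = 1,
                     covariate_lengthscale = 2)
  pa1 <- simulate_population_and_admin(cfg1)
  expect_true(all(pa1$admin$values == 1))

  cfg <- sim_config(seed = 8, grid_shape = c(18, 18), n_admin = 6,
                    covariate_lengthscale = 2)
  pa <- simulate_population_and_admin(cfg)
  expect_setequal(unique(as.vector(pa$admin$values)), 1:6)
  expect_true(all(pa$population$values >= 0))
  expect_true(all(pa$adult_fraction$values >= 0 &
                    pa$adult_fraction$values <= 1))
  by_admin <- tapply(pa$population$values, pa$admin$values, sum)
  expect_equal(sum(by_admin), sum(pa$population$values))

  expect_error(simulate_population_and_admin(
    sim_config(seed = 9, grid_shape = c(3, 3), n_admin = 10)),
    "exceeds number of cells")
})

test_that("hydrology-derived covariates slot into the stack", {
  cfg <- sim_config(seed = 10, grid_shape = c(30, 30),
                    covariate_lengthscale = 3)
  stack <- simulate_hydro_covariates(simulate_covariates(cfg), cfg)
  expect_setequal(stack$names, podomap:::covariate_names(7))
  expect_true(grids_aligned(stack$grids$dist_water, stack$grids$flow_accum))
})
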