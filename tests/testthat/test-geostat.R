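test_that("exponential correlation has its closed form and monotonicity", {
  expect_equal(exp_correlation(0, 2), 1)
  expect_equal(exp_correlation(2, 2), exp(-1))
  u <- seq(0, 10, by = 0.5)
  expect_true(all(diff(exp_correlation(u, 3)) < 0))
  expect_error(exp_correlation(-1, 2), "non-negative")
  expect_error(exp_correlation(1, 0), "positive")
})

test_that("without spatial structure the fit reduces to logistic regression", {
  fx <- flat_survey(seed = 41, n_villages = 200)
  sv <- fx$survey
  s <- extract_at_points(grid_stack(list(s = fx$suitability)), sv)$s

  glm_fit <- glm(cbind(n_cases, n_examined - n_cases) ~ s,
                 family = binomial(), data = sv)
  fit0 <- fit_geostat(sv, fx$suitability,
                      opts = list(fix = list(sigma2 = 0, tau2 = 0)))
  expect_equal(fit0$estimate$alpha, unname(coef(glm_fit)[1]))
  expect_equal(fit0$estimate$beta, unname(coef(glm_fit)[2]))

  ## the full (Laplace) fit lands near the truth and near the glm
  fit <- fit_geostat(sv, fx$suitability, opts = list(method = "laplace"))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate$alpha - (-4.5)), 2 * fit$se$alpha + 0.2)
  expect_lt(abs(fit$estimate$beta - 2), 2 * fit$se$beta + 0.2)
  expect_lt(fit$estimate$sigma2 + fit$estimate$tau2, 0.3)
})

test_that("constraining beta to zero on beta-free data barely moves the likelihood", {
  cfg <- sim_config(seed = 42, grid_shape = c(30, 30), n_villages = 120,
                    examined_range = c(150L, 250L),
                    covariate_lengthscale = 3,
                    geostat_truth = list(alpha = -4, beta = 0, sigma2 = 0.5,
                                         phi = 4, tau2 = 0))
  stack <- simulate_covariates(cfg)
  fl <- simulate_prevalence_field(stack, cfg)
  sv <- sample_survey(fl$prevalence, cfg)
  free <- fit_geostat(sv, fl$suitability, opts = list(method = "laplace",
                                                      fix = list(tau2 = 0)))
  null <- fit_geostat(sv, fl$suitability,
                      opts = list(method = "laplace",
                                  fix = list(beta = 0, tau2 = 0)))
  lrt <- 2 * (free$loglik - null$loglik)
  expect_gte(lrt, -0.2)              # numerical slack on nested optima
  expect_lt(lrt, qchisq(0.999, 1))   # consistent with a chi-square(1) draw
})

test_that("village records with at least twenty rows and clean inputs are enforced", {
  fx <- flat_survey(seed = 43, n_villages = 100)
  expect_error(fit_geostat(fx$survey[1:10, ], fx$suitability),
               "at least 20")
  dup <- fx$survey
  dup$x[2] <- dup$x[1]; dup$y[2] <- dup$y[1]
  expect_error(fit_geostat(dup, fx$suitability), "duplicate")
})

test_that("prediction surfaces are internally consistent", {
  cfg <- sim_config(seed = 44, grid_shape = c(30, 30), n_villages = 80,
                    examined_range = c(100L, 200L),
                    covariate_lengthscale = 3,
                    geostat_truth = list(alpha = -4, beta = 2, sigma2 = 0.5,
                                         phi = 4, tau2 = 0))
  stack <- simulate_covariates(cfg)
  fl <- simulate_prevalence_field(stack, cfg)
  sv <- sample_survey(fl$prevalence, cfg)
  fit <- fit_geostat(sv, fl$suitability, opts = list(method = "laplace",
                                                     fix = list(tau2 = 0)))
  pred <- predict_surface(fit, fl$suitability, limits = NULL, n_sim = 400,
                          threshold = 0.01, keep_draws = TRUE, seed = 4)
  cells <- pred$cells
  expect_true(all(pred$lower95$values[cells] <= pred$mean_prev$values[cells]))
  expect_true(all(pred$upper95$values[cells] >= pred$mean_prev$values[cells]))
  expect_true(all(pred$mean_prev$values[cells] >= 0 &
                    pred$mean_prev$values[cells] <= 1))
  ## exceedance equals one minus the empirical cdf of the stored draws
  expect_equal(pred$exceedance$values[cells],
               rowMeans(pred$draws > 0.01))
  ## threshold zero is exceeded by every draw
  pred0 <- predict_surface(fit, fl$suitability, n_sim = 150, threshold = 0,
                           seed = 4)
  expect_true(all(pred0$exceedance$values[pred0$cells] == 1))
  expect_error(predict_surface(fit, fl$suitability, n_sim = 50), "100")
})

test_that("prediction shrinks toward a co-located precise observation", {
  ## a village with 0 cases out of many at a known cell, no nugget: the
  ## predicted prevalence there must be near zero
  fx <- flat_survey(seed = 45, n_villages = 60)
  sv <- fx$survey
  sv$n_examined[1] <- 5000L
  sv$n_cases[1] <- 0L
  fit <- fit_geostat(sv, fx$suitability, opts = list(method = "laplace",
                                                     fix = list(tau2 = 0)))
  pred <- predict_surface(fit, fx$suitability, n_sim = 500, seed = 5)
  rc <- podomap:::point_to_cell(fx$suitability, sv$x[1], sv$y[1])
  m <- pred$mean_prev$values[rc$row, rc$col]
  expect_lt(m, 0.01)
  expect_lt(pred$exceedance$values[rc$row, rc$col], 0.2)
})

test_that("the fit is invariant to the ordering of village records", {
  fx <- flat_survey(seed = 46, n_villages = 80)
  fit1 <- fit_geostat(fx$survey, fx$suitability,
                      opts = list(method = "laplace"))
  perm <- podomap:::with_seed(1, sample(nrow(fx$survey)))
  fit2 <- fit_geostat(fx$survey[perm, ], fx$suitability,
                      opts = list(method = "laplace"))
  expect_equal(fit1$estimate$alpha, fit2$estimate$alpha, tolerance = 1e-3)
  expect_equal(fit1$estimate$beta, fit2$estimate$beta, tolerance = 1e-3)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-5)
})

test_that("the Monte Carlo likelihood prefers the truth to gross perturbations", {
  cfg <- sim_config(seed = 47, grid_shape = c(30, 30), n_villages = 120,
                    examined_range = c(150L, 250L),
                    covariate_lengthscale = 3,
                    geostat_truth = list(alpha = -4, beta = 2, sigma2 = 0.8,
                                         phi = 4, tau2 = 0.05))
  stack <- simulate_covariates(cfg)
  fl <- simulate_prevalence_field(stack, cfg)
  sv <- sample_survey(fl$prevalence, cfg)
  y <- sv$n_cases; n <- sv$n_examined
  s <- extract_at_points(grid_stack(list(s = fl$suitability)), sv)$s
  D <- as.matrix(dist(cbind(sv$x, sv$y)))
  truth <- c(-4, 2, log(0.8), log(4), log(0.05))
  mc <- podomap:::make_mcml_loglik(truth, y, n, s, D, m = 300, seed = 6)
  l_truth <- mc$loglik(truth)
  l_phi <- mc$loglik(truth + c(0, 0, 0, log(2), 0))     # 2x phi
  l_sig <- mc$loglik(truth + c(0, 0, log(4), 0, 0))     # 4x sigma2
  expect_gt(l_truth, l_phi)
  expect_gt(l_truth, l_sig)
})

test_that("variogram validation flags spatial residual structure and not its absence", {
  fx <- flat_survey(seed = 48, n_villages = 100)
  fit <- fit_geostat(fx$survey, fx$suitability,
                     opts = list(fix = list(sigma2 = 0, tau2 = 0)))
  vg <- variogram_validate(fit, n_perm = 199, seed = 2)
  expect_true(vg$pass)
  expect_true(nrow(vg$variogram) >= 2)
  expect_equal(nrow(vg$envelope), nrow(vg$variogram))
  expect_error(variogram_validate(fit, n_perm = 0), "n_perm")

  cfg <- sim_config(seed = 49, grid_shape = c(30, 30), n_villages = 100,
                    examined_range = c(150L, 250L),
                    covariate_lengthscale = 3,
                    geostat_truth = list(alpha = -4, beta = 0.5, sigma2 = 2,
                                         phi = 6, tau2 = 0))
  stack <- simulate_covariates(cfg)
  fl <- simulate_prevalence_field(stack, cfg)
  sv <- sample_survey(fl$prevalence, cfg)
  fit_ns <- fit_geostat(sv, fl$suitability,
                        opts = list(fix = list(sigma2 = 0, tau2 = 0)))
  vg_ns <- variogram_validate(fit_ns, n_perm = 199, seed = 3)
  expect_false(vg_ns$pass)
})
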