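test_that("covariate screening drops correlated duplicates", {
  stack <- make_test_stack(25, 25, k = 3, seed = 31)
  dup <- stack$grids[[1]]
  stack4 <- grid_stack(c(stack$grids, list(dup1 = dup)))
  scr <- screen_covariates(stack4, NULL, cut = 0.8)
  expect_length(scr$retained, 3)
  expect_true(xor("dup1" %in% scr$retained,
                  stack$names[1] %in% scr$retained))

  indep <- screen_covariates(stack, NULL, cut = 0.8)
  expect_setequal(indep$retained, stack$names)

  ## brute force over the correlation matrix agrees on the retained count
  M <- podomap:::stack_matrix(stack4)
  cm <- abs(cor(M))
  diag(cm) <- 0
  expect_equal(length(scr$retained),
               ncol(M) - sum(apply(upper.tri(cm) & cm > 0.8, 1, any)))
  cstack <- grid_stack(list(a = grid_create(matrix(1, 5, 5)),
                            b = grid_create(matrix(2, 5, 5))))
  expect_error(screen_covariates(cstack, NULL), "constant")
})

test_that("runs cross pseudoabsence sets with stratified seeded splits", {
  land <- threshold_landscape(seed = 32, n_points = 100)
  pres <- land$values[land$labels == 1, ]
  abs1 <- land$values[land$labels == 0, ]
  pa <- lapply(1:5, function(i) abs1[sample(nrow(abs1), 30), ])
  runs <- make_runs(pres, NULL, pa, n_splits = 10, seed = 7)
  expect_length(runs, 50)
  expect_equal(max(vapply(runs, `[[`, 0, "pa_set")), 5)
  r <- runs[[13]]
  n_total <- nrow(pres) + 30
  expect_equal(nrow(r$train) + nrow(r$test), n_total)
  expect_true(all(c(0, 1) %in% r$train$label))
  expect_true(all(c(0, 1) %in% r$test$label))
  runs2 <- make_runs(pres, NULL, pa, n_splits = 10, seed = 7)
  expect_identical(lapply(runs, `[[`, "train"), lapply(runs2, `[[`, "train"))
})

test_that("rank AUC matches the all-pairs oracle on every random instance", {
  expect_equal(auc_mw(c(0.9, 0.7, 0.7, 0.2), c(1, 1, 0, 0)), 0.875)
  expect_equal(auc_mw(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(auc_mw(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_error(auc_mw(1:3, c(1, 1, 1)), "both classes")
  podomap:::with_seed(33, {
    for (i in 1:10) {
      n <- sample(10:200, 1)
      scores <- round(runif(n), 2)   # ties likely
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      expect_equal(auc_mw(scores, labels), brute_auc(scores, labels))
    }
  })
  skip_if_not_installed("pROC")
  sc <- c(0.9, 0.7, 0.7, 0.2, 0.4, 0.8)
  lb <- c(1, 1, 0, 0, 1, 0)
  expect_equal(auc_mw(sc, lb),
               as.numeric(pROC::auc(lb, sc, quiet = TRUE, direction = "<")))
})

test_that("learners separate a threshold landscape and degrade to chance on noise", {
  land <- threshold_landscape(seed = 34, n_points = 240)
  df <- cbind(label = land$labels, land$values)
  df$weight <- 1
  tr <- df[1:180, ]; te <- df[181:240, ]
  for (kind in c("glm", "brt", "rf")) {
    m <- fit_learner(kind, tr, list(seed = 1, max_trees = 500))
    expect_gte(evaluate(m, te)$auc, 0.85)
  }
  ## separable toy: training AUC is exactly 1
  toy <- data.frame(label = rep(c(0, 1), each = 20),
                    x = c(rnorm(20, -3), rnorm(20, 3)))
  mg <- fit_learner("glm", toy)
  expect_equal(auc_mw(predict(mg, toy), toy$label), 1)

  ## labels independent of covariates: test AUC near one half
  noise <- podomap:::with_seed(35, data.frame(
    label = rbinom(2000, 1, 0.5), a = rnorm(2000), b = rnorm(2000)))
  mn <- fit_learner("glm", noise[1:1000, ])
  expect_lt(abs(evaluate(mn, noise[1001:2000, ])$auc - 0.5), 0.06)
})

test_that("boosted trees beat the linear model on a pure interaction", {
  xor_data <- podomap:::with_seed(36, {
    n <- 1200
    a <- rnorm(n); b <- rnorm(n)
    p <- plogis(6 * sign(a) * sign(b))
    data.frame(label = rbinom(n, 1, p), a = a, b = b)
  })
  tr <- xor_data[1:900, ]; te <- xor_data[901:1200, ]
  m_glm <- fit_learner("glm", tr)
  m_brt <- fit_learner("brt", tr, list(seed = 2, max_trees = 1500))
  expect_gt(evaluate(m_brt, te)$auc, evaluate(m_glm, te)$auc)
  expect_gt(evaluate(m_brt, te)$auc, 0.8)
})

test_that("ensemble weighting reproduces hand-computed means and honours the cut", {
  stack <- grid_stack(list(c1 = grid_create(matrix(0, 2, 2))))
  members <- list(
    c(const_learner(1.0, auc = 0.9), pa_set = 1, split = 1),
    c(const_learner(0.0, auc = 0.8), pa_set = 1, split = 2),
    c(const_learner(0.5, auc = 0.85), pa_set = 2, split = 1))
  ens <- build_ensemble(members, stack, auc_cut = 0.8)
  expect_equal(ens$mean_suitability$values[1, 1],
               (0.9 * 1 + 0.8 * 0 + 0.85 * 0.5) / 2.55)
  expect_equal(ens$n_members_kept, 3)

  ## order invariance
  ens_r <- build_ensemble(rev(members), stack, auc_cut = 0.8)
  expect_equal(ens_r$mean_suitability$values, ens$mean_suitability$values)

  ## raising the cut can only shrink the ensemble, down to a single member
  ens2 <- build_ensemble(members, stack, auc_cut = 0.86)
  expect_equal(ens2$n_members_kept, 1)
  expect_equal(ens2$mean_suitability$values[1, 1], 1)
  expect_equal(ens2$ui_lower$values, ens2$ui_upper$values)
  expect_error(build_ensemble(members, stack, auc_cut = 0.95),
               "best AUC = 0.900")

  two <- list(c(const_learner(0.2, auc = 0.9), pa_set = 1, split = 1),
              c(const_learner(0.8, auc = 0.9), pa_set = 1, split = 2))
  expect_equal(build_ensemble(two, stack, 0.8)$mean_suitability$values[1, 1],
               0.5)
})

test_that("threshold selection maximises TSS with documented tie-breaks", {
  th <- select_threshold(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(th$threshold, 0.8)
  expect_equal(th$sens, 1); expect_equal(th$spec, 1)

  flat <- select_threshold(rep(0.5, 8), rep(c(1, 0), 4))
  expect_equal(flat$threshold, 0.5)
  expect_equal(flat$tss, 0)

  ## presence deterministically above a covariate cut: perfect recovery
  x <- seq(-2, 2, length.out = 60)
  th2 <- select_threshold(plogis(x), as.numeric(x > 0.4))
  expect_equal(th2$sens, 1)
  expect_equal(th2$spec, 1)
  expect_error(select_threshold(1:4, rep(1, 4)), "both classes")
})

test_that("binarize thresholds the surface and propagates missing cells", {
  g <- grid_create(matrix(c(0.1, 0.7, NA, 0.602), 2, 2))
  b <- binarize(g, 0.602)
  expect_equal(b$values, matrix(c(0, 1, NA, 1), 2, 2))
  expect_true(all(binarize(g, 0)$values[!is.na(g$values)] == 1))
  expect_true(all(binarize(grid_create(matrix(0.6, 3, 3)), 0.602)$values == 0))
})

test_that("partial dependence recovers marginal structure", {
  land <- threshold_landscape(seed = 37, n_points = 300)
  df <- cbind(label = land$labels, land$values)
  m <- fit_learner("brt", df, list(seed = 3, max_trees = 600))
  pd1 <- partial_dependence(m, land$stack$names[1], n_grid = 15)
  pd2 <- partial_dependence(m, land$stack$names[2], n_grid = 15)
  expect_gt(cor(pd1$value, pd1$response, method = "spearman"), 0.85)
  expect_lt(diff(range(pd2$response)), 0.5 * diff(range(pd1$response)))
  expect_true(all(pd1$response >= 0 & pd1$response <= 1))
  expect_error(partial_dependence(m, "nope"), "unknown covariate")
})
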