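make_pred <- function(mean, lower = mean, upper = mean) {
  structure(list(mean_prev = mean, lower95 = lower, upper95 = upper),
            class = "prediction_surface")
}

test_that("case surfaces multiply prevalence, population and adult fraction", {
  prev <- grid_create(matrix(0.01, 1, 1))
  pred <- make_pred(prev, grid_create(matrix(0.005, 1, 1)),
                    grid_create(matrix(0.02, 1, 1)))
  cg <- cases_surface(pred, grid_create(matrix(5000, 1, 1)),
                      grid_create(matrix(0.5, 1, 1)))
  expect_equal(cg$mean$values[1, 1], 25)
  expect_equal(cg$lower$values[1, 1], 12.5)
  expect_equal(cg$upper$values[1, 1], 50)

  zero <- make_pred(grid_create(matrix(0, 4, 4)))
  cg0 <- cases_surface(zero, grid_create(matrix(100, 4, 4)),
                       grid_create(matrix(0.6, 4, 4)))
  expect_true(all(cg0$mean$values == 0))

  off <- grid_create(matrix(1, 4, 4), origin_x = 2)
  expect_error(cases_surface(zero, off, off), "not aligned")
})

test_that("population at risk sums over suitable cells", {
  pop <- grid_create(matrix(10, 4, 4))
  none <- grid_create(matrix(0, 4, 4))
  all_s <- grid_create(matrix(1, 4, 4))
  checker <- grid_create(matrix(rep(c(1, 0), 8), 4, 4))
  expect_equal(population_at_risk(pop, none)$total, 0)
  expect_equal(population_at_risk(pop, all_s)$total, 160)
  expect_equal(population_at_risk(pop, checker)$total, 80)
})

test_that("suitable area converts cell counts to area and percent", {
  m <- matrix(0, 25, 40)            # 1000 cells
  m[sample(1000, 42)] <- 1
  sa <- suitable_area(grid_create(m), cell_area = 1)
  expect_equal(sa$area_km2, 42)
  expect_equal(sa$fraction_pct, 4.2)
  expect_equal(suitable_area(grid_create(matrix(1, 3, 3)))$fraction_pct, 100)
  expect_equal(suitable_area(grid_create(matrix(0, 3, 3)))$area_km2, 0)
})

test_that("published regional burden rows aggregate to the published totals", {
  tab <- read.csv(system.file("extdata", "kenya_region_burden.csv",
                              package = "podomap"))
  tot <- burden_totals(tab)
  expect_equal(tot$cases_mean, 9344)
  expect_equal(tot$cases_lower, 4222)
  expect_equal(tot$cases_upper, 17962)
  expect_equal(tot$suitable_area_km2, 24405)
  expect_equal(tot$population_at_risk, 2239168)
})

test_that("zonal aggregation is additive and respects the limits mask", {
  pop <- grid_create(matrix(100, 6, 6))
  af <- grid_create(matrix(0.5, 6, 6))
  admin <- grid_create(matrix(rep(1:3, each = 12), 6, 6))
  limits <- grid_create(matrix(rep(c(1, 0), 18), 6, 6))
  prev <- grid_create(matrix(0.02, 6, 6))
  pred <- make_pred(prev)
  cg <- cases_surface(pred, pop, af)
  tab <- aggregate_by_admin(cg, pop, limits, admin)
  rows <- tab[tab$admin_id != "total", ]
  tot <- tab[tab$admin_id == "total", ]
  for (col in c("suitable_area_km2", "population_at_risk", "cases_mean",
                "cases_lower", "cases_upper"))
    expect_equal(tot[[col]], sum(rows[[col]]))
  expect_equal(tot$population_at_risk, 100 * 18)
  expect_equal(tot$cases_mean, 0.02 * 100 * 0.5 * 18)

  ## a single admin unit: its row equals the totals row
  one <- grid_create(matrix(1, 6, 6))
  tab1 <- aggregate_by_admin(cg, pop, limits, one)
  expect_equal(unlist(tab1[1, -1]), unlist(tab1[2, -1]))

  ## enlarging the mask never shrinks population at risk or area
  bigger <- grid_create(matrix(1, 6, 6))
  tab2 <- aggregate_by_admin(cg, pop, bigger, admin)
  expect_true(all(tab2$population_at_risk >= tab$population_at_risk))
  expect_true(all(tab2$suitable_area_km2 >= tab$suitable_area_km2))

  holes <- grid_create(matrix(c(NA, rep(1, 35)), 6, 6))
  expect_error(aggregate_by_admin(cg, pop, limits, holes), "missing admin")
})

test_that("interval ordering propagates from surfaces to aggregates", {
  nr <- 5
  lo <- grid_create(matrix(runif(nr^2, 0, 0.01), nr, nr))
  mid <- grid_create(lo$values + runif(nr^2, 0, 0.01))
  hi <- grid_create(mid$values + runif(nr^2, 0, 0.01))
  pred <- make_pred(mid, lo, hi)
  pop <- grid_create(matrix(200, nr, nr))
  af <- grid_create(matrix(0.55, nr, nr))
  admin <- grid_create(matrix(rep(1:5, 5), nr, nr))
  limits <- grid_create(matrix(1, nr, nr))
  tab <- aggregate_by_admin(cases_surface(pred, pop, af), pop, limits, admin)
  expect_true(all(tab$cases_lower <= tab$cases_mean + 1e-12))
  expect_true(all(tab$cases_mean <= tab$cases_upper + 1e-12))
})

test_that("crude prevalence reproduces the published pooled estimate", {
  sv <- data.frame(n_cases = c(10, 6), n_examined = c(3000, 3228))
  cp <- crude_prevalence(sv)
  expect_equal(cp$cases, 16)
  expect_equal(cp$examined, 6228)
  expect_equal(cp$percent, 0.3)
  expect_lt(cp$ci_lower, 16 / 6228)
  expect_gt(cp$ci_upper, 16 / 6228)
  expect_equal(crude_prevalence(data.frame(n_cases = 0,
                                           n_examined = 500))$percent, 0)
  expect_equal(crude_prevalence(data.frame(n_cases = 50,
                                           n_examined = 100))$percent, 50)
  expect_error(crude_prevalence(data.frame(n_cases = 0, n_examined = 0)),
               "zero participants")
})
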