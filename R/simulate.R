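#' Configuration for the synthetic landscape generator
#'
#' Bundles every knob of the synthetic world: grid geometry, covariate
#' autocorrelation, the logit-linear suitability coefficients, the
#' geostatistical truth (intercept, suitability effect, partial sill, range,
#' nugget), the survey design and the administrative partition. Defaults
#' emulate a national mapping survey of a rare, environmentally limited
#' disease: 48 villages with 44-311 examined each, logit intercept -6 and
#' suitability effect +4 so villages carry mostly 0-4 cases.
#'
#' @param seed integer RNG seed; every generator derives its stream from it.
#' @param grid_shape integer (rows, cols).
#' @param cell_size cell edge in km.
#' @param n_covariates number of environmental layers (default 7).
#' @param covariate_lengthscale Gaussian smoothing length-scale of the
#'   covariate fields, in cells (0 = white noise).
#' @param suitability_coefs logit-scale coefficients of the standardised
#'   covariates in the true suitability surface; recycled/truncated to
#'   `n_covariates`.
#' @param suitability_intercept logit-scale intercept of the suitability
#'   surface. The default (-2.5) keeps most of the landscape unsuitable with
#'   a suitable minority, so that with `alpha = -6`, `beta = 4` a survey of
#'   48 villages yields a handful of endemic villages with low counts, as in
#'   a national mapping survey of a rare environmentally limited disease.
#' @param geostat_truth named list `alpha`, `beta`, `sigma2`, `phi`, `tau2`:
#'   prevalence logit = alpha + beta * suitability + S(x) + village nugget,
#'   with S a stationary Gaussian process, covariance
#'   `sigma2 * exp(-d / phi)`. `phi` defaults to 0.15 * grid width (km).
#' @param n_villages number of surveyed villages (>= 10).
#' @param examined_range integer (min, max) examined per village.
#' @param n_admin number of administrative units.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       grid_shape = c(60L, 60L),
                       cell_size = 1,
                       n_covariates = 7L,
                       covariate_lengthscale = 6,
                       suitability_coefs = c(1.2, -0.9, 0.9, -0.6, 0.45,
                                             0.3, 0.15),
                       suitability_intercept = -2.5,
                       geostat_truth = list(alpha = -6, beta = 4, sigma2 = 1,
                                            phi = NULL, tau2 = 0.1),
                       n_villages = 48L,
                       examined_range = c(44L, 311L),
                       n_admin = 8L) {
  if (is.null(geostat_truth$phi))
    geostat_truth$phi <- 0.15 * grid_shape[2L] * cell_size
  stopifnot(geostat_truth$sigma2 > 0, geostat_truth$phi > 0,
            geostat_truth$tau2 >= 0,
            examined_range[1L] >= 1L, examined_range[1L] <= examined_range[2L],
            n_villages >= 10L, n_covariates >= 1L, all(grid_shape >= 2L))
  coefs <- rep_len(suitability_coefs, n_covariates)
  structure(list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
                 cell_size = cell_size, n_covariates = as.integer(n_covariates),
                 covariate_lengthscale = covariate_lengthscale,
                 suitability_coefs = coefs,
                 suitability_intercept = suitability_intercept,
                 geostat_truth = geostat_truth,
                 n_villages = as.integer(n_villages),
                 examined_range = as.integer(examined_range),
                 n_admin = as.integer(n_admin)),
            class = "sim_config")
}

## canonical layer names for the default 7-covariate world
covariate_names <- function(k) {
  base <- c("temp_wet_quarter", "precip_cold_quarter", "iron_content",
            "orthent_prob", "dist_water", "flow_accum", "nightlights")
  if (k <= length(base)) base[seq_len(k)]
  else c(base, paste0("cov", seq_len(k - length(base)) + length(base)))
}

#' Simulate spatially autocorrelated environmental covariates
#'
#' Each layer is a Gaussian random field built by circular FFT convolution of
#' white noise with a Gaussian kernel of the configured length-scale, then
#' standardised. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a [grid_stack()] of `cfg$n_covariates` layers.
#' @export
simulate_covariates <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nr <- cfg$grid_shape[1L]; nc <- cfg$grid_shape[2L]
  with_seed(cfg$seed + 101L, {
    grids <- lapply(seq_len(cfg$n_covariates), function(i)
      grid_create(smoothed_field(nr, nc, cfg$covariate_lengthscale),
                  cell_size = cfg$cell_size))
    grid_stack(grids, covariate_names(cfg$n_covariates))
  })
}

#' Replace layers with hydrology-derived covariates
#'
#' Rebuilds the `dist_water` and `flow_accum` layers of a simulated stack
#' from an auxiliary smooth elevation field, using the package's own distance
#' transform and D8 flow accumulation, so the raster derivations are
#' exercised end to end. Water bodies are the lowest decile of a smooth
#' field; flow accumulation is log1p-standardised.
#'
#' @param stack covariate stack from [simulate_covariates()].
#' @param cfg the same [sim_config()].
#' @return the stack with the two layers replaced (when present).
#' @export
simulate_hydro_covariates <- function(stack, cfg) {
  stopifnot(is_stack(stack), inherits(cfg, "sim_config"))
  nr <- cfg$grid_shape[1L]; nc <- cfg$grid_shape[2L]
  with_seed(cfg$seed + 107L, {
    if ("dist_water" %in% stack$names) {
      wf <- smoothed_field(nr, nc, cfg$covariate_lengthscale)
      water <- grid_create((wf <= stats::quantile(wf, 0.1)) * 1,
                           cell_size = cfg$cell_size)
      d <- distance_to_features(water)
      d$values <- (d$values - mean(d$values)) / stats::sd(as.vector(d$values))
      stack$grids[["dist_water"]] <- d
    }
    if ("flow_accum" %in% stack$names) {
      dem <- grid_create(smoothed_field(nr, nc, cfg$covariate_lengthscale),
                         cell_size = cfg$cell_size)
      acc <- flow_accumulation(flow_direction(dem))
      a <- log1p(acc$values)
      acc$values <- (a - mean(a)) / max(stats::sd(as.vector(a)), 1e-12)
      stack$grids[["flow_accum"]] <- acc
    }
  })
  stack
}

## exact stationary exponential-covariance GRF on the grid of `template`.
## Dense Cholesky for small grids, 2-D circulant embedding otherwise.
simulate_exp_gp <- function(template, sigma2, phi, chol_max_cells = 2500L) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  h <- template$cell_size
  n <- nr * nc
  if (n <= chol_max_cells) {
    cc <- grid_cell_centres(template)
    xy <- cbind(rep(cc$x, each = nr), rep(cc$y, times = nc))
    d <- as.matrix(stats::dist(xy))
    K <- sigma2 * exp(-d / phi)
    L <- tryCatch(chol(K + diag(1e-10 * sigma2, n)),
                  error = function(e) stop(
                    "covariance construction is not positive definite: ",
                    conditionMessage(e)))
    s <- as.vector(t(L) %*% stats::rnorm(n))
    return(grid_create(matrix(s, nr, nc), template$origin_x,
                       template$origin_y, h, template$nodata))
  }
  ## circulant embedding on a torus, padding doubled until the spectrum is
  ## (numerically) non-negative
  mfac <- 2L
  repeat {
    M <- stats::nextn(mfac * nr, c(2L, 3L)); N <- stats::nextn(mfac * nc, c(2L, 3L))
    di <- pmin(seq_len(M) - 1, M - (seq_len(M) - 1)) * h
    dj <- pmin(seq_len(N) - 1, N - (seq_len(N) - 1)) * h
    covmat <- sigma2 * exp(-sqrt(outer(di^2, dj^2, `+`)) / phi)
    lambda <- Re(stats::fft(covmat))
    tol <- 1e-8 * max(lambda)
    if (min(lambda) > -tol || mfac >= 16L) break
    mfac <- mfac * 2L
  }
  if (min(lambda) < -1e-8 * max(lambda))
    stop("covariance construction is not positive definite: ",
         "circulant embedding has negative eigenvalues at maximum padding")
  lambda[lambda < 0] <- 0
  z <- matrix(complex(real = stats::rnorm(M * N),
                      imaginary = stats::rnorm(M * N)), M, N)
  w <- stats::fft(sqrt(lambda / (M * N)) * z)
  grid_create(matrix(Re(w)[seq_len(nr), seq_len(nc)], nr, nc),
              template$origin_x, template$origin_y, h, template$nodata)
}

#' Simulate the true suitability and prevalence surfaces
#'
#' Suitability is the logistic of the configured linear combination of the
#' (standardised) covariates. Prevalence on the logit scale is
#' `alpha + beta * suitability + S(x)` with S a zero-mean stationary Gaussian
#' process with covariance `sigma2 * exp(-d/phi)`, realised exactly on the
#' grid. The nugget is *not* added here: it is a village-level effect applied
#' by [sample_survey()].
#'
#' @param stack aligned covariate stack.
#' @param cfg a [sim_config()].
#' @return list with grids `suitability` and `prevalence`.
#' @export
simulate_prevalence_field <- function(stack, cfg) {
  stopifnot(is_stack(stack), inherits(cfg, "sim_config"))
  X <- stack_matrix(stack)
  X <- scale(X)
  X[is.nan(X)] <- 0   # constant layers carry no signal
  k <- min(ncol(X), length(cfg$suitability_coefs))
  lin <- (cfg$suitability_intercept %||% 0) +
    as.vector(X[, seq_len(k), drop = FALSE] %*%
                cfg$suitability_coefs[seq_len(k)])
  tmpl <- stack$grids[[1L]]
  nr <- nrow(tmpl$values); nc <- ncol(tmpl$values)
  suit <- grid_create(matrix(expit(lin), nr, nc), tmpl$origin_x,
                      tmpl$origin_y, tmpl$cell_size, tmpl$nodata)
  tr <- cfg$geostat_truth
  S <- with_seed(cfg$seed + 211L,
                 simulate_exp_gp(tmpl, tr$sigma2, tr$phi))
  prev_logit <- tr$alpha + tr$beta * suit$values + S$values
  prev <- grid_create(expit(prev_logit), tmpl$origin_x, tmpl$origin_y,
                      tmpl$cell_size, tmpl$nodata)
  list(suitability = suit, prevalence = prev, spatial_effect = S)
}

#' Draw a village survey from a prevalence surface
#'
#' Samples `n_villages` distinct cells uniformly over valid cells, draws the
#' number examined uniformly in `examined_range`, perturbs each village's
#' prevalence on the logit scale by an independent N(0, tau2) nugget, then
#' draws cases binomially.
#'
#' @param prevalence prevalence grid (values in `[0,1]`).
#' @param cfg a [sim_config()].
#' @return data.frame of village records: `id`, `x`, `y`, `n_examined`,
#'   `n_cases`, `endemic` (1 iff at least one case).
#' @export
sample_survey <- function(prevalence, cfg) {
  stopifnot(is_grid(prevalence), inherits(cfg, "sim_config"))
  v <- prevalence$values
  valid <- which(!is.na(v))
  if (cfg$n_villages > length(valid))
    stop(sprintf("n_villages (%d) exceeds available cells (%d)",
                 cfg$n_villages, length(valid)))
  nr <- nrow(v)
  with_seed(cfg$seed + 307L, {
    cells <- sample(valid, cfg$n_villages)
    rows <- ((cells - 1L) %% nr) + 1L
    cols <- ((cells - 1L) %/% nr) + 1L
    x <- prevalence$origin_x + (cols - 0.5) * prevalence$cell_size
    y <- prevalence$origin_y - (rows - 0.5) * prevalence$cell_size
    n_ex <- sample(seq(cfg$examined_range[1L], cfg$examined_range[2L]),
                   cfg$n_villages, replace = TRUE)
    lp <- logit(pmin(pmax(v[cells], 0), 1))
    if (cfg$geostat_truth$tau2 > 0)
      lp <- lp + stats::rnorm(cfg$n_villages,
                              sd = sqrt(cfg$geostat_truth$tau2))
    p <- expit(lp)
    cases <- stats::rbinom(cfg$n_villages, n_ex, p)
    data.frame(id = seq_len(cfg$n_villages), x = x, y = y,
               n_examined = n_ex, n_cases = cases,
               endemic = as.integer(cases >= 1L))
  })
}

#' Simulate population, adult fraction and administrative units
#'
#' Population density is log-normal over a smooth field (median about 30
#' persons per cell, heavy right tail); the adult (>= 15 y) fraction is a
#' smooth surface around 0.55; administrative units are the Voronoi cells of
#' `n_admin` seed points (nearest seed, ties to the lowest label), which are
#' contiguous and partition the grid.
#'
#' @param cfg a [sim_config()].
#' @return list of grids `population`, `adult_fraction`, `admin`.
#' @export
simulate_population_and_admin <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nr <- cfg$grid_shape[1L]; nc <- cfg$grid_shape[2L]
  if (cfg$n_admin > nr * nc)
    stop(sprintf("n_admin (%d) exceeds number of cells (%d)",
                 cfg$n_admin, nr * nc))
  with_seed(cfg$seed + 401L, {
    pop <- grid_create(exp(3.4 + 1.1 * smoothed_field(nr, nc,
                                                      cfg$covariate_lengthscale)),
                       cell_size = cfg$cell_size)
    af <- grid_create(expit(0.2 + 0.4 * smoothed_field(nr, nc,
                                                       cfg$covariate_lengthscale)),
                      cell_size = cfg$cell_size)
    seeds <- sample(nr * nc, cfg$n_admin)
    sr <- ((seeds - 1L) %% nr) + 1L
    sc <- ((seeds - 1L) %/% nr) + 1L
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    best <- matrix(Inf, nr, nc); lab <- matrix(0L, nr, nc)
    for (a in seq_len(cfg$n_admin)) {
      d2 <- (rows - sr[a])^2 + (cols - sc[a])^2
      upd <- d2 < best
      best[upd] <- d2[upd]; lab[upd] <- a
    }
    admin <- grid_create(lab, cell_size = cfg$cell_size)
    list(population = pop, adult_fraction = af, admin = admin)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running every generator in order: covariates (with the
#' hydrology-derived layers), true suitability and prevalence surfaces, the
#' village survey, and the population/admin rasters.
#'
#' @param cfg a [sim_config()].
#' @param hydro replace `dist_water`/`flow_accum` with raster-derived layers.
#' @return named list: `config`, `covariates`, `suitability`, `prevalence`,
#'   `spatial_effect`, `survey`, `population`, `adult_fraction`, `admin`.
#' @export
simulate_landscape <- function(cfg = sim_config(), hydro = TRUE) {
  stack <- simulate_covariates(cfg)
  if (hydro) stack <- simulate_hydro_covariates(stack, cfg)
  fields <- simulate_prevalence_field(stack, cfg)
  survey <- sample_survey(fields$prevalence, cfg)
  pa <- simulate_population_and_admin(cfg)
  c(list(config = cfg, covariates = stack), fields,
    list(survey = survey), pa)
}
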