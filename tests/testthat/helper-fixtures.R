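# shared fixtures built in code

# small random covariate stack (independent smooth fields)
make_test_stack <- function(nr = 30, nc = 30, k = 3, seed = 1, ls = 3) {
  cfg <- sim_config(seed = seed, grid_shape = c(nr, nc), n_covariates = k,
                    covariate_lengthscale = ls)
  simulate_covariates(cfg)
}

# brute-force nearest-feature distance (the oracle the fast transform is
# checked against)
brute_distance <- function(mask) {
  v <- mask$values
  fe <- which(v == 1, arr.ind = TRUE)
  out <- v * 0
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
    out[i, j] <- min(sqrt((i - fe[, 1])^2 + (j - fe[, 2])^2)) * mask$cell_size
  out
}

# brute-force flow accumulation: follow every cell's flow path and count
# visits downstream
brute_accumulation <- function(fd) {
  off <- list(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
              dc = c(1, 1, 0, -1, -1, -1, 0, 1))
  v <- fd$values
  cnt <- v * 0
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
    ci <- i; cj <- j
    repeat {
      k <- v[ci, cj]
      if (is.na(k) || k == 0) break
      ci2 <- ci + off$dr[k]; cj2 <- cj + off$dc[k]
      cnt[ci2, cj2] <- cnt[ci2, cj2] + 1
      ci <- ci2; cj <- cj2
    }
  }
  cnt
}

# brute-force all-pairs AUC with half credit for ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# landscape where presence is a (steep-logistic) noisy threshold of the
# first covariate: the setting in which every learner should discriminate
# almost perfectly
threshold_landscape <- function(seed = 1, n_points = 300, nr = 40, nc = 40) {
  stack <- make_test_stack(nr, nc, k = 4, seed = seed)
  c1 <- stack$grids[[1]]$values
  thr <- stats::quantile(c1, 0.7)
  withr_seed <- function(s, code) podomap:::with_seed(s, code)
  withr_seed(seed + 99, {
    cells <- sample(length(c1), n_points)
    p_pres <- stats::plogis(12 * (c1[cells] - thr))
    labels <- stats::rbinom(n_points, 1, p_pres)
    nrr <- nrow(c1)
    rows <- ((cells - 1) %% nrr) + 1
    cols <- ((cells - 1) %/% nrr) + 1
    g <- stack$grids[[1]]
    pts <- data.frame(id = seq_len(n_points),
                      x = g$origin_x + (cols - 0.5) * g$cell_size,
                      y = g$origin_y - (rows - 0.5) * g$cell_size)
    vals <- extract_at_points(stack, pts)[, stack$names]
    list(stack = stack, points = pts, values = vals, labels = labels)
  })
}

# constant-output learner used to test ensemble arithmetic in isolation
const_learner <- function(value, auc) {
  model <- structure(list(value = value, kind = "const",
                          covariates = character()),
                     class = "const_learner")
  list(model = model,
       scores = structure(list(auc = auc, tss = NA_real_, pcc = NA_real_),
                          class = "eval_scores"))
}

predict.const_learner <- function(object, newdata, ...) {
  if (inherits(newdata, "podo_stack")) {
    tmpl <- newdata$grids[[1]]
    return(grid_create(matrix(object$value, nrow(tmpl$values),
                              ncol(tmpl$values)),
                       tmpl$origin_x, tmpl$origin_y, tmpl$cell_size))
  }
  rep(object$value, nrow(newdata))
}
.S3method("predict", "const_learner", predict.const_learner)

# quick non-spatial survey generator for variogram-level checks
flat_survey <- function(seed, n_villages = 100, nr = 30, nc = 30) {
  cfg <- sim_config(seed = seed, grid_shape = c(nr, nc),
                    n_villages = n_villages, examined_range = c(100L, 300L),
                    covariate_lengthscale = 3,
                    geostat_truth = list(alpha = -4.5, beta = 2, sigma2 = 1e-10,
                                         phi = 5, tau2 = 0))
  stack <- simulate_covariates(cfg)
  fl <- simulate_prevalence_field(stack, cfg)
  list(survey = sample_survey(fl$prevalence, cfg),
       suitability = fl$suitability)
}
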