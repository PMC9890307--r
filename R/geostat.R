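#' Exponential correlation function
#'
#' `exp(-u / phi)`: correlation between two locations a distance `u` apart
#' under the exponential model with range parameter `phi`.
#'
#' @param u non-negative distance(s).
#' @param phi positive range parameter (same unit as `u`).
#' @return correlation value(s) in `(0, 1]`.
#' @export
exp_correlation <- function(u, phi) {
  if (any(u < 0)) stop("distances must be non-negative")
  if (phi <= 0) stop("phi must be positive")
  exp(-u / phi)
}

## numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x <= 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

## binomial log-likelihood (up to the constant binomial coefficient)
binom_ll <- function(y, n, eta) sum(y * eta - n * log1pexp(eta))

## working parameter vector: (alpha, beta, log sigma2, log phi, log tau2)
par_names <- c("alpha", "beta", "log_sigma2", "log_phi", "log_tau2")

theta_to_list <- function(theta) {
  list(alpha = theta[1L], beta = theta[2L], sigma2 = exp(theta[3L]),
       phi = exp(theta[4L]), tau2 = exp(theta[5L]))
}

## covariance of the latent village effects: sigma2 * R(phi) + tau2 * I,
## with a tiny ridge for numerical positive-definiteness
build_sigma <- function(D, p, jitter = 1e-8) {
  S <- p$sigma2 * exp(-D / p$phi)
  diag(S) <- diag(S) + p$tau2 + jitter * (p$sigma2 + p$tau2 + 1e-3)
  S
}

## Laplace approximation to the marginal log-likelihood. Newton with
## step-halving for the latent mode; warm start supported. Returns the
## approximate log-likelihood and the mode machinery needed downstream.
laplace_eval <- function(theta, y, n, s, D, Tstart = NULL,
                         max_newton = 50L, tol = 1e-8) {
  p <- theta_to_list(theta)
  nn <- length(y)
  Sigma <- build_sigma(D, p)
  cS <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cS)) return(list(l = -Inf))
  Tcur <- if (is.null(Tstart)) rep(0, nn) else Tstart
  sig_inv_T <- function(Tv) backsolve(cS, forwardsolve(t(cS), Tv))
  obj <- function(Tv, SiT) binom_ll(y, n, p$alpha + p$beta * s + Tv) -
    0.5 * sum(Tv * SiT)
  SiT <- sig_inv_T(Tcur)
  f_cur <- obj(Tcur, SiT)
  for (it in seq_len(max_newton)) {
    eta <- p$alpha + p$beta * s + Tcur
    prob <- expit(eta)
    W <- n * prob * (1 - prob)
    g <- (y - n * prob) - SiT
    ## Newton step: (W + Sigma^{-1})^{-1} g = (Sigma W + I)^{-1} Sigma g
    M <- Sigma * rep(W, each = nn)
    diag(M) <- diag(M) + 1
    step <- tryCatch(solve(M, Sigma %*% g), error = function(e) NULL)
    if (is.null(step)) return(list(l = -Inf))
    lam <- 1
    repeat {
      Tnew <- Tcur + lam * as.vector(step)
      SiTnew <- sig_inv_T(Tnew)
      f_new <- obj(Tnew, SiTnew)
      if (f_new >= f_cur - 1e-12 || lam < 1e-4) break
      lam <- lam / 2
    }
    done <- abs(f_new - f_cur) < tol * (abs(f_cur) + 1)
    Tcur <- Tnew; SiT <- SiTnew; f_cur <- f_new
    if (done) break
  }
  eta <- p$alpha + p$beta * s + Tcur
  prob <- expit(eta)
  W <- n * prob * (1 - prob)
  M <- Sigma * rep(W, each = nn)
  diag(M) <- diag(M) + 1
  ldet <- determinant(M, logarithm = TRUE)$modulus
  l <- binom_ll(y, n, eta) - 0.5 * sum(Tcur * SiT) - 0.5 * as.numeric(ldet)
  list(l = l, Tmode = Tcur, W = W, Sigma = Sigma, cS = cS, prob = prob)
}

## conditional simulation of the latent effects T | y at theta0 by
## preconditioned MALA in the whitened space u = cQ (T - Tmode), where
## Q = W + Sigma^{-1} is the Laplace precision. The target there is close to
## N(0, I), so a single adapted step size mixes well. Returns m (thinned)
## samples.
sample_latent_mala <- function(theta0, y, n, s, D, m, seed,
                               burn = 1000L, thin = 5L) {
  lap0 <- laplace_eval(theta0, y, n, s, D)
  p <- theta_to_list(theta0)
  nn <- length(y)
  Sig0_inv <- chol2inv(lap0$cS)
  Q <- Sig0_inv
  diag(Q) <- diag(Q) + lap0$W
  cQ <- chol(Q)
  Tmode <- lap0$Tmode
  T_of <- function(u) Tmode + backsolve(cQ, u)
  ## log conditional (up to a constant) and its u-space gradient
  logpost <- function(Tv) {
    eta <- p$alpha + p$beta * s + Tv
    binom_ll(y, n, eta) - 0.5 * sum(Tv * (Sig0_inv %*% Tv))
  }
  grad_u <- function(Tv) {
    eta <- p$alpha + p$beta * s + Tv
    gT <- (y - n * expit(eta)) - as.vector(Sig0_inv %*% Tv)
    ## d T / d u = cQ^{-1}; grad_u = cQ^{-T} grad_T
    forwardsolve(t(cQ), gT)
  }
  with_seed(seed, {
    u <- rep(0, nn)
    Tv <- T_of(u)
    lp <- logpost(Tv); gu <- grad_u(Tv)
    h <- 1.2 / nn^(1 / 6)
    iters <- burn + m * thin
    keep <- matrix(0, nn, m)
    acc <- 0L; kept <- 0L
    for (it in seq_len(iters)) {
      mu_f <- u + 0.5 * h^2 * gu
      up <- mu_f + h * stats::rnorm(nn)
      Tp <- T_of(up)
      lpp <- logpost(Tp); gup <- grad_u(Tp)
      mu_b <- up + 0.5 * h^2 * gup
      lr <- (lpp - lp) +
        (-sum((u - mu_b)^2) + sum((up - mu_f)^2)) / (2 * h^2)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        u <- up; Tv <- Tp; lp <- lpp; gu <- gup; acc <- acc + 1L
      }
      if (it <= burn && it %% 50L == 0L) {
        rate <- acc / it
        h <- h * if (rate > 0.6) 1.15 else if (rate < 0.45) 0.85 else 1
      }
      if (it > burn && (it - burn) %% thin == 0L) {
        kept <- kept + 1L
        keep[, kept] <- Tv
      }
    }
    list(Tsamp = keep, accept = acc / iters, lap0 = lap0)
  })
}

## Monte-Carlo (Geyer) likelihood-ratio approximant: with T_j drawn from the
## conditional distribution at theta0, the weights are identically 1 at
## theta0 and l_m(theta) estimates l(theta) - l(theta0) + const, smooth in
## theta under common random numbers.
make_mcml_loglik <- function(theta0, y, n, s, D, m, seed) {
  sim <- sample_latent_mala(theta0, y, n, s, D, m, seed)
  Tsamp <- sim$Tsamp
  nn <- length(y)
  p0 <- theta_to_list(theta0)
  Sigma0 <- build_sigma(D, p0)
  cS0 <- chol(Sigma0)
  u0 <- forwardsolve(t(cS0), Tsamp)
  lmvn0 <- -sum(log(diag(cS0))) - 0.5 * colSums(u0^2)
  eta0 <- p0$alpha + p0$beta * s + Tsamp
  llb0 <- colSums(y * eta0 - n * log1pexp(eta0))
  loglik <- function(theta) {
    p <- theta_to_list(theta)
    Sigma <- build_sigma(D, p)
    cS <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(cS)) return(-Inf)
    u <- forwardsolve(t(cS), Tsamp)
    lmvn <- -sum(log(diag(cS))) - 0.5 * colSums(u^2)
    eta <- p$alpha + p$beta * s + Tsamp
    llb <- colSums(y * eta - n * log1pexp(eta))
    a <- (llb - llb0) + (lmvn - lmvn0)
    amax <- max(a)
    amax + log(mean(exp(a - amax)))
  }
  list(loglik = loglik, Tsamp = Tsamp, accept = sim$accept, lap0 = sim$lap0)
}

## central-difference Hessian
num_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * 1e-3
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit the binomial logistic geostatistical model
#'
#' Village counts are modelled as `Y_i ~ Binomial(n_i, p_i)` with
#' `logit(p_i) = alpha + beta * s(x_i) + S(x_i) + Z_i`, where `s` is the
#' environmental suitability at the village, `S` a zero-mean stationary
#' Gaussian process with covariance `sigma2 * exp(-d / phi)` and `Z_i` iid
#' `N(0, tau2)` nugget effects. Estimation is Monte-Carlo maximum
#' likelihood: a Laplace-approximate likelihood is maximised first, then the
#' likelihood ratio is re-estimated by conditional simulation of the latent
#' effects (preconditioned MALA at the Laplace optimum) and re-maximised
#' from there under common random numbers. Standard errors come from the
#' numerical Hessian of the Laplace-approximate log-likelihood at the final
#' estimate, whose curvature tracks the exact likelihood closely at survey
#' denominators while being free of Monte-Carlo noise; variance parameters
#' are estimated on the log scale.
#'
#' @param survey data.frame of village records: `x`, `y`, `n_examined`,
#'   `n_cases` (at least 20 villages, distinct coordinates).
#' @param suitability suitability [grid_create()] grid to extract at village
#'   coordinates, or a numeric vector of suitability values per village.
#' @param opts list of options: `method` ("mcml", the default, or "laplace"),
#'   `mc_samples` (importance samples, default 500), `fix` (named list of
#'   parameters held fixed, e.g. `list(sigma2 = 0)` for a nugget-only model
#'   or `list(beta = 0)`), `start` (named list of starting values),
#'   `duplicates` ("error" or "jitter"), `seed` (importance-sample seed,
#'   default 1), `maxit` (outer Nelder-Mead iterations, default 400).
#' @return a `geostat_fit`: estimates and standard errors for `alpha`,
#'   `beta`, `sigma2`, `phi`, `tau2`, log-likelihood, convergence flag,
#'   `mc_samples`, and the data needed for prediction.
#' @export
fit_geostat <- function(survey, suitability, opts = list()) {
  stopifnot(is.data.frame(survey),
            all(c("x", "y", "n_examined", "n_cases") %in% names(survey)))
  if (nrow(survey) < 20L)
    stop("at least 20 villages are required to fit the geostatistical model")
  method <- opts$method %||% "mcml"
  m <- opts$mc_samples %||% 500L
  fix <- opts$fix %||% list()
  seed <- opts$seed %||% 1L
  maxit <- opts$maxit %||% 400L

  s <- if (is_grid(suitability)) {
    st <- grid_stack(list(s = suitability))
    extract_at_points(st, survey)[["s"]]
  } else as.numeric(suitability)
  if (anyNA(s)) stop("suitability is missing at one or more villages")
  y <- survey$n_cases; n <- survey$n_examined
  coords <- cbind(survey$x, survey$y)
  D <- as.matrix(stats::dist(coords))
  if (any(D[upper.tri(D)] == 0)) {
    if ((opts$duplicates %||% "error") == "jitter") {
      coords <- coords + matrix(stats::rnorm(length(coords), sd = 1e-4),
                                ncol = 2L)
      D <- as.matrix(stats::dist(coords))
    } else stop("duplicate village coordinates; set opts$duplicates='jitter'")
  }

  ## non-spatial shortcut: both variance components fixed at zero
  if (!is.null(fix$sigma2) && fix$sigma2 == 0 &&
      !is.null(fix$tau2) && fix$tau2 == 0) {
    g <- stats::glm(cbind(y, n - y) ~ s, family = stats::binomial())
    cf <- stats::coef(g); se <- sqrt(diag(stats::vcov(g)))
    est <- list(alpha = unname(cf[1L]), beta = unname(cf[2L]),
                sigma2 = 0, phi = NA_real_, tau2 = 0)
    return(structure(list(
      estimate = est,
      se = list(alpha = se[1L], beta = se[2L], log_sigma2 = NA_real_,
                log_phi = NA_real_, log_tau2 = NA_real_),
      loglik = as.numeric(stats::logLik(g)), converged = g$converged,
      method = "glm", mc_samples = 0L, fix = fix,
      data = list(y = y, n = n, s = s, coords = coords),
      Tmode = rep(0, length(y)),
      fitted_fixed = expit(cf[1L] + cf[2L] * s)),
      class = "geostat_fit"))
  }

  ## starting values
  g0 <- stats::glm(cbind(y, n - y) ~ s, family = stats::binomial())
  elog <- log((y + 0.5) / (n - y + 0.5))
  res0 <- elog - (stats::coef(g0)[1L] + stats::coef(g0)[2L] * s)
  v0 <- max(stats::var(res0), 0.05)
  start <- list(alpha = unname(stats::coef(g0)[1L]),
                beta = unname(stats::coef(g0)[2L]),
                sigma2 = 0.5 * v0, phi = stats::median(D) / 3,
                tau2 = 0.25 * v0)
  start[names(opts$start %||% list())] <- opts$start
  start[names(fix)] <- fix

  theta_full <- c(start$alpha, start$beta,
                  log(max(start$sigma2, 1e-8)),
                  log(max(start$phi, 1e-8)),
                  log(max(start$tau2, 1e-8)))
  names(theta_full) <- par_names
  fixed_mask <- c(alpha = !is.null(fix$alpha), beta = !is.null(fix$beta),
                  log_sigma2 = !is.null(fix$sigma2),
                  log_phi = !is.null(fix$phi) ||
                    (!is.null(fix$sigma2) && fix$sigma2 == 0),
                  log_tau2 = !is.null(fix$tau2))
  if (!is.null(fix$sigma2) && fix$sigma2 == 0) theta_full["log_sigma2"] <- -Inf
  if (!is.null(fix$tau2) && fix$tau2 == 0) theta_full["log_tau2"] <- -Inf
  free <- which(!fixed_mask)

  env <- new.env()
  env$Tcur <- NULL
  expand <- function(th_free) {
    th <- theta_full
    th[free] <- th_free
    th
  }
  lap_obj <- function(th_free) {
    out <- laplace_eval(expand(th_free), y, n, s, D, Tstart = env$Tcur)
    if (is.finite(out$l)) env$Tcur <- out$Tmode
    out$l
  }
  opt_lap <- stats::optim(theta_full[free], lap_obj,
                          control = list(fnscale = -1, maxit = maxit,
                                         reltol = 1e-6))
  theta_lap <- expand(opt_lap$par)

  refine_convergence <- NA
  if (method == "laplace" || m == 0L) {
    theta_hat <- theta_lap
    opt <- opt_lap
    mc_used <- 0L
  } else {
    mc <- make_mcml_loglik(theta_lap, y, n, s, D, m, seed)
    opt <- stats::optim(theta_lap[free], function(tf) mc$loglik(expand(tf)),
                        control = list(fnscale = -1, reltol = 1e-6,
                                       maxit = opts$maxit_mcml %||% 300L))
    theta_hat <- expand(opt$par)
    mc_used <- m
    refine_convergence <- opt$convergence == 0
    opt <- opt_lap
  }

  ## curvature from the (smooth) Laplace-approximate likelihood at the final
  ## estimate: with large binomial denominators it tracks the exact
  ## likelihood closely, whereas the Hessian of the finite-sample Monte-Carlo
  ## ratio is anti-conservative
  loglik_fun <- function(tf) laplace_eval(expand(tf), y, n, s, D,
                                          Tstart = env$Tcur)$l
  H <- num_hessian(loglik_fun, theta_hat[free])
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V)))) {
    ## boundary-flat directions (variance components at ~0) make the full
    ## information singular; invert the curved block and leave the rest to
    ## the likelihood-scan fallback below
    V <- matrix(NA_real_, length(free), length(free))
    ok <- which(diag(-H) > 1e-8)
    if (length(ok)) {
      Vok <- tryCatch(solve(-H[ok, ok, drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(Vok)) V[ok, ok] <- Vok
    }
  }
  se_free <- suppressWarnings(sqrt(diag(V)))
  se <- stats::setNames(rep(NA_real_, 5L), par_names)
  se[free] <- se_free

  ## variance parameters stuck at (or near) the zero boundary leave the
  ## log-scale Wald machinery degenerate; fall back to a 1-D likelihood scan
  ## (others held at their estimates) for those intervals
  ci_override <- list()
  natural <- c(log_sigma2 = "sigma2", log_phi = "phi", log_tau2 = "tau2")
  for (b in which(!is.finite(se_free))) {
    pn <- par_names[free[b]]
    if (!pn %in% names(natural)) next
    gridv <- seq(-16, max(theta_hat[free[b]] + 6, 2), length.out = 49L)
    lv <- vapply(gridv, function(g) {
      tf <- theta_hat[free]; tf[b] <- g; loglik_fun(tf)
    }, numeric(1L))
    ok <- gridv[lv >= max(lv) - stats::qchisq(0.95, 1L) / 2]
    ci <- exp(range(ok))
    if (min(ok) <= -15.9) ci[1L] <- 0
    ci_override[[natural[[pn]]]] <- ci
  }

  p_hat <- theta_to_list(theta_hat)
  if (!is.null(fix$sigma2)) p_hat$sigma2 <- fix$sigma2
  if (!is.null(fix$tau2)) p_hat$tau2 <- fix$tau2
  if (!is.null(fix$phi)) p_hat$phi <- fix$phi
  if (!is.null(fix$alpha)) p_hat$alpha <- fix$alpha
  if (!is.null(fix$beta)) p_hat$beta <- fix$beta

  final_lap <- laplace_eval(theta_hat, y, n, s, D, Tstart = env$Tcur)
  structure(list(
    estimate = p_hat,
    se = as.list(se),
    vcov = V, free = par_names[free], theta = theta_hat,
    ## the MC objective is a likelihood *ratio*; report the Laplace
    ## log-likelihood at the final estimate as the comparable scalar
    loglik = final_lap$l,
    converged = opt$convergence == 0 &&
      sum(!is.finite(se_free)) == length(ci_override),
    ci_override = ci_override,
    refine_convergence = refine_convergence,
    method = method, mc_samples = mc_used, fix = fix,
    data = list(y = y, n = n, s = s, coords = coords),
    Tmode = final_lap$Tmode, W = final_lap$W,
    fitted_fixed = expit(p_hat$alpha + p_hat$beta * s)),
    class = "geostat_fit")
}

#' @export
print.geostat_fit <- function(x, ...) {
  cat(sprintf("binomial logistic geostatistical fit (%s, %d villages)\n",
              x$method, length(x$data$y)))
  e <- x$estimate
  cat(sprintf("  alpha  %8.3f (se %s)\n", e$alpha, format(x$se$alpha,
                                                          digits = 3)))
  cat(sprintf("  beta   %8.3f (se %s)\n", e$beta, format(x$se$beta,
                                                         digits = 3)))
  cat(sprintf("  sigma2 %8.3f   phi %8.3f   tau2 %8.4f\n",
              e$sigma2, e$phi, e$tau2))
  cat(sprintf("  log-likelihood %.3f, converged: %s\n", x$loglik,
              x$converged))
  invisible(x)
}

#' Confidence intervals for geostatistical parameters
#'
#' Wald intervals: direct for `alpha` and `beta`; on the log scale
#' (back-transformed) for `sigma2`, `phi` and `tau2`.
#'
#' @param object a `geostat_fit`.
#' @param parm parameters to include (default all free).
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return data.frame with `param`, `estimate`, `lower`, `upper`.
#' @export
confint.geostat_fit <- function(object, parm = NULL, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  e <- object$estimate
  rows <- list(
    alpha = c(e$alpha, e$alpha - z * object$se$alpha,
              e$alpha + z * object$se$alpha),
    beta = c(e$beta, e$beta - z * object$se$beta,
             e$beta + z * object$se$beta),
    sigma2 = c(e$sigma2, e$sigma2 * exp(-z * object$se$log_sigma2),
               e$sigma2 * exp(z * object$se$log_sigma2)),
    phi = c(e$phi, e$phi * exp(-z * object$se$log_phi),
            e$phi * exp(z * object$se$log_phi)),
    tau2 = c(e$tau2, e$tau2 * exp(-z * object$se$log_tau2),
             e$tau2 * exp(z * object$se$log_tau2)))
  for (nm in names(object$ci_override %||% list()))
    rows[[nm]][2:3] <- object$ci_override[[nm]]
  out <- do.call(rbind, lapply(names(rows), function(nm)
    data.frame(param = nm, estimate = rows[[nm]][1L],
               lower = rows[[nm]][2L], upper = rows[[nm]][3L])))
  if (!is.null(parm)) out <- out[out$param %in% parm, , drop = FALSE]
  out
}

#' Predict the prevalence surface with uncertainty and exceedance
#'
#' Plug-in conditional simulation at the parameter estimates: latent village
#' effects are drawn from their Gaussian (Laplace) approximation given the
#' data, the spatial process is extended to prediction cells by conditional
#' Gaussian simulation (the nugget, being village-level noise, is excluded
#' from spatial prediction), and each draw is mapped through the logit link.
#' Cells outside the binary limits map are `NA`.
#'
#' @param fit a converged `geostat_fit`.
#' @param suitability suitability grid (prediction covariate).
#' @param limits binary limits grid aligned to `suitability` (`NULL` to
#'   predict every valid cell).
#' @param n_sim predictive draws per cell (>= 100; default 1000).
#' @param threshold prevalence exceedance threshold (default 0.01).
#' @param keep_draws retain the draw matrix (cells x n_sim) for diagnostics.
#' @param seed RNG seed for the predictive draws.
#' @return a `prediction_surface`: grids `mean_prev`, `lower95`, `upper95`,
#'   `sd`, `se_count` (mean/sd) and `exceedance`; plus `draws` when
#'   requested.
#' @export
predict_surface <- function(fit, suitability, limits = NULL, n_sim = 1000L,
                            threshold = 0.01, keep_draws = FALSE, seed = 1L) {
  stopifnot(inherits(fit, "geostat_fit"), is_grid(suitability))
  if (n_sim < 100L)
    stop("n_sim must be at least 100 for stable percentile intervals")
  if (!is.null(limits) && !grids_aligned(suitability, limits))
    stop("limits grid is not aligned to the suitability grid")
  if (!isTRUE(fit$converged))
    warning("geostatistical fit did not converge; predictions are tentative")
  e <- fit$estimate
  sv <- suitability$values
  mask <- !is.na(sv)
  if (!is.null(limits)) mask <- mask & !is.na(limits$values) &
    limits$values == 1
  cells <- which(mask)
  if (!length(cells)) stop("no suitable cells to predict")
  nr <- nrow(sv)
  cx <- suitability$origin_x + (((cells - 1L) %/% nr) + 0.5) *
    suitability$cell_size
  cy <- suitability$origin_y - (((cells - 1L) %% nr) + 0.5) *
    suitability$cell_size
  s_pred <- sv[cells]

  y <- fit$data$y; n <- fit$data$n; s_obs <- fit$data$s
  coords <- fit$data$coords
  no <- length(y); ng <- length(cells)
  D <- as.matrix(stats::dist(coords))
  p <- list(alpha = e$alpha, beta = e$beta, sigma2 = max(e$sigma2, 1e-12),
            phi = if (is.na(e$phi)) 1 else e$phi, tau2 = max(e$tau2, 0))
  Sigma <- build_sigma(D, p)
  cS <- chol(Sigma)
  ## posterior (Laplace) precision of the latent village effects
  Q <- chol2inv(cS)
  eta_hat <- p$alpha + p$beta * s_obs + fit$Tmode
  prob_hat <- expit(eta_hat)
  diag(Q) <- diag(Q) + n * prob_hat * (1 - prob_hat)
  cQ <- chol(Q)

  ## cross-covariance spatial-process-at-cells vs latent village effects
  dxg <- outer(coords[, 1L], cx, `-`); dyg <- outer(coords[, 2L], cy, `-`)
  C <- p$sigma2 * exp(-sqrt(dxg^2 + dyg^2) / p$phi)   # no x ng
  A <- backsolve(cS, forwardsolve(t(cS), C))          # Sigma^{-1} C
  ## conditional covariance of the process at prediction cells
  dgg <- as.matrix(stats::dist(cbind(cx, cy)))
  Vg <- p$sigma2 * exp(-dgg / p$phi) - crossprod(C, A)
  Vg <- (Vg + t(Vg)) / 2
  diag(Vg) <- diag(Vg) + 1e-10 * (p$sigma2 + 1e-3)
  cV <- tryCatch(chol(Vg), error = function(e2)
    chol(Vg + diag(1e-6 * p$sigma2 + 1e-9, ng)))

  draws <- with_seed(seed, {
    Zt <- matrix(stats::rnorm(no * n_sim), no, n_sim)
    Tdraw <- fit$Tmode + backsolve(cQ, Zt)            # no x n_sim
    mu_g <- crossprod(A, Tdraw)                       # ng x n_sim
    Zg <- matrix(stats::rnorm(ng * n_sim), ng, n_sim)
    Sg <- mu_g + crossprod(cV, Zg)
    unname(expit(p$alpha + p$beta * s_pred + Sg))
  })
  dimnames(draws) <- NULL

  qs <- apply(draws, 1L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  mean_p <- rowMeans(draws)
  sd_p <- apply(draws, 1L, stats::sd)
  exceed <- rowMeans(draws > threshold)

  blank <- function() matrix(NA_real_, nrow(sv), ncol(sv))
  as_grid <- function(v) {
    mres <- blank(); mres[cells] <- v
    grid_create(mres, suitability$origin_x, suitability$origin_y,
                suitability$cell_size, suitability$nodata)
  }
  out <- list(mean_prev = as_grid(mean_p), lower95 = as_grid(qs[1L, ]),
              upper95 = as_grid(qs[2L, ]), sd = as_grid(sd_p),
              se_count = as_grid(mean_p / pmax(sd_p, 1e-12)),
              exceedance = as_grid(exceed),
              threshold = threshold, n_sim = n_sim, cells = cells)
  if (keep_draws) out$draws <- draws
  structure(out, class = "prediction_surface")
}

## binned empirical semivariogram of a residual vector over locations
empirical_variogram <- function(r, coords, n_bins = 8L, max_dist = NULL) {
  D <- as.matrix(stats::dist(coords))
  ij <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[upper.tri(D)]
  if (is.null(max_dist)) max_dist <- max(d) / 2
  keep <- d > 0 & d <= max_dist
  ij <- ij[keep, , drop = FALSE]; d <- d[keep]
  breaks <- seq(0, max_dist, length.out = n_bins + 1L)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  sq <- 0.5 * (r[ij[, 1L]] - r[ij[, 2L]])^2
  gamma <- tapply(sq, bin, mean)
  npairs <- tapply(sq, bin, length)
  mid <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  present <- sort(unique(bin))
  data.frame(bin = present, dist = mid[present],
             gamma = as.numeric(gamma[as.character(present)]),
             n_pairs = as.numeric(npairs[as.character(present)]))
}

#' Variogram-based validation of the fitted spatial structure
#'
#' Computes the empirical semivariogram of the empirical-logit village
#' residuals (`log((y+0.5)/(n-y+0.5))` minus the fixed-effect linear
#' predictor, the scale on which residual spatial structure is additive with
#' stable variance) and compares it with the
#' distribution of variograms obtained by randomly permuting residuals over
#' locations, which destroys any spatial structure. The envelope is
#' *simultaneous*: permutation curves are ranked by their maximum
#' standardised deviation from the permutation mean, the envelope is the
#' pointwise range of the `level` fraction least-extreme curves, and the fit
#' passes iff the observed curve is no more extreme than that fraction —
#' so "inside the envelope at all bins" holds with familywise probability
#' `level` under the null.
#'
#' @param fit a `geostat_fit`.
#' @param survey optional survey data.frame (defaults to the data stored in
#'   the fit).
#' @param n_perm number of permutations (default 999).
#' @param n_bins distance bins (default 8).
#' @param max_dist maximum pair distance (default half the largest).
#' @param level envelope level (default 0.95).
#' @param seed RNG seed.
#' @return list: `variogram` (data.frame), `envelope` (data.frame with
#'   `dist`, `lo`, `hi`), `pass` (logical), `p_value`.
#' @export
variogram_validate <- function(fit, survey = NULL, n_perm = 999L,
                               n_bins = 8L, max_dist = NULL, level = 0.95,
                               seed = 1L) {
  stopifnot(inherits(fit, "geostat_fit"))
  if (n_perm < 1L) stop("n_perm must be at least 1")
  y <- fit$data$y; n <- fit$data$n
  coords <- fit$data$coords
  r <- log((y + 0.5) / (n - y + 0.5)) - logit(fit$fitted_fixed)
  ## precompute pair indices and bin membership once; permutations only
  ## re-aggregate squared differences
  D <- as.matrix(stats::dist(coords))
  d <- D[upper.tri(D)]
  if (is.null(max_dist)) max_dist <- max(d) / 2
  ij <- which(upper.tri(D), arr.ind = TRUE)
  keep <- d > 0 & d <= max_dist
  ij <- ij[keep, , drop = FALSE]; d <- d[keep]
  breaks <- seq(0, max_dist, length.out = n_bins + 1L)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  present <- sort(unique(bin))
  if (length(present) < 2L) stop("fewer than 2 populated distance bins")
  nb <- tabulate(bin, nbins = n_bins)[present]
  curve_of <- function(rv) {
    sq <- 0.5 * (rv[ij[, 1L]] - rv[ij[, 2L]])^2
    as.numeric(rowsum(sq, bin)[, 1L]) / nb
  }
  mid <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  emp <- data.frame(bin = present, dist = mid[present],
                    gamma = curve_of(r), n_pairs = nb)
  perm_curves <- with_seed(seed, vapply(seq_len(n_perm),
                                        function(i) curve_of(sample(r)),
                                        numeric(length(present))))
  mu <- rowMeans(perm_curves)
  sdv <- apply(perm_curves, 1L, stats::sd)
  sdv <- pmax(sdv, 1e-12)
  stat <- function(g) max(abs(g - mu) / sdv)
  obs_stat <- stat(emp$gamma)
  perm_stats <- apply(perm_curves, 2L, stat)
  p_value <- (1 + sum(perm_stats >= obs_stat)) / (n_perm + 1)
  cutoff <- stats::quantile(perm_stats, level, type = 7)
  inside <- perm_curves[, perm_stats <= cutoff, drop = FALSE]
  envelope <- data.frame(dist = emp$dist,
                         lo = apply(inside, 1L, min),
                         hi = apply(inside, 1L, max))
  list(variogram = emp, envelope = envelope,
       pass = obs_stat <= cutoff, p_value = p_value)
}
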