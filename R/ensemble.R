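#' Screen covariates for collinearity
#'
#' Computes pairwise Pearson correlations of the covariates over presence
#' cells plus a background sample, and greedily drops one member of every
#' pair with `|r|` above the cut, keeping the covariate with the larger
#' absolute loading on the leading principal component (i.e. the one that
#' carries more of the dominant environmental gradient).
#'
#' @param stack covariate [grid_stack()].
#' @param presence_points data.frame with `x`, `y` of presence locations.
#' @param cut correlation threshold (default 0.8).
#' @param background_n background cells sampled from the stack (default 2000,
#'   capped at the number of valid cells).
#' @param seed RNG seed for the background sample.
#' @return list: `retained`, `dropped`, and a `report` data.frame of the
#'   dropped pairs.
#' @export
screen_covariates <- function(stack, presence_points, cut = 0.8,
                              background_n = 2000L, seed = 1L) {
  stopifnot(is_stack(stack), length(stack$names) >= 2L)
  X <- stack_matrix(stack)
  valid <- which(stats::complete.cases(X))
  bg <- with_seed(seed, sample(valid, min(background_n, length(valid))))
  Xp <- if (!is.null(presence_points) && nrow(presence_points)) {
    ex <- extract_at_points(stack, presence_points)
    as.matrix(ex[, stack$names, drop = FALSE])
  } else NULL
  M <- rbind(X[bg, , drop = FALSE], Xp)
  M <- M[stats::complete.cases(M), , drop = FALSE]
  sds <- apply(M, 2L, stats::sd)
  if (all(sds < 1e-12)) stop("all covariates are constant; nothing to screen")
  keep <- stack$names[sds >= 1e-12]
  M <- M[, keep, drop = FALSE]
  pc1 <- abs(stats::prcomp(M, scale. = TRUE)$rotation[, 1L])
  report <- NULL
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(stats::cor(M[, keep, drop = FALSE]))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    if (cm[worst[1L], worst[2L]] <= cut) break
    pair <- keep[worst]
    drop <- pair[which.min(pc1[pair])]
    report <- rbind(report, data.frame(
      kept = setdiff(pair, drop), dropped = drop,
      abs_r = cm[worst[1L], worst[2L]]))
    keep <- setdiff(keep, drop)
  }
  list(retained = keep, dropped = setdiff(stack$names, keep), report = report)
}

## assemble a labelled training table from covariate-value data.frames,
## weighting classes to an effective prevalence of 0.5 (the usual SDM
## convention when pseudoabsences outnumber presences)
training_table <- function(presences, absences, pseudoabsences) {
  pres <- cbind(label = 1, presences)
  abs1 <- if (!is.null(absences) && nrow(absences)) cbind(label = 0, absences)
  abs2 <- if (!is.null(pseudoabsences) && nrow(pseudoabsences))
    cbind(label = 0, pseudoabsences)
  out <- rbind(pres, abs1, abs2)
  if (is.null(out$weight)) {
    n1 <- sum(out$label == 1); n0 <- sum(out$label == 0)
    out$weight <- ifelse(out$label == 1, n0 / n1, 1)
  }
  out
}

#' Build calibration/evaluation runs
#'
#' Crosses every pseudoabsence set with `n_splits` stratified random 80/20
#' partitions of presences + absences + that pseudoabsence set, giving
#' `length(pa_sets) * n_splits` runs (5 x 10 = 50 by default). Stratification
#' guarantees both classes appear in both partitions.
#'
#' @param presences,absences data.frames of covariate values at presence /
#'   surveyed-absence locations (absences may be `NULL`).
#' @param pa_sets list of covariate-value data.frames, one per pseudoabsence
#'   set.
#' @param n_splits splits per pseudoabsence set (default 10).
#' @param train_frac calibration fraction (default 0.8).
#' @param seed RNG seed.
#' @return list of runs: each has `train`, `test` (data.frames with `label`,
#'   `weight` and covariate columns), `pa_set`, `split`.
#' @export
make_runs <- function(presences, absences, pa_sets, n_splits = 10L,
                      train_frac = 0.8, seed = 1L) {
  stopifnot(n_splits >= 1L, length(pa_sets) >= 1L,
            train_frac > 0, train_frac < 1)
  with_seed(seed, {
    runs <- list()
    for (s in seq_along(pa_sets)) {
      full <- training_table(presences, absences, pa_sets[[s]])
      if (min(table(full$label)) < 2L)
        stop("each class needs at least 2 records to stratify an 80/20 split")
      for (j in seq_len(n_splits)) {
        tr_idx <- unlist(lapply(split(seq_len(nrow(full)), full$label),
                                function(ix) {
          k <- min(max(round(train_frac * length(ix)), 1L), length(ix) - 1L)
          sample(ix, k)
        }), use.names = FALSE)
        runs[[length(runs) + 1L]] <- list(
          train = full[sort(tr_idx), , drop = FALSE],
          test = full[-sort(tr_idx), , drop = FALSE],
          pa_set = s, split = j)
      }
    }
    runs
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a component suitability learner
#'
#' All learners are probability-outputting binary classifiers over the
#' covariate columns of `train`. `glm` is logistic regression with linear
#' terms; `brt` is a boosted regression tree (learning rate 0.005,
#' interaction depth 4, bag fraction 0.5, tree count chosen on an internal
#' 20% validation split); `rf` is a 500-tree random forest; `maxent` is a
#' ridge-penalised logistic approximation (requires glmnet).
#'
#' @param kind one of `"glm"`, `"brt"`, `"rf"`, `"maxent"`.
#' @param train data.frame with `label` (0/1), optional `weight`, and
#'   covariate columns.
#' @param hyper named list of hyperparameter overrides: `learning_rate`,
#'   `interaction_depth`, `max_trees`, `n_trees`, `bag_fraction`.
#' @return a `podo_learner` with a [predict.podo_learner()] method.
#' @export
fit_learner <- function(kind = c("glm", "brt", "rf", "maxent"), train,
                        hyper = list()) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(train), "label" %in% names(train))
  if (length(unique(train$label)) < 2L)
    stop("training data must contain both classes")
  covs <- setdiff(names(train), c("label", "weight"))
  X <- as.matrix(train[, covs, drop = FALSE])
  y <- train$label
  w <- train$weight %||% rep(1, nrow(train))
  fit <- switch(kind,
    glm = {
      df <- data.frame(label = y, train[, covs, drop = FALSE])
      m <- suppressWarnings(stats::glm(label ~ ., family = stats::binomial(),
                                       data = df, weights = w))
      if (anyNA(stats::coef(m)))
        stop("singular design matrix in logistic regression; ",
             "run screen_covariates() to drop collinear covariates")
      m
    },
    brt = {
      eta <- hyper$learning_rate %||% 0.005
      depth <- hyper$interaction_depth %||% 4L
      bag <- hyper$bag_fraction %||% 0.5
      max_trees <- hyper$max_trees %||% 3000L
      params <- list(objective = "binary:logistic", eta = eta,
                     max_depth = depth, subsample = bag, nthread = 1L)
      nrounds <- hyper$n_trees
      if (is.null(nrounds)) {
        if (nrow(X) >= 60L) {
          hold <- with_seed(hyper$seed %||% 1L,
                            sample(nrow(X), max(round(0.2 * nrow(X)), 10L)))
          dtr <- xgboost::xgb.DMatrix(X[-hold, , drop = FALSE],
                                      label = y[-hold], weight = w[-hold])
          dva <- xgboost::xgb.DMatrix(X[hold, , drop = FALSE],
                                      label = y[hold], weight = w[hold])
          probe <- xgboost::xgb.train(params = params, data = dtr,
                                      nrounds = max_trees,
                                      evals = list(val = dva),
                                      early_stopping_rounds = 50L, verbose = 0)
          nrounds <- max(xgboost::xgb.attr(probe, "best_iteration") %||%
                           max_trees, 50L)
          nrounds <- as.integer(nrounds)
        } else nrounds <- 1000L
      }
      dall <- xgboost::xgb.DMatrix(X, label = y, weight = w)
      xgboost::xgb.train(params = params, data = dall, nrounds = nrounds,
                         verbose = 0)
    },
    rf = {
      ntree <- hyper$n_trees %||% 500L
      with_seed(hyper$seed %||% 1L,
                randomForest::randomForest(x = as.data.frame(X),
                                           y = factor(y), ntree = ntree))
    },
    maxent = {
      if (!requireNamespace("glmnet", quietly = TRUE))
        stop("the maxent adapter requires the glmnet package")
      with_seed(hyper$seed %||% 1L,
                glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                                  weights = w, nfolds = 5L))
    })
  structure(list(kind = kind, fit = fit, covariates = covs, train = train),
            class = "podo_learner")
}

#' Predict suitability probabilities from a fitted learner
#'
#' @param object a `podo_learner`.
#' @param newdata data.frame/matrix with the learner's covariate columns, or
#'   a [grid_stack()] (returns a grid; cells with missing covariates are
#'   `NA`).
#' @param ... unused.
#' @return numeric vector of probabilities, or a grid when `newdata` is a
#'   stack.
#' @export
predict.podo_learner <- function(object, newdata, ...) {
  if (is_stack(newdata)) {
    X <- stack_matrix(newdata)[, object$covariates, drop = FALSE]
    ok <- stats::complete.cases(X)
    p <- rep(NA_real_, nrow(X))
    if (any(ok))
      p[ok] <- predict(object, as.data.frame(X[ok, , drop = FALSE]))
    tmpl <- newdata$grids[[1L]]
    return(grid_create(matrix(p, nrow(tmpl$values), ncol(tmpl$values)),
                       tmpl$origin_x, tmpl$origin_y, tmpl$cell_size,
                       tmpl$nodata))
  }
  nd <- as.data.frame(newdata)[, object$covariates, drop = FALSE]
  X <- as.matrix(nd)
  switch(object$kind,
    glm = unname(stats::predict(object$fit, nd, type = "response")),
    brt = stats::predict(object$fit, xgboost::xgb.DMatrix(X)),
    rf = unname(stats::predict(object$fit, as.data.frame(X),
                               type = "prob")[, "1"]),
    maxent = as.vector(stats::predict(object$fit, X, s = "lambda.min",
                                      type = "response")))
}

#' Rank-based AUC (Mann-Whitney, half credit for ties)
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = presence).
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

## confusion metrics at a threshold (predict presence iff score >= t)
metrics_at <- function(scores, labels, t) {
  pred <- scores >= t
  pos <- labels == 1
  sens <- sum(pred & pos) / sum(pos)
  spec <- sum(!pred & !pos) / sum(!pos)
  c(sens = sens, spec = spec, tss = sens + spec - 1,
    pcc = mean(pred == pos))
}

#' Choose the suitability threshold maximising the true skill statistic
#'
#' Scans the observed scores as candidate thresholds (presence predicted at
#' `score >= t`), maximising TSS = sensitivity + specificity - 1; ties are
#' broken by higher PCC, then by the lower threshold.
#'
#' @param scores ensemble (or member) scores at labelled points.
#' @param labels binary labels.
#' @return list: `threshold`, `sens`, `spec`, `pcc`, `tss`.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  if (length(unique(labels)) < 2L)
    stop("threshold selection needs both classes")
  cand <- sort(unique(scores))
  m <- vapply(cand, function(t) metrics_at(scores, labels, t), numeric(4L))
  best <- order(-m["tss", ], -m["pcc", ], cand)[1L]
  list(threshold = cand[best], sens = unname(m["sens", best]),
       spec = unname(m["spec", best]), pcc = unname(m["pcc", best]),
       tss = unname(m["tss", best]))
}

#' Evaluate a learner on held-out data
#'
#' AUC via the rank (Mann-Whitney) formulation; TSS and PCC at the model's
#' own max-TSS threshold.
#'
#' @param model a `podo_learner`.
#' @param test data.frame with `label` and covariate columns, both classes
#'   present.
#' @return an `eval_scores` list: `auc`, `tss`, `pcc`, `sens`, `spec`,
#'   `threshold_used`.
#' @export
evaluate <- function(model, test) {
  stopifnot(is.data.frame(test), "label" %in% names(test))
  if (length(unique(test$label)) < 2L)
    stop("evaluation requires both classes in the test set")
  p <- predict(model, test)
  th <- select_threshold(p, test$label)
  structure(list(auc = auc_mw(p, test$label), tss = th$tss, pcc = th$pcc,
                 sens = th$sens, spec = th$spec,
                 threshold_used = th$threshold),
            class = "eval_scores")
}

#' AUC-weighted ensemble of suitability learners
#'
#' Predicts every member on the stack, discards members with AUC below the
#' cut, and combines the rest by per-cell AUC-weighted mean. Per-pixel
#' uncertainty is the 2.5-97.5 percentile band of the kept members'
#' predictions.
#'
#' @param members list of `list(model = <podo_learner>, scores =
#'   <eval_scores>, ...)` entries, e.g. one per run.
#' @param stack covariate stack to predict over.
#' @param auc_cut exclusion threshold on member AUC (default 0.8).
#' @return an `ensemble_result`: grids `mean_suitability`, `ui_lower`,
#'   `ui_upper`; `member_scores` data.frame; `n_members_kept`; `weights`.
#' @export
build_ensemble <- function(members, stack, auc_cut = 0.8) {
  stopifnot(length(members) >= 1L, is_stack(stack))
  aucs <- vapply(members, function(m) m$scores$auc, numeric(1L))
  keep <- which(aucs >= auc_cut)
  if (!length(keep))
    stop(sprintf("no member reaches AUC >= %g (best AUC = %.3f)",
                 auc_cut, max(aucs)))
  preds <- vapply(members[keep],
                  function(m) as.vector(predict(m$model, stack)$values),
                  numeric(length(stack$grids[[1L]]$values)))
  w <- aucs[keep]
  mean_p <- as.vector(preds %*% (w / sum(w)))
  if (length(keep) == 1L) {
    lo <- hi <- preds[, 1L]
  } else {
    qs <- apply(preds, 1L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE, type = 7)
    lo <- qs[1L, ]; hi <- qs[2L, ]
  }
  tmpl <- stack$grids[[1L]]
  as_grid <- function(v) grid_create(matrix(v, nrow(tmpl$values),
                                            ncol(tmpl$values)),
                                     tmpl$origin_x, tmpl$origin_y,
                                     tmpl$cell_size, tmpl$nodata)
  sc <- data.frame(
    member = seq_along(members),
    kind = vapply(members, function(m) m$model$kind, character(1L)),
    pa_set = vapply(members, function(m) m$pa_set %||% NA_integer_,
                    numeric(1L)),
    split = vapply(members, function(m) m$split %||% NA_integer_,
                   numeric(1L)),
    auc = aucs,
    tss = vapply(members, function(m) m$scores$tss, numeric(1L)),
    pcc = vapply(members, function(m) m$scores$pcc, numeric(1L)),
    kept = seq_along(members) %in% keep)
  structure(list(mean_suitability = as_grid(mean_p), ui_lower = as_grid(lo),
                 ui_upper = as_grid(hi), member_scores = sc,
                 n_members_kept = length(keep), weights = w),
            class = "ensemble_result")
}

#' Threshold a suitability surface into a binary limits map
#'
#' @param mean_suitability suitability grid in `[0, 1]`.
#' @param threshold suitability cutoff in `[0, 1]`; cells with
#'   `value >= threshold` are suitable (1).
#' @return binary grid (`NA` propagates).
#' @export
binarize <- function(mean_suitability, threshold) {
  stopifnot(is_grid(mean_suitability), threshold >= 0, threshold <= 1)
  out <- (mean_suitability$values >= threshold) * 1
  grid_create(out, mean_suitability$origin_x, mean_suitability$origin_y,
              mean_suitability$cell_size, mean_suitability$nodata)
}

#' Partial dependence of a learner on one covariate
#'
#' Marginal effect curve: at each of `n_grid` values spanning the covariate's
#' observed range, the covariate is substituted into every training row and
#' predictions are averaged, marginalising over the remaining covariates.
#'
#' @param model a `podo_learner` (typically the BRT).
#' @param covariate covariate name.
#' @param n_grid number of evaluation points (default 25).
#' @param data rows to marginalise over (default: the training data).
#' @return data.frame with columns `value` and `response`.
#' @export
partial_dependence <- function(model, covariate, n_grid = 25L, data = NULL) {
  stopifnot(inherits(model, "podo_learner"))
  if (!covariate %in% model$covariates)
    stop("unknown covariate: ", covariate)
  data <- data %||% model$train
  vals <- seq(min(data[[covariate]]), max(data[[covariate]]),
              length.out = n_grid)
  resp <- vapply(vals, function(v) {
    d <- data
    d[[covariate]] <- v
    mean(predict(model, d))
  }, numeric(1L))
  data.frame(value = vals, response = resp)
}
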