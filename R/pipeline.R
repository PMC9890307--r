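#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()]:
#' the synthetic-landscape block plus the stage parameters of the suitability
#' ensemble, the geostatistical model and the burden overlay. Every
#' stochastic stage derives its stream from the single master `seed`.
#'
#' @param seed master RNG seed.
#' @param sim named list of [sim_config()] overrides. The pipeline default
#'   enlarges the survey to 150 villages: a demonstration run needs enough
#'   labelled villages for held-out member AUCs to be estimated stably
#'   against the 0.8 inclusion cut.
#' @param envelope list: `lo_pct`, `hi_pct` (presence percentiles).
#' @param pseudoabsence list: `n_per_set`, `n_sets`.
#' @param ensemble list: `learners`, `n_splits`, `train_frac`, `auc_cut`,
#'   `strict_auc_cut` (when `FALSE`, the default, a run where no member
#'   reaches the cut keeps the best member with a warning instead of
#'   erroring), `brt` (hyperparameter list).
#' @param geostat list: `method`, `mc_samples`, `n_sim`, `exceedance_threshold`.
#' @return validated `podo_config` list.
#' @export
podo_config <- function(seed = 1L, sim = list(),
                        envelope = list(), pseudoabsence = list(),
                        ensemble = list(), geostat = list()) {
  merge_defaults <- function(user, def) {
    def[names(user)] <- user
    def
  }
  cfg <- list(
    seed = as.integer(seed),
    sim = utils::modifyList(list(n_villages = 150L), sim),
    envelope = merge_defaults(envelope, list(lo_pct = 5, hi_pct = 95)),
    pseudoabsence = merge_defaults(pseudoabsence,
                                   list(n_per_set = 200L, n_sets = 5L)),
    ensemble = merge_defaults(ensemble, list(
      learners = c("glm", "brt", "rf"), n_splits = 2L, train_frac = 0.8,
      auc_cut = 0.8, strict_auc_cut = FALSE,
      brt = list(max_trees = 800L))),
    geostat = merge_defaults(geostat, list(
      method = "mcml", mc_samples = 300L, n_sim = 500L,
      exceedance_threshold = 0.01)))
  validate_config(cfg)
  structure(cfg, class = "podo_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, path, msg) if (!ok) stop(sprintf(
    "invalid config at %s: %s", path, msg), call. = FALSE)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed",
      "must be a single integer")
  chk(cfg$envelope$lo_pct >= 0 && cfg$envelope$hi_pct <= 100 &&
        cfg$envelope$lo_pct <= cfg$envelope$hi_pct,
      "envelope", "percentiles must satisfy 0 <= lo <= hi <= 100")
  chk(cfg$pseudoabsence$n_per_set >= 1, "pseudoabsence$n_per_set", ">= 1")
  chk(cfg$pseudoabsence$n_sets >= 1, "pseudoabsence$n_sets", ">= 1")
  chk(all(cfg$ensemble$learners %in% c("glm", "brt", "rf", "maxent")),
      "ensemble$learners", "unknown learner kind")
  chk(cfg$ensemble$train_frac > 0 && cfg$ensemble$train_frac < 1,
      "ensemble$train_frac", "must be in (0, 1)")
  chk(cfg$ensemble$auc_cut >= 0 && cfg$ensemble$auc_cut <= 1,
      "ensemble$auc_cut", "must be in [0, 1]")
  chk(cfg$geostat$method %in% c("mcml", "laplace"), "geostat$method",
      "must be 'mcml' or 'laplace'")
  chk(cfg$geostat$exceedance_threshold >= 0 &&
        cfg$geostat$exceedance_threshold <= 1,
      "geostat$exceedance_threshold", "must be in [0, 1]")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the [podo_config()]
#'   arguments.
#' @return a `podo_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(podo_config, raw[intersect(names(raw),
                                     names(formals(podo_config)))])
}

artifact <- function(outdir, ...) file.path(outdir, ...)

require_artifacts <- function(outdir, files, needed_stage) {
  missing <- files[!file.exists(artifact(outdir, files))]
  if (length(missing))
    stop(sprintf("missing upstream artifacts (%s); run stage '%s' first",
                 paste(missing, collapse = ", "), needed_stage))
}

update_manifest <- function(outdir, cfg, stage, outputs) {
  path <- artifact(outdir, "manifest.yaml")
  man <- if (file.exists(path)) yaml::read_yaml(path) else
    list(config_hash = NULL, seed = cfg$seed,
         package_version = as.character(utils::packageVersion("podomap")),
         stages = list(), timestamps = list())
  cfg_file <- artifact(outdir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  man$config_hash <- unname(tools::md5sum(cfg_file))
  man$seed <- cfg$seed
  man$stages[[stage]] <- outputs
  man$timestamps[[stage]] <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  yaml::write_yaml(man, path)
  invisible(man)
}

stage_simulate <- function(cfg, outdir) {
  sim <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  land <- simulate_landscape(sim)
  dir.create(artifact(outdir, "covariates"), showWarnings = FALSE,
             recursive = TRUE)
  dir.create(artifact(outdir, "truth"), showWarnings = FALSE)
  outs <- character()
  for (nm in land$covariates$names) {
    rel <- file.path("covariates", paste0(nm, ".asc"))
    write_asc(land$covariates$grids[[nm]], artifact(outdir, rel))
    outs <- c(outs, rel)
  }
  write_asc(land$suitability, artifact(outdir, "truth", "suitability.asc"))
  write_asc(land$prevalence, artifact(outdir, "truth", "prevalence.asc"))
  utils::write.csv(land$survey, artifact(outdir, "survey.csv"),
                   row.names = FALSE)
  write_asc(land$population, artifact(outdir, "population.asc"))
  write_asc(land$adult_fraction, artifact(outdir, "adult_fraction.asc"))
  write_asc(land$admin, artifact(outdir, "admin.asc"))
  yaml::write_yaml(list(seed = sim$seed, grid_shape = sim$grid_shape,
                        cell_size = sim$cell_size,
                        suitability_coefs = sim$suitability_coefs,
                        geostat_truth = sim$geostat_truth,
                        n_villages = sim$n_villages,
                        examined_range = sim$examined_range,
                        n_admin = sim$n_admin),
                   artifact(outdir, "truth.yaml"))
  c(outs, "truth/suitability.asc", "truth/prevalence.asc", "survey.csv",
    "population.asc", "adult_fraction.asc", "admin.asc", "truth.yaml")
}

read_covariate_stack <- function(outdir) {
  files <- list.files(artifact(outdir, "covariates"), pattern = "\\.asc$",
                      full.names = TRUE)
  nms <- sub("\\.asc$", "", basename(files))
  grid_stack(stats::setNames(lapply(files, read_asc), nms))
}

stage_suitability <- function(cfg, outdir) {
  require_artifacts(outdir, c("survey.csv", "covariates"), "simulate")
  stack <- read_covariate_stack(outdir)
  survey <- utils::read.csv(artifact(outdir, "survey.csv"))
  pres_pts <- survey[survey$endemic == 1L, ]
  abs_pts <- survey[survey$endemic == 0L, ]

  scr <- screen_covariates(stack, pres_pts, seed = cfg$seed + 10L)
  stack <- grid_stack(stack$grids[scr$retained])

  vals <- extract_at_points(stack, survey)
  pres_vals <- vals[survey$endemic == 1L, stack$names, drop = FALSE]
  abs_vals <- vals[survey$endemic == 0L, stack$names, drop = FALSE]
  env <- fit_envelope(pres_vals, cfg$envelope$lo_pct, cfg$envelope$hi_pct)
  pa_pts <- sample_pseudoabsences(stack, env,
                                  n_per_set = cfg$pseudoabsence$n_per_set,
                                  n_sets = cfg$pseudoabsence$n_sets,
                                  seed = cfg$seed + 11L, exclude = survey)
  pa_vals <- lapply(pa_pts, function(p)
    extract_at_points(stack, p)[, stack$names, drop = FALSE])
  runs <- make_runs(pres_vals, abs_vals, pa_vals,
                    n_splits = cfg$ensemble$n_splits,
                    train_frac = cfg$ensemble$train_frac,
                    seed = cfg$seed + 12L)
  members <- list()
  for (kind in cfg$ensemble$learners) for (r in runs) {
    hyper <- if (kind == "brt") cfg$ensemble$brt else list()
    hyper$seed <- cfg$seed + 13L
    model <- fit_learner(kind, r$train, hyper)
    members[[length(members) + 1L]] <- list(
      model = model, scores = evaluate(model, r$test),
      pa_set = r$pa_set, split = r$split)
  }
  auc_cut <- cfg$ensemble$auc_cut
  best_auc <- max(vapply(members, function(mm) mm$scores$auc, numeric(1L)))
  if (best_auc < auc_cut && !isTRUE(cfg$ensemble$strict_auc_cut)) {
    ## synthetic demo surveys can leave every member under the cut; keep the
    ## best member rather than aborting, and say so
    warning(sprintf(
      "no member reached AUC >= %g (best %.3f); keeping the best member only",
      auc_cut, best_auc), call. = FALSE)
    auc_cut <- best_auc
  }
  ens <- build_ensemble(members, stack, auc_cut)

  train_pts <- rbind(
    data.frame(x = survey$x, y = survey$y, label = survey$endemic),
    do.call(rbind, lapply(pa_pts, function(p)
      data.frame(x = p$x, y = p$y, label = 0L))))
  sc <- extract_at_points(grid_stack(list(s = ens$mean_suitability)),
                          train_pts)$s
  th <- select_threshold(sc, train_pts$label)
  limits <- binarize(ens$mean_suitability, th$threshold)

  write_asc(ens$mean_suitability, artifact(outdir, "suitability_mean.asc"))
  write_asc(ens$ui_lower, artifact(outdir, "suitability_lower.asc"))
  write_asc(ens$ui_upper, artifact(outdir, "suitability_upper.asc"))
  write_asc(limits, artifact(outdir, "limits.asc"))
  utils::write.csv(ens$member_scores,
                   artifact(outdir, "member_scores.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(seq_along(pa_pts), function(i)
    pa_pts[[i]])), artifact(outdir, "pseudoabsences.csv"), row.names = FALSE)
  yaml::write_yaml(lapply(unclass(env), as.numeric),
                   artifact(outdir, "envelope.yaml"))
  yaml::write_yaml(c(th, list(screened_out = scr$dropped,
                              auc_cut_effective = auc_cut,
                              n_members_kept = ens$n_members_kept)),
                   artifact(outdir, "threshold.yaml"))
  ## partial dependence of the best BRT member, when one was fitted
  brts <- which(vapply(members, function(mm) mm$model$kind,
                       character(1L)) == "brt")
  if (length(brts)) {
    best <- brts[which.max(vapply(members[brts],
                                  function(mm) mm$scores$auc, numeric(1L)))]
    pd <- do.call(rbind, lapply(stack$names, function(nm)
      cbind(covariate = nm,
            partial_dependence(members[[best]]$model, nm))))
    utils::write.csv(pd, artifact(outdir, "partial_dependence.csv"),
                     row.names = FALSE)
  }
  c("suitability_mean.asc", "suitability_lower.asc", "suitability_upper.asc",
    "limits.asc", "member_scores.csv", "pseudoabsences.csv", "envelope.yaml",
    "threshold.yaml")
}

stage_geostat <- function(cfg, outdir) {
  require_artifacts(outdir, c("survey.csv", "suitability_mean.asc",
                              "limits.asc"), "suitability")
  survey <- utils::read.csv(artifact(outdir, "survey.csv"))
  suit <- read_asc(artifact(outdir, "suitability_mean.asc"))
  limits <- read_asc(artifact(outdir, "limits.asc"))
  fit <- fit_geostat(survey, suit,
                     opts = list(method = cfg$geostat$method,
                                 mc_samples = cfg$geostat$mc_samples,
                                 seed = cfg$seed + 14L))
  pred <- predict_surface(fit, suit, limits, n_sim = cfg$geostat$n_sim,
                          threshold = cfg$geostat$exceedance_threshold,
                          seed = cfg$seed + 15L)
  vg <- variogram_validate(fit, n_perm = 499L, seed = cfg$seed + 16L)
  write_asc(pred$mean_prev, artifact(outdir, "prev_mean.asc"))
  write_asc(pred$lower95, artifact(outdir, "prev_lower.asc"))
  write_asc(pred$upper95, artifact(outdir, "prev_upper.asc"))
  write_asc(pred$sd, artifact(outdir, "prev_sd.asc"))
  write_asc(pred$se_count, artifact(outdir, "prev_se_count.asc"))
  write_asc(pred$exceedance, artifact(outdir, "exceedance.asc"))
  utils::write.csv(vg$variogram, artifact(outdir, "variogram.csv"),
                   row.names = FALSE)
  utils::write.csv(vg$envelope, artifact(outdir, "variogram_envelope.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(
    estimate = fit$estimate, se = fit$se, loglik = fit$loglik,
    converged = fit$converged, mc_samples = fit$mc_samples,
    variogram_pass = vg$pass, variogram_p = vg$p_value),
    artifact(outdir, "geostat_fit.yaml"))
  c("prev_mean.asc", "prev_lower.asc", "prev_upper.asc", "prev_sd.asc",
    "prev_se_count.asc", "exceedance.asc", "variogram.csv",
    "variogram_envelope.csv", "geostat_fit.yaml")
}

stage_burden <- function(cfg, outdir) {
  require_artifacts(outdir, c("prev_mean.asc", "prev_lower.asc",
                              "prev_upper.asc"), "geostat")
  require_artifacts(outdir, c("population.asc", "adult_fraction.asc",
                              "admin.asc", "survey.csv"), "simulate")
  pred <- structure(list(
    mean_prev = read_asc(artifact(outdir, "prev_mean.asc")),
    lower95 = read_asc(artifact(outdir, "prev_lower.asc")),
    upper95 = read_asc(artifact(outdir, "prev_upper.asc"))),
    class = "prediction_surface")
  pop <- read_asc(artifact(outdir, "population.asc"))
  af <- read_asc(artifact(outdir, "adult_fraction.asc"))
  admin <- read_asc(artifact(outdir, "admin.asc"))
  limits <- read_asc(artifact(outdir, "limits.asc"))
  survey <- utils::read.csv(artifact(outdir, "survey.csv"))
  cg <- cases_surface(pred, pop, af)
  tab <- aggregate_by_admin(cg, pop, limits, admin)
  area <- suitable_area(limits)
  par_tot <- population_at_risk(pop, limits)
  crude <- crude_prevalence(survey)
  utils::write.csv(tab, artifact(outdir, "burden_table.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(
    total_cases = tab$cases_mean[tab$admin_id == "total"],
    total_cases_lower = tab$cases_lower[tab$admin_id == "total"],
    total_cases_upper = tab$cases_upper[tab$admin_id == "total"],
    population_at_risk = par_tot$total,
    suitable_area_km2 = area$area_km2,
    suitable_fraction_pct = area$fraction_pct,
    crude_prevalence_pct = crude$percent),
    artifact(outdir, "national_summary.yaml"))
  c("burden_table.csv", "national_summary.yaml")
}

stage_report <- function(cfg, outdir) {
  require_artifacts(outdir, c("national_summary.yaml", "geostat_fit.yaml",
                              "threshold.yaml"), "burden")
  rep <- list(
    national = yaml::read_yaml(artifact(outdir, "national_summary.yaml")),
    geostat = yaml::read_yaml(artifact(outdir, "geostat_fit.yaml")),
    suitability_threshold = yaml::read_yaml(artifact(outdir,
                                                     "threshold.yaml")))
  yaml::write_yaml(rep, artifact(outdir, "report.yaml"))
  "report.yaml"
}

#' Run the mapping pipeline
#'
#' Orchestrates the stages in dependency order, writing every artifact (ASCII
#' grids, CSV tables, YAML summaries) plus a manifest recording the config
#' hash, master seed, package version and per-stage outputs, to `outdir`.
#' Identical configurations reproduce identical outputs (the manifest differs
#' only in its timestamps).
#'
#' @param stage one of `"simulate"`, `"suitability"`, `"geostat"`,
#'   `"burden"`, `"report"`, `"all"`.
#' @param config a [podo_config()], a YAML path, or `NULL` for defaults.
#' @param outdir output directory (created if needed).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "suitability",
                                   "geostat", "burden", "report"),
                         config = NULL, outdir = "podomap_run") {
  stage <- match.arg(stage)
  cfg <- if (is.null(config)) podo_config()
  else if (is.character(config)) read_config(config)
  else { validate_config(config); config }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all")
    c("simulate", "suitability", "geostat", "burden", "report") else stage
  man <- NULL
  for (st in stages) {
    message(sprintf("[podomap] stage %s (seed %d)", st, cfg$seed))
    outputs <- switch(st,
      simulate = stage_simulate(cfg, outdir),
      suitability = stage_suitability(cfg, outdir),
      geostat = stage_geostat(cfg, outdir),
      burden = stage_burden(cfg, outdir),
      report = stage_report(cfg, outdir))
    man <- update_manifest(outdir, cfg, st, as.list(outputs))
  }
  invisible(man)
}
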