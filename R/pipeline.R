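#' Worked-example feature fixture
#'
#' The six published worked examples of the score: per case the MPA outlet
#' CSA (100 mm^2), MPA outlet hydraulic diameter (10 mm) and MPA
#' bifurcation area (100 mm^2), with the score each case displays (2
#' decimals). Cases are labelled B-G after the source panels.
#'
#' @return data.frame with columns `case`, `MPA outlet CSA`,
#'   `MPA outlet hydraulic diameter`, `MPA bifurcation area`,
#'   `expected_score`.
#' @export
make_fig3_fixture <- function() {
  data.frame(
    case = c("B", "C", "D", "E", "F", "G"),
    `MPA outlet CSA` = c(7.68, 13.04, 6.74, 15.04, 9.34, 11.72),
    `MPA outlet hydraulic diameter` = c(2.94, 3.40, 2.88, 4.15, 2.76,
                                        3.45),
    `MPA bifurcation area` = c(0.84, 5.78, 0.79, 4.07, 0.88, 5.57),
    expected_score = c(3.01, 8.32, 2.84, 7.32, 3.12, 8.02),
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Exclusion-flow accounting
#'
#' Applies a sequence of labelled exclusion counts to an initial record
#' count and reports the running balance -- the generic form of a study
#' inclusion flow chart. The reference study's flow is the default: 391
#' initial records, seven exclusion groups, 296 enrolled.
#'
#' @param n_initial initial record count.
#' @param exclusions named integer vector of exclusion counts.
#' @return list with `n_initial`, `exclusions`, `n_excluded`, `n_enrolled`,
#'   `flow` (data.frame of running counts).
#' @export
exclusion_flow <- function(n_initial = 391,
                           exclusions = c(
                             "no CTPA data" = 17,
                             "reperfusion before CTPA" = 5,
                             "cor pulmonale" = 10,
                             "malignancy" = 2,
                             "heart failure" = 13,
                             "pregnancy" = 2,
                             "missing biomarkers/echocardiography" = 46)) {
  if (any(exclusions < 0) || any(exclusions != round(exclusions)))
    stop("exclusion_flow: exclusion counts must be nonnegative integers")
  running <- n_initial - cumsum(exclusions)
  if (any(running < 0))
    stop("exclusion_flow: exclusions exceed the record count")
  list(n_initial = n_initial,
       exclusions = exclusions,
       n_excluded = sum(exclusions),
       n_enrolled = n_initial - sum(exclusions),
       flow = data.frame(step = names(exclusions),
                         excluded = as.integer(exclusions),
                         remaining = as.integer(running)))
}

#' Pipeline run configuration
#'
#' A declarative description of a full synthetic run: which stages to
#' execute, where artifacts go, the seeds of every stochastic stage, and
#' the score-formula source. Round-trips through YAML unchanged.
#'
#' @param stages character subset of
#'   `c("geometry", "measure", "cohort", "fit", "score", "evaluate")`.
#' @param out_dir artifact directory.
#' @param seeds named list/vector with `geometry`, `cohort`, `folds`.
#' @param formula `"paper"` for the published score or a path to a formula
#'   JSON.
#' @param geometry optional list of [bifurcation_spec()] arguments.
#' @param cohort optional list of [cohort_spec()] arguments.
#' @return object of class `run_config`.
#' @export
run_config <- function(stages = c("geometry", "measure", "cohort", "fit",
                                  "score", "evaluate"),
                       out_dir = "pabifurc-run",
                       seeds = list(geometry = 1L, cohort = 1L, folds = 1L),
                       formula = "paper",
                       geometry = list(),
                       cohort = list()) {
  known <- c("geometry", "measure", "cohort", "fit", "score", "evaluate")
  if (!all(stages %in% known))
    stop("run_config: unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  need <- c("geometry", "cohort", "folds")
  if (!all(need %in% names(seeds)))
    stop("run_config: seeds must name ", paste(need, collapse = ", "))
  structure(list(stages = stages, out_dir = out_dir,
                 seeds = lapply(seeds, as.integer), formula = formula,
                 geometry = geometry, cohort = cohort),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Execute a pipeline run
#'
#' Runs the enabled stages in order -- generate geometry, measure it,
#' simulate a cohort, fit the LASSO score on the training set, score the
#' worked-example fixture and the cohort, evaluate ROC/PR/DCA per set --
#' writing each artifact under the configured directory, and returns a
#' manifest with a config hash and per-artifact checksums. Stages are
#' deterministic given the configured seeds, so re-running an identical
#' config reproduces identical checksums.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return object of class `run_manifest`: `config_hash`, `version`,
#'   `stages` (status per stage), `checksums` (md5 per artifact file).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pabifurc] ", ...)
  status <- list()
  art <- character(0)
  add_art <- function(p) art <<- c(art, p)

  if ("geometry" %in% config$stages) {
    say("stage geometry")
    spec <- do.call(bifurcation_spec,
                    c(config$geometry,
                      list(seed = config$seeds$geometry)))
    gm <- generate_bifurcation_mesh(spec)
    mesh_path <- file.path(config$out_dir, "mesh.ply")
    write_mesh(gm$surface, mesh_path); add_art(mesh_path)
    gt_path <- file.path(config$out_dir, "ground_truth.json")
    write_ground_truth(gm$truth, gt_path); add_art(gt_path)
    status$geometry <- "ok"
    if ("measure" %in% config$stages) {
      say("stage measure")
      met <- measure_vessel(gm$surface)
      met_path <- file.path(config$out_dir, "metrics.json")
      write_metrics(met, met_path); add_art(met_path)
      status$measure <- "ok"
    }
  } else if ("measure" %in% config$stages) {
    stop("run_pipeline: measure stage requires the geometry stage")
  }

  cohort <- NULL
  if ("cohort" %in% config$stages) {
    say("stage cohort")
    cspec <- do.call(cohort_spec,
                     c(config$cohort, list(seed = config$seeds$cohort)))
    cohort <- simulate_cohort(cspec)
    cpath <- file.path(config$out_dir, "cohort.csv")
    write_cohort_csv(cohort, cpath); add_art(cpath)
    status$cohort <- "ok"
  }

  formula <- if (identical(config$formula, "paper")) paper_formula()
  else read_formula(config$formula)

  if ("fit" %in% config$stages) {
    if (is.null(cohort)) stop("run_pipeline: fit stage requires cohort")
    say("stage fit")
    fit <- fit_lasso_cv(cohort, seed = config$seeds$folds)
    fml <- extract_formula(fit, "1se")
    fpath <- file.path(config$out_dir, "fitted_formula.json")
    write_formula(fml, fpath); add_art(fpath)
    status$fit <- "ok"
  }

  if ("score" %in% config$stages) {
    say("stage score")
    fx <- make_fig3_fixture()
    fx$score <- sprintf("%.2f", apply_formula(paper_formula(), fx))
    spath <- file.path(config$out_dir, "worked_examples.csv")
    write.csv(fx, spath, row.names = FALSE); add_art(spath)
    if (!is.null(cohort)) {
      sc <- data.frame(score = sprintf(
        "%.2f", .predict_formula_df(formula, cohort)),
        event = cohort$event, set = cohort$set)
      cpath2 <- file.path(config$out_dir, "scores.csv")
      write.csv(sc, cpath2, row.names = FALSE); add_art(cpath2)
    }
    status$score <- "ok"
  }

  if ("evaluate" %in% config$stages) {
    if (is.null(cohort)) stop("run_pipeline: evaluate stage requires cohort")
    say("stage evaluate")
    ev <- evaluate_sets(cohort, formula, seed = config$seeds$folds)
    report <- lapply(ev, function(e) list(
      auc_score = e$roc_score$auc, auc_score_ci = e$roc_score$ci,
      auc_dilation = e$roc_dilation$auc,
      delta_auc = e$delong$delta, delong_p = e$delong$p_value,
      youden_cutoff = e$roc_score$youden$cutoff,
      mean_precision_score = e$pr_score$mean_precision,
      mean_precision_dilation = e$pr_dilation$mean_precision))
    rpath <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(report, rpath, auto_unbox = TRUE, digits = 6)
    add_art(rpath)
    for (st in names(ev)) {
      dpath <- file.path(config$out_dir, paste0("dca_", st, ".csv"))
      dd <- ev[[st]]$dca_score
      dd$net_benefit <- signif(dd$net_benefit, 6)
      dd$treat_all <- signif(dd$treat_all, 6)
      write.csv(dd, dpath, row.names = FALSE); add_art(dpath)
    }
    status$evaluate <- "ok"
  }

  # the config hash identifies the run (stages, seeds, parameters), not
  # its location on disk
  cfg_id <- unclass(config)
  cfg_id$out_dir <- NULL
  cfg_yaml <- yaml::as.yaml(cfg_id)
  manifest <- structure(list(
    config_hash = unname(tools::md5sum(
      {tf <- tempfile(); writeLines(cfg_yaml, tf); tf})),
    version = as.character(utils::packageVersion("pabifurc")),
    stages = status,
    checksums = if (length(art)) tools::md5sum(art) else character(0)),
    class = "run_manifest")
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(list(config_hash = manifest$config_hash,
                            version = manifest$version,
                            stages = manifest$stages,
                            checksums = as.list(manifest$checksums)),
                       mpath, auto_unbox = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest v", x$version, ">\n", sep = "")
  for (s in names(x$stages)) cat(" ", s, ":", x$stages[[s]], "\n")
  cat(" ", length(x$checksums), "artifact(s)\n")
  invisible(x)
}
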