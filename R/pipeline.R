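#' Configured end-to-end pipeline runs
#'
#' Orchestrates simulate -> process -> metrics -> compare -> model as
#' reproducible, logged stages writing CSV/JSON artifacts into a run
#' directory. The YAML run configuration mirrors [default_config()] plus a
#' `run` block (seed, mesh/cohort settings); unknown keys are rejected.
#'
#' @name cli_pipeline
NULL

#' Read and validate a YAML run configuration
#'
#' @param path YAML file; when NULL returns the defaults
#' @return validated nested configuration list
#' @export
read_run_config <- function(path = NULL) {
  base <- default_config()
  base$run <- list(seed = 1, mode = "metrics",
                   groups = c("HCM_VF", "HCM"),
                   counts = c(17, 20),
                   phases = c("peak", "recovery"),
                   mesh = list(n_rings = 22, n_segments = 9,
                               apex_base_mm = 90, radius_mm = 14),
                   measures = c("recovery_mean_at", "recovery_mean_ari",
                                "peak_mean_ari", "peak_grad_at"),
                   preset_file = NULL)
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop("config file not found: ", path)
  merge_config(base, yaml::read_yaml(path))
}

#' Run the pipeline stages
#'
#' Stages: `simulate` (cohort generation), `process`+`metrics` (waveform
#' cohorts only; raw strips to heart metrics), `compare` (group statistics),
#' `model` (screen, collinearity, stepwise logistic, cross-validation).
#' Later stages read the artifacts of earlier ones from `out_dir`, so a
#' stage whose inputs are missing raises a dependency error naming the
#' missing artifact.
#'
#' @param config configuration list from [read_run_config()]
#' @param out_dir run directory
#' @param stages subset of `c("simulate", "process", "compare", "model")`
#' @return `out_dir`, invisibly
#' @export
run_pipeline <- function(config = read_run_config(), out_dir,
                         stages = c("simulate", "process", "compare", "model")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create run directory: ", out_dir)
  run <- config$run
  presets <- load_presets(run$preset_file)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                                "\n", sep = "", file = logf, append = TRUE)
  feat_path <- file.path(out_dir, "feature_table.csv")
  metrics_path <- file.path(out_dir, "heart_metrics.csv")

  mesh <- do.call(mesh_spheroid, run$mesh)

  if ("simulate" %in% stages) {
    counts <- stats::setNames(as.integer(run$counts), run$groups)
    log_line("simulate: mode=", run$mode, " seed=", run$seed,
             " counts=", paste(run$counts, collapse = "/"))
    generate_cohort(presets, counts, mesh = mesh, out_dir = out_dir,
                    seed = run$seed, mode = run$mode, phases = run$phases)
  }

  if ("process" %in% stages && identical(run$mode, "waveform")) {
    sig_files <- list.files(out_dir, "_signals\\.csv$", full.names = TRUE)
    if (!length(sig_files))
      stop("dependency error: no *_signals.csv in ", out_dir,
           " (run the simulate stage in waveform mode first)")
    nbr <- neighbor_index(mesh, config$markers$radius_mm)
    rows <- list()
    for (f in sig_files) {
      sc <- jsonlite::read_json(sub("\\.csv$", ".json", f),
                                simplifyVector = TRUE)
      sig <- as.matrix(utils::read.csv(f))
      pr <- process_subject(sig, sc$fs_hz, mesh, config = config[
        intersect(names(config), c("preprocess", "delineate", "markers"))],
        nbr = nbr)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject = sc$subject_id, group = sc$group,
                   phase = sc$phase), as.data.frame(pr$metrics))
      rej <- pr$markers[!pr$markers$accepted, ]
      if (nrow(rej))
        log_line("process: ", sc$subject_id, "/", sc$phase, " rejected ",
                 nrow(rej), " nodes (",
                 paste(unique(rej$reason), collapse = ","), ")")
    }
    hm <- do.call(rbind, rows)
    utils::write.csv(hm, metrics_path, row.names = FALSE)
    # reshape to one row per subject for downstream modelling
    wide <- stats::reshape(
      hm, direction = "wide", idvar = c("subject", "group"),
      timevar = "phase",
      v.names = setdiff(names(hm), c("subject", "group", "phase")))
    names(wide) <- sub("^(.*)\\.(peak|recovery)$", "\\2_\\1", names(wide))
    utils::write.csv(wide, feat_path, row.names = FALSE)
  }

  if ("compare" %in% stages) {
    if (!file.exists(feat_path))
      stop("dependency error: missing ", feat_path,
           " (run the simulate/process stages first)")
    feat <- utils::read.csv(feat_path)
    grp <- unique(feat$group)
    meas <- grep("^(peak|recovery)_(mean|disp|grad)_", names(feat),
                 value = TRUE)
    cmp <- list()
    for (i in seq_along(grp)) for (j in seq_len(i - 1L)) {
      cmp[[length(cmp) + 1L]] <-
        compare_groups(feat, grp[i], grp[j], meas)
    }
    utils::write.csv(do.call(rbind, cmp),
                     file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    log_line("compare: ", length(cmp), " group pair(s), ",
             length(meas), " measures")
  }

  if ("model" %in% stages) {
    if (!file.exists(feat_path))
      stop("dependency error: missing ", feat_path,
           " (run the simulate/process stages first)")
    feat <- utils::read.csv(feat_path)
    feat <- feat[feat$group %in% c("HCM_VF", "HCM"), ]
    if (!nrow(feat)) stop("model stage needs HCM_VF and HCM subjects")
    mcfg <- config$model
    cand <- intersect(run$measures, names(feat))
    qual <- screen_univariate(feat, cand, alpha = mcfg$alpha)
    log_line("model: qualifying measures: ", paste(qual, collapse = ", "))
    sel <- drop_collinear(feat, if (length(qual)) qual else cand,
                          r_threshold = mcfg$r_threshold)
    step <- backward_stepwise(feat, sel, p_stop = mcfg$p_stop)
    log_line("model: removal order: ",
             paste(step$removal_order, collapse = " -> "))
    report <- list(candidates = cand, qualifying = qual,
                   collinear_dropped = attr(sel, "dropped"),
                   retained = step$retained,
                   removal_order = step$removal_order)
    if (!is.null(step$fit)) {
      cv <- crossvalidate(feat, step$retained, k = mcfg$k_folds,
                          repeats = mcfg$repeats, seed = run$seed,
                          threshold = mcfg$threshold)
      report <- c(report, list(
        coefficients = as.list(step$fit$coef),
        odds_ratios = step$fit$or,
        llr_p = step$fit$llr_p,
        cv = list(auc = cv$auc, auc_ci = cv$ci$auc,
                  balanced_accuracy = cv$balanced_accuracy,
                  balanced_accuracy_ci = cv$ci$balanced_accuracy,
                  acc_pos = cv$acc_pos, acc_neg = cv$acc_neg,
                  youden_sensitivity = cv$youden$sensitivity,
                  youden_specificity = cv$youden$specificity,
                  k = cv$k, repeats = cv$repeats)))
      utils::write.csv(cv$predictions,
                       file.path(out_dir, "cv_predictions.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
  }

  manifest <- list(seed = run$seed, stages = stages,
                   config_sha = unname(tools::md5sum(
                     write_config_tmp(config, out_dir))),
                   package = paste0("epimapr ",
                                    as.character(utils::packageVersion("epimapr"))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @keywords internal
#' @noRd
write_config_tmp <- function(config, out_dir) {
  p <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(config, p)
  p
}
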