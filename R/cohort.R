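#' Synthetic subjects and cohorts
#'
#' A simulated subject is a set of calibrated truth fields on a mesh plus,
#' in full-waveform mode, a raw multi-beat signals matrix (samples x nodes)
#' realizing those fields. Cohorts combine seeded subjects from the group
#' presets; the fast metrics-only mode samples whole-heart measures directly
#' from the preset distributions without synthesizing waveforms.
#'
#' @name synthetic_cohort
NULL

#' Simulate one subject (truth fields + raw signals)
#'
#' Samples subject-level target metrics, pattern flags and heart rate from
#' the group preset, builds calibrated truth fields, and synthesizes the raw
#' electrogram strip for the requested phase.
#'
#' @param presets a `group_presets`
#' @param group group label
#' @param phase `"peak"` or `"recovery"`
#' @param mesh an `epi_mesh`
#' @param seed integer seed (one subject = one seed)
#' @param params waveform parameters
#' @param targets optional pre-sampled target row (overrides sampling)
#' @param patterns optional pattern flag list (overrides sampling)
#' @param waveform if FALSE skip signal synthesis (truth only)
#' @param grad_fn optional precomputed [gradient_operator()] for `mesh`
#' @return list with `truth` (a `subject_truth`), `signals`, `fs`, `hr_bpm`,
#'   `rr_ms`, `onsets`, `h`, `group`, `phase`
#' @export
simulate_subject <- function(presets, group, phase, mesh, seed,
                             params = NULL, targets = NULL, patterns = NULL,
                             waveform = TRUE, grad_fn = NULL) {
  params <- params %||% do.call(waveform_params, presets$waveform %||% list())
  seeds <- spawn_seeds(seed, 4L)
  if (is.null(targets)) {
    tt <- sample_subject_metrics(presets, group, phase, n = 1, seed = seeds[1])
    targets <- as.list(stats::setNames(
      as.numeric(tt[1, paste0(phase, "_", preset_measures())]),
      preset_measures()))
  }
  if (is.null(patterns)) {
    pf <- sample_pattern_flags(presets, group, 1, seed = seeds[2])
    patterns <- as.list(pf[1, ])
  }
  truth <- build_truth_fields(targets, mesh, patterns, seed = seeds[3],
                              field_cfg = presets$field, grad_fn = grad_fn)
  hr <- sample_heart_rates(presets, group, 1, seed = seeds[4])
  hr_bpm <- if (phase == "peak") hr$peak_hr else hr$recovery_hr
  out <- list(truth = truth, group = group, phase = phase, hr_bpm = hr_bpm)
  if (waveform) {
    syn <- synthesize_subject_signals(truth, params, 60000 / hr_bpm,
                                      seed = seeds[4])
    out <- c(out, syn[c("signals", "fs", "onsets", "rr_ms", "rr_mean_ms", "ld")])
  }
  out
}

#' Process a raw signals matrix into per-node markers and heart metrics
#'
#' The full processing chain for one subject/phase: zero-phase baseline
#' filtering of every node trace, beat detection and template selection on
#' the cross-node RMS composite (so that regions of interest are common to
#' all nodes and inter-node timing is preserved), template matching,
#' signal averaging, delineation, quality rejection, marker extraction and
#' whole-heart metric assembly.
#'
#' @param signals samples x nodes voltage matrix (mV)
#' @param fs sampling rate (Hz)
#' @param mesh the `epi_mesh` the columns live on (column j = node j)
#' @param config optional configuration overrides (see [default_config()]):
#'   keys under `preprocess`, `delineate`, `markers`
#' @param nbr optional precomputed neighbour index for the gradient metric
#' @return list with `metrics` (a `heart_metrics` row), `markers` (per-node
#'   data.frame), `delineations`, `egms`, `windows`, `t0`
#' @export
process_subject <- function(signals, fs, mesh, config = NULL, nbr = NULL) {
  cfg <- merge_config(default_config(), config)
  pp <- cfg$preprocess
  filt <- remove_baseline_matrix(signals, fs, pp$cutoff_hz)
  composite <- sqrt(rowMeans(filt^2))
  dl <- cfg$delineate
  n_nodes <- ncol(filt)

  run_pass <- function(alt_phase) {
    tpl <- pick_template(composite, fs, pre_ms = pp$pre_ms,
                         max_post_ms = pp$max_post_ms,
                         alt_phase = alt_phase)
    rois <- match_rois(composite, tpl, k = pp$k_beats,
                       corr_floor = pp$corr_floor)
    lags <- rep(0L, length(rois))
    egms <- vector("list", n_nodes)
    delins <- vector("list", n_nodes)
    for (j in seq_len(n_nodes)) {
      egm <- signal_average(rois, filt[, j], fs, node_id = mesh$node_ids[j],
                            lags = lags)
      d <- tryCatch(
        delineate_egm(egm, theta_qrs = dl$theta_qrs, theta_t = dl$theta_t,
                      smooth_ms = cfg$markers$smoothing_ms),
        error = function(e) NULL)
      if (is.null(d)) {
        d <- list(qrs_on = NA_integer_, qrs_off = NA_integer_,
                  t_on = NA_integer_, t_off = NA_integer_,
                  labels = NULL, quality = "rejected_no_qrs")
        class(d) <- "delineation"
      } else {
        d <- assess_quality(egm, d, t_amp_frac = dl$t_amp_frac,
                            max_deflections = dl$max_deflections,
                            prominence_frac = dl$deflection_prominence)
      }
      egms[[j]] <- egm
      delins[[j]] <- d
    }
    list(egms = egms, delins = delins, rois = rois,
         n_acc = sum(vapply(delins, function(d)
           identical(d$quality, "accepted"), logical(1))))
  }

  pass <- run_pass(FALSE)
  # if the windows rotated into the wrong part of the cycle (T before QRS),
  # most nodes lose their T wave; retry anchored on the alternate phase
  if (pass$n_acc < 0.5 * n_nodes) {
    alt <- run_pass(TRUE)
    if (alt$n_acc > pass$n_acc) pass <- alt
  }
  mk <- node_markers(pass$egms, pass$delins,
                     smooth_ms = cfg$markers$smoothing_ms)
  metrics <- heart_metrics(mk, mesh, radius = cfg$markers$radius_mm, nbr = nbr,
                           gradient_method = cfg$markers$gradient_method)
  t0 <- global_qrs_start(pass$delins)
  list(metrics = metrics, markers = mk, delineations = pass$delins,
       egms = pass$egms, windows = pass$rois, t0 = t0)
}

#' Default run configuration
#'
#' All tunable parameters of the processing chain with their documented
#' defaults. Any subset can be overridden via the YAML run configuration or
#' the `config` argument of [process_subject()].
#'
#' @return nested list of configuration defaults
#' @export
default_config <- function() {
  list(
    preprocess = list(cutoff_hz = 0.5, corr_floor = 0.8, k_beats = 10,
                      pre_ms = 80, max_post_ms = 520),
    delineate = list(theta_qrs = 0.2, theta_t = 0.15, t_amp_frac = 0.05,
                     max_deflections = 3, deflection_prominence = 0.1),
    markers = list(radius_mm = 5, gradient_method = "plane",
                   smoothing_ms = 10),
    model = list(alpha = 0.05, r_threshold = 0.9, p_stop = 0.15,
                 k_folds = 5, repeats = 20, threshold = 0.5)
  )
}

#' @keywords internal
#' @noRd
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      unknown <- setdiff(names(override[[k]]), names(base[[k]]))
      if (length(unknown))
        stop("unknown config key(s): ", k, ".",
             paste(unknown, collapse = paste0(", ", k, ".")))
      base[[k]] <- utils::modifyList(base[[k]], override[[k]])
    } else if (k %in% names(base)) {
      base[[k]] <- override[[k]]
    } else {
      stop("unknown config key: ", k)
    }
  }
  base
}

#' Generate a synthetic cohort on disk
#'
#' Metrics-only mode samples whole-heart measures from the preset
#' distributions and writes a feature table CSV. Full-waveform mode writes,
#' per subject and phase, the raw signals matrix (CSV), a JSON sidecar
#' (sampling rate, units, node ids, phase, subject id), and the truth table
#' CSV, along with the feature table of achieved truth metrics. A manifest
#' JSON records seeds, preset file hash, mode and counts.
#'
#' @param presets a `group_presets`
#' @param counts named integer vector of subjects per group
#' @param mesh an `epi_mesh` (full-waveform mode)
#' @param out_dir output directory (created if missing)
#' @param seed root seed; per-subject seeds are spawned from it
#' @param mode `"metrics"` or `"waveform"`
#' @param phases phases to generate
#' @param params waveform parameters
#' @return the manifest, invisibly
#' @export
generate_cohort <- function(presets, counts, mesh = NULL, out_dir,
                            seed = 1, mode = c("metrics", "waveform"),
                            phases = c("peak", "recovery"),
                            params = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(counts >= 1), !is.null(names(counts)))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  groups <- names(counts)
  group_seeds <- spawn_seeds(seed, length(groups))
  rows <- list()
  if (mode == "metrics") {
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      tab <- sample_subject_metrics(presets, g, phase = "both",
                                    n = counts[[gi]], seed = group_seeds[gi])
      pf <- sample_pattern_flags(presets, g, counts[[gi]],
                                 seed = group_seeds[gi] + 1L)
      rows[[gi]] <- cbind(tab, pf)
    }
    feat <- do.call(rbind, rows)
    feat$subject <- sprintf("S%03d", seq_len(nrow(feat)))
  } else {
    if (is.null(mesh)) stop("full-waveform mode needs a mesh")
    grad_fn <- gradient_operator(mesh, 5)
    sid <- 0L
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      subj_seeds <- spawn_seeds(group_seeds[gi], counts[[gi]])
      for (si in seq_len(counts[[gi]])) {
        sid <- sid + 1L
        subject <- sprintf("S%03d", sid)
        phase_rows <- list()
        for (ph in phases) {
          sim <- simulate_subject(presets, g, ph, mesh,
                                  seed = subj_seeds[si], params = params,
                                  grad_fn = grad_fn)
          write_subject_files(sim, subject, out_dir)
          phase_rows[[ph]] <- data.frame(
            subject = subject, group = g, phase = ph,
            as.data.frame(sim$truth$achieved),
            hr_bpm = sim$hr_bpm)
        }
        rows[[length(rows) + 1L]] <- do.call(rbind, phase_rows)
      }
    }
    feat <- do.call(rbind, rows)
  }
  feat_path <- file.path(out_dir, "feature_table.csv")
  utils::write.csv(feat, feat_path, row.names = FALSE)
  manifest <- list(
    mode = mode, seed = seed, counts = as.list(counts), phases = phases,
    preset_file = basename(presets$path),
    preset_sha = unname(tools::md5sum(presets$path)),
    n_subjects = if (mode == "metrics") nrow(feat) else length(rows),
    created_by = paste0("epimapr ", as.character(utils::packageVersion("epimapr")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @keywords internal
#' @noRd
write_subject_files <- function(sim, subject, out_dir) {
  stem <- file.path(out_dir, paste0(subject, "_", sim$phase))
  utils::write.csv(round(sim$signals, 5), paste0(stem, "_signals.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(fs_hz = sim$fs, units = "mV",
         node_ids = sim$truth$node_ids %||% seq_along(sim$truth$at_ms),
         phase = sim$phase, subject_id = subject, group = sim$group,
         hr_bpm = sim$hr_bpm, rr_mean_ms = sim$rr_mean_ms),
    paste0(stem, "_signals.json"), auto_unbox = TRUE, digits = NA)
  truth_df <- data.frame(node_id = seq_along(sim$truth$at_ms),
                         at_ms = sim$truth$at_ms, rt_ms = sim$truth$rt_ms,
                         ari_ms = sim$truth$ari_ms,
                         polarity = sim$truth$t_polarity)
  utils::write.csv(truth_df, paste0(stem, "_truth.csv"), row.names = FALSE)
  invisible(stem)
}

#' Extract heart metrics for a list of simulated subjects
#'
#' Convenience wrapper running [process_subject()] over subjects from
#' [simulate_subject()] and binding the per-subject whole-heart metrics.
#'
#' @param sims list of simulated subjects (full-waveform)
#' @param mesh the shared `epi_mesh`
#' @param config optional configuration overrides
#' @return data.frame of per-subject metrics with group/phase columns
#' @export
extract_cohort_metrics <- function(sims, mesh, config = NULL) {
  nbr <- neighbor_index(mesh, (merge_config(default_config(), config))$markers$radius_mm)
  rows <- lapply(seq_along(sims), function(i) {
    s <- sims[[i]]
    pr <- process_subject(s$signals, s$fs, mesh, config = config, nbr = nbr)
    cbind(data.frame(subject = i, group = s$group, phase = s$phase),
          as.data.frame(pr$metrics))
  })
  do.call(rbind, rows)
}
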