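#' Group presets for the synthetic cohort generator
#'
#' Presets hold, per study group and exercise phase, the distribution
#' (mean, SD) of each whole-heart measure, the heart-rate distribution, the
#' qualitative pattern injection probabilities, the subject-level
#' inter-measure correlation structure, and the waveform/field synthesis
#' defaults. They are stored in a versioned YAML file rather than code; the
#' packaged default can be replaced via `path`.
#'
#' @param path YAML preset file; defaults to the packaged preset file
#' @return a `group_presets` list
#' @export
load_presets <- function(path = NULL) {
  path <- path %||% system.file("extdata", "group_presets.yaml",
                                package = "epimapr")
  if (!nzchar(path) || !file.exists(path))
    stop("preset file not found: ", path)
  p <- yaml::read_yaml(path)
  for (g in names(p$groups)) {
    for (ph in c("peak", "recovery")) {
      blk <- p$groups[[g]][[ph]]
      for (m in names(blk)) {
        if (!is.numeric(blk[[m]]$sd) || blk[[m]]$sd < 0)
          stop("preset ", g, "/", ph, "/", m, ": sd must be >= 0")
      }
    }
    pr <- p$groups[[g]]$patterns
    if (any(unlist(pr) < 0 | unlist(pr) > 1))
      stop("preset ", g, ": pattern probabilities must be in [0, 1]")
  }
  p$path <- path
  class(p) <- "group_presets"
  p
}

# Canonical measure names in a fixed order, per phase.
#' @keywords internal
#' @noRd
preset_measures <- function() {
  c("mean_at", "disp_at", "grad_at", "mean_ari", "disp_ari", "grad_ari")
}

#' Assemble the subject-level inter-measure correlation matrix
#'
#' Builds the correlation matrix over `phase_measure` pairs (e.g.
#' `recovery_mean_at`) from the preset's within-phase block, cross-phase
#' same-measure entries, scaled cross-phase cross-measure entries, and
#' explicit overrides, then projects to a positive-definite correlation
#' matrix by eigenvalue clipping (floor 1e-4) and re-standardization.
#'
#' @param presets a `group_presets`
#' @param vars character vector of `phase_measure` names (default: all 12)
#' @return correlation matrix with `vars` as dimnames
#' @export
measure_correlation <- function(presets, vars = NULL) {
  meas <- preset_measures()
  co <- presets$correlations
  wkey <- function(a, b) {
    k1 <- paste0(a, ".", b); k2 <- paste0(b, ".", a)
    co$within_phase[[k1]] %||% co$within_phase[[k2]] %||% co$within_phase$default
  }
  W <- diag(6); dimnames(W) <- list(meas, meas)
  for (a in meas) for (b in meas) if (a != b) W[a, b] <- wkey(a, b)
  all_vars <- c(paste0("peak_", meas), paste0("recovery_", meas))
  R <- diag(12); dimnames(R) <- list(all_vars, all_vars)
  for (a in meas) for (b in meas) {
    R[paste0("peak_", a), paste0("peak_", b)] <- W[a, b]
    R[paste0("recovery_", a), paste0("recovery_", b)] <- W[a, b]
    v <- if (a == b) (co$cross_phase_same[[a]] %||% co$cross_phase_same$default)
         else co$cross_phase_scale * W[a, b]
    R[paste0("peak_", a), paste0("recovery_", b)] <- v
    R[paste0("recovery_", b), paste0("peak_", a)] <- v
  }
  for (k in names(co$overrides)) {
    ab <- strsplit(k, ".", fixed = TRUE)[[1]]
    R[ab[1], ab[2]] <- R[ab[2], ab[1]] <- co$overrides[[k]]
  }
  diag(R) <- 1
  # positive-definite projection: clip eigenvalues, re-standardize
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 1e-4) {
    lam <- pmax(e$values, 1e-4)
    R <- e$vectors %*% diag(lam) %*% t(e$vectors)
    s <- sqrt(diag(R))
    R <- R / tcrossprod(s)
    dimnames(R) <- list(all_vars, all_vars)
  }
  if (is.null(vars)) return(R)
  miss <- setdiff(vars, all_vars)
  if (length(miss)) stop("unknown measure(s): ", paste(miss, collapse = ", "))
  R[vars, vars, drop = FALSE]
}

#' Sample subject-level target metrics for a group
#'
#' Draws `n` subjects from a multivariate normal whose means/SDs come from
#' the group preset and whose correlation comes from
#' [measure_correlation()]. Reproducible under a fixed seed.
#'
#' @param presets a `group_presets`
#' @param group group label (e.g. `"HCM_VF"`)
#' @param phase `"peak"`, `"recovery"`, or `"both"`
#' @param n number of subjects
#' @param seed integer seed
#' @param measures which measures to draw (default: all six)
#' @return data.frame of subject-level targets, one row per subject, columns
#'   `phase_measure`
#' @export
sample_subject_metrics <- function(presets, group, phase = "recovery", n,
                                   seed = 1, measures = preset_measures()) {
  if (n < 1L) stop("n must be >= 1")
  gp <- presets$groups[[group]]
  if (is.null(gp)) stop("unknown group: ", group)
  phases <- if (phase == "both") c("peak", "recovery") else match.arg(phase, c("peak", "recovery"))
  vars <- as.vector(t(outer(phases, measures, paste, sep = "_")))
  mu <- vapply(vars, function(v) {
    ab <- regmatches(v, regexpr("^(peak|recovery)", v))
    m <- sub("^(peak|recovery)_", "", v)
    gp[[ab]][[m]]$mean
  }, numeric(1))
  sds <- vapply(vars, function(v) {
    ab <- regmatches(v, regexpr("^(peak|recovery)", v))
    m <- sub("^(peak|recovery)_", "", v)
    gp[[ab]][[m]]$sd
  }, numeric(1))
  R <- measure_correlation(presets, vars)
  S <- diag(sds, length(sds)) %*% R %*% diag(sds, length(sds))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev))
    stop("implied covariance is not positive semi-definite; check presets")
  set.seed(seed)
  X <- MASS::mvrnorm(n, mu, S)
  if (n == 1L) X <- matrix(X, nrow = 1)
  colnames(X) <- vars
  # physical floors: the measures are positive by definition, so rare deep
  # negative Gaussian draws are clamped (well below 2 SD for every preset)
  floors <- c(mean_at = 5, disp_at = 5, grad_at = 0.02,
              mean_ari = 120, disp_ari = 5, grad_ari = 0.05)
  for (v in vars) {
    m <- sub("^(peak|recovery)_", "", v)
    X[, v] <- pmax(X[, v], floors[[m]])
  }
  # gradient-to-dispersion ratio floor: a 200-node surface cannot represent
  # fields whose mean 5-mm gradient is arbitrarily small relative to their
  # dispersion; keep draws on the representable side
  for (ph in intersect(c("peak", "recovery"), sub("_.*", "", vars))) {
    for (d in c("at", "ari")) {
      g <- paste0(ph, "_grad_", d); dd <- paste0(ph, "_disp_", d)
      if (g %in% vars && dd %in% vars)
        X[, g] <- pmax(X[, g], 0.004 * X[, dd])
    }
  }
  out <- as.data.frame(X)
  out$subject <- seq_len(n)
  out$group <- group
  out[, c("subject", "group", vars)]
}

#' Sample per-phase heart rates for a group
#' @inheritParams sample_subject_metrics
#' @return data.frame with columns `peak_hr`, `recovery_hr` (bpm)
#' @export
sample_heart_rates <- function(presets, group, n, seed = 1) {
  gp <- presets$groups[[group]]
  if (is.null(gp)) stop("unknown group: ", group)
  set.seed(seed)
  data.frame(
    peak_hr = pmax(60, stats::rnorm(n, gp$peak$heart_rate$mean,
                                    gp$peak$heart_rate$sd)),
    recovery_hr = pmax(45, stats::rnorm(n, gp$recovery$heart_rate$mean,
                                        gp$recovery$heart_rate$sd))
  )
}

#' Sample qualitative pattern flags for a group
#' @inheritParams sample_subject_metrics
#' @return logical data.frame with one column per pattern
#' @export
sample_pattern_flags <- function(presets, group, n, seed = 1) {
  pr <- presets$groups[[group]]$patterns
  set.seed(seed)
  out <- lapply(pr, function(p) stats::runif(n) < p)
  as.data.frame(out)
}
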