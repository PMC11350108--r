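#' Activation and repolarization markers (Wyatt method) and whole-heart metrics
#'
#' Per-node markers are defined on the signal-averaged electrogram relative to
#' a subject-level global QRS start: local activation time (LAT) is the time of
#' the steepest negative slope (minimum dV/dt) inside the QRS window; local
#' repolarization time (LRT) is the time of the steepest positive slope
#' (maximum dV/dt) inside the T-wave window, which is well-defined for both
#' upright and inverted T waves; the activation-recovery interval (ARI) is
#' LRT - LAT, a surrogate of local action-potential duration.
#'
#' Whole-heart summaries cover three analysis domains: the mean (overall
#' conduction delay / repolarization duration), the central 95% range
#' (dispersion), and the mean spatial gradient over 5-mm neighbourhoods
#' (steepness of local change).
#'
#' @name markers
NULL

#' Global QRS start across a subject's accepted delineations
#'
#' The common time zero for all marker times of one subject/phase: the
#' earliest QRS onset over accepted nodes.
#'
#' @param delins list of [delineate_egm()] results (or a data.frame with
#'   columns `qrs_on` and `quality`)
#' @return sample index of the global QRS start
#' @export
global_qrs_start <- function(delins) {
  if (is.data.frame(delins)) {
    ok <- delins$quality == "accepted"
    if (!any(ok)) stop("empty map: no accepted nodes")
    return(min(delins$qrs_on[ok]))
  }
  ons <- vapply(delins, function(d) {
    if (identical(d$quality, "accepted")) d$qrs_on else NA_integer_
  }, numeric(1))
  if (all(is.na(ons))) stop("empty map: no accepted nodes")
  min(ons, na.rm = TRUE)
}

#' Local activation time of one averaged electrogram
#'
#' Time from the global QRS start to the minimum of the smoothed dV/dt within
#' the delineated QRS window (steepest negative slope). Ties break to the
#' earliest sample.
#'
#' @param egm an `averaged_egm` (see [signal_average()])
#' @param delin its delineation (see [delineate_egm()])
#' @param t0 global QRS start (sample index, from [global_qrs_start()])
#' @param smooth_ms derivative smoothing window, ms
#' @return LAT in ms
#' @export
local_activation_time <- function(egm, delin, t0, smooth_ms = 10) {
  sd <- smoothed_derivative(egm$voltage, egm$fs, smooth_ms)
  idx <- delin$qrs_on:delin$qrs_off
  seg <- sd[idx]
  if (min(seg) >= 0)
    stop("no activation: derivative is non-negative throughout the QRS window")
  at_sample <- refine_extremum(sd, idx[which.min(seg)])
  (at_sample - t0) * 1000 / egm$fs
}

#' Local repolarization time of one averaged electrogram (Wyatt method)
#'
#' Time from the global QRS start to the maximum of the smoothed dV/dt within
#' the delineated T window (steepest positive slope), defined identically for
#' upright and inverted T waves. Ties break to the earliest sample.
#'
#' @inheritParams local_activation_time
#' @return LRT in ms
#' @export
local_repolarization_time <- function(egm, delin, t0, smooth_ms = 10) {
  if (is.na(delin$t_on) || is.na(delin$t_off))
    stop("no T window delineated for this electrogram")
  sd <- smoothed_derivative(egm$voltage, egm$fs, smooth_ms)
  idx <- delin$t_on:delin$t_off
  seg <- sd[idx]
  if (max(seg) <= 0)
    stop("no repolarization: derivative is non-positive throughout the T window")
  rt_sample <- refine_extremum(sd, idx[which.max(seg)])
  (rt_sample - t0) * 1000 / egm$fs
}

#' Activation-recovery interval
#'
#' ARI = LRT - LAT. A non-positive ARI is physiologically invalid; the value
#' is returned with an attribute `valid = FALSE` rather than raising, so the
#' caller can flag the node as rejected.
#'
#' @param lat LAT in ms
#' @param lrt LRT in ms
#' @return ARI in ms with attribute `valid`
#' @export
activation_recovery_interval <- function(lat, lrt) {
  stopifnot(is.finite(lat), is.finite(lrt))
  ari <- lrt - lat
  attr(ari, "valid") <- ari > 0
  ari
}

#' Central 95% range (dispersion)
#'
#' The 97.5th minus the 2.5th percentile using the linear-interpolation
#' percentile definition (R quantile type 7).
#'
#' @param values numeric vector (>= 10 values)
#' @return dispersion in the units of `values`
#' @export
dispersion95 <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10L)
    stop("dispersion95 needs at least 10 values, got ", length(values))
  q <- stats::quantile(values, c(0.025, 0.975), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Mean spatial gradient of a node field over local neighbourhoods
#'
#' For every node with at least `min_points` points (the node plus its
#' neighbours within `radius` mm), the field is fitted with a least-squares
#' plane over the 3D neighbourhood coordinates and the per-node gradient is
#' the magnitude of the fitted slope vector. Rank-deficient neighbourhood
#' geometries (e.g. nearly collinear points) are handled by truncating
#' singular values below 10% of the largest, which makes the fit the
#' directional derivative along the populated directions. The whole-heart
#' value is the mean over qualifying nodes.
#'
#' @param mesh an `epi_mesh`
#' @param values per-node field (ms), NA for rejected nodes
#' @param radius neighbourhood radius in mm (default 5, the reporting
#'   standard for epicardial gradient maps)
#' @param min_points minimum neighbourhood size including the node itself
#' @param nbr optional precomputed neighbour index from `neighbor_index()`
#' @param per_node if TRUE return the per-node gradient vector instead of
#'   the mean
#' @return mean gradient in ms/mm (or per-node vector)
#' @export
mean_spatial_gradient <- function(mesh, values, radius = 5, min_points = 3,
                                  nbr = NULL, per_node = FALSE) {
  stopifnot(length(values) == nrow(mesh$vertices))
  if (is.null(nbr)) nbr <- neighbor_index(mesh, radius)
  ok <- which(is.finite(values))
  grad <- rep(NA_real_, length(values))
  v <- mesh$vertices
  for (i in ok) {
    nb <- nbr[[i]]
    nb <- nb[nb %in% ok]
    pts <- c(i, nb)
    if (length(pts) < min_points) next
    grad[i] <- plane_fit_gradient(v[pts, , drop = FALSE], values[pts])
  }
  if (per_node) return(grad)
  if (all(is.na(grad)))
    stop("no node has a valid neighbourhood at radius ", radius, " mm")
  mean(grad, na.rm = TRUE)
}

# Magnitude of the least-squares plane fit slope, with relative singular
# value truncation at 0.1 for ill-conditioned point sets.
#' @keywords internal
#' @noRd
plane_fit_gradient <- function(pts, vals, sv_tol = 0.1) {
  A <- sweep(pts, 2, colMeans(pts))
  b <- vals - mean(vals)
  s <- svd(A)
  keep <- s$d >= sv_tol * s$d[1] & s$d > 1e-12
  if (!any(keep)) return(0)
  g <- s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], b)) / s$d[keep])
  sqrt(sum(g^2))
}

#' Alternative gradient definition: neighbourhood range over span
#'
#' Max pairwise value range divided by max pairwise distance within each
#' neighbourhood; provided for sensitivity analysis against the plane-fit
#' reference definition.
#' @inheritParams mean_spatial_gradient
#' @return mean gradient in ms/mm
#' @export
range_spatial_gradient <- function(mesh, values, radius = 5, min_points = 3,
                                   nbr = NULL) {
  stopifnot(length(values) == nrow(mesh$vertices))
  if (is.null(nbr)) nbr <- neighbor_index(mesh, radius)
  ok <- which(is.finite(values))
  v <- mesh$vertices
  grads <- rep(NA_real_, length(values))
  for (i in ok) {
    nb <- nbr[[i]]
    nb <- nb[nb %in% ok]
    pts <- c(i, nb)
    if (length(pts) < min_points) next
    dd <- stats::dist(v[pts, , drop = FALSE])
    grads[i] <- diff(range(values[pts])) / max(dd)
  }
  mean(grads, na.rm = TRUE)
}

#' Assemble node markers from averaged electrograms and delineations
#'
#' Runs LAT/LRT/ARI extraction for every node, referencing all times to the
#' subject's global QRS start, and flags nodes whose delineation was rejected
#' or whose ARI is non-positive.
#'
#' @param egms list of `averaged_egm`
#' @param delins list of delineations matching `egms`
#' @param smooth_ms derivative smoothing window, ms
#' @return data.frame with one row per node: `node_id`, `lat_ms`, `lrt_ms`,
#'   `ari_ms`, `accepted`, `reason`
#' @export
node_markers <- function(egms, delins, smooth_ms = 10) {
  t0 <- global_qrs_start(delins)
  rows <- lapply(seq_along(egms), function(i) {
    egm <- egms[[i]]; d <- delins[[i]]
    out <- data.frame(node_id = egm$node_id, lat_ms = NA_real_,
                      lrt_ms = NA_real_, ari_ms = NA_real_,
                      accepted = FALSE, reason = d$quality,
                      stringsAsFactors = FALSE)
    if (!identical(d$quality, "accepted")) return(out)
    lat <- tryCatch(local_activation_time(egm, d, t0, smooth_ms),
                    error = function(e) NA_real_)
    lrt <- tryCatch(local_repolarization_time(egm, d, t0, smooth_ms),
                    error = function(e) NA_real_)
    if (is.na(lat) || is.na(lrt)) {
      out$reason <- "rejected_marker_failure"
      return(out)
    }
    ari <- activation_recovery_interval(lat, lrt)
    out$lat_ms <- lat; out$lrt_ms <- lrt; out$ari_ms <- as.numeric(ari)
    if (attr(ari, "valid")) {
      out$accepted <- TRUE
    } else {
      out$reason <- "rejected_nonpositive_ari"
    }
    out
  })
  do.call(rbind, rows)
}

#' Whole-heart metrics for one subject and phase
#'
#' Mean, central-95% dispersion and mean 5-mm spatial gradient of LAT and ARI
#' over accepted nodes.
#'
#' @param markers data.frame from [node_markers()] (or any data.frame with
#'   `node_id`, `lat_ms`, `ari_ms`, `accepted`)
#' @param mesh the `epi_mesh` the markers live on
#' @param radius gradient neighbourhood radius, mm
#' @param nbr optional precomputed neighbour index
#' @param gradient_method `"plane"` (reference) or `"range"`
#' @return one-row data.frame of class `heart_metrics`
#' @export
heart_metrics <- function(markers, mesh, radius = 5, nbr = NULL,
                          gradient_method = c("plane", "range")) {
  gradient_method <- match.arg(gradient_method)
  acc <- markers$accepted
  n_used <- sum(acc)
  if (n_used < 10L)
    stop("heart_metrics needs >= 10 accepted nodes, got ", n_used)
  lat <- rep(NA_real_, nrow(mesh$vertices))
  ari <- rep(NA_real_, nrow(mesh$vertices))
  pos <- match(markers$node_id[acc], mesh$node_ids)
  if (anyNA(pos)) stop("marker node ids not found on mesh")
  lat[pos] <- markers$lat_ms[acc]
  ari[pos] <- markers$ari_ms[acc]
  gfun <- if (gradient_method == "plane") mean_spatial_gradient else range_spatial_gradient
  out <- data.frame(
    mean_at = mean(lat, na.rm = TRUE),
    disp_at = dispersion95(lat[is.finite(lat)]),
    grad_at = gfun(mesh, lat, radius, nbr = nbr),
    mean_ari = mean(ari, na.rm = TRUE),
    disp_ari = dispersion95(ari[is.finite(ari)]),
    grad_ari = gfun(mesh, ari, radius, nbr = nbr),
    nodes_used = n_used,
    nodes_rejected = sum(!acc)
  )
  class(out) <- c("heart_metrics", class(out))
  out
}

#' Bazett rate correction of an interval
#'
#' `interval / sqrt(rr)` with the RR interval in seconds. Declared stand-in
#' formula for rate-corrected ARI/QT comparisons.
#'
#' @param interval interval in ms
#' @param rr preceding RR interval in seconds (> 0)
#' @return corrected interval in ms
#' @export
rate_correct <- function(interval, rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("rr must be positive (seconds)")
  interval / sqrt(rr)
}
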