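#' Rule-based detectors for qualitative epicardial map patterns
#'
#' Deterministic numeric stand-ins for the visually assessed map patterns of
#' the HCM electrotype: late isolated activation patches surrounded by high
#' gradient, relatively prolonged ARI at the apex, apical T-wave inversion,
#' and isolated T-inversion patches. All rule parameters are explicit and
#' configurable; the flags depend only on the marker fields, the T-polarity
#' calls and the mesh landmarks, and are invariant to node ordering.
#'
#' @param markers data.frame from [node_markers()] (needs `node_id`,
#'   `lat_ms`, `ari_ms`, `accepted`)
#' @param polarity per-node T polarity (+1 upright / -1 inverted), in mesh
#'   node order
#' @param mesh an `epi_mesh` with landmarks
#' @param min_patch minimum connected node count for a patch
#' @param late_sd threshold (in field SDs above the mean) for "late"
#' @param apical_ari_ms apical-minus-basal mean ARI threshold, ms
#' @param apical_frac fraction of apical-third nodes that must be inverted
#' @param radius gradient neighbourhood radius, mm
#' @return a `pattern_report`: list of logical flags `late_patch`,
#'   `apical_ari`, `apical_t_inversion`, `isolated_t_inversion`, plus
#'   supporting node-id sets
#' @export
detect_patterns <- function(markers, polarity, mesh, min_patch = 5,
                            late_sd = 1.5, apical_ari_ms = 10,
                            apical_frac = 0.5, radius = 5) {
  if (is.null(mesh$apex) || is.null(mesh$base_centroid))
    stop("mesh landmarks (apex, base centroid) are required")
  n <- nrow(mesh$vertices)
  pos <- match(markers$node_id, mesh$node_ids)
  if (anyNA(pos)) stop("marker node ids not found on mesh")
  lat <- rep(NA_real_, n); ari <- rep(NA_real_, n)
  lat[pos[markers$accepted]] <- markers$lat_ms[markers$accepted]
  ari[pos[markers$accepted]] <- markers$ari_ms[markers$accepted]
  ab <- apicobasal_coord(mesh)
  adj <- mesh_adjacency(mesh)

  components <- function(nodes) {
    nodes <- nodes[!is.na(nodes)]
    seen <- logical(n)
    out <- list()
    inset <- logical(n); inset[nodes] <- TRUE
    for (s in nodes) {
      if (seen[s]) next
      comp <- integer(0); queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        comp <- c(comp, v)
        nb <- adj[[v]]
        nb <- nb[inset[nb] & !seen[nb]]
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      out[[length(out) + 1L]] <- comp
    }
    out
  }

  ## late activation patch: connected late nodes with high-gradient border
  mu <- mean(lat, na.rm = TRUE); sdv <- stats::sd(lat, na.rm = TRUE)
  grad <- mean_spatial_gradient(mesh, lat, radius, per_node = TRUE)
  mean_grad <- mean(grad, na.rm = TRUE)
  late_nodes <- which(lat > mu + late_sd * sdv)
  late_patch <- FALSE
  late_set <- integer(0)
  for (comp in components(late_nodes)) {
    if (length(comp) < min_patch) next
    border <- setdiff(unique(unlist(adj[comp])), comp)
    bg <- grad[border]
    bg <- bg[!is.na(bg)]
    # the border-gradient condition only applies where the gradient is
    # defined; a patch whose rim lies in the sparsely sampled band (no 5-mm
    # neighbourhoods) is judged on lateness and size alone
    if (length(bg) == 0L || mean(bg) > mean_grad) {
      late_patch <- TRUE
      late_set <- union(late_set, comp)
    }
  }

  ## apical ARI prolongation
  apical <- ab < 1 / 3; basal <- ab > 2 / 3
  apical_ari <- isTRUE(
    mean(ari[apical], na.rm = TRUE) - mean(ari[basal], na.rm = TRUE) >=
      apical_ari_ms)

  ## apical T inversion
  neg <- polarity < 0
  apical_t <- isTRUE(mean(neg[apical]) > apical_frac)

  ## isolated T-inversion patch surrounded by positive-T nodes
  iso <- FALSE
  iso_set <- integer(0)
  for (comp in components(which(neg))) {
    if (length(comp) < min_patch) next
    # a patch mostly inside the apical third is apical inversion, not an
    # isolated island in otherwise upright territory
    if (mean(ab[comp] < 1 / 3) > 0.5) next
    border <- setdiff(unique(unlist(adj[comp])), comp)
    if (length(border) && all(!neg[border])) {
      iso <- TRUE
      iso_set <- union(iso_set, comp)
    }
  }

  structure(list(
    late_patch = late_patch,
    apical_ari = apical_ari,
    apical_t_inversion = apical_t,
    isolated_t_inversion = iso,
    late_patch_nodes = mesh$node_ids[late_set],
    isolated_t_nodes = mesh$node_ids[iso_set]
  ), class = "pattern_report")
}
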