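#' Epicardial surface meshes
#'
#' An `epi_mesh` is a triangulated epicardial surface: vertex coordinates in
#' millimetres, triangular faces (1-based vertex indices), stable node
#' identifiers, and two anatomical landmarks (apex vertex and base centroid)
#' that define the apico-basal axis used by field synthesis and the pattern
#' detectors.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param node_ids optional vector of stable node identifiers (defaults to
#'   vertex order).
#' @param apex optional vertex index of the apex; defaults to the vertex
#'   farthest from the base centroid.
#' @param base_centroid optional length-3 point (mm); defaults to the centroid
#'   of the vertices farthest along the first principal axis from the apex.
#'
#' @return an object of class `epi_mesh`.
#' @export
epi_mesh <- function(vertices, faces, node_ids = NULL, apex = NULL,
                     base_centroid = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z in mm)")
  if (nrow(vertices) < 4L) stop("a mesh needs at least 4 vertices")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must be triangles (3 vertex indices per row)")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face references vertex index outside 1..", nrow(vertices))
  node_ids <- node_ids %||% seq_len(nrow(vertices))
  if (length(node_ids) != nrow(vertices))
    stop("node_ids must have one entry per vertex")
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")

  if (is.null(base_centroid)) {
    # pick the extreme slab along the longest principal axis as the "base"
    ctr <- colMeans(vertices)
    pc <- svd(sweep(vertices, 2, ctr))$v[, 1]
    proj <- as.vector(sweep(vertices, 2, ctr) %*% pc)
    top <- proj >= stats::quantile(proj, 0.9)
    base_centroid <- colMeans(vertices[top, , drop = FALSE])
  }
  base_centroid <- as.numeric(base_centroid)
  if (length(base_centroid) != 3L || !all(is.finite(base_centroid)))
    stop("base_centroid must be a finite 3D point")
  if (is.null(apex)) {
    d2 <- rowSums(sweep(vertices, 2, base_centroid)^2)
    apex <- which.max(d2)
  }
  apex <- as.integer(apex)
  if (apex < 1L || apex > nrow(vertices)) stop("apex index out of range")
  axis <- base_centroid - vertices[apex, ]
  if (sqrt(sum(axis^2)) <= 1e-9)
    stop("apico-basal axis has zero length; check landmarks")

  structure(
    list(vertices = vertices, faces = faces, node_ids = node_ids,
         apex = apex, base_centroid = base_centroid),
    class = "epi_mesh"
  )
}

#' @export
print.epi_mesh <- function(x, ...) {
  ext <- apply(x$vertices, 2, range)
  cat(sprintf("epi_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  extent (mm): x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  cat(sprintf("  apex node %s, apico-basal extent %.1f mm\n",
              as.character(x$node_ids[x$apex]), apicobasal_extent(x)))
  invisible(x)
}

#' Apico-basal extent of a mesh (apex to base centroid), mm
#' @param mesh an `epi_mesh`
#' @return distance in mm
#' @export
apicobasal_extent <- function(mesh) {
  sqrt(sum((mesh$base_centroid - mesh$vertices[mesh$apex, ])^2))
}

# Normalized apico-basal coordinate per node: 0 at apex, 1 at base centroid.
#' @keywords internal
#' @noRd
apicobasal_coord <- function(mesh) {
  a <- mesh$vertices[mesh$apex, ]
  u <- mesh$base_centroid - a
  u <- u / sqrt(sum(u^2))
  s <- as.vector(sweep(mesh$vertices, 2, a) %*% u) / apicobasal_extent(mesh)
  pmin(pmax(s, 0), 1)
}

#' Neighbouring nodes within a Euclidean radius
#'
#' Spatial neighbourhood query used by the 5-mm gradient metric. Distances are
#' Euclidean 3D distances in mm; the query node itself is excluded and results
#' are sorted by increasing distance.
#'
#' @param mesh an `epi_mesh`
#' @param node a node id present in `mesh$node_ids`
#' @param radius search radius in mm (> 0)
#' @return data.frame with columns `node_id` and `distance`
#' @export
neighbors_within <- function(mesh, node, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a single positive number (mm)")
  i <- match(node, mesh$node_ids)
  if (is.na(i)) stop("unknown node id: ", as.character(node))
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, mesh$vertices[i, ])^2))
  sel <- which(d <= radius & seq_along(d) != i)
  ord <- order(d[sel])
  data.frame(node_id = mesh$node_ids[sel][ord], distance = d[sel][ord])
}

# Precompute, for every vertex, the indices (and distances) of all vertices
# within `radius` mm. Returned as a list of integer matrices; reused heavily
# by the gradient metric and the field calibration loop.
#' @keywords internal
#' @noRd
neighbor_index <- function(mesh, radius) {
  v <- mesh$vertices
  n <- nrow(v)
  dmat <- as.matrix(stats::dist(v))
  lapply(seq_len(n), function(i) {
    sel <- which(dmat[i, ] <= radius & seq_len(n) != i)
    sel[order(dmat[i, sel])]
  })
}

# Vertex adjacency (shared triangle edge) as a list of integer vectors.
#' @keywords internal
#' @noRd
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  adj <- split(e[, 2], e[, 1])
  out <- rep(list(integer(0)), nrow(mesh$vertices))
  out[as.integer(names(adj))] <- lapply(adj, as.integer)
  out
}

#' Generate a prolate-spheroid ventricular surface mesh
#'
#' Builds a closed triangulated surface of revolution approximating a
#' ventricular epicardium: an ellipsoid of revolution with a long apico-basal
#' axis. Vertices lie on latitude rings between two polar vertices; the apex
#' is one pole and the base centroid is the centroid of the last ring before
#' the opposite pole. Ring count and segment count control node density; the
#' defaults give 200 nodes with a mean inter-node spacing such that 5-mm
#' neighbourhoods are populated along the meridians.
#'
#' @param n_rings number of latitude rings (excluding the two poles)
#' @param n_segments vertices per ring
#' @param apex_base_mm apex-to-base extent (long axis), mm
#' @param radius_mm equatorial radius (short semi-axis), mm
#' @param equator_spread ring redistribution towards the poles (0 =
#'   uniform colatitude). Larger values widen the equatorial ring gap,
#'   which lets synthetic fields carry steep apico-basal transitions
#'   through a sparsely sampled band
#' @return an `epi_mesh`
#' @export
mesh_spheroid <- function(n_rings = 22, n_segments = 9, apex_base_mm = 90,
                          radius_mm = 14, equator_spread = 0.8) {
  a <- apex_base_mm / 2
  b <- radius_mm
  u <- seq(0, 1, length.out = n_rings + 2L)
  theta <- pi * (u - equator_spread * sin(2 * pi * u) / (2 * pi))
  verts <- matrix(0, nrow = 2L + n_rings * n_segments, ncol = 3L)
  verts[1L, ] <- c(0, 0, -a)  # apex
  phi <- seq(0, 2 * pi, length.out = n_segments + 1L)[seq_len(n_segments)]
  row <- 2L
  for (r in seq_len(n_rings)) {
    th <- theta[r + 1L]
    z <- -a * cos(th)
    rad <- b * sin(th)
    verts[row:(row + n_segments - 1L), ] <-
      cbind(rad * cos(phi), rad * sin(phi), z)
    row <- row + n_segments
  }
  verts[nrow(verts), ] <- c(0, 0, a)  # base pole

  ring_start <- function(r) 2L + (r - 1L) * n_segments
  faces <- list()
  # apex cap
  s1 <- ring_start(1)
  faces[[1]] <- cbind(1L, s1 + (seq_len(n_segments) - 1L),
                      s1 + (seq_len(n_segments) %% n_segments))
  # bands
  k <- 2L
  for (r in seq_len(n_rings - 1L)) {
    sa <- ring_start(r); sb <- ring_start(r + 1L)
    i <- seq_len(n_segments) - 1L
    j <- seq_len(n_segments) %% n_segments
    faces[[k]] <- rbind(cbind(sa + i, sb + i, sb + j),
                        cbind(sa + i, sb + j, sa + j))
    k <- k + 1L
  }
  # base cap
  sl <- ring_start(n_rings)
  last <- nrow(verts)
  faces[[k]] <- cbind(sl + (seq_len(n_segments) - 1L), last,
                      sl + (seq_len(n_segments) %% n_segments))
  faces <- do.call(rbind, faces)

  base_ring <- verts[sl:(sl + n_segments - 1L), , drop = FALSE]
  epi_mesh(verts, faces, apex = 1L, base_centroid = colMeans(base_ring))
}

#' Read a surface mesh from PLY (ASCII) or VTK legacy polydata
#'
#' @param path file path
#' @param format `"ply"` or `"vtk-ascii"`; guessed from the file extension
#'   when missing.
#' @return an `epi_mesh`
#' @export
load_mesh <- function(path, format = c("auto", "ply", "vtk-ascii")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vtk$", path, ignore.case = TRUE)) "vtk-ascii" else "ply"
  }
  if (format == "ply") read_ply_ascii(path) else read_vtk_polydata(path)
}

#' @keywords internal
#' @noRd
read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("not a PLY file (missing 'ply' magic): ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("malformed PLY: no end_header")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("unsupported PLY format: only ascii is supported")
  el <- grep("^element\\s", hdr)
  counts <- list()
  for (i in el) {
    tok <- strsplit(trimws(hdr[i]), "\\s+")[[1]]
    counts[[tok[2]]] <- as.integer(tok[3])
  }
  if (is.null(counts$vertex)) stop("malformed PLY: missing element vertex")
  if (is.null(counts$face)) stop("malformed PLY: missing element face")
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  nv <- counts$vertex; nf <- counts$face
  if (length(body) < nv + nf) stop("malformed PLY: truncated body")
  vtx <- utils::read.table(text = body[seq_len(nv)])
  if (ncol(vtx) < 3L) stop("malformed PLY: element vertex needs x y z")
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(seq_along(fl), function(i) {
    v <- as.integer(fl[[i]])
    if (v[1] != 3L)
      stop("unsupported face in element face row ", i,
           ": only triangles are supported (got ", v[1], " vertices)")
    v[2:4] + 1L
  }, integer(3)))
  epi_mesh(as.matrix(vtx[, 1:3]), faces)
}

#' Write a mesh as ASCII PLY
#' @param mesh an `epi_mesh`
#' @param path output file path
#' @return `path`, invisibly
#' @export
save_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    paste("element face", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  utils::write.table(format(mesh$vertices, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @keywords internal
#' @noRd
read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pt_line <- grep("^POINTS\\s", lines)[1]
  if (is.na(pt_line)) stop("malformed VTK: missing POINTS")
  np <- as.integer(strsplit(trimws(lines[pt_line]), "\\s+")[[1]][2])
  nums <- numeric(0)
  i <- pt_line + 1L
  while (length(nums) < 3L * np && i <= length(lines)) {
    nums <- c(nums, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  if (length(nums) < 3L * np) stop("malformed VTK: truncated POINTS")
  verts <- matrix(nums[seq_len(3L * np)], ncol = 3L, byrow = TRUE)
  poly_line <- grep("^POLYGONS\\s", lines)[1]
  if (is.na(poly_line)) stop("malformed VTK: missing POLYGONS")
  nf <- as.integer(strsplit(trimws(lines[poly_line]), "\\s+")[[1]][2])
  faces <- matrix(0L, nrow = nf, ncol = 3L)
  for (k in seq_len(nf)) {
    v <- as.integer(strsplit(trimws(lines[poly_line + k]), "\\s+")[[1]])
    if (v[1] != 3L) stop("unsupported face in POLYGONS row ", k,
                         ": only triangles are supported")
    faces[k, ] <- v[2:4] + 1L
  }
  epi_mesh(verts, faces)
}

#' Export a mesh with per-node scalar maps as VTK legacy ASCII polydata
#'
#' Writes the surface plus any number of per-node scalar arrays (e.g. LAT,
#' LRT, ARI, gradient) so maps can be rendered in standard viewers.
#'
#' @param mesh an `epi_mesh`
#' @param scalars named list of numeric vectors, one value per node
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_vtk_map <- function(mesh, scalars, path) {
  stopifnot(is.list(scalars))
  n <- nrow(mesh$vertices)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "epimapr map export", "ASCII",
               "DATASET POLYDATA", paste("POINTS", n, "float")), con)
  utils::write.table(format(mesh$vertices, digits = 8, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  nf <- nrow(mesh$faces)
  writeLines(paste("POLYGONS", nf, 4L * nf), con)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (length(scalars)) {
    writeLines(paste("POINT_DATA", n), con)
    for (nm in names(scalars)) {
      v <- scalars[[nm]]
      if (length(v) != n) stop("scalar '", nm, "' must have one value per node")
      writeLines(c(paste("SCALARS", nm, "float 1"), "LOOKUP_TABLE default"), con)
      writeLines(format(v, digits = 8, trim = TRUE, scientific = FALSE), con)
    }
  }
  invisible(path)
}
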