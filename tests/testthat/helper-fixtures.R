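# Shared fixtures, built in code at test time.

# smallest valid mesh: regular tetrahedron (edge ~ 2 mm)
tetra_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  epi_mesh(v, f)
}

# flat triangulated grid in the z = 0 plane, spacing in mm
planar_mesh <- function(nx = 6, ny = 6, spacing = 2) {
  g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  idx <- function(i, j) (j - 1) * nx + i
  f <- do.call(rbind, lapply(seq_len(nx - 1), function(i) {
    do.call(rbind, lapply(seq_len(ny - 1), function(j) {
      rbind(c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
            c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }))
  }))
  epi_mesh(v, f, apex = 1L, base_centroid = c((nx - 1) * spacing, (ny - 1) * spacing, 1))
}

# random cloud mesh (faces irrelevant for distance-based tests)
cloud_mesh <- function(n = 50, scale = 20, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::runif(3 * n, 0, scale), ncol = 3)
  f <- cbind(1:(n - 2), 2:(n - 1), 3:n)
  epi_mesh(v, f)
}

small_spheroid <- function() mesh_spheroid(n_rings = 10, n_segments = 7,
                                           apex_base_mm = 60, radius_mm = 12)

# clean single-node averaged EGM with known AT/RT (noise-free)
canonical_egm <- function(at = 40, rt = 290, pol = 1, fs = 1000,
                          noise = 0, wander = 0, beats = 10, rr = 600,
                          seed = 1) {
  p <- waveform_params(noise_sd_mv = noise, wander_amp_mv = wander,
                       fs_hz = fs, beats = beats)
  tr <- synthesize_beat_train(at, rt, pol, p, rr_ms = rep(rr, beats),
                              seed = seed)
  list(trace = as.numeric(tr), params = p, onsets = attr(tr, "onsets"),
       ld = attr(tr, "ld"))
}

# process one single-node trace through template matching and averaging
average_one <- function(trace, fs = 1000) {
  tpl <- pick_template(trace, fs)
  rois <- match_rois(trace, tpl)
  signal_average(rois, trace, fs, node_id = 1)
}

# default presets, loaded once
test_presets <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- load_presets()
    p
  }
})
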