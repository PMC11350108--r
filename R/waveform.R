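#' Synthetic unipolar electrogram waveforms
#'
#' One beat is composed of an rS-type QRS complex and a monophasic T wave:
#'
#' * QRS: half-cosine R upstroke, flat plateau, slow linear descent of
#'   length `ld`, steep cosine downstroke (half-width 12 ms) whose slope
#'   profile is symmetric about its centre - so the steepest negative slope
#'   sits exactly at the configured activation time for both the raw and
#'   the smoothed derivative - and a 100-ms S recovery.
#' * T: Gaussian lobe (SD `t_width/6`), upright or inverted. Its steepest
#'   positive slope sits exactly at the configured repolarization time
#'   (one SD before the apex for upright, one SD after for inverted T).
#'
#' The slow-descent length `ld` sets the delay from the detectable QRS
#' onset (the descent start) to the steepest negative slope independently
#' of the QRS footprint after the slope; the subject-level synthesizer
#' solves it so that the detected global QRS start of the map coincides
#' with the truth time zero.
#'
#' @name waveforms
NULL

#' Default waveform parameters
#'
#' @param fs_hz sampling rate (Hz)
#' @param qrs_amp_mv QRS peak-to-peak amplitude (mV)
#' @param t_amp_mv T-wave amplitude (mV)
#' @param t_width_ms T-wave width (ms); the Gaussian SD is a sixth of this
#' @param wander_amp_mv baseline-wander amplitude (mV)
#' @param wander_hz baseline-wander frequency (Hz)
#' @param noise_sd_mv additive white-noise SD per trace (mV)
#' @param noise_indep_frac fraction of the noise SD that is independent per
#'   node; the remainder is a common noise trace shared by all nodes of a
#'   subject, emulating the spatially smooth noise of regularized inverse
#'   reconstructions (node-independent noise at the full level would imply
#'   marker scatter far beyond what reconstructed maps show)
#' @param beats beats per strip
#' @param rr_jitter_frac RR jitter SD as a fraction of the mean RR
#' @return list of waveform parameters
#' @export
waveform_params <- function(fs_hz = 1000, qrs_amp_mv = 1.0,
                            t_amp_mv = 0.45, t_width_ms = 140,
                            wander_amp_mv = 0.3, wander_hz = 0.25,
                            noise_sd_mv = 0.02, noise_indep_frac = 0.05,
                            beats = 10, rr_jitter_frac = 0.03) {
  stopifnot(fs_hz > 0, beats >= 1, t_width_ms > 0)
  list(fs_hz = fs_hz, qrs_amp_mv = qrs_amp_mv,
       t_amp_mv = t_amp_mv, t_width_ms = t_width_ms,
       wander_amp_mv = wander_amp_mv, wander_hz = wander_hz,
       noise_sd_mv = noise_sd_mv, noise_indep_frac = noise_indep_frac,
       beats = beats, rr_jitter_frac = rr_jitter_frac)
}

# QRS shape constants (ms unless noted): R-rise width, inter-wave plateau,
# steep downstroke half-width, S-side linear continuation, S recovery
# width, R amplitude fraction. The slow-descent length `ld` is the free
# parameter controlling the delay from the detectable QRS onset (descent
# start) to the steepest negative slope, independent of the QRS's
# footprint after the slope.
.qrs_shape <- list(rise = 42, plateau = 12, hd = 12, ls = 8, tail = 100,
                   a_r = 0.45, a_s = 0.55, sd_frac = 0.35)

# Evaluate one clean beat at times `t_ms` relative to the beat's time zero.
# at_ms: steepest-negative-slope time; rt_ms: steepest-positive-slope time of
# the T wave; pol: +1 upright, -1 inverted; ld: slow-descent length (ms).
#' @keywords internal
#' @noRd
beat_voltage <- function(t_ms, at_ms, rt_ms, pol, params, ld) {
  amp <- params$qrs_amp_mv
  q <- .qrs_shape
  a_r <- q$a_r * amp; a_s <- q$a_s * amp
  hd <- q$hd; ls <- q$ls
  # steep-segment slope profile: s(u) = sd + (smax - sd) cos(pi u / (2 hd)),
  # tangent-continuous with the linear descents on both sides and symmetric
  # about the centre, so the steepest negative slope is exactly at u = 0
  smax <- amp / (2 * hd * q$sd_frac + 4 * hd / pi * (1 - q$sd_frac) +
                   q$sd_frac * (ld + ls))
  sd_ <- q$sd_frac * smax
  u <- t_ms - at_ms  # 0 at the steepest negative slope
  v <- numeric(length(t_ms))
  d_start <- -hd - ld          # descent start (detectable QRS onset)
  r_start <- d_start - q$plateau - q$rise
  # R upstroke then flat plateau
  i <- u >= r_start & u < r_start + q$rise
  v[i] <- a_r / 2 * (1 - cos(pi * (u[i] - r_start) / q$rise))
  i <- u >= r_start + q$rise & u < d_start
  v[i] <- a_r
  # slow linear descent
  i <- u >= d_start & u < -hd
  v[i] <- a_r - sd_ * (u[i] - d_start)
  # steep downstroke: integral of the slope profile
  v_hd <- a_r - sd_ * ld
  i <- u >= -hd & u <= hd
  v[i] <- v_hd - sd_ * (u[i] + hd) -
    (smax - sd_) * (2 * hd / pi) * (sin(pi * u[i] / (2 * hd)) + 1)
  v_s <- v_hd - 2 * hd * sd_ - (smax - sd_) * 4 * hd / pi
  # S-side linear continuation, then recovery to baseline
  i <- u > hd & u <= hd + ls
  v[i] <- v_s - sd_ * (u[i] - hd)
  trough <- v_s - sd_ * ls
  i <- u > hd + ls & u <= hd + ls + q$tail
  v[i] <- trough / 2 * (1 + cos(pi * (u[i] - hd - ls) / q$tail))
  # T wave: Gaussian lobe; steepest positive slope at rt_ms
  sig <- params$t_width_ms / 6
  t_center <- if (pol >= 0) rt_ms + sig else rt_ms - sig
  w <- t_ms - t_center
  i <- abs(w) <= 3.5 * sig
  v[i] <- v[i] + pol * params$t_amp_mv * exp(-w[i]^2 / (2 * sig^2))
  v
}

# Total extent of the QRS waveform before/after the steepest slope (ms).
#' @keywords internal
#' @noRd
qrs_extent <- function(ld) {
  q <- .qrs_shape
  c(before = q$rise + q$plateau + ld + q$hd, after = q$hd + q$ls + q$tail)
}

# Measure, on a clean single beat, the delay from the detected QRS onset
# to the steepest negative slope for a given slow-descent length. Used to
# choose `ld` so that the earliest node's detected onset lands on time
# zero.
#' @keywords internal
#' @noRd
onset_to_slope_lag <- function(ld, params, noisy = FALSE, prob = 0.5) {
  fs <- params$fs_hz
  at <- 250; rt <- at + 250
  n <- round((rt + 120) * fs / 1000)
  t_ms <- (seq_len(n) - 1L) * 1000 / fs
  v0 <- beat_voltage(t_ms, at, rt, +1, params, ld)
  one <- function(v) {
    d <- delineate_egm(list(voltage = v, fs = fs))
    sd <- smoothed_derivative(v, fs)
    idx <- d$qrs_on:d$qrs_off
    (idx[which.min(sd[idx])] - d$qrs_on) * 1000 / fs
  }
  if (!noisy || params$noise_sd_mv == 0) return(one(v0))
  # under noise the detected onset sits at the suprathreshold region start;
  # measure the lag as a median over representative noisy realizations at
  # the post-averaging noise level
  s <- params$noise_sd_mv / sqrt(params$beats)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(760531L)
  lags <- vapply(seq_len(15L), function(i) {
    one(v0 + stats::rnorm(length(v0), 0, s))
  }, numeric(1))
  stats::quantile(lags, prob, names = FALSE)
}

# Solve the slow-descent length `ld` (ms) such that the onset-to-slope lag
# of the shape approximately equals `target_lag_ms`. The lag is roughly
# `ld` plus the steep half-width; clamped to [0, 70] ms.
#' @keywords internal
#' @noRd
solve_onset_lag <- function(target_lag_ms, params, noisy = FALSE,
                            prob = 0.5) {
  ld <- min(max(target_lag_ms - .qrs_shape$hd, 0), 70)
  for (i in 1:8) {
    lag <- onset_to_slope_lag(ld, params, noisy = noisy, prob = prob)
    if (abs(target_lag_ms - lag) < 0.5) break
    ld <- min(max(ld + (target_lag_ms - lag), 0), 70)
  }
  ld
}

# Simulated offset of the detected global QRS start: rebuild the earliest
# activations as noisy averaged beats (shared common-noise realization, as
# after signal averaging), delineate them, and measure where the minimum
# detected onset lands relative to the map's time zero. Median over
# realizations; used to fine-tune `ld` so the offset vanishes.
#' @keywords internal
#' @noRd
simulate_t0_offset <- function(ld, at, params, reps = 9L, n_low = 10L) {
  fs <- params$fs_hz
  a_low <- sort(at)[seq_len(min(n_low, length(at)))]
  a_rel <- a_low - a_low[1]
  base <- 250
  rt <- base + 300
  n <- round((rt + 120) * fs / 1000)
  t_ms <- (seq_len(n) - 1L) * 1000 / fs
  beats <- lapply(a_rel, function(a)
    beat_voltage(t_ms, base + a, rt + a, +1, params, ld))
  s_com <- params$noise_sd_mv * sqrt(1 - params$noise_indep_frac^2) /
    sqrt(params$beats)
  s_ind <- params$noise_sd_mv * params$noise_indep_frac / sqrt(params$beats)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(981247L)
  offs <- vapply(seq_len(reps), function(r) {
    common <- stats::rnorm(n, 0, s_com)
    qo <- vapply(seq_along(beats), function(i) {
      v <- beats[[i]] + common + stats::rnorm(n, 0, s_ind)
      d <- tryCatch(delineate_egm(list(voltage = v, fs = fs)),
                    error = function(e) NULL)
      if (is.null(d)) NA_real_ else d$qrs_on * 1000 / fs
    }, numeric(1))
    # time zero of the mini-map sits at (base - target lag) = base - a_low[1]
    min(qo, na.rm = TRUE) - (base - a_low[1])
  }, numeric(1))
  stats::median(offs) - 1000 / fs  # sample index 1 is time 0
}

#' Synthesize a raw multi-beat electrogram for one node
#'
#' Builds `length(rr_ms)` beats whose QRS steepest negative slope falls at
#' (beat time zero + `at_ms`) and whose T-wave steepest positive slope falls
#' at (beat time zero + `rt_ms`), adds a baseline-wander sinusoid and white
#' noise, and returns the voltage trace. The placement of both events is
#' verified at generation by numerical differentiation of the clean beat.
#'
#' @param at_ms activation time within the beat (ms, from beat time zero)
#' @param rt_ms repolarization time within the beat (ms); must exceed `at_ms`
#' @param t_polarity +1 upright, -1 inverted T
#' @param params waveform parameters ([waveform_params()])
#' @param rr_ms vector of RR intervals (ms), one per beat
#' @param seed integer seed for wander phase and noise
#' @param ld QRS slow-descent length (ms); default solves the onset lag so
#'   that the node's detected QRS onset coincides with beat time zero
#' @param pad_ms quiet padding before the first and after the last beat
#' @return numeric voltage trace (mV) with attributes `onsets` (sample index
#'   of each beat's time zero) and `ld`
#' @export
synthesize_beat_train <- function(at_ms, rt_ms, t_polarity = 1, params = waveform_params(),
                                  rr_ms = rep(600, 10), seed = 1, ld = NULL,
                                  pad_ms = 400) {
  if (rt_ms <= at_ms) stop("rt_ms must exceed at_ms (positive ARI)")
  if (at_ms < 0 || rt_ms + params$t_width_ms / 2 > min(rr_ms))
    stop("activation/repolarization outside the beat period")
  fs <- params$fs_hz
  if (is.null(ld)) ld <- solve_onset_lag(at_ms, params)
  onsets_ms <- pad_ms + c(0, cumsum(rr_ms[-length(rr_ms)]))
  n <- round((pad_ms + sum(rr_ms) + pad_ms) * fs / 1000)
  t_ms <- (seq_len(n) - 1L) * 1000 / fs
  v <- numeric(n)
  ext <- qrs_extent(ld)
  span <- c(-(ext[["before"]] + 10), rt_ms + 3.5 * params$t_width_ms / 6 + 10)
  for (o in onsets_ms) {
    i1 <- max(1L, floor((o + at_ms + span[1]) * fs / 1000) + 1L)
    i2 <- min(n, ceiling((o + span[2]) * fs / 1000) + 1L)
    idx <- i1:i2
    v[idx] <- v[idx] + beat_voltage(t_ms[idx] - o, at_ms, rt_ms, t_polarity,
                                    params, ld)
  }
  set.seed(seed)
  phase <- stats::runif(1, 0, 2 * pi)
  v <- v + params$wander_amp_mv * sin(2 * pi * params$wander_hz * t_ms / 1000 + phase)
  if (params$noise_sd_mv > 0) v <- v + stats::rnorm(n, 0, params$noise_sd_mv)
  structure(v, onsets = round(onsets_ms * fs / 1000) + 1L, ld = ld)
}

# Synthesize the full signals matrix (samples x nodes) for one subject and
# phase from its truth fields. All nodes share the beat grid; the downstroke
# half-width is solved once from the earliest activation so that the
# extracted global QRS start coincides with the truth time zero.
#' @keywords internal
#' @noRd
synthesize_subject_signals <- function(truth, params, rr_mean_ms, seed) {
  fs <- params$fs_hz
  at <- truth$at_ms; rt <- truth$rt_ms; pol <- truth$t_polarity
  n_nodes <- length(at)
  # the extracted global QRS start is the minimum of noisy per-node onsets:
  # start from the clean single-beat solution, then fine-tune by direct
  # simulation of the detected minimum over the earliest activations
  ld <- solve_onset_lag(min(at), params)
  for (i in 1:3) {
    off <- simulate_t0_offset(ld, at, params)
    if (abs(off) < 0.5) break
    ld <- min(max(ld + off, 0), 70)  # a late t0 needs a longer onset lag
  }
  ext <- qrs_extent(ld)
  # QT-rate consistency clamp: the analysis window around each beat must
  # cover the latest T wave before the next beat's QRS energy begins
  rr_floor <- (max(rt) - min(at) + ext[["before"]] + 85) / 0.85
  rr_mean_ms <- max(rr_mean_ms, rr_floor)
  seeds <- spawn_seeds(seed, 3L)
  set.seed(seeds[1])
  rr <- rr_mean_ms * (1 + params$rr_jitter_frac * stats::rnorm(params$beats))
  rr <- pmax(rr, 0.85 * rr_mean_ms)
  pad_ms <- 400
  onsets_ms <- pad_ms + c(0, cumsum(rr[-length(rr)]))
  n <- round((pad_ms + sum(rr) + pad_ms) * fs / 1000)
  t_ms <- (seq_len(n) - 1L) * 1000 / fs

  # per-node beat segment placed additively at every onset
  seg_lo <- floor(min(at) - ext[["before"]] - 10)
  seg_hi <- ceiling(max(rt) + 3.5 * params$t_width_ms / 6 + 10)
  seg_t <- seq(seg_lo, seg_hi, by = 1000 / fs)
  onset_samples <- round(onsets_ms * fs / 1000)  # 0-based sample of time zero
  base_idx <- outer(round(seg_t * fs / 1000), onset_samples, "+") + 1L
  keep <- base_idx >= 1L & base_idx <= n
  sig <- matrix(0, nrow = n, ncol = n_nodes)
  for (j in seq_len(n_nodes)) {
    seg <- beat_voltage(seg_t, at[j], rt[j], pol[j], params, ld)
    vals <- matrix(seg, nrow = length(seg), ncol = length(onset_samples))
    vj <- numeric(n)
    vj[base_idx[keep]] <- vj[base_idx[keep]] + vals[keep]
    sig[, j] <- vj
  }
  set.seed(seeds[2])
  phases <- stats::runif(n_nodes, 0, 2 * pi)
  wander_t <- 2 * pi * params$wander_hz * t_ms / 1000
  sw <- sin(wander_t); cw <- cos(wander_t)
  sig <- sig + params$wander_amp_mv *
    (outer(sw, cos(phases)) + outer(cw, sin(phases)))
  set.seed(seeds[3])
  if (params$noise_sd_mv > 0) {
    s_ind <- params$noise_sd_mv * params$noise_indep_frac
    s_com <- sqrt(params$noise_sd_mv^2 - s_ind^2)
    common <- stats::rnorm(n, 0, s_com)
    sig <- sig + common +
      matrix(stats::rnorm(n * n_nodes, 0, s_ind), n, n_nodes)
  }
  list(signals = sig, fs = fs, onsets = onset_samples + 1L, rr_ms = rr,
       rr_mean_ms = rr_mean_ms, ld = ld)
}
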