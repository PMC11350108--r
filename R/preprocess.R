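#' Electrogram preprocessing: baseline removal, template matching, averaging
#'
#' Converts a raw multi-beat trace into one signal-averaged electrogram per
#' node: remove baseline wander with a zero-phase high-pass, pick a template
#' QRS-T complex, locate the most template-similar regions of interest by
#' normalized cross-correlation, and average them.
#'
#' @name preprocess
NULL

#' Remove baseline wander with a zero-phase high-pass filter
#'
#' Second-order Butterworth high-pass (default cutoff 0.5 Hz) applied
#' forward-backward (zero phase), which preserves the dV/dt timing the
#' markers depend on. The trace is reflection-padded before filtering to
#' suppress edge transients.
#'
#' @param trace voltage samples (mV)
#' @param fs sampling rate, Hz
#' @param cutoff_hz high-pass cutoff, Hz
#' @return filtered trace, same length
#' @export
remove_baseline <- function(trace, fs, cutoff_hz = 0.5) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  n <- length(trace)
  if (n < fs) stop("trace must contain at least 1 s of samples")
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "high")
  pad <- min(n - 1L, as.integer(2 * fs))
  padded <- c(rev(trace[seq_len(pad) + 1L]), trace,
              rev(trace[(n - pad):(n - 1L)]))
  out <- signal::filtfilt(bf, padded)
  out[(pad + 1L):(pad + n)]
}

# Filter all columns of a samples x nodes matrix at once.
#' @keywords internal
#' @noRd
remove_baseline_matrix <- function(mat, fs, cutoff_hz = 0.5) {
  apply(mat, 2, remove_baseline, fs = fs, cutoff_hz = cutoff_hz)
}

#' Detect beats on a trace by slope-threshold peak picking
#'
#' Marks one fiducial sample per beat: local maxima of the smoothed |dV/dt|
#' above a fraction of its robust maximum, separated by a refractory period.
#'
#' The refractory period adapts to the rhythm: the RR interval is first
#' estimated from the autocorrelation of the smoothed |dV/dt| (dominant lag
#' above `min_separation_ms`), and marks closer than 70% of it keep only the
#' strongest slope — so T-wave slopes never register as extra beats.
#'
#' @param trace voltage samples
#' @param fs Hz
#' @param min_separation_ms minimum refractory period between beat marks
#' @param threshold_frac detection threshold as fraction of the robust
#'   maximum of smoothed |dV/dt|
#' @return integer vector of beat fiducial samples
#' @export
detect_beats <- function(trace, fs, min_separation_ms = 250,
                         threshold_frac = 0.4) {
  sda <- abs(smoothed_derivative(trace, fs))
  thr <- threshold_frac * stats::quantile(sda, 0.999, names = FALSE)
  runs <- true_runs(sda >= thr)
  if (nrow(runs) == 0L) return(integer(0))
  marks <- apply(runs, 1, function(r) {
    seg <- r[1]:r[2]
    seg[which.max(sda[seg])]
  })
  marks <- sort(marks)
  # refractory period from the autocorrelation-estimated RR
  min_sep <- min_separation_ms * fs / 1000
  rr_est <- rr_estimate(trace, fs, min_separation_ms)
  if (!is.na(rr_est)) min_sep <- max(min_sep, 0.7 * rr_est)
  keep <- c()
  for (m in marks) {
    if (length(keep) && (m - keep[length(keep)]) < min_sep) {
      if (sda[m] > sda[keep[length(keep)]]) keep[length(keep)] <- m
    } else keep <- c(keep, m)
  }
  as.integer(keep)
}

# Window geometry around a beat anchor: start/end offsets in samples.
# `post` is capped both by the configured QT coverage and by the median RR so
# that a window never reaches far into the next beat's QRS.
#' @keywords internal
#' @noRd
beat_window_offsets <- function(fs, rr_med, pre_ms = 80, max_post_ms = 520,
                                rr_frac = 0.85) {
  pre <- round(pre_ms * fs / 1000)
  post <- round(min(max_post_ms * fs / 1000, rr_frac * rr_med))
  list(pre = as.integer(pre), post = as.integer(post))
}

# RR period estimate (samples) from the autocorrelation of a slope
# envelope. The global autocorrelation maximum sits at the true period or
# one of its multiples (all near-exact repeats); intra-beat structure (the
# QRS-T alternation) creates strong but clearly weaker sub-multiple peaks.
# Step down through integer sub-multiples of the global peak lag while
# the autocorrelation there stays within 90% of the peak.
#' @keywords internal
#' @noRd
rr_estimate <- function(envelope, fs, min_ms = 250) {
  lag_max <- min(length(envelope) - 1L, round(2.5 * fs))
  ac <- stats::acf(envelope, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[-1]
  lo <- ceiling(min_ms * fs / 1000)
  if (lo >= length(ac)) return(NA_integer_)
  pk <- lo - 1L + which.max(ac[lo:length(ac)])
  best <- pk
  for (k in 4:2) {
    cand <- pk / k
    if (cand < lo) next
    win <- max(lo, round(0.93 * cand)):min(length(ac), round(1.07 * cand))
    if (max(ac[win]) >= 0.95 * ac[pk]) {
      best <- win[which.max(ac[win])]
      break
    }
  }
  as.integer(best)
}

# Beat anchors on a multi-node composite: the ends of the long quiet
# stretches of the smoothed |dV/dt| envelope (diastolic gaps), kept to the
# phase cluster - modulo the autocorrelation RR - with the most slope
# energy right after the anchor. On a composite, |dV/dt| peak positions are
# ambiguous (the pooled T band can rival the activation band diluted over
# the activation spread), but each cycle has exactly one diastole and the
# QRS band that follows it carries the largest slope energy.
#' @keywords internal
#' @noRd
beat_anchors <- function(envelope, fs, frac = 0.1, min_quiet_ms = 60,
                         rr = NULL, alt_phase = FALSE) {
  n <- length(envelope)
  floor_env <- stats::median(envelope)
  thr <- floor_env + frac * (max(envelope) - floor_env)
  quiet <- true_runs(envelope < thr)
  min_q <- round(min_quiet_ms * fs / 1000)
  quiet <- quiet[quiet[, 2] - quiet[, 1] + 1L >= min_q, , drop = FALSE]
  cand <- unname(quiet[, 2]) + 1L
  cand <- cand[cand <= n - round(0.3 * fs)]
  if (length(cand) < 2L) return(as.integer(cand))
  if (is.null(rr)) rr <- rr_estimate(envelope, fs)
  if (is.na(rr)) return(as.integer(sort(cand)))
  span <- round(0.35 * rr)
  # the band following a diastole holds the activation complex, whose
  # envelope peak dominates any repolarization band
  score <- vapply(cand, function(a)
    max(envelope[a:min(n, a + span)]), numeric(1))
  seed <- cand[which.max(score)]
  if (alt_phase) {
    ph0 <- ((cand - seed) %% rr + rr) %% rr
    others <- cand[ph0 > 0.25 * rr & ph0 < 0.75 * rr]
    if (length(others)) seed <- others[which.max(score[match(others, cand)])]
  }
  ph <- ((cand - seed) %% rr + rr) %% rr
  keep <- ph <= 0.2 * rr | ph >= 0.8 * rr
  anchors <- sort(cand[keep])
  # deduplicate anchors closer than half a period (keep the stronger)
  out <- integer(0)
  for (a in anchors) {
    if (length(out) && a - out[length(out)] < 0.5 * rr) {
      if (score[match(a, cand)] > score[match(out[length(out)], cand)])
        out[length(out)] <- a
    } else out <- c(out, a)
  }
  as.integer(out)
}

#' Select the template QRS-T complex
#'
#' Automates the interactive template choice: among the detected beats, pick
#' the one maximizing the mean normalized cross-correlation against all other
#' beats. Windows are anchored on the onset of each beat's suprathreshold
#' slope region (stable against where the |dV/dt| argmax falls within the
#' QRS band). A `manual_index` (0-based beat index) overrides the automatic
#' choice.
#'
#' @param trace voltage samples (baseline-filtered)
#' @param fs Hz
#' @param manual_index optional 0-based index of the beat to use
#' @param pre_ms window start before the beat anchor, ms
#' @param max_post_ms maximum window extent after the anchor, ms
#' @param alt_phase anchor on the second-best beat-phase cluster (fallback
#'   when the primary anchoring rotates the window into the wrong part of
#'   the cycle)
#' @return a `beat_window`: list with `start`, `end` (sample indices),
#'   `score` (mean correlation against other beats), `marks` (all beat
#'   fiducials), `rr_med` (median RR in samples)
#' @export
pick_template <- function(trace, fs, manual_index = NULL, pre_ms = 80,
                          max_post_ms = 520, alt_phase = FALSE) {
  if (length(detect_beats(trace, fs)) < 2L)
    stop("insufficient beats: need >= 2 detectable beats")
  sda <- abs(smoothed_derivative(trace, fs))
  sda <- pmax(sda - stats::quantile(sda, 0.25, names = FALSE), 0)  # noise-floor correction
  envelope <- moving_average(sda, round(30 * fs / 1000))
  anchors <- beat_anchors(envelope, fs, rr = rr_estimate(trace, fs),
                          alt_phase = alt_phase)
  marks <- anchors
  if (length(anchors) < 2L)
    stop("insufficient beats: need >= 2 detectable beats, found ",
         length(anchors))
  rr_med <- stats::median(diff(anchors))
  off <- beat_window_offsets(fs, rr_med, pre_ms, max_post_ms)
  n <- length(trace)
  win_ok <- anchors - off$pre >= 1L & anchors + off$post <= n
  marks_ok <- anchors[win_ok]
  if (length(marks_ok) < 2L) stop("insufficient beats with complete windows")
  segs <- lapply(marks_ok, function(m) trace[(m - off$pre):(m + off$post)])
  k <- length(segs)
  cmat <- matrix(1, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    cmat[i, j] <- cmat[j, i] <- stats::cor(segs[[i]], segs[[j]])
  }
  mean_cor <- (rowSums(cmat) - 1) / (k - 1)
  if (!is.null(manual_index)) {
    if (manual_index < 0L || manual_index >= k)
      stop("manual_index out of range: 0..", k - 1L)
    best <- manual_index + 1L
  } else {
    best <- which.max(mean_cor)
  }
  m <- marks_ok[best]
  structure(list(start = m - off$pre, end = m + off$post,
                 score = mean_cor[best], marks = marks,
                 rr_med = rr_med, pre = off$pre, post = off$post),
            class = "beat_window")
}

#' Find the regions of interest most similar to the template
#'
#' Slides the template over the whole trace by normalized cross-correlation
#' and keeps up to `k` windows with the highest correlation, subject to a
#' minimum separation of 60% of the median RR. Windows below the correlation
#' floor are not returned; the shortfall (k minus windows found) is recorded.
#'
#' @param trace voltage samples
#' @param template a `beat_window` from [pick_template()]
#' @param k number of regions of interest to collect
#' @param corr_floor minimum acceptable correlation
#' @return list of `beat_window`s (each with `start`, `end`, `score`),
#'   with attributes `shortfall` and `lags` (refined alignment lags)
#' @export
match_rois <- function(trace, template, k = 10, corr_floor = 0.8) {
  tpl <- trace[template$start:template$end]
  ncc <- sliding_ncc(trace, tpl)
  len <- length(tpl)
  min_sep <- max(1, round(0.6 * template$rr_med))
  ord <- order(ncc, decreasing = TRUE)
  starts <- integer(0); scores <- numeric(0)
  for (s in ord) {
    if (ncc[s] < corr_floor) break
    if (length(starts) >= k) break
    if (length(starts) && any(abs(starts - s) < min_sep)) next
    starts <- c(starts, s); scores <- c(scores, ncc[s])
  }
  if (length(starts) == 0L)
    stop("no regions of interest matched above the correlation floor ",
         corr_floor)
  o <- order(starts)
  starts <- starts[o]; scores <- scores[o]
  wins <- lapply(seq_along(starts), function(i) {
    structure(list(start = starts[i], end = starts[i] + len - 1L,
                   score = scores[i]), class = "beat_window")
  })
  attr(wins, "shortfall") <- max(0L, as.integer(k) - length(wins))
  wins
}

#' Signal-average a set of beat windows
#'
#' Aligns each window to the first (template) window by the lag maximizing
#' the cross-correlation within `max_lag_ms`, then takes the pointwise mean.
#' Precomputed lags can be supplied to enforce a common alignment across
#' nodes (so that inter-node timing is preserved).
#'
#' @param windows list of `beat_window`s (from [match_rois()])
#' @param trace voltage samples the windows index into
#' @param fs Hz
#' @param node_id identifier stored on the output
#' @param lags optional integer vector of per-window alignment lags
#'   (samples); 0 keeps the window where it is
#' @param max_lag_ms alignment search half-range, ms
#' @return an `averaged_egm`: list with `node_id`, `voltage`, `fs`,
#'   `beats_used`
#' @export
signal_average <- function(windows, trace, fs, node_id = NA, lags = NULL,
                           max_lag_ms = 15) {
  if (length(windows) < 1L) stop("signal_average needs at least one window")
  len <- windows[[1]]$end - windows[[1]]$start + 1L
  for (w in windows) {
    if (w$end - w$start + 1L != len)
      stop("window lengths inconsistent: cannot align for averaging")
  }
  ref <- trace[windows[[1]]$start:windows[[1]]$end]
  max_lag <- round(max_lag_ms * fs / 1000)
  n <- length(trace)
  if (is.null(lags)) {
    lags <- vapply(seq_along(windows), function(i) {
      if (i == 1L) return(0L)
      w <- windows[[i]]
      cand <- (-max_lag):max_lag
      cand <- cand[w$start + cand >= 1L & w$end + cand <= n]
      cors <- vapply(cand, function(l) {
        stats::cor(ref, trace[(w$start + l):(w$end + l)])
      }, numeric(1))
      as.integer(cand[which.max(cors)])
    }, integer(1))
  }
  if (length(lags) != length(windows))
    stop("lags must match the number of windows")
  acc <- matrix(NA_real_, nrow = len, ncol = length(windows))
  for (i in seq_along(windows)) {
    s <- windows[[i]]$start + lags[i]
    e <- windows[[i]]$end + lags[i]
    if (s < 1L || e > n) stop("aligned window out of trace bounds")
    acc[, i] <- trace[s:e]
  }
  structure(list(node_id = node_id, voltage = rowMeans(acc), fs = fs,
                 beats_used = length(windows)),
            class = "averaged_egm")
}
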