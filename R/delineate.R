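#' Rule-based delineation of an averaged electrogram
#'
#' Locates the QRS complex and the T wave on a signal-averaged electrogram
#' with a deterministic slope-threshold rule, and produces a per-sample label
#' track (baseline / QRS / T):
#'
#' * QRS: the contiguous region where the smoothed |dV/dt| exceeds
#'   `theta_qrs` times its global maximum (the region containing that
#'   maximum), expanded outward to the nearest sign changes of the smoothed
#'   derivative.
#' * T: among the post-QRS regions where smoothed |dV/dt| exceeds `theta_t`
#'   times its own post-QRS maximum (regions separated by less than
#'   `merge_gap_ms` are merged, which bridges the zero-slope T apex), the
#'   region containing the post-QRS |dV/dt| maximum; if that run was
#'   discarded as truncated next-beat energy, the region with the largest
#'   integrated |dV/dt|.
#'
#' All thresholds are relative, so delineation is invariant to voltage
#' scaling.
#'
#' @param egm an `averaged_egm` (see [signal_average()]); any list with
#'   `voltage` and `fs` works
#' @param theta_qrs QRS slope threshold (fraction of global max)
#' @param theta_t T slope threshold (fraction of post-QRS max)
#' @param smooth_ms smoothing window for |dV/dt|, ms
#' @param merge_gap_ms maximum gap between suprathreshold T regions merged
#'   into one T wave
#' @param refractory_ms blanking after QRS end before the T search starts
#' @param min_run_ms suprathreshold runs shorter than this are treated as
#'   noise and discarded before merging
#' @param cut_frac candidate T regions that run into the end of the window
#'   while their |dV/dt| is still above this fraction of the region maximum
#'   are discarded: such still-rising truncated energy is the beginning of
#'   the next beat's QRS, whereas a merely truncated T wave is already
#'   decaying at the cut
#' @return a `delineation`: list with sample indices `qrs_on`, `qrs_off`,
#'   `t_on`, `t_off` (T fields NA if no T found), per-sample `labels`
#'   (factor: baseline/QRS/T), and `quality` (initially `"accepted"` or
#'   `"rejected_no_t"`; see [assess_quality()])
#' @export
delineate_egm <- function(egm, theta_qrs = 0.2, theta_t = 0.15,
                          smooth_ms = 10, merge_gap_ms = 40,
                          refractory_ms = 20, min_run_ms = 8,
                          cut_frac = 0.7) {
  v <- egm$voltage
  fs <- egm$fs
  if (length(v) < 0.3 * fs)
    stop("electrogram too short: delineation needs >= 300 ms of samples")
  sd_signed <- smoothed_derivative(v, fs, smooth_ms)
  sda <- moving_average(abs(central_diff(v) * fs / 1000),
                        round(smooth_ms * fs / 1000))
  n <- length(v)
  # the mean |dV/dt| of additive noise does not average away: subtract a
  # lower-quartile noise-floor estimate (robust to the fraction of the
  # window occupied by signal) so the relative thresholds act on the
  # signal's slope energy alone
  sda <- pmax(sda - stats::quantile(sda, 0.25, names = FALSE), 0)

  ## --- QRS ---
  peak <- which.max(sda)
  thr_q <- theta_qrs * sda[peak]
  runs <- true_runs(sda >= thr_q)
  if (nrow(runs) == 0L) stop("no QRS: no suprathreshold slope region")
  qrun <- runs[runs[, 1] <= peak & runs[, 2] >= peak, , drop = FALSE]
  if (nrow(qrun) == 0L) stop("no QRS: no suprathreshold slope region")
  qrs_on <- unname(qrun[1, 1]); qrs_off <- unname(qrun[1, 2])
  # expand to the nearest sign changes of the smoothed derivative; the
  # expansion also stops where |dV/dt| decays below 5% of the QRS maximum,
  # so it cannot wander through sign-runs of smoothed noise
  floor_q <- 0.05 * sda[peak]
  while (qrs_on > 1L && sign(sd_signed[qrs_on - 1L]) == sign(sd_signed[qrs_on]) &&
         sd_signed[qrs_on - 1L] != 0 && sda[qrs_on - 1L] >= floor_q)
    qrs_on <- qrs_on - 1L
  while (qrs_off < n && sign(sd_signed[qrs_off + 1L]) == sign(sd_signed[qrs_off]) &&
         sd_signed[qrs_off + 1L] != 0 && sda[qrs_off + 1L] >= floor_q)
    qrs_off <- qrs_off + 1L

  ## --- T ---
  # short blanking after the QRS region (which already spans the terminal
  # S recovery), proportional to the detected QRS duration
  refractory <- max(round(refractory_ms * fs / 1000),
                    round(0.25 * (qrs_off - qrs_on)))
  t_start <- qrs_off + refractory
  t_on <- NA_integer_; t_off <- NA_integer_
  quality <- "accepted"
  if (t_start < n - 4L) {
    post <- sda[t_start:n]
    thr_t <- theta_t * max(post)
    runs_t <- true_runs(post >= thr_t)
    # discard noise blips and still-rising energy truncated by the window
    # end (partial next-beat QRS)
    min_run <- round(min_run_ms * fs / 1000)
    keep_run <- vapply(seq_len(nrow(runs_t)), function(i) {
      r <- runs_t[i, ]
      if (r[2] - r[1] + 1L < min_run) return(FALSE)
      if (r[2] >= length(post) - 3L &&
          post[r[2]] >= cut_frac * max(post[r[1]:r[2]])) return(FALSE)
      TRUE
    }, logical(1))
    runs_t <- runs_t[keep_run, , drop = FALSE]
    if (nrow(runs_t) > 0L) {
      gap <- round(merge_gap_ms * fs / 1000)
      merged <- runs_t[1, , drop = FALSE]
      if (nrow(runs_t) > 1L) for (i in 2L:nrow(runs_t)) {
        if (runs_t[i, 1] - merged[nrow(merged), 2] <= gap) {
          merged[nrow(merged), 2] <- runs_t[i, 2]
        } else merged <- rbind(merged, runs_t[i, , drop = FALSE])
      }
      # a T wave has an apex: its smoothed derivative swings both ways.
      # Single-signed slope regions (e.g. the terminal QRS recovery) are
      # not T candidates. The check looks 15 ms past the region in case
      # the descending limb was truncated by the window end.
      biphasic <- vapply(seq_len(nrow(merged)), function(i) {
        idx <- (t_start + merged[i, 1] - 1L):
          min(n, t_start + merged[i, 2] - 1L + round(15 * fs / 1000))
        seg <- sd_signed[idx]
        mx <- max(abs(seg))
        max(seg) >= 0.3 * mx && min(seg) <= -0.3 * mx
      }, logical(1))
      merged <- merged[biphasic, , drop = FALSE]
    }
    if (nrow(runs_t) > 0L && nrow(merged) > 0L) {
      pk <- which.max(post)
      best <- which(merged[, 1] <= pk & merged[, 2] >= pk)
      if (length(best) != 1L) {
        energy <- apply(merged, 1, function(r) sum(post[r[1]:r[2]]))
        best <- which.max(energy)
      }
      t_on <- unname(t_start + merged[best, 1] - 1L)
      t_off <- unname(t_start + merged[best, 2] - 1L)
    } else {
      quality <- "rejected_no_t"
    }
  } else {
    quality <- "rejected_no_t"
  }

  labels <- rep("baseline", n)
  labels[qrs_on:qrs_off] <- "QRS"
  if (!is.na(t_on)) labels[t_on:t_off] <- "T"
  structure(list(qrs_on = qrs_on, qrs_off = qrs_off,
                 t_on = t_on, t_off = t_off,
                 labels = factor(labels, levels = c("baseline", "QRS", "T")),
                 quality = quality),
            class = "delineation")
}

#' Count prominent deflections in a signal segment
#'
#' A deflection is a local extremum whose prominence (height above the higher
#' of the two flanking saddle levels) is at least `prominence_frac` of the
#' segment's peak-to-peak amplitude. A flat segment has zero deflections.
#'
#' @param segment voltage samples
#' @param prominence_frac prominence floor as a fraction of peak-to-peak
#' @return integer count of deflections
#' @export
count_deflections <- function(segment, prominence_frac = 0.1) {
  if (length(segment) == 0L) stop("segment must be non-empty")
  ptp <- diff(range(segment))
  if (ptp == 0) return(0L)
  floor_prom <- prominence_frac * ptp
  n <- length(segment)
  dx <- diff(segment)
  s <- sign(dx)
  s_nz <- s[s != 0]
  idx_nz <- which(s != 0)
  if (length(s_nz) < 2L) return(0L)

  # prominence of the extremum at i: on each side, the lowest (for a max) /
  # highest (for a min) level reached before a sample beyond the extremum's
  # own level; the prominence is the drop to the higher of the two bases
  prominence <- function(i, is_max) {
    val <- segment[i]
    side_base <- function(idx_seq) {
      base <- val
      for (j in idx_seq) {
        if (is_max) {
          if (segment[j] > val) break
          base <- min(base, segment[j])
        } else {
          if (segment[j] < val) break
          base <- max(base, segment[j])
        }
      }
      base
    }
    lb <- side_base(rev(seq_len(max(i - 1L, 1L))))
    rb <- side_base(seq.int(min(i + 1L, n), n))
    if (is_max) val - max(lb, rb) else min(lb, rb) - val
  }

  count <- 0L
  for (j in seq_len(length(s_nz) - 1L)) {
    if (s_nz[j] != s_nz[j + 1L]) {
      i <- idx_nz[j + 1L]  # extremum at the end of the preceding run
      if (prominence(i, is_max = s_nz[j] > 0) >= floor_prom)
        count <- count + 1L
    }
  }
  count
}

#' Interpretability-based quality assessment of a delineated electrogram
#'
#' Applies the rejection rules used before marker extraction: electrograms
#' whose T-wave amplitude is low relative to the QRS are rejected
#' (`rejected_low_amplitude`, threshold `t_amp_frac` of QRS peak-to-peak),
#' as are T waves with three or more prominent deflections
#' (`rejected_t_deflections`). Electrograms without a T wave keep
#' `rejected_no_t`.
#'
#' @param egm an `averaged_egm`
#' @param delin its `delineation`
#' @param t_amp_frac minimum T peak-to-peak as a fraction of QRS peak-to-peak
#' @param max_deflections rejection threshold on the deflection count
#' @param prominence_frac passed to [count_deflections()]
#' @return the delineation with `quality` set
#' @export
assess_quality <- function(egm, delin, t_amp_frac = 0.05,
                           max_deflections = 3, prominence_frac = 0.1) {
  if (!identical(delin$quality, "accepted")) return(delin)
  v <- egm$voltage
  qrs_ptp <- diff(range(v[delin$qrs_on:delin$qrs_off]))
  tseg <- v[delin$t_on:delin$t_off]
  t_ptp <- diff(range(tseg))
  if (t_ptp < t_amp_frac * qrs_ptp) {
    delin$quality <- "rejected_low_amplitude"
  } else if (count_deflections(tseg, prominence_frac) >= max_deflections) {
    delin$quality <- "rejected_t_deflections"
  }
  delin
}
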