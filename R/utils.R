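# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  # force odd width: a centered window keeps smoothed extrema unshifted
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  k <- rep(1 / width, width)
  n <- length(x)
  # centered moving average with edge shrinkage (partial windows at the ends)
  csum <- cumsum(c(0, x))
  half_lo <- (width - 1L) %/% 2L
  half_hi <- width %/% 2L
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)
}

# Central-difference derivative, units of x per sample. Endpoints use
# one-sided differences so the output has the same length as the input.
#' @keywords internal
#' @noRd
central_diff <- function(x) {
  n <- length(x)
  if (n < 3L) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  d
}

# Smoothed signed derivative in units per ms (the derivative used for all
# marker timing: central difference then a 10 ms moving average by default).
#' @keywords internal
#' @noRd
smoothed_derivative <- function(x, fs, smooth_ms = 10) {
  d <- central_diff(x) * fs / 1000  # per ms
  moving_average(d, round(smooth_ms * fs / 1000))
}

# Contiguous runs of TRUE in a logical vector -> matrix with columns start,end.
#' @keywords internal
#' @noRd
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Normalized cross-correlation of a template against every lag of a trace.
# Returns a vector of length length(trace) - length(template) + 1 with the
# Pearson correlation between the template and each aligned window.
#' @keywords internal
#' @noRd
sliding_ncc <- function(trace, template) {
  nt <- length(template)
  n <- length(trace)
  if (nt > n) stop("template longer than trace", call. = FALSE)
  tm <- template - mean(template)
  denom_t <- sqrt(sum(tm^2))
  if (denom_t == 0) stop("template is constant", call. = FALSE)
  # cross-correlation numerator via FFT convolution with the reversed template
  num <- stats::convolve(trace, tm, conj = TRUE, type = "filter")
  # window sums for local mean/energy
  cs <- cumsum(c(0, trace))
  cs2 <- cumsum(c(0, trace^2))
  idx <- seq_len(n - nt + 1L)
  wsum <- cs[idx + nt] - cs[idx]
  wsum2 <- cs2[idx + nt] - cs2[idx]
  wvar <- pmax(wsum2 - wsum^2 / nt, 0)
  denom <- denom_t * sqrt(wvar)
  out <- ifelse(denom > 0, num / denom, 0)
  pmin(pmax(out, -1), 1)
}

# Draw n reproducible sub-seeds (31-bit) from a root seed without disturbing
# the caller's RNG stream more than once.
#' @keywords internal
#' @noRd
spawn_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Sub-sample refinement of a discrete extremum: least-squares parabola over
# +/- half samples around index i, vertex clamped to +/-2 samples. Returns
# the fractional sample index. Without refinement, one-sample quantization
# of marker times creates spurious discontinuities between close mesh
# neighbours.
#' @keywords internal
#' @noRd
refine_extremum <- function(y, i, half = 4L) {
  lo <- max(1L, i - half); hi <- min(length(y), i + half)
  u <- (lo:hi) - i
  if (length(u) < 5L) return(as.numeric(i))
  fit <- stats::lm.fit(cbind(1, u, u^2), y[lo:hi])
  a2 <- fit$coefficients[3]
  if (!is.finite(a2) || a2 == 0) return(as.numeric(i))
  v <- unname(-fit$coefficients[2] / (2 * a2))
  as.numeric(i) + min(max(v, -2), 2)
}
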