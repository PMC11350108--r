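test_that("baseline filter preserves the beat and attenuates wander by >= 20 dB", {
  fx <- canonical_egm(at = 40, rt = 290)
  clean <- fx$trace
  fs <- 1000
  out <- remove_baseline(clean, fs)
  expect_length(out, length(clean))
  # passband preservation within 5% of QRS amplitude (the DC offset of the
  # beat train is stop-band content by definition)
  expect_lt(max(abs(out - (clean - mean(clean)))), 0.05 * 1.0)
  # add a 0.25 Hz sinusoid and measure the residual at that frequency
  t <- seq_along(clean) / fs
  wander <- 0.3 * sin(2 * pi * 0.25 * t)
  filt <- remove_baseline(clean + wander, fs)
  amp_at <- function(x) {
    c0 <- sum(x * cos(2 * pi * 0.25 * t)); s0 <- sum(x * sin(2 * pi * 0.25 * t))
    2 * sqrt(c0^2 + s0^2) / length(x)
  }
  atten_db <- 20 * log10(amp_at(wander) / max(amp_at(filt - clean), 1e-9))
  expect_gt(atten_db, 20)
  expect_error(remove_baseline(clean, -1), "positive")
})

test_that("markers survive baseline drift end to end", {
  p <- waveform_params(noise_sd_mv = 0, wander_amp_mv = 0.3)
  tr <- synthesize_beat_train(40, 290, 1, p, rr_ms = rep(600, 10), seed = 2)
  filt <- remove_baseline(as.numeric(tr), 1000)
  egm <- average_one(filt)
  d <- delineate_egm(egm)
  expect_equal(local_activation_time(egm, d, d$qrs_on), 40, tolerance = 1)
})

test_that("template selection prefers the consensus beat", {
  fx <- canonical_egm(at = 40, rt = 290)
  tpl <- pick_template(fx$trace, 1000)
  expect_gt(tpl$score, 0.999)  # identical beats: any beat, score ~ 1
  # distort one beat's morphology (T lobe halved): the template must come
  # from the other nine (a pure amplitude change is invisible to
  # normalized cross-correlation by construction)
  tr2 <- fx$trace
  o <- fx$onsets[4]
  span <- o + (220:420)
  tr2[span] <- 0.5 * tr2[span]
  tpl2 <- pick_template(tr2, 1000)
  # brute-force oracle: the automatic choice attains the maximum mean
  # correlation over all beats, and the distorted beat scores strictly lower
  manual_scores <- sapply(0:9, function(b)
    pick_template(tr2, 1000, manual_index = b)$score)
  expect_equal(tpl2$score, max(manual_scores), tolerance = 1e-12)
  expect_lt(min(manual_scores), tpl2$score - 0.001)
  # manual override is a pass-through (0-based index)
  tpl3 <- pick_template(fx$trace, 1000, manual_index = 3)
  expect_equal(tpl3$start, sort(sapply(seq_along(fx$onsets), function(b)
    pick_template(fx$trace, 1000, manual_index = b - 1)$start))[4])
  expect_error(pick_template(fx$trace, 1000, manual_index = 99), "out of range")
  one_beat <- synthesize_beat_train(40, 290, 1,
    waveform_params(noise_sd_mv = 0, wander_amp_mv = 0),
    rr_ms = 1200, seed = 1)
  expect_error(pick_template(as.numeric(one_beat), 1000),
               "insufficient beats")
})

test_that("ROI matching finds every identical beat with unit correlation", {
  fx <- canonical_egm(at = 40, rt = 290)
  tpl <- pick_template(fx$trace, 1000)
  rois <- match_rois(fx$trace, tpl)
  expect_length(rois, 10)
  expect_equal(attr(rois, "shortfall"), 0)
  scores <- vapply(rois, `[[`, numeric(1), "score")
  expect_true(all(scores > 1 - 1e-6))
  starts <- vapply(rois, `[[`, numeric(1), "start")
  expect_equal(diff(starts), diff(fx$onsets), tolerance = 3)
})

test_that("ROI matching agrees with an exhaustive sliding-correlation oracle", {
  p <- waveform_params(noise_sd_mv = 0.01, wander_amp_mv = 0)
  tr <- as.numeric(synthesize_beat_train(40, 290, 1, p,
                                         rr_ms = rep(600, 6), seed = 5))
  tpl <- pick_template(tr, 1000)
  template <- tr[tpl$start:tpl$end]
  # oracle: direct correlation at every admissible lag
  nlag <- length(tr) - length(template) + 1
  cc <- vapply(seq_len(nlag), function(s)
    cor(template, tr[s:(s + length(template) - 1)]), numeric(1))
  expect_equal(epimapr:::sliding_ncc(tr, template), cc, tolerance = 1e-8)
  rois <- match_rois(tr, tpl, k = 10)
  expect_length(rois, 6)
  expect_equal(attr(rois, "shortfall"), 4)
  # each returned window sits on a local optimum of the oracle correlation
  for (w in rois) expect_gt(cc[w$start], 0.95)
})

test_that("signal averaging is exact for identical beats and order-invariant", {
  fx <- canonical_egm(at = 40, rt = 290)
  tpl <- pick_template(fx$trace, 1000)
  rois <- match_rois(fx$trace, tpl)
  egm <- signal_average(rois, fx$trace, 1000, node_id = 1)
  expect_equal(egm$beats_used, 10)
  one <- fx$trace[rois[[1]]$start:rois[[1]]$end]
  expect_equal(egm$voltage, one, tolerance = 1e-9)
  egm_perm <- signal_average(rev(rois), fx$trace, 1000, node_id = 1)
  expect_equal(sort(egm_perm$voltage), sort(egm$voltage), tolerance = 1e-9)
  single <- signal_average(rois[1], fx$trace, 1000, node_id = 1)
  expect_equal(single$voltage, one)
})

test_that("averaging ten beats reduces white noise by about sqrt(10)", {
  clean <- canonical_egm(at = 40, rt = 290, seed = 3)$trace
  noisy <- canonical_egm(at = 40, rt = 290, noise = 0.02, seed = 3)$trace
  tpl <- pick_template(noisy, 1000)
  rois <- match_rois(noisy, tpl)
  egm_n <- signal_average(rois, noisy, 1000, lags = rep(0L, length(rois)))
  egm_c <- signal_average(rois, clean, 1000, lags = rep(0L, length(rois)))
  resid_sd <- sd(egm_n$voltage - egm_c$voltage)
  expect_lt(abs(resid_sd - 0.02 / sqrt(10)), 0.2 * 0.02 / sqrt(10))
})

test_that("averaged-beat activation beats any single raw beat against truth", {
  # RMSE of LAT from the 10-beat average vs from single beats, over nodes
  set.seed(21)
  err_avg <- c(); err_one <- c()
  for (i in 1:25) {
    at <- runif(1, 30, 55)
    fx <- canonical_egm(at = at, rt = at + 230, noise = 0.05, seed = 100 + i)
    tpl <- pick_template(fx$trace, 1000)
    rois <- match_rois(fx$trace, tpl)
    egm <- signal_average(rois, fx$trace, 1000, lags = rep(0L, length(rois)))
    d <- tryCatch(delineate_egm(egm), error = function(e) NULL)
    if (is.null(d) || !identical(d$quality, "accepted")) next
    lat <- tryCatch(local_activation_time(egm, d, d$qrs_on),
                    error = function(e) NA)
    err_avg <- c(err_avg, lat - at)
    one <- signal_average(rois[3], fx$trace, 1000)
    d1 <- tryCatch(delineate_egm(one), error = function(e) NULL)
    lat1 <- if (is.null(d1)) NA else
      tryCatch(local_activation_time(one, d1, d1$qrs_on), error = function(e) NA)
    err_one <- c(err_one, lat1 - at)
  }
  rmse <- function(e) sqrt(mean(e^2, na.rm = TRUE))
  expect_lt(rmse(err_avg), rmse(err_one))
})
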