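test_that("delineation brackets the configured events on a clean beat", {
  egm <- average_one(canonical_egm(at = 40, rt = 290)$trace)
  d <- delineate_egm(egm)
  expect_identical(d$quality, "accepted")
  t0 <- d$qrs_on
  at_s <- t0 + 40  # event positions in window samples (1 ms sampling)
  expect_lte(d$qrs_on, at_s); expect_gte(d$qrs_off, at_s)
  rt_s <- t0 + 290
  expect_lte(d$t_on, rt_s); expect_gte(d$t_off, rt_s)
  expect_true(d$qrs_on < d$qrs_off, d$qrs_off <= d$t_on)
  expect_error(delineate_egm(list(voltage = rnorm(100), fs = 1000)),
               "300 ms")
})

test_that("delineation is invariant to voltage scaling", {
  egm <- average_one(canonical_egm(at = 45, rt = 280, noise = 0.01,
                                   seed = 4)$trace)
  d1 <- delineate_egm(egm)
  egm2 <- egm; egm2$voltage <- 40 * egm$voltage
  d2 <- delineate_egm(egm2)
  expect_equal(d1[c("qrs_on", "qrs_off", "t_on", "t_off")],
               d2[c("qrs_on", "qrs_off", "t_on", "t_off")])
})

test_that("per-sample labels agree with the generator's truth label track", {
  # truth labels come from the waveform geometry: QRS spans the detectable
  # slow descent through the S trough, T spans the suprathreshold slope
  # band of the Gaussian lobe (apex +/- 2.9 SD)
  set.seed(77)
  agree <- c()
  for (i in 1:6) {
    at <- runif(1, 30, 55)
    rt <- at + 240
    fx <- canonical_egm(at = at, rt = rt, seed = 200 + i)
    egm <- average_one(fx$trace)
    got <- delineate_egm(egm)
    # locate the beat inside the window via the known activation sample
    sdv <- epimapr:::smoothed_derivative(egm$voltage, egm$fs)
    zero <- which.min(sdv) - at  # window sample of the beat's time zero
    q <- epimapr:::.qrs_shape
    n <- length(egm$voltage)
    truth <- rep("baseline", n)
    # QRS runs from the slow-descent onset through the S trough
    qrs_span <- round(zero + at - (fx$ld + q$hd)):round(zero + at + q$hd + q$ls)
    truth[qrs_span[qrs_span >= 1 & qrs_span <= n]] <- "QRS"
    sig <- 140 / 6
    t_span <- round(zero + rt + sig - 2.9 * sig):round(zero + rt + sig + 2.9 * sig)
    truth[t_span[t_span >= 1 & t_span <= n]] <- "T"
    agree <- c(agree, mean(truth == as.character(got$labels)))
  }
  expect_gte(mean(agree), 0.95)
})

test_that("deflection counting matches an exhaustive extremum-scan oracle", {
  t <- seq(0, 1, length.out = 400)
  mono <- sin(pi * t)                       # single lobe
  expect_equal(count_deflections(mono), 1)
  bi <- sin(2 * pi * t)                     # two opposed lobes
  expect_equal(count_deflections(bi), 2)
  # k = 4 prominent interior lobes (alternating Gaussian bumps)
  centers <- c(0.2, 0.4, 0.6, 0.8)
  multi <- rowSums(sapply(seq_along(centers), function(k)
    (-1)^k * exp(-(t - centers[k])^2 / (2 * 0.03^2))))
  # oracle: enumerate strict local extrema, then count those whose
  # prominence (drop to the higher flanking saddle) clears 10% of ptp
  oracle <- function(x, frac = 0.1) {
    n <- length(x); cnt <- 0
    for (i in 2:(n - 1)) {
      if ((x[i] > x[i - 1] && x[i] > x[i + 1]) ||
          (x[i] < x[i - 1] && x[i] < x[i + 1])) {
        is_max <- x[i] > x[i - 1]
        base <- function(idx) {
          b <- x[i]
          for (j in idx) {
            if (is_max && x[j] > x[i]) break
            if (!is_max && x[j] < x[i]) break
            b <- if (is_max) min(b, x[j]) else max(b, x[j])
          }
          b
        }
        lb <- base(rev(seq_len(i - 1))); rb <- base((i + 1):n)
        prom <- if (is_max) x[i] - max(lb, rb) else min(lb, rb) - x[i]
        if (prom >= frac * diff(range(x))) cnt <- cnt + 1
      }
    }
    cnt
  }
  expect_equal(count_deflections(multi), 4)
  expect_equal(count_deflections(multi), oracle(multi))
  set.seed(6)
  wig <- sin(3 * 2 * pi * t) + 0.02 * rnorm(400)
  expect_equal(count_deflections(wig), oracle(wig))
  expect_equal(count_deflections(rep(1, 50)), 0)
  expect_error(count_deflections(numeric(0)), "non-empty")
})

test_that("quality rules reject low-amplitude and polymorphic T waves", {
  p_small <- waveform_params(noise_sd_mv = 0, wander_amp_mv = 0,
                             t_amp_mv = 0.008)  # T under 5% of QRS
  tr <- synthesize_beat_train(40, 290, 1, p_small, rr_ms = rep(600, 10))
  egm <- average_one(as.numeric(tr))
  d <- delineate_egm(egm)
  d <- assess_quality(egm, d)
  expect_match(d$quality, "rejected")

  clean <- average_one(canonical_egm(at = 40, rt = 290)$trace)
  dc <- assess_quality(clean, delineate_egm(clean))
  expect_identical(dc$quality, "accepted")
})

test_that("injected triphasic T waves are rejected, clean nodes kept", {
  # cohort of 40 averaged EGMs, 25% injected with a 3-lobed T wave
  qualities <- character(0)
  injected <- logical(0)
  for (i in 1:40) {
    bad <- i %% 4 == 0
    fx <- canonical_egm(at = 40, rt = 280, noise = 0.01, seed = 300 + i)
    tr <- fx$trace
    if (bad) {
      # superimpose two extra opposed lobes after the main T
      t <- seq_along(tr)
      for (o in fx$onsets) {
        idx <- o + 300:420
        tr[idx] <- tr[idx] + 0.25 * sin(2 * pi * (0:120) / 80)
      }
    }
    egm <- average_one(tr)
    d <- assess_quality(egm, delineate_egm(egm))
    qualities <- c(qualities, d$quality)
    injected <- c(injected, bad)
  }
  expect_gte(mean(qualities[injected] != "accepted"), 0.9)
  expect_lte(mean(qualities[!injected] != "accepted"), 0.05)
})
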