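test_that("metric sampler is seeded, respects degenerate SDs, and matches its moments", {
  presets <- test_presets()
  a <- sample_subject_metrics(presets, "HCM", "recovery", n = 8, seed = 5)
  b <- sample_subject_metrics(presets, "HCM", "recovery", n = 8, seed = 5)
  expect_identical(a, b)

  # zero-SD preset: every subject equals the preset means exactly
  p0 <- presets
  for (m in names(p0$groups$HCM$recovery))
    p0$groups$HCM$recovery[[m]]$sd <- 0
  z <- sample_subject_metrics(p0, "HCM", "recovery", n = 5, seed = 1)
  expect_equal(unique(z$recovery_mean_at), 58.6)
  expect_equal(unique(z$recovery_mean_ari), 275.5)

  # law-of-large-numbers check against the sampler's own parameters
  big <- sample_subject_metrics(presets, "HCM_VF", "recovery", n = 100000,
                                seed = 9,
                                measures = c("mean_at", "mean_ari"))
  expect_equal(mean(big$recovery_mean_at), 64.4, tolerance = 0.01 * 64.4)
  expect_equal(sd(big$recovery_mean_at), 7.0, tolerance = 0.01 * 7.0)
  expect_equal(cor(big$recovery_mean_at, big$recovery_mean_ari), 0.3,
               tolerance = 0.015)
})

test_that("measure correlation matrix is positive definite with the designed entries", {
  R <- measure_correlation(test_presets())
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(R["recovery_mean_at", "recovery_mean_ari"], 0.3,
               tolerance = 0.02)
  expect_equal(R["peak_mean_at", "recovery_mean_at"], 0.93, tolerance = 0.02)
})

test_that("calibrated truth fields match their targets and keep ARI positive", {
  mesh <- mesh_spheroid()
  grad_fn <- epimapr:::gradient_operator(mesh, 5)
  targets <- list(mean_at = 60.1, disp_at = 55.2, grad_at = 0.40,
                  mean_ari = 227.2, disp_ari = 82, grad_ari = 1.72)
  tr <- build_truth_fields(targets, mesh, seed = 3,
                           field_cfg = test_presets()$field,
                           grad_fn = grad_fn)
  ach <- tr$achieved
  expect_equal(ach$mean_at, 60.1, tolerance = 0.5)
  expect_equal(ach$disp_at, 55.2, tolerance = max(0.02 * 55.2, 0.5))
  expect_equal(ach$grad_at, 0.40, tolerance = max(0.02 * 0.40, 0.01))
  expect_equal(ach$mean_ari, 227.2, tolerance = 0.5)
  expect_equal(ach$grad_ari, 1.72, tolerance = max(0.02 * 1.72, 0.01))
  expect_true(all(tr$ari_ms > 0))
  expect_equal(tr$rt_ms, tr$at_ms + tr$ari_ms)
})

test_that("apical ARI prolongation raises the apical third above the basal third", {
  mesh <- mesh_spheroid()
  grad_fn <- epimapr:::gradient_operator(mesh, 5)
  targets <- list(mean_at = 58, disp_at = 50, grad_at = 0.4,
                  mean_ari = 230, disp_ari = 80, grad_ari = 1.7)
  tr <- build_truth_fields(targets, mesh, list(apical_ari = TRUE), seed = 4,
                           field_cfg = test_presets()$field,
                           grad_fn = grad_fn)
  ab <- epimapr:::apicobasal_coord(mesh)
  expect_gt(mean(tr$ari_ms[ab < 1/3]), mean(tr$ari_ms[ab > 2/3]) + 10)
})

test_that("beat trains place both slope events exactly and count their beats", {
  p <- waveform_params(noise_sd_mv = 0, wander_amp_mv = 0)
  tr <- synthesize_beat_train(40, 290, 1, p, rr_ms = rep(600, 10), seed = 1)
  # duration arithmetic: 10 beats at RR 600 plus padding
  expect_gte(length(tr), 6000)
  # threshold counting of QRS complexes
  expect_length(detect_beats(as.numeric(tr), 1000), 10)
  # numerical-derivative oracle on one beat: steepest slopes at AT and RT
  o <- attr(tr, "onsets")[3]
  beat <- as.numeric(tr)[o:(o + 500)]
  dv <- diff(beat)
  expect_equal(which.min(dv), 40 + 1, tolerance = 1)
  twin <- 200:420
  expect_equal(twin[which.max(dv[twin])], 290, tolerance = 1)
  expect_error(synthesize_beat_train(100, 90, 1, p), "positive ARI")
  expect_error(synthesize_beat_train(40, 590, 1, p, rr_ms = rep(600, 5)),
               "outside the beat period")
})

test_that("full subject extraction recovers the truth metrics at default noise", {
  mesh <- mesh_spheroid()
  presets <- test_presets()
  grad_fn <- epimapr:::gradient_operator(mesh, 5)
  nbr <- epimapr:::neighbor_index(mesh, 5)
  biases <- sapply(1:6, function(i) {
    sim <- simulate_subject(presets, "HCM_pooled", "peak", mesh,
                            seed = 4000 + i, grad_fn = grad_fn)
    pr <- process_subject(sim$signals, sim$fs, mesh, nbr = nbr)
    c(at = pr$metrics$mean_at - sim$truth$achieved$mean_at,
      ari = pr$metrics$mean_ari - sim$truth$achieved$mean_ari,
      grad = pr$metrics$grad_at - sim$truth$achieved$grad_at)
  })
  expect_lt(abs(mean(biases["at", ])), 2)
  expect_lt(abs(mean(biases["ari", ])), 3)
  expect_lt(abs(mean(biases["grad", ])), 0.05)
})

test_that("cohort generation is reproducible and writes the documented artifacts", {
  presets <- test_presets()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(presets, c(HCM_VF = 17, HCM = 20), out_dir = d1,
                  seed = 11, mode = "metrics")
  generate_cohort(presets, c(HCM_VF = 17, HCM = 20), out_dir = d2,
                  seed = 11, mode = "metrics")
  f1 <- utils::read.csv(file.path(d1, "feature_table.csv"))
  f2 <- utils::read.csv(file.path(d2, "feature_table.csv"))
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 37)
  expect_equal(sum(f1$group == "HCM_VF"), 17)
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(m1$preset_sha, m2$preset_sha)
  expect_identical(m1$seed, m2$seed)
})

test_that("waveform-mode cohorts carry one signal column per mesh node", {
  presets <- test_presets()
  mesh <- small_spheroid()
  d <- withr::local_tempdir()
  generate_cohort(presets, c(control = 1), mesh = mesh, out_dir = d,
                  seed = 21, mode = "waveform", phases = "peak")
  sig <- utils::read.csv(list.files(d, "_signals\\.csv$", full.names = TRUE)[1])
  expect_equal(ncol(sig), nrow(mesh$vertices))
  truth <- utils::read.csv(list.files(d, "_truth\\.csv$", full.names = TRUE)[1])
  expect_equal(nrow(truth), nrow(mesh$vertices))
  expect_true(all(truth$ari_ms > 0))
})
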